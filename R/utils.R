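# Shared helpers: typed error conditions, seed scoping, numeric checks.

stop_domain <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("maizeNrec_domain_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_input <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("maizeNrec_input_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop_domain(sprintf("`%s` must be a non-missing number", name))
  }
  lo_bad <- if (strict_min) any(x <= min) else any(x < min)
  hi_bad <- if (strict_max) any(x >= max) else any(x > max)
  if (lo_bad || hi_bad) {
    stop_domain(sprintf(
      "`%s` must lie in %s%g, %g%s (got %s)",
      name,
      if (strict_min) "(" else "[", min, max, if (strict_max) ")" else "]",
      paste(signif(x[lo_bad | hi_bad | is.infinite(x)][1], 6), collapse = ", ")
    ))
  }
  invisible(x)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

#' Relative difference in percent
#'
#' Percentage difference of `value` relative to `reference`,
#' `100 * (value - reference) / reference`, reported to 0.1 of a percent.
#' This is the form used when comparing a treatment's index against the
#' conventional blanket fertilizer schedule (RDF).
#'
#' @param value Numeric value(s) to compare.
#' @param reference Non-zero reference value(s).
#' @return Percentage difference rounded to one decimal place.
#' @examples
#' relative_difference_pct(1.40, 1.18) # 18.6
#' @export
relative_difference_pct <- function(value, reference) {
  if (any(reference == 0, na.rm = TRUE)) {
    stop_domain("`reference` must be non-zero")
  }
  round(100 * (value - reference) / reference, 1)
}
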