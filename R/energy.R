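# Energy-input accounting: coefficient-weighted inventory totals with
# direct/indirect and renewable/non-renewable splits.

# Category memberships used throughout: labour, fuel and electricity are
# direct energy; seeds, fertilizers, machinery and chemicals indirect;
# seeds and labour count as renewable.
.direct_classes <- c("labour", "fuel", "electricity")
.indirect_classes <- c("seed", "fertilizer", "machinery", "chemical")
.renewable_classes <- c("seed", "labour")

#' Aggregate energy inputs
#'
#' Multiplies each inventory quantity by its energy coefficient
#' (MJ per unit) and totals the result, with subtotals by the two
#' standard partitions: direct (labour, fuel, electricity) versus
#' indirect (seeds, fertilizers, machinery, chemicals) energy, and
#' renewable (seeds, labour) versus non-renewable sources. Both
#' partitions always sum to the grand total.
#'
#' @param inventory Data frame with columns `item` and `quantity`
#'   (amount applied per hectare, in the coefficient's unit).
#' @param coefficients Data frame with columns `item`,
#'   `mj_per_unit` and `class` (one of labour, fuel, electricity, seed,
#'   fertilizer, machinery, chemical). Every inventory item must have a
#'   coefficient. See [demo_energy_coefficients()] for a demo table.
#' @return An object of class `energy_summary`: `total_mj`,
#'   `direct_mj`, `indirect_mj`, `renewable_mj`, `nonrenewable_mj` and
#'   the per-item breakdown.
#' @export
energy_input <- function(inventory, coefficients) {
  if (nrow(inventory) == 0) {
    return(structure(
      list(total_mj = 0, direct_mj = 0, indirect_mj = 0,
           renewable_mj = 0, nonrenewable_mj = 0,
           items = data.frame(item = character(), mj = numeric())),
      class = "energy_summary"
    ))
  }
  if (!all(c("item", "quantity") %in% names(inventory))) {
    stop_input("`inventory` needs columns item, quantity")
  }
  if (!all(c("item", "mj_per_unit", "class") %in% names(coefficients))) {
    stop_input("`coefficients` needs columns item, mj_per_unit, class")
  }
  idx <- match(inventory$item, coefficients$item)
  if (anyNA(idx)) {
    stop_input(sprintf(
      "no energy coefficient for item(s): %s",
      paste(inventory$item[is.na(idx)], collapse = ", ")
    ))
  }
  cls <- coefficients$class[idx]
  bad <- !cls %in% c(.direct_classes, .indirect_classes)
  if (any(bad)) {
    stop_input(sprintf("unknown energy class(es): %s",
                       paste(unique(cls[bad]), collapse = ", ")))
  }
  mj <- inventory$quantity * coefficients$mj_per_unit[idx]
  structure(
    list(
      total_mj = sum(mj),
      direct_mj = sum(mj[cls %in% .direct_classes]),
      indirect_mj = sum(mj[cls %in% .indirect_classes]),
      renewable_mj = sum(mj[cls %in% .renewable_classes]),
      nonrenewable_mj = sum(mj[!cls %in% .renewable_classes]),
      items = data.frame(item = inventory$item, class = cls, mj = mj)
    ),
    class = "energy_summary"
  )
}

#' @export
print.energy_summary <- function(x, ...) {
  cat(sprintf(
    "Energy input %.1f MJ/ha (direct %.1f + indirect %.1f; renewable %.1f + non-renewable %.1f)\n",
    x$total_mj, x$direct_mj, x$indirect_mj, x$renewable_mj, x$nonrenewable_mj
  ))
  invisible(x)
}

#' Demo energy-coefficient table
#'
#' Loads the demo coefficient table shipped with the package
#' (`inst/extdata/energy_coefficients_demo.csv`). These are
#' illustrative round-number values for examples and tests only; for
#' real accounting supply your own coefficient table from an
#' authoritative source.
#'
#' @return Data frame with columns `item`, `mj_per_unit`, `unit`,
#'   `class`.
#' @export
demo_energy_coefficients <- function() {
  path <- system.file("extdata", "energy_coefficients_demo.csv",
                      package = "maizeNrec", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
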