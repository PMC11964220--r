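# Dark green colour index (DGCI): RGB -> hue/saturation/brightness -> DGCI,
# per-pixel and aggregated over a leaf mask.

#' Convert normalized RGB to hue/saturation/brightness
#'
#' Implements the piecewise hue formula of the HSB (HSV) colour space on
#' normalized channels: brightness `B = max(R, G, Bl)`, chroma
#' `C = max - min`, saturation `S = C / B` (0 when `B = 0`), and hue
#' computed from the branch belonging to the maximal channel
#' (`60 * (G - Bl) / C` at max red, `60 * (2 + (Bl - R) / C)` at max green,
#' `60 * (4 + (R - G) / C)` at max blue), taken modulo 360 into
#' `[0, 360)`. Hue is undefined (`NA`) for achromatic pixels
#' (chroma zero).
#'
#' @param r,g,b Numeric vectors of equal length with normalized red,
#'   green and blue levels in `[0, 1]`. 8-bit values must be divided by
#'   255 before use.
#' @return A data frame with columns `h` (degrees in `[0, 360)`, `NA`
#'   when undefined), `s` and `b` (both in `[0, 1]`).
#' @examples
#' rgb_to_hsb(0, 1, 0)           # pure green: h = 120
#' rgb_to_hsb(0.5, 0.5, 0.5)     # grey: hue undefined
#' @export
rgb_to_hsb <- function(r, g, b) {
  n <- length(r)
  if (length(g) != n || length(b) != n) {
    stop_input("`r`, `g` and `b` must have equal length")
  }
  for (nm in c("r", "g", "b")) {
    x <- get(nm)
    if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
      stop_domain(sprintf("channel `%s` must lie in [0, 1]", nm))
    }
  }
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  ch <- mx - mn
  s <- ifelse(mx > 0, ch / mx, 0)
  h <- rep(NA_real_, n)
  chromatic <- ch > 0
  # branch on which channel attains the maximum (ties give equal hue)
  is_r <- chromatic & mx == r
  is_g <- chromatic & !is_r & mx == g
  is_b <- chromatic & !is_r & !is_g
  h[is_r] <- 60 * (g[is_r] - b[is_r]) / ch[is_r]
  h[is_g] <- 60 * (2 + (b[is_g] - r[is_g]) / ch[is_g])
  h[is_b] <- 60 * (4 + (r[is_b] - g[is_b]) / ch[is_b])
  h <- h %% 360
  data.frame(h = h, s = s, b = mx)
}

#' Convert hue/saturation/brightness back to RGB
#'
#' Inverse of [rgb_to_hsb()], using the standard sector decomposition of
#' the hue circle. Used by the synthetic leaf-image generator, which
#' samples colours directly in HSB space.
#'
#' @param h Hue in degrees (any real; reduced modulo 360).
#' @param s,b Saturation and brightness in `[0, 1]`.
#' @return Data frame with columns `r`, `g`, `b` in `[0, 1]`.
#' @export
hsb_to_rgb <- function(h, s, b) {
  check_number(s, "s", 0, 1)
  check_number(b, "b", 0, 1)
  h <- (h %% 360) / 60
  c_ <- b * s
  x <- c_ * (1 - abs(h %% 2 - 1))
  m <- b - c_
  sector <- floor(h) %% 6
  # channel pattern per sector: 1 -> chroma, 2 -> x, 0 -> 0
  pick <- function(code) ifelse(code == 1, c_, ifelse(code == 2, x, 0))
  rgb_sector <- rbind(
    c(1, 2, 0), c(2, 1, 0), c(0, 1, 2),
    c(0, 2, 1), c(2, 0, 1), c(1, 0, 2)
  )
  idx <- sector + 1
  data.frame(
    r = pick(rgb_sector[idx, 1]) + m,
    g = pick(rgb_sector[idx, 2]) + m,
    b = pick(rgb_sector[idx, 3]) + m
  )
}

#' Per-pixel dark green colour index
#'
#' DGCI maps leaf greenness onto a scale correlated with leaf nitrogen:
#' `DGCI = [(H/60 - 1) + (1 - S) + (1 - B)] / 3`. Pure green
#' (`h = 120, s = 1, b = 1`) gives 1/3; a fully saturated yellow
#' (`h = 60`) gives 0. No clamping is applied: for hue in `[0, 360)` the
#' mathematical range is `[-1/3, 4/3]`, and restricting aggregation to
#' the green-yellow hue band is the caller's choice (see
#' [image_dgci()]).
#'
#' @param h Hue in degrees; `NA` marks an undefined (achromatic) hue and
#'   propagates as `NA` rather than an error, so such pixels can be
#'   excluded from aggregation.
#' @param s,b Saturation and brightness in `[0, 1]`.
#' @return Numeric vector of DGCI values (`NA` where hue is undefined).
#' @examples
#' pixel_dgci(120, 1, 1) # 1/3
#' pixel_dgci(60, 1, 1)  # 0
#' @export
pixel_dgci <- function(h, s, b) {
  check_number(s, "s", 0, 1)
  check_number(b, "b", 0, 1)
  ((h / 60 - 1) + (1 - s) + (1 - b)) / 3
}

#' Construct a leaf image object
#'
#' A minimal container for an 8-bit-derived RGB image: a
#' `height x width x 3` array of normalized channels plus an optional
#' logical leaf mask of the same spatial dimensions.
#'
#' @param pixels Numeric array `[height, width, 3]` with values in
#'   `[0, 1]`.
#' @param mask Optional logical matrix `[height, width]`; `TRUE` marks
#'   leaf pixels.
#' @param source Optional source path or label.
#' @param meta Optional list of free-form capture metadata.
#' @return An object of class `leaf_image`.
#' @export
leaf_image <- function(pixels, mask = NULL, source = NA_character_,
                       meta = list()) {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    stop_input("`pixels` must be a height x width x 3 array")
  }
  if (min(pixels) < 0 || max(pixels) > 1) {
    stop_domain("pixel channels must lie in [0, 1]")
  }
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), dim(pixels)[1:2])) {
      stop_input("`mask` must be a logical matrix matching the pixel grid")
    }
  }
  structure(
    list(pixels = pixels, mask = mask, source = source, meta = meta),
    class = "leaf_image"
  )
}

#' @export
print.leaf_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<leaf_image> %d x %d pixels%s%s\n", d[1], d[2],
    if (!is.null(x$mask)) sprintf(", mask (%d leaf px)", sum(x$mask)) else "",
    if (!is.na(x$source)) paste0(", from ", x$source) else ""
  ))
  invisible(x)
}

#' Read a PNG or JPEG leaf photograph
#'
#' Reads an 8-bit RGB image into a [leaf_image()]. An alpha channel, if
#' present, is dropped with a warning; greyscale images are expanded to
#' three identical channels.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return A `leaf_image`.
#' @export
read_leaf_image <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("no such image file: %s", path))
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop_input(sprintf("unsupported image format `.%s` (need PNG or JPEG)", ext))
  )
  if (length(dim(px)) == 2) {
    px <- array(rep(px, 3), dim = c(dim(px), 3))
  } else if (dim(px)[3] == 4) {
    warning("alpha channel dropped from ", path)
    px <- px[, , 1:3, drop = FALSE]
  } else if (dim(px)[3] == 2) {
    warning("alpha channel dropped from ", path)
    px <- array(rep(px[, , 1], 3), dim = c(dim(px)[1:2], 3))
  }
  leaf_image(px, source = path)
}

#' Write a leaf image to PNG
#'
#' @param img A [leaf_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_leaf_png <- function(img, path) {
  stopifnot(inherits(img, "leaf_image"))
  png::writePNG(img$pixels, path)
  invisible(path)
}

#' Segment the leaf from its background
#'
#' A deliberately simple, fully configurable rule: a pixel belongs to
#' the leaf when green strictly dominates both red and blue and its
#' brightness (max channel) lies within configurable bounds. This is
#' generic green-vegetation thresholding, not a reconstruction of any
#' particular phone app's internal segmentation.
#'
#' @param img A [leaf_image()].
#' @param min_brightness,max_brightness Brightness bounds in `[0, 1]`.
#' @return Logical matrix marking leaf pixels.
#' @export
segment_leaf <- function(img, min_brightness = 0.05, max_brightness = 1) {
  stopifnot(inherits(img, "leaf_image"))
  check_number(min_brightness, "min_brightness", 0, 1)
  check_number(max_brightness, "max_brightness", 0, 1)
  px <- img$pixels
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  bright <- pmax(r, g, b)
  mask <- g > r & g > b & bright >= min_brightness & bright <= max_brightness
  if (!any(mask)) {
    stop_domain(sprintf(
      "no leaf pixels found (green-dominant, brightness in [%g, %g])",
      min_brightness, max_brightness
    ))
  }
  mask
}

#' Image-level DGCI summary
#'
#' Converts every masked pixel to HSB, computes per-pixel DGCI and
#' aggregates. Achromatic pixels (undefined hue) are excluded from the
#' mean rather than assigned a default hue, since any default would bias
#' the index. Optionally the aggregation is restricted to a hue band
#' (e.g. `c(60, 180)`, the green-yellow band the index was designed
#' for) to guard against sky or soil pixels that slip through the mask.
#'
#' @param img A [leaf_image()].
#' @param mask Logical matrix of leaf pixels; defaults to the image's
#'   own mask, or the full image when neither is present.
#' @param hue_band Optional length-2 numeric; only pixels with hue in
#'   `[hue_band[1], hue_band[2]]` enter the aggregation.
#' @return An object of class `dgci_summary`: `mean_dgci`, `dgci_sd`,
#'   `pixel_count` (pixels used) and `excluded_count` (out-of-mask,
#'   achromatic or out-of-band pixels).
#' @export
image_dgci <- function(img, mask = NULL, hue_band = NULL) {
  stopifnot(inherits(img, "leaf_image"))
  if (is.null(mask)) mask <- img$mask
  d <- dim(img$pixels)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (!identical(dim(mask), d[1:2])) {
    stop_input("`mask` dimensions do not match the image")
  }
  total <- prod(d[1:2])
  idx <- which(mask)
  r <- img$pixels[, , 1][idx]
  g <- img$pixels[, , 2][idx]
  b <- img$pixels[, , 3][idx]
  hsb <- rgb_to_hsb(r, g, b)
  keep <- !is.na(hsb$h)
  if (!is.null(hue_band)) {
    stopifnot(length(hue_band) == 2)
    keep <- keep & hsb$h >= hue_band[1] & hsb$h <= hue_band[2]
  }
  if (!any(keep)) stop_domain("no leaf pixels with defined hue to aggregate")
  dg <- pixel_dgci(hsb$h[keep], hsb$s[keep], hsb$b[keep])
  structure(
    list(
      mean_dgci = mean(dg),
      dgci_sd = stats::sd(dg),
      pixel_count = length(dg),
      excluded_count = total - length(dg)
    ),
    class = "dgci_summary"
  )
}

#' @export
print.dgci_summary <- function(x, ...) {
  cat(sprintf(
    "DGCI %.4f (sd %.4f) over %d leaf pixels (%d excluded)\n",
    x$mean_dgci, ifelse(is.na(x$dgci_sd), 0, x$dgci_sd),
    x$pixel_count, x$excluded_count
  ))
  invisible(x)
}
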