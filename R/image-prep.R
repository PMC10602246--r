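#' Split an RGB image into its three channel grids
#'
#' @param image a `skin_image` or an H x W x 3 array of 8-bit intensities.
#' @return a named list `red`, `green`, `blue` of H x W integer matrices.
#' @export
split_channels <- function(image) {
  px <- if (inherits(image, "skin_image")) image$pixels else image
  if (length(dim(px)) != 3 || dim(px)[3] != 3)
    stop("expected an H x W x 3 image")
  list(red = px[, , 1], green = px[, , 2], blue = px[, , 3])
}

#' Crop a centred circular region of interest
#'
#' The mask is true exactly where the Euclidean distance from the image
#' centre, taken at `((H - 1) / 2, (W - 1) / 2)` in 0-based pixel
#' coordinates, is `<= radius` pixels. Pixels outside the mask are excluded
#' from all later co-occurrence counting.
#'
#' @param values an H x W intensity matrix (one channel).
#' @param radius ROI radius in pixels; `2 * radius` must not exceed the
#'   smaller image dimension. Default 300, the capture-device ROI used to
#'   cut away the vignetted image periphery.
#' @return a list with `values` (unchanged) and logical `mask`.
#' @export
crop_circular_roi <- function(values, radius = 300) {
  h <- nrow(values); w <- ncol(values)
  if (2 * radius > min(h, w))
    stop("ROI radius ", radius, " too large for a ", h, " x ", w, " image")
  rc <- (h - 1) / 2; cc <- (w - 1) / 2
  d2 <- outer((0:(h - 1) - rc)^2, (0:(w - 1) - cc)^2, "+")
  list(values = values, mask = d2 <= radius^2)
}

#' Quantize intensities to Ng grey levels over the fixed 8-bit range
#'
#' `level = floor(v * Ng / 256) + 1`, so for the default `Ng = 64` each
#' level spans four intensity units and `v = 0 -> 1`, `v = 255 -> 64`. The
#' map is fixed over `[0, 255]` (not per-image min-max) so that
#' delta-radiomics ratios across timepoints compare like with like.
#'
#' @param values H x W matrix of intensities in `[0, 255]`.
#' @param mask logical matrix from [crop_circular_roi()].
#' @param ng number of grey levels (>= 2), default 64.
#' @return a `masked_level_grid`: list with `levels` (integer matrix, `NA`
#'   outside the mask), `mask` and `ng`.
#' @export
quantize_levels <- function(values, mask, ng = 64) {
  if (ng < 2) stop("ng must be >= 2")
  if (any(values < 0 | values > 255)) stop("intensities must lie in [0, 255]")
  lv <- matrix(as.integer(floor(values * ng / 256) + 1), nrow(values), ncol(values))
  lv[!mask] <- NA_integer_
  structure(list(levels = lv, mask = mask, ng = as.integer(ng)),
            class = "masked_level_grid")
}
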