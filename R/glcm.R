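#' GLCM construction parameters
#'
#' @param ng number of quantized grey levels (default 64).
#' @param d displacement in pixels (default 1).
#' @param angles offset angles in degrees, a subset of `c(0, 45, 90, 135)`.
#' @param symmetric accumulate each pixel pair in both directions (default
#'   `TRUE`), making 0 and 180 degrees equivalent.
#' @param dialect feature dialect: `"matlab_toolbox"` reproduces the
#'   conventions of the widely circulated MATLAB GLCM feature code
#'   (difference variance identical to contrast; variance centred on the
#'   mean of the matrix entries; sum variance centred on the sum entropy);
#'   `"haralick_1973"` uses the original textbook centrings.
#' @param roi_radius circular ROI radius in pixels applied before
#'   quantization (default 300).
#' @return an object of class `glcm_params`.
#' @export
glcm_params <- function(ng = 64, d = 1, angles = c(0, 45, 90, 135),
                        symmetric = TRUE,
                        dialect = c("matlab_toolbox", "haralick_1973"),
                        roi_radius = 300) {
  if (d < 1) stop("displacement d must be >= 1")
  if (!all(angles %in% c(0, 45, 90, 135)))
    stop("angles must be a subset of {0, 45, 90, 135}")
  structure(list(ng = as.integer(ng), d = as.integer(d), angles = angles,
                 symmetric = isTRUE(symmetric), dialect = match.arg(dialect),
                 roi_radius = roi_radius),
            class = "glcm_params")
}

#' The 18 texture feature names, in canonical order
#' @export
haralick_feature_names <- function() {
  c("autocorrelation", "contrast", "correlation", "cluster_prominence",
    "cluster_shade", "dissimilarity", "energy", "entropy", "homogeneity",
    "maximum_probability", "variance", "sum_average", "sum_variance",
    "sum_entropy", "difference_variance", "difference_entropy",
    "imc1", "imc2")
}

# (row, col) offset for an angle in degrees, displacement d
angle_offset <- function(angle, d) {
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("unsupported angle: ", angle))
}

#' Compute a normalized grey-level co-occurrence matrix
#'
#' Counts every ordered pixel pair `(a, a + offset)` with both pixels inside
#' the mask; in symmetric mode the reversed pair is counted too. The matrix
#' is normalized to sum to one.
#'
#' @param grid a `masked_level_grid` from [quantize_levels()].
#' @param params a [glcm_params()]; `grid$ng` must match `params$ng`.
#' @param angle one of the configured angles, in degrees.
#' @return a `glcm_matrix`: list with `p` (Ng x Ng, sums to 1), `params`,
#'   `angle` and `pair_count` (number of accumulated pairs, including the
#'   mirrored ones when symmetric).
#' @export
compute_glcm <- function(grid, params = glcm_params(), angle = 0) {
  stopifnot(inherits(grid, "masked_level_grid"))
  if (grid$ng != params$ng) stop("grid ng does not match params ng")
  if (!angle %in% params$angles) stop("angle ", angle, " not in params$angles")
  off <- angle_offset(angle, params$d)
  lv <- grid$levels
  h <- nrow(lv); w <- ncol(lv)
  r1 <- max(1, 1 - off[1]):min(h, h - off[1])
  c1 <- max(1, 1 - off[2]):min(w, w - off[2])
  i <- lv[r1, c1, drop = FALSE]
  j <- lv[r1 + off[1], c1 + off[2], drop = FALSE]
  ok <- !is.na(i) & !is.na(j)
  if (!any(ok)) stop("no valid pixel pair: mask too small for offset")
  ng <- grid$ng
  counts <- matrix(tabulate((i[ok] - 1L) * ng + j[ok], nbins = ng * ng),
                   ng, ng, byrow = TRUE)
  if (params$symmetric) counts <- counts + t(counts)
  total <- sum(counts)
  structure(list(p = counts / total, params = params, angle = angle,
                 pair_count = total),
            class = "glcm_matrix")
}

#' Compute the 18 Haralick-type texture features of a GLCM
#'
#' Uses the marginal distributions `p_x`, `p_y`, the sum distribution
#' `p_{x+y}` and the difference distribution `p_{x-y}` of the normalized
#' matrix; all entropies use the natural logarithm with `0 log 0 = 0`. On a
#' degenerate single-cell matrix, correlation and IMC 1 are undefined
#' (zero marginal variance / zero marginal entropy) and are returned as
#' `NA` with a warning.
#'
#' @param glcm a `glcm_matrix` from [compute_glcm()].
#' @return a named numeric vector of the 18 features
#'   (see [haralick_feature_names()]).
#' @export
haralick_features <- function(glcm) {
  stopifnot(inherits(glcm, "glcm_matrix"))
  p <- glcm$p
  ng <- nrow(p)
  iv <- seq_len(ng)
  I <- matrix(iv, ng, ng)        # row index i
  J <- t(I)                      # col index j

  px <- rowSums(p); py <- colSums(p)
  mux <- sum(iv * px); muy <- sum(iv * py)
  sx <- sqrt(sum((iv - mux)^2 * px)); sy <- sqrt(sum((iv - muy)^2 * py))

  psum <- as.vector(rowsum(as.vector(p), group = as.vector(I + J)))   # k = 2..2Ng
  ks <- 2:(2 * ng)
  pdiff <- as.vector(rowsum(as.vector(p), group = as.vector(abs(I - J))))  # k = 0..Ng-1
  kd <- 0:(ng - 1)

  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  HX <- -sum(xlogx(px)); HY <- -sum(xlogx(py))
  HXY <- -sum(xlogx(p))
  pxpy <- outer(px, py)
  HXY1 <- -sum(p[pxpy > 0] * log(pxpy[pxpy > 0]))
  HXY2 <- -sum(xlogx(pxpy))

  autoc <- sum(I * J * p)
  contrast <- sum((I - J)^2 * p)
  correlation <- if (sx > 0 && sy > 0) (autoc - mux * muy) / (sx * sy) else {
    warning("degenerate GLCM: correlation undefined (zero marginal variance)")
    NA_real_
  }
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else {
    warning("degenerate GLCM: IMC 1 undefined (zero marginal entropy)")
    NA_real_
  }

  sum_entropy <- -sum(xlogx(psum))
  sum_average <- sum(ks * psum)

  out <- c(
    autocorrelation = autoc,
    contrast = contrast,
    correlation = correlation,
    cluster_prominence = sum((I + J - mux - muy)^4 * p),
    cluster_shade = sum((I + J - mux - muy)^3 * p),
    dissimilarity = sum(abs(I - J) * p),
    energy = sum(p^2),
    entropy = HXY,
    homogeneity = sum(p / (1 + abs(I - J))),
    maximum_probability = max(p),
    variance = NA_real_,
    sum_average = sum_average,
    sum_variance = NA_real_,
    sum_entropy = sum_entropy,
    difference_variance = NA_real_,
    difference_entropy = -sum(xlogx(pdiff)),
    imc1 = imc1,
    imc2 = sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY))))
  )
  if (glcm$params$dialect == "matlab_toolbox") {
    out["variance"] <- sum((I - mean(p))^2 * p)
    out["sum_variance"] <- sum((ks - sum_entropy)^2 * psum)
    out["difference_variance"] <- sum(kd^2 * pdiff)
  } else {
    mu_d <- sum(kd * pdiff)
    out["variance"] <- sum((I - mux)^2 * p)
    out["sum_variance"] <- sum((ks - sum_average)^2 * psum)
    out["difference_variance"] <- sum((kd - mu_d)^2 * pdiff)
  }
  out[haralick_feature_names()]
}

#' Average feature vectors feature by feature
#'
#' Elementwise arithmetic mean over a list of 18-feature vectors (one per
#' offset angle, or one per channel). Degenerate (`NA`) entries are skipped
#' with a warning; a feature degenerate in every vector stays `NA`.
#'
#' @param vectors non-empty list of named feature vectors.
#' @return one named feature vector.
#' @export
average_feature_vectors <- function(vectors) {
  if (length(vectors) == 0) stop("empty list of feature vectors")
  m <- do.call(rbind, vectors)
  if (anyNA(m))
    warning("degenerate feature values skipped in averaging")
  out <- colMeans(m, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Extract the 18-feature vector of one RGB image
#'
#' For each channel: crop the centred circular ROI, quantize to `ng`
#' levels, compute the GLCM at each configured angle, compute the features
#' and average them over angles; then average the per-channel vectors.
#' The averaging order (angles first, then channels) is fixed. When the
#' three channels are identical the computation is done once.
#'
#' @param image a `skin_image` (or H x W x 3 array).
#' @param params a [glcm_params()].
#' @param per_channel if `TRUE`, also return the per-channel (angle-averaged)
#'   vectors in an attribute `"channels"` for debugging.
#' @return a named numeric vector of 18 features.
#' @export
extract_image_features <- function(image, params = glcm_params(),
                                   per_channel = FALSE) {
  ch <- split_channels(image)
  same <- identical(ch$red, ch$green) && identical(ch$red, ch$blue)
  channel_vec <- function(values) {
    roi <- crop_circular_roi(values, params$roi_radius)
    grid <- quantize_levels(roi$values, roi$mask, params$ng)
    average_feature_vectors(lapply(params$angles, function(a)
      haralick_features(compute_glcm(grid, params, a))))
  }
  vecs <- if (same) {
    v <- channel_vec(ch$red)
    list(red = v, green = v, blue = v)
  } else {
    lapply(ch, channel_vec)
  }
  out <- average_feature_vectors(vecs)
  if (per_channel) attr(out, "channels") <- vecs
  out
}
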