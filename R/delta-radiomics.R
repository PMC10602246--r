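FEATURE_KEYS <- c("patient_id", "side", "point_site", "mode", "timepoint")

#' Build the longitudinal feature table of a cohort
#'
#' Runs [extract_image_features()] on every image of a cohort manifest.
#' Images are read from `path` when the manifest has one, otherwise rendered
#' on the fly from the synthetic configuration (keeping memory flat for
#' large cohorts).
#'
#' @param cohort a list as returned by [generate_cohort()] (`manifest`,
#'   `doses`, `config`), or a manifest data.frame with a `path` column.
#' @param params a [glcm_params()].
#' @param verbose print progress every 200 images.
#' @return a data.frame with the key columns (`patient_id`, `side`,
#'   `point_site`, `mode`, `timepoint`) and 18 feature columns; one row per
#'   image.
#' @export
build_feature_table <- function(cohort, params = glcm_params(), verbose = FALSE) {
  manifest <- if (is.data.frame(cohort)) cohort else cohort$manifest
  config <- if (is.data.frame(cohort)) NULL else cohort$config
  key <- do.call(paste, manifest[FEATURE_KEYS])
  if (anyDuplicated(key))
    stop("duplicate (patient, side, site, mode, timepoint) keys in manifest")
  has_path <- !is.null(manifest$path)
  if (!has_path && is.null(config))
    stop("manifest has no image paths and no synthetic config was supplied")

  feats <- matrix(NA_real_, nrow(manifest), 18,
                  dimnames = list(NULL, haralick_feature_names()))
  for (r in seq_len(nrow(manifest))) {
    img <- if (has_path && !is.na(manifest$path[r])) {
      read_skin_image(manifest$path[r], manifest$patient_id[r], manifest$side[r],
                      manifest$point_site[r], manifest$mode[r], manifest$timepoint[r])
    } else {
      render_image(config, manifest$patient_id[r], manifest$side[r],
                   manifest$point_site[r], manifest$mode[r],
                   manifest$timepoint[r], manifest$dose_cGy[r])
    }
    feats[r, ] <- suppressWarnings(extract_image_features(img, params))
    if (verbose && r %% 200 == 0)
      message("  features: ", r, "/", nrow(manifest), " images")
  }
  cbind(manifest[FEATURE_KEYS], as.data.frame(feats))
}

#' Delta-radiomics: ratio of every feature to its pre-treatment baseline
#'
#' For each (patient, side, site, mode) series, divides each timepoint's
#' feature values by the same series' baseline values. Baseline rows emit
#' exactly 1. A zero or missing baseline value makes that feature's deltas
#' `NA` for the series (flagged with a warning), never zero.
#'
#' @param features a feature table from [build_feature_table()].
#' @param baseline label of the baseline timepoint (default `"Before_RT"`).
#' @return a data.frame of the same shape with feature columns replaced by
#'   ratios.
#' @export
delta_ratios <- function(features, baseline = "Before_RT") {
  fn <- haralick_feature_names()
  series <- do.call(paste, features[c("patient_id", "side", "point_site", "mode")])
  base <- features[features$timepoint == baseline, ]
  if (nrow(base) == 0) stop("no baseline (", baseline, ") rows present")
  base_key <- do.call(paste, base[c("patient_id", "side", "point_site", "mode")])
  idx <- match(series, base_key)
  if (anyNA(idx)) {
    missing_keys <- unique(series[is.na(idx)])
    stop("missing baseline record for: ", paste(missing_keys, collapse = "; "))
  }
  out <- features
  bad_base <- FALSE
  for (f in fn) {
    b <- base[[f]][idx]
    b[!is.na(b) & b == 0] <- NA_real_
    if (anyNA(b)) bad_base <- TRUE
    out[[f]] <- features[[f]] / b
  }
  out[out$timepoint == baseline, fn] <- 1   # exact, not subject to rounding
  if (bad_base)
    warning("zero or degenerate baseline values: affected deltas set to NA")
  out
}

#' Aggregate the four measurement points to one value per breast
#'
#' Arithmetic mean of the per-point deltas over the available sites, per
#' (patient, side, mode, timepoint, feature). Missing per-point values are
#' dropped from the mean; `n_points` records the contributing count per
#' feature (minimum over features shown in the column, full per-feature
#' counts in attribute `"n_points"`).
#'
#' @param deltas a delta table from [delta_ratios()] (or a raw feature
#'   table, if points are to be averaged on the raw scale).
#' @return a data.frame keyed by (`patient_id`, `side`, `mode`,
#'   `timepoint`) with 18 feature columns and `n_points`.
#' @export
aggregate_points <- function(deltas) {
  fn <- haralick_feature_names()
  keys <- c("patient_id", "side", "mode", "timepoint")
  g <- interaction(deltas[keys], drop = TRUE, lex.order = TRUE)
  vals <- as.data.frame(lapply(deltas[fn], function(v)
    as.vector(tapply(v, g, mean, na.rm = TRUE))))
  ns <- as.data.frame(lapply(deltas[fn], function(v)
    as.vector(tapply(!is.na(v), g, sum))))
  if (any(ns == 0)) warning("groups with zero contributing points: value is NA")
  head_rows <- !duplicated(g)
  out <- cbind(deltas[head_rows, keys][order(g[head_rows]), ], vals)
  rownames(out) <- NULL
  out$n_points <- do.call(pmin, ns)
  vals[ns == 0] <- NA_real_
  out[fn] <- vals
  attr(out, "n_points") <- ns
  out
}

#' Cross-patient summary: mean and SD per side, timepoint, mode and feature
#'
#' Sample SD uses the n - 1 denominator; with fewer than 2 patients the SD
#' is reported missing. Baseline cells are exactly `1 +/- 0` by the delta
#' construction.
#'
#' @param patient_values output of [aggregate_points()].
#' @return a long data.frame: `mode`, `side`, `timepoint`, `feature`,
#'   `mean`, `sd`, `n`.
#' @export
summarize_deltas <- function(patient_values) {
  fn <- haralick_feature_names()
  keys <- c("mode", "side", "timepoint")
  g <- interaction(patient_values[keys], drop = TRUE, lex.order = TRUE)
  rows <- lapply(fn, function(f) {
    v <- patient_values[[f]]
    data.frame(
      patient_values[!duplicated(g), keys][order(g[!duplicated(g)]), ],
      feature = f,
      mean = as.vector(tapply(v, g, mean, na.rm = TRUE)),
      sd = as.vector(tapply(v, g, function(x) {
        x <- x[!is.na(x)]
        if (length(x) < 2) NA_real_ else stats::sd(x)
      })),
      n = as.vector(tapply(!is.na(v), g, sum)),
      row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$feature, fn), out$mode, out$side, out$timepoint), ]
  rownames(out) <- NULL
  out
}
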