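#' Configuration for the synthetic longitudinal skin-image cohort
#'
#' Defines the study conditions the generator emulates: per-site skin doses
#' measured once on the treated breast, three imaging modes, four imaging
#' times, and a dose- and time-dependent injury signal (uniform darkening
#' plus blotchy heterogeneity) on the treated side with an attenuated,
#' dose-independent echo on the untreated side.
#'
#' @param n_patients number of patients in the cohort.
#' @param image_height,image_width image size in pixels. Defaults match the
#'   1624 x 1212 capture geometry of the handheld skin analysis device the
#'   pipeline targets.
#' @param modes character vector of imaging modes, a subset of
#'   `c("normal", "polarized", "UV")`.
#' @param timepoints ordered imaging times; the first is the pre-treatment
#'   baseline and must carry zero severity.
#' @param dose_means,dose_sds named per-site (`upper`, `lower`, `inner`,
#'   `outer`) means and SDs, in cGy, of the single-fraction surface dose
#'   sampled per patient. Defaults reproduce the published cohort means
#'   253.1 +/- 14.7, 247.8 +/- 18.1, 212.4 +/- 19.6 and 226.8 +/- 23.5 cGy.
#' @param base_mean_intensity named per-mode mean intensity (0-255) of the
#'   healthy-skin base field.
#' @param base_texture_sd SD, in intensity units, of the smooth base texture.
#' @param correlation_length spatial correlation length of the base and
#'   blotch fields, in pixels.
#' @param speckle_density fraction of pixels darkened to emulate pores.
#' @param speckle_depth intensity drop of a speckle pixel.
#' @param darkening_coefficient intensity units of uniform darkening per
#'   unit severity (kappa_dark).
#' @param heterogeneity_coefficient amplitude, in intensity units per unit
#'   severity, of the blotch field (kappa_het).
#' @param severity_profile named list (one numeric vector per mode, named by
#'   timepoint) of nonnegative severity weights `w(t)` with
#'   `w(baseline) = 0`. Defaults are monotone increasing in time, steepest
#'   in UV mode.
#' @param contralateral_attenuation gamma in `[0, 1]`: the untreated side
#'   receives severity `gamma * w(t)`, independent of dose.
#' @param channel_weights named list (per mode) of length-3 multiplicative
#'   red/green/blue channel weights; default `c(1, 1, 1)` for every mode.
#' @param seed master integer seed; every image and dose draw derives its
#'   own sub-stream from it, so cohorts are reproducible and any single
#'   image can be regenerated in isolation.
#'
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 20,
                             image_height = 1212,
                             image_width = 1624,
                             modes = c("normal", "polarized", "UV"),
                             timepoints = c("Before_RT", "RT_D7", "RT_D14", "After_RT_D10"),
                             dose_means = c(upper = 253.1, lower = 247.8,
                                            inner = 212.4, outer = 226.8),
                             dose_sds = c(upper = 14.7, lower = 18.1,
                                          inner = 19.6, outer = 23.5),
                             base_mean_intensity = c(normal = 150, polarized = 140, UV = 90),
                             base_texture_sd = 10,
                             correlation_length = 6,
                             speckle_density = 0.02,
                             speckle_depth = 40,
                             darkening_coefficient = 30,
                             heterogeneity_coefficient = 20,
                             severity_profile = NULL,
                             contralateral_attenuation = 0.25,
                             channel_weights = NULL,
                             seed = 1L) {
  sites <- c("upper", "lower", "inner", "outer")
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (image_height < 2 || image_width < 2) stop("image dimensions too small")
  modes <- match.arg(modes, c("normal", "polarized", "UV"), several.ok = TRUE)
  if (length(timepoints) < 2) stop("need at least baseline plus one time point")
  if (!all(sites %in% names(dose_means)) || !all(sites %in% names(dose_sds)))
    stop("dose_means and dose_sds must name all four sites: ",
         paste(sites, collapse = ", "))
  if (any(dose_sds < 0)) stop("dose_sds must be non-negative")
  if (any(dose_means <= 0)) stop("dose_means must be positive")
  if (!all(modes %in% names(base_mean_intensity)))
    stop("base_mean_intensity must be named per mode")
  if (contralateral_attenuation < 0 || contralateral_attenuation > 1)
    stop("contralateral_attenuation must lie in [0, 1]")

  if (is.null(severity_profile)) {
    severity_profile <- list(
      normal    = c(0, 0.5, 1.0, 1.2),
      polarized = c(0, 0.4, 0.8, 1.0),
      UV        = c(0, 0.6, 1.2, 1.5)
    )
    severity_profile <- lapply(severity_profile[modes], function(w) {
      w <- w[seq_along(timepoints)]
      stats::setNames(w, timepoints)
    })
  }
  for (m in modes) {
    w <- severity_profile[[m]]
    if (is.null(w) || !all(timepoints %in% names(w)))
      stop("severity_profile must give w(t) for every timepoint of mode ", m)
    if (w[[timepoints[1]]] != 0)
      stop("severity at the baseline timepoint must be 0 (mode ", m, ")")
    if (any(w < 0)) stop("severity weights must be non-negative (mode ", m, ")")
  }
  if (is.null(channel_weights))
    channel_weights <- stats::setNames(rep(list(c(1, 1, 1)), length(modes)), modes)

  structure(list(
    n_patients = as.integer(n_patients),
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    modes = modes,
    timepoints = timepoints,
    sites = sites,
    sides = c("ipsilateral", "contralateral"),
    dose_means = dose_means[sites],
    dose_sds = dose_sds[sites],
    base_mean_intensity = base_mean_intensity,
    base_texture_sd = base_texture_sd,
    correlation_length = correlation_length,
    speckle_density = speckle_density,
    speckle_depth = speckle_depth,
    darkening_coefficient = darkening_coefficient,
    heterogeneity_coefficient = heterogeneity_coefficient,
    severity_profile = severity_profile,
    contralateral_attenuation = contralateral_attenuation,
    channel_weights = channel_weights,
    reference_dose = mean(dose_means[sites]),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Sample per-site surface doses for one patient
#'
#' Draws one dose per measurement site (upper, lower, inner, outer) of the
#' treated breast from a normal distribution with the configured per-site
#' mean and SD, truncated at zero by redrawing. Doses are measured once per
#' patient (first treatment fraction) and reused at every imaging time.
#'
#' @param config a [synthetic_config()].
#' @param patient_id patient identifier (integer or character); together
#'   with the master seed it fully determines the draw.
#' @return a data.frame with columns `patient_id`, `point_site`, `dose_cGy`.
#' @export
sample_doses <- function(config, patient_id) {
  stopifnot(inherits(config, "synthetic_config"))
  doses <- with_local_seed(tuple_seed(config$seed, "dose", patient_id), {
    d <- stats::rnorm(4, config$dose_means, config$dose_sds)
    while (any(d <= 0))  # truncation at zero; essentially never triggers at defaults
      d[d <= 0] <- stats::rnorm(sum(d <= 0), config$dose_means[d <= 0],
                                config$dose_sds[d <= 0])
    d
  })
  data.frame(patient_id = patient_id, point_site = config$sites,
             dose_cGy = doses, row.names = NULL)
}

#' Injury severity for one side at one time
#'
#' The scalar that drives both uniform darkening and textural heterogeneity
#' in the rendered image: `w(t) * dose / reference_dose` on the treated
#' (ipsilateral) side and the dose-independent `gamma * w(t)` on the
#' untreated (contralateral) side; zero at baseline for both.
#'
#' @param config a [synthetic_config()].
#' @param side `"ipsilateral"` or `"contralateral"`.
#' @param timepoint one of the configured timepoints.
#' @param dose skin dose in cGy (ignored for the contralateral side).
#' @param mode imaging mode whose severity profile applies.
#' @return a non-negative scalar.
#' @export
severity <- function(config, side, timepoint, dose, mode = config$modes[1]) {
  stopifnot(inherits(config, "synthetic_config"))
  side <- match.arg(side, config$sides)
  mode <- match.arg(mode, config$modes)
  if (!timepoint %in% config$timepoints)
    stop("unknown timepoint: ", timepoint)
  w <- config$severity_profile[[mode]][[timepoint]]
  if (side == "ipsilateral") w * dose / config$reference_dose
  else config$contralateral_attenuation * w
}

#' Render one synthetic skin surface image
#'
#' Builds a smooth base texture field (with dark pore speckle) that is fixed
#' for a given (patient, side, site, mode) across all timepoints, then
#' subtracts `kappa_dark * severity` uniformly and
#' `kappa_het * severity * blotch` where `blotch` is an independent smooth
#' zero-mean field, clips to `[0, 255]` and applies the per-mode channel
#' weights. Deterministic given the identifiers and the master seed.
#'
#' @inheritParams severity
#' @param patient_id,point_site image identity within the design.
#' @return a `skin_image`: list with `pixels` (H x W x 3 integer array) and
#'   the metadata fields.
#' @export
render_image <- function(config, patient_id, side, point_site, mode, timepoint, dose) {
  stopifnot(inherits(config, "synthetic_config"))
  side <- match.arg(side, config$sides)
  point_site <- match.arg(point_site, config$sites)
  mode <- match.arg(mode, config$modes)
  h <- config$image_height; w <- config$image_width

  base <- with_local_seed(tuple_seed(config$seed, "base", patient_id, side, point_site, mode), {
    f <- config$base_mean_intensity[[mode]] +
      config$base_texture_sd * smooth_field(h, w, config$correlation_length)
    n_spk <- floor(config$speckle_density * h * w)
    if (n_spk > 0) {
      idx <- sample.int(h * w, n_spk)
      f[idx] <- f[idx] - config$speckle_depth
    }
    f
  })
  blotch <- with_local_seed(tuple_seed(config$seed, "blotch", patient_id, side, point_site, mode),
                            smooth_field(h, w, config$correlation_length))

  sev <- severity(config, side, timepoint, dose, mode)
  field <- base - config$darkening_coefficient * sev -
    config$heterogeneity_coefficient * sev * blotch

  wts <- config$channel_weights[[mode]]
  px <- array(0L, dim = c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- as.integer(clip8(wts[ch] * field))

  structure(list(pixels = px, patient_id = patient_id, side = side,
                 point_site = point_site, mode = mode, timepoint = timepoint),
            class = "skin_image")
}

#' Generate a full synthetic cohort
#'
#' Enumerates the complete imaging design — 4 sites x 2 sides x
#' `length(timepoints)` times x `length(modes)` modes per patient — and
#' samples the per-patient doses. Images are rendered lazily from the
#' manifest unless `dir` is given, in which case each image is written as an
#' 8-bit RGB PNG and the manifest gains a `path` column;
#' `manifest.csv` and `doses.csv` are written alongside.
#'
#' @param config a [synthetic_config()].
#' @param dir optional output directory for PNG images and CSVs.
#' @return a list with `manifest` (one row per image), `doses` (one row per
#'   patient x site) and the `config`.
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  ids <- seq_len(config$n_patients)
  manifest <- expand.grid(patient_id = ids, side = config$sides,
                          point_site = config$sites, mode = config$modes,
                          timepoint = config$timepoints,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$patient_id, manifest$side,
                             manifest$point_site, manifest$mode,
                             match(manifest$timepoint, config$timepoints)), ]
  rownames(manifest) <- NULL
  doses <- do.call(rbind, lapply(ids, function(p) sample_doses(config, p)))
  manifest$dose_cGy <- doses$dose_cGy[match(
    paste(manifest$patient_id, manifest$point_site),
    paste(doses$patient_id, doses$point_site))]

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    manifest$path <- file.path(dir, sprintf(
      "p%03d_%s_%s_%s_%s.png", manifest$patient_id, manifest$side,
      manifest$point_site, manifest$mode, manifest$timepoint))
    if (anyDuplicated(manifest$path)) stop("overlapping output paths")
    for (r in seq_len(nrow(manifest))) {
      img <- render_image(config, manifest$patient_id[r], manifest$side[r],
                          manifest$point_site[r], manifest$mode[r],
                          manifest$timepoint[r], manifest$dose_cGy[r])
      png::writePNG(img$pixels / 255, manifest$path[r])
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    utils::write.csv(doses, file.path(dir, "doses.csv"), row.names = FALSE)
  }
  list(manifest = manifest, doses = doses, config = config)
}

#' Read a skin surface image from a PNG or TIFF file
#'
#' @param path file path (`.png`, `.tif`/`.tiff`).
#' @param patient_id,side,point_site,mode,timepoint metadata attached to the
#'   returned object.
#' @return a `skin_image`.
#' @export
read_skin_image <- function(path, patient_id = NA, side = NA, point_site = NA,
                            mode = NA, timepoint = NA) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", ext))
  if (length(dim(raw)) == 2) raw <- array(rep(raw, 3), dim = c(dim(raw), 3))
  if (dim(raw)[3] > 3) raw <- raw[, , 1:3]
  px <- array(as.integer(round(raw * 255)), dim = dim(raw))
  structure(list(pixels = px, patient_id = patient_id, side = side,
                 point_site = point_site, mode = mode, timepoint = timepoint),
            class = "skin_image")
}
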