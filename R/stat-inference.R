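# Two-way fully within-subject repeated-measures ANOVA via orthonormal
# contrasts, with Mauchly's sphericity test and the Greenhouse-Geisser
# correction, plus the normality-gated paired / correlation tests and the
# multiplicity corrections used downstream.

# (k-1) x k orthonormal within-factor contrast rows
orthonormal_contrasts <- function(k) {
  C <- t(stats::contr.helmert(k))
  C / sqrt(rowSums(C^2))
}

# One within-subject effect: Y (n x cells) of per-subject cell means, M the
# orthonormal contrast rows for the effect.
ws_effect <- function(Y, M, alpha = 0.05) {
  n <- nrow(Y)
  q <- nrow(M)
  Yc <- Y %*% t(M)
  mbar <- colMeans(Yc)
  ss_eff <- n * sum(mbar^2)
  ss_err <- sum(sweep(Yc, 2, mbar)^2)
  df1 <- q
  df2 <- q * (n - 1)
  if (ss_err <= 1e-300) stop("zero residual variance in within-subject effect")
  F <- (ss_eff / df1) / (ss_err / df2)
  p <- stats::pf(F, df1, df2, lower.tail = FALSE)

  if (q == 1) {  # a single contrast is trivially spherical
    mauchly_W <- 1; mauchly_p <- NA_real_; eps <- 1
  } else {
    S <- stats::cov(Yc)
    mauchly_W <- det(S) / (sum(diag(S)) / q)^q
    # chi-square approximation with the second-order (order n^-2) term
    nu <- n - 1
    rho <- 1 - (2 * q^2 + q + 2) / (6 * q * nu)
    w2 <- (q + 2) * (q - 1) * (q - 2) * (2 * q^3 + 6 * q^2 + 3 * q + 2) /
      (288 * (nu * q * rho)^2)
    chi2 <- -nu * rho * log(max(mauchly_W, .Machine$double.xmin))
    f <- q * (q + 1) / 2 - 1
    pr1 <- stats::pchisq(chi2, f, lower.tail = FALSE)
    pr2 <- stats::pchisq(chi2, f + 4, lower.tail = FALSE)
    mauchly_p <- pr1 + w2 * (pr2 - pr1)
    eps <- sum(diag(S))^2 / (q * sum(S^2))
  }
  corrected <- !is.na(mauchly_p) && mauchly_p < alpha
  p_corrected <- if (corrected)
    stats::pf(F, eps * df1, eps * df2, lower.tail = FALSE) else p
  list(F = F, df1 = df1, df2 = df2, p = p,
       mauchly_W = mauchly_W, mauchly_p = mauchly_p,
       gg_epsilon = eps, correction_applied = corrected,
       p_corrected = p_corrected)
}

#' Two-way repeated-measures ANOVA (time x group, both within subject)
#'
#' Classical univariate within-subject decomposition: for each effect an
#' orthonormal contrast matrix is applied to the per-subject cell means and
#' `F` is the ratio of the contrast-mean to the residual quadratic form.
#' Mauchly's `W` is computed on the contrast covariance with its chi-squared
#' approximation; when the sphericity test rejects at `alpha`, the
#' Greenhouse-Geisser `epsilon` rescales both degrees of freedom and the
#' p-value is recomputed. An effect with a single contrast (two levels) is
#' spherical by construction (`epsilon = 1`, no correction).
#'
#' @param data data.frame with columns `patient`, `time`, `group`, `value`:
#'   a complete balanced grid, one value per patient x time x group.
#' @param alpha level of the sphericity gate (default 0.05).
#' @return an `anova_result`: list of per-effect results (`time`, `group`,
#'   `time_group`), each with `F`, `df1`, `df2`, `p`, `mauchly_W`,
#'   `mauchly_p`, `gg_epsilon`, `correction_applied`, `p_corrected`.
#' @export
rm_anova_two_way <- function(data, alpha = 0.05) {
  stopifnot(all(c("patient", "time", "group", "value") %in% names(data)))
  tl <- if (is.factor(data$time)) levels(data$time) else unique(data$time)
  gl <- if (is.factor(data$group)) levels(data$group) else unique(data$group)
  pl <- unique(data$patient)
  n <- length(pl); nt <- length(tl); ng <- length(gl)
  if (n < 3) stop("need at least 3 subjects")
  tab <- table(data$patient, data$time, data$group)
  if (nrow(data) != n * nt * ng || any(tab != 1))
    stop("incomplete or unbalanced within-subject grid")

  # cells ordered group-fastest within time
  cell <- paste(match(data$time, tl), match(data$group, gl))
  cells <- as.vector(outer(seq_len(ng), seq_len(nt),
                           function(g, t) paste(t, g)))
  Y <- matrix(NA_real_, n, nt * ng)
  Y[cbind(match(data$patient, pl), match(cell, cells))] <- data$value

  Ct <- orthonormal_contrasts(nt)
  Cg <- orthonormal_contrasts(ng)
  mean_t <- matrix(1 / nt, 1, nt)
  mean_g <- matrix(1 / ng, 1, ng)
  norm_rows <- function(M) M / sqrt(rowSums(M^2))

  res <- list(
    time = ws_effect(Y, norm_rows(Ct %x% mean_g), alpha),
    group = ws_effect(Y, norm_rows(mean_t %x% Cg), alpha),
    time_group = ws_effect(Y, Ct %x% Cg, alpha)
  )
  structure(c(res, list(n = n, time_levels = tl, group_levels = gl,
                        alpha = alpha)),
            class = "anova_result")
}

# Shapiro-Wilk p, with degenerate inputs treated as non-normal (p = 0)
shapiro_p <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || stats::sd(x) == 0) return(0)
  stats::shapiro.test(x)$p.value
}

#' Normality-gated paired comparison
#'
#' Shapiro-Wilk is run on each of the two paired samples; if both pass at
#' `gate_alpha` a paired t-test is used, otherwise the Wilcoxon signed-rank
#' test (zero differences dropped; exact distribution up to 25 non-zero
#' pairs and no ties, normal approximation with continuity and tie
#' correction beyond). All-zero differences are degenerate: `p = 1` with a
#' flag.
#'
#' @param x,y paired samples of equal length (n >= 4).
#' @param gate_alpha level of the normality gate (default 0.05).
#' @return a `paired_test_result`: list with `test_used`, `statistic`, `p`,
#'   `normality_ps`, `n`, `degenerate`.
#' @export
gated_paired_test <- function(x, y, gate_alpha = 0.05) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  d <- x - y
  sw <- c(x = shapiro_p(x), y = shapiro_p(y))
  if (all(d == 0)) {
    return(structure(list(test_used = NA_character_, statistic = NA_real_,
                          p = 1, normality_ps = sw, n = n, degenerate = TRUE),
                     class = "paired_test_result"))
  }
  if (all(sw >= gate_alpha)) {
    ht <- stats::t.test(x, y, paired = TRUE)
    used <- "paired_t"
  } else {
    nz <- sum(d != 0)
    ht <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, exact = nz <= 25, correct = TRUE))
    used <- "wilcoxon_signed_rank"
  }
  structure(list(test_used = used, statistic = unname(ht$statistic),
                 p = ht$p.value, normality_ps = sw, n = n, degenerate = FALSE),
            class = "paired_test_result")
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha family-wise level.
#' @param m number of comparisons.
#' @return `alpha / m`, with a `"display"` attribute giving the 4-decimal
#'   form used in reports (e.g. `0.05 / 3` prints as `"0.0167"`).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 3) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  structure(alpha / m, display = sprintf("%.4f", alpha / m))
}

#' Normality-gated correlation
#'
#' Shapiro-Wilk on both variables; Pearson when both pass at `gate_alpha`,
#' Spearman (tie-corrected ranks, asymptotic p with ties) otherwise.
#'
#' @param x,y numeric vectors of equal length (n >= 5).
#' @param gate_alpha level of the normality gate (default 0.05).
#' @return a `correlation_result`: list with `method`, `r`, `p`,
#'   `normality_ps`, `n` (and `p_adjusted` once a family adjustment has been
#'   applied by the caller).
#' @export
gated_correlation <- function(x, y, gate_alpha = 0.05) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5) stop("need at least 5 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in correlation input")
  sw <- c(x = shapiro_p(x), y = shapiro_p(y))
  method <- if (all(sw >= gate_alpha)) "pearson" else "spearman"
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = method,
                    exact = if (method == "spearman") FALSE else NULL))
  structure(list(method = method, r = unname(ht$estimate), p = ht$p.value,
                 normality_ps = sw, n = n, p_adjusted = NA_real_),
            class = "correlation_result")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Run the full longitudinal inference harness
#'
#' Per mode and per feature: (a) two-way repeated-measures ANOVA of the
#' patient-level deltas over time x side; (b) treated-vs-untreated paired
#' comparisons at each post-baseline timepoint, judged at `alpha / 3`;
#' (c) correlations between per-point skin doses and the per-point deltas
#' at each post-baseline timepoint; (d) correlations of the patient-level
#' delta at the first post-baseline timepoint with the later timepoints
#' (treated side only). Families (c) and (d) are Benjamini-Hochberg
#' adjusted over the 18 features within each mode x timepoint family.
#'
#' @param patient_values output of [aggregate_points()] (deltas averaged
#'   over points per breast).
#' @param deltas per-point delta table from [delta_ratios()] (correlation
#'   analyses are per measurement point).
#' @param doses per-patient dose table (`patient_id`, `point_site`,
#'   `dose_cGy`).
#' @param alpha significance level (default 0.05).
#' @param baseline baseline timepoint label.
#' @return an `inference_report`: list of data.frames `anova`, `paired`,
#'   `dose_correlations`, `followup_correlations`, plus `alpha` and the
#'   Bonferroni `posthoc_threshold`.
#' @export
run_full_inference <- function(patient_values, deltas, doses, alpha = 0.05,
                               baseline = "Before_RT") {
  fn <- haralick_feature_names()
  tps <- unique(as.character(patient_values$timepoint))
  post <- setdiff(tps, baseline)
  thr <- bonferroni_threshold(alpha, length(post))
  modes <- unique(as.character(patient_values$mode))

  anova_rows <- list(); paired_rows <- list()
  dose_rows <- list(); fu_rows <- list()

  for (m in modes) {
    pv <- patient_values[patient_values$mode == m, ]
    dl <- deltas[deltas$mode == m & deltas$side == "ipsilateral", ]
    for (f in fn) {
      dat <- data.frame(patient = pv$patient_id,
                        time = factor(pv$timepoint, levels = tps),
                        group = factor(pv$side),
                        value = pv[[f]])
      an <- tryCatch(rm_anova_two_way(dat, alpha), error = function(e) NULL)
      if (!is.null(an)) {
        anova_rows[[length(anova_rows) + 1]] <- data.frame(
          mode = m, feature = f,
          effect = c("time", "group", "time_group"),
          F = sapply(an[1:3], `[[`, "F"),
          df1 = sapply(an[1:3], `[[`, "df1"),
          df2 = sapply(an[1:3], `[[`, "df2"),
          mauchly_W = sapply(an[1:3], `[[`, "mauchly_W"),
          mauchly_p = sapply(an[1:3], `[[`, "mauchly_p"),
          gg_epsilon = sapply(an[1:3], `[[`, "gg_epsilon"),
          correction_applied = sapply(an[1:3], `[[`, "correction_applied"),
          p = sapply(an[1:3], `[[`, "p"),
          p_corrected = sapply(an[1:3], `[[`, "p_corrected"),
          row.names = NULL)
      }
      for (tp in post) {
        ip <- pv[pv$side == "ipsilateral" & pv$timepoint == tp, ]
        co <- pv[pv$side == "contralateral" & pv$timepoint == tp, ]
        idx <- match(ip$patient_id, co$patient_id)
        pt <- tryCatch(gated_paired_test(ip[[f]], co[[f]][idx]),
                       error = function(e) NULL)
        if (!is.null(pt))
          paired_rows[[length(paired_rows) + 1]] <- data.frame(
            mode = m, feature = f, timepoint = tp,
            test_used = pt$test_used %||% NA_character_,
            statistic = pt$statistic, p = pt$p, n = pt$n,
            degenerate = pt$degenerate,
            significant = !is.na(pt$p) && pt$p < thr, row.names = NULL)
      }
      # (c) dose vs per-point delta, treated side, pooled across patients
      for (tp in post) {
        dsub <- dl[dl$timepoint == tp, ]
        dd <- doses$dose_cGy[match(paste(dsub$patient_id, dsub$point_site),
                                   paste(doses$patient_id, doses$point_site))]
        ct <- tryCatch(gated_correlation(dd, dsub[[f]]), error = function(e) NULL)
        if (!is.null(ct))
          dose_rows[[length(dose_rows) + 1]] <- data.frame(
            mode = m, feature = f, timepoint = tp, method = ct$method,
            r = ct$r, p = ct$p, n = ct$n, row.names = NULL)
      }
      # (d) first post-baseline delta vs later deltas, treated side,
      #     patient-level values
      first <- post[1]
      pvi <- pv[pv$side == "ipsilateral", ]
      x0 <- pvi[pvi$timepoint == first, ]
      for (tp in post[-1]) {
        x1 <- pvi[pvi$timepoint == tp, ]
        v1 <- x1[[f]][match(x0$patient_id, x1$patient_id)]
        ct <- tryCatch(gated_correlation(x0[[f]], v1), error = function(e) NULL)
        if (!is.null(ct))
          fu_rows[[length(fu_rows) + 1]] <- data.frame(
            mode = m, feature = f, from = first, to = tp, method = ct$method,
            r = ct$r, p = ct$p, n = ct$n, row.names = NULL)
      }
    }
  }

  bind <- function(rows) if (length(rows)) do.call(rbind, rows) else NULL
  anova_df <- bind(anova_rows); paired_df <- bind(paired_rows)
  dose_df <- bind(dose_rows); fu_df <- bind(fu_rows)

  # BH within each mode x timepoint family of 18 features
  if (!is.null(dose_df)) {
    dose_df$p_adjusted <- NA_real_
    for (g in split(seq_len(nrow(dose_df)),
                    paste(dose_df$mode, dose_df$timepoint)))
      dose_df$p_adjusted[g] <- bh_adjust(dose_df$p[g])
    dose_df$significant <- dose_df$p_adjusted < alpha
  }
  if (!is.null(fu_df)) {
    fu_df$p_adjusted <- NA_real_
    for (g in split(seq_len(nrow(fu_df)), paste(fu_df$mode, fu_df$to)))
      fu_df$p_adjusted[g] <- bh_adjust(fu_df$p[g])
    fu_df$significant <- fu_df$p_adjusted < alpha
  }
  # table annotations: "*" = significant time and time x group effects;
  # "†" = paired difference significant at alpha/3 at every post-baseline time
  if (!is.null(anova_df)) {
    star <- tapply(seq_len(nrow(anova_df)),
                   paste(anova_df$mode, anova_df$feature), function(ix) {
      pc <- anova_df$p_corrected[ix]
      ef <- anova_df$effect[ix]
      all(pc[ef %in% c("time", "time_group")] < alpha)
    })
    anova_df$star <- as.vector(star[paste(anova_df$mode, anova_df$feature)])
  }
  if (!is.null(paired_df)) {
    dag <- tapply(paired_df$significant,
                  paste(paired_df$mode, paired_df$feature), all)
    paired_df$dagger <- as.vector(dag[paste(paired_df$mode, paired_df$feature)])
  }

  structure(list(anova = anova_df, paired = paired_df,
                 dose_correlations = dose_df,
                 followup_correlations = fu_df,
                 alpha = alpha, posthoc_threshold = thr),
            class = "inference_report")
}
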