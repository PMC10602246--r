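# Independent brute-force oracles: explicit double loops over pixels and
# literal Haralick formulas, deliberately written without reusing any of the
# package's vectorized code paths.

oracle_offset <- function(angle, d) {
  switch(as.character(angle),
         "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0), "135" = c(-d, -d))
}

# levels: integer matrix with NA outside the mask
oracle_glcm <- function(levels, ng, angle, d = 1, symmetric = TRUE) {
  off <- oracle_offset(angle, d)
  p <- matrix(0, ng, ng)
  h <- nrow(levels); w <- ncol(levels)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 < 1 || r2 > h || c2 < 1 || c2 > w) next
    i <- levels[r, c]; j <- levels[r2, c2]
    if (is.na(i) || is.na(j)) next
    p[i, j] <- p[i, j] + 1
    if (symmetric) p[j, i] <- p[j, i] + 1
  }
  p / sum(p)
}

oracle_features <- function(p, dialect = "matlab_toolbox") {
  ng <- nrow(p)
  px <- numeric(ng); py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    px[i] <- px[i] + p[i, j]
    py[j] <- py[j] + p[i, j]
  }
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  sx <- sqrt(sum((1:ng - mux)^2 * px)); sy <- sqrt(sum((1:ng - muy)^2 * py))
  psum <- numeric(2 * ng - 1)     # index k - 1, k = 2..2ng
  pdiff <- numeric(ng)            # index k + 1, k = 0..ng-1
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j - 1] <- psum[i + j - 1] + p[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p[i, j]
  }
  ent <- function(q) { s <- 0; for (v in q) if (v > 0) s <- s - v * log(v); s }
  HX <- ent(px); HY <- ent(py); HXY <- ent(as.vector(p))
  HXY1 <- 0; HXY2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    q <- px[i] * py[j]
    if (q > 0) {
      if (p[i, j] > 0) HXY1 <- HXY1 - p[i, j] * log(q)
      HXY2 <- HXY2 - q * log(q)
    }
  }
  autoc <- 0; contrast <- 0; cp <- 0; cs <- 0; diss <- 0; homog <- 0
  for (i in 1:ng) for (j in 1:ng) {
    autoc <- autoc + i * j * p[i, j]
    contrast <- contrast + (i - j)^2 * p[i, j]
    cp <- cp + (i + j - mux - muy)^4 * p[i, j]
    cs <- cs + (i + j - mux - muy)^3 * p[i, j]
    diss <- diss + abs(i - j) * p[i, j]
    homog <- homog + p[i, j] / (1 + abs(i - j))
  }
  sum_avg <- sum((2:(2 * ng)) * psum)
  sum_ent <- ent(psum)
  if (dialect == "matlab_toolbox") {
    dv <- sum((0:(ng - 1))^2 * pdiff)
    sv <- sum(((2:(2 * ng)) - sum_ent)^2 * psum)
    u <- sum(p) / ng^2
    va <- 0; for (i in 1:ng) for (j in 1:ng) va <- va + (i - u)^2 * p[i, j]
  } else {
    mu_d <- sum((0:(ng - 1)) * pdiff)
    dv <- sum(((0:(ng - 1)) - mu_d)^2 * pdiff)
    sv <- sum(((2:(2 * ng)) - sum_avg)^2 * psum)
    va <- 0; for (i in 1:ng) for (j in 1:ng) va <- va + (i - mux)^2 * p[i, j]
  }
  c(autocorrelation = autoc,
    contrast = contrast,
    correlation = if (sx > 0 && sy > 0) (autoc - mux * muy) / (sx * sy) else NA,
    cluster_prominence = cp,
    cluster_shade = cs,
    dissimilarity = diss,
    energy = sum(p^2),
    entropy = HXY,
    homogeneity = homog,
    maximum_probability = max(p),
    variance = va,
    sum_average = sum_avg,
    sum_variance = sv,
    sum_entropy = sum_ent,
    difference_variance = dv,
    difference_entropy = ent(pdiff),
    imc1 = if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else NA,
    imc2 = sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY)))))
}

# random masked level grid for property tests
random_masked_grid <- function(nr, nc, ng, circular = FALSE) {
  vals <- matrix(sample.int(ng, nr * nc, replace = TRUE), nr, nc)
  mask <- if (circular) {
    rc <- (nr - 1) / 2; cc <- (nc - 1) / 2
    outer((0:(nr - 1) - rc)^2, (0:(nc - 1) - cc)^2, "+") <= (min(nr, nc) / 2.5)^2
  } else matrix(TRUE, nr, nc)
  lv <- vals; lv[!mask] <- NA
  structure(list(levels = lv, mask = mask, ng = as.integer(ng)),
            class = "masked_level_grid")
}

# small synthetic config used across tests: reduced geometry, same design
small_config <- function(n_patients = 2, seed = 11, ...) {
  synthetic_config(n_patients = n_patients, image_height = 96,
                   image_width = 96, seed = seed, ...)
}

small_params <- function(...) glcm_params(roi_radius = 40, ...)
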