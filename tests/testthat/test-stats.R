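sim_rm_data <- function(n = 10, nt = 4, ng = 2, effect = 0, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(patient = 1:n, time = paste0("t", 1:nt),
                      group = paste0("g", 1:ng), stringsAsFactors = FALSE)
  subj <- rnorm(n)[grid$patient]
  bump <- effect * (grid$time == "t3") * (grid$group == "g1")
  grid$value <- subj + bump + rnorm(nrow(grid))
  grid
}

test_that("RM-ANOVA F, Mauchly W and GG epsilon match the base-R mlm machinery", {
  d <- sim_rm_data(n = 12, seed = 42, effect = 0.8)
  res <- rm_anova_two_way(d)

  # independent route: multivariate lm + anova.mlm / mauchly.test on the
  # same orthonormal within-subject contrasts (cells ordered group-fastest)
  Y <- matrix(NA_real_, 12, 8)
  cells <- expand.grid(group = paste0("g", 1:2), time = paste0("t", 1:4),
                       stringsAsFactors = FALSE)
  for (k in 1:8)
    Y[, k] <- d$value[d$time == cells$time[k] & d$group == cells$group[k]][
      order(d$patient[d$time == cells$time[k] & d$group == cells$group[k]])]
  fit <- lm(Y ~ 1)
  norm_rows <- function(M) M / sqrt(rowSums(M^2))
  Ct <- norm_rows(t(contr.helmert(4)))
  Cg <- norm_rows(t(contr.helmert(2)))
  T_time <- norm_rows(Ct %x% matrix(1 / 2, 1, 2))
  T_grp <- norm_rows(matrix(1 / 4, 1, 4) %x% Cg)
  T_int <- Ct %x% Cg

  check_effect <- function(eff, T) {
    ref <- anova(fit, T = T, test = "Spherical")
    expect_equal(eff$F, ref$F[1], tolerance = 1e-8)
    expect_equal(eff$df1, ref$`num Df`[1])
    expect_equal(eff$df2, ref$`den Df`[1])
    expect_equal(eff$p, ref$`Pr(>F)`[1], tolerance = 1e-8)
    # the G-G column checks the epsilon estimate through the corrected p
    expect_equal(pf(eff$F, eff$gg_epsilon * eff$df1, eff$gg_epsilon * eff$df2,
                    lower.tail = FALSE),
                 ref$`G-G Pr`[1], tolerance = 1e-8)
    if (nrow(T) > 1) {
      mt <- mauchly.test(fit, T = T)
      expect_equal(eff$mauchly_W, unname(mt$statistic), tolerance = 1e-8)
      # base R's second-order chi-square term uses a slightly different w2
      # factor, so p-values agree closely but not to machine precision
      expect_equal(eff$mauchly_p, mt$p.value, tolerance = 5e-3)
    }
  }
  check_effect(res$time, T_time)
  check_effect(res$group, T_grp)
  check_effect(res$time_group, T_int)

  # two-level effect: trivially spherical, no correction
  expect_equal(res$group$gg_epsilon, 1)
  expect_false(res$group$correction_applied)
  expect_equal(res$group$p_corrected, res$group$p)
  # epsilon ranges and df identity
  for (eff in list(res$time, res$time_group)) {
    expect_gt(eff$gg_epsilon, 1 / (eff$df1))
    expect_lte(eff$gg_epsilon, 1 + 1e-12)
  }
  expect_error(rm_anova_two_way(d[-1, ]), "unbalanced|incomplete")
})

test_that("RM-ANOVA rejects under a real interaction and stays calibrated under the null", {
  d <- sim_rm_data(n = 20, seed = 7, effect = 2)
  res <- rm_anova_two_way(d)
  expect_lt(res$time_group$p_corrected, 0.05)

  rej <- replicate(300, {
    d0 <- sim_rm_data(n = 10, seed = sample.int(1e6, 1))
    r <- rm_anova_two_way(d0)
    c(r$time$p_corrected, r$group$p_corrected, r$time_group$p_corrected) < 0.05
  })
  rates <- rowMeans(rej)
  for (rate in rates)   # 3 SE binomial band around 0.05 at 300 reps
    expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 300) + 1e-9)
})

test_that("paired test gate follows Shapiro-Wilk and reproduces the textbook t", {
  set.seed(5)
  x <- rnorm(12); y <- x - c(1, 2, 3, rnorm(9, 2))
  r <- gated_paired_test(x, y)
  expect_true(r$test_used %in% c("paired_t", "wilcoxon_signed_rank"))
  expect_identical(r$test_used == "paired_t", all(r$normality_ps >= 0.05))

  # differences (1, 2, 3): t = mean/sd * sqrt(n) = 2 * sqrt(3), df = 2
  ht <- t.test(c(1, 2, 3) + rnorm(3, 0, 0), rep(0, 3), paired = TRUE)
  expect_equal(unname(ht$statistic), 2 * sqrt(3), tolerance = 1e-12)

  # heavy-tailed inputs fail the gate: Wilcoxon branch
  set.seed(11)
  hx <- rcauchy(30); hy <- hx + 0.5
  rw <- gated_paired_test(hx, hy)
  expect_equal(rw$test_used, "wilcoxon_signed_rank")

  # x = y: degenerate, p = 1
  rz <- gated_paired_test(x, x)
  expect_true(rz$degenerate)
  expect_equal(rz$p, 1)
  expect_error(gated_paired_test(1:3, 4:6), "at least 4")
})

test_that("both gated tests hold their nominal level under the null", {
  set.seed(99)
  p_pair <- replicate(400, gated_paired_test(rnorm(20), rnorm(20))$p)
  expect_lt(abs(mean(p_pair < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
  p_cor <- replicate(400, gated_correlation(rnorm(20), rnorm(20))$p)
  expect_lt(abs(mean(p_cor < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("Bonferroni threshold divides the level and prints at 4 decimals", {
  b <- bonferroni_threshold(0.05, 3)
  expect_equal(as.numeric(b), 0.05 / 3)
  expect_identical(attr(b, "display"), "0.0167")
  expect_equal(as.numeric(bonferroni_threshold(0.05, 1)), 0.05)
  expect_equal(as.numeric(bonferroni_threshold(0.01, 4)), 0.0025)
  expect_error(bonferroni_threshold(0.05, 0), "m")
})

test_that("gated correlation reproduces hand-computed coefficients and branch rules", {
  x <- c(1, 2, 3, 4, 5); y <- 2 * x + 1
  expect_error(gated_correlation(x, rep(1, 5)), "zero variance")
  r <- suppressWarnings(gated_correlation(x, y))
  expect_equal(r$r, 1)

  # x = (1,2,3), y = (6,4,5): Pearson and Spearman both -0.5
  expect_equal(unname(cor(c(1, 2, 3), c(6, 4, 5))), -0.5)
  expect_equal(unname(cor(c(1, 2, 3), c(6, 4, 5), method = "spearman")), -0.5)

  set.seed(3)
  hx <- rcauchy(25); hy <- hx + rnorm(25)
  rs <- gated_correlation(hx, hy)
  expect_equal(rs$method, "spearman")
  nx <- rnorm(25); ny <- nx + rnorm(25)
  rp <- gated_correlation(nx, ny)
  expect_identical(rp$method == "pearson", all(rp$normality_ps >= 0.05))
})

test_that("BH adjustment matches the step-up enumeration and dominates Bonferroni", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 6)), rep(0.07, 6))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(8)
  p <- runif(18)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  # independent step-up enumeration: adj_(i) = min_{j >= i} m p_(j) / j
  ord <- order(p)
  ref <- sapply(seq_along(p), function(i)
    min(1, min(18 * sort(p)[i:18] / (i:18))))
  expect_equal(adj[ord], ref)
  expect_true(all(diff(adj[ord]) >= -1e-15))
  # every Bonferroni-significant p is BH-significant
  alpha <- 0.05
  expect_true(all(adj[p < alpha / 18] < alpha))
})
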