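grid_from <- function(m, ng) {
  structure(list(levels = m, mask = !is.na(m), ng = as.integer(ng)),
            class = "masked_level_grid")
}

test_that("hand-enumerated co-occurrence probabilities are reproduced", {
  # constant grid: all mass on (1, 1)
  g <- grid_from(matrix(1L, 4, 4), 4)
  gl <- compute_glcm(g, glcm_params(ng = 4), 0)
  expect_equal(gl$p[1, 1], 1)
  expect_equal(sum(gl$p), 1)

  # 2x2 grid [[1,1],[1,64]], horizontal symmetric: two ordered pairs + mirrors
  g2 <- grid_from(matrix(c(1L, 1L, 1L, 64L), 2, 2, byrow = TRUE), 64)
  gl2 <- compute_glcm(g2, glcm_params(ng = 64), 0)
  expect_equal(gl2$p[1, 1], 0.5)
  expect_equal(gl2$p[1, 64], 0.25)
  expect_equal(gl2$p[64, 1], 0.25)
  expect_equal(sum(gl2$p), 1)
  expect_equal(gl2$pair_count, 4)

  # fully masked-out grid has no valid pair
  g3 <- grid_from(matrix(NA_integer_, 3, 3), 4)
  expect_error(compute_glcm(g3, glcm_params(ng = 4), 0), "no valid pixel pair")
})

test_that("GLCM and all 18 features match the brute-force oracle on random masked grids", {
  set.seed(101)
  for (rep in 1:40) {
    nr <- sample(4:12, 1); nc <- sample(4:12, 1); ng <- sample(2:8, 1)
    g <- random_masked_grid(nr, nc, ng, circular = rep %% 2 == 0)
    for (dialect in c("matlab_toolbox", "haralick_1973")) {
      pars <- glcm_params(ng = ng, dialect = dialect)
      for (a in c(0, 45, 90, 135)) {
        gl <- compute_glcm(g, pars, a)
        ref_p <- oracle_glcm(g$levels, ng, a)
        expect_equal(gl$p, ref_p, tolerance = 1e-12, ignore_attr = TRUE)
        fv <- suppressWarnings(haralick_features(gl))
        ref <- suppressWarnings(oracle_features(ref_p, dialect))
        expect_equal(fv, ref, tolerance = 1e-10)
      }
    }
  }
})

test_that("features of hand-built matrices match literal substitution", {
  # single-cell GLCM
  p1 <- matrix(0, 4, 4); p1[1, 1] <- 1
  gl1 <- structure(list(p = p1, params = glcm_params(ng = 4), angle = 0,
                        pair_count = 10), class = "glcm_matrix")
  w <- capture_warnings(fv1 <- haralick_features(gl1))
  expect_match(w, "degenerate", all = TRUE)
  expect_length(w, 2)   # correlation and IMC 1 both undefined
  expect_equal(unname(fv1["energy"]), 1)
  expect_equal(unname(fv1["entropy"]), 0)
  expect_equal(unname(fv1["contrast"]), 0)
  expect_equal(unname(fv1["dissimilarity"]), 0)
  expect_equal(unname(fv1["homogeneity"]), 1)
  expect_equal(unname(fv1["maximum_probability"]), 1)
  expect_true(is.na(fv1["correlation"]))
  expect_true(is.na(fv1["imc1"]))

  # {(1,1): .5, (1,64): .25, (64,1): .25}
  p2 <- matrix(0, 64, 64); p2[1, 1] <- 0.5; p2[1, 64] <- p2[64, 1] <- 0.25
  gl2 <- structure(list(p = p2, params = glcm_params(), angle = 0,
                        pair_count = 4), class = "glcm_matrix")
  fv2 <- haralick_features(gl2)
  expect_equal(unname(fv2["energy"]), 0.375)
  expect_equal(unname(fv2["maximum_probability"]), 0.5)
  expect_equal(unname(fv2["contrast"]), 0.5 * 63^2)  # 1984.5
})

test_that("feature bounds, symmetry and normalization hold on random inputs", {
  set.seed(202)
  for (rep in 1:25) {
    ng <- sample(3:8, 1)
    g <- random_masked_grid(10, 10, ng)
    gl <- compute_glcm(g, glcm_params(ng = ng), sample(c(0, 45, 90, 135), 1))
    expect_equal(sum(gl$p), 1)
    expect_equal(gl$p, t(gl$p))
    fv <- haralick_features(gl)
    expect_true(fv["energy"] > 0 && fv["energy"] <= 1)
    expect_true(fv["maximum_probability"] > 0 && fv["maximum_probability"] <= 1)
    expect_true(fv["homogeneity"] > 0 && fv["homogeneity"] <= 1)
    expect_true(fv["entropy"] >= 0 && fv["entropy"] <= 2 * log(ng) + 1e-12)
    expect_true(fv["imc2"] >= 0 && fv["imc2"] < 1)
    # dialect identity
    expect_equal(unname(fv["difference_variance"]), unname(fv["contrast"]),
                 tolerance = 1e-12)
  }
})

test_that("angle averaging is the elementwise arithmetic mean", {
  v1 <- setNames(rep(0.2, 18), haralick_feature_names())
  v2 <- setNames(rep(0.4, 18), haralick_feature_names())
  expect_equal(average_feature_vectors(list(v1, v1, v1)), v1)
  expect_equal(unname(average_feature_vectors(list(v1, v2))["energy"]), 0.3)
  set.seed(7)
  vs <- lapply(1:4, function(i) setNames(runif(18), haralick_feature_names()))
  expect_equal(average_feature_vectors(vs),
               Reduce(`+`, vs) / 4)
  # degenerate entries are skipped, all-degenerate stays NA
  v3 <- v1; v3["correlation"] <- NA
  expect_warning(av <- average_feature_vectors(list(v3, v2)), "degenerate")
  expect_equal(unname(av["correlation"]), 0.4)
  expect_error(average_feature_vectors(list()), "empty")
})

test_that("whole-image extraction yields 18 named features, deterministically", {
  sc <- small_config(seed = 31)
  img <- render_image(sc, 1, "ipsilateral", "outer", "UV", "RT_D14", 240)
  fv <- extract_image_features(img, small_params())
  expect_named(fv, haralick_feature_names())
  expect_identical(fv, extract_image_features(img, small_params()))
  # identical channels: channel averaging equals a single channel's vector
  ch <- split_channels(img)
  roi <- crop_circular_roi(ch$red, 40)
  grid <- quantize_levels(roi$values, roi$mask, 64)
  single <- average_feature_vectors(lapply(c(0, 45, 90, 135), function(a)
    haralick_features(compute_glcm(grid, small_params(), a))))
  expect_equal(fv, single)
})

test_that("rising severity lowers energy and raises entropy and contrast", {
  sc <- small_config(seed = 77)
  fvs <- sapply(sc$timepoints, function(tp) {
    img <- render_image(sc, 2, "ipsilateral", "upper", "normal", tp, 250)
    extract_image_features(img, small_params())
  })
  expect_true(all(diff(fvs["energy", ]) < 0))
  expect_true(all(diff(fvs["entropy", ]) > 0))
  expect_true(all(diff(fvs["contrast", ]) > 0))
})
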