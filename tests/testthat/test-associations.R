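test_that("Spearman correlation matches rank-formula values and invariances", {
  expect_equal(spearman_assoc(1:10, (1:10)^3)$estimate, 1)
  # 1 - 6*sum(d^2)/(n(n^2-1)) with d = (0, 1.. ) for y = (3,1,2)
  expect_equal(spearman_assoc(c(1, 2, 3), c(3, 1, 2))$estimate, -0.5)
  set.seed(1)
  x <- rnorm(30); y <- rnorm(30)
  r0 <- spearman_assoc(x, y)$estimate
  expect_equal(spearman_assoc(exp(x), y)$estimate, r0)       # monotone map
  expect_equal(spearman_assoc(x, 5 * y - 2)$estimate, r0)
  expect_error(spearman_assoc(1:2, 1:2), "n >= 3")
})

test_that("Spearman p-values are uniform under the null", {
  set.seed(2)
  pv <- vapply(1:2000, function(i)
    spearman_assoc(rnorm(25), rnorm(25))$p, numeric(1))
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("partial correlation agrees with its two oracles", {
  set.seed(3)
  n <- 100
  z1 <- rnorm(n); z2 <- rnorm(n)
  x <- z1 + 0.5 * z2 + rnorm(n)
  y <- -0.7 * z1 + rnorm(n)
  # empty control set reduces to Pearson
  expect_equal(partial_correlation(x, y)$estimate, cor(x, y), tolerance = 1e-12)
  # residual method vs the recursive partial-correlation formula
  pc <- partial_correlation(x, y, cbind(z1, z2))$estimate
  rec1 <- function(a, b, c) (cor(a, b) - cor(a, c) * cor(b, c)) /
    sqrt((1 - cor(a, c)^2) * (1 - cor(b, c)^2))
  # second-order recursion: condition on z1 first, then remove z2 | z1
  r_xy_1 <- rec1(x, y, z1); r_xz2_1 <- rec1(x, z2, z1); r_yz2_1 <- rec1(y, z2, z1)
  oracle <- (r_xy_1 - r_xz2_1 * r_yz2_1) /
    sqrt((1 - r_xz2_1^2) * (1 - r_yz2_1^2))
  expect_lt(abs(pc - oracle), 1e-10)
  expect_error(partial_correlation(x, y, cbind(z1, x + 1e-14 * z1)),
               "collinear")
})

test_that("conditioning on the common cause removes the association", {
  set.seed(4)
  est <- vapply(1:200, function(i) {
    z <- rnorm(50)
    partial_correlation(z + rnorm(50), z + rnorm(50), cbind(z))$estimate
  }, numeric(1))
  expect_lt(abs(mean(est)), 0.02)
})

test_that("AICc follows the corrected formula and its limits", {
  expect_equal(aicc(-5, 0, 20), 10)
  expect_equal(aicc(-10, 3, 20), 20 + 6 + 24 / 16)   # = 27.5
  expect_equal(aicc(-10, 3, 20), 27.5)
  # correction vanishes with n
  expect_lt(aicc(-10, 3, 1e5) - (2 * 10 + 2 * 3), 1e-3)
  expect_error(aicc(-10, 3, 4), "n > k")
})

test_that("model averaging reduces to OLS with one predictor", {
  set.seed(5)
  x <- rnorm(60); y <- 0.6 * x + rnorm(60)
  ma <- model_average(y, cbind(x = x))
  ols <- coef(lm(scale(y)[, 1] ~ scale(x)[, 1]))[2]
  # with one predictor the null model carries some weight under zero-method
  man <- model_average(y, cbind(x = x), method = "natural")
  expect_equal(unname(coef(man)["x"]), unname(ols), tolerance = 1e-10)
  expect_equal(unname(ma$importance_pct), 100)
  expect_equal(sum(ma$models$weight), 1, tolerance = 1e-12)
})

test_that("averaging weights and importances are well-formed and symmetric", {
  set.seed(6)
  n <- 120
  x1 <- rnorm(n)
  x2 <- x1 + 0.02 * rnorm(n)      # near-duplicate
  x3 <- rnorm(n)
  y <- x1 + x2 + 0.5 * x3 + rnorm(n)
  ma <- model_average(y, cbind(a = x1, b = x2, c = x3))
  expect_equal(sum(ma$models$weight), 1, tolerance = 1e-12)
  expect_equal(sum(ma$importance_pct), 100, tolerance = 1e-9)
  expect_error(model_average(y, cbind(a = x1, b = x1)), "collinear")
  expect_error(model_average(y, matrix(rnorm(n * 13), n)), "12 predictors")
  # in any one fit the collinear pair splits arbitrarily, but importance is
  # symmetric in expectation across datasets
  imp <- replicate(200, {
    u <- rnorm(n); v <- u + 0.1 * rnorm(n)
    yy <- u + v + rnorm(n)
    model_average(yy, cbind(a = u, b = v))$importance_pct
  })
  diffs <- imp["a", ] - imp["b", ]
  expect_lt(abs(mean(diffs)), 4 * sd(diffs) / sqrt(length(diffs)))
})

test_that("null predictors earn near-uniform importance and centred betas", {
  set.seed(7)
  bsum <- c(a = 0, b = 0, c = 0)
  for (i in 1:300) {
    y <- rnorm(40)
    ma <- model_average(y, cbind(a = rnorm(40), b = rnorm(40), c = rnorm(40)))
    bsum <- bsum + coef(ma)
  }
  expect_lt(max(abs(bsum / 300)), 0.02)
})

test_that("the mixed model collapses to OLS when group variance is absent", {
  # under a true group variance of 0 the REML variance estimate sits on the
  # boundary in a fair share of datasets; whenever it does, the fixed-effect
  # estimates must reduce to OLS exactly
  boundary_cases <- 0
  sigmas <- numeric(10)
  for (i in 1:10) {
    d <- generate_microcosm(microcosm_config(seed = 400 + i, n_replicates = 3,
                                             sigma_combination = 0))
    X <- as.data.frame(d$ground_truth$design_matrix)
    y <- d$functions$soil_N
    fm <- fit_mixed(y, X, d$design$combination)
    expect_false(fm$ols_fallback)
    sigmas[i] <- fm$sigma_group
    if (fm$sigma_group < 1e-8) {
      boundary_cases <- boundary_cases + 1
      ols <- coef(lm(y ~ ., data = cbind(X, y = y)))
      expect_lt(max(abs(coef(fm) - ols)), 1e-6)
    }
  }
  expect_gt(boundary_cases, 0)
  expect_lt(median(sigmas), 0.3)
})

test_that("a single-level grouping factor falls back to OLS with a flag", {
  set.seed(8)
  X <- data.frame(x = rnorm(30))
  y <- 2 * X$x + rnorm(30)
  expect_warning(fm <- fit_mixed(y, X, rep("g1", 30)), "single level")
  expect_true(fm$ols_fallback)
  expect_equal(unname(coef(fm)["x"]), unname(coef(lm(y ~ x, X))["x"]),
               tolerance = 1e-12)
})

test_that("mixed model recovers the generating fixed effects", {
  d <- generate_microcosm(microcosm_config(seed = 22, n_replicates = 4))
  X <- as.data.frame(d$ground_truth$design_matrix)
  fm <- fit_mixed(d$functions$plant_biomass, X, d$design$combination)
  truth <- d$ground_truth$beta_true["plant_biomass", ]
  est <- fm$coefficients[rownames(fm$coefficients) != "(Intercept)", ]
  expect_lt(max(abs(est$estimate - truth)), 4 * max(est$se))
})
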