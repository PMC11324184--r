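test_that("standardize_function rescales to [0,1] with transforms", {
  expect_equal(standardize_function(c(2, 4, 6)), c(0, 0.5, 1))
  # log10 spacing of (1, 10, 100) is exactly linear
  expect_equal(standardize_function(c(1, 10, 100), "log"), c(0, 0.5, 1))
  expect_equal(standardize_function(c(0, 1, 4), "sqrt"), c(0, 0.5, 1))
  expect_error(standardize_function(c(5, 5, 5)), "degenerate")
  expect_error(standardize_function(c(-1, 2, 3), "log"), "positive")
  expect_error(standardize_function(c(-1, 2, 3), "sqrt"), "non-negative")
  x <- rnorm(30)
  s <- standardize_function(x)
  expect_equal(order(s), order(x))
  expect_equal(range(s), c(0, 1))
})

test_that("weighted EMF is the two-stage mean and reduces to the flat mean", {
  m <- random_function_matrix(n = 15, p = 6, seed = 2)
  sm <- service_map_of_sizes(m, c(3, 2, 1))
  mf <- multifunctionality(m, sm)
  expect_equal(mf$emf_weighted,
               setNames(brute_force_weighted_emf(mf$standardized, sm),
                        names(mf$emf_weighted)),
               tolerance = 1e-12)
  # one service holding all functions: weighted == averaged
  mf1 <- multifunctionality(m, list(all = colnames(m)))
  expect_equal(mf1$emf_weighted, mf1$emf_averaged, tolerance = 1e-12)
  # equal service sizes: weighted == averaged
  mf2 <- multifunctionality(m, service_map_of_sizes(m, c(2, 2, 2)))
  expect_equal(mf2$emf_weighted, mf2$emf_averaged, tolerance = 1e-12)
  # hand-set service means (0.2, 0.4, 0.6) average to 0.4
  expect_equal(mean(c(0.2, 0.4, 0.6)), 0.4)
})

test_that("weighted EMF equals the brute-force two-stage mean on many random matrices", {
  for (i in 1:1000) {
    m <- random_function_matrix(n = 8, p = 6, seed = i)
    sizes <- list(c(3, 2, 1), c(2, 2, 2), c(1, 1, 4), c(3, 3))[[(i %% 4) + 1]]
    sm <- service_map_of_sizes(m, sizes)
    mf <- multifunctionality(m, sm)
    expect_lt(max(abs(mf$emf_weighted -
                        brute_force_weighted_emf(mf$standardized, sm))), 1e-12)
  }
})

test_that("EMF and composites stay inside [0,1] and survive affine maps", {
  for (i in 1:25) {
    m <- random_function_matrix(n = 12, p = 6, seed = 100 + i)
    sm <- service_map_of_sizes(m, c(3, 2, 1))
    mf <- multifunctionality(m, sm)
    expect_true(all(mf$standardized >= 0 & mf$standardized <= 1))
    expect_true(all(mf$emf_weighted >= 0 & mf$emf_weighted <= 1))
    expect_true(all(mf$emf_averaged >= 0 & mf$emf_averaged <= 1))
    # strictly increasing affine map of a raw column changes nothing
    m2 <- m
    m2[, 3] <- 2.5 * m2[, 3] + 7
    mf2 <- multifunctionality(m2, sm)
    expect_equal(mf$standardized, mf2$standardized, tolerance = 1e-12)
    expect_equal(mf$emf_weighted, mf2$emf_weighted, tolerance = 1e-12)
  }
})

test_that("missing values are excluded pairwise and fully-missing services flagged", {
  m <- random_function_matrix(n = 10, p = 4, seed = 3)
  sm <- service_map_of_sizes(m, c(2, 2))
  m[1, 1] <- NA
  mf <- multifunctionality(m, sm)
  expect_equal(unname(mf$service_means[1, 1]),
               mf$standardized[1, 2])
  expect_true(mf$complete[1])
  m[2, 3] <- NA; m[2, 4] <- NA
  mf2 <- multifunctionality(m, sm)
  expect_false(mf2$complete[2])
  expect_true(is.na(mf2$service_means[2, 2]))
})

test_that("composite richness averages independently standardized groups", {
  expect_equal(composite_richness(cbind(g = c(10, 20, 30))), c(0, 0.5, 1))
  rich <- cbind(plant = c(1, 5, 3, 2), bacteria = c(100, 900, 400, 200),
                fungi = c(10, 70, 20, 90))
  comp <- composite_richness(rich)
  oracle <- rowMeans(apply(rich, 2, function(x) (x - min(x)) / diff(range(x))))
  expect_equal(comp, oracle, tolerance = 1e-12)
  expect_true(all(comp >= 0 & comp <= 1))
  expect_error(composite_richness(cbind(a = c(2, 2, 2))), "constant")
})

test_that("multithreshold counts follow the strict-exceedance definition", {
  m <- matrix(c(1, 0.5, 10, 2), 2, 2,
              dimnames = list(c("a", "b"), c("f1", "f2")))
  counts <- multithreshold_counts(m, thresholds = 50)
  expect_equal(unname(counts[, "t50"]), c(2L, 0L))
  # >= variant counts the boundary sample
  counts_ge <- multithreshold_counts(m, thresholds = 50, strict = FALSE)
  expect_equal(unname(counts_ge[, "t50"]), c(2L, 1L))
  # a threshold below every min/max ratio counts all functions
  m2 <- matrix(c(9, 10, 18, 20), 2, 2, dimnames = list(NULL, c("f1", "f2")))
  expect_equal(unname(multithreshold_counts(m2, 5)[, 1]), c(2L, 2L))
  # near-100% threshold: at most the argmax sample counts each function
  c99 <- multithreshold_counts(random_function_matrix(10, 5, 4), 99.999)
  expect_lte(sum(c99), 5)
  expect_error(multithreshold_counts(m, thresholds = 0), "between 0 and 100")
  expect_error(multithreshold_counts(m, thresholds = 100), "between 0 and 100")
})

test_that("threshold counts are non-increasing in the threshold", {
  for (i in 1:20) {
    m <- random_function_matrix(n = 10, p = 8, seed = 200 + i)
    counts <- multithreshold_counts(abs(m), thresholds = seq(5, 99, by = 2))
    expect_true(all(apply(counts, 1, function(r) all(diff(r) <= 0))))
    expect_true(all(counts >= 0 & counts <= 8))
  }
})

test_that("threshold slopes match an independent normal-equations solve", {
  set.seed(31)
  div <- rnorm(25, 10, 3)
  m <- random_function_matrix(25, 6, seed = 8)
  counts <- multithreshold_counts(m, thresholds = c(10, 25, 50, 75, 90))
  sl <- threshold_slope_curve(div, counts)
  for (i in seq_len(nrow(sl))) {
    X <- cbind(1, div)
    b <- solve(t(X) %*% X, t(X) %*% counts[, i])
    expect_lt(abs(sl$slope[i] - b[2]), 1e-10)
  }
  # counts exactly 2 * diversity: slope 2, perfect fit
  div2 <- 1:10
  counts2 <- matrix(2L * div2, ncol = 1, dimnames = list(NULL, "t50"))
  sl2 <- suppressWarnings(threshold_slope_curve(div2, counts2))
  expect_equal(sl2$slope, 2)
  expect_equal(sl2$r2adj, 1)
  # constant counts: zero slope, no explained variance
  counts3 <- matrix(3L, nrow = 10, ncol = 1, dimnames = list(NULL, "t50"))
  sl3 <- threshold_slope_curve(div2, counts3)
  expect_equal(sl3$slope, 0)
  expect_lte(sl3$r2adj, 0)
  expect_error(threshold_slope_curve(rep(1, 10), counts2), "degenerate")
})

test_that("best_fit_regression picks the right functional form", {
  x <- seq(-3, 3, length.out = 30)
  para <- suppressWarnings(best_fit_regression(x, 2 + x - 0.5 * x^2))
  expect_equal(para$fit, "quadratic")
  expect_equal(para$r2adj, 1)
  lin <- suppressWarnings(best_fit_regression(x, 1 + 2 * x))
  expect_equal(lin$fit, "linear")
  expect_equal(lin$r2adj, 1)
  # pure noise: selection near chance, coefficients centered on zero
  picks <- character(500); slopes <- numeric(500)
  set.seed(77)
  for (i in 1:500) {
    y <- rnorm(30)
    bf <- best_fit_regression(x, y)
    picks[i] <- bf$fit
    slopes[i] <- bf$coefficients[["x"]]
  }
  expect_gt(mean(picks == "linear"), 0.25)
  expect_lt(mean(picks == "linear"), 0.90)
  expect_lt(abs(mean(slopes)), 0.05)
  expect_error(best_fit_regression(rep(1, 10), rnorm(10)), "constant")
})
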