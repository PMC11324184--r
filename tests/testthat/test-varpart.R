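test_that("adjusted R2 follows the Ezekiel formula", {
  set.seed(1)
  x <- rnorm(11)
  # perfect fit
  expect_equal(adjusted_r2(2 * x + 1, cbind(x)), 1)
  # R2 = 0.5, n = 11, p = 1  ->  1 - 0.5 * 10 / 9
  y <- rnorm(11)
  fit <- lm(y ~ x)
  r2 <- summary(fit)$r.squared
  expect_equal(adjusted_r2(y, cbind(x)),
               1 - (1 - r2) * 10 / 9, tolerance = 1e-12)
  expect_equal(1 - 0.5 * 10 / 9, 4 / 9)
  # independence: mean adjusted R2 near zero
  vals <- vapply(1:300, function(i) {
    set.seed(i); adjusted_r2(rnorm(30), cbind(rnorm(30)))
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.02)
  expect_error(adjusted_r2(rnorm(3), cbind(rnorm(3), rnorm(3))), "n > p")
})

test_that("k = 2 fractions equal the closed-form identities", {
  set.seed(2)
  n <- 40
  A <- matrix(rnorm(n * 2), n, 2)
  B <- matrix(rnorm(n), n, 1)
  y <- A %*% c(1, -0.5) + 0.3 * B[, 1] + rnorm(n)
  vp <- varpart(y, list(A = A, B = B), nperm = 0)
  zA <- apply(A, 2, scale); zB <- apply(B, 2, scale)
  rA <- adjusted_r2(y, zA); rB <- adjusted_r2(y, zB)
  rAB <- adjusted_r2(y, cbind(zA, zB))
  fr <- setNames(vp$fractions$raw, vp$fractions$fraction)
  expect_equal(unname(fr["A"]), rAB - rB, tolerance = 1e-12)
  expect_equal(unname(fr["B"]), rAB - rA, tolerance = 1e-12)
  expect_equal(unname(fr["A:B"]), rA + rB - rAB, tolerance = 1e-12)
  expect_equal(unname(fr["residual"]), 1 - rAB, tolerance = 1e-12)
})

test_that("untruncated fractions sum exactly to the full-model adjusted R2", {
  set.seed(3)
  for (i in 1:60) {
    k <- sample(2:4, 1)
    n <- 35
    groups <- lapply(seq_len(k), function(j) matrix(rnorm(n * sample(1:2, 1)), n))
    names(groups) <- letters[seq_len(k)]
    y <- rowSums(do.call(cbind, groups)) + rnorm(n)
    vp <- varpart(y, groups, nperm = 0)
    fr <- vp$fractions
    expect_lt(abs(sum(fr$raw[fr$fraction != "residual"]) - vp$r2adj_full), 1e-12)
    expect_true(all(fr$truncated >= 0))
  }
})

test_that("constructed datasets partition as designed", {
  set.seed(4)
  n <- 200
  a <- rnorm(n)
  b <- rnorm(n)
  # y a function of A only: unique(A) ~ full R2, unique(B) ~ 0
  y <- 2 * a + 0.05 * rnorm(n)
  vp <- varpart(y, list(A = a, B = b), nperm = 0)
  fr <- setNames(vp$fractions$raw, vp$fractions$fraction)
  expect_gt(fr[["A"]], 0.95)
  expect_lt(abs(fr[["B"]]), 0.02)
  expect_lt(abs(fr[["A:B"]]), 0.02)
  # duplicated group: all variance shared
  vp2 <- varpart(y, list(A = a, B = a + 1e-4 * rnorm(n)), nperm = 0)
  fr2 <- setNames(vp2$fractions$raw, vp2$fractions$fraction)
  expect_lt(abs(fr2[["A"]]), 0.01)
  expect_lt(abs(fr2[["B"]]), 0.01)
  expect_gt(fr2[["A:B"]], 0.95)
  # orthogonal designed groups: shared ~ 0, uniques sum to full R2adj
  g1 <- rep(c(-1, 1), each = n / 2)
  g2 <- rep(c(-1, 1), times = n / 2)
  y3 <- g1 + 0.5 * g2 + rnorm(n, 0, 0.3)
  vp3 <- varpart(y3, list(g1 = g1, g2 = g2), nperm = 0)
  fr3 <- setNames(vp3$fractions$raw, vp3$fractions$fraction)
  expect_lt(abs(fr3[["g1"]] + fr3[["g2"]] +
                  fr3[["g1:g2"]] - vp3$r2adj_full), 1e-10)
  expect_lt(abs(fr3[["g1:g2"]]), 0.01)
})

test_that("fractions are invariant to group ordering", {
  set.seed(5)
  n <- 50
  g <- list(p = rnorm(n), q = rnorm(n), r = rnorm(n))
  y <- g$p + 0.5 * g$q + rnorm(n)
  vp1 <- varpart(y, g, nperm = 0)
  vp2 <- varpart(y, g[c("r", "p", "q")], nperm = 0)
  f1 <- setNames(vp1$fractions$raw, vp1$fractions$fraction)
  f2 <- setNames(vp2$fractions$raw, vp2$fractions$fraction)
  expect_equal(unname(f1["p"]), unname(f2["p"]), tolerance = 1e-12)
  expect_equal(unname(f1["q"]), unname(f2["q"]), tolerance = 1e-12)
  expect_equal(unname(f1["p:q:r"]), unname(f2["r:p:q"]), tolerance = 1e-12)
})

test_that("varpart matches vegan on a shared instance", {
  skip_if_not_installed("vegan")
  set.seed(6)
  n <- 60
  X1 <- matrix(rnorm(n * 2), n, 2)
  X2 <- matrix(rnorm(n), n, 1)
  y <- X1 %*% c(0.8, -0.4) + 0.6 * X2[, 1] + rnorm(n)
  vp <- varpart(scale(y)[, 1], list(A = X1, B = X2), nperm = 0)
  vv <- vegan::varpart(scale(y)[, 1], scale(X1), scale(X2))
  ind <- vv$part$indfract
  fr <- setNames(vp$fractions$raw, vp$fractions$fraction)
  expect_equal(unname(fr["A"]), ind$Adj.R.square[1], tolerance = 1e-6)
  expect_equal(unname(fr["B"]), ind$Adj.R.square[2], tolerance = 1e-6)
  expect_equal(unname(fr["A:B"]), ind$Adj.R.square[3], tolerance = 1e-6)
})

test_that("Freedman-Lane permutation test behaves at the extremes", {
  set.seed(7)
  n <- 100
  z <- rnorm(n)
  # focal group duplicating the conditioning group: F ~ 0, p ~ 1
  y <- z + rnorm(n)
  p_dup <- test_unique_fraction(y, focal = z, conditioning = z,
                                nperm = 199, seed = 1)
  expect_gt(p_dup, 0.9)
  # strong unique signal reaches the attainable minimum
  x <- rnorm(n)
  y2 <- 3 * x + 0.2 * z + rnorm(n, 0, 0.2)
  p_min <- test_unique_fraction(y2, focal = x, conditioning = z,
                                nperm = 999, seed = 1)
  expect_equal(p_min, 1 / 1000)
})

test_that("Freedman-Lane test is calibrated under the null", {
  set.seed(8)
  nrej <- 0
  nsim <- 400
  for (i in seq_len(nsim)) {
    z <- rnorm(30)
    x <- rnorm(30)
    y <- z + rnorm(30)        # x truly has no unique contribution
    p <- test_unique_fraction(y, x, z, nperm = 99, seed = i)
    nrej <- nrej + (p <= 0.05)
  }
  rate <- nrej / nsim
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / nsim)
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("varpart input contracts are enforced", {
  y <- rnorm(30)
  g <- list(a = rnorm(30))
  expect_error(varpart(y, g), "2-4")
  expect_error(varpart(y, c(g, list(b = rnorm(30), c = rnorm(30),
                                    d = rnorm(30), e = rnorm(30)))), "2-4")
  expect_error(varpart(y, list(rnorm(30), rnorm(30))), "named")
  expect_error(varpart(y, list(a = rnorm(30), b = rnorm(30)), nperm = 50),
               ">= 99")
})
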