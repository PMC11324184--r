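#' Adjusted R-squared of an OLS fit
#'
#' Ezekiel adjustment: \code{1 - (1 - R2) * (n - 1) / (n - p - 1)} with R2
#' from an intercept OLS of y on X.
#'
#' @param y numeric response.
#' @param X numeric matrix or data frame of predictors (p columns, n > p + 1).
#' @return adjusted R-squared (scalar; can be negative).
#' @export
adjusted_r2 <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) stop("need n > p + 1")
  fit <- stats::lm.fit(cbind(1, X), y)
  if (fit$rank < p + 1) stop("rank-deficient predictor matrix")
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

subset_label <- function(names, members) paste(names[members], collapse = ":")

#' Variation partitioning of adjusted R-squared among predictor groups
#'
#' Partitions the adjusted R-squared of an OLS regression of \code{y} on 2-4
#' named groups of predictors into unique and shared fractions. The adjusted
#' R-squared of every non-empty subset model is computed, and individual
#' fractions are obtained by Moebius inclusion-exclusion so that the
#' untruncated fractions sum exactly to the full-model adjusted R-squared.
#' Negative fractions (a known artefact of the adjustment) are reported raw
#' and also truncated to zero, following the convention that negative
#' explained fractions are interpreted as zeros. Significance of each
#' group's unique fraction is assessed by a Freedman-Lane permutation test:
#' residuals of the reduced model (all other groups) are permuted and a
#' pseudo-F for the focal group's partial contribution is recomputed.
#'
#' @param y numeric response.
#' @param groups named list of 2-4 predictor matrices / data frames / numeric
#'   vectors (disjoint groups, e.g. plant richness, microbial richness,
#'   environment axis, aridity).
#' @param nperm permutations for the unique-fraction tests (>= 99); 0 skips
#'   testing.
#' @param seed seed of the permutation stream.
#' @return object of class \code{"befmf_varpart"}: \code{r2adj_subsets} (named,
#'   one per non-empty group subset), \code{fractions} data frame (one row
#'   per fraction plus residual: \code{fraction}, \code{raw},
#'   \code{truncated}), \code{p_unique} (named), \code{r2adj_full}.
#' @export
varpart <- function(y, groups, nperm = 999, seed = 17) {
  k <- length(groups)
  if (k < 2 || k > 4) stop("number of predictor groups must be 2-4")
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be named")
  if (anyDuplicated(names(groups))) stop("group names must be distinct")
  groups <- lapply(groups, function(g) {
    g <- as.matrix(g)
    apply(g, 2, zscore)
  })
  gnames <- names(groups)
  n <- length(y)

  subsets <- lapply(seq_len(2^k - 1), function(code) which(bitwAnd(code, 2^(seq_len(k) - 1)) > 0))
  r2 <- vapply(subsets, function(s)
    adjusted_r2(y, do.call(cbind, groups[s])), numeric(1))
  names(r2) <- vapply(subsets, subset_label, "", names = gnames)

  # R(S) lookup by membership code; R(empty) = 0
  code_of <- function(s) sum(2^(s - 1))
  Rlook <- numeric(2^k)                 # index = code + 1
  Rlook[1] <- 0
  for (i in seq_along(subsets)) Rlook[code_of(subsets[[i]]) + 1] <- r2[i]

  full <- seq_len(k)
  fractions <- data.frame(fraction = character(0), raw = numeric(0))
  for (i in seq_along(subsets)) {
    A <- subsets[[i]]
    comp <- setdiff(full, A)
    # c_A = sum over T subset of A of (-1)^(|T|+1) R(T union complement(A))
    val <- 0
    tsubs <- c(list(integer(0)), lapply(seq_len(2^length(A) - 1), function(code)
      A[which(bitwAnd(code, 2^(seq_along(A) - 1)) > 0)]))
    for (T in tsubs) {
      val <- val + (-1)^(length(T) + 1) * Rlook[code_of(union(T, comp)) + 1]
    }
    fractions <- rbind(fractions,
                       data.frame(fraction = subset_label(gnames, A), raw = val))
  }
  r2full <- Rlook[code_of(full) + 1]
  fractions <- rbind(fractions,
                     data.frame(fraction = "residual", raw = 1 - r2full))
  fractions$truncated <- pmax(fractions$raw, 0)

  p_unique <- NULL
  if (nperm > 0) {
    if (nperm < 99) stop("nperm must be >= 99 (or 0 to skip)")
    p_unique <- vapply(seq_len(k), function(i) {
      test_unique_fraction(y, groups[[i]], do.call(cbind, groups[-i]),
                           nperm = nperm, seed = stream_seed(seed, gnames[i]))
    }, numeric(1))
    names(p_unique) <- gnames
  }

  structure(list(r2adj_subsets = r2, fractions = fractions,
                 p_unique = p_unique, r2adj_full = r2full,
                 n = n, nperm = nperm),
            class = "befmf_varpart")
}

#' @method print befmf_varpart
#' @export
print.befmf_varpart <- function(x, digits = 4, ...) {
  cat(sprintf("Variation partitioning (adjusted R^2), n = %d\n", x$n))
  cat(sprintf("  full model R^2adj = %.*f\n", digits, x$r2adj_full))
  df <- x$fractions
  df$raw <- round(df$raw, digits)
  df$truncated <- round(df$truncated, digits)
  if (!is.null(x$p_unique)) {
    df$p <- NA_real_
    un <- match(names(x$p_unique), df$fraction)
    df$p[un] <- round(x$p_unique, 4)
  }
  print(df, row.names = FALSE)
  invisible(x)
}

#' Freedman-Lane permutation test of a unique fraction
#'
#' Tests whether a focal predictor group explains variation beyond a set of
#' conditioning predictors. The observed pseudo-F compares the residual sums
#' of squares of the reduced (conditioning-only) and full models; the null
#' distribution is built by permuting the reduced-model residuals, adding
#' them back to the reduced-model fitted values, and recomputing the
#' pseudo-F (Freedman-Lane scheme). p = (#\{F_perm >= F_obs\} + 1) /
#' (nperm + 1).
#'
#' @param y response.
#' @param focal matrix of the focal group's predictors.
#' @param conditioning matrix of the conditioning predictors.
#' @param nperm number of permutations (>= 99).
#' @param seed RNG seed for the permutation stream.
#' @return permutation p-value (scalar).
#' @export
test_unique_fraction <- function(y, focal, conditioning, nperm = 999, seed = 17) {
  if (nperm < 99) stop("nperm must be >= 99")
  focal <- as.matrix(focal)
  conditioning <- as.matrix(conditioning)
  n <- length(y)
  Xr <- cbind(1, conditioning)
  Xf <- cbind(Xr, focal)
  fit_r <- stats::lm.fit(Xr, y)
  if (fit_r$rank < ncol(Xr)) stop("degenerate reduced model")
  df1 <- ncol(focal)
  df2 <- n - ncol(Xf)
  if (df2 <= 0) stop("not enough residual degrees of freedom")
  pseudo_f <- function(yy) {
    rss_r <- sum(stats::lm.fit(Xr, yy)$residuals^2)
    rss_f <- sum(stats::lm.fit(Xf, yy)$residuals^2)
    ((rss_r - rss_f) / df1) / (rss_f / df2)
  }
  f_obs <- pseudo_f(y)
  fitted_r <- y - fit_r$residuals
  res_r <- fit_r$residuals
  f_perm <- with_stream(seed, "freedman-lane", {
    vapply(seq_len(nperm), function(i)
      pseudo_f(fitted_r + res_r[sample.int(n)]), numeric(1))
  })
  (sum(f_perm >= f_obs) + 1) / (nperm + 1)
}
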