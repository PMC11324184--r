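#' Spearman rank correlation
#'
#' Rank correlation with midrank ties and a two-sided p-value (exact for
#' small tie-free samples, t approximation otherwise, as in
#' \code{stats::cor.test}).
#'
#' @param x,y numeric vectors, n >= 3.
#' @param controls ignored; present for interface symmetry with
#'   [partial_correlation()].
#' @return object of class \code{"association"}: \code{estimate} (rho),
#'   \code{p}, \code{n}, \code{method}, \code{controls}.
#' @export
spearman_assoc <- function(x, y, controls = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need n >= 3")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  structure(list(estimate = unname(ct$estimate), p = ct$p.value,
                 n = length(x), method = "spearman", controls = character(0)),
            class = "association")
}

#' @method print association
#' @export
print.association <- function(x, ...) {
  lab <- if (x$method == "spearman") "rho" else "partial r"
  cat(sprintf("%s = %.4f, p = %.4g, n = %d",
              lab, x$estimate, x$p, x$n))
  if (length(x$controls))
    cat(sprintf("  (controlling for %s)", paste(x$controls, collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Partial Pearson correlation
#'
#' Correlation between x and y after removing the linear contribution of a
#' set of control variables: both x and y are regressed on the controls
#' (with intercept) and the Pearson correlation of the residuals is
#' returned, with a t-based p-value on n - #controls - 2 degrees of freedom.
#' An empty control set reduces to the plain Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param controls numeric matrix / data frame of control variables (or
#'   NULL).
#' @return object of class \code{"association"}.
#' @export
partial_correlation <- function(x, y, controls = NULL) {
  n <- length(x)
  q <- if (is.null(controls)) 0L else ncol(as.matrix(controls))
  if (n <= q + 2) stop("need n > #controls + 2")
  if (q > 0) {
    Z <- cbind(1, as.matrix(controls))
    rx <- stats::lm.fit(Z, x)$residuals
    ry <- stats::lm.fit(Z, y)$residuals
    if (stats::sd(rx) < 1e-10 * stats::sd(x) || stats::sd(ry) < 1e-10 * stats::sd(y))
      stop("controls are collinear with x or y (no residual variance)")
  } else {
    rx <- x; ry <- y
  }
  r <- stats::cor(rx, ry)
  df <- n - q - 2
  tt <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  cn <- if (q > 0) colnames(as.matrix(controls)) %||% paste0("z", seq_len(q)) else character(0)
  structure(list(estimate = r, p = p, n = n, method = "partial", controls = cn),
            class = "association")
}

#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2 logLik + 2k + 2k(k + 1) / (n - k - 1), where k counts all
#' estimated parameters (coefficients plus the residual variance).
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size (> k + 1).
#' @return AICc (scalar).
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: need n > k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' AICc-weighted all-subsets model averaging
#'
#' Fits every subset of the candidate predictors (including the
#' intercept-only model) by OLS on z-scored response and predictors, weights
#' models by Akaike weights w = exp(-dAICc/2) / sum, and averages the
#' standardized coefficients over the full model set, with a coefficient of
#' zero in models that exclude the predictor ("zero method"; set
#' \code{method = "natural"} to average only over models containing the
#' predictor). Predictor importance is the share of each averaged
#' coefficient's absolute value in the sum of all averaged absolute
#' coefficients, expressed in percent; the model-averaged adjusted
#' R-squared is reported alongside as the total-variance figure.
#'
#' @param y response (z-scored internally).
#' @param X matrix / data frame of <= 12 candidate predictors (z-scored
#'   internally).
#' @param method coefficient averaging: \code{"zero"} (default) or
#'   \code{"natural"}.
#' @return object of class \code{"model_averaging"}: \code{models} data
#'   frame (terms, k, AICc, delta, weight, r2adj), \code{coefficients}
#'   (averaged standardized betas), \code{se} (unconditional SEs),
#'   \code{importance_pct}, \code{r2adj_avg}.
#' @export
model_average <- function(y, X, method = c("zero", "natural")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 1) stop("need at least one predictor")
  if (p > 12) stop("all-subsets averaging limited to 12 predictors")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  y <- zscore(y)
  X <- apply(X, 2, zscore)
  if (p > 1 && kappa(crossprod(X), exact = TRUE) > 1e10)
    stop("predictors are (near-)collinear")
  n <- length(y)

  n_models <- 2^p
  beta <- matrix(0, n_models, p, dimnames = list(NULL, colnames(X)))
  bse <- matrix(0, n_models, p)
  inc <- matrix(FALSE, n_models, p)
  aiccs <- numeric(n_models)
  r2adj <- numeric(n_models)
  terms <- character(n_models)
  for (code in 0:(n_models - 1)) {
    s <- which(bitwAnd(code, 2^(seq_len(p) - 1)) > 0)
    Xm <- cbind(`(Intercept)` = rep(1, n), X[, s, drop = FALSE])
    fit <- stats::lm.fit(Xm, y)
    rss <- sum(fit$residuals^2)
    km <- length(s) + 2           # coefficients + intercept + sigma
    ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
    aiccs[code + 1] <- aicc(ll, km, n)
    r2 <- 1 - rss / sum((y - mean(y))^2)
    r2adj[code + 1] <- 1 - (1 - r2) * (n - 1) / (n - length(s) - 1)
    if (length(s)) {
      beta[code + 1, s] <- fit$coefficients[-1]
      sigma2 <- rss / (n - length(s) - 1)
      XtXi <- chol2inv(chol(crossprod(Xm)))
      bse[code + 1, s] <- sqrt(sigma2 * diag(XtXi)[-1])
      inc[code + 1, s] <- TRUE
    }
    terms[code + 1] <- if (length(s)) paste(colnames(X)[s], collapse = "+") else "(null)"
  }
  delta <- aiccs - min(aiccs)
  w <- exp(-delta / 2)
  w <- w / sum(w)

  if (method == "zero") {
    bbar <- colSums(w * beta)
    se <- vapply(seq_len(p), function(j)
      sum(w * sqrt(bse[, j]^2 + (beta[, j] - bbar[j])^2)), numeric(1))
  } else {
    bbar <- vapply(seq_len(p), function(j) {
      wj <- w[inc[, j]] / sum(w[inc[, j]])
      sum(wj * beta[inc[, j], j])
    }, numeric(1))
    se <- vapply(seq_len(p), function(j) {
      sel <- inc[, j]
      wj <- w[sel] / sum(w[sel])
      sum(wj * sqrt(bse[sel, j]^2 + (beta[sel, j] - bbar[j])^2))
    }, numeric(1))
  }
  names(bbar) <- names(se) <- colnames(X)
  denom <- sum(abs(bbar))
  importance <- if (denom > 0) 100 * abs(bbar) / denom else
    stats::setNames(rep(NA_real_, p), colnames(X))

  structure(list(models = data.frame(terms = terms, k = rowSums(inc) + 2,
                                     AICc = aiccs, delta = delta, weight = w,
                                     r2adj = r2adj),
                 coefficients = bbar, se = se,
                 importance_pct = importance,
                 r2adj_avg = sum(w * r2adj),
                 method = method, n = n),
            class = "model_averaging")
}

#' @method print model_averaging
#' @export
print.model_averaging <- function(x, digits = 4, ...) {
  cat(sprintf("AICc model averaging (%s method), %d models, n = %d\n",
              x$method, nrow(x$models), x$n))
  df <- data.frame(beta_avg = round(x$coefficients, digits),
                   se = round(x$se, digits),
                   importance_pct = round(x$importance_pct, 1))
  print(df)
  cat(sprintf("model-averaged R^2adj = %.*f\n", digits, x$r2adj_avg))
  invisible(x)
}

#' @export
coef.model_averaging <- function(object, ...) object$coefficients

#' Linear mixed model with a single random intercept
#'
#' REML fit of a Gaussian linear mixed model with one random intercept (the
#' plant-combination contract: a random effect per species combination to
#' absorb compositional variation), via \pkg{lmerTest}. Fixed effects get
#' Satterthwaite-type t/F tests. When the grouping factor has a single
#' level the model degenerates and an OLS fit is returned with a fallback
#' flag.
#'
#' @param y response.
#' @param predictors data frame of fixed-effect predictors.
#' @param group grouping factor for the random intercept.
#' @return object of class \code{"mixedfit"}: \code{coefficients} data
#'   frame (estimate, se, df, t, p per fixed effect), \code{sigma_group},
#'   \code{sigma_resid}, \code{ols_fallback}, and the underlying fit in
#'   \code{model}.
#' @export
fit_mixed <- function(y, predictors, group) {
  predictors <- as.data.frame(predictors)
  group <- as.factor(group)
  dat <- data.frame(.y = y, predictors, .grp = group, check.names = FALSE)
  fixed <- paste(colnames(predictors), collapse = " + ")
  if (nlevels(droplevels(group)) < 2) {
    warning("grouping factor has a single level; falling back to OLS")
    fm <- stats::lm(stats::as.formula(paste(".y ~", fixed)), data = dat)
    sm <- summary(fm)$coefficients
    tab <- data.frame(estimate = sm[, 1], se = sm[, 2],
                      df = stats::df.residual(fm), t = sm[, 3], p = sm[, 4])
    return(structure(list(coefficients = tab, sigma_group = 0,
                          sigma_resid = summary(fm)$sigma,
                          ols_fallback = TRUE, model = fm),
                     class = "mixedfit"))
  }
  f <- stats::as.formula(paste(".y ~", fixed, "+ (1 | .grp)"))
  fm <- lmerTest::lmer(f, data = dat, REML = TRUE)
  sm <- stats::coef(summary(fm))
  tab <- data.frame(estimate = sm[, "Estimate"], se = sm[, "Std. Error"],
                    df = sm[, "df"], t = sm[, "t value"], p = sm[, "Pr(>|t|)"])
  vc <- as.data.frame(lme4::VarCorr(fm))
  structure(list(coefficients = tab,
                 sigma_group = vc$sdcor[vc$grp == ".grp"],
                 sigma_resid = vc$sdcor[vc$grp == "Residual"],
                 ols_fallback = FALSE, model = fm),
            class = "mixedfit")
}

#' @method print mixedfit
#' @export
print.mixedfit <- function(x, digits = 4, ...) {
  cat("Linear mixed model (single random intercept",
      if (x$ols_fallback) ", OLS fallback)" else ")", "\n", sep = "")
  print(round(x$coefficients, digits))
  cat(sprintf("random-intercept SD = %.4f, residual SD = %.4f\n",
              x$sigma_group, x$sigma_resid))
  invisible(x)
}

#' @export
coef.mixedfit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, rownames(object$coefficients))
}
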