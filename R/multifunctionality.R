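#' Min-max standardize one ecosystem function
#'
#' Rescales a raw function column to the unit interval as
#' \code{(x - min(x)) / (max(x) - min(x))}, after an optional transform
#' (\code{"log"} = log10, requires strictly positive values; \code{"sqrt"}
#' requires non-negative values). The observed minimum maps to 0 and the
#' observed maximum to 1; ordering is preserved. Missing values are excluded
#' from the min/max and propagated.
#'
#' @param x numeric vector of raw function values.
#' @param transform one of \code{"none"}, \code{"log"}, \code{"sqrt"}.
#' @return numeric vector in [0, 1].
#' @export
standardize_function <- function(x, transform = c("none", "log", "sqrt")) {
  transform <- match.arg(transform)
  ok <- is.finite(x)
  if (sum(ok) < 2) stop("need at least 2 finite values")
  if (transform == "log") {
    if (any(x[ok] <= 0)) stop("log transform requires strictly positive values")
    x <- log10(x)
  } else if (transform == "sqrt") {
    if (any(x[ok] < 0)) stop("sqrt transform requires non-negative values")
    x <- sqrt(x)
  }
  if (length(unique(x[is.finite(x)])) < 2)
    stop("degenerate input: constant column cannot be min-max standardized")
  r <- range(x, na.rm = TRUE)
  (x - r[1]) / (r[2] - r[1])
}

as_function_matrix <- function(functions) {
  if (is.data.frame(functions)) {
    ids <- if ("sample_id" %in% names(functions)) functions$sample_id else rownames(functions)
    num <- functions[, setdiff(names(functions), "sample_id"), drop = FALSE]
    m <- as.matrix(num)
    rownames(m) <- ids
    m
  } else {
    m <- as.matrix(functions)
    if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
    m
  }
}

check_service_map <- function(service_map, function_names) {
  if (length(service_map) == 0) stop("empty service map")
  for (s in names(service_map)) {
    if (length(service_map[[s]]) == 0) stop("empty service: ", s)
    missing <- setdiff(service_map[[s]], function_names)
    if (length(missing))
      stop("service map names absent functions: ", paste(missing, collapse = ", "))
  }
  mapped <- unlist(service_map, use.names = FALSE)
  if (anyDuplicated(mapped))
    stop("functions must belong to exactly one service; duplicated: ",
         paste(unique(mapped[duplicated(mapped)]), collapse = ", "))
  invisible(service_map)
}

#' Ecosystem multifunctionality indices
#'
#' Standardizes every ecosystem function to [0, 1] (after optional
#' per-function transforms), averages functions within each named ecosystem
#' service, and computes two multifunctionality indices per sample: the
#' weighted index (mean over service means, so every service contributes
#' equally regardless of how many functions it holds) and the averaged index
#' (flat mean over all standardized functions). Missing values are excluded
#' pairwise; a sample whose every function within some service is missing is
#' flagged incomplete.
#'
#' @param functions data frame (optionally with a \code{sample_id} column) or
#'   matrix of raw function values, samples in rows.
#' @param service_map named list mapping each service to its member function
#'   names; every function must belong to exactly one service.
#' @param transform_map optional named character vector of per-function
#'   transforms (\code{"none"}, \code{"log"}, \code{"sqrt"}).
#' @return object of class \code{"multifunctionality"}: list with
#'   \code{standardized} (samples x functions, in [0, 1]),
#'   \code{service_means} (samples x services), \code{emf_weighted},
#'   \code{emf_averaged} (per-sample), \code{complete} (logical flag),
#'   \code{service_map}, \code{transform_map}.
#' @export
multifunctionality <- function(functions, service_map, transform_map = NULL) {
  m <- as_function_matrix(functions)
  if (any(colSums(is.finite(m)) == 0)) stop("all-missing function column")
  check_service_map(service_map, colnames(m))
  mapped <- unlist(service_map, use.names = FALSE)
  extra <- setdiff(colnames(m), mapped)
  if (length(extra))
    stop("functions not assigned to any service: ", paste(extra, collapse = ", "))

  std <- m
  for (j in colnames(m)) {
    tr <- if (!is.null(transform_map) && j %in% names(transform_map))
      transform_map[[j]] else "none"
    std[, j] <- standardize_function(m[, j], tr)
  }

  svc <- sapply(service_map, function(fns)
    rowMeans(std[, fns, drop = FALSE], na.rm = TRUE))
  svc[is.nan(svc)] <- NA_real_
  complete <- apply(svc, 1, function(r) all(is.finite(r)))

  out <- list(standardized = std,
              service_means = svc,
              emf_weighted = rowMeans(svc, na.rm = TRUE),
              emf_averaged = rowMeans(std, na.rm = TRUE),
              complete = complete,
              service_map = service_map,
              transform_map = transform_map)
  class(out) <- "multifunctionality"
  out
}

#' @method print multifunctionality
#' @export
print.multifunctionality <- function(x, ...) {
  cat("Ecosystem multifunctionality\n")
  cat(sprintf("  %d samples, %d functions in %d services\n",
              nrow(x$standardized), ncol(x$standardized), length(x$service_map)))
  cat(sprintf("  weighted EMF:  mean %.3f  range [%.3f, %.3f]\n",
              mean(x$emf_weighted), min(x$emf_weighted), max(x$emf_weighted)))
  cat(sprintf("  averaged EMF:  mean %.3f  range [%.3f, %.3f]\n",
              mean(x$emf_averaged), min(x$emf_averaged), max(x$emf_averaged)))
  if (!all(x$complete))
    cat(sprintf("  %d sample(s) with a fully missing service\n", sum(!x$complete)))
  invisible(x)
}

#' Composite richness metric
#'
#' Min-max standardizes the richness of each organism group to [0, 1] and
#' averages the groups equally, so each group contributes the same weight to
#' the composite (e.g. microbial = bacteria + fungi; multitrophic = plants +
#' microbes).
#'
#' @param richness data frame or matrix of per-group richness columns.
#' @return numeric vector in [0, 1], one value per sample.
#' @export
composite_richness <- function(richness) {
  had_names <- !is.null(rownames(richness)) ||
    (is.data.frame(richness) && "sample_id" %in% names(richness))
  m <- as_function_matrix(richness)
  if (ncol(m) < 1) stop("need at least one richness group")
  std <- apply(m, 2, minmax01)
  out <- rowMeans(std)
  if (!had_names) out <- unname(out)
  out
}

#' Multi-threshold function counts
#'
#' For each threshold t (percent), counts how many functions each sample
#' holds above t% of that function's maximum observed value across the
#' analyzed samples. Exceedance is strict (\code{>}) by default, switchable
#' to \code{>=}. When a transform map is supplied, counting is done on the
#' transformed scale.
#'
#' @param functions raw function matrix or data frame (see
#'   [multifunctionality()]).
#' @param thresholds percentages in (0, 100); default the 5-99 grid plus
#'   nothing else (the primary set 10/25/50/75/90 is a subset).
#' @param transform_map optional per-function transforms applied before
#'   thresholding.
#' @param strict logical; \code{TRUE} uses strict exceedance.
#' @return integer matrix, samples x thresholds (columns named "t5" etc.).
#' @export
multithreshold_counts <- function(functions, thresholds = 5:99,
                                  transform_map = NULL, strict = TRUE) {
  m <- as_function_matrix(functions)
  if (any(thresholds <= 0 | thresholds >= 100))
    stop("thresholds must lie strictly between 0 and 100")
  if (!is.null(transform_map)) {
    for (j in intersect(names(transform_map), colnames(m))) {
      tr <- transform_map[[j]]
      if (tr == "log") m[, j] <- log10(m[, j]) else if (tr == "sqrt") m[, j] <- sqrt(m[, j])
    }
  }
  maxf <- apply(m, 2, max, na.rm = TRUE)
  counts <- vapply(thresholds, function(t) {
    cut <- (t / 100) * maxf
    cmp <- sweep(m, 2, cut, if (strict) ">" else ">=")
    as.integer(rowSums(cmp, na.rm = TRUE))
  }, integer(nrow(m)))
  counts <- matrix(counts, nrow = nrow(m),
                   dimnames = list(rownames(m), paste0("t", thresholds)))
  counts
}

#' Diversity slope per functioning threshold
#'
#' Regresses the per-sample count of functions above each threshold on a
#' diversity metric, returning the slope, its standard error, adjusted
#' R-squared and p-value per threshold; optionally picks the better of a
#' linear and a quadratic fit by adjusted R-squared. The slope-versus-
#' threshold curve characterizes whether diversity supports high or low
#' levels of functioning.
#'
#' @param diversity numeric vector (>= 3 distinct values).
#' @param counts matrix from [multithreshold_counts()].
#' @param fit \code{"linear"} or \code{"best"} (linear vs quadratic by
#'   adjusted R-squared; for \code{"best"} the reported slope is the linear
#'   coefficient of the chosen fit).
#' @return data frame with one row per threshold: \code{threshold},
#'   \code{slope}, \code{se}, \code{r2adj}, \code{p}, \code{fit}.
#' @export
threshold_slope_curve <- function(diversity, counts, fit = c("linear", "best")) {
  fit <- match.arg(fit)
  if (length(unique(diversity)) < 3)
    stop("degenerate input: diversity needs >= 3 distinct values")
  ths <- as.numeric(sub("^t", "", colnames(counts)))
  rows <- lapply(seq_along(ths), function(i) {
    y <- counts[, i]
    if (stats::var(y) == 0) {
      return(data.frame(threshold = ths[i], slope = 0, se = 0, r2adj = 0,
                        p = NA_real_, fit = "linear"))
    }
    if (fit == "best") {
      bf <- best_fit_regression(diversity, y)
      sm <- summary(bf$model)
      data.frame(threshold = ths[i],
                 slope = sm$coefficients[2, 1], se = sm$coefficients[2, 2],
                 r2adj = bf$r2adj, p = bf$p, fit = bf$fit)
    } else {
      fm <- stats::lm(y ~ diversity)
      sm <- summary(fm)
      pv <- stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                      lower.tail = FALSE)
      data.frame(threshold = ths[i],
                 slope = sm$coefficients[2, 1], se = sm$coefficients[2, 2],
                 r2adj = sm$adj.r.squared,
                 p = unname(pv), fit = "linear")
    }
  })
  do.call(rbind, rows)
}

#' Best of linear vs quadratic regression
#'
#' Fits \code{y ~ x} and \code{y ~ x + x^2} and returns the fit with the
#' larger adjusted R-squared (ties resolved in favour of the linear fit).
#'
#' @param x,y numeric vectors, n >= 4, x not constant.
#' @return list: \code{fit} ("linear"/"quadratic"), \code{model} (the lm),
#'   \code{coefficients}, \code{r2adj}, \code{p} (overall F-test).
#' @export
best_fit_regression <- function(x, y) {
  if (length(x) < 4) stop("need n >= 4")
  if (length(unique(x)) < 2) stop("degenerate input: constant x")
  lin <- stats::lm(y ~ x)
  quad <- stats::lm(y ~ x + I(x^2))
  r2l <- summary(lin)$adj.r.squared
  r2q <- summary(quad)$adj.r.squared
  pick <- if (r2q > r2l) "quadratic" else "linear"
  model <- if (pick == "quadratic") quad else lin
  sm <- summary(model)
  p <- if (is.null(sm$fstatistic)) NA_real_ else
    unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE))
  list(fit = pick, model = model, coefficients = stats::coef(model),
       r2adj = sm$adj.r.squared, p = p)
}
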