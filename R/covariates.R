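#' Aridity index
#'
#' Ratio of mean annual precipitation to potential evapotranspiration
#' (dimensionless); lower values indicate more arid sites.
#'
#' @param map mean annual precipitation, mm/yr (>= 0).
#' @param pet potential evapotranspiration, mm/yr (> 0).
#' @return numeric aridity index, MAP / PET.
#' @export
aridity_index <- function(map, pet) {
  if (any(pet <= 0)) stop("PET must be > 0")
  if (any(map < 0)) stop("MAP must be >= 0")
  map / pet
}

#' UNEP aridity classification
#'
#' Classifies an aridity index into the UNEP (1992) categories: hyperarid
#' (AI < 0.05), arid (0.05 <= AI < 0.2), semiarid (0.2 <= AI < 0.5), dry
#' subhumid (0.5 <= AI < 0.65) and humid (AI >= 0.65). Lower bounds are
#' inclusive, upper bounds exclusive.
#'
#' @param ai numeric aridity index (>= 0).
#' @return character vector of lower-case class labels.
#' @export
classify_aridity <- function(ai) {
  if (any(ai < 0)) stop("aridity index must be >= 0")
  out <- character(length(ai))
  out[ai < 0.05] <- "hyperarid"
  out[ai >= 0.05 & ai < 0.2] <- "arid"
  out[ai >= 0.2 & ai < 0.5] <- "semiarid"
  out[ai >= 0.5 & ai < 0.65] <- "dry subhumid"
  out[ai >= 0.65] <- "humid"
  out
}

new_composition_axis <- function(scores, varexp, method, ids = NULL,
                                 negative_eigenvalues = NULL) {
  structure(list(scores = stats::setNames(scores, ids),
                 variance_explained = varexp, method = method,
                 negative_eigenvalues = negative_eigenvalues),
            class = "composition_axis")
}

#' @method print composition_axis
#' @export
print.composition_axis <- function(x, ...) {
  cat(sprintf("Composite axis (%s): %d samples, %.1f%% variance explained\n",
              x$method, length(x$scores), 100 * x$variance_explained))
  if (!is.null(x$negative_eigenvalues) && length(x$negative_eigenvalues))
    cat(sprintf("  %d negative eigenvalue(s), most negative %.4g\n",
                length(x$negative_eigenvalues), min(x$negative_eigenvalues)))
  invisible(x)
}

#' First principal-component axis as a composite covariate
#'
#' Z-scores every column (PCA on the correlation structure, since the inputs
#' mix units), extracts scores on the leading eigenvector of the correlation
#' matrix, fixes the sign so the loading of the first input column is
#' non-negative, and z-scores the scores. Used to collapse several
#' environmental or plant attributes into one standardized covariate.
#'
#' @param x numeric matrix or data frame, >= 3 rows, >= 2 non-constant
#'   columns.
#' @return object of class \code{"composition_axis"}: standardized scores,
#'   fraction of variance explained, method tag \code{"PCA"}.
#' @export
pca_first_axis <- function(x) {
  m <- as_function_matrix(x)
  if (nrow(m) < 3 || ncol(m) < 2) stop("need >= 3 rows and >= 2 columns")
  z <- apply(m, 2, zscore)
  e <- eigen(stats::cov(z), symmetric = TRUE)
  if (e$values[1] <= 1e-12) stop("rank-0 matrix")
  v <- e$vectors[, 1]
  if (v[1] < 0) v <- -v
  scores <- drop(z %*% v)
  new_composition_axis(zscore(scores), e$values[1] / sum(pmax(e$values, 0)),
                       "PCA", rownames(m))
}

#' Leading PCoA axis of Jaccard distances
#'
#' Computes pairwise Jaccard dissimilarity d = 1 - |A and B| / |A or B| on a
#' presence/absence matrix, applies classical scaling (principal coordinates
#' via the double-centered Gower matrix), and returns standardized scores on
#' the leading axis, with the sign fixed so the covariance of the scores with
#' the first input column is non-negative. Negative eigenvalues, if any, are
#' reported but not corrected. Serves as the community-composition covariate.
#'
#' @param x binary (0/1) matrix or data frame, >= 3 rows; no row may be all
#'   zero (Jaccard is undefined for an empty pair).
#' @return object of class \code{"composition_axis"} with method tag
#'   \code{"PCoA-Jaccard"}.
#' @export
jaccard_pcoa_axis <- function(x) {
  m <- as_function_matrix(x)
  if (nrow(m) < 3) stop("need >= 3 rows")
  if (!all(m %in% c(0, 1))) stop("matrix must be binary presence/absence")
  zero <- rownames(m)[rowSums(m) == 0]
  if (length(zero))
    stop("Jaccard distance undefined for all-zero rows: ",
         paste(zero, collapse = ", "))
  d <- stats::dist(m, method = "binary")
  sc <- stats::cmdscale(d, k = min(nrow(m) - 1, 10), eig = TRUE)
  ev <- sc$eig
  scores <- sc$points[, 1]
  if (stats::cov(scores, m[, 1]) < 0) scores <- -scores
  new_composition_axis(zscore(scores), max(ev[1], 0) / sum(pmax(ev, 0)),
                       "PCoA-Jaccard", rownames(m),
                       negative_eigenvalues = ev[ev < -1e-12])
}

#' Shannon diversity index
#'
#' H' = -sum p_i log(p_i) over taxa with positive abundance, natural log.
#'
#' @param abundance non-negative numeric vector with positive sum.
#' @return Shannon-Wiener index H' >= 0.
#' @export
shannon_index <- function(abundance) {
  if (any(abundance < 0)) stop("abundances must be non-negative")
  s <- sum(abundance)
  if (s <= 0) stop("total abundance must be positive")
  p <- abundance[abundance > 0] / s
  -sum(p * log(p))
}
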