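#' Declare a piecewise structural equation model
#'
#' A piecewise SEM is a directed acyclic graph of observed variables in
#' which every endogenous node is modelled by its own (optionally mixed)
#' linear regression on its parents. The returned object holds the DAG, optional
#' random-intercept groupings per equation, and optional composite
#' variables (a named linear combination of indicator columns, fitted from
#' the data when the model is fit).
#'
#' @param edges either a data frame with columns \code{from}, \code{to} or
#'   a list of formulas (\code{y ~ x1 + x2} declares edges x1 -> y,
#'   x2 -> y).
#' @param random optional named character vector mapping an endogenous node
#'   to the column name of its random-intercept grouping factor.
#' @param composites optional named list mapping a composite variable name
#'   to its indicator column names; the composite is formed as the fitted
#'   linear combination of the indicators taken from the regression of the
#'   composite's (topologically first) child on the indicators, then
#'   standardized.
#' @return object of class \code{"sem_spec"}: \code{nodes}, \code{edges},
#'   \code{topo} (deterministic topological order), \code{random},
#'   \code{composites}.
#' @export
sem_spec <- function(edges, random = NULL, composites = NULL) {
  if (is.list(edges) && !is.data.frame(edges)) {
    rows <- lapply(edges, function(f) {
      stopifnot(inherits(f, "formula"))
      to <- as.character(f[[2]])
      from <- all.vars(f[[3]])
      data.frame(from = from, to = rep(to, length(from)),
                 stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, rows)
  }
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  edges <- edges[, c("from", "to")]
  if (any(edges$from == edges$to)) stop("self-loop in edge set")
  if (anyDuplicated(edges)) stop("duplicated edge")
  nodes <- sort(unique(c(edges$from, edges$to)))
  topo <- topo_sort(nodes, edges)          # errors on cycles
  endo <- unique(edges$to)
  if (!is.null(random) && !all(names(random) %in% endo))
    stop("random groupings must be declared for endogenous nodes")
  structure(list(nodes = nodes, edges = edges, topo = topo,
                 random = random, composites = composites),
            class = "sem_spec")
}

# Kahn's algorithm; ties broken by node name for a deterministic order.
topo_sort <- function(nodes, edges) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (v in edges$to) indeg[v] <- indeg[v] + 1L
  out <- character(0)
  avail <- sort(names(indeg)[indeg == 0])
  while (length(avail)) {
    u <- avail[1]
    avail <- avail[-1]
    out <- c(out, u)
    ch <- edges$to[edges$from == u]
    for (v in ch) {
      indeg[v] <- indeg[v] - 1L
      if (indeg[v] == 0) avail <- sort(c(avail, v))
    }
  }
  if (length(out) < length(nodes)) stop("edge set is cyclic")
  out
}

parents_of <- function(spec, v) sort(spec$edges$from[spec$edges$to == v])

#' d-separation basis set of a DAG
#'
#' For every pair of non-adjacent variables, emits the independence claim
#' (u, v | union of the parents of both), with u the earlier and v the
#' later variable in the deterministic topological order. Testing each
#' claim and combining the p-values with Fisher's C yields the overall
#' goodness-of-fit test of the piecewise SEM.
#'
#' @param spec a [sem_spec()].
#' @return list of claims, each a list with \code{u}, \code{v},
#'   \code{conditioning} (character vector).
#' @export
basis_set <- function(spec) {
  stopifnot(inherits(spec, "sem_spec"))
  pos <- match(spec$nodes, spec$topo)
  names(pos) <- spec$nodes
  adj <- paste(spec$edges$from, spec$edges$to)
  claims <- list()
  nn <- spec$topo
  for (i in seq_along(nn)) for (j in seq_along(nn)) {
    if (i >= j) next
    u <- nn[i]; v <- nn[j]
    if (paste(u, v) %in% adj || paste(v, u) %in% adj) next
    cond <- setdiff(union(parents_of(spec, u), parents_of(spec, v)), c(u, v))
    claims[[length(claims) + 1]] <- list(u = u, v = v, conditioning = sort(cond))
  }
  claims
}

#' Fisher's C statistic
#'
#' Combines the p-values of the d-separation claims into
#' \eqn{C = -2 \sum \ln p_i}, chi-square distributed with 2k degrees of
#' freedom when all claims hold; the model is conventionally accepted when
#' the resulting p-value exceeds 0.05. An empty claim set means the DAG is
#' saturated: C = 0, df = 0 and the p-value is reported as 1 with a
#' saturated flag.
#'
#' @param p numeric vector of claim p-values in (0, 1].
#' @return list: \code{C}, \code{df}, \code{p}, \code{saturated},
#'   \code{degenerate} (TRUE when some p was 0, making C infinite).
#' @export
fishers_c <- function(p) {
  if (length(p) == 0)
    return(list(C = 0, df = 0L, p = 1, saturated = TRUE, degenerate = FALSE))
  if (any(p < 0 | p > 1)) stop("p-values must lie in (0, 1]")
  if (any(p == 0))
    return(list(C = Inf, df = 2L * length(p), p = 0, saturated = FALSE,
                degenerate = TRUE))
  C <- max(-2 * sum(log(p)), 0)
  df <- 2L * length(p)
  list(C = C, df = df, p = stats::pchisq(C, df, lower.tail = FALSE),
       saturated = FALSE, degenerate = FALSE)
}

fit_equation <- function(response, rhs, data, grouping = NULL) {
  f <- stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
  if (!is.null(grouping)) {
    f <- stats::as.formula(paste(response, "~", paste(rhs, collapse = " + "),
                                 "+ (1 |", grouping, ")"))
    fm <- lmerTest::lmer(f, data = data, REML = TRUE)
    sm <- stats::coef(summary(fm))
    list(model = fm, coefs = sm[, "Estimate"], se = sm[, "Std. Error"],
         p = sm[, "Pr(>|t|)"],
         r2 = stats::cor(stats::fitted(fm), data[[response]])^2,
         k = nrow(sm) + 2)            # + RE variance + residual variance
  } else {
    fm <- stats::lm(f, data = data)
    sm <- summary(fm)$coefficients
    list(model = fm, coefs = sm[, 1], se = sm[, 2], p = sm[, 4],
         r2 = summary(fm)$r.squared, k = nrow(sm) + 1)
  }
}

#' Fit a piecewise structural equation model
#'
#' Fits each endogenous node's equation separately (OLS, or a single
#' random-intercept mixed model where a grouping is declared), standardizes
#' path coefficients by the SD ratio of predictor to response, tests every
#' d-separation claim of the basis set (p-value of u in the regression of v
#' on parents(v) and u), and combines the claim p-values into Fisher's C.
#' The model-level AIC is reported in the piecewise form C + 2K, with K the
#' total number of parameters estimated across the structural equations.
#'
#' @param spec a [sem_spec()].
#' @param data data frame holding every spec variable (plus composite
#'   indicators and grouping factors).
#' @return object of class \code{"sem_fit"}: \code{paths} data frame
#'   (from, to, estimate, se, std_estimate, std_se, p), \code{r2} named
#'   per-equation R-squared, \code{basis} data frame of claims with
#'   p-values, \code{C}, \code{df}, \code{p_C}, \code{saturated},
#'   \code{AIC}, \code{K}, \code{data} (with composites appended).
#' @export
fit_sem <- function(spec, data) {
  stopifnot(inherits(spec, "sem_spec"))
  data <- as.data.frame(data)
  if (!is.null(spec$composites)) {
    for (cn in names(spec$composites)) {
      ind <- spec$composites[[cn]]
      missing <- setdiff(ind, names(data))
      if (length(missing))
        stop("composite indicators absent from data: ",
             paste(missing, collapse = ", "))
      child <- spec$topo[spec$topo %in% spec$edges$to[spec$edges$from == cn]][1]
      if (is.na(child)) stop("composite ", cn, " has no child equation")
      cf <- stats::coef(stats::lm(
        stats::as.formula(paste(child, "~", paste(ind, collapse = " + "))),
        data = data))[-1]
      data[[cn]] <- zscore(as.matrix(data[, ind, drop = FALSE]) %*% cf)
    }
  }
  missing <- setdiff(spec$nodes, names(data))
  if (length(missing))
    stop("spec variables absent from data: ", paste(missing, collapse = ", "))

  endo <- intersect(spec$topo, unique(spec$edges$to))
  paths <- list()
  r2 <- stats::setNames(numeric(length(endo)), endo)
  K <- 0
  for (v in endo) {
    pa <- parents_of(spec, v)
    grouping <- if (!is.null(spec$random)) unname(spec$random[v]) else NULL
    if (!is.null(grouping) && is.na(grouping)) grouping <- NULL
    eq <- fit_equation(v, pa, data, grouping)
    if (any(!is.finite(eq$coefs)))
      stop("rank-deficient equation for node ", v)
    r2[v] <- eq$r2
    K <- K + eq$k
    sdy <- stats::sd(data[[v]])
    for (x in pa) {
      sc <- stats::sd(data[[x]]) / sdy
      paths[[length(paths) + 1]] <- data.frame(
        from = x, to = v, estimate = unname(eq$coefs[x]),
        se = unname(eq$se[x]),
        std_estimate = unname(eq$coefs[x]) * sc,
        std_se = unname(eq$se[x]) * sc,
        p = unname(eq$p[x]), stringsAsFactors = FALSE)
    }
  }
  paths <- do.call(rbind, paths)

  claims <- basis_set(spec)
  basis <- NULL
  pvals <- numeric(0)
  if (length(claims)) {
    rows <- lapply(claims, function(cl) {
      v <- cl$v; u <- cl$u
      rhs <- unique(c(parents_of(spec, v), cl$conditioning, u))
      grouping <- if (!is.null(spec$random)) unname(spec$random[v]) else NULL
      if (!is.null(grouping) && is.na(grouping)) grouping <- NULL
      eq <- fit_equation(v, rhs, data, grouping)
      data.frame(u = u, v = v,
                 conditioning = paste(cl$conditioning, collapse = ","),
                 p = unname(eq$p[u]), stringsAsFactors = FALSE)
    })
    basis <- do.call(rbind, rows)
    pvals <- basis$p
  }
  fc <- fishers_c(pvals)

  structure(list(paths = paths, r2 = r2, basis = basis,
                 C = fc$C, df = fc$df, p_C = fc$p,
                 saturated = fc$saturated, degenerate = fc$degenerate,
                 K = K, AIC = fc$C + 2 * K, spec = spec, data = data),
            class = "sem_fit")
}

#' @method print sem_fit
#' @export
print.sem_fit <- function(x, digits = 4, ...) {
  cat("Piecewise structural equation model\n")
  df <- x$paths
  for (cl in c("estimate", "se", "std_estimate", "std_se", "p"))
    df[[cl]] <- round(df[[cl]], digits)
  print(df, row.names = FALSE)
  cat("R^2 per equation:\n")
  print(round(x$r2, digits))
  if (x$saturated) {
    cat("Saturated model (empty basis set): C = 0, df = 0, p = 1\n")
  } else {
    cat(sprintf("Fisher's C = %.3f, df = %d, p = %.4f%s\n", x$C, x$df, x$p_C,
                if (x$degenerate) " (degenerate: a claim p-value was 0)" else ""))
  }
  cat(sprintf("AIC (C + 2K) = %.3f, K = %d\n", x$AIC, x$K))
  invisible(x)
}

#' Direct, indirect and total effects in a fitted piecewise SEM
#'
#' The direct effect is the standardized coefficient of the edge from ->
#' to (0 if absent); each indirect effect is the product of standardized
#' coefficients along a directed path of length >= 2; the total effect is
#' their sum.
#'
#' @param fit a [fit_sem()] result.
#' @param from,to node names.
#' @return list: \code{direct}, \code{indirect} (sum over paths),
#'   \code{total}, \code{paths} (list of the contributing paths).
#' @export
sem_effects <- function(fit, from, to) {
  stopifnot(inherits(fit, "sem_fit"))
  ed <- fit$paths
  coef_of <- function(a, b) {
    i <- which(ed$from == a & ed$to == b)
    if (length(i)) ed$std_estimate[i] else NA_real_
  }
  out_paths <- list()
  walk <- function(node, acc, prod) {
    if (node == to && length(acc) > 1) {
      out_paths[[length(out_paths) + 1]] <<- list(path = acc, effect = prod)
      return(invisible())
    }
    for (nxt in ed$to[ed$from == node]) {
      if (nxt %in% acc) next
      walk(nxt, c(acc, nxt), prod * coef_of(node, nxt))
    }
  }
  walk(from, from, 1)
  direct <- coef_of(from, to)
  if (!length(which(ed$from == from & ed$to == to))) direct <- 0
  indirect_paths <- Filter(function(p) length(p$path) > 2, out_paths)
  indirect <- if (length(indirect_paths))
    sum(vapply(indirect_paths, `[[`, numeric(1), "effect")) else 0
  list(direct = direct, indirect = indirect, total = direct + indirect,
       paths = out_paths)
}
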