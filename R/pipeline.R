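#' Validate a set of input tables
#'
#' Checks id alignment across the function, diversity and design tables,
#' duplicated sample ids, missingness, constant columns and service-map
#' closure. Fatal problems (misaligned or duplicated ids, functions named
#' in the service map but absent from the function table) are separated
#' from non-fatal warnings (missing cells, constant columns).
#'
#' @param functions function table (with \code{sample_id}).
#' @param diversity diversity table (with \code{sample_id}), or NULL.
#' @param design design / covariate table (with \code{sample_id}), or NULL.
#' @param service_map named list mapping services to function names, or
#'   NULL.
#' @return list with \code{errors}, \code{warnings} (character vectors) and
#'   \code{ok} (TRUE when no fatal error).
#' @export
validate_inputs <- function(functions, diversity = NULL, design = NULL,
                            service_map = NULL) {
  errors <- character(0)
  warnings <- character(0)
  tabs <- list(functions = functions, diversity = diversity, design = design)
  tabs <- Filter(Negate(is.null), tabs)
  for (nm in names(tabs)) {
    t <- tabs[[nm]]
    if (!"sample_id" %in% names(t)) {
      errors <- c(errors, sprintf("%s: missing sample_id column", nm))
      next
    }
    dup <- unique(t$sample_id[duplicated(t$sample_id)])
    if (length(dup))
      errors <- c(errors, sprintf("%s: duplicated sample id(s): %s", nm,
                                  paste(dup, collapse = ", ")))
    for (cl in setdiff(names(t), "sample_id")) {
      nmiss <- sum(is.na(t[[cl]]))
      if (nmiss > 0)
        warnings <- c(warnings, sprintf("%s: column %s has %d missing cell(s)",
                                        nm, cl, nmiss))
      v <- t[[cl]][!is.na(t[[cl]])]
      if (is.numeric(v) && length(v) > 1 && length(unique(v)) == 1)
        warnings <- c(warnings, sprintf("%s: column %s is constant", nm, cl))
    }
  }
  if (length(tabs) > 1 && "sample_id" %in% names(tabs[[1]])) {
    ids <- tabs[[1]]$sample_id
    for (nm in names(tabs)[-1]) {
      if (!"sample_id" %in% names(tabs[[nm]])) next
      if (!setequal(ids, tabs[[nm]]$sample_id))
        errors <- c(errors, sprintf("sample ids of %s do not match functions",
                                    nm))
    }
  }
  if (!is.null(service_map)) {
    fn <- setdiff(names(functions), "sample_id")
    mapped <- unlist(service_map, use.names = FALSE)
    absent <- setdiff(mapped, fn)
    if (length(absent))
      errors <- c(errors, sprintf("service map names absent function(s): %s",
                                  paste(absent, collapse = ", ")))
    if (anyDuplicated(mapped))
      errors <- c(errors, "service map assigns a function to several services")
  }
  list(errors = errors, warnings = warnings, ok = length(errors) == 0)
}

#' Run the full analysis pipeline on synthetic or user data
#'
#' Orchestrates an end-to-end run: generate (or accept) the data tables,
#' compute multifunctionality indices and composite richness, derive
#' covariate axes, and run the enabled analyses (multi-threshold curves,
#' variation partitioning, AICc model averaging, piecewise SEM). All
#' randomness flows from the single seed through named stage streams.
#' Per-stage CSV/JSON outputs plus a manifest (config hash, seed, counts)
#' are written when \code{out_dir} is given.
#'
#' @param mode \code{"microcosm"}, \code{"survey"} or \code{"user"}.
#' @param config generator configuration ([microcosm_config()] or
#'   [survey_config()]); built from \code{seed} with defaults when NULL.
#' @param data for \code{mode = "user"}: list with \code{functions},
#'   \code{diversity}, \code{design}, \code{service_map}.
#' @param analyses character subset of
#'   \code{c("emf", "thresholds", "varpart", "modelavg", "sem")}.
#' @param seed integer master seed.
#' @param out_dir optional output directory.
#' @param nperm permutations for varpart tests.
#' @return list of class \code{"befmf_run"} with the data tables and one
#'   element per executed analysis, plus \code{manifest}.
#' @export
run_pipeline <- function(mode = c("microcosm", "survey", "user"),
                         config = NULL, data = NULL,
                         analyses = c("emf", "thresholds", "varpart",
                                      "modelavg", "sem"),
                         seed = 1L, out_dir = NULL, nperm = 199) {
  mode <- match.arg(mode)
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (mode == "microcosm") {
    config <- config %||% microcosm_config(seed = seed)
    dat <- generate_microcosm(config)
    functions <- dat$functions
    diversity <- dat$diversity
    design <- dat$design
    service_map <- dat$service_map
  } else if (mode == "survey") {
    config <- config %||% survey_config(seed = seed)
    dat <- generate_survey(config)
    functions <- dat$functions
    diversity <- dat$diversity
    design <- dat$sites
    service_map <- dat$service_map
  } else {
    if (is.null(data)) stop("mode 'user' requires a data list")
    functions <- data$functions
    diversity <- data$diversity
    design <- data$design
    service_map <- data$service_map
  }
  val <- validate_inputs(functions, diversity, design, service_map)
  if (!val$ok)
    stop("input validation failed: ", paste(val$errors, collapse = "; "))

  out <- list(mode = mode, functions = functions, diversity = diversity,
              design = design, service_map = service_map, validation = val)

  mf <- NULL
  if (any(c("emf", "thresholds", "varpart", "modelavg", "sem") %in% analyses)) {
    mf <- multifunctionality(functions, service_map)
    out$emf <- mf
  }
  rich_cols <- intersect(c("plant", "plant_richness", "bacteria", "fungi"),
                         names(diversity))
  micro_cols <- intersect(c("bacteria", "fungi"), names(diversity))
  comp_microbial <- if (length(micro_cols) >= 1)
    composite_richness(diversity[, micro_cols, drop = FALSE]) else NULL
  plant_col <- intersect(c("plant_richness", "plant"), names(diversity))[1]

  if ("thresholds" %in% analyses) {
    counts <- multithreshold_counts(functions)
    out$threshold_counts <- counts
    if (!is.null(comp_microbial))
      out$threshold_slopes <- threshold_slope_curve(comp_microbial, counts)
  }

  if ("varpart" %in% analyses && !is.na(plant_col) && !is.null(comp_microbial)) {
    groups <- list(plant = diversity[[plant_col]], microbial = comp_microbial)
    if (mode == "survey") {
      env <- pca_first_axis(design[, c("pH", "MAT", "clay_pct", "soil_C")])
      groups$environment <- env$scores
      groups$aridity <- design$aridity_index
    } else if ("drought" %in% names(design)) {
      groups$drought <- design$drought
    }
    out$varpart <- varpart(mf$emf_weighted, groups, nperm = nperm,
                           seed = stream_seed(seed, "varpart"))
  }

  if ("modelavg" %in% analyses && !is.na(plant_col) && !is.null(comp_microbial)) {
    X <- data.frame(plant = diversity[[plant_col]], microbial = comp_microbial)
    if ("drought" %in% names(design)) X$drought <- design$drought
    if ("aridity_index" %in% names(design)) X$aridity <- design$aridity_index
    out$modelavg <- model_average(mf$emf_weighted, X)
  }

  if ("sem" %in% analyses && !is.na(plant_col) && !is.null(comp_microbial)) {
    semdat <- data.frame(plant_richness = diversity[[plant_col]],
                         microbial_richness = comp_microbial,
                         EMF = mf$emf_weighted)
    edges <- list(microbial_richness ~ plant_richness,
                  EMF ~ plant_richness + microbial_richness)
    if ("drought" %in% names(design)) {
      semdat$drought <- design$drought
      edges <- list(microbial_richness ~ plant_richness + drought,
                    EMF ~ plant_richness + microbial_richness + drought)
    }
    out$sem <- fit_sem(sem_spec(edges), semdat)
  }

  out$manifest <- list(
    mode = mode, seed = seed,
    n_samples = nrow(functions),
    n_functions = ncol(functions) - 1L,
    n_services = length(service_map),
    services = names(service_map),
    analyses = analyses,
    config_hash = fnv1a(paste(deparse(config %||% data), collapse = "")),
    package_version = as.character(utils::packageVersion("befmf")))

  if (!is.null(out_dir)) write_run(out, out_dir)
  class(out) <- "befmf_run"
  out
}

write_run <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                          row.names = FALSE)
  wcsv(out$functions, "functions.csv")
  wcsv(out$diversity, "diversity.csv")
  wcsv(out$design, "design.csv")
  if (!is.null(out$emf))
    wcsv(data.frame(sample_id = out$functions$sample_id,
                    emf_weighted = out$emf$emf_weighted,
                    emf_averaged = out$emf$emf_averaged,
                    complete = out$emf$complete), "emf.csv")
  if (!is.null(out$threshold_slopes)) wcsv(out$threshold_slopes, "threshold_slopes.csv")
  if (!is.null(out$varpart)) {
    vp <- out$varpart$fractions
    if (!is.null(out$varpart$p_unique)) {
      vp$p <- NA_real_
      vp$p[match(names(out$varpart$p_unique), vp$fraction)] <- out$varpart$p_unique
    }
    wcsv(vp, "varpart.csv")
  }
  if (!is.null(out$modelavg))
    wcsv(data.frame(predictor = names(out$modelavg$coefficients),
                    beta_avg = out$modelavg$coefficients,
                    se = out$modelavg$se,
                    importance_pct = out$modelavg$importance_pct),
         "modelavg.csv")
  if (!is.null(out$sem)) {
    wcsv(out$sem$paths, "sem_paths.csv")
    jsonlite::write_json(list(C = out$sem$C, df = out$sem$df, p = out$sem$p_C,
                              AIC = out$sem$AIC, K = out$sem$K,
                              saturated = out$sem$saturated,
                              r2 = as.list(out$sem$r2)),
                         file.path(out_dir, "sem_fit.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @method print befmf_run
#' @export
print.befmf_run <- function(x, ...) {
  cat(sprintf("befmf pipeline run (%s mode): %d samples, %d functions in %d services\n",
              x$mode, x$manifest$n_samples, x$manifest$n_functions,
              x$manifest$n_services))
  cat("stages:", paste(x$manifest$analyses, collapse = ", "), "\n")
  invisible(x)
}
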