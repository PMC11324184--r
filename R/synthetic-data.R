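#' Microcosm generator configuration
#'
#' Builds and validates the configuration of the synthetic full-factorial
#' microcosm experiment: plant richness gradients (1-4 species drawn from a
#' small pool), a dilution-to-extinction soil microbial diversity gradient
#' (HD/MD/LD inocula with calibrated per-kingdom richness retention), and a
#' binary drought treatment. Sixteen ecosystem functions grouped into six
#' services are generated from a linear ground-truth model with a random
#' plant-combination intercept.
#'
#' Dilution is modelled as independent Bernoulli survival of each zOTU, so
#' realized richness per kingdom is Binomial(pool size, retention fraction).
#' The default retention fractions reproduce the calibrated reductions of the
#' dilution-to-extinction approach: at MD, bacteria keep 91% and fungi 86% of
#' their undiluted richness; at LD, 48% and 27% respectively. Guild-level
#' retention (mycorrhizal, saprotrophic, plant-pathogenic fungi) defaults to
#' the fungal kingdom calibration.
#'
#' @param n_species_pool size of the plant species pool.
#' @param richness_levels plant richness levels of the factorial design.
#' @param retention named list with elements \code{bacteria} and \code{fungi},
#'   each a named vector of retention fractions for levels HD, MD, LD.
#'   Fractions must be in (0, 1], equal 1 at HD, and be non-increasing
#'   HD -> MD -> LD.
#' @param guild_retention named list of retention vectors for the fungal
#'   guilds \code{mycorrhizal}, \code{saprotroph}, \code{pathogen}.
#' @param drought_levels treatment codes; 0 = drought, 1 = well-watered.
#' @param n_replicates replicate pots per factorial cell.
#' @param pool_richness named vector of baseline zOTU counts per kingdom.
#' @param guild_pool named vector of baseline zOTU counts per fungal guild.
#' @param beta 16 x 3 matrix of true standardized effects (columns
#'   \code{plant_richness}, \code{microbial_richness}, \code{drought}) per
#'   function; \code{NULL} for the packaged defaults (+0.3, +0.3, -0.3, with
#'   drought increasing total soil P).
#' @param sigma_combination SD of the random plant-combination intercept.
#' @param sigma_resid residual SD of each function.
#' @param resid_cor exchangeable residual correlation among the 16 functions
#'   within a pot (default 0, i.e. independent residuals).
#' @param dropout probability that a pot is lost before harvest (default 0).
#' @param seed integer seed; all randomness in [generate_microcosm()] flows
#'   from it through named sub-streams.
#' @return a validated list of class \code{"microcosm_config"}.
#' @seealso [generate_microcosm()]
#' @export
microcosm_config <- function(n_species_pool = 5L,
                             richness_levels = 1:4,
                             retention = list(
                               bacteria = c(HD = 1, MD = 0.91, LD = 0.48),
                               fungi    = c(HD = 1, MD = 0.86, LD = 0.27)
                             ),
                             guild_retention = NULL,
                             drought_levels = c(0L, 1L),
                             n_replicates = 8L,
                             pool_richness = c(bacteria = 2000L, fungi = 400L),
                             guild_pool = c(mycorrhizal = 60L, saprotroph = 200L,
                                            pathogen = 80L),
                             beta = NULL,
                             sigma_combination = 0.3,
                             sigma_resid = 1,
                             resid_cor = 0,
                             dropout = 0,
                             seed = 1L) {
  fn <- microcosm_function_names()
  if (is.null(guild_retention)) {
    guild_retention <- list(mycorrhizal = retention$fungi,
                            saprotroph  = retention$fungi,
                            pathogen    = retention$fungi)
  }
  if (is.null(beta)) {
    beta <- matrix(rep(c(0.3, 0.3, -0.3), each = 16L), nrow = 16L,
                   dimnames = list(fn, c("plant_richness", "microbial_richness",
                                         "drought")))
    beta["soil_P", "drought"] <- 0.3
  }
  cfg <- list(n_species_pool = as.integer(n_species_pool),
              richness_levels = as.integer(richness_levels),
              dilution_levels = c("HD", "MD", "LD"),
              retention = retention, guild_retention = guild_retention,
              drought_levels = as.integer(drought_levels),
              n_replicates = as.integer(n_replicates),
              pool_richness = pool_richness, guild_pool = guild_pool,
              beta = beta, sigma_combination = sigma_combination,
              sigma_resid = sigma_resid, resid_cor = resid_cor,
              dropout = dropout, n_functions = 16L,
              service_map = microcosm_service_map(), seed = as.integer(seed))
  validate_microcosm_config(cfg)
  class(cfg) <- "microcosm_config"
  cfg
}

microcosm_function_names <- function() {
  c("soil_C", "soil_N", "soil_P",
    "inorganic_N", "phosphate",
    "basal_respiration", "glucose_mineralization", "lignin_degradation",
    "DOC", "TDN",
    "plant_biomass", "plant_height", "canopy_cover",
    "leaf_C", "leaf_N", "leaf_P")
}

#' Service grouping of the 16 microcosm ecosystem functions
#'
#' Six named ecosystem services partitioning the 16 functions: soil nutrient
#' storage (total C, N, P), soil inorganic pools (inorganic N, phosphate),
#' organic-matter decomposition (basal respiration, glucose mineralization,
#' lignin degradation), soil dissolved pools (DOC, TDN), plant production
#' (biomass, height, canopy cover) and leaf nutrient uptake (leaf C, N, P).
#'
#' @return named list mapping service name to function names.
#' @export
microcosm_service_map <- function() {
  list(soil_nutrient_storage = c("soil_C", "soil_N", "soil_P"),
       soil_inorganic_pools  = c("inorganic_N", "phosphate"),
       om_decomposition      = c("basal_respiration", "glucose_mineralization",
                                 "lignin_degradation"),
       soil_dissolved_pools  = c("DOC", "TDN"),
       plant_production      = c("plant_biomass", "plant_height", "canopy_cover"),
       leaf_uptake           = c("leaf_C", "leaf_N", "leaf_P"))
}

validate_retention <- function(r, what) {
  if (is.null(names(r)) || !identical(names(r), c("HD", "MD", "LD")))
    stop(what, " retention must be a named vector over HD, MD, LD")
  if (any(r <= 0) || any(r > 1)) stop(what, " retention fractions must lie in (0, 1]")
  if (r[["HD"]] != 1) stop(what, " retention at HD must be 1")
  if (is.unsorted(rev(r))) stop(what, " retention must be non-increasing HD -> MD -> LD")
  invisible(r)
}

validate_microcosm_config <- function(cfg) {
  if (any(cfg$richness_levels > cfg$n_species_pool))
    stop("richness level exceeds the plant species pool size")
  if (any(cfg$richness_levels < 0)) stop("richness levels must be >= 0")
  for (k in names(cfg$retention)) validate_retention(cfg$retention[[k]], k)
  for (k in names(cfg$guild_retention)) validate_retention(cfg$guild_retention[[k]], k)
  if (cfg$sigma_combination < 0 || cfg$sigma_resid < 0) stop("SDs must be >= 0")
  if (cfg$resid_cor < 0 || cfg$resid_cor >= 1) stop("resid_cor must lie in [0, 1)")
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("dropout must lie in [0, 1)")
  if (length(cfg$service_map) == 0) stop("empty service map")
  mapped <- unlist(cfg$service_map, use.names = FALSE)
  fn <- rownames(cfg$beta)
  if (anyDuplicated(mapped) || !setequal(mapped, fn))
    stop("service_map must partition the function set")
  if (!identical(colnames(cfg$beta),
                 c("plant_richness", "microbial_richness", "drought")))
    stop("beta columns must be plant_richness, microbial_richness, drought")
  invisible(cfg)
}

#' Generate a synthetic microcosm dataset
#'
#' Draws one full-factorial realization of the microcosm design described by
#' a [microcosm_config()]: one row per pot, a plant composition drawn as
#' presence/absence from the species pool at the pot's richness level,
#' per-kingdom and per-guild microbial richness drawn as Binomial(pool,
#' retention) under the pot's dilution level, and 16 ecosystem functions
#' generated as
#' \deqn{y = \beta_1 z(\mathrm{plant}) + \beta_2 z(\mathrm{microbial}) +
#'       \beta_3 \mathrm{drought} + b_{\mathrm{combination}} + \varepsilon}
#' with Gaussian random combination intercepts and residuals. The microbial
#' predictor is the composite microbial richness (mean of min-max
#' standardized bacterial and fungal richness), z-scored, so the betas are
#' standardized effects.
#'
#' Randomness flows from \code{config$seed} through named per-table streams
#' (design, microbes, random effects, residuals, dropout), so adding outputs
#' never perturbs earlier draws and identical configs give byte-identical
#' tables.
#'
#' @param config a [microcosm_config()].
#' @return list of class \code{"microcosm_data"} with elements
#'   \code{design} (pot, treatments, plant combination), \code{diversity}
#'   (plant and microbial richness per pot), \code{functions} (pot x 16
#'   function matrix as a data frame), \code{service_map}, and
#'   \code{ground_truth} (true betas, realized combination intercepts,
#'   realized retention fractions, and the design matrix used).
#' @export
generate_microcosm <- function(config) {
  stopifnot(inherits(config, "microcosm_config"))
  cfg <- config
  cells <- expand.grid(replicate = seq_len(cfg$n_replicates),
                       drought = cfg$drought_levels,
                       dilution = cfg$dilution_levels,
                       plant_richness = cfg$richness_levels,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- cells[, c("plant_richness", "dilution", "drought", "replicate")]
  n <- nrow(cells)
  pool <- LETTERS[seq_len(cfg$n_species_pool)]

  combos <- with_stream(cfg$seed, "design", {
    vapply(cells$plant_richness, function(k) {
      if (k == 0) "none" else paste(sort(sample(pool, k)), collapse = "")
    }, character(1))
  })
  design <- data.frame(sample_id = sprintf("pot%03d", seq_len(n)),
                       plant_richness = cells$plant_richness,
                       combination = combos,
                       dilution = cells$dilution,
                       drought = cells$drought,
                       replicate = cells$replicate,
                       stringsAsFactors = FALSE)

  draw_rich <- function(pools, retention_list) {
    out <- list()
    for (g in names(pools)) {
      ret <- retention_list[[g]][design$dilution]
      out[[g]] <- stats::rbinom(n, pools[[g]], ret)
    }
    out
  }
  micro <- with_stream(cfg$seed, "microbes", {
    c(draw_rich(as.list(cfg$pool_richness), cfg$retention),
      draw_rich(as.list(cfg$guild_pool), cfg$guild_retention))
  })
  diversity <- data.frame(sample_id = design$sample_id,
                          plant_richness = design$plant_richness,
                          bacteria = micro$bacteria, fungi = micro$fungi,
                          mycorrhizal = micro$mycorrhizal,
                          saprotroph = micro$saprotroph,
                          pathogen = micro$pathogen,
                          stringsAsFactors = FALSE)

  ucomb <- sort(unique(design$combination))
  b_comb <- with_stream(cfg$seed, "random_effects",
                        stats::setNames(stats::rnorm(length(ucomb), 0,
                                                     cfg$sigma_combination), ucomb))

  z_plant <- zscore_safe(design$plant_richness)
  rng_b <- range(diversity$bacteria)
  rng_f <- range(diversity$fungi)
  comp_microbial <- ((diversity$bacteria - rng_b[1]) / max(diff(rng_b), 1) +
                     (diversity$fungi - rng_f[1]) / max(diff(rng_f), 1)) / 2
  z_microbial <- zscore_safe(comp_microbial)
  X <- cbind(plant_richness = z_plant, microbial_richness = z_microbial,
             drought = design$drought)

  eps <- with_stream(cfg$seed, "residuals", {
    ind <- matrix(stats::rnorm(n * cfg$n_functions), n, cfg$n_functions)
    if (cfg$resid_cor > 0) {
      shared <- stats::rnorm(n)
      ind <- sqrt(cfg$resid_cor) * shared + sqrt(1 - cfg$resid_cor) * ind
    }
    cfg$sigma_resid * ind
  })
  Y <- X %*% t(cfg$beta) + b_comb[design$combination] + eps
  colnames(Y) <- rownames(cfg$beta)
  functions <- data.frame(sample_id = design$sample_id, Y,
                          stringsAsFactors = FALSE, check.names = FALSE)

  keep <- rep(TRUE, n)
  if (cfg$dropout > 0)
    keep <- with_stream(cfg$seed, "dropout",
                        stats::runif(n) >= cfg$dropout)

  retention_realized <- data.frame(
    sample_id = design$sample_id, dilution = design$dilution,
    bacteria = micro$bacteria / cfg$pool_richness[["bacteria"]],
    fungi = micro$fungi / cfg$pool_richness[["fungi"]],
    stringsAsFactors = FALSE)

  out <- list(design = design[keep, , drop = FALSE],
              diversity = diversity[keep, , drop = FALSE],
              functions = functions[keep, , drop = FALSE],
              service_map = cfg$service_map,
              ground_truth = list(beta_true = cfg$beta,
                                  random_effects = b_comb,
                                  retention_realized = retention_realized[keep, , drop = FALSE],
                                  design_matrix = X[keep, , drop = FALSE],
                                  config = cfg))
  class(out) <- "microcosm_data"
  out
}

#' Survey generator configuration
#'
#' Configuration of the synthetic global grassland survey: about a hundred
#' sites spanning environmental gradients (soil pH 4.3-8.6, mean annual
#' precipitation 26-1471 mm, mean annual temperature -2.7 to 27.2 degrees C)
#' and an aridity gradient from humid to hyperarid, with plant, bacterial and
#' fungal richness correlated with the environment and five ecosystem
#' functions in three services generated from a linear ground-truth model.
#'
#' @param n_sites number of sites (>= 10).
#' @param env_ranges named list of c(min, max) ranges per covariate.
#' @param aridity_mixture named shares of sites per UNEP aridity category
#'   (humid, dry subhumid, semiarid, arid, hyperarid); must sum to 1.
#' @param richness_base,richness_ai_slope,richness_sd named vectors (plant,
#'   bacteria, fungi) giving mean richness, its slope on z-scored aridity
#'   index (wetter sites richer), and residual SD.
#' @param beta 5 x 5 matrix of true effects of z-scored plant, bacterial and
#'   fungal richness, aridity index and soil pH on each function; \code{NULL}
#'   for defaults.
#' @param sigma_resid residual SD of each function.
#' @param seed integer seed.
#' @return a validated list of class \code{"survey_config"}.
#' @export
survey_config <- function(n_sites = 101L,
                          env_ranges = list(pH = c(4.3, 8.6),
                                            MAP = c(26, 1471),
                                            MAT = c(-2.7, 27.2),
                                            clay_pct = c(5, 60),
                                            soil_C = c(0.2, 10),
                                            plant_cover_pct = c(10, 100),
                                            distance_equator = c(0, 60)),
                          aridity_mixture = c(humid = 0.25, `dry subhumid` = 0.15,
                                              semiarid = 0.30, arid = 0.20,
                                              hyperarid = 0.10),
                          richness_base = c(plant = 25, bacteria = 1800, fungi = 350),
                          richness_ai_slope = c(plant = 8, bacteria = 300, fungi = 80),
                          richness_sd = c(plant = 5, bacteria = 200, fungi = 50),
                          beta = NULL,
                          sigma_resid = 1,
                          seed = 1L) {
  fn <- survey_function_names()
  if (is.null(beta)) {
    beta <- matrix(rep(c(0.3, 0.2, 0.2, 0.3, -0.1), each = 5L), nrow = 5L,
                   dimnames = list(fn, c("plant", "bacteria", "fungi",
                                         "aridity_index", "pH")))
  }
  cfg <- list(n_sites = as.integer(n_sites), env_ranges = env_ranges,
              aridity_mixture = aridity_mixture,
              richness_base = richness_base,
              richness_ai_slope = richness_ai_slope,
              richness_sd = richness_sd, beta = beta,
              sigma_resid = sigma_resid,
              service_map = survey_service_map(), seed = as.integer(seed))
  validate_survey_config(cfg)
  class(cfg) <- "survey_config"
  cfg
}

survey_function_names <- function() {
  c("glucose_mineralization", "nitrate", "ammonium", "phosphate", "NPP")
}

#' Service grouping of the 5 survey ecosystem functions
#'
#' Organic-matter decomposition (glucose-induced respiration), soil inorganic
#' pools (nitrate, ammonium, phosphate availability) and plant production
#' (net primary productivity).
#'
#' @return named list mapping service name to function names.
#' @export
survey_service_map <- function() {
  list(om_decomposition     = "glucose_mineralization",
       soil_inorganic_pools = c("nitrate", "ammonium", "phosphate"),
       plant_production     = "NPP")
}

validate_survey_config <- function(cfg) {
  if (cfg$n_sites < 10) stop("n_sites must be >= 10")
  for (nm in names(cfg$env_ranges)) {
    r <- cfg$env_ranges[[nm]]
    if (length(r) != 2 || !all(is.finite(r)) || r[1] >= r[2])
      stop("env range for ", nm, " must be finite with min < max")
  }
  mix <- cfg$aridity_mixture
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
    stop("infeasible aridity category mixture: shares must be >= 0 and sum to 1")
  if (!all(names(mix) %in% c("humid", "dry subhumid", "semiarid", "arid", "hyperarid")))
    stop("unknown aridity category in mixture")
  invisible(cfg)
}

# AI ranges used to sample within each UNEP category.
aridity_category_ranges <- function() {
  list(hyperarid = c(0.005, 0.05), arid = c(0.05, 0.2),
       semiarid = c(0.2, 0.5), `dry subhumid` = c(0.5, 0.65),
       humid = c(0.65, 1.4))
}

#' Generate a synthetic grassland survey dataset
#'
#' Draws site covariates uniformly within the configured ranges, an aridity
#' index matching the configured category mixture (sites apportioned by
#' largest remainder, AI uniform within each category's range, potential
#' evapotranspiration derived as MAP / AI), richness correlated with the
#' aridity gradient, and five ecosystem functions from the linear
#' ground-truth model with z-scored predictors.
#'
#' @param config a [survey_config()].
#' @return list of class \code{"survey_data"} with elements \code{sites},
#'   \code{diversity}, \code{functions}, \code{service_map},
#'   \code{ground_truth}.
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "survey_config"))
  cfg <- config
  n <- cfg$n_sites
  mix <- cfg$aridity_mixture[cfg$aridity_mixture > 0]
  counts <- floor(mix * n)
  rem <- mix * n - counts
  short <- n - sum(counts)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[add] <- counts[add] + 1
  }
  cats <- rep(names(counts), counts)

  rng <- aridity_category_ranges()
  sites <- with_stream(cfg$seed, "sites", {
    ai <- vapply(cats, function(cl) stats::runif(1, rng[[cl]][1], rng[[cl]][2]),
                 numeric(1))
    env <- lapply(cfg$env_ranges, function(r) stats::runif(n, r[1], r[2]))
    data.frame(sample_id = sprintf("site%03d", seq_len(n)),
               MAP = env$MAP, PET = env$MAP / ai, MAT = env$MAT,
               pH = env$pH, clay_pct = env$clay_pct, soil_C = env$soil_C,
               plant_cover_pct = env$plant_cover_pct,
               distance_equator = env$distance_equator,
               aridity_index = ai,
               aridity_class = classify_aridity(ai),
               stringsAsFactors = FALSE)
  })

  z_ai <- zscore(sites$aridity_index)
  diversity <- with_stream(cfg$seed, "richness", {
    draw <- function(g) {
      pmax(1L, as.integer(round(cfg$richness_base[[g]] +
        cfg$richness_ai_slope[[g]] * z_ai +
        stats::rnorm(n, 0, cfg$richness_sd[[g]]))))
    }
    data.frame(sample_id = sites$sample_id, plant = draw("plant"),
               bacteria = draw("bacteria"), fungi = draw("fungi"),
               stringsAsFactors = FALSE)
  })

  X <- cbind(plant = zscore(diversity$plant),
             bacteria = zscore(diversity$bacteria),
             fungi = zscore(diversity$fungi),
             aridity_index = z_ai, pH = zscore(sites$pH))
  eps <- with_stream(cfg$seed, "residuals",
                     matrix(stats::rnorm(n * nrow(cfg$beta), 0, cfg$sigma_resid),
                            n, nrow(cfg$beta)))
  Y <- X %*% t(cfg$beta) + eps
  colnames(Y) <- rownames(cfg$beta)
  functions <- data.frame(sample_id = sites$sample_id, Y,
                          stringsAsFactors = FALSE, check.names = FALSE)

  out <- list(sites = sites, diversity = diversity, functions = functions,
              service_map = cfg$service_map,
              ground_truth = list(beta_true = cfg$beta, design_matrix = X,
                                  config = cfg))
  class(out) <- "survey_data"
  out
}
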