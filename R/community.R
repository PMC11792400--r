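#' Default uptake-flux ladder
#'
#' The 14 per-source uptake flux thresholds (mmol per gram dry weight per
#' hour) at which community simulations are run, from near-starvation
#' (0.01) to the unrestricted default (1000).
#'
#' @return Strictly increasing numeric vector.
#' @export
flux_ladder <- function() {
  c(0.01, 0.05, 0.1, 0.5, 1, 3, 5, 8, 10, 50, 100, 200, 500, 1000)
}

#' Cross-feeding configuration
#'
#' @param beta Scaling coefficient of the pooled-secretion carbon cap
#'   (the cap states that `beta` times the pooled secreted carbon flux
#'   may not exceed the community's realized carbon uptake times its
#'   growth-weighted secretion efficiency). Default 1.
#' @param secretion_floor Minimum flux (mmol/gDW/h) below which pooled
#'   secretions are discarded (default 0.01).
#' @param scaling How pooled secretions are reduced to satisfy the cap;
#'   only proportional scaling is defined.
#' @return Object of class `crossfeed_config`.
#' @export
crossfeed_config <- function(beta = 1, secretion_floor = 0.01,
                             scaling = "proportional") {
  if (beta <= 0) stop("beta must be > 0", call. = FALSE)
  scaling <- match.arg(scaling, "proportional")
  structure(list(beta = beta, secretion_floor = secretion_floor,
                 scaling = scaling), class = "crossfeed_config")
}

#' Simulate every model individually at one flux level
#'
#' Runs one FBA per model with every allowed carbon source capped at
#' `flux_level`, and extracts from the deterministic (minimum-total-flux)
#' flux vector: the growth rate, the number of absorbed carbon sources
#' `N_i` (uptake flux above the noise floor), the secreted carbon
#' metabolite set `M_i` (excluding CO2, at or above the secretion
#' floor), and the carbon secretion efficiency `CSE_i`.
#'
#' @param models List of `metabolic_model` objects.
#' @param medium Base `fba_medium` of allowed carbon sources.
#' @param flux_level Per-source uptake cap for this simulation.
#' @param eps Noise floor for counting absorbed sources.
#' @param secretion_floor Minimum secretion flux for membership in `M_i`.
#' @return Data frame (`model_id`, `growth_rate`, `n_absorbed`, `cse`)
#'   with per-model uptake and secretion flux vectors attached as
#'   attributes `uptakes` and `secretions` (named lists), and the carbon
#'   atom map as attribute `carbon`.
#' @export
simulate_individuals <- function(models, medium, flux_level,
                                 eps = 1e-6, secretion_floor = 0.01) {
  stopifnot(length(models) > 0)
  med <- apply_uptake_limit(medium, flux_level)
  uptakes <- list()
  secretions <- list()
  carbon <- numeric(0)
  rows <- lapply(models, function(m) {
    sol <- solve_fba(m, med)
    catoms <- stats::setNames(m$mets$carbon_atoms, m$mets$id)
    carbon <<- c(carbon, catoms[setdiff(names(catoms), names(carbon))])
    up <- sol$uptake_fluxes[sol$uptake_fluxes > eps]
    sec <- sol$secretion_fluxes
    sec <- sec[names(sec) != "co2" & sec >= secretion_floor]
    uptakes[[m$model_id]] <<- up
    secretions[[m$model_id]] <<- sec
    data.frame(
      model_id = m$model_id, growth_rate = sol$growth_rate,
      n_absorbed = length(up),
      cse = cse(sol$uptake_fluxes, sol$secretion_fluxes, catoms),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "uptakes") <- uptakes
  attr(out, "secretions") <- secretions
  attr(out, "carbon") <- carbon
  attr(out, "flux_level") <- flux_level
  out
}

#' Carbon secretion efficiency of one model
#'
#' Carbon-atom-weighted ratio of secreted to absorbed flux:
#' `sum_m(secretion_m * C_m) / sum_n(uptake_n * C_n)`, with CO2 excluded
#' from the numerator (respiratory loss is not a reusable secretion).
#' Undefined (`NA`) when nothing is absorbed.
#'
#' @param individual_uptakes Named vector of uptake flux magnitudes by
#'   metabolite.
#' @param individual_secretions Named vector of secretion fluxes by
#'   metabolite.
#' @param carbon_counts Named vector of carbon atoms per metabolite.
#' @param co2_id Metabolite id excluded from the numerator.
#' @return Secretion efficiency in `[0, 1]`, or `NA` if nothing is
#'   absorbed.
#' @export
cse <- function(individual_uptakes, individual_secretions, carbon_counts,
                co2_id = "co2") {
  denom <- sum(individual_uptakes * carbon_counts[names(individual_uptakes)])
  if (!length(individual_uptakes) || denom <= 0) return(NA_real_)
  sec <- individual_secretions[names(individual_secretions) != co2_id]
  num <- if (length(sec)) sum(sec * carbon_counts[names(sec)]) else 0
  num / denom
}

#' Community metrics at one flux level
#'
#' Aggregates individual results into the community statistics: the
#' average number of absorbed carbon sources (ANAC, mean of `N_i`), the
#' number of distinct secreted carbon types (CST, cardinality of the
#' union of the `M_i`), the community carbon secretion efficiency (CCSE,
#' growth-rate-weighted mean of the defined `CSE_i`; defined as 0 when
#' all growth rates are 0), the mean growth rate, and the adjusted
#' Fisher-Pearson sample skewness of the growth rates.
#'
#' @param individuals Result of [simulate_individuals()].
#' @param flux_level Flux level label (defaults to the attribute carried
#'   by `individuals`).
#' @return One-row data frame (`flux_level`, `anac`, `cst`, `ccse`,
#'   `mean_growth`, `skewness`).
#' @export
community_metrics <- function(individuals,
                              flux_level = attr(individuals, "flux_level")) {
  stopifnot(nrow(individuals) >= 1)
  secretions <- attr(individuals, "secretions")
  cst <- length(unique(unlist(lapply(secretions, names))))
  g <- individuals$growth_rate
  cse_i <- individuals$cse
  ok <- !is.na(cse_i) & g > 0
  ccse <- if (any(ok)) sum(g[ok] * cse_i[ok]) / sum(g[ok]) else 0
  skew <- if (length(g) >= 3 && stats::sd(g) > 0) {
    e1071::skewness(g, type = 2)
  } else NA_real_
  data.frame(
    flux_level = flux_level %||% NA_real_, anac = mean(individuals$n_absorbed),
    cst = cst, ccse = ccse, mean_growth = mean(g), skewness = skew
  )
}

#' Community growth-rate variability across the flux ladder
#'
#' Finite-difference slope of the community mean growth rate between
#' adjacent ladder levels: `(mean growth at a - mean growth at b) /
#' (a - b)` for each adjacent pair `a > b`.
#'
#' @param metrics_by_level Data frame of per-level community metrics
#'   (rows from [community_metrics()]), any order, no duplicate levels.
#' @return Data frame (`flux_a`, `flux_b`, `cgrv`).
#' @export
cgrv_profile <- function(metrics_by_level) {
  if (nrow(metrics_by_level) < 2) stop("need at least two flux levels",
                                       call. = FALSE)
  if (anyDuplicated(metrics_by_level$flux_level)) {
    stop("duplicate flux levels", call. = FALSE)
  }
  m <- metrics_by_level[order(metrics_by_level$flux_level), ]
  i <- seq_len(nrow(m) - 1)
  data.frame(
    flux_a = m$flux_level[i + 1], flux_b = m$flux_level[i],
    cgrv = (m$mean_growth[i + 1] - m$mean_growth[i]) /
      (m$flux_level[i + 1] - m$flux_level[i])
  )
}

#' Build the cross-feeding medium from a first-pass simulation
#'
#' Pools per-metabolite secretion fluxes across all models, discards
#' pooled entries below the secretion floor, and enforces the
#' carbon-conservation cap: `beta` times the pooled secreted carbon flux
#' may not exceed `CCSE x sum_t(uptake_t * C_t)`, the community's
#' realized carbon uptake weighted by its secretion efficiency. If the
#' pool exceeds the cap, all pooled fluxes are scaled down
#' proportionally to meet it with equality. The returned medium allows
#' the base carbon sources (capped at the flux level) plus each pooled
#' secretion, whose uptake is limited by the smaller of its pooled flux
#' and the flux level.
#'
#' @param individuals First-pass result of [simulate_individuals()] at
#'   the same flux level.
#' @param base_medium The base carbon-source medium.
#' @param flux_level Per-source uptake cap.
#' @param cfg A [crossfeed_config()].
#' @return List with `medium`, `pooled` (named secretion fluxes after
#'   floor and scaling), `cap`, `scale` (applied factor), and `ccse`.
#' @export
build_crossfeed_medium <- function(individuals, base_medium, flux_level,
                                   cfg = crossfeed_config()) {
  carbon <- attr(individuals, "carbon")
  secretions <- attr(individuals, "secretions")
  uptakes <- attr(individuals, "uptakes")
  pooled_all <- unlist(lapply(secretions, identity))
  pooled <- if (length(pooled_all)) {
    v <- tapply(pooled_all, sub("^.*\\.", "", names(pooled_all)), sum)
    stats::setNames(as.numeric(v), names(v))
  } else numeric(0)
  pooled <- pooled[pooled >= cfg$secretion_floor]
  ccse_val <- community_metrics(individuals, flux_level)$ccse
  uptake_carbon <- sum(vapply(uptakes, function(u) {
    if (!length(u)) 0 else sum(u * carbon[names(u)])
  }, numeric(1)))
  cap <- ccse_val * uptake_carbon
  scale <- 1
  if (length(pooled)) {
    pooled_carbon <- sum(pooled * carbon[names(pooled)])
    if (cap <= 0) {
      pooled <- numeric(0)
    } else if (cfg$beta * pooled_carbon > cap) {
      scale <- cap / (cfg$beta * pooled_carbon)
      pooled <- pooled * scale
    }
  }
  med <- pmin(unclass(base_medium), flux_level)
  if (length(pooled)) {
    extra <- stats::setNames(pmin(pooled, flux_level),
                             paste0("EX_", names(pooled)))
    med <- c(med[setdiff(names(med), names(extra))], extra)
  }
  list(medium = make_medium(med), pooled = pooled, cap = cap,
       scale = scale, ccse = ccse_val)
}

#' Two-pass community simulation with cross-feeding
#'
#' Pass 1 simulates every model on the base carbon sources at the given
#' flux level; the secreted byproducts are pooled under the
#' carbon-conservation cap (see [build_crossfeed_medium()]); pass 2
#' re-runs every model on the enriched medium. Because pass 2 only adds
#' allowed uptakes, every model's growth can only increase.
#'
#' @param models List of `metabolic_model` objects.
#' @param base_medium Base carbon-source medium.
#' @param flux_level Per-source uptake cap.
#' @param cfg A [crossfeed_config()].
#' @return Object of class `crossfeed_result`: list with `flux_level`,
#'   `individuals` (pass 1), `individuals_crossfed` (pass 2), `pooled`,
#'   `cap`, `scale`, `growth_without`, `growth_with`, and `rd`.
#' @export
simulate_with_crossfeeding <- function(models, base_medium, flux_level,
                                       cfg = crossfeed_config()) {
  pass1 <- simulate_individuals(models, base_medium, flux_level,
                                secretion_floor = cfg$secretion_floor)
  cf <- build_crossfeed_medium(pass1, base_medium, flux_level, cfg)
  pass2 <- simulate_individuals(models, cf$medium, flux_level,
                                secretion_floor = cfg$secretion_floor)
  structure(
    list(flux_level = flux_level, individuals = pass1,
         individuals_crossfed = pass2, pooled = cf$pooled, cap = cf$cap,
         scale = cf$scale,
         growth_without = stats::setNames(pass1$growth_rate, pass1$model_id),
         growth_with = stats::setNames(pass2$growth_rate, pass2$model_id),
         rd = relative_divergence(pass2$growth_rate, pass1$growth_rate)),
    class = "crossfeed_result"
  )
}

#' @export
print.crossfeed_result <- function(x, ...) {
  cat("<crossfeed_result> flux", x$flux_level,
      " pooled secretions:", length(x$pooled),
      " RD:", format(x$rd, digits = 4), "\n")
  invisible(x)
}

#' Relative divergence of community growth with vs without cross-feeding
#'
#' Symmetric relative difference of the community average growth rates:
#' `(G_cross - G_non) / ((G_cross + G_non) / 2)`. Zero when both
#' averages are zero; bounded by 2 when growth exists only with
#' cross-feeding.
#'
#' @param growth_with,growth_without Equal-length vectors of per-model
#'   growth rates.
#' @return A single number in `[-2, 2]`.
#' @export
relative_divergence <- function(growth_with, growth_without) {
  stopifnot(length(growth_with) == length(growth_without),
            length(growth_with) > 0)
  gw <- mean(growth_with)
  gn <- mean(growth_without)
  if (gw == 0 && gn == 0) return(0)
  (gw - gn) / ((gw + gn) / 2)
}

#' Compare decomposer and exploiter model groups across flux levels
#'
#' Splits the models by trophic role and reports, per flux level, the
#' group mean growth rates and their decomposer/exploiter ratio
#' (ratio of group means) together with the group mean number of
#' absorbed sources; group mean carbon utilization breadth is computed
#' once (it does not depend on the flux level).
#'
#' @param models List of `metabolic_model` objects.
#' @param role_calls Data frame with columns `model_id` and `role`
#'   (containing at least one `"decomposer"` and one `"exploiter"`).
#' @param medium Base carbon-source medium.
#' @param flux_levels Vector of per-source uptake caps.
#' @param carbon_source_ids Sources for the CUB computation; by default
#'   the niche bookkeeping attached by [gen_toy_models()] is used
#'   instead of re-solving.
#' @return Data frame with one row per flux level: `flux_level`,
#'   `growth_decomposer`, `growth_exploiter`, `growth_ratio_de`,
#'   `n_absorbed_decomposer`, `n_absorbed_exploiter`, `cub_decomposer`,
#'   `cub_exploiter`.
#' @export
compare_trophic_groups <- function(models, role_calls, medium, flux_levels,
                                   carbon_source_ids = NULL) {
  ids <- vapply(models, function(m) m$model_id, character(1))
  dec <- ids[ids %in% role_calls$model_id[role_calls$role == "decomposer"]]
  exp_ <- ids[ids %in% role_calls$model_id[role_calls$role == "exploiter"]]
  if (!length(dec) || !length(exp_)) {
    stop("both trophic groups must be non-empty", call. = FALSE)
  }
  cub_of <- function(m) {
    if (is.null(carbon_source_ids)) length(attr(m, "niche"))
    else compute_cub(m, carbon_source_ids)
  }
  cub <- vapply(models, cub_of, numeric(1))
  names(cub) <- ids
  rows <- lapply(flux_levels, function(fl) {
    ind <- simulate_individuals(models, medium, fl)
    gd <- ind$growth_rate[ind$model_id %in% dec]
    ge <- ind$growth_rate[ind$model_id %in% exp_]
    data.frame(
      flux_level = fl,
      growth_decomposer = mean(gd), growth_exploiter = mean(ge),
      growth_ratio_de = if (mean(ge) > 0) mean(gd) / mean(ge) else NA_real_,
      n_absorbed_decomposer = mean(ind$n_absorbed[ind$model_id %in% dec]),
      n_absorbed_exploiter = mean(ind$n_absorbed[ind$model_id %in% exp_]),
      cub_decomposer = mean(cub[dec]), cub_exploiter = mean(cub[exp_])
    )
  })
  do.call(rbind, rows)
}
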