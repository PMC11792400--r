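#' Flux balance analysis
#'
#' Maximizes the biomass reaction flux subject to the steady-state
#' constraint `S v = 0` and the flux bounds, with the medium's uptake
#' limits applied to the exchange reactions (uptake limit L sets the
#' exchange lower bound to `max(-L, lb)`; exchanges not in the medium are
#' secretion-only). Among the typically many optimal flux vectors, the
#' reported one additionally minimizes the total absolute flux, so
#' secretion sets are deterministic rather than solver-dependent.
#'
#' @param model A `metabolic_model`.
#' @param medium An `fba_medium` (see [make_medium()]).
#' @param minimize_total_flux Resolve alternate optima by minimizing
#'   `sum(|v|)` at the optimal growth rate (default `TRUE`).
#' @return An `fba_solution`: list with `status` (`"optimal"` or
#'   `"infeasible"`), `growth_rate`, `fluxes` (named by reaction),
#'   `uptake_fluxes` and `secretion_fluxes` (named by exchanged
#'   metabolite, both as positive magnitudes).
#' @examples
#' # chain model: uptake bound 10 limits growth
#' m <- metabolic_model(
#'   "chain",
#'   data.frame(id = c("A", "BM", "co2"), carbon_atoms = c(2, 1, 1)),
#'   list(
#'     list(id = "EX_A", stoich = c(A = -1), lb = -1000, ub = 1000,
#'          is_exchange = TRUE, is_biomass = FALSE),
#'     list(id = "conv", stoich = c(A = -1, BM = 1, co2 = 1),
#'          lb = 0, ub = 1000, is_exchange = FALSE, is_biomass = FALSE),
#'     list(id = "bio", stoich = c(BM = -1), lb = 0, ub = 1000,
#'          is_exchange = FALSE, is_biomass = TRUE),
#'     list(id = "EX_co2", stoich = c(co2 = -1), lb = 0, ub = 1000,
#'          is_exchange = TRUE, is_biomass = FALSE)
#'   )
#' )
#' sol <- solve_fba(m, make_medium(c(EX_A = 10)))
#' sol$growth_rate  # 10
#' @export
solve_fba <- function(model, medium, minimize_total_flux = TRUE) {
  stopifnot(inherits(model, "metabolic_model"))
  rxns <- model$rxns
  lb <- rxns$lb
  ub <- rxns$ub
  ex <- rxns$is_exchange
  ## medium-applied bounds: allowed uptakes get lb = -limit, the rest of
  ## the exchanges become secretion-only
  lb[ex] <- pmax(lb[ex], 0)
  allowed <- intersect(names(medium), rxns$id[ex])
  if (length(allowed)) {
    i <- match(allowed, rxns$id)
    lb[i] <- pmax(rxns$lb[i], -unclass(medium)[allowed])
  }
  n <- nrow(rxns)
  obj <- as.numeric(rxns$is_biomass)
  b0 <- rep(0, nrow(model$S))
  sol <- simplex_box(obj, model$S, b0, lb, ub, maximize = TRUE)
  if (sol$status != "optimal") {
    return(new_fba_solution(model, "infeasible", rep(0, n)))
  }
  v <- sol$x
  if (minimize_total_flux) {
    ## fix growth at its optimum, minimize sum(|v|) via v = p - n split
    fstar <- sol$obj
    A2 <- rbind(cbind(model$S, -model$S), c(obj, -obj))
    lb2 <- c(pmax(lb, 0), pmax(-ub, 0))
    ub2 <- c(pmax(ub, 0), pmax(-lb, 0))
    sol2 <- simplex_box(rep(1, 2 * n), A2, c(b0, fstar), lb2, ub2,
                        maximize = FALSE)
    if (sol2$status == "optimal") {
      v <- sol2$x[seq_len(n)] - sol2$x[n + seq_len(n)]
    }
  }
  new_fba_solution(model, "optimal", v)
}

new_fba_solution <- function(model, status, v) {
  names(v) <- model$rxns$id
  growth <- if (status == "optimal") max(v[[model$biomass_id]], 0) else 0
  ex_mets <- exchange_metabolites(model$S, model$rxns)
  exv <- v[names(ex_mets)]
  up <- -exv[exv < 0]
  sec <- exv[exv > 0]
  names(up) <- ex_mets[names(up)]
  names(sec) <- ex_mets[names(sec)]
  structure(
    list(status = status, growth_rate = growth, fluxes = v,
         uptake_fluxes = up, secretion_fluxes = sec,
         model_id = model$model_id),
    class = "fba_solution"
  )
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("<fba_solution>", x$model_id, " status:", x$status,
      " growth:", format(x$growth_rate, digits = 6), "\n")
  invisible(x)
}

#' Single-carbon-source utilization test
#'
#' A model can utilize a carbon source if, with only that source allowed
#' (uptake limit 1000, i.e. unrestricted), FBA yields a growth rate above
#' the noise floor AND a positive CO2 secretion flux. Growth without CO2
#' release does not count as utilization. A source whose exchange
#' reaction is absent from the model cannot be utilized.
#'
#' @param model A `metabolic_model`.
#' @param carbon_exchange_id Exchange reaction id of the source.
#' @param uptake_flux Uptake limit applied to the single source.
#' @param eps Noise floor for "above zero" (flux units).
#' @return Logical.
#' @export
can_utilize <- function(model, carbon_exchange_id, uptake_flux = 1000,
                        eps = 1e-6) {
  if (is.na(model$co2_exchange_id)) {
    stop("model lacks a CO2 exchange reaction", call. = FALSE)
  }
  if (!carbon_exchange_id %in% model$rxns$id[model$rxns$is_exchange]) {
    return(FALSE)
  }
  sol <- solve_fba(model, make_medium(stats::setNames(uptake_flux,
                                                      carbon_exchange_id)),
                   minimize_total_flux = FALSE)
  co2 <- sol$fluxes[[model$co2_exchange_id]]
  sol$status == "optimal" && sol$growth_rate > eps && co2 > eps
}

#' Carbon utilization breadth
#'
#' The number of carbon sources, out of a candidate list, that the model
#' can utilize in the sense of [can_utilize()] (growth and CO2 release on
#' that source alone).
#'
#' @param model A `metabolic_model`.
#' @param carbon_source_ids Character vector of exchange reaction ids or
#'   metabolite ids (metabolite ids are mapped to `EX_<id>`).
#' @return Integer in `[0, length(carbon_source_ids)]`.
#' @export
compute_cub <- function(model, carbon_source_ids) {
  if (!length(carbon_source_ids)) stop("empty carbon source list", call. = FALSE)
  ids <- ifelse(carbon_source_ids %in% model$mets$id,
                paste0("EX_", carbon_source_ids), carbon_source_ids)
  sum(vapply(ids, function(id) can_utilize(model, id), logical(1)))
}
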