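#' Construct a constraint-based metabolic model
#'
#' A minimal stoichiometric model: metabolites with per-molecule carbon
#' atom counts, reactions with flux bounds (mmol per gram dry weight per
#' hour), exactly one biomass reaction (the FBA objective), and exchange
#' reactions that each touch exactly one metabolite. The standard sign
#' convention is used throughout: negative exchange flux is uptake,
#' positive is secretion.
#'
#' @param model_id Model identifier.
#' @param metabolites Data frame with columns `id` and `carbon_atoms`
#'   (non-negative integers).
#' @param reactions List of reactions, each a list with elements `id`,
#'   `stoich` (named numeric: metabolite -> coefficient), `lb`, `ub`,
#'   `is_exchange`, `is_biomass`.
#' @param co2_id Metabolite id of carbon dioxide (its exchange reaction is
#'   detected automatically).
#' @return An object of class `metabolic_model`.
#' @examples
#' m <- metabolic_model(
#'   "toy",
#'   metabolites = data.frame(id = c("S", "BM", "co2"),
#'                            carbon_atoms = c(6, 1, 1)),
#'   reactions = list(
#'     list(id = "EX_S", stoich = c(S = -1), lb = -1000, ub = 1000,
#'          is_exchange = TRUE, is_biomass = FALSE),
#'     list(id = "conv", stoich = c(S = -1, BM = 5, co2 = 1),
#'          lb = 0, ub = 1000, is_exchange = FALSE, is_biomass = FALSE),
#'     list(id = "biomass", stoich = c(BM = -10), lb = 0, ub = 1000,
#'          is_exchange = FALSE, is_biomass = TRUE),
#'     list(id = "EX_co2", stoich = c(co2 = -1), lb = 0, ub = 1000,
#'          is_exchange = TRUE, is_biomass = FALSE)
#'   )
#' )
#' @export
metabolic_model <- function(model_id, metabolites, reactions,
                            co2_id = "co2") {
  stopifnot(all(c("id", "carbon_atoms") %in% names(metabolites)))
  met_ids <- as.character(metabolites$id)
  rxn_ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(met_ids)) stop("duplicate metabolite ids", call. = FALSE)
  if (anyDuplicated(rxn_ids)) stop("duplicate reaction ids", call. = FALSE)
  S <- matrix(0, nrow = length(met_ids), ncol = length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (r in reactions) {
    if (!all(names(r$stoich) %in% met_ids)) {
      stop("reaction ", r$id, " references unknown metabolites", call. = FALSE)
    }
    S[names(r$stoich), r$id] <- r$stoich
  }
  rxns <- data.frame(
    id = rxn_ids,
    lb = vapply(reactions, function(r) r$lb, numeric(1)),
    ub = vapply(reactions, function(r) r$ub, numeric(1)),
    is_exchange = vapply(reactions, function(r) isTRUE(r$is_exchange), logical(1)),
    is_biomass = vapply(reactions, function(r) isTRUE(r$is_biomass), logical(1)),
    stringsAsFactors = FALSE
  )
  biomass_id <- rxns$id[rxns$is_biomass]
  ex_mets <- exchange_metabolites(S, rxns)
  co2_ex <- names(ex_mets)[ex_mets == co2_id]
  obj <- structure(
    list(
      model_id = model_id,
      mets = data.frame(id = met_ids,
                        carbon_atoms = as.numeric(metabolites$carbon_atoms),
                        stringsAsFactors = FALSE),
      S = S,
      rxns = rxns,
      biomass_id = if (length(biomass_id)) biomass_id[1] else NA_character_,
      co2_exchange_id = if (length(co2_ex)) co2_ex[1] else NA_character_
    ),
    class = "metabolic_model"
  )
  validate_model(obj)
  obj
}

## map exchange reaction id -> its single metabolite id
exchange_metabolites <- function(S, rxns) {
  ex <- rxns$id[rxns$is_exchange]
  out <- character(0)
  for (id in ex) {
    touched <- rownames(S)[S[, id] != 0]
    out[id] <- if (length(touched) == 1L) touched else NA_character_
  }
  out
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: bounds ordered, exactly one biomass
#' reaction, every exchange touches exactly one metabolite, a CO2
#' exchange is present, and carbon atoms are conserved on every internal
#' non-biomass reaction (mass can only enter or leave through exchanges
#' and the biomass drain).
#'
#' @param model A `metabolic_model`.
#' @param tol Tolerance for the carbon balance.
#' @return The model, invisibly; errors on violation.
#' @export
validate_model <- function(model, tol = 1e-9) {
  stopifnot(inherits(model, "metabolic_model"))
  if (any(model$rxns$lb > model$rxns$ub)) {
    stop("reaction bounds with lb > ub", call. = FALSE)
  }
  if (sum(model$rxns$is_biomass) != 1L) {
    stop("model must have exactly one biomass reaction", call. = FALSE)
  }
  if (any(model$mets$carbon_atoms < 0)) {
    stop("negative carbon atom counts", call. = FALSE)
  }
  ex_mets <- exchange_metabolites(model$S, model$rxns)
  if (any(is.na(ex_mets))) {
    stop("exchange reactions must touch exactly one metabolite", call. = FALSE)
  }
  if (is.na(model$co2_exchange_id)) {
    stop("model lacks a CO2 exchange reaction", call. = FALSE)
  }
  carbon <- stats::setNames(model$mets$carbon_atoms, model$mets$id)
  internal <- !model$rxns$is_exchange & !model$rxns$is_biomass
  if (any(internal)) {
    bal <- as.vector(carbon[rownames(model$S)] %*%
                       model$S[, internal, drop = FALSE])
    if (any(abs(bal) > tol)) {
      stop("carbon not conserved on internal reaction(s): ",
           paste(model$rxns$id[internal][abs(bal) > tol], collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model>", x$model_id, "\n",
      " metabolites:", nrow(x$mets),
      " reactions:", nrow(x$rxns),
      " (", sum(x$rxns$is_exchange), "exchanges )\n")
  invisible(x)
}

#' Carbon-source exchange reactions of a model
#'
#' Exchange reactions whose metabolite contains carbon, excluding the CO2
#' exchange.
#'
#' @param model A `metabolic_model`.
#' @return Named character vector: exchange reaction id -> metabolite id.
#' @export
carbon_exchanges <- function(model) {
  ex_mets <- exchange_metabolites(model$S, model$rxns)
  carbon <- stats::setNames(model$mets$carbon_atoms, model$mets$id)
  keep <- carbon[ex_mets] > 0 & names(ex_mets) != model$co2_exchange_id
  ex_mets[keep]
}

#' Define a growth medium
#'
#' A medium is a named non-negative vector of maximum uptake fluxes
#' (mmol per gram dry weight per hour), keyed by exchange reaction id.
#' Exchanges absent from the medium are secretion-only.
#'
#' @param uptakes Named numeric vector of uptake limits.
#' @return Object of class `fba_medium`.
#' @examples
#' make_medium(c(EX_C01 = 1000, EX_C02 = 1000))
#' @export
make_medium <- function(uptakes) {
  if (length(uptakes) && (is.null(names(uptakes)) || any(names(uptakes) == ""))) {
    stop("uptake limits must be named by exchange reaction id", call. = FALSE)
  }
  if (any(uptakes < 0)) stop("uptake limits must be >= 0", call. = FALSE)
  structure(as.numeric(uptakes), names = names(uptakes), class = "fba_medium")
}

#' Cap every allowed uptake at a common flux level
#'
#' Applies one rung of the uptake-flux ladder: every carbon source allowed
#' by the medium is capped at `flux` (a per-source cap, not a shared
#' budget). A cap of 1000 reproduces the unrestricted default setting.
#'
#' @param medium An `fba_medium`.
#' @param flux Non-negative per-source uptake cap.
#' @return A capped `fba_medium`.
#' @export
apply_uptake_limit <- function(medium, flux) {
  if (length(flux) != 1L || is.na(flux) || flux < 0) {
    stop("`flux` must be a single non-negative number", call. = FALSE)
  }
  make_medium(pmin(unclass(medium), flux))
}
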