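#' Parse a reaction equation string
#'
#' Equations use the dialect `"1 A + 2 B -> 1 C"`; either side may be
#' empty (exchange and sink reactions), e.g. `"1 A ->"`.
#'
#' @param equation Equation string.
#' @return Named numeric stoichiometry (reactants negative).
#' @export
parse_reaction_equation <- function(equation) {
  sides <- strsplit(equation, "->", fixed = TRUE)[[1]]
  if (length(sides) < 1L || length(sides) > 2L) {
    stop("malformed equation: ", equation, call. = FALSE)
  }
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (is.na(s) || s == "") return(numeric(0))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (t in terms) {
      parts <- strsplit(t, "\\s+")[[1]]
      if (length(parts) == 1L) {
        out[parts[1]] <- sign
      } else if (length(parts) == 2L) {
        out[parts[2]] <- sign * as.numeric(parts[1])
      } else {
        stop("malformed term '", t, "' in equation: ", equation, call. = FALSE)
      }
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- if (length(sides) == 2L) parse_side(sides[2], 1) else numeric(0)
  st <- c(lhs, rhs)
  tapply_sum <- tapply(st, names(st), sum)
  stats::setNames(as.numeric(tapply_sum), names(tapply_sum))
}

format_reaction_equation <- function(stoich) {
  fmt <- function(v) {
    if (!length(v)) return("")
    paste(paste(format(abs(v), trim = TRUE, scientific = FALSE),
                names(v)), collapse = " + ")
  }
  paste(fmt(stoich[stoich < 0]), "->", fmt(stoich[stoich > 0]))
}

#' Write a model in the native TSV reaction-list dialect
#'
#' Two files: `<stem>_reactions.tsv` (columns `reaction_id`, `equation`,
#' `lb`, `ub`, `is_exchange`, `is_biomass`) and `<stem>_metabolites.tsv`
#' (columns `id`, `carbon_atoms`).
#'
#' @param model A `metabolic_model`.
#' @param stem Path stem for the two output files.
#' @return Character vector of the two paths, invisibly.
#' @export
write_model_tsv <- function(model, stem) {
  rx <- model$rxns
  rx$equation <- apply(model$S, 2, function(col) {
    format_reaction_equation(col[col != 0])
  })[rx$id]
  rx <- rx[, c("id", "equation", "lb", "ub", "is_exchange", "is_biomass")]
  names(rx)[1] <- "reaction_id"
  p1 <- paste0(stem, "_reactions.tsv")
  p2 <- paste0(stem, "_metabolites.tsv")
  utils::write.table(rx, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(model$mets, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2))
}

#' Read a model from the native TSV reaction-list dialect
#'
#' @param stem Path stem used by [write_model_tsv()], or explicit paths
#'   via `reactions` / `metabolites`.
#' @param model_id Model identifier (default: basename of the stem).
#' @param reactions,metabolites Optional explicit file paths.
#' @param co2_id Metabolite id of carbon dioxide.
#' @return A `metabolic_model`.
#' @export
read_model_tsv <- function(stem = NULL, model_id = NULL, reactions = NULL,
                           metabolites = NULL, co2_id = "co2") {
  if (is.null(reactions)) reactions <- paste0(stem, "_reactions.tsv")
  if (is.null(metabolites)) metabolites <- paste0(stem, "_metabolites.tsv")
  if (is.null(model_id)) model_id <- basename(stem %||% "model")
  rx <- utils::read.delim(reactions, stringsAsFactors = FALSE)
  mets <- utils::read.delim(metabolites, stringsAsFactors = FALSE)
  rlist <- lapply(seq_len(nrow(rx)), function(i) {
    list(id = rx$reaction_id[i],
         stoich = parse_reaction_equation(rx$equation[i]),
         lb = rx$lb[i], ub = rx$ub[i],
         is_exchange = as.logical(rx$is_exchange[i]),
         is_biomass = as.logical(rx$is_biomass[i]))
  })
  metabolic_model(model_id, mets, rlist, co2_id = co2_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a model as SBML Level 3 with the FBC extension
#'
#' Emits a minimal but standard-conformant SBML L3V1 document with FBC
#' version 2 flux bounds and a maximization objective on the biomass
#' reaction. Carbon atom counts are carried in `fbc:chemicalFormula`
#' (e.g. `C6`). Species and reaction ids receive the conventional `M_`
#' and `R_` prefixes.
#'
#' @param model A `metabolic_model`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_model_sbml <- function(model, path) {
  fbc <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:fbc" = fbc, level = "3", version = "1", "fbc:required" = "false"
  )
  mod <- xml2::xml_add_child(doc, "model", id = model$model_id,
                             "fbc:strict" = "true")
  comps <- xml2::xml_add_child(mod, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "c", constant = "true")
  sps <- xml2::xml_add_child(mod, "listOfSpecies")
  for (i in seq_len(nrow(model$mets))) {
    ca <- model$mets$carbon_atoms[i]
    sp <- xml2::xml_add_child(
      sps, "species", id = paste0("M_", model$mets$id[i]), compartment = "c",
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false"
    )
    if (ca > 0) xml2::xml_set_attr(sp, "fbc:chemicalFormula", paste0("C", ca))
  }
  pars <- xml2::xml_add_child(mod, "listOfParameters")
  rxs <- xml2::xml_add_child(mod, "listOfReactions")
  for (i in seq_len(nrow(model$rxns))) {
    id <- model$rxns$id[i]
    lbp <- paste0("lb_", id)
    ubp <- paste0("ub_", id)
    xml2::xml_add_child(pars, "parameter", id = lbp,
                        value = format(model$rxns$lb[i], scientific = FALSE),
                        constant = "true")
    xml2::xml_add_child(pars, "parameter", id = ubp,
                        value = format(model$rxns$ub[i], scientific = FALSE),
                        constant = "true")
    rx <- xml2::xml_add_child(
      rxs, "reaction", id = paste0("R_", id),
      reversible = if (model$rxns$lb[i] < 0) "true" else "false",
      fast = "false", "fbc:lowerFluxBound" = lbp, "fbc:upperFluxBound" = ubp
    )
    col <- model$S[, id]
    col <- col[col != 0]
    if (any(col < 0)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (m in names(col)[col < 0]) {
        xml2::xml_add_child(lr, "speciesReference", species = paste0("M_", m),
                            stoichiometry = format(-col[[m]], scientific = FALSE),
                            constant = "true")
      }
    }
    if (any(col > 0)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (m in names(col)[col > 0]) {
        xml2::xml_add_child(lp, "speciesReference", species = paste0("M_", m),
                            stoichiometry = format(col[[m]], scientific = FALSE),
                            constant = "true")
      }
    }
  }
  objs <- xml2::xml_add_child(mod, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
  o <- xml2::xml_add_child(objs, "fbc:objective", "fbc:id" = "obj",
                           "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(o, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lfo, "fbc:fluxObjective",
                      "fbc:reaction" = paste0("R_", model$biomass_id),
                      "fbc:coefficient" = "1")
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a model from SBML Level 3 with the FBC extension
#'
#' Reads the subset of SBML/FBC written by [write_model_sbml()]: species
#' with carbon counts in `fbc:chemicalFormula`, reactions with FBC flux
#' bound parameters, and the active maximization objective identifying
#' the biomass reaction. Reactions touching exactly one species are
#' treated as exchanges.
#'
#' @param path SBML file path.
#' @param co2_id Metabolite id of carbon dioxide (after stripping the
#'   `M_` prefix).
#' @return A `metabolic_model`.
#' @export
read_model_sbml <- function(path, co2_id = "co2") {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  model_node <- xml2::xml_find_first(doc, ".//d1:model", ns)
  model_id <- xml2::xml_attr(model_node, "id")
  strip <- function(x, prefix) sub(paste0("^", prefix), "", x)

  sp <- xml2::xml_find_all(doc, ".//d1:listOfSpecies/d1:species", ns)
  formula <- xml2::xml_attr(sp, "chemicalFormula")
  carbon <- ifelse(is.na(formula), 0, {
    num <- sub("^C([0-9]*)$", "\\1", formula)
    ifelse(num == "", 1, suppressWarnings(as.numeric(num)))
  })
  mets <- data.frame(id = strip(xml2::xml_attr(sp, "id"), "M_"),
                     carbon_atoms = as.numeric(carbon),
                     stringsAsFactors = FALSE)

  pars <- xml2::xml_find_all(doc, ".//d1:listOfParameters/d1:parameter", ns)
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                           xml2::xml_attr(pars, "id"))

  bio_rxn <- xml2::xml_attr(
    xml2::xml_find_first(doc, ".//fbc:fluxObjective", ns), "reaction"
  )
  bio_id <- strip(bio_rxn, "R_")

  rx_nodes <- xml2::xml_find_all(doc, ".//d1:listOfReactions/d1:reaction", ns)
  rlist <- lapply(rx_nodes, function(node) {
    id <- strip(xml2::xml_attr(node, "id"), "R_")
    get_refs <- function(tag, sign) {
      refs <- xml2::xml_find_all(node, paste0("./d1:", tag,
                                              "/d1:speciesReference"), ns)
      stats::setNames(
        sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
        strip(xml2::xml_attr(refs, "species"), "M_")
      )
    }
    st <- c(get_refs("listOfReactants", -1), get_refs("listOfProducts", 1))
    list(id = id, stoich = st,
         lb = pvals[[xml2::xml_attr(node, "lowerFluxBound")]],
         ub = pvals[[xml2::xml_attr(node, "upperFluxBound")]],
         is_exchange = length(st) == 1L && id != bio_id,
         is_biomass = id == bio_id)
  })
  metabolic_model(model_id, mets, rlist, co2_id = co2_id)
}
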