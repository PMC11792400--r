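#' Reference genome-survey and matching statistics
#'
#' Published summary numbers from a large genome survey of decomposer
#' communities, used as fixed inputs by [verify_targets()] and the
#' acceptance tooling: kingdom mean gene counts per functional group
#' (see [default_group_means()]), the printed fungal/bacterial fold
#' ratios for xylanase and ligninolytic genes, and the printed
#' numerator/denominator pairs behind the OTU-matching and CAZyme
#' assignment percentages.
#'
#' @return Nested list of reference constants.
#' @export
reference_survey_values <- function() {
  list(
    group_means = default_group_means(),
    printed_folds = c(xylanase = 8.38, ligninolytic = 16.57),
    match_counts = list(
      bacteria_pass1 = c(matched = 1164, total = 2190, printed_pct = 53.2),
      fungi_pass1 = c(matched = 95, total = 309, printed_pct = 30.7),
      bacteria_overall = c(matched = 1538, total = 2190, printed_pct = 70.2),
      fungi_overall = c(matched = 126, total = 309, printed_pct = 40.8),
      cazyme_assigned = c(matched = 7702, total = 12813, printed_pct = 60.1)
    )
  )
}

#' Recompute the reference arithmetic quantities
#'
#' Computes, from the reference inputs of [reference_survey_values()],
#' the fungal/bacterial fold ratios of mean xylanase and ligninolytic
#' gene counts and the match-fraction percentages from their
#' numerator/denominator pairs.
#'
#' @return Data frame (`quantity`, `value`, `printed`).
#' @export
reference_arithmetic <- function() {
  ref <- reference_survey_values()
  gm <- ref$group_means
  folds <- data.frame(
    quantity = c("xylanase_fold", "ligninolytic_fold"),
    value = c(gm$fungi[["xylanase"]] / gm$bacteria[["xylanase"]],
              gm$fungi[["ligninolytic"]] / gm$bacteria[["ligninolytic"]]),
    printed = as.numeric(ref$printed_folds)
  )
  mc <- ref$match_counts
  pcts <- data.frame(
    quantity = paste0("pct_", names(mc)),
    value = vapply(mc, function(x) 100 * x[["matched"]] / x[["total"]],
                   numeric(1)),
    printed = vapply(mc, function(x) x[["printed_pct"]], numeric(1))
  )
  out <- rbind(folds, pcts)
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' @param generator A [generator_config()].
#' @param ladder Uptake-flux ladder (strictly increasing).
#' @param crossfeed A [crossfeed_config()].
#' @param crossfeed_on Run the two-pass cross-feeding simulation and
#'   report relative divergence (default `TRUE`).
#' @param trophic_scheme Scheme for OTU-level trophic calls.
#' @param log_level `"info"` or `"quiet"`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            ladder = flux_ladder(),
                            crossfeed = crossfeed_config(),
                            crossfeed_on = TRUE,
                            trophic_scheme = c("observational",
                                               "synthetic_community"),
                            log_level = c("info", "quiet")) {
  stopifnot(all(diff(ladder) > 0), all(ladder > 0))
  structure(
    list(generator = generator, ladder = ladder, crossfeed = crossfeed,
         crossfeed_on = isTRUE(crossfeed_on),
         trophic_scheme = match.arg(trophic_scheme),
         log_level = match.arg(log_level)),
    class = "pipeline_config"
  )
}

.log_stage <- function(cfg, stage, t0) {
  if (cfg$log_level == "info") {
    message(sprintf("[decomplex] %-18s %6.1fs", stage,
                    as.numeric(Sys.time() - t0, units = "secs")))
  }
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline on synthetic data
#'
#' Generates a synthetic study bundle, scores PDI and enrichment,
#' classifies trophic roles at the OTU level (observational scheme) and
#' the model level (synthetic-community scheme on the linked genomes),
#' simulates the model community across the uptake-flux ladder with and
#' without cross-feeding, and writes per-stage TSVs plus a
#' reproducibility manifest to `output_dir`. With a fixed config the
#' numeric outputs are byte-identical across runs.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Output directory (created if missing).
#' @return Invisibly, a report list with all in-memory stage results and
#'   the written file paths.
#' @export
run_pipeline <- function(config, output_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  gen <- config$generator

  bundle <- gen_synthetic_bundle(gen)
  .log_stage(config, "generate", t0)

  ## PDI scoring and enrichment per kingdom
  pdi_tab <- compute_pdi(bundle$profiles)
  enrich <- do.call(rbind, lapply(split(pdi_tab, pdi_tab$kingdom),
                                  function(d) {
    data.frame(kingdom = d$kingdom[1],
               frac_above_semirange = pdi_enrichment(d$pdi, "semi_range"),
               frac_top20pct = pdi_enrichment(d$pdi, "pct_of_max", 0.2),
               mean_pdi = mean(d$pdi))
  }))
  rownames(enrich) <- NULL
  .log_stage(config, "score-pdi", t0)

  ## OTU-level trophic calls: match OTUs to genomes, take mean abundance
  matches <- match_otus_to_genomes(bundle$hits)
  mean_ab <- stats::aggregate(rel_abundance ~ otu_id, data = bundle$abundances,
                              FUN = mean)
  comp <- count_functional_groups(bundle$profiles)
  calls <- merge(matches, mean_ab, by = "otu_id")
  calls <- merge(calls, comp[, c("genome_id", "d_c", "d_x")], by = "genome_id")
  calls$cx_gene_count <- calls$d_c + calls$d_x
  calls$role <- classify_trophic_role(calls$cx_gene_count,
                                      calls$rel_abundance,
                                      config$trophic_scheme)
  calls <- calls[order(calls$otu_id),
                 c("otu_id", "genome_id", "pass", "cx_gene_count",
                   "rel_abundance", "role")]
  .log_stage(config, "classify-roles", t0)

  ## model community over the ladder
  med <- base_medium(gen)
  models <- bundle$models
  ## link model i to the i-th bacterial genome and classify with the
  ## gene-count-only synthetic-community scheme
  bact <- comp[comp$kingdom == "bacteria", ]
  link_n <- min(length(models), nrow(bact))
  model_roles <- data.frame(
    model_id = vapply(models, function(m) m$model_id, character(1))[seq_len(link_n)],
    genome_id = bact$genome_id[seq_len(link_n)],
    cx_gene_count = (bact$d_c + bact$d_x)[seq_len(link_n)],
    stringsAsFactors = FALSE
  )
  model_roles$role <- classify_trophic_role(model_roles$cx_gene_count,
                                            scheme = "synthetic_community")

  per_level <- list()
  crossfeed_rows <- list()
  comparison_rows <- list()
  for (fl in config$ladder) {
    if (config$crossfeed_on) {
      cfres <- simulate_with_crossfeeding(models, med, fl, config$crossfeed)
      ind <- cfres$individuals
      row <- community_metrics(ind, fl)
      row$rd <- cfres$rd
      crossfeed_rows[[as.character(fl)]] <- data.frame(
        flux_level = fl, n_pooled = length(cfres$pooled), cap = cfres$cap,
        scale = cfres$scale, rd = cfres$rd,
        mean_growth_crossfed = mean(cfres$growth_with)
      )
    } else {
      ind <- simulate_individuals(models, med, fl,
                                  secretion_floor = config$crossfeed$secretion_floor)
      row <- community_metrics(ind, fl)
    }
    per_level[[as.character(fl)]] <- row
    grp <- merge(ind, model_roles, by = "model_id")
    gd <- grp$growth_rate[grp$role == "decomposer"]
    ge <- grp$growth_rate[grp$role == "exploiter"]
    comparison_rows[[as.character(fl)]] <- data.frame(
      flux_level = fl,
      growth_decomposer = if (length(gd)) mean(gd) else NA_real_,
      growth_exploiter = if (length(ge)) mean(ge) else NA_real_,
      growth_ratio_de = if (length(gd) && length(ge) && mean(ge) > 0) {
        mean(gd) / mean(ge)
      } else NA_real_,
      n_decomposer = length(gd), n_exploiter = length(ge)
    )
  }
  metrics <- do.call(rbind, per_level)
  rownames(metrics) <- NULL
  cg <- cgrv_profile(metrics)
  metrics$cgrv_to_next <- c(cg$cgrv, NA_real_)
  comparison <- do.call(rbind, comparison_rows)
  rownames(comparison) <- NULL
  .log_stage(config, "community-sim", t0)

  files <- c(
    profiles = write_tsv(bundle$profiles, file.path(output_dir, "profiles.tsv")),
    pdi = write_tsv(pdi_tab, file.path(output_dir, "pdi.tsv")),
    enrichment = write_tsv(enrich, file.path(output_dir, "pdi_enrichment.tsv")),
    abundances = write_tsv(bundle$abundances,
                           file.path(output_dir, "abundances.tsv")),
    hits = write_tsv(bundle$hits, file.path(output_dir, "hits.tsv")),
    matches = write_tsv(matches, file.path(output_dir, "matches.tsv")),
    trophic = write_tsv(calls, file.path(output_dir, "trophic_calls.tsv")),
    model_roles = write_tsv(model_roles,
                            file.path(output_dir, "model_roles.tsv")),
    expression = write_tsv(
      group_expression_proportions(bundle$expression),
      file.path(output_dir, "expression_proportions.tsv")
    ),
    metrics = write_tsv(metrics, file.path(output_dir, "community_metrics.tsv")),
    comparison = write_tsv(comparison,
                           file.path(output_dir, "trophic_comparison.tsv"))
  )
  if (config$crossfeed_on) {
    crossfeed <- do.call(rbind, crossfeed_rows)
    rownames(crossfeed) <- NULL
    files["crossfeed"] <- write_tsv(crossfeed,
                                    file.path(output_dir, "crossfeed.tsv"))
  } else {
    crossfeed <- NULL
  }

  ## reproducibility manifest
  cfg_yaml <- file.path(output_dir, "config.yaml")
  write_pipeline_config(config, cfg_yaml)
  manifest <- list(
    seed = gen$seed,
    package = "decomplex",
    version = as.character(utils::packageVersion("decomplex")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_file = "config.yaml",
    config_md5 = unname(tools::md5sum(cfg_yaml)),
    outputs = basename(unname(files))
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files["manifest"] <- file.path(output_dir, "manifest.json")
  .log_stage(config, "write-outputs", t0)

  invisible(list(
    config = config, bundle = bundle, pdi = pdi_tab, enrichment = enrich,
    matches = matches, trophic_calls = calls, model_roles = model_roles,
    metrics = metrics, crossfeed = crossfeed, comparison = comparison,
    files = files
  ))
}

#' Write a pipeline config as YAML
#'
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  gen <- config$generator
  yaml::write_yaml(list(
    generator = gen[setdiff(names(gen), "group_mean_counts")],
    group_mean_counts = lapply(config$generator$group_mean_counts, as.list),
    ladder = config$ladder,
    crossfeed = unclass(config$crossfeed),
    crossfeed_on = config$crossfeed_on,
    trophic_scheme = config$trophic_scheme,
    log_level = config$log_level
  ), path, precision = 15)
  invisible(path)
}

#' Read a pipeline config from YAML
#'
#' @param path YAML file written by [write_pipeline_config()] (or
#'   hand-edited; every generator parameter is settable).
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen_args <- y$generator
  gen_args$group_mean_counts <- lapply(y$group_mean_counts, unlist)
  gen_args$cub_range <- unlist(gen_args$cub_range)
  gen_args$carbon_atoms_range <- unlist(gen_args$carbon_atoms_range)
  gen_args$byproduct_carbon_range <- unlist(gen_args$byproduct_carbon_range)
  pipeline_config(
    generator = do.call(generator_config, gen_args),
    ladder = unlist(y$ladder),
    crossfeed = do.call(crossfeed_config, y$crossfeed),
    crossfeed_on = isTRUE(y$crossfeed_on),
    trophic_scheme = y$trophic_scheme,
    log_level = y$log_level
  )
}

#' Evaluate the package's verification checks
#'
#' Recomputes the reference arithmetic (fold ratios and match
#' percentages from their printed inputs) and, when a pipeline report is
#' supplied, the structural properties of its outputs: PDI pool-sum
#' normalization, abundance column sums, the pooled-secretion carbon cap,
#' the relative-divergence range, and the CCSE convex-combination bound.
#' Prints and returns a pass/fail table.
#'
#' @param report Optional report list from [run_pipeline()].
#' @param quiet Suppress printing.
#' @return Data frame (`check`, `value`, `expected`, `pass`).
#' @export
verify_targets <- function(report = NULL, quiet = FALSE) {
  arith <- reference_arithmetic()
  is_fold <- grepl("fold", arith$quantity)
  rows <- data.frame(
    check = arith$quantity,
    value = arith$value,
    expected = arith$printed,
    pass = ifelse(is_fold,
                  abs(arith$value / arith$printed - 1) <= 0.005,
                  abs(round(arith$value, 1) - arith$printed) < 0.05),
    stringsAsFactors = FALSE
  )
  if (!is.null(report)) {
    pdi_sum <- sum(report$pdi$pdi)
    ab <- report$bundle$abundances
    colsum_dev <- max(abs(tapply(ab$rel_abundance, ab$sample_id, sum) - 1))
    extra <- data.frame(
      check = c("pdi_pool_sum", "abundance_colsum_dev"),
      value = c(pdi_sum, colsum_dev),
      expected = c(1, 0),
      pass = c(abs(pdi_sum - 1) < 1e-12, colsum_dev < 1e-9),
      stringsAsFactors = FALSE
    )
    rows <- rbind(rows, extra)
    if (!is.null(report$crossfeed)) {
      rows <- rbind(rows, data.frame(
        check = c("rd_range", "crossfeed_cap"),
        value = c(max(report$crossfeed$rd), max(report$crossfeed$scale)),
        expected = c(2, 1),
        pass = c(all(report$crossfeed$rd >= -1e-9 &
                       report$crossfeed$rd <= 2 + 1e-9),
                 all(report$crossfeed$scale <= 1 + 1e-9)),
        stringsAsFactors = FALSE
      ))
    }
    ccse_ok <- all(report$metrics$ccse >= -1e-9 &
                     report$metrics$ccse <= 1 + 1e-9)
    rows <- rbind(rows, data.frame(
      check = "ccse_convex_range", value = max(report$metrics$ccse),
      expected = 1, pass = ccse_ok, stringsAsFactors = FALSE
    ))
  }
  rownames(rows) <- NULL
  if (!quiet) {
    print(rows, digits = 6)
  }
  invisible(rows)
}
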