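#' Configuration for the synthetic-data generators
#'
#' One config object drives every generator, so a fixed seed yields a
#' byte-identical synthetic study. Defaults are chosen to emulate the
#' statistical structure of real decomposer communities: kingdom-specific
#' CAZyme group means (bacterial genomes average 1.59 cellulase, 0.72
#' xylanase, and 0.86 ligninolytic genes but carry large OH+PBH
#' repertoires; fungal genomes are 8-17-fold richer in the
#' residue-attacking groups), overdispersed per-genome counts, toy
#' metabolic models with configurable carbon niches and overflow
#' byproduct secretion, and an exploiter-dominant abundance regime.
#'
#' @param seed Integer RNG seed; every generator output is a pure
#'   function of the config including this seed.
#' @param n_bacteria,n_fungi Number of genomes per kingdom.
#' @param group_mean_counts List with elements `bacteria` and `fungi`,
#'   each a named vector of mean gene counts per functional group
#'   (`cellulase`, `xylanase`, `ligninolytic`, `oh_pbh`, `gt`, `other`).
#' @param dispersion Negative binomial size parameter for per-group gene
#'   count totals (smaller = more overdispersed).
#' @param n_carbon_sources Number of residue-derived carbon sources
#'   (default 35).
#' @param n_models Number of toy metabolic models in a community.
#' @param cub_range Integer interval from which each model's assigned
#'   carbon-niche size is drawn (within `[0, n_carbon_sources]`).
#' @param secretion_fraction Probability that an assigned carbon pathway
#'   carries an overflow branch secreting a byproduct.
#' @param carbon_atoms_range Integer interval of carbon atoms per source
#'   metabolite; the lower end must be at least 2 so that every pathway
#'   can couple growth to CO2 release.
#' @param exploiter_fraction Fraction of total community abundance
#'   assigned to low-CXL (cellulase+xylanase <= 2) genomes.
#' @param n_samples Number of samples in the abundance table.
#' @param n_byproducts Size of the shared byproduct catalog.
#' @param byproduct_carbon_range Carbon atoms per byproduct metabolite.
#' @param byproduct_use_prob Probability that a model carries an uptake
#'   pathway for a given byproduct (the cross-feeding consumer side).
#' @param efficient_cap Capacity (mmol per gDW per hour) of the
#'   high-yield "efficient" pathway per source; above this throughput the
#'   lower-yield overflow branch with obligatory byproduct secretion must
#'   be used, so secretion vanishes at low uptake flux.
#' @param mu_max_meanlog,mu_max_sdlog Lognormal parameters of each
#'   model's maximum growth rate.
#' @param biomass_yield Units of biomass precursor consumed per unit of
#'   growth flux.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(seed = 1,
                             n_bacteria = 2000,
                             n_fungi = 200,
                             group_mean_counts = default_group_means(),
                             dispersion = 2,
                             n_carbon_sources = 35,
                             n_models = 40,
                             cub_range = c(4, 28),
                             secretion_fraction = 0.6,
                             carbon_atoms_range = c(2, 6),
                             exploiter_fraction = 0.76,
                             n_samples = 6,
                             n_byproducts = 8,
                             byproduct_carbon_range = c(2, 3),
                             byproduct_use_prob = 0.4,
                             efficient_cap = 3,
                             mu_max_meanlog = log(8),
                             mu_max_sdlog = 0.6,
                             biomass_yield = 10) {
  cfg <- list(
    seed = as.integer(seed), n_bacteria = n_bacteria, n_fungi = n_fungi,
    group_mean_counts = group_mean_counts, dispersion = dispersion,
    n_carbon_sources = n_carbon_sources, n_models = n_models,
    cub_range = cub_range, secretion_fraction = secretion_fraction,
    carbon_atoms_range = carbon_atoms_range,
    exploiter_fraction = exploiter_fraction, n_samples = n_samples,
    n_byproducts = n_byproducts,
    byproduct_carbon_range = byproduct_carbon_range,
    byproduct_use_prob = byproduct_use_prob,
    efficient_cap = efficient_cap, mu_max_meanlog = mu_max_meanlog,
    mu_max_sdlog = mu_max_sdlog, biomass_yield = biomass_yield
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

#' Default kingdom x functional-group mean gene counts
#'
#' Bacterial means for the residue-attacking groups follow published
#' genome-survey averages (1.59 cellulase, 0.72 xylanase, 0.86
#' ligninolytic genes per genome, 16.36 OH+PBH genes); fungal means for
#' the same groups are the corresponding published fungal averages
#' (25.84, 6.04, 14.25). The remaining groups (fungal OH+PBH, GTs, other
#' non-GT CAZymes) are not published as means and are set to realistic
#' magnitudes.
#'
#' @return List with named vectors `bacteria` and `fungi`.
#' @export
default_group_means <- function() {
  list(
    bacteria = c(cellulase = 1.59, xylanase = 0.72, ligninolytic = 0.86,
                 oh_pbh = 16.36, gt = 15, other = 5),
    fungi = c(cellulase = 25.84, xylanase = 6.04, ligninolytic = 14.25,
              oh_pbh = 40, gt = 30, other = 15)
  )
}

validate_generator_config <- function(cfg) {
  with(cfg, {
    if (n_bacteria + n_fungi <= 0) {
      stop("n_bacteria + n_fungi must be positive", call. = FALSE)
    }
    if (any(unlist(group_mean_counts) < 0)) {
      stop("group mean counts must be >= 0", call. = FALSE)
    }
    if (dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
    if (cub_range[1] < 0 || cub_range[2] > n_carbon_sources ||
        cub_range[1] > cub_range[2]) {
      stop("cub_range must lie within [0, n_carbon_sources]", call. = FALSE)
    }
    if (secretion_fraction < 0 || secretion_fraction > 1 ||
        exploiter_fraction < 0 || exploiter_fraction > 1 ||
        byproduct_use_prob < 0 || byproduct_use_prob > 1) {
      stop("fractions must lie in [0, 1]", call. = FALSE)
    }
    if (carbon_atoms_range[1] < 2) {
      stop("carbon_atoms_range must start at >= 2 carbons so every ",
           "pathway can yield both biomass and CO2", call. = FALSE)
    }
    if (byproduct_carbon_range[1] < 2) {
      stop("byproduct_carbon_range must start at >= 2 carbons", call. = FALSE)
    }
  })
  invisible(cfg)
}

## families drawn for the groups outside the degradative catalog
.gt_families <- c("GT2", "GT4", "GT5", "GT28", "GT51")
.other_families <- c("GH13", "GH18", "GH23", "CBM2", "CBM3", "CBM6",
                     "PL1", "PL3", "PL4", "PL9")

#' Generate per-genome CAZyme family profiles
#'
#' For each genome and functional group, a group-total gene count is
#' drawn from a negative binomial distribution with the configured mean
#' and dispersion (gene-family counts across genomes are strongly
#' overdispersed), then allocated uniformly across the group's families
#' by a multinomial draw.
#'
#' @param cfg A [generator_config()].
#' @param catalog Functional-group catalog.
#' @return Long data frame (`genome_id`, `kingdom`, `family`, `count`);
#'   genomes whose draws are all zero are retained with a zero row.
#' @export
gen_genome_profiles <- function(cfg, catalog = cazyme_catalog()) {
  validate_generator_config(cfg)
  fam_by_group <- c(catalog, list(gt = .gt_families, other = .other_families))
  withr::with_seed(cfg$seed, {
    out <- list()
    for (kingdom in c("bacteria", "fungi")) {
      n <- if (kingdom == "bacteria") cfg$n_bacteria else cfg$n_fungi
      if (n == 0) next
      ids <- sprintf("%s%05d", if (kingdom == "bacteria") "B" else "F",
                     seq_len(n))
      means <- cfg$group_mean_counts[[kingdom]]
      for (grp in names(fam_by_group)) {
        mu <- if (grp %in% names(means)) means[[grp]] else 0
        if (mu == 0) next
        totals <- stats::rnbinom(n, size = cfg$dispersion, mu = mu)
        fams <- fam_by_group[[grp]]
        pos <- which(totals > 0)
        if (!length(pos)) next
        alloc <- vapply(
          totals[pos],
          function(t) stats::rmultinom(1, t, rep(1, length(fams)))[, 1],
          numeric(length(fams))
        )
        alloc <- matrix(alloc, nrow = length(fams))
        nz <- which(alloc > 0, arr.ind = TRUE)
        out[[paste(kingdom, grp)]] <- data.frame(
          genome_id = ids[pos][nz[, 2]], kingdom = kingdom,
          family = fams[nz[, 1]], count = alloc[nz],
          stringsAsFactors = FALSE
        )
      }
      out[[paste(kingdom, "registry")]] <- data.frame(
        genome_id = ids, kingdom = kingdom, family = "GH1", count = 0,
        stringsAsFactors = FALSE
      )
    }
    profiles <- do.call(rbind, out)
    rownames(profiles) <- NULL
    ## keep the zero registry row only for genomes with no positive rows
    has_pos <- unique(profiles$genome_id[profiles$count > 0])
    profiles <- profiles[profiles$count > 0 |
                           !profiles$genome_id %in% has_pos, ]
    profiles <- profiles[order(profiles$genome_id, profiles$family), ]
    rownames(profiles) <- NULL
    profiles
  })
}

#' Shared carbon source and byproduct catalogs of a config
#'
#' Source metabolites `C01..Cnn` and byproducts `B01..Bmm` with integer
#' carbon atom counts drawn once per config, so every model generated
#' under the same config shares the same carbon chemistry.
#'
#' @param cfg A [generator_config()].
#' @return List with data frames `sources` and `byproducts`
#'   (`id`, `carbon_atoms`).
#' @export
carbon_source_table <- function(cfg) {
  withr::with_seed(cfg$seed + 101L, {
    list(
      sources = data.frame(
        id = sprintf("C%02d", seq_len(cfg$n_carbon_sources)),
        carbon_atoms = sample(
          seq(cfg$carbon_atoms_range[1], cfg$carbon_atoms_range[2]),
          cfg$n_carbon_sources, replace = TRUE
        ),
        stringsAsFactors = FALSE
      ),
      byproducts = data.frame(
        id = sprintf("B%02d", seq_len(cfg$n_byproducts)),
        carbon_atoms = sample(
          seq(cfg$byproduct_carbon_range[1], cfg$byproduct_carbon_range[2]),
          cfg$n_byproducts, replace = TRUE
        ),
        stringsAsFactors = FALSE
      )
    )
  })
}

#' Generate toy constraint-based models
#'
#' Each model is assigned a carbon niche (a subset of the shared sources,
#' size drawn from `cub_range`) and, per source, a high-yield "efficient"
#' conversion pathway with limited capacity plus, with probability
#' `secretion_fraction`, an unlimited overflow pathway that diverts part
#' of the carbon into a secreted byproduct. Byproduct uptake pathways
#' (with probability `byproduct_use_prob` per byproduct) make the models
#' potential cross-feeding consumers. Every pathway releases CO2, so
#' growth on a source always satisfies the growth-and-CO2 utilization
#' test; models are feasible on every assigned source by construction.
#' Growth is capped by a per-model lognormal maximum rate, which is what
#' makes the number of absorbed sources shrink as uptake flux rises.
#'
#' @param cfg A [generator_config()].
#' @param model_ids Optional character vector of model ids (length
#'   `n_models`); defaults to `GMM001..`.
#' @return List of `metabolic_model` objects; the niche bookkeeping is
#'   attached to each model as attribute `niche`.
#' @export
gen_toy_models <- function(cfg, model_ids = NULL) {
  validate_generator_config(cfg)
  tabs <- carbon_source_table(cfg)
  src <- tabs$sources
  byp <- tabs$byproducts
  if (is.null(model_ids)) {
    model_ids <- sprintf("GMM%03d", seq_len(cfg$n_models))
  }
  stopifnot(length(model_ids) == cfg$n_models)
  withr::with_seed(cfg$seed + 2L, {
    lapply(seq_len(cfg$n_models), function(i) {
      k <- if (cfg$cub_range[1] == cfg$cub_range[2]) cfg$cub_range[1]
           else sample(seq(cfg$cub_range[1], cfg$cub_range[2]), 1)
      niche <- sort(sample(src$id, k))
      mu_max <- stats::rlnorm(1, cfg$mu_max_meanlog, cfg$mu_max_sdlog)
      rxns <- list()
      mets_used <- c("BM", "co2")
      add <- function(r) rxns[[length(rxns) + 1L]] <<- r
      for (s in niche) {
        cs <- src$carbon_atoms[src$id == s]
        add(list(id = paste0("EX_", s), stoich = stats::setNames(-1, s),
                 lb = -1000, ub = 1000, is_exchange = TRUE,
                 is_biomass = FALSE))
        add(list(id = paste0("eff_", s),
                 stoich = stats::setNames(c(-1, cs - 1, 1),
                                          c(s, "BM", "co2")),
                 lb = 0, ub = cfg$efficient_cap, is_exchange = FALSE,
                 is_biomass = FALSE))
        mets_used <- c(mets_used, s)
        if (stats::runif(1) < cfg$secretion_fraction) {
          b <- byp$id[sample(nrow(byp), 1)]
          cb <- byp$carbon_atoms[byp$id == b]
          if (cs >= cb + 2) {
            add(list(id = paste0("ovf_", s),
                     stoich = stats::setNames(c(-1, cs - 1 - cb, 1, 1),
                                              c(s, "BM", "co2", b)),
                     lb = 0, ub = 1000, is_exchange = FALSE,
                     is_biomass = FALSE))
            mets_used <- c(mets_used, b)
          }
        }
      }
      for (b in byp$id) {
        if (stats::runif(1) < cfg$byproduct_use_prob) {
          cb <- byp$carbon_atoms[byp$id == b]
          add(list(id = paste0("cat_", b),
                   stoich = stats::setNames(c(-1, cb - 1, 1),
                                            c(b, "BM", "co2")),
                   lb = 0, ub = 1000, is_exchange = FALSE,
                   is_biomass = FALSE))
          mets_used <- c(mets_used, b)
        }
      }
      ## one exchange per byproduct the model touches (secretion or uptake)
      for (b in intersect(byp$id, unique(mets_used))) {
        add(list(id = paste0("EX_", b), stoich = stats::setNames(-1, b),
                 lb = -1000, ub = 1000, is_exchange = TRUE,
                 is_biomass = FALSE))
      }
      add(list(id = "biomass",
               stoich = stats::setNames(-cfg$biomass_yield, "BM"),
               lb = 0, ub = mu_max, is_exchange = FALSE, is_biomass = TRUE))
      add(list(id = "EX_co2", stoich = c(co2 = -1), lb = 0, ub = 1000,
               is_exchange = TRUE, is_biomass = FALSE))
      mets_used <- unique(mets_used)
      atoms <- rbind(src, byp, data.frame(id = c("BM", "co2"),
                                          carbon_atoms = c(1, 1)))
      mets <- atoms[atoms$id %in% mets_used, ]
      m <- metabolic_model(model_ids[i], mets, rxns)
      attr(m, "niche") <- niche
      attr(m, "mu_max") <- mu_max
      m
    })
  })
}

#' Base medium over the shared carbon sources
#'
#' @param cfg A [generator_config()].
#' @param uptake Per-source uptake limit (default unrestricted, 1000).
#' @return An `fba_medium` allowing every generated carbon source.
#' @export
base_medium <- function(cfg, uptake = 1000) {
  src <- carbon_source_table(cfg)$sources
  make_medium(stats::setNames(rep(uptake, nrow(src)),
                              paste0("EX_", src$id)))
}

#' Generate an OTU relative-abundance table
#'
#' One OTU per bacterial genome. A configured fraction of the total
#' abundance in every sample is assigned to "low-CXL" genomes (cellulase
#' + xylanase gene count at most 2), emulating the exploiter-dominant
#' regime of evolved decomposer communities; per-sample columns sum to 1.
#'
#' @param cfg A [generator_config()].
#' @param profiles Profile table from [gen_genome_profiles()].
#' @return Long data frame (`otu_id`, `sample_id`, `rel_abundance`) with
#'   the OTU-to-genome map attached as attribute `otu_genome`.
#' @export
gen_otu_abundances <- function(cfg, profiles) {
  stopifnot(nrow(profiles) > 0)
  comp <- count_functional_groups(profiles)
  comp <- comp[comp$kingdom == "bacteria", ]
  if (!nrow(comp)) stop("no bacterial genomes in profiles", call. = FALSE)
  cx <- comp$d_c + comp$d_x
  low_cxl <- cx <= 2
  n <- nrow(comp)
  otu_ids <- sprintf("OTU%05d", seq_len(n))
  withr::with_seed(cfg$seed + 3L, {
    base_w <- stats::rlnorm(n, 0, 1)
    tabs <- lapply(seq_len(cfg$n_samples), function(s) {
      w <- base_w * stats::rlnorm(n, 0, 0.3)
      f <- cfg$exploiter_fraction
      if (any(low_cxl) && any(!low_cxl)) {
        w[low_cxl] <- w[low_cxl] / sum(w[low_cxl]) * f
        w[!low_cxl] <- w[!low_cxl] / sum(w[!low_cxl]) * (1 - f)
      } else {
        w <- w / sum(w)
      }
      data.frame(otu_id = otu_ids, sample_id = sprintf("S%02d", s),
                 rel_abundance = w / sum(w), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, tabs)
    attr(out, "otu_genome") <- data.frame(
      otu_id = otu_ids, genome_id = comp$genome_id, stringsAsFactors = FALSE
    )
    out
  })
}

#' Generate a homology hit table
#'
#' BLAST-style records (query, subject, identity, coverage, bitscore)
#' spanning the decision boundaries of the two-pass OTU-to-genome
#' matching rules: hits in the strict pass-1 region (identity >= 97,
#' coverage >= 95), in the relaxed pass-2-only band (95 <= identity <
#' 97), and in the reject region, plus secondary near-tie hits that
#' exercise the best-hit tie-breaking.
#'
#' @param cfg A [generator_config()].
#' @param profiles Profile table from [gen_genome_profiles()].
#' @return Data frame (`query_id`, `subject_id`, `subject_kingdom`,
#'   `identity`, `coverage`, `bitscore`).
#' @export
gen_hit_table <- function(cfg, profiles) {
  stopifnot(nrow(profiles) > 0)
  genomes <- unique(profiles$genome_id[profiles$kingdom == "bacteria"])
  n <- length(genomes)
  if (n == 0) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      subject_kingdom = character(0), identity = numeric(0),
                      coverage = numeric(0), bitscore = numeric(0)))
  }
  otu_ids <- sprintf("OTU%05d", seq_len(n))
  withr::with_seed(cfg$seed + 4L, {
    region <- sample(c("pass1", "pass2", "reject"), n, replace = TRUE,
                     prob = c(0.7, 0.15, 0.15))
    ## pin the first rows to the decision boundaries
    region[seq_len(min(3, n))] <- c("pass1", "pass2", "reject")[seq_len(min(3, n))]
    identity <- numeric(n)
    coverage <- numeric(n)
    identity[region == "pass1"] <- stats::runif(sum(region == "pass1"), 97, 99.9)
    coverage[region == "pass1"] <- stats::runif(sum(region == "pass1"), 95, 99.5)
    identity[region == "pass2"] <- stats::runif(sum(region == "pass2"), 95, 96.99)
    coverage[region == "pass2"] <- stats::runif(sum(region == "pass2"), 95, 99.5)
    nrej <- sum(region == "reject")
    low_id <- stats::runif(nrej) < 0.5
    identity[region == "reject"] <- ifelse(low_id,
                                           stats::runif(nrej, 85, 94.9),
                                           stats::runif(nrej, 96, 98))
    coverage[region == "reject"] <- ifelse(low_id,
                                           stats::runif(nrej, 80, 99),
                                           stats::runif(nrej, 80, 94.9))
    bitscore <- identity * 10 + stats::rnorm(n, 0, 5)
    hits <- data.frame(
      query_id = otu_ids, subject_id = genomes,
      subject_kingdom = "bacteria", identity = round(identity, 2),
      coverage = round(coverage, 2), bitscore = round(pmax(bitscore, 1), 1),
      stringsAsFactors = FALSE
    )
    ## secondary decoy hits against other genomes, some near-ties
    n_decoy <- max(0L, round(0.5 * n))
    if (n_decoy > 0 && n > 1) {
      di <- sample(n, n_decoy)
      decoy <- data.frame(
        query_id = otu_ids[di],
        subject_id = genomes[(match(otu_ids[di], otu_ids) %% n) + 1L],
        subject_kingdom = "bacteria",
        identity = round(pmax(85, hits$identity[di] -
                                stats::runif(n_decoy, 0.1, 3)), 2),
        coverage = round(pmin(99.5, pmax(80, hits$coverage[di] +
                                           stats::rnorm(n_decoy, 0, 2))), 2),
        bitscore = round(pmax(1, hits$bitscore[di] -
                                stats::runif(n_decoy, 1, 30)), 1),
        stringsAsFactors = FALSE
      )
      hits <- rbind(hits, decoy)
    }
    rownames(hits) <- NULL
    hits[order(hits$query_id, -hits$bitscore), ]
  })
}

#' Generate enzyme-group expression records
#'
#' TPM records per gene and sample, labelled by taxon and enzyme group,
#' emulating the observed division of expression: fungi dominate the
#' residue-attacking (CXL) groups while bacteria hold a large share of
#' OH+PBH expression.
#'
#' @param cfg A [generator_config()].
#' @param genes_per_cell Genes simulated per taxon x enzyme-group cell.
#' @return Data frame (`gene_id`, `sample_id`, `tpm`, `taxon`,
#'   `enzyme_group`).
#' @export
gen_expression_records <- function(cfg, genes_per_cell = 20) {
  groups <- c("cellulase", "xylanase", "ligninolytic", "oh_pbh")
  taxa <- c("fungi", "bacteria", "other")
  ## mean TPM per gene for each taxon x group cell
  mean_tpm <- rbind(
    fungi    = c(cellulase = 40, xylanase = 30, ligninolytic = 25, oh_pbh = 15),
    bacteria = c(cellulase = 1.5, xylanase = 1.5, ligninolytic = 1, oh_pbh = 15),
    other    = c(cellulase = 2, xylanase = 1.5, ligninolytic = 1, oh_pbh = 2)
  )
  withr::with_seed(cfg$seed + 5L, {
    rows <- list()
    gi <- 0L
    for (tx in taxa) {
      for (grp in groups) {
        for (g in seq_len(genes_per_cell)) {
          gi <- gi + 1L
          tpm <- stats::rlnorm(cfg$n_samples,
                               log(mean_tpm[tx, grp]) - 0.5, 1)
          rows[[gi]] <- data.frame(
            gene_id = sprintf("gene%05d", gi),
            sample_id = sprintf("S%02d", seq_len(cfg$n_samples)),
            tpm = round(tpm, 3), taxon = tx, enzyme_group = grp,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate a full synthetic study bundle
#'
#' Runs every generator under one config: CAZyme profiles, toy metabolic
#' models, an OTU abundance table, a homology hit table, and expression
#' records, with cross-consistent identifiers (every OTU with a hit maps
#' to a generated genome).
#'
#' @param cfg A [generator_config()].
#' @return List with elements `profiles`, `models`, `abundances`, `hits`,
#'   `expression`, and `carbon_sources`.
#' @export
gen_synthetic_bundle <- function(cfg) {
  profiles <- gen_genome_profiles(cfg)
  list(
    profiles = profiles,
    models = gen_toy_models(cfg),
    abundances = gen_otu_abundances(cfg, profiles),
    hits = gen_hit_table(cfg, profiles),
    expression = gen_expression_records(cfg),
    carbon_sources = carbon_source_table(cfg)
  )
}
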