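#' PDI weight vector
#'
#' Weights of the seven terms of the plant residue decomposition index:
#' cellulase and xylanase gene counts (30% each), ligninolytic gene count
#' (5%), OH+PBH gene count (10%), all non-GT CAZyme genes (10%),
#' distinct cellulase/xylanase/OH+PBH families (10%), and distinct non-GT
#' families (5%). Cellulase and xylanase carry the highest weights because
#' cellulose and xylan are the dominant residue polysaccharides;
#' ligninolytic enzymes carry the lowest because lignin breakdown releases
#' little usable carbon.
#'
#' @return Named numeric vector summing to 1.
#' @export
pdi_weights <- function() {
  c(d_c = 0.30, d_x = 0.30, d_l = 0.05, d_op = 0.10,
    d_gc = 0.10, d_f = 0.10, d_d = 0.05)
}

.pdi_terms <- c("d_c", "d_x", "d_l", "d_op", "d_gc", "d_f", "d_d")

#' Count CAZyme functional groups per genome
#'
#' Reduces a long profile table to the seven per-genome quantities that
#' enter the PDI: gene counts of cellulases (`d_c`), xylanases (`d_x`),
#' ligninolytic enzymes (`d_l`), OH+PBH (`d_op`), all non-GT CAZymes
#' (`d_gc`); and family diversities: distinct cellulase, xylanase and
#' OH+PBH families present (`d_f`) and distinct non-GT families present
#' (`d_d`). Ligninolytic families contribute to `d_l` and `d_d` but are
#' not part of the `d_f` trio.
#'
#' @param profiles Data frame with columns `genome_id`, `kingdom`,
#'   `family`, `count` (one row per genome x family; zero counts allowed).
#' @param catalog Catalog list from [cazyme_catalog()].
#' @return Data frame with one row per genome: `genome_id`, `kingdom`,
#'   and the seven term columns.
#' @examples
#' p <- data.frame(genome_id = "g1", kingdom = "bacteria",
#'                 family = c("GH7", "GH10", "GT2"), count = c(3, 2, 5))
#' count_functional_groups(p)
#' @export
count_functional_groups <- function(profiles, catalog = cazyme_catalog()) {
  stopifnot(all(c("genome_id", "kingdom", "family", "count") %in% names(profiles)))
  if (any(profiles$count < 0)) stop("negative CAZyme counts", call. = FALSE)
  grp <- classify_family(profiles$family, catalog)
  gid <- factor(profiles$genome_id, levels = unique(profiles$genome_id))
  cnt <- profiles$count
  pres <- cnt > 0

  sum_by <- function(mask) {
    v <- vapply(split(cnt[mask], gid[mask], drop = FALSE), sum, numeric(1))
    v[levels(gid)]
  }
  div_by <- function(mask) {
    v <- vapply(
      split(profiles$family[mask & pres], gid[mask & pres], drop = FALSE),
      function(f) length(unique(f)), numeric(1)
    )
    v[levels(gid)]
  }

  non_gt <- grp != "gt"
  out <- data.frame(
    genome_id = levels(gid),
    kingdom = profiles$kingdom[match(levels(gid), as.character(gid))],
    d_c  = sum_by(grp == "cellulase"),
    d_x  = sum_by(grp == "xylanase"),
    d_l  = sum_by(grp == "ligninolytic"),
    d_op = sum_by(grp == "oh_pbh"),
    d_gc = sum_by(non_gt),
    d_f  = div_by(grp %in% c("cellulase", "xylanase", "oh_pbh")),
    d_d  = div_by(non_gt),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out[is.na(out)] <- 0
  out
}

#' Plant residue decomposition index
#'
#' Pool-normalized weighted score of a genome's degradative repertoire:
#' for genome i, `pdi_i = sum_k w_k * D_{k,i} / T_k`, where the `D` terms
#' are the outputs of [count_functional_groups()], `T_k` is the pool sum
#' of term k over all genomes scored together, and the weights `w` are
#' [pdi_weights()]. Because each term is normalized by its pool total,
#' PDI values over a pool sum to exactly 1.
#'
#' A pool total of zero for some term would make that term's ratio
#' undefined; such a term is defined to contribute 0 for every genome
#' (with a warning), which preserves the sum invariant on degenerate
#' pools.
#'
#' @param profiles Long profile data frame (see
#'   [count_functional_groups()]) or a precomputed term table carrying the
#'   seven `d_*` columns.
#' @param catalog Catalog list from [cazyme_catalog()].
#' @return Data frame of per-genome terms plus a `pdi` column; pool totals
#'   are attached as attribute `totals`.
#' @examples
#' p <- data.frame(
#'   genome_id = rep(c("a", "b"), each = 2), kingdom = "bacteria",
#'   family = rep(c("GH7", "GH1"), 2), count = c(3, 1, 1, 4)
#' )
#' compute_pdi(p)
#' @export
compute_pdi <- function(profiles, catalog = cazyme_catalog()) {
  comp <- if (all(.pdi_terms %in% names(profiles))) profiles
          else count_functional_groups(profiles, catalog)
  if (nrow(comp) == 0L) stop("empty genome pool", call. = FALSE)
  w <- pdi_weights()
  totals <- colSums(comp[.pdi_terms])
  if (any(totals == 0)) {
    warning(
      "zero pool total for term(s) ",
      paste(.pdi_terms[totals == 0], collapse = ", "),
      "; these terms contribute 0", call. = FALSE
    )
  }
  pdi <- rep(0, nrow(comp))
  for (k in .pdi_terms) {
    if (totals[[k]] > 0) pdi <- pdi + w[[k]] * comp[[k]] / totals[[k]]
  }
  comp$pdi <- pdi
  attr(comp, "totals") <- totals
  comp
}

#' Fraction of PDI values in the enriched upper region
#'
#' Two threshold conventions are supported:
#' * `semi_range`: fraction of values strictly exceeding
#'   `min + (max - min) / 2` (the semi-range line). When all values are
#'   equal the range is 0 and the fraction is 0.
#' * `pct_of_max`: fraction of values at or above `pct * max`.
#'
#' @param pdis Numeric vector of at least two PDI values.
#' @param mode `"semi_range"` or `"pct_of_max"`.
#' @param pct Fraction of the maximum used by the `pct_of_max` mode.
#' @return Fraction in `[0, 1]`.
#' @examples
#' pdi_enrichment(0:10, "semi_range")          # 5/11
#' pdi_enrichment(c(1, 10), "pct_of_max", 0.2) # 1/2
#' @export
pdi_enrichment <- function(pdis, mode = c("semi_range", "pct_of_max"),
                           pct = 0.2) {
  mode <- match.arg(mode)
  if (length(pdis) < 2L) stop("need at least two values", call. = FALSE)
  if (mode == "semi_range") {
    rng <- max(pdis) - min(pdis)
    if (rng == 0) return(0)
    mean(pdis > min(pdis) + rng / 2)
  } else {
    mean(pdis >= pct * max(pdis))
  }
}

#' Ratio of product-consuming to residue-attacking gene counts
#'
#' `(OHs + PBHs) / CXLs`, i.e. `d_op / (d_c + d_x + d_l)`. When a genome
#' carries no CXL genes the ratio is undefined and `NA` is returned, so
#' such genomes drop out of group means.
#'
#' @param components Data frame with columns `d_c`, `d_x`, `d_l`, `d_op`
#'   (e.g. from [count_functional_groups()]).
#' @return Numeric vector; `NA` where the CXL sum is 0 (except that
#'   `0 / 0` with `d_op = 0` is also `NA`).
#' @export
ohpbh_cxl_ratio <- function(components) {
  cxl <- components$d_c + components$d_x + components$d_l
  ifelse(cxl > 0, components$d_op / cxl, NA_real_)
}

#' Classify taxa as exploiters, decomposers, or neither
#'
#' Two classification schemes are supported. The `observational` scheme
#' combines the cellulase+xylanase gene count of a taxon's matched genome
#' with its mean relative abundance: exploiters have at most 2 such genes
#' and abundance of at least 1%; decomposers have at least 5 genes and
#' abundance of at most 0.1 permille; all other taxa are `unclassified`.
#' The `synthetic_community` scheme uses gene counts alone: 0 genes is an
#' exploiter, more than 2 a decomposer, and 1 or 2 an `intermediate`
#' strain.
#'
#' @param cx_gene_count Integer vector of cellulase+xylanase gene counts.
#' @param abundance Numeric vector of relative abundances in `[0, 1]`
#'   (required by the observational scheme).
#' @param scheme `"observational"` or `"synthetic_community"`.
#' @return Character vector of roles.
#' @examples
#' classify_trophic_role(0, 0.03, "observational")    # exploiter
#' classify_trophic_role(2, scheme = "synthetic_community") # intermediate
#' @export
classify_trophic_role <- function(cx_gene_count, abundance = NULL,
                                  scheme = c("observational",
                                             "synthetic_community")) {
  scheme <- match.arg(scheme)
  if (any(cx_gene_count < 0)) stop("negative gene counts", call. = FALSE)
  if (scheme == "observational") {
    if (is.null(abundance)) {
      stop("the observational scheme requires `abundance`", call. = FALSE)
    }
    if (any(abundance < 0 | abundance > 1)) {
      stop("abundance must lie in [0, 1]", call. = FALSE)
    }
    out <- rep("unclassified", length(cx_gene_count))
    out[cx_gene_count <= 2 & abundance >= 0.01] <- "exploiter"
    out[cx_gene_count >= 5 & abundance <= 1e-4] <- "decomposer"
  } else {
    out <- rep("decomposer", length(cx_gene_count))
    out[cx_gene_count == 0] <- "exploiter"
    out[cx_gene_count %in% c(1, 2)] <- "intermediate"
  }
  out
}
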