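#' Read a BLAST-style tabular hit file
#'
#' Accepts either the package's headered TSV (columns `query_id`,
#' `subject_id`, `identity`, `coverage`, `bitscore`, optionally
#' `subject_kingdom`) or a headerless outfmt-6-like file whose first
#' columns are query, subject, identity; in that case `coverage` and
#' `bitscore` must be given as column indices.
#'
#' @param path File path.
#' @param coverage_col,bitscore_col Column indices used for headerless
#'   input (defaults follow qcovs-extended outfmt 6).
#' @return Hit table data frame.
#' @export
read_hit_table <- function(path, coverage_col = 13, bitscore_col = 12) {
  first <- readLines(path, n = 1)
  if (grepl("query_id", first, fixed = TRUE)) {
    return(utils::read.delim(path, stringsAsFactors = FALSE))
  }
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(
    query_id = raw[[1]], subject_id = raw[[2]], identity = raw[[3]],
    coverage = raw[[coverage_col]], bitscore = raw[[bitscore_col]],
    stringsAsFactors = FALSE
  )
}

.best_hit_order <- function(hits) {
  order(hits$query_id, -hits$identity, -hits$coverage, -hits$bitscore,
        hits$subject_id)
}

#' Two-pass OTU-to-genome matching
#'
#' Pass 1 requires at least 97% identity and 95% query coverage; queries
#' left unmatched are retried in pass 2 with identity relaxed to 95%
#' (coverage unchanged). For each query exactly one genome is retained -
#' the highest-similarity hit, with ties broken by identity, then
#' coverage, then bitscore, then lexicographic subject id. Pass-1
#' matches are never displaced by pass-2 candidates; a genome may serve
#' several queries.
#'
#' @param hits Hit table with columns `query_id`, `subject_id`,
#'   `identity`, `coverage`, `bitscore`.
#' @param identity_strict,identity_relaxed,min_coverage Thresholds in
#'   percent.
#' @return Data frame (`otu_id`, `genome_id`, `pass`); unmatched queries
#'   are absent.
#' @export
match_otus_to_genomes <- function(hits, identity_strict = 97,
                                  identity_relaxed = 95,
                                  min_coverage = 95) {
  pick_best <- function(h, pass) {
    if (!nrow(h)) {
      return(data.frame(otu_id = character(0), genome_id = character(0),
                        pass = integer(0), stringsAsFactors = FALSE))
    }
    h <- h[.best_hit_order(h), ]
    h <- h[!duplicated(h$query_id), ]
    data.frame(otu_id = h$query_id, genome_id = h$subject_id, pass = pass,
               stringsAsFactors = FALSE)
  }
  p1 <- pick_best(hits[hits$identity >= identity_strict &
                         hits$coverage >= min_coverage, ], 1L)
  rest <- hits[!hits$query_id %in% p1$otu_id &
                 hits$identity >= identity_relaxed &
                 hits$coverage >= min_coverage, ]
  p2 <- pick_best(rest, 2L)
  out <- rbind(p1, p2)
  out <- out[order(out$otu_id), ]
  rownames(out) <- NULL
  out
}

#' Kingdom assignment by bitscore-weighted vote
#'
#' For the hits of one gene, retains every hit whose bitscore is at
#' least 95% of the best bitscore and assigns the kingdom carried by a
#' strict majority (over 50%) of the retained hits; exact ties and empty
#' hit sets are `unclassified`.
#'
#' @param bitscore Numeric vector of hit bitscores for one gene.
#' @param kingdom Character vector of subject kingdoms (e.g. `"fungi"`,
#'   `"bacteria"`, `"other"`), same length.
#' @param retain_frac Bitscore retention fraction (default 0.95).
#' @return A single kingdom label or `"unclassified"`.
#' @export
taxonomic_vote <- function(bitscore, kingdom, retain_frac = 0.95) {
  stopifnot(length(bitscore) == length(kingdom))
  if (!length(bitscore)) return("unclassified")
  keep <- bitscore >= retain_frac * max(bitscore)
  tab <- table(kingdom[keep])
  top <- names(tab)[which.max(tab)]
  if (tab[[top]] > sum(tab) / 2) top else "unclassified"
}

#' Vote kingdoms for every query in a hit table
#'
#' Applies [taxonomic_vote()] per `query_id` using the
#' `subject_kingdom` column.
#'
#' @param hits Hit table with `query_id`, `bitscore`, `subject_kingdom`.
#' @return Data frame (`query_id`, `taxon`).
#' @export
taxonomic_vote_table <- function(hits) {
  stopifnot("subject_kingdom" %in% names(hits))
  sp <- split(hits, hits$query_id)
  data.frame(
    query_id = names(sp),
    taxon = vapply(sp, function(h) {
      taxonomic_vote(h$bitscore, h$subject_kingdom)
    }, character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Filter CAZyme-to-genome assignments at the 70/70 criterion
#'
#' Keeps records with at least 70% sequence identity and 70% alignment
#' coverage, then retains one best hit per query (highest bitscore, ties
#' broken by higher identity, then coverage, then subject id). The
#' operation is idempotent.
#'
#' @param hits Hit table.
#' @param min_identity,min_coverage Thresholds in percent (default 70).
#' @return Filtered hit table, one row per surviving query.
#' @export
filter_cazyme_hits <- function(hits, min_identity = 70, min_coverage = 70) {
  h <- hits[hits$identity >= min_identity & hits$coverage >= min_coverage, ]
  if (!nrow(h)) return(h)
  h <- h[order(h$query_id, -h$bitscore, -h$identity, -h$coverage,
               h$subject_id), ]
  h <- h[!duplicated(h$query_id), ]
  rownames(h) <- NULL
  h
}

#' Per-sample enzyme-group expression proportions by taxon
#'
#' Sums TPM over all genes within each (sample, taxon, enzyme group)
#' cell and expresses each taxon's sum as a proportion of the group
#' total in that sample, so proportions within a (sample, group) pair
#' sum to 1. Groups with zero total expression in a sample get `NA`
#' proportions.
#'
#' @param records Expression data frame with columns `gene_id`,
#'   `sample_id`, `tpm`, `taxon`, `enzyme_group`.
#' @return Data frame (`sample_id`, `enzyme_group`, `taxon`, `tpm_sum`,
#'   `proportion`).
#' @export
group_expression_proportions <- function(records) {
  stopifnot(all(c("sample_id", "tpm", "taxon", "enzyme_group") %in%
                  names(records)))
  if (any(records$tpm < 0)) stop("negative TPM values", call. = FALSE)
  agg <- stats::aggregate(tpm ~ sample_id + enzyme_group + taxon,
                          data = records, FUN = sum)
  names(agg)[names(agg) == "tpm"] <- "tpm_sum"
  totals <- stats::aggregate(tpm_sum ~ sample_id + enzyme_group, data = agg,
                             FUN = sum)
  names(totals)[names(totals) == "tpm_sum"] <- "group_total"
  out <- merge(agg, totals, by = c("sample_id", "enzyme_group"))
  out$proportion <- ifelse(out$group_total > 0,
                           out$tpm_sum / out$group_total, NA_real_)
  out$group_total <- NULL
  out <- out[order(out$sample_id, out$enzyme_group, out$taxon), ]
  rownames(out) <- NULL
  out
}

#' Residue complexity scalar
#'
#' Complexity of a plant residue is defined as the combined mass
#' fraction of its two degradation-resistant polymers, lignin and
#' cellulose. The formula is pluggable for users who prefer a different
#' composite.
#'
#' @param cellulose,hemicellulose,lignin Mass fractions in `[0, 1]`;
#'   their sum may not exceed 1.
#' @param formula Function of `(cellulose, hemicellulose, lignin)`
#'   returning the scalar; the default is `cellulose + lignin`.
#' @return Complexity value(s) in `[0, 1]`.
#' @examples
#' residue_complexity(0.40, 0.30, 0.20)  # 0.60
#' @export
residue_complexity <- function(cellulose, hemicellulose, lignin,
                               formula = function(c, h, l) c + l) {
  frac <- c(cellulose, hemicellulose, lignin)
  if (any(frac < 0 | frac > 1)) {
    stop("mass fractions must lie in [0, 1]", call. = FALSE)
  }
  if (any(cellulose + hemicellulose + lignin > 1 + 1e-9)) {
    stop("mass fractions sum to more than 1", call. = FALSE)
  }
  formula(cellulose, hemicellulose, lignin)
}

#' Simple linear association
#'
#' Ordinary least squares of `y` on a single predictor `x`, returning
#' the coefficient of determination, the two-sided p-value of the slope,
#' and the slope itself.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return List with `r_squared`, `p_value`, `slope`.
#' @export
linear_association <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("zero variance in x", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(
    r_squared = sm$r.squared,
    p_value = if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_,
    slope = stats::coef(fit)[["x"]]
  )
}
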