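hit_row <- function(q, s, id, cov, bits = id * 10, kingdom = "bacteria") {
  data.frame(query_id = q, subject_id = s, subject_kingdom = kingdom,
             identity = id, coverage = cov, bitscore = bits,
             stringsAsFactors = FALSE)
}

test_that("two-pass matching applies the strict-then-relaxed thresholds", {
  hits <- rbind(
    hit_row("o1", "g1", 98, 96),    # pass 1
    hit_row("o2", "g2", 96, 96),    # pass 2 only
    hit_row("o3", "g3", 94, 96),    # rejected: identity
    hit_row("o4", "g4", 98, 94)     # rejected: coverage
  )
  m <- match_otus_to_genomes(hits)
  expect_equal(m$otu_id, c("o1", "o2"))
  expect_equal(m$pass, c(1L, 2L))
  expect_equal(m$genome_id, c("g1", "g2"))
})

test_that("the single highest-similarity genome is retained per query", {
  hits <- rbind(
    hit_row("o1", "gA", 98, 96),
    hit_row("o1", "gB", 97.5, 99)
  )
  m <- match_otus_to_genomes(hits)
  expect_equal(nrow(m), 1)
  expect_equal(m$genome_id, "gA")
  # identity tie broken by coverage, then bitscore, then subject id
  tie <- rbind(hit_row("o2", "gC", 98, 95, bits = 900),
               hit_row("o2", "gD", 98, 95, bits = 950),
               hit_row("o2", "gB", 98, 97, bits = 800))
  expect_equal(match_otus_to_genomes(tie)$genome_id, "gB")
  tie2 <- rbind(hit_row("o3", "gZ", 98, 95, bits = 900),
                hit_row("o3", "gY", 98, 95, bits = 900))
  expect_equal(match_otus_to_genomes(tie2)$genome_id, "gY")
})

test_that("pass-1 matches are never displaced by pass-2 candidates", {
  hits <- rbind(
    hit_row("o1", "g_strict", 97, 95),       # qualifies in pass 1
    hit_row("o1", "g_better", 96.5, 99.9)    # higher coverage, pass-2 band
  )
  m <- match_otus_to_genomes(hits)
  expect_equal(m$genome_id, "g_strict")
  expect_equal(m$pass, 1L)
})

test_that("matching agrees with rule enumeration on a threshold grid", {
  ids <- c(94, 94.9, 95, 96.9, 97, 99)
  covs <- c(90, 94.9, 95, 99)
  grid <- expand.grid(identity = ids, coverage = covs)
  hits <- data.frame(query_id = sprintf("q%02d", seq_len(nrow(grid))),
                     subject_id = "g", identity = grid$identity,
                     coverage = grid$coverage, bitscore = 100)
  m <- match_otus_to_genomes(hits)
  want_pass <- ifelse(grid$coverage < 95 | grid$identity < 95, NA,
                      ifelse(grid$identity >= 97, 1L, 2L))
  got_pass <- m$pass[match(hits$query_id, m$otu_id)]
  expect_equal(got_pass, unname(want_pass))
})

test_that("kingdom vote retains near-best bitscores and needs a strict majority", {
  expect_equal(taxonomic_vote(c(100, 96, 90), c("fungi", "fungi", "bacteria")),
               "fungi")
  # 50/50 among retained entries is unclassified
  expect_equal(taxonomic_vote(c(100, 99), c("fungi", "bacteria")),
               "unclassified")
  expect_equal(taxonomic_vote(50, "bacteria"), "bacteria")
  expect_equal(taxonomic_vote(numeric(0), character(0)), "unclassified")
  # invariant to order and duplication of the full hit set
  b <- c(100, 97, 96, 80)
  k <- c("fungi", "bacteria", "fungi", "bacteria")
  v <- taxonomic_vote(b, k)
  o <- sample(length(b))
  expect_equal(taxonomic_vote(b[o], k[o]), v)
  expect_equal(taxonomic_vote(rep(b, 2), rep(k, 2)), v)
  # exhaustive small grid against direct rule enumeration
  for (n_f in 0:3) for (n_b in 0:3) {
    if (n_f + n_b == 0) next
    bits <- rep(100, n_f + n_b)
    kg <- c(rep("fungi", n_f), rep("bacteria", n_b))
    want <- if (n_f > (n_f + n_b) / 2) "fungi"
            else if (n_b > (n_f + n_b) / 2) "bacteria" else "unclassified"
    expect_equal(taxonomic_vote(bits, kg), want)
  }
})

test_that("vote table applies the rule per query", {
  hits <- rbind(hit_row("g1", "s1", 90, 90, bits = 100, kingdom = "fungi"),
                hit_row("g1", "s2", 90, 90, bits = 96, kingdom = "fungi"),
                hit_row("g1", "s3", 90, 90, bits = 90, kingdom = "bacteria"),
                hit_row("g2", "s4", 90, 90, bits = 50, kingdom = "bacteria"))
  v <- taxonomic_vote_table(hits)
  expect_equal(v$taxon[v$query_id == "g1"], "fungi")
  expect_equal(v$taxon[v$query_id == "g2"], "bacteria")
})

test_that("the 70/70 filter keeps one best hit per query and is idempotent", {
  hits <- rbind(
    hit_row("q1", "s1", 75, 75, bits = 200),
    hit_row("q1", "s2", 95, 95, bits = 150),
    hit_row("q2", "s3", 65, 95, bits = 300),   # identity fails
    hit_row("q3", "s4", 95, 65, bits = 300),   # coverage fails
    hit_row("q4", "s5", 70, 70, bits = 100)    # boundary kept
  )
  f <- filter_cazyme_hits(hits)
  expect_equal(sort(f$query_id), c("q1", "q4"))
  expect_equal(f$subject_id[f$query_id == "q1"], "s1")  # best bitscore wins
  expect_identical(filter_cazyme_hits(f), f)
  # bitscore tie -> higher identity
  tie <- rbind(hit_row("q5", "sA", 80, 80, bits = 100),
               hit_row("q5", "sB", 90, 80, bits = 100))
  expect_equal(filter_cazyme_hits(tie)$subject_id, "sB")
})

test_that("expression proportions sum to one within each sample and group", {
  rec <- data.frame(
    gene_id = sprintf("g%d", 1:4), sample_id = "s1",
    tpm = c(90, 10, 2, 3),
    taxon = c("fungi", "bacteria", "fungi", "bacteria"),
    enzyme_group = c("cellulase", "cellulase", "oh_pbh", "oh_pbh")
  )
  pr <- group_expression_proportions(rec)
  expect_equal(pr$proportion[pr$enzyme_group == "cellulase" &
                               pr$taxon == "fungi"], 0.9)
  sums <- tapply(pr$proportion, paste(pr$sample_id, pr$enzyme_group), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # three taxa 2/3/5
  rec3 <- data.frame(gene_id = c("a", "b", "c"), sample_id = "s1",
                     tpm = c(2, 3, 5), taxon = c("fungi", "bacteria", "other"),
                     enzyme_group = "xylanase")
  expect_equal(sort(group_expression_proportions(rec3)$proportion),
               c(0.2, 0.3, 0.5))
})

test_that("residue complexity is the lignin plus cellulose fraction", {
  expect_equal(residue_complexity(0.40, 0.30, 0.20), 0.60)
  expect_equal(residue_complexity(0, 1, 0), 0)
  expect_equal(residue_complexity(0, 0, 1), 1)
  expect_error(residue_complexity(0.6, 0.3, 0.2), "sum")
  # the composite is pluggable
  expect_equal(residue_complexity(0.4, 0.2, 0.2,
                                  formula = function(c, h, l) l / (c + h + l)),
               0.25)
})

test_that("linear association reproduces closed-form OLS", {
  r <- linear_association(c(1, 2, 3), c(1, 3, 2))
  expect_equal(r$r_squared, 0.25, tolerance = 1e-12)
  expect_equal(r$slope, 0.5, tolerance = 1e-12)
  exact <- suppressWarnings(linear_association(1:10, 2 * (1:10)))
  expect_equal(exact$r_squared, 1)
  expect_error(linear_association(rep(1, 5), 1:5), "variance")
})

test_that("hit tables round-trip through the TSV reader", {
  hits <- rbind(hit_row("q1", "s1", 97.5, 96.2), hit_row("q2", "s2", 91, 88))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(hits, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_hit_table(tmp)
  expect_equal(back, hits)
  # headerless outfmt-6-like input
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  out6 <- data.frame(hits$query_id, hits$subject_id, hits$identity,
                     len = 100, mm = 1, go = 0, qs = 1, qe = 100, ss = 1,
                     se = 100, ev = 1e-50, bits = hits$bitscore,
                     qcov = hits$coverage)
  utils::write.table(out6, tmp2, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  back6 <- read_hit_table(tmp2)
  expect_equal(back6$identity, hits$identity)
  expect_equal(back6$coverage, hits$coverage)
  expect_equal(back6$bitscore, hits$bitscore)
})
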