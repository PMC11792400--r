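test_that("functional group counting applies the group definitions", {
  p <- data.frame(genome_id = "g1", kingdom = "bacteria",
                  family = c("GH7", "GH10", "GT2"), count = c(3, 2, 5))
  cc <- count_functional_groups(p)
  expect_equal(cc$d_c, 3)
  expect_equal(cc$d_x, 2)
  expect_equal(cc$d_l, 0)
  expect_equal(cc$d_op, 0)
  expect_equal(cc$d_gc, 5)   # GT2 excluded from the non-GT gene count
  expect_equal(cc$d_f, 2)
  expect_equal(cc$d_d, 2)
})

test_that("ligninolytic families count in d_l and d_d but not d_f", {
  p <- data.frame(genome_id = "g1", kingdom = "fungi",
                  family = "AA2", count = 1)
  cc <- count_functional_groups(p)
  expect_equal(cc$d_l, 1)
  expect_equal(cc$d_f, 0)
  expect_equal(cc$d_d, 1)
})

test_that("zero and empty profiles give all-zero terms", {
  p <- data.frame(genome_id = c("g1", "g2"), kingdom = "bacteria",
                  family = "GH1", count = c(0, 0))
  cc <- count_functional_groups(p)
  expect_equal(unlist(cc[, c("d_c", "d_x", "d_l", "d_op", "d_gc",
                             "d_f", "d_d")]),
               rep(0, 14), ignore_attr = TRUE)
})

test_that("PDI matches an independent transcription on a worked 3-genome pool", {
  terms <- data.frame(
    genome_id = c("A", "B", "C"), kingdom = "bacteria",
    d_c = c(6, 2, 0), d_x = c(2, 2, 0), d_l = c(1, 0, 1),
    d_op = c(4, 8, 0), d_gc = c(20, 15, 3), d_f = c(5, 4, 0),
    d_d = c(12, 10, 2)
  )
  res <- compute_pdi(terms)
  # hand arithmetic of the weighted pool-ratio sum for genome A
  expect_equal(res$pdi[1],
               0.30 * 6 / 8 + 0.30 * 2 / 4 + 0.05 * 1 / 2 + 0.10 * 4 / 12 +
                 0.10 * 20 / 38 + 0.10 * 5 / 9 + 0.05 * 12 / 24,
               tolerance = 1e-15)
  expect_equal(res$pdi, oracle_pdi(terms), tolerance = 1e-12)
  expect_equal(sum(res$pdi), 1, tolerance = 1e-12)
})

test_that("single-genome and identical-genome pools give the symmetric PDIs", {
  p <- data.frame(genome_id = "solo", kingdom = "fungi",
                  family = c("GH7", "GH10", "AA2", "GH1"),
                  count = c(2, 1, 1, 3))
  expect_equal(compute_pdi(p)$pdi, 1)
  p2 <- rbind(p, transform(p, genome_id = "twin"))
  expect_equal(compute_pdi(p2)$pdi, c(0.5, 0.5))
})

test_that("PDI normalization, scaling, and rank monotonicity hold on random pools", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    terms <- data.frame(
      genome_id = paste0("g", seq_len(n)), kingdom = "bacteria",
      d_c = rpois(n, 3), d_x = rpois(n, 2), d_l = rpois(n, 1),
      d_op = rpois(n, 8), d_gc = rpois(n, 20) + 1, d_f = rpois(n, 4),
      d_d = rpois(n, 10) + 1
    )
    res <- suppressWarnings(compute_pdi(terms))
    expect_equal(sum(res$pdi), 1, tolerance = 1e-12)
    # replicating every genome k times divides each pdi by k
    k <- 3
    rep_terms <- do.call(rbind, lapply(seq_len(k), function(i) {
      transform(terms, genome_id = paste0(genome_id, "_", i))
    }))
    res_k <- suppressWarnings(compute_pdi(rep_terms))
    expect_equal(res_k$pdi[seq_len(n)], res$pdi / k, tolerance = 1e-12)
    # raising one genome's d_c never lowers its rank among the others
    i <- sample(n, 1)
    bumped <- terms
    bumped$d_c[i] <- bumped$d_c[i] + 5
    r1 <- suppressWarnings(compute_pdi(terms))$pdi
    r2 <- suppressWarnings(compute_pdi(bumped))$pdi
    expect_gte(sum(r2[i] >= r2[-i]), sum(r1[i] >= r1[-i]))
  }
})

test_that("zero pool totals contribute nothing but keep the sum invariant", {
  terms <- data.frame(
    genome_id = c("a", "b"), kingdom = "bacteria",
    d_c = c(1, 3), d_x = c(0, 0), d_l = c(0, 0), d_op = c(2, 2),
    d_gc = c(3, 5), d_f = c(2, 2), d_d = c(3, 3)
  )
  expect_warning(res <- compute_pdi(terms), "zero pool total")
  expect_equal(sum(res$pdi), 1 - 0.30 - 0.05, tolerance = 1e-12)
})

test_that("enrichment fractions follow both threshold conventions", {
  expect_equal(pdi_enrichment(0:10, "semi_range"), 5 / 11)
  expect_equal(pdi_enrichment(rep(2, 5), "semi_range"), 0)
  expect_equal(pdi_enrichment(c(1, 10), "pct_of_max", 0.2), 1 / 2)
  expect_error(pdi_enrichment(1), "two values")
})

test_that("OH+PBH to CXL ratio guards the zero denominator", {
  comp <- data.frame(d_c = c(1, 0, 0), d_x = c(0, 0, 0), d_l = c(0, 0, 0),
                     d_op = c(18, 7, 0))
  r <- ohpbh_cxl_ratio(comp)
  expect_equal(r[1], 18)
  expect_true(is.na(r[2]))
  expect_true(is.na(r[3]))
})

test_that("trophic classification matches the threshold rules on a grid", {
  counts <- 0:8
  abunds <- c(0, 5e-5, 1e-4, 5e-4, 0.009, 0.01, 0.2, 1)
  grid <- expand.grid(count = counts, ab = abunds)
  got <- classify_trophic_role(grid$count, grid$ab, "observational")
  # enumeration oracle: direct restatement of the two rules
  want <- mapply(function(ct, ab) {
    if (ct <= 2 && ab >= 0.01) "exploiter"
    else if (ct >= 5 && ab <= 1e-4) "decomposer"
    else "unclassified"
  }, grid$count, grid$ab)
  expect_equal(got, unname(want))
  # roles are mutually exclusive and exhaustive
  expect_true(all(got %in% c("exploiter", "decomposer", "unclassified")))

  got_s <- classify_trophic_role(counts, scheme = "synthetic_community")
  want_s <- ifelse(counts == 0, "exploiter",
                   ifelse(counts <= 2, "intermediate", "decomposer"))
  expect_equal(got_s, want_s)
  expect_error(classify_trophic_role(1, 1.5, "observational"), "\\[0, 1\\]")
})
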