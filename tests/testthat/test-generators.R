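test_that("generators are pure functions of the config", {
  cfg <- small_test_config(seed = 42)
  b1 <- gen_synthetic_bundle(cfg)
  b2 <- gen_synthetic_bundle(cfg)
  expect_identical(b1$profiles, b2$profiles)
  expect_identical(b1$abundances, b2$abundances)
  expect_identical(b1$hits, b2$hits)
  expect_identical(b1$expression, b2$expression)
  expect_identical(lapply(b1$models, unclass), lapply(b2$models, unclass))
  # and the generator does not disturb the caller's RNG stream
  set.seed(7); x1 <- runif(1)
  set.seed(7); invisible(gen_genome_profiles(cfg)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("profile group means recover the configured means", {
  cfg <- generator_config(seed = 3, n_bacteria = 2000, n_fungi = 0)
  p <- gen_genome_profiles(cfg)
  comp <- count_functional_groups(p)
  n <- nrow(comp)
  expect_equal(n, 2000)
  means <- cfg$group_mean_counts$bacteria
  for (pair in list(c("d_c", "cellulase"), c("d_x", "xylanase"),
                    c("d_l", "ligninolytic"), c("d_op", "oh_pbh"))) {
    mu <- means[[pair[2]]]
    se <- sqrt(mu + mu^2 / cfg$dispersion) / sqrt(n)   # NB variance
    expect_lt(abs(mean(comp[[pair[1]]]) - mu), 3 * se)
  }
})

test_that("all-zero means give all-zero profiles", {
  zero <- list(
    bacteria = c(cellulase = 0, xylanase = 0, ligninolytic = 0,
                 oh_pbh = 0, gt = 0, other = 0),
    fungi = c(cellulase = 0, xylanase = 0, ligninolytic = 0,
              oh_pbh = 0, gt = 0, other = 0)
  )
  cfg <- generator_config(seed = 1, n_bacteria = 10, n_fungi = 5,
                          group_mean_counts = zero)
  p <- gen_genome_profiles(cfg)
  expect_equal(sum(p$count), 0)
  expect_equal(length(unique(p$genome_id)), 15)
  expect_error(generator_config(n_bacteria = 0, n_fungi = 0), "positive")
})

test_that("toy model niches hit the configured breadth exactly", {
  cfg <- generator_config(seed = 2, n_bacteria = 10, n_fungi = 0,
                          n_models = 4, n_carbon_sources = 12,
                          cub_range = c(5, 5))
  models <- gen_toy_models(cfg)
  src <- carbon_source_table(cfg)$sources$id
  for (m in models) {
    expect_equal(compute_cub(m, src), 5L)
  }
})

test_that("zero secretion fraction yields no non-CO2 secretion exchanges", {
  cfg <- generator_config(seed = 2, n_bacteria = 10, n_fungi = 0,
                          n_models = 4, n_carbon_sources = 10,
                          cub_range = c(3, 6), secretion_fraction = 0,
                          byproduct_use_prob = 0)
  for (m in gen_toy_models(cfg)) {
    ex <- m$rxns$id[m$rxns$is_exchange]
    expect_false(any(grepl("^EX_B", ex)))
    expect_true("EX_co2" %in% ex)
  }
})

test_that("abundance tables are normalized and exploiter-dominant", {
  cfg <- small_test_config(seed = 6, exploiter_fraction = 0.9)
  p <- gen_genome_profiles(cfg)
  ab <- gen_otu_abundances(cfg, p)
  sums <- tapply(ab$rel_abundance, ab$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # recount the share on low-CXL genomes from the emitted table
  comp <- count_functional_groups(p)
  map <- attr(ab, "otu_genome")
  cx <- with(comp, stats::setNames(d_c + d_x, genome_id))
  low <- map$otu_id[cx[map$genome_id] <= 2]
  share <- sum(ab$rel_abundance[ab$otu_id %in% low]) /
    length(unique(ab$sample_id))
  expect_gte(share, 0.85)
})

test_that("hit tables span the matching decision boundaries", {
  cfg <- small_test_config(seed = 8)
  p <- gen_genome_profiles(cfg)
  hits <- gen_hit_table(cfg, p)
  pass1 <- hits$identity >= 97 & hits$coverage >= 95
  pass2 <- hits$identity >= 95 & hits$identity < 97 & hits$coverage >= 95
  reject <- hits$identity < 95 | hits$coverage < 95
  expect_gt(sum(pass1), 0)
  expect_gt(sum(pass2), 0)
  expect_gt(sum(reject), 0)
  # empty-profile edge
  empty <- p[p$kingdom == "fungi", ]
  expect_equal(nrow(gen_hit_table(cfg, empty)), 0)
})

test_that("config invariants are validated", {
  expect_error(generator_config(cub_range = c(5, 40)), "cub_range")
  expect_error(generator_config(dispersion = 0), "dispersion")
  expect_error(generator_config(carbon_atoms_range = c(1, 4)), "carbon")
  expect_error(generator_config(secretion_fraction = 1.2), "fractions")
})
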