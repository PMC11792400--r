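test_that("community metric formulas reduce to their definitions", {
  # anac = mean N_i; cst = |union M_i|; ccse = growth-weighted mean CSE
  ind <- data.frame(model_id = c("a", "b"), growth_rate = c(1, 1),
                    n_absorbed = c(2L, 4L), cse = c(0.2, 0.4))
  attr(ind, "secretions") <- list(a = c(x = 1, y = 2), b = c(y = 1, z = 3))
  m <- community_metrics(ind, 10)
  expect_equal(m$anac, 3)
  expect_equal(m$cst, 3L)
  expect_equal(m$ccse, 0.3)
  # all growth zero: ccse defined as 0
  ind0 <- transform(ind, growth_rate = 0)
  attr(ind0, "secretions") <- attr(ind, "secretions")
  expect_equal(community_metrics(ind0, 1)$ccse, 0)
})

test_that("secretion efficiency is the carbon-weighted flux ratio", {
  carbon <- c(S = 6, X = 2, co2 = 1)
  expect_equal(cse(c(S = 10), c(X = 5), carbon), 1 / 6)
  expect_equal(cse(c(S = 10), numeric(0), carbon), 0)
  # CO2 is excluded from the numerator
  expect_equal(cse(c(S = 10), c(co2 = 60), carbon), 0)
  # boundary: secreted carbon equals absorbed carbon
  expect_equal(cse(c(S = 1), c(X = 3), carbon), 1)
  expect_true(is.na(cse(numeric(0), c(X = 1), carbon)))
})

test_that("growth-rate variability is the slope between adjacent levels", {
  m <- data.frame(flux_level = c(5, 10), mean_growth = c(2, 4))
  cg <- cgrv_profile(m)
  expect_equal(cg$cgrv, 0.4)
  m2 <- data.frame(flux_level = c(1, 5, 10), mean_growth = c(3, 3, 3))
  expect_equal(cgrv_profile(m2)$cgrv, c(0, 0))
  expect_error(cgrv_profile(data.frame(flux_level = c(1, 1),
                                       mean_growth = c(1, 2))), "duplicate")
})

test_that("individual simulation applies the secretion floor", {
  donor <- make_donor_model()
  med <- make_medium(c(EX_S = 1000))
  # at flux 0.005 the byproduct flux (0.005) is under the 0.01 floor
  ind_lo <- simulate_individuals(list(donor), med, 0.005)
  expect_equal(length(attr(ind_lo, "secretions")$donor), 0)
  ind_hi <- simulate_individuals(list(donor), med, 1)
  expect_equal(attr(ind_hi, "secretions")$donor, c(X = 1), tolerance = 1e-9)
})

test_that("pooled secretions are scaled proportionally onto the carbon cap", {
  # hand-built pass-1 state: uptake 10 of C6, secretion 4+4 of X (C2),
  # cse chosen so the cap is half the pooled carbon
  ind <- data.frame(model_id = c("a", "b"), growth_rate = c(1, 1),
                    n_absorbed = c(1L, 1L), cse = c(1 / 15, 1 / 15))
  attr(ind, "secretions") <- list(a = c(X = 4), b = c(X = 4))
  attr(ind, "uptakes") <- list(a = c(S = 10), b = c(S = 10))
  attr(ind, "carbon") <- c(S = 6, X = 2, co2 = 1)
  base <- make_medium(c(EX_S = 1000))
  cf <- build_crossfeed_medium(ind, base, 10)
  # pooled carbon 16, cap = (1/15) * 120 = 8 -> scale 1/2
  expect_equal(cf$cap, 8, tolerance = 1e-12)
  expect_equal(cf$scale, 0.5, tolerance = 1e-12)
  expect_equal(cf$pooled, c(X = 4), tolerance = 1e-12)
  expect_equal(unclass(cf$medium)[["EX_X"]], 4, tolerance = 1e-12)
  # below-cap pool is left unchanged
  ind2 <- ind
  ind2$cse <- c(0.5, 0.5)
  cf2 <- build_crossfeed_medium(ind2, base, 10)
  expect_equal(cf2$scale, 1)
  expect_equal(cf2$pooled, c(X = 8), tolerance = 1e-12)
  # zero community secretion efficiency adds no secreted sources
  ind3 <- ind
  ind3$cse <- c(0, 0)
  cf3 <- build_crossfeed_medium(ind3, base, 10)
  expect_equal(length(cf3$pooled), 0)
  expect_false("EX_X" %in% names(cf3$medium))
})

test_that("a donor feeds a consumer at limiting flux", {
  models <- list(make_donor_model(), make_consumer_model())
  med <- make_medium(c(EX_S = 1000))
  res <- simulate_with_crossfeeding(models, med, 1)
  # donor secretes X; the consumer picks it up and grows strictly faster
  expect_gt(res$growth_with[["consumer"]], res$growth_without[["consumer"]])
  expect_gte(res$rd, 0)
  # nobody loses from an enriched medium
  expect_true(all(res$growth_with >= res$growth_without - 1e-9))
  # the pooled-carbon cap holds post hoc
  carbon <- c(S = 6, X = 2, co2 = 1)
  pooled_carbon <- sum(res$pooled * carbon[names(res$pooled)])
  expect_lte(pooled_carbon, res$cap + 1e-9)
})

test_that("cross-feeding is a no-op when nothing is secreted", {
  m1 <- make_chain_model("c1", yield = 1, atoms = 3)
  m2 <- make_chain_model("c2", yield = 2, atoms = 3)
  med <- make_medium(c(EX_A = 1000))
  res <- simulate_with_crossfeeding(list(m1, m2), med, 5)
  expect_equal(length(res$pooled), 0)
  expect_identical(unname(res$growth_with), unname(res$growth_without))
  expect_equal(res$rd, 0)
})

test_that("relative divergence is the symmetric relative difference", {
  expect_equal(relative_divergence(c(1, 1), c(1, 1)), 0)
  expect_equal(relative_divergence(3, 1), 1)
  expect_equal(relative_divergence(2, 0), 2)
  expect_equal(relative_divergence(0, 0), 0)
})

test_that("trophic group comparison reports ratios and breadths", {
  cfg <- small_test_config(seed = 12)
  models <- gen_toy_models(cfg)
  ids <- vapply(models, function(m) m$model_id, character(1))
  roles <- data.frame(model_id = ids,
                      role = rep(c("decomposer", "exploiter"), length.out = length(ids)))
  med <- base_medium(cfg)
  cmp <- compare_trophic_groups(models, roles, med, c(0.1, 1000))
  expect_equal(nrow(cmp), 2)
  expect_true(all(cmp$growth_decomposer >= 0))
  # identical groups give unit ratio
  roles_same <- roles
  roles_same$role <- "decomposer"
  expect_error(compare_trophic_groups(models, roles_same, med, 1),
               "non-empty")
  # wider niches give larger mean breadth
  cfg_wide <- small_test_config(seed = 12, cub_range = c(9, 11))
  wide <- gen_toy_models(cfg_wide)
  all_models <- c(models, wide)
  all_ids <- vapply(all_models, function(m) m$model_id, character(1))
  all_roles <- data.frame(
    model_id = make.unique(all_ids),
    role = rep(c("exploiter", "decomposer"), each = length(models))
  )
  for (i in seq_along(all_models)) all_models[[i]]$model_id <- all_roles$model_id[i]
  cmp2 <- compare_trophic_groups(all_models, all_roles, med, 1)
  expect_gt(cmp2$cub_decomposer, cmp2$cub_exploiter)
})
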