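# Hand-built fixture models used by the FBA and community tests.

# Linear chain: EX_A -> conv (1 A -> yield BM + 1 co2) -> biomass.
make_chain_model <- function(id = "chain", yield = 1, atoms = 2,
                             biomass_coeff = 1, mu_max = 1000,
                             conv_cap = 1000) {
  metabolic_model(
    id,
    data.frame(id = c("A", "BM", "co2"), carbon_atoms = c(atoms, 1, 1)),
    list(
      list(id = "EX_A", stoich = c(A = -1), lb = -1000, ub = 1000,
           is_exchange = TRUE, is_biomass = FALSE),
      list(id = "conv", stoich = c(A = -1, BM = yield, co2 = atoms - yield),
           lb = 0, ub = conv_cap, is_exchange = FALSE, is_biomass = FALSE),
      list(id = "biomass", stoich = c(BM = -biomass_coeff), lb = 0,
           ub = mu_max, is_exchange = FALSE, is_biomass = TRUE),
      list(id = "EX_co2", stoich = c(co2 = -1), lb = 0, ub = 1000,
           is_exchange = TRUE, is_biomass = FALSE)
    )
  )
}

# Donor: growth on S obligatorily secretes byproduct X (C2).
make_donor_model <- function(id = "donor") {
  metabolic_model(
    id,
    data.frame(id = c("S", "X", "BM", "co2"), carbon_atoms = c(6, 2, 1, 1)),
    list(
      list(id = "EX_S", stoich = c(S = -1), lb = -1000, ub = 1000,
           is_exchange = TRUE, is_biomass = FALSE),
      list(id = "conv", stoich = c(S = -1, BM = 3, co2 = 1, X = 1),
           lb = 0, ub = 1000, is_exchange = FALSE, is_biomass = FALSE),
      list(id = "biomass", stoich = c(BM = -1), lb = 0, ub = 1000,
           is_exchange = FALSE, is_biomass = TRUE),
      list(id = "EX_X", stoich = c(X = -1), lb = -1000, ub = 1000,
           is_exchange = TRUE, is_biomass = FALSE),
      list(id = "EX_co2", stoich = c(co2 = -1), lb = 0, ub = 1000,
           is_exchange = TRUE, is_biomass = FALSE)
    )
  )
}

# Consumer: grows weakly on S, can also catabolize byproduct X.
make_consumer_model <- function(id = "consumer") {
  metabolic_model(
    id,
    data.frame(id = c("S", "X", "BM", "co2"), carbon_atoms = c(6, 2, 1, 1)),
    list(
      list(id = "EX_S", stoich = c(S = -1), lb = -1000, ub = 1000,
           is_exchange = TRUE, is_biomass = FALSE),
      list(id = "conv_S", stoich = c(S = -1, BM = 5, co2 = 1),
           lb = 0, ub = 1000, is_exchange = FALSE, is_biomass = FALSE),
      list(id = "conv_X", stoich = c(X = -1, BM = 1, co2 = 1),
           lb = 0, ub = 1000, is_exchange = FALSE, is_biomass = FALSE),
      list(id = "biomass", stoich = c(BM = -1), lb = 0, ub = 1000,
           is_exchange = FALSE, is_biomass = TRUE),
      list(id = "EX_X", stoich = c(X = -1), lb = -1000, ub = 1000,
           is_exchange = TRUE, is_biomass = FALSE),
      list(id = "EX_co2", stoich = c(co2 = -1), lb = 0, ub = 1000,
           is_exchange = TRUE, is_biomass = FALSE)
    )
  )
}

small_test_config <- function(seed = 1, cub_range = c(3, 8), n_models = 6,
                              ...) {
  generator_config(seed = seed, n_bacteria = 60, n_fungi = 15,
                   n_models = n_models, n_carbon_sources = 12,
                   cub_range = cub_range, ...)
}
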