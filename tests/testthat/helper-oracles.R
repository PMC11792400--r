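# Independent oracles used across the suite. These are deliberately
# naive (enumeration / direct transcription) and share no code with the
# implementation paths they check.

# Brute-force LP oracle: enumerate candidate basic solutions of
# {A x = b, lb <= x <= ub} and return the maximum objective, or NA if no
# feasible candidate exists. Only viable for small n.
enum_lp_max <- function(obj, A, b, lb, ub) {
  n <- length(obj)
  r <- qr(A)$rank
  best <- -Inf
  found <- FALSE
  basis_sets <- if (r == 0) list(integer(0)) else utils::combn(n, r, simplify = FALSE)
  for (bs in basis_sets) {
    B <- A[, bs, drop = FALSE]
    if (r > 0 && qr(B)$rank < r) next
    nb <- setdiff(seq_len(n), bs)
    grid <- expand.grid(rep(list(c(TRUE, FALSE)), length(nb)))
    for (gi in seq_len(max(1, nrow(grid)))) {
      xn <- ifelse(unlist(grid[gi, ]), lb[nb], ub[nb])
      rhs <- b - if (length(nb)) as.vector(A[, nb, drop = FALSE] %*% xn) else 0
      xb <- tryCatch(qr.solve(B, rhs), error = function(e) NULL)
      if (is.null(xb)) next
      x <- numeric(n)
      x[nb] <- xn
      x[bs] <- xb
      if (max(abs(A %*% x - b)) > 1e-7) next
      if (any(x < lb - 1e-8) || any(x > ub + 1e-8)) next
      found <- TRUE
      best <- max(best, sum(obj * x))
    }
  }
  if (!found) NA_real_ else best
}

# Solve a model's FBA objective with the enumeration oracle.
oracle_fba_growth <- function(model, medium) {
  rxns <- model$rxns
  lb <- rxns$lb
  ub <- rxns$ub
  ex <- rxns$is_exchange
  lb[ex] <- pmax(lb[ex], 0)
  allowed <- intersect(names(medium), rxns$id[ex])
  if (length(allowed)) {
    i <- match(allowed, rxns$id)
    lb[i] <- pmax(rxns$lb[i], -unclass(medium)[allowed])
  }
  enum_lp_max(as.numeric(rxns$is_biomass), model$S, rep(0, nrow(model$S)),
              lb, ub)
}

# Direct transcription of the PDI formula for a table of the seven
# per-genome terms: weighted sum of term / pool-total ratios.
oracle_pdi <- function(terms_df) {
  w <- c(0.30, 0.30, 0.05, 0.10, 0.10, 0.10, 0.05)
  cols <- c("d_c", "d_x", "d_l", "d_op", "d_gc", "d_f", "d_d")
  sapply(seq_len(nrow(terms_df)), function(i) {
    s <- 0
    for (k in seq_along(cols)) {
      Tk <- sum(terms_df[[cols[k]]])
      if (Tk > 0) s <- s + w[k] * terms_df[[cols[k]]][i] / Tk
    }
    s
  })
}

# Random small model for oracle equivalence tests: a few sources, random
# conversion yields and bounds; <= 8 reactions.
random_small_model <- function(id, n_sources = 2) {
  srcs <- paste0("S", seq_len(n_sources))
  atoms <- sample(2:6, n_sources, replace = TRUE)
  rxns <- list()
  for (i in seq_len(n_sources)) {
    rxns[[length(rxns) + 1L]] <- list(
      id = paste0("EX_", srcs[i]), stoich = stats::setNames(-1, srcs[i]),
      lb = -stats::runif(1, 0, 20), ub = 1000,
      is_exchange = TRUE, is_biomass = FALSE
    )
    rxns[[length(rxns) + 1L]] <- list(
      id = paste0("conv_", srcs[i]),
      stoich = stats::setNames(c(-1, atoms[i] - 1, 1),
                               c(srcs[i], "BM", "co2")),
      lb = 0, ub = stats::runif(1, 0.5, 10),
      is_exchange = FALSE, is_biomass = FALSE
    )
  }
  rxns[[length(rxns) + 1L]] <- list(
    id = "biomass", stoich = c(BM = -sample(2:5, 1)), lb = 0,
    ub = stats::runif(1, 1, 20), is_exchange = FALSE, is_biomass = TRUE
  )
  rxns[[length(rxns) + 1L]] <- list(
    id = "EX_co2", stoich = c(co2 = -1), lb = 0, ub = 1000,
    is_exchange = TRUE, is_biomass = FALSE
  )
  metabolic_model(
    id,
    data.frame(id = c(srcs, "BM", "co2"), carbon_atoms = c(atoms, 1, 1)),
    rxns
  )
}
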