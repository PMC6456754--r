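# Toy-model builders used across the FBA tests.

# Minimal chain: A_e -> A (bounded uptake), biomass consumes `per_unit` A
# per unit of growth. Optimal growth = uptake_ub / per_unit.
toy_chain <- function(uptake_ub = 10, per_unit = 10) {
  metabolic_model(
    metabolites = list(metabolite("A_e", is_external = TRUE),
                       metabolite("A"),
                       metabolite("BIO_e", is_external = TRUE)),
    reactions = list(
      reaction("UPT", c(A_e = -1, A = 1), upper_bound = uptake_ub),
      reaction("GROW", stats::setNames(c(-per_unit, 1), c("A", "BIO_e")),
               objective_coefficient = 1)))
}

# Chain plus a dead-end branch A -> W_e, for ratio-constraint tests.
toy_branched <- function(uptake_ub = 10, per_unit = 10) {
  m <- toy_chain(uptake_ub, per_unit)
  m$metabolites$W_e <- metabolite("W_e", is_external = TRUE)
  m$reactions$WASTE <- reaction("WASTE", c(A = -1, W_e = 1))
  m
}

# ATP-maintenance toy: uptake 10 of A; A -> ATP; biomass consumes 1 A +
# gam ATP (annotation hooks wired); ATPM drains ATP. Closed form:
# growth(gam, ngam) = (10 - ngam) / (gam + 1).
toy_atpm <- function() {
  m <- metabolic_model(
    metabolites = list(metabolite("A_e", is_external = TRUE),
                       metabolite("A"), metabolite("ATP"),
                       metabolite("S_e", is_external = TRUE),
                       metabolite("BIO_e", is_external = TRUE)),
    reactions = list(
      reaction("UPT", c(A_e = -1, A = 1), upper_bound = 10),
      reaction("CAT", c(A = -1, ATP = 1)),
      reaction("ATPM", c(ATP = -1, S_e = 1)),
      reaction("BIOMASS", c(A = -1, ATP = -10, BIO_e = 1),
               objective_coefficient = 1)))
  m$annotations <- list(atpm_reaction = "ATPM", biomass_reaction = "BIOMASS",
                        atp_metabolite = "ATP")
  m
}

# Random small feasible network for property tests: a linear chain with
# random per-step stoichiometry, an optional parallel branch and random
# bounds; biomass at the end of the chain. Always bounded and feasible
# (zero flux is feasible), usually with positive optimal growth.
random_toy_model <- function(seed) {
  withr::with_seed(seed, {
    k <- sample(2:4, 1)
    mets <- c(list(metabolite("X_e", is_external = TRUE),
                   metabolite("BIO_e", is_external = TRUE)),
              lapply(paste0("M", seq_len(k)), metabolite))
    up <- round(stats::runif(1, 2, 20), 1)
    rxns <- list(reaction("UPT", c(X_e = -1, M1 = 1), upper_bound = up))
    for (i in seq_len(k - 1)) {
      coef <- sample(1:2, 1)
      sto <- stats::setNames(c(-1, coef),
                             c(paste0("M", i), paste0("M", i + 1)))
      rxns[[length(rxns) + 1L]] <-
        reaction(paste0("C", i), sto,
                 upper_bound = round(stats::runif(1, 5, 60), 1))
    }
    if (stats::runif(1) < 0.5 && k >= 3) {
      # parallel route M1 -> M_k with its own yield
      sto <- stats::setNames(c(-1, sample(1:2, 1)),
                             c("M1", paste0("M", k)))
      rxns[[length(rxns) + 1L]] <-
        reaction("ALT", sto, upper_bound = round(stats::runif(1, 1, 30), 1))
    }
    per <- sample(2:6, 1)
    rxns[[length(rxns) + 1L]] <-
      reaction("GROW", stats::setNames(c(-per, 1), c(paste0("M", k), "BIO_e")),
               objective_coefficient = 1)
    metabolic_model(mets, rxns)
  })
}
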