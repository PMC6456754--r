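# Seeded synthetic-data generators.
#
# Every input the pipeline consumes can be generated offline: labeling
# datasets from the two-parameter forward model, metabolite-pool tables with
# configurable per-metabolite fold changes, and OD time series. Each
# generator is a pure function of its spec (seed included), so repeated
# calls are identical.

#' Specification for the synthetic-data generators
#'
#' Defaults encode the measured growth condition: strain presets WT
#' (PDH share 0.33) and the ldh/mdh double knockout (0.73), both with a 24%
#' labeled CO2 pool; pool effects with the ED diagnostic KDPG increased
#' ~60-fold, other increased pools (G6P, F6P, FBP, citrate, 6PG) at 4-fold,
#' decreased pools (PEP, 2PG+3PG, R5P) at 0.3-fold and unchanged TCA pools;
#' three biological replicates per condition; 20% pool CV; growth rate
#' 0.205 h^-1 from a 0.01 starting OD.
#'
#' @param seed integer master seed.
#' @param label_params_by_strain named list of [label_params()] per strain.
#' @param pool_effects named positive vector of methanol/methane fold
#'   changes.
#' @param replicate_count biological replicates per condition (>= 2).
#' @param noise_cv coefficient of variation of replicate pools (lognormal).
#' @param growth_mu specific growth rate for OD series, h^-1.
#' @param od_noise_cv multiplicative OD noise CV.
#' @return a `"synth_spec"` list.
#' @export
synth_spec <- function(seed = 1L,
                       label_params_by_strain = list(
                         WT = label_params(0.33, 0.24, noise_sd = 0.01),
                         ldh_mdh = label_params(0.73, 0.24, noise_sd = 0.01)),
                       pool_effects = c(
                         KDPG = 60, G6P = 4, F6P = 4, FBP = 4,
                         citrate = 4, "6PG" = 4,
                         PEP = 0.3, "2PG+3PG" = 0.3, R5P = 0.3,
                         malate = 1, succinate = 1, "2-oxoglutarate" = 1),
                       replicate_count = 3L, noise_cv = 0.2,
                       growth_mu = 0.205, od_noise_cv = 0.02) {
  stopifnot(all(pool_effects > 0), replicate_count >= 2L,
            noise_cv >= 0, growth_mu >= 0, od_noise_cv >= 0)
  structure(list(seed = as.integer(seed),
                 label_params_by_strain = label_params_by_strain,
                 pool_effects = pool_effects,
                 replicate_count = as.integer(replicate_count),
                 noise_cv = noise_cv, growth_mu = growth_mu,
                 od_noise_cv = od_noise_cv),
            class = "synth_spec")
}

#' Generate labeling datasets (one per strain)
#'
#' Wraps [simulate_labeling()] per strain with per-strain seeds derived from
#' the master seed; optionally writes the flat MID-table dialect.
#'
#' @param spec a [synth_spec()].
#' @param path optional output file for [write_mid_table()].
#' @return named list of `"label_dataset"` objects (invisibly returns the
#'   path instead when `path` is given).
#' @export
gen_label_data <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  strains <- names(spec$label_params_by_strain)
  out <- lapply(seq_along(strains), function(i)
    simulate_labeling(spec$label_params_by_strain[[i]],
                      seed = spec$seed + i, strain = strains[i]))
  names(out) <- strains
  if (!is.null(path)) {
    write_mid_table(out, path)
    return(invisible(path))
  }
  out
}

#' Generate a metabolite-pool measurement table
#'
#' Lognormal replicate pools per metabolite and condition, with methanol
#' means scaled by `pool_effects`; internal-standard responses and biomass
#' amounts drawn per sample so normalization is exercised.
#'
#' @param spec a [synth_spec()].
#' @return data frame in the [volcano()] input layout (`metabolite`,
#'   `condition`, `replicate`, `signal`, `is_signal`, `biomass`).
#' @export
gen_pool_data <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  withr::with_seed(spec$seed, {
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    rows <- list()
    base <- 100
    for (m in names(spec$pool_effects)) {
      for (cond in c("methane", "methanol")) {
        mu <- base * if (cond == "methanol") spec$pool_effects[[m]] else 1
        for (r in seq_len(spec$replicate_count)) {
          abund <- stats::rlnorm(1, log(mu) - sdlog^2 / 2, sdlog)
          is_sig <- stats::rlnorm(1, log(1e4), 0.05)
          biomass <- stats::runif(1, 0.003, 0.006)
          rows[[length(rows) + 1L]] <- data.frame(
            metabolite = m, condition = cond, replicate = r,
            signal = abund * is_sig * biomass,
            is_signal = is_sig, biomass = biomass)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate an exponential OD time series
#'
#' `OD(t) = 0.01 * exp(mu * t)` with multiplicative lognormal noise.
#'
#' @param spec a [synth_spec()].
#' @param times sampling times in hours (default hourly to 20 h).
#' @return data frame with `time` and `od`.
#' @export
gen_growth_curves <- function(spec, times = seq(0, 20, by = 1)) {
  stopifnot(inherits(spec, "synth_spec"))
  withr::with_seed(spec$seed, {
    od <- 0.01 * exp(spec$growth_mu * times)
    if (spec$od_noise_cv > 0) {
      sdlog <- sqrt(log(1 + spec$od_noise_cv^2))
      od <- od * stats::rlnorm(length(od), -sdlog^2 / 2, sdlog)
    }
    data.frame(time = times, od = od)
  })
}
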