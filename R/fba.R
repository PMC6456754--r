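# Flux balance analysis with 13C-derived constraints.
#
# The LP is: maximize the biomass objective subject to S v = 0 over internal
# metabolites, reaction bounds, and the scenario's extra linear rows
# (flux-ratio equalities, flux-order inequalities, the O2/substrate ratio
# floor). Maintenance energy enters two ways: NGAM as a lower bound on the
# ATP-maintenance reaction, GAM as the ATP coefficient of the biomass
# equation (set through the model's annotation hooks so a loaded model's
# default can be overridden per scenario).

#' ATP maintenance parameters
#'
#' @param gam growth-associated maintenance, mmol ATP per gcdw of biomass
#'   formed (default 54.35).
#' @param ngam non-growth-associated maintenance, mmol ATP/(gcdw h)
#'   (default 8.39).
#' @return a `"maintenance_config"` list.
#' @export
maintenance_config <- function(gam = 54.35, ngam = 8.39) {
  stopifnot(gam >= 0, ngam >= 0)
  structure(list(gam = gam, ngam = ngam), class = "maintenance_config")
}

#' Flux-ratio and flux-order constraints
#'
#' A ratio constraint fixes `v_num = ratio * v_den` (a linear equality); an
#' order constraint enforces `v_greater >= v_lesser`.
#'
#' @param numerator,denominator,greater,lesser reaction ids.
#' @param ratio positive dimensionless ratio.
#' @return a `"ratio_constraint"` / `"order_constraint"` list.
#' @export
ratio_constraint <- function(numerator, denominator, ratio) {
  stopifnot(is.character(numerator), is.character(denominator),
            is.numeric(ratio), ratio > 0)
  structure(list(numerator = numerator, denominator = denominator,
                 ratio = ratio), class = "ratio_constraint")
}

#' @rdname ratio_constraint
#' @export
order_constraint <- function(greater, lesser) {
  stopifnot(is.character(greater), is.character(lesser))
  structure(list(greater = greater, lesser = lesser),
            class = "order_constraint")
}

#' Scenario configuration for an FBA run
#'
#' One scenario is one experimental condition translated into constraints:
#' measured uptake and secretion rates (applied as fixed exchange fluxes),
#' biomass-composition fractions for glycogen and EPS, a floor on the
#' O2/substrate consumption ratio, maintenance energies, 13C-derived
#' ratio/order constraints and arbitrary fixed fluxes (a knockout is a fixed
#' flux of 0, applied to both directions). Any field set to `NULL` leaves
#' the model untouched in that respect, so bare toy models solve with
#' `scenario_config()` defaults of `NULL` everywhere.
#'
#' @param methanol_uptake substrate uptake, mmol/(gcdw h), fixed (both
#'   bounds) on the model's annotated uptake reaction.
#' @param formate_production secretion rate fixed on the annotated formate
#'   exchange.
#' @param glycogen_fraction,eps_fraction dry-weight fractions in `[0, 1]`
#'   rewritten into the biomass equation via the model's molar-mass hooks.
#' @param o2_per_methanol_min lower bound on the O2/substrate consumption
#'   ratio (linear row `v_O2 - r * v_substrate >= 0`).
#' @param maintenance a [maintenance_config()], or `NULL` to keep the model's
#'   own maintenance settings.
#' @param ratio_constraints list of [ratio_constraint()] objects.
#' @param order_constraints list of [order_constraint()] objects.
#' @param fixed_fluxes named numeric vector, reaction id -> fixed flux value.
#' @param name scenario label used in reports.
#' @return a `"scenario_config"` list.
#' @export
scenario_config <- function(methanol_uptake = NULL, formate_production = NULL,
                            glycogen_fraction = NULL, eps_fraction = NULL,
                            o2_per_methanol_min = NULL, maintenance = NULL,
                            ratio_constraints = list(),
                            order_constraints = list(),
                            fixed_fluxes = NULL, name = "scenario") {
  num_ok <- function(x) is.null(x) || (is.numeric(x) && x >= 0)
  stopifnot(num_ok(methanol_uptake), num_ok(formate_production),
            num_ok(o2_per_methanol_min))
  frac_ok <- function(x) is.null(x) || (is.numeric(x) && x >= 0 && x <= 1)
  stopifnot(frac_ok(glycogen_fraction), frac_ok(eps_fraction))
  structure(list(methanol_uptake = methanol_uptake,
                 formate_production = formate_production,
                 glycogen_fraction = glycogen_fraction,
                 eps_fraction = eps_fraction,
                 o2_per_methanol_min = o2_per_methanol_min,
                 maintenance = maintenance,
                 ratio_constraints = ratio_constraints,
                 order_constraints = order_constraints,
                 fixed_fluxes = fixed_fluxes,
                 name = name),
            class = "scenario_config")
}

#' Derive a scenario from another, overriding fields
#'
#' @param scenario base [scenario_config()].
#' @param ... fields to override (appended ratio/order constraints should be
#'   passed as full replacement lists).
#' @return a new `"scenario_config"`.
#' @export
scenario_with <- function(scenario, ...) {
  stopifnot(inherits(scenario, "scenario_config"))
  dots <- list(...)
  for (k in names(dots)) scenario[[k]] <- dots[[k]]
  scenario
}

#' The control growth condition on methanol
#'
#' Measured methanol uptake 19.3 mmol/(gcdw h), formate production
#' 1.82 mmol/(gcdw h), glycogen 42% and EPS 10% of dry weight,
#' O2/methanol consumption ratio >= 0.5, GAM 54.35 and NGAM 8.39.
#'
#' @return a `"scenario_config"`.
#' @export
scenario_control <- function() {
  scenario_config(methanol_uptake = 19.3, formate_production = 1.82,
                  glycogen_fraction = 0.42, eps_fraction = 0.10,
                  o2_per_methanol_min = 0.5,
                  maintenance = maintenance_config(),
                  name = "Control")
}

#' The four-step nested scenario ladder
#'
#' Control; then an incomplete oxidative TCA cycle (fumarase fixed to 0 and
#' alpha-ketoglutarate dehydrogenase flux >= succinyl-CoA synthetase flux);
#' then the 13C-derived acetyl-CoA split as MCL/PDH flux ratio = 3; then
#' ED/EMP flux ratio = 1. Reaction ids are resolved from the model's
#' annotation hooks.
#'
#' @param model a [metabolic_model()] carrying the annotation hooks.
#' @param mcl_pdh_ratio MCL/PDH flux ratio for step 3 (default 3, the
#'   rounded published constraint; pass the raw 13C estimate to use it
#'   instead).
#' @param ed_emp_ratio ED/EMP flux ratio for step 4 (default 1).
#' @return ordered list of four `"scenario_config"` objects.
#' @export
scenario_ladder_table3 <- function(model, mcl_pdh_ratio = 3,
                                   ed_emp_ratio = 1) {
  an <- model$annotations
  need <- c("fumarase_reaction", "akgdh_reaction", "scs_reaction",
            "mcl_reaction", "pdh_reaction", "ed_reaction", "emp_reaction")
  miss <- setdiff(need, names(an))
  if (length(miss))
    stop("model annotations missing hook(s): ", paste(miss, collapse = ", "))
  s1 <- scenario_control()
  s2 <- scenario_with(
    s1, name = "TCA_constrained",
    fixed_fluxes = stats::setNames(0, an$fumarase_reaction),
    order_constraints = list(order_constraint(an$akgdh_reaction,
                                              an$scs_reaction)))
  s3 <- scenario_with(
    s2, name = "MCL1A/PDH_constrained",
    ratio_constraints = list(ratio_constraint(an$mcl_reaction,
                                              an$pdh_reaction,
                                              mcl_pdh_ratio)))
  s4 <- scenario_with(
    s3, name = "ED/EMP_constrained",
    ratio_constraints = c(s3$ratio_constraints,
                          list(ratio_constraint(an$ed_reaction,
                                                an$emp_reaction,
                                                ed_emp_ratio))))
  list(s1, s2, s3, s4)
}

# Resolve a reaction id against the model, with a clear error.
resolve_rxn <- function(model, id, what) {
  if (!id %in% names(model$reactions))
    stop("configuration error: ", what, " reaction '", id,
         "' is not in the model")
  id
}

# Apply scenario-driven edits to the biomass equation (GAM, glycogen/EPS
# dry-weight fractions) through the model's annotation hooks.
apply_biomass_hooks <- function(model, scenario) {
  an <- model$annotations
  bio <- an$biomass_reaction
  if (is.null(bio) || !bio %in% names(model$reactions)) return(model)
  sto <- model$reactions[[bio]]$stoichiometry
  if (!is.null(scenario$maintenance) && !is.null(an$atp_metabolite))
    sto[[an$atp_metabolite]] <- -scenario$maintenance$gam
  set_frac <- function(sto, met, mw, frac) {
    if (!is.null(frac) && !is.null(met) && !is.null(mw))
      sto[[met]] <- -frac / mw
    sto
  }
  sto <- set_frac(sto, an$glycogen_metabolite, an$glycogen_mw,
                  scenario$glycogen_fraction)
  sto <- set_frac(sto, an$eps_metabolite, an$eps_mw, scenario$eps_fraction)
  model$reactions[[bio]]$stoichiometry <- sto[sto != 0]
  model
}

#' Solve the flux balance LP for one scenario
#'
#' Maximizes the model's objective (biomass growth rate) subject to
#' steady-state mass balance over internal metabolites, reaction bounds,
#' and all scenario constraints. Every optimal solution is checked to
#' satisfy `max |S v| < 1e-6` before being returned.
#'
#' @param model a [metabolic_model()].
#' @param scenario a [scenario_config()] or `NULL` (model as-is).
#' @param minimize_total_flux if `TRUE`, a second lexicographic LP minimizes
#'   the total absolute flux at the optimal growth rate, giving a canonical
#'   flux vector under degeneracy. Only the objective value and explicitly
#'   constrained fluxes are contract-stable otherwise.
#' @return an `"fba_solution"`: list with `status` (`"optimal"`,
#'   `"infeasible"`, `"unbounded"`), `growth_rate`, named `fluxes`, and
#'   `derived` (`o2_per_methanol`, `biomass_yield` in g biomass/g methanol,
#'   when the model annotates the relevant exchanges).
#' @examples
#' sol <- solve_fba(core_model_fixture(), scenario_control())
#' sol$growth_rate
#' @export
solve_fba <- function(model, scenario = NULL, minimize_total_flux = FALSE) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!is.null(scenario)) {
    stopifnot(inherits(scenario, "scenario_config"))
    model <- apply_biomass_hooks(model, scenario)
  }
  an <- model$annotations
  rxns <- model$reactions
  rids <- names(rxns)
  n <- length(rxns)

  lb <- vapply(rxns, function(r) r$lower_bound, 0)
  ub <- vapply(rxns, function(r) r$upper_bound, 0)
  obj <- vapply(rxns, function(r) r$objective_coefficient, 0)

  int_met <- names(model$metabolites)[
    !vapply(model$metabolites, function(m) m$is_external, TRUE)]
  S <- matrix(0, length(int_met), n,
              dimnames = list(int_met, rids))
  for (j in seq_len(n)) {
    sto <- rxns[[j]]$stoichiometry
    keep <- intersect(names(sto), int_met)
    S[keep, j] <- sto[keep]
  }
  mat <- S
  dir <- rep("=", nrow(S))
  rhs <- rep(0, nrow(S))

  add_row <- function(row, d, r) {
    mat <<- rbind(mat, row); dir <<- c(dir, d); rhs <<- c(rhs, r)
  }

  if (!is.null(scenario)) {
    # Fixing a flux never relaxes the reaction's own bounds: a fixed value
    # outside [lb, ub] makes the problem infeasible (lb > ub), which is what
    # ends a robustness scan at a capacity limit.
    fix <- function(id, value, what) {
      id <- resolve_rxn(model, id, what)
      if (value < lb[[id]] - 1e-9 || value > ub[[id]] + 1e-9) {
        lb[[id]] <<- 1; ub[[id]] <<- 0
      } else {
        lb[[id]] <<- value; ub[[id]] <<- value
      }
    }
    if (!is.null(scenario$methanol_uptake) && !is.null(an$uptake_reaction))
      fix(an$uptake_reaction, scenario$methanol_uptake, "uptake")
    if (!is.null(scenario$formate_production) && !is.null(an$formate_reaction))
      fix(an$formate_reaction, scenario$formate_production, "formate")
    if (!is.null(scenario$maintenance) && !is.null(an$atpm_reaction)) {
      id <- resolve_rxn(model, an$atpm_reaction, "ATP maintenance")
      lb[[id]] <- max(lb[[id]], scenario$maintenance$ngam)
    }
    for (id in names(scenario$fixed_fluxes))
      fix(id, scenario$fixed_fluxes[[id]], "fixed-flux")
    if (!is.null(scenario$o2_per_methanol_min) &&
        !is.null(an$o2_reaction) && !is.null(an$uptake_reaction)) {
      row <- stats::setNames(rep(0, n), rids)
      row[resolve_rxn(model, an$o2_reaction, "O2")] <- 1
      row[resolve_rxn(model, an$uptake_reaction, "uptake")] <-
        -scenario$o2_per_methanol_min
      add_row(row, ">=", 0)
    }
    for (rc in scenario$ratio_constraints) {
      row <- stats::setNames(rep(0, n), rids)
      row[resolve_rxn(model, rc$numerator, "ratio numerator")] <- 1
      row[resolve_rxn(model, rc$denominator, "ratio denominator")] <-
        -rc$ratio
      add_row(row, "=", 0)
    }
    for (oc in scenario$order_constraints) {
      row <- stats::setNames(rep(0, n), rids)
      row[resolve_rxn(model, oc$greater, "order greater")] <- 1
      row[resolve_rxn(model, oc$lesser, "order lesser")] <- -1
      add_row(row, ">=", 0)
    }
  }

  res <- lp_solve(obj, mat, dir, rhs, lb, ub, maximize = TRUE)
  if (res$status != "optimal") {
    return(structure(list(status = res$status, growth_rate = NA_real_,
                          fluxes = stats::setNames(numeric(0), character(0)),
                          derived = list(), scenario = scenario),
                     class = "fba_solution"))
  }
  v <- stats::setNames(res$x, rids)

  if (minimize_total_flux) {
    # Lexicographic step: fix optimal growth, minimize sum |v| via t >= +/-v.
    obj2 <- c(rep(0, n), rep(1, n))
    mat2 <- rbind(cbind(mat, matrix(0, nrow(mat), n)),
                  cbind(diag(-1, n), diag(1, n)),
                  cbind(diag(1, n), diag(1, n)),
                  c(obj, rep(0, n)))
    dir2 <- c(dir, rep(">=", 2 * n), "=")
    rhs2 <- c(rhs, rep(0, 2 * n), res$objval)
    big <- pmax(abs(lb), abs(ub))
    res2 <- lp_solve(obj2, mat2, dir2, rhs2,
                     c(lb, rep(0, n)), c(ub, big),
                     maximize = FALSE)
    if (res2$status == "optimal") v <- stats::setNames(res2$x[seq_len(n)], rids)
  }

  resid <- max(abs(S %*% v))
  if (resid > 1e-6)
    stop("internal error: mass-balance residual ", format(resid),
         " exceeds 1e-6")

  derived <- list()
  if (!is.null(an$uptake_reaction) && !is.null(an$o2_reaction)) {
    up <- abs(v[[an$uptake_reaction]])
    if (up > 1e-12)
      derived$o2_per_methanol <- abs(v[[an$o2_reaction]]) / up
  }
  if (!is.null(an$uptake_reaction)) {
    up <- abs(v[[an$uptake_reaction]])
    if (up > 1e-12)
      derived$biomass_yield <- res$objval / (up * 0.03204)
  }

  structure(list(status = "optimal", growth_rate = res$objval,
                 fluxes = v, derived = derived, scenario = scenario),
            class = "fba_solution")
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("FBA solution:", x$status, "\n")
  if (x$status == "optimal") {
    cat(sprintf("  growth rate: %.3f 1/h\n", x$growth_rate))
    if (!is.null(x$derived$o2_per_methanol))
      cat(sprintf("  O2/substrate: %.3f\n", x$derived$o2_per_methanol))
    if (!is.null(x$derived$biomass_yield))
      cat(sprintf("  biomass yield: %.3f g/g\n", x$derived$biomass_yield))
  }
  invisible(x)
}

#' Run an ordered ladder of scenarios
#'
#' Solves each scenario in turn and tabulates growth rate, O2/substrate
#' ratio and biomass yield. When each scenario adds constraints to the
#' previous one, optimal growth is non-increasing down the ladder. An
#' infeasible scenario is reported in its row and the ladder continues.
#'
#' @param model a [metabolic_model()].
#' @param scenarios ordered list of [scenario_config()] objects.
#' @return data frame with one row per scenario: `scenario`, `status`,
#'   `growth_rate`, `o2_per_methanol`, `biomass_yield`.
#' @export
run_scenario_ladder <- function(model, scenarios) {
  rows <- lapply(scenarios, function(sc) {
    sol <- solve_fba(model, sc)
    data.frame(
      scenario = sc$name, status = sol$status,
      growth_rate = if (sol$status == "optimal") sol$growth_rate else NA_real_,
      o2_per_methanol = if (!is.null(sol$derived$o2_per_methanol))
        sol$derived$o2_per_methanol else NA_real_,
      biomass_yield = if (!is.null(sol$derived$biomass_yield))
        sol$derived$biomass_yield else NA_real_)
  })
  do.call(rbind, rows)
}

#' Robustness scan of one reaction's flux
#'
#' Fixes the reaction flux at each grid point from 0 upward (equality
#' constraint) and re-optimizes growth, stopping at the first infeasible
#' point (or at `max_value`). The feasibility boundary is refined by
#' bisection to within `step / 10`.
#'
#' @param model a [metabolic_model()].
#' @param scenario base [scenario_config()] (or `NULL`).
#' @param reaction reaction id to scan.
#' @param step grid spacing, mmol/(gcdw h) (> 0).
#' @param max_value optional scan ceiling.
#' @return a `"robustness_curve"`: list with `reaction`, `grid`, `growth`
#'   (NA where infeasible), `max_feasible`, and `argmax` (grid value(s) of
#'   maximal growth).
#' @export
robustness_scan <- function(model, scenario = NULL, reaction,
                            step = 0.1, max_value = NULL) {
  stopifnot(step > 0)
  resolve_rxn(model, reaction, "scanned")
  if (is.null(scenario)) scenario <- scenario_config(name = "scan-base")
  grid <- numeric(0); growth <- numeric(0)
  solve_at <- function(value) {
    fx <- scenario$fixed_fluxes
    fx <- c(fx[setdiff(names(fx), reaction)],
            stats::setNames(value, reaction))
    solve_fba(model, scenario_with(scenario, fixed_fluxes = fx))
  }
  value <- 0
  last_feasible <- NA_real_
  hit_infeasible <- FALSE
  repeat {
    if (!is.null(max_value) && value > max_value + 1e-12) break
    sol <- solve_at(value)
    grid <- c(grid, value)
    if (sol$status == "optimal") {
      growth <- c(growth, sol$growth_rate)
      last_feasible <- value
    } else {
      growth <- c(growth, NA_real_)
      hit_infeasible <- TRUE
      break
    }
    value <- value + step
  }
  max_feasible <- last_feasible
  if (hit_infeasible && !is.na(last_feasible)) {
    lo <- last_feasible; hi <- last_feasible + step
    while (hi - lo > step / 10) {
      mid <- (lo + hi) / 2
      if (solve_at(mid)$status == "optimal") lo <- mid else hi <- mid
    }
    max_feasible <- lo
  }
  ok <- !is.na(growth)
  argmax <- if (any(ok)) grid[ok][growth[ok] >= max(growth[ok]) - 1e-9]
            else numeric(0)
  structure(list(reaction = reaction, grid = grid, growth = growth,
                 max_feasible = max_feasible, argmax = argmax),
            class = "robustness_curve")
}

#' @export
print.robustness_curve <- function(x, ...) {
  cat("Robustness scan of", x$reaction, "over", length(x$grid), "points\n")
  cat(sprintf("  max feasible flux: %.3f mmol/(gcdw h)\n", x$max_feasible))
  if (length(x$argmax))
    cat(sprintf("  optimal flux range: [%.3f, %.3f]\n",
                min(x$argmax), max(x$argmax)))
  invisible(x)
}

#' Sensitivity of growth to a flux ratio
#'
#' Re-solves the FBA for each candidate value of a ratio constraint
#' `v_num = r * v_den` (logarithmic grids are natural here).
#'
#' @param model a [metabolic_model()].
#' @param scenario base [scenario_config()] (or `NULL`).
#' @param numerator,denominator reaction ids of the ratio.
#' @param ratio_values positive ratio values to test.
#' @return data frame with `ratio`, `status`, `growth_rate`.
#' @export
ratio_sensitivity_scan <- function(model, scenario = NULL,
                                   numerator, denominator, ratio_values) {
  stopifnot(all(ratio_values > 0))
  if (is.null(scenario)) scenario <- scenario_config(name = "ratio-base")
  rows <- lapply(ratio_values, function(r) {
    sc <- scenario_with(
      scenario,
      ratio_constraints = c(scenario$ratio_constraints,
                            list(ratio_constraint(numerator, denominator, r))))
    sol <- solve_fba(model, sc)
    data.frame(ratio = r, status = sol$status,
               growth_rate = if (sol$status == "optimal") sol$growth_rate
                             else NA_real_)
  })
  do.call(rbind, rows)
}

#' Growth over a grid of maintenance-energy values
#'
#' Solves the FBA at every (GAM, NGAM) pair. Growth is non-increasing in
#' each maintenance parameter with the other held fixed.
#'
#' @param model a [metabolic_model()] with the GAM annotation hook.
#' @param scenario base [scenario_config()]; its maintenance field is
#'   replaced pointwise.
#' @param gam_values,ngam_values nonnegative grids.
#' @return numeric matrix of growth rates (NA where infeasible), rows
#'   indexed by `gam_values`, columns by `ngam_values`.
#' @export
atpm_grid <- function(model, scenario = NULL, gam_values, ngam_values) {
  stopifnot(all(gam_values >= 0), all(ngam_values >= 0))
  if (is.null(scenario)) scenario <- scenario_config(name = "atpm-base")
  out <- matrix(NA_real_, length(gam_values), length(ngam_values),
                dimnames = list(gam = format(gam_values),
                                ngam = format(ngam_values)))
  for (i in seq_along(gam_values)) {
    for (j in seq_along(ngam_values)) {
      sc <- scenario_with(scenario,
                          maintenance = maintenance_config(gam_values[i],
                                                           ngam_values[j]))
      sol <- solve_fba(model, sc)
      if (sol$status == "optimal") out[i, j] <- sol$growth_rate
    }
  }
  out
}
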