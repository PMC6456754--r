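# Growth rates from OD time series, and specific yields per substrate.

#' Fit an exponential growth rate from an OD time series
#'
#' Least-squares slope of `ln(OD)` against time over the supplied window
#' (the caller selects the exponential-phase slice; no automatic phase
#' detection).
#'
#' @param times time points in hours, strictly increasing, length >= 3.
#' @param ods optical densities (> 0), same length.
#' @return list with `rate` (h^-1) and `r_squared`.
#' @examples
#' t <- 0:10
#' fit_growth_rate(t, 0.01 * exp(0.2 * t))$rate
#' @export
fit_growth_rate <- function(times, ods) {
  if (length(times) < 3L || length(ods) != length(times))
    stop("need >= 3 paired (time, OD) points")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (any(!is.finite(ods)) || any(ods <= 0))
    stop("ODs must be positive")
  fit <- stats::lm(log(ods) ~ times)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
  list(rate = unname(stats::coef(fit)[2]),
       r_squared = if (is.nan(r2)) 1 else r2)
}

#' Specific rates container
#'
#' @param methanol_uptake substrate uptake, mmol/(gcdw h), > 0 for yield
#'   computations.
#' @param product_rates named numeric vector of secretion rates,
#'   mmol/(gcdw h).
#' @param growth_rate specific growth rate, h^-1.
#' @return a `"rate_set"` list.
#' @export
rate_set <- function(methanol_uptake, product_rates = numeric(0),
                     growth_rate = NA_real_) {
  stopifnot(is.numeric(methanol_uptake), methanol_uptake >= 0,
            all(product_rates >= 0))
  structure(list(methanol_uptake = methanol_uptake,
                 product_rates = product_rates,
                 growth_rate = growth_rate),
            class = "rate_set")
}

#' Product yields per mole of substrate
#'
#' `yield_p = rate_p / methanol_uptake` for each product, mmol product per
#' mmol methanol consumed.
#'
#' @param rates a [rate_set()].
#' @return named numeric vector of yields.
#' @examples
#' product_yield(rate_set(19.3, c(formate = 1.82)))
#' @export
product_yield <- function(rates) {
  stopifnot(inherits(rates, "rate_set"))
  if (rates$methanol_uptake <= 0)
    stop("methanol uptake must be > 0 to compute yields")
  rates$product_rates / rates$methanol_uptake
}

#' Biomass yield in g biomass per g methanol
#'
#' `growth_rate / (methanol_uptake * methanol_molar_mass)` with the molar
#' mass of methanol fixed at 0.03204 g/mmol (32.04 g/mol).
#'
#' @param growth_rate specific growth rate, h^-1.
#' @param methanol_uptake substrate uptake, mmol/(gcdw h), > 0.
#' @param methanol_molar_mass g/mmol (default 0.03204).
#' @return biomass yield, g/g.
#' @examples
#' biomass_yield(0.205, 19.3)
#' @export
biomass_yield <- function(growth_rate, methanol_uptake,
                          methanol_molar_mass = 0.03204) {
  if (methanol_uptake <= 0)
    stop("methanol uptake must be > 0")
  growth_rate / (methanol_uptake * methanol_molar_mass)
}
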