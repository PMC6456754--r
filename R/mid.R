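# 13C mass-isotopomer algebra for the C3-C4 / acetyl-CoA node.
#
# During steady-state growth on 13C methanol, everything upstream of PEP is
# fully labeled, so the only information left in the labeling pattern sits
# downstream of the pyruvate node where unlabeled CO2 (from the medium) is
# fixed by carboxylation. Oxaloacetate (OAA, measured via threonine) and
# malate carry M+3 (fully labeled C3 + unlabeled CO2) and M+4 (labeled CO2);
# acetyl-CoA is M+2 when made from pyruvate via pyruvate dehydrogenase (PDH)
# and inherits one CO2-derived carbon (so M+1 or M+2) when cleaved from
# malyl-CoA by malyl-CoA lyase (MCL). Citrate condenses OAA with AcCoA, and
# that convolution is invertible: citrate + OAA MIDs give the AcCoA MID, and
# the AcCoA + malate MIDs give the PDH/MCL flux split.

#' Construct a mass-isotopomer distribution (MID)
#'
#' An MID is the vector of fractional abundances of the M+0 ... M+n mass
#' shifts of a metabolite, where n is its carbon count. Fractions must be
#' nonnegative and are validated to sum to 1 within `tol`.
#'
#' @param metabolite metabolite identifier (e.g. `"citrate"`).
#' @param fractions numeric vector of fractional abundances, index 1 = M+0.
#' @param tol tolerance on the unit-sum invariant.
#' @return an object of class `"mid"`.
#' @examples
#' mid("oaa", c(0, 0, 0, 0.76, 0.24))
#' @export
mid <- function(metabolite, fractions, tol = 1e-6) {
  fractions <- as.numeric(fractions)
  if (!length(fractions) || anyNA(fractions))
    stop("MID fractions must be non-missing numerics")
  if (any(fractions < -tol))
    stop("MID fractions must be nonnegative (", metabolite, ")")
  fractions[fractions < 0] <- 0
  s <- sum(fractions)
  if (abs(s - 1) > tol)
    stop("MID fractions for '", metabolite, "' sum to ", format(s),
         ", not 1 (tolerance ", tol, ")")
  names(fractions) <- paste0("M+", seq_along(fractions) - 1L)
  structure(list(metabolite = metabolite, fractions = fractions),
            class = "mid")
}

#' @export
print.mid <- function(x, digits = 4, ...) {
  cat("MID of", x$metabolite, "\n")
  print(round(x$fractions, digits))
  invisible(x)
}

# Fraction at a given mass shift, 0 when beyond the vector.
mid_at <- function(x, shift) {
  f <- x$fractions
  i <- shift + 1L
  if (i < 1L || i > length(f)) 0 else unname(f[i])
}

#' Normalize a raw isotopomer signal vector into an MID
#'
#' Divides a vector of nonnegative raw abundances by its sum so the result
#' sums to exactly 1, preserving order. Idempotent on already-normalized
#' input.
#'
#' @param raw numeric vector of nonnegative raw abundances (index 1 = M+0).
#' @param metabolite metabolite identifier attached to the result.
#' @return an object of class `"mid"`.
#' @examples
#' normalize_mid(c(2, 2))
#' @export
normalize_mid <- function(raw, metabolite = "metabolite") {
  raw <- as.numeric(raw)
  if (anyNA(raw) || any(raw < 0))
    stop("raw abundances must be nonnegative and non-missing")
  s <- sum(raw)
  if (s <= 0) stop("degenerate input: all-zero abundance vector")
  mid(metabolite, raw / s)
}

#' Convolve two MIDs (condensation labeling)
#'
#' The MID of a molecule formed by condensing two precursors is the discrete
#' convolution of their MIDs: `result[k] = sum_i a[i] * b[k - i]`. This is
#' exactly how citrate labeling arises from oxaloacetate + acetyl-CoA
#' condensation by citrate synthase.
#'
#' @param a,b objects of class `"mid"`.
#' @param metabolite identifier for the product (default pastes the inputs).
#' @return an object of class `"mid"` of length `length(a) + length(b) - 1`.
#' @examples
#' oaa <- mid("oaa", c(0, 0, 0, 0.76, 0.24))
#' accoa <- mid("accoa", c(0, 0.5092, 0.4908))
#' convolve_mids(oaa, accoa, "citrate")
#' @export
convolve_mids <- function(a, b, metabolite = NULL) {
  stopifnot(inherits(a, "mid"), inherits(b, "mid"))
  if (is.null(metabolite))
    metabolite <- paste0(a$metabolite, "+", b$metabolite)
  fa <- a$fractions; fb <- b$fractions
  out <- numeric(length(fa) + length(fb) - 1L)
  for (i in seq_along(fa))
    out[i + seq_along(fb) - 1L] <- out[i + seq_along(fb) - 1L] + fa[i] * fb
  mid(metabolite, out)
}

#' Labeling-model parameters for the acetyl-CoA node
#'
#' @param p_pdh fraction of de novo acetyl-CoA made from pyruvate via PDH,
#'   in `[0, 1]`. The complement is made from malate via malyl-CoA lyase.
#' @param f_co2 labeled fraction of the intracellular CO2 pool, in `[0, 1]`
#'   (default 0.24: the pool is dominated by unlabeled CO2 diffusing in from
#'   the medium, with a labeled share from methanol oxidation).
#' @param noise_sd additive truncated-Gaussian noise SD applied per mass
#'   channel in simulations (0 = noise-free).
#' @return a validated list of class `"label_params"`.
#' @export
label_params <- function(p_pdh, f_co2 = 0.24, noise_sd = 0) {
  stopifnot(is.numeric(p_pdh), p_pdh >= 0, p_pdh <= 1,
            is.numeric(f_co2), f_co2 >= 0, f_co2 <= 1,
            is.numeric(noise_sd), noise_sd >= 0)
  structure(list(p_pdh = p_pdh, f_co2 = f_co2, noise_sd = noise_sd),
            class = "label_params")
}

#' Simulate a steady-state labeling dataset
#'
#' Forward model of the C3-C4/AcCoA node under 13C methanol:
#' de novo OAA and malate come from carboxylation of fully labeled C3
#' precursors, so `OAA = malate = (M+3: 1 - f_co2, M+4: f_co2)`; acetyl-CoA
#' is fully labeled (M+2) from PDH with probability `p_pdh`, while the MCL
#' route passes one malate carbon that is CO2-derived, giving
#' `AcCoA(M+2) = p + (1 - p) f` and `AcCoA(M+1) = (1 - p)(1 - f)`; citrate is
#' the OAA (x) AcCoA convolution and threonine reports the OAA backbone.
#' Optional truncated-Gaussian noise is added per channel and the MIDs
#' renormalized.
#'
#' @param params a [label_params()] object.
#' @param seed integer seed; the simulation is a pure function of
#'   `(params, seed)`.
#' @param strain strain label stored in the dataset.
#' @return a `"label_dataset"`: list with `strain` and `mids` (named list of
#'   [mid()] objects for citrate, threonine, malate, succinate).
#' @examples
#' simulate_labeling(label_params(p_pdh = 0.33), seed = 1)
#' @export
simulate_labeling <- function(params, seed = 1L, strain = "WT") {
  stopifnot(inherits(params, "label_params"))
  p <- params$p_pdh; f <- params$f_co2
  oaa <- mid("threonine", c(0, 0, 0, 1 - f, f))
  malate <- mid("malate", c(0, 0, 0, 1 - f, f))
  accoa <- mid("accoa", c(0, (1 - p) * (1 - f), p + (1 - p) * f))
  citrate <- convolve_mids(oaa, accoa, "citrate")
  succinate <- mid("succinate", c(0, 0, 0, 1 - f, f))
  mids <- list(citrate = citrate, threonine = oaa,
               malate = malate, succinate = succinate)
  if (params$noise_sd > 0) {
    mids <- withr::with_seed(as.integer(seed), lapply(mids, function(m) {
      raw <- m$fractions + stats::rnorm(length(m$fractions), 0, params$noise_sd)
      raw[raw < 0] <- 0
      normalize_mid(raw, m$metabolite)
    }))
  }
  structure(list(strain = strain, mids = mids), class = "label_dataset")
}

#' Infer the acetyl-CoA MID from citrate and OAA labeling
#'
#' Acetyl-CoA pools are too small to measure directly, so its M+1 and M+2
#' fractions are deconvolved from the citrate condensation product:
#' `AcCoA(M+1) = citrate(M+4) / OAA(M+3)` and
#' `AcCoA(M+2) = (citrate(M+5) - OAA(M+4) * AcCoA(M+1)) / OAA(M+3)`.
#' Negative intermediate results (possible under noise) are clipped to zero
#' and flagged.
#'
#' @param citrate citrate [mid()] (6 carbons).
#' @param oaa OAA [mid()], usually measured as threonine (4 backbone carbons).
#' @return list of class `"accoa_mid"` with elements `m1`, `m2` (fractions)
#'   and `clipped` (logical).
#' @export
estimate_accoa_mid <- function(citrate, oaa) {
  stopifnot(inherits(citrate, "mid"), inherits(oaa, "mid"))
  o3 <- mid_at(oaa, 3)
  if (o3 <= 1e-9)
    stop("unidentifiable: OAA M+3 fraction is ~0, the deconvolution divides by it")
  m1 <- mid_at(citrate, 4) / o3
  m2 <- (mid_at(citrate, 5) - mid_at(oaa, 4) * m1) / o3
  clipped <- FALSE
  if (m1 < 0) { m1 <- 0; clipped <- TRUE }
  if (m2 < 0) { m2 <- 0; clipped <- TRUE }
  structure(list(m1 = m1, m2 = m2, clipped = clipped), class = "accoa_mid")
}

#' Partition de novo acetyl-CoA synthesis between PDH and MCL
#'
#' Solves the linear labeling balance at the acetyl-CoA node:
#' `F_MCL * malate(M+3) = AcCoA(M+1)` and
#' `F_PDH + F_MCL * malate(M+4) = AcCoA(M+2)`, then normalizes to relative
#' contributions `f_pdh + f_mcl = 1`. The alternative ratio implied by
#' equating `F_PDH / F_MCL` with `AcCoA(M+1) / AcCoA(M+2)` is inconsistent
#' with this balance (PDH-derived acetyl-CoA is fully labeled, so M+1 cannot
#' be PDH-derived); it is reported in `diagnostics` only.
#'
#' @param accoa an `"accoa_mid"` from [estimate_accoa_mid()] (or a list with
#'   `m1`, `m2`).
#' @param malate malate [mid()].
#' @return list of class `"flux_split"` with `f_pdh`, `f_mcl`, `raw_pdh`,
#'   `raw_mcl`, `clipped`, and `diagnostics` (`alt_ratio_pdh_over_mcl`).
#' @export
estimate_flux_split <- function(accoa, malate) {
  stopifnot(inherits(malate, "mid"))
  m3 <- mid_at(malate, 3)
  if (m3 <= 1e-9)
    stop("unidentifiable: malate M+3 fraction is ~0")
  raw_mcl <- accoa$m1 / m3
  raw_pdh <- accoa$m2 - raw_mcl * mid_at(malate, 4)
  clipped <- isTRUE(accoa$clipped)
  if (raw_pdh < 0) { raw_pdh <- 0; clipped <- TRUE }
  if (raw_mcl < 0) { raw_mcl <- 0; clipped <- TRUE }
  tot <- raw_pdh + raw_mcl
  if (tot <= 1e-9)
    stop("unidentifiable: both PDH and MCL contributions are ~0")
  alt <- if (accoa$m2 > 1e-12) accoa$m1 / accoa$m2 else Inf
  structure(list(
    f_pdh = raw_pdh / tot, f_mcl = raw_mcl / tot,
    raw_pdh = raw_pdh, raw_mcl = raw_mcl, clipped = clipped,
    diagnostics = list(alt_ratio_pdh_over_mcl = alt)
  ), class = "flux_split")
}

#' @export
print.flux_split <- function(x, digits = 3, ...) {
  cat(sprintf("Acetyl-CoA source split: PDH %.1f%%, MCL %.1f%%\n",
              100 * x$f_pdh, 100 * x$f_mcl))
  if (x$clipped) cat("  (negative intermediate clipped to 0)\n")
  invisible(x)
}

#' Estimate the labeled fraction of the CO2 pool
#'
#' De novo OAA arises from carboxylation of fully labeled C3, so its M+4
#' share (relative to M+3 + M+4) reports the labeled fraction of the CO2
#' pool: `f = OAA(M+4) / (OAA(M+3) + OAA(M+4))`.
#'
#' @param oaa OAA [mid()] (threonine measurement).
#' @return scalar labeled fraction in `[0, 1]`.
#' @examples
#' estimate_co2_fraction(mid("threonine", c(0, 0, 0, 0.76, 0.24)))
#' @export
estimate_co2_fraction <- function(oaa) {
  stopifnot(inherits(oaa, "mid"))
  den <- mid_at(oaa, 3) + mid_at(oaa, 4)
  if (den <= 1e-9)
    stop("unidentifiable: OAA M+3 + M+4 is ~0")
  mid_at(oaa, 4) / den
}

#' Full labeling analysis of one strain's dataset
#'
#' Chains [estimate_accoa_mid()] (threonine standing in for OAA) and
#' [estimate_flux_split()], plus [estimate_co2_fraction()], and reports
#' diagnostics: clipping flags, the alternative PDH/MCL ratio, and the
#' residual of the redundant citrate M+6 channel
#' (`citrate(M+6) - OAA(M+4) * AcCoA(M+2)`).
#'
#' @param data a `"label_dataset"` (from [simulate_labeling()] or
#'   [read_mid_table()]).
#' @return list with `split` (a `"flux_split"`), `co2_fraction`, `accoa`,
#'   and `diagnostics`.
#' @examples
#' analyze_dataset(simulate_labeling(label_params(0.33), seed = 1))
#' @export
analyze_dataset <- function(data) {
  stopifnot(inherits(data, "label_dataset"))
  need <- c("citrate", "threonine", "malate")
  miss <- setdiff(need, names(data$mids))
  if (length(miss))
    stop("dataset is missing required metabolite MID(s): ",
         paste(miss, collapse = ", "))
  citrate <- data$mids$citrate
  oaa <- data$mids$threonine
  malate <- data$mids$malate
  accoa <- estimate_accoa_mid(citrate, oaa)
  split <- estimate_flux_split(accoa, malate)
  co2 <- estimate_co2_fraction(oaa)
  resid_m6 <- mid_at(citrate, 6) - mid_at(oaa, 4) * accoa$m2
  list(
    strain = data$strain,
    split = split,
    co2_fraction = co2,
    accoa = accoa,
    diagnostics = list(
      clipped = split$clipped,
      alt_ratio_pdh_over_mcl = split$diagnostics$alt_ratio_pdh_over_mcl,
      citrate_m6_residual = resid_m6
    )
  )
}

#' Read / write MID tables
#'
#' The on-disk dialect is a delimited table with columns `strain`,
#' `metabolite`, `mass_shift` (integer, 0-based) and `fraction` — the natural
#' flat export of a per-metabolite MID spreadsheet. `read_mid_table()`
#' returns one `"label_dataset"` per strain; missing mass shifts are zero.
#'
#' @param path file path.
#' @param sep field separator (tab default).
#' @return `read_mid_table()`: named list of `"label_dataset"` objects, one
#'   per strain. `write_mid_table()`: invisibly, the path.
#' @export
read_mid_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("strain", "metabolite", "mass_shift", "fraction")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("MID table is missing column(s): ", paste(miss, collapse = ", "))
  out <- list()
  for (s in unique(df$strain)) {
    ds <- df[df$strain == s, ]
    mids <- list()
    for (m in unique(ds$metabolite)) {
      dm <- ds[ds$metabolite == m, ]
      n <- max(dm$mass_shift)
      fr <- numeric(n + 1L)
      fr[dm$mass_shift + 1L] <- dm$fraction
      mids[[m]] <- mid(m, fr)
    }
    out[[s]] <- structure(list(strain = s, mids = mids),
                          class = "label_dataset")
  }
  out
}

#' @param datasets a `"label_dataset"` or list of them.
#' @rdname read_mid_table
#' @export
write_mid_table <- function(datasets, path, sep = "\t") {
  if (inherits(datasets, "label_dataset")) datasets <- list(datasets)
  rows <- do.call(rbind, lapply(datasets, function(d) {
    do.call(rbind, lapply(d$mids, function(m) {
      data.frame(strain = d$strain, metabolite = m$metabolite,
                 mass_shift = seq_along(m$fractions) - 1L,
                 fraction = unname(m$fractions))
    }))
  }))
  utils::write.table(rows, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
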