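# Targeted-metabolomics pool comparison (volcano analysis).
#
# Raw peak responses are normalized to a co-extracted internal standard and
# to the biomass of the extracted sample; fold changes are computed on the
# normalized means (methanol over methane) and significance from Welch's
# unequal-variance t test on log-transformed abundances, a robust default
# for small-n lognormal pool data.

#' Normalize a pool measurement
#'
#' Divides the raw peak response by the internal-standard response and the
#' extracted biomass: `signal / (is_signal * biomass)`. Vectorized.
#'
#' @param signal raw peak response (> 0, arbitrary units).
#' @param is_signal internal-standard peak response (> 0, same units).
#' @param biomass gcdw of the extracted sample (> 0).
#' @return dimensionless normalized abundance per gcdw.
#' @examples
#' normalize_pool(10, 2, 0.5)
#' @export
normalize_pool <- function(signal, is_signal, biomass) {
  if (any(!is.finite(signal)) || any(signal <= 0) ||
      any(!is.finite(is_signal)) || any(is_signal <= 0) ||
      any(!is.finite(biomass)) || any(biomass <= 0))
    stop("signal, is_signal and biomass must all be positive and finite")
  signal / (is_signal * biomass)
}

#' Volcano analysis of metabolite pools, methanol vs methane
#'
#' For each metabolite with both conditions present (>= 2 replicates each):
#' normalizes every measurement with [normalize_pool()], computes
#' `log2_fc = log2(mean(methanol) / mean(methane))` on the normalized
#' abundances, and a two-sided Welch t-test p-value on their log10 values.
#' A metabolite is `"increased"`/`"decreased"` when
#' `|fold change| >= fc_threshold` and `p < p_threshold`, else
#' `"unchanged"`.
#'
#' @param pools data frame with columns `metabolite`, `condition`
#'   (`"methane"` / `"methanol"`), `replicate`, `signal`, `is_signal`,
#'   `biomass`.
#' @param fc_threshold fold-change cutoff (default 2).
#' @param p_threshold significance cutoff on the (possibly adjusted)
#'   p-value (default 0.05).
#' @param adjust if `TRUE`, Benjamini-Hochberg adjust the p-values before
#'   categorizing (the default mirrors plotting raw p-values).
#' @return data frame with `metabolite`, `log2_fc`, `p_value`, `category`;
#'   attribute `"test"` records the test used. Metabolites missing a
#'   condition are skipped with a warning.
#' @export
volcano <- function(pools, fc_threshold = 2, p_threshold = 0.05,
                    adjust = FALSE) {
  need <- c("metabolite", "condition", "signal", "is_signal", "biomass")
  miss <- setdiff(need, names(pools))
  if (length(miss))
    stop("pool table is missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(pools$condition), c("methane", "methanol"))
  if (length(bad))
    stop("unknown condition(s): ", paste(bad, collapse = ", "))
  pools$abund <- normalize_pool(pools$signal, pools$is_signal, pools$biomass)

  rows <- list()
  for (m in unique(pools$metabolite)) {
    pm <- pools[pools$metabolite == m, ]
    a <- pm$abund[pm$condition == "methanol"]
    b <- pm$abund[pm$condition == "methane"]
    if (length(a) < 2L || length(b) < 2L) {
      warning("metabolite ", m,
              " lacks >=2 replicates in both conditions; skipped")
      next
    }
    lfc <- log2(mean(a) / mean(b))
    p <- stats::t.test(log10(a), log10(b), var.equal = FALSE)$p.value
    rows[[m]] <- data.frame(metabolite = m, log2_fc = lfc, p_value = p)
  }
  if (!length(rows))
    return(structure(data.frame(metabolite = character(0),
                                log2_fc = numeric(0), p_value = numeric(0),
                                category = character(0)),
                     test = "welch_t_log10"))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  p_used <- if (adjust) stats::p.adjust(out$p_value, "BH") else out$p_value
  sig <- p_used < p_threshold & abs(out$log2_fc) >= log2(fc_threshold)
  out$category <- ifelse(!sig, "unchanged",
                         ifelse(out$log2_fc > 0, "increased", "decreased"))
  structure(out, test = "welch_t_log10",
            p_adjust = if (adjust) "BH" else "none")
}
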