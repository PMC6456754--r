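# End-to-end orchestration: labeling analysis -> 13C-derived flux-ratio
# constraint -> FBA scenario ladder -> pool volcano -> growth/yields ->
# combined report. Stages are isolated: a failing stage is reported and the
# stages that depend on it are skipped, while independent stages still run.

#' Configuration for an end-to-end run
#'
#' Any `NULL` input path falls back to packaged synthetic data (labeling,
#' pools, growth) or the packaged core model, so a demo run needs no files.
#'
#' @param model_path metabolic model file (JSON or reaction table); `NULL`
#'   uses [core_model_fixture()].
#' @param mid_path MID table in the [read_mid_table()] dialect; `NULL`
#'   simulates from `spec`.
#' @param pool_path pool-measurement table (TSV with [volcano()] columns);
#'   `NULL` generates from `spec`.
#' @param growth_path OD time-series TSV (`time`, `od`); `NULL` generates.
#' @param out_dir output directory (created if absent).
#' @param seed master seed for all generated data.
#' @param spec a [synth_spec()] used for any generated inputs; its seed is
#'   overridden by `seed`.
#' @param mcl_pdh_ratio if non-`NULL`, pins the ladder's MCL/PDH ratio to a
#'   literal value instead of the raw estimator ratio.
#' @param methanol_uptake,formate_production measured rates forwarded to the
#'   yield stage and the ladder scenarios.
#' @return a `"run_config"` list.
#' @export
run_config <- function(model_path = NULL, mid_path = NULL, pool_path = NULL,
                       growth_path = NULL, out_dir = tempfile("mflx_run_"),
                       seed = 1L, spec = synth_spec(seed = seed),
                       mcl_pdh_ratio = NULL,
                       methanol_uptake = 19.3, formate_production = 1.82) {
  spec$seed <- as.integer(seed)
  structure(list(model_path = model_path, mid_path = mid_path,
                 pool_path = pool_path, growth_path = growth_path,
                 out_dir = out_dir, seed = as.integer(seed), spec = spec,
                 mcl_pdh_ratio = mcl_pdh_ratio,
                 methanol_uptake = methanol_uptake,
                 formate_production = formate_production),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the labeling analysis, converts the recovered MCL/PDH
#' contribution ratio into a flux-ratio constraint, runs the four-step FBA
#' scenario ladder, the pool volcano analysis and the growth/yield
#' computations, writing TSV tables plus a JSON summary under
#' `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return a `"mflx_report"`: list with per-stage `status`, the stage
#'   results, and `out_dir`; `any_error` is `TRUE` iff some stage failed.
#' @examples
#' \donttest{
#' rep <- run_all(run_config(seed = 1))
#' rep$status
#' }
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  status <- list()
  results <- list()
  stage <- function(name, expr) {
    out <- tryCatch(list(ok = TRUE, value = force(expr)),
                    error = function(e) list(ok = FALSE, value = conditionMessage(e)))
    status[[name]] <<- if (out$ok) "ok" else paste0("error: ", out$value)
    if (out$ok) results[[name]] <<- out$value
    out$ok
  }

  # -- labeling analysis ----------------------------------------------------
  mid_ok <- stage("mid", {
    datasets <- if (is.null(config$mid_path)) gen_label_data(config$spec)
                else read_mid_table(config$mid_path)
    analyses <- lapply(datasets, analyze_dataset)
    tab <- do.call(rbind, lapply(analyses, function(a)
      data.frame(strain = a$strain, f_pdh = a$split$f_pdh,
                 f_mcl = a$split$f_mcl, co2_fraction = a$co2_fraction,
                 clipped = a$diagnostics$clipped)))
    utils::write.table(tab, file.path(config$out_dir, "flux_split.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    list(analyses = analyses, table = tab)
  })

  # -- 13C-derived constraint + FBA ladder ---------------------------------
  stage("fba_ladder", {
    model <- if (is.null(config$model_path)) core_model_fixture()
             else read_model(config$model_path)
    ratio <- config$mcl_pdh_ratio
    ratio_source <- "pinned"
    if (is.null(ratio)) {
      if (!mid_ok) stop("labeling stage failed and no literal ratio pinned")
      sp <- results$mid$analyses[[1]]$split
      if (sp$raw_pdh <= 0) stop("estimated PDH contribution is 0; ratio undefined")
      ratio <- sp$raw_mcl / sp$raw_pdh
      ratio_source <- "estimated"
    }
    ladder <- run_scenario_ladder(model,
                                  scenario_ladder_table3(model, ratio))
    utils::write.table(ladder, file.path(config$out_dir, "ladder.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    list(ladder = ladder, mcl_pdh_ratio = ratio,
         ratio_source = ratio_source)
  })

  # -- pool volcano ---------------------------------------------------------
  stage("volcano", {
    pools <- if (is.null(config$pool_path)) gen_pool_data(config$spec)
             else utils::read.table(config$pool_path, header = TRUE,
                                    sep = "\t", stringsAsFactors = FALSE,
                                    check.names = FALSE)
    vt <- volcano(pools)
    utils::write.table(vt, file.path(config$out_dir, "volcano.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    vt
  })

  # -- growth + yields ------------------------------------------------------
  stage("yields", {
    gc <- if (is.null(config$growth_path)) gen_growth_curves(config$spec)
          else utils::read.table(config$growth_path, header = TRUE,
                                 sep = "\t")
    fit <- fit_growth_rate(gc$time, gc$od)
    rates <- rate_set(config$methanol_uptake,
                      c(formate = config$formate_production),
                      growth_rate = fit$rate)
    yl <- list(growth_rate = fit$rate, r_squared = fit$r_squared,
               product_yield = as.list(product_yield(rates)),
               biomass_yield = biomass_yield(fit$rate,
                                             config$methanol_uptake))
    jsonlite::write_json(yl, file.path(config$out_dir, "yields.json"),
                         auto_unbox = TRUE, digits = NA)
    yl
  })

  any_error <- any(vapply(status, function(s) startsWith(s, "error"), TRUE))
  summary <- list(seed = config$seed, status = status,
                  any_error = any_error)
  jsonlite::write_json(summary, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(c(summary, list(results = results, out_dir = config$out_dir)),
            class = "mflx_report")
}

#' @export
print.mflx_report <- function(x, ...) {
  cat("Pipeline run (seed", x$seed, ") ->", x$out_dir, "\n")
  for (s in names(x$status)) cat(sprintf("  %-10s %s\n", s, x$status[[s]]))
  invisible(x)
}

#' Command-line dispatcher
#'
#' Entry point used by the `inst/scripts/methanoflux` wrapper; exposed as a
#' function so the CLI is testable in-process. Subcommands:
#' `run-all`, `mid-simulate`, `mid-estimate`, `ladder`, `robustness`,
#' `volcano`, `yields`. Run with no arguments (or `help`) for usage.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status (0 on success), invisibly.
#' @export
mflx_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: methanoflux <command> [options]",
    "  run-all      --out DIR [--seed N] [--model PATH] [--mids PATH]",
    "  mid-simulate --p P [--f F] [--noise SD] [--seed N] --out FILE",
    "  mid-estimate --input FILE",
    "  ladder       [--model PATH] [--ratio R]",
    "  robustness   --reaction ID [--step S] [--model PATH] [--max V]",
    "  volcano      --input FILE [--out FILE]",
    "  yields       --growth FILE [--uptake U]",
    sep = "\n")
  opt <- function(flag, default = NULL) {
    i <- match(flag, args)
    if (is.na(i) || i == length(args)) default else args[i + 1L]
  }
  num <- function(flag, default = NULL) {
    v <- opt(flag); if (is.null(v)) default else as.numeric(v)
  }
  cmd <- if (length(args)) args[1L] else "help"
  code <- tryCatch({
    switch(cmd,
      "run-all" = {
        rep <- run_all(run_config(
          model_path = opt("--model"), mid_path = opt("--mids"),
          out_dir = opt("--out", tempfile("mflx_run_")),
          seed = as.integer(num("--seed", 1))))
        print(rep)
        if (rep$any_error) 1L else 0L
      },
      "mid-simulate" = {
        ds <- simulate_labeling(
          label_params(num("--p"), num("--f", 0.24), num("--noise", 0)),
          seed = as.integer(num("--seed", 1)))
        write_mid_table(ds, opt("--out", stop("--out required")))
        0L
      },
      "mid-estimate" = {
        datasets <- read_mid_table(opt("--input", stop("--input required")))
        for (d in datasets) {
          a <- analyze_dataset(d)
          cat(sprintf("%s\tf_pdh=%.4f\tf_mcl=%.4f\tco2=%.4f\n",
                      a$strain, a$split$f_pdh, a$split$f_mcl,
                      a$co2_fraction))
        }
        0L
      },
      "ladder" = {
        model <- if (is.null(opt("--model"))) core_model_fixture()
                 else read_model(opt("--model"))
        lad <- run_scenario_ladder(
          model, scenario_ladder_table3(model, num("--ratio", 3)))
        utils::write.table(format(lad, digits = 4), sep = "\t",
                           row.names = FALSE, quote = FALSE)
        0L
      },
      "robustness" = {
        model <- if (is.null(opt("--model"))) core_model_fixture()
                 else read_model(opt("--model"))
        rc <- robustness_scan(model, scenario_control(),
                              reaction = opt("--reaction",
                                             stop("--reaction required")),
                              step = num("--step", 0.1),
                              max_value = num("--max"))
        print(rc)
        0L
      },
      "volcano" = {
        pools <- utils::read.table(opt("--input", stop("--input required")),
                                   header = TRUE, sep = "\t",
                                   check.names = FALSE)
        vt <- volcano(pools)
        out <- opt("--out")
        if (is.null(out)) print(vt)
        else utils::write.table(vt, out, sep = "\t", row.names = FALSE,
                                quote = FALSE)
        0L
      },
      "yields" = {
        gc <- utils::read.table(opt("--growth", stop("--growth required")),
                                header = TRUE, sep = "\t")
        fit <- fit_growth_rate(gc$time, gc$od)
        up <- num("--uptake", 19.3)
        cat(sprintf("growth_rate\t%.4f\nbiomass_yield\t%.4f\n",
                    fit$rate, biomass_yield(fit$rate, up)))
        0L
      },
      { message(usage); if (cmd %in% c("help", "--help", "-h")) 0L else 2L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}
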