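# Isotopomer algebra: construction, convolution, the forward labeling
# model, and the inverse estimators.

test_that("normalize_mid scales, preserves order, rejects degenerate input", {
  expect_equal(unname(normalize_mid(c(2, 2))$fractions), c(0.5, 0.5))
  v <- c(0.1, 0.2, 0.7)
  expect_equal(unname(normalize_mid(v)$fractions), v)  # idempotent
  expect_equal(unname(normalize_mid(c(0.38699, 0.49521, 0.11779, 0.00001))$fractions),
               c(0.3870, 0.4952, 0.1178, 0.0000), tolerance = 1e-4)
  expect_error(normalize_mid(c(0, 0, 0)), "degenerate")
  expect_error(normalize_mid(c(-1, 2)), "nonnegative")
})

test_that("mid() enforces the unit-sum invariant", {
  expect_error(mid("x", c(0.5, 0.6)), "sum")
  m <- mid("x", c(0.25, 0.75))
  expect_named(m$fractions, c("M+0", "M+1"))
})

oaa_wt <- mid("oaa", c(0, 0, 0, 0.76, 0.24))
accoa_wt <- mid("accoa", c(0, 0.5092, 0.4908))

test_that("convolution reproduces the citrate condensation values", {
  cit <- convolve_mids(oaa_wt, accoa_wt, "citrate")
  expect_length(cit$fractions, 7)
  expect_equal(unname(cit$fractions[5:7]),
               c(0.386992, 0.495216, 0.117792), tolerance = 1e-12)

  d0 <- mid("d", 1)
  expect_equal(unname(convolve_mids(d0, d0)$fractions), 1)
})

test_that("convolution is commutative, associative, normalization-preserving", {
  for (seed in 1:10) {
    ms <- withr::with_seed(seed, list(
      a = normalize_mid(stats::runif(4) + 0.01),
      b = normalize_mid(stats::runif(3) + 0.01),
      c = normalize_mid(stats::runif(5) + 0.01)))
    ab <- convolve_mids(ms$a, ms$b)
    ba <- convolve_mids(ms$b, ms$a)
    expect_equal(unname(ab$fractions), unname(ba$fractions))
    expect_equal(sum(ab$fractions), 1, tolerance = 1e-12)
    expect_true(all(ab$fractions >= 0))
    l <- convolve_mids(convolve_mids(ms$a, ms$b), ms$c)
    r <- convolve_mids(ms$a, convolve_mids(ms$b, ms$c))
    expect_equal(unname(l$fractions), unname(r$fractions))
  }
})

test_that("noise-free forward model matches its closed form", {
  # pure PDH, unlabeled CO2: AcCoA = delta(M+2), citrate = delta(M+5)
  d <- simulate_labeling(label_params(1, 0), seed = 1)
  expect_equal(unname(d$mids$citrate$fractions),
               c(0, 0, 0, 0, 0, 1, 0))

  d <- simulate_labeling(label_params(0.33, 0.24), seed = 1)
  expect_equal(unname(d$mids$citrate$fractions[5:7]),
               c(0.386992, 0.495216, 0.117792), tolerance = 1e-12)
  expect_equal(unname(d$mids$threonine$fractions),
               c(0, 0, 0, 0.76, 0.24))

  d <- simulate_labeling(label_params(0.73, 0.24), seed = 1)
  accoa <- estimate_accoa_mid(d$mids$citrate, d$mids$threonine)
  expect_equal(accoa$m1, 0.2052, tolerance = 1e-12)
  expect_equal(accoa$m2, 0.7948, tolerance = 1e-12)
})

test_that("acetyl-CoA deconvolution inverts the condensation", {
  cit <- convolve_mids(oaa_wt, accoa_wt, "citrate")
  est <- estimate_accoa_mid(cit, oaa_wt)
  expect_equal(est$m1, 0.5092, tolerance = 1e-12)
  expect_equal(est$m2, 0.4908, tolerance = 1e-12)
  expect_false(est$clipped)

  est <- estimate_accoa_mid(mid("cit", c(0, 0, 0, 0, 0, 1, 0)),
                            mid("oaa", c(0, 0, 0, 1, 0)))
  expect_equal(est$m1, 0)
  expect_equal(est$m2, 1)

  expect_error(estimate_accoa_mid(cit, mid("oaa", c(1, 0, 0, 0, 0))),
               "unidentifiable")

  # round trip for arbitrary AcCoA supported on {M+1, M+2}
  for (seed in 1:10) {
    a1 <- withr::with_seed(seed, stats::runif(1))
    ac <- mid("ac", c(0, a1, 1 - a1))
    est <- estimate_accoa_mid(convolve_mids(oaa_wt, ac), oaa_wt)
    expect_equal(est$m1, a1, tolerance = 1e-12)
    expect_equal(est$m2, 1 - a1, tolerance = 1e-12)
  }
})

test_that("flux split reproduces the published WT and mutant partitions", {
  mal <- mid("malate", c(0, 0, 0, 0.76, 0.24))
  sp <- estimate_flux_split(list(m1 = 0.5092, m2 = 0.4908), mal)
  expect_equal(sp$f_pdh, 0.33, tolerance = 1e-12)
  expect_equal(sp$f_mcl, 0.67, tolerance = 1e-12)

  sp <- estimate_flux_split(list(m1 = 0.2052, m2 = 0.7948), mal)
  expect_equal(sp$f_pdh, 0.73, tolerance = 1e-12)

  sp <- estimate_flux_split(list(m1 = 0, m2 = 1),
                            mid("malate", c(0, 0, 0, 1, 0)))
  expect_equal(sp$f_pdh, 1)
  expect_equal(sp$f_mcl, 0)

  # the rejected third-equation ratio is surfaced as a diagnostic
  sp <- estimate_flux_split(list(m1 = 0.5092, m2 = 0.4908), mal)
  expect_equal(sp$diagnostics$alt_ratio_pdh_over_mcl, 0.5092 / 0.4908)
})

test_that("negative intermediates are clipped and flagged, never silent", {
  # citrate M+5 too small -> negative raw AcCoA M+2
  cit <- mid("cit", c(0, 0, 0, 0, 0.9, 0.01, 0.09))
  est <- estimate_accoa_mid(cit, oaa_wt)
  expect_true(est$clipped)
  expect_gte(est$m2, 0)
  sp <- estimate_flux_split(est, mid("malate", c(0, 0, 0, 0.76, 0.24)))
  expect_true(sp$clipped)
})

test_that("CO2-fraction estimator and its identities", {
  expect_equal(estimate_co2_fraction(oaa_wt), 0.24, tolerance = 1e-12)
  expect_equal(estimate_co2_fraction(mid("oaa", c(0, 0, 0, 0, 1))), 1)
  expect_error(estimate_co2_fraction(mid("oaa", c(1, 0, 0, 0, 0))),
               "unidentifiable")
})

test_that("estimator-after-simulator identity on a (p, f) grid", {
  for (p in c(0, 0.1, 0.33, 0.5, 0.73, 0.9, 1)) {
    for (f in c(0.05, 0.24, 0.5, 0.9)) {
      a <- analyze_dataset(simulate_labeling(label_params(p, f), seed = 1))
      expect_equal(a$split$f_pdh, p, tolerance = 1e-9,
                   info = sprintf("p=%g f=%g", p, f))
      expect_equal(a$co2_fraction, f, tolerance = 1e-9)
      expect_lt(abs(a$diagnostics$citrate_m6_residual), 1e-9)
    }
  }
})

test_that("analyze_dataset names missing metabolites", {
  d <- simulate_labeling(label_params(0.33), seed = 1)
  d$mids$malate <- NULL
  expect_error(analyze_dataset(d), "malate")
})

test_that("MID tables round-trip through the flat dialect", {
  d <- simulate_labeling(label_params(0.33, 0.24, noise_sd = 0.01),
                         seed = 3, strain = "WT")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mid_table(d, path)
  back <- read_mid_table(path)
  expect_named(back, "WT")
  expect_equal(back$WT$mids$citrate$fractions, d$mids$citrate$fractions,
               tolerance = 1e-12)
  expect_error(read_mid_table(textConnection("a\tb\n1\t2")), "column")
})

test_that("noisy replicates recover the split with small bias (mini MC)", {
  est <- vapply(1:40, function(s)
    analyze_dataset(simulate_labeling(label_params(0.33, 0.24,
                                                   noise_sd = 0.01),
                                      seed = s))$split$f_pdh, 0)
  expect_lt(abs(mean(est) - 0.33), 0.02)
  expect_lt(stats::sd(est), 0.05)
})
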