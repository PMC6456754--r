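# Model containers, both I/O formats, validation, and the packaged fixture.

make_table <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c("id\tname\tequation\tlb\tub\tobjective", lines), path)
  path
}

test_that("reaction table parsing: minimal, exchange, malformed", {
  p <- make_table(c("R1\tr1\tA_ext_e -> A\t0\t10\t0",
                    "BIO\tbio\tA -> B_e\t0\t1000\t1"))
  m <- read_model(p)
  expect_length(m$reactions, 2)
  expect_length(m$metabolites, 3)
  expect_equal(m$reactions$R1$stoichiometry, c(A_ext_e = -1, A = 1))
  expect_equal(m$reactions$R1$upper_bound, 10)

  # no-product exchange row: single negative coefficient
  p <- make_table(c("EX\tex\tA ->\t0\t5\t0",
                    "BIO\tbio\tA_e -> A\t0\t10\t1"))
  m <- read_model(p)
  expect_equal(m$reactions$EX$stoichiometry, c(A = -1))

  p <- make_table(c("R1\tr1\tA -> + ->\t0\t10\t1"))
  expect_error(read_model(p), "R1")

  p <- make_table(c("R1\tr1\tA_e -> A\t0\t10\t1",
                    "R1\tr1\tA_e -> A\t0\t10\t0"))
  expect_error(read_model(p), "duplicate")
})

test_that("unknown table columns are ignored with a warning", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tname\tequation\tlb\tub\tobjective\tnotes",
               "R1\tr1\tA_e -> A\t0\t10\t1\thello"), path)
  expect_warning(m <- read_model(path), "notes")
  expect_length(m$reactions, 1)
})

test_that("validate_model reports bound, resolution and orphan findings", {
  expect_length(validate_model(core_model_fixture()), 0)

  m <- metabolic_model(
    list(metabolite("A"), metabolite("Z")),
    list(reaction("R", c(A = -1, B = 1), lower_bound = 5, upper_bound = 1,
                  objective_coefficient = 1)))
  f <- validate_model(m)
  sev <- vapply(f, function(x) x$severity, "")
  msg <- vapply(f, function(x) x$message, "")
  expect_true(any(sev == "error" & grepl("lower bound", msg)))
  expect_true(any(sev == "error" & grepl("undeclared", msg)))
  expect_true(any(sev == "warning" & grepl("^metabolite Z", msg)))

  m2 <- metabolic_model(list(metabolite("A")),
                        list(reaction("R", c(A = -1))))
  expect_true(any(grepl("objective", vapply(validate_model(m2),
                                            function(x) x$message, ""))))
})

expect_models_equal <- function(a, b) {
  expect_equal(names(a$reactions), names(b$reactions))
  expect_equal(sort(names(a$metabolites)), sort(names(b$metabolites)))
  for (id in names(a$reactions)) {
    ra <- a$reactions[[id]]; rb <- b$reactions[[id]]
    expect_equal(sort(names(ra$stoichiometry)), sort(names(rb$stoichiometry)))
    expect_equal(ra$stoichiometry[sort(names(ra$stoichiometry))],
                 rb$stoichiometry[sort(names(rb$stoichiometry))])
    expect_equal(ra$lower_bound, rb$lower_bound)
    expect_equal(ra$upper_bound, rb$upper_bound)
    expect_equal(ra$objective_coefficient, rb$objective_coefficient)
  }
  for (id in names(a$metabolites))
    expect_equal(a$metabolites[[id]]$is_external,
                 b$metabolites[[id]]$is_external)
}

test_that("round trips are identities for both formats", {
  fixture <- core_model_fixture()
  for (ext in c(".json", ".tsv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_model(fixture, path)
    expect_models_equal(read_model(path), fixture)
  }
  # annotations survive the JSON schema
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fixture, path)
  expect_equal(read_model(path)$annotations$uptake_reaction, "MEOHt")
})

test_that("round-trip identity holds on random generated models", {
  for (seed in 1:15) {
    m <- random_toy_model(seed)
    for (ext in c(".json", ".tsv")) {
      path <- withr::local_tempfile(fileext = ext)
      write_model(m, path)
      expect_models_equal(read_model(path), m)
    }
  }
})

test_that("core fixture honours its structural contract", {
  m <- core_model_fixture()
  expect_true(all(c("FDH", "EDD", "PDH", "MCL", "FUM") %in%
                  names(m$reactions)))
  expect_equal(length(m$reactions), 28)
  # every internal metabolite participates in >= 2 reactions (no dead ends)
  internal <- names(m$metabolites)[
    !vapply(m$metabolites, function(x) x$is_external, TRUE)]
  counts <- stats::setNames(integer(length(internal)), internal)
  for (r in m$reactions) {
    hit <- intersect(names(r$stoichiometry), internal)
    counts[hit] <- counts[hit] + 1L
  }
  expect_true(all(counts >= 2L))
})

test_that("core fixture grows, and not without carbon", {
  m <- core_model_fixture()
  sol <- solve_fba(m, scenario_control())
  expect_equal(sol$status, "optimal")
  expect_gt(sol$growth_rate, 0)

  starved <- solve_fba(m, scenario_with(scenario_control(),
                                        methanol_uptake = 0))
  expect_true(starved$status == "infeasible" ||
              abs(starved$growth_rate) < 1e-9)
})
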