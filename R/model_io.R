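# Metabolic-model containers and I/O.
#
# Two on-disk formats are supported: a native JSON schema (lossless,
# including annotations) and a delimited reaction table with columns
# id, name, equation, lb, ub, objective -- the dialect a model supplement
# spreadsheet exports to. In the table dialect, metabolite ids ending in
# "_e" denote external/boundary species (excluded from mass balance);
# "->" marks an irreversible equation, "<=>" a reversible one. SBML is a
# declared non-goal.

#' Construct a metabolite
#'
#' @param id short unique identifier (nonempty).
#' @param name free-text name.
#' @param compartment compartment tag (`"c"` cytosol, `"e"` extracellular).
#' @param is_external logical; external (boundary) species are excluded from
#'   the steady-state mass balance.
#' @return an object of class `"mflx_metabolite"`.
#' @export
metabolite <- function(id, name = id, compartment = "c",
                       is_external = FALSE) {
  stopifnot(is.character(id), nzchar(id), length(id) == 1L)
  structure(list(id = id, name = name, compartment = compartment,
                 is_external = isTRUE(is_external)),
            class = "mflx_metabolite")
}

#' Construct a reaction
#'
#' @param id short unique identifier.
#' @param stoichiometry named numeric vector mapping metabolite id to signed
#'   coefficient (negative = consumed).
#' @param name free-text name.
#' @param lower_bound,upper_bound flux bounds in mmol/(gcdw h).
#' @param objective_coefficient objective weight (nonzero only for the
#'   biomass reaction in typical use).
#' @return an object of class `"mflx_reaction"`. Constructors are light;
#'   invariants (bound order, resolvable metabolites) are checked by
#'   [validate_model()].
#' @export
reaction <- function(id, stoichiometry, name = id,
                     lower_bound = 0, upper_bound = 1000,
                     objective_coefficient = 0) {
  stopifnot(is.character(id), nzchar(id), length(id) == 1L,
            is.numeric(stoichiometry), !is.null(names(stoichiometry)))
  structure(list(id = id, name = name,
                 stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 objective_coefficient = as.numeric(objective_coefficient)),
            class = "mflx_reaction")
}

#' Construct a metabolic model
#'
#' @param metabolites list of [metabolite()] objects.
#' @param reactions list of [reaction()] objects.
#' @param annotations free-form key/value metadata. Recognized hook keys used
#'   by [solve_fba()]: `uptake_reaction`, `o2_reaction`, `formate_reaction`,
#'   `atpm_reaction`, `biomass_reaction`, `atp_metabolite`,
#'   `glycogen_metabolite`, `glycogen_mw`, `eps_metabolite`, `eps_mw`,
#'   `emp_reaction`, `ed_reaction`, `pdh_reaction`, `mcl_reaction`,
#'   `fumarase_reaction`, `akgdh_reaction`, `scs_reaction`.
#' @return an object of class `"metabolic_model"`.
#' @export
metabolic_model <- function(metabolites, reactions, annotations = list()) {
  mids <- vapply(metabolites, function(m) m$id, "")
  rids <- vapply(reactions, function(r) r$id, "")
  if (anyDuplicated(mids))
    stop("duplicate metabolite id(s): ",
         paste(unique(mids[duplicated(mids)]), collapse = ", "))
  if (anyDuplicated(rids))
    stop("duplicate reaction id(s): ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))
  names(metabolites) <- mids
  names(reactions) <- rids
  structure(list(metabolites = metabolites, reactions = reactions,
                 annotations = annotations),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model:", length(x$metabolites), "metabolites,",
      length(x$reactions), "reactions\n")
  nob <- sum(vapply(x$reactions,
                    function(r) r$objective_coefficient != 0, TRUE))
  cat("  objective reactions:", nob, "\n")
  invisible(x)
}

# ---- equation string <-> stoichiometry ------------------------------------

parse_equation <- function(eq, row_label = eq) {
  rev <- grepl("<=>", eq, fixed = TRUE)
  parts <- strsplit(eq, if (rev) "<=>" else "->", fixed = TRUE)[[1]]
  if (length(parts) > 2L || (!rev && !grepl("->", eq, fixed = TRUE)))
    stop("malformed equation in row '", row_label, "': ", eq)
  side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(numeric(0))
    terms <- strsplit(s, "+", fixed = TRUE)[[1]]
    out <- numeric(0)
    for (tm in terms) {
      tm <- trimws(tm)
      if (!nzchar(tm)) stop("malformed equation in row '", row_label, "'")
      toks <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(toks) == 1L) {
        coef <- 1; met <- toks
      } else if (length(toks) == 2L) {
        coef <- suppressWarnings(as.numeric(toks[1]))
        met <- toks[2]
        if (is.na(coef))
          stop("malformed stoichiometry '", tm, "' in row '", row_label, "'")
      } else stop("malformed term '", tm, "' in row '", row_label, "'")
      out[met] <- (if (is.na(out[met])) 0 else out[met]) + sign * coef
    }
    out
  }
  lhs <- side(parts[1], -1)
  rhs <- if (length(parts) == 2L) side(parts[2], +1) else numeric(0)
  sto <- lhs
  for (m in names(rhs)) sto[m] <- (if (is.na(sto[m])) 0 else sto[m]) + rhs[m]
  sto <- sto[sto != 0]
  if (!length(sto))
    stop("equation in row '", row_label, "' has no net stoichiometry")
  list(stoichiometry = sto, reversible = rev)
}

format_equation <- function(sto, reversible) {
  fmt <- function(v) {
    paste(vapply(names(v), function(m) {
      coef <- abs(v[[m]])
      if (coef == 1) m else paste(format(coef, digits = 15, scientific = FALSE), m)
    }, ""), collapse = " + ")
  }
  lhs <- fmt(sto[sto < 0])
  rhs <- fmt(sto[sto > 0])
  paste(lhs, if (reversible) "<=>" else "->", rhs)
}

# ---- read / write ---------------------------------------------------------

guess_format <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "reaction-table"
}

#' Read a metabolic model
#'
#' @param path file path.
#' @param format `"json"` or `"reaction-table"`; guessed from the extension
#'   by default.
#' @param sep field separator for the table dialect (tab for `.tsv`,
#'   comma for `.csv`; guessed from the extension).
#' @return a validated [metabolic_model()]. Unknown table columns are ignored
#'   with a warning; a duplicate reaction id or malformed stoichiometry is an
#'   error naming the offending row.
#' @export
read_model <- function(path, format = guess_format(path), sep = NULL) {
  if (!file.exists(path)) stop("model file not found: ", path)
  format <- match.arg(format, c("json", "reaction-table"))
  if (format == "json") {
    j <- jsonlite::read_json(path, simplifyVector = FALSE)
    mets <- lapply(j$metabolites, function(m)
      metabolite(m$id, m$name, m$compartment, isTRUE(m$is_external)))
    rxns <- lapply(j$reactions, function(r)
      reaction(r$id, unlist(r$stoichiometry), r$name,
               r$lower_bound, r$upper_bound, r$objective_coefficient))
    model <- metabolic_model(mets, rxns,
                             annotations = if (is.null(j$annotations)) list()
                                           else j$annotations)
  } else {
    if (is.null(sep))
      sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "#", check.names = FALSE)
    model <- model_from_reaction_table(df)
  }
  findings <- validate_model(model)
  errs <- findings[vapply(findings, function(f) f$severity == "error", TRUE)]
  if (length(errs))
    stop("model fails validation: ",
         paste(vapply(errs, function(f) f$message, ""), collapse = "; "))
  model
}

# Build a model from a reaction-table data frame (dialect described above).
model_from_reaction_table <- function(df) {
  need <- c("id", "equation", "lb", "ub")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("reaction table is missing column(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(df), c(need, "name", "objective"))
  if (length(extra))
    warning("ignoring unknown reaction-table column(s): ",
            paste(extra, collapse = ", "))
  if (anyDuplicated(df$id))
    stop("duplicate reaction id(s) in table: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  rxns <- vector("list", nrow(df))
  met_ids <- character(0)
  for (i in seq_len(nrow(df))) {
    pe <- parse_equation(df$equation[i], row_label = df$id[i])
    lb <- as.numeric(df$lb[i]); ub <- as.numeric(df$ub[i])
    if (is.na(lb)) lb <- if (pe$reversible) -1000 else 0
    if (is.na(ub)) ub <- 1000
    rxns[[i]] <- reaction(
      df$id[i], pe$stoichiometry,
      name = if ("name" %in% names(df)) df$name[i] else df$id[i],
      lower_bound = lb, upper_bound = ub,
      objective_coefficient =
        if ("objective" %in% names(df)) as.numeric(df$objective[i]) else 0)
    met_ids <- union(met_ids, names(pe$stoichiometry))
  }
  mets <- lapply(met_ids, function(m)
    metabolite(m, compartment = if (endsWith(m, "_e")) "e" else "c",
               is_external = endsWith(m, "_e")))
  metabolic_model(mets, rxns)
}

#' Write a metabolic model
#'
#' Writing then reading a model reproduces it field for field (for the table
#' dialect this holds for models following the `_e` external-naming
#' convention; annotations are carried by the JSON schema only).
#'
#' @param model a [metabolic_model()].
#' @param path output file path.
#' @param format `"json"` or `"reaction-table"` (guessed from extension).
#' @param sep separator for the table dialect.
#' @return invisibly, `path`.
#' @export
write_model <- function(model, path, format = guess_format(path), sep = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  format <- match.arg(format, c("json", "reaction-table"))
  if (format == "json") {
    j <- list(
      metabolites = lapply(unname(model$metabolites), function(m)
        list(id = m$id, name = m$name, compartment = m$compartment,
             is_external = m$is_external)),
      reactions = lapply(unname(model$reactions), function(r)
        list(id = r$id, name = r$name,
             stoichiometry = as.list(r$stoichiometry),
             lower_bound = r$lower_bound, upper_bound = r$upper_bound,
             objective_coefficient = r$objective_coefficient)),
      annotations = model$annotations)
    jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    if (is.null(sep))
      sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- do.call(rbind, lapply(unname(model$reactions), function(r) {
      data.frame(id = r$id, name = r$name,
                 equation = format_equation(r$stoichiometry,
                                            r$lower_bound < 0),
                 lb = r$lower_bound, ub = r$upper_bound,
                 objective = r$objective_coefficient)
    }))
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Validate a metabolic model
#'
#' @param model a [metabolic_model()].
#' @return a list of findings, each `list(severity, message)` with severity
#'   `"error"` or `"warning"`; empty iff all invariants hold. Orphan
#'   metabolites (referenced by no reaction) are warnings; bound-order
#'   violations, unresolved metabolites, empty stoichiometries and a missing
#'   objective are errors.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  findings <- list()
  add <- function(severity, message)
    findings[[length(findings) + 1L]] <<- list(severity = severity,
                                               message = message)
  met_ids <- names(model$metabolites)
  used <- character(0)
  n_obj <- 0L
  for (r in model$reactions) {
    if (r$lower_bound > r$upper_bound)
      add("error", sprintf("reaction %s: lower bound %g > upper bound %g",
                           r$id, r$lower_bound, r$upper_bound))
    unknown <- setdiff(names(r$stoichiometry), met_ids)
    if (length(unknown))
      add("error", sprintf("reaction %s references undeclared metabolite(s): %s",
                           r$id, paste(unknown, collapse = ", ")))
    if (!length(r$stoichiometry) || all(r$stoichiometry == 0))
      add("error", sprintf("reaction %s has no nonzero stoichiometry", r$id))
    if (r$objective_coefficient != 0) n_obj <- n_obj + 1L
    used <- union(used, names(r$stoichiometry))
  }
  if (n_obj == 0L)
    add("error", "model has no reaction with a nonzero objective coefficient")
  for (m in setdiff(met_ids, used))
    add("warning", sprintf("metabolite %s is referenced by no reaction", m))
  findings
}

#' Packaged core-model fixture
#'
#' A ~28-reaction lumped model of methylotroph central carbon metabolism:
#' methanol oxidation to formaldehyde, formate and CO2 (FDH); formaldehyde
#' fixation by the RuMP cycle into hexose phosphate; EMP and ED (EDD)
#' branches to pyruvate (differing in ATP yield); PEP/pyruvate carboxylation
#' to OAA; the two acetyl-CoA routes (PDH and the MCL route via malate);
#' a TCA arc with fumarase (FUM); glycogen and EPS sinks; lumped ATP/NADH
#' currency with an electron-transport reaction; ATP maintenance; and an
#' illustrative biomass equation carrying growth-associated ATP, glycogen
#' and EPS via annotation hooks. Its purpose is exercising the FBA engine at
#' desk scale, not reproducing genome-scale predictions.
#'
#' @return a validated [metabolic_model()] with the annotation hooks used by
#'   [solve_fba()] populated.
#' @examples
#' m <- core_model_fixture()
#' length(m$reactions)
#' @export
core_model_fixture <- function() {
  path <- system.file("extdata", "core_model.tsv", package = "methanoflux",
                      mustWork = TRUE)
  model <- read_model(path, format = "reaction-table")
  model$annotations <- list(
    description = "desk-scale core fixture; lumped cofactors; illustrative biomass",
    uptake_reaction = "MEOHt", o2_reaction = "O2t",
    formate_reaction = "FORt", atpm_reaction = "ATPM",
    biomass_reaction = "BIOMASS", atp_metabolite = "ATP",
    glycogen_metabolite = "GLYCOGEN", glycogen_mw = 0.162,
    eps_metabolite = "EPS", eps_mw = 0.162,
    emp_reaction = "EMP", ed_reaction = "EDD",
    pdh_reaction = "PDH", mcl_reaction = "MCL",
    fumarase_reaction = "FUM", akgdh_reaction = "AKGDH",
    scs_reaction = "SCS", fdh_reaction = "FDH")
  model
}
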