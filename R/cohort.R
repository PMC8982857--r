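# Linked-cohort container and delimited-table IO.
#
# A cohort is five joinable tables keyed on participant id (pid):
#   participants : pid, enrol_date, sex, age_at_enrol
#   diagnoses    : pid, code_system (ICD10/ICD9), code, position, event_date
#   procedures   : pid, code_system (OPCS4), code, event_date
#   deaths       : one row per recorded cause: pid, death_date, code_system,
#                  code, role (underlying/contributing)
#   self_reports : pid, category (illness/procedure), item_code

.COHORT_TABLES <- c("participants", "diagnoses", "procedures", "deaths",
                    "self_reports")

.COHORT_COLS <- list(
  participants = c("pid", "enrol_date", "sex", "age_at_enrol"),
  diagnoses    = c("pid", "code_system", "code", "position", "event_date"),
  procedures   = c("pid", "code_system", "code", "event_date"),
  deaths       = c("pid", "death_date", "code_system", "code", "role"),
  self_reports = c("pid", "category", "item_code")
)

.DATE_COLS <- list(
  participants = "enrol_date", diagnoses = "event_date",
  procedures = "event_date", deaths = "death_date", self_reports = character()
)

.empty_cohort_table <- function(name) {
  cols <- .COHORT_COLS[[name]]
  out <- data.table::setnames(
    data.table::as.data.table(rep(list(character()), length(cols))), cols)
  for (dc in .DATE_COLS[[name]]) out[[dc]] <- as.Date(character())
  if (name == "participants") out[["age_at_enrol"]] <- integer()
  out[]
}

.canonical_sort <- function(tab, name) {
  ord <- switch(name,
    participants = "pid",
    diagnoses    = c("pid", "event_date", "code_system", "code", "position"),
    procedures   = c("pid", "event_date", "code_system", "code"),
    deaths       = c("pid", "role", "code_system", "code"),
    self_reports = c("pid", "category", "item_code"))
  data.table::setorderv(tab, ord, na.last = FALSE)
  tab
}

#' Construct a linked EHR cohort
#'
#' Bundles the five source tables into a validated `cad_cohort`. Columns are
#' coerced to canonical types (character ids and codes, `Date` dates, integer
#' age) and each table is canonically sorted, so two cohorts built from the
#' same rows in any order compare identical.
#'
#' @param participants Baseline table with columns `pid`, `enrol_date`,
#'   `sex` (`"male"`/`"female"`), `age_at_enrol`.
#' @param diagnoses Hospital diagnosis table (`pid`, `code_system`, `code`,
#'   `position` = `"primary"`/`"secondary"`, `event_date`).
#' @param procedures Hospital procedure table (`pid`, `code_system`, `code`,
#'   `event_date`).
#' @param deaths Death-registry table, one row per cause (`pid`,
#'   `death_date`, `code_system`, `code`, `role` =
#'   `"underlying"`/`"contributing"`).
#' @param self_reports Baseline questionnaire items (`pid`, `category` =
#'   `"illness"`/`"procedure"`, `item_code`).
#' @return A `cad_cohort`: named list of data.tables.
#' @export
cad_cohort <- function(participants,
                       diagnoses = NULL, procedures = NULL,
                       deaths = NULL, self_reports = NULL) {
  tabs <- list(participants = participants, diagnoses = diagnoses,
               procedures = procedures, deaths = deaths,
               self_reports = self_reports)
  for (nm in .COHORT_TABLES) {
    tab <- tabs[[nm]]
    if (is.null(tab)) { tabs[[nm]] <- .empty_cohort_table(nm); next }
    tab <- data.table::as.data.table(tab)
    miss <- setdiff(.COHORT_COLS[[nm]], names(tab))
    if (length(miss))
      .stopf("table '%s' is missing required column(s): %s", nm,
             paste(miss, collapse = ", "))
    tab <- tab[, .COHORT_COLS[[nm]], with = FALSE]
    tab[, pid := as.character(pid)]
    for (dc in .DATE_COLS[[nm]]) tab[[dc]] <- .as_date(tab[[dc]])
    for (cc in intersect(c("code_system", "code", "position", "role",
                           "category", "item_code", "sex"), names(tab)))
      tab[[cc]] <- as.character(tab[[cc]])
    # canonical text forms, idempotent with what read_cohort applies
    if ("code_system" %in% names(tab))
      tab[, code_system := toupper(trimws(code_system))]
    if ("code" %in% names(tab))
      tab[, code := normalize_code(code, strict = FALSE)]
    if ("item_code" %in% names(tab))
      tab[, item_code := normalize_code(item_code, strict = FALSE)]
    for (cc in intersect(c("position", "role", "category", "sex"),
                         names(tab)))
      tab[[cc]] <- tolower(trimws(tab[[cc]]))
    if (nm == "participants") tab[, age_at_enrol := as.integer(age_at_enrol)]
    tabs[[nm]] <- .canonical_sort(tab, nm)
  }

  p <- tabs$participants
  if (anyDuplicated(p$pid))
    .stopf("duplicate pid in participants: %s",
           paste(head(unique(p$pid[duplicated(p$pid)]), 5), collapse = ", "))
  bad_sex <- setdiff(unique(p$sex), c("male", "female"))
  if (length(bad_sex))
    .stopf("participants$sex must be 'male'/'female'; found: %s",
           paste(head(bad_sex, 5), collapse = ", "))
  for (nm in setdiff(.COHORT_TABLES, "participants")) {
    orphan <- setdiff(tabs[[nm]]$pid, p$pid)
    if (length(orphan))
      .stopf("table '%s' refers to pid(s) absent from participants: %s",
             nm, paste(head(orphan, 5), collapse = ", "))
  }

  structure(tabs, class = "cad_cohort")
}

#' @export
print.cad_cohort <- function(x, ...) {
  cat("<cad_cohort>\n")
  for (nm in .COHORT_TABLES)
    cat(sprintf("  %-13s %8d rows\n", nm, nrow(x[[nm]])))
  rej <- attr(x, "rejects")
  if (!is.null(rej) && nrow(rej))
    cat(sprintf("  (%d input row(s) rejected; see cohort_rejects())\n",
                nrow(rej)))
  invisible(x)
}

#' Rows rejected while reading a cohort
#'
#' @param cohort A `cad_cohort` returned by [read_cohort()].
#' @return data.table with columns `table`, `row` (input row number after the
#'   header), `pid`, `reason`; zero rows if nothing was rejected.
#' @export
cohort_rejects <- function(cohort) {
  attr(cohort, "rejects") %||%
    data.table(table = character(), row = integer(),
               pid = character(), reason = character())
}

.apply_schema <- function(dt, map, table_name) {
  if (is.null(map)) return(dt)
  for (logical_name in names(map)) {
    actual <- map[[logical_name]]
    if (!actual %in% names(dt))
      .stopf("schema maps '%s' to column '%s' but table '%s' has no such column",
             logical_name, actual, table_name)
    data.table::setnames(dt, actual, logical_name)
  }
  dt
}

#' Read a linked cohort from delimited files
#'
#' Reads the five source tables (comma- or tab-delimited with a header row),
#' renames columns through an optional schema mapping, normalizes clinical
#' codes, parses dates, and applies referential-integrity filtering. Rows
#' that fail parsing (bad/missing dates, empty codes, unknown categorical
#' values, pids absent from the participants table) are collected into a
#' rejects report attached to the result - never silently dropped.
#'
#' @param paths Either a directory containing `participants.csv`,
#'   `diagnoses.csv`, `procedures.csv`, `deaths.csv`, `self_reports.csv`
#'   (`.tsv` also accepted), or a named list/vector of file paths keyed by
#'   those table names. Only `participants` is required to exist.
#' @param schema Optional schema mapping logical field names to actual column
#'   names: either a YAML file path or a nested list, e.g.
#'   `list(participants = list(pid = "eid", enrol_date = "date_recr"))`.
#' @return A [cad_cohort()] with a rejects report (see [cohort_rejects()]).
#' @export
read_cohort <- function(paths, schema = NULL) {
  if (length(paths) == 1 && is.character(paths) && is.null(names(paths)) &&
      dir.exists(paths)) {
    found <- lapply(.COHORT_TABLES, function(nm) {
      for (ext in c(".csv", ".tsv")) {
        f <- file.path(paths, paste0(nm, ext))
        if (file.exists(f)) return(f)
      }
      NULL
    })
    names(found) <- .COHORT_TABLES
    paths <- found[!vapply(found, is.null, logical(1))]
  }
  paths <- as.list(paths)
  bad <- setdiff(names(paths), .COHORT_TABLES)
  if (length(bad))
    .stopf("unknown table name(s) in paths: %s", paste(bad, collapse = ", "))
  if (!"participants" %in% names(paths))
    .stopf("a participants table is required")

  if (is.character(schema) && length(schema) == 1)
    schema <- yaml::read_yaml(schema)

  rejects <- list()
  note <- function(tab, rows, pids, reason) {
    if (!length(rows)) return()
    rejects[[length(rejects) + 1L]] <<-
      data.table(table = tab, row = as.integer(rows),
                 pid = as.character(pids), reason = reason)
  }

  raw <- list()
  for (nm in .COHORT_TABLES) {
    if (is.null(paths[[nm]])) { raw[[nm]] <- .empty_cohort_table(nm); next }
    f <- paths[[nm]]
    if (!file.exists(f)) .stopf("file for table '%s' not found: %s", nm, f)
    dt <- data.table::fread(f, colClasses = "character", na.strings = c("", "NA"))
    dt <- .apply_schema(dt, schema[[nm]], nm)
    miss <- setdiff(.COHORT_COLS[[nm]], names(dt))
    if (length(miss))
      .stopf("table '%s' is missing required column(s): %s", nm,
             paste(miss, collapse = ", "))
    dt <- dt[, .COHORT_COLS[[nm]], with = FALSE]
    dt[, .row := .I]

    # row-level cleaning; failures go to the rejects report
    keep <- rep(TRUE, nrow(dt))
    if (nrow(dt)) {
      if (anyNA(dt$pid)) {
        i <- which(is.na(dt$pid))
        note(nm, dt$.row[i], NA, "missing_pid"); keep[i] <- FALSE
      }
      for (dc in .DATE_COLS[[nm]]) {
        parsed <- .as_date(dt[[dc]])
        i <- which(is.na(parsed) & keep)
        note(nm, dt$.row[i], dt$pid[i], paste0("missing_or_unparseable_", dc))
        keep[i] <- FALSE
        dt[[dc]] <- parsed
      }
      if ("code" %in% names(dt)) {
        dt[, code_system := toupper(trimws(code_system))]
        dt[, code := normalize_code(code, strict = FALSE)]
        i <- which(!nzchar(dt$code) & keep)
        note(nm, dt$.row[i], dt$pid[i], "empty_code_after_normalization")
        keep[i] <- FALSE
      }
      if ("position" %in% names(dt)) {
        dt[, position := tolower(trimws(position))]
        i <- which(!dt$position %in% c("primary", "secondary") & keep)
        note(nm, dt$.row[i], dt$pid[i], "unknown_diagnosis_position")
        keep[i] <- FALSE
      }
      if ("role" %in% names(dt)) {
        dt[, role := tolower(trimws(role))]
        i <- which(!dt$role %in% c("underlying", "contributing") & keep)
        note(nm, dt$.row[i], dt$pid[i], "unknown_cause_role")
        keep[i] <- FALSE
      }
      if ("category" %in% names(dt)) {
        dt[, category := tolower(trimws(category))]
        i <- which(!dt$category %in% c("illness", "procedure") & keep)
        note(nm, dt$.row[i], dt$pid[i], "unknown_selfreport_category")
        keep[i] <- FALSE
      }
      if ("item_code" %in% names(dt)) {
        dt[, item_code := normalize_code(item_code, strict = FALSE)]
        i <- which(!nzchar(dt$item_code) & keep)
        note(nm, dt$.row[i], dt$pid[i], "empty_item_code"); keep[i] <- FALSE
      }
      if (nm == "participants") {
        dt[, sex := tolower(trimws(sex))]
        i <- which(!dt$sex %in% c("male", "female") & keep)
        note(nm, dt$.row[i], dt$pid[i], "unknown_sex"); keep[i] <- FALSE
        suppressWarnings(dt[, age_at_enrol := as.integer(age_at_enrol)])
        i <- which(is.na(dt$age_at_enrol) & keep)
        note(nm, dt$.row[i], dt$pid[i], "missing_or_unparseable_age")
        keep[i] <- FALSE
      }
    }
    raw[[nm]] <- dt[keep]
  }

  p <- raw$participants
  if (anyDuplicated(p$pid))
    .stopf("duplicate pid in participants: %s",
           paste(head(unique(p$pid[duplicated(p$pid)]), 5), collapse = ", "))
  for (nm in setdiff(.COHORT_TABLES, "participants")) {
    orphan <- which(!raw[[nm]]$pid %in% p$pid)
    note(nm, raw[[nm]]$.row[orphan], raw[[nm]]$pid[orphan],
         "pid_not_in_participants")
    if (length(orphan)) raw[[nm]] <- raw[[nm]][-orphan]
  }
  for (nm in .COHORT_TABLES)
    if (".row" %in% names(raw[[nm]]))
      data.table::set(raw[[nm]], j = ".row", value = NULL)

  cohort <- cad_cohort(raw$participants, raw$diagnoses, raw$procedures,
                       raw$deaths, raw$self_reports)
  attr(cohort, "rejects") <- if (length(rejects)) {
    data.table::rbindlist(rejects)
  } else {
    data.table(table = character(), row = integer(),
               pid = character(), reason = character())
  }
  cohort
}

#' Write a cohort back to delimited files
#'
#' Writes the five tables as CSV in canonical column order and canonical row
#' sort, so `write_cohort(read_cohort(x))` reproduces the same normalized
#' files byte for byte.
#'
#' @param cohort A `cad_cohort`.
#' @param dir Output directory (created if needed).
#' @param rejects If `TRUE` and the cohort carries a rejects report, also
#'   write `rejects.csv`.
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir, rejects = TRUE) {
  stopifnot(inherits(cohort, "cad_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (nm in .COHORT_TABLES) {
    f <- file.path(dir, paste0(nm, ".csv"))
    data.table::fwrite(cohort[[nm]], f)
    files <- c(files, f)
  }
  rej <- attr(cohort, "rejects")
  if (rejects && !is.null(rej) && nrow(rej)) {
    f <- file.path(dir, "rejects.csv")
    data.table::fwrite(rej, f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Validate a cohort against temporal and coding sanity rules
#'
#' Pure reporting: counts rule violations without mutating or dropping data.
#' Flagged classes are deaths recorded before enrolment (dirty but possible in
#' real linkage), any event or death dated after the censor date, rows using
#' an unrecognized code system, and participants with conflicting death dates.
#'
#' @param cohort A `cad_cohort`.
#' @param censor_date Administrative censor date; default
#'   [default_censor_date()].
#' @return A `cad_validation` list of violation counts.
#' @export
validate_cohort <- function(cohort, censor_date = default_censor_date()) {
  stopifnot(inherits(cohort, "cad_cohort"))
  censor_date <- .as_date(censor_date)
  p <- cohort$participants
  dd <- cohort$deaths[, .(death_date = .min_date(death_date),
                          n_dates = data.table::uniqueN(death_date)),
                      by = pid]
  pj <- merge(p[, .(pid, enrol_date)], dd, by = "pid", all.x = TRUE)

  after_censor <-
    sum(cohort$diagnoses$event_date > censor_date, na.rm = TRUE) +
    sum(cohort$procedures$event_date > censor_date, na.rm = TRUE) +
    sum(dd$death_date > censor_date, na.rm = TRUE)
  unknown_cs <-
    sum(!cohort$diagnoses$code_system %in% c("ICD10", "ICD9")) +
    sum(!cohort$procedures$code_system %in% "OPCS4") +
    sum(!cohort$deaths$code_system %in% "ICD10")

  structure(list(
    n_participants = nrow(p),
    death_before_enrolment = sum(pj$death_date < pj$enrol_date, na.rm = TRUE),
    events_after_censor = after_censor,
    unknown_code_system = unknown_cs,
    inconsistent_death_date = sum(dd$n_dates > 1L),
    censor_date = censor_date
  ), class = "cad_validation")
}

#' @export
print.cad_validation <- function(x, ...) {
  cat("<cad_validation>", sprintf("(censor %s)\n", x$censor_date))
  for (nm in c("death_before_enrolment", "events_after_censor",
               "unknown_code_system", "inconsistent_death_date"))
    cat(sprintf("  %-25s %d\n", nm, x[[nm]]))
  invisible(x)
}
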