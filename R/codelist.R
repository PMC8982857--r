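# Code lists: normalization, longest-prefix matching, and extraction of
# dated qualifying events from a cohort.

#' Normalize a clinical code
#'
#' Uppercases and strips dots and all whitespace, the canonical form used
#' throughout the package (`"I21.4"` -> `"I214"`, `" k401"` -> `"K401"`).
#'
#' @param code Character vector of raw codes.
#' @param strict If `TRUE` (default) an empty-after-normalization code is an
#'   error; if `FALSE` it is returned as `""` for the caller to handle.
#' @return Character vector of normalized codes.
#' @export
normalize_code <- function(code, strict = TRUE) {
  out <- toupper(gsub("[.[:space:]]", "", as.character(code)))
  out[is.na(code)] <- ""
  if (strict && any(!nzchar(out)))
    .stopf("code empty after normalization at position %d",
           which(!nzchar(out))[1])
  out
}

#' Construct a phenotype code list
#'
#' A code list is a set of normalized code *prefixes*, each tagged with a
#' coding system (`ICD10`, `ICD9`, `OPCS4`, or `SELFREPORT` for baseline
#' procedure tokens) and a phenotype tag (`MI` or `CAD_noMI`). Matching is
#' longest-prefix-wins, which is also how exclusions are expressed: with
#' `I25 -> CAD_noMI` and `I252 -> MI` in the same list, `I252x` codes match
#' MI while all other `I25x` codes match CAD without MI.
#'
#' Two entries with the *identical* (code_system, prefix) but different
#' phenotype tags are ambiguous and rejected; cross-tag strict-prefix
#' overlaps are legal (resolved by prefix length).
#'
#' @param entries data.frame with columns `code_system`, `code`,
#'   `phenotype_tag`, and optionally `description`.
#' @param name,version Metadata carried along for provenance.
#' @return A `cad_code_list`.
#' @export
cad_code_list <- function(entries, name = "codelist", version = "1") {
  e <- data.table::as.data.table(entries)
  miss <- setdiff(c("code_system", "code", "phenotype_tag"), names(e))
  if (length(miss))
    .stopf("code list is missing column(s): %s", paste(miss, collapse = ", "))
  if (!"description" %in% names(e)) e[, description := ""]
  e <- e[, .(code_system = toupper(trimws(code_system)),
             prefix = normalize_code(code),
             phenotype_tag = as.character(phenotype_tag),
             description = as.character(description))]
  bad_cs <- setdiff(unique(e$code_system), .CODE_SYSTEMS)
  if (length(bad_cs))
    .stopf("unknown code system(s): %s", paste(bad_cs, collapse = ", "))
  bad_tag <- setdiff(unique(e$phenotype_tag), .PHENO_TAGS)
  if (length(bad_tag))
    .stopf("unknown phenotype tag(s): %s (expected %s)",
           paste(bad_tag, collapse = ", "), paste(.PHENO_TAGS, collapse = "/"))
  amb <- e[, .(ntag = data.table::uniqueN(phenotype_tag)),
           by = .(code_system, prefix)][ntag > 1L]
  if (nrow(amb))
    .stopf("ambiguous entries (same code_system+prefix, different tags): %s",
           paste(head(paste(amb$code_system, amb$prefix), 5), collapse = ", "))
  e <- unique(e, by = c("code_system", "prefix", "phenotype_tag"))
  data.table::setorder(e, code_system, prefix, phenotype_tag)
  structure(list(entries = e[], name = name, version = version),
            class = "cad_code_list")
}

#' @export
print.cad_code_list <- function(x, ...) {
  cat(sprintf("<cad_code_list> '%s' v%s: %d entries\n",
              x$name, x$version, nrow(x$entries)))
  print(x$entries[, .N, by = .(code_system, phenotype_tag)])
  invisible(x)
}

#' Read a code list from CSV
#'
#' Expected columns: `code_system`, `code`, `phenotype_tag`, `description`.
#'
#' @param path CSV/TSV file.
#' @inheritParams cad_code_list
#' @return A [cad_code_list()].
#' @export
read_code_list <- function(path, name = basename(path), version = "1") {
  cad_code_list(data.table::fread(path, colClasses = "character"),
                name = name, version = version)
}

#' Default CAD/MI code list
#'
#' The code lists shipped with the package as replaceable defaults
#' (swap in study-specific lists via [read_code_list()]): MI as ICD-10
#' I21/I22/I23/I241/I252 and ICD-9 410/412; CAD without MI as ICD-10
#' I20/I240/I248/I249/I25 (I252 excluded via the longest-prefix rule),
#' OPCS-4 revascularisation codes K40-K46/K49/K50/K75, and self-reported
#' revascularisation procedure tokens (CABG/PTCA/angioplasty).
#'
#' @return A [cad_code_list()].
#' @export
default_code_list <- function() {
  read_code_list(system.file("extdata", "cad_codes_default.csv",
                             package = "phenocad", mustWork = TRUE),
                 name = "phenocad_default", version = "1")
}

#' Match codes against a code list (longest prefix wins)
#'
#' For each code, returns the entry whose prefix is the longest prefix of the
#' code within the same code system, or no match. An entry never matches a
#' code shorter than the entry itself. Exact-duplicate prefixes across tags
#' are barred by the constructor; for equal-length hypotheticals MI takes
#' priority over CAD_noMI.
#'
#' @param codes Character vector of *normalized* codes.
#' @param codelist A [cad_code_list()].
#' @param code_system Single code system the codes belong to.
#' @return data.table with one row per code: `code`, `matched` (logical),
#'   `prefix`, `phenotype_tag` (NA when unmatched).
#' @export
match_code <- function(codes, codelist, code_system) {
  stopifnot(inherits(codelist, "cad_code_list"), length(code_system) == 1)
  cs <- toupper(code_system)
  ents <- codelist$entries[code_system == cs]
  n <- length(codes)
  best_len <- integer(n)
  best_idx <- rep(NA_integer_, n)
  if (nrow(ents)) {
    # scan entries ordered by (length, MI-last) so later hits override
    # shorter ones, and MI wins length ties
    ord <- order(nchar(ents$prefix), ents$phenotype_tag == "MI")
    for (i in ord) {
      len <- nchar(ents$prefix[i])
      hit <- startsWith(codes, ents$prefix[i]) & len >= best_len
      best_idx[hit] <- i
      best_len[hit] <- len
    }
  }
  data.table(
    code = codes,
    matched = !is.na(best_idx),
    prefix = ents$prefix[best_idx],
    phenotype_tag = ents$phenotype_tag[best_idx]
  )
}

#' Extract dated qualifying events from a cohort
#'
#' Scans hospital diagnoses, hospital procedures, death-registry causes and
#' self-reported procedure items against a code list, emitting one qualifying
#' event per matching row. Death-registry causes are dated at the death date;
#' self-reported procedures are undated (classified as prevalent downstream).
#' Events dated after the censor date are dropped before classification.
#'
#' @param cohort A [cad_cohort()].
#' @param codelist A [cad_code_list()].
#' @param config An [algorithm_config()]; controls the censor date, eligible
#'   diagnosis positions, eligible death-cause roles, and which sources count
#'   towards each phenotype tag.
#' @return data.table sorted by (pid, event_date): `pid`, `phenotype_tag`,
#'   `event_date` (`NA` for self-reported procedures), `source`
#'   (`hospital_dx`, `hospital_proc`, `death_registry`, `selfreport_proc`),
#'   `code`.
#' @export
extract_events <- function(cohort, codelist = default_code_list(),
                           config = algorithm_config()) {
  stopifnot(inherits(cohort, "cad_cohort"),
            inherits(config, "cad_algorithm_config"))
  censor <- config$censor_date
  pieces <- list()

  dx <- cohort$diagnoses
  if (config$diagnosis_positions == "primary") dx <- dx[position == "primary"]
  if (nrow(dx)) {
    for (cs in unique(dx$code_system)) {
      sub <- dx[code_system == cs]
      m <- match_code(sub$code, codelist, cs)
      sub <- sub[m$matched]
      if (nrow(sub))
        pieces[[length(pieces) + 1L]] <- sub[, .(
          pid, phenotype_tag = m$phenotype_tag[m$matched],
          event_date, source = "hospital_dx", code)]
    }
  }

  pr <- cohort$procedures
  if (nrow(pr)) {
    for (cs in unique(pr$code_system)) {
      sub <- pr[code_system == cs]
      m <- match_code(sub$code, codelist, cs)
      sub <- sub[m$matched]
      if (nrow(sub))
        pieces[[length(pieces) + 1L]] <- sub[, .(
          pid, phenotype_tag = m$phenotype_tag[m$matched],
          event_date, source = "hospital_proc", code)]
    }
  }

  de <- cohort$deaths[role %in% config$death_roles]
  if (nrow(de)) {
    m <- match_code(de$code, codelist, "ICD10")
    de <- de[m$matched]
    if (nrow(de))
      pieces[[length(pieces) + 1L]] <- de[, .(
        pid, phenotype_tag = m$phenotype_tag[m$matched],
        event_date = death_date, source = "death_registry", code)]
  }

  sp <- cohort$self_reports[category == "procedure"]
  if (nrow(sp)) {
    m <- match_code(sp$item_code, codelist, "SELFREPORT")
    sp <- sp[m$matched]
    if (nrow(sp))
      pieces[[length(pieces) + 1L]] <- sp[, .(
        pid, phenotype_tag = m$phenotype_tag[m$matched],
        event_date = as.Date(NA), source = "selfreport_proc",
        code = item_code)]
  }

  ev <- if (length(pieces)) data.table::rbindlist(pieces) else
    data.table(pid = character(), phenotype_tag = character(),
               event_date = as.Date(character()), source = character(),
               code = character())

  # eligibility: each source x tag pair is independently configurable
  keep <- logical(nrow(ev))
  for (tag in .PHENO_TAGS)
    keep <- keep | (ev$phenotype_tag == tag &
                      ev$source %in% config$sources[[tag]])
  ev <- ev[keep]
  ev <- ev[is.na(event_date) | event_date <= censor]
  data.table::setorder(ev, pid, event_date, source, code, na.last = FALSE)
  ev[]
}
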