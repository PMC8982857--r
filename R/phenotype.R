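# The hierarchical classification algorithm: every participant receives
# exactly one of six CAD sub-phenotype labels or one of two control labels.
#
# Hierarchy (a participant is censored from further classification at the
# first step that claims them):
#   1. EHR-coded MI            -> prevalent_MI / incident_MI
#   2. EHR-coded CAD without MI (incl. self-reported revascularisation
#      procedures)             -> prevalent_CAD_noMI / incident_CAD_noMI
#   3. self-reported heart attack -> sr_MI
#   4. self-reported angina       -> sr_CAD_noMI
#   5. otherwise control       -> never_CAD (died) / no_CAD (alive)

#' Configuration of the phenotyping algorithm
#'
#' @param censor_date Administrative censor date; events after it are ignored.
#' @param resolution When qualifying events exist both before and after
#'   enrolment within one phenotype tag, classify as `"incident"` (default;
#'   the more recent event has greater certainty of date and diagnosis) or
#'   `"prevalent"`.
#' @param on_enrolment_date_is Whether an event dated exactly on the
#'   enrolment date counts as `"prevalent"` (default) or `"incident"`.
#' @param diagnosis_positions `"all"` (default; primary and secondary
#'   hospital diagnosis positions both count) or `"primary"`.
#' @param sources Named list giving, per phenotype tag, the event sources
#'   that may contribute qualifying events. Defaults: MI from hospital
#'   diagnoses and death-registry causes; CAD without MI from hospital
#'   diagnoses, hospital procedures, death-registry causes and self-reported
#'   procedures.
#' @param death_roles Death-registry cause roles that count
#'   (default: both `"underlying"` and `"contributing"`).
#' @param sr_illness Named map from normalized self-reported illness tokens
#'   to phenotype tags, used by the lower hierarchy steps.
#' @return A `cad_algorithm_config`.
#' @export
algorithm_config <- function(censor_date = default_censor_date(),
                             resolution = c("incident", "prevalent"),
                             on_enrolment_date_is = c("prevalent", "incident"),
                             diagnosis_positions = c("all", "primary"),
                             sources = list(
                               MI = c("hospital_dx", "death_registry"),
                               CAD_noMI = c("hospital_dx", "hospital_proc",
                                            "death_registry",
                                            "selfreport_proc")),
                             death_roles = c("underlying", "contributing"),
                             sr_illness = c(HEART_ATTACK = "MI",
                                            ANGINA = "CAD_noMI")) {
  resolution <- match.arg(resolution)
  on_enrolment_date_is <- match.arg(on_enrolment_date_is)
  diagnosis_positions <- match.arg(diagnosis_positions)
  if (!setequal(names(sources), .PHENO_TAGS))
    .stopf("sources must be a named list with elements %s",
           paste(.PHENO_TAGS, collapse = " and "))
  for (tag in .PHENO_TAGS) {
    bad <- setdiff(sources[[tag]], .EVENT_SOURCES)
    if (length(bad))
      .stopf("unknown source name(s) for %s: %s (known: %s)", tag,
             paste(bad, collapse = ", "),
             paste(.EVENT_SOURCES, collapse = ", "))
  }
  bad_role <- setdiff(death_roles, c("underlying", "contributing"))
  if (length(bad_role))
    .stopf("unknown death cause role(s): %s", paste(bad_role, collapse = ", "))
  if (!all(sr_illness %in% .PHENO_TAGS))
    .stopf("sr_illness values must be phenotype tags (%s)",
           paste(.PHENO_TAGS, collapse = "/"))
  structure(list(censor_date = .as_date(censor_date),
                 resolution = resolution,
                 on_enrolment_date_is = on_enrolment_date_is,
                 diagnosis_positions = diagnosis_positions,
                 sources = sources, death_roles = death_roles,
                 sr_illness = sr_illness),
            class = "cad_algorithm_config")
}

# Vectorized classifier core. `events` as produced by extract_events();
# `participants` needs pid/enrol_date; `self_reports` the questionnaire
# table; `death_dates` a data.table(pid, death_date).
.classify_core <- function(events, participants, self_reports, death_dates,
                           config) {
  censor <- config$censor_date
  res_incident <- config$resolution == "incident"
  base <- data.table(pid = participants$pid,
                     enrol_date = .as_date(participants$enrol_date))

  # per pid x tag: any/earliest event on each side of enrolment
  if (nrow(events)) {
    ev <- merge(events, base, by = "pid")
    if (config$on_enrolment_date_is == "prevalent") {
      ev[, prev_side := is.na(event_date) | event_date <= enrol_date]
    } else {
      ev[, prev_side := is.na(event_date) | event_date < enrol_date]
    }
    agg <- ev[, .(
      prev = any(prev_side),
      inc = any(!prev_side),
      prev_date = .min_date(event_date[prev_side]),
      inc_date = .min_date(event_date[!prev_side])
    ), by = .(pid, phenotype_tag)]
  } else {
    agg <- data.table(pid = character(), phenotype_tag = character(),
                      prev = logical(), inc = logical(),
                      prev_date = as.Date(character()),
                      inc_date = as.Date(character()))
  }

  for (tag in .PHENO_TAGS) {
    sub <- agg[phenotype_tag == tag]
    data.table::setnames(sub, c("prev", "inc", "prev_date", "inc_date"),
                         paste0(c("prev_", "inc_", "prev_date_", "inc_date_"),
                                tag))
    sub[, phenotype_tag := NULL]
    base <- merge(base, sub, by = "pid", all.x = TRUE)
  }
  for (col in paste0(rep(c("prev_", "inc_"), 2),
                     rep(.PHENO_TAGS, each = 2)))
    base[[col]] <- !is.na(base[[col]]) & base[[col]]

  # self-reported illness flags via the configured vocabulary
  sr <- self_reports[category == "illness"]
  sr_tag <- config$sr_illness[sr$item_code]
  sr_mi <- base$pid %in% unique(sr$pid[!is.na(sr_tag) & sr_tag == "MI"])
  sr_cad <- base$pid %in%
    unique(sr$pid[!is.na(sr_tag) & sr_tag == "CAD_noMI"])

  dd <- death_dates[!is.na(death_date), .(death_date = .min_date(death_date)),
                    by = pid]
  base <- merge(base, dd, by = "pid", all.x = TRUE)
  died <- !is.na(base$death_date) & base$death_date <= censor

  # step 1: EHR MI
  mi_any <- base$prev_MI | base$inc_MI
  mi_incident <- base$inc_MI & (!base$prev_MI | res_incident)
  # step 2: EHR / self-report-procedure CAD without MI
  cad_any <- !mi_any & (base$prev_CAD_noMI | base$inc_CAD_noMI)
  cad_incident <- base$inc_CAD_noMI & (!base$prev_CAD_noMI | res_incident)

  label <- data.table::fcase(
    mi_any & mi_incident, "incident_MI",
    mi_any, "prevalent_MI",
    cad_any & cad_incident, "incident_CAD_noMI",
    cad_any, "prevalent_CAD_noMI",
    sr_mi, "sr_MI",
    sr_cad, "sr_CAD_noMI",
    died, "never_CAD",
    rep(TRUE, nrow(base)), "no_CAD"
  )
  q_date <- data.table::fcase(
    label == "incident_MI", base$inc_date_MI,
    label == "prevalent_MI", base$prev_date_MI,
    label == "incident_CAD_noMI", base$inc_date_CAD_noMI,
    label == "prevalent_CAD_noMI", base$prev_date_CAD_noMI,
    rep(TRUE, nrow(base)), as.Date(NA)
  )

  out <- data.table(pid = base$pid, label = label, qualifying_date = q_date)

  # source/code of the chosen qualifying event
  out[, source := NA_character_]
  out[, qualifying_code := NA_character_]
  out[label %in% c("sr_MI", "sr_CAD_noMI"), source := "selfreport_illness"]
  ehr <- out[label %in% c("prevalent_MI", "incident_MI",
                          "prevalent_CAD_noMI", "incident_CAD_noMI")]
  if (nrow(ehr) && nrow(events)) {
    ehr[, tag := data.table::fifelse(label %in% c("prevalent_MI", "incident_MI"),
                                     "MI", "CAD_noMI")]
    evs <- events[, .(pid, phenotype_tag, event_date, source, code)]
    evs[, pr := match(source, .EVENT_SOURCES)]
    hit <- merge(ehr[, .(pid, tag, qualifying_date)], evs,
                 by.x = c("pid", "tag", "qualifying_date"),
                 by.y = c("pid", "phenotype_tag", "event_date"))
    data.table::setorder(hit, pid, pr, code)
    hit <- unique(hit, by = "pid")
    out[match(hit$pid, pid), `:=`(source = hit$source,
                                  qualifying_code = hit$code)]
    # prevalent CAD supported only by an undated self-reported procedure
    und <- out$label == "prevalent_CAD_noMI" & is.na(out$qualifying_date)
    if (any(und)) {
      spx <- events[source == "selfreport_proc"]
      out[und, source := "selfreport_proc"]
      out[und, qualifying_code := spx$code[match(pid, spx$pid)]]
    }
  }

  data.table::setorder(out, pid)
  out[]
}

#' Classify one participant
#'
#' Applies the full hierarchy to a single participant given their qualifying
#' events (already censor-filtered, as produced by [extract_events()]) and
#' self-report items. Total over valid inputs: always returns a label.
#'
#' @param events data.table of qualifying events for this pid (possibly
#'   zero rows) with columns `pid`, `phenotype_tag`, `event_date`, `source`,
#'   `code`.
#' @param participant List or one-row data.frame with `pid`, `enrol_date`
#'   and optionally `death_date`.
#' @param self_reports Optional data.table of this participant's
#'   questionnaire items (`pid`, `category`, `item_code`).
#' @param config An [algorithm_config()].
#' @return One-row data.table: `pid`, `label`, `qualifying_date`, `source`,
#'   `qualifying_code`.
#' @export
classify_participant <- function(events = NULL, participant,
                                 self_reports = NULL,
                                 config = algorithm_config()) {
  participant <- as.list(participant)
  p <- data.table(pid = as.character(participant$pid),
                  enrol_date = .as_date(participant$enrol_date))
  ev <- if (is.null(events) || !nrow(events)) {
    data.table(pid = character(), phenotype_tag = character(),
               event_date = as.Date(character()), source = character(),
               code = character())
  } else data.table::as.data.table(events)
  sr <- if (is.null(self_reports) || !nrow(self_reports)) {
    .empty_cohort_table("self_reports")
  } else {
    s <- data.table::as.data.table(self_reports)
    s[, item_code := normalize_code(item_code, strict = FALSE)]
    s
  }
  dd <- data.table(pid = p$pid,
                   death_date = .as_date(participant$death_date %||% NA))
  .classify_core(ev, p, sr, dd, config)
}

#' Run the full phenotyping algorithm over a cohort
#'
#' Extracts qualifying events with the supplied code list, applies the
#' hierarchical classifier to every participant and returns one assignment
#' per pid together with a run log of counts at each hierarchy step in
#' execution order (so module-wise runs can be reconciled with a full run).
#'
#' @param cohort A [cad_cohort()].
#' @param codelist A [cad_code_list()]; default [default_code_list()].
#' @param config An [algorithm_config()].
#' @return A `cad_assignments` data.table (`pid`, `label`,
#'   `qualifying_date`, `source`, `qualifying_code`) with the run log in
#'   `attr(, "log")` (see [run_log()]) and the config in `attr(, "config")`.
#' @export
run_algorithm <- function(cohort, codelist = default_code_list(),
                          config = algorithm_config()) {
  stopifnot(inherits(cohort, "cad_cohort"))
  events <- extract_events(cohort, codelist, config)
  dd <- cohort$deaths[, .(pid, death_date)]
  out <- .classify_core(events, cohort$participants, cohort$self_reports,
                        dd, config)

  cnt <- function(lbl) sum(out$label == lbl)
  log <- data.table(
    step = 1:11,
    description = c(
      "participants entering the algorithm",
      "EHR-coded MI identified",
      "assigned prevalent_MI",
      "assigned incident_MI",
      "EHR/self-report-procedure CAD without MI identified",
      "assigned prevalent_CAD_noMI",
      "assigned incident_CAD_noMI",
      "assigned sr_MI (self-reported heart attack)",
      "assigned sr_CAD_noMI (self-reported angina)",
      "assigned never_CAD (control, died)",
      "assigned no_CAD (control, alive)"),
    n = c(nrow(out),
          cnt("prevalent_MI") + cnt("incident_MI"),
          cnt("prevalent_MI"), cnt("incident_MI"),
          cnt("prevalent_CAD_noMI") + cnt("incident_CAD_noMI"),
          cnt("prevalent_CAD_noMI"), cnt("incident_CAD_noMI"),
          cnt("sr_MI"), cnt("sr_CAD_noMI"),
          cnt("never_CAD"), cnt("no_CAD")))

  data.table::setattr(out, "class",
                      c("cad_assignments", class(data.table())))
  data.table::setattr(out, "log", log)
  data.table::setattr(out, "config", config)
  out
}

#' Run log of a phenotyping run
#'
#' @param assignments A `cad_assignments` from [run_algorithm()].
#' @return data.table of step counts in execution order.
#' @export
run_log <- function(assignments) attr(assignments, "log")

#' @export
print.cad_assignments <- function(x, ...) {
  cat(sprintf("<cad_assignments> %d participants\n", nrow(x)))
  counts <- table(factor(x$label, levels = .PHENO_LABELS))
  for (nm in names(counts)) cat(sprintf("  %-20s %d\n", nm, counts[[nm]]))
  invisible(x)
}

#' Aggregate sub-phenotype counts into the all-CAD summary
#'
#' Combines the six sub-phenotype counts into an aggregated all-CAD total
#' and the complementary control count.
#'
#' @param x Either a `cad_assignments` table, or a numeric vector of counts:
#'   length 6 in hierarchy order (the six disease labels; supply `n_total`
#'   for the control count), length 8 (all labels), or named by label.
#' @param n_total Total cohort size, required to derive the control count
#'   when `x` has only the six disease counts.
#' @return List with `label_counts` (named, whichever labels were supplied),
#'   `all_cad`, `controls` (`NA` if underivable) and `n`.
#' @export
aggregate_all_cad <- function(x, n_total = NULL) {
  if (inherits(x, "cad_assignments") || (is.data.frame(x) && "label" %in% names(x))) {
    counts <- table(factor(x$label, levels = .PHENO_LABELS))
    counts <- setNames(as.numeric(counts), .PHENO_LABELS)
    n_total <- nrow(x)
  } else if (is.numeric(x)) {
    if (!is.null(names(x))) {
      bad <- setdiff(names(x), .PHENO_LABELS)
      if (length(bad))
        .stopf("unknown label(s): %s", paste(bad, collapse = ", "))
      counts <- x
    } else if (length(x) == 6) {
      counts <- setNames(x, .CASE_LABELS)
    } else if (length(x) == 8) {
      counts <- setNames(x, .PHENO_LABELS)
    } else {
      .stopf("unnamed counts must have length 6 or 8")
    }
  } else .stopf("x must be assignments or a numeric vector of counts")

  all_cad <- sum(counts[intersect(names(counts), .CASE_LABELS)])
  controls <- if (all(.CONTROL_LABELS %in% names(counts))) {
    sum(counts[.CONTROL_LABELS])
  } else if (!is.null(n_total)) n_total - all_cad else NA_real_
  n <- if (!is.null(n_total)) n_total else
    if (!is.na(controls)) all_cad + controls else NA_real_
  list(label_counts = counts, all_cad = all_cad, controls = controls, n = n)
}

#' Mortality split between all-CAD cases and controls
#'
#' Small formatter for headline mortality figures: total deaths and the
#' percentage dead in the aggregated all-CAD group and in the CAD-free
#' control group, at one decimal place.
#'
#' @param deaths_cad,deaths_controls Death counts in each group.
#' @param n_cad,n_controls Group sizes.
#' @param digits Decimal places for the percentages (default 1).
#' @return List with `deaths_total`, `cad_death_pct`, `control_death_pct`.
#' @export
cad_death_summary <- function(deaths_cad, deaths_controls, n_cad,
                              n_controls, digits = 1) {
  list(deaths_total = deaths_cad + deaths_controls,
       cad_death_pct = round(100 * deaths_cad / n_cad, digits),
       control_death_pct = round(100 * deaths_controls / n_controls, digits))
}

#' Compute the case/control mortality split from assignments
#'
#' Counts deaths on or before the censor date among the aggregated all-CAD
#' group and among controls, and formats them via [cad_death_summary()].
#'
#' @param assignments A `cad_assignments`.
#' @param cohort The matching [cad_cohort()].
#' @param censor_date Censor date; deaths after it do not count.
#' @return As [cad_death_summary()], plus `n_cad` and `n_controls`.
#' @export
summarize_mortality <- function(assignments, cohort,
                                censor_date = default_censor_date()) {
  censor_date <- .as_date(censor_date)
  dd <- cohort$deaths[!is.na(death_date), .(death_date = .min_date(death_date)),
                      by = pid]
  died <- dd$pid[dd$death_date <= censor_date]
  is_case <- assignments$label %in% .CASE_LABELS
  n_cad <- sum(is_case); n_controls <- sum(!is_case)
  deaths_cad <- sum(assignments$pid[is_case] %in% died)
  deaths_controls <- sum(assignments$pid[!is_case] %in% died)
  c(cad_death_summary(deaths_cad, deaths_controls, n_cad, n_controls),
    list(n_cad = n_cad, n_controls = n_controls,
         deaths_cad = deaths_cad, deaths_controls = deaths_controls))
}

#' Baseline characteristics by phenotype
#'
#' Means with standard deviations for continuous covariates and level
#' proportions for categorical covariates, one row per phenotype label plus
#' the aggregated all-CAD and control rows. Single-member groups get a mean
#' but no SD; empty groups get `n = 0` and absent statistics.
#'
#' @param assignments A `cad_assignments`.
#' @param cohort The matching [cad_cohort()]; covariates are taken from the
#'   participants table.
#' @param continuous,categorical Column names in `participants` to
#'   summarize.
#' @return data.table with one row per group: `group`, `n`, `<var>_mean`,
#'   `<var>_sd` for each continuous variable, `<var>_prop_<level>` for each
#'   level of each categorical variable.
#' @export
summarize_baseline <- function(assignments, cohort,
                               continuous = "age_at_enrol",
                               categorical = "sex") {
  p <- merge(data.table::as.data.table(assignments)[, .(pid, label)],
             cohort$participants, by = "pid")
  groups <- c(.PHENO_LABELS, "all_CAD", "controls")
  members <- function(g) {
    if (g == "all_CAD") p[label %in% .CASE_LABELS]
    else if (g == "controls") p[label %in% .CONTROL_LABELS]
    else p[label == g]
  }
  cat_levels <- lapply(categorical, function(v) sort(unique(p[[v]])))
  names(cat_levels) <- categorical

  rows <- lapply(groups, function(g) {
    sub <- members(g)
    row <- list(group = g, n = nrow(sub))
    for (v in continuous) {
      row[[paste0(v, "_mean")]] <-
        if (nrow(sub)) mean(sub[[v]], na.rm = TRUE) else NA_real_
      row[[paste0(v, "_sd")]] <-
        if (nrow(sub) > 1) sd(sub[[v]], na.rm = TRUE) else NA_real_
    }
    for (v in categorical) for (lev in cat_levels[[v]]) {
      row[[paste0(v, "_prop_", lev)]] <-
        if (nrow(sub)) mean(sub[[v]] == lev, na.rm = TRUE) else NA_real_
    }
    row
  })
  data.table::rbindlist(rows)
}
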