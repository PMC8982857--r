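# Fidelity evaluation 1: all-cause mortality by phenotype.
# Kaplan-Meier curves and age/sex-adjusted Cox proportional-hazards models
# comparing each phenotype (and the aggregated all-CAD group) with CAD-free
# controls. Follow-up starts at enrolment for prevalent/self-report cases
# and controls, and at the qualifying event date for incident cases.

#' Build per-participant time-to-event records
#'
#' One row per participant: follow-up start `t0` (enrolment date for
#' prevalent, self-reported and control labels; qualifying event date for
#' incident labels), `time` in days to death or administrative censoring at
#' the censor date, the event indicator, and the age/sex covariates.
#' Participants whose recorded death precedes their follow-up start are
#' excluded and counted in `attr(, "n_excluded")`.
#'
#' @param assignments A `cad_assignments` from [run_algorithm()].
#' @param cohort The matching [cad_cohort()].
#' @param censor_date Censor date; deaths after it are treated as censored.
#' @return A `cad_survival` data.table: `pid`, `group`, `t0`, `time`
#'   (days, >= 0), `event` (1 = died), `age_at_enrol`, `sex`.
#' @export
build_survival_records <- function(assignments, cohort,
                                   censor_date = default_censor_date()) {
  censor_date <- .as_date(censor_date)
  a <- data.table::as.data.table(assignments)[
    , .(pid, group = label, qualifying_date)]
  m <- merge(a, cohort$participants, by = "pid")
  dd <- cohort$deaths[!is.na(death_date), .(death_date = .min_date(death_date)),
                      by = pid]
  m <- merge(m, dd, by = "pid", all.x = TRUE)

  m[, t0 := data.table::fifelse(group %in% .INCIDENT_LABELS,
                                qualifying_date, enrol_date)]
  m[, died := !is.na(death_date) & death_date <= censor_date]
  n_excl <- m[died & death_date < t0, .N] + m[t0 > censor_date, .N]
  m <- m[!(died & death_date < t0) & t0 <= censor_date]
  m[, end := data.table::fifelse(died, death_date, censor_date)]
  m[, time := as.numeric(end - t0)]
  m[, event := as.integer(died)]

  out <- m[, .(pid, group, t0, time, event, age_at_enrol, sex)]
  data.table::setattr(out, "class",
                      c("cad_survival", class(data.table())))
  data.table::setattr(out, "n_excluded", n_excl)
  data.table::setattr(out, "censor_date", censor_date)
  out
}

#' Kaplan-Meier survival curve for one group
#'
#' Product-limit estimator with log-transformed 95% confidence band, as a
#' step-function table. The returned curve starts at `S(0) = 1` and is
#' non-increasing.
#'
#' @param records A `cad_survival` table from [build_survival_records()].
#' @param group Phenotype label to estimate; `NULL` uses all records (e.g.
#'   when `records` is already subset). `"all_CAD"` pools the six disease
#'   labels, `"controls"` the two control labels.
#' @return data.table: `time`, `n_risk`, `n_event`, `n_censor`, `surv`,
#'   `lower`, `upper`.
#' @export
km_curve <- function(records, group = NULL) {
  dat <- .survival_subset(records, group)
  if (!nrow(dat)) .stopf("no survival records for group '%s'", group)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = dat)
  out <- data.table(time = c(0, fit$time),
                    n_risk = c(nrow(dat), fit$n.risk),
                    n_event = c(0, fit$n.event),
                    n_censor = c(0, fit$n.censor),
                    surv = c(1, fit$surv),
                    lower = c(1, fit$lower),
                    upper = c(1, fit$upper))
  out[]
}

.survival_subset <- function(records, group) {
  if (is.null(group)) return(data.table::as.data.table(records))
  r <- data.table::as.data.table(records)
  want <- if (identical(group, "all_CAD")) .CASE_LABELS
          else if (identical(group, "controls")) .CONTROL_LABELS
          else group
  r[which(r[["group"]] %in% want)]
}

#' Age/sex-adjusted Cox model for one phenotype versus controls
#'
#' Fits a Cox proportional-hazards model (Efron tie handling) with a
#' case-group indicator plus linear age at enrolment and sex, on the given
#' phenotype's records pooled with the CAD-free controls. The
#' proportional-hazards assumption for the group term is summarized by the
#' correlation of its scaled Schoenfeld residuals with time and the
#' corresponding score-test p-value; the check is reported, never used to
#' reject a fit.
#'
#' @param records A `cad_survival` table.
#' @param group Phenotype label (or `"all_CAD"` for the aggregate).
#' @param controls Labels forming the comparison pool (default both control
#'   labels).
#' @return A `cad_hazard_estimate` list: `group`, `hazard_ratio`, `ci_low`,
#'   `ci_high`, `n_cases`, `n_controls`, `n_events`, `ph_corr`, `ph_p`,
#'   `flagged` (`TRUE` when the fit shows signs of complete separation and
#'   the CI is unreliable).
#' @export
cox_fit <- function(records, group, controls = .CONTROL_LABELS) {
  cases <- .survival_subset(records, group)
  ctrl <- .survival_subset(records, controls)
  if (!nrow(cases)) .stopf("no records for case group '%s'", group)
  if (!nrow(ctrl)) .stopf("no records for the control group")
  dat <- data.table::rbindlist(list(cases[, case := 1L],
                                    ctrl[, case := 0L]))
  if (sum(dat$event) == 0L)
    .stopf("no deaths observed in '%s' vs controls; hazard not estimable",
           group)
  two_sex <- data.table::uniqueN(dat$sex) > 1L
  fml <- if (two_sex) {
    survival::Surv(time, event) ~ case + age_at_enrol + sex
  } else {
    survival::Surv(time, event) ~ case + age_at_enrol
  }
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  b <- coef(fit)[["case"]]
  se <- sqrt(vcov(fit)["case", "case"])
  flagged <- !is.finite(b) || !is.finite(se) || abs(b) > 15 || se > 15

  ph_corr <- NA_real_; ph_p <- NA_real_
  zph <- tryCatch(survival::cox.zph(fit, transform = "identity"),
                  error = function(e) NULL)
  if (!is.null(zph)) {
    ycol <- grep("^case$", colnames(zph$y))
    if (length(ycol)) {
      ph_corr <- suppressWarnings(cor(zph$x, zph$y[, ycol]))
      ph_p <- zph$table["case", "p"]
    }
  }

  structure(list(group = if (length(group) == 1) group else "cases",
                 hazard_ratio = exp(b),
                 ci_low = exp(b - qnorm(0.975) * se),
                 ci_high = exp(b + qnorm(0.975) * se),
                 log_hr = b, se = se,
                 n_cases = nrow(cases), n_controls = nrow(ctrl),
                 n_events = sum(dat$event),
                 ph_corr = ph_corr, ph_p = ph_p,
                 flagged = flagged),
            class = "cad_hazard_estimate")
}

#' @export
print.cad_hazard_estimate <- function(x, ...) {
  cat(sprintf("%s vs controls: HR %.2f (95%% CI %.2f-%.2f), %d cases / %d controls, %d deaths%s\n",
              x$group, x$hazard_ratio, x$ci_low, x$ci_high,
              x$n_cases, x$n_controls, x$n_events,
              if (isTRUE(x$flagged)) " [FLAGGED: unreliable]" else ""))
  if (is.finite(x$ph_p))
    cat(sprintf("  PH check: scaled-Schoenfeld corr %.3f, p = %.3g\n",
                x$ph_corr, x$ph_p))
  invisible(x)
}

#' Hazard-ratio table across phenotypes
#'
#' Runs [cox_fit()] for each phenotype versus the shared control pool, plus
#' the aggregated all-CAD group.
#'
#' @param records A `cad_survival` table.
#' @param groups Phenotype labels to evaluate (default: the six disease
#'   labels present in the data).
#' @param include_all_cad Add the aggregated all-CAD row (default TRUE).
#' @return data.table: `group`, `n`, `n_events`, `hr`, `ci_low`, `ci_high`,
#'   `ph_corr`, `ph_p`, `flagged`.
#' @export
hazard_table <- function(records, groups = NULL, include_all_cad = TRUE) {
  r <- data.table::as.data.table(records)
  if (is.null(groups))
    groups <- intersect(.CASE_LABELS, unique(r$group))
  if (include_all_cad) groups <- c(groups, "all_CAD")
  rows <- lapply(groups, function(g) {
    est <- cox_fit(r, g)
    data.table(group = g, n = est$n_cases, n_events = est$n_events,
               hr = est$hazard_ratio, ci_low = est$ci_low,
               ci_high = est$ci_high, ph_corr = est$ph_corr,
               ph_p = est$ph_p, flagged = est$flagged)
  })
  data.table::rbindlist(rows)
}
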