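# The hierarchical classifier and its summaries.

ev_row <- function(pid, tag, date, source = "hospital_dx", code = "I214") {
  data.table::data.table(pid = pid, phenotype_tag = tag,
                         event_date = as.Date(date), source = source,
                         code = code)
}

test_that("single participants classify per the hierarchy", {
  p <- list(pid = "X", enrol_date = "2007-01-01")

  # MI before enrolment, nothing else -> prevalent MI dated at the event
  a <- classify_participant(ev_row("X", "MI", "2004-05-02"), p)
  expect_equal(a$label, "prevalent_MI")
  expect_equal(a$qualifying_date, as.Date("2004-05-02"))

  # CAD before enrolment AND MI after -> the MI step runs first
  ev <- rbind(ev_row("X", "CAD_noMI", "2005-01-01", code = "I209"),
              ev_row("X", "MI", "2010-01-01"))
  a <- classify_participant(ev, p)
  expect_equal(a$label, "incident_MI")
  expect_equal(a$qualifying_date, as.Date("2010-01-01"))

  # MI on both sides of enrolment resolves per config, dated at the
  # earliest event on the chosen side
  ev <- rbind(ev_row("X", "MI", "2004-05-02"),
              ev_row("X", "MI", "2012-01-01"),
              ev_row("X", "MI", "2010-06-01"))
  a <- classify_participant(ev, p)
  expect_equal(a$label, "incident_MI")
  expect_equal(a$qualifying_date, as.Date("2010-06-01"))
  a <- classify_participant(ev, p,
                            config = algorithm_config(resolution = "prevalent"))
  expect_equal(a$label, "prevalent_MI")
  expect_equal(a$qualifying_date, as.Date("2004-05-02"))

  # no EHR events; self-reported heart attack -> sr_MI, no date
  a <- classify_participant(NULL, p, data.frame(
    pid = "X", category = "illness", item_code = "heart_attack"))
  expect_equal(a$label, "sr_MI")
  expect_true(is.na(a$qualifying_date))

  # nothing at all: died -> never_CAD, alive -> no_CAD
  a <- classify_participant(NULL, c(p, death_date = "2012-01-01"))
  expect_equal(a$label, "never_CAD")
  a <- classify_participant(NULL, p)
  expect_equal(a$label, "no_CAD")
})

test_that("enrolment-day events are prevalent by default and configurable", {
  p <- list(pid = "X", enrol_date = "2007-01-01")
  ev <- ev_row("X", "MI", "2007-01-01")
  expect_equal(classify_participant(ev, p)$label, "prevalent_MI")
  cfg <- algorithm_config(on_enrolment_date_is = "incident")
  expect_equal(classify_participant(ev, p, config = cfg)$label,
               "incident_MI")
})

test_that("undated self-reported procedures classify as prevalent CAD without MI", {
  p <- list(pid = "X", enrol_date = "2007-01-01")
  ev <- ev_row("X", "CAD_noMI", NA, source = "selfreport_proc",
               code = "CABG")
  a <- classify_participant(ev, p)
  expect_equal(a$label, "prevalent_CAD_noMI")
  expect_true(is.na(a$qualifying_date))
  expect_equal(a$source, "selfreport_proc")
  # with an additional dated post-enrolment CAD event the default
  # (incident) resolution applies
  ev2 <- rbind(ev, ev_row("X", "CAD_noMI", "2010-01-01", code = "I209"))
  a2 <- classify_participant(ev2, p)
  expect_equal(a2$label, "incident_CAD_noMI")
  expect_equal(a2$qualifying_date, as.Date("2010-01-01"))
})

test_that("run_algorithm on the worked mini-cohort assigns and logs correctly", {
  co <- mini_cohort()
  a <- run_algorithm(co)
  got <- setNames(a$label, a$pid)
  expect_equal(got[["A"]], "prevalent_MI")
  expect_equal(got[["B"]], "incident_CAD_noMI")
  expect_equal(got[["C"]], "never_CAD")
  expect_equal(got[["D"]], "sr_MI")
  log <- run_log(a)
  expect_equal(log$n[log$step == 1], 4)
  # the assignment steps partition the cohort (steps 2 and 5 are the
  # identification tallies, not assignments)
  expect_equal(sum(log$n[log$step %in% c(3, 4, 6, 7, 8, 9, 10, 11)]), 4)
})

test_that("empty and all-control cohorts are handled", {
  co <- cad_cohort(participants = data.frame(
    pid = character(), enrol_date = character(), sex = character(),
    age_at_enrol = integer()))
  a <- run_algorithm(co)
  expect_equal(nrow(a), 0)
  expect_true(all(run_log(a)$n == 0))

  sim <- simulate_cohort(quick_config(200, seed = 2, label_fractions = c(
    prevalent_MI = 0, incident_MI = 0, prevalent_CAD_noMI = 0,
    incident_CAD_noMI = 0, sr_MI = 0, sr_CAD_noMI = 0,
    never_CAD = 0.05, no_CAD = 0.95)))
  a <- run_algorithm(sim$cohort)
  expect_equal(sum(a$label %in% cad_labels("control")), 200)
})

test_that("assignments form a partition with consistent dates, idempotently", {
  sim <- simulate_cohort(quick_config(1500, seed = 8, adversarial = TRUE))
  a1 <- run_algorithm(sim$cohort)
  a2 <- run_algorithm(sim$cohort)
  expect_identical(as.data.frame(a1), as.data.frame(a2))
  expect_equal(nrow(a1), 1500)
  expect_equal(anyDuplicated(a1$pid), 0)
  expect_true(all(a1$label %in% cad_labels()))

  m <- merge(a1, sim$cohort$participants, by = "pid")
  inc <- m[m$label %in% c("incident_MI", "incident_CAD_noMI")]
  expect_true(all(inc$qualifying_date > inc$enrol_date))
  prev <- m[m$label %in% c("prevalent_MI", "prevalent_CAD_noMI") &
              !is.na(m$qualifying_date)]
  expect_true(all(prev$qualifying_date <= prev$enrol_date))
  undated <- m[is.na(m$qualifying_date)]
  expect_true(all(
    undated$label %in% c("sr_MI", "sr_CAD_noMI", "never_CAD", "no_CAD") |
      (undated$label == "prevalent_CAD_noMI" &
         undated$source == "selfreport_proc")))
})

test_that("adding an MI event never demotes a participant down the hierarchy", {
  set.seed(31)
  sim <- simulate_cohort(quick_config(300, seed = 31, adversarial = TRUE))
  co <- sim$cohort
  base <- run_algorithm(co)
  victims <- sample(co$participants$pid, 40)
  extra <- data.table::data.table(
    pid = victims, code_system = "ICD10",
    code = sample(c("I214", "I219", "I220"), 40, replace = TRUE),
    position = "primary",
    event_date = as.Date("2000-01-01") + sample(0:6000, 40, TRUE))
  co2 <- cad_cohort(co$participants, rbind(co$diagnoses, extra),
                    co$procedures, co$deaths, co$self_reports)
  after <- run_algorithm(co2)
  b <- setNames(base$label, base$pid)
  f <- setNames(after$label, after$pid)
  expect_true(all(hierarchy_level(f[victims]) <=
                    hierarchy_level(b[victims])))
  # and the added events are post-censor-proof: untouched pids unchanged
  others <- setdiff(co$participants$pid, victims)
  expect_equal(f[others], b[others])
})

test_that("participants with only post-censor events are controls", {
  co <- cad_cohort(
    participants = data.frame(pid = "A", enrol_date = "2010-01-01",
                              sex = "male", age_at_enrol = 50L),
    diagnoses = data.frame(pid = "A", code_system = "ICD10", code = "I214",
                           position = "primary", event_date = "2017-06-01"))
  a <- run_algorithm(co)
  expect_equal(a$label, "no_CAD")
})

test_that("all-CAD aggregation reproduces the count algebra", {
  agg <- aggregate_all_cad(c(4900, 4621, 10910, 8668, 2754, 5623))
  expect_equal(agg$all_cad, 37476)
  agg <- aggregate_all_cad(c(4900, 4621, 10910, 8668, 2754, 5623),
                           n_total = 502631)
  expect_equal(agg$controls, 465155)
  expect_equal(aggregate_all_cad(rep(0, 6))$all_cad, 0)

  sim <- simulate_cohort(quick_config(800, seed = 12))
  a <- run_algorithm(sim$cohort)
  agg <- aggregate_all_cad(a)
  expect_equal(agg$all_cad + agg$controls, 800)
  expect_equal(unname(agg$label_counts[cad_labels()]),
               as.vector(table(factor(a$label, cad_labels()))))
})

test_that("baseline summaries recover planted covariate structure", {
  cfg <- quick_config(20000, seed = 77)
  sim <- simulate_cohort(cfg)
  a <- run_algorithm(sim$cohort)
  s <- summarize_baseline(a, sim$cohort)
  expect_setequal(s$group, c(cad_labels(), "all_CAD", "controls"))

  # planted male fractions recovered within binomial 99% CIs
  for (g in c("all_CAD", "sr_CAD_noMI")) {
    row <- s[s$group == g]
    p0 <- if (g == "sr_CAD_noMI") 0.467 else
      sum(cfg$male_fraction[cad_labels("case")] *
            cfg$label_fractions[cad_labels("case")]) /
      sum(cfg$label_fractions[cad_labels("case")])
    half <- qnorm(0.995) * sqrt(p0 * (1 - p0) / row$n)
    expect_lt(abs(row$sex_prop_male - p0), half + 1e-9)
  }
  # age mean near the uniform 40-69 midpoint
  expect_lt(abs(s[s$group == "controls"]$age_at_enrol_mean - 54.5), 0.5)
})

test_that("degenerate groups summarize gracefully", {
  co <- cad_cohort(participants = data.frame(
    pid = c("A", "B"), enrol_date = "2007-01-01",
    sex = c("male", "female"), age_at_enrol = c(50L, 60L)),
    self_reports = data.frame(pid = "A", category = "illness",
                              item_code = "angina"))
  a <- run_algorithm(co)
  s <- summarize_baseline(a, co)
  one <- s[s$group == "sr_CAD_noMI"]
  expect_equal(one$n, 1)
  expect_equal(one$age_at_enrol_mean, 50)
  expect_true(is.na(one$age_at_enrol_sd))
  empty <- s[s$group == "prevalent_MI"]
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$age_at_enrol_mean))
})

test_that("the mortality split formatter reports one-decimal percentages", {
  d <- cad_death_summary(3770, 10649, 37476, 465155)
  expect_equal(d$deaths_total, 14419)
  expect_equal(d$cad_death_pct, 10.1)
  expect_equal(d$control_death_pct, 2.3)
})
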