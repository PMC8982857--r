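# Code normalization, prefix matching, and qualifying-event extraction.

test_that("code normalization uppercases and strips dots and whitespace", {
  expect_equal(normalize_code("I21.4"), "I214")
  expect_equal(normalize_code(" k401"), "K401")
  expect_equal(normalize_code("410.9"), "4109")
  expect_equal(normalize_code(c("i 25.2", "K40 .1")), c("I252", "K401"))
  expect_error(normalize_code(" . "), "empty")
  expect_equal(normalize_code(".", strict = FALSE), "")
})

test_that("matching is longest-prefix-wins and never matches shorter codes", {
  cl <- cad_code_list(data.frame(
    code_system = "ICD10", code = c("I21", "I22"),
    phenotype_tag = "MI"))
  expect_true(match_code("I214", cl, "ICD10")$matched)
  expect_false(match_code("I21", cad_code_list(data.frame(
    code_system = "ICD10", code = "I214", phenotype_tag = "MI")),
    "ICD10")$matched)
  expect_false(match_code("I250", cl, "ICD10")$matched)

  # the I25/I252 cross-tag overlap resolves by prefix length
  dft <- default_code_list()
  expect_equal(match_code("I252", dft, "ICD10")$phenotype_tag, "MI")
  expect_equal(match_code("I2520", dft, "ICD10")$phenotype_tag, "MI")
  expect_equal(match_code("I259", dft, "ICD10")$phenotype_tag, "CAD_noMI")
  # code systems are disjoint namespaces
  expect_false(match_code("I214", dft, "OPCS4")$matched)
})

test_that("identical prefixes with conflicting tags are rejected at load", {
  expect_error(cad_code_list(data.frame(
    code_system = "ICD10", code = c("I25", "I25"),
    phenotype_tag = c("MI", "CAD_noMI"))), "ambiguous")
  expect_error(cad_code_list(data.frame(
    code_system = "ICD10", code = "I21", phenotype_tag = "banana")),
    "phenotype tag")
  expect_error(cad_code_list(data.frame(
    code_system = "READ2", code = "G30", phenotype_tag = "MI")),
    "code system")
})

test_that("match_code agrees with a brute-force scan on random instances", {
  set.seed(42)
  dft <- default_code_list()
  ents <- as.data.frame(dft$entries)
  for (rep in 1:10) {
    # random codes biased to collide with real prefixes
    stems <- c("I2", "I25", "I21", "K4", "K7", "4", "J4", "X")
    codes <- paste0(sample(stems, 100, replace = TRUE),
                    sample(c("", "0", "1", "2", "9", "52", "19"),
                           100, replace = TRUE))
    for (cs in c("ICD10", "ICD9", "OPCS4")) {
      got <- match_code(codes, dft, cs)$phenotype_tag
      want <- vapply(codes, bf_match_tag, character(1),
                     entries = ents, cs = cs)
      expect_equal(got, unname(want))
    }
  }
})

test_that("qualifying events come from the configured sources with censor filtering", {
  co <- cad_cohort(
    participants = data.frame(
      pid = c("A", "B", "C"),
      enrol_date = c("2007-01-01", "2007-01-01", "2007-01-01"),
      sex = "male", age_at_enrol = 50L),
    diagnoses = data.frame(
      pid = c("A", "C"), code_system = "ICD10", code = c("I214", "I219"),
      position = "primary", event_date = c("2005-03-01", "2017-01-01")),
    deaths = data.frame(
      pid = "B", death_date = "2010-06-01", code_system = "ICD10",
      code = c("C349", "I220"), role = c("underlying", "contributing")))
  ev <- extract_events(co)
  # A: hospital MI diagnosis; B: contributing-cause MI at death date;
  # C: post-censor event dropped
  expect_equal(nrow(ev), 2)
  a <- ev[ev$pid == "A"]
  expect_equal(a$phenotype_tag, "MI")
  expect_equal(a$event_date, as.Date("2005-03-01"))
  expect_equal(a$source, "hospital_dx")
  b <- ev[ev$pid == "B"]
  expect_equal(b$source, "death_registry")
  expect_equal(b$event_date, as.Date("2010-06-01"))
  expect_false("C" %in% ev$pid)

  # underlying-only config drops the contributing cause
  cfg <- algorithm_config(death_roles = "underlying")
  expect_false("B" %in% extract_events(co, config = cfg)$pid)
  # primary-position-only config
  co2 <- cad_cohort(
    participants = data.frame(pid = "A", enrol_date = "2007-01-01",
                              sex = "male", age_at_enrol = 50L),
    diagnoses = data.frame(pid = "A", code_system = "ICD10", code = "I214",
                           position = "secondary",
                           event_date = "2005-03-01"))
  expect_equal(nrow(extract_events(co2)), 1)
  cfgp <- algorithm_config(diagnosis_positions = "primary")
  expect_equal(nrow(extract_events(co2, config = cfgp)), 0)
  # unknown source name in config is a config error
  expect_error(algorithm_config(sources = list(MI = "gp_records",
                                               CAD_noMI = "hospital_dx")),
               "unknown source")
})

test_that("extraction is monotone in the code list and row-order invariant", {
  set.seed(9)
  sim <- simulate_cohort(quick_config(400, seed = 5, adversarial = TRUE))
  co <- sim$cohort
  small <- cad_code_list(data.frame(
    code_system = "ICD10", code = c("I21", "I22"), phenotype_tag = "MI"))
  bigger <- cad_code_list(data.frame(
    code_system = c("ICD10", "ICD10", "ICD10", "OPCS4"),
    code = c("I21", "I22", "I20", "K40"),
    phenotype_tag = c("MI", "MI", "CAD_noMI", "CAD_noMI")))
  e1 <- extract_events(co, small)
  e2 <- extract_events(co, bigger)
  expect_gte(nrow(e2), nrow(e1))
  key <- function(e) paste(e$pid, e$phenotype_tag, e$event_date, e$code)
  expect_true(all(key(e1) %in% key(e2)))

  shuf <- cad_cohort(co$participants[sample(nrow(co$participants))],
                     co$diagnoses[sample(nrow(co$diagnoses))],
                     co$procedures[sample(nrow(co$procedures))],
                     co$deaths[sample(nrow(co$deaths))],
                     co$self_reports[sample(nrow(co$self_reports))])
  expect_equal(as.data.frame(extract_events(shuf)),
               as.data.frame(extract_events(co)))
})

test_that("self-reported procedures yield undated prevalent CAD evidence", {
  co <- cad_cohort(
    participants = data.frame(pid = "A", enrol_date = "2007-01-01",
                              sex = "male", age_at_enrol = 50L),
    self_reports = data.frame(pid = "A", category = "procedure",
                              item_code = "cabg"))
  ev <- extract_events(co)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$source, "selfreport_proc")
  expect_equal(ev$phenotype_tag, "CAD_noMI")
  expect_true(is.na(ev$event_date))
})
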