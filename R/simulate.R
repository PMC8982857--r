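# Synthetic linked-biobank generator.
#
# Generates baseline, hospital, death-registry, self-report tables and a
# genotype dosage matrix with planted phenotype labels, a planted mortality
# hazard gradient and planted per-SD PRS effects, so that every other module
# has a ground-truth oracle. Each label is emitted as a record pattern that
# the phenotyping hierarchy maps back to that label by construction; the
# adversarial mode adds distractor records whose correct resolution is still
# uniquely determined by the hierarchy.

.default_label_fractions <- function() {
  counts <- c(prevalent_MI = 4900, incident_MI = 4621,
              prevalent_CAD_noMI = 10910, incident_CAD_noMI = 8668,
              sr_MI = 2754, sr_CAD_noMI = 5623,
              never_CAD = 10649, no_CAD = 454506)
  counts / sum(counts)
}

#' Configuration of the synthetic biobank generator
#'
#' Defaults mirror the study conditions the package is designed around: a
#' 2006-2010 enrolment window, ages 40-69 at enrolment, administrative
#' censoring on 2016-11-01, label fractions proportional to the published
#' sub-phenotype counts over 502,631 participants, the published age/sex-
#' adjusted mortality hazard-ratio gradient, and a per-SD PRS odds-ratio
#' gradient anchored at the published strongest (1.50) and weakest (1.08)
#' associations.
#'
#' @param n Number of participants.
#' @param seed Mandatory RNG seed; all outputs are deterministic given it.
#' @param label_fractions Named fractions over the 8 labels, summing to 1.
#'   The two control fractions are planted as a combined control mass; the
#'   realized never/no split follows from the simulated mortality.
#' @param enrol_window Two dates bounding enrolment (uniform).
#' @param prevalent_window_start Earliest date for pre-enrolment events.
#' @param censor_date Administrative censor date.
#' @param baseline_hazard Baseline all-cause death rate per year for a
#'   control of mean age (default 0.002, calibrated so that control
#'   mortality over the ~8-year follow-up is a few percent).
#' @param beta_age Log-hazard per year of age (default 0.08).
#' @param beta_sex Log-hazard for male vs female (default 0.3).
#' @param mean_age Centering age for the hazard model.
#' @param hazard_ratios Named per-label mortality hazard ratios vs controls.
#' @param prs_or Named per-label odds ratios per 1 SD of the true score.
#' @param m_variants,block_size,block_r2 Genotype panel size, LD block size,
#'   and target within-block dosage r-squared.
#' @param n_causal_blocks Number of blocks carrying a causal variant.
#' @param af_range Effect-allele frequency range (uniform).
#' @param male_fraction Named male fractions per case label plus
#'   `"control"`.
#' @param age_range Integer age range at enrolment.
#' @param genotypes Simulate the dosage matrix and PRS link (default TRUE
#'   when `m_variants > 0`).
#' @param adversarial Add distractor records (see module header).
#' @return A `cad_sim_config`.
#' @export
simulation_config <- function(n, seed,
                              label_fractions = .default_label_fractions(),
                              enrol_window = c("2006-01-01", "2010-12-31"),
                              prevalent_window_start = "1992-01-01",
                              censor_date = default_censor_date(),
                              baseline_hazard = 0.002,
                              beta_age = 0.08, beta_sex = 0.3,
                              mean_age = 54.5,
                              hazard_ratios = c(
                                prevalent_MI = 2.52, incident_MI = 6.66,
                                prevalent_CAD_noMI = 1.75,
                                incident_CAD_noMI = 5.65,
                                sr_MI = 1.77, sr_CAD_noMI = 1.31),
                              prs_or = c(
                                prevalent_MI = 1.50, incident_MI = 1.35,
                                prevalent_CAD_noMI = 1.44,
                                incident_CAD_noMI = 1.30,
                                sr_MI = 1.20, sr_CAD_noMI = 1.08),
                              m_variants = 150, block_size = 5,
                              block_r2 = 0.5, n_causal_blocks = 20,
                              af_range = c(0.1, 0.5),
                              male_fraction = c(
                                prevalent_MI = 0.701, incident_MI = 0.701,
                                prevalent_CAD_noMI = 0.701,
                                incident_CAD_noMI = 0.701,
                                sr_MI = 0.701, sr_CAD_noMI = 0.467,
                                control = 0.45),
                              age_range = c(40L, 69L),
                              genotypes = m_variants > 0,
                              adversarial = FALSE) {
  if (missing(seed) || is.null(seed)) .stopf("seed is mandatory")
  if (missing(n) || n < 0) .stopf("n must be a non-negative integer")
  if (!setequal(names(label_fractions), .PHENO_LABELS))
    .stopf("label_fractions must be named by the 8 phenotype labels")
  if (abs(sum(label_fractions) - 1) > 1e-8)
    .stopf("label_fractions must sum to 1 (got %.6f)", sum(label_fractions))
  if (any(label_fractions < 0)) .stopf("label_fractions must be >= 0")
  if (baseline_hazard < 0) .stopf("baseline_hazard must be positive")
  if (!setequal(names(hazard_ratios), .CASE_LABELS) ||
      any(hazard_ratios <= 0))
    .stopf("hazard_ratios must be positive and named by the 6 case labels")
  if (!setequal(names(prs_or), .CASE_LABELS) || any(prs_or <= 0))
    .stopf("prs_or must be positive and named by the 6 case labels")
  if (genotypes && block_size > m_variants)
    .stopf("block_size (%d) exceeds m_variants (%d)", block_size, m_variants)
  if (genotypes && (block_r2 < 0 || block_r2 >= 1))
    .stopf("block_r2 must lie in [0, 1)")
  enrol_window <- .as_date(enrol_window)
  censor_date <- .as_date(censor_date)
  if (enrol_window[2] > censor_date)
    .stopf("enrolment window must end on or before the censor date")
  structure(list(
    n = as.integer(n), seed = as.integer(seed),
    label_fractions = label_fractions[.PHENO_LABELS],
    enrol_window = enrol_window,
    prevalent_window_start = .as_date(prevalent_window_start),
    censor_date = censor_date,
    baseline_hazard = baseline_hazard, beta_age = beta_age,
    beta_sex = beta_sex, mean_age = mean_age,
    hazard_ratios = hazard_ratios[.CASE_LABELS],
    prs_or = prs_or[.CASE_LABELS],
    m_variants = as.integer(m_variants), block_size = as.integer(block_size),
    block_r2 = block_r2, n_causal_blocks = as.integer(n_causal_blocks),
    af_range = af_range, male_fraction = male_fraction,
    age_range = as.integer(age_range),
    genotypes = isTRUE(genotypes), adversarial = isTRUE(adversarial)
  ), class = "cad_sim_config")
}

# bivariate-normal orthant probability P(X < a, Y < a) via 1-D quadrature
.pbvn <- function(a, rho) {
  if (rho <= 0) return(pnorm(a)^2)
  integrate(function(x) pnorm((a - rho * x) / sqrt(1 - rho^2)) * dnorm(x),
            -Inf, a, rel.tol = 1e-9)$value
}

# latent-Gaussian correlation giving a target correlation between two
# Bernoulli(p) indicators thresholded from the latent pair
.calibrate_rho <- function(p, target_r) {
  if (target_r <= 1e-8) return(0)
  a <- qnorm(p)
  f <- function(rho) (.pbvn(a, rho) - p^2) / (p * (1 - p)) - target_r
  uniroot(f, c(1e-6, 1 - 1e-6), tol = 1e-7)$root
}

#' Simulate a blockwise-correlated genotype panel with GWAS-style weights
#'
#' Dosages are sums of two latent-Gaussian gametes thresholded at
#' Hardy-Weinberg allele frequencies; within each LD block the latent
#' correlation is calibrated (via the bivariate-normal orthant probability)
#' so the *dosage* correlation matches `sqrt(block_r2)`. Blocks are placed
#' more than the clumping window apart. The first `n_causal_blocks` blocks
#' carry one causal variant (smallest p-value in its block) plus one
#' correlated decoy that also passes the significance filter, so clumping is
#' exercised; remaining variants are nulls with non-significant p-values.
#' The true score is the beta-weighted sum over causal variants,
#' standardized.
#'
#' @param n Number of participants.
#' @param config A [simulation_config()].
#' @param seed Optional seed; when `NULL` the current RNG state is used
#'   (as when called from [simulate_cohort()]).
#' @return List: `dosages` (n x m matrix, colnames = vid), `variants`
#'   (weights table: vid, chrom, pos, effect_allele, beta, pvalue), `z_true`
#'   (standardized true score), `causal_vids`.
#' @export
simulate_genotypes <- function(n, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- config$m_variants
  bs <- config$block_size
  nb <- ceiling(m / bs)
  block <- rep(seq_len(nb), each = bs)[seq_len(m)]
  chrom <- as.character(((block - 1L) %% 22L) + 1L)
  within_chrom <- ((block - 1L) %/% 22L)
  offset <- unlist(lapply(split(seq_len(m), block),
                          function(ix) seq_along(ix)), use.names = FALSE)
  pos <- 1e6 + within_chrom * 2e6 + offset * 1e4
  vid <- sprintf("rs%05d", seq_len(m))
  # allele frequency is drawn per LD block with slight per-variant jitter,
  # so the calibrated latent correlation holds across the whole block
  block_af <- runif(nb, config$af_range[1], config$af_range[2])
  af <- pmin(pmax(block_af[block] + runif(m, -0.02, 0.02), 0.02), 0.98)

  target_r <- sqrt(config$block_r2)
  dos <- matrix(0L, nrow = n, ncol = m, dimnames = list(NULL, vid))
  for (b in seq_len(nb)) {
    ix <- which(block == b)
    rho <- .calibrate_rho(mean(af[ix]), target_r)
    for (g in 1:2) {
      f <- rnorm(n)
      for (j in ix) {
        lat <- sqrt(rho) * f + sqrt(1 - rho) * rnorm(n)
        dos[, j] <- dos[, j] + (lat < qnorm(af[j]))
      }
    }
  }

  causal <- decoy <- integer(0)
  for (b in seq_len(min(config$n_causal_blocks, nb))) {
    ix <- which(block == b)
    causal <- c(causal, ix[1])
    if (length(ix) > 1) decoy <- c(decoy, ix[2])
  }
  beta <- rnorm(m, 0, 0.01)
  beta[causal] <- sample(c(-1, 1), length(causal), TRUE) *
    runif(length(causal), 0.03, 0.15)
  beta[decoy] <- 0.8 * beta[causal[seq_along(decoy)]]
  pvalue <- runif(m, 1e-4, 1)
  pvalue[causal] <- 10^-runif(length(causal), 6.6, 15)
  pvalue[decoy] <- 10^-runif(length(decoy), 5.35, 6.5)

  z_true <- if (n > 1 && length(causal)) {
    raw <- drop(dos[, causal, drop = FALSE] %*% beta[causal])
    if (sd(raw) > 0) (raw - mean(raw)) / sd(raw) else rep(0, n)
  } else rep(0, n)

  variants <- data.table(vid = vid, chrom = chrom, pos = pos,
                         effect_allele = sample(c("A", "C", "G", "T"), m,
                                                replace = TRUE),
                         beta = beta, pvalue = pvalue)
  list(dosages = dos, variants = variants, z_true = z_true,
       causal_vids = vid[causal])
}

#' Assign phenotype labels, optionally linked to a risk score
#'
#' Without a score, labels are a plain multinomial draw from the configured
#' fractions (controls pooled). With a score, labels follow a multinomial
#' logit with the control class as reference: the weight of case label g for
#' a participant with standardized score z is
#' `f_g * exp(beta_g * z - beta_g^2 / 2)` with `beta_g` the configured
#' per-SD log-odds, so a case-control logistic regression of any phenotype
#' versus controls on z recovers exactly the planted slope, while marginal
#' label fractions stay (to first order) at the configured values.
#'
#' @param n Number of participants.
#' @param config A [simulation_config()].
#' @param z Optional standardized score vector of length n.
#' @return Character labels: one of the six case labels or `"control"`
#'   (controls are split into never/no only after mortality is simulated).
#' @export
assign_labels <- function(n, config, z = NULL) {
  f_case <- config$label_fractions[.CASE_LABELS]
  f_ctrl <- sum(config$label_fractions[.CONTROL_LABELS])
  pool <- c(.CASE_LABELS, "control")
  if (n == 0) return(character(0))
  b <- log(config$prs_or)
  if (is.null(z) || all(b == 0))
    return(sample(pool, n, replace = TRUE, prob = c(f_case, f_ctrl)))
  stopifnot(length(z) == n)
  W <- exp(outer(z, b) - rep(b^2 / 2, each = n)) *
    rep(f_case, each = n)                       # n x 6 case weights
  tot <- f_ctrl + rowSums(W)
  u <- runif(n) * tot
  labels <- rep("control", n)
  acc <- rep(f_ctrl, n)
  undecided <- u > acc
  for (k in seq_along(.CASE_LABELS)) {
    acc <- acc + W[, k]
    hit <- undecided & u <= acc
    labels[hit] <- .CASE_LABELS[k]
    undecided <- undecided & !hit
  }
  labels
}

#' Simulate death dates under a proportional-hazards model
#'
#' Time to death is exponential with rate
#' `baseline * HR(label) * exp(beta_age * (age - mean_age) + beta_sex * male)`
#' per year, measured from each participant's follow-up origin `t0`
#' (enrolment for prevalent/self-report/control labels, the qualifying event
#' for incident labels). Deaths falling after the censor date are emitted as
#' alive (`NA`).
#'
#' @param labels Label vector (case labels, `"control"`, or control labels).
#' @param age Age at enrolment.
#' @param sex `"male"`/`"female"` vector.
#' @param t0 Follow-up origin dates.
#' @param config A [simulation_config()].
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return Date vector of death dates (`NA` = alive at censor).
#' @export
simulate_survival <- function(labels, age, sex, t0, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(labels)
  if (n == 0) return(as.Date(character(0)))
  hr <- c(config$hazard_ratios, control = 1, never_CAD = 1, no_CAD = 1)
  rate <- config$baseline_hazard * hr[labels] *
    exp(config$beta_age * (age - config$mean_age) +
          config$beta_sex * (sex == "male"))
  yrs <- rexp(n, rate = pmax(rate, 1e-300))
  if (config$baseline_hazard == 0) yrs <- rep(Inf, n)
  death <- t0 + round(yrs * 365.25)
  death[!is.finite(yrs) | death > config$censor_date] <- NA
  as.Date(death, origin = "1970-01-01")
}

.sample_days <- function(from, to) {
  # one uniform date per row in [from, to] (vectors of equal length)
  span <- as.integer(to - from)
  from + floor(runif(length(from)) * (span + 1))
}

.MI_ICD10 <- c("I210", "I211", "I212", "I213", "I214", "I219",
               "I220", "I228", "I229", "I231", "I236", "I252")
.MI_ICD10_ACUTE <- c("I210", "I211", "I214", "I219", "I220", "I229")
.MI_ICD9 <- c("410", "4109", "412")
.CAD_ICD10 <- c("I200", "I201", "I208", "I209", "I240", "I248", "I249",
                "I251", "I255", "I259")
.CAD_OPCS <- c("K401", "K402", "K411", "K451", "K452", "K491", "K492",
               "K493", "K502", "K751", "K752")
.NEUTRAL_DEATH <- c("C349", "C509", "C61", "J449", "G309")
.NOISE_DX <- c("J459", "E119", "K219", "M545", "N390")

#' Simulate a fully linked synthetic biobank with ground truth
#'
#' Draws participants (enrolment date, age, sex), optionally a genotype
#' panel and true polygenic score, assigns phenotype labels (score-linked
#' when genotypes are on), simulates mortality under the configured hazard
#' gradient, and emits the five cohort tables containing, for each
#' participant, a record pattern that the phenotyping algorithm maps back to
#' the planted label. With `adversarial = TRUE`, distractor records (e.g. a
#' CAD code before enrolment for an incident-MI case, self-reported items
#' for EHR cases, MI death-registry causes for incident-MI deaths,
#' background non-CAD diagnoses) are added; their resolution is still
#' uniquely determined by the hierarchy. Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A `cad_simulation` list: `cohort` ([cad_cohort()]),
#'   `ground_truth` (data.table pid, true_label, true_event_date,
#'   death_date, plus true_score_z / true_score_pct when genotypes are on),
#'   and when genotypes are on `dosages` (rownames = pid), `variants`,
#'   `causal_vids`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cad_sim_config"))
  set.seed(config$seed)
  n <- config$n
  pid <- if (n > 0) sprintf("P%07d", seq_len(n)) else character(0)
  enrol <- if (n > 0) {
    .sample_days(rep(config$enrol_window[1], n),
                 rep(config$enrol_window[2], n))
  } else as.Date(character(0))
  age <- if (n > 0) {
    sample(seq(config$age_range[1], config$age_range[2]), n, replace = TRUE)
  } else integer(0)

  geno <- NULL
  if (config$genotypes && n > 0) geno <- simulate_genotypes(n, config)
  labels <- assign_labels(n, config, z = geno$z_true)

  mf <- config$male_fraction
  pm <- ifelse(labels == "control", mf[["control"]], mf[labels])
  sex <- ifelse(rbinom(n, 1, pm) == 1, "male", "female")

  # planted qualifying-event dates
  ev_date <- rep(as.Date(NA), n)
  is_prev <- labels %in% c("prevalent_MI", "prevalent_CAD_noMI")
  is_inc <- labels %in% .INCIDENT_LABELS
  ev_date[is_prev] <- .sample_days(
    rep(config$prevalent_window_start, sum(is_prev)), enrol[is_prev])
  ev_date[is_inc] <- .sample_days(enrol[is_inc] + 1,
                                  rep(config$censor_date, sum(is_inc)))

  # evidence mode for prevalent CAD without MI: hospital diagnosis,
  # hospital procedure, or undated self-reported procedure
  pcad <- which(labels == "prevalent_CAD_noMI")
  pcad_mode <- sample(c("dx", "proc", "srproc"), length(pcad),
                      replace = TRUE, prob = c(0.5, 0.3, 0.2))
  ev_date[pcad[pcad_mode == "srproc"]] <- NA
  icad <- which(labels == "incident_CAD_noMI")
  icad_mode <- sample(c("dx", "proc"), length(icad), replace = TRUE,
                      prob = c(0.6, 0.4))

  t0 <- data.table::fifelse(is_inc, ev_date, enrol)
  death <- simulate_survival(labels, age, sex, t0, config)

  true_label <- labels
  true_label[labels == "control" & !is.na(death)] <- "never_CAD"
  true_label[labels == "control" & is.na(death)] <- "no_CAD"

  # ---- emit tables ----------------------------------------------------
  dx <- list(); pr <- list(); srp <- list(); de <- list()
  add_dx <- function(ix, cs, codes, dates) {
    if (!length(ix)) return()
    dx[[length(dx) + 1L]] <<- data.table(
      pid = pid[ix], code_system = cs,
      code = sample(codes, length(ix), replace = TRUE),
      position = sample(c("primary", "secondary"), length(ix),
                        replace = TRUE),
      event_date = dates)
  }
  add_proc <- function(ix, dates) {
    if (!length(ix)) return()
    pr[[length(pr) + 1L]] <<- data.table(
      pid = pid[ix], code_system = "OPCS4",
      code = sample(.CAD_OPCS, length(ix), replace = TRUE),
      event_date = dates)
  }
  add_sr <- function(ix, category, items) {
    if (!length(ix)) return()
    srp[[length(srp) + 1L]] <<- data.table(
      pid = pid[ix], category = category,
      item_code = if (length(items) == 1) items else
        sample(items, length(ix), replace = TRUE))
  }

  pmi <- which(labels == "prevalent_MI")
  pmi_icd9 <- pmi[runif(length(pmi)) < 0.2]
  pmi_icd10 <- setdiff(pmi, pmi_icd9)
  add_dx(pmi_icd10, "ICD10", .MI_ICD10, ev_date[pmi_icd10])
  add_dx(pmi_icd9, "ICD9", .MI_ICD9, ev_date[pmi_icd9])
  imi <- which(labels == "incident_MI")
  add_dx(imi, "ICD10", .MI_ICD10_ACUTE, ev_date[imi])
  add_dx(pcad[pcad_mode == "dx"], "ICD10", .CAD_ICD10,
         ev_date[pcad[pcad_mode == "dx"]])
  add_proc(pcad[pcad_mode == "proc"], ev_date[pcad[pcad_mode == "proc"]])
  add_sr(pcad[pcad_mode == "srproc"], "procedure",
         c("CABG", "PTCA", "ANGIOPLASTY"))
  add_dx(icad[icad_mode == "dx"], "ICD10", .CAD_ICD10,
         ev_date[icad[icad_mode == "dx"]])
  add_proc(icad[icad_mode == "proc"], ev_date[icad[icad_mode == "proc"]])
  add_sr(which(labels == "sr_MI"), "illness", "HEART_ATTACK")
  add_sr(which(labels == "sr_CAD_noMI"), "illness", "ANGINA")

  died <- which(!is.na(death))
  if (length(died))
    de[[1]] <- data.table(pid = pid[died], death_date = death[died],
                          code_system = "ICD10",
                          code = sample(.NEUTRAL_DEATH, length(died),
                                        replace = TRUE),
                          role = "underlying")

  if (config$adversarial && n > 0) {
    # cross-tag distractors: resolution remains forced by the hierarchy
    add_dx(pmi, "ICD10", .CAD_ICD10,
           .sample_days(enrol[pmi] + 1, rep(config$censor_date,
                                            length(pmi))))
    add_sr(pmi, "illness", "HEART_ATTACK")
    add_dx(imi, "ICD10", .CAD_ICD10,
           .sample_days(rep(config$prevalent_window_start, length(imi)),
                        enrol[imi]))
    add_sr(imi, "illness", "ANGINA")
    imi_died <- intersect(imi, died)
    if (length(imi_died))
      de[[length(de) + 1L]] <- data.table(
        pid = pid[imi_died], death_date = death[imi_died],
        code_system = "ICD10", code = "I219", role = "contributing")
    add_sr(pcad, "illness", "HEART_ATTACK")
    add_sr(icad, "illness", "ANGINA")
    add_sr(which(labels == "sr_MI"), "illness", "ANGINA")
    noisy <- which(runif(n) < 0.1)
    add_dx(noisy, "ICD10", .NOISE_DX,
           .sample_days(rep(config$prevalent_window_start, length(noisy)),
                        rep(config$censor_date, length(noisy))))
  }

  participants <- data.table(pid = pid, enrol_date = enrol, sex = sex,
                             age_at_enrol = as.integer(age))
  cohort <- cad_cohort(
    participants,
    diagnoses = if (length(dx)) data.table::rbindlist(dx) else NULL,
    procedures = if (length(pr)) data.table::rbindlist(pr) else NULL,
    deaths = if (length(de)) data.table::rbindlist(de) else NULL,
    self_reports = if (length(srp)) data.table::rbindlist(srp) else NULL)

  gt <- data.table(pid = pid, true_label = true_label,
                   true_event_date = ev_date, death_date = death)
  out <- list(cohort = cohort, ground_truth = gt, config = config)
  if (!is.null(geno)) {
    rownames(geno$dosages) <- pid
    gt[, true_score_z := geno$z_true]
    gt[, true_score_pct := if (n > 1) rank(geno$z_true) / n else numeric(n)]
    out$dosages <- geno$dosages
    out$variants <- geno$variants
    out$causal_vids <- geno$causal_vids
  }
  structure(out, class = "cad_simulation")
}

#' @export
print.cad_simulation <- function(x, ...) {
  cat(sprintf("<cad_simulation> n = %d (seed %d%s)\n", x$config$n,
              x$config$seed,
              if (x$config$adversarial) ", adversarial" else ""))
  print(x$ground_truth[, .N, by = true_label])
  invisible(x)
}

#' Write a simulation to delimited files
#'
#' Writes the five cohort tables, `ground_truth.csv`, and (when genotypes
#' were simulated) `dosages.csv` (pid + one column per variant) and
#' `weights.csv`.
#'
#' @param sim A `cad_simulation`.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "cad_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- write_cohort(sim$cohort, dir)
  f <- file.path(dir, "ground_truth.csv")
  data.table::fwrite(sim$ground_truth, f)
  files <- c(files, f)
  if (!is.null(sim$dosages)) {
    d <- data.table(pid = rownames(sim$dosages))
    d <- cbind(d, data.table::as.data.table(sim$dosages))
    fd <- file.path(dir, "dosages.csv")
    data.table::fwrite(d, fd)
    fw <- file.path(dir, "weights.csv")
    data.table::fwrite(sim$variants, fw)
    files <- c(files, fd, fw)
  }
  invisible(files)
}
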