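# Fidelity evaluation 2: polygenic risk score (PRS) association gradient.
# Greedy LD clumping of GWAS summary weights on in-sample dosages,
# weighted-sum scoring with mean-imputation of missing dosages, and per-SD
# logistic odds ratios for each phenotype versus CAD-free controls.

.check_variants <- function(variants) {
  v <- data.table::as.data.table(variants)
  miss <- setdiff(c("vid", "chrom", "pos", "effect_allele", "beta", "pvalue"),
                  names(v))
  if (length(miss))
    .stopf("variant table is missing column(s): %s",
           paste(miss, collapse = ", "))
  v[, `:=`(vid = as.character(vid), chrom = as.character(chrom),
           pos = as.numeric(pos), beta = as.numeric(beta),
           pvalue = as.numeric(pvalue))]
  if (any(!is.finite(v$pvalue) | v$pvalue <= 0 | v$pvalue > 1))
    .stopf("pvalue must lie in (0, 1]")
  if (any(!is.finite(v$pos) | v$pos <= 0))
    .stopf("pos must be a positive base-pair coordinate")
  v
}

#' Greedy LD clumping of GWAS variants
#'
#' Restricts to variants with `pvalue < p_threshold`, then repeatedly takes
#' the remaining variant with the smallest p-value (ties broken by chrom,
#' pos, vid) as an index and removes every other remaining variant on the
#' same chromosome within `window_kb` whose squared Pearson correlation of
#' dosages with the index exceeds `r2_threshold`. Correlation is computed on
#' the supplied (in-sample) dosages; a zero-variance column has undefined
#' correlation, which is treated as 0 (it cannot be clumped away) and
#' counted in `attr(, "n_zero_variance")`.
#'
#' @param variants Variant metadata with columns `vid`, `chrom`, `pos`,
#'   `effect_allele`, `beta`, `pvalue`.
#' @param dosages Numeric matrix of effect-allele dosages in `[0, 2]`
#'   (missing allowed), participants x variants, with `colnames` = vids.
#' @param p_threshold Significance filter applied before clumping
#'   (default 5e-6).
#' @param r2_threshold Squared-correlation threshold (default 0.2).
#' @param window_kb Clumping window in kilobases (default 250).
#' @return The retained variants, sorted by (chrom, pos), with attribute
#'   `n_zero_variance`. No retained pair on one chromosome within the
#'   window has r-squared above the threshold.
#' @export
ld_clump <- function(variants, dosages, p_threshold = 5e-6,
                     r2_threshold = 0.2, window_kb = 250) {
  v <- .check_variants(variants)
  v <- v[pvalue < p_threshold]
  if (!nrow(v)) return(structure(v[], n_zero_variance = 0L))
  missing_cols <- setdiff(v$vid, colnames(dosages))
  if (length(missing_cols))
    .stopf("dosage matrix lacks column(s): %s",
           paste(head(missing_cols, 5), collapse = ", "))

  data.table::setorder(v, pvalue, chrom, pos, vid)
  n <- nrow(v)
  alive <- rep(TRUE, n)
  keep <- logical(n)
  n_zero_var <- 0L
  window_bp <- window_kb * 1000
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    near <- which(alive & v$chrom == v$chrom[i] &
                    abs(v$pos - v$pos[i]) <= window_bp)
    if (!length(near)) next
    r <- suppressWarnings(
      cor(dosages[, v$vid[i]], dosages[, v$vid[near], drop = FALSE],
          use = "pairwise.complete.obs"))
    r <- as.numeric(r)
    nz <- is.na(r)
    n_zero_var <- n_zero_var + sum(nz)
    r[nz] <- 0
    alive[near[r^2 > r2_threshold]] <- FALSE
  }
  out <- v[keep]
  data.table::setorder(out, chrom, pos, vid)
  data.table::setattr(out, "n_zero_variance", n_zero_var)
  out[]
}

#' Compute raw and standardized polygenic risk scores
#'
#' Raw score = sum over selected variants of beta x effect-allele dosage,
#' with missing dosages imputed as twice the column's effect-allele
#' frequency (i.e. the column mean of observed dosages). Scores are then
#' standardized to mean 0, SD 1 over the scored sample. Invariant to the
#' column order of the dosage matrix (variants are matched by `vid`).
#'
#' @param dosages Participants x variants dosage matrix, `colnames` = vids;
#'   `rownames` (participant ids) are carried onto the scores if present.
#' @param variants Selected variants (e.g. from [ld_clump()]) with `vid` and
#'   `beta`; must be a subset of the dosage columns.
#' @param dosage_alleles Optional named character vector (vid ->
#'   effect allele of the dosage column) for allele harmonization; variants
#'   whose `effect_allele` mismatches are dropped with a count in
#'   `attr(, "n_allele_mismatch")`.
#' @return List with `raw` and `z` score vectors; attributes
#'   `n_allele_mismatch` and `n_imputed` (count of imputed entries).
#' @export
compute_prs <- function(dosages, variants, dosage_alleles = NULL) {
  v <- data.table::as.data.table(variants)
  stopifnot(all(c("vid", "beta") %in% names(v)))
  v[, vid := as.character(vid)]
  n_mismatch <- 0L
  if (!is.null(dosage_alleles)) {
    ok <- !is.na(dosage_alleles[v$vid]) &
      dosage_alleles[v$vid] == v$effect_allele
    n_mismatch <- sum(!ok)
    v <- v[ok]
  }
  missing_cols <- setdiff(v$vid, colnames(dosages))
  if (length(missing_cols))
    .stopf("selected variants absent from dosage matrix: %s",
           paste(head(missing_cols, 5), collapse = ", "))
  if (!nrow(v)) .stopf("no variants left to score")

  X <- dosages[, v$vid, drop = FALSE]
  n_imputed <- 0L
  if (anyNA(X)) {
    cm <- colMeans(X, na.rm = TRUE)   # = 2 * effect-allele frequency
    idx <- which(is.na(X), arr.ind = TRUE)
    n_imputed <- nrow(idx)
    X[idx] <- cm[idx[, 2]]
  }
  raw <- drop(X %*% v$beta)
  s <- sd(raw)
  if (!is.finite(s) || s == 0)
    .stopf("standardization error: polygenic score is constant (SD = 0)")
  out <- list(raw = raw, z = (raw - mean(raw)) / s)
  attr(out, "n_allele_mismatch") <- n_mismatch
  attr(out, "n_imputed") <- n_imputed
  out
}

#' Clump and score in one step
#'
#' Convenience wrapper: [ld_clump()] on the weights, then [compute_prs()]
#' on the retained variants.
#'
#' @inheritParams ld_clump
#' @inheritParams compute_prs
#' @return A `cad_prs_model` list: `selected` variants, `raw`, `z`,
#'   `params`.
#' @export
build_prs <- function(dosages, variants, p_threshold = 5e-6,
                      r2_threshold = 0.2, window_kb = 250,
                      dosage_alleles = NULL) {
  sel <- ld_clump(variants, dosages, p_threshold, r2_threshold, window_kb)
  if (!nrow(sel)) .stopf("no variants pass p < %g", p_threshold)
  sc <- compute_prs(dosages, sel, dosage_alleles)
  structure(list(selected = sel, raw = sc$raw, z = sc$z,
                 params = list(p_threshold = p_threshold,
                               r2_threshold = r2_threshold,
                               window_kb = window_kb)),
            class = "cad_prs_model")
}

#' @export
print.cad_prs_model <- function(x, ...) {
  cat(sprintf("<cad_prs_model> %d variants after clumping (p < %g, r2 = %g, %g kb); %d participants scored\n",
              nrow(x$selected), x$params$p_threshold, x$params$r2_threshold,
              x$params$window_kb, length(x$z)))
  invisible(x)
}

#' Per-SD logistic association of the PRS with one phenotype
#'
#' Maximum-likelihood logistic regression of case status (the named
#' phenotype versus CAD-free controls; all other labels excluded) on the
#' standardized score, adjusted for age at enrolment and sex. Reports the
#' odds ratio per 1 SD of score with a Wald 95% CI. Fits with fewer than two
#' cases or showing complete separation are flagged.
#'
#' @param z Standardized scores, named by pid (or a data.frame with `pid`
#'   and `z` columns).
#' @param assignments A `cad_assignments`.
#' @param group Phenotype label (or `"all_CAD"`).
#' @param cohort The matching [cad_cohort()] (for age/sex covariates).
#' @param controls Control labels (default both).
#' @return A `cad_association` list: `group`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `log_or`, `se`, `n_cases`, `n_controls`, `flagged`.
#' @export
logistic_association <- function(z, assignments, group, cohort,
                                 controls = .CONTROL_LABELS) {
  if (is.data.frame(z)) z <- setNames(z$z, z$pid)
  if (is.null(names(z)))
    .stopf("z must be named by pid (or a data.frame with pid and z)")
  a <- data.table::as.data.table(assignments)[, .(pid, label)]
  case_labels <- if (identical(group, "all_CAD")) .CASE_LABELS else group
  dat <- merge(a[label %in% c(case_labels, controls)],
               cohort$participants[, .(pid, age_at_enrol, sex)], by = "pid")
  dat[, z := z[pid]]
  dat <- dat[!is.na(z)]
  dat[, case := as.integer(label %in% case_labels)]
  n_cases <- sum(dat$case); n_controls <- sum(!dat$case)
  if (n_controls == 0L) .stopf("no scored controls available")
  flagged <- n_cases < 2L

  two_sex <- data.table::uniqueN(dat$sex) > 1L
  fml <- if (two_sex) case ~ z + age_at_enrol + sex else case ~ z + age_at_enrol
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(fml, data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  b <- coef(fit)[["z"]]
  se <- sqrt(vcov(fit)["z", "z"])
  flagged <- flagged || sep_warn || !is.finite(b) || !is.finite(se) ||
    abs(b) > 15 || se > 15

  structure(list(group = if (length(group) == 1) group else "cases",
                 odds_ratio = exp(b),
                 ci_low = exp(b - qnorm(0.975) * se),
                 ci_high = exp(b + qnorm(0.975) * se),
                 log_or = b, se = se,
                 n_cases = n_cases, n_controls = n_controls,
                 flagged = flagged),
            class = "cad_association")
}

#' @export
print.cad_association <- function(x, ...) {
  cat(sprintf("%s vs controls: OR per SD %.2f (95%% CI %.2f-%.2f), %d cases / %d controls%s\n",
              x$group, x$odds_ratio, x$ci_low, x$ci_high,
              x$n_cases, x$n_controls,
              if (isTRUE(x$flagged)) " [FLAGGED: unreliable]" else ""))
  invisible(x)
}

#' PRS odds-ratio table across phenotypes
#'
#' Runs [logistic_association()] for each phenotype versus the shared
#' control pool, plus the aggregated all-CAD group.
#'
#' @inheritParams logistic_association
#' @param groups Labels to evaluate (default: the six disease labels
#'   present in the assignments).
#' @param include_all_cad Add the aggregated all-CAD row (default TRUE).
#' @return data.table: `group`, `n_cases`, `or`, `ci_low`, `ci_high`,
#'   `flagged`.
#' @export
association_table <- function(z, assignments, cohort, groups = NULL,
                              include_all_cad = TRUE) {
  if (is.null(groups))
    groups <- intersect(.CASE_LABELS, unique(assignments$label))
  if (include_all_cad) groups <- c(groups, "all_CAD")
  rows <- lapply(groups, function(g) {
    est <- logistic_association(z, assignments, g, cohort)
    data.table(group = g, n_cases = est$n_cases, or = est$odds_ratio,
               ci_low = est$ci_low, ci_high = est$ci_high,
               flagged = est$flagged)
  })
  data.table::rbindlist(rows)
}

#' Read PRS inputs from delimited files
#'
#' Dosage input is a delimited matrix with a participant id column (`pid`)
#' followed by one column per variant (named by vid); variant metadata is a
#' CSV with columns `vid`, `chrom`, `pos`, `effect_allele`, `beta`,
#' `pvalue`.
#'
#' @param dosage_path,weights_path File paths.
#' @return List with `dosages` (numeric matrix, rownames = pid) and
#'   `variants` (data.table).
#' @export
read_prs_inputs <- function(dosage_path, weights_path) {
  d <- data.table::fread(dosage_path)
  if (!"pid" %in% names(d)) .stopf("dosage file must have a 'pid' column")
  pid <- as.character(d$pid)
  d[, pid := NULL]
  m <- as.matrix(d)
  rownames(m) <- pid
  if (length(m) && (min(m, na.rm = TRUE) < 0 || max(m, na.rm = TRUE) > 2))
    .stopf("dosages must lie in [0, 2]")
  v <- .check_variants(data.table::fread(weights_path))
  list(dosages = m, variants = v)
}
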