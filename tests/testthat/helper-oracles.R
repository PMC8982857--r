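# Independent brute-force references used as oracles, deliberately written
# as literal scans/loops so they share no code path with the package.

# longest-prefix match by exhaustive scan over all entries
bf_match_tag <- function(code, entries, cs) {
  sub <- entries[entries$code_system == cs, , drop = FALSE]
  hit <- sub[startsWith(code, sub$prefix), , drop = FALSE]
  if (!nrow(hit)) return(NA_character_)
  hit <- hit[order(-nchar(hit$prefix), hit$phenotype_tag != "MI"), ,
             drop = FALSE]
  hit$phenotype_tag[1]
}

# greedy clumping by repeated whole-table rescan
bf_clump <- function(variants, dosages, p_threshold = 5e-6,
                     r2_threshold = 0.2, window_kb = 250) {
  v <- as.data.frame(variants)
  v <- v[v$pvalue < p_threshold, , drop = FALSE]
  v <- v[order(v$pvalue, v$chrom, v$pos, v$vid), , drop = FALSE]
  kept <- character()
  while (nrow(v)) {
    idx <- v[1, ]
    kept <- c(kept, idx$vid)
    drop <- rep(FALSE, nrow(v))
    drop[1] <- TRUE
    for (j in seq_len(nrow(v))[-1]) {
      if (v$chrom[j] == idx$chrom &&
          abs(v$pos[j] - idx$pos) <= window_kb * 1000) {
        r <- suppressWarnings(cor(dosages[, idx$vid], dosages[, v$vid[j]],
                                  use = "pairwise.complete.obs"))
        if (is.na(r)) r <- 0
        if (r^2 > r2_threshold) drop[j] <- TRUE
      }
    }
    v <- v[!drop, , drop = FALSE]
  }
  sort(kept)
}

# product-limit estimator computed directly as the closed-form product
bf_km <- function(time, event, at) {
  ts <- sort(unique(time[event == 1]))
  sapply(at, function(tt) {
    s <- 1
    for (u in ts[ts <= tt]) {
      d <- sum(time == u & event == 1)
      n <- sum(time >= u)
      s <- s * (1 - d / n)
    }
    s
  })
}

# random small clump instance (correlated column groups, random map)
rand_clump_instance <- function(n_obs = 50, m = 10) {
  chrom <- as.character(sample(1:2, m, replace = TRUE))
  pos <- sample(1:2000, m) * 1000
  base <- matrix(rnorm(n_obs * m), n_obs, m)
  # induce correlation between random pairs
  for (k in seq_len(m %/% 2)) {
    i <- sample(m, 2)
    base[, i[2]] <- base[, i[1]] + rnorm(n_obs, sd = runif(1, 0.1, 2))
  }
  dos <- pmin(pmax(round(base - min(base)) %% 3, 0), 2)
  colnames(dos) <- sprintf("v%03d", seq_len(m))
  variants <- data.frame(
    vid = colnames(dos), chrom = chrom, pos = pos,
    effect_allele = "A",
    beta = rnorm(m, 0, 0.1),
    pvalue = 10^-runif(m, 2, 10))
  list(variants = variants, dosages = dos)
}

# minimal hand-built cohort used across unit tests
mini_cohort <- function() {
  cad_cohort(
    participants = data.frame(
      pid = c("A", "B", "C", "D"),
      enrol_date = c("2007-01-01", "2008-06-15", "2009-03-10", "2010-02-02"),
      sex = c("male", "female", "male", "female"),
      age_at_enrol = c(55L, 60L, 48L, 52L)),
    diagnoses = data.frame(
      pid = c("A", "B"),
      code_system = c("ICD10", "ICD10"),
      code = c("I21.4", "I20.0"),
      position = c("primary", "secondary"),
      event_date = c("2004-05-02", "2012-07-01")),
    deaths = data.frame(
      pid = "C", death_date = "2014-09-09", code_system = "ICD10",
      code = "C349", role = "underlying"),
    self_reports = data.frame(
      pid = "D", category = "illness", item_code = "heart_attack"))
}

# quick sim config with genotypes off (fast path for phenotyper/survival)
quick_config <- function(n, seed, ...) {
  simulation_config(n = n, seed = seed, genotypes = FALSE, ...)
}

# hierarchy step that claimed the participant (1 = EHR MI ... 5 = control)
hierarchy_level <- function(label) {
  lv <- c(prevalent_MI = 1, incident_MI = 1,
          prevalent_CAD_noMI = 2, incident_CAD_noMI = 2,
          sr_MI = 3, sr_CAD_noMI = 4, never_CAD = 5, no_CAD = 5)
  unname(lv[label])
}
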