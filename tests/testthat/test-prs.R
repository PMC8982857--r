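# LD clumping, PRS construction, logistic association.

test_that("greedy clumping follows the p-value/window/r2 rules", {
  set.seed(1)
  # three co-located, strongly correlated variants: only the smallest p
  base <- rnorm(200)
  dos <- cbind(v1 = base, v2 = base + rnorm(200, sd = 0.3),
               v3 = base + rnorm(200, sd = 0.3))
  dos <- 2 * pnorm(scale(dos))  # monotone squash into [0, 2]
  v <- data.frame(vid = c("v1", "v2", "v3"), chrom = "1",
                  pos = c(1e6, 1.01e6, 1.02e6), effect_allele = "A",
                  beta = 0.1, pvalue = c(1e-8, 1e-7, 1e-6))
  stopifnot(min(cor(dos)^2) > 0.5)
  sel <- ld_clump(v, dos)
  expect_equal(sel$vid, "v1")

  # 300 kb apart with a 250 kb window: both retained regardless of r2
  v2 <- v[1:2, ]; v2$pos <- c(1e6, 1.3e6)
  expect_setequal(ld_clump(v2, dos)$vid, c("v1", "v2"))
  # same distance on different chromosomes: both retained
  v3 <- v[1:2, ]; v3$chrom <- c("1", "2")
  expect_setequal(ld_clump(v3, dos)$vid, c("v1", "v2"))
  # the p threshold filters before clumping (variants spaced beyond the
  # window so only the filter decides)
  v4 <- v; v4$pos <- c(1e6, 2e6, 3e6); v4$pvalue <- c(1e-8, 0.5, 1e-6)
  expect_setequal(ld_clump(v4, dos)$vid, c("v1", "v3"))

  # zero-variance dosage column: correlation treated as 0, variant kept
  dos0 <- dos; dos0[, "v2"] <- 1
  sel0 <- ld_clump(v, dos0)
  expect_true("v2" %in% sel0$vid)
  expect_gte(attr(sel0, "n_zero_variance"), 1)
})

test_that("clumping matches the brute-force reference on random instances", {
  set.seed(99)
  for (i in 1:80) {
    inst <- rand_clump_instance()
    got <- sort(ld_clump(inst$variants, inst$dosages,
                         p_threshold = 1e-3)$vid)
    want <- bf_clump(inst$variants, inst$dosages, p_threshold = 1e-3)
    expect_identical(got, want)
  }
})

test_that("no retained pair within the window exceeds the r2 threshold", {
  set.seed(4)
  for (i in 1:10) {
    inst <- rand_clump_instance(n_obs = 80, m = 14)
    sel <- ld_clump(inst$variants, inst$dosages, p_threshold = 1e-2,
                    r2_threshold = 0.2, window_kb = 250)
    if (nrow(sel) < 2) next
    for (a in 1:(nrow(sel) - 1)) for (b in (a + 1):nrow(sel)) {
      if (sel$chrom[a] != sel$chrom[b]) next
      if (abs(sel$pos[a] - sel$pos[b]) > 250e3) next
      r <- cor(inst$dosages[, sel$vid[a]], inst$dosages[, sel$vid[b]],
               use = "pairwise.complete.obs")
      if (is.na(r)) r <- 0
      expect_lte(r^2, 0.2)
    }
  }
})

test_that("scores are the beta-weighted dosage sums with mean imputation", {
  dos <- rbind(c(2, 1, 0), c(0, 1, 2), c(1, 1, 1))
  colnames(dos) <- c("a", "b", "c")
  v <- data.frame(vid = c("a", "b", "c"), beta = c(0.1, 0.2, 0.3))
  sc <- compute_prs(dos, v)
  expect_equal(sc$raw, c(0.4, 0.8, 0.6))
  expect_equal(mean(sc$z), 0, tolerance = 1e-12)
  expect_equal(sd(sc$z), 1, tolerance = 1e-12)

  # all-zero betas: constant score -> standardization error
  v0 <- v; v0$beta <- 0
  expect_error(compute_prs(dos, v0), "constant")

  # missing dosage at an allele-frequency-0.5 column imputes to 1.0
  dosm <- rbind(c(2, 1), c(0, 1), c(NA, 1), c(2, 0), c(0, 2))
  colnames(dosm) <- c("a", "b")
  vm <- data.frame(vid = "a", beta = 1)
  scm <- compute_prs(dosm, vm)
  expect_equal(scm$raw[3], 1.0)
  expect_equal(attr(scm, "n_imputed"), 1L)
})

test_that("scoring is invariant to dosage column order and harmonizes alleles", {
  set.seed(6)
  dos <- matrix(sample(0:2, 60, TRUE), 20, 3,
                dimnames = list(NULL, c("a", "b", "c")))
  v <- data.frame(vid = c("a", "b", "c"), effect_allele = c("A", "C", "G"),
                  beta = c(0.5, -0.2, 0.1))
  s1 <- compute_prs(dos, v)
  s2 <- compute_prs(dos[, c("c", "a", "b")], v)
  expect_equal(s1$raw, s2$raw)

  # allele mismatches are dropped with a count
  al <- c(a = "A", b = "T", c = "G")
  s3 <- compute_prs(dos, v, dosage_alleles = al)
  expect_equal(attr(s3, "n_allele_mismatch"), 1L)
  expect_equal(s3$raw, drop(dos[, c("a", "c")] %*% c(0.5, 0.1)))

  expect_error(compute_prs(dos, data.frame(vid = "zzz", beta = 1)), "zzz")
})

test_that("standardized scores from the full pipeline have mean 0 and SD 1", {
  sim <- simulate_cohort(simulation_config(n = 3000, seed = 14))
  m <- build_prs(sim$dosages, sim$variants)
  expect_lt(abs(mean(m$z)), 1e-8)
  expect_lt(abs(sd(m$z) - 1), 1e-8)
  # clumping on the synthetic panel keeps exactly the causal variants
  expect_setequal(m$selected$vid, sim$causal_vids)
})

test_that("logistic association recovers planted effects, nulls and flags", {
  cfg <- simulation_config(n = 40000, seed = 15)
  sim <- simulate_cohort(cfg)
  a <- run_algorithm(sim$cohort)
  m <- build_prs(sim$dosages, sim$variants)
  z <- setNames(m$z, rownames(sim$dosages))

  est <- logistic_association(z, a, "prevalent_MI", sim$cohort)
  expect_false(est$flagged)
  expect_true(est$ci_low <= 1.50 && 1.50 <= est$ci_high)
  # planted log-OR recovered within 3 Wald SEs
  expect_lt(abs(est$log_or - log(1.50)), 3 * est$se)

  # score independent of case status: CI covers 1
  cfg0 <- simulation_config(n = 40000, seed = 16,
                            prs_or = setNames(rep(1, 6),
                                              cad_labels("case")))
  sim0 <- simulate_cohort(cfg0)
  a0 <- run_algorithm(sim0$cohort)
  m0 <- build_prs(sim0$dosages, sim0$variants)
  z0 <- setNames(m0$z, rownames(sim0$dosages))
  est0 <- logistic_association(z0, a0, "all_CAD", sim0$cohort)
  expect_true(est0$ci_low <= 1 && 1 <= est0$ci_high)

  # fewer than two cases is flagged
  tiny <- a[a$label %in% cad_labels("control")][1:50]
  tiny$label[1] <- "sr_MI"
  est_t <- logistic_association(z, tiny, "sr_MI", sim$cohort)
  expect_true(est_t$flagged)
})

test_that("PRS inputs round-trip through the delimited interfaces", {
  sim <- simulate_cohort(simulation_config(n = 120, seed = 17))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  inp <- read_prs_inputs(file.path(dir, "dosages.csv"),
                         file.path(dir, "weights.csv"))
  expect_equal(dim(inp$dosages), dim(sim$dosages))
  expect_equal(rownames(inp$dosages), rownames(sim$dosages))
  expect_equal(unname(inp$dosages), unname(sim$dosages))
  expect_equal(inp$variants$vid, sim$variants$vid)
  m1 <- build_prs(sim$dosages, sim$variants)
  m2 <- build_prs(inp$dosages, inp$variants)
  expect_equal(m1$z, m2$z)
})
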