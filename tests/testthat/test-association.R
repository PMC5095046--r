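test_that("logistic MLE reproduces closed-form 2x2 odds ratios", {
  # OR = (20*60)/(30*10) = 4 with 0/1 dosage coding
  co <- table_cohort(20, 30, 10, 60, carrier_dose = 1)
  r <- fit_study_association(co, "snpA")
  expect_equal(r$status, "ok")
  expect_equal(r$beta, log(4), tolerance = 1e-8)
  # OR = (10*80)/(40*20) = 1 -> beta = 0 exactly at the MLE, even with the
  # 0/2 dosage coding (which would halve a nonzero beta)
  co0 <- table_cohort(10, 40, 20, 80, carrier_dose = 2)
  r0 <- fit_study_association(co0, "snpA")
  expect_equal(r0$beta, 0, tolerance = 1e-10)
})

test_that("degenerate fits are flagged, not fatal", {
  co <- table_cohort(20, 30, 10, 60)
  co$dosages[, 1] <- 1  # constant dosage
  expect_equal(fit_study_association(co, "snpA")$status, "constant")
  # perfect separation: carriers are exactly the cases
  cos <- table_cohort(50, 0, 0, 50)
  expect_equal(fit_study_association(cos, "snpA")$status, "separation")
  expect_error(fit_study_association(co, "nope"), "not present")
})

test_that("IVW meta-analysis matches hand-computed weighted means", {
  m1 <- meta_analyze(0.3, 0.1)
  expect_equal(m1$beta, 0.3, tolerance = 1e-12)
  expect_equal(m1$se, 0.1, tolerance = 1e-12)
  m2 <- meta_analyze(c(0.2, 0.4), c(0.1, 0.1))
  expect_equal(m2$beta, 0.3, tolerance = 1e-12)
  expect_equal(m2$se, 0.1 / sqrt(2), tolerance = 1e-12)
  m3 <- meta_analyze(c(0.0, 1.0), c(0.05, 0.5))
  expect_equal(m3$beta, 4 / 404, tolerance = 1e-12)
  expect_error(meta_analyze(numeric(0), numeric(0)), "at least one")
  expect_error(meta_analyze(c(0.1, 0.2), c(0.1, -0.1)), "> 0")
})

test_that("meta-analysis is study-order invariant and precision-dominant", {
  set.seed(42)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    beta <- rnorm(k)
    se <- runif(k, 0.05, 0.5)
    m <- meta_analyze(beta, se)
    perm <- sample(k)
    mp <- meta_analyze(beta[perm], se[perm])
    expect_equal(m$beta, mp$beta, tolerance = 1e-14)
    expect_equal(m$se, mp$se, tolerance = 1e-14)
    expect_equal(m$p, mp$p, tolerance = 1e-14)
    expect_lte(m$se, min(se))
    # brute-force oracle: WLS fit of study betas to a constant
    wls <- lm(beta ~ 1, weights = 1 / se^2)
    expect_equal(m$beta, unname(coef(wls)[1]), tolerance = 1e-10)
  }
})

test_that("p-values are consistent with beta/se under the normal approximation", {
  d <- tiny_dataset(seed = 21)
  gw <- run_association_scan(d$cohorts, d$snp_meta$snp_id[1:50])
  expect_equal(gw$p, 2 * pnorm(-abs(gw$beta / gw$se)), tolerance = 1e-10)
  expect_true(all(gw$se > 0))
  expect_true(all(gw$p > 0 & gw$p <= 1))
})

test_that("scan composes per-study fits and applies the exclusion rule", {
  d <- tiny_dataset(seed = 9)
  ids <- d$snp_meta$snp_id[1:3]
  gw <- run_association_scan(d$cohorts, ids)
  expect_equal(nrow(gw), 3)
  expect_true(all(gw$n_studies == 2))
  # make one SNP constant in study 1 only: meta must use study 2 alone
  d$cohorts[[1]]$dosages[, ids[2]] <- 1
  gw2 <- run_association_scan(d$cohorts, ids)
  expect_equal(gw2$n_studies[2], 1)
  solo <- fit_study_association(d$cohorts[[2]], ids[2])
  expect_equal(gw2$beta[2], solo$beta, tolerance = 1e-12)
  # absent everywhere -> error naming the SNP
  d$cohorts[[1]]$dosages[, ids[3]] <- 1
  d$cohorts[[2]]$dosages[, ids[3]] <- 1
  expect_error(run_association_scan(d$cohorts, ids), ids[3])
})

test_that("null scan p-values are uniform at genome scale", {
  cfg <- simulation_config(
    n_studies = 1,
    samples_per_study = data.frame(n_cases = 250, n_controls = 750),
    n_snps = 5000, n_genes = 200, maf_range = c(0.05, 0.5),
    esnp_fraction_per_threshold = c(tier1 = 0.1, tier2 = 0.05,
                                    tier3 = 0.05),
    gene_sets = data.frame(name = "S1", db_tag = "KEGG", size = 10),
    seed = 5)
  sim <- simulate_cohorts(cfg)
  gw <- run_association_scan(sim$cohorts, sim$snp_meta$snp_id)
  frac <- mean(gw$p < 0.05)
  expect_gte(frac, 0.04)
  expect_lte(frac, 0.06)
  expect_gt(stats::ks.test(gw$p, "punif")$p.value, 0.01)
  # null coverage: |beta| < 3 se nearly always
  expect_gte(mean(abs(gw$beta) < 3 * gw$se), 0.985)
})

test_that("score-test fast path agrees with the Wald logistic scan", {
  cfg <- simulation_config(
    n_studies = 2,
    samples_per_study = data.frame(n_cases = c(300, 200),
                                   n_controls = c(700, 800)),
    n_snps = 1000, n_genes = 200, maf_range = c(0.05, 0.5),
    esnp_fraction_per_threshold = c(tier1 = 0.3, tier2 = 0.1, tier3 = 0.1),
    gene_sets = data.frame(name = "S1", db_tag = "KEGG", size = 10),
    seed = 11)
  sim <- simulate_cohorts(cfg)
  gw <- run_association_scan(sim$cohorts, sim$snp_meta$snp_id)
  sc <- score_scan(sim$cohorts)
  expect_gt(cor(rank(gw$p), rank(sc$p)), 0.99)
  # permuted labels conserve per-study case totals exactly
  set.seed(99)
  ys <- permute_phenotypes(sim$cohorts)
  for (k in 1:2) {
    expect_identical(sum(ys[[k]]), sum(sim$cohorts[[k]]$phenotype))
    expect_identical(sort(ys[[k]]), sort(sim$cohorts[[k]]$phenotype))
  }
})
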