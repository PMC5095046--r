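test_that("gene ranking sorts by statistic with lexicographic tie-break", {
  r <- ranked_from_stats(c(g1 = 1.2, g2 = 3.4, g3 = 0.5))
  expect_identical(r$genes, c("g2", "g1", "g3"))
  expect_identical(r$statistics, c(3.4, 1.2, 0.5))
  rt <- ranked_from_stats(c(b = 1, c = 1, a = 1))
  expect_identical(rt$genes, c("a", "b", "c"))
  # 100 random statistics match a brute-force stable sort
  set.seed(17)
  stats <- setNames(round(runif(100), 2), sprintf("g%03d", sample(100)))
  r100 <- ranked_from_stats(stats)
  ref <- stats[order(-stats, names(stats))]
  expect_identical(r100$genes, names(ref))
  expect_identical(r100$statistics, unname(ref))
})

test_that("enrichment score reproduces hand-computed running sums", {
  r <- ranked_from_stats(c(g1 = 3, g2 = 2, g3 = 1))
  # hit at the top: +3/3 then misses -1/2, -1/2 -> extremum 1.0
  expect_equal(enrichment_score(r, "g1"), 1.0, tolerance = 1e-14)
  # hit at the bottom: -0.5, -1.0, then +1 -> extremum -1.0
  expect_equal(enrichment_score(r, "g3"), -1.0, tolerance = 1e-14)
  expect_error(enrichment_score(r, "absent"), "no gene")
  expect_error(enrichment_score(r, c("g1", "g2", "g3")), "entire")
})

test_that("unweighted enrichment score equals the classic KS statistic", {
  set.seed(23)
  for (i in 1:50) {
    n <- sample(20:100, 1)
    stats <- setNames(sort(runif(n, 0, 3), decreasing = TRUE),
                      sprintf("g%03d", 1:n))
    members <- sample(names(stats), sample(3:(n - 3), 1))
    es <- enrichment_score(ranked_from_stats(stats), members, weight_p = 0)
    hit_pos <- which(names(stats) %in% members)
    ks <- suppressWarnings(stats::ks.test(hit_pos, setdiff(1:n, hit_pos)))
    expect_equal(abs(es), unname(ks$statistic), tolerance = 1e-12)
  }
})

test_that("enrichment score is bounded and attains 1 on concentrated hits", {
  set.seed(29)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    stats <- setNames(sort(rexp(n), decreasing = TRUE),
                      sprintf("g%03d", 1:n))
    members <- sample(names(stats), sample(2:(n - 2), 1))
    es <- enrichment_score(ranked_from_stats(stats), members)
    expect_gte(es, -1)
    expect_lte(es, 1)
  }
  # all hits strictly before all misses -> running sum reaches exactly 1
  stats <- setNames(c(5, 4, 3, 2, 1), paste0("g", 1:5))
  expect_equal(enrichment_score(ranked_from_stats(stats),
                                c("g1", "g2", "g3")), 1, tolerance = 1e-14)
})

test_that("permutation p-value implements the plus-one estimator", {
  expect_equal(permutation_p(0.25, c(0.1, 0.2, 0.3)), 0.5)     # (1+1)/4
  expect_equal(permutation_p(2, rep(0.5, 1000)), 1 / 1001)
  expect_equal(permutation_p(0.05, rep(0.5, 1000)), 1)
  expect_equal(permutation_p(-0.25, c(0.1, -0.2, 0.3)), 0.5)   # sign-agnostic
  expect_error(permutation_p(1, numeric(0)), "empty")
})

test_that("normalization divides by the same-sign null mean", {
  null1 <- matrix(c(0.4, 0.6, -0.2, -0.4), 1)   # mean pos 0.5, mean |neg| 0.3
  nrm <- normalize_scores(c(P = 1.0), null1)
  expect_equal(unname(nrm$nes_obs), 2.0, tolerance = 1e-12)
  expect_equal(normalize_scores(c(P = 0.5), null1)$nes_obs[["P"]], 1.0,
               tolerance = 1e-12)
  expect_equal(normalize_scores(c(P = -0.3), null1)$nes_obs[["P"]], -1.0,
               tolerance = 1e-12)
  # random 10-pathway instance vs a brute-force per-row recomputation
  set.seed(41)
  es_null <- matrix(rnorm(10 * 50, sd = 0.4), 10)
  es_obs <- setNames(rnorm(10, sd = 0.4), paste0("p", 1:10))
  nrm10 <- normalize_scores(es_obs, es_null)
  for (i in 1:10) {
    row <- es_null[i, ]
    eo <- unname(es_obs[i])
    expected <- if (eo > 0) eo / mean(row[row > 0])
                else if (eo < 0) eo / mean(abs(row[row < 0]))
                else 0
    expect_equal(unname(nrm10$nes_obs[i]), expected, tolerance = 1e-12)
    j <- sample(50, 1)
    expected_null <- if (row[j] > 0) row[j] / mean(row[row > 0])
                     else if (row[j] < 0) row[j] / mean(abs(row[row < 0]))
                     else 0
    expect_equal(nrm10$nes_null[i, j], expected_null, tolerance = 1e-12)
  }
  expect_warning(normalize_scores(c(P = 0.5), matrix(c(-1, -2), 1)),
                 "no same-sign")
})

test_that("FDR matches hand counts and is calibrated under the null", {
  nes_obs <- c(a = 3, b = 2, c = 1)
  nes_null <- matrix(1, 3, 4)  # pooled null: twelve 1s
  f <- compute_fdr(nes_obs, nes_null)
  expect_equal(f$fdr[f$pathway == "a"], 0)
  expect_equal(f$fdr[f$pathway == "c"], 1)  # (12/12)/(3/3)
  # one pathway more extreme than every pooled null value -> FDR 0
  f1 <- compute_fdr(c(top = 2), matrix(runif(100), 1))
  expect_equal(f1$fdr, 0)
  # observed and null identically distributed -> median raw FDR near 1
  set.seed(43)
  obs <- abs(rnorm(50))
  nul <- matrix(abs(rnorm(50 * 100)), 50)
  fn <- compute_fdr(setNames(obs, paste0("p", 1:50)), nul)
  expect_gte(median(fn$fdr_raw), 0.5)
  expect_lte(median(fn$fdr_raw), 1.5)
})

test_that("size filter uses inclusive bounds on represented genes", {
  genome <- sprintf("g%03d", 1:300)
  sets <- list(s2 = genome[1:2], s3 = genome[1:3], s50 = genome[1:50],
               s200 = genome[1:200], s201 = genome[1:201])
  coll <- gene_set_collection(sets)
  surr <- data.frame(gene_id = genome, snp_id = paste0("x", 1:300),
                     p_gwas = 0.5, gene_statistic = -log10(0.5))
  flt <- size_filter(coll, surr)
  expect_setequal(names(flt$collection$sets), c("s3", "s50", "s200"))
  expect_identical(unname(flt$size_represented), c(3L, 50L, 200L))
  # partially represented: membership counts only genes with surrogates
  flt2 <- size_filter(coll, surr[1:2, ])
  expect_length(flt2$collection$sets, 0)
})

test_that("permutation null is reproducible and conserves case totals", {
  d <- tiny_dataset(seed = 19)
  qc <- suppressMessages(apply_qc(select_esnps(d$eqtl, 1e-4), d$snp_meta))
  gw <- run_association_scan(d$cohorts, unique(qc$snp_id))
  surr <- assign_surrogates(qc, gw)
  flt <- size_filter(d$collection, surr)
  n1 <- permute_and_rescore(d$cohorts, qc, flt$collection, b = 1, seed = 5)
  n2 <- permute_and_rescore(d$cohorts, qc, flt$collection, b = 1, seed = 5)
  expect_identical(n1$es_null, n2$es_null)
  n3 <- permute_and_rescore(d$cohorts, qc, flt$collection, b = 1, seed = 6)
  expect_false(identical(n1$es_null, n3$es_null))
  expect_equal(dim(n1$es_null), c(length(flt$collection$sets), 1))
})

test_that("full enrichment run is deterministic and order-invariant", {
  d <- tiny_dataset(seed = 33)
  run <- function(coll) {
    out <- suppressMessages(
      run_enrichment(d$cohorts, d$eqtl, d$snp_meta, coll, b = 25, seed = 3))
    attr(out, "details") <- NULL
    out
  }
  r1 <- run(d$collection)
  r2 <- run(d$collection)
  expect_identical(r1, r2)
  # permute pathway input order: identical results up to row order
  perm <- sample(length(d$collection$sets))
  shuffled <- gene_set_collection(d$collection$sets[perm],
                                  d$collection$db_tags[perm])
  r3 <- run(shuffled)
  expect_identical(r1[order(r1$pathway), ], r3[order(r3$pathway), ],
                   ignore_attr = TRUE)
  # significance flag is exactly the conjunction rule
  expect_identical(r1$significant, r1$p_perm < 0.05 & r1$fdr < 0.2)
})

test_that("planted effect size increases detection monotonically", {
  med_p <- vapply(c(1.1, 1.5, 2.2), function(or) {
    ps <- vapply(1:5, function(rep) {
      cfg <- tiny_config(seed = 600 + rep,
                         planted = c(P01 = log(or)))
      sim <- simulate_cohorts(cfg)
      eq <- simulate_eqtl_table(cfg, sim$truth)
      gs <- simulate_gene_sets(cfg)
      res <- suppressMessages(suppressWarnings(
        run_enrichment(sim$cohorts, eq, sim$snp_meta, gs, b = 100,
                       seed = 700 + rep)))
      res$p_perm[res$pathway == "P01"]
    }, numeric(1))
    median(ps)
  }, numeric(1))
  expect_true(all(diff(med_p) <= 0))
})

test_that("sensitivity runner equals single runs and grows representation", {
  d <- tiny_dataset(seed = 37)
  sens <- suppressMessages(
    sensitivity_runner(d$cohorts, d$eqtl, d$snp_meta, d$collection,
                       thresholds = c(1e-5, 1e-4), b = 25, seed = 11))
  single <- suppressMessages(
    run_enrichment(d$cohorts, d$eqtl, d$snp_meta, d$collection,
                   eqtl_threshold = 1e-5, b = 25, seed = 11))
  expect_identical(sens[["1e-05"]], single)
  common <- intersect(sens[["1e-05"]]$pathway, sens[["1e-04"]]$pathway)
  sz1 <- sens[["1e-05"]]$size_represented[match(common,
                                                sens[["1e-05"]]$pathway)]
  sz2 <- sens[["1e-04"]]$size_represented[match(common,
                                                sens[["1e-04"]]$pathway)]
  expect_true(all(sz2 >= sz1))
  expect_error(sensitivity_runner(d$cohorts, d$eqtl, d$snp_meta,
                                  d$collection, thresholds = c(1e-5, 1e-5)),
               "distinct")
})

test_that("a pathway can enter the tested universe only at looser thresholds", {
  # constructed fixture: set of 3 genes; two have tier-1 eSNPs, the third
  # only a tier-3 eSNP, so the set is size-2 (excluded) at 1e-5 and size-3
  # (tested) at 1e-4
  d <- tiny_dataset(seed = 39)
  snps <- d$cohorts[[1]]$snp_ids[1:8]
  eq <- data.frame(snp_id = snps,
                   gene_id = c("gA", "gB", "gC", "gD", "gE", "gF", "gG",
                               "gH"),
                   p_eqtl = c(1e-6, 1e-6, 8e-5, rep(1e-6, 5)))
  meta <- data.frame(snp_id = snps, chr = 1, pos = 1:8,
                     maf = 0.3, imp_r2 = 0.9)
  coll <- gene_set_collection(list(BORDER = c("gA", "gB", "gC")))
  sens <- suppressWarnings(suppressMessages(
    sensitivity_runner(d$cohorts, eq, meta, coll,
                       thresholds = c(1e-4, 1e-5), b = 10, seed = 2)))
  expect_identical(sens[["1e-04"]]$pathway, "BORDER")
  expect_false("BORDER" %in% sens[["1e-05"]]$pathway)
  expect_equal(nrow(sens[["1e-05"]]), 0)
})

test_that("fold over chance returns the expected count and ratio", {
  f <- fold_over_chance(0, 100, 0.05)
  expect_equal(f$expected, 5)
  expect_equal(f$fold, 0)
  expect_error(fold_over_chance(1, 0, 0.05))
})
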