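---
title: "Methods: eSNP-integrated pathway enrichment for case-control GWAS"
author: "esnpgsea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eSNP-integrated pathway enrichment for case-control GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esnpgsea)
```

## The problem

Single-marker genome-wide association scans of a complex disease such as
basal cell carcinoma detect only the strongest individual signals, leaving
variants of moderate effect below the genome-wide threshold. Pathway-level
analysis aggregates such moderate signals across functionally related genes.
`esnpgsea` implements a specific flavour of this idea: genes are represented
not by the SNPs that happen to fall inside their boundaries, but by
*expression-related SNPs* (eSNPs) — variants associated with the gene's
expression in a disease-relevant tissue — so that the SNP chosen for a gene
is plausibly functional and may act in *trans* from a distant locus.

The pipeline has four statistical stages, each exposed as ordinary R
functions:

1. **Association.** In each case-control study, every SNP's allele dosage is
   tested against disease status with a multivariate logistic regression
   adjusted for age and the first three genetic principal components. The
   per-study log-odds estimates are combined by fixed-effect
   inverse-variance-weighted (IVW) meta-analysis,
   $\hat\beta = \sum_i w_i \hat\beta_i / \sum_i w_i$ with $w_i = 1/se_i^2$,
   the same scheme METAL uses by default.
2. **Gene representation.** eSNPs are selected from an eQTL summary table at
   a significance threshold ($10^{-5}$ for the main analysis; $5\times
   10^{-5}$ and $10^{-4}$ as sensitivity analyses), filtered to MAF $> 1\%$
   and imputation $R^2 > 0.4$ (all strict inequalities), and each gene with
   at least one qualifying eSNP is assigned a single *surrogate eSNP*: the
   one most significantly associated with disease. The gene's ranking
   statistic is $-\log_{10} p$ of that association.
3. **Enrichment.** Genes are ranked by statistic and each pathway is scored
   with the weighted Kolmogorov–Smirnov-like running sum: walking down the
   ranked list, member genes ("hits") add $|r_j|^p / N_R$ (with
   $N_R = \sum_{hits} |r_j|^p$) and non-members subtract $1/(N - N_H)$; the
   enrichment score (ES) is the excursion of maximal absolute magnitude.
   Only pathways with between 3 and 200 represented genes (inclusive) are
   tested.
4. **Inference.** Case-control labels are permuted within each study and
   the entire association → surrogate-selection → ranking → ES chain is
   recomputed (1,000 permutations by default), giving each pathway a
   permutation p-value, a normalized enrichment score (NES: ES divided by
   the mean same-sign permuted ES of the same pathway), and a pooled-null
   FDR estimate. A pathway is reported significant when $p < 0.05$ and
   FDR $< 0.2$.

## Design choices

Several details of the procedure are under-determined in the literature;
the package settles them as follows.

* **Gene-ranking statistic.** The surrogate's meta-analysis p-value on the
  $-\log_{10}$ scale. It is monotone in the Wald chi-square, non-negative
  (so meaningful enrichment is positive-ES), and scale-friendly as the
  running-sum weight. The weight exponent defaults to $p = 1$, the standard
  GSEA weighting; `weight_p = 0` recovers the classic unweighted KS
  statistic (asserted against `stats::ks.test` in the tests).
* **Surrogate re-selection inside permutations.** The per-gene minimum over
  association p-values is part of the test statistic, so the null must
  include the selection step; freezing the observed surrogates would bias
  the null anti-conservatively. Each permutation therefore re-runs
  `assign_surrogates()` before re-ranking.
* **Score-test fast path.** Refitting a full logistic regression per SNP,
  study and permutation would be prohibitively slow. Inside the permutation
  loop the package uses the covariate-adjusted Rao score test: one
  covariate-only logistic fit per study per permutation, then a vectorized
  score statistic $U = g'(y-\hat\mu)$, $V = g'Wg - g'WX(X'WX)^{-1}X'Wg$ for
  all SNPs at once, summed across studies (the stratified score test, the
  asymptotic equivalent of the IVW Wald meta-analysis). The observed-data
  pass uses the full maximum-likelihood fit; rank agreement between the two
  (> 0.99) is asserted in the test suite, and the null calibration check
  below confirms the mixture does not distort inference.
* **Permutation p-value.** The plus-one estimator
  $p = (1 + \#\{|ES_\pi| \ge |ES_{obs}|\})/(1 + B)$, sign-agnostic, so the
  smallest reportable value at $B = 1000$ is about $0.001$. Reported
  p-values below that resolution (as sometimes printed in the literature)
  cannot arise from a within-run label permutation and are not emulated.
* **Label permutation within study.** Shuffling labels within each study
  conserves per-study case totals and covariate distributions exactly,
  respecting the stratified design; covariates stay attached to samples.
* **FDR per database.** The pooled-null NES FDR is computed separately
  within each pathway collection (KEGG, GO, BioCarta, ...), since each
  collection forms its own testing universe. The raw GSEA-style ratio is
  reported alongside a value capped at 1; Benjamini–Hochberg on the
  permutation p-values is available via `fdr_method = "BH"` for comparison.
* **Strict thresholds.** eSNP selection ($p_{eqtl} < t$), MAF
  ($> 0.01$) and imputation quality ($> 0.4$) all use strict inequalities;
  boundary behaviour is pinned by tests. Ties in surrogate selection break
  to the lexicographically smallest SNP id; ties in gene ranking to the
  lexicographically smallest gene id — both so results are independent of
  input order.
* **Degenerate fits.** Constant dosages, separation (detected as
  $|\hat\beta| > 15$), non-convergence (IRLS, relative tolerance $10^{-10}$,
  50 iterations) and an inestimable dosage coefficient are flagged and the
  study is dropped from that SNP's meta-analysis rather than crashing the
  scan. A pathway whose running sum has no same-sign permuted value gets an
  `NA` NES with a warning. If every hit in a pathway has zero weight
  ($N_R = 0$, possible only when all hit p-values are exactly 1), hit
  increments fall back to the unweighted $1/N_H$.

## The synthetic-data generator

Real cohort genotypes and eQTL resources of this kind are access-controlled,
so the package ships a generator that emulates the statistical structure the
analysis assumes, with known ground truth:

* **Cohorts.** The default design is eight case-control studies with
  unbalanced case fractions totalling 2,323 cases and 7,275 controls.
  Genotypes are Hardy–Weinberg draws at a per-SNP MAF sampled uniformly
  from `maf_range`; imputed dosages are produced by attenuating the
  genotype toward its mean with calibrated Gaussian noise so that
  $\mathrm{cor}(dosage, genotype)^2$ matches the per-SNP imputation $R^2$,
  then clipping to $[0, 2]$.
* **Phenotype.** A logistic disease model with per-gene effects planted on
  each causal gene's eSNP; the study intercept is tuned by root-finding so
  the expected case count matches the configured one. Age
  $\sim N(60, 8)$ and three standard-normal PCs are independent of genotype
  by default, with an optional confounding knob (`covariate_effects`).
* **eQTL table.** eSNPs are organized in three tiers whose p-values fall in
  $[10^{-7}, 10^{-5})$, $[10^{-5}, 5\times10^{-5})$ and
  $[5\times10^{-5}, 10^{-4})$, so the three selection thresholds recover
  cumulative tier counts; non-eSNPs get p-values on $[10^{-3}, 1]$. Every
  causal gene receives a dedicated tier-1 eSNP so planted signal survives
  all thresholds.
* **Gene sets.** Configurable (name, database tag, size) with random,
  possibly overlapping membership; the default collection spans the 3–200
  filter and includes one undersized and one oversized set to exercise it.

Deliberate simplifications: SNPs are independent (no linkage
disequilibrium) — the analysis operates on one surrogate eSNP per gene, so
inter-SNP LD is not needed to exercise any stage; disease effects are
planted directly on eSNP dosages rather than through an expression
intermediate, because the joint distribution of eQTL and disease effect
sizes is not characterized in the source material; and there is no
population stratification or sex-chromosome structure. Passing tests on
this generator therefore demonstrate the statistical machinery is correct
and calibrated, not that any particular real pathway is (or is not)
associated with disease.

## Calibration and power designs

Two fixed designs characterize the pipeline's operating behaviour at desk
scale (sizes chosen once as realistic-but-small analogues of the
multi-cohort design):

* `null_calibration_config()` — two studies, 2,000 samples, 2,000 SNPs
  (1,500 eSNPs), 400 genes, 40 pathways, no planted effects. Across ten
  seeds with 200 permutations each, pathway permutation p-values are
  uniform (pooled Kolmogorov–Smirnov test) and on average at most 10% of
  pathways reach nominal $p < 0.05$.
* `planted_pathway_config()` — 6,000 samples, one 10-gene pathway planted
  at a per-gene allelic odds ratio of 1.4 among 39 null pathways. Over 25
  replicates the planted pathway attains the smallest permutation p-value
  in at least 80% of runs and is called significant ($p < 0.05$,
  FDR $< 0.2$) in the majority.

Both checks are part of the test suite and are recomputed, together with
the fold-over-chance arithmetic and the enrichment-score oracle agreement,
by `scripts/acceptance.R`.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(
  n_studies = 2,
  samples_per_study = data.frame(n_cases = c(150, 120),
                                 n_controls = c(350, 380)),
  n_snps = 300, n_genes = 100,
  esnp_fraction_per_threshold = c(tier1 = 0.3, tier2 = 0.1, tier3 = 0.1),
  gene_sets = data.frame(name = sprintf("P%02d", 1:10),
                         db_tag = "KEGG", size = 8),
  planted_pathways = c(P01 = 0.4),
  seed = 42)
sim <- simulate_cohorts(cfg)
res <- run_enrichment(sim$cohorts,
                      simulate_eqtl_table(cfg, sim$truth),
                      sim$snp_meta,
                      simulate_gene_sets(cfg),
                      b = 200, seed = 7)
head(res)
```

## Known limitations

* The permutation null and the observed pass use asymptotically equivalent
  but not identical per-SNP tests (score vs Wald); at very small study
  sizes (tens of samples) the approximation degrades along with the
  logistic asymptotics themselves.
* Pathways sharing genes produce correlated enrichment scores; the
  fold-over-chance summary is therefore conservative, and the pooled FDR
  inherits the usual GSEA caveats.
* The FDR estimator is the raw pooled ratio without monotonicity
  enforcement across thresholds.
* With $B$ permutations, p-values are bounded below by $1/(B+1)$; ranking
  among top pathways with tied minimal p-values is driven by NES.
* The generator does not emulate LD, so SNP-level statistics are
  independent across loci in a way real GWAS data are not; pathway-level
  inference is insulated from this by the one-surrogate-per-gene design.
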