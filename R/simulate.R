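# Derive a stream-specific seed from the user seed; kept below 2^31 - 1.
.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1e6) * 1009 + 7 * k + 1) %% 2147483647L
}

#' Simulation configuration for multi-study case-control cohorts
#'
#' Builds and validates the configuration object consumed by
#' [simulate_cohorts()], [simulate_eqtl_table()] and [simulate_gene_sets()].
#' The defaults emulate the design of a multi-cohort basal-cell-carcinoma
#' GWAS: eight nested case-control studies with unbalanced case fractions
#' totalling 2,323 cases and 7,275 controls, dosage genotypes with an
#' imputation-quality spectrum, a skin-tissue-like eQTL summary table with
#' three significance tiers, and KEGG/GO/BioCarta-like gene-set collections.
#'
#' @param n_studies number of case-control studies.
#' @param samples_per_study data.frame (or list of pairs) with columns
#'   `n_cases`, `n_controls`, one row per study.
#' @param n_snps number of SNPs genotyped in every study.
#' @param n_genes number of genes in the simulated genome.
#' @param maf_range length-2 numeric, minor allele frequencies drawn uniformly
#'   from this interval; must lie in (0, 0.5].
#' @param esnp_fraction_per_threshold named numeric of length 3
#'   (`tier1`, `tier2`, `tier3`): fraction of SNPs that are eSNPs with an eQTL
#'   p-value in \eqn{[10^{-7}, 10^{-5})}, \eqn{[10^{-5}, 5\times10^{-5})} and
#'   \eqn{[5\times10^{-5}, 10^{-4})} respectively, so that the tiers accumulate
#'   across the selection thresholds 1e-5, 5e-5 and 1e-4.
#' @param gene_sets data.frame with columns `name`, `db_tag`, `size` describing
#'   the pathway collection to simulate. The default collection spans the
#'   3-200 represented-size filter and deliberately includes one undersized
#'   (2 genes) and one oversized (250 genes, when `n_genes` allows) pathway.
#' @param planted_pathways named numeric: pathway name -> per-gene disease
#'   effect (log-odds per dosage unit) planted on every member gene's causal
#'   eSNP. Empty by default (global null).
#' @param imputation_r2_range length-2 numeric in (0, 1]; per-SNP imputation
#'   quality drawn uniformly from this interval.
#' @param covariate_effects named numeric `c(age = , pc = )` giving log-odds
#'   per unit of age (centred) and per principal-component unit; both zero by
#'   default so covariates are pure noise unless confounding is requested.
#' @param seed integer seed; together with the configuration it fully
#'   determines every generated output.
#'
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_studies = 8,
                              samples_per_study = NULL,
                              n_snps = 20000,
                              n_genes = 3000,
                              maf_range = c(0.01, 0.5),
                              esnp_fraction_per_threshold = c(tier1 = 0.035,
                                                              tier2 = 0.008,
                                                              tier3 = 0.005),
                              gene_sets = NULL,
                              planted_pathways = numeric(0),
                              imputation_r2_range = c(0.3, 1),
                              covariate_effects = c(age = 0, pc = 0),
                              seed = 1L) {
  if (is.null(samples_per_study)) {
    if (n_studies == 8) {
      # unbalanced split of 2,323 cases / 7,275 controls across eight studies
      samples_per_study <- data.frame(
        n_cases    = c(400, 350, 300, 300, 250, 250, 250, 223),
        n_controls = c(1300, 1100, 1000, 950, 900, 800, 700, 525))
    } else {
      samples_per_study <- data.frame(
        n_cases = rep(250, n_studies), n_controls = rep(750, n_studies))
    }
  }
  if (is.list(samples_per_study) && !is.data.frame(samples_per_study)) {
    samples_per_study <- data.frame(
      n_cases    = vapply(samples_per_study, `[`, numeric(1), 1),
      n_controls = vapply(samples_per_study, `[`, numeric(1), 2))
  }
  if (is.null(gene_sets)) gene_sets <- default_gene_sets(n_genes)

  cfg <- structure(list(
    n_studies = as.integer(n_studies),
    samples_per_study = samples_per_study,
    n_snps = as.integer(n_snps),
    n_genes = as.integer(n_genes),
    maf_range = as.numeric(maf_range),
    esnp_fraction_per_threshold = esnp_fraction_per_threshold,
    gene_sets = gene_sets,
    planted_pathways = planted_pathways,
    imputation_r2_range = as.numeric(imputation_r2_range),
    covariate_effects = covariate_effects,
    seed = as.integer(seed)), class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  sps <- cfg$samples_per_study
  if (nrow(sps) != cfg$n_studies)
    stop("samples_per_study must have one row per study", call. = FALSE)
  if (any(sps$n_cases < 1) || any(sps$n_controls < 1))
    stop("every study needs at least one case and one control", call. = FALSE)
  if (cfg$n_snps < 1 || cfg$n_genes < 1)
    stop("n_snps and n_genes must be >= 1", call. = FALSE)
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  if (length(cfg$imputation_r2_range) != 2 ||
      cfg$imputation_r2_range[1] <= 0 || cfg$imputation_r2_range[2] > 1)
    stop("imputation_r2_range must lie within (0, 1]", call. = FALSE)
  fr <- cfg$esnp_fraction_per_threshold
  if (length(fr) != 3 || any(fr < 0) || sum(fr) > 1)
    stop("esnp_fraction_per_threshold must be 3 non-negative fractions summing to <= 1",
         call. = FALSE)
  gs <- cfg$gene_sets
  if (!all(c("name", "db_tag", "size") %in% names(gs)))
    stop("gene_sets needs columns name, db_tag, size", call. = FALSE)
  if (anyDuplicated(gs$name))
    stop("gene set names must be unique", call. = FALSE)
  if (any(gs$size < 1)) stop("gene set sizes must be >= 1", call. = FALSE)
  if (any(gs$size > cfg$n_genes))
    stop("requested gene set sizes exceed n_genes", call. = FALSE)
  pp <- cfg$planted_pathways
  if (length(pp) && !all(names(pp) %in% gs$name))
    stop("every planted pathway must appear in gene_sets: missing ",
         paste(setdiff(names(pp), gs$name), collapse = ", "), call. = FALSE)
  invisible(cfg)
}

#' Default simulated pathway collection
#'
#' KEGG/GO/BioCarta-tagged pathways whose sizes span the 3-200 filter, plus
#' one deliberately undersized (2 genes) and, when the genome is large enough,
#' one oversized (250 genes) pathway so the size filter is exercised.
#'
#' @param n_genes genome size; caps pathway sizes.
#' @return data.frame with columns `name`, `db_tag`, `size`.
#' @export
default_gene_sets <- function(n_genes) {
  base_sizes <- c(3, 5, 8, 10, 15, 20, 30, 50, 75, 100, 150, 200)
  base_sizes <- base_sizes[base_sizes <= n_genes]
  out <- data.frame(
    name = sprintf("KEGG_SET_%02d", seq_along(base_sizes)),
    db_tag = "KEGG", size = base_sizes)
  go_sizes <- c(4, 12, 25, 60)
  go_sizes <- go_sizes[go_sizes <= n_genes]
  out <- rbind(out, data.frame(
    name = sprintf("GO_SET_%02d", seq_along(go_sizes)),
    db_tag = "GO", size = go_sizes))
  extras <- data.frame(name = "TINY_SET", db_tag = "BioCarta",
                       size = min(2L, n_genes))
  if (n_genes >= 250)
    extras <- rbind(extras, data.frame(name = "HUGE_SET", db_tag = "BioCarta",
                                       size = 250L))
  rbind(out, extras)
}

.gene_ids <- function(n) sprintf("gene%05d", seq_len(n))
.snp_ids <- function(n) sprintf("snp%06d", seq_len(n))

# Membership draw for the configured pathway collection (seeded sub-stream).
.draw_gene_sets <- function(config) {
  set.seed(.sub_seed(config$seed, 1))
  genes <- .gene_ids(config$n_genes)
  sets <- lapply(config$gene_sets$size, function(sz) sort(sample(genes, sz)))
  names(sets) <- config$gene_sets$name
  db <- stats::setNames(as.character(config$gene_sets$db_tag),
                        config$gene_sets$name)
  gene_set_collection(sets, db)
}

# Ground truth: causal genes/pathways, per-gene effects, SNP -> (gene, tier)
# eSNP assignment. Every causal gene gets a dedicated tier-1 eSNP (so it is
# selected at all three thresholds) which also carries the planted disease
# effect; remaining eSNP slots are assigned to uniformly chosen genes.
.simulation_truth <- function(config) {
  collection <- .draw_gene_sets(config)
  pp <- config$planted_pathways
  causal_pathways <- names(pp)
  effect_map <- numeric(0)
  for (pw in causal_pathways) {
    members <- collection$sets[[pw]]
    eff <- stats::setNames(rep(pp[[pw]], length(members)), members)
    # a gene in two planted pathways keeps the larger |effect|
    keep <- !(members %in% names(effect_map)) |
      abs(eff) > abs(effect_map[members])[match(members, names(effect_map))]
    keep[is.na(keep)] <- TRUE
    effect_map[members[keep]] <- eff[keep]
  }
  effect_map <- effect_map[effect_map != 0]
  causal_genes <- names(effect_map)

  set.seed(.sub_seed(config$seed, 2))
  snps <- .snp_ids(config$n_snps)
  genes <- .gene_ids(config$n_genes)
  n_tier <- round(config$esnp_fraction_per_threshold * config$n_snps)
  if (n_tier[1] < length(causal_genes))
    stop("tier-1 eSNP budget (", n_tier[1], ") too small for ",
         length(causal_genes), " causal genes", call. = FALSE)
  pool <- sample(snps)
  take <- function(k) {
    if (k == 0) return(character(0))
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  causal_snp <- stats::setNames(take(length(causal_genes)), causal_genes)
  esnp <- data.frame(
    snp_id = as.character(causal_snp),
    gene_id = causal_genes,
    tier = rep(1L, length(causal_genes)),
    stringsAsFactors = FALSE)
  for (t in 1:3) {
    extra <- n_tier[t] - if (t == 1) length(causal_genes) else 0L
    if (extra > 0) {
      esnp <- rbind(esnp, data.frame(
        snp_id = take(extra),
        gene_id = sample(genes, extra, replace = TRUE),
        tier = rep(t, extra), stringsAsFactors = FALSE))
    }
  }
  rownames(esnp) <- NULL
  structure(list(
    causal_genes = causal_genes,
    causal_pathways = causal_pathways,
    effect_map = effect_map,
    causal_snp = causal_snp,
    esnp_map = esnp), class = "simulation_truth")
}

# Per-SNP metadata: MAF, imputation quality, and arbitrary (but fixed)
# autosomal coordinates.
.snp_metadata <- function(config) {
  set.seed(.sub_seed(config$seed, 3))
  n <- config$n_snps
  data.frame(
    snp_id = .snp_ids(n),
    chr = sample(1:22, n, replace = TRUE),
    pos = sample.int(2.4e8, n, replace = TRUE),
    maf = stats::runif(n, config$maf_range[1], config$maf_range[2]),
    imp_r2 = stats::runif(n, config$imputation_r2_range[1],
                          config$imputation_r2_range[2]),
    stringsAsFactors = FALSE)
}

#' Generate multi-study case-control cohorts with known ground truth
#'
#' Simulates one dosage cohort per configured study. Genotypes are drawn under
#' Hardy-Weinberg equilibrium at the per-SNP minor allele frequency, then
#' degraded to continuous imputed dosages whose squared correlation with the
#' true genotype matches the per-SNP imputation R-squared (attenuation toward
#' the allele-frequency mean plus calibrated noise, clipped to \[0, 2\]).
#' Disease status follows a logistic model
#' \deqn{\mathrm{logit}\,P(\mathrm{case}) = \alpha_s + \sum_g \beta_g d_{g} +
#'   \gamma\,\mathrm{age} + \delta\,\mathrm{PC}_{1..3}}
#' where \eqn{d_g} is the dosage of gene g's causal eSNP and the study
#' intercept \eqn{\alpha_s} is tuned by root-finding so the expected case
#' count equals the configured one. Age is Normal(60, 8); the three principal
#' components are standard normal, independent of genotype by default.
#'
#' @param config a [simulation_config()].
#' @return list with elements `cohorts` (list of [cohort_data()]), `truth`
#'   (causal genes/pathways, effect map, eSNP assignments) and `snp_meta`
#'   (per-SNP metadata data.frame).
#' @export
simulate_cohorts <- function(config) {
  validate_simulation_config(config)
  truth <- .simulation_truth(config)
  meta <- .snp_metadata(config)
  snps <- meta$snp_id
  causal_idx <- match(truth$causal_snp, snps)
  betas <- truth$effect_map

  cohorts <- vector("list", config$n_studies)
  for (s in seq_len(config$n_studies)) {
    set.seed(.sub_seed(config$seed, 10 + s))
    n_cases <- config$samples_per_study$n_cases[s]
    n_controls <- config$samples_per_study$n_controls[s]
    n <- n_cases + n_controls
    if (n_cases > n)
      stop("requested cases exceed samples in study ", s, call. = FALSE)

    age <- stats::rnorm(n, 60, 8)
    pcs <- matrix(stats::rnorm(n * 3), n, 3,
                  dimnames = list(NULL, c("pc1", "pc2", "pc3")))

    g <- matrix(stats::rbinom(n * config$n_snps, 2L,
                              rep(meta$maf, each = n)),
                n, config$n_snps)
    mu <- 2 * meta$maf
    r2 <- meta$imp_r2
    sd_noise <- sqrt(pmax(r2 * (1 - r2) * 2 * meta$maf * (1 - meta$maf), 0))
    dos <- sweep(g, 2, mu) * rep(r2, each = n) +
      matrix(stats::rnorm(n * config$n_snps), n) * rep(sd_noise, each = n)
    dos <- sweep(dos, 2, mu, `+`)
    dos[dos < 0] <- 0
    dos[dos > 2] <- 2
    colnames(dos) <- snps

    eta <- rep(0, n)
    if (length(betas))
      eta <- eta + drop(dos[, causal_idx, drop = FALSE] %*% betas)
    ce <- config$covariate_effects
    eta <- eta + ce[["age"]] * (age - 60) + ce[["pc"]] * rowSums(pcs)

    f <- function(a) sum(stats::plogis(a + eta)) - n_cases
    alpha <- stats::uniroot(f, c(-40, 40), tol = 1e-9)$root
    y <- stats::rbinom(n, 1L, stats::plogis(alpha + eta))
    if (sum(y) == 0 || sum(y) == n)
      stop("degenerate phenotype draw in study ", s,
           "; increase the study size", call. = FALSE)

    cohorts[[s]] <- cohort_data(
      study_id = sprintf("study%02d", s),
      sample_ids = sprintf("study%02d_s%05d", s, seq_len(n)),
      phenotype = y,
      covariates = cbind(age = age, pcs),
      dosages = dos)
  }
  list(cohorts = cohorts, truth = truth, snp_meta = meta)
}

#' Simulate an eQTL summary table
#'
#' Every SNP designated an eSNP at tier t in the simulation truth receives an
#' eQTL p-value drawn uniformly from that tier's interval
#' (tier 1: \[1e-7, 1e-5), tier 2: \[1e-5, 5e-5), tier 3: \[5e-5, 1e-4)), so
#' the three selection thresholds 1e-5, 5e-5 and 1e-4 recover the cumulative
#' tier counts. Non-eSNPs receive p-values uniform on \[1e-3, 1\] against a
#' uniformly chosen gene. A gene may carry several eSNPs and a SNP may appear
#' for several genes (trans regulation).
#'
#' @param config a [simulation_config()].
#' @param truth the `truth` element returned by [simulate_cohorts()].
#' @return data.frame with columns `snp_id`, `gene_id`, `p_eqtl`.
#' @export
simulate_eqtl_table <- function(config, truth) {
  validate_simulation_config(config)
  set.seed(.sub_seed(config$seed, 4))
  lo <- c(1e-7, 1e-5, 5e-5)
  hi <- c(1e-5, 5e-5, 1e-4)
  em <- truth$esnp_map
  p_esnp <- stats::runif(nrow(em), lo[em$tier], hi[em$tier])
  # runif can in principle return its upper bound; fold back inside the tier
  p_esnp <- pmin(p_esnp, hi[em$tier] * (1 - 1e-12))
  rest <- setdiff(.snp_ids(config$n_snps), em$snp_id)
  out <- rbind(
    data.frame(snp_id = em$snp_id, gene_id = em$gene_id, p_eqtl = p_esnp,
               stringsAsFactors = FALSE),
    data.frame(snp_id = rest,
               gene_id = sample(.gene_ids(config$n_genes), length(rest),
                                replace = TRUE),
               p_eqtl = stats::runif(length(rest), 1e-3, 1),
               stringsAsFactors = FALSE))
  out <- out[order(out$snp_id, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Simulate a gene-set collection
#'
#' Materializes the pathway collection described in the configuration as a
#' [gene_set_collection()]: for each configured (name, db_tag, size) a random
#' but seed-determined subset of the simulated genome. Overlap between sets is
#' allowed (and with the default collection, expected), mirroring the gene
#' sharing between curated pathways.
#'
#' @param config a [simulation_config()].
#' @return a [gene_set_collection()].
#' @export
simulate_gene_sets <- function(config) {
  validate_simulation_config(config)
  .draw_gene_sets(config)
}

#' Reference study designs for calibration and power evaluation
#'
#' Two fixed synthetic designs used to characterize the pipeline's operating
#' behaviour. `null_calibration_config()` is a global-null design (no planted
#' effects): two studies totalling 2,000 samples, 2,000 SNPs (1,500 of them
#' eSNPs across the three tiers), 400 genes and 40 KEGG-tagged pathways of
#' sizes 5-30; pathway permutation p-values on this design should be uniform.
#' `planted_pathway_config()` plants one 10-gene pathway with a per-gene
#' allelic odds ratio (default 1.4) among 39 null pathways in a 6,000-sample
#' two-study design; the planted pathway should dominate the ranking.
#'
#' @param seed integer seed.
#' @return a [simulation_config()].
#' @export
null_calibration_config <- function(seed = 1L) {
  simulation_config(
    n_studies = 2,
    samples_per_study = data.frame(n_cases = c(300, 200),
                                   n_controls = c(700, 800)),
    n_snps = 2000, n_genes = 400,
    maf_range = c(0.05, 0.5),
    esnp_fraction_per_threshold = c(tier1 = 0.4, tier2 = 0.2, tier3 = 0.15),
    gene_sets = data.frame(
      name = sprintf("KEGG_NULL_%02d", 1:40),
      db_tag = "KEGG",
      size = rep(c(5, 8, 10, 12, 15, 20, 25, 30), 5)),
    planted_pathways = numeric(0),
    imputation_r2_range = c(0.6, 1),
    seed = seed)
}

#' @rdname null_calibration_config
#' @param or per-gene allelic odds ratio planted on every member of the
#'   planted pathway.
#' @export
planted_pathway_config <- function(seed = 1L, or = 1.4) {
  simulation_config(
    n_studies = 2,
    samples_per_study = data.frame(n_cases = c(750, 750),
                                   n_controls = c(2250, 2250)),
    n_snps = 1500, n_genes = 400,
    maf_range = c(0.05, 0.5),
    esnp_fraction_per_threshold = c(tier1 = 0.4, tier2 = 0.2, tier3 = 0.15),
    gene_sets = rbind(
      data.frame(name = "PLANTED", db_tag = "KEGG", size = 10),
      data.frame(name = sprintf("KEGG_NULL_%02d", 1:39),
                 db_tag = "KEGG",
                 size = rep(c(5, 8, 10, 12, 15, 20, 25, 30), length.out = 39))),
    planted_pathways = c(PLANTED = log(or)),
    imputation_r2_range = c(0.6, 1),
    seed = seed)
}
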