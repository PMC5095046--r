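# Small simulation design shared across tests: 2 modest studies, dense eSNP
# coverage so most genes are represented.
tiny_config <- function(seed = 1, planted = numeric(0),
                        gene_sets = data.frame(name = sprintf("P%02d", 1:10),
                                               db_tag = "KEGG",
                                               size = rep(8, 10)),
                        n_snps = 300, n_genes = 100, ...) {
  simulation_config(
    n_studies = 2,
    samples_per_study = data.frame(n_cases = c(150, 120),
                                   n_controls = c(350, 380)),
    n_snps = n_snps, n_genes = n_genes,
    maf_range = c(0.05, 0.5),
    esnp_fraction_per_threshold = c(tier1 = 0.3, tier2 = 0.1, tier3 = 0.1),
    gene_sets = gene_sets,
    planted_pathways = planted,
    imputation_r2_range = c(0.6, 1),
    seed = seed, ...)
}

tiny_dataset <- function(seed = 1, ...) {
  cfg <- tiny_config(seed = seed, ...)
  sim <- simulate_cohorts(cfg)
  list(config = cfg, cohorts = sim$cohorts, truth = sim$truth,
       snp_meta = sim$snp_meta,
       eqtl = simulate_eqtl_table(cfg, sim$truth),
       collection = simulate_gene_sets(cfg))
}

# Independent brute-force running-sum oracle: explicit position-by-position
# loop, kept deliberately naive.
oracle_running_sum_es <- function(stats, hit, weight_p) {
  N <- length(stats)
  nh <- sum(hit)
  nr <- sum(abs(stats[hit])^weight_p)
  cur <- 0
  best <- 0
  for (j in seq_len(N)) {
    cur <- cur + if (hit[j]) {
      if (nr > 0) abs(stats[j])^weight_p / nr else 1 / nh
    } else {
      -1 / (N - nh)
    }
    if (abs(cur) > abs(best)) best <- cur
  }
  best
}

# Build a ranked_gene_list directly from named statistics.
ranked_from_stats <- function(stats) {
  rank_genes(data.frame(gene_id = names(stats),
                        snp_id = paste0("s_", names(stats)),
                        p_gwas = 10^(-stats),
                        gene_statistic = unname(stats),
                        stringsAsFactors = FALSE))
}

# Minimal single-SNP cohort for closed-form logistic tests. Covariates are
# all zero, i.e. aliased with the intercept and dropped by pivoting.
table_cohort <- function(case_carrier, case_non, ctrl_carrier, ctrl_non,
                         carrier_dose = 1) {
  y <- c(rep(1, case_carrier + case_non), rep(0, ctrl_carrier + ctrl_non))
  g <- c(rep(carrier_dose, case_carrier), rep(0, case_non),
         rep(carrier_dose, ctrl_carrier), rep(0, ctrl_non))
  n <- length(y)
  cohort_data("tab", sprintf("s%03d", seq_len(n)), y,
              matrix(0, n, 4, dimnames = list(NULL,
                                              c("age", "pc1", "pc2", "pc3"))),
              matrix(g, n, 1, dimnames = list(NULL, "snpA")))
}
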