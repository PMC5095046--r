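#' Named gene-set collection
#'
#' @param sets named list of character vectors (member gene ids); no set may
#'   be empty and names must be unique.
#' @param db_tags named character vector (pathway -> database tag, e.g.
#'   `"KEGG"`, `"GO"`, `"BioCarta"`, `"custom"`); defaults to `"custom"`.
#' @param annotations optional named character vector of free-text notes.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, db_tags = NULL, annotations = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("every gene set needs a name", call. = FALSE)
  if (anyDuplicated(names(sets)))
    stop("duplicate gene set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "),
         call. = FALSE)
  if (any(lengths(sets) == 0))
    stop("empty gene sets are not allowed", call. = FALSE)
  if (is.null(db_tags))
    db_tags <- stats::setNames(rep("custom", length(sets)), names(sets))
  structure(list(sets = sets,
                 db_tags = db_tags[names(sets)],
                 annotations = annotations),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets (%s); sizes %d-%d\n",
              length(x$sets),
              paste(names(table(x$db_tags)), collapse = "/"),
              min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Rank genes by disease-association statistic
#'
#' Orders represented genes by descending gene statistic
#' (\eqn{-\log_{10} p} of the surrogate eSNP's disease association); ties are
#' broken by ascending gene id so the ranking is deterministic.
#'
#' @param surrogates surrogate table from [assign_surrogates()].
#' @return object of class `ranked_gene_list`: list with `genes` (ordered
#'   ids) and `statistics` (aligned non-increasing values).
#' @export
rank_genes <- function(surrogates) {
  if (nrow(surrogates) == 0) stop("no genes to rank", call. = FALSE)
  ord <- order(-surrogates$gene_statistic, surrogates$gene_id)
  structure(list(genes = surrogates$gene_id[ord],
                 statistics = surrogates$gene_statistic[ord]),
            class = "ranked_gene_list")
}

# Core running sum. r: non-increasing statistics; hit: logical membership
# aligned with r; weight_p: exponent on |r| for hit increments. Hits add
# |r|^p / N_R, misses subtract 1/(N - N_H); the ES is the running-sum value
# of maximal absolute magnitude (earliest such position on exact ties).
.running_sum_es <- function(r, hit, weight_p) {
  N <- length(r)
  nh <- sum(hit)
  w <- abs(r)^weight_p
  nr <- sum(w[hit])
  inc <- numeric(N)
  # all-zero hit weights (e.g. every hit has p = 1): fall back to equal steps
  inc[hit] <- if (nr > 0) w[hit] / nr else 1 / nh
  inc[!hit] <- -1 / (N - nh)
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

#' Weighted Kolmogorov-Smirnov-like enrichment score
#'
#' Walks down the ranked gene list accumulating \eqn{|r_j|^p / N_R} at every
#' pathway member ("hit", \eqn{N_R = \sum_{hits} |r_j|^p}) and
#' \eqn{-1/(N - N_H)} at every non-member. The enrichment score is the
#' running-sum value of maximal absolute magnitude, signed; with `weight_p =
#' 0` this reduces to the classic (unweighted) Kolmogorov-Smirnov statistic.
#'
#' @param ranked a [rank_genes()] result.
#' @param members character vector of pathway member gene ids.
#' @param weight_p weight exponent; 1 (the GSEA default) unless overridden.
#' @return the enrichment score, a number in \[-1, 1\].
#' @export
enrichment_score <- function(ranked, members, weight_p = 1) {
  stopifnot(inherits(ranked, "ranked_gene_list"))
  hit <- ranked$genes %in% members
  if (!any(hit))
    stop("pathway has no gene in the ranked list", call. = FALSE)
  if (all(hit))
    stop("pathway covers the entire ranked list; ES undefined", call. = FALSE)
  .running_sum_es(ranked$statistics, hit, weight_p)
}

#' Filter pathways by represented size
#'
#' A pathway is tested only if the number of its member genes that carry a
#' surrogate eSNP lies within \[`lo`, `hi`\] (inclusive); 3 and 200 are used
#' unless overridden.
#'
#' @param collection a [gene_set_collection()].
#' @param surrogates surrogate table from [assign_surrogates()].
#' @param lo,hi inclusive bounds on represented size.
#' @return list with `collection` (the tested subset), `size_represented`
#'   and `size_annotated` (named integer vectors over tested pathways).
#' @export
size_filter <- function(collection, surrogates, lo = 3, hi = 200) {
  stopifnot(lo <= hi)
  represented <- unique(surrogates$gene_id)
  n_rep <- vapply(collection$sets,
                  function(m) sum(m %in% represented), integer(1))
  keep <- n_rep >= lo & n_rep <= hi
  sub <- gene_set_collection(collection$sets[keep],
                             collection$db_tags[keep],
                             collection$annotations)
  list(collection = sub,
       size_represented = n_rep[keep],
       size_annotated = lengths(collection$sets)[keep])
}

#' Phenotype-permutation null for pathway enrichment scores
#'
#' Builds the permutation null by, for each of `b` permutations: shuffling
#' case-control labels independently within each study (covariates stay
#' attached to their samples, so per-study case totals and covariate
#' distributions are conserved exactly), recomputing every eSNP's disease
#' association with the covariate-adjusted stratified score test
#' ([score_scan()]), re-selecting each gene's surrogate eSNP under the
#' permuted labels (the per-gene minimum over association p-values is part of
#' the statistic, so the null must include the selection step), re-ranking
#' genes, and recomputing the enrichment score of every tested pathway.
#'
#' @param cohorts list of [cohort_data()] sharing a SNP panel.
#' @param esnps QC-passed eQTL records (`snp_id`, `gene_id`) defining the
#'   gene-eSNP universe.
#' @param collection the tested [gene_set_collection()] (already
#'   size-filtered).
#' @param b number of permutations (1,000 in the reference design).
#' @param seed integer seed; the null is reproducible from it.
#' @param weight_p enrichment-score weight exponent.
#' @return object of class `permutation_null`: list with `b`, `seed`,
#'   `pathways` and `es_null` (pathway-by-permutation matrix).
#' @export
permute_and_rescore <- function(cohorts, esnps, collection, b = 1000,
                                seed = 1L, weight_p = 1) {
  stopifnot(b >= 1)
  prep <- .perm_prep(cohorts, esnps, collection)
  set.seed(as.integer(seed))
  es <- matrix(NA_real_, length(collection$sets), b,
               dimnames = list(names(collection$sets), NULL))
  for (perm in seq_len(b)) {
    ys <- permute_phenotypes(cohorts)
    p_snp <- score_scan(cohorts, prep$snp_idx, phenotypes = ys)$p
    es[, perm] <- .es_from_snp_p(p_snp, prep, weight_p)
  }
  structure(list(b = b, seed = as.integer(seed),
                 pathways = names(collection$sets), es_null = es),
            class = "permutation_null")
}

#' Permute case-control labels within each study
#'
#' Draws one phenotype permutation: labels are shuffled independently within
#' every study, so per-study case and control totals are conserved exactly
#' and covariates stay attached to their samples. Uses the current RNG
#' state.
#'
#' @param cohorts list of [cohort_data()].
#' @return list of permuted 0/1 phenotype vectors, one per cohort.
#' @export
permute_phenotypes <- function(cohorts) {
  lapply(cohorts, function(co)
    co$phenotype[sample.int(length(co$phenotype))])
}

# Shared machinery between observed and permuted passes: SNP coordinates,
# per-gene eSNP row groups, and per-pathway membership masks over the fixed
# set of represented genes.
.perm_prep <- function(cohorts, esnps, collection) {
  snp_ids <- unique(esnps$snp_id)
  snp_idx <- match(snp_ids, cohorts[[1]]$snp_ids)
  if (anyNA(snp_idx))
    stop("eSNP(s) absent from the cohort dosage panel: ",
         paste(utils::head(snp_ids[is.na(snp_idx)], 5), collapse = ", "),
         call. = FALSE)
  row_snp <- match(esnps$snp_id, snp_ids)
  genes <- sort(unique(esnps$gene_id))
  groups <- split(row_snp, factor(esnps$gene_id, levels = genes))
  # row index of the lexicographically smallest SNP id per group position is
  # irrelevant here: only the min p feeds the ranking statistic
  memb <- lapply(collection$sets, function(m) genes %in% m)
  list(snp_ids = snp_ids, snp_idx = snp_idx, genes = genes,
       groups = groups, memb = memb)
}

# From a per-SNP p-value vector (aligned with prep$snp_ids) to the vector of
# pathway enrichment scores.
.es_from_snp_p <- function(p_snp, prep, weight_p) {
  stat <- -log10(vapply(prep$groups, function(ix) min(p_snp[ix]), numeric(1)))
  ord <- order(-stat, prep$genes)
  r <- stat[ord]
  vapply(prep$memb,
         function(mb) .running_sum_es(r, mb[ord], weight_p),
         numeric(1))
}

#' Permutation p-value for one pathway
#'
#' Sign-agnostic plus-one estimator
#' \eqn{p = (1 + \#\{\pi: |ES_\pi| \ge |ES_{obs}|\}) / (1 + b)}; strictly
#' positive, with smallest attainable value \eqn{1/(b+1)} (about 0.001 at
#' 1,000 permutations).
#'
#' @param es_obs observed enrichment score.
#' @param es_null_row numeric vector of null enrichment scores.
#' @return the permutation p-value in (0, 1\].
#' @export
permutation_p <- function(es_obs, es_null_row) {
  if (length(es_null_row) == 0) stop("empty null row", call. = FALSE)
  (1 + sum(abs(es_null_row) >= abs(es_obs))) / (1 + length(es_null_row))
}

#' Sign-stratified normalization of enrichment scores
#'
#' Divides every positive (negative) enrichment score by the mean positive
#' (mean absolute negative) null enrichment score of its pathway, yielding
#' normalized enrichment scores (NES) comparable across pathways of
#' different sizes. The same row-wise normalization is applied to the null
#' matrix itself. A pathway with no same-sign null value gets `NA` with a
#' warning.
#'
#' @param es_obs named numeric vector of observed enrichment scores.
#' @param es_null pathway-by-permutation matrix of null enrichment scores
#'   (rows aligned with `es_obs`).
#' @return list with `nes_obs` and `nes_null`.
#' @export
normalize_scores <- function(es_obs, es_null) {
  stopifnot(length(es_obs) == nrow(es_null))
  n <- length(es_obs)
  nes_obs <- numeric(n)
  nes_null <- es_null
  missing_norm <- character(0)
  for (i in seq_len(n)) {
    row <- es_null[i, ]
    mpos <- mean(row[row > 0])
    mneg <- mean(abs(row[row < 0]))
    scale_one <- function(x) {
      ifelse(x > 0, x / mpos, ifelse(x < 0, x / mneg, 0))
    }
    nes_obs[i] <- scale_one(es_obs[i])
    nes_null[i, ] <- scale_one(row)
    if (is.na(nes_obs[i]))
      missing_norm <- c(missing_norm, names(es_obs)[i] %||% as.character(i))
  }
  if (length(missing_norm))
    warning("no same-sign null ES; NES undefined for: ",
            paste(missing_norm, collapse = ", "), call. = FALSE)
  names(nes_obs) <- names(es_obs)
  list(nes_obs = nes_obs, nes_null = nes_null)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Permutation-based FDR from normalized enrichment scores
#'
#' GSEA-style estimate: for an observed NES\* the FDR is the fraction of
#' pooled same-sign null NES values at least as extreme as NES\*, divided by
#' the fraction of observed same-sign NES values at least as extreme. The
#' raw ratio is reported alongside a value capped at 1.
#'
#' @param nes_obs named numeric vector of observed NES (one collection, i.e.
#'   one pathway-database universe).
#' @param nes_null matrix of null NES, rows aligned with `nes_obs`.
#' @return data.frame with `pathway`, `fdr_raw`, `fdr`.
#' @export
compute_fdr <- function(nes_obs, nes_null) {
  pooled <- as.vector(nes_null)
  pooled <- pooled[is.finite(pooled)]
  pos_null <- pooled[pooled >= 0]
  neg_null <- pooled[pooled < 0]
  obs <- nes_obs[is.finite(nes_obs)]
  pos_obs <- obs[obs >= 0]
  neg_obs <- obs[obs < 0]
  fdr_raw <- vapply(nes_obs, function(s) {
    if (!is.finite(s)) return(NA_real_)
    if (s >= 0) {
      num_d <- length(pos_null)
      num <- if (num_d == 0) 0 else sum(pos_null >= s) / num_d
      den <- sum(pos_obs >= s) / length(pos_obs)
    } else {
      num_d <- length(neg_null)
      num <- if (num_d == 0) 0 else sum(neg_null <= s) / num_d
      den <- sum(neg_obs <= s) / length(neg_obs)
    }
    if (den == 0) return(if (num == 0) 0 else 1)
    num / den
  }, numeric(1))
  data.frame(pathway = names(nes_obs) %||% seq_along(nes_obs),
             fdr_raw = unname(fdr_raw),
             fdr = pmin(1, unname(fdr_raw)),
             stringsAsFactors = FALSE)
}

#' Fold enrichment of nominally significant pathways over chance
#'
#' Compares the count of pathways reaching nominal significance with the
#' count expected by chance, `alpha * n_tested`. A conservative summary when
#' pathways overlap (the effective number of independent pathways is
#' smaller).
#'
#' @param n_significant pathways with nominal p below `alpha`.
#' @param n_tested pathways tested.
#' @param alpha nominal level, default 0.05.
#' @return list with `expected` (= `alpha * n_tested`) and `fold`
#'   (= `n_significant / expected`).
#' @export
fold_over_chance <- function(n_significant, n_tested, alpha = 0.05) {
  stopifnot(n_tested >= 1, alpha > 0, alpha < 1)
  expected <- alpha * n_tested
  list(expected = expected, fold = n_significant / expected)
}

#' End-to-end pathway enrichment analysis
#'
#' Composes the full pipeline on one eQTL selection threshold: eSNP selection
#' and QC, per-study logistic association with inverse-variance-weighted
#' meta-analysis, surrogate-eSNP assignment, gene ranking, the 3-200
#' represented-size filter, weighted-KS enrichment scores, the within-study
#' phenotype-permutation null, NES normalization, and the permutation FDR
#' computed separately within each pathway database. A pathway is called
#' significant when its permutation p-value is below 0.05 and its FDR below
#' 0.2.
#'
#' @param cohorts list of [cohort_data()].
#' @param eqtl eQTL summary table (`snp_id`, `gene_id`, `p_eqtl`).
#' @param snp_meta SNP metadata (`snp_id`, `maf`, `imp_r2`).
#' @param collection a [gene_set_collection()].
#' @param eqtl_threshold eSNP selection level (1e-5 main; 5e-5 / 1e-4 for
#'   sensitivity analyses).
#' @param maf_min,r2_min QC cutoffs (strict), defaults 0.01 and 0.4.
#' @param b permutations, default 1000.
#' @param weight_p enrichment-score weight exponent, default 1.
#' @param size_min,size_max inclusive represented-size bounds, defaults 3
#'   and 200.
#' @param seed seed for the permutation null.
#' @param p_basis `"es"` (default) computes permutation p-values from raw
#'   enrichment scores; `"nes"` from normalized ones.
#' @param fdr_method `"gsea"` (default) pooled-permutation NES FDR;
#'   `"BH"` Benjamini-Hochberg on the permutation p-values (for comparison).
#' @param p_significant,fdr_significant significance rule thresholds
#'   (defaults 0.05 and 0.2).
#' @return data.frame with one row per tested pathway: `pathway`, `db_tag`,
#'   `size_annotated`, `size_represented`, `es`, `nes`, `p_perm`, `fdr_raw`,
#'   `fdr`, `significant`; sorted by database, then p, then name. The
#'   surrogate table, ranked list, association scan and null matrix are
#'   attached as the `"details"` attribute.
#' @export
run_enrichment <- function(cohorts, eqtl, snp_meta, collection,
                           eqtl_threshold = 1e-5, maf_min = 0.01,
                           r2_min = 0.4, b = 1000, weight_p = 1,
                           size_min = 3, size_max = 200, seed = 1L,
                           p_basis = c("es", "nes"),
                           fdr_method = c("gsea", "BH"),
                           p_significant = 0.05, fdr_significant = 0.2) {
  p_basis <- match.arg(p_basis)
  fdr_method <- match.arg(fdr_method)

  sel <- select_esnps(eqtl, eqtl_threshold)
  available <- Reduce(union, lapply(cohorts, `[[`, "snp_ids"))
  qc <- apply_qc(sel, snp_meta, maf_min, r2_min, available_snps = available)
  if (nrow(qc) == 0) stop("no eSNP passed selection and QC", call. = FALSE)

  gwas <- run_association_scan(cohorts, unique(qc$snp_id))
  surr <- assign_surrogates(qc, gwas)
  ranked <- rank_genes(surr)
  flt <- size_filter(collection, surr, size_min, size_max)
  tested <- flt$collection
  if (length(tested$sets) == 0) {
    warning("no pathway passes the represented-size filter", call. = FALSE)
    out <- data.frame(pathway = character(0), db_tag = character(0),
                      size_annotated = integer(0),
                      size_represented = integer(0), es = numeric(0),
                      nes = numeric(0), p_perm = numeric(0),
                      fdr_raw = numeric(0), fdr = numeric(0),
                      significant = logical(0))
    attr(out, "details") <- list(gwas = gwas, surrogates = surr,
                                 ranked = ranked, null = NULL,
                                 esnps_selected = sel, esnps_qc = qc)
    return(out)
  }

  es_obs <- vapply(tested$sets,
                   function(m) enrichment_score(ranked, m, weight_p),
                   numeric(1))
  null <- permute_and_rescore(cohorts, qc, tested, b = b, seed = seed,
                              weight_p = weight_p)
  nrm <- normalize_scores(es_obs, null$es_null)

  if (p_basis == "es") {
    p_perm <- vapply(seq_along(es_obs), function(i)
      permutation_p(es_obs[i], null$es_null[i, ]), numeric(1))
  } else {
    p_perm <- vapply(seq_along(es_obs), function(i)
      permutation_p(nrm$nes_obs[i], nrm$nes_null[i, ]), numeric(1))
  }

  dbs <- tested$db_tags
  fdr_raw <- fdr <- rep(NA_real_, length(es_obs))
  for (db in unique(dbs)) {
    i <- which(dbs == db)
    if (fdr_method == "gsea") {
      f <- compute_fdr(nrm$nes_obs[i], nrm$nes_null[i, , drop = FALSE])
      fdr_raw[i] <- f$fdr_raw
      fdr[i] <- f$fdr
    } else {
      fdr_raw[i] <- fdr[i] <- stats::p.adjust(p_perm[i], method = "BH")
    }
  }

  out <- data.frame(
    pathway = names(tested$sets),
    db_tag = unname(dbs),
    size_annotated = unname(flt$size_annotated),
    size_represented = unname(flt$size_represented),
    es = unname(es_obs),
    nes = unname(nrm$nes_obs),
    p_perm = p_perm,
    fdr_raw = fdr_raw,
    fdr = fdr,
    stringsAsFactors = FALSE)
  out$significant <- out$p_perm < p_significant & out$fdr < fdr_significant
  out <- out[order(out$db_tag, out$p_perm, out$pathway), ]
  rownames(out) <- NULL
  attr(out, "details") <- list(gwas = gwas, surrogates = surr,
                               ranked = ranked, null = null,
                               esnps_selected = sel, esnps_qc = qc)
  out
}

#' Sensitivity analysis across eSNP selection thresholds
#'
#' Re-runs the full enrichment pipeline at each eQTL threshold with the same
#' seed base, mirroring the main (1e-5) versus sensitivity (5e-5, 1e-4)
#' design. Relaxing the threshold can only add represented genes, so a
#' pathway's represented size is non-decreasing across thresholds, and
#' pathways may enter or leave the tested universe through the size filter.
#'
#' @inheritParams run_enrichment
#' @param thresholds distinct eQTL significance levels.
#' @param ... further arguments passed to [run_enrichment()].
#' @return named list (threshold -> [run_enrichment()] result).
#' @export
sensitivity_runner <- function(cohorts, eqtl, snp_meta, collection,
                               thresholds = c(1e-5, 5e-5, 1e-4), ...) {
  if (anyDuplicated(thresholds)) stop("thresholds must be distinct",
                                      call. = FALSE)
  res <- lapply(thresholds, function(th)
    run_enrichment(cohorts, eqtl, snp_meta, collection,
                   eqtl_threshold = th, ...))
  names(res) <- formatC(thresholds, format = "e", digits = 0)
  res
}
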