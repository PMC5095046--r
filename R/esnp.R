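#' Select eSNPs at an eQTL significance threshold
#'
#' Keeps exactly the SNP-gene records whose eQTL p-value is strictly below
#' the threshold. A SNP associated with the expression of k genes yields k
#' records. Strict inequality is deliberate and tested at the boundary;
#' relaxing the threshold can therefore only grow the selection
#' (monotonicity), mirroring the 1e-5 / 5e-5 / 1e-4 main-vs-sensitivity
#' design.
#'
#' @param eqtl data.frame with columns `snp_id`, `gene_id`, `p_eqtl`.
#' @param threshold significance level in (0, 1).
#' @return the selected subset of `eqtl`, row order preserved.
#' @export
select_esnps <- function(eqtl, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            threshold > 0, threshold < 1)
  .check_columns(eqtl, c("snp_id", "gene_id", "p_eqtl"), "eqtl table")
  out <- eqtl[eqtl$p_eqtl < threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Quality-control filter for selected eSNPs
#'
#' Retains records whose SNP has minor allele frequency strictly above
#' `maf_min` and imputation R-squared strictly above `r2_min`. When
#' `available_snps` is supplied (the SNPs for which GWAS results exist),
#' records for unavailable SNPs are dropped and the count is reported via
#' `message()` — the identified-vs-available bookkeeping step.
#'
#' @param esnps data.frame of selected eQTL records.
#' @param meta SNP metadata data.frame with `snp_id`, `maf`, `imp_r2`; every
#'   eSNP must have a metadata row.
#' @param maf_min minor-allele-frequency cutoff (strict), default 0.01.
#' @param r2_min imputation-quality cutoff (strict), default 0.4.
#' @param available_snps optional character vector of SNPs with GWAS results.
#' @return the retained subset of `esnps`.
#' @export
apply_qc <- function(esnps, meta, maf_min = 0.01, r2_min = 0.4,
                     available_snps = NULL) {
  .check_columns(meta, c("snp_id", "maf", "imp_r2"), "SNP metadata")
  i <- match(esnps$snp_id, meta$snp_id)
  if (anyNA(i))
    stop("missing metadata for SNP(s): ",
         paste(unique(esnps$snp_id[is.na(i)]), collapse = ", "),
         call. = FALSE)
  keep <- meta$maf[i] > maf_min & meta$imp_r2[i] > r2_min
  out <- esnps[keep, , drop = FALSE]
  if (!is.null(available_snps)) {
    avail <- out$snp_id %in% available_snps
    n_drop <- length(unique(out$snp_id[!avail]))
    if (n_drop > 0)
      message(n_drop, " eSNP(s) without GWAS results dropped (",
              length(unique(out$snp_id)) - n_drop, " of ",
              length(unique(out$snp_id)), " available)")
    out <- out[avail, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Assign each gene its surrogate eSNP
#'
#' For every gene with at least one qualifying eSNP, picks the eSNP most
#' significantly associated with disease (smallest meta-analysis p-value) as
#' the gene's surrogate; ties are broken by lexicographically smallest SNP id
#' so output is independent of input order. A SNP may serve as surrogate for
#' several genes (trans regulation). The per-gene ranking statistic is
#' \eqn{-\log_{10} p} of the surrogate's disease association.
#'
#' @param esnps QC-passed eQTL records (`snp_id`, `gene_id`).
#' @param gwas association table with `snp_id` and `p` (meta-analysis
#'   p-value); every eSNP must be present.
#' @return data.frame with columns `gene_id`, `snp_id`, `p_gwas`,
#'   `gene_statistic`, one row per represented gene, sorted by `gene_id`.
#' @export
assign_surrogates <- function(esnps, gwas) {
  .check_columns(gwas, c("snp_id", "p"), "GWAS table")
  i <- match(esnps$snp_id, gwas$snp_id)
  if (anyNA(i))
    stop("eSNP(s) missing from the GWAS table: ",
         paste(unique(esnps$snp_id[is.na(i)]), collapse = ", "),
         call. = FALSE)
  p <- gwas$p[i]
  ord <- order(esnps$gene_id, p, esnps$snp_id)
  first <- !duplicated(esnps$gene_id[ord])
  sel <- ord[first]
  out <- data.frame(gene_id = esnps$gene_id[sel],
                    snp_id = esnps$snp_id[sel],
                    p_gwas = p[sel],
                    gene_statistic = -log10(p[sel]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " lacks required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(df)
}
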