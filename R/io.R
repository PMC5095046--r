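# Full-precision float formatting: shortest representation that round-trips.
.fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- sprintf("%.15g", v)
    if (as.numeric(s) == v) s else sprintf("%.17g", v)
  }, character(1))
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], .fmt_num)
  con <- file(path, open = "wb")  # fixed LF endings for byte-identical output
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df))
    writeLines(do.call(paste, c(unname(df), sep = "\t")), con)
  invisible(path)
}

.read_tsv <- function(path, required, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

.check_numeric_col <- function(df, col, path) {
  x <- df[[col]]
  if (is.character(x)) {
    y <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(y) & !is.na(x))
    if (length(bad))
      stop("malformed numeric value in column '", col, "' of ", path,
           " at data row ", bad[1], ": '", x[bad[1]], "'", call. = FALSE)
    df[[col]] <- y
  }
  df
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description (used as the database tag), then the
#' member gene ids, all tab-separated. Duplicate member ids within a line are
#' collapsed with a warning; empty lines are skipped; duplicate set names or
#' lines with fewer than three fields are errors.
#'
#' @param path GMT file path.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 tab-separated fields",
         call. = FALSE)
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm))
    stop("duplicate gene set name(s) in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  desc <- vapply(fields, `[[`, character(1), 2)
  sets <- lapply(fields, function(f) f[-(1:2)])
  dups <- vapply(sets, anyDuplicated, integer(1)) > 0
  if (any(dups)) {
    warning("duplicate member ids collapsed in set(s): ",
            paste(nm[dups], collapse = ", "), call. = FALSE)
    sets <- lapply(sets, unique)
  }
  names(sets) <- nm
  gene_set_collection(sets, stats::setNames(desc, nm))
}

#' Write a gene-set collection as GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$db_tags[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read / write GWAS summary statistics
#'
#' Summary statistics are exchanged as TSV with columns `snp_id`, `beta`,
#' `se`, `p`, `n_studies`; floats are serialized with round-trip precision so
#' a written file re-reads to exactly equal values.
#'
#' @param path TSV file path.
#' @return data.frame of associations.
#' @export
read_summary_stats <- function(path) {
  df <- .read_tsv(path, c("snp_id", "beta", "se", "p", "n_studies"),
                  "summary statistics")
  for (col in c("beta", "se", "p")) df <- .check_numeric_col(df, col, path)
  if (any(df$p <= 0, na.rm = TRUE))
    stop("p-values must be > 0 in ", path, call. = FALSE)
  if (any(df$se <= 0, na.rm = TRUE))
    stop("standard errors must be > 0 in ", path, call. = FALSE)
  df
}

#' @rdname read_summary_stats
#' @param gwas association table from [run_association_scan()].
#' @export
write_summary_stats <- function(gwas, path) {
  .write_tsv(gwas[order(gwas$snp_id), ], path)
}

#' Read an eQTL summary table
#'
#' @param path TSV with columns `snp_id`, `gene_id`, `p_eqtl`; p-values must
#'   lie in (0, 1\].
#' @return data.frame of eQTL records.
#' @export
read_eqtl <- function(path) {
  df <- .read_tsv(path, c("snp_id", "gene_id", "p_eqtl"), "eQTL")
  df <- .check_numeric_col(df, "p_eqtl", path)
  if (any(df$p_eqtl <= 0 | df$p_eqtl > 1))
    stop("p_eqtl must lie in (0, 1] in ", path, call. = FALSE)
  df
}

#' Read a SNP metadata table
#'
#' @param path TSV with columns `snp_id`, `chr`, `pos`, `maf`, `imp_r2`.
#' @return data.frame of SNP metadata.
#' @export
read_snp_meta <- function(path) {
  df <- .read_tsv(path, c("snp_id", "chr", "pos", "maf", "imp_r2"),
                  "SNP metadata")
  for (col in c("maf", "imp_r2")) df <- .check_numeric_col(df, col, path)
  if (any(df$maf <= 0 | df$maf > 0.5))
    stop("maf must lie in (0, 0.5] in ", path, call. = FALSE)
  df
}

#' Read / write a cohort TSV
#'
#' Cohort files carry one sample per row: `sample_id`, `study`, `status`
#' (0/1), `age`, `pc1`..`pc3`, then one column per SNP dosage.
#'
#' @param path TSV file path.
#' @return a [cohort_data()].
#' @export
read_cohort <- function(path) {
  df <- .read_tsv(path, c("sample_id", "study", "status", "age",
                          "pc1", "pc2", "pc3"), "cohort")
  snp_cols <- setdiff(names(df), c("sample_id", "study", "status", "age",
                                   "pc1", "pc2", "pc3"))
  cohort_data(study_id = df$study[1],
              sample_ids = df$sample_id,
              phenotype = df$status,
              covariates = as.matrix(df[c("age", "pc1", "pc2", "pc3")]),
              dosages = as.matrix(df[snp_cols]))
}

#' @rdname read_cohort
#' @param cohort a [cohort_data()].
#' @export
write_cohort <- function(cohort, path) {
  df <- data.frame(sample_id = cohort$sample_ids,
                   study = cohort$study_id,
                   status = cohort$phenotype,
                   cohort$covariates,
                   cohort$dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' @rdname read_eqtl
#' @param eqtl eQTL table.
#' @export
write_eqtl <- function(eqtl, path) {
  .write_tsv(eqtl[order(eqtl$snp_id, eqtl$gene_id), ], path)
}

#' @rdname read_snp_meta
#' @param meta SNP metadata table.
#' @export
write_snp_meta <- function(meta, path) {
  .write_tsv(meta[order(meta$snp_id), ], path)
}

#' Write the simulation ground truth as JSON
#'
#' @param truth the `truth` element of [simulate_cohorts()].
#' @param path destination JSON file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(
    causal_genes = truth$causal_genes,
    causal_pathways = truth$causal_pathways,
    effect_map = as.list(truth$effect_map),
    causal_snp = as.list(truth$causal_snp),
    esnp_map = truth$esnp_map), path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}

#' Run the full pipeline and write all artifacts
#'
#' Simulates (or loads) the inputs, runs association, eSNP selection and
#' pathway enrichment at one or more eQTL thresholds, and writes every
#' artifact to `out_dir`: cohort TSVs, SNP metadata, eQTL table, gene sets
#' (GMT), truth JSON, per-threshold summary statistics, enrichment result
#' tables, per-gene surrogate detail tables, and a run manifest (JSON) with
#' input digests, the active thresholds, and the stage-count bookkeeping
#' (eSNPs identified, available in the GWAS, genes represented, pathways
#' tested, nominally significant, FDR-significant) plus the fold-over-chance
#' summary per pathway database. Identical configuration and seed produce
#' byte-identical files.
#'
#' @param sim_config a [simulation_config()]; ignored when `inputs` is given.
#' @param out_dir output directory (created if needed).
#' @param inputs optional pre-built list with elements `cohorts`, `eqtl`,
#'   `snp_meta`, `collection` (and optionally `truth`) to analyze instead of
#'   simulating.
#' @param thresholds eQTL selection thresholds to run (first = main
#'   analysis).
#' @param b permutations per threshold.
#' @param seed seed for the permutation null (simulation uses the seed in
#'   `sim_config`).
#' @param ... further arguments passed to [run_enrichment()].
#' @return the run manifest, invisibly (also written to
#'   `manifest.json`).
#' @export
run_all <- function(sim_config = simulation_config(), out_dir,
                    inputs = NULL, thresholds = 1e-5, b = 1000,
                    seed = 1L, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(inputs)) {
    sim <- simulate_cohorts(sim_config)
    inputs <- list(cohorts = sim$cohorts,
                   eqtl = simulate_eqtl_table(sim_config, sim$truth),
                   snp_meta = sim$snp_meta,
                   collection = simulate_gene_sets(sim_config),
                   truth = sim$truth)
  }
  in_files <- character(0)
  for (co in inputs$cohorts) {
    f <- file.path(out_dir, paste0("cohort_", co$study_id, ".tsv"))
    write_cohort(co, f)
    in_files <- c(in_files, f)
  }
  write_eqtl(inputs$eqtl, file.path(out_dir, "eqtl.tsv"))
  write_snp_meta(inputs$snp_meta, file.path(out_dir, "snp_meta.tsv"))
  write_gmt(inputs$collection, file.path(out_dir, "gene_sets.gmt"))
  in_files <- c(in_files, file.path(out_dir, c("eqtl.tsv", "snp_meta.tsv",
                                               "gene_sets.gmt")))
  if (!is.null(inputs$truth))
    write_truth(inputs$truth, file.path(out_dir, "truth.json"))

  completed <- character(0)
  stage_counts <- list()
  fold <- list()
  for (th in thresholds) {
    tag <- formatC(th, format = "e", digits = 0)
    res <- run_enrichment(inputs$cohorts, inputs$eqtl, inputs$snp_meta,
                          inputs$collection, eqtl_threshold = th,
                          b = b, seed = seed, ...)
    det <- attr(res, "details")
    write_summary_stats(det$gwas,
                        file.path(out_dir, paste0("summary_stats_", tag,
                                                  ".tsv")))
    .write_tsv(res, file.path(out_dir, paste0("enrichment_", tag, ".tsv")))
    detail <- .surrogate_detail(res, det$surrogates, inputs$snp_meta,
                                inputs$collection)
    .write_tsv(detail, file.path(out_dir, paste0("pathway_genes_", tag,
                                                 ".tsv")))
    stage_counts[[tag]] <- list(
      esnps_identified = length(unique(det$esnps_selected$snp_id)),
      esnps_available = length(unique(det$esnps_qc$snp_id)),
      genes_represented = nrow(det$surrogates),
      pathways_tested = nrow(res),
      nominal_significant = sum(res$p_perm < 0.05),
      fdr_significant = sum(res$significant))
    fold[[tag]] <- lapply(split(res, res$db_tag), function(d)
      fold_over_chance(sum(d$p_perm < 0.05), nrow(d)))
    completed <- c(completed, tag)
  }

  manifest <- list(
    seed = as.integer(seed),
    thresholds = list(eqtl = as.numeric(thresholds),
                      maf_min = 0.01, r2_min = 0.4,
                      size_min = 3, size_max = 200,
                      p_significant = 0.05, fdr_significant = 0.2,
                      permutations = b),
    input_digests = as.list(tools::md5sum(sort(in_files))),
    stage_counts = stage_counts,
    fold_over_chance = fold,
    completed_stages = completed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Per-gene detail rows for tested pathways: pathway, gene, surrogate SNP,
# GWAS p, chromosome and position of the surrogate.
.surrogate_detail <- function(res, surr, snp_meta, collection) {
  rows <- lapply(res$pathway, function(pw) {
    genes <- intersect(collection$sets[[pw]], surr$gene_id)
    if (length(genes) == 0) return(NULL)
    s <- surr[match(sort(genes), surr$gene_id), ]
    m <- snp_meta[match(s$snp_id, snp_meta$snp_id), ]
    data.frame(pathway = pw, gene_id = s$gene_id,
               surrogate_snp = s$snp_id, p_gwas = s$p_gwas,
               chr = m$chr, pos = m$pos,
               chr_position = paste0(m$chr, ":", m$pos),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
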