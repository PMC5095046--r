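#' Per-study cohort container
#'
#' Bundles one case-control study's phenotype, covariates and SNP dosages.
#' Missing dosage values are mean-imputed per SNP at construction time, the
#' standard dosage-file convention, so downstream matrices stay dense.
#'
#' @param study_id study label.
#' @param sample_ids character vector of sample identifiers.
#' @param phenotype 0/1 vector, 1 = case; at least one of each required.
#' @param covariates numeric matrix with columns `age`, `pc1`, `pc2`, `pc3`.
#' @param dosages numeric sample-by-SNP matrix of allele dosages in \[0, 2\];
#'   column names are the SNP ids.
#' @return an object of class `cohort_data`.
#' @export
cohort_data <- function(study_id, sample_ids, phenotype, covariates, dosages) {
  n <- length(sample_ids)
  phenotype <- as.integer(phenotype)
  if (length(phenotype) != n || nrow(covariates) != n || nrow(dosages) != n)
    stop("phenotype, covariates and dosages must share the sample dimension",
         call. = FALSE)
  if (!all(phenotype %in% c(0L, 1L)))
    stop("phenotype must be 0/1", call. = FALSE)
  if (sum(phenotype) == 0 || sum(phenotype) == n)
    stop("study ", study_id, " needs at least one case and one control",
         call. = FALSE)
  if (is.null(colnames(dosages)))
    stop("dosages must carry SNP ids as column names", call. = FALSE)
  if (anyNA(dosages)) {
    for (j in seq_len(ncol(dosages))) {
      miss <- is.na(dosages[, j])
      if (any(miss)) dosages[miss, j] <- mean(dosages[!miss, j])
    }
  }
  rng <- range(dosages)
  if (rng[1] < 0 || rng[2] > 2)
    stop("dosage values must lie in [0, 2]", call. = FALSE)
  structure(list(study_id = study_id,
                 sample_ids = sample_ids,
                 phenotype = phenotype,
                 covariates = as.matrix(covariates),
                 dosages = dosages,
                 snp_ids = colnames(dosages)),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("<cohort_data> %s: %d samples (%d cases / %d controls), %d SNPs\n",
              x$study_id, length(x$sample_ids), sum(x$phenotype),
              sum(1 - x$phenotype), length(x$snp_ids)))
  invisible(x)
}

# Wald standard errors from a glm.fit object (pivot-aware, as in summary.glm).
.glm_se <- function(fit) {
  p1 <- seq_len(fit$rank)
  cov <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
  se <- rep(NA_real_, length(fit$coefficients))
  se[fit$qr$pivot[p1]] <- sqrt(diag(cov))
  se
}

#' Logistic association of one SNP in one study
#'
#' Maximum-likelihood logistic regression of case-control status on allele
#' dosage, adjusted for age and the first three principal components, with
#' Wald standard error and two-sided normal p-value. Fitting uses iteratively
#' reweighted least squares (relative tolerance 1e-10, at most 50 iterations).
#' Degenerate inputs are flagged rather than fatal: a constant dosage, a
#' rank-deficient design, a non-converged fit, or apparent separation
#' (|beta| > 15) yields `status != "ok"` and is excluded from meta-analysis.
#'
#' @param cohort a [cohort_data()].
#' @param snp_id SNP to test; must be present in the cohort.
#' @return list with `beta`, `se`, `p`, `status` (one of `"ok"`,
#'   `"constant"`, `"separation"`, `"nonconverged"`, `"collinear"`).
#' @export
fit_study_association <- function(cohort, snp_id) {
  j <- match(snp_id, cohort$snp_ids)
  if (is.na(j)) stop("SNP ", snp_id, " not present in ", cohort$study_id,
                     call. = FALSE)
  g <- cohort$dosages[, j]
  X <- cbind(`(Intercept)` = 1, dosage = g, cohort$covariates)
  .fit_logistic_dosage(X, cohort$phenotype)
}

# X must have the dosage as its second column.
.fit_logistic_dosage <- function(X, y) {
  if (stats::var(X[, 2L]) < .Machine$double.eps * 100)
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                status = "constant"))
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = glm.control(epsilon = 1e-10, maxit = 50)))
  beta <- fit$coefficients[2L]
  # aliased covariate columns are pivoted out harmlessly; only an
  # inestimable dosage coefficient disqualifies the fit
  if (is.na(beta))
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                status = "collinear"))
  if (!fit$converged)
    return(list(beta = beta, se = NA_real_, p = NA_real_,
                status = "nonconverged"))
  if (abs(beta) > 15)
    return(list(beta = beta, se = NA_real_, p = NA_real_,
                status = "separation"))
  se <- .glm_se(fit)[2L]
  z <- beta / se
  list(beta = unname(beta), se = unname(se),
       p = 2 * pnorm(-abs(z)), status = "ok")
}

#' Fixed-effect inverse-variance-weighted meta-analysis
#'
#' Combines per-study log-odds estimates with weights \eqn{w_i = 1/se_i^2}:
#' \eqn{\beta = \sum w_i \beta_i / \sum w_i}, \eqn{se = (\sum w_i)^{-1/2}},
#' with a two-sided normal p-value for \eqn{\beta / se}. This is the standard
#' fixed-effect scheme used by GWAS meta-analysis tools such as METAL.
#'
#' @param beta numeric vector of per-study estimates.
#' @param se matching vector of standard errors, all > 0.
#' @return list with `beta`, `se`, `p`, `n_studies`.
#' @export
meta_analyze <- function(beta, se) {
  if (length(beta) == 0) stop("meta-analysis needs at least one study",
                              call. = FALSE)
  if (length(beta) != length(se)) stop("beta and se lengths differ",
                                       call. = FALSE)
  if (any(!is.finite(se)) || any(se <= 0))
    stop("all standard errors must be finite and > 0", call. = FALSE)
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- sqrt(1 / sum(w))
  list(beta = b, se = s, p = 2 * pnorm(-abs(b / s)),
       n_studies = length(beta))
}

#' Genome-wide (or eSNP-wide) association scan with meta-analysis
#'
#' Fits the covariate-adjusted logistic model for every requested SNP in
#' every study and combines the per-study estimates by fixed-effect
#' inverse-variance weighting. Studies where a SNP's fit is flagged (constant
#' dosage, separation, non-convergence) are skipped for that SNP; a SNP with
#' no usable study at all is an error.
#'
#' @param cohorts list of [cohort_data()].
#' @param snp_ids SNPs to scan; a SNP absent from a study is skipped there.
#' @return data.frame with columns `snp_id`, `beta`, `se`, `p`, `n_studies`,
#'   one row per SNP, in the order requested.
#' @export
run_association_scan <- function(cohorts, snp_ids) {
  stopifnot(length(cohorts) >= 1)
  per_study <- lapply(cohorts, function(co) {
    idx <- match(snp_ids, co$snp_ids)
    X <- cbind(`(Intercept)` = 1, dosage = 0, co$covariates)
    list(co = co, idx = idx, X = X)
  })
  n <- length(snp_ids)
  beta <- se <- p <- rep(NA_real_, n)
  n_studies <- integer(n)
  failed <- character(0)
  for (i in seq_len(n)) {
    bs <- ss <- numeric(0)
    for (ps in per_study) {
      j <- ps$idx[i]
      if (is.na(j)) next
      ps$X[, 2L] <- ps$co$dosages[, j]
      r <- .fit_logistic_dosage(ps$X, ps$co$phenotype)
      if (r$status == "ok") {
        bs <- c(bs, r$beta)
        ss <- c(ss, r$se)
      }
    }
    if (length(bs) == 0) {
      failed <- c(failed, snp_ids[i])
      next
    }
    m <- meta_analyze(bs, ss)
    beta[i] <- m$beta
    se[i] <- m$se
    p[i] <- m$p
    n_studies[i] <- m$n_studies
  }
  if (length(failed))
    stop("no usable study for SNP(s): ",
         paste(utils::head(failed, 10), collapse = ", "),
         if (length(failed) > 10) " ...", call. = FALSE)
  data.frame(snp_id = snp_ids, beta = beta, se = se, p = p,
             n_studies = n_studies, stringsAsFactors = FALSE)
}

#' Covariate-adjusted score test for all SNPs at once
#'
#' Fast path used inside the permutation loop: per study, the covariate-only
#' logistic model is fitted once, and every SNP's association is then scored
#' with the Rao score statistic \eqn{U = g'(y - \hat\mu)} and its variance
#' \eqn{V = g'Wg - g'WX (X'WX)^{-1} X'Wg} (W the logistic weights), summed
#' across studies (the stratified score test, the asymptotic equivalent of
#' the inverse-variance-weighted Wald meta-analysis). One vectorized pass
#' replaces one logistic fit per SNP per study; agreement with the full-MLE
#' Wald scan is asserted in the test suite.
#'
#' @param cohorts list of [cohort_data()].
#' @param snp_idx integer columns of the dosage matrices to score (same
#'   coordinates in every cohort); default all SNPs.
#' @param phenotypes optional list of replacement 0/1 phenotype vectors (one
#'   per cohort), e.g. permuted labels; defaults to the observed phenotypes.
#' @return data.frame with `snp_id`, `score`, `p` where `score` = U/sqrt(V)
#'   (signed, standard normal under the null) and `p` the two-sided normal
#'   p-value; SNPs with no information (constant in all studies) get p = 1.
#' @export
score_scan <- function(cohorts, snp_idx = NULL, phenotypes = NULL) {
  if (is.null(snp_idx)) snp_idx <- seq_along(cohorts[[1]]$snp_ids)
  U <- V <- numeric(length(snp_idx))
  for (k in seq_along(cohorts)) {
    co <- cohorts[[k]]
    y <- if (is.null(phenotypes)) co$phenotype else phenotypes[[k]]
    X <- cbind(1, co$covariates)
    fit <- suppressWarnings(
      glm.fit(X, y, family = binomial(),
              control = glm.control(epsilon = 1e-10, maxit = 50)))
    mu <- fit$fitted.values
    w <- mu * (1 - mu)
    G <- co$dosages[, snp_idx, drop = FALSE]
    r <- y - mu
    Us <- drop(crossprod(G, r))
    WX <- X * w
    M <- solve(crossprod(X, WX))
    B <- crossprod(G, WX)                      # p x k
    Vs <- drop(crossprod(G^2, w)) - rowSums((B %*% M) * B)
    bad <- !is.finite(Vs) | Vs <= 1e-12
    Us[bad] <- 0
    Vs[bad] <- 0
    U <- U + Us
    V <- V + Vs
  }
  z <- ifelse(V > 0, U / sqrt(V), 0)
  data.frame(snp_id = cohorts[[1]]$snp_ids[snp_idx],
             score = z,
             p = ifelse(V > 0, 2 * pnorm(-abs(z)), 1),
             stringsAsFactors = FALSE)
}
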