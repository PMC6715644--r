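## Probe-level QC, per-CpG cluster-association ANOVA with covariate
## adjustment, pairwise contrast decomposition, and inflation diagnostics.

#' Probe-level quality filtering
#'
#' Removes CpGs with a poor detection rate (detection p > 0.05 in more
#' than 5% of samples), listed cross-reactive probes, and probes on
#' non-autosomal chromosomes.
#'
#' @param beta CpGs x samples beta matrix.
#' @param manifest data frame (cpg_id, chrom, pos, ...) covering every CpG.
#' @param detection_p optional CpGs x samples detection p-value matrix.
#' @param crossreactive_ids CpG ids to drop as cross-reactive.
#' @param detection_alpha detection p threshold (0.05).
#' @param max_fail_frac maximum tolerated failing-sample fraction (0.05,
#'   strict: removal requires failing in MORE than this fraction).
#' @return list with filtered `beta`, matching `manifest`, and `removed`
#'   counts per filter class.
#' @export
filter_probes <- function(beta, manifest, detection_p = NULL,
                          crossreactive_ids = character(0),
                          detection_alpha = 0.05, max_fail_frac = 0.05) {
  B <- as.matrix(beta)
  ids <- rownames(B)
  gap <- setdiff(ids, manifest$cpg_id)
  if (length(gap))
    stop("manifest does not resolve CpG(s): ",
         paste(utils::head(gap, 5), collapse = ", "), call. = FALSE)
  mf <- manifest[match(ids, manifest$cpg_id), ]
  rm_det <- rep(FALSE, length(ids))
  if (!is.null(detection_p)) {
    D <- as.matrix(detection_p)[ids, , drop = FALSE]
    rm_det <- rowMeans(D > detection_alpha) > max_fail_frac
  }
  rm_xr <- ids %in% crossreactive_ids
  autosomes <- c(paste0("chr", 1:22), as.character(1:22))
  rm_chr <- !(mf$chrom %in% autosomes)
  removed <- c(detection = sum(rm_det & !rm_xr & !rm_chr),
               crossreactive = sum(rm_xr & !rm_chr),
               non_autosomal = sum(rm_chr))
  keep <- !(rm_det | rm_xr | rm_chr)
  message("filter_probes: removed ", sum(!keep), " CpG(s) [detection ",
          removed["detection"], ", cross-reactive ", removed["crossreactive"],
          ", non-autosomal ", removed["non_autosomal"], "]")
  list(beta = B[keep, , drop = FALSE], manifest = mf[keep, ],
       removed = removed)
}

## shared OLS engine: F-test of the block added to `reduced` to give
## `full`, applied to every row of a response matrix at once.
ols_block_ftest <- function(Y, X_full, X_reduced) {
  n <- nrow(Y)
  qf <- qr(X_full); qr_ <- qr(X_reduced)
  rss1 <- colSums(qr.resid(qf, Y)^2)
  rss0 <- colSums(qr.resid(qr_, Y)^2)
  df1 <- qf$rank - qr_$rank
  df2 <- n - qf$rank
  f <- ((rss0 - rss1) / df1) / (rss1 / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  list(f = f, p = p, df1 = df1, df2 = df2, rss_full = rss1,
       rss_reduced = rss0, partial_r2 = (rss0 - rss1) / rss0, qr_full = qf)
}

#' Per-CpG cluster-association ANOVA
#'
#' Fits, for every CpG, an ordinary least-squares model of methylation on
#' the cluster factor plus adjustment covariates and tests the cluster
#' factor by a partial F-test (k-1 numerator df). P-values are
#' Benjamini-Hochberg adjusted across all tested CpGs. Zero-variance CpGs
#' are recorded with p = 1 and flagged.
#'
#' @param beta CpGs x samples beta matrix (or M-values when
#'   `use_mvalues`).
#' @param assignment `cluster_assignment` aligned to the samples.
#' @param covariates covariate table from [build_covariates()] (the
#'   `sample_id` column is dropped).
#' @param fdr_threshold FDR used by the `significant` flag (default 0.1).
#' @param use_mvalues model log2 M-values instead of beta values.
#' @return data frame: cpg_id, f_statistic, p, q, variance_explained,
#'   per-pair adjusted mean differences (`delta_<A>_<B>`), significance
#'   flag, `zero_variance` flag. Attributes: `df1`, `df2`, `n_tests`.
#' @export
cluster_anova <- function(beta, assignment, covariates,
                          fdr_threshold = 0.1, use_mvalues = FALSE) {
  B <- as.matrix(beta)
  check_alignment(colnames(B), assignment$sample_ids,
                  covariates$sample_id, what = "beta/assignment/covariates")
  cl <- factor(assignment$label)
  if (nlevels(cl) < 2 || any(table(cl) < 2))
    stop("need >= 2 clusters each with >= 2 samples", call. = FALSE)
  Xr <- build_design(covariate_design(covariates))
  cl_mm <- stats::model.matrix(~ cl)[, -1, drop = FALSE]
  colnames(cl_mm) <- paste0("cluster", levels(cl)[-1])
  Xf <- build_design(covariate_design(covariates), extra = cl_mm)
  Y <- t(if (use_mvalues) beta2m(B) else B)
  zv <- apply(B, 1, stats::sd) == 0
  ft <- ols_block_ftest(Y, Xf, Xr)
  f <- ft$f; p <- ft$p; r2 <- ft$partial_r2
  f[zv] <- NA; p[zv] <- 1; r2[zv] <- 0
  q <- stats::p.adjust(p, "BH")
  ## covariate-adjusted cluster means via dummy coefficients
  coefs <- qr.coef(ft$qr_full, Y)
  lev <- levels(cl)
  dummy_rows <- match(paste0("cluster", lev[-1]), rownames(coefs))
  mu <- rbind(0, coefs[dummy_rows, , drop = FALSE])  # relative to reference
  rownames(mu) <- lev
  pairs <- utils::combn(lev, 2)
  out <- data.frame(cpg_id = rownames(B), f_statistic = f, p = p, q = q,
                    variance_explained = r2, zero_variance = zv,
                    significant = q < fdr_threshold,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[2, j]; b <- pairs[1, j]   # later (more severe) minus earlier
    out[[paste0("delta_", a, "_", b)]] <- mu[a, ] - mu[b, ]
  }
  attr(out, "df1") <- ft$df1
  attr(out, "df2") <- ft$df2
  attr(out, "n_tests") <- nrow(B)
  attr(out, "cluster_levels") <- lev
  out
}

#' Pairwise cluster contrasts within ANOVA-significant CpGs
#'
#' Within the FDR-significant CpG set only, per-pair t-tests of cluster
#' contrasts are taken from the same covariate-adjusted model, with
#' Benjamini-Hochberg adjustment within each contrast. The reported
#' delta-beta is the difference of covariate-adjusted cluster means.
#'
#' @param anova_hits character vector of significant CpG ids (or the
#'   result of [cluster_anova()], from which the significant set is
#'   taken).
#' @param beta,assignment,covariates as in [cluster_anova()].
#' @param fdr_threshold per-contrast FDR flag threshold (default 0.1).
#' @return long data frame: cpg_id, contrast, delta_beta, t, p, q,
#'   significant.
#' @export
pairwise_contrasts <- function(anova_hits, beta, assignment, covariates,
                               fdr_threshold = 0.1) {
  if (is.data.frame(anova_hits))
    anova_hits <- anova_hits$cpg_id[anova_hits$significant]
  B <- as.matrix(beta)[anova_hits, , drop = FALSE]
  if (!nrow(B)) return(data.frame())
  check_alignment(colnames(B), assignment$sample_ids,
                  covariates$sample_id, what = "beta/assignment/covariates")
  cl <- factor(assignment$label)
  lev <- levels(cl)
  cl_mm <- stats::model.matrix(~ cl)[, -1, drop = FALSE]
  colnames(cl_mm) <- paste0("cluster", lev[-1])
  Xf <- build_design(covariate_design(covariates), extra = cl_mm)
  Y <- t(B)
  qf <- qr(Xf)
  df2 <- nrow(Y) - qf$rank
  coefs <- qr.coef(qf, Y)
  sigma2 <- colSums(qr.resid(qf, Y)^2) / df2
  XtXinv <- chol2inv(qr.R(qf))
  rownames(XtXinv) <- colnames(XtXinv) <- colnames(Xf)[qf$pivot]
  res <- list()
  pairs <- utils::combn(lev, 2)
  for (j in seq_len(ncol(pairs))) {
    b <- pairs[1, j]; a <- pairs[2, j]
    if (!sum(cl == a) || !sum(cl == b)) {
      message("pairwise_contrasts: skipping contrast ", a, " vs ", b,
              " (empty cluster)")
      next
    }
    cvec <- stats::setNames(numeric(ncol(Xf)), colnames(Xf)[qf$pivot])
    da <- paste0("cluster", a); db <- paste0("cluster", b)
    if (da %in% names(cvec)) cvec[da] <- 1
    if (db %in% names(cvec)) cvec[db] <- cvec[db] - 1
    delta <- as.numeric(cvec %*% coefs[qf$pivot, , drop = FALSE])
    se <- sqrt(as.numeric(t(cvec) %*% XtXinv %*% cvec) * sigma2)
    tt <- delta / se
    pp <- 2 * stats::pt(abs(tt), df2, lower.tail = FALSE)
    res[[paste0(a, "_vs_", b)]] <-
      data.frame(cpg_id = anova_hits, contrast = paste0(a, "_vs_", b),
                 delta_beta = delta, t = tt, p = pp,
                 q = stats::p.adjust(pp, "BH"), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$significant <- out$q < fdr_threshold
  out
}

#' Genomic inflation factor of a p-value set
#'
#' lambda = median of the chi-square(1 df) quantile transform of the
#' p-values divided by the null median (qchisq(0.5, 1)).
#'
#' @param p_values numeric p-values in (0, 1].
#' @return list with `lambda` and `n_tests` (class `inflation_report`).
#' @export
inflation_lambda <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (!length(p)) stop("empty p-value input", call. = FALSE)
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  structure(list(lambda = stats::median(chisq) / stats::qchisq(0.5, 1),
                 n_tests = length(p)),
            class = "inflation_report")
}

#' @export
print.inflation_report <- function(x, ...) {
  cat(sprintf("genomic inflation factor lambda = %.3f (%d tests)\n",
              x$lambda, x$n_tests))
  invisible(x)
}
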