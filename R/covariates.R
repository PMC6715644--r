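## Adjustment covariates for every association model: medication principal
## components, reference-free cell-composition surrogates, and genetic
## ancestry components.

#' Medication principal components
#'
#' Centered PCA of a samples x binary-medications matrix. The number of
#' retained components is chosen by cell-wise cross-validated
#' reconstruction error (same impute-by-rank-d scheme as the MCA dimension
#' selection), capped at `max_pc` (3).
#'
#' @param med_matrix samples x medications 0/1 matrix.
#' @param n_folds folds for the cross-validation (default 3).
#' @param seed integer seed.
#' @param max_pc cap on retained components.
#' @return samples x retained-components score matrix (columns
#'   `medpc1..`), with attribute `sdev` (all singular values / sqrt(n-1)).
#' @export
medication_pca <- function(med_matrix, n_folds = 3, seed = 1L, max_pc = 3) {
  X <- as.matrix(med_matrix)
  if (ncol(X) < 2) stop("need at least 2 medications", call. = FALSE)
  if (all(apply(X, 2, function(x) length(unique(x)) == 1))) {
    warning("constant medication matrix: returning zero components")
    out <- matrix(numeric(0), nrow(X), 0)
    attr(out, "sdev") <- numeric(0)
    return(out)
  }
  max_pc <- min(max_pc, ncol(X) - 1, nrow(X) - 1)
  set.seed(child_seed(seed, 601L))
  fold <- matrix(sample(rep_len(seq_len(n_folds), length(X))),
                 nrow(X), ncol(X))
  err <- numeric(max_pc)
  for (d in seq_len(max_pc)) {
    for (f in seq_len(n_folds)) {
      M <- X; hold <- fold == f; M[hold] <- NA
      imp <- svd_impute(M, d)
      err[d] <- err[d] + sum((imp[hold] - X[hold])^2)
    }
  }
  n_pc <- which.min(err)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_pc), drop = FALSE]
  colnames(scores) <- paste0("medpc", seq_len(n_pc))
  attr(scores, "sdev") <- pc$sdev
  scores
}

#' Reference-free cell-composition surrogates (ReFACTor-style)
#'
#' Sites are standardized; a rank-`k` SVD approximation is computed; sites
#' are ranked by the Euclidean distance between their observed and
#' low-rank-reconstructed standardized profiles; PCA on the `t`
#' lowest-distance sites yields `k` component scores used as
#' cell-composition surrogates.
#'
#' @param beta CpGs x samples beta matrix.
#' @param k assumed number of cell types (default 6).
#' @param t number of retained sites (default 500).
#' @return samples x k score matrix (columns `cellc1..`), with attributes
#'   `selected_sites` and `sdev` (full spectrum of the selected-site PCA).
#' @export
refactor_components <- function(beta, k = 6, t = 500) {
  B <- as.matrix(beta)
  if (k >= ncol(B))
    stop("configuration error: k must be smaller than the number of samples",
         call. = FALSE)
  t <- min(t, nrow(B))
  sds <- apply(B, 1, stats::sd)
  keep <- sds > 0
  Bs <- (B[keep, , drop = FALSE] - rowMeans(B[keep, , drop = FALSE])) /
    sds[keep]
  sv <- svd(Bs, nu = k, nv = k)
  R <- sv$u %*% (sv$d[seq_len(k)] * t(sv$v))
  dist <- sqrt(rowSums((Bs - R)^2))
  ord <- order(dist)                     # row-order invariant: by distance
  sel <- rownames(Bs)[ord[seq_len(min(t, nrow(Bs)))]]
  pc <- stats::prcomp(t(Bs[ord[seq_len(min(t, nrow(Bs)))], , drop = FALSE]),
                      center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("cellc", seq_len(k))
  rownames(scores) <- colnames(B)
  attr(scores, "selected_sites") <- sel
  attr(scores, "sdev") <- pc$sdev
  scores
}

#' Genetic ancestry principal components
#'
#' PCA of mean-imputed dosages standardized by sqrt(2 p (1-p)), where p is
#' the per-SNP allele frequency. Monomorphic SNPs are skipped.
#'
#' @param genotypes SNPs x samples dosage matrix ({0,1,2}, NA allowed).
#' @param n_components components returned.
#' @return samples x n_components score matrix (columns `ancpc1..`).
#' @export
ancestry_pcs <- function(genotypes, n_components = 3) {
  G <- as.matrix(genotypes)
  if (n_components == 0) {
    out <- matrix(numeric(0), ncol(G), 0)
    rownames(out) <- colnames(G)
    return(out)
  }
  ## mean imputation within SNP
  mu <- rowMeans(G, na.rm = TRUE)
  na_idx <- which(is.na(G))
  if (length(na_idx)) G[na_idx] <- mu[((na_idx - 1) %% nrow(G)) + 1]
  p <- rowMeans(G) / 2
  poly <- p > 0 & p < 1
  if (!any(poly))
    stop("all SNPs are monomorphic: cannot compute ancestry components",
         call. = FALSE)
  Gs <- (G[poly, , drop = FALSE] - 2 * p[poly]) /
    sqrt(2 * p[poly] * (1 - p[poly]))
  sv <- svd(t(Gs), nu = n_components, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  colnames(scores) <- paste0("ancpc", seq_len(n_components))
  rownames(scores) <- colnames(G)
  scores
}

#' Assemble the full modelling covariate table
#'
#' Binds demographic/behavioural covariates with medication PCs, ancestry
#' PCs and cell-composition surrogates, with the stable column names used
#' by every downstream model.
#'
#' @param covariates data frame with at least `sample_id`, `sex`, `age`,
#'   `smoking`, `alcohol` (medication columns `med*` used when
#'   `med_pcs` is NULL).
#' @param med_pcs,ancestry,cell optional score matrices from
#'   [medication_pca()], [ancestry_pcs()], [refactor_components()].
#' @return data frame keyed by `sample_id` with columns sex, age, smoke,
#'   alcohol, medpc*, ancpc*, cellc*.
#' @export
build_covariates <- function(covariates, med_pcs = NULL, ancestry = NULL,
                             cell = NULL) {
  out <- data.frame(sample_id = covariates$sample_id,
                    sex = covariates$sex, age = covariates$age,
                    smoke = covariates$smoking,
                    alcohol = covariates$alcohol,
                    stringsAsFactors = FALSE)
  for (block in list(med_pcs, ancestry, cell)) {
    if (!is.null(block) && ncol(block) > 0) {
      check_alignment(out$sample_id,
                      rownames(block) %||% out$sample_id,
                      what = "covariate blocks")
      out <- cbind(out, as.data.frame(block))
    }
  }
  rownames(out) <- out$sample_id
  out
}

## modelling matrix (numeric columns only, sample_id dropped)
covariate_design <- function(covariate_table) {
  df <- covariate_table[, setdiff(names(covariate_table), "sample_id"),
                        drop = FALSE]
  df
}
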