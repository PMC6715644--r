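## Gene-set, chromatin-state and ethnicity-permutation enrichment of
## cluster-associated CpGs.

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric p-value of observing at least the overlap
#' between the hit genes and the gene set, within the given universe.
#'
#' @param hit_genes character set of hit genes (subset of `universe`).
#' @param gene_set character set to test against (subset of `universe`).
#' @param universe character set of all eligible genes.
#' @return list with `overlap`, `expected`, and `p`.
#' @export
hypergeom_enrichment <- function(hit_genes, gene_set, universe) {
  if (!length(universe)) stop("empty gene universe", call. = FALSE)
  hit_genes <- intersect(unique(hit_genes), universe)
  gene_set <- intersect(unique(gene_set), universe)
  k <- length(intersect(hit_genes, gene_set))
  p <- stats::phyper(k - 1, length(gene_set),
                     length(universe) - length(gene_set),
                     length(hit_genes), lower.tail = FALSE)
  list(overlap = k,
       expected = length(hit_genes) * length(gene_set) / length(universe),
       p = p)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (one set per line: name, description, genes...).
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  fgsea::gmtPathways(path)
}

#' Chromatin-state enrichment of hit CpGs
#'
#' Assigns every CpG to the chromatin state covering its position (BED
#' intervals, 0-based half-open; manifest positions are 1-based) and, per
#' state and cell type, computes a two-sided Fisher exact test on the
#' 2x2 table (hit vs non-hit universe CpGs x in-state vs not), with BH
#' adjustment across all state-by-cell-type tests. CpGs outside all
#' intervals are excluded and counted.
#'
#' @param hit_cpgs character ids of hit CpGs.
#' @param universe_cpgs character ids of the CpG universe (includes hits).
#' @param manifest data frame with cpg_id, chrom, pos.
#' @param state_beds named list (per cell type) of BED file paths, or of
#'   GRanges with the state label in the `name` column.
#' @return data frame: cell_type, state, counts, odds_ratio, p, q,
#'   direction; attribute `n_unassigned`.
#' @export
chromatin_enrichment <- function(hit_cpgs, universe_cpgs, manifest,
                                 state_beds) {
  mf <- manifest[match(universe_cpgs, manifest$cpg_id), ]
  cpg_gr <- GenomicRanges::GRanges(
    seqnames = mf$chrom,
    ranges = IRanges::IRanges(start = mf$pos, width = 1L))
  is_hit <- universe_cpgs %in% hit_cpgs
  res <- list()
  n_unassigned <- 0L
  for (ct in names(state_beds)) {
    bed <- state_beds[[ct]]
    gr <- if (is.character(bed)) rtracklayer::import(bed, format = "BED")
          else bed
    hits <- GenomicRanges::findOverlaps(cpg_gr, gr, select = "first")
    assigned <- !is.na(hits)
    n_unassigned <- n_unassigned + sum(!assigned)
    state_of <- rep(NA_character_, length(cpg_gr))
    state_of[assigned] <- as.character(gr$name[hits[assigned]])
    for (st in sort(unique(state_of[assigned]))) {
      in_state <- state_of == st
      tab <- matrix(c(sum(is_hit & in_state & assigned),
                      sum(is_hit & !in_state & assigned),
                      sum(!is_hit & in_state & assigned),
                      sum(!is_hit & !in_state & assigned)), 2, 2)
      ft <- stats::fisher.test(tab)
      res[[paste(ct, st)]] <- data.frame(
        cell_type = ct, state = st,
        hit_in = tab[1, 1], hit_out = tab[2, 1],
        bg_in = tab[1, 2], bg_out = tab[2, 2],
        odds_ratio = unname(ft$estimate), p = ft$p.value,
        stringsAsFactors = FALSE)
    }
  }
  if (n_unassigned)
    message("chromatin_enrichment: ", n_unassigned,
            " CpG-by-cell-type assignments outside all intervals, excluded")
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, "BH")
  out$direction <- ifelse(out$odds_ratio < 1, "depleted", "enriched")
  rownames(out) <- NULL
  attr(out, "n_unassigned") <- n_unassigned
  out
}

## count of CpGs whose ethnicity term (joint partial F over all levels) is
## significant, for a given label vector; vectorized over CpG rows
count_ethnicity_assoc <- function(Y, eth, W, alpha, mode) {
  Xf <- cbind(W, stats::model.matrix(~ eth)[, -1, drop = FALSE])
  ft <- ols_block_ftest(Y, Xf, W)
  if (mode == "fdr") {
    sum(stats::p.adjust(ft$p, "BH") < alpha)
  } else {
    sum(ft$p < alpha)
  }
}

#' Permutation enrichment of ethnicity-associated CpGs among
#' cluster-associated CpGs
#'
#' For each cluster-associated CpG a linear model of methylation on
#' ethnicity (modelled as a factor, tested by the joint partial F of all
#' its levels) plus covariates is fitted; the observed count N_race of
#' CpGs with ethnicity significance below the threshold is compared with
#' the same count recomputed under `n_perm` random permutations of the
#' ethnicity labels. The enrichment statistic is
#' (N_race / N_cluster) / mean(null / N_cluster) and the permutation
#' p-value uses the add-one estimator.
#'
#' @param beta CpGs x samples beta matrix.
#' @param ethnicity character/factor labels (>= 2 levels).
#' @param covariates covariate table including ancestry PCs; must not
#'   itself contain ethnicity.
#' @param cluster_cpgs the cluster-associated CpG set (non-empty).
#' @param n_perm permutations (default 1000).
#' @param alpha per-CpG significance threshold (default 0.05 on raw p;
#'   set `mode = "fdr"` for the BH-adjusted variant).
#' @param mode `"p"` (raw p < alpha) or `"fdr"` (BH q < alpha).
#' @param seed integer seed.
#' @return `enrichment_perm_result`: list with n_cluster, n_race_observed,
#'   null_counts, enrichment_statistic, p_perm, n_perm, seed.
#' @export
ethnicity_permutation_enrichment <- function(beta, ethnicity, covariates,
                                             cluster_cpgs, n_perm = 1000,
                                             alpha = 0.05, mode = c("p", "fdr"),
                                             seed = 1L) {
  mode <- match.arg(mode)
  if (!length(cluster_cpgs)) stop("empty cluster CpG set", call. = FALSE)
  eth <- factor(ethnicity)
  if (nlevels(eth) < 2)
    stop("ethnicity must have at least 2 levels", call. = FALSE)
  B <- as.matrix(beta)[cluster_cpgs, , drop = FALSE]
  check_alignment(colnames(B), covariates$sample_id,
                  what = "beta/covariates")
  W <- build_design(covariate_design(covariates))
  Y <- t(B)
  n_obs <- count_ethnicity_assoc(Y, eth, W, alpha, mode)
  set.seed(child_seed(seed, 907L))
  null_counts <- vapply(seq_len(n_perm), function(i)
    count_ethnicity_assoc(Y, sample(eth), W, alpha, mode), numeric(1))
  n_cluster <- length(cluster_cpgs)
  structure(list(
    n_cluster = n_cluster,
    n_race_observed = n_obs,
    null_counts = null_counts,
    enrichment_statistic = (n_obs / n_cluster) /
      mean(null_counts / n_cluster),
    p_perm = (1 + sum(null_counts >= n_obs)) / (n_perm + 1),
    n_perm = n_perm, alpha = alpha, mode = mode, seed = seed),
    class = "enrichment_perm_result")
}

#' @export
print.enrichment_perm_result <- function(x, ...) {
  cat(sprintf(
    "ethnicity enrichment: %d of %d cluster CpGs ethnicity-associated\n",
    x$n_race_observed, x$n_cluster))
  cat(sprintf("null mean %.1f, enrichment statistic %.2f, p_perm %.4g (%d perms)\n",
              mean(x$null_counts), x$enrichment_statistic, x$p_perm,
              x$n_perm))
  invisible(x)
}
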