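## Genotype QC and cis-meQTL scanning of cluster-associated CpGs against
## all SNPs within 1 Mb.

#' Hardy-Weinberg exact test
#'
#' Exact conditional test: given the allele counts, the p-value is the sum
#' of probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed configuration
#' (Wigginton-style enumeration, computed here from first principles on
#' the log scale).
#'
#' @param n_homref,n_het,n_homalt genotype counts.
#' @return the exact p-value.
#' @export
hwe_exact_test <- function(n_homref, n_het, n_homalt) {
  if (any(c(n_homref, n_het, n_homalt) < 0))
    stop("genotype counts must be non-negative", call. = FALSE)
  n <- n_homref + n_het + n_homalt
  if (n == 0) stop("total genotype count must be positive", call. = FALSE)
  n_a <- 2 * n_homalt + n_het            # minor-ish allele count
  n_b <- 2 * n_homref + n_het
  if (n_a > n_b) { tmp <- n_a; n_a <- n_b; n_b <- tmp }
  ## possible heterozygote counts share the parity of n_a
  hets <- seq(n_a %% 2, n_a, by = 2)
  ## log P(n_het = h | allele counts) up to a constant:
  ## log n! - log naa! - log h! - log nbb! + h log 2
  naa <- (n_a - hets) / 2
  nbb <- (n_b - hets) / 2
  logp <- lfactorial(n) - lfactorial(naa) - lfactorial(hets) -
    lfactorial(nbb) + hets * log(2)
  logp <- logp - max(logp)
  prob <- exp(logp) / sum(exp(logp))
  obs <- which(hets == n_het)
  if (!length(obs))
    stop("heterozygote count incompatible with allele counts", call. = FALSE)
  min(1, sum(prob[prob <= prob[obs] * (1 + 1e-12)]))
}

#' Genotype quality control
#'
#' Applies, in order: call-rate filter (SNPs with more than
#' `1 - call_rate_min` missing dropped), MAF filter (only SNPs with minor
#' allele frequency strictly greater than `maf_min` retained), and
#' Hardy-Weinberg exact-test filter (p < `hwe_alpha` dropped).
#'
#' @param genotypes SNPs x samples dosage matrix ({0,1,2}, NA = missing).
#' @param snp_info data frame aligned to the rows of `genotypes`.
#' @param call_rate_min minimum call rate (0.95).
#' @param maf_min MAF retention threshold, strict (0.05).
#' @param hwe_alpha HWE rejection level (1e-4).
#' @return list with filtered `genotypes`, `snp_info`, and `removed`
#'   counts per filter.
#' @export
genotype_qc <- function(genotypes, snp_info = NULL, call_rate_min = 0.95,
                        maf_min = 0.05, hwe_alpha = 1e-4) {
  G <- as.matrix(genotypes)
  if (!all(G %in% c(0, 1, 2) | is.na(G)))
    stop("dosages must be in {0,1,2} or missing", call. = FALSE)
  call_rate <- rowMeans(!is.na(G))
  keep1 <- call_rate >= call_rate_min
  af <- rowMeans(G, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep2 <- keep1 & maf > maf_min
  keep3 <- keep2
  for (i in which(keep2)) {
    g <- G[i, ]
    cnt <- c(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
             sum(g == 2, na.rm = TRUE))
    keep3[i] <- hwe_exact_test(cnt[1], cnt[2], cnt[3]) >= hwe_alpha
  }
  removed <- c(call_rate = sum(!keep1), maf = sum(keep1 & !keep2),
               hwe = sum(keep2 & !keep3))
  message("genotype_qc: removed ", sum(!keep3), " SNP(s) [call-rate ",
          removed["call_rate"], ", MAF ", removed["maf"], ", HWE ",
          removed["hwe"], "]")
  if (!any(keep3)) stop("all SNPs removed by QC", call. = FALSE)
  list(genotypes = G[keep3, , drop = FALSE],
       snp_info = if (is.null(snp_info)) NULL else snp_info[keep3, ],
       removed = removed)
}

#' Windowed greedy LD pruning
#'
#' Slides a window of `window` SNPs in steps of `step` along each
#' chromosome (input must be position-sorted); within a window, for every
#' pair with squared dosage correlation above `r2_max`, the
#' later-positioned SNP is dropped.
#'
#' @param genotypes SNPs x samples dosages (mean-imputed for correlation).
#' @param snp_info data frame with `chrom` and `pos`, aligned and sorted.
#' @param r2_max maximum tolerated r-squared (0.8).
#' @param window window size in SNPs (50).
#' @param step step size in SNPs (5).
#' @return character vector of retained SNP ids.
#' @export
ld_prune <- function(genotypes, snp_info, r2_max = 0.8, window = 50,
                     step = 5) {
  G <- as.matrix(genotypes)
  for (ch in unique(snp_info$chrom)) {
    idx <- which(snp_info$chrom == ch)
    if (is.unsorted(snp_info$pos[idx]))
      stop("SNPs must be position-sorted within chromosome", call. = FALSE)
  }
  mu <- rowMeans(G, na.rm = TRUE)
  na_idx <- which(is.na(G))
  if (length(na_idx)) G[na_idx] <- mu[((na_idx - 1) %% nrow(G)) + 1]
  keep <- rep(TRUE, nrow(G))
  for (ch in unique(snp_info$chrom)) {
    idx <- which(snp_info$chrom == ch)
    start <- 1
    repeat {
      win <- idx[seq(start, min(start + window - 1, length(idx)))]
      win <- win[keep[win]]
      if (length(win) > 1) {
        r2 <- suppressWarnings(stats::cor(t(G[win, , drop = FALSE])))^2
        r2[is.na(r2)] <- 0
        for (a in seq_along(win)) {
          if (!keep[win[a]]) next
          for (b in seq_along(win)) {
            if (b <= a || !keep[win[b]]) next
            if (r2[a, b] > r2_max) keep[win[b]] <- FALSE
          }
        }
      }
      if (start + window - 1 >= length(idx)) break
      start <- start + step
    }
  }
  snp_ids <- snp_info$snp_id %||% rownames(G)
  snp_ids[keep]
}

#' Enumerate cis SNP-CpG pairs
#'
#' Pairs every SNP with every CpG on the same chromosome at a distance
#' strictly below `window_bp`. Chromosome names are normalized ("1" and
#' "chr1" match).
#'
#' @param snp_pos data frame: snp_id, chrom, pos (1-based).
#' @param cpg_pos data frame: cpg_id, chrom, pos (1-based).
#' @param window_bp cis window (default 1,000,000; strict "<").
#' @return data frame: snp_id, cpg_id, chrom, snp_bp, cpg_bp, distance.
#' @export
map_cis_pairs <- function(snp_pos, cpg_pos, window_bp = 1e6) {
  norm_chr <- function(x) sub("^chr", "", as.character(x))
  sc <- norm_chr(snp_pos$chrom); cc <- norm_chr(cpg_pos$chrom)
  out <- vector("list", 0)
  for (ch in intersect(unique(sc), unique(cc))) {
    si <- which(sc == ch); ci <- which(cc == ch)
    ## interval query via IRanges: CpG +/- (window - 1)
    q <- IRanges::IRanges(start = pmax(1L, cpg_pos$pos[ci] - window_bp + 1L),
                          end = cpg_pos$pos[ci] + window_bp - 1L)
    s <- IRanges::IRanges(start = snp_pos$pos[si], width = 1L)
    hits <- IRanges::findOverlaps(s, q)
    if (!length(hits)) next
    i <- si[S4Vectors::queryHits(hits)]
    j <- ci[S4Vectors::subjectHits(hits)]
    out[[length(out) + 1]] <- data.frame(
      snp_id = snp_pos$snp_id[i], cpg_id = cpg_pos$cpg_id[j],
      chrom = ch, snp_bp = snp_pos$pos[i], cpg_bp = cpg_pos$pos[j],
      distance = abs(snp_pos$pos[i] - cpg_pos$pos[j]),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(snp_id = character(0), cpg_id = character(0),
                      chrom = character(0), snp_bp = integer(0),
                      cpg_bp = integer(0), distance = integer(0)))
  res <- do.call(rbind, out)
  res <- res[res$distance < window_bp, , drop = FALSE]  # strict inequality
  rownames(res) <- NULL
  res
}

#' Fit cis-meQTL linear models
#'
#' For every (SNP, CpG) pair, fits methylation ~ dosage + covariates by
#' OLS (missing dosages mean-imputed within SNP) and BH-adjusts across all
#' tested pairs. Effects are per counted (minor) allele on the beta scale.
#'
#' @param beta CpGs x samples beta matrix.
#' @param genotypes SNPs x samples dosages.
#' @param covariates covariate table ([build_covariates()]).
#' @param pairs data frame from [map_cis_pairs()].
#' @param fdr significance flag threshold (0.05).
#' @return data frame: snp_id, cpg_id, distance, beta, se, t, p, q,
#'   significant.
#' @export
fit_meqtl <- function(beta, genotypes, covariates, pairs, fdr = 0.05) {
  B <- as.matrix(beta)
  G <- as.matrix(genotypes)
  check_alignment(colnames(B), colnames(G), covariates$sample_id,
                  what = "beta/genotypes/covariates")
  ok <- pairs$snp_id %in% rownames(G) & pairs$cpg_id %in% rownames(B)
  if (any(!ok)) {
    warning("skipping ", sum(!ok), " pair(s) referencing filtered features")
    pairs <- pairs[ok, , drop = FALSE]
  }
  X0 <- build_design(covariate_design(covariates))
  q0 <- qr(X0)
  n <- ncol(B)
  df2 <- n - q0$rank - 1
  ## Frisch-Waugh: residualize methylation and dosage on covariates, then
  ## per-pair simple regression (identical estimates to the full model).
  Rb <- qr.resid(q0, t(B[unique(pairs$cpg_id), , drop = FALSE]))
  colnames(Rb) <- unique(pairs$cpg_id)
  mu <- rowMeans(G, na.rm = TRUE)
  na_idx <- which(is.na(G))
  if (length(na_idx)) G[na_idx] <- mu[((na_idx - 1) %% nrow(G)) + 1]
  Rg <- qr.resid(q0, t(G[unique(pairs$snp_id), , drop = FALSE]))
  colnames(Rg) <- unique(pairs$snp_id)
  est <- se <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    x <- Rg[, pairs$snp_id[i]]
    y <- Rb[, pairs$cpg_id[i]]
    sxx <- sum(x^2)
    b <- sum(x * y) / sxx
    rss <- sum((y - b * x)^2)
    est[i] <- b
    se[i] <- sqrt(rss / df2 / sxx)
  }
  tt <- est / se
  p <- 2 * stats::pt(abs(tt), df2, lower.tail = FALSE)
  out <- data.frame(snp_id = pairs$snp_id, cpg_id = pairs$cpg_id,
                    distance = pairs$distance, beta = est, se = se, t = tt,
                    p = p, q = stats::p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  out$significant <- out$q < fdr
  out
}

#' Distance decay of meQTL signal
#'
#' Fraction of tested pairs significant at the given FDR flag, per
#' SNP-CpG distance bin. Empty bins are reported as NA, not 0.
#'
#' @param results data frame from [fit_meqtl()].
#' @param bin_edges increasing vector of distance bin edges.
#' @return data frame: bin start/end, n tested, n significant, fraction.
#' @export
distance_decay <- function(results, bin_edges) {
  if (!nrow(results)) stop("empty meQTL results", call. = FALSE)
  bin <- cut(results$distance, bin_edges, include.lowest = TRUE,
             right = FALSE)
  n_tested <- as.vector(table(bin))
  n_sig <- as.vector(tapply(results$significant, bin, sum))
  n_sig[is.na(n_sig)] <- 0
  frac <- ifelse(n_tested > 0, n_sig / n_tested, NA_real_)
  data.frame(bin_start = utils::head(bin_edges, -1),
             bin_end = utils::tail(bin_edges, -1),
             n_tested = n_tested, n_significant = n_sig, fraction = frac)
}
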