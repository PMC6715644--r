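## Causal inference test (CIT) for methylation mediation of SNP-cluster
## associations: four component tests whose maximum p-value is the CIT
## p-value. G = dosage, M = methylation, Y = ordinal cluster label.

## F-test of the columns `add` given base design `X0`, for response y
block_f <- function(y, X0, add) {
  X1 <- cbind(X0, add)
  q0 <- qr(X0); q1 <- qr(X1)
  rss0 <- sum(qr.resid(q0, y)^2)
  rss1 <- sum(qr.resid(q1, y)^2)
  df1 <- q1$rank - q0$rank
  df2 <- length(y) - q1$rank
  f <- ((rss0 - rss1) / df1) / (rss1 / df2)
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Causal inference test for one (G, M, Y) triplet
#'
#' Components (all covariate-adjusted OLS):
#' 1. G and Y associated (F-test of G in Y ~ G + W);
#' 2. G associated with M given Y (F-test of G in M ~ G + Y + W);
#' 3. M associated with Y given G (F-test of M in Y ~ M + G + W);
#' 4. G independent of Y given M: permutation equivalence test. G is
#'    residualized on Y (and W); the residuals are permuted and re-added
#'    to the fitted part, so each permuted G* preserves the marginal G-Y
#'    association while destroying the mediated pathway. The observed
#'    conditional F (G in Y ~ M + G + W) is compared against the permuted
#'    F*: p4 = (1 + #\{F* <= F_obs\}) / (n_perm + 1). Small p4 therefore
#'    supports conditional independence (mediation); if dependence
#'    remains, F_obs sits among or above the F* and p4 is large.
#'
#' The CIT p-value is the maximum of the four component p-values.
#'
#' @param G dosage vector.
#' @param M methylation vector.
#' @param Y ordinal cluster encoding (e.g. M=0, S1=1, S2=2) or binary.
#' @param covariates optional covariate table or matrix (aligned).
#' @param n_perm permutations for component 4 (>= 100 advised).
#' @param seed integer seed for the permutations.
#' @return `cit_result`: list with p1..p4, p_cit and component F
#'   statistics.
#' @export
cit_test <- function(G, M, Y, covariates = NULL, n_perm = 1000, seed = 1L) {
  if (stats::sd(G) == 0 || stats::sd(M) == 0)
    stop("constant G or M", call. = FALSE)
  if (n_perm < 100)
    warning("n_perm < 100 gives a coarse component-4 p-value")
  n <- length(G)
  W <- if (is.null(covariates)) {
    matrix(1, n, 1)
  } else {
    if (is.data.frame(covariates) && "sample_id" %in% names(covariates))
      covariates <- covariate_design(covariates)
    build_design(covariates)
  }
  Y <- as.numeric(Y); G <- as.numeric(G); M <- as.numeric(M)
  t1 <- block_f(Y, W, G)
  t2 <- block_f(M, cbind(W, Y), G)
  t3 <- block_f(Y, cbind(W, G), M)
  ## component 4
  XWM <- cbind(W, M)
  qWM <- qr(XWM)
  f_obs <- block_f(Y, XWM, G)$f
  qWY <- qr(cbind(W, Y))
  g_fit <- qr.fitted(qWY, G)
  g_res <- qr.resid(qWY, G)
  set.seed(child_seed(seed, 701L))
  perm <- replicate(n_perm, sample.int(n))
  Gstar <- g_fit + matrix(g_res[perm], n, n_perm)      # n x n_perm
  ## F* for each G*: residualize Y and G* on [W, M], then 1-df F from the
  ## squared partial correlation.
  ry <- qr.resid(qWM, Y)
  Rg <- qr.resid(qWM, Gstar)
  df2 <- n - qWM$rank - 1
  num <- colSums(Rg * ry)^2
  r2 <- num / (colSums(Rg^2) * sum(ry^2))
  f_star <- df2 * r2 / (1 - r2)
  p4 <- (1 + sum(f_star <= f_obs)) / (n_perm + 1)
  ps <- c(p1 = t1$p, p2 = t2$p, p3 = t3$p, p4 = p4)
  structure(list(p1 = ps[[1]], p2 = ps[[2]], p3 = ps[[3]], p4 = ps[[4]],
                 p_cit = max(ps), f1 = t1$f, f2 = t2$f, f3 = t3$f,
                 f4_obs = f_obs, n_perm = n_perm),
            class = "cit_result")
}

#' @export
print.cit_result <- function(x, ...) {
  cat(sprintf("CIT: p1=%.3g p2=%.3g p3=%.3g p4=%.3g -> p_cit=%.3g\n",
              x$p1, x$p2, x$p3, x$p4, x$p_cit))
  invisible(x)
}

#' Screen meQTL pairs for methylation mediation of cluster association
#'
#' Stage 1: every unique meQTL SNP is tested for cluster association with
#' the same covariate-adjusted model (F-test of G in Y ~ G + W) and the
#' survivors at BH FDR < `fdr` are kept. Stage 2: the CIT is run on every
#' surviving (SNP, CpG) pair and BH is applied across the CIT p-values.
#'
#' @param meqtl_results significant meQTL pairs ([fit_meqtl()] rows; only
#'   `snp_id`/`cpg_id` are used).
#' @param beta,genotypes,covariates aligned matrices/table.
#' @param assignment `cluster_assignment` providing the ordinal Y.
#' @param fdr FDR for both stages (0.05).
#' @param n_perm,seed CIT permutation settings.
#' @return data frame: snp_id, cpg_id, snp_cluster_p, snp_cluster_q,
#'   p1..p4, p_cit, q_cit, mediation flag. Zero-row with a message when no
#'   SNP survives stage 1.
#' @export
screen_mediation <- function(meqtl_results, beta, genotypes, assignment,
                             covariates, fdr = 0.05, n_perm = 1000,
                             seed = 1L) {
  B <- as.matrix(beta); G <- as.matrix(genotypes)
  check_alignment(colnames(B), colnames(G), assignment$sample_ids,
                  covariates$sample_id,
                  what = "beta/genotypes/assignment/covariates")
  Y <- as.numeric(factor(assignment$label)) - 1    # ordinal 0..k-1
  W <- build_design(covariate_design(covariates))
  snps <- unique(meqtl_results$snp_id)
  p_stage1 <- vapply(snps, function(s) {
    g <- G[s, ]; g[is.na(g)] <- mean(g, na.rm = TRUE)
    block_f(Y, W, g)$p
  }, numeric(1))
  q_stage1 <- stats::p.adjust(p_stage1, "BH")
  surv <- snps[q_stage1 < fdr]
  pairs <- meqtl_results[meqtl_results$snp_id %in% surv,
                         c("snp_id", "cpg_id")]
  if (!nrow(pairs)) {
    message("screen_mediation: no meQTL SNP is cluster-associated at FDR ",
            fdr)
    return(data.frame(snp_id = character(0), cpg_id = character(0),
                      snp_cluster_p = numeric(0), snp_cluster_q = numeric(0),
                      p1 = numeric(0), p2 = numeric(0), p3 = numeric(0),
                      p4 = numeric(0), p_cit = numeric(0),
                      q_cit = numeric(0), mediation = logical(0)))
  }
  cits <- lapply(seq_len(nrow(pairs)), function(i) {
    g <- G[pairs$snp_id[i], ]; g[is.na(g)] <- mean(g, na.rm = TRUE)
    cit_test(g, B[pairs$cpg_id[i], ], Y, covariates, n_perm = n_perm,
             seed = child_seed(seed, 811L + i))
  })
  out <- data.frame(snp_id = pairs$snp_id, cpg_id = pairs$cpg_id,
                    snp_cluster_p = p_stage1[match(pairs$snp_id, snps)],
                    snp_cluster_q = q_stage1[match(pairs$snp_id, snps)],
                    p1 = vapply(cits, `[[`, numeric(1), "p1"),
                    p2 = vapply(cits, `[[`, numeric(1), "p2"),
                    p3 = vapply(cits, `[[`, numeric(1), "p3"),
                    p4 = vapply(cits, `[[`, numeric(1), "p4"),
                    p_cit = vapply(cits, `[[`, numeric(1), "p_cit"),
                    stringsAsFactors = FALSE)
  out$q_cit <- stats::p.adjust(out$p_cit, "BH")
  out$mediation <- out$q_cit < fdr
  rownames(out) <- NULL
  out
}

#' Mediation effect profile: dependence of cluster on genotype with and
#' without methylation adjustment
#'
#' Two covariate-adjusted OLS fits of Y on G, without and with M;
#' coefficients and 95% confidence intervals are returned. Under pure
#' mediation the adjusted coefficient shrinks toward zero.
#'
#' @param G,M,Y,covariates as in [cit_test()].
#' @return data frame with rows `unadjusted` and `adjusted`: estimate,
#'   lower, upper.
#' @export
mediation_effect_profile <- function(G, M, Y, covariates = NULL) {
  n <- length(G)
  if (abs(stats::cor(G, M)) > 1 - 1e-12)
    stop("G and M are perfectly collinear", call. = FALSE)
  W <- if (is.null(covariates)) NULL else {
    if (is.data.frame(covariates) && "sample_id" %in% names(covariates))
      covariates <- covariate_design(covariates)
    build_design(covariates)[, -1, drop = FALSE]  # lm adds the intercept
  }
  fit_one <- function(X) {
    fit <- stats::lm(Y ~ ., data = as.data.frame(X))
    ci <- stats::confint(fit)["G", ]
    c(estimate = unname(stats::coef(fit)["G"]), lower = ci[[1]],
      upper = ci[[2]])
  }
  un <- fit_one(if (is.null(W)) data.frame(G = G) else data.frame(G = G, W))
  ad <- fit_one(if (is.null(W)) data.frame(G = G, M = M)
                else data.frame(G = G, M = M, W))
  out <- as.data.frame(rbind(unadjusted = un, adjusted = ad))
  out$model <- rownames(out)
  out
}
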