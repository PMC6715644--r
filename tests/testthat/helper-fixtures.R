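# shared fixtures and independent oracles, all built in code

# scaled-down cohort keeping the default generator's proportions roughly
small_sim_config <- function(seed = 1, ...) {
  args <- list(n_cpgs = 2000, n_cluster_cpgs = 60, n_meqtl = 20,
               n_cell_cpgs = 200, n_ethnic_cpgs = 40, n_snps = 300,
               mediation_scenarios = c(causal = 2, reactive = 2,
                                       independent = 2),
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

truth_assignment <- function(cohort) {
  lab <- c("M", paste0("S", seq_len(max(cohort$truth$true_cluster) - 1)))
  as_cluster_assignment(lab[cohort$truth$true_cluster],
                        colnames(cohort$beta))
}

# full covariate table; cell = "true" uses the generator's factor scores
cohort_covariates <- function(cohort, cell = c("true", "refactor", "none"),
                              seed = 1) {
  cell <- match.arg(cell)
  med <- as.matrix(cohort$covariates[, grep("^med", names(cohort$covariates)),
                                     drop = FALSE])
  medpc <- suppressWarnings(medication_pca(med, seed = seed))
  rownames(medpc) <- cohort$covariates$sample_id
  anc <- ancestry_pcs(cohort$genotypes, 3)
  cellm <- switch(cell,
    none = NULL,
    refactor = refactor_components(cohort$beta, k = 4, t = 200),
    true = {
      m <- cohort$truth$cell_factor_scores
      colnames(m) <- paste0("cellc", seq_len(ncol(m)))
      rownames(m) <- cohort$covariates$sample_id
      m
    })
  build_covariates(cohort$covariates, medpc, anc, cellm)
}

# ---- independent oracles ---------------------------------------------

# OLS via explicit normal equations
ols_oracle <- function(X, y) {
  bt <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% bt
  list(coef = drop(bt), rss = sum(res^2))
}

# principal row coordinates of correspondence analysis via MASS::corresp
mca_oracle_coords <- function(criteria, nf) {
  X <- unclass(as.matrix(criteria))
  Q <- ncol(X)
  Z <- matrix(0, nrow(X), 2 * Q)
  Z[, seq(1, 2 * Q, 2)] <- 1 - X
  Z[, seq(2, 2 * Q, 2)] <- X
  cr <- MASS::corresp(Z, nf = nf)
  cr$rscore %*% diag(cr$cor, nf)
}

# HWE exact p by direct enumeration over all genotype configurations with
# the observed allele counts, probabilities from multinomial coefficients
hwe_oracle <- function(naa, nab, nbb) {
  n <- naa + nab + nbb
  na_ <- 2 * naa + nab
  hets <- seq(na_ %% 2, min(na_, 2 * n - na_), by = 2)
  w <- vapply(hets, function(h) {
    a <- (na_ - h) / 2
    b <- n - a - h
    exp(lchoose(n, a) + lchoose(n - a, h) + h * log(2))
  }, numeric(1))
  p_each <- w / sum(w)
  obs <- p_each[hets == nab]
  sum(p_each[p_each <= obs * (1 + 1e-12)])
}

# upper-tail hypergeometric p by full enumeration of the mass function
hyper_oracle <- function(k, set_size, universe, draws) {
  xs <- max(0, draws - (universe - set_size)):min(draws, set_size)
  mass <- choose(set_size, xs) * choose(universe - set_size, draws - xs) /
    choose(universe, draws)
  sum(mass[xs >= k])
}

# two-sided Fisher p for a 2x2 table by enumeration (minimum-likelihood)
fisher_oracle <- function(tab) {
  m <- sum(tab[1, ]); n_ <- sum(tab[2, ]); k <- sum(tab[, 1])
  xs <- max(0, k - n_):min(k, m)
  mass <- choose(m, xs) * choose(n_, k - xs) / choose(m + n_, k)
  obs <- mass[xs == tab[1, 1]]
  sum(mass[mass <= obs * (1 + 1e-7)])
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
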