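make_manifest <- function(ids, chrom = "chr1") {
  data.frame(cpg_id = ids, chrom = chrom,
             pos = seq_along(ids) * 1000L, gene = "G1", region = "Body",
             stringsAsFactors = FALSE)
}

test_that("probe filtering applies detection, cross-reactive, autosome rules", {
  set.seed(1)
  beta <- matrix(runif(6 * 100), 6, 100,
                 dimnames = list(paste0("cg", 1:6), paste0("s", 1:100)))
  mf <- make_manifest(rownames(beta))
  mf$chrom[3] <- "chrX"
  det <- matrix(0, 6, 100, dimnames = dimnames(beta))
  det[1, 1:6] <- 0.2   # fails in 6% of samples -> removed
  det[2, 1:5] <- 0.2   # fails in exactly 5% -> kept
  out <- filter_probes(beta, mf, detection_p = det,
                       crossreactive_ids = "cg4")
  expect_setequal(rownames(out$beta), c("cg2", "cg5", "cg6"))
  expect_equal(unname(out$removed),
               c(1L, 1L, 1L))
  expect_error(filter_probes(beta, mf[-1, ]), "cg1")
})

test_that("per-CpG ANOVA matches the normal-equations oracle", {
  set.seed(2)
  n <- 18
  cl <- factor(rep(c("M", "S1", "S2"), each = 6))
  covs <- data.frame(sample_id = paste0("s", 1:n),
                     sex = rbinom(n, 1, 0.5), age = rnorm(n, 45, 8),
                     smoke = rbinom(n, 1, 0.2), alcohol = rbinom(n, 1, 0.5))
  beta <- matrix(runif(5 * n, 0.2, 0.8), 5, n,
                 dimnames = list(paste0("cg", 1:5), covs$sample_id))
  asg <- as_cluster_assignment(cl, covs$sample_id)
  res <- cluster_anova(beta, asg, covs)
  X <- cbind(1, covs$sex, covs$age, covs$smoke, covs$alcohol,
             cl == "S1", cl == "S2")
  X0 <- X[, 1:5]
  for (i in 1:5) {
    o1 <- ols_oracle(X, beta[i, ])
    o0 <- ols_oracle(X0, beta[i, ])
    f <- ((o0$rss - o1$rss) / 2) / (o1$rss / (n - ncol(X)))
    expect_equal(res$f_statistic[i], f, tolerance = 1e-8)
    expect_equal(res$variance_explained[i], (o0$rss - o1$rss) / o0$rss,
                 tolerance = 1e-8)
    # adjusted cluster mean differences come from the dummy coefficients
    expect_equal(res$delta_S2_M[i], o1$coef[7], tolerance = 1e-8)
    expect_equal(res$delta_S1_M[i], o1$coef[6], tolerance = 1e-8)
  }
})

test_that("F equals squared t for two clusters; degenerate rows flagged", {
  set.seed(3)
  n <- 30
  covs <- data.frame(sample_id = paste0("s", 1:n), sex = rbinom(n, 1, 0.5),
                     age = rnorm(n, 40, 5), smoke = 0 * 1:n %% 2,
                     alcohol = rbinom(n, 1, 0.5))
  cl <- rep(c("M", "S1"), each = n / 2)
  beta <- matrix(runif(4 * n), 4, n,
                 dimnames = list(paste0("cg", 1:4), covs$sample_id))
  beta[4, ] <- 0.5   # zero variance
  asg <- as_cluster_assignment(cl, covs$sample_id)
  res <- suppressWarnings(cluster_anova(beta, asg, covs))
  X <- model.matrix(~ sex + age + alcohol + factor(cl), data = covs)
  for (i in 1:3) {
    fit <- summary(lm(beta[i, ] ~ X - 1))
    expect_equal(res$f_statistic[i], fit$coefficients[5, "t value"]^2,
                 tolerance = 1e-10)
  }
  expect_true(res$zero_variance[4])
  expect_equal(res$p[4], 1)
  # duplicated rows give identical statistics
  res2 <- suppressWarnings(cluster_anova(beta[c(1, 1, 2), ], asg, covs))
  expect_equal(res2$f_statistic[1], res2$f_statistic[2])
})

test_that("pairwise contrasts localize single-cluster effects", {
  co <- simulate_cohort(small_sim_config(seed = 14,
                                         delta_beta = c(0, 0, -0.06)))
  asg <- truth_assignment(co)
  covs <- cohort_covariates(co, cell = "true")
  planted <- co$truth$cluster_cpgs[1:30]
  con <- pairwise_contrasts(planted, co$beta, asg, covs,
                            fdr_threshold = 0.05)
  hits <- function(ct) {
    x <- con[con$contrast == ct, ]
    mean(x$significant)
  }
  expect_gt(hits("S2_vs_M"), 0.8)
  expect_gt(hits("S2_vs_S1"), 0.8)
  expect_lt(hits("S1_vs_M"), 0.2)
  # swapping two cluster labels flips the sign, keeps the p-value
  lab2 <- as.character(asg$label)
  lab2[lab2 == "S2"] <- "zz"; lab2[lab2 == "M"] <- "S2"; lab2[lab2 == "zz"] <- "M"
  asg2 <- as_cluster_assignment(factor(lab2, levels = c("M", "S1", "S2")),
                                asg$sample_ids)
  con2 <- pairwise_contrasts(planted, co$beta, asg2, covs,
                             fdr_threshold = 0.05)
  a <- con[con$contrast == "S2_vs_M", ]
  b <- con2[con2$contrast == "S2_vs_M", ]
  expect_equal(a$delta_beta, -b$delta_beta, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-10)
})

test_that("detection power grows with the planted shift", {
  power_at <- function(delta, seed) {
    co <- simulate_cohort(small_sim_config(
      seed = seed, delta_beta = c(delta, 0, -delta), n_cpgs = 1500,
      n_cluster_cpgs = 80, n_meqtl = 0, n_ethnic_cpgs = 0, n_med_cpgs = 0,
      mediation_scenarios = c(causal = 0, reactive = 0, independent = 0)))
    covs <- cohort_covariates(co, cell = "true")
    dm <- cluster_anova(co$beta, truth_assignment(co), covs)
    mean(dm$significant[dm$cpg_id %in% co$truth$cluster_cpgs])
  }
  p05 <- power_at(0.05, 31)
  p01 <- power_at(0.012, 31)
  expect_gt(p05, p01)
  expect_gt(p05, 0.8)
})

test_that("inflation factor behaves at its fixed points", {
  expect_equal(inflation_lambda(rep(0.5, 100))$lambda, 1)
  set.seed(4)
  infl <- inflation_lambda(runif(50000))
  expect_lt(abs(infl$lambda - 1), 0.03)
  # planted signal inflates
  expect_gt(inflation_lambda(c(runif(1000), rep(1e-6, 200)))$lambda, 1)
  expect_error(inflation_lambda(numeric(0)), "empty")
  expect_error(inflation_lambda(c(0.5, 0)), "0, 1")
})
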