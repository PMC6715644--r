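test_that("random-forest training tracks separability and is reproducible", {
  set.seed(1)
  n <- 120
  cl <- factor(rep(c("M", "S1", "S2"), each = n / 3))
  sep <- cbind(a = as.integer(cl == "M"), b = as.integer(cl == "S1"),
               c = as.integer(cl == "S2"),
               matrix(rbinom(n * 5, 1, 0.5), n, 5,
                      dimnames = list(NULL, paste0("x", 1:5))))
  rownames(sep) <- paste0("s", 1:n)
  grid <- list(ntree = c(100, 200), mtry = c(2, 4))
  m <- train_cluster_model(sep, cl, param_grid = grid, seed = 2)
  expect_lt(m$oob_error, 0.05)
  expect_equal(nrow(m$oob_error_curve), 4)
  m2 <- train_cluster_model(sep, cl, param_grid = grid, seed = 2)
  expect_identical(m$oob_error_curve, m2$oob_error_curve)
  expect_identical(m$selected_params, m2$selected_params)
  # label-permuted training cannot beat the majority class
  perm <- train_cluster_model(sep, sample(cl), param_grid = grid, seed = 3)
  expect_gt(perm$oob_error, 1 - max(table(cl)) / n - 0.12)
  expect_error(train_cluster_model(sep, factor(rep("M", n))), "single")
})

test_that("label transfer aligns by column name and flags missing criteria", {
  set.seed(2)
  n <- 90
  cl <- factor(rep(c("M", "S1"), each = n / 2))
  X <- cbind(a = as.integer(cl == "M"),
             matrix(rbinom(n * 4, 1, 0.5), n, 4,
                    dimnames = list(NULL, paste0("x", 1:4))))
  rownames(X) <- paste0("s", 1:n)
  m <- train_cluster_model(X, cl,
                           param_grid = list(ntree = 100, mtry = 2),
                           seed = 1)
  pred_tr <- transfer_labels(m, X)
  # identical sample -> identical prediction
  expect_equal(as.character(pred_tr$label[1]),
               as.character(transfer_labels(m, X[1, , drop = FALSE])$label))
  # shuffled columns give identical predictions
  shuf <- X[, c(3, 1, 5, 2, 4)]
  expect_identical(transfer_labels(m, shuf)$label, pred_tr$label)
  expect_error(transfer_labels(m, X[, -1]), "lack column")
  expect_equal(rowSums(pred_tr$votes), rep(1, n), ignore_attr = TRUE)
})

test_that("transfer to a replication cohort approaches the accuracy ceiling", {
  co <- simulate_cohort(small_sim_config(seed = 23, n_cpgs = 300,
                                         n_cluster_cpgs = 20, n_meqtl = 5,
                                         n_cell_cpgs = 30, n_ethnic_cpgs = 10))
  ext_cfg <- small_sim_config(seed = 24, n_cpgs = 300, n_cluster_cpgs = 20,
                              n_meqtl = 5, n_cell_cpgs = 30,
                              n_ethnic_cpgs = 10)
  ext_cfg$effect_seed <- co$config$effect_seed
  ext <- simulate_cohort(ext_cfg)
  m <- train_cluster_model(co$criteria, truth_assignment(co),
                           param_grid = list(ntree = 300, mtry = 4),
                           seed = 5)
  pred <- transfer_labels(m, ext$criteria)
  agree <- mean(as.integer(pred$label) == ext$truth$true_cluster)
  expect_gt(agree, 0.75)   # Bayes accuracy of these profiles is ~0.88
  # accuracy degrades monotonically with criterion noise
  noisy <- function(rate, seed) {
    set.seed(seed)
    X <- ext$criteria
    flip <- matrix(runif(length(X)) < rate, nrow(X))
    X[flip] <- 1L - X[flip]
    mean(as.integer(transfer_labels(m, X)$label) == ext$truth$true_cluster)
  }
  a1 <- noisy(0.15, 31); a2 <- noisy(0.4, 31)
  expect_gt(agree, a1)
  expect_gt(a1, a2)
})

test_that("external validation reproduces planted delta-beta structure", {
  co <- simulate_cohort(small_sim_config(seed = 25))
  ext_cfg <- small_sim_config(seed = 26)
  ext_cfg$effect_seed <- co$config$effect_seed
  ext <- simulate_cohort(ext_cfg)
  asg <- truth_assignment(co)
  covs <- cohort_covariates(co, cell = "true")
  disc <- pairwise_contrasts(co$truth$cluster_cpgs, co$beta, asg, covs)
  ext_asg <- truth_assignment(ext)
  ext_covs <- cohort_covariates(ext, cell = "true")
  val <- validate_cpgs(ext$beta, ext_asg, ext_covs,
                       co$truth$cluster_cpgs, discovery_contrasts = disc)
  expect_gt(val$validated_fraction, 0.8)
  expect_true(all(val$delta_correlation > 0.9))
  # discovery against itself: r = 1
  self <- validate_cpgs(co$beta, asg, covs, co$truth$cluster_cpgs,
                        discovery_contrasts = disc)
  expect_equal(unname(self$delta_correlation),
               rep(1, length(self$delta_correlation)), tolerance = 1e-10)
  # null external cohort: nominal validated fraction, r near 0
  null_cfg <- small_sim_config(seed = 27, delta_beta = c(0, 0, 0),
                               meqtl_effect = 0, n_ethnic_cpgs = 0,
                               n_med_cpgs = 0, n_cell_factors = 0,
                               mediation_scenarios = c(causal = 0,
                                                       reactive = 0,
                                                       independent = 0),
                               n_meqtl = 0)
  nul <- simulate_cohort(null_cfg)
  nul_val <- validate_cpgs(nul$beta, truth_assignment(nul),
                           cohort_covariates(nul, cell = "none"),
                           rownames(nul$beta)[1:200],
                           discovery_contrasts = disc)
  expect_lt(nul_val$validated_fraction, 0.1)
  expect_error(validate_cpgs(ext$beta, ext_asg, ext_covs, "cg_nonexistent"),
               "overlap")
})
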