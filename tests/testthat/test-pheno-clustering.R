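test_that("dichotomization applies rules, excludes unmapped, flags constants", {
  raw <- data.frame(sample_id = paste0("P", 1:5),
                    rash = c("present", "absent", "present", "absent",
                             "unknown"),
                    renal = c("yes", "no", "yes", "no", "yes"),
                    stringsAsFactors = FALSE)
  rules <- list(rash = c(present = 1, absent = 0),
                renal = c(yes = 1, no = 0))
  expect_message(cm <- dichotomize_criteria(raw, rules), "excluding 1")
  expect_equal(nrow(cm), 4)
  expect_true(all(cm %in% 0:1))
  expect_equal(unname(cm[, "rash"]), c(1L, 0L, 1L, 0L))
  expect_error(dichotomize_criteria(raw, rules["rash"]),
               "no dichotomization rule")
  # all-zero criterion retained but flagged
  raw2 <- data.frame(sample_id = paste0("P", 1:4),
                     a = c("yes", "no", "yes", "no"),
                     b = rep("no", 4))
  cm2 <- dichotomize_criteria(raw2, list(a = c(yes = 1, no = 0),
                                         b = c(yes = 1, no = 0)))
  expect_equal(attr(cm2, "zero_variance"), "b")
  expect_true("b" %in% colnames(cm2))
})

test_that("MCA inertia equals (J/Q)-1 and eigenvalues sum to it", {
  co <- simulate_cohort(small_sim_config(seed = 1, n_samples = 80,
                                         n_cpgs = 100, n_cluster_cpgs = 10,
                                         n_meqtl = 5, n_cell_cpgs = 10,
                                         n_ethnic_cpgs = 5))
  fit <- mca(co$criteria)
  expect_equal(fit$total_inertia,
               fit$n_categories / fit$n_variables - 1, tolerance = 1e-10)
  expect_equal(sum(fit$eigenvalues), fit$total_inertia, tolerance = 1e-8)
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
  expect_error(mca(matrix(1, 10, 3)), "constant")
})

test_that("MCA row coordinates match the correspondence-analysis oracle", {
  set.seed(7)
  X <- matrix(rbinom(60 * 6, 1, 0.4), 60, 6)
  rownames(X) <- paste0("s", 1:60)
  colnames(X) <- paste0("c", 1:6)
  fit <- mca(X)
  orc <- mca_oracle_coords(X, nf = 4)
  for (j in 1:4) {
    d <- min(max(abs(fit$coordinates[, j] - orc[, j])),
             max(abs(fit$coordinates[, j] + orc[, j])))
    expect_lt(d, 1e-8)
  }
  # permutation equivariance
  perm <- sample(nrow(X))
  fit2 <- mca(X[perm, ])
  expect_equal(unname(fit2$coordinates), unname(fit$coordinates[perm, ]),
               tolerance = 1e-10)
})

test_that("cross-validated dimension selection recovers planted rank", {
  set.seed(11)
  n <- 150; Q <- 10
  scores <- matrix(rnorm(n * 2), n, 2)
  load <- matrix(rnorm(2 * Q, sd = 2), 2, Q)
  X <- (plogis(scores %*% load) > runif(n * Q)) * 1L
  colnames(X) <- paste0("c", 1:Q)
  expect_equal(select_dimensions(X, max_dim = 5, seed = 3), 2)
  noise <- matrix(rbinom(n * Q, 1, 0.5), n, Q,
                  dimnames = list(NULL, paste0("c", 1:Q)))
  expect_equal(select_dimensions(noise, max_dim = 5, seed = 3), 1)
  expect_error(select_dimensions(X, n_folds = 1), "n_folds")
})

test_that("k-means recovers separated structure and handles degenerate k", {
  pts <- rbind(matrix(rnorm(40, 0, 0.01), 20, 2),
               matrix(rnorm(40, 5, 0.01), 20, 2))
  rownames(pts) <- paste0("s", 1:40)
  fit <- kmeans_cluster(pts, 2, seed = 1)
  expect_equal(length(unique(fit$cluster[1:20])), 1)
  expect_equal(length(unique(fit$cluster[21:40])), 1)
  expect_lt(fit$tot_withinss, 0.1)
  fit_n <- kmeans_cluster(pts, nrow(pts), seed = 1, n_restarts = 5)
  expect_equal(fit_n$tot_withinss, 0, tolerance = 1e-12)
  expect_error(kmeans_cluster(pts, 41, seed = 1), "exceed")
  expect_identical(kmeans_cluster(pts, 2, seed = 9)$cluster,
                   kmeans_cluster(pts, 2, seed = 9)$cluster)
})

test_that("bootstrap stability selects the true k on separated data", {
  set.seed(5)
  pts <- rbind(matrix(rnorm(60, 0, 0.1), 30, 2),
               matrix(rnorm(60, 4, 0.1), 30, 2),
               cbind(rnorm(30, 0, 0.1), rnorm(30, 4, 0.1)))
  st <- bootstrap_stability(pts, 2:4, n_bootstrap = 100, seed = 2,
                            n_restarts = 10, n_restarts_boot = 5)
  expect_equal(st$selected_k, 3)
  expect_true(all(st$per_cluster_jaccard[["3"]] >= 0.95))
  expect_true(all(st$stable[["3"]]))
  expect_error(bootstrap_stability(pts, integer(0)), "empty")
  expect_error(bootstrap_stability(pts, 2:3, n_bootstrap = 5), "20")
})

test_that("label noise strictly degrades mean Jaccard stability", {
  set.seed(6)
  base <- rbind(matrix(rnorm(80, 0, 0.1), 40, 2),
                matrix(rnorm(80, 4, 0.1), 40, 2))
  jit <- function(noise_sd) {
    pts <- base + matrix(rnorm(length(base), 0, noise_sd), nrow(base))
    st <- bootstrap_stability(pts, 2, n_bootstrap = 40, seed = 3,
                              n_restarts = 5, n_restarts_boot = 5)
    mean(st$per_cluster_jaccard[[1]])
  }
  j0 <- jit(0); j1 <- jit(1.2); j2 <- jit(2.5)
  expect_gt(j0, j1)
  expect_gt(j1, j2)
})

test_that("severity ordering labels clusters M, S1, ... correctly", {
  crit <- rbind(matrix(0, 10, 5), matrix(1, 10, 5))
  colnames(crit) <- c("a", "b", "renal", "d", "e")
  rownames(crit) <- paste0("s", 1:20)
  asg <- as_cluster_assignment(rep(c("g2", "g1"), each = 10),
                               rownames(crit))
  asg$centroids <- matrix(0, 2, 1)
  out <- order_clusters_by_severity(asg, crit)
  expect_equal(as.character(out$label[1]), "M")   # low criterion count
  expect_equal(as.character(out$label[11]), "S1")
  # supplied severity column wins over criterion count
  sev <- c(rep(10, 10), rep(1, 10))
  out2 <- order_clusters_by_severity(asg, crit, severity = sev)
  expect_equal(as.character(out2$label[1]), "S1")
  # k = 1 identity
  one <- as_cluster_assignment(rep("x", 20), rownames(crit))
  one$centroids <- matrix(0, 1, 1)
  expect_equal(levels(order_clusters_by_severity(one, crit)$label), "M")
})

test_that("paper-scale cohorts cluster near the model's accuracy ceiling", {
  # under conditionally independent Bernoulli criteria the latent clusters
  # overlap; the discovered partition should approach the Bayes partition
  co <- simulate_cohort(small_sim_config(seed = 21, n_cpgs = 200,
                                         n_cluster_cpgs = 20, n_meqtl = 5,
                                         n_cell_cpgs = 20, n_ethnic_cpgs = 10))
  fit <- mca(co$criteria)
  asg <- kmeans_cluster(fit$coordinates[, 1:2], 3, seed = 1)
  pv <- co$config$criterion_prevalence
  ll <- co$criteria %*% t(log(pv)) + (1 - co$criteria) %*% t(log(1 - pv))
  ll <- sweep(ll, 2, log(co$config$cluster_proportions), "+")
  bayes <- max.col(ll)
  expect_gt(ari(asg$cluster, bayes), 0.55)
  expect_gt(ari(asg$cluster, co$truth$true_cluster), 0.45)
})
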