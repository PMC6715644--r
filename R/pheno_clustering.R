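## Phenotypic subtype discovery: multiple correspondence analysis of binary
## ACR criteria, K-means on the retained dimensions, and bootstrap Jaccard
## stability selection of the number of clusters.

#' Dichotomize a raw phenotype table into a binary criteria matrix
#'
#' Every criterion column must have a mapping rule (named vector
#' value -> 0/1). Samples carrying a value not covered by the rule for any
#' criterion are excluded and reported.
#'
#' @param raw data frame with a `sample_id` column plus one column per
#'   criterion.
#' @param rules named list: one named 0/1 vector per criterion column.
#' @return a samples x criteria 0/1 matrix (`criteria_matrix`), with
#'   attributes `zero_variance` (flagged constant columns) and
#'   `excluded_samples`.
#' @export
dichotomize_criteria <- function(raw, rules) {
  stopifnot("sample_id" %in% names(raw))
  crit_cols <- setdiff(names(raw), "sample_id")
  missing_rules <- setdiff(crit_cols, names(rules))
  if (length(missing_rules))
    stop("configuration error: no dichotomization rule for criterion ",
         paste(missing_rules, collapse = ", "), call. = FALSE)
  out <- matrix(NA_integer_, nrow(raw), length(crit_cols),
                dimnames = list(raw$sample_id, crit_cols))
  for (cc in crit_cols) {
    rule <- rules[[cc]]
    out[, cc] <- unname(rule[as.character(raw[[cc]])])
  }
  bad <- rowSums(is.na(out)) > 0
  if (any(bad))
    message("dichotomize_criteria: excluding ", sum(bad),
            " sample(s) with unmapped values: ",
            paste(utils::head(raw$sample_id[bad], 5), collapse = ", "))
  out <- out[!bad, , drop = FALSE]
  if (any(!out %in% c(0L, 1L)))
    stop("dichotomization rules must map to 0/1 only", call. = FALSE)
  zv <- colnames(out)[apply(out, 2, function(x) length(unique(x)) == 1)]
  attr(out, "zero_variance") <- zv
  attr(out, "excluded_samples") <- raw$sample_id[bad]
  class(out) <- c("criteria_matrix", class(out))
  out
}

#' Multiple correspondence analysis of a binary criteria matrix
#'
#' Correspondence analysis of the complete indicator matrix (each binary
#' criterion expanded to an absent/present category pair). Row coordinates
#' are returned in principal scale; for Q complete binary variables the
#' total inertia is (J/Q) - 1 = 1 with J = 2Q categories.
#'
#' @param criteria samples x criteria 0/1 matrix.
#' @return `mca_result`: list with `coordinates` (samples x dims, principal
#'   scale), `eigenvalues`, `total_inertia`, `category_coordinates`.
#' @export
mca <- function(criteria) {
  X <- unclass(as.matrix(criteria))
  if (nrow(X) < 2 || ncol(X) < 2)
    stop("mca needs at least 2 samples and 2 criteria", call. = FALSE)
  keep <- apply(X, 2, function(x) length(unique(x)) > 1)
  if (!any(keep))
    stop("degenerate input: all criteria are constant", call. = FALSE)
  X <- X[, keep, drop = FALSE]
  Q <- ncol(X)
  ## indicator expansion: [absent, present] per criterion
  Z <- matrix(0, nrow(X), 2 * Q)
  Z[, seq(1, 2 * Q, 2)] <- 1 - X
  Z[, seq(2, 2 * Q, 2)] <- X
  colnames(Z) <- as.vector(rbind(paste0(colnames(X), ":0"),
                                 paste0(colnames(X), ":1")))
  P <- Z / sum(Z)
  r <- rowSums(P)
  cm <- colSums(P)
  S <- (P - outer(r, cm)) / sqrt(outer(r, cm))
  sv <- svd(S)
  nd <- sum(sv$d > 1e-10)
  d <- sv$d[seq_len(nd)]
  U <- sv$u[, seq_len(nd), drop = FALSE]
  V <- sv$v[, seq_len(nd), drop = FALSE]
  ## deterministic, permutation-stable sign: skewness of category loadings
  for (j in seq_len(nd)) {
    s <- sum(V[, j]^3)
    if (abs(s) < 1e-12) s <- V[which.max(abs(V[, j])), j]
    if (s < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
  }
  coords <- sweep(U, 1, sqrt(r), "/") %*% diag(d, nd)
  cat_coords <- sweep(V, 1, sqrt(cm), "/") %*% diag(d, nd)
  rownames(coords) <- rownames(criteria)
  rownames(cat_coords) <- colnames(Z)
  colnames(coords) <- colnames(cat_coords) <- paste0("Dim", seq_len(nd))
  structure(list(coordinates = coords,
                 eigenvalues = d^2,
                 total_inertia = sum(sv$d^2),
                 category_coordinates = cat_coords,
                 n_categories = 2 * Q, n_variables = Q),
            class = "mca_result")
}

#' Select the number of MCA dimensions by cell-wise cross-validation
#'
#' Random cells of the indicator matrix are held out in `n_folds` folds;
#' each fold is imputed by an iterative rank-d SVD scheme and the
#' reconstruction error on the held-out cells is accumulated. Returns the
#' dimension count minimizing cross-validated error, ties broken toward
#' fewer dimensions.
#'
#' @param criteria samples x criteria 0/1 matrix.
#' @param max_dim largest dimensionality tried.
#' @param n_folds number of cell folds (>= 2).
#' @param seed integer seed.
#' @return integer, the selected number of dimensions.
#' @export
select_dimensions <- function(criteria, max_dim = 5, n_folds = 3, seed = 1L) {
  if (n_folds < 2)
    stop("configuration error: n_folds must be >= 2", call. = FALSE)
  X <- unclass(as.matrix(criteria))
  Q <- ncol(X)
  max_dim <- min(max_dim, Q - 1, nrow(X) - 1)
  set.seed(child_seed(seed, 211L))
  fold <- matrix(sample(rep_len(seq_len(n_folds), length(X))),
                 nrow(X), ncol(X))
  err <- numeric(max_dim)
  for (d in seq_len(max_dim)) {
    for (f in seq_len(n_folds)) {
      M <- X
      hold <- fold == f
      M[hold] <- NA
      imp <- svd_impute(M, d)
      err[d] <- err[d] + sum((imp[hold] - X[hold])^2)
    }
  }
  which.min(err)  # which.min takes the first (smallest d) on ties
}

## iterative regularized rank-d SVD imputation of a matrix with missing
## cells; singular values are shrunk by the residual noise estimate so
## higher ranks do not overfit the held-out cells
svd_impute <- function(M, d, n_iter = 25, tol = 1e-6) {
  miss <- is.na(M)
  mu <- colMeans(M, na.rm = TRUE)
  mu[is.na(mu)] <- 0.5
  M[miss] <- matrix(mu, nrow(M), ncol(M), byrow = TRUE)[miss]
  last <- Inf
  for (it in seq_len(n_iter)) {
    ctr <- colMeans(M)
    sv <- svd(sweep(M, 2, ctr))
    dd <- seq_len(min(d, length(sv$d)))
    dl <- sv$d[dd]
    if (length(sv$d) > length(dd)) {
      s2 <- mean(sv$d[-dd]^2)
      dl <- pmax(0, (dl^2 - s2) / dl)
    }
    R <- sv$u[, dd, drop = FALSE] %*% (dl * t(sv$v[, dd, drop = FALSE]))
    R <- sweep(R, 2, ctr, "+")
    delta <- sum((M[miss] - R[miss])^2)
    M[miss] <- R[miss]
    if (abs(last - delta) < tol) break
    last <- delta
  }
  M
}

## k-means++ seeding (Arthur & Vassilvitskii) on a coordinate matrix
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- numeric(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1] <- sample.int(n, 1, prob = p)
    nd <- rowSums((x - matrix(x[centers[j + 1], ], n, ncol(x),
                              byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  x[centers, , drop = FALSE]
}

#' K-means clustering with k-means++ initialization
#'
#' Lloyd iterations from k-means++ seeds, best of `n_restarts` restarts by
#' within-cluster sum of squares; deterministic given `seed`.
#'
#' @param coords samples x dimensions coordinate matrix (e.g. retained MCA
#'   dimensions).
#' @param k number of clusters (2 <= k <= n).
#' @param seed integer seed.
#' @param n_restarts independent restarts.
#' @return `cluster_assignment`: list with `sample_ids`, `cluster`
#'   (integers 1..k), `label` (same, until severity ordering), `centroids`,
#'   `tot_withinss`.
#' @export
kmeans_cluster <- function(coords, k, seed = 1L, n_restarts = 50) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k > n) stop("k cannot exceed the number of samples", call. = FALSE)
  if (k < 1) stop("k must be positive", call. = FALSE)
  set.seed(child_seed(seed, 307L))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- kmeanspp_centers(coords, k)
    fit <- suppressWarnings(
      stats::kmeans(coords, centers = init, iter.max = 100,
                    algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  ## canonical cluster numbering: by first coordinate of centroid
  ord <- do.call(order, as.data.frame(best$centers))
  relab <- match(seq_len(k), ord)
  cl <- relab[best$cluster]
  structure(list(sample_ids = rownames(coords) %||% seq_len(n),
                 cluster = cl,
                 label = as.character(cl),
                 centroids = best$centers[ord, , drop = FALSE],
                 tot_withinss = best$tot.withinss),
            class = "cluster_assignment")
}

#' Build a cluster assignment from known labels
#'
#' Wraps externally supplied per-sample labels (e.g. simulated ground
#' truth, or labels transferred from another cohort) in the object the
#' association modules consume.
#'
#' @param labels per-sample cluster labels (factor or vector).
#' @param sample_ids sample identifiers aligned to `labels`.
#' @return a `cluster_assignment`.
#' @export
as_cluster_assignment <- function(labels, sample_ids = names(labels)) {
  f <- factor(labels)
  structure(list(sample_ids = sample_ids %||% seq_along(f),
                 cluster = as.integer(f),
                 label = f,
                 centroids = matrix(NA_real_, nlevels(f), 0,
                                    dimnames = list(levels(f), NULL))),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Cluster assignment:", length(x$sample_ids), "samples,",
      nrow(x$centroids), "clusters\n")
  print(table(x$label))
  invisible(x)
}

## Jaccard index between two index sets
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Bootstrap Jaccard stability of K-means partitions
#'
#' For each candidate k the full data are clustered; each bootstrap
#' resample is re-clustered and every original cluster is matched to the
#' bootstrap cluster maximizing the Jaccard index, computed over the
#' distinct points present in the resample. Per-cluster means over
#' resamples are reported and the selected k maximizes the minimum
#' per-cluster mean stability. Clusters with mean stability above
#' `stable_threshold` (0.82) are flagged as stable.
#'
#' @param coords samples x dimensions coordinates.
#' @param k_candidates integer vector of candidate cluster counts.
#' @param n_bootstrap bootstrap resamples (>= 20).
#' @param seed integer seed.
#' @param n_restarts restarts for the full-data clustering.
#' @param n_restarts_boot restarts for each resample clustering.
#' @param stable_threshold mean-stability flag threshold.
#' @return `stability_profile`: list with `k_values`,
#'   `per_cluster_jaccard` (list of per-cluster means per k), `selected_k`,
#'   `n_bootstrap`, `stable` (per-k logical vectors).
#' @export
bootstrap_stability <- function(coords, k_candidates = 2:6,
                                n_bootstrap = 100, seed = 1L,
                                n_restarts = 50, n_restarts_boot = 10,
                                stable_threshold = 0.82) {
  if (!length(k_candidates))
    stop("configuration error: empty k candidate list", call. = FALSE)
  if (n_bootstrap < 20)
    stop("configuration error: n_bootstrap must be >= 20", call. = FALSE)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  per_k <- vector("list", length(k_candidates))
  names(per_k) <- as.character(k_candidates)
  set.seed(child_seed(seed, 401L))
  boot_idx <- replicate(n_bootstrap, sample.int(n, n, replace = TRUE),
                        simplify = FALSE)
  for (ki in seq_along(k_candidates)) {
    k <- k_candidates[ki]
    full <- kmeans_cluster(coords, k, seed = child_seed(seed, 500L + k),
                           n_restarts = n_restarts)
    orig <- split(seq_len(n), full$cluster)
    jac <- matrix(NA_real_, n_bootstrap, k)
    for (b in seq_len(n_bootstrap)) {
      idx <- boot_idx[[b]]
      fit <- kmeans_cluster(coords[idx, , drop = FALSE], k,
                            seed = child_seed(seed, 1000L + k * 137L + b),
                            n_restarts = n_restarts_boot)
      present <- unique(idx)
      boot_cl <- split(idx, fit$cluster)           # point ids per cluster
      boot_cl <- lapply(boot_cl, unique)
      for (g in seq_len(k)) {
        a <- intersect(orig[[g]], present)
        if (!length(a)) next
        jac[b, g] <- max(vapply(boot_cl, jaccard, numeric(1), a = a))
      }
    }
    per_k[[ki]] <- colMeans(jac, na.rm = TRUE)
  }
  min_mean <- vapply(per_k, min, numeric(1))
  selected_k <- k_candidates[which.max(min_mean)]
  structure(list(k_values = k_candidates,
                 per_cluster_jaccard = per_k,
                 selected_k = selected_k,
                 n_bootstrap = n_bootstrap,
                 stable = lapply(per_k, function(x) x > stable_threshold)),
            class = "stability_profile")
}

#' @export
print.stability_profile <- function(x, ...) {
  cat("Bootstrap Jaccard stability (", x$n_bootstrap, " resamples)\n",
      sep = "")
  for (i in seq_along(x$k_values))
    cat("  k =", x$k_values[i], ": ",
        paste(sprintf("%.3f", x$per_cluster_jaccard[[i]]), collapse = " "),
        "\n")
  cat("selected k =", x$selected_k, "\n")
  invisible(x)
}

#' Order clusters by clinical severity and relabel M, S1, ..., S(k-1)
#'
#' Clusters are ranked by the mean of a supplied per-sample severity
#' column when present, otherwise by mean per-sample criterion count. Ties
#' are broken by renal-criterion prevalence, then by original label.
#'
#' @param assignment a `cluster_assignment`.
#' @param criteria samples x criteria 0/1 matrix aligned to the
#'   assignment.
#' @param severity optional numeric per-sample severity score.
#' @return the assignment with `label` renamed M < S1 < ... and a
#'   `severity_order` field.
#' @export
order_clusters_by_severity <- function(assignment, criteria,
                                       severity = NULL) {
  criteria <- unclass(as.matrix(criteria))
  check_alignment(assignment$sample_ids, rownames(criteria),
                  what = "assignment and criteria")
  k <- nrow(assignment$centroids)
  cl <- assignment$cluster
  stat <- if (!is.null(severity)) {
    tapply(severity, cl, mean)
  } else {
    tapply(rowSums(criteria), cl, mean)
  }
  renal_col <- grep("renal", colnames(criteria), ignore.case = TRUE)
  tie2 <- if (length(renal_col)) {
    tapply(criteria[, renal_col[1]], cl, mean)
  } else rep(0, k)
  ord <- order(stat, tie2, as.integer(names(stat)))
  if (anyDuplicated(round(stat, 12)))
    message("order_clusters_by_severity: tie in ordering statistic broken ",
            "by renal prevalence / original label")
  labels <- c("M", paste0("S", seq_len(max(k - 1, 0))))[seq_len(k)]
  new_label <- labels[match(cl, as.integer(names(stat))[ord])]
  assignment$label <- factor(new_label, levels = labels)
  assignment$severity_order <- stats::setNames(labels,
                                               as.integer(names(stat))[ord])
  assignment$cluster <- match(new_label, labels)
  assignment$centroids <- assignment$centroids[as.integer(names(stat))[ord], ,
                                               drop = FALSE]
  rownames(assignment$centroids) <- labels
  assignment
}
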