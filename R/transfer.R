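## Random-forest transfer of discovered cluster labels to an external
## cohort, and validation of CpG associations there.

#' Train a random-forest cluster-label model on ACR criteria
#'
#' Grid search over tree count and features-per-split, selecting the
#' combination minimizing out-of-bag (OOB) error; the full error curve is
#' retained.
#'
#' @param criteria samples x criteria 0/1 matrix.
#' @param labels `cluster_assignment` (or factor) for the same samples.
#' @param param_grid list with `ntree` and `mtry` vectors; the default
#'   grid is ntree in \{250, 500, 1000\} and mtry in
#'   \{sqrt(p), p/3, p\}.
#' @param seed integer seed.
#' @return `transfer_model`: list with `forest` (the selected
#'   randomForest), `oob_error_curve`, `selected_params`, `classes`,
#'   `features`.
#' @export
train_cluster_model <- function(criteria, labels, param_grid = NULL,
                                seed = 1L) {
  X <- as.data.frame(unclass(as.matrix(criteria)))
  y <- if (inherits(labels, "cluster_assignment")) factor(labels$label)
       else factor(labels)
  if (nlevels(droplevels(y)) < 2)
    stop("labels contain a single class", call. = FALSE)
  y <- droplevels(y)
  p <- ncol(X)
  if (is.null(param_grid))
    param_grid <- list(ntree = c(250, 500, 1000),
                       mtry = unique(pmax(1, round(c(sqrt(p), p / 3, p)))))
  grid <- expand.grid(ntree = param_grid$ntree, mtry = param_grid$mtry)
  curve <- numeric(nrow(grid))
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    set.seed(child_seed(seed, 1013L + i))
    fits[[i]] <- randomForest::randomForest(
      x = X, y = y, ntree = grid$ntree[i], mtry = grid$mtry[i])
    curve[i] <- fits[[i]]$err.rate[grid$ntree[i], "OOB"]
  }
  best <- which.min(curve)
  structure(list(forest = fits[[best]],
                 oob_error_curve = cbind(grid, oob_error = curve),
                 selected_params = grid[best, ],
                 oob_error = curve[best],
                 classes = levels(y),
                 features = colnames(X)),
            class = "transfer_model")
}

#' @export
print.transfer_model <- function(x, ...) {
  cat("Random-forest cluster-label model:", length(x$features),
      "criteria,", length(x$classes), "classes\n")
  cat(sprintf("selected ntree=%d mtry=%d, OOB error %.3f\n",
              x$selected_params$ntree, x$selected_params$mtry,
              x$oob_error))
  invisible(x)
}

#' Transfer cluster labels to an external cohort
#'
#' Predicts a cluster label (plus class-vote fractions) for every external
#' sample. Criteria are aligned by column name; a missing criterion is an
#' error.
#'
#' @param model a `transfer_model`.
#' @param external_criteria samples x criteria 0/1 matrix, dichotomized
#'   identically to the training data.
#' @return `cluster_assignment` with `votes` (samples x classes matrix).
#' @export
transfer_labels <- function(model, external_criteria) {
  X <- as.data.frame(unclass(as.matrix(external_criteria)))
  miss <- setdiff(model$features, colnames(X))
  if (length(miss))
    stop("external criteria lack column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  X <- X[, model$features, drop = FALSE]
  pred <- stats::predict(model$forest, X, type = "response")
  votes <- stats::predict(model$forest, X, type = "vote")
  structure(list(sample_ids = rownames(external_criteria),
                 cluster = as.integer(pred),
                 label = factor(as.character(pred), levels = model$classes),
                 centroids = matrix(NA_real_, length(model$classes), 0,
                                    dimnames = list(model$classes, NULL)),
                 votes = votes),
            class = "cluster_assignment")
}

#' Validate discovery CpG associations in an external cohort
#'
#' Re-runs the per-CpG cluster ANOVA in the external cohort (with its
#' reduced covariate set) on the CpGs present on the external platform,
#' and correlates the external covariate-adjusted pairwise delta-beta
#' against the discovery values per contrast.
#'
#' @param external_beta CpGs x samples beta matrix of the external cohort.
#' @param labels transferred `cluster_assignment`.
#' @param external_covariates covariate table for the external cohort
#'   (typically sex, age, ancestry and cell components only).
#' @param cpg_list discovery CpGs to validate (intersected with the
#'   external platform's rows).
#' @param discovery_contrasts long contrast table from
#'   [pairwise_contrasts()] on the discovery cohort (cpg_id, contrast,
#'   delta_beta).
#' @param fdr validation FDR (0.1).
#' @return list with `validation` (per-CpG table), `validated_fraction`,
#'   and `delta_correlation` (per contrast Pearson r).
#' @export
validate_cpgs <- function(external_beta, labels, external_covariates,
                          cpg_list, discovery_contrasts = NULL, fdr = 0.1) {
  present <- intersect(cpg_list, rownames(external_beta))
  if (!length(present))
    stop("no overlapping CpGs between discovery list and external platform",
         call. = FALSE)
  B <- as.matrix(external_beta)[present, , drop = FALSE]
  res <- cluster_anova(B, labels, external_covariates,
                       fdr_threshold = fdr)
  out <- list(validation = res,
              n_tested = length(present),
              validated_fraction = mean(res$q < fdr))
  if (!is.null(discovery_contrasts)) {
    ext_con <- pairwise_contrasts(present, B, labels, external_covariates,
                                  fdr_threshold = fdr)
    r <- vapply(unique(ext_con$contrast), function(con) {
      e <- ext_con[ext_con$contrast == con, ]
      d <- discovery_contrasts[discovery_contrasts$contrast == con, ]
      m <- match(e$cpg_id, d$cpg_id)
      if (sum(!is.na(m)) < 3) return(NA_real_)
      stats::cor(e$delta_beta[!is.na(m)], d$delta_beta[m[!is.na(m)]])
    }, numeric(1))
    out$delta_correlation <- r
    out$external_contrasts <- ext_con
  }
  out
}
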