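## End-to-end pipeline runner: synthetic cohort (optional) -> phenotypic
## clustering -> covariate construction -> differential methylation ->
## cis-meQTL -> mediation (CIT) -> enrichment -> external transfer.
## Every stage writes TSV/JSON artifacts plus a manifest of versions,
## seeds and file hashes; a rerun with the same configuration is
## bit-identical.

#' Pipeline configuration
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param sim a [sim_config()] for the synthetic cohort (its seed is
#'   overridden by `seed`).
#' @param stages character vector of enabled stages, in order, among
#'   simulate, cluster, covariates, dm, meqtl, cit, enrichment, transfer.
#' @param k_min,k_max candidate cluster-count range.
#' @param n_bootstrap bootstrap resamples for stability.
#' @param dm_fdr,meqtl_fdr,cit_fdr stagewise FDR thresholds.
#' @param cis_window cis window in bp (strict "<").
#' @param maf_min,hwe_alpha,r2_max genotype QC thresholds.
#' @param n_perm permutations for the ethnicity enrichment.
#' @param cit_n_perm permutations for CIT component 4.
#' @param refactor_k,refactor_t cell-surrogate parameters.
#' @param restrict_meqtl_to_hits scan only cluster-associated CpGs (the
#'   default) or all CpGs.
#' @param platform_overlap_frac fraction of CpGs treated as present on
#'   the external platform in simulate mode.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(seed = seed),
                            stages = c("simulate", "cluster", "covariates",
                                       "dm", "meqtl", "cit", "enrichment",
                                       "transfer"),
                            k_min = 2, k_max = 4,
                            n_bootstrap = 50,
                            dm_fdr = 0.1, meqtl_fdr = 0.05, cit_fdr = 0.05,
                            cis_window = 1e6,
                            maf_min = 0.05, hwe_alpha = 1e-4, r2_max = 0.8,
                            n_perm = 200, cit_n_perm = 500,
                            refactor_k = 4, refactor_t = 500,
                            restrict_meqtl_to_hits = TRUE,
                            platform_overlap_frac = 0.6) {
  cfg <- as.list(environment())
  stopifnot(dm_fdr > 0, dm_fdr < 1, meqtl_fdr > 0, meqtl_fdr < 1,
            cit_fdr > 0, cit_fdr < 1, cis_window > 0,
            maf_min >= 0, maf_min < 0.5, r2_max > 0, r2_max <= 1,
            k_min >= 2, k_max >= k_min, n_perm >= 1)
  if (identical(cfg$sim$effect_seed, cfg$sim$seed))
    cfg$sim$effect_seed <- seed
  cfg$sim$seed <- seed
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields of the YAML override [pipeline_config()] defaults;
#' entries under `sim:` override [sim_config()] defaults.
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  y$sim <- NULL
  base_seed <- y$seed %||% 1L
  sim <- do.call(sim_config, c(sim_args, list(seed = base_seed)))
  do.call(pipeline_config, c(y, list(sim = sim)))
}

stage_log <- function(stage, n_in, n_out, t0) {
  message(sprintf("[%s] n_in=%s n_out=%s elapsed=%.1fs", stage,
                  n_in, n_out, as.numeric(Sys.time()) - t0))
}

#' Run the full integrative subtyping pipeline
#'
#' Executes the enabled stages in order and writes per-stage artifacts
#' under `out_dir`, plus `manifest.json` listing the package version, the
#' seeds used, and an md5 hash of every artifact. A stage whose inputs
#' were produced by a disabled stage raises an error naming both stages.
#'
#' @param config a [pipeline_config()].
#' @param out_dir artifact directory (created).
#' @param cohort optionally, a pre-built `sle_cohort` to use instead of
#'   the simulate stage.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- config$stages
  need <- function(stage, from, what) {
    if (is.null(what))
      stop("stage '", stage, "' requires output of disabled stage '", from,
           "'", call. = FALSE)
    what
  }
  res <- list()
  seed <- config$seed

  if ("simulate" %in% st) {
    t0 <- as.numeric(Sys.time())
    cohort <- simulate_cohort(config$sim)
    stage_log("simulate", "-", ncol(cohort$beta), t0)
  }
  if (is.null(cohort) && length(setdiff(st, "simulate")))
    stop("stage '", setdiff(st, "simulate")[1],
         "' requires output of disabled stage 'simulate'", call. = FALSE)
  res$cohort <- cohort

  if ("cluster" %in% st) {
    t0 <- as.numeric(Sys.time())
    crit <- need("cluster", "simulate", cohort$criteria)
    fit <- mca(crit)
    ndim <- select_dimensions(crit, max_dim = 4, n_folds = 3,
                              seed = child_seed(seed, 1L))
    ndim <- max(ndim, 2)   # K-means needs a plane; CV can pick 1 on noise
    coords <- fit$coordinates[, seq_len(ndim), drop = FALSE]
    stab <- bootstrap_stability(coords, config$k_min:config$k_max,
                                n_bootstrap = config$n_bootstrap,
                                seed = child_seed(seed, 2L))
    assign <- kmeans_cluster(coords, stab$selected_k,
                             seed = child_seed(seed, 3L))
    assign <- order_clusters_by_severity(assign, crit,
                                         cohort$covariates$severity_index)
    res$mca <- fit; res$stability <- stab; res$assignment <- assign
    res$n_dimensions <- ndim
    write_tsv(data.frame(sample_id = assign$sample_ids,
                         cluster_label = as.character(assign$label)),
              file.path(out_dir, "cluster_assignment.tsv"))
    jsonlite::write_json(
      list(k_values = stab$k_values,
           per_cluster_jaccard = stab$per_cluster_jaccard,
           selected_k = stab$selected_k,
           n_bootstrap = stab$n_bootstrap,
           n_dimensions = ndim),
      file.path(out_dir, "stability.json"), auto_unbox = TRUE, digits = NA)
    stage_log("cluster", nrow(crit), stab$selected_k, t0)
  }

  if ("covariates" %in% st) {
    t0 <- as.numeric(Sys.time())
    med_cols <- grep("^med", names(cohort$covariates), value = TRUE)
    med <- as.matrix(cohort$covariates[, med_cols, drop = FALSE])
    medpc <- medication_pca(med, seed = child_seed(seed, 4L))
    rownames(medpc) <- cohort$covariates$sample_id
    qc <- genotype_qc(cohort$genotypes, cohort$snp_info,
                      maf_min = config$maf_min,
                      hwe_alpha = config$hwe_alpha)
    anc <- ancestry_pcs(qc$genotypes, 3)
    cell <- refactor_components(cohort$beta, k = config$refactor_k,
                                t = config$refactor_t)
    covs <- build_covariates(cohort$covariates, medpc, anc, cell)
    res$covariates <- covs
    res$genotypes_qc <- qc
    write_tsv(covs, file.path(out_dir, "covariates_model.tsv"))
    stage_log("covariates", ncol(cohort$beta), ncol(covs) - 1, t0)
  }

  if ("dm" %in% st) {
    t0 <- as.numeric(Sys.time())
    covs <- need("dm", "covariates", res$covariates)
    assign <- need("dm", "cluster", res$assignment)
    filt <- filter_probes(cohort$beta, cohort$manifest)
    dm <- cluster_anova(filt$beta, assign, covs,
                        fdr_threshold = config$dm_fdr)
    res$hit_cpgs <- dm$cpg_id[dm$significant]
    if (!length(res$hit_cpgs)) {
      message("[dm] no CpG significant at FDR ", config$dm_fdr,
              "; downstream stages use the top 50 by p-value")
      res$hit_cpgs <- dm$cpg_id[order(dm$p)][1:min(50, nrow(dm))]
    }
    contr <- pairwise_contrasts(res$hit_cpgs, filt$beta, assign, covs,
                                fdr_threshold = config$dm_fdr)
    infl <- inflation_lambda(dm$p[!dm$zero_variance])
    res$filtered <- filt; res$dm <- dm; res$contrasts <- contr
    res$lambda <- infl$lambda
    write_tsv(dm, file.path(out_dir, "dm_associations.tsv"))
    write_tsv(contr, file.path(out_dir, "dm_contrasts.tsv"))
    ps <- sort(dm$p[!dm$zero_variance])
    write_tsv(data.frame(expected = -log10(stats::ppoints(length(ps))),
                         observed = -log10(ps)),
              file.path(out_dir, "dm_qq.tsv"))
    jsonlite::write_json(list(lambda = infl$lambda,
                              n_significant = sum(dm$significant)),
                         file.path(out_dir, "dm_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    stage_log("dm", nrow(filt$beta), sum(dm$significant), t0)
  }

  if ("meqtl" %in% st) {
    t0 <- as.numeric(Sys.time())
    qc <- need("meqtl", "covariates", res$genotypes_qc)
    dm <- need("meqtl", "dm", res$dm)
    covs <- res$covariates
    ord <- order(factor(qc$snp_info$chrom,
                        levels = unique(qc$snp_info$chrom)),
                 qc$snp_info$pos)
    info <- qc$snp_info[ord, ]
    geno <- qc$genotypes[ord, , drop = FALSE]
    kept <- ld_prune(geno, info, r2_max = config$r2_max)
    geno <- geno[kept, , drop = FALSE]
    info <- info[match(kept, info$snp_id), ]
    hit_cpgs <- if (config$restrict_meqtl_to_hits)
      res$hit_cpgs else dm$cpg_id
    mf <- res$filtered$manifest
    cpg_pos <- mf[mf$cpg_id %in% hit_cpgs, c("cpg_id", "chrom", "pos")]
    pairs <- map_cis_pairs(info[, c("snp_id", "chrom", "pos")], cpg_pos,
                           window_bp = config$cis_window)
    mq <- fit_meqtl(res$filtered$beta, geno, covs, pairs,
                    fdr = config$meqtl_fdr)
    res$meqtl <- mq
    res$meqtl_genotypes <- geno
    write_tsv(mq, file.path(out_dir, "meqtl.tsv"))
    if (nrow(mq)) {
      decay <- distance_decay(mq, seq(0, config$cis_window, length.out = 6))
      write_tsv(decay, file.path(out_dir, "meqtl_distance_decay.tsv"))
    }
    stage_log("meqtl", nrow(pairs), sum(mq$significant), t0)
  }

  if ("cit" %in% st) {
    t0 <- as.numeric(Sys.time())
    mq <- need("cit", "meqtl", res$meqtl)
    sig <- mq[mq$significant, ]
    cit <- screen_mediation(sig, res$filtered$beta, res$meqtl_genotypes,
                            res$assignment, res$covariates,
                            fdr = config$cit_fdr,
                            n_perm = config$cit_n_perm,
                            seed = child_seed(seed, 5L))
    res$cit <- cit
    write_tsv(cit, file.path(out_dir, "cit.tsv"))
    stage_log("cit", nrow(sig), sum(cit$mediation), t0)
  }

  if ("enrichment" %in% st) {
    t0 <- as.numeric(Sys.time())
    dm <- need("enrichment", "dm", res$dm)
    mf <- res$filtered$manifest
    hit_cpgs <- res$hit_cpgs
    hit_genes <- unique(mf$gene[mf$cpg_id %in% hit_cpgs])
    universe <- unique(mf$gene)
    ## reference gene set: in simulate mode, the genes of the first half
    ## of the planted cluster CpGs (a synthetic stand-in for a curated
    ## pathway set)
    gs <- unique(mf$gene[mf$cpg_id %in%
                           utils::head(cohort$truth$cluster_cpgs,
                                       length(cohort$truth$cluster_cpgs) %/% 2)])
    hg <- hypergeom_enrichment(hit_genes, gs, universe)
    eth <- ethnicity_permutation_enrichment(
      res$filtered$beta, cohort$covariates$ethnicity, res$covariates,
      hit_cpgs, n_perm = config$n_perm, seed = child_seed(seed, 6L))
    res$hypergeom <- hg; res$ethnicity_enrichment <- eth
    jsonlite::write_json(
      list(gene_set = hg,
           ethnicity = list(n_cluster = eth$n_cluster,
                            n_race_observed = eth$n_race_observed,
                            enrichment_statistic = eth$enrichment_statistic,
                            p_perm = eth$p_perm,
                            null_counts = eth$null_counts)),
      file.path(out_dir, "enrichment.json"), auto_unbox = TRUE, digits = NA)
    stage_log("enrichment", length(hit_cpgs), eth$n_race_observed, t0)
  }

  if ("transfer" %in% st) {
    t0 <- as.numeric(Sys.time())
    assign <- need("transfer", "cluster", res$assignment)
    model <- train_cluster_model(cohort$criteria, assign,
                                 param_grid = list(ntree = c(250, 500),
                                                   mtry = c(4, 6)),
                                 seed = child_seed(seed, 7L))
    ext_cfg <- config$sim
    ext_cfg$seed <- child_seed(seed, 8L)
    external <- simulate_cohort(ext_cfg)
    ext_labels <- transfer_labels(model, external$criteria)
    ## platform intersection: deterministic subset of CpGs
    hit_cpgs <- res$hit_cpgs
    n_keep <- ceiling(length(hit_cpgs) * config$platform_overlap_frac)
    platform <- utils::head(hit_cpgs, n_keep)
    ext_covs <- build_covariates(
      external$covariates,
      ancestry = ancestry_pcs(external$genotypes, 3),
      cell = refactor_components(external$beta, k = config$refactor_k,
                                 t = config$refactor_t))
    val <- validate_cpgs(external$beta, ext_labels, ext_covs, platform,
                         discovery_contrasts = res$contrasts,
                         fdr = config$dm_fdr)
    res$transfer_model <- model; res$external_labels <- ext_labels
    res$validation <- val
    write_tsv(data.frame(sample_id = ext_labels$sample_ids,
                         cluster_label = as.character(ext_labels$label),
                         ext_labels$votes),
              file.path(out_dir, "transfer_predictions.tsv"))
    jsonlite::write_json(
      list(oob_error = model$oob_error,
           selected_params = as.list(model$selected_params),
           validated_fraction = val$validated_fraction,
           delta_correlation = as.list(val$delta_correlation)),
      file.path(out_dir, "transfer_summary.json"), auto_unbox = TRUE,
      digits = NA)
    stage_log("transfer", length(ext_labels$sample_ids),
              val$n_tested, t0)
  }

  arts <- setdiff(list.files(out_dir, full.names = TRUE),
                  file.path(out_dir, "manifest.json"))
  hashes <- tools::md5sum(sort(arts))
  names(hashes) <- basename(names(hashes))
  manifest <- list(
    package = "sleclust",
    version = as.character(utils::packageVersion("sleclust")),
    seed = seed,
    stages = st,
    thresholds = config[c("dm_fdr", "meqtl_fdr", "cit_fdr", "cis_window",
                          "maf_min", "hwe_alpha", "r2_max", "n_perm")],
    artifacts = as.list(hashes))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
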