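## Synthetic multi-ethnic SLE cohort generator.
##
## Emulates the statistical structure the downstream pipeline assumes:
## latent clinical clusters with cluster-specific ACR-criterion prevalences,
## CpGs with cluster-dependent beta shifts, cis SNPs controlling a subset of
## those CpGs, genotype->methylation->cluster mediation triplets under
## causal/reactive/independent generative graphs, ethnicity labels correlated
## with cluster severity and with a subset of CpGs independently of genotype,
## latent cell-composition factors, and medication use correlated with
## cluster. All methylation is generated on the logit scale and
## inverse-transformed so beta values are strictly inside (0, 1).

#' Default cluster-by-criterion prevalence matrix
#'
#' Prevalences (proportions) of 18 ACR classification criteria and
#' sub-criteria in three clinical clusters of increasing severity
#' (M = mild, S1, S2), patterned on a published multi-ethnic SLE cohort.
#'
#' @return a 3 x 18 numeric matrix of probabilities, rows M/S1/S2.
#' @export
default_criterion_prevalence <- function() {
  crit <- c("malar_rash", "discoid_rash", "oral_ulcers", "arthritis",
            "pleuritis", "pericarditis", "seizure", "psychosis",
            "anti_dsdna", "anti_smith", "ana", "hemolytic_anemia",
            "leukopenia", "lymphopenia", "thrombocytopenia", "renal",
            "photosensitivity", "apla")
  m <- rbind(
    M  = c(68.3, 14.9, 70.3, 93.1, 48.0, 13.0,  8.0, 5.0, 35.6,  9.9,
           89.1,  1.0,  4.0, 19.8,  8.9, 15.8, 73.3, 25.7),
    S1 = c(20.8,  5.2, 26.6, 66.2, 17.5, 13.6,  4.5, 0.6, 76.0, 27.9,
           98.7,  8.5, 11.7, 16.9, 13.0, 62.3, 18.2, 32.5),
    S2 = c(62.8, 20.5, 48.7, 88.5, 38.5, 35.9,  9.0, 9.0, 92.3, 57.7,
           98.7, 15.4, 65.4, 76.9, 34.6, 57.7, 41.0, 42.3)
  ) / 100
  colnames(m) <- crit
  m
}

default_ethnicity_groups <- function() {
  list(
    labels = c("White", "Hispanic", "AfricanAmerican", "Asian", "Other"),
    proportions = c(0.29, 0.23, 0.11, 0.35, 0.02),
    # severity offsets on the latent cluster-propensity scale; negative =
    # milder. Calibrated so White patients concentrate in the mild cluster
    # and Asian patients in the severe clusters.
    severity_offset = c(-0.6, 0.1, 0.0, 0.35, -0.2)
  )
}

#' Simulation configuration for a synthetic SLE cohort
#'
#' Collects every knob of the generator with defaults that mirror the study
#' conditions of the motivating cohort (333 patients split 101/154/78 over
#' three severity-ordered clusters, 18 binary ACR criteria with
#' cluster-specific prevalences, beta-scale cluster shifts of 0.05,
#' per-allele cis-meQTL effects of 0.05).
#'
#' @param n_samples cohort size.
#' @param n_clusters number of latent clinical clusters.
#' @param cluster_proportions simplex vector of cluster sizes.
#' @param criterion_prevalence cluster x criterion probability matrix.
#' @param n_cpgs total CpGs simulated.
#' @param n_cluster_cpgs CpGs carrying a cluster-dependent mean shift.
#' @param delta_beta per-cluster beta-scale mean shifts (length
#'   `n_clusters`); each cluster CpG gets a random sign.
#' @param n_snps total SNPs simulated.
#' @param maf_range minor-allele-frequency interval for simulated SNPs.
#' @param n_meqtl number of plain cis-meQTL pairs planted on cluster CpGs.
#' @param meqtl_effect per-minor-allele beta-scale shift at meQTL CpGs.
#' @param mediation_scenarios named counts of planted
#'   causal/reactive/independent genotype-methylation-cluster triplets.
#' @param mediation_effects named list: `gm` per-allele beta shift on the
#'   mediator CpG, `my` propensity weight per SD of mediator methylation,
#'   `gy` direct per-allele propensity weight (reactive/independent arms).
#' @param n_cell_factors latent cell-composition-like factors.
#' @param n_cell_cpgs CpGs loading on the cell factors.
#' @param cell_effect SD of beta-scale cell-factor loadings.
#' @param ethnicity_groups list with `labels`, marginal `proportions` and
#'   `severity_offset` per group (offsets induce the cluster-conditional
#'   ethnicity mix).
#' @param n_ethnic_cpgs CpGs with non-genetic ethnicity-dependent shifts.
#' @param ethnic_overlap fraction of ethnic CpGs drawn from the cluster-CpG
#'   set.
#' @param ethnic_effect SD of per-group beta-scale ethnic shifts.
#' @param n_meds binary medication columns; usage of the first half is
#'   correlated with cluster severity.
#' @param n_med_cpgs CpGs shifted by use of the first medication.
#' @param med_effect beta-scale shift for medication-driven CpGs.
#' @param fst Balding-Nichols divergence of per-ethnicity allele
#'   frequencies around the global MAF.
#' @param noise_sd beta-scale residual SD of methylation.
#' @param miss_rate genotype missingness rate.
#' @param seed integer seed for the sampling layer (which patients are
#'   drawn); all sample-level randomness fans out from it.
#' @param effect_seed integer seed for the biology layer (coordinates,
#'   allele frequencies, base methylation levels, effect directions and
#'   loadings). Defaults to `seed`; give two cohorts the same
#'   `effect_seed` and different `seed` to emulate a replication cohort
#'   measuring the same biology in new patients.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 333,
                       n_clusters = 3,
                       cluster_proportions = c(101, 154, 78) / 333,
                       criterion_prevalence = default_criterion_prevalence(),
                       n_cpgs = 20000,
                       n_cluster_cpgs = 256,
                       delta_beta = c(0.05, 0, -0.05),
                       n_snps = 1000,
                       maf_range = c(0.05, 0.5),
                       n_meqtl = 50,
                       meqtl_effect = 0.05,
                       mediation_scenarios = c(causal = 5, reactive = 5,
                                               independent = 5),
                       mediation_effects = list(gm = 0.05, my = 2, gy = 0.6),
                       n_cell_factors = 2,
                       n_cell_cpgs = 2000,
                       cell_effect = 0.08,
                       ethnicity_groups = default_ethnicity_groups(),
                       n_ethnic_cpgs = 200,
                       ethnic_overlap = 0.8,
                       ethnic_effect = 0.05,
                       n_meds = 8,
                       n_med_cpgs = 20,
                       med_effect = 0.05,
                       fst = 0.02,
                       noise_sd = 0.03,
                       miss_rate = 0,
                       seed = 1L,
                       effect_seed = NULL) {
  cfg <- as.list(environment())
  if (is.null(cfg$effect_seed)) cfg$effect_seed <- cfg$seed
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stop_field <- function(field, msg) {
    stop("invalid simulation configuration: field '", field, "' ", msg,
         call. = FALSE)
  }
  if (cfg$n_samples < 1) stop_field("n_samples", "must be positive")
  if (cfg$n_clusters < 1) stop_field("n_clusters", "must be positive")
  if (length(cfg$cluster_proportions) != cfg$n_clusters)
    stop_field("cluster_proportions", "length must equal n_clusters")
  if (abs(sum(cfg$cluster_proportions) - 1) > 1e-12)
    stop_field("cluster_proportions", "must sum to 1")
  if (any(cfg$cluster_proportions < 0))
    stop_field("cluster_proportions", "must be non-negative")
  pv <- cfg$criterion_prevalence
  if (!is.matrix(pv) || nrow(pv) != cfg$n_clusters)
    stop_field("criterion_prevalence", "must be a cluster x criterion matrix")
  if (any(pv < 0 | pv > 1))
    stop_field("criterion_prevalence", "entries must be probabilities")
  if (cfg$n_cluster_cpgs > cfg$n_cpgs)
    stop_field("n_cluster_cpgs", "cannot exceed n_cpgs")
  if (length(cfg$delta_beta) != cfg$n_clusters)
    stop_field("delta_beta", "length must equal n_clusters")
  if (any(abs(cfg$delta_beta) >= 0.5))
    stop_field("delta_beta", "shifts must stay well inside (0,1)")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stop_field("maf_range", "must be an interval inside (0, 0.5]")
  n_trip <- sum(cfg$mediation_scenarios)
  if (cfg$n_meqtl + n_trip > cfg$n_snps)
    stop_field("n_snps", "too small for planted meQTLs and triplets")
  if (cfg$n_meqtl > cfg$n_cluster_cpgs)
    stop_field("n_meqtl", "cannot exceed n_cluster_cpgs")
  if (cfg$n_cluster_cpgs + n_trip + cfg$n_med_cpgs > cfg$n_cpgs)
    stop_field("n_cpgs", "too small for planted CpG classes")
  if (cfg$n_cell_factors < 0)
    stop_field("n_cell_factors", "must be non-negative")
  if (cfg$noise_sd <= 0) stop_field("noise_sd", "must be positive")
  eg <- cfg$ethnicity_groups
  if (length(eg$labels) != length(eg$proportions) ||
      length(eg$labels) != length(eg$severity_offset))
    stop_field("ethnicity_groups", "labels/proportions/offsets must align")
  invisible(TRUE)
}

## ranked cut of a continuous propensity into clusters of exact sizes;
## higher propensity -> more severe cluster.
cut_by_rank <- function(propensity, proportions) {
  n <- length(propensity)
  sizes <- diff(round(cumsum(c(0, proportions)) * n))
  sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])
  cl <- integer(n)
  ord <- order(propensity)
  cl[ord] <- rep.int(seq_along(sizes), sizes)
  cl
}

#' Simulate a fully labelled synthetic SLE cohort
#'
#' Generative order: ethnicity -> genotypes (Balding-Nichols allele
#' frequencies per ethnic group, Hardy-Weinberg within group) -> mediator
#' CpG methylation -> latent severity propensity (mediator methylation,
#' direct genetic effects, ethnicity offsets, noise) -> cluster labels
#' (rank-cut to exact proportions) -> ACR criteria (Bernoulli with
#' cluster-specific prevalence) -> medications, cell factors, covariates ->
#' full methylation matrix (base level + cluster shift + meQTL allele
#' effect + ethnic shift + cell-factor term + medication term + noise, all
#' composed on the logit scale).
#'
#' @param config a [sim_config()].
#' @return an object of class `sle_cohort`: list with `criteria`
#'   (samples x criteria 0/1 matrix), `beta` (CpGs x samples), `manifest`
#'   (cpg_id, chrom, pos, gene, region), `genotypes` (SNPs x samples
#'   dosages), `snp_info`, `covariates` (incl. medications and a
#'   severity-index column), and `truth` (ground-truth labels and planted
#'   feature sets).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  cfg <- config
  n <- cfg$n_samples
  K <- cfg$n_clusters
  sample_ids <- sprintf("S%04d", seq_len(n))

  eg <- cfg$ethnicity_groups
  n_trip <- sum(cfg$mediation_scenarios)
  scen <- rep(names(cfg$mediation_scenarios), cfg$mediation_scenarios)

  ## --- ethnicity ------------------------------------------------------
  set.seed(child_seed(cfg$seed, 11L))
  ethnicity <- sample(eg$labels, n, replace = TRUE,
                      prob = eg$proportions / sum(eg$proportions))
  eth_idx <- match(ethnicity, eg$labels)

  ## --- population allele frequencies (biology layer) ------------------
  set.seed(child_seed(cfg$effect_seed, 23L))
  p_global <- stats::runif(cfg$n_snps, cfg$maf_range[1], cfg$maf_range[2])
  ## planted meQTL / mediation SNPs sit on common variants so every
  ## planted effect is tested at comparable power
  n_planted <- cfg$n_meqtl + n_trip
  if (n_planted)
    p_global[seq_len(n_planted)] <-
      stats::runif(n_planted, max(0.2, cfg$maf_range[1]),
                   min(0.4, cfg$maf_range[2]))
  if (cfg$fst > 0) {
    a <- p_global * (1 - cfg$fst) / cfg$fst
    b <- (1 - p_global) * (1 - cfg$fst) / cfg$fst
    p_group <- vapply(seq_along(eg$labels), function(g)
      stats::rbeta(cfg$n_snps, a, b), numeric(cfg$n_snps))
  } else {
    p_group <- matrix(p_global, cfg$n_snps, length(eg$labels))
  }
  p_group <- pmin(pmax(p_group, 1e-4), 1 - 1e-4)

  ## --- genotype draws (sampling layer) ---------------------------------
  set.seed(child_seed(cfg$seed, 29L))
  G <- matrix(NA_real_, cfg$n_snps, n)
  for (g in seq_along(eg$labels)) {
    idx <- which(eth_idx == g)
    if (length(idx))
      G[, idx] <- stats::rbinom(cfg$n_snps * length(idx), 2L,
                                rep(p_group[, g], length(idx)))
  }
  if (cfg$miss_rate > 0) {
    drop <- stats::runif(length(G)) < cfg$miss_rate
    G[drop] <- NA_real_
  }
  snp_ids <- sprintf("rs%06d", seq_len(cfg$n_snps))
  rownames(G) <- snp_ids; colnames(G) <- sample_ids

  ## --- CpG layout and coordinates -------------------------------------
  ## index blocks: [cluster CpGs][triplet CpGs][medication CpGs][background]
  cpg_ids <- sprintf("cg%07d", seq_len(cfg$n_cpgs))
  idx_cluster <- seq_len(cfg$n_cluster_cpgs)
  idx_trip <- if (n_trip) cfg$n_cluster_cpgs + seq_len(n_trip) else integer(0)
  idx_med <- if (cfg$n_med_cpgs)
    cfg$n_cluster_cpgs + n_trip + seq_len(cfg$n_med_cpgs) else integer(0)

  set.seed(child_seed(cfg$effect_seed, 31L))
  chrom <- sample(paste0("chr", 1:22), cfg$n_cpgs, replace = TRUE)
  pos <- sample.int(240e6, cfg$n_cpgs, replace = TRUE)
  gene <- paste0("GENE", sprintf("%05d", ceiling(seq_len(cfg$n_cpgs) / 3)))
  region <- sample(c("TSS200", "TSS1500", "5UTR", "Body", "3UTR"),
                   cfg$n_cpgs, replace = TRUE)
  manifest <- data.frame(cpg_id = cpg_ids, chrom = chrom, pos = pos,
                         gene = gene, region = region,
                         stringsAsFactors = FALSE)

  ## cis SNPs: meQTL SNPs sit next to the first n_meqtl cluster CpGs,
  ## triplet SNPs next to their triplet CpGs; the rest are background.
  idx_meqtl_snp <- if (cfg$n_meqtl) seq_len(cfg$n_meqtl) else integer(0)
  idx_trip_snp <- if (n_trip) cfg$n_meqtl + seq_len(n_trip) else integer(0)
  snp_chrom <- sample(paste0("chr", 1:22), cfg$n_snps, replace = TRUE)
  snp_pos <- sample.int(240e6, cfg$n_snps, replace = TRUE)
  cis_of <- function(cpg_i) {
    off <- sample(c(-1, 1), length(cpg_i), replace = TRUE) *
      sample.int(100000L, length(cpg_i), replace = TRUE)
    list(chrom = manifest$chrom[cpg_i],
         pos = pmax(1L, manifest$pos[cpg_i] + off))
  }
  if (length(idx_meqtl_snp)) {
    cc <- cis_of(idx_cluster[seq_len(cfg$n_meqtl)])
    snp_chrom[idx_meqtl_snp] <- cc$chrom; snp_pos[idx_meqtl_snp] <- cc$pos
  }
  if (length(idx_trip_snp)) {
    cc <- cis_of(idx_trip)
    snp_chrom[idx_trip_snp] <- cc$chrom; snp_pos[idx_trip_snp] <- cc$pos
  }
  snp_info <- data.frame(snp_id = snp_ids, chrom = snp_chrom, pos = snp_pos,
                         ref = "A", alt = "G", maf = p_global,
                         stringsAsFactors = FALSE)

  ## --- per-CpG biology: base levels, effect signs, loadings ------------
  set.seed(child_seed(cfg$effect_seed, 43L))
  me <- cfg$mediation_effects
  base_mu <- stats::runif(cfg$n_cpgs, 0.15, 0.85)
  noise_logit <- logit_scale(cfg$noise_sd, base_mu)
  sgn <- sample(c(-1, 1), cfg$n_cluster_cpgs, replace = TRUE)
  n_cf <- cfg$n_cell_factors
  loadings <- matrix(0, cfg$n_cpgs, max(1, n_cf))
  if (n_cf > 0) {
    ## mediator CpGs stay free of cell loadings so their generative graph
    ## is exactly the labelled scenario
    pool <- setdiff(seq_len(cfg$n_cpgs), idx_trip)
    idx_cell <- sample(pool, min(cfg$n_cell_cpgs, length(pool)))
    loadings[idx_cell, ] <- stats::rnorm(length(idx_cell) * n_cf,
                                         0, cfg$cell_effect)
  }
  n_eth_in <- round(cfg$n_ethnic_cpgs * cfg$ethnic_overlap)
  idx_eth <- c(sample(idx_cluster, min(n_eth_in, length(idx_cluster))),
               sample(setdiff(seq_len(cfg$n_cpgs),
                              c(idx_cluster, idx_trip, idx_med)),
                      max(0, cfg$n_ethnic_cpgs - n_eth_in)))
  eth_shift <- matrix(stats::rnorm(length(idx_eth) * length(eg$labels),
                                   0, cfg$ethnic_effect),
                      length(idx_eth), length(eg$labels))
  idx_age <- sample(setdiff(seq_len(cfg$n_cpgs), idx_trip),
                    round(cfg$n_cpgs * 0.1))

  ## --- mediator methylation and cluster propensity (sampling layer) ----
  set.seed(child_seed(cfg$seed, 47L))
  trip_M_part <- matrix(0, max(1, n_trip), n)  # pre-propensity mediator betas
  propensity <- stats::rnorm(n, 0, 1)
  propensity <- propensity + eg$severity_offset[eth_idx]
  if (n_trip) {
    for (j in seq_len(n_trip)) {
      ci <- idx_trip[j]; si <- idx_trip_snp[j]
      g <- G[si, ]; g[is.na(g)] <- mean(g, na.rm = TRUE)
      if (scen[j] == "causal") {
        lm_ <- logit(base_mu[ci]) +
          logit_scale(me$gm, base_mu[ci]) * g +
          stats::rnorm(n, 0, noise_logit[ci])
        m <- inv_logit(lm_)
        trip_M_part[j, ] <- m
        propensity <- propensity + me$my * as.numeric(scale(m))
      } else if (scen[j] == "independent") {
        lm_ <- logit(base_mu[ci]) +
          logit_scale(me$gm, base_mu[ci]) * g +
          stats::rnorm(n, 0, noise_logit[ci])
        trip_M_part[j, ] <- inv_logit(lm_)
        propensity <- propensity + me$gy * (g - mean(g))
      } else { # reactive: direct G -> Y; M responds to Y later
        propensity <- propensity + me$gy * (g - mean(g))
      }
    }
  }
  true_cluster <- cut_by_rank(propensity, cfg$cluster_proportions)

  ## --- criteria --------------------------------------------------------
  set.seed(child_seed(cfg$seed, 59L))
  pv <- cfg$criterion_prevalence
  n_crit <- ncol(pv)
  criteria <- matrix(stats::rbinom(n * n_crit, 1L,
                                   t(pv[true_cluster, , drop = FALSE])),
                     nrow = n, ncol = n_crit, byrow = TRUE)
  dimnames(criteria) <- list(sample_ids,
                             colnames(pv) %||% paste0("crit", seq_len(n_crit)))

  ## --- covariates ------------------------------------------------------
  set.seed(child_seed(cfg$seed, 71L))
  sex <- stats::rbinom(n, 1L, 0.9)          # 1 = female
  age <- round(stats::rnorm(n, 45, 12))
  smoking <- stats::rbinom(n, 1L, 0.15)
  alcohol <- stats::rbinom(n, 1L, 0.4)
  sev_mu <- c(5.6, 7.39, 7.41)[pmin(true_cluster, 3)]
  severity_index <- stats::rnorm(n, sev_mu, 1.4)
  meds <- matrix(0L, n, cfg$n_meds)
  colnames(meds) <- paste0("med", seq_len(cfg$n_meds))
  sev_z <- as.numeric(scale(true_cluster))
  for (m in seq_len(cfg$n_meds)) {
    slope <- if (m <= ceiling(cfg$n_meds / 2)) 0.9 else 0
    meds[, m] <- stats::rbinom(n, 1L, inv_logit(-1.2 + slope * sev_z))
  }
  covariates <- data.frame(sample_id = sample_ids, sex = sex, age = age,
                           smoking = smoking, alcohol = alcohol,
                           ethnicity = ethnicity,
                           severity_index = severity_index,
                           meds, stringsAsFactors = FALSE)

  ## --- cell factor scores ----------------------------------------------
  set.seed(child_seed(cfg$seed, 83L))
  cell_scores <- matrix(0, n, max(1, n_cf))
  if (n_cf > 0) {
    cell_scores <- matrix(stats::rnorm(n * n_cf), n, n_cf)
    cell_scores[, 1] <- 0.3 * sev_z + sqrt(1 - 0.09) * cell_scores[, 1]
  }

  ## --- methylation matrix ---------------------------------------------
  set.seed(child_seed(cfg$seed, 97L))
  L <- matrix(logit(base_mu), cfg$n_cpgs, n)  # logit-scale accumulator

  ## cluster shifts (per-CpG sign from the biology layer)
  shift_bc <- outer(sgn, cfg$delta_beta[true_cluster])   # beta scale
  L[idx_cluster, ] <- L[idx_cluster, ] +
    shift_bc / (base_mu[idx_cluster] * (1 - base_mu[idx_cluster]))

  ## meQTL allele effects on the first n_meqtl cluster CpGs
  meqtl_pairs <- data.frame(snp_id = character(0), cpg_id = character(0),
                            effect = numeric(0))
  if (cfg$n_meqtl) {
    for (j in seq_len(cfg$n_meqtl)) {
      ci <- idx_cluster[j]; si <- idx_meqtl_snp[j]
      g <- G[si, ]; g[is.na(g)] <- mean(g, na.rm = TRUE)
      L[ci, ] <- L[ci, ] + logit_scale(cfg$meqtl_effect, base_mu[ci]) * g
    }
    meqtl_pairs <- data.frame(snp_id = snp_ids[idx_meqtl_snp],
                              cpg_id = cpg_ids[idx_cluster[seq_len(cfg$n_meqtl)]],
                              effect = cfg$meqtl_effect,
                              stringsAsFactors = FALSE)
  }

  ## triplet CpGs: causal/independent keep their pre-propensity draw;
  ## reactive CpGs respond to the realized cluster.
  if (n_trip) {
    for (j in seq_len(n_trip)) {
      ci <- idx_trip[j]
      if (scen[j] %in% c("causal", "independent")) {
        L[ci, ] <- logit(pmin(pmax(trip_M_part[j, ], 1e-6), 1 - 1e-6))
      } else {
        L[ci, ] <- L[ci, ] +
          logit_scale(me$gm, base_mu[ci]) * sev_z +
          stats::rnorm(n, 0, 0)  # noise added globally below
      }
    }
  }

  ## ethnic CpGs: additive per-group shifts, independent of genotype
  for (k in seq_along(idx_eth)) {
    ci <- idx_eth[k]
    L[ci, ] <- L[ci, ] + logit_scale(eth_shift[k, eth_idx], base_mu[ci])
  }

  ## medication CpGs: shifted by use of med1 only
  if (length(idx_med)) {
    L[idx_med, ] <- L[idx_med, ] +
      outer(logit_scale(cfg$med_effect, base_mu[idx_med]), meds[, 1])
  }

  ## cell-factor term + nuisance age/sex effects + noise
  if (n_cf > 0) {
    L <- L + (loadings %*% t(cell_scores)) /
      (base_mu * (1 - base_mu))
  }
  L[idx_age, ] <- L[idx_age, ] +
    outer(logit_scale(0.0008, base_mu[idx_age]), age - mean(age))
  noise_done <- !(seq_len(cfg$n_cpgs) %in%
                    idx_trip[scen %in% c("causal", "independent")])
  E <- matrix(stats::rnorm(cfg$n_cpgs * n), cfg$n_cpgs, n) * noise_logit
  L[noise_done, ] <- L[noise_done, ] + E[noise_done, ]
  beta <- inv_logit(L)
  rownames(beta) <- cpg_ids; colnames(beta) <- sample_ids

  truth <- list(
    true_cluster = stats::setNames(true_cluster, sample_ids),
    cluster_cpgs = cpg_ids[idx_cluster],
    meqtl_pairs = meqtl_pairs,
    mediation_triplets = if (n_trip)
      data.frame(snp_id = snp_ids[idx_trip_snp], cpg_id = cpg_ids[idx_trip],
                 scenario = scen, stringsAsFactors = FALSE)
      else data.frame(snp_id = character(0), cpg_id = character(0),
                      scenario = character(0)),
    ethnic_cpgs = cpg_ids[idx_eth],
    med_cpgs = cpg_ids[idx_med],
    cell_factor_scores = cell_scores,
    cell_factor_loadings = loadings,
    base_mu = base_mu
  )

  structure(list(criteria = criteria, beta = beta, manifest = manifest,
                 genotypes = G, snp_info = snp_info,
                 covariates = covariates, truth = truth, config = cfg),
            class = "sle_cohort")
}

#' @export
print.sle_cohort <- function(x, ...) {
  cat("Synthetic SLE cohort:", ncol(x$beta), "samples,",
      ncol(x$criteria), "criteria,", nrow(x$beta), "CpGs,",
      nrow(x$genotypes), "SNPs\n")
  cat("cluster sizes:", paste(table(x$truth$true_cluster), collapse = "/"),
      "\n")
  invisible(x)
}

#' Simulate standalone genotype-methylation-outcome triplets
#'
#' Generates (G, M, Y) triplets under three generative graphs: `causal`
#' (G -> M -> Y), `reactive` (G -> Y -> M) and `independent` (G -> M and
#' G -> Y with M and Y conditionally independent given G). Y is returned
#' as an ordinal cluster label (0/1/2) obtained by rank-cutting the
#' continuous outcome.
#'
#' @param n_per_scenario triplets per scenario.
#' @param effects named list of edge coefficients `gm`, `my`, `gy` (on the
#'   standardized latent scale).
#' @param n_samples samples per triplet.
#' @param seed integer seed.
#' @param maf minor allele frequency of G.
#' @param n_levels number of ordinal Y levels.
#' @return list with `triplets` (list of lists with G, M, Y vectors) and
#'   `scenario` labels.
#' @export
simulate_mediation_triplets <- function(n_per_scenario,
                                        effects = list(gm = 0.7, my = 0.7,
                                                       gy = 0.7),
                                        n_samples = 500,
                                        seed = 1L,
                                        maf = 0.3,
                                        n_levels = 3) {
  if (n_per_scenario <= 0 || n_samples <= 0)
    stop("invalid configuration: n_per_scenario and n_samples must be positive",
         call. = FALSE)
  set.seed(child_seed(seed, 131L))
  scen <- rep(c("causal", "reactive", "independent"), each = n_per_scenario)
  ordinalize <- function(y) {
    cut_by_rank(y, rep(1 / n_levels, n_levels)) - 1L
  }
  triplets <- lapply(seq_along(scen), function(i) {
    G <- stats::rbinom(n_samples, 2L, maf)
    gz <- as.numeric(scale(G))
    if (scen[i] == "causal") {
      M <- effects$gm * gz + stats::rnorm(n_samples)
      Y <- ordinalize(effects$my * M + stats::rnorm(n_samples))
    } else if (scen[i] == "reactive") {
      Ylat <- effects$gy * gz + stats::rnorm(n_samples)
      Y <- ordinalize(Ylat)
      M <- effects$my * as.numeric(scale(Y)) + stats::rnorm(n_samples)
    } else {
      M <- effects$gm * gz + stats::rnorm(n_samples)
      Y <- ordinalize(effects$gy * gz + stats::rnorm(n_samples))
    }
    list(G = G, M = M, Y = Y)
  })
  list(triplets = triplets, scenario = scen)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cohort's standard fixture file set
#'
#' Emits criteria TSV, beta-matrix TSV, CpG manifest TSV, genotype dosage
#' TSV plus a VCF v4.2 (GT field, dosages rendered as unphased genotypes),
#' covariates TSV and ground-truth JSON.
#'
#' @param cohort an `sle_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(criteria = file.path(dir, "criteria.tsv"),
             beta = file.path(dir, "beta.tsv"),
             manifest = file.path(dir, "manifest.tsv"),
             dosage = file.path(dir, "dosages.tsv"),
             vcf = file.path(dir, "genotypes.vcf"),
             covariates = file.path(dir, "covariates.tsv"),
             truth = file.path(dir, "truth.json"))
  write_tsv(data.frame(sample_id = rownames(cohort$criteria),
                       cohort$criteria, check.names = FALSE),
            paths["criteria"])
  write_tsv(data.frame(cpg_id = rownames(cohort$beta), cohort$beta,
                       check.names = FALSE), paths["beta"])
  write_tsv(cohort$manifest, paths["manifest"])
  write_tsv(data.frame(snp_id = rownames(cohort$genotypes),
                       cohort$genotypes, check.names = FALSE),
            paths["dosage"])
  write_vcf(cohort$genotypes, cohort$snp_info, paths["vcf"])
  write_tsv(cohort$covariates, paths["covariates"])
  truth <- cohort$truth
  truth$cell_factor_scores <- NULL
  truth$cell_factor_loadings <- NULL
  truth$base_mu <- NULL
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(paths)
}

## minimal VCF v4.2 writer: dosages {0,1,2,NA} -> GT {0/0, 0/1, 1/1, ./.}
write_vcf <- function(genotypes, snp_info, path) {
  gt_map <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(genotypes), ncol(genotypes))
  ok <- !is.na(genotypes)
  gt[ok] <- gt_map[genotypes[ok] + 1L]
  ord <- order(factor(snp_info$chrom, levels = unique(snp_info$chrom)),
               snp_info$pos)
  body <- cbind(snp_info$chrom, snp_info$pos, snp_info$snp_id,
                snp_info$ref, snp_info$alt, ".", "PASS", ".", "GT",
                gt)[ord, , drop = FALSE]
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(genotypes)), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a VCF into a dosage matrix
#'
#' Parses the GT field of a VCF (v4.2) into counted-alt-allele dosages
#' \{0,1,2, NA\} plus a SNP information table.
#'
#' @param path VCF file.
#' @return list with `genotypes` (SNP x sample dosage matrix) and
#'   `snp_info` data frame.
#' @export
read_vcf_dosage <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean == "0/0"] <- 0
  dos[clean %in% c("0/1", "1/0")] <- 1
  dos[clean == "1/1"] <- 2
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  snp_info <- data.frame(snp_id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT, stringsAsFactors = FALSE)
  rownames(dos) <- fix$ID
  list(genotypes = dos, snp_info = snp_info)
}
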