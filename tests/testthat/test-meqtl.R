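test_that("HWE exact test matches full enumeration", {
  expect_equal(hwe_exact_test(5, 4, 1), hwe_oracle(5, 4, 1),
               tolerance = 1e-12)
  # single possible configuration -> p = 1
  expect_equal(hwe_exact_test(10, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 1, 0), 1)
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
  # HWE-consistent large counts give large p, never NaN
  set.seed(1)
  for (i in 1:20) {
    p <- runif(1, 0.1, 0.5); n <- 200
    g <- rbinom(n, 2, p)
    pv <- hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
    expect_false(is.na(pv))
    expect_gt(pv, 1e-4)
  }
})

test_that("genotype QC applies call-rate, MAF and HWE filters in order", {
  n <- 100
  set.seed(2)
  keepers <- matrix(rbinom(3 * n, 2, 0.3), 3, n)
  maf05 <- rbinom(n, 1, 0.5) * 0  # build MAF exactly 0.05: 10 alt alleles
  maf05[1:10] <- 1
  missing6 <- rbinom(n, 2, 0.3); missing6[1:6] <- NA
  mono <- rep(0, n)
  hwe_bad <- rep(c(0, 2), n / 2)  # no heterozygotes at p = 0.5
  G <- rbind(keepers, maf05, missing6, mono, hwe_bad)
  rownames(G) <- paste0("rs", 1:7)
  colnames(G) <- paste0("s", 1:n)
  out <- suppressMessages(genotype_qc(G))
  expect_setequal(rownames(out$genotypes), paste0("rs", 1:3))
  expect_equal(unname(out$removed),
               c(call_rate = 1L, maf = 2L, hwe = 1L), ignore_attr = TRUE)
  # idempotent
  out2 <- suppressMessages(genotype_qc(out$genotypes))
  expect_identical(out2$genotypes, out$genotypes)
  expect_error(suppressMessages(genotype_qc(matrix(0, 2, 10))), "removed")
  expect_error(genotype_qc(matrix(3, 2, 10)), "dosages")
})

test_that("LD pruning removes duplicates and enforces the r2 ceiling", {
  set.seed(3)
  n <- 80
  base <- matrix(rbinom(200 * n, 2, 0.3), 200, n)
  base[2, ] <- base[1, ]                    # r2 = 1 pair
  rownames(base) <- sprintf("rs%03d", 1:200)
  colnames(base) <- paste0("s", 1:n)
  info <- data.frame(snp_id = rownames(base), chrom = "chr1",
                     pos = seq_len(200) * 1000L)
  kept <- ld_prune(base, info, r2_max = 0.8, window = 50, step = 5)
  expect_true("rs001" %in% kept)
  expect_false("rs002" %in% kept)
  # brute-force post-condition within windows
  Gk <- base[kept, ]
  ik <- info[match(kept, info$snp_id), ]
  for (start in seq(1, length(kept) - 1, by = 5)) {
    win <- start:min(start + 49, length(kept))
    if (length(win) < 2) next
    r2 <- cor(t(Gk[win, ]))^2
    expect_lte(max(r2[upper.tri(r2)]), 0.8)
  }
  # independent SNPs all retained
  ind <- matrix(rbinom(30 * n, 2, 0.4), 30, n,
                dimnames = list(sprintf("ri%02d", 1:30), colnames(base)))
  info2 <- data.frame(snp_id = rownames(ind), chrom = "chr2",
                      pos = 1:30 * 500L)
  expect_length(ld_prune(ind, info2), 30)
  expect_error(ld_prune(ind, transform(info2, pos = rev(pos))), "sorted")
})

test_that("cis pairing is strict, chromosome-aware and name-normalized", {
  snp <- data.frame(snp_id = c("a", "b", "c"),
                    chrom = c("chr1", "chr1", "chr2"),
                    pos = c(1000000L, 1L, 1000000L))
  cpg <- data.frame(cpg_id = c("x", "y"),
                    chrom = c("1", "1"),
                    pos = c(1999999L, 1000001L))
  pr <- map_cis_pairs(snp, cpg, window_bp = 1e6)
  key <- paste(pr$snp_id, pr$cpg_id)
  expect_true("a x" %in% key)      # distance 999,999
  expect_false("b x" %in% key)     # distance 1,999,998
  expect_true("a y" %in% key)      # distance 1
  expect_false("b y" %in% key)     # distance exactly 1,000,000: excluded
  expect_false(any(pr$snp_id == "c"))  # other chromosome
  expect_true(all(pr$distance < 1e6))
})

test_that("meQTL fits match a per-pair lm oracle", {
  set.seed(4)
  n <- 12
  covs <- data.frame(sample_id = paste0("s", 1:n), sex = rbinom(n, 1, 0.5),
                     age = rnorm(n, 50, 6), smoke = rbinom(n, 1, 0.3),
                     alcohol = rbinom(n, 1, 0.5))
  G <- matrix(rbinom(3 * n, 2, 0.4), 3, n,
              dimnames = list(paste0("rs", 1:3), covs$sample_id))
  B <- matrix(runif(3 * n, 0.2, 0.8), 3, n,
              dimnames = list(paste0("cg", 1:3), covs$sample_id))
  pairs <- data.frame(snp_id = paste0("rs", 1:3),
                      cpg_id = paste0("cg", 1:3), distance = 100L)
  res <- fit_meqtl(B, G, covs, pairs)
  for (i in 1:3) {
    fit <- summary(lm(B[i, ] ~ G[i, ] + covs$sex + covs$age + covs$smoke +
                        covs$alcohol))
    expect_equal(res$beta[i], fit$coefficients[2, 1], tolerance = 1e-8)
    expect_equal(res$se[i], fit$coefficients[2, 2], tolerance = 1e-8)
    expect_equal(res$p[i], fit$coefficients[2, 4], tolerance = 1e-8)
  }
  # filtered-feature pairs are skipped with a warning
  bad <- rbind(pairs, data.frame(snp_id = "rs9", cpg_id = "cg1",
                                 distance = 1L))
  expect_warning(res2 <- fit_meqtl(B, G, covs, bad), "skipping")
  expect_equal(nrow(res2), 3)
})

test_that("permuted genotypes give near-nominal significant fractions", {
  co <- simulate_cohort(small_sim_config(seed = 16))
  covs <- cohort_covariates(co, cell = "true")
  set.seed(5)
  Gp <- co$genotypes[, sample(ncol(co$genotypes))]
  colnames(Gp) <- colnames(co$genotypes)
  pairs <- data.frame(snp_id = rep(rownames(Gp)[1:100], each = 3),
                      cpg_id = rownames(co$beta)[1:300], distance = 1L)
  res <- fit_meqtl(co$beta, Gp, covs, pairs)
  expect_lt(mean(res$p < 0.05), 0.10)
  expect_lte(sum(res$significant), 3)
})

test_that("distance decay reflects planted proximal effects", {
  res <- data.frame(snp_id = "s", cpg_id = "c",
                    distance = c(5e4, 8e4, 3e5, 6e5, 9e5, 2e5),
                    significant = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  dd <- distance_decay(res, c(0, 1e5, 5e5, 1e6))
  expect_equal(dd$fraction, c(1, 1 / 2, 0))
  # empty bin -> NA, not zero
  dd2 <- distance_decay(res[1:2, ], c(0, 1e5, 5e5))
  expect_true(is.na(dd2$fraction[2]))
  # single bin collapses to the global fraction
  dd3 <- distance_decay(res, c(0, 1e6))
  expect_equal(dd3$fraction, 0.5)
  expect_error(distance_decay(res[0, ], c(0, 1)), "empty")
})
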