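test_that("genotype simulation is deterministic and respects MAF targets", {
  cfg <- small_cfg()
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosages, g2$dosages)
  expect_identical(g1$map, g2$map)

  # forced frequency: all realized MAF ~ 0.5 within 3 binomial SE
  cfg5 <- sim_config(n_samples = 2000, n_variants = 200,
                     maf_range = c(0.5, 0.5), ld_block_size = 1,
                     qtl_spec = list(), missing_rate = 0, seed = 9)
  g5 <- simulate_genotypes(cfg5)
  af <- colMeans(g5$dosages) / 2
  se <- sqrt(0.5 * 0.5 / (2 * 2000))
  # per-variant deviations within binomial sampling noise (200 simultaneous
  # checks, so allow the usual multiplicity slack beyond 3 SE), and the
  # average frequency pinned tightly to the target
  expect_gt(mean(abs(af - 0.5) <= 3 * se), 0.95)
  expect_true(all(abs(af - 0.5) <= 5 * se))
  expect_lt(abs(mean(af) - 0.5), 3 * se / sqrt(200) + 1e-3)

  # positions strictly increasing per chromosome; dosages are hard calls
  expect_true(all(g1$dosages %in% 0:2))
  for (ch in unique(g1$map$chrom)) {
    expect_true(all(diff(g1$map$pos[g1$map$chrom == ch]) > 0))
  }
})

test_that("LD exists within blocks and vanishes between blocks", {
  cfg <- sim_config(n_samples = 1200, n_variants = 400, ld_block_size = 10,
                    n_founders = 4, qtl_spec = list(), missing_rate = 0,
                    maf_range = c(0.2, 0.5), seed = 5)
  g <- simulate_genotypes(cfg)
  # pairs inside one block vs pairs in different blocks (same chromosome)
  r2_within <- ld_r2(g, g$map$id[1], g$map$id[2:10])
  blocks <- ceiling(seq_len(nrow(g$map)) / 10)
  other_block <- which(blocks == 3)[1:5]
  r2_between <- ld_r2(g, g$map$id[1], g$map$id[other_block])
  expect_gt(mean(r2_within, na.rm = TRUE), 0.1)
  expect_lt(mean(r2_between, na.rm = TRUE), 0.05)

  # block size 1: essentially no LD anywhere
  cfg1 <- sim_config(n_samples = 1000, n_variants = 100, ld_block_size = 1,
                     qtl_spec = list(), missing_rate = 0, seed = 5)
  g1 <- simulate_genotypes(cfg1)
  r2 <- ld_r2(g1, g1$map$id[1], g1$map$id[2:20])
  expect_lt(mean(r2, na.rm = TRUE), 0.05)
})

test_that("phenotype simulation hits QTL variance and missingness targets", {
  # one QTL, fraction 0.10, n = 2000: regression R2 ~ 0.10 +/- 0.03
  cfg <- sim_config(n_samples = 2000, n_variants = 500, n_traits = 1,
                    trait_groups = list(g = 1L), h2 = 0.4,
                    genetic_corr = matrix(1),
                    qtl_spec = list(list(chrom = "1", pos = 50e6, traits = 1L,
                                         frac = 0.10)),
                    missing_rate = 0, seed = 21)
  g <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(g, cfg)
  cv <- sim$truth$causal
  x <- g$dosages[, cv$variant_id[1]]
  r2 <- summary(lm(sim$phen$values[, 1] ~ x))$r.squared
  expect_gt(r2, 0.07)
  expect_lt(r2, 0.13)

  # per-trait missingness matches its configured rate (binomial tolerance)
  cfgm <- small_cfg(miss = c(0.37, 0.05, 0))
  gm <- simulate_genotypes(cfgm)
  simm <- simulate_phenotypes(gm, cfgm)
  fr <- colMeans(is.na(simm$phen$values))
  n <- cfgm$n_samples
  expect_lt(abs(fr[1] - 0.37), 4 * sqrt(0.37 * 0.63 / n))
  expect_lt(abs(fr[2] - 0.05), 4 * sqrt(0.05 * 0.95 / n))
  expect_identical(unname(fr[3]), 0)

  # no genetic signal: phenotype correlations ~ 0
  cfg0 <- null_cfg(seed = 8, n = 1500, m = 300, d = 3, h2 = 0, rg = 0)
  g0 <- simulate_genotypes(cfg0)
  s0 <- simulate_phenotypes(g0, cfg0)
  cm <- cor(s0$phen$values)
  off <- cm[upper.tri(cm)]
  expect_true(all(abs(off) < 3 / sqrt(1500)))
})

test_that("realized heritability and genetic correlation track the config", {
  h2_hat <- matrix(NA_real_, 6, 2)
  rg_hat <- numeric(6)
  for (i in 1:6) {
    cfg <- null_cfg(seed = 100 + i, n = 2000, m = 600, d = 2,
                    h2 = 0.5, rg = 0.6)
    g <- simulate_genotypes(cfg)
    s <- simulate_phenotypes(g, cfg)
    Y <- s$phen$values
    # genetic part = value minus the (independent) residual is not directly
    # observable; use the truth record instead
    h2_hat[i, ] <- s$truth$realized_h2
    # realized genetic correlation from the polygenic construction: estimate
    # via cross-trait phenotypic correlation corrected for h2
    rg_hat[i] <- cor(Y[, 1], Y[, 2]) / sqrt(prod(s$truth$realized_h2))
  }
  expect_true(all(abs(colMeans(h2_hat) - 0.5) < 0.05))
  expect_lt(abs(mean(rg_hat) - 0.6), 0.1)
})

test_that("drEBV eligibility filters behave as specified", {
  ph <- pheno_set(values = matrix(rnorm(40), 20, 2),
                  reliability = matrix(0.9, 20, 2),
                  weight = matrix(9, 20, 2))
  # all reliable, all within 1 SD-ish: no-op
  out <- apply_drebv_filters(ph, min_reliability = 0.3, sd_limit = 5,
                             min_records = 5)
  expect_identical(out$values, ph$values)

  # one extreme outlier removed (n large enough that the outlier itself
  # does not materially inflate the trait SD)
  set.seed(31)
  v <- matrix(rnorm(400), 200, 2)
  v[7, 1] <- mean(v[-7, 1]) + 7 * sd(v[-7, 1])
  ph2 <- pheno_set(v, matrix(0.9, 200, 2), matrix(9, 200, 2))
  out2 <- apply_drebv_filters(ph2, sd_limit = 5, min_records = 5)
  expect_true(is.na(out2$values[7, 1]))
  expect_identical(sum(is.na(out2$values)), 1L)

  # low-reliability records dropped; trait below min_records dropped
  rel <- matrix(0.9, 20, 2)
  rel[1:18, 2] <- 0.1
  ph3 <- pheno_set(matrix(rnorm(40), 20, 2), rel, matrix(9, 20, 2))
  expect_message(out3 <- apply_drebv_filters(ph3, min_reliability = 0.3,
                                             min_records = 5))
  expect_identical(attr(out3, "dropped_traits"), "T2")
  expect_identical(out3$trait_names, "T1")
})

test_that("complete-case restriction counts samples correctly", {
  v <- matrix(rnorm(9), 3, 3)
  v[2, 1] <- NA
  ph <- pheno_set(v, matrix(1, 3, 3), matrix(1, 3, 3),
                  sample_ids = c("a", "b", "c"))
  cc <- complete_case_subset(ph, "all")
  expect_identical(cc$sample_ids, c("a", "c"))

  # multiplicative shrinkage under independent per-trait missingness
  set.seed(2)
  n <- 4000; d <- 8; rate <- 0.05
  v <- matrix(rnorm(n * d), n, d)
  v[matrix(runif(n * d) < rate, n, d)] <- NA
  ph <- pheno_set(v, matrix(1, n, d), matrix(1, n, d))
  cc <- complete_case_subset(ph, "all")
  expected <- n * (1 - rate)^d
  expect_lt(abs(length(cc$sample_ids) - expected), 4 * sqrt(expected))

  ph_empty <- pheno_set(matrix(NA_real_, 2, 1), matrix(1, 2, 1),
                        matrix(1, 2, 1))
  expect_error(complete_case_subset(ph_empty, "all"), "smaller")
})

test_that("imputation-CV masking partitions and round-trips", {
  co <- small_cohort()
  g <- co$geno
  keep <- g$map$id[seq(1, nrow(g$map), by = 2)]
  hold <- g$sample_ids[1:10]
  mk <- mask_for_imputation_cv(g, keep, hold)
  expect_identical(dim(mk$truth$dosages),
                   c(10L, nrow(g$map) - length(keep)))
  # masked entries NA for holdout, untouched elsewhere
  masked_sites <- setdiff(g$map$id, keep)
  expect_true(all(is.na(mk$masked$dosages[hold, masked_sites])))
  expect_identical(mk$masked$dosages[g$sample_ids[11:20], ],
                   g$dosages[g$sample_ids[11:20], ])
  expect_identical(mk$masked$dosages[hold, keep], g$dosages[hold, keep])
  # truth matrix holds exactly the masked values
  expect_identical(mk$truth$dosages, g$dosages[hold, masked_sites])

  all_kept <- mask_for_imputation_cv(g, g$map$id, hold)
  expect_identical(ncol(all_kept$truth$dosages), 0L)
})
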