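test_that("Bonferroni thresholds reproduce the standard array/sequence values", {
  expect_equal(signif(bonferroni_threshold(0.05, 40382), 3), 1.24e-6)
  expect_equal(signif(bonferroni_threshold(0.05, 16051635), 3), 3.11e-9)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0))
})

test_that("analytic FDR reproduces reference values and is monotone in A", {
  P <- 0.05 / 40382
  expect_equal(round(fdr_analytic(P, 49, 40382), 2), 0.10)
  expect_equal(round(fdr_analytic(P, 1, 40382), 2), 5.00)
  expect_equal(fdr_analytic(0.01, 100, 100), 0)      # A = T: numerator dies
  expect_warning(expect_true(is.na(fdr_analytic(0.01, 0, 100))))
  fdrs <- vapply(c(1, 5, 20, 100, 1000), fdr_analytic, numeric(1),
                 P = P, T_total = 40382)
  expect_true(all(diff(fdrs) < 0))
})

test_that("inflation factor is anchored, scales, and is calibrated on uniform p", {
  expect_equal(inflation_factor(rep(0.5, 200)), 1.0)

  # doubling the chi-square statistics doubles lambda
  set.seed(61)
  chi <- rchisq(20000, 1)
  p1 <- pchisq(chi, 1, lower.tail = FALSE)
  p2 <- pchisq(2 * chi, 1, lower.tail = FALSE)
  l1 <- inflation_factor(p1)
  l2 <- inflation_factor(p2)
  expect_equal(l2 / l1, 2, tolerance = 0.05)

  p <- runif(1e5)
  expect_equal(inflation_factor(p), 1, tolerance = 0.02)

  expect_error(inflation_factor(runif(50)), "100")
  expect_warning(inflation_factor(c(rep(0.5, 199), 0)), "clamped")
})

test_that("method comparison decomposes overlaps and pairs p-values", {
  mk <- function(ids, p) {
    data.frame(variant_id = ids, chrom = "1",
               pos = match(ids, paste0("v", 1:10)) * 1000, p = p,
               stringsAsFactors = FALSE)
  }
  universe <- paste0("v", 1:10)
  p1 <- rep(0.5, 10); p1[1:3] <- 1e-8          # {v1, v2, v3}
  p2 <- rep(0.5, 10); p2[2:4] <- 1e-8          # {v2, v3, v4}
  cmp <- compare_methods(list(A = mk(universe, p1), B = mk(universe, p2)),
                         threshold = 1e-6)
  expect_setequal(cmp$significant$A, c("v1", "v2", "v3"))
  counts <- as.list(cmp$subset_counts)
  expect_identical(counts[["A&B"]], 2L)
  expect_identical(counts[["A"]], 1L)
  expect_identical(counts[["B"]], 1L)
  # inclusion-exclusion: subset counts sum to the union size
  expect_identical(sum(cmp$subset_counts),
                   length(unique(c(cmp$significant$A, cmp$significant$B))))

  # identical result sets: everything in the full intersection
  cmp2 <- compare_methods(list(A = mk(universe, p1), B = mk(universe, p1)),
                          threshold = 1e-6)
  expect_identical(as.list(cmp2$subset_counts)[["A&B"]], 3L)

  expect_error(compare_methods(list(A = mk(universe, p1),
                                    B = mk(paste0("w", 1:10), p2)),
                               threshold = 1e-6), "disjoint")
})

test_that("imputation accuracy scores concordance and dosage correlation", {
  map4 <- data.frame(chrom = "1", pos = 1:4 * 1000L, id = paste0("v", 1:4),
                     ref = "A", alt = "C", stringsAsFactors = FALSE)
  truth <- geno_matrix(matrix(c(0, 1, 2, 1,
                                2, 2, 0, 0,
                                1, 1, 1, 1,
                                0, 0, 2, 2), 4, 4), map4)
  acc0 <- imputation_accuracy(truth, truth)
  expect_equal(acc0$overall$concordance_ratio, 1)
  expect_equal(acc0$overall$dosage_r2, 1)

  # 15 of 16 genotypes match
  imp <- truth
  imp$dosages[1, 1] <- 2
  acc1 <- imputation_accuracy(truth, imp)
  expect_equal(acc1$overall$concordance_ratio, 15 / 16)

  # fractional dosages: best-guess calls match, R2 from the Pearson oracle
  tr <- geno_matrix(matrix(c(0, 1, 2, 1), 4, 1), map4[1, ])
  im <- geno_matrix(matrix(c(0.1, 0.9, 1.8, 1.2), 4, 1), map4[1, ])
  acc2 <- imputation_accuracy(tr, im)
  expect_equal(acc2$overall$concordance_ratio, 1)
  expect_equal(acc2$overall$dosage_r2,
               cor(c(0.1, 0.9, 1.8, 1.2), c(0, 1, 2, 1))^2, tolerance = 1e-12)

  # tie at 1.5 rounds toward the heterozygote by default, away under "round"
  trt <- geno_matrix(matrix(c(1, 1), 2, 1), map4[1, ])
  imt <- geno_matrix(matrix(c(1.5, 0.5), 2, 1), map4[1, ])
  expect_equal(imputation_accuracy(trt, imt)$overall$concordance_ratio, 1)

  # allele relabelling applied to both matrices leaves CR unchanged and an
  # affine recoding of the imputed dosages leaves R2 unchanged
  flip <- function(g) { g$dosages <- 2 - g$dosages; g }
  acc_f <- imputation_accuracy(flip(truth), flip(imp))
  expect_equal(acc_f$overall$concordance_ratio,
               acc1$overall$concordance_ratio)
  im_aff <- im
  im_aff$dosages <- pmin(pmax(0.8 * im$dosages + 0.2, 0), 2)
  expect_equal(imputation_accuracy(tr, im_aff)$overall$dosage_r2,
               acc2$overall$dosage_r2, tolerance = 1e-12)

  # bin counts sum to the total number of compared genotypes
  accb <- imputation_accuracy(truth, imp)
  expect_identical(sum(accb$by_bin$n_genotypes), accb$overall$n_genotypes)
})

test_that("masking plus a noisy imputer yields sensible CR/R2 via the CV path", {
  co <- small_cohort(seed = 62, n = 150, m = 200, miss = 0)
  keep <- co$geno$map$id[seq(1, 200, by = 2)]
  hold <- co$geno$sample_ids[1:30]
  mk <- mask_for_imputation_cv(co$geno, keep, hold)
  # a crude "imputer": truth plus symmetric dosage noise
  set.seed(1)
  imp <- mk$truth
  noise <- matrix(rnorm(length(imp$dosages), 0, 0.2), nrow(imp$dosages))
  imp$dosages <- pmin(pmax(imp$dosages + noise, 0), 2)
  acc <- imputation_accuracy(mk$truth, imp)
  expect_gt(acc$overall$concordance_ratio, 0.95)
  expect_gt(acc$overall$dosage_r2, 0.85)
})
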