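test_that("QTL calling windows, merges and splits correctly", {
  res <- function(pos, p, chrom = "1") {
    data.frame(variant_id = paste0(chrom, "_", as.integer(pos)), chrom = chrom,
               pos = pos, p = p, stringsAsFactors = FALSE)
  }
  # two significant variants in one window: one QTL
  q1 <- call_qtl(res(c(4e5, 6e5), c(1e-8, 1e-9)), threshold = 1e-6)
  expect_identical(nrow(q1), 1L)
  expect_identical(q1$n_windows, 1L)
  expect_identical(q1$lead_variant, "1_600000")   # smallest p leads

  # adjacent windows merge into one region spanning both
  q2 <- call_qtl(res(c(9e5, 1.1e6), c(1e-8, 1e-7)), threshold = 1e-6)
  expect_identical(nrow(q2), 1L)
  expect_identical(q2$n_windows, 2L)
  expect_identical(q2$start_bp, 9e5)
  expect_identical(q2$stop_bp, 1.1e6)
  # without merging they stay separate
  q2s <- call_qtl(res(c(9e5, 1.1e6), c(1e-8, 1e-7)), threshold = 1e-6,
                  merge_adjacent = FALSE)
  expect_identical(nrow(q2s), 2L)

  # distant windows and different chromosomes: separate QTL
  q3 <- call_qtl(rbind(res(c(4e5), 1e-8), res(5e5, 1e-9, chrom = "2")),
                 threshold = 1e-6)
  expect_identical(nrow(q3), 2L)
  expect_setequal(q3$chrom, c("1", "2"))

  # partition property: every significant variant in exactly one region,
  # none in more; lead ties break by position
  set.seed(51)
  pos <- sort(sample.int(2e7, 200))
  p <- runif(200)
  p[c(10, 11, 120)] <- 1e-9
  rr <- res(pos, p)
  qq <- call_qtl(rr, threshold = 1e-6)
  sig <- rr[rr$p < 1e-6, ]
  covered <- vapply(seq_len(nrow(sig)), function(i) {
    sum(qq$chrom == sig$chrom[i] & qq$start_bp <= sig$pos[i] &
          qq$stop_bp >= sig$pos[i])
  }, numeric(1))
  expect_true(all(covered >= 1))
  expect_identical(sum(qq$n_significant), nrow(sig))
  expect_identical(nrow(call_qtl(rr, threshold = 1e-12)), 0L)

  tie <- res(c(100, 200), c(1e-9, 1e-9))
  expect_identical(call_qtl(tie, 1e-6)$lead_variant, "1_100")
})

test_that("LD r2 matches brute-force Pearson correlation", {
  g <- toy_geno(cbind(c(0, 1, 2, 0, 1, 2), c(2, 1, 0, 2, 1, 0),
                      c(0, 0, 1, 1, 0, 2), c(0, 1, 0, 1, 0, 1)))
  ids <- g$map$id
  expect_equal(unname(ld_r2(g, ids[1], ids[1])), 1.0)
  expect_equal(unname(ld_r2(g, ids[1], ids[2])), 1.0)  # perfect negative LD

  g4 <- toy_geno(cbind(c(0, 0, 1, 1), c(0, 1, 0, 1)))
  expect_equal(unname(ld_r2(g4, g4$map$id[1], g4$map$id[2])), 0.0)

  # brute force over complete pairs with missing data
  set.seed(52)
  dos <- matrix(rbinom(300, 2, 0.4), 50, 6)
  dos[sample(300, 30)] <- NA
  gm <- toy_geno(dos)
  r2 <- ld_r2(gm, gm$map$id[1], gm$map$id[-1])
  for (j in 2:6) {
    ok <- !is.na(dos[, 1]) & !is.na(dos[, j])
    expect_equal(unname(r2[j - 1]), cor(dos[ok, 1], dos[ok, j])^2,
                 tolerance = 1e-12)
  }

  # zero-variance variant: NA
  dz <- cbind(c(0, 1, 2, 1), rep(2, 4))
  gz <- toy_geno(dz)
  expect_true(is.na(ld_r2(gz, gz$map$id[1], gz$map$id[2])))
})

test_that("variance explained: plug-in values and joint-fit shrinkage", {
  # lead with p = 0.5, beta ~ 1 against phenotype variance ~ 1: ~50%,
  # and the reported value equals the plug-in formula exactly
  set.seed(53)
  n <- 6000
  x <- rbinom(n, 2, 0.5)
  y <- (x - mean(x)) + rnorm(n, 0, sqrt(0.5))   # var ~ 0.5 + 0.5 = 1
  g <- toy_geno(matrix(x, ncol = 1))
  ve <- variance_explained(y, g, g$map$id[1])
  expect_equal(ve$pct_variance_explained, 100 * 2 * ve$maf * (1 - ve$maf) *
                 ve$beta^2 / var(y), tolerance = 1e-12)
  expect_gt(ve$pct_variance_explained, 45)
  expect_lt(ve$pct_variance_explained, 55)

  # rare lead: explained share collapses toward 0
  xr <- rbinom(n, 2, 0.003)
  gr <- toy_geno(matrix(xr, ncol = 1))
  ver <- variance_explained(y, gr, gr$map$id[1])
  expect_lt(ver$pct_variance_explained, 1)

  # two leads in LD each with marginal signal: joint fit sums to less than
  # the marginal fits (the overlap is no longer double counted)
  cfg <- sim_config(n_samples = 2000, n_variants = 300, n_traits = 1,
                    trait_groups = list(g = 1L), h2 = 0.3,
                    genetic_corr = matrix(1), ld_block_size = 15,
                    n_founders = 4,
                    qtl_spec = list(list(chrom = "1", pos = 30e6, traits = 1L,
                                         frac = 0.05)),
                    missing_rate = 0, seed = 54)
  gg <- simulate_genotypes(cfg)
  ss <- simulate_phenotypes(gg, cfg)
  causal <- ss$truth$causal$variant_id[1]
  r2 <- ld_r2(gg, causal)
  partner <- names(which(r2 > 0.3 & r2 < 0.95))[1]
  expect_false(is.na(partner))  # the 4-founder blocks guarantee LD partners
  y <- setNames(ss$phen$values[, 1], ss$phen$sample_ids)
  joint <- variance_explained(y, gg, c(causal, partner))
  marg <- vapply(c(causal, partner), function(v) {
    variance_explained(y, gg, v)$pct_variance_explained
  }, numeric(1))
  expect_lt(sum(joint$pct_variance_explained), sum(marg))

  # collinear leads: the later one dropped
  dup <- toy_geno(cbind(x, x))
  expect_warning(ved <- variance_explained(rnorm(n), dup, dup$map$id),
                 "dropped")
  expect_identical(nrow(ved), 1L)
})

test_that("variance explained recovers the simulated QTL fraction", {
  rel_err <- vapply(1:10, function(i) {
    cfg <- sim_config(n_samples = 2000, n_variants = 200, n_traits = 1,
                      trait_groups = list(g = 1L), h2 = 0.3,
                      genetic_corr = matrix(1),
                      qtl_spec = list(list(chrom = "2", pos = 50e6,
                                           traits = 1L, frac = 0.05)),
                      missing_rate = 0, seed = 500 + i)
    g <- simulate_genotypes(cfg)
    s <- simulate_phenotypes(g, cfg)
    y <- setNames(s$phen$values[, 1], s$phen$sample_ids)
    ve <- variance_explained(y, g, s$truth$causal$variant_id[1])
    (ve$pct_variance_explained - 5) / 5
  }, numeric(1))
  expect_lt(abs(mean(rel_err)), 0.3)
})
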