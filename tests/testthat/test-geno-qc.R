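test_that("panel merging unions samples and harmonises alleles", {
  map <- data.frame(chrom = "1", pos = c(100L, 200L), id = c("v1", "v2"),
                    ref = c("A", "G"), alt = c("C", "T"),
                    stringsAsFactors = FALSE)
  p1 <- geno_matrix(matrix(c(0, 1, 2, 2, 1, 0), 3, 2), map,
                    c("s1", "s2", "s3"))
  p2 <- geno_matrix(matrix(c(2, 0, 1, 1, 0, 2), 3, 2), map,
                    c("s4", "s5", "s6"))
  mg <- merge_panels(list(p1, p2))
  expect_setequal(mg$sample_ids, paste0("s", 1:6))
  expect_identical(nrow(mg$map), 2L)
  expect_identical(unname(mg$dosages["s4", "v1"]), 2)

  # ref/alt swap: dosages flipped to 2 - x
  map_sw <- map
  map_sw$ref <- map$alt; map_sw$alt <- map$ref
  p2s <- geno_matrix(matrix(c(2, 0, 1, 1, 0, 2), 3, 2), map_sw,
                     c("s4", "s5", "s6"))
  mgs <- merge_panels(list(p1, p2s))
  expect_identical(unname(mgs$dosages["s4", "v1"]), 0)
  expect_identical(unname(mgs$dosages["s6", "v2"]), 0)

  # same position, irreconcilable alleles: variant dropped and counted
  map_bad <- map
  map_bad$ref[1] <- "T"; map_bad$alt[1] <- "G"
  p2b <- geno_matrix(matrix(c(2, 0, 1, 1, 0, 2), 3, 2), map_bad,
                     c("s4", "s5", "s6"))
  mgb <- merge_panels(list(p1, p2b))
  expect_identical(mgb$map$id, "v2")
  expect_identical(unname(attr(mgb, "merge_report")["allele_mismatch"]), 1L)

  # duplicated position within a panel: both removed as non-unique
  map_dup <- data.frame(chrom = "1", pos = c(100L, 100L), id = c("a", "b"),
                        ref = c("A", "A"), alt = c("C", "C"),
                        stringsAsFactors = FALSE)
  # construct directly (geno_matrix would reject non-increasing positions)
  pd <- structure(list(sample_ids = c("s1", "s2"), map = map_dup,
                       dosages = matrix(0, 2, 2,
                                        dimnames = list(c("s1", "s2"),
                                                        c("a", "b")))),
                  class = "geno_matrix")
  mgd <- merge_panels(list(pd, p1))
  expect_false(any(mgd$map$pos == 100))
})

test_that("HWE exact test matches full enumeration and known cases", {
  expect_equal(hwe_exact_p(25, 50, 25), 1.0)
  expect_lt(hwe_exact_p(0, 50, 0), 1e-5)
  expect_equal(hwe_exact_p(40, 0, 0), 1.0)

  # full-enumeration oracle agreement across a grid of tables
  for (tab in list(c(5, 10, 5), c(20, 5, 1), c(3, 30, 60), c(50, 50, 50),
                   c(0, 10, 90), c(7, 1, 0), c(12, 0, 13))) {
    expect_equal(hwe_exact_p(tab[1], tab[2], tab[3]),
                 hwe_enum_p(tab[1], tab[2], tab[3]),
                 tolerance = 1e-12,
                 info = paste(tab, collapse = "/"))
  }
  expect_error(hwe_exact_p(0, 0, 0))
})

test_that("QC filter applies thresholds in order and is idempotent", {
  set.seed(1)
  n <- 60
  dos <- matrix(rbinom(n * 10, 2, 0.3), n, 10)
  dos[, 4] <- rbinom(n, 2, 0.002)        # low MAF
  map <- data.frame(chrom = "1", pos = (1:10) * 100L, id = paste0("v", 1:10),
                    ref = "A", alt = "C", stringsAsFactors = FALSE)
  g <- geno_matrix(dos, map)
  res <- qc_filter(g, maf_min = 0.05, hwe_p_min = 0, var_call_min = 0,
                   sample_call_min = 0)
  expect_false("v4" %in% res$geno$map$id)
  expect_identical(res$report$maf, 1L)
  expect_identical(res$report$n_output_variants,
                   res$report$n_input_variants - 1L)

  # idempotence
  res2 <- qc_filter(res$geno, maf_min = 0.05, hwe_p_min = 0,
                    var_call_min = 0, sample_call_min = 0)
  expect_identical(res2$geno$dosages, res$geno$dosages)
  expect_identical(res2$report$n_output_variants,
                   res2$report$n_input_variants)

  # all thresholds 0 = identity
  res0 <- qc_filter(g, maf_min = 0, hwe_p_min = 0, var_call_min = 0,
                    sample_call_min = 0)
  expect_identical(res0$geno$dosages, g$dosages)

  # post-imputation preset drops DR2 < 0.6
  map$dr2 <- c(0.9, 0.5, rep(0.95, 8))
  gi <- geno_matrix(dos, map)
  pr <- qc_preset("post_imputation")
  resi <- qc_filter(gi, maf_min = pr$maf_min, hwe_p_min = pr$hwe_p_min,
                    var_call_min = pr$var_call_min,
                    sample_call_min = pr$sample_call_min, dr2_min = pr$dr2_min)
  expect_false("v2" %in% resi$geno$map$id)
  expect_identical(resi$report$dr2, 1L)

  # call-rate filters remove sparse samples/variants before MAF
  dos2 <- dos
  dos2[1, ] <- NA                      # sample with 0% call rate
  dos2[-1, 7] <- NA                    # variant missing everywhere else
  res3 <- qc_filter(geno_matrix(dos2, map), maf_min = 0, hwe_p_min = 0,
                    var_call_min = 0.5, sample_call_min = 0.5)
  expect_identical(res3$report$n_removed_samples, 1L)
  expect_identical(res3$report$var_call, 1L)
})

test_that("autosome restriction removes non-autosomal variants first", {
  set.seed(2)
  dos <- matrix(rbinom(120, 2, 0.4), 20, 6)
  map <- data.frame(chrom = c("1", "1", "X", "X", "2", "Y"),
                    pos = c(100L, 200L, 100L, 200L, 100L, 100L),
                    id = paste0("v", 1:6), ref = "A", alt = "C",
                    stringsAsFactors = FALSE)
  g <- geno_matrix(dos, map)
  res <- qc_filter(g, maf_min = 0, hwe_p_min = 0, var_call_min = 0,
                   sample_call_min = 0, autosomes = c("1", "2"))
  expect_setequal(res$geno$map$chrom, c("1", "2"))
  expect_identical(res$report$non_autosomal, 3L)
})

test_that("centred GRM matches hand and brute-force computations", {
  # n = 2, dosages (0, 2) at every variant: G = [[1, -1], [-1, 1]]
  g2 <- toy_geno(matrix(c(0, 2, 0, 2, 0, 2), 2, 3))
  G2 <- compute_grm_centered(g2)
  expect_equal(G2$matrix, matrix(c(1, -1, -1, 1), 2, 2,
                                 dimnames = list(c("S1", "S2"), c("S1", "S2"))))

  # row sums ~ 0 and brute-force double-loop agreement on 20 x 50
  set.seed(4)
  dos <- matrix(rbinom(1000, 2, 0.3), 20, 50)
  dos[sample(1000, 40)] <- NA
  g <- toy_geno(dos)
  G <- compute_grm_centered(g)
  expect_lt(max(abs(rowSums(G$matrix))), 1e-8 * 20)

  mu <- colMeans(dos, na.rm = TRUE)
  Xc <- sweep(dos, 2, mu); Xc[is.na(Xc)] <- 0
  brute <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20) {
    brute[i, j] <- sum(Xc[i, ] * Xc[j, ]) / 50
  }
  expect_lt(max(abs(G$matrix - brute)), 1e-10)

  # PSD up to tolerance; duplicated individual gives identical rows
  expect_gt(min(eigen(G$matrix, symmetric = TRUE, only.values = TRUE)$values),
            -1e-10)
  gd <- toy_geno(rbind(dos, dos[1, ]))
  Gd <- compute_grm_centered(gd)
  expect_equal(Gd$matrix[1, ], Gd$matrix[21, ], ignore_attr = TRUE)
})

test_that("GRM PCA separates clusters and orders variance fractions", {
  # two clusters of duplicated individuals
  set.seed(6)
  base <- matrix(rbinom(2 * 80, 2, 0.4), 2, 80)
  dos <- base[c(rep(1, 10), rep(2, 10)), ] + 0
  g <- toy_geno(dos)
  G <- compute_grm_centered(g)
  pc <- pca_grm(G, 3)
  expect_true(all(pc$coords[1:10, 1] * pc$coords[11:20, 1] > 0) ||
              all(sign(pc$coords[1:10, 1]) != sign(pc$coords[11:20, 1])))
  expect_gt(pc$fractions[1], 0.99)  # all variance is between clusters

  # generic properties: fractions sum <= 1 and non-increasing
  dos2 <- matrix(rbinom(30 * 100, 2, 0.3), 30, 100)
  Gr <- compute_grm_centered(toy_geno(dos2))
  pr <- pca_grm(Gr, 10)
  expect_lte(sum(pr$fractions), 1 + 1e-12)
  expect_true(all(diff(pr$fractions) <= 1e-12))
  expect_error(pca_grm(Gr, 31), "exceed")
})
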