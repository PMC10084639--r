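# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the whole suite stays fast.

# A small two-group cohort with one pleiotropic QTL.
small_cfg <- function(seed = 42, n = 400, m = 800, miss = c(0.1, 0.05, 0.2)) {
  sim_config(
    n_samples = n, n_variants = m, n_traits = 3,
    trait_groups = list(production = 1:2, conformation = 3L),
    h2 = c(0.45, 0.35, 0.5),
    genetic_corr = matrix(c(1, 0.4, 0.1,
                            0.4, 1, 0.1,
                            0.1, 0.1, 1), 3, 3),
    qtl_spec = list(list(chrom = "1", pos = 40e6, traits = 1:2,
                         frac = c(0.06, 0.04))),
    missing_rate = miss, ld_block_size = 10, seed = seed
  )
}

small_cohort <- function(seed = 42, ...) {
  cfg <- small_cfg(seed = seed, ...)
  g <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(g, cfg)
  list(cfg = cfg, geno = g, phen = sim$phen, truth = sim$truth,
       grm = compute_grm_centered(g))
}

# Null cohort: polygenic background only, no QTL, no missingness.
null_cfg <- function(seed, n = 400, m = 1000, d = 2, h2 = 0.3, rg = 0.5,
                     block = 10) {
  gc <- matrix(rg, d, d); diag(gc) <- 1
  groups <- list(g1 = seq_len(d))
  sim_config(n_samples = n, n_variants = m, n_traits = d,
             trait_groups = groups, h2 = rep(h2, d), genetic_corr = gc,
             qtl_spec = list(), missing_rate = 0, ld_block_size = block,
             seed = seed)
}

# Plain genotype matrix with given dosage columns (one chromosome).
toy_geno <- function(dos, chrom = "1", pos = NULL) {
  dos <- as.matrix(dos)
  m <- ncol(dos)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  map <- data.frame(chrom = chrom, pos = pos,
                    id = paste0(chrom, "_", pos),
                    ref = "A", alt = "C", stringsAsFactors = FALSE)
  geno_matrix(dos, map)
}

# Independent brute-force HWE enumeration oracle via log-factorials:
# P(n_Aa = h | allele counts) over all compatible tables.
hwe_enum_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  hets <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (na - h) / 2
    AA <- (nA - h) / 2
    lfactorial(n) - lfactorial(AA) - lfactorial(h) - lfactorial(aa) +
      h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}
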