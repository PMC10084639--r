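#' Simulation configuration for a synthetic breeding cohort
#'
#' Bundles every knob of the cohort generator with defaults that emulate a
#' medium-size pig breeding study: a few thousand genotyped animals, tens of
#' thousands of array SNPs with MAF > 5% spread over several autosomes,
#' drEBV-like phenotypes in reproduction/production/conformation trait groups
#' with heritabilities spanning roughly 0.05-0.67, modest within-group genetic
#' correlations, a handful of pleiotropic QTL each explaining a few percent of
#' trait variance, per-trait missingness up to 37% and reliability-derived
#' record weights.
#'
#' @param n_samples number of animals.
#' @param n_variants total number of variants across all chromosomes.
#' @param chrom_lengths named numeric vector, chromosome -> length in bp.
#' @param maf_range length-2 numeric in (0, 0.5], target minor-allele
#'   frequency range variants are drawn from.
#' @param ld_block_size number of consecutive variants per founder-haplotype
#'   block; blocks are in linkage disequilibrium internally and independent of
#'   each other. `1` gives (essentially) LD-free genotypes.
#' @param n_founders number of founder haplotypes per block (default 20);
#'   fewer founders means stronger within-block LD; realized allele
#'   frequencies are quantised to multiples of `1/n_founders`.
#' @param ld_decay mean number of founder carrier swaps between adjacent
#'   variants of a block (default 1); smaller values give tighter LD between
#'   neighbouring variants, 0 makes all variants of equal target frequency
#'   perfectly correlated within a block.
#' @param n_traits number of traits.
#' @param trait_groups named list partitioning trait indices into groups.
#' @param h2 per-trait heritability of the simulated drEBV, length `n_traits`.
#' @param genetic_corr d x d genetic correlation matrix (symmetric, unit
#'   diagonal, positive semi-definite).
#' @param qtl_spec list of QTL; each element a list with `chrom`, `pos`,
#'   `traits` (trait indices or names) and `frac` (per-trait variance
#'   fraction, recycled to `length(traits)`).
#' @param reliability_range length-2 numeric in (0, 1\]; per-record drEBV
#'   reliabilities are drawn uniformly from it.
#' @param missing_rate per-trait missingness fraction in \[0, 1), recycled.
#' @param seed integer master seed; per-stage substreams are derived from it
#'   so the genotype and phenotype stages are individually reproducible.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 1000,
                       n_variants = 10000,
                       chrom_lengths = c(`1` = 100e6, `2` = 100e6, `3` = 100e6,
                                         `4` = 100e6, `5` = 100e6),
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 20,
                       n_founders = 20,
                       ld_decay = 1,
                       n_traits = 6,
                       trait_groups = list(reproduction = 1:2,
                                           production = 3:4,
                                           conformation = 5:6),
                       h2 = c(0.07, 0.29, 0.53, 0.37, 0.41, 0.67),
                       genetic_corr = default_genetic_corr(trait_groups, n_traits),
                       qtl_spec = default_qtl_spec(),
                       reliability_range = c(0.3, 0.99),
                       missing_rate = c(0.10, 0.05, 0.30, 0.05, 0.37, 0.02),
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_variants = as.integer(n_variants),
    chrom_lengths = chrom_lengths, maf_range = as.numeric(maf_range),
    ld_block_size = as.integer(ld_block_size), n_founders = as.integer(n_founders),
    ld_decay = as.numeric(ld_decay),
    n_traits = as.integer(n_traits), trait_groups = trait_groups,
    h2 = rep_len(as.numeric(h2), n_traits),
    genetic_corr = as.matrix(genetic_corr),
    qtl_spec = qtl_spec,
    reliability_range = as.numeric(reliability_range),
    missing_rate = rep_len(as.numeric(missing_rate), n_traits),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param cfg object to validate.
#' @export
validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_samples < 1 || n_variants < 1) stop("n_samples and n_variants must be positive")
    if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
        maf_range[1] > maf_range[2]) {
      stop("maf_range must be an increasing pair in (0, 0.5]")
    }
    if (ld_block_size < 1 || ld_block_size > n_variants) {
      stop("ld_block_size must be in [1, n_variants]")
    }
    if (n_founders < 2) stop("need at least 2 founder haplotypes")
    if (ld_decay < 0) stop("ld_decay must be non-negative")
    if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
    if (any(chrom_lengths < n_variants)) stop("chromosomes too short for the variant count")
    gm <- genetic_corr
    if (nrow(gm) != n_traits || ncol(gm) != n_traits) stop("genetic_corr must be d x d")
    if (max(abs(gm - t(gm))) > 1e-10) stop("genetic_corr must be symmetric")
    if (max(abs(diag(gm) - 1)) > 1e-10) stop("genetic_corr must have unit diagonal")
    if (min(eigen(gm, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop("genetic_corr must be positive semi-definite")
    }
    if (any(h2 < 0 | h2 > 1)) stop("h2 must lie in [0, 1]")
    tg <- sort(unlist(trait_groups))
    if (!identical(as.integer(tg), seq_len(n_traits))) {
      stop("trait_groups must partition 1..n_traits")
    }
    qtl_frac <- numeric(n_traits)
    for (q in qtl_spec) {
      if (!all(c("chrom", "pos", "traits", "frac") %in% names(q))) {
        stop("each qtl_spec entry needs chrom, pos, traits, frac")
      }
      if (!as.character(q$chrom) %in% names(chrom_lengths)) {
        stop("QTL chromosome ", q$chrom, " not in chrom_lengths")
      }
      if (q$pos < 1 || q$pos > chrom_lengths[[as.character(q$chrom)]]) {
        stop("QTL position outside chromosome ", q$chrom)
      }
      fr <- rep_len(q$frac, length(q$traits))
      qtl_frac[q$traits] <- qtl_frac[q$traits] + fr
    }
    if (any(qtl_frac > h2 + 1e-12)) {
      stop("per-trait QTL variance fractions must not exceed the trait heritability")
    }
    if (length(reliability_range) != 2 || reliability_range[1] <= 0 ||
        reliability_range[2] > 1 || reliability_range[1] > reliability_range[2]) {
      stop("reliability_range must be an increasing pair in (0, 1]")
    }
    if (any(missing_rate < 0 | missing_rate >= 1)) stop("missing_rate must be in [0, 1)")
  })
  invisible(cfg)
}

#' Default genetic correlation matrix for grouped traits
#'
#' Within-group correlations of 0.14 (reproduction), 0.32 (production) and
#' 0.17 (conformation) with 0.10 between groups, mirroring the magnitude of
#' mean within-group drEBV correlations reported for breeding cohorts; any
#' unnamed group gets 0.2.
#'
#' @param trait_groups named list of trait index vectors.
#' @param n_traits total trait count.
#' @return A d x d correlation matrix.
#' @export
default_genetic_corr <- function(trait_groups, n_traits) {
  within <- c(reproduction = 0.14, production = 0.32, conformation = 0.17)
  gm <- matrix(0.10, n_traits, n_traits)
  for (g in names(trait_groups)) {
    w <- if (g %in% names(within)) within[[g]] else 0.2
    idx <- trait_groups[[g]]
    gm[idx, idx] <- w
  }
  diag(gm) <- 1
  # guarantee PSD for arbitrary partitions
  ev <- eigen(gm, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    gm <- ev$vectors %*% diag(pmax(ev$values, 1e-8)) %*% t(ev$vectors)
    gm <- stats::cov2cor(gm)
  }
  gm
}

#' Default pleiotropic QTL layout
#'
#' Three QTL: a strongly pleiotropic production locus, a production x
#' conformation locus, and a smaller conformation locus, with per-trait
#' variance fractions in the 1-8% range typical of detectable livestock QTL.
#'
#' @return A list suitable for `sim_config(qtl_spec = )`.
#' @export
default_qtl_spec <- function() {
  list(
    list(chrom = "1", pos = 40e6, traits = 3:4, frac = c(0.08, 0.05)),
    list(chrom = "3", pos = 60e6, traits = c(4L, 5L), frac = c(0.04, 0.06)),
    list(chrom = "5", pos = 25e6, traits = 6L, frac = 0.03)
  )
}

# Per-stage substream seeds derived from the master seed (kept < 2^31).
stage_seed <- function(seed, stage) {
  offsets <- c(geno = 101L, phen = 211L, missing = 307L, reliability = 401L,
               resid = 467L, qc = 503L, scan = 601L)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}

#' Simulate genotypes with block LD structure
#'
#' Variants are laid out on the configured chromosomes at sorted uniform
#' positions and grouped into haplotype blocks of `ld_block_size` consecutive
#' variants. Each block carries `n_founders` founder haplotypes whose allele
#' counts are matched to a per-variant target frequency drawn from
#' `maf_range`; every individual draws two founder haplotypes per block, so
#' variants within a block are in LD while blocks are independent.
#'
#' @param cfg a [sim_config()].
#' @return A [geno_matrix()] of hard genotypes (0/1/2), QTL sites included.
#' @export
simulate_genotypes <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(stage_seed(cfg$seed, "geno"))
  n <- cfg$n_samples
  m <- cfg$n_variants
  k <- cfg$n_founders

  # allocate variants to chromosomes proportionally to length
  chroms <- names(cfg$chrom_lengths)
  alloc <- floor(m * cfg$chrom_lengths / sum(cfg$chrom_lengths))
  rem <- m - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1

  map <- do.call(rbind, lapply(chroms, function(ch) {
    mi <- alloc[[ch]]
    if (mi == 0) return(NULL)
    pos <- sort(sample.int(cfg$chrom_lengths[[ch]], mi, replace = FALSE))
    # reserve slots for configured QTL on this chromosome: snap the nearest
    # simulated variant onto the requested position so truth sites exist
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }))
  for (qi in seq_along(cfg$qtl_spec)) {
    q <- cfg$qtl_spec[[qi]]
    on_ch <- which(map$chrom == as.character(q$chrom))
    j <- on_ch[which.min(abs(map$pos[on_ch] - q$pos))]
    map$pos[j] <- as.integer(q$pos)
    map$pos[on_ch] <- sort(map$pos[on_ch])  # keep ordering after the snap
  }
  map <- map[order(map$chrom, map$pos), ]
  # enforce strictly increasing positions within chromosomes (snapping and
  # sampling collisions are resolved by a minimal forward shift)
  for (ch in unique(map$chrom)) {
    i <- which(map$chrom == ch)
    p <- map$pos[i]
    if (length(p) > 1) for (j in 2:length(p)) if (p[j] <= p[j - 1]) p[j] <- p[j - 1] + 1L
    map$pos[i] <- p
  }
  map$id <- paste0(map$chrom, "_", map$pos)
  alleles <- matrix(sample(c("A", "C", "G", "T"), 2 * nrow(map), replace = TRUE),
                    ncol = 2)
  swap <- alleles[, 1] == alleles[, 2]
  alleles[swap, 2] <- ifelse(alleles[swap, 1] == "A", "G", "A")
  map$ref <- alleles[, 1]
  map$alt <- alleles[, 2]

  m <- nrow(map)
  # founder allele counts are quantised frequencies (multiples of 1/k),
  # clamped so no variant is monomorphic in the founder pool; within a block
  # they follow a bounded lazy random walk so neighbouring variants have
  # similar frequencies, as on real haplotypes
  cl <- max(1L, as.integer(round(k * cfg$maf_range[1])))
  cu <- max(cl, min(k - 1L, as.integer(round(k * cfg$maf_range[2]))))
  founder_count <- integer(m)
  for (bl0 in split(seq_len(m), ceiling(seq_len(m) / cfg$ld_block_size))) {
    ccur <- if (cl == cu) cl else sample(cl:cu, 1)
    founder_count[bl0[1]] <- ccur
    for (j in seq_along(bl0)[-1]) {
      step <- sample(c(-1L, 0L, 1L), 1, prob = c(0.25, 0.5, 0.25))
      ccur <- min(max(ccur + step, cl), cu)
      founder_count[bl0[j]] <- ccur
    }
  }

  dos <- matrix(0L, n, m)
  blocks <- split(seq_len(m), ceiling(seq_len(m) / cfg$ld_block_size))
  for (bl in blocks) {
    # founder patterns evolve along the block: each variant's carrier set is
    # the previous one adjusted to its target count, plus a few random
    # carrier/non-carrier swaps -- so LD is high between close variants and
    # decays along the block, while blocks stay independent
    H <- matrix(0L, k, length(bl))
    pat <- rep(0L, k)
    pat[sample.int(k, founder_count[bl[1]])] <- 1L
    H[, 1] <- pat
    if (length(bl) > 1) {
      for (j in 2:length(bl)) {
        delta <- founder_count[bl[j]] - sum(pat)
        if (delta > 0) {
          pat[resample(which(pat == 0L), delta)] <- 1L
        } else if (delta < 0) {
          pat[resample(which(pat == 1L), -delta)] <- 0L
        }
        n_swap <- min(stats::rpois(1, cfg$ld_decay),
                      sum(pat == 1L), sum(pat == 0L))
        if (n_swap > 0) {
          pat[resample(which(pat == 1L), n_swap)] <- 0L
          pat[resample(which(pat == 0L), n_swap)] <- 1L
        }
        H[, j] <- pat
      }
    }
    f1 <- sample.int(k, n, replace = TRUE)
    f2 <- sample.int(k, n, replace = TRUE)
    dos[, bl] <- H[f1, , drop = FALSE] + H[f2, , drop = FALSE]
  }
  geno_matrix(dos, map, paste0("S", seq_len(n)))
}

#' Simulate drEBV-like phenotypes with known genetic truth
#'
#' Builds, per trait, a genetic value as the sum of configured QTL effects
#' (allele-substitution effects sized to hit the target variance fractions on
#' the realized dosage variance, with one random sign per QTL shared across
#' its traits) and a polygenic term constructed from standardized genotypes
#' with per-variant effects correlated across traits according to
#' `genetic_corr`. Residuals are independent across traits and scaled so each
#' trait has unit total variance in expectation. Reliabilities are uniform on
#' `reliability_range`, weights are `r / (1 - r)`, and records are set
#' missing completely at random at the per-trait `missing_rate`.
#'
#' @param geno a [geno_matrix()] from [simulate_genotypes()].
#' @param cfg the same [sim_config()].
#' @return A list with elements `phen` (a [pheno_set()]) and `truth` (a list
#'   with `causal`, a data.frame of per-QTL-per-trait effects and realized
#'   variance fractions, and `realized_h2`, the per-trait realized
#'   genetic-variance fraction).
#' @export
simulate_phenotypes <- function(geno, cfg) {
  validate_sim_config(cfg)
  set.seed(stage_seed(cfg$seed, "phen"))
  n <- length(geno$sample_ids)
  d <- cfg$n_traits
  X <- geno$dosages
  m <- ncol(X)

  trait_names <- unlist(lapply(names(cfg$trait_groups), function(g) {
    paste0(toupper(substr(g, 1, 4)), seq_along(cfg$trait_groups[[g]]))
  }))
  trait_names <- trait_names[order(unlist(cfg$trait_groups))]
  group_of <- character(d)
  for (g in names(cfg$trait_groups)) group_of[cfg$trait_groups[[g]]] <- g
  names(group_of) <- trait_names

  # QTL component
  qtl_g <- matrix(0, n, d)
  causal <- NULL
  qtl_frac <- numeric(d)
  for (qi in seq_along(cfg$qtl_spec)) {
    q <- cfg$qtl_spec[[qi]]
    vid <- paste0(q$chrom, "_", q$pos)
    j <- match(vid, geno$map$id)
    if (is.na(j)) {
      # position may have been nudged by deduplication; take nearest variant
      on_ch <- which(geno$map$chrom == as.character(q$chrom))
      if (!length(on_ch)) stop("qtl_spec references chromosome absent from genotypes: ", q$chrom)
      j <- on_ch[which.min(abs(geno$map$pos[on_ch] - q$pos))]
      if (abs(geno$map$pos[j] - q$pos) > 10) {
        stop("qtl_spec variant ", vid, " absent from genotypes")
      }
      vid <- geno$map$id[j]
    }
    x <- X[, j]
    vx <- stats::var(x)
    if (vx < 1e-12) stop("QTL variant ", vid, " is monomorphic in this cohort")
    fr <- rep_len(q$frac, length(q$traits))
    sgn <- sample(c(-1, 1), 1)  # one sign per QTL, shared across its traits
    for (ti in seq_along(q$traits)) {
      tr <- q$traits[ti]
      beta <- sgn * sqrt(fr[ti] / vx)  # unit trait variance target
      qtl_g[, tr] <- qtl_g[, tr] + beta * x
      causal <- rbind(causal, data.frame(
        qtl = qi, variant_id = vid, chrom = as.character(q$chrom),
        pos = geno$map$pos[j], trait = trait_names[tr], effect = beta,
        target_frac = fr[ti], stringsAsFactors = FALSE
      ))
      qtl_frac[tr] <- qtl_frac[tr] + fr[ti]
    }
  }

  # polygenic component through standardized genotypes, correlated over traits
  poly_var <- pmax(cfg$h2 - qtl_frac, 0)
  sdx <- apply(X, 2, stats::sd)
  keep <- which(sdx > 1e-12)
  Z <- scale(X[, keep, drop = FALSE])  # n x m'
  Sg <- diag(sqrt(poly_var), d) %*% cfg$genetic_corr %*% diag(sqrt(poly_var), d)
  ev <- eigen(Sg, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), d)
  A <- matrix(stats::rnorm(length(keep) * d), length(keep), d) %*% t(L) /
    sqrt(length(keep))
  poly_g <- Z %*% A

  # reliabilities and deregression weights w = r/(1-r); the residual of a
  # record scales with its inverse weight (normalised to mean 1 per trait so
  # the average residual variance stays 1 - h2), as it does for deregressed
  # proofs where low-reliability records carry more noise
  set.seed(stage_seed(cfg$seed, "reliability"))
  R <- matrix(stats::runif(n * d, cfg$reliability_range[1],
                           pmin(cfg$reliability_range[2], 1 - 1e-9)), n, d)
  W <- R / (1 - R)
  inv_w <- 1 / W
  inv_w <- sweep(inv_w, 2, colMeans(inv_w), `/`)

  set.seed(stage_seed(cfg$seed, "resid"))
  resid_sd <- sqrt(pmax(1 - cfg$h2, 0))
  eps <- matrix(stats::rnorm(n * d), n, d) %*% diag(resid_sd, d) * sqrt(inv_w)
  Y <- qtl_g + poly_g + eps

  set.seed(stage_seed(cfg$seed, "missing"))
  for (tr in seq_len(d)) {
    miss <- stats::runif(n) < cfg$missing_rate[tr]
    Y[miss, tr] <- NA_real_
  }

  g_total <- qtl_g + poly_g
  realized_h2 <- apply(g_total, 2, stats::var)  # unit total variance target
  names(realized_h2) <- trait_names
  if (!is.null(causal)) {
    causal$realized_frac <- vapply(seq_len(nrow(causal)), function(i) {
      j <- match(causal$variant_id[i], geno$map$id)
      causal$effect[i]^2 * stats::var(X[, j])
    }, numeric(1))
  }

  phen <- pheno_set(Y, R, W, geno$sample_ids, trait_names, group_of)
  list(phen = phen,
       truth = list(causal = causal, realized_h2 = realized_h2,
                    poly_var = stats::setNames(poly_var, trait_names)))
}

#' Eligibility filtering of drEBV records
#'
#' Applies the standard pseudo-phenotype eligibility cascade: records with
#' reliability at or below `min_reliability` are dropped, records further
#' than `sd_limit` trait standard deviations from the trait mean are dropped,
#' and traits left with fewer than `min_records` non-missing records are
#' removed entirely (reported via the `dropped_traits` attribute and a
#' message).
#'
#' @param phen a [pheno_set()].
#' @param min_reliability reliability threshold (records must exceed it);
#'   default 0.3.
#' @param sd_limit outlier cut in trait SD units; default 5.
#' @param min_records minimum non-missing records per retained trait;
#'   default 2000.
#' @return A filtered [pheno_set()]; dropped trait names in
#'   `attr(, "dropped_traits")`.
#' @export
apply_drebv_filters <- function(phen, min_reliability = 0.3, sd_limit = 5,
                                min_records = 2000) {
  Y <- phen$values
  Y[!is.na(Y) & phen$reliability <= min_reliability] <- NA_real_
  mu <- colMeans(Y, na.rm = TRUE)
  sd_ <- apply(Y, 2, stats::sd, na.rm = TRUE)
  for (j in seq_len(ncol(Y))) {
    if (is.finite(sd_[j]) && sd_[j] > 0) {
      out <- !is.na(Y[, j]) & abs(Y[, j] - mu[j]) > sd_limit * sd_[j]
      Y[out, j] <- NA_real_
    }
  }
  n_rec <- colSums(!is.na(Y))
  keep <- n_rec >= min_records
  dropped <- phen$trait_names[!keep]
  if (length(dropped)) {
    message("dropping trait(s) with fewer than ", min_records, " records: ",
            paste(dropped, collapse = ", "))
  }
  if (!any(keep)) stop("all traits dropped by the record-count filter")
  out <- pheno_set(Y[, keep, drop = FALSE],
                   phen$reliability[, keep, drop = FALSE],
                   phen$weight[, keep, drop = FALSE],
                   phen$sample_ids, phen$trait_names[keep],
                   phen$group_of[keep])
  attr(out, "dropped_traits") <- dropped
  out
}

#' Complete-case restriction within a trait group
#'
#' Keeps only the samples with a non-missing record for every trait of the
#' group, as required by joint multivariate scans (and by the matched
#' complete-case meta-analysis design).
#'
#' @param phen a [pheno_set()].
#' @param group group name, or `"all"` for every trait.
#' @return A [pheno_set()] restricted to the group's traits and its complete
#'   cases.
#' @export
complete_case_subset <- function(phen, group = "all") {
  traits <- if (identical(group, "all")) phen$trait_names else {
    if (!group %in% phen$group_of) stop("unknown trait group: ", group)
    phen$trait_names[phen$group_of == group]
  }
  Y <- phen$values[, traits, drop = FALSE]
  keep <- rowSums(is.na(Y)) == 0
  if (!any(keep)) {
    stop("no sample has complete records for group '", group,
         "'; consider a smaller trait group")
  }
  pheno_set(Y[keep, , drop = FALSE],
            phen$reliability[keep, traits, drop = FALSE],
            phen$weight[keep, traits, drop = FALSE],
            phen$sample_ids[keep], traits, phen$group_of[traits])
}

#' Mask genotypes for imputation cross-validation
#'
#' Reduces a set of holdout samples to a sparse scaffold of `keep_sites` and
#' returns both the masked matrix and the truth matrix of the masked entries,
#' for evaluating an external imputer with [imputation_accuracy()].
#'
#' @param geno a [geno_matrix()] of hard genotypes.
#' @param keep_sites variant ids retained in the holdout samples.
#' @param holdout_samples sample ids whose other sites get masked.
#' @return list(masked = geno_matrix with non-kept sites NA for holdout
#'   samples, truth = geno_matrix of holdout samples at the masked sites).
#' @export
mask_for_imputation_cv <- function(geno, keep_sites, holdout_samples) {
  if (!all(keep_sites %in% geno$map$id)) stop("keep_sites must be a subset of variant ids")
  if (!all(holdout_samples %in% geno$sample_ids)) stop("holdout samples absent from genotypes")
  masked_sites <- setdiff(geno$map$id, keep_sites)
  dos <- geno$dosages
  hi <- match(holdout_samples, geno$sample_ids)
  truth <- NULL
  if (length(masked_sites)) {
    mj <- match(masked_sites, geno$map$id)
    truth <- geno_matrix(dos[hi, mj, drop = FALSE],
                         geno$map[mj, , drop = FALSE],
                         geno$sample_ids[hi])
    dos[hi, mj] <- NA_real_
  } else {
    truth <- geno_matrix(matrix(numeric(0), nrow = length(hi), ncol = 0),
                         geno$map[0, , drop = FALSE], geno$sample_ids[hi])
  }
  list(masked = geno_matrix(dos, geno$map, geno$sample_ids), truth = truth)
}

# sample() without the length-1 surprise
resample <- function(x, size) x[sample.int(length(x), size)]
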