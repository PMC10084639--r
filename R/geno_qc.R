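#' Merge genotype panels on physical position
#'
#' Panels are combined on the union of their samples. Variants are matched by
#' (chromosome, position): where the allele pair of a later panel is the
#' ref/alt swap of the first panel carrying the site, its dosages are flipped
#' to `2 - x`; allele pairs that cannot be reconciled by a swap cause the
#' position to be dropped. Positions carrying more than one variant within a
#' panel, or conflicting ids across panels, are dropped as non-unique.
#' Genotypes of a sample at variants absent from all of its panels are
#' missing.
#'
#' @param panels list of [geno_matrix()] objects sharing one coordinate
#'   convention.
#' @return A merged [geno_matrix()] with a `merge_report` attribute counting
#'   dropped variants by reason (`duplicate_position`, `allele_mismatch`).
#' @export
merge_panels <- function(panels) {
  stopifnot(length(panels) >= 1)
  if (length(panels) == 1) return(panels[[1]])

  keys <- lapply(panels, function(p) paste(p$map$chrom, p$map$pos, sep = ":"))
  # positions duplicated inside any single panel are non-unique everywhere
  dup_within <- unique(unlist(lapply(keys, function(k) k[duplicated(k)])))

  all_keys <- unique(unlist(keys))
  ref_map <- NULL          # first-seen allele definition per key
  drop_mismatch <- character(0)
  for (i in seq_along(panels)) {
    mp <- panels[[i]]$map
    mp$key <- keys[[i]]
    new <- !(mp$key %in% ref_map$key)
    ref_map <- rbind(ref_map, mp[new, c("key", "chrom", "pos", "id", "ref", "alt")])
    # check allele compatibility of the already-known ones
    old <- mp[!new, ]
    if (nrow(old)) {
      ref_rows <- ref_map[match(old$key, ref_map$key), ]
      same <- old$ref == ref_rows$ref & old$alt == ref_rows$alt
      swap <- old$ref == ref_rows$alt & old$alt == ref_rows$ref
      drop_mismatch <- c(drop_mismatch, old$key[!(same | swap)])
    }
  }
  drop <- union(dup_within, unique(drop_mismatch))
  ref_map <- ref_map[!(ref_map$key %in% drop), ]
  ref_map <- ref_map[order(ref_map$chrom, ref_map$pos), ]

  samples <- unique(unlist(lapply(panels, `[[`, "sample_ids")))
  dos <- matrix(NA_real_, length(samples), nrow(ref_map),
                dimnames = list(samples, ref_map$id))
  for (i in seq_along(panels)) {
    p <- panels[[i]]
    key <- keys[[i]]
    vkeep <- which(key %in% ref_map$key & !duplicated(key))
    col <- match(key[vkeep], ref_map$key)
    x <- p$dosages[, vkeep, drop = FALSE]
    flip <- p$map$ref[vkeep] == ref_map$alt[col]  # swapped orientation
    if (any(flip)) x[, flip] <- 2 - x[, flip]
    dos[p$sample_ids, col] <- x
  }
  out <- geno_matrix(dos, ref_map[c("chrom", "pos", "id", "ref", "alt")], samples)
  attr(out, "merge_report") <- c(duplicate_position = length(dup_within),
                                 allele_mismatch = length(unique(drop_mismatch)))
  out
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test on the genotype counts of a biallelic variant:
#' given the allele counts, the p-value is the total probability of all
#' heterozygote counts whose conditional probability does not exceed that of
#' the observed table (probability ordering, no mid-p correction).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative integers).
#' @return p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("no genotypes observed")
  n_rare <- 2 * min(n_AA, n_aa) + n_Aa   # rare-allele count
  if (n_rare == 0) return(1)             # monomorphic: single possible table

  # distribution of the heterozygote count via the standard two-sided
  # recurrence anchored at (near) the mode, normalised at the end
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  probs <- numeric(length(hets))
  mid <- n_rare * (2 * n - n_rare) / (2 * n)
  mid_i <- which.min(abs(hets - mid))
  probs[mid_i] <- 1
  if (mid_i > 1) {
    for (i in (mid_i - 1):1) {
      h <- hets[i + 1]                  # moving from h to h - 2
      hom_r <- (n_rare - h) / 2         # rare homozygotes at h
      hom_c <- n - h - hom_r            # common homozygotes at h
      probs[i] <- probs[i + 1] * h * (h - 1) / (4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  if (mid_i < length(hets)) {
    for (i in (mid_i + 1):length(hets)) {
      h <- hets[i - 1]                  # moving from h to h + 2
      hom_r <- (n_rare - h) / 2
      hom_c <- n - h - hom_r
      probs[i] <- probs[i - 1] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  obs <- probs[match(n_Aa, hets)]
  min(1, sum(probs[probs <= obs * (1 + 1e-12)]))
}

#' Quality-control presets
#'
#' Three standard filter presets: `array` (MAF > 0.5%, HWE P >= 1e-5, call
#' rates >= 80%), `gwas` (as `array` but MAF > 5%), and `post_imputation`
#' (MAF > 5%, HWE P >= 1e-8, plus DR2 >= 0.6 when the variant map carries a
#' `dr2` field).
#'
#' @param preset one of `"array"`, `"gwas"`, `"post_imputation"`.
#' @return A named list of thresholds usable as arguments to [qc_filter()].
#' @export
qc_preset <- function(preset = c("array", "gwas", "post_imputation")) {
  preset <- match.arg(preset)
  switch(preset,
    array = list(maf_min = 0.005, hwe_p_min = 1e-5, var_call_min = 0.8,
                 sample_call_min = 0.8, dr2_min = NA_real_),
    gwas = list(maf_min = 0.05, hwe_p_min = 1e-5, var_call_min = 0.8,
                sample_call_min = 0.8, dr2_min = NA_real_),
    post_imputation = list(maf_min = 0.05, hwe_p_min = 1e-8, var_call_min = 0,
                           sample_call_min = 0, dr2_min = 0.6)
  )
}

#' Variant and sample quality control
#'
#' Filters are applied in a fixed, documented order: sample call rate,
#' variant call rate, imputation DR2 (only when a threshold is given and the
#' map has a `dr2` column), Hardy-Weinberg exact test, MAF. Each removed
#' variant is attributed to the first filter that failed it. MAF is computed
#' on non-missing dosages; HWE on hard-called genotypes (dosages rounded) of
#' non-missing entries.
#'
#' @param geno a [geno_matrix()].
#' @param maf_min minimum minor-allele frequency (exclusive).
#' @param hwe_p_min minimum HWE exact p-value (exclusive: P < threshold
#'   removes the variant).
#' @param var_call_min minimum variant call rate (inclusive).
#' @param sample_call_min minimum sample call rate (inclusive).
#' @param dr2_min optional minimum model-based imputation accuracy
#'   (inclusive); `NA` disables the filter.
#' @param autosomes optional character vector of autosome labels; variants on
#'   other chromosomes are removed first (`non_autosomal`).
#' @return list(geno = filtered [geno_matrix()], report = one-row data.frame
#'   with input/output counts and per-filter removal counts).
#' @export
qc_filter <- function(geno, maf_min = 0.005, hwe_p_min = 1e-5,
                      var_call_min = 0.8, sample_call_min = 0.8,
                      dr2_min = NA_real_, autosomes = NULL) {
  stopifnot(maf_min >= 0, maf_min <= 1, var_call_min >= 0, var_call_min <= 1)
  dos <- geno$dosages
  n_in <- ncol(dos)
  removed <- c(non_autosomal = 0L, sample_call = 0L, var_call = 0L,
               dr2 = 0L, hwe = 0L, maf = 0L)

  keep_var <- rep(TRUE, ncol(dos))
  if (!is.null(autosomes)) {
    bad <- !(geno$map$chrom %in% as.character(autosomes))
    removed["non_autosomal"] <- sum(bad)
    keep_var[bad] <- FALSE
  }

  scall <- rowMeans(!is.na(dos[, keep_var, drop = FALSE]))
  keep_samp <- scall >= sample_call_min
  removed["sample_call"] <- sum(!keep_samp)
  dos <- dos[keep_samp, , drop = FALSE]

  vcall <- colMeans(!is.na(dos))
  bad <- keep_var & vcall < var_call_min
  removed["var_call"] <- sum(bad)
  keep_var[bad] <- FALSE

  if (!is.na(dr2_min) && !is.null(geno$map$dr2)) {
    bad <- keep_var & !is.na(geno$map$dr2) & geno$map$dr2 < dr2_min
    removed["dr2"] <- sum(bad)
    keep_var[bad] <- FALSE
  }

  if (hwe_p_min > 0) {
    idx <- which(keep_var)
    hwe_p <- vapply(idx, function(j) {
      g <- round(dos[, j])
      g <- g[!is.na(g)]
      if (!length(g)) return(1)
      hwe_exact_p(sum(g == 0), sum(g == 1), sum(g == 2))
    }, numeric(1))
    bad <- idx[hwe_p < hwe_p_min]
    removed["hwe"] <- length(bad)
    keep_var[bad] <- FALSE
  }

  af <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0
  bad <- keep_var & maf < maf_min
  removed["maf"] <- sum(bad)
  keep_var[bad] <- FALSE

  if (!any(keep_var)) warning("no variants left after QC")
  out <- geno_matrix(dos[, keep_var, drop = FALSE],
                     geno$map[keep_var, , drop = FALSE],
                     geno$sample_ids[keep_samp])
  report <- data.frame(
    n_input_variants = n_in,
    n_output_variants = sum(keep_var),
    n_removed_samples = sum(!keep_samp),
    t(removed)
  )
  list(geno = out, report = report)
}

#' Centred genomic relationship matrix
#'
#' Mean-centres each dosage column (missing entries are replaced by the
#' variant mean, i.e. centred to zero) and returns `G = Xc Xc' / m`, the
#' centred GRM convention of mixed-model association tools. Variants with all
#' entries missing are excluded from `m` with a warning.
#'
#' @param geno a [geno_matrix()].
#' @return A [grm()].
#' @export
compute_grm_centered <- function(geno) {
  dos <- geno$dosages
  all_miss <- colSums(!is.na(dos)) == 0
  if (any(all_miss)) {
    warning(sum(all_miss), " all-missing variant(s) excluded from the GRM")
    dos <- dos[, !all_miss, drop = FALSE]
  }
  m <- ncol(dos)
  if (m < 1) stop("need at least one variant with data")
  mu <- colMeans(dos, na.rm = TRUE)
  Xc <- sweep(dos, 2, mu)
  Xc[is.na(Xc)] <- 0
  G <- tcrossprod(Xc) / m
  grm((G + t(G)) / 2, geno$sample_ids, m)
}

#' Principal components of a GRM
#'
#' @param g a [grm()].
#' @param k number of components (k <= n).
#' @return list(coords = n x k matrix of eigenvectors scaled by
#'   sqrt(eigenvalue), fractions = length-k eigenvalue / trace shares,
#'   eigenvalues = the top-k eigenvalues).
#' @export
pca_grm <- function(g, k = 10) {
  n <- length(g$sample_ids)
  if (k > n) stop("k must not exceed the number of samples")
  ev <- eigen(g$matrix, symmetric = TRUE)
  lam <- pmax(ev$values[seq_len(k)], 0)
  coords <- ev$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k)
  rownames(coords) <- g$sample_ids
  colnames(coords) <- paste0("PC", seq_len(k))
  tr <- sum(pmax(ev$values, 0))
  list(coords = coords, fractions = lam / tr, eigenvalues = lam)
}
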