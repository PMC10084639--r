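#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_tests number of tests.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  stopifnot(n_tests >= 1, alpha > 0, alpha < 1)
  alpha / n_tests
}

#' Analytic false discovery rate
#'
#' `FDR = P (1 - A/T) / ((A/T) (1 - P))`, reported in percent, where `P` is
#' the significance threshold, `A` the number of significant variants and
#' `T` the total number of tests.
#'
#' @param P significance threshold in (0, 1).
#' @param A number of significant variants (0 < A <= T gives a value; A = 0
#'   is undefined and returns `NA` with a warning).
#' @param T_total total number of tests.
#' @return FDR in percent.
#' @export
fdr_analytic <- function(P, A, T_total) {
  stopifnot(P > 0, P < 1, A >= 0, A <= T_total)
  if (A == 0) {
    warning("FDR undefined with zero significant variants")
    return(NA_real_)
  }
  q <- A / T_total
  100 * P * (1 - q) / (q * (1 - P))
}

#' Genomic inflation factor
#'
#' Median of the chi-square(1) quantile-transformed p-values divided by the
#' chi-square(1) median (0.4549364): ~1 for well-calibrated scans, > 1 under
#' inflation (e.g. uncorrected stratification).
#'
#' @param pvalues numeric vector of at least 100 p-values.
#' @return `lambda_gc`.
#' @export
inflation_factor <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (length(pvalues) < 100) stop("need at least 100 p-values")
  if (any(pvalues <= 0)) {
    warning("p-values of 0 clamped to the smallest positive double")
    pvalues[pvalues <= 0] <- .Machine$double.xmin
  }
  chi <- stats::qchisq(pvalues, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}

#' Cross-method comparison of association results
#'
#' Computes per-method significant variant sets, the full overlap
#' decomposition (count of variants significant in exactly each non-empty
#' subset of methods), optional QTL-level calls via [call_qtl()], and paired
#' `-log10 p` values over variants significant in at least one method of
#' each pair, with their Pearson correlation (the QQ-style comparison of
#' lead signals between methods).
#'
#' @param results named list (>= 2) of data.frames with columns
#'   `variant_id`/`id`, `chrom`, `pos`, `p`; all sharing one variant
#'   universe.
#' @param threshold significance threshold, scalar or named per method.
#' @param do_qtl also call QTL per method (default TRUE).
#' @param ... passed to [call_qtl()].
#' @return list of class `method_comparison`: `significant` (named list of
#'   id sets), `subset_counts` (named count per method-subset),
#'   `qtl` (named list of `qtl_regions`), `pairs` (per method pair: paired
#'   -log10 p data.frame over the union of the two significant sets, and
#'   `cor`), `lead_pairs` (per pair: paired -log10 p at the union of both
#'   methods' QTL lead variants, and `cor`).
#' @export
compare_methods <- function(results, threshold, do_qtl = TRUE, ...) {
  stopifnot(length(results) >= 2, !is.null(names(results)))
  idcol <- function(df) if ("variant_id" %in% names(df)) df$variant_id else df$id
  universes <- lapply(results, idcol)
  common <- Reduce(intersect, universes)
  if (!length(common)) stop("methods have disjoint variant universes")
  if (length(threshold) == 1) {
    threshold <- stats::setNames(rep(threshold, length(results)), names(results))
  }
  sig <- lapply(names(results), function(m) {
    df <- results[[m]]
    idcol(df)[!is.na(df$p) & df$p < threshold[[m]]]
  })
  names(sig) <- names(results)

  # overlap decomposition over all non-empty method subsets
  all_sig <- unique(unlist(sig))
  membership <- vapply(sig, function(s) all_sig %in% s, logical(length(all_sig)))
  if (length(all_sig) == 1) membership <- matrix(membership, nrow = 1,
                                                 dimnames = list(NULL, names(sig)))
  key <- apply(membership, 1, function(row) paste(names(sig)[row], collapse = "&"))
  subset_counts <- table(key)

  qtl <- NULL
  if (do_qtl) {
    qtl <- lapply(names(results), function(m) call_qtl(results[[m]], threshold[[m]], ...))
    names(qtl) <- names(results)
  }

  pv <- function(df, ids) {
    p <- df$p[match(ids, idcol(df))]
    -log10(p)
  }
  pairs <- list()
  lead_pairs <- list()
  nm <- names(results)
  for (i in seq_len(length(nm) - 1)) for (j in (i + 1):length(nm)) {
    a <- nm[i]; b <- nm[j]
    ids <- intersect(union(sig[[a]], sig[[b]]),
                     intersect(universes[[a]], universes[[b]]))
    df <- data.frame(variant_id = ids, stringsAsFactors = FALSE)
    df[[a]] <- pv(results[[a]], ids)
    df[[b]] <- pv(results[[b]], ids)
    pr <- if (nrow(df) >= 3 && stats::sd(df[[a]]) > 0 && stats::sd(df[[b]]) > 0) {
      stats::cor(df[[a]], df[[b]])
    } else NA_real_
    pairs[[paste(a, b, sep = "|")]] <- list(paired = df, cor = pr)
    if (do_qtl) {
      leads <- intersect(unique(c(qtl[[a]]$lead_variant, qtl[[b]]$lead_variant)),
                         intersect(universes[[a]], universes[[b]]))
      ldf <- data.frame(variant_id = leads, stringsAsFactors = FALSE)
      ldf[[a]] <- pv(results[[a]], leads)
      ldf[[b]] <- pv(results[[b]], leads)
      lr <- if (nrow(ldf) >= 3 && stats::sd(ldf[[a]]) > 0 && stats::sd(ldf[[b]]) > 0) {
        stats::cor(ldf[[a]], ldf[[b]])
      } else NA_real_
      lead_pairs[[paste(a, b, sep = "|")]] <- list(paired = ldf, cor = lr)
    }
  }
  structure(
    list(significant = sig, subset_counts = subset_counts, qtl = qtl,
         pairs = pairs, lead_pairs = lead_pairs),
    class = "method_comparison"
  )
}

#' Imputation accuracy: concordance ratio and dosage R-squared
#'
#' Compares imputed dosages with true hard genotypes: the concordance ratio
#' (CR) is the share of entries whose best-guess genotype (imputed dosage
#' rounded to 0/1/2, ties at 0.5/1.5 rounded toward the heterozygote by
#' default) equals the truth; the dosage R-squared is the squared Pearson
#' correlation between imputed and true dosages. Both are reported overall
#' and within MAF bins computed from the truth panel.
#'
#' @param truth a [geno_matrix()] of hard genotypes.
#' @param imputed a [geno_matrix()] with the same samples and variants.
#' @param maf_bins increasing bin edges over (0, 0.5\]
#'   (default `c(0, 0.05, 0.1, 0.25, 0.5)`).
#' @param ties `"het"` (default: dosage exactly 0.5/1.5 calls the
#'   heterozygote) or `"round"` (banker's rounding via `round()`).
#' @return list of class `imputation_accuracy`: `overall` (CR, R2,
#'   n_genotypes) and `by_bin` data.frame.
#' @export
imputation_accuracy <- function(truth, imputed,
                                maf_bins = c(0, 0.05, 0.1, 0.25, 0.5),
                                ties = c("het", "round")) {
  ties <- match.arg(ties)
  stopifnot(identical(truth$sample_ids, imputed$sample_ids),
            identical(truth$map$id, imputed$map$id))
  Tm <- truth$dosages
  Im <- imputed$dosages
  call_geno <- function(d) {
    if (ties == "het") {
      ifelse(d < 0.5, 0, ifelse(d <= 1.5, 1, 2))
    } else {
      pmin(pmax(round(d), 0), 2)
    }
  }
  ok <- !is.na(Tm) & !is.na(Im)
  cr_all <- mean(call_geno(Im[ok]) == Tm[ok])
  r2_all <- if (stats::var(Tm[ok]) > 0 && stats::var(Im[ok]) > 0) {
    stats::cor(Im[ok], Tm[ok])^2
  } else NA_real_

  af <- colMeans(Tm, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  bin <- cut(maf, breaks = maf_bins, include.lowest = TRUE)
  by_bin <- do.call(rbind, lapply(levels(bin), function(bl) {
    cols <- which(bin == bl)
    if (!length(cols)) {
      return(data.frame(bin = bl, concordance_ratio = NA_real_,
                        dosage_r2 = NA_real_, n_genotypes = 0L))
    }
    tb <- Tm[, cols, drop = FALSE]
    ib <- Im[, cols, drop = FALSE]
    okb <- !is.na(tb) & !is.na(ib)
    if (!any(okb)) {
      return(data.frame(bin = bl, concordance_ratio = NA_real_,
                        dosage_r2 = NA_real_, n_genotypes = 0L))
    }
    r2 <- if (stats::var(tb[okb]) > 0 && stats::var(ib[okb]) > 0) {
      stats::cor(ib[okb], tb[okb])^2
    } else NA_real_
    data.frame(bin = bl, concordance_ratio = mean(call_geno(ib[okb]) == tb[okb]),
               dosage_r2 = r2, n_genotypes = sum(okb))
  }))
  structure(
    list(overall = data.frame(concordance_ratio = cr_all, dosage_r2 = r2_all,
                              n_genotypes = sum(ok)),
         by_bin = by_bin),
    class = "imputation_accuracy"
  )
}
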