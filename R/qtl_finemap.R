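#' Call QTL regions from per-variant p-values
#'
#' Significant variants (`p < threshold`) are binned into non-overlapping
#' 1-Mb windows anchored on a fixed genome grid (windows start at bp 1,
#' 1e6 + 1, ...). Every window holding at least one significant variant is a
#' QTL; with `merge_adjacent` (default), runs of consecutive significant
#' windows on a chromosome merge into a single region, which is how
#' multi-megabase QTL arise under a 1-Mb-window definition. The lead variant
#' is the smallest p-value in the region (ties broken by position, then id).
#'
#' @param results data.frame with columns `variant_id` (or `id`), `chrom`,
#'   `pos`, `p`.
#' @param threshold significance threshold on p.
#' @param merge_adjacent merge runs of adjacent significant windows
#'   (default `TRUE`).
#' @param window_bp window size in bp (default 1e6).
#' @return data.frame of class `qtl_regions`: `qtl`, `chrom`, `start_bp`,
#'   `stop_bp`, `windows` (comma-separated window indices), `n_windows`,
#'   `lead_variant`, `lead_p`, `n_significant`. Zero rows when nothing is
#'   significant.
#' @export
call_qtl <- function(results, threshold, merge_adjacent = TRUE, window_bp = 1e6) {
  id_col <- if ("variant_id" %in% names(results)) "variant_id" else "id"
  stopifnot(all(c(id_col, "chrom", "pos", "p") %in% names(results)))
  sig <- results[!is.na(results$p) & results$p < threshold, ]
  empty <- data.frame(qtl = integer(0), chrom = character(0),
                      start_bp = numeric(0), stop_bp = numeric(0),
                      windows = character(0), n_windows = integer(0),
                      lead_variant = character(0), lead_p = numeric(0),
                      n_significant = integer(0), stringsAsFactors = FALSE)
  class(empty) <- c("qtl_regions", "data.frame")
  if (!nrow(sig)) return(empty)

  sig$window <- (sig$pos - 1) %/% window_bp
  out <- NULL
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, ]
    wins <- sort(unique(s$window))
    grp <- if (merge_adjacent) cumsum(c(1, diff(wins) > 1)) else seq_along(wins)
    for (gset in split(wins, grp)) {
      v <- s[s$window %in% gset, ]
      v <- v[order(v$p, v$pos, v[[id_col]]), ]
      out <- rbind(out, data.frame(
        chrom = ch, start_bp = min(v$pos), stop_bp = max(v$pos),
        windows = paste(gset, collapse = ","), n_windows = length(gset),
        lead_variant = v[[id_col]][1], lead_p = v$p[1],
        n_significant = nrow(v), stringsAsFactors = FALSE
      ))
    }
  }
  out <- out[order(out$chrom, out$start_bp), ]
  out <- cbind(qtl = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("qtl_regions", "data.frame")
  out
}

#' Linkage disequilibrium (r^2) with an anchor variant
#'
#' Squared Pearson correlation of allele dosages between the anchor and each
#' other variant, over the samples non-missing at both. Variants with zero
#' dosage variance in the shared samples are reported as `NA`.
#'
#' @param geno a [geno_matrix()].
#' @param anchor variant id.
#' @param others variant ids to correlate with the anchor (default: all
#'   variants on the anchor's chromosome).
#' @return Named numeric vector of r^2 values.
#' @export
ld_r2 <- function(geno, anchor, others = NULL) {
  ja <- match(anchor, geno$map$id)
  if (is.na(ja)) stop("anchor variant not found: ", anchor)
  if (is.null(others)) {
    others <- geno$map$id[geno$map$chrom == geno$map$chrom[ja]]
  }
  jo <- match(others, geno$map$id)
  if (anyNA(jo)) stop("unknown variant ids: ", paste(others[is.na(jo)], collapse = ", "))
  xa <- geno$dosages[, ja]
  out <- vapply(jo, function(j) {
    xb <- geno$dosages[, j]
    ok <- !is.na(xa) & !is.na(xb)
    if (sum(ok) < 2) return(NA_real_)
    va <- stats::var(xa[ok])
    vb <- stats::var(xb[ok])
    if (va < 1e-12 || vb < 1e-12) return(NA_real_)
    stats::cor(xa[ok], xb[ok])^2
  }, numeric(1))
  stats::setNames(out, others)
}

#' Per-lead variance explained with joint fitting
#'
#' Regresses the phenotype on the dosages of all lead variants
#' simultaneously (intercept included) and reports, per lead,
#' `100 * 2 p (1-p) beta^2 / sigma^2`, where `p` is the lead's minor-allele
#' frequency and `sigma^2` the phenotype variance. Joint fitting removes the
#' overlap that marginal fits double-count when leads are in LD. Leads with
#' pairwise r^2 > 0.99 to an earlier lead are dropped with a warning.
#'
#' @param y phenotype vector aligned to `geno` samples (names matched when
#'   present); missing entries dropped.
#' @param geno a [geno_matrix()].
#' @param lead_variants variant ids significant for this trait.
#' @return data.frame: `variant_id`, `af` (effect-allele frequency), `maf`,
#'   `beta`, `pct_variance_explained`.
#' @export
variance_explained <- function(y, geno, lead_variants) {
  jl <- match(lead_variants, geno$map$id)
  if (anyNA(jl)) stop("lead variants absent from genotypes: ",
                      paste(lead_variants[is.na(jl)], collapse = ", "))
  if (!is.null(names(y))) {
    idx <- match(names(y), geno$sample_ids)
    if (anyNA(idx)) stop("phenotype names must match genotype samples")
  } else {
    stopifnot(length(y) == length(geno$sample_ids))
    idx <- seq_along(y)
  }
  keep <- !is.na(y)
  y <- y[keep]
  X <- geno$dosages[idx[keep], jl, drop = FALSE]
  mu <- colMeans(X, na.rm = TRUE)
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas)) X[nas] <- mu[nas[, 2]]
  colnames(X) <- lead_variants

  # drop later leads in near-perfect LD with an earlier one
  keep_lead <- rep(TRUE, ncol(X))
  if (ncol(X) > 1) {
    r2 <- suppressWarnings(stats::cor(X))^2
    for (j in 2:ncol(X)) {
      if (any(r2[j, seq_len(j - 1)][keep_lead[seq_len(j - 1)]] > 0.99, na.rm = TRUE)) {
        keep_lead[j] <- FALSE
        warning("lead ", colnames(X)[j],
                " is in near-perfect LD with an earlier lead; dropped")
      }
    }
  }
  X <- X[, keep_lead, drop = FALSE]
  jl <- jl[keep_lead]

  fit <- stats::lm.fit(cbind(1, X), y)
  beta <- fit$coefficients[-1]
  af <- colMeans(X) / 2
  maf <- pmin(af, 1 - af)
  s2 <- stats::var(y)
  pct <- 100 * 2 * maf * (1 - maf) * beta^2 / s2
  data.frame(variant_id = colnames(X), af = af, maf = maf, beta = beta,
             pct_variance_explained = pct,
             row.names = NULL, stringsAsFactors = FALSE)
}
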