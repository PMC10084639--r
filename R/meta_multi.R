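#' Assemble the signed t-value matrix from single-trait summary statistics
#'
#' Computes `t = beta/se` per trait and variant, restricts to the variants
#' present in every trait's summary statistics, and harmonises effect alleles
#' to the first trait's orientation (t-values of traits reporting the swapped
#' allele pair are sign-flipped; allele pairs irreconcilable by a swap drop
#' the variant).
#'
#' @param stats list of two or more `summary_stats` objects
#'   (from [score_scan()]).
#' @return An object of class `t_matrix`: `index` (chrom, pos, id,
#'   effect_allele, other_allele), `traits`, `t` (m x d), `source_n` (m x d
#'   per-cell sample sizes), `n_dropped_allele`.
#' @export
assemble_t <- function(stats) {
  stopifnot(length(stats) >= 2)
  traits <- vapply(stats, `[[`, character(1), "trait")
  if (anyDuplicated(traits)) stop("trait names must be unique")
  recs <- lapply(stats, `[[`, "records")
  ids <- Reduce(intersect, lapply(recs, `[[`, "variant_id"))
  if (!length(ids)) stop("no variant is shared across all traits")

  ref <- recs[[1]][match(ids, recs[[1]]$variant_id), ]
  tmat <- matrix(NA_real_, length(ids), length(traits),
                 dimnames = list(ids, traits))
  nmat <- tmat
  drop_mismatch <- rep(FALSE, length(ids))
  for (k in seq_along(recs)) {
    r <- recs[[k]][match(ids, recs[[k]]$variant_id), ]
    same <- r$effect_allele == ref$effect_allele & r$other_allele == ref$other_allele
    swap <- r$effect_allele == ref$other_allele & r$other_allele == ref$effect_allele
    drop_mismatch <- drop_mismatch | !(same | swap)
    tv <- r$beta / r$se
    tv[swap] <- -tv[swap]
    tmat[, k] <- tv
    nmat[, k] <- r$n
  }
  keep <- !drop_mismatch & rowSums(!is.finite(tmat)) == 0
  ref <- ref[keep, ]
  ord <- order(ref$chrom, ref$pos)
  structure(
    list(index = data.frame(chrom = ref$chrom, pos = ref$pos,
                            id = ref$variant_id,
                            effect_allele = ref$effect_allele,
                            other_allele = ref$other_allele,
                            stringsAsFactors = FALSE)[ord, ],
         traits = traits,
         t = tmat[keep, , drop = FALSE][ord, , drop = FALSE],
         source_n = nmat[keep, , drop = FALSE][ord, , drop = FALSE],
         n_dropped_allele = sum(drop_mismatch)),
    class = "t_matrix"
  )
}

#' Estimate the trait correlation matrix of t-values
#'
#' `V` is the Pearson correlation of the t-value columns over markers. Mode
#' `null_markers` restricts the estimation to variants with `|t| < 2` for
#' every trait, which protects `V` from inflation by strong QTL.
#'
#' @param tm a [assemble_t()] result.
#' @param mode `"all_markers"` (default) or `"null_markers"`.
#' @param ridge non-negative diagonal ridge, added only when explicitly
#'   requested (default 0).
#' @param max_condition condition-number cap above which estimation fails
#'   with advice to prune traits or enable the ridge.
#' @return An object of class `v_matrix`: `traits`, `V`, `estimation_mode`,
#'   `condition_number`, `n_markers_used`.
#' @export
estimate_v <- function(tm, mode = c("all_markers", "null_markers"),
                       ridge = 0, max_condition = 1e8) {
  mode <- match.arg(mode)
  t <- tm$t
  d <- ncol(t)
  if (nrow(t) < 10 * d) stop("need at least 10 x d markers to estimate V")
  if (mode == "null_markers") {
    null_rows <- rowSums(abs(t) >= 2) == 0
    if (sum(null_rows) < 10 * d) {
      warning("too few null markers; falling back to all markers")
    } else {
      t <- t[null_rows, , drop = FALSE]
    }
  }
  V <- stats::cor(t)
  if (ridge > 0) {
    V <- V + diag(ridge, d)
    V <- stats::cov2cor(V)
  }
  evs <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  cond <- if (min(evs) <= 0) Inf else max(evs) / min(evs)
  if (!is.finite(cond) || cond > max_condition) {
    stop("V matrix is (near) singular (condition number ",
         format(cond, digits = 3),
         "); prune correlated traits or enable a diagonal ridge")
  }
  structure(
    list(traits = tm$traits, V = V, estimation_mode = mode,
         condition_number = cond, n_markers_used = nrow(t)),
    class = "v_matrix"
  )
}

#' Multi-trait meta-analysis chi-square statistic
#'
#' Per variant j, `chi2_j = t_j' V^{-1} t_j`. P-values use either `d` degrees
#' of freedom (matching the quadratic-form construction) or `d - 1`
#' (default); both conventions are in circulation for this statistic, and
#' both columns can be compared by calling with each mode.
#'
#' @param tm a [assemble_t()] result.
#' @param v an [estimate_v()] result (or any `v_matrix`-shaped list).
#' @param df_mode `"d_minus_1"` (default) or `"d"`.
#' @return data.frame of class `meta_result`: index columns plus `chi2`,
#'   `df`, `p`, sorted by chrom/pos.
#' @export
meta_chi2 <- function(tm, v, df_mode = c("d_minus_1", "d")) {
  df_mode <- match.arg(df_mode)
  d <- length(tm$traits)
  stopifnot(identical(tm$traits, v$traits))
  Vinv <- solve(v$V)
  chi2 <- rowSums((tm$t %*% Vinv) * tm$t)
  df <- as.integer(if (df_mode == "d") d else max(d - 1L, 1L))
  out <- cbind(tm$index,
               data.frame(chi2 = chi2, df = df,
                          p = stats::pchisq(chi2, df = df, lower.tail = FALSE)))
  rownames(out) <- NULL
  class(out) <- c("meta_result", "data.frame")
  out
}
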