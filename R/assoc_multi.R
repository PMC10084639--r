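#' Multivariate mixed-model association scan
#'
#' Per variant, the d-vector of allele-substitution effects is estimated by
#' generalized least squares under the matrix-variate null covariance
#' `G (x) Vg + I (x) Ve`, computed through the GRM eigen-rotation so each
#' rotated sample contributes an independent d x d system. Significance is a
#' Wald chi-square with d degrees of freedom. The variance components are
#' estimated once under the global null ([estimate_mt_vc()]) and held fixed
#' across variants.
#'
#' @param Y complete-case n x d phenotype matrix (rownames matched against
#'   the GRM sample ids when present).
#' @param geno a [geno_matrix()] covering the samples of `Y`.
#' @param g a [grm()].
#' @param vc an [estimate_mt_vc()] result computed on the same samples.
#' @param maf_min minimum minor-allele frequency on the scan samples.
#' @param max_traits hard cap on d (default 24); a warning is issued above
#'   10 traits, where multivariate mixed models are prone to
#'   over-parametrisation.
#' @return data.frame of class `mv_assoc`: variant columns, per-trait
#'   `beta_*` columns, `wald_chi2`, `df`, `p`, sorted by chrom/pos.
#' @export
mv_scan <- function(Y, geno, g, vc, maf_min = 0.05, max_traits = 24) {
  Y <- as.matrix(Y)
  if (anyNA(Y)) stop("Y must be complete-case")
  d <- ncol(Y)
  if (d > max_traits) stop("more than ", max_traits, " traits; refusing to scan")
  if (d > 10) warning("multivariate scans with more than 10 traits risk over-parametrisation")
  for (M in list(vc$Vg, vc$Ve)) {
    if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop("variance components must be positive semi-definite")
    }
  }
  if (!is.null(rownames(Y))) g <- subset_grm(g, rownames(Y))
  stopifnot(nrow(Y) == length(g$sample_ids))
  n <- nrow(Y)

  fake_null <- list(sample_ids = g$sample_ids)
  prep <- prep_scan_dosages(structure(fake_null, class = "lmm_null"), geno, maf_min)
  keep <- prep$keep
  X <- prep$X[, keep, drop = FALSE]
  map <- geno$map[keep, , drop = FALSE]
  af <- prep$af[keep]
  m <- ncol(X)

  ev <- eigen(g$matrix, symmetric = TRUE)
  dvals <- pmax(ev$values, 0)
  U <- ev$vectors
  Yr <- crossprod(U, Y)
  wv <- drop(crossprod(U, rep(1, n)))
  Xr <- crossprod(U, X)

  # per rotated sample: Sigma_i^{-1} (stacked as rows of length d^2) and
  # Sigma_i^{-1} y_i; plus the intercept blocks
  Sinv <- matrix(0, n, d * d)
  Siy <- matrix(0, n, d)
  Kww <- matrix(0, d, d)
  Rw <- numeric(d)
  # small ridge so exactly-PSD-boundary components stay invertible
  eps <- 1e-10 * (mean(diag(vc$Vg)) + mean(diag(vc$Ve)))
  for (i in seq_len(n)) {
    Si <- dvals[i] * vc$Vg + vc$Ve
    inv <- solve(Si + diag(eps, d))
    Sinv[i, ] <- as.vector(inv)
    Siy[i, ] <- drop(inv %*% Yr[i, ])
    Kww <- Kww + wv[i]^2 * inv
    Rw <- Rw + wv[i] * Siy[i, ]
  }
  T_xx <- crossprod(Xr^2, Sinv)        # m x d^2
  T_wx <- crossprod(Xr * wv, Sinv)     # m x d^2
  R_x <- crossprod(Xr, Siy)            # m x d

  Kww_inv <- solve(Kww)
  aw <- drop(Kww_inv %*% Rw)

  betas <- matrix(NA_real_, m, d)
  wald <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    Kxx <- matrix(T_xx[j, ], d, d)
    Kwx <- matrix(T_wx[j, ], d, d)
    Sx <- Kxx - Kwx %*% Kww_inv %*% Kwx
    rhs <- R_x[j, ] - drop(Kwx %*% aw)
    bj <- try(solve(Sx, rhs), silent = TRUE)
    if (inherits(bj, "try-error")) next
    betas[j, ] <- bj
    wald[j] <- sum(rhs * bj)
  }
  p <- stats::pchisq(wald, df = d, lower.tail = FALSE)

  tn <- colnames(Y)
  if (is.null(tn)) tn <- paste0("T", seq_len(d))
  out <- data.frame(
    variant_id = map$id, chrom = map$chrom, pos = map$pos,
    effect_allele = map$alt, other_allele = map$ref, af = af,
    stringsAsFactors = FALSE
  )
  bdf <- as.data.frame(betas)
  names(bdf) <- paste0("beta_", tn)
  out <- cbind(out, bdf)
  out$wald_chi2 <- wald
  out$df <- d
  out$p <- p
  out <- out[!is.na(out$wald_chi2), ]
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  class(out) <- c("mv_assoc", "data.frame")
  out
}
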