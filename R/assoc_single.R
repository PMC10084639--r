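#' Fit the null linear mixed model for a single-trait scan
#'
#' Eigendecomposes the GRM once, rotates phenotype and covariates into the
#' eigenbasis, and estimates the variance ratio `lambda = sigma_a2/sigma_e2`
#' by profiled REML. The returned object carries everything the per-variant
#' score test needs in O(n) per variant.
#'
#' @param y phenotype vector aligned to the GRM rows (or named, in which case
#'   it is matched against the GRM sample ids); missing entries dropped.
#' @param g a [grm()].
#' @param covariates optional numeric matrix of extra fixed effects (an
#'   intercept is always included); must be full rank together with the
#'   intercept.
#' @param lambda optional fixed variance ratio; when supplied the REML search
#'   is skipped (used for method-equivalence checks).
#' @param eig optional precomputed `eigen()` of the (already subset) GRM.
#' @param trait trait label carried into the summary statistics.
#' @return An object of class `lmm_null`.
#' @export
fit_null <- function(y, g, covariates = NULL, lambda = NULL, eig = NULL,
                     trait = "trait") {
  if (!is.null(names(y))) g <- subset_grm(g, names(y))
  stopifnot(length(y) == length(g$sample_ids))
  keep <- !is.na(y)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == length(g$sample_ids))
    keep <- keep & rowSums(is.na(covariates)) == 0
  }
  y <- y[keep]
  n <- length(y)
  sample_ids <- g$sample_ids[keep]
  X0 <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  if (!is.null(covariates)) {
    X0 <- cbind(X0, covariates[keep, , drop = FALSE])
    if (is.null(colnames(X0))) colnames(X0) <- paste0("c", seq_len(ncol(X0)))
  }
  qx <- qr(X0)
  if (qx$rank < ncol(X0)) {
    bad <- colnames(X0)[qx$pivot[(qx$rank + 1):ncol(X0)]]
    stop("covariates are rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (is.null(eig)) {
    eig <- eigen(g$matrix[keep, keep, drop = FALSE], symmetric = TRUE)
  }
  dvals <- pmax(eig$values, 0)
  U <- eig$vectors
  yr <- drop(crossprod(U, y))
  X0r <- crossprod(U, X0)

  if (is.null(lambda)) {
    fit <- reml_optimize(yr, X0r, dvals)
    lambda <- fit$lambda
    sigma2 <- fit$sigma_e2
    beta <- fit$beta
    loglik <- fit$loglik
  } else {
    v <- lambda * dvals + 1
    w <- 1 / v
    XtWX <- crossprod(X0r, X0r * w)
    beta <- drop(solve(XtWX, crossprod(X0r, yr * w)))
    r <- yr - X0r %*% beta
    sigma2 <- sum(w * r^2) / (n - ncol(X0r))
    loglik <- rll_lambda(lambda, yr, X0r, dvals)
  }
  structure(
    list(trait = trait, mu_hat = beta[1], coef = beta, lambda = lambda,
         sigma2 = sigma2, eigvals = dvals, U = U, rotated_y = yr,
         rotated_X0 = X0r, X0 = X0, y = y, sample_ids = sample_ids,
         n_used = n, loglik = loglik),
    class = "lmm_null"
  )
}

#' @export
print.lmm_null <- function(x, ...) {
  cat(sprintf("lmm_null [%s]: n = %d, lambda = %.4g (h2 ~ %.3f), sigma_e2 = %.4g\n",
              x$trait, x$n_used, x$lambda, x$lambda / (1 + x$lambda), x$sigma2))
  invisible(x)
}

# Align a genotype matrix to the null model's samples and mean-impute
# missing dosages; returns dosage matrix, allele freq and column keep mask.
prep_scan_dosages <- function(null, geno, maf_min) {
  if (!all(null$sample_ids %in% geno$sample_ids)) {
    stop("genotypes must cover every sample of the null model")
  }
  idx <- match(null$sample_ids, geno$sample_ids)
  X <- geno$dosages[idx, , drop = FALSE]
  mu <- colMeans(X, na.rm = TRUE)
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas)) X[nas] <- mu[nas[, 2]]
  af <- mu / 2
  maf <- pmin(af, 1 - af)
  vx <- matrixStats_colVars(X)
  keep <- is.finite(maf) & maf >= maf_min & vx > 1e-12
  list(X = X, af = af, keep = keep)
}

# colVars without a hard dependency
matrixStats_colVars <- function(X) {
  n <- nrow(X)
  if (n < 2) return(rep(0, ncol(X)))
  mu <- colMeans(X)
  (colSums(X^2) - n * mu^2) / (n - 1)
}

#' Single-trait mixed-model association scan
#'
#' Score test per variant under the null-model variance structure (the
#' variance ratio is estimated once in [fit_null()] and held fixed across
#' variants). Effect sizes and standard errors come from the generalized
#' least-squares fit at the null variance parameters, so `t = beta/se` is the
#' signed test statistic consumed by the meta-analysis, and
#' `p = P(chi2_1 > (beta/se)^2)`.
#'
#' @param null an [fit_null()] model.
#' @param geno a [geno_matrix()] covering the null model's samples.
#' @param maf_min minimum minor-allele frequency among the scan samples
#'   (default 0.05); MAF is recomputed on the scan subset.
#' @param exclude variant ids to leave out of the scan.
#' @return An object of class `summary_stats`: list with `trait`, `records`
#'   (data.frame: trait, variant_id, chrom, pos, effect_allele, other_allele,
#'   af, beta, se, p, n, sorted by chrom/pos), `n_variants`, `n_skipped`.
#' @export
score_scan <- function(null, geno, maf_min = 0.05, exclude = NULL) {
  prep <- prep_scan_dosages(null, geno, maf_min)
  keep <- prep$keep
  if (!is.null(exclude)) keep <- keep & !(geno$map$id %in% exclude)
  n_skipped <- sum(!keep)
  X <- prep$X[, keep, drop = FALSE]
  map <- geno$map[keep, , drop = FALSE]
  af <- prep$af[keep]

  w <- 1 / (null$lambda * null$eigvals + 1)
  Xr <- crossprod(null$U, X)
  X0r <- null$rotated_X0
  yr <- null$rotated_y
  WX0 <- X0r * w
  C <- solve(crossprod(X0r, WX0))
  a0 <- crossprod(WX0, yr)            # c x 1
  Ca0 <- C %*% a0
  S <- crossprod(WX0, Xr)             # c x m
  xWy <- drop(crossprod(Xr, w * yr))
  xWx <- colSums(Xr^2 * w)
  xPy <- xWy - drop(crossprod(S, Ca0))
  xPx <- xWx - colSums(S * (C %*% S))

  ok <- xPx > 1e-12
  n_skipped <- n_skipped + sum(!ok)
  beta <- se <- p <- rep(NA_real_, length(xPx))
  beta[ok] <- xPy[ok] / xPx[ok]
  se[ok] <- sqrt(null$sigma2 / xPx[ok])
  chi <- (beta / se)^2
  p[ok] <- stats::pchisq(chi[ok], df = 1, lower.tail = FALSE)

  rec <- data.frame(
    trait = null$trait, variant_id = map$id, chrom = map$chrom, pos = map$pos,
    effect_allele = map$alt, other_allele = map$ref, af = af,
    beta = beta, se = se, p = p, n = null$n_used,
    stringsAsFactors = FALSE
  )[ok, ]
  rec <- rec[order(rec$chrom, rec$pos), ]
  rownames(rec) <- NULL
  structure(
    list(trait = null$trait, records = rec, n_variants = nrow(rec),
         n_skipped = n_skipped, threshold_used = NA_real_),
    class = "summary_stats"
  )
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("summary_stats [%s]: %d variants (min p = %.3g), %d skipped\n",
              x$trait, x$n_variants,
              if (x$n_variants) min(x$records$p) else NA, x$n_skipped))
  invisible(x)
}

#' Conditional association scan
#'
#' Re-runs a single-trait scan with the dosages of a set of fixed variants
#' (typically lead SNPs) appended to the covariate matrix. The null model is
#' refitted (new variance ratio) and the fixed variants themselves are
#' excluded from the scan. Fixed variants collinear with the covariates are
#' dropped with a warning.
#'
#' @param null an [fit_null()] model (its phenotype, covariates and samples
#'   are reused).
#' @param geno a [geno_matrix()].
#' @param fixed_variants variant ids to fit as fixed effects.
#' @param maf_min scan MAF threshold.
#' @return A `summary_stats` object; identical to [score_scan()] when
#'   `fixed_variants` is empty.
#' @export
conditional_scan <- function(null, geno, fixed_variants, maf_min = 0.05) {
  if (!length(fixed_variants)) return(score_scan(null, geno, maf_min))
  miss <- setdiff(fixed_variants, geno$map$id)
  if (length(miss)) stop("fixed variants absent from genotypes: ",
                         paste(miss, collapse = ", "))
  idx <- match(null$sample_ids, geno$sample_ids)
  Z <- geno$dosages[idx, match(fixed_variants, geno$map$id), drop = FALSE]
  mu <- colMeans(Z, na.rm = TRUE)
  nas <- which(is.na(Z), arr.ind = TRUE)
  if (nrow(nas)) Z[nas] <- mu[nas[, 2]]
  colnames(Z) <- fixed_variants

  base_cov <- if (ncol(null$X0) > 1) null$X0[, -1, drop = FALSE] else NULL
  # drop fixed variants collinear with the existing covariates
  keep_fix <- rep(TRUE, ncol(Z))
  for (j in seq_len(ncol(Z))) {
    test <- cbind(matrix(1, nrow(Z), 1), base_cov, Z[, which(keep_fix[seq_len(j - 1)]), drop = FALSE], Z[, j])
    if (qr(test)$rank < ncol(test)) {
      keep_fix[j] <- FALSE
      warning("fixed variant ", colnames(Z)[j],
              " is collinear with covariates; dropped")
    }
  }
  Z <- Z[, keep_fix, drop = FALSE]
  covs <- cbind(base_cov, Z)
  null2 <- fit_null(stats::setNames(null$y, null$sample_ids),
                    grm_from_null(null), covariates = covs,
                    eig = list(values = null$eigvals, vectors = null$U),
                    trait = null$trait)
  score_scan(null2, geno, maf_min, exclude = fixed_variants)
}

# Reconstitute a grm-shaped object for refits on the same samples; the
# eigendecomposition is passed through, so the matrix itself is never used.
grm_from_null <- function(null) {
  G <- null$U %*% (null$eigvals * t(null$U))
  grm((G + t(G)) / 2, null$sample_ids)
}
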