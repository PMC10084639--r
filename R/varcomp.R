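# Restricted log-likelihood of the eigen-rotated single-trait LMM at a given
# variance ratio lambda = sigma_a2 / sigma_e2, with sigma_e2 profiled out.
# yr, Xr live in the rotated basis; d are the GRM eigenvalues.
rll_lambda <- function(lambda, yr, Xr, d) {
  v <- lambda * d + 1
  w <- 1 / v
  XtWX <- crossprod(Xr, Xr * w)
  bh <- solve(XtWX, crossprod(Xr, yr * w))
  r <- yr - Xr %*% bh
  n <- length(yr)
  c <- ncol(Xr)
  s2 <- sum(w * r^2) / (n - c)
  ld <- determinant(XtWX, logarithm = TRUE)$modulus[1]
  -0.5 * ((n - c) * (1 + log(2 * pi * s2)) + sum(log(v)) + ld)
}

# Maximise the restricted likelihood over log(lambda); returns the ratio, the
# profiled residual variance and the GLS fixed effects at the optimum.
reml_optimize <- function(yr, Xr, d, interval = c(-14, 14)) {
  f <- function(ll) rll_lambda(exp(ll), yr, Xr, d)
  opt <- stats::optimize(f, interval = interval, maximum = TRUE, tol = 1e-10)
  lambda <- exp(opt$maximum)
  # boundary: a maximiser at the lower edge means no resolvable genetic signal
  if (opt$maximum <= interval[1] + 1e-6 || f(interval[1]) >= opt$objective - 1e-10) {
    if (f(interval[1]) >= opt$objective - 1e-10) lambda <- 0
  }
  v <- lambda * d + 1
  w <- 1 / v
  XtWX <- crossprod(Xr, Xr * w)
  bh <- solve(XtWX, crossprod(Xr, yr * w))
  r <- yr - Xr %*% bh
  s2 <- sum(w * r^2) / (length(yr) - ncol(Xr))
  list(lambda = lambda, sigma_e2 = s2, beta = drop(bh),
       loglik = rll_lambda(max(lambda, 1e-300), yr, Xr, d))
}

# Expected (REML) information matrix for (sigma_a2, sigma_e2) on the rotated
# diagonal model; P = V^-1 - V^-1 X (X'V^-1X)^-1 X'V^-1 handled by rank-c
# algebra so the cost stays O(n c^2).
reml_expected_info <- function(sigma_a2, sigma_e2, d, Xr) {
  v <- sigma_a2 * d + sigma_e2
  w <- 1 / v
  U1 <- Xr * w
  C <- solve(crossprod(Xr, U1))
  Mii <- rowSums((U1 %*% C) * U1)
  tr_pair <- function(a, b) {
    Qa <- crossprod(U1, a * U1)
    Qb <- crossprod(U1, b * U1)
    sum(w^2 * a * b) - 2 * sum(w * a * b * Mii) + sum(diag(C %*% Qa %*% C %*% Qb))
  }
  ones <- rep(1, length(d))
  0.5 * matrix(c(tr_pair(d, d), tr_pair(d, ones),
                 tr_pair(d, ones), tr_pair(ones, ones)), 2, 2)
}

#' Single-trait REML estimation of genomic heritability
#'
#' Fits `y = mu + u + e` with `u ~ N(0, G sigma_a2)` and
#' `e ~ N(0, D sigma_e2)`, `D = diag(1/w_i)` (identity without weights), by
#' profiled REML on the eigendecomposed problem: the weighted model is
#' transformed by `D^{-1/2}` so a single eigendecomposition and a 1-D search
#' over the variance ratio suffice. Standard errors come from the inverse
#' expected information.
#'
#' @param y numeric phenotype vector aligned to the GRM rows (names optional;
#'   if named, they are matched against the GRM sample ids). Missing entries
#'   are dropped together with their GRM rows.
#' @param g a [grm()].
#' @param weights optional positive record weights aligned to `y`; the
#'   residual variance of record i is `sigma_e2 / weights[i]`.
#' @param max_ratio log-scale bound of the variance-ratio search.
#' @return list of class `var_components`: `sigma_a2` (additive genetic
#'   variance on the per-individual scale, i.e. the per-unit-G component
#'   times the mean GRM diagonal), `sigma_e2`, `h2 = sigma_a2 /
#'   (sigma_a2 + sigma_e2)`, `h2_se` (inverse expected information, delta
#'   method), `n_used`, `converged`, `identifiable`, `lambda` (the
#'   per-unit-G variance ratio), `loglik`.
#' @export
reml_single <- function(y, g, weights = NULL, max_ratio = 14) {
  if (!is.null(names(y))) {
    g <- subset_grm(g, names(y))
  }
  stopifnot(length(y) == length(g$sample_ids))
  keep <- !is.na(y)
  y <- y[keep]
  G <- g$matrix[keep, keep, drop = FALSE]
  n <- length(y)
  if (n < 10) stop("too few non-missing records for REML")
  # mean genomic variance per individual: converts the per-unit-G component
  # to the phenotypic scale (a centred GRM's diagonal is the heterozygosity,
  # not 1)
  tau <- mean(diag(G))
  if (!is.null(weights)) {
    weights <- weights[keep]
    if (any(!is.finite(weights) | weights <= 0)) stop("weights must be positive")
    # normalise so the mean residual multiplier mean(1/w) is 1: sigma_e2 is
    # then the average residual variance (constant weights reduce to the
    # unweighted fit)
    weights <- weights * mean(1 / weights)
    s <- sqrt(weights)
    G <- s * sweep(G, 2, s, `*`)  # D^{-1/2} G D^{-1/2}
    y <- s * y
    X <- matrix(s, ncol = 1)
  } else {
    X <- matrix(1, n, 1)
  }
  ev <- eigen(G, symmetric = TRUE)
  dvals <- pmax(ev$values, 0)
  yr <- crossprod(ev$vectors, y)
  Xr <- crossprod(ev$vectors, X)

  identifiable <- stats::sd(dvals) > 1e-8 * max(mean(dvals), 1)
  if (!identifiable) {
    s2 <- stats::var(drop(y))
    out <- list(sigma_a2 = 0, sigma_e2 = s2, h2 = 0, h2_se = NA_real_,
                n_used = n, converged = TRUE, identifiable = FALSE,
                lambda = 0, loglik = NA_real_)
    class(out) <- "var_components"
    return(out)
  }

  fit <- reml_optimize(yr, Xr, dvals, c(-max_ratio, max_ratio))
  sigma_e2 <- fit$sigma_e2
  sa_unit <- fit$lambda * sigma_e2          # component on the G scale
  sigma_a2 <- sa_unit * tau                 # per-individual genetic variance
  floor_ <- 1e-8 * stats::var(drop(y))
  if (sigma_a2 < floor_) sigma_a2 <- 0
  h2 <- sigma_a2 / (sigma_a2 + sigma_e2)

  h2_se <- NA_real_
  info <- try(reml_expected_info(max(sa_unit, floor_), sigma_e2, dvals, Xr),
              silent = TRUE)
  if (!inherits(info, "try-error")) {
    V <- try(solve(info), silent = TRUE)
    if (!inherits(V, "try-error")) {
      # delta method on h2(sa_unit, se) = sa_unit*tau / (sa_unit*tau + se)
      tot <- sa_unit * tau + sigma_e2
      gr <- c(tau * sigma_e2, -sa_unit * tau) / tot^2
      h2_var <- drop(t(gr) %*% V %*% gr)
      if (is.finite(h2_var) && h2_var >= 0) h2_se <- sqrt(h2_var)
    }
  }
  out <- list(sigma_a2 = sigma_a2, sigma_e2 = sigma_e2, h2 = h2, h2_se = h2_se,
              n_used = n, converged = TRUE, identifiable = TRUE,
              lambda = fit$lambda, loglik = fit$loglik)
  class(out) <- "var_components"
  out
}

#' @export
print.var_components <- function(x, ...) {
  cat(sprintf("var_components: h2 = %.3f (SE %s), sigma_a2 = %.4g, sigma_e2 = %.4g, n = %d%s\n",
              x$h2, ifelse(is.na(x$h2_se), "NA", sprintf("%.3f", x$h2_se)),
              x$sigma_a2, x$sigma_e2, x$n_used,
              ifelse(x$identifiable, "", " [not identifiable]")))
  invisible(x)
}

#' Multi-trait genetic and residual covariance estimation
#'
#' EM iterations on the GRM-eigen-rotated complete-case phenotype matrix
#' under the matrix-variate null model `vec(Y) ~ N(., G (x) Vg + I (x) Ve)`,
#' with a GLS intercept per trait re-estimated every iteration and each
#' update projected onto the positive semi-definite cone.
#'
#' @param Y complete-case n x d numeric matrix, rows aligned to the GRM (if
#'   rownames are present they are matched against the GRM sample ids).
#' @param g a [grm()].
#' @param max_iter maximum EM iterations (default 200).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param debug if `TRUE`, the per-iteration log-likelihood trace is kept in
#'   `$loglik_trace` (used to verify EM monotonicity).
#' @return list of class `mt_vc`: `Vg`, `Ve` (d x d), `converged`, `n_iter`,
#'   `degenerate`, `loglik`.
#' @export
estimate_mt_vc <- function(Y, g, max_iter = 200, tol = 1e-6, debug = FALSE) {
  Y <- as.matrix(Y)
  if (anyNA(Y)) stop("Y must be complete-case (no missing entries)")
  if (!is.null(rownames(Y))) g <- subset_grm(g, rownames(Y))
  stopifnot(nrow(Y) == length(g$sample_ids))
  d <- ncol(Y)
  n <- nrow(Y)
  if (d == 1) {
    vc <- reml_single(drop(Y), g)
    # Vg stays on the per-unit-G scale (it multiplies GRM eigenvalues)
    out <- list(Vg = matrix(vc$lambda * vc$sigma_e2,
                            dimnames = list(colnames(Y), colnames(Y))),
                Ve = matrix(vc$sigma_e2, dimnames = list(colnames(Y), colnames(Y))),
                converged = vc$converged, n_iter = 0L, degenerate = FALSE,
                loglik = vc$loglik)
    class(out) <- "mt_vc"
    return(out)
  }

  degenerate <- FALSE
  cv <- stats::cov(Y)
  if (min(eigen(cv, symmetric = TRUE, only.values = TRUE)$values) <
      1e-10 * mean(diag(cv))) {
    warning("phenotype matrix is (near) rank-deficient; estimates will be degenerate")
    degenerate <- TRUE
  }

  ev <- eigen(g$matrix, symmetric = TRUE)
  dvals <- pmax(ev$values, 0)
  Yr <- crossprod(ev$vectors, Y)
  wr <- drop(crossprod(ev$vectors, rep(1, n)))

  psd <- function(M) {
    M <- (M + t(M)) / 2
    e <- eigen(M, symmetric = TRUE)
    lo <- 1e-12 * max(e$values, 1e-12)
    e$vectors %*% (pmax(e$values, lo) * t(e$vectors))
  }

  Vg <- psd(cv / 2)
  Ve <- psd(cv / 2)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    inv_list <- vector("list", n)
    ll <- 0
    A <- matrix(0, d, d)
    b <- numeric(d)
    for (i in seq_len(n)) {
      Si <- dvals[i] * Vg + Ve
      inv <- solve(Si)
      inv_list[[i]] <- inv
      A <- A + wr[i]^2 * inv
      b <- b + wr[i] * drop(inv %*% Yr[i, ])
    }
    alpha <- solve(A, b)
    Vg_new <- matrix(0, d, d)
    Ve_new <- matrix(0, d, d)
    for (i in seq_len(n)) {
      r <- Yr[i, ] - wr[i] * alpha
      inv <- inv_list[[i]]
      ll <- ll - 0.5 * (determinant(dvals[i] * Vg + Ve)$modulus[1] +
                          drop(t(r) %*% inv %*% r))
      gV <- dvals[i] * Vg
      mg <- drop(gV %*% inv %*% r)
      Cg <- gV - gV %*% inv %*% gV
      if (dvals[i] > 1e-10) {
        Vg_new <- Vg_new + (tcrossprod(mg) + Cg) / dvals[i]
      } else {
        Vg_new <- Vg_new + Vg  # no information: keep the prior contribution
      }
      e <- r - mg
      Ce <- Ve - Ve %*% inv %*% Ve
      Ve_new <- Ve_new + tcrossprod(e) + Ce
    }
    Vg <- psd(Vg_new / n)
    Ve <- psd(Ve_new / n)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  tn <- colnames(Y)
  dimnames(Vg) <- dimnames(Ve) <- list(tn, tn)
  out <- list(Vg = Vg, Ve = Ve, converged = converged, n_iter = it,
              degenerate = degenerate, loglik = ll_trace[length(ll_trace)])
  if (debug) out$loglik_trace <- ll_trace
  class(out) <- "mt_vc"
  out
}

#' @export
print.mt_vc <- function(x, ...) {
  d <- ncol(x$Vg)
  ratio <- diag(x$Vg) / diag(x$Ve)
  cat(sprintf("mt_vc: %d traits, per-trait Vg/Ve %s; %sconverged in %d iterations%s\n",
              d, paste(sprintf("%.2f", ratio), collapse = "/"),
              ifelse(x$converged, "", "NOT "), x$n_iter,
              ifelse(x$degenerate, " [degenerate]", "")))
  invisible(x)
}
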