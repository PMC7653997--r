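# Null-model REML and the mixed-linear-model association scan.
#
# Model: y = 1 mu + u + e with u ~ N(0, G sigma_u^2), e ~ N(0, I sigma_e^2).
# After rotating by the eigenvectors of G the covariance is diagonal, so
# the restricted likelihood profiles to a one-dimensional function of
# h2 = sigma_u^2 / (sigma_u^2 + sigma_e^2), maximized by Brent search.
# The variance components are then held fixed while each variant is
# tested by generalized least squares, exactly the two-step scheme of
# standard MLMA software.

# Restricted log-likelihood profiled over the common scale sigma^2,
# as a function of h2, in the rotated basis.
reml_profile_ll <- function(h2, d, ystar, xstar, n) {
  v <- h2 * d + (1 - h2)
  xv <- xstar^2 / v
  xtx <- sum(xv)
  beta <- sum(xstar * ystar / v) / xtx
  r <- ystar - xstar * beta
  ypy <- sum(r^2 / v)
  sigma2 <- ypy / (n - 1)
  -0.5 * ((n - 1) * (log(2 * pi) + log(sigma2) + 1) + sum(log(v)) + log(xtx))
}

# Unprofiled restricted log-likelihood in (sigma_u2, sigma_e2); used for
# the observed-information standard error.
reml_ll_vc <- function(su, se, d, ystar, xstar, n) {
  v <- su * d + se
  if (any(v <= 0)) return(-Inf)
  xtx <- sum(xstar^2 / v)
  beta <- sum(xstar * ystar / v) / xtx
  r <- ystar - xstar * beta
  -0.5 * ((n - 1) * log(2 * pi) + sum(log(v)) + log(xtx) + sum(r^2 / v))
}

#' Null-model REML for a single trait
#'
#' Restricted maximum likelihood for `y = 1 mu + u + e` with
#' `u ~ N(0, G sigma_u^2)`. The GRM is eigendecomposed once and the
#' likelihood maximized over the heritability ratio by Brent search with
#' a profiled scale, which is exact for this one-kernel model. The
#' standard error of h2 comes from the numeric observed information of
#' the two variance components and the delta method.
#'
#' @param y Corrected trait vector (one value per GRM individual).
#' @param grm A `grm`.
#' @param eig Optional precomputed [grm_eigen()] result.
#' @return A `varcomp`: `sigma_u2`, `sigma_e2`, `h2`, `se_h2`, `loglik`,
#'   `converged`, `n`.
#' @export
fit_null_reml <- function(y, grm, eig = NULL) {
  n <- length(y)
  if (n != nrow(grm$K)) stop_data("length(y) does not match the GRM dimension")
  if (anyNA(y)) stop_data("y contains missing values")
  if (n < 3) stop_data("need at least 3 individuals")
  eig <- eig %||% grm_eigen(grm)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  ystar <- drop(crossprod(U, y))
  xstar <- drop(crossprod(U, rep(1, n)))
  opt <- optimize(reml_profile_ll, c(1e-6, 1 - 1e-6), maximum = TRUE,
                  tol = 1e-9, d = d, ystar = ystar, xstar = xstar, n = n)
  h2 <- opt$maximum
  v <- h2 * d + (1 - h2)
  xtx <- sum(xstar^2 / v)
  beta <- sum(xstar * ystar / v) / xtx
  sigma2 <- sum((ystar - xstar * beta)^2 / v) / (n - 1)
  sigma_u2 <- max(h2 * sigma2, 1e-8)
  sigma_e2 <- max((1 - h2) * sigma2, 1e-8)
  se_h2 <- tryCatch({
    par <- c(sigma_u2, sigma_e2)
    step <- pmax(1e-4 * par, 1e-8)
    f <- function(p) reml_ll_vc(p[1], p[2], d, ystar, xstar, n)
    H <- matrix(0, 2, 2)
    for (i in 1:2) for (j in 1:2) {
      ei <- ej <- c(0, 0); ei[i] <- step[i]; ej[j] <- step[j]
      H[i, j] <- (f(par + ei + ej) - f(par + ei - ej) -
                  f(par - ei + ej) + f(par - ei - ej)) / (4 * step[i] * step[j])
    }
    V <- solve(-(H + t(H)) / 2)
    s <- sum(par)
    gr <- c(par[2], -par[1]) / s^2
    qf <- drop(t(gr) %*% V %*% gr)
    # near the h2 = 0 boundary the information can be numerically singular
    if (!is.finite(qf) || qf < 0) NA_real_ else sqrt(qf)
  }, error = function(e) NA_real_)
  structure(list(sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
                 h2 = sigma_u2 / (sigma_u2 + sigma_e2), se_h2 = se_h2,
                 loglik = opt$objective, converged = TRUE, n = n),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("<varcomp> sigma_u2 = %.4g, sigma_e2 = %.4g, h2 = %.3f (SE %.3f), logRL = %.3f\n",
              x$sigma_u2, x$sigma_e2, x$h2,
              if (is.na(x$se_h2)) NA else x$se_h2, x$loglik))
  invisible(x)
}

#' Mixed-linear-model association scan
#'
#' Tests every variant in turn under `y = 1 mu + x b + u + e` with the
#' covariance `V = G sigma_u^2 + I sigma_e^2` held fixed at the
#' null-model estimates. Estimates are generalized least squares in the
#' rotated (diagonal) basis; `se` comes from the GLS information, `z =
#' b/se`, and `p` from the two-sided standard-normal tail. Monomorphic
#' variants are flagged and emitted with `z = 0`, `p = 1` rather than
#' dropped. When `sigma_u2 = 0` the scan reduces exactly to per-variant
#' OLS with known residual variance.
#'
#' @param g A `geno_matrix` (fractional imputed dosages in \[0, 2\] are
#'   accepted).
#' @param y Corrected trait vector.
#' @param grm A `grm` on the same individuals.
#' @param vc A `varcomp` from [fit_null_reml()] on the same `y`/`grm`.
#' @param eig Optional precomputed [grm_eigen()] result.
#' @return A `gwas_result` data.frame: `variant_id`, `chrom`, `pos`,
#'   `maf`, `beta`, `se`, `z`, `p`, `monomorphic`.
#' @export
run_mlma <- function(g, y, grm, vc, eig = NULL) {
  X <- impute_dosage(g$dosage)
  n <- nrow(X)
  if (length(y) != n) stop_data("length(y) does not match the genotypes")
  if (n != nrow(grm$K)) stop_data("GRM dimension does not match the genotypes")
  eig <- eig %||% grm_eigen(grm)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  w <- 1 / (vc$sigma_u2 * d + vc$sigma_e2)
  ystar <- drop(crossprod(U, y))
  ostar <- drop(crossprod(U, rep(1, n)))
  Xstar <- crossprod(U, X)
  a11 <- sum(w * ostar^2)
  a12 <- drop(crossprod(Xstar, w * ostar))
  a22 <- drop(crossprod(Xstar^2, w))
  b1 <- sum(w * ostar * ystar)
  b2 <- drop(crossprod(Xstar, w * ystar))
  colvar <- colMeans(X^2) - colMeans(X)^2
  mono <- colvar <= 1e-12
  det <- a11 * a22 - a12^2
  det[mono] <- NA
  beta <- (a11 * b2 - a12 * b1) / det
  se <- sqrt(a11 / det)
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1]
  beta[mono] <- 0; se[mono] <- NA_real_; z[mono] <- 0; p[mono] <- 1
  if (any(mono))
    message(sprintf("%d monomorphic variant(s) emitted with z = 0, p = 1", sum(mono)))
  pf <- colMeans(X) / 2
  out <- data.frame(
    variant_id = g$map$variant_id,
    chrom = g$map$chrom,
    pos = g$map$pos,
    maf = pmin(pf, 1 - pf),
    beta = beta, se = se, z = z, p = p,
    monomorphic = mono,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' Run null REML + MLMA for several traits over one GRM
#'
#' @param g A `geno_matrix`.
#' @param corrected Data.frame of precorrected traits (plus `animal_id`).
#' @param grm A `grm`; its eigendecomposition is computed once and shared.
#' @param traits Trait columns to scan (default: every non-id column).
#' @return A list with `results` (named list of `gwas_result`) and
#'   `varcomps` (named list of `varcomp`).
#' @export
run_gwas <- function(g, corrected, grm, traits = NULL) {
  traits <- traits %||% setdiff(names(corrected), "animal_id")
  eig <- grm_eigen(grm)
  varcomps <- list()
  results <- list()
  for (tr in traits) {
    y <- corrected[[tr]]
    vc <- fit_null_reml(y, grm, eig = eig)
    varcomps[[tr]] <- vc
    results[[tr]] <- run_mlma(g, y, grm, vc, eig = eig)
  }
  list(results = results, varcomps = varcomps)
}
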