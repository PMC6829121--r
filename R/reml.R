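# REML for univariate and bivariate GBLUP models with a known relationship
# matrix. Both fits rotate the data by the eigenvectors of K once, after
# which every likelihood evaluation is O(n): in the rotated basis the
# univariate covariance is diagonal and the bivariate covariance is
# block-diagonal in 2x2 blocks d_i*G + R.

#' Eigendecomposition of a relationship matrix, reusable across fits
#'
#' Fitting many models on the same (sub)matrix repeats an O(n^3)
#' eigendecomposition; compute it once and pass it to the fitting
#' functions via their `eig` argument.
#'
#' @param K A [grm] or symmetric PD matrix.
#' @return `eigen()` result (symmetric), with line ids carried along.
#' @export
grm_eigen <- function(K) {
  e <- eigen(unclass(K), symmetric = TRUE)
  e$ids <- rownames(K)
  if (min(e$values) <= 0)
    stop("relationship matrix is not positive definite ",
         "(min eigenvalue ", format(min(e$values)), "); jitter it")
  e
}

uni_profile <- function(h2, d, ystar, xstar, n) {
  W <- h2 * d + (1 - h2)
  xw <- xstar / W
  cxx <- sum(xstar * xw)
  mu <- sum(ystar * xw) / cxx
  resid <- ystar - xstar * mu
  rss <- sum(resid^2 / W)
  s <- rss / (n - 1)
  ll <- -0.5 * ((n - 1) * (log(2 * pi) + 1 + log(s)) +
                  sum(log(W)) + log(cxx))
  list(ll = ll, mu = mu, s = s, resid = resid, W = W)
}

#' Fit a univariate GBLUP model by REML
#'
#' Model: `y = mu + u + e`, `u ~ N(0, g K)`, `e ~ N(0, r I)`. The
#' likelihood is profiled down to a one-dimensional optimization over the
#' heritability `h^2 = g / (g + r)` using the eigendecomposition of `K`.
#'
#' @param y Phenotype vector, length = `nrow(K)`, ideally named by line id.
#' @param K A [grm] or PD matrix.
#' @param eig Optional precomputed [grm_eigen()] of `K`.
#' @param tol Optimization tolerance on `h^2`.
#' @return Object of class `uni_reml`: `mu_hat`, `g_hat`, `r_hat`,
#'   `h2_hat`, `u_hat_o` (BLUPs, named), `loglik_reml`, `boundary` flag.
#' @export
fit_univariate_reml <- function(y, K, eig = NULL, tol = 1e-9) {
  y <- as.numeric(y)
  n <- length(y)
  if (!all(is.finite(y))) stop("phenotypes must be finite")
  if (n < 10) stop("need at least 10 observations for REML")
  if (var(y) == 0) stop("phenotype has zero variance")
  if (is.null(eig)) eig <- grm_eigen(K)
  if (length(eig$values) != n) stop("length(y) does not match dim(K)")
  d <- eig$values
  Q <- eig$vectors
  ystar <- drop(crossprod(Q, y))
  xstar <- drop(crossprod(Q, rep(1, n)))
  opt <- optimize(function(h2) uni_profile(h2, d, ystar, xstar, n)$ll,
                  interval = c(1e-8, 1 - 1e-8), maximum = TRUE, tol = tol)
  h2 <- opt$maximum
  prof <- uni_profile(h2, d, ystar, xstar, n)
  g <- h2 * prof$s
  r <- (1 - h2) * prof$s
  # BLUP in rotated basis: g*d_i / (g*d_i + r) * residual
  ustar <- h2 * d * prof$resid / prof$W
  u_hat <- drop(Q %*% ustar)
  names(u_hat) <- eig$ids
  structure(list(mu_hat = prof$mu, g_hat = g, r_hat = r, h2_hat = h2,
                 u_hat_o = u_hat, loglik_reml = prof$ll,
                 boundary = h2 < 1e-4 || h2 > 1 - 1e-4),
            class = "uni_reml")
}

#' Univariate BLUPs with fixed, known variance components
#'
#' Same prediction formula as [fit_univariate_reml()] but with `g`, `r`
#' (and optionally the intercept) supplied rather than estimated; used for
#' oracle analyses with the true simulation parameters.
#'
#' @inheritParams fit_univariate_reml
#' @param g,r Genetic and residual variances (`g >= 0`, `r > 0`).
#' @param mu Known intercept; `NULL` (default) estimates it by GLS.
#' @return A `uni_reml` object.
#' @export
blup_univariate_fixed <- function(y, K, g, r, mu = NULL, eig = NULL) {
  stopifnot(g >= 0, r > 0)
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(eig)) eig <- grm_eigen(K)
  d <- eig$values
  Q <- eig$vectors
  ystar <- drop(crossprod(Q, y))
  xstar <- drop(crossprod(Q, rep(1, n)))
  W <- g * d + r
  if (is.null(mu)) mu <- sum(ystar * xstar / W) / sum(xstar^2 / W)
  resid <- ystar - xstar * mu
  ustar <- g * d * resid / W
  u_hat <- drop(Q %*% ustar)
  names(u_hat) <- eig$ids
  ll <- -0.5 * (sum(log(W)) + sum(resid^2 / W) + log(sum(xstar^2 / W)) +
                  (n - 1) * log(2 * pi))
  structure(list(mu_hat = mu, g_hat = g, r_hat = r, h2_hat = g / (g + r),
                 u_hat_o = u_hat, loglik_reml = ll, boundary = FALSE),
            class = "uni_reml")
}

#' @export
print.uni_reml <- function(x, ...) {
  cat(sprintf(
    "Univariate REML fit: mu=%.4g g=%.4g r=%.4g (h2=%.3f)%s  logLik=%.3f\n",
    x$mu_hat, x$g_hat, x$r_hat, x$h2_hat,
    if (x$boundary) " [boundary]" else "", x$loglik_reml))
  invisible(x)
}

theta_to_chol <- function(th3) {
  matrix(c(exp(th3[1]), th3[2], 0, exp(th3[3])), 2L)
}

chol_to_theta <- function(S) {
  L <- t(chol(S))
  c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
}

# Negative REML log-likelihood and (optionally) GLS/BLUP byproducts for the
# bivariate model, everything vectorized over the n eigenvalues.
biv_eval <- function(G, R, d, Ystar, xstar, n, want_blup = FALSE,
                     gls = TRUE) {
  a <- d * G[1, 1] + R[1, 1]
  b <- d * G[1, 2] + R[1, 2]
  cc <- d * G[2, 2] + R[2, 2]
  det <- a * cc - b * b
  if (any(det <= 0) || any(a <= 0)) return(list(nll = 1e10))
  y1 <- Ystar[, 1]; y2 <- Ystar[, 2]
  x2 <- xstar * xstar
  C11 <- sum(x2 * cc / det); C12 <- -sum(x2 * b / det)
  C22 <- sum(x2 * a / det)
  detC <- C11 * C22 - C12 * C12
  if (detC <= 0) return(list(nll = 1e10))
  if (gls) {
    r1 <- sum(xstar * (cc * y1 - b * y2) / det)
    r2 <- sum(xstar * (a * y2 - b * y1) / det)
    mu1 <- (C22 * r1 - C12 * r2) / detC
    mu2 <- (C11 * r2 - C12 * r1) / detC
  } else {
    mu1 <- mu2 <- 0
  }
  e1 <- y1 - xstar * mu1
  e2 <- y2 - xstar * mu2
  quad <- sum((cc * e1 * e1 - 2 * b * e1 * e2 + a * e2 * e2) / det)
  nll <- 0.5 * (sum(log(det)) + quad + log(detC) +
                  (2 * n - 2) * log(2 * pi))
  if (!is.finite(nll)) return(list(nll = 1e10))
  out <- list(nll = nll, mu = c(mu1, mu2))
  if (want_blup) {
    w1 <- (cc * e1 - b * e2) / det
    w2 <- (a * e2 - b * e1) / det
    out$ustar <- cbind(d * (G[1, 1] * w1 + G[1, 2] * w2),
                       d * (G[1, 2] * w1 + G[2, 2] * w2))
  }
  out
}

finish_biv <- function(G, R, d, Ystar, xstar, Q, ids, n, converged,
                       loglik) {
  ev <- biv_eval(G, R, d, Ystar, xstar, n, want_blup = TRUE)
  U <- Q %*% ev$ustar
  dimnames(U) <- list(ids, c("trait1", "trait2"))
  eigG <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  eigR <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  structure(list(mu_hat = ev$mu, G_hat = G, R_hat = R, u_hat_o = U,
                 loglik_reml = loglik, converged = converged,
                 singular = min(eigG) < 1e-6 * max(eigG) ||
                   min(eigR) < 1e-6 * max(eigR)),
            class = "biv_reml")
}

#' Fit a bivariate GBLUP model by REML
#'
#' Model for stacked traits `y = vec(Y)`:
#' `u ~ N(0, G (x) K)`, `e ~ N(0, R (x) I)`, intercept per trait. `G` and
#' `R` are parameterized through log-Cholesky factors (guaranteeing
#' positive definiteness) and estimated by quasi-Newton maximization of
#' the REML log-likelihood; each evaluation costs O(n) after a one-time
#' eigendecomposition of `K`. Starting values are half the sample
#' covariance of `Y` for both matrices, with a diagonal-only restart if
#' needed; non-convergence is flagged, not thrown.
#'
#' @param Y n x 2 phenotype matrix (rownames = line ids).
#' @param K A [grm] or PD matrix.
#' @param eig Optional precomputed [grm_eigen()] of `K`.
#' @param maxit Maximum BFGS iterations.
#' @return Object of class `biv_reml`: `mu_hat` (length 2), `G_hat`,
#'   `R_hat` (2x2), `u_hat_o` (n x 2 BLUPs), `loglik_reml`, `converged`,
#'   `singular` flags.
#' @export
fit_bivariate_reml <- function(Y, K, eig = NULL, maxit = 500L) {
  Y <- as.matrix(Y)
  stopifnot(ncol(Y) == 2L)
  n <- nrow(Y)
  if (!all(is.finite(Y))) stop("phenotypes must be finite")
  if (n < 20) stop("need at least 20 observations for bivariate REML")
  if (is.null(eig)) eig <- grm_eigen(K)
  if (length(eig$values) != n) stop("nrow(Y) does not match dim(K)")
  d <- eig$values
  Q <- eig$vectors
  Ystar <- crossprod(Q, Y)
  xstar <- drop(crossprod(Q, rep(1, n)))

  S <- cov(Y)
  if (var(Y[, 1]) == 0 && var(Y[, 2]) == 0)
    stop("both phenotypes have zero variance")
  half <- 0.5 * S + diag(1e-8 * mean(diag(S)), 2L)
  starts <- list(c(chol_to_theta(half), chol_to_theta(half)),
                 c(chol_to_theta(diag(diag(half))),
                   chol_to_theta(diag(diag(half)))))
  obj <- function(theta) {
    Lg <- theta_to_chol(theta[1:3]); Lr <- theta_to_chol(theta[4:6])
    biv_eval(tcrossprod(Lg), tcrossprod(Lr), d, Ystar, xstar, n)$nll
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, obj, method = "BFGS",
            control = list(maxit = maxit, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
    if (!is.null(best) && best$convergence == 0) break
  }
  if (is.null(best) || best$convergence != 0) {
    # derivative-free fallback for likelihoods BFGS cannot handle
    # (e.g. degenerate phenotypes driving the covariances singular)
    nm <- tryCatch(
      optim(starts[[1]], obj, method = "Nelder-Mead",
            control = list(maxit = 10 * maxit)),
      error = function(e) NULL)
    if (!is.null(nm) && (is.null(best) || nm$value < best$value)) best <- nm
  }
  if (is.null(best))
    best <- list(par = starts[[1]], value = obj(starts[[1]]),
                 convergence = 1L)
  G <- tcrossprod(theta_to_chol(best$par[1:3]))
  R <- tcrossprod(theta_to_chol(best$par[4:6]))
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("estimated residual covariance is singular")
  finish_biv(G, R, d, Ystar, xstar, Q, eig$ids, n,
             converged = best$convergence == 0, loglik = -best$value)
}

#' Bivariate BLUPs with fixed, known covariance matrices
#'
#' Same prediction machinery as [fit_bivariate_reml()] but with `G` and
#' `R` supplied (no optimization); used for oracle analyses with the true
#' simulation parameters.
#'
#' @inheritParams fit_bivariate_reml
#' @param G,R 2x2 PD covariance matrices.
#' @param mu Known intercepts (length 2); `NULL` (default) estimates them
#'   by GLS.
#' @return A `biv_reml` object.
#' @export
blup_with_fixed_components <- function(Y, K, G, R, mu = NULL, eig = NULL) {
  Y <- as.matrix(Y)
  stopifnot(ncol(Y) == 2L, nrow(G) == 2L, nrow(R) == 2L)
  n <- nrow(Y)
  if (is.null(eig)) eig <- grm_eigen(K)
  d <- eig$values
  Q <- eig$vectors
  Ystar <- crossprod(Q, Y)
  xstar <- drop(crossprod(Q, rep(1, n)))
  if (!is.null(mu)) {
    # subtract the known mean and predict from the exact residuals
    Ystar <- Ystar - outer(xstar, mu)
    ev <- biv_eval(G, R, d, Ystar, xstar, n, want_blup = TRUE, gls = FALSE)
    U <- Q %*% ev$ustar
    dimnames(U) <- list(eig$ids, c("trait1", "trait2"))
    return(structure(list(mu_hat = mu, G_hat = G, R_hat = R, u_hat_o = U,
                          loglik_reml = -ev$nll, converged = TRUE,
                          singular = FALSE),
                     class = "biv_reml"))
  }
  ev <- biv_eval(G, R, d, Ystar, xstar, n)
  finish_biv(G, R, d, Ystar, xstar, Q, eig$ids, n,
             converged = TRUE, loglik = -ev$nll)
}

#' @export
print.biv_reml <- function(x, ...) {
  cat("Bivariate REML fit",
      if (!x$converged) "[NOT CONVERGED]",
      if (x$singular) "[near-singular covariance]", "\n")
  cat("  mu:", signif(x$mu_hat, 4), "\n")
  cat("  G: ", signif(x$G_hat[c(1, 2, 4)], 4), "(g11, g12, g22)\n")
  cat("  R: ", signif(x$R_hat[c(1, 2, 4)], 4), "(r11, r12, r22)\n")
  cat("  logLik:", signif(x$loglik_reml, 6), "\n")
  invisible(x)
}

#' Serialize a fit to a one-row data frame
#'
#' @param fit A `uni_reml` or `biv_reml` object.
#' @return One-row data frame of components, flags and log-likelihood.
#' @export
fit_summary_row <- function(fit) {
  if (inherits(fit, "uni_reml"))
    data.frame(model = "univariate", mu1 = fit$mu_hat, mu2 = NA_real_,
               g11 = fit$g_hat, g12 = NA_real_, g22 = NA_real_,
               r11 = fit$r_hat, r12 = NA_real_, r22 = NA_real_,
               loglik = fit$loglik_reml, converged = TRUE,
               flagged = fit$boundary)
  else
    data.frame(model = "bivariate", mu1 = fit$mu_hat[1], mu2 = fit$mu_hat[2],
               g11 = fit$G_hat[1, 1], g12 = fit$G_hat[1, 2],
               g22 = fit$G_hat[2, 2],
               r11 = fit$R_hat[1, 1], r12 = fit$R_hat[1, 2],
               r22 = fit$R_hat[2, 2],
               loglik = fit$loglik_reml, converged = fit$converged,
               flagged = fit$singular)
}
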