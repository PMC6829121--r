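# Shared fixtures and independent brute-force oracles. The oracles work
# from the full joint multivariate-normal covariance of (U, Y) assembled
# with kronecker() and dense solves -- deliberately naive linear algebra,
# independent of the package's eigendecomposition/Schur-complement paths.

# random symmetric PD matrix with ~unit diagonal (a GRM-like toy)
rand_pd <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(n * 2 * n), n, 2 * n)
  K <- tcrossprod(A) / (2 * n)
  K <- K / mean(diag(K))
  grm(K, ids = sprintf("T%02d", seq_len(n)))
}

# E[u_n1 | y_o1] under the univariate model (g, r), zero mean
oracle_single <- function(K, g, r, nidx, oidx, y_o1) {
  K <- unclass(K)
  V <- g * K + r * diag(nrow(K))
  drop(g * K[nidx, oidx] %*% solve(V[oidx, oidx], y_o1))
}

# E[u_n1 | y_o (both traits)] under the bivariate model, zero mean
oracle_cv1 <- function(K, G, R, nidx, oidx, Y_o) {
  K <- unclass(K)
  n <- nrow(K)
  SigU <- kronecker(G, K)
  SigY <- SigU + kronecker(R, diag(n))
  yo_idx <- c(oidx, n + oidx)
  y_o <- c(Y_o[, 1], Y_o[, 2])
  drop(SigU[nidx, yo_idx] %*% solve(SigY[yo_idx, yo_idx], y_o))
}

# E[u_n1 | u_o (both traits), y_n2] under the bivariate model, zero mean
oracle_cv2 <- function(K, G, R, nidx, oidx, U_o, y_n2) {
  K <- unclass(K)
  n <- nrow(K)
  m <- length(nidx)
  SigU <- kronecker(G, K)
  uo_idx <- c(oidx, n + oidx)
  yn2_idx <- n + nidx
  cov_uo_yn2 <- SigU[uo_idx, yn2_idx]
  var_yn2 <- SigU[yn2_idx, yn2_idx] + R[2, 2] * diag(m)
  Cond <- rbind(cbind(SigU[uo_idx, uo_idx], cov_uo_yn2),
                cbind(t(cov_uo_yn2), var_yn2))
  cvec <- cbind(SigU[nidx, uo_idx], SigU[nidx, yn2_idx])
  drop(cvec %*% solve(Cond, c(U_o[, 1], U_o[, 2], y_n2)))
}

# Schur complement via brute-force full inversion (oracle for
# conditional_blocks): inverse of the nn block of K^-1
oracle_schur <- function(K, nidx) {
  Kinv <- solve(unclass(K))
  solve(Kinv[nidx, nidx])
}

# a fixed-component biv_reml-shaped object for feeding predictors truth
fixed_fit <- function(G, R, U_o = NULL, mu = c(0, 0)) {
  structure(list(mu_hat = mu, G_hat = G, R_hat = R, u_hat_o = U_o,
                 loglik_reml = NA_real_, converged = TRUE,
                 singular = FALSE),
            class = "biv_reml")
}
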