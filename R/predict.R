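# The three genetic-value predictors for test-partition lines:
# single-trait GBLUP, multi-trait CV1 (training phenotypes only) and the
# two-step multi-trait CV2 (which additionally uses the test lines' own
# secondary-trait phenotypes).

check_blocks_fit <- function(u_hat, blocks) {
  if (length(u_hat) != ncol(blocks$projection))
    stop("fit has ", length(u_hat), " training BLUPs but blocks expect ",
         ncol(blocks$projection))
}

#' Single-trait GBLUP prediction for test lines
#'
#' Carries the training BLUPs of the focal trait to the test partition
#' through the relatedness projection: `u_n1 = Kno Koo^-1 u_o1`.
#'
#' @param fit A `uni_reml` fit on the training partition.
#' @param blocks [conditional_blocks()] for the same partition.
#' @return Named vector of predicted genetic values for the test lines.
#' @export
predict_single <- function(fit, blocks) {
  stopifnot(inherits(fit, "uni_reml"))
  check_blocks_fit(fit$u_hat_o, blocks)
  out <- drop(blocks$projection %*% fit$u_hat_o)
  names(out) <- blocks$test_ids
  out
}

#' Multi-trait CV1 prediction for test lines
#'
#' Same projection as [predict_single()] but using the focal-trait BLUPs
#' from the bivariate fit, so secondary-trait information enters only
#' through the training lines (no phenotypes of the test lines are used).
#'
#' @param fit A `biv_reml` fit on the training partition.
#' @param blocks [conditional_blocks()] for the same partition.
#' @return Named vector of predicted genetic values for the test lines.
#' @export
predict_cv1 <- function(fit, blocks) {
  stopifnot(inherits(fit, "biv_reml"))
  check_blocks_fit(fit$u_hat_o[, 1], blocks)
  out <- drop(blocks$projection %*% fit$u_hat_o[, 1])
  names(out) <- blocks$test_ids
  out
}

#' Two-step multi-trait CV2 prediction for test lines
#'
#' Adds to the CV1 prediction the information carried by the test lines'
#' own secondary-trait phenotypes `y_n2`:
#' \deqn{\hat u_{n1} = P\hat u_{o1} +
#'   \hat g_{12}\,\Sigma_c V_c^{-1}\,(y_{n2} - \hat\mu_2 - P\hat u_{o2}),}
#' where `P = Kno Koo^-1`, `Sigma_c` is the Schur complement of the
#' training block (the conditional genetic covariance of test lines), and
#' `V_c = g22 * Sigma_c + r22 * I` is the conditional variance of `y_n2`.
#' The solve against `V_c` uses its Cholesky factor; no explicit inverse.
#'
#' @param fit A `biv_reml` fit on the training partition (estimated or
#'   fixed components).
#' @param blocks [conditional_blocks()] for the same partition.
#' @param y_n2 Secondary-trait phenotypes of the test lines, in
#'   `blocks$test_ids` order.
#' @return Named vector of predicted genetic values for the test lines.
#' @export
predict_cv2 <- function(fit, blocks, y_n2) {
  stopifnot(inherits(fit, "biv_reml"))
  check_blocks_fit(fit$u_hat_o[, 1], blocks)
  y_n2 <- as.numeric(y_n2)
  m <- length(blocks$test_ids)
  if (length(y_n2) != m)
    stop("y_n2 has length ", length(y_n2), ", expected ", m)
  g12 <- fit$G_hat[1, 2]
  g22 <- fit$G_hat[2, 2]
  r22 <- fit$R_hat[2, 2]
  if (r22 <= 0) stop("V_c is singular: residual variance r22 must be > 0")
  base1 <- drop(blocks$projection %*% fit$u_hat_o[, 1])
  base2 <- drop(blocks$projection %*% fit$u_hat_o[, 2])
  Vc <- g22 * blocks$schur + diag(r22, m)
  Vc <- (Vc + t(Vc)) / 2
  ch <- chol(Vc)
  w <- backsolve(ch, forwardsolve(t(ch), y_n2 - fit$mu_hat[2] - base2))
  out <- base1 + g12 * drop(blocks$schur %*% w)
  names(out) <- blocks$test_ids
  out
}
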