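# Accuracy estimators for cross-validated genomic predictions: true
# (against simulated genetic values), naive phenotype-validated,
# full-data-EBV (demonstrably invalid), parametric selection-index,
# semi-parametric bias-corrected, and CV2* (clone / nearest-relative
# surrogate validation).

safe_cor <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch between vectors")
  if (length(a) < 3) stop("need at least 3 pairs for a correlation")
  if (sd(a) == 0 || sd(b) == 0) {
    warning("zero variance; correlation undefined, returning NA")
    return(NA_real_)
  }
  cor(a, b)
}

h_factor <- function(h1_sq, h_power) {
  stopifnot(h1_sq > 0, h1_sq <= 1)
  h1_sq^h_power
}

#' True prediction accuracy
#'
#' Pearson correlation between predicted and true (simulated) genetic
#' values of the test lines.
#'
#' @param u_hat Predicted genetic values.
#' @param u_true True genetic values, same lines and order.
#' @return Correlation in `[-1, 1]`, or `NA` if either input is constant.
#' @export
true_accuracy <- function(u_hat, u_true) safe_cor(u_hat, u_true)

#' Naive phenotype-validated accuracy estimate
#'
#' The standard cross-validation score when true genetic values are
#' unknown: correlation of predictions with the test lines' own focal
#' phenotypes, divided by `h = sqrt(h1_sq)` to account for the larger
#' variance of phenotypes relative to genetic values (under the model,
#' `cor(u_hat, y) = cor(u_hat, u) * h`). Set `h_power = 1` to divide by
#' `h^2` instead.
#'
#' @param u_hat Predicted genetic values of test lines.
#' @param y_n1 Focal-trait phenotypes of the same lines.
#' @param h1_sq Focal-trait heritability used for the correction.
#' @param h_power Exponent on `h1_sq` in the correction denominator
#'   (default `0.5`).
#' @return Corrected accuracy estimate (may exceed 1).
#' @export
naive_accuracy <- function(u_hat, y_n1, h1_sq, h_power = 0.5) {
  safe_cor(u_hat, y_n1) / h_factor(h1_sq, h_power)
}

#' Full-data EBV predictand (invalid by construction)
#'
#' Fits the bivariate model to the complete dataset -- including the test
#' lines' focal phenotypes -- and returns their focal-trait BLUPs. Scoring
#' predictions against this predictand violates the separation of training
#' and testing data and dramatically over-estimates accuracy; the function
#' exists so that this failure mode can be demonstrated and quantified.
#'
#' @param Y_all Complete n x 2 phenotype matrix (all lines).
#' @param grm The full [grm].
#' @param test_ids Lines whose EBVs to return.
#' @param eig Optional precomputed [grm_eigen()] of the full GRM.
#' @return Named vector of full-data focal-trait BLUPs for `test_ids`.
#' @export
full_data_ebv_predictand <- function(Y_all, grm, test_ids, eig = NULL) {
  fit <- fit_bivariate_reml(Y_all, grm, eig = eig)
  idx <- match(test_ids, rownames(fit$u_hat_o))
  if (anyNA(idx)) stop("test ids not present in phenotype matrix")
  setNames(fit$u_hat_o[idx, 1], test_ids)
}

#' Parametric (selection-index) accuracy estimate
#'
#' Treats the prediction as a selection index `I` for the phenotype `y`:
#' its accuracy as a predictor of the genetic value of `y` is the genetic
#' correlation between index and phenotype times the square root of the
#' index heritability, `rho_g(I, y) * h_I`. Both parameters are estimated
#' by a bivariate REML fit of `(I, y)` on the validation lines only, using
#' the validation block of the GRM, so no training-stage estimates leak
#' into the score.
#'
#' @param u_hat Predicted genetic values (the index) of validation lines.
#' @param y_n1 Focal-trait phenotypes of the same lines.
#' @param K_nn Validation block of the GRM (PD).
#' @param eig Optional precomputed [grm_eigen()] of `K_nn`.
#' @return Estimated accuracy, or `NA` if the fit does not converge.
#' @export
parametric_accuracy <- function(u_hat, y_n1, K_nn, eig = NULL) {
  Y <- cbind(index = as.numeric(u_hat), y = as.numeric(y_n1))
  fit <- tryCatch(fit_bivariate_reml(Y, K_nn, eig = eig),
                  error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(NA_real_)
  g_Iy <- fit$G_hat[1, 2]
  g_yy <- fit$G_hat[2, 2]
  p_II <- fit$G_hat[1, 1] + fit$R_hat[1, 1]
  if (g_yy <= 0 || p_II <= 0) return(NA_real_)
  # rho_g(I,y) * h_I = g_Iy / sqrt(g_II g_yy) * sqrt(g_II / p_II); the
  # index's own genetic variance cancels, keeping the estimate stable
  # when the index carries little genetic signal
  g_Iy / sqrt(g_yy * p_II)
}

#' Semi-parametric bias of the naive CV2 accuracy estimate
#'
#' The CV2 predictor uses the test lines' secondary phenotypes `y_n2`,
#' whose residuals are correlated (`cov = r12 I`) with the residuals of
#' the focal phenotypes `y_n1` used as the naive predictand. The resulting
#' expected excess of the sample covariance `cov(u_hat3, y_n1)` over
#' `cov(u_hat3, u_n1)` is, exactly,
#' \deqn{\hat g_{12}\,\hat r_{12}\,
#'   \mathrm{tr}(S\,\Sigma_c V_c^{-1})/(n-1), \quad S = I - 11^\top/n,}
#' which this function evaluates together with its correlation-scale
#' version (divided by the sample standard deviations of `u_hat3` and
#' `y_n1`). The bias is exactly zero when either `g12` or `r12` is zero,
#' and its sign is the sign of `g12 * r12`.
#'
#' @param fit The training `biv_reml` fit (or fixed-component oracle fit)
#'   whose `g12`, `g22`, `r12`, `r22` enter the correction.
#' @param blocks [conditional_blocks()] of the partition.
#' @param u_hat3 CV2 predictions for the test lines.
#' @param y_n1 Focal phenotypes of the test lines.
#' @return Object of class `bias_correction`: `bias_cov`
#'   (covariance scale), `bias_hat` (correlation scale), `n`, and the
#'   components used.
#' @export
semiparametric_bias <- function(fit, blocks, u_hat3, y_n1) {
  stopifnot(inherits(fit, "biv_reml"))
  m <- length(blocks$test_ids)
  if (m < 3) stop("need at least 3 test lines")
  g12 <- fit$G_hat[1, 2]; g22 <- fit$G_hat[2, 2]
  r12 <- fit$R_hat[1, 2]; r22 <- fit$R_hat[2, 2]
  Vc <- g22 * blocks$schur + diag(r22, m)
  A <- blocks$schur %*% solve((Vc + t(Vc)) / 2)   # Sigma_c V_c^-1
  tr_SA <- sum(diag(A)) - sum(A) / m              # tr((I - 11'/m) A)
  bias_cov <- g12 * r12 * tr_SA / (m - 1)
  v_u <- var(as.numeric(u_hat3)); v_y <- var(as.numeric(y_n1))
  bias_hat <- if (v_u > 0 && v_y > 0) bias_cov / sqrt(v_u * v_y)
              else NA_real_
  structure(list(bias_cov = bias_cov, bias_hat = bias_hat, n = m,
                 g12 = g12, r12 = r12, trace_term = tr_SA,
                 var_u_hat = v_u, var_y = v_y),
            class = "bias_correction")
}

#' @export
print.bias_correction <- function(x, ...) {
  cat(sprintf(
    "CV2 naive-accuracy bias: %.4g (correlation scale; cov scale %.4g)\n",
    x$bias_hat, x$bias_cov))
  invisible(x)
}

#' Semi-parametric bias-corrected accuracy estimate
#'
#' Subtracts the estimated residual-correlation bias from the raw
#' correlation with the focal phenotypes, then applies the same
#' heritability correction as [naive_accuracy()].
#'
#' @param naive_cor Raw (uncorrected) correlation `cor(u_hat3, y_n1)`.
#' @param bias A [semiparametric_bias()] object.
#' @param h1_sq Focal-trait heritability.
#' @param h_power Exponent on `h1_sq` in the correction (default `0.5`).
#' @return Corrected accuracy estimate.
#' @export
semiparametric_accuracy <- function(naive_cor, bias, h1_sq, h_power = 0.5) {
  stopifnot(inherits(bias, "bias_correction"))
  (naive_cor - bias$bias_hat) / h_factor(h1_sq, h_power)
}

#' CV2* accuracy estimate from clone or nearest-relative surrogates
#'
#' Scores CV2-style predictions against focal-trait phenotypes measured on
#' individuals that share genetics with the test lines but not their
#' micro-environment: a second, independently raised clone copy (`clone`
#' design) or the most closely related held-out line (`relative` design).
#' Because the surrogate's residual is independent of the secondary-trait
#' phenotype used for prediction, the residual-correlation bias channel of
#' the naive estimator is severed.
#'
#' The heritability correction matches the design's variance convention:
#' in the clone design each phenotype copy carries residual variance
#' `2 r11`, so the correction divides by
#' `sqrt(h1_sq / (h1_sq + 2 r11))`; in the relative design by
#' `sqrt(h1_sq)` (per-trait phenotypic variance 1). Apply the same factor
#' to every method compared so model comparison is unaffected.
#'
#' @param u_hat3 Predictions for the test lines (for the clone design,
#'   computed from copy-A secondary phenotypes).
#' @param y_x1 Surrogate focal phenotypes: copy-B (`clone`) or the
#'   surrogate relatives' phenotypes in test-line order (`relative`).
#' @param h1_sq Focal-trait heritability.
#' @param design `"clone"` or `"relative"`.
#' @param r11 Focal residual variance; default `1 - h1_sq` (standardized
#'   phenotypes).
#' @return Corrected accuracy estimate.
#' @export
cv2star_accuracy <- function(u_hat3, y_x1,
                             h1_sq, design = c("clone", "relative"),
                             r11 = 1 - h1_sq) {
  design <- match.arg(design)
  raw <- safe_cor(u_hat3, y_x1)
  denom <- switch(design,
                  clone = sqrt(h1_sq / (h1_sq + 2 * r11)),
                  relative = sqrt(h1_sq))
  raw / denom
}
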