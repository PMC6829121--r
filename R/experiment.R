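# Factorial simulation study: for each replicate and architecture,
# simulate a trait pair on the GRM (common random numbers across
# architectures), partition, fit, predict, score with every estimator the
# design supports, and summarise model-selection behaviour.

offset_seed <- function(stream_seed, r) {
  as.integer((as.numeric(stream_seed) + r - 1) %% (.Machine$integer.max - 1) + 1)
}

design_test_fraction <- function(design) {
  switch(design, naive = 0.1, parametric = 0.5, clone = 0.1,
         relative = 0.1)
}

arch_cols <- function(arch_row) {
  data.frame(h1_sq = arch_row$h1_sq, h2_sq = arch_row$h2_sq,
             rho_g = arch_row$rho_g, rho_r = arch_row$rho_r)
}

acc_row <- function(arch_row, r, method, estimator, value, converged) {
  cbind(arch_cols(arch_row),
        data.frame(rep = r, method = method, estimator = estimator,
                   value = value, converged = converged))
}

na_rows <- function(arch_row, r, methods, estimators) {
  do.call(rbind, lapply(seq_along(methods), function(i)
    acc_row(arch_row, r, methods[i], estimators[i], NA_real_, FALSE)))
}

# One replicate x architecture cell for a given design; returns a small
# data.frame of accuracy rows.
run_cell <- function(design, grm, arch_row, r, rep_data, part, blocks,
                     Koo, eig_oo, eig_nn, eig_full, Y_full,
                     include_fulldata_ebv, h_power) {
  arch <- genetic_architecture(arch_row$h1_sq, arch_row$h2_sq,
                               arch_row$rho_g, arch_row$rho_r)
  test <- part$test_ids
  train <- part$train_ids
  Y_o <- rep_data$Y[train, , drop = FALSE]
  u_n1 <- rep_data$U[test, 1]
  y_n1 <- rep_data$Y[test, 1]
  h1 <- arch$h1_sq

  ufit <- fit_univariate_reml(Y_o[, 1], Koo, eig = eig_oo)
  bfit <- fit_bivariate_reml(Y_o, Koo, eig = eig_oo)
  ok <- bfit$converged && !bfit$singular

  pred_single <- predict_single(ufit, blocks)
  pred_cv1 <- predict_cv1(bfit, blocks)
  y_n2_pred <- if (design == "clone") rep_data$Y_a[test, 2]
               else rep_data$Y[test, 2]
  pred_cv2 <- predict_cv2(bfit, blocks, y_n2_pred)

  rows <- list(
    acc_row(arch_row, r, "single", "true",
            true_accuracy(pred_single, u_n1), TRUE),
    acc_row(arch_row, r, "cv1", "true",
            true_accuracy(pred_cv1, u_n1), ok),
    acc_row(arch_row, r, "cv2", "true",
            true_accuracy(pred_cv2, u_n1), ok))

  if (design %in% c("naive", "parametric")) {
    rows <- c(rows, list(
      acc_row(arch_row, r, "single", "naive",
              naive_accuracy(pred_single, y_n1, h1, h_power), TRUE),
      acc_row(arch_row, r, "cv1", "naive",
              naive_accuracy(pred_cv1, y_n1, h1, h_power), ok),
      acc_row(arch_row, r, "cv2", "naive",
              naive_accuracy(pred_cv2, y_n1, h1, h_power), ok)))
  }

  if (design == "naive") {
    bias <- semiparametric_bias(bfit, blocks, pred_cv2, y_n1)
    raw <- safe_cor(pred_cv2, y_n1)
    rows <- c(rows, list(
      acc_row(arch_row, r, "cv2", "semiparametric",
              semiparametric_accuracy(raw, bias, h1, h_power), ok)))
    if (include_fulldata_ebv) {
      u_tilde <- full_data_ebv_predictand(Y_full, grm, test, eig = eig_full)
      rows <- c(rows, list(
        acc_row(arch_row, r, "single", "ebv",
                safe_cor(pred_single, u_tilde), TRUE),
        acc_row(arch_row, r, "cv1", "ebv",
                safe_cor(pred_cv1, u_tilde), ok),
        acc_row(arch_row, r, "cv2", "ebv",
                safe_cor(pred_cv2, u_tilde), ok)))
    }
  }

  if (design == "parametric") {
    K_nn <- unclass(grm)[test, test, drop = FALSE]
    rows <- c(rows, list(
      acc_row(arch_row, r, "single", "parametric",
              parametric_accuracy(pred_single, y_n1, K_nn, eig = eig_nn),
              TRUE),
      acc_row(arch_row, r, "cv2", "parametric",
              parametric_accuracy(pred_cv2, y_n1, K_nn, eig = eig_nn),
              ok)))
  }

  if (design == "clone") {
    y_x1 <- rep_data$Y_b[test, 1]
    rows <- c(rows, list(
      acc_row(arch_row, r, "single", "cv2star",
              cv2star_accuracy(pred_single, y_x1, h1, "clone"), TRUE),
      acc_row(arch_row, r, "cv2", "cv2star",
              cv2star_accuracy(pred_cv2, y_x1, h1, "clone"), ok)))
  }

  if (design == "relative") {
    y_x1 <- rep_data$Y[part$surrogate_ids, 1]
    rows <- c(rows, list(
      acc_row(arch_row, r, "single", "cv2star",
              cv2star_accuracy(pred_single, y_x1, h1, "relative"), TRUE),
      acc_row(arch_row, r, "cv2", "cv2star",
              cv2star_accuracy(pred_cv2, y_x1, h1, "relative"), ok)))
  }

  do.call(rbind, rows)
}

cell_methods <- function(design, include_fulldata_ebv) {
  base <- data.frame(method = c("single", "cv1", "cv2"),
                     estimator = "true")
  extra <- switch(design,
    naive = rbind(data.frame(method = c("single", "cv1", "cv2"),
                             estimator = "naive"),
                  data.frame(method = "cv2", estimator = "semiparametric"),
                  if (include_fulldata_ebv)
                    data.frame(method = c("single", "cv1", "cv2"),
                               estimator = "ebv")),
    parametric = rbind(data.frame(method = c("single", "cv1", "cv2"),
                                  estimator = "naive"),
                       data.frame(method = c("single", "cv2"),
                                  estimator = "parametric")),
    clone = data.frame(method = c("single", "cv2"), estimator = "cv2star"),
    relative = data.frame(method = c("single", "cv2"),
                          estimator = "cv2star"))
  rbind(base, extra)
}

#' Run the factorial cross-validation simulation study
#'
#' For each replicate: draw one set of standard-normal matrices (shared
#' across all architectures -- common random numbers), draw one partition,
#' then for each architecture simulate traits, fit univariate and
#' bivariate REML models on the training partition, form the single-trait,
#' CV1 and CV2 predictions, and evaluate every estimator the chosen design
#' supports. Individual fit failures yield `NA` rows for that cell only.
#'
#' Designs and their default splits and estimators:
#' * `naive` (90:10): `true`, `naive`, `semiparametric` (CV2), optional
#'   `ebv` (full-data predictand).
#' * `parametric` (50:50): `true`, `naive`, `parametric`.
#' * `clone` (90:10 plus two independent clone phenotype copies of
#'   variance `2R` for test lines): `true`, `cv2star`.
#' * `relative` (80:10:10 nearest-relative surrogates): `true`, `cv2star`.
#'
#' @param grm A [grm].
#' @param archs Data frame of architectures (columns `h1_sq`, `h2_sq`,
#'   `rho_g`, `rho_r`); see [default_grid()].
#' @param n_reps Replicates per architecture.
#' @param design One of `"naive"`, `"parametric"`, `"clone"`,
#'   `"relative"`.
#' @param seed Root seed; all streams derive from it and the result is
#'   fully reproducible.
#' @param test_fraction Test-set proportion; default depends on `design`.
#' @param include_fulldata_ebv Also score against full-data EBVs (naive
#'   design only; one extra full-data bivariate fit per cell).
#' @param h_power Heritability-correction exponent (see
#'   [naive_accuracy()]).
#' @param progress Print per-replicate progress to stderr.
#' @return Data frame with one row per (architecture, replicate, method,
#'   estimator): columns `h1_sq`, `h2_sq`, `rho_g`, `rho_r`, `rep`,
#'   `method`, `estimator`, `value`, `converged`.
#' @export
#' @examples
#' K <- simulate_breeding_grm(60, 6, 200, seed = 1)
#' res <- run_grid(K, default_grid(rho_g = 0.6, rho_r = -0.6, h2_sq = 0.6),
#'                 n_reps = 2, design = "naive", seed = 1)
run_grid <- function(grm, archs = default_grid(), n_reps = 200,
                     design = c("naive", "parametric", "clone", "relative"),
                     seed = 1, test_fraction = NULL,
                     include_fulldata_ebv = FALSE, h_power = 0.5,
                     progress = FALSE) {
  design <- match.arg(design)
  if (is.null(test_fraction)) test_fraction <- design_test_fraction(design)
  streams <- seed_streams(seed)
  n <- nrow(grm)
  ids <- grm_ids(grm)
  scheme <- if (design == "relative") "nearest_relative" else "random_split"
  eig_full <- if (include_fulldata_ebv && design == "naive")
    grm_eigen(grm) else NULL

  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    if (progress) message("replicate ", r, "/", n_reps)
    part <- make_partition(grm, scheme, test_fraction,
                           seed = offset_seed(streams["partition"], r))
    blocks <- conditional_blocks(grm, part)
    Koo <- unclass(grm)[part$train_ids, part$train_ids, drop = FALSE]
    eig_oo <- grm_eigen(Koo)
    eig_nn <- if (design == "parametric")
      grm_eigen(unclass(grm)[part$test_ids, part$test_ids, drop = FALSE])
    else NULL
    draws <- make_draws(n, seed = offset_seed(streams["traits"], r))
    clone_seed <- offset_seed(streams["clones"], r)

    rep_rows <- lapply(seq_len(nrow(archs)), function(a) {
      arch_row <- archs[a, , drop = FALSE]
      tryCatch({
        arch <- genetic_architecture(arch_row$h1_sq, arch_row$h2_sq,
                                     arch_row$rho_g, arch_row$rho_r)
        rep_data <- simulate_traits(grm, arch, draws)
        if (design == "clone")
          rep_data <- make_clone_phenotypes(rep_data, part, clone_seed)
        run_cell(design, grm, arch_row, r, rep_data, part, blocks, Koo,
                 eig_oo, eig_nn, eig_full, rep_data$Y,
                 include_fulldata_ebv, h_power)
      }, error = function(e) {
        cm <- cell_methods(design, include_fulldata_ebv)
        na_rows(arch_row, r, cm$method, cm$estimator)
      })
    })
    out[[r]] <- do.call(rbind, rep_rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "design") <- design
  res
}

#' Model-selection frequency of an accuracy estimator
#'
#' For each architecture, declares the "best" of the two methods to be the
#' one with the higher mean true accuracy over replicates, then reports
#' the fraction of replicates in which the named estimator ranks that
#' method highest. Exact ties count 0.5; replicates with a missing
#' estimate for either method are dropped from the denominator.
#'
#' @param grid A [run_grid()] result containing `true` values and the
#'   named estimator for both methods.
#' @param estimator Estimator label to evaluate (e.g. `"naive"`).
#' @param methods Length-2 character vector of methods to compare.
#' @return Data frame per architecture: `best_method`,
#'   `fraction_correctly_selected`, `n_eff` (replicates used), `se`
#'   (binomial Monte-Carlo standard error).
#' @export
selection_frequency <- function(grid, estimator,
                                methods = c("single", "cv2")) {
  stopifnot(length(methods) == 2)
  if (!estimator %in% grid$estimator)
    stop("estimator '", estimator, "' not present in grid results")
  keys <- c("h1_sq", "h2_sq", "rho_g", "rho_r")
  archs <- unique(grid[keys])
  out <- lapply(seq_len(nrow(archs)), function(i) {
    sub <- merge(archs[i, , drop = FALSE], grid, by = keys)
    tv <- vapply(methods, function(m)
      mean(sub$value[sub$method == m & sub$estimator == "true"],
           na.rm = TRUE), numeric(1))
    best <- methods[which.max(tv)]
    other <- setdiff(methods, best)
    eb <- sub[sub$method == best & sub$estimator == estimator,
              c("rep", "value")]
    eo <- sub[sub$method == other & sub$estimator == estimator,
              c("rep", "value")]
    mrg <- merge(eb, eo, by = "rep", suffixes = c("_best", "_other"))
    mrg <- mrg[is.finite(mrg$value_best) & is.finite(mrg$value_other), ]
    n_eff <- nrow(mrg)
    frac <- if (n_eff)
      mean((mrg$value_best > mrg$value_other) +
             0.5 * (mrg$value_best == mrg$value_other))
    else NA_real_
    cbind(archs[i, , drop = FALSE],
          data.frame(best_method = best,
                     fraction_correctly_selected = frac,
                     n_eff = n_eff,
                     se = if (n_eff) sqrt(frac * (1 - frac) / n_eff)
                          else NA_real_))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-architecture summary of a simulation grid
#'
#' Means and Monte-Carlo standard errors (over replicates) per
#' architecture, method and estimator.
#'
#' @param grid A [run_grid()] result.
#' @param path Optional path to also write the summary as a tab-delimited
#'   file.
#' @return Data frame with `mean`, `se` (sd over replicates / sqrt(n)) and
#'   `n` per group.
#' @export
summarize_grid <- function(grid, path = NULL) {
  if (!nrow(grid)) stop("empty grid result")
  keys <- c("h1_sq", "h2_sq", "rho_g", "rho_r", "method", "estimator")
  agg <- aggregate(value ~ h1_sq + h2_sq + rho_g + rho_r +
                     method + estimator,
                   data = grid, FUN = function(v) {
                     v <- v[is.finite(v)]
                     c(mean = mean(v), se = sd(v) / sqrt(length(v)),
                       n = length(v))
                   }, na.action = stats::na.pass)
  res <- cbind(agg[keys], as.data.frame(agg$value))
  res <- res[do.call(order, unname(res[keys])), ]
  rownames(res) <- NULL
  if (!is.null(path))
    write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  res
}

#' Plot mean accuracy against residual correlation
#'
#' Accuracy curves per method and estimator over `rho_r`, with
#' `+/- 1.96 SE` ribbons, faceted by secondary-trait heritability and
#' genetic correlation. Requires ggplot2.
#'
#' @param summary A [summarize_grid()] result.
#' @return A ggplot object.
#' @export
plot_grid_summary <- function(summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_grid_summary requires the ggplot2 package")
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = rho_r, y = mean,
                               colour = method,
                               linetype = estimator)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mean - 1.96 * se,
                                      ymax = mean + 1.96 * se,
                                      fill = method),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(ggplot2::vars(h2_sq),
                        ggplot2::vars(rho_g),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "residual correlation", y = "accuracy")
}
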