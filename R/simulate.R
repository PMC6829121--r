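# Trait-pair simulation: genetic architectures, matrix-normal draws on a
# GRM, partition schemes, clone phenotype copies for CV2* designs.

#' Define a two-trait genetic architecture
#'
#' Phenotypic variances are standardized to 1 per trait, so the genetic
#' variance of trait i equals its heritability and the residual variance
#' equals `1 - h_i^2`:
#' \deqn{G = \begin{bmatrix} h_1^2 & \rho_g h_1 h_2 \\ . & h_2^2 \end{bmatrix},
#'       \quad
#'       R = \begin{bmatrix} 1-h_1^2 & \rho_R\sqrt{(1-h_1^2)(1-h_2^2)} \\
#'                           . & 1-h_2^2 \end{bmatrix}.}
#'
#' @param h1_sq,h2_sq Heritabilities of the focal and secondary trait,
#'   in (0, 1).
#' @param rho_g Genetic correlation between traits, in (-1, 1).
#' @param rho_r Residual (non-genetic) correlation, in (-1, 1).
#' @return Object of class `genetic_architecture` with elements `h1_sq`,
#'   `h2_sq`, `rho_g`, `rho_r`, `G`, `R`.
#' @export
#' @examples
#' genetic_architecture(0.2, 0.6, 0.6, -0.6)
genetic_architecture <- function(h1_sq, h2_sq, rho_g = 0, rho_r = 0) {
  stopifnot(h1_sq > 0, h1_sq < 1, h2_sq > 0, h2_sq < 1)
  if (abs(rho_g) >= 1 || abs(rho_r) >= 1)
    stop("|correlation| = 1 gives a singular trait covariance")
  cov2 <- build_covariances(h1_sq, h2_sq, rho_g, rho_r)
  structure(list(h1_sq = h1_sq, h2_sq = h2_sq,
                 rho_g = rho_g, rho_r = rho_r,
                 G = cov2$G, R = cov2$R),
            class = "genetic_architecture")
}

#' @export
print.genetic_architecture <- function(x, ...) {
  cat(sprintf(
    "Genetic architecture: h1^2=%.2g h2^2=%.2g rho_g=%.2g rho_R=%.2g\n",
    x$h1_sq, x$h2_sq, x$rho_g, x$rho_r))
  invisible(x)
}

#' Genetic and residual covariance matrices from architecture parameters
#'
#' @inheritParams genetic_architecture
#' @return List with 2x2 matrices `G` and `R`, both positive definite.
#' @export
build_covariances <- function(h1_sq, h2_sq, rho_g = 0, rho_r = 0) {
  stopifnot(h1_sq > 0, h1_sq < 1, h2_sq > 0, h2_sq < 1)
  if (abs(rho_g) >= 1 || abs(rho_r) >= 1)
    stop("|correlation| = 1 gives a singular trait covariance")
  h1 <- sqrt(h1_sq); h2 <- sqrt(h2_sq)
  r1 <- 1 - h1_sq;  r2 <- 1 - h2_sq
  G <- matrix(c(h1_sq, rho_g * h1 * h2, rho_g * h1 * h2, h2_sq), 2L)
  R <- matrix(c(r1, rho_r * sqrt(r1 * r2), rho_r * sqrt(r1 * r2), r2), 2L)
  list(G = G, R = R)
}

#' Standard-normal draws shared across architectures
#'
#' One replicate's underlying randomness: `Z_u` feeds the genetic values,
#' `Z_e` the residuals. Reusing the same draws across all architectures of
#' a grid (common random numbers) removes between-architecture Monte-Carlo
#' noise from comparisons.
#'
#' @param n_lines Number of lines.
#' @param seed Integer seed for this replicate's stream.
#' @return Object of class `common_draws` with `Z_u`, `Z_e`
#'   (`n_lines` x 2 each).
#' @export
make_draws <- function(n_lines, seed) {
  with_seed(seed, {
    structure(list(Z_u = matrix(rnorm(2L * n_lines), n_lines, 2L),
                   Z_e = matrix(rnorm(2L * n_lines), n_lines, 2L)),
              class = "common_draws")
  })
}

chol_lower <- function(S, what = "matrix") {
  L <- tryCatch(t(chol(S)),
                error = function(e)
                  stop(what, " is not positive definite; jitter it ",
                       "(e.g. ensure_positive_definite)", call. = FALSE))
  L
}

#' Simulate a correlated trait pair on a GRM
#'
#' Draws `U ~ MN(0, K, G)` and `E ~ MN(0, I, R)` via two-sided Cholesky
#' transforms of the shared standard-normal draws, and returns phenotypes
#' `Y = U + E`. With the same `draws` object, different architectures
#' reuse identical underlying normals.
#'
#' @param grm A [grm] `K`.
#' @param arch A [genetic_architecture].
#' @param draws A [make_draws()] object matching `nrow(grm)`.
#' @return Object of class `trait_replicate`: matrices `Y`, `U`, `E`
#'   (lines x 2, rownames = line ids), plus `arch`.
#' @export
simulate_traits <- function(grm, arch, draws) {
  stopifnot(inherits(arch, "genetic_architecture"),
            inherits(draws, "common_draws"))
  n <- nrow(grm)
  if (nrow(draws$Z_u) != n)
    stop("draws were made for ", nrow(draws$Z_u), " lines, GRM has ", n)
  L_K <- chol_lower(unclass(grm), "GRM")
  L_G <- chol_lower(arch$G, "G")
  L_R <- chol_lower(arch$R, "R")
  U <- L_K %*% draws$Z_u %*% t(L_G)
  E <- draws$Z_e %*% t(L_R)
  Y <- U + E
  ids <- grm_ids(grm)
  dimnames(U) <- dimnames(E) <- dimnames(Y) <-
    list(ids, c("trait1", "trait2"))
  structure(list(Y = Y, U = U, E = E, arch = arch),
            class = "trait_replicate")
}

#' Draw a training/testing partition from a GRM
#'
#' `random_split` samples `ceiling(test_fraction * n)` test lines uniformly
#' without replacement. `nearest_relative` additionally assigns each test
#' line a surrogate: its most-related remaining line (`argmax_j K_ij`),
#' assigned greedily in descending order of each test line's best available
#' relatedness (ties broken by line order), without replacement; the
#' training set is everything left.
#'
#' @param grm A [grm].
#' @param scheme `"random_split"` or `"nearest_relative"`.
#' @param test_fraction Proportion of lines in the test set, in (0, 0.5].
#' @param seed Integer seed for the partition draw.
#' @return A [partition].
#' @export
make_partition <- function(grm, scheme = c("random_split", "nearest_relative"),
                           test_fraction = 0.1, seed) {
  scheme <- match.arg(scheme)
  stopifnot(test_fraction > 0, test_fraction <= 0.5)
  ids <- grm_ids(grm)
  n <- length(ids)
  n_test <- ceiling(test_fraction * n)
  test <- with_seed(seed, sample(ids, n_test))
  if (scheme == "random_split")
    return(partition(test, setdiff(ids, test)))

  K <- unclass(grm)
  pool <- setdiff(ids, test)
  if (length(pool) < length(test))
    stop("not enough remaining lines to assign surrogates")
  # greedy by strongest available relative first
  best <- vapply(test, function(i) max(K[i, pool]), numeric(1))
  order_test <- test[order(-best, match(test, ids))]
  surrogate <- character(length(test))
  names(surrogate) <- order_test
  for (i in order_test) {
    if (!length(pool)) stop("no remaining candidates for surrogate of ", i)
    j <- pool[which.max(K[i, pool])]
    surrogate[i] <- j
    pool <- setdiff(pool, j)
  }
  surrogate <- surrogate[test]   # re-align to test order
  partition(test, setdiff(ids, c(test, surrogate)), surrogate_ids = surrogate)
}

#' Add independent clone phenotype copies for the test partition
#'
#' For the clone-based CV2* design: each test line gets two phenotype
#' copies `Y_a` and `Y_b` sharing its true genetic values but with fresh,
#' mutually independent residuals of variance `2R` (each copy is based on
#' half the data of a line mean, doubling the residual variance). Training
#' lines keep their original phenotypes.
#'
#' @param rep A [simulate_traits()] replicate.
#' @param partition A [partition]; copies are produced for its test lines.
#' @param seed Integer seed for the extra residual draws.
#' @return `rep` with matrices `Y_a`, `Y_b` added (rows = test lines).
#' @export
make_clone_phenotypes <- function(rep, partition, seed) {
  stopifnot(inherits(rep, "trait_replicate"))
  test <- partition$test_ids
  if (!length(test)) stop("test partition is empty")
  if (!all(test %in% rownames(rep$Y)))
    stop("partition test ids not present in replicate")
  R2 <- 2 * rep$arch$R
  L <- chol_lower(R2, "2R")
  m <- length(test)
  with_seed(seed, {
    Ea <- matrix(rnorm(2L * m), m, 2L) %*% t(L)
    Eb <- matrix(rnorm(2L * m), m, 2L) %*% t(L)
  })
  U_test <- rep$U[test, , drop = FALSE]
  rep$Y_a <- U_test + Ea
  rep$Y_b <- U_test + Eb
  dimnames(rep$Y_a) <- dimnames(rep$Y_b) <-
    list(test, c("trait1", "trait2"))
  rep
}

#' The default architecture grid
#'
#' All combinations of `h2_sq` in \{0.2, 0.6\}, `rho_g` in \{0, 0.3, 0.6\}
#' and `rho_r` in \{-0.6, -0.4, -0.2, 0, 0.2, 0.4, 0.6\} at a fixed focal
#' heritability (42 architectures at the default `h1_sq = 0.2`).
#'
#' @param h1_sq Focal-trait heritability (scalar or vector).
#' @param h2_sq,rho_g,rho_r Grid levels.
#' @return Data frame with one row per architecture.
#' @export
default_grid <- function(h1_sq = 0.2,
                         h2_sq = c(0.2, 0.6),
                         rho_g = c(0, 0.3, 0.6),
                         rho_r = c(-0.6, -0.4, -0.2, 0, 0.2, 0.4, 0.6)) {
  expand.grid(h1_sq = h1_sq, h2_sq = h2_sq, rho_g = rho_g, rho_r = rho_r,
              KEEP.OUT.ATTRS = FALSE)
}

#' Write simulated phenotypes (and truth) to a delimited file
#'
#' @param rep A [simulate_traits()] replicate.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(rep, path, sep = "\t") {
  df <- data.frame(id = rownames(rep$Y),
                   y1 = rep$Y[, 1], y2 = rep$Y[, 2],
                   u1 = rep$U[, 1], u2 = rep$U[, 2])
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
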