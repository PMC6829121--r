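# Genomic relationship matrices: construction, IO, validation, partitioned
# conditional blocks.

#' Construct a GRM object
#'
#' A `grm` is a square symmetric relatedness matrix with line identifiers.
#' Diagonal entries are near 1 for non-inbred individuals (up to 2 for
#' fully inbred lines); off-diagonals measure genomic relatedness.
#'
#' @param values Square numeric matrix.
#' @param ids Character vector of line identifiers, one per row/column.
#'   Defaults to the rownames of `values`.
#' @param symmetrize_tol Maximum allowed asymmetry `max|K - t(K)|`;
#'   asymmetry below this is removed by averaging, above it is an error.
#' @return An object of class `grm`: the matrix with `ids` as dimnames.
#' @export
#' @examples
#' K <- grm(diag(2), ids = c("A", "B"))
grm <- function(values, ids = rownames(values), symmetrize_tol = 1e-6) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("GRM must be square; got ", nrow(values), "x", ncol(values))
  if (!is.numeric(values) || anyNA(values))
    stop("GRM must be numeric with no missing values")
  if (is.null(ids)) ids <- as.character(seq_len(nrow(values)))
  ids <- as.character(ids)
  if (length(ids) != nrow(values))
    stop("number of ids (", length(ids), ") does not match GRM dimension (",
         nrow(values), ")")
  if (anyDuplicated(ids)) stop("duplicated line ids in GRM")
  asym <- max(abs(values - t(values)))
  if (asym >= symmetrize_tol)
    stop("GRM asymmetry ", format(asym), " exceeds tolerance ",
         format(symmetrize_tol))
  values <- (values + t(values)) / 2
  if (any(diag(values) <= 0)) stop("GRM diagonal entries must be positive")
  dimnames(values) <- list(ids, ids)
  structure(values, class = c("grm", "matrix", "array"))
}

#' @export
print.grm <- function(x, ...) {
  cat("Genomic relationship matrix:", nrow(x), "lines\n")
  cat("  diagonal: mean", signif(mean(diag(x)), 3),
      " off-diagonal: mean", signif(mean(x[upper.tri(x)]), 3), "\n")
  invisible(x)
}

grm_ids <- function(grm) rownames(grm)

#' Read a GRM from a dense delimited file
#'
#' Expects a header row of line ids, a first column of line ids, and a
#' square numeric body. Comma- and tab-delimited files are both accepted.
#' Asymmetry below `1e-6` is averaged away; anything larger is an error.
#'
#' @param path Path to the file.
#' @param sep Field separator; `NULL` (default) autodetects `,` vs tab.
#' @return A [grm] with ids in file order.
#' @seealso [write_grm()]
#' @export
load_grm <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("GRM file not found: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
  }
  tab <- read.table(path, header = TRUE, sep = sep, row.names = 1L,
                    check.names = FALSE, colClasses = NA)
  m <- as.matrix(tab)
  if (!is.numeric(m)) stop("non-numeric cell in GRM file ", path)
  if (nrow(m) != ncol(m))
    stop("GRM file is not square: ", nrow(m), " rows x ", ncol(m), " columns")
  if (!identical(rownames(m), colnames(m)))
    stop("row and column ids disagree in GRM file ", path)
  grm(m, ids = rownames(m))
}

#' Write a GRM to a dense delimited file
#'
#' Writes the dialect [load_grm()] reads: header row and first column of
#' ids, numeric body at 17 significant digits so that a write/read
#' round-trip is bit-identical.
#'
#' @param grm A [grm].
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_grm <- function(grm, path, sep = "\t") {
  df <- as.data.frame(format(unclass(grm), digits = 17, trim = TRUE,
                             scientific = TRUE))
  write.table(cbind(id = rownames(grm), df), path, sep = sep,
              quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' VanRaden genomic relationship matrix from a marker dosage matrix
#'
#' Centers each marker by twice its allele frequency and scales the
#' cross-product by the total expected heterozygosity:
#' \deqn{K = \frac{(M - 2p)(M - 2p)^\top}{2 \sum_m p_m (1 - p_m)}.}
#' Monomorphic markers carry no information and are dropped.
#'
#' @param M Lines x markers matrix of allele dosages in 0, 1, 2.
#' @param ids Line identifiers (default rownames of `M`).
#' @return A [grm].
#' @export
grm_from_markers <- function(M, ids = rownames(M)) {
  M <- as.matrix(M)
  p <- colMeans(M) / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("all markers are monomorphic; cannot form a GRM")
  M <- M[, keep, drop = FALSE]
  p <- p[keep]
  W <- sweep(M, 2L, 2 * p)
  K <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  grm(K, ids = ids)
}

#' Simulate a family-structured breeding-population GRM
#'
#' Emulates a line-breeding program: `n_families` biparental families, each
#' founded by two unrelated outbred parents (four founder haplotypes drawn
#' at population allele frequencies), with lines inheriting one haplotype
#' from each parent independently per marker. Within-family pairs are full
#' sibs with expected genomic relatedness 0.5; between-family relatedness
#' is near 0. The GRM is the VanRaden cross-product of the dosages,
#' jittered to positive definiteness.
#'
#' @param n_lines Number of lines (>= 2 per family).
#' @param n_families Number of families; lines are split as evenly as
#'   possible among them.
#' @param n_markers Number of biallelic markers (>= 100).
#' @param seed Integer seed; the same seed always yields the same GRM.
#' @param min_eig Positive-definiteness floor passed to
#'   [ensure_positive_definite()].
#' @return A [grm] with ids `L001`, `L002`, ...; attribute `family` holds
#'   the family index of each line.
#' @export
#' @examples
#' K <- simulate_breeding_grm(40, 4, 200, seed = 1)
simulate_breeding_grm <- function(n_lines, n_families, n_markers, seed,
                                  min_eig = 1e-8) {
  stopifnot(n_lines >= 2 * n_families, n_markers >= 100, n_families >= 1)
  fam <- sort(rep_len(seq_len(n_families), n_lines))
  with_seed(seed, {
    for (attempt in 1:10) {
      p <- runif(n_markers, 0.1, 0.9)
      M <- matrix(0L, n_lines, n_markers)
      for (f in seq_len(n_families)) {
        rows <- which(fam == f)
        # 4 founder haplotypes per family; per-marker Mendelian sampling
        H <- matrix(rbinom(4L * n_markers, 1L, rep(p, each = 4L)),
                    nrow = 4L)
        for (i in rows) {
          pick1 <- sample.int(2L, n_markers, replace = TRUE)
          pick2 <- sample.int(2L, n_markers, replace = TRUE) + 2L
          idx <- seq_len(n_markers)
          M[i, ] <- H[cbind(pick1, idx)] + H[cbind(pick2, idx)]
        }
      }
      freq <- colMeans(M) / 2
      if (any(freq > 0 & freq < 1)) {
        ids <- sprintf("L%03d", seq_len(n_lines))
        rownames(M) <- ids
        K <- ensure_positive_definite(grm_from_markers(M), min_eig = min_eig)
        attr(K, "family") <- fam
        return(K)
      }
    }
    stop("all markers fixed after 10 attempts; increase n_markers")
  })
}

#' Raise the smallest eigenvalue of a GRM to a floor
#'
#' If the smallest eigenvalue is below `min_eig`, adds
#' `(min_eig - lambda_min)` to the diagonal, leaving an already
#' well-conditioned matrix untouched.
#'
#' @param grm A [grm] (or symmetric matrix).
#' @param min_eig Eigenvalue floor.
#' @return A [grm] with all eigenvalues `>= min_eig`.
#' @export
ensure_positive_definite <- function(grm, min_eig = 1e-8) {
  K <- unclass(grm)
  lam <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  lmin <- min(lam)
  if (lmin < min_eig) {
    K <- K + diag(min_eig - lmin, nrow(K))
  }
  out <- structure(K, class = c("grm", "matrix", "array"))
  attr(out, "family") <- attr(grm, "family")
  out
}

#' Define a training/testing (and optional surrogate) partition
#'
#' @param test_ids Ids of the testing ("new") partition.
#' @param train_ids Ids of the training ("old") partition.
#' @param surrogate_ids Optional ids of surrogate validation lines for the
#'   nearest-relative CV2* design; must be the same length as `test_ids`,
#'   with `surrogate_ids[i]` the surrogate of `test_ids[i]`.
#' @return An object of class `partition`.
#' @seealso [make_partition()] which draws partitions from a GRM.
#' @export
partition <- function(test_ids, train_ids, surrogate_ids = NULL) {
  test_ids <- as.character(test_ids)
  train_ids <- as.character(train_ids)
  if (!length(test_ids) || !length(train_ids))
    stop("training and testing partitions must be non-empty")
  all_ids <- c(test_ids, train_ids, surrogate_ids)
  if (anyDuplicated(all_ids))
    stop("partition sets must be disjoint")
  if (!is.null(surrogate_ids)) {
    surrogate_ids <- as.character(surrogate_ids)
    if (length(surrogate_ids) != length(test_ids))
      stop("surrogate set must match test set size")
  }
  structure(list(test_ids = test_ids, train_ids = train_ids,
                 surrogate_ids = surrogate_ids),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("Partition: ", length(x$train_ids), " training / ",
      length(x$test_ids), " testing",
      if (!is.null(x$surrogate_ids))
        paste0(" / ", length(x$surrogate_ids), " surrogate"),
      " lines\n", sep = "")
  invisible(x)
}

check_partition <- function(part, grm) {
  ids <- grm_ids(grm)
  miss <- setdiff(c(part$test_ids, part$train_ids, part$surrogate_ids), ids)
  if (length(miss))
    stop("partition ids not present in GRM: ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Conditional covariance blocks of a partitioned GRM
#'
#' For a GRM partitioned into testing (`n`) and training (`o`) blocks,
#' computes the projection `Kno Koo^-1` that carries training BLUPs to test
#' lines, and the Schur complement
#' `Sigma_c = Knn - Kno Koo^-1 Kon`, the conditional genetic covariance of
#' test lines given training lines. Both are computed by solving against
#' `Koo`; the full matrix is never inverted.
#'
#' @param grm A [grm].
#' @param partition A [partition] valid for `grm` (surrogate lines, if any,
#'   are excluded from both blocks).
#' @return List with components `projection` (n_test x n_train), `schur`
#'   (n_test x n_test, symmetric PSD), and the ids of each block.
#' @export
conditional_blocks <- function(grm, partition) {
  check_partition(partition, grm)
  K <- unclass(grm)
  n_idx <- match(partition$test_ids, grm_ids(grm))
  o_idx <- match(partition$train_ids, grm_ids(grm))
  Koo <- K[o_idx, o_idx, drop = FALSE]
  Kon <- K[o_idx, n_idx, drop = FALSE]
  Knn <- K[n_idx, n_idx, drop = FALSE]
  sol <- tryCatch(solve(Koo, Kon),
                  error = function(e)
                    stop("training block Koo is singular; jitter the GRM ",
                         "with ensure_positive_definite()", call. = FALSE))
  projection <- t(sol)                      # Kno Koo^-1
  schur <- Knn - projection %*% Kon
  schur <- (schur + t(schur)) / 2
  list(projection = projection, schur = schur,
       test_ids = partition$test_ids, train_ids = partition$train_ids)
}
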