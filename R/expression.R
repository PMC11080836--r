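#' Log2 counts-per-million
#'
#' `log2((count + prior) / (libsize + 2 * prior) * 1e6)` with the library
#' size being the column sum.  The prior damps the variance of
#' low-count features; doubling a sample's counts shifts its column by
#' (almost) nothing beyond the prior's influence.
#'
#' @param counts non-negative integer matrix, features x samples, with
#'   dimnames.
#' @param prior pseudo-count (default 2).
#' @return Numeric matrix of the same shape.
#' @export
log_cpm <- function(counts, prior = 2.0) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  libsize <- colSums(counts)
  if (any(libsize == 0)) stop("zero library size in sample(s): ",
                              paste(colnames(counts)[libsize == 0],
                                    collapse = ", "))
  log2(sweep(counts + prior, 2, libsize + 2 * prior, "/") * 1e6)
}

#' Read a feature-by-sample count matrix from TSV
#'
#' First column feature ids, header row sample ids.
#'
#' @param path TSV path.
#' @return Integer matrix with dimnames.
#' @export
read_count_matrix <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop("duplicate feature or sample ids in ", path)
  m
}

#' Leading-log-fold-change multidimensional scaling
#'
#' The distance between two samples is the root-mean-square of the
#' `top_n` largest absolute log-CPM differences across features (computed
#' per pair).  Samples are then embedded by classical metric MDS: double
#' centering of the squared distance matrix, eigendecomposition, and
#' coordinates scaled by the square root of the eigenvalues.  The sign of
#' each axis is fixed deterministically: the loading with the largest
#' magnitude is positive, so embeddings are reproducible and equivariant
#' under sample reordering.
#'
#' @param logcpm numeric matrix, features x samples (see [log_cpm()]).
#' @param top_n number of largest fold changes entering each pairwise
#'   distance (default 500; capped at the feature count with a warning).
#' @param k embedding dimensions (default 2; capped at samples - 1).
#' @return Object of class `mds_result`: `coordinates` (samples x k),
#'   `eigenvalues` (descending, all n), `distance_matrix`.
#' @export
leading_logfc_mds <- function(logcpm, top_n = 500L, k = 2L) {
  n <- ncol(logcpm)
  if (n < 3L) stop("MDS needs at least 3 samples")
  if (top_n > nrow(logcpm)) {
    warning("top_n exceeds the feature count; using all ", nrow(logcpm),
            " features")
    top_n <- nrow(logcpm)
  }
  k <- min(k, n - 1L)
  D <- matrix(0, n, n, dimnames = list(colnames(logcpm), colnames(logcpm)))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      d2 <- (logcpm[, i] - logcpm[, j])^2
      top <- sort(d2, decreasing = TRUE, method = "quick")[seq_len(top_n)]
      D[i, j] <- D[j, i] <- sqrt(mean(top))
    }
  }
  # classical MDS: B = -1/2 J D^2 J
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D * D) %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  ev <- eig$values
  coords <- matrix(0, n, k, dimnames = list(colnames(logcpm),
                                            paste0("dim", seq_len(k))))
  for (d in seq_len(k)) {
    if (ev[d] > 0) {
      v <- eig$vectors[, d] * sqrt(ev[d])
      # deterministic sign: the largest-magnitude loading is positive
      # (invariant under sample reordering)
      if (any(abs(v) > 1e-12) && v[which.max(abs(v))] < 0) v <- -v
      coords[, d] <- v
    }
  }
  structure(list(coordinates = coords, eigenvalues = ev,
                 distance_matrix = D),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat(sprintf("mds_result: %d samples, %d dimension(s)\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  print(head(x$coordinates))
  invisible(x)
}

#' Permutation test for a dimer-driven batch effect
#'
#' For each MDS dimension, computes the Spearman correlation between the
#' per-sample adapter-dimer percentage and the sample coordinate, and a
#' two-sided permutation p-value
#' `(1 + #{perm : |rho*| >= |rho|}) / (n_perm + 1)` obtained by permuting
#' the dimer percentages with a seeded generator.  A small p on a leading
#' dimension means the technical variable, not biology, organises the
#' embedding.
#'
#' @param mds an `mds_result` from [leading_logfc_mds()].
#' @param pct_dimer numeric vector of dimer percentages, named by sample
#'   or in the coordinate row order.
#' @param n_perm number of permutations (>= 100; default 10000).
#' @param seed RNG seed for the permutations.
#' @return Data frame with one row per dimension: `dimension`,
#'   `spearman_rho`, `p_perm`, `n_perm`, `seed`.
#' @export
dimer_batch_effect_test <- function(mds, pct_dimer, n_perm = 10000L,
                                    seed = 1L) {
  stopifnot(inherits(mds, "mds_result"), n_perm >= 100L)
  coords <- mds$coordinates
  if (!is.null(names(pct_dimer))) {
    if (!setequal(names(pct_dimer), rownames(coords)))
      stop("pct_dimer sample names do not match the MDS samples")
    pct_dimer <- pct_dimer[rownames(coords)]
  }
  if (length(pct_dimer) != nrow(coords))
    stop("pct_dimer length does not match the number of samples")
  if (stats::sd(pct_dimer) == 0) {
    warning("pct_dimer is constant; the batch-effect test is undefined")
    return(data.frame(dimension = seq_len(ncol(coords)),
                      spearman_rho = NA_real_, p_perm = NA_real_,
                      n_perm = as.integer(n_perm), seed = as.integer(seed)))
  }
  rd <- rank(pct_dimer)
  with_seed(seed, {
    res <- lapply(seq_len(ncol(coords)), function(d) {
      rc <- rank(coords[, d])
      rho <- cor(rd, rc)
      null <- vapply(seq_len(n_perm),
                     function(i) cor(sample(rd), rc), numeric(1))
      p <- (1 + sum(abs(null) >= abs(rho) - 1e-12)) / (n_perm + 1)
      data.frame(dimension = d, spearman_rho = rho, p_perm = p,
                 n_perm = as.integer(n_perm), seed = as.integer(seed))
    })
    do.call(rbind, res)
  })
}
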