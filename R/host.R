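#' Sørensen similarity between two presence/absence vectors
#'
#' `S = 2|A n B| / (|A| + |B|)` on the positive sets.
#'
#' @param a,b Binary vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
sorensen_similarity <- function(a, b) {
  if (length(a) != length(b)) abort("vectors must have equal length")
  a <- as.numeric(a > 0); b <- as.numeric(b > 0)
  if (sum(a) + sum(b) == 0) abort("undefined similarity: both vectors empty")
  2 * sum(a * b) / (sum(a) + sum(b))
}

#' Read a binary ISSR band matrix
#'
#' CSV with one row per individual (first column the individual id) and one
#' 0/1 column per scored band.
#'
#' @param path CSV path.
#' @return Numeric binary matrix, individuals in rows.
#' @export
read_band_matrix <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  bm <- as.matrix(tab[, -1])
  rownames(bm) <- as.character(tab[[1]])
  check_band_matrix(bm)
}

check_band_matrix <- function(bm) {
  if (!is.matrix(bm) || !all(bm %in% c(0, 1))) {
    abort("band matrix must be strictly binary")
  }
  invisible(bm)
}

#' Host genetic dissimilarity from ISSR bands
#'
#' Pairwise `1 - Sørensen similarity` between individuals.
#'
#' @param bm Binary band matrix (individuals x bands).
#' @return Symmetric dissimilarity matrix.
#' @export
host_distance_matrix <- function(bm) {
  check_band_matrix(bm)
  n <- nrow(bm)
  shared <- bm %*% t(bm)
  sizes <- rowSums(bm)
  tot <- outer(sizes, sizes, `+`)
  if (any(tot == 0)) abort("undefined similarity: individual with no bands")
  d <- 1 - 2 * shared / tot
  diag(d) <- 0
  dimnames(d) <- list(rownames(bm), rownames(bm))
  d
}

#' PCA of the host band matrix
#'
#' Column-centred, unscaled principal component analysis of the binary band
#' matrix. Axis signs follow a deterministic convention: the
#' largest-magnitude loading of each component is positive. The first two
#' score columns are the host axes (HSTPC1, HSTPC2) used as explanatory
#' factors downstream.
#'
#' @param bm Binary band matrix (individuals x bands).
#' @param n_axes Number of axes to retain (default 2).
#' @return A `trflp_pca` object: list with `scores` (individuals x axes),
#'   `explained_variance`, `loadings` and the tibble accessor [tidy()].
#' @export
host_pca <- function(bm, n_axes = 2) {
  check_band_matrix(bm)
  if (nrow(bm) < 3L) abort("need at least 3 individuals")
  if (sum(apply(bm, 2, stats::var) > 0) < 2L) {
    abort("need at least 2 non-constant bands")
  }
  pc <- stats::prcomp(bm, center = TRUE, scale. = FALSE)
  n_axes <- min(n_axes, ncol(pc$x))
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  scores <- sweep(pc$x, 2, flip, `*`)
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  structure(
    list(
      scores = scores[, seq_len(n_axes), drop = FALSE],
      all_scores = scores,
      loadings = loadings[, seq_len(n_axes), drop = FALSE],
      explained_variance = pc$sdev^2,
      total_variance = sum(pc$sdev^2)
    ),
    class = "trflp_pca"
  )
}

#' @export
print.trflp_pca <- function(x, ...) {
  pct <- 100 * x$explained_variance[1:2] / x$total_variance
  cat(sprintf("<trflp_pca> %d individuals; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), pct[1], pct[2]))
  invisible(x)
}

#' @export
tidy.trflp_pca <- function(x, ...) {
  as_tibble(x$scores, rownames = "id")
}

#' Assign host individuals to genetic groups
#'
#' k-means (fixed seed, multiple restarts) on the first two PCA axes; the
#' reference survey resolved three host groups, hence `k = 3` by default.
#' Group labels are renumbered so group 1 has the smallest mean PC1 score.
#'
#' @param pca A `trflp_pca` from [host_pca()].
#' @param k Number of groups (default 3).
#' @param seed Seed for the k-means restarts.
#' @return Tibble with `id` and `host_group`.
#' @export
host_groups <- function(pca, k = 3, seed = 1) {
  stopifnot(inherits(pca, "trflp_pca"))
  sc <- pca$scores[, 1:2, drop = FALSE]
  km <- withr::with_seed(seed, stats::kmeans(sc, centers = k, nstart = 20))
  relabel <- rank(tapply(sc[, 1], km$cluster, mean), ties.method = "first")
  tibble(
    id = rownames(sc) %||% as.character(seq_len(nrow(sc))),
    host_group = as.integer(relabel[km$cluster])
  )
}
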