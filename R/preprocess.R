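#' Log-normalize counts
#'
#' Adds a `"lognorm"` layer: `ln(1 + count * scale / total)` per cell,
#' the conventional counts-per-`scale` log transform. Cells with zero
#' total counts keep an all-zero row and are flagged in the cell metadata
#' column `zero_total`.
#'
#' @param dataset an [ens_dataset()]
#' @param scale library-size target (default 1e4, i.e. CP10K)
#' @return the dataset with layer `"lognorm"` added
#' @export
normalize_counts <- function(dataset, scale = 1e4) {
  counts <- as_dense(dataset$counts)
  totals <- rowSums(counts)
  denom <- ifelse(totals > 0, totals, 1)
  lognorm <- log1p(counts * (scale / denom))
  dimnames(lognorm) <- dimnames(counts)
  dataset$layers[["lognorm"]] <- lognorm
  dataset$cell_meta$zero_total <- totals == 0
  if (any(totals == 0)) {
    warn(sprintf("%d cell(s) with zero total counts flagged", sum(totals == 0)))
  }
  dataset
}

# PCA scores of a cells-by-genes layer: centered, unscaled.
pca_scores <- function(mat, n_pcs) {
  n_pcs <- min(n_pcs, ncol(mat) - 1L, nrow(mat) - 1L)
  pc <- prcomp(mat, center = TRUE, scale. = FALSE, rank. = n_pcs)
  pc$x
}

# k nearest neighbors (excluding self) by Euclidean distance, computed
# blockwise from the Gram matrix to bound memory.
knn_indices <- function(scores, k, block = 1024L) {
  n <- nrow(scores)
  sq <- rowSums(scores^2)
  out <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(scores[idx, , drop = FALSE],
                                                   scores)
    for (j in seq_along(idx)) {
      d2[j, idx[j]] <- Inf  # exclude self
      out[idx[j], ] <- order(d2[j, ])[seq_len(k)]
    }
  }
  out
}

#' Impute dropout by k-nearest-neighbor averaging
#'
#' Adds an `"imputed"` layer: for each cell, the mean of the `"lognorm"`
#' values over its `k` nearest neighbors (Euclidean distance in the top
#' `n_pcs` principal components of the centered, unscaled lognorm layer),
#' excluding the cell itself. A deterministic smoother of dropout zeros:
#' a transcript detected in a cell's transcriptomic neighborhood
#' contributes a positive imputed value even where the cell's own count
#' is zero.
#'
#' @param dataset an [ens_dataset()] with a `"lognorm"` layer
#' @param k number of neighbors (default 15)
#' @param n_pcs number of principal components (default 20; enough to
#'   span cluster and program structure while excluding noise-dominated
#'   components that would blur neighbor choice)
#' @return the dataset with layer `"imputed"` added
#' @export
impute_knn <- function(dataset, k = 15, n_pcs = 20) {
  assert_that("lognorm" %in% names(dataset$layers),
              "run normalize_counts() first: no lognorm layer")
  ln <- get_layer(dataset, "lognorm")
  assert_that(k < nrow(ln), "k must be smaller than the number of cells")
  scores <- pca_scores(ln, n_pcs)
  nn <- knn_indices(scores, k)
  imputed <- matrix(0, nrow(ln), ncol(ln), dimnames = dimnames(ln))
  for (i in seq_len(nrow(ln))) {
    imputed[i, ] <- colMeans(ln[nn[i, ], , drop = FALSE])
  }
  dataset$layers[["imputed"]] <- imputed
  dataset
}
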