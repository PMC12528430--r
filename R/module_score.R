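#' Expression-matched module score
#'
#' Scores each cell for a gene set as the mean expression of the set genes
#' minus the mean of expression-matched control genes. Genes are ranked by
#' their dataset-wide mean on the evaluated layer and cut into `n_bins`
#' equal-frequency bins; each set gene draws `n_ctrl` control genes
#' uniformly without replacement from the non-set members of its own bin
#' (capped at the pool size), so the control background matches the set's
#' expression distribution without containing the set itself. Control
#' draws are governed by `seed`, making scores reproducible.
#'
#' @param mat dense cells-by-genes expression matrix (a layer)
#' @param gene_set character vector of gene symbols to score
#' @param n_bins number of equal-frequency average-expression bins
#' @param n_ctrl control genes drawn per set gene
#' @param seed integer seed for the control draws
#' @return numeric vector, one score per cell
#' @export
score_genes <- function(mat, gene_set, n_bins = 25, n_ctrl = 50, seed = 1L) {
  assert_that(n_bins >= 1, "n_bins must be >= 1")
  genes <- colnames(mat)
  assert_that(!is.null(genes), "matrix must have gene column names")
  gene_set <- unique(gene_set)
  present <- gene_set %in% genes
  if (!any(present)) {
    abort(paste0("no gene of the set is present in the dataset; missing: ",
                 paste(gene_set, collapse = ", ")))
  }
  gene_set <- gene_set[present]

  bin <- score_bins(mat, n_bins)
  set_idx <- match(gene_set, genes)

  ctrl_mean <- matrix(0, nrow(mat), length(set_idx))
  with_seed(seed, {
    for (j in seq_along(set_idx)) {
      pool <- setdiff(which(bin == bin[set_idx[j]]), set_idx)
      if (length(pool) == 0) pool <- which(bin == bin[set_idx[j]])
      draws <- pool[sample.int(length(pool), min(n_ctrl, length(pool)))]
      ctrl_mean[, j] <- rowMeans(mat[, draws, drop = FALSE])
    }
  })
  set_mean <- rowMeans(mat[, set_idx, drop = FALSE])
  unname(set_mean - rowMeans(ctrl_mean))
}

# Equal-frequency bin index per gene, by dataset-wide mean expression.
# Ties in the mean are broken by gene symbol so the binning is
# deterministic across platforms.
score_bins <- function(mat, n_bins) {
  means <- colMeans(mat)
  ord <- order(means, colnames(mat))
  rank_first <- integer(length(means))
  rank_first[ord] <- seq_along(means)
  pmin(floor((rank_first - 1) * n_bins / length(means)) + 1L, n_bins)
}
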