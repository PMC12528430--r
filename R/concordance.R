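# Long-form concordance matrix: one row per (row_id, col_id) pair with a
# named statistic. Kept tidy so results chain with dplyr/ggplot2;
# as_matrix() gives the wide view.
new_concordance <- function(df, statistic_name) {
  structure(as_tibble(df),
            class = c("ens_concordance", class(as_tibble(df))),
            statistic_name = statistic_name)
}

#' Wide matrix view of a concordance table
#'
#' @param x an `ens_concordance` tibble (`row_id`, `col_id`, `value`)
#' @return numeric matrix with row/column names
#' @export
as_matrix <- function(x) {
  rows <- unique(x$row_id); cols <- unique(x$col_id)
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  m[cbind(match(x$row_id, rows), match(x$col_id, cols))] <- x$value
  m
}

#' Statistic carried by a concordance table
#' @param x an `ens_concordance`
#' @return character scalar, e.g. `"spearman_rho"`
#' @export
statistic_name <- function(x) attr(x, "statistic_name")

#' Pseudobulk cluster profiles
#'
#' Mean lognorm expression per cluster: one profile row per cluster,
#' standing in for a bulk sample of that population.
#'
#' @param dataset an [ens_dataset()] with a `"lognorm"` layer and cluster
#'   labels
#' @param layer layer to average (default `"lognorm"`)
#' @return numeric matrix, clusters by genes
#' @export
pseudobulk <- function(dataset, layer = "lognorm") {
  mat <- get_layer(dataset, layer)
  cl <- dataset$cell_meta$cluster
  assert_that(!anyNA(cl), "cluster labels required for pseudobulk")
  clusters <- sort(unique(cl))
  out <- t(vapply(clusters, function(k)
    colMeans(mat[cl == k, , drop = FALSE]), numeric(ncol(mat))))
  rownames(out) <- clusters
  out
}

#' Select anchor features shared by two datasets
#'
#' Anchor features are genes present in both datasets that are highly
#' variable in at least one of them: genes are ranked within each dataset
#' by decreasing variance of the lognorm layer (rank 1 = most variable),
#' and the shared genes are ordered by the minimum of their two ranks.
#' The top `n` are returned; `n` is capped at the shared-gene count with a
#' warning. Ties are broken by gene symbol.
#'
#' @param a,b [ens_dataset()] objects with `"lognorm"` layers
#' @param n number of anchors (the comparisons of interest use 3000 and
#'   100)
#' @return character vector of anchor gene symbols
#' @export
anchor_features <- function(a, b, n = 3000) {
  shared <- intersect(a$gene_ids, b$gene_ids)
  assert_that(length(shared) >= 3, "datasets share fewer than 3 genes")
  if (n > length(shared)) {
    warn(sprintf("n = %d anchors requested but only %d shared genes; using all",
                 n, length(shared)))
    n <- length(shared)
  }
  var_rank <- function(ds) {
    v <- apply(get_layer(ds, "lognorm"), 2, var)
    r <- rank(-v, ties.method = "first")
    setNames(r, ds$gene_ids)
  }
  ra <- var_rank(a)[shared]
  rb <- var_rank(b)[shared]
  combined <- pmin(ra, rb)
  shared[order(combined, shared)][seq_len(n)]
}

# Spearman rho of two numeric vectors: Pearson correlation of mid-ranks
# (average ranks on ties), the standard convention.
spearman_rho <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  cor(rx, ry, method = "pearson")
}

#' Spearman correlation matrix between two sets of cluster profiles
#'
#' Correlates every cluster profile of dataset A with every profile of
#' dataset B over the anchor genes, using Spearman's rank correlation
#' (mid-ranks on ties).
#'
#' @param pb_a,pb_b pseudobulk matrices from [pseudobulk()] (clusters by
#'   genes, with gene column names)
#' @param anchors character vector of at least 3 anchor gene symbols
#' @return an `ens_concordance` tibble with
#'   `statistic_name = "spearman_rho"`
#' @export
spearman_matrix <- function(pb_a, pb_b, anchors) {
  anchors <- intersect(anchors, intersect(colnames(pb_a), colnames(pb_b)))
  assert_that(length(anchors) >= 3, "need at least 3 anchors present in both")
  a <- pb_a[, anchors, drop = FALSE]
  b <- pb_b[, anchors, drop = FALSE]
  grid <- expand.grid(row_id = rownames(a), col_id = rownames(b),
                      stringsAsFactors = FALSE)
  grid$value <- mapply(function(i, j) spearman_rho(a[i, ], b[j, ]),
                       grid$row_id, grid$col_id)
  new_concordance(as_tibble(grid), "spearman_rho")
}

#' Pairwise dataset concordance by anchored Spearman correlation
#'
#' Convenience wrapper running [pseudobulk()], [anchor_features()] and
#' [spearman_matrix()] at each requested anchor count (both resolutions
#' are reported side by side, as the comparisons of interest use a broad
#' and a narrow anchor set).
#'
#' @param a,b [ens_dataset()] objects with `"lognorm"` layers
#' @param n_anchors integer vector of anchor counts (default
#'   `c(3000, 100)`)
#' @return named list of `ens_concordance` tibbles, one per anchor count
#'   (names `"anchors_3000"` etc.)
#' @export
concordance_spearman <- function(a, b, n_anchors = c(3000, 100)) {
  pa <- pseudobulk(a); pb <- pseudobulk(b)
  out <- lapply(n_anchors, function(n) {
    anchors <- anchor_features(a, b, n)
    spearman_matrix(pa, pb, anchors)
  })
  setNames(out, paste0("anchors_", n_anchors))
}
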