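# Wilcoxon rank-sum test, two-sided.
#
# Exact path: when both groups have <= `exact_max` observations the null
# distribution of the rank-sum is enumerated over all C(n, n1) group
# assignments of the observed (mid-)ranks, which handles ties exactly.
# Otherwise the normal approximation with tie correction is used (no
# continuity correction).
ranksum_p <- function(x, y, exact_max = 10L) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (n1 <= exact_max && n2 <= exact_max) {
    combos <- combn(n, n1)
    sums <- colSums(matrix(r[combos], nrow = n1))
    mu <- mean(sums)
    mean(abs(sums - mu) >= abs(w - mu) - 1e-12)
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- (w - mu) / sqrt(sigma2)
    min(1, 2 * pnorm(-abs(z)))
  }
}

#' Cluster-vs-rest marker statistics
#'
#' For one cluster, tests every gene for upregulation against all other
#' cells: log2 fold-change of de-logged lognorm means (pseudocount 1e-9)
#' and a two-sided Wilcoxon rank-sum p-value (exact enumeration when both
#' groups have at most 10 cells, normal approximation with tie correction
#' otherwise), with Benjamini-Hochberg q-values over all genes.
#'
#' @param dataset an [ens_dataset()] with a `"lognorm"` layer
#' @param cluster cluster label to test (must exist in the metadata)
#' @param layer layer used for testing (default `"lognorm"`)
#' @return tibble with `cluster`, `gene`, `log2fc`, `p`, `q`, ordered by
#'   descending log2fc (ties: smaller p, then gene symbol)
#' @export
rank_markers <- function(dataset, cluster, layer = "lognorm") {
  assert_that(layer %in% names(dataset$layers),
              "requested layer not present; run normalize_counts()")
  in_group <- dataset$cell_meta$cluster == cluster
  if (!any(in_group)) abort(paste0("cluster '", cluster, "' not found"))
  assert_that(sum(in_group) >= 3, "cluster must have at least 3 cells")
  mat <- get_layer(dataset, layer)
  eps <- 1e-9
  m_in <- colMeans(expm1(mat[in_group, , drop = FALSE]))
  m_out <- colMeans(expm1(mat[!in_group, , drop = FALSE]))
  log2fc <- log2((m_in + eps) / (m_out + eps))
  p <- vapply(seq_len(ncol(mat)), function(g) {
    xi <- mat[in_group, g]; yo <- mat[!in_group, g]
    if (all(xi == xi[1]) && all(yo == xi[1])) return(1)
    ranksum_p(xi, yo)
  }, numeric(1))
  q <- p.adjust(p, method = "BH")
  tibble(cluster = cluster, gene = colnames(mat), log2fc = log2fc,
         p = p, q = q) |>
    arrange(desc(.data$log2fc), .data$p, .data$gene)
}

#' Marker tables for every cluster of a dataset
#'
#' @param dataset an [ens_dataset()] with cluster labels and a lognorm layer
#' @param layer layer used for testing
#' @return tibble stacking [rank_markers()] over all clusters
#' @export
rank_all_markers <- function(dataset, layer = "lognorm") {
  clusters <- sort(unique(dataset$cell_meta$cluster))
  bind_rows(lapply(clusters, function(k) rank_markers(dataset, k, layer)))
}

#' Build per-cluster signature modules from marker tables
#'
#' A cluster's signature module is its top `k_top` significantly
#' upregulated genes: `q <= q_max`, `log2fc > 0`, ranked by descending
#' log2 fold-change (ties broken by smaller p, then gene symbol). Modules
#' with fewer than 5 genes are flagged.
#'
#' @param markers tibble from [rank_all_markers()] (or one or more
#'   [rank_markers()] results bound together)
#' @param dataset_id identifier recorded as the signatures' source
#' @param k_top maximum genes per module (default 100)
#' @param q_max BH-adjusted significance cutoff (default 0.05)
#' @return tibble of class `ens_signatures` with `source_dataset`,
#'   `source_cluster`, `gene`, `log2fc`, `p`, `q`, `rank`, `flagged`
#' @export
build_signatures <- function(markers, dataset_id = "ref", k_top = 100,
                             q_max = 0.05) {
  sig <- markers |>
    filter(.data$q <= q_max, .data$log2fc > 0) |>
    group_by(.data$cluster) |>
    arrange(desc(.data$log2fc), .data$p, .data$gene, .by_group = TRUE) |>
    mutate(rank = seq_len(n())) |>
    filter(.data$rank <= k_top) |>
    ungroup() |>
    mutate(source_dataset = dataset_id, flagged = FALSE) |>
    rename(source_cluster = "cluster") |>
    select("source_dataset", "source_cluster", "gene", "log2fc", "p", "q",
           "rank", "flagged")
  small <- sig |> count(.data$source_cluster) |> filter(.data$n < 5)
  if (nrow(small) > 0) {
    warn(paste0("signature module(s) with fewer than 5 genes: ",
                paste(small$source_cluster, collapse = ", ")))
    sig$flagged <- sig$source_cluster %in% small$source_cluster
  }
  structure(sig, class = c("ens_signatures", class(sig)))
}

#' Signature modules as a named list of gene vectors
#' @param signatures an `ens_signatures` tibble
#' @return named list; names are `source_dataset.source_cluster`
#' @export
signature_sets <- function(signatures) {
  key <- paste(signatures$source_dataset, signatures$source_cluster,
               sep = ".")
  split(signatures$gene, factor(key, levels = unique(key)))
}

#' Score signature modules across a query dataset
#'
#' Scores every signature module in every cell of the query via the
#' expression-matched module score, then averages within query clusters:
#' the cross-dataset module-score heatmap. Signatures with no gene present
#' in the query yield a column of `NA` with a warning.
#'
#' @param query an [ens_dataset()] with the scored layer present
#' @param signatures an `ens_signatures` tibble (from another dataset)
#' @param layer layer to score on (default `"lognorm"`)
#' @param n_bins,n_ctrl,seed module-score parameters
#' @return an `ens_concordance` tibble: `row_id` (query cluster),
#'   `col_id` (signature), `value` (mean module score), with
#'   `statistic_name = "mean_module_score"`
#' @export
cross_score <- function(query, signatures, layer = "lognorm", n_bins = 25,
                        n_ctrl = 50, seed = 1L) {
  mat <- get_layer(query, layer)
  sets <- signature_sets(signatures)
  clusters <- query$cell_meta$cluster
  out <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    nm <- names(sets)[i]
    if (!any(sets[[i]] %in% colnames(mat))) {
      warn(paste0("signature '", nm, "' shares no genes with the query"))
      sc <- rep(NA_real_, nrow(mat))
    } else {
      sc <- score_genes(mat, sets[[i]], n_bins = n_bins, n_ctrl = n_ctrl,
                        seed = stage_seed(seed, nm))
    }
    out[[i]] <- tibble(row_id = clusters, col_id = nm, score = sc) |>
      group_by(.data$row_id, .data$col_id) |>
      summarise(value = mean(.data$score), .groups = "drop")
  }
  new_concordance(bind_rows(out), "mean_module_score")
}

#' Marker-list intersection report
#'
#' Venn-style breakdown of user-supplied named marker lists: for every
#' non-empty subset of list names, the genes found in exactly those lists,
#' plus the all-lists intersection.
#'
#' @param marker_lists named list (>= 2 entries) of gene-symbol vectors
#' @return list with `membership` (tibble: `subset`, `n_genes`, `genes`)
#'   and `shared_all` (character vector in every list)
#' @export
marker_overlap_report <- function(marker_lists) {
  assert_that(length(marker_lists) >= 2 && !is.null(names(marker_lists)),
              "need at least two named marker lists")
  marker_lists <- lapply(marker_lists, unique)
  genes <- unique(unlist(marker_lists))
  member <- vapply(marker_lists, function(s) genes %in% s,
                   logical(length(genes)))
  if (length(genes) == 1L) member <- matrix(member, nrow = 1)
  subset_key <- apply(member, 1, function(m)
    paste(names(marker_lists)[m], collapse = "&"))
  membership <- tibble(gene = genes, subset = subset_key) |>
    group_by(.data$subset) |>
    summarise(n_genes = n(),
              genes = paste(sort(.data$gene), collapse = ";"),
              .groups = "drop") |>
    arrange(desc(.data$n_genes))
  shared_all <- genes[rowSums(member) == length(marker_lists)]
  list(membership = membership, shared_all = sort(shared_all))
}

#' Read / write gene-set collections in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name <tab> description <tab> gene1 <tab> gene2 ...`.
#'
#' @param path GMT file path
#' @return for `read_gmt`, a named list of gene-symbol vectors
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(parts, function(p) unique(p[-c(1, 2)])),
           vapply(parts, `[`, character(1), 1))
}

#' @rdname read_gmt
#' @param sets named list of gene vectors
#' @param description description field written for each set
#' @export
write_gmt <- function(sets, path, description = "ensid") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
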