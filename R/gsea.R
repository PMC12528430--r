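#' Ranked gene list for pre-ranked GSEA
#'
#' Orders a cluster's marker table by descending log2 fold-change (ties
#' broken by gene symbol, for determinism) into the pre-ranked input of
#' the enrichment walk.
#'
#' @param markers marker tibble for one cluster (from [rank_markers()])
#' @return list with `genes` (ordered symbols) and `metric` (their log2
#'   fold-changes)
#' @export
ranked_list <- function(markers) {
  assert_that(all(c("gene", "log2fc") %in% names(markers)),
              "markers must have gene and log2fc columns")
  assert_that(!anyDuplicated(markers$gene), "duplicate genes in ranked list")
  assert_that(all(is.finite(markers$log2fc)), "ranking metric must be finite")
  ord <- order(-markers$log2fc, markers$gene)
  list(genes = markers$gene[ord], metric = markers$log2fc[ord])
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks down the ranked list: at a set gene ("hit") the running sum rises
#' by that gene's share of the set's total weight
#' (`|metric|^weight_exponent`); at a miss it falls by `1/(N - n_set)`.
#' The enrichment score is the maximal signed deviation of the running sum
#' from zero.
#'
#' @param ranked a [ranked_list()]
#' @param gene_set character vector of gene symbols
#' @param weight_exponent exponent on `|metric|` for hit increments
#'   (default 1; 0 gives the unweighted KS statistic)
#' @return list with `es` (the score) and `running` (the running sum at
#'   every position)
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  genes <- ranked$genes
  hit <- genes %in% gene_set
  assert_that(any(hit), "no gene of the set occurs in the ranked list")
  n <- length(genes)
  n_set <- sum(hit)
  w <- abs(ranked$metric)^weight_exponent
  w_hit <- w * hit
  denom <- sum(w_hit)
  inc <- if (denom > 0) w_hit / denom else hit / n_set
  miss_pen <- if (n > n_set) 1 / (n - n_set) else 0
  steps <- inc - (!hit) * miss_pen
  running <- cumsum(steps)
  es <- signed_extreme(max(running), min(running))
  list(es = es, running = running)
}

# ES from hit positions only, O(n_set) per evaluation. The running sum is
# piecewise linear between hits, so its extrema occur immediately after a
# hit or immediately before the next one; checking those points suffices.
es_from_positions <- function(hit_pos, hit_w, n) {
  m <- length(hit_pos)
  denom <- sum(hit_w)
  inc <- if (denom > 0) hit_w / denom else rep(1 / m, m)
  pen <- if (n > m) 1 / (n - m) else 0
  cw <- cumsum(inc)
  after <- cw - (hit_pos - seq_len(m)) * pen
  before <- c(0, cw[-m]) - (hit_pos - seq_len(m)) * pen
  cand <- c(after, before)
  signed_extreme(max(cand, 0), min(cand, 0))
}

# Signed maximal deviation; on a magnitude tie (to within floating-point
# tolerance) the positive extreme wins, so both ES code paths agree
# deterministically.
signed_extreme <- function(mx, mn) {
  if (mx >= -mn - 1e-12) mx else mn
}

#' NES and permutation p-value for one gene set
#'
#' The null distribution is generated by gene-set permutation: `n_perm`
#' random same-size gene sets drawn from the ranked list (the only valid
#' permutation scheme for pre-ranked input). Normalization is
#' sign-stratified: NES = ES divided by the mean |null ES| of the same
#' sign; the p-value is the add-one-corrected fraction of same-sign null
#' scores at least as extreme.
#'
#' @param ranked a [ranked_list()]
#' @param gene_set character vector of gene symbols
#' @param n_perm number of permutations (>= 100; default 1000)
#' @param weight_exponent see [enrichment_score()]
#' @param seed integer seed
#' @return tibble (`es`, `nes`, `p`, `n_hits`, `n_perm`)
#' @export
nes_and_p <- function(ranked, gene_set, n_perm = 1000, weight_exponent = 1,
                      seed = 1L) {
  assert_that(n_perm >= 100, "n_perm must be at least 100")
  obs <- enrichment_score(ranked, gene_set, weight_exponent)$es
  n_set <- sum(ranked$genes %in% gene_set)
  null_es <- null_es_distribution(ranked, n_set, n_perm, weight_exponent,
                                  seed)
  same <- null_es[sign(null_es) == sign(obs)]
  nes <- if (length(same) > 0 && mean(abs(same)) > 0) {
    obs / mean(abs(same))
  } else if (obs == 0) 0 else NA_real_
  p <- (1 + sum(abs(same) >= abs(obs))) / (1 + length(same))
  tibble(es = obs, nes = nes, p = p, n_hits = n_set, n_perm = n_perm)
}

# Null ES sample for random same-size gene sets, drawn by hit position
# (equivalent to sampling gene identities uniformly without replacement).
null_es_distribution <- function(ranked, n_set, n_perm, weight_exponent,
                                 seed) {
  n <- length(ranked$genes)
  w <- abs(ranked$metric)^weight_exponent
  with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pos <- sort(sample.int(n, n_set))
      es_from_positions(pos, w[pos], n)
    }, numeric(1))
  })
}

#' NES matrix across clusters and pathways
#'
#' Runs pre-ranked GSEA for every (cluster, pathway) combination and
#' assembles the clusters-by-pathways NES matrix restricted to pathways
#' significant (BH q <= `q_max`, within each cluster's test family) in at
#' least one cluster. Non-significant entries are set to 0.
#'
#' @param markers combined marker tibble (from [rank_all_markers()],
#'   possibly over several datasets; cluster ids should carry dataset
#'   provenance)
#' @param pathways named list of gene sets (e.g. from [read_gmt()] or
#'   [simulate_pathway_catalog()])
#' @param q_max significance cutoff for the at-least-one-cluster filter
#'   (default 0.25)
#' @param n_perm,weight_exponent,seed see [nes_and_p()]
#' @param min_hits skip pathways with fewer matching genes (default 3)
#' @return list with `matrix` (an `ens_concordance`, statistic `"nes"`)
#'   and `table` (full per-pair GSEA results with q-values)
#' @export
nes_matrix <- function(markers, pathways, q_max = 0.25, n_perm = 1000,
                       weight_exponent = 1, seed = 1L, min_hits = 3) {
  clusters <- unique(markers$cluster)
  res <- vector("list", length(clusters))
  for (i in seq_along(clusters)) {
    k <- clusters[i]
    ranked <- ranked_list(markers[markers$cluster == k, ])
    # share the size-matched null across same-size pathways: the null ES
    # depends only on the set size, not on which genes are in the set
    null_cache <- new.env(parent = emptyenv())
    rows <- lapply(names(pathways), function(pw) {
      hits <- sum(ranked$genes %in% pathways[[pw]])
      if (hits < min_hits) return(NULL)
      key <- as.character(hits)
      if (is.null(null_cache[[key]])) {
        null_cache[[key]] <- null_es_distribution(
          ranked, hits, n_perm, weight_exponent,
          seed = stage_seed(seed, paste(k, "null", hits)))
      }
      null_es <- null_cache[[key]]
      obs <- enrichment_score(ranked, pathways[[pw]], weight_exponent)$es
      same <- null_es[sign(null_es) == sign(obs)]
      nes <- if (length(same) > 0 && mean(abs(same)) > 0) {
        obs / mean(abs(same))
      } else if (obs == 0) 0 else NA_real_
      p <- (1 + sum(abs(same) >= abs(obs))) / (1 + length(same))
      tibble(es = obs, nes = nes, p = p, n_hits = hits, n_perm = n_perm,
             cluster = k, pathway = pw)
    })
    tab <- bind_rows(rows)
    if (nrow(tab) > 0) tab$q <- p.adjust(tab$p, method = "BH")
    res[[i]] <- tab
  }
  tab <- bind_rows(res)
  assert_that(nrow(tab) > 0, "no pathway had enough genes in any ranked list")
  sig_pw <- unique(tab$pathway[tab$q <= q_max])
  assert_that(length(sig_pw) > 0, "no pathway enriched in any cluster")
  wide <- tab |>
    filter(.data$pathway %in% sig_pw) |>
    mutate(value = ifelse(.data$q <= q_max, .data$nes, 0)) |>
    dplyr::transmute(row_id = .data$cluster, col_id = .data$pathway,
                     value = .data$value) |>
    tidyr::complete(row_id = clusters, col_id = sig_pw,
                    fill = list(value = 0))
  list(matrix = new_concordance(wide, "nes"), table = tab)
}

#' Hierarchical clustering of clusters by NES profile
#'
#' Agglomerative clustering of the NES matrix rows (enteric neuron
#' clusters from any number of datasets) and a cut into `k` groups; the
#' dendrogram is also returned as a Newick string with branch lengths
#' equal to merge heights.
#'
#' @param nes an `ens_concordance` with statistic `"nes"` (or any numeric
#'   matrix / concordance of cluster profiles)
#' @param k number of groups to cut (default 4, the resolution at which
#'   the tree separates its main branches)
#' @param linkage agglomeration method (default `"average"`)
#' @param distance distance metric (default `"euclidean"`)
#' @return list with `labels` (tibble `row_id`, `group`), `hclust`,
#'   `newick`
#' @export
cluster_nes <- function(nes, k = 4, linkage = "average",
                        distance = "euclidean") {
  m <- if (inherits(nes, "ens_concordance")) as_matrix(nes) else as.matrix(nes)
  assert_that(nrow(m) >= k, "need at least k rows to cut into k groups")
  hc <- hclust(dist(m, method = distance), method = linkage)
  groups <- cutree(hc, k = k)
  phylo <- ape::as.phylo(hc)
  newick <- ape::write.tree(phylo)
  list(labels = tibble(row_id = names(groups), group = unname(groups)),
       hclust = hc, newick = newick)
}

#' Meta-cluster pathway averages
#'
#' Averages NES per pathway within each group of the tree cut and flags
#' pathways uniquely enriched in one group: positive mean there and
#' non-positive mean in every other group.
#'
#' @param nes an `ens_concordance` with statistic `"nes"`
#' @param labels tibble (`row_id`, `group`) from [cluster_nes()]
#' @return list with `means` (tibble `group`, `pathway`, `mean_nes`) and
#'   `unique_pathways` (tibble `group`, `pathway`)
#' @export
metacluster_pathways <- function(nes, labels) {
  df <- left_join(as_tibble(nes), labels, by = "row_id")
  assert_that(!anyNA(df$group), "labels must cover every matrix row")
  means <- df |>
    group_by(.data$group, pathway = .data$col_id) |>
    summarise(mean_nes = mean(.data$value), .groups = "drop")
  uniq <- means |>
    group_by(.data$pathway) |>
    filter(.data$mean_nes > 0 & sum(.data$mean_nes > 0) == 1) |>
    ungroup() |>
    select("group", "pathway")
  list(means = means, unique_pathways = arrange(uniq, .data$group,
                                                .data$pathway))
}
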