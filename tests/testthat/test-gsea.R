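toy_ranked <- function(n = 5, metric = NULL) {
  ranked_list(tibble::tibble(gene = paste0("g", seq_len(n)),
                             log2fc = metric %||% seq(n, 1)))
}

test_that("enrichment score walks match hand computations", {
  r <- toy_ranked(5)
  # single hit at rank 1: full normalized weight before any miss penalty
  expect_equal(enrichment_score(r, "g1")$es, 1)
  # the full list as a set can only rise, reaching exactly 1
  expect_equal(enrichment_score(r, paste0("g", 1:5))$es, 1)
  # single hit at the last rank: four miss steps of -1/4 reach -1
  expect_equal(enrichment_score(r, "g5")$es, -1)
  expect_error(enrichment_score(r, "absent"), "no gene")
})

test_that("ranked lists are ordered by metric with deterministic ties", {
  mk <- tibble::tibble(gene = c("b", "a", "c"), log2fc = c(2, 2, 5))
  r <- ranked_list(mk)
  expect_equal(r$genes, c("c", "a", "b"))
  expect_error(ranked_list(tibble::tibble(gene = c("a", "a"),
                                          log2fc = c(1, 2))), "duplicate")
  expect_error(ranked_list(tibble::tibble(gene = "a", log2fc = Inf)),
               "finite")
})

test_that("ES equals the brute-force running-sum oracle on short lists", {
  set.seed(21)
  for (trial in 1:100) {
    n <- sample(3:12, 1)
    metric <- sort(round(runif(n, -2, 4), 2), decreasing = TRUE)
    genes <- paste0("x", seq_len(n))
    r <- list(genes = genes, metric = metric)
    set_genes <- sample(genes, sample(1:n, 1))
    w_exp <- sample(c(0, 1), 1)
    expect_equal(enrichment_score(r, set_genes, w_exp)$es,
                 oracle_es(genes, metric, set_genes, w_exp),
                 tolerance = 1e-12)
  }
})

test_that("reversing the list negates the unweighted ES", {
  set.seed(22)
  metric <- sort(runif(10, 0.5, 3), decreasing = TRUE)
  genes <- paste0("g", 1:10)
  r_fwd <- list(genes = genes, metric = metric)
  r_rev <- list(genes = rev(genes), metric = rev(metric))
  for (trial in 1:10) {
    s <- sample(genes, 3)
    es_f <- enrichment_score(r_fwd, s, weight_exponent = 0)$es
    es_r <- enrichment_score(r_rev, s, weight_exponent = 0)$es
    if (abs(abs(es_f) - abs(es_r)) < 1e-9 && abs(es_f) > 1e-9) {
      expect_equal(es_r, -es_f, tolerance = 1e-9)
    }
  }
})

test_that("our ES agrees with fgsea's statistic", {
  skip_if_not_installed("fgsea")
  set.seed(23)
  n <- 50
  stats_v <- sort(rnorm(n, 0, 2), decreasing = TRUE)
  names(stats_v) <- paste0("g", 1:n)
  r <- list(genes = names(stats_v), metric = unname(stats_v))
  idx <- sort(sample(n, 8))
  es_ours <- enrichment_score(r, names(stats_v)[idx])$es
  es_fgsea <- fgsea::calcGseaStat(stats_v, idx, gseaParam = 1)
  expect_equal(es_ours, es_fgsea, tolerance = 1e-9)
})

test_that("NES is seed-deterministic and detects planted signal", {
  set.seed(24)
  metric <- sort(rnorm(300, 0, 1.5), decreasing = TRUE)
  r <- list(genes = paste0("g", 1:300), metric = metric)
  top_set <- paste0("g", 1:12)
  a <- nes_and_p(r, top_set, n_perm = 1000, seed = 7)
  b <- nes_and_p(r, top_set, n_perm = 1000, seed = 7)
  expect_identical(a, b)
  expect_gt(a$nes, 0)
  expect_lte(a$p, 0.01)
  expect_error(nes_and_p(r, top_set, n_perm = 50), "at least 100")
})

test_that("NES matrix keeps pathways enriched somewhere and zeroes the rest", {
  set.seed(25)
  mk <- dplyr::bind_rows(lapply(c("K1", "K2"), function(k) {
    fc <- rnorm(200, 0, 0.3)
    names(fc) <- sprintf("g%03d", 1:200)
    if (k == "K1") fc[1:10] <- fc[1:10] + 4
    tibble::tibble(cluster = k, gene = names(fc), log2fc = unname(fc))
  }))
  pw <- list(SIG = sprintf("g%03d", 1:10),
             NULL1 = sprintf("g%03d", 101:115),
             NULL2 = sprintf("g%03d", 151:165))
  res <- nes_matrix(mk, pw, q_max = 0.05, n_perm = 500, seed = 3)
  m <- as_matrix(res$matrix)
  expect_true("SIG" %in% colnames(m))
  expect_setequal(rownames(m), c("K1", "K2"))
  expect_gt(m["K1", "SIG"], 0)
  # entries not significant are exactly zero
  tab <- res$table
  ns <- tab[tab$q > 0.05 & tab$pathway %in% colnames(m), ]
  if (nrow(ns) > 0) {
    vals <- mapply(function(k, p) m[k, p], ns$cluster, ns$pathway)
    expect_true(all(vals == 0))
  }
})

test_that("hierarchical NES clustering recovers planted groups", {
  skip_if_not_installed("mclust")
  set.seed(26)
  centers <- matrix(rnorm(4 * 20, 0, 2), 4, 20)
  rows <- centers[rep(1:4, each = 3), ] + rnorm(12 * 20, 0, 0.1)
  rownames(rows) <- sprintf("r%02d", 1:12)
  cut <- cluster_nes(rows, k = 4)
  ari <- mclust::adjustedRandIndex(cut$labels$group, rep(1:4, each = 3))
  expect_equal(ari, 1)
  expect_match(cut$newick, "^\\(")
  # identical rows merge first at height zero
  two <- rbind(a = rows[1, ], b = rows[1, ], c = rows[7, ])
  hc <- cluster_nes(two, k = 2)$hclust
  expect_equal(hc$height[1], 0)
  # k = number of rows: singletons
  singl <- cluster_nes(rows, k = 12)
  expect_equal(sort(unique(singl$labels$group)), 1:12)
  expect_error(cluster_nes(rows[1:2, ], k = 4), "at least k")
})

test_that("meta-cluster averaging flags uniquely enriched pathways", {
  df <- tidyr::expand_grid(row_id = sprintf("r%d", 1:4),
                           col_id = c("pwA", "pwB", "pwC"))
  df$value <- 0
  df$value[df$col_id == "pwA" & df$row_id %in% c("r1", "r2")] <- 2
  df$value[df$col_id == "pwB"] <- 1  # positive everywhere
  nes <- ensid:::new_concordance(df, "nes")
  labels <- tibble::tibble(row_id = sprintf("r%d", 1:4),
                           group = c(1, 1, 2, 2))
  out <- metacluster_pathways(nes, labels)
  uniq <- out$unique_pathways
  expect_equal(uniq$pathway[uniq$group == 1], "pwA")
  expect_false("pwC" %in% uniq$pathway)  # all-zero column unique nowhere
  expect_false("pwB" %in% uniq$pathway)  # positive in both groups
  cm <- out$means
  expect_equal(cm$mean_nes[cm$pathway == "pwB"], c(1, 1))
})
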