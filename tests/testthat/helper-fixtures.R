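# Shared fixtures, built in code. Heavy simulated objects are cached in an
# environment so several test files can reuse one realization.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# A tiny fully deterministic dataset: 6 cells, 8 genes, two clusters.
tiny_dataset <- function() {
  genes <- c("NOS1", "NOS1AP", "ASL", "CHAT", "SLC5A7", "G1", "G2", "G3")
  counts <- rbind(
    c(5, 4, 3, 0, 0, 2, 1, 1),
    c(4, 5, 4, 0, 0, 1, 2, 1),
    c(6, 3, 5, 0, 0, 2, 2, 1),
    c(0, 0, 0, 5, 4, 1, 1, 2),
    c(0, 0, 0, 4, 6, 2, 1, 1),
    c(0, 0, 0, 6, 5, 1, 2, 2)
  )
  colnames(counts) <- genes
  rownames(counts) <- paste0("c", 1:6)
  meta <- tibble::tibble(barcode = paste0("c", 1:6), dataset_id = "toy",
                         cluster = rep(c("K1", "K2"), each = 3),
                         annotation = rep(c("IMN", "EMN"), each = 3))
  ens_dataset(counts, cell_meta = meta)
}

# Moderate simulated dataset with programs, used by preprocess/classify
# tests (cached: one simulation serves several files).
small_sim <- function() {
  cache_get("small_sim", function() {
    cfg <- sim_config(n_cells = 800, n_genes = 1200, n_clusters = 4,
                      seed = 301L, dropout_rate = 0.1)
    sim <- simulate_dataset(cfg)
    sim$dataset <- impute_knn(normalize_counts(sim$dataset))
    sim
  })
}

# Small separable dataset pair for transfer/concordance unit tests.
small_pair <- function() {
  cache_get("small_pair", function() {
    cfg <- sim_config(n_cells = 600, n_genes = 1200, n_clusters = 5,
                      seed = 302L, batch_effect_sd = 0.3,
                      anchor_programs = TRUE)
    pair <- simulate_dataset_pair(cfg, divergence_seed = 77L)
    pair$a$dataset <- normalize_counts(pair$a$dataset)
    pair$b$dataset <- normalize_counts(pair$b$dataset)
    pair
  })
}

# Independent dense module-score oracle: explicit loops, own binning, same
# documented RNG protocol for the control draws (seeded sample.int on the
# sorted non-set pool).
oracle_module_score <- function(mat, gene_set, n_bins, n_ctrl, seed) {
  genes <- colnames(mat)
  gene_set <- unique(gene_set[gene_set %in% genes])
  means <- numeric(ncol(mat))
  for (g in seq_len(ncol(mat))) means[g] <- mean(mat[, g])
  ord <- order(means, genes)
  rk <- integer(ncol(mat)); rk[ord] <- seq_len(ncol(mat))
  bin <- pmin(floor((rk - 1) * n_bins / ncol(mat)) + 1L, n_bins)
  set_idx <- match(gene_set, genes)
  ctrl <- matrix(0, nrow(mat), length(set_idx))
  withr::with_seed(seed, {
    for (j in seq_along(set_idx)) {
      pool <- setdiff(which(bin == bin[set_idx[j]]), set_idx)
      if (length(pool) == 0) pool <- which(bin == bin[set_idx[j]])
      draws <- pool[sample.int(length(pool), min(n_ctrl, length(pool)))]
      for (c in seq_len(nrow(mat))) ctrl[c, j] <- mean(mat[c, draws])
    }
  })
  out <- numeric(nrow(mat))
  for (c in seq_len(nrow(mat))) {
    out[c] <- mean(mat[c, set_idx]) - mean(ctrl[c, ])
  }
  out
}

# Exhaustive rank-sum enumeration oracle over actual values.
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(n, n1)
  sums <- colSums(matrix(r[combos], nrow = n1))
  mu <- mean(sums)
  mean(abs(sums - mu) >= abs(w_obs - mu) - 1e-12)
}

# Brute-force GSEA running-sum oracle (position-by-position walk).
oracle_es <- function(genes, metric, gene_set, w_exp = 1) {
  n <- length(genes)
  hit <- genes %in% gene_set
  w <- abs(metric)^w_exp
  denom <- sum(w[hit])
  running <- numeric(n); s <- 0
  for (i in seq_len(n)) {
    s <- s + if (hit[i]) {
      if (denom > 0) w[i] / denom else 1 / sum(hit)
    } else -1 / (n - sum(hit))
    running[i] <- s
  }
  mx <- max(running); mn <- min(running)
  if (mx >= -mn - 1e-12) mx else mn
}

expect_fraction <- function(x) {
  testthat::expect_true(all(x >= 0 & x <= 1))
}
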