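test_that("config validation rejects degenerate settings", {
  expect_error(sim_config(n_cells = 0), "positive")
  expect_error(sim_config(multiplicity_probs = c(0.5, 0.5, 0.5, 0.5)),
               "sum to 1")
  expect_error(sim_config(dropout_rate = 1.5), "dropout")
  expect_error(sim_config(n_genes = 50), "too small")
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_cells = 150, n_genes = 400, n_clusters = 3,
                    markers_per_cluster = 4, seed = 9L)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(as.matrix(s1$dataset$counts), as.matrix(s2$dataset$counts))
  expect_identical(s1$truth, s2$truth)
})

test_that("program effect drives hallmark expression as configured", {
  # disabled effect: planted and unplanted means agree
  cfg0 <- sim_config(n_cells = 1200, n_genes = 800, n_clusters = 3,
                     program_effect = 1, dropout_rate = 0, seed = 21L)
  s0 <- simulate_dataset(cfg0)
  cnt0 <- as.matrix(s0$dataset$counts)
  planted0 <- grepl("nitrergic", s0$truth$planted)
  ratio0 <- mean(cnt0[planted0, "NOS1"]) / mean(cnt0[!planted0, "NOS1"])
  expect_gt(ratio0, 0.8); expect_lt(ratio0, 1.25)

  # effect 8: fold change recovered within Monte-Carlo error
  cfg8 <- sim_config(n_cells = 2000, n_genes = 800, n_clusters = 3,
                     program_effect = 8, seed = 7L)
  s8 <- simulate_dataset(cfg8)
  cnt8 <- as.matrix(s8$dataset$counts)
  planted8 <- grepl("nitrergic", s8$truth$planted)
  ratio8 <- mean(cnt8[planted8, "NOS1"]) / mean(cnt8[!planted8, "NOS1"])
  expect_gt(ratio8, 6); expect_lt(ratio8, 10)
})

test_that("planted multiplicity follows the configured probabilities", {
  cfg <- sim_config(n_cells = 2000, n_genes = 800, n_clusters = 4, seed = 5L)
  s <- simulate_dataset(cfg)
  frac_assigned <- mean(s$truth$multiplicity >= 1)
  # 1 - P(0) = 0.9, binomial 3 SE ~ 0.02
  expect_lt(abs(frac_assigned - 0.9), 0.025)
  expect_true(all(s$truth$multiplicity %in% 0:3))
  expect_true(all(vapply(strsplit(s$truth$planted, ";"), function(x)
    !anyDuplicated(x), logical(1))))
})

test_that("dataset pairs share archetypes but diverge in batch and names", {
  cfg <- sim_config(n_cells = 300, n_genes = 600, n_clusters = 4,
                    batch_effect_sd = 0, dropout_rate = 0, seed = 31L,
                    anchor_programs = TRUE)
  pair <- simulate_dataset_pair(cfg, divergence_seed = 8L)
  map <- pair$archetype_map
  # bijection between the two cluster vocabularies
  expect_false(anyDuplicated(map$cluster_a) > 0)
  expect_false(anyDuplicated(map$cluster_b) > 0)
  expect_setequal(map$cluster_a, unique(pair$a$dataset$cell_meta$cluster))
  expect_setequal(map$cluster_b, unique(pair$b$dataset$cell_meta$cluster))
  expect_true(length(intersect(map$cluster_a, map$cluster_b)) == 0)

  # batch_effect_sd = 0: matched archetype pseudobulk agree in expectation
  a <- normalize_counts(pair$a$dataset); b <- normalize_counts(pair$b$dataset)
  pa <- pseudobulk(a); pb <- pseudobulk(b)
  for (i in seq_len(nrow(map))) {
    expect_gt(cor(pa[map$cluster_a[i], ], pb[map$cluster_b[i], ]), 0.98)
  }
})

test_that("synthetic pathway catalog aligns with planted programs", {
  cfg <- sim_config(n_cells = 50, n_genes = 600, n_clusters = 3, seed = 2L)
  s <- simulate_dataset(cfg)
  cat6 <- default_program_catalog()
  pw <- simulate_pathway_catalog(s$dataset$gene_ids, cat6, n_decoy = 10,
                                 seed = 4L)
  expect_length(pw, 16)
  expect_setequal(pw$PROGRAM_NITRERGIC,
                  c("NOS1", "NOS1AP", "ARG1", "ARG2", "ASL", "ASS1"))
  expect_true(all(unlist(pw) %in% s$dataset$gene_ids))
})

test_that("simulation bundles round-trip to disk with ground truth", {
  cfg <- sim_config(n_cells = 60, n_genes = 500, n_clusters = 3, seed = 12L)
  s <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_simulation(s, dir)
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  back <- read_ens_dataset(dir)
  expect_equal(as.matrix(back$counts), as.matrix(s$dataset$counts))
})
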