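test_that("hallmark gate is the max-over-set rule", {
  mat <- matrix(c(0, 0.7,
                  0, 0,
                  1.2, 0), nrow = 3, byrow = TRUE,
                dimnames = list(NULL, c("GAD1", "GAD2")))
  expect_equal(hallmark_gate(mat, c("GAD1", "GAD2")), c(TRUE, FALSE, TRUE))
  expect_equal(hallmark_gate(mat, "GAD1"), c(FALSE, FALSE, TRUE))
  # raising min_expr never flips a failing cell to passing
  g0 <- hallmark_gate(mat, c("GAD1", "GAD2"), min_expr = 0)
  g1 <- hallmark_gate(mat, c("GAD1", "GAD2"), min_expr = 0.9)
  expect_true(all(g0 | !g1))
  expect_error(hallmark_gate(mat, "ABSENT"), "no hallmark")
})

test_that("both steps are required for a final call", {
  # cell 1 co-expresses NOS1 and CHAT programs; cell 2 has support without
  # hallmark; cells 3-6 background
  genes <- c("NOS1", "NOS1AP", "ARG1", "ASL", "CHAT", "SLC5A7", "ACHE",
             paste0("g", 1:13))
  mat <- matrix(rep(c(0.4, 0.5, 0.45, 0.5, 0.42, 0.48), 20), 6, 20)
  colnames(mat) <- genes
  mat[1, c("NOS1", "NOS1AP", "ARG1", "ASL")] <- 3
  mat[1, c("CHAT", "SLC5A7", "ACHE")] <- 3
  mat[2, c("NOS1AP", "ARG1", "ASL")] <- 3
  mat[2, "NOS1"] <- 0   # support without hallmark
  ds <- ens_dataset(matrix(1L, 6, 20, dimnames = list(NULL, genes)))
  ds$layers$lognorm <- mat
  progs <- dplyr::bind_rows(
    ens_program("nitrergic", "NOS1", c("NOS1AP", "ARG1", "ASL")),
    ens_program("cholinergic", "CHAT", c("SLC5A7", "ACHE"))
  )
  calls <- classify_neurochem(ds, progs, layer = "lognorm", n_bins = 1,
                              n_ctrl = 10, seed = 2)
  cs <- called_sets(calls)
  expect_true(grepl("cholinergic", cs$called_set[1]) &&
                grepl("nitrergic", cs$called_set[1]))
  expect_equal(cs$called_set[2], "")
  df <- tibble::as_tibble(calls)
  expect_true(all(df$hallmark_pass[df$final_call]))
})

test_that("raising the score threshold only shrinks called sets", {
  sim <- small_sim()
  lo <- called_sets(classify_neurochem(sim$dataset, layer = "lognorm",
                                       score_threshold = 0, seed = 4))
  hi <- called_sets(classify_neurochem(sim$dataset, layer = "lognorm",
                                       score_threshold = 0.5, seed = 4))
  split_sets <- function(x) strsplit(x, ";", fixed = TRUE)
  shrunk <- mapply(function(a, b) all(b %in% a),
                   split_sets(lo$called_set), split_sets(hi$called_set))
  expect_true(all(shrunk))
  expect_true(all(hi$multiplicity <= lo$multiplicity))
})

test_that("multiplicity profile counts mono/double/unassigned correctly", {
  df <- tibble::tibble(
    barcode = c("a", "b", "c"), layer = "lognorm",
    class = "nitrergic", hallmark_pass = TRUE, module_score = 1,
    final_call = TRUE)
  calls <- structure(df, class = c("ens_calls", class(df)),
                     layer = "lognorm",
                     called = tibble::tibble(
                       barcode = c("a", "b", "c"),
                       called_set = c("X", "X;Y", ""),
                       multiplicity = c(1L, 2L, 0L)))
  prof <- multiplicity_profile(calls)
  expect_equal(prof$n_cells, c(1L, 1L, 1L, 0L))
  expect_equal(sum(prof$frac_assigned, na.rm = TRUE), 1)
  expect_fraction(prof$frac_all)
})

test_that("class-by-cluster fractions count calls within clusters", {
  df <- tibble::tibble(
    barcode = sprintf("c%02d", 1:10), layer = "lognorm",
    class = "nitrergic", hallmark_pass = TRUE,
    module_score = 1,
    final_call = c(rep(TRUE, 4), rep(FALSE, 6)))
  df2 <- dplyr::mutate(df, class = "cholinergic", final_call = FALSE)
  calls <- structure(dplyr::bind_rows(df, df2),
                     class = c("ens_calls", class(df)), layer = "lognorm",
                     called = NULL)
  meta <- tibble::tibble(barcode = sprintf("c%02d", 1:10), cluster = "K1")
  tab <- class_by_cluster(calls, meta)
  expect_equal(tab$fraction[tab$class == "nitrergic"], 0.4)
  expect_equal(tab$fraction[tab$class == "cholinergic"], 0)
})

test_that("anchored archetypes are recovered as per-cluster dominant classes", {
  cfg <- sim_config(n_cells = 1000, n_genes = 1200, n_clusters = 6,
                    anchor_programs = TRUE, seed = 17L)
  sim <- simulate_dataset(cfg)
  ds <- impute_knn(normalize_counts(sim$dataset))
  calls <- classify_neurochem(ds, layer = "imputed", seed = 18)
  tab <- class_by_cluster(calls, ds$cell_meta)
  wide <- as_matrix(new_conc <- structure(
    dplyr::transmute(tab, row_id = cluster, col_id = class, value = fraction),
    class = c("ens_concordance", class(tab))))
  vocab <- sim$vocabulary
  anchors <- c(IMN = "nitrergic", EMN = "cholinergic", IPAN = "glutamatergic",
               IN = "catecholaminergic", PSN = "serotonergic",
               PSVN = "GABAergic")
  hit <- vapply(seq_len(nrow(vocab)), function(i) {
    colnames(wide)[which.max(wide[vocab$cluster[i], ])] ==
      unname(anchors[vocab$annotation[i]])
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})
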