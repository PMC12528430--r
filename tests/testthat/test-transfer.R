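test_that("training split caps per-cluster sampling and partitions cells", {
  meta <- tibble::tibble(barcode = sprintf("c%03d", 1:260),
                         cluster = c(rep("big", 250), rep("small", 10)))
  counts <- matrix(1L, 260, 5, dimnames = list(meta$barcode, paste0("g", 1:5)))
  ds <- ens_dataset(counts, cell_meta = meta)
  sp <- select_training(ds, n_per_cluster = 100, seed = 3)
  cl <- meta$cluster[sp$train]
  expect_equal(sum(cl == "big"), 100)
  expect_equal(sum(cl == "small"), 5)
  expect_length(intersect(sp$train, sp$heldout), 0)
  expect_equal(sort(c(sp$train, sp$heldout)), 1:260)
})

test_that("pair features binarize with ties counted as not-greater", {
  pairs <- tibble::tibble(g1 = c("a", "b"), g2 = c("b", "c"))
  mat <- matrix(c(2, 2, 1,
                  5, 1, 1), nrow = 2, byrow = TRUE,
                dimnames = list(NULL, c("a", "b", "c")))
  f <- ensid:::pair_matrix(mat, pairs)
  expect_equal(unname(f), matrix(c(0L, 1L, 1L, 0L), 2, 2),
               ignore_attr = TRUE)
  # monotone per-cell transform leaves features unchanged
  f10 <- ensid:::pair_matrix(mat * 10, pairs)
  expect_equal(f, f10, ignore_attr = TRUE)
})

test_that("discriminative pairs are found in a two-class toy", {
  mat <- matrix(0.1, 40, 4, dimnames = list(NULL, c("gA", "gB", "n1", "n2")))
  labels <- rep(c("X", "Y"), each = 20)
  mat[labels == "X", "gA"] <- 3
  mat[labels == "Y", "gB"] <- 3
  pairs <- top_pair_features(mat, labels, n_top_genes = 3, n_pairs = 2)
  key <- paste(pairs$g1, pairs$g2)
  expect_true(any(key %in% c("gA gB", "gB gA")))
  expect_true(all(pairs$gap <= 1))
})

test_that("transfer model is deterministic, rejects nulls and self-annotates", {
  pair <- small_pair()
  a <- pair$a$dataset
  m1 <- train_transfer(a, n_per_cluster = 60, n_trees = 200, seed = 5)
  m2 <- train_transfer(a, n_per_cluster = 60, n_trees = 200, seed = 5)
  expect_identical(m1$heldout_confusion, m2$heldout_confusion)
  expect_true("random" %in% m1$class_names)
  expect_gte(min(m1$heldout_report$accuracy), 0.9)

  ann <- annotate_transfer(m1, pair$b$dataset)
  probs <- as.matrix(ann[, grep("^prob_", names(ann))])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-9)

  cam <- cross_annotation_matrix(ann, pair$b$dataset$cell_meta)
  m <- as_matrix(cam)
  expect_equal(unname(rowSums(m)), rep(1, nrow(m)), tolerance = 1e-9)

  # broom-style accessors
  td <- tidy(m1)
  expect_setequal(names(td), c("truth", "n", "accuracy"))
  gl <- glance(m1)
  expect_equal(gl$n_classes, 5)
})

test_that("label transfer recovers the archetype correspondence", {
  pair <- small_pair()
  model <- train_transfer(pair$a$dataset, n_per_cluster = 60,
                          n_trees = 200, seed = 5)
  ann <- annotate_transfer(model, pair$b$dataset)
  cam <- as_matrix(cross_annotation_matrix(ann, pair$b$dataset$cell_meta))
  amap <- setNames(pair$archetype_map$cluster_a, pair$archetype_map$cluster_b)
  refs <- setdiff(colnames(cam), "random")
  hit <- vapply(rownames(cam), function(q)
    refs[which.max(cam[q, refs])] == amap[q], logical(1))
  expect_gte(mean(hit), 0.8)
})

test_that("self-transfer beats label-permuted transfer", {
  pair <- small_pair()
  a <- pair$a$dataset
  model <- train_transfer(a, n_per_cluster = 60, n_trees = 200, seed = 5)
  acc_self <- glance(model)$heldout_accuracy
  perm <- a
  perm$cell_meta$cluster <- withr::with_seed(9,
    sample(perm$cell_meta$cluster))
  ann <- annotate_transfer(model, perm)
  acc_perm <- mean(ann$label == perm$cell_meta$cluster)
  expect_gt(acc_self, acc_perm)
})

test_that("queries missing most pair genes are refused", {
  pair <- small_pair()
  model <- train_transfer(pair$a$dataset, n_per_cluster = 60,
                          n_trees = 100, seed = 5)
  b <- pair$b$dataset
  keep <- !(b$gene_ids %in% unique(c(model$pairs$g1, model$pairs$g2)))
  crippled <- ens_dataset(b$counts[, keep], cell_meta = b$cell_meta,
                          gene_ids = b$gene_ids[keep])
  crippled$layers$lognorm <- get_layer(b, "lognorm")[, keep]
  expect_error(annotate_transfer(model, crippled), "pair genes")
})
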