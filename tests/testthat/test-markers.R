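test_that("rank-sum p matches exact enumeration on the classic toy", {
  expect_equal(ensid:::ranksum_p(c(5, 6, 7), c(1, 2, 3)), 0.1)
  # identical distributions: p = 1
  expect_equal(ensid:::ranksum_p(c(2, 2, 2), c(2, 2, 2)), 1)
})

test_that("exact path equals the enumeration oracle for small groups", {
  set.seed(4)
  for (trial in 1:40) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
    # draw with ties to exercise mid-rank handling
    x <- sample(1:5, n1, replace = TRUE)
    y <- sample(1:5, n2, replace = TRUE)
    expect_equal(ensid:::ranksum_p(x, y), oracle_ranksum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("normal approximation is sane for larger groups", {
  set.seed(5)
  x <- rnorm(40, 1); y <- rnorm(60, 0)
  p_big <- ensid:::ranksum_p(x, y)
  expect_lt(p_big, 0.01)
  p_null <- ensid:::ranksum_p(rnorm(40), rnorm(60))
  expect_gt(p_null, 0.001)
  expect_lte(p_null, 1)
})

test_that("marker tables carry fold-changes, p and BH q per cluster", {
  ds <- normalize_counts(tiny_dataset())
  mk <- rank_markers(ds, "K1")
  expect_setequal(names(mk), c("cluster", "gene", "log2fc", "p", "q"))
  expect_true(all(mk$log2fc[match(c("NOS1", "NOS1AP", "ASL"), mk$gene)] > 0))
  expect_true(all(mk$log2fc[match(c("CHAT", "SLC5A7"), mk$gene)] < 0))
  # q-values: BH step-up on (.01,.02,.03,.04) gives all .04
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_true(all(diff(mk$log2fc) <= 1e-12))
  expect_error(rank_markers(ds, "missing"), "not found")
})

test_that("signature modules keep top-K positive significant genes", {
  set.seed(8)
  mk <- tibble::tibble(
    cluster = "K1",
    gene = sprintf("g%03d", 1:300),
    log2fc = c(seq(5, 0.1, length.out = 250), rep(-1, 50)),
    p = rep(1e-6, 300), q = rep(1e-5, 300))
  sig <- build_signatures(mk, "dsX", k_top = 100, q_max = 0.05)
  expect_equal(nrow(sig), 100)
  expect_true(all(sig$log2fc > 0))
  expect_equal(sig$gene[1], "g001")

  mk2 <- dplyr::mutate(mk, q = c(rep(1e-5, 2), rep(0.9, 298)))
  expect_warning(sig2 <- build_signatures(mk2, "dsX"), "fewer than 5")
  expect_equal(nrow(sig2), 2)
  expect_true(all(sig2$flagged))
})

test_that("marker overlap report reproduces set algebra", {
  r <- marker_overlap_report(list(A = c("x", "y"), B = c("y", "z")))
  expect_equal(r$shared_all, "y")
  m <- setNames(r$membership$genes, r$membership$subset)
  expect_equal(unname(m["A"]), "x")
  expect_equal(unname(m["A&B"]), "y")

  # three lists sharing exactly one gene
  r3 <- marker_overlap_report(list(
    UM = c("NOS1", "TAC1", "PENK", "CALCB"),
    AR = c("NOS1", "GAL", "TAC1", "PENK"),
    ST = c("NOS1", "TAC1", "PENK", "CHAT")))
  expect_setequal(r3$shared_all, c("NOS1", "TAC1", "PENK"))
  r1 <- marker_overlap_report(list(A = "u", B = "v"))
  expect_length(r1$shared_all, 0)
  expect_error(marker_overlap_report(list(c("a"))), "two named")
})

test_that("GMT files round-trip", {
  sets <- list(PATH_A = c("g1", "g2", "g3"), PATH_B = c("g9"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_equal(read_gmt(path), sets)
})

test_that("self cross-scoring puts each signature's source cluster on top", {
  pair <- small_pair()
  a <- pair$a$dataset
  sigs <- build_signatures(rank_all_markers(a), dataset_id = "dsA")
  cs <- cross_score(a, sigs, seed = 6)
  m <- as_matrix(cs)
  for (s in colnames(m)) {
    src <- sub("^dsA\\.", "", s)
    expect_equal(rownames(m)[which.max(m[, s])], src)
  }
})

test_that("random gene signatures score near zero everywhere", {
  pair <- small_pair()
  a <- pair$a$dataset
  set.seed(30)
  rand_sig <- tibble::tibble(
    source_dataset = "rnd", source_cluster = "R1",
    gene = sample(a$gene_ids, 60), log2fc = 1, p = 0.01, q = 0.01,
    rank = 1:60, flagged = FALSE)
  class(rand_sig) <- c("ens_signatures", class(rand_sig))
  cs <- cross_score(a, rand_sig, seed = 31)
  expect_true(all(abs(cs$value) < 0.2))
})
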