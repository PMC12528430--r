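#' Pipeline run configuration
#'
#' Bundles every stage's parameters for [run_pipeline()]. Either supply
#' `input_dirs` (two dataset directories readable by
#' [read_ens_dataset()]) or leave it `NULL` to simulate a dataset pair
#' from `sim`. A single global `seed` is fanned out to per-stage
#' substreams, so one integer reproduces the whole run.
#'
#' @param out_dir output directory for the report bundle
#' @param seed global integer seed
#' @param sim a [sim_config()] used when `input_dirs` is `NULL`
#' @param input_dirs optional character vector of two dataset directories
#' @param programs program catalog for classification
#' @param gmt optional path to a GMT pathway catalog; when `NULL` a
#'   synthetic catalog aligned to the programs is generated
#' @param impute_k,n_pcs imputation parameters ([impute_knn()])
#' @param score_threshold,n_bins,n_ctrl classifier parameters
#'   ([classify_neurochem()])
#' @param k_top,q_max signature parameters ([build_signatures()])
#' @param n_per_cluster,n_trees transfer parameters ([train_transfer()])
#' @param n_anchors anchor counts for the Spearman stage
#' @param gsea_k,gsea_n_perm,gsea_q_max GSEA stage parameters
#' @return a list of class `ens_run_config`
#' @export
run_config <- function(out_dir, seed = 1L, sim = sim_config(),
                       input_dirs = NULL, programs = default_program_catalog(),
                       gmt = NULL, impute_k = 15, n_pcs = 20,
                       score_threshold = NULL, n_bins = 25, n_ctrl = 50,
                       k_top = 100, q_max = 0.05, n_per_cluster = 100,
                       n_trees = 500, n_anchors = c(3000, 100),
                       gsea_k = 4, gsea_n_perm = 2000, gsea_q_max = 0.25) {
  if (!is.null(input_dirs)) {
    assert_that(length(input_dirs) == 2 && all(dir.exists(input_dirs)),
                "input_dirs must name two existing directories")
  }
  if (!is.null(gmt)) assert_that(file.exists(gmt), "gmt file does not exist")
  structure(as.list(environment()), class = "ens_run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full annotation-concordance pipeline
#'
#' Executes, in order: simulate (optional), preprocess (normalize +
#' impute), the two-step neurochemical classifier on both layers,
#' signature building and cross-scoring, label transfer with rejection,
#' anchored Spearman concordance, and GSEA-based NES clustering; then a
#' consolidated per-cluster method-agreement table. All tables are written
#' as TSV with `#`-prefixed provenance headers (tool version, config
#' hash, seed) and a `manifest.tsv` of MD5 checksums closes the bundle.
#' Rerunning with the same config and seed reproduces identical
#' checksums.
#'
#' @param config an [run_config()] object
#' @return (invisibly) a list of in-memory stage results
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  hdr <- c(paste0("config_hash=", config_hash(config)),
           paste0("seed=", seed))

  # --- inputs -------------------------------------------------------------
  if (is.null(config$input_dirs)) {
    sim <- config$sim
    sim$seed <- stage_seed(seed, "simulate")
    pair <- simulate_dataset_pair(sim,
                                  divergence_seed = stage_seed(seed, "divergence"))
    a <- pair$a$dataset; b <- pair$b$dataset
    true_map <- pair$archetype_map
    write_simulation(pair$a, file.path(out, "dsA"))
    write_simulation(pair$b, file.path(out, "dsB"))
  } else {
    a <- read_ens_dataset(config$input_dirs[1])
    b <- read_ens_dataset(config$input_dirs[2])
    true_map <- NULL
  }

  # --- preprocess ---------------------------------------------------------
  a <- impute_knn(normalize_counts(a), k = config$impute_k,
                  n_pcs = config$n_pcs)
  b <- impute_knn(normalize_counts(b), k = config$impute_k,
                  n_pcs = config$n_pcs)

  # --- classify -----------------------------------------------------------
  calls <- list()
  for (ds in c("a", "b")) {
    dataset <- if (ds == "a") a else b
    for (layer in c("lognorm", "imputed")) {
      cl <- classify_neurochem(dataset, config$programs, layer = layer,
                               score_threshold = config$score_threshold,
                               n_bins = config$n_bins, n_ctrl = config$n_ctrl,
                               seed = stage_seed(seed, paste0("classify_", ds)))
      calls[[paste(ds, layer, sep = "_")]] <- cl
    }
  }
  calls_tab <- bind_rows(lapply(names(calls), function(nm) {
    mutate(as_tibble(calls[[nm]]), dataset = sub("_.*", "", nm))
  }))
  write_tsv_header(calls_tab, file.path(out, "calls.tsv"),
                   c(hdr, paste0("score_threshold=",
                                 config$score_threshold %||% "layer-default")))
  mult <- bind_rows(lapply(names(calls), function(nm)
    mutate(multiplicity_profile(calls[[nm]]), run = nm)))
  write_tsv_header(mult, file.path(out, "multiplicity.tsv"), hdr)
  cbc <- class_by_cluster(calls[["b_imputed"]], b$cell_meta)
  write_tsv_header(cbc, file.path(out, "class_by_cluster.tsv"), hdr)

  # --- signatures ---------------------------------------------------------
  markers_a <- rank_all_markers(a)
  markers_b <- rank_all_markers(b)
  write_tsv_header(markers_a, file.path(out, "markers_dsA.tsv"), hdr)
  write_tsv_header(markers_b, file.path(out, "markers_dsB.tsv"), hdr)
  sigs <- build_signatures(markers_a, dataset_id = "dsA",
                           k_top = config$k_top, q_max = config$q_max)
  write_gmt(signature_sets(sigs), file.path(out, "signatures.gmt"))
  cs <- cross_score(b, sigs, seed = stage_seed(seed, "cross_score"))
  write_tsv_header(as_tibble(cs), file.path(out, "cross_score.tsv"), hdr)

  # --- label transfer -----------------------------------------------------
  model <- train_transfer(a, n_per_cluster = config$n_per_cluster,
                          n_trees = config$n_trees,
                          seed = stage_seed(seed, "transfer"))
  ann <- annotate_transfer(model, b)
  write_tsv_header(ann, file.path(out, "annotations.tsv"), hdr)
  cam <- cross_annotation_matrix(ann, b$cell_meta)
  write_tsv_header(as_tibble(cam), file.path(out, "cross_annotation.tsv"), hdr)
  write_tsv_header(tidy(model), file.path(out, "transfer_report.tsv"), hdr)

  # --- concordance --------------------------------------------------------
  spear <- concordance_spearman(a, b, n_anchors = config$n_anchors)
  for (nm in names(spear)) {
    write_tsv_header(as_tibble(spear[[nm]]),
                     file.path(out, paste0("spearman_", sub("anchors_", "", nm),
                                           ".tsv")), hdr)
  }
  anchors <- anchor_features(a, b, max(config$n_anchors))
  writeLines(anchors, file.path(out, "anchors.txt"))

  # --- GSEA clustering ----------------------------------------------------
  pathways <- if (!is.null(config$gmt)) read_gmt(config$gmt) else
    simulate_pathway_catalog(a$gene_ids, config$programs,
                             seed = stage_seed(seed, "pathways"))
  gsea_markers <- bind_rows(mutate(markers_a, cluster = paste0("dsA.", .data$cluster)),
                            mutate(markers_b, cluster = paste0("dsB.", .data$cluster)))
  nm_res <- nes_matrix(gsea_markers, pathways, q_max = config$gsea_q_max,
                       n_perm = config$gsea_n_perm,
                       seed = stage_seed(seed, "gsea"))
  write_tsv_header(nm_res$table, file.path(out, "gsea.tsv"), hdr)
  write_tsv_header(as_tibble(nm_res$matrix), file.path(out, "nes_matrix.tsv"), hdr)
  tree <- cluster_nes(nm_res$matrix, k = config$gsea_k)
  writeLines(tree$newick, file.path(out, "dendrogram.nwk"))
  write_tsv_header(tree$labels, file.path(out, "groups.tsv"), hdr)
  meta <- metacluster_pathways(nm_res$matrix, tree$labels)
  write_tsv_header(meta$means, file.path(out, "metacluster_nes.tsv"), hdr)

  # --- agreement ----------------------------------------------------------
  agree <- agreement_summary(cam, cs, spear[[1]], tree$labels,
                             nes = nm_res$matrix, ref_id = "dsA",
                             query_id = "dsB", true_map = true_map)
  write_tsv_header(agree, file.path(out, "agreement.tsv"), hdr)

  # --- manifest -----------------------------------------------------------
  files <- setdiff(list.files(out, recursive = TRUE), "manifest.tsv")
  sums <- tools::md5sum(file.path(out, files))
  manifest <- tibble(file = files, md5 = unname(sums))
  readr::write_tsv(manifest, file.path(out, "manifest.tsv"))

  invisible(list(datasets = list(a = a, b = b), calls = calls,
                 signatures = sigs, cross_score = cs, model = model,
                 cross_annotation = cam, spearman = spear,
                 nes = nm_res, tree = tree, agreement = agree,
                 manifest = manifest, true_map = true_map))
}

#' Per-cluster agreement of the four concordance methods
#'
#' For every query cluster, records the reference cluster picked by each
#' method — label transfer (modal non-random assignment), signature
#' module scoring (column-max signature), anchored Spearman correlation
#' (best-correlated reference cluster), and NES tree co-membership
#' (nearest reference NES profile within the same tree group) — with the
#' number of methods agreeing on the modal verdict and, when the true
#' archetype map is known, each method's correctness.
#'
#' @param cross_annotation `ens_concordance` from
#'   [cross_annotation_matrix()] (query clusters x reference classes)
#' @param cross_score_mat `ens_concordance` from [cross_score()]
#' @param spearman `ens_concordance` from [spearman_matrix()] (reference
#'   clusters x query clusters)
#' @param nes_labels tibble from [cluster_nes()] over rows named
#'   `<ref_id>.<cluster>` / `<query_id>.<cluster>`
#' @param nes optional `ens_concordance` NES matrix used to break ties
#'   among co-grouped reference clusters by profile distance
#' @param ref_id,query_id dataset id prefixes used in signature and NES
#'   row names
#' @param true_map optional tibble (`cluster_a`, `cluster_b`) of true
#'   correspondences (reference = a, query = b)
#' @return tibble, one row per query cluster
#' @export
agreement_summary <- function(cross_annotation, cross_score_mat, spearman,
                              nes_labels, nes = NULL, ref_id = "dsA",
                              query_id = "dsB", true_map = NULL) {
  cam <- as_matrix(cross_annotation)
  csm <- as_matrix(cross_score_mat)
  spm <- as_matrix(spearman)
  query_clusters <- sort(rownames(cam))

  strip <- function(x, id) sub(paste0("^", id, "\\."), "", x)

  pick_transfer <- function(q) {
    row <- cam[q, setdiff(colnames(cam), "random"), drop = TRUE]
    if (all(row == 0)) return(NA_character_)
    names(row)[which.max(row)]
  }
  pick_score <- function(q) {
    row <- csm[q, , drop = TRUE]
    if (all(is.na(row))) return(NA_character_)
    strip(names(row)[which.max(row)], ref_id)
  }
  pick_spearman <- function(q) {
    col <- spm[, q, drop = TRUE]
    rownames(spm)[which.max(col)]
  }
  nes_group <- setNames(nes_labels$group, nes_labels$row_id)
  nes_mat <- if (!is.null(nes)) as_matrix(nes) else NULL
  pick_nes <- function(q) {
    qkey <- paste0(query_id, ".", q)
    if (!qkey %in% names(nes_group)) return(NA_character_)
    mates <- names(nes_group)[nes_group == nes_group[qkey] &
                                startsWith(names(nes_group), paste0(ref_id, "."))]
    if (length(mates) == 0) return(NA_character_)
    if (!is.null(nes_mat) && qkey %in% rownames(nes_mat) &&
        all(mates %in% rownames(nes_mat)) && length(mates) > 1) {
      d <- apply(nes_mat[mates, , drop = FALSE], 1, function(r)
        sum((r - nes_mat[qkey, ])^2))
      mates <- names(sort(d))
    }
    strip(mates[1], ref_id)
  }

  out <- tibble(query_cluster = query_clusters) |>
    mutate(transfer = map_chr(.data$query_cluster, pick_transfer),
           module_score = map_chr(.data$query_cluster, pick_score),
           spearman = map_chr(.data$query_cluster, pick_spearman),
           nes_tree = map_chr(.data$query_cluster, pick_nes))
  out$n_agree <- apply(out[, c("transfer", "module_score", "spearman",
                               "nes_tree")], 1, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) 0L else max(table(v))
  })
  if (!is.null(true_map)) {
    truth <- setNames(true_map$cluster_a, true_map$cluster_b)
    for (m in c("transfer", "module_score", "spearman", "nes_tree")) {
      out[[paste0(m, "_correct")]] <-
        out[[m]] == unname(truth[out$query_cluster])
    }
  }
  out
}
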