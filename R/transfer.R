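#' Split a reference dataset into training and held-out cells
#'
#' Samples up to `n_per_cluster` cells per cluster for training (capped at
#' half the cluster so every cluster retains held-out cells), without
#' replacement; the remainder is held out for performance reporting.
#'
#' @param dataset an [ens_dataset()] with cluster labels
#' @param n_per_cluster training cells per cluster (default 100)
#' @param seed integer seed
#' @return list with integer cell indices `train` and `heldout`
#' @export
select_training <- function(dataset, n_per_cluster = 100, seed = 1L) {
  cl <- dataset$cell_meta$cluster
  assert_that(all(table(cl) >= 2), "every cluster needs at least 2 cells")
  with_seed(seed, {
    train <- unlist(lapply(split(seq_along(cl), cl), function(idx) {
      n_take <- min(n_per_cluster, floor(length(idx) / 2))
      sort(sample(idx, n_take))
    }), use.names = FALSE)
  })
  train <- sort(train)
  list(train = train, heldout = setdiff(seq_along(cl), train))
}

# Rank-based gene-pair features: feature (g1, g2) is 1 iff
# expr(g1) > expr(g2) within the cell (ties are "not greater"), so the
# representation is invariant to any monotone per-cell transform and
# needs no cross-dataset normalization.
pair_matrix <- function(mat, pairs) {
  n_missing <- sum(!c(pairs$g1, pairs$g2) %in% colnames(mat))
  get_col <- function(g) {
    if (g %in% colnames(mat)) mat[, g] else rep(0, nrow(mat))
  }
  out <- matrix(0L, nrow(mat), nrow(pairs))
  for (j in seq_len(nrow(pairs))) {
    out[, j] <- as.integer(get_col(pairs$g1[j]) > get_col(pairs$g2[j]))
  }
  colnames(out) <- paste(pairs$g1, pairs$g2, sep = ">")
  attr(out, "n_missing_genes") <- n_missing
  out
}

#' Select discriminative gene-pair features
#'
#' Per class: genes are ranked by the absolute class-vs-rest difference of
#' mean expression (the class template; up- and down-regulated genes are
#' both informative in a pair); all pairs among the top
#' `n_top_genes` candidates are scored by
#' `|P(g1 > g2 | class) - P(g1 > g2 | rest)|`, and the `n_pairs` best
#' pairs per class are kept (pooled and de-duplicated across classes).
#'
#' @param mat cells-by-genes training expression matrix
#' @param labels class label per training cell
#' @param n_top_genes template genes per class entering pairing
#'   (default 50)
#' @param n_pairs pairs kept per class (default 250)
#' @return tibble with columns `g1`, `g2`, `class`, `gap`
#' @export
top_pair_features <- function(mat, labels, n_top_genes = 50, n_pairs = 250) {
  classes <- sort(unique(labels))
  assert_that(length(classes) >= 2, "need at least 2 classes")
  out <- vector("list", length(classes))
  for (ci in seq_along(classes)) {
    cn <- classes[ci]
    in_cl <- labels == cn
    template <- colMeans(mat[in_cl, , drop = FALSE]) -
      colMeans(mat[!in_cl, , drop = FALSE])
    top <- colnames(mat)[order(-abs(template), colnames(mat))][
      seq_len(min(n_top_genes, ncol(mat)))]
    cmb <- combn(top, 2)
    sub_in <- mat[in_cl, top, drop = FALSE]
    sub_out <- mat[!in_cl, top, drop = FALSE]
    gap <- numeric(ncol(cmb))
    for (j in seq_len(ncol(cmb))) {
      g1 <- cmb[1, j]; g2 <- cmb[2, j]
      gap[j] <- abs(mean(sub_in[, g1] > sub_in[, g2]) -
                      mean(sub_out[, g1] > sub_out[, g2]))
    }
    keep <- order(-gap, cmb[1, ], cmb[2, ])[seq_len(min(n_pairs, length(gap)))]
    out[[ci]] <- tibble(g1 = cmb[1, keep], g2 = cmb[2, keep],
                        class = cn, gap = gap[keep])
  }
  bind_rows(out) |> distinct(.data$g1, .data$g2, .keep_all = TRUE)
}

#' Train a label-transfer model with a rejection class
#'
#' Supervised cross-dataset annotation in the top-scoring-pair style: the
#' reference is split into training and held-out cells, discriminative
#' rank-based gene-pair features are selected, and a probability random
#' forest is trained on the reference classes plus a synthetic `"random"`
#' class built by permuting each feature column independently (a null with
#' matched marginals). Query cells resembling no reference class are
#' absorbed by `"random"` rather than forced into a class.
#'
#' @param dataset reference [ens_dataset()] with cluster labels and the
#'   evaluated layer
#' @param layer expression layer used for features (default `"lognorm"`)
#' @param n_per_cluster training cells per cluster (default 100)
#' @param n_top_genes,n_pairs pair-selection parameters
#'   (see [top_pair_features()])
#' @param n_trees random-forest size (default 500)
#' @param seed integer seed governing the split, the null class and the
#'   forest
#' @return an object of class `ens_transfer`: forest, selected pairs,
#'   class names (including `"random"`), held-out report and parameters
#' @export
train_transfer <- function(dataset, layer = "lognorm", n_per_cluster = 100,
                           n_top_genes = 50, n_pairs = 250, n_trees = 500,
                           seed = 1L) {
  mat <- get_layer(dataset, layer)
  split_idx <- select_training(dataset, n_per_cluster,
                               seed = stage_seed(seed, "split"))
  labels <- dataset$cell_meta$cluster
  train_mat <- mat[split_idx$train, , drop = FALSE]
  train_lab <- labels[split_idx$train]

  pairs <- top_pair_features(train_mat, train_lab, n_top_genes, n_pairs)
  feat <- pair_matrix(train_mat, pairs)

  n_random <- round(mean(table(train_lab)))
  rand_feat <- with_seed(stage_seed(seed, "random_class"), {
    apply(feat, 2, function(col) col[sample.int(nrow(feat), n_random)])
  })
  x <- rbind(feat, rand_feat)
  y <- factor(c(train_lab, rep("random", n_random)),
              levels = c(sort(unique(train_lab)), "random"))
  df <- data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  df$.class <- y
  forest <- ranger::ranger(
    dependent.variable.name = ".class", data = df, num.trees = n_trees,
    probability = TRUE, seed = stage_seed(seed, "forest"),
    num.threads = 1, respect.unordered.factors = TRUE
  )
  model <- structure(list(
    forest = forest, pairs = pairs,
    class_names = levels(y), layer = layer,
    params = list(n_per_cluster = n_per_cluster, n_top_genes = n_top_genes,
                  n_pairs = n_pairs, n_trees = n_trees, seed = seed)
  ), class = "ens_transfer")

  heldout <- subset_cells(dataset, split_idx$heldout)
  ann <- annotate_transfer(model, heldout)
  truth <- labels[split_idx$heldout]
  model$heldout_report <- tibble(truth = truth, label = ann$label) |>
    group_by(.data$truth) |>
    summarise(n = n(), accuracy = mean(.data$label == .data$truth),
              .groups = "drop")
  model$heldout_confusion <- table(truth = truth, label = ann$label)
  model
}

#' Annotate a query dataset with a trained transfer model
#'
#' Computes the model's gene-pair features on the query (a missing pair
#' gene contributes expression 0, and the count of degraded features is
#' recorded), obtains per-class probabilities from the forest, and labels
#' each cell with the arg-max class; ties — including the all-flat case —
#' resolve to `"random"`.
#'
#' @param model an `ens_transfer` from [train_transfer()]
#' @param query an [ens_dataset()] with the model's layer present
#' @return tibble with `barcode`, `label`, and one probability column per
#'   class (`prob_*`); probability rows sum to 1
#' @export
annotate_transfer <- function(model, query) {
  mat <- get_layer(query, model$layer)
  pair_genes <- unique(c(model$pairs$g1, model$pairs$g2))
  missing <- setdiff(pair_genes, colnames(mat))
  if (length(missing) * 2 > length(pair_genes)) {
    abort(paste0("query lacks more than half of the model's pair genes: ",
                 paste(head(missing, 20), collapse = ", "),
                 if (length(missing) > 20) " ..."))
  }
  feat <- pair_matrix(mat, model$pairs)
  res <- predict_features(model, feat)
  out <- tibble(barcode = query$cell_meta$barcode, label = res$label)
  prob_df <- as_tibble(as.data.frame(res$probs))
  names(prob_df) <- paste0("prob_", model$class_names)
  dplyr::bind_cols(out, prob_df)
}

#' Pair-feature matrix of a dataset under a trained model
#'
#' @param model an `ens_transfer`
#' @param dataset an [ens_dataset()] with the model's layer
#' @return binary cells-by-features matrix (see [top_pair_features()])
#' @export
transfer_features <- function(model, dataset) {
  pair_matrix(get_layer(dataset, model$layer), model$pairs)
}

#' Predict classes from a precomputed pair-feature matrix
#'
#' Lower-level companion to [annotate_transfer()]: takes the binarized
#' gene-pair feature matrix directly (as built during training), useful
#' for null experiments such as feature-permuted queries.
#'
#' @param model an `ens_transfer`
#' @param feat binary matrix, cells by pair features, column order as
#'   `model$pairs`
#' @return list with `probs` (cells x classes, rows sum to 1) and `label`
#'   (arg-max class; ties resolve to `"random"`)
#' @export
predict_features <- function(model, feat) {
  df <- data.frame(feat)
  names(df) <- paste0("f", seq_len(ncol(feat)))
  probs <- stats::predict(model$forest, data = df,
                          num.threads = 1)$predictions
  probs <- probs[, model$class_names, drop = FALSE]
  label <- apply(probs, 1, function(p) {
    top <- which(p == max(p))
    if (length(top) > 1) "random" else model$class_names[top]
  })
  list(probs = probs, label = unname(label))
}

#' Cross-annotation matrix
#'
#' Fraction of each query cluster assigned to each reference class
#' (including `"random"`). Rows sum to 1.
#'
#' @param annotations tibble from [annotate_transfer()]
#' @param cell_meta query cell metadata with `barcode` and `cluster`
#' @return an `ens_concordance` with
#'   `statistic_name = "assignment_fraction"`
#' @export
cross_annotation_matrix <- function(annotations, cell_meta) {
  df <- left_join(annotations[, c("barcode", "label")],
                  cell_meta[, c("barcode", "cluster")], by = "barcode")
  df |>
    count(.data$cluster, .data$label) |>
    tidyr::complete(cluster = unique(df$cluster),
                    label = sort(unique(df$label)),
                    fill = list(n = 0L)) |>
    group_by(.data$cluster) |>
    mutate(value = .data$n / sum(.data$n)) |>
    ungroup() |>
    dplyr::transmute(row_id = .data$cluster, col_id = .data$label,
                     value = .data$value) |>
    new_concordance("assignment_fraction")
}

#' @export
print.ens_transfer <- function(x, ...) {
  cat(sprintf("<ens_transfer> %d classes (+'random'), %d pair features, %d trees\n",
              length(x$class_names) - 1L, nrow(x$pairs),
              x$params$n_trees))
  acc <- x$heldout_report
  cat(sprintf("  held-out accuracy: %.3f (min class %.3f)\n",
              sum(acc$accuracy * acc$n) / sum(acc$n), min(acc$accuracy)))
  invisible(x)
}

#' Tidy a label-transfer model
#'
#' `tidy()` returns one row per reference class with its held-out
#' accuracy; `glance()` returns a one-row model summary.
#'
#' @param x an `ens_transfer`
#' @param ... unused
#' @return a tibble
#' @export
tidy.ens_transfer <- function(x, ...) x$heldout_report

#' @rdname tidy.ens_transfer
#' @export
glance.ens_transfer <- function(x, ...) {
  acc <- x$heldout_report
  tibble(n_classes = length(x$class_names) - 1L,
         n_features = nrow(x$pairs),
         n_trees = x$params$n_trees,
         heldout_accuracy = sum(acc$accuracy * acc$n) / sum(acc$n),
         min_class_accuracy = min(acc$accuracy))
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
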