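#' Hallmark-enzyme gate (step 1 of the two-step classifier)
#'
#' A cell passes the gate for a neurochemical class when any hallmark
#' rate-limiting synthesis enzyme of that class exceeds `min_expr` on the
#' evaluated layer (e.g. NOS1 for nitrergic, GAD1 or GAD2 for GABAergic).
#'
#' @param mat dense cells-by-genes expression matrix (a layer)
#' @param hallmark_genes character vector of hallmark gene symbols
#' @param min_expr exclusive threshold; a cell passes iff
#'   `max(hallmark) > min_expr`
#' @return logical vector, one entry per cell
#' @export
hallmark_gate <- function(mat, hallmark_genes, min_expr = 0) {
  present <- intersect(hallmark_genes, colnames(mat))
  assert_that(length(present) >= 1, "no hallmark gene present in the dataset")
  sub <- mat[, present, drop = FALSE]
  mx <- do.call(pmax, c(as.data.frame(sub), list(na.rm = TRUE)))
  unname(mx > min_expr)
}

#' Two-step neurochemical classification
#'
#' For every program in the catalog and every cell: step 1 gates on
#' expression of the hallmark rate-limiting synthesis enzyme(s); step 2
#' module-scores the curated support set (metabolism enzymes and transport
#' proteins) against expression-matched controls. A class is called only
#' when both steps pass, so transcriptional evidence for both synthesis and
#' handling of the transmitter is required. Programs whose support set is
#' empty (or entirely absent from the data) fall back to the hallmark gate
#' alone, with a warning.
#'
#' On the `"imputed"` layer the gate threshold defaults to 0.1 rather than
#' 0 because neighbor averaging destroys exact zeros, and the score
#' threshold defaults to 0.2 rather than 0 because averaging over a
#' neighborhood leaks small amounts of the neighbors' programs into every
#' cell, shifting the null score distribution upward; a margin above the
#' matched-control background compensates. All thresholds are recorded in
#' the returned object.
#'
#' @param dataset an [ens_dataset()] with the evaluated layer present
#' @param programs an `ens_program_catalog`
#'   (default [default_program_catalog()])
#' @param layer layer name to classify on (`"lognorm"` or `"imputed"`)
#' @param score_threshold support module score must exceed this; default 0
#'   (above the matched-control background) on raw layers, 0.2 on
#'   `"imputed"` (see Details)
#' @param min_expr hallmark gate threshold; default 0 on raw layers, 0.1 on
#'   `"imputed"`
#' @param n_bins,n_ctrl,seed module-score parameters (see [score_genes()])
#' @return an object of class `ens_calls`: a tibble with one row per
#'   (barcode, class) holding `hallmark_pass`, `module_score`,
#'   `final_call`, plus attributes `layer`, `params` and `called`
#'   (per-cell called set summary)
#' @export
classify_neurochem <- function(dataset, programs = default_program_catalog(),
                               layer = "lognorm", score_threshold = NULL,
                               min_expr = NULL, n_bins = 25, n_ctrl = 50,
                               seed = 1L) {
  mat <- get_layer(dataset, layer)
  if (is.null(min_expr)) min_expr <- if (layer == "imputed") 0.1 else 0
  if (is.null(score_threshold)) {
    score_threshold <- if (layer == "imputed") 0.2 else 0
  }
  programs <- restrict_programs(programs, colnames(mat))
  sets <- program_sets(programs)
  classes <- names(sets)

  per_class <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    s <- sets[[classes[i]]]
    gate <- hallmark_gate(mat, s$hallmark, min_expr)
    if (length(s$support) == 0) {
      warn(paste0("class '", classes[i],
                  "': empty support set, using hallmark gate only"))
      score <- rep(NA_real_, nrow(mat))
      call <- gate
    } else {
      score <- score_genes(mat, s$support, n_bins = n_bins, n_ctrl = n_ctrl,
                           seed = stage_seed(seed, classes[i]))
      call <- gate & score > score_threshold
    }
    per_class[[i]] <- tibble(
      barcode = dataset$cell_meta$barcode, layer = layer,
      class = classes[i], hallmark_pass = gate, module_score = score,
      final_call = call
    )
  }
  calls <- bind_rows(per_class)
  called <- calls |>
    group_by(.data$barcode) |>
    summarise(called_set = paste(sort(.data$class[.data$final_call]),
                                 collapse = ";"),
              multiplicity = sum(.data$final_call), .groups = "drop")
  called <- called[match(dataset$cell_meta$barcode, called$barcode), ]
  structure(calls,
            class = c("ens_calls", class(calls)),
            layer = layer, called = called,
            params = list(layer = layer, score_threshold = score_threshold,
                          min_expr = min_expr, n_bins = n_bins,
                          n_ctrl = n_ctrl, seed = seed))
}

#' Per-cell called-set summary of a classification
#'
#' @param calls an `ens_calls` object from [classify_neurochem()]
#' @return tibble with `barcode`, `called_set` (semicolon-joined class
#'   names) and `multiplicity`
#' @export
called_sets <- function(calls) attr(calls, "called")

#' Mono- and multi-transmitter profile
#'
#' Counts cells predicted to synthesize 0, 1, 2, 3 or more
#' neurotransmitters. Fractions are reported both over all cells and over
#' assigned cells only (multiplicity >= 1), the denominator used when
#' profiling the co-transmission spectrum.
#'
#' @param calls an `ens_calls` object
#' @return tibble with `multiplicity_bin` (`0`,`1`,`2`,`3+`), `n_cells`,
#'   `frac_all`, `frac_assigned`
#' @export
multiplicity_profile <- function(calls) {
  cs <- called_sets(calls)
  bin <- cut(cs$multiplicity, breaks = c(-0.5, 0.5, 1.5, 2.5, Inf),
             labels = c("0", "1", "2", "3+"))
  n_all <- nrow(cs)
  n_assigned <- sum(cs$multiplicity >= 1)
  tibble(multiplicity_bin = levels(bin)) |>
    mutate(n_cells = as.integer(table(bin)[.data$multiplicity_bin]),
           frac_all = .data$n_cells / n_all,
           frac_assigned = ifelse(.data$multiplicity_bin == "0", NA_real_,
                                  .data$n_cells / n_assigned))
}

#' Neurochemical class abundance per cluster
#'
#' Fraction of each cluster's cells called for each class. Rows are
#' clusters, and because cells can carry several classes the fractions in
#' a row need not sum to 1.
#'
#' @param calls an `ens_calls` object
#' @param cell_meta cell metadata tibble with `barcode` and `cluster`
#' @return tibble with `cluster`, `class`, `n_cells`, `fraction`
#' @export
class_by_cluster <- function(calls, cell_meta) {
  assert_that(all(c("barcode", "cluster") %in% names(cell_meta)),
              "cell_meta needs barcode and cluster columns")
  df <- left_join(as_tibble(calls), cell_meta[, c("barcode", "cluster")],
                  by = "barcode")
  df |>
    group_by(.data$cluster, .data$class) |>
    summarise(n_cells = n(), fraction = mean(.data$final_call),
              .groups = "drop") |>
    arrange(.data$cluster, .data$class)
}
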