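#' Simulation configuration for synthetic enteric-neuron datasets
#'
#' Builds the parameter object consumed by [simulate_dataset()] and
#' [simulate_dataset_pair()]. Counts follow a gamma-Poisson (negative
#' binomial) model with a log-normal per-cell library size. Each cell sits
#' in one cluster archetype and carries 0-3 planted neurotransmitter
#' programs; planted program genes have their expected expression
#' multiplied by `program_effect`. Independent Bernoulli dropout is applied
#' on top of sampling zeros.
#'
#' Cluster archetypes are defined by (i) a sparse set of exclusive
#' archetype marker genes, and (ii) log-normal per-cluster expression
#' factors on a random subset of "identity" genes, so cluster identity and
#' neurochemical identity are separable axes. When `anchor_programs` is
#' `TRUE` each archetype has a preferred program that is always the first
#' member of a cell's planted set, linking clusters to neurochemical
#' classes the way discrete subtypes do in tissue.
#'
#' @param n_cells,n_genes,n_clusters positive integer dimensions
#' @param programs an `ens_program_catalog`; defaults to
#'   [default_program_catalog()]
#' @param multiplicity_probs probability vector over 0,1,2,3 planted
#'   programs per cell; must sum to 1
#' @param program_effect fold-change multiplier applied to hallmark and
#'   support genes of a cell's planted programs
#' @param batch_effect_sd log-scale SD of per-gene batch factors (used by
#'   [simulate_dataset_pair()])
#' @param dropout_rate probability that an observed count is zeroed
#' @param library_size_mean expected total counts per cell
#' @param library_size_sd log-scale SD of the per-cell library size
#' @param dispersion negative-binomial dispersion (var = mu + dispersion
#'   mu^2)
#' @param markers_per_cluster number of exclusive marker genes per
#'   archetype
#' @param marker_effect fold-change of a cluster's markers within it
#' @param program_baseline expected baseline count of program genes in
#'   cells not carrying the program (kept low: hallmark enzymes are near
#'   silent outside their class)
#' @param identity_frac fraction of filler genes given per-cluster
#'   expression factors
#' @param identity_sd log-scale SD of those per-cluster factors
#' @param aux_per_program auxiliary co-expressed genes per program
#'   (default 10). A transmitter phenotype entails more than its curated
#'   synthesis/transport list — receptors, vesicle and release machinery
#'   are co-regulated with it — so each planted program also boosts a
#'   module of auxiliary genes that the classifier never sees
#' @param anchor_programs logical; tie each archetype to a preferred
#'   program (see Details)
#' @param seed integer seed; the same config yields bit-identical data
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_cells = 2000, n_genes = 2000, n_clusters = 8,
                       programs = default_program_catalog(),
                       multiplicity_probs = c(0.1, 0.5, 0.3, 0.1),
                       program_effect = 8, batch_effect_sd = 0,
                       dropout_rate = 0.1, library_size_mean = 5000,
                       library_size_sd = 0.3, dispersion = 0.1,
                       markers_per_cluster = 10, marker_effect = 6,
                       program_baseline = 1, identity_frac = 0.4,
                       identity_sd = 1.25, aux_per_program = 10,
                       anchor_programs = FALSE, seed = 1L) {
  assert_that(is_count_scalar(n_cells), "n_cells must be a positive integer")
  assert_that(is_count_scalar(n_genes), "n_genes must be a positive integer")
  assert_that(is_count_scalar(n_clusters), "n_clusters must be a positive integer")
  assert_that(length(multiplicity_probs) == 4 && all(multiplicity_probs >= 0),
              "multiplicity_probs must be 4 non-negative probabilities")
  assert_that(abs(sum(multiplicity_probs) - 1) < 1e-9,
              "multiplicity_probs must sum to 1")
  assert_that(dropout_rate >= 0 && dropout_rate <= 1,
              "dropout_rate must be in [0,1]")
  assert_that(program_effect > 0, "program_effect must be positive")
  assert_that(batch_effect_sd >= 0, "batch_effect_sd must be non-negative")
  assert_that(library_size_mean > 0, "library_size_mean must be positive")
  assert_that(dispersion > 0, "dispersion must be positive")
  n_classes <- length(unique(programs$class_name))
  n_prog_genes <- length(program_genes(programs)) +
    n_classes * aux_per_program
  if (n_genes < n_prog_genes + n_clusters * markers_per_cluster + 10) {
    abort("n_genes too small for the program and marker gene namespace")
  }
  structure(list(
    n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
    n_clusters = as.integer(n_clusters), programs = programs,
    multiplicity_probs = multiplicity_probs,
    program_effect = program_effect, batch_effect_sd = batch_effect_sd,
    dropout_rate = dropout_rate, library_size_mean = library_size_mean,
    library_size_sd = library_size_sd, dispersion = dispersion,
    markers_per_cluster = as.integer(markers_per_cluster),
    marker_effect = marker_effect, program_baseline = program_baseline,
    identity_frac = identity_frac, identity_sd = identity_sd,
    aux_per_program = as.integer(aux_per_program),
    anchor_programs = isTRUE(anchor_programs), seed = as.integer(seed)
  ), class = "sim_config")
}

# Archetype definitions shared by both members of a dataset pair:
# gene namespace, baseline means, per-cluster factors, anchor programs.
build_archetypes <- function(config) {
  with_seed(stage_seed(config$seed, "archetypes"), {
    prog_genes <- program_genes(config$programs)
    classes <- unique(config$programs$class_name)
    aux_genes <- if (config$aux_per_program > 0) {
      sprintf("AUX_%s_%02d",
              rep(toupper(substr(classes, 1, 4)),
                  each = config$aux_per_program),
              rep(seq_len(config$aux_per_program), length(classes)))
    } else character()
    aux_by_class <- split(aux_genes,
                          rep(classes, each = config$aux_per_program))
    n_mark <- config$n_clusters * config$markers_per_cluster
    marker_genes <- sprintf("MK%02d_%02d",
                            rep(seq_len(config$n_clusters),
                                each = config$markers_per_cluster),
                            rep(seq_len(config$markers_per_cluster),
                                config$n_clusters))
    n_fill <- config$n_genes - length(prog_genes) - length(aux_genes) -
      n_mark
    filler <- sprintf("G%06d", seq_len(n_fill))
    genes <- c(prog_genes, aux_genes, marker_genes, filler)

    # baseline expected counts per gene for a cell at nominal library size
    w <- rlnorm(config$n_genes, meanlog = 0, sdlog = 1.2)
    mu0 <- config$library_size_mean * w / sum(w)
    names(mu0) <- genes
    mu0[prog_genes] <- config$program_baseline
    mu0[aux_genes] <- config$program_baseline
    mu0[marker_genes] <- config$program_baseline

    # per-cluster expression factors: marker boost + identity-gene wobble
    fac <- matrix(1, config$n_clusters, config$n_genes,
                  dimnames = list(NULL, genes))
    for (k in seq_len(config$n_clusters)) {
      mk <- marker_genes[(k - 1) * config$markers_per_cluster +
                           seq_len(config$markers_per_cluster)]
      fac[k, mk] <- config$marker_effect
    }
    identity_idx <- sort(sample(which(genes %in% filler),
                                round(config$identity_frac * n_fill)))
    fac[, identity_idx] <- exp(matrix(
      rnorm(config$n_clusters * length(identity_idx), 0, config$identity_sd),
      config$n_clusters, length(identity_idx)))

    classes <- unique(config$programs$class_name)
    anchor <- if (config$anchor_programs) {
      classes[((seq_len(config$n_clusters) - 1) %% length(classes)) + 1]
    } else rep(NA_character_, config$n_clusters)

    list(genes = genes, mu0 = mu0, cluster_factor = fac, anchor = anchor,
         prog_genes = prog_genes, marker_genes = marker_genes,
         aux = aux_by_class, sets = program_sets(config$programs))
  })
}

# Two annotation vocabularies for the same functional archetypes, in the
# style of independently annotated atlases (e.g. "IMN1" vs "PIMN3").
archetype_vocabulary <- function(arch, style = c("plain", "putative")) {
  style <- match.arg(style)
  base <- c(nitrergic = "IMN", cholinergic = "EMN", glutamatergic = "IPAN",
            catecholaminergic = "IN", serotonergic = "PSN",
            GABAergic = "PSVN")
  fun <- ifelse(is.na(arch$anchor), "NEUR", unname(base[arch$anchor]))
  fun[is.na(fun)] <- "NEUR"
  prefix <- if (style == "putative") paste0("P", fun) else fun
  idx <- stats::ave(seq_along(prefix), prefix, FUN = seq_along)
  offset <- if (style == "putative") 0L else 0L
  tibble(archetype = seq_along(prefix),
         cluster = paste0(prefix, idx + offset),
         annotation = fun)
}

simulate_cells <- function(config, arch, cell_seed, batch = NULL,
                           vocab = NULL, dataset_id = "sim") {
  n <- config$n_cells
  g <- config$n_genes
  classes <- names(arch$sets)
  if (is.null(batch)) batch <- rep(1, g)
  if (is.null(vocab)) vocab <- archetype_vocabulary(arch, "plain")
  with_seed(cell_seed, {
    cluster <- sample(config$n_clusters, n, replace = TRUE)
    mult <- sample(0:3, n, replace = TRUE, prob = config$multiplicity_probs)
    planted <- vector("list", n)
    for (i in seq_len(n)) {
      m <- mult[i]
      if (m == 0L) { planted[[i]] <- character(); next }
      a <- arch$anchor[cluster[i]]
      if (config$anchor_programs && !is.na(a)) {
        extra <- if (m > 1L) sample(setdiff(classes, a), m - 1L) else character()
        planted[[i]] <- c(a, extra)
      } else {
        planted[[i]] <- sample(classes, m)
      }
    }
    lib <- rlnorm(n, meanlog = log(config$library_size_mean) -
                    config$library_size_sd^2 / 2,
                  sdlog = config$library_size_sd)
    libfac <- lib / config$library_size_mean

    mu <- arch$cluster_factor[cluster, , drop = FALSE]
    mu <- sweep(mu, 2, arch$mu0 * batch, `*`)
    mu <- mu * libfac
    if (config$program_effect != 1) {
      for (cn in classes) {
        cells_p <- which(vapply(planted, function(s) cn %in% s, logical(1)))
        if (!length(cells_p)) next
        gidx <- which(arch$genes %in% c(unlist(arch$sets[[cn]]),
                                        arch$aux[[cn]]))
        mu[cells_p, gidx] <- mu[cells_p, gidx] * config$program_effect
      }
    }
    lambda <- matrix(rgamma(n * g, shape = 1 / config$dispersion,
                            scale = config$dispersion * mu), n, g)
    counts <- matrix(rpois(n * g, lambda), n, g)
    if (config$dropout_rate > 0) {
      keep <- matrix(rbinom(n * g, 1L, 1 - config$dropout_rate), n, g)
      counts <- counts * keep
    }
    dimnames(counts) <- list(sprintf("%s_c%05d", dataset_id, seq_len(n)),
                             arch$genes)

    cluster_label <- vocab$cluster[cluster]
    meta <- tibble(barcode = rownames(counts), dataset_id = dataset_id,
                   cluster = cluster_label,
                   annotation = vocab$annotation[cluster])
    ds <- ens_dataset(Matrix::Matrix(counts, sparse = TRUE),
                      cell_meta = meta, gene_ids = arch$genes)
    truth <- tibble(
      barcode = meta$barcode, archetype = cluster,
      cluster = cluster_label,
      multiplicity = lengths(planted),
      planted = vapply(planted, function(s)
        paste(sort(s), collapse = ";"), character(1))
    )
    list(dataset = ds, truth = truth, vocabulary = vocab)
  })
}

#' Simulate one synthetic single-cell dataset with planted ground truth
#'
#' @param config a [sim_config()]
#' @param dataset_id identifier stored in the cell metadata
#' @return a list with elements `dataset` (an [ens_dataset()]), `truth`
#'   (tibble: barcode, archetype, cluster, planted classes
#'   semicolon-joined, multiplicity) and `vocabulary` (tibble mapping
#'   archetype id to cluster label and functional annotation)
#' @export
simulate_dataset <- function(config, dataset_id = "sim") {
  arch <- build_archetypes(config)
  simulate_cells(config, arch, stage_seed(config$seed, "cells"),
                 vocab = archetype_vocabulary(arch, "plain"),
                 dataset_id = dataset_id)
}

#' Simulate a pair of datasets sharing archetypes but not batch or
#' vocabulary
#'
#' Both datasets draw cells from the same cluster archetypes (same marker
#' genes, identity factors and anchor programs) but receive independent
#' per-gene batch factors (`exp(N(0, batch_effect_sd))`) and use divergent
#' annotation vocabularies, emulating two independently produced and
#' annotated atlases of the same tissue.
#'
#' @param config a [sim_config()]
#' @param divergence_seed seed controlling batch factors and the second
#'   dataset's cell draw
#' @return list with elements `a`, `b` (each as [simulate_dataset()]) and
#'   `archetype_map`, a tibble (`archetype`, `cluster_a`, `cluster_b`)
#'   giving the true correspondence between the two cluster vocabularies
#' @export
simulate_dataset_pair <- function(config, divergence_seed = 99L) {
  arch <- build_archetypes(config)
  vocab_a <- archetype_vocabulary(arch, "plain")
  vocab_b <- archetype_vocabulary(arch, "putative")
  batches <- with_seed(stage_seed(divergence_seed, "batch"), {
    list(a = exp(rnorm(config$n_genes, 0, config$batch_effect_sd)),
         b = exp(rnorm(config$n_genes, 0, config$batch_effect_sd)))
  })
  a <- simulate_cells(config, arch, stage_seed(config$seed, "cells_a"),
                      batch = batches$a, vocab = vocab_a, dataset_id = "dsA")
  b <- simulate_cells(config, arch,
                      stage_seed(divergence_seed, "cells_b"),
                      batch = batches$b, vocab = vocab_b, dataset_id = "dsB")
  map <- tibble(archetype = vocab_a$archetype,
                cluster_a = vocab_a$cluster, cluster_b = vocab_b$cluster)
  list(a = a, b = b, archetype_map = map)
}

#' Synthetic pathway catalog aligned to planted programs
#'
#' Builds a GMT-style named list of gene sets: one pathway per
#' neurotransmitter program (its hallmark plus support genes) and
#' `n_decoy` random gene sets drawn from the dataset's gene namespace, so
#' enrichment analyses have a recoverable signal amid a null background.
#'
#' @param genes character vector of available gene symbols
#' @param programs an `ens_program_catalog`
#' @param n_decoy number of random decoy pathways
#' @param decoy_size genes per decoy pathway
#' @param seed integer seed
#' @return named list of character vectors
#' @export
simulate_pathway_catalog <- function(genes, programs = default_program_catalog(),
                                     n_decoy = 50, decoy_size = 15,
                                     seed = 1L) {
  sets <- program_sets(programs)
  catalog <- lapply(sets, function(s)
    intersect(c(s$hallmark, s$support), genes))
  names(catalog) <- paste0("PROGRAM_", toupper(names(sets)))
  with_seed(stage_seed(seed, "pathways"), {
    for (i in seq_len(n_decoy)) {
      catalog[[sprintf("DECOY_%03d", i)]] <- sample(genes, decoy_size)
    }
  })
  catalog
}

#' Write a simulated dataset bundle to disk
#'
#' Writes the expression files via [write_ens_dataset()] plus
#' `truth.tsv` (barcode, planted classes semicolon-joined, archetype id).
#'
#' @param sim result of [simulate_dataset()]
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_simulation <- function(sim, dir) {
  write_ens_dataset(sim$dataset, dir)
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
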