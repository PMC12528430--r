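#' Define a neurotransmitter program
#'
#' A neurotransmitter program couples the hallmark rate-limiting synthesis
#' enzyme(s) of one neurochemical class with a curated support set of
#' metabolism enzymes and transport proteins. The two-step classifier gates
#' on the hallmark genes and module-scores the support set.
#'
#' @param class_name class label, e.g. `"nitrergic"`
#' @param hallmark_genes non-empty character vector of hallmark gene symbols
#' @param support_genes character vector of support gene symbols; may be
#'   empty (with a warning), in which case classification falls back to the
#'   hallmark gate alone
#' @return a tibble row-set of class `ens_program_catalog` with one row per
#'   (class, role, gene)
#' @export
ens_program <- function(class_name, hallmark_genes, support_genes = character()) {
  assert_that(length(class_name) == 1L && nzchar(class_name),
              "class_name must be a single non-empty string")
  assert_that(length(hallmark_genes) >= 1L, "hallmark_genes must be non-empty")
  hallmark_genes <- unique(as.character(hallmark_genes))
  support_genes <- unique(as.character(support_genes))
  assert_that(!any(hallmark_genes %in% support_genes),
              paste0(class_name, ": hallmark and support sets must be disjoint"))
  if (length(support_genes) == 0L) {
    warn(paste0("program '", class_name, "' has an empty support set; ",
                "classification will use the hallmark gate only"))
  }
  out <- bind_rows(
    tibble(class_name = class_name, role = "hallmark", gene = hallmark_genes),
    if (length(support_genes))
      tibble(class_name = class_name, role = "support", gene = support_genes)
  )
  class(out) <- c("ens_program_catalog", class(out))
  out
}

#' Default six-class neurotransmitter program catalog
#'
#' The six neurochemical classes routinely ascribed to enteric neurons:
#' nitrergic, cholinergic, glutamatergic, catecholaminergic, GABAergic and
#' serotonergic. Each class is keyed by its rate-limiting synthesis
#' enzyme(s) (e.g. NOS1 for nitric oxide, CHAT for acetylcholine, GAD1/GAD2
#' for GABA) and a support set of metabolism and transport genes. The
#' nitrergic support set is the curated NO metabolism/transport list
#' (NOS1AP, ARG1, ARG2, ASL, ASS1); the other support sets are standard
#' pathway members that users working with real data should review and can
#' replace via [read_programs()].
#'
#' @return an `ens_program_catalog` tibble (class_name, role, gene)
#' @export
default_program_catalog <- function() {
  catalog <- bind_rows(
    ens_program("nitrergic", "NOS1",
                c("NOS1AP", "ARG1", "ARG2", "ASL", "ASS1")),
    ens_program("cholinergic", "CHAT",
                c("SLC5A7", "SLC18A3", "ACHE")),
    ens_program("glutamatergic", "GLS",
                c("SLC17A6", "SLC17A7", "GLUL")),
    ens_program("catecholaminergic", "TH",
                c("DDC", "DBH", "SLC18A2")),
    ens_program("GABAergic", c("GAD1", "GAD2"),
                c("SLC32A1", "ABAT", "SLC6A1")),
    ens_program("serotonergic", "TPH2",
                c("SLC6A4", "SLC18A1", "MAOA"))
  )
  class(catalog) <- c("ens_program_catalog", setdiff(class(catalog),
                                                     "ens_program_catalog"))
  catalog
}

#' Split a program catalog into per-class gene sets
#'
#' @param catalog an `ens_program_catalog`
#' @return named list with one element per class:
#'   `list(hallmark = chr, support = chr)`
#' @export
program_sets <- function(catalog) {
  cls <- unique(catalog$class_name)
  setNames(lapply(cls, function(cn) {
    sub <- catalog[catalog$class_name == cn, ]
    list(hallmark = sub$gene[sub$role == "hallmark"],
         support = sub$gene[sub$role == "support"])
  }), cls)
}

#' All gene symbols referenced by a program catalog
#' @param catalog an `ens_program_catalog`
#' @return character vector of unique gene symbols
#' @export
program_genes <- function(catalog) unique(catalog$gene)

#' Read / write a program catalog as TSV
#'
#' The on-disk format is three tab-separated columns:
#' `class_name`, `role` (`hallmark` or `support`), `gene_symbol` — an
#' editable mirror of a curated marker table.
#'
#' @param path TSV file path
#' @return for `read_programs`, an `ens_program_catalog`
#' @export
read_programs <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  nm <- names(df)
  if ("gene_symbol" %in% nm) df <- rename(df, gene = "gene_symbol")
  assert_that(all(c("class_name", "role", "gene") %in% names(df)),
              "programs file needs columns class_name, role, gene_symbol")
  assert_that(all(df$role %in% c("hallmark", "support")),
              "role must be 'hallmark' or 'support'")
  cls <- unique(df$class_name)
  out <- bind_rows(lapply(cls, function(cn) {
    sub <- df[df$class_name == cn, ]
    ens_program(cn, sub$gene[sub$role == "hallmark"],
                sub$gene[sub$role == "support"])
  }))
  class(out) <- c("ens_program_catalog", setdiff(class(out),
                                                 "ens_program_catalog"))
  out
}

#' @rdname read_programs
#' @param catalog an `ens_program_catalog`
#' @export
write_programs <- function(catalog, path) {
  out <- tibble(class_name = catalog$class_name, role = catalog$role,
                gene_symbol = catalog$gene)
  readr::write_tsv(out, path)
  invisible(path)
}

# Restrict a catalog to genes present in `gene_ids`. Per class/role set:
# drop missing genes with a warning if at least half the set survives,
# otherwise error — keeps runs robust to annotation-version drift without
# silently gutting a program.
restrict_programs <- function(catalog, gene_ids) {
  keyed <- split(catalog, paste(catalog$class_name, catalog$role))
  kept <- lapply(keyed, function(sub) {
    present <- sub$gene %in% gene_ids
    if (all(present)) return(sub)
    missing <- sub$gene[!present]
    if (sum(present) * 2 < length(present) ||
        (sub$role[1] == "hallmark" && sum(present) == 0)) {
      abort(paste0("program '", sub$class_name[1], "' ", sub$role[1],
                   " set loses too many genes: missing ",
                   paste(missing, collapse = ", ")))
    }
    warn(paste0("program '", sub$class_name[1], "' ", sub$role[1],
                ": dropping absent gene(s) ", paste(missing, collapse = ", ")))
    sub[present, , drop = FALSE]
  })
  out <- bind_rows(kept)
  out <- out[order(match(out$class_name, unique(catalog$class_name)),
                   out$role, out$gene), ]
  class(out) <- c("ens_program_catalog", setdiff(class(out),
                                                 "ens_program_catalog"))
  out
}
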