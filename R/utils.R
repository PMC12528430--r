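#' @importFrom rlang %||% abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows across n rename count pull desc distinct
#' @importFrom purrr map map_dbl map_chr map_lgl imap pmap
#' @importFrom stats prcomp rnorm rpois rgamma rbinom runif p.adjust cor
#'   hclust cutree dist as.dendrogram setNames quantile var sd median
#'   pnorm ks.test rlnorm
#' @importFrom utils head combn packageVersion
#' @importFrom methods as
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All stochastic operations in the package go
# through this so a single integer fully determines their output.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a per-stage seed from a global seed and a stage name, so stages
# consume independent substreams without coupling. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# Dense numeric matrix view of a layer (rows = cells, cols = genes).
as_dense <- function(m) {
  if (inherits(m, "Matrix")) as.matrix(m) else m
}

is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

# Write a tibble as TSV with '#'-prefixed provenance header lines.
write_tsv_header <- function(df, path, header = character()) {
  lines <- c(
    paste0("# ensid ", as.character(packageVersion("ensid"))),
    paste0("# ", header)
  )
  writeLines(lines, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_tsv_header <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
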