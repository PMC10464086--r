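#' Read a taxon count table
#'
#' Reads a taxa-by-samples count table from TSV (first column = taxon ID,
#' remaining columns = samples) or from a BIOM file (extension `.biom`;
#' requires the `biomformat` package).
#'
#' @param path file path.
#' @return numeric matrix, taxa in rows.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stopf("reading BIOM requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    return(as(biomformat::biom_data(b), "matrix"))
  }
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   row.names = 1, comment.char = "")
  as.matrix(df)
}

#' Write a taxon count table
#'
#' Writes a taxa-by-samples count matrix as TSV (taxon IDs in the first
#' column, header `taxon_id`) or BIOM when `path` ends in `.biom`.
#'
#' @param counts matrix or [community_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  x <- if (inherits(counts, "community_matrix")) counts$counts else counts
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stopf("writing BIOM requires the 'biomformat' package")
    }
    biomformat::write_biom(biomformat::make_biom(x), path)
    return(invisible(path))
  }
  df <- data.frame(taxon_id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Read a community matrix from counts and metadata files
#'
#' @param counts_path TSV or BIOM count table (see [read_counts()]).
#' @param metadata_path TSV with columns `sample`, `layer`, `season`.
#' @return a [community_matrix()].
#' @export
read_community <- function(counts_path, metadata_path) {
  counts <- read_counts(counts_path)
  meta <- read_tsv(metadata_path)
  need <- c("sample", "layer", "season")
  if (!all(need %in% names(meta))) {
    stopf("metadata must have columns: %s", paste(need, collapse = ", "))
  }
  missing <- setdiff(colnames(counts), meta$sample)
  if (length(missing)) {
    stopf("samples missing from metadata: %s", paste(head(missing, 5), collapse = ", "))
  }
  meta <- meta[match(colnames(counts), meta$sample), ]
  community_matrix(counts, meta$layer, meta$season)
}

#' Write a synthetic dataset to a directory
#'
#' Emits the generator outputs in their interchange formats: counts as TSV
#' (and BIOM when `biom = TRUE`), tree as Newick, metadata, physics and age
#' anchors as TSV, truth table as TSV, and the configuration as YAML.
#'
#' @param ds a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @param biom also write a BIOM copy of the counts (default `FALSE`).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, biom = FALSE) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(ds$counts, file.path(dir, "counts.tsv"))
  if (biom) write_counts(ds$counts, file.path(dir, "counts.biom"))
  ape::write.tree(ds$tree, file.path(dir, "tree.nwk"))
  write_tsv(ds$counts$sample_meta, file.path(dir, "metadata.tsv"))
  write_tsv(ds$physics, file.path(dir, "physics.tsv"))
  write_tsv(ds$age_anchors, file.path(dir, "age_anchors.tsv"))
  write_tsv(ds$truth, file.path(dir, "truth.tsv"))
  cfg <- ds$config
  class(cfg) <- NULL
  cfg$dropout <- cfg$dropout %||% character(0)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
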