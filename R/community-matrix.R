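#' Construct a community matrix with depth-layer and season labels
#'
#' The central container of the package: a taxon-by-sample matrix of
#' non-negative integer counts together with per-sample metadata giving the
#' sediment depth layer (1 = surface) and the season (sampling campaign) of
#' each core subsample.
#'
#' @param counts numeric matrix, taxa in rows, samples in columns, with
#'   unique row and column names.  Values must be non-negative; counts are
#'   expected to be integers (rarefaction and Chao1 require them).
#' @param layer integer vector, one depth-layer index per sample (column).
#' @param season character vector, one season label per sample.
#' @return An object of class `community_matrix`: a list with elements
#'   `counts` and `sample_meta` (data frame with columns `sample`, `layer`,
#'   `season`).
#' @examples
#' x <- matrix(c(5L, 0L, 3L, 2L), 2, 2,
#'             dimnames = list(c("OTU_1", "OTU_2"), c("s1", "s2")))
#' community_matrix(x, layer = c(1, 2), season = c("aug", "aug"))
#' @export
community_matrix <- function(counts, layer, season) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stopf("'counts' must be a numeric matrix (taxa x samples)")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stopf("'counts' needs taxon row names and sample column names")
  }
  if (anyDuplicated(rownames(counts))) stopf("duplicated taxon IDs")
  if (anyDuplicated(colnames(counts))) stopf("duplicated sample IDs")
  if (any(counts < 0) || anyNA(counts)) stopf("counts must be non-negative and complete")
  if (length(layer) != ncol(counts) || length(season) != ncol(counts)) {
    stopf("'layer' and 'season' must have one entry per sample")
  }
  layer <- as.integer(layer)
  if (anyNA(layer) || any(layer < 1L)) stopf("layers must be positive integers")
  m <- structure(
    list(
      counts = counts,
      sample_meta = data.frame(
        sample = colnames(counts),
        layer = layer,
        season = as.character(season),
        stringsAsFactors = FALSE
      )
    ),
    class = "community_matrix"
  )
  m
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf(
    "community_matrix: %d taxa x %d samples (%d layers, %d seasons)\n",
    nrow(x$counts), ncol(x$counts),
    length(unique(x$sample_meta$layer)),
    length(unique(x$sample_meta$season))
  ))
  invisible(x)
}

n_taxa <- function(m) nrow(m$counts)
n_samples <- function(m) ncol(m$counts)

assert_community_matrix <- function(m) {
  if (!inherits(m, "community_matrix")) stopf("expected a 'community_matrix'")
  invisible(m)
}

#' Subset a community matrix by samples
#'
#' @param m a [community_matrix()].
#' @param idx logical, integer or character index over samples.
#' @return a `community_matrix` restricted to the selected samples.
#' @export
subset_samples <- function(m, idx) {
  assert_community_matrix(m)
  counts <- m$counts[, idx, drop = FALSE]
  meta <- m$sample_meta[match(colnames(counts), m$sample_meta$sample), ]
  community_matrix(counts, meta$layer, meta$season)
}

#' Pool seasonal samples of the same depth layer
#'
#' Sums the counts of all samples that share a depth layer, mirroring the
#' "seasonally merged" sample treatment in which raw reads of temporal
#' samples from the same depth are pooled before downstream analysis.
#'
#' @param m a [community_matrix()].
#' @return a `community_matrix` with one sample per layer (named `L<layer>`,
#'   season label `"merged"`), ordered by increasing layer.
#' @examples
#' x <- matrix(1:8, 2, 4, dimnames = list(c("a", "b"), paste0("s", 1:4)))
#' m <- community_matrix(x, layer = c(1, 1, 2, 2), season = c("w", "s", "w", "s"))
#' merge_seasons(m)$counts
#' @export
merge_seasons <- function(m) {
  assert_community_matrix(m)
  layers <- sort(unique(m$sample_meta$layer))
  merged <- vapply(layers, function(l) {
    rowSums(m$counts[, m$sample_meta$layer == l, drop = FALSE])
  }, numeric(n_taxa(m)))
  colnames(merged) <- sprintf("L%02d", layers)
  rownames(merged) <- rownames(m$counts)
  community_matrix(merged, layer = layers, season = rep("merged", length(layers)))
}
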