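#' Rarefy a community matrix to even depth
#'
#' Subsamples every sample without replacement to exactly `depth` reads,
#' the standard correction for uneven sequencing effort applied before all
#' community statistics.
#'
#' @param m a [community_matrix()] of integer counts.
#' @param depth target reads per sample, or `"min"` (default) for the
#'   smallest sample sum.
#' @param seed integer seed; the draw is deterministic under it.
#' @return a rarefied `community_matrix`; every column sums to `depth`.
#' @export
rarefy <- function(m, depth = "min", seed = 1) {
  assert_community_matrix(m)
  if (any(m$counts != floor(m$counts))) stopf("rarefaction needs integer counts")
  totals <- colSums(m$counts)
  if (identical(depth, "min")) depth <- min(totals)
  if (!is_count(depth, 1L)) stopf("depth must be a positive integer or \"min\"")
  short <- totals < depth
  if (any(short)) {
    stopf("sample(s) below rarefaction depth %d: %s", depth,
          paste(colnames(m$counts)[short], collapse = ", "))
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  # depth <= every sample total is checked above; vegan's residual
  # "observed counts" heuristic warning is not informative here
  rare <- t(suppressWarnings(vegan::rrarefy(t(m$counts), sample = depth)))
  storage.mode(rare) <- "integer"
  community_matrix(rare, m$sample_meta$layer, m$sample_meta$season)
}

#' Per-sample alpha diversity
#'
#' Computes observed richness, bias-corrected Chao1 richness
#' \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))} (where \eqn{F_1},
#' \eqn{F_2} are singleton and doubleton counts), Shannon entropy (natural
#' log) and Pielou's evenness \eqn{H / \ln S_{obs}}.  Pielou is reported as
#' `NA` when a sample holds at most one taxon.
#'
#' @param m a [community_matrix()] of integer counts (Chao1 requires
#'   integers).
#' @return data frame with one row per sample: `sample`, `layer`, `season`,
#'   `observed`, `chao1`, `shannon`, `pielou`.
#' @export
alpha_diversity <- function(m) {
  assert_community_matrix(m)
  if (any(m$counts != floor(m$counts))) stopf("Chao1 requires integer counts")
  per_sample <- function(x) {
    x <- x[x > 0]
    s_obs <- length(x)
    f1 <- sum(x == 1)
    f2 <- sum(x == 2)
    chao1 <- s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
    p <- x / sum(x)
    h <- -sum(p * log(p))
    pielou <- if (s_obs > 1) h / log(s_obs) else NA_real_
    c(observed = s_obs, chao1 = chao1, shannon = h, pielou = pielou)
  }
  stats <- t(apply(m$counts, 2, per_sample))
  cbind(m$sample_meta, as.data.frame(stats), row.names = NULL)
}

#' Pairwise community dissimilarity
#'
#' Bray-Curtis on abundances, \eqn{\sum |x - y| / \sum (x + y)}, or binary
#' Jaccard on presence/absence, \eqn{1 - |A \cap B| / |A \cup B|}.
#'
#' @param m a [community_matrix()].
#' @param metric `"bray_curtis"` (default) or `"jaccard_binary"`.
#' @param relative if `TRUE`, columns are scaled to relative abundance
#'   before Bray-Curtis (no effect on binary Jaccard); default `FALSE`,
#'   i.e. dissimilarity on (rarefied) counts.
#' @return symmetric sample-by-sample matrix with zero diagonal, values in
#'   \[0, 1\].
#' @export
dissimilarity <- function(m, metric = c("bray_curtis", "jaccard_binary"),
                          relative = FALSE) {
  assert_community_matrix(m)
  metric <- match.arg(metric)
  if (n_samples(m) < 2L) stopf("need at least 2 samples")
  zero <- colSums(m$counts) == 0
  if (any(zero)) {
    stopf("sample(s) with zero total counts: %s",
          paste(colnames(m$counts)[zero], collapse = ", "))
  }
  x <- t(m$counts)
  if (relative && metric == "bray_curtis") x <- x / rowSums(x)
  d <- switch(metric,
    bray_curtis = vegan::vegdist(x, method = "bray"),
    jaccard_binary = vegan::vegdist(x, method = "jaccard", binary = TRUE)
  )
  as.matrix(d)
}

assert_dissimilarity <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stopf("expected a square matrix")
  if (!isSymmetric(unname(d), tol = 1e-10)) stopf("dissimilarity matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stopf("dissimilarity diagonal must be zero")
  invisible(d)
}

#' Principal coordinates analysis
#'
#' Classical metric scaling (Gower double-centering of squared
#' dissimilarities followed by eigendecomposition).  Negative eigenvalues
#' are reported as-is, without correction; the proportion explained is
#' computed over the positive eigenvalues and the total negative mass is
#' returned alongside.
#'
#' @param d symmetric dissimilarity matrix (e.g. from [dissimilarity()]).
#' @param k number of axes to return, `k < nrow(d)`.
#' @return list with `coordinates` (samples x k), `eigenvalues` (all n),
#'   `proportion_explained` (over positive eigenvalues, first k) and
#'   `negative_mass` (sum of |negative eigenvalues|).
#' @export
pcoa <- function(d, k = 2) {
  assert_dissimilarity(d)
  if (!is_count(k, 1L) || k >= nrow(d)) stopf("k must satisfy 1 <= k < n_samples")
  fit <- cmdscale(as.dist(d), k = k, eig = TRUE)
  eig <- fit$eig
  pos <- pmax(eig, 0)
  prop <- if (sum(pos) > 0) pos / sum(pos) else pos
  list(
    coordinates = fit$points,
    eigenvalues = eig,
    proportion_explained = prop[seq_len(k)],
    negative_mass = sum(abs(pmin(eig, 0)))
  )
}

#' UPGMA clustering of samples
#'
#' Average-linkage agglomeration of a dissimilarity matrix.  Samples are
#' ordered lexicographically before clustering so that ties in merge
#' heights resolve deterministically.  Reported node heights follow the
#' ultrametric tree convention (half the cophenetic dissimilarity), as in
#' the dendrogram produced by converting the clustering to a phylogeny.
#'
#' @param d symmetric dissimilarity matrix with sample names.
#' @return list of class `upgma_clustering`: `hclust` (the raw
#'   [stats::hclust()] object, merge heights on the dissimilarity scale),
#'   `tree` (ultrametric [ape] phylogeny), `merge_heights` (tree-scale
#'   heights, i.e. `hclust$height / 2`).
#' @export
upgma <- function(d) {
  assert_dissimilarity(d)
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hc <- hclust(as.dist(d), method = "average")
  structure(
    list(hclust = hc, tree = ape::as.phylo(hc), merge_heights = hc$height / 2),
    class = "upgma_clustering"
  )
}

#' Cut a UPGMA clustering into k groups
#'
#' @param clustering an [upgma()] result.
#' @param k number of flat clusters.
#' @return named integer vector of cluster memberships.
#' @export
upgma_cut <- function(clustering, k) {
  stopifnot(inherits(clustering, "upgma_clustering"))
  cutree(clustering$hclust, k = k)
}

#' Analysis of similarities (ANOSIM)
#'
#' Tests whether between-group rank dissimilarities exceed within-group
#' ones.  The R statistic follows the standard definition
#' \eqn{R = (\bar r_B - \bar r_W) / (M / 2)} with \eqn{M = n(n-1)/2}; the
#' p-value uses label permutations with the add-one rule,
#' \eqn{p = (\#\{R_{perm} \ge R\} + 1) / (n_{perm} + 1)}.
#'
#' @param d symmetric dissimilarity matrix.
#' @param groups group label per sample; at least two groups, each with at
#'   least two members.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return list with `R`, `p_value`, `n_perm`.
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = 1) {
  assert_dissimilarity(d)
  groups <- as.factor(groups)
  if (length(groups) != nrow(d)) stopf("one group label per sample required")
  tab <- table(groups)
  if (length(tab) < 2L) stopf("need at least two groups")
  if (any(tab < 2L)) {
    stopf("singleton group(s): %s", paste(names(tab)[tab < 2], collapse = ", "))
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  fit <- vegan::anosim(as.dist(d), grouping = groups, permutations = n_perm)
  list(R = unname(fit$statistic), p_value = fit$signif, n_perm = n_perm)
}

#' Multiple-timepoint abundance-based dissimilarity
#'
#' Baselga's abundance-based multiple-site dissimilarity over the seasonal
#' snapshots of one layer, partitioned into balanced-variation and
#' abundance-gradient components.  With pairwise terms
#' \eqn{b_{ij} = \sum_s \max(0, x_{si} - x_{sj})} and
#' \eqn{A_{ij} = \sum_s \min(x_{si}, x_{sj})}:
#' \deqn{total = \frac{\sum_{i<j} \min(b_{ij}, b_{ji}) + \sum_{i<j} \max(b_{ij}, b_{ji})}
#'   {2 \sum_{i<j} A_{ij} + \sum_{i<j} \min + \sum_{i<j} \max}}
#' \deqn{balanced = \frac{\sum \min}{\sum A + \sum \min}, \quad
#'   gradient = total - balanced.}
#' For two samples the total reduces exactly to their pairwise Bray-Curtis
#' dissimilarity.
#'
#' @param m a [community_matrix()] (or plain taxon-by-sample matrix) of the
#'   timepoints of a single layer; at least 2 samples.
#' @return list with `total`, `balanced`, `gradient`, `n_samples`.
#' @export
multi_timepoint_dissimilarity <- function(m) {
  x <- if (inherits(m, "community_matrix")) m$counts else m
  if (!is.matrix(x) || ncol(x) < 2L) stopf("need at least 2 timepoint samples")
  n <- ncol(x)
  sum_min_b <- sum_max_b <- sum_a <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      a <- sum(pmin(x[, i], x[, j]))
      bij <- sum(x[, i]) - a
      bji <- sum(x[, j]) - a
      sum_min_b <- sum_min_b + min(bij, bji)
      sum_max_b <- sum_max_b + max(bij, bji)
      sum_a <- sum_a + a
    }
  }
  denom <- 2 * sum_a + sum_min_b + sum_max_b
  total <- if (denom > 0) (sum_min_b + sum_max_b) / denom else 0
  balanced <- if (sum_a + sum_min_b > 0) sum_min_b / (sum_a + sum_min_b) else 0
  list(total = total, balanced = balanced, gradient = total - balanced,
       n_samples = n)
}

#' Seasonal fluctuation per depth layer
#'
#' Applies [multi_timepoint_dissimilarity()] to the seasonal snapshots of
#' each layer.
#'
#' @param m a [community_matrix()] with multiple seasons.
#' @return data frame with one row per layer: `layer`, `n_seasons`,
#'   `total`, `balanced`, `gradient`.  Layers with a single snapshot are
#'   skipped with a warning.
#' @export
layer_fluctuation <- function(m) {
  assert_community_matrix(m)
  layers <- sort(unique(m$sample_meta$layer))
  rows <- lapply(layers, function(l) {
    idx <- m$sample_meta$layer == l
    if (sum(idx) < 2L) {
      warnf("layer %d has a single snapshot; skipped", l)
      return(NULL)
    }
    r <- multi_timepoint_dissimilarity(m$counts[, idx, drop = FALSE])
    data.frame(layer = l, n_seasons = r$n_samples, total = r$total,
               balanced = r$balanced, gradient = r$gradient)
  })
  do.call(rbind, rows)
}

#' Per-taxon connection degree in the OTU-layer bipartite network
#'
#' On a seasonally merged matrix, a taxon is connected to a layer when its
#' log10-transformed abundance is at least 1 (i.e. abundance >= 10); the
#' connection degree is the number of layers so connected.
#'
#' @param m a [community_matrix()], typically from [merge_seasons()].
#' @param threshold minimum abundance for an edge (default 10).
#' @return named integer vector of degrees, one per taxon, in
#'   `[0, n_samples]`.
#' @export
connection_degree <- function(m, threshold = 10) {
  assert_community_matrix(m)
  rowSums(m$counts >= threshold)
}
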