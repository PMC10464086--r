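#' Ensemble random-forest importance of taxa for the damming split
#'
#' Trains `n_forests` independent random-forest classifiers of pre- versus
#' post-horizon samples and pools the per-forest mean-decrease-Gini (MDG)
#' importances by their arithmetic mean, the order-insensitive analogue of
#' combining forests.  Classification accuracy is summarized by the mean
#' out-of-bag (OOB) misclassification rate.  Class imbalance is handled by
#' a stratified bootstrap per tree (downsampling to the minority class
#' size) unless `stratify = FALSE`.
#'
#' @param features samples-by-taxa matrix of (relative) abundances; taxa
#'   typically aggregated to phylum or class rank via [aggregate_taxa()].
#' @param labels two-level factor (e.g. `"pre"`/`"post"`) per sample; both
#'   classes must be present.
#' @param n_forests number of forest replicates (default 100).
#' @param n_trees trees per forest (default 1000).
#' @param seed master seed; per-forest seeds derive from it.
#' @param stratify stratified per-tree bootstrap (default `TRUE`).
#' @return object of class `importance_ranking`: list with `ranking` (data
#'   frame `taxon`, `importance`, `rank`, sorted by decreasing pooled MDG),
#'   `oob_error`, `n_forests`, `n_trees`.
#' @export
rf_importance_ensemble <- function(features, labels, n_forests = 100,
                                   n_trees = 1000, seed = 1, stratify = TRUE) {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (is.null(colnames(features))) stopf("features need taxon column names")
  y <- factor(labels)
  if (length(y) != nrow(features)) stopf("one label per sample required")
  if (nlevels(droplevels(y)) < 2L) stopf("both classes must be present")
  y <- droplevels(y)
  seeds <- derive_seeds(seed, n_forests)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  imp <- matrix(0, ncol(features), n_forests)
  oob <- numeric(n_forests)
  samp <- if (stratify) rep(min(table(y)), nlevels(y)) else NULL
  for (f in seq_len(n_forests)) {
    set.seed(seeds[f])
    rf <- if (stratify) {
      randomForest::randomForest(x = features, y = y, ntree = n_trees,
                                 strata = y, sampsize = samp)
    } else {
      randomForest::randomForest(x = features, y = y, ntree = n_trees)
    }
    imp[, f] <- rf$importance[, "MeanDecreaseGini"]
    oob[f] <- rf$err.rate[n_trees, "OOB"]
  }
  pooled <- rowMeans(imp)
  ord <- order(-pooled, colnames(features))
  ranking <- data.frame(
    taxon = colnames(features)[ord],
    importance = pooled[ord],
    rank = seq_along(ord)
  )
  structure(list(ranking = ranking, oob_error = mean(oob),
                 n_forests = n_forests, n_trees = n_trees),
            class = "importance_ranking")
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat(sprintf("importance_ranking: %d taxa, %d forests x %d trees, OOB error %.3f\n",
              nrow(x$ranking), x$n_forests, x$n_trees, x$oob_error))
  print(head(x$ranking, 10), row.names = FALSE)
  invisible(x)
}

## RSS of fitting one segment of y (constant mean, or a sloped line).
segment_cost <- function(y, segment) {
  n <- length(y)
  if (segment == "constant") return(sum(y^2) - sum(y)^2 / n)
  if (n <= 2L) return(0)  # a line interpolates two points exactly
  x <- seq_len(n)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sum((y - mean(y))^2) - sxy^2 / sxx
}

#' Breakpoints in a ranked importance curve
#'
#' Least-squares segmentation of the descending importance sequence by
#' dynamic programming (optimal for a given number of breaks), with the
#' number of breaks chosen by BIC up to `max_breaks`.  The taxa ranked
#' before the first breakpoint form the selected ("damming-sensitive")
#' set.  Segments are piecewise-constant by default; `segment = "linear"`
#' fits a sloped line per segment.
#'
#' @param ranking an `importance_ranking` (from
#'   [rf_importance_ensemble()]) or a numeric vector of ranked importances
#'   (>= 4 values).
#' @param max_breaks maximum number of breakpoints considered; must be
#'   less than `n / 2` (minimum segment length is 2).
#' @param segment `"constant"` (default) or `"linear"` per-segment model.
#' @return list with `breakpoints` (indices of the last element of each
#'   segment except the final one; empty if BIC keeps a single segment),
#'   `n_breaks`, `rss`, `bic` (per candidate break count), `selected`
#'   (taxon names or indices before the first breakpoint) and `ranking`
#'   (data frame with a logical `selected` column when an
#'   `importance_ranking` was supplied).
#' @export
importance_breakpoints <- function(ranking, max_breaks = 3,
                                   segment = c("constant", "linear")) {
  segment <- match.arg(segment)
  rk <- NULL
  if (inherits(ranking, "importance_ranking")) {
    rk <- ranking$ranking
    y <- rk$importance
  } else {
    y <- as.numeric(ranking)
  }
  n <- length(y)
  if (n < 4L) stopf("breakpoint search needs at least 4 ranked values")
  if (!is_count(max_breaks, 0L) || max_breaks >= n / 2) {
    stopf("max_breaks must be an integer < n/2")
  }
  min_seg <- 2L
  ## cost[i, j]: RSS of segment i..j (Inf when shorter than min_seg)
  cost <- matrix(Inf, n, n)
  for (i in seq_len(n - min_seg + 1L)) {
    for (j in seq.int(i + min_seg - 1L, n)) {
      cost[i, j] <- segment_cost(y[i:j], segment)
    }
  }
  ## f[m+1, j]: best RSS splitting 1..j into m+1 segments
  f <- matrix(Inf, max_breaks + 1L, n)
  back <- matrix(NA_integer_, max_breaks + 1L, n)
  f[1L, ] <- cost[1L, ]
  if (max_breaks >= 1L) {
    for (m in seq_len(max_breaks)) {
      for (j in seq_len(n)) {
        ts <- seq_len(j - 1L)
        vals <- f[m, ts] + cost[cbind(ts + 1L, rep(j, length(ts)))]
        if (all(!is.finite(vals))) next
        t_best <- which.min(vals)
        f[m + 1L, j] <- vals[t_best]
        back[m + 1L, j] <- t_best
      }
    }
  }
  p <- if (segment == "constant") 1L else 2L
  rss <- f[, n]
  ms <- 0:max_breaks
  npar <- (ms + 1L) * p + ms
  bic <- n * log(pmax(rss, 1e-12) / n) + npar * log(n)
  m_best <- ms[which.min(bic)]
  bp <- integer(0)
  if (m_best > 0L) {
    j <- n
    for (m in seq.int(m_best + 1L, 2L)) {
      j <- back[m, j]
      bp <- c(j, bp)
    }
  }
  selected_idx <- if (length(bp)) seq_len(bp[1]) else integer(0)
  selected <- if (!is.null(rk)) rk$taxon[selected_idx] else selected_idx
  if (!is.null(rk)) rk$selected <- rk$rank %in% selected_idx
  list(breakpoints = bp, n_breaks = m_best, rss = rss[m_best + 1L],
       bic = setNames(bic, paste0("breaks_", ms)), selected = selected,
       ranking = rk)
}

#' Unsupervised random-forest clustering of samples
#'
#' Trains a forest to separate the real samples from a synthetic contrast
#' class sampled from the product of the feature marginals (the standard
#' unsupervised random-forest construction), derives sample-to-sample
#' proximities as co-leaf frequencies, and partitions the samples into two
#' groups by average-linkage clustering of `1 - proximity`.
#'
#' @param features samples-by-taxa matrix (>= 4 samples, not all columns
#'   constant).
#' @param n_trees trees in the forest (default 2000).
#' @param seed integer seed.
#' @return list with `distance` (1 - proximity, zero diagonal),
#'   `coordinates` (2-D classical scaling), `clusters` (named k = 2
#'   membership vector).
#' @export
unsupervised_rf_clustering <- function(features, n_trees = 2000, seed = 1) {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (nrow(features) < 4L) stopf("need at least 4 samples")
  if (all(apply(features, 2, var) == 0)) stopf("all features are constant")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  rf <- randomForest::randomForest(x = features, ntree = n_trees, proximity = TRUE)
  prox <- rf$proximity
  d <- 1 - prox
  diag(d) <- 0
  coords <- cmdscale(as.dist(d), k = 2)
  clusters <- cutree(hclust(as.dist(d), method = "average"), k = 2)
  list(distance = d, coordinates = coords, clusters = clusters)
}

#' Aggregate a community matrix to a coarser taxonomic rank
#'
#' Sums counts of taxa sharing a rank label (e.g. phylum or class) and
#' returns per-sample relative abundances, the feature table of the
#' damming-sensitivity screen.
#'
#' @param m a [community_matrix()].
#' @param taxonomy named character vector mapping taxon IDs to rank labels
#'   (must cover all taxa of `m`).
#' @param relative return per-sample relative abundances (default `TRUE`).
#' @return samples-by-groups numeric matrix.
#' @export
aggregate_taxa <- function(m, taxonomy, relative = TRUE) {
  assert_community_matrix(m)
  missing <- setdiff(rownames(m$counts), names(taxonomy))
  if (length(missing)) {
    stopf("%d taxa lack a rank label, e.g.: %s", length(missing),
          paste(head(missing, 5), collapse = ", "))
  }
  groups <- taxonomy[rownames(m$counts)]
  agg <- rowsum(m$counts, group = groups)
  out <- t(agg)
  if (relative) out <- out / rowSums(out)
  out
}
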