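#' Patristic distance matrix aligned to a taxon set
#'
#' @param tree rooted phylogeny (`phylo`) with branch lengths.
#' @param taxa optional character vector; the matrix is restricted to and
#'   ordered by these taxa.  Taxa absent from the tree raise an error (no
#'   silent dropping).
#' @return symmetric patristic (cophenetic) distance matrix.
#' @export
patristic_distances <- function(tree, taxa = NULL) {
  if (!inherits(tree, "phylo")) stopf("expected an ape 'phylo' tree")
  d <- cophenetic(tree)
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, rownames(d))
    if (length(missing)) {
      stopf("%d taxa absent from the tree, e.g.: %s", length(missing),
            paste(head(missing, 5), collapse = ", "))
    }
    d <- d[taxa, taxa]
  }
  d
}

align_community <- function(x, dist) {
  if (length(x) != nrow(dist)) {
    if (is.null(names(x))) stopf("community length does not match the distance matrix")
    missing <- setdiff(names(x), rownames(dist))
    if (length(missing)) stopf("taxa absent from distance matrix: %s",
                               paste(head(missing, 5), collapse = ", "))
    full <- setNames(numeric(nrow(dist)), rownames(dist))
    full[names(x)] <- x
    return(full)
  }
  if (!is.null(names(x)) && !is.null(rownames(dist)) &&
      !identical(names(x), rownames(dist))) {
    x <- x[rownames(dist)]
  }
  x
}

#' Mean nearest taxon distance (MNTD)
#'
#' For every taxon present in the community, the phylogenetic distance to
#' its nearest other present taxon, averaged either arithmetically
#' (`weighted = FALSE`) or weighted by relative abundance.
#'
#' @param x abundance vector over the taxa of `dist` (named vectors are
#'   aligned by name).
#' @param dist patristic distance matrix, e.g. [patristic_distances()].
#' @param weighted abundance-weighted mean (default `TRUE`).
#' @return MNTD, a non-negative scalar.
#' @export
mntd <- function(x, dist, weighted = TRUE) {
  x <- align_community(x, dist)
  present <- which(x > 0)
  if (length(present) < 2L) stopf("MNTD needs at least 2 taxa present")
  dp <- dist[present, present, drop = FALSE]
  diag(dp) <- Inf
  ntd <- row_mins(dp)
  if (weighted) {
    w <- x[present] / sum(x[present])
    sum(w * ntd)
  } else {
    mean(ntd)
  }
}

#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' For every taxon of one community, the distance to the nearest taxon
#' present in the other; the two directed means are averaged.  A taxon
#' shared by both communities contributes a nearest distance of zero.
#'
#' @param x1,x2 abundance vectors over the taxa of `dist`.
#' @inheritParams mntd
#' @return betaMNTD, a non-negative symmetric scalar.
#' @export
beta_mntd <- function(x1, x2, dist, weighted = TRUE) {
  x1 <- align_community(x1, dist)
  x2 <- align_community(x2, dist)
  p1 <- which(x1 > 0)
  p2 <- which(x2 > 0)
  if (!length(p1) || !length(p2)) stopf("betaMNTD needs non-empty communities")
  beta_mntd_idx(x1, x2, p1, p2, dist, weighted)
}

## core kernel: p1/p2 are tip indices into dist (possibly permuted for nulls)
beta_mntd_idx <- function(x1, x2, p1, p2, dist, weighted, perm = NULL) {
  i1 <- if (is.null(perm)) p1 else perm[p1]
  i2 <- if (is.null(perm)) p2 else perm[p2]
  m12 <- dist[i1, i2, drop = FALSE]
  ntd1 <- row_mins(m12)
  ntd2 <- row_mins(t(m12))
  if (weighted) {
    f1 <- x1[p1] / sum(x1[p1])
    f2 <- x2[p2] / sum(x2[p2])
    0.5 * (sum(f1 * ntd1) + sum(f2 * ntd2))
  } else {
    0.5 * (mean(ntd1) + mean(ntd2))
  }
}

#' Nearest taxon index (NTI)
#'
#' Standardized effect size of MNTD against a null model that shuffles
#' taxon labels across all tips of the distance matrix:
#' \deqn{NTI = -\frac{MNTD_{obs} - \overline{MNTD_{null}}}{sd(MNTD_{null})}}
#' Positive NTI indicates phylogenetic clustering (stronger than expected
#' environmental filtering).
#'
#' @inheritParams mntd
#' @param n_null number of label randomizations (default 999).
#' @param seed integer seed.
#' @param pool_present restrict shuffling to the taxa present in the
#'   community instead of the full tip pool (default `FALSE`,
#'   metacommunity-wide shuffle).
#' @return NTI as a scalar; `NA` (with a warning) when the null standard
#'   deviation is zero.  Attributes: `obs`, `null_mean`, `null_sd`, and
#'   `p` = add-one rank probability of a null MNTD at or below the
#'   observed (small values = clustered).
#' @export
nti <- function(x, dist, n_null = 999, seed = 1, weighted = TRUE,
                pool_present = FALSE) {
  x <- align_community(x, dist)
  present <- which(x > 0)
  if (length(present) < 2L) stopf("NTI needs at least 2 taxa present")
  obs <- mntd(x, dist, weighted)
  pool <- if (pool_present) present else seq_len(nrow(dist))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  w <- if (weighted) x[present] / sum(x[present]) else NULL
  nulls <- vapply(seq_len(n_null), function(i) {
    idx <- if (pool_present) sample(pool) else sample(pool, length(present))
    dp <- dist[idx[seq_along(present)], idx[seq_along(present)], drop = FALSE]
    diag(dp) <- Inf
    ntd <- row_mins(dp)
    if (weighted) sum(w * ntd) else mean(ntd)
  }, numeric(1))
  null_sd <- sd(nulls)
  p <- (sum(nulls <= obs) + 1) / (n_null + 1)
  if (null_sd == 0) {
    warnf("null MNTD has zero variance; NTI undefined")
    return(structure(NA_real_, obs = obs, null_mean = mean(nulls),
                     null_sd = 0, p = p))
  }
  structure(-(obs - mean(nulls)) / null_sd,
            obs = obs, null_mean = mean(nulls), null_sd = null_sd, p = p)
}

#' Between-community nearest taxon index (betaNTI)
#'
#' Standardized effect size of betaMNTD against tip-label randomization:
#' \deqn{\beta NTI = \frac{\beta MNTD_{obs} - \overline{\beta MNTD_{null}}}
#'   {sd(\beta MNTD_{null})}}
#' Each null replicate draws one permutation of all tip labels and applies
#' it to both communities, preserving their shared-taxon structure under
#' the null.  `betaNTI > 2` indicates heterogeneous selection,
#' `betaNTI < -2` homogeneous selection, `|betaNTI| < 2` a stochastic
#' pairing.
#'
#' @inheritParams beta_mntd
#' @param n_null number of randomizations (default 999).
#' @param seed integer seed.
#' @param pool_present restrict the shuffle to taxa present in either
#'   community (default `FALSE`: all tips of `dist`).
#' @return betaNTI scalar (`NA` with warning if the null sd is zero), with
#'   attributes `obs`, `null_mean`, `null_sd`.
#' @export
bnti <- function(x1, x2, dist, n_null = 999, seed = 1, weighted = TRUE,
                 pool_present = FALSE) {
  x1 <- align_community(x1, dist)
  x2 <- align_community(x2, dist)
  p1 <- which(x1 > 0)
  p2 <- which(x2 > 0)
  if (!length(p1) || !length(p2)) stopf("betaNTI needs non-empty communities")
  obs <- beta_mntd_idx(x1, x2, p1, p2, dist, weighted)
  n <- nrow(dist)
  pool <- if (pool_present) sort(union(p1, p2)) else seq_len(n)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  perm_full <- seq_len(n)
  nulls <- vapply(seq_len(n_null), function(i) {
    perm <- perm_full
    perm[pool] <- sample(pool)
    beta_mntd_idx(x1, x2, p1, p2, dist, weighted, perm = perm)
  }, numeric(1))
  null_sd <- sd(nulls)
  if (null_sd == 0) {
    warnf("null betaMNTD has zero variance; betaNTI undefined")
    return(structure(NA_real_, obs = obs, null_mean = mean(nulls), null_sd = 0))
  }
  structure((obs - mean(nulls)) / null_sd,
            obs = obs, null_mean = mean(nulls), null_sd = null_sd)
}

## Assemble one null community: `richness` taxa drawn without replacement
## with probability proportional to metacommunity occurrence frequency;
## each gets one individual, the remaining (total - richness) individuals
## are distributed multinomially proportional to metacommunity relative
## abundance.
null_community <- function(richness, total, occ_freq, pool_ab) {
  s <- length(occ_freq)
  idx <- sample.int(s, richness, prob = occ_freq)
  x <- numeric(s)
  x[idx] <- 1
  if (total > richness) {
    x[idx] <- x[idx] + as.vector(rmultinom(1, total - richness, prob = pool_ab[idx]))
  }
  x
}

## RC scaling: mid-P (ties at half weight) mapped onto [-1, 1]
rc_scale <- function(below, ties, n_null) {
  2 * ((below + 0.5 * ties) / n_null) - 1
}

bray_rel <- function(x, y) {
  px <- x / sum(x)
  py <- y / sum(y)
  sum(abs(px - py)) / 2
}

#' Bray-Curtis-based Raup-Crick metric (RC_bray)
#'
#' Compares the observed Bray-Curtis dissimilarity of a sample pair to a
#' distribution of dissimilarities between probabilistically assembled null
#' communities that preserve each sample's observed richness and total
#' abundance: taxa are drawn without replacement proportional to their
#' metacommunity occurrence frequency, remaining individuals proportional
#' to metacommunity relative abundance.  With `n_below` nulls below the
#' observed value and `n_tie` ties (counted at half weight),
#' \deqn{RC = 2 \frac{n_{below} + 0.5\, n_{tie}}{n_{null}} - 1 \in [-1, 1].}
#' Conditional on a stochastic betaNTI (`|betaNTI| < 2`), `RC > 0.95`
#' indicates dispersal limitation, `RC < -0.95` homogenizing dispersal and
#' `|RC| <= 0.95` ecological drift.  Bray-Curtis is computed on relative
#' abundances.
#'
#' @param x1,x2 count vectors over the metacommunity's taxa.
#' @param metacommunity a [community_matrix()] (or taxon-by-sample count
#'   matrix) defining occurrence frequencies and pool abundances.
#' @param n_null number of null pairs (default 9999).
#' @param seed integer seed.
#' @return RC value in \[-1, 1\] with attribute `bc_obs`.
#' @export
raup_crick_bray <- function(x1, x2, metacommunity, n_null = 9999, seed = 1) {
  meta <- if (inherits(metacommunity, "community_matrix")) {
    metacommunity$counts
  } else {
    metacommunity
  }
  if (!is.matrix(meta)) stopf("metacommunity must be a matrix or community_matrix")
  if (length(x1) != nrow(meta) || length(x2) != nrow(meta)) {
    stopf("communities must span the metacommunity taxon universe")
  }
  r1 <- sum(x1 > 0); r2 <- sum(x2 > 0)
  if (r1 == 0L || r2 == 0L) stopf("empty community")
  n1 <- sum(x1); n2 <- sum(x2)
  occ <- rowSums(meta > 0)
  pool <- rowSums(meta)
  pool <- pool / sum(pool)
  bc_obs <- bray_rel(x1, x2)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  below <- ties <- 0L
  eps <- 1e-12
  for (i in seq_len(n_null)) {
    b1 <- null_community(r1, n1, occ, pool)
    b2 <- null_community(r2, n2, occ, pool)
    bc_null <- bray_rel(b1, b2)
    if (bc_null < bc_obs - eps) below <- below + 1L
    else if (bc_null <= bc_obs + eps) ties <- ties + 1L
  }
  structure(rc_scale(below, ties, n_null), bc_obs = bc_obs)
}

#' Five-way partition of community assembly processes
#'
#' Classifies each pairwise comparison by the rules: `betaNTI > 2`
#' heterogeneous selection; `betaNTI < -2` homogeneous selection;
#' otherwise (stochastic) `RC > 0.95` dispersal limitation, `RC < -0.95`
#' homogenizing dispersal, `|RC| <= 0.95` ecological drift.
#'
#' Pairs with an undefined betaNTI or RC (e.g. zero null variance) are
#' classified `NA` with a warning; fractions are computed over the defined
#' pairs.
#'
#' @param bnti numeric vector of betaNTI values.
#' @param rc numeric vector of RC_bray values on the same pairs.
#' @return list with `process` (factor per pair) and `fractions` (named
#'   numeric over the five processes, summing to 1 over defined pairs).
#' @export
partition_processes <- function(bnti, rc) {
  if (length(bnti) != length(rc)) stopf("betaNTI and RC must cover the same pairs")
  und <- is.na(bnti) | is.na(rc)
  if (any(und)) warnf("%d pair(s) with undefined betaNTI/RC left unclassified", sum(und))
  if (any(abs(rc) > 1 + 1e-9)) stopf("RC values must lie in [-1, 1]")
  lev <- c("heterogeneous_selection", "homogeneous_selection",
           "dispersal_limitation", "homogenizing_dispersal", "drift")
  proc <- ifelse(bnti > 2, lev[1],
          ifelse(bnti < -2, lev[2],
          ifelse(rc > 0.95, lev[3],
          ifelse(rc < -0.95, lev[4], lev[5]))))
  proc <- factor(proc, levels = lev)
  n_def <- sum(!und)
  if (n_def == 0L) stopf("no defined pair to partition")
  fr <- as.numeric(table(proc)) / n_def
  names(fr) <- lev
  list(process = proc, fractions = fr)
}

#' Pairwise assembly analysis over all samples
#'
#' Computes betaNTI and RC_bray for every sample pair of a community
#' matrix and partitions the pairs into the five assembly processes.
#'
#' @param m a [community_matrix()].
#' @param tree phylogeny covering the matrix's taxa.
#' @param n_null_bnti,n_null_rc randomization counts (full-scale defaults
#'   999 and 9999; reduce for desk-scale runs).
#' @param seed master seed; per-pair seeds derive from it.
#' @param weighted abundance-weighted betaMNTD (default `TRUE`).
#' @param metacommunity pool for the Raup-Crick null; defaults to `m`
#'   itself.  Pass the full system when analysing a subset of samples
#'   (e.g. one depth zone) against the regional pool.
#' @return list of class `assembly_result`: `bnti` and `rc` (sample
#'   matrices), `pairs` (long data frame with process labels), `fractions`.
#' @export
assembly_analysis <- function(m, tree, n_null_bnti = 999, n_null_rc = 9999,
                              seed = 1, weighted = TRUE, metacommunity = NULL) {
  assert_community_matrix(m)
  metacommunity <- metacommunity %||% m
  d <- patristic_distances(tree, rownames(m$counts))
  ns <- n_samples(m)
  if (ns < 2L) stopf("need at least 2 samples")
  np <- ns * (ns - 1L) / 2L
  seeds <- derive_seeds(seed, 2L * np)
  bnti_m <- rc_m <- matrix(NA_real_, ns, ns,
                           dimnames = list(colnames(m$counts), colnames(m$counts)))
  rows <- vector("list", np)
  k <- 0L
  for (i in seq_len(ns - 1L)) {
    for (j in seq.int(i + 1L, ns)) {
      k <- k + 1L
      b <- bnti(m$counts[, i], m$counts[, j], d, n_null = n_null_bnti,
                seed = seeds[2L * k - 1L], weighted = weighted)
      r <- raup_crick_bray(m$counts[, i], m$counts[, j], metacommunity,
                           n_null = n_null_rc, seed = seeds[2L * k])
      bnti_m[i, j] <- bnti_m[j, i] <- as.numeric(b)
      rc_m[i, j] <- rc_m[j, i] <- as.numeric(r)
      rows[[k]] <- data.frame(
        sample_1 = colnames(m$counts)[i], sample_2 = colnames(m$counts)[j],
        bnti = as.numeric(b), rc = as.numeric(r)
      )
    }
  }
  diag(bnti_m) <- diag(rc_m) <- 0
  pairs <- do.call(rbind, rows)
  part <- partition_processes(pairs$bnti, pairs$rc)
  pairs$process <- part$process
  structure(list(bnti = bnti_m, rc = rc_m, pairs = pairs,
                 fractions = part$fractions),
            class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat(sprintf("assembly_result over %d pairwise comparisons\n", nrow(x$pairs)))
  print(round(x$fractions, 3))
  invisible(x)
}

#' betaNTI/RC profile across adjacent depth layers
#'
#' Computes one betaNTI and RC_bray value per adjacent-layer boundary,
#' either on seasonally merged layers (`mode = "merged"`) or per season on
#' same-season snapshots (`mode = "snapshots"`).  The metacommunity for the
#' Raup-Crick null is the full supplied matrix.
#'
#' @param m a [community_matrix()].
#' @param tree phylogeny covering the matrix's taxa.
#' @param mode `"merged"` or `"snapshots"`.
#' @param n_null_bnti,n_null_rc randomization counts.
#' @param seed master seed.
#' @param weighted abundance-weighted betaMNTD (default `TRUE`).
#' @return data frame ordered by boundary depth with columns `layer_top`,
#'   `layer_bottom`, `season` (`"merged"` in merged mode), `bnti`, `rc`,
#'   `process`.
#' @export
adjacent_layer_profile <- function(m, tree, mode = c("merged", "snapshots"),
                                   n_null_bnti = 999, n_null_rc = 9999,
                                   seed = 1, weighted = TRUE) {
  assert_community_matrix(m)
  mode <- match.arg(mode)
  work <- if (mode == "merged") merge_seasons(m) else m
  d <- patristic_distances(tree, rownames(work$counts))
  layers <- sort(unique(work$sample_meta$layer))
  seasons <- if (mode == "merged") "merged" else sort(unique(work$sample_meta$season))
  combos <- expand.grid(l = layers[-length(layers)], s = seasons,
                        stringsAsFactors = FALSE)
  seeds <- derive_seeds(seed, 2L * nrow(combos))
  rows <- vector("list", nrow(combos))
  for (k in seq_len(nrow(combos))) {
    l <- combos$l[k]
    s <- combos$s[k]
    pick <- function(layer) {
      sel <- work$sample_meta$layer == layer &
        (mode == "merged" | work$sample_meta$season == s)
      which(sel)
    }
    i1 <- pick(l)
    i2 <- pick(l + 1L)
    if (!length(i1) || !length(i2)) {
      warnf("no sample for boundary %d-%d (season %s); skipped", l, l + 1L, s)
      next
    }
    x1 <- rowSums(work$counts[, i1, drop = FALSE])
    x2 <- rowSums(work$counts[, i2, drop = FALSE])
    b <- bnti(x1, x2, d, n_null = n_null_bnti, seed = seeds[2L * k - 1L],
              weighted = weighted)
    r <- raup_crick_bray(x1, x2, work, n_null = n_null_rc, seed = seeds[2L * k])
    rows[[k]] <- data.frame(layer_top = l, layer_bottom = l + 1L, season = s,
                            bnti = as.numeric(b), rc = as.numeric(r))
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) stopf("no adjacent-layer pair could be formed")
  out$process <- partition_processes(out$bnti, out$rc)$process
  out[order(out$layer_top, out$season), , drop = FALSE]
}
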