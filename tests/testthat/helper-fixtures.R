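# Shared fixtures and independent oracles, built in code.

tiny_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# two clearly separated clades of equal size with staggered tip depths
# (within-clade distances vary, so tip-shuffle nulls are non-degenerate)
two_clade_tree <- function(n_per_clade = 8) {
  tip <- function(p) {
    paste0("(", paste0(p, seq_len(n_per_clade), ":",
                       0.05 * seq_len(n_per_clade), collapse = ","), ")")
  }
  ape::read.tree(text = paste0("(", tip("A"), ":5,", tip("B"), ":5);"))
}

make_cm <- function(counts, layer = NULL, season = NULL) {
  if (is.null(rownames(counts))) rownames(counts) <- paste0("t", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  community_matrix(counts,
                   layer = layer %||% seq_len(ncol(counts)),
                   season = season %||% rep("S1", ncol(counts)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

small_dataset <- function(seed = 1, ...) {
  args <- list(n_taxa = 60, n_layers = 6, n_seasons = 2, damming_layer = 3,
               library_size = 1500, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  generate_dataset(do.call(generator_config, args))
}

# ---- brute-force oracles (straight from the definitions) -------------

bf_mntd <- function(x, d, weighted) {
  pres <- which(x > 0)
  ntd <- vapply(pres, function(i) min(d[i, setdiff(pres, i)]), numeric(1))
  if (weighted) sum(x[pres] / sum(x[pres]) * ntd) else mean(ntd)
}

bf_beta_mntd <- function(x1, x2, d, weighted) {
  p1 <- which(x1 > 0); p2 <- which(x2 > 0)
  nt1 <- vapply(p1, function(i) min(d[i, p2]), numeric(1))
  nt2 <- vapply(p2, function(i) min(d[i, p1]), numeric(1))
  if (weighted) {
    0.5 * (sum(x1[p1] / sum(x1[p1]) * nt1) + sum(x2[p2] / sum(x2[p2]) * nt2))
  } else {
    0.5 * (mean(nt1) + mean(nt2))
  }
}

# Baselga's abundance-based multiple-site partition, written directly
# from the pairwise sums.
bf_multisite <- function(x) {
  n <- ncol(x)
  smin <- smax <- sa <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    b_ij <- sum(pmax(0, x[, i] - x[, j]))
    b_ji <- sum(pmax(0, x[, j] - x[, i]))
    sa <- sa + sum(pmin(x[, i], x[, j]))
    smin <- smin + min(b_ij, b_ji)
    smax <- smax + max(b_ij, b_ji)
  }
  total <- (smin + smax) / (2 * sa + smin + smax)
  balanced <- smin / (sa + smin)
  c(total = total, balanced = balanced, gradient = total - balanced)
}

# Exhaustive least-squares segmentation (minimum segment length 2) for
# small n: returns best RSS and breakpoints for each break count.
bf_segmentation <- function(y, max_breaks, segment = "constant") {
  n <- length(y)
  cost <- function(i, j) {
    z <- y[i:j]
    if (segment == "constant") return(sum(z^2) - sum(z)^2 / length(z))
    if (length(z) <= 2) return(0)
    fit <- lm(z ~ seq_along(z))
    sum(fit$residuals^2)
  }
  best <- list()
  for (m in 0:max_breaks) {
    if (m == 0) {
      best[[1]] <- list(rss = cost(1, n), breaks = integer(0))
      next
    }
    combos <- utils::combn(seq_len(n - 1), m, simplify = FALSE)
    ok <- Filter(function(b) all(diff(c(0, b, n)) >= 2), combos)
    res <- lapply(ok, function(b) {
      lo <- c(1, b + 1); hi <- c(b, n)
      list(rss = sum(mapply(cost, lo, hi)), breaks = b)
    })
    best[[m + 1]] <- res[[which.min(vapply(res, `[[`, numeric(1), "rss"))]]
  }
  best
}

# binomial 99% confidence band around a nominal proportion
binom_band99 <- function(p, n) {
  se <- sqrt(p * (1 - p) / n)
  c(p - stats::qnorm(0.995) * se, p + stats::qnorm(0.995) * se)
}
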