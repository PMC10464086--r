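#' Levin's niche breadth per taxon
#'
#' Treats the depth layers of a seasonally merged matrix as habitats and
#' computes, for each taxon \eqn{j},
#' \deqn{B_j = 1 / \sum_{i=1}^{N} P_{ij}^2}
#' where \eqn{P_{ij}} is the share of taxon \eqn{j}'s total abundance found
#' in layer \eqn{i} and \eqn{N} the number of layers.  \eqn{B_j = 1} for a
#' single-layer specialist and \eqn{B_j = N} for a perfectly uniform
#' generalist.
#'
#' @param m a [community_matrix()] with one sample per layer (see
#'   [merge_seasons()]).
#' @return named numeric vector of breadths for every taxon with non-zero
#'   total abundance; all-zero taxa are dropped with a warning.
#' @export
levins_breadth <- function(m) {
  assert_community_matrix(m)
  if (anyDuplicated(m$sample_meta$layer)) {
    stopf("niche breadth needs one sample per layer; pool seasons first")
  }
  totals <- rowSums(m$counts)
  if (any(totals == 0)) {
    warnf("%d all-zero taxa excluded from niche breadth", sum(totals == 0))
  }
  x <- m$counts[totals > 0, , drop = FALSE]
  p <- x / rowSums(x)
  1 / rowSums(p^2)
}

#' Community mean niche breadth per layer
#'
#' The abundance-weighted mean of per-taxon Levin's breadths in each local
#' community: \eqn{\bar B_i = \sum_j Q_{ij} B_j} with \eqn{Q_{ij}} the
#' within-layer relative abundance.  Values lie in \eqn{[1, N]}: since
#' every \eqn{B_j \ge 1}, so is any weighted mean of them.
#'
#' @param m a [community_matrix()] with one sample per layer.
#' @param b optional per-taxon breadths from [levins_breadth()]; computed
#'   from `m` when omitted.
#' @return data frame with `layer` and `mnb`.
#' @export
mean_niche_breadth <- function(m, b = NULL) {
  assert_community_matrix(m)
  if (is.null(b)) {
    b <- withCallingHandlers(levins_breadth(m),
                             warning = function(w) invokeRestart("muffleWarning"))
  }
  if (any(colSums(m$counts) == 0)) stopf("empty layer(s) in the matrix")
  x <- m$counts[names(b), , drop = FALSE]
  q <- sweep(x, 2, colSums(m$counts), "/")
  ## all-zero taxa carry zero weight, so restricting Q to taxa with a
  ## breadth keeps each column summing to 1
  mnb <- colSums(q * b)
  data.frame(layer = m$sample_meta$layer, mnb = as.numeric(mnb))
}

#' Quadratic depth profile of mean niche breadth
#'
#' Ordinary least-squares fit of per-layer mean niche breadth on layer
#' index and its square, summarizing the characteristic mid-profile bulge
#' of generalists near a transition horizon.
#'
#' @param mnb numeric vector of per-layer MNB values (>= 4 layers), or the
#'   data frame returned by [mean_niche_breadth()].
#' @param layer layer indices; defaults to `seq_along(mnb)` (or the data
#'   frame's `layer` column).
#' @return list with `coefficients` (`intercept`, `linear`, `quadratic`),
#'   `r_squared`, `vertex` (stationary layer, `NA` if the fit is linear)
#'   and the fitted `model`.
#' @export
fit_mnb_depth <- function(mnb, layer = NULL) {
  if (is.data.frame(mnb)) {
    layer <- layer %||% mnb$layer
    mnb <- mnb$mnb
  }
  layer <- layer %||% seq_along(mnb)
  if (length(mnb) < 4L) stopf("quadratic fit needs at least 4 layers")
  if (length(layer) != length(mnb)) stopf("layer and mnb lengths differ")
  df <- data.frame(layer = as.numeric(layer), mnb = as.numeric(mnb))
  fit <- lm(mnb ~ layer + I(layer^2), data = df)
  cf <- coef(fit)
  names(cf) <- c("intercept", "linear", "quadratic")
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((df$mnb - mean(df$mnb))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  vertex <- if (abs(cf[["quadratic"]]) > 1e-12) {
    -cf[["linear"]] / (2 * cf[["quadratic"]])
  } else {
    NA_real_
  }
  list(coefficients = cf, r_squared = r2, vertex = vertex, model = fit)
}
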