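test_that("community_matrix validates its inputs", {
  x <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_s3_class(community_matrix(x, 1:2, c("w", "w")), "community_matrix")
  expect_error(community_matrix(unname(x), 1:2, c("w", "w")), "names")
  expect_error(community_matrix(x, 1, "w"), "one entry per sample")
  x2 <- x; x2[1, 1] <- -1
  expect_error(community_matrix(x2, 1:2, c("w", "w")), "non-negative")
})

test_that("merge_seasons pools counts by layer and conserves totals", {
  x <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 2, 4,
              dimnames = list(c("a", "b"), paste0("s", 1:4)))
  m <- community_matrix(x, layer = c(1, 1, 2, 2), season = c("w", "s", "w", "s"))
  mg <- merge_seasons(m)
  expect_equal(ncol(mg$counts), 2L)
  expect_equal(unname(mg$counts[, "L01"]), c(1 + 3, 2 + 4))
  expect_equal(sum(mg$counts), sum(x))
  # single season: merging is the identity on counts
  m1 <- subset_samples(m, m$sample_meta$season == "w")
  expect_equal(unname(merge_seasons(m1)$counts), unname(m1$counts))
  # two seasons with identical counts double the layer total
  m2 <- community_matrix(cbind(w = x[, 1], s = x[, 1]), c(1, 1), c("w", "s"))
  expect_equal(unname(merge_seasons(m2)$counts[, 1]), unname(2 * x[, 1]))
})

test_that("rarefaction subsamples every column to the target depth", {
  set.seed(1)
  x <- matrix(rpois(60, 20), 6, 10,
              dimnames = list(paste0("t", 1:6), paste0("s", 1:10)))
  m <- make_cm(x)
  r <- rarefy(m, depth = 50, seed = 3)
  expect_true(all(colSums(r$counts) == 50))
  # taxon set shrinks or stays within the original
  expect_true(all(r$counts <= m$counts))
  # determinism under seed
  expect_identical(rarefy(m, 50, seed = 3)$counts, r$counts)
  # single-taxon sample is degenerate hypergeometric
  y <- matrix(c(10, 0, 8, 3), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  r2 <- rarefy(make_cm(y), depth = 5, seed = 1)
  expect_equal(unname(r2$counts[, 1]), c(5, 0))
  # samples already at depth are unchanged in total
  expect_error(rarefy(m, depth = 10000), "below rarefaction depth")
})

test_that("alpha diversity matches hand-computed Chao1 and Pielou", {
  # 10 taxa each with count 5: no singletons, perfectly even
  x <- matrix(5L, 10, 1, dimnames = list(paste0("t", 1:10), "s1"))
  a <- alpha_diversity(make_cm(x))
  expect_equal(a$chao1, 10)
  expect_equal(a$pielou, 1)
  # S_obs = 10, F1 = 4, F2 = 2 -> chao1 = 12
  x2 <- matrix(c(1, 1, 1, 1, 2, 2, 5, 6, 7, 8), 10, 1,
               dimnames = list(paste0("t", 1:10), "s1"))
  expect_equal(alpha_diversity(make_cm(x2))$chao1, 10 + 4 * 3 / 6)
  # pielou for (9, 1)
  x3 <- matrix(c(9L, 1L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  h <- -(0.9 * log(0.9) + 0.1 * log(0.1))
  expect_equal(alpha_diversity(make_cm(x3))$pielou, h / log(2))
  # single-taxon sample: evenness undefined
  x4 <- matrix(c(4L, 0L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_true(is.na(alpha_diversity(make_cm(x4))$pielou))
  expect_error(alpha_diversity(make_cm(matrix(c(1.5, 1), 2, 1))), "integer")
})

test_that("alpha diversity agrees with vegan's estimators", {
  set.seed(9)
  x <- matrix(rpois(80, 3), 20, 4,
              dimnames = list(paste0("t", 1:20), paste0("s", 1:4)))
  a <- alpha_diversity(make_cm(x))
  v <- t(vegan::estimateR(t(x)))
  expect_equal(a$chao1, unname(v[, "S.chao1"]))
  expect_equal(a$shannon, unname(vegan::diversity(t(x))))
})

test_that("dissimilarities match hand arithmetic and stay in range", {
  x <- matrix(c(2, 0, 6, 1, 3, 2), 3, 2,
              dimnames = list(paste0("t", 1:3), c("s1", "s2")))
  m <- make_cm(x)
  bc <- dissimilarity(m, "bray_curtis")
  expect_equal(bc["s1", "s2"], 8 / 14)
  # presence sets {t1,t3} vs {t1,t2,t3}
  jc <- dissimilarity(m, "jaccard_binary")
  expect_equal(jc["s1", "s2"], 1 / 3)
  # identical samples at distance zero
  xx <- cbind(x, s3 = x[, 1])
  d2 <- dissimilarity(make_cm(xx), "bray_curtis")
  expect_equal(d2["s1", "s3"], 0)
  # range and symmetry on random data
  set.seed(2)
  y <- matrix(rpois(200, 4), 20, 10,
              dimnames = list(paste0("t", 1:20), paste0("s", 1:10)))
  d <- dissimilarity(make_cm(y), "bray_curtis")
  expect_true(all(d >= 0 & d <= 1))
  expect_true(isSymmetric(d))
  y[, 1] <- 0
  expect_error(dissimilarity(make_cm(y)), "zero total")
})

test_that("PCoA reproduces classical scaling geometry", {
  # equilateral triangle: two equal positive eigenvalues summing to 1
  d <- matrix(1, 3, 3, dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  diag(d) <- 0
  p <- pcoa(d, k = 2)
  expect_equal(p$eigenvalues[1], p$eigenvalues[2])
  expect_equal(sum(p$eigenvalues[1:2]), 1)
  expect_lt(abs(p$eigenvalues[3]), 1e-10)
  # duplicated sample: identical coordinates
  d4 <- as.matrix(dist(c(0, 1, 1, 3)))
  dimnames(d4) <- list(paste0("s", 1:4), paste0("s", 1:4))
  p4 <- pcoa(d4, k = 2)
  expect_equal(p4$coordinates[2, ], p4$coordinates[3, ])
  # Euclidean input reconstructed exactly
  set.seed(4)
  pts <- matrix(rnorm(20), 10, 2)
  de <- as.matrix(dist(pts))
  dimnames(de) <- list(paste0("s", 1:10), paste0("s", 1:10))
  pe <- pcoa(de, k = 2)
  expect_equal(as.matrix(dist(pe$coordinates)), unname(de),
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_error(pcoa(d, k = 3), "k must satisfy")
})

test_that("UPGMA agglomerates by average linkage with halved heights", {
  d <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cl <- upgma(d)
  expect_equal(cl$merge_heights, c(1, 4))
  expect_equal(sort(upgma_cut(cl, 2)[c("A", "B")]), c(A = 1, B = 1))
  # k = n: every sample its own cluster
  expect_equal(length(unique(upgma_cut(cl, 3))), 3L)
  # planted two-block structure recovered at k = 2
  ds <- small_dataset(seed = 3)
  bc <- dissimilarity(merge_seasons(ds$counts), "bray_curtis")
  k2 <- upgma_cut(upgma(bc), 2)
  lay <- as.integer(sub("L", "", names(k2)))
  above <- lay <= ds$config$damming_layer
  expect_true(length(unique(k2[above])) == 1 && length(unique(k2[!above])) == 1 &&
                k2[above][1] != k2[!above][1])
})

test_that("ANOSIM returns R = 1 for perfect separation and valid p-values", {
  # two tight blocks far apart
  set.seed(5)
  pts <- rbind(matrix(rnorm(12, 0, 0.1), 6), matrix(rnorm(12, 10, 0.1), 6))
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:12), paste0("s", 1:12))
  g <- rep(c("a", "b"), each = 6)
  res <- anosim_test(d, g, n_perm = 99, seed = 1)
  expect_equal(res$R, 1)
  expect_gte(res$p_value, 1 / 100)
  expect_error(anosim_test(d, c(rep("a", 11), "b")), "singleton")
  expect_error(anosim_test(d, rep("a", 12)), "two groups")
})

test_that("ANOSIM R is centred at zero under random labels", {
  set.seed(6)
  rs <- replicate(100, {
    d <- as.matrix(dist(matrix(rnorm(24), 12)))
    dimnames(d) <- list(paste0("s", 1:12), paste0("s", 1:12))
    anosim_test(d, sample(rep(c("a", "b"), each = 6)), n_perm = 19,
                seed = sample.int(1e6, 1))$R
  })
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("ANOSIM permutation p-values are uniform under the null", {
  set.seed(7)
  ps <- replicate(200, {
    d <- as.matrix(dist(matrix(rnorm(20), 10)))
    dimnames(d) <- list(paste0("s", 1:10), paste0("s", 1:10))
    anosim_test(d, sample(rep(c("a", "b"), each = 5)), n_perm = 199,
                seed = sample.int(1e6, 1))$p_value
  })
  # p-values are discrete (199 permutations), so ties are expected
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("multiple-timepoint dissimilarity partitions like the formula", {
  # all timepoints identical -> 0
  x <- matrix(rep(c(3, 1, 4), 3), 3, 3,
              dimnames = list(paste0("t", 1:3), paste0("s", 1:3)))
  expect_equal(multi_timepoint_dissimilarity(x)$total, 0)
  # n = 2 reduces exactly to pairwise Bray-Curtis
  set.seed(8)
  for (i in 1:100) {
    y <- matrix(rpois(10, 5), 5, 2,
                dimnames = list(paste0("t", 1:5), c("s1", "s2")))
    if (any(colSums(y) == 0)) next
    mt <- multi_timepoint_dissimilarity(y)$total
    bc <- dissimilarity(make_cm(y), "bray_curtis")["s1", "s2"]
    expect_equal(mt, bc, tolerance = 1e-12)
  }
  # three-site worked example against the straight-from-formula oracle
  z <- matrix(c(5, 0, 0, 5, 5, 5), 2, 3,
              dimnames = list(c("t1", "t2"), paste0("s", 1:3)))
  got <- multi_timepoint_dissimilarity(z)
  oracle <- bf_multisite(z)
  expect_equal(got$total, oracle[["total"]])
  expect_equal(got$balanced, oracle[["balanced"]])
  expect_equal(got$gradient, oracle[["gradient"]])
  # random tables agree with the oracle too
  set.seed(9)
  for (i in 1:20) {
    w <- matrix(rpois(24, 4), 6, 4,
                dimnames = list(paste0("t", 1:6), paste0("s", 1:4)))
    expect_equal(multi_timepoint_dissimilarity(w)$total,
                 bf_multisite(w)[["total"]], tolerance = 1e-12)
  }
  expect_error(multi_timepoint_dissimilarity(x[, 1, drop = FALSE]), "at least 2")
})

test_that("layer fluctuation summarizes each layer's snapshots", {
  ds <- small_dataset(seed = 4)
  fl <- layer_fluctuation(ds$counts)
  expect_equal(fl$layer, 1:6)
  expect_true(all(fl$total >= 0 & fl$total <= 1))
  expect_equal(fl$total, fl$balanced + fl$gradient)
})

test_that("connection degree applies the log10 >= 1 threshold inclusively", {
  x <- rbind(always10 = rep(10, 11), always9 = rep(9, 11),
             mixed = c(0, 9, 10, 1000, rep(0, 7)))
  colnames(x) <- paste0("s", 1:11)
  deg <- connection_degree(make_cm(x))
  expect_equal(unname(deg), c(11, 0, 2))
})
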