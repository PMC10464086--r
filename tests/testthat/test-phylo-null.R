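test_that("MNTD matches hand-computed distances on the three-tip tree", {
  d <- patristic_distances(tiny_tree())
  x <- c(A = 1, B = 1, C = 1)
  expect_equal(mntd(x, d, weighted = FALSE), (2 + 2 + 4) / 3)
  expect_equal(mntd(c(A = 0.5, B = 0.25, C = 0.25), d, weighted = TRUE), 2.5)
  # any two-taxon community: MNTD is their patristic distance
  expect_equal(mntd(c(A = 1, C = 3), d, weighted = FALSE), 4)
  expect_error(mntd(c(A = 1), d), "at least 2")
})

test_that("betaMNTD matches hand values and is symmetric", {
  d <- patristic_distances(tiny_tree())
  expect_equal(beta_mntd(c(A = 2, B = 1, C = 0), c(A = 2, B = 1, C = 0), d), 0)
  expect_equal(beta_mntd(c(A = 1, B = 0, C = 0), c(A = 0, B = 0, C = 1), d), 4)
  set.seed(1)
  x1 <- c(A = 3, B = 0, C = 2); x2 <- c(A = 0, B = 5, C = 1)
  expect_equal(beta_mntd(x1, x2, d), beta_mntd(x2, x1, d))
})

test_that("MNTD and betaMNTD equal brute force on all 5-tip communities", {
  set.seed(10)
  tree <- generate_tree(5, seed = 10)
  d <- patristic_distances(tree)
  taxa <- rownames(d)
  subsets <- unlist(lapply(1:5, function(k) {
    utils::combn(5, k, simplify = FALSE)
  }), recursive = FALSE)
  abund <- setNames(runif(5, 0.5, 3), taxa)
  for (w in c(TRUE, FALSE)) {
    for (s in Filter(function(s) length(s) >= 2, subsets)) {
      x <- numeric(5); names(x) <- taxa; x[s] <- abund[s]
      expect_equal(mntd(x, d, weighted = w), bf_mntd(x, d, w))
    }
    for (s1 in subsets) for (s2 in subsets) {
      x1 <- numeric(5); names(x1) <- taxa; x1[s1] <- abund[s1]
      x2 <- numeric(5); names(x2) <- taxa; x2[s2] <- abund[s2]
      expect_equal(beta_mntd(x1, x2, d, weighted = w), bf_beta_mntd(x1, x2, d, w))
    }
  }
})

test_that("MNTD and betaMNTD agree with picante", {
  skip_if_not_installed("picante")
  set.seed(11)
  tree <- generate_tree(12, seed = 11)
  d <- patristic_distances(tree)
  x1 <- setNames(rpois(12, 2), rownames(d))
  x2 <- setNames(rpois(12, 2), rownames(d))
  x1[1:3] <- 1; x2[10:12] <- 1  # guarantee non-empty
  samp <- rbind(s1 = x1, s2 = x2)
  expect_equal(mntd(x1, d, weighted = TRUE),
               picante::mntd(samp[1, , drop = FALSE], d, abundance.weighted = TRUE))
  expect_equal(beta_mntd(x1, x2, d, weighted = TRUE),
               as.numeric(picante::comdistnt(samp, d, abundance.weighted = TRUE)))
})

test_that("NTI flags degenerate nulls and detects planted clustering", {
  # star-like tree: all tips equidistant, MNTD invariant under shuffles
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  ds <- patristic_distances(star)
  expect_warning(v <- nti(c(A = 1, B = 1, C = 0, D = 0), ds, n_null = 49, seed = 1),
                 "zero variance")
  expect_true(is.na(v))
  # one clade's tips on a two-clade tree are clustered
  tree <- two_clade_tree(8)
  d <- patristic_distances(tree)
  hits <- vapply(1:20, function(s) {
    x <- setNames(numeric(16), rownames(d))
    x[paste0("A", 1:8)] <- 1
    as.numeric(nti(x, d, n_null = 99, seed = s)) > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("NTI is centred near zero for random communities", {
  tree <- generate_tree(40, seed = 12)
  d <- patristic_distances(tree)
  set.seed(12)
  vals <- replicate(200, {
    x <- setNames(numeric(40), rownames(d))
    x[sample(40, 10)] <- rexp(10) + 0.1
    as.numeric(nti(x, d, n_null = 99, seed = sample.int(1e6, 1)))
  })
  expect_lt(abs(mean(vals)), 0.15)
})

test_that("betaNTI is symmetric under a shared seed", {
  tree <- generate_tree(20, seed = 13)
  d <- patristic_distances(tree)
  set.seed(13)
  x1 <- setNames(rpois(20, 1), rownames(d)); x1[1] <- 2
  x2 <- setNames(rpois(20, 1), rownames(d)); x2[20] <- 2
  expect_equal(as.numeric(bnti(x1, x2, d, n_null = 99, seed = 7)),
               as.numeric(bnti(x2, x1, d, n_null = 99, seed = 7)))
})

test_that("betaNTI exceeds +2 across a strong selection step", {
  hits <- vapply(1:10, function(s) {
    ds <- generate_dataset(generator_config(
      n_taxa = 200, n_layers = 4, n_seasons = 2, damming_layer = 2,
      library_size = 2000, seed = s))
    mm <- merge_seasons(ds$counts)
    d <- patristic_distances(ds$tree, rownames(mm$counts))
    as.numeric(bnti(mm$counts[, 2], mm$counts[, 3], d, n_null = 199,
                    seed = s + 100)) > 2
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("Raup-Crick scaling and bounds follow the mid-P formula", {
  expect_equal(sedistrat:::rc_scale(5000, 100, 9999), 2 * (5050 / 9999) - 1)
  expect_equal(sedistrat:::rc_scale(0, 0, 999), -1)
  expect_equal(sedistrat:::rc_scale(999, 0, 999), 1)
  # observed more extreme than every null: RC = 1.  The observed pair is
  # skewed onto opposite taxa while the pool is uniform, so richness- and
  # abundance-preserving null pairs are all far less dissimilar.
  meta <- matrix(10, 8, 10,
                 dimnames = list(paste0("t", 1:8), paste0("s", 1:10)))
  x1 <- c(1000, rep(1, 6), 0)
  x2 <- c(0, rep(1, 6), 1000)
  rc <- raup_crick_bray(x1, x2, meta, n_null = 199, seed = 3)
  expect_equal(as.numeric(rc), 1)
  expect_gt(attr(rc, "bc_obs"), 0.99)
  expect_error(raup_crick_bray(rep(0, 8), x2, meta), "empty")
})

test_that("process partition applies the betaNTI/RC rule table", {
  p <- partition_processes(c(3, 3, 3), c(0, 0.99, -0.99))
  expect_equal(unname(p$fractions["heterogeneous_selection"]), 1)
  p2 <- partition_processes(c(1, 0, -3), c(0.99, 0, 0))
  expect_equal(unname(p2$fractions[c("dispersal_limitation", "drift",
                                     "homogeneous_selection")]),
               rep(1 / 3, 3))
  # fractions always total one
  set.seed(15)
  b <- rnorm(50, 0, 3); r <- runif(50, -1, 1)
  expect_equal(sum(partition_processes(b, r)$fractions), 1)
  expect_error(partition_processes(1:3, 1:2), "same pairs")
  expect_warning(partition_processes(c(NA, 1), c(0, 0)), "undefined")
})

test_that("adjacent-layer profile returns one value per boundary", {
  ds <- small_dataset(seed = 6)
  prof <- adjacent_layer_profile(ds$counts, ds$tree, mode = "merged",
                                 n_null_bnti = 49, n_null_rc = 49, seed = 1)
  expect_equal(nrow(prof), 5L)
  expect_equal(prof$layer_top, 1:5)
  snap <- adjacent_layer_profile(ds$counts, ds$tree, mode = "snapshots",
                                 n_null_bnti = 49, n_null_rc = 49, seed = 1)
  expect_equal(nrow(snap), 10L)
  expect_true(all(table(snap$season) == 5))
})

test_that("taxa missing from the tree raise an error rather than dropping", {
  ds <- small_dataset(seed = 7)
  tree <- ape::drop.tip(ds$tree, "OTU_0001")
  expect_error(patristic_distances(tree, rownames(ds$counts$counts)),
               "OTU_0001")
})
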