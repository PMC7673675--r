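test_that("Ward clustering recovers well-separated groups", {
  set.seed(1)
  g1 <- matrix(c(80, 15, 5), 10, 3, byrow = TRUE) + runif(30, 0, 2)
  g2 <- matrix(c(5, 15, 80), 10, 3, byrow = TRUE) + runif(30, 0, 2)
  pct <- pollen_percentages(rbind(g1, g2))
  colnames(pct) <- c("a", "b", "c")
  cm <- ward_cluster(pct, k = 2)
  expect_equal(canon_partition(cm$cluster),
               canon_partition(rep(1:2, each = 10)))
  # silhouette selection also finds 2
  expect_equal(ward_cluster(pct)$k, 2)
  # k = n gives singletons
  expect_equal(length(unique(ward_cluster(pct, k = 20)$cluster)), 20)
  expect_error(ward_cluster(pct, k = 0), "k must be")
})

test_that("merge partitions match exhaustive Ward search on small data", {
  # Euclidean Ward has a closed-form merge cost; compare every partition
  # level against brute-force minimisation for several random datasets
  for (s in 1:5) {
    set.seed(s)
    n <- sample(4:6, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    pct <- t(apply(abs(X), 1, function(r) 100 * r / sum(r)))
    colnames(pct) <- c("a", "b", "c")
    cm <- ward_cluster(pct, k = 2, dissimilarity = "euclidean")
    oracle <- ward_oracle_partitions(pct)
    for (k in 2:(n - 1))
      expect_equal(cutree_partition(cm$hclust, k), oracle[[k]],
                   info = sprintf("seed %d, k %d", s, k))
  }
})

test_that("phytosociological frequency classes follow the 20% cutoffs", {
  cl <- structure(list(cluster = rep(1:2, each = 10), k = 2), class = "cluster_model")
  pct <- matrix(0, 20, 3, dimnames = list(NULL, c("ubiq", "half", "rare")))
  pct[, "ubiq"] <- 60
  pct[1:10, "half"] <- c(rep(40, 5), rep(0, 5))   # 50% of cluster 1
  pct[11:20, "half"] <- 40
  pct[, "rare"] <- 100 - rowSums(pct)
  ft <- phytosociology(cl, pct)
  g <- function(clu, tax, col)
    ft[ft$cluster == clu & ft$taxon == tax, col]
  expect_equal(g(1, "ubiq", "freq_class"), 5)       # present everywhere
  expect_equal(g(1, "half", "freq_class"), 3)       # exactly half
  expect_equal(g(1, "half", "freq_pct"), 50)
  expect_equal(g(2, "half", "freq_class"), 5)
  # absent taxon: frequency zero, no class
  pct2 <- cbind(pct, gone = 0)
  pct2[, "rare"] <- pct2[, "rare"]   # rows still sum to 100
  ft2 <- phytosociology(cl, pct2)
  expect_equal(ft2[ft2$cluster == 1 & ft2$taxon == "gone", "freq_pct"], 0)
  expect_true(is.na(ft2[ft2$cluster == 1 & ft2$taxon == "gone",
                        "freq_class"]))
  # summary statistics
  expect_equal(g(1, "ubiq", "mean_pct"), 60)
  expect_equal(g(1, "half", "median_pct"), 20)
})

test_that("halophyte screening removes exactly the flagged clusters", {
  pol <- sample_pollen(seq(0, 1, length.out = 30), taxa = 6,
                       halophyte_cluster = TRUE, seed = 4)
  taxa <- attr(pol, "taxon_names")
  pct <- pollen_percentages(as.matrix(pol[taxa]))
  cm <- ward_cluster(pct, k = 3)
  ft <- phytosociology(cm, pct)
  keep <- screen_halophytes(ft, cm, "Halophyte")
  # every generated salt-marsh sample is dropped, no clean sample from a
  # halophyte-free cluster is lost
  expect_true(all(!keep[pol$is_halophyte_truth]))
  halo_free <- setdiff(unique(cm$cluster),
                       unique(cm$cluster[pol$is_halophyte_truth]))
  zero_occurrence <- vapply(halo_free, function(g)
    all(pct[cm$cluster == g, "Halophyte"] == 0), logical(1))
  expect_true(all(keep[cm$cluster %in% halo_free[zero_occurrence]]))
  # monotone in the threshold: stricter classes retain supersets
  k5 <- screen_halophytes(ft, cm, "Halophyte", class_threshold = 5)
  k4 <- screen_halophytes(ft, cm, "Halophyte", class_threshold = 4)
  expect_true(all(k4 <= k5))
  # no halophytes anywhere: identity
  clean <- pct[, setdiff(colnames(pct), "Halophyte")]
  cmc <- ward_cluster(pollen_percentages(clean), k = 2)
  ftc <- phytosociology(cmc, pollen_percentages(clean))
  expect_true(all(screen_halophytes(ftc, cmc, "Halophyte")))
  expect_error(screen_halophytes(ft, cm, character(0)), "nonempty")
  expect_error(screen_halophytes(ft, cm, "Halophyte", 7), "1..5")
})

test_that("nMDS axis 1 recovers a compositional gradient", {
  grad <- seq(0, 1, length.out = 25)
  pol <- sample_pollen(grad, taxa = 2, counts_per_sample = 2000, seed = 6)
  pct <- pollen_percentages(as.matrix(pol[attr(pol, "taxon_names")]))
  ord <- suppressWarnings(nmds(pct, dims = 1, restarts = 10, seed = 2))
  rho <- abs(cor(ord$points[, 1], grad, method = "spearman"))
  expect_gt(rho, 0.99)
  # duplicated samples land on (nearly) the same point
  pct2 <- rbind(pct, pct[3, ])
  ord2 <- suppressWarnings(nmds(pct2, dims = 2, restarts = 10, seed = 3))
  expect_lt(sqrt(sum((ord2$points[26, ] - ord2$points[3, ])^2)),
            1e-3 * max(dist(ord2$points)))
  # stress never increases with added dimensions
  s2 <- suppressWarnings(nmds(pct, dims = 2, restarts = 10, seed = 4))$stress
  s3 <- suppressWarnings(nmds(pct, dims = 3, restarts = 10, seed = 4))$stress
  expect_lte(s3, s2 + 1e-8)
  expect_error(nmds(pct[c(1, 1, 1, 1), ]), "identical")
})

test_that("the vegetation trend smooths toward the underlying signal", {
  # noise-free line is reproduced with vanishing uncertainty
  ages <- seq(1000, 9000, length.out = 40)
  line <- 0.002 * ages - 3
  tr <- veg_index_trend(ages, line, grid = ages)
  expect_equal(tr$trend, line, tolerance = 1e-6)
  expect_lt(max(tr$se), 1e-6)
  # known smooth signal plus noise: the smoother beats the raw data
  set.seed(8)
  truth <- sin(ages / 1500)
  noisy <- truth + rnorm(40, 0, 0.3)
  fit <- veg_index_trend(ages, noisy, grid = ages)
  expect_lt(sqrt(mean((fit$trend - truth)^2)),
            sqrt(mean((noisy - truth)^2)))
  # permutation invariance
  p <- sample(40)
  fit2 <- veg_index_trend(ages[p], noisy[p], grid = ages)
  expect_equal(fit2$trend, fit$trend, tolerance = 1e-10)
  expect_error(veg_index_trend(ages[1:5], noisy[1:5]), "at least 8")
})
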