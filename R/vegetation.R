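#' Convert pollen counts to land-taxon percentages
#'
#' @param counts matrix/data.frame of counts, samples in rows, taxa in
#'   named columns.
#' @return matrix of percentages; rows sum to 100.
#' @export
pollen_percentages <- function(counts) {
  m <- as.matrix(counts)
  tot <- rowSums(m)
  if (any(tot == 0)) stop("sample with zero total count")
  sweep(m, 1, tot, "/") * 100
}

#' Ward clustering of pollen assemblages
#'
#' Agglomerative clustering with Ward's minimum-variance criterion
#' (Lance-Williams update, `hclust` method `ward.D2`) on Bray-Curtis
#' dissimilarities of the percentage matrix (Euclidean available as an
#' alternative).  When `k` is NULL the cut level is chosen by maximizing
#' the mean silhouette width over `k = 2..8`.
#'
#' @param percent matrix of percentages (rows sum to 100) or counts
#'   (converted via [pollen_percentages()] when rows do not sum to 100).
#' @param k number of clusters, or NULL for silhouette selection.
#' @param dissimilarity `"bray"` (default) or `"euclidean"`.
#' @return object of class `cluster_model`: `cluster` (per-sample id),
#'   `k`, `hclust` (the merge tree), `silhouette` (mean width at the
#'   chosen k, when selected), `dissimilarity`.
#' @export
ward_cluster <- function(percent, k = NULL, dissimilarity = c("bray",
                                                              "euclidean")) {
  dissimilarity <- match.arg(dissimilarity)
  m <- as.matrix(percent)
  if (max(abs(rowSums(m) - 100)) > 1e-6) m <- pollen_percentages(m)
  n <- nrow(m)
  if (!is.null(k) && (k < 1 || k > n)) stop("k must be in 1..n")
  d <- if (dissimilarity == "bray") vegan::vegdist(m, "bray") else dist(m)
  hc <- hclust(d, method = "ward.D2")
  sil <- NA_real_
  if (is.null(k)) {
    ks <- 2:min(8, n - 1)
    msil <- vapply(ks, function(kk)
      mean_silhouette(cutree(hc, kk), as.matrix(d)), numeric(1))
    k <- ks[which.max(msil)]
    sil <- max(msil)
  }
  structure(list(cluster = cutree(hc, k), k = k, hclust = hc,
                 silhouette = sil, dissimilarity = dissimilarity),
            class = "cluster_model")
}

# mean silhouette width from a cluster labelling and a distance matrix
mean_silhouette <- function(cl, dm) {
  n <- length(cl)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cl == cl[i]
    a <- if (sum(own) > 1) mean(dm[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(g) mean(dm[i, cl == g]), numeric(1)))
    s[i] <- if (sum(own) > 1) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("Ward clustering (%s dissimilarity): %d samples, k = %d\n",
              x$dissimilarity, length(x$cluster), x$k))
  print(table(cluster = x$cluster))
  invisible(x)
}

#' Phytosociological frequency table
#'
#' For every cluster-taxon pair: the occurrence frequency (share of the
#' cluster's samples containing the taxon, as a percent), its frequency
#' class on even 20% cutoffs — class 5 covering (80, 100], i.e. taxa
#' present in 81-100% of samples — and the mean, median and interquartile
#' range of the taxon's percentage.  Absent taxa get frequency 0 and no
#' class.
#'
#' @param model a [ward_cluster()] result.
#' @param percent the percentage matrix the model was built from.
#' @return data.frame of class `frequency_table`: `cluster`, `taxon`,
#'   `n_samples`, `freq_pct`, `freq_class` (1-5 or NA), `mean_pct`,
#'   `median_pct`, `iqr_pct`.
#' @export
phytosociology <- function(model, percent) {
  m <- as.matrix(percent)
  if (max(abs(rowSums(m) - 100)) > 1e-6) m <- pollen_percentages(m)
  cl <- model$cluster
  if (nrow(m) != length(cl)) stop("matrix rows and cluster labels differ")
  rows <- list()
  for (g in sort(unique(cl))) {
    sub <- m[cl == g, , drop = FALSE]
    ns <- nrow(sub)
    freq <- 100 * colSums(sub > 0) / ns
    rows[[as.character(g)]] <- data.frame(
      cluster = g, taxon = colnames(m), n_samples = ns,
      freq_pct = unname(freq),
      freq_class = ifelse(freq == 0, NA_integer_,
                          pmin(5L, as.integer(ceiling(freq / 20)))),
      mean_pct = unname(colMeans(sub)),
      median_pct = unname(apply(sub, 2, median)),
      iqr_pct = unname(apply(sub, 2, function(v)
        diff(quantile(v, c(0.25, 0.75))))),
      stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, c(rows, make.row.names = FALSE)),
            class = c("frequency_table", "data.frame"))
}

#' Screen halophyte-dominated clusters
#'
#' Removes every sample belonging to a cluster in which any listed
#' halophyte taxon reaches frequency class `class_threshold` or above —
#' the rule for excluding salt-marsh-driven assemblages from a land-cover
#' index.
#'
#' @param table a [phytosociology()] frequency table.
#' @param model the matching [ward_cluster()] model.
#' @param halophyte_taxa character vector of halophyte taxon names
#'   (nonempty).
#' @param class_threshold frequency class (1-5) at or above which a
#'   cluster is screened (default 4, i.e. halophytes in > 60% of the
#'   cluster's samples).
#' @return logical vector over samples: TRUE = retained.
#' @export
screen_halophytes <- function(table, model, halophyte_taxa,
                              class_threshold = 4) {
  if (length(halophyte_taxa) == 0) stop("halophyte_taxa must be nonempty")
  if (class_threshold < 1 || class_threshold > 5)
    stop("class_threshold must be in 1..5")
  tb <- as.data.frame(table)
  bad <- unique(tb$cluster[tb$taxon %in% halophyte_taxa &
                             !is.na(tb$freq_class) &
                             tb$freq_class >= class_threshold])
  !(model$cluster %in% bad)
}

#' Nonmetric multidimensional scaling of assemblages
#'
#' Kruskal stress-1 minimization over Bray-Curtis dissimilarities via
#' [vegan::metaMDS()] (no autotransform), best of `restarts` random
#' starts, reproducible for a fixed seed.
#'
#' @param percent percentage (or count) matrix, samples in rows.
#' @param dims ordination dimensions (default 2).
#' @param dissimilarity vegdist method (default `"bray"`).
#' @param restarts random starts (default 20).
#' @param seed integer seed.
#' @return object of class `ordination_result`: `points` (samples x
#'   dims), `stress` (fraction, 0-1), `converged`.
#' @export
nmds <- function(percent, dims = 2, dissimilarity = "bray", restarts = 20,
                 seed = 1) {
  m <- as.matrix(percent)
  if (nrow(m) < dims + 2) stop("need at least dims + 2 samples")
  d <- vegan::vegdist(m, dissimilarity)
  if (max(d) == 0) stop("all samples identical: zero dissimilarity matrix")
  fit <- with_substream(seed, "nmds",
    vegan::metaMDS(m, k = dims, distance = dissimilarity,
                   trymax = restarts, trace = 0, autotransform = FALSE,
                   wascores = FALSE))
  structure(list(points = vegan::scores(fit, display = "sites"),
                 stress = fit$stress, converged = fit$converged > 0,
                 dims = dims, engine = fit),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("nMDS: %d samples on %d axes, stress %.4f (%sconverged)\n",
              nrow(x$points), x$dims, x$stress,
              if (x$converged) "" else "not "))
  invisible(x)
}

#' Smooth vegetation-index trend through time
#'
#' Penalized cubic regression spline (roughness penalty by generalized
#' cross-validation) of ordination axis-1 scores against sample age,
#' evaluated with pointwise standard errors on a regular age grid.
#'
#' @param ages_bp sample ages, yr BP (>= 8 samples, not all equal).
#' @param scores axis-1 scores, same length.
#' @param grid output ages; default 100 points over the data span.
#' @param k spline basis dimension (default `min(10, n - 1)`).
#' @return data.frame `age_bp`, `trend`, `se`; attribute `gam` holds the
#'   fitted model.
#' @export
veg_index_trend <- function(ages_bp, scores, grid = NULL, k = NULL) {
  ok <- is.finite(ages_bp) & is.finite(scores)
  ages_bp <- ages_bp[ok]; scores <- scores[ok]
  n <- length(ages_bp)
  if (n < 8) stop("need at least 8 samples")
  if (length(unique(ages_bp)) < 4) stop("too few distinct ages")
  if (is.null(k)) k <- min(10L, length(unique(ages_bp)) - 1L)
  if (is.null(grid)) grid <- seq(min(ages_bp), max(ages_bp),
                                 length.out = 100)
  df <- data.frame(age = ages_bp, y = scores)
  fit <- mgcv::gam(y ~ s(age, bs = "cr", k = k), data = df,
                   method = "GCV.Cp")
  pr <- predict(fit, newdata = data.frame(age = grid), se.fit = TRUE)
  structure(data.frame(age_bp = grid, trend = as.numeric(pr$fit),
                       se = as.numeric(pr$se.fit)),
            gam = fit, class = c("veg_trend", "data.frame"))
}
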