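# shared fixtures, all generated in code

# linear sea-level history rising at `rate` mm/yr toward the present
linear_truth <- function(rate = 2, span = c(0, 10)) {
  synthetic_truth(data.frame(age_ka = span, rate_mm_yr = c(rate, rate)))
}

# two-phase history: fast early rise slowing at `t_break`
two_phase_truth <- function(fast = 3, slow = 0.8, t_break = 4.5) {
  synthetic_truth(data.frame(age_ka = c(0, t_break - 0.5, t_break + 0.5, 10),
                             rate_mm_yr = c(slow, slow, fast, fast)))
}

# tiny two-endmember foram training set: taxon A only at 1.0 m, B at 2.0 m
endmember_training <- function(reps = 5, count = 100) {
  cnt <- rbind(matrix(rep(c(count, 0), reps), reps, 2, byrow = TRUE),
               matrix(rep(c(0, count), reps), reps, 2, byrow = TRUE))
  colnames(cnt) <- c("A", "B")
  list(counts = cnt, elevation = rep(c(1, 2), each = reps))
}

# canonical form of a partition, for label-free comparison
canon_partition <- function(cl) {
  split(seq_along(cl), cl) |> lapply(sort) |>
    (\(x) x[order(vapply(x, min, 1L))])() |> unname()
}

# independent exhaustive Ward agglomeration on Euclidean data: at each
# step merge the pair with minimum within-cluster SSE increase
ward_oracle_partitions <- function(X) {
  X <- as.matrix(X)
  clusters <- as.list(seq_len(nrow(X)))
  out <- list()
  out[[length(clusters)]] <- lapply(clusters, identity)
  while (length(clusters) > 1) {
    best <- NULL; best_inc <- Inf
    for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      A <- clusters[[i]]; B <- clusters[[j]]
      mA <- colMeans(X[A, , drop = FALSE]); mB <- colMeans(X[B, , drop = FALSE])
      inc <- length(A) * length(B) / (length(A) + length(B)) *
        sum((mA - mB)^2)
      if (inc < best_inc) { best_inc <- inc; best <- c(i, j) }
    }
    clusters[[best[1]]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[2]]] <- NULL
    out[[length(clusters)]] <- lapply(clusters, identity)
  }
  out   # out[[k]] = list of index sets at k clusters
}

# partition from a cluster id vector, canonical
cutree_partition <- function(hc, k) canon_partition(stats::cutree(hc, k))
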