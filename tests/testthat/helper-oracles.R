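# Shared fixtures and independent oracles used across the suite.

tiny_atlas <- function(n = 8, subnets = c("A", "B")) {
  generate_atlas(n, subnets)
}

rand_ts <- function(T, atlas, seed = 1, tr = 2) {
  set.seed(seed)
  subject_timeseries(matrix(rnorm(T * nrow(atlas)), T), tr,
                     atlas$roi_id, sprintf("seed%d", seed))
}

# enumerate all set partitions of n elements (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(a, i, m) {
    if (i > n) {
      out[[length(out) + 1L]] <<- a
      return(invisible())
    }
    for (v in seq_len(m + 1L)) {
      a[i] <- v
      rec(a, i + 1L, max(m, v))
    }
  }
  rec(integer(n), 1L, 0L)
  out
}

# direct double-sum modularity (independent of the package's optimiser
# internals): Q = (1/2m) * sum_{ij in same community} (A_ij - k_i k_j / 2m)
oracle_modularity <- function(A, membership) {
  m2 <- sum(A)
  k <- rowSums(A)
  same <- outer(membership, membership, "==")
  (sum(A[same]) - sum(outer(k, k)[same]) / m2) / m2
}

# exhaustive modularity maximisation over all partitions
oracle_best_partition <- function(A) {
  parts <- all_partitions(nrow(A))
  qs <- vapply(parts, function(p) oracle_modularity(A, p), 0)
  best <- which.max(qs)
  list(q = qs[best], membership = parts[[best]])
}

# streaming (Welford) mean and sample SD, an independent oracle for
# MLI/LF
oracle_stream_stats <- function(x) {
  m <- 0; s <- 0; n <- 0
  for (v in x) {
    n <- n + 1
    d <- v - m
    m <- m + d / n
    s <- s + d * (v - m)
  }
  c(mean = m, sd = if (n > 1) sqrt(s / (n - 1)) else NA_real_)
}

# random symmetric non-negative weighted graph on n nodes
rand_graph <- function(n, seed, p_edge = 0.7) {
  set.seed(seed)
  A <- matrix(0, n, n)
  ut <- upper.tri(A)
  A[ut] <- runif(sum(ut)) * rbinom(sum(ut), 1, p_edge)
  A + t(A)
}

# a small synthetic cohort analysed to metric level, reused by several
# statistical tests (kept small for speed)
small_cohort_metrics <- function(seed, n_per_group = 8, n_timepoints = 90,
                                 window = 40, group_effect = 0.05) {
  spec <- simulation_spec(n_timepoints = n_timepoints, n_discard = 0,
                          group_effect = group_effect, seed = 1)
  coh <- simulate_cohort(spec, n_per_group, seed = seed)
  ws <- window_spec(window, 1)
  lat <- lapply(coh$subjects, function(s) {
    laterality_series(s$ts, ws, coh$atlas)
  })
  list(cohort = coh, lat = lat,
       metrics = build_metric_table(lat, coh$atlas, coh$group,
                                    levels = c("subnetwork", "hemisphere")))
}
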