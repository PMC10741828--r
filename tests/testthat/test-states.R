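test_that("spherical k-means recovers planted orthogonal groups", {
  set.seed(2)
  d1 <- c(1, 0, 0, 0); d2 <- c(0, 0, 1, 0)
  x <- rbind(t(sapply(1:20, function(i) d1 * runif(1, 0.5, 2))),
             t(sapply(1:20, function(i) d2 * runif(1, 0.5, 2))))
  x <- x + matrix(rnorm(80, sd = 0.01), 40, 4)
  fit <- spherical_kmeans(x, 2, seed = 1)
  # brute-force assignment check: the two planted groups separate exactly
  expect_length(unique(fit$cluster[1:20]), 1L)
  expect_length(unique(fit$cluster[21:40]), 1L)
  expect_false(fit$cluster[1] == fit$cluster[21])

  # positive rescalings of one direction collapse to it with zero inertia
  y <- t(sapply(1:10, function(i) runif(1, 0.1, 5) * c(1, 2, 2, 0)))
  fit1 <- spherical_kmeans(y, 3, seed = 2)
  expect_lt(fit1$inertia, 1e-12)

  # determinism and contract errors
  expect_identical(spherical_kmeans(x, 3, seed = 9),
                   spherical_kmeans(x, 3, seed = 9))
  expect_error(spherical_kmeans(x, 41, seed = 1), "exceeds")
  expect_error(spherical_kmeans(rbind(x, 0), 2, seed = 1), "zero-norm")
})

test_that("centroid pooling concatenates with provenance", {
  mats <- lapply(1:3, function(s) matrix(rnorm(10), 2, 5))
  pooled <- pool_centroids(mats)
  expect_equal(dim(pooled), c(6L, 5L))
  expect_equal(rownames(pooled)[3], "s2:1")
  expect_equal(pool_centroids(mats[1]), mats[[1]], ignore_attr = TRUE)
  expect_error(pool_centroids(list()), "no centroid")
  expect_error(pool_centroids(list(mats[[1]], matrix(0, 2, 4))),
               "differ in column count")
})

test_that("centroid similarity graph clips negative cosines", {
  pooled <- rbind(c(1, 0), c(2, 0), c(0, 3), c(-1, 0))
  g <- centroid_similarity_graph(pooled)
  A <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  expect_equal(A[1, 2], 1)            # identical direction
  expect_equal(A[1, 3], 0)            # orthogonal
  expect_equal(A[1, 4], 0)            # antipodal, clipped
  gs <- centroid_similarity_graph(pooled, negative_weights = "shift")
  As <- igraph::as_adjacency_matrix(gs, attr = "weight", sparse = FALSE)
  expect_equal(As[1, 4], 0, tolerance = 1e-12)
  expect_equal(As[1, 3], 0.5)
  expect_error(centroid_similarity_graph(rbind(c(1, 0), c(0, 0))),
               "zero-norm")
})

test_that("multi-resolution sweep matches exhaustive modularity search", {
  # two disconnected unit triangles: 2 communities at every resolution
  A <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(2, 3), c(1, 3))) {
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1
    A[e[1] + 3, e[2] + 3] <- A[e[2] + 3, e[1] + 3] <- 1
  }
  sw <- afg_sweep(A, seed = 1)
  expect_equal(sw$resolutions$n_communities, rep(2L, 15))
  for (j in seq_len(15)) {
    Ar <- A; diag(Ar) <- sw$resolutions$r[j]
    expect_equal(sw$resolutions$modularity[j], oracle_best_partition(Ar)$q,
                 tolerance = 1e-12)
  }

  # single edge: optimum matches exhaustive search at every r (the
  # optimal count is 1 below r = 1 and 2 above; at r = 1 both tie)
  A2 <- matrix(c(0, 1, 1, 0), 2, 2)
  sw2 <- afg_sweep(A2, seed = 1)
  for (j in seq_len(15)) {
    Ar <- A2; diag(Ar) <- sw2$resolutions$r[j]
    expect_equal(sw2$resolutions$modularity[j],
                 oracle_best_partition(Ar)$q, tolerance = 1e-12)
  }
  expect_equal(sw2$resolutions$n_communities,
               c(rep(1L, 9), rep(2L, 6)))

  # random weighted graphs: optimiser attains the exhaustive optimum,
  # and always beats the trivial partitions
  for (trial in 1:8) {
    n <- 3 + (trial %% 5)
    A3 <- rand_graph(n, seed = 100 + trial)
    for (r in c(0.1, 0.8, 1.5)) {
      Ar <- A3; diag(Ar) <- r
      fit <- dynlat:::maximize_modularity(Ar, seed = trial)
      expect_equal(fit$modularity, oracle_best_partition(Ar)$q,
                   tolerance = 1e-10)
      expect_gte(fit$modularity,
                 oracle_modularity(Ar, seq_len(n)) - 1e-12)
      expect_gte(fit$modularity,
                 oracle_modularity(Ar, rep(1L, n)) - 1e-12)
    }
  }
  expect_error(afg_sweep(matrix(0, 0, 0)), "empty|no weight")
})

test_that("persistence rule picks the longest run, ties toward smaller k", {
  fake <- function(counts) {
    runs <- rle(counts)
    structure(list(persistence = stats::aggregate(
      list(run = runs$lengths),
      by = list(n_communities = runs$values), max)), class = "afg_sweep")
  }
  expect_equal(select_persistent_k(fake(c(2, 2, 2, 2, 3, 3))), 2L)
  expect_equal(select_persistent_k(fake(c(2, 2, 3, 3))), 2L)
  expect_equal(select_persistent_k(fake(c(4, 3, 3, 3, 2))), 3L)
})

test_that("final centroids recover tight bundles and saturate at k = M", {
  set.seed(6)
  dirs <- diag(3)[, 1:3]
  pooled <- do.call(rbind, lapply(1:3, function(s) {
    t(sapply(1:15, function(i) dirs[s, ] + rnorm(3, sd = 0.03)))
  }))
  cent <- final_centroids(pooled, 3, seed = 4)
  sims <- apply(tcrossprod(cent, dirs), 1L, max)
  expect_true(all(sims >= 0.99))
  # k = M returns the normalised inputs
  m5 <- pooled[1:5, ]
  c5 <- final_centroids(m5, 5, seed = 1)
  norm5 <- m5 / sqrt(rowSums(m5^2))
  reorder <- apply(tcrossprod(c5, norm5), 1L, which.max)
  expect_equal(c5, norm5[reorder, ], tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(final_centroids(pooled, 3, seed = 4),
                   final_centroids(pooled, 3, seed = 4))
})

test_that("window assignment is the brute-force nearest centroid", {
  at <- tiny_atlas(6, "S")
  ls_list <- lapply(1:2, function(s) {
    laterality_series(rand_ts(40, at, seed = 50 + s),
                      window_spec(15, 1), at)
  })
  set.seed(3)
  cent <- matrix(rnorm(18), 3, 6)
  out <- assign_windows(ls_list, cent)
  cn <- cent / sqrt(rowSums(cent^2))
  for (s in 1:2) {
    xn <- ls_list[[s]]$values /
      sqrt(rowSums(ls_list[[s]]$values^2))
    ref <- apply(xn %*% t(cn), 1L, which.max)
    expect_equal(out$assignments[[s]], ref)
  }
  expect_equal(sum(out$occupancy), 1)
  # a window equal to a centroid is assigned to it
  ls_list[[1]]$values[4, ] <- 2 * cent[2, ]
  out2 <- assign_windows(ls_list, cent)
  expect_equal(out2$assignments[[1]][4], 2L)
})

test_that("subject order permutation only permutes provenance", {
  spec <- simulation_spec(n_timepoints = 110, n_discard = 0,
                          group_effect = 0, seed = 4)
  coh <- simulate_cohort(spec, 4, seed = 4)
  ls_list <- lapply(coh$subjects, function(s) {
    laterality_series(s$ts, window_spec(50, 1), coh$atlas)
  })
  m1 <- fit_laterality_states(ls_list, k1 = 3, seed = 2)
  perm <- c(5, 2, 8, 1, 6, 3, 7, 4)
  m2 <- fit_laterality_states(ls_list[perm], k1 = 3, seed = 2)
  expect_equal(m2$k, m1$k)
  # same states up to label permutation; compare via pooled accuracy
  match <- match_state_labels(unlist(m2$assignments),
                              unlist(m1$assignments[perm]), m1$k)
  expect_gte(match$accuracy, 0.99)
})
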