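#' Spherical k-means (cosine distance)
#'
#' k-means on the unit hypersphere: rows and centroids are L2-normalised
#' and the distance is `1 - cosine similarity`. Cosine distance suits the
#' high-dimensional laterality windows, whose informative content is the
#' direction of the whole-brain DLI pattern rather than its magnitude.
#' Initialisation is k-means++ (seeded); empty clusters are re-seeded
#' from the point farthest from its centroid.
#'
#' @param x numeric M-by-N matrix of observations (rows).
#' @param k number of clusters (`k <= M`).
#' @param seed integer seed; the whole fit is deterministic given it.
#' @param n_start number of seeded restarts; the best inertia wins.
#' @param max_iter,tol iteration cap and relative-inertia tolerance.
#' @return List with `centroids` (k-by-N, unit rows), `cluster`
#'   (length-M assignment), and `inertia` (sum of cosine distances).
#' @export
spherical_kmeans <- function(x, k, seed = 1L, n_start = 1L,
                             max_iter = 500L, tol = 1e-6) {
  x <- as.matrix(x)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(x)) {
    stop("k (", k, ") exceeds the number of observations (", nrow(x), ")")
  }
  xn <- row_l2_normalize(x, "observation")
  best <- NULL
  for (s in seq_len(n_start)) {
    fit <- with_seed(derive_seed(seed, s), skm_once(xn, k, max_iter, tol))
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  best
}

skm_once <- function(xn, k, max_iter, tol) {
  m <- nrow(xn)
  # k-means++ on cosine distance
  centers <- integer(k)
  centers[1L] <- sample.int(m, 1L)
  d <- pmax(0, 1 - drop(xn %*% xn[centers[1L], ]))
  if (k > 1L) {
    for (j in 2L:k) {
      p <- d^2
      centers[j] <- if (sum(p) <= 0) sample.int(m, 1L) else
        sample.int(m, 1L, prob = p)
      d <- pmin(d, pmax(0, 1 - drop(xn %*% xn[centers[j], ])))
    }
  }
  cent <- xn[centers, , drop = FALSE]
  inertia <- Inf
  for (it in seq_len(max_iter)) {
    sim <- tcrossprod(xn, cent)                 # M x k cosine similarity
    assign <- max.col(sim, ties.method = "first")
    for (j in seq_len(k)) {                     # re-seed empty clusters
      if (!any(assign == j)) {
        far <- which.min(sim[cbind(seq_len(m), assign)])
        assign[far] <- j
        sim[far, ] <- 0; sim[far, j] <- 1
      }
    }
    new_inertia <- sum(1 - sim[cbind(seq_len(m), assign)])
    cent <- matrix(0, k, ncol(xn))
    for (j in seq_len(k)) {
      cs <- colSums(xn[assign == j, , drop = FALSE])
      nrm <- sqrt(sum(cs^2))
      cent[j, ] <- if (nrm > 0) cs / nrm else xn[sample.int(m, 1L), ]
    }
    if (is.finite(inertia) &&
        abs(inertia - new_inertia) <= tol * max(inertia, .Machine$double.eps)) {
      inertia <- new_inertia
      break
    }
    inertia <- new_inertia
  }
  sim <- tcrossprod(xn, cent)
  assign <- max.col(sim, ties.method = "first")
  list(centroids = cent, cluster = assign,
       inertia = sum(1 - sim[cbind(seq_len(nrow(xn)), assign)]))
}

#' Stage 1: cluster one subject's laterality windows
#'
#' Per-subject spherical k-means with a small over-clustering `k1`
#' (default 5) that preserves subject-level pattern diversity before the
#' centroids of all subjects are pooled.
#'
#' @param ls a `laterality_series`.
#' @param k1 number of per-subject clusters.
#' @param seed integer seed.
#' @return k1-by-N matrix of unit-norm centroids.
#' @export
subject_kmeans <- function(ls, k1 = 5L, seed = 1L) {
  if (k1 > nrow(ls$values)) {
    stop("k1 (", k1, ") exceeds the number of windows (",
         nrow(ls$values), ")")
  }
  spherical_kmeans(ls$values, k1, seed = seed)$centroids
}

#' Stage 2a: pool per-subject centroids
#'
#' Row-concatenates the per-subject centroid matrices, retaining
#' provenance (subject index and local centroid index) in the row names.
#'
#' @param per_subject list of centroid matrices with a common column count.
#' @return M-by-N matrix of pooled centroids.
#' @export
pool_centroids <- function(per_subject) {
  if (length(per_subject) == 0L) stop("no centroid matrices to pool")
  nc <- vapply(per_subject, ncol, integer(1))
  if (length(unique(nc)) != 1L) {
    stop("centroid matrices differ in column count")
  }
  out <- do.call(rbind, per_subject)
  labs <- unlist(lapply(seq_along(per_subject), function(s) {
    sprintf("s%d:%d", s, seq_len(nrow(per_subject[[s]])))
  }))
  rownames(out) <- labs
  out
}

#' Stage 2b: cosine-similarity graph over pooled centroids
#'
#' Nodes are pooled centroids; the edge weight between two centroids is
#' their cosine similarity, with negative similarities clipped to zero
#' (modularity assumes non-negative weights) or, alternatively, shifted
#' into `[0, 1]`. No self-loops at this stage; the multi-resolution sweep
#' adds them.
#'
#' @param pooled M-by-N matrix of centroids (M >= 2).
#' @param negative_weights `"clip"` (default) or `"shift"`.
#' @return An undirected weighted `igraph` graph on M nodes.
#' @export
centroid_similarity_graph <- function(pooled,
                                      negative_weights = c("clip", "shift")) {
  negative_weights <- match.arg(negative_weights)
  if (nrow(pooled) < 2L) stop("need at least 2 centroids")
  cn <- row_l2_normalize(as.matrix(pooled), "centroid")
  s <- tcrossprod(cn)
  w <- if (negative_weights == "clip") pmax(s, 0) else (s + 1) / 2
  diag(w) <- 0
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

graph_adjacency <- function(graph) {
  if (igraph::is_igraph(graph)) {
    a <- igraph::as_adjacency_matrix(graph, attr = "weight", sparse = FALSE)
  } else {
    a <- as.matrix(graph)
    if (nrow(a) != ncol(a) || any(a != t(a))) {
      stop("adjacency must be a symmetric square matrix")
    }
  }
  if (any(a < 0)) stop("modularity requires non-negative weights")
  a
}

# Newman-Girvan modularity of a partition; A includes self-loops on the
# diagonal (counted once; total weight 2m = sum(A))
modularity_q <- function(A, membership) {
  m2 <- sum(A)
  if (m2 <= 0) stop("graph has no weight")
  k <- rowSums(A)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    q <- q + sum(A[idx, idx]) - sum(k[idx])^2 / m2
  }
  q / m2
}

# one Louvain run: local moves in the given node order, then aggregation,
# repeated until modularity stops improving
louvain_once <- function(A, node_order) {
  n0 <- nrow(A)
  mem_global <- seq_len(n0)
  A_cur <- A
  order_cur <- node_order
  repeat {
    n <- nrow(A_cur)
    mem <- seq_len(n)
    k <- rowSums(A_cur)
    m2 <- sum(A_cur)
    tot <- k
    improved <- FALSE
    repeat {
      moved <- FALSE
      for (i in order_cur) {
        ci <- mem[i]
        w <- A_cur[i, ]; w[i] <- 0
        wc <- rowsum(w, mem)                    # per-community link weight
        comms <- as.integer(rownames(wc))
        tot_i <- tot[comms]
        self_c <- match(ci, comms)
        tot_i[self_c] <- tot_i[self_c] - k[i]
        gain <- wc[, 1L] - k[i] * tot_i / m2

        best <- max(gain)
        cand <- comms[gain >= best - 1e-12]
        target <- if (ci %in% cand) ci else min(cand)
        if (target != ci) {
          tot[ci] <- tot[ci] - k[i]
          tot[target] <- tot[target] + k[i]
          mem[i] <- target
          moved <- TRUE; improved <- TRUE
        }
      }
      if (!moved) break
    }
    if (!improved) break
    # relabel 1..C and aggregate
    mem <- match(mem, sort(unique(mem)))
    mem_global <- mem[mem_global]
    A_new <- rowsum(t(rowsum(A_cur, mem)), mem)
    if (nrow(A_new) == nrow(A_cur)) break
    A_cur <- A_new
    tot <- NULL
    order_cur <- seq_len(nrow(A_cur))
  }
  mem_global
}

# modularity maximisation: deterministic ascending-order pass plus seeded
# random-order restarts; best modularity wins (deterministic given seed)
maximize_modularity <- function(A, seed = 1L, n_restarts = 4L) {
  n <- nrow(A)
  orders <- c(list(seq_len(n)),
              lapply(seq_len(n_restarts), function(s) {
                with_seed(derive_seed(seed, s), sample.int(n))
              }))
  best_mem <- NULL; best_q <- -Inf
  for (ord in orders) {
    mem <- louvain_once(A, ord)
    q <- modularity_q(A, mem)
    if (q > best_q + 1e-12) { best_q <- q; best_mem <- mem }
  }
  list(membership = match(best_mem, sort(unique(best_mem))),
       modularity = best_q)
}

#' Multi-resolution community-detection sweep
#'
#' For each resolution `r` on the grid, a uniform self-loop of weight `r`
#' is added to every node of the centroid graph and the weighted
#' Newman-Girvan modularity of the augmented graph is maximised by a
#' Louvain-style greedy optimiser (deterministic ascending node order
#' plus seeded random-order restarts). Sweeping `r` from small to large
#' shifts the optimum from coarse to fine partitions; the community
#' count that persists over the longest consecutive stretch of
#' resolutions is the stable one.
#'
#' @param graph an undirected weighted `igraph` graph (or a symmetric
#'   non-negative adjacency matrix).
#' @param r_min,r_max,r_step resolution grid (defaults 0.1 to 1.5 in
#'   steps of 0.1).
#' @param seed integer seed for optimiser restarts.
#' @return An `afg_sweep` object: data frame `resolutions` (columns `r`,
#'   `n_communities`, `modularity`), list `partitions`, and the
#'   `persistence` table (community count, longest consecutive run).
#' @export
afg_sweep <- function(graph, r_min = 0.1, r_max = 1.5, r_step = 0.1,
                      seed = 1L) {
  A0 <- graph_adjacency(graph)
  if (nrow(A0) < 1L) stop("empty graph")
  if (!(r_step > 0 && r_max >= r_min)) stop("invalid resolution grid")
  rs <- round(seq(r_min, r_max, by = r_step), 10)
  partitions <- vector("list", length(rs))
  counts <- integer(length(rs))
  mods <- numeric(length(rs))
  for (j in seq_along(rs)) {
    A <- A0
    diag(A) <- diag(A) + rs[j]
    fit <- maximize_modularity(A, seed = derive_seed(seed, j))
    partitions[[j]] <- fit$membership
    counts[j] <- max(fit$membership)
    mods[j] <- fit$modularity
  }
  runs <- rle(counts)
  persistence <- stats::aggregate(
    list(run = runs$lengths), by = list(n_communities = runs$values), max)
  persistence <- persistence[order(persistence$n_communities), ]
  structure(
    list(resolutions = data.frame(r = rs, n_communities = counts,
                                  modularity = mods),
         partitions = partitions,
         persistence = persistence),
    class = "afg_sweep"
  )
}

#' @export
print.afg_sweep <- function(x, ...) {
  cat("multi-resolution sweep over", nrow(x$resolutions), "resolutions\n")
  print(x$resolutions, row.names = FALSE)
  invisible(x)
}

#' Select the most persistent community count
#'
#' The optimal number of laterality states is the community count held
#' over the longest run of consecutive resolutions; ties break toward
#' the smaller count.
#'
#' @param sweep an `afg_sweep`.
#' @return Integer `k`.
#' @export
select_persistent_k <- function(sweep) {
  p <- sweep$persistence
  if (nrow(p) == 0L) stop("empty sweep")
  best <- p$n_communities[p$run == max(p$run)]
  as.integer(min(best))
}

#' Stage 3: final state centroids
#'
#' Spherical k-means with `k` fixed, run on the pooled per-subject
#' centroids with 20 seeded restarts; the lowest-inertia solution is
#' kept. Output rows are unit-norm.
#'
#' @param pooled M-by-N pooled centroid matrix.
#' @param k number of states.
#' @param seed integer seed.
#' @param n_start number of restarts.
#' @return k-by-N matrix of unit-norm state centroids.
#' @export
final_centroids <- function(pooled, k, seed = 1L, n_start = 20L) {
  spherical_kmeans(pooled, k, seed = seed, n_start = n_start)$centroids
}

#' Assign windows to laterality states
#'
#' Every window of every subject goes to the nearest centroid in cosine
#' distance (ties to the lowest state id). Occupancy is the per-state
#' fraction of all windows pooled over subjects.
#'
#' @param ls_list list of `laterality_series` (common unit set).
#' @param centroids k-by-N state centroid matrix.
#' @return List with `assignments` (list of per-window integer vectors)
#'   and `occupancy` (length-k fractions summing to 1).
#' @export
assign_windows <- function(ls_list, centroids) {
  cn <- row_l2_normalize(as.matrix(centroids), "centroid")
  assignments <- lapply(ls_list, function(ls) {
    if (ncol(ls$values) != ncol(cn)) {
      stop("window dimensionality does not match centroids")
    }
    xn <- row_l2_normalize(ls$values, "window")
    max.col(tcrossprod(xn, cn), ties.method = "first")
  })
  all_a <- unlist(assignments)
  occupancy <- tabulate(all_a, nbins = nrow(cn)) / length(all_a)
  list(assignments = assignments, occupancy = occupancy)
}

#' Three-stage laterality-state discovery
#'
#' Runs the full state pipeline: per-subject spherical k-means (stage 1),
#' pooling of centroids and a multi-resolution community-detection sweep
#' on their cosine-similarity graph to fix the number of states
#' (stage 2), then spherical k-means with `k` fixed for the final
#' centroids and nearest-centroid assignment of every window (stage 3).
#'
#' @param ls_list list of `laterality_series`, one per subject.
#' @param k1 per-subject cluster count (stage 1).
#' @param r_min,r_max,r_step resolution grid for the sweep.
#' @param seed master seed; stages derive their own streams from it.
#' @param k optional fixed state count (skips the sweep-based selection
#'   but still records the sweep when `record_sweep` is `TRUE`).
#' @param negative_weights see [centroid_similarity_graph()].
#' @return A `state_model`: `k`, `centroids`, `assignments`, `occupancy`,
#'   `sweep`, `k1`, `subject_ids`.
#' @export
fit_laterality_states <- function(ls_list, k1 = 5L, r_min = 0.1,
                                  r_max = 1.5, r_step = 0.1, seed = 1L,
                                  k = NULL,
                                  negative_weights = c("clip", "shift")) {
  negative_weights <- match.arg(negative_weights)
  if (length(ls_list) == 0L) stop("no subjects")
  per_subject <- lapply(ls_list, function(ls) {
    subject_kmeans(ls, k1 = k1,
                   seed = derive_seed(seed,
                                      1000 + seed_from_string(ls$subject_id)))
  })
  pooled <- pool_centroids(per_subject)
  graph <- centroid_similarity_graph(pooled, negative_weights)
  sweep <- afg_sweep(graph, r_min, r_max, r_step,
                     seed = derive_seed(seed, 2))
  if (is.null(k)) k <- select_persistent_k(sweep)
  centroids <- final_centroids(pooled, k, seed = derive_seed(seed, 3))
  asg <- assign_windows(ls_list, centroids)
  structure(
    list(k = as.integer(k), centroids = centroids,
         assignments = asg$assignments, occupancy = asg$occupancy,
         sweep = sweep, k1 = as.integer(k1),
         subject_ids = vapply(ls_list, function(l) l$subject_id, "")),
    class = "state_model"
  )
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("state_model: k = %d states over %d subjects\n",
              x$k, length(x$assignments)))
  cat("occupancy:", paste(sprintf("%.3f", x$occupancy), collapse = " "), "\n")
  invisible(x)
}

#' Match estimated state labels to reference labels
#'
#' Searches all permutations of the state labels and returns the one
#' maximising agreement with a reference labelling (used to score
#' planted-state recovery; feasible for small k).
#'
#' @param estimated,reference integer vectors of equal length.
#' @param k number of states.
#' @return List with `accuracy` (best fraction agreeing) and `perm`
#'   (permutation applied to `estimated`).
#' @export
match_state_labels <- function(estimated, reference, k) {
  if (length(estimated) != length(reference)) stop("length mismatch")
  perms <- all_permutations(k)
  best_acc <- -1; best_p <- NULL
  for (p in perms) {
    acc <- mean(p[estimated] == reference)
    if (acc > best_acc) { best_acc <- acc; best_p <- p }
  }
  list(accuracy = best_acc, perm = best_p)
}

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}
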