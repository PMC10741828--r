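test_that("window count obeys floor((T - length)/step) + 1", {
  expect_length(sliding_windows(142, window_spec(50, 1)), 93L)
  expect_length(sliding_windows(50, window_spec(50, 1)), 1L)
  expect_error(sliding_windows(10, window_spec(50, 1)), "exceeds")
  # property over a grid of geometries
  set.seed(4)
  for (i in 1:40) {
    T <- sample(10:300, 1)
    len <- sample(2:T, 1)
    step <- sample(seq_len(len), 1)
    got <- sliding_windows(T, window_spec(len, step))
    expect_length(got, floor((T - len) / step) + 1)
    expect_true(all(got + len - 1 <= T))
  }
})

test_that("hemispheric global signal is the per-timepoint ROI mean", {
  at <- tiny_atlas(8, c("A", "B"))
  ts <- rand_ts(30, at, seed = 5)
  gs <- hemisphere_global_signal(ts, at, "L")
  expect_equal(gs, rowMeans(ts$values[, 1:4]))
  # two-column mean oracle
  at2 <- roi_atlas(1:4, letters[1:4], c("L", "L", "R", "R"), rep("S", 4))
  v <- matrix(c(1, 3, 0, 0), 1, 4)
  ts2 <- subject_timeseries(rbind(v, v + 1), 2, 1:4)
  expect_equal(hemisphere_global_signal(ts2, at2, "L")[1], 2)
  # independence from the other hemisphere
  ts3 <- ts
  ts3$values[, 5:8] <- ts$values[, sample(5:8)]
  expect_equal(hemisphere_global_signal(ts3, at, "L"), gs)
})

test_that("dli_window equals the hand-computed Fisher-z difference", {
  at <- tiny_atlas(8, c("A", "B"))
  set.seed(11)
  w <- matrix(rnorm(25 * 8), 25, 8)
  got <- dli_window(w, at)
  gl <- rowMeans(w[, 1:4]); gr <- rowMeans(w[, 5:8])
  for (i in 1:8) {
    expect_equal(got[i], atanh(cor(w[, i], gl)) - atanh(cor(w[, i], gr)),
                 tolerance = 1e-12)
  }
  # antisymmetry under hemisphere relabelling is exact
  expect_identical(dli_window(w, flip_hemispheres(at)), -got)
  # mirrored data gives exactly zero DLI
  wm <- cbind(w[, 1:4], w[, 1:4])
  expect_equal(dli_window(wm, at), rep(0, 8))
  # degenerate inputs abort
  wc <- w; wc[, 3] <- 1
  expect_error(dli_window(wc, at), "zero-variance ROI 3")
  expect_error(dli_window(w[1:2, ], at), "at least 3")
})

test_that("laterality_series matches the per-window reference path", {
  at <- tiny_atlas(10, c("A", "B"))
  ts <- rand_ts(70, at, seed = 21)
  for (ex in c(FALSE, TRUE)) {
    sp <- window_spec(20, 3)
    ls <- laterality_series(ts, sp, at, gs_exclude_self = ex)
    starts <- sliding_windows(70, sp)
    ref <- t(vapply(starts, function(s) {
      dli_window(ts$values[s:(s + 19), ], at, gs_exclude_self = ex)
    }, numeric(10)))
    expect_equal(unname(ls$values), ref, tolerance = 1e-10)
  }
  # time reversal with step 1 reverses the window order
  sp1 <- window_spec(20, 1)
  fwd <- laterality_series(ts, sp1, at)
  rev_ts <- subject_timeseries(ts$values[70:1, ], 2, ts$roi_ids)
  bwd <- laterality_series(rev_ts, sp1, at)
  expect_equal(unname(bwd$values),
               unname(fwd$values[nrow(fwd$values):1, ]),
               tolerance = 1e-10)
})

test_that("MLI/LF match hand arithmetic and the streaming oracle", {
  at <- tiny_atlas(4, "S")
  ls <- structure(list(values = cbind(c(0.1, 0.2, 0.3),
                                      rep(0.5, 3),
                                      c(-1, 0, 1),
                                      c(2, 2, 5)),
                       window_starts = 1:3, window_length = 2, step = 1,
                       ids = as.character(1:4), level = "node",
                       subject_id = "s"),
                  class = "laterality_series")
  m <- compute_metrics(ls)
  expect_equal(m$mli[1], 0.2)
  expect_equal(m$lf[1], 0.1)
  expect_equal(m$lf[2], 0)       # constant column
  # streaming-oracle agreement on random data
  set.seed(31)
  big <- rand_ts(60, at, seed = 31)
  lsr <- laterality_series(big, window_spec(20, 1), at)
  mr <- compute_metrics(lsr)
  for (j in seq_len(ncol(lsr$values))) {
    o <- oracle_stream_stats(lsr$values[, j])
    expect_equal(mr$mli[j], unname(o["mean"]), tolerance = 1e-12)
    expect_equal(mr$lf[j], unname(o["sd"]), tolerance = 1e-12)
  }
  # subsets: singleton defines MLI, flags LF; empty flags both
  m1 <- compute_metrics(ls, subset = 2L)
  expect_equal(m1$mli[1], 0.2)
  expect_true(is.na(m1$lf[1]))
  m0 <- compute_metrics(ls, subset = integer(0))
  expect_true(all(is.na(m0$mli)))
  expect_equal(m0$n_windows[1], 0L)
  expect_error(compute_metrics(ls, subset = 99L), "out of range")
})

test_that("state partition recovers ALL-window MLI and LF", {
  # mean law exactly; variance by the law of total variance
  at <- tiny_atlas(6, "S")
  ts <- rand_ts(80, at, seed = 77)
  ls <- laterality_series(ts, window_spec(20, 1), at)
  W <- nrow(ls$values)
  set.seed(7)
  states <- sample(1:3, W, replace = TRUE)
  all_m <- compute_metrics(ls)
  parts <- lapply(1:3, function(s) compute_metrics(ls, which(states == s)))
  ns <- vapply(1:3, function(s) sum(states == s), 0)
  mli_rec <- Reduce(`+`, lapply(1:3, function(s) ns[s] * parts[[s]]$mli)) / W
  expect_equal(mli_rec, all_m$mli, tolerance = 1e-12)
  # total variance = mean within-variance + variance of means (ddof 0)
  for (j in 1:6) {
    v_within <- sum(vapply(1:3, function(s) {
      (ns[s] - 1) * parts[[s]]$lf[j]^2
    }, 0))
    means <- vapply(1:3, function(s) parts[[s]]$mli[j], 0)
    v_between <- sum(ns * (means - all_m$mli[j])^2)
    expect_equal((v_within + v_between) / (W - 1), all_m$lf[j]^2,
                 tolerance = 1e-12)
  }
})

test_that("unit aggregation averages member ROIs per window", {
  at <- roi_atlas(1:6, letters[1:6],
                  c("L", "L", "L", "R", "R", "R"),
                  c("P", "Q", "Q", "P", "Q", "Q"))
  vals <- matrix(rnorm(40 * 6), 40, 6)
  ts <- subject_timeseries(vals, 2, 1:6)
  ls <- laterality_series(ts, window_spec(15, 2), at)
  ag <- aggregate_units(ls, at, "subnetwork")
  expect_setequal(ag$ids, c("P_L", "Q_L", "P_R", "Q_R"))
  # single-ROI unit passthrough and two-member mean oracle
  expect_equal(ag$values[, ag$ids == "P_L"], ls$values[, 1])
  expect_equal(ag$values[, ag$ids == "Q_L"],
               rowMeans(ls$values[, 2:3]))
  hem <- aggregate_units(ls, at, "hemisphere")
  expect_equal(hem$values[, hem$ids == "HEM_R"],
               rowMeans(ls$values[, 4:6]))
})

test_that("hemisphere relabelling negates MLI exactly and preserves LF", {
  at <- tiny_atlas(10, c("A", "B"))
  ts <- rand_ts(60, at, seed = 13)
  sp <- window_spec(25, 1)
  ls <- laterality_series(ts, sp, at)
  ls_f <- laterality_series(ts, sp, flip_hemispheres(at))
  expect_identical(ls_f$values, -ls$values)
  m <- compute_metrics(ls); mf <- compute_metrics(ls_f)
  expect_identical(mf$mli, -m$mli)
  expect_identical(mf$lf, m$lf)
})

test_that("state correlation matrix equals brute-force pooled Pearson", {
  at <- tiny_atlas(6, "S")
  ls_list <- lapply(1:3, function(s) {
    laterality_series(rand_ts(50, at, seed = 40 + s),
                      window_spec(20, 1), at)
  })
  set.seed(5)
  asg <- lapply(ls_list, function(l) {
    sample(1:2, nrow(l$values), replace = TRUE)
  })
  cm <- state_laterality_correlation(ls_list, asg, 1)
  pooled <- do.call(rbind, mapply(function(l, a) {
    l$values[a == 1, , drop = FALSE]
  }, ls_list, asg, SIMPLIFY = FALSE))
  for (i in 1:6) for (j in 1:6) {
    expect_equal(cm[i, j], cor(pooled[, i], pooled[, j]),
                 tolerance = 1e-12)
  }
  expect_equal(diag(cm), rep(1, 6), ignore_attr = TRUE)
  expect_equal(cm, t(cm))
  # too few windows is an error
  asg0 <- lapply(ls_list, function(l) rep(2L, nrow(l$values)))
  asg0[[1]][1] <- 1L
  expect_error(state_laterality_correlation(ls_list, asg0, 1),
               "fewer than 3")
})
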