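#' Sliding-window specification
#'
#' @param length window length in samples (default 50, i.e. 100 s at a
#'   2 s repetition time).
#' @param step window step in samples (default 1).
#' @return A `window_spec` list.
#' @export
window_spec <- function(length = 50L, step = 1L) {
  length <- as.integer(length); step <- as.integer(step)
  if (length < 2L) stop("window length must be >= 2 samples")
  if (step < 1L || step > length) stop("step must satisfy 1 <= step <= length")
  structure(list(length = length, step = step), class = "window_spec")
}

#' Enumerate sliding windows
#'
#' Returns the start index of every window over a series of `T` samples.
#' The number of windows obeys `floor((T - length) / step) + 1`; a
#' 142-sample series with 50-sample windows at step 1 yields 93 windows.
#'
#' @param T number of time points.
#' @param spec a `window_spec`.
#' @return Integer vector of 1-based window start indices; window `w`
#'   covers samples `start[w] .. start[w] + length - 1`.
#' @export
sliding_windows <- function(T, spec = window_spec()) {
  T <- as.integer(T)
  if (spec$length > T) {
    stop("window length (", spec$length, ") exceeds series length (", T, ")")
  }
  seq.int(1L, T - spec$length + 1L, by = spec$step)
}

#' Hemispheric global signal
#'
#' The global signal of one hemisphere is the unweighted mean, at each
#' time point, of that hemisphere's ROI columns.
#'
#' @param ts a `subject_ts`.
#' @param atlas a `roi_atlas` aligned with the columns of `ts`.
#' @param side `"L"` or `"R"`.
#' @return Numeric vector of length T.
#' @export
hemisphere_global_signal <- function(ts, atlas, side) {
  check_alignment(ts, atlas)
  idx <- hemisphere_index(atlas, side)
  rowMeans(ts$values[, idx, drop = FALSE])
}

check_alignment <- function(ts, atlas) {
  validate_atlas(atlas)
  if (ncol(ts$values) != nrow(atlas) ||
      !all(ts$roi_ids == atlas$roi_id)) {
    stop("time-series columns do not align with atlas roi_ids")
  }
  invisible(TRUE)
}

#' Dynamic laterality index of one window
#'
#' For each ROI, the DLI is the difference of Fisher-z-transformed
#' Pearson correlations of the ROI's signal with the left and the right
#' hemispheric global signal, all computed within the window:
#' `DLI_i = atanh(r(x_i, GS_L)) - atanh(r(x_i, GS_R))`.
#'
#' A positive DLI means the region co-fluctuates more strongly with the
#' left hemisphere; relabelling hemispheres negates every value. By
#' default a region's own signal is included in its hemisphere's global
#' signal; set `gs_exclude_self = TRUE` to leave each ROI out of its own
#' reference.
#'
#' @param window_values numeric length-by-N matrix (one window of data).
#' @param atlas a `roi_atlas` aligned with the columns.
#' @param gs_exclude_self exclude each ROI from its own hemisphere mean.
#' @return Numeric N-vector of DLI values.
#' @export
dli_window <- function(window_values, atlas, gs_exclude_self = FALSE) {
  window_values <- as.matrix(window_values)
  if (nrow(window_values) < 3L) stop("window must span at least 3 samples")
  validate_atlas(atlas)
  if (ncol(window_values) != nrow(atlas)) {
    stop("window columns do not match atlas size")
  }
  li <- which(atlas$hemisphere == "L")
  ri <- which(atlas$hemisphere == "R")
  gl <- rowMeans(window_values[, li, drop = FALSE])
  gr <- rowMeans(window_values[, ri, drop = FALSE])
  n <- ncol(window_values)
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- window_values[, i]
    g_l <- gl; g_r <- gr
    if (gs_exclude_self) {
      if (atlas$hemisphere[i] == "L") {
        if (length(li) < 2L) stop("cannot exclude the only left ROI")
        g_l <- (length(li) * gl - x) / (length(li) - 1L)
      } else {
        if (length(ri) < 2L) stop("cannot exclude the only right ROI")
        g_r <- (length(ri) * gr - x) / (length(ri) - 1L)
      }
    }
    if (stats::sd(x) == 0) {
      stop("zero-variance ROI ", atlas$roi_id[i], " within window")
    }
    rl <- stats::cor(x, g_l)
    rr <- stats::cor(x, g_r)
    if (!is.finite(rl) || !is.finite(rr) || abs(rl) >= 1 || abs(rr) >= 1) {
      stop("degenerate correlation (|r| >= 1 or undefined) for ROI ",
           atlas$roi_id[i])
    }
    out[i] <- atanh(rl) - atanh(rr)
  }
  out
}

# sliding sums over windows of length L at the given starts (step implicit)
window_sums <- function(m, L, starts) {
  cs <- apply(rbind(0, m), 2L, cumsum)
  cs[starts + L, , drop = FALSE] - cs[starts, , drop = FALSE]
}

# windowed Pearson correlation of each column of x with a reference whose
# windowed sums/cross-sums are supplied; returns W x N matrix
windowed_cor <- function(L, Sx, Sxx, Sg, Sgg, Sxg) {
  vx <- L * Sxx - Sx^2
  vg <- L * Sgg - Sg^2
  (L * Sxg - Sx * Sg) / sqrt(vx * vg)
}

#' Laterality time series of a subject
#'
#' Computes the per-window DLI of every ROI over all sliding windows
#' (an efficient running-sums implementation; `dli_window()` applied per
#' window gives the same values and serves as the reference path).
#'
#' @param ts a `subject_ts`.
#' @param spec a `window_spec`.
#' @param atlas a `roi_atlas` aligned with the columns of `ts`.
#' @param gs_exclude_self see [dli_window()].
#' @return A `laterality_series`: list with `values` (W-by-N matrix of
#'   DLI), `window_starts`, `window_length`, `step`, `ids`, `level` and
#'   `subject_id`.
#' @export
laterality_series <- function(ts, spec = window_spec(), atlas,
                              gs_exclude_self = FALSE) {
  check_alignment(ts, atlas)
  starts <- sliding_windows(nrow(ts$values), spec)
  L <- spec$length
  x <- sweep(ts$values, 2L, colMeans(ts$values))  # centring aids precision
  li <- which(atlas$hemisphere == "L")
  ri <- which(atlas$hemisphere == "R")
  gl <- rowMeans(x[, li, drop = FALSE])
  gr <- rowMeans(x[, ri, drop = FALSE])

  Sx <- window_sums(x, L, starts)
  Sxx <- window_sums(x^2, L, starts)
  Sgl <- window_sums(matrix(gl), L, starts)[, 1L]
  Sgr <- window_sums(matrix(gr), L, starts)[, 1L]
  Sglgl <- window_sums(matrix(gl^2), L, starts)[, 1L]
  Sgrgr <- window_sums(matrix(gr^2), L, starts)[, 1L]
  Sxgl <- window_sums(x * gl, L, starts)
  Sxgr <- window_sums(x * gr, L, starts)

  W <- length(starts); n <- ncol(x)
  r_l <- matrix(NA_real_, W, n)
  r_r <- matrix(NA_real_, W, n)
  for (side in c("L", "R")) {
    cols <- if (side == "L") li else ri
    other <- if (side == "L") ri else li
    nh <- length(cols)
    Sg_own <- if (side == "L") Sgl else Sgr
    Sgg_own <- if (side == "L") Sglgl else Sgrgr
    Sxg_own <- if (side == "L") Sxgl[, cols, drop = FALSE] else
      Sxgr[, cols, drop = FALSE]
    if (gs_exclude_self) {
      if (nh < 2L) stop("cannot exclude the only ", side, " ROI")
      Sxc <- Sx[, cols, drop = FALSE]
      Sxxc <- Sxx[, cols, drop = FALSE]
      Su <- (nh * Sg_own - Sxc) / (nh - 1)
      Sxu <- (nh * Sxg_own - Sxxc) / (nh - 1)
      Suu <- (nh^2 * Sgg_own - 2 * nh * Sxg_own + Sxxc) / (nh - 1)^2
      r_own <- windowed_cor(L, Sxc, Sxxc, Su, Suu, Sxu)
    } else {
      r_own <- windowed_cor(L, Sx[, cols, drop = FALSE],
                            Sxx[, cols, drop = FALSE],
                            Sg_own, Sgg_own, Sxg_own)
    }
    Sg_oth <- if (side == "L") Sgr else Sgl
    Sgg_oth <- if (side == "L") Sgrgr else Sglgl
    Sxg_oth <- if (side == "L") Sxgr[, cols, drop = FALSE] else
      Sxgl[, cols, drop = FALSE]
    r_oth <- windowed_cor(L, Sx[, cols, drop = FALSE],
                          Sxx[, cols, drop = FALSE],
                          Sg_oth, Sgg_oth, Sxg_oth)
    if (side == "L") {
      r_l[, cols] <- r_own; r_r[, cols] <- r_oth
    } else {
      r_r[, cols] <- r_own; r_l[, cols] <- r_oth
    }
  }
  bad <- !is.finite(r_l) | !is.finite(r_r) | abs(r_l) >= 1 | abs(r_r) >= 1
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop("degenerate correlation (|r| >= 1 or zero variance) for ROI ",
         atlas$roi_id[w[2L]], " in window ", w[1L])
  }
  new_laterality_series(atanh(r_l) - atanh(r_r), starts, spec,
                        as.character(atlas$roi_id), "node", ts$subject_id)
}

new_laterality_series <- function(values, starts, spec, ids, level,
                                  subject_id) {
  colnames(values) <- ids
  structure(
    list(values = values, window_starts = as.integer(starts),
         window_length = spec$length, step = spec$step,
         ids = ids, level = level, subject_id = subject_id),
    class = "laterality_series"
  )
}

#' @export
print.laterality_series <- function(x, ...) {
  cat(sprintf("laterality_series '%s' (%s level): %d windows x %d units\n",
              x$subject_id, x$level, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Mean laterality index and laterality fluctuation
#'
#' MLI is the mean DLI over a window set; LF is its standard deviation
#' (sample SD, `ddof = 1`, by default). The window set is either all
#' windows or the subset assigned to one laterality state. Windowless
#' entries come back as `NA` with `n_windows = 0` rather than silent
#' zeros; a single-window subset defines MLI but flags LF as `NA`.
#'
#' @param ls a `laterality_series`.
#' @param subset `"all"` or an integer vector of window indices.
#' @param lf_ddof degrees-of-freedom correction for LF (1 = sample SD).
#' @return Data frame with columns `unit_id`, `mli`, `lf`, `n_windows`.
#' @export
compute_metrics <- function(ls, subset = "all", lf_ddof = 1L) {
  v <- ls$values
  if (!identical(subset, "all")) {
    subset <- as.integer(subset)
    if (length(subset) > 0 &&
        (min(subset) < 1L || max(subset) > nrow(v))) {
      stop("window subset out of range")
    }
    v <- v[subset, , drop = FALSE]
  }
  nw <- nrow(v)
  if (nw == 0L) {
    mli <- rep(NA_real_, ncol(v)); lf <- rep(NA_real_, ncol(v))
  } else {
    mli <- colMeans(v)
    if (nw >= 2L) {
      dev <- sweep(v, 2L, mli)
      lf <- sqrt(colSums(dev^2) / (nw - lf_ddof))
    } else {
      lf <- rep(NA_real_, ncol(v))
    }
  }
  data.frame(unit_id = ls$ids, mli = mli, lf = lf, n_windows = nw,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate a laterality series to coarser units
#'
#' Produces the unit-level laterality series whose value in each window
#' is the unweighted mean of the member ROIs' DLI ("aggregate then
#' summarise"). With the standard 5-subnetwork atlas this yields 10
#' subnetwork-by-hemisphere units, or 2 units at hemisphere level.
#'
#' @param ls a node-level `laterality_series`.
#' @param atlas the aligned `roi_atlas`.
#' @param level `"subnetwork"` or `"hemisphere"`.
#' @return A `laterality_series` over units.
#' @export
aggregate_units <- function(ls, atlas, level = c("subnetwork", "hemisphere")) {
  level <- match.arg(level)
  if (!identical(ls$ids, as.character(atlas$roi_id))) {
    stop("laterality series columns do not align with atlas roi_ids")
  }
  units <- atlas_units(atlas, level)
  vals <- vapply(units$members, function(m) {
    cols <- match(as.character(m), ls$ids)
    rowMeans(ls$values[, cols, drop = FALSE])
  }, numeric(nrow(ls$values)))
  if (nrow(ls$values) == 1L) vals <- matrix(vals, nrow = 1L)
  new_laterality_series(vals, ls$window_starts,
                        window_spec(ls$window_length, ls$step),
                        units$unit_id, level, ls$subject_id)
}

#' Pooled laterality correlation matrix of a state
#'
#' Pearson correlation between ROI DLI columns over all windows assigned
#' to one state, pooled across subjects (the state-wise laterality
#' correlation matrix used to portray each state's pattern).
#'
#' @param ls_list list of node-level `laterality_series`, one per subject.
#' @param assignments list of integer vectors (per subject, per window
#'   state labels) aligned with `ls_list`.
#' @param state the state id to pool.
#' @return Symmetric N-by-N correlation matrix with unit diagonal.
#' @export
state_laterality_correlation <- function(ls_list, assignments, state) {
  if (length(ls_list) != length(assignments)) {
    stop("ls_list and assignments must have the same length")
  }
  rows <- mapply(function(ls, a) {
    if (length(a) != nrow(ls$values)) {
      stop("assignment length mismatch for subject ", ls$subject_id)
    }
    ls$values[a == state, , drop = FALSE]
  }, ls_list, assignments, SIMPLIFY = FALSE)
  pooled <- do.call(rbind, rows)
  if (is.null(pooled) || nrow(pooled) < 3L) {
    stop("state ", state, " has fewer than 3 pooled windows")
  }
  stats::cor(pooled)
}
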