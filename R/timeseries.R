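#' Subject BOLD time series
#'
#' A `subject_ts` holds one subject's ROI-level BOLD data: a numeric
#' T-by-N matrix `values` (rows = time points, columns = ROIs in atlas
#' `roi_id` order), the repetition time `tr_seconds`, the column labels
#' `roi_ids` and a `subject_id`.
#'
#' @param values numeric T-by-N matrix, no missing values, T >= 2.
#' @param tr_seconds sampling interval in seconds.
#' @param roi_ids integer labels for the columns.
#' @param subject_id character identifier.
#' @return An object of class `subject_ts`.
#' @export
subject_timeseries <- function(values, tr_seconds, roi_ids = NULL,
                               subject_id = "subject") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L) stop("time series needs at least 2 time points")
  if (anyNA(values) || any(!is.finite(values))) {
    stop("time series contains missing or non-finite values")
  }
  if (is.null(roi_ids)) roi_ids <- seq_len(ncol(values))
  if (length(roi_ids) != ncol(values)) {
    stop("roi_ids length must match the number of columns")
  }
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0) {
    stop("tr_seconds must be a positive scalar")
  }
  structure(
    list(values = values, tr_seconds = as.numeric(tr_seconds),
         roi_ids = as.integer(roi_ids), subject_id = as.character(subject_id)),
    class = "subject_ts"
  )
}

#' @export
print.subject_ts <- function(x, ...) {
  cat(sprintf("subject_ts '%s': %d time points x %d ROIs, TR = %g s\n",
              x$subject_id, nrow(x$values), ncol(x$values), x$tr_seconds))
  invisible(x)
}

#' @export
dim.subject_ts <- function(x) dim(x$values)

#' Read an ROI-by-time matrix from tab-separated text
#'
#' Expects a TSV whose header row holds the ROI ids and whose subsequent
#' rows are time points. Parsing is strict: a ragged row or a non-numeric
#' cell aborts with an error naming the offending row.
#'
#' @param path file path.
#' @param tr_seconds repetition time to attach (seconds).
#' @param subject_id identifier; defaults to the file stem.
#' @return A `subject_ts`.
#' @export
read_roi_timeseries <- function(path, tr_seconds = 2,
                                subject_id = NULL) {
  if (!file.exists(path)) stop("time-series file not found: ", path)
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("file must have a header row and data rows")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  n <- length(header)
  roi_ids <- suppressWarnings(as.integer(gsub("^[^0-9]*", "", header)))
  if (anyNA(roi_ids)) roi_ids <- seq_len(n)
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != n)
  if (length(bad) > 0L) {
    stop("ragged row ", bad[1L], ": expected ", n, " fields, got ",
         length(rows[[bad[1L]]]))
  }
  vals <- suppressWarnings(vapply(rows, as.numeric, numeric(n)))
  if (anyNA(vals)) {
    badcell <- which(apply(is.na(vals), 2L, any))[1L]
    stop("non-numeric cell in data row ", badcell)
  }
  values <- if (n == 1L) matrix(vals, ncol = 1L) else t(vals)
  subject_timeseries(values, tr_seconds, roi_ids, subject_id)
}

#' Write an ROI-by-time matrix as tab-separated text
#'
#' @param ts a `subject_ts`.
#' @param path output path.
#' @export
write_roi_timeseries <- function(ts, path) {
  m <- ts$values
  colnames(m) <- as.character(ts$roi_ids)
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract ROI mean time series from a labelled 4D volume
#'
#' Averages, per time point, all voxels sharing an atlas label. Volumes
#' are plain R arrays (x, y, z, t) and (x, y, z); file-format handling is
#' left to the caller so the extraction itself stays testable.
#'
#' @param image4d numeric 4D array (x, y, z, t).
#' @param labels integer 3D array on the same spatial grid; 0 = background.
#' @param atlas a `roi_atlas`; every `roi_id` must occur in `labels`.
#' @param tr_seconds repetition time (seconds).
#' @param subject_id identifier.
#' @return A `subject_ts` with one column per atlas ROI (atlas order).
#' @export
extract_roi_means <- function(image4d, labels, atlas, tr_seconds = 2,
                              subject_id = "subject") {
  validate_atlas(atlas)
  d4 <- dim(image4d)
  d3 <- dim(labels)
  if (length(d4) != 4L) stop("image4d must be a 4D array")
  if (length(d3) != 3L || !all(d4[1:3] == d3)) {
    stop("image and label volumes must share the same spatial grid")
  }
  nt <- d4[4L]
  vox <- matrix(image4d, nrow = prod(d3), ncol = nt)
  lab <- as.integer(labels)
  present <- unique(lab)
  missing_ids <- setdiff(atlas$roi_id, present)
  if (length(missing_ids) > 0L) {
    stop("label volume lacks roi_id(s): ",
         paste(missing_ids, collapse = ", "))
  }
  values <- vapply(atlas$roi_id, function(id) {
    sel <- lab == id
    if (sum(sel) == 1L) vox[sel, ] else colMeans(vox[sel, , drop = FALSE])
  }, numeric(nt))
  subject_timeseries(values, tr_seconds, atlas$roi_id, subject_id)
}

#' Discard initial volumes
#'
#' Drops the first `n_discard` time points (scanner calibration /
#' acclimatisation period; 10 volumes of a 152-point acquisition in the
#' reference design, leaving 142).
#'
#' @param ts a `subject_ts`.
#' @param n_discard number of leading time points to drop (`< T`).
#' @return The shortened `subject_ts`.
#' @export
discard_initial_volumes <- function(ts, n_discard = 10L) {
  n_discard <- as.integer(n_discard)
  if (n_discard < 0L) stop("n_discard must be non-negative")
  if (n_discard >= nrow(ts$values)) {
    stop("n_discard (", n_discard, ") must be smaller than T (",
         nrow(ts$values), ")")
  }
  if (n_discard == 0L) return(ts)
  subject_timeseries(ts$values[-seq_len(n_discard), , drop = FALSE],
                     ts$tr_seconds, ts$roi_ids, ts$subject_id)
}

#' Linear detrend and nuisance regression
#'
#' Replaces every ROI column by its residual from an ordinary least
#' squares fit on an intercept, a linear ramp, and any supplied confound
#' columns (e.g. tissue signals or motion expansions computed upstream).
#'
#' @param ts a `subject_ts`.
#' @param confounds optional numeric T-by-C matrix of nuisance regressors.
#' @return The residualised `subject_ts`.
#' @export
detrend_and_regress <- function(ts, confounds = NULL) {
  y <- ts$values
  tt <- nrow(y)
  design <- cbind(intercept = 1, ramp = seq_len(tt))
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != tt) {
      stop("confounds must have one row per time point (", tt, ")")
    }
    if (anyNA(confounds)) stop("confounds contain missing values")
    design <- cbind(design, confounds)
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    stop("rank-deficient nuisance design (rank ", qrd$rank, " < ",
         ncol(design), " columns); prune collinear confounds")
  }
  resid <- y - design %*% qr.coef(qrd, y)
  subject_timeseries(resid, ts$tr_seconds, ts$roi_ids, ts$subject_id)
}

# --- Butterworth band-pass -------------------------------------------------
# No DSP package is assumed; the classic design chain (analog prototype ->
# band transform -> bilinear) and a zero-phase forward-backward pass with
# odd-symmetric edge padding are implemented here.

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0i) - c(0i, p * rt)
  p
}

# digital Butterworth band-pass coefficients (order = 2 * n_prototype)
butter_bandpass <- function(n, low_hz, high_hz, fs) {
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low_hz / fs)
  w2 <- fs2 * tan(pi * high_hz / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # unit LP poles
  sc <- proto * bw / 2
  poles_s <- c(sc + sqrt(sc^2 - w0^2), sc - sqrt(sc^2 - w0^2))
  zeros_s <- rep(0 + 0i, n)
  gain_s <- bw^n
  # bilinear transform
  poles_z <- (fs2 + poles_s) / (fs2 - poles_s)
  zeros_z <- c((fs2 + zeros_s) / (fs2 - zeros_s), rep(-1 + 0i, n))
  gain_z <- gain_s * Re(prod(fs2 - zeros_s) / prod(fs2 - poles_s))
  b <- Re(poly_from_roots(zeros_z)) * gain_z
  a <- Re(poly_from_roots(poles_z))
  list(b = b, a = a)
}

# direct-form II transposed IIR filter with initial state zi
iir_filter <- function(b, a, x, zi = NULL) {
  nfilt <- length(a)
  b <- b / a[1L]; a <- a / a[1L]
  z <- if (is.null(zi)) numeric(nfilt - 1L) else zi
  y <- numeric(length(x))
  for (m in seq_along(x)) {
    xm <- x[m]
    ym <- b[1L] * xm + z[1L]
    if (nfilt > 2L) {
      for (i in seq_len(nfilt - 2L)) {
        z[i] <- b[i + 1L] * xm + z[i + 1L] - a[i + 1L] * ym
      }
    }
    z[nfilt - 1L] <- b[nfilt] * xm - a[nfilt] * ym
    y[m] <- ym
  }
  y
}

# steady-state initial conditions for a unit step (cf. lfilter_zi)
filter_zi <- function(b, a) {
  n <- length(a) - 1L
  b <- b / a[1L]; a <- a / a[1L]
  comp <- rbind(-a[-1L], cbind(diag(1, n - 1L), 0))
  B <- b[-1L] - b[1L] * a[-1L]
  solve(diag(n) - t(comp), B)
}

filtfilt_padded <- function(b, a, x) {
  padlen <- 3L * max(length(a), length(b))
  n <- length(x)
  if (n <= padlen) {
    stop("series too short (", n, " points) for zero-phase filtering ",
         "(needs > ", padlen, ")")
  }
  ext <- c(2 * x[1L] - x[(padlen + 1L):2L],
           x,
           2 * x[n] - x[(n - 1L):(n - padlen)])
  zi <- filter_zi(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1L])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass (default 4th-order prototype, passed
#' forward and backward for zero phase) to every ROI column. The default
#' 0.01-0.1 Hz band is the conventional resting-state BOLD range. Edge
#' transients are reduced by odd-symmetric reflection padding.
#'
#' @param ts a `subject_ts`.
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 < low < high < 1/(2 * tr_seconds)`.
#' @param order Butterworth prototype order (the band-pass filter has
#'   twice this many poles).
#' @return The filtered `subject_ts`.
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.1, order = 4L) {
  fs <- 1 / ts$tr_seconds
  nyq <- fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop("band edges must satisfy 0 < low < high < Nyquist (",
         signif(nyq, 4), " Hz)")
  }
  coefs <- butter_bandpass(order, low_hz, high_hz, fs)
  filt <- apply(ts$values, 2L, function(col) {
    filtfilt_padded(coefs$b, coefs$a, col)
  })
  subject_timeseries(filt, ts$tr_seconds, ts$roi_ids, ts$subject_id)
}
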