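#' Build the tidy MLI/LF metric table of a cohort
#'
#' For every subject, computes MLI and LF at node, subnetwork-by-
#' hemisphere and hemisphere level, over all windows and (when state
#' `assignments` are given) within each state's window subset. Unit
#' series at the coarser levels are the unweighted mean of member-ROI
#' DLI per window ("aggregate then summarise", the default); the
#' alternative `"roi_mean"` mode averages per-ROI MLI/LF instead (the
#' two differ for LF).
#'
#' @param ls_list list of node-level `laterality_series`, one per subject.
#' @param atlas the aligned `roi_atlas`.
#' @param group character vector of group labels per subject.
#' @param assignments optional list of per-window state labels (from a
#'   `state_model`).
#' @param k number of states (required with `assignments`).
#' @param levels which unit levels to include.
#' @param lf_ddof degrees-of-freedom correction for LF.
#' @param aggregate `"series"` or `"roi_mean"`.
#' @return Data frame with columns `subject_id`, `group`, `unit_id`,
#'   `unit_level`, `state` (`"ALL"` or `"1"`..`"k"`), `mli`, `lf`,
#'   `n_windows`. Subjects with no windows in a state keep their rows
#'   with `NA` metrics and `n_windows = 0`.
#' @export
build_metric_table <- function(ls_list, atlas, group,
                               assignments = NULL, k = NULL,
                               levels = c("node", "subnetwork",
                                          "hemisphere"),
                               lf_ddof = 1L,
                               aggregate = c("series", "roi_mean")) {
  aggregate <- match.arg(aggregate)
  if (length(group) != length(ls_list)) {
    stop("group must have one label per subject")
  }
  if (!is.null(assignments)) {
    if (is.null(k)) k <- max(unlist(assignments))
    if (length(assignments) != length(ls_list)) {
      stop("assignments must align with ls_list")
    }
  }
  states <- c("ALL", if (!is.null(assignments)) as.character(seq_len(k)))
  out <- vector("list", length(ls_list) * length(states) * length(levels))
  pos <- 0L
  for (i in seq_along(ls_list)) {
    ls <- ls_list[[i]]
    series <- list()
    for (lv in levels) {
      series[[lv]] <- if (lv == "node") ls else aggregate_units(ls, atlas, lv)
    }
    for (st in states) {
      subset <- if (st == "ALL") "all" else {
        which(assignments[[i]] == as.integer(st))
      }
      for (lv in levels) {
        m <- if (aggregate == "series" || lv == "node") {
          compute_metrics(series[[lv]], subset, lf_ddof)
        } else {
          roi_mean_metrics(ls, atlas, lv, subset, lf_ddof)
        }
        pos <- pos + 1L
        out[[pos]] <- data.frame(
          subject_id = ls$subject_id, group = group[i],
          unit_id = m$unit_id, unit_level = lv, state = st,
          mli = m$mli, lf = m$lf, n_windows = m$n_windows,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# summarise-then-average alternative: per-ROI MLI/LF averaged over the
# unit's member ROIs
roi_mean_metrics <- function(ls, atlas, level, subset, lf_ddof) {
  node <- compute_metrics(ls, subset, lf_ddof)
  units <- atlas_units(atlas, level)
  agg <- lapply(units$members, function(mm) {
    rows <- match(as.character(mm), node$unit_id)
    c(mli = mean(node$mli[rows]), lf = mean(node$lf[rows]))
  })
  data.frame(unit_id = units$unit_id,
             mli = vapply(agg, `[[`, 0, "mli"),
             lf = vapply(agg, `[[`, 0, "lf"),
             n_windows = node$n_windows[1L],
             stringsAsFactors = FALSE)
}
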