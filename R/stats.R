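#' Two-sample t-test
#'
#' Pooled-variance (Student) two-sample two-tailed t-test, the default
#' inferential tool for MLI/LF group comparisons; Welch's unequal-
#' variance form is available via `welch = TRUE`. The statistic is for
#' `mean(x) - mean(y)`.
#'
#' @param x,y numeric samples (each with at least 2 finite values).
#' @param welch use the Welch-Satterthwaite form.
#' @return List with `t`, `df` and the two-tailed `p`.
#' @export
two_sample_ttest <- function(x, y, welch = FALSE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("each sample needs at least 2 values")
  vx <- stats::var(x); vy <- stats::var(y)
  diff <- mean(x) - mean(y)
  if (welch) {
    sterr2 <- vx / nx + vy / ny
    if (sterr2 == 0) {
      if (diff == 0) return(list(t = 0, df = nx + ny - 2, p = 1))
      stop("zero variance with unequal means")
    }
    df <- sterr2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    t <- diff / sqrt(sterr2)
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    df <- nx + ny - 2
    if (sp2 == 0) {
      if (diff == 0) return(list(t = 0, df = df, p = 1))
      stop("zero pooled variance with unequal means")
    }
    t <- diff / sqrt(sp2 * (1 / nx + 1 / ny))
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up control of the false discovery rate:
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1; a hypothesis is
#' rejected when its q-value is at most `alpha`.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return List with `q` (adjusted values, input order) and `reject`
#'   (logical).
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0L) {
    return(list(q = numeric(0), reject = logical(0)))
  }
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(pvalues)
  o <- order(pvalues)
  ranked <- pvalues[o] * m / seq_len(m)
  qsorted <- pmin(rev(cummin(rev(ranked))), 1)
  q <- numeric(m)
  q[o] <- qsorted
  list(q = q, reject = q <= alpha)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties), with the
#' p-value from the Student-t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of
#' freedom. `alternative` selects the sidedness; `method =
#' "exact"` delegates to the exact null distribution (small n, no ties).
#'
#' @param x,y paired numeric samples, `n >= 3`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param method `"t"` (default) or `"exact"`.
#' @return List with `rho`, `n` and `p` (`rho = NA` with a warning when
#'   either input is constant).
#' @export
spearman_corr <- function(x, y,
                          alternative = c("two.sided", "greater", "less"),
                          method = c("t", "exact")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(list(rho = NA_real_, n = n, p = NA_real_))
  }
  if (method == "exact") {
    ct <- stats::cor.test(x, y, method = "spearman",
                          alternative = alternative, exact = TRUE)
    return(list(rho = unname(ct$estimate), n = n, p = ct$p.value))
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- spearman_pvalue(rho, n, alternative)
  list(rho = rho, n = n, p = p)
}

# t-approximation p-value for a Spearman coefficient
spearman_pvalue <- function(rho, n,
                            alternative = c("two.sided", "greater",
                                            "less")) {
  alternative <- match.arg(alternative)
  if (abs(rho) >= 1) {
    t <- sign(rho) * Inf
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
  }
  switch(alternative,
         two.sided = 2 * stats::pt(-abs(t), n - 2),
         greater = stats::pt(t, n - 2, lower.tail = FALSE),
         less = stats::pt(t, n - 2))
}

#' Pearson chi-square test for a 2-by-2 table
#'
#' Without continuity correction, df = 1, two-tailed.
#'
#' @param table 2-by-2 matrix of non-negative counts with positive
#'   margins.
#' @return List with `chi2`, `df` and `p`.
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0)) stop("counts must be non-negative")
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin in 2x2 table")
  e <- outer(rs, cs) / sum(table)
  chi2 <- sum((table - e)^2 / e)
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1L,
                                               lower.tail = FALSE))
}

#' Group comparison of laterality metrics with FDR control
#'
#' One pooled-variance t-test per unit (patient minus control), with
#' Benjamini-Hochberg correction applied within the declared family:
#' either the 12 hemisphere-plus-subnetwork units (`family =
#' "subnet12"`) or the node set (`family = "node"`), per metric per
#' state. Subjects lacking a metric value (e.g. no windows in the
#' state) are dropped pairwise; units with fewer than 2 subjects per
#' group are excluded with a warning.
#'
#' @param metrics a metric table from [build_metric_table()].
#' @param metric `"mli"` or `"lf"`.
#' @param state `"ALL"` or a state id as character.
#' @param family `"subnet12"` or `"node"`.
#' @param group_order length-2 vector (control, patient); the t
#'   statistic is patient minus control.
#' @param alpha FDR level.
#' @param welch use Welch's t-test instead of pooled variance.
#' @return Data frame with one row per unit: group means and SDs, `t`,
#'   `df`, `p`, `q`, `significant`, plus the family metadata.
#' @export
group_compare <- function(metrics, metric = c("mli", "lf"),
                          state = "ALL",
                          family = c("subnet12", "node"),
                          group_order = NULL, alpha = 0.05,
                          welch = FALSE) {
  metric <- match.arg(metric)
  family <- match.arg(family)
  rows <- metrics[metrics$state == state, , drop = FALSE]
  rows <- if (family == "node") {
    rows[rows$unit_level == "node", , drop = FALSE]
  } else {
    rows[rows$unit_level %in% c("hemisphere", "subnetwork"), , drop = FALSE]
  }
  if (nrow(rows) == 0L) stop("no metric rows for state ", state)
  if (is.null(group_order)) {
    gs <- unique(rows$group)
    group_order <- if (setequal(gs, c("NC", "BD"))) c("NC", "BD") else
      sort(gs)
  }
  if (length(group_order) != 2L) stop("exactly two groups required")
  units <- unique(rows[, c("unit_id", "unit_level")])
  res <- lapply(seq_len(nrow(units)), function(i) {
    u <- rows[rows$unit_id == units$unit_id[i] &
                rows$unit_level == units$unit_level[i], ]
    v <- u[[metric]]
    ctrl <- v[u$group == group_order[1L] & is.finite(v)]
    pat <- v[u$group == group_order[2L] & is.finite(v)]
    n_drop <- sum(!is.finite(v))
    if (length(ctrl) < 2L || length(pat) < 2L) {
      warning("unit ", units$unit_id[i],
              " excluded: fewer than 2 subjects per group")
      return(NULL)
    }
    tt <- two_sample_ttest(pat, ctrl, welch = welch)
    data.frame(unit_id = units$unit_id[i],
               unit_level = units$unit_level[i],
               metric = metric, state = state,
               mean_ctrl = mean(ctrl), sd_ctrl = stats::sd(ctrl),
               mean_pat = mean(pat), sd_pat = stats::sd(pat),
               n_ctrl = length(ctrl), n_pat = length(pat),
               n_dropped = n_drop,
               t = tt$t, df = tt$df, p = tt$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    warning("no testable units for ", metric, " in state ", state)
    return(data.frame(unit_id = character(0), unit_level = character(0),
                      metric = character(0), state = character(0),
                      mean_ctrl = numeric(0), sd_ctrl = numeric(0),
                      mean_pat = numeric(0), sd_pat = numeric(0),
                      n_ctrl = integer(0), n_pat = integer(0),
                      n_dropped = integer(0), t = numeric(0),
                      df = numeric(0), p = numeric(0), q = numeric(0),
                      significant = logical(0), family = character(0)))
  }
  adj <- bh_fdr(res$p, alpha)
  res$q <- adj$q
  res$significant <- adj$reject
  res$family <- family
  rownames(res) <- NULL
  res
}

#' Clinical-score correlations for significant units
#'
#' For each selected (unit, metric, state) and each clinical scale,
#' computes the Spearman correlation between the metric and the score
#' across patients (uncorrected p, sidedness configurable — the
#' exploratory convention).
#'
#' @param metrics a metric table from [build_metric_table()].
#' @param scores data frame with `subject_id` and score columns.
#' @param selection data frame with columns `unit_id`, `unit_level`,
#'   `metric`, `state` (e.g. significant rows of [group_compare()]).
#' @param patient_group label of the patient group.
#' @param score_names which score columns to use.
#' @param alternative sidedness passed to [spearman_corr()].
#' @return Data frame with one row per selection-by-score pair: `rho`,
#'   `n`, `p`.
#' @export
clinical_correlations <- function(metrics, scores, selection,
                                  patient_group = "BD",
                                  score_names = c("BPRS", "SANS", "YMRS"),
                                  alternative = "two.sided") {
  if (nrow(selection) == 0L) {
    return(data.frame(unit_id = character(0), unit_level = character(0),
                      metric = character(0), state = character(0),
                      score = character(0), rho = numeric(0),
                      n = integer(0), p = numeric(0)))
  }
  out <- list()
  for (i in seq_len(nrow(selection))) {
    sel <- selection[i, ]
    rows <- metrics[metrics$unit_id == sel$unit_id &
                      metrics$unit_level == sel$unit_level &
                      metrics$state == sel$state &
                      metrics$group == patient_group, ]
    merged <- merge(rows[, c("subject_id", sel$metric)], scores,
                    by = "subject_id")
    for (sc in score_names) {
      v <- merged[[sel$metric]]; s <- merged[[sc]]
      keep <- is.finite(v) & is.finite(s)
      if (sum(keep) < 3L) {
        warning("skipping ", sel$unit_id, " x ", sc,
                ": fewer than 3 complete pairs")
        next
      }
      cr <- spearman_corr(v[keep], s[keep], alternative = alternative)
      out[[length(out) + 1L]] <- data.frame(
        unit_id = sel$unit_id, unit_level = sel$unit_level,
        metric = sel$metric, state = sel$state, score = sc,
        rho = cr$rho, n = cr$n, p = cr$p, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(unit_id = character(0), unit_level = character(0),
                      metric = character(0), state = character(0),
                      score = character(0), rho = numeric(0),
                      n = integer(0), p = numeric(0))
  }
  rownames(res) <- NULL
  res
}

#' Demographics comparison table
#'
#' Group means and SDs with two-tailed t-tests for continuous fields and
#' a chi-square test (no continuity correction) for the gender split.
#' When raw right/left tapping-style counts are given instead of a
#' handedness score, the score is `(Right - Left) / (Right + Left)`.
#'
#' @param demo data frame with columns `subject_id`, `group`, `age`,
#'   `gender` (`"M"`/`"F"`), `education_years`, and either `handscore`
#'   or both `hand_right` and `hand_left`.
#' @param group_order length-2 vector (control, patient).
#' @param welch use Welch's t-test for continuous fields.
#' @return Data frame with one row per variable: per-group summaries and
#'   the p-value.
#' @export
demographics_table <- function(demo, group_order = NULL, welch = FALSE) {
  need <- c("subject_id", "group", "age", "gender", "education_years")
  missing_cols <- setdiff(need, names(demo))
  if (length(missing_cols) > 0L) {
    stop("demographics lack columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (!("handscore" %in% names(demo))) {
    if (!all(c("hand_right", "hand_left") %in% names(demo))) {
      stop("need handscore or hand_right/hand_left columns")
    }
    demo$handscore <- (demo$hand_right - demo$hand_left) /
      (demo$hand_right + demo$hand_left)
  }
  for (cc in c("age", "education_years", "handscore")) {
    if (anyNA(demo[[cc]])) {
      stop("missing ", cc, " for subject(s): ",
           paste(demo$subject_id[is.na(demo[[cc]])], collapse = ", "))
    }
  }
  if (is.null(group_order)) {
    gs <- unique(demo$group)
    group_order <- if (setequal(gs, c("NC", "BD"))) c("NC", "BD") else
      sort(gs)
  }
  g1 <- demo[demo$group == group_order[1L], ]
  g2 <- demo[demo$group == group_order[2L], ]
  cont <- function(varname) {
    tt <- two_sample_ttest(g2[[varname]], g1[[varname]], welch = welch)
    data.frame(
      variable = varname,
      ctrl = sprintf("%.2f ± %.2f", mean(g1[[varname]]),
                     stats::sd(g1[[varname]])),
      pat = sprintf("%.2f ± %.2f", mean(g2[[varname]]),
                    stats::sd(g2[[varname]])),
      p = tt$p, test = "t", stringsAsFactors = FALSE)
  }
  tab <- rbind(cont("age"), cont("education_years"), cont("handscore"))
  counts <- rbind(c(sum(g1$gender == "M"), sum(g1$gender == "F")),
                  c(sum(g2$gender == "M"), sum(g2$gender == "F")))
  cs <- chi_square_2x2(counts)
  gender_row <- data.frame(
    variable = "gender_MF",
    ctrl = sprintf("%d/%d", counts[1L, 1L], counts[1L, 2L]),
    pat = sprintf("%d/%d", counts[2L, 1L], counts[2L, 2L]),
    p = cs$p, test = "chi2", stringsAsFactors = FALSE)
  res <- rbind(tab[1L, ], gender_row, tab[2:3, ])
  names(res)[names(res) == "ctrl"] <- group_order[1L]
  names(res)[names(res) == "pat"] <- group_order[2L]
  rownames(res) <- NULL
  res
}
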