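test_that("pooled t-test matches hand computation and the stats oracle", {
  r <- two_sample_ttest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t, -sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.2878641, tolerance = 1e-6)
  # identical samples: zero statistic by convention
  same <- two_sample_ttest(c(1, 1, 2), c(2, 1, 1))
  expect_equal(same$t, 0)
  # scale invariance
  r2 <- two_sample_ttest(10 * c(1, 2, 3), 10 * c(2, 3, 4))
  expect_equal(r2$t, r$t, tolerance = 1e-12)
  # random-sample agreement with stats::t.test, both variants
  set.seed(14)
  for (i in 1:20) {
    x <- rnorm(sample(3:20, 1)); y <- rnorm(sample(3:20, 1), sd = 2)
    for (w in c(FALSE, TRUE)) {
      mine <- two_sample_ttest(x, y, welch = w)
      ref <- t.test(x, y, var.equal = !w)
      expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-12)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    }
  }
  expect_error(two_sample_ttest(c(1, 1), c(2, 2)), "zero pooled variance")
  expect_error(two_sample_ttest(1, c(1, 2)), "at least 2")
})

test_that("BH step-up matches the textbook procedure", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.2))
  expect_equal(r$reject, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(r$q, p.adjust(c(0.01, 0.02, 0.03, 0.2), "BH"),
               tolerance = 1e-12)
  expect_true(all(bh_fdr(rep(0.01, 10))$reject))
  expect_length(bh_fdr(numeric(0))$q, 0L)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # random vectors against the independent implementation, plus q >= p
  set.seed(15)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    r <- bh_fdr(p)
    expect_equal(r$q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(r$q >= p - 1e-15))
  }
})

test_that("Spearman correlation reproduces the published anchors", {
  # |rho| = 0.320 at n = 48, two-tailed t-approximation
  expect_lt(abs(dynlat:::spearman_pvalue(-0.320, 48) - 0.026), 1e-3)
  # the one-tailed reading of the manic/psychotic-scale results
  expect_lt(abs(dynlat:::spearman_pvalue(0.243, 48, "greater") - 0.048),
            1e-3)
  expect_lt(abs(dynlat:::spearman_pvalue(0.241, 48, "greater") - 0.049),
            1e-3)
  # rank invariance under strictly monotone transforms
  set.seed(16)
  x <- rnorm(30); y <- x^3 + rnorm(30, sd = 0.2)
  base <- spearman_corr(x, y)
  expect_equal(spearman_corr(exp(x), y)$rho, base$rho, tolerance = 1e-12)
  expect_equal(spearman_corr(x, qlogis(plogis(y)))$rho, base$rho,
               tolerance = 1e-12)
  expect_equal(spearman_corr(x, x^5)$rho, 1)
  # agreement with the reference implementation (t-approximation branch)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(base$rho, unname(ref$estimate), tolerance = 1e-12)
  # exact method delegates to the exact null distribution
  xs <- rnorm(8); ys <- rnorm(8)
  ex <- spearman_corr(xs, ys, method = "exact")
  refx <- cor.test(xs, ys, method = "spearman", exact = TRUE)
  expect_equal(ex$p, refx$p.value, tolerance = 1e-12)
  expect_warning(out <- spearman_corr(rep(1, 5), rnorm(5)), "constant")
  expect_true(is.na(out$rho))
  expect_error(spearman_corr(1:2, 2:3), "at least 3")
})

test_that("chi-square without continuity correction matches anchors", {
  r <- chi_square_2x2(rbind(c(26, 22), c(27, 21)))
  expect_equal(round(r$p, 3), 0.837)
  expect_equal(chi_square_2x2(rbind(c(10, 10), c(10, 10)))$chi2, 0)
  expect_equal(chi_square_2x2(rbind(c(10, 10), c(10, 10)))$p, 1)
  strong <- chi_square_2x2(rbind(c(20, 0), c(0, 20)))
  expect_equal(strong$chi2, 40)
  expect_lt(strong$p, 1e-9)
  expect_error(chi_square_2x2(rbind(c(0, 0), c(1, 2))), "zero margin")
  expect_error(chi_square_2x2(matrix(1, 3, 2)), "2x2")
})

test_that("group comparison is deterministic and FDR-disciplined", {
  sc <- small_cohort_metrics(seed = 5)
  g1 <- group_compare(sc$metrics, "mli", "ALL", "subnet12")
  g2 <- group_compare(sc$metrics, "mli", "ALL", "subnet12")
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 12L)
  expect_true(all(g1$q >= g1$p - 1e-15))
  expect_true(all(g1$significant == (g1$q <= 0.05)))
  # patient-minus-control sign convention
  up <- g1$t[g1$unit_id == "AN_R"]
  expect_gt(up, 0)
  # subjects lacking the metric are dropped pairwise; tiny groups excluded
  broken <- sc$metrics
  broken$mli[broken$unit_id == "MAN_L" & broken$group == "BD"][1:7] <- NA
  expect_warning(g3 <- group_compare(broken, "mli", "ALL", "subnet12"),
                 "MAN_L")
  expect_false("MAN_L" %in% g3$unit_id)
})

test_that("planted clinical coupling is recovered on patients", {
  # coupling 0.6 plants a metric-score rank correlation near 0.5 at the
  # default effect heterogeneity; replicate count reduced for runtime
  rhos <- numeric(12)
  for (r in 1:12) {
    spec <- simulation_spec(n_timepoints = 142, n_discard = 0,
                            clinical_coupling = 0.6, seed = 1)
    coh <- simulate_cohort(spec, 48, seed = 300 + r)
    bd <- which(coh$group == "BD")
    mli <- vapply(bd, function(i) {
      ls <- laterality_series(coh$subjects[[i]]$ts, window_spec(50, 1),
                              coh$atlas)
      m <- compute_metrics(aggregate_units(ls, coh$atlas, "subnetwork"))
      m$mli[m$unit_id == "AN_R"]
    }, 0)
    rhos[r] <- spearman_corr(mli, coh$scores$YMRS[bd])$rho
  }
  expect_lt(abs(median(rhos) - 0.5), 0.1)

  # selection plumbing: requested pairs come back with n and p
  sc <- small_cohort_metrics(seed = 6)
  sel <- data.frame(unit_id = "AN_R", unit_level = "subnetwork",
                    metric = "mli", state = "ALL",
                    stringsAsFactors = FALSE)
  cc <- clinical_correlations(sc$metrics, sc$cohort$scores, sel)
  expect_equal(nrow(cc), 3L)
  expect_equal(cc$n, rep(8L, 3))
  expect_true(all(abs(cc$rho) <= 1))
  empty <- clinical_correlations(sc$metrics, sc$cohort$scores, sel[0, ])
  expect_equal(nrow(empty), 0L)
  # constant scores are flagged, not silently correlated
  const_scores <- sc$cohort$scores
  const_scores$BPRS[sc$cohort$group == "BD"] <- 42
  expect_warning(cc2 <- clinical_correlations(sc$metrics, const_scores,
                                              sel), "constant")
  expect_true(is.na(cc2$rho[cc2$score == "BPRS"]))
})

test_that("demographics table reproduces published anchor and contracts", {
  # identical groups: p = 1 throughout
  base <- data.frame(
    subject_id = sprintf("s%02d", 1:8),
    group = rep(c("NC", "BD"), each = 4),
    age = rep(c(30, 40, 35, 28), 2),
    gender = rep(c("M", "M", "F", "F"), 2),
    education_years = rep(c(12, 16, 14, 15), 2),
    handscore = rep(c(0.9, 1, 0.8, 0.95), 2),
    stringsAsFactors = FALSE)
  tab <- demographics_table(base)
  expect_equal(tab$p, rep(1, 4), tolerance = 1e-12)
  # the published gender split
  demo <- data.frame(
    subject_id = sprintf("s%03d", 1:96),
    group = rep(c("NC", "BD"), c(48, 48)),
    age = rnorm(96, 34, 9),
    gender = c(rep("M", 26), rep("F", 22), rep("M", 27), rep("F", 21)),
    education_years = rnorm(96, 15, 2),
    hand_right = 9, hand_left = 0,
    stringsAsFactors = FALSE)
  tab2 <- demographics_table(demo)
  expect_equal(round(tab2$p[tab2$variable == "gender_MF"], 3), 0.837)
  # handedness from raw counts: all-right scores exactly 1
  expect_match(tab2[tab2$variable == "handscore", "NC"], "^1\\.00")
  demo$age[3] <- NA
  expect_error(demographics_table(demo), "s003")
})
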