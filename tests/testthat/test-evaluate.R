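# Validation statistics: Wilson intervals, per-base confusion, concordance
# and cohort summaries.

# independent oracle: invert the binomial score test numerically
score_test_ci <- function(k, n, conf = 0.95) {
  z2 <- qnorm(1 - (1 - conf) / 2)^2
  g <- function(p) (k / n - p)^2 - z2 * p * (1 - p) / n
  hi <- if (k == n) 1 - 1e-9 else k / n - 1e-9
  lower <- if (k == 0) 0 else uniroot(g, c(1e-12, hi), tol = 1e-12)$root
  lo <- if (k == 0) 1e-9 else k / n + 1e-9
  upper <- if (k == n) 1 else uniroot(g, c(lo, 1 - 1e-12), tol = 1e-12)$root
  c(lower, upper)
}

test_that("wilson_ci matches numeric score-test inversion and closed forms", {
  for (case in list(c(8, 10), c(1, 1), c(135, 135), c(0, 20), c(50, 1000))) {
    got <- wilson_ci(case[1], case[2])
    want <- score_test_ci(case[1], case[2])
    expect_equal(unname(got[1, ]), want, tolerance = 1e-6)
  }
  # k = n closed form 1/(1 + z^2/n); strictly increasing in n
  ns <- c(1, 2, 5, 10, 135, 1000, 53399)
  z2 <- qnorm(0.975)^2
  lows <- wilson_ci(ns, ns)[, "lower"]
  expect_equal(lows, 1 / (1 + z2 / ns), tolerance = 1e-12)
  expect_true(all(diff(lows) > 0))
  expect_equal(round(unname(wilson_ci(1, 1)[1, "lower"]), 4), 0.2065)
  # interval always within [0, 1]
  set.seed(1)
  for (i in 1:50) {
    n <- sample(1:500, 1); k <- sample(0:n, 1)
    ci <- wilson_ci(k, n)
    expect_true(ci[1, "lower"] >= 0 && ci[1, "upper"] <= 1 &&
                ci[1, "lower"] <= k / n && k / n <= ci[1, "upper"])
  }
})

test_that("per-base confusion reproduces the panel-validation arithmetic", {
  iv <- data.frame(contig = "c1", start = 0L, end = 53534L)
  set.seed(3)
  pos <- sort(sample.int(53534L, 135L) - 1L)
  truth <- data.frame(contig = "c1", pos = pos, ref = "A", alt = "G",
                      vaf = 0.1, label = paste0("v", seq_along(pos)))
  calls <- data.frame(contig = "c1", pos = pos, ref = "A", alt = "G",
                      filter_status = "PASS")
  conf <- per_base_confusion(calls, truth, iv)
  expect_equal(conf$tp, 135)
  expect_equal(conf$tn, 53399)
  expect_equal(conf$fp, 0)
  expect_equal(conf$fn, 0)
  expect_equal(conf$total, 53534)
  expect_equal(conf$tp + conf$tn + conf$fp + conf$fn, conf$total)

  met <- metrics_with_ci(conf)
  expect_equal(met$point, rep(100, 4))
  sens <- met[met$metric == "sensitivity", ]
  expect_equal(round(sens$lower, 1), 97.2)
  expect_equal(round(sens$upper, 1), 100)
  spec <- met[met$metric == "specificity", ]
  expect_equal(round(spec$lower, 2), 99.99)
})

test_that("per-base confusion handles misses, spurious calls and mismatches", {
  iv <- data.frame(contig = "c1", start = 0L, end = 10L)
  truth1 <- data.frame(contig = "c1", pos = 4L)
  none <- data.frame(contig = character(), pos = integer())
  c0 <- per_base_confusion(none, truth1, iv)
  expect_equal(c(c0$tp, c0$fn, c0$tn, c0$fp), c(0, 1, 9, 0))

  spur <- data.frame(contig = "c1", pos = 7L)
  c1 <- per_base_confusion(spur, data.frame(contig = character(), pos = integer()), iv)
  expect_equal(c(c1$fp, c1$tn), c(1, 9))

  out <- data.frame(contig = "c1", pos = 12L)
  expect_error(per_base_confusion(out, truth1, iv), "region mismatch")
})

test_that("undefined metrics are flagged, never silently 0/0", {
  conf <- confusion_counts(0, 10, 0, 0)
  met <- metrics_with_ci(conf)
  expect_false(met$defined[met$metric == "sensitivity"])
  expect_false(met$defined[met$metric == "precision"])
  expect_true(met$defined[met$metric == "specificity"])
  expect_true(is.na(met$point[met$metric == "sensitivity"]))
})

test_that("vaf_concordance agrees with the brute-force covariance formula", {
  # identity and simple CV checks
  x <- c(4, 5, 8, 16.7, 25)
  id <- vaf_concordance(x, matrix(x, ncol = 1))
  expect_equal(id$pearson_r, 1)
  expect_equal(id$per_variant$cv, rep(NA_real_, 5))  # single replicate: sd NA
  three <- vaf_concordance(c(1, 2, 3), rbind(c(9, 10, 11), c(19, 20, 21),
                                             c(29, 30, 31)))
  expect_equal(three$per_variant$mean, c(10, 20, 30))
  expect_equal(three$per_variant$cv[1], 100 * 1 / 10)

  set.seed(11)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    e <- runif(n); o <- matrix(runif(n * 4), n)
    got <- vaf_concordance(e, o)
    om <- rowMeans(o)
    r_manual <- sum((e - mean(e)) * (om - mean(om))) /
      sqrt(sum((e - mean(e))^2) * sum((om - mean(om))^2))
    expect_equal(got$pearson_r, r_manual, tolerance = 1e-12)
    expect_equal(got$r_squared, r_manual^2, tolerance = 1e-12)
  }

  flat <- vaf_concordance(c(1, 1, 1), matrix(runif(9), 3))
  expect_false(flat$defined)
})

test_that("reported inter-laboratory standard stats are internally consistent", {
  tab <- reference_standard_stats()
  expect_equal(nrow(tab), 12L)
  # correlation of expected vs mean estimates, frozen from the direct
  # covariance formula on the printed pairs
  r <- vaf_concordance(tab$expected_vaf,
                       matrix(tab$interlab_mean, ncol = 1))$pearson_r
  expect_equal(r, 0.9981376, tolerance = 1e-6)
  expect_gte(r, 0.996)
  # printed CVs agree with CVs recomputed from the rounded means/SDs only
  # approximately (rounding of mean and SD propagates into the ratio)
  cv_re <- 100 * tab$interlab_sd / tab$interlab_mean
  expect_true(all(abs(cv_re - tab$interlab_cv) <= 0.15))
})

test_that("cohort summaries reproduce the worked rate examples", {
  # 140 samples of which 130 interpretable -> analyzability 92.9%
  qc_a <- data.frame(
    sample_id = sprintf("s%03d", 1:140),
    delta_qc = 2,
    interpretable = c(rep(TRUE, 130), rep(FALSE, 10)))
  cs <- cohort_summary(qc_a)
  expect_equal(cs$n_interpretable, 130)
  expect_equal(cs$analyzability_pct, 92.9)

  # 38 degraded samples of which 27 interpretable -> 71% rescue
  qc_b <- data.frame(
    sample_id = sprintf("d%02d", 1:38),
    delta_qc = 5,
    interpretable = c(rep(TRUE, 27), rep(FALSE, 11)))
  cs_b <- cohort_summary(qc_b)
  expect_equal(cs_b$n_degraded, 38)
  expect_equal(cs_b$n_degraded_interpretable, 27)
  expect_equal(round(100 * cs_b$rescue), 71)
  expect_equal(cs_b$rescue_pct, 71.1)

  empty <- cohort_summary(qc_a[0, ])
  expect_true(is.na(empty$analyzability))
  expect_true(is.na(empty$rescue))

  # mutation class tallies and diagnosis rates from call sets
  mkcalls <- function(classes) data.frame(
    contig = rep("c", length(classes)), pos = seq_along(classes),
    ref = rep("A", length(classes)), alt = rep("G", length(classes)),
    class = classes, filter_status = rep("PASS", length(classes)))
  sets <- list(s1 = mkcalls(c("SNV", "SNV")), s2 = mkcalls("DEL"),
               s3 = mkcalls(character(0)))
  qc3 <- data.frame(sample_id = c("s1", "s2", "s3"), delta_qc = 1,
                    interpretable = TRUE)
  cs3 <- cohort_summary(qc3, sets)
  expect_equal(cs3$n_mutated_samples, 2L)
  expect_equal(unname(cs3$mutations_by_class[c("SNV", "DEL")]), c(2L, 1L))
  expect_equal(cs3$diagnosis_rate_interpretable, 2 / 3)
})

test_that("percentages round half away from zero", {
  expect_equal(round_half_up(92.85, 1), 92.9)
  expect_equal(round_half_up(71.05, 1), 71.1)
  expect_equal(round_half_up(2.5, 0), 3)
})
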