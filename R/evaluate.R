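# Validation statistics: per-base confusion counts, diagnostic metrics
# with Wilson score confidence intervals, allele-fraction concordance and
# cohort summaries.

#' Wilson score confidence interval for a binomial proportion
#'
#' Obtained by inverting the score test; well-behaved at proportions of 0
#' or 1 (for k = n the lower bound is the closed form `1/(1 + z^2/n)`).
#' This is the interval method whose bounds match the assay's published
#' validation tables; the exact (Clopper-Pearson) interval does not.
#'
#' @param k successes.
#' @param n trials.
#' @param conf confidence level.
#' @return named numeric `c(lower, upper)` (vectorised over `k`, `n`:
#'   a 2-column matrix).
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(all(n > 0), all(k >= 0), all(k <= n))
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  cbind(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

#' Confusion counts over interrogated bases
#'
#' @param tp,tn,fp,fn non-negative nucleotide-position counts.
#' @return a `confusion_counts` list; `total` always equals
#'   `tp + tn + fp + fn`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 total = tp + tn + fp + fn),
            class = "confusion_counts")
}

#' Per-base confusion of PASS calls against truth
#'
#' Positions are compared at nucleotide resolution over the interrogated
#' intervals: TP = truth positions called, FN = truth positions missed,
#' FP = called positions absent from truth, TN = all remaining
#' interrogated positions. Indels count at their left-normalized anchor
#' position.
#'
#' @param calls consensus table (only `PASS` rows are used) or any
#'   data.frame with `contig`, `pos` (and optionally `filter_status`).
#' @param truth truth-variant data.frame.
#' @param interrogated data.frame of intervals (`contig`, `start`, `end`),
#'   0-based half-open.
#' @return a [confusion_counts()].
#' @export
per_base_confusion <- function(calls, truth, interrogated) {
  total <- sum(interrogated$end - interrogated$start)
  inside <- function(contig, pos) {
    vapply(seq_along(pos), function(i)
      any(interrogated$contig == contig[i] & interrogated$start <= pos[i] &
          interrogated$end > pos[i]), logical(1))
  }
  if (nrow(truth) && !all(inside(truth$contig, truth$pos)))
    stop_fmt("truth positions outside the interrogated regions")
  if (!is.null(calls$filter_status))
    calls <- calls[calls$filter_status == "PASS", , drop = FALSE]
  if (nrow(calls) && !all(inside(calls$contig, calls$pos)))
    stop_fmt("call positions outside the interrogated regions (region mismatch)")
  kt <- unique(paste(truth$contig, truth$pos))
  kc <- if (nrow(calls)) unique(paste(calls$contig, calls$pos)) else character()
  tp <- sum(kt %in% kc)
  fn <- length(kt) - tp
  fp <- length(setdiff(kc, kt))
  tn <- total - tp - fn - fp
  confusion_counts(tp, tn, fp, fn)
}

#' Diagnostic metrics with Wilson confidence intervals
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy
#' (TP+TN)/total and precision TP/(TP+FP), each as a percentage with a
#' Wilson score interval. A metric whose denominator is zero is flagged
#' `defined = FALSE` rather than silently reported as 0/0.
#'
#' @param confusion a [confusion_counts()].
#' @param conf confidence level.
#' @return data.frame with `metric`, `point`, `lower`, `upper` (percent)
#'   and `defined`.
#' @export
metrics_with_ci <- function(confusion, conf = 0.95) {
  x <- confusion
  spec <- list(
    sensitivity = c(x$tp, x$tp + x$fn),
    specificity = c(x$tn, x$tn + x$fp),
    accuracy = c(x$tp + x$tn, x$total),
    precision = c(x$tp, x$tp + x$fp))
  rows <- lapply(names(spec), function(nm) {
    k <- spec[[nm]][1]; n <- spec[[nm]][2]
    if (n == 0)
      return(data.frame(metric = nm, point = NA_real_, lower = NA_real_,
                        upper = NA_real_, defined = FALSE))
    ci <- wilson_ci(k, n, conf)
    data.frame(metric = nm, point = 100 * k / n, lower = 100 * ci[1, "lower"],
               upper = 100 * ci[1, "upper"], defined = TRUE)
  })
  do.call(rbind, rows)
}

#' Expected-versus-observed allele-fraction concordance
#'
#' Pearson correlation between the expected fractions and the
#' replicate-mean observed fractions, with per-variant replicate
#' mean, SD (n-1 denominator) and CV% = 100 * SD / mean.
#'
#' @param expected numeric vector of expected fractions (>= 3 values).
#' @param observed matrix or data.frame, one row per variant, one column
#'   per replicate.
#' @return list of class `concordance_stats`: `pearson_r`, `r_squared`,
#'   `p_value`, `per_variant` (mean, sd, cv) and `defined`.
#' @export
vaf_concordance <- function(expected, observed) {
  observed <- as.matrix(observed)
  stopifnot(length(expected) == nrow(observed), length(expected) >= 3L,
            ncol(observed) >= 1L)
  obs_mean <- rowMeans(observed, na.rm = TRUE)
  obs_sd <- apply(observed, 1L, sd, na.rm = TRUE)
  cv <- 100 * obs_sd / obs_mean
  defined <- sd(expected) > 0 && sd(obs_mean) > 0
  if (defined) {
    ct <- cor.test(expected, obs_mean, method = "pearson")
    r <- unname(ct$estimate); pv <- ct$p.value
  } else {
    r <- NA_real_; pv <- NA_real_
  }
  structure(list(pearson_r = r, r_squared = r^2, p_value = pv,
                 per_variant = data.frame(mean = obs_mean, sd = obs_sd, cv = cv),
                 defined = defined),
            class = "concordance_stats")
}

#' @export
print.concordance_stats <- function(x, ...) {
  if (x$defined)
    cat(sprintf("Pearson r = %.4f (R^2 = %.4f), p = %.3g; %d variants\n",
                x$pearson_r, x$r_squared, x$p_value, nrow(x$per_variant)))
  else cat("concordance undefined (zero variance)\n")
  invisible(x)
}

rate_or_na <- function(num, den) if (den > 0) num / den else NA_real_

#' Cohort-level summary
#'
#' Analyzability (interpretable / total), degraded-sample rescue
#' (interpretable among delta-Qc above threshold), molecular diagnosis
#' rates (mutated samples over interpretable samples, and over all
#' samples as an alternative denominator), and mutation counts by class.
#' Percentages are reported rounded half-up to one decimal; raw fractions
#' are retained. Rates with zero denominators are `NA` and flagged.
#'
#' @param qc_records data.frame with at least `delta_qc` and
#'   `interpretable`.
#' @param call_sets optional named list of per-sample consensus tables
#'   (PASS rows are counted).
#' @param routine_mutated optional logical vector: was each sample called
#'   mutated by the routine comparator?
#' @param threshold delta-Qc triage threshold.
#' @return list of class `cohort_summary`.
#' @export
cohort_summary <- function(qc_records, call_sets = NULL,
                           routine_mutated = NULL, threshold = 4) {
  n <- nrow(qc_records)
  n_interp <- sum(qc_records$interpretable, na.rm = TRUE)
  degraded <- qc_records$delta_qc > threshold
  n_degr <- sum(degraded, na.rm = TRUE)
  n_degr_ok <- sum(degraded & qc_records$interpretable, na.rm = TRUE)

  analyzability <- rate_or_na(n_interp, n)
  rescue <- rate_or_na(n_degr_ok, n_degr)

  mut_by_class <- c(SNV = 0L, MNV = 0L, DEL = 0L, INS = 0L)
  n_mut_samples <- NA_integer_
  diagnosis_rate <- NA_real_
  diagnosis_rate_all <- NA_real_
  if (!is.null(call_sets)) {
    pass <- lapply(call_sets, function(cs)
      cs[cs$filter_status == "PASS", , drop = FALSE])
    n_mut_samples <- sum(vapply(pass, nrow, integer(1)) > 0L)
    cls <- unlist(lapply(pass, function(p) p$class))
    if (length(cls)) {
      tab <- table(factor(cls, levels = names(mut_by_class)))
      mut_by_class[] <- as.integer(tab)
    }
    diagnosis_rate <- rate_or_na(n_mut_samples, n_interp)
    diagnosis_rate_all <- rate_or_na(n_mut_samples, n)
  }
  routine_rate <- if (!is.null(routine_mutated))
    rate_or_na(sum(routine_mutated, na.rm = TRUE), n) else NA_real_

  structure(list(
    n_samples = n, n_interpretable = n_interp,
    n_degraded = n_degr, n_degraded_interpretable = n_degr_ok,
    analyzability = analyzability,
    analyzability_pct = round_half_up(100 * analyzability, 1),
    rescue = rescue, rescue_pct = round_half_up(100 * rescue, 1),
    n_mutated_samples = n_mut_samples,
    diagnosis_rate_interpretable = diagnosis_rate,
    diagnosis_rate_interpretable_pct = round_half_up(100 * diagnosis_rate, 1),
    diagnosis_rate_all = diagnosis_rate_all,
    diagnosis_rate_all_pct = round_half_up(100 * diagnosis_rate_all, 1),
    routine_diagnosis_rate = routine_rate,
    mutations_by_class = mut_by_class),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("%d samples: analyzability %s%%, degraded rescue %s%%\n",
              x$n_samples, format(x$analyzability_pct),
              format(x$rescue_pct)))
  if (!is.na(x$n_mutated_samples))
    cat(sprintf("  %d mutated; diagnosis rate %s%% (of interpretable), %s%% (of all)\n",
                x$n_mutated_samples,
                format(x$diagnosis_rate_interpretable_pct),
                format(x$diagnosis_rate_all_pct)))
  invisible(x)
}
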