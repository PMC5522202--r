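# Sample quality triage (delta-Qc) and data-driven depth-cutoff
# determination from dilution series.

#' delta-Qc from a Cq pair
#'
#' @param cq_sample,cq_control qPCR cycle values (`Inf` allowed for a
#'   non-amplifiable sample).
#' @return `cq_sample - cq_control`; infinity propagates.
#' @export
delta_qc <- function(cq_sample, cq_control) {
  stopifnot(is.numeric(cq_sample), is.numeric(cq_control))
  cq_sample - cq_control
}

#' Triage a sample by delta-Qc
#'
#' Samples at or below the threshold are processed as standard; more
#' degraded samples are still processed (`DEGRADED_ATTEMPT`) with a
#' compensating input scale-up of `2^(delta_qc - threshold)`, capped. The
#' boundary `delta_qc == threshold` counts as standard (the degraded class
#' is defined by strict excess). Interpretability is decided later, after
#' sequencing, from median read depth - not here.
#'
#' @param dqc delta-Qc value (may be `Inf`).
#' @param threshold triage threshold (default 4).
#' @param max_scaling cap on the input scale-up factor.
#' @return list with `triage` (`"STANDARD"`/`"DEGRADED_ATTEMPT"`) and
#'   `input_scaling`.
#' @export
triage <- function(dqc, threshold = 4, max_scaling = 16) {
  stopifnot(threshold > 0)
  if (is.na(dqc)) stop_fmt("delta-Qc is NA")
  if (dqc <= threshold) return(list(triage = "STANDARD", input_scaling = 1))
  list(triage = "DEGRADED_ATTEMPT",
       input_scaling = min(2^(dqc - threshold), max_scaling))
}

#' Build a QC record for one sample
#'
#' @param sample_id sample name.
#' @param cq_sample,cq_control qPCR cycle values.
#' @param median_depth named numeric (LIB1, LIB2) median per-amplicon
#'   read-pair depths (NA before sequencing).
#' @param interpretable logical verdict (NA before sequencing).
#' @param threshold triage threshold.
#' @return one-row data.frame.
#' @export
qc_record <- function(sample_id, cq_sample, cq_control,
                      median_depth = c(LIB1 = NA_real_, LIB2 = NA_real_),
                      interpretable = NA, threshold = 4) {
  dqc <- delta_qc(cq_sample, cq_control)
  tr <- triage(dqc, threshold)
  data.frame(sample_id = sample_id, cq_sample = cq_sample,
             cq_control = cq_control, delta_qc = dqc, triage = tr$triage,
             median_depth_lib1 = unname(median_depth[1]),
             median_depth_lib2 = unname(median_depth[2]),
             interpretable = interpretable,
             input_scaling = tr$input_scaling, stringsAsFactors = FALSE)
}

#' Write / read the QC table
#' @param records data.frame of QC records.
#' @param path TSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_qc_table <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_qc_table
#' @export
read_qc_table <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Simulate a dilution series and tally concordance per point
#'
#' Library concentration maps linearly to sequencing depth (the simplest
#' faithful mapping: depth at concentration c is `depth * c / max(conc)`).
#' Each point records the realized median per-amplicon depth (the smaller
#' of the two libraries' medians) and TP/FP/FN of PASS calls against the
#' truth set.
#'
#' @param design a `PanelDesign`.
#' @param variants truth-variant set.
#' @param concentrations nM values, descending (default 4 down to 0.03).
#' @param damage a [damage_model()].
#' @param seqmodel a [sequencing_model()] (its `depth` applies at the top
#'   concentration).
#' @param params a [caller_params()].
#' @param n_molecules molecules per amplicon.
#' @param seed integer seed.
#' @return data.table of `DilutionPoint`s: `concentration`,
#'   `median_depth`, `tp`, `fp`, `fn`.
#' @export
run_dilution_series <- function(design, variants,
                                concentrations = c(4, 2, 1, 0.5, 0.25, 0.12,
                                                   0.06, 0.03),
                                damage = damage_model(),
                                seqmodel = sequencing_model(),
                                params = caller_params(),
                                n_molecules = 2000L, seed = 1L) {
  stopifnot(all(diff(concentrations) < 0), all(concentrations > 0))
  out <- vector("list", length(concentrations))
  for (i in seq_along(concentrations)) {
    sc <- concentrations[i] / max(concentrations)
    pool <- make_sample(design, variants, damage, n_molecules,
                        seed = seed + i, sample_id = sprintf("dil%g", concentrations[i]))
    libs <- simulate_libraries(pool, seqmodel, seed = seed + 100L + i,
                               depth_scale = sc)
    res <- call_sample(libs, design, params)
    cmp <- compare_to_truth(res$consensus, variants)
    out[[i]] <- data.table::data.table(
      concentration = concentrations[i],
      median_depth = min(res$qc$median_depth),
      tp = cmp$tp, fp = cmp$fp, fn = cmp$fn)
  }
  data.table::rbindlist(out)
}

#' Compare PASS consensus calls to a truth set by exact variant key
#' @param consensus consensus-call table.
#' @param truth truth-variant data.frame.
#' @return list with `tp`, `fp`, `fn` and the matched table.
#' @export
compare_to_truth <- function(consensus, truth) {
  pass <- consensus[consensus$filter_status == "PASS", , drop = FALSE]
  kt <- paste(truth$contig, truth$pos, truth$ref, truth$alt)
  kc <- if (nrow(pass)) paste(pass$contig, pass$pos, pass$ref, pass$alt) else
    character()
  list(tp = sum(kt %in% kc), fp = sum(!kc %in% kt), fn = sum(!kt %in% kc),
       detected = kt %in% kc)
}

#' Determine the median read-depth cutoff from a dilution series
#'
#' Scans the series from the highest concentration down and returns the
#' smallest realized median depth within the maximal prefix of fully
#' concordant points (FP = 0 and FN = 0). The returned cutoff is always a
#' realized depth from the series.
#'
#' @param series data.frame of dilution points sorted by concentration
#'   descending (`concentration`, `median_depth`, `tp`, `fp`, `fn`).
#' @return the depth cutoff.
#' @export
determine_depth_cutoff <- function(series) {
  if (is.null(series) || nrow(series) == 0L)
    stop_fmt("empty dilution series")
  if (nrow(series) > 1L && any(diff(series$concentration) >= 0))
    stop_fmt("dilution series must be sorted by concentration, descending")
  conc <- series$fp == 0 & series$fn == 0
  if (!conc[1])
    stop_fmt("no concordant dilution point: sequence deeper before defining a cutoff")
  last <- if (all(conc)) nrow(series) else which(!conc)[1] - 1L
  min(series$median_depth[seq_len(last)])
}
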