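# Orchestration: bundled fixtures, run configuration, end-to-end pipeline,
# and the two canned experiments used for validation (control-sample
# replicates and the simulated per-base validation cohort).

#' Write the bundled fixture set
#'
#' Panel gene table, toy reference FASTA, amplicon manifest (BED6 + primer
#' TSV), the two reference-standard truth sets as VCF, the common-SNP
#' blacklist and a demo run config. Regenerating with the same seed is
#' byte-identical.
#'
#' @param outdir output directory (created if needed).
#' @param seed integer seed.
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(outdir, seed = 1L) {
  if (!dir.exists(outdir))
    if (!dir.create(outdir, recursive = TRUE))
      stop_fmt("cannot create output directory %s", outdir)
  design <- build_demo_panel(seed)
  paths <- c(
    panel = file.path(outdir, "panel_genes.tsv"),
    reference = file.path(outdir, "reference.fa"),
    bed = file.path(outdir, "amplicons.bed"),
    primers = file.path(outdir, "primers.tsv"),
    truq3 = file.path(outdir, "truth_truq3.vcf"),
    ffpe_qm = file.path(outdir, "truth_ffpe_qm.vcf"),
    blacklist = file.path(outdir, "snp_blacklist.tsv"),
    config = file.path(outdir, "demo_config.yaml"))
  write_panel_table(design, paths["panel"])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(design$reference),
                              paths["reference"])
  write_amplicon_manifest(design, paths["bed"], paths["primers"])
  write_truth_vcf(make_reference_standards(design, "TRUQ3"), design,
                  paths["truq3"], seed = seed)
  write_truth_vcf(make_reference_standards(design, "FFPE_QM"), design,
                  paths["ffpe_qm"], seed = seed)
  write.table(attr(design, "snp_blacklist"), paths["blacklist"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- list(seed = as.integer(seed), outdir = "pipeline_out",
              panel_seed = as.integer(seed),
              n_molecules = 2000L,
              samples = list(
                list(id = "truq3_control", standard = "TRUQ3", depth = 1000),
                list(id = "ffpe_control", standard = "FFPE_QM", depth = 2000)),
              params = list(), write_fastq = FALSE)
  yaml::write_yaml(cfg, paths["config"])
  invisible(paths)
}

#' Read and validate a run configuration
#'
#' @param path YAML config path, or an already-parsed list.
#' @return validated config list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$panel_seed <- as.integer(cfg$panel_seed %||% 1L)
  cfg$n_molecules <- as.integer(cfg$n_molecules %||% 2000L)
  cfg$write_fastq <- isTRUE(cfg$write_fastq)
  if (is.null(cfg$outdir)) stop_fmt("run config: 'outdir' is required")
  if (is.null(cfg$samples) || !length(cfg$samples))
    stop_fmt("run config: at least one sample is required")
  for (s in cfg$samples) {
    if (is.null(s$id)) stop_fmt("run config: every sample needs an 'id'")
    std <- s$standard %||% "TRUQ3"
    if (!std %in% c("TRUQ3", "FFPE_QM") && !file.exists(std))
      stop_fmt("run config: sample %s references missing truth file '%s'",
               s$id, std)
  }
  structure(cfg, class = "run_config")
}

#' Run the full pipeline from a configuration
#'
#' simulate -> call -> qc -> evaluate for every configured sample; writes
#' one consensus VCF and one truth VCF per sample, a cohort QC table and a
#' JSON evaluation report. Every output header carries the package
#' version, the seed and a config hash.
#'
#' @param config a config list or YAML path (see [read_run_config()]).
#' @return list with per-sample results and the report path, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
  chash <- object_hash(unclass(cfg))
  design <- build_demo_panel(cfg$panel_seed)
  params <- do.call(caller_params, cfg$params %||% list())
  qcs <- list(); results <- list()
  for (i in seq_along(cfg$samples)) {
    s <- cfg$samples[[i]]
    std <- s$standard %||% "TRUQ3"
    truth <- if (std %in% c("TRUQ3", "FFPE_QM"))
      make_reference_standards(design, std) else read_truth_vcf(std)
    dmg <- if (!is.null(s$delta_qc)) calibrate_fragmentation(design, s$delta_qc)
      else damage_model()
    seed_i <- cfg$seed * 1000L + i
    message(sprintf("[%s] simulate (seed %d)", s$id, seed_i))
    pool <- make_sample(design, truth, dmg, cfg$n_molecules, seed = seed_i,
                        sample_id = s$id)
    qp <- simulate_qpcr(pool)
    sm <- sequencing_model(depth = s$depth %||% 1000)
    libs <- simulate_libraries(pool, sm, seed = seed_i + 500L)
    if (cfg$write_fastq) {
      for (ln in names(libs))
        write_library_fastq(libs[[ln]],
          file.path(cfg$outdir, sprintf("%s_%s_R1.fastq.gz", s$id, ln)),
          file.path(cfg$outdir, sprintf("%s_%s_R2.fastq.gz", s$id, ln)))
    }
    message(sprintf("[%s] call", s$id))
    res <- call_sample(libs, design, params)
    write_consensus_vcf(res$consensus, design,
                        file.path(cfg$outdir, paste0(s$id, ".vcf")),
                        sample_id = s$id, seed = seed_i, config_hash = chash)
    write_truth_vcf(truth, design,
                    file.path(cfg$outdir, paste0(s$id, ".truth.vcf")),
                    seed = seed_i)
    cmp <- compare_to_truth(res$consensus, truth)
    qcs[[i]] <- qc_record(s$id, qp$cq_sample, qp$cq_control,
                          res$qc$median_depth,
                          res$qc$verdict == "INTERPRETABLE")
    results[[s$id]] <- list(truth = truth, consensus = res$consensus,
                            comparison = cmp, qc = res$qc)
  }
  qct <- do.call(rbind, qcs)
  write_qc_table(qct, file.path(cfg$outdir, "qc.tsv"))
  report <- list(
    version = as.character(packageVersion("dstpanel")),
    seed = cfg$seed, config_hash = chash,
    samples = lapply(results, function(r)
      list(n_truth = nrow(r$truth),
           n_pass = sum(r$consensus$filter_status == "PASS"),
           tp = r$comparison$tp, fp = r$comparison$fp, fn = r$comparison$fn,
           median_depth = as.list(r$qc$median_depth),
           verdict = r$qc$verdict)))
  report_path <- file.path(cfg$outdir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(list(results = results, qc = qct, report = report_path))
}

#' Simulate replicate runs of a reference standard
#'
#' Simulates `n_rep` independently seeded samples of a control variant
#' set at a fixed per-library depth, runs the dual-strand caller on each,
#' and collects per-variant PASS status and combined VAF estimates.
#'
#' @param design a `PanelDesign`.
#' @param which `"TRUQ3"` or `"FFPE_QM"`.
#' @param n_rep number of replicates.
#' @param depth per-library per-amplicon read-pair depth.
#' @param base_seed replicate seeds are derived from this.
#' @param damage a [damage_model()].
#' @param params a [caller_params()].
#' @param n_molecules molecules per amplicon.
#' @return list with `truth`, `vaf` (variants x replicates matrix of
#'   combined VAF fractions, NA when not PASS), `pass` (logical matrix)
#'   and `runs` (per-replicate caller output).
#' @export
run_control_replicates <- function(design, which = "TRUQ3", n_rep = 6L,
                                   depth = 1000, base_seed = 1L,
                                   damage = damage_model(),
                                   params = caller_params(),
                                   n_molecules = 2000L) {
  truth <- make_reference_standards(design, which)
  kt <- paste(truth$contig, truth$pos, truth$ref, truth$alt)
  vaf <- matrix(NA_real_, nrow(truth), n_rep,
                dimnames = list(truth$label, paste0("rep", seq_len(n_rep))))
  pass <- matrix(FALSE, nrow(truth), n_rep,
                 dimnames = dimnames(vaf))
  runs <- vector("list", n_rep)
  sm <- sequencing_model(depth = depth)
  for (r in seq_len(n_rep)) {
    s <- base_seed * 1000L + r
    pool <- make_sample(design, truth, damage, n_molecules, seed = 2L * s,
                        sample_id = sprintf("%s_rep%d", tolower(which), r))
    libs <- simulate_libraries(pool, sm, seed = 2L * s + 1L)
    res <- call_sample(libs, design, params)
    cons <- res$consensus
    p <- cons[cons$filter_status == "PASS", ]
    kp <- paste(p$contig, p$pos, p$ref, p$alt)
    m <- match(kt, kp)
    pass[, r] <- !is.na(m)
    vaf[, r] <- p$vaf_combined[m]
    runs[[r]] <- res
  }
  list(truth = truth, vaf = vaf, pass = pass, runs = runs)
}

#' Simulate a per-base validation cohort
#'
#' Re-creates a method-comparison experiment at nucleotide resolution: a
#' set of samples whose interrogated footprints sum to `total_bases`
#' (whole-panel footprints plus one partial sample), carrying
#' `n_variants` truth SNVs at allele fractions drawn from `vaf_range`,
#' each sequenced and called, with per-base confusion accumulated over
#' every sample's interrogated intervals.
#'
#' @param design a `PanelDesign`.
#' @param seed integer seed.
#' @param n_variants total truth variant positions across the cohort.
#' @param total_bases total interrogated nucleotides across the cohort.
#' @param depth per-library read-pair depth per amplicon.
#' @param vaf_range truth allele-fraction range.
#' @param damage a [damage_model()].
#' @param params a [caller_params()].
#' @param n_molecules molecules per amplicon.
#' @return list with `confusion` ([confusion_counts()]), `metrics`
#'   (from [metrics_with_ci()]) and `per_sample` details.
#' @export
run_validation_cohort <- function(design, seed = 1L, n_variants = 135L,
                                  total_bases = 53534L, depth = 500,
                                  vaf_range = c(0.05, 0.40),
                                  damage = damage_model(),
                                  params = caller_params(),
                                  n_molecules = 2000L) {
  tr <- design$target_regions
  widths <- tr$end - tr$start
  panel_bp <- sum(widths)
  n_full <- total_bases %/% panel_bp
  rem <- total_bases - n_full * panel_bp

  full_iv <- data.frame(contig = tr$contig, start = tr$start, end = tr$end)
  sample_iv <- rep(list(full_iv), n_full)
  if (rem > 0L) {
    cw <- cumsum(widths)
    k <- which(cw >= rem)[1]
    part <- full_iv[seq_len(k), , drop = FALSE]
    part$end[k] <- part$end[k] - (cw[k] - rem)
    sample_iv[[n_full + 1L]] <- part
  }
  n_samples <- length(sample_iv)

  with_seed(seed, {
    # allocate variant counts proportionally to footprint size
    bp <- vapply(sample_iv, function(iv) sum(iv$end - iv$start), numeric(1))
    alloc <- floor(n_variants * bp / sum(bp))
    short <- n_variants - sum(alloc)
    if (short > 0L) alloc[seq_len(short)] <- alloc[seq_len(short)] + 1L

    amp <- design$amplicons
    insert_of <- function(contig, pos)
      any(amp$contig == contig & amp$insert_start <= pos & amp$insert_end > pos)

    per_sample <- vector("list", n_samples)
    tp <- tn <- fp <- fn <- 0
    for (si in seq_len(n_samples)) {
      iv <- sample_iv[[si]]
      cand <- do.call(rbind, lapply(seq_len(nrow(iv)), function(j)
        data.frame(contig = iv$contig[j], pos = seq(iv$start[j], iv$end[j] - 1L))))
      keep <- vapply(seq_len(nrow(cand)), function(j)
        insert_of(cand$contig[j], cand$pos[j]), logical(1))
      cand <- cand[keep, , drop = FALSE]
      sel <- integer(0)
      ord <- sample.int(nrow(cand))
      for (j in ord) {
        if (length(sel) >= alloc[si]) break
        near <- cand$contig[sel] == cand$contig[j] &
          abs(cand$pos[sel] - cand$pos[j]) <= 2L
        if (!any(near)) sel <- c(sel, j)
      }
      if (length(sel) < alloc[si])
        stop_fmt("could not place %d variants in sample %d", alloc[si], si)
      refb <- vapply(sel, function(j)
        ref_seg(design$reference[[cand$contig[j]]], cand$pos[j],
                cand$pos[j] + 1L), "")
      truth <- data.frame(
        contig = cand$contig[sel], pos = cand$pos[sel], ref = refb,
        alt = unname(transition_base(refb)),
        vaf = runif(length(sel), vaf_range[1], vaf_range[2]),
        label = sprintf("cohort_s%02d_v%02d", si, seq_along(sel)),
        stringsAsFactors = FALSE)
      sid <- sprintf("cohort_s%02d", si)
      pool <- make_sample(design, truth, damage, n_molecules,
                          seed = seed * 10000L + 2L * si, sample_id = sid)
      libs <- simulate_libraries(pool, sequencing_model(depth = depth),
                                 seed = seed * 10000L + 2L * si + 1L)
      res <- call_sample(libs, design, params)
      pass <- res$consensus[res$consensus$filter_status == "PASS", ]
      # evaluation is restricted to this sample's interrogated intervals
      inside <- vapply(seq_len(nrow(pass)), function(j)
        any(iv$contig == pass$contig[j] & iv$start <= pass$pos[j] &
            iv$end > pass$pos[j]), logical(1))
      pass <- pass[inside, , drop = FALSE]
      conf <- per_base_confusion(pass, truth, iv)
      tp <- tp + conf$tp; tn <- tn + conf$tn
      fp <- fp + conf$fp; fn <- fn + conf$fn
      per_sample[[si]] <- list(sample_id = sid, truth = truth,
                               confusion = conf,
                               verdict = res$qc$verdict)
    }
    confusion <- confusion_counts(tp, tn, fp, fn)
    list(confusion = confusion, metrics = metrics_with_ci(confusion),
         per_sample = per_sample)
  })
}
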