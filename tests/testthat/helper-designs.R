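# Shared fixtures: a miniature single-gene panel for fast simulator/caller
# tests, a cached full demo panel, and a cached fixture directory.

tiny_design <- function(seed = 42L, n_amp = 3L, insert = 80L, primer = 25L,
                        overlap = 24L, n_genes = 1L) {
  dstpanel:::with_seed(seed, {
    amp_rows <- list(); tr_rows <- list()
    refs <- character(0)
    for (g in seq_len(n_genes)) {
      ctg <- paste0("TCTG", g)
      starts <- 60L + (seq_len(n_amp) - 1L) * (insert - overlap)
      clen <- starts[n_amp] + insert + primer + 60L
      refseq <- paste(sample(c("A", "C", "G", "T"), clen, replace = TRUE),
                      collapse = "")
      refs[ctg] <- refseq
      for (j in seq_len(n_amp)) {
        st <- starts[j]
        amp_rows[[length(amp_rows) + 1L]] <- data.frame(
          amplicon_id = sprintf("%s_a%d", ctg, j), contig = ctg,
          fwd_start = st - primer, fwd_end = st,
          insert_start = st, insert_end = st + insert,
          rev_start = st + insert, rev_end = st + insert + primer,
          pool = if (j %% 2L) "FORWARD_POOL" else "REVERSE_POOL",
          stringsAsFactors = FALSE)
      }
      span_end <- starts[n_amp] + insert
      tr_rows[[length(tr_rows) + 1L]] <- data.frame(
        contig = ctg, start = 60L, end = span_end,
        exon_start = 65L, exon_end = span_end - 5L,
        gene = ctg, exon = 1L, stringsAsFactors = FALSE)
    }
    amp <- do.call(rbind, amp_rows)
    amp$fwd_primer <- vapply(seq_len(nrow(amp)), function(i)
      dstpanel:::ref_seg(refs[[amp$contig[i]]], amp$fwd_start[i], amp$fwd_end[i]), "")
    amp$rev_primer <- revcomp(vapply(seq_len(nrow(amp)), function(i)
      dstpanel:::ref_seg(refs[[amp$contig[i]]], amp$rev_start[i], amp$rev_end[i]), ""))
    stopifnot(!anyDuplicated(c(amp$fwd_primer, amp$rev_primer)))
    genes <- data.frame(gene = names(refs), transcript = "NM_TEST.1",
                        stringsAsFactors = FALSE)
    genes$exons <- rep(list(1L), n_genes)
    genes$note <- NA_character_
    panel_design(genes, reference = refs,
                 target_regions = do.call(rbind, tr_rows), amplicons = amp)
  })
}

# SNV placed mid-insert of amplicon `which_amp` on the tiny design
tiny_snv <- function(design, vaf, which_amp = 1L, offset = 0L,
                     label = "snv") {
  a <- design$amplicons[which_amp, ]
  pos <- (a$insert_start + a$insert_end) %/% 2L + offset
  rb <- dstpanel:::ref_seg(design$reference[[a$contig]], pos, pos + 1L)
  data.frame(contig = a$contig, pos = pos, ref = rb,
             alt = unname(dstpanel:::transition_base(rb)), vaf = vaf,
             label = label, stringsAsFactors = FALSE)
}

# cache expensive fixtures for the whole test run
.cache <- new.env(parent = emptyenv())

demo_design <- function() {
  if (is.null(.cache$demo)) .cache$demo <- build_demo_panel(1L)
  .cache$demo
}

fixture_dir <- function() {
  if (is.null(.cache$fixdir)) {
    d <- file.path(tempdir(), "dstp_fixtures")
    write_fixtures(d, seed = 1L)
    .cache$fixdir <- d
  }
  .cache$fixdir
}

# one standard simulated tiny sample, reused across caller tests
tiny_run <- function(truth, seed = 7L, depth = 800, n_mol = 1500L,
                     damage = damage_model(deamination_rate = 0),
                     error_rate = 1e-3,
                     params = caller_params(min_depth = 100L),
                     design = tiny_design()) {
  pool <- make_sample(design, truth, damage, n_mol, seed = seed)
  libs <- simulate_libraries(pool,
                             sequencing_model(depth = depth,
                                              error_rate = error_rate),
                             seed = seed + 1L)
  c(list(pool = pool, libs = libs, design = design, truth = truth),
    call_sample(libs, design, params))
}
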