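# Primer assignment, pileups, per-library calling, consensus and
# left-normalization.

mk_readset <- function(seqs1, seqs2 = NULL, quals1 = NULL, quals2 = NULL,
                       amplicon = NA_character_, lib = "LIB1") {
  n <- length(seqs1)
  if (is.null(seqs2)) seqs2 <- seqs1
  structure(list(sample_id = "t", library_id = lib,
                 reads = data.table::data.table(
                   name = sprintf("t:%s:x:%d", lib, seq_len(n)),
                   amplicon = rep(amplicon, n), hap = NA_integer_,
                   seq1 = seqs1, seq2 = seqs2,
                   qual1 = quals1 %||% strrep("?", nchar(seqs1)),
                   qual2 = quals2 %||% strrep("?", nchar(seqs2)))),
            class = "LibraryReadSet")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("primer assignment: exact match, tolerance boundary, and ties", {
  d <- tiny_design()
  a <- d$amplicons[1, ]
  refseq <- d$reference[[a$contig]]
  template <- dstpanel:::ref_seg(refseq, a$fwd_start, a$rev_end)
  r1 <- substr(template, 1, 100)
  r2 <- substr(revcomp(template), 1, 100)

  asn <- assign_and_trim(mk_readset(r1, r2), d, k = 2L)
  expect_equal(asn$unassigned, 0)
  expect_equal(unique(asn$obs$amplicon_id), a$amplicon_id)
  expect_setequal(asn$obs$side, c("L", "R"))
  lobs <- asn$obs[asn$obs$side == "L"]
  # primer removed: trimmed read starts at the insert
  expect_equal(substr(lobs$seq_top, 1, 10),
               dstpanel:::ref_seg(refseq, a$insert_start, a$insert_start + 10L))
  expect_equal(lobs$ref_start, a$insert_start)
  expect_equal(asn$pair_depth$pairs, 1)

  # mutate k mismatches in the primer -> still assigned; k+1 -> unassigned
  mut <- function(x, npos) {
    for (p in seq_len(npos)) {
      b <- substr(x, p, p)
      substr(x, p, p) <- setdiff(c("A", "C", "G", "T"), b)[1]
    }
    x
  }
  asn2 <- assign_and_trim(mk_readset(mut(r1, 2L), mut(r2, 2L)), d, k = 2L)
  expect_equal(asn2$unassigned, 0)
  asn3 <- assign_and_trim(mk_readset(mut(r1, 3L), mut(r2, 3L)), d, k = 2L)
  expect_equal(asn3$unassigned, 2)

  # duplicate primer across two amplicons -> tie -> discarded
  d2 <- d
  d2$amplicons$fwd_primer[2] <- d2$amplicons$fwd_primer[1]
  asn4 <- assign_and_trim(mk_readset(r1, r1), d2, k = 2L)
  expect_equal(asn4$unassigned, 2)
})

test_that("error-free assignment reproduces the hidden source tags exactly", {
  d <- tiny_design(n_amp = 4L)
  run <- tiny_run(tiny_snv(d, 0.2), depth = 150, n_mol = 200L,
                  error_rate = 0, design = d)
  for (lib in c("lib1", "lib2")) {
    asn <- assign_and_trim(run$libs[[lib]], d)
    expect_equal(asn$unassigned, 0)
    expect_true(all(asn$obs$amplicon_id == asn$obs$true_amplicon))
  }
})

test_that("base-quality floor excludes low-quality bases from the pileup", {
  d <- tiny_design()
  a <- d$amplicons[1, ]
  refseq <- d$reference[[a$contig]]
  template <- dstpanel:::ref_seg(refseq, a$fwd_start, a$rev_end)
  r1 <- substr(template, 1, 100)
  # plant a mismatch at insert offset 10 with quality Q20
  mpos <- (a$insert_start - a$fwd_start) + 11L
  b <- substr(r1, mpos, mpos)
  substr(r1, mpos, mpos) <- setdiff(c("A", "C", "G", "T"), b)[1]
  q1 <- strrep("?", 100)
  substr(q1, mpos, mpos) <- "5"   # Q20
  rs <- mk_readset(rep(r1, 10), rep(substr(revcomp(template), 1, 100), 10),
                   quals1 = rep(q1, 10))
  g_target <- a$insert_start + 10L
  # floor Q20: the substituted base is tallied
  p20 <- build_pileup(assign_and_trim(rs, d), d, caller_params())
  alt20 <- p20$site[p20$site$gpos == g_target]
  expect_equal(sum(alt20[, c("A", "C", "G", "T")] > 0), 2)  # ref + alt allele
  # floor Q25: the Q20 base is dropped from counts and coverage
  p25 <- build_pileup(assign_and_trim(rs, d), d,
                      caller_params(base_quality_floor = 25L))
  alt25 <- p25$site[p25$site$gpos == g_target]
  expect_equal(sum(alt25[, c("A", "C", "G", "T")] > 0), 1)
  expect_lt(alt25$depth, alt20$depth)
})

mk_pileup <- function(site = NULL, indels = NULL, mnv = NULL,
                      pair_depth = NULL, lib = "LIB1") {
  s <- data.table::data.table(
    contig = character(), gpos = integer(), ref = character(),
    A = numeric(), C = numeric(), G = numeric(), T = numeric(),
    delspan = numeric(), depth = numeric())
  if (!is.null(site)) s <- data.table::rbindlist(list(s, site), fill = TRUE)
  if (nrow(s)) data.table::setkey(s, contig, gpos)
  structure(list(
    sample_id = "t", library_id = lib, site = s,
    indels = indels %||% data.table::data.table(
      contig = character(), pos = integer(), ref = character(),
      alt = character(), count = numeric()),
    mnv = mnv %||% data.table::data.table(
      contig = character(), key_ = character(), w = numeric()),
    pair_depth = pair_depth %||% data.table::data.table(
      amplicon_id = character(), pairs = numeric()),
    unassigned = 0), class = "Pileup")
}

test_that("per-library calling applies depth, count and fraction floors", {
  d <- tiny_design()
  site <- data.table::data.table(
    contig = "TCTG1",
    gpos = c(100L, 101L, 102L),
    ref = c("A", "A", "A"),
    A = c(950, 998, 45), C = c(0, 0, 0), G = c(50, 2, 5), T = c(0, 0, 0),
    delspan = 0, depth = c(1000, 1000, 50))
  p <- mk_pileup(site)
  calls <- call_library(p, d, caller_params(min_depth = 100L))
  expect_equal(nrow(calls), 1L)                     # 50/1000 passes
  expect_equal(calls$pos, 100L)
  expect_equal(calls$vaf, 0.05)
  expect_equal(calls$alt_count, 50)
  # 2/1000 fails the count floor; 5/50 fails the depth gate but is flagged
  low <- attr(calls, "low_depth_sites")
  expect_equal(low$pos, 102L)
  # empty pileup -> empty call set
  expect_equal(nrow(call_library(mk_pileup(), d, caller_params())), 0L)
})

test_that("consensus keeps dual-library variants and audits the rest", {
  base <- data.table::data.table(
    contig = "TCTG1", pos = 100L, ref = "A", alt = "G",
    alt_count = 50, depth = 1000, vaf = 0.050, class = "SNV",
    library_id = "LIB1")
  c1 <- data.table::copy(base)
  c2 <- data.table::copy(base); c2$vaf <- 0.052; c2$library_id <- "LIB2"
  art <- data.table::data.table(
    contig = "TCTG1", pos = 200L, ref = "C", alt = "T",
    alt_count = 30, depth = 1000, vaf = 0.03, class = "SNV",
    library_id = "LIB1")
  cons <- consensus_calls(rbind(c1, art), c2)
  pass <- cons[cons$filter_status == "PASS"]
  expect_equal(nrow(pass), 1L)
  expect_equal(pass$vaf_combined, 0.051)
  rej <- cons[cons$filter_status != "PASS"]
  expect_equal(rej$pos, 200L)
  expect_equal(rej$filter_status, "SINGLE_LIBRARY_REJECTED")
  # swapping the library labels leaves the combined VAF unchanged
  cons_sw <- consensus_calls(c2, rbind(c1, art))
  expect_equal(cons_sw[cons_sw$filter_status == "PASS"]$vaf_combined,
               pass$vaf_combined)
  # empty inputs -> empty output
  expect_equal(nrow(consensus_calls(c1[0], c2[0])), 0L)
  # pooled combination is available as an alternative
  cp <- consensus_calls(c1, c2, params = caller_params(vaf_combine = "pooled"))
  expect_equal(cp[cp$filter_status == "PASS"]$vaf_combined, 100 / 2000)
})

test_that("interpretability gates on the median depth of both libraries", {
  d <- tiny_design(n_amp = 3L)
  pd <- function(x) data.table::data.table(
    amplicon_id = d$amplicons$amplicon_id, pairs = x)
  p1k <- mk_pileup(pair_depth = pd(c(1000, 1000, 1000)))
  p699 <- mk_pileup(pair_depth = pd(c(699, 699, 699)), lib = "LIB2")
  p12 <- mk_pileup(pair_depth = pd(c(1200, 1200, 1200)), lib = "LIB2")
  expect_equal(sample_interpretability(p1k, p12, d)$verdict, "INTERPRETABLE")
  expect_equal(sample_interpretability(p1k, p699, d)$verdict,
               "NOT_INTERPRETABLE")
  expect_equal(
    sample_interpretability(p1k, p699, d,
                            caller_params(depth_cutoff = 1e-9))$verdict,
    "INTERPRETABLE")
  # an amplicon with no reads counts as zero depth
  p_missing <- mk_pileup(pair_depth = pd(c(1000, 1000, 1000))[1:2])
  med <- sample_interpretability(p_missing, p12, d)$median_depth
  expect_equal(unname(med["LIB1"]), 1000)
})

test_that("error-free calls equal truth exactly (oracle equivalence)", {
  d <- tiny_design(n_amp = 4L)
  truth <- rbind(tiny_snv(d, 0.05, 1L, label = "low"),
                 tiny_snv(d, 0.40, 3L, label = "high"))
  run <- tiny_run(truth, seed = 17L, depth = 1000, n_mol = 1000L,
                  error_rate = 0, design = d)
  pass <- run$consensus[run$consensus$filter_status == "PASS"]
  expect_equal(nrow(pass), 2L)
  cmp <- compare_to_truth(run$consensus, truth)
  expect_equal(c(cmp$tp, cmp$fp, cmp$fn), c(2, 0, 0))
  # PASS calls are a subset of both libraries' call sets
  key <- function(x) paste(x$contig, x$pos, x$ref, x$alt)
  expect_true(all(key(pass) %in% key(run$calls1)))
  expect_true(all(key(pass) %in% key(run$calls2)))
})

test_that("a jackpot-inflated artifact site is still strand-confined", {
  d <- tiny_design()
  a <- d$amplicons[2, ]
  refseq <- d$reference[[a$contig]]
  mid <- (a$insert_start + a$insert_end) %/% 2L
  art_pos <- mid + which(strsplit(dstpanel:::ref_seg(refseq, mid, mid + 20L),
                                  "")[[1]] == "C")[1] - 1L
  jp <- data.frame(contig = a$contig, pos = art_pos, strand = "fwd", rate = 0.10)
  run <- tiny_run(NULL, seed = 33L, depth = 600, n_mol = 500L,
                  damage = damage_model(deamination_rate = 0, jackpot = jp),
                  params = caller_params(min_depth = 50L), design = d)
  hit <- run$consensus[run$consensus$pos == art_pos & run$consensus$alt == "T"]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$filter_status, "SINGLE_LIBRARY_REJECTED")
  expect_true(is.na(hit$vaf_lib2))
  expect_gt(hit$vaf_lib1, 0.05)
})

test_that("deletions and insertions are recovered at their spiked fractions", {
  d <- tiny_design(n_amp = 3L, insert = 90L)
  refseq <- d$reference[["TCTG1"]]
  a <- d$amplicons[1, ]
  dp <- a$insert_start + 20L
  del <- within(list(), {
    v <- normalize_variant(refseq, dp, dstpanel:::ref_seg(refseq, dp, dp + 16L),
                           dstpanel:::ref_seg(refseq, dp, dp + 1L))
  })$v
  del_df <- data.frame(contig = "TCTG1", pos = del$pos, ref = del$ref,
                       alt = del$alt, vaf = 0.08, label = "del15")
  ip <- d$amplicons[3, ]$insert_start + 30L
  ib <- dstpanel:::ref_seg(refseq, ip, ip + 1L)
  ins <- normalize_variant(refseq, ip, ib, paste0(ib, "ACGTA"))
  ins_df <- data.frame(contig = "TCTG1", pos = ins$pos, ref = ins$ref,
                       alt = ins$alt, vaf = 0.15, label = "ins5")
  truth <- rbind(del_df, ins_df)
  run <- tiny_run(truth, seed = 19L, depth = 1000, n_mol = 2000L, design = d)
  pass <- run$consensus[run$consensus$filter_status == "PASS"]
  cmp <- compare_to_truth(run$consensus, truth)
  expect_equal(c(cmp$tp, cmp$fp, cmp$fn), c(2, 0, 0))
  vd <- pass[pass$class == "DEL"]$vaf_combined
  vi <- pass[pass$class == "INS"]$vaf_combined
  expect_lt(abs(vd - 0.08), 0.03)
  expect_lt(abs(vi - 0.15), 0.04)
})

test_that("a true MNV is merged while independent neighbours stay split", {
  d <- tiny_design()
  a <- d$amplicons[2, ]
  refseq <- d$reference[[a$contig]]
  pos <- a$insert_start + 25L
  rr <- dstpanel:::ref_seg(refseq, pos, pos + 2L)
  aa <- paste0(dstpanel:::transition_base(substr(rr, 1, 1)),
               dstpanel:::transition_base(substr(rr, 2, 2)))
  mnv <- data.frame(contig = a$contig, pos = pos, ref = rr, alt = aa,
                    vaf = 0.20, label = "mnv2")
  run <- tiny_run(mnv, seed = 23L, depth = 800, n_mol = 1000L, design = d)
  pass <- run$consensus[run$consensus$filter_status == "PASS"]
  expect_equal(nrow(pass), 1L)
  expect_equal(pass$class, "MNV")
  expect_equal(pass$ref, rr)
  expect_equal(pass$alt, aa)
  expect_lt(abs(pass$vaf_combined - 0.20), 0.06)
})

# brute-force oracle: the leftmost minimal equivalent representation of a
# variant within a window, by exhaustive enumeration
brute_normalize <- function(win, pos, ref, alt) {
  apply_v <- function(p, r, a)
    paste0(substr(win, 1, p), a, substring(win, p + nchar(r) + 1))
  hap <- apply_v(pos, ref, alt)
  best <- NULL
  for (p in 0:(nchar(win) - 1)) {
    for (lr in 1:(nchar(win) - p)) {
      la <- lr + nchar(alt) - nchar(ref)
      if (la < 1) next
      r2 <- substr(win, p + 1, p + lr)
      h2 <- apply_v(p, r2, "")
      # alt implied by requiring the haplotype to match
      a2_len <- nchar(hap) - nchar(win) + lr
      if (a2_len != la) next
      a2 <- substr(hap, p + 1, p + la)
      if (r2 == a2) next
      # only minimal representations compete: no shared suffix, and no
      # shared prefix beyond the single anchor base indels require
      if (substr(r2, lr, lr) == substr(a2, la, la)) next
      if (lr > 1 && la > 1 && substr(r2, 1, 1) == substr(a2, 1, 1)) next
      if (apply_v(p, r2, a2) == hap) {
        cand <- list(pos = p, ref = r2, alt = a2)
        if (is.null(best) || cand$pos < best$pos ||
            (cand$pos == best$pos && nchar(cand$ref) < nchar(best$ref)))
          best <- cand
      }
    }
  }
  best
}

test_that("left-normalization is idempotent and position-minimal", {
  set.seed(77)
  for (i in 1:40) {
    win <- paste(sample(c("A", "T"), 20, replace = TRUE), collapse = "")
    pos <- sample(5:12, 1)
    if (i %% 2 == 0) {  # deletion
      len <- sample(1:4, 1)
      ref <- substr(win, pos + 1, pos + 1 + len)
      alt <- substr(win, pos + 1, pos + 1)
    } else {            # insertion
      ref <- substr(win, pos + 1, pos + 1)
      alt <- paste0(ref, paste(sample(c("A", "T"), sample(1:3, 1),
                                      replace = TRUE), collapse = ""))
    }
    if (ref == alt) next
    got <- normalize_variant(win, pos, ref, alt)
    again <- normalize_variant(win, got$pos, got$ref, got$alt)
    expect_equal(again, got)            # idempotent
    want <- brute_normalize(win, pos, ref, alt)
    expect_equal(got$pos, want$pos)     # leftmost
    expect_equal(got$ref, want$ref)
    expect_equal(got$alt, want$alt)
  }
})
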