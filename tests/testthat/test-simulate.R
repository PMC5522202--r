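# Template-pool and read-library simulation: purity in the error-free
# limit, allele-fraction calibration, strand confinement of damage, qPCR
# arithmetic and byte-level determinism.

test_that("with damage and errors off, no template carries a non-truth allele", {
  d <- tiny_design()
  truth <- tiny_snv(d, 0.3)
  pool <- make_sample(d, truth, damage_model(deamination_rate = 0),
                      n_molecules = 300L, seed = 3L)
  for (pa in pool$amplicons) {
    refamp <- dstpanel:::ref_seg(d$reference[[pa$contig]], pa$fwd_start,
                                 pa$rev_end)
    alt_hap <- refamp
    if (nrow(pa$variants)) {
      lp <- pa$variants$pos[1] - pa$fwd_start
      substr(alt_hap, lp + 1L, lp + 1L) <- pa$variants$alt[1]
    }
    expect_true(all(pa$hap_seqs %in% c(refamp, alt_hap)))
    # both strands of one molecule share the haplotype
    expect_equal(pa$fwd_hap, pa$rev_hap)
  }
})

test_that("target_vaf = 1 fixes the variant on every molecule", {
  d <- tiny_design()
  truth <- tiny_snv(d, 1.0)
  pool <- make_sample(d, truth, n_molecules = 200L, seed = 4L)
  pa <- pool$amplicons[[1]]
  expect_equal(nrow(pa$variants), 1L)
  expect_true(all(pa$carriage))
})

test_that("variants outside the panel footprint are rejected by name", {
  d <- tiny_design()
  bad <- data.frame(contig = "TCTG1", pos = 5L, ref = "A", alt = "G",
                    vaf = 0.1, label = "off_target")
  bad$ref <- dstpanel:::ref_seg(d$reference[["TCTG1"]], 5L, 6L)
  expect_error(make_sample(d, bad), "off_target")
  bad2 <- data.frame(contig = "chrZ", pos = 100L, ref = "A", alt = "G",
                     vaf = 0.1, label = "no_contig")
  expect_error(make_sample(d, bad2), "no_contig")
  # ref-allele mismatch is caught
  v <- tiny_snv(d, 0.1)
  v$ref <- setdiff(c("A", "C", "G", "T"), v$ref)[1]
  expect_error(make_sample(d, v), "does not match reference")
})

test_that("emitted read-pair counts concentrate around depth x amplicons x 2", {
  d <- tiny_design(n_amp = 10L, n_genes = 2L)   # 20 amplicons
  pool <- make_sample(d, NULL, n_molecules = 200L, seed = 5L)
  libs <- simulate_libraries(pool, sequencing_model(depth = 500), seed = 6L)
  n <- nrow(libs$lib1$reads) + nrow(libs$lib2$reads)
  expect_lt(abs(n - 2 * 20 * 500), 5 * sqrt(2 * 20 * 500))
  # depth scaling emulates library dilution
  libs_dil <- simulate_libraries(pool, sequencing_model(depth = 1000),
                                 seed = 7L, depth_scale = 0.03 / 4)
  per_amp <- nrow(libs_dil$lib1$reads) / 20
  expect_lt(abs(per_amp - 7.5), 3)
})

test_that("library reads derive exclusively from their own strand's templates", {
  d <- tiny_design()
  pool <- make_sample(d, NULL, damage_model(deamination_rate = 0.02),
                      n_molecules = 300L, seed = 8L)
  libs <- simulate_libraries(pool, sequencing_model(depth = 300), seed = 9L)
  for (pa in pool$amplicons) {
    strands <- vapply(pa$hap_meta, function(h)
      if (is.null(h$damage)) "none" else h$damage$strand[1], "")
    fwd_damaged <- which(strands == "fwd")
    rev_damaged <- which(strands == "rev")
    h1 <- libs$lib1$reads[libs$lib1$reads$amplicon == pa$amplicon_id]$hap
    h2 <- libs$lib2$reads[libs$lib2$reads$amplicon == pa$amplicon_id]$hap
    expect_false(any(h1 %in% rev_damaged))
    expect_false(any(h2 %in% fwd_damaged))
  }
})

test_that("observed allele fractions are binomially consistent with truth", {
  d <- tiny_design()
  p <- 0.10
  for (seed in c(21L, 22L, 23L)) {
    run <- tiny_run(tiny_snv(d, p), seed = seed, depth = 500, n_mol = 2000L,
                    design = d)
    est <- run$consensus[run$consensus$filter_status == "PASS" &
                         run$consensus$pos == run$truth$pos]$vaf_combined
    expect_length(est, 1L)
    se <- sqrt(p * (1 - p) * (1 / 2000 + 1 / 1000))
    expect_lt(abs(est - p), 4 * se)
  }
})

test_that("qPCR Cq arithmetic anchors the delta-Qc scale", {
  mkpool <- function(f) structure(list(amplifiable_fraction = f),
                                  class = "TemplatePool")
  expect_equal(simulate_qpcr(mkpool(1), mkpool(1))$delta_qc, 0)
  expect_equal(simulate_qpcr(mkpool(1 / 16), mkpool(1))$delta_qc, 4)
  q0 <- simulate_qpcr(mkpool(0), mkpool(1))
  expect_equal(q0$cq_sample, Inf)
  expect_equal(q0$delta_qc, Inf)
  expect_equal(triage(q0$delta_qc)$triage, "DEGRADED_ATTEMPT")
})

test_that("fragmentation calibration hits requested delta-Qc bands", {
  d <- tiny_design(n_amp = 6L)
  dm_mid <- calibrate_fragmentation(d, 6.6)
  pool <- make_sample(d, NULL, dm_mid, n_molecules = 3000L, seed = 10L)
  dq <- simulate_qpcr(pool)$delta_qc
  expect_gt(dq, 4.3); expect_lt(dq, 10.1)
  # monotone: more fragmentation => larger delta-Qc
  dm_hi <- calibrate_fragmentation(d, 10.1)
  pool_hi <- make_sample(d, NULL, dm_hi, n_molecules = 3000L, seed = 10L)
  expect_gt(simulate_qpcr(pool_hi)$delta_qc, dq)
  # presets cover the triage-band endpoints
  pres <- damage_presets(d, c(1, 4.3))
  expect_named(pres, c("dq1", "dq4.3"))
  expect_gt(pres$dq1$fragment_length_mean, pres$dq4.3$fragment_length_mean)
})

test_that("identical seeds give byte-identical FASTQ output", {
  d <- tiny_design()
  dir <- withr::local_tempdir()
  md5 <- function(tag) {
    pool <- make_sample(d, tiny_snv(d, 0.2), n_molecules = 150L, seed = 12L)
    libs <- simulate_libraries(pool, sequencing_model(depth = 150), seed = 13L)
    f1 <- file.path(dir, paste0(tag, "_R1.fastq.gz"))
    f2 <- file.path(dir, paste0(tag, "_R2.fastq.gz"))
    write_library_fastq(libs$lib1, f1, f2)
    unname(tools::md5sum(c(f1, f2)))
  }
  expect_identical(md5("a"), md5("b"))
})

test_that("FASTQ files round-trip through the reader", {
  d <- tiny_design()
  pool <- make_sample(d, NULL, n_molecules = 100L, seed = 14L,
                      sample_id = "rt")
  libs <- simulate_libraries(pool, sequencing_model(depth = 50), seed = 15L)
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "r1.fastq.gz"); f2 <- file.path(dir, "r2.fastq.gz")
  write_library_fastq(libs$lib1, f1, f2)
  back <- read_library_fastq(f1, f2)
  expect_equal(back$sample_id, "rt")
  expect_equal(back$library_id, "LIB1")
  expect_equal(back$reads$seq1, libs$lib1$reads$seq1)
  expect_equal(back$reads$seq2, libs$lib1$reads$seq2)
  expect_equal(back$reads$qual1, libs$lib1$reads$qual1)
  expect_equal(back$reads$name, libs$lib1$reads$name)
  expect_equal(back$reads$amplicon, libs$lib1$reads$amplicon)
})

test_that("reference standards mirror the two control-sample compositions", {
  d <- demo_design()
  tq <- make_reference_standards(d, "TRUQ3")
  expect_equal(nrow(tq), 12L)
  expect_equal(sum(tq$vaf >= 0.04 & tq$vaf <= 0.05), 7L)
  dels <- tq[nchar(tq$ref) > nchar(tq$alt), ]
  expect_setequal(nchar(dels$ref) - nchar(dels$alt), c(15L, 1L))
  expect_equal(max(tq$vaf), 0.30)

  fq <- make_reference_standards(d, "FFPE_QM")
  expect_equal(min(fq$vaf), 0.01)
  expect_true(any(nchar(fq$ref) - nchar(fq$alt) == 15L & fq$vaf == 0.02))
  expect_true(any(fq$vaf == 0.03 & nchar(fq$ref) == 1L))
  # both sets satisfy the simulator's placement preconditions
  expect_silent(make_sample(d, tq, n_molecules = 2L, seed = 1L))
  expect_silent(make_sample(d, fq, n_molecules = 2L, seed = 1L))
})
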