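# Synthetic panel fixtures.
#
# The assay's real genomic coordinates are not redistributable, so the demo
# panel fabricates one toy contig per gene whose exon structure matches the
# published 16-gene/48-exon actionable target list. Amplicons tile each
# padded exon with short (120-150 bp) amplicons, 22-30 base primers and
# >= 1 base tiling overlap, and the merged target footprint is calibrated
# to the assay's theoretical on-target size of 8,870 bp. Everything is a
# deterministic function of the seed.

#' The 16-gene actionable solid-tumour target list
#'
#' Gene symbols, reference transcripts and hotspot exons recommended for
#' routine solid-tumour genotyping (lung, colorectal, melanoma, GIST);
#' 48 exon-level targets over 16 genes.
#'
#' @return data.frame with columns `gene`, `transcript`, `exons` (list
#'   column), `note`.
#' @export
panel_gene_table <- function() {
  rows <- list(
    list("AKT1",   "NM_001014431.1", 3L,                              NA),
    list("ALK",    "NM_004304.1",    c(23L, 24L, 25L),                NA),
    list("BRAF",   "NM_004333.4",    c(11L, 15L),                     NA),
    list("EGFR",   "NM_005228.3",    c(18L, 19L, 20L, 21L),           NA),
    list("ERBB2",  "NM_004448.2",    20L,                             NA),
    list("ERBB4",  "NM_005235.2",    c(10L, 12L),                     "E452K and R393W"),
    list("FGFR2",  "NM_000141.4",    c(7L, 12L, 14L),                 "S252, N549, K659"),
    list("FGFR3",  "NM_000142.4",    c(7L, 9L, 14L),                  "R248 to S249 and G370 to Y373"),
    list("HRAS",   "NM_005343.2",    c(2L, 3L, 4L),                   NA),
    list("KIT",    "NM_000222.2",    c(8L, 9L, 11L, 13L, 17L, 18L),   NA),
    list("KRAS",   "NM_033360.2",    c(2L, 3L, 4L),                   NA),
    list("MAP2K1", "NM_002755.3",    2L,                              NA),
    list("MET",    "NM_001127500.1", c(2L, 14L, 15L, 16L, 17L, 18L, 19L, 20L), NA),
    list("NRAS",   "NM_002524.3",    c(2L, 3L, 4L),                   NA),
    list("PDGFRA", "NM_006206.4",    c(12L, 14L, 18L),                NA),
    list("PIK3CA", "NM_006218.2",    c(10L, 21L),                     NA))
  genes <- data.frame(gene = vapply(rows, `[[`, "", 1),
                      transcript = vapply(rows, `[[`, "", 2),
                      stringsAsFactors = FALSE)
  genes$exons <- lapply(rows, `[[`, 3)
  genes$note <- vapply(rows, function(r) as.character(r[[4]]), "")
  genes
}

# Per-exon tiling plan: number of amplicons, insert length I and tiling
# overlap o so that the covered region length is R = c*I - (c-1)*o.
# Constraints keep amplicon totals in [120,150] after adding 22-30 base
# primers (I in [76,90]) and exon sizes within 60-220 bp.
draw_exon_plan <- function(n_amplicons) {
  c_ <- n_amplicons
  if (c_ == 1L) {
    I <- sample(76:90, 1L); o <- 0L
  } else if (c_ == 4L) {
    I <- sample(76:78, 1L)
    omin <- max(18L, as.integer(ceiling((4L * I - 230L) / 3)))
    o <- sample(omin:28L, 1L)
  } else {
    I <- sample(76:90, 1L)
    omin <- max(18L, as.integer(ceiling((c_ * I - 230L) / (c_ - 1L))))
    o <- sample(omin:28L, 1L)
  }
  list(c = c_, I = I, o = o)
}

plan_region_len <- function(p) p$c * p$I - (p$c - 1L) * p$o

# Nudge insert lengths (and, if needed, tiling overlaps) so the merged
# target footprint hits total_bp exactly. Inserts may shrink to 72 bp
# during calibration; primer draws compensate to keep amplicons >= 120 bp.
calibrate_plans <- function(plans, total_bp) {
  total <- sum(vapply(plans, plan_region_len, integer(1)))
  imax <- function(p) if (p$c == 4L) min(90L, (230L + 3L * p$o) %/% 4L) else 90L
  for (pass in 1:400) {
    if (total == total_bp) break
    moved <- FALSE
    for (i in seq_along(plans)) {
      p <- plans[[i]]
      if (total - total_bp >= p$c && p$I > 72L) {
        plans[[i]]$I <- p$I - 1L; total <- total - p$c; moved <- TRUE
      } else if (total_bp - total >= p$c && p$I < imax(p)) {
        plans[[i]]$I <- p$I + 1L; total <- total + p$c; moved <- TRUE
      } else if (p$c > 1L) {
        step <- p$c - 1L
        if (total - total_bp >= step && p$o < 28L) {
          plans[[i]]$o <- p$o + 1L; total <- total - step; moved <- TRUE
        } else if (total_bp - total >= step && p$o > 18L &&
                   p$c * p$I - (p$c - 1L) * (p$o - 1L) <= 230L) {
          plans[[i]]$o <- p$o - 1L; total <- total + step; moved <- TRUE
        }
      }
      if (total == total_bp) break
    }
    if (!moved) break
  }
  if (total != total_bp)
    stop_fmt("footprint calibration failed: reached %d, wanted %d", total, total_bp)
  plans
}

#' Build the bundled demo panel design
#'
#' Fabricates a toy multi-contig reference (one contig per gene), tiles the
#' 48 exon targets with exactly 150 amplicons obeying the default design
#' constraints, and returns the complete `PanelDesign`. Deterministic in
#' `seed`.
#'
#' @param seed integer RNG seed.
#' @param total_target_bp merged target footprint to calibrate to, in bp.
#' @return a `PanelDesign` with genes, reference, target regions,
#'   amplicons and a `snp_blacklist` attribute.
#' @export
build_demo_panel <- function(seed = 1L, total_target_bp = 8870L) {
  with_seed(seed, {
    genes <- panel_gene_table()
    exon_tab <- data.frame(
      gene = rep(genes$gene, lengths(genes$exons)),
      exon = unlist(genes$exons))
    n_exons <- nrow(exon_tab)  # 48
    # amplicons per exon: 4x1 + 6x2 + 18x3 + 20x4 = 150
    counts <- sample(rep(c(1L, 2L, 3L, 4L), c(4L, 6L, 18L, 20L)))
    plans <- lapply(counts, draw_exon_plan)
    plans <- calibrate_plans(plans, total_target_bp)

    pad <- c(5L, 5L)
    amp_rows <- list()
    tr_rows <- list()
    contig_len <- integer(0)
    contig_seq <- character(0)
    for (g in genes$gene) {
      ex_idx <- which(exon_tab$gene == g)
      pos <- 150L
      for (k in ex_idx) {
        p <- plans[[k]]
        R <- plan_region_len(p)
        tr_rows[[length(tr_rows) + 1L]] <- data.frame(
          contig = g, start = pos, end = pos + R,
          exon_start = pos + pad[1], exon_end = pos + R - pad[2],
          gene = g, exon = exon_tab$exon[k], stringsAsFactors = FALSE)
        starts <- pos + (seq_len(p$c) - 1L) * (p$I - p$o)
        for (j in seq_len(p$c)) {
          p1 <- sample(22:30, 1L); p2 <- sample(22:30, 1L)
          # keep the primer-inclusive length within [120, 150]
          while (p$I + p1 + p2 > 150L) { if (p1 > p2) p1 <- p1 - 1L else p2 <- p2 - 1L }
          while (p$I + p1 + p2 < 120L) { if (p1 < p2) p1 <- p1 + 1L else p2 <- p2 + 1L }
          st <- starts[j]
          amp_rows[[length(amp_rows) + 1L]] <- data.frame(
            amplicon_id = sprintf("%s_e%02d_a%d", g, exon_tab$exon[k], j),
            contig = g,
            fwd_start = st - p1, fwd_end = st,
            insert_start = st, insert_end = st + p$I,
            rev_start = st + p$I, rev_end = st + p$I + p2,
            pool = if (j %% 2L == 1L) "FORWARD_POOL" else "REVERSE_POOL",
            stringsAsFactors = FALSE)
        }
        pos <- pos + R + 120L
      }
      contig_len[g] <- pos + 30L
      contig_seq[g] <- paste(sample(c("A", "C", "G", "T"), contig_len[g],
                                    replace = TRUE), collapse = "")
    }
    amp <- do.call(rbind, amp_rows)
    tr <- do.call(rbind, tr_rows)

    # Nudge primer footprints into a comfortable GC band (0.25-0.75) by
    # flipping bases; footprints never overlap each other so fixes commute.
    for (i in seq_len(nrow(amp))) {
      for (iv in list(c(amp$fwd_start[i], amp$fwd_end[i]),
                      c(amp$rev_start[i], amp$rev_end[i]))) {
        ctg <- amp$contig[i]
        repeat {
          seg <- ref_seg(contig_seq[ctg], iv[1], iv[2])
          gc <- gc_fraction(seg)
          if (gc >= 0.25 && gc <= 0.75) break
          chars <- strsplit(seg, "")[[1]]
          if (gc < 0.25) {
            at <- which(chars %in% c("A", "T"))[1]
            chars[at] <- c("G", "C")[1L + at %% 2L]
          } else {
            cg <- which(chars %in% c("G", "C"))[1]
            chars[cg] <- c("A", "T")[1L + cg %% 2L]
          }
          substr(contig_seq[ctg], iv[1] + 1L, iv[2]) <- paste(chars, collapse = "")
        }
      }
    }

    amp$fwd_primer <- vapply(seq_len(nrow(amp)), function(i)
      ref_seg(contig_seq[amp$contig[i]], amp$fwd_start[i], amp$fwd_end[i]), "")
    amp$rev_primer <- revcomp(vapply(seq_len(nrow(amp)), function(i)
      ref_seg(contig_seq[amp$contig[i]], amp$rev_start[i], amp$rev_end[i]), ""))
    if (anyDuplicated(c(amp$fwd_primer, amp$rev_primer)))
      stop_fmt("fixture generator produced duplicate primer sequences; change the seed")

    # common-SNP blacklist placed in insert interiors, away from every
    # primer footprint on the contig
    in_primer <- function(ctg, pos) {
      ac <- amp[amp$contig == ctg, ]
      any((pos >= ac$fwd_start & pos < ac$fwd_end) |
          (pos >= ac$rev_start & pos < ac$rev_end))
    }
    pick <- seq(3L, nrow(amp), by = 5L)
    blk_pos <- integer(0); blk_ctg <- character(0)
    for (i in pick) {
      mid <- (amp$insert_start[i] + amp$insert_end[i]) %/% 2L
      for (off in 0:40) {
        cand <- mid + ifelse(off %% 2L == 0L, off %/% 2L, -(off %/% 2L + 1L))
        if (cand >= amp$insert_start[i] && cand < amp$insert_end[i] &&
            !in_primer(amp$contig[i], cand)) {
          blk_pos <- c(blk_pos, cand); blk_ctg <- c(blk_ctg, amp$contig[i])
          break
        }
      }
    }
    blk <- data.frame(contig = blk_ctg, pos = blk_pos, stringsAsFactors = FALSE)

    d <- panel_design(genes, reference = contig_seq, target_regions = tr,
                      amplicons = amp)
    attr(d, "snp_blacklist") <- blk
    attr(d, "seed") <- as.integer(seed)
    d
  })
}

# Deterministic variant-site search. A usable site of length `len` must lie
# inside at least one amplicon insert with `margin` bases to spare, must be
# fully inside or fully outside every insert (no boundary straddling, which
# the simulator rejects), and must not intrude on `avoid` intervals.
find_variant_site <- function(design, gene, len, margin = 4L,
                              avoid = NULL, skip_amplicons = 0L) {
  amp <- design$amplicons[design$amplicons$contig == gene, , drop = FALSE]
  if (nrow(amp) == 0L) stop_fmt("no amplicons on contig %s", gene)
  skipped <- 0L
  for (i in seq_len(nrow(amp))) {
    lo <- amp$insert_start[i] + margin
    hi <- amp$insert_end[i] - len - margin
    if (hi < lo) next
    for (pos in lo:hi) {
      iv <- c(pos, pos + len)
      ok <- TRUE
      for (j in seq_len(nrow(amp))) {
        s <- amp$insert_start[j]; e <- amp$insert_end[j]
        inside <- iv[1] >= s + margin && iv[2] <= e - margin
        outside <- iv[2] <= s || iv[1] >= e
        if (!inside && !outside) { ok <- FALSE; break }
      }
      if (ok && !is.null(avoid) && nrow(avoid) > 0L) {
        clash <- avoid$contig == gene &
          avoid$start < iv[2] + 8L & avoid$end > iv[1] - 8L
        if (any(clash)) ok <- FALSE
      }
      if (ok) {
        if (skipped < skip_amplicons) { skipped <- skipped + 1L; break }
        return(pos)
      }
    }
  }
  stop_fmt("no variant site of length %d found on %s", len, gene)
}

transition_base <- function(b)
  c(A = "G", G = "A", C = "T", T = "C")[b]

#' Reference-standard variant sets
#'
#' Returns truth variants emulating the two quantitative multiplex control
#' samples used to validate the assay:
#' * `"TRUQ3"` - a non-degraded 12-variant standard: ten SNVs (two adjacent
#'   pairs mimicking neighbouring hotspot codons), one 15-bp deletion and
#'   one 1-bp deletion, with expected allele fractions from 4.0% to 30.0%
#'   (seven variants between 4% and 5%).
#' * `"FFPE_QM"` - an FFPE-derived multiplex control whose lowest spike-in
#'   is a 1% SNV, with a 15-bp deletion at 2% and an SNV at 3% plus
#'   higher-fraction endogenous-like variants.
#'
#' Positions are placed deterministically inside amplicon inserts of the
#' matching gene contigs; alt alleles are transitions of the local
#' reference base.
#'
#' @param design a full `PanelDesign` (e.g. [build_demo_panel()]).
#' @param which `"TRUQ3"` or `"FFPE_QM"`.
#' @return data.frame of truth variants: `contig`, `pos` (0-based), `ref`,
#'   `alt`, `vaf`, `label`.
#' @export
make_reference_standards <- function(design, which = c("TRUQ3", "FFPE_QM")) {
  which <- match.arg(which)
  refv <- design$reference
  used <- data.frame(contig = character(), start = integer(), end = integer())
  out <- list()
  note_used <- function(contig, pos, len)
    used <<- rbind(used, data.frame(contig = contig, start = pos, end = pos + len))

  add_snv <- function(gene, vaf, label, offset_from = NULL) {
    pos <- if (is.null(offset_from))
      find_variant_site(design, gene, 1L, avoid = used)
    else offset_from
    rb <- ref_seg(refv[gene], pos, pos + 1L)
    out[[length(out) + 1L]] <<- data.frame(
      contig = gene, pos = pos, ref = rb, alt = unname(transition_base(rb)),
      vaf = vaf, label = label, stringsAsFactors = FALSE)
    note_used(gene, pos, 1L)
    pos
  }
  add_del <- function(gene, dlen, vaf, label) {
    pos <- find_variant_site(design, gene, dlen + 1L, margin = 6L, avoid = used)
    v <- normalize_variant(refv[gene], pos,
                           ref_seg(refv[gene], pos, pos + dlen + 1L),
                           ref_seg(refv[gene], pos, pos + 1L))
    out[[length(out) + 1L]] <<- data.frame(
      contig = gene, pos = v$pos, ref = v$ref, alt = v$alt,
      vaf = vaf, label = label, stringsAsFactors = FALSE)
    note_used(gene, v$pos, nchar(v$ref))
    v$pos
  }
  add_pair <- function(gene, gap, vaf1, vaf2, lab1, lab2) {
    pos <- find_variant_site(design, gene, gap + 1L, avoid = used)
    add_snv(gene, vaf1, lab1, offset_from = pos)
    add_snv(gene, vaf2, lab2, offset_from = pos + gap)
  }

  if (which == "TRUQ3") {
    # adjacent hotspot pair on BRAF (codon-600-like), 4% and 8%
    add_pair("BRAF", 1L, 0.040, 0.080, "BRAF_V600M_like", "BRAF_V600E_like")
    add_del("EGFR", 15L, 0.042, "EGFR_E746_A750del_like")
    add_snv("MET", 0.040, "MET_Y1253D_like")
    add_del("MET", 1L, 0.200, "MET_L238fs_like")
    # codon-12/13-like pair on KRAS, 4 bases apart
    add_pair("KRAS", 4L, 0.050, 0.250, "KRAS_G12S_like", "KRAS_G13D_like")
    add_snv("KRAS", 0.050, "KRAS_A146T_like")
    add_snv("NRAS", 0.050, "NRAS_Q61H_like")
    add_snv("PIK3CA", 0.050, "PIK3CA_E542K_like")
    add_snv("PIK3CA", 0.300, "PIK3CA_H1047R_like")
    add_snv("EGFR", 0.167, "EGFR_G719S_like")
  } else {
    add_snv("EGFR", 0.010, "EGFR_T790M_like")
    add_del("EGFR", 15L, 0.020, "EGFR_E746_A750del_like")
    add_snv("EGFR", 0.030, "EGFR_L858R_like")
    add_snv("EGFR", 0.245, "EGFR_G719S_like")
    add_snv("KRAS", 0.060, "KRAS_G12D_like")
    add_snv("KRAS", 0.150, "KRAS_G13D_like")
    add_snv("BRAF", 0.105, "BRAF_V600E_like")
    add_snv("KIT", 0.100, "KIT_D816V_like")
    add_snv("NRAS", 0.125, "NRAS_Q61K_like")
    add_snv("PIK3CA", 0.090, "PIK3CA_E545K_like")
    add_snv("PIK3CA", 0.175, "PIK3CA_H1047R_like")
  }
  do.call(rbind, out)
}

#' Published inter-laboratory summaries for the 12-variant standard
#'
#' Expected droplet-PCR allele fractions and the reported two-laboratory
#' mean/SD/CV of the NGS estimates for the commercial 12-variant multiplex
#' reference standard. Used for concordance regression tests; CV values
#' recomputed from the rounded means and SDs can differ from the printed
#' CVs by up to about 0.05.
#'
#' @return data.frame with columns `label`, `expected_vaf`,
#'   `interlab_mean`, `interlab_sd`, `interlab_cv`.
#' @export
reference_standard_stats <- function() {
  data.frame(
    label = c("BRAF_V600M_like", "EGFR_E746_A750del_like", "MET_Y1253D_like",
              "KRAS_A146T_like", "KRAS_G12S_like", "NRAS_Q61H_like",
              "PIK3CA_E542K_like", "BRAF_V600E_like", "EGFR_G719S_like",
              "MET_L238fs_like", "KRAS_G13D_like", "PIK3CA_H1047R_like"),
    expected_vaf = c(4.0, 4.2, 4.0, 5.0, 5.0, 5.0, 5.0, 8.0, 16.7, 20.0, 25.0, 30.0),
    interlab_mean = c(4.01, 4.06, 4.44, 5.02, 5.07, 4.87, 5.71, 7.30, 16.01,
                      19.97, 25.80, 28.71),
    interlab_sd = c(0.37, 0.39, 0.38, 0.55, 0.43, 0.86, 0.80, 0.33, 0.51,
                    0.45, 2.16, 0.55),
    interlab_cv = c(9.16, 9.64, 8.45, 10.86, 8.46, 17.70, 14.05, 4.56, 3.22,
                    2.26, 8.38, 1.93),
    stringsAsFactors = FALSE)
}
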