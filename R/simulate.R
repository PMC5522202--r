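# FFPE-like sample simulator.
#
# Each amplicon target captures its own pool of double-stranded source
# molecules (extension-ligation chemistry captures each target
# independently). Every molecule contributes one forward-strand and one
# reverse-strand template; truth variants are applied per molecule to both
# strands, while cytosine deamination hits single strands only: C>T on the
# forward template, or G>A in top-strand coordinates when the damaged
# cytosine sits on the reverse strand. This asymmetry is exactly what the
# dual-library consensus exploits downstream. Primer footprints are
# synthesised from the oligo, so variants and damage are only realised
# inside amplicon inserts.

#' FFPE damage model
#'
#' @param deamination_rate per-cytosine, per-single-strand probability of a
#'   C->T conversion. The default 3e-4 is a stand-in (no published rate is
#'   available for this assay) chosen so that per-site artifact fractions
#'   stay well below a 1% true-variant allele fraction.
#' @param fragment_length_mean lognormal mean fragment length, bp.
#' @param fragment_length_sdlog lognormal sdlog of fragment length.
#' @param crosslink_failure_rate per-molecule probability that crosslinking
#'   blocks amplification outright.
#' @param jackpot optional data.frame (`contig`, `pos`, `strand`
#'   ("fwd"/"rev"), `rate`) inflating deamination at chosen sites, for
#'   stress-testing the consensus filter (a crude PCR-jackpot analogue).
#' @return a `damage_model` list.
#' @export
damage_model <- function(deamination_rate = 3e-4,
                         fragment_length_mean = 3000,
                         fragment_length_sdlog = 0.35,
                         crosslink_failure_rate = 0,
                         jackpot = NULL) {
  stopifnot(deamination_rate >= 0, deamination_rate <= 1,
            crosslink_failure_rate >= 0, crosslink_failure_rate <= 1,
            fragment_length_mean > 0, fragment_length_sdlog > 0)
  structure(list(deamination_rate = deamination_rate,
                 fragment_length_mean = fragment_length_mean,
                 fragment_length_sdlog = fragment_length_sdlog,
                 crosslink_failure_rate = crosslink_failure_rate,
                 jackpot = jackpot),
            class = "damage_model")
}

#' Sequencing model
#'
#' @param error_rate per-base substitution error rate (must be < 0.01).
#' @param read_length bases per read; paired 2 x `read_length` cycles.
#' @param depth target read-pair count per amplicon per library.
#' @param depth_size negative-binomial size for per-amplicon depth
#'   dispersion (`Inf` gives Poisson depths).
#' @return a `sequencing_model` list.
#' @export
sequencing_model <- function(error_rate = 1e-3, read_length = 100L,
                             depth = 1000, depth_size = 80) {
  stopifnot(error_rate >= 0, error_rate < 0.01, read_length > 0, depth >= 0)
  structure(list(error_rate = error_rate,
                 read_length = as.integer(read_length),
                 depth = depth, depth_size = depth_size),
            class = "sequencing_model")
}

# map a haplotype-local coordinate back to the reference, given the
# variants (design-level rows) applied to this haplotype
hap_to_ref_pos <- function(local, fs, applied) {
  g <- fs + local
  if (nrow(applied) == 0L) return(g)
  for (i in seq_len(nrow(applied))) {
    # alt block of variant i occupies hap coords [vstart, vstart+nchar(alt))
    vstart <- applied$pos[i] - fs + applied$shift_before[i]
    la <- nchar(applied$alt[i]); lr <- nchar(applied$ref[i])
    if (local >= vstart + la) g <- g - (la - lr) else if (local >= vstart)
      return(applied$pos[i])  # inside the alt block: anchor position
  }
  g
}

validate_truth_variants <- function(design, variants) {
  if (is.null(variants) || nrow(variants) == 0L)
    return(data.frame(contig = character(), pos = integer(), ref = character(),
                      alt = character(), vaf = numeric(), label = character(),
                      stringsAsFactors = FALSE))
  amp <- design$amplicons
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    lab <- v$label %||% sprintf("%s:%d", v$contig, v$pos)
    if (nchar(v$ref) == 0L || nchar(v$alt) == 0L)
      stop_fmt("variant %s: empty allele", lab)
    if (is.na(v$vaf) || v$vaf <= 0 || v$vaf > 1)
      stop_fmt("variant %s: target VAF %s outside (0,1]", lab, format(v$vaf))
    if (!v$contig %in% names(design$reference))
      stop_fmt("variant %s is outside the panel footprint (unknown contig %s)",
               lab, v$contig)
    seg <- ref_seg(design$reference[[v$contig]], v$pos, v$pos + nchar(v$ref))
    if (!identical(seg, v$ref))
      stop_fmt("variant %s: ref allele '%s' does not match reference '%s'",
               lab, v$ref, seg)
    a <- amp[amp$contig == v$contig, , drop = FALSE]
    iv <- c(v$pos, v$pos + nchar(v$ref))
    inside <- iv[1] >= a$insert_start & iv[2] <= a$insert_end
    straddle <- !inside & iv[1] < a$insert_end & iv[2] > a$insert_start
    if (!any(inside))
      stop_fmt("variant %s is outside the panel footprint (no amplicon insert contains it)",
               lab)
    if (any(straddle))
      stop_fmt("variant %s straddles an amplicon insert boundary (%s)",
               lab, paste(a$amplicon_id[straddle], collapse = ","))
  }
  variants
}

#' Build a template pool for one sample
#'
#' Draws `n_molecules` double-stranded source molecules per amplicon,
#' assigns each truth variant to molecules with probability `vaf` (both
#' strands of a carrier molecule), removes molecules whose drawn fragment
#' length is shorter than their template or that fail crosslink filtering,
#' and applies single-strand deamination damage. Fully deterministic in
#' `seed`.
#'
#' @param design a `PanelDesign` with reference and amplicons.
#' @param variants truth-variant data.frame (`contig`, `pos`, `ref`, `alt`,
#'   `vaf`, `label`), or `NULL` for a wild-type pool.
#' @param damage a [damage_model()].
#' @param n_molecules molecules per amplicon.
#' @param seed integer seed.
#' @param sample_id sample identifier carried into read names.
#' @return a `TemplatePool`.
#' @export
make_sample <- function(design, variants = NULL, damage = damage_model(),
                        n_molecules = 2000L, seed = 1L, sample_id = "sample") {
  variants <- validate_truth_variants(design, variants)
  amp <- design$amplicons
  with_seed(seed, {
    pools <- vector("list", nrow(amp))
    names(pools) <- amp$amplicon_id
    total_mol <- 0L
    total_surv <- 0L
    for (i in seq_len(nrow(amp))) {
      a <- amp[i, ]
      refseq <- design$reference[[a$contig]]
      amp_seq <- ref_seg(refseq, a$fwd_start, a$rev_end)
      p1 <- a$insert_start - a$fwd_start
      p2 <- a$rev_end - a$insert_end
      vi <- which(variants$contig == a$contig &
                  variants$pos >= a$insert_start &
                  variants$pos + nchar(variants$ref) <= a$insert_end)
      av <- variants[vi, , drop = FALSE]
      k <- nrow(av)

      carriage <- if (k) matrix(runif(n_molecules * k) < rep(av$vaf, each = n_molecules),
                                nrow = n_molecules) else
        matrix(FALSE, nrow = n_molecules, ncol = 0L)
      sig <- if (k) 1L + as.integer(carriage %*% (2^(seq_len(k) - 1L))) else
        rep(1L, n_molecules)

      sigs <- sort(unique(sig))
      hap_seqs <- character(0)
      hap_meta <- list()   # per hap: sig, strand damage events (gpos, alt)
      sig_hap <- integer(max(sigs))
      sig_applied <- vector("list", max(sigs))
      for (s in sigs) {
        bits <- which(bitwAnd(s - 1L, 2^(seq_len(max(k, 1L)) - 1L)) > 0L)
        hs <- amp_seq
        app <- av[bits, , drop = FALSE]
        if (nrow(app)) {
          app <- app[order(app$pos, decreasing = TRUE), , drop = FALSE]
          for (j in seq_len(nrow(app))) {
            lp <- app$pos[j] - a$fwd_start
            stopifnot(substr(hs, lp + 1L, lp + nchar(app$ref[j])) == app$ref[j])
            hs <- paste0(substr(hs, 1L, lp), app$alt[j],
                         substring(hs, lp + nchar(app$ref[j]) + 1L))
          }
          app <- app[order(app$pos), , drop = FALSE]
          app$shift_before <- cumsum(c(0L, head(nchar(app$alt) - nchar(app$ref), -1L)))
        } else app$shift_before <- integer(0)
        hap_seqs <- c(hap_seqs, hs)
        hap_meta[[length(hap_meta) + 1L]] <-
          list(sig = s, damage = NULL)
        sig_hap[s] <- length(hap_seqs)
        sig_applied[[s]] <- app
      }

      # fragmentation / crosslink survival (template length depends on indels)
      hap_len <- nchar(hap_seqs)
      mol_len <- hap_len[sig_hap[sig]]
      fraglen <- rlnorm(n_molecules, meanlog = log(damage$fragment_length_mean),
                        sdlog = damage$fragment_length_sdlog)
      surv <- fraglen >= mol_len &
        runif(n_molecules) >= damage$crosslink_failure_rate

      fwd_hap <- sig_hap[sig]
      rev_hap <- sig_hap[sig]

      # single-strand deamination (insert portion only; primers are oligo)
      d <- damage$deamination_rate
      for (strand in c("fwd", "rev")) {
        target_base <- if (strand == "fwd") "C" else "G"
        conv_base <- if (strand == "fwd") "T" else "A"
        # candidate positions per signature (hap-local, insert part only)
        cand <- lapply(sigs, function(s) {
          hs <- hap_seqs[sig_hap[s]]
          loc <- which(strsplit(hs, "")[[1]] == target_base)
          loc[loc > p1 & loc <= nchar(hs) - p2]
        })
        names(cand) <- as.character(sigs)
        ncand <- vapply(cand, length, integer(1))[as.character(sig)]
        ndam <- ifelse(surv & d > 0, rbinom(n_molecules, ncand, d), 0L)
        # site-specific jackpot inflation
        jp <- damage$jackpot
        jp_here <- NULL
        if (!is.null(jp)) {
          jp_here <- jp[jp$contig == a$contig & jp$strand == strand &
                        jp$pos >= a$insert_start & jp$pos < a$insert_end, ,
                        drop = FALSE]
        }
        hit <- which(ndam > 0L)
        jp_mol <- list()
        if (!is.null(jp_here) && nrow(jp_here)) {
          for (r in seq_len(nrow(jp_here))) {
            sel <- which(surv & runif(n_molecules) < jp_here$rate[r])
            jp_mol[[r]] <- sel
            hit <- union(hit, sel)
          }
        }
        for (m in hit) {
          s <- sig[m]
          loc_all <- cand[[as.character(s)]]
          loc <- if (ndam[m] > 0L)
            sort(sample(loc_all, min(ndam[m], length(loc_all)))) else integer(0)
          if (length(jp_mol)) {
            for (r in seq_along(jp_mol)) if (m %in% jp_mol[[r]]) {
              # jackpot pos is a reference coordinate; map to hap-local
              app <- sig_applied[[s]]
              lp <- jp_here$pos[r] - a$fwd_start
              if (nrow(app)) for (q in seq_len(nrow(app)))
                if (app$pos[q] < jp_here$pos[r])
                  lp <- lp + nchar(app$alt[q]) - nchar(app$ref[q])
              lp <- lp + 1L  # 1-based local
              if (substr(hap_seqs[sig_hap[s]], lp, lp) == target_base)
                loc <- sort(union(loc, lp))
            }
          }
          if (!length(loc)) next
          hs <- hap_seqs[if (strand == "fwd") fwd_hap[m] else rev_hap[m]]
          # damage applies to the strand's own template; start from base hap
          hs <- hap_seqs[sig_hap[s]]
          for (lp in loc) substr(hs, lp, lp) <- conv_base
          hap_seqs <- c(hap_seqs, hs)
          gpos <- vapply(loc, function(lp)
            hap_to_ref_pos(lp - 1L, a$fwd_start, sig_applied[[s]]), integer(1))
          hap_meta[[length(hap_meta) + 1L]] <- list(
            sig = s,
            damage = data.frame(strand = strand, gpos = gpos,
                                ref = target_base, alt = conv_base,
                                stringsAsFactors = FALSE))
          if (strand == "fwd") fwd_hap[m] <- length(hap_seqs) else
            rev_hap[m] <- length(hap_seqs)
        }
      }

      total_mol <- total_mol + n_molecules
      total_surv <- total_surv + sum(surv)
      pools[[i]] <- list(
        amplicon_id = a$amplicon_id, contig = a$contig,
        fwd_start = a$fwd_start, insert_start = a$insert_start,
        insert_end = a$insert_end, rev_end = a$rev_end,
        hap_seqs = hap_seqs, hap_meta = hap_meta,
        fwd_hap = fwd_hap, rev_hap = rev_hap, surv = surv,
        variants = av, carriage = carriage)
    }
    structure(list(sample_id = sample_id, design = design, damage = damage,
                   n_molecules = n_molecules, amplicons = pools,
                   variants = variants,
                   amplifiable_fraction = total_surv / max(total_mol, 1L),
                   seed = as.integer(seed)),
              class = "TemplatePool")
  })
}

#' @export
print.TemplatePool <- function(x, ...) {
  cat(sprintf("TemplatePool '%s': %d amplicons x %d molecules, amplifiable fraction %.3g\n",
              x$sample_id, length(x$amplicons), x$n_molecules,
              x$amplifiable_fraction))
  invisible(x)
}

apply_read_errors <- function(seqs, quals, e, q_err = "5") {
  if (e <= 0 || length(seqs) == 0L) return(list(seqs = seqs, quals = quals))
  nch <- nchar(seqs)
  k <- rbinom(length(seqs), nch, e)
  idx <- which(k > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(nch[i], k[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      alt <- sample(setdiff(bases, cur), 1L)
      substr(seqs[i], p, p) <- alt
      substr(quals[i], p, p) <- q_err
    }
  }
  list(seqs = seqs, quals = quals)
}

#' Simulate the two strand-specific libraries of a sample
#'
#' Per amplicon and per library, the number of read pairs is drawn around
#' the target depth (negative binomial), molecules are sampled with
#' replacement from the surviving templates of the matching strand, and
#' 2 x `read_length` paired reads are emitted with substitution errors at
#' the configured rate. Library LIB1 reads derive only from forward-strand
#' templates, LIB2 only from reverse-strand templates. Correct bases carry
#' Q30 ("?"), substituted bases Q20 ("5").
#'
#' @param pool a `TemplatePool` from [make_sample()].
#' @param seqmodel a [sequencing_model()].
#' @param seed integer seed.
#' @param depth_scale multiplier on the target depth (dilution series use
#'   depth proportional to library concentration).
#' @return list of two `LibraryReadSet` objects (`lib1`, `lib2`).
#' @export
simulate_libraries <- function(pool, seqmodel = sequencing_model(), seed = 1L,
                               depth_scale = 1) {
  stopifnot(inherits(pool, "TemplatePool"))
  rl <- seqmodel$read_length
  with_seed(seed, {
    out <- list()
    for (lib in c("LIB1", "LIB2")) {
      acc <- vector("list", length(pool$amplicons))
      serial <- 0L
      for (i in seq_along(pool$amplicons)) {
        pa <- pool$amplicons[[i]]
        survived <- which(pa$surv)
        mu <- seqmodel$depth * depth_scale
        n_pairs <- if (length(survived) == 0L || mu <= 0) 0L else
          if (is.infinite(seqmodel$depth_size)) rpois(1L, mu) else
            rnbinom(1L, mu = mu, size = seqmodel$depth_size)
        if (n_pairs == 0L) next
        mol <- survived[sample.int(length(survived), n_pairs, replace = TRUE)]
        hid <- if (lib == "LIB1") pa$fwd_hap[mol] else pa$rev_hap[mol]
        uh <- unique(hid)
        tops <- pa$hap_seqs[uh]
        rcs <- revcomp(tops)
        if (lib == "LIB1") {
          r1u <- substr(tops, 1L, rl); r2u <- substr(rcs, 1L, rl)
        } else {
          r1u <- substr(rcs, 1L, rl); r2u <- substr(tops, 1L, rl)
        }
        m <- match(hid, uh)
        acc[[i]] <- data.table::data.table(
          name = sprintf("%s:%s:%s:%d", pool$sample_id, lib, pa$amplicon_id,
                         serial + seq_len(n_pairs)),
          amplicon = pa$amplicon_id, hap = hid,
          seq1 = r1u[m], seq2 = r2u[m])
        serial <- serial + n_pairs
      }
      reads <- data.table::rbindlist(acc)
      if (nrow(reads)) {
        reads[, `:=`(qual1 = strrep("?", nchar(seq1)),
                     qual2 = strrep("?", nchar(seq2)))]
        e1 <- apply_read_errors(reads$seq1, reads$qual1, seqmodel$error_rate)
        e2 <- apply_read_errors(reads$seq2, reads$qual2, seqmodel$error_rate)
        reads[, `:=`(seq1 = e1$seqs, qual1 = e1$quals,
                     seq2 = e2$seqs, qual2 = e2$quals)]
      } else {
        reads <- data.table::data.table(
          name = character(), amplicon = character(), hap = integer(),
          seq1 = character(), seq2 = character(),
          qual1 = character(), qual2 = character())
      }
      out[[tolower(lib)]] <- structure(
        list(sample_id = pool$sample_id, library_id = lib, reads = reads),
        class = "LibraryReadSet")
    }
    out
  })
}

#' @export
print.LibraryReadSet <- function(x, ...) {
  cat(sprintf("LibraryReadSet %s/%s: %d read pairs\n",
              x$sample_id, x$library_id, nrow(x$reads)))
  invisible(x)
}

#' qPCR quality assay on a template pool
#'
#' Cq = Cq0 - log2(amplifiable fraction), where the amplifiable fraction is
#' the proportion of molecules that pass the fragmentation and crosslink
#' filters. The control Cq uses an undamaged reference pool (fraction 1
#' when `reference_pool` is omitted). A fully non-amplifiable pool yields
#' `Inf`, which downstream triage must handle.
#'
#' @param pool sample `TemplatePool`.
#' @param reference_pool optional undamaged control `TemplatePool`.
#' @param cq0 baseline cycle value.
#' @return list with `cq_sample`, `cq_control` and `delta_qc`.
#' @export
simulate_qpcr <- function(pool, reference_pool = NULL, cq0 = 24) {
  f_s <- pool$amplifiable_fraction
  f_c <- if (is.null(reference_pool)) 1 else reference_pool$amplifiable_fraction
  cq <- function(f) if (f <= 0) Inf else cq0 - log2(f)
  cqs <- cq(f_s); cqc <- cq(f_c)
  list(cq_sample = cqs, cq_control = cqc, delta_qc = delta_qc(cqs, cqc))
}

#' Calibrate fragmentation to a target delta-Qc
#'
#' Solves for the lognormal mean fragment length whose expected template
#' survival over the design's amplicon lengths equals `2^-target_delta_qc`.
#'
#' @param design a `PanelDesign`.
#' @param target_delta_qc desired delta-Qc.
#' @param fragment_length_sdlog lognormal sdlog.
#' @param deamination_rate,crosslink_failure_rate passed to [damage_model()].
#' @return a [damage_model()] with the calibrated fragment length.
#' @export
calibrate_fragmentation <- function(design, target_delta_qc,
                                    fragment_length_sdlog = 0.35,
                                    deamination_rate = 3e-4,
                                    crosslink_failure_rate = 0) {
  lens <- amplicon_lengths(design$amplicons)
  target <- 2^(-target_delta_qc)
  f <- function(logL) {
    s <- mean(plnorm(lens, meanlog = logL, sdlog = fragment_length_sdlog,
                     lower.tail = FALSE)) * (1 - crosslink_failure_rate)
    s - target
  }
  sol <- uniroot(f, lower = log(1), upper = log(1e6), tol = 1e-10)
  damage_model(deamination_rate = deamination_rate,
               fragment_length_mean = exp(sol$root),
               fragment_length_sdlog = fragment_length_sdlog,
               crosslink_failure_rate = crosslink_failure_rate)
}

#' Damage presets spanning the triage bands
#'
#' Returns damage models calibrated so that simulated samples land at
#' delta-Qc values of roughly 1, 4.3, 6.6, 10.1 and 15.1 - the interesting
#' endpoints of the triage scale (standard, borderline-degraded, rescued,
#' and non-interpretable samples).
#'
#' @param design a `PanelDesign`.
#' @param delta_qc numeric vector of target delta-Qc values.
#' @return named list of [damage_model()] objects.
#' @export
damage_presets <- function(design, delta_qc = c(1, 4.3, 6.6, 10.1, 15.1)) {
  setNames(lapply(delta_qc, function(dq) calibrate_fragmentation(design, dq)),
           paste0("dq", delta_qc))
}

#' Write a library's reads as paired gzip FASTQ
#'
#' Four-line records; identical seeds upstream give byte-identical files.
#'
#' @param readset a `LibraryReadSet`.
#' @param r1_path,r2_path output paths (gzip written when the path ends in
#'   `.gz`).
#' @return invisibly, the two paths.
#' @export
write_library_fastq <- function(readset, r1_path, r2_path) {
  wr <- function(path, seqs, quals, names) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con))
    lines <- character(4L * length(seqs))
    lines[seq(1L, by = 4L, length.out = length(seqs))] <- paste0("@", names)
    lines[seq(2L, by = 4L, length.out = length(seqs))] <- seqs
    lines[seq(3L, by = 4L, length.out = length(seqs))] <- "+"
    lines[seq(4L, by = 4L, length.out = length(seqs))] <- quals
    writeLines(lines, con)
  }
  r <- readset$reads
  wr(r1_path, r$seq1, r$qual1, r$name)
  wr(r2_path, r$seq2, r$qual2, r$name)
  invisible(c(r1 = r1_path, r2 = r2_path))
}

#' Read paired FASTQ files back into a `LibraryReadSet`
#'
#' Read names follow `sample:library:amplicon:serial`; sample and library
#' identifiers are recovered from the first record when not supplied.
#'
#' @param r1_path,r2_path FASTQ paths (gzip allowed).
#' @return a `LibraryReadSet`.
#' @export
read_library_fastq <- function(r1_path, r2_path) {
  s1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r1_path))
  s2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r2_path))
  stopifnot(length(s1) == length(s2))
  nm <- names(s1)
  parts <- data.table::tstrsplit(nm, ":", fixed = TRUE)
  reads <- data.table::data.table(
    name = nm,
    amplicon = if (length(parts) >= 3L) parts[[3]] else NA_character_,
    hap = NA_integer_,
    seq1 = as.character(s1), seq2 = as.character(s2),
    qual1 = as.character(Biostrings::quality(s1)),
    qual2 = as.character(Biostrings::quality(s2)))
  structure(list(
    sample_id = if (length(parts) >= 1L) parts[[1]][1] else "sample",
    library_id = if (length(parts) >= 2L) parts[[2]][1] else "LIB1",
    reads = reads), class = "LibraryReadSet")
}
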