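# Panel model: gene/exon targets, amplicons and design-level validation.
#
# A PanelDesign bundles
#   * genes          - one row per gene target (symbol, transcript, exons)
#   * reference      - named character vector of contig sequences
#   * target_regions - exon +/- padding intervals, 0-based half-open
#   * amplicons      - tiled amplicons with primer and insert intervals
#
# Amplicon anatomy on the top strand:
#   [fwd_start, insert_start) forward primer
#   [insert_start, insert_end) insert (the only part that is genotyped)
#   [insert_end, rev_end)      reverse-primer footprint
# fwd_primer is the top-strand sequence of the forward primer; rev_primer is
# the reverse complement of the reverse-primer footprint, i.e. both primers
# are stored 5'->3' as they would be synthesised.

#' Construct a gene target
#'
#' @param gene_symbol HGNC-style symbol, unique within a panel.
#' @param transcript_accession reference transcript (e.g. RefSeq NM_ number).
#' @param exon_numbers positive integers, strictly increasing.
#' @param note optional free-text hotspot restriction.
#' @return a `gene_target` list.
#' @export
gene_target <- function(gene_symbol, transcript_accession, exon_numbers,
                        note = NA_character_) {
  exon_numbers <- as.integer(exon_numbers)
  if (length(exon_numbers) == 0L)
    stop_fmt("gene %s: exon list is empty", gene_symbol)
  if (any(exon_numbers <= 0L) || anyNA(exon_numbers))
    stop_fmt("gene %s: exon numbers must be positive integers", gene_symbol)
  if (is.unsorted(exon_numbers, strictly = TRUE))
    stop_fmt("gene %s: exon numbers must be strictly increasing with no duplicates",
             gene_symbol)
  structure(list(gene_symbol = gene_symbol,
                 transcript_accession = transcript_accession,
                 exon_numbers = exon_numbers,
                 note = note),
            class = "gene_target")
}

#' Construct a panel design
#'
#' @param genes data.frame with columns `gene`, `transcript`, `exons`
#'   (list column of integer vectors) and `note`.
#' @param reference named character vector of contig sequences (may be
#'   `NULL` for a genes-only design).
#' @param target_regions data.frame (`contig`, `start`, `end`, `gene`,
#'   `exon`), 0-based half-open.
#' @param amplicons data.frame of amplicon records (see package docs).
#' @return object of class `PanelDesign`.
#' @export
panel_design <- function(genes, reference = NULL, target_regions = NULL,
                         amplicons = NULL) {
  if (anyDuplicated(genes$gene))
    stop_fmt("duplicate gene symbol in panel: %s",
             paste(unique(genes$gene[duplicated(genes$gene)]), collapse = ", "))
  structure(list(genes = genes,
                 reference = reference,
                 target_regions = target_regions,
                 amplicons = amplicons),
            class = "PanelDesign")
}

#' @export
print.PanelDesign <- function(x, ...) {
  cat(sprintf("PanelDesign: %d genes, %d exon targets, %d amplicons\n",
              nrow(x$genes), sum(lengths(x$genes$exons)),
              if (is.null(x$amplicons)) 0L else nrow(x$amplicons)))
  invisible(x)
}

#' Number of exon-level targets in a design
#' @param design a `PanelDesign`.
#' @return integer count.
#' @export
n_exon_targets <- function(design) sum(lengths(design$genes$exons))

#' Read a panel gene table
#'
#' Parses a TSV with header `gene  transcript  exons  note` (`note`
#' optional); `exons` is a comma-separated list of positive integers.
#'
#' @param path path to the TSV file.
#' @return a genes-only `PanelDesign`.
#' @export
load_panel_table <- function(path) {
  if (!file.exists(path)) stop_fmt("panel table not found: %s", path)
  tab <- tryCatch(
    read.delim(path, sep = "\t", header = TRUE, colClasses = "character"),
    error = function(e) stop_fmt("panel table format error: %s", conditionMessage(e)))
  if (nrow(tab) == 0L) stop_fmt("panel table format error: no data rows in %s", path)
  need <- c("gene", "transcript", "exons")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop_fmt("panel table format error: missing column(s) %s",
             paste(miss, collapse = ", "))
  exons <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    parts <- trimws(strsplit(tab$exons[i], ",", fixed = TRUE)[[1]])
    vals <- suppressWarnings(as.integer(parts))
    if (length(vals) == 0L || anyNA(vals))
      stop_fmt("panel table row %d (%s): cannot parse exon list '%s'",
               i, tab$gene[i], tab$exons[i])
    # constructor enforces ordering/positivity
    exons[[i]] <- gene_target(tab$gene[i], tab$transcript[i], vals)$exon_numbers
  }
  genes <- data.frame(gene = tab$gene, transcript = tab$transcript,
                      stringsAsFactors = FALSE)
  genes$exons <- exons
  genes$note <- if ("note" %in% names(tab)) tab$note else NA_character_
  panel_design(genes)
}

#' Write a panel gene table
#' @param design a `PanelDesign`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_panel_table <- function(design, path) {
  tab <- data.frame(
    gene = design$genes$gene,
    transcript = design$genes$transcript,
    exons = vapply(design$genes$exons, paste, "", collapse = ","),
    note = design$genes$note %||% NA_character_,
    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default design-constraint set
#'
#' The assay targets degraded DNA, so amplicons are short: total length
#' (primers + insert) must lie in \[120, 150\] bp and primers in
#' \[22, 30\] bases. Exon padding profiles: the default symmetric 5 bp
#' minimum, or the asymmetric `c(7, 6)` profile (left/right) selectable
#' here.
#'
#' @param amplicon_length bp bounds on primer-inclusive amplicon length.
#' @param primer_length bounds on primer length in bases.
#' @param min_padding minimum exon padding; length-1 (symmetric) or
#'   length-2 `c(left, right)`.
#' @param min_overlap minimum tiling overlap between adjacent amplicons of
#'   one exon, in bases.
#' @param primer_gc allowed primer GC fraction range.
#' @param snp_blacklist optional data.frame (`contig`, `pos`) of common SNP
#'   positions that primer footprints must avoid.
#' @return a `design_constraints` list.
#' @export
design_constraints <- function(amplicon_length = c(120L, 150L),
                               primer_length = c(22L, 30L),
                               min_padding = 5L,
                               min_overlap = 1L,
                               primer_gc = c(0.2, 0.8),
                               snp_blacklist = NULL) {
  if (length(min_padding) == 1L) min_padding <- rep(min_padding, 2L)
  structure(list(amplicon_length = as.integer(amplicon_length),
                 primer_length = as.integer(primer_length),
                 min_padding = as.integer(min_padding),
                 min_overlap = as.integer(min_overlap),
                 primer_gc = primer_gc,
                 snp_blacklist = snp_blacklist),
            class = "design_constraints")
}

amplicon_lengths <- function(amp) amp$rev_end - amp$fwd_start

#' Validate a panel design against assay constraints
#'
#' Checks every amplicon and target region: amplicon and primer length
#' bounds, primer GC range, exon padding, 100% target coverage by inserts,
#' minimum tiling overlap between adjacent amplicons of an exon, and
#' (optionally) that no primer footprint covers a blacklisted common-SNP
#' position. Violations are returned as data, not raised as errors.
#'
#' @param design a `PanelDesign` with amplicons and target regions.
#' @param constraints a [design_constraints()] set.
#' @return list with elements `pass` (logical) and `violations`
#'   (data.frame `amplicon_id`, `rule`, `detail`).
#' @export
validate_design <- function(design, constraints = design_constraints()) {
  amp <- design$amplicons
  tr <- design$target_regions
  if (is.null(amp) || nrow(amp) == 0L) stop_fmt("design has no amplicons")
  if (is.null(tr) || nrow(tr) == 0L) stop_fmt("design has no target regions")
  v <- list()
  add <- function(id, rule, detail)
    v[[length(v) + 1L]] <<- data.frame(amplicon_id = id, rule = rule,
                                       detail = detail, stringsAsFactors = FALSE)

  len <- amplicon_lengths(amp)
  bad <- which(len < constraints$amplicon_length[1] |
               len > constraints$amplicon_length[2])
  for (i in bad) add(amp$amplicon_id[i], "amplicon_length",
                     sprintf("%d bp outside [%d,%d]", len[i],
                             constraints$amplicon_length[1],
                             constraints$amplicon_length[2]))

  for (sidecol in c("fwd_primer", "rev_primer")) {
    pl <- nchar(amp[[sidecol]])
    bad <- which(pl < constraints$primer_length[1] |
                 pl > constraints$primer_length[2])
    for (i in bad) add(amp$amplicon_id[i], "primer_length",
                       sprintf("%s %d bases outside [%d,%d]", sidecol, pl[i],
                               constraints$primer_length[1],
                               constraints$primer_length[2]))
    gc <- gc_fraction(amp[[sidecol]])
    bad <- which(gc < constraints$primer_gc[1] | gc > constraints$primer_gc[2])
    for (i in bad) add(amp$amplicon_id[i], "primer_gc",
                       sprintf("%s GC %.2f outside [%.2f,%.2f]", sidecol, gc[i],
                               constraints$primer_gc[1], constraints$primer_gc[2]))
  }

  # structural consistency: primer intervals flank the insert exactly
  bad <- which(amp$fwd_end != amp$insert_start | amp$rev_start != amp$insert_end)
  for (i in bad) add(amp$amplicon_id[i], "primer_interval",
                     "primer intervals must flank the insert without gap or overlap")
  ins_len <- amp$insert_end - amp$insert_start
  bad <- which(ins_len != len - nchar(amp$fwd_primer) - nchar(amp$rev_primer))
  for (i in bad) add(amp$amplicon_id[i], "insert_length",
                     "insert length != amplicon length - primer lengths")

  # coverage and overlap per target region
  for (j in seq_len(nrow(tr))) {
    reg <- tr[j, ]
    on_contig <- amp[amp$contig == reg$contig &
                     amp$insert_start < reg$end & amp$insert_end > reg$start, ,
                     drop = FALSE]
    if (nrow(on_contig) == 0L) {
      add(NA_character_, "target_coverage",
          sprintf("target %s:%d-%d covered by no amplicon insert",
                  reg$contig, reg$start, reg$end))
      next
    }
    ir <- IRanges::IRanges(start = on_contig$insert_start + 1L,
                           end = on_contig$insert_end)
    covered <- IRanges::reduce(ir)
    regr <- IRanges::IRanges(start = reg$start + 1L, end = reg$end)
    uncov <- IRanges::setdiff(regr, covered)
    if (sum(IRanges::width(uncov)) > 0L)
      add(NA_character_, "target_coverage",
          sprintf("target %s:%d-%d has %d uncovered base(s)",
                  reg$contig, reg$start, reg$end, sum(IRanges::width(uncov))))
    if (nrow(on_contig) > 1L) {
      o <- on_contig[order(on_contig$insert_start), , drop = FALSE]
      ovl <- head(o$insert_end, -1L) - tail(o$insert_start, -1L)
      bad <- which(ovl < constraints$min_overlap)
      for (i in bad) add(o$amplicon_id[i + 1L], "tiling_overlap",
                         sprintf("overlap %d < %d with previous amplicon",
                                 ovl[i], constraints$min_overlap))
    }
  }

  # exon padding: each target region must extend >= min_padding beyond its exon
  if (!is.null(tr$exon_start) && !is.null(tr$exon_end)) {
    bad <- which(tr$exon_start - tr$start < constraints$min_padding[1] |
                 tr$end - tr$exon_end < constraints$min_padding[2])
    for (i in bad) add(NA_character_, "exon_padding",
                       sprintf("target %s exon %s padding below minimum",
                               tr$gene[i], tr$exon[i]))
  }

  # primer footprints must avoid blacklisted common-SNP positions
  bl <- constraints$snp_blacklist
  if (!is.null(bl) && nrow(bl) > 0L) {
    for (i in seq_len(nrow(amp))) {
      hit <- bl$contig == amp$contig[i] &
        ((bl$pos >= amp$fwd_start[i] & bl$pos < amp$insert_start[i]) |
         (bl$pos >= amp$insert_end[i] & bl$pos < amp$rev_end[i]))
      if (any(hit))
        add(amp$amplicon_id[i], "primer_snp",
            sprintf("primer footprint covers blacklisted position(s) %s",
                    paste(bl$pos[hit], collapse = ",")))
    }
  }

  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(amplicon_id = character(), rule = character(),
               detail = character(), stringsAsFactors = FALSE)
  list(pass = nrow(violations) == 0L, violations = violations)
}

#' Design summary statistics
#'
#' Length statistics are computed over primer-inclusive amplicon lengths
#' and primer lengths; the median of an even-count list is the mean of the
#' two central values (the [stats::median()] convention).
#'
#' @param design a `PanelDesign` with at least one amplicon.
#' @return list of class `design_stats`.
#' @export
design_stats <- function(design) {
  amp <- design$amplicons
  if (is.null(amp) || nrow(amp) == 0L) stop_fmt("design has no amplicons")
  len <- amplicon_lengths(amp)
  ins <- amp$insert_end - amp$insert_start
  pl <- c(nchar(amp$fwd_primer), nchar(amp$rev_primer))
  tr <- design$target_regions
  total_bp <- if (is.null(tr)) NA_integer_ else {
    ir <- IRanges::reduce(IRanges::IRanges(start = tr$start + 1L, end = tr$end))
    # reduce() per contig: split to avoid merging across contigs
    sum(vapply(split(seq_len(nrow(tr)), tr$contig), function(ix) {
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(start = tr$start[ix] + 1L, end = tr$end[ix]))))
    }, integer(1)))
  }
  per_gene <- vapply(split(lengths(design$genes$exons), design$genes$gene), sum,
                     integer(1))
  structure(list(
    n_amplicons = nrow(amp),
    amplicon_length = c(min = min(len), median = median(len), max = max(len)),
    insert_length = c(min = min(ins), median = median(ins), max = max(ins)),
    primer_length = c(min = min(pl), median = median(pl), max = max(pl)),
    total_target_bp = total_bp,
    per_gene_exons = per_gene), class = "design_stats")
}

#' @export
print.design_stats <- function(x, ...) {
  cat(sprintf(
    "%d amplicons; amplicon bp min/median/max %g/%g/%g; primer min/median/max %g/%g/%g; target %s bp\n",
    x$n_amplicons, x$amplicon_length["min"], x$amplicon_length["median"],
    x$amplicon_length["max"], x$primer_length["min"], x$primer_length["median"],
    x$primer_length["max"], format(x$total_target_bp)))
  invisible(x)
}

#' Write an amplicon manifest (BED6 + primer TSV)
#'
#' Inserts are exported as BED6 (name = amplicon id, score = 0, strand `+`
#' for the forward oligo pool, `-` for the reverse pool); primer sequences
#' and footprints go to a tab-separated sidecar.
#'
#' @param design a `PanelDesign` with amplicons.
#' @param bed_path output BED path.
#' @param primer_path output primer TSV path.
#' @return invisibly, the two paths.
#' @export
write_amplicon_manifest <- function(design, bed_path, primer_path) {
  amp <- design$amplicons
  gr <- GenomicRanges::GRanges(
    seqnames = amp$contig,
    ranges = IRanges::IRanges(start = amp$insert_start + 1L, end = amp$insert_end),
    strand = ifelse(amp$pool == "FORWARD_POOL", "+", "-"))
  S4Vectors::mcols(gr)$name <- amp$amplicon_id
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export(gr, bed_path, format = "BED")
  prim <- data.frame(amplicon_id = amp$amplicon_id,
                     fwd_primer_seq = amp$fwd_primer,
                     rev_primer_seq = amp$rev_primer,
                     fwd_start = amp$fwd_start, fwd_end = amp$insert_start,
                     rev_start = amp$insert_end, rev_end = amp$rev_end,
                     stringsAsFactors = FALSE)
  write.table(prim, primer_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bed = bed_path, primers = primer_path))
}

#' Read an amplicon manifest back into a design
#'
#' @param bed_path insert BED6 path.
#' @param primer_path primer TSV path.
#' @param reference_fasta path to the contig FASTA.
#' @param panel_table optional panel gene TSV (adds the gene table).
#' @param target_regions optional target-region data.frame to attach.
#' @return a `PanelDesign`.
#' @export
read_amplicon_manifest <- function(bed_path, primer_path, reference_fasta,
                                   panel_table = NULL, target_regions = NULL) {
  gr <- rtracklayer::import(bed_path, format = "BED")
  prim <- read.delim(primer_path, sep = "\t", header = TRUE,
                     colClasses = c(amplicon_id = "character",
                                    fwd_primer_seq = "character",
                                    rev_primer_seq = "character"))
  ord <- match(S4Vectors::mcols(gr)$name, prim$amplicon_id)
  if (anyNA(ord)) stop_fmt("manifest mismatch: BED names absent from primer TSV")
  prim <- prim[ord, , drop = FALSE]
  ref <- Biostrings::readDNAStringSet(reference_fasta)
  refv <- setNames(as.character(ref), sub("\\s.*$", "", names(ref)))
  amp <- data.frame(
    amplicon_id = S4Vectors::mcols(gr)$name,
    contig = as.character(GenomicRanges::seqnames(gr)),
    fwd_start = prim$fwd_start,
    insert_start = GenomicRanges::start(gr) - 1L,
    insert_end = GenomicRanges::end(gr),
    rev_end = prim$rev_end,
    pool = ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                  "REVERSE_POOL", "FORWARD_POOL"),
    fwd_primer = prim$fwd_primer_seq,
    rev_primer = prim$rev_primer_seq,
    stringsAsFactors = FALSE)
  amp$fwd_end <- amp$insert_start
  amp$rev_start <- amp$insert_end
  genes <- if (!is.null(panel_table)) load_panel_table(panel_table)$genes else
    data.frame(gene = character(), transcript = character(),
               note = character(), stringsAsFactors = FALSE)
  if (is.null(genes$exons)) genes$exons <- list()
  d <- panel_design(genes, reference = refv, target_regions = target_regions,
                    amplicons = amp)
  d
}
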