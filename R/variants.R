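# Variant representation and VCF v4.2 emission.
#
# Internally variants are (contig, pos, ref, alt) with pos 0-based; the
# writer converts to 1-based VCF coordinates. Left-normalization follows
# the usual convention: trim the shared allele suffix, extending to the
# left with reference bases whenever an allele would empty, then trim the
# shared prefix - yielding the smallest possible position with an anchored,
# minimal representation.

#' Left-normalize a variant against the reference
#'
#' @param refseq reference contig sequence (character scalar).
#' @param pos 0-based position of the first `ref` base.
#' @param ref,alt allele strings (non-empty).
#' @return list with normalized `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(refseq, pos, ref, alt) {
  pos <- as.integer(pos)
  if (identical(ref, alt)) return(list(pos = pos, ref = ref, alt = alt))
  repeat {
    lr <- nchar(ref); la <- nchar(alt)
    if (substr(ref, lr, lr) != substr(alt, la, la)) break
    if (lr == 1L || la == 1L) {
      if (pos == 0L) break  # cannot shift past the contig start
      b <- ref_seg(refseq, pos - 1L, pos)
      ref <- paste0(b, substr(ref, 1L, lr - 1L))
      alt <- paste0(b, substr(alt, 1L, la - 1L))
      pos <- pos - 1L
    } else {
      ref <- substr(ref, 1L, lr - 1L)
      alt <- substr(alt, 1L, la - 1L)
    }
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substring(ref, 2L); alt <- substring(alt, 2L)
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

variant_class <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  ifelse(lr == 1L & la == 1L, "SNV",
         ifelse(lr == la, "MNV", ifelse(lr > la, "DEL", "INS")))
}

vcf_header <- function(design, extra_meta = character(), info_lines = character(),
                       filter_lines = character(), sample_col = NULL) {
  contigs <- if (!is.null(design$reference))
    sprintf("##contig=<ID=%s,length=%d>", names(design$reference),
            nchar(design$reference)) else character()
  c("##fileformat=VCFv4.2",
    sprintf("##source=dstpanel-%s", as.character(packageVersion("dstpanel"))),
    extra_meta, contigs, info_lines, filter_lines,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (!is.null(sample_col)) c("FORMAT", sample_col)), collapse = "\t"))
}

#' Write a truth-variant set as VCF v4.2
#'
#' @param variants truth data.frame (`contig`, `pos`, `ref`, `alt`, `vaf`,
#'   `label`).
#' @param design a `PanelDesign` (for contig headers).
#' @param path output path.
#' @param seed optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_truth_vcf <- function(variants, design, path, seed = NULL) {
  meta <- c(if (!is.null(seed)) sprintf("##seed=%d", as.integer(seed)),
            "##INFO=<ID=TVAF,Number=1,Type=Float,Description=\"Target variant allele fraction\">",
            "##INFO=<ID=LABEL,Number=1,Type=String,Description=\"Variant label\">")
  hdr <- vcf_header(design, extra_meta = meta[!vapply(meta, is.null, TRUE)])
  rec <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\tTVAF=%s;LABEL=%s",
                 variants$contig, variants$pos + 1L, variants$label,
                 variants$ref, variants$alt,
                 format(variants$vaf, trim = TRUE, scientific = FALSE),
                 variants$label)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a truth VCF written by [write_truth_vcf()]
#' @param path VCF path.
#' @return truth-variant data.frame.
#' @export
read_truth_vcf <- function(path) {
  ln <- readLines(path)
  body <- ln[!startsWith(ln, "#")]
  if (!length(body))
    return(data.frame(contig = character(), pos = integer(), ref = character(),
                      alt = character(), vaf = numeric(), label = character()))
  f <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  info <- f[[8]]
  gv <- function(key) sub(sprintf(".*%s=([^;]*).*", key), "\\1", info)
  data.frame(contig = f[[1]], pos = as.integer(f[[2]]) - 1L,
             ref = f[[4]], alt = f[[5]],
             vaf = as.numeric(gv("TVAF")), label = gv("LABEL"),
             stringsAsFactors = FALSE)
}

#' Write consensus calls as VCF v4.2
#'
#' INFO carries the per-library and combined allele fractions and depths
#' (`VAF1`, `VAF2`, `VAFC`, `DP1`, `DP2`); FILTER is `PASS`,
#' `single_library` or `low_depth`.
#'
#' @param consensus consensus-call data.frame from [consensus_calls()].
#' @param design a `PanelDesign`.
#' @param path output path.
#' @param sample_id sample name recorded in the header.
#' @param seed,config_hash optional provenance stamps for the header.
#' @return `path`, invisibly.
#' @export
write_consensus_vcf <- function(consensus, design, path, sample_id = "sample",
                                seed = NULL, config_hash = NULL) {
  meta <- c(sprintf("##sample=%s", sample_id),
            if (!is.null(seed)) sprintf("##seed=%d", as.integer(seed)),
            if (!is.null(config_hash)) sprintf("##confighash=%s", config_hash))
  info_lines <- c(
    "##INFO=<ID=VAF1,Number=1,Type=Float,Description=\"Allele fraction in library 1\">",
    "##INFO=<ID=VAF2,Number=1,Type=Float,Description=\"Allele fraction in library 2\">",
    "##INFO=<ID=VAFC,Number=1,Type=Float,Description=\"Combined allele fraction\">",
    "##INFO=<ID=DP1,Number=1,Type=Integer,Description=\"Depth in library 1\">",
    "##INFO=<ID=DP2,Number=1,Type=Integer,Description=\"Depth in library 2\">")
  filter_lines <- c(
    "##FILTER=<ID=single_library,Description=\"Detected in only one strand library\">",
    "##FILTER=<ID=low_depth,Description=\"Confirming library lacks depth at the site\">")
  hdr <- vcf_header(design, extra_meta = meta, info_lines = info_lines,
                    filter_lines = filter_lines)
  fmt_v <- function(x) ifelse(is.na(x), ".", format(round(x, 6), trim = TRUE,
                                                    scientific = FALSE))
  fmt_d <- function(x) ifelse(is.na(x), ".", format(x, trim = TRUE))
  filt <- c(PASS = "PASS", SINGLE_LIBRARY_REJECTED = "single_library",
            LOW_DEPTH = "low_depth")[consensus$filter_status]
  rec <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tVAF1=%s;VAF2=%s;VAFC=%s;DP1=%s;DP2=%s",
                 consensus$contig, consensus$pos + 1L, consensus$ref,
                 consensus$alt, filt,
                 fmt_v(consensus$vaf_lib1), fmt_v(consensus$vaf_lib2),
                 fmt_v(consensus$vaf_combined),
                 fmt_d(consensus$depth_lib1), fmt_d(consensus$depth_lib2))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a consensus VCF written by [write_consensus_vcf()]
#' @param path VCF path.
#' @return consensus-call data.frame.
#' @export
read_consensus_vcf <- function(path) {
  ln <- readLines(path)
  body <- ln[!startsWith(ln, "#")]
  empty <- data.frame(contig = character(), pos = integer(), ref = character(),
                      alt = character(), vaf_lib1 = numeric(),
                      vaf_lib2 = numeric(), vaf_combined = numeric(),
                      depth_lib1 = integer(), depth_lib2 = integer(),
                      filter_status = character(), stringsAsFactors = FALSE)
  if (!length(body)) return(empty)
  f <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  info <- f[[8]]
  gv <- function(key) {
    x <- sub(sprintf(".*%s=([^;]*).*", key), "\\1", info)
    suppressWarnings(as.numeric(ifelse(x == ".", NA, x)))
  }
  status <- c(PASS = "PASS", single_library = "SINGLE_LIBRARY_REJECTED",
              low_depth = "LOW_DEPTH")[f[[7]]]
  data.frame(contig = f[[1]], pos = as.integer(f[[2]]) - 1L,
             ref = f[[4]], alt = f[[5]],
             vaf_lib1 = gv("VAF1"), vaf_lib2 = gv("VAF2"),
             vaf_combined = gv("VAFC"),
             depth_lib1 = as.integer(gv("DP1")),
             depth_lib2 = as.integer(gv("DP2")),
             filter_status = unname(status), stringsAsFactors = FALSE)
}
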