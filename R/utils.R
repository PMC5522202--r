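# Small shared helpers. Sequences are plain uppercase character strings in
# top-strand orientation unless stated otherwise; Biostrings is used for
# reverse complement and file I/O so the heavy lifting stays in C.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of character sequences
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that
#' keeps inputs and outputs as plain character vectors.
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' GC fraction of sequences
#' @param x character vector of DNA sequences.
#' @return numeric vector in \[0, 1\].
#' @export
gc_fraction <- function(x) {
  if (length(x) == 0L) return(numeric())
  f <- Biostrings::letterFrequency(Biostrings::DNAStringSet(x),
                                   letters = c("G", "C"))
  as.numeric(rowSums(f)) / nchar(x)
}

#' Round half away from zero
#'
#' Reported percentages use commercial ("half-up") rounding rather than
#' banker's rounding, so 92.85 prints as 92.9.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run code under a fixed RNG state and restore the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Character matrix (length x n) of equal-length strings as integer UTF-8
# codes; columns are sequences. Used for vectorised mismatch counting.
seq_code_matrix <- function(seqs, len = nchar(seqs[1])) {
  stopifnot(all(nchar(seqs) == len))
  matrix(utf8ToInt(paste(seqs, collapse = "")), nrow = len)
}

BASE_CODES <- setNames(utf8ToInt("ACGT"), c("A", "C", "G", "T"))

# substring of a reference contig, 0-based half-open
ref_seg <- function(refseq, start, end) substr(refseq, start + 1L, end)

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

# md5 hash of an arbitrary R object (via its serialisation to a temp file);
# used to stamp configs into output headers.
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
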