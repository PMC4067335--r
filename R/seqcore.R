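#' @importFrom Biostrings readBStringSet DNAStringSet writeXStringSet DNAString matchPattern
#' @importFrom utils write.table read.table
NULL

# Internal: validate a vector of DNA strings over {A,C,G,T,N}.
.check_alphabet <- function(seqs, what = "sequence") {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    ch <- unique(unlist(strsplit(gsub("[ACGTN]", "", seqs[bad]), "")))
    stop(sprintf("illegal character(s) %s in %s (alphabet is A/C/G/T/N)",
                 paste(sQuote(ch), collapse = ", "), what), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a multi-FASTA file of input sequences
#'
#' Reads FASTA records, uppercases them, converts RNA `U` to `T`, and
#' validates that only `A/C/G/T/N` remain. Record identifiers are the full
#' header lines and must be unique.
#'
#' @param path Path to a FASTA file. Sequences are expected 5'->3'.
#' @return A named character vector of uppercase DNA sequences; names are
#'   record IDs in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- names(set)
  if (any(!nzchar(ids))) stop("empty record ID in ", path, call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate record ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- chartr("U", "T", toupper(as.character(set)))
  .check_alphabet(seqs, sprintf("FASTA file '%s'", path))
  names(seqs) <- ids
  seqs
}

#' Write sequences to a multi-FASTA file
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Load and normalize a reference genome
#'
#' Pre-treats a multi-FASTA genome the way downstream scanning expects:
#' headers are truncated to their first whitespace-delimited token (the
#' chromosome name, dropping e.g. Ensembl description fields), sequences are
#' uppercased so soft-masked (lowercase) repeat regions are scanned like any
#' other DNA.
#'
#' @param path Path to a (multi-)FASTA genome file.
#' @return A named character vector: chromosome name -> uppercase sequence.
#' @export
format_genome <- function(path) {
  seqs <- read_fasta(path)
  names(seqs) <- vapply(strsplit(names(seqs), "[ \t]+"), `[[`, character(1), 1L)
  if (anyDuplicated(names(seqs))) {
    stop("duplicate chromosome name(s) after header truncation: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  }
  seqs
}

#' Reverse-complement a DNA string
#'
#' @param seq A DNA string over `A/C/G/T/N` (vectorized).
#' @return The reverse complement; `N` maps to `N`.
#' @examples
#' revcomp("ACGTN")  # "NACGT"
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq))
  .check_alphabet(seq)
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

#' GC content of a DNA string, in percent
#'
#' `N` bases count in the denominator but never as G/C, so ambiguous
#' stretches lower the reported GC.
#'
#' @param seq A non-empty DNA string (vectorized).
#' @return Numeric percentage in \[0, 100\].
#' @examples
#' gc_percent("ACGT")  # 50
#' @export
gc_percent <- function(seq) {
  stopifnot(is.character(seq))
  if (any(!nzchar(seq))) stop("empty sequence has no GC content", call. = FALSE)
  .check_alphabet(seq)
  100 * (nchar(seq) - nchar(gsub("[GC]", "", seq))) / nchar(seq)
}
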