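# Guide QC, cloning-oligo construction and validation-amplicon extraction.

#' Quality-check a spacer sequence for vector construction
#'
#' A spacer is rejected when it contains sequence that breaks sgRNA
#' expression or synthesis: 5 or more consecutive `T` (a 4-6 nt poly-T tract
#' terminates RNA polymerase III transcription), 6 or more consecutive `A`,
#' `C` or `G`, or a di-/tri-nucleotide unit tandemly repeated more than 6
#' times (>6 copies).
#'
#' @param guide Spacer sequence over `A/C/G/T`.
#' @return A list: `pass` (logical) and `reason` (`NA` when passing).
#' @examples
#' qc_guide("GACGTTAAACCGGATTACCA")$pass   # TRUE
#' qc_guide("ACGTTTTTACGTACGTACGT")$pass   # FALSE: poly-T
#' @export
qc_guide <- function(guide) {
  stopifnot(length(guide) == 1L, is.character(guide))
  if (grepl("[^ACGT]", guide)) {
    stop("guide must be over A/C/G/T", call. = FALSE)
  }
  if (grepl("TTTTT", guide, fixed = TRUE)) {
    return(list(pass = FALSE, reason = "poly_T_run"))
  }
  if (grepl("AAAAAA|CCCCCC|GGGGGG", guide)) {
    return(list(pass = FALSE, reason = "homopolymer_run"))
  }
  if (grepl("([ACGT]{2})\\1{6,}", guide) || grepl("([ACGT]{3})\\1{6,}", guide)) {
    return(list(pass = FALSE, reason = "tandem_repeat"))
  }
  list(pass = TRUE, reason = NA_character_)
}

#' Build the annealing oligo pair for BsaI cloning of a spacer
#'
#' Prepends the vector-specific 4-nt adapters (lowercase) to the spacer and
#' its reverse complement; the defaults (`"accg"`/`"aaac"`) fit a
#' U6-promoter sgRNA vector cut at a BsaI site. Annealing the two oligos
#' yields a ds insert whose overhangs match the digested vector.
#'
#' @param guide Spacer sequence; must pass [qc_guide()].
#' @param guide_id Optional ID carried into the result.
#' @param adapter_sense,adapter_antisense Adapter strings added to the 5'
#'   end of the sense and antisense oligo.
#' @return A data frame row: `guide_id`, `sense_oligo`, `antisense_oligo`.
#' @examples
#' make_oligos("GACGTTAAACCGGATTACCA")
#' @export
make_oligos <- function(guide, guide_id = "guide",
                        adapter_sense = "accg", adapter_antisense = "aaac") {
  qc <- qc_guide(guide)
  if (!qc$pass) {
    stop("guide fails QC (", qc$reason, "); refusing to design oligos",
         call. = FALSE)
  }
  data.frame(guide_id = guide_id,
             sense_oligo = paste0(adapter_sense, guide),
             antisense_oligo = paste0(adapter_antisense, revcomp(guide)),
             stringsAsFactors = FALSE)
}

#' Extract the genomic window flanking a cleavage site
#'
#' Returns up to `window` bp centered on a predicted cleavage position (Cas9
#' cuts 3 nt upstream of the PAM), for use as a PCR/T7E1 validation
#' template. For even windows the center sits just left of the window's
#' midpoint (`floor((window-1)/2)` bases to its left); the window is
#' truncated at chromosome bounds, so less than `window` bp may be returned
#' near an end.
#'
#' @param genome Named character vector from [format_genome()].
#' @param chrom Chromosome name.
#' @param center 1-based cleavage-center position.
#' @param window Total window length in bp (default 1000).
#' @return A one-element named character vector; the name encodes
#'   `chrom:start-end` so the region round-trips.
#' @export
extract_flank <- function(genome, chrom, center, window = 1000L) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom, call. = FALSE)
  len <- nchar(genome[[chrom]])
  if (center < 1L || center > len) {
    stop("center outside chromosome bounds", call. = FALSE)
  }
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  start <- max(1L, as.integer(center) - as.integer(floor((window - 1) / 2)))
  end <- min(len, start + as.integer(window) - 1L)
  out <- substring(genome[[chrom]], start, end)
  names(out) <- sprintf("%s:%d-%d", chrom, start, end)
  out
}

#' Cleavage-center position of a hit
#'
#' The blunt cut falls between positions 3 and 4 upstream of the PAM; the
#' reported center is the spacer base 3 nt upstream of the PAM on the
#' reference strand.
#'
#' @param hit One row of a hit data frame (`start`, `end`, `strand`).
#' @return 1-based genomic position.
#' @export
cleavage_center <- function(hit) {
  # guide+PAM spans [start, end]; PAM is at the end on "+", the start on "-"
  ifelse(hit$strand == "+", hit$end - 5L, hit$start + 5L)
}
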