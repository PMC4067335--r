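# Genome-wide k-mismatch off-target enumeration under SpCas9 PAM tolerance:
# a window is a hit when its first L bases are within k mismatches of the
# guide and its PAM reads NGG (canonical) or NAG (tolerated); NCG/NTG/NGA/
# NGT/NGC windows are discarded. The PAM's N is never compared and the
# GG->AG change is never counted as a mismatch. Mismatch positions are
# numbered from the PAM-proximal base (1, adjacent to the PAM) to the
# PAM-distal base (L).

.HIT_COLS <- c("guide_id", "chrom", "start", "end", "strand", "site_seq",
               "mismatch_positions", "n_mismatch", "pam_class")

.substr0 <- function(x, s, e) {
  if (length(s) == 0L) character(0) else substring(x, s, e)
}

.empty_hits <- function() {
  data.frame(guide_id = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), site_seq = character(),
             mismatch_positions = character(), n_mismatch = integer(),
             pam_class = character(), stringsAsFactors = FALSE)
}

# Classify a vector of 3-nt PAMs read 5'->3' on the hit strand.
.pam_class <- function(pam) {
  p23 <- substring(pam, 2L, 3L)
  ifelse(p23 == "GG", "NGG", ifelse(p23 == "AG", "NAG", NA_character_))
}

# Build hit rows from candidate full-site sequences (5'->3' on hit strand).
# starts/ends are genomic coordinates of guide+PAM. Drops bad PAMs and >k.
.make_hits <- function(guide_id, guide, chrom, starts, ends, strand,
                       sites, k) {
  if (length(sites) == 0L) return(.empty_hits())
  L <- nchar(guide)
  pam <- substring(sites, L + 1L, L + 3L)
  cls <- .pam_class(pam)
  keep <- !is.na(cls)
  if (!any(keep)) return(.empty_hits())
  starts <- starts[keep]; ends <- ends[keep]
  sites <- sites[keep]; cls <- cls[keep]
  gch <- strsplit(guide, "")[[1]]
  rows <- lapply(seq_along(sites), function(i) {
    sch <- strsplit(sites[i], "")[[1]]
    mm5 <- which(sch[seq_len(L)] != gch)     # 5'-based indices
    if (length(mm5) > k) return(NULL)
    mmp <- sort(L + 1L - mm5)                # PAM-proximal numbering
    sch[mm5] <- tolower(sch[mm5])
    data.frame(guide_id = guide_id, chrom = chrom,
               start = starts[i], end = ends[i], strand = strand,
               site_seq = paste(sch, collapse = ""),
               mismatch_positions = paste(mmp, collapse = ","),
               n_mismatch = length(mm5), pam_class = cls[i],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(.empty_hits())
  do.call(rbind, rows)
}

# Engine for one guide on one chromosome. Biostrings::matchPattern performs
# the exhaustive Hamming-neighborhood scan (fixed letters, so a genomic N
# mismatches every guide base); PAM admissibility is checked on the 3 nt
# past the spacer match. Windows running off a chromosome end are skipped.
.scan_chrom <- function(guide_id, guide, chrom_name, chrom_seq, k) {
  L <- nchar(guide)
  n <- nchar(chrom_seq)
  if (n < L + 3L) return(.empty_hits())
  subj <- Biostrings::DNAString(chrom_seq)
  out <- list()

  m <- Biostrings::matchPattern(Biostrings::DNAString(guide), subj,
                                max.mismatch = k)
  s <- BiocGenerics::start(m); e <- BiocGenerics::end(m)
  ok <- e + 3L <= n
  s <- s[ok]; e <- e[ok]
  out$plus <- .make_hits(guide_id, guide, chrom_name, s, e + 3L, "+",
                         .substr0(chrom_seq, s, e + 3L), k)

  m <- Biostrings::matchPattern(Biostrings::DNAString(revcomp(guide)), subj,
                                max.mismatch = k)
  s <- BiocGenerics::start(m); e <- BiocGenerics::end(m)
  ok <- s - 3L >= 1L
  s <- s[ok]; e <- e[ok]
  out$minus <- .make_hits(guide_id, guide, chrom_name, s - 3L, e, "-",
                          revcomp(.substr0(chrom_seq, s - 3L, e)), k)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Search a genome for all off-target sites of a set of guides
#'
#' For every guide, reports every genomic window (both strands) whose spacer
#' region is within `k` mismatches of the guide and whose PAM is NGG or NAG.
#' The on-target perfect match itself is included. A palindromic site may
#' yield one hit per strand.
#'
#' @param guides A protospacer data frame (from [find_protospacers_all()]),
#'   or a named character vector `guide_id -> spacer sequence`.
#' @param genome Named character vector from [format_genome()].
#' @param k Maximum number of spacer mismatches (default 5).
#' @return A data frame of hits: `guide_id`, `chrom`, `start`, `end`
#'   (1-based closed, guide+PAM), `strand`, `site_seq` (5'->3' on the hit
#'   strand, mismatched bases lowercased), `mismatch_positions`
#'   (comma-separated, PAM-proximal = 1), `n_mismatch`, `pam_class`.
#' @export
search_offtargets <- function(guides, genome, k = 5L) {
  stopifnot(k >= 0L)
  gmap <- .guide_map(guides)
  res <- lapply(names(gmap), function(gid) {
    per_chrom <- lapply(names(genome), function(cn) {
      .scan_chrom(gid, gmap[[gid]], cn, genome[[cn]], k)
    })
    do.call(rbind, per_chrom)
  })
  out <- do.call(rbind, c(res, list(.empty_hits())))
  rownames(out) <- NULL
  out[order(match(out$guide_id, names(gmap)), match(out$chrom, names(genome)),
            out$start, out$strand), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

# Accept either a protospacer data frame (unique spacer per guide_id) or a
# named character vector.
.guide_map <- function(guides) {
  if (is.data.frame(guides)) {
    stopifnot(all(c("guide_id", "guide") %in% names(guides)))
    g <- guides$guide
    names(g) <- guides$guide_id
  } else {
    g <- guides
  }
  if (is.null(names(g)) || any(!nzchar(names(g)))) {
    stop("guides must carry guide IDs", call. = FALSE)
  }
  if (anyDuplicated(names(g))) stop("duplicate guide_id", call. = FALSE)
  .check_alphabet(g, "guide")
  if (any(grepl("N", g, fixed = TRUE))) {
    stop("guides containing N cannot be searched", call. = FALSE)
  }
  as.list(g)
}

#' Naive exhaustive off-target scan (test oracle)
#'
#' Same contract as [search_offtargets()] for a single guide, implemented as
#' a direct position-by-position Hamming comparison over every window of
#' both strands, with no indexing or pattern-matching library. Intended as
#' an independent oracle for validating the engine.
#'
#' @param guide Spacer sequence (no N).
#' @param guide_id ID to stamp on hits.
#' @param genome Named character vector of chromosomes.
#' @param k Maximum mismatches.
#' @return Hit data frame in the [search_offtargets()] schema.
#' @export
brute_force_scan <- function(guide, genome, k = 5L, guide_id = "guide") {
  L <- nchar(guide)
  gch <- strsplit(guide, "")[[1]]
  res <- lapply(names(genome), function(cn) {
    chrom <- genome[[cn]]
    n <- nchar(chrom)
    if (n < L + 3L) return(.empty_hits())
    one_strand <- function(seqstr) {
      ch <- strsplit(seqstr, "")[[1]]
      np <- n - (L + 3L) + 1L
      p <- seq_len(np)
      mm <- integer(np)
      for (i in seq_len(L)) mm <- mm + (ch[p + i - 1L] != gch[i])
      keep <- mm <= k
      p[keep]
    }
    rows <- list()
    p <- one_strand(chrom)
    rows$plus <- .make_hits(guide_id, guide, cn, p, p + L + 2L, "+",
                            .substr0(chrom, p, p + L + 2L), k)
    rc <- revcomp(chrom)
    p <- one_strand(rc)
    # window [p, p+L+2] on the reverse strand maps to sense coordinates
    rows$minus <- .make_hits(guide_id, guide, cn,
                             n - (p + L + 2L) + 1L, n - p + 1L, "-",
                             .substr0(rc, p, p + L + 2L), k)
    do.call(rbind, rows)
  })
  out <- do.call(rbind, c(res, list(.empty_hits())))
  out <- out[order(match(out$chrom, names(genome)), out$start, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Total off-target count for one guide
#'
#' Counts all hits (including the on-target perfect match) attributed to a
#' guide in a search result; an unknown ID counts 0.
#'
#' @param hits Hit data frame from [search_offtargets()].
#' @param guide_id Guide ID.
#' @return Integer count.
#' @export
count_offtargets <- function(hits, guide_id) {
  sum(hits$guide_id == guide_id)
}

#' Write the raw and re-analyzed off-target tables
#'
#' `seqmap_output.txt` holds the raw mapping columns; `search_OT.txt` is the
#' re-analyzed table with mismatched bases lowercased in the site sequence.
#'
#' @param hits Hit data frame.
#' @param out_dir Output directory.
#' @return Files written, invisibly.
#' @export
write_offtarget_reports <- function(hits, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(out_dir, "seqmap_output.txt")
  raw <- hits
  raw$site_seq <- toupper(raw$site_seq)
  write.table(raw[, c("guide_id", "chrom", "start", "end", "strand",
                      "site_seq", "n_mismatch")],
              f1, sep = "\t", quote = FALSE, row.names = FALSE)
  f2 <- file.path(out_dir, "search_OT.txt")
  write.table(hits[, c("site_seq", "n_mismatch", "guide_id", "chrom",
                       "start", "end", "strand", "pam_class")],
              f2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f1, f2))
}
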