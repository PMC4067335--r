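# Protospacer discovery: every L+3 window ending in a -GG PAM (positions 2-3
# of the PAM; the N is free), on the requested strand(s), filtered by the 5'
# pattern prefix and spacer GC content.

.PS_COLS <- c("guide_id", "record_id", "strand", "start", "end",
              "guide", "pam", "pattern", "gc")

.empty_protospacers <- function() {
  data.frame(guide_id = character(), record_id = character(),
             strand = character(), start = integer(), end = integer(),
             guide = character(), pam = character(), pattern = character(),
             gc = numeric(), stringsAsFactors = FALSE)
}

# Scan one strand of one record (given 5'->3'). Returns 1-based start
# positions of full sites (guide+PAM) in the scanned string, plus fields.
.scan_strand <- function(seq, L, pattern, gc_min, gc_max) {
  n <- nchar(seq)
  W <- L + 3L
  if (n < W) return(NULL)
  ch <- strsplit(seq, "")[[1]]
  p <- seq_len(n - W + 1L)
  ok <- ch[p + L + 1L] == "G" & ch[p + L + 2L] == "G"
  if (pattern == "GX19") {
    ok <- ok & ch[p] == "G"
  } else if (pattern == "GGX18") {
    ok <- ok & ch[p] == "G" & ch[p + 1L] == "G"
  } else if (pattern != "X20") {
    stop("unknown pattern: ", pattern, call. = FALSE)
  }
  p <- p[ok]
  if (length(p) == 0L) return(NULL)
  guide <- substring(seq, p, p + L - 1L)
  pam <- substring(seq, p + L, p + L + 2L)
  keep <- !grepl("N", guide, fixed = TRUE)   # un-synthesizable guides
  p <- p[keep]; guide <- guide[keep]; pam <- pam[keep]
  if (length(p) == 0L) return(NULL)
  gc <- gc_percent(guide)
  keep <- gc >= gc_min & gc <= gc_max
  list(p = p[keep], guide = guide[keep], pam = pam[keep], gc = gc[keep])
}

#' Compose a guide identifier
#'
#' IDs follow the `{record_id}_{S|A}_{ordinal}` scheme, ordinals being
#' 1-based in ascending start coordinate on the searched strand.
#'
#' @param record_id Source FASTA record ID.
#' @param strand `"S"` (sense) or `"A"` (antisense).
#' @param ordinal Positive integer rank of the site on that strand.
#' @return The guide ID string.
#' @examples
#' guide_naming("hEMX1_exon2", "A", 12)
#' @export
guide_naming <- function(record_id, strand, ordinal) {
  stopifnot(all(strand %in% c("S", "A")), all(ordinal >= 1))
  paste(record_id, strand, ordinal, sep = "_")
}

#' Find candidate CRISPR/Cas9 target sites in one sequence
#'
#' Scans for windows of `guide_len + 3` nt whose last two bases read `GG`
#' (the PAM's fixed positions; the N is unconstrained), optionally requiring
#' a 5' `G`/`GG` prefix so U6/T7-driven transcripts start with G, and keeps
#' sites whose spacer GC lies in `[gc_min, gc_max]`. Antisense sites are
#' found on the reverse complement and reported in sense-strand coordinates.
#' Overlapping sites are all reported; guides containing `N` are dropped.
#'
#' @param record_id ID of the input record (used in guide IDs).
#' @param seq The record's DNA sequence, 5'->3' (the "sense strand").
#' @param mode `"sense"`, `"antisense"` or `"both"`.
#' @param pattern 5' pattern: `"X20"` (no prefix constraint), `"GX19"` or
#'   `"GGX18"`. Pattern names refer to the canonical 20-nt spacer; they apply
#'   equally to truncated guides.
#' @param guide_len Spacer length L in nt (default 20; 17-18 for tru-gRNA).
#' @param gc_min,gc_max Inclusive GC%% bounds on the spacer (defaults 20/80).
#' @return A data frame with one row per protospacer: `guide_id`,
#'   `record_id`, `strand` (`S`/`A`), `start`/`end` (1-based closed, on the
#'   input record's sense strand, spanning guide+PAM), `guide`, `pam`,
#'   `pattern`, `gc`.
#' @export
find_protospacers <- function(record_id, seq,
                              mode = c("both", "sense", "antisense"),
                              pattern = c("X20", "GX19", "GGX18"),
                              guide_len = 20L, gc_min = 20, gc_max = 80) {
  mode <- match.arg(mode)
  pattern <- match.arg(pattern)
  stopifnot(length(seq) == 1L, guide_len >= 15L)
  .check_alphabet(seq, sprintf("record '%s'", record_id))
  L <- as.integer(guide_len)
  n <- nchar(seq)
  out <- list()

  if (mode %in% c("sense", "both")) {
    hit <- .scan_strand(seq, L, pattern, gc_min, gc_max)
    if (!is.null(hit) && length(hit$p)) {
      out$S <- data.frame(
        guide_id = guide_naming(record_id, "S", seq_along(hit$p)),
        record_id = record_id, strand = "S",
        start = hit$p, end = hit$p + L + 2L,
        guide = hit$guide, pam = hit$pam, pattern = pattern, gc = hit$gc,
        stringsAsFactors = FALSE)
    }
  }
  if (mode %in% c("antisense", "both")) {
    hit <- .scan_strand(revcomp(seq), L, pattern, gc_min, gc_max)
    if (!is.null(hit) && length(hit$p)) {
      W <- L + 3L
      out$A <- data.frame(
        guide_id = guide_naming(record_id, "A", seq_along(hit$p)),
        record_id = record_id, strand = "A",
        start = n - (hit$p + W - 1L) + 1L, end = n - hit$p + 1L,
        guide = hit$guide, pam = hit$pam, pattern = pattern, gc = hit$gc,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(.empty_protospacers())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Enumerate PAM-out guide pairs for double nicking
#'
#' Pairs one antisense-strand protospacer (PAM at the genomically left end;
#' the sense strand reads `CCN` there) with one sense-strand protospacer
#' (PAM `NGG` at the right) on the same record, keeping pairs whose sgRNA
#' offset -- the signed gap in bp between the two PAM-distal (5') guide ends,
#' i.e. `sense site start - antisense site end - 1` in sense coordinates --
#' falls within `[offset_min, offset_max]`. Abutting guides have offset 0;
#' overlaps are negative. One protospacer may appear in several pairs.
#'
#' @inheritParams find_protospacers
#' @param offset_min,offset_max Inclusive offset window in bp (defaults -2
#'   and 32, the window supporting 5'-overhang double nicks).
#' @return A data frame with the antisense member (`left_*` columns), sense
#'   member (`right_*` columns) and `offset`.
#' @export
find_pairs <- function(record_id, seq, pattern = c("X20", "GX19", "GGX18"),
                       guide_len = 20L, gc_min = 20, gc_max = 80,
                       offset_min = -2L, offset_max = 32L) {
  if (offset_min > offset_max) {
    stop("offset_min exceeds offset_max", call. = FALSE)
  }
  ps <- find_protospacers(record_id, seq, mode = "both",
                          pattern = match.arg(pattern), guide_len = guide_len,
                          gc_min = gc_min, gc_max = gc_max)
  a <- ps[ps$strand == "A", , drop = FALSE]
  s <- ps[ps$strand == "S", , drop = FALSE]
  pairs <- list()
  if (nrow(a) && nrow(s)) {
    grid <- expand.grid(ai = seq_len(nrow(a)), si = seq_len(nrow(s)))
    offset <- s$start[grid$si] - a$end[grid$ai] - 1L
    keep <- offset >= offset_min & offset <= offset_max
    if (any(keep)) {
      ai <- grid$ai[keep]; si <- grid$si[keep]
      left <- a[ai, , drop = FALSE]
      right <- s[si, , drop = FALSE]
      names(left) <- paste0("left_", names(left))
      names(right) <- paste0("right_", names(right))
      pairs <- cbind(left, right, offset = offset[keep])
      pairs <- pairs[order(pairs$left_start, pairs$right_start), , drop = FALSE]
      rownames(pairs) <- NULL
      return(pairs)
    }
  }
  empty <- .empty_protospacers()
  left <- empty; names(left) <- paste0("left_", names(left))
  right <- empty; names(right) <- paste0("right_", names(right))
  cbind(left, right, offset = integer())
}

#' Run protospacer search over a whole input set
#'
#' @param seqs Named character vector from [read_fasta()].
#' @inheritParams find_protospacers
#' @return Row-bound data frame of protospacers across records.
#' @export
find_protospacers_all <- function(seqs, mode = "both", pattern = "X20",
                                  guide_len = 20L, gc_min = 20, gc_max = 80) {
  res <- lapply(names(seqs), function(id) {
    find_protospacers(id, seqs[[id]], mode = mode, pattern = pattern,
                      guide_len = guide_len, gc_min = gc_min, gc_max = gc_max)
  })
  out <- do.call(rbind, c(res, list(.empty_protospacers())))
  rownames(out) <- NULL
  out
}

#' Write protospacer report files
#'
#' Emits `report_protospacer_single.txt` and (when pairs are given)
#' `report_protospacer_pairs.txt` as tab-delimited tables with a header row.
#' Single-site rows carry the full site sequence (guide+PAM, 5'->3').
#'
#' @param protospacers Data frame from [find_protospacers_all()].
#' @param pairs Optional data frame from [find_pairs()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_protospacer_reports <- function(protospacers, pairs = NULL, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  single <- protospacers
  single$sequence <- paste0(single$guide, single$pam)
  f1 <- file.path(out_dir, "report_protospacer_single.txt")
  write.table(single[, c("guide_id", "record_id", "strand", "start", "end",
                         "sequence", "pattern", "gc")],
              f1, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- f1
  if (!is.null(pairs)) {
    f2 <- file.path(out_dir, "report_protospacer_pairs.txt")
    write.table(pairs, f2, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f2)
  }
  invisible(files)
}
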