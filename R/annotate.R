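# GTF intersection: flag off-target/POT loci falling in annotated features.

#' Read a GTF annotation
#'
#' Parses a 9-column Ensembl-dialect GTF (quoted attribute values, embedded
#' semicolons handled) into a feature table.
#'
#' @param path Path to a GTF file.
#' @return Data frame: `chrom`, `source`, `feature_type`, `start`, `end`
#'   (1-based closed), `strand`, `gene_id`, `gene_name`.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  out <- data.frame(
    chrom = as.character(df$seqnames),
    source = if ("source" %in% names(df)) as.character(df$source) else NA_character_,
    feature_type = as.character(df$type),
    start = df$start, end = df$end,
    strand = as.character(df$strand),
    gene_id = if ("gene_id" %in% names(df)) as.character(df$gene_id) else NA_character_,
    gene_name = if ("gene_name" %in% names(df)) as.character(df$gene_name) else NA_character_,
    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("malformed GTF interval", call. = FALSE)
  out
}

# Strip a leading "chr" so Ensembl ("1") and UCSC ("chr1") names compare.
.harmonize_chrom <- function(x, strip_chr = TRUE) {
  if (strip_chr) sub("^chr", "", x) else x
}

#' Annotate hits with overlapping genomic features
#'
#' Each hit gains the features whose interval overlaps its `[start, end]`
#' by at least 1 bp (strand-agnostic: a cleavage event disrupts both
#' strands). Hits overlapping nothing are labeled `intergenic`.
#'
#' @param hits Hit or POT data frame (`chrom`, `start`, `end`).
#' @param features Feature data frame from [read_gtf()].
#' @param types_of_interest Feature types considered (default CDS, exon,
#'   gene).
#' @param strip_chr Harmonize chromosome dialects by stripping a leading
#'   `"chr"` on both sides (default TRUE).
#' @return `hits` with `feature_types`, `gene_ids`, `gene_names` columns
#'   (semicolon-joined; `"intergenic"`/`NA` when no overlap).
#' @export
annotate_hits <- function(hits, features,
                          types_of_interest = c("CDS", "exon", "gene"),
                          strip_chr = TRUE) {
  features <- features[features$feature_type %in% types_of_interest, ,
                       drop = FALSE]
  hc <- .harmonize_chrom(hits$chrom, strip_chr)
  fc <- .harmonize_chrom(features$chrom, strip_chr)
  hits$feature_types <- "intergenic"
  hits$gene_ids <- NA_character_
  hits$gene_names <- NA_character_
  if (nrow(hits) && nrow(features) && !any(hc %in% fc)) {
    warning("no chromosome name shared between hits and features")
    return(hits)
  }
  if (nrow(hits) == 0L || nrow(features) == 0L) return(hits)
  keep_f <- fc %in% hc
  features <- features[keep_f, , drop = FALSE]
  fc <- fc[keep_f]
  if (nrow(features) == 0L) return(hits)
  lv <- unique(c(hc, fc))
  hgr <- GenomicRanges::GRanges(factor(hc, lv),
                                IRanges::IRanges(hits$start, hits$end))
  fgr <- GenomicRanges::GRanges(factor(fc, lv),
                                IRanges::IRanges(features$start, features$end))
  ov <- GenomicRanges::findOverlaps(hgr, fgr, minoverlap = 1L)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  if (length(qh)) {
    agg <- function(vals) {
      tapply(vals[sh], qh, function(v) paste(unique(v), collapse = ";"))
    }
    ft <- agg(features$feature_type)
    gi <- agg(features$gene_id)
    gn <- agg(features$gene_name)
    idx <- as.integer(names(ft))
    hits$feature_types[idx] <- as.character(ft)
    hits$gene_ids[idx] <- as.character(gi)
    hits$gene_names[idx] <- as.character(gn)
  }
  hits
}
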