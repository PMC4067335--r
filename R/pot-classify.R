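# POT classification. The spacer is segmented, counting from the PAM:
# region I = positions 1-7, region II = 8-12 (I+II form the seed),
# region III = 13-L (non-seed). Types by mismatch placement:
#   Type I   : 1-5 mismatches, all in region III
#   Type II  : 1-5 mismatches in II+III, at least one in II, none in I
#   Type III : 1-3 mismatches, at least one in region I
# A region-I mismatch with 4-5 total mismatches fits no type -> excluded.
# Perfect NGG matches are not POT (they feed the multi-locus filter);
# perfect NAG matches are Type I with n = 0 and top risk.

#' Spacer region scheme
#'
#' @param L Spacer length (>= 13 so region III is non-empty).
#' @return A list with integer position vectors `region_I`, `region_II`,
#'   `region_III`, `seed`, `non_seed` (positions counted PAM-proximal = 1).
#' @export
region_scheme <- function(L = 20L) {
  stopifnot(L >= 13L)
  list(region_I = 1:7, region_II = 8:12, region_III = 13:L,
       seed = 1:12, non_seed = 13:L)
}

# Core pure classifier: positions are PAM-proximal indices.
.classify_one <- function(pos, n, pam_class, L) {
  if (length(pos) && (min(pos) < 1L || max(pos) > L)) {
    stop("mismatch position outside 1..L", call. = FALSE)
  }
  if (n == 0L) {
    return(if (pam_class == "NGG") "perfect" else "I")
  }
  if (n > 5L) return("excluded")
  if (any(pos <= 7L)) {
    if (n <= 3L) "III" else "excluded"
  } else if (any(pos <= 12L)) {
    "II"
  } else {
    "I"
  }
}

#' Classify off-target hits into POT types
#'
#' Adds a `pot_type` column (`"I"`, `"II"`, `"III"`, `"excluded"` or
#' `"perfect"`) to a hit table per the positional rules above, plus a
#' logical `nag_perfect` flag marking zero-mismatch NAG sites (reported as
#' Type I with `n_mismatch = 0`).
#'
#' @param hits Hit data frame from [search_offtargets()].
#' @param L Spacer length used in the search.
#' @return `hits` with `pot_type` and `nag_perfect` columns.
#' @export
classify_hits <- function(hits, L = 20L) {
  scheme <- region_scheme(L)   # validates L
  pos_list <- .parse_positions(hits$mismatch_positions)
  hits$pot_type <- vapply(seq_len(nrow(hits)), function(i) {
    .classify_one(pos_list[[i]], hits$n_mismatch[i], hits$pam_class[i], L)
  }, character(1))
  hits$nag_perfect <- hits$n_mismatch == 0L & hits$pam_class == "NAG"
  hits
}

.parse_positions <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  lapply(strsplit(x, ",", fixed = TRUE),
         function(v) as.integer(v[nzchar(v)]))
}

#' Classify a single hit
#'
#' @param mismatch_positions Integer vector of PAM-proximal positions.
#' @param pam_class `"NGG"` or `"NAG"`.
#' @param L Spacer length.
#' @return One of `"perfect"`, `"I"`, `"II"`, `"III"`, `"excluded"`.
#' @export
classify_hit <- function(mismatch_positions, pam_class = "NGG", L = 20L) {
  region_scheme(L)
  .classify_one(as.integer(mismatch_positions),
                length(mismatch_positions), pam_class, L)
}

#' Rank POT records by cleavage risk
#'
#' Risk order: Type I (seed intact, cleaves most readily) > II > III, and
#' within a type fewer mismatches are more dangerous. Rank 1 is the most
#' dangerous; identical (type, n) records share a rank (dense ranking).
#' Perfect and excluded records get `NA`.
#'
#' @param pots Classified hit data frame from [classify_hits()].
#' @return `pots` with a `risk_rank` integer column.
#' @export
rank_risk <- function(pots) {
  type_idx <- match(pots$pot_type, c("I", "II", "III"))
  key <- ifelse(is.na(type_idx), NA_real_,
                type_idx * 10 + pmin(pots$n_mismatch, 9L))
  uk <- sort(unique(key[!is.na(key)]))
  pots$risk_rank <- as.integer(match(key, uk))
  pots
}

#' Build per-guide off-target summary reports
#'
#' @param guides Protospacer data frame (defines the guide universe; guides
#'   with no hits at all still get a report row).
#' @param pots Classified (and optionally ranked) hit data frame.
#' @return One row per guide: `guide_id`, `total_ot` (all NGG/NAG hits,
#'   on-target included), `n_perfect` (zero-mismatch NGG loci),
#'   `pot_I`/`pot_II`/`pot_III`, `total_pot`, `min_mm_pot` (smallest
#'   mismatch count among POT, `NA` if none), `n_pot_mm12` (POT carrying
#'   1 or 2 mismatches; zero-mismatch NAG POT do not count).
#' @export
guide_reports <- function(guides, pots) {
  ids <- unique(guides$guide_id)
  is_pot <- pots$pot_type %in% c("I", "II", "III")
  rep1 <- function(gid) {
    h <- pots[pots$guide_id == gid, , drop = FALSE]
    p <- h[h$pot_type %in% c("I", "II", "III"), , drop = FALSE]
    data.frame(
      guide_id = gid,
      total_ot = nrow(h),
      n_perfect = sum(h$n_mismatch == 0L & h$pam_class == "NGG"),
      pot_I = sum(p$pot_type == "I"),
      pot_II = sum(p$pot_type == "II"),
      pot_III = sum(p$pot_type == "III"),
      total_pot = nrow(p),
      min_mm_pot = if (nrow(p)) min(p$n_mismatch) else NA_integer_,
      n_pot_mm12 = sum(p$n_mismatch %in% 1:2),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(lapply(ids, rep1), list(data.frame(
    guide_id = character(), total_ot = integer(), n_perfect = integer(),
    pot_I = integer(), pot_II = integer(), pot_III = integer(),
    total_pot = integer(), min_mm_pot = integer(), n_pot_mm12 = integer(),
    stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}

#' Select high-specificity guides
#'
#' Applies the filter cascade, in order: (1) guides with no perfect-match
#' genomic locus (e.g. spanning an exon junction) are discarded
#' (`not_on_genome`); (2) guides matching more than one locus perfectly are
#' discarded (`multi_locus`); (3) guides with any POT carrying 1 or 2
#' mismatches are discarded (`has_1or2_mm_pot`). Survivors are sorted by
#' total POT then total off-target count, ascending.
#'
#' @param reports Data frame from [guide_reports()].
#' @return `reports` with `verdict` (`kept`/`discarded`) and
#'   `discard_reason` (`none`, `not_on_genome`, `multi_locus`,
#'   `has_1or2_mm_pot`); kept rows first in specificity order.
#' @export
select_guides <- function(reports) {
  reason <- rep("none", nrow(reports))
  reason[reports$n_pot_mm12 > 0L] <- "has_1or2_mm_pot"
  reason[reports$n_perfect > 1L] <- "multi_locus"
  reason[reports$n_perfect == 0L] <- "not_on_genome"
  reports$verdict <- ifelse(reason == "none", "kept", "discarded")
  reports$discard_reason <- reason
  kept <- reports[reports$verdict == "kept", , drop = FALSE]
  kept <- kept[order(kept$total_pot, kept$total_ot), , drop = FALSE]
  disc <- reports[reports$verdict == "discarded", , drop = FALSE]
  out <- rbind(kept, disc)
  rownames(out) <- NULL
  out
}

#' Write POT classification and selection reports
#'
#' Mirrors the pipeline's output layout: one TSV per type under
#' `Type_I_POT/`, `Type_II_POT/`, `Type_III_POT/`; one file per guide under
#' `Sort_POT_byID/` listing its POT (site sequence with mismatches
#' lowercased, mismatch count, ID, chromosome, position, strand, type);
#' kept guides under `Final_report/`.
#'
#' @param pots Classified, risk-ranked hit data frame.
#' @param selection Data frame from [select_guides()].
#' @param out_dir Output directory root.
#' @return `out_dir`, invisibly.
#' @export
write_pot_reports <- function(pots, selection, out_dir) {
  pot_cols <- c("site_seq", "n_mismatch", "guide_id", "chrom", "start",
                "end", "strand", "pot_type", "pam_class", "risk_rank",
                "nag_perfect")
  pot_cols <- intersect(pot_cols, names(pots))
  is_pot <- pots$pot_type %in% c("I", "II", "III")
  for (tp in c("I", "II", "III")) {
    d <- file.path(out_dir, sprintf("Type_%s_POT", tp))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write.table(pots[is_pot & pots$pot_type == tp, pot_cols, drop = FALSE],
                file.path(d, sprintf("Type_%s_POT.txt", tp)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  byid <- file.path(out_dir, "Sort_POT_byID")
  dir.create(byid, recursive = TRUE, showWarnings = FALSE)
  for (gid in unique(pots$guide_id)) {
    sel <- is_pot & pots$guide_id == gid
    write.table(pots[sel, pot_cols, drop = FALSE],
                file.path(byid, paste0(gid, ".txt")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  fin <- file.path(out_dir, "Final_report")
  dir.create(fin, recursive = TRUE, showWarnings = FALSE)
  write.table(selection[selection$verdict == "kept", , drop = FALSE],
              file.path(fin, "final_report.txt"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(selection, file.path(fin, "selection_all.txt"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
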