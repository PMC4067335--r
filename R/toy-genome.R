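# Synthetic toy genomes with planted on-/off-target sites, so the whole
# pipeline is testable without reference downloads. Deterministic for a
# fixed seed; the caller's RNG state is preserved.

# Cyclic substitution guarantees a real mismatch at a chosen position.
.mutate_base <- function(b) chartr("ACGT", "CGTA", b)

#' Declare a planted site for the toy genome
#'
#' @param guide Spacer the site derives from.
#' @param chrom Chromosome name.
#' @param pos 1-based start of the full site (guide+PAM) on the reference
#'   strand.
#' @param strand `"+"` or `"-"` (the strand the site reads 5'->3' on).
#' @param mismatch_positions PAM-proximal positions (1 = adjacent to PAM)
#'   to mutate away from the guide.
#' @param pam 3-nt PAM planted 3' of the spacer (e.g. `"AGG"`, `"TAG"`,
#'   `"TCG"` for a rejected class).
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(guide, chrom, pos, strand = "+",
                       mismatch_positions = integer(0), pam = "AGG") {
  stopifnot(nchar(pam) == 3L, strand %in% c("+", "-"))
  .check_alphabet(c(guide, pam))
  L <- nchar(guide)
  if (length(mismatch_positions) &&
      (min(mismatch_positions) < 1L || max(mismatch_positions) > L)) {
    stop("mismatch position outside 1..L", call. = FALSE)
  }
  structure(list(guide = guide, chrom = chrom, pos = as.integer(pos),
                 strand = strand,
                 mismatch_positions = as.integer(mismatch_positions),
                 pam = pam),
            class = "plant_spec")
}

# The site sequence as read 5'->3' on its own strand.
.plant_site_seq <- function(spec) {
  L <- nchar(spec$guide)
  ch <- strsplit(spec$guide, "")[[1]]
  i5 <- L + 1L - spec$mismatch_positions   # PAM-proximal -> 5' index
  ch[i5] <- .mutate_base(ch[i5])
  paste0(paste(ch, collapse = ""), spec$pam)
}

#' Generate a toy genome with planted sites
#'
#' Draws a uniform-random A/C/G/T background and overwrites it with each
#' planted site (reverse-complemented for `"-"`-strand plants). Planted
#' windows may not collide with each other or run off a chromosome. The
#' returned truth table records, for every plant, its expected coordinates,
#' mismatch count, PAM class and site sequence, so engine output can be
#' checked against ground truth (background may add extra bona fide hits).
#'
#' @param seed Integer RNG seed; the same seed reproduces the same genome.
#' @param chrom_len Named integer vector: chromosome name -> length in bp.
#' @param plants List of [plant_spec()] objects.
#' @param gc Background GC fraction (default 0.5; uniform base composition).
#' @return A list: `genome` (named character vector) and `truth` (data
#'   frame: `guide`, `chrom`, `start`, `end`, `strand`, `n_mismatch`,
#'   `mismatch_positions`, `pam`, `pam_class`, `site_seq`).
#' @export
make_toy_genome <- function(seed, chrom_len, plants = list(), gc = 0.5) {
  stopifnot(!is.null(names(chrom_len)), all(chrom_len >= 1L))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  genome <- vapply(chrom_len, function(n) {
    paste(sample(names(probs), n, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))

  occupied <- lapply(chrom_len, function(n) integer(0))
  truth <- list()
  for (spec in plants) {
    if (!spec$chrom %in% names(genome)) {
      stop("plant on unknown chromosome: ", spec$chrom, call. = FALSE)
    }
    W <- nchar(spec$guide) + 3L
    start <- spec$pos
    end <- start + W - 1L
    if (start < 1L || end > chrom_len[[spec$chrom]]) {
      stop("planted window out of bounds on ", spec$chrom, call. = FALSE)
    }
    span <- start:end
    if (any(span %in% occupied[[spec$chrom]])) {
      stop("planted windows collide on ", spec$chrom, call. = FALSE)
    }
    occupied[[spec$chrom]] <- c(occupied[[spec$chrom]], span)
    site <- .plant_site_seq(spec)
    written <- if (spec$strand == "+") site else revcomp(site)
    g <- genome[[spec$chrom]]
    genome[[spec$chrom]] <- paste0(substring(g, 1L, start - 1L), written,
                                   substring(g, end + 1L, nchar(g)))
    truth[[length(truth) + 1L]] <- data.frame(
      guide = spec$guide, chrom = spec$chrom, start = start, end = end,
      strand = spec$strand, n_mismatch = length(spec$mismatch_positions),
      mismatch_positions = paste(sort(spec$mismatch_positions), collapse = ","),
      pam = spec$pam,
      pam_class = ifelse(is.na(.pam_class(spec$pam)), "rejected",
                         .pam_class(spec$pam)),
      site_seq = site, stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(guide = character(), chrom = character(), start = integer(),
               end = integer(), strand = character(), n_mismatch = integer(),
               mismatch_positions = character(), pam = character(),
               pam_class = character(), site_seq = character(),
               stringsAsFactors = FALSE)
  list(genome = genome, truth = truth)
}
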