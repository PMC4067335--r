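# End-to-end pipeline: target search -> genome-wide off-target scan ->
# POT classification -> selection cascade -> oligo design -> flank
# extraction (-> optional GTF annotation), with a run log of stage counts.

#' Build a run configuration
#'
#' Defaults follow the standard design conditions: 20-nt spacer, GC 20-80%,
#' up to 5 mismatches in the off-target scan, nickase pair offsets -2..32 bp,
#' 1000-bp validation amplicons.
#'
#' @param input_path Multi-FASTA of target sequences (5'->3').
#' @param genome_path Multi-FASTA reference genome.
#' @param gtf_path Optional GTF for coding-region annotation.
#' @param guide_len Spacer length L (nt).
#' @param gc_min,gc_max Inclusive GC%% window for spacers.
#' @param strand_mode `"s"` (sense), `"a"` (antisense) or `"b"` (both).
#' @param design_type `"single"` or `"paired"` (nickase pairs).
#' @param max_mismatch Off-target mismatch budget k.
#' @param offset_min,offset_max Pair offset window (bp).
#' @param pattern `"X20"`, `"GX19"` or `"GGX18"`.
#' @param output_dir Directory for report files.
#' @param adapter_sense,adapter_antisense Cloning-oligo adapters.
#' @param flank_window Validation amplicon length (bp).
#' @return A `run_config` list.
#' @export
run_config <- function(input_path, genome_path, gtf_path = NULL,
                       guide_len = 20L, gc_min = 20, gc_max = 80,
                       strand_mode = c("b", "s", "a"),
                       design_type = c("single", "paired"),
                       max_mismatch = 5L, offset_min = -2L, offset_max = 32L,
                       pattern = c("X20", "GX19", "GGX18"),
                       output_dir = "protospacer_out",
                       adapter_sense = "accg", adapter_antisense = "aaac",
                       flank_window = 1000L) {
  strand_mode <- match.arg(strand_mode)
  design_type <- match.arg(design_type)
  pattern <- match.arg(pattern)
  if (gc_min > gc_max) stop("gc_min exceeds gc_max", call. = FALSE)
  if (offset_min > offset_max) stop("offset_min exceeds offset_max", call. = FALSE)
  structure(list(input_path = input_path, genome_path = genome_path,
                 gtf_path = gtf_path, guide_len = as.integer(guide_len),
                 gc_min = gc_min, gc_max = gc_max, strand_mode = strand_mode,
                 design_type = design_type,
                 max_mismatch = as.integer(max_mismatch),
                 offset_min = as.integer(offset_min),
                 offset_max = as.integer(offset_max), pattern = pattern,
                 output_dir = output_dir, adapter_sense = adapter_sense,
                 adapter_antisense = adapter_antisense,
                 flank_window = as.integer(flank_window)),
            class = "run_config")
}

.mode_name <- function(m) c(s = "sense", a = "antisense", b = "both")[[m]]

#' Run the full guide-design pipeline
#'
#' Executes: protospacer search (and pair enumeration when
#' `design_type = "paired"`), genome-wide off-target scan, POT
#' classification and risk ranking, the selection cascade, oligo design for
#' kept guides passing sequence QC, and flank extraction around each kept
#' guide's on-target cleavage site; GTF annotation of POT when a GTF is
#' configured. All report files are written under `config$output_dir`, and
#' per-stage counts go to `run.log` there.
#'
#' @param config A [run_config()] object.
#' @return Invisibly, a list with every intermediate table: `protospacers`,
#'   `pairs`, `hits`, `pots`, `reports`, `selection`, `oligos`, `flanks`,
#'   `annotated`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  seqs <- stage("read_input", read_fasta(config$input_path))
  genome <- stage("read_genome", format_genome(config$genome_path))
  say("input: %d record(s); genome: %d chromosome(s), %d bp",
      length(seqs), length(genome), sum(nchar(genome)))

  ps <- stage("target_search", find_protospacers_all(
    seqs, mode = .mode_name(config$strand_mode), pattern = config$pattern,
    guide_len = config$guide_len, gc_min = config$gc_min,
    gc_max = config$gc_max))
  say("protospacers found: %d", nrow(ps))
  non_g <- ps$guide[!startsWith(ps$guide, "G")]
  if (length(non_g)) {
    say("WARN: %d guide(s) do not start with G (U6/T7 transcripts start with G)",
        length(non_g))
  }

  pairs <- NULL
  if (config$design_type == "paired") {
    pairs <- stage("pair_search", do.call(rbind, lapply(names(seqs), function(id) {
      find_pairs(id, seqs[[id]], pattern = config$pattern,
                 guide_len = config$guide_len, gc_min = config$gc_min,
                 gc_max = config$gc_max, offset_min = config$offset_min,
                 offset_max = config$offset_max)
    })))
    say("nickase pairs in offset window [%d, %d]: %d",
        config$offset_min, config$offset_max,
        if (is.null(pairs)) 0L else nrow(pairs))
  }

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  write_protospacer_reports(ps, pairs, config$output_dir)

  # off-target scan over unique spacers (duplicate spacers share hits)
  uniq <- ps[!duplicated(ps$guide), , drop = FALSE]
  hits_u <- stage("offtarget_scan",
                  search_offtargets(uniq, genome, k = config$max_mismatch))
  hits <- do.call(rbind, lapply(seq_len(nrow(ps)), function(i) {
    uid <- uniq$guide_id[match(ps$guide[i], uniq$guide)]
    h <- hits_u[hits_u$guide_id == uid, , drop = FALSE]
    if (nrow(h)) h$guide_id <- ps$guide_id[i]
    h
  }))
  if (is.null(hits)) hits <- .empty_hits()
  rownames(hits) <- NULL
  say("off-target scan (k = %d): %d hit(s)", config$max_mismatch, nrow(hits))
  write_offtarget_reports(hits, config$output_dir)

  pots <- stage("classification",
                rank_risk(classify_hits(hits, L = config$guide_len)))
  say("POT: %d Type I, %d Type II, %d Type III (excluded: %d)",
      sum(pots$pot_type == "I"), sum(pots$pot_type == "II"),
      sum(pots$pot_type == "III"), sum(pots$pot_type == "excluded"))

  reports <- stage("selection", guide_reports(ps, pots))
  selection <- select_guides(reports)
  say("guides kept: %d of %d", sum(selection$verdict == "kept"), nrow(selection))
  write_pot_reports(pots, selection, config$output_dir)

  kept <- selection$guide_id[selection$verdict == "kept"]
  oligos <- list(); flanks <- character(0)
  for (gid in kept) {
    g <- ps$guide[ps$guide_id == gid][1]
    qc <- qc_guide(g)
    if (!qc$pass) {
      say("WARN: kept guide %s fails sequence QC (%s); no oligos designed",
          gid, qc$reason)
      next
    }
    oligos[[gid]] <- make_oligos(g, gid, config$adapter_sense,
                                 config$adapter_antisense)
    h <- pots[pots$guide_id == gid & pots$n_mismatch == 0L &
                pots$pam_class == "NGG", , drop = FALSE]
    if (nrow(h) == 1L) {
      fl <- extract_flank(genome, h$chrom, cleavage_center(h),
                          config$flank_window)
      if (nchar(fl) < config$flank_window) {
        say("WARN: flank for %s truncated at chromosome bound (%d bp)",
            gid, nchar(fl))
      }
      names(fl) <- paste0(gid, " ", names(fl))
      flanks <- c(flanks, fl)
    }
  }
  oligos <- if (length(oligos)) do.call(rbind, oligos) else
    data.frame(guide_id = character(), sense_oligo = character(),
               antisense_oligo = character(), stringsAsFactors = FALSE)
  rownames(oligos) <- NULL
  write.table(oligos, file.path(config$output_dir, "sgRNA_oligos.txt"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(flanks)) {
    write_fasta(flanks, file.path(config$output_dir, "target_flanks.fa"))
  }
  say("oligos designed: %d; flank amplicons: %d", nrow(oligos), length(flanks))

  annotated <- NULL
  if (!is.null(config$gtf_path)) {
    feats <- stage("annotation_read", read_gtf(config$gtf_path))
    annotated <- stage("annotation",
                       annotate_hits(pots[pots$pot_type %in%
                                            c("I", "II", "III"), , drop = FALSE],
                                     feats))
    write.table(annotated,
                file.path(config$output_dir, "POT_annotated.txt"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    say("annotated POT in features: %d of %d",
        sum(annotated$feature_types != "intergenic"), nrow(annotated))
  }

  writeLines(log_lines, file.path(config$output_dir, "run.log"))
  invisible(list(protospacers = ps, pairs = pairs, hits = hits, pots = pots,
                 reports = reports, selection = selection, oligos = oligos,
                 flanks = flanks, annotated = annotated, config = config))
}

#' Parse command-line arguments into a run configuration
#'
#' Flag grammar: `-i` input FASTA, `-g` genome FASTA, `-x` spacer length,
#' `-l`/`-m` GC%% min/max, `-o` strand mode (s|a|b), `-t` design type
#' (s single | p paired), `-n` max mismatches, `-s`/`-e` pair offset
#' min/max, `-d` output directory, `-v` accepted and ignored (historical
#' platform switch), `--gtf`, `--pattern`, `--flank`.
#'
#' @param argv Character vector of arguments (e.g. `commandArgs(TRUE)`).
#' @return A [run_config()] object.
#' @export
parse_cli <- function(argv) {
  opts <- list(
    optparse::make_option(c("-i", "--input"), type = "character", dest = "input",
                          help = "input FASTA of target sequences"),
    optparse::make_option(c("-g", "--genome"), type = "character", dest = "genome",
                          help = "reference genome FASTA"),
    optparse::make_option(c("-x", "--length"), type = "integer", default = 20L,
                          dest = "len", help = "spacer length [20]"),
    optparse::make_option(c("-l", "--gc-min"), type = "double", default = 20,
                          dest = "gcmin", help = "min GC%% [20]"),
    optparse::make_option(c("-m", "--gc-max"), type = "double", default = 80,
                          dest = "gcmax", help = "max GC%% [80]"),
    optparse::make_option(c("-o", "--mode"), type = "character", default = "b",
                          dest = "mode", help = "strand mode s|a|b [b]"),
    optparse::make_option(c("-t", "--type"), type = "character", default = "s",
                          dest = "type", help = "design type s|p [s]"),
    optparse::make_option(c("-n", "--mismatch"), type = "integer", default = 5L,
                          dest = "mm", help = "max mismatches [5]"),
    optparse::make_option(c("-s", "--offset-min"), type = "integer", default = -2L,
                          dest = "omin", help = "pair offset min [-2]"),
    optparse::make_option(c("-e", "--offset-max"), type = "integer", default = 32L,
                          dest = "omax", help = "pair offset max [32]"),
    optparse::make_option(c("-v", "--system"), type = "character", default = NULL,
                          dest = "system",
                          help = "accepted and ignored (platform switch)"),
    optparse::make_option(c("-d", "--outdir"), type = "character",
                          default = "protospacer_out", dest = "outdir",
                          help = "output directory [protospacer_out]"),
    optparse::make_option("--gtf", type = "character", default = NULL,
                          help = "GTF annotation (optional)"),
    optparse::make_option("--pattern", type = "character", default = "X20",
                          help = "search pattern X20|GX19|GGX18 [X20]"),
    optparse::make_option("--flank", type = "integer", default = 1000L,
                          help = "validation amplicon length [1000]"))
  parser <- optparse::OptionParser(option_list = opts,
                                   prog = "protospacer-cli")
  parsed <- tryCatch(optparse::parse_args(parser, args = argv),
                     error = function(e) {
                       stop("usage error: ", conditionMessage(e), call. = FALSE)
                     })
  if (is.null(parsed$input) || is.null(parsed$genome)) {
    stop("usage error: -i <input.fa> and -g <genome.fa> are required",
         call. = FALSE)
  }
  if (!parsed$mode %in% c("s", "a", "b")) {
    stop("usage error: -o must be s, a or b", call. = FALSE)
  }
  if (!parsed$type %in% c("s", "p")) {
    stop("usage error: -t must be s or p", call. = FALSE)
  }
  run_config(input_path = parsed$input, genome_path = parsed$genome,
             gtf_path = parsed$gtf, guide_len = parsed$len,
             gc_min = parsed$gcmin, gc_max = parsed$gcmax,
             strand_mode = parsed$mode,
             design_type = if (parsed$type == "p") "paired" else "single",
             max_mismatch = parsed$mm, offset_min = parsed$omin,
             offset_max = parsed$omax, pattern = parsed$pattern,
             output_dir = parsed$outdir, flank_window = parsed$flank)
}
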