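#' Pipeline configuration
#'
#' Builds the effective parameter set from defaults, an optional YAML file,
#' and explicit overrides (precedence: overrides > file > defaults).
#' Unknown keys are rejected.
#'
#' @param path Optional YAML file.
#' @param ... Named overrides.
#' @return A list of class `PipelineConfig`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  defaults <- list(collapse_threshold = 6L, min_run_len = 6L,
                   max_interruptions = 2L, circular = TRUE,
                   genetic_code = 13L,
                   match = 5, mismatch = -4, gap_open = -10,
                   gap_extend = -0.5, min_score = 50,
                   min_aa = 25L, orphan_min_aa = 100L,
                   out_dir = ".", seed = 1L)
  cfg <- defaults
  apply_over <- function(cfg, over, src) {
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown) > 0L)
      stop("unknown configuration key(s) in ", src, ": ",
           paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
    cfg
  }
  if (!is.null(path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read config files")
    cfg <- apply_over(cfg, yaml::read_yaml(path), path)
  }
  over <- list(...)
  if (length(over) > 0L) cfg <- apply_over(cfg, over, "arguments")
  for (k in c("collapse_threshold", "min_run_len", "max_interruptions"))
    if (cfg[[k]] < 1L) stop(k, " must be >= 1")
  structure(cfg, class = "PipelineConfig")
}

## annotations data.frame -> GRanges (1-based inclusive, like GFF3)
.annotations_to_granges <- function(annotations, seq_id) {
  if (nrow(annotations) == 0L) {
    return(GenomicRanges::GRanges())
  }
  gr <- GenomicRanges::GRanges(
    seqnames = seq_id,
    ranges = IRanges::IRanges(start = annotations$start,
                              end = annotations$end),
    strand = annotations$strand)
  gr$type <- "gene"
  gr$ID <- annotations$gene_symbol
  gr$Name <- annotations$gene_symbol
  if ("n_edited" %in% names(annotations))
    gr$n_edited <- annotations$n_edited
  if ("transcript_id" %in% names(annotations))
    gr$transcript_id <- annotations$transcript_id
  gr
}

#' Write pipeline outputs to a directory
#'
#' Writes gene annotations as GFF3 (with `edited_homopolymer` features for
#' the edit events), homopolymer runs as a BED track, plus TSV tables for
#' runs, events, composition statistics, and validation flags.  Columns and
#' row order are stable, so reruns on identical inputs are byte-identical;
#' the returned manifest carries an md5 checksum per file.
#'
#' @param out_dir Output directory (created if missing).
#' @param genome A [circular_sequence()] (used for ids and the FASTA copy).
#' @param annotations Optional annotation data.frame (see
#'   [annotate_genes()]).
#' @param runs Optional run table from [find_runs()].
#' @param events Optional edit-event table (e.g. from [edit_dna_to_rna()]
#'   or synthetic truth `insertions`).
#' @param stats Optional `HomopolymerStats`.
#' @param validation Optional `ValidationReport`.
#' @return Data.frame manifest: `file`, `md5`.
#' @export
write_outputs <- function(out_dir, genome, annotations = NULL, runs = NULL,
                          events = NULL, stats = NULL, validation = NULL) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  files <- character()
  seq_id <- genome$id

  fa <- file.path(out_dir, "genome.fasta")
  write_fasta(list(genome), fa)
  files <- c(files, fa)

  if (!is.null(annotations)) {
    gff <- file.path(out_dir, "annotations.gff3")
    gr <- .annotations_to_granges(annotations, seq_id)
    if (!is.null(events) && nrow(events) > 0L &&
        all(c("genomic_start", "genomic_end") %in% names(events))) {
      ev <- GenomicRanges::GRanges(
        seqnames = seq_id,
        ranges = IRanges::IRanges(start = events$genomic_start,
                                  end = events$genomic_end),
        strand = "*")
      ev$type <- "edited_homopolymer"
      ev$ID <- sprintf("edit%d", seq_len(nrow(events)))
      gr <- suppressWarnings(c(gr, ev))
    }
    rtracklayer::export.gff3(gr, gff)
    files <- c(files, gff)

    tsv <- file.path(out_dir, "annotations.tsv")
    cols <- intersect(c("gene_symbol", "start", "end", "n_edited", "strand",
                        "transcript_id"), names(annotations))
    write.table(annotations[cols], tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, tsv)
  }

  if (!is.null(runs)) {
    bed <- file.path(out_dir, "homopolymers.bed")
    track <- runs_to_track(runs, seq_len_cs(genome), seq_id)
    write.table(track, bed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    files <- c(files, bed)
  }

  if (!is.null(stats)) {
    st <- file.path(out_dir, "homopolymer_stats.tsv")
    df <- data.frame(base = names(stats$covered_fraction),
                     run_count = unname(stats$run_count),
                     bases_covered = unname(stats$bases_covered),
                     fraction = unname(stats$covered_fraction),
                     percent = percent_1dp(unname(stats$covered_fraction)),
                     stringsAsFactors = FALSE)
    write.table(df, st, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, st)
  }

  if (!is.null(events)) {
    evf <- file.path(out_dir, "edit_events.tsv")
    write.table(events, evf, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, evf)
  }

  if (!is.null(validation)) {
    vf <- file.path(out_dir, "validation.tsv")
    write.table(validation$flags, vf, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, vf)
  }

  data.frame(file = files, md5 = unname(tools::md5sum(files)),
             stringsAsFactors = FALSE)
}
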