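#' Annotate genes on a homopolymer-edited mitogenome
#'
#' Implements the grammar-driven annotation procedure: each transcript is
#' mapped onto the genome with [map_transcript_to_genome()]; the coding
#' extent of every gene in the (polycistronic) transcript is determined with
#' [find_orfs()] on the edited sequence; CDS boundaries are projected back
#' to genomic coordinates through the alignment, anchoring the stop codon on
#' its (uniquely aligned) T so that the placement degeneracy inside the
#' poly-A spacers cannot displace gene ends; and the edited poly-T sites of
#' every gene are counted with [count_edited_sites()].
#'
#' When protein queries are supplied, gene symbols are assigned from the
#' query whose [six_frame_search()] hit best overlaps an annotation;
#' otherwise genes are named `orf1`, `orf2`, ... in genomic order.  ORFs of
#' at least `orphan_min_aa` amino acids that overlap no annotated gene are
#' reported with the symbol `orfX`.
#'
#' @param genome A [circular_sequence()].
#' @param transcripts Named character vector (or list) of edited transcript
#'   sequences; names are used as transcript ids.
#' @param protein_queries Optional named character vector of protein
#'   sequences used for naming.
#' @param code A [genetic_code()].
#' @param collapse_threshold,max_interruptions Editing-model parameters.
#' @param scheme Nucleotide [scoring_scheme()] for transcript mapping.
#' @param min_aa Minimum protein length for a transcript-internal gene ORF.
#' @param min_score Minimum mapping score (below: transcript is skipped).
#' @param orphan_min_aa Minimum length for reporting unassigned genomic ORFs;
#'   `NA` disables orphan reporting.
#' @return A list of class `AnnotationSet`: `genes` (data.frame with
#'   `gene_symbol`, `start`, `end`, `strand`, `n_edited`, `transcript_id`,
#'   `wraps_origin`, `ambiguous_start`), `skipped` (unmapped transcript
#'   ids), and `mappings` (per-transcript `TranscriptMapping`s).
#' @export
annotate_genes <- function(genome, transcripts,
                           protein_queries = NULL,
                           code = genetic_code(13L),
                           collapse_threshold = 6L,
                           max_interruptions = 2L,
                           scheme = scoring_scheme(),
                           min_aa = 25L, min_score = 50,
                           orphan_min_aa = 100L) {
  stopifnot(inherits(genome, "CircularSequence"))
  if ((is.null(transcripts) || length(transcripts) == 0L) &&
      is.null(protein_queries) && is.na(orphan_min_aa))
    stop("provide transcripts and/or protein queries")
  transcripts <- unlist(transcripts)
  if (length(transcripts) > 0L && is.null(names(transcripts)))
    names(transcripts) <- paste0("transcript", seq_along(transcripts))
  L <- seq_len_cs(genome)

  skipped <- character()
  mappings <- list()
  rows <- list()

  for (tid in names(transcripts)) {
    tr <- toupper(transcripts[[tid]])
    mp <- map_transcript_to_genome(tr, genome, scheme,
                                   collapse_threshold, max_interruptions,
                                   min_score)
    mappings[[tid]] <- mp
    if (!mp$mapped) { skipped <- c(skipped, tid); next }
    q2t <- alignment_coordinate_map(mp$alignment)

    # cut the polycistronic transcript into gene blocks at the projected
    # poly-A spacer gaps (genes are separated by genomically encoded poly-A;
    # with left-shifted gaps the base before a spacer gap is the stop
    # codon's T, so a block ends two bases later, after the stop's AA)
    sp <- mp$gaps[mp$gaps$class == "poly_A_spacer", , drop = FALSE]
    cut_after <- sort(unique(pmin(sp$transcript_pos + 2L, nchar(tr))))
    block_start <- c(1L, cut_after + 1L)
    block_end <- c(cut_after, nchar(tr))
    keep_blk <- block_start <= block_end
    block_start <- block_start[keep_blk]; block_end <- block_end[keep_blk]

    chosen <- list()
    for (bi in seq_along(block_start)) {
      blk <- substr(tr, block_start[bi], block_end[bi])
      if (nchar(blk) < 3L * (min_aa + 2L)) next
      orfs <- find_orfs(circular_sequence(blk), code = code,
                        min_aa = min_aa, mode = "start-to-stop")
      orfs <- orfs[orfs$strand == "+", , drop = FALSE]   # mRNA sense only
      if (nrow(orfs) == 0L) next
      orfs <- orfs[order(-orfs$has_stop, -orfs$n_aa, orfs$start), ,
                   drop = FALSE]
      o <- orfs[1L, ]
      o$start <- o$start + block_start[bi] - 1L
      o$end <- o$end + block_start[bi] - 1L
      chosen[[length(chosen) + 1L]] <- o
    }

    for (o in chosen) {
      g <- .project_cds(o, q2t, mp, L, genome$is_circular)
      if (is.null(g)) next
      n_ed <- count_edited_sites(genome, g$start, g$end, g$strand,
                                 collapse_threshold, max_interruptions)
      amb <- .ambiguous_start(genome, g$start, g$end, g$strand, code,
                              collapse_threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_symbol = NA_character_, start = g$start, end = g$end,
        strand = g$strand, n_edited = n_ed, transcript_id = tid,
        wraps_origin = g$wraps, ambiguous_start = amb,
        stringsAsFactors = FALSE)
    }
  }

  genes <- if (length(rows)) do.call(rbind, rows)
           else data.frame(gene_symbol = character(), start = integer(),
                           end = integer(), strand = character(),
                           n_edited = integer(), transcript_id = character(),
                           wraps_origin = logical(),
                           ambiguous_start = logical(),
                           stringsAsFactors = FALSE)
  genes <- genes[order(genes$start, genes$end), , drop = FALSE]
  rownames(genes) <- NULL

  # symbols: protein queries when given, positional otherwise
  if (nrow(genes) > 0L) {
    genes$gene_symbol <- paste0("orf", seq_len(nrow(genes)))
    if (!is.null(protein_queries)) {
      pscheme <- scoring_scheme(alphabet = "protein")
      for (qn in names(protein_queries)) {
        hits <- six_frame_search(protein_queries[[qn]], genome,
                                 pscheme, code)
        if (nrow(hits) == 0L) next
        h <- hits[1L, ]
        ov <- which(genes$strand == h$strand &
                    pmin(genes$end, h$end) - pmax(genes$start, h$start) >= 0L)
        if (length(ov) > 0L) {
          best <- ov[which.max(pmin(genes$end[ov], h$end) -
                               pmax(genes$start[ov], h$start))]
          genes$gene_symbol[best] <- qn
        }
      }
    }
  }

  # orphan ORFs between annotated genes
  if (!is.na(orphan_min_aa)) {
    gorfs <- find_orfs(genome, code = code, min_aa = orphan_min_aa,
                       mode = "start-to-stop")
    for (i in seq_len(nrow(gorfs))) {
      o <- gorfs[i, ]
      if (o$wraps_origin) next
      overlaps <- nrow(genes) > 0L &&
        any(pmin(genes$end, o$end) - pmax(genes$start, o$start) >= 0L)
      if (overlaps) next
      rows_o <- data.frame(
        gene_symbol = "orfX", start = o$start, end = o$end,
        strand = o$strand,
        n_edited = count_edited_sites(genome, o$start, o$end, o$strand,
                                      collapse_threshold, max_interruptions),
        transcript_id = NA_character_, wraps_origin = FALSE,
        ambiguous_start = FALSE, stringsAsFactors = FALSE)
      genes <- rbind(genes, rows_o)
    }
    genes <- genes[order(genes$start, genes$end), , drop = FALSE]
    rownames(genes) <- NULL
  }

  structure(list(genes = genes, skipped = skipped, mappings = mappings),
            class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat(sprintf("AnnotationSet: %d genes, %d skipped transcripts\n",
              nrow(x$genes), length(x$skipped)))
  print(x$genes[, c("gene_symbol", "start", "end", "n_edited", "strand",
                    "transcript_id")])
  invisible(x)
}

## project a transcript-space ORF onto the genome through the alignment.
## The stop codon's T (a uniquely aligned base) anchors the 3' end: gaps
## inside the flanking poly-A spacer are placement-degenerate, but the T is
## not, so end = aligned(T) + 2 is exact.  Left-shifted gaps make aligned
## starts 3'-most within a homopolymer, which anchors the 5' end.
.project_cds <- function(orf, q2t, mp, L, circular) {
  a <- orf$start; b <- orf$end            # transcript coords, stop included
  if (orf$has_stop) {
    tpos <- q2t[b - 2L]
    if (is.na(tpos)) return(NULL)
    scan_end <- tpos + 2L
  } else {
    scan_end <- q2t[b]
    if (is.na(scan_end)) return(NULL)
  }
  scan_start <- q2t[a]
  if (is.na(scan_start)) return(NULL)
  dep <- .lift_interval(scan_start, scan_end, mp$strand, L, circular)
  wraps <- dep[2L] < dep[1L]
  list(start = dep[1L], end = dep[2L], strand = mp$strand, wraps = wraps)
}

## flag the start as ambiguous when an A-run of threshold length or more
## sits in the 5' region of the coding sequence with an alternative in-frame
## start codon downstream of it (the situation where transcript evidence
## cannot tell whether translation starts before or after the run)
.ambiguous_start <- function(genome, start, end, strand, code,
                             collapse_threshold) {
  cds <- subseq_circular(genome, start, end)
  if (strand == "-") cds <- revcomp(cds)
  head_len <- min(nchar(cds), 120L)
  head_seq <- substr(cds, 1L, head_len)
  runs <- find_runs(circular_sequence(head_seq), min_len = collapse_threshold,
                    bases = "A")
  if (nrow(runs) == 0L) return(FALSE)
  run_end <- runs$start[1L] + runs$length[1L]      # 0-based half-open
  # first in-frame codon position at or after the run end
  p0 <- (((run_end + 2L) %/% 3L) * 3L) + 1L
  if (p0 > head_len - 2L) return(FALSE)
  for (p in seq(p0, head_len - 2L, by = 3L)) {
    if (substr(head_seq, p, p + 2L) %in% code$starts) return(TRUE)
  }
  FALSE
}

#' Validate annotations against the structural grammar
#'
#' Checks, per gene, the rules that characterize a poly-T-edited
#' mitogenome: the coding-strand CDS ends with TAA; the run immediately 3'
#' of the stop is an A-run longer than the collapse threshold; no A-run of
#' collapse-threshold length or more occurs inside the CDS; and the edited
#' CDS has a length divisible by 3 with no internal stop codon.
#'
#' @param genome A [circular_sequence()].
#' @param annotations A data.frame with `gene_symbol`, `start`, `end`,
#'   `strand` (e.g. the `genes` element of an [annotate_genes()] result, or
#'   synthetic truth).
#' @param collapse_threshold,max_interruptions Editing-model parameters.
#' @param code A [genetic_code()].
#' @return A list of class `ValidationReport`: `flags` (per-gene logical
#'   columns `ends_with_TAA`, `followed_by_polyA`, `no_internal_polyA`,
#'   `cds_len_multiple_of_3`, `no_internal_stop`), `violations`
#'   (long-format data.frame of failed checks) and `n_violations`.
#' @export
validate_structure <- function(genome, annotations,
                               collapse_threshold = 6L,
                               max_interruptions = 2L,
                               code = genetic_code(13L)) {
  stopifnot(inherits(genome, "CircularSequence"))
  n <- seq_len_cs(genome)
  if (nrow(annotations) > 0L &&
      (any(annotations$start < 1L | annotations$start > n) ||
       any(annotations$end < 1L | annotations$end > n)))
    stop("annotation coordinates out of genome bounds")

  flag_rows <- lapply(seq_len(nrow(annotations)), function(i) {
    g <- annotations[i, ]
    cds <- subseq_circular(genome, g$start, g$end)
    if (g$strand == "-") cds <- revcomp(cds)
    len <- nchar(cds)

    ends_taa <- len >= 3L && substr(cds, len - 2L, len) == "TAA"

    # downstream on the coding strand
    down <- if (g$strand == "+") {
      if (genome$is_circular) subseq_circular(genome, g$end + 1L, g$end + 60L)
      else if (g$end < n) substr(genome$residues, g$end + 1L,
                                 min(n, g$end + 60L)) else ""
    } else {
      s <- if (genome$is_circular) subseq_circular(genome, g$start - 60L,
                                                   g$start - 1L)
           else if (g$start > 1L) substr(genome$residues,
                                         max(1L, g$start - 60L),
                                         g$start - 1L) else ""
      if (nchar(s)) revcomp(s) else ""
    }
    lead_a <- if (nchar(down)) attr(regexpr("^A*", down), "match.length")
              else 0L
    followed_polya <- lead_a > collapse_threshold

    internal_a <- find_runs(circular_sequence(cds),
                            min_len = collapse_threshold, bases = "A")
    no_internal_polya <- nrow(internal_a) == 0L

    ed <- edit_dna_to_rna(cds, collapse_threshold, max_interruptions)$edited
    len_ok <- nchar(ed) %% 3L == 0L
    no_stop <- if (len_ok && nchar(ed) >= 6L) {
      body <- substr(ed, 1L, nchar(ed) - 3L)
      !grepl("*", translate_cds(body, code), fixed = TRUE)
    } else len_ok
    data.frame(gene_symbol = g$gene_symbol, ends_with_TAA = ends_taa,
               followed_by_polyA = followed_polya,
               no_internal_polyA = no_internal_polya,
               cds_len_multiple_of_3 = len_ok,
               no_internal_stop = no_stop, stringsAsFactors = FALSE)
  })
  flags <- if (length(flag_rows)) do.call(rbind, flag_rows)
           else data.frame(gene_symbol = character(),
                           ends_with_TAA = logical(),
                           followed_by_polyA = logical(),
                           no_internal_polyA = logical(),
                           cds_len_multiple_of_3 = logical(),
                           no_internal_stop = logical(),
                           stringsAsFactors = FALSE)
  checks <- setdiff(names(flags), "gene_symbol")
  viol <- do.call(rbind, lapply(checks, function(cc) {
    bad <- which(!flags[[cc]])
    if (length(bad) == 0L) return(NULL)
    data.frame(gene_symbol = flags$gene_symbol[bad], check = cc,
               stringsAsFactors = FALSE)
  }))
  if (is.null(viol))
    viol <- data.frame(gene_symbol = character(), check = character(),
                       stringsAsFactors = FALSE)
  structure(list(flags = flags, violations = viol,
                 n_violations = nrow(viol)),
            class = "ValidationReport")
}

#' @export
print.ValidationReport <- function(x, ...) {
  cat(sprintf("ValidationReport: %d gene(s), %d violation(s)\n",
              nrow(x$flags), x$n_violations))
  if (x$n_violations > 0L) print(x$violations)
  invisible(x)
}
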