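#' Scoring scheme for local alignment
#'
#' Affine-gap scoring: a gap of length L costs
#' `gap_open + (L - 1) * gap_extend` (the first gapped column pays the
#' opening penalty).  Defaults follow the EMBOSS `water` convention for
#' nucleotides (match 5, mismatch -4, gap -10/-0.5); the protein scheme uses
#' BLOSUM62 with the same gap penalties.
#'
#' @param match Match score (> 0, nucleotide only).
#' @param mismatch Mismatch score (<= 0, nucleotide only).
#' @param gap_open Gap opening penalty (<= gap_extend <= 0).
#' @param gap_extend Gap extension penalty.
#' @param alphabet `"dna"` or `"protein"`.
#' @param matrix Substitution matrix name for proteins (only `"BLOSUM62"`
#'   is bundled via Biostrings).
#' @return A list of class `ScoringScheme`.
#' @export
scoring_scheme <- function(match = 5, mismatch = -4, gap_open = -10,
                           gap_extend = -0.5,
                           alphabet = c("dna", "protein"),
                           matrix = "BLOSUM62") {
  alphabet <- match.arg(alphabet)
  if (!(gap_open <= gap_extend && gap_extend <= 0))
    stop("affine semantics require gap_open <= gap_extend <= 0")
  if (alphabet == "dna") {
    if (match <= 0) stop("match score must be positive")
    if (mismatch > 0) stop("mismatch penalty must be <= 0")
    letters <- c("A", "C", "G", "T", "N")
    sm <- base::matrix(mismatch, 5, 5, dimnames = list(letters, letters))
    diag(sm) <- match
    sm["N", ] <- mismatch; sm[, "N"] <- mismatch  # N never matches, even N
  } else {
    if (matrix != "BLOSUM62") stop("unsupported protein matrix: ", matrix)
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    sm <- env$BLOSUM62
  }
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, alphabet = alphabet,
                 submat = sm),
            class = "ScoringScheme")
}

## encode a sequence as 1-based indices into the scheme's matrix
.encode_seq <- function(s, scheme) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  idx <- match(ch, rownames(scheme$submat))
  if (anyNA(idx))
    stop("sequence contains characters outside the scheme's alphabet: ",
         paste(unique(ch[is.na(idx)]), collapse = ","))
  idx
}

#' Local (Smith-Waterman) alignment with affine gaps
#'
#' Computes the optimal local alignment of `query` against `target` under a
#' [scoring_scheme()], returning one optimal traceback deterministically
#' (ties prefer the diagonal, then the query-consuming, then the
#' target-consuming move).  When no cell scores above zero the result is an
#' empty alignment with score 0.
#'
#' @param query,target Sequences (character scalars) over the scheme's
#'   alphabet.
#' @param scheme A [scoring_scheme()].
#' @param score_only If `TRUE`, skip the traceback.
#' @return An object of class `LocalAlignment`: list with `score`,
#'   `query_start`/`query_end` and `target_start`/`target_end` (0-based
#'   half-open), `cigar` (ops `M`, `I` = query-only, `D` = target-only),
#'   `percent_identity` over aligned columns, and the input sequences.
#' @examples
#' smith_waterman("ACGTACGT", "ACGTACGT")$score   # 40 at match = 5
#' @export
smith_waterman <- function(query, target, scheme = scoring_scheme(),
                           score_only = FALSE) {
  if (nchar(query) == 0L || nchar(target) == 0L)
    stop("empty sequence")
  q <- .encode_seq(query, scheme)
  t <- .encode_seq(target, scheme)
  res <- .sw_align(q, t, scheme$submat, scheme$gap_open, scheme$gap_extend,
                   score_only)
  pid <- if (res$n_col > 0L) 100 * res$n_match / res$n_col else NA_real_
  structure(list(score = res$score,
                 query_start = res$query_start, query_end = res$query_end,
                 target_start = res$target_start, target_end = res$target_end,
                 cigar = res$cigar, n_match = res$n_match, n_col = res$n_col,
                 percent_identity = pid,
                 query = query, target = target, scheme = scheme),
            class = "LocalAlignment")
}

#' @export
print.LocalAlignment <- function(x, ...) {
  cat(sprintf(
    "LocalAlignment: score %.1f, query [%d,%d), target [%d,%d), %s%% id\n",
    x$score, x$query_start, x$query_end, x$target_start, x$target_end,
    ifelse(is.na(x$percent_identity), "NA",
           sprintf("%.1f", x$percent_identity))))
  invisible(x)
}

## expand "3M2D1M" into c("M","M","M","D","D","M")
.cigar_ops <- function(cigar) {
  if (nchar(cigar) == 0L) return(character())
  n <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[MID]", cigar))[[1]]
  rep(op, n)
}

.ops_to_cigar <- function(ops) {
  if (length(ops) == 0L) return("")
  r <- rle(ops)
  paste0(r$lengths, r$values, collapse = "")
}

#' Left-shift alignment gaps inside homopolymers
#'
#' Gap placement within a homopolymer run is degenerate; this normalizes
#' every gap to its 5'-most equivalent placement (shifting a gap one step
#' left whenever the base entering the gap equals the base leaving it),
#' which makes gap coordinates canonical and comparable against planted
#' truth.  The alignment score is unchanged.
#'
#' @param aln A `LocalAlignment` from [smith_waterman()].
#' @return The alignment with a normalized `cigar`.
#' @export
left_shift_gaps <- function(aln) {
  ops <- .cigar_ops(aln$cigar)
  if (length(ops) == 0L) return(aln)
  qch <- strsplit(toupper(aln$query), "", fixed = TRUE)[[1]]
  tch <- strsplit(toupper(aln$target), "", fixed = TRUE)[[1]]
  repeat {
    # per-column 1-based consumed positions (recomputed after every shift)
    qpos <- aln$query_start + cumsum(ops %in% c("M", "I"))
    tpos <- aln$target_start + cumsum(ops %in% c("M", "D"))
    moved <- FALSE
    k <- 2L
    while (k <= length(ops)) {
      if (ops[k] %in% c("D", "I") && ops[k - 1L] == "M") {
        e <- k
        while (e < length(ops) && ops[e + 1L] == ops[k]) e <- e + 1L
        ch <- if (ops[k] == "D") tch else qch
        pos_before <- if (ops[k] == "D") tpos[k - 1L] else qpos[k - 1L]
        pos_end <- if (ops[k] == "D") tpos[e] else qpos[e]
        if (ch[pos_before] == ch[pos_end]) {
          ops[c(k - 1L, e)] <- ops[c(e, k - 1L)]  # slide gap run left by one
          moved <- TRUE
          break
        }
        k <- e + 1L
      } else k <- k + 1L
    }
    if (!moved) break
  }
  aln$cigar <- .ops_to_cigar(ops)
  aln
}

#' Per-position coordinate map of a local alignment
#'
#' @param aln A `LocalAlignment`.
#' @return Integer vector `q2t` of length `nchar(query)`: for each query
#'   position (1-based) the aligned target position, or `NA` outside the
#'   alignment / in query-only columns.
#' @export
alignment_coordinate_map <- function(aln) {
  q2t <- rep(NA_integer_, nchar(aln$query))
  ops <- .cigar_ops(aln$cigar)
  qp <- aln$query_start; tp <- aln$target_start
  for (op in ops) {
    if (op == "M") { qp <- qp + 1L; tp <- tp + 1L; q2t[qp] <- tp }
    else if (op == "I") { qp <- qp + 1L }
    else { tp <- tp + 1L }
  }
  q2t
}

## extract gap runs from an alignment: for each maximal I or D run, the
## consumed interval (1-based inclusive) on its sequence and the flanking
## position on the other one
.alignment_gaps <- function(aln) {
  ops <- .cigar_ops(aln$cigar)
  out <- list()
  qp <- aln$query_start; tp <- aln$target_start
  k <- 1L
  while (k <= length(ops)) {
    if (ops[k] == "M") { qp <- qp + 1L; tp <- tp + 1L; k <- k + 1L; next }
    op <- ops[k]
    len <- 0L
    while (k <= length(ops) && ops[k] == op) { len <- len + 1L; k <- k + 1L }
    if (op == "D") {
      out[[length(out) + 1L]] <- list(op = "D",
                                      target_start = tp + 1L,
                                      target_end = tp + len,
                                      query_after = qp)
      tp <- tp + len
    } else {
      out[[length(out) + 1L]] <- list(op = "I",
                                      query_start = qp + 1L,
                                      query_end = qp + len,
                                      target_after = tp)
      qp <- qp + len
    }
  }
  out
}

#' Six-frame protein search against a genome
#'
#' Translates all six frames of the genome (across the origin for circular
#' molecules, capped at one wrap) under the given genetic code and aligns a
#' protein query locally against each translation, lifting hit coordinates
#' back to deposited-strand nucleotide positions.
#'
#' @param protein_query Amino-acid string.
#' @param genome A [circular_sequence()].
#' @param scheme A protein [scoring_scheme()].
#' @param code A [genetic_code()].
#' @param min_score Minimum alignment score to report.
#' @return A data.frame of hits: `start`, `end` (1-based inclusive,
#'   deposited strand), `strand`, `frame`, `score`, `percent_identity`,
#'   sorted by decreasing score.
#' @export
six_frame_search <- function(protein_query, genome,
                             scheme = scoring_scheme(alphabet = "protein"),
                             code = genetic_code(13L), min_score = 50) {
  stopifnot(inherits(genome, "CircularSequence"))
  L <- seq_len_cs(genome)
  if (L < 3L) stop("genome too short to translate")
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") genome$residues else revcomp(genome$residues)
    if (genome$is_circular) s <- paste0(s, s, substr(s, 1L, 2L))
    for (f in 0:2) {
      m <- (nchar(s) - f) %/% 3L
      if (m < 1L) next
      aa <- translate_cds(substr(s, f + 1L, f + 3L * m), code)
      aln <- smith_waterman(protein_query, aa, scheme)
      if (aln$score < min_score) next
      # protein hit [target_start, target_end) -> scanned-strand nucleotides
      nt1 <- f + 3L * aln$target_start + 1L
      nt2 <- f + 3L * aln$target_end
      if (nt2 - nt1 + 1L > L) next                # longer than one wrap
      if (genome$is_circular && nt1 > L) next     # duplicate, second copy
      g <- .lift_interval(nt1, nt2, strand, L, genome$is_circular)
      rows[[length(rows) + 1L]] <- data.frame(
        start = g[1L], end = g[2L], strand = strand, frame = f,
        score = aln$score, percent_identity = aln$percent_identity,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      score = numeric(), percent_identity = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## lift an interval on the scanned strand (possibly doubled) back to the
## deposited strand; returns c(start, end) 1-based inclusive
.lift_interval <- function(p1, p2, strand, L, circular) {
  if (strand == "-") {
    n <- if (circular) 2L * L else L
    tmp <- c(n - p2 + 1L, n - p1 + 1L)
    p1 <- tmp[1L]; p2 <- tmp[2L]
  }
  if (circular) {
    p1 <- ((p1 - 1L) %% L) + 1L
    p2 <- ((p2 - 1L) %% L) + 1L
  }
  c(p1, p2)
}

#' Map an edited transcript onto the genome and classify alignment gaps
#'
#' Aligns the transcript against both strands of the genome (doubled for
#' circular molecules so the origin can be crossed), left-normalizes the
#' gaps, and classifies every transcript-side gap as
#' `poly_T_edit` (the genomic gap sits in an editable poly-T tract whose
#' collapse removes exactly the gapped bases), `poly_A_spacer` (the gap is
#' an A-run longer than the collapse threshold), or `other`.
#'
#' @param transcript Edited coding-strand nucleotide string.
#' @param genome A [circular_sequence()].
#' @param scheme A nucleotide [scoring_scheme()].
#' @param collapse_threshold,max_interruptions Editing-model parameters used
#'   for gap classification.
#' @param min_score Minimum acceptable alignment score; below it the result
#'   is flagged unmapped rather than raising an error.
#' @return A list of class `TranscriptMapping`: `mapped` (logical), `strand`,
#'   `alignment` (on the scanned strand), `gaps` (data.frame: `class`,
#'   `genomic_start`, `genomic_end` deposited 1-based, `scan_start`,
#'   `scan_end` scanned-strand coords, `bases`, `transcript_pos`), plus the
#'   scanned-strand `target` and genome length `L`.
#' @export
map_transcript_to_genome <- function(transcript, genome,
                                     scheme = scoring_scheme(),
                                     collapse_threshold = 6L,
                                     max_interruptions = 2L,
                                     min_score = 50) {
  stopifnot(inherits(genome, "CircularSequence"))
  L <- seq_len_cs(genome)
  tgt_plus <- if (genome$is_circular) paste0(genome$residues, genome$residues)
              else genome$residues
  tgt_minus <- revcomp(tgt_plus)
  a_plus <- smith_waterman(transcript, tgt_plus, scheme)
  a_minus <- smith_waterman(transcript, tgt_minus, scheme)
  strand <- if (a_plus$score >= a_minus$score) "+" else "-"
  aln <- if (strand == "+") a_plus else a_minus
  span <- aln$target_end - aln$target_start
  if (aln$score < min_score || span > L) {
    return(structure(list(mapped = FALSE, strand = NA_character_,
                          alignment = aln, gaps = NULL,
                          target = NULL, L = L),
                     class = "TranscriptMapping"))
  }
  aln <- left_shift_gaps(aln)
  target <- if (strand == "+") tgt_plus else tgt_minus

  gaps <- .alignment_gaps(aln)
  rows <- lapply(gaps, function(gp) {
    if (gp$op == "I") {
      return(data.frame(class = "other", genomic_start = NA_integer_,
                        genomic_end = NA_integer_,
                        scan_start = NA_integer_, scan_end = NA_integer_,
                        bases = gp$query_end - gp$query_start + 1L,
                        transcript_pos = gp$query_start,
                        stringsAsFactors = FALSE))
    }
    j1 <- gp$target_start; j2 <- gp$target_end
    glen <- j2 - j1 + 1L
    cls <- "other"; rep1 <- j1; rep2 <- j2
    # poly-T edit: the gap lies inside an editable tract whose collapse
    # removes exactly this many bases
    w1 <- max(1L, j1 - (collapse_threshold + max_interruptions + 2L))
    w2 <- min(nchar(target), j2 + (collapse_threshold + max_interruptions + 2L))
    ev <- find_editable_tracts(substr(target, w1, w2),
                               collapse_threshold, max_interruptions)
    if (nrow(ev) > 0L) {
      ev$start <- ev$start + w1 - 1L
      ev$end <- ev$end + w1 - 1L
      # gap placement is degenerate when the tract's interruption matches a
      # flanking base, so require overlap (not containment) plus an exact
      # removable-base count
      hit <- which(ev$start <= j2 & ev$end >= j1 & ev$bases_removed == glen)
      if (length(hit) == 1L) {
        cls <- "poly_T_edit"
        rep1 <- ev$start[hit]; rep2 <- ev$end[hit]
      }
    }
    if (cls == "other") {
      content <- substr(target, j1, j2)
      if (grepl("^A+$", content)) {
        # expand to the maximal A-run
        r1 <- j1; while (r1 > 1L && substr(target, r1 - 1L, r1 - 1L) == "A")
          r1 <- r1 - 1L
        r2 <- j2
        while (r2 < nchar(target) && substr(target, r2 + 1L, r2 + 1L) == "A")
          r2 <- r2 + 1L
        if (r2 - r1 + 1L > collapse_threshold) cls <- "poly_A_spacer"
      }
    }
    dep <- .lift_interval(rep1, rep2, strand, L, genome$is_circular)
    data.frame(class = cls, genomic_start = dep[1L], genomic_end = dep[2L],
               scan_start = rep1, scan_end = rep2, bases = glen,
               transcript_pos = gp$query_after, stringsAsFactors = FALSE)
  })
  gaps_df <- if (length(rows)) do.call(rbind, rows)
             else data.frame(class = character(), genomic_start = integer(),
                             genomic_end = integer(), scan_start = integer(),
                             scan_end = integer(), bases = integer(),
                             transcript_pos = integer(),
                             stringsAsFactors = FALSE)
  gaps_df <- .reconcile_edit_gaps(gaps_df, aln, transcript, target,
                                  strand, L, genome$is_circular,
                                  collapse_threshold, max_interruptions)
  structure(list(mapped = TRUE, strand = strand, alignment = aln,
                 gaps = gaps_df, target = target, L = L),
            class = "TranscriptMapping")
}

## Gap placement inside a gene block can be degenerate in a second way: a
## tract that sheds a single base can score better merged into a neighbour's
## gap plus a mismatch than as its own gap (gap opening costs more than a
## mismatch).  Within each gene block (the stretch between poly-A spacer
## gaps) the editing model is the ground truth: when the editing image of
## the aligned genomic block equals the transcript block exactly, the
## block's edit gaps are replaced by the model's own tract list, which is
## independent of alignment-path degeneracy.
.reconcile_edit_gaps <- function(gaps_df, aln, transcript, target, strand,
                                 L, circular, collapse_threshold,
                                 max_interruptions) {
  sp <- gaps_df[gaps_df$class == "poly_A_spacer", , drop = FALSE]
  q_cuts <- c(aln$query_start, sp$transcript_pos, aln$query_end)
  t_cuts_lo <- c(aln$target_start + 1L, sp$scan_end + 1L)
  t_cuts_hi <- c(sp$scan_start - 1L, aln$target_end)
  keep <- gaps_df[gaps_df$class != "poly_T_edit" &
                  gaps_df$class != "other" |
                  is.na(gaps_df$scan_start), , drop = FALSE]
  dropped <- gaps_df[!(rownames(gaps_df) %in% rownames(keep)), ,
                     drop = FALSE]
  new_rows <- list()
  ok_blocks <- logical(length(t_cuts_lo))
  for (b in seq_along(t_cuts_lo)) {
    bs <- t_cuts_lo[b]; be <- t_cuts_hi[b]
    qs <- q_cuts[b] + 1L; qe <- q_cuts[b + 1L]
    if (bs > be || qs > qe) { ok_blocks[b] <- TRUE; next }
    sub <- substr(target, bs, be)
    ed <- edit_dna_to_rna(sub, collapse_threshold, max_interruptions)
    if (!identical(ed$edited, substr(transcript, qs, qe))) next
    ok_blocks[b] <- TRUE
    ev <- ed$events
    for (k in seq_len(nrow(ev))) {
      s_abs <- ev$start[k] + bs - 1L
      e_abs <- ev$end[k] + bs - 1L
      dep <- .lift_interval(s_abs, e_abs, strand, L, circular)
      new_rows[[length(new_rows) + 1L]] <- data.frame(
        class = "poly_T_edit", genomic_start = dep[1L],
        genomic_end = dep[2L], scan_start = s_abs, scan_end = e_abs,
        bases = ev$bases_removed[k],
        transcript_pos = qs - 1L + ed$dna_to_rna[ev$start[k]],
        stringsAsFactors = FALSE)
    }
  }
  if (!all(ok_blocks)) {
    # fall back to per-gap classification for blocks the model cannot
    # explain (e.g. genuine transcript/genome differences)
    for (b in which(!ok_blocks)) {
      bs <- t_cuts_lo[b]; be <- t_cuts_hi[b]
      old <- dropped[!is.na(dropped$scan_start) &
                     dropped$scan_start >= bs & dropped$scan_end <= be, ,
                     drop = FALSE]
      if (nrow(old)) new_rows[[length(new_rows) + 1L]] <- old
    }
  }
  out <- rbind(keep, if (length(new_rows)) do.call(rbind, new_rows))
  out <- out[order(is.na(out$scan_start), out$scan_start,
                   out$transcript_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
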