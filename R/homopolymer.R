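#' Find maximal homopolymer runs on a (possibly circular) sequence
#'
#' Scans the deposited strand for maximal runs of identical bases and
#' returns those of the requested bases with length at least `min_len`.
#' On a circular sequence a run spanning the origin is reported once, with
#' `wraps_origin = TRUE`; a single-base circular sequence yields one run of
#' the full length.  `N` bases never form or extend a run.
#'
#' @param seq A [circular_sequence()] (a plain character string is also
#'   accepted and treated as linear).
#' @param min_len Minimum run length to report (>= 2).
#' @param bases Bases to report runs for; subset of `c("A","C","G","T")`.
#' @return A data.frame with columns `base`, `start` (0-based position on
#'   the deposited strand), `length`, and `wraps_origin`, sorted by `start`.
#' @examples
#' find_runs(circular_sequence("TTTAAATTT", is_circular = TRUE), min_len = 6)
#' @export
find_runs <- function(seq, min_len = 6L, bases = c("A", "C", "G", "T")) {
  if (is.character(seq)) seq <- circular_sequence(seq)
  stopifnot(inherits(seq, "CircularSequence"))
  if (min_len < 2L) stop("min_len must be >= 2")
  bases <- match.arg(bases, c("A", "C", "G", "T"), several.ok = TRUE)

  n <- seq_len_cs(seq)
  r <- rle(strsplit(seq$residues, "", fixed = TRUE)[[1]])
  starts0 <- cumsum(c(0L, r$lengths[-length(r$lengths)]))  # 0-based
  runs <- data.frame(base = r$values, start = starts0,
                     length = r$lengths, wraps_origin = FALSE,
                     stringsAsFactors = FALSE)

  # Circular: merge a shared first/last run across the origin.
  if (seq$is_circular && nrow(runs) > 1L &&
      runs$base[1L] == runs$base[nrow(runs)]) {
    k <- nrow(runs)
    runs$length[k] <- runs$length[k] + runs$length[1L]
    runs$wraps_origin[k] <- TRUE
    runs <- runs[-1L, , drop = FALSE]
  }

  keep <- runs$base %in% bases & runs$length >= min_len
  out <- runs[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Homopolymer composition statistics
#'
#' Computes, per base, the fraction of sequence positions covered by runs of
#' that base at or above a length threshold, the run count, and the combined
#' A+T coverage -- the quantities behind statements such as "34.8 percent
#' A-homopolymers of length six or more".
#'
#' @param runs A run table from [find_runs()], produced with
#'   `min_len = threshold` on the same sequence.
#' @param seq_length Length of the source sequence in bases.
#' @param threshold The run-length threshold the runs were produced with.
#' @return An object of class `HomopolymerStats`: a list with `threshold`,
#'   `covered_fraction` (named over A/C/G/T), `run_count`, `bases_covered`,
#'   and `total_AT_fraction`.
#' @export
composition_stats <- function(runs, seq_length, threshold = 6L) {
  stopifnot(is.data.frame(runs), seq_length >= 1L)
  if (nrow(runs) > 0L) {
    if (any(runs$length < threshold))
      stop("runs contain entries below the stated threshold")
    if (any(runs$start < 0L | runs$start >= seq_length))
      stop("run coordinates inconsistent with seq_length")
    if (any(runs$length > seq_length))
      stop("run longer than the sequence")
  }
  bases <- c("A", "C", "G", "T")
  covered <- vapply(bases, function(b) {
    sum(runs$length[runs$base == b])
  }, numeric(1))
  covered <- pmin(covered, seq_length)  # a full-circle run covers every base once
  counts <- vapply(bases, function(b) sum(runs$base == b), integer(1))
  structure(
    list(threshold = as.integer(threshold),
         seq_length = as.integer(seq_length),
         bases_covered = covered,
         covered_fraction = covered / seq_length,
         run_count = counts,
         total_AT_fraction = (covered[["A"]] + covered[["T"]]) / seq_length),
    class = "HomopolymerStats"
  )
}

#' @export
print.HomopolymerStats <- function(x, ...) {
  cat(sprintf("Homopolymer coverage at threshold %d (sequence %d bp):\n",
              x$threshold, x$seq_length))
  for (b in names(x$covered_fraction)) {
    cat(sprintf("  %s: %2d runs, %6d bases, %s%%\n", b, x$run_count[[b]],
                x$bases_covered[[b]], percent_1dp(x$covered_fraction[[b]])))
  }
  cat(sprintf("  A+T combined: %s%%\n", percent_1dp(x$total_AT_fraction)))
  invisible(x)
}

#' Format a fraction as a percentage rounded half-up to one decimal
#'
#' Report-level formatting; `round()`'s round-half-even would turn 0.3485
#' into "34.8" or "34.9" depending on binary representation, so half-up is
#' applied explicitly.
#'
#' @param frac Numeric fraction in `[0, 1]` (or any numeric).
#' @return Character scalar, e.g. `"34.8"`.
#' @export
percent_1dp <- function(frac) {
  sprintf("%.1f", floor(frac * 1000 + 0.5) / 10)
}

#' Convert homopolymer runs to a BED-style interval track
#'
#' Intervals are 0-based half-open with the run's base as the name field.
#' A run wrapping the origin of a circular sequence is split into two rows
#' that share a name, so the pair remains identifiable as one feature.
#'
#' @param runs A run table from [find_runs()].
#' @param seq_length Sequence length (needed to split wrapping runs).
#' @param seq_id Sequence identifier for the BED `chrom` column.
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`
#'   (BED 0-based half-open).
#' @export
runs_to_track <- function(runs, seq_length, seq_id = "seq") {
  cols <- c("chrom", "start", "end", "name")
  if (nrow(runs) == 0L) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      stringsAsFactors = FALSE)
    return(out[cols])
  }
  rows <- lapply(seq_len(nrow(runs)), function(i) {
    r <- runs[i, ]
    nm <- sprintf("%s_run_%d", r$base, i)
    if (!r$wraps_origin) {
      data.frame(chrom = seq_id, start = r$start, end = r$start + r$length,
                 name = nm, stringsAsFactors = FALSE)
    } else {
      first_part <- seq_length - r$start
      rbind(
        data.frame(chrom = seq_id, start = r$start, end = seq_length,
                   name = nm, stringsAsFactors = FALSE),
        data.frame(chrom = seq_id, start = 0L, end = r$length - first_part,
                   name = nm, stringsAsFactors = FALSE)
      )
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Profile a genome's homopolymer content in one call
#'
#' Convenience wrapper: [find_runs()] then [composition_stats()] and
#' [runs_to_track()].
#'
#' @inheritParams find_runs
#' @return A list with `runs`, `stats`, and `track`.
#' @export
profile_homopolymers <- function(seq, min_len = 6L,
                                 bases = c("A", "C", "G", "T")) {
  if (is.character(seq)) seq <- circular_sequence(seq)
  runs <- find_runs(seq, min_len = min_len, bases = bases)
  list(runs = runs,
       stats = composition_stats(runs, seq_len_cs(seq), threshold = min_len),
       track = runs_to_track(runs, seq_len_cs(seq), seq_id = seq$id))
}
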