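#' Find editable poly-T tracts in a coding-strand region
#'
#' A tract is a maximal chain of T-runs in which consecutive runs may be
#' bridged across single non-T bases (each interruption flanked by at least
#' one T on both sides).  Chains are built without a cap, so tracts are
#' maximal and disjoint; a chain qualifies as *editable* when its total
#' T count exceeds `collapse_threshold` **and** it carries at most
#' `max_interruptions` interruptions.  Editing (see [edit_dna_to_rna()])
#' collapses each editable tract to exactly `collapse_threshold` T's,
#' removing the interruptions with it.
#'
#' Chains that are too interrupted are deliberately left whole rather than
#' split into sub-tracts: splitting would leave adjacent collapsible
#' remnants behind and break the idempotence of the editing map.
#'
#' @param region Coding-strand nucleotide string.
#' @param collapse_threshold T-count retained per tract after editing
#'   (default 6; a tract must exceed it to be editable).
#' @param max_interruptions Maximum number of single non-T bases allowed
#'   inside an editable tract (default 2).
#' @return A data.frame of edit events with columns `start`, `end` (1-based
#'   inclusive within `region`), `t_count`, `n_interruptions`,
#'   `interruption_pos` (comma-separated 1-based positions, `""` if none),
#'   `bases_removed`, `retained_start`, `retained_end` (the 5'-most
#'   `collapse_threshold` T's that survive editing).
#' @examples
#' find_editable_tracts("GGTTTTTTTTGG")           # 8 T -> remove 2
#' find_editable_tracts("TTTTATTTT")              # 4+4 T bridged by A
#' @export
find_editable_tracts <- function(region, collapse_threshold = 6L,
                                 max_interruptions = 2L) {
  stopifnot(is.character(region), length(region) == 1L)
  region <- toupper(region)
  n <- nchar(region)
  empty <- data.frame(start = integer(), end = integer(),
                      t_count = integer(), n_interruptions = integer(),
                      interruption_pos = character(),
                      bases_removed = integer(),
                      retained_start = integer(), retained_end = integer(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)

  ch <- strsplit(region, "", fixed = TRUE)[[1]]
  r <- rle(ch == "T")
  run_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  run_end <- run_start + r$lengths - 1L

  t_idx <- which(r$values)
  if (length(t_idx) == 0L) return(empty)

  # Chain T-runs bridged by single non-T runs (uncapped maximal chains).
  chains <- list()
  i <- 1L
  while (i <= length(t_idx)) {
    j <- i
    while (j < length(t_idx) &&
           t_idx[j + 1L] == t_idx[j] + 2L &&           # one non-T run between
           r$lengths[t_idx[j] + 1L] == 1L) {           # ... of length one
      j <- j + 1L
    }
    chains[[length(chains) + 1L]] <- t_idx[i:j]
    i <- j + 1L
  }

  rows <- lapply(chains, function(members) {
    t_count <- sum(r$lengths[members])
    n_int <- length(members) - 1L
    if (t_count <= collapse_threshold || n_int > max_interruptions)
      return(NULL)
    s <- run_start[members[1L]]
    e <- run_end[members[length(members)]]
    ints <- if (n_int > 0L) run_start[members[-length(members)] + 1L]
            else integer()
    # retained 6-mer: the 5'-most collapse_threshold T positions of the chain
    tpos <- setdiff(s:e, ints)
    retained <- tpos[seq_len(collapse_threshold)]
    data.frame(start = s, end = e, t_count = t_count,
               n_interruptions = n_int,
               interruption_pos = paste(ints, collapse = ","),
               bases_removed = t_count + n_int - collapse_threshold,
               retained_start = retained[1L],
               retained_end = retained[length(retained)],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply the poly-T collapse editing model (DNA to RNA)
#'
#' Replaces every editable tract of `region` (see [find_editable_tracts()])
#' by exactly `collapse_threshold` T's; all other bases are copied verbatim.
#' The operation is idempotent: editing an already edited string changes
#' nothing.
#'
#' The returned coordinate map relates the edited (transcript) string to the
#' genomic `region`: `rna_to_dna[k]` is the 1-based genomic position of
#' transcript base `k`, and `dna_to_rna[g]` the transcript position of
#' genomic base `g` (a removed genomic base maps to the transcript position
#' of the last retained base at or before it, or 0 before the first).
#'
#' @inheritParams find_editable_tracts
#' @return A list with `edited` (the RNA-side string), `events` (the edit
#'   table), `rna_to_dna`, and `dna_to_rna`.
#' @examples
#' edit_dna_to_rna(paste0("GG", strrep("T", 10), "GG"))$edited
#' @export
edit_dna_to_rna <- function(region, collapse_threshold = 6L,
                            max_interruptions = 2L) {
  region <- toupper(region)
  ev <- find_editable_tracts(region, collapse_threshold, max_interruptions)
  n <- nchar(region)
  keep <- rep(TRUE, n)
  if (nrow(ev) > 0L) {
    for (i in seq_len(nrow(ev))) {
      # drop the whole tract, then restore the 5'-most threshold T's (the
      # retained window can straddle an interruption, so mark T positions
      # individually rather than a contiguous span)
      tract <- ev$start[i]:ev$end[i]
      ints <- as.integer(strsplit(ev$interruption_pos[i], ",")[[1]])
      tpos <- setdiff(tract, ints)
      keep[tract] <- FALSE
      keep[tpos[seq_len(collapse_threshold)]] <- TRUE
    }
  }
  rna_to_dna <- which(keep)
  edited <- paste(strsplit(region, "", fixed = TRUE)[[1]][keep],
                  collapse = "")
  dna_to_rna <- cumsum(keep)          # removed base -> preceding retained pos
  list(edited = edited, events = ev,
       rna_to_dna = rna_to_dna, dna_to_rna = as.integer(dna_to_rna))
}

#' Count edited poly-T sites within a gene
#'
#' Extracts the gene's coding-strand sequence from the genome (reverse
#' complement for minus-strand genes) and counts the editable tracts -- the
#' per-gene "number of edited homopolymers" of an annotation table.
#'
#' @param genome A [circular_sequence()].
#' @param start,end 1-based inclusive gene coordinates on the deposited
#'   strand (`end < start` wraps the origin of a circular genome).
#' @param strand `"+"` or `"-"`.
#' @inheritParams find_editable_tracts
#' @return Integer count of editable tracts.
#' @export
count_edited_sites <- function(genome, start, end, strand = "+",
                               collapse_threshold = 6L,
                               max_interruptions = 2L) {
  stopifnot(inherits(genome, "CircularSequence"), strand %in% c("+", "-"))
  n <- seq_len_cs(genome)
  if (start < 1L || start > n || end < 1L || end > n)
    stop("gene coordinates out of range")
  s <- subseq_circular(genome, start, end)
  if (strand == "-") s <- revcomp(s)
  nrow(find_editable_tracts(s, collapse_threshold, max_interruptions))
}
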