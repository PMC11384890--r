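#' Circular (or linear) nucleotide sequence
#'
#' Lightweight container for a nucleotide sequence together with a
#' circularity flag.  Residues are stored as a single uppercase string over
#' the alphabet `A, C, G, T, N`; anything else is rejected at construction
#' time.
#'
#' @param residues Character scalar, the nucleotide sequence.  Lowercase is
#'   accepted and uppercased.
#' @param is_circular Logical scalar; `TRUE` for a circular molecule.
#' @param id Sequence identifier.
#' @return An object of class `CircularSequence`.
#' @examples
#' g <- circular_sequence("ACGTACGT", is_circular = TRUE, id = "demo")
#' seq_len_cs(g)
#' @export
circular_sequence <- function(residues, is_circular = FALSE, id = "seq") {
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) == 0L)
    stop("empty sequence is not allowed")
  if (grepl("[^ACGTN]", residues))
    stop("sequence contains characters outside the {A,C,G,T,N} alphabet")
  structure(
    list(residues = residues,
         is_circular = isTRUE(is_circular),
         id = as.character(id)),
    class = "CircularSequence"
  )
}

#' @export
print.CircularSequence <- function(x, ...) {
  cat(sprintf("CircularSequence '%s': %d bp, %s\n", x$id, seq_len_cs(x),
              if (x$is_circular) "circular" else "linear"))
  invisible(x)
}

#' @export
as.character.CircularSequence <- function(x, ...) x$residues

#' Sequence length of a CircularSequence
#' @param x A `CircularSequence`.
#' @return Integer length in bases.
#' @export
seq_len_cs <- function(x) {
  stopifnot(inherits(x, "CircularSequence"))
  nchar(x$residues)
}

#' Extract a subsequence, wrapping across the origin when circular
#'
#' Coordinates are 1-based inclusive on the deposited strand.  For a
#' circular sequence, `end` may be smaller than `start`, in which case the
#' extracted region wraps across the origin, or either bound may exceed the
#' sequence length (interpreted modulo the length).
#'
#' @param x A `CircularSequence`.
#' @param start,end 1-based inclusive coordinates.
#' @return Character scalar with the extracted residues.
#' @export
subseq_circular <- function(x, start, end) {
  stopifnot(inherits(x, "CircularSequence"))
  n <- seq_len_cs(x)
  if (!x$is_circular) {
    if (start < 1L || end > n || start > end)
      stop("coordinates out of range for a linear sequence")
    return(substr(x$residues, start, end))
  }
  wrap1 <- function(p) ((p - 1L) %% n) + 1L
  s <- wrap1(start); e <- wrap1(end)
  if (s <= e) substr(x$residues, s, e)
  else paste0(substr(x$residues, s, n), substr(x$residues, 1L, e))
}

#' Reverse complement of a nucleotide string
#' @param s Character scalar over `A,C,G,T,N`.
#' @return The reverse complement, as a character scalar.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Read FASTA into CircularSequence objects
#'
#' Sequences are uppercased.  Circularity is taken from the `circular`
#' argument, or, per record, from a `circular=true` tag in the FASTA header.
#'
#' @param path FASTA file.
#' @param circular Default circularity applied to records without a
#'   `circular=` header tag.
#' @return A list of [circular_sequence()] objects.
#' @export
read_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA input: ", path)
  lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    id <- strsplit(header, "\\s+")[[1]][1]
    circ <- circular
    if (grepl("circular=true", header, ignore.case = TRUE)) circ <- TRUE
    if (grepl("circular=false", header, ignore.case = TRUE)) circ <- FALSE
    circular_sequence(as.character(set[[i]]), is_circular = circ, id = id)
  })
}

#' Write CircularSequence objects (or named strings) to FASTA
#'
#' @param seqs A list of `CircularSequence` objects, or a named character
#'   vector of sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    x <- Biostrings::DNAStringSet(seqs)
  } else {
    strs <- vapply(seqs, function(s) s$residues, character(1))
    nm <- vapply(seqs, function(s) {
      paste0(s$id, if (s$is_circular) " circular=true" else "")
    }, character(1))
    x <- Biostrings::DNAStringSet(setNames(strs, nm))
  }
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
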