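#' Genetic code table
#'
#' Wraps the NCBI genetic-code tables shipped with Biostrings and attaches
#' the start- and stop-codon sets.  Table 13 (ascidian mitochondrial:
#' TGA=Trp, AGA/AGG=Gly, ATA=Met; stops TAA/TAG; starts TTG/ATA/ATG/GTG) is
#' the working code of this package; table 1 is available for comparison.
#'
#' @param id NCBI genetic-code id (integer or string), e.g. `13` or `1`.
#' @return A list of class `GeneticCode` with `id`, `codons` (named
#'   character vector, stops as `"*"`), `starts`, `stops`.
#' @examples
#' genetic_code(13)$codons[["TGA"]]   # "W"
#' @export
genetic_code <- function(id = 13L) {
  tbl <- tryCatch(Biostrings::getGeneticCode(as.character(id)),
                  error = function(e) stop("invalid genetic code id: ", id))
  codons <- setNames(as.character(tbl), names(tbl))
  stops <- names(codons)[codons == "*"]
  starts <- if (as.integer(id) == 13L) c("TTG", "ATA", "ATG", "GTG")
            else unique(c("ATG", attr(tbl, "alt_init_codons")))
  structure(list(id = as.integer(id), codons = codons,
                 starts = starts, stops = stops),
            class = "GeneticCode")
}

#' Translate a coding sequence
#'
#' Codon-wise translation under a [genetic_code()].  Stop codons render as
#' `"*"`; codons containing `N` render as `"X"`.
#'
#' @param seq Nucleotide string with length divisible by 3.
#' @param code A [genetic_code()] (default table 13).
#' @return Amino-acid string.
#' @export
translate_cds <- function(seq, code = genetic_code(13L)) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  if (n == 0L) return("")
  codons <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(code$codons[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

## split a logical stop mask into maximal stop-free codon stretches
.stop_free_stretches <- function(is_stop) {
  m <- length(is_stop)
  if (m == 0L) return(list())
  r <- rle(!is_stop)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  lapply(keep, function(k) c(starts[k], ends[k]))
}

## scan one linear strand-sequence; returns codon-space calls
.scan_frames_linear <- function(s, code, min_aa, mode) {
  n <- nchar(s)
  out <- list()
  for (f in 0:2) {
    m <- (n - f) %/% 3L
    if (m < 1L) next
    cod <- substring(s, f + seq(1L, by = 3L, length.out = m),
                     f + seq(3L, by = 3L, length.out = m))
    is_stop <- cod %in% code$stops
    for (st in .stop_free_stretches(is_stop)) {
      a <- st[1L]; b <- st[2L]
      has_stop <- b < m && is_stop[b + 1L]
      if (mode == "start-to-stop") {
        hit <- which(cod[a:b] %in% code$starts)
        if (length(hit) == 0L) next
        a <- a + hit[1L] - 1L
      }
      n_aa <- b - a + 1L
      if (n_aa < min_aa) next
      out[[length(out) + 1L]] <- list(
        frame = f, codon_start = a,
        codon_end = if (has_stop) b + 1L else b,   # include terminating stop
        n_aa = n_aa, has_stop = has_stop,
        protein = paste(code$codons[cod[a:b]], collapse = ""))
    }
  }
  out
}

#' Find open reading frames on a (possibly circular) genome
#'
#' Scans both strands in all three frames under the given genetic code.  In
#' `stop-to-stop` mode an ORF is a maximal stop-free codon stretch; in
#' `start-to-stop` mode the stretch is trimmed to its first start codon.  On
#' circular sequences the scan runs over the doubled sequence so that ORFs
#' spanning the origin are found; duplicates are removed and an ORF never
#' exceeds one full wrap.  Reported coordinates include the terminating stop
#' codon when one bounds the ORF (`has_stop`).
#'
#' @param genome A [circular_sequence()] or plain string (treated linear).
#' @param code A [genetic_code()].
#' @param min_aa Minimum protein length in amino acids (stop excluded).
#' @param mode `"stop-to-stop"` or `"start-to-stop"`.
#' @return A data.frame with columns `start`, `end` (1-based inclusive on
#'   the deposited strand), `strand`, `frame`, `nt_length`, `n_aa`,
#'   `has_stop`, `wraps_origin`, `protein`, ordered by genomic start.
#' @examples
#' find_orfs("ATGAAATAA", code = genetic_code(13), min_aa = 2,
#'           mode = "start-to-stop")
#' @export
find_orfs <- function(genome, code = genetic_code(13L), min_aa = 30L,
                      mode = c("stop-to-stop", "start-to-stop")) {
  mode <- match.arg(mode)
  if (min_aa < 1L) stop("min_aa must be >= 1")
  if (is.character(genome)) genome <- circular_sequence(genome)
  L <- seq_len_cs(genome)
  rows <- list()

  for (strand in c("+", "-")) {
    s <- if (strand == "+") genome$residues else revcomp(genome$residues)
    if (genome$is_circular) {
      calls <- .scan_frames_circular(s, L, code, min_aa, mode)
    } else {
      calls <- .scan_frames_linear(s, code, min_aa, mode)
    }
    for (cl in calls) {
      # nucleotide interval on the scanned strand (1-based inclusive)
      if (is.null(cl$p1)) {
        p1 <- cl$frame + 3L * (cl$codon_start - 1L) + 1L
        p2 <- cl$frame + 3L * cl$codon_end
      } else {
        p1 <- cl$p1
        p2 <- cl$p2
      }
      if (strand == "+") {
        g1 <- p1; g2 <- p2
      } else {
        g1 <- L - (((p2 - 1L) %% L) + 1L) + 1L
        g2 <- L - (((p1 - 1L) %% L) + 1L) + 1L
      }
      if (genome$is_circular) {
        g1 <- ((g1 - 1L) %% L) + 1L
        g2 <- ((g2 - 1L) %% L) + 1L
      }
      wraps <- (p2 - p1 + 1L) <= L && g2 < g1
      rows[[length(rows) + 1L]] <- data.frame(
        start = g1, end = g2, strand = strand, frame = cl$frame,
        nt_length = p2 - p1 + 1L, n_aa = cl$n_aa, has_stop = cl$has_stop,
        wraps_origin = wraps, protein = cl$protein,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      nt_length = integer(), n_aa = integer(),
                      has_stop = logical(), wraps_origin = logical(),
                      protein = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[c("start", "end", "strand")]), , drop = FALSE]
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## scan a circular molecule (one strand) by walking the codon cycle(s).
## When L is divisible by 3 each frame is its own cycle of L/3 codons;
## otherwise the walk 1, 4, 7, ... (mod L) visits every position once and
## forms a single cycle of L codons.  Stop-free stretches are taken
## cyclically between consecutive stops, so the scan is exact and
## rotation-invariant; ORFs are capped at one full wrap (a capped ORF
## reports has_stop = FALSE).  A completely stop-free cycle yields one
## full-wrap ORF anchored at the cycle's smallest position.
.scan_frames_circular <- function(s, L, code, min_aa, mode) {
  s2 <- paste0(s, s)
  max_codons <- L %/% 3L
  cycles <- if (L %% 3L == 0L) {
    lapply(1:3, function(f) seq(f, L, by = 3L))
  } else {
    list(((3L * (seq_len(L) - 1L)) %% L) + 1L)
  }
  out <- list()
  emit <- function(cyc, cod, idxs, has_stop) {
    if (mode == "start-to-stop") {
      hit <- which(cod[idxs] %in% code$starts)
      if (length(hit) == 0L) return(NULL)
      idxs <- idxs[hit[1L]:length(idxs)]
    }
    if (length(idxs) > max_codons) {
      idxs <- idxs[seq_len(max_codons)]
      has_stop <- FALSE
    }
    n_aa <- length(idxs)
    if (n_aa < min_aa) return(NULL)
    if (has_stop && 3L * (n_aa + 1L) > L) has_stop <- FALSE
    p1 <- cyc[idxs[1L]]
    list(frame = (p1 - 1L) %% 3L, p1 = p1,
         p2 = p1 + 3L * (n_aa + has_stop) - 1L,
         n_aa = n_aa, has_stop = has_stop,
         protein = paste(code$codons[cod[idxs]], collapse = ""))
  }
  for (cyc in cycles) {
    K <- length(cyc)
    cod <- substring(s2, cyc, cyc + 2L)
    is_stop <- cod %in% code$stops
    stops <- which(is_stop)
    if (length(stops) == 0L) {
      a <- which.min(cyc)
      idxs <- ((a - 1L + seq_len(min(K, max_codons)) - 1L) %% K) + 1L
      r <- emit(cyc, cod, idxs, FALSE)
      if (!is.null(r)) out[[length(out) + 1L]] <- r
      next
    }
    for (si in seq_along(stops)) {
      s_i <- stops[si]
      s_j <- if (si < length(stops)) stops[si + 1L] else stops[1L]
      len <- (s_j - s_i - 1L) %% K
      if (len == 0L) next
      idxs <- ((s_i - 1L + seq_len(len)) %% K) + 1L
      r <- emit(cyc, cod, idxs, TRUE)
      if (!is.null(r)) out[[length(out) + 1L]] <- r
    }
  }
  out
}
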