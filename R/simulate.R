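#' Simulation parameters for a synthetic poly-T-edited mitogenome
#'
#' The defaults emulate the organization of the *O. dioica*-type mitogenome:
#' eight protein-coding genes on both strands with a realistic spread of
#' lengths, each gene carrying several poly-T insertions longer than the
#' collapse threshold (occasionally interrupted by a single non-T base),
#' genes separated by poly-A spacers longer than the threshold, and a large
#' AT-homopolymer-rich noncoding control region.  The published genome does
#' not report the length distribution of its insertions, so
#' `insertion_length_range` is an arbitrary (documented) choice.
#'
#' @param n_genes Number of protein-coding genes.
#' @param gene_length_range Gene length in codons, `c(min, max)`
#'   (stop codon included).
#' @param minus_strand_fraction Probability that a gene lies on the minus
#'   strand of the deposited sequence.
#' @param insertion_count_range Poly-T insertions per gene, `c(min, max)`.
#' @param insertion_length_range T-count of an inserted tract,
#'   `c(min, max)`; the minimum must exceed `collapse_threshold`.
#' @param interruption_prob Probability that a tract carries one embedded
#'   non-T base.
#' @param spacer_length_range Poly-A spacer length in bases, `c(min, max)`;
#'   the minimum must exceed `collapse_threshold`.
#' @param control_region_length Length of the noncoding control region.
#' @param collapse_threshold Editing threshold (tracts longer than this are
#'   collapsed to exactly this many T's).
#' @param max_interruptions Editing-model interruption cap.
#' @param seed Random seed; all randomness in [assemble_mitogenome()] is
#'   derived from it through R's default generator.
#' @return A list of class `SimulationSpec`.
#' @export
simulation_spec <- function(n_genes = 8L,
                            gene_length_range = c(200L, 680L),
                            minus_strand_fraction = 0.25,
                            insertion_count_range = c(3L, 12L),
                            insertion_length_range = c(7L, 15L),
                            interruption_prob = 0.2,
                            spacer_length_range = c(7L, 20L),
                            control_region_length = 22000L,
                            collapse_threshold = 6L,
                            max_interruptions = 2L,
                            seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes),
               gene_length_range = as.integer(gene_length_range),
               minus_strand_fraction = minus_strand_fraction,
               insertion_count_range = as.integer(insertion_count_range),
               insertion_length_range = as.integer(insertion_length_range),
               interruption_prob = interruption_prob,
               spacer_length_range = as.integer(spacer_length_range),
               control_region_length = as.integer(control_region_length),
               collapse_threshold = as.integer(collapse_threshold),
               max_interruptions = as.integer(max_interruptions),
               seed = as.integer(seed))
  if (spec$insertion_length_range[1L] <= spec$collapse_threshold)
    stop("insertion_length_range minimum must exceed collapse_threshold ",
         "(insertions must be editable)")
  if (spec$spacer_length_range[1L] <= spec$collapse_threshold)
    stop("spacer_length_range minimum must exceed collapse_threshold")
  if (spec$n_genes < 1L || spec$gene_length_range[1L] < 10L)
    stop("need at least one gene of at least 10 codons")
  if (spec$minus_strand_fraction < 0 || spec$minus_strand_fraction > 1)
    stop("minus_strand_fraction must be in [0, 1]")
  structure(spec, class = "SimulationSpec")
}

.BASES <- c("A", "C", "G", "T")

#' Generate a random coding sequence free of structural-rule violations
#'
#' Draws codons under the given genetic code so that the result begins with
#' a start codon, ends with TAA, contains no internal in-frame stop, no
#' A-run of `collapse_threshold` or more bases anywhere, and no editable
#' poly-T tract (so that the editing model maps it to itself).
#'
#' @param n_codons Total codon count including the stop (>= 2).
#' @param code A [genetic_code()].
#' @param collapse_threshold,max_interruptions Editing-model parameters the
#'   sequence must be inert under.
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return A nucleotide string of length `3 * n_codons`.
#' @export
generate_coding_sequence <- function(n_codons, code = genetic_code(13L),
                                     collapse_threshold = 6L,
                                     max_interruptions = 2L,
                                     seed = NULL) {
  if (n_codons < 2L) stop("n_codons must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  non_stop <- setdiff(names(code$codons), code$stops)
  start <- sample(code$starts, 1L)
  body_n <- n_codons - 2L
  codons <- c(start,
              if (body_n > 0L) sample(non_stop, body_n, replace = TRUE),
              "TAA")
  for (iter in seq_len(2000L)) {
    s <- paste(codons, collapse = "")
    bad <- .first_violation(s, collapse_threshold, max_interruptions)
    if (is.na(bad)) return(s)
    ci <- ((bad - 1L) %/% 3L) + 1L                 # codon covering the spot
    ci <- min(max(ci, 2L), n_codons - 1L)
    codons[ci] <- sample(non_stop, 1L)
  }
  stop("failed to generate a rule-conforming coding sequence")
}

## 1-based position of the first structural violation, NA if clean
.first_violation <- function(s, collapse_threshold, max_interruptions) {
  a_runs <- find_runs(circular_sequence(s), min_len = collapse_threshold,
                      bases = "A")
  ev <- find_editable_tracts(s, collapse_threshold, max_interruptions)
  cand <- c(if (nrow(a_runs) > 0L) a_runs$start[1L] + 1L + 2L,
            if (nrow(ev) > 0L) ev$start[1L] + 2L)
  if (length(cand) == 0L) NA_integer_ else min(cand)
}

#' Plant poly-T insertions into a coding sequence
#'
#' Inserts `n` poly-T tracts (T-count drawn from
#' `insertion_length_range`, each carrying one embedded non-T base with
#' probability `interruption_prob`) at codon boundaries chosen so that every
#' tract is flanked by non-T bases, cannot chain-bridge to any neighbouring
#' T of the CDS or another tract, and never splits the start or stop codon.
#' Editing collapses each tract to `collapse_threshold` T's, so the edited
#' image of the output is `cds` with `collapse_threshold` T's spliced in at
#' every insertion point (returned as `edited_cds`); placing tracts at codon
#' boundaries keeps that image in frame (the retained T's read as
#' phenylalanine codons) and free of in-frame stops.
#'
#' @param cds A coding sequence from [generate_coding_sequence()].
#' @param n_insertions Number of tracts to plant.
#' @param insertion_length_range T-count range `c(min, max)`, min above the
#'   collapse threshold.
#' @param interruption_prob Probability of one embedded non-T base.
#' @param collapse_threshold Editing threshold.
#' @param seed Optional seed.
#' @return A list: `gene` (the genomic gene string), `edited_cds` (the
#'   editing-model image of `gene`) and `events` (data.frame: `start`,
#'   `end` 1-based within `gene`, `t_count`, `interrupted`,
#'   `bases_removed`).
#' @export
inject_poly_t_insertions <- function(cds, n_insertions,
                                     insertion_length_range = c(7L, 15L),
                                     interruption_prob = 0.2,
                                     collapse_threshold = 6L,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n_insertions == 0L)
    return(list(gene = cds, edited_cds = cds,
                events = data.frame(start = integer(), end = integer(),
                                    t_count = integer(),
                                    interrupted = logical(),
                                    bases_removed = integer())))
  ch <- strsplit(cds, "", fixed = TRUE)[[1]]
  # candidate points p: the tract goes between p and p+1, at a codon
  # boundary, with a 2-base T-free margin on both sides so tracts cannot
  # chain-bridge into the CDS (codon boundaries are >= 3 apart, which also
  # keeps distinct tracts in separate chains)
  cand <- seq(3L, n - 3L, by = 3L)
  ok <- vapply(cand, function(p) all(ch[(p - 1L):(p + 2L)] != "T"),
               logical(1))
  cand <- cand[ok]
  if (length(cand) < n_insertions)
    stop("cds too short (or too T-rich) to host ", n_insertions,
         " insertions")
  points <- sort(sample(cand, n_insertions))
  lens <- sample(seq(insertion_length_range[1L], insertion_length_range[2L]),
                 n_insertions, replace = TRUE)
  interrupted <- runif(n_insertions) < interruption_prob

  tracts <- vapply(seq_len(n_insertions), function(i) {
    tr <- strrep("T", lens[i])
    if (interrupted[i]) {
      pos <- sample(seq(2L, lens[i]), 1L)      # never at tract edges
      base <- sample(c("A", "C", "G"), 1L)
      tr <- paste0(substr(tr, 1L, pos - 1L), base, substr(tr, pos, lens[i]))
    }
    tr
  }, character(1))

  # splice from the right so earlier coordinates stay valid, then compute
  # final coordinates left to right
  gene <- cds
  edited_cds <- cds
  retained <- strrep("T", collapse_threshold)
  for (i in rev(seq_len(n_insertions))) {
    gene <- paste0(substr(gene, 1L, points[i]), tracts[i],
                   substr(gene, points[i] + 1L, nchar(gene)))
    edited_cds <- paste0(substr(edited_cds, 1L, points[i]), retained,
                         substr(edited_cds, points[i] + 1L,
                                nchar(edited_cds)))
  }
  offs <- cumsum(c(0L, nchar(tracts)[-n_insertions]))
  starts <- points + offs + 1L
  ends <- starts + nchar(tracts) - 1L
  events <- data.frame(start = starts, end = ends, t_count = lens,
                       interrupted = interrupted,
                       bases_removed = lens + as.integer(interrupted) -
                                       collapse_threshold)
  list(gene = gene, edited_cds = edited_cds, events = events)
}

#' Assemble a synthetic circular mitogenome with ground truth
#'
#' Builds a circular genome as `[gene + poly-A spacer] x n_genes + control
#' region`, reverse-complementing minus-strand gene blocks in place (so
#' their TAA + poly-A structure lies on the coding strand and a poly-T run
#' precedes them on the deposited strand).  The control region alternates
#' random A- and T-tracts (6-30 bases) with short non-AT spacers.
#'
#' @param spec A [simulation_spec()].
#' @param code A [genetic_code()].
#' @return A list of class `SyntheticTruth`: `genome`
#'   (a [circular_sequence()]), `genes` (data.frame with deposited-strand
#'   1-based coordinates, strand, `n_edited`, plus the pre-insertion `cds`,
#'   its edited transcript image `edited_cds`, and the genomic coding-strand
#'   `gene_seq`), `insertions` (deposited and
#'   gene-relative intervals of every planted tract), `spacers`,
#'   `control_region`, and `spec`.
#' @export
assemble_mitogenome <- function(spec = simulation_spec(),
                                code = genetic_code(13L)) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed)

  blocks <- character(spec$n_genes)
  gene_rows <- vector("list", spec$n_genes)
  ins_rows <- vector("list", spec$n_genes)
  spacer_rows <- vector("list", spec$n_genes)
  offset <- 0L

  for (i in seq_len(spec$n_genes)) {
    n_cod <- sample(seq(spec$gene_length_range[1L],
                        spec$gene_length_range[2L]), 1L)
    cds <- generate_coding_sequence(n_cod, code, spec$collapse_threshold,
                                    spec$max_interruptions)
    n_ins <- sample(seq(spec$insertion_count_range[1L],
                        spec$insertion_count_range[2L]), 1L)
    inj <- inject_poly_t_insertions(cds, n_ins,
                                    spec$insertion_length_range,
                                    spec$interruption_prob,
                                    spec$collapse_threshold)
    k <- sample(seq(spec$spacer_length_range[1L],
                    spec$spacer_length_range[2L]), 1L)
    strand <- if (runif(1L) < spec$minus_strand_fraction) "-" else "+"

    glen <- nchar(inj$gene)
    block <- paste0(inj$gene, strrep("A", k))
    if (strand == "-") {
      block <- revcomp(block)
      gs <- offset + k + 1L
      ge <- offset + k + glen
      sp <- c(offset + 1L, offset + k)
    } else {
      gs <- offset + 1L
      ge <- offset + glen
      sp <- c(offset + glen + 1L, offset + glen + k)
    }
    blocks[i] <- block
    gene_rows[[i]] <- data.frame(
      gene_symbol = paste0("gene", i), start = gs, end = ge,
      strand = strand, n_edited = nrow(inj$events),
      spacer_length = k, cds = cds, edited_cds = inj$edited_cds,
      gene_seq = inj$gene, stringsAsFactors = FALSE)
    if (nrow(inj$events) > 0L) {
      ev <- inj$events
      if (strand == "+") {
        ev$genomic_start <- gs + ev$start - 1L
        ev$genomic_end <- gs + ev$end - 1L
      } else {
        ev$genomic_start <- ge - ev$end + 1L
        ev$genomic_end <- ge - ev$start + 1L
      }
      ev$gene_symbol <- paste0("gene", i)
      ins_rows[[i]] <- ev
    }
    spacer_rows[[i]] <- data.frame(gene_symbol = paste0("gene", i),
                                   start = sp[1L], end = sp[2L],
                                   stringsAsFactors = FALSE)
    offset <- offset + nchar(block)
  }

  control <- .control_region(spec$control_region_length)
  genome_str <- paste0(paste(blocks, collapse = ""), control)
  genome <- circular_sequence(
    genome_str, is_circular = TRUE,
    id = sprintf("synthetic_mitogenome_seed%d", spec$seed))

  genes <- do.call(rbind, gene_rows)
  insertions <- if (any(!vapply(ins_rows, is.null, logical(1))))
    do.call(rbind, ins_rows[!vapply(ins_rows, is.null, logical(1))])
  else data.frame(start = integer(), end = integer(), t_count = integer(),
                  interrupted = logical(), bases_removed = integer(),
                  genomic_start = integer(), genomic_end = integer(),
                  gene_symbol = character(), stringsAsFactors = FALSE)
  structure(list(genome = genome, genes = genes, insertions = insertions,
                 spacers = do.call(rbind, spacer_rows),
                 control_region = c(offset + 1L, offset + nchar(control)),
                 spec = spec),
            class = "SyntheticTruth")
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf(
    "SyntheticTruth: %d bp circular genome, %d genes, %d planted insertions\n",
    seq_len_cs(x$genome), nrow(x$genes), nrow(x$insertions)))
  invisible(x)
}

## control region: alternating A/T tracts (uniform 6-30) separated by short
## non-AT spacers; terminated by a non-AT guard so the circle junction never
## extends a run into the first gene
.control_region <- function(len) {
  if (len <= 0L) return("")
  parts <- character()
  total <- 0L
  base <- sample(c("A", "T"), 1L)
  while (total < len - 4L) {
    tract <- strrep(base, sample(6:30, 1L))
    gap <- paste(sample(c("C", "G"), sample(2:4, 1L), replace = TRUE),
                 collapse = "")
    parts <- c(parts, tract, gap)
    total <- total + nchar(tract) + nchar(gap)
    base <- if (base == "A") "T" else "A"
  }
  s <- paste0(paste(parts, collapse = ""), "GC")
  s <- substr(s, 1L, len - 2L)
  paste0(s, "GC")  # guard at the junction back to gene 1
}

#' Generate edited polycistronic transcripts from a synthetic truth
#'
#' Groups consecutive same-strand genes (at most `genes_per_transcript` per
#' group; minus-strand groups in their coding 5'-to-3' order, i.e. reverse
#' deposited order) and emits, per group, the editing-model image of the
#' concatenated coding-strand gene sequences.  Spacers are not part of the
#' transcripts: they show up as alignment gaps when mapping back.
#'
#' @param truth A [assemble_mitogenome()] result.
#' @param genes_per_transcript Maximum genes per transcript.
#' @return A list: `sequences` (named character vector) and `genes`
#'   (data.frame `transcript_id`, `gene_symbol`, `position`).
#' @export
generate_edited_transcripts <- function(truth, genes_per_transcript = 3L) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  g <- truth$genes
  r <- rle(g$strand)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  groups <- list()
  for (k in seq_along(r$values)) {
    members <- seq(idx_start[k], idx_end[k])
    if (r$values[k] == "-") members <- rev(members)
    while (length(members) > 0L) {
      take <- utils::head(members, genes_per_transcript)
      groups[[length(groups) + 1L]] <- take
      members <- members[-seq_along(take)]
    }
  }
  seqs <- character(length(groups))
  rows <- list()
  for (j in seq_along(groups)) {
    tid <- paste0("transcript", j)
    edited <- vapply(groups[[j]], function(i) {
      edit_dna_to_rna(g$gene_seq[i], truth$spec$collapse_threshold,
                      truth$spec$max_interruptions)$edited
    }, character(1))
    seqs[j] <- paste(edited, collapse = "")
    rows[[j]] <- data.frame(transcript_id = tid,
                            gene_symbol = g$gene_symbol[groups[[j]]],
                            position = seq_along(groups[[j]]),
                            stringsAsFactors = FALSE)
  }
  names(seqs) <- paste0("transcript", seq_along(groups))
  list(sequences = seqs, genes = do.call(rbind, rows))
}
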