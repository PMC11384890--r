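test_that("self-alignment and hopeless pairs behave as defined", {
  a <- smith_waterman("ACGTACGT", "ACGTACGT")
  expect_equal(a$score, 40)                     # 8 matches at +5
  expect_equal(a$query_start, 0)
  expect_equal(a$query_end, 8)
  expect_equal(a$percent_identity, 100)

  b <- smith_waterman("AAAA", "CCCC")
  expect_equal(b$score, 0)
  expect_equal(b$cigar, "")

  expect_error(scoring_scheme(gap_open = -0.5, gap_extend = -10), "affine")
  expect_error(smith_waterman("ACGT", "ACGU"), "alphabet")
})

test_that("alignment scores match the independent plain-R Gotoh oracle", {
  set.seed(21)
  for (i in 1:150) {
    q <- random_dna(sample(3:40, 1))
    t <- random_dna(sample(3:40, 1))
    got <- smith_waterman(q, t, score_only = TRUE)$score
    expect_equal(got, sw_score_oracle(q, t), info = paste(q, t))
  }
})

test_that("alignment scores agree with Biostrings::pairwiseAlignment", {
  # library cross-check; Biostrings charges gapOpening + gapExtension * L
  # for a gap of length L, so open 9.5 / extend 0.5 is our -10 / -0.5
  mat <- Biostrings::nucleotideSubstitutionMatrix(5, -4)
  set.seed(25)
  for (i in 1:60) {
    q <- random_dna(sample(5:60, 1)); t <- random_dna(sample(5:60, 1))
    ours <- smith_waterman(q, t, score_only = TRUE)$score
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      q, t, type = "local", substitutionMatrix = mat,
      gapOpening = 9.5, gapExtension = 0.5))
    expect_equal(ours, max(ref, 0), info = paste(q, t))
  }
})

test_that("the plain-R oracle itself matches exhaustive path enumeration", {
  set.seed(22)
  for (i in 1:12) {
    q <- random_dna(sample(2:5, 1))
    t <- random_dna(sample(2:5, 1))
    expect_equal(sw_score_oracle(q, t), sw_score_exhaustive(q, t),
                 info = paste(q, t))
  }
})

test_that("scores are symmetric for symmetric schemes", {
  set.seed(23)
  for (i in 1:30) {
    q <- random_dna(sample(5:30, 1)); t <- random_dna(sample(5:30, 1))
    expect_equal(smith_waterman(q, t, score_only = TRUE)$score,
                 smith_waterman(t, q, score_only = TRUE)$score)
  }
})

test_that("the reported score is reproducible from the CIGAR", {
  set.seed(24)
  sch <- scoring_scheme()
  for (i in 1:60) {
    q <- random_dna(sample(10:60, 1), at_rich = TRUE)
    t <- random_dna(sample(10:60, 1), at_rich = TRUE)
    a <- smith_waterman(q, t, sch)
    if (a$score == 0) next
    ops <- strsplit(gsub("([MID])", "\\1 ", a$cigar), " ")[[1]]
    qp <- a$query_start; tp <- a$target_start
    sc <- 0; prev <- ""
    for (op in ops) {
      n <- as.integer(sub("[MID]", "", op))
      type <- sub("[0-9]+", "", op)
      if (type == "M") {
        for (k in seq_len(n)) {
          qp <- qp + 1; tp <- tp + 1
          sc <- sc + if (substr(q, qp, qp) == substr(t, tp, tp))
            sch$match else sch$mismatch
        }
      } else {
        sc <- sc + sch$gap_open + (n - 1) * sch$gap_extend
        if (type == "I") qp <- qp + n else tp <- tp + n
      }
      prev <- type
    }
    expect_equal(sc, a$score, info = paste(q, t, a$cigar))
    expect_equal(qp, a$query_end)
    expect_equal(tp, a$target_end)
  }
})

test_that("gaps are normalized to their 5'-most placement", {
  # deletion inside a homopolymer must sit flush against its 5' boundary
  q <- "GGGGTTTTTTGGGG"
  t <- paste0("GGGG", strrep("T", 10), "GGGG")
  a <- left_shift_gaps(smith_waterman(q, t))
  expect_equal(a$cigar, "4M4D10M")
})

test_that("six_frame_search finds planted genes on either strand", {
  spec <- simulation_spec(n_genes = 2, gene_length_range = c(60, 90),
                          minus_strand_fraction = 0,
                          insertion_count_range = c(0, 0),
                          insertion_length_range = c(7, 9),
                          spacer_length_range = c(7, 12),
                          control_region_length = 200, seed = 31)
  truth <- assemble_mitogenome(spec)
  g1 <- truth$genes[1, ]
  prot <- translate_cds(substr(g1$cds, 1, nchar(g1$cds) - 3))
  hits <- six_frame_search(prot, truth$genome)
  expect_gt(nrow(hits), 0)
  expect_equal(hits$start[1], g1$start)
  expect_equal(hits$end[1] , g1$end - 3)        # protein excludes the stop
  expect_equal(hits$strand[1], "+")

  spec2 <- simulation_spec(n_genes = 2, gene_length_range = c(60, 90),
                           minus_strand_fraction = 1,
                           insertion_count_range = c(0, 0),
                           insertion_length_range = c(7, 9),
                           spacer_length_range = c(7, 12),
                           control_region_length = 200, seed = 32)
  truth2 <- assemble_mitogenome(spec2)
  g2 <- truth2$genes[1, ]
  prot2 <- translate_cds(substr(g2$cds, 1, nchar(g2$cds) - 3))
  hits2 <- six_frame_search(prot2, truth2$genome)
  expect_gt(nrow(hits2), 0)
  expect_equal(hits2$strand[1], "-")
  expect_equal(hits2$start[1], g2$start + 3)    # stop excluded, minus strand
  expect_equal(hits2$end[1], g2$end)

  # a random protein finds nothing above the default threshold
  set.seed(33)
  junk <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 40,
                       replace = TRUE), collapse = "")
  expect_equal(nrow(six_frame_search(junk, truth$genome, min_score = 50)), 0)
})

test_that("transcript mapping classifies edit and spacer gaps exactly", {
  spec <- small_spec(41)
  truth <- assemble_mitogenome(spec)
  txs <- generate_edited_transcripts(truth, 2)

  got <- character(); classes <- character()
  for (tid in names(txs$sequences)) {
    mp <- map_transcript_to_genome(txs$sequences[[tid]], truth$genome)
    expect_true(mp$mapped)
    gp <- mp$gaps[mp$gaps$class == "poly_T_edit", ]
    got <- c(got, paste(gp$genomic_start, gp$genomic_end))
    classes <- c(classes, mp$gaps$class)
  }
  want <- paste(truth$insertions$genomic_start, truth$insertions$genomic_end)
  expect_setequal(got, want)
  # polycistronic transcripts show spacer gaps between gene blocks
  multi <- names(which(table(txs$genes$transcript_id) > 1))
  if (length(multi) > 0) expect_true("poly_A_spacer" %in% classes)

  # an unedited genome region maps back with zero gaps
  region <- subseq_circular(truth$genome, 1, 60)
  mp0 <- map_transcript_to_genome(region, truth$genome)
  expect_true(mp0$mapped)
  expect_equal(nrow(mp0$gaps), 0)

  # junk transcript: explicit unmapped result, no error
  expect_false(
    map_transcript_to_genome(strrep("GC", 15), truth$genome,
                             min_score = 120)$mapped)
})

test_that("re-editing the region implied by a poly_T_edit gap removes
           exactly the gapped bases", {
  spec <- small_spec(42)
  truth <- assemble_mitogenome(spec)
  txs <- generate_edited_transcripts(truth, 2)
  for (tid in names(txs$sequences)) {
    mp <- map_transcript_to_genome(txs$sequences[[tid]], truth$genome)
    gp <- mp$gaps[mp$gaps$class == "poly_T_edit", ]
    for (k in seq_len(nrow(gp))) {
      tract <- substr(mp$target, gp$scan_start[k], gp$scan_end[k])
      ed <- edit_dna_to_rna(tract)
      expect_equal(nchar(tract) - nchar(ed$edited), gp$bases[k])
    }
  }
})
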