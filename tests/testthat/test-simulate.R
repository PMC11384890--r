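test_that("simulation_spec enforces its invariants", {
  expect_error(simulation_spec(insertion_length_range = c(6, 10)),
               "exceed collapse_threshold")
  expect_error(simulation_spec(spacer_length_range = c(5, 10)),
               "exceed collapse_threshold")
  expect_error(simulation_spec(minus_strand_fraction = 1.5), "fraction")
  expect_s3_class(simulation_spec(), "SimulationSpec")
})

test_that("generated coding sequences satisfy the structural contract", {
  code <- genetic_code(13)
  set.seed(60)
  for (sd in 1:25) {
    n_cod <- sample(10:120, 1)
    cds <- generate_coding_sequence(n_cod, code, seed = sd)
    expect_equal(nchar(cds), 3 * n_cod)
    expect_true(substr(cds, 1, 3) %in% code$starts)
    expect_equal(substr(cds, nchar(cds) - 2, nchar(cds)), "TAA")
    # no internal in-frame stop
    prot <- translate_cds(substr(cds, 1, nchar(cds) - 3), code)
    expect_false(grepl("*", prot, fixed = TRUE))
    # no A-run of 6+ anywhere
    expect_equal(nrow(find_runs(cds, min_len = 6, bases = "A")), 0)
    # inert under the editing model
    expect_equal(edit_dna_to_rna(cds)$edited, cds)
  }
  # the 2-codon minimum is a bare start + stop
  tiny <- generate_coding_sequence(2, code, seed = 1)
  expect_equal(nchar(tiny), 6)
  expect_error(generate_coding_sequence(1), "n_codons")
})

test_that("poly-T injection round-trips through the editing model", {
  code <- genetic_code(13)
  set.seed(61)
  cds <- generate_coding_sequence(60, code)

  # zero insertions: identity
  inj0 <- inject_poly_t_insertions(cds, 0)
  expect_equal(inj0$gene, cds)
  expect_equal(nrow(inj0$events), 0)

  for (sd in 1:20) {
    inj <- inject_poly_t_insertions(cds, 3, c(7, 12), 0.4, seed = sd)
    extra <- sum(inj$events$t_count + inj$events$interrupted)
    expect_equal(nchar(inj$gene), nchar(cds) + extra)
    ed <- edit_dna_to_rna(inj$gene)
    expect_equal(ed$edited, inj$edited_cds)
    expect_equal(nrow(ed$events), 3)
    # the image is the cds with six retained T's spliced per site
    expect_equal(nchar(inj$edited_cds), nchar(cds) + 3 * 6)
    # and stays a clean CDS
    prot <- translate_cds(substr(inj$edited_cds, 1,
                                 nchar(inj$edited_cds) - 3))
    expect_false(grepl("*", prot, fixed = TRUE))
  }

  # an uninterrupted 10-T insertion: +10 bases, editing removes 4
  inj10 <- inject_poly_t_insertions(cds, 1, c(10, 10), 0, seed = 3)
  expect_equal(nchar(inj10$gene), nchar(cds) + 10)
  ed10 <- edit_dna_to_rna(inj10$gene)
  expect_equal(ed10$events$bases_removed, 4)
  expect_equal(nchar(ed10$edited), nchar(cds) + 6)

  expect_error(inject_poly_t_insertions("ATGTAA", 5), "too short")
})

test_that("assembled genomes respect the grammar and tile correctly", {
  for (sd in 1:10) {
    truth <- assemble_mitogenome(small_spec(sd))
    g <- truth$genes
    L <- seq_len_cs(truth$genome)

    # gene and spacer intervals tile the non-control portion without overlap
    iv <- rbind(cbind(g$start, g$end),
                cbind(truth$spacers$start, truth$spacers$end))
    iv <- iv[order(iv[, 1]), ]
    expect_equal(iv[1, 1], 1)
    expect_true(all(iv[-1, 1] == head(iv[, 2], -1) + 1))
    expect_equal(iv[nrow(iv), 2], truth$control_region[1] - 1)
    expect_equal(truth$control_region[2], L)

    # every gene ends with TAA on its coding strand, followed by a long A run
    v <- validate_structure(truth$genome, g)
    expect_equal(v$n_violations, 0, info = paste("seed", sd))

    # planted tract intervals carry T (or the interruption) on coding strand
    for (k in seq_len(nrow(truth$insertions))) {
      ins <- truth$insertions[k, ]
      gg <- g[g$gene_symbol == ins$gene_symbol, ]
      seq <- subseq_circular(truth$genome, ins$genomic_start,
                             ins$genomic_end)
      if (gg$strand == "-") seq <- revcomp(seq)
      tc <- sum(strsplit(seq, "")[[1]] == "T")
      expect_equal(tc, ins$t_count)
    }
  }
})

test_that("minus-strand genes show the reverse-complement grammar on the
           deposited strand", {
  spec <- simulation_spec(n_genes = 3, gene_length_range = c(40, 80),
                          minus_strand_fraction = 1,
                          insertion_count_range = c(1, 3),
                          insertion_length_range = c(7, 10),
                          spacer_length_range = c(8, 14),
                          control_region_length = 200, seed = 71)
  truth <- assemble_mitogenome(spec)
  for (i in seq_len(nrow(truth$genes))) {
    g <- truth$genes[i, ]
    # gene region starts with TTA (reverse complement of the TAA stop)
    expect_equal(subseq_circular(truth$genome, g$start, g$start + 2), "TTA")
    # and is preceded by a T-run longer than 6 on the deposited strand
    up <- subseq_circular(truth$genome, g$start - 7, g$start - 1)
    expect_equal(up, strrep("T", 7))
  }
})

test_that("edited transcripts are the editing image of their gene blocks", {
  spec <- small_spec(81)
  truth <- assemble_mitogenome(spec)
  txs <- generate_edited_transcripts(truth, 2)
  expect_setequal(txs$genes$gene_symbol, truth$genes$gene_symbol)

  for (tid in unique(txs$genes$transcript_id)) {
    members <- txs$genes$gene_symbol[txs$genes$transcript_id == tid]
    rows <- truth$genes[match(members, truth$genes$gene_symbol), ]
    expected <- paste(vapply(rows$gene_seq,
                             function(s) edit_dna_to_rna(s)$edited,
                             character(1)), collapse = "")
    expect_equal(unname(txs$sequences[[tid]]), expected)
    expect_equal(nchar(txs$sequences[[tid]]),
                 sum(nchar(rows$edited_cds)))
  }

  # a gene with no insertions transcribes to its own coding sequence
  spec0 <- simulation_spec(n_genes = 1, gene_length_range = c(40, 60),
                           minus_strand_fraction = 0,
                           insertion_count_range = c(0, 0),
                           insertion_length_range = c(7, 9),
                           spacer_length_range = c(8, 10),
                           control_region_length = 100, seed = 82)
  truth0 <- assemble_mitogenome(spec0)
  txs0 <- generate_edited_transcripts(truth0)
  expect_equal(unname(txs0$sequences[[1]]), truth0$genes$cds[1])

  # planted tracts appear as exactly-threshold T runs in the transcript
  g1 <- truth$genes[truth$genes$n_edited > 0, ][1, ]
  tid <- txs$genes$transcript_id[txs$genes$gene_symbol == g1$gene_symbol]
  tr <- txs$sequences[[tid]]
  runs <- find_runs(tr, min_len = 6, bases = "T")
  expect_true(all(runs$length == 6))
})
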