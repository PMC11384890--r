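test_that("annotation recovers planted genes exactly", {
  for (sd in c(5, 17, 29)) {
    truth <- assemble_mitogenome(small_spec(sd))
    txs <- generate_edited_transcripts(truth, 2)
    ann <- annotate_genes(truth$genome, txs$sequences, orphan_min_aa = NA)
    key <- function(d) sort(paste(d$start, d$end, d$strand, d$n_edited))
    expect_equal(key(ann$genes), key(truth$genes), info = paste("seed", sd))
    expect_length(ann$skipped, 0)
    # projection consistency: genomic span minus removed bases is the
    # edited CDS length (3 x (protein + stop))
    for (i in seq_len(nrow(truth$genes))) {
      g <- truth$genes[i, ]
      removed <- sum(truth$insertions$bases_removed[
        truth$insertions$gene_symbol == g$gene_symbol])
      expect_equal((g$end - g$start + 1) - removed, nchar(g$edited_cds))
    }
  }
})

test_that("gene symbols come from protein queries when supplied", {
  truth <- assemble_mitogenome(small_spec(33))
  txs <- generate_edited_transcripts(truth, 2)
  g2 <- truth$genes[2, ]
  queries <- setNames(
    translate_cds(substr(g2$edited_cds, 1, nchar(g2$edited_cds) - 3)),
    "nad1")
  ann <- annotate_genes(truth$genome, txs$sequences,
                        protein_queries = queries, orphan_min_aa = NA)
  named <- ann$genes[ann$genes$gene_symbol == "nad1", ]
  expect_equal(nrow(named), 1)
  expect_equal(c(named$start, named$end), c(g2$start, g2$end))
})

test_that("unmapped transcripts are skipped, not fatal", {
  truth <- assemble_mitogenome(small_spec(34))
  txs <- generate_edited_transcripts(truth, 2)
  seqs <- c(txs$sequences, junk = strrep("GC", 20))
  ann <- annotate_genes(truth$genome, seqs, orphan_min_aa = NA,
                        min_score = 120)
  expect_equal(ann$skipped, "junk")
  expect_equal(nrow(ann$genes), nrow(truth$genes))
})

test_that("orphan ORFs are reported as orfX when no transcript covers them", {
  truth <- assemble_mitogenome(small_spec(35))
  txs <- generate_edited_transcripts(truth, 2)
  # drop the transcript covering gene1: its ORF should reappear as orfX
  covered <- txs$genes$transcript_id[txs$genes$gene_symbol == "gene1"]
  seqs <- txs$sequences[setdiff(names(txs$sequences), covered)]
  ann <- annotate_genes(truth$genome, seqs, min_aa = 25, orphan_min_aa = 30)
  orfx <- ann$genes[ann$genes$gene_symbol == "orfX", ]
  expect_gt(nrow(orfx), 0)
  g1 <- truth$genes[1, ]
  hit <- any(orfx$strand == g1$strand &
             pmin(orfx$end, g1$end) >= pmax(orfx$start, g1$start))
  expect_true(hit)
})

test_that("validate_structure flags each deliberately corrupted fixture", {
  truth <- assemble_mitogenome(small_spec(36))
  base <- validate_structure(truth$genome, truth$genes)
  expect_equal(base$n_violations, 0)

  code <- genetic_code(13)
  mk_genome <- function(gene, spacer_len) {
    circular_sequence(paste0(gene, strrep("A", spacer_len), "GCGC",
                             strrep("T", 20), "GCGC"), is_circular = TRUE)
  }
  cds <- generate_coding_sequence(50, code, seed = 99)
  ann1 <- data.frame(gene_symbol = "g", start = 1, end = nchar(cds),
                     strand = "+", stringsAsFactors = FALSE)

  # short spacer (5 A) -> followed_by_polyA violation
  v1 <- validate_structure(mk_genome(cds, 5), ann1)
  expect_false(v1$flags$followed_by_polyA)
  expect_true(v1$flags$ends_with_TAA)

  # internal A-run inside the CDS
  bad_a <- paste0(substr(cds, 1, 30), strrep("A", 6),
                  substr(cds, 37, nchar(cds)))
  v2 <- validate_structure(mk_genome(bad_a, 10), ann1)
  expect_false(v2$flags$no_internal_polyA)

  # in-frame internal stop
  bad_stop <- paste0(substr(cds, 1, 30), "TAG", substr(cds, 34, nchar(cds)))
  v3 <- validate_structure(mk_genome(bad_stop, 10), ann1)
  expect_false(v3$flags$no_internal_stop)

  # stop codon destroyed
  bad_end <- paste0(substr(cds, 1, nchar(cds) - 3), "GGG")
  v4 <- validate_structure(mk_genome(bad_end, 10), ann1)
  expect_false(v4$flags$ends_with_TAA)

  # frame broken by a single-base deletion
  bad_len <- paste0(substr(cds, 1, 30), substr(cds, 32, nchar(cds)))
  ann2 <- ann1; ann2$end <- nchar(bad_len)
  v5 <- validate_structure(mk_genome(bad_len, 10), ann2)
  expect_false(v5$flags$cds_len_multiple_of_3)

  expect_error(validate_structure(truth$genome,
                                  data.frame(gene_symbol = "g", start = 0,
                                             end = 10, strand = "+")),
               "bounds")
})

test_that("annotation without transcripts still reports genomic ORFs", {
  truth <- assemble_mitogenome(small_spec(37))
  ann <- annotate_genes(truth$genome, character(), orphan_min_aa = 30)
  expect_equal(nrow(ann$genes[ann$genes$gene_symbol != "orfX", ]), 0)
  expect_gt(nrow(ann$genes), 0)
  expect_true(all(ann$genes$gene_symbol == "orfX"))
})
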