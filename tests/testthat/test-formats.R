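test_that("FASTA read normalises, validates, and round-trips", {
  p <- tempfile(fileext = ".fa")
  writeLines(c(">a descr", "acgt", ">b", "ACGTN", "ACGT"), p)
  x <- read_fasta(p)
  expect_identical(x, c(a = "ACGT", b = "ACGTNACGT"))

  writeLines(c(">a", "ACGT", ">a", "TTTT"), p)
  expect_error(read_fasta(p), "duplicate.*a")
  writeLines(c(">a", "ACXT"), p)
  expect_error(read_fasta(p), "illegal.*a")
  writeLines(character(0), p)
  expect_error(read_fasta(p), "empty")

  set.seed(7)
  seqs <- setNames(vapply(c(5, 80, 333), rand_dna, ""), c("s1", "s2", "s3"))
  write_fasta(seqs, p, width = 60)
  expect_identical(read_fasta(p), seqs)
})

test_that("GTF annotation read validates and round-trips", {
  p <- tempfile(fileext = ".gtf")
  writeLines(c(
    "chr2L\tsrc\texon\t1001\t1500\t.\t+\t.\tgene_id \"geneA\"; transcript_id \"geneA.t1\";",
    "chr2L\tsrc\texon\t1701\t1900\t.\t+\t.\tgene_id \"geneA\"; transcript_id \"geneA.t1\";",
    "chr2L\tsrc\tgene\t1001\t1900\t.\t+\t.\tgene_id \"geneA\";"), p)
  ann <- read_annotation(p)
  expect_equal(ann$start[1], 1001)
  expect_equal(ann$end[1], 1500)
  expect_equal(sum(ann$transcript_id == "geneA.t1", na.rm = TRUE), 2)

  writeLines("chr1\tsrc\texon\t500\t400\t.\t+\t.\tgene_id \"g\";", p)
  expect_error(read_annotation(p), "line 1.*end < start")
  writeLines("chr1\tsrc\texon\t400\t500\t.\t?\t.\tgene_id \"g\";", p)
  expect_error(read_annotation(p), "line 1.*strand")

  p2 <- tempfile(fileext = ".gtf")
  write_annotation(ann, p2)
  expect_equal(read_annotation(p2), ann)
})

test_that("BED output converts closed 1-based loci to 0-based half-open", {
  cand <- structure(list(list(candidate_id = "c1", gene_group = "c1",
                              isoforms = c("c1_i1", "c1_i2"),
                              sequences = c(c1_i1 = "ACGTACGT", c1_i2 = "ACGT"),
                              chrom = "chr1", start = 1001L, end = 1500L,
                              strand = "+")),
                    class = "candidate_set")
  out <- tempfile()
  paths <- write_candidate_outputs(cand, out)
  bed <- read.delim(paths[["bed"]], header = FALSE)
  expect_equal(bed$V2, 1000)  # BED start = GTF start - 1
  expect_equal(bed$V3, 1500)  # BED end = GTF end
  gtf <- read_annotation(paths[["gtf"]])
  expect_equal(sum(gtf$feature_class == "exon"), 2)  # one per isoform
  expect_equal(sum(gtf$feature_class == "gene"), 1)

  empty <- structure(list(), class = "candidate_set")
  paths <- write_candidate_outputs(empty, tempfile())
  rep <- read.delim(paths[["report"]])
  expect_equal(nrow(rep), 0)
  expect_true(all(c("candidate_id", "max_TPM", "synteny_tier") %in% names(rep)))
})

test_that("expression table read applies the zero rule and rejects bad cells", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tlibA\tlibB", "t1\t5\t", "t2\t0\t2.5"), p)
  m <- read_expression_table(p)
  expect_equal(m["t1", "libB"], 0)
  expect_equal(m["t2", "libB"], 2.5)

  writeLines(c("transcript_id\tlibA", "t1\t-1"), p)
  expect_error(read_expression_table(p), "negative")
  writeLines(c("transcript_id\tlibA", "t1\tnope"), p)
  expect_error(read_expression_table(p), "non-numeric")
})

test_that("ortholog table enforces unique (focal, species) pairs", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("focal_gene_id\toutgroup_species\tortholog_gene_id",
               "g1\tsp1\to1", "g1\tsp2\to2"), p)
  expect_equal(nrow(read_ortholog_table(p)), 2)
  writeLines(c("focal_gene_id\toutgroup_species\tortholog_gene_id",
               "g1\tsp1\to1", "g1\tsp1\to2"), p)
  expect_error(read_ortholog_table(p), "duplicate")
})

test_that("introns derive as gaps between consecutive exons", {
  ann <- mini_annotation(
    list(class = "exon", start = 1001, end = 1500, transcript_id = "t1"),
    list(class = "exon", start = 2001, end = 2300, transcript_id = "t1"),
    list(class = "exon", start = 5000, end = 5100, transcript_id = "t2"))
  intr <- derive_introns(ann)
  expect_equal(nrow(intr), 1)
  expect_equal(intr$start, 1501)
  expect_equal(intr$end, 2000)
  expect_equal(intr$feature_class, "intron")
})
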