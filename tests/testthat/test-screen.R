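test_that("Trinity IDs parse into gene group and isoform", {
  p <- parse_trinity_id(c("TRINITY_DN7862_c0_g3_i2", "TRINITY_DN90_c0_g3"))
  expect_equal(p$gene_group, c("TRINITY_DN7862_c0_g3", "TRINITY_DN90_c0_g3"))
  expect_equal(p$isoform, c(2L, 1L))

  expect_error(parse_trinity_id("foo_bar", strict = TRUE), "unparseable")
  expect_warning(p2 <- parse_trinity_id("foo_bar"), "singleton")
  expect_equal(p2$gene_group, "foo_bar")
})

test_that("exon distance follows closed-coordinate gap arithmetic", {
  ann <- mini_annotation(list(class = "exon", start = 501, end = 750,
                              transcript_id = "t"))
  expect_equal(exon_distance(list(chrom = "chr1", start = 1001, end = 1500),
                             ann), 250)
  expect_equal(exon_distance(list(chrom = "chr1", start = 700, end = 900),
                             ann), 0)   # overlap
  expect_equal(exon_distance(list(chrom = "chr1", start = 751, end = 900),
                             ann), 0)   # adjacent
  empty <- mini_annotation(list(class = "gene", start = 1, end = 10))
  empty <- empty[empty$feature_class == "exon", ]
  expect_equal(exon_distance(list(chrom = "chr1", start = 1, end = 10),
                             denovoscan:::as_annotation(empty)), Inf)
})

test_that("genomic context separates intergenic, intronic, and exonic loci", {
  ann <- mini_annotation(
    list(class = "gene", start = 1000, end = 5000),
    list(class = "exon", start = 1000, end = 1200, transcript_id = "t"))
  ctx <- function(s, e) genic_context(list(chrom = "chr1", start = s, end = e), ann)
  expect_equal(ctx(2000, 2400), "intronic")
  expect_equal(ctx(8000, 8400), "intergenic")
  expect_equal(ctx(1100, 1300), "genic_overlap")
  # 40% inside the gene span, no exon overlap -> intergenic under the 50% rule
  expect_equal(ctx(4601, 5600), "intergenic")
  expect_equal(ctx(4401, 5400), "intronic")  # 60% inside
})

test_that("structural filter enforces strict boundaries in order", {
  ann <- mini_annotation(list(class = "exon", start = 501, end = 750,
                              transcript_id = "t"))
  cfg <- pipeline_config()
  far <- list(chrom = "chr1", start = 10001, end = 10400)
  expect_false(structural_filter(strrep("A", 300), far, ann, cfg)$pass)
  expect_equal(structural_filter(strrep("A", 300), far, ann, cfg)$reason, "short")
  expect_true(structural_filter(strrep("A", 302), far, ann, cfg)$pass)

  near250 <- list(chrom = "chr1", start = 1001, end = 1400)  # distance 250
  expect_equal(structural_filter(strrep("A", 302), near250, ann, cfg)$reason,
               "near_exon")
  near251 <- list(chrom = "chr1", start = 1002, end = 1401)  # distance 251
  expect_true(structural_filter(strrep("A", 302), near251, ann, cfg)$pass)
})

test_that("placement recovers exact loci, merges split segments, rejects noise", {
  set.seed(21)
  g <- rand_dna(50000)
  idx <- build_kmer_index(c(chrA = g), k = 11)
  crit <- match_criterion()

  loc <- place_on_genome(substr(g, 10001, 10500), idx, crit)
  expect_equal(c(loc$chrom, loc$start, loc$end), c("chrA", 10001, 10500))
  expect_equal(loc$placement_identity, 1.0)

  # two-exon transcript: 200 bp + 150 bp segments 300 bp apart on the genome
  tx2 <- paste0(substr(g, 20001, 20200), substr(g, 20501, 20650))
  loc2 <- place_on_genome(tx2, idx, crit)
  expect_equal(c(loc2$start, loc2$end), c(20001, 20650))
  expect_gte(loc2$n_segments, 2)

  expect_null(place_on_genome(rand_dna(400), idx, crit))
})

test_that("expression filter applies the inclusive threshold and isoform rescue", {
  tpm <- matrix(c(1.0, 0, 0.99, 0.2), nrow = 2, byrow = TRUE,
                dimnames = list(c("g_i1", "g_i2"), c("l1", "l2")))
  cfg <- pipeline_config()
  sp <- c(g_i1 = TRUE, g_i2 = TRUE)
  expect_true(expression_filter(c("g_i1", "g_i2"), sp, tpm, cfg)$pass)
  # only the sub-threshold isoform: fails
  expect_false(expression_filter("g_i2", sp, tpm, cfg)$pass)
  # rescue: i1 passes everything, i2 fails structure, both retained
  sp2 <- c(g_i1 = TRUE, g_i2 = FALSE)
  ef <- expression_filter(c("g_i1", "g_i2"), sp2, tpm, cfg)
  expect_true(ef$pass)
  expect_equal(ef$passing_isoforms, "g_i1")
})

test_that("the cascade partitions its input and is database-order independent", {
  ds <- default_dataset()
  run <- default_run()
  expect_equal(nrow(run$trace), length(ds$transcripts))
  expect_equal(sum(table(run$trace$stage)), length(ds$transcripts))
  expect_false(anyDuplicated(run$trace$transcript_id) > 0)

  # permute database order: survivors must not change
  tpm <- compute_tpm(ds$counts, ds$tx_lengths)
  dbs2 <- ds$databases
  dbs2$annotation_dbs <- rev(lapply(dbs2$annotation_dbs, rev))
  dbs2$outgroup_tx_dbs <- rev(dbs2$outgroup_tx_dbs)
  idx2 <- build_screen_indexes(dbs2, ds$focal_genome, pipeline_config())
  sub <- ds$transcripts[seq_len(20)]
  sr1 <- run_screen(sub, ds$databases, ds$annotation, tpm,
                    indexes = default_indexes())
  sr2 <- run_screen(sub, dbs2, ds$annotation, tpm, indexes = idx2)
  expect_identical(sr1$trace$stage, sr2$trace$stage)
})

test_that("the isoform-rescue group retains its short isoform as a candidate", {
  ds <- default_dataset()
  run <- default_run()
  tr <- merge(ds$truth, run$trace, by = "transcript_id")
  short_iso <- tr[tr$class == "true_denovo" &
                    nchar(ds$transcripts[tr$transcript_id]) <= 300, ]
  expect_gte(nrow(short_iso), 1)
  expect_true(all(short_iso$stage == "candidate"))
})
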