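test_that("flanking genes are the nearest spans on each side", {
  ann <- mini_annotation(
    list(class = "gene", start = 1, end = 10000, gene_id = "A"),
    list(class = "gene", start = 20000, end = 30000, gene_id = "B"))
  fl <- flanking_genes(list(chrom = "chr1", start = 12000, end = 13000), ann)
  expect_equal(fl$upstream, "A")
  expect_equal(fl$downstream, "B")

  fl2 <- flanking_genes(list(chrom = "chr1", start = 500, end = 600),
                        mini_annotation(list(class = "gene", start = 20000,
                                             end = 30000, gene_id = "B")))
  expect_true(is.na(fl2$upstream))
  expect_equal(fl2$downstream, "B")

  # equidistant overlapping spans: tie broken by lower gene_id
  ann3 <- mini_annotation(
    list(class = "gene", start = 100, end = 1000, gene_id = "zz"),
    list(class = "gene", start = 200, end = 1000, gene_id = "aa"))
  fl3 <- flanking_genes(list(chrom = "chr1", start = 1500, end = 1600), ann3)
  expect_equal(fl3$upstream, "aa")
})

test_that("query regions clip at chromosome boundaries", {
  g <- c(chr1 = strrep("ACGT", 25000))  # 100 kb
  r <- build_query_region(g, list(chrom = "chr1", start = 10001, end = 10500),
                          flank = 5000)
  expect_equal(c(r$start, r$end), c(5001, 15500))
  expect_false(r$clipped)
  expect_equal(nchar(r$sequence), 10500)

  r2 <- build_query_region(g, list(chrom = "chr1", start = 2001, end = 2500),
                           flank = 5000)
  expect_equal(r2$start, 1)
  expect_true(r2$clipped)

  r3 <- build_query_region(g, list(chrom = "chr1", start = 10001, end = 10500),
                           flank = 0)
  expect_equal(nchar(r3$sequence), 500)
})

test_that("ortholog lookup reports loci, absences, and unknown species", {
  ot <- data.frame(focal_gene_id = "gA", outgroup_species = "sp1",
                   ortholog_gene_id = "oA", chrom = "scaf1", start = 100L,
                   end = 900L, stringsAsFactors = FALSE)
  loci <- locate_orthologs(c("gA", "gB"), ot, "sp1")
  expect_equal(loci$gA$chrom, "scaf1")
  expect_true(is.null(loci$gB))
  expect_named(loci, c("gA", "gB"))
  expect_error(locate_orthologs("gA", ot, "sp9"), "species 'sp9'")
})

test_that("an identical outgroup validates every candidate; split flanks fail", {
  set.seed(41)
  g <- rand_dna(60000)
  genome <- c(chr1 = g)
  region <- build_query_region(genome,
                               list(chrom = "chr1", start = 30001, end = 30400),
                               flank = 5000)
  loci <- list(up = list(chrom = "chr1", start = 20000L, end = 24000L),
               dn = list(chrom = "chr1", start = 36000L, end = 40000L))
  v <- validate_microsynteny(region, loci, genome)
  expect_true(v$validated)

  # single located flank is sufficient
  v1 <- validate_microsynteny(region, loci["up"], genome)
  expect_true(v1$validated)

  # no located flanks
  v0 <- validate_microsynteny(region, list(), genome)
  expect_false(v0$validated)
  expect_equal(v0$reason, "no_flank_orthologs")

  # flanks on different scaffolds
  split_g <- c(chr1_s1 = substr(g, 1, 30200), chr1_s2 = substr(g, 30201, 60000))
  loci2 <- list(up = list(chrom = "chr1_s1", start = 20000L, end = 24000L),
                dn = list(chrom = "chr1_s2", start = 5800L, end = 9800L))
  v2 <- validate_microsynteny(region, loci2, split_g)
  expect_false(v2$validated)
  expect_equal(v2$reason, "split_flanks")
})

test_that("validation certifies region orthology, not transcript presence", {
  set.seed(42)
  g <- rand_dna(60000)
  genome <- c(chr1 = g)
  locus <- list(chrom = "chr1", start = 30001, end = 30400)
  region <- build_query_region(genome, locus, flank = 5000)
  # outgroup: candidate sequence replaced by unrelated sequence, flanks kept
  og <- paste0(substr(g, 1, 30000), rand_dna(400), substr(g, 30401, 60000))
  loci <- list(up = list(chrom = "chr1", start = 20000L, end = 24000L))
  v <- validate_microsynteny(region, loci, c(chr1 = og))
  expect_true(v$validated)
})

test_that("tiers partition candidates by per-species flags", {
  flags <- matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), ncol = 2,
                  byrow = TRUE, dimnames = list(c("a", "b", "c"), NULL))
  tiers <- tier_candidates(flags)
  expect_equal(unname(tiers), c("both_outgroups", "one_outgroup", "none"))
  expect_equal(sum(table(tiers)), 3)
})
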