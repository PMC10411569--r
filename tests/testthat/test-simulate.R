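small_plan <- function(seed = 42L)
  sim_plan(seed = seed, chrom_len = 200000L, n_genes = 20L, n_ncrna = 2L,
           n_trna = 2L, n_te = 4L,
           class_counts = c(true_denovo = 4L, annotated_copy = 2L,
                            te_copy = 2L, intronic = 2L, near_exon = 2L,
                            short = 2L, low_expression = 2L,
                            outgroup_shared = 2L))

test_that("genome mutation respects rates and keeps a consistent coordinate map", {
  set.seed(3)
  s <- rand_dna(100000)

  m0 <- mutate_genome(s, 0, 0, seed = 1)
  expect_identical(m0$sequence, s)
  expect_identical(m0$map, seq_len(nchar(s)))

  m <- mutate_genome(s, 0.05, 0, seed = 2)
  frac <- mean(strsplit(s, "")[[1]] != strsplit(m$sequence, "")[[1]])
  sd3 <- 3 * sqrt(0.05 * 0.95 / nchar(s))
  expect_lt(abs(frac - 0.05), sd3)

  # with indels but no substitutions, every surviving base is preserved at
  # its mapped position, and the map is strictly increasing
  mi <- mutate_genome(s, 0, 0.02, seed = 3)
  keep <- which(!is.na(mi$map))
  orig <- strsplit(s, "")[[1]]
  mut <- strsplit(mi$sequence, "")[[1]]
  expect_identical(mut[mi$map[keep]], orig[keep])
  expect_true(all(diff(mi$map[keep]) > 0))
})

test_that("simulation is deterministic and labels every planted transcript once", {
  d1 <- simulate_dataset(small_plan())
  d2 <- simulate_dataset(small_plan())
  expect_identical(d1$focal_genome, d2$focal_genome)
  expect_identical(d1$transcripts, d2$transcripts)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$ortholog_table, d2$ortholog_table)

  d3 <- simulate_dataset(small_plan(seed = 43L))
  expect_false(identical(d1$focal_genome, d3$focal_genome))

  expect_false(anyDuplicated(d1$truth$transcript_id) > 0)
  expect_setequal(unique(d1$truth$class),
                  c("true_denovo", "annotated_copy", "te_copy", "intronic",
                    "near_exon", "short", "low_expression", "outgroup_shared"))
})

test_that("zero divergence reproduces the focal genome in the outgroup", {
  pl <- small_plan()
  pl$divergence <- list(outgroup1 = c(sub = 0, indel = 0),
                        outgroup2 = c(sub = 0.05, indel = 0.01))
  pl$synteny_break_fraction <- 0
  ds <- simulate_dataset(pl)
  expect_identical(ds$outgroups$outgroup1$unbroken, ds$focal_genome)
})

test_that("an infeasible plan raises a sizing error", {
  pl <- small_plan()
  pl$chrom_len <- 30000L
  expect_error(simulate_dataset(pl), "sizing error")
})

test_that("simulated counts hit their class TPM targets through compute_tpm", {
  ds <- default_dataset()
  tpm <- compute_tpm(ds$counts, ds$tx_lengths)
  truth <- ds$truth

  low <- truth$transcript_id[truth$class == "low_expression"]
  expect_true(all(tpm[low, ] < 1))            # below threshold in every library
  expect_true(all(apply(tpm[low, ], 1, max) > 0.4))  # near the 0.5 target

  lead <- vapply(split(truth, truth$gene_group), function(g)
    g$transcript_id[g$isoform == 1][1], "")
  td <- lead[vapply(split(truth, truth$gene_group), function(g)
    g$class[1] == "true_denovo", TRUE)]
  expect_true(all(apply(tpm[td, ], 1, max) >= 1))  # passes the TPM rule

  # planted lengths straddle the structural boundary as designed
  sh <- truth$transcript_id[truth$class == "short"]
  expect_true(all(nchar(ds$transcripts[sh]) <= 300))
  expect_true(all(nchar(ds$transcripts[td]) >= 302))
})

test_that("near-exon and intronic decoys sit where their stage requires", {
  ds <- default_dataset()
  ann <- ds$annotation
  truth <- ds$truth
  for (cl in c("near_exon", "intronic")) {
    ids <- truth$transcript_id[truth$class == cl]
    for (id in ids) {
      r <- truth[truth$transcript_id == id, ]
      d <- exon_distance(list(chrom = r$chrom, start = r$start, end = r$end),
                         ann)
      if (cl == "near_exon") expect_lte(d, 250) else expect_gt(d, 250)
      if (cl == "intronic")
        expect_equal(genic_context(list(chrom = r$chrom, start = r$start,
                                        end = r$end), ann), "intronic")
    }
  }
})
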