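test_that("TPM normalisation matches closed forms", {
  m1 <- matrix(7L, 1, 1, dimnames = list("t1", "l1"))
  expect_equal(compute_tpm(m1, c(t1 = 500))[1, 1], 1e6)

  # equal counts, lengths L and 2L
  m2 <- matrix(c(10L, 10L), 2, 1, dimnames = list(c("a", "b"), "l1"))
  tpm2 <- compute_tpm(m2, c(a = 1000, b = 2000))
  expect_equal(tpm2["a", 1], 666666.67, tolerance = 0.01 / 666666.67)
  expect_equal(tpm2["b", 1], 333333.33, tolerance = 0.01 / 333333.33)

  m3 <- matrix(c(0L, 5L), 2, 1, dimnames = list(c("a", "b"), "l1"))
  expect_equal(compute_tpm(m3, c(a = 100, b = 100))["a", 1], 0)

  expect_error(compute_tpm(m1, c(zz = 1)), "missing length")
})

test_that("TPM columns sum to 1e6 and are scale invariant", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    counts <- matrix(rpois(n * 4, 50), n, 4,
                     dimnames = list(paste0("t", 1:n), paste0("l", 1:4)))
    lens <- setNames(sample(200:3000, n), rownames(counts))
    tpm <- compute_tpm(counts, lens)
    expect_equal(colSums(tpm), setNames(rep(1e6, 4), colnames(counts)),
                 tolerance = 1e-6)
    scaled <- counts
    scaled[, 2] <- scaled[, 2] * 17L
    expect_equal(compute_tpm(scaled, lens)[, 2], tpm[, 2], tolerance = 1e-12)
  }
  # all-zero library stays zero
  z <- matrix(0L, 2, 1, dimnames = list(c("a", "b"), "l1"))
  expect_true(all(compute_tpm(z, c(a = 100, b = 100)) == 0))
})

test_that("expression calls use inclusive any-library and strict replicate-mean rules", {
  expect_true(expressed_call(1.0, "any_library"))
  expect_false(expressed_call(0.999, "any_library"))
  expect_true(expressed_call(c(0.8, 1.4), "replicate_mean"))  # mean 1.1
  expect_false(expressed_call(1.0, "replicate_mean"))         # strict
  expect_error(expressed_call(numeric(0), "any_library"), "empty")
})

test_that("isoform pooling is additive and permutation invariant", {
  tpm <- matrix(c(0.6, 2, 0.5, 1, 0, 3), nrow = 3, byrow = TRUE,
                dimnames = list(c("i1", "i2", "i3"), c("l1", "l2")))
  expect_equal(pool_isoforms(tpm, c("i1", "i2"))[["l1"]], 1.1)
  expect_equal(pool_isoforms(tpm, c("i1", "i2")),
               pool_isoforms(tpm, c("i2", "i1")))
  expect_equal(pool_isoforms(tpm, "i1"), tpm["i1", ])
  expect_equal(pool_isoforms(tpm, c("i1", "absent"))[["l2"]], 2)
})

test_that("candidate summaries follow the expressed-observation definitions", {
  tpm <- matrix(c(1.2, 2.0, 0.5, 0), nrow = 1,
                dimnames = list("c1_i1", paste0("l", 1:4)))
  out <- summarize_candidates(tpm, list(c1 = "c1_i1"))
  s <- out$summaries
  expect_equal(s$n_libraries_expressed, 2)
  expect_equal(s$n_libraries_nonzero, 3)
  expect_equal(s$mean_TPM_of_expressed, 1.6)
  expect_equal(s$max_TPM, 2.0)

  # never-expressed candidate excluded from the cohort mean
  tpm2 <- rbind(tpm, c2_i1 = c(0.4, 0.2, 0, 0))
  out2 <- summarize_candidates(tpm2, list(c1 = "c1_i1", c2 = "c2_i1"))
  expect_equal(out2$cohort$mean_tpm_expressed, 1.6)
  expect_equal(out2$cohort$n_candidates, 2)

  empty <- summarize_candidates(tpm, list())
  expect_equal(empty$cohort$n_candidates, 0)
  expect_true(is.na(empty$cohort$mean_tpm_expressed))
})

test_that("fraction of annotated genes above the candidate max behaves and decreases", {
  tpm <- matrix(c(10, 5, 0.5, 2, 1.59, 0.1), ncol = 1,
                dimnames = list(c("a1", "a2", "a3", "a4", "c1", "c2"), "l1"))
  fr <- fraction_annotated_above_candidate_max(tpm, paste0("a", 1:4),
                                               c("c1", "c2"))
  expect_equal(unname(fr), 0.75)  # 3 of 4 exceed 1.59

  # candidate max 0: fraction of annotated genes with TPM > 0
  tpm0 <- tpm; tpm0[c("c1", "c2"), ] <- 0
  expect_equal(unname(fraction_annotated_above_candidate_max(
    tpm0, paste0("a", 1:4), c("c1", "c2"))), 1)

  # non-increasing in the candidate max
  fr_seq <- vapply(c(0, 1, 3, 6, 11), function(cm) {
    t2 <- tpm; t2["c1", ] <- cm
    unname(fraction_annotated_above_candidate_max(t2, paste0("a", 1:4), "c1"))
  }, 0)
  expect_true(all(diff(fr_seq) <= 0))
})
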