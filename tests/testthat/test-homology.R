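test_that("k-mer index stores exact seed positions and skips N windows", {
  idx <- build_kmer_index(c(s = "ACGTACGTACGT"), k = 8)
  hits <- denovoscan:::seed_hits(idx, denovoscan:::encode_dna("ACGTACGT"))
  expect_equal(sort(hits$spos), c(1, 5))  # 1-based starts

  hits <- denovoscan:::seed_hits(idx, denovoscan:::encode_dna("TTTTTTTT"))
  expect_null(hits)

  idxN <- build_kmer_index(c(s = "ACGTNCGTACGTACGTAAAA"), k = 8)
  # windows covering the N at position 5 are absent
  expect_false(any(idxN$pos <= 5 & idxN$pos >= 1 & idxN$pos + 7 >= 5))

  expect_error(build_kmer_index(c(s = "ACGT"), k = 8), "shortest")
  expect_error(build_kmer_index(c(s = "ACGTACGTACGT"), k = 20), "\\[8, 15\\]")
})

test_that("seed extension recovers the identity case and strands", {
  set.seed(11)
  s <- rand_dna(400)
  q <- substr(s, 101, 250)  # 150 bp exact copy
  al <- seed_extend(q, s, 1, 101)
  expect_equal(al$identity, 1.0)
  expect_equal(al$aligned_len, 150)
  expect_equal(c(al$s_start, al$s_end), c(101, 250))

  idx <- build_kmer_index(c(s = s), k = 11)
  hm <- has_match(denovoscan:::revcomp(q), idx)
  expect_true(hm$matched)
  expect_equal(hm$match$strand, "-")
  expect_equal(c(hm$match$s_start, hm$match$s_end), c(101, 250))
})

test_that("substituted queries agree with the optimal-alignment oracle", {
  set.seed(12)
  s <- rand_dna(400)
  q <- substr(s, 101, 200)
  x <- strsplit(q, "")[[1]]
  pos <- sample(100, 25)
  x[pos] <- vapply(x[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  qm <- paste(x, collapse = "")
  mine <- seed_extend(qm, s, which(!(seq_len(100) %in% pos))[1], 100 + which(!(seq_len(100) %in% pos))[1])
  orc <- oracle_local_align(qm, s)
  expect_equal(mine$score, orc$score)
  expect_equal(mine$identity, orc$identity, tolerance = 0.01)
})

test_that("the match criterion enforces both identity and length bounds", {
  set.seed(13)
  s <- rand_dna(2000)
  idx <- build_kmer_index(c(chr = s), k = 11)
  crit <- match_criterion(0.80, 100)

  # 150 bp exact substring qualifies
  expect_true(has_match(substr(s, 501, 650), idx, crit)$matched)

  # 99 bp at 100% identity fails the length bound
  expect_false(has_match(substr(s, 501, 599), idx, crit)$matched)

  # 75% identity over 120 bp fails the identity bound; confirmed by a
  # sliding-window scan that no >=100-column window reaches 80%
  q <- substr(s, 301, 420)
  x <- strsplit(q, "")[[1]]
  pos <- seq(2, 118, by = 4)
  x[pos] <- vapply(x[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  qm <- paste(x, collapse = "")
  is_match <- strsplit(qm, "")[[1]] == strsplit(q, "")[[1]]
  win_ident <- vapply(1:(120 - 99), function(i) mean(is_match[i:(i + 99)]), 0)
  expect_true(max(win_ident) < 0.80)  # construction check
  expect_false(has_match(qm, idx, crit)$matched)
})

test_that("raising the criterion thresholds is monotone and strands are symmetric", {
  set.seed(14)
  for (rep in 1:20) {
    pr <- make_pair(300, 500, seg_len = sample(80:200, 1),
                    identity = runif(1, 0.7, 1))
    idx <- build_kmer_index(c(s = pr$s), k = 11)
    base <- has_match(pr$q, idx, match_criterion(0.80, 100))$matched
    tighter_id <- has_match(pr$q, idx, match_criterion(0.90, 100))$matched
    tighter_len <- has_match(pr$q, idx, match_criterion(0.80, 150))$matched
    expect_true(!tighter_id || base)
    expect_true(!tighter_len || base)
    rc <- has_match(denovoscan:::revcomp(pr$q), idx,
                    match_criterion(0.80, 100))$matched
    expect_equal(rc, base)
  }
})
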