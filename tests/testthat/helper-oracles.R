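# Independent oracles and shared fixtures.
#
# The alignment oracle is Biostrings' optimal local aligner with the same
# scoring as the package's banded seed-and-extend (match +1, mismatch -2, a
# gap of length g costs 4 + g); the package path never calls it. The ORF
# oracle enumerates ORFs by regex over six-frame translations.

oracle_scoring <- local({
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  list(mat = mat, gapOpening = 4, gapExtension = 1)
})

# best local alignment stats of q vs s (both strands)
oracle_local_align <- function(q, s) {
  best <- NULL
  for (qq in c(q, denovoscan:::revcomp(q))) {
    al <- suppressWarnings(Biostrings::pairwiseAlignment(
      qq, s, type = "local", substitutionMatrix = oracle_scoring$mat,
      gapOpening = oracle_scoring$gapOpening,
      gapExtension = oracle_scoring$gapExtension))
    sc <- Biostrings::score(al)
    if (is.null(best) || sc > best$score) {
      cols <- nchar(as.character(Biostrings::alignedPattern(al)))
      best <- list(score = sc, columns = cols,
                   matches = Biostrings::nmatch(al),
                   identity = if (cols > 0) Biostrings::nmatch(al) / cols else 0)
    }
  }
  best
}

oracle_qualifies <- function(q, s, min_identity = 0.80, min_len = 100L) {
  b <- oracle_local_align(q, s)
  b$identity >= min_identity && b$columns >= min_len
}

# independent confirmation that a claimed match (spans on query/subject, as
# reported by has_match) is a qualifying alignment: globally align exactly
# the claimed substrings with the same scoring. Used to resolve cases where
# the single best-scoring local alignment is a co-optimal longer variant
# below the identity bound while a qualifying alignment nevertheless exists.
oracle_confirms_match <- function(q, s, m, min_identity = 0.80,
                                  min_len = 100L) {
  qq <- if (m$strand == "-") denovoscan:::revcomp(q) else q
  qs <- if (m$strand == "-") nchar(q) - m$q_end + 1L else m$q_start
  qe <- if (m$strand == "-") nchar(q) - m$q_start + 1L else m$q_end
  al <- suppressWarnings(Biostrings::pairwiseAlignment(
    substr(qq, qs, qe), substr(s, m$s_start, m$s_end), type = "global",
    substitutionMatrix = oracle_scoring$mat,
    gapOpening = oracle_scoring$gapOpening,
    gapExtension = oracle_scoring$gapExtension))
  cols <- nchar(as.character(Biostrings::alignedPattern(al)))
  cols >= min_len && Biostrings::nmatch(al) / cols >= min_identity
}

# six-frame ORF enumeration via regex over translations (ATG..stop, longest
# per stop, stop included in the length)
orf_oracle <- function(seq, min_len = 75L) {
  L <- nchar(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else denovoscan:::revcomp(seq)
    for (f in 0:2) {
      n_cod <- (nchar(s) - f) %/% 3L
      if (n_cod < 1L) next
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(s, f + 1L, f + 3L * n_cod)),
        no.init.codon = TRUE, if.fuzzy.codon = "X"))
      m <- gregexpr("M[^*]*\\*", aa)[[1]]
      if (m[1] == -1L) next
      for (i in seq_along(m)) {
        s0 <- f + 1L + (m[i] - 1L) * 3L
        e0 <- s0 + attr(m, "match.length")[i] * 3L - 1L
        len <- e0 - s0 + 1L
        if (len < min_len) next
        if (strand == "+") {
          st <- s0; en <- e0
        } else {
          st <- L - e0 + 1L; en <- L - s0 + 1L
        }
        rows[[length(rows) + 1L]] <- data.frame(strand = strand, frame = f,
                                                start = st, end = en,
                                                length_nt = len,
                                                stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(strand = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      length_nt = integer(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df[order(df$strand, df$frame, df$start), , drop = FALSE]
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# plant a homologous segment of `seg_len` at `identity` (with optional small
# indels) into two otherwise random sequences; returns list(q, s)
make_pair <- function(q_len, s_len, seg_len = 0L, identity = 1,
                      n_indel = 0L) {
  q <- rand_dna(q_len)
  s <- rand_dna(s_len)
  if (seg_len > 0L) {
    seg <- substr(q, 11L, 10L + seg_len)
    x <- strsplit(seg, "")[[1]]
    n_mut <- round((1 - identity) * seg_len)
    if (n_mut > 0L) {
      pos <- sample(seg_len, n_mut)
      x[pos] <- vapply(x[pos], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    }
    if (n_indel > 0L) {
      for (k in seq_len(n_indel)) {
        p <- sample(length(x) - 2L, 1L)
        if (stats::runif(1) < 0.5) x <- append(x, sample(c("A", "C", "G", "T"), 1L), p)
        else x <- x[-p]
      }
    }
    seg_mut <- paste(x, collapse = "")
    at <- sample(s_len - nchar(seg_mut) - 10L, 1L) + 5L
    s <- paste0(substr(s, 1L, at - 1L), seg_mut,
                substr(s, at + nchar(seg_mut), s_len))
  }
  list(q = q, s = s)
}

# default-plan dataset and pipeline run, computed once per test session
.run_cache <- new.env(parent = emptyenv())

default_dataset <- function() {
  if (is.null(.run_cache$dataset))
    .run_cache$dataset <- simulate_dataset(sim_plan())
  .run_cache$dataset
}

default_run <- function() {
  if (is.null(.run_cache$run)) {
    ds <- default_dataset()
    .run_cache$run <- run_all(list(), out_dir = tempfile("dns_default_"),
                              dataset = ds, quiet = TRUE)
  }
  .run_cache$run
}

default_indexes <- function() {
  if (is.null(.run_cache$indexes)) {
    ds <- default_dataset()
    .run_cache$indexes <- build_screen_indexes(ds$databases, ds$focal_genome,
                                               pipeline_config())
  }
  .run_cache$indexes
}

# minimal annotation data.frame builder
mini_annotation <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = r$chrom %||% "chr1", start = r$start, end = r$end,
               strand = r$strand %||% "+", feature_class = r$class,
               gene_id = r$gene_id %||% "g1",
               transcript_id = r$transcript_id %||% NA_character_,
               stringsAsFactors = FALSE)))
  denovoscan:::as_annotation(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
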