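# Seed-and-extend local homology search.
#
# This module realises the screening match criterion used throughout the
# pipeline: a hit counts as a match when it reaches >= 80% identity over at
# least 100 alignment columns (gaps included). Search is exact-k-mer seeding
# over an integer-coded subject index, followed by banded gapped extension
# (match +1, mismatch -2, gap open -4, gap extend -1, band +/-10) implemented
# in C++ (src/align.cpp). Both subject strands are searched by additionally
# querying the reverse complement.

#' Match acceptance criterion for homology screening
#'
#' @param min_identity Minimum identity fraction (matches / alignment columns,
#'   gaps counted as columns). Default 0.80.
#' @param min_len Minimum alignment length in columns. Default 100.
#' @return An object of class `match_criterion`.
#' @export
match_criterion <- function(min_identity = 0.80, min_len = 100L) {
  stopifnot(min_identity > 0, min_identity <= 1, min_len >= 1)
  structure(list(min_identity = min_identity, min_len = as.integer(min_len)),
            class = "match_criterion")
}

#' Build an exact k-mer index over subject sequences
#'
#' Positions of every k-mer (A/C/G/T only; windows containing N are skipped)
#' across all subject sequences, stored sorted for binary-search lookup.
#'
#' @param sequences Named character vector of subject sequences.
#' @param k Seed length, between 8 and 15. Default 11.
#' @return An object of class `seq_index`.
#' @export
build_kmer_index <- function(sequences, k = 11L) {
  k <- as.integer(k)
  if (k < 8L || k > 15L) stop_fmt("seed length k must be in [8, 15], got %d", k)
  if (length(sequences) == 0L) stop_fmt("cannot index an empty sequence set")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop_fmt("subject sequences must be named")
  lens <- nchar(sequences)
  if (min(lens) < k)
    stop_fmt("k = %d exceeds the shortest subject sequence (%d bp)", k, min(lens))
  ints <- lapply(unname(sequences), encode_dna)
  codes <- vector("list", length(ints))
  poss <- vector("list", length(ints))
  for (i in seq_along(ints)) {
    cd <- kmer_codes(ints[[i]], k)
    keep <- !is.na(cd)
    codes[[i]] <- cd[keep]
    poss[[i]] <- which(keep)
  }
  code <- unlist(codes, use.names = FALSE)
  pos <- unlist(poss, use.names = FALSE)
  subj <- rep.int(seq_along(ints), lengths(codes))
  o <- order(code)
  structure(list(k = k, names = names(sequences), lens = unname(lens),
                 ints = ints, codes = code[o], subj = subj[o], pos = pos[o]),
            class = "seq_index")
}

empty_match_df <- function() {
  data.frame(subject_id = character(0), strand = character(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             score = integer(0), matches = integer(0),
             aligned_len = integer(0), identity = numeric(0),
             stringsAsFactors = FALSE)
}

# expand k-mer hits of one query strand into (qpos, subj, spos) triples
seed_hits <- function(index, qints, max_hits_per_kmer = 64L) {
  qc <- kmer_codes(qints, index$k)
  if (!length(qc)) return(NULL)
  hi <- findInterval(qc, index$codes)
  lo <- findInterval(qc - 1, index$codes) + 1L
  cnt <- hi - lo + 1L
  cnt[is.na(qc) | cnt < 0L] <- 0L
  cnt[cnt > max_hits_per_kmer] <- 0L  # skip hyper-repetitive seeds
  sel <- which(cnt > 0L)
  if (!length(sel)) return(NULL)
  idx <- sequence(cnt[sel]) + rep.int(lo[sel] - 1L, cnt[sel])
  list(qpos = rep.int(sel, cnt[sel]), subj = index$subj[idx],
       spos = index$pos[idx])
}

align_scoring <- function() {
  list(match = 1L, mismatch = -2L, gap_open = 4L, gap_ext = 1L)
}

#' Banded gapped extension from an exact seed
#'
#' Extends an exact k-mer seed into a local alignment using banded dynamic
#' programming (band +/-10 diagonals around the seed diagonal; match +1,
#' mismatch -2, gap open -4, gap extend -1; a gap of length g costs 4 + g).
#' The returned alignment is the maximal-scoring local segment within the
#' band. Identity is matches / alignment columns, with gap columns counted.
#'
#' @param query,subject Character scalars (DNA).
#' @param q_pos,s_pos 1-based positions of the seed start in query / subject.
#' @param band Band half-width in diagonals. Default 10.
#' @return One-row data.frame: q_start, q_end, s_start, s_end (1-based
#'   closed), score, matches, aligned_len, identity.
#' @export
seed_extend <- function(query, subject, q_pos, s_pos, band = 10L) {
  sc <- align_scoring()
  res <- banded_local_align(encode_dna(query), encode_dna(subject),
                            as.integer(s_pos - q_pos), as.integer(band),
                            sc$match, sc$mismatch, sc$gap_open, sc$gap_ext)
  data.frame(q_start = res$q_start, q_end = res$q_end,
             s_start = res$s_start, s_end = res$s_end, score = res$score,
             matches = res$matches, aligned_len = res$columns,
             identity = if (res$columns > 0) res$matches / res$columns else 0,
             stringsAsFactors = FALSE)
}

#' Search a query against an indexed subject set
#'
#' Seeds on exact k-mers (both strands), clusters seed hits by subject and
#' diagonal, and runs one banded extension per cluster. Returns every distinct
#' local alignment found (not only qualifying ones).
#'
#' @param query Character scalar (DNA).
#' @param index A `seq_index` from [build_kmer_index()].
#' @param band Band half-width for extension.
#' @param max_clusters Cap on diagonal clusters examined per strand, densest
#'   first.
#' @param stop_at Optional `match_criterion`; if supplied, the search returns
#'   as soon as a qualifying match has been found (evidence may then not be
#'   the globally best match; membership decisions are unaffected).
#' @return data.frame of alignments; query coordinates always refer to the
#'   forward query, strand records the orientation of the hit.
#' @export
search_matches <- function(query, index, band = 10L, max_clusters = 400L,
                           stop_at = NULL) {
  stopifnot(inherits(index, "seq_index"))
  L <- nchar(query)
  out <- list()
  found_qualifying <- FALSE
  for (strand in c("+", "-")) {
    if (found_qualifying && !is.null(stop_at)) break
    qseq <- if (strand == "+") query else revcomp(query)
    qints <- encode_dna(qseq)
    hits <- seed_hits(index, qints)
    if (is.null(hits)) next
    diag <- hits$spos - hits$qpos
    bucket <- hits$subj * 2^33 + floor(diag / band)
    tab <- table(bucket)
    ord <- names(tab)[order(-as.integer(tab))]
    if (length(ord) > max_clusters) ord <- ord[seq_len(max_clusters)]
    seen <- character(0)
    for (b in ord) {
      sel <- which(bucket == as.numeric(b))
      subj <- hits$subj[sel[1]]
      dtab <- table(diag[sel])
      d0 <- as.integer(names(dtab)[which.max(dtab)])
      key <- paste(subj, d0, strand)
      if (key %in% seen) next
      seen <- c(seen, key)
      sc <- align_scoring()
      res <- banded_local_align(qints, index$ints[[subj]], d0,
                                as.integer(band), sc$match, sc$mismatch,
                                sc$gap_open, sc$gap_ext)
      if (res$score <= 0 || res$columns == 0) next
      if (strand == "+") {
        qs <- res$q_start; qe <- res$q_end
      } else {
        qs <- L - res$q_end + 1L; qe <- L - res$q_start + 1L
      }
      ident <- res$matches / res$columns
      out[[length(out) + 1L]] <- data.frame(
        subject_id = index$names[subj], strand = strand,
        q_start = qs, q_end = qe, s_start = res$s_start, s_end = res$s_end,
        score = res$score, matches = res$matches, aligned_len = res$columns,
        identity = ident, stringsAsFactors = FALSE)
      if (!is.null(stop_at) && ident >= stop_at$min_identity &&
          res$columns >= stop_at$min_len) {
        found_qualifying <- TRUE
        break
      }
    }
  }
  if (!length(out)) return(empty_match_df())
  df <- do.call(rbind, out)
  df[!duplicated(df[c("subject_id", "strand", "q_start", "q_end",
                      "s_start", "s_end")]), , drop = FALSE]
}

#' Test a query against the match criterion
#'
#' TRUE iff some local alignment reaches `min_identity` over at least
#' `min_len` alignment columns, on either strand. The best qualifying match
#' is returned; ties on score are broken by higher identity, then
#' lexicographically lower subject id, then lower subject start.
#'
#' @inheritParams search_matches
#' @param criterion A `match_criterion`.
#' @param stop_at_first If TRUE, stop at the first qualifying match (faster;
#'   the reported match may then not be the best-scoring one).
#' @return list(matched = logical, match = one-row data.frame or NULL).
#' @export
has_match <- function(query, index, criterion = match_criterion(),
                      band = 10L, stop_at_first = FALSE) {
  m <- search_matches(query, index, band = band,
                      stop_at = if (stop_at_first) criterion else NULL)
  qual <- m[m$identity >= criterion$min_identity &
              m$aligned_len >= criterion$min_len, , drop = FALSE]
  if (nrow(qual) == 0L) return(list(matched = FALSE, match = NULL))
  o <- order(-qual$score, -qual$identity, qual$subject_id, qual$s_start)
  list(matched = TRUE, match = qual[o[1L], , drop = FALSE])
}
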