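# Six-frame ORF discovery: ATG through stop, both strands, all frames.
# Nested ORFs sharing a stop report only the longest. ORF length counts ATG
# through the stop codon inclusive; stopless (partial) ORFs at transcript
# ends are reported flagged and excluded from the minimum-length pass by
# default. Feeds coding-potential tools via peptide export.

STOP_CODONS <- c("TAA", "TAG", "TGA")

orfs_one_strand <- function(seq, strand, L) {
  n <- nchar(seq)
  out <- list()
  for (f in 0:2) {
    n_cod <- (n - f) %/% 3L
    if (n_cod < 1L) next
    starts <- f + 1L + 3L * (seq_len(n_cod) - 1L)
    codons <- substring(seq, starts, starts + 2L)
    is_start <- codons == "ATG"
    is_stop <- codons %in% STOP_CODONS
    stop_pos <- which(is_stop)
    prev_stop <- 0L
    for (sp in stop_pos) {
      cand <- which(is_start[(prev_stop + 1L):(sp - 1L)])
      if (length(cand)) {
        a <- prev_stop + cand[1L]  # earliest start -> longest ORF for this stop
        s0 <- starts[a]; e0 <- starts[sp] + 2L
        out[[length(out) + 1L]] <- list(frame = f, s = s0, e = e0,
                                        partial = FALSE)
      }
      prev_stop <- sp
    }
    # stopless tail ORF
    if (prev_stop < n_cod) {
      cand <- which(is_start[(prev_stop + 1L):n_cod])
      if (length(cand)) {
        a <- prev_stop + cand[1L]
        out[[length(out) + 1L]] <- list(frame = f, s = starts[a],
                                        e = starts[n_cod] + 2L, partial = TRUE)
      }
    }
  }
  if (!length(out)) return(NULL)
  df <- do.call(rbind, lapply(out, as.data.frame))
  df$strand <- strand
  if (strand == "+") {
    df$start <- df$s; df$end <- df$e
  } else {
    df$start <- L - df$e + 1L; df$end <- L - df$s + 1L
  }
  df$length_nt <- df$e - df$s + 1L
  df$seq_fwd_strand <- substring(seq, df$s, df$e)
  df[c("strand", "frame", "start", "end", "length_nt", "partial",
       "seq_fwd_strand")]
}

translate_orf <- function(orf_seq, partial) {
  cod <- if (partial) orf_seq else substr(orf_seq, 1L, nchar(orf_seq) - 3L)
  if (!nchar(cod)) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(cod),
                                     if.fuzzy.codon = "X"))
}

#' Find open reading frames on both strands of a transcript
#'
#' All ATG-to-stop spans in all 3 frames of both strands; nested ORFs
#' sharing a stop codon report only the longest. Results are filtered to
#' `length_nt >= min_len_nt` (ATG through stop inclusive) and sorted by
#' length descending, ties broken by strand (+ first) then lower start.
#' Coordinates are 1-based closed on the forward transcript.
#'
#' @param sequence Transcript sequence.
#' @param min_len_nt Minimum ORF length in nt. Default 75; 30 is a common
#'   permissive preset.
#' @param include_partial Also report stopless ORFs running into the
#'   transcript end (flagged `partial`). Default FALSE.
#' @return data.frame: strand, frame, start, end, length_nt, partial,
#'   peptide.
#' @export
find_orfs <- function(sequence, min_len_nt = 75L, include_partial = FALSE) {
  stopifnot(min_len_nt >= 3L)
  empty <- data.frame(strand = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      length_nt = integer(0), partial = logical(0),
                      peptide = character(0), stringsAsFactors = FALSE)
  L <- nchar(sequence)
  if (L < min_len_nt) return(empty)
  fwd <- orfs_one_strand(sequence, "+", L)
  rev <- orfs_one_strand(revcomp(sequence), "-", L)
  df <- rbind(fwd, rev)
  if (is.null(df) || !nrow(df)) return(empty)
  if (!include_partial) df <- df[!df$partial, , drop = FALSE]
  df <- df[df$length_nt >= min_len_nt, , drop = FALSE]
  if (!nrow(df)) return(empty)
  df$peptide <- mapply(translate_orf, df$seq_fwd_strand, df$partial,
                       USE.NAMES = FALSE)
  df <- df[order(-df$length_nt, df$strand != "+", df$start), ,
           drop = FALSE]
  rownames(df) <- NULL
  df[c("strand", "frame", "start", "end", "length_nt", "partial", "peptide")]
}

#' Export retained ORF peptides as FASTA
#'
#' One record per ORF, ID `<transcript_id>|<strand><frame>|<start>-<end>`;
#' the stop codon is not part of the peptide.
#'
#' @param candidates A `candidate_set`, or a named list of sequences.
#' @param path Output FASTA path.
#' @param min_len_nt Minimum ORF length in nt.
#' @return Invisibly, the data.frame of exported ORFs (with transcript_id).
#' @export
export_orf_peptides <- function(candidates, path, min_len_nt = 75L) {
  seqs <- if (inherits(candidates, "candidate_set"))
    unlist(lapply(unname(candidates), function(cd) cd$sequences)) else
      unlist(candidates)
  rows <- list()
  peps <- character(0)
  for (id in names(seqs)) {
    orfs <- find_orfs(seqs[[id]], min_len_nt)
    if (!nrow(orfs)) next
    orfs$transcript_id <- id
    rows[[id]] <- orfs
    rec <- sprintf("%s|%s%d|%d-%d", id, orfs$strand, orfs$frame, orfs$start,
                   orfs$end)
    peps <- c(peps, stats::setNames(orfs$peptide, rec))
  }
  if (length(peps)) {
    write_fasta(peps, path)
  } else {
    writeLines("# no ORFs passed the minimum length", path)
  }
  invisible(if (length(rows)) do.call(rbind, unname(rows)) else
    data.frame(strand = character(0), frame = integer(0), start = integer(0),
               end = integer(0), length_nt = integer(0), partial = logical(0),
               peptide = character(0), transcript_id = character(0),
               stringsAsFactors = FALSE))
}
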