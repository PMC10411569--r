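# Shared low-level helpers: sequence encoding, reverse complement, small
# assertions. All genomic coordinates in this package are 1-based closed
# (IRanges convention); BED output is converted on write.

DNA_BASES <- c("A", "C", "G", "T")

#' @useDynLib denovoscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# integer-encode a DNA string: A=0, C=1, G=2, T=3, N/other = -1
encode_dna <- function(seq) {
  x <- utf8ToInt(seq)
  code <- rep.int(-1L, length(x))
  code[x == 65L] <- 0L  # A
  code[x == 67L] <- 1L  # C
  code[x == 71L] <- 2L  # G
  code[x == 84L] <- 3L  # T
  code
}

decode_dna <- function(code) {
  chars <- rep("N", length(code))
  ok <- code >= 0L
  chars[ok] <- DNA_BASES[code[ok] + 1L]
  paste(chars, collapse = "")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# rolling k-mer integer codes; windows containing N (code -1) become NA
kmer_codes <- function(code, k) {
  n <- length(code)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  cd <- as.numeric(code)
  cd[cd < 0] <- NA_real_
  out <- numeric(m)
  for (j in seq_len(k)) {
    out <- out + cd[j:(m + j - 1L)] * 4^(k - j)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 1013) %% 2147483399)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}
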