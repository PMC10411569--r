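# TPM computation and the expression summaries reported for candidates:
# per-candidate library counts and max TPM, the cohort mean TPM of expressed
# observations, and the per-library fraction of annotated genes expressed
# above the candidate maximum.

#' Compute TPM from a counts matrix
#'
#' Per library: rate_t = count_t / length_t(kb); TPM_t = rate_t / sum(rates)
#' x 1e6. Columns of the result sum to 1e6 (all-zero libraries stay zero).
#' Effective length is the transcript length (the pipeline consumes counts,
#' not reads, so no fragment-length correction applies).
#'
#' @param counts Non-negative matrix, rows transcripts, columns libraries.
#' @param lengths Named vector of transcript lengths (bp) covering all rows.
#' @return TPM matrix with the same dimnames.
#' @export
compute_tpm <- function(counts, lengths) {
  if (is.null(rownames(counts))) stop_fmt("counts matrix must have row names")
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing))
    stop_fmt("missing length for counted transcript(s): %s",
             paste(utils::head(missing, 5), collapse = ", "))
  if (any(counts < 0)) stop_fmt("counts must be non-negative")
  len_kb <- lengths[rownames(counts)] / 1000
  rate <- counts / len_kb
  tot <- colSums(rate)
  tpm <- sweep(rate, 2, ifelse(tot > 0, tot, 1), "/") * 1e6
  tpm[, tot == 0] <- 0
  tpm
}

#' Expression call over a set of replicate values
#'
#' `any_library`: max(values) >= 1 (inclusive). `replicate_mean`:
#' mean(values) > 1 (strict). The two modes are kept distinct deliberately:
#' the within-study criterion is inclusive, the external-resource criterion
#' strict.
#'
#' @param values Numeric TPM values across replicates/libraries.
#' @param mode "any_library" or "replicate_mean".
#' @param threshold Expression threshold. Default 1.
#' @return Logical.
#' @export
expressed_call <- function(values, mode = c("any_library", "replicate_mean"),
                           threshold = 1.0) {
  mode <- match.arg(mode)
  if (!length(values)) stop_fmt("empty replicate set")
  if (mode == "any_library") max(values) >= threshold else mean(values) > threshold
}

#' Pool isoform TPMs into per-library candidate TPM
#'
#' Candidate TPM in a library is the sum of its isoform TPMs there (summing
#' isoform TPMs yields gene-level TPM); isoforms absent from the matrix
#' contribute 0.
#'
#' @param tpm TPM matrix.
#' @param isoform_ids Character vector of the candidate's isoforms.
#' @return Named numeric vector over libraries.
#' @export
pool_isoforms <- function(tpm, isoform_ids) {
  if (!length(isoform_ids)) stop_fmt("candidate has no isoforms")
  present <- intersect(isoform_ids, rownames(tpm))
  if (!length(present)) return(stats::setNames(rep(0, ncol(tpm)), colnames(tpm)))
  colSums(tpm[present, , drop = FALSE])
}

#' Per-candidate expression summaries and cohort statistics
#'
#' For each candidate (isoform-pooled TPMs): the number of libraries with
#' TPM >= threshold, the number with nonzero TPM, the maximum TPM, and the
#' mean TPM over expressed observations (TPM >= threshold only). Cohort
#' statistics: the mean of those means over candidates with at least one
#' expressed observation, and the mean number of nonzero libraries.
#'
#' @param tpm TPM matrix.
#' @param candidates A `candidate_set` or a named list mapping candidate id
#'   to isoform ids.
#' @param threshold Expression threshold. Default 1.
#' @return list(summaries = data.frame, cohort = list(mean_tpm_expressed,
#'   mean_libraries_nonzero, n_candidates)).
#' @export
summarize_candidates <- function(tpm, candidates, threshold = 1.0) {
  iso_of <- lapply(candidates, function(cd)
    if (is.list(cd) && !is.null(cd$isoforms)) cd$isoforms else cd)
  rows <- list()
  for (id in names(iso_of)) {
    v <- pool_isoforms(tpm, iso_of[[id]])
    expressed <- v[v >= threshold]
    rows[[id]] <- data.frame(
      candidate_id = id,
      n_libraries_expressed = sum(v >= threshold),
      n_libraries_nonzero = sum(v > 0),
      max_TPM = max(v),
      mean_TPM_of_expressed = if (length(expressed)) mean(expressed) else NA_real_,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(list(summaries = data.frame(candidate_id = character(0),
                                       n_libraries_expressed = integer(0),
                                       n_libraries_nonzero = integer(0),
                                       max_TPM = numeric(0),
                                       mean_TPM_of_expressed = numeric(0),
                                       stringsAsFactors = FALSE),
                cohort = list(mean_tpm_expressed = NA_real_,
                              mean_libraries_nonzero = NA_real_,
                              n_candidates = 0L)))
  df <- do.call(rbind, unname(rows))
  list(summaries = df,
       cohort = list(
         mean_tpm_expressed = mean(df$mean_TPM_of_expressed, na.rm = TRUE),
         mean_libraries_nonzero = mean(df$n_libraries_nonzero),
         n_candidates = nrow(df)))
}

#' Fraction of annotated genes expressed above the candidate maximum
#'
#' Per library: |{annotated genes with TPM > max candidate TPM}| /
#' |annotated genes|.
#'
#' @param tpm TPM matrix.
#' @param annotated_ids,candidate_ids Row subsets of `tpm` (candidate rows
#'   may be isoform-pooled rows or raw isoforms).
#' @param library Library (column) name or index; NULL = all libraries.
#' @return Named numeric vector of fractions per library.
#' @export
fraction_annotated_above_candidate_max <- function(tpm, annotated_ids,
                                                   candidate_ids,
                                                   library = NULL) {
  ann <- intersect(annotated_ids, rownames(tpm))
  cand <- intersect(candidate_ids, rownames(tpm))
  if (!length(ann)) stop_fmt("no annotated genes present in the TPM matrix")
  if (!length(cand)) stop_fmt("no candidates present in the TPM matrix")
  libs <- if (is.null(library)) colnames(tpm) else library
  out <- stats::setNames(numeric(length(libs)), libs)
  for (lb in libs) {
    cmax <- max(tpm[cand, lb])
    out[lb] <- mean(tpm[ann, lb] > cmax)
  }
  out
}
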