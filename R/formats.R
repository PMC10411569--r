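# Readers/writers for every external format the pipeline touches, and the
# coordinate conventions. Annotations and loci are held 1-based closed
# (IRanges convention); BED output is 0-based half-open, converted on write.

FEATURE_CLASSES <- c("gene", "exon", "CDS", "intron", "3UTR", "5UTR", "miRNA",
                     "miscRNA", "ncRNA", "pseudogene", "transposon", "tRNA",
                     "intergenic")

#' Read a FASTA file
#'
#' Record names are the token before the first whitespace; sequences are
#' uppercased and validated against the A/C/G/T/N alphabet.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_fmt("FASTA file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop_fmt("FASTA format error: empty file %s", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop_fmt("FASTA format error in %s: no header on first line", path)
  grp <- cumsum(hdr)
  names_full <- sub("^>", "", lines[hdr])
  nm <- vapply(strsplit(names_full, "\\s+"), `[`, "", 1)
  body <- split(lines[!hdr], factor(grp[!hdr], levels = seq_along(nm)))
  seqs <- vapply(body, function(x) toupper(paste(x, collapse = "")), "")
  if (any(!nzchar(seqs)))
    stop_fmt("FASTA format error in %s: empty record(s): %s", path,
             paste(nm[!nzchar(seqs)], collapse = ", "))
  names(seqs) <- nm
  dup <- unique(nm[duplicated(nm)])
  if (length(dup))
    stop_fmt("FASTA format error in %s: duplicate record name(s): %s",
             path, paste(dup, collapse = ", "))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop_fmt("FASTA format error in %s: illegal characters in record(s): %s",
             path, paste(nm[bad], collapse = ", "))
  seqs
}

#' Write sequences as FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @param width Line width for wrapping. Default 70.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", names(sequences)[i]), con)
    s <- sequences[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a GTF-style annotation
#'
#' Accepts the 9-column GTF subset: seqname, source, feature, start, end,
#' score, strand, frame, attributes (with `gene_id` and optionally
#' `transcript_id`). Coordinates are 1-based closed and kept that way.
#'
#' @param path Path to a GTF file.
#' @return data.frame of class `annotation` with columns chrom, start, end,
#'   strand, feature_class, gene_id, transcript_id.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop_fmt("annotation file not found: %s", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^#", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop_fmt("annotation format error: no feature lines in %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop_fmt("annotation format error in %s, line %d: expected 9 tab-separated columns",
             path, lineno[which(nf != 9L)[1]])
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  bad <- is.na(start) | is.na(end)
  if (any(bad))
    stop_fmt("annotation format error in %s, line %d: non-integer coordinates",
             path, lineno[which(bad)[1]])
  bad <- end < start | start < 1L
  if (any(bad))
    stop_fmt("annotation format error in %s, line %d: end < start or start < 1",
             path, lineno[which(bad)[1]])
  bad <- !(m[, 7] %in% c("+", "-"))
  if (any(bad))
    stop_fmt("annotation format error in %s, line %d: unknown strand '%s'",
             path, lineno[which(bad)[1]], m[which(bad)[1], 7])
  bad <- !(m[, 3] %in% FEATURE_CLASSES)
  if (any(bad))
    stop_fmt("annotation format error in %s, line %d: unknown feature class '%s'",
             path, lineno[which(bad)[1]], m[which(bad)[1], 3])
  attr_field <- m[, 9]
  get_attr <- function(key) {
    val <- rep(NA_character_, length(attr_field))
    pat <- paste0(key, "[ =]+\"?([^\";]+)\"?")
    hit <- regexpr(pat, attr_field)
    ok <- hit > 0
    val[ok] <- sub(pat, "\\1",
                   regmatches(attr_field, hit))
    val
  }
  gene_id <- get_attr("gene_id")
  if (anyNA(gene_id))
    stop_fmt("annotation format error in %s, line %d: missing gene_id",
             path, lineno[which(is.na(gene_id))[1]])
  ann <- data.frame(chrom = m[, 1], start = start, end = end, strand = m[, 7],
                    feature_class = m[, 3], gene_id = gene_id,
                    transcript_id = get_attr("transcript_id"),
                    stringsAsFactors = FALSE)
  class(ann) <- c("annotation", "data.frame")
  ann
}

#' Write an annotation as GTF
#'
#' @param ann `annotation` data.frame.
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @export
write_annotation <- function(ann, path, source = "denovoscan") {
  attrs <- ifelse(is.na(ann$transcript_id),
                  sprintf("gene_id \"%s\";", ann$gene_id),
                  sprintf("gene_id \"%s\"; transcript_id \"%s\";",
                          ann$gene_id, ann$transcript_id))
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s", ann$chrom, source,
                   ann$feature_class, ann$start, ann$end, ann$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}

as_annotation <- function(df) {
  if (!"transcript_id" %in% names(df)) df$transcript_id <- NA_character_
  df <- df[c("chrom", "start", "end", "strand", "feature_class", "gene_id",
             "transcript_id")]
  class(df) <- c("annotation", "data.frame")
  df
}

# GRanges view of a feature-class subset
annotation_granges <- function(ann, classes = NULL) {
  sub <- if (is.null(classes)) ann else ann[ann$feature_class %in% classes, ]
  GenomicRanges::GRanges(sub$chrom,
                         IRanges::IRanges(sub$start, sub$end),
                         strand = sub$strand,
                         gene_id = sub$gene_id,
                         transcript_id = sub$transcript_id)
}

#' Derive intron features from exon annotations
#'
#' Introns are the gaps between consecutive exons of each transcript; useful
#' when the source annotation carries no explicit intron records.
#'
#' @param ann `annotation` data.frame containing exon features.
#' @return `annotation` data.frame of intron features (possibly empty).
#' @export
derive_introns <- function(ann) {
  ex <- ann[ann$feature_class == "exon" & !is.na(ann$transcript_id), ]
  out <- list()
  for (tx in unique(ex$transcript_id)) {
    e <- ex[ex$transcript_id == tx, ]
    e <- e[order(e$start), ]
    if (nrow(e) < 2L) next
    istart <- e$end[-nrow(e)] + 1L
    iend <- e$start[-1L] - 1L
    ok <- iend >= istart
    if (!any(ok)) next
    out[[tx]] <- data.frame(chrom = e$chrom[1], start = istart[ok],
                            end = iend[ok], strand = e$strand[1],
                            feature_class = "intron", gene_id = e$gene_id[1],
                            transcript_id = tx, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(as_annotation(data.frame(chrom = character(0), start = integer(0),
                                    end = integer(0), strand = character(0),
                                    feature_class = character(0),
                                    gene_id = character(0),
                                    stringsAsFactors = FALSE)))
  as_annotation(do.call(rbind, out))
}

#' Read a transcript-by-library expression table
#'
#' TSV with a header row of library names and transcript IDs in the first
#' column. Blank cells become 0; negative or non-numeric cells are errors.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix, rows = transcripts, columns = libraries.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop_fmt("expression table %s has no library columns", path)
  ids <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  mat[mat == "" | is.na(mat)] <- "0"
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = list(ids, colnames(df)[-1])))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop_fmt("expression table %s: non-numeric value for transcript '%s', library '%s'",
             path, ids[bad[1]], colnames(num)[bad[2]])
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1, ]
    stop_fmt("expression table %s: negative value for transcript '%s', library '%s'",
             path, ids[bad[1]], colnames(num)[bad[2]])
  }
  num
}

#' Write an expression matrix as TSV
#' @param mat Numeric matrix (rows transcripts, columns libraries).
#' @param path Output path.
#' @export
write_expression_table <- function(mat, path) {
  df <- data.frame(transcript_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ortholog table
#'
#' TSV with columns focal_gene_id, outgroup_species, ortholog_gene_id and
#' optionally chrom, start, end (the ortholog locus in outgroup coordinates).
#'
#' @param path Path to the TSV.
#' @return data.frame; (focal_gene_id, outgroup_species) pairs are unique.
#' @export
read_ortholog_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("focal_gene_id", "outgroup_species", "ortholog_gene_id")
  if (!all(need %in% names(df)))
    stop_fmt("ortholog table %s must have columns: %s", path,
             paste(need, collapse = ", "))
  key <- paste(df$focal_gene_id, df$outgroup_species)
  if (anyDuplicated(key))
    stop_fmt("ortholog table %s: duplicate (focal_gene_id, outgroup_species) pair: %s",
             path, key[duplicated(key)][1])
  df
}

#' Write candidate outputs (BED, FASTA, merged GTF, report TSV)
#'
#' @param candidates A `candidate_set` (see [run_screen()]), optionally
#'   carrying expression summaries, synteny tiers and ORF lengths.
#' @param out_dir Output directory (created if needed).
#' @param reference_annotation Optional `annotation` to merge candidate
#'   features into.
#' @param prefix File name prefix. Default "candidates".
#' @return Named character vector of the paths written.
#' @export
write_candidate_outputs <- function(candidates, out_dir,
                                    reference_annotation = NULL,
                                    prefix = "candidates") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(bed = file.path(out_dir, paste0(prefix, ".bed")),
             fasta = file.path(out_dir, paste0(prefix, ".fa")),
             gtf = file.path(out_dir, paste0(prefix, "_merged.gtf")),
             report = file.path(out_dir, paste0(prefix, "_report.tsv")))

  # BED: 0-based half-open (start - 1, end); unknown strand written "+"
  bed_lines <- character(0)
  fasta <- character(0)
  cand_feats <- list()
  rows <- list()
  for (cd in candidates) {
    strand <- if (is.na(cd$strand)) "+" else cd$strand
    bed_lines <- c(bed_lines, sprintf("%s\t%d\t%d\t%s\t0\t%s", cd$chrom,
                                      cd$start - 1L, cd$end, cd$candidate_id,
                                      strand))
    fasta <- c(fasta, cd$sequences)
    gene_row <- data.frame(chrom = cd$chrom, start = cd$start, end = cd$end,
                           strand = strand, feature_class = "gene",
                           gene_id = cd$candidate_id,
                           transcript_id = NA_character_,
                           stringsAsFactors = FALSE)
    iso_rows <- do.call(rbind, lapply(cd$isoforms, function(tx) {
      data.frame(chrom = cd$chrom, start = cd$start, end = cd$end,
                 strand = strand, feature_class = rep(c("exon"), 1),
                 gene_id = cd$candidate_id, transcript_id = tx,
                 stringsAsFactors = FALSE)
    }))
    cand_feats[[cd$candidate_id]] <- rbind(gene_row, iso_rows)
    rows[[cd$candidate_id]] <- data.frame(
      candidate_id = cd$candidate_id,
      n_isoforms = length(cd$isoforms),
      locus = sprintf("%s:%d-%d(%s)%s", cd$chrom, cd$start, cd$end, strand,
                      if (is.na(cd$strand)) "*" else ""),
      n_libraries_expressed = cd$n_libraries_expressed %||% NA_integer_,
      max_TPM = cd$max_tpm %||% NA_real_,
      synteny_tier = cd$synteny_tier %||% NA_character_,
      longest_ORF_nt = cd$longest_orf_nt %||% NA_integer_,
      stringsAsFactors = FALSE)
  }
  writeLines(bed_lines, paths["bed"])
  write_fasta(fasta, paths["fasta"])
  merged <- do.call(rbind, c(list(if (!is.null(reference_annotation))
    as.data.frame(reference_annotation)), unname(cand_feats)))
  if (is.null(merged))
    merged <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), strand = character(0),
                         feature_class = character(0), gene_id = character(0),
                         transcript_id = character(0), stringsAsFactors = FALSE)
  write_annotation(as_annotation(merged), paths["gtf"])
  report <- if (length(rows)) do.call(rbind, unname(rows)) else
    data.frame(candidate_id = character(0), n_isoforms = integer(0),
               locus = character(0), n_libraries_expressed = integer(0),
               max_TPM = numeric(0), synteny_tier = character(0),
               longest_ORF_nt = integer(0), stringsAsFactors = FALSE)
  utils::write.table(report, paths["report"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
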