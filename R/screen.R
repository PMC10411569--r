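# The filter cascade: assembled transcripts -> candidate de novo genes.
# Stages, applied in fixed order with a conserved audit trail (FilterTrace):
#   1. annotation_screen      (match vs any annotation-class DB, any species)
#   2. outgroup_transcript_screen (match vs any outgroup transcript DB)
#   3. place_on_genome        (qualifying placement on the focal genome)
#   4. structural_filter      (length > 300, exon distance > 250, intergenic)
#   5. expression_filter      (group level: TPM >= 1 in >= 1 library for at
#                              least one structurally valid isoform; all
#                              surviving isoforms of a passing group retained)

#' Pipeline configuration
#'
#' All thresholds used by the cascade. Defaults implement the screening
#' criteria: matches count at 80% identity over >= 100 alignment columns;
#' candidates must be > 300 bp, > 250 bp from the nearest annotated exon,
#' intergenic, and expressed at TPM >= 1 in at least one library.
#'
#' @param min_identity,min_match_len Match criterion (see [match_criterion()]).
#' @param min_transcript_len Minimum transcript length, strict. Default 300.
#' @param min_exon_distance Minimum distance to the nearest exon, strict.
#'   Default 250.
#' @param tpm_threshold Expression threshold, inclusive. Default 1.
#' @param synteny_flank Flank added around a candidate locus when building
#'   the microsynteny query region (bp). Default 5000.
#' @param orf_min_len Minimum ORF length in nt for [find_orfs()]. Default 75
#'   (the common coding-potential tool default); 30 is a frequently used
#'   permissive alternative.
#' @param kmer Seed length for homology search.
#' @param band Band half-width for gapped extension.
#' @param strict_ids Error on unparseable transcript IDs instead of treating
#'   them as singleton groups.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_identity = 0.80, min_match_len = 100L,
                            min_transcript_len = 300L,
                            min_exon_distance = 250L, tpm_threshold = 1.0,
                            synteny_flank = 5000L, orf_min_len = 75L,
                            kmer = 11L, band = 10L, strict_ids = FALSE) {
  vals <- c(min_identity, min_match_len, min_transcript_len,
            min_exon_distance, tpm_threshold, synteny_flank, orf_min_len)
  if (any(vals <= 0)) stop_fmt("all pipeline thresholds must be positive")
  structure(list(match_criterion = match_criterion(min_identity, min_match_len),
                 min_transcript_len = as.integer(min_transcript_len),
                 min_exon_distance = as.integer(min_exon_distance),
                 tpm_threshold = tpm_threshold,
                 synteny_flank = as.integer(synteny_flank),
                 orf_min_len = as.integer(orf_min_len), kmer = as.integer(kmer),
                 band = as.integer(band), strict_ids = strict_ids),
            class = "pipeline_config")
}

#' Parse a Trinity-style transcript ID into gene group and isoform
#'
#' `TRINITY_DN<k>_c<x>_g<j>_i<m>` parses to gene group
#' `TRINITY_DN<k>_c<x>_g<j>` and isoform `m`; a missing isoform suffix
#' defaults to 1.
#'
#' @param id Character vector of transcript IDs.
#' @param strict Error on unparseable IDs; otherwise each becomes its own
#'   singleton group with a warning.
#' @return data.frame(transcript_id, gene_group, isoform).
#' @export
parse_trinity_id <- function(id, strict = FALSE) {
  pat <- "^(TRINITY_DN[0-9]+_c[0-9]+_g[0-9]+)(_i([0-9]+))?$"
  ok <- grepl(pat, id)
  if (any(!ok)) {
    if (strict)
      stop_fmt("unparseable transcript id(s): %s",
               paste(id[!ok], collapse = ", "))
    warning(sprintf("treating unparseable id(s) as singleton groups: %s",
                    paste(id[!ok], collapse = ", ")), call. = FALSE)
  }
  group <- ifelse(ok, sub(pat, "\\1", id), id)
  iso <- rep(1L, length(id))
  has_iso <- ok & grepl("_i[0-9]+$", id)
  iso[has_iso] <- as.integer(sub(pat, "\\3", id[has_iso]))
  data.frame(transcript_id = id, gene_group = group, isoform = iso,
             stringsAsFactors = FALSE)
}

# flatten per-species per-class databases into one index; subject ids are
# "species::class::name" so evidence can be recovered from the best match
build_annotation_db_index <- function(annotation_dbs, k) {
  seqs <- character(0)
  for (sp in names(annotation_dbs))
    for (cl in names(annotation_dbs[[sp]])) {
      s <- annotation_dbs[[sp]][[cl]]
      if (!length(s)) next
      names(s) <- paste(sp, cl, names(s), sep = "::")
      seqs <- c(seqs, s)
    }
  if (!length(seqs))
    stop_fmt("configuration error: empty annotation database set")
  build_kmer_index(seqs[nchar(seqs) >= k], k)
}

build_outgroup_db_index <- function(outgroup_tx_dbs, k) {
  seqs <- character(0)
  for (sp in names(outgroup_tx_dbs)) {
    s <- outgroup_tx_dbs[[sp]]
    if (!length(s)) next
    names(s) <- paste(sp, names(s), sep = "::")
    seqs <- c(seqs, s)
  }
  if (!length(seqs))
    stop_fmt("configuration error: empty outgroup transcript database set")
  build_kmer_index(seqs[nchar(seqs) >= k], k)
}

#' Prebuild the search indexes used by [run_screen()]
#'
#' @param databases list(annotation_dbs = species -> class -> sequences,
#'   outgroup_tx_dbs = species -> sequences).
#' @param focal_genome Named character vector of chromosome sequences.
#' @param config A [pipeline_config()].
#' @return list of `seq_index` objects.
#' @export
build_screen_indexes <- function(databases, focal_genome, config = pipeline_config()) {
  list(annotation = build_annotation_db_index(databases$annotation_dbs, config$kmer),
       outgroup = build_outgroup_db_index(databases$outgroup_tx_dbs, config$kmer),
       genome = build_kmer_index(focal_genome, config$kmer))
}

#' Screen transcripts against annotation-class databases
#'
#' A transcript is removed iff it has a qualifying match against any
#' annotation class of any species. Evidence records species, class and the
#' matched subject.
#'
#' @param transcripts Named character vector.
#' @param annotation_dbs Per-species per-class sequence sets.
#' @param criterion A [match_criterion()].
#' @param index Optional prebuilt index (from [build_screen_indexes()]).
#' @return list(survivors = named character, removed = data.frame with
#'   evidence).
#' @export
annotation_screen <- function(transcripts, annotation_dbs,
                              criterion = match_criterion(), index = NULL) {
  if (is.null(index)) index <- build_annotation_db_index(annotation_dbs, 11L)
  screen_against(transcripts, index, criterion, split_levels = 3L)
}

#' Screen transcripts against outgroup transcript databases
#'
#' @inheritParams annotation_screen
#' @param outgroup_tx_dbs Per-species transcript sequence sets.
#' @return list(survivors, removed) as in [annotation_screen()].
#' @export
outgroup_transcript_screen <- function(transcripts, outgroup_tx_dbs,
                                       criterion = match_criterion(),
                                       index = NULL) {
  if (is.null(index)) index <- build_outgroup_db_index(outgroup_tx_dbs, 11L)
  screen_against(transcripts, index, criterion, split_levels = 2L)
}

screen_against <- function(transcripts, index, criterion, split_levels) {
  removed <- list()
  keep <- logical(length(transcripts))
  for (i in seq_along(transcripts)) {
    hm <- has_match(transcripts[[i]], index, criterion, stop_at_first = TRUE)
    if (hm$matched) {
      parts <- strsplit(hm$match$subject_id, "::", fixed = TRUE)[[1]]
      removed[[length(removed) + 1L]] <- data.frame(
        transcript_id = names(transcripts)[i],
        species = parts[1],
        db_class = if (split_levels == 3L) parts[2] else "transcript",
        subject = parts[length(parts)],
        identity = hm$match$identity, aligned_len = hm$match$aligned_len,
        stringsAsFactors = FALSE)
    } else keep[i] <- TRUE
  }
  list(survivors = transcripts[keep],
       removed = if (length(removed)) do.call(rbind, removed) else
         data.frame(transcript_id = character(0), species = character(0),
                    db_class = character(0), subject = character(0),
                    identity = numeric(0), aligned_len = integer(0),
                    stringsAsFactors = FALSE))
}

#' Place a transcript on the focal genome
#'
#' The locus is the subject span of the highest-scoring qualifying match,
#' merged with co-linear qualifying matches on the same chromosome and
#' strand within 1 kb (multi-exon placement). Chimeric placements (other
#' chromosomes/strands) keep only the best segment and are flagged.
#'
#' @param transcript Character scalar.
#' @param genome_index `seq_index` over the focal genome.
#' @param criterion A [match_criterion()].
#' @param band Extension band half-width.
#' @return list(chrom, start, end, strand, placement_identity, n_segments,
#'   chimeric) or NULL if unplaced.
#' @export
place_on_genome <- function(transcript, genome_index,
                            criterion = match_criterion(), band = 10L) {
  m <- search_matches(transcript, genome_index, band = band)
  qual <- m[m$identity >= criterion$min_identity &
              m$aligned_len >= criterion$min_len, , drop = FALSE]
  if (!nrow(qual)) return(NULL)
  o <- order(-qual$score, -qual$identity, qual$subject_id, qual$s_start)
  qual <- qual[o, , drop = FALSE]
  best <- qual[1, ]
  same <- qual[qual$subject_id == best$subject_id &
                 qual$strand == best$strand, , drop = FALSE]
  # co-linear merge within 1 kb of the growing locus
  same <- same[order(same$s_start), ]
  sel <- which(same$score == best$score & same$s_start == best$s_start)[1]
  lo <- same$s_start[sel]; hi <- same$s_end[sel]
  merged <- sel
  repeat {
    grow <- FALSE
    for (r in seq_len(nrow(same))) {
      if (r %in% merged) next
      gap_lo <- same$s_start[r] - hi - 1L
      gap_hi <- lo - same$s_end[r] - 1L
      if ((gap_lo >= -50L && gap_lo <= 1000L) ||
          (gap_hi >= -50L && gap_hi <= 1000L)) {
        lo <- min(lo, same$s_start[r]); hi <- max(hi, same$s_end[r])
        merged <- c(merged, r); grow <- TRUE
      }
    }
    if (!grow) break
  }
  list(chrom = best$subject_id, start = lo, end = hi, strand = best$strand,
       placement_identity = best$identity, n_segments = length(merged),
       chimeric = nrow(qual) > nrow(same))
}

#' Distance from a locus to the nearest annotated exon
#'
#' 0 if the locus overlaps any exon; otherwise the gap in bp to the nearest
#' exon of any gene on either strand (adjacent intervals have distance 0).
#' With no exons annotated, +Inf.
#'
#' @param locus list(chrom, start, end) in 1-based closed coordinates.
#' @param annotation `annotation` data.frame.
#' @return Numeric distance in bp.
#' @export
exon_distance <- function(locus, annotation) {
  ex <- annotation[annotation$feature_class == "exon", ]
  if (!nrow(ex)) return(Inf)
  gr <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start, ex$end))
  q <- GenomicRanges::GRanges(locus$chrom,
                              IRanges::IRanges(locus$start, locus$end))
  d <- GenomicRanges::distance(q, gr, ignore.strand = TRUE)
  d <- d[!is.na(d)]
  if (!length(d)) return(Inf)
  min(d)
}

#' Genomic context of a locus: intergenic, intronic, or genic overlap
#'
#' `genic_overlap` if the locus overlaps any exon; `intronic` if at least
#' half of the locus lies within an annotated gene span without touching its
#' exons; otherwise `intergenic`.
#'
#' @inheritParams exon_distance
#' @return One of "genic_overlap", "intronic", "intergenic".
#' @export
genic_context <- function(locus, annotation) {
  q <- GenomicRanges::GRanges(locus$chrom,
                              IRanges::IRanges(locus$start, locus$end))
  ex <- annotation[annotation$feature_class == "exon", ]
  if (nrow(ex)) {
    egr <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start, ex$end))
    if (length(GenomicRanges::findOverlaps(q, egr, ignore.strand = TRUE)))
      return("genic_overlap")
  }
  gn <- annotation[annotation$feature_class == "gene", ]
  if (nrow(gn)) {
    ggr <- GenomicRanges::GRanges(gn$chrom, IRanges::IRanges(gn$start, gn$end))
    hits <- GenomicRanges::findOverlaps(q, ggr, ignore.strand = TRUE)
    if (length(hits)) {
      ov <- GenomicRanges::pintersect(rep(q, length(hits)),
                                      ggr[S4Vectors::subjectHits(hits)])
      frac <- max(GenomicRanges::width(ov)) / (locus$end - locus$start + 1)
      if (frac >= 0.5) return("intronic")
    }
  }
  "intergenic"
}

#' Structural filter: length, exon distance, genomic context
#'
#' Pass iff transcript length > `min_transcript_len` AND exon distance >
#' `min_exon_distance` AND the locus is intergenic. The first violated rule
#' (in that order) is reported.
#'
#' @param transcript Character scalar.
#' @param locus As returned by [place_on_genome()].
#' @param annotation `annotation` data.frame.
#' @param config A [pipeline_config()].
#' @return list(pass = logical, reason = "short"/"near_exon"/
#'   "not_intergenic" or NA).
#' @export
structural_filter <- function(transcript, locus, annotation,
                              config = pipeline_config()) {
  if (nchar(transcript) <= config$min_transcript_len)
    return(list(pass = FALSE, reason = "short"))
  if (exon_distance(locus, annotation) <= config$min_exon_distance)
    return(list(pass = FALSE, reason = "near_exon"))
  if (genic_context(locus, annotation) != "intergenic")
    return(list(pass = FALSE, reason = "not_intergenic"))
  list(pass = TRUE, reason = NA_character_)
}

#' Group-level expression filter with the isoform-rescue rule
#'
#' A gene group passes iff at least one isoform satisfies all criteria
#' (structural pass and TPM >= threshold in >= 1 library); a passing group
#' retains all of its isoforms.
#'
#' @param isoform_ids Transcript IDs of the group's isoforms.
#' @param structural_pass Named logical: structural result per isoform.
#' @param tpm Numeric matrix (transcripts x libraries); absent rows count 0.
#' @param config A [pipeline_config()].
#' @return list(pass, passing_isoforms).
#' @export
expression_filter <- function(isoform_ids, structural_pass, tpm,
                              config = pipeline_config()) {
  max_tpm <- vapply(isoform_ids, function(id)
    if (id %in% rownames(tpm)) max(tpm[id, ]) else 0, 0)
  full_pass <- structural_pass[isoform_ids] & max_tpm >= config$tpm_threshold
  list(pass = any(full_pass), passing_isoforms = isoform_ids[full_pass])
}

#' Run the full screening cascade
#'
#' Applies, in order: annotation screen, outgroup transcript screen, genome
#' placement, structural filter, group-level expression filter. Returns the
#' candidate set and a FilterTrace assigning every input transcript exactly
#' one terminal stage.
#'
#' @param transcripts Named character vector (Trinity-style IDs).
#' @param databases list(annotation_dbs, outgroup_tx_dbs).
#' @param annotation Focal `annotation` data.frame.
#' @param tpm Numeric TPM matrix.
#' @param focal_genome Named character vector (ignored if `indexes` given).
#' @param config A [pipeline_config()].
#' @param indexes Optional prebuilt [build_screen_indexes()] output.
#' @return list(candidates = `candidate_set`, trace = data.frame
#'   (transcript_id, stage, evidence)).
#' @export
run_screen <- function(transcripts, databases, annotation, tpm,
                       focal_genome = NULL, config = pipeline_config(),
                       indexes = NULL) {
  if (is.null(indexes)) {
    if (is.null(focal_genome))
      stop_fmt("configuration error in placement stage: focal_genome or indexes required")
    indexes <- build_screen_indexes(databases, focal_genome, config)
  }
  ids <- names(transcripts)
  if (is.null(ids) || any(!nzchar(ids)))
    stop_fmt("configuration error: transcripts must be named")
  stage <- stats::setNames(rep(NA_character_, length(ids)), ids)
  evidence <- stats::setNames(rep("", length(ids)), ids)
  crit <- config$match_criterion

  s1 <- screen_against(transcripts, indexes$annotation, crit, split_levels = 3L)
  for (r in seq_len(nrow(s1$removed))) {
    x <- s1$removed[r, ]
    stage[x$transcript_id] <- "annotation_match"
    evidence[x$transcript_id] <- sprintf("%s %s %s (%.1f%% / %d cols)",
                                         x$species, x$db_class, x$subject,
                                         100 * x$identity, x$aligned_len)
  }
  s2 <- screen_against(s1$survivors, indexes$outgroup, crit, split_levels = 2L)
  for (r in seq_len(nrow(s2$removed))) {
    x <- s2$removed[r, ]
    stage[x$transcript_id] <- "outgroup_transcript_match"
    evidence[x$transcript_id] <- sprintf("%s %s (%.1f%% / %d cols)", x$species,
                                         x$subject, 100 * x$identity,
                                         x$aligned_len)
  }

  loci <- list()
  for (id in names(s2$survivors)) {
    loc <- place_on_genome(s2$survivors[[id]], indexes$genome, crit,
                           config$band)
    if (is.null(loc)) {
      stage[id] <- "unplaced"
      evidence[id] <- "no qualifying placement on focal genome"
    } else {
      loci[[id]] <- loc
      if (loc$chimeric) evidence[id] <- "chimeric placement; best segment kept"
    }
  }

  placed <- names(loci)
  struct <- list()
  for (id in placed)
    struct[[id]] <- structural_filter(s2$survivors[[id]], loci[[id]],
                                      annotation, config)
  struct_pass <- vapply(struct, `[[`, TRUE, "pass")

  groups <- parse_trinity_id(placed, strict = config$strict_ids)
  candidates <- list()
  for (g in unique(groups$gene_group)) {
    iso <- groups$transcript_id[groups$gene_group == g]
    ef <- expression_filter(iso, struct_pass, tpm, config)
    if (ef$pass) {
      stage[iso] <- "candidate"
      lead <- ef$passing_isoforms[1]
      chroms <- vapply(iso, function(id) loci[[id]]$chrom, "")
      same <- iso[chroms == loci[[lead]]$chrom]
      cand <- list(candidate_id = g, gene_group = g, isoforms = iso,
                   sequences = s2$survivors[iso],
                   chrom = loci[[lead]]$chrom,
                   start = min(vapply(same, function(id) loci[[id]]$start, 0)),
                   end = max(vapply(same, function(id) loci[[id]]$end, 0)),
                   strand = loci[[lead]]$strand,
                   placement_identity = loci[[lead]]$placement_identity,
                   isoform_loci = loci[iso])
      candidates[[g]] <- cand
    } else {
      for (id in iso) {
        if (struct[[id]]$pass) {
          stage[id] <- "low_expression"
          evidence[id] <- sprintf("max TPM < %g in all libraries",
                                  config$tpm_threshold)
        } else {
          stage[id] <- struct[[id]]$reason
        }
      }
    }
  }
  if (anyNA(stage)) stop_fmt("internal error: transcripts without a terminal stage")
  trace <- data.frame(transcript_id = ids, stage = unname(stage[ids]),
                      evidence = unname(evidence[ids]),
                      stringsAsFactors = FALSE)
  structure(list(candidates = structure(candidates, class = "candidate_set"),
                 trace = trace, config = config), class = "screen_result")
}
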