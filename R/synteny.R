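# Microsynteny validation. For each candidate locus: find the annotated
# genes immediately upstream and downstream, look up their orthologs in each
# outgroup, and ask whether the candidate's flank window (locus +/- 5 kb)
# has a qualifying homologous segment on the outgroup scaffold spanned by
# the ortholog loci (extended 50 kb each side). Candidates are tiered, never
# removed, by this validation.

#' Annotated genes immediately flanking a locus
#'
#' Upstream = the nearest gene whose span ends before the locus start;
#' downstream = the nearest whose span starts after the locus end. Same
#' chromosome, either strand; ties broken by lower gene_id.
#'
#' @param locus list(chrom, start, end), 1-based closed.
#' @param annotation `annotation` data.frame.
#' @return list(upstream = gene_id or NA, downstream = gene_id or NA).
#' @export
flanking_genes <- function(locus, annotation) {
  gn <- annotation[annotation$feature_class == "gene" &
                     annotation$chrom == locus$chrom, ]
  up <- gn[gn$end < locus$start, ]
  dn <- gn[gn$start > locus$end, ]
  pick <- function(df, dist) {
    if (!nrow(df)) return(NA_character_)
    o <- order(dist, df$gene_id)
    df$gene_id[o[1]]
  }
  list(upstream = pick(up, locus$start - up$end),
       downstream = pick(dn, dn$start - locus$end))
}

#' Extract the flank-window query region around a locus
#'
#' The sequence spanning [start - flank, end + flank], clipped at chromosome
#' boundaries (clipping flagged).
#'
#' @param focal_genome Named character vector of chromosomes.
#' @param locus list(chrom, start, end).
#' @param flank Flank size in bp. Default 5000.
#' @return list(sequence, chrom, start, end, clipped).
#' @export
build_query_region <- function(focal_genome, locus, flank = 5000L) {
  L <- nchar(focal_genome[[locus$chrom]])
  s <- locus$start - flank
  e <- locus$end + flank
  clipped <- s < 1L || e > L
  s <- max(1L, s); e <- min(L, e)
  list(sequence = substring(focal_genome[[locus$chrom]], s, e),
       chrom = locus$chrom, start = s, end = e, clipped = clipped)
}

#' Locate outgroup loci of the orthologs of focal genes
#'
#' @param genes Character vector of focal gene ids (NAs allowed).
#' @param ortholog_table data.frame from [read_ortholog_table()] (with
#'   chrom/start/end locus columns).
#' @param species Outgroup species name.
#' @return Named list per gene: list(chrom, start, end, ortholog_gene_id) or
#'   NULL with attribute "reason" when absent.
#' @export
locate_orthologs <- function(genes, ortholog_table, species) {
  if (!species %in% ortholog_table$outgroup_species)
    stop_fmt("configuration error: species '%s' not in the ortholog table",
             species)
  sub <- ortholog_table[ortholog_table$outgroup_species == species, ]
  out <- list()
  for (g in genes) {
    if (is.na(g)) next
    row <- sub[sub$focal_gene_id == g, ]
    if (!nrow(row) || is.null(row$chrom) || is.na(row$chrom[1])) {
      out[g] <- list(NULL)  # absent marker, name preserved
      next
    }
    out[[g]] <- list(chrom = row$chrom[1], start = row$start[1],
                     end = row$end[1], ortholog_gene_id = row$ortholog_gene_id[1])
  }
  out
}

#' Validate microsynteny of one candidate in one outgroup
#'
#' Validated iff (a) the located flank-ortholog loci lie on one outgroup
#' scaffold (a single located flank defines it), and (b) the flank-window
#' query region has a qualifying homologous segment on that scaffold within
#' the interval spanned by the ortholog loci extended by `window_ext` on
#' each side. The match may hit flank sequence only: the check certifies
#' region orthology, not transcript presence.
#'
#' @param query_region From [build_query_region()].
#' @param ortholog_loci List of located loci (from [locate_orthologs()]),
#'   NULLs dropped.
#' @param outgroup_genome Named character vector of outgroup scaffolds.
#' @param criterion A [match_criterion()].
#' @param window_ext Extension of the ortholog interval, bp. Default 50000.
#' @param kmer,band Homology search parameters.
#' @return list(validated, reason, match = data.frame or NULL).
#' @export
validate_microsynteny <- function(query_region, ortholog_loci, outgroup_genome,
                                  criterion = match_criterion(),
                                  window_ext = 50000L, kmer = 11L, band = 10L) {
  loci <- Filter(Negate(is.null), ortholog_loci)
  if (!length(loci))
    return(list(validated = FALSE, reason = "no_flank_orthologs", match = NULL))
  scaffolds <- unique(vapply(loci, `[[`, "", "chrom"))
  if (length(scaffolds) > 1L)
    return(list(validated = FALSE, reason = "split_flanks", match = NULL))
  sc <- scaffolds[1]
  if (!sc %in% names(outgroup_genome))
    return(list(validated = FALSE, reason = "scaffold_missing", match = NULL))
  span <- range(unlist(lapply(loci, function(x) c(x$start, x$end))))
  L <- nchar(outgroup_genome[[sc]])
  ws <- max(1L, span[1] - window_ext)
  we <- min(L, span[2] + window_ext)
  window <- substring(outgroup_genome[[sc]], ws, we)
  if (nchar(window) < kmer)
    return(list(validated = FALSE, reason = "window_too_small", match = NULL))
  idx <- build_kmer_index(stats::setNames(window, sc), kmer)
  hm <- has_match(query_region$sequence, idx, criterion, band = band,
                  stop_at_first = TRUE)
  if (!hm$matched)
    return(list(validated = FALSE, reason = "no_region_match", match = NULL))
  m <- hm$match
  m$s_start <- m$s_start + ws - 1L
  m$s_end <- m$s_end + ws - 1L
  list(validated = TRUE, reason = NA_character_, match = m)
}

#' Tier candidates by per-species microsynteny validation
#'
#' Candidates are never removed here: tier is `both_outgroups`,
#' `one_outgroup`, or `none`.
#'
#' @param flags Logical matrix or data.frame, rows candidates, one column per
#'   outgroup species.
#' @return Character vector of tiers, named by candidate.
#' @export
tier_candidates <- function(flags) {
  flags <- as.matrix(flags)
  n_ok <- rowSums(flags)
  tiers <- ifelse(n_ok == ncol(flags), "both_outgroups",
                  ifelse(n_ok >= 1, "one_outgroup", "none"))
  stats::setNames(tiers, rownames(flags))
}

#' Run microsynteny validation for a candidate set
#'
#' @param candidates A `candidate_set` from [run_screen()].
#' @param annotation Focal `annotation` data.frame.
#' @param focal_genome Named character vector.
#' @param ortholog_table Ortholog table with outgroup loci.
#' @param outgroup_genomes Named list: species -> named character vector of
#'   scaffolds.
#' @param config A [pipeline_config()].
#' @return list(results = data.frame per candidate x species, tiers = named
#'   character vector).
#' @export
run_synteny <- function(candidates, annotation, focal_genome, ortholog_table,
                        outgroup_genomes, config = pipeline_config()) {
  rows <- list()
  flags <- matrix(FALSE, nrow = length(candidates),
                  ncol = length(outgroup_genomes),
                  dimnames = list(names(candidates), names(outgroup_genomes)))
  for (cd in candidates) {
    locus <- list(chrom = cd$chrom, start = cd$start, end = cd$end)
    fl <- flanking_genes(locus, annotation)
    region <- build_query_region(focal_genome, locus, config$synteny_flank)
    for (sp in names(outgroup_genomes)) {
      loci <- locate_orthologs(c(fl$upstream, fl$downstream), ortholog_table,
                               sp)
      v <- validate_microsynteny(region, loci, outgroup_genomes[[sp]],
                                 config$match_criterion,
                                 kmer = config$kmer, band = config$band)
      flags[cd$candidate_id, sp] <- v$validated
      rows[[length(rows) + 1L]] <- data.frame(
        candidate_id = cd$candidate_id, species = sp,
        upstream_gene = fl$upstream %||% NA_character_,
        downstream_gene = fl$downstream %||% NA_character_,
        n_flank_orthologs = length(Filter(Negate(is.null), loci)),
        validated = v$validated,
        reason = v$reason %||% NA_character_,
        match_start = if (!is.null(v$match)) v$match$s_start else NA_integer_,
        match_end = if (!is.null(v$match)) v$match$s_end else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(candidate_id = character(0), species = character(0),
               upstream_gene = character(0), downstream_gene = character(0),
               n_flank_orthologs = integer(0), validated = logical(0),
               reason = character(0), match_start = integer(0),
               match_end = integer(0), stringsAsFactors = FALSE)
  list(results = results, tiers = tier_candidates(flags))
}
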