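# Orchestration: simulate (or load) -> screen -> expression -> synteny ->
# orf -> report, as one reproducible call. All thresholds live in
# pipeline_config; the run manifest snapshots them together with stage
# counts so a run can be reproduced exactly.

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_fmt("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_fmt("config must be a list or a YAML file path")
  config
}

config_from_list <- function(cfg) {
  keys <- c("min_identity", "min_match_len", "min_transcript_len",
            "min_exon_distance", "tpm_threshold", "synteny_flank",
            "orf_min_len", "kmer", "band", "strict_ids")
  do.call(pipeline_config, cfg[intersect(names(cfg), keys)])
}

load_inputs <- function(cfg) {
  need <- c("focal_genome", "annotation", "transcripts", "counts",
            "orthologs", "outgroup_genomes", "annotation_dbs",
            "outgroup_tx_dbs")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop_fmt("configuration error: missing input key(s): %s",
             paste(missing, collapse = ", "))
  genome <- read_fasta(cfg$focal_genome)
  ann <- read_annotation(cfg$annotation)
  bad <- setdiff(unique(ann$chrom), names(genome))
  if (length(bad))
    stop_fmt("configuration error: annotation chromosome(s) absent from genome: %s",
             paste(bad, collapse = ", "))
  counts <- read_expression_table(cfg$counts)
  tx <- read_fasta(cfg$transcripts)
  list(focal_genome = genome, annotation = ann, transcripts = tx,
       counts = counts,
       tx_lengths = NULL,
       ortholog_table = read_ortholog_table(cfg$orthologs),
       outgroup_genomes = lapply(cfg$outgroup_genomes, read_fasta),
       databases = list(
         annotation_dbs = lapply(cfg$annotation_dbs,
                                 function(sp) lapply(sp, read_fasta)),
         outgroup_tx_dbs = lapply(cfg$outgroup_tx_dbs, read_fasta)))
}

#' Run the complete pipeline
#'
#' Either on a simulated dataset (config entry `sim_plan`: arguments for
#' [sim_plan()], or an existing plan/dataset) or on files named in the
#' config. Writes candidate BED/FASTA/merged GTF/report, the FilterTrace,
#' expression and synteny summaries, ORF outputs, and a run manifest.
#'
#' @param config A list or YAML file path. For self-contained runs supply
#'   `sim_plan`; otherwise input file paths (see vignette). Threshold keys
#'   (min_identity, min_match_len, min_transcript_len, min_exon_distance,
#'   tpm_threshold, synteny_flank, orf_min_len) override defaults.
#' @param out_dir Output directory.
#' @param dataset Optional prebuilt `synthetic_dataset` (overrides
#'   `sim_plan`).
#' @param indexes Optional prebuilt [build_screen_indexes()].
#' @param quiet Suppress stage log lines on stderr.
#' @return Invisibly, list(candidates, trace, expression, synteny, orfs,
#'   manifest, dataset, paths).
#' @export
run_all <- function(config = list(), out_dir = tempfile("denovoscan_run_"),
                    dataset = NULL, indexes = NULL, quiet = FALSE) {
  cfg <- load_config(config)
  pc <- config_from_list(cfg)
  log <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }

  if (is.null(dataset) && !is.null(cfg$sim_plan)) {
    plan <- if (inherits(cfg$sim_plan, "sim_plan")) cfg$sim_plan else
      do.call(sim_plan, cfg$sim_plan)
    log("simulate", "generating synthetic dataset (seed %d)", plan$seed)
    dataset <- simulate_dataset(plan)
  }
  if (!is.null(dataset)) {
    inputs <- list(focal_genome = dataset$focal_genome,
                   annotation = dataset$annotation,
                   transcripts = dataset$transcripts,
                   counts = dataset$counts,
                   tx_lengths = dataset$tx_lengths,
                   ortholog_table = dataset$ortholog_table,
                   outgroup_genomes = lapply(dataset$outgroups, `[[`, "genome"),
                   databases = dataset$databases)
  } else {
    inputs <- load_inputs(cfg)
  }
  if (is.null(inputs$tx_lengths)) {
    lens <- nchar(inputs$transcripts)
    # annotated rows of the counts table get spliced lengths from annotation
    ex <- inputs$annotation[inputs$annotation$feature_class == "exon" &
                              !is.na(inputs$annotation$transcript_id), ]
    ann_len <- tapply(ex$end - ex$start + 1L, ex$transcript_id, sum)
    inputs$tx_lengths <- c(lens, ann_len[setdiff(names(ann_len), names(lens))])
  }

  log("expression", "computing TPM for %d transcripts x %d libraries",
      nrow(inputs$counts), ncol(inputs$counts))
  known <- intersect(rownames(inputs$counts), names(inputs$tx_lengths))
  tpm <- compute_tpm(inputs$counts[known, , drop = FALSE], inputs$tx_lengths)

  log("screen", "screening %d transcripts", length(inputs$transcripts))
  if (is.null(indexes))
    indexes <- build_screen_indexes(inputs$databases, inputs$focal_genome, pc)
  sr <- run_screen(inputs$transcripts, inputs$databases, inputs$annotation,
                   tpm, config = pc, indexes = indexes)
  log("screen", "%d candidate gene group(s)", length(sr$candidates))

  log("synteny", "validating microsynteny in %d outgroup(s)",
      length(inputs$outgroup_genomes))
  sy <- run_synteny(sr$candidates, inputs$annotation, inputs$focal_genome,
                    inputs$ortholog_table, inputs$outgroup_genomes, pc)
  for (id in names(sr$candidates))
    sr$candidates[[id]]$synteny_tier <- unname(sy$tiers[id])

  ex_sum <- summarize_candidates(tpm, sr$candidates, pc$tpm_threshold)
  for (r in seq_len(nrow(ex_sum$summaries))) {
    id <- ex_sum$summaries$candidate_id[r]
    sr$candidates[[id]]$n_libraries_expressed <-
      ex_sum$summaries$n_libraries_expressed[r]
    sr$candidates[[id]]$max_tpm <- ex_sum$summaries$max_TPM[r]
  }

  log("orf", "extracting ORFs (min %d nt)", pc$orf_min_len)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  orfs <- export_orf_peptides(sr$candidates,
                              file.path(out_dir, "orf_peptides.fa"),
                              pc$orf_min_len)
  for (id in names(sr$candidates)) {
    own <- orfs[orfs$transcript_id %in% sr$candidates[[id]]$isoforms, ]
    sr$candidates[[id]]$longest_orf_nt <-
      if (nrow(own)) max(own$length_nt) else NA_integer_
  }

  paths <- write_candidate_outputs(sr$candidates, out_dir, inputs$annotation)
  p_trace <- file.path(out_dir, "filter_trace.tsv")
  utils::write.table(sr$trace, p_trace, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p_expr <- file.path(out_dir, "expression_summary.tsv")
  utils::write.table(ex_sum$summaries, p_expr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p_syn <- file.path(out_dir, "synteny.tsv")
  utils::write.table(sy$results, p_syn, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p_orf <- file.path(out_dir, "orfs.tsv")
  utils::write.table(orfs[setdiff(names(orfs), "peptide")], p_orf, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  stage_counts <- table(sr$trace$stage)
  snapshot <- unclass(pc)
  snapshot$match_criterion <- NULL
  snapshot <- c(list(min_identity = pc$match_criterion$min_identity,
                     min_match_len = pc$match_criterion$min_len), snapshot)
  manifest <- list(
    config = snapshot,
    seed = if (!is.null(dataset)) dataset$plan$seed else NA,
    n_input_transcripts = length(inputs$transcripts),
    stage_counts = as.list(stage_counts),
    candidate_count = length(sr$candidates),
    tier_counts = as.list(table(sy$tiers)),
    cohort = ex_sum$cohort,
    timestamp = format(Sys.time(), tz = "UTC"))
  if (sum(stage_counts) != length(inputs$transcripts))
    stop_fmt("internal error: FilterTrace does not partition the input")
  p_manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p_manifest, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths <- c(paths, trace = p_trace, expression = p_expr, synteny = p_syn,
             orfs = p_orf, manifest = p_manifest)
  log("report", "outputs in %s", out_dir)
  invisible(list(candidates = sr$candidates, trace = sr$trace, tpm = tpm,
                 expression = ex_sum, synteny = sy, orfs = orfs,
                 manifest = manifest, dataset = dataset, config = pc,
                 paths = paths, out_dir = out_dir))
}

#' Compare a pipeline run against the simulator's ground truth
#'
#' Precision and recall over gene groups (a group is a true positive when it
#' is reported as a candidate and was planted as true_denovo), plus a
#' per-class confusion table of designed vs observed filter stages.
#'
#' @param trace FilterTrace data.frame from [run_all()] / [run_screen()].
#' @param truth Truth manifest data.frame (from a `synthetic_dataset`).
#' @return list(precision, recall, n_true, n_predicted, confusion =
#'   data.frame).
#' @export
compare_to_truth <- function(trace, truth) {
  if (!all(truth$transcript_id %in% trace$transcript_id))
    stop_fmt("ID mismatch: truth transcripts missing from the trace")
  m <- merge(truth, trace, by = "transcript_id")
  true_groups <- unique(m$gene_group[m$class == "true_denovo"])
  pred_groups <- unique(m$gene_group[m$stage == "candidate"])
  tp <- length(intersect(true_groups, pred_groups))
  confusion <- stats::aggregate(
    list(n = m$transcript_id),
    by = list(class = m$class, designed_stage = m$expected_stage,
              observed_stage = m$stage),
    FUN = length)
  list(precision = if (length(pred_groups)) tp / length(pred_groups) else NA_real_,
       recall = if (length(true_groups)) tp / length(true_groups) else NA_real_,
       n_true = length(true_groups), n_predicted = length(pred_groups),
       confusion = confusion[order(confusion$class), ])
}
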