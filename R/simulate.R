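# Synthetic dataset generator. Produces a focal genome with annotated
# multi-exon genes, two outgroup genomes at controlled divergence (with
# optional synteny breaks at planted candidate loci), an ortholog table,
# annotation-class sequence databases, outgroup transcript databases, and a
# set of planted transcripts: true intergenic de novo genes plus one decoy
# class per filter stage, with per-library expression levels straddling the
# TPM threshold. Every planted transcript carries a ground-truth label and
# the stage at which the cascade is expected to dispose of it.

#' Simulation plan
#'
#' Defaults define the study conditions used throughout the test-suite:
#' 2 chromosomes of 500 kb, 60 annotated genes, 12 true de novo gene groups
#' (15 transcripts; one group carries a short 250 bp second isoform to
#' exercise the isoform-rescue rule), at least 5 decoys per class, 6
#' libraries, and two outgroups at roughly D. simulans-like (5% substitution,
#' 1% indel) and D. yakuba-like (10%, 2%) divergence.
#'
#' @param seed Integer RNG seed; recorded in the dataset metadata.
#' @param n_chroms,chrom_len Number and length (bp) of focal chromosomes.
#' @param n_genes Annotated genes in total (coding + ncRNA + tRNA).
#' @param exons_per_gene Integer range of exon counts for coding genes.
#' @param exon_len,intron_len Integer ranges (bp).
#' @param n_ncrna,n_trna Counts of single-exon ncRNA / tRNA genes (within
#'   `n_genes`).
#' @param n_te Transposable-element features planted in intergenic space.
#' @param te_len Integer range of TE lengths (bp).
#' @param divergence Named list per outgroup: c(sub = ..., indel = ...).
#' @param synteny_break_fraction Fraction of true de novo loci whose outgroup
#'   region is split across scaffolds (in both outgroups).
#' @param class_counts Named integer vector of planted transcript classes.
#'   `true_denovo` counts gene groups, the rest transcripts.
#' @param n_libraries Expression libraries (tissue x genotype).
#' @param ortholog_missing_fraction Fraction of genes dropped from the
#'   ortholog table per outgroup.
#' @return A `sim_plan` list.
#' @export
sim_plan <- function(seed = 20230601L,
                     n_chroms = 2L, chrom_len = 500000L,
                     n_genes = 60L, exons_per_gene = c(2L, 3L),
                     exon_len = c(150L, 300L), intron_len = c(1400L, 2000L),
                     n_ncrna = 6L, n_trna = 4L,
                     n_te = 8L, te_len = c(800L, 1500L),
                     divergence = list(outgroup1 = c(sub = 0.05, indel = 0.01),
                                       outgroup2 = c(sub = 0.10, indel = 0.02)),
                     synteny_break_fraction = 0.25,
                     class_counts = c(true_denovo = 12L, annotated_copy = 6L,
                                      te_copy = 5L, intronic = 5L,
                                      near_exon = 5L, short = 5L,
                                      low_expression = 5L,
                                      outgroup_shared = 5L),
                     n_libraries = 6L,
                     ortholog_missing_fraction = 0) {
  rates <- unlist(divergence)
  if (any(rates < 0) || any(rates >= 1))
    stop_fmt("divergence rates must lie in [0, 1)")
  if (any(class_counts < 0)) stop_fmt("class counts must be >= 0")
  structure(list(seed = as.integer(seed), n_chroms = n_chroms,
                 chrom_len = chrom_len, n_genes = n_genes,
                 exons_per_gene = exons_per_gene, exon_len = exon_len,
                 intron_len = intron_len, n_ncrna = n_ncrna, n_trna = n_trna,
                 n_te = n_te, te_len = te_len, divergence = divergence,
                 synteny_break_fraction = synteny_break_fraction,
                 class_counts = class_counts, n_libraries = n_libraries,
                 ortholog_missing_fraction = ortholog_missing_fraction),
            class = "sim_plan")
}

#' Mutate a genome sequence at given substitution and indel rates
#'
#' Per-site independent substitutions (uniform over the 3 alternative bases)
#' and indels (position-wise rate; insertion or deletion with equal
#' probability; lengths geometric with mean 2). Returns the mutated sequence
#' plus a coordinate map from focal to mutated positions (NA for deleted
#' sites).
#'
#' @param sequence DNA string.
#' @param sub_rate,indel_rate Rates in [0, 1).
#' @param seed Integer seed.
#' @return list(sequence = character, map = integer vector of length
#'   nchar(sequence)).
#' @export
mutate_genome <- function(sequence, sub_rate, indel_rate, seed) {
  stopifnot(sub_rate >= 0, sub_rate < 1, indel_rate >= 0, indel_rate < 1)
  n <- nchar(sequence)
  x <- strsplit(sequence, "", fixed = TRUE)[[1]]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  if (sub_rate > 0) {
    subs <- which(stats::runif(n) < sub_rate)
    if (length(subs)) {
      idx <- match(x[subs], DNA_BASES)
      idx[is.na(idx)] <- 1L
      shift <- sample.int(3L, length(subs), replace = TRUE)
      x[subs] <- DNA_BASES[((idx - 1L + shift) %% 4L) + 1L]
    }
  }
  rep_str <- x
  deleted <- rep(FALSE, n)
  if (indel_rate > 0) {
    ev <- which(stats::runif(n) < indel_rate)
    if (length(ev)) {
      is_ins <- stats::runif(length(ev)) < 0.5
      lens <- stats::rgeom(length(ev), prob = 0.5) + 1L
      for (t in which(!is_ins)) {
        span <- ev[t]:min(n, ev[t] + lens[t] - 1L)
        deleted[span] <- TRUE
      }
      rep_str[deleted] <- ""
      for (t in which(is_ins)) {
        p <- ev[t]
        if (deleted[p]) next
        rep_str[p] <- paste0(x[p], paste(sample(DNA_BASES, lens[t],
                                                replace = TRUE),
                                         collapse = ""))
      }
    }
  }
  outlen <- nchar(rep_str)
  ends <- cumsum(outlen)
  map <- ifelse(deleted, NA_integer_, as.integer(c(0L, ends[-n]) + 1L))
  list(sequence = paste(rep_str, collapse = ""), map = map)
}

# map a focal interval through a coordinate map; NA-safe
map_interval <- function(map, start, end) {
  m <- map[start:end]
  m <- m[!is.na(m)]
  if (!length(m)) return(c(NA_integer_, NA_integer_))
  c(min(m), max(m))
}

rint <- function(n, range) {
  if (range[1] >= range[2]) rep(range[1], n) else
    sample(seq(range[1], range[2]), n, replace = TRUE)
}

# --- focal genome layout -----------------------------------------------------

build_focal <- function(plan) {
  n_coding <- plan$n_genes - plan$n_ncrna - plan$n_trna
  biotypes <- c(rep("coding", n_coding), rep("ncRNA", plan$n_ncrna),
                rep("tRNA", plan$n_trna))
  gene_chrom <- rep(seq_len(plan$n_chroms), length.out = plan$n_genes)
  biotypes <- sample(biotypes)  # spread biotypes across chroms

  cc <- plan$class_counts
  # locus-needing planted items (true_denovo groups, outgroup_shared, short,
  # low_expression); near_exon attaches to genes; intronic sits in introns
  mk_items <- function(kind, count) if (count > 0)
    data.frame(kind = kind, idx = seq_len(count), stringsAsFactors = FALSE)
  items <- do.call(rbind, c(list(mk_items("true_denovo", cc[["true_denovo"]]),
                                 mk_items("outgroup_shared", cc[["outgroup_shared"]]),
                                 mk_items("short", cc[["short"]]),
                                 mk_items("low_expression", cc[["low_expression"]]),
                                 mk_items("near_exon", cc[["near_exon"]]),
                                 mk_items("te", plan$n_te))))
  items$chrom <- rep(seq_len(plan$n_chroms), length.out = nrow(items))

  ann_rows <- list(); gene_rows <- list(); te_rows <- list()
  planted_rows <- list()
  chrom_names <- paste0("chr", seq_len(plan$n_chroms))
  genome <- character(plan$n_chroms)
  gap <- function() sample(1500:3000, 1L)

  gi <- 0L; ti <- 0L
  for (ci in seq_len(plan$n_chroms)) {
    gsel <- which(gene_chrom == ci)
    others <- items[items$chrom == ci, , drop = FALSE]
    others <- others[sample(nrow(others)), , drop = FALSE]
    n_g <- length(gsel)
    # distribute others into the n_g - 1 inner gene gaps (flanking genes on
    # both sides of every planted locus, so microsynteny always has anchors)
    gap_of <- rep(seq_len(max(n_g - 1L, 1L)), length.out = nrow(others))
    cursor <- 3000L
    last_gene_end <- NA_integer_
    for (g in seq_len(n_g)) {
      gi <- gi + 1L
      bt <- biotypes[gsel[g]]
      gid <- sprintf("FG%04d", gi)
      txid <- paste0(gid, ".t1")
      strand <- sample(c("+", "-"), 1L)
      if (bt == "coding") {
        n_ex <- rint(1L, plan$exons_per_gene)
        ex_lens <- rint(n_ex, plan$exon_len)
        in_lens <- if (n_ex > 1L) rint(n_ex - 1L, plan$intron_len) else integer(0)
      } else if (bt == "ncRNA") {
        n_ex <- 1L; ex_lens <- rint(1L, c(400L, 800L)); in_lens <- integer(0)
      } else {
        n_ex <- 1L; ex_lens <- 90L; in_lens <- integer(0)
      }
      gstart <- cursor + gap()
      pos <- gstart
      ex <- list()
      for (e in seq_len(n_ex)) {
        ex[[e]] <- c(pos, pos + ex_lens[e] - 1L)
        pos <- pos + ex_lens[e] + if (e < n_ex) in_lens[e] else 0L
      }
      gend <- ex[[n_ex]][2]
      gene_rows[[gi]] <- data.frame(gene_id = gid, transcript_id = txid,
                                    biotype = bt, chrom = chrom_names[ci],
                                    start = gstart, end = gend,
                                    strand = strand, n_exons = n_ex,
                                    stringsAsFactors = FALSE)
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        chrom = chrom_names[ci],
        start = c(gstart, vapply(ex, `[`, 0, 1)),
        end = c(gend, vapply(ex, `[`, 0, 2)),
        strand = strand,
        feature_class = c("gene", rep("exon", n_ex)),
        gene_id = gid,
        transcript_id = c(NA_character_, rep(txid, n_ex)),
        stringsAsFactors = FALSE)
      cursor <- gend
      last_gene_end <- gend
      # items assigned to the gap after this gene
      if (g <= max(n_g - 1L, 1L)) {
        sel <- which(gap_of == g)
        # near-exon decoys first, anchored to this gene's terminal exon
        sel <- sel[order(others$kind[sel] != "near_exon")]
        for (oi in sel) {
          kind <- others$kind[oi]
          if (kind == "near_exon") {
            d <- sample(1:250, 1L)
            len <- rint(1L, c(302L, 600L))
            ostart <- last_gene_end + d
          } else if (kind == "te") {
            len <- rint(1L, plan$te_len)
            ostart <- cursor + gap()
          } else {
            len <- switch(kind,
                          true_denovo = if (others$idx[oi] == 1L) 302L
                          else if (others$idx[oi] == cc[["true_denovo"]] - 1L) 700L
                          else rint(1L, c(302L, 900L)),
                          outgroup_shared = rint(1L, c(302L, 700L)),
                          short = rint(1L, c(150L, 298L)),
                          low_expression = rint(1L, c(302L, 700L)))
            ostart <- cursor + gap()
          }
          oend <- ostart + len - 1L
          if (kind == "te") {
            ti <- ti + 1L
            te_rows[[ti]] <- data.frame(te_id = sprintf("TE%03d", ti),
                                        chrom = chrom_names[ci],
                                        start = ostart, end = oend,
                                        stringsAsFactors = FALSE)
            ann_rows[[length(ann_rows) + 1L]] <- data.frame(
              chrom = chrom_names[ci], start = ostart, end = oend,
              strand = "+", feature_class = "transposon",
              gene_id = sprintf("TE%03d", ti),
              transcript_id = NA_character_, stringsAsFactors = FALSE)
          } else {
            planted_rows[[length(planted_rows) + 1L]] <- data.frame(
              class = kind, idx = others$idx[oi], chrom = chrom_names[ci],
              start = ostart, end = oend, stringsAsFactors = FALSE)
          }
          cursor <- max(cursor, oend)
        }
      }
    }
    if (cursor + 3000L > plan$chrom_len)
      stop_fmt("sizing error: chromosome %s needs %d bp but plan allows %d",
               chrom_names[ci], cursor + 3000L, plan$chrom_len)
    genome[ci] <- random_dna(plan$chrom_len)
  }
  names(genome) <- chrom_names
  list(genome = genome,
       annotation = as_annotation(do.call(rbind, ann_rows)),
       gene_info = do.call(rbind, gene_rows),
       te_info = do.call(rbind, te_rows),
       planted_loci = do.call(rbind, planted_rows))
}

# assign intronic decoy loci inside gene introns
place_intronic <- function(focal, plan) {
  cc <- plan$class_counts[["intronic"]]
  if (cc == 0L) return(focal)
  multi <- focal$gene_info[focal$gene_info$n_exons >= 2L, ]
  if (nrow(multi) < cc)
    stop_fmt("placement error: %d intronic decoys but only %d multi-exon genes",
             cc, nrow(multi))
  hosts <- multi[sample(nrow(multi), cc), ]
  rows <- list()
  for (i in seq_len(cc)) {
    g <- hosts[i, ]
    ex <- focal$annotation[focal$annotation$feature_class == "exon" &
                             focal$annotation$gene_id == g$gene_id, ]
    ex <- ex[order(ex$start), ]
    istart <- ex$end[1] + 1L; iend <- ex$start[2] - 1L
    ilen <- iend - istart + 1L
    len <- rint(1L, c(310L, 450L))
    if (ilen < len + 502L)
      stop_fmt("placement error: intron of %s too small for intronic decoy",
               g$gene_id)
    s <- istart + (ilen - len) %/% 2L
    rows[[i]] <- data.frame(class = "intronic", idx = i, chrom = g$chrom,
                            start = s, end = s + len - 1L,
                            stringsAsFactors = FALSE)
  }
  focal$planted_loci <- rbind(focal$planted_loci, do.call(rbind, rows))
  focal
}

# spliced transcript sequence of an annotated gene (exons in genomic order;
# minus-strand genes are reverse-complemented)
spliced_seq <- function(genome, ann, tx_id) {
  ex <- ann[ann$feature_class == "exon" & !is.na(ann$transcript_id) &
              ann$transcript_id == tx_id, ]
  ex <- ex[order(ex$start), ]
  s <- paste(substring(genome[[ex$chrom[1]]], ex$start, ex$end), collapse = "")
  if (ex$strand[1] == "-") revcomp(s) else s
}

#' Plant labelled transcripts into a simulated dataset
#'
#' Extracts transcript sequences for every planted locus and decoy class and
#' attaches the ground-truth manifest (class and the filter stage each class
#' is designed to terminate at). True de novo transcripts are copies of focal
#' intergenic sequence; annotated_copy / te_copy decoys copy annotation
#' classes; outgroup_shared decoys are additionally injected (mutated) into
#' an outgroup transcript database by [simulate_dataset()].
#'
#' @param dataset Partial dataset from [simulate_dataset()] internals.
#' @return The dataset with `transcripts` (named character) and `truth`
#'   (data.frame transcript_id, gene_group, isoform, class, expected_stage).
#' @export
plant_transcripts <- function(dataset) {
  plan <- dataset$plan
  genome <- dataset$focal_genome
  loci <- dataset$planted_loci
  cc <- plan$class_counts
  dn_pool <- sample(1000:99999)
  dn_i <- 0L
  next_dn <- function() { dn_i <<- dn_i + 1L; dn_pool[dn_i] }
  expected <- c(true_denovo = "candidate", annotated_copy = "annotation_match",
                te_copy = "annotation_match",
                outgroup_shared = "outgroup_transcript_match",
                intronic = "not_intergenic", near_exon = "near_exon",
                short = "short", low_expression = "low_expression")
  seqs <- character(0)
  truth <- list()
  add <- function(group, iso, class, seq, chrom = NA, start = NA, end = NA) {
    id <- sprintf("%s_i%d", group, iso)
    seqs[[id]] <<- seq
    truth[[id]] <<- data.frame(transcript_id = id, gene_group = group,
                               isoform = iso, class = class,
                               expected_stage = expected[[class]],
                               chrom = chrom, start = start, end = end,
                               stringsAsFactors = FALSE)
  }
  # locus-based classes
  for (cl in c("true_denovo", "outgroup_shared", "intronic", "near_exon",
               "short", "low_expression")) {
    sub <- loci[loci$class == cl, , drop = FALSE]
    for (r in seq_len(nrow(sub))) {
      x <- sub[r, ]
      group <- sprintf("TRINITY_DN%d_c0_g1", next_dn())
      full <- substring(genome[[x$chrom]], x$start, x$end)
      add(group, 1L, cl, full, x$chrom, x$start, x$end)
      if (cl == "true_denovo" && x$idx == cc[["true_denovo"]] - 1L &&
          nchar(full) >= 500L) {
        # a second, structurally valid isoform (prefix of the locus)
        add(group, 2L, cl, substring(full, 1L, 400L), x$chrom, x$start,
            x$start + 399L)
      }
      if (cl == "true_denovo" && x$idx == cc[["true_denovo"]]) {
        # a short 250 bp isoform: rescued by the isoform rule
        add(group, 2L, cl, substring(full, 1L, 250L), x$chrom, x$start,
            x$start + 249L)
      }
    }
  }
  # annotated_copy: verbatim copies of focal spliced transcripts
  coding <- dataset$gene_info[dataset$gene_info$biotype != "tRNA", ]
  hosts <- coding[sample(nrow(coding), cc[["annotated_copy"]]), ]
  for (r in seq_len(nrow(hosts))) {
    group <- sprintf("TRINITY_DN%d_c0_g1", next_dn())
    add(group, 1L, "annotated_copy",
        spliced_seq(genome, dataset$annotation, hosts$transcript_id[r]))
  }
  # te_copy: copies of transposon intervals
  tes <- dataset$te_info[sample(nrow(dataset$te_info), cc[["te_copy"]],
                                replace = nrow(dataset$te_info) < cc[["te_copy"]]), ]
  for (r in seq_len(nrow(tes))) {
    group <- sprintf("TRINITY_DN%d_c0_g1", next_dn())
    x <- tes[r, ]
    len <- min(x$end - x$start + 1L, rint(1L, c(302L, 800L)))
    add(group, 1L, "te_copy", substring(genome[[x$chrom]], x$start,
                                        x$start + len - 1L))
  }
  dataset$transcripts <- unlist(seqs)
  dataset$truth <- do.call(rbind, unname(truth))
  rownames(dataset$truth) <- NULL
  dataset
}

#' Simulate per-library counts with class-targeted TPM levels
#'
#' Each transcript (annotated and planted) is assigned a target TPM per
#' library; counts are the deterministic rounding of target x length(kb) x
#' depth, so that [compute_tpm()] reproduces each target within a few
#' percent. True de novo groups are expressed at 1.2-7 TPM in 1-3 libraries;
#' the low_expression class at 0.5 TPM (below threshold everywhere);
#' annotated genes over a broad positive range.
#'
#' @param dataset Dataset with transcripts planted.
#' @return The dataset with `counts` (integer matrix), `tx_lengths`, and
#'   `libraries` (data.frame of library metadata).
#' @export
simulate_counts <- function(dataset) {
  plan <- dataset$plan
  tissues <- c("spermatheca", "seminal_receptacle", "parovaria")
  libs <- data.frame(
    library = sprintf("%s_%s",
                      rep(c("RAL304", "RAL307"),
                          each = ceiling(plan$n_libraries / 2))[seq_len(plan$n_libraries)],
                      rep(tissues, length.out = plan$n_libraries)),
    genotype = rep(c("RAL304", "RAL307"),
                   each = ceiling(plan$n_libraries / 2))[seq_len(plan$n_libraries)],
    tissue = rep(tissues, length.out = plan$n_libraries),
    stringsAsFactors = FALSE)

  ann_tx <- dataset$gene_info$transcript_id
  ann_len <- vapply(ann_tx, function(tx)
    nchar(spliced_seq(dataset$focal_genome, dataset$annotation, tx)), 0L)
  pl_tx <- names(dataset$transcripts)
  pl_len <- nchar(dataset$transcripts)
  nlib <- plan$n_libraries

  target <- matrix(0, nrow = length(ann_tx) + length(pl_tx), ncol = nlib,
                   dimnames = list(c(ann_tx, pl_tx), libs$library))
  # annotated genes: broad positive lognormal range, mild per-library noise
  base <- stats::rlnorm(length(ann_tx), meanlog = 3, sdlog = 1.5)
  for (j in seq_len(nlib))
    target[seq_along(ann_tx), j] <- base * stats::rlnorm(length(ann_tx), 0, 0.3)

  truth <- dataset$truth
  groups <- unique(truth$gene_group)
  denovo_levels <- c(1.2, 1.5, 2, 3, 5, 7)
  for (g in groups) {
    tr <- truth[truth$gene_group == g, ]
    cl <- tr$class[1]
    ids <- tr$transcript_id
    if (cl == "true_denovo") {
      n_on <- sample(1:3, 1L)
      on <- sample(nlib, n_on)
      target[ids[1], on] <- sample(denovo_levels, 1L)
      if (length(ids) > 1L)  # secondary isoforms: below threshold
        target[ids[-1], on[1]] <- 0.4
    } else if (cl == "low_expression") {
      on <- sample(nlib, 2L)
      target[ids, on] <- 0.5
    } else {
      target[ids, sample(nlib, 1L)] <- 2
    }
  }
  # make the first true group sit just above the threshold in one library
  first_true <- truth$transcript_id[truth$class == "true_denovo"][1]
  on <- which(target[first_true, ] > 0)
  target[first_true, ] <- 0
  target[first_true, on[1]] <- 1.2

  # normalise so per-library targets sum to 1e6 (scaling annotated genes)
  lens <- c(ann_len, pl_len)
  for (j in seq_len(nlib)) {
    planted_sum <- sum(target[pl_tx, j])
    ann_sum <- sum(target[ann_tx, j])
    target[ann_tx, j] <- target[ann_tx, j] * (1e6 - planted_sum) / ann_sum
  }
  depth <- 50
  counts <- round(target * (lens / 1000) * depth)
  storage.mode(counts) <- "integer"
  dataset$counts <- counts
  dataset$tx_lengths <- stats::setNames(lens, rownames(counts))
  dataset$libraries <- libs
  dataset
}

# build annotation-class and outgroup transcript databases
build_databases <- function(dataset) {
  plan <- dataset$plan
  genome <- dataset$focal_genome
  ann <- dataset$annotation
  gi <- dataset$gene_info
  class_of <- c(coding = "CDS", ncRNA = "ncRNA", tRNA = "tRNA")

  species_db <- function(seq_fetch, prefix) {
    db <- list()
    for (bt in names(class_of)) {
      sub <- gi[gi$biotype == bt, ]
      if (!nrow(sub)) next
      s <- vapply(sub$transcript_id, seq_fetch, "")
      names(s) <- paste0(prefix, sub$transcript_id)
      db[[class_of[[bt]]]] <- s[nzchar(s)]
    }
    db
  }
  te_seqs <- function(extract) {
    s <- vapply(seq_len(nrow(dataset$te_info)), function(i) {
      x <- dataset$te_info[i, ]
      extract(x$chrom, x$start, x$end)
    }, "")
    names(s) <- dataset$te_info$te_id
    s[nzchar(s)]
  }

  focal_fetch <- function(tx) spliced_seq(genome, ann, tx)
  ann_dbs <- list(focal = c(species_db(focal_fetch, "mel_"),
                            list(transposon = te_seqs(function(ch, s, e)
                              substring(genome[[ch]], s, e)))))

  out_tx_dbs <- list()
  for (sp in names(dataset$outgroups)) {
    og <- dataset$outgroups[[sp]]
    fetch <- function(tx) {
      ex <- ann[ann$feature_class == "exon" & !is.na(ann$transcript_id) &
                  ann$transcript_id == tx, ]
      ex <- ex[order(ex$start), ]
      ch <- ex$chrom[1]
      parts <- character(0)
      for (r in seq_len(nrow(ex))) {
        iv <- map_interval(og$maps[[ch]], ex$start[r], ex$end[r])
        if (is.na(iv[1])) next
        parts <- c(parts, substring(og$unbroken[[ch]], iv[1], iv[2]))
      }
      s <- paste(parts, collapse = "")
      if (nchar(s) && ex$strand[1] == "-") revcomp(s) else s
    }
    extract_te <- function(ch, s, e) {
      iv <- map_interval(dataset$outgroups[[sp]]$maps[[ch]], s, e)
      if (is.na(iv[1])) return("")
      substring(dataset$outgroups[[sp]]$unbroken[[ch]], iv[1], iv[2])
    }
    ann_dbs[[sp]] <- c(species_db(fetch, paste0(sp, "_")),
                       list(transposon = te_seqs(extract_te)))
    tx_db <- vapply(gi$transcript_id, fetch, "")
    names(tx_db) <- paste0(sp, "_", gi$transcript_id)
    out_tx_dbs[[sp]] <- tx_db[nchar(tx_db) >= 25L]
  }
  # inject outgroup_shared decoys (mutated copies) into outgroup 1 transcripts
  shared <- dataset$truth$transcript_id[dataset$truth$class == "outgroup_shared"]
  sp1 <- names(dataset$outgroups)[1]
  for (i in seq_along(shared)) {
    mut <- mutate_genome(dataset$transcripts[[shared[i]]], 0.10, 0.01,
                         derive_seed(plan$seed, 700 + i))
    out_tx_dbs[[sp1]][[paste0(sp1, "_shared_", i)]] <- mut$sequence
  }
  dataset$databases <- list(annotation_dbs = ann_dbs,
                            outgroup_tx_dbs = out_tx_dbs)
  dataset
}

#' Simulate a complete labelled dataset
#'
#' Runs the full generator: focal genome and annotation, planted loci, two
#' diverged outgroup genomes with coordinate maps and optional synteny
#' breaks, ortholog table, annotation-class and outgroup transcript
#' databases, planted transcripts with ground truth, and per-library counts.
#' Deterministic given `plan$seed`.
#'
#' @param plan A [sim_plan()].
#' @return An object of class `synthetic_dataset`.
#' @export
simulate_dataset <- function(plan = sim_plan()) {
  stopifnot(inherits(plan, "sim_plan"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(plan$seed, 1L))

  focal <- build_focal(plan)
  focal <- place_intronic(focal, plan)
  dataset <- structure(list(plan = plan, focal_genome = focal$genome,
                            annotation = focal$annotation,
                            gene_info = focal$gene_info,
                            te_info = focal$te_info,
                            planted_loci = focal$planted_loci),
                       class = "synthetic_dataset")

  # outgroup genomes
  dataset$outgroups <- list()
  for (i in seq_along(plan$divergence)) {
    sp <- names(plan$divergence)[i]
    rates <- plan$divergence[[i]]
    maps <- list(); seqs <- character(0)
    for (ch in names(dataset$focal_genome)) {
      m <- mutate_genome(dataset$focal_genome[[ch]], rates[[1]], rates[[2]],
                         derive_seed(plan$seed, 100L + i * 10L + match(ch, names(dataset$focal_genome))))
      maps[[ch]] <- m$map
      seqs[[ch]] <- m$sequence
    }
    dataset$outgroups[[sp]] <- list(unbroken = seqs, maps = maps)
  }

  set.seed(derive_seed(plan$seed, 2L))
  dataset <- plant_transcripts(dataset)

  # synteny breaks: split outgroup scaffolds at selected true de novo loci
  true_loci <- dataset$planted_loci[dataset$planted_loci$class == "true_denovo", ]
  n_break <- round(plan$synteny_break_fraction * nrow(true_loci))
  break_idx <- if (n_break > 0) sort(sample(nrow(true_loci), n_break)) else integer(0)
  dataset$broken_loci <- true_loci[break_idx, , drop = FALSE]
  for (sp in names(dataset$outgroups)) {
    og <- dataset$outgroups[[sp]]
    breakpoints <- list()
    for (r in seq_len(nrow(dataset$broken_loci))) {
      x <- dataset$broken_loci[r, ]
      mid <- (x$start + x$end) %/% 2L
      bp <- og$maps[[x$chrom]][mid]
      if (is.na(bp)) bp <- og$maps[[x$chrom]][which(!is.na(og$maps[[x$chrom]][x$start:x$end]))[1] + x$start - 1L]
      breakpoints[[x$chrom]] <- c(breakpoints[[x$chrom]], bp)
    }
    genome_out <- character(0)
    seg_tab <- list()  # per chrom: data.frame(seg_name, start, end)
    for (ch in names(og$unbroken)) {
      L <- nchar(og$unbroken[[ch]])
      bps <- sort(unique(breakpoints[[ch]] %||% integer(0)))
      starts <- c(1L, bps + 1L)
      ends <- c(bps, L)
      segn <- if (length(bps)) paste0(ch, "_s", seq_along(starts)) else ch
      for (s in seq_along(starts))
        genome_out[[segn[s]]] <- substring(og$unbroken[[ch]], starts[s], ends[s])
      seg_tab[[ch]] <- data.frame(seg = segn, start = starts, end = ends,
                                  stringsAsFactors = FALSE)
    }
    og$genome <- genome_out
    og$segments <- seg_tab
    dataset$outgroups[[sp]] <- og
  }

  # ortholog table with outgroup loci in (possibly segmented) coordinates
  set.seed(derive_seed(plan$seed, 3L))
  rows <- list()
  for (sp in names(dataset$outgroups)) {
    og <- dataset$outgroups[[sp]]
    keep <- rep(TRUE, nrow(dataset$gene_info))
    if (plan$ortholog_missing_fraction > 0)
      keep <- stats::runif(nrow(dataset$gene_info)) >= plan$ortholog_missing_fraction
    for (r in which(keep)) {
      g <- dataset$gene_info[r, ]
      iv <- map_interval(og$maps[[g$chrom]], g$start, g$end)
      if (is.na(iv[1])) next
      seg <- og$segments[[g$chrom]]
      si <- findInterval(iv[1], seg$start)
      # a gene overlapping a breakpoint is assigned to its starting segment
      rows[[length(rows) + 1L]] <- data.frame(
        focal_gene_id = g$gene_id, outgroup_species = sp,
        ortholog_gene_id = paste0(sp, "_", g$gene_id),
        chrom = seg$seg[si],
        start = iv[1] - seg$start[si] + 1L,
        end = min(iv[2], seg$end[si]) - seg$start[si] + 1L,
        stringsAsFactors = FALSE)
    }
  }
  dataset$ortholog_table <- do.call(rbind, rows)

  dataset <- build_databases(dataset)
  set.seed(derive_seed(plan$seed, 4L))
  dataset <- simulate_counts(dataset)
  dataset
}

#' Write a simulated dataset to disk in pipeline input formats
#'
#' @param dataset A `synthetic_dataset`.
#' @param out_dir Output directory.
#' @return Named vector of written paths.
#' @export
write_simulated_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(out_dir, "focal_genome.fa"),
             annotation = file.path(out_dir, "focal_annotation.gtf"),
             transcripts = file.path(out_dir, "transcripts.fa"),
             counts = file.path(out_dir, "counts.tsv"),
             orthologs = file.path(out_dir, "orthologs.tsv"),
             truth = file.path(out_dir, "truth_manifest.tsv"))
  write_fasta(dataset$focal_genome, paths["genome"])
  write_annotation(dataset$annotation, paths["annotation"])
  write_fasta(dataset$transcripts, paths["transcripts"])
  write_expression_table(dataset$counts, paths["counts"])
  utils::write.table(dataset$ortholog_table, paths["orthologs"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (sp in names(dataset$outgroups)) {
    p <- file.path(out_dir, sprintf("%s_genome.fa", sp))
    write_fasta(dataset$outgroups[[sp]]$genome, p)
    paths[paste0("genome_", sp)] <- p
    p <- file.path(out_dir, sprintf("%s_transcripts.fa", sp))
    write_fasta(dataset$databases$outgroup_tx_dbs[[sp]], p)
    paths[paste0("transcripts_", sp)] <- p
  }
  invisible(paths)
}
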