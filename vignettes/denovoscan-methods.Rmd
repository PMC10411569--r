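---
title: "Identifying candidate de novo genes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying candidate de novo genes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

De novo genes are genes born from ancestrally nongenic DNA. Detecting
candidates among de novo assembled transcripts is a subtraction exercise: a
transcript is interesting only if it matches *nothing* — no annotated gene
class in the focal species or its relatives, no transcript assembled from
outgroup tissues — while still mapping cleanly to intergenic sequence of the
focal genome and showing reproducible expression. Because each of those
subtractions is a threshold decision, small implementation ambiguities
(inclusive vs strict bounds, identity denominators, coordinate conventions)
change the candidate set. `denovoscan` implements the complete cascade as a
single tested package so every decision is explicit and auditable.

The pipeline stages, in fixed order:

1. **Annotation screen** — remove transcripts with a qualifying match to any
   annotation-class database (3'UTR, 5'UTR, intron, miRNA, miscRNA, ncRNA,
   pseudogene, transposon, tRNA, CDS) of any species supplied.
2. **Outgroup transcript screen** — remove transcripts matching any outgroup
   transcriptome assembly.
3. **Genome placement** — locate the transcript on the focal genome; failure
   is a terminal stage (`unplaced`), not a silent drop.
4. **Structural filter** — length > 300 bp (strict), distance to the nearest
   annotated exon > 250 bp (strict), intergenic context.
5. **Expression filter** (gene-group level) — TPM >= 1 (inclusive) in at
   least one library for at least one isoform that also passed the
   structural filter; a passing group retains **all** of its isoforms, so a
   250 bp isoform can ride along with a qualifying sibling.
6. **Microsynteny validation** — candidates are tiered
   (`both_outgroups` / `one_outgroup` / `none`), never removed, according to
   whether the locus' flank window can be located in the outgroup region
   anchored by the orthologs of the immediately flanking genes.

Every input transcript ends at exactly one terminal stage; the `FilterTrace`
is a partition of the input and is written with the evidence for each
removal.

## The match criterion

Every screening decision reduces to one primitive: *does this transcript
have a local alignment at >= 80% identity over >= 100 alignment columns to
any database sequence?* `denovoscan` implements it as exact 11-mer seeding
over an integer-coded index, followed by banded gapped extension (band
±10 diagonals; match +1, mismatch −2, gap open −4, gap extend −1, so a gap
of length *g* costs 4 + *g*). Identity is matches / alignment columns with
gap columns counted, and `aligned_len` means alignment columns, so a gapped
alignment spanning 100 columns satisfies the 100 bp bound — both BLAST
conventions. Both strands are searched by reverse-complementing the query.
The tests hold this primitive against an independent optimal local aligner
(`Biostrings::pairwiseAlignment`) with identical scoring on hundreds of
planted-homology pairs.

Numerical notes:

* Seed *k* = 11 balances sensitivity at 80% identity against index size;
  it is configurable in `pipeline_config()`.
* Seeds containing N are not indexed; N mismatches every base during
  extension.
* Ties between qualifying matches are broken by score, then identity, then
  lexicographic subject id, then subject start — fully deterministic.
* No low-complexity masking is applied; the simulator avoids long
  homopolymer runs instead.

## Coordinates

Internally every interval is 1-based closed, the IRanges convention, because
interval queries (exon distance, genic context, overlap fractions) are
delegated to `GenomicRanges`/`IRanges`. GTF is read and written natively in
that convention; BED output converts on write (BED start = GTF start − 1,
BED end = GTF end). Exon distance is a gap length: adjacent intervals have
distance 0, and an empty exon set yields +Inf (the filter passes vacuously).
A locus is `intronic` when >= 50% of it lies inside an annotated gene span
without touching an exon; partial straddles below 50% count as intergenic.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_identity` | 0.80 | identity fraction of a qualifying match |
| `min_match_len` | 100 | minimum alignment columns |
| `min_transcript_len` | 300 bp | strict lower bound on transcript length |
| `min_exon_distance` | 250 bp | strict lower bound on distance to any exon |
| `tpm_threshold` | 1.0 | inclusive TPM bound, any-library mode |
| `synteny_flank` | 5000 bp | flank around the locus in the synteny query |
| `orf_min_len` | 75 nt | minimum ORF length (ATG through stop) |
| `kmer`, `band` | 11, 10 | homology search internals |

Two expression-call modes exist deliberately: `any_library` (max TPM >= 1,
inclusive — the within-study criterion) and `replicate_mean` (mean TPM > 1,
strict — the criterion used for external expression resources). They are not
harmonised because the two rules are genuinely different.

For the minimum ORF length, 75 nt is the default (the common
coding-potential tool default) and 30 nt is exposed as a permissive preset;
sources differ on which bound matters, so both are provided and neither is
hard-coded anywhere downstream.

## Microsynteny validation

The region test asks whether the candidate's flank window (locus ± 5 kb)
has a qualifying match within the outgroup interval spanned by the located
flank-ortholog loci, extended by 50 kb on each side. Design choices, made
where the procedure is genuinely underdetermined:

* One located flank ortholog (of two) is enough to attempt validation; zero
  is automatic failure (`no_flank_orthologs`).
* Both located orthologs on different scaffolds is failure
  (`split_flanks`) — this is exactly the signature the simulator's
  synteny-break class plants.
* The region match may hit flank sequence only. The candidate itself may be
  diverged or absent in the outgroup — the check certifies *region*
  orthology, not transcript presence, and a constructed test asserts that
  deleting the candidate's own sequence from the outgroup still validates.
* Failures are tiered, never rescued or removed.

## The synthetic data generator

The simulator is first-class, tested code: it is the only way to know the
right answer at every stage. `sim_plan()` defaults define the study
conditions used across the test-suite:

* 2 chromosomes × 500 kb of uniform random sequence; 60 annotated genes
  (50 coding with 2–3 exons of 150–300 bp and introns of 1.4–2 kb, 6 ncRNA,
  4 tRNA) and 8 transposon features, laid out so that every planted locus
  has annotated genes on both sides (microsynteny always has anchors).
* 12 true de novo gene groups: copies of focal intergenic sequence,
  >= 302 bp, > 250 bp from any exon; one group carries a structurally valid
  second isoform and one a 250 bp second isoform (exercising isoform
  rescue). The shortest group is pinned at exactly 302 bp to sit on the
  accepted side of the length boundary.
* One decoy class per filter stage, >= 5 each: `annotated_copy` and
  `te_copy` (caught by the annotation screen), `outgroup_shared` (planted,
  mutated at 10% divergence, into an outgroup transcript database),
  `intronic`, `near_exon` (1–250 bp from a terminal exon), `short`
  (150–298 bp), and `low_expression` (0.5 TPM target).
* Two outgroup genomes derived by per-site mutation: substitutions uniform
  over the three alternatives, indels at half rate insertion/deletion with
  geometric(mean 2) lengths — the simplest neutral model that produces
  controlled divergence plus a focal→outgroup coordinate map. Defaults are
  5% substitutions / 1% indels and 10% / 2%, bracketing close and more
  distant outgroups while staying below the 80% match ceiling.
* Synteny breaks: 25% of the true loci (3 of 12) have the outgroup
  scaffold split at the locus midpoint in both outgroups, putting the two
  flank orthologs on different scaffolds.
* 6 libraries (2 genotypes × 3 female reproductive tract tissues). Counts
  are the deterministic rounding of target-TPM × length(kb) × depth with
  per-library targets normalised to 10^6, so `compute_tpm()` reproduces
  each class target within a few percent: true de novo groups at 1.2–7 TPM
  in 1–3 libraries (straddling the threshold from above), the
  low-expression class at 0.5 TPM, annotated genes over a broad lognormal
  range.

What the simulator does **not** emulate — and therefore what passing tests
do not show about real data: sequencing error and read-level artefacts
(counts are generated, not aligned), assembly chimerism and fragmentation,
paralogous gene families and segmental duplications, repeat-driven
mis-seeding beyond the planted transposons, annotation errors, and the
scale of a real annotation (60 genes vs tens of thousands — so, e.g., the
per-library fraction of annotated genes expressed above the candidate
maximum is structurally near 1 here, because 10^6 TPM shared among 60 genes
makes every annotated gene highly expressed).

With zero divergence the outgroup equals the focal genome, and the full
pipeline on the default plan recovers exactly the planted groups
(precision = recall = 1) with every decoy at its designed stage; this is
asserted in the acceptance tests.

## Monotonicity: what is and is not monotone

Raising `min_transcript_len`, `min_exon_distance` or `tpm_threshold` can
only shrink the candidate set, and the tests sweep all three. The homology
knobs are different in kind: raising `min_identity` or `min_match_len`
makes the *screens* remove fewer transcripts, and a transcript spared by a
stricter criterion re-enters the cascade and can become a candidate — so
candidate count is genuinely **not** monotone in the match criterion (on
the default simulation, sweeping `min_identity` 0.80 → 0.95 raises the
count from 12 to 17 as the outgroup-shared decoys at 10% divergence stop
matching). What is monotone is the match decision itself: tightening the
criterion never turns a non-match into a match, so each screen's removal
set shrinks nestedly. The tests assert exactly these two properties.

## Problem sizes and runtime

The default conditions (1 Mb focal genome, two outgroups, ~50 transcripts,
6 libraries) run end-to-end in well under a minute on one core; the whole
test-suite, including oracle-equivalence sweeps and a second full run for
byte-level determinism, completes in a few minutes. These sizes were chosen
as the smallest at which every stage has >= 5 labelled cases per decoy
class and the homology search still operates in its realistic regime
(genome-scale index, seed clustering, banded extension).

## Known limitations

* The placement merge (co-linear qualifying matches within 1 kb) stands in
  for spliced alignment; long introns or many small exons (< 100 bp, below
  the match length bound) will fragment or fail placement.
* Identity is computed over the best-scoring banded alignment; co-optimal
  alignments can trade length against identity near the 80%/100-column
  boundary, which is why oracle agreement is asserted at 99% with
  borderline cases tolerated rather than at 100%.
* The ortholog table is trusted as given; paralogy confusion is out of
  scope.
* Coding-potential scoring itself (CPC2/CPAT/SignalP-class tools) is out of
  scope: the package extracts and exports ORF peptides for them.
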