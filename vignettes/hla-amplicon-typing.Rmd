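---
title: "Amplicon-based HLA genotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amplicon-based HLA genotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hlatyper is a desk-scale implementation of an automated amplicon
next-generation-sequencing workflow for HLA class I and class II typing.
This vignette explains the science the package implements, the tunable
parameters and their defaults, what the synthetic data emulates (and does
not), and the design decisions taken where the problem left room.

## The typing problem

HLA genes are the most polymorphic loci in the human genome. Clinical
typing must resolve genotypes to at least 4-digit (two-field, protein-level)
resolution, e.g. `A*01:01`. Two properties make this hard with conventional
Sanger sequencing-based typing (SBT):

* **Cis/trans (phase) ambiguity.** Sanger reads both chromosomes at once, so
  a heterozygous sample yields IUPAC mixtures at variant positions. Every
  genotype pair whose superposition matches the trace is equally consistent:
  the *ambiguity string*. Clonal amplicon sequencing reads single molecules,
  phasing all variants within a read and collapsing most of these strings.
* **Null alleles.** Alleles such as `A*01:01:01:02N` are not expressed on
  the cell surface — transplantation-relevant — yet often differ from their
  expressed counterparts only in introns. They can only be excluded when
  intronic sequence flanking the exon is read and compared.

## The workflow model

The package mirrors a fusion-primer amplicon assay on a pyrosequencing-class
instrument, as a chain of tibble-in/tibble-out stages:

1. **Panel** (`mock_panel()`): 17 amplicons over HLA-A (exons 2–4),
   -B (1–4), -C (1–4, 7), generic DRB (2, 3), -DQB1 (2, 3) and -DPB1 (2).
   Each fusion primer is adapter ‖ 10 bp MID ‖ template primer. Five short
   amplicons form the *short pool* (pooling factor 0.5), the remaining 12
   the *long pool*; DRB exon 2 carries factor 6 because the generic DRB
   primers co-amplify DRB1, DRB3/4/5 and pseudogenes, diluting per-locus
   depth. Primer footprints that extend into an exon (DQB1 exon 2: 9 bases
   5′, 3 bases 3′; DRB exon 2: 21 bases 3′) are masked from matching — the
   PCR primer overwrites the template there, which is also why a variant
   under the primer (the `DRB1*03:68N` analogue) is undetectable.
2. **Library preparation** (`fit_standard_curve()`,
   `concentration_to_molecules()`, `compute_pool_plan()`): fluorometric
   quantification against an 8-point 0–100 ng/µl standard series with an
   r² > 0.98 QC gate, conversion to molecules/µl using an average
   double-stranded base-pair mass of 660 g/mol/bp (standard practice;
   configurable), and a two-pool plan with
   `pooling_factor × 10⁹` molecules per amplicon. Low-yield amplicons are
   flagged for re-PCR (volume > 20 µl), never silently rescaled.
3. **Preprocessing** (`demultiplex()`, `trim_reads()`): a read is assigned
   iff its first 10 bases *exactly* equal a known MID and the following
   bases exactly equal a panel primer; everything else is kept in an
   unassigned pool with its reject reason. Trimming removes MID and primer
   and cuts after the targeted exon (MID + primer + primer-to-exon distance
   + exon length, plus an offset), in `exon_plus_flank` mode retaining up to
   10 bp of intron flank on each side where the amplicon geometry provides
   it. Reverse reads are reverse-complemented first so all downstream
   coordinates are in forward gene orientation.
4. **Genotyping** (`partition_layers()`, `build_haplotype_clusters()`,
   `call_genotype()`, `exclude_null_alleles()`): described below.
5. **Reporting** (`build_run_report()`, `concordance()`,
   `export_4digit()`): run metrics named after the usual sequencing report
   fields (passed filter reads, median read length, per-amplicon counts),
   a per-sample typing report with candidates and exclusions, and a flat
   4-digit export.

## The calling engine

**Layers.** Per amplicon, each trimmed read's best mismatch count
(substitutions + gap bases, computed as a fitting alignment with free end
gaps on the read's flanks) over all alleles of the amplicon's target loci
decides its layer: ≤ `fail_threshold` (default 4) → *master*; otherwise
*failed* (pseudogene-derived or heavily erroneous reads; the packaged
pseudogene sequences sit ≥ 8 substitutions from every functional allele).
On the generic DRB amplicons, reads whose 5′ and 3′ exon segments
best-match *different* loci without equalling any single allele are
*deactivated* as PCR crossover chimeras. Reads can be moved between layers
explicitly (`move_reads()`), mirroring manual review.

**Clusters.** Master reads are grouped by exact trimmed sequence; groups
differing only in one homopolymer run length are merged — the
characteristic pyrosequencing error. The divergent run length is resolved
by a direction-unanimity rule: if exactly one sequencing direction is
internally unanimous at that run, its length wins; otherwise weighted
majority with forward reads breaking ties. This encodes the manual fix for
the 5-base C homopolymer at the start of C*07 exon 4, where clean forward
reads override undercalled reverse reads. Clusters below
`min_cluster_fraction` (default 0.10) of master reads are dropped as noise;
at most two are kept and a surviving third sets the review flag.

**Pair search.** All allele pairs of the locus are enumerated; a pair is
compatible iff at every required amplicon each cluster consensus exactly
reproduces the covered exon span of one pair member (both clusters covered
when two exist). Pair assignment is free per amplicon because phase
*between* amplicons is physically unobservable — which is exactly why
exon-shuffled allele pairs remain in the ambiguity string. Reference
features that are ABSENT (unannotated introns are the norm in real
references) act as wildcards: an allele can never be contradicted by
sequence nobody deposited. A locus is `no_result` when any required
amplicon has fewer than `min_reads` (default 20) master reads; with the
simulated mean of ~200 reads per amplicon this mirrors reliable-call
practice.

**Phase layers.** For a candidate pair, `MM` is the total mismatch count
under the best globally consistent cluster-to-allele orientation; `MM3` and
`MM4` re-count with the exon 3 (exon 4) pairing swapped against the exon 2
anchor. A true pair shows `MM = 0` with nonzero `MM3`/`MM4` — the cis/trans
ambiguity an unphased method would face — while an exon-shuffle decoy shows
`MM > 0` with `MM3 = 0`, exposing the phase-between-exons ambiguity.

**Null-allele exclusion.** In `exon_plus_flank` mode, a candidate pair is
removed when a member's annotated intron flank conflicts with the observed
flank consensus; the discriminating feature (e.g. `intron2`) is recorded.
The exclusion is evidence-based and symmetric: if the sample truly carries
the null allele, the *expressed* variant is excluded instead. Alleles whose
distinguishing variation lies under a primer or outside every amplicon
(the `A*68:11N` analogue in exon 1) are retained with a warning — they need
orthogonal verification typing. In `exon_only` mode no exclusion happens.

**Ambiguity metrics.** `sanger_ambiguity_count()` builds the per-exon IUPAC
superposition of the two haplotypes over the exons a generic SBT kit covers
(A/B: 2–4; C, DQB1: 2–3; DRB, DPB1: 2) and counts all database pairs with
an identical superposition, deduplicated at 4-digit resolution, null
alleles included. `phased_pair_count()` is the clonal counterpart on exact
haplotype sequences, and `ambiguity_reduction()` is
`100 × (unphased − phased) / unphased`.

## The mock reference database

`mock_allele_db()` builds a deterministic nine-locus reference
("mock-3.7.0": A, B, C, DRB1, DRB3/4/5, DQB1, DPB1, plus the `DRBP`
pseudo-locus) with compact genes — class I features total ~2.1 kb — and at
least eight alleles per typing locus. It deliberately packages the allele
classes that stress a typing assay: intron-only null/low-expression
variants (`A*01:01:01:02N`, `A*24:02:01:02L`, `B*15:01:01:02N`), an exonic
6 bp deletion null (`A*74:12N`), a primer-shadowed null (`DRB1*03:68N`
analogue), an uncovered-exon null (`A*68:11N` analogue), an exon-shuffled
decoy pair (`A*80:01`/`A*81:01`), a cis/trans quartet
(`B*07:02:01`/`B*08:01` vs `B*44:02`/`B*44:03` share one exon 2–4
superposition), and C*07 alleles opening exon 4 with `CCCCC`. The DRB
family shares its primer regions and carries locus-identifying substitution
blocks in both halves of each exon so that crossover chimeras switch locus
identity mid-read.

The database is generated in code rather than shipped as a file to keep the
repository lean; `read_allele_db()`/`write_allele_db()` provide a
byte-stable annotated-FASTA dialect (1-based inclusive feature coordinates
in the header), with a single-locus example under `inst/extdata/`.

## The simulator and its error model

`simulate_genotypes()` draws diploid genotypes per sample and locus, 10.3%
homozygous by default — the composition of a realistic validation panel.
`simulate_reads()` emits fusion-primer reads (MID ‖ primer ‖ template),
both orientations equiprobable, with depth per amplicon negative-binomial
(`size` 10) around `mean_depth × pooling_factor`, short-pool amplicons
boosted ×1.4 for their higher emulsion-PCR efficiency. The error model
defaults — chosen once as plausible instrument-class values, stated here
because no published constants exist for them — are:

| parameter | default | meaning |
|---|---|---|
| `substitution_rate` | 0.1 %/bp | uniform miscalls, MID included |
| `homopolymer_base_rate` | 0.5 % × (run − 1) | per run ≥ 3, ±1 bp equiprobable |
| `reverse_bias` | 3× | extra homopolymer errors near the 5′ exon start on reverse reads |
| `chimera_rate` | 5 % | DRB exon 2 crossover chimeras, single uniform crossover |
| `pseudogene_fraction` | 10 % | DRB exon 2 reads drawn from the pseudo-locus |

Same seed, byte-identical FASTA. The simulator records per-read truth
(source allele, injected error counts, read class) for recovery testing.

What the simulation does *not* emulate: flowgram-level signal, quality
scores, emulsion-PCR bead statistics, well-level metrics (carried as null
pass-through report fields), context-dependent substitution hotspots, and
the allele diversity of a full curated reference release (dozens versus
thousands of alleles).
Passing the synthetic validation therefore demonstrates that the decision
logic — demultiplexing, layering, clustering, pair enumeration, exclusion —
is correct under a realistic error process at desk scale; it does not
certify performance on real instrument data.

## Numerical and design choices

* **Mismatch convention.** Alignment distance counts substitutions plus
  gap bases, with reference overhang free (fitting alignment); verified
  against a brute-force DP oracle in the tests.
* **Trimming offset.** Default 10 bp of retained intron flank per side in
  `exon_plus_flank` mode, 0 in `exon_only`; the flank is what makes
  intron-based exclusion possible, and the slack absorbs small upstream
  indels so the cut never eats exon bases.
* **Thresholds.** `fail_threshold` 4 separates sequencing-error reads
  (almost always ≤ 2 edits at the default rates) from pseudogene reads
  (≥ 8 by construction). `min_cluster_fraction` 0.10 is far below a real
  haplotype's expected 50 % share yet far above the share of any recurrent
  error sequence. All thresholds are exposed as arguments.
* **Tie-breaks.** Candidates sort lexicographically; cluster order within
  an amplicon is by read count, then sequence; consensus run-length ties
  fall to the forward direction.
* **Degenerate inputs.** Empty read sets produce all-zero reports; a locus
  without master reads is `no_result`; an amplicon quantified at 0 ng/µl is
  flagged `failed` in the pooling plan rather than dropped; all-identical
  standard concentrations are a degenerate-fit error.
* **Batching.** `validation_run()` processes samples in sequencing runs of
  ten (the panel carries 14 MIDs), each with its own run id, MID
  association and seed offset, and accumulates typing results across runs —
  the way a multi-run validation study is actually conducted. The scaled
  problem sizes used throughout (20 samples × 3 class I loci × depth 200
  for the validation; smaller for unit fixtures) were chosen as the
  package's desk-scale study design.
* **Sanger exon sets.** The SBT comparison uses full exon sequences per
  locus kit; the clonal counterpart in reports uses the same convention so
  the unphased count can never undercut the phased count. Ambiguity counts
  are of distinct 4-digit genotype *pairs* (suffixes kept), one documented
  choice among the possible "string" conventions.

## Known limitations

* Exact-match demultiplexing discards every read with an error in MID or
  primer (a few percent at default rates); the fuzzy MID mode (≤ 1
  mismatch, safe at pairwise distance ≥ 3) exists behind a flag.
* Trimming is arithmetic, not alignment-based: reads with large upstream
  indels can be cut slightly off; such reads rarely survive exact-sequence
  clustering, which is the safety net.
* DRB3/4/5 presence is decided purely by cluster evidence; no copy-number
  model.
* Novel alleles are not named: they surface as a best pair with persistent
  nonzero MM and a review flag.
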