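---
title: "Dual-strand amplicon panel: models, parameters and design choices"
author: "dstpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-strand amplicon panel: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Somatic genotyping of formalin-fixed, paraffin-embedded (FFPE) tumour
samples is hard for two reasons. First, fixation fragments the DNA and
chemically damages it — most importantly by deaminating cytosines, which
sequence as C:G→T:A substitutions and mimic true low-fraction mutations.
Second, clinically actionable variants may be present at allele fractions
of a few percent, close to or below the artifact floor.

`dstpanel` models a complete validation workflow for an assay built
around two countermeasures:

* **Short amplicons.** Each target is amplified as a 120–150 bp amplicon
  (22–30 base primers), so even heavily fragmented templates remain
  amplifiable.
* **Dual-strand libraries.** Each sample yields *two* sequencing
  libraries, one built from the forward strand of every template molecule
  and one from the reverse strand. A true variant is present on both
  strands of its molecule, so it appears in both libraries. A
  single-strand chemical lesion (a deaminated cytosine) exists on one
  strand only, so its signal is confined to one library. Reporting only
  variants detected independently in both libraries removes this entire
  artifact class structurally, not statistically.

The package contains a panel model and design validator, a synthetic-data
generator for FFPE-like samples, a primer-anchored dual-library caller, a
qPCR-based triage layer, and the validation statistics used to judge the
assay (per-base confusion, Wilson confidence intervals, allele-fraction
concordance, cohort rates).

## The panel model

The assay targets 48 exons of 16 actionable genes
(`panel_gene_table()`), tiled by 150 amplicons. Real genomic coordinates
are proprietary to the vendor design and are in any case unnecessary for
validating the computational workflow, so `build_demo_panel()` fabricates
one toy contig per gene whose exon structure matches the published gene
list, and tiles each padded exon with amplicons satisfying every design
constraint:

* amplicon length (primers included) in [120, 150] bp;
* primer length in [22, 30] bases, GC fraction within [0.2, 0.8];
* at least 5 bp of intronic padding around each exon (an asymmetric
  −7/+6 profile can be selected in `design_constraints()`);
* every target base covered by at least one amplicon insert, adjacent
  amplicons overlapping by at least 1 base;
* no primer footprint over a position in a supplied common-SNP blacklist
  (a file stands in for a live database lookup, for reproducibility).

Exon sizes are drawn in the 60–220 bp range and the merged target
footprint is calibrated to exactly 8,870 bp, the assay's theoretical
on-target size. (The assay's documentation also quotes "approximately
20 Kb per library"; the relationship between the two figures — primers,
both pools — is not specified, so only the 8.87 kb figure is modelled.)
All coordinates are 0-based half-open internally; VCF output is 1-based.

## The synthetic-data generator

`make_sample()` builds, per amplicon, a pool of `n_molecules`
double-stranded source molecules (default 2000, a realistic template
count for a few ng of FFPE DNA). Extension–ligation chemistry captures
each target independently, which is why molecules are per-amplicon. Each
molecule contributes one forward-strand and one reverse-strand template.

* **Truth variants** (SNV, MNV, insertion, deletion) are assigned to
  molecules independently with probability equal to the target allele
  fraction; a carrier molecule carries the variant on *both* strands.
  Variants are only realised inside amplicon inserts — primer footprints
  are synthesised from the oligo, so a variant under a neighbouring
  amplicon's primer is invisible to that amplicon (and its primer bases
  are trimmed before genotyping, so no reference dilution occurs either).
  The simulator rejects variants that straddle an insert boundary.
* **Fragmentation** draws a lognormal fragment length per molecule
  (default mean 3000 bp, sdlog 0.35) and removes molecules shorter than
  their template; a per-molecule crosslink-failure probability removes
  more. `calibrate_fragmentation()` solves for the fragment-length mean
  whose expected survival equals `2^-delta_qc`, so presets can place
  samples at delta-Qc ≈ 1, 4.3, 6.6, 10.1 or 15.1 — the interesting
  points of the triage scale.
* **Deamination** converts cytosines to thymines independently per
  cytosine per *single strand* at rate `d` (default 3×10⁻⁴ per cytosine
  per molecule). On the reverse strand the lesion appears as G→A in
  top-strand coordinates. No published per-cytosine rate exists for this
  assay; the default was chosen once so that per-site artifact fractions
  (~10⁻³–10⁻²%) sit well below a 1% true variant. A `jackpot` option
  inflates chosen sites to several percent for stress-testing the
  consensus filter — a crude stand-in for PCR jackpot amplification of an
  early-cycle lesion.
* **Sequencing** (`simulate_libraries()`) draws per-amplicon, per-library
  read-pair counts from a negative binomial around the target depth
  (default 1000 pairs, size 80), samples surviving molecules of the
  matching strand with replacement, and emits 2×100-base paired reads
  with substitution errors at rate 10⁻³ per base. Correct bases carry
  Q30, substituted bases Q20 — deterministic qualities that make a
  base-quality floor meaningful without modelling recalibration.
  Dilution series map library concentration to depth linearly
  (`depth_scale`), the simplest faithful reading of "normalized to 4 nM".

Everything downstream of a seed is deterministic: identical seeds give
byte-identical FASTQ files.

What the generator does **not** model: PCR chimeras and polymerase
slippage, jackpot structure beyond the single-site option, melanin or
other inhibitors, base-quality miscalibration, and any coupling between
depth and sample quality other than via the explicit depth scale. A green
validation here therefore shows that the *bioinformatic* layer behaves as
designed under the stated noise models, not that the wet assay would.

## The caller

Reads are amplicon copies, so "alignment" is primer-anchored positional
mapping:

1. **Assignment** (`assign_and_trim()`): each mate is assigned to the
   unique primer (forward or reverse, across all amplicons) that best
   matches its prefix within `k = 2` mismatches; ties are discarded and
   counted. Matching uses an exact-lookup fast path with a
   primer-half-seed fallback, so only reads with errors in both primer
   halves pay for a full scan.
2. **Pileup** (`build_pileup()`): trimmed reads are compared column-wise
   against the reference window they must cover. Reads whose mismatch
   pattern could hide an indel (≥ 3 mismatches, or any mismatch within 6
   bases of the raw read tail, where a breakpoint produces few visible
   mismatches) are realigned with an affine-gap global–local aligner
   (match +1, mismatch −2, gap open 5, extend 0.5; compiled, the one hot
   loop in the package). The primer is re-attached during realignment to
   pin the alignment to its anchor — without this, a free subject start
   can slide a deletion read into a spurious insertion interpretation.
   Only insert positions are tallied, and only bases at or above the Q20
   quality floor. Depth at a position is base observations plus
   deletion-spanning observations.
3. **Per-library calling** (`call_library()`): a variant is emitted where
   per-library depth ≥ 100, supporting observations ≥ 4 and allele
   fraction ≥ 0.005. These floors are deliberately permissive: a 1%
   variant at 1000–2000 pairs per library has tens of supporting
   observations, while artifact control is delegated to the consensus.
   The original assay's exact per-library filters are not public, so
   these values are this package's own, config-overridable choices.
   Indels are left-normalized (trim shared suffix, extend left, trim
   shared prefix — property-tested against exhaustive enumeration).
   Adjacent SNVs are merged into an MNV when their supporting reads are
   shared in ≥ 90% of cases (an invented rule; the assay reports MNVs but
   not how they are formed).
4. **Consensus** (`consensus_calls()`): variants keyed by (contig,
   position, ref, alt) present in both libraries are `PASS`, with the
   combined fraction the arithmetic mean of the two library fractions (a
   pooled-count alternative is selectable; reported assay results give a
   single VAF per variant without stating a combination rule). Single-library variants are
   retained for audit as `single_library` — never PASS — or `low_depth`
   when the confirming library lacked callable depth.

Because both mates of a pair overlap mid-insert, positional depth can
exceed the pair count; allele-fraction estimates are unaffected (both
mates reflect the same molecule) and per-amplicon depth for QC purposes
is counted in pairs.

## Triage and the depth cutoff

`delta_qc()` is the Cq difference between the sample and an undamaged
control; the simulator's qPCR model gives Cq = Cq₀ − log₂(amplifiable
fraction), anchoring delta-Qc = 4 at a 1/16 amplifiable fraction. Samples
with delta-Qc ≤ 4 are standard; above 4 they are flagged degraded but
*still processed* — that is the assay's point — with an input scale-up of
2^(delta-Qc − 4), capped (the manufacturer's dilution lookup is not
published; this formula is stand-in plumbing). The boundary value 4 is
standard, reading "> 4" literally. Interpretability is decided only after
sequencing: a sample is interpretable when the median per-amplicon pair
depth of *both* libraries reaches the cutoff (default 700).

`determine_depth_cutoff()` derives that cutoff from a dilution series: it
returns the smallest realized median depth within the maximal prefix of
fully concordant points (no false positives, no false negatives),
scanning from the highest concentration down — verified against a
brute-force scan.

## Validation statistics

Per-base confusion counts treat every interrogated reference position as
one potential true negative, indels counted at their normalized anchor.
Sensitivity, specificity, accuracy and precision are reported with
**Wilson score** intervals. The Wilson choice is deliberate and verified:
for 135/135 the Wilson lower bound is 97.23% (printed 97.2%), whereas
Clopper–Pearson gives 97.30% — only Wilson reproduces the assay's
published intervals. For k = n the lower bound reduces to
1/(1 + z²/n), which the tests check against a numeric inversion of the
score test. Metrics with zero denominators are flagged undefined rather
than silently reported.

Concordance between expected and observed allele fractions uses Pearson
correlation on replicate means, with per-variant SD (n−1) and
CV% = 100·SD/mean. Reported percentages round half away from zero to one
decimal (92.857% prints as 92.9%). A note on the published
inter-laboratory table bundled in `reference_standard_stats()`: CVs
recomputed from the rounded means and SDs differ from the printed CVs by
up to ~0.11 (rounding propagation), so the regression test uses a 0.15
tolerance.

## Problem sizes used in the test-suite experiments

The validation experiments run at the assay's stated conditions: the
12-variant multiplex standard at 1000 pairs per amplicon per library with
six replicates; the FFPE multiplex control (1%/2%/3% spikes) at 2000
pairs with three replicates; and a per-base method comparison totalling
53,534 interrogated nucleotides carrying 135 variant positions at ≥ 5%
allele fraction, assembled from whole-panel samples (8,870 bp each) plus
one partial sample, sequenced at 500 pairs per amplicon — fractions that
high are detected with large margin at any depth in the hundreds, so the
lower depth changes nothing but runtime. Property suites (artifact
suppression, normalization, cutoff determination) run on a miniature
3-amplicon panel where each simulated sample takes about a second.

## Known limitations

* Molecules are independent per amplicon; there is no shared genomic
  fragmentation structure across overlapping amplicons.
* The consensus removes single-strand lesions; it cannot remove an
  artifact present on both strands of a molecule (e.g. a true early-PCR
  error propagated to both libraries — not modelled here).
* MNV merging and the delta-Qc→input scaling formula are package
  inventions standing in for unpublished procedures, and are labelled as
  such above.
* The cohort-level mutation spectra of the original clinical study depend
  on patient-level data that is not public; the package reproduces the
  analytic statistics and control-sample experiments, not the cohort's
  biological content.
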