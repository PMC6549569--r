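---
title: "Error-corrected consensus sequencing and ctDNA quantification with didaseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error-corrected consensus sequencing and ctDNA quantification with didaseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(didaseq)
```

## The problem

Circulating tumor DNA (ctDNA) is the tumor-derived subfraction of cell-free
DNA (cfDNA) in blood plasma. In patients monitored across treatment it can
sit at variant allele fractions (VAF) of 0.01% and below — far beneath the
~0.1–1% error floor of standard sequencing. didaseq implements the analysis
side of a dual-indexed degenerate adapter (DIDA) assay: every input molecule
receives a degenerate molecular barcode (UMI) on each adapter side, so all
PCR and sequencing copies of one molecule can be recognised, grouped, and
collapsed into a single-strand consensus sequence (SSCS). Consensus removes
the errors introduced after barcoding; what remains is a small residual
background measured from negative controls, against which a one-sided
binomial test decides whether a blood draw contains tumor signal.

## The pipeline model

1. **Demultiplexing and UMI extraction** (`demultiplex`): each fragment has
   two 14-base index reads; the first 8 bases are a fixed sample index, the
   remaining 6 the degenerate barcode. The split is configurable
   (`index_layout`) — 4–6 base UMIs in leading or trailing position —
   because adapter designs vary and the cycle split is a property of the
   kit, not of the method. Fixed indices match the sample sheet within
   `max_mismatch` per index (default 0; conservative demultiplexing
   minimises sample bleed-through). The sheet is rejected outright if two
   samples could both match one read at the chosen radius.
2. **Family grouping** (`group_families`): reads sharing chromosome,
   fragment start/end (the full insert span), orientation, and the ordered
   UMI pair are presumed copies of one molecule. Coordinates are 0-based
   half-open internally. Families keyed on a UMI containing `N` are dropped
   and counted: an ambiguous barcode could silently merge distinct
   molecules.
3. **Consensus calling** (`call_sscs`): families need at least
   `min_family_size = 3` reads, otherwise the molecule is omitted. At each
   position the modal base is called when it reaches `agreement = 0.90` of
   the non-`N` member bases, *inclusive* — "90% agreement" is read at face
   value, so 9 of 10 calls the base. Below threshold, or on a tie, the
   position becomes `N`. `N`s in members are excluded from the denominator
   because they carry no evidence. Families whose members disagree on
   aligned span (the indel analogue of a mixed cigar class) are dropped and
   counted rather than consensused — the tracked sites are SNVs only, and
   fabricating an indel consensus would be worse than omission.
4. **End masking** (`mask_ends`): five bases at either consensus end become
   `N`, removing ligation- and quality-degraded positions. Consensus reads
   of length ≤ 2 × 5 become all-`N` and are effectively blank.
5. **Mate-overlap collapsing** (`collapse_mate_overlap`): where the two
   mates of one fragment overlap, each reference position must contribute
   at most one consensus base per molecule. Agreeing mates keep the base;
   disagreeing mates give `N` (the conservative analogue of the consensus
   rule); an `N` on one mate defers to the other mate's call, again because
   `N` is absence of evidence, not counter-evidence.
6. **Tag-swap filtering** (`filter_tag_swaps`): PCR-mediated recombination,
   index hopping between co-multiplexed libraries, and single barcode
   errors all create consensus reads that duplicate an existing molecule.
   Within each group of SSCS sharing the *exact* same start and stop, any
   two records matching on either 6-bp barcode are clustered (transitively)
   and only one representative survives — the largest family, ties broken
   lexicographically by barcode pair, so output is deterministic. The
   filter is idempotent and never empties a position group. By default it
   compares across all samples in a run, since index hops by construction
   land in the wrong sample.

Counts are conserved at every stage: input families equal consensused
families plus the omissions by reason, and the pipeline metrics report each
term.

## The error model

Negative-control libraries (DNA known not to carry the panel mutations) are
sequenced through the same pipeline and their pileups pooled site-wise
(`pool_negative_controls`). Sites with a pooled control VAF strictly above
0.05 are excluded (`flag_high_error_sites`): errors of that magnitude are
dominated by recurrent mismapping, not polymerase chemistry, and would
poison a panel-wide rate. Zero-coverage sites are excluded as
uninformative.

The panel-wide error rate is the pooled count of *alt-matching* consensus
reads divided by the pooled informative (non-`N`) depth
(`estimate_error_rate`). Only alt-matching errors enter the numerator
because detection asks specifically about the patient's known alternate
allele at each site; other non-reference bases are tracked and reported but
are not part of the null. Per-substitution-class rates (e.g. `C>T`) are
reported for diagnostics by the same formula restricted to each class.

The conservative rate is an exact one-sided Clopper–Pearson 95% upper bound
(`binom_upper`, via the beta-quantile identity; at zero observed errors it
reduces to `1 − 0.05^(1/n)`). Exact binomial is the assumption-free choice
at rates near zero where normal approximations fail; one-sided because only
an *under*-estimated background inflates false positives. A two-sided
variant is available (`two_sided = TRUE`), which is equivalent to a
one-sided 97.5% bound.

## Detection, quantification, limit of detection

For each blood draw, mutant reads and informative depth are summed over the
included panel sites (`panel_vaf`); their ratio is the panel VAF. `N`
consensus calls are excluded from the depth so the binomial test's trials
are on the same scale as the error model's rate — counting `N`s as trials
would bias the VAF low by roughly the masked fraction (~12% under default
masking of 120-bp inserts) and make the test anti-conservative in depth.

`detect` computes the one-sided upper-tail binomial probability of the
observed mutant-read count at the model's upper-bound rate; `p < 0.05` is a
detection. The test is one-sided because ctDNA can only add mutant reads.

`mutant_genomes` converts VAF to an absolute abundance:

```
cfDNA concentration (ng/mL plasma) / 0.003 (ng/genome) × VAF
  = mutant genomes per mL plasma
```

with the per-genome mass an overridable named constant (3 pg per haploid
genome).

`lod` inverts the test: the smallest integer `k_min` whose tail probability
at the achieved depth falls below alpha, converted to a VAF
(`k_min / depth`) and optionally to mutant genomes per mL. By construction
`k_min` is detected and `k_min − 1` is not, a property tested over a
rate-by-depth grid. At a 1e-5 error rate and 3×10⁶ pooled depth (15 sites ×
200,000×), `k_min = 40`, i.e. an LOD VAF of 1.3×10⁻⁵ — comfortably below
one altered allele in 10,000.

Timepoints are classified three ways (`classify_timepoint`): `detected`;
`not_detected` when depth is adequate but the signal is statistically
indistinguishable from background (such points are reported at their
per-timepoint LOD for plotting); and `insufficient_depth` below a
configurable floor, default 10,000 consensus reads — the assay cannot make
an informative negative statement from a shallow draw. The floor is a
package default; no published threshold exists for it.
`mean_lod` averages finite per-timepoint LODs for display;
`build_timeseries` assembles the per-patient longitudinal table with
replicate means ± SEM per day.

## Panel selection

`filter_candidates` keeps SNVs with tumor VAF ≥ 0.1, ≥ 3 supporting reads,
and at least one alt read on each strand. `select_panel` always includes
passing variants in driver genes (default PIK3CA, TP53, AKT1), then fills
remaining slots preferring substitution classes outside `{T>C, G>A}` —
classes with systematically higher background — and, within class
preference, higher tumor VAF, with positional tie-breaks for determinism.
Classes are matched as written (not reverse-complement collapsed); the
collapse convention is configurable since either reading is defensible.
The default target of 20 sites sits inside the 10–50 range typical of
patient-specific panels; drivers are never sacrificed to the target size.

## The synthetic-data generator

`simulate_library` emulates the generative process the pipeline corrects:

- **Molecules**: `n_molecules` fragments, each assigned to one panel site,
  with normal fragment lengths (mean 120 bp, sd 15 — cfDNA-like insert
  sizes) and the site placed uniformly within the fragment. Each molecule
  carries the alt allele with probability `true_vaf`, a unique random UMI
  pair, and a random orientation.
- **PCR**: each sequenced read descends through `pcr_cycles = 8` binary
  lineage splits; per-base errors are drawn per lineage node at
  `pcr_error_rate = 1e-6` per base per cycle (a proofreading polymerase)
  and inherited by every read under that node. This produces the jackpot
  structure that matters for error modelling: an error before a family's
  most recent common ancestor is shared by all its reads and *survives
  consensus* — exactly the residual background the negative-control model
  measures.
- **Sequencing**: independent per-read substitutions at
  `seq_error_rate = 1e-3` per base (typical raw Illumina error), which
  consensus almost entirely removes.
- **Reads per molecule**: 1 + geometric with mean 6 (truncated at 30),
  giving the skewed family-size distribution real libraries show; ~69% of
  molecules reach the minimum family size of 3.
- **Index hopping**: each read swaps its fixed index to another library
  with probability `index_hop_rate`, landing in the wrong sample bin with
  its coordinates and UMIs intact — the artefact the tag-swap filter
  removes.

All randomness flows from one master seed through named substreams, so a
fixed seed gives byte-identical output and changing, say, the hop rate does
not perturb the molecule draw. Reads are emitted pre-aligned (the simulator
knows the truth), bypassing external alignment; `sim_read_quartet` can emit
the FASTQ-style quartet for end-to-end demultiplexing runs.

`simulate_dilution_series` scales the expected mutant-molecule fraction by
each dilution factor against a constant background, in replicate libraries
with deterministically derived seeds — the in-silico analogue of serially
diluting tumor DNA into unmatched buffy-coat DNA in triplicate.
`simulate_consensus_pileups` draws post-consensus pileup counts directly
from the binomial model (alt probability `true_vaf + error_rate`); it is
the statistical model the detection test inverts, and is used for
calibration and power studies at depths where read-level simulation adds
nothing but time.

### What the generator does and does not emulate

It reproduces the features the pipeline's correctness depends on: family
structure, jackpot PCR errors, dominant sequencing noise, barcode
collisions and index hops, dilution linearity. It does **not** model
base-quality variation (the pipeline ignores qualities), GC or capture
bias, indel errors, copy-number variation, fragment-end biology, or
mismapping — so the high-error-site exclusion is exercised only by
construction, not emergently, and passing tests demonstrate correctness of
the statistical machinery, not robustness to alignment artefacts in real
data.

## Numerical choices and problem sizes

- Exact binomial tails via `pbinom`; `lod`'s search starts at the binomial
  quantile and adjusts to the exact boundary, so it is exact for any
  rate/depth.
- The agreement threshold is applied inclusively with plain floating-point
  comparison; the count ratios involved (e.g. 9/10) are exactly
  representable against 0.90's double.
- Consensus of homogeneous families takes a fast path (the common case —
  at a 1e-3 sequencing error over 60-bp reads, ~94% of mates are
  error-free); heterogeneous families go through the per-position tally.
- Validation problem sizes were fixed by power analysis before running:
  the dilution-series check uses 45,000 molecules per library (15-site
  panel, factors 1/0.1/0.01 in triplicate), at which binomial sampling
  error contributes about 0.03 SD to the fitted slope against the
  [0.9, 1.1] acceptance band; calibration and coverage checks use the
  pileup-level generator at the assay's working depth (15 × 200,000×).

## Known limitations

- SSCS only: without duplex (double-strand) consensus, first-cycle PCR
  errors on the barcoded strand are indistinguishable from real variants;
  they are what the error model absorbs.
- No post-consensus realignment: SSCS coordinates are inherited from the
  input alignments. Real pipelines may realign consensus reads; the CLI
  documents where such a hook would sit.
- The binomial null treats consensus reads as independent trials; residual
  family-structure correlation (e.g. two SSCS from the two strands of one
  molecule) is not modelled.
- No multiple-testing correction across timepoints, by design: each draw
  is an independent clinical question.
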