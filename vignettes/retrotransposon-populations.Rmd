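---
title: "Retrotransposon copy populations: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrotransposon copy populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(retropop)
```

# The scientific model

An LTR retrotransposon inserts as a unit with two identical long terminal
repeats flanking an internal coding region, and duplicates a short stretch of
host DNA (the target-site duplication, TSD) on both sides. From the moment of
insertion the copy is a fossil: the two LTRs accumulate substitutions
independently, so their divergence measures the insertion age; the internal
coding sequence degenerates (in-frame stop codons, frameshifts); and copies
descending from the same replicating "master" lineage share that lineage's
diagnostic substitutions, which makes sub-families recoverable from a variant
matrix exactly as populations of individuals are recovered from SNP panels.

`retropop` treats each retrotransposon copy as an individual genome:

1. **Discovery.** Chromosomes are scanned with family LTR consensus
   sequences. A hit is retained when it covers >95% of the consensus at >80%
   identity with at most 5 bp missing per side. Same-strand hits at the
   family-specific outer distance are paired into full-length candidates;
   the internal region must align in translation to the family polyprotein;
   the shortest and longest 3% of candidates are flagged (large structural
   variants); TSDs are detected but not required (observed TSD fractions in
   real data are well below 100%, so requiring them would bias the
   population); unpaired complete LTR hits with a TSD are solo-LTRs (the
   product of intra-element recombination).
2. **Dating.** For each copy the two LTRs are aligned locally (gap open 10,
   extend 0.5); transitions (P) and transversions (Q) are counted over
   gap-free columns; the Kimura two-parameter distance
   K = -1/2 ln((1-2P-Q) sqrt(1-2Q)) corrects for multiple hits while
   distinguishing the two substitution classes; age = K / (2r) because both
   LTRs mutate. The clock r = 1.3e-8 substitutions per site per year is the
   standard rate for grass intergenic DNA.
3. **Sub-family divergence.** Copies with near-intact reading frames (at
   most three in-frame stops, no frameshift) are paired across groups, their
   predicted proteins aligned, and the alignment back-mapped codon by codon.
   Only four-fold degenerate third positions are counted (Ala, Gly, Leu,
   Pro, Arg, Ser, Thr, Val; for the six-codon Leu/Arg/Ser only the CT/TC/CG
   codon groups are four-fold), and only when the two codons agree at their
   first two positions — this guards against counting third positions whose
   context differs. The divergence-time estimate is the mode (peak histogram
   bin midpoint) of the per-pair d/(2r) distribution, which is robust to the
   long right tail created by copies that kept mutating after insertion.
4. **Variant matrix and PCA.** All copies are aligned to the family
   consensus (gap open 50, extend 0.1 — long gaps are cheap, so diverged
   copies still align collinearly). Substitutions become haploid allele
   calls; insertions in copies are ignored (they have no consensus
   coordinate); deletions are missing data. Sites with minor-allele
   frequency below 10% or missingness above 90% are removed. PCA uses
   site-mean imputation and centring (optional EIGENSTRAT scaling), with a
   deterministic sign convention so runs are comparable. Sub-families are
   regions in PC1/PC2 — user-defined polygons, exactly as an analyst would
   draw them, stored as plain data so the manual step is reproducible; a
   k-means/convex-hull proposal is available but only advisory.
5. **Summaries.** 40-Mb chromosomal bins, activity-through-time tables per
   sub-family and sub-genome, and introgression-segment signatures: segments
   with at least 40 elements are projected with per-sub-genome controls, and
   a segment is "distinct" when its PC1/PC2 centroid is farther than 2x the
   nearest control's RMS dispersion from that control's centroid. This
   formalises the visual "forms a distinct group" judgement; the factor 2 is
   configurable and was fixed before any calibration run.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `rate` | 1.3e-8 | subst/site/yr | grass intergenic clock used for all dating |
| `kappa` | 2 | — | transition/transversion rate ratio of the simulator's K2P process |
| `min_identity`, `min_coverage` | 0.80, 0.95 | fraction | hit retention thresholds of the scan |
| completeness | 5 | bp/side | maximum missing LTR sequence per side |
| `distance_window` | element length ±1 kb | bp | admissible outer LTR-pair span per family |
| `tsd_length`, `max_mismatches` | 5, 2 | bp | TSD rule; ±2 bp boundary jitter tolerated |
| `tail_fraction` | 0.03 | fraction | size-distribution trim per tail (ceiling) |
| `maf_min`, `missing_max` | 0.10, 0.90 | fraction | variant-site filters |
| `mode_bin_years` | 1e5 | years | histogram bin for the divergence mode |
| `min_elements` | 40 | copies | minimum segment size for a PCA signature |
| `distinct_factor` | 2 | — | centroid distance multiple for the distinct flag |

# What the simulator emulates — and what it does not

`simulate_te_genome()` plants a family of sub-family lineages into an i.i.d.
random background (default GC 0.46):

* Each sub-family consensus derives from the family ancestor by a K2P
  substitution process with expected per-site count `rate x
  lineage_divergence_years`; mutations that would create an in-frame stop in
  the consensus CDS are reverted, so lineage consensuses stay
  coding-competent and dead-on-arrival statistics are controlled solely by
  `doa_lambda`.
* Each copy samples an age from its sub-family's activity wave (normal,
  truncated at zero), starts from the lineage consensus with both LTRs
  identical, and accumulates post-insertion substitutions at `rate x age`
  per site — LTRs independently, so the expected LTR-LTR divergence is
  `2 x rate x age`. Poisson(`doa_lambda`) stop codons are injected at
  insertion; small (1-3 bp) indels at a low rate give the size trim
  something to trim; a TSD is duplicated with per-base corruption
  probability `tsd_mismatch_prob`; an exact count of copies
  (`round(solo_fraction x copy_count)`) is reduced to solo-LTRs, so planted
  totals are reproducible. Decoy half-LTR fragments without TSDs exercise
  false-positive filtering.
* Introgression intervals are inputs (not detected): copies planted inside
  them take the interval's own sub-family mix, which is how a divergent
  donor lineage is modelled.

Because copies branch off a *fixed* lineage consensus, the divergence
between copies of two lineages is `2·r·T_split` plus each copy's own
post-insertion divergence `r·(age_a + age_b)`. Real populations have the
same property (the master lineage keeps evolving until each insertion), and
the four-fold estimator consequently dates splits slightly above the lineage
split when copies are old. The calibration worlds therefore use young
activity waves, as the estimator's intended inputs (near-intact, mostly
young copies) do.

The simulator does **not** model nested insertions (the pipeline explicitly
excludes interrupted copies), gene content, recombination, rate
heterogeneity along the sequence, or population-genetic drift. A green
recovery test therefore establishes correctness of the estimators under the
stated substitution model — not robustness to nested or fragmented copies,
which are out of scope by design.

# Numerical and design choices

* **Alignment engine.** Affine-gap Gotoh DP in C++; a gap of length L costs
  `gap_open + L x gap_extend`, which is the convention under which the
  stated penalty pairs (10/0.2, 10/0.5, 50/0.1) are applied. Traceback ties
  are broken diagonal > up > left and the local traceback starts at the
  maximum cell with the smallest coordinates, so outputs are deterministic.
  Default nucleotide scores are match +2 / mismatch -1 (simple integers keep
  the brute-force oracle exact); the genome scan uses mismatch -2 so that,
  as with blastn-style extension, alignments cannot creep through flanking
  non-homologous sequence and inflate consensus coverage. Protein alignment
  uses BLOSUM62 with the stop symbol scoring -4 against everything. An
  optional band accelerates copy-versus-consensus alignment (default
  half-width 250 against ≤3 bp planted indels); banding is never used where
  the optimum could leave the band.
* **Consensus rules.** Majority per column over non-gap residues; columns
  with a gap fraction above 0.5 are dropped; ties break alphabetically and
  are reported. These conventions are this package's own (the behaviour of
  ad-hoc consensus scripts on ties is generally unspecified).
* **Greedy pairing.** When three hits A, B, C admit both A-B and B-C, A-B is
  paired and C is left over (left-to-right, nearest admissible partner) — a
  documented resolution of an ambiguity the thresholds alone do not decide.
* **Size trim marks, not deletes.** The flagged 3% tails stay in the output
  with `size_trimmed = TRUE`, keeping the filter auditable; population
  analyses exclude them, recovery is measured on full-length calls.
* **TSDs recorded, not required.** Retention does not depend on a TSD;
  solo-LTR calls do require one (an unpaired hit without a TSD is an
  unclassified fragment).
* **MAF denominator.** "Occurs in at least 10% of copies" is computed over
  non-missing calls (the natural reading for sites inside common deletions);
  `maf_all_copies = TRUE` switches to the all-copies denominator. The
  boundary is inclusive with a 1e-9 tolerance so exactly-10% sites pass.
* **Missing-data cutoff.** Applied per site (drop when >90% of copies are
  missing); a per-copy variant is available through alignment coverage
  filtering (`min_cov` in `align_copies_to_consensus()`).
* **Multi-allelic sites.** Up to three alternate alleles are kept, ordered
  by decreasing count then alphabetically; rarer alleles become missing.
* **Degenerate inputs.** Identical LTRs date to exactly 0; saturated K2P
  corrections (1-2P-Q <= 0 or 1-2Q <= 0) return a "saturated" status, and
  alignments covering <50% of the shorter LTR an "undatable" status, rather
  than numbers. `extract_cds()` reports "no CDS" for alignments below 60%
  identity or 60 columns (random sequence chains low-scoring local
  alignments under cheap gap extension; the guard keeps junk out of stop
  counts).
* **Divergence mode.** Fixed-width histogram (default 100 kyr), midpoint of
  the peak bin; the bin width trades resolution against stability of the
  peak and matches the age-bin width of the activity tables.
* **Cross-group pairs only.** Within-group pairs would dilute the divergence
  signal toward the within-lineage age distribution, so the estimator uses
  cross-group pairs exclusively.
* **PCA normalization.** Centring is the default; EIGENSTRAT-style scaling
  is provided because SNP tooling commonly applies it. On these matrices the
  cluster structure is robust to either choice.

# Known limitations

* Discovery assumes consensus LTRs are available; de novo structural
  discovery (LTRharvest-style) is out of scope.
* Nested and fragmented copies are neither simulated nor annotated.
* No confidence intervals on ages or divergence times (a bootstrap over
  pairs would be a natural extension).
* The "distinct cluster" criterion is a summary in two components; real
  introgression analysis should inspect the projection (see
  `autoplot.te_pca()`).
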