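---
title: "Confirming additive nucleotides in Sanger ITS traces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confirming additive nucleotides in Sanger ITS traces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itshybrid)
```

## The problem

Direct Sanger sequencing of the nuclear ribosomal internal transcribed
spacer (ITS1--5.8S--ITS2) from a heterozygous plant shows *additive
nucleotides*: positions where two bases appear simultaneously as a double
peak, written with IUPAC codes (Y = C+T, R = A+G). Because the rDNA repeats
of the two parental lineages are amplified together, the relative height of
the secondary peak carries information about the parental mixture. The
difficulty is telling a genuine secondary peak from electrophoresis
background noise.

`itshybrid` implements a statistical confirmation procedure for such sites
and the downstream hybridization analysis for cultivated *Codonopsis*
germplasm: mixture calibration, ITS typing, hybrid-ratio estimation,
parental-lineage inference and a neighbor-joining phylogeny.

## The S/N statistics and the decision rule

At a query site with main-peak intensity $I_1$ and secondary-peak intensity
$I_2$, and with $I_0$ the average noise intensity over a window around the
site, the two statistics are

$$S = \frac{I_2}{I_1 + I_2}, \qquad N = \frac{I_0}{I_0 + I_1}.$$

Both are scale-invariant ratios on $[0, 1]$, so they can be compared
directly. Over sequencing replicates the package tests $S$ against $N$ with
a two-group one-way ANOVA (`anova_s_vs_n()`); with two groups the $F$
statistic is exactly the squared pooled-variance $t$ statistic, and a Welch
variant is available behind a flag.

`decide_additivity()` applies the decision rule:

* mean $S \ge 0.15$ (`direct_threshold`): the double peak is confirmed
  directly;
* mean $S < 0.15$ but the ANOVA is significant at $\alpha = 0.01$ **and**
  the $S$ mean exceeds the $N$ mean: confirmed by test;
* otherwise: not confirmed.

The directional requirement is a deliberate design choice: the two-sided
ANOVA would also fire when the secondary signal is significantly *below*
the noise level (which happens for a truly homozygous template, where the
secondary channel is bounded by the noise floor from above but its mean can
sit below the windowed noise statistic), and that is not evidence of a
second base.

### The noise window

$I_0$ is taken over an 11-position window centred on the site (positions
117--127 for the canonical site 122), **excluding** the query site, using
each window position's *second-largest* channel: the main peak at a
neighbouring position is true signal, so its runner-up channel is the
natural noise analogue of $I_2$. Window endpoints are arguments of
`extract_peaks()`, so the including-site convention or other widths are one
call away. Note a distributional consequence: the runner-up channel at a
pure position is the maximum of the three non-called noise channels, so the
windowed noise statistic sits slightly above the raw per-channel noise mean
($\mu + 0.846\,\sigma$ for three Gaussian draws).

### Two-strand confirmation

Before any statistics, `detect_candidate_sites()` requires the per-position
secondary ratio to exceed `min_secondary` on **both** strands at the same
ITS coordinate (reverse positions mapped through the reverse complement).
The default threshold 0.14 is about four replicate standard deviations
above the expected noise ratio (~0.099), so single-strand noise excursions
are essentially never flagged, while every confirmable heterozygous
fraction (15% and up, expected $S \ge 0.16$) always is.

## The synthetic-data generator

No raw instrument files are distributed, so the package ships a simulator
that emulates the study conditions.

* **Moment-level sampler** (`simulate_sn_replicates()`): $S$ replicates are
  truncated-normal draws around $a f + b$ with $a = 0.905$, $b = 0.025$ and
  SD 0.015; $N$ replicates around $0.11/1.11 \approx 0.099$ with SD 0.011,
  both truncated to $[0,1]$. The linear, slightly attenuated mean model is
  fit to the published calibration series of sequenced PCR mixtures
  (fractions 10--50%, five replicates each); the chosen slope/intercept
  reproduce every published per-fraction mean within 0.013 (the
  unconstrained least-squares fit, slope 0.923 / intercept 0.019, does so
  within 0.012 --- the difference is immaterial and both are exposed as
  `sim_params()` fields). This sampler is canonical for all calibration
  statistics.
* **Full trace renderer** (`render_trace()`): four channel intensities per
  position --- called channel at `amplitude`, other channels
  truncated-normal noise at `noise_mean_frac * amplitude`, and at
  heterozygous sites the minor channel set to $A\,S/(1-S)$ with $S$ drawn
  from the same model (truncated at 0.5 so the called base remains the
  argmax channel). The reverse strand is the reverse complement with sites
  mirrored. This path exists to exercise the peak-extraction pipeline
  end to end.
* **Reference sequence** (`make_reference()`): a 655-nt ITS with ITS1/5.8S/
  ITS2 of 257/163/235 nt, the four boundary motifs placed exactly once at
  the region junctions, 397 G+C overall, and the baseline alleles C/G/C/G
  at the variable positions 122/135/226/500. Filler outside the constrained
  positions is random under a fixed seed; its biological realism is a
  non-goal, and no conclusions depend on it (every assertion concerns the
  constrained positions and composition).

What the simulator deliberately does **not** model: dye blobs, mobility
shifts, base-calling quality, PCR amplification bias, indels. Passing tests
therefore demonstrate the statistical machinery under the calibrated noise
model, not robustness to every artifact of real electropherograms.

## Detection limit

With five replicates per mixture and $\alpha = 0.01$, the smallest fraction
on the 10/15/20/30/40/50% grid that the test confirms is 15%: at 10% the
expected $S$ (0.116) sits ~1.7 pooled standard errors above the noise mean,
giving only ~16--17% power, while at 15% (expected $S$ = 0.161) power
exceeds 99%. Because the per-seed probabilities (~0.83 for "smallest
significant = 15%", ~0.17 for "10% flagged") lie close to the documentation
bounds of 0.80/0.20, the property test resolves them with 1000 root seeds;
the headline detection limit itself is a majority verdict that is stable
from ~20 seeds up.

## ITS typing and the heterozygosity census

Thirteen ITS types are defined over the four variable positions: four
homozygous pure lines (P0, PM0, T0, S0, with GenBank accessions recorded in
the definition table) and nine heterozygous cultivar types. A type is
identified by (i) base composition per site, (ii) major/minor peak
orientation at heterozygous sites (e.g. Y with T taller vs Y with C
taller), and (iii) species context: P1 and PM1 share composition and
orientation and are told apart only by the (morphological) species
determination, which the package treats as a required input and never
infers from sequence.

The packaged 46-specimen panel carries two type-assignment columns because
the two published source tables disagree for seven vouchers (CP34, CP37,
CP38, CPM42--CPM45); the ratio-table assignment is canonical since its
per-type counts match the type-definition table (33/1/1/2/2 for P1--P5,
4/1/1 for PM1--PM3, 1 for T1), and the pipeline warns about the discrepancy
on every run. On this panel all 45 non-tangshen specimens (and the
R-carrying tangshen specimen as well) are heterozygous; no pure line
occurs.

The per-type mean hybrid ratios are recomputed from the per-specimen
values. For the single-specimen types they match previously reported group
averages exactly (P2 at 226: 33.5; PM3 at 122: 27.35; P3 at 122: 32.7); for
the multi-specimen types the previously reported averages do not equal the
arithmetic means of the tabulated per-specimen values, so the report flags
them instead of reproducing them.

## Lineage inference

Under a one-locus gamete model, a pair of parents explains a target type
when at every variable site one allele from each parent can be chosen so
that together they equal the target's composition. Orientation is ignored
here --- which parental repeat ends up more abundant in a hybrid's rDNA
array is not predicted by the cross. `infer_single_cross()` enumerates all
ten unordered pure-line pairs (self-pairs included); the result matches the
published supposed parental lineages exactly, including the two unexplained
types (P2, whose composition no sampled pair yields, and T1, which needs an
A at position 135 that no sampled line carries ---
`hypothetical_partner()` reports the unsampled genotype that would work,
clearly marked hypothetical). `enumerate_two_step()` chains a feasible
line-by-line cross into an intermediate heterozygous type and crosses the
intermediate with a third line; both documented chains to P1/PM1 (via PM2
and via PM3) are recovered.

## Phylogeny

Distances are uncorrected p-distances with fractional IUPAC overlap: per
site, codes expand to base sets and the mismatch is
$1 - |A \cap B| / \max(|A|, |B|)$, so C vs Y scores 0.5. At divergences of
at most 4 sites in 655 a model correction is immaterial; JC69 is available
behind a flag. The neighbor-joining agglomeration is implemented in the
package with documented tie-breaking (the lowest pair in the current label
order wins), because reproducible topologies on this highly tied matrix
require a pinned rule; `ape::nj` serves as an independent cross-check in
the tests, together with an additive-matrix oracle (random trees, their
cophenetic matrices, exact recovery). Negative branch-length estimates are
clamped to zero with a message. Bootstrap supports use
`ape::boot.phylo` with site resampling.

On the 13 rendered sequences the tree cleanly separates {T0, T1} (the
tangshen pure line and cultivar, distinguished by sites 135 and 500) from
the clade holding the other three pure lines and the eight remaining
cultivar types. `clade_partition()` formalizes the clade query: among
internal edges that cleanly separate the reference labels it returns the
one with the longest branch --- branch length is the natural measure of how
strongly the data support a separation, and the naive "smallest side
containing the references" rule demonstrably picks a near-zero-length edge
deep inside the cultivar clade instead. Within-clade arrangement is
deliberately unasserted: several rendered types are identical in sequence,
so their arrangement is tie-driven noise.

## Numerical and degenerate-input choices

* Truncated normals are drawn by inverse-CDF, so every generator is
  deterministic under a seed; all seeds derive from one root seed.
* Zero within-group variance in the ANOVA: p = 1 when the means agree
  (no evidence of any difference), p = 0 otherwise.
* Argmax ties in traces break in fixed base order A < C < G < T.
* Assembly (`assemble_contig()`) is exact-overlap based; the simulator
  never emits indels and indel handling is out of scope. A plain base
  against its IUPAC superset merges to the superset; disjoint bases are
  recorded as conflicts and merged to the union code with a warning.
* GC content excludes ambiguity codes from the numerator --- the unique
  simple convention consistent with every packaged type GC value from the
  397/655 baseline.
* Multiple-testing correction across sites is off by default (one or two
  known sites are tested per specimen); a Bonferroni-style correction can
  be applied by passing a reduced `alpha`.

## Problem sizes

The shipped tests and the acceptance script use: 10,000 draws for moment
checks, 1000 replicates for estimator-recovery checks, 1000 bootstrap
replicates for the 13-taxon tree, 200 random trees for the NJ oracle, 1000
root seeds for the per-seed detection-limit proportions and 20--25 seeds
for the majority detection limit. These sizes make every Monte Carlo margin
at least ~2.5 standard errors wide.

## Limitations

* The simulator's noise model is Gaussian and position-independent; real
  traces show autocorrelated noise, dye-dependent artifacts and mobility
  effects.
* Hybrid-ratio interpretation assumes the S-value tracks template fraction
  with the calibrated attenuation; concerted evolution of rDNA arrays can
  decouple repeat-type abundance from parental contribution over
  generations, so ratios are descriptive, not generation counts.
* Species context is an input; the marker itself cannot separate
  *C. pilosula* from var. *modesta* (types P1/PM1 are sequence-identical).
* The geography module correlates hybrid ratio with altitude only;
  coordinates are not in the packaged tables and are never invented.

## Reproducing the headline numbers

```r
# detection limit (majority over seeds)
detection_limit(seeds = 1:20)$majority_pct         # 15

# per-type ratio means
agg <- aggregate_ratios_by_type(build_specimen_panel())
agg[agg$its_type %in% c("P2", "PM3", "P3"), ]

# GC values and region lengths
ref <- packaged_reference()
gc_content(render_type_sequence("P1", ref))        # 60.31
extract_regions(ref)$table$length                  # 257 163 235 655
```

`scripts/acceptance.R` (repository root) recomputes all of these from
scratch and writes them as JSON.
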