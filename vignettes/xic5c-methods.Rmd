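---
title: "Methods: 5C map processing for rearranged alleles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 5C map processing for rearranged alleles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xic5c)
```

# Scope and model

`xic5c` analyses 5C (chromosome conformation capture carbon copy) contact
maps of a sub-megabase regulatory locus — the motivating system is the
mouse X-inactivation centre, where the *Xist*/*Tsix* locus sits at the
boundary between two TADs — and compares wild-type maps against alleles
carrying engineered inversions or deletions of CTCF site clusters.
Because no public read-level data accompany maps of this kind, the
package ships a synthetic-data module that generates every input the
pipeline consumes, with programmed ground truth, so each processing
stage can be validated by parameter recovery rather than by eye.

## The synthetic contact model

For forward primer $i$ and reverse primer $j$ at genomic separation
$d_{ij}$ the expected contact count is

$$\Lambda_{ij} = \mathrm{depth}\cdot c\cdot d_{ij}^{-\alpha}\cdot
T_{ij}\cdot L_{ij},$$

with $T_{ij}$ equal to `tad_factor` when the two primer midpoints share
a TAD and `cross_boundary_factor` otherwise; $L_{ij} = 1 +
\mathrm{loop\_strength}\cdot s_a s_b$ on the single pixel nearest to a
convergent CTCF site pair (upstream motif pointing right, downstream
motif pointing left — the orientation rule governing CTCF loops); and
$c$ normalising $\sum\Lambda$ to `depth`. Counts are independent
Poisson draws. Defaults ($\alpha = 1$, depth $10^6$, `tad_factor` 2,
`cross_boundary_factor` 0.5, `loop_strength` 3) are free parameters of
the generator: no quantitative loop or TAD strengths are available for
the motivating locus, so these were fixed once at values giving a 4:1
within/cross TAD contrast and a few-fold loop enrichment typical of
published 5C maps, and were not revisited afterwards.

Deliberate idealisations: fragments are uniform (a real HindIII digest
is irregular) so the primer-midpoint grid is regular; loops do not
stack (one convergent pair per pixel); noise is Poisson without
overdispersion, keeping the Monte-Carlo oracles closed-form. Passing
recovery tests on these maps therefore shows the *pipeline arithmetic*
is right; it does not certify performance on overdispersed, digest-
biased real libraries.

`xic_locus()` packages the default study system: ~1 Mb with TAD
boundaries at 300 kb, 600 kb and 804 kb, and three anchor clusters laid
out like *Linx* (right-oriented, strength 1.5), *Chic1* (left-oriented)
and *Xite* (left-oriented, at the TAD boundary), plus a 240 kb
grid-aligned intra-TAD inversion analogue and a 14,106 bp deletion
analogue (the deletion length is the study's sequenced *Chic1* deletion;
the inversion analogue is grid-aligned rather than the printed 244,689 bp
so that recovery checks are exact, see below).

# Processing stages

**Pooling and normalisation.** Replicates are summed and scaled to
counts-per-million over unmasked cells; all downstream statistics are
scale-free, so the target total only fixes units.

**Outlier and singleton filtering.** A probe whose total exceeds the
median by more than 3 MAD-sd on the log1p scale is masked; a pixel
above the global 99.9th percentile and more than 10 times its brightest
8-neighbour is masked as a singleton. The filter is standard for 5C
maps but its constants are not published; both are exposed as
arguments.

**Running-median binning.** Bin anchors sit every 6 kb; the bin value
is the median of contacts whose primer midpoints fall in the
30 kb × 30 kb window around the anchor pair, entered symmetrically so
the binned map is symmetric by construction. Bins with fewer than
`min_pairs = 3` supporting primer pairs are invalid (an sd over fewer
points is meaningless downstream). Even-count medians average the two
central values.

**Neighbourhood CV mask.** Chromatin behaves as a polymer, so a
contact frequency cannot be wildly different from its neighbours'; a
pixel whose 10 × 10 neighbourhood has coefficient of variation above 1
is treated as noise and masked (grey in differential maps). Because a
10 × 10 square has no centre pixel, the window covers offsets −5..+4 on
both axes, clipped at edges — a fixed asymmetric convention that keeps
results deterministic. CV uses the sample sd ($n-1$); squares with
fewer than 4 valid pixels or zero mean are masked as unsupported.
`cv_distribution()` reports the CV histogram and, when the smoothed
density is genuinely bimodal (both flanking peaks at least twice the
valley density — shallow kernel wiggles are not modes), suggests the
valley as a threshold; it never applies it.

**Distance-stratified z-scores.** 5C signal is dominated by distance
decay, so z-scores computed over the whole map would encode distance,
not structure. Pixels are grouped by genomic separation and
standardised within strata on log1p values. Strata are keyed by the
(rounded-bp) separation *value*, not by the bin-diagonal index: on the
default grid the two coincide exactly, but when deletion-adjusted
distances are supplied, rearrangement-spanning pixels — whose mutant
separation is the reference separation minus the deleted length — fall
into their own post-deletion strata. The distance adjustment is thereby
performed along with the z-score computation. Strata with fewer than 3
valid pixels or zero sd are degenerate: z is set to 0 and flagged.
Whether published 5C differential work z-scored raw or
distance-stratified values is not documented; stratification is this
package's choice and the raw alternative is available via
`log_transform`/`distances` arguments.

**Differential maps.** The difference of the two genotypes' z maps,
masked by the union of their invalid/CV-masked pixels.

**Insulation and boundaries.** Crane-style sliding square: the score at
bin $b$ is the log2 ratio of the mean contact in the
5 × 5-bin square upstream-versus-downstream of $b$ to the global mean
of such squares. Lower scores mean stronger insulation; troughs below
both flanking maxima by at least 0.2 log2 units (configurable) are
called boundaries, ties resolving to the lowest bin. The square size
and normalisation are field-standard choices, not published constants,
so absolute insulation values are not comparable to any figure — only
trough positions and their ordering are asserted anywhere.

# Rearranged alleles

**Inversions.** Reads from an inverted allele still identify reference
primers, so the mutant map stays indexed by reference primer identity.
Virtual-inversion correction assigns each primer its coordinate on the
inverted genome (`rearrange_primers()`: intervals reflect through the
segment, categories flip because the primer now reads off the other
strand) and the map is binned in those coordinates. On the uniform
grid, with breakpoints on fragment boundaries and no structural element
inside the segment, the corrected mutant expected map is
*pixel-identical* to the wild type — the package's exactness check.
With anchors inside the segment, differences confine to the
repositioned anchors. Two caveats are deliberate design:

* Exactness needs the reflected midpoint grid to land on itself; for a
  digest whose fragments are irregular inside the segment the spanning
  distances genuinely change and no correction can make the maps
  pixel-identical. The generator's uniform fragments encode this
  requirement.
* A bin-level permutation (`build_permutation()`/`remap_matrix()`) is
  also provided to reorient an already-binned map; it is an exact
  involution, but because the half-open running-median windows reflect
  into oppositely-open windows, re-binning in mutant coordinates — not
  permuting reference bins — is the route used for pixel-exact
  comparisons. Bins straddling a breakpoint are invalidated rather
  than split: the true junction sequence is chimeric, and masking
  mirrors the grey filtered pixels of differential maps.

**Deletions.** Deleted alleles are not remapped; instead
`deletion_adjust()` shortens the separation of deletion-spanning pairs
by the deleted length and removes bins inside the deletion, and the
adjusted distances feed `distance_zscore()` as above. On decay-only
simulations this restores a flat z field (the spanning pixels join
strata of their true mutant separation), while omitting the adjustment
leaves a systematic positive-z artifact across the deletion.

The package's deletion checks place the deletion near the map edge.
This is not cosmetic: the visibility of the uncorrected artifact
depends on spanning pairs being a minority within their distance
strata. In a real 4.5 Mb 5C window a 14 kb deletion affects a small
fraction of each stratum; a small simulated locus with a central
deletion would instead let spanning pairs dominate mid-range strata,
where standardisation absorbs the shift. Edge placement restores the
realistic minority regime at desk-scale problem sizes.

# Expression statistics

`normalize_ncounter()` applies the two-step control scaling used for
digital expression counting: per sample, equate the geometric mean of
positive-control probes to the cross-sample average, then repeat with
housekeeping genes. Geometric means are standard for the assay class
and robust to single-gene spikes; the step is idempotent.
`fold_change_vs_reference()` divides each gene by its reference sample
(wild-type day 0 in the motivating design). Genotype comparisons use a
two-tailed paired Student's t-test with the time point as the pairing
key; pairing across replicate pairs instead is possible by passing the
matching series — experimental reports of this kind rarely state which
pairing they used, so neither is asserted as canonical. Zero-variance
differences yield an explicit `p_undefined` flag instead of a p-value.

Allelic imbalance uses the Mann–Whitney U test on per-embryo ratios
$A/(A+B)$: exact by full enumeration (valid under ties) when
$\min(n_A, n_B)\le 8$ and $n_A+n_B\le 20$, otherwise the
tie-corrected, continuity-corrected normal approximation — thresholds
fixed for reproducibility. Significance stars follow the 0.05 / 0.01 /
0.001 / 0.0001 cutpoints.

# Numerical conventions and degenerate inputs

All coordinates are 0-based half-open (BED convention); a base at $p$
inside an inverted $[a,b)$ maps to $a+b-1-p$, which makes the
inversion an involution. Nearest-slot assignment for off-grid
reflections breaks ties toward the lower index. All-zero maps,
zero-geometric-mean control sets, empty groups and too-small maps are
rejected with descriptive errors rather than propagating NaNs. Every
stochastic function takes an explicit seed; there is no hidden global
state.

# Problem sizes used by the test-suite and acceptance script

Recovery runs use the ~1 Mb / 166-fragment locus (depth $5\times10^5$
for boundary calling over 100 replicates, $2\times10^6$ for expected-map
comparisons) and a 600 kb / 100-fragment locus for deletion checks at
depth $5\times10^6$ — the depth at which counting noise at the largest
separations stays below the 14 kb distance-shift signal, chosen from
the mixture-z power analysis above, not fitted to any outcome.
Statistical calibration uses 500 replicates per condition. Differential
confinement is evaluated on expected (noise-free) maps: with Poisson
noise, z standardisation inside structurally homogeneous strata rescales
pure noise to unit variance, so a fixed |Δz| threshold would flag
background pixels at a rate set by the noise, not by the structure the
check is about; expected maps isolate the structural signal.

# Known limitations

No ICE/matrix balancing, no overdispersion in the noise model, no
multi-breakpoint rearrangements (translocations, duplications), no
directionality-index or HMM boundary callers, and no claim of numerical
comparability of insulation values to any published figure. The
exact-match read counter replaces aligner-based processing and is only
appropriate for the generator's noise-free junction reads.
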