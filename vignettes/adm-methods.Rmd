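---
title: "Average distance maps and disorder prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Average distance maps and disorder prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admap)
```

## The model

An average distance map (ADM) is a sequence-only analogue of a contact
map. From a set of solved structures, all Cα–Cα distances are pooled by
unordered residue-type pair and by sequence-separation range M
(`range_index()`: M = 1 covers separations k = 1–8, M = 2 covers 9–20,
and every further range a decade, 10M − 9 … 10M). Pooling is per range,
not per individual k, and no outlier trimming is applied. An entry is
*statistically significant* when its observation count reaches
`min_count` (default 10; the package treats this as the operational
meaning of "statistically significant" since the statistics source does
not publish one).

For a query of length N, a pair (i, j) is plotted when its table mean
distance is below a per-range threshold. The thresholds are not free
parameters: they are chosen so the whole-map plot density ρ (plots per
upper-triangle cell, n/(N(N−1)/2)) matches the real-distance-map law
ρ = C/N, with C = 36.12 reproducing contact-map density at a 15 Å
cutoff (`rdm_density()` computes that reference density from a
structure). We interpret ρ as a per-cell density — the law then says the
expected number of contacts per residue is constant in N, which is
exactly the behaviour of a 15 Å contact map.

Within range M the plotted count obeys P(M)~C~ = (D/M)·P(M), where P(M)
counts the query's significant pairs in that range and the 1/M factor
downweights long separations. A single global D is shared across ranges
(the equation has one D; a per-range D would make it vacuous). D solves
the continuous piecewise-linear equation
Σ~M~ min((D/M)·P(M), P(M)) = round(C(N−1)/2); per-range counts are then
rounded half away from zero and capped at P(M). Because rounding is per
range, the realised plot count can differ from the target by at most
max~M~/2 plots — the calibration tests allow 5% slack for this. When
even plotting every significant pair cannot reach the target (short or
composition-poor sequences), all of them are plotted and a warning
reports the shortfall.

Thresholds are realised as order statistics: the P(M)~C~ smallest mean
distances in the range are plotted, and the recorded threshold is the
midpoint between the last plotted and the first unplotted value, so
"mean distance < threshold" reproduces the selection. Ties at the
boundary are broken by ascending (i, j) — determinism over elegance.

## Compact-region scanning

At each index i the upper-triangular map splits into a triangular part
and the remaining trapezoid (cross pairs belong to the trapezoid), and
Δρ~i~ = ρ(triangle) − ρ(trapezoid) is recorded (`adm_scan()`). The
horizontal scan takes the triangle of pairs with both endpoints ≥ i and
peaks at the *start* of a dense block; the vertical scan takes both
endpoints ≤ i and peaks at its *end*. A candidate region [m, n] pairs a
horizontal peak with a vertical peak and is scored by
η = Δρ^h^~m~ + Δρ^v^~n~; overlaps are resolved greedily by descending η.
Divisions where one part has no cells are undefined and reported as
`NA`, never zero-filled.

Peak detection (`scan_peaks()`) takes strict interior local maxima above
`min_height` (default 0.01 density units), resolving plateaus to their
leftmost index; a monotone profile therefore has no peaks. Divisions
whose triangular part spans fewer than `min_part` residues (default 10)
are excluded: a triangle of a handful of cells has sampling noise far
above any real boundary signal, and on pure-noise maps these edge
divisions would otherwise dominate the extrema. With this guard, block
boundaries are recovered to ±2 residues on synthetic two-domain maps at
block densities ≥ 3× background; suppressing *all* spurious peaks on
dense noise maps additionally needs `min_height` of roughly three times
the null standard deviation of Δρ at mid-sequence, which is larger than
the 0.01 default for maps at ρ ≈ 0.2 — callers scanning noisy maps
should raise `min_height` accordingly. The minimum region span
`min_span` defaults to 20 residues, the scale of the smallest structural
domains.

## Disorder probability

Disordered regions are depleted in long-range ADM plots. Each residue's
incident plots in the band `k_lo ≤ k ≤ k_hi` are counted
(`residue_plot_counts()`); the default band 9–29 combines the long-range
definition (more than 8 residues apart) with the restriction to
separations below 30 that keeps the signal local enough to resolve
*partially* disordered chains. The band is a configuration parameter
because the two definitions appear separately in the method's
provenance and their conjunction is the natural combined reading.
Counts are smoothed by a truncated moving average of half-width 5
(11-residue windows, shrinking at the ends).

Calibration (`calibrate_disorder()`) pools annotated residues of
admissible training proteins — a protein is excluded when its disordered
regions cover less than `min_coverage` (default 10%) of the sequence, or
its ordered regions do — bins them by integer-rounded smoothed count,
and fits the per-bin disorder fraction by least squares, weighted by bin
occupancy. The fit is a cubic polynomial: the lowest degree that tracks
the sigmoid-like fall of disorder probability with plot count without
oscillating. Its output is clamped to [0, 1] and inputs outside the
observed count domain are clamped to the domain boundary, so the curve
is total. Empty bins are absent, not zero, and never influence the fit.

Classification labels residue i disordered when probability ≥ θ.
θ = 0.62 (`"accw"`) maximises balanced accuracy and is the default;
θ = 0.53 (`"accp"`) maximises plain accuracy. No minimum segment length
is imposed on output — segments as short as a few residues are
legitimate predictions. Evaluation is residue-level; residues annotated
in neither class are excluded from scoring rather than assumed ordered,
and pooling across proteins is micro-averaged (counts summed before
metrics). ACC~w~ is reported as `NA` with a warning when a class is
missing — never silently zero.

The tandem (dimer-like) mode predicts on the plain concatenation of the
sequence with itself. No artificial linker is inserted: any linker
composition would inject statistics of its own into the junction band,
which is exactly the region of interest.

## The synthetic generators

The package is fully testable offline through three seeded generators.
`synth_chain()` produces ideal geometries (straight 3.8 Å chains and
α-helices with closed-form distances for exact oracles; a collapsed
random walk rescaled into a sphere of radius 2.5·N^1/3^ Å for
globule-like distance spectra). `synth_table()` produces either a
uniform table (every pair significant, seeded mean-distance spread:
the setting for exact selection oracles and density calibration) or a
two-class table in which pairs of order-prone residues (A C F I L M V W
Y) have short means, mirroring the hydrophobic depletion of real IDRs.

`synth_annotated_set()` composes sequences of alternating order-prone
and disorder-prone segments (segment lengths 35–65, composition purity
0.95), realises each protein's smoothed plot counts under the two-class
table, and draws each residue's disordered label from a known law — a
logistic in the smoothed count with midpoint 12 and scale 2
(`synth_law()`). The segment parameters were chosen so the
class-conditional count distributions are clearly bimodal (disorder-prone
segments mostly below 8 counts, order-prone mostly above 16), and the
law's scale so that the transition is gentle enough for a cubic to track
while residues far from the midpoint are nearly deterministic. Under
these defaults calibration recovers the law to within 0.05
occupancy-weighted mean absolute deviation on ≥ 5,000 pooled residues,
and held-out balanced accuracy at the swept optimal threshold exceeds
0.9 — both are exercised by the test suite, and they are statements
about this synthetic regime only.

What the generators do *not* emulate: real evolutionary composition
biases, sequence correlations beyond segment blocks, annotation noise
from experimental disorder assignment, structural heterogeneity of the
statistics source, or any relation between the two synthetic classes and
real hydropathy scales beyond the sign of the effect. Passing tests
therefore demonstrate internal correctness of the pipeline and its
calibration machinery, not field accuracy on DisProt/IDEAL data — that
requires a statistics table compiled from a real structure set
(`build_distance_table()` over PDB files) and real annotations.

## Numerical choices

- Rounding is half-away-from-zero everywhere a count is produced
  (`round(0.5) = 1`), avoiding the platform-independent but surprising
  banker's rounding of base `round()`.
- The D solver walks the kinks of the piecewise-linear total; no
  iterative optimisation, no tolerance.
- All randomness flows through explicit seeds (`withr::with_seed`); no
  generator touches the global RNG state of the caller.
- Degenerate inputs fail loudly with classed conditions
  (`admap_error_*`): sequences shorter than 2, traces without Cα atoms,
  empty training pools, reversed intervals, overlapping class
  annotations, unknown configuration keys.
- `X` in a sequence is accepted and unplottable (it has no table
  entries); other non-standard letters are rejected.
- The curve serialisation carries a format-version tag so future layout
  changes stay detectable.

## Problem sizes

The test suite and the acceptance script run at desk scale by design:
calibration recovery uses 40 training and 12 held-out proteins of
100–199 residues (≈ 6,000 pooled residues), the selection oracle runs
100 seeded instances at N = 25–55, the null-scan study 200 maps at
N = 60, and the calibration target a single N = 150 sequence. These
sizes keep every property statistically meaningful for the regimes the
method addresses (the 60–219-residue proteins it was designed around)
while the whole suite stays fast.

## Known limitations

- The statistics table of the original method is not published; users
  must compile their own from a structure set, and absolute accuracies
  depend on that choice.
- Compact-region pairing assumes non-overlapping domains; nested or
  discontinuous domains are out of scope.
- The per-range threshold construction is exact for the density target
  but makes the plotted set depend on the query's own composition; two
  sequences sharing a subsequence need not share its plots.
- Scanning near sequence termini is intrinsically noisy; boundaries
  within `min_part` residues of an end are not detectable.
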