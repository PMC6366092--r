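# admap

Prediction of intrinsically disordered regions (IDRs) in proteins from
amino-acid sequence alone, using **average distance maps (ADMs)** built
from inter-residue average distance statistics.

Intrinsically disordered proteins and regions lack a stable 3D structure
under physiological conditions, yet they carry out essential signalling
and regulatory functions; predicting where a sequence is disordered is a
standard first step in characterising such proteins. `admap` implements a
statistics-driven predictor for structural bioinformaticians: no
evolutionary profiles, no machine-learned features — only pooled
Cα–Cα distance statistics from known structures and a calibrated
density argument.

## The method

1. **Distance statistics.** For a set of structures, all Cα–Cα
   distances are pooled by unordered residue-type pair and by sequence
   separation range *M* (range 1: separations k = 1–8; range 2: 9–20;
   then decades 21–30, 31–40, …). The result is a table of mean
   distances with observation counts; entries with at least `min_count`
   observations count as statistically significant.

2. **ADM construction.** For a query sequence, a pair (i, j) is plotted
   when its table mean distance falls below a per-range threshold. The
   thresholds are set so that the whole-map plot density matches the
   real-distance-map law ρ<sub>av</sub> = C/N with C = 36.12 (which
   reproduces contact-map density at a 15 Å cutoff). Within range M the
   number of plotted pairs obeys P(M)<sub>C</sub> = (D/M)·P(M), with a
   single global D solved so the total plot count meets
   round(C(N−1)/2).

3. **Compact-region scanning.** The map is divided at every residue
   index, horizontally and vertically, and the density difference
   Δρ<sub>i</sub> = ρ(triangle) − ρ(trapezoid) is profiled. Peaks mark
   compact-region boundaries; a candidate region [m, n] is scored by the
   compactness measure η = Δρ<sup>h</sup><sub>m</sub> +
   Δρ<sup>v</sup><sub>n</sub>.

4. **Disorder probability.** Each residue's ADM plots in the separation
   band 9 ≤ k ≤ 29 are counted and smoothed over ±5 residues. On
   annotated training proteins (any protein whose disordered or ordered
   regions cover less than 10% of the sequence is excluded), the
   per-count disorder fraction is fitted by count-weighted least squares
   (cubic), giving a disorder-probability curve. A residue is predicted
   disordered when its probability reaches the threshold θ — preset
   `"accw"` (0.62, maximises balanced accuracy) or `"accp"` (0.53,
   maximises plain accuracy).

5. **Evaluation.** Residue-level confusion counts against interval
   annotations, with ACC<sub>p</sub> = (TP+TN)/(TP+TN+FP+FN) and
   ACC<sub>w</sub> = ½(TP/(TP+FN) + TN/(TN+FP)), disordered positive.

A tandem mode predicts on the sequence concatenated with itself, probing
order that only emerges through self-association (dimerisation), as in
the p53 tetramerization domain.

## Worked example

```r
library(admap)

tab   <- synth_table("two_class", seed = 1)            # statistics table
set   <- synth_annotated_set(8, c(100, 199), seed = 1, table = tab)
curve <- calibrate_disorder(set$sequences, set$annotations, tab)
curve
#> <disorder_curve> degree 3 over counts [0, 38], 1235 residues in 39 bins

pred <- predict_disorder(set$sequences$sequence[1], tab, curve, id = "synth001")
glance(pred)
#> # A tibble: 1 x 5
#>   id           N theta n_disordered n_segments
#> 1 synth001   167  0.62           79          2
disorder_segments(pred)
#>   start   end
#> 1     1    31
#> 2    79   126

evaluate_disorder(pred, set$annotations)
#>   protein_id    tp    fn    tn    fp acc_p acc_w
#> 1 synth001      78     7    81     1 0.952 0.953
#> 2 pooled        78     7    81     1 0.952 0.953
```

The prediction tibble has one row per residue (`raw_count`,
`smoothed_count`, `probability`, `label`); `disorder_segments()` lists the
maximal disordered runs, here residues 1–31 and 79–126, and the
evaluation row shows 159 of 167 annotated residues classified correctly
(ACC<sub>w</sub> 0.953). The underlying map itself:

```r
adm <- build_adm(set$sequences$sequence[1], tab, id = "synth001")
glance(adm)
#>   id           N n_plots density density_N     C     D target
#> 1 synth001   167    2999   0.216      36.1  36.1 0.790   2998
plot_ratios(adm)
#>   n_residues n_short n_long short_ratio long_ratio
#> 1        167    1027   1972        6.15       11.8
```

`density_N` ≈ 36.1 shows the per-range thresholds hit the ρ = C/N
calibration. `autoplot()` methods render the map, the scanning profiles
(`adm_scan()`), the calibration curve and the per-residue prediction.

## Command line

A thin wrapper around the same functions is installed at
`inst/exec/admap`:

```sh
admap synth --what set --seed 1 --out fixtures
admap calibrate --fasta fixtures.fasta --annotations fixtures.annotations.tsv \
      --table fixtures.table.tsv --out curve.tsv
admap predict --fasta query.fasta --table fixtures.table.tsv \
      --curve curve.tsv --theta accw --out pred
```

Subcommands: `stats-build`, `adm-build`, `scan`, `calibrate`, `predict`,
`tandem`, `evaluate`, `synth`; a YAML config file (`--config`) can set
any documented parameter.

## Further reading

The methods vignette (`vignettes/adm-methods.Rmd`) documents the model
assumptions, every tunable parameter with its default and units, what the
synthetic generators do and do not emulate, and the package's numerical
choices.
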