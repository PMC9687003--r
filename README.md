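# parasegmentr

Quantitative analysis of contractile compartment boundaries in the early
*Drosophila* germband.

During germband extension (GBE), the embryonic ectoderm is divided into
parasegments. The columns of cell–cell interfaces between them — the
parasegmental boundaries (PSBs), which sit at the anterior border of each
*engrailed* stripe — are actomyosin-enriched and stay mechanically straight
while the surrounding tissue intercalates. `parasegmentr` provides the full
analysis chain used to measure this behaviour:

* **Dot tracking** — detection of nascent-transcription reporter dots in
  intensity images, greedy nearest-neighbour tracking through time,
  point-in-polygon assignment of dots to tracked cells, expressing-cell
  calling, stripe-parity classification from dot brightness, and kymographs
  of dot positions along the AP axis.
* **Boundary identification** — parasegment labelling from expressing-cell
  stripes, classification of PSB and control (−1, +1) interface columns
  (one cell diameter anterior/posterior of the boundary), and label
  propagation through tracked frames.
* **Co-alignment statistics** — interface orientation angles θ relative to
  the AP axis reflected about 90° to [0°, 90°]; the co-alignment proportion
  `p(t) = P(θ' ≥ 60°)` over a −10 to 50 min window; LOESS-smoothed curves
  (span 0.75) with 95% bands; two-sample Kolmogorov–Smirnov comparisons of
  cumulative angle distributions at t = 30 min.
* **Fixed-embryo quantification** — boundary straightness
  `S = chord / arc` of a traced interface, and the Myosin II enrichment
  ratio `R = log10[(PSB − bg_PSB) / (control − bg_ctl)]`, where each
  trace's background is the mean of its dimmest 20% of pixels; pairs with
  dividing boundary cells are excluded.
* **In silico screen** — identifier standardisation through an alias table,
  exact three-way criterion intersection (striped expression × cell-surface
  protein × pair-rule regulation), the strict `< 5%` early-expression
  temporal filter, and an exclusion ledger for the manual QC rules.
* **Synthetic embryos** — a generator producing stripe-patterned tissues on
  a jittered lattice with a boundary-tension dial `beta`, transcription-dot
  movies with parity-dependent brightness, line-trace pairs with a known
  enrichment factor, and screen fixtures with planted intersections — all
  with complete ground truth, so every analysis is validated by parameter
  recovery.

## Worked example

Simulate a wild-type-like embryo (boundary tension `beta = 0.9`), run the
dot → boundary → co-alignment pipeline, and compare conditions at 30 min:

```r
library(parasegmentr)

cfg <- pipeline_config(list(synthesis = list(beta = 0.9)), seed = 1)
res <- run_pipeline(cfg, "out")
res$coalign
#> Co-alignment comparison (KS at t = 30 min):
#>  condition_a condition_b         D   p_value n_a n_b significance
#>          PSB      minus1 0.7916667 0.0000000 120 120          ***
#>          PSB       plus1 0.7750000 0.0000000 120 120          ***
#>       minus1       plus1 0.1166667 0.3876511 120 120           ns
```

The boundary column is sharply distinguishable from both control columns
(D ≈ 0.78–0.79, p < 0.001) while the two controls are statistically
indistinguishable. The smoothed curves show why: the PSB stays fully
co-aligned while the +1 column decays as intercalation-like disorder grows,

```r
cv <- res$coalign$curves
cv[cv$time_min %in% c(0, 30, 50) & cv$condition == "plus1", ]
#>   condition time_min n_interfaces proportion loess_fit ci_lo ci_hi
#> 1     plus1        0           40       1.00     0.994 0.975 1.013
#> 2     plus1       30           40       0.65     0.743 0.722 0.764
#> 3     plus1       50           40       0.55     0.617 0.577 0.658
plot_coalignment(cv)   # publication-style curves with 95% ribbons
```

Fixed-embryo quantification recovers a planted enrichment factor from 50
noisy trace pairs:

```r
bq <- batch_quantify(generate_line_trace_set(
  trace_set_config(n_pairs = 50, enrichment_factor = 1.5, noise_sd = 5,
                   seed = 2)))
mean(bq$results$R)
#> [1] 0.1775459     # true value log10(1.5) = 0.1760913
```

A thin CLI over the same functions is installed at
`inst/cli/parasegmentr.R` (subcommands `simulate`, `track`, `boundaries`,
`coalign`, `fixedquant`, `screen`, `all`).

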