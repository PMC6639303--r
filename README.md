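# pmrq

Quantification of live-cell plasma membrane repair (PMR) assays and the
calcium-handling machinery behind them.

When a muscle cell's plasma membrane is wounded — by a pulsed laser or by
rolling glass beads — a healthy cell reseals within about a minute, while
repair-deficient cells (for example patient myoblasts lacking an
ER-resident anoctamin channel) keep admitting extracellular dye, clear
the injury-triggered cytosolic Ca²⁺ surge slowly, and fragment their
tubular ER near the wound. `pmrq` turns the time-lapse recordings of
these experiments into numbers:

* **ΔF/F kinetic traces** from TIFF stacks + ROI sidecars, with optional
  background correction: `extract_mean_trace()`, `to_delta_f_over_f()`;
* **repaired/failed calls** per injured cell from FM-dye entry traces
  (sliding-window plateau detection + hinge-fit plateau onset):
  `classify_repair()`, `cohort_repair_summary()`;
* **Ca²⁺ clearance metrics** from Fluo-4 traces — peak, time for the
  peak to fall by 75% (τ·ln 4 for an exponential decay of constant τ),
  and area under the curve: `compute_calcium_metrics()`;
* **ER fragmentation** — the fraction of the cell's longest axis from
  the injury point over which tubular ER has become punctate, scored by
  structure-tensor orientation coherence: `injury_axis()`,
  `score_fragmentation()`;
* **FRAP fits** — mobile fraction and recovery τ from
  `y0 + M(1 − e^{−t/τ})`: `normalize_frap()`, `fit_recovery()`;
* **bead-assay counts** — injured (green-dextran⁺) and failed
  (green⁺red⁺) cells, failure as % of injured:
  `segment_labelled_cells()`, `compute_failure_rate()`;
* **two-group statistics** — unpaired Student's t vs Mann–Whitney with
  the conventional automatic selection (Shapiro–Wilk + Levene), exact
  rank-sum p for small groups: `compare_groups()`, `render_summary()`.

Every assay has a synthetic generator (`generate_influx_stack()`,
`generate_transient_trace()`, `generate_er_stack()`,
`generate_frap_trace()`, `generate_bead_field()`) that emits image
stacks or traces **with machine-readable ground truth**, so the entire
pipeline is validated end-to-end without microscope data. The methods
vignette (`vignettes/membrane-repair-quantification.Rmd`) documents the
models, defaults and numerical choices.

## Worked example

Two simulated cohorts — repair-competent ("healthy", 90% repairing) and
repair-deficient ("patient", 25% repairing) — classified from their
dye-entry ΔF/F traces:

```r
library(pmrq)

healthy <- generate_repair_cohort(12, repair_fraction = 0.9,  seed = 101)
patient <- generate_repair_cohort(12, repair_fraction = 0.25, seed = 102)
results <- lapply(c(healthy$traces, patient$traces),
                  function(tr) classify_repair(to_delta_f_over_f(tr)))
cohort_repair_summary(results, rep(c("healthy", "patient"), each = 12))
#> <repair_cohort_summary>
#>    group  n n_repaired fraction_repaired
#>  healthy 12         11         0.9166667
#>  patient 12          3         0.2500000

results[[1]]
#> <repair_result> repaired (plateau at 38 s), final dF/F = 1.91
```

The fractions recover the simulated repair probabilities; the first
cell's dye entry plateaued 38 s after injury (its simulated resealing
time), at a final dye load of 1.91 ΔF/F.

A slow-clearing ("patient-like", decay τ = 40 s) calcium transient and a
FRAP fit:

```r
m <- transient_model(decay_tau = 40)
compute_calcium_metrics(to_delta_f_over_f(generate_transient_trace(m, seed = 7)))
#> <calcium_metrics> peak dF/F = 0.499 at 5.99 s; AUC = 22.69 dF/F*s
#>   75% clearance in 56.4 s after the peak

fit_recovery(normalize_frap(generate_frap_trace(0.7, 15, seed = 3)))
#> <frap_fit> mobile fraction = 0.711, tau = 15.3 s (t1/2 = 10.6 s), rms = 0.017
```

The transient peaks at ≈0.5 ΔF/F (peak amplitude 50 AU on a baseline of
100) and takes 56.4 s ≈ 40·ln 4 to clear 75% of the peak — the slow
clearance that distinguishes repair-deficient cells. The FRAP fit
recovers the simulated mobile fraction 0.7 and τ = 15 s to within the
2% trace noise.

Bead-injury counting and the small-sample exact rank test:

```r
field <- generate_bead_field(bead_field_spec(n_cells = 150, n_injured = 150,
                                             n_failed = 30, seed = 5))
compute_failure_rate(segment_labelled_cells(field$stack))
#> <bead_assay_counts> 150 injured, 30 failed to repair (20.0%)

compare_groups(1:5, 6:10, test = "mann_whitney")
#> <group_comparison> A vs B: Mann-Whitney rank sum, statistic = 0, p = 0.007937
```

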