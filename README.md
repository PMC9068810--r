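# hfqcompete

Single-molecule analysis of small-RNA competition for the bacterial
chaperone Hfq.

## The problem

Hfq is a ring-shaped RNA chaperone present in far fewer copies than the
small regulatory RNAs (sRNAs) and mRNAs that need it, so RNAs compete for
the protein.  In a two-colour smTIRF competition assay, Hfq hexamers
pre-loaded with a Cy3-labelled *resident* sRNA are immobilized on a slide
and challenged with a Cy5-labelled *competitor*; both channels are recorded
for five minutes (3,000 frames at 100 ms, alternating excitation after the
first second).  Per molecule, three exchange pathways are distinguished:

* **passive competition** — the resident dissociates before any competitor
  has colocalized;
* **active competition** — the resident departs while a competitor is bound
  and the competitor remains (displacement time `t_diss`);
* **stable coexistence** — both RNAs cohabit the hexamer for more than 20 s
  (coexistence time `t_co`).

`hfqcompete` implements the full analysis chain for such experiments, plus
a stochastic simulator that generates ground-truth movies and traces so
every stage is testable without raw microscope data:

1. **simulate** — event-driven kinetics (`simulate_molecule()`,
   `competition_preset()`) rendered into traces (`render_traces()`) or
   16-bit multi-page TIFF image stacks (`render_movie()`);
2. **extract** — spot detection, AOI filtering, affine channel mapping,
   intensity integration (`extract_traces()`);
3. **segment** — flow-time change-point detection (`detect_flow_time()`),
   hysteresis-threshold interval segmentation (`segment_trace()`),
   fluorophore-unit estimation and stoichiometry quantization;
4. **classify** — occupancy timelines, `t_bind` / `t_diss` / `t_co`
   extraction and mode flags (`competition_record()`);
5. **fitkinetics** — censored multi-exponential maximum-likelihood fits
   with the dwell-time likelihood

   log L = Σ_uncens log Σ_j (a_j/τ_j) e^(−t_i/τ_j) + Σ_cens log Σ_j a_j e^(−t_i/τ_j),

   sub-resolution interval terms, likelihood-ratio model selection,
   case-resampling bootstrap CIs (`fit_mle_mixture()`, `select_model()`,
   `bootstrap_errors()`), plus ECDF fits, binomial-error density
   histograms and a two-sample Kolmogorov–Smirnov comparison;
6. **report** — end-to-end orchestration with CSV/JSON artifacts,
   survival curves and competition-mode heat maps (`run_pipeline()`),
   and a thin CLI in `inst/cli/hfqcompete.R`.

## Worked example

```r
library(hfqcompete)

res <- run_pipeline(list(pair = "H-DA_vs_CX",   # DsrA resident, ChiX competitor
                         n_molecules = 150, seed = 5,
                         acquisition = list(noise_sd = 15),
                         fit = list(n_boot = 0)),
                    out_dir = "demo_out", verbose = FALSE)
res$summary
#> H-DA resident vs CX competitor (n = 150 molecules, 2 replicates)
#>   passive                0.7% +/- 0.7
#>   coexistence           14.7% +/- 1.3
#>   active                79.3% +/- 2.0
tail(res$survival, 1)
#>     time_s percent_remaining n_bound
#> 301    300          15.33333      23
res$fits$t_diss$fit
#> Exponential mixture (3 components, censored MLE)
#>   tau1 = 0.5324 s  (fraction 0.319)
#>   tau2 = 6.284 s  (fraction 0.523)
#>   tau3 = 63.29 s  (fraction 0.158)
#>   n = 119 (0 censored), logLik = -378.64
```

A strong class-II competitor (ChiX) displaces a class-I resident (DsrA)
from most Hfq molecules within the movie: ~15% of residents remain after
5 minutes, ~79% of molecules show active displacement, and the fitted
displacement-time mixture resolves a sub-second clash component, a
seconds-scale component and a minor slow component.  The `demo_out/`
directory contains the interval, dwell, record, survival and heat-map
CSVs, the fit JSON and a machine-readable manifest.

The analytic stable-coexistence threshold argument is available directly:

```r
access_time_bound(copies = c(10, 60), volume_um3 = 0.5, k_on = 2e5)
#>   copies concentration_nM access_time_s
#> 1     10          33.2203     150.50748
#> 2     60         199.3218      25.08458
```

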