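---
title: "Modelling and analysing sRNA competition for Hfq at the single-molecule level"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and analysing sRNA competition for Hfq at the single-molecule level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfqcompete)
```

## The experiment being modelled

Bacterial small RNAs (sRNAs) depend on the hexameric chaperone Hfq, which is
present in far fewer copies than its RNA clients.  In a two-colour smTIRF
competition assay, Hfq hexamers pre-loaded with a Cy3-labelled "resident"
sRNA are immobilized on a slide; a Cy5-labelled "competitor" sRNA is then
flowed in, and both channels are recorded for five minutes.  Three exchange
pathways can be distinguished per molecule:

* **passive competition** — the resident dissociates before any competitor
  has colocalized with the same hexamer;
* **active competition** — the resident departs while a competitor is bound
  and the competitor stays on (a displacement, with dwell $t_{diss}$
  measured from the start of the colocalization episode);
* **stable coexistence** — resident and competitor cohabit the hexamer for
  more than 20 s (dwell $t_{co}$, ending with either RNA's departure).

`hfqcompete` implements the full analysis chain for such experiments —
trace extraction from image stacks, interval segmentation, per-molecule
classification, and censored multi-exponential dwell-time fitting — plus a
stochastic simulator that generates ground-truth data so every stage can be
validated without access to raw microscope movies.

## The kinetic simulator

`simulate_molecule()` runs an event-driven simulation with exact event
times.  The resident is bound at $t = 0$.  After the flow time, competitors
arrive as a Poisson process with rate `k_arrival` (a pseudo-first-order
constant, $k_{on} \times$ concentration) while fewer than `max_competitors`
are bound.  Each arrival is:

* with probability `p_probe`, a short nonproductive *probe* (exponential
  dwell, mean `tau_probe`) — these reproduce the repeated transient Cy5
  events seen before a stable complex forms;
* otherwise a stable binder.  If the resident is present it either triggers
  *displacement* (probability `p_displace`; the resident leaves after a
  delay drawn from the exponential mixture `diss_mixture`) or *coexists*
  (joint dwell drawn from `co_mixture`, ended by the resident with
  probability `p_resident_leaves_first`, else by the competitor).

A lone bound RNA dissociates spontaneously at rate `k_passive`.  Keeping
event times exact (discretization happens only at rendering) preserves
sub-frame displacement delays: these are what produce an apparent
zero-lifetime component when dwell times are fitted at the camera's
resolution.

Design choices that were genuinely open:

* **Probes cannot trigger displacement** by default (`probe_can_displace`
  flag).  The experimental taxonomy ties displacement to stable binding;
  making probes displace would blur the distinction between probing and
  active competition.
* **A coexisting competitor occupies one slot**, and further arrivals
  remain possible up to `max_competitors` (default 3, i.e. up to four RNAs
  counting the resident) — this reproduces multi-sRNA occupancy of stable
  complexes.
* **After a displacement the winning competitor remains bound** with only
  the passive off-rate acting on it; within a 300 s movie it is usually
  right-censored, which is what the experiment sees.
* **Photobleaching lives in the renderers**, not the kinetic scheme: it is
  exposure-proportional, so only the acquisition layer (which knows the
  excitation mask) can apply it per excited frame.  This is also why
  alternating excitation doubles fluorophore survival, which the test suite
  checks explicitly.

### Presets

`competition_preset()` provides four parameter sets named after the core
resident/competitor pairs (DsrA and ChiX in all four combinations).  The
values were chosen once, inside the experimentally reported regimes — e.g.
displacement lifetimes of roughly 0–0.5 s, 4–13 s and 58–133 s with a
13–22% slow fraction; rare passive exchange; stable coexistence more
frequent for heterotypic pairs; endpoint resident survival ranging from
~15% (class II challenging class I) to ~85% (the reverse) — and are meant
as realistic fixtures, not as refits of any particular dataset.

## Rendering and acquisition

`acquisition_params()` encodes the movie structure: 3,000 frames of 100 ms,
both lasers on during the first and last second, alternating excitation in
between (so each channel is sampled every 0.2 s), and a Cy5 background step
from `background_pre` to `background_post` at the flow frame.  The Cy3
camera background is taken equal to `background_pre` for the whole movie.

`render_traces()` produces per-frame intensities
(background + unit_intensity × occupancy × excitation + Gaussian noise),
sampling occupancy at frame midpoints.  `render_movie()` draws each bound
fluorophore as a 2-D Gaussian PSF on a two-half-field camera (Cy3 left,
Cy5 right, related by an affine `channel_transform`), writing 16-bit
multi-page TIFF via `write_movie_tiff()`.  Movie and trace rendering share
the same occupancy computation, so AOI-integrated movie intensities match
the traces up to PSF truncation (<1% for the default box).

## Extraction and segmentation

Spot detection operates on the mean of the first ten both-excited frames:
local maxima above a robust background threshold (median + k·MAD), refined
to subpixel centroids.  AOIs closer than `min_separation` (default 5 px)
are *all* discarded — an AOI that may contain two Hfq molecules cannot be
kept even once its neighbour is removed — which makes the filter symmetric
and order-independent.  Channel mapping applies the affine transform and
drops AOIs whose mapped box leaves the field.  Intensities are integrated
over a 5×5 box (halfwidth 2) with a per-frame local baseline from the
median of a surrounding annulus, which automatically follows the Cy5
background step.

Segmentation works on each channel's own excited-frame timebase (0.2 s
during alternation) and uses hysteresis thresholding: runs of at least
`min_frames` (default 2) frames above baseline + 3σ seed intervals, which
are extended through contiguous frames above baseline + 1σ, and dark gaps
of up to `gap_frames` (default 1) excited frames are bridged.  The low
threshold prevents occasional noise dips from splitting a long bound
interval into a spurious "displacement"; at zero noise both thresholds
coincide with the baseline, so noise-free segmentation is exact.  The σ
estimate comes from the median absolute first difference of the trace
(robust to plateaus and steps).  Whether real blinking gaps should be
bridged at all is an open experimental question; `gap_frames` is exposed
for that reason.

The flow time is located as a change point in the Cy5 background.  Because
binding events also raise the Cy5 signal, the detector median-filters the
trace and then takes the *earliest* significant upward step (recursing into
the left segment of the best two-segment split): the background step always
precedes binding.  The pipeline applies this to a per-frame lower-quartile
aggregate across AOIs, where unsynchronized binding excursions vanish while
the synchronized step survives.  An undetectable step (<5% variance
improvement, or a step smaller than 3σ) raises an error asking for a manual
flow time.

Stoichiometry is quantized by rounding each sample's background-subtracted
intensity to a fluorophore count and median-of-3 filtering, so a count
change must persist for at least two excited samples (0.4 s) to be
resolved; the ground-truth discretizer applies the same resolvability rule.

## Classification

`pair_intervals()` merges the two channels into a piecewise-constant
occupancy timeline `(resident_bound, competitor_count)`.  A colocalization
episode starts when the competitor count rises from zero with the resident
bound and is reset only when it returns to zero, so multi-competitor
loading before a displacement stays within one episode.  From the timeline:

* $t_{bind}$ — flow time to the first colocalizing competitor interval
  (molecules that never bind are reported right-censored at the remaining
  movie length, and dropped from CDF fits by default);
* $t_{diss}$ — episode start to a resident departure that is followed by
  continued competitor occupancy;
* $t_{co}$ — duration of each maximal colocalization episode, with the
  outcome (`resident_left`, `competitor_left`, `censored`) that ended it.

Mode flags follow the taxonomy above.  Passive requires that *no*
competitor colocalized at any time before the departure — the conservative
reading of "before a competitor binds".  A molecule can be both `active`
and `stable_coexistence` (a long cohabitation later resolved by
displacement).  A censored coexistence episode already longer than 20 s
counts as stable coexistence, since its true dwell can only be longer.
Maximum concurrent occupancy (resident + quantized competitors) is
reported as the stable-complex stoichiometry; cumulative visitor counts
would be an alternative reading, but concurrency is what a stepwise
intensity increase actually measures.

The 20 s stable-coexistence threshold is justified by a cellular
access-time argument implemented in `access_time_bound()`: 10–60 copies of
an mRNA in a 0.5 µm³ cell give 30–200 nM, and with
$k_{on} \approx 2\times10^5\,\mathrm{M^{-1}s^{-1}}$ an RNA needs 25–150 s
to reach Hfq, so 20 s is a sensible minimum residence time for a complex
to matter in vivo.

## Dwell-time kinetics

The core estimator is `fit_mle_mixture()`, a censored maximum-likelihood
fit of a 1–3 component exponential mixture

$$\mathcal{L} = \sum_{\mathrm{uncens}} \log \sum_j \frac{a_j}{\tau_j}
e^{-t_i/\tau_j} + \sum_{\mathrm{cens}} \log \sum_j a_j e^{-t_i/\tau_j},$$

with observations below the acquisition resolution (0.2 s under
alternating excitation) contributing the interval probability
$\sum_j a_j (1 - e^{-\mathrm{res}/\tau_j})$.  Lifetimes are optimized on
the log scale (which enforces positivity) and fractions through a softmax;
multi-start quasi-Newton optimization guards against local optima, and
components are reported sorted by ascending lifetime.  A fitted component
whose lifetime falls below the resolution is reported as 0 s
(sub-resolution) with the raw optimum retained in `lifetimes_raw`.  For a
single component without sub-resolution data the closed-form censored MLE
$\hat\tau = \sum_i t_i / n_{\mathrm{uncens}}$ is used directly.

`fit_cdf_exponentials()` provides the complementary least-squares fit of
$F(t) = \sum_j A_j(1-e^{-t/\tau_j})$ to the empirical CDF, used for
association-time (cumulative fraction bound) analysis; on large uncensored
single-exponential samples the two estimators agree within 2%.

The number of components is chosen by `select_model()`: the smallest $k$
not rejected against $k+1$ by a likelihood-ratio test at $\alpha = 0.05$
(2 degrees of freedom per added component), with BIC reported alongside.
The LRT matches the nested structure of the mixtures; at small sample
sizes it deliberately prefers fewer components — with $n = 30$ and a
lifetime ratio of 1.5, a single component is the honest answer.

Errors come from `bootstrap_errors()`: case resampling of the dwells (not
residuals, matching how dwell datasets are collected), refitting each
replicate from the point estimate, percentile 68%/95% intervals, label
switching resolved by sorting lifetimes.  Censored observations are
excluded from ECDF plots but enter the MLE through survival terms — the
300 s observation window makes long-lived states systematically censored,
and ignoring this demonstrably biases lifetimes low (a test covers this).

`density_histogram()` computes probability densities with binomial error
bars, $\sqrt{p_i(1-p_i)/N}/w_i$ — the package's stated convention for
histogram uncertainties.  `ks_two_sample()` wraps the asymptotic
two-sample Kolmogorov–Smirnov test used to compare dwell distributions
(e.g. all binding events vs. binding events that led to displacement).

## The pipeline and its outputs

`run_pipeline()` chains simulate → (render movie → extract | render
traces) → segment → classify → fit → summarize, writing intervals, dwells,
per-molecule records, survival curve, pair summary and heat-map CSVs, fit
JSON, a survival-curve PDF, and a machine-readable manifest (seed, config,
per-stage molecule counts) from which every table is regenerable.  Stage
failures abort with the stage named; molecule counts in and out of each
filter are logged because AOI exclusion and QC silently shrink the sample.
A thin command-line front end over these functions ships in
`inst/cli/hfqcompete.R`.

## What the synthetic data does and does not show

The simulator emulates: competitor arrival after a background-step flow
event, probing vs stable binding, displacement with mixture-distributed
delays, coexistence with either-species departure, multi-competitor
occupancy (up to 3 + resident), alternating excitation, exposure-dependent
photobleaching, Gaussian PSFs on a mapped two-half-field camera, and
right-censoring by the movie end.  It does **not** model sRNA secondary
structure, the geometry of Hfq's faces, base pairing, spectral cross-talk,
camera gain statistics (EMCCD excess noise), stage drift, or nonlinear
field distortion.  Passing tests therefore demonstrate that the analysis
correctly recovers the phenomenological kinetic scheme from realistic
noise — not that every optical artefact of a real microscope is handled.

## Problem sizes and numerical choices

The validation suite uses sizes chosen to make sampling error negligible
relative to the tolerances tested: 10,000 dwells for mixture recovery
(~1% relative SE on lifetimes), 10,000 molecules for analytic survival
(binomial SE < 0.5%), 500 molecules for noise-free oracle equivalence,
100 simulations × 500 bootstrap replicates for CI calibration, and one
100-molecule full-length movie (3,000 frames, 128×256 px) for the image
path.  Optimizer tolerances are `optim`'s BFGS defaults; mixture fractions
are normalized within 1e-6; ties in interval pairing are broken by the
half-open `[t_start, t_end)` convention throughout.  Degenerate inputs
(all dwells identical, empty traces, saturated images, singular channel
transforms) raise informative errors rather than fitting nonsense.

## Known limitations

* Dwells shorter than one excited frame per channel are unobservable;
  they surface only through the sub-resolution component convention.
* The flow-time detector assumes the background step precedes appreciable
  binding; if competitors are pre-bound before the flow event it will
  return the earliest step it can defend, and the pipeline falls back to
  the configured flow time on failure.
* Stoichiometry quantization trusts the single-fluorophore unit estimate;
  at high concurrent occupancy (>4) or strong bleaching the lowest-mode
  estimator can drift.
* The CDF least-squares fit ignores censoring by construction; it is kept
  for association-time analysis where censored molecules are dropped
  explicitly, and the censored MLE is the estimator of record elsewhere.
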