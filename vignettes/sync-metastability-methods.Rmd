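---
title: "Phase synchrony and metastability of parcellated BOLD time series: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase synchrony and metastability of parcellated BOLD time series: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syncmeta)
```

## The model

`syncmeta` treats each functional network of a parcellated resting-state
BOLD acquisition as a population of coupled oscillators and asks two
questions about it at every instant: *how coordinated is it* and *how much
does that coordination fluctuate*. For a network $n$ containing parcels $p$
with instantaneous phases $\theta_p(t)$, the instantaneous synchrony is the
Kuramoto order parameter

$$\varphi_n(t) = \left| \left\langle e^{i\theta_p(t)}
\right\rangle_{p \in n} \right|,$$

the modulus of the complex mean of the parcels' unit phasors: 1 when all
parcels share one phase, and approaching $1/\sqrt{N}$ for $N$ uniformly
dispersed phases ($E[\varphi^2] = 1/N$). Two scalars summarize the time
course over an acquisition:

* **sync** — the time mean of $\varphi_n(t)$;
* **metastability** — the standard deviation of $\varphi_n(t)$ over time
  (population normalization, divisor $T$), the standard variance-of-the-
  order-parameter definition from the coordination-dynamics literature.
  Since $\varphi \in [0, 1]$, metastability is bounded by $0.5$.

Metrics are computed for every labeled network plus a **Global** network
containing all parcels, in one fixed order (assignment-file order, Global
last). The **combined sync-metastability feature vector** concatenates all
networks' sync values followed by all metastability values; with 14
networks it is 28-dimensional. The comparator throughout is **static FC**:
the Fisher z-transformed Pearson correlation matrix between parcel time
series, vectorized as the off-diagonal upper triangle.

## Phase extraction

Phases come from narrowband components obtained by empirical mode
decomposition (EMD) rather than a prescribed band-pass filter, so no a
priori frequency band is imposed. Sifting follows the classic recipe:
locate local extrema, interpolate upper and lower envelopes with cubic
splines, subtract the envelope mean, and iterate until a Cauchy-type
criterion $\sum_t (h_{k-1} - h_k)^2 / \sum_t h_{k-1}^2 < 0.2$ is met (100
sift cap); extraction recurses on the residual up to `max_imfs` (default 4)
modes. The residual is defined as input minus IMF sum, so reconstruction is
exact by construction and is asserted to $10^{-8}$ relative error in the
tests. Envelope boundaries use mirror extension of the two outermost
extrema at each end, the standard mitigation of the spline end effect.

Mode 0 (the fastest IMF) corresponds to the canonical slow BOLD band
(~0.04–0.07 Hz on data simulated in that band); mode 1 is the next slower
component (~0.01–0.04 Hz). Either can be selected via
`run_config(mode_index =)`.

Instantaneous phase is the argument of the analytic signal, built in the
frequency domain: double the positive-frequency Fourier coefficients, zero
the negative ones, leave DC and (for even lengths) the Nyquist bin
untouched. Instantaneous frequency is the derivative of the unwrapped phase
(centered differences inside, one-sided at the ends) divided by $2\pi\,
\mathrm{TR}$. On a pure 0.05 Hz tone the recovered frequency is within 1%
away from the first/last 10 samples, and sine/cosine of one tone differ by
exactly $\pi/2$.

### Trimming

Two trims bracket every phase series (`run_config` defaults):

* `discard_initial = 60` s removed from the start of the *raw* signal
  (scan-onset transients);
* `edge_trim = 5` samples removed from *each end of the phase series*,
  after the transform, where decomposition edge artifacts concentrate.

A 10-min session at TR 1.16 s (517 samples) retains $517 - 51 - 10 = 456$
samples $= 8.8$ min. The same window (identical rows of the raw matrix) is
used for the FC comparator so the two metric families see the same data.

## Split-half reliability engine

Sessions are split into two disjoint halves A and B; partitions are unique
across iterations and everything is a deterministic function of one master
seed. The **baseline** feature vector is computed from the concatenation of
all sessions in A. For each duration step $k = 1..|B|$, $k$ sessions are
drawn fresh (without replacement, independently per duration) from B, the
test vector is computed from their concatenation, and similarity to the
baseline is Pearson correlation (feature vectors) or the normalized
absolute error $1 - |x - b|/|b|$ (single-network scalars, where
correlation is undefined; the unnormalized form $1 - |x - b|$ is available
behind `scalar_similarity_form`). Mean, population SD, and the
normal-approximation 95% CI ($\bar r \pm 1.96\,\mathrm{SD}/\sqrt{n}$) are
reported per duration; at around 1,000 iterations the normal and percentile
intervals are indistinguishable.

Because $\varphi_n(t)$ is instantaneous, metrics of a concatenation depend
only on the pooled time points: the engine therefore precomputes, per
session and network, the count, sum and sum of squares of
$\varphi_n(t)$ (and, for FC, the column sums and cross-products of the
trimmed raw series) once, and assembles any baseline/test combination
exactly from these sufficient statistics. No cross-session phase
continuity is assumed or needed, and draw order is immaterial (asserted in
the tests). Departure from a reference session is $1 - r$ between feature
vectors: 0 for the reference, 1 for uncorrelated, 2 for anti-correlated.

Multi-part acquisitions (e.g. 30-min sessions analyzed as three 10-min
sessions) are handled by `msc_session_split()`, which requires exact
divisibility and relabels contiguous blocks.

No multiple-comparison correction is applied across networks: the profiles
characterize per-network data requirements, not between-network hypothesis
tests.

## Surrogate nulls

`phase_randomize()` multiplies each positive-frequency Fourier coefficient
of each parcel by an independent random unit phasor, mirrors the conjugates,
and inverts — amplitude spectra (hence autocorrelations, by
Wiener–Khinchin) are preserved to machine precision while cross-parcel
phase relationships are destroyed. Randomization is independent per parcel
(the coupling-destroying variant; a shared phase vector would preserve
coupling and is deliberately not used). DC and the Nyquist bin are left
untouched so the inverse transform is exactly real.

`surrogate_null_metrics()` conceptually draws `n_surrogates_per_session`
surrogates per session and evaluates `pick_per_session` of them through the
full pipeline. Each surrogate is a pure function of a per-(session, index)
sub-seed, so only the picked surrogates are materialized; the result is
bit-identical to generating all of them first. Empirical and null
distributions are compared with the pooled-variance Student t test
(df $= n_1 + n_2 - 2$; Welch via `var_equal = FALSE`), the Mann–Whitney U
test, and Cohen's d with the pooled sample SD.

## The synthetic cohort generator

The generator emulates a highly sampled single-subject acquisition: by
default 84 sessions of 517 samples at TR 1.16 s (599.72 s — the nearest
whole number of samples to a nominal 10-min run), 333 parcels in 13
labeled networks of realistic sizes, natural frequencies drawn once per
subject uniformly from 0.01–0.07 Hz, fresh uniform initial phases per
session (independent runs), and additive Gaussian observation noise on an
amplitude-1 cosine observation model. Within-network Kuramoto dynamics

$$d\theta_p = \omega_p\,dt + \frac{K_n}{|n|} \sum_{q \in n}
\sin(\theta_q - \theta_p)\,dt + \sigma_\theta\,dW$$

are integrated by Euler–Maruyama at an internal step of TR/10, subsampled
to TR; when a configuration demands strong coupling the step is refined
automatically so that $K\,dt \le 0.25$, since the nominal step is unstable
for $K$ of order 10 and above. Coupling is strictly within-network, making
per-network coupling strengths the ground truth that downstream metrics
must recover. The latent phase matrix is attached to each simulated session
for oracle checks.

Parameter choices, and why:

* `coupling_per_network = 0.15`, `phase_noise_sd = 0.1`, `noise_sd = 0.3`
  (defaults): a latent-phase sweep across $K$ shows this regime reproduces
  the empirically typical operating point of resting BOLD networks — sync
  around 0.3–0.45 and metastability around 0.14–0.18 — i.e. weak partial
  synchrony, far from phase lock. For uniform frequency dispersion over
  0.01–0.07 Hz the mean-field critical coupling is $K_c = 2\,\Delta\omega/
  \pi \approx 0.24$; finite-$N$ order-parameter fluctuations (metastability)
  peak just below $K_c$, around $K \approx 0.15$, which is why that value
  serves as the "intermediate" coupling in the parameter-recovery
  experiments, flanked by $K = 0$ (independence) and $K = 50$ (lock).
* **Observation noise and EMD interact**: white noise has most of its power
  above the oscillation band, so with too much of it the *fastest* IMF
  tracks noise rather than the oscillation. Experiments whose point is the
  phase coupling itself (surrogate coupling destruction, parameter
  recovery) use `noise_sd = 0.1`, where mode 0 carries the oscillation;
  the reliability experiments keep `noise_sd = 0.3` as a harsher, more
  realistic session-to-session variability. Preprocessed BOLD has strongly
  attenuated high-frequency noise, so real mode-0 extraction sits closer
  to the low-noise regime.
* `simulate_linear_null()` generates independent band-limited Gaussian
  processes (exact frequency-domain masking, unit variance) — the negative
  control with no cross-parcel dependence by construction. Each parcel is a
  pure function of (seed, session, parcel index), so parcels are
  exchangeable.

What the generator deliberately does **not** model: hemodynamic response
convolution, scanner drift and physiological artifact spectra, motion,
and between-subject variability. Passing tests on these cohorts
demonstrate that the estimator chain is correct and that the engine's
statistical behavior (convergence with duration, surrogate contrast,
coupling recovery) is as designed — not that any particular real dataset
will show specific numeric reliability values.

## Numerical choices and degenerate inputs

* Fisher z at $|r| \to 1$: $r$ is clipped to $\pm(1 - 10^{-15})$ before
  `atanh`, keeping vectors finite; inert for real data.
* Metastability uses divisor-$T$ (population) SD; frozen because sync/meta
  of pooled concatenations must compose exactly from per-session moments.
* Single-parcel networks have $\varphi \equiv 1$ (sync 1, metastability 0)
  by definition; they are allowed but flagged with a warning.
* Signals with fewer than 4 extrema cannot be sifted and are returned
  whole as a degenerate residual; missing values are rejected, never
  imputed (censoring is an upstream concern).
* A cohort needs an even session count of at least 4 to half-split, and the
  number of requested iterations may not exceed $\binom{n}{n/2}/2$, the
  count of distinct unordered partitions.
* All sub-seeds are derived from the master seed by fixed integer mixing,
  below $2^{31}$, so every command and profile is byte-reproducible.

## Problem sizes used in the shipped experiments

The test suite and `scripts/acceptance.R` run entirely on synthetic
cohorts sized for a desktop: reliability uses 24 sessions × 5 min of 20
parcels in 2 networks with 100 split-half iterations; surrogate contrast
uses 20 sessions of 12 parcels (coupled) and 20 replicate cohorts of 10
sessions (uncoupled); parameter recovery uses 20 replicate sessions per
coupling level. These sizes give Monte-Carlo standard errors comfortably
inside the margins being asserted while keeping the full run in minutes.

## Known limitations

* EMD sift-convergence settings differ across implementations; on identical
  data, mode boundaries (and hence metric values) can differ in detail from
  other EMD codes even though the qualitative structure is stable.
* The scalar-similarity scale $1 - |x-b|/|b|$ is undefined at $b = 0$ and
  asymmetric in $b$; it is the appropriate scale only for strictly positive
  baseline scalars such as sync and metastability.
* The engine assumes stationarity across sessions of one subject
  (frequencies fixed per subject); state changes between sessions are the
  object of the departure analysis, not the reliability profiles.
* Observed similarity profiles on synthetic cohorts are not predictions of
  real-data reliability values; they validate engine behavior only.
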