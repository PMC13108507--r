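# syncmeta

Phase synchrony and metastability of parcellated resting-state BOLD fMRI
time series, with a split-half engine for profiling how reliable those
metrics are as a function of how much scan time you have.

## The problem

Metastability — the tendency of brain networks to switch intermittently
between coordinated and desynchronized states — is a widely used proxy of
brain dynamics in clinical and behavioral fMRI studies. Before a
metastability estimate can serve as an individual-level biomarker, one has
to know how much acquisition time is needed for the estimate to be stable
within a subject, the same question long settled for static functional
connectivity (FC). `syncmeta` is for researchers who want to (a) compute
per-network synchrony and metastability from parcellated BOLD data, (b)
quantify their within-subject reliability versus total acquisition
duration, (c) check the metrics against phase-randomized surrogate nulls,
and (d) quantify state changes (e.g. pharmacological sessions) as departure
from baseline.

## The metrics

For parcels $p$ in network $n$ with instantaneous phases
$\theta_p(t)$, the instantaneous network synchrony is the Kuramoto order
parameter

$$\varphi_n(t) = \left|\left\langle e^{i\theta_p(t)}\right\rangle_{p\in n}\right|,$$

and over an acquisition:

* **sync** $= \operatorname{mean}_t \varphi_n(t)$ — average coordination,
* **metastability** $= \operatorname{sd}_t\, \varphi_n(t)$ — temporal
  flexibility of coordination.

Phases are extracted per parcel by empirical mode decomposition (mode 0 is
the fastest intrinsic oscillation, the canonical ~0.04–0.07 Hz BOLD band)
followed by the analytic-signal (Hilbert) transform. Per-network values —
including an all-parcels "Global" network — are concatenated into the
**combined sync-metastability feature vector** (28-dimensional for 14
networks: all sync values, then all metastability values). Reliability of a
feature vector is its Pearson correlation to a baseline computed from a
held-out half of the sessions; single-network scalars use the normalized
absolute error $1-|x-b|/|b|$ instead. Static FC (Fisher-z correlation
matrix) is computed with identical trimming as the comparator.

Everything runs on plain tab-separated text (one time × parcels table per
session plus a two-column parcel→network table); a coupled phase-oscillator
simulator generates multi-session synthetic cohorts with known coupling for
validation, so no imaging data is required to exercise any part of the
package.

## Worked example

Simulate a 12-session cohort of 20 parcels in two networks with different
within-network coupling, compute per-network metrics, profile reliability,
and compare against surrogate nulls:

```r
library(syncmeta)

cfg <- simulation_config(n_parcels = 20, network_sizes = c(10, 10),
                         network_labels = c("A", "B"), n_sessions = 12,
                         session_duration = 300, tr = 2,
                         coupling_per_network = c(0.1, 0.3),
                         noise_sd = 0.1, seed = 1)
sessions   <- simulate_kuramoto_sessions(cfg)
assignment <- make_network_assignment(cfg$network_sizes, cfg$network_labels)
cohort     <- validate_cohort(sessions, assignment)
rc <- run_config(discard_initial = 30, edge_trim = 5,
                 n_iterations = 50, seed = 1)

network_metrics(session_phases(sessions[[1]], rc), assignment)
#>   network      sync metastability
#> 1       A 0.3912391    0.17900511
#> 2       B 0.8381036    0.08665178
#> 3  Global 0.4827019    0.14980460
```

Network B was simulated with three times network A's coupling, and its
higher sync (0.84 vs 0.39) and lower metastability (0.09 vs 0.18) recover
that: stronger coupling means tighter, less variable coordination.

```r
plan  <- build_split_plan(cohort$session_ids, rc$n_iterations, seed = rc$seed)
stats <- cohort_feature_stats(cohort, rc)
convergence_profile(stats, plan, "combined", rc)
#> reliability_profile 'combined': 50 iterations, durations 4.17-25 min
#>     metric duration_min   mean        sd  ci_lo  ci_hi
#> 1 combined        4.167 0.9982 0.0010626 0.9979 0.9985
#> 2 combined        8.333 0.9991 0.0006351 0.9989 0.9993
#> ...
#> 6 combined       25.000 0.9996 0.0002457 0.9996 0.9997
```

Each row: with that many minutes of test data, the combined
sync-metastability vector correlates with the held-out baseline at `mean`
(± `sd` across the 50 random split-half iterations) — already 0.998 from a
single retained session and converging monotonically.

```r
res <- cmd_surrogate(cohort, rc, n_surrogates = 100)
subset(res$comparison, network == "All")
#>          metric network mean_empirical mean_null    t df      p_t    U      p_u cohens_d
#> 1          sync     All          0.548     0.257 7.84 70 3.53e-11 1250 2.92e-15    1.849
#> 5 metastability     All          0.132     0.121 1.43 70 1.57e-01  782 1.33e-01    0.338
```

Phase randomization preserves every parcel's power spectrum but destroys
interregional coupling: empirical sync (0.55) collapses to the independence
floor (0.26, ≈ $1/\sqrt{N}$ for the 10-parcel networks), Cohen's d = 1.85 —
the synchrony is genuine coupling, not spectral artifact.

The same operations are scriptable from a shell via
`inst/scripts/syncmeta` (`simulate`, `metrics`, `reliability`, `surrogate`,
`departure` subcommands), all driven by one master seed.

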