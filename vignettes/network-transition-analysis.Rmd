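---
title: "Sliding-window functional network analysis of the preictal-ictal transition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sliding-window functional network analysis of the preictal-ictal transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(ictalnet)
library(dplyr)
```

## The problem and the model

In drug-resistant temporal lobe epilepsy (TLE), presurgical evaluation
combines scalp EEG (10–20 system) with semi-invasive foramen ovale
electrodes (FOE) that record directly from the mesial temporal surface on
each side. `ictalnet` treats such a multichannel recording as a time-varying
functional network and asks two questions about the transition from the
preictal to the ictal stage:

1. **Global reorganisation.** Does seizure onset increase overall
   synchronisation — more links (higher density of links, DoL), shorter
   average path length (APL), higher average weighted clustering (ACC) — and
   does the increase come from *inter-regional* links, visible as a drop in
   the modularity (Q) of the fixed anatomical four-community partition
   (left/right scalp, left/right mesial)?
2. **Mesial imbalance.** Is functional connectivity within the 6-contact
   mesial subnetwork on the side of seizure origin (ipsilateral) lower than
   on the opposite side, both before and during the seizure?

The pipeline is deliberately simple and close to clinical practice: signals
are re-referenced to the midline average (Fz + Cz + Pz)/3, band-pass
filtered to 0.5–60 Hz, resampled to 200 Hz, and cut into contiguous
non-overlapping windows of 1000 samples (5 s). Within each window,
functional connectivity between every channel pair is either

* the absolute Pearson correlation at zero lag, `|rho_ij|`, or
* the mean phase coherence `R_ij = |mean(exp(i (phi_i - phi_j)))|`, with
  instantaneous phases from the analytic (Hilbert) signal — an
  amplitude-free alternative that is less sensitive to volume conduction,

both bounded in [0, 1]. A link is kept when its coupling strictly exceeds a
threshold (default 0.5, scanned over 0.1–0.8 for robustness), and the graph
measures above are computed per window, for the whole 28-channel network and
for each 6-node mesial subnetwork. Two voltage-dependent measures that
ignore cross-channel structure are tracked alongside: the per-channel
normalised excitability (mean absolute derivative scaled by a 12-window
preictal baseline; values above 2.5 mark epileptiform activity) and the
spectral entropy (SE), the Shannon entropy of the unit-normalised
periodogram over the analysis band. A seizure typically imposes a dominant
rhythm, concentrating spectral mass and lowering SE regardless of which band
the rhythm occupies.

The statistical layer compares the two minutes before onset with the two
minutes after (24 windows each) using paired one-tailed Wilcoxon signed-rank
tests and standardized mean differences (SMD, pooled-SD denominator). The
battery has nine hypotheses: H1–H5 test the global transition (ACC up, APL
down, DoL up, Mod down, SE down); H6–H8 test the mesial imbalance
(ipsilateral DoL lower, APL higher, ACC lower) window-paired within each
stage; H9 tests a left–right SE imbalance irrespective of lateralization.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| window length `W` | 1000 | samples | 5 s at 200 Hz: long enough for a stable correlation estimate over 0.5–60 Hz, short enough to track seizure dynamics |
| band | 0.5–60 | Hz | clinical acquisition band; both connectivity and SE use the band-limited signal |
| link threshold | 0.5 | coupling | midpoint default; the `threshold_scan()` grid 0.1–0.8 shows conclusions do not hinge on it |
| epoch span | 120 | s | matches the typical TLE seizure duration (~106 s) and the persistence of post-onset changes |
| excitability baseline | 12 | windows | one minute of preictal activity; must precede onset |
| excitability threshold | 2.5 | – | strict inequality; empirical level for epileptiform activity |
| alpha | 0.05 | – | one-sided, per hypothesis, no multiplicity correction in the decisions (a Bonferroni column is reported) |

## The synthetic generator

Real seizure recordings of this montage are not publicly available, so the
package ships a seeded generator (`synth_config()`, `generate_recording()`)
that reproduces the *statistical structure* the analysis assumes, not the
biophysics. Each channel is a unit-variance linear mixture

```
x_i = w_priv * e_i + sqrt(a_i) * g_c(i) + sqrt(b_t) * G  (+ ictal rhythm)
```

of a private 1/f ("pink") noise source, one of four anatomical group
drivers, and a global driver. Variance shares map directly onto pairwise
correlations: within-group correlation is about `base_coupling +
global_coupling`, between-group about `global_coupling`. After onset the
global share is multiplied by `ictal_gain` and a shared sinusoid at
`ictal_freq` Hz ramps over 10 s to `ictal_amp` times the background RMS
(the ramp avoids a step discontinuity that would dominate excitability).

Default study conditions: 16 scalp + 2×6 FOE channels at 200 Hz, 300 s with
onset at 150 s (which covers the 24-window epochs on both sides and the
12-window baseline), `base_coupling = 0.6`, `global_coupling = 0.05`,
`ictal_gain = 3`, `ictal_freq = 7`, `ictal_amp = 2`, `ipsi_deficit = 0.5`,
left lateralization. The coupling shares were chosen once from a margin
argument: with a 0.5 link threshold the contralateral mesial within-group
correlation (~0.65) sits safely above the threshold and the ipsilateral one
(0.6 × 0.5 + 0.05 = 0.35) safely below it, so the designed deficit is
expressed in the thresholded graph rather than hidden inside sub-threshold
weights. The ipsilateral mesial channels receive the ictal rhythm scaled by
`max(0, 2 * ipsi_deficit - 1)` — zero at the default deficit — modelling a
seizure rhythm that propagates through the well-connected network while the
functionally disconnected ipsilateral subnetwork fails to phase-lock to it;
without this the shared rhythm saturates both mesial subnetworks at DoL = 1
and the designed ictal-stage imbalance would vanish. Linear mixing was
preferred over coupled oscillators because it gives analytically
controllable correlation targets; a Kuramoto-style generator would exercise
the phase measure more distinctively and is a natural extension point.

What the generator does **not** emulate: artifacts, non-stationary
background drift, interictal spikes, true seizure morphology (recruitment,
post-ictal suppression), or realistic volume conduction. Tests passing on
synthetic data therefore validate the *pipeline* — its bookkeeping,
estimators, statistics and their directions — not clinical performance on
real EEG.

```{r example}
gen <- generate_recording(synth_config(seed = 1))
analysis <- run_transition_analysis(gen$recording, method = "pearson",
                                    threshold = 0.5)
tidy(analysis) |> select(id, stage, measure, p_value, smd, decision)
glance(analysis)
```

```{r traces, fig.height = 6}
autoplot(analysis, span = 10)
```

## Numerical and design choices

* **Filtering.** 4th-order Butterworth applied forward–backward
  (`signal::filtfilt`), so the filter is zero-phase and the phase
  synchronisation downstream is unbiased. The high-pass and low-pass
  sections are cascaded instead of designed as one band-pass: a joint
  band-pass with a normalized corner at 0.5/(fs/2) is numerically fragile,
  while the cascade is stable and meets the stop-band (>20 dB at 100 Hz for
  fs = 500) and pass-band (<5% at 10 Hz) requirements.
* **Order of operations.** Re-reference → filter → resample → window.
  Filtering before downsampling avoids aliasing; the order is recorded in
  the recording's provenance.
* **Resampling.** Zero-phase Butterworth anti-alias low-pass at 90% of the
  target Nyquist followed by cubic-spline evaluation at the new sample
  times; pass-band amplitude error measured below 0.1%.
* **Windows.** A trailing partial window is dropped so all windows carry
  equal information. A window starting exactly at onset belongs to the
  ictal epoch (half-open convention).
* **Excitability.** The per-sample derivative magnitudes are summarised by
  their mean within each window before the baseline SD is taken
  (`baseline = "window"`, the default); pooling all baseline samples is
  available as `baseline = "pooled"`. A channel whose baseline SD is zero
  raises an error naming the channel. Strict `>` at the 2.5 threshold.
* **Spectral entropy.** Plain periodogram of the already band-passed
  window, restricted to the 0.5–60 Hz bins (n_freq = 298 at W = 1000,
  fs = 200), no taper; natural logarithm, so the flat-spectrum maximum is
  `log(n_freq)` nats and `0 log 0 := 0`. An all-zero window yields a
  flagged missing value and group means adjust their divisor.
* **Phase coherence.** Analytic signal via the frequency-domain Hilbert
  transform; 10% of samples are trimmed at each window edge before the
  circular average because the analytic signal is distorted at the window
  boundaries (fraction exposed as `edge_trim`). No extra band-restriction
  beyond the global filter: the broadband phase tracks the instantaneous
  dominant rhythm.
* **Graphs.** Links require coupling strictly above the threshold, so ties
  are dropped and the edge count is monotone in the threshold scan.
  Surviving edges keep the coupling as weight — used by the Barrat
  clustering coefficient — while DoL, APL and Q are computed on the binary
  graph, matching the binary character of the companion measures. Nodes
  with fewer than two neighbours get clustering 0.
* **APL on disconnected graphs.** Mean over reachable pairs with the
  unreachable fraction attached as an attribute; an edgeless graph is a
  flagged missing value. Averaging within the largest component is
  available via `mode = "largest_component"`. Because the graph is
  undirected, ordered and unordered pair averages coincide.
* **Modularity.** The headline trace is Newman–Girvan Q of the *fixed*
  anatomical four-community partition, which directly operationalises "how
  close is the current network to the regional sub-division" as one scalar
  per window and drops when inter-regional links appear. Greedy
  modularity maximization (`detect_communities()`) and its normalized
  mutual information against the anatomical partition are secondary
  outputs; on small graphs the greedy optimum is verified against
  exhaustive partition enumeration in the tests.
* **Wilcoxon conventions.** Zero differences dropped, average ranks for
  ties, exact signed-rank null for n ≤ 25 without ties (via the exact
  distribution function), normal approximation with tie and continuity
  corrections otherwise. Consecutive 5-s windows are serially correlated
  and the paired test is applied to them anyway — replicating the
  procedure under study — so each result carries the lag-1 autocorrelation
  of its epochs as a caveat metric; it plays no role in the decisions.
* **SMD sign convention.** Transition rows report pre − post (positive =
  the measure decreased during the seizure); imbalance rows report left −
  right (positive = higher on the left), irrespective of which side is
  ipsilateral. The hypothesis direction, not the SMD sign, encodes the
  ipsi/contra mapping.
* **H6–H8 pairing.** Window-wise pairs (left vs right value of the same
  window) within each stage, evaluated separately for the preictal and
  ictal stages; per-stage summaries would discard the pairing information.

## Problem sizes

The test-suite and acceptance runs use 300-s synthetic recordings (60
windows of 5 s, 28 channels), 20-seed batches for parameter recovery,
50-seed batches for null calibration, 1000 simulated epoch pairs for the
type-I check, and graphs of up to 10 nodes wherever a brute-force oracle or
exhaustive partition enumeration is the reference. These sizes make every
stochastic check reproducible in minutes on a single core while leaving the
Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* Sensor-space analysis: volume conduction is mitigated (average-ish
  reference, phase synchronisation option), not removed; no source
  reconstruction, no Phase Lag Index.
* Undirected, zero-lag coupling only — no directed or lagged connectivity.
* The link threshold induces dependence among all graph measures; the scan
  quantifies, but does not eliminate, this.
* Wilcoxon p-values on serially correlated windows are anti-conservative in
  principle; the null-calibration tests bound the practical effect under
  the generator's conditions only.
* EDF input is not implemented; recordings enter as delimited text matrices
  (the standard ASCII export of clinical review software) plus a YAML
  channel map.
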