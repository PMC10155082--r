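---
title: "Passive-sensing features and symptom association: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive-sensing features and symptom association: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobsense)
```

`mobsense` turns two raw smartphone streams — timestamped GPS fixes and
Wi-Fi connection events — into per-participant behavioral features, and
fits covariate-adjusted linear models of depression (PHQ-9) and PTSD
(PCL-5) severity on those features. This vignette documents the methods
and the judgment calls behind them, in the spirit of a lab notebook: a
green test establishes exactly what is written here, no more.

## Cohort assembly

**Device replacements.** A participant who loses a phone and receives a
replacement produces two event streams. They are concatenated and
analysed as a single time-ordered sequence (`merge_device_streams()`).
Events identical on every payload column are deduplicated once; near
duplicates (same second, jittered coordinates) are kept, since there is
no principled fuzz radius that is right for both GPS and Wi-Fi.

**Study window.** Events recorded beyond 180 days after a participant's
first event are discarded before anything else is computed — devices
that keep uploading after study end are not data. The window is
anchored at each participant's earliest recorded event because
enrollment timestamps are not part of the sensor streams.

**Inclusion.** A participant is retained only with at least 14 distinct
local calendar days containing a Wi-Fi event; "less than 14" is the
exclusion rule, so exactly 14 retains. We count *calendar days* in a
configurable time zone (default `America/Chicago`) rather than rolling
24-hour spans: calendar days are what a two-week baseline is meant to
balance (each weekday observed twice), and they are reproducible
without defining a per-participant clock origin. Every exclusion is
reported with a reason; the filter is idempotent.

**Out-of-region travel.** Fixes are flagged against a closed
latitude/longitude box (default: an Illinois-wide box, since
"out-of-state" travel is the behavior of interest at this deployment).
Cluster and entropy features use only in-region fixes; daily distance
uses all fixes, because a trip away is genuine distance covered but
should not mint spurious far-away clusters.

## Wi-Fi features

**Session heuristic.** Connectivity is observed only as discrete
events, so connected time must be reconstructed. A session is a maximal
run of events whose consecutive gaps are ≤ `gap_threshold` seconds
(default 1000); a longer gap is read as a disconnect and reconnect.
Session duration is last event time minus first, so total time equals
the sum of all below-threshold gaps, a singleton session contributes 0,
and three limits hold exactly: total time is monotone non-decreasing in
the threshold, equals the event span at threshold ∞, and equals 0 at
threshold 0. The alternative reading — counting each gap to the *next*
event regardless of size — is not monotone and over-counts idle time;
we rejected it for that reason. The 1000 is taken literally as 1000
seconds (≈ 16.7 min) and exposed as a parameter, since nothing in the
event format justifies rounding it to 15 minutes.

**Attribution.** A session belongs to the SSID of its first event, and
an SSID change splits the session at the change point even without a
long gap. Without the split, time on one network would silently bleed
into another's total.

**Classification.** A name containing "guest" (case-insensitive) is
public; otherwise a name matching the shipped venue lexicon
(`inst/extdata/public_ssid_lexicon.txt`: libraries, transit, hotels,
café chains, carrier hotspots; case-insensitive substring match, first
matching pattern wins) is public; every other non-empty name is
private; an empty name is unclassifiable. Exactly one rule fires per
SSID and is recorded, so any classification can be audited. The lexicon
is a plain editable text file because no canonical list of "common"
public network names exists.

**Features.** Total minutes, mean daily minutes over distinct observed
days, per-network duration shares, public/private/unclassifiable
shares, the dominant network's share, and a private-dominance flag
(private share strictly greater than 0.5). Shares are weighted by
session duration; in the degenerate case where every session is a
singleton (total duration 0) they fall back to event counts so that
shares still sum to 1.

## Mobility features

**Binning.** GPS arrives several times a minute, so raw fixes
over-represent well-sampled periods. Fixes are grouped into half-open
15-minute intervals aligned to the Unix epoch (a boundary fix belongs
to the later bin), each represented by the component-wise median of its
member coordinates — robust to single-fix jitter, which a mean is not.

**Clustering.** Density-based clustering under the haversine metric
(sphere radius 6371.0088 km) with eps = 0.5 km and minPts = 5: a bin
is a core point when ≥ 5 bins (itself included) lie within 0.5 km;
clusters are maximal density-connected sets; the rest is noise.
Distances are spherical, not planar, because eps is stated in
kilometres. Two determinism choices depart from textbook DBSCAN, whose
border assignment is input-order dependent: clusters are computed as
connected components of the core-point graph, a border point attaches
to its lowest-index core neighbour's cluster, and labels are
canonicalised by smallest member index. The result is invariant to
input permutation, which the tests verify, and agrees with a
brute-force reachability-closure oracle on hundreds of random
instances. Neighbor search uses a lat/lon grid (cells sized to cover
eps) with exact haversine verification, so dense anchor clouds do not
need quadratic memory.

**Entropy.** With pᵢ the fraction of clustered time in cluster i,
E = −Σ pᵢ ln pᵢ (natural log; the normalized version E/ln K is
base-invariant anyway). Each bin carries a uniform 900-second weight
rather than its fix count — the binning exists precisely to remove
sampling-density bias. Noise bins are excluded from numerator and
denominator: unclustered time has no pᵢ to belong to. Both choices are
parameters of interpretation rather than of the formula, and both are
documented here because reasonable pipelines have differed on them.
Normalized entropy is undefined for K ≤ 1 and reported missing;
participants with K = 1 have E = 0.

**Daily distance.** Sum of haversine legs between consecutive fixes
within each local calendar day, a cross-midnight leg charged to the day
it starts, with a miles helper (× 0.621371). Note that raw-fix
summation is jitter-inflated: a stationary phone with 10 m GPS noise
sampled twice a minute accrues tens of kilometres of apparent movement
per day. We keep the definition because it is the plain reading of
"distance between consecutive recorded points", and flag it as a known
limitation rather than silently smoothing.

## Symptom association

Each model is ordinary least squares of one outcome (PCL-5 or PHQ-9
total) on one predictor (entropy, normalized entropy, cluster count, or
mean daily Wi-Fi minutes). Full-cohort models adjust for employment,
school enrollment and shelter site; shelter-stratified entropy models
adjust for employment and school only (the stratum *is* the shelter).
The fit uses a QR decomposition and reports two-sided t-test p-values
on n − p degrees of freedom; a rank-deficient design is a fatal error
naming the aliased columns instead of silent coefficient dropping. A
covariate with no variation inside a stratum is dropped from that cell
(it carries no information and would alias the intercept), and a cell
with n ≤ p is reported "not estimable" without stopping the suite.

The effect size reported beside each adjusted coefficient is the
*bivariate* R² — the squared Pearson correlation of predictor and
outcome alone — which answers "how much variance does this signal
explain by itself" and is invariant to affine rescaling. Participants
missing a feature (e.g. normalized entropy with K ≤ 1) are dropped
listwise from that model only, with per-model n reported. Primary
p-values are unadjusted; a Benjamini–Hochberg column is appended as a
clearly-labelled supplementary quantity.

PHQ-9 totals band at cuts 5/10/15/20 (score equal to a cut enters the
higher band); a PCL-5 total ≥ 33 flags probable PTSD.

## The synthetic cohort

The generator exists so the pipeline can be exercised with known ground
truth. Its defaults state a world resembling the motivating deployment:
19 participants, a 180-day window, log-normal active spans with mean
90 days, GPS twice a minute, and 3-in-19 chances each of a device
replacement and of a brief out-of-state trip. Covariate prevalences
default to 15.8% employed, 57.9% enrolled in school, and an even
shelter split.

**Movement** is semi-Markov dwell across 2–8 anchors placed ≥ 3 km
apart within 8 km of central Chicago: episodes drawn with probability
equal to the dwell weights and log-normal lengths (mean 2.5 h, sdlog
0.5 — short dwell episodes fit an unstably-housed population cycling
between shelter, school, work and services, and give 60-day traces
enough episodes to estimate occupancy to ±0.03), so long-run occupancy
converges to the weights and programmed entropy is −Σ w ln w. Between
different anchors the participant traverses the straight corridor at
25 km/h, but only ~5% of in-transit 15-minute intervals record fixes —
phone GPS in vehicles and underground drops out in long stretches — so
corridors appear as sparse noise bins rather than chains that would
density-connect anchor clusters. GPS jitter is isotropic Gaussian with
10 m SD (typical smartphone accuracy), converted from km to degrees
with the local metric (÷111.195 for latitude, ÷111.195·cos(lat) for
longitude — adequate at city scale). Whole 15-minute intervals drop out
at 15% to emulate collection gaps.

**Wi-Fi** is one private home/shelter network plus two public venue
networks per participant, session counts Poisson at per-network daily
rates scaled by a log-normal participant-level intensity (spanning
roughly 10–600 min/day), log-normal session lengths, and events every
30–120 s within a session. Session windows are laid out without overlap
and separated by more than the gap threshold, so programmed minutes are
recoverable up to one event spacing per session — the tests assert
exactly that bound.

**Symptoms** are generated *from* the programmed features (the
features → symptoms direction only): outcome = linear predictor +
Gaussian noise, rounded and clipped to the instrument range, with the
clipping rate reported as an attribute. Default effect magnitudes are
plausible for these scales (−30.55 PCL-5 and −7.08 PHQ-9 points per nat
of entropy; 0.09 PCL-5 points per daily Wi-Fi minute; no Wi-Fi effect
on PHQ-9) around baselines that keep scores mid-range. Clipping biases
recovered coefficients toward zero when effects push scores past the
scale ends; the calibration tests therefore use a design (entropy
SD 0.25, baseline centred at 40) in which the clipping rate is
verifiably below 2%, and the recovery test's noise SD comes from the
closed form sd = |β|·sd(entropy)·√((1−R²)/R²) targeting a bivariate
R² of 0.3.

**What the generator does not emulate:** street-network routing,
circadian structure (no day/night rhythm), captive portals or BSSID
semantics, symptom feedback on movement, and item-level instrument
responses. A green end-to-end test therefore establishes that the
pipeline recovers programmed ground truth under this stated world — not
that any particular empirical effect exists in real cohorts.

## Numerical and degenerate-input policy

- Haversine uses R = 6371.0088 km with the arcsine clamped to [0, 1]
  against rounding at antipodes.
- Coordinates outside [−90, 90] × [−180, 180] and unparseable
  timestamps are rejected at read time and counted, never silently
  dropped; a missing required column is fatal.
- Empty event streams yield empty session/bin lists; a participant
  whose bins are all noise has missing entropy; a day with fewer than
  two fixes has distance 0.
- All randomness flows through explicit seeds; identical
  (configuration, seed) reproduces every output byte-for-byte, and run
  manifests deliberately contain no timestamps for that reason.

## Known limitations

Raw-fix daily distance is jitter-inflated (above). The session
heuristic cannot see time connected between two isolated probe events
farther apart than the threshold. The public/private classifier is a
name heuristic and inherits the lexicon's coverage. The grid-indexed
neighbor search does not handle traces spanning the antimeridian
(irrelevant at city scale but stated for completeness). Entropy
convergence to programmed weights is asymptotic in observation span;
short spans under-disperse.
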