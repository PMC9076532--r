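---
title: "Engagement-gated place codes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Engagement-gated place codes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`placegate` reimplements, as a tested pipeline, the analysis chain used to
ask whether hippocampal CA1 place codes persist when a mouse voluntarily
stops performing a navigation task: classify trials into engaged and
disengaged states from licking behavior, detect place fields against a
shuffle null separately in the two states, and decode position with a
Poisson naive-Bayes population decoder under several train/test protocols.
Because the package is exercised on synthetic sessions, every analysis can
be checked against the generative ground truth.

# The task and data model

A head-fixed mouse runs on a 2-m virtual linear track that repeats in a
circular topology. Licking in a 20-cm reward zone (10 cm of anticipatory
zone is prepended for all analyses) triggers a water reward on *standard*
trials; *probe* trials omit the reward; *crutch* trials deliver it at zone
entry regardless of licking. A session is a `pg_session`: per-frame
position, speed, lick and reward booleans and trial indices at 30 Hz, plus
a cells x frames nonnegative deconvolved-activity matrix.

# Synthetic session generator

The generator (`gen_config()`, `generate_session()`) is a stated world,
not a fitting device; its defaults encode the conditions the analysis is
meant to face.

* **Engagement states.** A two-state Markov chain over trials (default
  self-transitions 0.95/0.90, started engaged) produces streaky
  disengagement, as observed late in real sessions.
* **Trajectory.** Speed is generated first and position integrated from
  it, so frames per trial vary with state. Engaged trials slow down by a
  relative depth (default 0.5) in the 20 cm before the reward zone (flat
  dip with 5-cm cosine ramps); disengaged trials run at a
  position-independent mean speed. Per-trial lognormal speed factors
  (CV 0.1) and 1.5 cm/s frame jitter add realistic variability.
* **Licking.** Engaged trials draw ~10 licks per trial from a wrapped
  normal around the reward-zone start (s.d. 10 cm); disengaged trials draw
  ~1 lick uniformly. Rewards follow the task rules; a consumption bout is
  emitted after each reward with probability 1 (engaged) or 0.25
  (disengaged — satiated mice largely ignore rewards, which is also why
  they disengage). Consumption modelling matters because the lick metrics
  must exclude consumption licks.
* **Tuning.** Half the cells carry a place field: a wrapped Gaussian
  (s.d. 10 cm, amplitude 1, baseline 0.02) at a uniform center. On
  disengaged trials, 52% of tuned cells lose their field (flat curve at
  the same mean rate, conserving population activity), half of the
  survivors remap to a new uniform center, and 25% of untuned cells gain
  a field. These fractions are the degradation levels reported for real
  data and are the recovery targets of the acceptance tests.
* **Activity.** Frame activity is the state-appropriate tuning curve at
  the current position, scaled by a per-cell, per-trial lognormal
  amplitude factor (mean 1, CV 0.3; variance inflated 3x on disengaged
  trials) plus additive exponential noise (mean 0.05, inflated 3x when
  disengaged). Everything is nonnegative by construction.
* **Reproducibility.** A single seed expands into independent per-component
  substreams, so the same `(config, seed)` is bit-identical and individual
  components can be regenerated in isolation.

Where the source protocol stated values (track geometry, trial-type
probabilities, bin sizes, smoothing widths, the 52%/25% degradation
fractions), the defaults use them; lick counts, speeds and noise levels
are not reported anywhere, so defaults were chosen once for qualitative
realism (trained mice run ~20 cm/s and emit on the order of ten
anticipatory licks per rewarded trial) and are not tuned thereafter.

# Behavioral state classification

Two per-trial metrics summarize licking: **lick selectivity**
\[(s_{rz} - s_{opp}) / (s_{rz} + s_{opp})\], where \(s\) are the masses of
the Gaussian-smoothed (s.d. 10 cm, 2-cm bins) non-consumption lick profile
in the 30-cm analysis reward zone and in the equally sized zone half a
track away; and **bins with licks**, the number of 5-cm bins containing at
least one non-consumption lick. The metric lick set contains every
non-consumption lick plus the *first* lick after reward availability (the
reward-triggering lick); only the subsequent consumption bout is excluded.

Numerical choices worth noting:

* The lick-profile kernel is truncated at 3 s.d. A truncated kernel makes
  "no licks near either zone" a real, attainable state — with infinite
  tails the selectivity of a trial with one lick anywhere collapses to
  exactly +/-1 through the ratio of two negligible tail masses. Trials
  with zero mass in both zones have undefined selectivity.
* Trials with no metric licks cannot be task-engaged and are labeled
  disengaged without entering the clustering (k-means cannot take
  undefined inputs).
* Both metrics are z-scored before 2-means clustering (the normalization
  is not specified further in the source; z-scoring is the scale-free
  default). k-means runs with a fixed seed and 10 restarts; the cluster
  with the larger normalized centroid sum is engaged, ties broken on the
  selectivity coordinate.
* Silhouette scores use squared Euclidean distance, matching the default
  of the MATLAB implementation the original analysis would have used.
* Clustering can be run per session or on trials pooled across sessions
  (`cluster_engagement()` is agnostic to where its metric pairs come
  from); pooling is what the original analysis did.

Streak statistics (`streak_stats()`) decompose the label sequence into
maximal runs and report the disengaged streak-length histogram and the
2x2 transition matrix, against a 1,000-permutation shuffle control.
Transitions are counted circularly (last trial to first): each trial then
contributes exactly one outgoing transition and the shuffle expectation of
P(D to D) is exactly \((k-1)/(n-1)\) for \(k\) disengaged of \(n\) trials.

Exclusions: trials shorter than 3 s or longer than 60 s; crutch trials
whose metric licks all fall in the analysis zone (reward is guaranteed
there, so such licking carries no evidence of engagement); annotated
manual-reward trials. Sessions need at least 50 trials, mean lick
selectivity above 0.7, at least 20 sliding-decoder trials below 10 cm
error, and more than ten trials of each state.

# Place fields

Activity is averaged in 40 5-cm bins per trial (frames below 5 cm/s are
excluded — the speed filter is applied to field detection as well as
decoding, since place-cell activity is locomotion-dependent), zero-
occupancy bins are interpolated from circular neighbors and flagged, and
profiles are circularly smoothed (Gaussian s.d. 10 cm = 2 bins).

The shuffle null circularly shifts the behavioral series relative to the
activity by at least 500 frames, cuts it into 6 equal chunks (remainder to
the last) and permutes their order, preserving temporal autocorrelation
while destroying position locking. A field is a maximal circular run of at
least 3 bins whose trial-averaged activity exceeds the per-bin 99th
percentile of 100 (screening) or 1,000 (quantitative) surrogates; if a
cell has several candidate runs, the one containing the global peak is
kept.

Per-field metrics: **reliability** is the mean pairwise Pearson
correlation of per-trial binned activity (pairs with a constant vector are
skipped and counted); **selectivity** is \((\bar A_{in} - \bar A_{out}) /
(\bar A_{in} + \bar A_{out})\) with per-bin-normalized means. Engaged and
disengaged fields are computed on matched trial sets: all trials of the
smaller class plus the equally many trials of the larger class closest to
the smaller class's median trial index (ties to the earlier trial).
`compare_fields()` cross-tabulates field presence (both / lost / gained /
neither) and reports circular peak distances; "similar location" defaults
to 4 bins = 20 cm, a configurable convention (the original threshold is
not printed).

# Decoding

The Poisson naive-Bayes decoder scores each 5-cm bin by
\(\log P(pos \mid a) = \sum_i a_i \log(f_i(pos) + \varepsilon) - \tau
\sum_i (f_i(pos) + \varepsilon) + C\) with a uniform prior,
\(\tau = 1/30\) s, and \(f\) the trial-averaged smoothed rate map of the
training trials. The floor \(\varepsilon\) is 1% of the grand-mean
template value (zero-rate handling is unspecified in the source;
the floor preserves likelihood ordering), applied at decode time only.
All computation is in the log domain with per-frame max subtraction; MAP
ties go to the lowest bin. Decoding error is the circular bin distance
(0–20 bins = 0–100 cm); chance level under uniform decoding is exactly
\(n_{bins}/4\) = 10 bins = 50 cm.

Protocols:

* **Sliding** (`sliding_decoder()`): train on 20 trials, test the next;
  feeds session inclusion.
* **Engagement-split** (`engagement_decoder()`): train on consecutive
  non-overlapping blocks of 10 same-state trials, test on all held-out
  trials, average trial-wise errors per train/test condition. (The exact
  block-sampling scheme is ambiguous in the source; consecutive
  non-overlapping blocks are the deterministic default.)
* **Speed-matched** (`speed_match()`, `speed_matched_decoding()`): within
  each 2-cm spatial bin, speed is discretized into 5 cm/s bins and
  min(count A, count B) frames are subsampled without replacement from
  each block of a pair, equalizing the per-position speed distributions
  exactly; pairs with more than ten empty spatial bins are excluded.
* **Streak-onset** (`streak_onset_decoder()`): for disengaged streaks of
  at least 10 trials preceded by 30 trials at least 80% engaged, train on
  trials 21–30 before onset, test on the next 20 and the streak, aligned
  to onset.
* **Template matching** (`template_match_decode()`): cosine similarity
  against template columns, a control without the Poisson assumption.

Test-frame activity is the smoothed deconvolved value, consistent with the
rate maps (whether the original decoding smoothed test frames is not
restated there).

# What a green test does and does not establish

The generator reproduces: streaky disengagement; state-dependent licking
and the pre-reward slowdown; field loss/gain/remapping at the reported
fractions; and a disengaged code that degrades cross-state decoding while
remaining above chance. Green tests establish that the pipeline recovers
these constructed truths at the stated tolerances.

Two fidelity limits are worth knowing. First, the ground-truth model is a
*fixed* disengaged tuning curve per cell, so the disengaged code is
internally coherent: a decoder trained and tested within disengaged trials
performs well here, whereas on real data it was as poor as cross-state
decoding. Reproducing that would need trial-unstable disengaged maps,
which the data model deliberately omits. Second, the per-trial amplitude
factor is scale-invariant under Pearson correlation, so it lowers
reliability only by pushing weak trials into the additive-noise floor;
reliability contrasts between states are therefore much weaker than in
real data, and the state contrast in field quality shows mainly in the
mask-based selectivity timecourse around disengagement onset.

Label recovery by the lick-based clustering saturates near 0.93, not 1.0:
a disengaged trial whose single stray lick lands near the reward zone is
metrically indistinguishable from a low-lick engaged trial — a property of
the behavioral definition, not an implementation artifact.

# Degenerate inputs and tie rules

Undefined lick selectivity is a value state (NA + disengaged label), not
an error. Trials with no frames above the speed filter are flagged and
excluded from their rate map. Cells with all-zero templates decode via the
floor. MAP and centroid ties, trial-matching distance ties, and sequence-
sort peak ties all break to the lower index. The shuffle null requires
more than 1,000 frames in the trial set (so a 500-frame shift exists);
`run_pipeline()` flags and skips the field stage on shorter matched sets.
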