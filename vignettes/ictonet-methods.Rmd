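---
title: "Peri-ictal brain network ictogenicity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peri-ictal brain network ictogenicity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Resective epilepsy surgery aims to remove the tissue that generates
seizures. When intracranial electrodes sample the *ictogenic network* well,
a computational model placed on the functional connectivity (FC) inferred
from the recordings can predict how much a given resection would reduce
seizure propensity. But FC changes with brain state, and there is no a
priori way to know whether the FC inferred from a given recording
represents the ictogenic network at all. `ictonet` implements a full
pipeline around one answer to that question: simulate seizure dynamics on
FC networks inferred from successive peri-ictal time windows, quantify each
network's propensity to seize — its *brain network ictogenicity* (BNI) —
and use the presence of a consistent ictal BNI elevation as a per-subject
marker that the FC captures the ictogenic network, which in turn stratifies
how much the model's virtual-resection score (ΔBNI) can be trusted.

## FC inference with surrogate correction

Each annotated recording (3 min pre-ictal, a seizure, 3 min post-ictal) is
down-sampled to 512 Hz, re-referenced against the cross-channel median,
band-pass filtered 0.5–120 Hz and notch filtered 48–52 Hz (zero-phase
Butterworth: 4th-order high/low-pass cascade, 2nd-order band-stop), and cut
into 8 s segments with 1 s gaps, each segment labelled by the epoch that
contains it.

For each segment, every channel is randomized into 10 iterated amplitude
adjusted Fourier transform (IAAFT) surrogates. IAAFT alternates between
imposing the original Fourier amplitude spectrum and rank-ordering the
original sample values onto the result; iteration stops when the rank
ordering fixes itself or after 100 iterations. Surrogates preserve each
channel's amplitude distribution exactly and its power spectrum
approximately while destroying cross-channel coupling, so they provide the
null ensemble for association testing. The segment is divided into 10
subsegments of 2 s with uniform start spacing of (8−2)/9 s — the unique
uniform layout minimizing the maximum pairwise overlap — and the same grid
is applied to each surrogate, giving 10 original and 100 surrogate
subsegments.

The association between two channels is either the absolute zero-lag
Pearson correlation |ρ| or the nonlinear h² index (variance explained by a
piecewise-linear regression curve through per-bin means over 10 equal-count
bins, symmetrized as the maximum over both directions). For each channel
pair a one-sided Mann–Whitney U test asks whether the 10 original
associations are stochastically larger than the 100 surrogate ones;
Bonferroni–Holm step-down over all N(N−1)/2 pairs controls the family-wise
error. The corrected weight is

  C_ij = max(0, (ρ₀ − ρ_surr) / (1 − ρ_surr)) · s_ij

for the Pearson measure (H_ij = h²_ij · s_ij for h²), with s the Holm
rejection mask and ρ₀, ρ_surr the medians of the original and surrogate
association samples. The median was chosen as the per-pair scalar summary
because it is the natural companion of the rank-based significance test;
the absolute value and the clipping at 0 reflect that the downstream model
needs nonnegative coupling weights. One-sided testing is used because only
an excess of association over the surrogate null is evidence of coupling.

## The theta-neuron network model and BNI

Each FC node carries a theta neuron,

  dθ_j/dt = (1 − cos θ_j) + (1 + cos θ_j) · I_j(t),
  I_j(t) = I₀ + ξ_j(t) + (K/N) Σ_i a_ij [1 − cos(θ_i − θ_i^s)],

with a_ij the FC weight, K a global coupling scale, and θ_i^s =
−arccos((1+I₀)/(1−I₀)) the stable fixed point of the uncoupled node. With
I₀ < 0 the node is excitable: noise can push it through the saddle-node on
invariant circle (SNIC) bifurcation into a full phase rotation (a spike);
for I₀ > 0 it spikes autonomously with period π/√I₀ — the closed form used
in the tests. Integration is Euler–Maruyama with the noise entering through
the same (1 + cos θ) gain as the deterministic input, step dt, phases
wrapped to (−π, π], spikes recorded at upward crossings of θ = π.

Defaults: I₀ = −1.2 (homogeneous), noise SD 0.6, dt = 0.01, 4 × 10⁶ steps
in the `paper` profile and 2 × 10⁵ in the `test` profile. I₀ near the
bifurcation with moderate noise gives rare spontaneous escapes at zero
coupling and robust network recruitment at strong coupling; BNI comparisons
are only meaningful between networks simulated with identical parameters,
so the absolute values of these defaults matter less than holding them
fixed.

A node is "in the seizure state" at time t if it spiked within the trailing
window w = 3π/√0.5 time units (three nominal inter-spike intervals of the
spiking regime, so sustained spiking maps to contiguous seizure time);
BNI\*(K) is the average over nodes of the fraction of the simulation spent
in that state, after discarding the first 10% of steps as transient. Since
BNI\* depends on the arbitrary K, BNI is defined as the trapezoidal
integral of BNI\*(K) over a fixed interval [K₁, K₂], K₁ = 0. K₂ is fixed
per subject: every segment network is scanned by coupling doubling until
BNI\* ≥ 0.95, and K₂ is 1.2 times the largest saturation coupling, with a
21-point linear grid over [0, K₂] for the integral. Segment significance
graphs can leave nodes with no edges, which caps BNI\* below 0.95 no matter
how large K is; such segments are dropped from the K₂ rule, and if no
segment reaches 0.95 the pipeline relaxes the saturation level stepwise
(scaling it by 0.85 and then 0.6) rather than aborting the subject. Whether [K₁, K₂]
should be fixed per subject or globally is ambiguous in principle; it is
fixed per subject here because BNI values are only ever compared within a
subject before normalization.

Per recording, the segment BNI series is normalized by its maximum over the
whole peri-ictal epoch and the ictal portion is linearly resampled onto 10
equally spaced points in normalized seizure time, making seizures of
different durations comparable. A subject shows *elevated ictal BNI* when a
one-tailed U test finds the ictal values stochastically larger than the
pre-ictal values in **both** peri-ictal recordings independently.

## Virtual resection

The resection substrate is the mean corrected-FC matrix over segments in
the first half of the ictal periods (pooled over both recordings) — the
window whose connectivity best reflects epileptogenic tissue — computed
with the same Pearson-based correction and the theta model (one FC method
and one dynamical model throughout). The global coupling is calibrated by
bracketing and bisection until BNI\*(K_ref) = 0.5 ± 0.05, averaged over 3
noise realizations; 0.5 leaves maximal headroom in both directions.
Removing the resected node set n_s (rows and columns deleted, N in the K/N
prefactor reduced accordingly) and re-simulating at K_ref gives

  ΔBNI = (BNI_pre − BNI_post) / BNI_pre,

the model's prediction of resection benefit: near 1 when removal suppresses
seizure activity, near 0 when it does not.

## Cohort statistics

Pooled epoch comparison uses the Kruskal–Wallis test; elevated-ictal versus
dichotomized outcome (Engel I–II good, III–IV poor) is tested by a
permutation chi-square — 10,000 random reassignments of the elevated flags
preserving their count, add-one p-value convention to avoid p = 0. ΔBNI's
outcome discrimination is the rank-based ROC AUC; two groups' AUCs are
compared by enumerating all ⌊n/2⌋-subsets containing both outcome classes
("half-group splitting"), computing the AUC of each, and comparing the two
AUC distributions with a two-sided U test. The 2 × 2 dichotomization and
the subset reading of "half-group splitting" are the two places the
statistical protocol needed an interpretation; both are noted here as the
package's choices.

## The synthetic cohort

Clinical peri-ictal iEEG is not publicly available, so validation runs on a
ground-truthed generator. Each synthetic subject has a random background
coupling graph (edge density 0.2), a designated *ictogenic core* that is a
fully connected subnetwork — a core with no internal coupling could not
play the role of a seizure-generating subnetwork — a responder flag, and a
resection mask that either covers the core (intended good outcome) or
overlaps it in fewer than 40% of core nodes (intended poor). Signals are a
switched first-order vector autoregression at 512 Hz: diagonal 0.5,
off-diagonal 0.15 on background edges, core–core couplings multiplied by
β = 2.5 during the ictal epoch of responders, every epoch matrix rescaled
to spectral radius 0.95 when it exceeds it. Epochs are 180 s pre-ictal, a
60–120 s seizure (uniform, so the 10-point ictal resampling is exercised
with varying segment counts), 180 s post-ictal; 16 subjects, half
responders, two recordings each.

A VAR(1) is used deliberately instead of a neural-mass simulation: it has a
controllable correlation structure, it is fast, and the pipeline under test
never sees the generator's internals. That also bounds what passing tests
show about real data: the generator produces stationary Gaussian signals
with epoch-switched covariance — no 1/f spectra, no spikes or artifacts, no
nonstationarity within epochs — so the tests validate the machinery
(inference, dynamics, statistics), not robustness to real iEEG pathology.
Note the spectral-radius rescaling dilutes the raw effect of the ictal
boost: absolute core correlations rise only moderately even for responders,
and detection rests on the surrogate test's sensitivity rather than on
large raw correlation shifts.

## Problem sizes, numerics and reproducibility

Simulation-heavy checks run reduced, stated problem sizes chosen as this
package's desk-scale defaults: cohort-level validation uses 16 subjects
with 8 channels at 128 Hz (band-pass 0.5–40 Hz, no notch — the generator
has no line noise), 36 s pre/post epochs, 36–54 s seizures, 2 × 10⁴
integration steps, an 11-point coupling grid, and 3 cohort seeds; the
calibration target runs the full `test` profile (2 × 10⁵ steps, 20 nodes).
Effect sizes (β = 2.5, coupling 0.15, core 3 of 8) are the same as the
default specification.

Numerical conventions worth knowing:

* fractional-sample segment and subsegment starts are rounded to the
  nearest sample, making segmentation bit-reproducible;
* U tests use the exact distribution when both samples are small and
  tie-free and the tie-corrected normal approximation otherwise (the
  `stats::wilcox.test` rules); a completely tied comparison returns p = 1;
* a pair whose association is undefined (constant channel) is excluded
  from the Holm family and never becomes an edge;
* the 10 subsegments of a segment overlap by construction, so the 10
  original associations of a pair are positively dependent; the U test
  treats them as independent, which makes the per-pair test
  anti-conservative under a strict null in family-wise terms. The
  entry-wise fraction of false edges stays below the nominal level (this
  is the controlled and tested quantity), but on fully uncoupled data the
  probability that *some* edge appears in a segment exceeds the nominal
  family-wise level — a property of the subsegment-ensemble protocol
  itself, worth knowing when interpreting single edges;
* `ρ_surr = 1` would make the correction formula divide by zero; such
  pairs get weight 0 with a warning;
* calibration evaluates a noisy function, so bisection keeps the
  best-so-far evaluation and stops on |BNI\* − target| ≤ tol rather than on
  bracket width;
* every stochastic stage derives its stream from one master seed
  (`with_seed` restores the caller's RNG state), so identical
  configuration + seed reproduces per-subject outputs bit-for-bit.

## Limitations

The elevated-ictal marker and ΔBNI are validated here against a generator
whose ground truth is by construction recoverable; performance on clinical
iEEG depends on electrode coverage, artifact handling (this package applies
no automatic artifact rejection — the median reference takes an optional
channel-exclusion list instead), and the adequacy of the theta model's
two-state description. Mutual-information FC, lagged or directed
connectivity measures, alternative bifurcation mechanisms, and searching
for optimal resections over node subsets are intentionally out of scope;
only the supplied resection mask is evaluated.
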