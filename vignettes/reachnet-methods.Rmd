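---
title: "Methods: spectral perturbation and directed connectivity of movement preparation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral perturbation and directed connectivity of movement preparation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachnet)
```

# Overview

`reachnet` analyses source-level EEG recorded around the preparation of a
visually cued reaching movement. Trials are epoched from −1 to +3 s around
the cue (cue at 0 s, go-signal at 2 s, 512 Hz sampling), and each of 16
cortical regions of interest (ROIs, 8 per hemisphere: cuneus CU, lateral
occipital LO, precuneus PCU, superior parietal SP, post-central PoC,
precentral PrC, paracentral PaC, superior frontal SF) contributes one
representative time course. Two arms run in parallel:

* the **ERSP arm** quantifies event-related
  desynchronization/synchronization (ERD/ERS) as percent power change from
  the pre-cue baseline, per frequency and time, reduced to alpha (8–13 Hz)
  and beta (13–30 Hz) band summaries over the late post-cue window (1–2 s);
* the **connectivity arm** quantifies directed interactions between ROIs
  with frequency-domain Granger causality (GC), contrasting the same late
  post-cue window against the baseline window, and summarises the directed
  graph with in-degree/out-degree centralities.

A synthetic-data generator with fully known ground truth exercises the
whole pipeline end to end; it is first-class, tested code, not a fixture.

# ERSP model

For each trial and ROI the continuous wavelet transform is taken with the
complex Morlet mother wavelet
$$\psi(t) = (\pi B)^{-1/2}\, e^{-t^2/B}\, e^{i 2 \pi C t},$$
with bandwidth $B = 1.5$ and normalized centre frequency $C = 1.0$
(`cmor1.5-1.0`). At sampling rate $f_s$ the daughter wavelet at scale $a$
analyses $f = C f_s / a$; at 512 Hz, scale 64 analyses 8 Hz. The default
analysis grid is 4–32 Hz in 1 Hz steps, which covers both bands with
uniform weighting when band averages are taken.

Squared coefficient moduli are averaged across trials — separately per
reaching target, because the task design allows target-specific responses —
and normalized per frequency by the mean baseline power $B(f)$ over
$[-1, 0)$ s:
$$\mathrm{ERSP}(t, f) = 100 \cdot \frac{P(t, f) - B(f)}{B(f)} \ [\%].$$
By construction the baseline-window mean of an ERSP map is exactly zero at
every frequency, and the map is invariant to any global rescaling of the
signals. Whether the per-target maps may be pooled is checked with paired
cluster permutation tests between every target pair (Benjamini–Hochberg
corrected per band); pooling is an explicit separate step, mirroring the
analysis order test-then-pool.

Band averages use half-open intervals — alpha $[8, 13)$ Hz, beta
$[13, 30]$ Hz — so the shared 13 Hz boundary is counted once (in beta,
whose upper edge is closed). Note a discrepancy inherited from the
method's description: the printed wavelet scale endpoints (64–42 for
alpha, 42–16 for beta) correspond to 8–12.19 Hz and 12.19–32 Hz rather
than the stated band edges in Hz; the implementation follows the band
definitions in Hz and documents, rather than resolves, the mismatch.

## Edge handling

The baseline window abuts the epoch edge, where a finite-support transform
is biased: zero padding both attenuates on-peak power (by the missing
wavelet mass) and inflates off-peak power (a truncation discontinuity
widens the effective bandwidth — precisely the cone-of-influence effect).
With a narrowband oscillation this biases the baseline by several percent
and would leak into every ERSP value. `cwt_power()` therefore extends each
signal beyond the epoch by autoregressive extrapolation (Burg, order 30)
before transforming: a stationary AR forecast continues each narrowband
component phase-coherently, so the wavelet never sees a truncation. On
synthetic stationary oscillations this removes the edge bias to below
0.1 %. The extension is deterministic, scale-equivariant (so the ERSP
rescaling invariance is preserved) and can be disabled
(`edge_correction = FALSE`, plain zero padding). Cone-of-influence
masking (`coi_mask()`) is additionally available but is not applied by
default, matching the reference analysis which does not mask.

# Directed connectivity model

Every ordered ROI pair is modelled, within each condition window, by a
bivariate vector-autoregressive (VAR) model of order $p = 30$:
$$x[n] = \sum_{k=1}^{p} A_k\, x[n-k] + e[n], \qquad e \sim N(0, \Sigma).$$
Windows are the baseline $[-1, 0)$ s and the late post-cue $[1, 2)$ s
(the 0–1 s window is dominated by the visual evoked response and is not
analysed). Before fitting, the across-trial evoked waveform is removed per
target group, and each 1 s window is cut per trial and demeaned.
Coefficients are estimated by ordinary least squares with no intercept on
design rows accumulated *within* each trial segment only, so no lag ever
spans a trial boundary — the estimation equivalent of concatenating
trials. The residual covariance is the pooled maximum-likelihood estimate.

With transfer function $H(f) = (I - \sum_k A_k e^{-i 2 \pi f k / f_s})^{-1}$
and spectral matrix $S(f) = H \Sigma H^*$, Geweke's causal-power
decomposition gives the spectral GC from ROI $j$ to ROI $i$:
$$GC_{j \to i}(f) = \ln \frac{S_{ii}(f)}
  {S_{ii}(f) - \left(\Sigma_{jj} - \Sigma_{ij}^2 / \Sigma_{ii}\right)
   |H_{ij}(f)|^2}.$$
The cross term $H_{ij}$ is invariant under the innovation-orthogonalizing
transformation, so this expression is exact for correlated innovations as
well. The same formula evaluated on *known* coefficients
(`analytic_spectral_gc()`) is the oracle against which the estimator is
verified to machine precision, and against which its consistency with
growing data is tested. The ratio is invariant to the one- vs two-sided
spectral convention; the implementation works with the two-sided form.

GC spectra on a 1–45 Hz grid (0.5 Hz steps) are averaged over the alpha
and beta bands, giving four $16 \times 16$ matrices per subject (band
$\times$ condition; rows = source, columns = target, zero diagonal). Each
matrix is normalized to unit off-diagonal sum,
$\tilde A = A / \sum_{i \neq j} A_{ij}$, so entries express each
connection's share of the total connectivity. In-degree (column sums) and
out-degree (row sums) then each total exactly 1.

Numerical guards: negative GC values arising from roundoff are clamped to
zero (clamp events are counted on the matrix object); a non-positive
denominator is floored at $10^{-12} S_{ii}$ and flagged; a normal matrix
with condition number above $10^{10}$ raises an error suggesting more data
or a lower order; an unstable fitted companion matrix warns and proceeds
with a flag.

# Statistical layer

1. *ERSP vs baseline*: per ROI and band, the late-window band ERSP across
   subjects is compared to 0 with a Wilcoxon signed-rank test;
   Benjamini–Hochberg FDR at $\alpha = 0.05$ within each 16-test battery.
2. *Lateralization*: the 8 homologous left/right ROI pairs are compared
   with paired Wilcoxon tests, BH-corrected per band.
3. *Connectivity contrast*: each of the $16 \times 15 = 240$ ordered pairs
   is compared between conditions with a paired sign-flip permutation test
   (5000 permutations, statistic = mean paired difference, add-one
   two-sided p). Raw and BH-adjusted p are both reported; the rejection
   flag follows the raw p by default (`gc_correction = "raw"`), since the
   reference battery reports no correction for these tests — the
   BH-corrected reading is one switch away.
4. *Degree contrast*: in- and out-degree per ROI and band, paired Wilcoxon
   with BH per 16-test battery.

The Wilcoxon test drops zero differences; with up to 15 non-zero
differences the two-sided p comes from exact enumeration of all sign
assignments (implemented as a subset-sum convolution, valid under midrank
ties); beyond that a normal approximation with tie and continuity
correction is used, matching `wilcox.test`. The cluster permutation test
thresholds pointwise paired t statistics at the two-sided 0.05 critical
value by default (configurable), forms sign-consistent contiguous
clusters scored by summed t, and calibrates them against the max-cluster
null from subject-level sign flips.

All permutation schemes, the generator and the pipeline derive their
randomness from one master seed through a documented Lehmer-style
splitting rule (`derive_seed()`), making every output reproducible
bit-for-bit from the configuration.

# What the generator emulates — and what it does not

Each synthetic trial is the sum of

* a stable VAR background (default: order 2, self-decay 0.5/−0.1,
  innovation sd 0.3, a sparse set of posterior-to-frontal couplings of
  weight 0.15) whose coefficients cross-fade (50 ms, configurable) from
  the baseline model to the post-cue model at 0.5 s after the cue — the
  reference analysis defines windows, not a generative switch, so the
  switch time and fade are explicit design choices;
* amplitude-modulated sinusoids per ROI — alpha 10 Hz (amplitude 2.0) and
  beta 20 Hz (amplitude 1.5) — with fresh uniform random phase per trial,
  so trial-averaged evoked contamination of induced power is negligible.
  ERD/ERS is programmed through a multiplicative post-cue amplitude gain
  reached by a linear ramp (0.5–1 s); power changes as gain², so gain 0.9
  programs a −19 % band ERSP, in the −15..−25 % range reported for this
  paradigm. The oscillation-to-background power ratio in the alpha band
  exceeds 100, so band power is oscillation-dominated — chosen so that
  programmed gains map cleanly onto band ERSP;
* a deterministic cue-locked evoked transient (damped 5 Hz oscillation,
  0.5 s, extinguished by ~500 ms as observed for the visual response) on
  the visual ROIs;
* 1/f-shaped Gaussian noise (spectral shaping of white noise, sd 0.2).

The default cohort is 20 subjects, 5 targets, 60 trials per target
(300 per subject). Target labels are randomly interleaved; the programmed
dynamics are target-independent, so the target-difference cluster check is
null by construction.

Not emulated: scalp-level volume conduction and electrode mixing (signals
are generated directly at ROI level, since source modelling is outside the
pipeline's entry point), realistic oscillation bandwidth (components are
line spectra with random phase rather than narrowband noise), artifacts,
and inter-subject anatomical variability. Passing tests therefore
demonstrate correctness of the estimators and calibration of the
statistics under the stated generative model — not robustness to inverse
modelling errors or to broadband oscillatory dynamics.

# Test problem sizes

The suite verifies heavy properties at reduced but statistically adequate
sizes, chosen once: GC estimation consistency uses a 2-node VAR(1) with
300 s of concatenated 1 s windows — because the band-averaged estimate at
$p = 30$ has sampling sd ≈ 0.033 there, its 0.02 tolerance is asserted on
the mean of 25 independent realizations (sd ≈ 0.007) rather than on one
draw; gain recovery uses one 60-trial subject at full 512 Hz; the
end-to-end planted-network cohort uses 20 subjects at 15 trials per
target with ERSP computed at 128 Hz (decimation by 4 after the 1–60 Hz
band-pass, which keeps the whole 4–32 Hz grid below the new Nyquist);
type-I calibration uses 1000–1500 null replicates per test. The planted
end-to-end effects are study-sized on purpose: one extra directed edge of
background weight (0.15) and one ROI with the generator's default alpha
ERD gain (0.9), so recovery is demonstrated at realistic effect sizes
rather than caricatured ones.

# Known limitations

* Pairwise (bivariate) GC only; conditional/multivariate GC, spectral
  factorization (non-parametric) GC and time-varying connectivity are out
  of scope.
* GC magnitudes at $p = 30$ carry the usual small-sample variance; a
  single subject's band GC value is noisy, and inference is designed to
  happen at the group level.
* Power changes at a ROI alter its fitted bivariate models and hence its
  GC values even without coupling changes — a known confound of
  GC-on-amplitude-modulated signals. The planted-recovery test keeps the
  programmed ERD at study size partly for this reason.
* Share normalization couples entries: one strongly increased connection
  deflates every other normalized entry, which group tests can detect as
  weak global decreases. This is a property of the normalization choice,
  inherited by design.
* The AR edge extension assumes local stationarity at the epoch ends; for
  strongly non-stationary edges the first/last ~0.2 s of the lowest
  frequencies remain approximate (COI masking is available when that
  matters).
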