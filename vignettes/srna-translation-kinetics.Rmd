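---
title: "Ribosome-modulated small-RNA silencing: model, noise and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ribosome-modulated small-RNA silencing: model, noise and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnakin)
```

## The model

Many bacterial small RNAs (sRNAs) silence a target by base-pairing at the
5'UTR, typically next to the ribosome binding site (RBS), causing
translational repression and codegradation of the sRNA–mRNA pair. Because
the two machineries share the same stretch of RNA, the strength of ribosome
binding can modulate the sRNA's efficacy — negatively, if the two compete
for the site, or positively, if bound ribosomes effectively recruit the
sRNA (directly, through Hfq, or by remodeling local structure).

`srnakin` implements a coarse-grained three-state description of the
interaction region (naked, ribosome-bound, sRNA-bound). Assuming rapid
ribosome binding/unbinding and fast equilibration of the sRNA–mRNA complex,
the mean copy numbers of mRNA $m$, sRNA $s$ and protein $p$ obey

$$\dot m = \alpha_m - \beta_m m - k\,s\,m,\qquad
  \dot s = \alpha_s - \beta_s s - k\,s\,m,\qquad
  \dot p = \gamma m - \beta_p p,$$

with effective rates that carry the ribosome dependence through the RBS
affinity $x$:

$$\beta_m = \beta_{m0}\,\frac{1+wx}{1+x},\qquad
  k = k_0\,\frac{1+xy}{(1+x)\,(1+z+xyz)},\qquad
  \gamma = \gamma_0\,\frac{x}{1+x}.$$

The dimensionless ratios have direct mechanistic readings: $w$ compares
degradation of ribosome-bound and naked mRNA ($w<1$ = protection), $y$
compares the sRNA interaction rate with and without a bound ribosome
($y<1$ = competition, $y>1$ = recruitment), and $z$ compares dissociation
and degradation of the sRNA–mRNA complex. Everything is in molecules and
minutes. Two printed presets ship with the package
(`preset_params("fig2")`, `preset_params("fig5")`); they differ only in
$\beta_{m0}$ (0.4 vs 0.42 min$^{-1}$) and are deliberately never merged.
Both correspond to a basal leakage rate
$\lambda_0 = \beta_{m0}\beta_s/k_0 = 1$ min$^{-1}$; the package treats
$k_0$ and $\lambda_0$ as interchangeable parameterizations through this
relation.

Steady states have a closed form (the positive root of a quadratic in
$\beta_m m$); an independent 1-D root-finding solver is retained purely as
an oracle (`steady_state(..., method = "numeric")`). The silencing efficacy
is reported as fold repression $p_{\text{off}}/p_{\text{on}} \ge 1$
(translation and protein turnover cancel, so it is an mRNA ratio); the
reciprocal on/off convention is available behind a flag. The regulatory
regime follows the transcription-rate ratio $\alpha_s/\alpha_m$: expressed
below 0.5, silenced at or above 2, crossover between — thresholds chosen to
bracket the two printed regimes (ratio 1 and 2) and configurable.

A key behavioral dichotomy, exercised in the acceptance suite: with $w=1$,
efficacy is monotonically decreasing in $x$ for $y/w<1$, but unimodal with
an interior maximum for $y/w>1$, peaking where the naked and
ribosome-assisted sRNA-binding channels balance.

**Open question resolved.** The leakage rate is defined with the
*effective* rates, $\lambda = \beta_m\beta_s/k$, so it varies with $x$;
this choice makes the printed basal constants consistent across presets.
"Translational activity" on response-curve axes is likewise ambiguous in
figure form; the package exposes `x`, $\gamma/\gamma_0 = x/(1+x)$ and the
unregulated expression as selectable axes and defaults to unregulated
expression in the pipeline, because that is the experimentally plotted
quantity.

## Fluctuations

Intrinsic noise is computed by the linear noise approximation: with $J$ the
Jacobian at the steady state and $N$ the diffusion matrix assembled from
the stoichiometry of the seven elementary reactions (mRNA/sRNA birth and
decay, codegradation, protein birth and decay), the stationary covariance
$C$ solves $JC + CJ^\top + N = 0$. The codegradation channel contributes
the one non-obvious entry, the positive cross term $N_{ms} = k\,s\,m$; at
steady state the RNA diagonals collapse to $2\alpha_m$ and $2\alpha_s$ by
mass balance. Without sRNA the protein Fano factor reduces to the two-stage
closed form $1 + b/(1+\beta_p/\beta_m)$ with burst size $b=\gamma/\beta_m$,
approaching $\eta = (1+b)/\langle p\rangle$ for long-lived proteins — both
checked to $10^{-8}$.

The prediction that motivates the noise assay: in the recruitment mode at
the crossover regime, the noise $\eta = \sigma_p^2/\langle p\rangle^2$ is
*non-monotone* in translational activity, with a local maximum where
repression is optimal, whereas the competition mode predicts monotone noise
reduction everywhere.

An exact Gillespie simulator (direct method, compiled, own deterministic
RNG stream per trajectory) acts as the independent oracle. Defaults:
burn-in of ten relaxation times of the slowest mode, sampling every
effective mRNA lifetime to limit autocorrelation, standard errors by batch
means over trajectories.

**Where the linear noise approximation fails.** At the printed
molecule-scale rates, the strong-repression recruitment conditions drive
the mRNA mean to $\sim 0.05$–$0.3$ molecules. There the mean-field steady
state and the LNA acquire large $O(1/\Omega)$ corrections: with the
noise preset rescaled to $\beta_p = 0.1$ min$^{-1}$, the simulated protein
mean exceeds the deterministic one by $\sim$60% at crossover, and the LNA
overestimates CV$^2$ by $\sim$40%. The acceptance criterion that compares
the two at this scale is therefore left failing by design — the package
reports the discrepancy rather than hiding it — while a property test
verifies that under van Kampen system-size scaling
($\alpha_m,\alpha_s \propto \Omega$, $k_0 \propto 1/\Omega$, $\Omega=100$)
all six $(y, \alpha_s/\alpha_m)$ combinations agree (means within ~1%,
CV$^2$ within ~4%). The same reasoning bounds what a green LNA test
establishes: the approximation is quantitative only when copy numbers are
tens or more.

Similarly, the sharp threshold-linear response $m \to
\max(\alpha_m-\alpha_s,0)/\beta_m$ holds when
$|\alpha_m-\alpha_s| \gg \sqrt{\lambda\alpha_m}$ — the width of the
crossover transition — not merely $\ge 10\lambda$ as the acceptance wording
has it; the acceptance test samples the stated (too permissive) region and
stays red near its boundary, while the property test asserts the correct
asymptotic statement.

## Synthetic data

No deposited datasets exist, so the generators *are* the data layer. Each
is a pure function of (config, seed) and serializes its ground truth as a
JSON sidecar, enabling closed-loop recovery scoring of every estimator.

* **Plate reader** (`simulate_plate_reader`): exponential OD growth
  (doubling time 45 min, a typical minimal-medium value), reads every
  10 min for 2 h; total fluorescence
  $(g_{\text{true}}\cdot f_r + a)\cdot\mathrm{OD}\cdot(1+\varepsilon)$
  with autofluorescence rate $a$, 2% technical noise, a detector ceiling,
  three technical replicates, and a lognormal biological-repeat factor
  $f_r$ (sd 0.1 in log) as the extrinsic plate-level variability. A
  reporter-free blank strain provides the autofluorescence control. The
  library defaults to ten RBS variants log-spaced over $x\in(0.008, 50)$;
  with $w=1$ expression scales as $x/(1+x)$, so this is what it takes to
  span the two orders of magnitude of translational efficiency the design
  calls for (a narrower span such as 0.05–50 only spans ~21-fold).
* **Flow cytometry** (`simulate_flow_cytometry`): 50 000 cells per sample;
  per-cell reporter levels gamma-distributed with the model mean and
  CV$^2 = \eta_{\text{int}} + \eta_{\text{ext}}$ (gamma matches
  burst-driven expression and is fully determined by mean + CV$^2$, which
  is all the estimator uses), plus additive Gaussian autofluorescence. The
  extrinsic constant defaults to 0.05 — a placeholder, configurable,
  since no measured value is stated.
* **Decay qPCR** (`simulate_decay_qpcr`): rifampicin-chase series
  $f(t) = f_0 2^{-t/\tau_{1/2}}$ mapped to quantification cycles with
  configurable amplification efficiencies, Gaussian cycle noise (sd 0.1),
  a flat 16S reference channel, sampling at 1, 2, 3, 5, 7 min; default
  $\tau_{1/2} = 1.6$ min, the measured average for the reporter library.

One fluorescence unit equals one protein before a single global gain
(default 50 RFU/molecule); gains cancel in efficacy and CV$^2$, and the
pipeline takes the gain from the truth sidecar only for the affinity
inversion (an assumed calibration).

What the generators deliberately omit: FCS binary format, detector shot
noise, growth-phase physiology (free-ribosome availability), gating and
compensation. A green closed-loop test therefore establishes estimator
correctness under the stated noise structure, not robustness to real
instrument pathologies.

## Estimators

The estimators mirror the measurement pipeline exactly. 'GFP per cell' is
the OLS slope of fluorescence against OD restricted to the linear window
(default: central 60% of the OD range, detector-ceiling reads masked — the
instrument's true linear-range rule is unstated, so both bounds are
configurable). Repeats aggregate by the published formulas
$g = n^{-1}\sum_r g_r$ and
$\sigma_g = n^{-1}\sqrt{\sum_r[(g_r-g)^2+\sigma_{g_r}^2]}$ — note this is
*not* the conventional SEM, which is available behind a flag but never the
default. Autofluorescence is subtracted from each repeat; negative
corrected means are flagged, never clipped. Efficacy ratios carry
delta-method errors (no error treatment is stated for the original
ratios; first-order propagation is this package's choice). CV$^2$ is
variance over squared mean after subtracting the independently measured
autofluorescence mean and variance, combined across repeats by the same
published formulas. Half-lives come from efficiency-corrected
$\Delta\Delta C_q$ quantification against the reference channel followed by
nonlinear least squares of $f_0 2^{-t/\tau_{1/2}}$; time points whose
replicate $C_q$ spread exceeds 1.0 cycles are excluded and logged — the
documented point exclusion ("low signal-to-noise") is formalized this way
because no numeric criterion is stated.

## Mode inference

The pipeline inverts each variant's ribosome affinity from its unregulated
expression ($x = p/(A - wp)$ with $A = \gamma_0\alpha_m/\beta_{m0}\beta_p$;
variants at $\ge 99\%$ of saturation are excluded as unbounded), then fits
$(y, k_0)$ by weighted least squares of log fold-repression with $w$ fixed
at 1, as supported by the half-life result that RBS strength leaves mRNA
stability unchanged. A residual bootstrap over variants gives a confidence
interval for $\log_{10}(y/w)$, and the mode label follows the interval:
recruitment above 0, competition below, otherwise indeterminate. This is a
deliberate strengthening — the original conclusion rests on qualitative
curve shapes plus the $w\approx 1$ measurement — and reports should read it
as such.

Two fitting choices deserve record:

* **Identifiability box.** The family has an asymptotic degeneracy: as
  $y\to\infty$ with $k_0 y$ fixed and $z>0$, the $z$-mediated term makes
  $k(x)$ decay like the competition shape, so unconstrained fits of noisy
  competition data can escape to $y\sim 10^5$. Free parameters are bounded
  to $\log_{10} y \in [-4,4]$, $\log_{10} k_0 \in [-6,2]$ — ratios beyond
  $10^{\pm 4}$ have no mechanistic reading.
* **One-sided identifiability of $y$.** Once $xy \ll 1$ across the whole
  library the curve no longer depends on $y$, so in the competition mode
  only an upper bound on $y$ is recoverable; bounded fits pile up at the
  lower box edge. The pipeline's recovery guarantee on $\log_{10}\hat y$
  therefore applies in the recruitment direction; in the competition
  direction the deliverable is the label.

The noise signature test orders per-variant CV$^2$ by expression and
combines an interior-local-maximum detector (a point must exceed both
neighbors by the combined standard errors) with a weighted trend — the
slope of noise against log expression, assessed on the log-noise scale
because CV$^2$ profiles span decades and are strongly convex on the natural
scale (the transform stabilizes variance without changing the sign of a
monotone trend). Verdicts: declining (competition-consistent),
non-declining (recruitment-consistent), inconclusive. The flow assay runs
in the crossover regime, where the anomalous maximum is predicted, and only
on variants whose expression clears three times the autofluorescence level
— dimmer samples cannot support a CV$^2$ measurement, and their diverging
$(1+b)/\langle p\rangle$ noise would mask the interior signature. The
efficacy assay instead uses the silenced regime (ratio 2), mirroring
strong-induction fold-repression measurements.

## Numerical and design notes

* Quadratic steady-state root in the numerically stable form; $s$ from the
  sRNA balance $\alpha_s/(\beta_s+km)$, avoiding catastrophic cancellation
  at small $\lambda$ (mass balance then holds to $10^{-10}$).
* Lyapunov equation solved exactly via the $9\times 9$ Kronecker system;
  stability of $J$ is checked first.
* SSA comparison point for the oracle tests: $x = 1$, chosen a priori as
  the balanced-occupancy point where the coarse-grained effects are
  largest.
* Seeds: every generator and the bootstrap take explicit seeds; the
  pipeline derives per-stage seeds from the master seed by fixed offsets.
  Identical (config, seed) runs are byte-identical, including the JSON
  report (no timestamps or absolute paths).
* Efficacy in the deterministic layer treats counts as continuous means.

## Limitations

No Hfq or RNase E mechanism, no ribosome traffic, no free-ribosome
physiology beyond $x$ as an input; no fitting to real measurements (none
are deposited); the quantitative mode fit extends, rather than reproduces,
the original qualitative analysis; LNA-based noise predictions are
quantitative only at adequate copy numbers, as discussed above.
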