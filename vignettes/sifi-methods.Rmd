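---
title: "Models and methods behind sifir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sifir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sifir)
```

# What this package models

Cy3 attached to DNA brightens when its excited-state *trans*-to-*cis*
photoisomerization is sterically blocked. Stacking of the dye into a nick,
gap or single-strand overhang of a duplex does exactly that — a
stacking-induced fluorescence increase (SIFI) — and turns a single Cy3 into
a probe of local DNA structure. The package implements the four analyses
such an experiment needs, each with a synthetic-data generator carrying a
known ground truth, so every stage is verifiable by parameter recovery:

1. **TCSPC reconvolution** (`fit_reconvolution`): multi-exponential
   fluorescence decay analysis with IRF convolution.
2. **Two-state dwell kinetics** (`segment_trace`, `fit_dwell_times`):
   opening/closing rates of a hairpin from single-molecule intensity
   traces.
3. **Accessible-volume geometry** (`compute_av`): where a linker-tethered
   dye can physically be on a B-form duplex.
4. **Positional periodicity** (`fit_periodic_model`): modulation of the
   dye's stacking as a single abasic site is moved along the duplex.

# TCSPC decay model

A measured decay is modelled as the circular convolution over one
repetition window of the normalized IRF with

$$I(t) = \sum_{i=1}^{n} \alpha_i e^{-t/\tau_i}, \qquad n \le 4,$$

plus a constant background, with a fractional-channel IRF shift as a free
parameter (implemented as exact linear interpolation of the IRF in the
Fourier domain). Circular (wrap-around) convolution is used because at
10 MHz repetition and nanosecond lifetimes a small but nonzero tail
survives into the next excitation period.

Fitting minimizes the Neyman-weighted residual sum
$\sum_k (y_k - \mu_k)^2/\max(y_k, 1)$ by Levenberg–Marquardt, which
reproduces the $\chi^2$ convention of the commercial TCSPC packages this
workflow mirrors; a Poisson maximum-likelihood objective (signed deviance
residuals) is available via `weighting = "mle"` and is preferable when the
peak counts are low. Lifetimes and component scales are log-parameterized
(positivity without constraints); amplitudes are initialized by weighted
linear least squares on each candidate lifetime ladder. Initialization is
multi-start over log-spaced lifetime ladders between twice the channel
width and a third of the repetition window (5 restarts by default,
tie-break by lowest $\chi^2$). Optimizer runs that exhaust the iteration
budget are retained as candidates: on noise-free data the $10^{-12}$
relative tolerance is unattainable even though the parameters are
converged to machine precision.

The fit range runs from 10 channels before the IRF peak to the last
channel with at least $\max(\text{background}, 5)$ counts. Reported
components are sorted by descending lifetime, which is also how component
identity (long / intermediate / short) is assigned across samples.

Fit acceptance follows standard practice: reduced $\chi^2$ near 1 and a
runs test on the signs of the weighted residuals
(`goodness_of_fit`). `select_n_components` returns the smallest $n$ whose
fit passes both (default band $1 \pm 0.2$, runs level 0.01), falling back
to the best-$\chi^2$ model with a flag.

Two average lifetimes summarize a fit: the amplitude-weighted average
$\langle\tau\rangle = \sum\alpha_i\tau_i / \sum\alpha_i$ (proportional to
steady-state intensity) and the intensity-weighted average
$\bar\tau = \sum\alpha_i\tau_i^2 / \sum\alpha_i\tau_i$ (mean time in the
excited state); $\bar\tau \ge \langle\tau\rangle$ always, with equality
only for a single component. The fractional intensity
$f_i = \alpha_i\tau_i/\sum_j \alpha_j\tau_j$ is each conformation's share
of the steady-state emission.

## The decay generator

`simulate_irf` draws a Gaussian IRF — standard for ps-pulsed laser/SPAD
systems and analytically checkable — with configurable FWHM (default
120 ps) on the 8 ps channel grid of a 10 MHz instrument.
`simulate_decay` scales the expected convolved curve so that the expected
peak-channel count equals the accumulation target (20000 by default,
emulating the accumulate-to-N stopping rule without event-by-event
simulation) and draws Poisson counts once. The tri-exponential Cy3 preset
(`cy3_abasic_model`) uses the conformer lifetimes 2.65 / 1.3 / 0.30 ns
with amplitudes 0.25 / 0.25 / 0.50; `cy3b_model` is the mono-exponential
(2.8 ns) control for the non-isomerizing Cy3B analogue.

# Two-state single-molecule kinetics

The hidden open/closed hairpin state is a continuous-time Markov chain
(opening rate $k_{open}$ out of the closed state, closing rate
$k_{close}$). Dye photophysics (microsecond photoisomerization, fast
stacking exchange) is orders of magnitude faster than the 50 ms frame
time, so each simulated frame reports the *exact time-weighted average* of
the open and closed brightness over the frame — not the state at the frame
start — plus Poisson counting noise. The closed state is brighter by the
enhancement factor (up to ~2.5).

Segmentation fits a 1–2 component Gaussian mixture to the intensity
histogram (mclust, model-based EM); with two supported modes the threshold
is the midpoint of the component means. A mixture was chosen over an HMM
because the two levels are well separated at the enhancements of interest;
an HMM would add dwell-prior assumptions the threshold approach avoids.
A terminal drop below the open level minus three standard deviations
without recovery is treated as photobleaching and excluded.

Dwells are consecutive same-state frame runs; the first and last dwell of
every trace are censored (their boundaries were not observed) and excluded
from rate fitting, since truncated dwells bias rates upward. Because
dwells shorter than one frame are unobservable, the rate MLE uses the
geometric likelihood on frame counts: $\hat p = n/\sum m_i$ and
$\hat k = -\log(1-\hat p)/\Delta t$, with the standard error from the
Fisher information. A least-squares mode on the 1-frame-binned dwell
histogram (first bin excluded, where missed events distort the count) is
provided for parity with histogram-fitting workflows. Molecules are
aggregated by pooling dwells, not by averaging per-molecule rates.

The enhancement factor is the ratio of background-subtracted
state-conditional mean intensities, computed after dropping the first and
last frame of every dwell — those frames mix occupancy of both states and
would bias the ratio toward 1.

# Accessible-volume geometry

`compute_av` performs a grid search (default 0.9 Å spacing) around the
attachment atom: a point belongs to the AV iff a clash-free tether path of
length at most the linker length (default 20 Å) and width 4.5 Å connects
it to the attachment, and a dye sphere (default radius 3.5 Å, AV1; three
radii supported) fits there. These linker/dye defaults describe a
sulfo-Cy3 on a long NHS-ester linker as commonly parameterized for
AV screening; they are package defaults, not measured values, and the
geometric conclusions quoted here are bounds ("at most four bases"), not
exact volumes.

Path lengths are computed in two passes: points whose straight segment
from the tether origin is clash-free get the exact Euclidean distance;
shadowed points get the shortest-path distance on the clash-free grid
graph (5×5×5 neighborhood, 49 primitive directions, Euclidean edge
weights). The graph distance slightly overestimates true geodesics (a
chamfer-metric property), so the AV is exact in free space and mildly
conservative behind obstacles — the safe direction for every reach bound.
At spacing $L/25$ the free-space AV reproduces the analytic sphere volume
within 2%.

The duplex is coarse-grained, not all-atom: ideal B-form geometry (rise
3.4 Å, twist 36°/bp, strands 154° apart) with ten spheres per paired
nucleotide — an azimuthally spread phosphate/sugar ridge, two base
spheres, and groove-wall spheres that close the minor groove and leave
the major groove as a wedge-shaped channel. The sphere set is denser than
the minimal 2–3 spheres per nucleotide one might first try because the
clearance-dilated surface of a sparse model has artificial holes ~20 Å
wide where real groove gaps are a few Å; tether paths thread through such
holes and produce physically impossible reach. Single-stranded
(unpaired) nucleotides keep only backbone and base spheres. The C5
attachment atom of the labelled pyrimidine sits inside the dilated coarse
surface, so the attachment nucleotide's own spheres and all spheres
within 6.5 Å do not block the *path* mask (the dye is covalently bonded
there and the tether demonstrably exits the groove); they still block the
dye sphere, and the offset from the attachment to the first free grid
point is charged against the linker length.

`axial_reach` is the maximum displacement of allowed dye positions along
the helix axis from the attachment base-pair center, in bases (rounded
up). With the defaults this is at most 4 bases on an intact duplex.
`stacking_fraction` is the fraction of the AV within a shell of the
junction terminal base's sphere surface (default 5 Å). Because the coarse
spheres inflate contact distances, resolving the accessibility *ordering*
of constructs with the dye 0/2/4 bases from a junction requires a wider
shell (10 Å); at the contact shell the far constructs are exactly zero.

# Positional periodicity

`simulate_position_profile` generates per-position replicate decays whose
ground-truth amplitude-weighted lifetime follows

$$\tau(x) = \tau_0 + d(x) + A\,\cos\!\big(2\pi (x - x_0)/P\big)\,
e^{-x/\lambda},$$

with $x$ the abasic position in bp from the nick (1-based), a Gaussian
near-nick dip $d(x)$ (default depth 0.25 ns at 2.5 ± 1.5 bp, emulating
direct dye insertion into a nearby abasic site), baseline 1.1375 ns (the
control construct's $\langle\tau\rangle$), modulation amplitude 0.08 ns,
period 10 bp (the B-DNA pitch), maximum at 15 bp and damping length
30 bp so the modulation has returned to baseline by ~19–21 bp. The
generator realizes $\tau(x)$ by exchanging amplitude between the stacked
(2.65 ns) and unstacked (0.30 ns) components — which is also what makes
their fractional intensities anticorrelated, as in the experiment the
model emulates. Replicate noise (s.d. 0.03 ns per decay, 13 decays per
position split 4/4/5 over 3 experiments) was chosen so the per-position
SEM (~8 ps) matches the scale of published per-position lifetime error
bars. The cosine is a stand-in parametric form: the data the model
emulates constrain the period and the return to baseline, not the
functional shape, which is why period estimation is cross-checked with a
nonparametric least-squares periodogram (`profile_periodogram`).

The fitted model is the same damped cosine, weighted by $1/\mathrm{SEM}^2$,
with a period grid search (6–16 bp in 0.1 bp steps, damping on a coarse
grid) followed by Nelder–Mead refinement; positions below 6 bp are
excluded by default because the near-nick dip reflects direct stacking
into the abasic site, a different mechanism from the through-backbone
modulation being estimated (tests confirm the fitted period moves by
< 0.5 bp when the window is widened to include them). Amplitudes within
two standard errors of zero are flagged as "no significant modulation".
Confidence intervals bootstrap the experiment structure: experiments are
resampled with replacement, then decays within each experiment × position
cell.

# Numerical choices and degenerate inputs

* All generators take an integer seed; the same seed reproduces outputs
  bit for bit, including through the command-line interface.
* FWHM is measured by linear interpolation at half maximum; an IRF
  narrower than two channels is rejected as unrepresentable.
* Lifetimes below one channel width are simulable but flagged
  unresolvable; fitted lifetime ratios below 1.2 raise a
  collapsed-components warning.
* Unimodal intensity histograms produce a single-state segmentation with
  a no-transitions flag rather than an error; rate fitting requires at
  least 20 uncensored dwells per state and names the deficient state.
* An attachment whose surroundings are sterically sealed beyond the local
  exclusion raises an explicit "buried" error rather than returning an
  empty AV.
* Zero-SEM profiles fall back to unweighted least squares; a profile
  identical to the control returns an all-equal flag instead of
  fabricating crossings.

# Problem sizes

The default instrument uses the full 12500-channel repetition window;
unit tests exercise the same code on a 2048-channel window at 50 MHz,
which leaves all physics intact at a quarter of the FFT cost. The
dwell-kinetics checks pool tens of traces of 2000 frames (thousands of
transitions, matching the scale of a typical single-molecule dataset),
and the profile pipeline fits 13 decays at each of 12 positions plus a
control. The AV grid at 0.9 Å spacing over a 20 Å linker contains ~10^5
candidate points.

# Known limitations

* Discrete exponential components only: if the three Cy3 conformer
  lifetimes are really centroids of distributions, the fitted $\alpha_i$
  absorb the widths. No lifetime-distribution (MEM) analysis and no
  global multi-dataset fits.
* The coarse duplex is sequence-independent ideal B-form; no bending,
  breathing or sequence-dependent groove geometry, and the stacking
  fraction is a geometric proxy, not an energy.
* The trace simulator has no salt-to-rate mapping: rates, enhancement and
  closed fraction are direct parameters.
* Synthetic data are simpler than real data in known ways: the IRF is a
  clean Gaussian (no afterpulsing or tail), traces have no baseline
  drift, blinking, or multi-step bleaching, and profile replicates share
  one instrument. Passing recovery tests therefore validates the
  estimators' correctness, not their robustness to every instrumental
  artifact.
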