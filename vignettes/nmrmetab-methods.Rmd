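---
title: "Methods and design notes for nmrmetab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for nmrmetab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrmetab)
```

# Scope

`nmrmetab` implements the computational core of a 1D NMR metabolomics
workflow plus a 13C metabolic-tracer toolkit: Bruker import/export, the
standard processing chain (apodization, zero filling, Fourier
transformation, phasing, referencing, water suppression, spline
baseline correction), two automatic phase-correction algorithms,
series-level pre-processing for multivariate statistics (region
exclusion, segmental alignment, noise filtering, bucketing, TSA/PQN
normalization, glog variance stabilization, MetaboAnalyst/Excel
export), HSQC multiplet analysis driven by carbon-carbon scalar
couplings, and estimation of isotopomer distributions from multiplet
fractions combined with GC-MS mass isotopologue distributions.  There
is no GUI; everything is callable from R or the `nmlab` command line.

# The single-spectrum model

A free induction decay is modelled as a sum of exponentially decaying
complex sinusoids,
$x(t) = \sum_p A_p\, e^{(2\pi i f_p - \pi \lambda_p) t} + \varepsilon(t)$,
where $f_p$ is the offset from the carrier in Hz and $\lambda_p$ the
Lorentzian full width at half maximum.  Exponential apodization with
line broadening `lb` multiplies point $k$ by
$e^{-\pi\,\mathrm{lb}\,k\,\Delta t}$ and adds exactly `lb` Hz to every
linewidth.  `fourier_transform()` performs a plain FFT by default, so
Parseval's identity holds exactly; the processing chain
(`process_fid()`, the generator, the CLI) passes
`first_point_scale = 0.5`, the conventional correction for one-sided
sampling.  Without it, every resonance leaves a constant offset
$A_p/2$ across the whole spectrum; that offset is invisible in casual
inspection but it dominates any objective that measures the baseline,
and it created spurious optima for automatic phasing during
development.  The Bruker digital-filter group delay is compensated by
a circular shift of the rounded delay plus a first-order phase ramp
for the fractional remainder.

Phase correction multiplies point $k$ by
$\exp(i \pi/180\,(\phi_0 + \phi_1 f_k))$ with $f_k = k/(N-1)$ measured
from the left (high-ppm) edge, i.e. the pivot of the first-order term
is the left edge.  Pivot conventions differ between packages; this one
is stated explicitly because stored $\phi_1$ values are only
comparable within one convention.

The spline baseline correction takes anchor values as the median of
the real part within two points of each anchor; when adjacent anchors
are further apart than `max_gap_points`, intermediate anchors are
inserted on the straight line between them, preventing the cubic
spline from bending into dense signal regions ("linear-spline"
behaviour).  The spline uses natural end conditions; the alternative
(clamped) requires end-slope estimates that noisy spectra do not
support.

# Automatic phase correction

Two algorithms are provided.

**Reference-baseline phasing** (`autophase_baseline_ref()`) serves
series of similar spectra.  Starting from the phases of an
already-corrected reference spectrum, it minimises the absolute
difference between the baseline regions at the spectrum edges (left
`> 10.0` ppm, right `< -0.5` ppm) with Powell's conjugate direction
method.  Two readings of "difference between the baseline regions" are
implemented:

* With the reference spectrum available (recommended, used by the
  CLI), the objective is the summed squared magnitude of the complex
  difference between the spectrum's edge regions (after trial phasing)
  and the reference's edge baselines, the latter smoothed by a running
  mean because noise is not baseline.  Using both quadratures keeps
  the sample-noise statistics independent of the trial phase; this
  estimator reaches the Cramér-Rao bound of the edge information in
  simulation (about 0.5 degrees in $\phi_0$ at the default synthetic
  noise).  The objective has a unique minimum whenever the shared edge
  baseline is nonzero, and degrades exactly when baseline
  characteristics differ across the series - the documented limitation
  of the method.
* Without the reference spectrum, a composite of edge flatness (binned
  absolute segment sums) and edge level difference is used.  This form
  is sign-blind ($\phi_0 \to \phi_0 + 180$ is an exact symmetry) and
  assumes a flat, near-zero edge baseline; near-degenerate twins at
  $\phi_1 \pm 180/360$ are resolved by preferring the candidate with
  the least negative-intensity energy over the spectrum interior.

Because phase distortions across a series can exceed the basin of
attraction around the reference phases, Powell's method is seeded from
a coarse grid of offsets around the reference (distinct basins only)
before polishing; line searches scan before golden-section refinement
because absolute-value objectives have kinks.

**Per-spectrum phasing** (`autophase_single()`) is a deterministic
stand-in for published entropy-minimisation algorithms.  A
first-derivative-entropy objective with a negative-intensity penalty
was implemented first, but on spectra containing a realistic broad
background it carried reproducible biases of several degrees in every
variant tried (raw, smoothed, high-passed by mean, median or masked
mean), so it was replaced: the local phase of each of the strongest
well-separated peaks is measured as the argument of its
baseline-corrected complex area (integrated on a window re-centred at
the parabola-interpolated magnitude maximum, which cancels the odd
dispersive component), and $\phi(f) = \phi_0 + \phi_1 f$ is fitted to
those local phases by weighted circular regression.  Recovery on the
synthetic mixture is within (0.1, 0.5) degrees noiseless and well
inside (2, 10) degrees at the default noise.

# Series pre-processing

Stages run in the fixed order exclude, align, noise filter, bucket,
normalize, glog; excluded regions are zeroed before alignment and an
alignment segment overlapping an excluded region is a configuration
error.  Conventions:

* A ppm region `c(lo, hi)` covers `lo <= ppm < hi`.
* Segmental alignment maximises the Pearson correlation between the
  integer-shifted segment and the reference segment (ties broken
  toward the smallest magnitude, then negative shifts); vacated points
  are filled with the mean of the segment's two edge values to avoid
  step artifacts.  If the reference segment has no signal, nothing is
  aligned.
* The noise filter pools the real points of a signal-free region
  (default 10.0-10.5 ppm) across all spectra into one SD estimate and
  zeroes every point whose across-sample maximum falls below
  `k * sd` (default `k = 4`); `k = 0` disables it.  The rule is this
  package's construction - only the feature itself is standard.
* Buckets are contiguous half-open ppm bins from the high-ppm end,
  aggregated by sum so total intensity is conserved (mean is available
  by flag); labels are bin centres.
* TSA divides each sample by its total and rescales by the cohort
  mean; PQN applies TSA first, then divides by the median quotient
  against the feature-wise median sample.  The returned factors are
  the overall per-sample divisors (TSA factor times quotient), so an
  exact dilution series yields factors proportional to the dilutions -
  the quotient factors alone would all be 1 after the TSA step.
* glog is $y = \ln(x + \sqrt{x^2 + \lambda})$ with user-supplied
  $\lambda$ (no maximum-likelihood optimisation); a flag guards
  against double application.

# HSQC multiplet analysis and isotopomer estimation

For a carbon with one-bond couplings to at most two neighbours, the
possible multiplet components are singlet, doublet(s) and doublet of
doublets, one per labelling pattern of the coupled neighbours.  Traces
are fitted as sums of unit-area Lorentzian sticks with one shared
linewidth and one centre offset: amplitudes are solved by
non-negative least squares inside a bounded quasi-Newton profile over
(log linewidth, centre).  A shared linewidth was chosen over
per-component linewidths because the components are resonances of the
same carbon.  $R^2$ is computed over the fitted multiplet window
(sticks plus five linewidths), clamped to $[0, 1]$, and mapped to
traffic-light flags at 0.90 (green) and 0.50 (amber); the thresholds
are this package's choice.

The isotopomer space of an $n$-carbon metabolite has $2^n$ binary
labelling states.  GC-MS mass isotopologue distributions constrain the
popcount classes; HSQC multiplet fractions constrain neighbour
patterns conditional on the observed carbon being labelled.  Because
the number of independent observations (each block sums to 1, so a
block of length $m$ carries $m - 1$) is generally smaller than the
number of isotopomers, the fit is restricted to a user-selected
subset; the diagnostics report `dof = n_obs - |subset| + 1` and warn
when the fit is underdetermined.  Ratio observations enter as
cross-multiplied residuals (numerator minus observed fraction times
denominator), keeping the objective polynomial; the simplex constraint
is enforced by a softmax parameterisation, multi-started from
Dirichlet-random points under a fixed internal seed so results are
deterministic.  Softmax cannot represent exact zeros, so nested-model
comparisons hold up to about 1e-9 in the residual rather than exactly.
Natural-abundance correction of MIDs is assumed done upstream.

# The synthetic world

All test inputs are generated in code.  The default acquisition
emulates a 600 MHz instrument: 7200 Hz sweep centred on water at
4.7 ppm, 32k complex points, so the axis spans about 10.7 to -1.3 ppm
and covers both autophase edge regions.  The default mixture is
urea (50 mM, broad), creatinine (0.78 mM), alanine (0.68 mM),
isoleucine (0.23 mM) and TMSP (0.5 mM), amplitudes proportional to
concentration times proton count, linewidth 1.2 Hz, plus a residual
water hump and a very broad (1.5 kHz) probe/solvent background.  The
background deserves a note: real spectra always carry a smooth
baseline component (strongest on cryoprobes), it is shared across a
series from one instrument, and its phase-sensitive edge tails are
exactly what reference-baseline phasing measures.  A background-free
synthetic world makes the edge regions carry almost no phase
information (the Cramér-Rao bound on $\phi_0$ exceeds 1 degree there
for *any* estimator), which is an unrealistically adversarial case,
not a neutral default.  Its amplitude is set so the edge baseline is a
few times the point noise.

Time-domain noise defaults to a complex circular Gaussian with SD 0.05
per channel in the generator's amplitude units.  On the default grid
this puts the frequency-domain SNR of the creatinine 3.04 ppm line
near 500 (peak height is approximately $A/(\pi\,\mathrm{lb}\,\Delta t)
\approx 1910 A$ and the noise floor $0.05\sqrt{N} \approx 9$), typical
of a 32-transient acquisition of a sub-millimolar metabolite.

The alignment scenario uses a doublet with a 2 Hz splitting inside a
0.3 ppm segment.  The narrow splitting is deliberate: with the stated
displacement range (up to 0.02 ppm, i.e. 27-55 points) a 7 Hz doublet
would occasionally land one stick on top of the other
(displacement close to 32 points), producing a pre-alignment
correlation near 0.5 by stick coincidence rather than by genuine
similarity; the claim being tested excludes such coincidences, so the
generator avoids them by construction.

What the generators do **not** emulate: J-evolution and strong
coupling (multiplets are stick models), pH-dependent shift changes of
individual resonances, coloured noise, receiver artifacts, and
incompletely suppressed solvent lineshape distortions.  A green test
therefore establishes correctness of the algorithms under the stated
model, not instrument-grade robustness.

# Numerical choices

* Powell's conjugate direction minimiser is implemented in-package
  (about 60 lines; base R has no Powell method): scan-plus-refine line
  searches, `xtol = 1e-4` degrees, `ftol = 1e-6` relative, at most 200
  cycles.
* Non-negative least squares is a compact Lawson-Hanson active-set
  implementation.
* Bruker export scales processed intensities so the largest magnitude
  uses at least $2^{28}$, with the exponent stored as `NC_proc`;
  read-back error is below $2^{-28}$ of the maximum intensity.
* The native dataset format is a single zip container (`.nmds`) with a
  JSON manifest and little-endian float64 arrays; the format version
  string is checked on load and mismatches are an explicit error.  The
  layout is this package's own.
* Excel workbooks are written by a minimal built-in xlsx emitter
  (inline strings plus numeric cells) because the runtime environment
  ships no xlsx-writing package; output is verified against `readxl`
  in the test suite.
* `.mlinfo` metabolite files are line-oriented text (sections
  `metabolite:`, `carbons:`, `jcc:`; `#` comments) so users can extend
  the shipped starter library (lactate, alanine) without code.

# Known limitations

Reference-baseline phasing requires the series to share baseline
characteristics and signal-free edges; it has no defence against
signal in the edge regions.  The per-spectrum phaser needs at least
one peak well above the noise floor.  Multiplet models cover at most
two coupled neighbours (no long-range couplings).  Isotopomer fits
inherit the biases of subset pre-selection, which is exactly why the
degrees-of-freedom warning exists.  Varian/Agilent, NMRPipe and MATLAB
imports, 2D processing, and wavelet water suppression (a reserved
hook that raises a clear error) are out of scope.
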