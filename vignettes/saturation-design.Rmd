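---
title: "Simulating saturation-prepared arterial-blood contrast for fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating saturation-prepared arterial-blood contrast for fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satprep)
```

## The contrast mechanism

High-resolution BOLD fMRI is biased toward the pial surface: the
deoxygenation signal drains into ascending and pial veins, so the apparent
activation peaks superficially regardless of where the neurons fired.
Arterial cerebral-blood-volume (CBV) changes are spatially much more
specific. One way to weight a gradient-echo acquisition toward arterial
blood is a *T2-selective saturation preparation*: an on-resonance train of
rectangular subpulses with zero net flip angle destroys the longitudinal
magnetization of short-T2 spins (the macromolecular pool, T2 ~ 70 us, and
to a lesser degree venous blood, T2 ~ 7 ms at 7 T) while returning long-T2
spins (arterial blood, T2 ~ 67.5 ms; free water and CSF, T2 ~ 900 ms) to
the +z axis essentially untouched. Repeating the train every few hundred
milliseconds drives the tissue into a quasi-steady state in which
magnetization transfer (MT) from the saturated macromolecular pool also
suppresses the tissue water signal, leaving arterial blood as the brightest
moving compartment.

`satprep` simulates this chain end to end: the train itself (delta-pulse
Bloch simulation), the coupled two-pool inter-train dynamics, the
saturation buildup to quasi-steady state, the five-compartment suppression
predictions, the timing of the k-space center (k0), a sparse dual-readout
variant, and a synthetic cortical ribbon for exercising the downstream
analysis (MTR maps, percent signal change, depth profiles).

## The pulse-train engine

A train is a list of contiguous rectangular subpulses (amplitude in uT,
duration in ms, phase in degrees). `simulate_train()` discretizes the RF as
a finely sampled series of delta pulses (default step d = 5 us): each step
applies an instantaneous rotation by `2 * pi * gamma * B1 * d` about the
transverse axis set by the subpulse phase, then free evolution over `d`
(off-resonance precession about z, T2 decay of the transverse components,
exact-exponential T1 recovery of Mz). The proton gyromagnetic ratio is
taken as 42.577 MHz/T. The sample step must not exceed the shortest
subpulse; a 10x finer step changes the result by less than 1e-3 per
component (this is a regression-tested oracle).

The discretization is part of the method, not merely an approximation: for
the macromolecular pool (T2 = 70 us, only ~14 steps per T2) the delta-pulse
construction yields slightly less saturation than a continuous-wave limit
would, and the package's benchmarks are defined at d = 5 us.

### The default schedule

The defining constraint on the 7-subpulse, 10 uT, 6 ms default train is
qualitative - phase-modulated with zero net flip - plus four quantitative
benchmarks of its response:

* ~92.5% saturation of the macromolecular pool in a single train,
* ~37% single-train loss for venous blood (T2 = 7 ms),
* free-water suppression below 5% at *every* offset within +-300 Hz,
* venous and macromolecular attenuation non-decreasing (and only mildly
  changing) over B1 = 7, 10, 20 uT.

These constrain but do not uniquely determine the schedule. The package's
default was chosen once, by a design-time search over symmetric
alternating-phase (0/180 degree) patterns, and then frozen: durations
`c(0.52, 0.41, 0.98, 2.18, 0.98, 0.41, 0.52)` ms with phases
`c(0, 180, 0, 180, 0, 180, 0)`. The signed rotation sum is exactly zero,
so `net_flip_angle(default_train())` is 0 for any amplitude. With this
schedule the engine produces 92.4% macromolecular saturation, 37.1% venous
loss, 4.7% arterial loss and 0.4% free-water loss on resonance, a maximum
free-water suppression of 3.1% within +-300 Hz, and venous loss of
36.2/37.1/38.9% at 7/10/20 uT. Because all phases are 0 or 180 degrees,
the Mz offset response is exactly symmetric, `Mz(+df) = Mz(-df)`.

The macromolecular saturation is almost schedule-independent (it is set by
the RF energy and the step size); the venous number is what the duration
pattern actually tunes, because venous loss depends on how long the
magnetization dwells near the transverse plane. Users can supply any other
schedule via `pulse_train()`.

## Coupled two-pool dynamics between trains

Tissue is a free-water pool (T1 = 2500 ms, T2 = 900 ms) exchanging
longitudinal magnetization with a macromolecular pool (T1 = 500 ms, T2 =
70 us). In fractional-saturation coordinates `S = (Szf, Szm)` the
inter-train evolution is linear, `dS/dt = -A S`, with

```
A = [ R1f + kf    -kf   ]
    [  -km     R1m + km ]
```

and detailed balance `(1 - f) kf = f km` tying the two exchange rates to
the macromolecular fraction `f` (`derive_exchange()`). `coupled_relax()`
evaluates the eigen-solution in closed form; the free-pool decay is a
biexponential `a1 exp(-lambda1 t) + a2 exp(-lambda2 t)` whose rates are
always real and positive (the radicand `(R1f + kf - R1m - km)^2 + 4 kf km`
is non-negative, and `det A > 0` for positive R1), with `a1 + a2 = Szf(0)`
(`biexp_solution()`). The implementation is validated against `deSolve`
numerical integration to better than 1e-6 over random physical parameter
draws, and exchange alone (R1 = 0, representable as `T1 = Inf`) conserves
the pool-weighted magnetization `(1 - f) Szf + f Szm` to 1e-9.

The train enters this picture as an instantaneous per-pool multiplicative
operator on Mz (`train_operator()`), justified by the 60-fold separation
between the 6 ms train and the 387 ms period. Both pools' post-train states
are carried into the inter-train interval - including the small direct
saturation of the free pool, not only the macromolecular hit.

`buildup()` iterates (train operator, coupled relaxation over
`period - train duration`) from equilibrium and also solves the per-period
affine map's fixed point exactly (a 2x2 linear solve); the probed sequence
is monotone non-decreasing and converges geometrically to that fixed point.
`inter_train_decay_curve()` samples the quasi-steady-state interval: for
coupled tissue the curve is genuinely biexponential (a single-exponential
fit leaves structured residuals), for liquids (`f = 0`) it is exactly
monoexponential.

## The five compartments and the calibrated exchange rate

`default_compartments()` builds gray matter (f = 0.15) and white matter
(f = 0.30) as two-pool tissues and CSF (T2 = 900 ms), arterial (T2 =
67.5 ms) and venous (T2 = 7 ms) blood as liquids, all liquids with T1 =
2500 ms and no macromolecular pool. Venous oxygenation changes,
blood-tissue water exchange and inflow are deliberately not modeled.

Only the *ratio* of the exchange rates is fixed by detailed balance; the
absolute rate `km` is a free parameter of this model family. It is
calibrated once against a single anchor - 20% gray-matter suppression at
the 100 ms probe of the dense scheme's quasi-steady state - giving
`KM_DEFAULT = 1.0139` 1/s, and then held fixed. White matter, sharing every
parameter except `f = 0.30`, then *predicts* 33.0% suppression at the same
probe; that this lands on the expected value is the strongest single check
of the coupled-pool implementation. `calibrate_km()` reproduces the
calibration.

## What repetition does to the blood compartments

Applying the same machinery to the liquids exposes a real property of this
model class that is easy to underestimate: the saturation train is
non-selective in space, so *every* static compartment builds up saturation
under repetition. With a 387 ms period and T1 = 2500 ms, a compartment
recovers only ~14% of its deficit per period, and the fixed point amplifies
the single-train loss several-fold: the venous compartment goes from 37%
(single train) to 77.5% suppression at the 100 ms probe, and arterial blood
from 4.7% to 25.0%. At quasi-steady state the *static* arterial compartment
is therefore suppressed slightly more than gray matter (25% vs 20%), and
the gray-matter-minus-arterial difference increases monotonically across
the inter-train interval (its grid argmax sits at the interval end, 381 ms,
not near 100 ms). Likewise, with the calibrated `km` the gray-matter
buildup needs ~23 trains to come within 1% (relative) of its fixed point,
not a handful.

In vivo, arterial blood is spared for a reason this model intentionally
excludes: flowing blood is continuously replaced, so it experiences only
its last few trains (arterial spins arrive essentially fresh; venous spins
carry part of the tissue's saturation history). The package's
quasi-steady-state blood predictions should therefore be read as the
static-blood limit - an upper bound on blood suppression - and the
arterial-sparing contrast seen experimentally is an inflow effect layered
on top of the T2-selectivity simulated here. The acceptance checks shipped
with the package assert the conventional expectations for these quantities
and are left failing where the static model disagrees; the test file says
so explicitly rather than silently retuning the model.

## Scheme design

`abc_scheme()` is the dense operating point: one 6 ms train per 387 ms
period, a 218 ms readout segment, and k0 sampled 100 ms after the train
(center-slice-out ordering makes the k0 time the contrast-defining moment
of a segmented readout). `optimal_k0()` performs the grid argmax of the
gray-matter-minus-arterial suppression difference with ties broken toward
earlier times; its result is stable under grid refinement.

`isolated_abc_scheme()` is the sparse dual-readout variant: four
4-subpulse 12 uT trains separated by 60 ms cross-relaxation gaps, repeated
every 3.3 s, with two 1500 ms volumes per period. The first k0 falls 100 ms
after the last train (near maximum tissue saturation), the second 1500 ms
later (near equilibrium); dividing the first readout by the second isolates
the saturation-driven contrast. The per-subpulse duration (6/7 ms) matches
the dense train's average, and the 4 x 4 split follows the reading that the
16-subpulse preparation is divided into four trains; both choices are
configurable. Simulated with the default compartments, the composite
preparation suppresses gray matter by 7.1% at the first k0 vs 5.5% at the
second, more than a single merged 16-subpulse train (4.2%) - the
cross-relaxation gaps let macromolecular saturation transfer to water
between sub-trains - and far less than the dense scheme (20%), matching the
expectation that sparse repetition trades suppression efficacy for readout
time. `sar_proxy()` summarizes RF power as the B1^2 duty per period
relative to the dense scheme (quadratic in amplitude, inverse in period);
the sparse scheme sits at 0.39.

Feasibility is enforced, not assumed: `scheme_timing()` rejects schemes
whose preparation plus readout exceed the period, or whose k0 delays fall
outside the free interval.

## The synthetic ribbon

`make_ribbon()` builds an 11-bin, 1-D cortical ribbon from the white-matter
boundary to the pial surface as partial-volume mixtures of the five
compartments: the venous fraction rises strictly pial-ward (1% to 6% by
default, emulating ascending veins pooling into the pial network), the
arterial fraction is flat at 2%, and gray matter fills the remainder. It is
an artifact construct for exercising the analysis code - it has no
equivolume layering, no 3-D geometry, no physiological noise - and passing
its tests shows the *mixing arithmetic* is right, not that real cortex
behaves this way.

The functional response is mechanistic and linear: during ON blocks an
arterial CBV increase reallocates 1 percentage point of voxel volume from
gray matter to arterial blood, and the venous compartment's signal rises by
20% (a venous-centric surrogate of the deoxygenation signal; at a 3%
venous fraction this is a ~0.6% voxel-level change). In the unprepared
("BOLD") contrast all compartment weights are 1, so the volume reallocation
cancels exactly and only the venous term survives; in the prepared
contrast each term is weighted by `1 - suppression` at k0, so the venous
response is attenuated by the venous suppression factor automatically. The
block design defaults to ON = OFF = 13.5 s with a 2.7 s volume TR and 14
cycles; the response is a boxcar (no haemodynamic convolution), noise is
i.i.d. Gaussian relative to baseline, and every stochastic output is
parameterized by an explicit seed.

Percent signal change is extracted by epoch averaging with a configurable
haemodynamic-delay skip (default: drop 2 volumes after every transition)
rather than a GLM: at this scale epoch averaging has an exact noiseless
expectation, which the tests assert to 1e-6. `mtr_map()` divides prepared
by unprepared series (masking low denominators), and `depth_profile()`
summarizes the superficial bias as the pial/deep response ratio. With the
defaults, the unprepared profile rises strictly pial-ward (ratio ~7.6)
while the divided, saturation-isolated profile is much flatter (~4.4), and
venous-dominated voxels lose more response under preparation than
arterial-dominated ones - the mechanism the preparation exists to exploit.

## Numerical choices and degenerate inputs

* Delta-pulse step d = 5 us; subpulses are split into an integer number of
  steps (the step is shrunk, never stretched, within a subpulse).
* Propagators use the eigen-decomposition; a scaling-and-squaring Taylor
  fallback covers (near-)degenerate rate pairs.
* `f = 0` and/or `km = 0` decouple the pools cleanly; `T1 = Inf` or
  `T2 = Inf` are accepted for idealized invariant checks.
* The zero-net-flip tolerance asserted for shipped trains is 1 degree;
  the default constructions are exact by symmetry.
* Grid searches break ties toward earlier times; `optimal_k0()` agreement
  between 10 ms and 1 ms grids is within one coarse step.
* Tests use deliberately small problem sizes (25-100 random draws for the
  ODE-vs-eigen property, 31-61 offsets for the off-resonance scans, 2-14
  block cycles for the ribbon), chosen so the full suite runs in seconds
  while still exercising every code path.

## Known limitations

* No inflow/outflow or blood-tissue water exchange: static compartments
  only (see above - this dominates the quasi-steady-state blood numbers).
* No frequency-offset dependence of the MT saturation rate, no dipolar
  order, no super-Lorentzian lineshape: the macromolecular pool enters only
  through its T2 in the Bloch engine and its T1/exchange in the coupled
  dynamics.
* No readout physics: the readout enters only through its duration and the
  k0 sampling time.
* The ribbon is a 1-D mixing phantom, not an anatomical model; its BOLD
  surrogate is a venous signal scaling, not a T2* model.
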