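---
title: "Models and methods behind mesobuffer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mesobuffer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesobuffer)
```

`mesobuffer` analyses how the preparation buffer shifts the pH-dependent
phase behaviour of ionizable lipid mesophases and, downstream, the
expression kinetics of LNP-transfected cells. This vignette explains the
models, the defaults and the numerical choices, and states what the
synthetic-data generators do and do not emulate.

## Buffer speciation and ionic strength

A polyprotic acid H&#8345;A distributes over its deprotonation states
according to the closed-form alpha fractions of the
Henderson–Hasselbalch equilibrium; `speciate()` evaluates them in log10
space so that extreme pH values (where the raw terms span many orders of
magnitude) stay numerically stable. The counterion — sodium for all
buffers shipped as presets — is assigned by electroneutrality, including
the H⁺/OH⁻ contribution by default; between pH 3.5 and 7.5 that
contribution is below 0.01 mM and a flag (`include_water_ions = FALSE`)
removes it. If charge balance at very low pH would demand a *negative*
sodium concentration, the balancing ion is reported as a monovalent
co-ion (chloride) instead, which keeps every concentration non-negative
and the charge balance exact.

Three decisions matter here:

* **Full pKa sets.** The presets carry the complete polyprotic ladders
  (citric 3.13/4.76/6.40, phosphoric 2.15/7.20/12.35, acetic 4.76).
  Using only the pKa nearest the working pH underestimates the citrate
  ionic strength almost threefold: the divalent and trivalent citrate
  species dominate I = ½ Σ c z² through their z² weight. With the full
  sets, the 50 mM buffers at pH 5.5 give I = 150.4 / 51.9 / 42.3 mM
  (citrate / phosphate / acetate).

```{r ionic}
purrr::map_dfr(c("citrate", "phosphate", "acetate"),
               ~ glance(speciate(.x, ph = 5.5, c_total = 50)))
```

* **Ideal-solution assumption.** Activity coefficients are ignored. At
  I ≈ 150 mM a Davies correction would move apparent pKa values by a few
  hundredths; for the comparative questions the package answers
  (ordering and shifts between buffers) that is immaterial, but absolute
  speciation at high ionic strength should be treated as approximate.

* **Exactly linear inversion.** At fixed pH the buffer's contribution to
  I is linear in total concentration, so
  `concentration_for_ionic_strength()` solves for the concentration
  directly from two evaluations; the only non-linearity is the kink
  where the required counterion changes sign (relevant only at extreme
  pH), which is caught by a bisection refinement. When the target equals
  the background contribution alone, the smallest solution (zero buffer)
  is returned.

## Phase identification from 1D SAXS profiles

Lyotropic phases are identified from relative Bragg peak positions, the
standard practice for lipid mesophases. The registry
(`space_group_registry()`) carries the inverse hexagonal lattice
(spacings ∝ √(h²+hk+k²)), the micellar cubic *Fd*3*m*
(√N, N = 3, 8, 11, 12, 16, 19, …), hexagonally close packed P6₃/mmc
(two lattice parameters, hcp extinctions h+2k = 3n with l odd removed),
and — for completeness — the bicontinuous cubics Pn3m, Im3m and Ia3d,
which are not part of the pH series the generators emulate.

**Peak detection.** The background is estimated by an iterated
rolling-minimum followed by a rolling mean in log intensity (window:
1/8 of the profile), which tracks the smooth small-angle background
without cutting into Bragg peaks. The corrected signal is lightly
smoothed (running mean over 7 grid points) before the maxima search;
Bragg peaks span tens of grid points, so this only suppresses
single-point noise ripples. Peaks are kept if their topographic
prominence exceeds both a fraction (5%) of the strongest corrected
intensity and a noise floor scaled from the robust point-noise estimate;
each kept maximum is refined to sub-grid precision by a three-point
parabolic fit.

**Indexing.** For every candidate group the first observed peak is
hypothesised to be one of the group's three leading reflections; each
hypothesis predicts the full pattern, observed peaks are matched
greedily within a relative tolerance (default 0.5%), and the lattice is
refit by exact least squares — 1/a is linear for one-parameter groups,
and q² is linear in (1/a², 1/c²) for P6₃/mmc, so no iterative optimiser
is involved. Two structural guards reject spurious fits: the group's
leading reflection must be among the matches (a pattern whose strongest
low-order line is absent is not credible), and a P6₃/mmc fit must use at
least one basal and one non-basal reflection — its basal (l = 0) lines
coincide exactly with the 2D hexagonal set, so a fit using only those
cannot distinguish hcp from H\_II nor determine c. Candidates are ranked
by matched-peak count, then rms relative residual, then fewer free
parameters, then alphabetically. A peak list containing a single broad
peak is assigned to the disordered micellar phase L\_II with
d\_NN = 2π/q.

**Coexistence.** `decompose_mixture()` peels phases iteratively: assign
the top-ranked phase, remove its matched peaks, re-index the remainder.
On a pure phase this returns exactly one assignment; leftover single
peaks are left unassigned rather than mislabelled as L\_II.

**Nearest-neighbor distances.** d\_NN = a for H\_II (cylinder center to
center), √2/4 · a for *Fd*3*m* and min(a, √(a²/3 + c²/4)) for P6₃/mmc
(which both reduce to the in-plane spacing at the ideal axial ratio),
and 2π/q for L\_II. The *Fd*3*m* factor is a convention for the shortest
center-to-center distance in the two-micelle-type cubic and is exposed
in the registry (`fd3m_dnn_factor`) for reconciliation against other
conventions; the bicontinuous-cubic factors are likewise conventions.

## Phase diagrams and the transition pH

`assemble_phase_diagram()` stacks per-sample assignments over a
(buffer × pH) grid; `extract_transition_ph()` defines the transition pH
as the **highest sampled pH at which the target phase (H\_II by
default) appears**, alone or in coexistence. When phases coexist over
several pH steps there is no unique "transition point", so the
bracketing interval — the lowest sampled pH above the transition without
the target, down to the transition itself — is reported alongside. The
extraction is invariant to row order and to adding higher-pH samples
that lack the target.

## The bending-energy mechanism model

The competition between inverse micelles (sphere, curvatures 1/R, 1/R)
and inverse hexagonal cylinders (1/R, 0) is scored by the Helfrich
energy per lipid: the density κ(C₁+C₂−C₀)²/2 + κ_G·C₁C₂ at the optimal
water-core radius, times the phase's area per lipid (0.53 nm² micellar,
0.45 nm² hexagonal, from atomistic simulation values). The spontaneous
curvature carries the pH dependence,

C₀(pH) = C₀_neutral + f(pH) · ΔC₀_charge + ΔC₀_buffer,

with f the protonated fraction of the ionizable lipid
(pKa 6.44 by default) and ΔC₀_buffer a per-buffer scalar offset
standing in for specific ion adsorption at the headgroups. Electrostatic
charging energy is folded into ΔC₀_charge rather than computed from a
Poisson–Boltzmann model: the package's aim is the *direction and
monotonicity* of buffer-induced shifts, not quantitative elastic
energies, and no measured κ, κ_G or C₀ values exist for this system.
Accordingly κ = 10 (arbitrary energy units), κ_G/κ = −0.8 (a typical
monolayer ratio, negative), and C₀_neutral = 0.08 nm⁻¹ with
ΔC₀_charge = −0.13 nm⁻¹ were fixed once so that the default transition
falls near the lipid pKa — the regime the model is meant to illustrate —
and every parameter is overridable.

The radius is optimised by a bounded golden-section scan over
R ∈ [0.5, 50] nm (`optimize()`, tolerance 1e-10, with an explicit
end-point check because boundary minima occur when C₀ is small or
negative); a brute-force grid oracle confirms the optima to 1e-6
relative in the tests. `predict_transition_ph()` reports the highest
grid pH at which the cylinder energy drops below the sphere energy,
mirroring the diagram convention. With ΔC₀_charge = ΔC₀_buffer = 0 the
ordering is pH-independent and no transition is reported. The shipped
buffer offsets (citrate −0.02, phosphate +0.01, acetate +0.02 nm⁻¹) are
illustrative magnitudes encoding the adsorption picture — citrate
shrinks the headgroup area and favours H\_II (transition shifted to
higher pH), acetate swells it and favours the micellar phases — and
reproduce the qualitative ordering pH*(citrate) > pH*(phosphate) >
pH*(acetate).

## Expression kinetics

Single-cell GFP trajectories are summarised by onset time and AUC.

* **AUC**: trapezoidal integral of baseline-subtracted fluorescence over
  0–30 h, negative excursions clipped at zero; the per-cell baseline is
  the mean over the first hour. Window edges are interpolated onto the
  grid, making AUC exactly additive over adjacent windows.
* **Onset (threshold rule)**: first time the signal exceeds the baseline
  mean + 3 baseline standard deviations for 3 consecutive samples,
  linearly interpolated to the crossing. No onset is a valid result and
  such cells are excluded from onset means but still counted — with
  their near-zero AUC — in efficiency means, so a condition's mean AUC
  reflects the whole observed population. The threshold rule is a
  detector: at finite signal-to-noise it fires systematically *after*
  the true onset by about 3σ divided by the initial rise slope.
* **Onset (model fit)**: where unbiased onset *estimates* are needed,
  `fit_expression_model()` fits
  G(t) = A·(e^(−γ(t−t₀)) − e^(−δ(t−t₀))) for t ≥ t₀ by
  Levenberg–Marquardt, with δ > γ enforced through the parameterisation
  δ = γ + e^s (the curve is symmetric under swapping the rates, so the
  ordering resolves the label ambiguity) and the degenerate δ = γ limit
  handled by its analytic form A·γ·(t−t₀)e^(−γ(t−t₀)). The fitted t₀
  recovers generator onsets to well within one 10-min sampling interval
  at signal-to-noise 10, where the threshold detector alone would lag by
  over an hour.
* **Relative efficiency**: mean AUC normalised to a reference condition
  (the reference is exactly 1 by construction).

## Synthetic data: what it emulates and what it does not

`simulate_saxs_profile()` builds powder-diffraction-like 1D patterns:
pseudo-Voigt peaks (Lorentzian fraction 0.5, relative FWHM 0.8%) at the
exact predicted positions, peak heights decaying as q⁻², a smooth
power-law background, and Gaussian noise proportional to the local
intensity. `phase_series_presets()` encodes the buffer-specific pH
sequences of the MC3/cholesterol system — citrate: L\_II → P6₃/mmc
(pH 7.0) → *Fd*3*m* (6.5) → H\_II (6.0 and below); acetate shifted
down (P6₃/mmc 6.5, *Fd*3*m* 6.0–5.5, H\_II from 5.0); phosphate:
L\_II down to 6.0, mixed P6₃/mmc + *Fd*3*m* at 5.5, H\_II from 5.0 —
with representative lattice constants (H\_II a ≈ 6 nm growing gently as
pH falls, *Fd*3*m* 15 nm, P6₃/mmc 7 nm at the ideal axial ratio,
L\_II correlation distance 5.5 nm). These are plausible magnitudes for
inverse lipid mesophases, not measured values.

The generators do **not** emulate measured form factors or absolute
intensities, instrument smearing, detector geometry, capillary
background, or the gradual peak broadening near phase boundaries. A
passing recovery test therefore demonstrates that the indexing logic is
correct and robust to position-preserving noise — not that it would
survive arbitrary instrument artefacts. Likewise
`simulate_trajectories()` draws lognormal amplitudes and truncated-normal
onsets around a fixed two-exponential shape; real single-cell data show
heavier-tailed heterogeneity and correlated noise.

All generators are pure functions of (parameters, seed): per-profile and
per-cell sub-seeds are derived by indexed offset from one master seed,
the caller's RNG state is restored afterwards, and identical seeds give
bit-identical output.

## Problem sizes and numerical choices

The shipped tests run the recovery study on 200 seeded profiles spanning
the four series phases, lattice constants 2–20 nm and noise up to 5%
(the indexing must top-rank the true group in at least 95% of cases and
hit the lattice constant within 0.5% whenever the group is right), 500
cells for onset recovery, and 1000 cells for the AUC expectation check —
sizes chosen to keep the binomial and Monte-Carlo margins comfortable
(at 200 profiles the 95% recovery bound has a ~3% standard error) while
remaining quick to re-run during development.
Matching tolerance (0.5% in q), the peak-prominence floor (5% of the
strongest peak) and the smoothing window (7 points) are the defaults
used everywhere, including the acceptance script; all are exposed as
arguments.

## Known limitations

* Speciation is ideal-solution; no activity corrections, no
  temperature-dependent pKa (the van't Hoff temperature shift is
  discussed qualitatively in the literature but not modelled).
* The mechanism model is deliberately minimal: sphere geometry proxies
  all inverse micellar phases (no *Fd*3*m*-specific packing
  energetics), electrostatics is folded into a curvature offset, and
  elastic constants are illustrative, so only orderings and shift
  directions — not absolute transition pH values — are meaningful.
* The *Fd*3*m* and bicontinuous-cubic d\_NN factors are conventions;
  compare like with like when matching other analyses.
* Indexing assumes the first observed peak is a genuine low-order
  reflection; patterns whose leading reflection is suppressed by a form
  factor minimum would need the candidate-hypothesis width
  (`max_first`) raised.
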