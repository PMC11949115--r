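# mesobuffer

Buffer-specific analysis of ionizable lipid mesophases and lipid
nanoparticle (LNP) transfection kinetics.

LNPs deliver mRNA by escaping the endosome, and the pH-driven structural
transition of their ionizable-lipid core — from inverse micellar phases
(disordered L<sub>II</sub>, hexagonally close packed P6₃/mmc, cubic
*Fd*3*m*) to the inverse hexagonal phase H<sub>II</sub> — is thought to
gate that escape. The pH at which this transition happens depends not only
on the lipid's pKa but on the chemical identity of the buffer used during
preparation (citrate vs phosphate vs acetate). `mesobuffer` provides the
computational side of such a study for people working with SAXS pH series
of lipid mesophases and live-cell transfection reporters:

* **Buffer chemistry** — closed-form polyprotic Henderson–Hasselbalch
  speciation. The fraction of an *n*-protic acid in deprotonation state
  *j* is α_j = ([H⁺]^(n−j) ∏_{i≤j} K_i) / Σ_k ([H⁺]^(n−k) ∏_{i≤k} K_i);
  sodium counterions follow from electroneutrality and the ionic strength
  is I = ½ Σ c_i z_i². A 50 mM citrate buffer at pH 5.5 carries I ≈ 150 mM
  — three times its nominal concentration — while acetate carries only
  42 mM, a fact the speciation module makes explicit.
* **SAXS phase identification** — Bragg peak detection (baseline
  subtraction, prominence filtering, parabolic sub-grid refinement) and
  space-group assignment from relative peak positions:
  q = (4π/√3·a)·√(h²+hk+k²) for the 2D hexagonal lattice,
  q = (2π/a)·√N with N ∈ {3, 8, 11, 12, …} for *Fd*3*m*, and the
  two-parameter hcp relation for P6₃/mmc. Lattice constants come from
  exact least squares, coexisting phases are resolved by iterative
  peeling, and every assignment carries the nearest-neighbor distance
  d_NN between water cores.
* **Phase diagrams** — assembly of per-sample assignments over a
  (buffer × pH) grid, extraction of the transition pH (highest pH at
  which H<sub>II</sub> appears) with its bracketing interval, and long
  d_NN-vs-pH tables ready for ggplot2.
* **Mechanism model** — a Helfrich bending-energy description,
  E = κ(C₁+C₂−C₀)²/2 + κ_G·C₁C₂, of the sphere (inverse micelle) vs
  cylinder (H<sub>II</sub>) competition, with the spontaneous curvature
  driven by the protonated fraction of the ionizable lipid and a
  per-buffer curvature offset representing specific ion adsorption.
* **Expression kinetics** — per-cell onset time, area under the curve
  (AUC) and two-exponential model fits for single-cell GFP trajectories,
  aggregated into per-condition efficiencies relative to a reference
  buffer.
* **Synthetic data** — seeded generators for SAXS profiles with known
  phase/lattice ground truth, buffer-specific pH series, and single-cell
  trajectory populations, so the entire pipeline is testable without
  synchrotron or microscopy data.

Everything is data-frame-first: functions take tibbles and return tibbles,
results have `tidy()`/`glance()` methods, and plotting helpers
(`autoplot()`, `plot_dnn_vs_ph()`, `plot_trajectories()`, …) return
ggplot objects.

## Worked example

```r
library(mesobuffer)

# how much ionic strength does a 50 mM citrate buffer at pH 5.5 carry?
glance(speciate("citrate", ph = 5.5, c_total = 50))
#> # A tibble: 1 × 6
#>   buffer     ph c_total_mM counterion_mM mean_valency  I_mM
#>   <chr>   <dbl>      <dbl>         <dbl>        <dbl> <dbl>
#> 1 citrate   5.5         50          97.8         1.96  150.

# identify a phase from a (here: synthetic) scattering profile
prof <- simulate_saxs_profile(phase_truth("Fd3m", lattice_a = 15), seed = 7,
                              buffer = "citrate", ph = 6.5)
tidy(analyze_profile(prof))
#> # A tibble: 1 × 9
#>   buffer     ph label group_id lattice_a lattice_c  d_nn n_matched
#>   <chr>   <dbl> <chr> <chr>        <dbl>     <dbl> <dbl>     <int>
#> 1 citrate   6.5 <NA>  Fd3m          15.0        NA  5.30         6
```

The speciation row says each citrate molecule carries on average 1.96
charges at pH 5.5, needing 97.8 mM of sodium, for an ionic strength of
150 mM. The assignment row identifies the *Fd*3*m* inverse micellar cubic
phase with its lattice constant recovered at 15.0 nm from 6 matched
reflections and a micelle center-to-center distance d_NN = 5.30 nm
(= √2/4 · a).

A full synthetic study — three buffers, pH 7.5 → 3.5 — runs as:

```r
series <- simulate_phase_series(phase_series_presets(), seed = 1)
assignments <- purrr::list_rbind(purrr::map(series$profile, analyze_profile))
diagram <- assemble_phase_diagram(assignments)
extract_transition_ph(diagram)   # citrate 6.0; acetate / phosphate 5.0
autoplot(diagram)
```

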