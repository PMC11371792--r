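---
title: "Modelling electromicrobiological concentration cells"
author: "emcc package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling electromicrobiological concentration cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emcc)
```

## The model

An electromicrobiological concentration cell (EMCC) is a galvanic cell in
which one redox reaction runs forward at one location and in reverse at a
distant, electrically connected location. Cable bacteria, conductive
minerals and conductive biofilms can carry electrons over millimetres to
centimetres, so the two halves of a reaction can sit in genuinely different
chemical environments. Writing `X` for the oxidized form of the substrate
and `XHn` for the reduced form, the oxidation

$$XH_n \rightarrow X + n\,H^+ + n\,e^-$$

runs in the *reducing* compartment, the electrons travel along the
conductor, and the reverse reaction runs in the *oxidizing* compartment.
Summing the two (subscripts track **where** a species is produced or
consumed, not its redox state):

$$XH_{n,red} + n\,H^+_{ox} + X_{ox} \rightarrow
  XH_{n,ox} + n\,H^+_{red} + X_{red}$$

The substrates and products are chemically identical, so the standard free
energies cancel and the reaction is driven purely by concentration
differences, minus what the conductor dissipates:

$$\Delta G = RT \ln\!\left(
   \frac{[XH_n]_{ox}\,[H^+]_{red}^{\,n}\,[X]_{red}}
        {[XH_n]_{red}\,[H^+]_{ox}^{\,n}\,[X]_{ox}}\right) + nFED$$

where $E$ is the potential drop per unit conductor length and $D$ the
length. The cell potential is $\Delta E = -\Delta G / (nF)$. The package
computes the free energy by this canonical route (`emcc_delta_g()`);
half-cell Nernst potentials are provided as a cross-check and satisfy
$E_{red} + E_{ox} = -RT\ln Q/(nF)$ exactly under one self-consistent
grouping of the quotient terms (only the *sum* of the two half-cell values
is physically constrained — the individual numbers shift with $E^0$ and
with which concentration terms are booked to which half).

Two species names carry conventions. Water always has activity 1: the
aqueous standard state is absorbed into the standard potential, so water
never appears in the quotient. When the proton itself is the oxidized form
(the $H^+/H_2$ couple), its contribution is carried entirely by the
$n$-proton pH exponent and it is excluded from the `X` term; this keeps the
quotient identical to the explicit hydrogen-cell expression and avoids
double counting.

### Assumptions

* **Linear conductor loss.** The potential drop is $E \cdot D$ regardless
  of current. Real losses follow Ohm's law and depend on the current, which
  depends on turnover; a current-coupled loss model is out of scope, so the
  reported energies are conservative for cells running very slowly.
* **Activities equal concentrations.** Proton activity is $10^{-pH}$
  exactly; no activity-coefficient corrections.
* **Single varying species.** Each scenario alters one chemical species
  between the compartments; everything else is held at equal activity on
  both ends and cancels from the quotient (implementation detail: such
  species are set to unit activity when absent from the data).
* **Static gradients.** The cell itself would erode the concentration
  difference over time; some other biotic or abiotic process is assumed to
  maintain it.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `temperature_K` | 293 | K | temperate sediment; enters every $RT$ term |
| `loss_V_per_mm` | 0.013 | V/mm | midpoint of the 12.3–14.6 mV/mm range estimated for cable bacteria filaments |
| `concentration_floor_M` | 1e-9 | mol/L | 1 nM, just below the 2–20 nM detection limit of the best microsensors — the practical meaning of a "zero" reading |
| `energy_threshold_J_per_mol` | −10000 | J/mol | assumed minimum exergonicity for ATP synthesis |

The floor deserves emphasis: every decade by which the assumed minimum
concentration is lowered adds $RT\ln 10 \approx 5.6$ kJ/mol at 293 K to the
available energy (`per_decade_sensitivity()`), so conclusions are sensitive
to what "zero" is taken to mean. The gas constant (8.314 J mol⁻¹ K⁻¹) and
Faraday constant (96485.3 C mol⁻¹) are fixed.

```{r worked}
res <- emcc_delta_g(preset_couple("oxygen"),
                    red = compartment(c(O2 = 1e-9), pH = 7),
                    ox  = compartment(c(O2 = 3e-4), pH = 7),
                    distance_mm = 2)
res
```

Note one rounding subtlety: computing $\Delta G$ from the *rounded*
potential (0.054 V) gives −20.8 kJ/mol, while unrounded arithmetic gives
−20.7 kJ/mol. The package always reports unrounded values and rounds only
for display (kJ/mol to one decimal, volts to three).

## Gradient scenarios

`preset_scenario()` encodes three literature-parameterised cases: oxygen
(0.5 mm penetration, 300 µM maximum, consumed at the sediment surface),
sulfide (7 mm, 2 mM, produced at depth) and hydrogen (1 mm, 2.5 µM,
produced at a subsurface source). Concentrations transition linearly from
maximum to minimum across the penetration depth and are constant beyond
it; pH is constant. One half-reaction is pinned at the reference depth
(0 mm) and $\Delta G$ is evaluated against every other depth, with the
conductor spanning the distance between them.

Three qualitative behaviours follow directly from the equation and are
enforced by tests: the curve is **concave** in the gradient zone when the
reference species is consumed there and **convex** when it is produced at
depth; the curve is **exactly linear with slope $nFE$** once the
concentration is constant; and order-of-magnitude changes in the
concentration span shift the concentration term **linearly** by
$RT\ln 10$ per decade.

Design choices that the underlying description left open:

* The sulfide scenario places its single-point reference at the 0 mm,
  low-sulfide end; the reducing end of each pair is then the deep,
  sulfide-rich side. Only the distance convention, not the energetics,
  depends on this choice.
* The sulfate/sulfide standard potential is not needed for any
  concentration-cell quantity (it cancels); the preset records 0.301 V, a
  standard-table value, purely so individual half-cell potentials print.
* Grid defaults: 0.01 mm steps to 4× the penetration depth — fine enough
  that discrete second differences resolve the curve shape, wide enough to
  show the loss-dominated tail.
* The feasibility envelope measures concentration spans in decades **above
  the 1 nM floor** and uses a 1 mm gradient; the electron-number and
  decade grids are caller-supplied.

## Microprofile processing

Real microsensor exports are emulated by a canonical delimited-text
dialect: UTF-8 CSV/TSV, `#` comments, columns `depth_mm`,
`<species>_uM`, `pH`; `read_microprofile()` remaps foreign column names
and converts cm→mm and mM/M→µM. The cleaning rules are:

1. `filter_subsurface()` — keep depths ≥ 0 mm (downward positive). The
   0 mm boundary is retained because it is the usual reference point.
2. `apply_floor()` — readings at or below 1 nM (including literal zeros
   and negative noise excursions) are raised to the floor so logarithms
   stay finite. Negative readings are treated like zeros.
3. `plateau_override()` — when a sensor never settles to a stable zero
   (e.g. hovering at 0–2 µM for centimetres below the oxic zone), all
   readings from the depth where the signal is consistently at its minimum
   are forced to the floor.
4. `fill_missing_ph()` — interior pH gaps are linearly interpolated; a
   missing deepest reading is filled either with a constant (assuming the
   stable downcore trend continued) or by extending the nearest value.
5. `align_profiles()` — pH is linearly interpolated onto the concentration
   grid (concentration and pH sensors rarely sample the same depths);
   outside the pH range the boundary value extends.

The chain is idempotent, flooring never lowers a value, and duplicate
depths are averaged (replicate handling is unspecified upstream; the mean
is the least-surprising choice).

`profile_delta_g()` then assigns the reducing and oxidizing ends
automatically: for an electron acceptor (O₂) the oxidizing end is where
its concentration is high; for a donor (H₂S, H₂) the reducing end is. The
assignment is made once from the profile's overall gradient direction and
can be overridden. Measured pH enters each end separately, so pH
differences between the ends are taken into account: a reducing end one pH
unit *more acidic* than the oxidizing end costs $n_{protons} RT\ln 10$
(about 22 kJ/mol for the 4-proton oxygen cell) — enough to veto an
otherwise feasible cell.

## The synthetic generator

`generate_profile()` emulates the structure of sediment microsensor
exports, not their diagenesis: monotone decay (linear or exponential) or
sigmoidal rise of one species, a constant-pH baseline with an optional
Gaussian-shaped excursion, Gaussian sensor noise truncated at zero, and —
mimicking detection limits — optional literal `0.0` readings where the
true value is at or below 2 nM (the low end of the 2–20 nM sensitivity of
current sensors). Default noise is small (≤1 % of the maximum), pH noise
0.01 units. The pH grid is offset by half a depth step so the pair always
exercises the alignment step. Everything is seeded; there is no unseeded
generation path, and the generator restores the caller's RNG state.

What passing tests on synthetic data do **not** show: real profiles have
non-monotone structure (bioturbation, photosynthesis peaks), correlated
sensor drift, and site-specific temperature; none of these are modelled,
so the synthetic results demonstrate correctness of the calculation, not
realism of any particular sediment.

Fixture battery sizes (chosen to keep the full test run in seconds):
profiles of 40–120 points at 0.05–0.5 mm steps; scenario grids of a few
hundred points; the oracle cross-check uses 100–120 randomized cells.

## Numerical choices

* Cancelling quotient terms are differenced *before* summing, so identical
  compartments give $Q = 1$ and $\Delta G = 0$ to the last bit, and
  swapping compartments negates $\Delta G$ exactly.
* The linear profile's endpoints are pinned so the plateau is exactly the
  minimum concentration (naive interpolation leaves a ~1e-15 relative
  residue that breaks exact-plateau expectations downstream).
* An unbounded feasible distance (lossless conductor, exergonic cell) is
  returned as `Inf`, never as a large finite number; a cell that misses
  the threshold even at zero distance returns 0.
* The reference depth for a measured profile must lie on the grid (within
  1e-9 mm); the error suggests the nearest grid point rather than silently
  snapping.

## Known limitations

* No current-dependent (Ohmic, rate-coupled) loss model; the linear
  13 mV/mm drop is an empirical stand-in, and cells running slowly could
  remain exergonic over longer distances than reported here.
* No kinetics, turnover rates, or attribution of the conserved energy to
  the oxidizing versus reducing cell.
* One-dimensional geometry only; no time evolution of the gradients.
* Activity coefficients, ionic strength and in-situ temperature profiles
  are ignored.
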