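---
title: "Methods: models, estimators and numerical choices in gelsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and numerical choices in gelsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelsim)
```

`gelsim` builds a gelatin chain from a collagen sequence and computes the
observables by which an atomistic gelatin model is judged. This vignette is
the package's own account of the science behind each estimator: the model
assumed, the tunable parameters and their defaults, the numerical choices
made where a published description was ambiguous, and what the synthetic
generators do and do not emulate. It states no empirical result that the
test suite does not itself compute.

## 1. Sequence stage

**Hydroxyproline.** Collagen's defining repeat is the G-X-Y triplet whose
Y-position proline is commonly hydroxylated; plain FASTA alphabets have no
code for hydroxyproline, so the package writes it as `X`. Published
descriptions of gelatin models typically state *that* hydroxyproline is
introduced but not *which* prolines are converted. `hydroxylate_prolines()`
therefore implements a deterministic rule: scan left to right, consume a
triplet at each glycine, and substitute a proline found in the triplet's
third position. Consuming the whole triplet at each anchor (rather than
re-anchoring inside it) makes the rule idempotent — the set of glycine
anchors never changes and `X` is never re-substituted. Because the true
hydroxylation pattern is a biochemical property the sequence alone cannot
decide, `rule = "all"` and `rule = "none"` are also provided.

**Trypsin digestion.** The cleavage rule is the classical one: cut on the
C-terminal side of lysine or arginine, except when the next residue is
proline. Three edge cases are fixed deliberately: a terminal K/R produces no
cut (there is nothing on its carboxyl side); consecutive K/R are each tested
independently; and hydroxyproline (`X`) does *not* block cleavage — only
proline does, and the substitution rule above never touches a residue
following K/R anyway (that would be an X position of the repeat, not Y).
All coordinates are 0-based and end-exclusive, and fragments always
partition the parent: concatenating them reproduces it exactly.

**Chain assembly.** How a single chain of a stated length (e.g. 280
residues) is selected from a digest is usually unstated in the literature.
The default `"ordered"` policy concatenates fragments in parent order until
the target is first reached and truncates at the last whole-fragment
boundary otherwise, reporting the achieved length and warning when it
differs — a length is never silently assumed. The policy is pluggable
(`policy =` a function) precisely because this step is a modelling choice,
not a law.

**The packaged collagen record.** The real human collagen α-1(I) UniProt
entry (1464 residues) cannot be shipped without network access, so
`make_synthetic_collagen()` generates — and `inst/extdata/` carries — a
clearly-labelled *synthetic* stand-in of the same length: a G-X-Y body with
collagen-like residue statistics (glycine every third residue, proline-rich,
K/R at collagen-like rates) between two short non-repetitive flanks. Tests
that use it establish behaviour of the pipeline at realistic scale, not
agreement with the real sequence's fragment distribution.

## 2. WAXS by the Debye equation

A powder diffraction profile requires orientational averaging; a bare
projection of interatomic vectors on a single scattering vector does not
produce a real isotropic intensity. `debye_intensity()` therefore implements
the isotropic Debye kernel

$$I(q) = \sum_k \sum_j f_k(s)\, f_j(s)\, \mathrm{sinc}(q\, r_{kj}), \qquad
q = \frac{4\pi \sin\theta}{\lambda},$$

with self terms ($r = 0$, $\mathrm{sinc} = 1$) included. Both conventions of
the scattering variable are reported side by side — the physical $q$ drives
the phases, while the crystallographic $s = 2\sin\theta/\lambda$ is the
column against which form factors are tabulated — to avoid the factor-of-
$2\pi$ ambiguity that plagues comparisons between codes.

Form factors use the Cromer–Mann four-Gaussian-plus-constant
parameterization for H, C, N, O, S (extensible via `register_element()`);
at $s = 0$ they recover the electron count within 1%.

**Periodic frames.** Pair distances use the minimum-image convention with a
hard cutoff at half the shortest box edge — the smallest-assumption
treatment of periodicity. Truncating the pair sum at a finite radius causes
termination ripples; an optional Lorch window (`window = "lorch"`) damps
them, default off so the raw sum is what you see. For Bragg-position
checks the test suite uses an *isolated* lattice grain (no box): the
low-angle rise of a periodic minimum-image sum otherwise dominates the
profile window. `main_peak()` is a plain argmax over a window (default
5–50°, the range usually scanned for gelatin) with optional running-mean
smoothing, default off.

The wavelength default is Cu Kα, 1.54178 Å. Accuracy is guarded by two
independent routes in the tests: a closed-form two-atom profile, and a
brute-force double-loop sum that must agree with the pair-grouped
implementation to 1e-10 on frames of up to 200 atoms.

## 3. Occupied volume and FFV

`occupied_volume()` classifies the cells of a regular grid over the periodic
box. Three conventions are exposed because the literature's prose and
figures often conflate two of them:

- `vdw`: union of van der Waals spheres (Bondi radii);
- `accessible`: spheres inflated by the probe radius — the volume excluded
  to the *probe center*;
- `connolly` (default): the solvent-excluded volume — vdW volume plus
  re-entrant space the probe sphere cannot reach.

The probe defaults to 1.4 Å (the conventional water probe; FFV magnitudes
are strongly convention- and probe-dependent, so both are always reported
alongside the number). Grid spacing defaults to 0.25 Å.

**Numerics.** All three conventions derive from one signed distance field
$d_a(x) = \min_a(|x - x_a| - r_a)$ evaluated at cell centers with
minimum-image offsets: `vdw` is $d_a \le 0$, `accessible` is
$d_a \le r_p$. For `connolly`, the probe-reachable (free) region is
computed from the 1-Lipschitz property of $d_a$: every point within
$d_a(c)$ of a center $c$ with $d_a(c) > r_p$ is reachable, so free space is
a union of balls $B(c,\, r_p + e_c)$ with $e_c = \min(d_a(c) - r_p,\,
h\sqrt{3})$. That union is evaluated *exactly* through the power distance
$\min_c(|p - c|^2 - R_c^2)$, which is separable into three capped
one-dimensional min-plus passes with periodic wrapping. Keeping the
per-cell extension $e_c$ removes the first-order (half-a-cell) bias that a
plain binary dilation of free cells suffers at the free boundary.

Convergence: for frames whose interstitial features the probe resolves,
halving the grid spacing moves the occupied volume by well under 1% (the
suite checks 0.3 → 0.15 Å). Tightly packed frames converge more slowly
under the `connolly` convention — free pockets comparable to a cell appear
and disappear with the grid — which is an intrinsic property of grid-based
morphology, shared by the standard tools, not a defect of a particular
spacing. Against a seeded Monte-Carlo point-sampling oracle the `vdw` and
`accessible` volumes agree within 1% at 0.2 Å spacing.

`ffv_series()` averages per-frame FFV arithmetically and keeps the
per-frame values, which are the regression inputs for FFV(T) trends.

## 4. Regression, ANOVA and the expansion coefficient

`linear_fit_anova()` is ordinary least squares with the classical
decomposition about the mean: `sse_total = sse_model + sse_error`,
`df (1, n−2)`, `F = mse_model/mse_error`, and the two-sided upper-tail
p-value from the F survival function (`f_sf()`, backed by the incomplete
beta through `stats::pf`; the identity against the beta form and against
the squared-t form is in the tests). The identities hold to 1e-12 relative
and are asserted on every fit the suite produces. One convention is worth
stating: for an exactly collinear fit the p-value is clamped to the
smallest positive double, keeping it in (0, 1].

Both pointwise 95% bands are provided — confidence (mean response) and
prediction (new observation) — because published figures of such fits
typically show both; they use the t quantile with n−2 degrees of freedom.
The module never hard-codes a sample size: it fits whatever series it is
given.

For a fixed-mass system $\rho = M/V$ gives
$\alpha_p = \frac{1}{V}\left(\frac{\partial V}{\partial T}\right)_p =
-\left(\frac{\partial \ln\rho}{\partial T}\right)_p$, so
`expansion_coefficient()` regresses $\ln\rho$ on $T$ and reports
$\alpha_p = -\text{slope}$ with its standard error and the full fit. The
estimator is invariant to rescaling the density by any positive constant (a
pure intercept shift), which the suite checks.

## 5. Glass transition

Dilatometric practice identifies $T_g$ as the knee in specific volume vs
temperature. "Change of curvature" is not an estimator, so
`glass_transition()` makes it one: a *continuous* two-segment linear model
(hinge basis $\{1,\ (t-c),\ (t-c)_+\}$), with the breakpoint $c$ chosen by
SSE over candidates at every midpoint between consecutive temperatures
(keeping at least three points per side) and refined by golden-section
search to 0.1 K. Continuity at the breakpoint is part of the model, not an
afterthought — an unconstrained two-line fit can place its discontinuity
anywhere between two samples.

A pure straight line has no knee: when the two-segment model improves SSE
over a single line by less than 5% (relative), the fit is flagged
`reliable = FALSE` rather than reporting a meaningless breakpoint. A
single-line SSE already at numerical zero is treated as flat for the same
reason.

## 6. Hansen solubility parameter and swelling formulas

The cohesive energy density of frame $i$ is $E_i^{nb}/V_i$; the Hansen
parameter is its square root, $\delta_i = \sqrt{E_i^{nb}/V_i}$ in MPa$^{0.5}$
— the square root is required by the units even where shorthand equations
print $\delta = CED$. Two reductions over frames are offered:
`"mean-of-sqrt"` (default; consistent with reporting a mean ± spread of
per-frame $\delta_i$) and `"sqrt-of-mean"`. They differ only through
fluctuations (Jensen's inequality), and the choice is surfaced rather than
hidden. Nonbonded force-field energies are conventionally negative
(attractive); the default `sign = "magnitude"` uses their absolute value as
cohesive energy, while `sign = "as-is"` makes a negative CED an error naming
the frame. Energies are declared per mole (`kcal/mol`, `kJ/mol`, `J/mol`)
and volumes are in Å³ by the `thermo_series` contract; conversion to MPa
happens at this boundary.

Downstream formulas are evaluated as printed, with their unit conventions
made explicit:

- $\chi_{sp} = V(\delta_s - \delta_p)^2 / (RT)$ with $V$ the *solvent molar
  volume* (the standard Flory–Huggins usage; in cm³/mol and MPa^0.5 the SI
  conversion factors cancel);
- the Flory–Rehner crosslink density
  $d = [\ln(1-v_s) + v_s + \chi v_s^2] \,/\, [V_{sol}(v_s^{1/3} - 2 v_s \phi)]$,
  with $v_s$ read as the polymer *volume fraction* (the reading forced by
  $Q = 1/v_s$). The expression's sign flips where the denominator crosses
  zero; a negative denominator triggers a warning, and a denominator within
  1e-12 of zero is an error rather than an astronomically large number;
- the Fujita model $D = D_0 R T A\, e^{-B/\mathrm{FFV}}$, whose printed
  linearization collapses to $\log D = C + \log T - B/\mathrm{FFV}$ with
  $C = \log(D_0 R A)$; `gelsim` uses natural logarithms throughout and fits
  $\ln D - \ln T$ against $1/\mathrm{FFV}$, so only $C$ and $B$ are free —
  $D_0$ and $A$ are not separately identifiable from such data and are
  reported only as the product $e^C/R$.

## 7. The synthetic world

The generators state, once, the world the estimators are validated in:

- `make_thermo_series()`: $\rho(T) = \rho_0 e^{-\alpha_p T}(1+\varepsilon)$
  on 273–318 K at ~1 K increments (46 points), $\alpha_p = 6.072\times
  10^{-4}$ 1/K, $\rho(298\,\mathrm{K}) = 1.3248$ g/cm³. The relative noise
  sd 6.653e-3 is the square root of the reference residual MSE of the
  ln ρ(T) ANOVA (4.42581e-5). With `mass` set (default cell ≈ 25876 g/mol,
  a 31.89 Å cube at the reference density), volumes follow $\rho = M/V$ and
  a drifting $\delta(T) = 27.2 + 0.01005\,(T-298)$ MPa^0.5 (noise sd
  0.2363, again from the reference residual MSE) is inverted into a
  consistent nonbonded-energy column.
- `make_bilinear_series()`: dilatometry on 100–600 K in 50 K steps
  (11 points), knee at 424.7 K, glassy slope $4.6\times10^{-4}$
  cm³/(g K) (≈ $v\,\alpha_p$ at $v \approx 0.755$ cm³/g), rubbery slope
  three times larger, noise sd 0.002 cm³/g (~0.25% of the specific volume —
  a realistic NPT scatter, chosen a priori).
- `make_lattice()` / `make_random_box()`: Bragg-law oracle inputs and
  random packings with a minimum-image distance constraint.
- `make_cleavage_sequences()`: sequences with constructively known cut
  sites (K/R rate 0.1, post-K/R proline rate 0.2).

Every generator threads one integer seed through a locally scoped RNG
(`withr::with_seed`), so outputs are bit-reproducible and the caller's RNG
state is untouched.

What the synthetic world does *not* emulate: real MD autocorrelation
(noise here is i.i.d.), force-field systematics, finite-size effects, the
amorphous packing of an actual gelatin box, or the real collagen fragment
distribution. A green test therefore establishes that an estimator recovers
what was planted under stated noise — not that the reference simulation's
published numbers are reproduced, which would require re-running the MD.

## 8. Known limitations

- The Connolly convention's grid convergence degrades for tightly packed
  frames (sub-cell pockets); use finer grids there and treat FFV magnitudes
  as convention-qualified quantities.
- The Debye sum is $O(N^2)$ per profile; it is intended for validation-size
  frames (up to a few thousand atoms), not for trajectories of large boxes.
- `read_pdb`/`read_frames` cover the common ATOM/HETATM/CRYST1, XYZ,
  extended-XYZ and `ITEM:`-block dump dialects only; binary trajectory
  formats and topology files are out of scope.
- The probe radius used by any particular published FFV number is often
  unstated; comparisons across tools must fix probe and convention first.
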