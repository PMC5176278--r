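---
title: "An exosomal-microRNA-driven model of early NSCLC: equations, parameters and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An exosomal-microRNA-driven model of early NSCLC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtumor)
```

## The biological system and the model

Non-small-cell lung cancer (NSCLC) cells shed exosomes carrying
microRNAs; the three most overexpressed in NSCLC are miR-21, miR-205 and
miR-155. miR-21 blocks the endogenous tyrosine-kinase inhibitor (TKI),
miR-21 and miR-205 block PTEN, and miR-155 blocks Apaf-1, the scaffold of
the apoptosome. Through these three blockades the miRs de-repress the two
EGF-EGFR-driven proliferation pathways (MAPK and PI3K-AKT) and suppress
apoptosis. `mirtumor` simulates this network inside a growing tumor in
two complementary geometries: a planar invasion front and a small
proliferating sphere.

All state variables are mass concentrations in g/cm^3, which lets
protein, vesicle and cell densities share one unit system. miR-21 and
miR-205 are pooled into one
species with an exosomal pool `m1` and a cellular pool `m1i`; miR-155 is
`m2`/`m2i` likewise.

**Intracellular kinetics.** Six proteins evolve pointwise, each equation
scaled by `C/C_0` so that turnover only happens inside cancer cells:

* EGF-EGFR `E`: production `lam_E` inhibited by MAPK (`1/(1 + M/K_ME)`,
  standing in for the ERK negative feedback), linear decay `d_E`.
* MAPK `M`: activated by `E`, resisted by TKI; AKT `A`: activated by `E`
  directly and through Ras (taken proportional to MAPK, weight
  `lam_MA`), inhibited by PTEN and TKI. PI3K is eliminated by a
  quasi-steady-state argument (its half-life is minutes), which folds
  its production and decay constants into `lam_A` and `K_MA`.
* TKI `T`: production inhibited by miR-21. Because miR-21 is only half
  of the pooled `m1` species, the inhibition reads
  `1/(1 + (m1 + m1i)/(2 K_mT))`; PTEN `P` is inhibited by the full pool
  (both miR-21 and miR-205 target it); apoptosome `Ap` by the miR-155
  pool.

**Transported species.** Exosomes `Ec` are shed at `lam_Ec C` and break
up on contact with cancer cells at `d_Ec Ec C/(K_C + C)`, releasing
exosomal miRs (source `lam_m sub Ec C/(K_C+C)`); cellular miRs are made
by the cells themselves (`lam_m1i C`) and diffuse with the cells'
diffusivity. Cancer cells grow logistically at a rate set by MAPK and
AKT and die by apoptosome-mediated apoptosis plus a basal rate.

**Invasion phase.** On x in [0, 2] cm, the bulk tumor occupies x < 0 and
imposes Dirichlet values at x = 0; the front advances by the nonlinear
directed-migration flux `chi C dC/dx` (competition for space), plus a
small Fickian diffusivity. Everything starts at zero inside the domain.

**Proliferation phase.** A sphere of radius R(t) (R(0) = 0.01 cm) in
which cancer cells `C` and normal cells `N` share space at constant
total density `theta` = 0.6 g/cm^3. Adding the two cell equations under
`C + N = theta` yields the radial velocity

u(r) = 1/(theta r^2) * Int_0^r xi^2 [growth(C) + growth(N) - death(C) - death(N)] d xi,

and the free boundary moves with the cells: dR/dt = u(R). The
directed-migration flux is dropped in this phase (growth, not migration,
dominates) and the logistic terms gain the competition terms `eps N` and
`eps C` (`eps` = 0.1).

## Parameters: derivation, not fitting

Every rate is derived from literature constants by unit conversion and
steady-state inversion; nothing is fitted to the simulations.

* Degradation rates from half-lives, `d_X = ln 2 / t_half` (e.g. 20 h
  for EGF-EGFR, 45 min for PTEN, 30 h for the miRs).
* Steady-state concentrations from copy numbers or molar concentrations
  times molecular weight (e.g. 2.5e6 EGFR of 170 kDa in a 1e-9 cm^3
  cell gives `E_0` = 7.057e-4 g/cm^3).
* Every half-saturation at the steady state of its species
  (`K_M = M_0`, ...), except the miR half-saturations, set to one fifth
  of the steady state (`K_mT = K_mP = m_10/5`, `K_m2 = m_20/5`) because
  miR repression is taken to be more potent than protein-level
  inhibition.
* Production rates then follow in closed form from the zero
  right-hand-side conditions, e.g. `lam_E = 2 d_E E_0`,
  `lam_T = 28.5 d_T T_0`, `lam_Ec = d_Ec E_C0 / (2 C_0)`. The factor
  28.5 is `1 + (1/2)(1 + gamma) m_10 / (m_10/5)` with `gamma` = 10 the
  cellular:exosomal miR ratio.
* The combined steady proliferation rate `lam_C` = 0.46/day is split 2:1
  between the MAPK and AKT branches; apoptosis is split 9:1 between the
  apoptosome route (`d_D` = 0.9 `lam_C`) and basal death
  (`d_C` = 0.05 `lam_C`).

`validate_parameters()` re-checks all of these identities to a relative
1e-3 (absorbing the 4-significant-figure rounding of printed constants);
`tests/` verify that all reaction terms vanish at the steady state to
1e-12 when the unrounded derived rates are used.

Two printed constants contradict their own derivations, and the package
follows the derivations:

* `K_ME`: the tabulated 3.936e-5 g/cm^3 is the ERK concentration, but
  the derivation `lam_E = 2 d_E E_0` (and the steady state of `E`)
  requires `K_ME = M_0` = 8.4e-6. The package uses `M_0`.
* `lam_N`: tabulated 0.092/day versus the derived `0.8 lam_C` =
  0.368/day. At the stated proliferation steady state (C = 0.46,
  N = 0.14) the per-capita net growth of normal cells is -0.18/day
  under 0.092 — normal cells collapse and the average cancer density
  runs to theta — while under 0.368 the per-capita rates of the two
  populations balance (0.032/day each) and the stated composition is an
  equilibrium. The proliferation phase therefore defaults to the derived
  value; both variants are exposed via
  `default_parameter_set(lambda_N = )`, and the invasion phase (no
  normal cells) keeps the tabulated value.

The unprinted cellular-miR production rates are closed from the
steady-state convention `m1i = gamma m_10` at `C = C_0`:
`lam_m1i = d_m1 gamma m_10 / C_0` (~3.88e-12/day), and analogously
`lam_m2i`. This closure is the single largest structural uncertainty of
the reimplementation; see *Fidelity* below.

## Scenarios

Mutations and drugs are multiplicative parameter modifications
(`builtin_scenario()`): oncogene activations raise `lam_E`/`lam_M`/
`lam_A` by 1.3/1.6/1.8 (dual mutations 1.15 & 1.3/1.4), paclitaxel
rescales the proliferation-phase growth rates from 1.4x to 1.3x the
migratory baseline, gefitinib knocks a 3x EGFR mutation down to 1.5x,
and cisplatin raises `d_C` and `d_D` by 1.1. Anti-miR treatment halves
the miR-21/205 production; since an anti-miR suppresses the microRNA
itself, the package halves the production of *both* pools
(`lam_m1` and `lam_m1i`) — halving only the exosomal rate leaves the
10x-larger cellular pool untouched and produces a ~1% effect, which is
clearly not what an anti-miR intervention means. For the invasion model
the Dirichlet data at x = 0 are recomputed as the bulk tumor's steady
state under the *current* parameters (`invasion_boundary_values()`), so
a treated run faces a consistently treated bulk tumor.

Efficacy is reported as the fractional day-60 reduction of tumor extent
(`phi_R`, front position or radius) and tumor mass (`phi_M`, linear or
total cancer mass).

## Numerics

**Invasion** (semi-implicit finite differences): uniform grid,
default `dx` = 0.01 cm, `dt` = 1e-3 day; linear diffusion implicit
(Thomas solves), reactions and the conservative half-node discretization
of `chi d/dx (C dC/dx)` explicit. The explicit flux bounds the step at
roughly `dx^2 / (2 chi C_M)` (about 2e-3 day at `chi` = 3e-2). Dirichlet
at x = 0, no-flux at x = 2; proteins are advanced pointwise (they have
no spatial operator). Round-off negatives are clipped at zero; values
below -1e-8 g/cm^3 abort with advice to reduce `dt`. Halving `dx` and
`dt` moves the day-10 front by ~0.01%.

**Proliferation** (fully implicit moving mesh): default 101 radial
nodes, `tau` = 1e-3 day. Nodes are advected with the implicit velocity
(`r_i <- r_i + u_i tau`), which removes the advective derivative from
the per-node equations; the remaining `X (u_r + 2u/r)` divergence term,
diffusion (nonuniform three-point formulas) and linear sinks are
implicit, nonlinear sources are converged by Picard iteration (tolerance
1e-10 on the scaled update, cap 50; typically 3–7 iterations). The
velocity integral uses exact xi^2-moment integration of the
piecewise-linear integrand — a plain trapezoid is 50% biased at the
first node off the origin and would violate the closed form
`u = s r/(3 theta)` for a uniform source `s`. At r = 0, symmetry gives
`Delta f ~ 6 (f_1 - f_0)/h^2` and `u(0) = 0` by the series limit; at
r = R the fields obey no-flux. If any mesh cell collapses below
1e-4 R the fields are re-interpolated onto a fresh uniform mesh by
monotone (Fritsch–Carlson) cubics; with the default settings this never
triggers in 60 days. On a frozen mesh with u = 0 the stepper matches a
stiff method-of-lines reference (deSolve) to 1e-4.

The proliferation initial data place the growth inhibitors above and the
growth promoters below their steady states, with C = 0.35, N = 0.25.
The initial cellular miR pools, which the stated initial conditions omit,
are set to `gamma` times the exosomal ones, mirroring the steady-state
ratio.

**Sensitivity runs** use the coarser settings 51 nodes and
`tau` = 5e-3 day (the day-60 radius changes by well under 1%, and rank
correlations are insensitive to that). The bundled test suite runs the
Latin hypercube at n = 100 with a fixed seed and checks the sign
pattern; the full n = 1000 study runs in a few minutes via
`run_sensitivity()` or `exec/simulate.R sens`.

## Sensitivity analysis

`lhs_sample()` draws a Latin hypercube (one uniform draw per
equal-probability stratum per parameter, via the `lhs` package) over
[value/2, 2 value] ranges for the eleven production/turnover parameters
of the default design. `prcc()` rank-transforms inputs and output
(average ranks on ties) and correlates the residuals of each rank-column
and the rank-output after regressing out all other columns; p-values
come from the usual t statistic with n - 2 - (k - 1) degrees of freedom.
Tumor radius at day 60 is the output.

## Fidelity and limitations

What the package reproduces under the derived defaults (all computed by
the test suite and `scripts/acceptance.R`, never asserted as constants):

* all closed-form rate derivations to 4 significant figures, and exact
  steady-state annihilation of every reaction term;
* the proliferation plateau (volume-averaged cancer density 0.46 ± 0.01
  g/cm^3 at day 60, total cell density within 2% of theta throughout);
* the ~8-fold growth of the day-60 front across the directed-migration
  range (measured 9.0), the ~40% front reduction under combined
  anti-miR-21+155, and the PRCC sign pattern (positive `lam_E`,
  `lam_M`, `lam_MA`, `lam_m1`; negative `lam_T`, `lam_P`, `lam_Ap`,
  `d_Ec`).

Where the reimplementation deviates quantitatively: the anti-miR-21-
alone front reduction comes out near 28% (reported: ~17%), the combined
treatment's mass reduction near 49% (reported: ~65%), the
single-mutation mass increases near 38% (reported: ~25%), and the
anti-miR efficacies over the `chi` sweep are essentially flat
(`phi_R` 0.48 to 0.45, `phi_M` 0.63 to 0.59) rather than moderately
increasing. All of these ratios are controlled by how strongly the
*cellular* miR pools respond to the interventions, i.e. by
`lam_m1i`/`lam_m2i` — exactly the constants the source never states;
with the documented closure the treatment acts multiplicatively on the
growth rate, and since the front speed scales like
sqrt(growth x `chi`), the efficacy becomes nearly `chi`-independent.
Scans over the front threshold (0.025–0.7 C_0), the treated-versus-
untreated bulk boundary convention and both printed `chi` values shift
these ratios by a few points but cannot reconcile all of them
simultaneously, so the package keeps the documented closure and reports
what it computes.

Known limitations, by construction: no immune response or angiogenesis
(the model is an early-stage tumor), no pharmacokinetics (drugs are
constant parameter rescalings), one spatial dimension per phase
(planar front / radial symmetry), and the serum-versus-tissue miR
correlation is outside the model — the simulated tissue miR masses are
at most a first step toward serum biomarker curves.
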