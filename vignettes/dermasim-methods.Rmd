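---
title: "Mechanistic models behind the virtual Franz cell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic models behind the virtual Franz cell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dermasim` assembles every virtual experiment — release through an inert
membrane (IVRT) or permeation through skin (IVPT) — as a network of
well-mixed compartments exchanging drug across interfaces. This vignette
records the governing models, the conventions and defaults the package
commits to where the source transport tables are silent, the numerical
choices, and the known limitations. Everything quantitative quoted here is
computed by the test suite or by `scripts/acceptance.R`.

## The transport law and its conventions

Every link carries the diffusive interface flux

$$J_{A\to B} = P\,SA\,(C_A - C_B/K_p),$$

which vanishes at partition equilibrium $C_B = K_p C_A$. **Convention:**
the $K_p$ stored on a link oriented $A\to B$ is the equilibrium
concentration ratio of the B phase over the A phase. All published
partition values are mounted in their physically sensible orientation for
a lipophilic permeant (logP 2.35): the vehicle holds 223.872× the aqueous
receptor concentration, the SC lipid holds 18.8× (cream) or 11.6×
(ointment) the vehicle concentration. The sources never state their
orientation explicitly; this is the only assignment in which the drug
prefers oil and lipid over water, and it is applied uniformly.

`series_permeability()` implements the composite-film formula exactly as
conventionally printed alongside the flux law,
$P = 1/(\delta_A K_p/D_A + \delta_B/D_B)$. That formula is only consistent
with the flux law at $K_p = 1$: at a partitioned interface it misweights
the B-side film (for the default IVRT membrane the steady slab flux comes
out 1.2 % high, exactly as the algebra predicts). The network assembly
therefore uses the exact two-film composite
$P = 1/(\delta_A/D_A + \delta_B/(K_p D_B))$ (`interface_permeability()`),
which reduces to the printed form at $K_p = 1$ and restores the closed-form
slab limits (steady flux and the $L^2/6D$ lag) to within 1 % — the property
suite asserts both.

## Donor vehicles

The donor layer is thick (0.92 cm) relative to the diffusion depth reached
in 24–36 h ($\sqrt{2Dt}\approx$ 4–5 mm), so a well-mixed donor would be
badly wrong. The vehicle is a 1-D finite-volume stack (default 40 cells)
geometrically refined toward the barrier face (ratio 1.2, smallest cell
≈ 1.3 µm).

* **Solution** — single phase, diffusivity $10^{-10}$ m²/s by default.
* **Cream (emulsion)** — oil droplets (diameter 3.37 µm) in a continuous
  phase. Per cell, a lumped droplet reservoir exchanges with the continuous
  phase across the total droplet surface $3\phi V/r$; only the continuous
  phase (D = 0.85·10⁻¹⁰ m²/s) diffuses cell-to-cell. The
  continuous/dispersed partition 4.484 is taken at face value in the
  continuous-over-dispersed orientation. The dispersed volume fraction is
  not published; the default is $\phi = 0.2$, a typical oil fraction for
  o/w pharmaceutical creams, configurable. Droplet exchange equilibrates in
  seconds, so the cream behaves as a locally buffered single phase.
* **Ointment (suspension)** — solid particles (diameter 3.37 µm) dissolve
  by the Nernst–Brunner law. The dissolved phase is initialised saturated
  at $C_s$ (0.63, interpreted as mg/mL — the printed value carries no
  units) with the remaining dose as solid, distributed uniformly. Particles
  are monodisperse shrinking spheres: the particle number is conserved and
  the radius follows the remaining solid mass, because the $R_p$ in the
  denominator of the rate law is only meaningful if tracked; a fixed-
  geometry switch exists. Solid density defaults to 1300 kg/m³ (typical
  crystalline steroid). Numerical guards: the radius is clamped below at
  1 nm and exhausted cells exchange nothing, which keeps the
  dissolution term from blowing up the stiffness at exhaustion.

Dissolution is fast relative to release, so the vehicle stays saturated
while solid remains — the ointment's effective donor concentration is its
solubility. This single fact drives most of the cream/ointment asymmetry
discussed under *Limitations*.

## The skin barrier

The stratum corneum is an explicit 2-D brick-and-mortar unit cell:
for the default geometry (14.075 µm SC, 0.8 µm corneocytes, 0.075 µm lipid
layers) the commensurability relation $n t_c + (n{+}1) t_l = T$ gives
exactly 16 corneocyte and 17 lipid layers. Corneocytes 40 µm wide are
separated laterally by lipid channels one lipid-layer wide and staggered
between successive layers by half a unit cell (offset configurable); the
lateral boundary is periodic. Lipid/corneocyte contacts use the published
directional interface permeabilities (vertical for depth-direction links,
horizontal for lateral ones); same-phase contacts use series films.

Two transport pathways coexist: the transcellular chain of 32
lipid/corneocyte interfaces, and the tortuous continuous-lipid channel
pathway. With the default phase diffusivities ($D_{lipid} = 10^{-11}$,
$D_{corneocyte} = 10^{-12}$ m²/s, literature-typical orders) the interface
chain carries ~75 % of the flux and the lipid channel the rest; the
corneocyte interior is never rate-limiting (asserted by test). The
effective SC permeability is grid-converged at the default lateral
resolution of 8 sub-cells per corneocyte (< 1 % change on doubling);
aligned bricks (offset 0) measurably raise the permeability relative to
staggered ones, as geometry dictates.

Below the SC sit a viable epidermis (56 µm, 10 cells) and dermis (1.2 mm
default, 20 cells; a `specimen_thickness_um` override rescales the dermis
for dermatomed skin), both refined toward their upstream interface, then a
dermis/receptor exit permeability.

**Partition defaults the tables do not print.** Only the lipid/vehicle
partition is published. Setting the remaining internal partitions to 1
would make corneocytes and viable epidermis as lipophilic as the SC lipid,
which is indefensible for a logP 2.35 steroid and inflates skin loading by
an order of magnitude. The package instead derives defaults once from logP
with standard QSPR forms (`qspr_partitions()`): lipid/water
$= K_{ow}^{0.69} \approx 41.8$, keratin/water $= 5.6K_{ow}^{0.27}$, the
corneocyte as a 45 % keratin hydrated mixture (corneocyte/lipid ≈ 0.27),
and the viable epidermis and dermis as aqueous tissue. All are plain
configuration fields.

## Receptor sampling

The printed receptor balance $V_R\,dC_R/dt = J_{in} - Q\,C_R$ writes
sampling as a continuous sink, but the protocol (a 400 µL aliquot replaced
by fresh buffer at scheduled times) and the observed concentration drops
are discrete. The simulator applies discrete replace events
$C' = (C(V_R - V_s) + C_{repl}V_s)/V_R$ between integration segments —
the integrator restarts at every event, so no event is smoothed over — and
retains a continuous-rate mode; a property test shows many small discrete
events converge to the continuous form within 1 %. A sample drawn at the
final time point is the terminal assay aliquot and moves no mass out of
the cumulative ledger.

Note that with the strong vehicle/receptor partition the receptor is *not*
a sink in IVRT: it approaches its partition equilibrium within the study,
which is why the release curves plateau and why sampling visibly perturbs
them. The cumulative ledger $Q(t)$ (receptor + withdrawn aliquots, per
area) is only sampling-invariant far from that equilibrium.

## Numerics

Stiff integration uses `deSolve::lsoda` with an analytic Jacobian: the
linear network is pre-assembled into one dense amount-operator matrix, and
the only nonlinearity (dissolution) contributes a sparse analytic block.
Defaults rtol $10^{-8}$, atol $10^{-12}$ kg/m³; halving tolerances moves
headline outputs by < 0.1 % (tested). Rare stiffness stalls near
dissolution exhaustion are retried once with 100× relaxed tolerances
before erroring. Mass balance closes to $10^{-6}$ relative on every run;
`mass_balance_report()` audits it the way the experimental recovery ledger
does.

Calibration minimises the RMSE between simulated and observed cumulative
per-area profiles (replicate mean by default, pooled optionally; stage 2
can add terminal layer-deposition residuals with a configurable weight).
Transport parameters are optimised on a log scale; multi-parameter fits
use Nelder–Mead with seeded multi-start, single parameters use golden
section with a 10⁻³ log-unit tolerance — about 0.1 % parameter resolution,
safely above the solver noise floor, which a tighter tolerance would chase.
Every run emits the evaluation trace (best-so-far is non-increasing by
construction) and a ±2 % finite-difference sensitivity of the objective at
the optimum. That report matters: under the default IVRT protocol the
membrane, not the vehicle, limits release, so the vehicle diffusivity has
a nearly flat likelihood and is recoverable only from noiseless data; the
vehicle/receptor partition, which sets the plateau, is strongly
identified. The two-stage pipeline recovers its generating parameters
exactly on noiseless synthetic data (tested to 1–5 %).

## What the synthetic data do and do not emulate

`generate_dataset()` simulates the ground-truth model at the experiment's
sampling schedule and multiplies each replicate observation by i.i.d.
lognormal noise, median-unbiased, with CV 0.15 by default (error bars in
published Franz-cell data grow with the mean, which multiplicative noise
reproduces and additive noise does not); permeation runs also get noisy
terminal layer depositions. n defaults to 6 replicates for release and 5
for permeation studies. The generator does **not** emulate inter-donor
skin variability, assay LOQ censoring, or within-replicate autocorrelation
— passing recovery tests on these data therefore demonstrate correctness
of the pipeline, not robustness to real-skin heterogeneity. Four canned
datasets (cream/ointment × IVRT/IVPT, documented seeds, reduced grid
resolution recorded in their manifest) ship under `inst/extdata/` and
regenerate bitwise.

## Limitations and open discrepancies

* With all published vehicle and skin presets mounted, the virtual cream
  releases and permeates several-fold more than the virtual ointment,
  because the cream's continuous-phase concentration (~2.5 mg/mL at the
  published phase split) times its lipid partition (18.8) exceeds the
  ointment's solubility-pinned 0.63 mg/mL times 11.6 by ~6.5×. The
  reference experiments and the original simulations report *comparable*
  36 h permeation and *higher* ointment skin deposition. No assignment of
  the unpublished parameters closes this gap for both formulations at
  once; the likely culprits are the unstated units of the ointment
  solubility or the phase to which the vehicle partitions refer. The
  acceptance checks encoding the published deposition values are left
  failing rather than tuned, and `scripts/acceptance.R` reports what the
  model actually computes (cream epidermis ≈ 1.48 µg/mg vs published
  5.09·10⁻¹; ointment epidermis ≈ 0.27 vs 6.97·10⁻¹; dermis values 2×
  high and 3.4× low respectively). The qualitative orderings — cream
  releasing faster than ointment, earlier cream permeation, epidermal over
  dermal deposition — all hold.
* No ionisation correction (pKa 13.44 vs pH 7.4 leaves the drug neutral;
  both are carried as metadata only), no temperature dependence, no
  vehicle evaporation or film thinning, no viscosity or particle-size
  distribution effects, no follicular pathway, no skin metabolism.
* The membrane porosity of the dialysis membrane is not published; the
  default 0.5 (with a molecular-weight-estimated aqueous diffusivity) is a
  plain configuration field and a legitimate stage-1 calibration target.
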