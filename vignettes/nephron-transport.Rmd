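---
title: "Steady-state epithelial transport along rat and mouse nephrons: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady-state epithelial transport along rat and mouse nephrons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`nephrosim` simulates steady-state water and solute transport along the
nephron populations of a rat or mouse kidney. Six nephron classes are
represented — one superficial (SF) and five juxtamedullary (JM-1 … JM-5)
whose loops of Henle reach 1–5 mm into the inner medulla — with population
weights of 2/3 and 0.4/3, 0.3/3, 0.15/3, 0.1/3, 0.05/3 for the rat. For the
mouse the superficial fraction is 0.82 and the published juxtamedullary
sub-fractions (0.4, 0.3, 0.15, 0.1, 0.05) are read as fractions of the
juxtamedullary pool, because taken literally they would sum with the
superficial fraction to 1.64; this normalization choice is flagged here
rather than asserted as the source's intent. A rat kidney carries 36,000
nephrons, a mouse kidney 12,000. Juxtamedullary single-nephron filtration
is 45% above superficial in the rat (the published range is 40–50%) and
20% above in the mouse.

Each segment — proximal convoluted tubule (PCT), proximal straight tubule
(S3), short descending limb (SDL), long descending and thin ascending
limbs (LDL/LAL, juxtamedullary classes only), medullary and cortical thick
ascending limbs, early and late distal convoluted tubule, connecting
tubule (CNT), and cortical, outer- and inner-medullary collecting ducts
(CCD/OMCD/IMCD) — is a tubule lined by epithelial cells. A cross-section
couples four or five compartments: lumen, one or two cell types (principal
and intercalated cells in the CCD and OMCD), the lateral interspace, and
the interstitium. Fifteen solutes are carried: Na+, K+, Cl-, HCO3-,
H2CO3, CO2, NH3, NH4+, HPO4^2-, H2PO4-, H+, HCO2-, H2CO2, urea and
glucose.

## Fluxes

Transmembrane water flux is osmotic plus hydrostatic,
$J_v = A L_p (\sigma RT \sum_k \Delta C_k + \Delta P)$, with per-solute
reflection coefficients. Solute flux across a membrane is the sum of four
mechanisms: convection $(1-\sigma_k)\bar C_k J_v$ with the log-mean
membrane concentration $\bar C_k$; electrodiffusion by the
Goldman–Hodgkin–Katz constant-field law
$h\,\zeta (C_a - C_b e^{-\zeta})/(1-e^{-\zeta})$, $\zeta = zF\Delta V/RT$,
reducing to Fickian diffusion for uncharged species; coupled transport
across cotransporters and exchangers; and primary active transport across
ATPases (Na+-K+-ATPase with 3:2 stoichiometry and Hill-type saturation
whose Na+ affinity is modulated by external K+; an apical H+-K+-ATPase).

Coupled transporters default to the linear nonequilibrium-thermodynamic
form: cycle flux = activity × stoichiometry-weighted sum of
electrochemical potential differences. Three carriers — NHE3, NKCC2 and
NCC — instead use a saturable reversible-carrier form in which forward and
reverse occupancy products (normalized by reference concentrations chosen
so the Haldane condition holds) bound the flux by the activity. This
matters scientifically: with the purely linear form, a change in
transporter abundance is largely absorbed by a shift of the thermodynamic
drive (the cell re-equilibrates), and the tabulated sex- and
species-differences in NHE3/NKCC2/NCC activity would have almost no
functional consequence. The saturable form makes flux
activity-proportional away from equilibrium, which is what lets a 32%
NHE3 difference between the species produce the large difference in
proximal fractional reabsorption that the models are built to study. NHE3
and NKCC2 each carry a parallel mode in which NH4+ substitutes for H+ or
K+, the proximal ammonia-secretion and thick-limb ammonium-reabsorption
pathways.

The proximal tubule is compliant, $r = r_0(1 + \mu(P - P_0))$, and its
luminal-side fluxes are scaled by the microvillous-torque factor
$S_{torq} = 1 + s(\tau/\tau_0 - 1)$ with
$\tau = 8\mu Q l_{mv}/r^2\,(1 + (l_{mv}+\delta_{mv})/r + l_{mv}^2/2r^2)$,
clamped below at zero. The reference torque is evaluated per nephron class
at its own baseline inflow and reference radius, so the scale is unity at
baseline and mediates glomerulotubular balance when filtration changes
(for example under the saline-load protocol). The scaling factor
$s = 0.6$ is a configuration entry of the packaged set; no printed value
exists for it.

## Cross-section closure

The unknowns at one axial station are the cell and interspace
compositions (15 log-concentrations each), membrane potentials, the cell
volume, the interspace pressure and the luminal potential. Equations per
interior compartment: mass balance for the five non-reacting solutes;
balance of the phosphate, ammonia and formate buffer totals and of total
CO2; a free-CO2 equation (finite-rate hydration in cells, scaled by a
carbonic-anhydrase factor; equilibrium in the interspace); the four pair
mass-action relations; electroneutrality including the impermeant
(cytosolic anions of configurable charge, interstitial protein); zero net
ionic current; and volume balance. Cell volume enters through the
impermeant concentration (fixed impermeant amount divided by volume), the
classic pump-leak closure; interspace pressure through the
basement-membrane water flux. One further equation imposes zero net
current out of the lumen and closes the luminal potential. H+ is carried
as a free concentration with electroneutrality closing the system rather
than as a conserved total.

## Axial integration and the open CO2 system

The axial march carries, per nephron of the population, the conserved
luminal quantities: volume flow, pressure, the five non-reacting solute
flows and the three buffer totals, all as $\omega Q C$ with $\omega$ the
number of tubules per nephron. Species are recovered at each station by
imposing the buffer equilibria and luminal electroneutrality, which fixes
pH; consistency of this implicit charge bookkeeping with the fluxes is
guaranteed by the zero-current closure. Luminal pCO2 is clamped to the
local interstitial value (an open system): gas permeabilities make free
CO2 a fast variable whose closed-pool dynamics would be numerically
meaningless at any affordable grid, and luminal bicarbonate then follows
the open-system equilibrium. A consequence worth stating plainly: total
CO2 is not a conserved quantity of the march, and the conservation
accounting covers volume and the eight carried quantities.

Coalescence: the connecting tubules merge as
$\omega_{CNT}(x) = 2 - 2.32^{x/L}$, clamped below at 0.182 (about 2/11,
six tubules converging on one cortical collecting duct) because the
printed formula reaches −0.32 at the segment end; the clamp is an
implementation safeguard, and the pre-clamp value remains available for
testing. The inner-medullary ducts merge as
$\omega_{IMCD}(x) = 0.1(1 - 0.95 (x/L)^2) e^{-2.75 x/L}$. Because these
fractions use different normalizations, the march uses each segment's
inlet-normalized shape and keeps the population flow continuous at
segment boundaries; conservation is applied to $\omega Q$ and
$\omega Q C$ with the wall flux per unit population length scaled by
$\omega$. The cortical collecting duct inlet is the population-weighted,
flow-weighted mixture of the six connecting-tubule outflows.

The marching scheme is implicit per-station: a trapezoidal (second-order)
step solved by a damped Newton iteration on the ten luminal states, with
the epithelial cross-section re-solved — warm-started, with a chord
Jacobian shared along the segment — inside every evaluation. Implicit
coupling is not a refinement but a necessity: luminal osmolality is a
stiff mode whose relaxation length (tenths of a millimetre in the
proximal tubule, far less at collecting-duct flows) is much shorter than
any affordable grid step, and explicit schemes oscillate and diverge. The
second order, rather than first, is needed for grid-insensitivity: under
step halving the packaged sets change urinary flow by well under 0.1%.

## Numerical choices

Cross-sections are solved by a damped Newton iteration on
log-concentration unknowns (enforcing positivity and scale-balancing a
state that spans nine orders of magnitude), with Armijo backtracking on
the residual sum of squares, chord reuse of the LU-factored Jacobian,
activity-continuation from a ramped-down transporter state on failure,
and a Levenberg–Marquardt fallback (minpack.lm). The default tolerance is
2e-11 on the scaled residuals; solves that stagnate at the numerical
noise floor below 1e-6 (about 1e-3 pmol/min per cm of tubule in
absolute terms) are accepted and flagged. Residual scales: solute
balances in units of 1000 pmol/min/cm, volume balances 100 nL/min/cm,
electroneutrality 100 mM. Initialization uses the interstitial
composition with a generic intracellular ion shift and −60 mV — solver
settings, not physiological claims. Trial states that would overflow the
flux kernels or drive a carried quantity non-positive are rejected before
evaluation; failed implicit steps retry with recursive halving. The
GHK kernel switches to a series expansion below |ζ| = 1e-4 (a removable
singularity). Every species keeps a minimal basolateral leak (1e-7 cm/s)
so that no cell balance equation is structurally degenerate.

Two further safeguards concern the inner-medullary duct tip, where the
printed coalescence law makes the per-tubule flow grow e-fold per few
tens of micrometres: the inlet-normalized population fraction is floored
at 0.05 (`solver$imcd_floor`), mirroring the connecting-tubule clamp, and
axial stretches where the implicit step map is too ill-conditioned are
integrated with fixed explicit micro-steps (stable because the sub-step
is far below the stiff mode's scale). Segment inlets and the duct tip use
geometrically graded sub-steps so that step-halving error is dominated by
the smooth interior. All solves are deterministic: identical inputs give
identical iterates.

# Parameters

Units follow the conventions of this model family: concentrations mM,
lengths cm, pressures mmHg, potentials mV, flows nL/min per tubule,
membrane water permeability as osmotic Pf in cm/s, solute permeabilities
in 1e-5 cm/s, transporter activities in pmol/min per cm² of (amplified)
membrane. The chemistry constants (phosphate pK 6.80, ammonium 9.15,
formate 3.76, carbonic 3.57; CO2 hydration/dehydration rates giving an
apparent CO2/HCO3- pK of 6.1) are configuration entries.

The literature this model family rests on reports *relative* sex and
species differences, not absolute baselines. The packaged male-rat set is
therefore a calibrated transcription: a self-consistent absolute set tuned
so that the solved model reproduces textbook rat function — about
three-quarters of filtered Na+ reabsorbed proximally, near-complete
reabsorption of filtered Na+/Cl-/HCO3-/water, urinary fractional K+
excretion of a few tens of percent — while every structural element the
tabulated differences reference (transporters, channel permeabilities,
paracellular permeabilities, dimensions) exists and carries the delta.
Every value is provenance-tagged `transcribed`; values modified by a delta
chain are tagged `delta-derived`; the toy set is tagged `fixture`.

The three delta tables (`deltas_rat_f`, `deltas_mouse_m`,
`deltas_mouse_f`) list one row per tabulated segment/parameter pair,
including explicit no-ops where a column reports no difference, so a
completeness test can enumerate them. Rows whose source carried stray
trailing marks are read as the printed percentage and annotated. Combined
length/diameter entries are split; geometry deltas rescale segment length
and radius, and since membrane areas are amplification × circumference ×
length, transport capacity scales with length × diameter as it should.
The ENaC row of the distal convoluted tubule is applied to the late
portion only (the early portion carries no ENaC); all other DCT rows apply
to both portions. Female plasma K+ is derived relatively (−10% rat, −7%
mouse) from the transcribed baseline.

Juxtamedullary tubule radii scale with the SNGFR ratio
(`jm_tubule_scale`, default equal to `jm_sngfr_ratio`): larger nephrons
filter more and are dimensionally larger, and without this
glomerulotubular matching the class-averaged deliveries would be
dominated by a mismatch the source models do not have.

The interstitial composition is prescribed, not solved: piecewise
exponential axial profiles (cortex → outer-medullary boundary → papillary
tip) for Na+ (multipliers 1, 1.6, 1.95 of plasma), K+ (1, 2, 1.6), urea
(5, 40, 450 mM) and total ammonia (0.2, 2, 4 mM), other solutes at
cortical plasma values, pH 7.4. These are documented approximations;
the source family obtains them from prior models.

# The toy fixture

`build_toy_fixture()` is a first-class reduced parameter set, not stored
data: the same thirteen segments and schema as the full baseline (so every
delta row resolves and every code path runs — compliant torque-modulated
proximal tubule, coalescing CNT and IMCD, principal plus intercalated
collecting-duct cells), with segment lengths scaled to 30% and two
nephron classes (SF at weight 0.75, JM-2 at 0.25). It solves in seconds
and is the substrate of the conservation, protocol and grid-refinement
tests. What passing toy tests shows: the accounting is exact, the solver
is deterministic and grid-insensitive, the protocols modify exactly what
they claim. What it does not show: quantitative fidelity to any animal —
the toy's short segments reabsorb far less than a real kidney, and its
fractional excretions are high.

# Protocols

* `run_baseline()` — solve and tabulate absolute and fractional
  deliveries of volume, Na+, K+, Cl-, HCO3-, NH4+ at each segment-group
  inlet plus urine.
* `run_saline_load()` — SNGFR ×1.50 (male) or ×1.65 (female), all other
  parameters unchanged; the torque reference stays at baseline, so
  proximal reabsorption rises with load (glomerulotubular balance).
  `excretion_ratio()` converts per-kidney excretions into the
  bolus-normalized female-to-male ratio (female rats carry half the male
  bolus; male mice 30% more than female).
* `run_segment_swap()` — set the transporter and channel activities of
  one mouse segment group to the sex-matched rat values by inverting the
  rat-to-mouse delta column for that group; geometry and SNGFR are never
  touched, and paracellular permeabilities are included only where that
  column lists them (IMCD). Reports per-region fractional changes in
  Na+/K+/water transport and in excretions.
* `run_sex_swap()` — make one female-mouse sex difference rat-like,
  referenced to male-mouse values: proximal water permeability to 36%
  below male; Na+-K+-ATPase along TAL/DCT/CNT doubled; or ENaC along
  CNT/CCD/OMCD set 30/50/20% above male.

# Problem sizes

The packaged axial grids are 10 stations along the PCT, 6–8 along the
other long segments and 3–5 along short ones; the toy uses 3–4. These
were chosen as the coarsest grids whose step-halving changes urinary flow
by less than 0.1%. A full four-model baseline comparison solves roughly
3,000 epithelial cross-sections per model.

# Known limitations

* The interstitium is prescribed a priori; there is no nephron-to-
  interstitium feedback and no tubuloglomerular feedback — filtration is
  an input per protocol, as in the source models.
* Total CO2 exchanges with a clamped luminal reservoir (open system), so
  acid-base disequilibrium pH effects along the lumen are not
  represented.
* Absolute transporter kinetic constants are not printed anywhere in the
  source literature accessible to this package; the baseline is a
  calibrated transcription, and quantitative agreement with any specific
  published table should be read at the level of orderings and patterns,
  which is what the test suite asserts.
* Steady state only: no dynamic cell-volume regulation, no time-resolved
  excretion curves, no transporter remodeling under chronic loads.
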