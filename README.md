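# nephrosim

Steady-state, sex- and species-specific simulation of water and solute
transport along rat and mouse nephrons.

## The scientific problem

Renal Na+, K+ and water handling is set by the pattern of transporters
along the nephron — NHE3 in the proximal tubule, NKCC2 in the thick
ascending limb, NCC in the distal convoluted tubule, ENaC and the
K+-secreting channels of the connecting tubule and collecting duct, with
the basolateral Na+-K+-ATPase driving the whole chain. This pattern
differs between males and females and between rats and mice: female
proximal tubules carry less NHE3 activity and less transport area, while
the female distal nephron is up-regulated; mouse nephrons are smaller and
carry less NHE3 than sex-matched rat nephrons. `nephrosim` is a
computational test bench for the functional consequences of those
differences: it solves the coupled steady-state transport equations for
six nephron classes (one superficial, five juxtamedullary) that coalesce
into a shared collecting duct, and derives the female-rat, male-mouse and
female-mouse models from a male-rat baseline by applying tabulated
relative parameter differences.

It is aimed at renal physiologists and modelers who want to ask
"what if this transporter had the other sex's (or species') abundance?"
quantitatively, per segment, with full mass, charge and water accounting.

## The model in brief

At each axial station a cross-section couples the lumen, one or two cell
types, the lateral interspace and the interstitium through:

* water flux `J_v = A Lp (sigma RT sum dC + dP)` per membrane;
* solute flux as convection `(1 - sigma) Cbar J_v`, Goldman–Hodgkin–Katz
  electrodiffusion `h zeta (C_a - C_b e^-zeta)/(1 - e^-zeta)`, coupled
  transport (cotransporters/exchangers), and ATPase pumping (3Na:2K Hill
  kinetics; apical H-K-ATPase);
* conservation of volume and of the 15 solutes (Na+, K+, Cl-, HCO3-,
  H2CO3, CO2, NH3, NH4+, HPO4^2-, H2PO4-, H+, HCO2-, H2CO2, urea,
  glucose) with acid-base pairs at mass action, finite-rate CO2 hydration
  in cells, electroneutrality and zero net current.

The proximal tubule is compliant and its transport is modulated by
microvillous torque (`S_torq = 1 + s (tau/tau0 - 1)`), giving
glomerulotubular balance. Connecting tubules merge as
`omega_CNT(x) = 2 - 2.32^(x/L)` and inner-medullary collecting ducts as
`omega_IMCD(x) = 0.1 (1 - 0.95 (x/L)^2) exp(-2.75 x/L)`. The axial march
is implicit (trapezoidal, Newton-in-Newton) because luminal osmolality is
numerically stiff. See the methods vignette
(`vignettes/nephron-transport.Rmd`) for the full account.

## A worked example

The toy fixture is a miniature but structurally complete kidney (two
nephron classes, short segments) that solves in a few seconds:

```r
library(nephrosim)
toy <- build_toy_fixture()
res <- run_baseline(toy)
print(res$deliveries, digits = 3)
```

```
Per-kidney deliveries (volume uL/min, solutes umol/min):
 boundary volume    Na    K    Cl  HCO3    NH4
       PT   1202 173.0 6.01 146.1 29.17 0.2361
       DL    718 124.8 5.59 125.9  2.05 0.4129
     mTAL    475 114.9 5.28 115.7  2.04 0.4833
      DCT    475  71.7 3.30  70.1  2.01 0.0294
      CNT    479  66.1 3.53  64.8  2.03 0.0357
      CCD    474  64.9 3.84  63.9  2.02 0.0383
     OMCD    472  64.5 3.89  63.5  2.00 0.0392
     IMCD    438  64.1 3.89  63.2  1.93 0.0425
    urine    291  63.6 3.80  62.8  1.70 0.0510
```

Each row is the delivery to the inlet of that nephron region, summed over
the nephron population and scaled per kidney; the difference between
consecutive rows is the net transport of the intervening segment, and the
last row is urinary excretion. Reading the `Na` column: of 173 umol/min
filtered, the proximal tubule reabsorbs 48 (173 to 125 at the descending
limb), the loop and distal segments most of the rest. `res$fd` holds the
same table as percent of filtered load. (The toy's short segments
deliberately reabsorb much less than a real kidney.)

The four full models are built from the packaged male-rat baseline and
the delta tables:

```r
mouse_f <- build_model("mouse", "female")   # rat_male + rat-to-mouse
                                            # + mouse male-to-female deltas
kid <- assemble_kidney(compile_model(mouse_f))   # a few minutes
fractional_delivery(delivery_table(kid))
```

Protocols: `run_saline_load()` (SNGFR +50% male / +65% female),
`run_segment_swap()` (mouse transporter activities set to sex-matched rat
values, one segment group at a time), `run_sex_swap()` (selected
female-mouse sex differences made rat-like). A thin command-line wrapper
lives at `inst/cli/simulate.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/simulate.R", package="nephrosim"))')" \
    --toy --protocol baseline --out out/
```

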