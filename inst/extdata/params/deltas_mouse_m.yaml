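# Male-rat-to-male-mouse parameter deltas.
# Combined length/diameter entries are split into separate relative changes.
# overrides: species-level structural values that are not per-segment deltas
# (nephron population, juxtamedullary SNGFR ratio, class weights; the
# published mouse class weights are normalized to sum to one by reading the
# juxtamedullary sub-fractions as fractions of the juxtamedullary pool).
column: rat_male_to_mouse_male
rows:
  - {segment: global, parameter: SNGFR, change: -0.667}
  - {segment: global, parameter: Plasma K, change: null}
  - {segment: PT, parameter: Length/diameter, length_change: -0.636, diameter_change: -0.20}
  - {segment: PT, parameter: NHE3 activity, change: -0.32}
  - {segment: PT, parameter: SGLT2 activity, change: null, scope: [PCT]}
  - {segment: PT, parameter: NaPi activity, change: null}
  - {segment: PT, parameter: Paracellular P_Na, change: null}
  - {segment: PT, parameter: Paracellular P_Cl, change: null}
  - {segment: PT, parameter: Apical P_f, change: null}
  - {segment: SDL, parameter: Length/diameter, length_change: -0.429, diameter_change: -0.40}
  - {segment: TAL, parameter: Length/diameter, length_change: -0.35, diameter_change: -0.10}
  - {segment: TAL, parameter: Na-K-ATPase activity, change: -0.13}
  - {segment: TAL, parameter: NHE activity, change: null}
  - {segment: TAL, parameter: NaPi activity, change: null}
  - {segment: TAL, parameter: NKCC2 activity, change: null}
  - {segment: TAL, parameter: KCC4 activity, change: null}
  - {segment: TAL, parameter: Paracellular P_Na, change: null}
  - {segment: TAL, parameter: Paracellular P_Cl, change: null}
  - {segment: DCT, parameter: Length/diameter, length_change: -0.30, diameter_change: -0.067}
  - {segment: DCT, parameter: NCC activity, change: -0.27}
  - {segment: DCT, parameter: Na-K-ATPase activity, change: -0.20}
  - {segment: DCT, parameter: Apical P_K, change: -0.67}
  - {segment: DCT, parameter: ENaC activity, change: -0.49, scope: [DCTl]}
  - {segment: DCT, parameter: Apical P_f, change: null}
  - {segment: DCT, parameter: Paracellular P_Na, change: null}
  - {segment: DCT, parameter: Paracellular P_Cl, change: null}
  - {segment: DCT, parameter: NHE activity, change: null}
  - {segment: DCT, parameter: NaPi activity, change: null}
  - {segment: CNT, parameter: Length/diameter, length_change: -0.60, diameter_change: -0.167}
  - {segment: CNT, parameter: Apical P_K, change: -0.75}
  - {segment: CNT, parameter: H-K-ATPase, change: -0.50}
  - {segment: CNT, parameter: Apical P_f, change: null}
  - {segment: CNT, parameter: Paracellular P_Na, change: null}
  - {segment: CNT, parameter: Paracellular P_Cl, change: null}
  - {segment: CNT, parameter: NHE activity, change: null}
  - {segment: CNT, parameter: NaPi activity, change: null}
  - {segment: CNT, parameter: Na-K-ATPase activity, change: null}
  - {segment: CNT, parameter: ENaC activity, change: null}
  - {segment: CCD, parameter: Length/diameter, length_change: -0.50, diameter_change: -0.04}
  - {segment: CCD, parameter: H-K-ATPase, change: -0.50}
  - {segment: CCD, parameter: Apical P_f, change: null}
  - {segment: CCD, parameter: Apical P_K, change: null}
  - {segment: CCD, parameter: Paracellular P_Na, change: null}
  - {segment: CCD, parameter: Paracellular P_Cl, change: null}
  - {segment: CCD, parameter: NHE activity, change: null}
  - {segment: CCD, parameter: NaPi activity, change: null}
  - {segment: CCD, parameter: Na-K-ATPase activity, change: null}
  - {segment: CCD, parameter: ENaC activity, change: null}
  - {segment: OMCD, parameter: Length/diameter, length_change: -0.35, diameter_change: -0.04}
  - {segment: OMCD, parameter: H-K-ATPase, change: -0.50}
  - {segment: OMCD, parameter: Apical P_f, change: null}
  - {segment: OMCD, parameter: Apical P_K, change: null}
  - {segment: OMCD, parameter: "Apical P_Na, P_Cl", change: null}
  - {segment: OMCD, parameter: NHE activity, change: null}
  - {segment: OMCD, parameter: NaPi activity, change: null}
  - {segment: OMCD, parameter: Na-K-ATPase activity, change: null}
  - {segment: OMCD, parameter: ENaC activity, change: null}
  - {segment: IMCD, parameter: Length/diameter, length_change: -0.32, diameter_change: -0.07}
  - {segment: IMCD, parameter: NHE activity, change: -0.67}
  - {segment: IMCD, parameter: Na-K-ATPase activity, change: -0.25}
  - {segment: IMCD, parameter: H-K-ATPase activity, change: -0.75}
  - {segment: IMCD, parameter: Paracellular P_Na, change: -0.33}
  - {segment: IMCD, parameter: Apical P_f, change: null}
  - {segment: IMCD, parameter: Apical P_Na, change: null}
  - {segment: IMCD, parameter: Apical P_K, change: null}
  - {segment: IMCD, parameter: Paracellular P_K, change: null}
  - {segment: IMCD, parameter: Paracellular P_Cl, change: null}
  - {segment: IMCD, parameter: KCC activity, change: null}
  - {segment: IMCD, parameter: NKCC activity, change: null}
overrides:
  nephrons: 12000
  jm_sngfr_ratio: 1.20
  class_weights: {SF: 0.82, JM1: 0.072, JM2: 0.054, JM3: 0.027, JM4: 0.018, JM5: 0.009}
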