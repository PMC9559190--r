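# Male-to-female parameter deltas for the rat model.
# change: signed relative change (female = male * (1 + change));
# null change = no difference reported for this column (explicit no-op).
column: rat_male_to_female
rows:
  - {segment: global, parameter: SNGFR, change: -0.20}
  - {segment: global, parameter: Plasma K, change: -0.10}
  - {segment: PT, parameter: Length/diameter, length_change: -0.20, diameter_change: -0.20}
  - {segment: PT, parameter: NHE3 activity, change: -0.17}
  - {segment: PT, parameter: SGLT2 activity, change: 1.50, scope: [PCT]}
  - {segment: PT, parameter: NaPi activity, change: -0.25}
  - {segment: PT, parameter: Paracellular P_Na, change: -0.60}
  - {segment: PT, parameter: Paracellular P_Cl, change: -0.60}
  - {segment: PT, parameter: Apical P_f, change: -0.36}
  - {segment: SDL, parameter: Length/diameter, length_change: -0.15, diameter_change: -0.15}
  - {segment: TAL, parameter: Length/diameter, length_change: -0.15, diameter_change: -0.15}
  - {segment: TAL, parameter: Na-K-ATPase activity, change: 1.00}
  - {segment: TAL, parameter: NHE activity, change: -0.20}
  - {segment: TAL, parameter: NaPi activity, change: -0.20}
  - {segment: TAL, parameter: NKCC2 activity, change: 1.00}
  - {segment: TAL, parameter: KCC4 activity, change: 0.50}
  - {segment: TAL, parameter: Paracellular P_Na, change: -0.10}
  - {segment: TAL, parameter: Paracellular P_Cl, change: -0.10}
  - {segment: DCT, parameter: Length/diameter, length_change: -0.15, diameter_change: -0.15}
  - {segment: DCT, parameter: NCC activity, change: 1.00}
  - {segment: DCT, parameter: Na-K-ATPase activity, change: 1.00}
  - {segment: DCT, parameter: Apical P_K, change: null}
  - {segment: DCT, parameter: ENaC activity, change: 1.00, scope: [DCTl]}
  - {segment: DCT, parameter: Apical P_f, change: 1.00}
  - {segment: DCT, parameter: Paracellular P_Na, change: 0.40}
  - {segment: DCT, parameter: Paracellular P_Cl, change: 0.40}
  - {segment: DCT, parameter: NHE activity, change: -0.15}
  - {segment: DCT, parameter: NaPi activity, change: -0.15}
  - {segment: CNT, parameter: Length/diameter, length_change: -0.15, diameter_change: -0.15}
  - {segment: CNT, parameter: Apical P_K, change: null}
  - {segment: CNT, parameter: H-K-ATPase, change: null}
  - {segment: CNT, parameter: Apical P_f, change: 0.50}
  - {segment: CNT, parameter: Paracellular P_Na, change: 0.40}
  - {segment: CNT, parameter: Paracellular P_Cl, change: 0.40}
  - {segment: CNT, parameter: NHE activity, change: -0.10}
  - {segment: CNT, parameter: NaPi activity, change: -0.10}
  - {segment: CNT, parameter: Na-K-ATPase activity, change: 1.00}
  - {segment: CNT, parameter: ENaC activity, change: 0.30}
  - {segment: CCD, parameter: Length/diameter, length_change: -0.15, diameter_change: -0.15}
  - {segment: CCD, parameter: H-K-ATPase, change: null}
  - {segment: CCD, parameter: Apical P_f, change: 1.00}
  - {segment: CCD, parameter: Apical P_K, change: -0.30}
  - {segment: CCD, parameter: Paracellular P_Na, change: 0.40}
  - {segment: CCD, parameter: Paracellular P_Cl, change: 0.40}
  - {segment: CCD, parameter: NHE activity, change: -0.10}
  - {segment: CCD, parameter: NaPi activity, change: -0.10}
  - {segment: CCD, parameter: Na-K-ATPase activity, change: 0.50}
  - {segment: CCD, parameter: ENaC activity, change: 0.50}
  - {segment: OMCD, parameter: Length/diameter, length_change: -0.15, diameter_change: -0.15}
  - {segment: OMCD, parameter: H-K-ATPase, change: null}
  - {segment: OMCD, parameter: Apical P_f, change: 1.00}
  - {segment: OMCD, parameter: Apical P_K, change: 0.20}
  - {segment: OMCD, parameter: "Apical P_Na, P_Cl", change: null}
  - {segment: OMCD, parameter: NHE activity, change: -0.10}
  - {segment: OMCD, parameter: NaPi activity, change: -0.10}
  - {segment: OMCD, parameter: Na-K-ATPase activity, change: 0.10}
  - {segment: OMCD, parameter: ENaC activity, change: 0.20}
  - {segment: IMCD, parameter: Length/diameter, length_change: -0.15, diameter_change: -0.15}
  - {segment: IMCD, parameter: NHE activity, change: null}
  - {segment: IMCD, parameter: Na-K-ATPase activity, change: 0.20}
  - {segment: IMCD, parameter: H-K-ATPase activity, change: 0.50}
  - {segment: IMCD, parameter: Paracellular P_Na, change: -0.50}
  - {segment: IMCD, parameter: Apical P_f, change: 1.00}
  - {segment: IMCD, parameter: Apical P_Na, change: -0.50}
  - {segment: IMCD, parameter: Apical P_K, change: 1.00}
  - {segment: IMCD, parameter: Paracellular P_K, change: null}
  - {segment: IMCD, parameter: Paracellular P_Cl, change: -0.50}
  - {segment: IMCD, parameter: KCC activity, change: 0.20}
  - {segment: IMCD, parameter: NKCC activity, change: -0.30}
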