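# Male-to-female parameter deltas for the mouse model.
# Rows whose source table carried stray trailing "--" marks (IMCD
# paracellular P_K/P_Cl and KCC) are read as the printed percentage only;
# noted per row.
column: mouse_male_to_female
rows:
  - {segment: global, parameter: SNGFR, change: -0.20}
  - {segment: global, parameter: Plasma K, change: -0.07}
  - {segment: PT, parameter: Length/diameter, length_change: -0.15, diameter_change: -0.15}
  - {segment: PT, parameter: NHE3 activity, change: -0.35}
  - {segment: PT, parameter: SGLT2 activity, change: null, scope: [PCT]}
  - {segment: PT, parameter: NaPi activity, change: -0.50}
  - {segment: PT, parameter: Paracellular P_Na, change: -0.40}
  - {segment: PT, parameter: Paracellular P_Cl, change: -0.40}
  - {segment: PT, parameter: Apical P_f, change: 0.40}
  - {segment: SDL, parameter: Length/diameter, change: null}
  - {segment: TAL, parameter: Length/diameter, change: null}
  - {segment: TAL, parameter: Na-K-ATPase activity, change: -0.10}
  - {segment: TAL, parameter: NHE activity, change: -0.25}
  - {segment: TAL, parameter: NaPi activity, change: null}
  - {segment: TAL, parameter: NKCC2 activity, change: 0.20}
  - {segment: TAL, parameter: KCC4 activity, change: 0.64}
  - {segment: TAL, parameter: Paracellular P_Na, change: null}
  - {segment: TAL, parameter: Paracellular P_Cl, change: null}
  - {segment: DCT, parameter: Length/diameter, change: null}
  - {segment: DCT, parameter: NCC activity, change: 1.00}
  - {segment: DCT, parameter: Na-K-ATPase activity, change: 0.25}
  - {segment: DCT, parameter: Apical P_K, change: null}
  - {segment: DCT, parameter: ENaC activity, change: 0.17, scope: [DCTl]}
  - {segment: DCT, parameter: Apical P_f, change: 0.50}
  - {segment: DCT, parameter: Paracellular P_Na, change: 0.30}
  - {segment: DCT, parameter: Paracellular P_Cl, change: 0.30}
  - {segment: DCT, parameter: NHE activity, change: null}
  - {segment: DCT, parameter: NaPi activity, change: null}
  - {segment: CNT, parameter: Length/diameter, change: null}
  - {segment: CNT, parameter: Apical P_K, change: null}
  - {segment: CNT, parameter: H-K-ATPase, change: null}
  - {segment: CNT, parameter: Apical P_f, change: 0.20}
  - {segment: CNT, parameter: Paracellular P_Na, change: 0.30}
  - {segment: CNT, parameter: Paracellular P_Cl, change: 0.30}
  - {segment: CNT, parameter: NHE activity, change: null}
  - {segment: CNT, parameter: NaPi activity, change: null}
  - {segment: CNT, parameter: Na-K-ATPase activity, change: null}
  - {segment: CNT, parameter: ENaC activity, change: null}
  - {segment: CCD, parameter: Length/diameter, change: null}
  - {segment: CCD, parameter: H-K-ATPase, change: null}
  - {segment: CCD, parameter: Apical P_f, change: null}
  - {segment: CCD, parameter: Apical P_K, change: null}
  - {segment: CCD, parameter: Paracellular P_Na, change: null}
  - {segment: CCD, parameter: Paracellular P_Cl, change: null}
  - {segment: CCD, parameter: NHE activity, change: null}
  - {segment: CCD, parameter: NaPi activity, change: null}
  - {segment: CCD, parameter: Na-K-ATPase activity, change: null}
  - {segment: CCD, parameter: ENaC activity, change: null}
  - {segment: OMCD, parameter: Length/diameter, change: null}
  - {segment: OMCD, parameter: H-K-ATPase, change: null}
  - {segment: OMCD, parameter: Apical P_f, change: null}
  - {segment: OMCD, parameter: Apical P_K, change: null}
  - {segment: OMCD, parameter: "Apical P_Na, P_Cl", change: -0.20}
  - {segment: OMCD, parameter: NHE activity, change: null}
  - {segment: OMCD, parameter: NaPi activity, change: null}
  - {segment: OMCD, parameter: Na-K-ATPase activity, change: null}
  - {segment: OMCD, parameter: ENaC activity, change: null}
  - {segment: IMCD, parameter: Length/diameter, change: null}
  - {segment: IMCD, parameter: NHE activity, change: 2.00}
  - {segment: IMCD, parameter: Na-K-ATPase activity, change: 0.20}
  - {segment: IMCD, parameter: H-K-ATPase activity, change: 0.50}
  - {segment: IMCD, parameter: Paracellular P_Na, change: -0.25}
  - {segment: IMCD, parameter: Apical P_f, change: 0.50}
  - {segment: IMCD, parameter: Apical P_Na, change: null}
  - {segment: IMCD, parameter: Apical P_K, change: 1.50}
  - {segment: IMCD, parameter: Paracellular P_K, change: 2.00, note: trailing-marks-ignored}
  - {segment: IMCD, parameter: Paracellular P_Cl, change: 1.00, note: trailing-marks-ignored}
  - {segment: IMCD, parameter: KCC activity, change: 3.00, note: trailing-marks-ignored}
  - {segment: IMCD, parameter: NKCC activity, change: 0.50}
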