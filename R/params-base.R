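# Baseline male-rat parameter set.
#
# The simulator's governing equations are species- and sex-agnostic; all
# inter-species and inter-sex differences enter through parameters. The
# published literature for this model family reports relative differences
# (deltas) rather than absolute values, so the absolute baseline below is a
# calibrated transcription: a self-consistent male-rat set tuned to
# reproduce textbook rat segmental function (about three-quarters of
# filtered Na+ reabsorbed proximally, near-complete reabsorption of filtered
# Na+/Cl-/HCO3-/water, fractional K+ excretion of order 25%). Every value is
# provenance-tagged "transcribed" and is configuration, not a measured
# constant.
#
# Config units: permeabilities h in 1e-5 cm/s; water as osmotic Pf in cm/s;
# transporter/pump activities in pmol min-1 cm-2 of (amplified) membrane;
# lengths cm; SNGFR nL/min.

mem_cfg <- function(area_factor, pf = 0, sigma = 1, h = list(),
                    transporters = list()) {
  list(area_factor = area_factor, pf = pf, sigma = sigma, h = h,
       transporters = transporters)
}

tr_coupled <- function(name, stoich, activity, km = NULL) {
  out <- list(name = name, kind = "coupled", stoich = stoich,
              activity = activity)
  if (!is.null(km)) out$km <- km
  out
}

# saturable reversible carrier (used for NHE3, NKCC2, NCC): flux is
# proportional to activity far from equilibrium instead of being buffered
# by the thermodynamic drive
tr_mm <- function(name, stoich, activity, cref = NULL) {
  out <- list(name = name, kind = "mm", stoich = stoich, activity = activity)
  if (!is.null(cref)) out$cref <- cref
  out
}

tr_channel <- function(name, solute, h) {
  list(name = name, kind = "channel", solute = solute, h = h)
}

tr_nka <- function(activity, k_na = 10, k_k = 1.5, k_na_mod = 8.33) {
  list(name = "Na-K-ATPase", kind = "atpase", stoich = list(Na = 3, K = -2),
       activity = activity, k_na_mod = k_na_mod,
       sites = list(list(solute = "Na", side = "a", K = k_na, n = 3),
                    list(solute = "K", side = "b", K = k_k, n = 2)))
}

tr_hka <- function(activity, k_k = 1.0, k_h = 1e-5) {
  # apical membrane (lumen -> cell orientation): K+ in, H+ out; the pump
  # needs cytosolic H+ (site on the cell side) so it shuts down rather
  # than alkalinizing the cell without bound
  list(name = "H-K-ATPase", kind = "atpase", stoich = list(K = 1, H = -1),
       activity = activity,
       sites = list(list(solute = "K", side = "a", K = k_k, n = 1),
                    list(solute = "H", side = "b", K = k_h, n = 1)))
}

tr_nhe3 <- function(activity, nh4_frac = 0.05) {
  list(tr_mm("NHE3", list(Na = 1, H = -1), activity,
             cref = list(Na = 140, H = 3e-6)),
       tr_mm("NHE3.NH4", list(Na = 1, NH4 = -1), activity * nh4_frac,
             cref = list(Na = 140, NH4 = 0.1)))
}

tr_nkcc2 <- function(activity, nh4_frac = 0.15) {
  list(tr_mm("NKCC2", list(Na = 1, K = 1, Cl = 2), activity,
             cref = list(Na = 100, K = 2, Cl = 80)),
       tr_mm("NKCC2.NH4", list(Na = 1, NH4 = 1, Cl = 2),
             activity * nh4_frac,
             cref = list(Na = 100, NH4 = 0.2, Cl = 80)))
}

# gas + background permeabilities shared by most membranes (1e-5 cm/s)
.h_gas <- list(CO2 = 2000, NH3 = 20, H2CO3 = 10, H = 20)

cell_cfg <- function(tag, apical, basolateral, frac = 1, imp_mM = 60,
                     z_imp = -1, volume_nl_per_cm = 120, ca_cell = 20,
                     p_cell = NULL) {
  list(tag = tag, frac = frac, imp_mM = imp_mM, z_imp = z_imp,
       volume_nl_per_cm = volume_nl_per_cm, ca_cell = ca_cell,
       p_cell = p_cell, apical = apical, basolateral = basolateral)
}

seg_cfg <- function(id, length_cm, radius_cm, n_grid, cells, junction,
                    basement, compliant = FALSE, coalesce = "none",
                    depth = c(0, 0), ca_lumen = 0) {
  list(id = id, length_cm = length_cm, radius_cm = radius_cm,
       n_grid = n_grid, compliant = compliant, coalesce = coalesce,
       depth_start = depth[1], depth_end = depth[2], ca_lumen = ca_lumen,
       cells = cells, junction = junction, basement = basement)
}

# Shared basement membrane: a leaky barrier in series; the interspace stays
# close to interstitial composition.
.basement <- function() {
  mem_cfg(area_factor = 15, pf = 0.8, sigma = 0,
          h = c(list(Na = 400, K = 400, Cl = 400, HCO3 = 300, NH4 = 300,
                     HPO4 = 150, H2PO4 = 150, HCO2 = 200, H2CO2 = 200,
                     urea = 300, glucose = 200), .h_gas))
}

params_rat_male <- function() {
  pct_cells <- list(cell_cfg(
    tag = "PC", imp_mM = 60, z_imp = -1, volume_nl_per_cm = 150,
    apical = mem_cfg(
      area_factor = 36, pf = 0.08,
      h = c(list(Na = 0.002, K = 0.03, Cl = 0.005, HCO3 = 0.002, NH4 = 0.07,
                 HPO4 = 0.001, H2PO4 = 0.003, HCO2 = 0.025, H2CO2 = 6000,
                 urea = 0.55, glucose = 0.003), .h_gas),
      transporters = c(tr_nhe3(30000), list(
        tr_coupled("CFEX", list(Cl = 1, HCO2 = -1), 36500),
        tr_coupled("SGLT2", list(Na = 1, glucose = 1), 2000),
        tr_coupled("NaPi", list(Na = 2, HPO4 = 1), 14)))),
    basolateral = mem_cfg(
      area_factor = 36, pf = 0.08,
      h = c(list(Na = 0.002, K = 0.72, Cl = 0.43, HCO3 = 0.55, NH4 = 0.023,
                 HPO4 = 0.005, H2PO4 = 0.01, HCO2 = 0.04, H2CO2 = 30,
                 urea = 0.55, glucose = 0.7), .h_gas),
      transporters = list(tr_nka(90000),
                          tr_coupled("NBC", list(Na = 1, HCO3 = 3), 56000),
                          tr_coupled("KCC", list(K = 1, Cl = 1), 134)))))
  pct_junction <- mem_cfg(
    area_factor = 0.2, pf = 0.36, sigma = 0.70,
    h = c(list(Na = 12, K = 240, Cl = 6, HCO3 = 1.5, NH4 = 11,
               HPO4 = 3.6, H2PO4 = 5.4, HCO2 = 11, H2CO2 = 11,
               urea = 18, glucose = 4.5),
          list(CO2 = 300, NH3 = 15, H2CO3 = 10, H = 100)))

  PCT <- seg_cfg("PCT", length_cm = 1.00, radius_cm = 0.0012, n_grid = 10,
                 cells = pct_cells, junction = pct_junction,
                 basement = .basement(), compliant = TRUE,
                 depth = c(0, 0), ca_lumen = 20)

  s3_cells <- list(cell_cfg(
    tag = "PC", imp_mM = 60, z_imp = -1, volume_nl_per_cm = 110,
    apical = mem_cfg(
      area_factor = 22, pf = 0.07,
      h = c(list(Na = 0.002, K = 0.03, Cl = 0.005, HCO3 = 0.0015, NH4 = 0.055,
                 HPO4 = 0.001, H2PO4 = 0.0025, HCO2 = 0.02, H2CO2 = 4000,
                 urea = 0.45, glucose = 0.002), .h_gas),
      transporters = c(tr_nhe3(16200), list(
        tr_coupled("CFEX", list(Cl = 1, HCO2 = -1), 21000),
        tr_coupled("SGLT2", list(Na = 1, glucose = 1), 460),
        tr_coupled("NaPi", list(Na = 2, HPO4 = 1), 8)))),
    basolateral = mem_cfg(
      area_factor = 22, pf = 0.07,
      h = c(list(Na = 0.002, K = 0.60, Cl = 0.35, HCO3 = 0.43, NH4 = 0.018,
                 HPO4 = 0.004, H2PO4 = 0.007, HCO2 = 0.027, H2CO2 = 25,
                 urea = 0.45, glucose = 0.45), .h_gas),
      transporters = list(tr_nka(56000),
                          tr_coupled("NBC", list(Na = 1, HCO3 = 3), 33700),
                          tr_coupled("KCC", list(K = 1, Cl = 1), 98)))))
  S3 <- seg_cfg("S3", length_cm = 0.50, radius_cm = 0.0011, n_grid = 6,
                cells = s3_cells, junction = pct_junction,
                basement = .basement(), compliant = TRUE,
                depth = c(0, 0.08), ca_lumen = 20)

  # descending limbs: water-permeable, low solute permeability
  sdl_cells <- list(cell_cfg(
    tag = "DL", imp_mM = 50, z_imp = -1, volume_nl_per_cm = 40,
    apical = mem_cfg(area_factor = 3, pf = 0.40,
                     h = c(list(Na = 0.02, K = 0.1, Cl = 0.02,
                                HCO3 = 0.01, NH4 = 0.05, urea = 0.5,
                                HPO4 = 0.01, H2PO4 = 0.02, HCO2 = 0.02,
                                H2CO2 = 5, glucose = 0.02), .h_gas)),
    basolateral = mem_cfg(area_factor = 5, pf = 0.40,
                          h = c(list(Na = 0.02, K = 0.4, Cl = 0.15,
                                     HCO3 = 0.05, NH4 = 0.05, urea = 0.5,
                                     HPO4 = 0.02, H2PO4 = 0.03,
                                     HCO2 = 0.03, H2CO2 = 5,
                                     glucose = 0.05), .h_gas),
                          transporters = list(tr_nka(4000)))))
  sdl_junction <- mem_cfg(area_factor = 0.2, pf = 2.5, sigma = 0.8,
                          h = c(list(Na = 12, K = 15, Cl = 10, HCO3 = 3,
                                     NH4 = 10, urea = 5, glucose = 1,
                                     HPO4 = 1, H2PO4 = 1, HCO2 = 1,
                                     H2CO2 = 1),
                                list(CO2 = 300, NH3 = 15, H2CO3 = 10,
                                     H = 100)))
  SDL <- seg_cfg("SDL", length_cm = 0.20, radius_cm = 0.0008, n_grid = 4,
                 cells = sdl_cells, junction = sdl_junction,
                 basement = .basement(), depth = c(0.05, 0.2))

  LDL <- seg_cfg("LDL", length_cm = 0.20, radius_cm = 0.0008, n_grid = 4,
                 cells = sdl_cells, junction = sdl_junction,
                 basement = .basement(), depth = c(0.2, 0.3))

  # ascending thin limb: water-tight, NaCl-permeable
  lal_cells <- list(cell_cfg(
    tag = "AL", imp_mM = 50, z_imp = -1, volume_nl_per_cm = 40,
    apical = mem_cfg(area_factor = 3, pf = 0,
                     h = c(list(Na = 0.05, K = 0.15, Cl = 0.4, HCO3 = 0.02,
                                NH4 = 0.1, urea = 0.3, HPO4 = 0.01,
                                H2PO4 = 0.02, HCO2 = 0.02, H2CO2 = 5,
                                glucose = 0.02), .h_gas)),
    basolateral = mem_cfg(area_factor = 5, pf = 0,
                          h = c(list(Na = 0.03, K = 0.4, Cl = 0.6,
                                     HCO3 = 0.1, NH4 = 0.1, urea = 0.3,
                                     HPO4 = 0.02, H2PO4 = 0.03,
                                     HCO2 = 0.03, H2CO2 = 5,
                                     glucose = 0.05), .h_gas),
                          transporters = list(tr_nka(2500)))))
  lal_junction <- mem_cfg(area_factor = 0.2, pf = 0, sigma = 0.9,
                          h = c(list(Na = 80, K = 30, Cl = 120, HCO3 = 2,
                                     NH4 = 25, urea = 3, glucose = 1,
                                     HPO4 = 1, H2PO4 = 1, HCO2 = 1,
                                     H2CO2 = 1),
                                list(CO2 = 300, NH3 = 15, H2CO3 = 10,
                                     H = 100)))
  LAL <- seg_cfg("LAL", length_cm = 0.20, radius_cm = 0.0008, n_grid = 4,
                 cells = lal_cells, junction = lal_junction,
                 basement = .basement(), depth = c(0.3, 0.2))

  tal_cells <- function(act_scale) list(cell_cfg(
    tag = "TAL", imp_mM = 60, z_imp = -1, volume_nl_per_cm = 90,
    apical = mem_cfg(
      area_factor = 6, pf = 0,
      h = c(list(Na = 0.01, K = 1.2, Cl = 0.01, HCO3 = 0.004, NH4 = 0.2,
                 HPO4 = 0.002, H2PO4 = 0.004, HCO2 = 0.02, H2CO2 = 10,
                 urea = 0.08, glucose = 0.002), .h_gas),
      transporters = c(tr_nkcc2(105000 * act_scale), list(
        tr_coupled("NHE", list(Na = 1, H = -1), 1200 * act_scale),
        tr_coupled("NaPi", list(Na = 2, HPO4 = 1), 6 * act_scale)))),
    basolateral = mem_cfg(
      area_factor = 20, pf = 0.002,
      h = c(list(Na = 0.01, K = 0.12, Cl = 0.9, HCO3 = 0.05, NH4 = 0.08,
                 HPO4 = 0.008, H2PO4 = 0.012, HCO2 = 0.08, H2CO2 = 10,
                 urea = 0.08, glucose = 0.8), .h_gas),
      transporters = list(tr_nka(28000 * act_scale),
                          tr_coupled("KCC4", list(K = 1, Cl = 1),
                                     2000 * act_scale)))))
  tal_junction <- mem_cfg(area_factor = 0.2, pf = 0, sigma = 0.85,
                          h = c(list(Na = 420, K = 200, Cl = 30, HCO3 = 2,
                                     NH4 = 150, urea = 1, glucose = 0.5,
                                     HPO4 = 0.5, H2PO4 = 0.5, HCO2 = 0.5,
                                     H2CO2 = 0.5),
                                list(CO2 = 300, NH3 = 15, H2CO3 = 10,
                                     H = 100)))
  mTAL <- seg_cfg("mTAL", length_cm = 0.40, radius_cm = 0.0010, n_grid = 6,
                  cells = tal_cells(1.0), junction = tal_junction,
                  basement = .basement(), depth = c(0.2, 0))
  cTAL <- seg_cfg("cTAL", length_cm = 0.40, radius_cm = 0.0010, n_grid = 6,
                  cells = tal_cells(0.8), junction = tal_junction,
                  basement = .basement(), depth = c(0, 0))

  dct_cell <- function(late) list(cell_cfg(
    tag = "DCT", imp_mM = 60, z_imp = -1, volume_nl_per_cm = 70,
    apical = mem_cfg(
      area_factor = 8, pf = 0.004,
      h = c(list(Na = 0.005, K = if (late) 0.13 else 0.07, Cl = 0.02,
                 HCO3 = 0.004, NH4 = 0.1, HPO4 = 0.002, H2PO4 = 0.006,
                 HCO2 = 0.04, H2CO2 = 10, urea = 0.04, glucose = 0.002),
            .h_gas),
      transporters = c(list(
        tr_mm("NCC", list(Na = 1, Cl = 1), if (late) 41000 else 75000,
                      cref = list(Na = 60, Cl = 40)),
        tr_coupled("NHE", list(Na = 1, H = -1), 350),
        tr_coupled("NaPi", list(Na = 2, HPO4 = 1), 8)),
        if (late) list(tr_channel("ENaC", "Na", 0.12)) else list())),
    basolateral = mem_cfg(
      area_factor = 20, pf = 0.02,
      h = c(list(Na = 0.008, K = 0.6, Cl = 0.6, HCO3 = 0.05, NH4 = 0.06,
                 HPO4 = 0.006, H2PO4 = 0.01, HCO2 = 0.06, H2CO2 = 10,
                 urea = 0.06, glucose = 0.6), .h_gas),
      transporters = list(tr_nka(20000, k_na = 6),
                          tr_coupled("KCC", list(K = 1, Cl = 1), 700)))))
  dct_junction <- mem_cfg(area_factor = 0.2, pf = 0.04, sigma = 0.85,
                          h = c(list(Na = 8, K = 8, Cl = 8, HCO3 = 1,
                                     NH4 = 6, urea = 0.4, glucose = 0.2,
                                     HPO4 = 0.2, H2PO4 = 0.2, HCO2 = 0.2,
                                     H2CO2 = 0.2),
                                list(CO2 = 300, NH3 = 15, H2CO3 = 10,
                                     H = 100)))
  DCTe <- seg_cfg("DCTe", length_cm = 0.10, radius_cm = 0.0010, n_grid = 3,
                  cells = dct_cell(FALSE), junction = dct_junction,
                  basement = .basement(), depth = c(0, 0))
  DCTl <- seg_cfg("DCTl", length_cm = 0.10, radius_cm = 0.0010, n_grid = 3,
                  cells = dct_cell(TRUE), junction = dct_junction,
                  basement = .basement(), depth = c(0, 0))

  cnt_cells <- list(cell_cfg(
    tag = "CNT", imp_mM = 60, z_imp = -1, volume_nl_per_cm = 80,
    apical = mem_cfg(
      area_factor = 4, pf = 0.05,
      h = c(list(Na = 0.004, K = 0.08, Cl = 0.02, HCO3 = 0.004, NH4 = 0.08,
                 HPO4 = 0.002, H2PO4 = 0.004, HCO2 = 0.03, H2CO2 = 10,
                 urea = 0.03, glucose = 0.002), .h_gas),
      transporters = list(
        tr_channel("ENaC", "Na", 1.10),
        tr_hka(120),
        tr_coupled("NHE", list(Na = 1, H = -1), 150),
        tr_coupled("NaPi", list(Na = 2, HPO4 = 1), 4))),
    basolateral = mem_cfg(
      area_factor = 10, pf = 0.05,
      h = c(list(Na = 0.006, K = 0.30, Cl = 0.5, HCO3 = 0.05, NH4 = 0.05,
                 HPO4 = 0.004, H2PO4 = 0.008, HCO2 = 0.05, H2CO2 = 10,
                 urea = 0.04, glucose = 0.4), .h_gas),
      transporters = list(tr_nka(50000, k_na = 6),
                          tr_coupled("KCC", list(K = 1, Cl = 1), 300)))))
  cd_junction <- mem_cfg(area_factor = 0.2, pf = 0.02, sigma = 0.9,
                         h = c(list(Na = 1.0, K = 0.8, Cl = 2.5, HCO3 = 0.5,
                                    NH4 = 2, urea = 0.25, glucose = 0.1,
                                    HPO4 = 0.1, H2PO4 = 0.1, HCO2 = 0.1,
                                    H2CO2 = 0.1),
                               list(CO2 = 300, NH3 = 15, H2CO3 = 10,
                                    H = 100)))
  CNT <- seg_cfg("CNT", length_cm = 0.20, radius_cm = 0.0011, n_grid = 6,
                 cells = cnt_cells, junction = cd_junction,
                 basement = .basement(), coalesce = "cnt", depth = c(0, 0))

  cd_principal <- function(enac, pf_ap, nka, hk_ap) cell_cfg(
    tag = "P", frac = 0.7, imp_mM = 60, z_imp = -1, volume_nl_per_cm = 60,
    apical = mem_cfg(
      area_factor = 3, pf = pf_ap,
      h = c(list(Na = 0.003, K = hk_ap, Cl = 0.02, HCO3 = 0.003, NH4 = 0.06,
                 HPO4 = 0.002, H2PO4 = 0.003, HCO2 = 0.02, H2CO2 = 10,
                 urea = 0.025, glucose = 0.002), .h_gas),
      transporters = list(tr_channel("ENaC", "Na", enac),
                          tr_coupled("NHE", list(Na = 1, H = -1), 60),
                          tr_coupled("NaPi", list(Na = 2, HPO4 = 1), 2))),
    basolateral = mem_cfg(
      area_factor = 8, pf = pf_ap,
      h = c(list(Na = 0.005, K = 0.7, Cl = 0.6, HCO3 = 0.04, NH4 = 0.04,
                 HPO4 = 0.003, H2PO4 = 0.005, HCO2 = 0.04, H2CO2 = 10,
                 urea = 0.03, glucose = 0.3), .h_gas),
      transporters = list(tr_nka(nka, k_na = 6),
                          tr_coupled("KCC", list(K = 1, Cl = 1), 450))))
  cd_intercalated <- function(hka) cell_cfg(
    tag = "IC", frac = 0.3, imp_mM = 60, z_imp = -1, volume_nl_per_cm = 30,
    apical = mem_cfg(
      area_factor = 3, pf = 0.001,
      h = c(list(Na = 0.002, K = 0.08, Cl = 0.02, HCO3 = 0.002, NH4 = 0.05,
                 HPO4 = 0.02, H2PO4 = 0.03, HCO2 = 0.03, H2CO2 = 10,
                 urea = 0.02, glucose = 0.005), .h_gas),
      transporters = list(tr_hka(hka))),
    basolateral = mem_cfg(
      area_factor = 6, pf = 0.001,
      h = c(list(Na = 0.01, K = 1.2, Cl = 1.2, HCO3 = 1.0, NH4 = 0.08,
                 HPO4 = 0.03, H2PO4 = 0.05, HCO2 = 0.05, H2CO2 = 10,
                 urea = 0.03, glucose = 0.3), .h_gas),
      transporters = list(tr_nka(6000),
                          tr_coupled("KCC", list(K = 1, Cl = 1), 150))))

  CCD <- seg_cfg("CCD", length_cm = 0.20, radius_cm = 0.0012, n_grid = 5,
                 cells = list(cd_principal(4.2, 0.08, 85000, 0.05),
                              cd_intercalated(6000)),
                 junction = cd_junction, basement = .basement(),
                 depth = c(0, 0))
  OMCD <- seg_cfg("OMCD", length_cm = 0.20, radius_cm = 0.0012, n_grid = 5,
                  cells = list(cd_principal(2.7, 0.07, 65000, 0.04),
                               cd_intercalated(30000)),
                  junction = cd_junction, basement = .basement(),
                  depth = c(0, 0.2))

  imcd_cells <- list(cell_cfg(
    tag = "IMCD", imp_mM = 60, z_imp = -1, volume_nl_per_cm = 50,
    apical = mem_cfg(
      area_factor = 3, pf = 0.12,
      h = c(list(Na = 1.6, K = 0.05, Cl = 0.03, HCO3 = 0.004, NH4 = 0.1,
                 HPO4 = 0.002, H2PO4 = 0.004, HCO2 = 0.02, H2CO2 = 10,
                 urea = 6, glucose = 0.002), .h_gas),
      transporters = list(tr_hka(30000),
                          tr_coupled("NHE", list(Na = 1, H = -1), 80))),
    basolateral = mem_cfg(
      area_factor = 8, pf = 0.12,
      h = c(list(Na = 0.006, K = 1.2, Cl = 0.8, HCO3 = 0.4, NH4 = 0.05,
                 HPO4 = 0.003, H2PO4 = 0.005, HCO2 = 0.03, H2CO2 = 10,
                 urea = 6, glucose = 0.3), .h_gas),
      transporters = list(tr_nka(48000, k_na = 6),
                          tr_coupled("KCC", list(K = 1, Cl = 1), 400),
                          tr_coupled("NKCC", list(Na = 1, K = 1, Cl = 2),
                                     120)))))
  imcd_junction <- mem_cfg(area_factor = 0.2, pf = 0.02, sigma = 0.9,
                           h = c(list(Na = 1.2, K = 1.0, Cl = 3, HCO3 = 0.5,
                                      NH4 = 2.5, urea = 2, glucose = 0.1,
                                      HPO4 = 0.1, H2PO4 = 0.1, HCO2 = 0.1,
                                      H2CO2 = 0.1),
                                 list(CO2 = 300, NH3 = 15, H2CO3 = 10,
                                      H = 100)))
  IMCD <- seg_cfg("IMCD", length_cm = 0.50, radius_cm = 0.0013, n_grid = 8,
                  cells = imcd_cells, junction = imcd_junction,
                  basement = .basement(), coalesce = "imcd",
                  depth = c(0.2, 0.7))

  list(
    meta = list(label = "rat_male", species = "rat", sex = "male",
                provenance = "transcribed"),
    chemistry = list(pK = list(phosphate = 6.80, ammonium = 9.15,
                               formate = 3.76, carbonic = 3.57),
                     kh_per_min = 0.039 * 60, kd_per_min = 13.2 * 60),
    global = list(
      nephrons = 36000,
      sngfr_sf = 30.0,
      jm_sngfr_ratio = 1.45,
      class_weights = list(SF = 2 / 3, JM1 = 0.4 / 3, JM2 = 0.3 / 3,
                           JM3 = 0.15 / 3, JM4 = 0.1 / 3, JM5 = 0.05 / 3),
      loop_depths_mm = list(JM1 = 1, JM2 = 2, JM3 = 3, JM4 = 4, JM5 = 5),
      inlet_pressure = 10.0,
      viscosity = 8.75e-8,
      cd_tubes_per_nephron = 0.182,
      plasma = list(Na = 144, K = 5.0, pH = 7.40, totCO2 = 25.5,
                    totP = 1.3, totN = 0.2, totF = 1.0, urea = 5.0,
                    glucose = 5.0, protein_mM = 1.2)),
    interstitium = list(
      pressure = 4.0,
      om_depth_cm = 0.2,
      total_depth_cm = 0.7,
      # multipliers of the cortical (plasma-derived) value at the
      # cortico-medullary boundary, OM-IM boundary, and papillary tip
      na_mult = c(1, 1.6, 1.95),
      k_mult = c(1, 2.0, 1.6),
      urea = c(5, 40, 450),
      totN = c(0.2, 2.0, 4.0),
      protein_mM = 0.1),
    torque = list(mu_pt = 0.020, p0 = 10.0, l_mv_cm = 2.5e-4,
                  delta_mv_cm = 1.5e-5, s = 0.6, floor = 0),
    solver = list(jscale = 1000, vscale = 100, escale = 100, h_floor = 0.01),
    segments = list(PCT = PCT, S3 = S3, SDL = SDL, LDL = LDL, LAL = LAL,
                    mTAL = mTAL, cTAL = cTAL, DCTe = DCTe, DCTl = DCTl,
                    CNT = CNT, CCD = CCD, OMCD = OMCD, IMCD = IMCD))
}
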