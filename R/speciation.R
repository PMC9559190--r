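# Luminal speciation. The axial march carries the conserved luminal
# quantities: the five non-reacting solutes plus the phosphate, ammonia and
# formate buffer totals. The CO2 system is open: luminal pCO2 is clamped to
# the local interstitial value, H2CO3 sits at hydration equilibrium with
# it, and HCO3- follows the open-system equilibrium HCO3- = K * H2CO3 / H+.
# Luminal pH is then fixed by electroneutrality; its consistency with the
# transmembrane fluxes is guaranteed by the zero-current closure of each
# cross-section (charge is marched implicitly).

.CARRIED <- c("Na", "K", "Cl", "urea", "glucose", "totP", "totN", "totF")
.NCAR <- length(.CARRIED)

# 8 x 16 map from per-species fluxes to carried-quantity fluxes
.carried_map <- local({
  M <- matrix(0, .NCAR, 16L, dimnames = list(.CARRIED, .SNAME))
  M["Na", "Na"] <- 1; M["K", "K"] <- 1; M["Cl", "Cl"] <- 1
  M["urea", "urea"] <- 1; M["glucose", "glucose"] <- 1
  M["totP", c("HPO4", "H2PO4")] <- 1
  M["totN", c("NH3", "NH4")] <- 1
  M["totF", c("HCO2", "H2CO2")] <- 1
  M
})

species_to_carried <- function(c16) {
  as.numeric(.carried_map %*% c16)
}

# Split carried totals into the 15 species + pH by luminal
# electroneutrality. tot: named length-8 vector of concentrations (mM);
# co2: clamped luminal CO2 (mM). target_charge allows a non-zero
# fixed-charge offset (unused for the lumen).
lumen_species <- function(tot, chem = chemistry_constants(), co2 = 1.2,
                          target_charge = 0) {
  if (any(!is.finite(tot)) || any(tot[c("Na", "K", "Cl", "totP", "totN",
                                        "totF")] <= 0))
    stop("lumen_species: non-positive carried concentration", call. = FALSE)
  ka <- .ka_mM(chem$pairs$pK)
  names(ka) <- chem$pairs$acid          # H2PO4, NH4, H2CO2, H2CO3
  keq <- chem$kh / chem$kd              # H2CO3 / CO2 at equilibrium
  h2co3 <- keq * co2
  kHco3 <- ka[["H2CO3"]] * h2co3        # HCO3- = kHco3 / H

  charge <- function(H) {
    nh4  <- tot[["totN"]] * H / (H + ka[["NH4"]])
    hpo4 <- tot[["totP"]] * ka[["H2PO4"]] / (H + ka[["H2PO4"]])
    h2po4 <- tot[["totP"]] - hpo4
    hco2 <- tot[["totF"]] * ka[["H2CO2"]] / (H + ka[["H2CO2"]])
    tot[["Na"]] + tot[["K"]] + H + nh4 -
      tot[["Cl"]] - kHco3 / H - 2 * hpo4 - h2po4 - hco2 - target_charge
  }
  # charge is strictly increasing in H: bracket on pH 14 .. 2.0
  lo <- 1e-11; hi <- 10^-2 * 1e3
  flo <- charge(lo); fhi <- charge(hi)
  if (flo > 0 || fhi < 0)
    stop("lumen_species: electroneutral pH outside [2, 14]", call. = FALSE)
  H <- stats::uniroot(charge, c(lo, hi), f.lower = flo, f.upper = fhi,
                      tol = 1e-16)$root

  c16 <- numeric(16L)
  names(c16) <- .SNAME
  c16["Na"] <- tot[["Na"]]; c16["K"] <- tot[["K"]]; c16["Cl"] <- tot[["Cl"]]
  c16["urea"] <- tot[["urea"]]; c16["glucose"] <- tot[["glucose"]]
  c16["H"] <- H
  c16["HPO4"] <- tot[["totP"]] * ka[["H2PO4"]] / (H + ka[["H2PO4"]])
  c16["H2PO4"] <- tot[["totP"]] - c16[["HPO4"]]
  c16["NH4"] <- tot[["totN"]] * H / (H + ka[["NH4"]])
  c16["NH3"] <- tot[["totN"]] - c16[["NH4"]]
  c16["HCO2"] <- tot[["totF"]] * ka[["H2CO2"]] / (H + ka[["H2CO2"]])
  c16["H2CO2"] <- tot[["totF"]] - c16[["HCO2"]]
  c16["CO2"] <- co2
  c16["H2CO3"] <- h2co3
  c16["HCO3"] <- kHco3 / H
  list(c16 = c16, pH = -log10(H * 1e-3))
}

# Build an equilibrated 16-species composition from a compact description:
# major ions + pH + totals; Cl- adjusted to satisfy electroneutrality with
# the stated impermeant charge. Used for plasma, filtrate and interstitium.
compose_fluid <- function(na, k, ph, totCO2, totP, totN, totF, urea, glucose,
                          imp = 0, z_imp = 0, chem = chemistry_constants()) {
  ka <- .ka_mM(chem$pairs$pK)
  names(ka) <- chem$pairs$acid
  H <- 10^(-ph) * 1e3
  keq <- chem$kh / chem$kd                  # H2CO3 / CO2 at equilibrium
  c16 <- numeric(16L); names(c16) <- .SNAME
  c16["Na"] <- na; c16["K"] <- k; c16["H"] <- H
  c16["urea"] <- urea; c16["glucose"] <- glucose
  c16["HPO4"] <- totP * ka[["H2PO4"]] / (H + ka[["H2PO4"]])
  c16["H2PO4"] <- totP - c16[["HPO4"]]
  c16["NH4"] <- totN * H / (H + ka[["NH4"]])
  c16["NH3"] <- totN - c16[["NH4"]]
  c16["HCO2"] <- totF * ka[["H2CO2"]] / (H + ka[["H2CO2"]])
  c16["H2CO2"] <- totF - c16[["HCO2"]]
  # CO2 system fully equilibrated: totCO2 = CO2 + H2CO3 + HCO3
  denom <- 1 + keq * (1 + ka[["H2CO3"]] / H)
  c16["CO2"] <- totCO2 / denom
  c16["H2CO3"] <- c16[["CO2"]] * keq
  c16["HCO3"] <- totCO2 - c16[["CO2"]] - c16[["H2CO3"]]
  c16["X"] <- imp
  # Cl- closes electroneutrality
  z <- .Z16; z[.IX] <- z_imp
  c16["Cl"] <- 0
  c16["Cl"] <- sum(z * c16)
  if (c16[["Cl"]] <= 0)
    stop("compose_fluid: electroneutral Cl- is non-positive", call. = FALSE)
  c16
}
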