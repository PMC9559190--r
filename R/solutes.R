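# Solute set, physical constants, and acid-base chemistry.
#
# The model carries 15 solutes. Internally every compartment concentration
# vector has a 16th slot, "X", holding the impermeant species of that
# compartment (cytosolic impermeant anions, interstitial protein). "X" never
# crosses a membrane; it contributes to osmolality and charge only.

#' Solute table
#'
#' The 15 solutes carried by the model, with display names, integer valences
#' and a flag marking members of an acid-base pair or of the CO2 hydration
#' system.
#'
#' @return A data.frame with columns `name`, `display`, `z`, `reacting`.
#' @export
#' @examples
#' solute_table()
solute_table <- function() .SOLUTES

#' Physical constants
#'
#' Ideal gas constant, body temperature and Faraday's constant, together with
#' the derived factors used by the flux kernels: `rt_mmhg`, the osmotic
#' pressure of a 1 mM concentration difference (mmHg/mM), and `rt_f_mv`,
#' RT/F in millivolts.
#'
#' @param T_K Thermodynamic temperature in kelvin (default rodent body
#'   temperature).
#' @return Named list with elements `R`, `T`, `F`, `rt_mmhg`, `rt_f_mv`.
#' @export
physical_constants <- function(T_K = 310.15) {
  stopifnot(T_K > 0)
  R <- 8.314462618   # J mol-1 K-1
  F <- 96485.33212   # C mol-1
  rt <- R * T_K      # J mol-1 == Pa per (mol m-3) == Pa per mM
  list(R = R, T = T_K, F = F,
       rt_mmhg = rt / 133.322368,   # mmHg per mM
       rt_f_mv = 1000 * rt / F)     # mV
}

#' Acid-base buffer pairs
#'
#' The three acid-base pairs plus the carbonic acid member of the CO2 system.
#' `pK` is the negative log10 dissociation constant on the mol/L scale;
#' `kinetic` marks the pair whose interconversion with CO2 is finite-rate
#' (CO2 hydration) rather than instantaneous.
#'
#' @return data.frame with columns `acid`, `base`, `pK`, `kinetic`.
#' @export
buffer_pairs <- function() {
  data.frame(
    acid    = c("H2PO4", "NH4", "H2CO2", "H2CO3"),
    base    = c("HPO4", "NH3", "HCO2", "HCO3"),
    pK      = c(6.80, 9.15, 3.76, 3.57),
    kinetic = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Default chemistry constants
#'
#' Buffer pK values and CO2 hydration/dehydration rate constants. The rates
#' are uncatalyzed values (per minute); compartments with carbonic anhydrase
#' scale both by a catalysis factor, which preserves the equilibrium constant.
#' `kh/kd` together with the H2CO3 pK of 3.57 gives an apparent CO2/HCO3- pK
#' of 6.1.
#'
#' @return list with `pairs` (see [buffer_pairs()]), `kh`, `kd` (min^-1).
#' @export
chemistry_constants <- function() {
  list(pairs = buffer_pairs(),
       kh = 0.039 * 60,     # CO2 + H2O -> H2CO3
       kd = 13.2 * 60)      # H2CO3 -> CO2 + H2O
}

# dissociation constants on the mM scale (acid <-> base + H+)
.ka_mM <- function(pK) 10^(-pK) * 1e3

#' Deviation of buffer pairs from mass-action equilibrium
#'
#' For each acid-base pair, returns `log10(base/acid) - (pH - pK)`, which is
#' zero exactly at mass-action equilibrium. Used both as a solver residual
#' building block and as a diagnostic.
#'
#' @param state Named numeric vector of concentrations (mM) for one
#'   compartment; must contain `H` and every acid/base species referenced by
#'   `pairs`.
#' @param pairs data.frame as returned by [buffer_pairs()]; rows with
#'   `kinetic = TRUE` are evaluated the same way (the finite-rate treatment
#'   of CO2 hydration lives in the conservation equations, not here).
#' @param compartment Label used in error messages.
#' @return Named numeric vector of per-pair residuals (log10 units).
#' @export
#' @examples
#' st <- c(H = 10^-7.4 * 1e3, HPO4 = 0.8, H2PO4 = 0.2,
#'         NH3 = 0.01, NH4 = 0.2, HCO2 = 1, H2CO2 = 1e-4,
#'         HCO3 = 24, H2CO3 = 24 * 10^(3.57 - 7.4))
#' buffer_residuals(st, buffer_pairs())
buffer_residuals <- function(state, pairs = buffer_pairs(),
                             compartment = "compartment") {
  need <- unique(c("H", pairs$acid, pairs$base))
  for (s in need) {
    v <- state[[s]]
    if (is.null(v) || !is.finite(v) || v <= 0) {
      stop(sprintf("non-positive concentration for %s in %s", s, compartment),
           call. = FALSE)
    }
  }
  pH <- -log10(state[["H"]] * 1e-3)
  res <- log10(state[pairs$base] / state[pairs$acid]) - (pH - pairs$pK)
  names(res) <- paste0(pairs$base, "/", pairs$acid)
  res
}
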