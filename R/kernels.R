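# Transmembrane flux kernels.
#
# Sign convention: every kernel computes flux from compartment a to
# compartment b, positive a -> b. Swapping the two compartments (and the
# signs of the driving differences) negates every passive flux.
#
# Internal units: concentration mM, potential mV, pressure mmHg, length cm,
# time min, volume nL, amount pmol. Water flux is nL min-1 cm-2 of membrane,
# solute flux pmol min-1 cm-2. With these choices a permeability expressed
# in nL min-1 cm-2 multiplied by a concentration in mM (= pmol/nL) gives a
# solute flux directly; the loader converts cm/s permeabilities by the
# factor 6e7.

#' Transmembrane water flux
#'
#' Osmotic plus hydrostatic volume flux across a membrane,
#' `J_v = A * Lp * (RT * sum(sigma_k * dC_k) + dP)`.
#'
#' @param area Membrane area (cm2 per cm of tubule, or absolute).
#' @param lp Hydraulic permeability, nL min-1 cm-2 mmHg-1.
#' @param sigma Reflection coefficient(s), recycled across solutes.
#' @param dC Per-solute concentration difference C_b - C_a (mM); water flows
#'   a -> b when the far side is more concentrated.
#' @param dP Hydrostatic pressure difference P_a - P_b (mmHg).
#' @param constants See [physical_constants()].
#' @return Volume flux, positive a -> b (nL/min if `area` includes length).
#' @export
#' @examples
#' water_flux(1, 1, 1, dC = 1, dP = 0)  # RT in mmHg times 1 mM
water_flux <- function(area, lp, sigma, dC, dP, constants = physical_constants()) {
  area * lp * (constants$rt_mmhg * sum(sigma * dC) + dP)
}

#' Logarithmic mean membrane concentration
#'
#' `(C_a - C_b) / (ln C_a - ln C_b)`, continuous at `C_a == C_b` where it
#' equals the common value. Vectorized.
#'
#' @param ca,cb Strictly positive concentrations (mM).
#' @return The log-mean, bounded by min and max of the inputs.
#' @export
#' @examples
#' log_mean_conc(100, 50)   # 50 / log(2)
log_mean_conc <- function(ca, cb) {
  if (any(!is.finite(ca)) || any(!is.finite(cb)) || any(ca <= 0) || any(cb <= 0))
    stop("log_mean_conc: concentrations must be positive and finite", call. = FALSE)
  r <- ca / cb
  out <- cb * (r - 1) / log(r)
  near <- abs(r - 1) < 1e-9
  if (any(near)) out[near] <- (ca[near] + cb[near]) / 2
  out
}

#' Electrodiffusive solute flux
#'
#' Goldman-Hodgkin-Katz constant-field flux for charged solutes,
#' `h * zeta * (C_a - C_b * exp(-zeta)) / (1 - exp(-zeta))` with
#' `zeta = z F dV / RT`; plain Fickian diffusion `h * (C_a - C_b)` for
#' uncharged solutes. The removable singularity at `zeta -> 0` is handled by
#' a series expansion, so the GHK branch converges to the Fick branch.
#' Vectorized over solutes.
#'
#' @param h Membrane permeability (nL min-1 cm-2; see [PERM_CM_S]).
#' @param z Integer valence(s).
#' @param ca,cb Concentrations on side a and b (mM).
#' @param dv Potential difference V_a - V_b (mV).
#' @param constants See [physical_constants()].
#' @return Solute flux, pmol min-1 cm-2, positive a -> b.
#' @export
electrodiffusive_flux <- function(h, z, ca, cb, dv, constants = physical_constants()) {
  zeta <- z * dv / constants$rt_f_mv
  out <- h * (ca - cb)                     # z == 0 or zeta ~ 0 limit
  act <- which(z != 0 & abs(zeta) >= 1e-4)
  if (length(act)) {
    zz <- zeta[act]
    em <- exp(-zz)
    out[act] <- h[act] * zz * (ca[act] - cb[act] * em) / (1 - em)
  }
  sm <- which(z != 0 & abs(zeta) < 1e-4)
  if (length(sm)) {
    zz <- zeta[sm]
    out[sm] <- h[sm] * ((ca[sm] - cb[sm]) + zz * (ca[sm] + cb[sm]) / 2 +
                          zz^2 * (ca[sm] - cb[sm]) / 12)
  }
  out
}

#' Convective (solvent drag) solute flux
#'
#' First term of the total flux decomposition: `(1 - sigma_k) * Cbar * J_v`.
#'
#' @param sigma_k Solute reflection coefficient(s) in `[0, 1]`.
#' @param cbar Mean membrane concentration, usually [log_mean_conc()] (mM).
#' @param jv Volume flux across the same membrane (nL min-1 cm-2).
#' @return Solute flux, pmol min-1 cm-2.
#' @export
convective_flux <- function(sigma_k, cbar, jv) {
  if (any(sigma_k < 0 | sigma_k > 1))
    stop("convective_flux: sigma_k must lie in [0, 1]", call. = FALSE)
  (1 - sigma_k) * cbar * jv
}

#' Coupled transport across a cotransporter or exchanger
#'
#' Linear nonequilibrium-thermodynamic form: the cycle flux is the activity
#' times the stoichiometry-weighted sum of electrochemical potential
#' differences (in RT units), and each participating solute moves in strict
#' proportion to its stoichiometric coefficient. Optionally a saturable
#' Michaelis factor multiplies the cycle flux (used for NHE3 and NKCC2/NCC
#' variants).
#'
#' @param transporter List with `kind = "coupled"`, named numeric `stoich`
#'   (positive = moves a -> b per forward cycle), `activity`
#'   (pmol min-1 cm-2), and optional `km` (named list of half-saturation
#'   constants applied to the cis-side driving concentration).
#' @param ca,cb Named concentration vectors for sides a and b (mM).
#' @param va,vb Potentials (mV).
#' @param z Named valence vector for the participating solutes.
#' @param constants See [physical_constants()].
#' @return Named per-solute flux vector (pmol min-1 cm-2), positive a -> b.
#' @export
#' @examples
#' nkcc2 <- list(name = "NKCC2", kind = "coupled", activity = 100,
#'               stoich = c(Na = 1, K = 1, Cl = 2))
#' z <- c(Na = 1, K = 1, Cl = -1)
#' ca <- c(Na = 140, K = 5, Cl = 110); cb <- c(Na = 15, K = 140, Cl = 20)
#' coupled_flux(nkcc2, ca, cb, 0, -60, z)
coupled_flux <- function(transporter, ca, cb, va, vb, z,
                         constants = physical_constants()) {
  if (!identical(transporter$kind, "coupled"))
    stop("coupled_flux: transporter kind must be 'coupled'", call. = FALSE)
  s <- transporter$stoich
  k <- names(s)
  dmu <- log(ca[k] / cb[k]) + z[k] * (va - vb) / constants$rt_f_mv
  j <- transporter$activity * sum(s * dmu)
  if (!is.null(transporter$km)) {
    for (sol in names(transporter$km)) {
      cc <- if (s[[sol]] > 0) ca[[sol]] else cb[[sol]]
      j <- j * cc / (cc + transporter$km[[sol]])
    }
  }
  out <- s * j
  names(out) <- k
  out
}

#' Primary active transport across an ATPase
#'
#' Saturable Hill-type pump rate. The cycle flux is
#' `activity * prod_i (C_i / (C_i + K_i))^(n_i)` over the driving sites, and
#' per-solute fluxes follow the pump stoichiometry exactly (e.g. 3 Na+ out :
#' 2 K+ in for the Na+-K+-ATPase). Monotone nondecreasing in each driving
#' concentration and bounded by `activity`.
#'
#' @param transporter List with `kind = "atpase"`, named `stoich` (positive =
#'   a -> b per cycle), `activity`, and `sites`: a list of driving sites,
#'   each `list(solute =, side = "a"|"b", K =, n =)`. Optional `k_na_mod`:
#'   when present, the `K` of the site named `Na` is multiplied by
#'   `(1 + C_K_b / k_na_mod)`, the external-K+ modulation of Na+ affinity
#'   used for the Na+-K+-ATPase.
#' @param ca,cb Named concentration vectors (mM).
#' @return Named per-solute flux vector, positive a -> b.
#' @export
atpase_flux <- function(transporter, ca, cb) {
  if (!identical(transporter$kind, "atpase"))
    stop("atpase_flux: transporter kind must be 'atpase'", call. = FALSE)
  rate <- transporter$activity
  for (site in transporter$sites) {
    cc <- if (identical(site$side, "a")) ca[[site$solute]] else cb[[site$solute]]
    if (!is.finite(cc) || cc < 0)
      stop(sprintf("atpase_flux: negative concentration for %s", site$solute),
           call. = FALSE)
    K <- site$K
    if (identical(site$solute, "Na") && !is.null(transporter$k_na_mod))
      K <- K * (1 + cb[["K"]] / transporter$k_na_mod)
    rate <- rate * (cc / (cc + K))^site$n
  }
  out <- transporter$stoich * rate
  names(out) <- names(transporter$stoich)
  out
}

#' Compliant proximal tubule radius
#'
#' `r = r0 * (1 + mu * (P - P0))`: linear pressure-radius relation used only
#' along the proximal tubule.
#'
#' @param r0 Reference radius (cm).
#' @param mu_pt Compliance (mmHg-1); zero gives a rigid tubule.
#' @param p Luminal pressure (mmHg).
#' @param p0 Reference pressure (mmHg).
#' @return Radius (cm).
#' @export
compliant_radius <- function(r0, mu_pt, p, p0) {
  r <- r0 * (1 + mu_pt * (p - p0))
  if (any(r <= 0))
    stop("compliant_radius: computed radius is non-positive (pressure outside physical range)",
         call. = FALSE)
  r
}

#' Microvillous torque
#'
#' Hydrodynamic torque on proximal tubule microvilli:
#' `tau = 8 mu Q l_mv / r^2 * (1 + (l_mv + delta_mv)/r + l_mv^2/(2 r^2))`.
#' Linear in flow, strictly decreasing in radius.
#'
#' @param q Luminal volume flow (cm3/min).
#' @param r Luminal radius (cm).
#' @param l_mv Microvillous length (cm).
#' @param delta_mv Height above the microvillous tip where drag acts (cm).
#' @param visc Luminal fluid viscosity (mmHg min).
#' @return Torque (arbitrary consistent units; only ratios are used).
#' @export
microvillous_torque <- function(q, r, l_mv, delta_mv, visc) {
  if (any(r <= 0)) stop("microvillous_torque: radius must be positive", call. = FALSE)
  8 * visc * q * l_mv / r^2 * (1 + (l_mv + delta_mv) / r + l_mv^2 / (2 * r^2))
}

#' Torque scaling of proximal transport
#'
#' `S_torq = 1 + s * (tau/tau0 - 1)`, clamped below at `floor` (default 0:
#' transport never reverses sign from torque feedback alone). Luminal-side
#' water and solute fluxes in proximal segments are multiplied by this
#' factor.
#'
#' @param tau Current torque.
#' @param tau0 Reference torque (> 0), computed at the segment's reference
#'   inflow and radius.
#' @param s Dimensionless scaling factor; zero disables torque feedback.
#' @param floor Lower clamp, >= 0.
#' @return Scale factor.
#' @export
torque_scale <- function(tau, tau0, s, floor = 0) {
  if (!is.finite(tau0) || tau0 <= 0)
    stop("torque_scale: reference torque must be positive", call. = FALSE)
  pmax(floor, 1 + s * (tau / tau0 - 1))
}

#' Total transmembrane solute flux with mechanism breakdown
#'
#' Sum of the four transport mechanisms for one solute across one membrane:
#' convection, electrodiffusion, coupled transport and ATP-driven transport.
#' This is the single-solute diagnostic form; the solver assembles the same
#' sum for all solutes at once.
#'
#' @param solute Solute name (row of [solute_table()]).
#' @param h Passive permeability for this solute.
#' @param sigma_k Reflection coefficient for this solute.
#' @param ca,cb Named concentration vectors for the two sides (mM).
#' @param va,vb Potentials (mV).
#' @param jv Volume flux across the membrane.
#' @param transporters List of transporter specs attached to the membrane.
#' @param constants See [physical_constants()].
#' @return List with `total` and the four components.
#' @export
total_solute_flux <- function(solute, h, sigma_k, ca, cb, va, vb, jv,
                              transporters = list(),
                              constants = physical_constants()) {
  tab <- solute_table()
  z_all <- stats::setNames(tab$z, tab$name)
  z <- z_all[[solute]]
  conv <- convective_flux(sigma_k, log_mean_conc(ca[[solute]], cb[[solute]]), jv)
  elec <- electrodiffusive_flux(h, z, ca[[solute]], cb[[solute]], va - vb, constants)
  coup <- 0; pump <- 0
  for (tr in transporters) {
    if (!solute %in% names(tr$stoich)) next
    if (identical(tr$kind, "coupled")) {
      coup <- coup + coupled_flux(tr, ca, cb, va, vb, z_all, constants)[[solute]]
    } else if (identical(tr$kind, "atpase")) {
      pump <- pump + atpase_flux(tr, ca, cb)[[solute]]
    }
  }
  list(total = conv + elec + coup + pump,
       convective = conv, electrodiffusive = elec,
       coupled = coup, atpase = pump)
}
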