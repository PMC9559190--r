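# Whole-membrane flux assembly used in the solver hot path.
#
# A membrane spec is a plain list:
#   area   : cm2 per cm tubule (cell-type area fraction already folded in)
#   lp     : nL min-1 cm-2 mmHg-1
#   sigma  : length-16 reflection coefficients (impermeant slot = 1)
#   h      : length-16 passive permeabilities (nL min-1 cm-2)
#   transporters : list of coupled/atpase specs (see kernels.R)
#
# membrane_flux() evaluates every mechanism for all 16 species at once and
# returns per-cm2 fluxes, positive in the membrane's a -> b orientation.

new_membrane <- function(area, lp = 0, sigma = 1, h = NULL,
                         transporters = list()) {
  hh <- numeric(16L)
  if (!is.null(h)) {
    idx <- match(names(h), .SNAME)
    if (anyNA(idx)) stop("unknown solute in membrane h: ",
                         paste(names(h)[is.na(idx)], collapse = ", "))
    hh[idx] <- as.numeric(h)
  }
  sg <- rep_len(as.numeric(sigma), 16L)
  sg[.IX] <- 1
  list(area = area, lp = lp, sigma = sg, h = hh, transporters = transporters)
}

# ca/cb: length-16 concentrations; za/zb: impermeant valences of the two
# sides (only used through the precomputed z vector argument).
# Returns list(jv, js) with js a length-16 vector (pmol min-1 cm-2).
membrane_flux <- function(mem, ca, cb, va, vb, pa, pb, z16 = .Z16,
                          constants = .CONST, breakdown = FALSE) {
  jv <- mem$lp * (constants$rt_mmhg * sum(mem$sigma * (cb - ca)) + (pa - pb))

  # electrodiffusive / Fickian (index sets precomputed at compile time;
  # fall back to full scan for hand-built membranes)
  ghk <- mem$ix_ghk %||% which(mem$h > 0 & z16 != 0)
  elec <- mem$h * (ca - cb)
  if (length(ghk)) {
    zz <- z16[ghk] * (va - vb) / constants$rt_f_mv
    big <- abs(zz) >= 1e-4
    if (any(big)) {
      i <- ghk[big]; z2 <- zz[big]
      em <- exp(-z2)
      elec[i] <- mem$h[i] * z2 * (ca[i] - cb[i] * em) / (1 - em)
    }
    if (!all(big)) {
      i <- ghk[!big]; z2 <- zz[!big]
      elec[i] <- mem$h[i] * ((ca[i] - cb[i]) + z2 * (ca[i] + cb[i]) / 2 +
                               z2^2 * (ca[i] - cb[i]) / 12)
    }
  }

  # convection (solvent drag); skipped for fully reflected species
  conv <- numeric(16L)
  if (jv != 0) {
    drag <- mem$ix_drag %||% which(mem$sigma < 1)
    if (length(drag)) {
      cda <- ca[drag]; cdb <- cb[drag]
      r <- cda / cdb
      cbar <- cdb * (r - 1) / log(r)
      near <- abs(r - 1) < 1e-9
      if (any(near)) cbar[near] <- (cda[near] + cdb[near]) / 2
      conv[drag] <- (1 - mem$sigma[drag]) * cbar * jv
    }
  }

  coup <- numeric(16L); pump <- numeric(16L)
  for (tr in mem$transporters) {
    ix <- tr$ix                       # precomputed integer indices of stoich
    if (identical(tr$kind, "mm")) {
      # saturable reversible carrier: fwd/rev occupancy products over the
      # participating solutes (normalized by reference concentrations, so
      # the Haldane condition holds and flux vanishes exactly at coupled
      # equilibrium); bounded by the activity
      ca_n <- ca[ix] / tr$cref
      cb_n <- cb[ix] / tr$cref
      spos <- tr$stoich > 0
      fwd <- prod(ca_n[spos]^tr$stoich[spos]) *
        prod(cb_n[!spos]^(-tr$stoich[!spos]))
      rev <- prod(cb_n[spos]^tr$stoich[spos]) *
        prod(ca_n[!spos]^(-tr$stoich[!spos]))
      j <- tr$activity * (fwd - rev) / (1 + fwd + rev)
      coup[ix] <- coup[ix] + tr$stoich * j
    } else if (identical(tr$kind, "coupled")) {
      dmu <- log(ca[ix] / cb[ix]) + z16[ix] * (va - vb) / constants$rt_f_mv
      j <- tr$activity * sum(tr$stoich * dmu)
      if (!is.null(tr$km)) {
        for (i in seq_along(tr$km_ix)) {
          cc <- if (tr$stoich[tr$km_side[i]] > 0) ca[tr$km_ix[i]] else cb[tr$km_ix[i]]
          j <- j * cc / (cc + tr$km[[i]])
        }
      }
      coup[ix] <- coup[ix] + tr$stoich * j
    } else {                          # atpase
      rate <- tr$activity
      for (site in tr$sites) {
        cc <- if (site$side_a) ca[site$ix] else cb[site$ix]
        K <- site$K
        if (site$na_mod > 0) K <- K * (1 + cb[.I$K] / site$na_mod)
        rate <- rate * (cc / (cc + K))^site$n
      }
      pump[ix] <- pump[ix] + tr$stoich * rate
    }
  }

  js <- conv + elec + coup + pump
  if (breakdown)
    list(jv = jv, js = js, convective = conv, electrodiffusive = elec,
         coupled = coup, atpase = pump)
  else list(jv = jv, js = js)
}

# Precompile a transporter spec: resolve solute names to integer indices so
# the hot path never does name matching.
.CREF <- c(Na = 140, K = 5, Cl = 110, HCO3 = 24, H2CO3 = 0.004, CO2 = 1.2,
           NH3 = 0.003, NH4 = 0.3, HPO4 = 1, H2PO4 = 0.3, H = 4e-5,
           HCO2 = 1, H2CO2 = 3e-4, urea = 5, glucose = 5, X = 1)

compile_transporter <- function(tr) {
  ix <- match(names(tr$stoich), .SNAME)
  if (anyNA(ix)) stop("unknown solute in transporter ", tr$name)
  tr$ix <- ix
  if (identical(tr$kind, "mm")) {
    cref <- .CREF[names(tr$stoich)]
    if (!is.null(tr$cref)) {
      ov <- unlist(tr$cref)
      cref[names(ov)] <- ov
    }
    tr$cref <- unname(cref)
  }
  tr$stoich <- as.numeric(tr$stoich)
  if (identical(tr$kind, "coupled") && !is.null(tr$km)) {
    tr$km_ix <- match(names(tr$km), .SNAME)
    tr$km_side <- match(names(tr$km), .SNAME[ix])
    tr$km <- as.numeric(tr$km)
  }
  if (identical(tr$kind, "atpase")) {
    tr$sites <- lapply(tr$sites, function(s) {
      s$ix <- match(s$solute, .SNAME)
      s$side_a <- identical(s$side, "a")
      s$na_mod <- if (identical(s$solute, "Na") && !is.null(tr$k_na_mod))
        tr$k_na_mod else 0
      s
    })
  }
  tr
}


# Precompute the hot-path index sets once the permeability and reflection
# vectors are final.
finalize_membrane <- function(mem) {
  mem$ix_ghk <- which(mem$h > 0 & .Z16 != 0)
  mem$ix_drag <- which(mem$sigma < 1)
  mem
}
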