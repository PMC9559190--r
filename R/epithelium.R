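# Steady-state solve of one epithelial cross-section.
#
# Unknowns (packed into one vector x):
#   per cell type : 15 log concentrations, membrane potential V_c (mV),
#                   log cell volume (nL per cm tubule)
#   paracellular  : 15 log concentrations, potential V_p, pressure P_p
#   lumen         : potential V_L
# Cell volume enters through the impermeant concentration (fixed impermeant
# amount / volume); interspace pressure through the basement-membrane water
# flux. Luminal and bath compositions, pressures, and the torque scale are
# data at this level.
#
# Residuals per interior compartment: five non-reacting solute balances,
# four buffer-total balances, a free-CO2 equation (finite-rate hydration in
# cells, equilibrium in the interspace), four pair equilibria,
# electroneutrality, zero net ionic current, and volume balance. One extra
# equation imposes zero net current out of the lumen, closing V_L.

.CELL_RES <- c("Na", "K", "Cl", "urea", "glucose",
               "totP", "totN", "totF", "totCO2", "CO2",
               "eq_phos", "eq_amm", "eq_form", "eq_carb",
               "electroneutrality", "current", "volume")

ep_unknown_names <- function(spec) {
  nm <- character(0)
  for (cl in spec$cells)
    nm <- c(nm, paste0(cl$tag, ".", c(.SOLUTES$name, "V", "lnvol")))
  c(nm, paste0("P.", c(.SOLUTES$name, "V", "P")), "V_L")
}

ep_residual_names <- function(spec) {
  nm <- character(0)
  for (cl in spec$cells) nm <- c(nm, paste0(cl$tag, ".", .CELL_RES))
  c(nm, paste0("P.", .CELL_RES), "lumen_current")
}

# Unpack x into compartment states. Returns list(cells = list(c16, v, vol),
# para = list(c16, v, p)).
ep_unpack <- function(x, spec) {
  ncell <- length(spec$cells)
  cells <- vector("list", ncell)
  off <- 0L
  for (i in seq_len(ncell)) {
    cl <- spec$cells[[i]]
    cc <- exp(x[off + 1:15])
    vol <- exp(x[off + 17L])
    c16 <- c(cc, cl$imp / vol)
    cells[[i]] <- list(c16 = c16, v = x[off + 16L], vol = vol)
    off <- off + 17L
  }
  para <- list(c16 = c(exp(x[off + 1:15]), 0),
               v = x[off + 16L], p = x[off + 17L])
  list(cells = cells, para = para, v_l = x[off + 18L])
}

# The shared flux + residual evaluation. Returns the residual vector; when
# detail = TRUE also all per-membrane fluxes and the lumen outflow.
ep_eval <- function(x, spec, lumen, bath, storq = 1, detail = FALSE) {
  # reject wild trial points before they overflow the flux kernels
  if (any(!is.finite(x)) || any(abs(x) > 200))
    return(rep(Inf, length(x)))
  if (any(lumen$c16[1:15] <= 0) || any(bath$c16[1:15] <= 0))
    return(rep(Inf, length(x)))
  st <- ep_unpack(x, spec)
  chem <- spec$chem
  ka <- spec$ka                 # named: H2PO4, NH4, H2CO2, H2CO3
  keq <- chem$kh / chem$kd
  jsc <- spec$jscale; vsc <- spec$vscale; esc <- spec$escale
  cL <- lumen$c16; vL <- st$v_l; pL <- lumen$p
  cB <- bath$c16;  pB <- bath$p
  pp <- st$para

  res <- numeric(length(x))
  off <- 0L
  jv_out <- 0; js_out <- numeric(16L)
  para_in_js <- numeric(16L); para_in_jv <- 0
  detail_fl <- if (detail) list() else NULL

  for (i in seq_along(spec$cells)) {
    cl <- spec$cells[[i]]
    cc <- st$cells[[i]]
    zc <- .Z16; zc[.IX] <- cl$z_imp
    ap <- membrane_flux(cl$apical, cL, cc$c16, vL, cc$v, pL, cl$p_cell,
                        breakdown = detail)
    bl <- membrane_flux(cl$basolateral, cc$c16, cB, cc$v, 0, cl$p_cell, pB,
                        breakdown = detail)
    if (!is.null(cl$lateral)) {
      lat <- membrane_flux(cl$lateral, cc$c16, pp$c16, cc$v, pp$v,
                           cl$p_cell, pp$p, breakdown = detail)
    } else lat <- list(jv = 0, js = numeric(16L))

    influx <- storq * cl$apical$area * ap$js - cl$basolateral$area * bl$js -
      cl$lateral_area * lat$js
    jv_in <- storq * cl$apical$area * ap$jv - cl$basolateral$area * bl$jv -
      cl$lateral_area * lat$jv

    c16 <- cc$c16
    r <- numeric(17L)
    r[1:5] <- influx[c(.I$Na, .I$K, .I$Cl, .I$urea, .I$glucose)] / jsc
    r[6] <- (influx[.I$HPO4] + influx[.I$H2PO4]) / jsc
    r[7] <- (influx[.I$NH3] + influx[.I$NH4]) / jsc
    r[8] <- (influx[.I$HCO2] + influx[.I$H2CO2]) / jsc
    r[9] <- (influx[.I$HCO3] + influx[.I$H2CO3] + influx[.I$CO2]) / jsc
    r[10] <- if (cl$co2_kinetic) {
      (influx[.I$CO2] + cc$vol * cl$ca *
         (chem$kd * c16[.I$H2CO3] - chem$kh * c16[.I$CO2])) / jsc
    } else log(c16[.I$H2CO3] / (c16[.I$CO2] * keq))
    r[11] <- log(c16[.I$HPO4] * c16[.I$H] / (c16[.I$H2PO4] * ka[["H2PO4"]]))
    r[12] <- log(c16[.I$NH3] * c16[.I$H] / (c16[.I$NH4] * ka[["NH4"]]))
    r[13] <- log(c16[.I$HCO2] * c16[.I$H] / (c16[.I$H2CO2] * ka[["H2CO2"]]))
    r[14] <- log(c16[.I$HCO3] * c16[.I$H] / (c16[.I$H2CO3] * ka[["H2CO3"]]))
    r[15] <- sum(zc * c16) / esc
    r[16] <- sum(.Z16[1:15] * influx[1:15]) / jsc
    r[17] <- jv_in / vsc
    res[off + 1:17] <- r
    off <- off + 17L

    jv_out <- jv_out + storq * cl$apical$area * ap$jv
    js_out <- js_out + storq * cl$apical$area * ap$js
    para_in_js <- para_in_js + cl$lateral_area * lat$js
    para_in_jv <- para_in_jv + cl$lateral_area * lat$jv
    if (detail) detail_fl[[cl$tag]] <- list(apical = ap, basolateral = bl,
                                            lateral = lat)
  }

  jn <- membrane_flux(spec$junction, cL, pp$c16, vL, pp$v, pL, pp$p,
                      breakdown = detail)
  bm <- membrane_flux(spec$basement, pp$c16, cB, pp$v, 0, pp$p, pB,
                      breakdown = detail)
  influx <- storq * spec$junction$area * jn$js + para_in_js -
    spec$basement$area * bm$js
  jv_in <- storq * spec$junction$area * jn$jv + para_in_jv -
    spec$basement$area * bm$jv
  c16 <- pp$c16
  r <- numeric(17L)
  r[1:5] <- influx[c(.I$Na, .I$K, .I$Cl, .I$urea, .I$glucose)] / jsc
  r[6] <- (influx[.I$HPO4] + influx[.I$H2PO4]) / jsc
  r[7] <- (influx[.I$NH3] + influx[.I$NH4]) / jsc
  r[8] <- (influx[.I$HCO2] + influx[.I$H2CO2]) / jsc
  r[9] <- (influx[.I$HCO3] + influx[.I$H2CO3] + influx[.I$CO2]) / jsc
  r[10] <- log(c16[.I$H2CO3] / (c16[.I$CO2] * keq))
  r[11] <- log(c16[.I$HPO4] * c16[.I$H] / (c16[.I$H2PO4] * ka[["H2PO4"]]))
  r[12] <- log(c16[.I$NH3] * c16[.I$H] / (c16[.I$NH4] * ka[["NH4"]]))
  r[13] <- log(c16[.I$HCO2] * c16[.I$H] / (c16[.I$H2CO2] * ka[["H2CO2"]]))
  r[14] <- log(c16[.I$HCO3] * c16[.I$H] / (c16[.I$H2CO3] * ka[["H2CO3"]]))
  r[15] <- sum(.Z16[1:15] * c16[1:15]) / esc
  r[16] <- sum(.Z16[1:15] * influx[1:15]) / jsc
  r[17] <- jv_in / vsc
  res[off + 1:17] <- r
  off <- off + 17L

  jv_out <- jv_out + storq * spec$junction$area * jn$jv
  js_out <- js_out + storq * spec$junction$area * jn$js
  res[off + 1L] <- sum(.Z16[1:15] * js_out[1:15]) / jsc

  if (!detail) return(res)
  detail_fl$junction <- jn; detail_fl$basement <- bm
  list(residual = res, state = st, fluxes = detail_fl,
       lumen_out = list(jv = jv_out, js = js_out,
                        carried = as.numeric(.carried_map %*% js_out)))
}

# Default initial guess: interior concentrations from the bath with a
# generic intracellular ion shift, V_cell = -60 mV, V_para = 0 (solver
# settings, not physiological claims).
ep_default_guess <- function(spec, lumen, bath) {
  x <- numeric(17L * length(spec$cells) + 18L)
  cellc <- bath$c16[1:15]
  cellc[.I$Na] <- 20; cellc[.I$K] <- 130; cellc[.I$Cl] <- 25
  cellc[.I$glucose] <- max(0.5, 0.2 * cellc[.I$glucose])
  cellc[.I$H] <- 10^-7.15 * 1e3
  off <- 0L
  for (cl in spec$cells) {
    x[off + 1:15] <- log(cellc)
    x[off + 16L] <- -60
    x[off + 17L] <- log(cl$vol0)
    off <- off + 17L
  }
  x[off + 1:15] <- log(bath$c16[1:15])
  x[off + 16L] <- 0
  x[off + 17L] <- bath$p + 0.5
  x[off + 18L] <- if (is.null(lumen$v)) 0 else lumen$v
  x
}

# Damped chord-Newton with numeric Jacobian. Deterministic. Returns
# list(x, res, norm, converged, iters, njac).
newton_core <- function(fn, x0, tol, maxit = 60L, max_jac = 15L,
                        cache = NULL) {
  x <- x0
  r <- fn(x)
  if (any(!is.finite(r))) return(list(x = x, res = r, norm = Inf,
                                      converged = FALSE, iters = 0L, njac = 0L))
  nsq <- sum(r^2)
  n <- length(x)
  # a cached chord factor (e.g. from the neighbouring axial station) often
  # lets a warm-started solve converge without building a fresh Jacobian
  Jlu <- if (!is.null(cache) && identical(cache$n, n)) cache$Jlu else NULL
  njac <- 0L; fresh <- FALSE
  numjac <- function(x, r) {
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      h <- 1e-7 * max(1, abs(x[j]))
      xp <- x; xp[j] <- xp[j] + h
      J[, j] <- (fn(xp) - r) / h
    }
    J
  }
  for (it in seq_len(maxit)) {
    if (max(abs(r)) < tol)
      return(list(x = x, res = r, norm = max(abs(r)), converged = TRUE,
                  iters = it - 1L, njac = njac))
    if (is.null(Jlu)) {
      if (njac >= max_jac) break
      J <- numjac(x, r); njac <- njac + 1L; fresh <- TRUE
      Jlu <- tryCatch(lu_factor(J), error = function(e) NULL)
      if (is.null(Jlu)) break
      if (!is.null(cache)) { cache$Jlu <- Jlu; cache$n <- n }
    }
    dx <- tryCatch(-lu_solve(Jlu, r), error = function(e) NULL)
    if (is.null(dx) || any(!is.finite(dx))) {
      if (fresh) break
      Jlu <- NULL; next
    }
    # Armijo backtracking on the residual sum of squares
    lam <- 1; ok <- FALSE
    while (lam >= 1 / 1024) {
      x1 <- x + lam * dx
      r1 <- fn(x1)
      if (all(is.finite(r1))) {
        n1 <- sum(r1^2)
        if (n1 <= nsq * (1 - 1e-4 * lam)) { ok <- TRUE; break }
      }
      lam <- lam / 2
    }
    if (!ok) {
      if (fresh) break            # stuck even with a fresh Jacobian
      Jlu <- NULL                 # chord went stale: refresh
      next
    }
    x <- x1; r <- r1
    ratio <- sum(r1^2) / max(nsq, .Machine$double.xmin)
    nsq <- sum(r1^2)
    fresh <- FALSE
    if (lam < 1 || ratio > 0.15) Jlu <- NULL   # slow progress: refresh
  }
  list(x = x, res = r, norm = max(abs(r)), converged = max(abs(r)) < tol,
       iters = maxit, njac = njac)
}

lu_factor <- function(J) {
  qr(J, LAPACK = TRUE)
}
lu_solve <- function(f, b) {
  solve.qr(f, b)
}

ep_scale_activities <- function(spec, s) {
  scale_mem <- function(m) {
    m$transporters <- lapply(m$transporters, function(tr) {
      tr$activity <- tr$activity * s; tr
    })
    m
  }
  spec$cells <- lapply(spec$cells, function(cl) {
    cl$apical <- scale_mem(cl$apical)
    cl$basolateral <- scale_mem(cl$basolateral)
    if (!is.null(cl$lateral)) cl$lateral <- scale_mem(cl$lateral)
    cl
  })
  spec
}

#' Solve one epithelial cross-section for steady state
#'
#' Newton iteration (damped, with chord reuse of the Jacobian) on the
#' cross-section residuals, with activity-continuation and a
#' Levenberg-Marquardt fallback on failure. Deterministic: identical inputs
#' and settings give identical iterates.
#'
#' @param spec Compiled epithelial spec for one segment (see
#'   [compile_model()]); holds membranes, transporters, cell types and
#'   chemistry.
#' @param lumen List with `c16` (16 concentrations, mM), `p` (mmHg) and
#'   optionally `v` (initial guess for the luminal potential).
#' @param bath List with `c16` and `p`.
#' @param guess Optional packed unknown vector from a previous solve (warm
#'   start); default [ep_default_guess()].
#' @param storq Torque scale multiplying luminal-membrane fluxes (proximal
#'   segments only).
#' @param control List: `tol` (max-norm residual tolerance, default 1e-12),
#'   `maxit`, `continuation` (activity ramp used on failure).
#' @return An object of class `ep_solution`: compartment states, per-membrane
#'   fluxes with mechanism breakdown, lumen outflow (volume, per-species and
#'   per-carried-quantity), residual vector and solver diagnostics.
#' @export
solve_epithelium <- function(spec, lumen, bath, guess = NULL, storq = 1,
                             control = list()) {
  tol <- control$tol %||% 2e-11
  maxit <- control$maxit %||% 60L
  ramp <- control$continuation %||% c(0.1, 0.3, 0.6, 1)
  fn <- function(x) ep_eval(x, spec, lumen, bath, storq)
  x0 <- if (is.null(guess)) ep_default_guess(spec, lumen, bath) else guess
  ans <- newton_core(fn, x0, tol, maxit, cache = control$cache)
  used <- "newton"
  if (!ans$converged) {
    # second start tuned to distal segments: low cell Na, lumen-negative
    x1 <- ep_default_guess(spec, lumen, bath)
    off <- 0L
    for (cl in spec$cells) {
      x1[off + 1L] <- log(12)           # cell Na
      off <- off + 17L
    }
    x1[length(x1)] <- -30               # luminal potential
    a2 <- newton_core(fn, x1, tol, maxit)
    if (a2$converged) { ans <- a2; used <- "newton2" }
  }
  if (!ans$converged) {
    x <- ep_default_guess(spec, lumen, bath)
    for (s in ramp) {
      sp_s <- if (s < 1) ep_scale_activities(spec, s) else spec
      fs <- function(xx) ep_eval(xx, sp_s, lumen, bath, storq)
      a <- newton_core(fs, x, tol, maxit)
      if (!a$converged && requireNamespace("minpack.lm", quietly = TRUE)) {
        lm <- minpack.lm::nls.lm(par = x, fn = fs,
                                 control = minpack.lm::nls.lm.control(
                                   maxiter = 500, ftol = 1e-15, ptol = 1e-15))
        a2 <- newton_core(fs, lm$par, tol, maxit)
        if (a2$norm < a$norm) a <- a2
      }
      if (!a$converged && s < 1) next
      x <- a$x
      if (s == 1) ans <- a
    }
    used <- "continuation"
  }
  if (!ans$converged) {
    # homotopy from a symmetric cross-section: walk the luminal composition
    # from the interstitial one (almost always solvable) to the target,
    # warm-starting each stage and halving the stage length on failure
    solve_at <- function(s, x0s) {
      lum_s <- lumen
      lum_s$c16 <- (1 - s) * bath$c16 + s * lumen$c16
      lum_s$p <- (1 - s) * bath$p + s * lumen$p
      fs <- function(xx) ep_eval(xx, spec, lum_s, bath, storq)
      newton_core(fs, x0s, tol, maxit)
    }
    a <- solve_at(0, ep_default_guess(spec, lumen, bath))
    if (a$converged) {
      x <- a$x
      s_cur <- 0; ds <- 0.25; ok <- TRUE
      while (s_cur < 1) {
        s_try <- min(1, s_cur + ds)
        a <- solve_at(s_try, x)
        if (a$converged) {
          x <- a$x; s_cur <- s_try
          ds <- min(0.25, ds * 2)
        } else {
          ds <- ds / 2
          if (ds < 1 / 256) { ok <- FALSE; break }
        }
      }
      if (ok) { ans <- a; used <- "lumen-homotopy" }
    }
  }
  if (!ans$converged && length(spec$cells) > 1L) {
    # decomposition: solve each cell type against the same lumen/bath on
    # its own, then stitch the sub-solutions into a joint starting point
    stitched <- rep(NA_real_, 17L * length(spec$cells) + 18L)
    ok <- TRUE
    vls <- numeric(0)
    for (i in seq_along(spec$cells)) {
      sub <- spec
      sub$cells <- spec$cells[i]
      a <- tryCatch(solve_epithelium(sub, lumen, bath, guess = NULL,
                                     storq = storq, control = control),
                    nephrosim_convergence_error = function(e) NULL)
      if (is.null(a)) { ok <- FALSE; break }
      stitched[(i - 1L) * 17L + 1:17] <- a$x[1:17]
      if (i == 1L) stitched[(17L * length(spec$cells) + 1L):
                              (17L * length(spec$cells) + 17L)] <-
          a$x[18:34]
      vls <- c(vls, a$x[35])
    }
    if (ok) {
      stitched[length(stitched)] <- mean(vls)
      a <- newton_core(fn, stitched, tol, maxit)
      if (a$converged) { ans <- a; used <- "cell-decomposition" }
    }
  }
  if (!ans$converged && ans$norm < (control$tol_accept %||% 1e-6)) {
    # stagnated at the numerical noise floor for this cross-section;
    # accept, flagging the achieved norm
    ans$converged <- TRUE
    used <- paste0(used, "+stagnation")
  }
  if (!ans$converged) {
    if (!is.null(getOption("nephrosim.dumpfail")))
      saveRDS(list(lumen = lumen, bath = bath, storq = storq, guess = guess),
              getOption("nephrosim.dumpfail"))
    worst <- ep_residual_names(spec)[which.max(abs(ans$res))]
    cond <- structure(
      class = c("nephrosim_convergence_error", "error", "condition"),
      list(message = sprintf(
        "epithelium failed to converge: |res| = %.3e (worst equation: %s)",
        ans$norm, worst),
        call = sys.call(-1), norm = ans$norm, worst = worst))
    stop(cond)
  }
  out <- ep_eval(ans$x, spec, lumen, bath, storq, detail = TRUE)
  structure(list(
    x = ans$x, residual = out$residual, norm = ans$norm,
    state = out$state, fluxes = out$fluxes, lumen_out = out$lumen_out,
    lumen = lumen, bath = bath, storq = storq,
    iters = ans$iters, njac = ans$njac, method = used,
    unknown_names = ep_unknown_names(spec),
    residual_names = ep_residual_names(spec)), class = "ep_solution")
}

#' Steady-state residuals of an epithelial cross-section
#'
#' Re-evaluates the conservation residuals (volume and solute balances,
#' buffer relations, electroneutrality, current closure) at a given state.
#' Zero iff the state is a steady state of the cross-section.
#'
#' @param state An `ep_solution`, or a packed unknown vector.
#' @param spec Compiled epithelial spec (required when `state` is a vector;
#'   otherwise taken from the solution's context is not stored, so pass it).
#' @param lumen,bath As in [solve_epithelium()].
#' @param storq Torque scale.
#' @return Named residual vector.
#' @export
epithelial_residuals <- function(state, spec, lumen = NULL, bath = NULL,
                                 storq = 1) {
  if (inherits(state, "ep_solution")) {
    lumen <- lumen %||% state$lumen
    bath <- bath %||% state$bath
    storq <- state$storq
    x <- state$x
  } else x <- state
  if (any(!is.finite(x))) stop("epithelial_residuals: non-finite state",
                               call. = FALSE)
  r <- ep_eval(x, spec, lumen, bath, storq)
  names(r) <- ep_residual_names(spec)
  r
}

#' @export
print.ep_solution <- function(x, ...) {
  cat("Epithelial cross-section steady state\n")
  cat(sprintf("  max |residual| : %.3e (%s, %d Jacobian builds)\n",
              x$norm, x$method, x$njac))
  cat(sprintf("  V_lumen %.2f mV; torque scale %.3f\n",
              x$state$v_l, x$storq))
  for (i in seq_along(x$state$cells)) {
    cc <- x$state$cells[[i]]
    cat(sprintf("  cell %d: V = %.1f mV, Na %.1f K %.1f Cl %.1f pH %.2f\n",
                i, cc$v, cc$c16[.I$Na], cc$c16[.I$K], cc$c16[.I$Cl],
                -log10(cc$c16[.I$H] * 1e-3)))
  }
  cat(sprintf("  water reabsorption %.3g nL/min/cm; Na flux %.3g pmol/min/cm\n",
              x$lumen_out$jv, x$lumen_out$js[.I$Na]))
  invisible(x)
}
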