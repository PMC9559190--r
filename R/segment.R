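# Axial integration along one tubule segment.
#
# The march carries, per nephron of the population: W = omega * Q (volume
# flow, nL/min), luminal pressure P (mmHg), and T = omega * Q * C for the
# ten conserved luminal quantities (pmol/min). omega is the absolute number
# of tubules per nephron (1 along the nephron proper, decreasing along the
# coalescing CNT, 0.182 tubes/nephron in the CCD/OMCD, further coalescence
# in the IMCD). Carrying population totals makes segment- and kidney-level
# mass balance exact by construction: net segmental reabsorption is the
# telescoped difference of inlet and outlet loads.

#' Connecting tubule population fraction
#'
#' Fraction of connecting tubules remaining at axial position `x` along a
#' connecting tubule of length `L`: `2 - 2.32^(x/L)`, equal to 1 at the
#' inlet and strictly decreasing. The printed formula reaches -0.32 at
#' `x = L`; it is therefore clamped below at `floor` (default 0.182, about
#' 2/11, six tubules merging toward one cortical collecting duct). Set
#' `clamp = FALSE` to obtain the raw formula value.
#'
#' @param x Axial position(s), 0 <= x <= L (cm).
#' @param L Connecting tubule length (cm).
#' @param floor Lower clamp for the tubule fraction.
#' @param clamp Apply the clamp (default) or return the raw formula.
#' @return Tubule fraction(s).
#' @export
#' @examples
#' omega_cnt(0, 1)                      # 1
#' omega_cnt(1, 1, clamp = FALSE)       # 2 - 2.32
omega_cnt <- function(x, L, floor = 0.182, clamp = TRUE) {
  if (any(x < 0 | x > L)) stop("omega_cnt: x outside [0, L]", call. = FALSE)
  w <- 2 - 2.32^(x / L)
  if (clamp) pmax(w, floor) else w
}

#' Inner-medullary collecting duct population fraction
#'
#' Fraction of collecting ducts remaining at axial position `x` along an
#' inner-medullary collecting duct of length `L`:
#' `0.1 * (1 - 0.95 * (x/L)^2) * exp(-2.75 * x/L)`; equals 0.1 at the
#' inner-medulla entrance and decreases strictly to about 3.2e-4 at the
#' papillary tip.
#'
#' @param x Axial position(s), 0 <= x <= L (cm).
#' @param L IMCD length (cm).
#' @return Collecting-duct fraction(s).
#' @export
#' @examples
#' omega_imcd(0, 1)     # 0.1
omega_imcd <- function(x, L) {
  if (any(x < 0 | x > L)) stop("omega_imcd: x outside [0, L]", call. = FALSE)
  0.1 * (1 - 0.95 * (x / L)^2) * exp(-2.75 * x / L)
}

# Absolute tubules-per-nephron profile for a segment: tubes0 at the inlet
# times the segment's own (inlet-normalized) coalescence shape.
segment_omega <- function(seg, x) {
  switch(seg$coalesce,
         none = seg$tubes0,
         cnt  = seg$tubes0 * omega_cnt(x, seg$L, floor = seg$wfloor),
         # the papillary-tip merge rate diverges; the inlet-normalized
         # fraction is floored (config solver$imcd_floor) as a numerical
         # safeguard, mirroring the connecting-tubule clamp
         imcd = seg$tubes0 * pmax(omega_imcd(x, seg$L) / omega_imcd(0, seg$L),
                                  seg$imcd_floor %||% 0.05))
}

#' Axial derivatives of the luminal state
#'
#' Conservation of volume, Poiseuille pressure drop and conservation of the
#' carried solute quantities for one axial station. For coalescing segments
#' conservation is applied to the population totals `omega * Q` and
#' `omega * Q * C`; the wall flux per unit length scales with the fraction
#' of tubules remaining.
#'
#' @param state List with `W` (population volume flow, nL/min), `P` (mmHg)
#'   and `T` (named carried solute flows, pmol/min).
#' @param flux List with `jv` (volume, nL min-1 cm-1 of one tubule) and
#'   `carried` (length-9 solute outflux, pmol min-1 cm-1), both positive
#'   out of the lumen.
#' @param r Luminal radius (cm).
#' @param omega Tubules per nephron at this station.
#' @param visc Luminal viscosity (mmHg min).
#' @return List `dW`, `dP`, `dT` (per cm).
#' @export
lumen_rhs <- function(state, flux, r, omega, visc) {
  if (r <= 0) stop("lumen_rhs: radius must be positive", call. = FALSE)
  if (any(!is.finite(flux$carried)) || !is.finite(flux$jv))
    stop("lumen_rhs: non-finite epithelial flux", call. = FALSE)
  q_cm3 <- (state$W / omega) * 1e-6          # per-tubule flow, cm3/min
  dT <- -omega * flux$carried
  names(dT) <- .CARRIED
  list(dW = -omega * flux$jv,
       dP = -8 * visc * q_cm3 / (pi * r^4),
       dT = dT)
}

# One full station evaluation: speciate, torque, epithelial solve, rhs.
station_eval <- function(y, x, seg, bath_fun, tau0, warm, control) {
  car <- y$T / y$W
  names(car) <- .CARRIED
  depth <- seg$depth_start + (seg$depth_end - seg$depth_start) *
    (if (seg$L > 0) x / seg$L else 0)
  bath <- bath_fun(depth)
  sp <- lumen_species(car, seg$chem, co2 = bath$c16[[.I$CO2]])
  omega <- segment_omega(seg, x)
  r <- seg$r0
  storq <- 1
  if (seg$compliant) {
    tq <- seg$torque
    r <- compliant_radius(seg$r0, tq$mu_pt, y$P, tq$p0)
    tau <- microvillous_torque((y$W / omega) * 1e-6, r, tq$l_mv, tq$delta_mv,
                               seg$visc)
    storq <- torque_scale(tau, tau0, tq$s, tq$floor)
  }
  lum <- list(c16 = sp$c16, p = y$P, v = 0)
  ep <- solve_epithelium(seg$ep, lum, bath, guess = warm, storq = storq,
                         control = control)
  rhs <- lumen_rhs(y, list(jv = ep$lumen_out$jv, carried = ep$lumen_out$carried),
                   r, omega, seg$visc)
  list(rhs = rhs, ep = ep, sp = sp, storq = storq, r = r, omega = omega,
       pH = sp$pH)
}

state_ok <- function(y) {
  is.finite(y$W) && y$W > 0 && all(is.finite(y$T)) && all(y$T > 0)
}

pack_y <- function(y) c(y$W, y$P, y$T)
unpack_y <- function(u) list(W = u[1], P = u[2],
                             T = stats::setNames(u[-(1:2)], .CARRIED))

#' Integrate the luminal state along one segment
#'
#' Marches volume flow, pressure and carried solute flows along the axial
#' grid with an implicit second-order (trapezoidal) scheme: each step
#' solves the coupled luminal update by a damped Newton iteration, with the
#' epithelial cross-section re-solved (warm-started) inside every
#' evaluation. Implicit per-station coupling is required because the
#' luminal osmolality is a stiff mode: its relaxation length is much
#' shorter than any affordable grid step, so explicit marching oscillates
#' and diverges. Proximal segments apply the torque scale to all
#' luminal-side fluxes. Failed steps are retried with halving.
#'
#' @param inlet List with `W` (nL/min per nephron), `P` (mmHg), `T` (named
#'   carried flows, pmol/min per nephron).
#' @param seg Compiled segment (see [compile_model()]).
#' @param bath_fun Function of corticomedullary depth (cm) returning the
#'   interstitial `list(c16, p)`.
#' @param tau0 Reference microvillous torque for this nephron class (ignored
#'   for non-compliant segments).
#' @param warm Optional epithelial warm-start vector.
#' @param control Solver control list (see [solve_epithelium()]).
#' @return List of class `segment_solution`: `inlet`, `outlet`, `reab`
#'   (named: volume plus carried quantities, inlet minus outlet load),
#'   `profile` (data.frame of x, flows, pressure, potential, pH, torque
#'   scale, major concentrations), `species` (matrix of luminal
#'   concentrations at the nodes), `warm` (epithelial state at the outlet),
#'   `id`.
#' @export
solve_segment <- function(inlet, seg, bath_fun, tau0 = NULL, warm = NULL,
                          control = list()) {
  y <- inlet
  names(y$T) <- .CARRIED
  n <- seg$n_grid
  if (seg$L <= 0 || n < 1) {
    reab <- c(volume = 0, stats::setNames(rep(0, .NCAR), .CARRIED))
    return(structure(list(inlet = inlet, outlet = inlet, reab = reab,
                          profile = NULL, species = NULL, warm = warm,
                          id = seg$id),
                     class = "segment_solution"))
  }
  h0 <- seg$L / n
  prof <- list()
  spmat <- list()
  # per-segment caches: the step-map chord Jacobian and the epithelial
  # chord factor shared across neighbouring stations
  control$cache <- new.env(parent = emptyenv())
  Jlu <- NULL                      # chord Jacobian of the step map

  s0 <- station_eval(y, 0, seg, bath_fun, tau0, warm, control)
  warm <- s0$ep$x

  record <- function(x, y, st) {
    prof[[length(prof) + 1L]] <<- data.frame(
      x = x, W = y$W, Q = y$W / st$omega, P = y$P,
      V_L = st$ep$state$v_l, pH = st$pH, storq = st$storq,
      omega = st$omega, r = st$r,
      Na = st$sp$c16[[.I$Na]], K = st$sp$c16[[.I$K]], Cl = st$sp$c16[[.I$Cl]],
      HCO3 = st$sp$c16[[.I$HCO3]], NH4 = st$sp$c16[[.I$NH4]],
      urea = st$sp$c16[[.I$urea]], glucose = st$sp$c16[[.I$glucose]],
      osm = sum(st$sp$c16))
    spmat[[length(spmat) + 1L]] <<- st$sp$c16
  }
  record(0, y, s0)

  rhs_vec <- function(st) c(st$rhs$dW, st$rhs$dP, st$rhs$dT)

  # one implicit trapezoid step from (y, st) at x over h; returns
  # list(y, st) at x + h or NULL on failure
  trapezoid_step <- function(y, st, x, h) {
    u0 <- pack_y(y)
    f0 <- rhs_vec(st)
    # the epithelial warm start advances only on *accepted* Newton points:
    # trial and finite-difference evaluations all start from the same state,
    # which keeps the step map smooth and cannot poison later solves
    gfun <- function(u) {
      yy <- unpack_y(u)
      if (!state_ok(yy)) return(NULL)
      stt <- tryCatch(
        station_eval(yy, x + h, seg, bath_fun, tau0, warm, control),
        nephrosim_convergence_error = function(e) NULL,
        error = function(e) NULL)
      if (is.null(stt)) {
        if (isTRUE(getOption("nephrosim.trace"))) message("  [station solve rejected]")
        return(NULL)
      }
      list(g = u - u0 - (h / 2) * (f0 + rhs_vec(stt)), st = stt)
    }
    # predictor: explicit Euler, clipped to stay positive
    u <- u0 + h * f0
    bad <- !state_ok(unpack_y(u))
    if (bad) u <- u0
    ev <- gfun(u)
    if (is.null(ev)) { ev <- gfun(u0); u <- u0 }
    if (is.null(ev)) {
      if (isTRUE(getOption("nephrosim.trace"))) message("  [predictor rejected]")
      return(NULL)
    }
    warm <<- ev$st$ep$x
    # work on relative scales: components of u span 5+ orders of magnitude
    su <- pmax(abs(u0), 1e-3)
    gs <- function(ev) ev$g / su
    tol_s <- 2e-6
    fresh <- FALSE
    for (it in 1:30) {
      if (all(abs(gs(ev)) < tol_s)) return(list(y = unpack_y(u), st = ev$st))
      if (is.null(Jlu)) {
        J <- matrix(0, length(u), length(u))
        for (k in seq_along(u)) {
          hh <- 1e-6 * su[k]
          up <- u; up[k] <- up[k] + hh
          evp <- gfun(up)
          if (is.null(evp)) { up[k] <- u[k] - hh; evp <- gfun(up); hh <- -hh }
          if (is.null(evp)) return(NULL)
          J[, k] <- (gs(evp) - gs(ev)) / (hh / su[k])
        }
        Jlu <<- tryCatch(qr(J, LAPACK = TRUE), error = function(e) NULL)
        if (is.null(Jlu)) return(NULL)
        fresh <- TRUE
      }
      dv <- tryCatch(-solve.qr(Jlu, gs(ev)), error = function(e) NULL)
      if (is.null(dv) || any(!is.finite(dv))) {
        if (fresh) return(NULL)
        Jlu <<- NULL; next
      }
      du <- dv * su
      lam <- 1; ok <- FALSE
      while (lam >= 1 / 64) {
        u1 <- u + lam * du
        ev1 <- if (state_ok(unpack_y(u1))) gfun(u1) else NULL
        if (!is.null(ev1) && sum(gs(ev1)^2) < sum(gs(ev)^2) *
            (1 - 1e-4 * lam) + 1e-30) { ok <- TRUE; break }
        lam <- lam / 2
      }
      if (!ok) {
        if (all(abs(gs(ev)) < 50 * tol_s))    # stalled at the noise floor
          return(list(y = unpack_y(u), st = ev$st))
        if (isTRUE(getOption("nephrosim.trace")))
          message("  [step linesearch stalled; it=", it, " fresh=", fresh,
                  " |g|=", signif(max(abs(gs(ev))), 3), "]")
        if (fresh) return(NULL)
        Jlu <<- NULL                     # stale chord: refresh and retry
        next
      }
      ratio <- sum(gs(ev1)^2) / max(sum(gs(ev)^2), 1e-300)
      u <- u1; ev <- ev1
      warm <<- ev$st$ep$x
      fresh <- FALSE
      if (lam < 1 || ratio > 0.3) Jlu <<- NULL   # slow progress: refresh
    }
    if (all(abs(gs(ev)) < 50 * tol_s)) list(y = unpack_y(u), st = ev$st)
    else {
      if (isTRUE(getOption("nephrosim.trace")))
        message("  [step maxit; |g|=", signif(max(abs(gs(ev))), 3), "]")
      NULL
    }
  }

  # explicit micro-stepping rescue for stretches where the implicit step
  # map is too ill-conditioned (e.g. the hypersensitive papillary tip);
  # stable because the sub-step is far below the stiff mode's scale
  micro_march <- function(y, st, x, h) {
    nsub <- 64L
    hs <- h / nsub
    for (i in seq_len(nsub)) {
      y1 <- list(W = y$W + hs * st$rhs$dW, P = y$P + hs * st$rhs$dP,
                 T = y$T + hs * st$rhs$dT)
      if (!state_ok(y1))
        stop("solve_segment: step control failed in segment ", seg$id,
             " at x = ", signif(x, 4), call. = FALSE)
      y <- y1
      x <- x + hs
      st <- station_eval(y, x, seg, bath_fun, tau0, warm, control)
      warm <<- st$ep$x
    }
    list(y = y, st = st)
  }

  march <- function(y, st, x, h, depth) {
    res <- trapezoid_step(y, st, x, h)
    if (!is.null(res)) return(res)
    if (depth >= 5L) return(micro_march(y, st, x, h))
    half <- march(y, st, x, h / 2, depth + 1L)
    march(half$y, half$st, x + h / 2, h / 2, depth + 1L)
  }

  st <- s0
  x <- 0
  for (j in seq_len(n)) {
    # graded entry: the luminal state adjusts to the segment's transport
    # regime in a thin boundary layer at the inlet; the coalescing
    # inner-medullary duct also steepens sharply toward the papillary tip.
    # Resolve both with geometric sub-steps so the step-halving error of
    # the whole march is dominated by the smooth interior.
    sub <- h0
    if (j == 1L) sub <- h0 * c(1, 1, 2, 4) / 8
    else if (j == n && identical(seg$coalesce, "imcd"))
      sub <- h0 * c(4, 2, 1, 1) / 8
    for (hs in sub) {
      res <- march(y, st, x, hs, 0L)
      y <- res$y; st <- res$st; x <- x + hs
    }
    record(x, y, st)
  }

  outlet <- list(W = y$W, P = y$P, T = y$T)
  reab <- c(volume = inlet$W - y$W, inlet$T - y$T)
  species <- do.call(rbind, spmat)
  colnames(species) <- .SNAME
  structure(list(inlet = inlet, outlet = outlet, reab = reab,
                 profile = do.call(rbind, prof), species = species,
                 warm = warm, id = seg$id),
            class = "segment_solution")
}

#' @export
print.segment_solution <- function(x, ...) {
  cat(sprintf("Segment %s: W %.3g -> %.3g nL/min; Na %.3g -> %.3g pmol/min\n",
              x$id, x$inlet$W, x$outlet$W, x$inlet$T[["Na"]],
              x$outlet$T[["Na"]]))
  invisible(x)
}
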