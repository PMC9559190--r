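# Compile a raw parameter set (nested config list, human units) into the
# flat numeric structures the solver consumes. Compilation is cheap and
# pure: the experiment protocols edit the raw parameter list and recompile.

.H_UNIT <- 1e-5 * PERM_CM_S        # config h (1e-5 cm/s) -> nL min-1 cm-2
.PF_UNIT <- 18e-6 * PERM_CM_S / .CONST$rt_mmhg  # Pf (cm/s) -> Lp

compile_membrane <- function(cfg, r, frac = 1) {
  circ <- 2 * pi * r
  h <- unlist(cfg$h)
  hh <- if (length(h)) h * .H_UNIT else NULL
  # named channels (ENaC and kin) fold into the passive permeability vector
  hvec <- numeric(16L); names(hvec) <- .SNAME
  if (length(hh)) {
    idx <- match(names(hh), .SNAME)
    if (anyNA(idx)) stop("unknown solute in membrane config: ",
                         paste(names(hh)[is.na(idx)], collapse = ", "))
    hvec[idx] <- hvec[idx] + as.numeric(hh)
  }
  kept <- list()
  for (tr in cfg$transporters %||% list()) {
    if (identical(tr$kind, "channel")) {
      hvec[tr$solute] <- hvec[tr$solute] + tr$h * .H_UNIT
    } else {
      tr$stoich <- unlist(tr$stoich)
      kept[[length(kept) + 1L]] <- compile_transporter(tr)
    }
  }
  mem <- new_membrane(area = cfg$area_factor * circ * frac,
                      lp = (cfg$pf %||% 0) * .PF_UNIT,
                      sigma = cfg$sigma %||% 1,
                      transporters = kept)
  mem$h <- unname(hvec)
  mem
}

compile_chem <- function(params) {
  pk <- params$chemistry$pK
  pairs <- data.frame(
    acid = c("H2PO4", "NH4", "H2CO2", "H2CO3"),
    base = c("HPO4", "NH3", "HCO2", "HCO3"),
    pK = c(pk$phosphate, pk$ammonium, pk$formate, pk$carbonic),
    kinetic = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  list(pairs = pairs,
       kh = params$chemistry$kh_per_min,
       kd = params$chemistry$kd_per_min)
}

compile_segment <- function(scfg, params, chem, ka) {
  r <- scfg$radius_cm
  sol <- params$solver
  # every species keeps a minimal basolateral leak so that no cell balance
  # equation is structurally degenerate (config: solver$h_floor, 1e-5 cm/s)
  h_floor <- (sol$h_floor %||% 0.01) * .H_UNIT
  cells <- lapply(scfg$cells, function(cc) {
    vol0 <- cc$volume_nl_per_cm * (cc$frac %||% 1)
    bl <- compile_membrane(cc$basolateral, r, cc$frac %||% 1)
    bl$h[1:15] <- pmax(bl$h[1:15], h_floor)
    list(tag = cc$tag,
         imp = cc$imp_mM * vol0,
         z_imp = cc$z_imp,
         vol0 = vol0,
         ca = cc$ca_cell %||% 1,
         co2_kinetic = TRUE,
         p_cell = cc$p_cell %||% params$interstitium$pressure,
         apical = finalize_membrane(compile_membrane(cc$apical, r,
                                                     cc$frac %||% 1)),
         basolateral = finalize_membrane(bl),
         lateral = NULL, lateral_area = 0)
  })
  ep <- list(cells = cells,
             junction = finalize_membrane(compile_membrane(scfg$junction, r)),
             basement = finalize_membrane(compile_membrane(scfg$basement, r)),
             chem = chem, ka = ka,
             jscale = sol$jscale, vscale = sol$vscale, escale = sol$escale)
  list(id = scfg$id, L = scfg$length_cm, r0 = r, n_grid = scfg$n_grid,
       compliant = isTRUE(scfg$compliant),
       coalesce = scfg$coalesce %||% "none",
       tubes0 = 1,
       wfloor = params$global$cd_tubes_per_nephron %||% 0.182,
       depth_start = scfg$depth_start, depth_end = scfg$depth_end,
       ca_lumen = scfg$ca_lumen %||% 0,
       imcd_floor = params$solver$imcd_floor %||% 0.05,
       visc = params$global$viscosity,
       torque = c(params$torque,
                  list(p0 = params$torque$p0, floor = params$torque$floor,
                       l_mv = params$torque$l_mv_cm,
                       delta_mv = params$torque$delta_mv_cm)),
       chem = chem, ep = ep)
}

make_bath_fun <- function(params, chem) {
  it <- params$interstitium
  pl <- params$global$plasma
  omd <- it$om_depth_cm; tot <- it$total_depth_cm
  interp <- function(depth, v) {
    # piecewise-exponential between cortex, OM-IM boundary, papillary tip
    if (depth <= 0) return(v[1])
    if (depth <= omd) return(v[1] * (v[2] / v[1])^(depth / omd))
    d2 <- min(depth - omd, tot - omd)
    v[2] * (v[3] / v[2])^(d2 / (tot - omd))
  }
  cache <- new.env(parent = emptyenv())
  function(depth) {
    key <- sprintf("%.6f", depth)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    c16 <- compose_fluid(
      na = pl$Na * interp(depth, it$na_mult),
      k = pl$K * interp(depth, it$k_mult),
      ph = 7.40,
      totCO2 = pl$totCO2,
      totP = pl$totP,
      totN = interp(depth, it$totN),
      totF = pl$totF,
      urea = interp(depth, it$urea),
      glucose = pl$glucose,
      imp = it$protein_mM, z_imp = 0, chem = chem)
    out <- list(c16 = c16, p = it$pressure)
    cache[[key]] <- out
    out
  }
}

.CLASS_LABELS <- c("SF", "JM1", "JM2", "JM3", "JM4", "JM5")

#' Compile a parameter set into a runnable kidney model
#'
#' Converts the raw, human-unit parameter configuration (see
#' [build_model()], [build_toy_fixture()]) into per-class segment chains
#' with precomputed membrane areas and permeabilities, the filtrate
#' composition, the interstitial profile function, and the per-class
#' reference microvillous torque.
#'
#' @param params Raw parameter set.
#' @return A `kidney_model` list consumed by [assemble_kidney()].
#' @export
compile_model <- function(params) {
  chem <- compile_chem(params)
  ka <- .ka_mM(chem$pairs$pK)
  names(ka) <- chem$pairs$acid
  g <- params$global
  pl <- g$plasma
  segs <- lapply(params$segments, compile_segment, params = params,
                 chem = chem, ka = ka)
  # collecting duct carries cd_tubes_per_nephron tubules per nephron
  for (id in c("CCD", "OMCD", "IMCD"))
    if (!is.null(segs[[id]])) segs[[id]]$tubes0 <- g$cd_tubes_per_nephron %||% 0.182

  weights <- unlist(g$class_weights)
  weights <- weights / sum(weights)
  classes <- list()
  for (lab in names(weights)) {
    sngfr <- if (lab == "SF") g$sngfr_sf else g$sngfr_sf * g$jm_sngfr_ratio
    chain <- c("PCT", "S3", "SDL")
    if (lab != "SF") chain <- c(chain, "LDL", "LAL")
    chain <- c(chain, "mTAL", "cTAL", "DCTe", "DCTl", "CNT")
    classes[[lab]] <- list(label = lab, weight = weights[[lab]],
                           sngfr = sngfr,
                           loop_mm = if (lab == "SF") 0 else
                             g$loop_depths_mm[[lab]],
                           chain = chain)
  }
  # Juxtamedullary nephrons filter more and are dimensionally larger;
  # their tubule radii (hence all membrane areas) scale with the SNGFR
  # ratio so that baseline glomerulotubular matching holds across classes.
  jm_scale <- g$jm_tubule_scale %||% g$jm_sngfr_ratio

  # per-class loop segments: length set by loop depth
  chains <- list()
  for (lab in names(classes)) {
    cl <- classes[[lab]]
    lst <- list()
    for (id in cl$chain) {
      scfg <- params$segments[[id]]
      if (lab != "SF") {
        scfg$radius_cm <- scfg$radius_cm * jm_scale
        sg <- compile_segment(scfg, params, chem, ka)
        sg$tubes0 <- 1
      } else sg <- segs[[id]]
      if (id %in% c("LDL", "LAL") && cl$loop_mm > 0) {
        sg$L <- cl$loop_mm * 0.1
        om <- params$interstitium$om_depth_cm
        if (id == "LDL") { sg$depth_start <- om; sg$depth_end <- om + sg$L }
        else { sg$depth_start <- om + sg$L; sg$depth_end <- om }
        sg$n_grid <- max(2L, ceiling(segs[[id]]$n_grid * cl$loop_mm / 2))
      }
      lst[[id]] <- sg
    }
    chains[[lab]] <- lst
  }
  tq <- params$torque
  tau0 <- vapply(classes, function(cl)
    microvillous_torque(cl$sngfr * 1e-6,
                        params$segments$PCT$radius_cm *
                          (if (cl$label == "SF") 1 else jm_scale),
                        tq$l_mv_cm, tq$delta_mv_cm, g$viscosity),
    numeric(1))

  plasma_c16 <- compose_fluid(pl$Na, pl$K, pl$pH, pl$totCO2, pl$totP,
                              pl$totN, pl$totF, pl$urea, pl$glucose,
                              imp = pl$protein_mM, z_imp = 0, chem = chem)
  filt_c16 <- compose_fluid(pl$Na, pl$K, pl$pH, pl$totCO2, pl$totP,
                            pl$totN, pl$totF, pl$urea, pl$glucose,
                            imp = 0, z_imp = 0, chem = chem)
  structure(list(
    meta = params$meta, params = params, chem = chem,
    classes = classes, chains = chains,
    cd_chain = segs[c("CCD", "OMCD", "IMCD")],
    tau0 = tau0,
    plasma_c16 = plasma_c16,
    filtrate = species_to_carried(filt_c16),
    bath_fun = make_bath_fun(params, chem),
    nephrons = g$nephrons,
    inlet_pressure = g$inlet_pressure), class = "kidney_model")
}

#' @export
print.kidney_model <- function(x, ...) {
  cat(sprintf("Kidney model: %s %s (%d nephrons, %d classes)\n",
              x$meta$species %||% "?", x$meta$sex %||% "?",
              x$nephrons, length(x$classes)))
  w <- vapply(x$classes, `[[`, numeric(1), "weight")
  s <- vapply(x$classes, `[[`, numeric(1), "sngfr")
  cat("  class weights:", paste(sprintf("%s %.3f", names(w), w),
                                collapse = ", "), "\n")
  cat("  SNGFR (nL/min):", paste(sprintf("%s %.2f", names(s), s),
                                 collapse = ", "), "\n")
  invisible(x)
}
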