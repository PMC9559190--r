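# Whole-kidney assembly: solve all nephron classes, merge the connecting
# tubule outflows into the cortical collecting duct, continue down the
# shared collecting duct, and account deliveries per kidney.

.BOUNDARIES <- c("PT", "DL", "mTAL", "DCT", "CNT", "CCD", "OMCD", "IMCD",
                 "urine")
.BOUNDARY_SEG <- c(PT = "PCT", DL = "SDL", mTAL = "mTAL", DCT = "DCTe",
                   CNT = "CNT", CCD = "CCD", OMCD = "OMCD", IMCD = "IMCD")

#' Solve the assembled six-class kidney
#'
#' Solves every nephron class from the proximal tubule to the connecting
#' tubule outlet, forms the cortical collecting duct inlet as the
#' population-weighted, flow-weighted mixture of the class outflows, and
#' integrates the shared collecting duct to the urine. All flows are
#' carried per average nephron and scaled to per-kidney totals by the
#' nephron count.
#'
#' @param model A compiled `kidney_model` (see [compile_model()]).
#' @param control Solver control passed to the per-station epithelial solves.
#' @param sngfr_scale Multiplier applied to every class SNGFR (used by the
#'   saline-load protocol); the torque reference stays at baseline.
#' @return Object of class `kidney_solution`.
#' @export
assemble_kidney <- function(model, control = list(), sngfr_scale = 1) {
  classes <- model$classes
  per_class <- list()
  cnt_out <- list()
  for (lab in names(classes)) {
    cl <- classes[[lab]]
    inlet <- list(W = cl$sngfr * sngfr_scale,
                  P = model$inlet_pressure,
                  T = cl$sngfr * sngfr_scale * model$filtrate)
    names(inlet$T) <- .CARRIED
    segsol <- list()
    y <- inlet
    warm <- NULL
    for (id in names(model$chains[[lab]])) {
      sg <- model$chains[[lab]][[id]]
      sol <- tryCatch(
        solve_segment(y, sg, model$bath_fun, tau0 = model$tau0[[lab]],
                      warm = NULL, control = control),
        nephrosim_convergence_error = function(e)
          stop(sprintf("class %s, segment %s: %s", lab, id,
                       conditionMessage(e)), call. = FALSE))
      segsol[[id]] <- sol
      y <- list(W = sol$outlet$W, P = sol$outlet$P, T = sol$outlet$T)
    }
    per_class[[lab]] <- list(inlet = inlet, segments = segsol, outlet = y)
    cnt_out[[lab]] <- y
  }

  # population-weighted merge into the CCD (flow-weighted solute mixing)
  w <- vapply(classes, `[[`, numeric(1), "weight")
  W0 <- sum(w * vapply(cnt_out, `[[`, numeric(1), "W"))
  T0 <- Reduce(`+`, Map(function(wi, yi) wi * yi$T, w, cnt_out))
  P0 <- sum(w * vapply(cnt_out, function(y) y$W * y$P, numeric(1))) /
    sum(w * vapply(cnt_out, `[[`, numeric(1), "W"))
  y <- list(W = W0, P = P0, T = T0)

  cd <- list()
  for (id in names(model$cd_chain)) {
    sg <- model$cd_chain[[id]]
    sol <- tryCatch(
      solve_segment(y, sg, model$bath_fun, tau0 = NULL, control = control),
      nephrosim_convergence_error = function(e)
        stop(sprintf("collecting duct segment %s: %s", id,
                     conditionMessage(e)), call. = FALSE))
    cd[[id]] <- sol
    y <- list(W = sol$outlet$W, P = sol$outlet$P, T = sol$outlet$T)
  }

  filtered <- Reduce(`+`, Map(function(wi, cl)
    wi * cl$sngfr * sngfr_scale * model$filtrate, w, classes))
  names(filtered) <- .CARRIED
  filtered_W <- sum(w * vapply(classes, `[[`, numeric(1), "sngfr")) *
    sngfr_scale

  structure(list(
    model = model, classes = per_class, cd = cd,
    cd_inlet = list(W = W0, T = T0),
    urine = y,
    filtered = filtered, filtered_W = filtered_W,
    nephrons = model$nephrons,
    sngfr_scale = sngfr_scale), class = "kidney_solution")
}

# Per-average-nephron delivery (W and carried T) at a named boundary.
boundary_state <- function(kid, boundary) {
  if (boundary == "urine")
    return(list(W = kid$urine$W, T = kid$urine$T))
  seg <- .BOUNDARY_SEG[[boundary]]
  if (seg %in% names(kid$cd))
    return(list(W = kid$cd[[seg]]$inlet$W, T = kid$cd[[seg]]$inlet$T))
  w <- vapply(kid$model$classes, `[[`, numeric(1), "weight")
  W <- 0; T <- 0
  for (lab in names(kid$classes)) {
    s <- kid$classes[[lab]]$segments[[seg]]
    W <- W + w[[lab]] * s$inlet$W
    T <- T + w[[lab]] * s$inlet$T
  }
  list(W = W, T = T)
}

#' Delivery table for a solved kidney
#'
#' Per-kidney deliveries of volume and key solutes (Na+, K+, Cl-, HCO3-,
#' NH4+) to the inlet of each nephron region, plus the urinary excretion
#' row, in absolute terms (volume uL/min, solutes umol/min) and as
#' fractional deliveries (% of filtered load). Species concentrations at a
#' boundary are recovered from the carried totals by luminal equilibrium
#' speciation.
#'
#' @param kid A `kidney_solution`.
#' @return data.frame of class `delivery_table`; attributes `filtered`
#'   (per-kidney filtered loads) and `nephrons`.
#' @export
delivery_table <- function(kid) {
  chem <- kid$model$chem
  n <- kid$nephrons
  co2 <- kid$model$plasma_c16[[.I$CO2]]
  sol_cols <- c("Na", "K", "Cl", "HCO3", "NH4")
  rows <- lapply(.BOUNDARIES, function(b) {
    st <- boundary_state(kid, b)
    car <- st$T / st$W
    names(car) <- .CARRIED
    c16 <- lumen_species(car, chem, co2 = co2)$c16
    vals <- c16[sol_cols] * st$W * n * 1e-6        # umol/min per kidney
    data.frame(boundary = b,
               volume = st$W * n * 1e-3,           # uL/min per kidney
               as.list(vals))
  })
  out <- do.call(rbind, rows)
  filt_c16 <- lumen_species(stats::setNames(kid$filtered / kid$filtered_W,
                                            .CARRIED), chem, co2 = co2)$c16
  filtered <- c(volume = kid$filtered_W * n * 1e-3,
                filt_c16[sol_cols] * kid$filtered_W * n * 1e-6)
  attr(out, "filtered") <- filtered
  attr(out, "nephrons") <- n
  class(out) <- c("delivery_table", "data.frame")
  out
}

#' Fractional deliveries from a delivery table
#'
#' `FD = 100 * delivery / filtered load` per boundary and quantity; the
#' fractional reabsorption of a region is the difference of consecutive
#' boundary FDs.
#'
#' @param deliveries A `delivery_table` (or data.frame of absolute
#'   deliveries with a `filtered` attribute).
#' @param filtered Optional named filtered loads overriding the attribute.
#' @return data.frame of percentages, same shape as `deliveries`.
#' @export
fractional_delivery <- function(deliveries, filtered = NULL) {
  filtered <- filtered %||% attr(deliveries, "filtered")
  if (is.null(filtered)) stop("fractional_delivery: filtered loads missing",
                              call. = FALSE)
  if (any(filtered <= 0)) stop("fractional_delivery: filtered load must be positive",
                               call. = FALSE)
  qn <- setdiff(names(deliveries), "boundary")
  out <- deliveries
  for (q in qn) out[[q]] <- 100 * deliveries[[q]] / filtered[[q]]
  class(out) <- "data.frame"
  out
}

# Whole-kidney balance per conserved quantity: filtered load minus the sum
# of segmental reabsorptions minus urinary excretion (per average nephron),
# relative to the gross load. Covers volume and the eight carried
# quantities (the CO2 system is open and excluded by construction).
kidney_balance <- function(kid) {
  w <- vapply(kid$model$classes, `[[`, numeric(1), "weight")
  reab <- 0
  for (lab in names(kid$classes))
    for (s in kid$classes[[lab]]$segments)
      reab <- reab + w[[lab]] * s$reab[.CARRIED]
  for (s in kid$cd) reab <- reab + s$reab[.CARRIED]
  bal <- kid$filtered - reab - kid$urine$T
  gross <- pmax(abs(kid$filtered), abs(reab), abs(kid$urine$T), 1e-9)
  rel <- bal / gross
  names(rel) <- .CARRIED
  rel
}

#' @export
print.kidney_solution <- function(x, ...) {
  cat(sprintf("Kidney solution: %s %s, %d nephrons (SNGFR scale %.2f)\n",
              x$model$meta$species %||% "?", x$model$meta$sex %||% "?",
              x$nephrons, x$sngfr_scale))
  fd <- fractional_delivery(delivery_table(x))
  u <- fd[fd$boundary == "urine", ]
  cat(sprintf("  urine: %.3g uL/min; FE volume %.2f%%, Na %.2f%%, K %.1f%%\n",
              delivery_table(x)$volume[match("urine", .BOUNDARIES)],
              u$volume, u$Na, u$K))
  invisible(x)
}

#' @export
print.delivery_table <- function(x, ...) {
  cat("Per-kidney deliveries (volume uL/min, solutes umol/min):\n")
  df <- x; class(df) <- "data.frame"
  print(format(df, digits = 3), row.names = FALSE)
  invisible(x)
}
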