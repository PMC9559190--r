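# Simulation protocols: baseline delivery profiles, acute saline load,
# segment-swap (mouse transporter activities set to sex-matched rat values,
# one segment group at a time) and sex-swap (selected female-mouse sex
# differences made rat-like). All protocols are deterministic re-solves of
# the steady-state model under modified parameters.

.SWAP_GROUPS <- list(PT = "PT", TAL = "TAL", DCT = "DCT", CNT = "CNT",
                     CCD_OMCD = c("CCD", "OMCD"), IMCD = "IMCD")

.REGION_SEGMENTS <- list(PT = c("PCT", "S3"), DL = c("SDL", "LDL"),
                         LAL = "LAL", TAL = c("mTAL", "cTAL"),
                         DCT = c("DCTe", "DCTl"), CNT = "CNT",
                         CCD_OMCD = c("CCD", "OMCD"), IMCD = "IMCD")

solve_params <- function(params, control = list(), sngfr_scale = 1) {
  assemble_kidney(compile_model(params), control = control,
                  sngfr_scale = sngfr_scale)
}

#' Baseline nephron transport
#'
#' Solves the model at baseline and returns the per-kidney delivery table
#' (absolute and fractional deliveries at each nephron region inlet plus
#' urinary excretion).
#'
#' @param params Raw parameter set (from [build_model()] or
#'   [build_toy_fixture()]).
#' @param control Solver control list.
#' @return List of class `protocol_result` with elements `kidney`
#'   (the `kidney_solution`), `deliveries`, `fd` (fractional deliveries, %).
#' @export
run_baseline <- function(params, control = list()) {
  kid <- solve_params(params, control)
  del <- delivery_table(kid)
  structure(list(protocol = "baseline", kidney = kid, deliveries = del,
                 fd = fractional_delivery(del)),
            class = "protocol_result")
}

#' Acute saline load
#'
#' Re-solves the model with SNGFR increased by 50% (male) or 65% (female)
#' in every nephron class, all other parameters unchanged; the torque
#' reference remains at its baseline value, so proximal transport responds
#' through the torque scale (glomerulotubular balance).
#'
#' @param params Raw parameter set; its `meta$sex` selects the multiplier.
#' @param control Solver control list.
#' @return `protocol_result` with an additional `summary` (urine flow
#'   uL/min, Na+ and K+ excretion umol/min, per kidney) and `sngfr_scale`.
#' @export
run_saline_load <- function(params, control = list()) {
  scale <- if (identical(params$meta$sex, "female")) 1.65 else 1.50
  kid <- solve_params(params, control, sngfr_scale = scale)
  del <- delivery_table(kid)
  ur <- del[del$boundary == "urine", ]
  structure(list(protocol = "saline_load", kidney = kid, deliveries = del,
                 fd = fractional_delivery(del),
                 sngfr_scale = scale,
                 summary = c(urine_flow = ur$volume, E_Na = ur$Na,
                             E_K = ur$K)),
            class = "protocol_result")
}

#' Fractional-excretion ratio between the sexes under a saline load
#'
#' Female-to-male ratio of excretion as a fraction of the administered
#' bolus: `(E_female / E_male) / weight_factor`, where `weight_factor` is
#' the female-to-male bolus volume ratio (boluses scale with body weight).
#' A female rat weighs about half a male (`weight_factor = 0.5`); a male
#' mouse about 30% more than a female (`weight_factor = 1/1.3`).
#'
#' @param e_female,e_male Excretion rates (any common unit), positive.
#' @param weight_factor Female-to-male bolus volume ratio, positive.
#' @return The fractional-excretion ratio.
#' @export
#' @examples
#' excretion_ratio(47, 54, 0.5)       # rat convention
#' excretion_ratio(10, 11, 1 / 1.3)   # mouse convention
excretion_ratio <- function(e_female, e_male, weight_factor) {
  if (any(c(e_female, e_male, weight_factor) <= 0) ||
      any(!is.finite(c(e_female, e_male, weight_factor))))
    stop("excretion_ratio: inputs must be positive", call. = FALSE)
  (e_female / e_male) / weight_factor
}

# net transport (reabsorption) of a carried quantity by a region, per
# average nephron
region_transport <- function(kid, region, quantity) {
  segs <- .REGION_SEGMENTS[[region]]
  w <- vapply(kid$model$classes, `[[`, numeric(1), "weight")
  tot <- 0
  for (lab in names(kid$classes)) {
    for (sid in segs) {
      s <- kid$classes[[lab]]$segments[[sid]]
      if (!is.null(s))
        tot <- tot + w[[lab]] * (if (quantity == "volume") s$reab[["volume"]]
                                 else s$reab[[quantity]])
    }
  }
  for (sid in segs) {
    s <- kid$cd[[sid]]
    if (!is.null(s))
      tot <- tot + (if (quantity == "volume") s$reab[["volume"]]
                    else s$reab[[quantity]])
  }
  tot
}

excretions <- function(kid) {
  c(Na = kid$urine$T[["Na"]], K = kid$urine$T[["K"]],
    volume = kid$urine$W)
}

swap_report <- function(base, mod, regions) {
  qty <- c("Na", "K", "volume")
  seg_changes <- do.call(rbind, lapply(regions, function(rg) {
    vals <- vapply(qty, function(q) {
      b <- region_transport(base, rg, q)
      m <- region_transport(mod, rg, q)
      if (abs(b) < 1e-12) 0 else 100 * (m - b) / abs(b)
    }, numeric(1))
    data.frame(region = rg, Na = vals[["Na"]], K = vals[["K"]],
               volume = vals[["volume"]])
  }))
  eb <- excretions(base); em <- excretions(mod)
  exc_changes <- 100 * (em - eb) / eb
  list(segment_changes = seg_changes, excretion_changes = exc_changes)
}

#' Segment-swap analysis: mouse transporter activities set to rat values
#'
#' For one segment group, applies the inverse of the rat-to-mouse
#' transporter/channel activity deltas to a mouse model (restoring
#' sex-matched rat values), re-solves, and reports fractional changes in
#' segmental Na+, K+ and water transport and in urinary Na+ excretion, K+
#' excretion and urine output relative to the unmodified mouse model.
#' Geometry (lengths, diameters) and SNGFR are never modified; paracellular
#' permeabilities are included only where the rat-to-mouse column lists
#' them.
#'
#' @param params Mouse parameter set (male or female).
#' @param group One of `"PT"`, `"TAL"`, `"DCT"`, `"CNT"`, `"CCD_OMCD"`,
#'   `"IMCD"`, or `"none"` (exact no-op, for testing).
#' @param control Solver control list.
#' @param deltas Rat-to-mouse delta file list; defaults to the packaged one.
#' @param baseline Optional precomputed baseline `kidney_solution` for the
#'   unmodified parameters (the solver is deterministic, so re-solving is
#'   redundant).
#' @return List of class `swap_result`: `group`, `applied` (the inverted
#'   rows), `segment_changes` (% change per region), `excretion_changes`
#'   (% change in Na+/K+ excretion and urine output), `baseline`, `swapped`
#'   (kidney solutions).
#' @export
run_segment_swap <- function(params, group, control = list(),
                             deltas = read_deltas(file.path(params_dir(),
                                                            "deltas_mouse_m.yaml")),
                             baseline = NULL) {
  if (!identical(group, "none") && !group %in% names(.SWAP_GROUPS))
    stop("run_segment_swap: unknown group '", group, "'", call. = FALSE)
  segs <- if (identical(group, "none")) character(0) else .SWAP_GROUPS[[group]]
  rows <- list()
  for (row in deltas$rows) {
    if (!row$segment %in% segs) next
    if (is.null(row$change)) next
    if (row$parameter %in% c("Length/diameter", "SNGFR", "Plasma K")) next
    row$change <- invert_delta(row$change)
    rows[[length(rows) + 1L]] <- row
  }
  base <- baseline %||% solve_params(params, control)
  mod <- if (length(rows)) solve_params(apply_deltas(params, rows), control)
         else baseline %||% solve_params(params, control)
  rep <- swap_report(base, mod, names(.SWAP_GROUPS))
  structure(list(group = group, applied = rows,
                 segment_changes = rep$segment_changes,
                 excretion_changes = rep$excretion_changes,
                 baseline = base, swapped = mod),
            class = "swap_result")
}

# set female-mouse parameters to rat-like sex differences, referenced to
# the male-mouse values
sex_swap_params <- function(female, male, feature) {
  set_pf <- function(p, segs, ref, factor) {
    for (sid in segs)
      for (i in seq_along(p$segments[[sid]]$cells))
        p$segments[[sid]]$cells[[i]]$apical$pf <-
          ref$segments[[sid]]$cells[[i]]$apical$pf * factor
    p
  }
  set_activity <- function(p, segs, ref, target, factor) {
    for (sid in segs) {
      for (i in seq_along(p$segments[[sid]]$cells)) {
        for (side in c("apical", "basolateral")) {
          trs <- p$segments[[sid]]$cells[[i]][[side]]$transporters
          ref_trs <- ref$segments[[sid]]$cells[[i]][[side]]$transporters
          for (j in seq_along(trs)) {
            if (tr_base_name(trs[[j]]$name) != target) next
            if (identical(trs[[j]]$kind, "channel"))
              trs[[j]]$h <- ref_trs[[j]]$h * factor
            else trs[[j]]$activity <- ref_trs[[j]]$activity * factor
          }
          p$segments[[sid]]$cells[[i]][[side]]$transporters <- trs
        }
      }
    }
    p
  }
  switch(feature,
         PT_Pf = set_pf(female, c("PCT", "S3"), male, 0.64),
         TAL_NKA = set_activity(female,
                                c("mTAL", "cTAL", "DCTe", "DCTl", "CNT"),
                                male, "Na-K-ATPase", 2.0),
         ENaC = {
           f <- set_activity(female, "CNT", male, "ENaC", 1.30)
           f <- set_activity(f, "CCD", male, "ENaC", 1.50)
           set_activity(f, "OMCD", male, "ENaC", 1.20)
         },
         none = female,
         stop("run_sex_swap: unknown feature '", feature, "'", call. = FALSE))
}

#' Sex-swap analysis: female-mouse sex differences made rat-like
#'
#' Replaces one of the three sex differences that differ qualitatively
#' between the species with its rat-like counterpart, referenced to the
#' male-mouse values: proximal tubule apical water permeability set 36%
#' below male (`"PT_Pf"`); Na+-K+-ATPase along thick ascending limb, distal
#' convoluted tubule and connecting tubule doubled from male
#' (`"TAL_NKA"`); ENaC along CNT/CCD/OMCD set 30%/50%/20% above male
#' (`"ENaC"`). Reports fractional changes along the affected segments and
#' in urinary excretion relative to the unmodified female mouse.
#'
#' @param female_params,male_params Female and male mouse parameter sets.
#' @param feature `"PT_Pf"`, `"TAL_NKA"`, `"ENaC"`, or `"none"`.
#' @param control Solver control list.
#' @param baseline Optional precomputed baseline `kidney_solution`.
#' @return List of class `swap_result` (see [run_segment_swap()]), with
#'   `feature` in place of `group`.
#' @export
run_sex_swap <- function(female_params, male_params, feature,
                         control = list(), baseline = NULL) {
  mod_params <- sex_swap_params(female_params, male_params, feature)
  base <- baseline %||% solve_params(female_params, control)
  mod <- solve_params(mod_params, control)
  affected <- switch(feature,
                     PT_Pf = "PT",
                     TAL_NKA = c("TAL", "DCT", "CNT"),
                     ENaC = c("CNT", "CCD_OMCD"),
                     none = names(.SWAP_GROUPS))
  rep <- swap_report(base, mod, affected)
  structure(list(feature = feature,
                 segment_changes = rep$segment_changes,
                 excretion_changes = rep$excretion_changes,
                 baseline = base, swapped = mod),
            class = "swap_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("Protocol: %s\n", x$protocol))
  print(x$deliveries)
  if (!is.null(x$summary)) {
    cat(sprintf("urine %.3g uL/min, E_Na %.3g umol/min, E_K %.3g umol/min (per kidney)\n",
                x$summary[["urine_flow"]], x$summary[["E_Na"]],
                x$summary[["E_K"]]))
  }
  invisible(x)
}

#' @export
print.swap_result <- function(x, ...) {
  lab <- x$group %||% x$feature
  cat(sprintf("Swap experiment (%s)\n", lab))
  cat("Segmental transport changes (%):\n")
  print(format(x$segment_changes, digits = 3), row.names = FALSE)
  cat("Excretion changes (%):\n")
  print(round(x$excretion_changes, 2))
  invisible(x)
}
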