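# Parameter-delta engine: the four models (male/female x rat/mouse) are
# derived from the packaged male-rat baseline by applying columns of
# tabulated relative differences. A delta row holds a segment group, a
# parameter name, and a signed relative change; "no data" rows are explicit
# no-ops so that the packaged tables can be checked for completeness.

.SEG_GROUPS <- list(PT = c("PCT", "S3"), SDL = "SDL",
                    TAL = c("mTAL", "cTAL"), DCT = c("DCTe", "DCTl"),
                    CNT = "CNT", CCD = "CCD", OMCD = "OMCD", IMCD = "IMCD",
                    global = "global")

.ACTIVITY_PARS <- c("NHE3 activity" = "NHE3", "SGLT2 activity" = "SGLT2",
                    "NaPi activity" = "NaPi", "NKCC2 activity" = "NKCC2",
                    "KCC4 activity" = "KCC4", "NCC activity" = "NCC",
                    "NHE activity" = "NHE", "KCC activity" = "KCC",
                    "NKCC activity" = "NKCC",
                    "Na-K-ATPase activity" = "Na-K-ATPase",
                    "H-K-ATPase activity" = "H-K-ATPase",
                    "H-K-ATPase" = "H-K-ATPase",
                    "ENaC activity" = "ENaC")

tr_base_name <- function(nm) sub("\\..*$", "", nm)

# multiply the activity (or channel permeability) of every transporter in a
# membrane whose base name matches `target`; returns list(mem, n_hit)
scale_transporters <- function(mem, target, factor) {
  hits <- 0L
  mem$transporters <- lapply(mem$transporters %||% list(), function(tr) {
    if (tr_base_name(tr$name) == target) {
      hits <<- hits + 1L
      if (identical(tr$kind, "channel")) tr$h <- tr$h * factor
      else tr$activity <- tr$activity * factor
    }
    tr
  })
  list(mem = mem, hits = hits)
}

scale_h <- function(mem, solute, factor) {
  if (is.null(mem$h[[solute]])) return(list(mem = mem, hits = 0L))
  mem$h[[solute]] <- mem$h[[solute]] * factor
  list(mem = mem, hits = 1L)
}

apply_row_segment <- function(seg, parameter, factor, lfac = NULL,
                              dfac = NULL) {
  hits <- 0L
  if (parameter == "Length/diameter") {
    seg$length_cm <- seg$length_cm * (lfac %||% factor)
    seg$radius_cm <- seg$radius_cm * (dfac %||% factor)
    return(list(seg = seg, hits = 1L))
  }
  if (parameter %in% names(.ACTIVITY_PARS)) {
    target <- .ACTIVITY_PARS[[parameter]]
    for (i in seq_along(seg$cells)) {
      for (side in c("apical", "basolateral")) {
        r <- scale_transporters(seg$cells[[i]][[side]], target, factor)
        seg$cells[[i]][[side]] <- r$mem
        hits <- hits + r$hits
      }
    }
    return(list(seg = seg, hits = hits))
  }
  if (parameter == "Apical P_f") {
    for (i in seq_along(seg$cells)) {
      seg$cells[[i]]$apical$pf <- (seg$cells[[i]]$apical$pf %||% 0) * factor
      hits <- hits + 1L
    }
    return(list(seg = seg, hits = hits))
  }
  m <- regmatches(parameter,
                  regexec("^(Apical|Paracellular) P_(Na|K|Cl)(, P_(Na|K|Cl))?$",
                          parameter))[[1]]
  if (length(m)) {
    solutes <- c(m[3], if (nzchar(m[5])) m[5])
    for (sol in solutes) {
      if (m[2] == "Apical") {
        for (i in seq_along(seg$cells)) {
          r <- scale_h(seg$cells[[i]]$apical, sol, factor)
          seg$cells[[i]]$apical <- r$mem
          hits <- hits + r$hits
        }
      } else {
        r <- scale_h(seg$junction, sol, factor)
        seg$junction <- r$mem
        hits <- hits + r$hits
      }
    }
    return(list(seg = seg, hits = hits))
  }
  list(seg = seg, hits = -1L)      # unknown parameter
}

#' Apply a list of parameter deltas
#'
#' Each delta row multiplies the named parameter of the named segment group
#' by `1 + change`. Combined length/diameter rows carry separate
#' `length_change` and `diameter_change`; rows with a null change are
#' explicit no-ops. Untouched parameters are returned identical to the
#' input. Every applied row is appended to the set's provenance record with
#' tag `"delta-derived"`.
#'
#' @param params Raw parameter set (see [build_model()]).
#' @param deltas Either a delta file list (with `$rows`) as returned by
#'   [read_deltas()], or a bare list of rows.
#' @return The modified parameter set.
#' @export
#' @examples
#' p <- build_toy_fixture()
#' p2 <- apply_deltas(p, list(list(segment = "PT",
#'                                 parameter = "NHE3 activity",
#'                                 change = -0.32)))
apply_deltas <- function(params, deltas) {
  rows <- if (!is.null(deltas$rows)) deltas$rows else deltas
  prov <- params$provenance %||% list()
  for (row in rows) {
    ch <- row$change
    lfc <- row$length_change; dfc <- row$diameter_change
    if (is.null(ch) && is.null(lfc)) next              # explicit no-op
    if (!is.null(ch) && ch <= -1)
      stop("apply_deltas: relative change must exceed -1 (row ",
           row$segment, " / ", row$parameter, ")", call. = FALSE)
    segids <- .SEG_GROUPS[[row$segment]]
    if (is.null(segids))
      stop("apply_deltas: unknown segment group '", row$segment, "'",
           call. = FALSE)
    if (!is.null(row$scope)) segids <- row$scope
    if (identical(segids, "global")) {
      if (row$parameter == "SNGFR") {
        params$global$sngfr_sf <- params$global$sngfr_sf * (1 + ch)
      } else if (row$parameter == "Plasma K") {
        params$global$plasma$K <- params$global$plasma$K * (1 + ch)
      } else stop("apply_deltas: unknown global parameter '",
                  row$parameter, "'", call. = FALSE)
    } else {
      total_hits <- 0L
      for (sid in segids) {
        if (is.null(params$segments[[sid]]))
          stop("apply_deltas: segment '", sid, "' not in parameter set",
               call. = FALSE)
        r <- apply_row_segment(params$segments[[sid]], row$parameter,
                               1 + (ch %||% 0),
                               if (!is.null(lfc)) 1 + lfc,
                               if (!is.null(dfc)) 1 + dfc)
        if (r$hits < 0L)
          stop("apply_deltas: unknown parameter '", row$parameter,
               "' (row ", row$segment, ")", call. = FALSE)
        params$segments[[sid]] <- r$seg
        total_hits <- total_hits + r$hits
      }
      if (total_hits == 0L)
        stop("apply_deltas: parameter '", row$parameter,
             "' not present in segment group '", row$segment, "'",
             call. = FALSE)
    }
    prov[[length(prov) + 1L]] <- list(
      path = paste0(row$segment, "/", row$parameter),
      tag = "delta-derived",
      change = ch %||% NA_real_)
  }
  params$provenance <- prov
  params
}

#' Restoring increase for a relative change
#'
#' The relative increase that undoes a prior relative change:
#' `1/(1 + change) - 1`. Applying a delta and then its inverse is the
#' identity; a -32% change is undone by a +47% increase.
#'
#' @param change Signed relative change, > -1.
#' @return The inverse relative change.
#' @export
#' @examples
#' invert_delta(-0.32)    # ~ +0.47
invert_delta <- function(change) {
  if (any(change <= -1)) stop("invert_delta: change must exceed -1",
                              call. = FALSE)
  1 / (1 + change) - 1
}

#' Read a parameter or delta configuration file
#'
#' @param path YAML file.
#' @return Nested list.
#' @export
read_params <- function(path) yaml::read_yaml(path)

#' @rdname read_params
#' @export
read_deltas <- function(path) yaml::read_yaml(path)

#' Write a parameter set to YAML
#'
#' @param params Parameter set.
#' @param path Output file.
#' @export
write_params <- function(params, path) {
  yaml::write_yaml(params, path, precision = 12)
  invisible(path)
}

params_dir <- function() {
  d <- system.file("extdata", "params", package = "nephrosim")
  if (!nzchar(d)) stop("packaged parameter files not found", call. = FALSE)
  d
}

#' Build one of the four packaged kidney models
#'
#' Loads the male-rat baseline configuration and derives the requested model
#' by the documented delta chains: male rat (identity), female rat
#' (male-to-female rat column), male mouse (rat-to-mouse column plus
#' species overrides: 12,000 nephrons, juxtamedullary SNGFR ratio 1.20 and
#' mouse class weights), female mouse (male mouse plus the mouse
#' male-to-female column).
#'
#' @param species `"rat"` or `"mouse"`.
#' @param sex `"male"` or `"female"`.
#' @param dir Directory holding `rat_male.yaml` and the delta files
#'   (defaults to the packaged configuration).
#' @return Raw parameter set; pass to [compile_model()].
#' @export
build_model <- function(species = c("rat", "mouse"),
                        sex = c("male", "female"),
                        dir = params_dir()) {
  species <- match.arg(species)
  sex <- match.arg(sex)
  params <- read_params(file.path(dir, "rat_male.yaml"))
  params$provenance <- list(list(path = "(baseline)",
                                 tag = params$meta$provenance %||% "transcribed",
                                 change = NA_real_))
  if (species == "mouse") {
    dm <- read_deltas(file.path(dir, "deltas_mouse_m.yaml"))
    params <- apply_deltas(params, dm)
    for (nm in names(dm$overrides %||% list()))
      params$global[[nm]] <- dm$overrides[[nm]]
    if (sex == "female")
      params <- apply_deltas(params,
                             read_deltas(file.path(dir, "deltas_mouse_f.yaml")))
  } else if (sex == "female") {
    params <- apply_deltas(params,
                           read_deltas(file.path(dir, "deltas_rat_f.yaml")))
  }
  params$meta$species <- species
  params$meta$sex <- sex
  params$meta$label <- paste(species, sex, sep = "_")
  params
}

#' Provenance report for a parameter set
#'
#' Summarizes where values came from: the baseline tag plus every
#' delta-derived modification recorded by [apply_deltas()].
#'
#' @param params Parameter set.
#' @return data.frame with columns `path`, `tag`, `change`.
#' @export
provenance_report <- function(params) {
  prov <- params$provenance %||%
    list(list(path = "(baseline)",
              tag = params$meta$provenance %||% "transcribed",
              change = NA_real_))
  do.call(rbind, lapply(prov, function(p)
    data.frame(path = p$path, tag = p$tag,
               change = p$change %||% NA_real_)))
}
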