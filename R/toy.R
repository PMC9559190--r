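# Reduced "toy nephron" parameter set: same structure and schema as the
# full baseline (so every delta row resolves and every code path runs),
# but short segments and coarse grids for fast tests.

#' Build the toy fixture parameter set
#'
#' A miniature, self-consistent parameter set: two nephron classes (one
#' superficial, one juxtamedullary with a 2 mm loop), segment lengths
#' scaled down to about a third, and coarse axial grids. It exercises the
#' compliant torque-modulated proximal tubule, the coalescing connecting
#' tubule and inner-medullary collecting duct, and both principal and
#' intercalated collecting-duct cells. All values are tagged `"fixture"`.
#'
#' @return Raw parameter set; pass to [compile_model()].
#' @export
#' @examples
#' toy <- build_toy_fixture()
#' names(toy$segments)
build_toy_fixture <- function() {
  p <- params_rat_male()
  p$meta <- list(label = "toy", species = "rat", sex = "male",
                 provenance = "fixture")
  p$global$class_weights <- list(SF = 0.75, JM2 = 0.25)
  p$global$loop_depths_mm <- list(JM2 = 2)
  scale_L <- 0.3
  ngrid <- c(PCT = 7L, S3 = 4L, SDL = 5L, LDL = 3L, LAL = 3L, mTAL = 7L,
             cTAL = 6L, DCTe = 3L, DCTl = 3L, CNT = 5L, CCD = 3L,
             OMCD = 6L, IMCD = 24L)
  for (id in names(p$segments)) {
    p$segments[[id]]$length_cm <- p$segments[[id]]$length_cm * scale_L
    p$segments[[id]]$n_grid <- ngrid[[id]]
  }
  p$provenance <- list(list(path = "(baseline)", tag = "fixture",
                            change = NA_real_))
  p
}
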