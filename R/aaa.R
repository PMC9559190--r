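# Package-level constants shared across files (this file collates first).

.SOLUTES <- data.frame(
  name    = c("Na", "K", "Cl", "HCO3", "H2CO3", "CO2", "NH3", "NH4",
              "HPO4", "H2PO4", "H", "HCO2", "H2CO2", "urea", "glucose"),
  display = c("Na+", "K+", "Cl-", "HCO3-", "H2CO3", "CO2", "NH3", "NH4+",
              "HPO4 2-", "H2PO4-", "H+", "HCO2-", "H2CO2", "urea", "glucose"),
  z       = c(1L, 1L, -1L, -1L, 0L, 0L, 0L, 1L,
              -2L, -1L, 1L, -1L, 0L, 0L, 0L),
  reacting = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE,
               TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
  stringsAsFactors = FALSE
)

.NSOL  <- 15L
.IX    <- 16L                       # impermeant slot
.SNAME <- c(.SOLUTES$name, "X")

# integer indices, used throughout the solver hot path
.I <- as.list(seq_len(16L))
names(.I) <- .SNAME

# valences with a neutral placeholder in the impermeant slot; compartments
# with charged impermeants override slot 16 locally
.Z16 <- c(.SOLUTES$z, 0)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname water_flux
#' @export
PERM_CM_S <- 6e7   # nL min-1 cm-2 per (cm/s): 1e6 nL/cm3 * 60 s/min

.CONST <- local({
  R <- 8.314462618; T_K <- 310.15; F <- 96485.33212
  rt <- R * T_K
  list(R = R, T = T_K, F = F,
       rt_mmhg = rt / 133.322368,
       rt_f_mv = 1000 * rt / F)
})
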