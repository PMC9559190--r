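test_that("solute table carries the fixed 15-species chemistry", {
  tab <- solute_table()
  expect_identical(nrow(tab), 15L)
  expect_identical(tab$z[tab$name == "Na"], 1L)
  expect_identical(tab$z[tab$name == "HPO4"], -2L)
  expect_identical(sum(tab$z), -2L)   # net valence of the 15 species
  k <- physical_constants()
  expect_true(all(unlist(k) > 0))
})

test_that("buffer residuals vanish at mass action and respond to departures", {
  pairs <- buffer_pairs()
  pH <- 7.4
  H <- 10^(-pH) * 1e3
  st <- c(H = H)
  for (i in seq_len(nrow(pairs))) {
    acid <- 1.0
    base <- acid * 10^(pH - pairs$pK[i])
    st[pairs$acid[i]] <- acid
    st[pairs$base[i]] <- base
  }
  expect_equal(unname(buffer_residuals(st, pairs)), rep(0, 4), tolerance = 1e-12)

  # doubling only the acid concentration departs from equilibrium
  st2 <- st
  st2[pairs$acid[1]] <- 2 * st2[pairs$acid[1]]
  expect_gt(abs(buffer_residuals(st2, pairs)[1]), 0.1)

  # random states agree with an independent recomputation of the
  # mass-action expression, and swapping labels negates the residual
  set.seed(11)
  for (rep in 1:20) {
    stR <- st
    for (s in c(pairs$acid, pairs$base)) stR[s] <- runif(1, 0.01, 10)
    stR["H"] <- 10^(-runif(1, 6, 8)) * 1e3
    got <- buffer_residuals(stR, pairs)
    pHr <- -log10(stR[["H"]] * 1e-3)
    want <- log10(stR[pairs$base] / stR[pairs$acid]) - (pHr - pairs$pK)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
    swapped <- pairs
    swapped$acid <- pairs$base; swapped$base <- pairs$acid
    swapped$pK <- -pairs$pK    # formal label swap: ratio inverts
    expect_equal(unname(log10(stR[swapped$base] / stR[swapped$acid])),
                 -unname(log10(stR[pairs$base] / stR[pairs$acid])),
                 tolerance = 1e-12)
  }
})

test_that("buffer residuals reject non-positive concentrations", {
  st <- c(H = 4e-5, HPO4 = 1, H2PO4 = 0, NH3 = 1, NH4 = 1,
          HCO2 = 1, H2CO2 = 1, HCO3 = 1, H2CO3 = 1)
  expect_error(buffer_residuals(st, compartment = "cell"),
               "H2PO4.*cell")
})

test_that("luminal speciation satisfies electroneutrality and conserves totals", {
  chem <- chemistry_constants()
  tot <- c(Na = 140, K = 4, Cl = 116, urea = 8, glucose = 1,
           totP = 2, totN = 0.5, totF = 1)
  sp <- nephrosim:::lumen_species(tot[nephrosim:::.CARRIED], chem, co2 = 1.2)
  z <- c(solute_table()$z, 0)
  expect_lt(abs(sum(z * sp$c16)), 1e-9)
  back <- nephrosim:::species_to_carried(sp$c16)
  expect_equal(back[1:8], unname(tot[nephrosim:::.CARRIED]), tolerance = 1e-12)
  # pair equilibria hold in the recovered speciation
  expect_equal(unname(buffer_residuals(sp$c16[1:15], buffer_pairs())),
               rep(0, 4), tolerance = 1e-10)
})
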