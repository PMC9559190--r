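# Cross-section solves against closed-form oracles and self-consistency.

test_that("passive cross-section matches the two-resistor closed form", {
  # urea is uncharged and uncoupled: at steady state its cell concentration
  # is the permeability-weighted mean of lumen and bath
  fx <- passive_spec(h_ap_urea = 0.8, h_bl_urea = 0.2)
  pl <- plasma_lumen(fx$model, scale_urea = 3)   # lumen urea 3x bath
  ep <- solve_epithelium(fx$seg$ep, pl$lumen, pl$bath)
  a <- 0.8 * fx$seg$ep$cells[[1]]$apical$area
  b <- 0.2 * fx$seg$ep$cells[[1]]$basolateral$area
  u_l <- pl$lumen$c16[["urea"]]; u_b <- pl$bath$c16[["urea"]]
  want <- (a * u_l + b * u_b) / (a + b)
  got <- ep$state$cells[[1]]$c16[[14]]
  expect_equal(got, want, tolerance = 2e-3)
  # converges from the default (bath-composition) initialization quickly
  expect_lte(ep$iters, 25)
})

test_that("converged solutions re-evaluate to tiny residuals and are stable", {
  fx <- passive_spec(0.5, 0.5)
  pl <- plasma_lumen(fx$model)
  ep <- solve_epithelium(fx$seg$ep, pl$lumen, pl$bath)
  r <- epithelial_residuals(ep, fx$seg$ep)
  expect_lt(max(abs(r)), 1e-10)

  # perturbing the converged state by <= 1% and re-solving returns to the
  # same solution (local uniqueness probe)
  set.seed(7)
  x1 <- ep$x * (1 + runif(length(ep$x), -0.01, 0.01))
  ep2 <- solve_epithelium(fx$seg$ep, pl$lumen, pl$bath, guess = x1)
  expect_equal(ep2$state$cells[[1]]$c16, ep$state$cells[[1]]$c16,
               tolerance = 1e-8)

  # identical inputs and settings give identical iterates (determinism)
  ep3 <- solve_epithelium(fx$seg$ep, pl$lumen, pl$bath)
  expect_identical(ep3$x, ep$x)
})

test_that("zero-permeability membranes carry exactly zero flux", {
  fx <- passive_spec(0.5, 0.5)
  spec <- fx$seg$ep
  spec$junction$h[2] <- 0                     # junctional K+ path removed
  spec$junction <- nephrosim:::finalize_membrane(spec$junction)
  pl <- plasma_lumen(fx$model)
  ep <- solve_epithelium(spec, pl$lumen, pl$bath)
  expect_identical(unname(ep$fluxes$junction$electrodiffusive[2]), 0)
})

test_that("mass and current conservation hold at the solution", {
  fx <- passive_spec(0.5, 0.5)
  pl <- plasma_lumen(fx$model)
  ep <- solve_epithelium(fx$seg$ep, pl$lumen, pl$bath)
  cl <- fx$seg$ep$cells[[1]]
  z <- c(solute_table()$z, 0)
  influx <- ep$storq * cl$apical$area * ep$fluxes[[cl$tag]]$apical$js -
    cl$basolateral$area * ep$fluxes[[cl$tag]]$basolateral$js
  # per-solute steady state for the non-reacting species
  for (i in c(1, 2, 3, 14, 15)) {
    gross <- max(abs(cl$apical$area * ep$fluxes[[cl$tag]]$apical$js[i]),
                 abs(cl$basolateral$area *
                       ep$fluxes[[cl$tag]]$basolateral$js[i]), 1e-4)
    expect_lt(abs(influx[i]) / gross, 1e-8)
  }
  # apical current equals basolateral exit current (cell charge balance)
  i_ap <- sum(z[1:15] * cl$apical$area * ep$fluxes[[cl$tag]]$apical$js[1:15])
  i_bl <- sum(z[1:15] * cl$basolateral$area *
                ep$fluxes[[cl$tag]]$basolateral$js[1:15])
  expect_equal(i_ap, i_bl, tolerance = 1e-6)
})
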