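test_that("coalescence fractions follow the printed formulas", {
  expect_identical(omega_cnt(0, 1), 1)
  expect_equal(omega_cnt(0.5, 1, clamp = FALSE), 2 - sqrt(2.32),
               tolerance = 1e-12)
  expect_equal(omega_cnt(1, 1, clamp = FALSE), 2 - 2.32, tolerance = 1e-12)
  expect_equal(omega_cnt(1, 1), 0.182)        # clamped at the floor
  xs <- seq(0, 1, length.out = 41)
  expect_true(all(diff(omega_cnt(xs, 1, clamp = FALSE)) < 0))
  expect_error(omega_cnt(1.2, 1), "outside")

  expect_identical(omega_imcd(0, 1), 0.1)
  expect_equal(omega_imcd(0.5, 1), 0.1 * (1 - 0.95 * 0.25) * exp(-1.375),
               tolerance = 1e-12)
  expect_equal(omega_imcd(1, 1), 0.1 * 0.05 * exp(-2.75), tolerance = 1e-12)
  expect_equal(omega_imcd(1, 1), 3.195e-4, tolerance = 1e-3)
  expect_true(all(diff(omega_imcd(xs, 1)) < 0))
  expect_error(omega_imcd(-0.1, 1), "outside")
})

test_that("luminal derivatives recover Poiseuille and conservation", {
  st <- list(W = 12, P = 10,
             T = stats::setNames(rep(10, 8), nephrosim:::.CARRIED))
  visc <- 8.75e-8; r <- 1e-3
  rhs <- lumen_rhs(st, list(jv = 0, carried = rep(0, 8)), r = r,
                   omega = 1, visc = visc)
  expect_identical(rhs$dW, 0)
  expect_true(all(rhs$dT == 0))
  expect_equal(rhs$dP, -8 * visc * (12e-6) / (pi * r^4), tolerance = 1e-12)

  # reabsorptive flux reduces luminal content, scaled by the tubule fraction
  rhs2 <- lumen_rhs(st, list(jv = 2, carried = c(5, rep(0, 7))), r = r,
                    omega = 0.5, visc = visc)
  expect_equal(rhs2$dW, -1)
  expect_equal(rhs2$dT[["Na"]], -2.5)
  expect_error(lumen_rhs(st, list(jv = NaN, carried = rep(0, 8)), r, 1, visc),
               "non-finite")
})

test_that("a zero-length segment is the identity", {
  m <- compile_model(toy_params())
  sg <- m$chains$SF$PCT
  sg$L <- 0
  inlet <- list(W = 10, P = 10, T = 10 * m$filtrate)
  names(inlet$T) <- nephrosim:::.CARRIED
  out <- solve_segment(inlet, sg, m$bath_fun, tau0 = m$tau0[["SF"]])
  expect_identical(out$outlet, inlet)
  expect_true(all(out$reab == 0))
})

test_that("without transmural transport, flows are constant and pressure falls", {
  p <- toy_params()
  seg <- p$segments$SDL
  # strip all transport: impermeable, inactive epithelium
  seg$cells[[1]]$apical$h <- list()
  seg$cells[[1]]$apical$pf <- 0
  seg$cells[[1]]$apical$transporters <- list()
  seg$junction$h <- list(); seg$junction$pf <- 0
  seg$depth_start <- 0; seg$depth_end <- 0
  chem <- nephrosim:::compile_chem(p)
  ka <- nephrosim:::.ka_mM(chem$pairs$pK); names(ka) <- chem$pairs$acid
  sg <- nephrosim:::compile_segment(seg, p, chem, ka)
  m <- compile_model(p)
  inlet <- list(W = 10, P = 10, T = 10 * m$filtrate)
  names(inlet$T) <- nephrosim:::.CARRIED
  out <- solve_segment(inlet, sg, m$bath_fun)
  expect_equal(unname(out$outlet$W), 10, tolerance = 1e-6)
  expect_equal(unname(out$outlet$T), unname(inlet$T), tolerance = 1e-6)
  # Poiseuille drop for constant flow is linear in x
  dP <- diff(out$profile$P)
  expect_lt(out$outlet$P, inlet$P)
  expect_equal(max(dP), min(dP), tolerance = 1e-4)
})

test_that("water abstraction concentrates a luminally impermeant solute", {
  p <- toy_params()
  seg <- p$segments$SDL
  # make glucose strictly impermeant on the luminal side; water still leaves
  seg$cells[[1]]$apical$h$glucose <- 0
  seg$junction$h$glucose <- 0
  seg$junction$pf <- 0                 # no junctional solvent drag
  seg$cells[[1]]$apical$transporters <- list()
  chem <- nephrosim:::compile_chem(p)
  ka <- nephrosim:::.ka_mM(chem$pairs$pK); names(ka) <- chem$pairs$acid
  sg <- nephrosim:::compile_segment(seg, p, chem, ka)
  m <- compile_model(p)
  inlet <- list(W = 10, P = 10, T = 10 * m$filtrate)
  names(inlet$T) <- nephrosim:::.CARRIED
  out <- solve_segment(inlet, sg, m$bath_fun)
  # the luminal glucose load is untouched while water is reabsorbed,
  # so its concentration strictly increases downstream
  expect_equal(unname(out$outlet$T[["glucose"]]),
               unname(inlet$T[["glucose"]]), tolerance = 1e-9)
  expect_lt(out$outlet$W, inlet$W)
  expect_gt(tail(out$profile$glucose, 1), out$profile$glucose[1])
})
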