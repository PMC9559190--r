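k <- physical_constants()

test_that("water flux follows the osmotic + hydrostatic law", {
  expect_identical(water_flux(1, 1, 1, dC = 0, dP = 0), 0)
  expect_identical(water_flux(2, 3, 0, dC = c(5, -2), dP = 0), 0)
  # unit membrane, unit Lp, 1 mM gradient: RT in mmHg
  expect_equal(water_flux(1, 1, 1, dC = 1, dP = 0), k$rt_mmhg,
               tolerance = 1e-12)
  # antisymmetry under swapping compartments
  dC <- c(3, -1, 0.5); dP <- 2.5
  expect_equal(water_flux(1.3, 0.7, 0.9, dC, dP),
               -water_flux(1.3, 0.7, 0.9, -dC, -dP), tolerance = 1e-12)
})

test_that("log-mean concentration is bounded, continuous and symmetric", {
  expect_equal(log_mean_conc(10, 10), 10)
  expect_equal(log_mean_conc(100, 50), 50 / log(2), tolerance = 1e-12)
  set.seed(4)
  a <- runif(50, 0.01, 300); b <- runif(50, 0.01, 300)
  m <- log_mean_conc(a, b)
  expect_true(all(m >= pmin(a, b) - 1e-12 & m <= pmax(a, b) + 1e-12))
  expect_equal(m, log_mean_conc(b, a), tolerance = 1e-12)
  expect_error(log_mean_conc(-1, 2), "positive")
})

test_that("electrodiffusion: Fick for uncharged, GHK for ions, smooth limit", {
  expect_equal(electrodiffusive_flux(1, 0, 12, 2, dv = 50), 10)
  # GHK converges to Fick as the potential vanishes
  for (ca in c(1, 20, 150)) for (cb in c(0.5, 80, 140)) {
    fick <- 1 * (ca - cb)
    ghk <- electrodiffusive_flux(1, 1, ca, cb, dv = 1e-9)
    if (abs(fick) > 0) expect_lt(abs(ghk - fick) / abs(fick), 1e-8)
  }
  # equal concentrations: flux is exactly h * zeta * C
  for (zeta in -5:5) {
    if (zeta == 0) next
    dv <- zeta * k$rt_f_mv
    expect_equal(electrodiffusive_flux(2, 1, 30, 30, dv), 2 * zeta * 30,
                 tolerance = 1e-10)
  }
  # antisymmetry
  expect_equal(electrodiffusive_flux(1, -1, 80, 120, dv = 13),
               -electrodiffusive_flux(1, -1, 120, 80, dv = -13),
               tolerance = 1e-12)
})

test_that("convective flux vanishes at full reflection or zero water flux", {
  expect_identical(convective_flux(1, 123, 9), 0)
  expect_identical(convective_flux(0.4, 123, 0), 0)
  expect_equal(convective_flux(0.3, 100, 2), 140)
  expect_error(convective_flux(1.2, 1, 1), "sigma")
})

test_that("coupled transport: strict stoichiometry, zero at equilibrium", {
  z <- c(Na = 1, K = 1, Cl = -1, H = 1, glucose = 0)
  nkcc2 <- list(name = "NKCC2", kind = "coupled", activity = 50,
                stoich = c(Na = 1, K = 1, Cl = 2))
  ca <- c(Na = 140, K = 5, Cl = 110, H = 4e-5, glucose = 5)
  cb <- c(Na = 15, K = 140, Cl = 20, H = 6e-5, glucose = 1)
  j <- coupled_flux(nkcc2, ca, cb, 0, -70, z)
  expect_equal(unname(j / j[["Na"]]), c(1, 1, 2), tolerance = 1e-12)

  # linear form equals an independent stoichiometry-weighted summation
  drive <- sum(c(1, 1, 2) * (log(ca[c("Na", "K", "Cl")] /
                               cb[c("Na", "K", "Cl")]) +
                               z[c("Na", "K", "Cl")] * 70 / k$rt_f_mv))
  expect_equal(j[["Cl"]], 50 * drive * 2, tolerance = 1e-10)

  # equilibrium states give zero flux, for many random stoichiometries
  set.seed(99)
  for (i in 1:1000) {
    s <- sample(c(-2, -1, 1, 2), 2)
    names(s) <- sample(names(z)[1:4], 2)
    tr <- list(name = "x", kind = "coupled", activity = runif(1, 1, 100),
               stoich = s)
    cb2 <- ca
    dv <- runif(1, -60, 60)
    # choose cb so that the stoichiometry-weighted gradient vanishes:
    # perturb one solute and solve for the other
    s1 <- names(s)[1]; s2 <- names(s)[2]
    cb2[s1] <- ca[s1] * runif(1, 0.5, 2)
    mu1 <- log(ca[s1] / cb2[s1]) + z[s1] * dv / k$rt_f_mv
    # s[1]*mu1 + s[2]*mu2 = 0  =>  mu2 = -s1/s2 * mu1
    mu2 <- -s[[1]] / s[[2]] * mu1
    cb2[s2] <- ca[s2] / exp(mu2 - z[s2] * dv / k$rt_f_mv)
    j <- coupled_flux(tr, ca, cb2, dv, 0, z)
    expect_lt(max(abs(j)), 1e-12)
  }

  expect_error(coupled_flux(list(kind = "atpase"), ca, cb, 0, 0, z),
               "coupled")
})

test_that("ATPase flux saturates, respects stoichiometry, needs substrate", {
  nka <- list(name = "NKA", kind = "atpase",
              stoich = c(Na = 3, K = -2), activity = 100,
              sites = list(list(solute = "Na", side = "a", K = 10, n = 3),
                           list(solute = "K", side = "b", K = 1.5, n = 2)))
  ca <- c(Na = 0, K = 140); cb <- c(Na = 140, K = 5)
  expect_equal(unname(atpase_flux(nka, ca, cb)), c(0, 0))
  ca["Na"] <- 1e9; cb["K"] <- 1e9
  j <- atpase_flux(nka, ca, cb)
  expect_equal(j[["Na"]], 300, tolerance = 1e-4)   # 3 x activity at saturation
  ca["Na"] <- 17; cb["K"] <- 4.2
  j <- atpase_flux(nka, ca, cb)
  expect_equal(abs(j[["Na"]] / j[["K"]]), 1.5, tolerance = 1e-12)
  expect_error(atpase_flux(nka, c(Na = -1, K = 5), cb), "negative")
})

test_that("compliant radius, microvillous torque and torque scale", {
  expect_equal(compliant_radius(1, 0.2, 10, 10), 1)
  expect_equal(compliant_radius(1, 0, 25, 10), 1)
  expect_equal(compliant_radius(1, 0.2, 10.5, 10), 1.1)
  expect_error(compliant_radius(1, 0.2, -100, 10), "radius")

  expect_identical(microvillous_torque(0, 1e-3, 2e-4, 1e-5, 1e-7), 0)
  t1 <- microvillous_torque(2e-5, 1e-3, 2e-4, 1e-5, 1e-7)
  expect_equal(microvillous_torque(4e-5, 1e-3, 2e-4, 1e-5, 1e-7), 2 * t1,
               tolerance = 1e-12)
  # term-by-term independent evaluation at random parameters
  set.seed(3)
  for (i in 1:25) {
    q <- runif(1, 1e-6, 1e-4); r <- runif(1, 5e-4, 3e-3)
    l <- runif(1, 1e-4, 5e-4); d <- runif(1, 1e-5, 5e-5)
    mu <- runif(1, 1e-8, 1e-6)
    want <- 8 * mu * q * l / r^2 * (1 + (l + d) / r + l^2 / (2 * r^2))
    expect_equal(microvillous_torque(q, r, l, d, mu), want,
                 tolerance = 1e-12)
  }
  # strictly decreasing in radius at fixed flow
  rr <- seq(5e-4, 3e-3, length.out = 20)
  tt <- microvillous_torque(1e-5, rr, 2e-4, 1e-5, 1e-7)
  expect_true(all(diff(tt) < 0))

  expect_equal(torque_scale(10, 10, 0.7), 1)
  expect_equal(torque_scale(20, 10, 0.7), 1.7)
  expect_equal(torque_scale(123, 10, 0), 1)
  expect_equal(torque_scale(0, 10, 5, floor = 0), 0)  # clamped
  expect_error(torque_scale(1, -1, 0.5), "positive")
})

test_that("total solute flux decomposes into its four mechanisms", {
  ca <- stats::setNames(rep(1, 15), solute_table()$name)
  cb <- ca
  ca["Na"] <- 140; cb["Na"] <- 14; ca["K"] <- 4; cb["K"] <- 130
  out <- total_solute_flux("Na", h = 2, sigma_k = 0.4, ca, cb,
                           va = -5, vb = -65, jv = 3,
                           transporters = list(
                             list(name = "NHE3", kind = "coupled",
                                  stoich = c(Na = 1, H = -1), activity = 10)))
  expect_equal(out$total,
               out$convective + out$electrodiffusive + out$coupled +
                 out$atpase, tolerance = 1e-12)
  # uncharged solute with only passive permeability: Fick alone
  out2 <- total_solute_flux("urea", h = 1.5, sigma_k = 1, ca * 2, ca,
                            va = 10, vb = 0, jv = 4)
  expect_equal(out2$total, 1.5 * (2 - 1), tolerance = 1e-12)
  expect_equal(out2$convective, 0)
})
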