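dirp <- system.file("extdata", "params", package = "nephrosim")

test_that("delta application follows value_new = value * (1 + change)", {
  p <- build_toy_fixture()
  act0 <- p$segments$PCT$cells[[1]]$apical$transporters[[1]]$activity
  p2 <- apply_deltas(p, list(list(segment = "PT",
                                  parameter = "NHE3 activity",
                                  change = -0.32)))
  act1 <- p2$segments$PCT$cells[[1]]$apical$transporters[[1]]$activity
  expect_equal(act1, act0 * 0.68, tolerance = 1e-12)
  # and the NH4-substitution mode scales with it
  expect_equal(p2$segments$PCT$cells[[1]]$apical$transporters[[2]]$activity,
               p$segments$PCT$cells[[1]]$apical$transporters[[2]]$activity *
                 0.68, tolerance = 1e-12)
  # arithmetic composition across columns: 100 -> 68 -> 44.2
  p3 <- apply_deltas(p2, list(list(segment = "PT",
                                   parameter = "NHE3 activity",
                                   change = -0.35)))
  act2 <- p3$segments$PCT$cells[[1]]$apical$transporters[[1]]$activity
  expect_equal(act2 / act0, 0.442, tolerance = 1e-12)

  # empty list is the identity
  expect_identical(apply_deltas(p, list())$segments, p$segments)
  # unknown rows fail loudly
  expect_error(apply_deltas(p, list(list(segment = "PT",
                                         parameter = "warp drive",
                                         change = 0.1))), "unknown parameter")
  expect_error(apply_deltas(p, list(list(segment = "medulla oblongata",
                                         parameter = "NHE3 activity",
                                         change = 0.1))), "segment")
})

test_that("invert_delta restores a relative change exactly", {
  expect_equal(invert_delta(-0.32), 0.470588, tolerance = 1e-5)
  expect_identical(invert_delta(0), 0)
  expect_equal(invert_delta(-0.5), 1)
  expect_error(invert_delta(-1), "exceed")
  # round trip: apply then invert reproduces the base set to 1e-12
  p <- build_toy_fixture()
  ch <- -0.27
  p2 <- apply_deltas(p, list(list(segment = "DCT", parameter = "NCC activity",
                                  change = ch)))
  p3 <- apply_deltas(p2, list(list(segment = "DCT", parameter = "NCC activity",
                                   change = invert_delta(ch))))
  a0 <- p$segments$DCTe$cells[[1]]$apical$transporters[[1]]$activity
  a3 <- p3$segments$DCTe$cells[[1]]$apical$transporters[[1]]$activity
  expect_equal(a3, a0, tolerance = 1e-12)
})

test_that("geometry deltas rescale length and diameter (area ~ L x d)", {
  p <- build_toy_fixture()
  p2 <- apply_deltas(p, list(list(segment = "PT",
                                  parameter = "Length/diameter",
                                  length_change = -0.636,
                                  diameter_change = -0.20)))
  expect_equal(p2$segments$PCT$length_cm, p$segments$PCT$length_cm * 0.364,
               tolerance = 1e-12)
  expect_equal(p2$segments$S3$radius_cm, p$segments$S3$radius_cm * 0.8,
               tolerance = 1e-12)
})

test_that("the packaged delta tables are complete and fully resolvable", {
  rows_of <- function(f) {
    d <- read_deltas(file.path(dirp, f))
    vapply(d$rows, function(r) paste(r$segment, r$parameter, sep = " / "),
           character(1))
  }
  r1 <- rows_of("deltas_rat_f.yaml")
  r2 <- rows_of("deltas_mouse_m.yaml")
  r3 <- rows_of("deltas_mouse_f.yaml")
  # all three columns enumerate the same table rows
  expect_setequal(r1, r2)
  expect_setequal(r1, r3)
  # the full tabulated row list, one entry per segment/parameter pair
  want <- c(
    "global / SNGFR", "global / Plasma K",
    paste("PT /", c("Length/diameter", "NHE3 activity", "SGLT2 activity",
                    "NaPi activity", "Paracellular P_Na", "Paracellular P_Cl",
                    "Apical P_f")),
    "SDL / Length/diameter",
    paste("TAL /", c("Length/diameter", "Na-K-ATPase activity",
                     "NHE activity", "NaPi activity", "NKCC2 activity",
                     "KCC4 activity", "Paracellular P_Na",
                     "Paracellular P_Cl")),
    paste("DCT /", c("Length/diameter", "NCC activity",
                     "Na-K-ATPase activity", "Apical P_K", "ENaC activity",
                     "Apical P_f", "Paracellular P_Na", "Paracellular P_Cl",
                     "NHE activity", "NaPi activity")),
    paste("CNT /", c("Length/diameter", "Apical P_K", "H-K-ATPase",
                     "Apical P_f", "Paracellular P_Na", "Paracellular P_Cl",
                     "NHE activity", "NaPi activity", "Na-K-ATPase activity",
                     "ENaC activity")),
    paste("CCD /", c("Length/diameter", "H-K-ATPase", "Apical P_f",
                     "Apical P_K", "Paracellular P_Na", "Paracellular P_Cl",
                     "NHE activity", "NaPi activity", "Na-K-ATPase activity",
                     "ENaC activity")),
    paste("OMCD /", c("Length/diameter", "H-K-ATPase", "Apical P_f",
                      "Apical P_K", "Apical P_Na, P_Cl", "NHE activity",
                      "NaPi activity", "Na-K-ATPase activity",
                      "ENaC activity")),
    paste("IMCD /", c("Length/diameter", "NHE activity",
                      "Na-K-ATPase activity", "H-K-ATPase activity",
                      "Paracellular P_Na", "Apical P_f", "Apical P_Na",
                      "Apical P_K", "Paracellular P_K", "Paracellular P_Cl",
                      "KCC activity", "NKCC activity")))
  expect_setequal(r1, want)

  # every non-null row resolves against both the packaged baseline and the
  # toy fixture without error
  base <- read_params(file.path(dirp, "rat_male.yaml"))
  toy <- build_toy_fixture()
  for (f in c("deltas_rat_f.yaml", "deltas_mouse_m.yaml",
              "deltas_mouse_f.yaml")) {
    d <- read_deltas(file.path(dirp, f))
    expect_no_error(apply_deltas(base, d))
    expect_no_error(apply_deltas(toy, d))
  }
})

test_that("model building follows the documented delta chains", {
  base <- read_params(file.path(dirp, "rat_male.yaml"))
  rm_ <- build_model("rat", "male")
  expect_identical(rm_$segments, base$segments)
  expect_identical(rm_$global$sngfr_sf, base$global$sngfr_sf)

  mm <- build_model("mouse", "male")
  expect_equal(mm$global$sngfr_sf, base$global$sngfr_sf * (1 - 0.667),
               tolerance = 1e-12)
  expect_identical(mm$global$nephrons, 12000L)
  expect_equal(mm$global$jm_sngfr_ratio, 1.2)

  mf <- build_model("mouse", "female")
  expect_equal(mf$global$sngfr_sf, mm$global$sngfr_sf * 0.8,
               tolerance = 1e-12)
  expect_equal(mf$global$plasma$K, mm$global$plasma$K * 0.93,
               tolerance = 1e-12)

  rf <- build_model("rat", "female")
  expect_equal(rf$global$plasma$K, base$global$plasma$K * 0.90,
               tolerance = 1e-12)

  # provenance: baseline tag plus delta-derived records
  pr <- provenance_report(mf)
  expect_identical(pr$tag[1], "transcribed")
  expect_gt(sum(pr$tag == "delta-derived"), 40)
})

test_that("the toy fixture is tagged and structurally complete", {
  toy <- build_toy_fixture()
  expect_identical(toy$meta$provenance, "fixture")
  expect_true(all(c("PCT", "S3", "SDL", "LDL", "LAL", "mTAL", "cTAL",
                    "DCTe", "DCTl", "CNT", "CCD", "OMCD", "IMCD") %in%
                    names(toy$segments)))
  expect_true(toy$segments$PCT$compliant)
  expect_identical(toy$segments$CNT$coalesce, "cnt")
  expect_identical(toy$segments$IMCD$coalesce, "imcd")
  expect_identical(length(toy$segments$CCD$cells), 2L)  # both cell types
})
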