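test_that("excretion ratio reproduces the bolus-normalized arithmetic", {
  expect_equal(round(excretion_ratio(47, 54, 0.5), 2), 1.74)
  expect_equal(round(excretion_ratio(10, 11, 1 / 1.3), 2), 1.18)
  expect_identical(excretion_ratio(5, 5, 1), 1)
  expect_error(excretion_ratio(-1, 2, 0.5), "positive")
})

test_that("fractional deliveries normalize to filtered load", {
  del <- data.frame(boundary = c("PT", "urine"),
                    volume = c(20, 5), Na = c(40, 2))
  fd <- fractional_delivery(del, filtered = c(volume = 20, Na = 40))
  expect_equal(fd$volume, c(100, 25))
  expect_equal(fd$Na, c(100, 5))
  expect_error(fractional_delivery(del, filtered = c(volume = 0, Na = 40)),
               "positive")
})

test_that("baseline protocol: PT-inlet delivery is 100% and accounting closes", {
  kid <- toy_kidney()
  fd <- fractional_delivery(delivery_table(kid))
  expect_equal(fd$volume[fd$boundary == "PT"], 100, tolerance = 1e-9)
  expect_equal(fd$Na[fd$boundary == "PT"], 100, tolerance = 1e-9)
  # segmental fractional reabsorptions plus excretion telescope to 100%
  for (q in c("volume", "Na", "K")) {
    reabs <- -diff(fd[[q]])
    expect_equal(sum(reabs) + fd[[q]][nrow(fd)], 100, tolerance = 1e-6)
  }
})

test_that("delivery speciation matches the carried totals at each boundary", {
  kid <- toy_kidney()
  del <- delivery_table(kid)
  # urinary Na+ flow equals carried urinary Na times the nephron count
  expect_equal(del$Na[del$boundary == "urine"],
               unname(kid$urine$T[["Na"]] * kid$nephrons * 1e-6),
               tolerance = 1e-12)
  expect_equal(del$volume[del$boundary == "urine"],
               unname(kid$urine$W * kid$nephrons * 1e-3), tolerance = 1e-12)
})
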