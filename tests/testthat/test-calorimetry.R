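test_that("Haldane transform reproduces the hand-computed oracle", {
  # FeO2 0.17, FeCO2 0.04, VE 100 L/min already standardised:
  # FeN2 = 0.79, FiN2 = 0.7903, VI = 100*0.79/0.7903 = 99.962 L/min
  # vo2 = 99.962*0.2093 - 100*0.17 = 3.9221 L/min
  # vco2 = 100*0.04 - 99.962*0.0004 = 3.9600 L/min
  s <- gas_sample(0.17, 0.04, expired_volume = 100, window_duration = 60,
                  volume_convention = "stpd")
  gx <- gas_exchange_from_sample(s)
  vi <- 100 * 0.79 / 0.7903
  expect_equal(gx$vo2_ml_min, 1000 * (vi * 0.2093 - 17), tolerance = 1e-9)
  expect_equal(gx$vco2_ml_min, 1000 * (4 - vi * 0.0004), tolerance = 1e-9)
  expect_equal(round(gx$vo2_ml_min), 3922)
  expect_equal(round(gx$vco2_ml_min), 3960)
})

test_that("gas exchange is linear in expired volume", {
  s1 <- gas_sample(0.165, 0.045, 50, 30, volume_convention = "stpd")
  s2 <- gas_sample(0.165, 0.045, 100, 30, volume_convention = "stpd")
  g1 <- gas_exchange_from_sample(s1)
  g2 <- gas_exchange_from_sample(s2)
  expect_equal(g2$vo2_ml_min, 2 * g1$vo2_ml_min)
  expect_equal(g2$vco2_ml_min, 2 * g1$vco2_ml_min)
  expect_equal(g1$rer, g2$rer)
})

test_that("gas exchange inverts a synthetic construction (Haldane oracle)", {
  # construct mixed-expired fractions from known vo2/vco2 and recover them
  fi_o2 <- 0.2093; fi_co2 <- 0.0004
  for (case in list(c(4.0, 3.6, 110), c(5.67, 6.5, 180), c(3.0, 2.4, 80))) {
    vo2 <- case[1]; vco2 <- case[2]; ve <- case[3]
    # nitrogen balance fixes VI given VE and fractions; solve forward:
    fi_n2 <- 1 - fi_o2 - fi_co2
    # pick fe via one Newton-free fixed point on the Haldane identity
    fe_o2 <- fi_o2; fe_co2 <- fi_co2
    for (i in 1:200) {
      vi <- ve * (1 - fe_o2 - fe_co2) / fi_n2
      fe_o2 <- (vi * fi_o2 - vo2) / ve
      fe_co2 <- (vco2 + vi * fi_co2) / ve
    }
    s <- gas_sample(fe_o2, fe_co2, ve, 60, volume_convention = "stpd")
    gx <- gas_exchange_from_sample(s)
    expect_equal(gx$vo2_ml_min, 1000 * vo2, tolerance = 1e-6)
    expect_equal(gx$vco2_ml_min, 1000 * vco2, tolerance = 1e-6)
  }
})

test_that("ATPS volumes are corrected for temperature and water vapour", {
  atps <- gas_sample(0.17, 0.04, 100, 60, ambient_temp = 22,
                     barometric_pressure = 755, volume_convention = "atps")
  stpd <- gas_sample(0.17, 0.04, 100, 60, volume_convention = "stpd")
  ga <- gas_exchange_from_sample(atps)
  gs <- gas_exchange_from_sample(stpd)
  # warm saturated air shrinks once standardised: uptake must be smaller
  expect_lt(ga$vo2_ml_min, gs$vo2_ml_min)
  factor <- ga$vo2_ml_min / gs$vo2_ml_min
  expect_equal(ga$vco2_ml_min / gs$vco2_ml_min, factor, tolerance = 1e-9)
  expect_gt(factor, 0.85); expect_lt(factor, 1)
})

test_that("degenerate and malformed samples are rejected", {
  expect_error(gas_sample(0.6, 0.5, 100, 60), "< 1")
  expect_error(gas_sample(0.17, 0.04, 0, 60), "expired_volume")
  s <- gas_sample(0.2093, 0.0004, 100, 60, volume_convention = "stpd")
  expect_error(gas_exchange_from_sample(s), "degenerate")
})

test_that("respiratory exchange ratio is the plain unclamped ratio", {
  expect_equal(respiratory_exchange_ratio(4, 4), 1)
  expect_equal(respiratory_exchange_ratio(4, 3.6), 0.9)
  expect_equal(round(respiratory_exchange_ratio(5.67, 6.5), 3), 1.146)
  expect_error(respiratory_exchange_ratio(0, 3), "vo2")
})

test_that("substrate partitioning reproduces hand-computed rates", {
  # vo2 4.0, vco2 3.6 L/min:
  # fat = (6.78 - 6.1236) * 9.75 = 6.4 kcal/min
  # cho = (16.506 - 12.904) * 4.07 = 14.66 kcal/min
  s <- substrate_oxidation(4.0, 3.6)
  expect_equal(s$fat_kcal_min, (4 * 1.695 - 3.6 * 1.701) * 9.75)
  expect_equal(s$cho_kcal_min, (3.6 * 4.585 - 4 * 3.226) * 4.07)
  expect_equal(round(s$fat_kcal_min, 3), 6.400)
  expect_equal(round(s$cho_kcal_min, 3), 14.660)
  expect_equal(round(s$fat_fraction, 4), 0.3039)
  expect_false(s$clipped)
  expect_equal(s$fat_g_min, s$fat_kcal_min / 9.75)
  expect_equal(s$cho_g_min, s$cho_kcal_min / 4.07)
})

test_that("substrate rates cross zero exactly at the stoichiometric RERs", {
  vo2 <- 4.5
  fat_zero <- substrate_oxidation(vo2, vo2 * 1.695 / 1.701)
  expect_equal(fat_zero$fat_kcal_min, 0, tolerance = 1e-12)
  expect_equal(fat_zero$fat_fraction, 0)
  cho_zero <- substrate_oxidation(vo2, vo2 * 3.226 / 4.585)
  expect_equal(cho_zero$cho_kcal_min, 0, tolerance = 1e-12)
  expect_equal(cho_zero$fat_fraction, 1)
})

test_that("fat fraction is monotone in RER, bounded, and flagged on clipping", {
  vo2 <- 5
  rers <- seq(0.65, 1.15, by = 0.01)
  fr <- substrate_oxidation(rep(vo2, length(rers)), vo2 * rers)
  expect_true(all(fr$fat_fraction >= 0 & fr$fat_fraction <= 1))
  expect_true(all(diff(fr$fat_fraction) <= 1e-12))
  expect_true(all(fr$fat_fraction[rers <= 3.226 / 4.585] == 1))
  expect_true(all(fr$fat_fraction[rers >= 1.695 / 1.701] == 0))
  expect_true(all(fr$clipped[rers > 1.695 / 1.701]))
  expect_true(all(fr$clipped[rers < 3.226 / 4.585]))
  mid <- rers > 3.226 / 4.585 & rers < 1.695 / 1.701
  expect_false(any(fr$clipped[mid]))
})
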