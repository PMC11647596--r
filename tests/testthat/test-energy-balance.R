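test_that("atmospheric pressure decays with altitude", {
  expect_equal(atmospheric_pressure(0), 101.3)
  expect_equal(atmospheric_pressure(8200), 101.3 / exp(1),
               tolerance = 1e-12)
  alts <- seq(0, 4000, by = 500)
  expect_true(all(diff(atmospheric_pressure(alts)) < 0))
  expect_error(atmospheric_pressure(-1000))
})

test_that("Tetens saturation curve, VPD and slope evaluate correctly", {
  expect_equal(saturation_vapor_pressure(25), 3.166, tolerance = 1e-3)
  expect_equal(vpd(25, 50), 1.583, tolerance = 1e-3)
  expect_equal(vpd(30, 100), 0)
  expect_true(all(diff(saturation_vapor_pressure(seq(-10, 50, 5))) > 0))
  expect_error(vpd(25, 0), "humidity")
  expect_error(saturation_vapor_pressure(80), "outside")

  expect_equal(saturation_slope(25, 101.3), 1.863e-3, tolerance = 1e-3)
  s_range <- saturation_slope(seq(0, 50, 5), 101.3)
  expect_true(all(diff(s_range) > 0))
  expect_equal(saturation_slope(25, 101.3 / 2),
               2 * saturation_slope(25, 101.3))
})

test_that("conductance formulas evaluate and scale as specified", {
  expect_equal(boundary_layer_conductance_heat(0.9, 0.1), 0.567)
  expect_equal(boundary_layer_conductance_heat(4 * 0.9, 0.1),
               2 * boundary_layer_conductance_heat(0.9, 0.1))
  expect_lt(boundary_layer_conductance_heat(0.9, 0.2),
            boundary_layer_conductance_heat(0.9, 0.1))
  # wind floor keeps the conductance finite and positive in still air
  expect_equal(boundary_layer_conductance_heat(0, 0.1),
               boundary_layer_conductance_heat(0.1, 0.1))

  expect_equal(radiative_conductance(20),
               4 * 5.67e-8 * 293.15^3 / 29.3, tolerance = 1e-12)
  expect_equal(radiative_conductance(20), 0.195, tolerance = 1e-3)
  tt <- seq(-10, 50, 10)
  expect_true(all(diff(radiative_conductance(tt)) > 0))
  expect_equal(radiative_conductance(tt) * 29.3 / (4 * 5.67e-8),
               (tt + 273.15)^3)
})

test_that("vapor conductances follow both combination modes", {
  v <- vapor_conductances(0.3, 0.9, 0.1, mode = "as_printed")
  expect_equal(v$g_va, 1.4 * 0.147 * 3, tolerance = 1e-12)
  expect_equal(v$g_wv, 0.5 * 0.15 * v$g_va / (0.15 + v$g_va),
               tolerance = 1e-12)
  expect_equal(v$g_wv, 0.0603, tolerance = 1e-3)
  vs <- vapor_conductances(0.3, 0.9, 0.1, mode = "series_hypostomatous")
  expect_equal(vs$g_wv, 0.3 * v$g_va / (0.3 + v$g_va), tolerance = 1e-12)
  # series bound in both modes
  expect_lt(v$g_wv, min(0.3, v$g_va))
  expect_lt(vs$g_wv, min(0.3, vs$g_va))
  # stomata wide open: series mode approaches the boundary-layer limit
  vbig <- vapor_conductances(1e6, 0.9, 0.1, mode = "series_hypostomatous")
  expect_equal(vbig$g_wv, vbig$g_va, tolerance = 1e-5)
  expect_error(vapor_conductances(0.3, 0.9, 0.1, mode = "nope"))
})

test_that("modified psychrometric constant is the gamma-scaled ratio", {
  expect_equal(modified_psychrometric(0.5, 0.5), 6.66e-4)
  expect_equal(modified_psychrometric(0.762, 0.0603), 8.41e-3,
               tolerance = 1e-3)
  expect_equal(modified_psychrometric(2 * 0.762, 0.0603),
               2 * modified_psychrometric(0.762, 0.0603))
})

test_that("isothermal net radiation composes absorbed shortwave and overrides", {
  expect_equal(isothermal_net_radiation(800, 0.5), 400)
  expect_equal(isothermal_net_radiation(0, 0.5), 0)
  expect_equal(isothermal_net_radiation(800, 0.5, rni_wm2 = 300), 300)
  expect_equal(isothermal_net_radiation(c(800, 800), c(0.5, 0.5),
                                        rni_wm2 = c(NA, -50)),
               c(400, -50))
})

test_that("leaf temperature equals air temperature when the bracket vanishes", {
  r <- leaf_temperature(tair_c = 25, rh_pct = 100, wind_ms = 1,
                        solar_wm2 = 0, width_m = 0.05, gs_mol = 0.3,
                        absorptance = 0.5)
  expect_identical(r$tleaf_c, 25)
  expect_identical(r$delta_t_c, 0)
  # saturated air but positive radiation load: leaf warmer than air
  r2 <- leaf_temperature(25, 100, 1, 800, 0.05, 0.3, 0.5)
  expect_gt(r2$tleaf_c, 25)
  expect_equal(r2$g_hr, r2$g_ha + r2$g_r, tolerance = 1e-12)
})

test_that("full pipeline matches the independent stepwise oracle on a parameter sweep", {
  set.seed(99)
  n <- 100
  Ta <- runif(n, 5, 40); RH <- runif(n, 20, 100); u <- runif(n, 0, 5)
  S <- runif(n, 0, 1000); d <- runif(n, 0.01, 0.2)
  gs <- runif(n, 0.02, 0.8); a <- runif(n, 0.3, 0.95)
  alt <- runif(n, 0, 2000)
  for (mode in c("as_printed", "series_hypostomatous")) {
    got <- leaf_temperature(Ta, RH, u, S, d, gs, a, altitude_m = alt,
                            gwv_mode = mode)$tleaf_c
    want <- vapply(seq_len(n), function(i)
      eb_oracle(Ta[i], RH[i], u[i], S[i], d[i], gs[i], a[i], alt[i], mode),
      numeric(1))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("leaf temperature responds with the right signs and limits", {
  base <- list(tair_c = 25, rh_pct = 50, wind_ms = 1, solar_wm2 = 800,
               width_m = 0.05, gs_mol = 0.3, absorptance = 0.5)
  tl <- function(args) do.call(leaf_temperature, args)$tleaf_c
  # dTl/dRni > 0 via the override
  up <- modifyList(base, list(rni_wm2 = 410)); dn <- modifyList(base, list(rni_wm2 = 390))
  expect_gt(tl(up), tl(dn))
  # dTl/dVPD < 0: drier air cools the transpiring leaf
  dry <- modifyList(base, list(rh_pct = 40)); wet <- modifyList(base, list(rh_pct = 60))
  expect_lt(tl(dry), tl(wet))
  # boundary layer collapse: Tl -> Ta monotonically as wind grows
  winds <- c(0.5, 1, 2, 4, 8, 16, 32, 64, 128, 256)
  dts <- vapply(winds, function(w)
    abs(do.call(leaf_temperature,
                modifyList(base, list(wind_ms = w)))$delta_t_c),
    numeric(1))
  expect_true(all(diff(dts) < 0))
  expect_lt(dts[length(dts)], 1)
})

test_that("batch results carry per-row outputs and site slopes", {
  df <- data.frame(species = "ACSA", site = rep(c("hot", "cold"), each = 4),
                   tree = rep(1:4, 2),
                   tair_c = c(30, 32, 34, 36, 27, 29, 31, 33),
                   rh_pct = 55, wind_ms = 1, solar_wm2 = c(rep(850, 4),
                                                           rep(700, 4)),
                   width_m = 0.06, gs_mol = c(rep(0.35, 4), rep(0.25, 4)),
                   absorptance = 0.85)
  out <- batch_delta_t(df)
  expect_equal(nrow(out$results), 8)
  expect_equal(nrow(out$slopes), 2)
  expect_true(all(is.finite(out$slopes$slope)))
  # identical rows give identical outputs
  two <- batch_delta_t(df[c(1, 1), ])
  expect_equal(two$results$tleaf_c[1], two$results$tleaf_c[2])
  # saturated, dark rows: no temperature difference anywhere
  df0 <- df; df0$rh_pct <- 100; df0$solar_wm2 <- 0
  expect_equal(batch_delta_t(df0)$results$delta_t_c, rep(0, 8))
  expect_error(batch_delta_t(df[, -4]), "missing columns")
})
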