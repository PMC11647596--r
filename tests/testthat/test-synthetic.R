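test_that("study design validates its invariants", {
  d <- study_design()
  expect_s3_class(d, "study_design")
  expect_equal(d$control_c, 22)
  expect_error(study_design(bath_temperatures_c = c(40, 22)),
               "strictly increasing")
  expect_error(study_design(trees_per_species_site = 0))
  expect_error(study_design(species = c("A", "A")), "duplicated")
})

test_that("generated record counts equal the closed-form design products", {
  d <- study_design()
  expect_equal(n_disks(d), 7 * 2 * 10 * 9 * 3)
  expect_equal(n_trees(d), 7 * 2 * 10)
  expect_equal(nrow(sim_fvfm_disks(d, seed = 3)), 3780)
  g <- sim_at_curves(d, seed = 3)
  expect_equal(nrow(g), 140 * 11)
  tr <- sim_trait_table(d, seed = 3)
  expect_equal(nrow(tr), 140 * 5)
  expect_equal(nrow(unique(tr[c("species", "site", "tree")])), 140)

  small <- study_design(species = c("ACSA", "TICO"),
                        trees_per_species_site = 4,
                        disks_per_tree_per_temperature = 2)
  expect_equal(nrow(sim_fvfm_disks(small, seed = 1)), 2 * 2 * 4 * 9 * 2)
})

test_that("same seed and config give byte-identical output", {
  for (gen in list(function(s) sim_microclimate(n_days = 3, seed = s),
                   function(s) sim_fvfm_disks(seed = s),
                   function(s) sim_at_curves(seed = s),
                   function(s) sim_trait_table(seed = s))) {
    a <- gen(11); b <- gen(11); c <- gen(12)
    expect_identical(a, b)
    expect_false(identical(a, c))
  }
})

test_that("microclimate generator honours its diurnal construction", {
  # identical parameters, zero noise: the two sites coincide
  p <- default_site_params(noise_sd = 0)
  p$t_mean <- 20; p$t_amplitude <- 10
  mc <- sim_microclimate(p, n_days = 2, seed = 5)
  hot <- mc[mc$site == "hot", ]; cold <- mc[mc$site == "cold", ]
  expect_equal(hot$tair_c, cold$tair_c)
  expect_equal(nrow(hot), 2 * 48)
  expect_true(all(mc$solar_wm2 >= 0))
  night <- as.numeric(format(mc$timestamp, "%H")) %in% c(0:5, 19:23)
  expect_true(all(mc$solar_wm2[night] == 0))

  # configured maximum offset of 3.4 C appears in the daily-max means
  mc2 <- sim_microclimate(default_site_params(noise_sd = 0), n_days = 5,
                          seed = 5)
  dmax <- tapply(mc2$tair_c, mc2$site, function(x)
    mean(tapply(x, rep(1:5, each = 48), max)))
  expect_equal(unname(dmax["hot"] - dmax["cold"]), 3.4, tolerance = 1e-10)

  expect_error(sim_microclimate(within(default_site_params(),
                                       t_mean <- c(NA, 20)), n_days = 1),
               "non-finite")
})

test_that("AR(1) noise has the configured lag-1 autocorrelation", {
  x <- with(list(), {set.seed(42); ar1_series(10000, 0.7, 1)})
  expect_equal(stats::acf(x, plot = FALSE)$acf[2], 0.7, tolerance = 0.05)
  expect_equal(sd(x), 1, tolerance = 0.05)
})

test_that("noiseless disks lie exactly on the tree logistic and fitting recovers T50", {
  p <- default_ht_params(tree_sd = 0, disk_sd = 0)
  d <- sim_fvfm_disks(study_design(species = "ACSA",
                                   trees_per_species_site = 2),
                      ht_params = p, seed = 1)
  mu <- logistic_fvfm(d$bath_c, p$theta1, p$theta2, p$theta3)
  expect_equal(d$fvfm, mu, tolerance = 1e-12)
  expect_equal(d$fvfm, fvfm(d$f0, d$fm), tolerance = 1e-12)

  one <- d[d$tree == 1 & d$site == "hot", ]
  fit <- fit_fvfm_logistic(one$bath_c, one$fvfm)
  true_t50 <- -p$theta2 / p$theta3
  expect_lt(abs(fit$t50 - true_t50), 0.01)

  expect_error(sim_fvfm_disks(ht_params = default_ht_params(theta3 = 0.2)),
               "negative")
  expect_error(sim_fvfm_disks(ht_params = default_ht_params(theta1 = 1.4)))
})

test_that("Fv/Fm control-temperature mean sits near theta1 and values stay in [0,1]", {
  d <- sim_fvfm_disks(seed = 8)
  expect_true(all(d$fvfm >= 0 & d$fvfm <= 1))
  expect_true(all(d$fm > d$f0 & d$f0 > 0))
  expect_equal(mean(d$fvfm[d$bath_c == 22]), 0.8, tolerance = 0.01)
})

test_that("A-T curves follow the Gaussian truth with positive companions", {
  des <- study_design(species = "ACSA", trees_per_species_site = 1)
  p <- default_tr_params(noise_sd = 0)
  g <- sim_at_curves(des, p, seed = 2)
  expect_equal(nrow(g[g$site == "hot", ]), 11)   # (40-20)/2 + 1 steps
  at_topt <- g$anet[g$tleaf_c == 28]
  expect_equal(at_topt, rep(p$p_opt, 2), tolerance = 1e-12)
  # one omega away from the optimum the rate is e^-1 of the peak
  at_40 <- g$anet[g$tleaf_c == 40 & g$site == "hot"]
  expect_equal(at_40 / p$p_opt, exp(-1), tolerance = 1e-12)
  expect_true(all(g$gs > 0 & g$e > 0))
  # transpiration tracks evaporative demand, i.e. rises with temperature
  expect_gt(cor(g$e, g$tleaf_c), 0)
  # stomatal conductance peaks around the photosynthetic optimum
  gs_mean <- tapply(g$gs, g$tleaf_c, mean)
  expect_lt(abs(as.numeric(names(which.max(gs_mean))) - 28), 6)
  expect_error(sim_at_curves(des, default_tr_params(omega = -1)), "omega")
})

test_that("trait tables respect mass and optics invariants", {
  tr <- sim_trait_table(seed = 4)
  expect_true(all(tr$fresh_mg >= tr$dry_mg))
  expect_true(all(tr$reflectance + tr$transmittance < 1))
  expect_true(all(tr$area_mm2 > 0 & tr$thickness_mm > 0))
  expect_equal(unname(table(interaction(tr$species, tr$site, tr$tree))[1]),
               5L)
  expect_error(sim_trait_table(trait_params = within(
    default_trait_params(), {refl_mean <- 0.7; trans_mean <- 0.4})),
    "optics")
})

test_that("silhouette shapes have their analytic inscribed-circle widths", {
  for (case in list(list("circle", c(r = 10), 20),
                    list("rectangle", c(w = 12, h = 40), 12),
                    list("ellipse", c(a = 20, b = 8), 16))) {
    s <- sim_leaf_silhouette(case[[1]], case[[2]], px_per_mm = 10)
    lw <- effective_leaf_width(s$mask, s$px_per_mm)
    expect_lt(abs(lw - case[[3]]), 2 / s$px_per_mm)  # one pixel-equivalent
  }
  s <- sim_leaf_silhouette("lobed", c(r = 10, depth = 0.3, lobes = 5),
                           px_per_mm = 8, seed = 3)
  expect_true(any(s$mask == 1))
  expect_error(sim_leaf_silhouette("circle", c(r = -2)))
})

test_that("per-cell truth tables drive the generators cell by cell", {
  des <- study_design(species = c("ACSA", "TICO"),
                      trees_per_species_site = 3)
  cells <- expand.grid(species = des$species, site = des$sites,
                       stringsAsFactors = FALSE)
  cells$p_opt <- c(20, 10, 20, 10); cells$t_opt <- 28; cells$omega <- 12
  cells$noise_sd <- 0; cells$gs_ref <- 0.3
  g <- sim_at_curves(des, cells, seed = 1)
  peak <- tapply(g$anet, g$species, max)
  expect_equal(unname(peak[["ACSA"]]), 20, tolerance = 1e-9)
  expect_equal(unname(peak[["TICO"]]), 10, tolerance = 1e-9)
  expect_error(sim_at_curves(des, cells[-1, ], seed = 1), "missing")
})
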