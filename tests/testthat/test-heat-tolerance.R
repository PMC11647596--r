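test_that("Fv/Fm ratio follows its definition and limits", {
  expect_equal(fvfm(300, 1500), 0.8)
  expect_equal(fvfm(1e-9, 1500), 1, tolerance = 1e-9)
  expect_error(fvfm(1500, 1500), "exceed")
  expect_error(fvfm(-1, 10))
  expect_equal(fvfm(c(300, 750), c(1500, 1500)), c(0.8, 0.5))
})

test_that("QC filter removes whole trees below the control threshold", {
  d <- sim_fvfm_disks(study_design(species = c("ACSA", "TICO"),
                                   trees_per_species_site = 3), seed = 2)
  ok <- qc_filter(d)
  expect_equal(nrow(ok$retained), nrow(d))
  expect_equal(nrow(ok$rejected), 0)
  # damage one tree's control disks
  bad <- d$species == "ACSA" & d$site == "hot" & d$tree == 1 &
    d$bath_c == 22
  d$fvfm[bad] <- 0.6
  flt <- qc_filter(d)
  expect_equal(nrow(flt$rejected), 1)
  expect_equal(flt$rejected$n_disks_removed, 27)
  expect_equal(nrow(flt$retained), nrow(d) - 27)
  expect_false(any(flt$retained$species == "ACSA" &
                     flt$retained$site == "hot" & flt$retained$tree == 1))
  # threshold 0 is the identity filter
  expect_equal(nrow(qc_filter(d, min_control_fvfm = 0)$retained), nrow(d))
  expect_error(qc_filter(d[d$bath_c > 30, ], control_c = 22), "control")
})

test_that("noiseless logistic disks are recovered to numerical precision", {
  d <- make_disks(0.8, 25, -0.5)
  fit <- fit_fvfm_logistic(d$bath_c, d$fvfm)
  expect_true(fit$converged)
  expect_equal(fit$theta1, 0.8, tolerance = 1e-6)
  expect_equal(fit$theta2, 25, tolerance = 1e-5)
  expect_equal(fit$theta3, -0.5, tolerance = 1e-6)
  expect_equal(fit$t50, 50, tolerance = 1e-5)
  # a flat (undamaged) response is flagged invalid, not fitted
  flat <- data.frame(bath_c = rep(c(22, 40, 44, 48, 52, 56), each = 3),
                     fvfm = 0.8)
  expect_false(fit_fvfm_logistic(flat$bath_c, flat$fvfm)$converged)
})

test_that("the logistic least-squares optimum matches a lattice search", {
  set.seed(23)
  d <- make_disks(0.8, 30, -0.6, sd = 0.03)
  fit <- fit_fvfm_logistic(d$bath_c, d$fvfm)
  lat <- logistic_lattice(d$bath_c, d$fvfm,
                          c(fit$theta1, fit$theta2, fit$theta3))
  expect_lte(fit$rss, lat$rss + 1e-9)
  expect_lt(abs(fit$theta1 - lat$theta1), 0.002)
  expect_lt(abs(fit$theta3 - lat$theta3), 0.002)
})

test_that("noisy replicates cover the logistic truth within 2 SE", {
  truth <- c(theta1 = 0.8, theta2 = 30, theta3 = -0.6)
  hits <- matrix(FALSE, 100, 3, dimnames = list(NULL, names(truth)))
  for (i in 1:100) {
    set.seed(2000 + i)
    d <- make_disks(0.8, 30, -0.6, sd = 0.03)
    f <- fit_fvfm_logistic(d$bath_c, d$fvfm)
    if (!f$converged) next
    for (p in names(truth))
      hits[i, p] <- abs(f[[p]] - truth[[p]]) <= 2 * f$se[[p]]
  }
  expect_true(all(colMeans(hits) >= 0.9))
})

test_that("threshold temperatures follow the closed form and their ordering", {
  expect_equal(threshold_temperature(25, -0.5, 0.5), 50)
  expect_equal(threshold_temperature(25, -0.5, 0.15),
               (log(0.85 / 0.15) - 25) / -0.5)
  expect_equal(threshold_temperature(25, -0.5, 0.15), 46.53,
               tolerance = 1e-3)
  expect_equal(threshold_temperature(25, -0.5, 0.95), 55.89,
               tolerance = 1e-3)
  expect_error(threshold_temperature(25, 0.5, 0.5), "negative")
  expect_error(threshold_temperature(25, -0.5, 1.2), "damage")
  # strictly increasing in damage for any declining curve
  set.seed(6)
  for (i in 1:25) {
    th2 <- runif(1, 10, 40); th3 <- -runif(1, 0.2, 1.5)
    tt <- threshold_temperature(th2, th3, c(0.15, 0.5, 0.95))
    expect_true(all(diff(tt) > 0))
  }
})

test_that("closed-form thresholds agree with numerical root finding", {
  set.seed(8)
  for (i in 1:50) {
    th1 <- runif(1, 0.5, 1); th2 <- runif(1, 10, 40)
    th3 <- -runif(1, 0.2, 1.5); dmg <- runif(1, 0.05, 0.95)
    target <- (1 - dmg) * th1
    root <- uniroot(function(t) logistic_fvfm(t, th1, th2, th3) - target,
                    c(-200, 300), tol = 1e-12)$root
    expect_equal(threshold_temperature(th2, th3, dmg), root,
                 tolerance = 1e-9)
  }
})

test_that("bootstrap collapses on noiseless disks and brackets its point estimate", {
  d <- make_disks(0.8, 30, -0.6)
  bt <- bootstrap_thresholds(d$bath_c, d$fvfm, n_boot = 20, seed = 3)
  expect_true(all(bt$table$ci_hi - bt$table$ci_lo < 1e-6))
  expect_equal(bt$n_failed, 0)
  expect_false(bt$unreliable)

  set.seed(41)
  dn <- make_disks(0.8, 30, -0.6, sd = 0.03)
  btn <- bootstrap_thresholds(dn$bath_c, dn$fvfm, n_boot = 50, seed = 4)
  expect_true(all(btn$table$estimate >= btn$table$ci_lo &
                    btn$table$estimate <= btn$table$ci_hi))
  # deterministic given the seed
  btn2 <- bootstrap_thresholds(dn$bath_c, dn$fvfm, n_boot = 50, seed = 4)
  expect_identical(btn$table, btn2$table)
})

test_that("doubling disk noise widens the mean bootstrap interval", {
  widths <- sapply(c(0.015, 0.03, 0.06), function(sdv) {
    mean(sapply(1:8, function(s) {
      set.seed(3000 + s)
      d <- make_disks(0.8, 30, -0.6, sd = sdv)
      bt <- bootstrap_thresholds(d$bath_c, d$fvfm, n_boot = 40,
                                 seed = 100 + s)
      diff(unlist(bt$table[bt$table$damage == 0.5, c("ci_lo", "ci_hi")]))
    }))
  })
  expect_true(all(diff(widths) > 0))
})

test_that("species table flags only the species with constructed contrasts", {
  des <- study_design(species = c("ACPL", "ACSA", "CEOC"),
                      trees_per_species_site = 5)
  cells <- expand.grid(species = des$species, site = des$sites,
                       stringsAsFactors = FALSE)
  cells$theta1 <- 0.8; cells$theta3 <- -0.6
  # ACPL hot trees tolerate 2 C more (theta2 = -theta3 * T50)
  cells$theta2 <- ifelse(cells$species == "ACPL" & cells$site == "hot",
                         0.6 * 52, 0.6 * 50)
  cells$tree_sd <- 0.05; cells$disk_sd <- 0.01
  d <- sim_fvfm_disks(des, cells, seed = 13)
  fits <- fit_heat_tolerance_all(d)
  expect_true(all(fits$converged))
  expect_true(all(fits$t_crit < fits$t50 & fits$t50 < fits$t95))
  tab <- species_ht_table(fits)
  t50 <- tab[tab$threshold == "t50", ]
  expect_true(t50$significant[t50$species == "ACPL"])
  expect_equal(t50$diff[t50$species == "ACPL"], 2, tolerance = 0.3)
  expect_false(any(t50$significant[t50$species != "ACPL"]))
  # the ~50 C regime holds for the null species
  expect_equal(mean(t50$mean_cold), 50, tolerance = 0.5)
})

test_that("undersampled species cells are skipped with a warning", {
  des <- study_design(species = c("ACSA", "TICO"),
                      trees_per_species_site = 3)
  d <- sim_fvfm_disks(des, seed = 5)
  fits <- fit_heat_tolerance_all(d)
  fits <- fits[!(fits$species == "TICO" & fits$site == "hot" &
                   fits$tree > 1), ]
  expect_warning(tab <- species_ht_table(fits), "undersampled")
  expect_false("TICO" %in% tab$species)
})
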