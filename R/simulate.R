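#' Default per-site microclimate parameters
#'
#' Diurnal-cycle parameters for the two study environments. The defaults
#' reproduce the summer site statistics of the temperate-city contrast the
#' package targets: the hot (urban heat island) site with mean air
#' temperature 23.3 degrees C and daily maximum 37.8 degrees C, the cold
#' site with mean 22.0 and maximum 34.4, i.e. a 1.3 degree mean offset and a
#' 3.4 degree maximum offset. With a sinusoidal diurnal cycle the implied
#' amplitudes are (max - mean): 14.5 and 12.4 degrees C.
#'
#' @param noise_sd Marginal SD (degrees C) of the AR(1) temperature noise
#'   added on top of the deterministic diurnal cycle.
#' @param phi Lag-1 autocorrelation of the noise process.
#' @param solar_max_wm2 Solar-noon irradiance of the clear-sky half-sine.
#' @return A data.frame with one row per site and columns `site`, `t_mean`,
#'   `t_amplitude`, `noise_sd`, `phi`, `solar_max_wm2`.
#' @export
default_site_params <- function(noise_sd = 1.0, phi = 0.7,
                                solar_max_wm2 = 800) {
  data.frame(site = c("hot", "cold"),
             t_mean = c(23.3, 22.0),
             t_amplitude = c(14.5, 12.4),
             noise_sd = noise_sd, phi = phi,
             solar_max_wm2 = solar_max_wm2,
             stringsAsFactors = FALSE)
}

#' Simulate paired-site microclimate series
#'
#' Generates 30-minute air temperature and solar irradiance records for each
#' site in `site_params`, emulating data loggers deployed in two urban
#' environments. Air temperature is a sinusoid peaking at 14:00 local time
#' (mean `t_mean`, amplitude `t_amplitude`) plus stationary AR(1) noise;
#' irradiance is a clear-sky half-sine between 06:00 and 18:00, zero at
#' night, so the day/night split downstream can use an irradiance threshold.
#'
#' @param site_params Data.frame as returned by [default_site_params()].
#' @param n_days Number of simulated days (48 records per day per site).
#' @param seed Integer seed; the same seed and parameters give identical
#'   output.
#' @param start_date First calendar day of the series.
#' @return A data.frame with columns `site`, `timestamp` (POSIXct, UTC),
#'   `tair_c`, `solar_wm2`.
#' @examples
#' mc <- sim_microclimate(n_days = 3, seed = 1)
#' table(mc$site)
#' @export
sim_microclimate <- function(site_params = default_site_params(),
                             n_days = 30, seed = 1,
                             start_date = as.Date("2021-07-01")) {
  stopifnot(is.data.frame(site_params), n_days >= 1)
  need <- c("site", "t_mean", "t_amplitude", "noise_sd", "phi",
            "solar_max_wm2")
  if (!all(need %in% names(site_params)))
    stop("site_params must have columns: ", paste(need, collapse = ", "))
  num <- unlist(site_params[setdiff(need, "site")])
  if (!all(is.finite(num))) stop("non-finite site parameters")
  if (any(site_params$noise_sd < 0)) stop("noise_sd must be >= 0")

  hours <- seq(0, 24 * n_days - 0.5, by = 0.5)
  t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  timestamp <- t0 + hours * 3600
  hod <- hours %% 24

  out <- lapply(seq_len(nrow(site_params)), function(i) {
    p <- site_params[i, ]
    tair <- p$t_mean + p$t_amplitude * cos(2 * pi * (hod - 14) / 24)
    noise <- with_seed(sub_seed(seed, i),
                       ar1_series(length(hours), p$phi, p$noise_sd))
    solar <- ifelse(hod >= 6 & hod <= 18,
                    p$solar_max_wm2 * pmax(0, sin(pi * (hod - 6) / 12)), 0)
    data.frame(site = p$site, timestamp = timestamp,
               tair_c = tair + noise, solar_wm2 = solar,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Default heat-tolerance truth parameters
#'
#' Logistic decline parameters for the synthetic Fv/Fm generator. The
#' defaults put the undamaged asymptote at the healthy-leaf value
#' (theta1 = 0.8) and the 50 percent damage temperature at
#' T50 = -theta2/theta3 = 50 degrees C, the regime the field observes for
#' temperate urban trees, with a decline steep enough that damage runs from
#' onset to near-complete over roughly 47-55 degrees C.
#'
#' @param theta1 Control asymptote of Fv/Fm, in (0, 1].
#' @param theta2 Logistic intercept.
#' @param theta3 Logistic slope per degree C; must be negative (decline).
#' @param tree_sd SD of the tree-level random shift applied to theta2
#'   (moves each tree's T50 without changing the slope).
#' @param disk_sd SD of disk-level Gaussian measurement noise on Fv/Fm.
#' @return Named list of the five parameters.
#' @export
default_ht_params <- function(theta1 = 0.8, theta2 = 30, theta3 = -0.6,
                              tree_sd = 0.3, disk_sd = 0.03) {
  list(theta1 = theta1, theta2 = theta2, theta3 = theta3,
       tree_sd = tree_sd, disk_sd = disk_sd)
}

#' Simulate the leaf-disk Fv/Fm heat-tolerance assay
#'
#' Draws one record per leaf disk of the full nested design: every species x
#' site x tree x bath-temperature x disk combination. Each tree's true
#' response is the logistic `theta1 / (1 + exp(-(theta2 + theta3 * T)))`
#' with a tree-level Gaussian shift on `theta2`; disks add independent
#' Gaussian noise and are clipped to [0, 1]. Raw fluorescence is emitted as
#' a fixed maximum `fm` with `f0 = fm * (1 - fvfm)` so `(fm - f0)/fm`
#' recovers the ratio.
#'
#' `ht_params` may be a single parameter list (applied to every
#' species-site cell) or a data.frame with columns `species`, `site`,
#' `theta1`, `theta2`, `theta3`, `tree_sd`, `disk_sd` for per-cell truth.
#'
#' @param design A [study_design()].
#' @param ht_params Truth parameters, see [default_ht_params()].
#' @param seed Integer seed.
#' @return Data.frame with columns `species`, `site`, `tree`, `disk`,
#'   `bath_c`, `f0`, `fm`, `fvfm`.
#' @examples
#' disks <- sim_fvfm_disks(study_design(), seed = 1)
#' nrow(disks)  # 3780 under the default design
#' @export
sim_fvfm_disks <- function(design = study_design(),
                           ht_params = default_ht_params(), seed = 1) {
  stopifnot(inherits(design, "study_design"))
  par_tab <- expand_cell_params(design, ht_params,
                                c("theta1", "theta2", "theta3",
                                  "tree_sd", "disk_sd"))
  if (any(par_tab$theta1 <= 0 | par_tab$theta1 > 1))
    stop("theta1 must be in (0, 1]")
  if (any(par_tab$theta3 >= 0))
    stop("theta3 must be negative (declining Fv/Fm)")
  if (any(par_tab$tree_sd < 0 | par_tab$disk_sd < 0))
    stop("noise SDs must be >= 0")

  fm_value <- 1500
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(par_tab)), function(i) {
      p <- par_tab[i, ]
      cell <- expand.grid(tree = seq_len(design$trees_per_species_site),
                          bath_c = design$bath_temperatures_c,
                          disk = seq_len(design$disks_per_tree_per_temperature),
                          KEEP.OUT.ATTRS = FALSE)
      theta2_tree <- p$theta2 +
        stats::rnorm(design$trees_per_species_site, 0, p$tree_sd)
      mu <- logistic_fvfm(cell$bath_c, p$theta1, theta2_tree[cell$tree],
                          p$theta3)
      fvfm <- pmin(1, pmax(0, mu + stats::rnorm(nrow(cell), 0, p$disk_sd)))
      data.frame(species = p$species, site = p$site, tree = cell$tree,
                 disk = cell$disk, bath_c = cell$bath_c,
                 f0 = pmin(pmax(fm_value * (1 - fvfm), 0.5),
                           fm_value - 0.5),
                 fm = fm_value,
                 fvfm = fvfm, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$species, out$site, out$tree, out$bath_c, out$disk), ]
    rownames(out) <- NULL
    out
  })
}

#' Default photosynthesis-temperature truth parameters
#'
#' Gaussian temperature-response truth for the synthetic gas-exchange
#' generator: optimum assimilation `p_opt` (micromol CO2 m-2 s-1) at leaf
#' temperature `t_opt`, with curve width `omega` (the offset at which the
#' rate falls to e^-1 of the optimum). Defaults sit mid-range for temperate
#' broadleaf trees measured at saturating light.
#'
#' @param p_opt Optimum net assimilation, > 0.
#' @param t_opt Thermal optimum, degrees C.
#' @param omega Curve width, degrees C, > 0.
#' @param noise_sd SD of Gaussian measurement noise on Anet.
#' @param gs_ref Stomatal conductance scale (mol m-2 s-1) for the companion
#'   gs series.
#' @return Named list.
#' @export
default_tr_params <- function(p_opt = 15, t_opt = 28, omega = 12,
                              noise_sd = 1.0, gs_ref = 0.3) {
  list(p_opt = p_opt, t_opt = t_opt, omega = omega,
       noise_sd = noise_sd, gs_ref = gs_ref)
}

#' Simulate photosynthesis-temperature response curves
#'
#' One gas-exchange record per leaf temperature on the design's measurement
#' grid (default 20-40 degrees C in 2 degree steps), for one leaf per tree.
#' Net assimilation is the Gaussian response plus Gaussian noise; stomatal
#' conductance and transpiration are generated as positive,
#' temperature-correlated companions (gs tracks a broadened version of the
#' assimilation curve; E scales with gs and temperature, as evaporative
#' demand does).
#'
#' @param design A [study_design()].
#' @param tr_params Truth parameters, a single list ([default_tr_params()])
#'   or a per-cell data.frame with columns `species`, `site`, `p_opt`,
#'   `t_opt`, `omega`, `noise_sd`, `gs_ref`.
#' @param seed Integer seed.
#' @return Data.frame with columns `species`, `site`, `tree`, `leaf`,
#'   `tleaf_c`, `anet`, `gs`, `e`.
#' @export
sim_at_curves <- function(design = study_design(),
                          tr_params = default_tr_params(), seed = 1) {
  stopifnot(inherits(design, "study_design"))
  par_tab <- expand_cell_params(design, tr_params,
                                c("p_opt", "t_opt", "omega",
                                  "noise_sd", "gs_ref"))
  if (any(par_tab$omega <= 0)) stop("omega must be > 0")
  if (any(par_tab$p_opt <= 0)) stop("p_opt must be > 0")
  if (any(par_tab$noise_sd < 0)) stop("noise_sd must be >= 0")

  tgrid <- design$at_curve_temperatures_c
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(par_tab)), function(i) {
      p <- par_tab[i, ]
      cell <- expand.grid(tleaf_c = tgrid,
                          tree = seq_len(design$trees_per_species_site),
                          KEEP.OUT.ATTRS = FALSE)
      anet <- gaussian_response(cell$tleaf_c, p$p_opt, p$t_opt, p$omega) +
        stats::rnorm(nrow(cell), 0, p$noise_sd)
      gs <- pmax(p$gs_ref * exp(-0.5 * ((cell$tleaf_c - p$t_opt) /
                                          (1.5 * p$omega))^2) *
                   exp(stats::rnorm(nrow(cell), 0, 0.05)), 1e-3)
      e <- gs * (0.5 + 0.12 * cell$tleaf_c) *
        exp(stats::rnorm(nrow(cell), 0, 0.05))
      data.frame(species = p$species, site = p$site, tree = cell$tree,
                 leaf = 1L, tleaf_c = cell$tleaf_c, anet = anet,
                 gs = gs, e = e, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$species, out$site, out$tree, out$tleaf_c), ]
    rownames(out) <- NULL
    out
  })
}

#' Simulate a binary leaf silhouette
#'
#' Rasterizes a simple leaf outline as a 0/1 mask at a given resolution,
#' for exercising the area and effective-leaf-width operations against
#' shapes whose largest inscribed circle is known analytically: a circle of
#' radius r (width 2r), a rectangle w x h (width min(w, h)), an ellipse with
#' semi-axes a >= b (width 2b). The `lobed` shape perturbs a circle's radius
#' with a cosine lobe pattern and has no closed-form width.
#'
#' @param shape One of `"circle"`, `"rectangle"`, `"ellipse"`, `"lobed"`.
#' @param dims_mm Named numeric: `r` for circle and lobed (plus optional
#'   `depth` in (0,1) and integer `lobes` for lobed), `w`,`h` for rectangle,
#'   `a`,`b` (semi-axes) for ellipse. All in mm.
#' @param px_per_mm Raster resolution, >= 2; use >= 10 px/mm for sub-2%
#'   width error.
#' @param seed Integer seed (used only by `lobed` for lobe phase).
#' @return List with `mask` (integer matrix, 1 = leaf), `px_per_mm`.
#' @examples
#' s <- sim_leaf_silhouette("circle", c(r = 10), px_per_mm = 10)
#' effective_leaf_width(s$mask, s$px_per_mm)  # ~20 mm
#' @export
sim_leaf_silhouette <- function(shape = c("circle", "rectangle", "ellipse",
                                          "lobed"),
                                dims_mm, px_per_mm = 10, seed = 1) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(dims_mm), all(dims_mm > 0), px_per_mm >= 2)
  d <- as.list(dims_mm)
  half_mm <- switch(shape,
    circle = c(d$r, d$r),
    lobed = c(d$r, d$r) * (1 + if (is.null(d$depth)) 0.3 else d$depth),
    rectangle = c(d$w, d$h) / 2,
    ellipse = c(d$a, d$b))
  if (any(!is.finite(unlist(half_mm))) || any(unlist(half_mm) <= 0))
    stop("degenerate dimensions")
  pad_mm <- 2
  nx <- ceiling((half_mm[[1]] + pad_mm) * 2 * px_per_mm)
  ny <- ceiling((half_mm[[2]] + pad_mm) * 2 * px_per_mm)
  # pixel-centre coordinates in mm relative to the shape centre
  x <- (seq_len(nx) - 0.5) / px_per_mm - (half_mm[[1]] + pad_mm)
  y <- (seq_len(ny) - 0.5) / px_per_mm - (half_mm[[2]] + pad_mm)
  xy_x <- matrix(x, nx, ny)
  xy_y <- matrix(y, nx, ny, byrow = TRUE)
  inside <- switch(shape,
    circle = xy_x^2 + xy_y^2 <= d$r^2,
    rectangle = abs(xy_x) <= d$w / 2 & abs(xy_y) <= d$h / 2,
    ellipse = (xy_x / d$a)^2 + (xy_y / d$b)^2 <= 1,
    lobed = {
      lobes <- if (is.null(d$lobes)) 5L else as.integer(d$lobes)
      depth <- if (is.null(d$depth)) 0.3 else d$depth
      stopifnot(depth > 0, depth < 1, lobes >= 2)
      phase <- with_seed(seed, stats::runif(1, 0, 2 * pi))
      ang <- atan2(xy_y, xy_x)
      rad <- d$r * (1 + depth * cos(lobes * ang + phase)) / (1 + depth)
      sqrt(xy_x^2 + xy_y^2) <= rad
    })
  list(mask = matrix(as.integer(inside), nx, ny), px_per_mm = px_per_mm)
}

#' Default leaf trait truth parameters
#'
#' Means and SDs for the synthetic raw-trait generator, set to mid-range
#' values for mature temperate broadleaf sun leaves: area ~3000 mm2,
#' thickness ~0.25 mm, fresh mass ~500 mg with dry:fresh fraction ~0.4
#' (LDMC ~400 mg/g), shortwave reflectance ~0.10 and transmittance ~0.05
#' (absorptance ~0.85).
#'
#' @return Named list of means and SDs.
#' @export
default_trait_params <- function() {
  list(area_mean = 3000, area_sd = 400,
       thickness_mean = 0.25, thickness_sd = 0.03,
       fresh_mean = 500, fresh_sd = 60,
       dmf_mean = 0.4, dmf_sd = 0.05,
       refl_mean = 0.10, refl_sd = 0.01,
       trans_mean = 0.05, trans_sd = 0.01)
}

#' Simulate raw leaf trait records
#'
#' Five leaves per tree across the full species x site x tree design, the
#' sampling intensity of standard trait protocols. Dry mass is generated as
#' a dry-matter fraction of fresh mass truncated to (0.01, 0.99), so
#' `fresh >= dry` holds by construction; reflectance and transmittance are
#' truncated to keep `R + T < 1` (physically, some light must be absorbed).
#'
#' @param design A [study_design()].
#' @param trait_params A single list ([default_trait_params()]) or a
#'   per-cell data.frame with `species`, `site` plus those fields.
#' @param leaves_per_tree Leaves collected per tree (default 5).
#' @param seed Integer seed.
#' @return Data.frame with columns `species`, `site`, `tree`, `leaf`,
#'   `area_mm2`, `thickness_mm`, `fresh_mg`, `dry_mg`, `reflectance`,
#'   `transmittance`.
#' @export
sim_trait_table <- function(design = study_design(),
                            trait_params = default_trait_params(),
                            leaves_per_tree = 5, seed = 1) {
  stopifnot(inherits(design, "study_design"), leaves_per_tree >= 1)
  fields <- names(default_trait_params())
  par_tab <- expand_cell_params(design, trait_params, fields)
  if (any(par_tab$area_mean <= 0 | par_tab$thickness_mean <= 0 |
          par_tab$fresh_mean <= 0 | par_tab$dmf_mean <= 0))
    stop("trait means must be positive")
  if (any(par_tab$refl_mean + par_tab$trans_mean >= 1))
    stop("impossible optics: mean reflectance + transmittance >= 1")

  rtrunc <- function(n, mean, sd, lo, hi = Inf) {
    x <- stats::rnorm(n, mean, sd)
    bad <- which(x <= lo | x >= hi)
    while (length(bad)) {
      x[bad] <- stats::rnorm(length(bad), mean, sd)
      bad <- bad[x[bad] <= lo | x[bad] >= hi]
    }
    x
  }
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(par_tab)), function(i) {
      p <- par_tab[i, ]
      n <- design$trees_per_species_site * leaves_per_tree
      cell <- expand.grid(leaf = seq_len(leaves_per_tree),
                          tree = seq_len(design$trees_per_species_site),
                          KEEP.OUT.ATTRS = FALSE)
      fresh <- rtrunc(n, p$fresh_mean, p$fresh_sd, 0)
      dmf <- rtrunc(n, p$dmf_mean, p$dmf_sd, 0.01, 0.99)
      refl <- rtrunc(n, p$refl_mean, p$refl_sd, 0, 1)
      tran <- rtrunc(n, p$trans_mean, p$trans_sd, 0, 1)
      bad <- which(refl + tran >= 1)
      while (length(bad)) {  # joint resample keeps the optics physical
        refl[bad] <- rtrunc(length(bad), p$refl_mean, p$refl_sd, 0, 1)
        tran[bad] <- rtrunc(length(bad), p$trans_mean, p$trans_sd, 0, 1)
        bad <- bad[refl[bad] + tran[bad] >= 1]
      }
      data.frame(species = p$species, site = p$site, tree = cell$tree,
                 leaf = cell$leaf,
                 area_mm2 = rtrunc(n, p$area_mean, p$area_sd, 0),
                 thickness_mm = rtrunc(n, p$thickness_mean, p$thickness_sd, 0),
                 fresh_mg = fresh, dry_mg = fresh * dmf,
                 reflectance = refl, transmittance = tran,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$species, out$site, out$tree, out$leaf), ]
    rownames(out) <- NULL
    out
  })
}

# Expand a single truth-parameter list to one row per species x site cell,
# or validate a user-supplied per-cell table against the design.
expand_cell_params <- function(design, params, fields) {
  cells <- expand.grid(species = design$species, site = design$sites,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (is.data.frame(params)) {
    need <- c("species", "site", fields)
    if (!all(need %in% names(params)))
      stop("per-cell params need columns: ", paste(need, collapse = ", "))
    merged <- merge(cells, params, by = c("species", "site"), all.x = TRUE)
    if (anyNA(merged[fields]))
      stop("params missing for some species x site cells")
    merged[order(merged$species, merged$site), , drop = FALSE]
  } else {
    if (!all(fields %in% names(params)))
      stop("params must contain: ", paste(fields, collapse = ", "))
    for (f in fields) cells[[f]] <- params[[f]]
    cells[order(cells$species, cells$site), , drop = FALSE]
  }
}
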