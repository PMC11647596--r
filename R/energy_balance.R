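# Linearized leaf-scale energy balance for a horizontal sun leaf.
#
# The leaf temperature equation balances absorbed isothermal net radiation
# against sensible heat, thermal re-radiation (linearized as a radiative
# conductance) and latent heat loss through the stomata-plus-boundary-layer
# vapor path:
#
#   Tl = Ta + gamma*/(s + gamma*) * [ Rni/(gHR cp) - VPD/(rho gamma*) ]
#
# with gHR = gHa + gr and gamma* = gamma * gHR/gwv. All conductances in
# mol m-2 s-1, radiation in W m-2, pressures in kPa, temperatures in deg C
# (Kelvin inside the radiation law).

#' Physical constants of the leaf energy balance
#'
#' Fixed constants: molar heat capacity of dry air `cp` = 29.3 J mol-1 C-1,
#' psychrometric constant `gamma` = 6.66e-4 C-1, Stefan-Boltzmann
#' `sigma` = 5.67e-8 W m-2 K-4, sea-level pressure 101.3 kPa and atmospheric
#' scale height 8200 m.
#'
#' @return Named list of constants.
#' @export
eb_constants <- function() {
  list(cp = 29.3, gamma = 6.66e-4, sigma = 5.67e-8,
       sea_level_kpa = 101.3, scale_height_m = 8200)
}

#' Atmospheric pressure from altitude
#'
#' Barometric decay `rho = 101.3 * exp(-altitude/8200)` kPa.
#'
#' @param altitude_m Altitude above sea level, m (>= -500).
#' @return Pressure in kPa (vectorized).
#' @export
atmospheric_pressure <- function(altitude_m) {
  if (any(!is.finite(altitude_m)) || any(altitude_m < -500))
    stop("altitude must be finite and >= -500 m")
  k <- eb_constants()
  k$sea_level_kpa * exp(-altitude_m / k$scale_height_m)
}

#' Saturation vapor pressure, VPD and the saturation-curve slope
#'
#' Tetens form: `es(T) = 0.611 * exp(17.502 T / (T + 240.97))` kPa, with
#' `VPD = es * (1 - RH/100)` and the slope term
#' `s = (d es/dT) / rho` used by the linearized energy balance (the
#' division by atmospheric pressure makes `s` commensurate with the
#' modified psychrometric constant).
#'
#' @param t_c Air temperature, deg C, in `[-20, 60]`.
#' @param rh_pct Relative humidity, percent, in (0, 100].
#' @param rho_kpa Atmospheric pressure, kPa.
#' @return kPa (es, vpd), C-1 (slope); all vectorized.
#' @export
saturation_vapor_pressure <- function(t_c) {
  if (any(!is.finite(t_c)) || any(t_c < -20 | t_c > 60))
    stop("temperature outside [-20, 60] C")
  0.611 * exp(17.502 * t_c / (t_c + 240.97))
}

#' @rdname saturation_vapor_pressure
#' @export
vpd <- function(t_c, rh_pct) {
  if (any(!is.finite(rh_pct)) || any(rh_pct <= 0 | rh_pct > 100))
    stop("relative humidity must be in (0, 100]")
  saturation_vapor_pressure(t_c) * (1 - rh_pct / 100)
}

#' @rdname saturation_vapor_pressure
#' @export
saturation_slope <- function(t_c, rho_kpa) {
  stopifnot(all(rho_kpa > 0))
  es <- saturation_vapor_pressure(t_c)
  delta <- es * 17.502 * 240.97 / (t_c + 240.97)^2
  delta / rho_kpa
}

#' Boundary-layer and radiative conductances
#'
#' `boundary_layer_conductance_heat`: forced-convection boundary-layer
#' conductance for heat of a flat leaf,
#' `gHa = 1.4 * 0.135 * sqrt(u/d)` mol m-2 s-1, with `u` wind speed (m s-1,
#' floored at `wind_floor` to keep the square root away from zero flow) and
#' `d` the effective leaf width (m).
#'
#' `radiative_conductance`: linearized thermal-radiation conductance
#' `gr = 4 sigma Ta_K^3 / cp` with `Ta_K` the air temperature in Kelvin.
#'
#' @param wind_ms Wind speed, m s-1.
#' @param width_m Effective leaf width, m, > 0.
#' @param wind_floor Minimum wind speed applied before the square root.
#' @param tair_c Air temperature, deg C, in `[-20, 60]`.
#' @return Conductance in mol m-2 s-1 (vectorized).
#' @export
boundary_layer_conductance_heat <- function(wind_ms, width_m,
                                            wind_floor = 0.1) {
  stopifnot(all(is.finite(wind_ms)), all(wind_ms >= 0),
            all(width_m > 0))
  u <- pmax(wind_ms, wind_floor)
  1.4 * 0.135 * sqrt(u / width_m)
}

#' @rdname boundary_layer_conductance_heat
#' @export
radiative_conductance <- function(tair_c) {
  if (any(!is.finite(tair_c)) || any(tair_c < -20 | tair_c > 60))
    stop("temperature outside [-20, 60] C")
  k <- eb_constants()
  4 * k$sigma * (tair_c + 273.15)^3 / k$cp
}

#' Water-vapor path conductances
#'
#' The boundary-layer conductance for vapor is
#' `gva = 1.4 * 0.147 * sqrt(u/d)`. The whole-path vapor conductance `gwv`
#' combines stomata and boundary layer; two combination rules are offered:
#'
#' * `"as_printed"` (default): `gwv = 0.5 * (gs/2) * gva / ((gs/2) + gva)`,
#'   the expression the source field protocol prints, which halves the
#'   stomatal conductance (one-sided stomata) and halves the series result.
#' * `"series_hypostomatous"`: the textbook series combination
#'   `gwv = gs * gva / (gs + gva)`.
#'
#' @param gs_mol Stomatal conductance to water vapor, mol m-2 s-1, > 0.
#' @param wind_ms Wind speed, m s-1.
#' @param width_m Effective leaf width, m.
#' @param mode Combination rule, see Details.
#' @param wind_floor Minimum wind speed.
#' @return List with `g_va` and `g_wv`, mol m-2 s-1.
#' @export
vapor_conductances <- function(gs_mol, wind_ms, width_m,
                               mode = c("as_printed", "series_hypostomatous"),
                               wind_floor = 0.1) {
  mode <- match.arg(mode)
  stopifnot(all(gs_mol > 0), all(width_m > 0), all(wind_ms >= 0))
  u <- pmax(wind_ms, wind_floor)
  g_va <- 1.4 * 0.147 * sqrt(u / width_m)
  g_wv <- switch(mode,
    as_printed = 0.5 * (gs_mol / 2) * g_va / ((gs_mol / 2) + g_va),
    series_hypostomatous = gs_mol * g_va / (gs_mol + g_va))
  list(g_va = g_va, g_wv = g_wv)
}

#' Modified psychrometric constant
#'
#' `gamma* = gamma * gHR / gwv`: the psychrometric constant rescaled by the
#' ratio of the heat-plus-radiative conductance to the vapor conductance,
#' so the latent-heat term sees the leaf's actual vapor path.
#'
#' @param g_hr Combined heat + radiative conductance, mol m-2 s-1, > 0.
#' @param g_wv Whole-path vapor conductance, mol m-2 s-1, > 0.
#' @return gamma* in C-1 (vectorized).
#' @export
modified_psychrometric <- function(g_hr, g_wv) {
  stopifnot(all(g_hr > 0), all(g_wv > 0))
  eb_constants()$gamma * g_hr / g_wv
}

#' Isothermal net radiation
#'
#' The net radiation the leaf would receive at air temperature. By default
#' only absorbed shortwave is counted (`a * solar` plus a configurable net
#' longwave term, default 0); a user-supplied `rni_wm2` overrides the
#' computation entirely, e.g. when net radiometer data exist.
#'
#' @param solar_wm2 Incident shortwave irradiance, W m-2, >= 0.
#' @param absorptance Leaf shortwave absorptance fraction.
#' @param rni_wm2 Optional override, W m-2.
#' @param net_longwave_wm2 Net longwave gain, W m-2 (default 0).
#' @return Rni in W m-2 (vectorized).
#' @export
isothermal_net_radiation <- function(solar_wm2, absorptance,
                                     rni_wm2 = NULL, net_longwave_wm2 = 0) {
  if (!is.null(rni_wm2) && !all(is.na(rni_wm2))) {
    out <- absorptance * solar_wm2 + net_longwave_wm2
    given <- !is.na(rni_wm2)
    out[given] <- rni_wm2[given]
    return(out)
  }
  stopifnot(all(solar_wm2 >= 0), all(absorptance > 0 & absorptance < 1))
  absorptance * solar_wm2 + net_longwave_wm2
}

#' Leaf temperature from the linearized energy balance
#'
#' Solves the linearized leaf energy balance for a horizontal sun leaf and
#' returns the predicted leaf temperature together with every intermediate
#' quantity, so each step of the chain can be audited.
#'
#' @param tair_c Air temperature, deg C.
#' @param rh_pct Relative humidity, percent, (0, 100].
#' @param wind_ms Wind speed, m s-1.
#' @param solar_wm2 Shortwave irradiance, W m-2.
#' @param width_m Effective leaf width, m.
#' @param gs_mol Stomatal conductance, mol m-2 s-1.
#' @param absorptance Leaf shortwave absorptance fraction.
#' @param altitude_m Site altitude, m (default 0).
#' @param rni_wm2 Optional isothermal net radiation override, W m-2.
#' @param gwv_mode Vapor-path combination rule, see [vapor_conductances()].
#' @param wind_floor Minimum wind speed, m s-1.
#' @return A data.frame (one row per input element) with `tleaf_c`,
#'   `delta_t_c` and the intermediates `rho_kpa`, `es_kpa`, `vpd_kpa`, `s`,
#'   `g_ha`, `g_r`, `g_hr`, `g_va`, `g_wv`, `gamma_star`, `rni_wm2`,
#'   `gwv_mode`.
#' @examples
#' leaf_temperature(tair_c = 25, rh_pct = 50, wind_ms = 1, solar_wm2 = 800,
#'                  width_m = 0.05, gs_mol = 0.3, absorptance = 0.5)
#' @export
leaf_temperature <- function(tair_c, rh_pct, wind_ms, solar_wm2,
                             width_m, gs_mol, absorptance,
                             altitude_m = 0, rni_wm2 = NULL,
                             gwv_mode = c("as_printed",
                                          "series_hypostomatous"),
                             wind_floor = 0.1) {
  gwv_mode <- match.arg(gwv_mode)
  k <- eb_constants()
  rho <- atmospheric_pressure(altitude_m)
  es <- saturation_vapor_pressure(tair_c)
  vpd_kpa <- vpd(tair_c, rh_pct)
  s <- saturation_slope(tair_c, rho)
  g_ha <- boundary_layer_conductance_heat(wind_ms, width_m, wind_floor)
  g_r <- radiative_conductance(tair_c)
  g_hr <- g_ha + g_r
  vap <- vapor_conductances(gs_mol, wind_ms, width_m, gwv_mode, wind_floor)
  gamma_star <- modified_psychrometric(g_hr, vap$g_wv)
  rni <- isothermal_net_radiation(solar_wm2, absorptance, rni_wm2)
  tl <- tair_c + gamma_star / (s + gamma_star) *
    (rni / (g_hr * k$cp) - vpd_kpa / (rho * gamma_star))
  out <- data.frame(tleaf_c = tl, delta_t_c = tl - tair_c,
                    tair_c = tair_c, rho_kpa = rho, es_kpa = es,
                    vpd_kpa = vpd_kpa, s = s, g_ha = g_ha, g_r = g_r,
                    g_hr = g_hr, g_va = vap$g_va, g_wv = vap$g_wv,
                    gamma_star = gamma_star, rni_wm2 = rni,
                    gwv_mode = gwv_mode, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Batch leaf temperature and site-level Tl vs Ta slope
#'
#' Applies [leaf_temperature()] to a table of per-tree leaf states paired
#' with their environment, and summarizes each site by the ordinary
#' least-squares slope of predicted leaf temperature on air temperature
#' (slopes above 1 indicate leaf temperatures pulling away from air
#' temperature as the air warms).
#'
#' @param trees Data.frame with columns `site`, `tair_c`, `rh_pct`,
#'   `wind_ms`, `solar_wm2`, `width_m`, `gs_mol`, `absorptance`, optional
#'   `altitude_m`, `rni_wm2` and id columns (`species`, `tree`) carried
#'   through.
#' @param gwv_mode,wind_floor Passed to [leaf_temperature()].
#' @return List with `results` (input ids + EBResult columns) and `slopes`
#'   (per site: OLS slope and intercept of tleaf_c ~ tair_c, mean delta T,
#'   n).
#' @export
batch_delta_t <- function(trees, gwv_mode = "as_printed", wind_floor = 0.1) {
  need <- c("site", "tair_c", "rh_pct", "wind_ms", "solar_wm2",
            "width_m", "gs_mol", "absorptance")
  stopifnot(is.data.frame(trees))
  miss <- setdiff(need, names(trees))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(trees[need])) stop("incomplete rows in input table")
  alt <- if ("altitude_m" %in% names(trees)) trees$altitude_m else 0
  rni <- if ("rni_wm2" %in% names(trees)) trees$rni_wm2 else NULL
  eb <- leaf_temperature(trees$tair_c, trees$rh_pct, trees$wind_ms,
                         trees$solar_wm2, trees$width_m, trees$gs_mol,
                         trees$absorptance, altitude_m = alt, rni_wm2 = rni,
                         gwv_mode = gwv_mode, wind_floor = wind_floor)
  ids <- trees[intersect(c("species", "site", "tree"), names(trees))]
  results <- cbind(ids, eb[setdiff(names(eb), "tair_c")],
                   tair_c = trees$tair_c)
  slopes <- do.call(rbind, lapply(split(results, results$site), function(d) {
    if (length(unique(d$tair_c)) > 1) {
      co <- stats::coef(stats::lm(tleaf_c ~ tair_c, data = d))
    } else co <- c(NA_real_, NA_real_)
    data.frame(site = d$site[1], slope = unname(co[2]),
               intercept = unname(co[1]),
               mean_delta_t_c = mean(d$delta_t_c), n = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(slopes) <- NULL
  list(results = results, slopes = slopes)
}
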