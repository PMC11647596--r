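#' Gaussian photosynthesis-temperature response
#'
#' `P(T) = P_opt * exp(-((T - T_opt)/Omega)^2)`: net photosynthesis peaks
#' at `P_opt` at the thermal optimum `T_opt` and falls symmetrically with
#' curve width `Omega` — the offset from `T_opt` at which the rate has
#' dropped to `e^-1` (about 37 percent) of the optimum.
#'
#' @param t_c Leaf temperature, deg C.
#' @param p_opt Optimum net assimilation.
#' @param t_opt Thermal optimum, deg C.
#' @param omega Curve width, deg C, > 0.
#' @return Predicted net assimilation (vectorized).
#' @export
gaussian_response <- function(t_c, p_opt, t_opt, omega) {
  stopifnot(all(omega > 0))
  p_opt * exp(-((t_c - t_opt) / omega)^2)
}

#' Predict from a fitted temperature-response curve
#'
#' @param fit A `gaussian_tr_fit` from [fit_temperature_response()].
#' @param t_c Leaf temperatures at which to predict.
#' @return Predicted net assimilation.
#' @export
predict_response <- function(fit, t_c) {
  stopifnot(inherits(fit, "gaussian_tr_fit"))
  if (!fit$converged) stop("cannot predict from a non-converged fit")
  gaussian_response(t_c, fit$p_opt, fit$t_opt, fit$omega)
}

#' Fit the Gaussian temperature response of photosynthesis
#'
#' Nonlinear least squares on `(T, Anet)` pairs with `Omega` parameterized
#' on the log scale (so the fitted width is always positive). The
#' initialization is deterministic: `T_opt` starts at the temperature
#' maximizing a 3-point moving average of Anet, `P_opt` at the maximum
#' Anet, and `Omega` is multistarted over 5, 10 and 20 deg C with the
#' lowest-residual fit kept. Standard errors come from the estimator
#' covariance; the `Omega` SE is delta-method transformed from the log
#' scale.
#'
#' @param tleaf_c Leaf temperatures, deg C; at least 5 distinct values
#'   spanning at least 10 deg C.
#' @param anet Net assimilation at those temperatures.
#' @param omega_starts Multistart values for Omega, deg C.
#' @return An object of class `gaussian_tr_fit`: list with `p_opt`,
#'   `t_opt`, `omega`, `se` (named vector), `sigma` (residual SD), `rss`,
#'   `n`, `converged`, `extrapolated` (TRUE when `t_opt` falls more than 5
#'   deg C outside the sampled range), and the underlying `nls` fit.
#' @examples
#' t <- seq(20, 40, 2)
#' fit <- fit_temperature_response(t, gaussian_response(t, 20, 28, 12))
#' c(fit$p_opt, fit$t_opt, fit$omega)
#' @export
fit_temperature_response <- function(tleaf_c, anet,
                                     omega_starts = c(5, 10, 20)) {
  stopifnot(length(tleaf_c) == length(anet))
  ok <- is.finite(tleaf_c) & is.finite(anet)
  tleaf_c <- tleaf_c[ok]; anet <- anet[ok]
  if (length(unique(tleaf_c)) < 5 || diff(range(tleaf_c)) < 10)
    stop("need >= 5 distinct temperatures spanning >= 10 C")
  ord <- order(tleaf_c)
  tleaf_c <- tleaf_c[ord]; anet <- anet[ord]

  sm <- stats::filter(anet, rep(1 / 3, 3), sides = 2)
  t_opt0 <- tleaf_c[which.max(ifelse(is.na(sm), -Inf, sm))]
  p_opt0 <- max(anet)
  df <- data.frame(t = tleaf_c, y = anet)

  best <- NULL
  for (w0 in omega_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ p * exp(-((t - to) / exp(lw))^2), data = df,
                        start = list(p = p_opt0, to = t_opt0, lw = log(w0)),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12)
        best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    out <- list(p_opt = NA_real_, t_opt = NA_real_, omega = NA_real_,
                se = c(p_opt = NA_real_, t_opt = NA_real_, omega = NA_real_),
                sigma = NA_real_, rss = NA_real_, n = length(anet),
                converged = FALSE, extrapolated = NA, fit = NULL)
    class(out) <- "gaussian_tr_fit"
    return(out)
  }
  co <- stats::coef(best$fit)
  omega <- exp(co[["lw"]])
  se <- tryCatch(sqrt(diag(stats::vcov(best$fit))),
                 error = function(e) rep(NA_real_, 3))
  se_named <- c(p_opt = unname(se[1]), t_opt = unname(se[2]),
                omega = omega * unname(se[3]))  # delta method for exp(lw)
  out <- list(p_opt = co[["p"]], t_opt = co[["to"]], omega = omega,
              se = se_named,
              sigma = stats::sigma(best$fit), rss = best$rss,
              n = length(anet), converged = TRUE,
              extrapolated = co[["to"]] < min(tleaf_c) - 5 ||
                co[["to"]] > max(tleaf_c) + 5,
              fit = best$fit)
  class(out) <- "gaussian_tr_fit"
  out
}

#' @export
print.gaussian_tr_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Gaussian temperature-response fit: NOT converged (n =", x$n, ")\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Gaussian temperature-response fit (n = %d)\n  P_opt = %.3f (SE %.3f)\n  T_opt = %.2f C (SE %.2f)\n  Omega = %.2f C (SE %.2f)\n",
    x$n, x$p_opt, x$se[["p_opt"]], x$t_opt, x$se[["t_opt"]],
    x$omega, x$se[["omega"]]))
  if (isTRUE(x$extrapolated)) cat("  (T_opt outside sampled range + 5 C)\n")
  invisible(x)
}

#' Fit temperature-response curves for every tree in a gas-exchange table
#'
#' @param records Data.frame with columns `species`, `site`, `tree`,
#'   `tleaf_c`, `anet` (as from [sim_at_curves()]).
#' @return Data.frame, one row per tree, with fitted `p_opt`, `t_opt`,
#'   `omega`, their SEs, `sigma`, `n`, `converged`.
#' @export
fit_temperature_response_all <- function(records) {
  need <- c("species", "site", "tree", "tleaf_c", "anet")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  key <- interaction(records$species, records$site, records$tree,
                     drop = TRUE)
  rows <- lapply(split(records, key), function(d) {
    f <- tryCatch(fit_temperature_response(d$tleaf_c, d$anet),
                  error = function(e) NULL)
    if (is.null(f)) f <- list(p_opt = NA, t_opt = NA, omega = NA,
                              se = c(p_opt = NA, t_opt = NA, omega = NA),
                              sigma = NA, n = nrow(d), converged = FALSE)
    data.frame(species = d$species[1], site = d$site[1], tree = d$tree[1],
               p_opt = f$p_opt, p_opt_se = f$se[["p_opt"]],
               t_opt = f$t_opt, t_opt_se = f$se[["t_opt"]],
               omega = f$omega, omega_se = f$se[["omega"]],
               sigma = f$sigma, n = f$n, converged = f$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$species, out$site, out$tree), ]
  rownames(out) <- NULL
  out
}

#' Standard-error overlap test for fitted parameters
#'
#' Compares two fitted parameters by the overlap statistic
#' `|x1 - x2| - t_crit * sqrt(SE1^2 + SE2^2)`; the difference is declared
#' significant when the statistic exceeds zero. The default multiplier
#' 2.99 is the adjusted t-score the field protocol uses for
#' multiple-comparison-corrected p = 0.05.
#'
#' @param x1,x2 Parameter estimates.
#' @param se1,se2 Their standard errors, > 0.
#' @param t_crit Critical multiplier (default 2.99).
#' @return List with `statistic` and `significant`.
#' @examples
#' overlap_test(30, 0.1, 28, 0.1)  # significant
#' @export
overlap_test <- function(x1, se1, x2, se2, t_crit = 2.99) {
  vals <- c(x1, se1, x2, se2, t_crit)
  if (any(!is.finite(vals))) stop("non-finite inputs")
  if (any(c(se1, se2) <= 0)) stop("standard errors must be positive")
  stat <- abs(x1 - x2) - t_crit * sqrt(se1^2 + se2^2)
  list(statistic = stat, significant = stat > 0)
}

#' Between-site contrast of fitted response parameters
#'
#' Aggregates per-tree fits to a species x site group estimate by
#' inverse-variance weighting (weights 1/SE^2; group SE =
#' `sqrt(1/sum(1/SE^2))`) and tests the hot-minus-cold difference of
#' `t_opt` and `p_opt` per species with [overlap_test()].
#'
#' @param fits Per-tree fit table from [fit_temperature_response_all()].
#' @param sites Length-2 character: the two site labels, difference taken
#'   as `sites[1] - sites[2]`.
#' @param t_crit Passed to [overlap_test()].
#' @return Data.frame with one row per species x parameter: `species`,
#'   `parameter`, estimates and SEs per site, `diff`, `statistic`,
#'   `significant`.
#' @export
site_parameter_contrast <- function(fits, sites = c("hot", "cold"),
                                    t_crit = 2.99) {
  stopifnot(is.data.frame(fits), length(sites) == 2)
  fits <- fits[fits$converged & is.finite(fits$t_opt_se) &
                 is.finite(fits$p_opt_se) & fits$t_opt_se > 0 &
                 fits$p_opt_se > 0, ]
  ivw <- function(x, se) {
    w <- 1 / se^2
    c(est = sum(w * x) / sum(w), se = sqrt(1 / sum(w)))
  }
  rows <- list()
  for (sp in unique(fits$species)) {
    d1 <- fits[fits$species == sp & fits$site == sites[1], ]
    d2 <- fits[fits$species == sp & fits$site == sites[2], ]
    if (nrow(d1) == 0 || nrow(d2) == 0) {
      warning("species ", sp, " present in only one site; skipped")
      next
    }
    for (par in c("t_opt", "p_opt")) {
      g1 <- ivw(d1[[par]], d1[[paste0(par, "_se")]])
      g2 <- ivw(d2[[par]], d2[[paste0(par, "_se")]])
      ot <- overlap_test(g1[["est"]], g1[["se"]], g2[["est"]], g2[["se"]],
                         t_crit)
      rows[[length(rows) + 1]] <- data.frame(
        species = sp, parameter = par,
        est_1 = g1[["est"]], se_1 = g1[["se"]],
        est_2 = g2[["est"]], se_2 = g2[["se"]],
        diff = g1[["est"]] - g2[["est"]],
        statistic = ot$statistic, significant = ot$significant,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("no species with fits in both sites")
  out <- do.call(rbind, rows)
  names(out)[names(out) == "est_1"] <- paste0("est_", sites[1])
  names(out)[names(out) == "se_1"] <- paste0("se_", sites[1])
  names(out)[names(out) == "est_2"] <- paste0("est_", sites[2])
  names(out)[names(out) == "se_2"] <- paste0("se_", sites[2])
  rownames(out) <- NULL
  out
}
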