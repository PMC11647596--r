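#' Maximum quantum efficiency of photosystem II
#'
#' `Fv/Fm = (Fm - F0)/Fm` from dark-adapted chlorophyll fluorescence:
#' the fraction of absorbed light that an undamaged photosystem II can use
#' photochemically (about 0.8 in healthy leaves; falls toward 0 as heat
#' damage accumulates).
#'
#' @param f0 Initial (minimal) fluorescence, > 0.
#' @param fm Maximal fluorescence, > `f0`.
#' @return The Fv/Fm ratio in (0, 1) (vectorized).
#' @export
fvfm <- function(f0, fm) {
  if (any(!is.finite(f0)) || any(!is.finite(fm)) || any(f0 <= 0))
    stop("fluorescence values must be positive and finite")
  if (any(fm <= f0)) stop("fm must exceed f0")
  (fm - f0) / fm
}

#' Logistic Fv/Fm decline with treatment temperature
#'
#' `theta1 / (1 + exp(-(theta2 + theta3 * T)))`: for `theta3 < 0` this
#' starts at the undamaged asymptote `theta1` and declines sigmoidally as
#' the water-bath treatment temperature `T` rises.
#'
#' @param t_c Treatment temperature, deg C.
#' @param theta1 Control asymptote (Fv/Fm units).
#' @param theta2 Intercept.
#' @param theta3 Slope, per deg C (negative for a decline).
#' @return Predicted Fv/Fm (vectorized).
#' @export
logistic_fvfm <- function(t_c, theta1, theta2, theta3) {
  theta1 / (1 + exp(-(theta2 + theta3 * t_c)))
}

#' Quality-control filter on control-temperature Fv/Fm
#'
#' Healthy dark-adapted leaves show Fv/Fm near 0.8; a tree whose
#' control-temperature disks average below `min_control_fvfm` was already
#' stressed before treatment and is excluded entirely (all its disks, at
#' every temperature).
#'
#' @param disks Disk table with columns `species`, `site`, `tree`,
#'   `bath_c`, `fvfm`.
#' @param control_c Control (lowest) bath temperature.
#' @param min_control_fvfm Exclusion threshold on the control mean
#'   (default 0.75).
#' @return List with `retained` (filtered disk table) and `rejected` (one
#'   row per excluded tree: ids, control mean, number of disks removed).
#' @export
qc_filter <- function(disks, control_c = min(disks$bath_c),
                      min_control_fvfm = 0.75) {
  need <- c("species", "site", "tree", "bath_c", "fvfm")
  stopifnot(is.data.frame(disks), all(need %in% names(disks)))
  if (!any(disks$bath_c == control_c))
    stop("no records at the control temperature ", control_c)
  key <- interaction(disks$species, disks$site, disks$tree, drop = TRUE)
  ctrl_mean <- tapply(disks$fvfm[disks$bath_c == control_c],
                      key[disks$bath_c == control_c], mean)
  bad <- names(ctrl_mean)[ctrl_mean < min_control_fvfm]
  # trees with no control disks at all cannot be QC'd; exclude them too
  no_ctrl <- setdiff(levels(key), names(ctrl_mean))
  bad <- c(bad, no_ctrl)
  rejected <- do.call(rbind, lapply(bad, function(k) {
    rows <- key == k
    data.frame(species = disks$species[rows][1], site = disks$site[rows][1],
               tree = disks$tree[rows][1],
               control_mean = if (k %in% names(ctrl_mean))
                 unname(ctrl_mean[k]) else NA_real_,
               n_disks_removed = sum(rows), stringsAsFactors = FALSE)
  }))
  if (is.null(rejected))
    rejected <- data.frame(species = character(), site = character(),
                           tree = integer(), control_mean = numeric(),
                           n_disks_removed = integer())
  list(retained = disks[!(key %in% bad), , drop = FALSE],
       rejected = rejected)
}

#' Fit the logistic heat-tolerance curve for one tree
#'
#' Nonlinear least squares of Fv/Fm on bath temperature with the
#' three-parameter logistic [logistic_fvfm()]. Initialization is
#' deterministic: `theta1` at the control-temperature mean, `theta3` from
#' the two-point slope of the logit-transformed means across the steepest
#' part of the decline, `theta2 = -theta3 * T_half` with `T_half` the
#' temperature where the mean first falls below half the control mean. A
#' fit with `theta3 >= 0` (no decline) is flagged invalid.
#'
#' @param bath_c Treatment temperatures (>= 5 distinct values including
#'   the lowest = control).
#' @param fvfm Measured Fv/Fm per disk.
#' @return An object of class `logistic_ht_fit`: list with `theta1`,
#'   `theta2`, `theta3`, `se` (named), `t_crit`, `t50`, `t95`, `sigma`,
#'   `rss`, `n`, `converged`, and the `nls` fit. Threshold temperatures are
#'   the closed-form damage temperatures at 15, 50 and 95 percent loss.
#' @examples
#' d <- sim_fvfm_disks(seed = 1)
#' one <- d[d$species == "ACPL" & d$site == "hot" & d$tree == 1, ]
#' fit_fvfm_logistic(one$bath_c, one$fvfm)
#' @export
fit_fvfm_logistic <- function(bath_c, fvfm) {
  stopifnot(length(bath_c) == length(fvfm))
  ok <- is.finite(bath_c) & is.finite(fvfm)
  bath_c <- bath_c[ok]; fvfm <- fvfm[ok]
  if (length(unique(bath_c)) < 5)
    stop("need >= 5 distinct bath temperatures")
  control_c <- min(bath_c)
  mt <- tapply(fvfm, bath_c, mean)
  ord_t <- order(as.numeric(names(mt)))
  mt <- mt[ord_t]
  temps <- as.numeric(names(mt))
  th1_0 <- max(unname(mt[1]), 0.05)
  # T_half: first temperature where the mean drops below half the control
  below <- which(mt < th1_0 / 2)
  t_half <- if (length(below)) temps[below[1]] else max(temps)
  # slope from the steepest adjacent drop of the mean curve
  dmu <- diff(mt) / diff(temps)
  th3_0 <- min(dmu) * 4 / th1_0   # logistic slope ~ 4/theta1 * dP/dT at T50
  if (!is.finite(th3_0) || th3_0 >= -1e-3) th3_0 <- -0.3
  th2_0 <- -th3_0 * t_half
  df <- data.frame(t = bath_c, y = fvfm)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ t1 / (1 + exp(-(t2 + t3 * t))), data = df,
                      start = list(t1 = th1_0, t2 = th2_0, t3 = th3_0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  bad <- function() {
    out <- list(theta1 = NA_real_, theta2 = NA_real_, theta3 = NA_real_,
                se = c(theta1 = NA_real_, theta2 = NA_real_,
                       theta3 = NA_real_),
                t_crit = NA_real_, t50 = NA_real_, t95 = NA_real_,
                sigma = NA_real_, rss = NA_real_, n = length(fvfm),
                converged = FALSE, fit = NULL)
    class(out) <- "logistic_ht_fit"
    out
  }
  if (is.null(fit)) return(bad())
  co <- stats::coef(fit)
  if (co[["t3"]] >= 0) return(bad())
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, 3))
  out <- list(theta1 = co[["t1"]], theta2 = co[["t2"]], theta3 = co[["t3"]],
              se = c(theta1 = unname(se[1]), theta2 = unname(se[2]),
                     theta3 = unname(se[3])),
              t_crit = threshold_temperature(co[["t2"]], co[["t3"]], 0.15),
              t50 = threshold_temperature(co[["t2"]], co[["t3"]], 0.50),
              t95 = threshold_temperature(co[["t2"]], co[["t3"]], 0.95),
              sigma = stats::sigma(fit), rss = sum(stats::resid(fit)^2),
              n = length(fvfm), converged = TRUE, fit = fit)
  class(out) <- "logistic_ht_fit"
  out
}

#' @export
print.logistic_ht_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Logistic heat-tolerance fit: NOT converged / no decline (n =",
        x$n, ")\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Logistic heat-tolerance fit (n = %d)\n  theta1 = %.3f  theta2 = %.2f  theta3 = %.3f /C\n  Tcrit = %.2f C  T50 = %.2f C  T95 = %.2f C\n",
    x$n, x$theta1, x$theta2, x$theta3, x$t_crit, x$t50, x$t95))
  invisible(x)
}

#' Damage-threshold temperature of a logistic decline
#'
#' Closed form for the temperature at which Fv/Fm has lost a given damage
#' fraction relative to the asymptote `theta1`: solving
#' `theta1/(1 + exp(-(theta2 + theta3 T))) = (1 - damage) * theta1` gives
#' `T = (log((1 - damage)/damage) - theta2) / theta3`. Damage 0.5 reduces
#' to `T50 = -theta2/theta3`; damage 0.15 and 0.95 give the onset (Tcrit)
#' and near-complete (T95) damage temperatures.
#'
#' @param theta2 Logistic intercept (or a `logistic_ht_fit`).
#' @param theta3 Logistic slope, < 0 (ignored if a fit is supplied).
#' @param damage Damage fraction in (0, 1).
#' @return Temperature in deg C (vectorized over `damage`).
#' @examples
#' threshold_temperature(25, -0.5, 0.5)   # 50
#' threshold_temperature(25, -0.5, 0.15)  # ~46.53
#' @export
threshold_temperature <- function(theta2, theta3 = NULL, damage = 0.5) {
  if (inherits(theta2, "logistic_ht_fit")) {
    fit <- theta2
    if (!fit$converged) stop("fit is not valid")
    theta3 <- fit$theta3
    theta2 <- fit$theta2
  }
  stopifnot(is.numeric(theta2), is.numeric(theta3))
  if (any(theta3 >= 0)) stop("theta3 must be negative (declining curve)")
  if (any(damage <= 0 | damage >= 1)) stop("damage must be in (0, 1)")
  (log((1 - damage) / damage) - theta2) / theta3
}

#' Bootstrap confidence intervals for heat-tolerance thresholds
#'
#' Resamples one tree's disks with replacement, refits the logistic, and
#' collects the threshold temperatures. Replicates whose refit fails or
#' shows no decline are dropped and counted; the interval is the 2.5/97.5
#' percentile of the surviving replicates.
#'
#' Resampling is plain (unstratified) by default. Stratifying by bath
#' temperature guarantees full temperature support in every replicate, but
#' with the usual three disks per temperature it deflates the within-
#' stratum bootstrap variance by a factor (n-1)/n = 2/3 and the resulting
#' intervals undercover markedly; it is available via `stratified = TRUE`
#' for designs with many disks per temperature.
#'
#' @param bath_c,fvfm One tree's disk data.
#' @param n_boot Number of bootstrap replicates (default 1000; 100 is the
#'   lighter replication some protocols use).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param stratified Resample within each bath temperature (default
#'   FALSE; see Details).
#' @param damage Damage fractions to track (default 0.15, 0.5, 0.95).
#' @return List with `point` (the full-sample `logistic_ht_fit`), `table`
#'   (per damage fraction: point estimate, bootstrap mean, `ci_lo`,
#'   `ci_hi`), `n_failed`, `unreliable` (TRUE when more than half the
#'   refits failed), and `replicates` (matrix of threshold draws).
#' @export
bootstrap_thresholds <- function(bath_c, fvfm, n_boot = 1000, seed = 1,
                                 stratified = FALSE,
                                 damage = c(0.15, 0.50, 0.95)) {
  stopifnot(n_boot >= 1)
  point <- fit_fvfm_logistic(bath_c, fvfm)
  if (!point$converged) stop("base fit invalid; nothing to bootstrap")
  idx_by_temp <- split(seq_along(bath_c), bath_c)
  draws <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      idx <- if (stratified) {
        unlist(lapply(idx_by_temp, function(i)
          i[sample.int(length(i), length(i), replace = TRUE)]),
          use.names = FALSE)
      } else {
        sample.int(length(bath_c), length(bath_c), replace = TRUE)
      }
      f <- tryCatch(fit_fvfm_logistic(bath_c[idx], fvfm[idx]),
                    error = function(e) NULL)
      if (is.null(f) || !f$converged) return(rep(NA_real_, length(damage)))
      threshold_temperature(f$theta2, f$theta3, damage)
    })
  })
  reps <- do.call(rbind, draws)
  colnames(reps) <- paste0("damage_", damage)
  ok <- stats::complete.cases(reps)
  n_failed <- sum(!ok)
  if (!any(ok)) stop("all bootstrap refits failed")
  tab <- data.frame(damage = damage,
                    estimate = threshold_temperature(point$theta2,
                                                     point$theta3, damage),
                    boot_mean = colMeans(reps[ok, , drop = FALSE]),
                    ci_lo = apply(reps[ok, , drop = FALSE], 2,
                                  stats::quantile, 0.025, names = FALSE),
                    ci_hi = apply(reps[ok, , drop = FALSE], 2,
                                  stats::quantile, 0.975, names = FALSE))
  rownames(tab) <- NULL
  list(point = point, table = tab, n_failed = n_failed,
       unreliable = n_failed > n_boot / 2, replicates = reps)
}

#' Fit heat-tolerance curves for every tree in a disk table
#'
#' Applies QC, fits each retained tree, and reports parameters and
#' thresholds; trees with invalid fits carry `converged = FALSE`.
#'
#' @param disks Disk table (`species`, `site`, `tree`, `bath_c`, `fvfm`).
#' @param min_control_fvfm QC threshold, see [qc_filter()].
#' @return Data.frame, one row per tree.
#' @export
fit_heat_tolerance_all <- function(disks, min_control_fvfm = 0.75) {
  qc <- qc_filter(disks, min_control_fvfm = min_control_fvfm)
  d <- qc$retained
  key <- interaction(d$species, d$site, d$tree, drop = TRUE)
  rows <- lapply(split(d, key), function(g) {
    f <- tryCatch(fit_fvfm_logistic(g$bath_c, g$fvfm),
                  error = function(e) NULL)
    conv <- !is.null(f) && f$converged
    data.frame(species = g$species[1], site = g$site[1], tree = g$tree[1],
               theta1 = if (conv) f$theta1 else NA_real_,
               theta2 = if (conv) f$theta2 else NA_real_,
               theta3 = if (conv) f$theta3 else NA_real_,
               t_crit = if (conv) f$t_crit else NA_real_,
               t50 = if (conv) f$t50 else NA_real_,
               t95 = if (conv) f$t95 else NA_real_,
               n = nrow(g), converged = conv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$species, out$site, out$tree), ]
  rownames(out) <- NULL
  out
}

#' Species-level heat-tolerance table and between-site contrast
#'
#' Averages tree-level thresholds to species x site means (SE = SD/sqrt(n))
#' and tests the hot-minus-cold difference of each threshold per species
#' with [overlap_test()].
#'
#' @param fits Tree-level fit table from [fit_heat_tolerance_all()].
#' @param sites Length-2 character, difference taken `sites[1] - sites[2]`.
#' @param min_trees Minimum valid trees per species x site (default 2).
#' @param t_crit_mult Overlap-test multiplier (default 2.99).
#' @return Data.frame with one row per species x threshold: means, SEs,
#'   `diff`, `statistic`, `significant`.
#' @export
species_ht_table <- function(fits, sites = c("hot", "cold"), min_trees = 2,
                             t_crit_mult = 2.99) {
  stopifnot(is.data.frame(fits), length(sites) == 2)
  fits <- fits[fits$converged, ]
  rows <- list()
  for (sp in unique(fits$species)) {
    d1 <- fits[fits$species == sp & fits$site == sites[1], ]
    d2 <- fits[fits$species == sp & fits$site == sites[2], ]
    if (nrow(d1) < min_trees || nrow(d2) < min_trees) {
      warning("species ", sp, " undersampled in at least one site; skipped")
      next
    }
    for (thr in c("t_crit", "t50", "t95")) {
      m1 <- mean(d1[[thr]]); s1 <- stats::sd(d1[[thr]]) / sqrt(nrow(d1))
      m2 <- mean(d2[[thr]]); s2 <- stats::sd(d2[[thr]]) / sqrt(nrow(d2))
      ot <- overlap_test(m1, max(s1, 1e-9), m2, max(s2, 1e-9), t_crit_mult)
      rows[[length(rows) + 1]] <- data.frame(
        species = sp, threshold = thr,
        mean_1 = m1, se_1 = s1, mean_2 = m2, se_2 = s2,
        diff = m1 - m2, statistic = ot$statistic,
        significant = ot$significant, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("no species with enough valid trees")
  out <- do.call(rbind, rows)
  names(out)[names(out) == "mean_1"] <- paste0("mean_", sites[1])
  names(out)[names(out) == "se_1"] <- paste0("se_", sites[1])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", sites[2])
  names(out)[names(out) == "se_2"] <- paste0("se_", sites[2])
  rownames(out) <- NULL
  out
}
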