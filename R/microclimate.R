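#' Daily temperature summaries for one site
#'
#' Collapses a 30-minute microclimate series to one row per calendar day
#' with the four summaries used for the site contrast: whole-day mean
#' (`t_mean`), daytime mean (`t_day_mean`), daytime maximum (`t_day_max`)
#' and night mean (`t_night_mean`). Daytime is defined by measured
#' irradiance above `solar_threshold` (loggers record irradiance; no clock
#' rule is assumed). Days with fewer than `min_coverage` of the expected 48
#' records are dropped to avoid biased maxima; days with no daytime records
#' carry `NA` day fields and are flagged.
#'
#' @param series Data.frame with columns `timestamp` (POSIXct), `tair_c`,
#'   `solar_wm2` (one site; a `site` column, if present, must be constant).
#' @param solar_threshold Irradiance (W m-2) above which a record counts as
#'   daytime. Default 5.
#' @param min_coverage Minimum fraction of the expected 48 records per day.
#' @return Data.frame with columns `date`, `t_mean`, `t_day_mean`,
#'   `t_day_max`, `t_night_mean`, `n_records`, `incomplete_day` (logical,
#'   TRUE when a day had no daytime or no night records).
#' @export
daily_summaries <- function(series, solar_threshold = 5,
                            min_coverage = 0.8) {
  stopifnot(is.data.frame(series),
            all(c("timestamp", "tair_c", "solar_wm2") %in% names(series)))
  if (nrow(series) == 0) stop("empty series")
  if ("site" %in% names(series) && length(unique(series$site)) > 1)
    stop("daily_summaries expects a single site; split by site first")
  if (!all(is.finite(series$tair_c))) stop("non-finite air temperatures")
  if (any(series$solar_wm2 < 0)) stop("negative irradiance")
  series <- series[order(series$timestamp), ]
  if (any(duplicated(series$timestamp))) stop("duplicated timestamps")

  date <- as.Date(series$timestamp, tz = "UTC")
  keep_days <- names(which(table(date) >= min_coverage * 48))
  if (length(keep_days) == 0) stop("no day reaches the coverage threshold")
  rows <- lapply(keep_days, function(d) {
    s <- series[date == as.Date(d), ]
    is_day <- s$solar_wm2 > solar_threshold
    data.frame(date = as.Date(d),
               t_mean = mean(s$tair_c),
               t_day_mean = if (any(is_day)) mean(s$tair_c[is_day]) else NA_real_,
               t_day_max = if (any(is_day)) max(s$tair_c[is_day]) else NA_real_,
               t_night_mean = if (any(!is_day)) mean(s$tair_c[!is_day]) else NA_real_,
               n_records = nrow(s),
               incomplete_day = !any(is_day) || !any(!is_day))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Remove serial correlation by autoregressive prewhitening
#'
#' Fits AR(p) models of order 0..`max_order` by Yule-Walker, selects the
#' order by BIC (the consistent criterion: AIC tends to pick spurious
#' positive orders on white series) and returns the residuals of the
#' selected model. This prepares
#' serially correlated daily temperature series for a rank-based location
#' test, whose nominal level assumes exchangeable observations. The fitted
#' series mean is added back to the innovations, so the residuals are
#' whitened but keep the series level — a downstream location test still
#' compares temperature levels, not innovation shapes. A constant series is
#' handled as order 0 with demeaned (all-zero) residuals.
#'
#' @param x Equally spaced numeric series, length > 10 * `max_order`.
#' @param max_order Maximum AR order considered (default 5).
#' @return List with `order` (selected p), `residuals` (length
#'   `length(x) - order`), and `ar` (the `stats::ar` fit, or NULL for a
#'   constant series).
#' @export
prewhiten_ar <- function(x, max_order = 5) {
  stopifnot(is.numeric(x), max_order >= 0)
  if (!all(is.finite(x))) stop("non-finite values in series")
  if (length(x) <= 10 * max_order)
    stop("series too short for max_order = ", max_order)
  if (stats::var(x) == 0)
    return(list(order = 0L, residuals = x - mean(x), ar = NULL))
  n <- length(x)
  bic <- numeric(max_order + 1)
  fits <- vector("list", max_order + 1)
  for (k in 0:max_order) {
    if (k == 0) {
      sigma2 <- mean((x - mean(x))^2)
    } else {
      fits[[k + 1]] <- stats::ar(x, aic = FALSE, order.max = k,
                                 method = "yule-walker")
      r <- fits[[k + 1]]$resid
      sigma2 <- mean(r^2, na.rm = TRUE)
    }
    bic[k + 1] <- n * log(sigma2) + (k + 1) * log(n)
  }
  best <- which.min(bic) - 1L
  if (best == 0L)
    return(list(order = 0L, residuals = x, ar = NULL))
  fit <- fits[[best + 1]]
  res <- as.numeric(fit$resid)
  res <- res[!is.na(res)] + fit$x.mean
  list(order = best, residuals = res, ar = fit)
}

#' Two-sample rank-sum (Wilcoxon/Mann-Whitney) test
#'
#' Location test on ranks: exact two-sided p-value by complete enumeration
#' of all rank assignments when `length(x) + length(y) <= exact_max`
#' (midranks make the enumeration valid under ties), and the normal
#' approximation with tie correction and continuity correction otherwise.
#' The statistic reported is W, the rank sum of `x` in the pooled sample.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param exact_max Pooled-size cutoff for exact enumeration (default 12).
#' @return List with `statistic` (W), `p_two_sided`, `method`.
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4))$p_two_sided  # 1/3, exact
#' @export
rank_sum_test <- function(x, y, exact_max = 12) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  if (!all(is.finite(c(x, y)))) stop("non-finite values")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  if (stats::var(c(x, y)) == 0) {
    warning("all values tied across both samples; p = 1")
    return(list(statistic = w, p_two_sided = 1, method = "degenerate"))
  }
  if (n <= exact_max) {
    sums <- utils::combn(r, nx, sum)
    p <- min(1, 2 * min(mean(sums <= w), mean(sums >= w)))
    return(list(statistic = w, p_two_sided = p, method = "exact"))
  }
  mu <- nx * (n + 1) / 2
  ties <- table(r)
  sig2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (abs(w - mu) - 0.5) / sqrt(sig2)   # continuity-corrected
  p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
  list(statistic = w, p_two_sided = max(p, .Machine$double.xmin),
       method = "normal")
}

#' Paired-site microclimate contrast
#'
#' Compares two sites' temperature regimes summary-by-summary: for each of
#' the four daily statistics (mean, daytime mean, daytime max, night mean)
#' it reports the difference of across-day means (site a minus site b) and
#' a rank-sum p-value computed on AR-prewhitened residuals of the two daily
#' series, so serial correlation does not inflate significance.
#'
#' @param a,b Microclimate data.frames (one site each) as produced by
#'   [sim_microclimate()] (columns `timestamp`, `tair_c`, `solar_wm2`).
#' @param solar_threshold Passed to [daily_summaries()].
#' @param max_order Passed to [prewhiten_ar()]; reduced automatically when
#'   the overlap is short.
#' @return Data.frame with one row per summary statistic: `statistic`,
#'   `diff_c`, `p_value`, `n_days`.
#' @export
site_contrast <- function(a, b, solar_threshold = 5, max_order = 5) {
  sa <- daily_summaries(a, solar_threshold)
  sb <- daily_summaries(b, solar_threshold)
  common <- intersect(as.character(sa$date), as.character(sb$date))
  if (length(common) == 0) stop("no overlapping days between the two sites")
  sa <- sa[as.character(sa$date) %in% common, ]
  sb <- sb[as.character(sb$date) %in% common, ]
  stats_cols <- c("t_mean", "t_day_mean", "t_day_max", "t_night_mean")
  ord <- min(max_order, max(0, floor((length(common) - 1) / 10)))
  rows <- lapply(stats_cols, function(sc) {
    xa <- sa[[sc]]; xb <- sb[[sc]]
    ok <- is.finite(xa) & is.finite(xb)
    xa <- xa[ok]; xb <- xb[ok]
    ra <- prewhiten_ar(xa, max_order = ord)$residuals
    rb <- prewhiten_ar(xb, max_order = ord)$residuals
    p <- suppressWarnings(rank_sum_test(ra, rb)$p_two_sided)
    data.frame(statistic = sc, diff_c = mean(xa) - mean(xb),
               p_value = p, n_days = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
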