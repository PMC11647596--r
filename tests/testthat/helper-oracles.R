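# Independent oracles used across the suite. Each one recomputes the
# quantity it checks from first principles (equations, enumeration or grid
# search), never by calling the implementation under test.

# Stepwise evaluation of the linearized energy-balance chain, written
# directly from the equations with its own constants.
eb_oracle <- function(Ta, RH, u, S, d, gs, a, alt = 0,
                      mode = "as_printed") {
  sigma <- 5.67e-8; cp <- 29.3; gamma <- 6.66e-4
  rho <- 101.3 * exp(-alt / 8200)
  es <- 0.611 * exp(17.502 * Ta / (Ta + 240.97))
  VPD <- es * (1 - RH / 100)
  slope <- es * 17.502 * 240.97 / (Ta + 240.97)^2 / rho
  uu <- max(u, 0.1)
  gHa <- 1.4 * 0.135 * sqrt(uu / d)
  gr <- 4 * sigma * (Ta + 273.15)^3 / cp
  gHR <- gHa + gr
  gva <- 1.4 * 0.147 * sqrt(uu / d)
  gwv <- if (mode == "as_printed") {
    0.5 * (gs / 2) * gva / ((gs / 2) + gva)
  } else {
    gs * gva / (gs + gva)
  }
  gstar <- gamma * gHR / gwv
  Rni <- a * S
  Ta + gstar / (slope + gstar) * (Rni / (gHR * cp) - VPD / (rho * gstar))
}

# Brute-force two-sided rank-sum p-value: enumerate every assignment of the
# pooled midranks to the x-sample and apply the doubled-tail rule.
rank_sum_enum <- function(x, y) {
  r <- rank(c(x, y))
  nx <- length(x)
  w <- sum(r[seq_len(nx)])
  sums <- utils::combn(r, nx, sum)
  min(1, 2 * min(mean(sums <= w), mean(sums >= w)))
}

# Coarse-to-fine grid search for the Gaussian temperature-response least
# squares minimum (final lattice step 0.01 on every parameter).
gaussian_lattice <- function(t, y, centre, half_width = 2) {
  best <- NULL
  search <- function(p_grid, to_grid, w_grid) {
    for (p in p_grid) for (to in to_grid) for (w in w_grid) {
      rss <- sum((y - p * exp(-((t - to) / w)^2))^2)
      if (is.null(best) || rss < best$rss)
        best <<- list(p_opt = p, t_opt = to, omega = w, rss = rss)
    }
  }
  search(seq(centre[1] - half_width, centre[1] + half_width, by = 0.1),
         seq(centre[2] - half_width, centre[2] + half_width, by = 0.1),
         seq(centre[3] - half_width, centre[3] + half_width, by = 0.1))
  c0 <- c(best$p_opt, best$t_opt, best$omega)
  search(seq(c0[1] - 0.15, c0[1] + 0.15, by = 0.01),
         seq(c0[2] - 0.15, c0[2] + 0.15, by = 0.01),
         seq(c0[3] - 0.15, c0[3] + 0.15, by = 0.01))
  best
}

# Same idea for the three-parameter logistic decline of Fv/Fm.
logistic_lattice <- function(t, y, centre) {
  best <- NULL
  search <- function(t1_grid, t2_grid, t3_grid) {
    for (t1 in t1_grid) for (t2 in t2_grid) for (t3 in t3_grid) {
      rss <- sum((y - t1 / (1 + exp(-(t2 + t3 * t))))^2)
      if (is.null(best) || rss < best$rss)
        best <<- list(theta1 = t1, theta2 = t2, theta3 = t3, rss = rss)
    }
  }
  search(seq(centre[1] - 0.1, centre[1] + 0.1, by = 0.01),
         seq(centre[2] - 5, centre[2] + 5, by = 0.25),
         seq(centre[3] - 0.2, centre[3] + 0.2, by = 0.01))
  c0 <- c(best$theta1, best$theta2, best$theta3)
  search(seq(c0[1] - 0.015, c0[1] + 0.015, by = 0.001),
         seq(c0[2] - 0.4, c0[2] + 0.4, by = 0.01),
         seq(c0[3] - 0.015, c0[3] + 0.015, by = 0.001))
  best
}

# One tree's noiseless disk set on a given logistic truth.
make_disks <- function(theta1 = 0.8, theta2 = 30, theta3 = -0.6, sd = 0,
                       baths = c(22, 40, 42.2, 44.5, 47, 49.3, 51.5,
                                 53.2, 56.5), disks = 3) {
  t <- rep(baths, each = disks)
  y <- theta1 / (1 + exp(-(theta2 + theta3 * t)))
  if (sd > 0) y <- pmin(1, pmax(0, y + rnorm(length(t), 0, sd)))
  data.frame(bath_c = t, fvfm = y)
}
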