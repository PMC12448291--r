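# Steady-state cross-feeding model: closed forms, mass balance, the PDE
# cross-check, release-rate optima, and trait-space phase structure.

test_that("degrader steady state follows logistic-with-mortality closed form", {
  p0 <- particle_params(lysis_rate = 0, death_rate = 0, secretion_cost = 0)
  expect_equal(degrader_steady_state(p0), p0$degrader_capacity)

  collapse <- particle_params(lysis_rate = 0.5, degrader_max_rate = 0.5)
  expect_equal(degrader_steady_state(collapse), 0)

  half <- particle_params(lysis_rate = 0.25, degrader_max_rate = 0.5)
  expect_equal(degrader_steady_state(half), half$degrader_capacity / 2)

  # secretion cost reduces the effective rate: r_eff = r (1 - c s)
  costly <- particle_params(lysis_rate = 0, death_rate = 0.1,
                            secretion_cost = 0.002, secretion_rate = 100,
                            degrader_max_rate = 0.5)
  r_eff <- 0.5 * (1 - 0.002 * 100)
  expect_equal(degrader_steady_state(costly),
               costly$degrader_capacity * (1 - 0.1 / r_eff))
})

test_that("vitamin release is linear in each channel and additive", {
  p <- particle_params(secretion_rate = 10, lysis_rate = 0.36)
  tr <- auxotroph_traits(1e-9, 50)
  expect_equal(vitamin_source(p, 0, tr, "both"), 0)
  p0 <- particle_params(secretion_rate = 0, lysis_rate = 0)
  expect_equal(vitamin_source(p0, 1e5, tr, "both"), 0)

  expect_equal(vitamin_source(p, 2e4, tr, "secretion"), 10 * 2e4)
  lys1 <- vitamin_source(p, 2e4, tr, "lysis")
  expect_equal(lys1, 0.36 / 3600 * 2e4 * 50)
  # doubling the quota doubles lysis release
  expect_equal(vitamin_source(p, 2e4, auxotroph_traits(1e-9, 100), "lysis"),
               2 * lys1)
  expect_equal(vitamin_source(p, 2e4, tr, "both"),
               vitamin_source(p, 2e4, tr, "secretion") + lys1)
  # an explicit producer quota overrides the auxotroph quota
  p_q <- particle_params(secretion_rate = 10, lysis_rate = 0.36,
                         producer_quota = 500)
  expect_equal(vitamin_source(p_q, 2e4, tr, "lysis"), 10 * lys1)
})

test_that("surface concentration matches the diffusion closed form without uptake", {
  p <- particle_params(n_auxotrophs = 0)
  tr <- auxotroph_traits(1e-9, 20)
  Q <- 1e6
  # steady diffusion from a sphere: C_s = C_inf + Q / (4 pi D R)
  R <- p$radius_um * 1e-6
  expected <- Q / (4 * pi * p$diffusivity * R) / (1000 * 6.02214076e23)
  expect_equal(solve_surface_concentration(p, tr, Q), expected,
               tolerance = 1e-9)
  expect_equal(solve_surface_concentration(p, tr, 0), 0)

  p_bg <- particle_params(n_auxotrophs = 0, far_field_molar = 1e-10)
  expect_equal(solve_surface_concentration(p_bg, tr, Q), expected + 1e-10,
               tolerance = 1e-9)
})

test_that("auxotroph growth is Monod in the surface concentration", {
  p <- particle_params()
  tr <- auxotroph_traits(2e-9, 20)
  expect_equal(auxotroph_growth(p, tr, 2e-9), p$auxotroph_max_rate / 2)
  expect_equal(auxotroph_growth(p, tr, 0), 0)
  expect_equal(auxotroph_growth(p, tr, 1), p$auxotroph_max_rate,
               tolerance = 1e-8)
  # substrate co-limitation multiplies in as a second Monod factor
  p_sub <- particle_params(substrate_half_sat = 1e-5, substrate_conc = 1e-5)
  expect_equal(auxotroph_growth(p_sub, tr, 2e-9), p_sub$auxotroph_max_rate / 4)
})

test_that("every solved steady state closes its mass balance to 1e-8", {
  samples <- gen_model_params(seed = 101, n = 8)
  for (i in seq_len(nrow(samples))) {
    s <- samples[i, ]
    p <- particle_params(radius_um = s$radius_um,
                         secretion_rate = s$secretion_rate,
                         lysis_rate = s$lysis_rate,
                         n_auxotrophs = s$n_auxotrophs)
    tr <- auxotroph_traits(s$half_saturation, s$quota)
    for (mode in c("secretion", "lysis", "both")) {
      ss <- steady_state(p, tr, mode)
      if (ss$source > 0) {
        expect_lt(abs(ss$source - ss$diffusive_loss - ss$consumption) / ss$source,
                  1e-8)
      }
      expect_gte(ss$surface_molar, 0)
      expect_true(ss$normalized_rate >= 0 && ss$normalized_rate <= 1)
    }
  }
})

test_that("bisection root agrees with the radial simulation oracle within 2%", {
  samples <- gen_model_params(seed = 2024, n = 4)
  for (i in seq_len(nrow(samples))) {
    s <- samples[i, ]
    p <- particle_params(radius_um = s$radius_um,
                         secretion_rate = s$secretion_rate,
                         lysis_rate = s$lysis_rate,
                         n_auxotrophs = s$n_auxotrophs)
    tr <- auxotroph_traits(s$half_saturation, s$quota)
    Q <- vitamin_source(p, degrader_steady_state(p), tr, "both")
    pde <- simulate_radial_pde(p, tr, Q)
    expect_true(pde$converged)
    # compare on the same finite shell the simulation used
    root <- solve_surface_concentration(p, tr, Q,
                                        outer_radius_um = pde$outer_radius_um)
    expect_lt(abs(pde$surface_molar - root) / root, 0.02)
  }
  # trivial cases: no source stays flat; no uptake matches the shell solution
  p0 <- particle_params(far_field_molar = 1e-10, n_auxotrophs = 0)
  tr0 <- auxotroph_traits(1e-9, 20)
  flat <- simulate_radial_pde(p0, tr0, Q = 0, n_shells = 100)
  expect_equal(flat$surface_molar, 1e-10, tolerance = 1e-6)
  shell <- simulate_radial_pde(p0, tr0, Q = 1e5, n_shells = 400)
  analytic <- solve_surface_concentration(p0, tr0, 1e5,
                                          outer_radius_um = shell$outer_radius_um)
  expect_equal(shell$surface_molar, analytic, tolerance = 2e-3)
})

test_that("lysis release is optimal at half the degrader growth rate", {
  p <- particle_params(secretion_rate = 0)
  tr <- auxotroph_traits(1e-9, 20)   # deeply sub-saturated
  sw <- sweep_release_rate(p, tr, mode = "lysis")
  expect_lt(max(sw$profile$normalized_rate), 0.5)  # sub-saturated regime
  expect_lt(abs(sw$optimum_rate - p$degrader_max_rate / 2), sw$rate_step + 1e-12)
  # growth collapses with the degraders at full-rate lysis
  expect_equal(dplyr::last(sw$profile$auxotroph_rate), 0)
})

test_that("costless secretion is monotone; cost plus mortality creates an optimum", {
  tr <- auxotroph_traits(1e-8, 100)
  free <- sweep_release_rate(particle_params(), tr, mode = "secretion")
  expect_true(all(diff(free$profile$auxotroph_rate) > -1e-12))

  costly <- particle_params(secretion_cost = 0.005, death_rate = 0.05)
  # grid spans the viable range: r_eff > m requires s < (1 - m/r)/c = 180
  sw <- sweep_release_rate(costly, tr, mode = "secretion",
                           rates = seq(0, 175, length.out = 200))
  i_opt <- which.max(sw$profile$auxotroph_rate)
  expect_gt(i_opt, 1)
  expect_lt(i_opt, nrow(sw$profile))
  # brute-force closed form for the released flux Q(s) on a fine grid
  s_grid <- seq(0, 0.999 / costly$secretion_cost, length.out = 5000)
  r_eff <- costly$degrader_max_rate * (1 - costly$secretion_cost * s_grid)
  Q <- s_grid * pmax(0, costly$degrader_capacity * (1 - costly$death_rate / r_eff))
  s_star <- s_grid[which.max(Q)]
  expect_lt(abs(sw$optimum_rate - s_star), 3 * sw$rate_step)
})

test_that("secretion phase structure matches the analytic L within factor 2", {
  p <- particle_params(lysis_rate = 0)
  pd <- compute_phase_diagram(p, mode = "secretion",
                              ks_grid = 10^seq(-11, -5, length.out = 30),
                              quota_grid = 10^seq(1, 6, length.out = 30))
  # log-interpolated location where growth drops through theta along an axis
  crossing_at <- function(axis, growth, theta) {
    i <- max(which(growth >= theta))
    if (i == length(axis)) return(NA_real_)  # no crossing inside the grid
    exp(approx(growth[c(i, i + 1)], log(axis[c(i, i + 1)]), xout = theta)$y)
  }
  for (theta in c(0.9, 0.5)) {
    th <- secretion_thresholds(p, theta)
    grid <- pd$grid
    # affinity arm: in rows far below the quota bound, the K_S at which
    # growth crosses theta must sit within a factor 2 of the bound
    low_q <- sort(unique(grid$quota))
    low_q <- low_q[low_q < th$quota_max / 4]
    for (q in low_q[seq(1, length(low_q), by = 4)]) {
      row <- dplyr::arrange(dplyr::filter(grid, quota == q), ks_molar)
      ks_cross <- crossing_at(row$ks_molar, row$normalized_growth, theta)
      expect_lt(abs(log(ks_cross / th$ks_max_molar)), log(2))
    }
    # supply arm: in columns far left of the affinity bound, the quota at
    # which growth crosses theta must sit within a factor 2 of the bound
    low_k <- sort(unique(grid$ks_molar))
    low_k <- low_k[low_k < th$ks_max_molar / 4]
    for (k in low_k[seq(1, length(low_k), by = 4)]) {
      col <- dplyr::arrange(dplyr::filter(grid, ks_molar == k), quota)
      q_cross <- crossing_at(col$quota, col$normalized_growth, theta)
      if (!is.na(q_cross)) {
        expect_lt(abs(log(q_cross / th$quota_max)), log(2))
      }
    }
  }
  # midpoint algebra: at theta = 0.5 the affinity bound equals C_s0
  th05 <- secretion_thresholds(p, 0.5)
  cs0 <- steady_state(particle_params(lysis_rate = 0, n_auxotrophs = 0),
                      auxotroph_traits(1e-9, 20), "secretion")$surface_molar
  expect_equal(th05$ks_max_molar, cs0, tolerance = 1e-6)
  # doubling s doubles the quota bound
  p2 <- particle_params(lysis_rate = 0,
                        secretion_rate = 2 * p$secretion_rate)
  expect_equal(secretion_thresholds(p2, 0.5)$quota_max,
               2 * th05$quota_max, tolerance = 1e-12)
})

test_that("lysis growth is scale-invariant in (K_S, quota) and slope 1 in each", {
  p <- particle_params(secretion_rate = 0)
  growth <- function(ks, q) {
    steady_state(p, auxotroph_traits(ks, q), "lysis")$normalized_rate
  }
  # scaling both trait axes by 10 leaves growth invariant (within 5%)
  for (ks in 10^c(-10, -8, -6)) {
    for (q in 10^c(1.5, 3)) {
      g1 <- growth(ks, q); g2 <- growth(10 * ks, 10 * q)
      if (g1 < 0.3) expect_lt(abs(g2 - g1) / g1, 0.05)
    }
  }
  # log-log slope 1 along each axis in the sub-saturated, consumption-light regime
  q_axis <- 10^seq(1, 2.5, length.out = 6)
  g_q <- vapply(q_axis, function(q) growth(1e-6, q), numeric(1))
  slope_q <- coef(lm(log(g_q) ~ log(q_axis)))[2]
  expect_lt(abs(slope_q - 1), 0.1)
  ks_axis <- 10^seq(-7, -5.5, length.out = 6)
  g_k <- vapply(ks_axis, function(ks) growth(ks, 30), numeric(1))
  slope_k <- coef(lm(log(g_k) ~ log(ks_axis)))[2]
  expect_lt(abs(slope_k + 1), 0.1)
})

test_that("phase diagrams are monotone in K_S and bounded in [0, 1]", {
  p <- particle_params()
  for (mode in c("secretion", "lysis")) {
    pd <- compute_phase_diagram(p, mode = mode,
                                ks_grid = 10^seq(-11, -5, length.out = 12),
                                quota_grid = 10^seq(1, 6, length.out = 10))
    expect_true(all(pd$grid$normalized_growth >= 0 &
                      pd$grid$normalized_growth <= 1))
    by_quota <- split(pd$grid[order(pd$grid$ks_molar), ],
                      pd$grid$quota[order(pd$grid$ks_molar)])
    for (chunk in by_quota) {
      expect_true(all(diff(chunk$normalized_growth) <= 1e-9))
    }
  }
})

test_that("measured biotin traits favor secretion and disfavor lysis", {
  # the two biotin auxotrophs: high affinity, tiny quota
  b7 <- list(auxotroph_traits(1.3e-10, 20), auxotroph_traits(3.1e-10, 20))
  p_sec <- particle_params(lysis_rate = 0)
  p_lys <- particle_params(secretion_rate = 0)
  for (tr in b7) {
    expect_gt(steady_state(p_sec, tr, "secretion")$normalized_rate, 0.9)
    expect_lt(steady_state(p_lys, tr, "lysis")$normalized_rate, 0.1)
  }
  # the low-affinity niacin auxotroph grows slowly in both channels
  b3 <- auxotroph_traits(4.6e-6, 1.4e5)
  expect_lt(steady_state(p_sec, b3, "secretion")$normalized_rate, 0.1)
  expect_lt(steady_state(p_lys, b3, "lysis")$normalized_rate, 0.1)
})

test_that("domain errors are raised for invalid model inputs", {
  p <- particle_params()
  tr <- auxotroph_traits(1e-9, 20)
  expect_error(secretion_thresholds(p, 1.2), class = "vitacross_domain_error")
  expect_error(solve_surface_concentration(p, tr, -1),
               class = "vitacross_bad_input")
  expect_error(auxotroph_traits(-1, 20), class = "vitacross_bad_input")
  expect_error(particle_params(radius_um = 0), class = "vitacross_bad_input")
})
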