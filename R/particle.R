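#' Parameters of the particle cross-feeding model
#'
#' Bundles the geometry, transport, and population parameters of the
#' steady-state model of vitamin cross-feeding on a spherical particle:
#' degraders colonize the particle, grow logistically toward a carrying
#' capacity, and release vitamins either by secretion from living cells or
#' by lysis (which frees the full cellular quota); vitamins diffuse away
#' into an infinite (or large finite) medium while surface-attached
#' auxotrophs take them up with Monod kinetics. All inputs are in bench
#' units (hours, micrometres, molar); conversion to SI
#' (seconds/metres/molecules) happens inside the operations.
#'
#' @param radius_um Particle radius in micrometres (default 50).
#' @param diffusivity Vitamin diffusivity in m^2/s (default 5e-10, a small
#'   molecule in seawater).
#' @param far_field_molar Background vitamin concentration far from the
#'   particle, molar (default 0).
#' @param degrader_max_rate Maximal degrader growth rate, h^-1
#'   (default 0.5).
#' @param degrader_capacity Degrader carrying capacity, cells per particle
#'   (default 1e5).
#' @param secretion_rate Per-cell vitamin secretion rate,
#'   molecules cell^-1 s^-1 (default 56.8).
#' @param lysis_rate Lysis rate, h^-1 (default half the maximal degrader
#'   rate, the release-optimal value).
#' @param death_rate Non-recycled mortality, h^-1 (default 0).
#' @param secretion_cost Linear growth-rate cost per unit secretion rate
#'   (dimensionless per molecules cell^-1 s^-1; default 0).
#' @param n_auxotrophs Auxotroph cells at the particle surface
#'   (default 1e5).
#' @param auxotroph_max_rate Maximal auxotroph growth rate, h^-1
#'   (default 0.5).
#' @param substrate_half_sat,substrate_conc Optional carbon co-limitation
#'   limb: half-saturation and surface concentration of the growth
#'   substrate (molar). When unset the substrate factor is 1
#'   (vitamin-limited growth).
#' @param producer_quota Vitamin content of a producer cell released on
#'   lysis, molecules/cell; `NULL` (default) means equal to the auxotroph
#'   quota.
#' @returns A list of class `particle_params`.
#' @export
particle_params <- function(radius_um = 50,
                            diffusivity = 5e-10,
                            far_field_molar = 0,
                            degrader_max_rate = 0.5,
                            degrader_capacity = 1e5,
                            secretion_rate = 56.8,
                            lysis_rate = degrader_max_rate / 2,
                            death_rate = 0,
                            secretion_cost = 0,
                            n_auxotrophs = 1e5,
                            auxotroph_max_rate = 0.5,
                            substrate_half_sat = NULL,
                            substrate_conc = NULL,
                            producer_quota = NULL) {
  p <- list(
    radius_um = radius_um, diffusivity = diffusivity,
    far_field_molar = far_field_molar,
    degrader_max_rate = degrader_max_rate,
    degrader_capacity = degrader_capacity,
    secretion_rate = secretion_rate, lysis_rate = lysis_rate,
    death_rate = death_rate, secretion_cost = secretion_cost,
    n_auxotrophs = n_auxotrophs, auxotroph_max_rate = auxotroph_max_rate,
    substrate_half_sat = substrate_half_sat, substrate_conc = substrate_conc,
    producer_quota = producer_quota
  )
  with(p, {
    if (radius_um <= 0 || diffusivity <= 0 || degrader_capacity <= 0 ||
        degrader_max_rate <= 0 || auxotroph_max_rate <= 0) {
      abort("radius, diffusivity, capacity and maximal rates must be positive.",
            class = "vitacross_bad_input")
    }
    if (secretion_rate < 0 || lysis_rate < 0 || death_rate < 0 ||
        secretion_cost < 0 || n_auxotrophs < 0 || far_field_molar < 0) {
      abort("rates, costs, counts and concentrations must be non-negative.",
            class = "vitacross_bad_input")
    }
  })
  structure(p, class = "particle_params")
}

#' Auxotroph uptake traits
#'
#' The two traits that place an auxotroph in the cross-feeding phase plane:
#' the Monod half-saturation constant for the vitamin (uptake affinity) and
#' the cellular quota, i.e. the inverse yield — vitamin molecules consumed
#' per cell produced, equal to the per-cell content released on lysis.
#'
#' @param half_saturation Half-saturation constant K_S, molar.
#' @param quota Vitamin quota (inverse yield), molecules/cell.
#' @returns A list of class `auxotroph_traits`.
#' @export
auxotroph_traits <- function(half_saturation = 1e-9, quota = 20) {
  if (half_saturation <= 0 || quota <= 0) {
    abort("half_saturation and quota must be positive.",
          class = "vitacross_bad_input")
  }
  structure(list(half_saturation = half_saturation, quota = quota),
            class = "auxotroph_traits")
}

# internal unit helpers -----------------------------------------------------
.per_h_to_per_s <- function(x) x / 3600
.molar_to_m3 <- function(x) x * 1000 * .N_A      # molecules per m^3
.m3_to_molar <- function(x) x / (1000 * .N_A)

# diffusive transfer coefficient (m^3/s): 4*pi*D*R for an infinite medium,
# 4*pi*D / (1/R - 1/R_out) for a finite shell
geometry_factor <- function(params, outer_radius_um = Inf) {
  R <- params$radius_um * 1e-6
  if (is.infinite(outer_radius_um)) {
    4 * pi * params$diffusivity * R
  } else {
    R_out <- outer_radius_um * 1e-6
    4 * pi * params$diffusivity / (1 / R - 1 / R_out)
  }
}

substrate_factor <- function(params) {
  if (is.null(params$substrate_half_sat) || is.null(params$substrate_conc)) {
    1
  } else {
    params$substrate_conc / (params$substrate_half_sat + params$substrate_conc)
  }
}

#' Steady-state degrader population
#'
#' Logistic growth with mortality: the degraders settle at
#' `N* = K * (1 - (mu + m) / r_eff)` with the effective growth rate
#' `r_eff = r_deg * (1 - c * s)` discounted by the linear secretion cost.
#' The population collapses to 0 when total mortality (lysis plus
#' non-recycled death) reaches the effective growth rate — the regime in
#' which over-lysing destroys the vitamin source.
#'
#' @param params A [particle_params()] object.
#' @returns Steady-state degrader population (cells), clamped at 0.
#' @export
degrader_steady_state <- function(params) {
  r_eff <- params$degrader_max_rate *
    (1 - params$secretion_cost * params$secretion_rate)
  if (r_eff <= 0) return(0)
  mortality <- params$lysis_rate + params$death_rate
  max(0, params$degrader_capacity * (1 - mortality / r_eff))
}

#' Vitamin release rate of the degrader population
#'
#' Secretion releases `s` molecules per living cell per second; lysis
#' releases the full producer quota of each lysed cell,
#' `mu * N_deg * q_deg`. The two channels add when both are active.
#'
#' @param params A [particle_params()] object.
#' @param n_deg Degrader population (cells), typically
#'   [degrader_steady_state()].
#' @param traits An [auxotroph_traits()] object (supplies the default
#'   producer quota).
#' @param mode `"secretion"`, `"lysis"`, or `"both"`.
#' @returns Release rate Q in molecules/second.
#' @export
vitamin_source <- function(params, n_deg, traits, mode = c("secretion", "lysis", "both")) {
  mode <- match.arg(mode)
  if (n_deg < 0) abort("n_deg must be >= 0.", class = "vitacross_bad_input")
  q_deg <- params$producer_quota %||% traits$quota
  q_sec <- params$secretion_rate * n_deg
  q_lys <- .per_h_to_per_s(params$lysis_rate) * n_deg * q_deg
  switch(mode,
         secretion = q_sec,
         lysis = q_lys,
         both = q_sec + q_lys)
}

#' Steady-state vitamin concentration at the particle surface
#'
#' Solves the surface mass balance
#' `g * (C_s - C_inf) + N_auxo * r_max * C_s/(K_S + C_s) * q = Q`,
#' where the first term is the diffusive loss through the transfer
#' coefficient `g = 4 pi D R` (or its finite-shell analogue) and the second
#' is Monod uptake by the surface auxotrophs. The left-hand side is
#' strictly increasing in `C_s`, so the root is unique; it is found by
#' bisection on `[0, C_inf + Q/g]` to relative tolerance 1e-10.
#'
#' @param params A [particle_params()] object.
#' @param traits An [auxotroph_traits()] object.
#' @param Q Vitamin release rate, molecules/second.
#' @param outer_radius_um Outer radius of the diffusion domain in
#'   micrometres; `Inf` (default) for an unbounded medium, finite to match
#'   a finite simulation shell.
#' @returns Surface concentration, molar.
#' @export
solve_surface_concentration <- function(params, traits, Q,
                                        outer_radius_um = Inf) {
  if (Q < 0) abort("Q must be >= 0.", class = "vitacross_bad_input")
  g <- geometry_factor(params, outer_radius_um)
  c_inf <- .molar_to_m3(params$far_field_molar)
  if (Q == 0 && c_inf == 0) return(0)
  ks <- .molar_to_m3(traits$half_saturation)
  uptake_coef <- params$n_auxotrophs *
    .per_h_to_per_s(params$auxotroph_max_rate) * substrate_factor(params) *
    traits$quota
  balance <- function(cs) g * (cs - c_inf) + uptake_coef * cs / (ks + cs) - Q

  lo <- 0
  hi <- c_inf + Q / g
  if (balance(hi) < 0) hi <- hi * (1 + 1e-12)  # guard against roundoff
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (balance(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) <= 1e-10 * max(hi, .Machine$double.xmin)) break
  }
  .m3_to_molar((lo + hi) / 2)
}

#' Auxotroph growth rate at a given surface concentration
#'
#' Monod growth on the vitamin, optionally co-limited by the carbon
#' substrate: `r = r_max * C_s/(K_S + C_s) * sigma`, with `sigma` the
#' substrate Monod factor (1 when the substrate limb is unset).
#'
#' @inheritParams solve_surface_concentration
#' @param surface_molar Vitamin concentration at the surface, molar.
#' @returns Growth rate in h^-1.
#' @export
auxotroph_growth <- function(params, traits, surface_molar) {
  if (any(surface_molar < 0)) {
    abort("surface_molar must be >= 0.", class = "vitacross_bad_input")
  }
  params$auxotroph_max_rate *
    surface_molar / (traits$half_saturation + surface_molar) *
    substrate_factor(params)
}

#' Full steady state of the cross-feeding chain
#'
#' Composes the chain degrader steady state -> vitamin release -> surface
#' concentration -> auxotroph growth, and reports the mass-balance pieces
#' (source, diffusive loss, consumption; the first equals the sum of the
#' other two at the solved root).
#'
#' @inheritParams vitamin_source
#' @inheritParams solve_surface_concentration
#' @returns A one-row tibble: `degrader_pop`, `source`
#'   (molecules/s), `surface_molar`, `diffusive_loss`, `consumption`
#'   (molecules/s), `auxotroph_rate` (h^-1), `normalized_rate`.
#' @export
steady_state <- function(params, traits, mode = c("secretion", "lysis", "both"),
                         outer_radius_um = Inf) {
  mode <- match.arg(mode)
  n_deg <- degrader_steady_state(params)
  Q <- vitamin_source(params, n_deg, traits, mode)
  cs <- solve_surface_concentration(params, traits, Q, outer_radius_um)
  g <- geometry_factor(params, outer_radius_um)
  sigma <- substrate_factor(params)
  rate <- auxotroph_growth(params, traits, cs)
  cs_m3 <- .molar_to_m3(cs)
  loss <- g * (cs_m3 - .molar_to_m3(params$far_field_molar))
  cons <- params$n_auxotrophs * .per_h_to_per_s(params$auxotroph_max_rate) *
    sigma * cs_m3 / (.molar_to_m3(traits$half_saturation) + cs_m3) * traits$quota
  tibble::tibble(
    degrader_pop = n_deg, source = Q, surface_molar = cs,
    diffusive_loss = loss, consumption = cons,
    auxotroph_rate = rate,
    normalized_rate = rate / (params$auxotroph_max_rate * sigma)
  )
}

#' Radial reaction-diffusion simulation around the particle
#'
#' Independent check on the algebraic steady state: integrates the
#' spherically symmetric diffusion equation
#' `dC/dt = D (1/r^2) d/dr (r^2 dC/dr)` on a logarithmically spaced
#' finite-volume mesh between the particle surface and an outer shell held
#' at the far-field concentration, with the net source (release minus
#' Monod uptake at the surface concentration) injected through the inner
#' face. The reported steady surface value extrapolates from the first
#' cell centre to the particle surface using the local steady flux profile
#' `C(r) = C(r_1) + (Q_net / 4 pi D) (1/r - 1/r_1)`.
#'
#' @inheritParams solve_surface_concentration
#' @param t_end Integration horizon in seconds; default five outer-shell
#'   diffusion times. Integration continues in further chunks of `t_end`
#'   (up to four) while the surface concentration is still moving.
#' @param n_shells Number of radial cells (default 400).
#' @param outer_factor Outer radius as a multiple of the particle radius
#'   (default 100).
#' @returns A list of class `radial_pde`: `trajectory` (tibble with
#'   `time_s`, `surface_molar`), `surface_molar` (final), `converged`
#'   (logical: relative surface derivative below 1e-6 per diffusion time),
#'   `residual` (that relative derivative), `outer_radius_um`.
#' @export
simulate_radial_pde <- function(params, traits, Q, t_end = NULL,
                                n_shells = 400, outer_factor = 100) {
  R <- params$radius_um * 1e-6
  R_out <- outer_factor * R
  D <- params$diffusivity
  faces <- R * (R_out / R)^(seq(0, 1, length.out = n_shells + 1))
  centers <- (faces[-1] + faces[-(n_shells + 1)]) / 2
  areas <- 4 * pi * faces^2
  vols <- 4 * pi / 3 * diff(faces^3)
  c_inf <- .molar_to_m3(params$far_field_molar)
  ks <- .molar_to_m3(traits$half_saturation)
  uptake_coef <- params$n_auxotrophs *
    .per_h_to_per_s(params$auxotroph_max_rate) * substrate_factor(params) *
    traits$quota
  diff_time <- R_out^2 / D
  if (is.null(t_end)) t_end <- 5 * diff_time

  dcenter <- diff(centers)
  d_outer <- faces[n_shells + 1] - centers[n_shells]

  deriv <- function(t, C, parms) {
    # interior face fluxes, positive outward (molecules/s)
    flux <- -D * diff(C) / dcenter * areas[2:n_shells]
    influx <- c(Q - uptake_coef * C[1] / (ks + C[1]), flux)
    outflux <- c(flux, -D * (c_inf - C[n_shells]) / d_outer * areas[n_shells + 1])
    list((influx - outflux) / vols)
  }

  c_scale <- max(c_inf, Q / geometry_factor(params, outer_factor * params$radius_um),
                 .Machine$double.xmin)
  to_surface <- function(C) {
    qn <- Q - uptake_coef * C[1] / (ks + C[1])
    C[1] + qn / (4 * pi * D) * (1 / R - 1 / centers[1])
  }
  surface_residual <- function(C) {
    dC <- deriv(0, C, NULL)[[1]][1]
    abs(dC) * diff_time / max(to_surface(C), c_scale)
  }
  # integrate in chunks of t_end, continuing while the surface is still moving
  y <- rep(c_inf, n_shells)
  sol_rows <- list()
  t_offset <- 0
  for (chunk in 1:4) {
    times <- unique(c(0, t_end * seq(0.05, 1, by = 0.05)))
    sol <- deSolve::lsoda(
      y = y, times = times, func = deriv, parms = NULL,
      jactype = "bandint", bandup = 1, banddown = 1,
      rtol = 1e-8, atol = c_scale * 1e-10
    )
    rows <- sol[if (chunk == 1) TRUE else -1, , drop = FALSE]
    rows[, 1] <- rows[, 1] + t_offset
    sol_rows[[chunk]] <- rows
    t_offset <- t_offset + t_end
    y <- as.numeric(sol[nrow(sol), -1])
    if (surface_residual(y) < 1e-6) break
  }
  sol <- do.call(rbind, sol_rows)
  C_final <- y
  surface <- to_surface(C_final)
  traj_surface <- vapply(seq_len(nrow(sol)), function(i) {
    to_surface(as.numeric(sol[i, -1]))
  }, numeric(1))
  residual <- surface_residual(C_final)
  converged <- residual < 1e-6
  if (!converged) {
    warn(sprintf("Radial simulation not converged: relative surface derivative %.3g.",
                 residual))
  }
  structure(
    list(
      trajectory = tibble::tibble(time_s = sol[, 1],
                                  surface_molar = .m3_to_molar(traj_surface)),
      surface_molar = .m3_to_molar(surface),
      converged = converged,
      residual = residual,
      outer_radius_um = outer_factor * params$radius_um
    ),
    class = "radial_pde"
  )
}

#' Sweep the vitamin release rate and locate the optimum for auxotrophs
#'
#' Evaluates the full steady-state chain across a grid of release rates —
#' lysis rates (h^-1) in lysis mode, secretion rates
#' (molecules cell^-1 s^-1) in secretion mode — and returns the growth
#' profile and the rate that maximizes auxotroph growth. In the
#' sub-saturated vitamin regime with no extra mortality, the lysis release
#' `Q(mu) = mu * K * (1 - mu/r_deg) * q` is maximized at `mu = r_deg / 2`:
#' the auxotrophs do best when the degraders give up half their maximal
#' growth rate. Costless secretion has no interior optimum (the profile is
#' non-decreasing); a cost plus non-recycled mortality creates one.
#'
#' @inheritParams steady_state
#' @param rates Numeric vector of release rates to evaluate. Defaults: 200
#'   evenly spaced lysis rates on `[0, r_deg]`, or 200 secretion rates on
#'   `[0, 2 * s_default]` (truncated to viability when secretion is
#'   costly).
#' @param mode `"lysis"` or `"secretion"`; the other release channel is
#'   switched off during the sweep.
#' @returns A list of class `release_sweep`: `profile` (tibble with
#'   `rate`, `auxotroph_rate`, `normalized_rate`, `degrader_pop`),
#'   `optimum_rate`, `optimum_normalized`, `mode`, and `rate_step`.
#' @export
sweep_release_rate <- function(params, traits, mode = c("lysis", "secretion"),
                               rates = NULL) {
  mode <- match.arg(mode)
  if (is.null(rates)) {
    rates <- if (mode == "lysis") {
      seq(0, params$degrader_max_rate, length.out = 200)
    } else {
      upper <- 2 * params$secretion_rate
      if (params$secretion_cost > 0) {
        upper <- min(upper, 0.999 / params$secretion_cost)
      }
      seq(0, upper, length.out = 200)
    }
  }
  if (length(rates) == 0 || all(!is.finite(rates))) {
    abort("Empty release-rate grid.", class = "vitacross_bad_input")
  }
  profile <- purrr::map_dfr(rates, function(rate) {
    p <- params
    if (mode == "lysis") {
      p$lysis_rate <- rate
      p$secretion_rate <- 0
    } else {
      p$secretion_rate <- rate
      p$lysis_rate <- 0
    }
    ss <- steady_state(p, traits, mode = mode)
    tibble::tibble(rate = rate,
                   auxotroph_rate = ss$auxotroph_rate,
                   normalized_rate = ss$normalized_rate,
                   degrader_pop = ss$degrader_pop)
  })
  i_opt <- which.max(profile$auxotroph_rate)
  structure(
    list(profile = profile,
         optimum_rate = profile$rate[i_opt],
         optimum_normalized = profile$normalized_rate[i_opt],
         mode = mode,
         rate_step = if (length(rates) > 1) diff(sort(rates))[1] else NA_real_),
    class = "release_sweep"
  )
}

#' @export
print.release_sweep <- function(x, ...) {
  cat(sprintf("Release-rate sweep (%s mode), %d rates\n",
              x$mode, nrow(x$profile)))
  cat(sprintf("  optimum at rate %.4g (normalized auxotroph growth %.3g)\n",
              x$optimum_rate, x$optimum_normalized))
  invisible(x)
}

#' Normalized auxotroph growth over the (K_S, quota) trait plane
#'
#' Evaluates the steady-state normalized auxotroph growth rate on a
#' log-spaced grid of half-saturation constants and quotas, under a single
#' release mode. Secretion diagrams show an "L" of two thresholds — a
#' maximal half-saturation (affinity must beat the concentration diffusion
#' allows) and a maximal quota (consumption cannot outrun supply); lysis
#' diagrams show diagonal iso-growth contours because release and
#' consumption both scale with the quota.
#'
#' @inheritParams steady_state
#' @param ks_grid Half-saturation grid, molar (default 40 log-spaced values
#'   over 1e-11 to 1e-5).
#' @param quota_grid Quota grid, molecules/cell (default 40 log-spaced
#'   values over 1e1 to 1e6).
#' @param levels Contour levels retained for plotting (default 0.9, 0.5,
#'   0.1).
#' @returns A list of class `phase_diagram`: `grid` (tibble with
#'   `ks_molar`, `quota`, `normalized_growth`), `mode`, `levels`, `params`.
#' @export
compute_phase_diagram <- function(params, mode = c("secretion", "lysis"),
                                  ks_grid = 10^seq(-11, -5, length.out = 40),
                                  quota_grid = 10^seq(1, 6, length.out = 40),
                                  levels = c(0.9, 0.5, 0.1)) {
  mode <- match.arg(mode)
  p <- params
  if (mode == "secretion") p$lysis_rate <- 0 else p$secretion_rate <- 0
  grid <- tidyr::expand_grid(ks_molar = ks_grid, quota = quota_grid)
  grid$normalized_growth <- purrr::map2_dbl(
    grid$ks_molar, grid$quota,
    function(ks, q) {
      steady_state(p, auxotroph_traits(ks, q), mode = mode)$normalized_rate
    }
  )
  structure(list(grid = grid, mode = mode, levels = levels, params = p),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("Trait-space phase diagram (%s mode): %d x %d grid\n",
              x$mode, dplyr::n_distinct(x$grid$ks_molar),
              dplyr::n_distinct(x$grid$quota)))
  cat(sprintf("  normalized growth range: %.3g to %.3g\n",
              min(x$grid$normalized_growth), max(x$grid$normalized_growth)))
  invisible(x)
}

#' Analytic secretion thresholds for a target growth level
#'
#' Closed-form bounds on the two arms of the secretion "L": growth at least
#' `theta` (as a fraction of maximum) requires
#' `K_S <= C_s0 * (1 - theta) / theta`, where
#' `C_s0 = s N* / (4 pi D R) + C_inf` is the consumption-free surface
#' concentration (affinity bound), and
#' `quota <= s N* / (N_auxo * theta * r_max)` (supply-balance bound: at the
#' threshold the auxotrophs' consumption equals the population's secretion).
#'
#' @param params A [particle_params()] object (lysis channel ignored).
#' @param target_growth Normalized growth level(s) theta in (0, 1).
#' @returns A tibble with columns `theta`, `ks_max_molar`, `quota_max`.
#' @export
secretion_thresholds <- function(params, target_growth) {
  if (any(target_growth <= 0 | target_growth >= 1)) {
    abort("target_growth must lie strictly inside (0, 1).",
          class = "vitacross_domain_error")
  }
  p <- params
  p$lysis_rate <- 0
  n_deg <- degrader_steady_state(p)
  g <- geometry_factor(p)
  cs0 <- .m3_to_molar(p$secretion_rate * n_deg / g) + p$far_field_molar
  r_si <- .per_h_to_per_s(p$auxotroph_max_rate) * substrate_factor(p)
  tibble::tibble(
    theta = target_growth,
    ks_max_molar = cs0 * (1 - target_growth) / target_growth,
    quota_max = p$secretion_rate * n_deg /
      (p$n_auxotrophs * target_growth * r_si)
  )
}
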