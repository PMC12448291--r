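#' Exponential-phase growth rate from an OD time series
#'
#' Log-transforms the optical densities and searches all contiguous windows
#' of at least `min_window` points for the steepest log-linear stretch whose
#' coefficient of determination passes `r2_threshold`; the slope of that
#' window is the growth rate (natural-log basis, h^-1; divide by `log(2)`
#' for doublings per hour). The exponential region is anchored by the
#' longest window that passes the r-squared threshold: the maximal slope is
#' taken over qualifying windows at least `min_length_frac` of that length.
#' Without the length guard the raw maximum is dominated by short, lucky
#' windows on noisy traces (a winner's-curse bias that inflates rates by
#' several standard errors); with it, clean data still reduce to the plain
#' maximal slope. Ties are broken by the earliest, then the longest,
#' window, so the estimate is deterministic. Curves with no qualifying window, or with a best slope
#' below `rate_floor`, are reported as no-growth with rate 0 — flat traces
#' otherwise yield spurious slopes from noise in the log domain.
#'
#' @param curve Data frame with (at least) the time and OD columns.
#' @param time,od Column names holding time (hours) and OD (600 nm);
#'   defaults `time_h` and `od`.
#' @param min_window Minimum points per window (default 4).
#' @param r2_threshold Minimum r-squared for a window to qualify
#'   (default 0.98).
#' @param od_detection OD below which points are excluded from the log fit
#'   (default 0.005).
#' @param rate_floor Slopes below this (h^-1) are clamped to 0 and flagged
#'   (default 0.02).
#' @param min_length_frac Qualifying windows shorter than this fraction of
#'   the longest qualifying window are not considered (default 0.6; 0
#'   recovers raw maximal slope over all windows).
#' @returns A one-row tibble: `rate` (h^-1), `intercept` (log-OD),
#'   `window_start`, `window_end` (indices into the filtered series),
#'   `n_points`, `r_squared`, `flag` (`"ok"` or `"no_growth"`).
#' @export
estimate_growth_rate <- function(curve, time = "time_h", od = "od",
                                 min_window = 4, r2_threshold = 0.98,
                                 od_detection = 0.005, rate_floor = 0.02,
                                 min_length_frac = 0.6) {
  curve <- tibble::as_tibble(curve)
  t_all <- curve[[time]]
  od_all <- curve[[od]]
  if (is.null(t_all) || is.null(od_all)) {
    abort("`curve` must contain the time and od columns.",
          class = "vitacross_bad_input")
  }
  if (is.unsorted(t_all, strictly = TRUE)) {
    abort("Times must be strictly increasing.", class = "vitacross_bad_input")
  }
  no_growth <- tibble::tibble(
    rate = 0, intercept = NA_real_, window_start = NA_integer_,
    window_end = NA_integer_, n_points = NA_integer_,
    r_squared = NA_real_, flag = "no_growth"
  )
  keep <- which(is.finite(od_all) & od_all >= od_detection)
  if (length(keep) < min_window) return(no_growth)
  x <- t_all[keep]
  y <- log(od_all[keep])

  best <- best_loglinear_window(x, y, min_window, r2_threshold,
                                min_length_frac)
  if (is.null(best) || best$slope < rate_floor) return(no_growth)
  tibble::tibble(
    rate = best$slope, intercept = best$intercept,
    window_start = keep[best$start], window_end = keep[best$end],
    n_points = best$end - best$start + 1L,
    r_squared = best$r2, flag = "ok"
  )
}

# All-windows linear regression via cumulative sums. The longest window
# passing the r2 threshold anchors the exponential region; the steepest
# qualifying window of at least min_length_frac of that length wins
# (ties: earliest start, then longest).
best_loglinear_window <- function(x, y, min_window, r2_threshold,
                                  min_length_frac = 0.6) {
  n <- length(x)
  cx <- c(0, cumsum(x)); cy <- c(0, cumsum(y))
  cxx <- c(0, cumsum(x * x)); cyy <- c(0, cumsum(y * y))
  cxy <- c(0, cumsum(x * y))
  stats_for_length <- function(L) {
    i <- seq_len(n - L + 1L)
    j <- i + L - 1L
    sx <- cx[j + 1L] - cx[i]; sy <- cy[j + 1L] - cy[i]
    sxx <- cxx[j + 1L] - cxx[i]; syy <- cyy[j + 1L] - cyy[i]
    sxy <- cxy[j + 1L] - cxy[i]
    ssxx <- L * sxx - sx^2
    ssyy <- L * syy - sy^2
    ssxy <- L * sxy - sx * sy
    slope <- ssxy / ssxx
    r2 <- ifelse(ssyy > .Machine$double.eps * L * pmax(syy, 1),
                 ssxy^2 / (ssxx * ssyy), NA_real_)
    list(i = i, j = j, L = L, slope = slope,
         intercept = (sy - slope * sx) / L, r2 = r2,
         ok = is.finite(slope) & is.finite(r2) & r2 >= r2_threshold)
  }
  # anchor: the longest qualifying window
  L_max <- 0L
  for (L in seq(n, min_window)) {
    if (any(stats_for_length(L)$ok)) { L_max <- L; break }
  }
  if (L_max == 0L) return(NULL)
  L_min <- max(min_window, ceiling(min_length_frac * L_max))
  best <- NULL
  for (L in seq(L_max, L_min)) {
    s <- stats_for_length(L)
    for (k in which(s$ok)) {
      cand <- list(slope = s$slope[k], start = s$i[k], end = s$j[k],
                   intercept = s$intercept[k], r2 = s$r2[k])
      if (is.null(best) ||
          cand$slope > best$slope + 1e-12 ||
          (abs(cand$slope - best$slope) <= 1e-12 &&
           (cand$start < best$start ||
            (cand$start == best$start && cand$end > best$end)))) {
        best <- cand
      }
    }
  }
  best
}

#' Growth rates for a table of growth curves
#'
#' Applies [estimate_growth_rate()] to each curve in a long table, grouped
#' by every column other than the time and OD columns.
#'
#' @inheritParams estimate_growth_rate
#' @param curves Long data frame, e.g. with columns `isolate_id`,
#'   `vitamin_id`, `concentration_molar`, `replicate`, `time_h`, `od`.
#' @param ... Passed on to [estimate_growth_rate()].
#' @returns A tibble with one row per curve: the grouping columns plus the
#'   columns of [estimate_growth_rate()].
#' @export
estimate_growth_rates <- function(curves, time = "time_h", od = "od", ...) {
  curves <- tibble::as_tibble(curves)
  keys <- setdiff(names(curves), c(time, od))
  dots <- list(...)
  one_curve <- function(chunk, key) {
    do.call(estimate_growth_rate, c(list(chunk, time = time, od = od), dots))
  }
  curves |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(.data[[time]], .by_group = TRUE) |>
    dplyr::group_modify(one_curve) |>
    dplyr::ungroup()
}

#' Fit a Monod dose-response curve to growth rates
#'
#' Nonlinear least squares of the Monod model
#' `r(S) = r_max * S / (K_S + S)` to per-concentration growth rates,
#' giving the maximal growth rate and the half-saturation constant `K_S`
#' (the concentration at which growth runs at half its maximum). The
#' response is fit untransformed on the (typically log-spaced)
#' concentrations; a zero-concentration condition enters as `S = 0`.
#' Standard errors come from the parameter covariance of the
#' Levenberg-Marquardt fit.
#'
#' @param data Data frame of dose-response observations.
#' @param concentration,rate Column names for concentration (molar) and
#'   growth rate (h^-1); defaults `concentration_molar` and `rate`.
#' @returns An object of class `monod_fit` with elements `r_max`,
#'   `half_saturation`, `se_r_max`, `se_half_saturation`, the underlying
#'   `nls` fit, and the data; supports [tidy()], [glance()], `predict()`
#'   and [autoplot()].
#' @examples
#' conc <- c(0, 10^seq(-12, -6))
#' rates <- 1 * conc / (1e-9 + conc)
#' fit <- fit_monod(data.frame(concentration_molar = conc, rate = rates))
#' tidy(fit)
#' @export
fit_monod <- function(data, concentration = "concentration_molar", rate = "rate") {
  data <- tibble::as_tibble(data)
  S <- data[[concentration]]
  r <- data[[rate]]
  if (is.null(S) || is.null(r)) {
    abort("`data` must contain the concentration and rate columns.",
          class = "vitacross_bad_input")
  }
  if (any(r < 0)) abort("Rates must be non-negative.", class = "vitacross_bad_input")
  pos <- unique(S[S > 0])
  if (length(pos) < 4 || log10(max(pos) / min(pos)) < 2) {
    abort("Need >= 4 distinct positive concentrations spanning >= 2 decades.",
          class = "vitacross_bad_input")
  }
  if (diff(range(r)) < .Machine$double.eps^0.5) {
    abort("All rates are equal: K_S is unidentifiable (degenerate fit).",
          class = "vitacross_degenerate_fit")
  }
  r_max0 <- max(r)
  half <- r_max0 / 2
  K0 <- S[S > 0][which.min(abs(r[S > 0] - half))]
  df <- tibble::tibble(S = S, r = r)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      r ~ r_max * S / (K_S + S), data = df,
      start = list(r_max = r_max0, K_S = K0),
      lower = c(r_max = 0, K_S = .Machine$double.xmin),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      abort(paste0("Monod fit failed to converge: ", conditionMessage(e)),
            class = "vitacross_fit_failure")
    }
  )
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA_real_, NA_real_))
  structure(
    list(
      r_max = unname(est["r_max"]),
      half_saturation = unname(est["K_S"]),
      se_r_max = unname(se[1]),
      se_half_saturation = unname(se[2]),
      fit = fit,
      data = df
    ),
    class = "monod_fit"
  )
}

#' @export
predict.monod_fit <- function(object, newdata = NULL, ...) {
  S <- if (is.null(newdata)) object$data$S else {
    if (is.data.frame(newdata)) {
      newdata$S %||% newdata$concentration_molar
    } else newdata
  }
  object$r_max * S / (object$half_saturation + S)
}

#' @export
print.monod_fit <- function(x, ...) {
  cat("Monod dose-response fit\n")
  cat(sprintf("  r_max          : %.4g h^-1 (se %.3g)\n", x$r_max, x$se_r_max))
  cat(sprintf("  half-saturation: %.4g M (se %.3g)\n",
              x$half_saturation, x$se_half_saturation))
  invisible(x)
}

#' @export
tidy.monod_fit <- function(x, ...) {
  tibble::tibble(
    term = c("r_max", "half_saturation"),
    estimate = c(x$r_max, x$half_saturation),
    std.error = c(x$se_r_max, x$se_half_saturation)
  )
}

#' @export
glance.monod_fit <- function(x, ...) {
  res <- stats::residuals(x$fit)
  tibble::tibble(
    sigma = sqrt(sum(res^2) / stats::df.residual(x$fit)),
    df.residual = stats::df.residual(x$fit),
    nobs = nrow(x$data),
    converged = x$fit$convInfo$isConv %||% TRUE
  )
}

#' Calibrate a power-law yield curve
#'
#' Fits `yield = a * concentration^b` by least squares on the log-log scale
#' (`log(yield) = log(a) + b * log(concentration)`); the calibration range
#' is retained so later inversions can be flagged as extrapolations. Used
#' to turn auxotroph yield into an untargeted estimate of total usable
#' vitamer concentration in a supernatant or lysate.
#'
#' @param data Data frame of calibration points.
#' @param concentration,yield Column names for concentration (molar) and
#'   yield (OD); defaults `concentration_molar` and `yield`.
#' @returns An object of class `powerlaw_fit` with elements `a`, `b`,
#'   `valid_range` (molar), the `lm` fit, and the data.
#' @export
fit_powerlaw_yield <- function(data, concentration = "concentration_molar",
                               yield = "yield") {
  data <- tibble::as_tibble(data)
  C <- data[[concentration]]
  y <- data[[yield]]
  if (is.null(C) || is.null(y)) {
    abort("`data` must contain the concentration and yield columns.",
          class = "vitacross_bad_input")
  }
  if (length(C) < 3) {
    abort("Need >= 3 calibration points.", class = "vitacross_bad_input")
  }
  if (any(C <= 0) || any(y <= 0)) {
    abort("Concentrations and yields must be strictly positive.",
          class = "vitacross_domain_error")
  }
  fit <- lm(log(y) ~ log(C))
  a <- exp(unname(coef(fit)[1]))
  b <- unname(coef(fit)[2])
  structure(
    list(a = a, b = b, valid_range = range(C), fit = fit,
         data = tibble::tibble(C = C, yield = y)),
    class = "powerlaw_fit"
  )
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat("Power-law yield calibration: yield = a * C^b\n")
  cat(sprintf("  a = %.4g, b = %.4g\n", x$a, x$b))
  cat(sprintf("  valid range: [%.3g, %.3g] M\n",
              x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' @export
tidy.powerlaw_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("log_a", "b"),
    estimate = unname(s[, 1]),
    std.error = unname(s[, 2])
  )
}

#' @export
glance.powerlaw_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r.squared = s$r.squared,
    sigma = s$sigma,
    nobs = nrow(x$data)
  )
}

#' Estimate a vitamer concentration from an observed yield
#'
#' Inverts a power-law yield calibration at an observed yield and corrects
#' for sample dilution: the estimate is
#' `mixing_factor * (observed_yield / a)^(1/b)`. The default
#' `mixing_factor = 2` corrects for mixing a supernatant or lysate 1:1 with
#' fresh medium. Estimates whose pre-mixing concentration falls outside the
#' calibration range are returned flagged (with a warning) rather than
#' refused, since percent-of-maximum yields can exceed calibration.
#'
#' @param fit A [fit_powerlaw_yield()] object.
#' @param observed_yield Observed yield (OD), vectorized.
#' @param mixing_factor Dilution correction factor (default 2 for a 1:1 mix).
#' @returns A tibble with columns `observed_yield`, `estimate_molar`,
#'   `extrapolated`.
#' @export
estimate_vitamer_concentration <- function(fit, observed_yield, mixing_factor = 2) {
  if (!inherits(fit, "powerlaw_fit")) {
    abort("`fit` must be a powerlaw_fit object.", class = "vitacross_bad_input")
  }
  if (any(observed_yield <= 0)) {
    abort("Observed yields must be strictly positive.",
          class = "vitacross_domain_error")
  }
  c_raw <- (observed_yield / fit$a)^(1 / fit$b)
  extrapolated <- c_raw < fit$valid_range[1] | c_raw > fit$valid_range[2]
  if (any(extrapolated)) {
    warn(sprintf("%d estimate(s) fall outside the calibration range and are flagged.",
                 sum(extrapolated)))
  }
  tibble::tibble(
    observed_yield = observed_yield,
    estimate_molar = mixing_factor * c_raw,
    extrapolated = extrapolated
  )
}
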