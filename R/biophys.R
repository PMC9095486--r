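# Biophysical fits: two-state melting (Tm), first-order nuclease decay,
# and Michaelis-Menten kinetics. All fits are deterministic given the
# data: Levenberg-Marquardt least squares from data-driven starts, no
# random restarts.

# unit handling: concentrations are carried in nM, rates in nM min^-1;
# anything else is converted on input, never assumed.
CONC_FACTORS <- c(nM = 1, uM = 1e3, mM = 1e6)
RATE_FACTORS <- c(nM_min = 1, nM_s = 60)

convert_units <- function(x, unit, factors, what) {
  f <- factors[unit]
  if (anyNA(f)) {
    rlang::abort(sprintf(
      "Unknown %s unit(s): %s.", what,
      paste(unique(unit[is.na(f)]), collapse = ", ")
    ))
  }
  x * unname(f)
}

# Melting ---------------------------------------------------------------------

boltzmann_melt <- function(temp, aL, bL, aU, bU, tm, width) {
  lower <- aL + bL * temp
  upper <- aU + bU * temp
  lower + (upper - lower) / (1 + exp((tm - temp) / width))
}

#' Fit a two-state melting curve
#'
#' Fits a Boltzmann sigmoid with linear folded/unfolded baselines,
#' `A(T) = bl(T) + (bu(T) - bl(T)) / (1 + exp((Tm - T)/w))`, by
#' Levenberg-Marquardt least squares. Tm is the inflection point of the
#' transition. A model-free estimate (the maximum of the smoothed dA/dT)
#' is returned alongside so the choice of sigmoid can be audited.
#'
#' @param curve A data frame with columns `temperature` (degrees C,
#'   strictly increasing, >= 20 points) and `absorbance` (relative A260).
#' @return A `melt_fit` object with elements `tm`, `width`,
#'   `tm_derivative`, `baselines`, the `nls` fit and the data. Use
#'   [generics::tidy()] / [generics::glance()] / [ggplot2::autoplot()].
#' @export
fit_melting <- function(curve) {
  curve <- tibble::as_tibble(curve)
  stopifnot(all(c("temperature", "absorbance") %in% names(curve)))
  if (nrow(curve) < 20) {
    rlang::abort("A melting curve needs at least 20 points.")
  }
  if (any(diff(curve$temperature) <= 0)) {
    rlang::abort("Temperatures must be strictly increasing.")
  }
  amp <- diff(range(curve$absorbance))
  if (amp <= 0 || !any(diff(curve$absorbance) > 0)) {
    rlang::abort("No melting transition detected (no absorbance increase).")
  }
  # model-free estimate: maximum of the smoothed derivative
  sp <- stats::smooth.spline(curve$temperature, curve$absorbance)
  grid <- seq(min(curve$temperature), max(curve$temperature), length.out = 2001)
  dAdT <- stats::predict(sp, grid, deriv = 1)$y
  tm_deriv <- grid[which.max(dAdT)]

  n <- nrow(curve)
  k <- max(3, floor(n / 4))
  lo <- stats::lm(absorbance ~ temperature, data = curve[seq_len(k), ])
  hi <- stats::lm(absorbance ~ temperature, data = curve[(n - k + 1):n, ])
  start <- list(
    aL = stats::coef(lo)[[1]], bL = stats::coef(lo)[[2]],
    aU = stats::coef(hi)[[1]], bU = stats::coef(hi)[[2]],
    tm = tm_deriv, width = 2
  )
  fit <- minpack.lm::nlsLM(
    absorbance ~ boltzmann_melt(temperature, aL, bL, aU, bU, tm, width),
    data = curve, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- stats::coef(fit)
  structure(
    list(
      tm = unname(est["tm"]),
      width = unname(est["width"]),
      tm_derivative = tm_deriv,
      baselines = est[c("aL", "bL", "aU", "bU")],
      fit = fit,
      data = curve
    ),
    class = "melt_fit"
  )
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf(
    "<melt_fit> Tm = %.2f C (derivative estimate %.2f C), width %.2f C\n",
    x$tm, x$tm_derivative, x$width
  ))
  invisible(x)
}

#' @export
tidy.melt_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @export
glance.melt_fit <- function(x, ...) {
  tibble::tibble(
    tm = x$tm,
    width = x$width,
    tm_derivative = x$tm_derivative,
    sigma = summary(x$fit)$sigma,
    converged = x$fit$convInfo$isConv,
    nobs = nrow(x$data)
  )
}

#' @export
autoplot.melt_fit <- function(object, ...) {
  grid <- tibble::tibble(temperature = seq(
    min(object$data$temperature), max(object$data$temperature),
    length.out = 400
  ))
  grid$absorbance <- stats::predict(object$fit, newdata = grid)
  ggplot2::ggplot(
    object$data, ggplot2::aes(.data$temperature, .data$absorbance)
  ) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::geom_vline(xintercept = object$tm, linetype = 2) +
    ggplot2::labs(
      x = "Temperature (°C)", y = "Relative absorbance (A260)",
      title = sprintf("Tm = %.1f °C", object$tm)
    )
}

#' Melting-temperature difference between two curves
#'
#' @param a,b `melt_fit` objects (or data frames, which are fitted first).
#' @return `Tm(a) - Tm(b)` in degrees C.
#' @export
delta_tm <- function(a, b) {
  if (!inherits(a, "melt_fit")) a <- fit_melting(a)
  if (!inherits(b, "melt_fit")) b <- fit_melting(b)
  a$tm - b$tm
}

# Michaelis-Menten ------------------------------------------------------------

#' Fit Michaelis-Menten kinetics
#'
#' Unweighted nonlinear least squares of `Vi = Vmax * S / (Km + S)`,
#' initialized at `Vmax0 = max(Vi)` and `Km0` = the substrate
#' concentration nearest half-maximal velocity. Concentrations are
#' converted to nM and velocities to nM min^-1 before fitting.
#'
#' @param d A data frame with columns `conc` and `vi`, optionally
#'   `conc_unit` (`"nM"`, `"uM"`, `"mM"`), `vi_unit` (`"nM_min"`,
#'   `"nM_s"`) and `replicate`.
#' @return An `mm_fit` with `km` (nM), `vmax` (nM min^-1), standard
#'   errors, the `nls` fit and the converted data. A warning is issued
#'   when the fitted Km falls outside the concentration grid (the
#'   saturation curve is then unconstrained on one side).
#' @export
fit_mm <- function(d) {
  d <- tibble::as_tibble(d)
  stopifnot(all(c("conc", "vi") %in% names(d)))
  if (!"conc_unit" %in% names(d)) d$conc_unit <- "nM"
  if (!"vi_unit" %in% names(d)) d$vi_unit <- "nM_min"
  d$s_nM <- convert_units(d$conc, d$conc_unit, CONC_FACTORS, "concentration")
  d$v_nM_min <- convert_units(d$vi, d$vi_unit, RATE_FACTORS, "velocity")
  if (any(d$s_nM <= 0)) {
    rlang::abort("Substrate concentrations must be positive.")
  }
  if (length(unique(d$s_nM)) < 4) {
    rlang::abort("Michaelis-Menten fitting needs >= 4 distinct concentrations.")
  }
  vmax0 <- max(d$v_nM_min)
  km0 <- d$s_nM[which.min(abs(d$v_nM_min - vmax0 / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v_nM_min ~ vmax * s_nM / (km + s_nM),
      data = d, start = list(vmax = vmax0, km = km0),
      lower = c(vmax = 0, km = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12)
    ),
    error = function(e) {
      rlang::abort(sprintf(
        "Michaelis-Menten fit did not converge (start vmax=%.3g, km=%.3g): %s",
        vmax0, km0, conditionMessage(e)
      ))
    }
  )
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  if (est["km"] > max(d$s_nM) || est["km"] < min(d$s_nM)) {
    rlang::warn(sprintf(
      paste(
        "Fitted Km (%.3g nM) lies outside the concentration grid",
        "[%.3g, %.3g] nM; the estimate is effectively unbounded."
      ),
      est["km"], min(d$s_nM), max(d$s_nM)
    ))
  }
  structure(
    list(
      km = unname(est["km"]), vmax = unname(est["vmax"]),
      km_se = unname(se["km"]), vmax_se = unname(se["vmax"]),
      fit = fit, data = d
    ),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf(
    "<mm_fit> Km = %.3g nM, Vmax = %.3g nM min^-1\n", x$km, x$vmax
  ))
  invisible(x)
}

#' @export
tidy.mm_fit <- function(x, ...) {
  tibble::tibble(
    term = c("km", "vmax"),
    estimate = c(x$km, x$vmax),
    std.error = c(x$km_se, x$vmax_se),
    unit = c("nM", "nM_min")
  )
}

#' @export
glance.mm_fit <- function(x, ...) {
  tibble::tibble(
    km = x$km, vmax = x$vmax,
    sigma = summary(x$fit)$sigma,
    converged = x$fit$convInfo$isConv,
    nobs = nrow(x$data)
  )
}

#' @export
autoplot.mm_fit <- function(object, ...) {
  grid <- tibble::tibble(s_nM = seq(0, max(object$data$s_nM), length.out = 400))
  grid$v <- object$vmax * grid$s_nM / (object$km + grid$s_nM)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$s_nM, .data$v_nM_min)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(
      data = grid, ggplot2::aes(.data$s_nM, .data$v), colour = "red"
    ) +
    ggplot2::labs(
      x = "[S] (nM)", y = expression(V[i] ~ "(nM" ~ min^-1 * ")"),
      title = sprintf(
        "Km = %.3g nM, Vmax = %.3g nM min^-1", object$km, object$vmax
      )
    )
}

# Nuclease decay --------------------------------------------------------------

#' Fit first-order decay of intact RNA
#'
#' Least-squares fit of `I(t) = exp(-k t)` to an intact-fraction time
#' series (fraction normalized to 1 at t = 0), as read off a nuclease
#' protection assay. The decay rate is initialized from a log-linear
#' regression and constrained non-negative.
#'
#' @param d A data frame with columns `time` (min) and `fraction`.
#' @return A `decay_fit` with `rate` (min^-1) and `half_life` (min).
#' @export
fit_decay <- function(d) {
  d <- tibble::as_tibble(d)
  stopifnot(all(c("time", "fraction") %in% names(d)))
  if (nrow(d) < 3) {
    rlang::abort("Decay fitting needs at least 3 time points.")
  }
  if (any(d$fraction <= 0)) {
    rlang::abort("Intact fractions must be positive.")
  }
  k0 <- max(0, -stats::coef(stats::lm(log(fraction) ~ 0 + time, data = d))[[1]])
  fit <- minpack.lm::nlsLM(
    fraction ~ exp(-k * time),
    data = d, start = list(k = k0), lower = c(k = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12)
  )
  k <- unname(stats::coef(fit)["k"])
  structure(
    list(
      rate = k,
      half_life = if (k > 0) log(2) / k else Inf,
      rate_se = summary(fit)$coefficients["k", "Std. Error"],
      fit = fit, data = d
    ),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> k = %.4g min^-1, half-life = %.3g min\n",
    x$rate, x$half_life
  ))
  invisible(x)
}

#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(
    term = "k", estimate = x$rate, std.error = x$rate_se, unit = "min^-1"
  )
}

#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(
    rate = x$rate, half_life = x$half_life,
    sigma = summary(x$fit)$sigma, nobs = nrow(x$data)
  )
}

#' @export
autoplot.decay_fit <- function(object, ...) {
  grid <- tibble::tibble(time = seq(0, max(object$data$time), length.out = 400))
  grid$fraction <- exp(-object$rate * grid$time)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time, .data$fraction)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::labs(
      x = "Time (min)", y = "Intact fraction",
      title = sprintf("k = %.3g min^-1", object$rate)
    )
}

#' Ratio of two decay rates
#'
#' Compares nuclease susceptibility of two species, e.g. tRNA with and
#' without a stabilizing modification.
#'
#' @param a,b `decay_fit` objects (or data frames, fitted first).
#' @return `rate(a) / rate(b)`.
#' @export
decay_ratio <- function(a, b) {
  if (!inherits(a, "decay_fit")) a <- fit_decay(a)
  if (!inherits(b, "decay_fit")) b <- fit_decay(b)
  a$rate / b$rate
}
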