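# Two-state thermal denaturation with linear folded/unfolded baselines.
#
# signal(T) = b_f(T) * theta(T) + b_u(T) * (1 - theta(T))
# theta     = 1 / (1 + K),  K = exp(-dG / (R T))
# dG(T)     = dH (1 - T/Tm) + dCp (T - Tm - T log(T/Tm))
#
# theta is the folded fraction; K the unfolding equilibrium constant.  The
# disulfide tether makes folding unimolecular (the dimer behaves as a single
# chain thermodynamically), so no concentration term appears.

gibbs_helmholtz <- function(temperature, tm, dh, dcp = 0) {
  dg <- dh * (1 - temperature / tm)
  if (any(dcp != 0)) {
    dg <- dg + dcp * (temperature - tm - temperature * log(temperature / tm))
  }
  dg
}

two_state_signal <- function(temperature, tm, dh, dcp, bf0, bf1, bu0, bu1) {
  k <- exp(-gibbs_helmholtz(temperature, tm, dh, dcp) / (.R_KCAL * temperature))
  theta <- 1 / (1 + k)
  (bf0 + bf1 * temperature) * theta + (bu0 + bu1 * temperature) * (1 - theta)
}

as_kelvin <- function(temperature, unit = c("auto", "K", "C")) {
  unit <- match.arg(unit)
  if (unit == "C" || (unit == "auto" && max(temperature) < 200)) {
    celsius_to_kelvin(temperature)
  } else {
    temperature
  }
}

#' Fit a two-state melt curve
#'
#' Fits a variable-temperature unfolding curve (e.g. CD mean residue
#' ellipticity vs temperature) to the unimolecular two-state model with
#' linear folded and unfolded baselines, returning least-squares estimates of
#' the midpoint `Tm`, the van't Hoff enthalpy `dH` at `Tm`, optionally a heat
#' capacity increment `dCp`, and the four baseline coefficients, with their
#' covariance.  `dCp` defaults to fixed 0: over the narrow transitions
#' measured in concentrated denaturant the curvature it adds is not
#' resolvable, but it can be fitted via `fit_dcp = TRUE`.
#'
#' @param curve Data frame with columns `temperature` and `signal`
#'   (temperatures strictly increasing, at least 10 points spanning both
#'   baselines).  Celsius input is detected (values < 200) and converted;
#'   force the interpretation with `unit`.
#' @param fit_dcp Fit `dCp` as a free parameter instead of fixing it at 0.
#' @param unit `"auto"`, `"K"` or `"C"`.
#' @param start Optional named list overriding the automatic starting values
#'   (`tm`, `dh`, `bf0`, `bf1`, `bu0`, `bu1`, and `dcp` when fitted).
#' @return An object of class `two_state_fit`: see [tidy.two_state_fit()],
#'   [glance.two_state_fit()], [delta_G()], [delta_delta_G()].
#' @examples
#' curve <- gen_melt(tm = 335, dh = 40, noise_sd = 0.2, seed = 1)
#' fit <- fit_two_state(curve)
#' glance(fit)
#' @export
fit_two_state <- function(curve, fit_dcp = FALSE, unit = "auto", start = NULL) {
  stopifnot(all(c("temperature", "signal") %in% names(curve)))
  t_k <- as_kelvin(curve$temperature, unit)
  y <- curve$signal
  if (length(t_k) < 10) abort("need at least 10 points on the melt curve")
  if (any(diff(t_k) <= 0)) abort("temperatures must be strictly increasing")

  n <- length(t_k)
  edge <- max(3L, floor(n / 5))
  b_lo <- coef(lm(y[seq_len(edge)] ~ t_k[seq_len(edge)]))
  b_hi <- coef(lm(y[seq(n - edge + 1L, n)] ~ t_k[seq(n - edge + 1L, n)]))
  # midpoint guess: temperature where the baseline-corrected signal crosses 1/2
  frac <- (y - (b_lo[1] + b_lo[2] * t_k)) /
    ((b_hi[1] + b_hi[2] * t_k) - (b_lo[1] + b_lo[2] * t_k))
  tm0 <- t_k[which.min(abs(frac - 0.5))]
  init <- list(tm = tm0, dh = 40,
               bf0 = unname(b_lo[1]), bf1 = unname(b_lo[2]),
               bu0 = unname(b_hi[1]), bu1 = unname(b_hi[2]))
  if (fit_dcp) init$dcp <- 0
  init[names(start)] <- start

  dat <- data.frame(temperature = t_k, signal = y)
  form <- if (fit_dcp) {
    signal ~ two_state_signal(temperature, tm, dh, dcp, bf0, bf1, bu0, bu1)
  } else {
    signal ~ two_state_signal(temperature, tm, dh, 0, bf0, bf1, bu0, bu1)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = init,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) abort(paste0("two-state fit did not converge: ",
                                     conditionMessage(e)))
  )
  est <- coef(fit)
  cv <- tryCatch(vcov(fit), error = function(e) {
    matrix(NA_real_, length(est), length(est),
           dimnames = list(names(est), names(est)))
  })
  if (est[["tm"]] < min(t_k) || est[["tm"]] > max(t_k)) {
    warn("fitted Tm lies outside the data range; the melt is not bracketed")
  }
  structure(
    list(
      coef = est,
      vcov = cv,
      se = sqrt(pmax(diag(cv), 0)),
      dcp = if (fit_dcp) est[["dcp"]] else 0,
      dcp_fitted = fit_dcp,
      data = tibble(temperature = t_k, signal = y,
                    fitted = stats::fitted(fit)),
      sigma = stats::sigma(fit),
      variant_id = attr(curve, "variant_id") %||% curve[["variant_id"]][1],
      nls = fit
    ),
    class = "two_state_fit"
  )
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat("Two-state melt fit",
      if (!is.null(x$variant_id) && !is.na(x$variant_id))
        paste0(" [", x$variant_id, "]"), "\n", sep = "")
  cat(sprintf("  Tm  = %.2f K (%.2f degC) +/- %.3f\n",
              x$coef[["tm"]], kelvin_to_celsius(x$coef[["tm"]]),
              x$se[["tm"]]))
  cat(sprintf("  dH  = %.2f kcal/mol +/- %.3f (van't Hoff, at Tm)\n",
              x$coef[["dh"]], x$se[["dh"]]))
  cat(sprintf("  dCp = %.3f kcal/mol/K%s\n", x$dcp,
              if (x$dcp_fitted) " (fitted)" else " (fixed)"))
  invisible(x)
}

#' @rdname fit_two_state
#' @param x,object A `two_state_fit`.
#' @param ... Unused.
#' @export
tidy.two_state_fit <- function(x, ...) {
  tibble(term = names(x$coef),
         estimate = unname(x$coef),
         std.error = unname(x$se[names(x$coef)]))
}

#' @rdname fit_two_state
#' @export
glance.two_state_fit <- function(x, ...) {
  tibble(tm = x$coef[["tm"]],
         tm_c = kelvin_to_celsius(x$coef[["tm"]]),
         dh_vh = x$coef[["dh"]],
         dcp = x$dcp,
         sigma = x$sigma,
         n = nrow(x$data))
}

#' @rdname fit_two_state
#' @export
autoplot.two_state_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$temperature)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$signal), alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#d55e00") +
    ggplot2::geom_vline(xintercept = object$coef[["tm"]], linetype = 2) +
    ggplot2::labs(x = "temperature (K)", y = "signal",
                  title = "Two-state melt fit")
}

#' Folding free energy from a melt fit
#'
#' Evaluates the Gibbs--Helmholtz free energy of unfolding
#' `dG(T) = dH (1 - T/Tm) + dCp (T - Tm - T log(T/Tm))` for a fitted curve.
#' `dG(Tm) = 0` by definition; `dG > 0` below `Tm` (folded favored).
#'
#' @param fit A [fit_two_state()] result.
#' @param temperature Temperature(s) in K (Celsius < 200 converted, as
#'   elsewhere).
#' @return Free energy in kcal/mol (vectorized).
#' @export
delta_G <- function(fit, temperature) {
  stopifnot(inherits(fit, "two_state_fit"))
  t_k <- as_kelvin(temperature)
  if (any(t_k <= 0)) abort("temperature must be positive (K)")
  gibbs_helmholtz(t_k, fit$coef[["tm"]], fit$coef[["dh"]], fit$dcp)
}

#' Stabilization free energy of a staple
#'
#' The stability change caused by stapling, evaluated at the non-stapled
#' reference's midpoint:
#' `ddG = dG_ref(Tm_ref) - dG_stapled(Tm_ref) = -dG_stapled(Tm_ref)`.
#' Stabilizing staples (higher `Tm`) give `ddG < 0`.  The standard error
#' comes from a seeded parametric bootstrap over both fits' parameter
#' covariances (the reference enters through the uncertainty of `Tm_ref`).
#'
#' @param fit_stapled,fit_ref Fits of the stapled variant and its
#'   non-stapled counterpart.
#' @param t_ref Evaluation temperature; defaults to the reference fit's `Tm`.
#'   Supplying a fixed value makes the operation exactly antisymmetric under
#'   swapping the two fits.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap.
#' @return One-row tibble: `ddg`, `se`, `reference_t` (K), `n_boot`.
#' @export
delta_delta_G <- function(fit_stapled, fit_ref, t_ref = NULL,
                          n_boot = 1000, seed = 1) {
  stopifnot(inherits(fit_stapled, "two_state_fit"),
            inherits(fit_ref, "two_state_fit"))
  fixed_t <- !is.null(t_ref)
  if (!fixed_t) t_ref <- fit_ref$coef[["tm"]]
  t_ref <- as_kelvin(t_ref)
  rng <- range(fit_stapled$data$temperature)
  if (t_ref < rng[1] - 10 || t_ref > rng[2] + 10) {
    warn("reference Tm lies far outside the stapled curve's data range; ddG is an extrapolation")
  }
  ddg <- delta_G(fit_ref, t_ref) - delta_G(fit_stapled, t_ref)

  draw_params <- function(fit, n) {
    if (any(!is.finite(fit$vcov))) {
      matrix(rep(fit$coef, each = n), nrow = n,
             dimnames = list(NULL, names(fit$coef)))
    } else {
      MASS::mvrnorm(n, mu = fit$coef, Sigma = fit$vcov)
    }
  }
  se <- withr::with_seed(seed, {
    ps <- draw_params(fit_stapled, n_boot)
    pr <- draw_params(fit_ref, n_boot)
    t_draw <- if (fixed_t) rep(t_ref, n_boot) else pr[, "tm"]
    dg_ref <- gibbs_helmholtz(t_draw, pr[, "tm"], pr[, "dh"],
                              if (fit_ref$dcp_fitted) pr[, "dcp"] else fit_ref$dcp)
    dg_stp <- gibbs_helmholtz(t_draw, ps[, "tm"], ps[, "dh"],
                              if (fit_stapled$dcp_fitted) ps[, "dcp"] else fit_stapled$dcp)
    sd(dg_ref - dg_stp)
  })
  tibble(ddg = ddg, se = se, reference_t = t_ref, n_boot = n_boot)
}

#' Write a melt-fit report to JSON
#'
#' Serializes parameter estimates, standard errors and the covariance matrix.
#'
#' @param fit A `two_state_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "two_state_fit"))
  report <- list(
    variant_id = fit$variant_id,
    parameters = as.list(fit$coef),
    se = as.list(fit$se),
    dcp = fit$dcp,
    dcp_fitted = fit$dcp_fitted,
    sigma = fit$sigma,
    covariance = fit$vcov
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
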