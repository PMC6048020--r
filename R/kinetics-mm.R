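# Small-sample corrected Akaike information criterion for an nls fit.
# k counts the residual variance as a parameter, as usual.
aicc_nls <- function(fit) {
  r <- resid(fit)
  n <- length(r)
  k <- length(coef(fit)) + 1
  n * log(sum(r^2) / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Catalytic efficiency from turnover number and Michaelis constant
#'
#' `kcat/KM` with KM converted from uM to M, giving the specificity constant
#' in M^-1 s^-1.
#'
#' @param kcat Turnover number, s^-1.
#' @param km_uM Michaelis constant, uM.
#' @return Efficiency in M^-1 s^-1.
#' @export
#' @examples
#' catalytic_efficiency(48.0, 15.3)
catalytic_efficiency <- function(kcat, km_uM) {
  kcat / (km_uM * 1e-6)
}

#' Initial rate from a progress curve
#'
#' Fits a least-squares line to the initial portion of a product progress
#' curve and converts the slope to uM/s via the signal calibration. The
#' window covers at most `max_fraction` substrate depletion (estimated
#' iteratively from the curve itself when `substrate_uM` is given) but never
#' fewer than `max(4, 10%)` of the points, so very fast curves still yield a
#' defined slope.
#'
#' @param curve Data frame with columns `time` (s) and `signal`.
#' @param calibration Signal units per uM of product (> 0).
#' @param substrate_uM Initial substrate concentration for the depletion
#'   estimate; `NULL` uses the first 10% of points (minimum 4).
#' @param max_fraction Maximal fraction of substrate consumed inside the
#'   fitting window (default 0.1).
#' @return Rate in uM/s.
#' @export
estimate_initial_rate <- function(curve, calibration, substrate_uM = NULL,
                                  max_fraction = 0.1) {
  if (calibration <= 0) stop("calibration must be > 0", call. = FALSE)
  stopifnot(all(c("time", "signal") %in% names(curve)))
  ord <- order(curve$time)
  t <- curve$time[ord]; y <- curve$signal[ord]
  if (length(t) < 4) stop("need at least 4 points", call. = FALSE)
  n_min <- max(4L, ceiling(0.1 * length(t)))
  keep <- n_min
  if (!is.null(substrate_uM)) {
    product <- (y - y[1]) / calibration
    # the window must be a leading stretch of the curve
    within <- cumall(product <= max_fraction * substrate_uM)
    lead <- if (any(within)) max(which(within)) else 0L
    keep <- max(n_min, lead)
  }
  keep <- min(keep, length(t))
  fit <- lm(y[seq_len(keep)] ~ t[seq_len(keep)])
  unname(coef(fit)[2]) / calibration
}

cumall <- function(x) cumprod(as.numeric(x)) > 0

#' Fit the Michaelis-Menten model to initial rates
#'
#' Nonlinear least squares of `v = kcat * E_active * S / (KM + S)` where
#' `E_active` (uM) is the known active-enzyme concentration, with starting
#' values from a Hanes-Woolf linearization (`S/v` regressed on `S`). Reports
#' `kcat` (s^-1), `KM` (uM), the catalytic efficiency `kcat/KM` (M^-1 s^-1)
#' with a delta-method standard error from the fit covariance, and a
#' `flagged` indicator when the fit does not converge cleanly or KM lands
#' outside 0.01-100x the designed substrate range.
#'
#' @param data Data frame with columns `substrate_uM` and `rate` (uM/s).
#' @param enzyme_nM Total enzyme concentration, nM.
#' @param active_fraction Fraction of enzyme that is catalytically active
#'   (0-1, default 1; determine with [fit_burst_titration()]).
#' @return An object of class `mm_fit`.
#' @export
#' @examples
#' s <- c(2, 5, 10, 20, 50, 100)
#' e_uM <- 0.06
#' v <- 48 * e_uM * s / (15.3 + s)
#' fit_michaelis_menten(data.frame(substrate_uM = s, rate = v),
#'                      enzyme_nM = 60)
fit_michaelis_menten <- function(data, enzyme_nM, active_fraction = 1) {
  stopifnot(all(c("substrate_uM", "rate") %in% names(data)))
  s <- data$substrate_uM; v <- data$rate
  if (length(unique(s)) < 5) {
    stop("need rates at >= 5 distinct substrate concentrations",
         call. = FALSE)
  }
  if (any(s <= 0)) stop("substrate concentrations must be > 0", call. = FALSE)
  e_uM <- enzyme_nM * active_fraction / 1000
  if (e_uM <= 0) stop("active enzyme concentration must be > 0",
                      call. = FALSE)
  # Hanes-Woolf start: S/v = KM/Vmax + S/Vmax
  pos <- v > 0
  hw <- lm(I(s[pos] / v[pos]) ~ s[pos])
  vmax0 <- unname(1 / coef(hw)[2])
  km0 <- unname(coef(hw)[1] * vmax0)
  if (!is.finite(vmax0) || vmax0 <= 0) vmax0 <- max(v)
  if (!is.finite(km0) || km0 <= 0) km0 <- median(s)
  fit <- nlsLM(
    rate ~ kcat * e_uM * substrate_uM / (KM + substrate_uM),
    data = data.frame(substrate_uM = s, rate = v),
    start = list(kcat = vmax0 / e_uM, KM = km0),
    lower = c(kcat = 0, KM = 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 2))
  vc <- tryCatch(vcov(fit), error = function(e) NULL)
  eff <- catalytic_efficiency(cf[["kcat"]], cf[["KM"]])
  eff_se <- NA_real_
  if (!is.null(vc)) {
    grad <- c(1e6 / cf[["KM"]], -1e6 * cf[["kcat"]] / cf[["KM"]]^2)
    eff_se <- sqrt(drop(t(grad) %*% vc %*% grad))
  }
  flagged <- !fit$convInfo$isConv ||
    cf[["KM"]] < 0.01 * min(s) || cf[["KM"]] > 100 * max(s)
  structure(
    list(kcat = unname(cf[["kcat"]]), KM = unname(cf[["KM"]]),
         efficiency = eff, kcat_se = unname(se[1]), KM_se = unname(se[2]),
         efficiency_se = eff_se, covariance = vc,
         enzyme_active_uM = e_uM, flagged = flagged, fit = fit,
         data = tibble::tibble(substrate_uM = s, rate = v)),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf(
    "<mm_fit> kcat = %.3g +/- %.2g s^-1 | KM = %.3g +/- %.2g uM | kcat/KM = %.4g M^-1 s^-1%s\n",
    x$kcat, x$kcat_se, x$KM, x$KM_se, x$efficiency,
    if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Broom-style accessors for kinetic fits
#'
#' `tidy()` returns one row per fitted parameter with its standard error and
#' a 95% Wald confidence interval; `glance()` returns one-row model-level
#' summaries.
#'
#' @param x A fitted object (`mm_fit`, `dose_response_fit`, `burst_fit`,
#'   `activation_fit`, `inhibition_mode_result`).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kcat", "KM", "efficiency"),
    estimate = c(x$kcat, x$KM, x$efficiency),
    std.error = c(x$kcat_se, x$KM_se, x$efficiency_se),
    conf.low = .data$estimate - 1.96 * .data$std.error,
    conf.high = .data$estimate + 1.96 * .data$std.error
  )
}

#' @rdname tidy.mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  r <- resid(x$fit)
  tibble::tibble(
    kcat = x$kcat, KM = x$KM, efficiency = x$efficiency,
    sigma = sqrt(sum(r^2) / (length(r) - 2)),
    nobs = length(r), flagged = x$flagged
  )
}

#' Display a Michaelis-Menten fit
#'
#' Observed rates and the fitted saturation curve.
#'
#' @param object An `mm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mm_fit <- function(object, ...) {
  s_grid <- seq(0, max(object$data$substrate_uM) * 1.05, length.out = 200)
  pred <- tibble::tibble(
    substrate_uM = s_grid,
    rate = object$kcat * object$enzyme_active_uM * s_grid / (object$KM + s_grid)
  )
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$substrate_uM, y = .data$rate)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = pred, colour = "steelblue") +
    ggplot2::labs(x = "[S] (uM)", y = "v (uM/s)") +
    ggplot2::theme_minimal()
}
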