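#' Fit a four-parameter log-logistic dose-response curve
#'
#' For an inhibitor, rates follow
#' `v = bottom + (top - bottom) / (1 + ([X]/IC50)^h)`, falling from `top` at
#' zero modifier to `bottom` at saturation; the midpoint of the fitted curve
#' is the reported IC50 and `v(IC50) = (top + bottom)/2` by construction. For
#' an activator the transition is rising and the midpoint is an EC50. The
#' Hill coefficient `h` is free (initialized at 1); `bottom` can be fixed
#' (commonly at 0) via `fix_bottom`.
#'
#' Rates measured with a constant coefficient of variation (multiplicative
#' noise) are better fitted with `weights = "relative"` (inverse-squared
#' rate), which keeps the standard errors calibrated; the default is
#' ordinary unweighted least squares.
#'
#' @param data Data frame with columns `conc_uM` (modifier concentration,
#'   zero allowed) and `rate`.
#' @param direction `"inhibition"` (default) or `"activation"`.
#' @param fix_bottom Optional fixed bottom plateau (e.g. 0).
#' @param weights `"none"` (default) or `"relative"` (1/rate^2, floored at
#'   5% of the maximal rate).
#' @return An object of class `dose_response_fit` with `ic50`, `hill`,
#'   `top`, `bottom` and standard errors.
#' @export
#' @examples
#' x <- c(0.5, 1, 2, 5, 10, 50, 100, 500)
#' v <- 1 / (1 + x / 3.6)
#' fit_dose_response(data.frame(conc_uM = x, rate = v), fix_bottom = 0)
fit_dose_response <- function(data, direction = c("inhibition", "activation"),
                              fix_bottom = NULL,
                              weights = c("none", "relative")) {
  direction <- match.arg(direction)
  weights <- match.arg(weights)
  stopifnot(all(c("conc_uM", "rate") %in% names(data)))
  x <- data$conc_uM; v <- data$rate
  if (length(unique(x)) < 5) {
    stop("need >= 5 modifier concentrations", call. = FALSE)
  }
  if (any(x < 0)) stop("concentrations must be >= 0", call. = FALSE)
  means <- tapply(v, x, mean)
  span <- diff(range(means))
  if (span < 0.02 * max(abs(means), 1e-12)) {
    stop("no transition: response is flat over the tested range",
         call. = FALSE)
  }
  lo_conc <- means[[1]]; hi_conc <- means[[length(means)]]
  top0 <- if (direction == "inhibition") max(means) else max(means)
  bottom0 <- fix_bottom %||% min(means)
  # midpoint start: concentration whose mean rate is nearest (top+bottom)/2
  mid <- (max(means) + min(means)) / 2
  xs <- as.numeric(names(means))
  ic0 <- xs[which.min(abs(means - mid))]
  if (ic0 <= 0) ic0 <- min(xs[xs > 0])
  sgn <- if (direction == "inhibition") 1 else -1
  d <- data.frame(x = x, v = v)
  wts <- if (weights == "relative") {
    1 / pmax(v, 0.05 * max(v))^2
  } else rep(1, length(v))
  if (is.null(fix_bottom)) {
    fit <- nlsLM(
      v ~ bottom + (top - bottom) / (1 + (x / ic50)^(sgn * hill)),
      data = d, weights = wts,
      start = list(top = top0, bottom = bottom0, ic50 = ic0, hill = 1),
      lower = c(top = 0, bottom = 0, ic50 = 1e-9, hill = 0.1),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
  } else {
    bottom <- fix_bottom
    fit <- nlsLM(
      v ~ bottom + (top - bottom) / (1 + (x / ic50)^(sgn * hill)),
      data = d, weights = wts,
      start = list(top = top0, ic50 = ic0, hill = 1),
      lower = c(top = 0, ic50 = 1e-9, hill = 0.1),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
  }
  cf <- as.list(coef(fit))
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    setNames(rep(NA_real_, length(cf)), names(cf)))
  top <- cf$top; bottom <- cf$bottom %||% fix_bottom
  if (direction == "inhibition" && top <= bottom) {
    warn("fitted top <= bottom; inhibition direction not supported by data")
  }
  structure(
    list(ic50 = cf$ic50, hill = cf$hill, top = top, bottom = bottom,
         ic50_se = unname(se[["ic50"]]),
         hill_se = unname(se[["hill"]]),
         top_se = unname(se[["top"]]),
         bottom_se = if (is.null(fix_bottom)) unname(se[["bottom"]]) else 0,
         direction = direction, fit = fit,
         data = tibble::tibble(conc_uM = x, rate = v)),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  lab <- if (x$direction == "inhibition") "IC50" else "EC50"
  cat(sprintf("<dose_response_fit> %s = %.3g +/- %.2g uM | hill = %.2f | top = %.3g | bottom = %.3g\n",
              lab, x$ic50, x$ic50_se, x$hill, x$top, x$bottom))
  invisible(x)
}

#' @rdname tidy.mm_fit
#' @export
tidy.dose_response_fit <- function(x, ...) {
  tibble::tibble(
    term = c("ic50", "hill", "top", "bottom"),
    estimate = c(x$ic50, x$hill, x$top, x$bottom),
    std.error = c(x$ic50_se, x$hill_se, x$top_se, x$bottom_se),
    conf.low = .data$estimate - 1.96 * .data$std.error,
    conf.high = .data$estimate + 1.96 * .data$std.error
  )
}

#' @rdname tidy.mm_fit
#' @export
glance.dose_response_fit <- function(x, ...) {
  r <- resid(x$fit)
  tibble::tibble(ic50 = x$ic50, hill = x$hill, top = x$top,
                 bottom = x$bottom, sigma = sqrt(mean(r^2)),
                 nobs = length(r), direction = x$direction)
}

#' @rdname autoplot.mm_fit
#' @export
autoplot.dose_response_fit <- function(object, ...) {
  xpos <- object$data$conc_uM[object$data$conc_uM > 0]
  grid <- exp(seq(log(min(xpos) / 3), log(max(xpos) * 3), length.out = 200))
  sgn <- if (object$direction == "inhibition") 1 else -1
  pred <- tibble::tibble(
    conc_uM = grid,
    rate = object$bottom + (object$top - object$bottom) /
      (1 + (grid / object$ic50)^(sgn * object$hill))
  )
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$conc_uM, y = .data$rate)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = pred, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "[modifier] (uM)", y = "v") +
    ggplot2::theme_minimal()
}

#' Fit a saturating (optionally attenuated) activation model
#'
#' Rates as a function of activator concentration are modelled as
#' `v([A]) = v0 * (1 + (F - 1) * [A]/(K_act + [A])) / (1 + [A]/K_att)`,
#' where `F` is the maximal fold-stimulation, `K_act` the half-maximal
#' activation constant and the optional attenuation constant `K_att` captures
#' the loss of stimulation sometimes seen at very high cation
#' concentrations; the pure saturation model is the `K_att -> Inf` limit.
#' Both variants are fitted and the small-sample corrected AIC selects
#' between them. Data whose replicate-mean rates decrease monotonically with
#' concentration are rejected: the modifier is not an activator.
#'
#' @param data Data frame with columns `conc_uM` (including 0) and `rate`.
#' @return An object of class `activation_fit` with `fold_max`, `K_act`,
#'   `K_att` (`Inf` for the pure model), `v0`, standard errors and the AICc
#'   table.
#' @export
fit_activation <- function(data) {
  stopifnot(all(c("conc_uM", "rate") %in% names(data)))
  x <- data$conc_uM; v <- data$rate
  if (length(unique(x)) < 5 || !any(x == 0)) {
    stop("need >= 5 activator levels including 0", call. = FALSE)
  }
  means <- tapply(v, x, mean)
  if (all(diff(means) <= 0) && means[[length(means)]] < means[[1]]) {
    stop("not an activator: rates decrease monotonically with concentration",
         call. = FALSE)
  }
  v00 <- means[[1]]
  f0 <- max(means) / v00
  xs <- as.numeric(names(means))
  half <- v00 * (1 + (f0 - 1) / 2)
  k0 <- xs[which.min(abs(means - half))]
  if (k0 <= 0) k0 <- median(xs[xs > 0])
  d <- data.frame(x = x, v = v)
  wrap <- function(fit) {
    list(coef = coef(fit), resid = as.numeric(resid(fit)),
         vcov = tryCatch(vcov(fit), error = function(e) NULL))
  }
  # pure saturation can always be fitted by profiling K_act: for fixed
  # K_act the model is linear in (v0, v0 * (fmax - 1)). This also covers
  # the flat case fmax ~ 1 where the K_act gradient vanishes and the
  # Levenberg-Marquardt packaging becomes singular.
  profile_pure <- function() {
    xpos <- x[x > 0]
    rss_k <- function(logk) {
      u <- x / (exp(logk) + x)
      sum(resid(lm(v ~ u))^2)
    }
    opt <- stats::optimize(rss_k, log(c(min(xpos) / 100, max(xpos) * 100)))
    k <- exp(opt$minimum)
    u <- x / (k + x)
    f <- lm(v ~ u)
    v0 <- unname(coef(f)[1])
    list(coef = c(v0 = v0, fmax = 1 + unname(coef(f)[2]) / v0, K_act = k),
         resid = as.numeric(resid(f)), vcov = NULL)
  }
  pure <- tryCatch(wrap(nlsLM(
    v ~ v0 * (1 + (fmax - 1) * x / (K_act + x)),
    data = d, start = list(v0 = v00, fmax = max(f0, 1.01), K_act = k0),
    lower = c(v0 = 1e-12, fmax = 1e-6, K_act = 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )), error = function(e) profile_pure())
  att <- tryCatch(wrap(nlsLM(
    v ~ v0 * (1 + (fmax - 1) * x / (K_act + x)) / (1 + x / K_att),
    data = d,
    start = list(v0 = v00, fmax = max(f0, 1.01), K_act = k0,
                 K_att = max(x) * 10),
    lower = c(v0 = 1e-12, fmax = 1e-6, K_act = 1e-9, K_att = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )), error = function(e) NULL)
  models <- list(pure = pure)
  if (!is.null(att)) models$attenuated <- att
  aicc <- vapply(models, function(m) {
    n <- length(m$resid); k <- length(m$coef) + 1
    n * log(sum(m$resid^2) / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  }, numeric(1))
  best <- names(which.min(aicc))
  fit <- models[[best]]
  cf <- as.list(fit$coef)
  se <- if (!is.null(fit$vcov)) {
    sqrt(diag(fit$vcov))
  } else setNames(rep(NA_real_, length(cf)), names(cf))
  structure(
    list(fold_max = cf$fmax, K_act = cf$K_act,
         K_att = cf$K_att %||% Inf, v0 = cf$v0,
         fold_max_se = unname(se[["fmax"]]), K_act_se = unname(se[["K_act"]]),
         model = best, aicc = aicc, fit = fit,
         data = tibble::tibble(conc_uM = x, rate = v)),
    class = "activation_fit"
  )
}

#' @export
print.activation_fit <- function(x, ...) {
  cat(sprintf("<activation_fit> fold_max = %.2f +/- %.2g | K_act = %.3g uM | model = %s\n",
              x$fold_max, x$fold_max_se, x$K_act, x$model))
  invisible(x)
}

#' @rdname tidy.mm_fit
#' @export
tidy.activation_fit <- function(x, ...) {
  cf <- x$fit$coef
  se <- if (!is.null(x$fit$vcov)) sqrt(diag(x$fit$vcov)) else
    rep(NA_real_, length(cf))
  tibble::tibble(term = names(cf), estimate = unname(cf),
                 std.error = unname(se),
                 conf.low = .data$estimate - 1.96 * .data$std.error,
                 conf.high = .data$estimate + 1.96 * .data$std.error)
}

#' @rdname tidy.mm_fit
#' @export
glance.activation_fit <- function(x, ...) {
  tibble::tibble(fold_max = x$fold_max, K_act = x$K_act, K_att = x$K_att,
                 v0 = x$v0, model = x$model, nobs = nrow(x$data))
}
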