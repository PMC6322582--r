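#' Fit a growth model to a trait trajectory
#'
#' Fits one of the six candidate growth families to trait values over time:
#' linear `a + b t`, power `a t^b`, exponential `a e^{b t}`, logarithmic
#' `a + b ln t`, quadratic `a + b t + c t^2`, or logistic
#' `K / (1 + a e^{-b t})`. Linear, quadratic and logarithmic fits are
#' closed-form least squares; power, exponential and logistic are
#' log-linearized for starting values and refined by Levenberg-Marquardt
#' nonlinear least squares. Goodness metrics (R-squared, MAPE, RMSE, SD of
#' the absolute percentage errors) compare fitted against observed values.
#'
#' @param t Time points (e.g. days); power and logarithmic require `t > 0`.
#' @param y Observed trait values; exponential, power and logistic require
#'   `y > 0`.
#' @param family One of `"linear"`, `"power"`, `"exponential"`,
#'   `"logarithmic"`, `"quadratic"`, `"logistic"`.
#' @param max_iter Iteration cap for the nonlinear refinement.
#' @return Object of class `"growth_fit"`: `family`, `coefficients`,
#'   `fitted.values`, `residuals`, `t`, `y`, `r_squared`, `mape`, `rmse`,
#'   `sd_ape`, `converged`. A non-convergent refinement returns the
#'   log-linearized fit with `converged = FALSE` rather than failing.
#' @examples
#' t <- 1:9
#' y <- 100 / (1 + 20 * exp(-0.4 * t))
#' fit <- fit_growth_model(t, y, "logistic")
#' coef(fit)
#' predict(fit, newdata = 10)
#' @export
fit_growth_model <- function(t, y,
                             family = c("linear", "power", "exponential",
                                        "logarithmic", "quadratic", "logistic"),
                             max_iter = 200) {
  family <- match.arg(family)
  stopifnot(length(t) == length(y))
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  npar <- switch(family, linear = 2, power = 2, exponential = 2,
                 logarithmic = 2, quadratic = 3, logistic = 3)
  if (length(y) < npar)
    stop("need at least ", npar, " points for a ", family, " fit")
  if (family %in% c("power", "logarithmic") && any(t <= 0))
    stop(family, " fit requires positive time values")
  if (family %in% c("power", "exponential", "logistic") && any(y <= 0))
    stop(family, " fit requires positive trait values")

  converged <- TRUE
  co <- switch(family,
    linear = {
      f <- lm(y ~ t); setNames(coef(f), c("a", "b"))
    },
    quadratic = {
      f <- lm(y ~ t + I(t^2)); setNames(coef(f), c("a", "b", "c"))
    },
    logarithmic = {
      f <- lm(y ~ log(t)); setNames(coef(f), c("a", "b"))
    },
    power = {
      init <- coef(lm(log(y) ~ log(t)))
      st <- list(a = exp(init[[1]]), b = init[[2]])
      nl <- tryCatch(minpack.lm::nlsLM(y ~ a * t^b, start = st,
                                       control = minpack.lm::nls.lm.control(
                                         maxiter = max_iter)),
                     error = function(e) NULL)
      if (is.null(nl)) { converged <- FALSE; unlist(st) }
      else setNames(coef(nl), c("a", "b"))
    },
    exponential = {
      init <- coef(lm(log(y) ~ t))
      st <- list(a = exp(init[[1]]), b = init[[2]])
      nl <- tryCatch(minpack.lm::nlsLM(y ~ a * exp(b * t), start = st,
                                       control = minpack.lm::nls.lm.control(
                                         maxiter = max_iter)),
                     error = function(e) NULL)
      if (is.null(nl)) { converged <- FALSE; unlist(st) }
      else setNames(coef(nl), c("a", "b"))
    },
    logistic = {
      K0 <- max(y) * 1.05
      z <- log(pmax(K0 / y - 1, 1e-9))
      init <- coef(lm(z ~ t)) # log((K-y)/y) = log a - b t
      st <- list(K = K0, a = exp(init[[1]]), b = -init[[2]])
      nl <- tryCatch(minpack.lm::nlsLM(y ~ K / (1 + a * exp(-b * t)),
                                       start = st,
                                       lower = c(K = 0, a = 0, b = -Inf),
                                       control = minpack.lm::nls.lm.control(
                                         maxiter = max_iter)),
                     error = function(e) NULL)
      if (is.null(nl)) { converged <- FALSE; unlist(st) }
      else setNames(coef(nl), c("K", "a", "b"))
    })

  fitted <- growth_eval(family, co, t)
  res <- y - fitted
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  structure(list(family = family, coefficients = co, fitted.values = fitted,
                 residuals = res, t = t, y = y, r_squared = r2,
                 mape = if (all(y != 0)) mape(fitted, y) else NA_real_,
                 rmse = rmse(fitted, y),
                 sd_ape = if (all(y != 0)) sd_ape(fitted, y) else NA_real_,
                 converged = converged),
            class = "growth_fit")
}

growth_eval <- function(family, co, t) {
  switch(family,
         linear = co[["a"]] + co[["b"]] * t,
         power = co[["a"]] * t^co[["b"]],
         exponential = co[["a"]] * exp(co[["b"]] * t),
         logarithmic = co[["a"]] + co[["b"]] * log(t),
         quadratic = co[["a"]] + co[["b"]] * t + co[["c"]] * t^2,
         logistic = co[["K"]] / (1 + co[["a"]] * exp(-co[["b"]] * t)))
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Growth fit (%s%s)\n", x$family,
              if (x$converged) "" else ", refinement did not converge"))
  print(round(x$coefficients, 6))
  cat(sprintf("R^2 = %.4f, MAPE = %.3f%%, RMSE = %.4g, SD_APE = %.3f%%\n",
              x$r_squared, x$mape, x$rmse, x$sd_ape))
  invisible(x)
}

#' @export
summary.growth_fit <- function(object, ...) {
  print(object)
  cat(sprintf("n = %d points over t in [%g, %g]\n",
              length(object$y), min(object$t), max(object$t)))
  invisible(object)
}

#' @export
coef.growth_fit <- function(object, ...) object$coefficients

#' @export
fitted.growth_fit <- function(object, ...) object$fitted.values

#' @export
residuals.growth_fit <- function(object, ...) object$residuals

#' @rdname fit_growth_model
#' @param object A `"growth_fit"`.
#' @param newdata Time points to predict at (default: the fitted ones).
#' @param ... Unused.
#' @export
predict.growth_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  growth_eval(object$family, object$coefficients, as.numeric(newdata))
}

#' @export
plot.growth_fit <- function(x, ...) {
  plot(x$t, x$y, pch = 16, xlab = "time", ylab = "trait value",
       main = sprintf("%s fit (R^2 = %.3f)", x$family, x$r_squared), ...)
  tt <- seq(min(x$t), max(x$t), length.out = 200)
  lines(tt, predict(x, tt), col = 2)
  invisible(x)
}

#' Compare the six candidate growth families on one trajectory
#'
#' Fits every family that is admissible for the data and tabulates the
#' goodness metrics; families whose positivity requirements the data violate
#' are skipped.
#'
#' @inheritParams fit_growth_model
#' @return Data frame (one row per family) with `family`, `r_squared`,
#'   `mape`, `rmse`, `sd_ape`, `converged`, ordered by increasing MAPE, with
#'   the fitted objects in `attr(, "fits")`.
#' @export
compare_growth_models <- function(t, y) {
  fams <- c("linear", "power", "exponential", "logarithmic", "quadratic",
            "logistic")
  fits <- list()
  rows <- list()
  for (f in fams) {
    fit <- tryCatch(fit_growth_model(t, y, f), error = function(e) NULL)
    if (is.null(fit)) next
    fits[[f]] <- fit
    rows[[f]] <- data.frame(family = f, r_squared = fit$r_squared,
                            mape = fit$mape, rmse = fit$rmse,
                            sd_ape = fit$sd_ape, converged = fit$converged)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$mape), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
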