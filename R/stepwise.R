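#' Forward stepwise yield model
#'
#' Forward stepwise ordinary least squares in the SPSS convention: at each
#' step the candidate with the smallest partial F-test p-value enters if that
#' p-value is below `p_enter`, and after every entry any included predictor
#' whose p-value has risen above `p_remove` is dropped. Rank-deficient
#' candidates (collinear with the current model) are skipped with a warning.
#'
#' @param traits Data frame or matrix of candidate predictors (plants in
#'   rows); constant columns are rejected.
#' @param response Numeric response (e.g. grain yield), one value per plant.
#' @param p_enter Entry significance threshold.
#' @param p_remove Removal significance threshold (must be >= `p_enter`).
#' @param max_steps Safety cap on entry steps.
#' @return Object of class `"stepwise_fit"`: `selected` (predictors in entry
#'   order), `coefficients` of the final model, `r` (multiple correlation),
#'   `r_squared`, `model` (the final `lm`), `steps` (entry/removal log).
#' @export
stepwise_yield_model <- function(traits, response, p_enter = 0.05,
                                 p_remove = 0.10, max_steps = ncol(traits)) {
  traits <- as.data.frame(traits)
  stopifnot(nrow(traits) == length(response), p_remove >= p_enter)
  if (any(vapply(traits, function(c) var(c, na.rm = TRUE) == 0, logical(1))))
    stop("constant candidate columns are not allowed")
  if (nrow(traits) < 3) stop("need more plants than predictors")
  dat <- cbind(.response = response, traits)
  selected <- character(0)
  steps <- list()
  fit <- lm(.response ~ 1, data = dat)
  repeat {
    if (length(selected) >= max_steps) break
    cands <- setdiff(names(traits), selected)
    if (length(cands) == 0) break
    pvals <- vapply(cands, function(v) {
      f2 <- tryCatch(stats::update(fit, stats::as.formula(
        paste(". ~ . +", sprintf("`%s`", v)))), error = function(e) NULL)
      if (is.null(f2) || any(is.na(coef(f2)))) return(NA_real_)
      a <- stats::anova(fit, f2)
      a[["Pr(>F)"]][2]
    }, numeric(1))
    if (any(is.na(pvals))) {
      warning("dropping rank-deficient candidate(s): ",
              paste(cands[is.na(pvals)], collapse = ", "))
      pvals <- pvals[!is.na(pvals)]
      cands <- names(pvals)
      if (length(cands) == 0) break
    }
    best <- which.min(pvals)
    if (pvals[best] >= p_enter) break
    selected <- c(selected, cands[best])
    steps[[length(steps) + 1]] <- list(action = "enter", term = cands[best],
                                       p = unname(pvals[best]))
    fit <- lm(stats::as.formula(paste(".response ~",
                                      paste(sprintf("`%s`", selected),
                                            collapse = " + "))), data = dat)
    # removal phase
    repeat {
      if (length(selected) < 2) break
      sm <- summary(fit)$coefficients
      pv <- sm[-1, 4]
      worst <- which.max(pv)
      if (pv[worst] <= p_remove) break
      gone <- selected[worst]
      selected <- selected[-worst]
      steps[[length(steps) + 1]] <- list(action = "remove", term = gone,
                                         p = unname(pv[worst]))
      fit <- lm(stats::as.formula(paste(".response ~",
                                        paste(sprintf("`%s`", selected),
                                              collapse = " + "))), data = dat)
    }
  }
  r2 <- if (length(selected)) summary(fit)$r.squared else 0
  structure(list(selected = selected, coefficients = coef(fit),
                 r = sqrt(r2), r_squared = r2, model = fit, steps = steps,
                 p_enter = p_enter, p_remove = p_remove),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("Forward stepwise model (enter p < %g, remove p > %g)\n",
              x$p_enter, x$p_remove))
  if (length(x$selected) == 0) {
    cat("  no predictor passed the entry threshold\n")
  } else {
    cat("  selected (entry order):", paste(x$selected, collapse = ", "), "\n")
    cat(sprintf("  R = %.3f, R^2 = %.3f\n", x$r, x$r_squared))
  }
  invisible(x)
}
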