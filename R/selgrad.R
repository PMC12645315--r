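# Lande-Arnold selection gradient estimation: the core model object.

#' Fit a standardized Lande-Arnold selection gradient
#'
#' Ordinary least squares regression of relative fitness on a
#' cohort-standardized trait. Under `model = "linear"` the fitted slope is the
#' linear selection gradient beta. Under `model = "quadratic"` the design is
#' `rlrs ~ z + I(z^2)`; the coefficient of `z` is reported as beta (the
#' directional gradient under the quadratic model) and the quadratic selection
#' gradient gamma is *twice* the fitted `z^2` coefficient, so the fitted
#' fitness surface is `a + beta*z + (gamma/2)*z^2`. Negative gamma indicates
#' concave (stabilizing-type) curvature.
#'
#' Confidence intervals use classical OLS standard errors with the normal
#' critical value 1.96. Because rLRS is a scaled count whose variance grows
#' with its mean, a heteroskedasticity-robust (HC3) covariance is available via
#' `robust = TRUE`.
#'
#' @param z Numeric vector of standardized trait values.
#' @param rlrs Numeric vector of relative fitness, same length as `z`.
#' @param model `"linear"` or `"quadratic"`.
#' @param robust Use a heteroskedasticity-consistent (HC3) covariance for
#'   standard errors and intervals.
#' @param min_n Minimum number of complete observations required.
#' @param conf_level Confidence level (interval uses the normal critical
#'   value, 1.96 at the default 0.95).
#' @param trait,stratum Optional labels carried into the estimate (a trait
#'   name and a named list such as `list(sex = "F", education = "primary")`).
#' @return An object of class `selgrad`: a list with elements `coefficients`
#'   (intercept, z, and for the quadratic model `z^2` — on the raw regression
#'   scale), `beta`, `gamma` (NA for the linear model), `se_beta`, `se_gamma`,
#'   `ci_beta`, `ci_gamma`, `vcov` (of the raw coefficients), `sigma2`, `n`,
#'   `model`, `robust`, `conf_level`, `trait`, `stratum`, `residuals`,
#'   `fitted`.
#' @examples
#' z <- c(-1, 0, 1)
#' w <- c(0.5, 1.0, 1.5)
#' fit <- selection_gradient(z, w, model = "linear", min_n = 3)
#' coef(fit)["z"]  # 0.5
#' @seealso [fitness_curve()], [gradient_by_stratum()], [ci_overlap()]
#' @export
selection_gradient <- function(z, rlrs, model = c("linear", "quadratic"),
                               robust = FALSE, min_n = 30L,
                               conf_level = 0.95,
                               trait = NA_character_, stratum = list()) {
  model <- match.arg(model)
  ok <- stats::complete.cases(z, rlrs)
  z <- as.numeric(z[ok])
  rlrs <- as.numeric(rlrs[ok])
  n <- length(z)
  if (n < min_n) {
    stop(sprintf("selection_gradient: n = %d is below the minimum stratum size %d",
                 n, min_n))
  }
  if (stats::var(z) == 0) stop("selection_gradient: trait has zero variance")
  if (model == "quadratic" && length(unique(z)) < 3L) {
    stop("selection_gradient: quadratic model needs >= 3 distinct trait values")
  }
  dat <- data.frame(rlrs = rlrs, z = z)
  fit <- if (model == "linear") {
    stats::lm(rlrs ~ z, data = dat)
  } else {
    stats::lm(rlrs ~ z + I(z^2), data = dat)
  }
  cf <- stats::coef(fit)
  # suppressWarnings: summary.lm warns on exact fits ("essentially perfect")
  V <- if (robust) sandwich::vcovHC(fit, type = "HC3") else suppressWarnings(stats::vcov(fit))
  se <- sqrt(diag(V))
  crit <- stats::qnorm(1 - (1 - conf_level) / 2)

  beta <- unname(cf["z"])
  se_beta <- unname(se["z"])
  ci_beta <- beta + c(-1, 1) * crit * se_beta
  if (model == "quadratic") {
    qc <- unname(cf["I(z^2)"])
    gamma <- 2 * qc
    se_gamma <- 2 * unname(se["I(z^2)"])
    ci_gamma <- gamma + c(-1, 1) * crit * se_gamma
  } else {
    gamma <- NA_real_
    se_gamma <- NA_real_
    ci_gamma <- c(NA_real_, NA_real_)
  }

  structure(list(
    coefficients = cf,
    beta = beta, gamma = gamma,
    se_beta = se_beta, se_gamma = se_gamma,
    ci_beta = ci_beta, ci_gamma = ci_gamma,
    vcov = V, sigma2 = stats::sigma(fit)^2,
    n = n, model = model, robust = robust, conf_level = conf_level,
    trait = trait, stratum = stratum,
    residuals = stats::residuals(fit), fitted = stats::fitted(fit)
  ), class = "selgrad")
}

#' @export
print.selgrad <- function(x, digits = 4, ...) {
  lab <- if (!is.na(x$trait)) paste0(" on ", x$trait) else ""
  str_lab <- if (length(x$stratum) > 0) {
    paste0(" [", paste(unlist(x$stratum), collapse = ", "), "]")
  } else ""
  cat(sprintf("%s Lande-Arnold selection gradient%s%s (n = %d)\n",
              x$model, lab, str_lab, x$n))
  cat(sprintf("  beta  = %s  (SE %s, %d%% CI %s to %s)\n",
              format(x$beta, digits = digits), format(x$se_beta, digits = digits),
              round(100 * x$conf_level),
              format(x$ci_beta[1], digits = digits),
              format(x$ci_beta[2], digits = digits)))
  if (x$model == "quadratic") {
    cat(sprintf("  gamma = %s  (SE %s, %d%% CI %s to %s)\n",
                format(x$gamma, digits = digits), format(x$se_gamma, digits = digits),
                round(100 * x$conf_level),
                format(x$ci_gamma[1], digits = digits),
                format(x$ci_gamma[2], digits = digits)))
  }
  invisible(x)
}

#' @export
summary.selgrad <- function(object, ...) {
  x <- object
  est <- data.frame(
    term = c("beta", if (x$model == "quadratic") "gamma"),
    estimate = c(x$beta, if (x$model == "quadratic") x$gamma),
    se = c(x$se_beta, if (x$model == "quadratic") x$se_gamma),
    ci_low = c(x$ci_beta[1], if (x$model == "quadratic") x$ci_gamma[1]),
    ci_high = c(x$ci_beta[2], if (x$model == "quadratic") x$ci_gamma[2])
  )
  peak <- if (x$model == "quadratic" && !is.na(x$gamma) && x$gamma < 0) {
    -x$beta / x$gamma
  } else NA_real_
  out <- list(estimates = est, n = x$n, model = x$model, trait = x$trait,
              stratum = x$stratum, robust = x$robust, peak = peak,
              resid_sd = sqrt(x$sigma2))
  class(out) <- "summary.selgrad"
  out
}

#' @export
print.summary.selgrad <- function(x, digits = 4, ...) {
  cat(sprintf("%s selection gradient%s, n = %d%s\n", x$model,
              if (!is.na(x$trait)) paste0(" on ", x$trait) else "", x$n,
              if (x$robust) " (robust SEs)" else ""))
  print(x$estimates, digits = digits, row.names = FALSE)
  if (!is.na(x$peak)) {
    cat(sprintf("concave fitted surface; peak at z = %s\n",
                format(x$peak, digits = digits)))
  }
  invisible(x)
}

#' @export
coef.selgrad <- function(object, ...) object$coefficients

#' @export
vcov.selgrad <- function(object, ...) object$vcov

#' @export
nobs.selgrad <- function(object, ...) object$n

#' @export
residuals.selgrad <- function(object, ...) object$residuals

#' @export
fitted.selgrad <- function(object, ...) object$fitted

#' @export
confint.selgrad <- function(object, parm = c("beta", "gamma"), level = NULL, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  if (!is.null(level) && level != object$conf_level) {
    stop("intervals are stored at conf_level = ", object$conf_level)
  }
  m <- rbind(beta = object$ci_beta, gamma = object$ci_gamma)
  colnames(m) <- c("low", "high")
  m[parm, , drop = FALSE]
}

#' Predicted fitness surface with point-wise confidence band
#'
#' @param object A `selgrad` fit.
#' @param newdata Optional `data.frame` with a `z` column (or a numeric vector
#'   of z values).
#' @param interval `"none"` or `"confidence"` (point-wise band from the
#'   coefficient covariance, normal critical value).
#' @param ... Unused.
#' @return A numeric vector of predictions, or with `interval = "confidence"`
#'   a `data.frame` with `fit`, `ci_low`, `ci_high`.
#' @export
predict.selgrad <- function(object, newdata = NULL,
                            interval = c("none", "confidence"), ...) {
  interval <- match.arg(interval)
  z <- if (is.null(newdata)) {
    stop("predict.selgrad requires newdata (a z vector or data.frame with $z)")
  } else if (is.data.frame(newdata)) {
    newdata$z
  } else {
    as.numeric(newdata)
  }
  if (length(z) == 0L) stop("empty prediction grid")
  X <- if (object$model == "linear") cbind(1, z) else cbind(1, z, z^2)
  fit <- drop(X %*% object$coefficients)
  if (interval == "none") return(fit)
  se <- sqrt(rowSums((X %*% object$vcov) * X))
  crit <- stats::qnorm(1 - (1 - object$conf_level) / 2)
  data.frame(fit = fit, ci_low = fit - crit * se, ci_high = fit + crit * se)
}

#' Evaluate a fitted quadratic selection curve on a z grid
#'
#' Returns the predicted relative fitness `a + beta*z + (gamma/2)*z^2` with a
#' point-wise confidence band, the machine-readable analogue of a plotted
#' selection curve. For a concave fit the peak lies at `z = -beta/gamma`.
#'
#' @param estimate A `selgrad` fit with `model = "quadratic"`.
#' @param z_grid Numeric vector of standardized trait values (non-empty).
#' @return A `data.frame` with columns `z`, `fit`, `ci_low`, `ci_high`.
#' @export
fitness_curve <- function(estimate, z_grid) {
  stopifnot(inherits(estimate, "selgrad"))
  if (estimate$model != "quadratic") {
    stop("fitness_curve requires a quadratic selgrad fit")
  }
  if (length(z_grid) == 0L) stop("empty z grid")
  pred <- predict(estimate, newdata = as.numeric(z_grid),
                  interval = "confidence")
  cbind(data.frame(z = as.numeric(z_grid)), pred)
}

#' @export
plot.selgrad <- function(x, z_range = c(-3, 3), npoints = 101, ...) {
  zg <- seq(z_range[1], z_range[2], length.out = npoints)
  pred <- predict(x, newdata = zg, interval = "confidence")
  graphics::plot(zg, pred$fit, type = "l",
                 xlab = sprintf("%s (z-score)",
                                if (is.na(x$trait)) "trait" else x$trait),
                 ylab = "relative fitness (rLRS)", ...)
  graphics::lines(zg, pred$ci_low, lty = 2)
  graphics::lines(zg, pred$ci_high, lty = 2)
  invisible(x)
}

#' @export
simulate.selgrad <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  z <- if (is.null(newdata)) {
    stop("simulate.selgrad requires newdata (z values)")
  } else if (is.data.frame(newdata)) newdata$z else as.numeric(newdata)
  mu <- predict(object, newdata = z)
  out <- replicate(nsim, mu + stats::rnorm(length(mu), 0, sqrt(object$sigma2)),
                   simplify = FALSE)
  as.data.frame(stats::setNames(out, paste0("sim_", seq_len(nsim))))
}

#' Do two confidence intervals indicate a difference?
#'
#' Implements the interval-overlap heuristic: two estimates are flagged as
#' indicatively different exactly when their confidence intervals do not
#' overlap. Touching intervals count as overlapping (conservative reading).
#'
#' @param a,b Numeric length-2 intervals `c(low, high)` with `low <= high`.
#' @return `TRUE` iff the intervals are disjoint.
#' @export
ci_overlap <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 2L || length(b) != 2L || anyNA(a) || anyNA(b) ||
      a[1] > a[2] || b[1] > b[2]) {
    stop("ci_overlap: intervals must be c(low, high) with low <= high")
  }
  a[2] < b[1] || b[2] < a[1]
}
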