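#' Fit the GABA-A current-voltage relation and estimate the reversal potential
#'
#' The central estimator of the package: a least-squares straight line
#' through peak GABA-evoked currents versus (series-resistance-corrected)
#' membrane potential.  The reversal potential is the zero crossing,
#' `E_GABA = -intercept / slope`; the slope is the chord conductance in nS.
#' A GABA-A I-V is approximately ohmic near its reversal over the usual
#' sampled range, and the residual diagnostics expose curvature when it is
#' not.
#'
#' @param iv A data.frame with columns `I_peak` (pA) and `V_corr` (mV), as
#'   produced by [measure_iv()]; a `V_com` column is used instead when
#'   `use = "V_com"` (the uncorrected fit, for comparison).
#' @param use Which potential column to regress on: `"V_corr"` (default)
#'   or `"V_com"`.
#' @param max_extrapolation_mV If the peak currents do not change sign
#'   across the sampled potentials, the fitted reversal may lie at most
#'   this far (mV) beyond the sampled span; further extrapolation is an
#'   error (default 10).
#' @return An object of class `"iv_fit"`: list with `E_rev` (mV),
#'   `conductance_nS` (slope), `intercept_pA`, `residual_rms_pA`,
#'   `extrapolated` (logical), `data`, and the underlying `lm` fit.
#'   Supported methods: `print`, `summary`, `coef`, `predict`,
#'   `residuals`, `confint`, `plot`.
#' @examples
#' iv <- data.frame(V_corr = c(-80, -60), I_peak = c(-30, 10))
#' fit <- fit_reversal(iv)
#' coef(fit)["E_rev"]  # -65 mV
#' @export
fit_reversal <- function(iv, use = c("V_corr", "V_com"),
                         max_extrapolation_mV = 10) {
  use <- match.arg(use)
  if (!all(c("I_peak", use) %in% names(iv))) {
    stop("'iv' must contain columns 'I_peak' and '", use, "'")
  }
  v <- iv[[use]]
  i <- iv$I_peak
  ok <- is.finite(v) & is.finite(i)
  v <- v[ok]; i <- i[ok]
  if (length(unique(v)) < 2) {
    stop("need at least 2 distinct potentials to fit a reversal")
  }
  fit <- stats::lm(i ~ v)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0) {
    stop("fitted slope (conductance) is not positive; non-physical I-V")
  }
  e_rev <- -intercept / slope
  sign_change <- min(i) < 0 && max(i) > 0
  span <- range(v)
  extrap <- e_rev < span[1] | e_rev > span[2]
  if (!sign_change && extrap) {
    dist <- max(span[1] - e_rev, e_rev - span[2])
    if (dist > max_extrapolation_mV) {
      stop(sprintf(paste0("currents do not change sign and the fitted ",
                          "reversal (%.1f mV) lies %.1f mV beyond the ",
                          "sampled span; refusing to extrapolate"),
                   e_rev, dist))
    }
  }
  structure(list(E_rev = e_rev,
                 conductance_nS = slope,
                 intercept_pA = intercept,
                 residual_rms_pA = sqrt(mean(stats::residuals(fit)^2)),
                 extrapolated = extrap,
                 potential = use,
                 data = data.frame(V = v, I = i),
                 lm = fit),
            class = "iv_fit")
}

#' @export
print.iv_fit <- function(x, ...) {
  cat("GABA-A current-voltage fit (straight line)\n")
  cat(sprintf("  E_rev        : %.2f mV%s\n", x$E_rev,
              if (x$extrapolated) "  [extrapolated]" else ""))
  cat(sprintf("  conductance  : %.3f nS\n", x$conductance_nS))
  cat(sprintf("  residual RMS : %.3f pA over %d points (%s)\n",
              x$residual_rms_pA, nrow(x$data), x$potential))
  invisible(x)
}

#' @export
coef.iv_fit <- function(object, ...) {
  c(E_rev = object$E_rev,
    conductance_nS = object$conductance_nS,
    intercept_pA = object$intercept_pA)
}

#' @export
residuals.iv_fit <- function(object, ...) stats::residuals(object$lm)

#' @export
predict.iv_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$lm))
  v <- if (is.data.frame(newdata)) {
    newdata[[object$potential]] %||% newdata$V %||% newdata[[1]]
  } else {
    as.numeric(newdata)
  }
  object$intercept_pA + object$conductance_nS * v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.iv_fit <- function(object, ...) {
  s <- summary(object$lm)
  se <- s$coefficients[, "Std. Error"]
  # delta-method SE for E_rev = -b0/b1
  V <- stats::vcov(object$lm)
  g <- c(-1 / object$conductance_nS,
         object$intercept_pA / object$conductance_nS^2)
  se_e <- sqrt(drop(t(g) %*% V %*% g))
  out <- list(fit = object, lm_summary = s, E_rev_se = se_e,
              intercept_se = unname(se[1]), slope_se = unname(se[2]))
  class(out) <- "summary.iv_fit"
  out
}

#' @export
print.summary.iv_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  E_rev SE (delta method): %.3f mV\n", x$E_rev_se))
  cat(sprintf("  slope SE: %.4f nS, intercept SE: %.3f pA, R^2 = %.4f\n",
              x$slope_se, x$intercept_se, x$lm_summary$r.squared))
  invisible(x)
}

#' @export
confint.iv_fit <- function(object, parm = "E_rev", level = 0.95, ...) {
  s <- summary(object)
  z <- stats::qt(1 - (1 - level) / 2, df = stats::df.residual(object$lm))
  est <- c(E_rev = object$E_rev, conductance_nS = object$conductance_nS,
           intercept_pA = object$intercept_pA)
  se <- c(E_rev = s$E_rev_se, conductance_nS = s$slope_se,
          intercept_pA = s$intercept_se)
  parm <- match.arg(parm, names(est), several.ok = TRUE)
  cbind(lower = est[parm] - z * se[parm], upper = est[parm] + z * se[parm])
}

#' @export
plot.iv_fit <- function(x, ...,
                        xlab = sprintf("membrane potential (mV, %s)", x$potential),
                        ylab = "peak current (pA)") {
  graphics::plot(x$data$V, x$data$I, xlab = xlab, ylab = ylab, pch = 19, ...)
  graphics::abline(x$intercept_pA, x$conductance_nS, col = "grey40")
  graphics::abline(h = 0, lty = 3)
  graphics::abline(v = x$E_rev, lty = 2, col = "red3")
  graphics::mtext(sprintf("E_rev = %.1f mV", x$E_rev), side = 3, cex = 0.8)
  invisible(x)
}

#' Intracellular chloride from a fitted reversal potential
#'
#' Combines a reversal-potential fit with the Nernst conversion: the
#' study's headline quantity.
#'
#' @param fit An [fit_reversal()] result, or a numeric `E_GABA` in mV.
#' @param params A [nernst_params()].
#' @return An object of class `"chloride_estimate"`: list with `E_GABA`
#'   (mV), `Cl_in` (mM), `params`, and `diagnostics` (residual RMS and
#'   extrapolation flag when a fit was supplied).
#' @examples
#' est <- estimate_chloride(-70.7, nernst_params(132.5))
#' est$Cl_in  # ~8.8 mM
#' @export
estimate_chloride <- function(fit, params) {
  stopifnot(inherits(params, "nernst_params"))
  if (inherits(fit, "iv_fit")) {
    e <- fit$E_rev
    diag <- list(residual_rms_pA = fit$residual_rms_pA,
                 extrapolated = fit$extrapolated,
                 n_points = nrow(fit$data),
                 span_mV = range(fit$data$V))
  } else {
    e <- as.numeric(fit)
    diag <- list()
  }
  cl <- chloride_from_nernst(e, params)
  structure(list(E_GABA = e, Cl_in = cl, params = params,
                 diagnostics = diag),
            class = "chloride_estimate")
}

#' @export
print.chloride_estimate <- function(x, ...) {
  cat(sprintf("E_GABA = %.2f mV  ->  [Cl-]i = %.2f mM", x$E_GABA, x$Cl_in))
  cat(sprintf("  ([Cl-]o = %.1f mM, T = %.2f K)\n",
              x$params$Cl_out, x$params$temperature))
  if (length(x$diagnostics)) {
    cat(sprintf("  fit: %d points, residual RMS %.3f pA%s\n",
                x$diagnostics$n_points, x$diagnostics$residual_rms_pA,
                if (isTRUE(x$diagnostics$extrapolated)) ", extrapolated" else ""))
  }
  invisible(x)
}
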