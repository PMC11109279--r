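#' @export
coef.her_fit <- function(object, ...) {
  unlist(object$params[vapply(object$params, is.numeric, logical(1))])
}

#' @export
residuals.her_fit <- function(object, ...) object$residuals

#' @export
fitted.her_fit <- function(object, ...) object$fitted

#' @export
print.her_fit <- function(x, digits = 4, ...) {
  cat("Model:", x$model, "\n")
  cat("Parameters:\n")
  print(signif(coef(x), digits))
  cat(sprintf("Residual sum of squares: %.4g on %d observations\n",
              x$rss, length(x$observed)))
  invisible(x)
}

#' @export
summary.her_fit <- function(object, ...) {
  out <- list(model = object$model, coef = coef(object), rss = object$rss,
              n = length(object$observed),
              sigma = sqrt(object$rss /
                             max(length(object$observed) -
                                   length(coef(object)), 1)))
  class(out) <- "summary.her_fit"
  out
}

#' @export
print.summary.her_fit <- function(x, digits = 4, ...) {
  cat("Model:", x$model, "\n")
  print(signif(x$coef, digits))
  cat(sprintf("n = %d, RSS = %.4g, residual sigma = %.4g\n",
              x$n, x$rss, x$sigma))
  invisible(x)
}

#' Predict from a fitted curve model
#'
#' For kinetic fits, \code{newdata} is a data.frame with the fit's predictor
#' column(s) (\code{S}, \code{x}, or \code{pH}); for ITC fits, a new
#' \code{titration_experiment}. Without \code{newdata}, returns fitted values.
#'
#' @param object A \code{her_fit}.
#' @param newdata Optional new predictor data.
#' @param ... Unused.
#' @return Predicted values.
#' @export
predict.her_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (inherits(object, "itc_fit")) {
    stopifnot(inherits(newdata, "titration_experiment"))
    return(if (object$model == "one_site")
      one_site_heat_curve(object$params, newdata)
      else sequential_heat_curve(object$params, newdata))
  }
  object$pred_fun(object$params, newdata)
}

#' @export
print.itc_fit <- function(x, digits = 4, ...) {
  cat("ITC binding fit:", x$model, "model\n")
  if (x$model == "one_site") {
    t <- x$thermo
    cat(sprintf("  Kd = %.3g uM  dH = %.3g kcal/mol  -TdS = %.3g  dG = %.3g (T = %.2f K)\n",
                t$Kd * 1e6, t$dH, t$minus_TdS, t$dG, t$temperature))
    cat(sprintf("  n = %.3g sites, q_offset = %.3g ucal\n",
                x$params$n, x$params$q_offset))
  } else {
    for (s in c("site1", "site2")) {
      t <- x$thermo[[s]]
      cat(sprintf("  %s: Kd = %.3g uM  dH = %.3g  -TdS = %.3g  dG = %.3g kcal/mol\n",
                  s, t$Kd * 1e6, t$dH, t$minus_TdS, t$dG))
    }
    cat("  positive cooperativity (Kd2 < Kd1):",
        x$thermo$positive_cooperativity, "\n")
  }
  cat(sprintf("  RSS = %.4g, saturation coverage (max molar ratio) = %.2f%s\n",
              x$rss, x$diagnostics$saturation_coverage,
              if (x$diagnostics$at_bound) "  [parameter at bound]" else ""))
  invisible(x)
}

#' Plot a fitted curve model with its data
#'
#' @param x A \code{her_fit}.
#' @param ... Passed to \code{plot.default}.
#' @export
plot.her_fit <- function(x, ...) {
  if (inherits(x, "itc_fit")) {
    cc <- cell_concentrations(x$expt)
    ratio <- cc$Xt / cc$Mt
    graphics::plot(ratio, x$observed, xlab = "molar ratio",
                   ylab = "injection heat (ucal)", ...)
    graphics::lines(ratio, x$fitted, col = 2)
  } else {
    xx <- x$data[[1]]
    graphics::plot(xx, x$observed, xlab = names(x$data)[1],
                   ylab = names(x$data)[2], ...)
    o <- order(xx)
    graphics::lines(xx[o], x$fitted[o], col = 2)
  }
  invisible(x)
}

#' Simulate noisy responses from a fitted curve model
#'
#' Draws Gaussian noise with the fit's residual standard deviation around the
#' fitted values.
#'
#' @param object A \code{her_fit}.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return data.frame with \code{nsim} columns of simulated responses.
#' @export
simulate.her_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  s <- summary(object)$sigma
  out <- as.data.frame(replicate(nsim, object$fitted +
                                   stats::rnorm(length(object$fitted), 0, s)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
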