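R_KCAL <- 1.9872e-3   # gas constant, kcal mol^-1 K^-1
KCAL_TO_UCAL <- 1e9

#' Construct an ITC titration experiment
#'
#' Titrant-into-cell convention (e.g. OcHeR injected into the Omr protein in
#' the cell). Heats are integrated per-injection heats in microcalories.
#'
#' @param V0 Cell volume (liters).
#' @param Mt0 Initial cell (macromolecule) concentration (molar).
#' @param X_syr Syringe (titrant) concentration (molar).
#' @param injection_volumes Numeric vector of injection volumes (liters).
#' @param observed_heats Optional numeric vector of per-injection heats
#'   (microcal), same length as \code{injection_volumes}.
#' @param temperature Temperature (kelvin, default 298.15).
#' @return \code{titration_experiment} list.
#' @export
titration_experiment <- function(V0, Mt0, X_syr, injection_volumes,
                                 observed_heats = NULL,
                                 temperature = 298.15) {
  stopifnot(V0 > 0, Mt0 > 0, X_syr > 0, all(injection_volumes > 0),
            temperature > 0)
  if (!is.null(observed_heats) &&
      length(observed_heats) != length(injection_volumes))
    stop("observed_heats must match injection_volumes in length")
  structure(list(V0 = V0, Mt0 = Mt0, X_syr = X_syr,
                 injection_volumes = injection_volumes,
                 observed_heats = observed_heats,
                 temperature = temperature),
            class = "titration_experiment")
}

# Post-injection cell concentrations under the displaced-volume convention
# (ITC200-style): the cell keeps constant volume V0 and each injection
# displaces an equal volume of the mixed contents.
cell_concentrations <- function(expt) {
  dv <- cumsum(expt$injection_volumes)
  f <- dv / expt$V0
  Mt <- expt$Mt0 * (1 - f / 2) / (1 + f / 2)
  Xt <- expt$X_syr * f / (1 + f / 2)
  if (any(Mt <= 0) || any(Xt < 0))
    stop("nonphysical concentrations after dilution; injected volume too large")
  list(Mt = Mt, Xt = Xt, dv = dv)
}

# Per-injection heats from cumulative cell heats, with the displaced-volume
# heat correction and per-injection offset (heat of dilution).
injection_heats <- function(Q, expt, q_offset) {
  Qprev <- c(0, Q[-length(Q)])
  dv <- expt$injection_volumes
  Q - Qprev + (dv / expt$V0) * (Q + Qprev) / 2 + q_offset
}

#' Predicted one-site (Wiseman) ITC heat curve
#'
#' Closed-form single-site isotherm: the bound fraction at each post-injection
#' composition solves the quadratic mass balance; the cumulative cell heat is
#' \code{Q = n Mt dH V0 theta} and per-injection heats apply the
#' displaced-volume correction plus a constant dilution offset.
#'
#' @param params List/vector with \code{n} (sites), \code{Ka} (1/M),
#'   \code{dH} (kcal/mol), \code{q_offset} (microcal, default 0).
#' @param expt \code{titration_experiment}.
#' @return Numeric vector of predicted per-injection heats (microcal).
#' @export
one_site_heat_curve <- function(params, expt) {
  p <- lapply(as.list(params), unname)
  if (is.null(p$q_offset)) p$q_offset <- 0
  stopifnot(p$Ka > 0, p$n > 0)
  cc <- cell_concentrations(expt)
  r <- cc$Xt / (p$n * cc$Mt)
  e <- 1 / (p$n * p$Ka * cc$Mt)
  theta <- (1 + r + e - sqrt((1 + r + e)^2 - 4 * r)) / 2
  Q <- p$n * cc$Mt * p$dH * expt$V0 * theta * KCAL_TO_UCAL
  injection_heats(Q, expt, p$q_offset)
}

# Independent route to the one-site heats: solve the mass balance for free
# titrant by bisection at every injection instead of the closed form.
one_site_heat_curve_bisect <- function(params, expt, tol = 1e-15) {
  p <- lapply(as.list(params), unname)
  if (is.null(p$q_offset)) p$q_offset <- 0
  cc <- cell_concentrations(expt)
  Q <- vapply(seq_along(cc$Mt), function(i) {
    Mt <- cc$Mt[i]; Xt <- cc$Xt[i]
    f <- function(X) X + p$n * Mt * p$Ka * X / (1 + p$Ka * X) - Xt
    lo <- 0; hi <- Xt
    for (k in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < tol * max(Xt, 1e-30)) break
    }
    X <- (lo + hi) / 2
    bound <- Xt - X
    bound * p$dH * expt$V0 * KCAL_TO_UCAL
  }, numeric(1))
  injection_heats(Q, expt, p$q_offset)
}

#' Predicted sequential two-site ITC heat curve
#'
#' Two-step sequential binding with stepwise constants: species fractions
#' \code{F1 = K1 X / (1 + K1 X + K1 K2 X^2)} and
#' \code{F2 = K1 K2 X^2 / (1 + K1 X + K1 K2 X^2)} at free titrant X obtained
#' by root-finding the mass balance \code{Xt = X + Mt (F1 + 2 F2)}.
#' Cumulative heat \code{Q = Mt V0 (F1 dH1 + F2 (dH1 + dH2))}, with the same
#' injection differencing as [one_site_heat_curve()].
#'
#' @param params List/vector with \code{K1}, \code{K2} (1/M), \code{dH1},
#'   \code{dH2} (kcal/mol), \code{q_offset} (microcal, default 0).
#' @param expt \code{titration_experiment}.
#' @return Numeric vector of predicted per-injection heats (microcal).
#' @export
sequential_heat_curve <- function(params, expt) {
  p <- lapply(as.list(params), unname)
  if (is.null(p$q_offset)) p$q_offset <- 0
  stopifnot(p$K1 > 0, p$K2 >= 0)
  cc <- cell_concentrations(expt)
  Q <- vapply(seq_along(cc$Mt), function(i) {
    Mt <- cc$Mt[i]; Xt <- cc$Xt[i]
    frac <- function(X) {
      D <- 1 + p$K1 * X + p$K1 * p$K2 * X^2
      c(F1 = p$K1 * X / D, F2 = p$K1 * p$K2 * X^2 / D)
    }
    g <- function(X) {
      fr <- frac(X)
      X + Mt * (fr["F1"] + 2 * fr["F2"]) - Xt
    }
    if (Xt == 0) {
      X <- 0
    } else {
      sol <- tryCatch(
        stats::uniroot(g, c(0, Xt), tol = 1e-18 * max(Xt, 1e-12)),
        error = function(e)
          stop("free-titrant root finding failed at injection ", i, ": ",
               conditionMessage(e)))
      X <- sol$root
    }
    fr <- frac(X)
    Mt * expt$V0 * (fr["F1"] * p$dH1 + fr["F2"] * (p$dH1 + p$dH2)) *
      KCAL_TO_UCAL
  }, numeric(1))
  injection_heats(Q, expt, p$q_offset)
}

#' Gibbs free energy from a dissociation constant
#'
#' \code{dG = R T ln(Kd)} with Kd in molar (1 M standard state) and
#' R = 1.9872e-3 kcal/(mol K); negative for sub-molar Kd.
#'
#' @param Kd Dissociation constant (molar), > 0.
#' @param temperature Kelvin (default 298.15, i.e. 25 C).
#' @return dG in kcal/mol.
#' @export
delta_g_from_kd <- function(Kd, temperature = 298.15) {
  if (any(Kd <= 0)) stop("Kd must be positive")
  R_KCAL * temperature * log(Kd)
}

#' Entropic term from dG and dH
#'
#' \code{-T dS = dG - dH} (kcal/mol).
#'
#' @param dG,dH kcal/mol.
#' @return \code{-T dS} in kcal/mol.
#' @export
entropy_term <- function(dG, dH) dG - dH

#' Fold change between two dissociation constants
#'
#' Ratio \code{kd_a / kd_b}, rounded the way such fold changes are reported:
#' to the nearest integer when >= 10, else to one decimal.
#'
#' @param kd_a,kd_b Positive values in the same unit.
#' @return Rounded fold change.
#' @export
fold_change <- function(kd_a, kd_b) {
  if (any(kd_b == 0)) stop("zero denominator")
  r <- kd_a / kd_b
  ifelse(r >= 10, round(r), round(r, 1))
}

#' Derived binding thermodynamics at temperature T
#'
#' @param Kd Molar dissociation constant.
#' @param dH Binding enthalpy (kcal/mol).
#' @param temperature Kelvin.
#' @return List: Kd, dH, dG, minus_TdS, temperature (dG = dH + minus_TdS).
#' @export
thermo_summary <- function(Kd, dH, temperature = 298.15) {
  dG <- delta_g_from_kd(Kd, temperature)
  list(Kd = Kd, dH = dH, dG = dG, minus_TdS = entropy_term(dG, dH),
       temperature = temperature)
}

itc_start_values <- function(expt, model) {
  heats <- expt$observed_heats
  dv1 <- expt$injection_volumes[1]
  mol1 <- expt$X_syr * dv1                       # mol injected first shot
  dH0 <- heats[1] / (mol1 * KCAL_TO_UCAL)        # assume fully bound
  cc <- cell_concentrations(expt)
  # midpoint heuristic: Ka ~ c/Mt with c = 10 at the curve half-height
  Ka0 <- 10 / expt$Mt0
  if (model == "one_site")
    list(n = 1, Ka = Ka0, dH = dH0, q_offset = 0)
  else
    list(K1 = Ka0, K2 = Ka0, dH1 = dH0, dH2 = dH0 / 2, q_offset = 0)
}

#' Fit an ITC binding model to a titration
#'
#' Nonlinear least squares (Levenberg-Marquardt) on the per-injection heats,
#' under the one-site Wiseman model or the two-step sequential model.
#' Association constants and (for one-site) stoichiometry are fitted on the
#' log scale to enforce positivity. Following the usual calorimetry-software
#' convention, the per-injection dilution offset is held at its configured
#' value (default 0) rather than fitted; set \code{fit_offset = TRUE} to
#' free it. The sequential model uses seeded multi-start (5 starts) with the
#' best residual norm winning. Returns a fitted-model object with the usual
#' methods (\code{print}, \code{summary}, \code{coef}, \code{predict},
#' \code{residuals}, \code{plot}).
#'
#' @param expt \code{titration_experiment} carrying \code{observed_heats}.
#' @param model \code{"one_site"} or \code{"sequential"}.
#' @param init Optional named list of starting values (model parameter scale).
#' @param n_starts Multi-start count for the sequential model (default 5).
#' @param seed Seed for the multi-start perturbations (default 1).
#' @param discard_first Drop the first injection from the fit (common ITC
#'   practice); default FALSE.
#' @param fit_offset Also fit the per-injection dilution offset
#'   (default FALSE).
#' @return Object of class \code{c("itc_fit", "her_fit")} with elements
#'   \code{params} (natural scale), \code{thermo} (thermodynamic summary, one
#'   per site for sequential, plus a \code{positive_cooperativity} flag),
#'   \code{fitted}, \code{residuals}, \code{rss}, \code{diagnostics}
#'   (saturation coverage = max molar ratio reached, bound-hitting flag).
#' @export
fit_binding <- function(expt, model = c("one_site", "sequential"),
                        init = NULL, n_starts = 5L, seed = 1L,
                        discard_first = FALSE, fit_offset = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(expt, "titration_experiment"))
  heats <- expt$observed_heats
  if (is.null(heats)) stop("experiment has no observed heats")
  n_inf <- length(heats) - as.integer(discard_first)
  if (n_inf < 8L) stop("need at least 8 informative injections")
  if (stats::sd(heats) < 1e-10 * (abs(mean(heats)) + 1e-10))
    stop("uninformative titration: heats are flat")
  keep <- if (discard_first) -1L else seq_along(heats)
  y <- heats[keep]

  base_start <- itc_start_values(expt, model)
  if (!is.null(init)) base_start[names(init)] <- init
  fixed_offset <- base_start$q_offset

  predict_fun <- function(theta) {
    qo <- if (fit_offset) theta[["q_offset"]] else fixed_offset
    p <- if (model == "one_site")
      list(n = exp(theta[["log_n"]]), Ka = exp(theta[["log_Ka"]]),
           dH = theta[["dH"]], q_offset = qo)
    else
      list(K1 = exp(theta[["log_K1"]]), K2 = exp(theta[["log_K2"]]),
           dH1 = theta[["dH1"]], dH2 = theta[["dH2"]], q_offset = qo)
    curve <- if (model == "one_site") one_site_heat_curve(p, expt)
             else sequential_heat_curve(p, expt)
    list(params = p, pred = curve[keep])
  }
  to_theta <- function(s) {
    th <- if (model == "one_site")
      c(log_n = log(s$n), log_Ka = log(s$Ka), dH = s$dH)
    else
      c(log_K1 = log(s$K1), log_K2 = log(s$K2), dH1 = s$dH1, dH2 = s$dH2)
    if (fit_offset) th <- c(th, q_offset = s$q_offset)
    th
  }
  lower <- if (model == "one_site")
    c(log_n = log(1e-2), log_Ka = log(1e-1), dH = -1e4)
  else
    c(log_K1 = log(1e-1), log_K2 = log(1e-1), dH1 = -1e4, dH2 = -1e4)
  upper <- if (model == "one_site")
    c(log_n = log(1e2), log_Ka = log(1e12), dH = 1e4)
  else
    c(log_K1 = log(1e12), log_K2 = log(1e12), dH1 = 1e4, dH2 = 1e4)
  if (fit_offset) {
    lower <- c(lower, q_offset = -1e6)
    upper <- c(upper, q_offset = 1e6)
  }

  starts <- list(to_theta(base_start))
  if (model == "sequential" && n_starts > 1L) {
    k_scale <- c(2, 2, rep(0.5 * abs(starts[[1]][[3]]) + 1,
                           length(starts[[1]]) - 2))
    rng <- local({ set.seed(seed); lapply(seq_len(n_starts - 1L), function(k)
      stats::rnorm(length(starts[[1]]), 0, 1)) })
    starts <- c(starts, lapply(rng, function(z) {
      th <- starts[[1]] + z * k_scale
      pmin(pmax(th, lower), upper)
    }))
  }

  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = th0,
        fn = function(theta) {
          names(theta) <- names(th0)
          pr <- tryCatch(predict_fun(theta)$pred,
                         error = function(e) rep(1e6, length(y)))
          y - pr
        },
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("all optimization starts failed")
  theta <- best$fit$par
  names(theta) <- names(starts[[1]])
  res <- predict_fun(theta)
  p <- lapply(res$params, unname)

  at_bound <- any(abs(theta - lower) < 1e-6) || any(abs(theta - upper) < 1e-6)
  cc <- cell_concentrations(expt)
  sat <- max(cc$Xt / cc$Mt)

  thermo <- if (model == "one_site") {
    thermo_summary(1 / p$Ka, p$dH, expt$temperature)
  } else {
    s <- list(site1 = thermo_summary(1 / p$K1, p$dH1, expt$temperature),
              site2 = thermo_summary(1 / p$K2, p$dH2, expt$temperature))
    s$positive_cooperativity <- s$site2$Kd < s$site1$Kd
    s
  }
  full_pred <- if (model == "one_site") one_site_heat_curve(p, expt)
               else sequential_heat_curve(p, expt)
  structure(list(
    model = model, params = p, thermo = thermo,
    fitted = full_pred, observed = heats,
    residuals = heats - full_pred, rss = best$rss,
    diagnostics = list(saturation_coverage = sat, at_bound = at_bound,
                       n_injections = length(heats),
                       discard_first = discard_first),
    expt = expt,
    call = match.call()
  ), class = c("itc_fit", "her_fit"))
}
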