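#' Michaelis-Menten rate
#'
#' \code{v = Vmax S / (Km + S)}. Units follow the inputs; the package
#' convention is Vmax in uM/min and Km in mM with S in mM.
#'
#' @param S Substrate concentration(s), >= 0.
#' @param Vmax Maximal rate.
#' @param Km Michaelis constant (same unit as S).
#' @return Rate(s).
#' @export
mm_rate <- function(S, Vmax, Km) {
  stopifnot(all(S >= 0))
  Vmax * S / (Km + S)
}

#' Turnover number from Vmax and enzyme concentration
#'
#' \code{kcat = (Vmax / E_total) / 60} converting per-minute rates to s^-1;
#' with Vmax in uM/min and E_total in uM this is the Table-style kcat (s^-1).
#'
#' @param Vmax Maximal rate (uM/min).
#' @param E_total Enzyme concentration (uM), > 0.
#' @return kcat in s^-1.
#' @export
kcat <- function(Vmax, E_total) {
  if (any(E_total <= 0)) stop("E_total must be positive")
  (Vmax / E_total) / 60
}

#' Specificity constant kcat/Km
#'
#' @param kcat_val kcat (s^-1).
#' @param Km_mM Km in millimolar, > 0.
#' @return kcat/Km in M^-1 s^-1.
#' @export
specificity_constant <- function(kcat_val, Km_mM) {
  stopifnot(all(Km_mM > 0))
  kcat_val / (Km_mM * 1e-3)
}

# Levenberg-Marquardt least squares on an explicit prediction function;
# avoids nls model-frame construction, which fails on zero-residual data.
lm_curve_fit <- function(pred_fun, start, y, lower = NULL, upper = NULL) {
  fit <- minpack.lm::nls.lm(
    par = unlist(start),
    fn = function(par) y - pred_fun(as.list(par)),
    lower = if (is.null(lower)) rep(-Inf, length(start)) else unlist(lower),
    upper = if (is.null(upper)) rep(Inf, length(start)) else unlist(upper),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  par <- as.list(fit$par)
  list(par = par, fitted = pred_fun(par), rss = sum(fit$fvec^2))
}

#' Fit the Michaelis-Menten equation to initial rates
#'
#' Least-squares fit of \code{v = Vmax S / (Km + S)}; attaches kcat and
#' kcat/Km derived from the enzyme concentration. When replicate parameter
#' sets are supplied later, [specificity_report()] gives both the
#' ratio-of-means and mean-of-ratios conventions.
#'
#' @param S Substrate concentrations (mM), >= 4 distinct values.
#' @param v Initial rates (uM/min).
#' @param E_total Enzyme concentration (uM, default 1).
#' @return \code{c("mm_fit", "her_fit")} with \code{params} (Vmax, Km, kcat,
#'   kcat_over_Km), fitted values and residuals.
#' @export
fit_mm <- function(S, v, E_total = 1) {
  stopifnot(length(S) == length(v))
  if (length(unique(S)) < 4L) stop("need >= 4 distinct substrate levels")
  if (stats::sd(v) < 1e-12 * (abs(mean(v)) + 1e-12))
    stop("rates are flat; cannot fit")
  Vmax0 <- max(v) * 1.2
  Km0 <- S[which.min(abs(v - max(v) / 2))]
  if (Km0 <= 0) Km0 <- stats::median(S[S > 0])
  pred <- function(p, S_new = S) mm_rate(S_new, p$Vmax, p$Km)
  fit <- lm_curve_fit(pred, list(Vmax = Vmax0, Km = Km0), v,
                      lower = list(Vmax = 1e-12, Km = 1e-12))
  params <- list(Vmax = fit$par$Vmax, Km = fit$par$Km,
                 kcat = kcat(fit$par$Vmax, E_total),
                 kcat_over_Km = specificity_constant(
                   kcat(fit$par$Vmax, E_total), fit$par$Km))
  structure(list(model = "michaelis_menten", params = params,
                 fitted = fit$fitted, observed = v,
                 residuals = v - fit$fitted, rss = fit$rss,
                 data = data.frame(S = S, v = v), E_total = E_total,
                 pred_fun = function(p, newdata) pred(p, newdata$S),
                 call = match.call()),
            class = c("mm_fit", "her_fit"))
}

#' Specificity constants under both averaging conventions
#'
#' Enzyme-kinetics tables built from replicate fits often report the mean of
#' per-replicate kcat/Km ratios, which differs from the ratio computed from
#' mean kcat and mean Km. Given per-replicate (kcat, Km) pairs this reports
#' both, labeled.
#'
#' @param kcat_vals Per-replicate kcat values (s^-1).
#' @param Km_vals Per-replicate Km values (mM).
#' @return List: \code{mean_of_ratios}, \code{ratio_of_means}.
#' @export
specificity_report <- function(kcat_vals, Km_vals) {
  stopifnot(length(kcat_vals) == length(Km_vals))
  list(mean_of_ratios = mean(specificity_constant(kcat_vals, Km_vals)),
       ratio_of_means = specificity_constant(mean(kcat_vals), mean(Km_vals)))
}

#' Four-parameter logistic dose-response value
#'
#' \code{y = A1 + (A2 - A1) / (1 + 10^((Logx0 - x) p))} with x a log10
#' concentration: A1 bottom, A2 top, Logx0 center, p hill slope.
#'
#' @param x log10 concentration(s).
#' @param A1,A2,Logx0,p Curve parameters (p != 0).
#' @return Response value(s).
#' @export
dose_response <- function(x, A1, A2, Logx0, p) {
  stopifnot(p != 0)
  A1 + (A2 - A1) / (1 + 10^((Logx0 - x) * p))
}

#' IC50 from dose-response parameters
#'
#' \code{IC50 = 10^Logx0}, in the concentration unit of the x axis.
#'
#' @param Logx0 Curve center (log10 concentration).
#' @return IC50 concentration.
#' @export
ic50 <- function(Logx0) 10^Logx0

#' Fit a four-parameter logistic dose-response curve
#'
#' @param x log10 concentrations (>= 4 points).
#' @param y Responses.
#' @param hill_sign Expected sign of the hill slope used to seed the fit
#'   (default taken from the data trend).
#' @return \code{c("drc_fit", "her_fit")} with \code{params} (A1, A2, Logx0,
#'   p, IC50).
#' @export
fit_dose_response <- function(x, y, hill_sign = NULL) {
  stopifnot(length(x) == length(y), length(unique(x)) >= 4L)
  if (stats::sd(y) < 1e-12 * (abs(mean(y)) + 1e-12))
    stop("responses are flat; cannot fit")
  if (is.null(hill_sign))
    hill_sign <- if (stats::cor(x, y) >= 0) 1 else -1
  start <- list(A1 = min(y), A2 = max(y),
                Logx0 = x[which.min(abs(y - (min(y) + max(y)) / 2))],
                p = hill_sign)
  pred <- function(p, x_new = x)
    dose_response(x_new, p$A1, p$A2, p$Logx0, p$p)
  fit <- lm_curve_fit(pred, start, y)
  est <- fit$par
  est$IC50 <- ic50(est$Logx0)
  structure(list(model = "dose_response_4pl", params = est,
                 fitted = fit$fitted, observed = y,
                 residuals = y - fit$fitted, rss = fit$rss,
                 data = data.frame(x = x, y = y),
                 pred_fun = function(p, newdata) pred(p, newdata$x),
                 call = match.call()),
            class = c("drc_fit", "her_fit"))
}

#' Single-exponential decay value
#'
#' \code{y = y0 + A1 exp(-x / t1)}.
#'
#' @param x Time(s).
#' @param y0 Offset.
#' @param A1 Amplitude.
#' @param t1 Time constant (> 0), same unit as x.
#' @return Value(s).
#' @export
exp_decay <- function(x, y0, A1, t1) {
  stopifnot(t1 > 0)
  y0 + A1 * exp(-x / t1)
}

#' Half-life from an exponential time constant
#'
#' \code{t_half = t1 ln 2}.
#'
#' @param t1 Time constant (> 0).
#' @return Half-life, same unit.
#' @export
half_life <- function(t1) {
  stopifnot(all(t1 > 0))
  t1 * log(2)
}

#' Fit a single-exponential decay
#'
#' @param x Times.
#' @param y Signal.
#' @return \code{c("decay_fit", "her_fit")} with \code{params} (y0, A1, t1,
#'   t_half).
#' @export
fit_decay <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4L)
  if (stats::sd(y) < 1e-12 * (abs(mean(y)) + 1e-12))
    stop("signal is flat; cannot fit")
  y0_0 <- min(y)
  A1_0 <- y[which.min(x)] - y0_0
  if (A1_0 == 0) A1_0 <- diff(range(y))
  t1_0 <- max(diff(range(x)) / 3, .Machine$double.eps)
  pred <- function(p, x_new = x) exp_decay(x_new, p$y0, p$A1, p$t1)
  fit <- lm_curve_fit(pred, list(y0 = y0_0, A1 = A1_0, t1 = t1_0), y,
                      lower = list(y0 = -Inf, A1 = -Inf, t1 = 1e-12))
  est <- fit$par
  est$t_half <- half_life(est$t1)
  structure(list(model = "exp_decay", params = est,
                 fitted = fit$fitted, observed = y,
                 residuals = y - fit$fitted, rss = fit$rss,
                 data = data.frame(x = x, y = y),
                 pred_fun = function(p, newdata) pred(p, newdata$x),
                 call = match.call()),
            class = c("decay_fit", "her_fit"))
}

#' Henderson-Hasselbalch pKa from a pH titration
#'
#' Fits the single-site titration sigmoid
#' \code{y = S_acid + (S_base - S_acid) / (1 + 10^(pKa - pH))} (the
#' deprotonated fraction follows Henderson-Hasselbalch); the signal is
#' half-maximal at pH = pKa.
#'
#' @param pH pH values (>= 4 points spanning the transition).
#' @param signal Observed signal (e.g. absorbance shift).
#' @return \code{c("pka_fit", "her_fit")} with \code{params} (S_acid, S_base,
#'   pKa).
#' @export
fit_pka <- function(pH, signal) {
  stopifnot(length(pH) == length(signal), length(unique(pH)) >= 4L)
  if (stats::sd(signal) < 1e-12 * (abs(mean(signal)) + 1e-12))
    stop("signal is flat across pH; cannot fit")
  start <- list(S_acid = signal[which.min(pH)],
                S_base = signal[which.max(pH)],
                pKa = pH[which.min(abs(signal - mean(range(signal))))])
  pred <- function(p, pH_new = pH)
    p$S_acid + (p$S_base - p$S_acid) / (1 + 10^(p$pKa - pH_new))
  fit <- lm_curve_fit(pred, start, signal)
  structure(list(model = "henderson_hasselbalch", params = fit$par,
                 fitted = fit$fitted, observed = signal,
                 residuals = signal - fit$fitted, rss = fit$rss,
                 data = data.frame(pH = pH, signal = signal),
                 pred_fun = function(p, newdata) pred(p, newdata$pH),
                 call = match.call()),
            class = c("pka_fit", "her_fit"))
}

#' Fit an inorganic-phosphate calibration line
#'
#' Linear calibration of A355 absorbance (phosphomolybdate assay) against
#' known Pi standards.
#'
#' @param Pi_uM Standard concentrations (uM), >= 3.
#' @param A355 Absorbances.
#' @return List with \code{slope}, \code{intercept}, \code{range} of
#'   calibrated absorbances.
#' @export
fit_pi_calibration <- function(Pi_uM, A355) {
  stopifnot(length(Pi_uM) == length(A355), length(Pi_uM) >= 3L)
  co <- stats::coef(stats::lm(A355 ~ Pi_uM))
  if (co[2] <= 0) stop("calibration slope must be positive")
  list(slope = unname(co[2]), intercept = unname(co[1]),
       range = range(A355))
}

#' Invert an absorbance to a Pi concentration
#'
#' @param A355 Absorbance(s) at 355 nm.
#' @param calibration From [fit_pi_calibration()].
#' @return Pi concentration(s) in uM; warns outside the calibrated range.
#' @export
pi_from_absorbance <- function(A355, calibration) {
  if (any(A355 < calibration$range[1] | A355 > calibration$range[2]))
    warning("absorbance outside the calibrated range; extrapolating")
  (A355 - calibration$intercept) / calibration$slope
}

#' MIC80 from a growth-vs-concentration table
#'
#' The MIC80 is the lowest drug concentration at which growth is inhibited by
#' at least 80% of the no-drug control, i.e. growth <= 20% of control.
#'
#' @param concentration Drug concentrations; must include 0 (control).
#' @param growth OD-based growth values, same length.
#' @return List: \code{mic} (numeric, or NA when unreached) and
#'   \code{label} (e.g. \code{"2"} or \code{"> 4"}).
#' @export
mic80 <- function(concentration, growth) {
  stopifnot(length(concentration) == length(growth))
  if (!any(concentration == 0)) stop("growth table needs a no-drug control")
  control <- growth[concentration == 0][1]
  if (control <= 0) stop("control growth must be positive")
  frac <- growth / control
  cand <- concentration[concentration > 0 & frac <= 0.2]
  if (!length(cand))
    return(list(mic = NA_real_,
                label = paste(">", max(concentration))))
  list(mic = min(cand), label = as.character(min(cand)))
}

#' Normalize a fluorescence (RFU) trace to its initial recording
#'
#' \code{normalized(t) = RFU(t) / RFU(0)};
#' \code{delta(t) = normalized(t) - normalized(0)}, so delta(0) = 0 and a
#' later delta is the change relative to the initial recording.
#'
#' @param time Time points, including 0.
#' @param rfu Fluorescence values; RFU at time 0 must be nonzero.
#' @return data.frame: time, rfu, normalized, delta.
#' @export
normalize_rfu <- function(time, rfu) {
  stopifnot(length(time) == length(rfu))
  i0 <- which(time == 0)
  if (!length(i0)) stop("trace has no value at time 0")
  r0 <- rfu[i0[1]]
  if (r0 == 0) stop("RFU at time 0 is zero; cannot normalize")
  normalized <- rfu / r0
  data.frame(time = time, rfu = rfu, normalized = normalized,
             delta = normalized - normalized[i0[1]])
}
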