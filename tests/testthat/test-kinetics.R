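test_that("Michaelis-Menten rate has the right anchor points", {
  expect_equal(mm_rate(19.2, 17.6, 19.2), 8.8)
  expect_equal(mm_rate(0, 17.6, 19.2), 0)
  S <- seq(0, 200, by = 5)
  v <- mm_rate(S, 17.6, 19.2)
  expect_true(all(diff(v) > 0))
  expect_true(all(v < 17.6))
})

test_that("kcat and specificity constants follow the unit conventions", {
  expect_equal(round(kcat(17.6, 1), 3), 0.293)
  expect_equal(round(kcat(18.2, 1), 3), 0.303)
  expect_equal(kcat(60, 1), 1.0)
  expect_error(kcat(10, 0), "positive")

  expect_equal(specificity_constant(0.293, 19.2), 15.3, tolerance = 0.005)
  expect_equal(specificity_constant(1, 1000), 1.0)
  expect_equal(fold_change(20.6, 3.7), 5.6)
})

test_that("published kcat values follow from printed Vmax at 1 uM enzyme", {
  tab <- read_kinetics_table()
  expect_true(all(abs(kcat(tab$Vmax, 1) - tab$kcat) <= 0.002))
})

test_that("specificity report distinguishes the two averaging conventions", {
  k <- c(0.25, 0.30, 0.33); km <- c(25, 15, 18)
  rep <- specificity_report(k, km)
  expect_equal(rep$mean_of_ratios,
               mean(k / (km * 1e-3)))
  expect_equal(rep$ratio_of_means, mean(k) / (mean(km) * 1e-3))
  expect_false(isTRUE(all.equal(rep$mean_of_ratios, rep$ratio_of_means)))
})

test_that("noiseless Michaelis-Menten data are recovered exactly", {
  d <- generate_kinetics("mm", list(Vmax = 17.6, Km = 19.2), noise_sd = 0)
  fit <- fit_mm(d$S, d$v)
  expect_equal(fit$params$Vmax, 17.6, tolerance = 1e-6)
  expect_equal(fit$params$Km, 19.2, tolerance = 1e-6)
  expect_equal(fit$params$kcat, kcat(17.6, 1), tolerance = 1e-6)
  expect_error(fit_mm(c(5, 5, 5, 5), c(1, 1.1, 0.9, 1)), "distinct")
  expect_error(fit_mm(c(1, 2, 4, 8), rep(2, 4)), "flat")
})

test_that("Vmax survives 5% noise across seeds", {
  errs <- vapply(1:50, function(s) {
    d <- generate_kinetics("mm", list(Vmax = 17.6, Km = 19.2),
                           noise_sd = 0.05, seed = s)
    abs(fit_mm(d$S, d$v)$params$Vmax - 17.6) / 17.6
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})

test_that("dose-response midpoint and IC50 identities hold", {
  expect_equal(dose_response(x = 1.5, A1 = 0.2, A2 = 0.9, Logx0 = 1.5,
                             p = -1.3), (0.2 + 0.9) / 2)
  expect_equal(ic50(0), 1)
  expect_equal(ic50(log10(47.4)), 47.4)
  # shifting x and the center together leaves the curve unchanged
  x <- seq(-2, 2, by = 0.5)
  y1 <- dose_response(x, 0, 1, 0.3, -1)
  y2 <- dose_response(x + 5, 0, 1, 5.3, -1)
  expect_equal(y1, y2)
})

test_that("a planted IC50 is recovered from noiseless 4PL data", {
  d <- generate_kinetics("dose_response",
                         list(A1 = 0.05, A2 = 1, Logx0 = log10(47.4),
                              p = -1), noise_sd = 0)
  fit <- fit_dose_response(d$x, d$y)
  expect_equal(fit$params$IC50, 47.4, tolerance = 1e-5)
})

test_that("exponential decay half-life identities hold", {
  expect_equal(round(half_life(1), 4), 0.6931)
  expect_equal(exp_decay(0, y0 = 0.2, A1 = 1.3, t1 = 4), 1.5)
  expect_equal(half_life(2 * 3.7), 2 * half_life(3.7))
})

test_that("half-life survives noise across seeds", {
  t1 <- 2.5
  errs <- vapply(1:50, function(s) {
    d <- generate_kinetics("decay", list(y0 = 0.1, A1 = 1, t1 = t1),
                           noise_sd = 0.05, seed = s)
    abs(fit_decay(d$t, d$y)$params$t_half - half_life(t1)) / half_life(t1)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})

test_that("pKa fits hit planted acidic and alkaline transitions", {
  da <- generate_kinetics("pka", list(S_acid = 1, S_base = 0, pKa = 2.9),
                          noise_sd = 0)
  expect_equal(fit_pka(da$pH, da$signal)$params$pKa, 2.9, tolerance = 1e-6)
  db <- generate_kinetics("pka", list(S_acid = 0, S_base = 1, pKa = 11.4),
                          noise_sd = 0)
  expect_equal(fit_pka(db$pH, db$signal)$params$pKa, 11.4, tolerance = 1e-6)
  # signal is half-maximal at pH = pKa
  fit <- fit_pka(da$pH, da$signal)
  mid <- predict(fit, data.frame(pH = 2.9))
  expect_equal(mid, (fit$params$S_acid + fit$params$S_base) / 2,
               tolerance = 1e-6)
  expect_error(fit_pka(c(2, 3, 4, 5), rep(1, 4)), "flat")
})

test_that("Pi calibration inverts absorbances linearly", {
  cal <- fit_pi_calibration(c(0, 50, 100, 200), c(0.05, 0.3, 0.55, 1.05))
  # the fitted intercept can sit just below the lowest standard, which
  # rightly triggers the extrapolation warning
  expect_equal(suppressWarnings(pi_from_absorbance(cal$intercept, cal)), 0,
               tolerance = 1e-8)
  expect_equal(pi_from_absorbance(cal$intercept + cal$slope * 75, cal), 75,
               tolerance = 1e-8)
  expect_warning(pi_from_absorbance(99, cal), "outside")
  expect_error(fit_pi_calibration(c(0, 100, 200), c(1, 0.5, 0.1)),
               "positive")
})

test_that("MIC80 picks the lowest concentration at >= 80% inhibition", {
  r <- mic80(c(0, 1, 2, 4), c(1.0, 0.9, 0.15, 0.05))
  expect_equal(r$mic, 2)
  high <- mic80(c(0, 1, 2, 4), c(1.0, 0.9, 0.8, 0.5))
  expect_true(is.na(high$mic))
  expect_identical(high$label, "> 4")
  expect_error(mic80(c(1, 2), c(1, 0.1)), "control")
})

test_that("RFU normalization and delta values behave", {
  const <- normalize_rfu(c(0, 5, 10), c(80, 80, 80))
  expect_equal(const$normalized, rep(1, 3))
  expect_equal(const$delta, rep(0, 3))
  tr <- normalize_rfu(c(0, 5), c(100, 90))
  expect_equal(tr$normalized, c(1.0, 0.9))
  expect_equal(tr$delta[2], -0.1)
  expect_error(normalize_rfu(c(0, 5), c(0, 90)), "zero")
  expect_error(normalize_rfu(c(1, 5), c(10, 90)), "time 0")
})

test_that("a planted linear RFU drift shows up in the delta trace", {
  time <- seq(0, 15, by = 1)
  slope <- 0.02                       # per-minute fractional gain
  rfu <- 100 * (1 + slope * time)
  tr <- normalize_rfu(time, rfu)
  expect_equal(tr$delta[tr$time == 15], slope * 15, tolerance = 1e-12)
})
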