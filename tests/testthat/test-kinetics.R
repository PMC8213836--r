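test_that("simulated traces follow the 1:1 Langmuir closed forms", {
  tr <- simulate_trace(1e5, 1e-3, conc = 20e-9, seed = 1)
  p <- attr(tr, "params")
  expect_equal(p$k_obs, 3e-3) # k_on * c + k_off
  expect_equal(p$K_D, 1e-8)
  expect_equal(p$Y_eq, 20e-9 / (20e-9 + 1e-8))
  # noiseless association approaches the plateau c / (c + K_D)
  long <- simulate_trace(1e5, 1e-3, t_assoc = 1e5, n_points = 50)
  expect_equal(tail(long$association$signal, 1), 20e-9 / (20e-9 + 1e-8),
               tolerance = 1e-9)
  # dissociation starts where association ended
  expect_equal(tr$dissociation$signal[1],
               p$Y_eq * (1 - exp(-3e-3 * 300)),
               tolerance = 1e-6)
})

test_that("zero off-rate gives a flat dissociation trace", {
  tr <- simulate_trace(1e5, 0, t_assoc = 1e5)
  expect_equal(diff(range(tr$dissociation$signal)), 0)
  fit <- fit_dissociation(tr)
  expect_true(isTRUE(fit$degenerate))
  expect_equal(fit$k_off, 0)
})

test_that("same seed reproduces the noisy trace exactly", {
  t1 <- simulate_trace(1e5, 1e-3, noise_sd = 0.01, seed = 7)
  t2 <- simulate_trace(1e5, 1e-3, noise_sd = 0.01, seed = 7)
  expect_identical(t1$association$signal, t2$association$signal)
  expect_identical(t1$dissociation$signal, t2$dissociation$signal)
})

test_that("noiseless monophasic dissociation is recovered to numerical precision", {
  tr <- simulate_trace(1e5, 1e-3)
  fit <- fit_dissociation(tr)
  expect_true(fit$converged)
  expect_equal(fit$rates[1], 1e-3, tolerance = 1e-6)
  expect_equal(fit$k_off, 1e-3, tolerance = 1e-6)
})

test_that("noiseless biphasic dissociation recovers both rates", {
  t <- seq(0, 30000, length.out = 500)
  y <- 0.5 * exp(-1e-2 * t) + 0.5 * exp(-1e-4 * t)
  set.seed(1) # restarts draw jitter from the session RNG
  fit <- fit_dissociation(data.frame(time_s = t, signal = y), n_phases = 2)
  expect_true(fit$converged)
  expect_equal(fit$rates[1], 1e-2, tolerance = 1e-3)
  expect_equal(fit$rates[2], 1e-4, tolerance = 1e-3)
  expect_equal(fit$amplitudes, c(0.5, 0.5), tolerance = 1e-3)
})

test_that("noiseless round trip recovers k_on, k_off and K_D", {
  tr <- simulate_trace(1e5, 1e-3, conc = 20e-9)
  diss <- fit_dissociation(tr)
  assoc <- fit_association(tr, diss$k_off)
  expect_false(assoc$invalid_kinetics)
  expect_equal(assoc$k_on, 1e5, tolerance = 1e-3)
  expect_equal(assoc$K_D, 1e-8, tolerance = 1e-3)
  # K_D = k_off / k_on holds by construction
  expect_equal(assoc$K_D, assoc$k_off / assoc$k_on)
})

test_that("an observed rate at or below k_off is flagged as invalid kinetics", {
  tr <- simulate_trace(1e5, 1e-3)
  assoc <- fit_association(tr, k_off = 0.1) # far above k_obs = 3e-3
  expect_true(assoc$invalid_kinetics)
  expect_true(is.na(assoc$k_on))
  expect_true(is.na(assoc$K_D))
})

test_that("model selection prefers the generating model and breaks ties by parsimony", {
  set.seed(2)
  # monophasic truth, mild noise -> mono chosen
  tr <- simulate_trace(1e5, 1e-3, noise_sd = 0.005, seed = 21)
  mono <- fit_dissociation(tr, 1)
  bi <- fit_dissociation(tr, 2)
  expect_equal(select_model(mono, bi)$n_phases, 1L)
  # well-separated biphasic truth -> biphasic chosen
  t <- seq(0, 30000, length.out = 500)
  y <- 0.5 * exp(-1e-2 * t) + 0.5 * exp(-1e-4 * t) + rnorm(500, sd = 0.002)
  d <- data.frame(time_s = t, signal = y)
  expect_equal(select_model(fit_dissociation(d, 1), fit_dissociation(d, 2))$n_phases,
               2L)
  # exact tie -> the simpler model
  a <- structure(list(n_phases = 1L, aicc = -100, converged = TRUE),
                 class = "kinetic_fit")
  b <- structure(list(n_phases = 2L, aicc = -100, converged = TRUE),
                 class = "kinetic_fit")
  expect_identical(select_model(a, b), a)
})

test_that("residuals of a correctly specified fit are mean-zero and uncorrelated", {
  tr <- simulate_trace(1e5, 1e-3, noise_sd = 0.01, seed = 31)
  fit <- fit_dissociation(tr)
  expect_lt(abs(mean(fit$residuals)), 3 * 0.01 / sqrt(length(fit$residuals)))
  lb <- Box.test(fit$residuals, lag = 10, type = "Ljung-Box")
  expect_gt(lb$p.value, 0.01)
})

test_that("the full pipeline and the CSV dialect round-trip", {
  tr <- simulate_trace(1e5, 1e-3, noise_sd = 0.005, seed = 41)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  df <- read_trace(path)
  expect_setequal(unique(df$phase), c("association", "dissociation"))
  set.seed(4)
  fit <- fit_kinetics(df)
  expect_equal(fit$k_on, 1e5, tolerance = 0.1)
  expect_equal(fit$k_off, 1e-3, tolerance = 0.1)
  expect_equal(fit$K_D, fit$k_off / fit$k_on)
})

test_that("invalid trace parameters are rejected", {
  expect_error(simulate_trace(-1, 1e-3), "positive")
  expect_error(simulate_trace(1e5, -1e-3), "non-negative")
  expect_error(simulate_trace(1e5, 1e-3, conc = 0), "positive")
  expect_error(fit_dissociation(data.frame(time_s = 1:5, signal = 1:5)),
               ">= 10")
})
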