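#' Simulate a biosensor binding trace (association + dissociation)
#'
#' Generates normalized fluorescence-proximity traces for a 1:1 Langmuir
#' binding model: during association the signal follows
#' `y(t) = Y_eq * (1 - exp(-k_obs * t))` with observed rate
#' `k_obs = k_on * c + k_off` and plateau `Y_eq = c / (c + K_D)`; during
#' dissociation the signal decays from the association end level as
#' `y(t) = y_end * exp(-k_off * t)`. Additive i.i.d. Gaussian noise of the
#' stated standard deviation emulates instrument noise.
#'
#' @param k_on Association rate constant in 1/(M s).
#' @param k_off Dissociation rate constant in 1/s (0 allowed: no decay).
#' @param conc Analyte concentration in M (default 20 nM).
#' @param t_assoc Association duration in s (default 300, i.e. 5 min).
#' @param t_diss Dissociation duration in s (default 3600, i.e. 60 min).
#' @param n_points Samples per phase (default 300).
#' @param noise_sd Gaussian noise standard deviation in signal units
#'   (default 0: noiseless).
#' @param seed Integer seed, or `NULL` to use the session RNG.
#' @return A list of class `kinetic_trace_pair` with elements
#'   `association` and `dissociation`, each a data frame
#'   `time_s, signal, phase, concentration_M` (dissociation time counted
#'   from the start of dissociation). True parameters are kept in the
#'   `"params"` attribute.
#' @examples
#' tr <- simulate_trace(1e5, 1e-3, seed = 1)
#' head(tr$association)
#' @export
simulate_trace <- function(k_on, k_off, conc = 20e-9, t_assoc = 300,
                           t_diss = 3600, n_points = 300, noise_sd = 0,
                           seed = NULL) {
  if (!is.finite(k_on) || k_on <= 0 || !is.finite(k_off) || k_off < 0 ||
      !is.finite(conc) || conc <= 0) {
    stop_invalid("k_on and conc must be positive, k_off non-negative")
  }
  if (t_assoc <= 0 || t_diss <= 0 || n_points < 2 || noise_sd < 0) {
    stop_invalid("durations must be positive, n_points >= 2, noise_sd >= 0")
  }
  k_obs <- k_on * conc + k_off
  K_D <- k_off / k_on
  Y_eq <- conc / (conc + K_D)
  t_a <- seq(0, t_assoc, length.out = n_points)
  t_d <- seq(0, t_diss, length.out = n_points)
  y_a <- Y_eq * (1 - exp(-k_obs * t_a))
  y_end <- Y_eq * (1 - exp(-k_obs * t_assoc))
  y_d <- y_end * exp(-k_off * t_d)
  noise <- with_seed(seed, rnorm(2 * n_points, sd = noise_sd))
  assoc <- data.frame(time_s = t_a, signal = y_a + noise[seq_len(n_points)],
                      phase = "association", concentration_M = conc)
  diss <- data.frame(time_s = t_d, signal = y_d + noise[n_points + seq_len(n_points)],
                     phase = "dissociation", concentration_M = conc)
  structure(
    list(association = assoc, dissociation = diss),
    params = list(k_on = k_on, k_off = k_off, conc = conc, k_obs = k_obs,
                  K_D = K_D, Y_eq = Y_eq, noise_sd = noise_sd, seed = seed),
    class = "kinetic_trace_pair"
  )
}

#' Read / write binding traces in the package CSV dialect
#'
#' Columns `time_s,signal,phase,concentration_M`; `phase` is
#' `"association"` or `"dissociation"`.
#'
#' @param trace A data frame in the trace dialect, or a
#'   `kinetic_trace_pair` (both phases are written).
#' @param path CSV path.
#' @return For `read_trace`, a data frame; for `write_trace`, `path`
#'   invisibly.
#' @export
write_trace <- function(trace, path) {
  if (inherits(trace, "kinetic_trace_pair")) {
    trace <- rbind(trace$association, trace$dissociation)
  }
  write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read.csv(path)
  need <- c("time_s", "signal", "phase", "concentration_M")
  if (!all(need %in% names(df))) {
    stop_invalid("trace CSV must have columns %s", paste(need, collapse = ","))
  }
  df
}

# Small-sample-corrected information criterion for a Gaussian LS fit.
aicc <- function(rss, n, n_par) {
  p <- n_par + 1 # +1 for the noise variance
  n * log(rss / n) + 2 * p + 2 * p * (p + 1) / max(n - p - 1, 1)
}

kinetic_fit <- function(...) {
  structure(list(...), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<kinetic_fit> FAILED:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("<kinetic_fit> %d-phase %s fit\n", x$n_phases, x$phase))
  for (i in seq_len(x$n_phases)) {
    cat(sprintf("  phase %d: amplitude %.4g, rate %.4g 1/s\n",
                i, x$amplitudes[i], x$rates[i]))
  }
  if (!is.null(x$k_off)) cat(sprintf("  k_off = %.4g 1/s\n", x$k_off))
  if (!is.null(x$k_on) && !is.na(x$k_on)) {
    cat(sprintf("  k_on = %.4g 1/(M s), K_D = %.4g M\n", x$k_on, x$K_D))
  }
  if (isTRUE(x$invalid_kinetics)) cat("  flagged: k_obs <= k_off\n")
  cat(sprintf("  RSS = %.4g, AICc = %.4g\n", x$rss, x$aicc))
  invisible(x)
}

# Fit y ~ sum_i A_i * exp(-k_i * t) (+ optional offset) by Levenberg-
# Marquardt least squares with non-negativity bounds and jittered restarts.
fit_exp_decay <- function(t, y, n_phases, offset, k0, A0, c0 = 0) {
  n <- length(t)
  df <- data.frame(t = t, y = y)
  make_formula <- function() {
    terms <- paste0("A", seq_len(n_phases), " * exp(-k", seq_len(n_phases),
                    " * t)")
    rhs <- paste(terms, collapse = " + ")
    if (offset) rhs <- paste(rhs, "+ c0")
    stats::as.formula(paste("y ~", rhs))
  }
  start <- c(as.list(stats::setNames(A0, paste0("A", seq_len(n_phases)))),
             as.list(stats::setNames(k0, paste0("k", seq_len(n_phases)))))
  if (offset) start$c0 <- c0
  lower <- rep(0, length(start))
  if (offset) lower[length(lower)] <- -Inf
  fit <- NULL
  for (try in 0:5) {
    st <- start
    if (try > 0) { # jittered restart
      jit <- lapply(start, function(v) v * exp(runif(1, -1, 1)))
      if (offset) jit$c0 <- start$c0 + runif(1, -0.1, 0.1)
      st <- jit
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(make_formula(), data = df, start = st, lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  fit
}

#' Fit the dissociation phase of a binding trace
#'
#' Nonlinear least-squares fit of a mono- or biphasic exponential decay
#' `y(t) = sum_i A_i exp(-k_i t)` (plus an optional constant offset) to a
#' dissociation trace. Rates are reported sorted descending. For a
#' monophasic fit `k_off` is the single rate; for a biphasic fit `k_off`
#' is the rate of the dominant-amplitude phase.
#'
#' Initial rate guesses come from the log-linearized tail slope; on
#' non-convergence the optimizer restarts from up to five jittered starts.
#' A fit that still fails returns a result with `converged = FALSE` and a
#' diagnostic message rather than a silent `NA`.
#'
#' @param trace Data frame with `time_s` and `signal` (a dissociation
#'   phase), or the `dissociation` element of [simulate_trace()] output.
#' @param n_phases 1 or 2.
#' @param offset Include a constant offset term? Default `FALSE`
#'   (normalized, blank-referenced traces are baseline-corrected).
#' @return A `kinetic_fit` with `amplitudes`, `rates` (descending),
#'   `k_off`, `rss`, `aicc`, `n_phases`, `converged`, `fitted`,
#'   `residuals`.
#' @export
fit_dissociation <- function(trace, n_phases = 1, offset = FALSE) {
  if (inherits(trace, "kinetic_trace_pair")) trace <- trace$dissociation
  n_phases <- as.integer(n_phases)
  if (!n_phases %in% 1:2) stop_invalid("n_phases must be 1 or 2")
  t <- trace$time_s
  y <- trace$signal
  if (length(t) < 10) stop_invalid("dissociation fit needs >= 10 points")
  amp0 <- max(y[1], max(y) - min(y), 1e-6)
  # degenerate constant trace: no decaying amplitude to fit
  if (sd(y) < 1e-12 || (max(y) - min(y)) < 1e-9 * max(abs(y), 1e-12)) {
    rss <- sum((y - mean(y))^2)
    return(kinetic_fit(phase = "dissociation", n_phases = n_phases,
                       amplitudes = rep(0, n_phases),
                       rates = rep(0, n_phases), k_off = 0,
                       rss = rss, n = length(y),
                       aicc = aicc(max(rss, 1e-300), length(y), 2 * n_phases),
                       converged = TRUE, degenerate = TRUE,
                       fitted = rep(mean(y), length(y)),
                       residuals = y - mean(y)))
  }
  # log-linear tail slope as the rate scale
  pos <- y > max(y) * 1e-3
  k_guess <- if (sum(pos) >= 3) {
    sl <- -coef(lm(log(y[pos]) ~ t[pos]))[[2]]
    max(sl, 1e-8)
  } else {
    1 / max(t[length(t)], 1)
  }
  if (n_phases == 1) {
    k0 <- k_guess
    A0 <- amp0
  } else {
    k0 <- c(5 * k_guess, k_guess / 5)
    A0 <- rep(amp0 / 2, 2)
  }
  fit <- fit_exp_decay(t, y, n_phases, offset, k0, A0)
  if (is.null(fit)) {
    return(kinetic_fit(phase = "dissociation", n_phases = n_phases,
                       converged = FALSE,
                       message = "nonlinear least squares did not converge",
                       rss = NA_real_, aicc = NA_real_))
  }
  cf <- coef(fit)
  A <- cf[paste0("A", seq_len(n_phases))]
  k <- cf[paste0("k", seq_len(n_phases))]
  ord <- order(k, decreasing = TRUE)
  A <- unname(A[ord]); k <- unname(k[ord])
  rss <- sum(resid(fit)^2)
  n_par <- 2 * n_phases + as.integer(offset)
  kinetic_fit(phase = "dissociation", n_phases = n_phases,
              amplitudes = A, rates = k,
              k_off = k[which.max(A)],
              offset = if (offset) unname(cf["c0"]) else NULL,
              rss = rss, n = length(y),
              aicc = aicc(max(rss, 1e-300), length(y), n_par),
              converged = TRUE,
              fitted = stats::fitted(fit), residuals = resid(fit))
}

#' Fit the association phase and derive k_on and K_D
#'
#' Fits `y(t) = sum_i Y_i (1 - exp(-k_obs_i t))` to an association trace
#' and converts the (dominant-amplitude) observed rate into the
#' association rate constant via `k_on = (k_obs - k_off) / c` and
#' `K_D = k_off / k_on`, using the `k_off` obtained from the dissociation
#' fit. If `k_obs <= k_off` the result carries an `invalid_kinetics` flag
#' (the implied `k_on` would be non-positive).
#'
#' @param trace Data frame with `time_s`, `signal` and `concentration_M`
#'   (an association phase), or the output of [simulate_trace()].
#' @param k_off Dissociation rate constant in 1/s, from
#'   [fit_dissociation()].
#' @param n_phases 1 or 2.
#' @param conc Analyte concentration in M; taken from the trace's
#'   `concentration_M` column if omitted.
#' @return A `kinetic_fit` with per-phase `amplitudes` and `rates`
#'   (`k_obs`, descending), plus `k_obs`, `k_on`, `k_off`, `K_D`,
#'   `invalid_kinetics`, `rss`, `aicc`.
#' @export
fit_association <- function(trace, k_off, n_phases = 1, conc = NULL) {
  if (inherits(trace, "kinetic_trace_pair")) trace <- trace$association
  n_phases <- as.integer(n_phases)
  if (!n_phases %in% 1:2) stop_invalid("n_phases must be 1 or 2")
  if (!is.finite(k_off) || k_off < 0) stop_invalid("k_off must be non-negative")
  t <- trace$time_s
  y <- trace$signal
  if (length(t) < 10) stop_invalid("association fit needs >= 10 points")
  if (is.null(conc)) {
    if (!"concentration_M" %in% names(trace)) {
      stop_invalid("conc not given and trace has no concentration_M column")
    }
    conc <- trace$concentration_M[1]
  }
  y_end <- mean(y[t >= quantile(t, 0.9)])
  # 63%-rise time sets the k_obs scale
  i63 <- which(y >= 0.632 * y_end)[1]
  k_guess <- if (!is.na(i63) && t[i63] > 0) 1 / t[i63] else 1 / max(t[2], 1e-6)
  if (n_phases == 1) {
    k0 <- k_guess
    A0 <- max(y_end, 1e-6)
  } else {
    k0 <- c(5 * k_guess, k_guess / 5)
    A0 <- rep(max(y_end, 1e-6) / 2, 2)
  }
  # same exponential machinery: y = sum A_i (1 - exp(-k_i t)) rewritten as
  # (sum A_i) - sum A_i exp(-k_i t); fit the decay of (plateau - y)
  df <- data.frame(t = t, y = y)
  terms <- paste0("A", seq_len(n_phases), " * (1 - exp(-k", seq_len(n_phases),
                  " * t))")
  form <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  start <- c(as.list(stats::setNames(A0, paste0("A", seq_len(n_phases)))),
             as.list(stats::setNames(k0, paste0("k", seq_len(n_phases)))))
  fit <- NULL
  for (try in 0:5) {
    st <- if (try == 0) start else lapply(start, function(v) v * exp(runif(1, -1, 1)))
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = df, start = st,
                        lower = rep(0, length(start)),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    return(kinetic_fit(phase = "association", n_phases = n_phases,
                       converged = FALSE,
                       message = "nonlinear least squares did not converge",
                       rss = NA_real_, aicc = NA_real_))
  }
  cf <- coef(fit)
  A <- cf[paste0("A", seq_len(n_phases))]
  k <- cf[paste0("k", seq_len(n_phases))]
  ord <- order(k, decreasing = TRUE)
  A <- unname(A[ord]); k <- unname(k[ord])
  k_obs <- k[which.max(A)]
  invalid <- k_obs <= k_off
  k_on <- if (invalid) NA_real_ else (k_obs - k_off) / conc
  K_D <- if (invalid) NA_real_ else k_off / k_on
  rss <- sum(resid(fit)^2)
  kinetic_fit(phase = "association", n_phases = n_phases,
              amplitudes = A, rates = k, k_obs = k_obs,
              k_off = k_off, k_on = k_on, K_D = K_D, conc = conc,
              invalid_kinetics = invalid,
              rss = rss, n = length(y),
              aicc = aicc(max(rss, 1e-300), length(y), 2 * n_phases),
              converged = TRUE,
              fitted = stats::fitted(fit), residuals = resid(fit))
}

#' Choose between mono- and biphasic fits
#'
#' Compares two fits of the same trace by their small-sample-corrected
#' information criterion (AICc). The model with more phases is chosen only
#' if its score improves on the simpler model by more than 2; on ties or
#' smaller improvements the simpler model wins (parsimony).
#'
#' @param fit_mono,fit_bi `kinetic_fit` objects for the same trace.
#' @return The chosen `kinetic_fit`.
#' @export
select_model <- function(fit_mono, fit_bi) {
  stopifnot(inherits(fit_mono, "kinetic_fit"), inherits(fit_bi, "kinetic_fit"))
  if (!isTRUE(fit_bi$converged)) return(fit_mono)
  if (!isTRUE(fit_mono$converged)) return(fit_bi)
  if (fit_mono$aicc - fit_bi$aicc > 2) fit_bi else fit_mono
}

#' Full kinetics analysis of an association/dissociation trace pair
#'
#' Fits the dissociation phase (mono- and biphasic, selecting by
#' [select_model()] when `n_phases = "auto"`), then fits the association
#' phase with the resulting `k_off` and derives `k_on` and `K_D`.
#'
#' @param trace A `kinetic_trace_pair`, or a data frame in the trace CSV
#'   dialect containing both phases.
#' @param n_phases `"auto"`, 1 or 2.
#' @param offset Passed to [fit_dissociation()].
#' @return A list with elements `dissociation` and `association` (both
#'   `kinetic_fit`), and scalar shortcuts `k_on`, `k_off`, `K_D`.
#' @examples
#' tr <- simulate_trace(1e5, 1e-3, noise_sd = 0.005, seed = 1)
#' fit <- fit_kinetics(tr)
#' c(fit$k_on, fit$k_off, fit$K_D)
#' @export
fit_kinetics <- function(trace, n_phases = "auto", offset = FALSE) {
  if (is.data.frame(trace)) {
    trace <- structure(
      list(association = trace[trace$phase == "association", ],
           dissociation = trace[trace$phase == "dissociation", ]),
      class = "kinetic_trace_pair")
  }
  if (identical(n_phases, "auto")) {
    d1 <- fit_dissociation(trace, 1, offset = offset)
    d2 <- fit_dissociation(trace, 2, offset = offset)
    diss <- select_model(d1, d2)
  } else {
    diss <- fit_dissociation(trace, n_phases, offset = offset)
  }
  if (!isTRUE(diss$converged)) {
    return(list(dissociation = diss, association = NULL,
                k_on = NA_real_, k_off = NA_real_, K_D = NA_real_))
  }
  if (identical(n_phases, "auto")) {
    a1 <- fit_association(trace, diss$k_off, 1)
    a2 <- fit_association(trace, diss$k_off, 2)
    assoc <- select_model(a1, a2)
  } else {
    assoc <- fit_association(trace, diss$k_off, n_phases)
  }
  list(dissociation = diss, association = assoc,
       k_on = assoc$k_on, k_off = diss$k_off, K_D = assoc$K_D)
}
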