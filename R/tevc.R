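#' @title Two-electrode voltage-clamp trace simulation and kinetics fitting
#' @description Simulates outwardly rectifying currents with
#'   single-exponential voltage-dependent gating, and fits activation /
#'   deactivation time constants by nonlinear least squares.  The activation
#'   time constant is fitted over the first 250 ms of the depolarizing pulse
#'   at +80 mV, and groups of fitted time constants are compared with a
#'   two-sample t-test.
#' @name tevc
NULL

#' Voltage-clamp step protocol
#'
#' Defaults reproduce the standard ClC-7 protocol: holding -30 mV, 2-s test
#' pulses from -80 to +80 mV in 20-mV steps, each followed by a 0.5-s
#' deactivation pulse at -80 mV.
#'
#' @param holding_mv holding potential, mV.
#' @param test_voltages test-pulse voltages, mV (distinct).
#' @param test_duration_s test-pulse duration, s.
#' @param deact_voltage_mv deactivation-pulse voltage, mV.
#' @param deact_duration_s deactivation-pulse duration, s.
#' @return list of class `clamp_protocol`.
#' @export
clamp_protocol <- function(holding_mv = -30,
                           test_voltages = seq(-80, 80, by = 20),
                           test_duration_s = 2,
                           deact_voltage_mv = -80,
                           deact_duration_s = 0.5) {
  if (anyDuplicated(test_voltages)) stop("test voltages must be distinct")
  if (test_duration_s <= 0 || deact_duration_s <= 0)
    stop("durations must be > 0")
  structure(list(holding_mv = holding_mv, test_voltages = test_voltages,
                 test_duration_s = test_duration_s,
                 deact_voltage_mv = deact_voltage_mv,
                 deact_duration_s = deact_duration_s),
            class = "clamp_protocol")
}

#' Trace-simulation parameters
#'
#' During a test pulse at voltage V the current is
#' `A(V) * (f + (1 - f) * (1 - exp(-t / tau_act)))` plus Gaussian noise,
#' where `f` is the instantaneous fraction and
#' `A(V) = conductance_scale * (V - reversal) / (1 + exp(-(V - mid)/slope))`
#' — a sigmoid-times-driving-force form chosen purely to produce outward
#' rectification; its parameters are descriptive plumbing, not fit targets.
#' During the deactivation pulse the current relaxes single-exponentially
#' with `tau_deact` toward `A(deact_voltage)`.
#'
#' @param tau_act,tau_deact time constants, ms (> 0).
#' @param instantaneous_fraction fraction of the conductance that is open
#'   with no delay, in [0, 1].
#' @param conductance_scale current units per mV of driving force.
#' @param reversal_potential_mv reversal potential, mV.
#' @param rectification_midpoint_mv,rectification_slope_mv sigmoid midpoint
#'   and slope of the rectification factor, mV.
#' @param noise_sd Gaussian noise sd per sample, current units.
#' @param sampling_interval_ms sampling interval, ms (> 0).
#' @return list of class `trace_sim_spec`.
#' @export
trace_sim_spec <- function(tau_act = 341, tau_deact = 80,
                           instantaneous_fraction = 0.15,
                           conductance_scale = 0.05,
                           reversal_potential_mv = 0,
                           rectification_midpoint_mv = 20,
                           rectification_slope_mv = 25,
                           noise_sd = 0,
                           sampling_interval_ms = 1) {
  if (tau_act <= 0 || tau_deact <= 0) stop("time constants must be > 0")
  if (sampling_interval_ms <= 0) stop("sampling interval must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (instantaneous_fraction < 0 || instantaneous_fraction > 1)
    stop("instantaneous_fraction must be in [0, 1]")
  structure(as.list(environment()), class = "trace_sim_spec")
}

## rectified driving-force amplitude
trace_amplitude <- function(spec, v) {
  spec$conductance_scale * (v - spec$reversal_potential_mv) /
    (1 + exp(-(v - spec$rectification_midpoint_mv) /
               spec$rectification_slope_mv))
}

#' Simulate voltage-clamp current traces
#'
#' @param spec a [trace_sim_spec()].
#' @param n_traces number of traces (independent noise realizations).
#' @param seed integer seed.
#' @param protocol a [clamp_protocol()].
#' @return List of `current_trace` objects: `time_ms`/`currents` for the
#'   test pulse (samples x voltages) and `deact_time_ms`/`deact_currents`
#'   for the deactivation segment.
#' @export
simulate_traces <- function(spec, n_traces = 1L, seed = 1L,
                            protocol = clamp_protocol()) {
  set.seed(seed)
  dt <- spec$sampling_interval_ms
  t_test <- seq(dt, protocol$test_duration_s * 1000, by = dt)
  t_deact <- seq(dt, protocol$deact_duration_s * 1000, by = dt)
  f <- spec$instantaneous_fraction
  volts <- protocol$test_voltages
  A <- trace_amplitude(spec, volts)
  A_deact <- trace_amplitude(spec, protocol$deact_voltage_mv)
  gate_test <- f + (1 - f) * (1 - exp(-t_test / spec$tau_act))
  gate_end <- f + (1 - f) * (1 - exp(-protocol$test_duration_s * 1000 /
                                       spec$tau_act))
  lapply(seq_len(n_traces), function(i) {
    cur <- outer(gate_test, A)
    dc <- vapply(seq_along(volts), function(j) {
      A_deact * (1 - (1 - gate_end) * exp(-t_deact / spec$tau_deact))
    }, numeric(length(t_deact)))
    if (spec$noise_sd > 0) {
      cur <- cur + stats::rnorm(length(cur), sd = spec$noise_sd)
      dc <- dc + stats::rnorm(length(dc), sd = spec$noise_sd)
    }
    colnames(cur) <- colnames(dc) <- paste0("mV_", volts)
    structure(list(protocol = protocol, time_ms = t_test, currents = cur,
                   deact_time_ms = t_deact, deact_currents = dc,
                   voltages = volts),
              class = "current_trace")
  })
}

## Core single-exponential least-squares fit of y(t) = a + b * exp(-t / tau).
## Initialized by log-linearization of |y - a0| with a0 estimated from the
## tail; refined by Levenberg-Marquardt.  Degenerate (flat) input yields a
## non-converged fit with zero amplitude rather than an error.
fit_single_exp <- function(t, y, rel_tol = 1e-8) {
  stopifnot(length(t) == length(y), length(t) >= 4L)
  o <- order(t); t <- t[o]; y <- y[o]
  tail_n <- max(3L, ceiling(length(y) * 0.1))
  a0 <- mean(y[(length(y) - tail_n + 1L):length(y)])
  resid0 <- y - a0
  amp0 <- y[1L] - a0
  flat <- list(tau = NA_real_, a = a0, b = 0, rss = sum((y - mean(y))^2),
               converged = FALSE)
  if (abs(amp0) < 1e-12 * (abs(a0) + 1e-12) || stats::sd(y) == 0)
    return(flat)
  use <- sign(resid0) == sign(amp0) & abs(resid0) > 1e-3 * abs(amp0)
  tau0 <- if (sum(use) >= 3L) {
    sl <- unname(stats::coef(stats::lm(log(abs(resid0[use])) ~ t[use]))[2L])
    if (is.finite(sl) && sl < 0) -1 / sl else diff(range(t)) / 3
  } else diff(range(t)) / 3
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a + b * exp(-t / tau),
                      start = list(a = a0, b = amp0, tau = tau0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = rel_tol, ptol = rel_tol)),
    error = function(e) NULL)
  if (is.null(fit)) return(flat)
  cf <- stats::coef(fit)
  list(tau = unname(cf["tau"]), a = unname(cf["a"]), b = unname(cf["b"]),
       rss = sum(stats::resid(fit)^2),
       converged = unname(cf["tau"]) > 0)
}

#' Fit the activation time constant of a test pulse
#'
#' Least-squares fit of `I(t) = I_ss - dI * exp(-t / tau)` over the first
#' `window_ms` of the test pulse at `voltage_mv` (defaults: first 250 ms at
#' +80 mV).
#'
#' @param trace a `current_trace`.
#' @param voltage_mv test voltage to fit.
#' @param window_ms fit window from pulse onset, ms.
#' @return list of class `exp_fit`: `tau_ms`, `steady_amplitude` (I_ss),
#'   `delta_amplitude` (dI), `rss`, `converged`.
#' @export
fit_activation <- function(trace, voltage_mv = 80, window_ms = 250) {
  col <- match(paste0("mV_", voltage_mv), colnames(trace$currents))
  if (is.na(col)) stop("voltage ", voltage_mv, " mV not in trace")
  keep <- trace$time_ms <= window_ms
  if (!any(keep)) stop("fit window not covered by samples")
  f <- fit_single_exp(trace$time_ms[keep], trace$currents[keep, col])
  structure(list(tau_ms = f$tau, steady_amplitude = f$a,
                 delta_amplitude = -f$b, rss = f$rss,
                 converged = f$converged, voltage_mv = voltage_mv,
                 segment = "activation"),
            class = "exp_fit")
}

#' Fit the deactivation (relaxation) time constant
#'
#' Single-exponential fit of the deactivation-pulse segment; the full 0.5-s
#' segment is used by default.
#'
#' @param trace a `current_trace`.
#' @param voltage_mv which test pulse's deactivation segment to fit (the
#'   relaxation always occurs at the protocol's deactivation voltage).
#' @param window_ms fit window, ms (default: whole segment).
#' @return An `exp_fit` (see [fit_activation()]).
#' @export
fit_deactivation <- function(trace, voltage_mv = 80, window_ms = Inf) {
  if (is.null(trace$deact_currents)) stop("no deactivation segment in trace")
  col <- match(paste0("mV_", voltage_mv), colnames(trace$deact_currents))
  if (is.na(col)) stop("voltage ", voltage_mv, " mV not in trace")
  keep <- trace$deact_time_ms <= window_ms
  f <- fit_single_exp(trace$deact_time_ms[keep],
                      trace$deact_currents[keep, col])
  structure(list(tau_ms = f$tau, steady_amplitude = f$a,
                 delta_amplitude = -f$b, rss = f$rss,
                 converged = f$converged, voltage_mv = voltage_mv,
                 segment = "deactivation"),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("%s fit at %+d mV: tau = %.3g ms (dI = %.3g, Iss = %.3g)%s\n",
              x$segment, as.integer(x$voltage_mv), x$tau_ms,
              x$delta_amplitude, x$steady_amplitude,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Normalized current-voltage relation across traces
#'
#' Per trace, the steady current at each voltage is the mean over the final
#' `end_window_ms` of the test pulse, normalized to the value at +80 mV;
#' the curve is the across-trace mean with standard errors.
#'
#' @param traces list of `current_trace` objects.
#' @param end_window_ms averaging window at the end of the pulse, ms.
#' @param ref_voltage_mv normalization voltage (must be present).
#' @return data.frame of class `iv_curve`: voltage_mv, current_norm, sem.
#' @export
normalize_iv <- function(traces, end_window_ms = 10, ref_voltage_mv = 80) {
  per_trace <- vapply(traces, function(tr) {
    ref <- match(paste0("mV_", ref_voltage_mv), colnames(tr$currents))
    if (is.na(ref)) stop("reference voltage ", ref_voltage_mv,
                         " mV not in trace")
    t_end <- max(tr$time_ms)
    rows <- tr$time_ms > t_end - end_window_ms
    ends <- colMeans(tr$currents[rows, , drop = FALSE])
    if (abs(ends[ref]) < .Machine$double.eps)
      stop("zero current at the reference voltage")
    ends / ends[ref]
  }, numeric(length(traces[[1L]]$voltages)))
  per_trace <- matrix(per_trace, ncol = length(traces))
  sem <- if (length(traces) > 1L)
    apply(per_trace, 1L, stats::sd) / sqrt(length(traces))
  else rep(NA_real_, nrow(per_trace))
  out <- data.frame(voltage_mv = traces[[1L]]$voltages,
                    current_norm = rowMeans(per_trace), sem = sem)
  class(out) <- c("iv_curve", class(out))
  out
}

#' Compare two groups of fitted time constants
#'
#' Two-sample t-test (equal-variance Student by default, Welch optional)
#' plus the fold ratio of group means — the effect size used to express
#' gating acceleration.
#'
#' @param taus_a,taus_b numeric vectors of fitted time constants (>= 2 each).
#' @param welch use the Welch (unequal-variance) test.
#' @return list: t, df, p, fold_ratio (mean a / mean b), mean_a, sem_a,
#'   mean_b, sem_b.
#' @export
compare_groups <- function(taus_a, taus_b, welch = FALSE) {
  if (length(taus_a) < 2L || length(taus_b) < 2L)
    stop("each group needs at least 2 values")
  if (stats::sd(taus_a) == 0 && stats::sd(taus_b) == 0) {
    same <- isTRUE(all.equal(mean(taus_a), mean(taus_b)))
    return(list(t = if (same) 0 else Inf, df = NA_real_,
                p = if (same) 1 else 0,
                fold_ratio = mean(taus_a) / mean(taus_b),
                mean_a = mean(taus_a), sem_a = 0,
                mean_b = mean(taus_b), sem_b = 0))
  }
  tt <- stats::t.test(taus_a, taus_b, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, fold_ratio = mean(taus_a) / mean(taus_b),
       mean_a = mean(taus_a), sem_a = stats::sd(taus_a) / sqrt(length(taus_a)),
       mean_b = mean(taus_b), sem_b = stats::sd(taus_b) / sqrt(length(taus_b)))
}
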