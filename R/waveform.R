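# Pulsatile pump forcing: a half-sine systolic ejection lobe with an
# optional dicrotic (early-diastolic backflow) lobe, plus the hydrostatic
# afterload conversion for the open-circuit water column.

#' Pump waveform parameters
#'
#' Parameterises the programmable pump flow waveform: a half-sine systolic
#' lobe of height `peak_flow` and width `systolic_duration`, an optional
#' negative dicrotic lobe immediately after systole, and zero flow for the
#' rest of the cycle.
#'
#' @param peak_flow Peak flow rate, mL/s (default 100).
#' @param heart_rate Beats per minute (default 60; cycle period = 60/HR s).
#' @param systolic_duration Width of the systolic half-sine, s. `NULL`
#'   (default) calibrates it with [calibrate_systolic_duration()] so that
#'   the cycle-mean flow equals `target_mean`.
#' @param target_mean Cycle-mean flow used for the default calibration,
#'   mL/s (default 27.74, the pump's programmed cycle integral).
#' @param dicrotic_backflow_fraction Depth of the dicrotic backflow lobe as
#'   a fraction of `peak_flow`, in `[0, 0.2)` (default 0, no backflow).
#' @param dicrotic_duration Width of the dicrotic lobe, s.
#' @param n_samples_per_cycle Number of uniform samples stored per cycle.
#' @return A `waveform_params` object.
#' @export
waveform_params <- function(peak_flow = 100, heart_rate = 60,
                            systolic_duration = NULL, target_mean = 27.74,
                            dicrotic_backflow_fraction = 0,
                            dicrotic_duration = 0,
                            n_samples_per_cycle = 1000) {
  period <- 60 / heart_rate
  if (peak_flow <= 0) stop("invalid 'peak_flow': must be > 0", call. = FALSE)
  if (heart_rate <= 0) stop("invalid 'heart_rate': must be > 0", call. = FALSE)
  if (is.null(systolic_duration))
    systolic_duration <- calibrate_systolic_duration(peak_flow, target_mean,
                                                     period)
  if (dicrotic_backflow_fraction < 0 || dicrotic_backflow_fraction >= 0.2)
    stop("invalid 'dicrotic_backflow_fraction': must be in [0, 0.2)",
         call. = FALSE)
  if (dicrotic_duration < 0)
    stop("invalid 'dicrotic_duration': must be >= 0", call. = FALSE)
  tot <- systolic_duration + dicrotic_duration
  if (systolic_duration <= 0 || tot >= period)
    stop("invalid 'systolic_duration': systolic + dicrotic duration must lie ",
         "in (0, period)", call. = FALSE)
  if (n_samples_per_cycle < 3)
    stop("invalid 'n_samples_per_cycle': must be >= 3", call. = FALSE)
  structure(list(peak_flow = peak_flow, heart_rate = heart_rate,
                 period = period, systolic_duration = systolic_duration,
                 dicrotic_backflow_fraction = dicrotic_backflow_fraction,
                 dicrotic_duration = dicrotic_duration,
                 n_samples_per_cycle = n_samples_per_cycle),
            class = "waveform_params")
}

#' Generate the pump flow waveform
#'
#' Samples one cardiac cycle of
#' \deqn{q(t) = Q_{peak} \sin(\pi t / T_{sys}), \quad 0 \le t \le T_{sys},}
#' followed by an optional negative dicrotic half-sine lobe and zero flow
#' until the end of the cycle. The returned object also carries the
#' analytic `q_fun(t)` closure (periodic in the cycle) and the exact peak
#' time `t_peak = T_sys / 2`.
#'
#' @param params A [waveform_params()] object.
#' @return A `flow_waveform` object with `times` (s, uniform over
#'   `[0, period)`), `q` (mL/s), `period`, `q_fun`, `t_peak`, `params`.
#' @export
#' @examples
#' w <- make_aortic_waveform(waveform_params())
#' peak_flow(w)   # 100
#' mean_flow(w)   # 27.74
make_aortic_waveform <- function(params) {
  if (!inherits(params, "waveform_params")) params <- do.call(waveform_params,
                                                              params)
  p <- params
  q_fun <- function(t) {
    t <- t %% p$period
    q <- numeric(length(t))
    i <- t <= p$systolic_duration
    q[i] <- p$peak_flow * sin(pi * t[i] / p$systolic_duration)
    if (p$dicrotic_backflow_fraction > 0 && p$dicrotic_duration > 0) {
      j <- t > p$systolic_duration &
        t <= p$systolic_duration + p$dicrotic_duration
      q[j] <- -p$dicrotic_backflow_fraction * p$peak_flow *
        sin(pi * (t[j] - p$systolic_duration) / p$dicrotic_duration)
    }
    q
  }
  n <- p$n_samples_per_cycle
  times <- seq(0, p$period, length.out = n + 1)[seq_len(n)]
  structure(list(times = times, q = q_fun(times), period = p$period,
                 q_fun = q_fun, t_peak = p$systolic_duration / 2,
                 params = p),
            class = "flow_waveform")
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf(paste0("flow_waveform: period %.3f s, %d samples, ",
                     "peak %.2f mL/s, mean %.3f mL/s\n"),
              x$period, length(x$times), peak_flow(x), mean_flow(x)))
  invisible(x)
}

#' Cycle-mean and peak flow of a waveform
#'
#' `mean_flow()` returns the cycle average `(1/period) * integral(q dt)` by
#' trapezoidal quadrature over the sampled cycle with periodic closure.
#' `peak_flow()` returns the maximum flow, refined at the analytic peak
#' time when the waveform carries its closure.
#'
#' @param w A `flow_waveform`.
#' @return Flow in mL/s.
#' @export
mean_flow <- function(w) {
  n <- length(w$times)
  if (n < 3) stop("waveform has fewer than 3 samples", call. = FALSE)
  tt <- c(w$times, w$period)
  qq <- c(w$q, w$q[1])          # periodic continuation
  sum(diff(tt) * (qq[-1] + qq[-length(qq)]) / 2) / w$period
}

#' @rdname mean_flow
#' @export
peak_flow <- function(w) {
  pk <- max(w$q)
  if (!is.null(w$q_fun) && !is.null(w$t_peak))
    pk <- max(pk, w$q_fun(w$t_peak))
  pk
}

#' Solve the systolic duration for a target mean flow
#'
#' Inverts the half-sine closed form `mean = 2 * peak * T / (pi * period)`:
#' returns `T = target_mean * pi * period / (2 * peak_flow)`.
#'
#' @param peak_flow Peak flow, mL/s.
#' @param target_mean Desired cycle-mean flow, mL/s; must lie in
#'   `(0, 2 * peak_flow / pi)` for the half-sine to fit in the cycle.
#' @param period Cycle period, s.
#' @return Systolic duration, s.
#' @export
calibrate_systolic_duration <- function(peak_flow, target_mean, period) {
  if (peak_flow <= 0) stop("peak_flow must be > 0", call. = FALSE)
  if (period <= 0) stop("period must be > 0", call. = FALSE)
  if (target_mean <= 0 || target_mean >= 2 * peak_flow / pi)
    stop("infeasible target_mean: must lie in (0, 2*peak_flow/pi)",
         call. = FALSE)
  target_mean * pi * period / (2 * peak_flow)
}

#' Convert a water-column height to pressure in mmHg
#'
#' Hydrostatic afterload of the open flow circuit: a column of water of the
#' given height exerts `height / 13.5951` mmHg (ratio of mercury to water
#' density at reference conditions).
#'
#' @param height_mm Water column height, mm (>= 0).
#' @return Pressure in mmHg.
#' @export
#' @examples
#' water_column_to_mmHg(1088)   # ~80 mmHg diastolic afterload
water_column_to_mmHg <- function(height_mm) {
  if (any(height_mm < 0)) stop("height must be >= 0", call. = FALSE)
  height_mm / 13.5951
}

#' Read and write waveform CSV
#'
#' Columns `time_s`, `flow_mL_per_s`; one cycle.
#'
#' @param w A `flow_waveform`.
#' @param path CSV file path.
#' @export
write_waveform_csv <- function(w, path) {
  utils::write.csv(data.frame(time_s = w$times, flow_mL_per_s = w$q),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @param period Cycle period, s; defaults to the sample spacing times the
#'   sample count (uniform grid over one cycle).
#' @return `read_waveform_csv()` returns a `flow_waveform` (sampled form,
#'   without the analytic closure).
#' @export
read_waveform_csv <- function(path, period = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "flow_mL_per_s") %in% names(d)))
    stop("waveform CSV must have columns time_s, flow_mL_per_s",
         call. = FALSE)
  if (is.null(period)) {
    dt <- diff(d$time_s)
    period <- d$time_s[length(d$time_s)] + stats::median(dt)
  }
  structure(list(times = d$time_s, q = d$flow_mL_per_s, period = period,
                 q_fun = NULL, t_peak = NULL, params = NULL),
            class = "flow_waveform")
}

#' Default calibrated pump waveform
#'
#' The default study waveform: peak 100 mL/s, 60 beats/min, systolic
#' duration calibrated so the cycle-mean flow is 27.74 mL/s, no dicrotic
#' backflow.
#'
#' @param ... Overrides passed to [waveform_params()].
#' @return A `flow_waveform`.
#' @export
default_aortic_waveform <- function(...) {
  make_aortic_waveform(waveform_params(...))
}
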