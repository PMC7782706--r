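# Extraction of the ten intrinsic electrophysiology parameters from
# voltage-clamp and current-clamp sweeps.

# helper: pull the vc sweep (trace + protocol row) from a sweep_set
get_vc <- function(sweeps) {
  idx <- which(sweeps$protocol$type == "vc")
  if (!length(idx)) return(NULL)
  row <- sweeps$protocol[idx[1], ]
  list(current = sweeps$traces[, row$sweep], row = row)
}

cc_rows <- function(sweeps) sweeps$protocol[sweeps$protocol$type == "cc", ]

# baseline-subtracted vc step currents: baseline = mean before onset
vc_currents <- function(sweeps, ss_fraction = 0.2, peak_window_ms = 5) {
  vc <- get_vc(sweeps)
  if (is.null(vc)) return(NULL)
  t <- sweeps$time_ms
  base <- mean(vc$current[t < vc$row$onset_ms])
  i <- vc$current - base
  dur <- vc$row$offset_ms - vc$row$onset_ms
  ss_win <- t >= vc$row$offset_ms - ss_fraction * dur & t < vc$row$offset_ms
  i_ss <- mean(i[ss_win])
  pk_win <- t >= vc$row$onset_ms & t < vc$row$onset_ms + peak_window_ms
  sgn <- sign(vc$row$amplitude)
  i_peak <- sgn * max(sgn * i[pk_win])
  list(i_ss = i_ss, i_peak = i_peak, i = i, t = t, row = vc$row,
       delta_v = vc$row$amplitude)
}

#' Input resistance from the voltage-clamp step
#'
#' The steady-state current of a `delta_v` step through the pipette gives
#' the total access, `delta_v / I_ss = R_s + R_in`; the membrane input
#' resistance is that total minus the series resistance estimated from the
#' peak transient.
#'
#' @param sweeps A `sweep_set` with a vc sweep.
#' @param ss_fraction Fraction of the step used as the steady-state window
#'   (default last 20%).
#' @return Resistance in MOhm (`NA` with a warning when the steady-state
#'   current is at the noise floor).
#' @export
input_resistance <- function(sweeps, ss_fraction = 0.2) {
  vc <- vc_currents(sweeps, ss_fraction)
  if (is.null(vc)) return(NA_real_)
  if (abs(vc$i_ss) < 1e-6) {
    warn("steady-state current is zero: input resistance undefined")
    return(NA_real_)
  }
  r_total <- vc$delta_v / vc$i_ss * 1000      # mV/pA = GOhm; *1000 = MOhm
  r_s <- series_resistance(sweeps)
  if (is.na(r_s)) r_s <- 0
  r_total - r_s
}

#' Series resistance from the voltage-clamp step
#'
#' `R_s = delta_v / I_peak`, the initial maximum (baseline-subtracted)
#' current within the first milliseconds of the step.
#'
#' @inheritParams input_resistance
#' @param peak_window_ms Window after onset searched for the peak
#'   (default 5 ms).
#' @return Resistance in MOhm.
#' @export
series_resistance <- function(sweeps, peak_window_ms = 5) {
  vc <- vc_currents(sweeps, peak_window_ms = peak_window_ms)
  if (is.null(vc)) return(NA_real_)
  if (abs(vc$i_peak) < 1e-6) {
    warn("no current transient: series resistance undefined")
    return(NA_real_)
  }
  vc$delta_v / vc$i_peak * 1000
}

#' Membrane capacitance from the voltage-step charge
#'
#' Integrates the transient charge `Q = integral (I(t) - I_ss) dt` over the
#' step and divides by the voltage step. Because the transient is filtered
#' through the series resistance, the raw `Q / delta_v` underestimates the
#' membrane capacitance by `(R_in / (R_s + R_in))^2`; the returned value
#' applies this series-resistance correction (the uncorrected charge-based
#' value is kept in attribute `raw_q_over_v`).
#'
#' @inheritParams input_resistance
#' @return Capacitance in pF.
#' @export
capacitance <- function(sweeps, ss_fraction = 0.2) {
  vc <- vc_currents(sweeps, ss_fraction)
  if (is.null(vc)) return(NA_real_)
  t <- vc$t
  inside <- t >= vc$row$onset_ms & t < vc$row$offset_ms
  excess <- vc$i[inside] - vc$i_ss
  q <- sum((excess[-1] + excess[-length(excess)]) / 2 * diff(t[inside]))
  q_pc <- q / 1000                            # pA*ms = fC; /1000 = pC
  if (q_pc < 0) {
    warn("negative transient charge: capacitance flagged")
  }
  raw <- q_pc / vc$delta_v * 1000             # pC/mV = nF; *1000 = pF
  r_s <- series_resistance(sweeps)
  r_in <- input_resistance(sweeps, ss_fraction)
  corr <- if (is.finite(r_s) && is.finite(r_in) && r_in > 0) {
    ((r_s + r_in) / r_in)^2
  } else 1
  structure(raw * corr, raw_q_over_v = raw)
}

#' Detect action potentials in a current-clamp trace
#'
#' Onsets where dV/dt first exceeds `dvdt_threshold` (with a refractory
#' period); per AP, the peak is the maximum before the next onset and the
#' trough the minimum after the peak.
#'
#' @param trace Voltage trace in mV.
#' @param time_ms Time base in ms.
#' @param dvdt_threshold Onset threshold in V/s (= mV/ms; default 20).
#' @param refractory_ms Minimum onset spacing (default 1 ms).
#' @return Tibble with `onset_ms`, `peak_ms`, `peak_mv`, `trough_ms`,
#'   `trough_mv` (zero rows when no AP).
#' @export
detect_aps <- function(trace, time_ms, dvdt_threshold = 20,
                       refractory_ms = 1) {
  dt <- diff(time_ms)
  dvdt <- diff(trace) / dt
  above <- dvdt >= dvdt_threshold
  crossings <- which(above & !c(FALSE, above[-length(above)]))
  onsets <- numeric(0)
  last <- -Inf
  for (i in crossings) {
    if (time_ms[i] - last >= refractory_ms) {
      onsets <- c(onsets, i)
      last <- time_ms[i]
    }
  }
  if (!length(onsets)) {
    return(tibble::tibble(onset_ms = numeric(), peak_ms = numeric(),
                          peak_mv = numeric(), trough_ms = numeric(),
                          trough_mv = numeric()))
  }
  bounds <- c(onsets[-1], length(trace))
  purrr::map_dfr(seq_along(onsets), function(j) {
    seg <- onsets[j]:bounds[j]
    pk <- seg[which.max(trace[seg])]
    after <- pk:bounds[j]
    tr <- after[which.min(trace[after])]
    tibble::tibble(onset_ms = time_ms[onsets[j]], peak_ms = time_ms[pk],
                   peak_mv = trace[pk], trough_ms = time_ms[tr],
                   trough_mv = trace[tr])
  })
}

#' Firing frequency versus injected current
#'
#' Spike counts per current-clamp step divided by step duration.
#'
#' @param sweeps A `sweep_set`.
#' @param dvdt_threshold Passed to [detect_aps()].
#' @return A `fi_curve` tibble: `i_pa`, `n_spikes`, `freq_hz`, `sweep`,
#'   sorted by current.
#' @export
fi_curve <- function(sweeps, dvdt_threshold = 20) {
  rows <- cc_rows(sweeps)
  if (!nrow(rows)) abort("no current-clamp sweeps")
  out <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
    row <- rows[i, ]
    inside <- sweeps$time_ms >= row$onset_ms & sweeps$time_ms <= row$offset_ms
    aps <- detect_aps(sweeps$traces[inside, row$sweep],
                      sweeps$time_ms[inside], dvdt_threshold)
    dur_s <- (row$offset_ms - row$onset_ms) / 1000
    tibble::tibble(i_pa = row$amplitude, n_spikes = nrow(aps),
                   freq_hz = nrow(aps) / dur_s, sweep = row$sweep)
  })
  out <- dplyr::arrange(out, .data$i_pa)
  structure(out, class = c("fi_curve", class(out)))
}

#' Firing threshold from the sigmoid F-I fit
#'
#' Fits the logistic `F(I) = Fmax / (1 + exp(-(I - I0)/s))` to the F-I
#' curve by least squares, takes the chord through the 20% and 80%
#' amplitude points, and reports the chord's x-axis intercept as the firing
#' threshold. For an exact logistic the intercept is
#' `I0 - (5/3) * log(4) * s` in closed form.
#'
#' @param fi A [fi_curve()] tibble (needs >= 4 points, >= 1 nonzero rate).
#' @return Threshold current in pA (`NA` with a warning when the fit fails).
#' @export
firing_threshold <- function(fi) {
  fi <- fi[fi$i_pa >= 0, , drop = FALSE]
  if (nrow(fi) < 4 || !any(fi$freq_hz > 0)) {
    abort("need >= 4 F-I points with at least one nonzero frequency")
  }
  fit <- fit_logistic_fi(fi)
  if (is.null(fit)) {
    warn("logistic F-I fit did not converge: threshold undefined")
    return(NA_real_)
  }
  with(fit, {
    i20 <- i0 - s * log(4)
    i80 <- i0 + s * log(4)
    slope <- (0.8 - 0.2) * fmax / (i80 - i20)
    i20 - 0.2 * fmax / slope
  })
}

fit_logistic_fi <- function(fi) {
  df <- data.frame(i = fi$i_pa, f = fi$freq_hz)
  fmax0 <- max(df$f)
  i0_0 <- df$i[which.min(abs(df$f - fmax0 / 2))]
  s0 <- max(diff(range(df$i)) / 10, 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ fmax / (1 + exp(-(i - i0) / s)), data = df,
                      start = list(fmax = fmax0, i0 = i0_0, s = s0),
                      lower = c(fmax = 1e-6, i0 = -Inf, s = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    fit <- tryCatch(
      stats::nls(f ~ fmax / (1 + exp(-(i - i0) / s)), data = df,
                 start = list(fmax = fmax0, i0 = i0_0, s = s0),
                 algorithm = "port",
                 lower = c(1e-6, -Inf, 1e-6)),
      error = function(e) NULL)
  }
  if (is.null(fit)) return(NULL)
  as.list(coef(fit))
}

#' Slope of the F-I curve
#'
#' Ordinary least-squares slope of frequency against current over the
#' window starting 50 pA after the first spiking step and ending 250 pA
#' later.
#'
#' @param fi A [fi_curve()] tibble.
#' @param window_start_pa,window_length_pa Window definition (defaults 50
#'   and 250 pA).
#' @return Slope in Hz/pA (`NA` with a warning when the window holds < 2
#'   points).
#' @export
df_di <- function(fi, window_start_pa = 50, window_length_pa = 250) {
  first <- fi$i_pa[which(fi$freq_hz > 0)[1]]
  if (is.na(first)) {
    warn("no spiking step: dF/dI undefined")
    return(NA_real_)
  }
  lo <- first + window_start_pa
  hi <- lo + window_length_pa
  sub <- fi[fi$i_pa >= lo & fi$i_pa <= hi, , drop = FALSE]
  if (nrow(sub) < 2) {
    warn("fewer than 2 F-I points in the dF/dI window")
    return(NA_real_)
  }
  unname(coef(stats::lm(freq_hz ~ i_pa, data = sub))[2])
}

#' Spike-train attenuation at the maximal step
#'
#' Ratio of the first to the last AP peak amplitude (peak minus the
#' pre-train baseline) on the maximal current step; values above 1 mean the
#' train attenuates.
#'
#' @param sweeps A `sweep_set`.
#' @param dvdt_threshold Passed to [detect_aps()].
#' @return The ratio (`NA` when < 2 APs on the maximal step).
#' @export
attenuation <- function(sweeps, dvdt_threshold = 20) {
  rows <- cc_rows(sweeps)
  if (!nrow(rows)) return(NA_real_)
  row <- rows[which.max(rows$amplitude), ]
  inside <- sweeps$time_ms >= row$onset_ms & sweeps$time_ms <= row$offset_ms
  trace <- sweeps$traces[inside, row$sweep]
  aps <- detect_aps(trace, sweeps$time_ms[inside], dvdt_threshold)
  if (nrow(aps) < 2) return(NA_real_)
  # amplitude relative to the voltage at each AP onset (threshold crossing)
  onset_v <- vapply(aps$onset_ms, function(o) {
    trace[which.min(abs(sweeps$time_ms[inside] - o))]
  }, numeric(1))
  amp <- aps$peak_mv - onset_v
  amp[1] / amp[nrow(aps)]
}

#' Sag potential on the -150 pA step
#'
#' Difference between the median membrane potential late in the step
#' (default window 1500-2250 ms after onset) and the minimum potential
#' early in the step (default 750-1000 ms after onset).
#'
#' @param sweeps A `sweep_set` containing a -150 pA cc sweep.
#' @param min_window_ms,median_window_ms Windows relative to step onset.
#' @param sag_current_pa Which step carries the sag (default -150).
#' @return Sag amplitude in mV (`NA` when the sweep or windows are absent).
#' @export
sag <- function(sweeps, min_window_ms = c(750, 1000),
                median_window_ms = c(1500, 2250), sag_current_pa = -150) {
  rows <- cc_rows(sweeps)
  row <- rows[rows$amplitude == sag_current_pa, ]
  if (!nrow(row)) {
    warn(sprintf("no %g pA sweep: sag undefined", sag_current_pa))
    return(NA_real_)
  }
  row <- row[1, ]
  if (row$offset_ms - row$onset_ms < median_window_ms[2]) {
    warn("sag windows exceed the step duration: sag undefined")
    return(NA_real_)
  }
  t <- sweeps$time_ms - row$onset_ms
  v <- sweeps$traces[, row$sweep]
  v_min <- min(v[t >= min_window_ms[1] & t <= min_window_ms[2]])
  v_med <- stats::median(v[t >= median_window_ms[1] & t <= median_window_ms[2]])
  v_med - v_min
}

#' Averaged single-AP shape metrics
#'
#' Aligns all APs of a trace on their peak, averages them, and measures the
#' averaged waveform: amplitude (peak minus trough), base width (between
#' the baseline crossings), half-width (width at baseline + half of the
#' peak-above-baseline amplitude), and symmetry (temporal position of the
#' peak between the 20% rising and falling crossings). Traces with fewer
#' than 3 APs are excluded.
#'
#' @param trace Voltage trace (mV) of one current-clamp step.
#' @param time_ms Matching time base.
#' @param dvdt_threshold Passed to [detect_aps()].
#' @param window_ms Half-width of the alignment window around each peak
#'   (default 3 ms).
#' @return List with `ap_amplitude_mv`, `ap_half_width_ms`,
#'   `ap_base_width_ms`, `ap_symmetry`, `ap_trough_mv`, `n_aps`, or all-NA
#'   when < 3 APs.
#' @export
ap_shape <- function(trace, time_ms, dvdt_threshold = 20, window_ms = 3) {
  aps <- detect_aps(trace, time_ms, dvdt_threshold)
  empty <- list(ap_amplitude_mv = NA_real_, ap_half_width_ms = NA_real_,
                ap_base_width_ms = NA_real_, ap_symmetry = NA_real_,
                ap_trough_mv = NA_real_, n_aps = nrow(aps))
  if (nrow(aps) < 3) return(empty)
  dt <- time_ms[2] - time_ms[1]
  half_n <- round(window_ms / dt)
  segs <- lapply(aps$peak_ms, function(pk) {
    i0 <- which.min(abs(time_ms - pk))
    idx <- (i0 - half_n):(i0 + half_n)
    if (idx[1] < 1 || idx[length(idx)] > length(trace)) return(NULL)
    trace[idx]
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (length(segs) < 3) return(empty)
  avg <- colMeans(do.call(rbind, segs))
  tt <- (seq_along(avg) - 1 - half_n) * dt      # time relative to peak
  pk_i <- half_n + 1
  baseline <- mean(avg[seq_len(max(1, round(0.2 * half_n)))])
  peak <- avg[pk_i]
  trough <- min(avg[pk_i:length(avg)])
  amp_above <- peak - baseline
  cross <- function(level) {
    # last upward crossing before peak, first downward after
    pre <- avg[1:pk_i]; post <- avg[pk_i:length(avg)]
    up <- which(pre[-length(pre)] < level & pre[-1] >= level)
    dn <- which(post[-length(post)] >= level & post[-1] < level)
    t_up <- if (length(up)) {
      i <- up[length(up)]
      tt[i] + dt * (level - pre[i]) / (pre[i + 1] - pre[i])
    } else NA_real_
    t_dn <- if (length(dn)) {
      i <- dn[1]
      tt[pk_i + i - 1] + dt * (post[i] - level) / (post[i] - post[i + 1])
    } else NA_real_
    c(t_up, t_dn)
  }
  half <- cross(baseline + 0.5 * amp_above)
  base <- cross(baseline + 0.02 * amp_above)   # just above baseline noise
  p20 <- cross(baseline + 0.2 * amp_above)
  list(ap_amplitude_mv = peak - trough,
       ap_half_width_ms = diff(half),
       ap_base_width_ms = diff(base),
       ap_symmetry = (0 - p20[1]) / (p20[2] - p20[1]),
       ap_trough_mv = trough - baseline,
       n_aps = nrow(aps))
}

#' Extract the ten intrinsic electrophysiology parameters
#'
#' Composes the passive (input resistance, series resistance, capacitance)
#' and active (firing threshold, dF/dI, attenuation, sag, AP amplitude, AP
#' half-width, AP symmetry) measurements into one row per cell. Single-AP
#' shape comes from the first trace with at least three APs; auxiliary
#' quantities (base width, trough amplitude) are emitted as extra columns.
#' Fields that cannot be measured are `NA`.
#'
#' @param sweeps A `sweep_set`.
#' @param dvdt_threshold AP detection threshold in V/s (default 20).
#' @return A one-row tibble with `cell_id`, the ten named parameters
#'   `input_resistance_mohm`, `series_resistance_mohm`, `capacitance_pf`,
#'   `firing_threshold_pa`, `df_di_hz_per_pa`, `attenuation_ratio`,
#'   `sag_mv`, `ap_amplitude_mv`, `ap_half_width_ms`, `ap_symmetry`, and
#'   auxiliary columns `ap_base_width_ms`, `ap_trough_mv`.
#' @export
extract_features <- function(sweeps, dvdt_threshold = 20) {
  stopifnot(inherits(sweeps, "sweep_set"))
  r_s <- suppressWarnings(series_resistance(sweeps))
  r_in <- suppressWarnings(input_resistance(sweeps))
  cap <- suppressWarnings(as.numeric(capacitance(sweeps)))
  rows <- cc_rows(sweeps)
  thr <- dfdi <- att <- sag_v <- NA_real_
  shape <- list(ap_amplitude_mv = NA_real_, ap_half_width_ms = NA_real_,
                ap_base_width_ms = NA_real_, ap_symmetry = NA_real_,
                ap_trough_mv = NA_real_, n_aps = 0L)
  if (nrow(rows)) {
    fi <- fi_curve(sweeps, dvdt_threshold)
    thr <- tryCatch(suppressWarnings(firing_threshold(fi)),
                    error = function(e) NA_real_)
    dfdi <- suppressWarnings(df_di(fi))
    att <- attenuation(sweeps, dvdt_threshold)
    sag_v <- suppressWarnings(sag(sweeps))
    cand <- fi$sweep[fi$n_spikes >= 3]
    if (length(cand)) {
      row <- rows[rows$sweep == cand[1], ]
      inside <- sweeps$time_ms >= row$onset_ms & sweeps$time_ms <= row$offset_ms
      shape <- ap_shape(sweeps$traces[inside, row$sweep],
                        sweeps$time_ms[inside], dvdt_threshold)
    }
  }
  tibble::tibble(
    cell_id = sweeps$cell_id,
    input_resistance_mohm = r_in,
    series_resistance_mohm = r_s,
    capacitance_pf = cap,
    firing_threshold_pa = thr,
    df_di_hz_per_pa = dfdi,
    attenuation_ratio = att,
    sag_mv = sag_v,
    ap_amplitude_mv = shape$ap_amplitude_mv,
    ap_half_width_ms = shape$ap_half_width_ms,
    ap_symmetry = shape$ap_symmetry,
    ap_base_width_ms = shape$ap_base_width_ms,
    ap_trough_mv = shape$ap_trough_mv)
}

#' The ten canonical intrinsic parameters
#'
#' Column names of the ten-parameter feature vector produced by
#' [extract_features()] (auxiliary columns excluded).
#' @return Character vector of length 10.
#' @export
ephys_parameter_names <- function() {
  c("input_resistance_mohm", "series_resistance_mohm", "capacitance_pf",
    "firing_threshold_pa", "df_di_hz_per_pa", "attenuation_ratio",
    "sag_mv", "ap_amplitude_mv", "ap_half_width_ms", "ap_symmetry")
}
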