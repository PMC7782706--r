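#' Simulate patch-clamp sweeps from an RC membrane model
#'
#' Renders one voltage-clamp sweep and a family of current-clamp sweeps for
#' a cell with the biophysics in `config$ephys_spec`.
#'
#' Voltage clamp: a `delta_v` step through series resistance `R_s` into the
#' parallel `R_in`/`C` membrane gives a single-exponential current transient
#' with peak `delta_v / R_s`, steady state `delta_v / (R_s + R_in)` and time
#' constant `tau = C * R_s * R_in / (R_s + R_in)`.
#'
#' Current clamp: square steps of 1.5 s (the -150 pA sag step is rendered
#' over 2.4 s so the standard sag windows fit). Subthreshold voltage follows
#' the membrane charging curve; spikes are placed at regular inter-spike
#' intervals with count `round(F(I) * duration)` from the logistic F-I law
#' `F(I) = F_max / (1 + exp(-(I - I0)/s))` (zero for non-positive steps), and
#' rendered from a triangular AP template whose amplitude declines linearly
#' by `accommodation` across the train. Sag is rendered as a Gaussian bump
#' of the configured amplitude within the early sag window.
#'
#' @param config A [simulation_config()].
#' @param cell_id Cell identifier carried in the output.
#' @param delta_v_mv Voltage-clamp step (default 5 mV).
#' @param cc_steps_pa Injected currents; default `seq(-150, 600, by = 50)`.
#' @param step_duration_ms Current-clamp step length (default 1500 ms).
#' @param sampling_rate_hz Sampling rate (default 20 kHz).
#' @param seed Seed for the noise stream; defaults to `config$seed`.
#' @return A `sweep_set`.
#' @export
simulate_sweeps <- function(config, cell_id = "cell_001",
                            delta_v_mv = 5,
                            cc_steps_pa = seq(-150, 600, by = 50),
                            step_duration_ms = 1500,
                            sampling_rate_hz = 20000,
                            seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  es <- config$ephys_spec
  for (nm in c("r_in_mohm", "r_s_mohm", "c_pf")) {
    if (is.null(es[[nm]]) || es[[nm]] <= 0) {
      abort(sprintf("ephys_spec$%s must be positive", nm))
    }
  }
  seed <- seed %||% config$seed
  dt_ms <- 1000 / sampling_rate_hz
  sag_duration <- 2400
  onset <- 100
  total_ms <- onset + sag_duration + 100
  time_ms <- seq(0, total_ms, by = dt_ms)
  n <- length(time_ms)

  with_seed(seed, {
    traces <- list()
    proto <- list()

    # --- voltage clamp ---
    r_s <- es$r_s_mohm; r_in <- es$r_in_mohm; cap <- es$c_pf
    i_peak <- delta_v_mv / r_s * 1000           # mV/MOhm = nA -> pA
    i_ss <- delta_v_mv / (r_s + r_in) * 1000
    tau_vc <- cap * (r_s * r_in) / (r_s + r_in) / 1000  # pF*MOhm = us -> ms
    vc_off <- onset + 200
    ivc <- numeric(n)
    inside <- time_ms >= onset & time_ms < vc_off
    ivc[inside] <- i_ss + (i_peak - i_ss) * exp(-(time_ms[inside] - onset) / tau_vc)
    after <- time_ms >= vc_off
    ivc[after] <- -(i_peak - i_ss) * exp(-(time_ms[after] - vc_off) / tau_vc)
    traces[["vc_1"]] <- ivc
    proto[[1]] <- tibble::tibble(sweep = "vc_1", type = "vc",
                                 amplitude = delta_v_mv,
                                 onset_ms = onset, offset_ms = vc_off)

    # --- current clamp ---
    tau_m <- r_in * cap / 1000                  # membrane time constant, ms
    v_rest <- es$v_rest_mv
    template <- ap_template(es, dt_ms)
    for (j in seq_along(cc_steps_pa)) {
      i_inj <- cc_steps_pa[j]
      dur <- if (i_inj == -150) sag_duration else step_duration_ms
      off <- onset + dur
      v <- rep(v_rest, n)
      inside <- time_ms >= onset & time_ms < off
      tloc <- time_ms[inside] - onset
      dv_ss <- i_inj * r_in / 1000              # pA * MOhm = uV -> /1000 = mV
      v[inside] <- v_rest + dv_ss * (1 - exp(-tloc / tau_m))
      relax <- time_ms >= off
      v_off <- v_rest + dv_ss * (1 - exp(-dur / tau_m))
      v[relax] <- v_rest + (v_off - v_rest) * exp(-(time_ms[relax] - off) / tau_m)
      if (i_inj == -150 && es$sag_mv > 0) {
        v <- v - es$sag_mv * exp(-((time_ms - (onset + 875)) / 120)^2)
      }
      freq <- if (i_inj > 0) {
        es$f_max_hz / (1 + exp(-(i_inj - es$i0_pa) / es$s_pa))
      } else 0
      n_spikes <- round(freq * dur / 1000)
      if (n_spikes > 0 && es$ap_amp_mv > 0) {
        is_max <- j == which.max(cc_steps_pa)
        sp_times <- onset + (seq_len(n_spikes) - 0.5) * dur / n_spikes
        for (k in seq_len(n_spikes)) {
          scale <- 1
          if (is_max && n_spikes > 1 && es$accommodation > 0) {
            scale <- 1 - es$accommodation * (k - 1) / (n_spikes - 1)
          }
          i0 <- round(sp_times[k] / dt_ms) + 1
          idx <- i0 + seq_along(template) - 1
          ok <- idx >= 1 & idx <= n
          v[idx[ok]] <- v[idx[ok]] + scale * template[ok]
        }
      }
      if (es$noise_sd_mv > 0) v <- v + rnorm(n, 0, es$noise_sd_mv)
      nm <- sprintf("cc_%02d", j)
      traces[[nm]] <- v
      proto[[j + 1]] <- tibble::tibble(sweep = nm, type = "cc",
                                       amplitude = i_inj,
                                       onset_ms = onset, offset_ms = off)
    }
    new_sweep_set(time_ms = time_ms,
                  traces = do.call(cbind, traces),
                  sampling_rate_hz = sampling_rate_hz,
                  protocol = dplyr::bind_rows(proto),
                  cell_id = cell_id)
  })
}

# triangular AP waveform added on top of the membrane voltage:
# rise from 0 to ap_amp over ap_rise_ms, fall to ap_trough over ap_fall_ms,
# recover to 0 over 2 ms
ap_template <- function(es, dt_ms) {
  if (es$ap_amp_mv <= 0) return(numeric(0))
  t_rise <- seq(0, es$ap_rise_ms, by = dt_ms)
  t_fall <- seq(dt_ms, es$ap_fall_ms, by = dt_ms)
  t_rec <- seq(dt_ms, 2, by = dt_ms)
  rise <- es$ap_amp_mv * t_rise / es$ap_rise_ms
  fall <- es$ap_amp_mv + (es$ap_trough_mv - es$ap_amp_mv) * t_fall / es$ap_fall_ms
  rec <- es$ap_trough_mv * (1 - t_rec / 2)
  c(rise, fall, rec)
}
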