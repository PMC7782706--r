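sim_sweeps <- function(es = list(), seed = 2, ...) {
  cfg <- simulation_config(seed = seed)
  cfg$ephys_spec[names(es)] <- es
  simulate_sweeps(cfg, "cellA", ...)
}

test_that("passive parameters are recovered from noiseless sweeps within 2%", {
  grid <- expand.grid(r_s = c(5, 10, 20), r_in = c(60, 90, 150),
                      c_pf = c(80, 150))
  for (i in seq_len(nrow(grid))) {
    sw <- sim_sweeps(list(r_s_mohm = grid$r_s[i], r_in_mohm = grid$r_in[i],
                          c_pf = grid$c_pf[i]),
                     cc_steps_pa = c(-150, 100))
    expect_lt(abs(series_resistance(sw) - grid$r_s[i]) / grid$r_s[i], 0.02)
    expect_lt(abs(input_resistance(sw) - grid$r_in[i]) / grid$r_in[i], 0.02)
    expect_lt(abs(as.numeric(capacitance(sw)) - grid$c_pf[i]) / grid$c_pf[i],
              0.02)
  }
})

test_that("voltage-clamp readouts follow Ohm's law on the generated transient", {
  sw <- sim_sweeps(cc_steps_pa = c(100))   # R_s 10, R_in 90, 5 mV
  expect_equal(series_resistance(sw), 10, tolerance = 0.02)
  expect_equal(input_resistance(sw), 90, tolerance = 0.02)
  # raw charge-based capacitance is Q/dV before the series correction
  cap <- capacitance(sw)
  raw <- attr(cap, "raw_q_over_v")
  expect_equal(as.numeric(cap) / raw, (100 / 90)^2, tolerance = 0.02)
})

test_that("AP detection finds rendered spikes and nothing on flat traces", {
  sw <- sim_sweeps(cc_steps_pa = c(-150, 600))
  fi <- fi_curve(sw)
  f_true <- 100 / (1 + exp(-(600 - 200) / 50))
  expect_equal(fi$n_spikes[fi$i_pa == 600], round(f_true * 1.5))
  expect_equal(fi$n_spikes[fi$i_pa == -150], 0)   # sag-only trace

  flat <- detect_aps(rep(-65, 1000), seq(0, 99.9, by = 0.1))
  expect_equal(nrow(flat), 0)
})

test_that("firing threshold matches the analytic logistic chord intercept", {
  f_max <- 100; i0 <- 200; s <- 50
  fi <- logistic_fi(seq(0, 600, by = 25), f_max, i0, s)
  analytic <- i0 - (5 / 3) * log(4) * s
  expect_lt(abs(firing_threshold(fi) - analytic), 0.1)

  # step-function F-I: threshold within one current step of the jump
  fi_step <- logistic_fi(seq(0, 600, by = 50), f_max, i0, s = 1e-3)
  fi_step$freq_hz <- ifelse(fi_step$i_pa >= 300, f_max, 0)
  thr <- suppressWarnings(firing_threshold(fi_step))
  expect_true(is.na(thr) || abs(thr - 300) <= 50)

  expect_error(firing_threshold(logistic_fi(seq(0, 300, 100), 0, 100, 10)),
               "nonzero")
})

test_that("dF/dI is the OLS slope over the stated window", {
  fi <- logistic_fi(seq(0, 600, by = 50), 100, 200, 50)
  fi$freq_hz <- pmax(0, 0.3 * (fi$i_pa - 100))   # linear above 100 pA
  expect_equal(df_di(fi), 0.3, tolerance = 1e-9)

  fi$freq_hz <- ifelse(fi$i_pa >= 100, 80, 0)    # saturated
  expect_equal(df_di(fi), 0)

  few <- logistic_fi(c(0, 100), 100, 50, 10)
  few$freq_hz <- c(0, 10)
  expect_warning(expect_true(is.na(df_di(few))), "window")
})

test_that("dF/dI from simulated sweeps approximates the logistic mid-slope", {
  # in the quasi-linear region around I0 the logistic slope is Fmax/(4s)
  sw <- sim_sweeps(list(i0_pa = 250, s_pa = 120, f_max_hz = 100),
                   cc_steps_pa = seq(0, 600, by = 50))
  fi <- fi_curve(sw)
  expect_equal(df_di(fi), 100 / (4 * 120), tolerance = 0.1)
})

test_that("attenuation is the first/last AP amplitude ratio", {
  sw_flat <- sim_sweeps(list(accommodation = 0), cc_steps_pa = c(600))
  expect_equal(attenuation(sw_flat), 1.0, tolerance = 0.02)

  sw_dec <- sim_sweeps(list(accommodation = 0.2), cc_steps_pa = c(600))
  expect_equal(attenuation(sw_dec), 1.25, tolerance = 0.05 * 1.25)

  one_ap <- sim_sweeps(list(f_max_hz = 0.7), cc_steps_pa = c(600))
  expect_true(is.na(attenuation(one_ap)))
})

test_that("sag is the late-median minus early-minimum difference", {
  sw <- sim_sweeps(list(sag_mv = 7), cc_steps_pa = c(-150, 100))
  expect_equal(sag(sw), 7, tolerance = 0.5 / 7)

  no_sweep <- sim_sweeps(cc_steps_pa = c(100))
  expect_warning(expect_true(is.na(sag(no_sweep))), "sag")
})

test_that("averaged AP shape metrics match the triangular template geometry", {
  # symmetric triangle: rise 0.8 ms, fall 0.8 ms, no trough undershoot
  es <- list(ap_rise_ms = 0.8, ap_fall_ms = 0.8, ap_trough_mv = 0,
             ap_amp_mv = 60, f_max_hz = 20)
  sw <- sim_sweeps(es, cc_steps_pa = c(600), sampling_rate_hz = 50000)
  fi <- fi_curve(sw)
  row <- sw$protocol[sw$protocol$sweep == fi$sweep[fi$n_spikes >= 3][1], ]
  inside <- sw$time_ms >= row$onset_ms & sw$time_ms <= row$offset_ms
  shape <- ap_shape(sw$traces[inside, row$sweep], sw$time_ms[inside])
  expect_equal(shape$ap_amplitude_mv, 60, tolerance = 0.02)
  expect_equal(shape$ap_half_width_ms, 0.8, tolerance = 0.05)
  expect_equal(shape$ap_symmetry, 0.5, tolerance = 0.05)

  # a trace with fewer than three APs is excluded
  sparse <- sim_sweeps(list(f_max_hz = 1.4), cc_steps_pa = c(600))
  fi2 <- fi_curve(sparse)
  expect_lte(max(fi2$n_spikes), 2)
  tr <- sparse$traces[, fi2$sweep[1]]
  expect_true(is.na(ap_shape(tr, sparse$time_ms)$ap_amplitude_mv))
})

test_that("extract_features returns the ten named parameters and honours partial input", {
  cfg <- simulation_config(seed = 6)
  cfg$ephys_spec$accommodation <- 0.15
  sw <- simulate_sweeps(cfg, "cellB")
  f <- extract_features(sw)
  expect_length(ephys_parameter_names(), 10)
  expect_true(all(ephys_parameter_names() %in% names(f)))
  expect_false(anyNA(f[ephys_parameter_names()]))
  es <- cfg$ephys_spec
  expect_equal(f$input_resistance_mohm, es$r_in_mohm, tolerance = 0.02)
  expect_equal(f$series_resistance_mohm, es$r_s_mohm, tolerance = 0.02)
  expect_equal(f$capacitance_pf, es$c_pf, tolerance = 0.02)
  thr_true <- es$i0_pa - (5 / 3) * log(4) * es$s_pa
  expect_equal(f$firing_threshold_pa, thr_true, tolerance = 0.05)

  # voltage-clamp-only input: passive three populated, active seven NA
  vc_only <- sw
  keep <- sw$protocol$type == "vc"
  vc_only$protocol <- sw$protocol[keep, ]
  vc_only$traces <- sw$traces[, sw$protocol$sweep[keep], drop = FALSE]
  f2 <- suppressWarnings(extract_features(vc_only))
  passive <- c("input_resistance_mohm", "series_resistance_mohm",
               "capacitance_pf")
  expect_false(anyNA(f2[passive]))
  expect_true(all(is.na(f2[setdiff(ephys_parameter_names(), passive)])))
})

test_that("features are invariant to a DC offset on voltage traces", {
  sw <- sim_sweeps(list(accommodation = 0.1), cc_steps_pa = c(-150, 300, 600))
  f0 <- extract_features(sw)
  sw_off <- sw
  cc <- sw$protocol$sweep[sw$protocol$type == "cc"]
  sw_off$traces[, cc] <- sw_off$traces[, cc] + 12.5
  f1 <- extract_features(sw_off)
  for (p in c("firing_threshold_pa", "df_di_hz_per_pa", "attenuation_ratio",
              "sag_mv", "ap_amplitude_mv", "ap_half_width_ms", "ap_symmetry")) {
    expect_equal(f1[[p]], f0[[p]], tolerance = 1e-8, label = p)
  }
})
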