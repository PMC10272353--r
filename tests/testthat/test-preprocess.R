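test_that("bandpass filter: null inputs, DC rejection, passband gain", {
  fs <- 30000
  spec <- filter_spec()
  expect_equal(bandpass_filter(numeric(3000), spec, fs), numeric(3000))
  # DC sits in the stopband: steady-state output is at least 40 dB down
  dc <- bandpass_filter(rep(1, 30000), spec, fs)
  expect_lt(max(abs(dc[10000:20000])), 10^(-40 / 20))
  # 1 kHz sits in the passband: measured zero-phase gain matches the designed
  # transfer function applied twice (forward-backward), within the ripple
  ba <- design_bandpass(spec, fs)
  w <- 2 * pi * 1000 / fs
  H <- sum(ba$b * exp(-1i * w * (seq_along(ba$b) - 1))) /
    sum(ba$a * exp(-1i * w * (seq_along(ba$a) - 1)))
  tt <- (0:59999) / fs
  x <- sin(2 * pi * 1000 * tt)
  y <- bandpass_filter(x, spec, fs)
  mid <- 20001:50000   # integer number of 1-kHz cycles, away from edges
  gain <- 2 * Mod(mean(y[mid] * exp(-2i * pi * 1000 * tt[mid])))
  expect_equal(gain, Mod(H)^2, tolerance = 1e-3)
  ripple <- 1 - 10^(-spec$ripple_db / 20)
  expect_lt(abs(Mod(H) - 1), ripple + 1e-12)
  expect_error(design_bandpass(filter_spec(high = 16000), fs), "Nyquist")
})

test_that("common average reference zeroes the ensemble mean exactly", {
  x <- matrix(rnorm(3000), 1000, 3)
  y <- common_average_reference(x)
  expect_equal(max(abs(rowMeans(y))), 0)
  same <- matrix(rep(rnorm(100), 4), 100, 4)
  expect_true(all(common_average_reference(same) == 0))
  pm <- cbind(rep(1, 50), rep(-1, 50))
  expect_equal(common_average_reference(pm), pm)
  tri <- matrix(rep(c(3, 1, 2), each = 10), 10, 3)
  expect_equal(common_average_reference(tri),
               matrix(rep(c(1, -1, 0), each = 10), 10, 3))
  expect_error(common_average_reference(matrix(1:5, 5, 1)), "single-channel")
  # per-array referencing zeroes each array independently
  x4 <- matrix(rnorm(400), 100, 4)
  y4 <- common_average_reference(x4, c("a", "a", "b", "b"))
  expect_equal(max(abs(rowMeans(y4[, 1:2]))), 0)
  expect_equal(max(abs(rowMeans(y4[, 3:4]))), 0)
})

test_that("nonlinear energy operator closed forms hold on interior samples", {
  n <- 200
  interior <- function(psi) {
    b <- attr(psi, "boundary")
    as.numeric(psi)[!b]
  }
  psi_c <- sneo(rep(3.7, n), k = 1, smooth_width = 1)
  expect_lt(max(abs(interior(psi_c))), 1e-9 * 3.7^2)
  psi_r <- sneo(as.numeric(1:n), k = 1, smooth_width = 1)
  expect_equal(interior(psi_r), rep(1, n - 2), tolerance = 1e-9)
  A <- 2.5; w <- 0.3
  x <- A * sin(w * (0:(n - 1)))
  psi_s <- sneo(x, k = 1, smooth_width = 1)
  expect_equal(interior(psi_s), rep(A^2 * sin(w)^2, n - 2), tolerance = 1e-9)
  # smoothing preserves the constant interior value (unit-area window)
  psi_sm <- sneo(x, k = 1, smooth_width = 5)
  expect_equal(interior(psi_sm), rep(A^2 * sin(w)^2, n - 6), tolerance = 1e-9)
  expect_error(sneo(c(1, 2), k = 1, smooth_width = 1), "shorter")
  expect_error(sneo(1:10, k = 1, smooth_width = 4), "odd")
})

make_test_recording <- function(n_channels = 16, dur = 10, rate_hz = 10,
                                noise_sd = 5, amp = 80, seed = 21) {
  fs <- 30000
  set.seed(seed)
  tpl <- spike_template_default(fs, amp)
  n <- dur * fs
  truth <- list(); tr <- matrix(0, n, n_channels)
  cfg <- sim_config(n_animals = 1, noise_sd = noise_sd, spike_amplitude = amp,
                    rng_seed = 1)
  for (c in seq_len(n_channels)) {
    st <- sort(stats::runif(rate_hz * dur, 0.01, dur - 0.01))
    tr[, c] <- channel_trace_for_test(n, st, tpl, noise_sd, fs)
    truth[[c]] <- st + (which.max(abs(tpl)) - 1) / fs
  }
  list(trace = tr, truth = truth, fs = fs)
}

channel_trace_for_test <- function(n, spike_times, tpl, noise_sd, fs) {
  x <- rnorm(n, 0, noise_sd)
  for (i in round(spike_times * fs) + 1L)
    x[i:(i + length(tpl) - 1L)] <- x[i:(i + length(tpl) - 1L)] + tpl
  x
}

test_that("spike detection recovers known spikes and is quiet on noise", {
  rec <- make_test_recording()
  tr <- bandpass_filter(rec$trace, filter_spec(), rec$fs)
  tr <- common_average_reference(tr)
  hits <- fdps <- numeric(ncol(tr))
  for (c in seq_len(ncol(tr))) {
    ev <- detect_spikes(tr[, c], detection_params(), rec$fs)
    m <- match_events(ev$time_s, rec$truth[[c]])
    hits[c] <- m$hit_rate; fdps[c] <- m$fdp
  }
  expect_gte(mean(hits), 0.95)
  expect_lte(mean(fdps), 0.05)

  expect_equal(nrow(detect_spikes(numeric(30000), detection_params(), 30000)), 0L)
  expect_error(detect_spikes(c(1, NA, 3), detection_params(), 30000),
               "non-finite")
  # pure noise below the amplitude floor: < 0.1 accepted events/s over 60 s
  set.seed(77)
  noise <- bandpass_filter(rnorm(60 * 30000, 0, 3), filter_spec(), 30000)
  ev0 <- detect_spikes(noise, detection_params(), 30000)
  expect_lt(nrow(ev0) / 60, 0.1)
})

test_that("detection is translation-equivariant", {
  fs <- 30000
  tpl <- spike_template_default(fs, 80)
  n <- fs
  st <- c(0.21, 0.47, 0.80)
  x <- numeric(n)
  for (i in round(st * fs) + 1L)
    x[i:(i + length(tpl) - 1L)] <- x[i:(i + length(tpl) - 1L)] + tpl
  m <- 900L
  y <- c(numeric(m), x[1:(n - m)])
  ev_x <- detect_spikes(x, detection_params(), fs)
  ev_y <- detect_spikes(y, detection_params(), fs)
  expect_equal(nrow(ev_x), length(st))
  expect_equal(ev_y$sample, ev_x$sample + m)
})

test_that("detection hit rate is non-decreasing in template amplitude", {
  rates <- vapply(c(20, 40, 80), function(a) {
    rec <- make_test_recording(n_channels = 8, dur = 8, amp = a, seed = 5)
    tr <- common_average_reference(
      bandpass_filter(rec$trace, filter_spec(), rec$fs))
    mean(vapply(1:2, function(c) {
      ev <- detect_spikes(tr[, c], detection_params(), rec$fs)
      match_events(ev$time_s, rec$truth[[c]])$hit_rate
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], rates[1])
})

test_that("artifact halo and ICMS blanking follow the 4-ms rule", {
  fs <- 30000
  ev <- data.frame(sample = round(c(10.000, 10.005) * fs) + 1L,
                   time_s = c(10.000, 10.005),
                   amplitude_uv = c(50, 50), energy = c(100, 100))
  trace <- numeric(11 * fs)
  trace[round(10.003 * fs) + 1L] <- 500   # artifact sample at t = 10.003
  out <- reject_artifacts(ev, trace, detection_params(), fs)
  # 3 ms away -> rejected; artifact at 10.003, event at 10.005 is 2 ms -> rejected
  expect_equal(out$accepted, c(FALSE, FALSE))
  expect_equal(out$reason, c("artifact_halo", "artifact_halo"))

  trace2 <- numeric(11 * fs)
  trace2[round(10.000 * fs) + 1L] <- -600
  ev2 <- data.frame(sample = round(c(10.005, 10.003) * fs) + 1L,
                    time_s = c(10.005, 10.003),
                    amplitude_uv = c(50, 50), energy = c(100, 100))
  out2 <- reject_artifacts(ev2, trace2, detection_params(), fs)
  expect_equal(out2$accepted, c(TRUE, FALSE))   # 5 ms retained, 3 ms rejected

  # no artifact, no ICMS: unchanged
  out3 <- reject_artifacts(ev2, numeric(11 * fs), detection_params(), fs)
  expect_true(all(out3$accepted))

  # ICMS blanking applies even without a supra-threshold sample:
  # 6 ms from the pulse is retained, 4 ms is inside the blank
  out4 <- reject_artifacts(ev2, numeric(11 * fs), detection_params(), fs,
                           icms_times = 9.999)
  expect_equal(out4$accepted, c(TRUE, FALSE))
  expect_equal(out4$reason[2], "icms_blank")
})

test_that("enlarging the artifact halo never increases accepted events", {
  fs <- 30000
  set.seed(9)
  ev <- data.frame(sample = sort(sample.int(10 * fs, 200)))
  ev$time_s <- (ev$sample - 1) / fs
  ev$amplitude_uv <- 50; ev$energy <- 10
  trace <- numeric(10 * fs)
  trace[round(c(2.0, 5.5, 7.3) * fs)] <- 1000
  counts <- vapply(c(1, 2, 4, 6, 8), function(h) {
    p <- detection_params(artifact_halo_ms = h)
    sum(reject_artifacts(ev, trace, p, fs)$accepted)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("streaming per-channel detection matches the matrix path", {
  cfg <- sim_config(n_animals = 1, channels_per_area = 2, n_shanks = 1,
                    sites_per_shank = 2, n_trials_per_type = 3, rng_seed = 17)
  plan <- cohort_plan(cfg)
  sp <- simulate_animal_spikes(plan, 1)
  rec <- synthesize_animal(plan, 1, sp)
  ev_mat <- detect_recording(rec)
  ev_str <- detect_animal(plan, 1, sp)
  attr(ev_mat, "counts") <- NULL
  rownames(ev_mat) <- rownames(ev_str) <- NULL
  expect_equal(ev_str$sample, ev_mat$sample)
  expect_equal(ev_str$accepted, ev_mat$accepted)
  expect_equal(ev_str$amplitude_uv, ev_mat$amplitude_uv, tolerance = 1e-9)
})
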