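test_that("trial schedule cycles types serially at 1-Hz spacing", {
  cfg <- sim_config(n_animals = 1, n_trials_per_type = 5, rng_seed = 1)
  sch <- build_schedule(cfg)
  expect_equal(nrow(sch), 15L)
  expect_equal(as.vector(table(sch$type)[cfg$trial_types]), rep(5L, 3))
  expect_equal(sch$type[1:6], rep(cfg$trial_types, 2))
  sol <- sch$solenoid_time[!is.na(sch$solenoid_time)]
  # solenoid-bearing trials within one cycle are 1 and 2 periods apart
  expect_true(all(abs(diff(sol) %% cfg$trial_period_s) < 1e-12 |
                    abs(diff(sol) %% cfg$trial_period_s - cfg$trial_period_s) < 1e-12))
  both <- sch[!is.na(sch$icms_time) & !is.na(sch$solenoid_time), ]
  expect_equal(both$solenoid_time - both$icms_time,
               rep(cfg$icms_latency_ms / 1000, nrow(both)))
  # ICMS-only trials still carry a pulse aligned to the notional solenoid slot
  expect_true(all(!is.na(sch$icms_time[sch$type == "ICMS"])))
  expect_true(all(is.na(sch$solenoid_time[sch$type == "ICMS"])))
})

test_that("intensity construction: degenerate, single-bump and area gating", {
  cfg <- sim_config(n_animals = 1, rng_seed = 1,
                    early_peak = list(latency_ms = 75, width_ms = 6, amplitude = 0),
                    late_peak = list(latency_ms = 100, width_ms = 10, amplitude = 0),
                    icms_peak = list(latency_ms = 5, width_ms = 3, amplitude = 0))
  lam <- build_intensity(cfg, list(area = "S1"), "Solenoid")
  tt <- seq(-0.2, 0.5, by = 0.001)
  expect_equal(lam(tt), rep(cfg$baseline_rate, length(tt)))

  cfg2 <- sim_config(n_animals = 1, rng_seed = 1,
                     early_peak = list(latency_ms = 75, width_ms = 6, amplitude = 17),
                     late_peak = list(latency_ms = 100, width_ms = 10, amplitude = 0),
                     icms_peak = list(latency_ms = 5, width_ms = 3, amplitude = 0))
  lam2 <- build_intensity(cfg2, list(area = "S1"), "Solenoid")
  expect_equal(max(lam2(tt)), cfg2$baseline_rate + 17)
  expect_equal(tt[which.max(lam2(tt))], 0.075)
  # the early bump is S1-specific: an RFA channel sees only baseline
  lam_rfa <- build_intensity(cfg2, list(area = "RFA"), "Solenoid")
  expect_equal(lam_rfa(tt), rep(cfg2$baseline_rate, length(tt)))
  # ICMS bump is RFA-specific and absent on Solenoid-only trials
  cfg3 <- sim_config(n_animals = 1, rng_seed = 1)
  lam_icms_s1 <- build_intensity(cfg3, list(area = "S1"), "ICMS")
  expect_equal(max(lam_icms_s1(tt)), cfg3$baseline_rate)
  lam_icms_rfa <- build_intensity(cfg3, list(area = "RFA"), "ICMS")
  expect_equal(max(lam_icms_rfa(tt)), cfg3$baseline_rate + cfg3$icms_peak$amplitude,
               tolerance = 1e-6)
  expect_error(build_intensity(cfg3, list(area = "M2"), "Solenoid"), "area")
  expect_error(build_intensity(cfg3, list(area = "S1"), "Tap"), "trial type")
})

test_that("intensity integral matches mean simulated spike count", {
  cfg <- sim_config(n_animals = 1, rng_seed = 1)
  lam <- build_intensity(cfg, list(area = "S1"), "Solenoid")
  win <- c(-0.25, 0.75)
  grid <- seq(win[1], win[2], by = 1e-4)
  expected <- sum(lam(grid)) * 1e-4
  set.seed(123)
  counts <- replicate(1000, length(simulate_spikes(lam, win)))
  se <- stats::sd(counts) / sqrt(1000)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("thinning sampler: trivial cases and Poisson closed form", {
  lam0 <- function(t) rep(0, length(t))
  attr(lam0, "upper") <- 0
  expect_identical(simulate_spikes(lam0, c(0, 10)), numeric(0))
  lam_unb <- function(t) 1 / (t + 1e-12)
  expect_error(simulate_spikes(lam_unb, c(0, 1)), "bounded")

  lam20 <- function(t) rep(20, length(t))
  attr(lam20, "upper") <- 20
  set.seed(7)
  counts <- replicate(500, length(simulate_spikes(lam20, c(0, 10))))
  se <- stats::sd(counts) / sqrt(500)
  expect_lt(abs(mean(counts) - 200), 3 * se)
  # reproducibility under a fixed seed
  set.seed(42); a <- simulate_spikes(lam20, c(0, 1))
  set.seed(42); b <- simulate_spikes(lam20, c(0, 1))
  expect_identical(a, b)
})

test_that("time-rescaled intervals are Exp(1) (Kolmogorov-Smirnov)", {
  cfg <- sim_config(n_animals = 1, rng_seed = 1, baseline_rate = 30)
  lam <- build_intensity(cfg, list(area = "S1"), "Solenoid")
  win <- c(-0.25, 0.75)
  grid <- seq(win[1], win[2], by = 1e-5)
  Lam <- cumsum(lam(grid)) * 1e-5
  set.seed(11)
  pass <- replicate(200, {
    st <- simulate_spikes(lam, win)
    if (length(st) < 5) return(NA)
    u <- stats::approx(grid, Lam, xout = st)$y
    suppressWarnings(stats::ks.test(diff(u), "pexp")$p.value) > 0.01
  })
  expect_gte(mean(pass, na.rm = TRUE), 0.95)
})

test_that("recording synthesis: silence, single spike, artifact window", {
  cfg <- tiny_sim_config(noise_sd = 0)
  sch <- plain_schedule(2)
  chans <- data.frame(channel = 1, area = "S1", shank = 1, site = 1,
                      artifact_gain = 1)
  empty <- data.frame(channel = integer(0), trial = integer(0),
                      time = numeric(0))
  rec0 <- synthesize_recording(sch, empty, cfg, chans)
  expect_true(all(rec0$trace == 0))

  one <- data.frame(channel = 1, trial = 1, time = 0.5)
  rec1 <- synthesize_recording(sch, one, cfg, chans)
  tpl <- spike_template_default(cfg$sample_rate, cfg$spike_amplitude)
  expect_equal(max(abs(rec1$trace)), max(abs(tpl)))
  pk <- which.max(abs(rec1$trace[, 1]))
  expect_equal(pk, round(0.5 * cfg$sample_rate) + which.max(abs(tpl)))

  # an ICMS-bearing schedule puts >450 uV inside the artifact window only
  sch2 <- sch
  sch2$icms_time <- c(0.29, NA)
  rec2 <- synthesize_recording(sch2, empty, cfg, chans)
  big <- which(abs(rec2$trace[, 1]) > 450)
  expect_gt(length(big), 0)
  t_big <- (big - 1) / cfg$sample_rate
  expect_true(all(t_big >= 0.29 & t_big <= 0.29 + 8 * cfg$artifact_tau_ms / 1000))
})

test_that("cohort generation: serial span, determinism, lesion distribution", {
  cfg <- sim_config(n_animals = 1, channels_per_area = 1, n_shanks = 1,
                    sites_per_shank = 1, n_trials_per_type = 2, rng_seed = 3)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$plan$schedule), 6L)
  expect_equal(co$recordings[[1]]$duration_s, 6)
  expect_equal(co$plan$schedule$type, rep(cfg$trial_types, 2))

  co2 <- generate_cohort(cfg)
  expect_identical(co$recordings[[1]]$trace, co2$recordings[[1]]$trace)
  expect_identical(co$truth$spikes, co2$truth$spikes)

  set.seed(5)
  v <- r_lesion_volume(1e4, 5.4, 3.7)
  expect_true(all(v > 0))
  se <- stats::sd(v) / 100
  expect_lt(abs(mean(v) - 5.4), 3 * se)

  # every spike lies inside its trial's recorded window
  sp <- co$truth$spikes[[1]]
  sch <- co$plan$schedule
  rel <- sp$time - sch$t_zero[sp$trial]
  expect_true(all(rel >= -cfg$pre_trial_s &
                    rel < cfg$trial_period_s - cfg$pre_trial_s))
})

test_that("empirical PSTH of true spikes converges to the intensity", {
  cfg <- sim_config(n_animals = 1, rng_seed = 2, baseline_rate = 20)
  lam <- build_intensity(cfg, list(area = "S1"), "Solenoid")
  win <- c(-0.25, 0.75)
  bw <- 0.01
  edges <- seq(win[1], win[2], by = bw)
  mids <- edges[-1] - bw / 2
  sup_err <- function(n_trials) {
    counts <- numeric(length(mids))
    for (i in seq_len(n_trials)) {
      st <- simulate_spikes(lam, win)
      counts <- counts + graphics::hist(st, breaks = edges, plot = FALSE)$counts
    }
    max(abs(counts / (n_trials * bw) - lam(mids)))
  }
  set.seed(31)
  expect_lt(sup_err(800), sup_err(50))
})

test_that("recording round-trips through the flat-binary format", {
  cfg <- tiny_sim_config()
  plan <- cohort_plan(cfg)
  sp <- simulate_animal_spikes(plan, 1)
  rec <- synthesize_animal(plan, 1, sp)
  dir <- withr::local_tempdir()
  write_recording(rec, dir, truth_spikes = sp)
  back <- read_recording(dir)
  expect_equal(back$sample_rate, rec$sample_rate)
  expect_equal(dim(back$trace), dim(rec$trace))
  expect_lt(max(abs(back$trace - rec$trace)), 0.195 / 2 + 1e-9)
  expect_equal(back$channels$area, rec$channels$area)
  expect_equal(back$schedule$t_zero, rec$schedule$t_zero)
})
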