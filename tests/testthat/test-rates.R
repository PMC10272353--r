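test_that("spike binning uses half-open 5-ms bins anchored at trial zero", {
  counts <- bin_spikes(c(0.001, 0.003, 0.012), trial_zeros = 0,
                       window = c(0, 15), bin_ms = 5)
  expect_equal(as.integer(counts), c(2L, 0L, 1L))
  expect_equal(attr(counts, "bin_starts_ms"), c(0, 5, 10))
  expect_true(all(bin_spikes(numeric(0), 0, c(0, 15)) == 0L))
  # a spike exactly at 5 ms falls in [5, 10)
  c2 <- bin_spikes(0.005, 0, c(0, 15), 5)
  expect_equal(as.integer(c2), c(0L, 1L, 0L))
  # count conservation over multiple trials
  set.seed(4)
  zeros <- c(1, 3, 5)
  tms <- sort(runif(200, 0.5, 6))
  cc <- bin_spikes(tms, zeros, c(-250, 300), 5)
  inwin <- sum(vapply(zeros, function(z) {
    rel <- (tms - z) * 1000
    sum(rel >= -250 & rel < 300)
  }, numeric(1)))
  expect_equal(sum(cc), inwin)
  expect_error(bin_spikes(c(1, NA), 0), "finite")
  expect_error(bin_spikes(1, 0, window = c(0, 13), bin_ms = 5), "multiple")
})

test_that("sqrt rate definition and the 2.4 cutoff inversion", {
  m <- matrix(c(1, 0, 0, 0), 4, 1)   # mean count 0.25 in one 5-ms bin
  expect_equal(sqrt_rate(m, 0.005), sqrt(50))
  expect_equal(sqrt_rate(matrix(0, 3, 4), 0.005), rep(0, 4))
  # the 2.4 sqrt(spikes/s) inclusion cutoff equals mean count 0.0288/bin
  expect_equal(2.4^2 * 0.005, 0.0288)
  expect_equal(sqrt_rate(matrix(0.0288, 1, 1), 0.005), 2.4)
  expect_error(sqrt_rate(matrix(numeric(0), 0, 3)), "trial")
})

test_that("Kaiser-weighted Savitzky-Golay smoothing preserves cubics", {
  y_const <- rep(4.2, 60)
  s <- smooth_sg_kaiser(y_const)
  expect_equal(as.numeric(s), y_const, tolerance = 1e-10)
  expect_equal(sum(attr(s, "edge")), 20L)
  x <- seq_len(60)
  y_cub <- 2 + 0.5 * x - 0.03 * x^2 + 0.001 * x^3
  s2 <- smooth_sg_kaiser(y_cub)
  expect_equal(as.numeric(s2), y_cub, tolerance = 1e-6)
  # a quartic is NOT reproduced (the filter does real smoothing)
  y_q <- (x - 30)^4 / 1000
  s3 <- smooth_sg_kaiser(y_q)
  expect_gt(max(abs(as.numeric(s3) - y_q)), 1e-3)
  expect_error(smooth_sg_kaiser(1:10), "shorter")
})

test_that("noise variance reduction matches the equivalent kernel norm", {
  # the smoother is linear: its interior kernel is the response to a unit
  # impulse far from the edges, and white-noise variance shrinks by ||h||^2
  n <- 41
  e <- numeric(n); e[21] <- 1
  h <- as.numeric(smooth_sg_kaiser(e))[21 + (-10:10)]
  h <- rev(h)
  expect_equal(sum(h), 1, tolerance = 1e-9)
  set.seed(8)
  mid <- vapply(seq_len(3000), function(i)
    as.numeric(smooth_sg_kaiser(rnorm(n)))[21], numeric(1))
  expect_equal(stats::var(mid), sum(h^2), tolerance = 0.1)
})

test_that("baseline statistics, threshold and inclusion rule", {
  starts <- seq(-250, 295, by = 5)
  rate <- rep(3.1, length(starts))
  bs <- baseline_stats(rate, starts)
  expect_equal(bs$n_bins, 30L)
  expect_equal(bs$mean, 3.1)
  expect_equal(bs$sd, 0)
  expect_equal(bs$threshold, 3.1)
  expect_true(bs$included)

  # alternating 2 and 4 over the 30 baseline bins: mean 3, sample sd by hand
  rate2 <- rate
  sel <- starts >= -200 & starts < -50
  rate2[sel] <- rep(c(2, 4), 15)
  bs2 <- baseline_stats(rate2, starts)
  expect_equal(bs2$mean, 3)
  expect_equal(bs2$sd, sqrt(30 / 29))      # 30 unit deviations, n - 1 = 29
  expect_equal(bs2$threshold, 3 + 3 * sqrt(30 / 29))

  rate3 <- rep(2.3, length(starts))
  expect_false(baseline_stats(rate3, starts)$included)
  expect_error(baseline_stats(rep(1, 40), seq(-200, -5, by = 5)),
               "insufficient")
})

test_that("evoked flags match a brute-force recomputation on random PETHs", {
  set.seed(42)
  starts <- seq(-250, 295, by = 5)
  for (i in 1:100) {
    raw <- sqrt(pmax(0, rnorm(length(starts), 10, 4)))
    sm <- smooth_sg_kaiser(raw)
    bs <- baseline_stats(as.numeric(sm), starts)
    got <- evoked_flags(sm, starts, bs, stim_onset_ms = 50)
    # independent recomputation with plain loops
    base <- c()
    for (j in seq_along(starts))
      if (starts[j] >= -200 && starts[j] < -50) base <- c(base, sm[j])
    thr <- mean(base) + 3 * stats::sd(base)
    sig <- FALSE
    edge <- attr(sm, "edge")
    for (j in seq_along(starts))
      if (starts[j] >= 50 && !edge[j] && sm[j] > thr) sig <- TRUE
    expect_equal(got$flags, as.numeric(sm) > thr)
    expect_identical(got$significant, sig)
  }
})

test_that("trivial and deterministic behavior of the bootstrap band", {
  counts <- matrix(rep(c(0L, 1L, 2L), each = 10), 10, 3)  # identical trials
  b <- suppressWarnings(confidence_band(counts, n_boot = 50))
  expect_equal(b$lower, b$upper)
  expect_equal(b$lower, b$estimate)
  set.seed(1); b1 <- confidence_band(matrix(rpois(300, 1), 30, 10), n_boot = 200)
  set.seed(1); b2 <- confidence_band(matrix(rpois(300, 1), 30, 10), n_boot = 200)
  expect_identical(b1, b2)
  expect_warning(confidence_band(matrix(0L, 5, 2), n_boot = 50), "n_boot")
  expect_error(confidence_band(matrix(0L, 1, 2)), "two trials")
})

test_that("bootstrap band attains near-nominal coverage on Poisson PETHs", {
  set.seed(14)
  lam <- 20; bw <- 0.005; nb <- 30; nt <- 100
  target <- sqrt(lam)   # smoothing a flat profile preserves it
  hit <- logical(500)
  for (r in seq_len(500)) {
    counts <- matrix(rpois(nt * nb, lam * bw), nt, nb)
    b <- confidence_band(counts, bw, n_boot = 200)
    hit[r] <- b$lower[15] <= target && target <= b$upper[15]
  }
  expect_gte(mean(hit), 0.90)
  expect_lte(mean(hit), 0.99)
})

test_that("sqrt transform stabilizes variance across Poisson rates", {
  set.seed(3)
  bw <- 0.005; nt <- 100
  rates <- c(5, 10, 20, 50)
  v_sqrt <- v_raw <- numeric(length(rates))
  for (i in seq_along(rates)) {
    reps <- replicate(400, {
      cc <- matrix(rpois(nt, rates[i] * bw), nt, 1)
      c(sqrt_rate(cc, bw), mean(cc) / bw)
    })
    v_sqrt[i] <- stats::var(reps[1, ])
    v_raw[i] <- stats::var(reps[2, ])
  }
  expect_lt(max(v_sqrt) / min(v_sqrt), 2)
  # raw-rate variance grows roughly in proportion to the rate
  expect_gt(v_raw[4] / v_raw[1], 5)
})

test_that("PETH assembly conserves counts and flags low channels", {
  cfg <- tiny_sim_config(baseline_rate = 25)
  plan <- cohort_plan(cfg)
  ev <- detect_animal(plan, 1)
  chans <- plan$channels
  res <- compute_peths(ev, plan$schedule, chans)
  expect_equal(nrow(res$summary), nrow(chans) * 3)
  expect_true(all(c("baseline_mean", "threshold", "included", "significant")
                  %in% names(res$summary)))
  # count conservation for one channel / type
  ty <- "Solenoid"
  zeros <- plan$schedule$t_zero[plan$schedule$type == ty]
  acc <- ev[ev$accepted & ev$channel == 1, ]
  rel <- as.vector(outer(acc$time_s, zeros, "-")) * 1000
  expect_equal(sum(res$counts[[ty]][["1"]]),
               sum(rel >= -250 & rel < 350))
})
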