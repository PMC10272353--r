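#' Build the trial schedule for one experimental block
#'
#' Trials of the three types are cycled serially, one trial at a time, with
#' trial zeros spaced `trial_period_s` apart so that solenoid strikes recur at
#' 1-Hz intervals. On ICMS-containing trials the pulse leads the (actual or
#' notional) solenoid onset by `icms_latency_ms`.
#'
#' @param config a [sim_config()].
#' @return data.frame with one row per trial: `trial`, `type`, `t_start`,
#'   `t_zero`, `solenoid_time`, `icms_time` (times in seconds from the start
#'   of the recording; `NA` where the event does not occur).
#' @export
build_schedule <- function(config) {
  validate_sim_config(config)
  n <- config$n_trials_per_type * 3L
  type <- rep(config$trial_types, config$n_trials_per_type)
  t_start <- (seq_len(n) - 1) * config$trial_period_s
  t_zero <- t_start + config$pre_trial_s
  sol_slot <- t_zero + config$solenoid_onset_ms / 1000
  solenoid_time <- ifelse(vapply(type, has_solenoid, logical(1), cfg = config),
                          sol_slot, NA_real_)
  icms_time <- ifelse(vapply(type, has_icms, logical(1), cfg = config),
                      sol_slot - config$icms_latency_ms / 1000, NA_real_)
  data.frame(trial = seq_len(n), type = type, t_start = t_start,
             t_zero = t_zero, solenoid_time = solenoid_time,
             icms_time = icms_time, stringsAsFactors = FALSE)
}

#' Evoked-rate intensity function for one channel and trial type
#'
#' Constructs the inhomogeneous Poisson intensity lambda(t) (spikes/s, t in
#' seconds relative to trial zero) as a baseline plus Gaussian bumps: an early
#' bump restricted to S1 channels on solenoid trials, a late bump shared by S1
#' and RFA on solenoid trials, and a short-latency bump restricted to RFA on
#' ICMS-containing trials. Bump amplitudes are scaled by the channel's
#' component gains, by the trial-type modifier (`late_icms_gain` on
#' ICMS+Solenoid trials) and log-linearly by the animal's lesion volume about
#' the cohort mean.
#'
#' @param config a [sim_config()].
#' @param channel list or one-row data.frame describing the channel; must have
#'   `area` ("RFA" or "S1"); optional `baseline`, `gain_early`, `gain_late`,
#'   `gain_icms`, `lesion_volume`.
#' @param trial_type one of the configured trial-type labels.
#' @return function lambda(t) with attributes `upper` (a bound on lambda) and
#'   `components` (the peak rates actually injected).
#' @export
build_intensity <- function(config, channel, trial_type) {
  validate_sim_config(config)
  channel <- as.list(channel)
  if (is.null(channel$area) || !channel$area %in% c("RFA", "S1"))
    stop("channel area must be 'RFA' or 'S1'")
  if (!trial_type %in% config$trial_types)
    stop("unknown trial type: ", trial_type)
  gety <- function(nm, default) if (is.null(channel[[nm]])) default else channel[[nm]]
  base <- gety("baseline", config$baseline_rate)
  lesion <- gety("lesion_volume", config$lesion_mean)
  es <- config$effect_sizes
  dl <- lesion - config$lesion_mean
  sol <- has_solenoid(trial_type, config)
  icms <- has_icms(trial_type, config)

  amp_early <- if (sol && channel$area == "S1")
    config$early_peak$amplitude * gety("gain_early", 1) *
      exp((es$lesion_early_coef %||% 0) * dl) else 0
  amp_late <- if (sol)
    config$late_peak$amplitude * gety("gain_late", 1) *
      exp((es$lesion_late_coef %||% 0) * dl) *
      (if (icms) es$late_icms_gain %||% 1 else 1) else 0
  amp_icms <- if (icms && channel$area == "RFA")
    config$icms_peak$amplitude * gety("gain_icms", 1) else 0

  mu_early <- config$early_peak$latency_ms / 1000
  mu_late <- config$late_peak$latency_ms / 1000
  mu_icms <- (config$solenoid_onset_ms - config$icms_latency_ms +
                config$icms_peak$latency_ms) / 1000
  s_early <- config$early_peak$width_ms / 1000
  s_late <- config$late_peak$width_ms / 1000
  s_icms <- config$icms_peak$width_ms / 1000

  lambda <- function(t) {
    v <- rep(base, length(t))
    if (amp_early > 0) v <- v + amp_early * exp(-0.5 * ((t - mu_early) / s_early)^2)
    if (amp_late > 0) v <- v + amp_late * exp(-0.5 * ((t - mu_late) / s_late)^2)
    if (amp_icms > 0) v <- v + amp_icms * exp(-0.5 * ((t - mu_icms) / s_icms)^2)
    pmax(v, 0)
  }
  attr(lambda, "upper") <- base + amp_early + amp_late + amp_icms
  attr(lambda, "components") <- c(baseline = base, early = amp_early,
                                  late = amp_late, icms = amp_icms)
  lambda
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample an inhomogeneous Poisson spike train by thinning
#'
#' Candidate events are drawn from a homogeneous Poisson process at the bound
#' `lambda_max` and retained with probability lambda(t)/lambda_max.
#'
#' @param lambda intensity function of time (spikes/s); if it carries an
#'   `upper` attribute that is used as the default bound.
#' @param window numeric length-2, the sampling interval in seconds.
#' @param lambda_max finite upper bound on lambda over the window.
#' @return sorted numeric vector of event times in seconds.
#' @export
simulate_spikes <- function(lambda, window, lambda_max = attr(lambda, "upper")) {
  if (is.null(lambda_max) || !is.finite(lambda_max))
    stop("lambda must be bounded above by a known finite constant")
  if (lambda_max < 0) stop("lambda_max must be >= 0")
  dur <- diff(window)
  if (dur <= 0) stop("window must have positive length")
  if (lambda_max == 0) return(numeric(0))
  n_cand <- stats::rpois(1, lambda_max * dur)
  if (n_cand == 0) return(numeric(0))
  tt <- stats::runif(n_cand, window[1], window[2])
  keep <- stats::runif(n_cand) * lambda_max < lambda(tt)
  sort(tt[keep])
}

#' Default biphasic multi-unit spike template
#'
#' Negative-leading biphasic waveform of ~1.2 ms, scaled so its peak absolute
#' amplitude equals `peak_uv`.
#'
#' @param sample_rate Hz.
#' @param peak_uv peak absolute amplitude, microvolts.
#' @return numeric vector of template samples (microvolts).
#' @export
spike_template_default <- function(sample_rate, peak_uv = 80) {
  tt <- seq(0, 1.2e-3, by = 1 / sample_rate)
  w <- -exp(-((tt - 0.35e-3) / 0.12e-3)^2) + 0.55 * exp(-((tt - 0.75e-3) / 0.2e-3)^2)
  peak_uv * w / max(abs(w))
}

## Critically damped transient used for the ICMS stimulation artifact:
## a(t) = A * (t/tau) * exp(1 - t/tau), peaking at A when t = tau.
artifact_waveform <- function(sample_rate, amplitude, tau_ms) {
  tau <- tau_ms / 1000
  tt <- seq(0, 8 * tau, by = 1 / sample_rate)
  amplitude * (tt / tau) * exp(1 - tt / tau)
}

## One channel's raw trace: noise + spike templates + scaled ICMS artifacts.
## With a non-NA seed the channel is reproducible in isolation, which lets
## large cohorts be synthesized and processed one channel at a time.
channel_trace <- function(n, spike_times, template, icms_times, artifact_gain,
                          config, seed = NA_integer_) {
  if (!is.na(seed)) set.seed(seed)
  fs <- config$sample_rate
  x <- if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else numeric(n)
  ntpl <- length(template)
  if (length(spike_times)) {
    i0 <- pmax(1L, round(spike_times * fs) + 1L)
    for (i in i0) {
      j1 <- min(n, i + ntpl - 1L)   # template clipped at the recording edge
      x[i:j1] <- x[i:j1] + template[seq_len(j1 - i + 1L)]
    }
  }
  if (length(icms_times)) {
    art <- artifact_waveform(fs, config$artifact_amplitude, config$artifact_tau_ms)
    for (it in icms_times) {
      j0 <- round(it * fs) + 1L
      j1 <- min(n, j0 + length(art) - 1L)
      x[j0:j1] <- x[j0:j1] + artifact_gain * art[seq_len(j1 - j0 + 1L)]
    }
  }
  if (!is.null(config$whisking_artifact)) {
    wa <- config$whisking_artifact
    x <- x + wa$amplitude * sin(2 * pi * wa$freq_hz * (seq_len(n) - 1) / fs)
  }
  x
}

#' Synthesize a raw multichannel recording from spike times
#'
#' The trace is white Gaussian noise plus the spike template inserted at each
#' spike time plus an ICMS artifact transient (peak > 450 uV) at each ICMS
#' time. Artifacts are mostly common-mode: each channel applies its
#' `artifact_gain` factor to the shared transient.
#'
#' @param schedule trial schedule from [build_schedule()].
#' @param spikes data.frame of ground-truth spikes with columns `channel`
#'   (index into `channels`), `trial`, `time` (seconds, absolute).
#' @param config a [sim_config()].
#' @param channels data.frame describing channels (one row each); needs
#'   `area`, `shank`, `site`; optional `artifact_gain`.
#' @param channel_seeds optional integer vector of per-channel noise seeds
#'   (by default the current RNG stream is used sequentially).
#' @return object of class `raw_recording`: list with `trace` (samples x
#'   channels matrix, microvolts), `sample_rate`, `channels`, `schedule`,
#'   `duration_s`.
#' @export
synthesize_recording <- function(schedule, spikes, config, channels,
                                 channel_seeds = rep(NA_integer_, nrow(channels))) {
  validate_sim_config(config)
  fs <- config$sample_rate
  if (any(diff(schedule$t_start) < config$trial_period_s - 1e-12))
    stop("overlapping trial windows")
  dur <- max(schedule$t_start) + config$trial_period_s
  n <- round(dur * fs)
  nch <- nrow(channels)
  tpl <- config$spike_template %||% spike_template_default(fs, config$spike_amplitude)
  ntpl <- length(tpl)
  if (nrow(spikes) && (min(spikes$time) < 0 || max(spikes$time) > dur))
    stop("spike times not covered by the recording span")
  icms_times <- schedule$icms_time[!is.na(schedule$icms_time)]
  trace <- matrix(0, n, nch)
  for (c in seq_len(nch)) {
    ag <- if (is.null(channels$artifact_gain)) 1 else channels$artifact_gain[c]
    trace[, c] <- channel_trace(n, spikes$time[spikes$channel == c], tpl,
                                icms_times, ag, config,
                                seed = channel_seeds[c])
  }
  structure(list(trace = trace, sample_rate = fs, channels = channels,
                 schedule = schedule, duration_s = dur),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("raw_recording: %d channels x %.1f s @ %g kHz (%d trials)\n",
              ncol(x$trace), x$duration_s, x$sample_rate / 1000,
              nrow(x$schedule)))
  invisible(x)
}

#' Lesion-volume sampler
#'
#' Lognormal distribution moment-matched to the requested mean and standard
#' deviation (volumes are strictly positive).
#'
#' @param n number of draws.
#' @param mean,sd target moments, mm3.
#' @return numeric vector of volumes, mm3.
#' @export
r_lesion_volume <- function(n, mean = 5.4, sd = 3.7) {
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Lay out the cohort: lesion volumes, channel maps, schedule, seeds
#'
#' Draws all animal- and channel-level random quantities (lesion volumes,
#' per-channel baseline rates and component gains, artifact coupling factors)
#' under the configured seed, and derives per-animal sub-seeds for spike
#' simulation and trace synthesis so that animals can be generated
#' independently and reproducibly.
#'
#' @param config a [sim_config()].
#' @return object of class `cohort_plan`: list with `config`,
#'   `lesion_volumes`, `channels` (data.frame over all animals), `schedule`,
#'   `spike_seeds`, `trace_seeds`.
#' @export
cohort_plan <- function(config) {
  validate_sim_config(config)
  set.seed(config$rng_seed)
  lesions <- r_lesion_volume(config$n_animals, config$lesion_mean, config$lesion_sd)
  es <- config$effect_sizes
  gsd <- es$channel_gain_sd %||% 0
  bsd <- es$baseline_sd %||% 0
  chans <- do.call(rbind, lapply(seq_len(config$n_animals), function(a) {
    nc <- 2L * config$channels_per_area
    data.frame(animal = a,
               channel = seq_len(nc),
               area = rep(c("RFA", "S1"), each = config$channels_per_area),
               shank = rep(rep(seq_len(config$n_shanks),
                               each = config$sites_per_shank), 2L),
               site = rep(seq_len(config$sites_per_shank),
                          2L * config$n_shanks),
               baseline = config$baseline_rate * exp(stats::rnorm(nc, 0, bsd)),
               gain_early = exp(stats::rnorm(nc, 0, gsd)),
               gain_late = exp(stats::rnorm(nc, 0, gsd)),
               gain_icms = exp(stats::rnorm(nc, 0, gsd)),
               artifact_gain = stats::runif(nc, 0.75, 1.25),
               lesion_volume = lesions[a],
               stringsAsFactors = FALSE)
  }))
  structure(list(config = config, lesion_volumes = lesions, channels = chans,
                 schedule = build_schedule(config),
                 spike_seeds = vapply(seq_len(config$n_animals), function(a)
                   derive_seed(config$rng_seed, a, 1L), integer(1)),
                 trace_seeds = vapply(seq_len(config$n_animals), function(a)
                   derive_seed(config$rng_seed, a, 2L), integer(1))),
            class = "cohort_plan")
}

#' Simulate ground-truth spike times for one animal
#'
#' @param plan a [cohort_plan()].
#' @param animal animal index.
#' @return data.frame with `channel`, `trial`, `time` (absolute seconds).
#' @export
simulate_animal_spikes <- function(plan, animal) {
  cfg <- plan$config
  set.seed(plan$spike_seeds[animal])
  chans <- plan$channels[plan$channels$animal == animal, ]
  sch <- plan$schedule
  out <- vector("list", nrow(chans) * nrow(sch))
  k <- 0L
  for (c in seq_len(nrow(chans))) {
    lam_by_type <- lapply(cfg$trial_types, function(tt)
      build_intensity(cfg, chans[c, ], tt))
    names(lam_by_type) <- cfg$trial_types
    for (i in seq_len(nrow(sch))) {
      lam <- lam_by_type[[sch$type[i]]]
      ## lambda is relative to trial zero; trial spans [-pre_trial, period-pre_trial)
      rel <- simulate_spikes(lam, c(-cfg$pre_trial_s,
                                    cfg$trial_period_s - cfg$pre_trial_s))
      if (length(rel)) {
        k <- k + 1L
        out[[k]] <- data.frame(channel = chans$channel[c], trial = i,
                               time = rel + sch$t_zero[i])
      }
    }
  }
  if (k == 0L)
    return(data.frame(channel = integer(0), trial = integer(0), time = numeric(0)))
  res <- do.call(rbind, out[seq_len(k)])
  res[order(res$channel, res$time), , drop = FALSE]
}

#' Synthesize the raw recording for one animal of a planned cohort
#'
#' @param plan a [cohort_plan()].
#' @param animal animal index.
#' @param spikes optional precomputed ground-truth spikes for this animal
#'   (from [simulate_animal_spikes()]); simulated if missing.
#' @return a `raw_recording`.
#' @export
synthesize_animal <- function(plan, animal, spikes = NULL) {
  if (is.null(spikes)) spikes <- simulate_animal_spikes(plan, animal)
  chans <- plan$channels[plan$channels$animal == animal, ]
  rec <- synthesize_recording(plan$schedule, spikes, plan$config, chans,
                              channel_seeds = animal_channel_seeds(plan, animal))
  rec$animal <- animal
  rec
}

## per-channel noise seeds for one animal (streaming and matrix synthesis
## must agree sample for sample)
animal_channel_seeds <- function(plan, animal) {
  nch <- sum(plan$channels$animal == animal)
  vapply(seq_len(nch), function(c)
    derive_seed(plan$trace_seeds[animal], c, 3L), integer(1))
}

#' Ground-truth temporal component shapes on the analysis grid
#'
#' Returns the flat (baseline), early and late evoked profiles evaluated at
#' the centers of the 5-ms bins of the 250-ms post-solenoid analysis window,
#' for aligning recovered components with the generator's truth.
#'
#' @param config a [sim_config()].
#' @param window_ms analysis window relative to trial zero (default the
#'   250 ms following solenoid onset).
#' @param bin_ms bin width, ms.
#' @return matrix (bins x 3) with columns `flat`, `early`, `late`.
#' @export
true_component_shapes <- function(config,
                                  window_ms = config$solenoid_onset_ms + c(0, 250),
                                  bin_ms = 5) {
  ctr <- seq(window_ms[1] + bin_ms / 2, window_ms[2] - bin_ms / 2, by = bin_ms)
  cbind(flat = rep(1, length(ctr)),
        early = exp(-0.5 * ((ctr - config$early_peak$latency_ms) /
                              config$early_peak$width_ms)^2),
        late = exp(-0.5 * ((ctr - config$late_peak$latency_ms) /
                             config$late_peak$width_ms)^2))
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper combining [cohort_plan()], [simulate_animal_spikes()]
#' and [synthesize_animal()] for every animal. For large cohorts prefer the
#' per-animal functions (or [run_pipeline()]) to bound memory.
#'
#' @param config a [sim_config()].
#' @param keep_traces synthesize and keep the raw traces (default TRUE).
#' @return list with `plan`, `truth` (list: `spikes` per animal,
#'   `shapes`, `effects`, `lesion_volumes`), and `recordings` (list of
#'   `raw_recording`, or NULL per animal when `keep_traces = FALSE`).
#' @export
generate_cohort <- function(config, keep_traces = TRUE) {
  plan <- cohort_plan(config)
  spikes <- lapply(seq_len(config$n_animals), function(a)
    simulate_animal_spikes(plan, a))
  recs <- lapply(seq_len(config$n_animals), function(a)
    if (keep_traces) synthesize_animal(plan, a, spikes[[a]]) else NULL)
  list(plan = plan,
       truth = list(spikes = spikes,
                    shapes = true_component_shapes(config),
                    effects = config$effect_sizes,
                    lesion_volumes = plan$lesion_volumes),
       recordings = recs)
}
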