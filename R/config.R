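#' Simulation configuration for a synthetic stimulation cohort
#'
#' Collects every parameter of the synthetic cohort generator: array geometry,
#' trial schedule, firing-rate model (baseline plus evoked Gaussian bumps),
#' effect sizes, spike waveform, noise, and the intracortical microstimulation
#' (ICMS) artifact. Defaults emulate the recording conditions the analysis
#' assumes: two 32-channel arrays (4 shanks x 8 sites) in RFA and S1 sampled
#' at 30 kHz, three trial types ("Solenoid", "ICMS", "ICMS+Solenoid") cycled
#' serially at 1 Hz, a solenoid strike 50 ms after trial zero lasting 50 ms,
#' an early evoked peak restricted to S1 at 75 ms (25 ms after solenoid
#' onset), a late peak shared by S1 and RFA at 100 ms, and an immediate
#' post-pulse peak in RFA on ICMS trials.
#'
#' @param n_animals number of animals in the cohort.
#' @param channels_per_area electrode sites per array (one array per area).
#' @param n_shanks,sites_per_shank array geometry; their product must equal
#'   `channels_per_area`.
#' @param sample_rate sampling rate in Hz.
#' @param n_trials_per_type trials of each type per experimental block.
#' @param trial_types ordered trial-type labels; the schedule cycles through
#'   them one trial at a time.
#' @param trial_period_s spacing of successive trials in seconds (1-Hz
#'   solenoid activation).
#' @param pre_trial_s recorded baseline before trial zero, seconds. The
#'   default 0.25 s leaves a 150-ms baseline window after trimming 50 ms at
#'   each end.
#' @param solenoid_onset_ms solenoid trigger time relative to trial zero, ms.
#' @param solenoid_contact_ms duration of solenoid contact, ms.
#' @param icms_latency_ms lead of the ICMS pulse before solenoid onset, ms.
#' @param baseline_rate baseline multi-unit rate, spikes/s per channel.
#' @param early_peak,late_peak,icms_peak lists with elements `latency_ms`
#'   (early/late: from trial zero; icms: after the pulse), `width_ms`
#'   (Gaussian sd) and `amplitude` (peak rate above baseline, spikes/s).
#' @param effect_sizes list of multiplicative modifiers:
#'   `late_icms_gain` (late-peak amplitude multiplier on ICMS+Solenoid
#'   trials), `lesion_early_coef`/`lesion_late_coef` (log-linear slope of
#'   the peak amplitudes per mm3 of lesion volume about the cohort mean),
#'   `channel_gain_sd` (sd of per-channel lognormal gains applied
#'   independently per evoked component) and `baseline_sd` (sd of the
#'   per-channel lognormal baseline-rate multiplier).
#' @param lesion_mean,lesion_sd cohort lesion-volume distribution, mm3.
#'   Volumes are lognormal with these moments so they are always positive.
#' @param noise_sd white-noise standard deviation, microvolts.
#' @param spike_amplitude peak absolute amplitude of the biphasic spike
#'   template, microvolts.
#' @param spike_template optional waveform override (numeric, microvolts);
#'   by default a negative-leading biphasic template of ~1.2 ms is used.
#' @param artifact_amplitude peak ICMS artifact amplitude, microvolts; must
#'   exceed the 450 uV artifact-detection criterion.
#' @param artifact_tau_ms time constant of the critically damped artifact
#'   transient, ms.
#' @param whisking_artifact optional low-frequency artifact injector: `NULL`
#'   (default, off) or a list with `amplitude` (uV) and `freq_hz`.
#' @param rng_seed integer seed governing all randomness in the generator.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_animals = 7,
                       channels_per_area = 32,
                       n_shanks = 4,
                       sites_per_shank = 8,
                       sample_rate = 30000,
                       n_trials_per_type = 100,
                       trial_types = c("Solenoid", "ICMS", "ICMS+Solenoid"),
                       trial_period_s = 1,
                       pre_trial_s = 0.25,
                       solenoid_onset_ms = 50,
                       solenoid_contact_ms = 50,
                       icms_latency_ms = 10,
                       baseline_rate = 10,
                       early_peak = list(latency_ms = 75, width_ms = 6, amplitude = 40),
                       late_peak = list(latency_ms = 100, width_ms = 10, amplitude = 30),
                       icms_peak = list(latency_ms = 5, width_ms = 3, amplitude = 50),
                       effect_sizes = list(late_icms_gain = 1.5,
                                           lesion_early_coef = 0,
                                           lesion_late_coef = 0,
                                           channel_gain_sd = 0.4,
                                           baseline_sd = 0.25),
                       lesion_mean = 5.4,
                       lesion_sd = 3.7,
                       noise_sd = 5,
                       spike_amplitude = 80,
                       spike_template = NULL,
                       artifact_amplitude = 2000,
                       artifact_tau_ms = 0.6,
                       whisking_artifact = NULL,
                       rng_seed = 1L) {
  cfg <- list(n_animals = n_animals, channels_per_area = channels_per_area,
              n_shanks = n_shanks, sites_per_shank = sites_per_shank,
              sample_rate = sample_rate, n_trials_per_type = n_trials_per_type,
              trial_types = trial_types, trial_period_s = trial_period_s,
              pre_trial_s = pre_trial_s, solenoid_onset_ms = solenoid_onset_ms,
              solenoid_contact_ms = solenoid_contact_ms,
              icms_latency_ms = icms_latency_ms, baseline_rate = baseline_rate,
              early_peak = early_peak, late_peak = late_peak,
              icms_peak = icms_peak, effect_sizes = effect_sizes,
              lesion_mean = lesion_mean, lesion_sd = lesion_sd,
              noise_sd = noise_sd, spike_amplitude = spike_amplitude,
              spike_template = spike_template,
              artifact_amplitude = artifact_amplitude,
              artifact_tau_ms = artifact_tau_ms,
              whisking_artifact = whisking_artifact,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_animals < 1) stop("n_animals must be >= 1")
  if (cfg$n_shanks * cfg$sites_per_shank != cfg$channels_per_area)
    stop("n_shanks * sites_per_shank must equal channels_per_area")
  if (length(cfg$trial_types) != 3L || anyDuplicated(cfg$trial_types))
    stop("trial_types must be three distinct labels")
  if (cfg$baseline_rate < 0) stop("baseline_rate must be >= 0")
  for (pk in c("early_peak", "late_peak", "icms_peak")) {
    p <- cfg[[pk]]
    if (p$amplitude < 0) stop(pk, " amplitude must be >= 0")
    if (p$width_ms <= 0) stop(pk, " width must be > 0")
  }
  for (d in c("sample_rate", "trial_period_s", "pre_trial_s",
              "solenoid_contact_ms", "artifact_tau_ms"))
    if (cfg[[d]] <= 0) stop(d, " must be > 0")
  if (cfg$artifact_amplitude <= 450)
    stop("artifact_amplitude must exceed 450 uV")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$lesion_mean <= 0 || cfg$lesion_sd <= 0)
    stop("lesion distribution parameters must be > 0")
  if (cfg$pre_trial_s + (cfg$solenoid_onset_ms + 250) / 1000 > cfg$trial_period_s)
    stop("trial_period_s too short for the analysis window")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d animal(s), %d channels/area (%d shanks x %d sites), %g kHz\n",
              x$n_animals, x$channels_per_area, x$n_shanks, x$sites_per_shank,
              x$sample_rate / 1000))
  cat(sprintf("  %d trials/type of {%s}, %g s period\n", x$n_trials_per_type,
              paste(x$trial_types, collapse = ", "), x$trial_period_s))
  cat(sprintf("  baseline %g sp/s; peaks: early %g@%gms, late %g@%gms, ICMS %g@+%gms\n",
              x$baseline_rate, x$early_peak$amplitude, x$early_peak$latency_ms,
              x$late_peak$amplitude, x$late_peak$latency_ms,
              x$icms_peak$amplitude, x$icms_peak$latency_ms))
  invisible(x)
}

## internal: deterministic sub-seed derivation (kept below 2^31)
derive_seed <- function(seed, animal, stream) {
  as.integer((as.numeric(seed) * 48271 + animal * 16807 + stream * 69621) %%
               2147483629) + 1L
}

#' Trial-type composition helpers
#'
#' @param type trial-type label.
#' @param cfg a [sim_config()].
#' @return logical: does the trial type include a solenoid strike / an ICMS
#'   pulse?
#' @keywords internal
has_solenoid <- function(type, cfg) type %in% cfg$trial_types[c(1, 3)]

#' @rdname has_solenoid
#' @keywords internal
has_icms <- function(type, cfg) type %in% cfg$trial_types[c(2, 3)]
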