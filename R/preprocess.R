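#' Bandpass filter specification
#'
#' 4th-order elliptic IIR bandpass used to isolate the spike band. Passband
#' ripple and stopband attenuation default to 0.1 dB and 40 dB.
#'
#' @param order overall filter order (even; the analog prototype has
#'   `order/2` pole pairs).
#' @param low,high passband cutoffs, Hz.
#' @param ripple_db passband ripple, dB.
#' @param atten_db stopband attenuation, dB.
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(order = 4, low = 300, high = 5000,
                        ripple_db = 0.1, atten_db = 40) {
  if (order %% 2 != 0 || order < 2) stop("order must be a positive even number")
  if (!(0 < low && low < high)) stop("need 0 < low cutoff < high cutoff")
  structure(list(order = order, low = low, high = high,
                 ripple_db = ripple_db, atten_db = atten_db),
            class = "filter_spec")
}

#' Design the elliptic bandpass for a given sampling rate
#'
#' @param spec a [filter_spec()].
#' @param rate sampling rate, Hz.
#' @return list with numerator `b` and denominator `a` coefficients.
#' @export
design_bandpass <- function(spec, rate) {
  nyq <- rate / 2
  if (spec$high >= nyq) stop("high cutoff must be below the Nyquist frequency")
  fl <- signal::ellip(spec$order / 2, spec$ripple_db, spec$atten_db,
                      c(spec$low, spec$high) / nyq, type = "pass")
  list(b = as.numeric(fl$b), a = as.numeric(fl$a))
}

## Zero-phase forward-backward IIR filtering with reflected-edge padding
## (MATLAB filtfilt-style initial-condition handling by signal extension).
filtfilt_iir <- function(b, a, x) {
  n <- length(x)
  nf <- 3L * (max(length(a), length(b)) - 1L)
  if (n <= nf) stop("signal too short for zero-phase filtering")
  xp <- c(2 * x[1] - x[(nf + 1):2], x, 2 * x[n] - x[(n - 1):(n - nf)])
  y <- .iir_filter(b, a, xp)
  y <- rev(.iir_filter(b, a, rev(y)))
  y[(nf + 1):(nf + n)]
}

#' Zero-phase bandpass filtering of voltage traces
#'
#' Applies the designed elliptic bandpass forward and backward so that spike
#' times are not lag-shifted. Accepts a vector (one channel) or a samples x
#' channels matrix.
#'
#' @param x numeric vector or matrix of samples (microvolts).
#' @param spec a [filter_spec()].
#' @param rate sampling rate, Hz.
#' @return filtered samples, same shape as the input.
#' @export
bandpass_filter <- function(x, spec = filter_spec(), rate) {
  ba <- design_bandpass(spec, rate)
  if (is.matrix(x)) {
    for (j in seq_len(ncol(x))) x[, j] <- filtfilt_iir(ba$b, ba$a, x[, j])
    x
  } else {
    filtfilt_iir(ba$b, ba$a, x)
  }
}

#' Common average reference
#'
#' Estimates a virtual reference as the ensemble mean of all channels on an
#' array and subtracts it from every channel, removing shared noise. When
#' `array_id` is supplied the reference is computed within each array.
#'
#' @param traces samples x channels matrix.
#' @param array_id optional vector (length = channels) of array labels.
#' @return re-referenced matrix; the ensemble mean of the output is exactly
#'   zero at every sample (per array).
#' @export
common_average_reference <- function(traces, array_id = NULL) {
  if (!is.matrix(traces)) stop("traces must be a samples x channels matrix")
  groups <- if (is.null(array_id)) list(seq_len(ncol(traces)))
            else split(seq_len(ncol(traces)), array_id)
  for (idx in groups) {
    if (length(idx) < 2)
      stop("common average reference undefined for a single-channel array")
    ref <- rowMeans(traces[, idx, drop = FALSE])
    traces[, idx] <- traces[, idx, drop = FALSE] - ref
  }
  traces
}

#' Smoothed nonlinear energy operator
#'
#' psi[n] = x[n]^2 - x[n-k] x[n+k], convolved with a unit-area triangular
#' window of `smooth_width` samples. The operator responds to simultaneous
#' amplitude and frequency transients, emphasizing spikes over background.
#' Boundary samples (where zero-padding enters either the operator or the
#' smoothing window) are flagged via the `boundary` attribute.
#'
#' @param x numeric trace.
#' @param k operator delay in samples.
#' @param smooth_width odd window width in samples; 1 disables smoothing.
#' @return numeric vector of energy values with attribute `boundary`
#'   (logical, TRUE at edge samples computed with zero-padding).
#' @export
sneo <- function(x, k = 1, smooth_width = 5) {
  n <- length(x)
  if (k < 1) stop("k must be >= 1")
  if (smooth_width %% 2 != 1) stop("smooth_width must be odd")
  if (n < 2 * k + 1) stop("trace shorter than 2k+1 samples")
  psi <- x^2
  idx <- (k + 1):(n - k)
  psi[idx] <- x[idx]^2 - x[idx - k] * x[idx + k]
  ## zero-padded ends: x[n-k] or x[n+k] taken as 0
  psi[seq_len(k)] <- x[seq_len(k)]^2
  psi[(n - k + 1):n] <- x[(n - k + 1):n]^2
  half <- (smooth_width - 1L) / 2L
  if (smooth_width > 1) {
    w <- (half + 1L) - abs(seq(-half, half))
    w <- w / sum(w)
    psi <- as.numeric(stats::filter(psi, w, sides = 2))
    if (half > 0) {
      psi[seq_len(half)] <- 0
      psi[(n - half + 1):n] <- 0
    }
  }
  bnd <- rep(FALSE, n)
  m <- k + half
  bnd[seq_len(m)] <- TRUE
  bnd[(n - m + 1):n] <- TRUE
  attr(psi, "boundary") <- bnd
  psi
}

#' Spike-detection parameters
#'
#' @param k nonlinear-energy operator delay, samples.
#' @param smooth_width energy smoothing width, samples (odd).
#' @param amplitude_floor minimum absolute waveform amplitude within
#'   +/-0.5 ms of a candidate, microvolts.
#' @param artifact_threshold absolute voltage defining an artifact sample,
#'   microvolts.
#' @param artifact_halo_ms rejection halo around artifact samples and the
#'   blanking half-width around ICMS pulses, ms.
#' @param dead_time_ms minimum separation of accepted events; closer events
#'   are merged keeping the larger energy peak.
#' @param threshold_multiplier energy threshold as a multiple of the
#'   median-based noise scale of the smoothed energy trace.
#' @return object of class `detection_params`.
#' @export
detection_params <- function(k = 1, smooth_width = 5, amplitude_floor = 15,
                             artifact_threshold = 450, artifact_halo_ms = 4,
                             dead_time_ms = 1, threshold_multiplier = 10) {
  if (smooth_width %% 2 != 1) stop("smooth_width must be odd")
  if (artifact_halo_ms <= 0) stop("artifact_halo_ms must be > 0")
  if (amplitude_floor <= 0) stop("amplitude_floor must be > 0")
  structure(list(k = k, smooth_width = smooth_width,
                 amplitude_floor = amplitude_floor,
                 artifact_threshold = artifact_threshold,
                 artifact_halo_ms = artifact_halo_ms,
                 dead_time_ms = dead_time_ms,
                 threshold_multiplier = threshold_multiplier),
            class = "detection_params")
}

#' Detect multi-unit spikes on a conditioned trace
#'
#' Candidate events are samples where the smoothed nonlinear energy exceeds
#' `threshold_multiplier` times a median-based noise scale of the energy
#' trace, subject to the waveform reaching `amplitude_floor` (absolute)
#' within +/-0.5 ms. The event time is the local energy maximum; events
#' closer than the dead time are merged keeping the larger energy peak.
#'
#' @param x filtered, referenced trace (microvolts).
#' @param params a [detection_params()].
#' @param rate sampling rate, Hz.
#' @return data.frame with `sample`, `time_s`, `amplitude_uv` (signed peak
#'   within +/-0.5 ms), `energy` (smoothed operator value at the event).
#' @export
detect_spikes <- function(x, params = detection_params(), rate) {
  if (anyNA(x) || any(!is.finite(x))) stop("trace contains non-finite samples")
  n <- length(x)
  psi <- sneo(x, params$k, params$smooth_width)
  noise_scale <- stats::median(abs(psi))
  thr <- params$threshold_multiplier * noise_scale
  above <- psi > thr & !attr(psi, "boundary")
  if (!any(above))
    return(data.frame(sample = integer(0), time_s = numeric(0),
                      amplitude_uv = numeric(0), energy = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  ev <- vapply(runs, function(j) {
    seg <- starts[j]:ends[j]
    seg[which.max(psi[seg])]
  }, integer(1))
  ## amplitude floor on the raw waveform within +/-0.5 ms
  hw <- round(5e-4 * rate)
  amp <- vapply(ev, function(i) {
    seg <- x[max(1L, i - hw):min(n, i + hw)]
    seg[which.max(abs(seg))]
  }, numeric(1))
  keep <- abs(amp) >= params$amplitude_floor
  ev <- ev[keep]; amp <- amp[keep]
  if (length(ev) > 1) {
    ## dead-time merge, keeping the larger energy peak
    dead <- round(params$dead_time_ms / 1000 * rate)
    keep_idx <- integer(0)
    cur <- 1L
    for (i in seq_along(ev)[-1]) {
      if (ev[i] - ev[cur] < dead) {
        if (psi[ev[i]] > psi[ev[cur]]) cur <- i
      } else {
        keep_idx <- c(keep_idx, cur)
        cur <- i
      }
    }
    keep_idx <- c(keep_idx, cur)
    ev <- ev[keep_idx]; amp <- amp[keep_idx]
  }
  data.frame(sample = ev, time_s = (ev - 1L) / rate, amplitude_uv = amp,
             energy = psi[ev])
}

#' Flag events near artifacts and ICMS pulses
#'
#' Any sample whose absolute voltage exceeds the artifact threshold defines
#' an artifact; events within the halo (default +/-4 ms, closed interval) of
#' any artifact sample are flagged `artifact_halo`. Events within the same
#' halo of an ICMS pulse time are flagged `icms_blank` (the imposed blanking
#' period). The accepted set excludes all flagged events.
#'
#' @param events data.frame from [detect_spikes()].
#' @param trace the trace the events were detected on (same time base).
#' @param params a [detection_params()].
#' @param rate sampling rate, Hz.
#' @param icms_times ICMS pulse times, seconds.
#' @return `events` with added columns `accepted` (logical) and `reason`
#'   (`NA`, `"artifact_halo"` or `"icms_blank"`).
#' @export
reject_artifacts <- function(events, trace, params = detection_params(), rate,
                             icms_times = numeric(0)) {
  ## closed interval, with half-sample slack so the boundary is not lost to
  ## floating-point rounding of sample-quantized times
  halo <- params$artifact_halo_ms / 1000 + 0.5 / rate
  reason <- rep(NA_character_, nrow(events))
  bad <- which(abs(trace) > params$artifact_threshold)
  if (length(bad)) {
    ## collapse artifact samples into intervals, then dilate by the halo
    brk <- which(diff(bad) > 1)
    lo <- bad[c(1L, brk + 1L)]
    hi <- bad[c(brk, length(bad))]
    t_lo <- (lo - 1L) / rate - halo
    t_hi <- (hi - 1L) / rate + halo
    for (i in seq_along(t_lo)) {
      hit <- events$time_s >= t_lo[i] & events$time_s <= t_hi[i]
      reason[hit & is.na(reason)] <- "artifact_halo"
    }
  }
  for (it in icms_times) {
    hit <- abs(events$time_s - it) <= halo
    reason[hit & is.na(reason)] <- "icms_blank"
  }
  events$accepted <- is.na(reason)
  events$reason <- reason
  events
}

#' Detect spikes across all channels of a recording
#'
#' Runs the conditioning and detection chain in the canonical order:
#' bandpass filter, common average reference per array, nonlinear-energy
#' detection per channel, artifact/blanking rejection.
#'
#' @param rec a `raw_recording`.
#' @param params a [detection_params()].
#' @param spec a [filter_spec()].
#' @return data.frame of events over channels with columns `animal`,
#'   `channel`, `sample`, `time_s`, `amplitude_uv`, `energy`, `accepted`,
#'   `reason`; per-channel accepted counts in attribute `counts`.
#' @export
#' Detect spikes for one animal of a planned cohort, one channel at a time
#'
#' Memory-bounded equivalent of [synthesize_animal()] followed by
#' [detect_recording()]: each channel's trace is synthesized from its own
#' seed, filtered, re-referenced and detected without ever materializing the
#' full samples x channels matrix. Because the bandpass filter is linear,
#' the common average reference of the filtered array equals the filtered
#' per-array mean trace, which is accumulated in a first streaming pass.
#'
#' @param plan a `cohort_plan`.
#' @param animal animal index.
#' @param spikes ground-truth spikes for the animal (simulated if NULL).
#' @param params a [detection_params()].
#' @param spec a [filter_spec()].
#' @return as [detect_recording()].
#' @export
detect_animal <- function(plan, animal, spikes = NULL,
                          params = detection_params(), spec = filter_spec()) {
  cfg <- plan$config
  if (is.null(spikes)) spikes <- simulate_animal_spikes(plan, animal)
  chans <- plan$channels[plan$channels$animal == animal, ]
  sch <- plan$schedule
  fs <- cfg$sample_rate
  n <- round((max(sch$t_start) + cfg$trial_period_s) * fs)
  tpl <- cfg$spike_template %||% spike_template_default(fs, cfg$spike_amplitude)
  icms_times <- sch$icms_time[!is.na(sch$icms_time)]
  seeds <- animal_channel_seeds(plan, animal)
  ba <- design_bandpass(spec, fs)
  gen <- function(c) channel_trace(n, spikes$time[spikes$channel == chans$channel[c]],
                                   tpl, icms_times, chans$artifact_gain[c],
                                   cfg, seeds[c])
  ## pass 1: filtered per-array mean trace = the common average reference
  refs <- list()
  for (ar in unique(chans$area)) {
    idx <- which(chans$area == ar)
    if (length(idx) < 2)
      stop("common average reference undefined for a single-channel array")
    acc <- numeric(n)
    for (c in idx) acc <- acc + gen(c)
    refs[[ar]] <- filtfilt_iir(ba$b, ba$a, acc / length(idx))
  }
  ## pass 2: filter, re-reference, detect, reject
  out <- vector("list", nrow(chans))
  for (c in seq_len(nrow(chans))) {
    x <- filtfilt_iir(ba$b, ba$a, gen(c)) - refs[[chans$area[c]]]
    ev <- detect_spikes(x, params, fs)
    ev <- reject_artifacts(ev, x, params, fs, icms_times)
    if (nrow(ev)) {
      ev$channel <- chans$channel[c]
      ev$animal <- animal
    }
    out[[c]] <- ev
  }
  out <- out[vapply(out, nrow, integer(1)) > 0]
  if (length(out)) do.call(rbind, out) else
    data.frame(sample = integer(0), time_s = numeric(0),
               amplitude_uv = numeric(0), energy = numeric(0),
               accepted = logical(0), reason = character(0),
               channel = integer(0), animal = integer(0))
}

detect_recording <- function(rec, params = detection_params(),
                             spec = filter_spec()) {
  fs <- rec$sample_rate
  tr <- bandpass_filter(rec$trace, spec, fs)
  tr <- common_average_reference(tr, rec$channels$area)
  icms_times <- rec$schedule$icms_time[!is.na(rec$schedule$icms_time)]
  out <- vector("list", ncol(tr))
  for (c in seq_len(ncol(tr))) {
    ev <- detect_spikes(tr[, c], params, fs)
    ev <- reject_artifacts(ev, tr[, c], params, fs, icms_times)
    if (nrow(ev)) {
      ev$channel <- rec$channels$channel[c]
      ev$animal <- if (is.null(rec$animal)) 1L else rec$animal
    }
    out[[c]] <- ev
  }
  out <- out[vapply(out, nrow, integer(1)) > 0]
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample = integer(0), time_s = numeric(0),
               amplitude_uv = numeric(0), energy = numeric(0),
               accepted = logical(0), reason = character(0),
               channel = integer(0), animal = integer(0))
  counts <- tapply(res$accepted, factor(res$channel,
                                        levels = rec$channels$channel), sum)
  counts[is.na(counts)] <- 0L
  attr(res, "counts") <- counts
  res
}
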