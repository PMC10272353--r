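#' Bin spike times into per-trial counts
#'
#' Half-open 5-ms bins `[t, t+width)` anchored at each trial zero.
#'
#' @param times spike times, absolute seconds.
#' @param trial_zeros trial-zero times, seconds (one per trial).
#' @param window analysis window relative to trial zero, ms (length 2); its
#'   length must be divisible by the bin width.
#' @param bin_ms bin width, ms.
#' @return integer matrix trials x bins with attribute `bin_starts_ms`.
#' @export
bin_spikes <- function(times, trial_zeros, window = c(-250, 350), bin_ms = 5) {
  if (anyNA(times) || any(!is.finite(times)))
    stop("spike times must be finite")
  span <- diff(window)
  if (span <= 0 || abs(span / bin_ms - round(span / bin_ms)) > 1e-9)
    stop("window length must be a positive multiple of the bin width")
  nb <- as.integer(round(span / bin_ms))
  counts <- matrix(0L, length(trial_zeros), nb)
  for (i in seq_along(trial_zeros)) {
    rel <- (times - trial_zeros[i]) * 1000
    ## picosecond guard so sample-aligned times land in their nominal bin
    idx <- floor((rel - window[1]) / bin_ms + 1e-9)
    idx <- idx[idx >= 0 & idx < nb]
    if (length(idx)) {
      tb <- tabulate(idx + 1L, nbins = nb)
      counts[i, ] <- tb
    }
  }
  attr(counts, "bin_starts_ms") <- window[1] + bin_ms * (seq_len(nb) - 1L)
  counts
}

#' Square-root-transformed mean spike rate
#'
#' The variance-stabilizing transform applied to the trial-mean rate:
#' `sqrt(mean count / bin width)`, in units of sqrt(spikes/s).
#'
#' @param counts trials x bins matrix from [bin_spikes()].
#' @param bin_width_s bin width, seconds.
#' @return numeric vector, one value per bin.
#' @export
sqrt_rate <- function(counts, bin_width_s = 0.005) {
  if (!is.matrix(counts)) counts <- matrix(counts, nrow = 1)
  if (nrow(counts) == 0) stop("at least one trial required")
  if (any(counts < 0)) stop("counts must be >= 0")
  sqrt(colMeans(counts) / bin_width_s)
}

## Kaiser window, w[i] = I0(beta * sqrt(1 - ((i - M)/M)^2)) / I0(beta).
## Exponentially scaled Bessel ratios keep this stable for large beta.
kaiser_window <- function(n, beta) {
  m <- (n - 1) / 2
  z <- beta * sqrt(pmax(0, 1 - ((seq_len(n) - 1 - m) / m)^2))
  exp(z - beta) * besselI(z, 0, expon.scaled = TRUE) /
    besselI(beta, 0, expon.scaled = TRUE)
}

## Hat matrix of the Kaiser-weighted polynomial fit over one window:
## row r gives the linear combination of the window samples that evaluates
## the weighted least-squares polynomial at offset r.
sg_kaiser_hat <- function(window = 21, beta = 38, poly_order = 3) {
  m <- (window - 1) / 2
  u <- (seq_len(window) - 1 - m) / m
  X <- outer(u, 0:poly_order, `^`)
  W <- diag(kaiser_window(window, beta))
  X %*% solve(crossprod(X, W %*% X), crossprod(X, W))
}

#' Kaiser-weighted Savitzky-Golay smoothing
#'
#' Local polynomial regression: each interior point is replaced by the center
#' value of an order-`poly_order` polynomial fit by weighted least squares
#' over the `window`-point neighborhood, with Kaiser(`window`, `beta`)
#' weights. Edge points are evaluated from the polynomial fit over the first
#' (last) full window, and the first and last `(window-1)/2` points are
#' flagged edge-unreliable.
#'
#' Edge samples (the first and last `(window-1)/2` points) cannot be covered
#' by a full centered window; they are passed through unsmoothed and flagged
#' edge-unreliable, mirroring the analysis' practice of disregarding 50 ms of
#' bins at each end of a smoothed segment. (A sharply concentrated Kaiser
#' weight makes polynomial extrapolation to the window ends ill-conditioned,
#' so passthrough is the numerically safe edge policy.)
#'
#' @param y numeric series (e.g. per-bin sqrt rates).
#' @param window window length, samples (odd).
#' @param beta Kaiser shape parameter.
#' @param poly_order polynomial order.
#' @return smoothed numeric vector with logical attribute `edge` marking
#'   edge-unreliable samples.
#' @export
smooth_sg_kaiser <- function(y, window = 21, beta = 38, poly_order = 3) {
  n <- length(y)
  if (n < window) stop("series shorter than the smoothing window")
  m <- (window - 1L) / 2L
  kern <- sg_kaiser_kernel(window, beta, poly_order)
  out <- as.numeric(stats::filter(y, rev(kern), sides = 2))
  edge_idx <- c(seq_len(m), (n - m + 1L):n)
  out[edge_idx] <- y[edge_idx]
  edge <- rep(FALSE, n)
  edge[edge_idx] <- TRUE
  attr(out, "edge") <- edge
  out
}

## central equivalent kernel, memoized (the hat matrix depends only on the
## window geometry)
.sg_cache <- new.env(parent = emptyenv())
sg_kaiser_kernel <- function(window, beta, poly_order) {
  key <- paste(window, beta, poly_order)
  if (is.null(.sg_cache[[key]]))
    .sg_cache[[key]] <- sg_kaiser_hat(window, beta, poly_order)[(window + 1L) / 2L, ]
  .sg_cache[[key]]
}

#' Baseline statistics and channel inclusion
#'
#' Mean and standard deviation of the smoothed sqrt rate over the baseline
#' window (by default the 30 bins in [-200, -50) ms, i.e. the 250 ms of
#' recorded pre-trial baseline with 50 ms trimmed at each end to avoid
#' smoothing-edge artifact). The evoked-significance threshold is the mean
#' plus three standard deviations; channels whose baseline mean falls below
#' 2.4 sqrt(spikes/s) are excluded as too quiet to power the analyses.
#'
#' @param rate per-bin (smoothed) sqrt-rate series.
#' @param bin_starts_ms bin start times, ms relative to trial zero.
#' @param baseline_window ms interval used for the statistics.
#' @param sd_mult threshold multiplier on the baseline sd.
#' @param include_cutoff inclusion cutoff on the baseline mean,
#'   sqrt(spikes/s).
#' @return list of class `baseline_stats`: `mean`, `sd`, `threshold`,
#'   `included`, `window`, `n_bins`.
#' @export
baseline_stats <- function(rate, bin_starts_ms, baseline_window = c(-200, -50),
                           sd_mult = 3, include_cutoff = 2.4) {
  if (min(bin_starts_ms) > baseline_window[1] - 50)
    stop("insufficient pre-trial baseline (need 50 ms margin before the window)")
  sel <- bin_starts_ms >= baseline_window[1] & bin_starts_ms < baseline_window[2]
  if (!any(sel)) stop("no bins in the baseline window")
  v <- rate[sel]
  m <- mean(v)
  s <- stats::sd(v)
  structure(list(mean = m, sd = s, threshold = m + sd_mult * s,
                 included = m >= include_cutoff,
                 window = baseline_window, n_bins = sum(sel)),
            class = "baseline_stats")
}

#' Per-bin evoked-activity flags and channel-level significance
#'
#' A bin is flagged when the smoothed rate exceeds the baseline threshold;
#' the channel's response is significant when any non-edge bin at or after
#' the stimulus onset is flagged.
#'
#' @param smoothed smoothed sqrt-rate series (with `edge` attribute from
#'   [smooth_sg_kaiser()], or supply `edge`).
#' @param bin_starts_ms bin start times, ms.
#' @param stats a [baseline_stats()].
#' @param stim_onset_ms stimulus onset, ms relative to trial zero.
#' @param edge optional logical vector of edge-unreliable bins.
#' @return list: `flags` (per-bin logical), `significant` (scalar logical).
#' @export
evoked_flags <- function(smoothed, bin_starts_ms, stats, stim_onset_ms = 50,
                         edge = attr(smoothed, "edge")) {
  if (is.null(edge)) edge <- rep(FALSE, length(smoothed))
  flags <- as.numeric(smoothed) > stats$threshold
  post <- bin_starts_ms >= stim_onset_ms
  list(flags = flags, significant = any(flags & post & !edge))
}

#' Bootstrap confidence band for the smoothed sqrt rate
#'
#' Percentile bootstrap over trials: trials are resampled with replacement,
#' the smoothed sqrt rate recomputed, and pointwise quantiles taken. The band
#' is widened, if necessary, to contain the point estimate.
#'
#' @param counts trials x bins matrix.
#' @param bin_width_s bin width, seconds.
#' @param n_boot bootstrap resamples (a warning is issued below 100).
#' @param level band coverage level.
#' @param smooth apply [smooth_sg_kaiser()] to each resample (default TRUE
#'   when the series is long enough).
#' @return list: `lower`, `upper`, `estimate` (per bin).
#' @export
confidence_band <- function(counts, bin_width_s = 0.005, n_boot = 1000,
                            level = 0.95, smooth = ncol(counts) >= 21) {
  if (nrow(counts) < 2) stop("at least two trials required")
  if (n_boot < 100) warning("n_boot < 100: band quantiles will be unstable")
  stat <- function(m) {
    r <- sqrt_rate(m, bin_width_s)
    if (smooth) as.numeric(smooth_sg_kaiser(r)) else r
  }
  est <- stat(counts)
  nb <- ncol(counts)
  boots <- matrix(0, n_boot, nb)
  nt <- nrow(counts)
  for (b in seq_len(n_boot))
    boots[b, ] <- stat(counts[sample.int(nt, nt, replace = TRUE), , drop = FALSE])
  alpha <- (1 - level) / 2
  lower <- apply(boots, 2, stats::quantile, probs = alpha, names = FALSE)
  upper <- apply(boots, 2, stats::quantile, probs = 1 - alpha, names = FALSE)
  list(lower = pmin(lower, est), upper = pmax(upper, est), estimate = est)
}

#' Build peri-event time histograms for every channel and trial type
#'
#' Bins accepted spikes per channel and trial type over the analysis window,
#' applies the sqrt transform and Kaiser-weighted smoothing, and computes
#' baseline statistics, inclusion and evoked significance. ICMS-only trials
#' use the same grid (aligned to where solenoid onset would fall) so
#' downstream response matrices are commensurate.
#'
#' @param events event data.frame from [detect_recording()] (only rows with
#'   `accepted` are used).
#' @param schedule trial schedule.
#' @param channels channel table (needs `channel`, `area`; optional
#'   `animal`, `lesion_volume`).
#' @param window,bin_ms PETH window (ms, relative to trial zero) and bin
#'   width.
#' @param stim_onset_ms solenoid onset relative to trial zero, ms.
#' @param sd_mult,include_cutoff see [baseline_stats()].
#' @param n_boot bootstrap resamples for the confidence band; 0 disables.
#' @return list: `peth` (long data.frame: one row per channel x trial type x
#'   bin with raw, smoothed, band, edge flag), `summary` (one row per
#'   channel x trial type: baseline stats, inclusion, significance),
#'   `counts` (nested list of count matrices, `[[type]][[channel]]`).
#' @export
compute_peths <- function(events, schedule, channels, window = c(-250, 350),
                          bin_ms = 5, stim_onset_ms = 50, sd_mult = 3,
                          include_cutoff = 2.4, n_boot = 0) {
  acc <- events[events$accepted, , drop = FALSE]
  types <- unique(schedule$type)
  peth_rows <- list()
  sum_rows <- list()
  count_store <- stats::setNames(vector("list", length(types)), types)
  for (ty in types) {
    zeros <- schedule$t_zero[schedule$type == ty]
    count_store[[ty]] <- list()
    for (ci in seq_len(nrow(channels))) {
      ch <- channels$channel[ci]
      tms <- acc$time_s[acc$channel == ch]
      counts <- bin_spikes(tms, zeros, window, bin_ms)
      starts <- attr(counts, "bin_starts_ms")
      raw <- sqrt_rate(counts, bin_ms / 1000)
      sm <- smooth_sg_kaiser(raw)
      bs <- baseline_stats(as.numeric(sm), starts, sd_mult = sd_mult,
                           include_cutoff = include_cutoff)
      ef <- evoked_flags(sm, starts, bs, stim_onset_ms)
      band <- if (n_boot > 0)
        confidence_band(counts, bin_ms / 1000, n_boot) else
        list(lower = rep(NA_real_, length(raw)), upper = rep(NA_real_, length(raw)))
      ani <- if (is.null(channels$animal)) 1L else channels$animal[ci]
      peth_rows[[length(peth_rows) + 1L]] <- data.frame(
        animal = ani, channel = ch, area = channels$area[ci], trial_type = ty,
        bin_start_ms = starts, raw_sqrt_rate = raw,
        smoothed = as.numeric(sm), ci_lo = band$lower, ci_hi = band$upper,
        edge = attr(sm, "edge"), evoked = ef$flags,
        stringsAsFactors = FALSE)
      sum_rows[[length(sum_rows) + 1L]] <- data.frame(
        animal = ani, channel = ch, area = channels$area[ci], trial_type = ty,
        lesion_volume = if (is.null(channels$lesion_volume)) NA_real_
                        else channels$lesion_volume[ci],
        n_trials = length(zeros), baseline_mean = bs$mean,
        baseline_sd = bs$sd, threshold = bs$threshold,
        included = bs$included, significant = ef$significant,
        stringsAsFactors = FALSE)
      count_store[[ty]][[as.character(ch)]] <- counts
    }
  }
  list(peth = do.call(rbind, peth_rows), summary = do.call(rbind, sum_rows),
       counts = count_store)
}
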