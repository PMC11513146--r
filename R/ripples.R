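#' Ripple-band envelope of an LFP trace
#'
#' Band-passes the trace between 100 and 250 Hz with a zero-phase FFT
#' filter, takes the magnitude of the analytic (Hilbert) signal -- or the
#' rectified filtered trace -- and smooths it with a Gaussian kernel
#' (s.d. 4 ms).
#'
#' @param lfp numeric vector of LFP samples, or an `lfp_trace` object.
#' @param fs sampling rate in Hz (ignored when `lfp` is an `lfp_trace`);
#'   must be >= 1000.
#' @param lo,hi ripple band edges in Hz.
#' @param smooth_sd_ms Gaussian smoothing s.d. in ms.
#' @param method `"hilbert"` (default) or `"rectify"`.
#' @return numeric envelope, same length as the input.
#' @export
ripple_envelope <- function(lfp, fs = NULL, lo = 100, hi = 250,
                            smooth_sd_ms = 4, method = c("hilbert", "rectify")) {
  method <- match.arg(method)
  if (inherits(lfp, "lfp_trace")) {
    fs <- lfp$fs
    lfp <- lfp$samples
  }
  if (is.null(fs)) stop("fs is required for a bare numeric trace")
  if (fs < 1000) stop("fs must be >= 1000 Hz")
  bad <- which(!is.finite(lfp))
  if (length(bad)) stop("non-finite sample in input at index ", bad[1])
  env <- if (method == "hilbert") {
    Mod(fft_bandpass(lfp, fs, lo, hi, analytic = TRUE))
  } else {
    abs(fft_bandpass(lfp, fs, lo, hi))
  }
  gauss_smooth(env, smooth_sd_ms / 1000 * fs)
}

#' Detect ripples from an envelope
#'
#' Candidate events are contiguous runs where the z-scored envelope exceeds
#' `boundary_sd`; a run becomes a ripple when its peak exceeds
#' `peak_threshold_sd`.  Onset and offset are the `boundary_sd` crossings
#' around the peak, so overlapping candidates are merged by construction
#' (one boundary-level run, one event, largest peak kept).  Events shorter
#' than `min_duration_ms` are dropped.  The envelope mean and s.d. are
#' computed over `stats_intervals` when given (e.g. slow-wave-sleep
#' intervals), else over the whole segment.
#'
#' @param envelope numeric envelope from [ripple_envelope()].
#' @param fs sampling rate (Hz).
#' @param peak_threshold_sd peak criterion in s.d. above the mean
#'   (default 5; 3 is used for content analyses).
#' @param boundary_sd onset/offset criterion (default 1).
#' @param min_duration_ms minimum event duration (default 20).
#' @param stats_intervals optional data.frame/matrix of `start_s`, `end_s`
#'   intervals over which mean/s.d. are computed and inside which events
#'   must fall.
#' @param t0 time of the first sample (s).
#' @return data.frame of class `ripple_events`: `onset_s`, `peak_s`,
#'   `offset_s`, `amplitude_sd`, `duration_ms`, `label`.
#' @export
detect_ripples <- function(envelope, fs, peak_threshold_sd = 5,
                           boundary_sd = 1, min_duration_ms = 20,
                           stats_intervals = NULL, t0 = 0) {
  if (peak_threshold_sd <= boundary_sd) {
    stop("peak_threshold_sd must exceed boundary_sd")
  }
  empty <- data.frame(onset_s = numeric(0), peak_s = numeric(0),
                      offset_s = numeric(0), amplitude_sd = numeric(0),
                      duration_ms = numeric(0), label = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("ripple_events", "data.frame")
  if (!length(envelope)) return(empty)
  tt <- t0 + (seq_along(envelope) - 1) / fs
  in_stats <- rep(TRUE, length(envelope))
  if (!is.null(stats_intervals)) {
    si <- as.data.frame(stats_intervals)
    in_stats <- rep(FALSE, length(envelope))
    for (i in seq_len(nrow(si))) {
      in_stats[tt >= si[i, 1] & tt < si[i, 2]] <- TRUE
    }
    if (!any(in_stats)) return(empty)
  }
  mu <- mean(envelope[in_stats])
  sdv <- stats::sd(envelope[in_stats])
  if (!is.finite(sdv) || sdv == 0) return(empty)
  z <- (envelope - mu) / sdv
  above <- z > boundary_sd & in_stats
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  # only runs containing at least one supra-threshold sample can yield an
  # event; skipping the rest keeps this linear in the number of candidates
  hot <- which(z > peak_threshold_sd & in_stats)
  if (length(hot)) {
    hot_runs <- findInterval(hot, starts[keep])
    keep <- keep[sort(unique(hot_runs[hot_runs >= 1]))]
  } else {
    keep <- integer(0)
  }
  out <- list()
  for (k in keep) {
    i0 <- starts[k]; i1 <- ends[k]
    seg <- z[i0:i1]
    pk <- which.max(seg)
    if (seg[pk] <= peak_threshold_sd) next
    dur_ms <- (i1 - i0) / fs * 1000
    if (dur_ms < min_duration_ms) next
    out[[length(out) + 1L]] <- c(tt[i0], tt[i0 + pk - 1L], tt[i1],
                                 seg[pk], dur_ms)
  }
  if (!length(out)) return(empty)
  m <- do.call(rbind, out)
  ev <- data.frame(onset_s = m[, 1], peak_s = m[, 2], offset_s = m[, 3],
                   amplitude_sd = m[, 4], duration_ms = m[, 5],
                   label = "unlabeled", stringsAsFactors = FALSE)
  ev <- ev[order(ev$onset_s), ]
  rownames(ev) <- NULL
  class(ev) <- c("ripple_events", "data.frame")
  ev
}

#' Simulated closed-loop ripple trigger
#'
#' Streams through the LFP with a causal FIR band-pass (100-250 Hz), a
#' rectified causally smoothed envelope, and emits a trigger the first time
#' the causal envelope crosses `trigger_sd` (normalization from a leading
#' calibration segment).  Triggers honor a refractory period and can be
#' delayed (`delay_ms`), mimicking the delayed-stimulation control group.
#'
#' @param lfp numeric samples or `lfp_trace`.
#' @param fs sampling rate (Hz).
#' @param trigger_sd trigger criterion in s.d. above the calibration mean
#'   (default 8).
#' @param pulse_ms stimulation pulse length bookkeeping only (default 150).
#' @param delay_ms added delay before the pulse (0 = closed-loop,
#'   150 = delayed control).
#' @param refractory_ms minimum spacing between triggers.
#' @param calibration_s leading segment used for the envelope mean/s.d.
#' @param n_taps FIR length (odd).
#' @param reference_onsets optional true/offline ripple onsets used to
#'   report per-trigger latency.
#' @return data.frame `trigger_s` (crossing time), `pulse_s`
#'   (= trigger + delay), and `latency_ms` relative to the nearest
#'   preceding reference onset (NA when unmatched within 250 ms).
#' @export
streaming_trigger <- function(lfp, fs = NULL, trigger_sd = 8, pulse_ms = 150,
                              delay_ms = 0, refractory_ms = 200,
                              calibration_s = 60, n_taps = 81,
                              reference_onsets = NULL) {
  if (inherits(lfp, "lfp_trace")) {
    fs <- lfp$fs
    lfp <- lfp$samples
  }
  if (is.null(fs)) stop("fs is required for a bare numeric trace")
  h <- fir_bandpass(n_taps, fs, 100, 250)
  filt <- causal_filter(lfp, h)
  # causal envelope: rectify + one-sided Gaussian-weighted average (4 ms)
  k <- gaussian_kernel(0.004 * fs)
  k <- k[seq((length(k) + 1) / 2, length(k))]   # causal half
  env <- causal_filter(abs(filt), k / sum(k))
  ncal <- min(length(env), round(calibration_s * fs))
  mu <- mean(env[seq_len(ncal)])
  sdv <- stats::sd(env[seq_len(ncal)])
  z <- (env - mu) / sdv
  cross <- which(z > trigger_sd & c(-Inf, z[-length(z)]) <= trigger_sd)
  refr <- refractory_ms / 1000
  trig <- numeric(0)
  last <- -Inf
  tt <- (cross - 1) / fs
  for (t in tt) {
    if (t - last >= refr) {
      trig <- c(trig, t)
      last <- t
    }
  }
  lat <- rep(NA_real_, length(trig))
  if (!is.null(reference_onsets) && length(trig)) {
    ro <- sort(reference_onsets)
    idx <- findInterval(trig, ro)
    ok <- idx > 0
    lat[ok] <- (trig[ok] - ro[idx[ok]]) * 1000
    lat[!is.na(lat) & lat > 250] <- NA
    lat <- lat + delay_ms
  }
  data.frame(trigger_s = trig, pulse_s = trig + delay_ms / 1000,
             latency_ms = lat)
}

#' Heuristic slow-wave-sleep detection
#'
#' A declared heuristic (no published algorithm): in 1-s bins, the 1-4 Hz
#' delta power must dominate the broadband LFP power
#' (`delta / broadband > ratio_threshold`, default 0.5).  Contiguous
#' delta-dominated stretches (gaps up to `merge_gap_s` bridged) containing
#' at least one detected ripple, and lasting at least `min_duration_s`,
#' are returned as SWS intervals.  A dominance ratio is used instead of a
#' median split so an epoch that is entirely (or never) slow-wave sleep is
#' classified correctly.
#'
#' @param lfp numeric samples or `lfp_trace`.
#' @param fs sampling rate (Hz).
#' @param ripples optional `ripple_events`; when given, intervals without
#'   any ripple are discarded.
#' @param bin_s power bin width (s).
#' @param ratio_threshold minimum delta-to-broadband power ratio.
#' @param min_duration_s minimum interval length (default 10).
#' @param merge_gap_s sub-threshold gap length bridged between
#'   delta-dominated stretches.
#' @param t0 time of the first sample (s).
#' @return data.frame `start_s`, `end_s`.
#' @export
detect_sws <- function(lfp, fs = NULL, ripples = NULL, bin_s = 1,
                       ratio_threshold = 0.5, min_duration_s = 10,
                       merge_gap_s = 2, t0 = 0) {
  if (inherits(lfp, "lfp_trace")) {
    fs <- lfp$fs
    lfp <- lfp$samples
  }
  if (is.null(fs)) stop("fs is required for a bare numeric trace")
  delta <- Mod(fft_bandpass(lfp, fs, 1, 4, transition = 0.5, analytic = TRUE))
  nb <- floor(length(delta) / (bin_s * fs))
  if (nb < 2) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  sel <- seq_len(nb * bin_s * fs)
  pw <- colMeans(matrix(delta[sel]^2 / 2, ncol = nb))   # sinusoid power
  x0 <- lfp[sel] - mean(lfp[sel])
  total <- colMeans(matrix(x0^2, ncol = nb))
  above <- pw / pmax(total, 1e-12) > ratio_threshold
  # bridge short gaps
  r <- rle(above)
  gapfill <- r$lengths <= merge_gap_s / bin_s & !r$values
  gapfill[c(1, length(gapfill))] <- FALSE
  r$values[gapfill] <- TRUE
  above <- inverse.rle(r)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(start_s = t0 + (starts[keep] - 1) * bin_s,
                    end_s = t0 + ends[keep] * bin_s)
  out <- out[out$end_s - out$start_s >= min_duration_s, , drop = FALSE]
  if (!is.null(ripples) && nrow(out)) {
    has <- vapply(seq_len(nrow(out)), function(i) {
      any(ripples$peak_s >= out$start_s[i] & ripples$peak_s < out$end_s[i])
    }, logical(1))
    out <- out[has, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
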