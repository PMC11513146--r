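#' Label ripples as memory vs non-memory
#'
#' A (post-training-sleep) ripple is memory-associated when the memory
#' assembly's activation strength exceeds `median + threshold_sd * s.d.`
#' in at least one 25-ms bin intersecting the half-open interval
#' `(onset, onset + 150 ms]`; otherwise it is non-memory.
#'
#' @param ripples a `ripple_events` data.frame.
#' @param trace an [activation_strength()] trace of the memory assembly,
#'   or `NULL` (all ripples left unlabeled, with a warning).
#' @param threshold_sd activation criterion in s.d. above the median
#'   (default 2).
#' @param window_ms association window after onset (default 150).
#' @return `ripples` with the `label` column set to `"memory"` /
#'   `"non_memory"` (or `"unlabeled"`).
#' @export
classify_ripples <- function(ripples, trace, threshold_sd = 2,
                             window_ms = 150) {
  if (is.null(trace)) {
    warning("no memory assembly supplied; ripples left unlabeled")
    ripples$label <- "unlabeled"
    return(ripples)
  }
  stopifnot(inherits(trace, "activation_trace"))
  cut <- stats::median(trace$strength) + threshold_sd * stats::sd(trace$strength)
  act_starts <- trace$times[trace$strength > cut]
  b <- trace$bin_s
  w <- window_ms / 1000
  lab <- vapply(ripples$onset_s, function(o) {
    # bin [a, a+b) intersects (o, o+w] iff a < o + w and a + b > o
    idx <- findInterval(o + w, act_starts, left.open = TRUE)
    idx >= 1 && act_starts[idx] + b > o
  }, logical(1))
  ripples$label <- ifelse(lab, "memory", "non_memory")
  ripples
}

#' Compare amplitude and duration of memory vs non-memory ripples
#'
#' Medians, interquartile ranges, and two-sided Wilcoxon rank-sum p-values
#' for `amplitude_sd` and `duration_ms` between the two classes.  With
#' fewer than 5 ripples in a class only the summaries are returned
#' (p = NA).
#'
#' @param ripples labeled `ripple_events`.
#' @return data.frame with one row per property: medians, IQRs, n per
#'   class, and `p_value`.
#' @export
compare_ripple_properties <- function(ripples) {
  mem <- ripples[ripples$label == "memory", ]
  non <- ripples[ripples$label == "non_memory", ]
  one <- function(prop) {
    x <- mem[[prop]]; y <- non[[prop]]
    p <- if (length(x) >= 5 && length(y) >= 5) {
      stats::wilcox.test(x, y, exact = FALSE)$p.value
    } else NA_real_
    data.frame(property = prop,
               median_memory = stats::median(x), iqr_memory = stats::IQR(x),
               median_non_memory = stats::median(y),
               iqr_non_memory = stats::IQR(y),
               n_memory = length(x), n_non_memory = length(y),
               p_value = p, stringsAsFactors = FALSE)
  }
  rbind(one("amplitude_sd"), one("duration_ms"))
}

pooled_window_rate <- function(ts, onsets, half_s = 0.1) {
  if (!length(onsets)) return(NA_real_)
  n <- sum(count_in_windows(ts, onsets - half_s, onsets + half_s))
  n / (length(onsets) * 2 * half_s)
}

diff_score <- function(a, b) {
  if (!is.finite(a) || !is.finite(b) || (a + b) == 0) return(NA_real_)
  abs(a - b) / (a + b)
}

# up/down/none grouping from the z of the (memory - non-memory) smoothed
# peri-ripple rate difference, using the same 3.3-z / 3-consecutive-bin rule.
difference_group <- function(ts, mem_onsets, non_onsets, window_ms = 500,
                             bin_ms = 5, smooth_sd_ms = 15,
                             test_window_ms = 150) {
  pm <- peri_event_histogram(ts, mem_onsets, window_ms, bin_ms, smooth_sd_ms)
  pn <- peri_event_histogram(ts, non_onsets, window_ms, bin_ms, smooth_sd_ms)
  d <- pm$smoothed_hz - pn$smoothed_hz
  draw <- pm$rate_hz - pn$rate_hz
  bl <- abs(pm$lag_ms) >= 300 & abs(pm$lag_ms) <= 500
  # same variance propagation as the peri-event z (raw-bin s.d. x ||kernel||)
  sdv <- stats::sd(draw[bl]) *
    sqrt(sum(gaussian_kernel(smooth_sd_ms / bin_ms)^2))
  if (!is.finite(sdv) || sdv == 0) return(list(group = "none", pm = pm, pn = pn))
  z <- (d - mean(d[bl])) / sdv
  sel <- abs(pm$lag_ms) <= test_window_ms
  up <- first_run_start(z[sel] >= 3.3, 3)
  dn <- first_run_start(z[sel] <= -3.3, 3)
  g <- if (up > 0) "up" else if (dn > 0) "down" else "none"
  list(group = g, pm = pm, pn = pn)
}

#' Per-unit ripple-content difference scores
#'
#' For each dCA1 unit: `M` and `N` are its mean rates within +/-100 ms of
#' memory and non-memory ripple onsets (spikes pooled over ripples);
#' `m_n = |M - N| / (M + N)`.  `m1_m2` and `n1_n2` are the same contrast
#' between two random equal halves within a class (odd class sizes drop one
#' seeded random ripple).  The `group` column is the up/down/none call on
#' the z of the memory-minus-non-memory peri-ripple difference.
#'
#' @param spikes dCA1 spike data.frame (`unit_id`, `time_s`).
#' @param ripples labeled `ripple_events` with >= 2 ripples per class.
#' @param split_seed seed for the within-class halves (shared across
#'   units).
#' @param half_ms half-window around onsets (default 100).
#' @return data.frame per unit: `unit_id`, `M`, `N`, `m_n`, `m1_m2`,
#'   `n1_n2`, `group`; units silent in all windows are excluded.
#' @export
firing_difference_scores <- function(spikes, ripples, split_seed = 1,
                                     half_ms = 100) {
  mem <- ripples$onset_s[ripples$label == "memory"]
  non <- ripples$onset_s[ripples$label == "non_memory"]
  if (length(mem) < 2 || length(non) < 2) {
    stop("need at least 2 memory and 2 non-memory ripples")
  }
  set.seed(split_seed)
  halves <- function(on) {
    on <- sample(on)
    if (length(on) %% 2 == 1) on <- on[-1]   # drop one (seeded) if odd
    h <- length(on) / 2
    list(on[seq_len(h)], on[h + seq_len(h)])
  }
  mh <- halves(mem)
  nh <- halves(non)
  half_s <- half_ms / 1000
  units <- sort(unique(spikes$unit_id))
  rows <- lapply(units, function(u) {
    ts <- sort(spikes$time_s[spikes$unit_id == u])
    M <- pooled_window_rate(ts, mem, half_s)
    N <- pooled_window_rate(ts, non, half_s)
    if ((M + N) == 0) return(NULL)   # silent in all windows
    g <- difference_group(ts, mem, non)$group
    data.frame(unit_id = u, M = M, N = N,
               m_n = diff_score(M, N),
               m1_m2 = diff_score(pooled_window_rate(ts, mh[[1]], half_s),
                                  pooled_window_rate(ts, mh[[2]], half_s)),
               n1_n2 = diff_score(pooled_window_rate(ts, nh[[1]], half_s),
                                  pooled_window_rate(ts, nh[[2]], half_s)),
               group = g, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ripple selectivity index at an amplitude threshold
#'
#' `S = M / (M + N)` where `M` (`N`) is the percentage of memory
#' (non-memory) ripples whose amplitude exceeds `threshold_sd`.  Higher
#' detection thresholds should yield higher selectivity when memory ripples
#' are enlarged.
#'
#' @param ripples labeled `ripple_events` (both classes non-empty).
#' @param threshold_sd amplitude threshold(s) in s.d.; vectorized
#'   (typically 4, 6, 8).
#' @return named numeric vector of `S` values (NA where `M + N = 0`).
#' @export
selectivity_index <- function(ripples, threshold_sd = c(4, 6, 8)) {
  mem <- ripples$amplitude_sd[ripples$label == "memory"]
  non <- ripples$amplitude_sd[ripples$label == "non_memory"]
  if (!length(mem) || !length(non)) stop("both ripple classes must be non-empty")
  out <- vapply(threshold_sd, function(th) {
    M <- 100 * mean(mem > th)
    N <- 100 * mean(non > th)
    if ((M + N) == 0) NA_real_ else M / (M + N)
  }, numeric(1))
  names(out) <- paste0("sd", threshold_sd)
  out
}

#' Population peri-ripple profiles by ripple class
#'
#' Per-unit smoothed z-traces around memory and non-memory ripple onsets,
#' the up/none/down grouping from the class-difference rule, and per-class
#' peak rate and peak latency.  Units are returned ordered
#' up -> none -> down for display.
#'
#' @param spikes dCA1 spike data.frame.
#' @param ripples labeled `ripple_events`.
#' @param window_ms,bin_ms,smooth_sd_ms histogram parameters.
#' @return list with `z_memory` and `z_non_memory` (units x lag-bins
#'   matrices), `lag_ms`, and `summary` (data.frame `unit_id`, `group`,
#'   `peak_hz_memory`, `peak_lag_ms_memory`, `peak_hz_non_memory`,
#'   `peak_lag_ms_non_memory`).
#' @export
population_peri_ripple_profiles <- function(spikes, ripples, window_ms = 500,
                                            bin_ms = 5, smooth_sd_ms = 15) {
  mem <- ripples$onset_s[ripples$label == "memory"]
  non <- ripples$onset_s[ripples$label == "non_memory"]
  units <- sort(unique(spikes$unit_id))
  zs_m <- list(); zs_n <- list(); rows <- list()
  for (u in units) {
    ts <- sort(spikes$time_s[spikes$unit_id == u])
    dg <- difference_group(ts, mem, non, window_ms, bin_ms, smooth_sd_ms)
    pm <- dg$pm; pn <- dg$pn
    zs_m[[u]] <- pm$z
    zs_n[[u]] <- pn$z
    peak_stats <- function(p) {
      sel <- abs(p$lag_ms) <= 150
      i <- which.max(p$smoothed_hz[sel])
      c(p$smoothed_hz[sel][i], p$lag_ms[sel][i])
    }
    sm <- peak_stats(pm); sn <- peak_stats(pn)
    rows[[u]] <- data.frame(unit_id = u, group = dg$group,
                            peak_hz_memory = sm[1], peak_lag_ms_memory = sm[2],
                            peak_hz_non_memory = sn[1],
                            peak_lag_ms_non_memory = sn[2],
                            stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  ord <- order(match(summary$group, c("up", "none", "down")))
  summary <- summary[ord, ]
  rownames(summary) <- NULL
  list(z_memory = do.call(rbind, zs_m)[ord, , drop = FALSE],
       z_non_memory = do.call(rbind, zs_n)[ord, , drop = FALSE],
       lag_ms = peri_event_histogram(numeric(0), onsets = 0, window_ms,
                                     bin_ms, smooth_sd_ms)$lag_ms,
       summary = summary)
}
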