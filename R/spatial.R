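gaussian_kernel_2d <- function(sigma_bins) {
  k <- gaussian_kernel(sigma_bins)
  outer(k, k)
}

# 2-D convolution with a small separable-equivalent kernel, "same" size.
conv2_same <- function(m, k) {
  r <- (nrow(k) - 1L) / 2L
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2 * r, nc + 2 * r)
  pad[r + seq_len(nr), r + seq_len(nc)] <- m
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(k))) {
    for (j in seq_len(ncol(k))) {
      if (k[i, j] == 0) next
      out <- out + k[i, j] * pad[(i - 1) + seq_len(nr), (j - 1) + seq_len(nc)]
    }
  }
  out
}

#' Occupancy-normalized spatial rate map
#'
#' Bins the trajectory into 1 x 1 cm bins (bin `i` covers `[i-1, i)` cm,
#' origin at the arena corner), assigns each spike a position by linear
#' interpolation of the trace, smooths the spike-count and occupancy-time
#' maps with the same Gaussian kernel ("filter width 5 bins", read as a
#' full width of about 5 bins, sigma = 5/2.355 bins), and divides.
#' Unvisited bins are masked (NA).
#'
#' @param spike_times spike times (s) of one unit.
#' @param position data.frame `time_s`, `x_cm`, `y_cm`, sampled at >= 10 Hz.
#' @param bin_cm spatial bin size (default 1).
#' @param filter_width_bins Gaussian filter width (default 5 bins);
#'   `sigma = filter_width_bins / 2.355`.
#' @param smooth_first smooth count and occupancy before dividing
#'   (default TRUE, the numerically stable order); `FALSE` smooths the raw
#'   ratio instead.
#' @return object of class `rate_map`: `rate` (Hz matrix), `occupancy_prob`
#'   (sums to 1 over visited bins), `mean_rate_hz`, `peak_rate_hz`,
#'   `si_bits_per_spike`, `bin_cm`.
#' @export
build_rate_map <- function(spike_times, position, bin_cm = 1,
                           filter_width_bins = 5, smooth_first = TRUE) {
  stopifnot(all(c("time_s", "x_cm", "y_cm") %in% names(position)))
  dt <- stats::median(diff(position$time_s))
  if (dt > 0.1) stop("position must be sampled at >= 10 Hz")
  spike_times <- spike_times[spike_times >= min(position$time_s) &
                               spike_times <= max(position$time_s)]
  nx <- ceiling(max(position$x_cm) / bin_cm)
  ny <- ceiling(max(position$y_cm) / bin_cm)
  if (nx < 2 || ny < 2) stop("arena smaller than 2x2 bins")
  bx <- pmin(floor(position$x_cm / bin_cm) + 1L, nx)
  by <- pmin(floor(position$y_cm / bin_cm) + 1L, ny)
  occ <- matrix(0, nx, ny)
  tab <- table(factor(bx, levels = seq_len(nx)), factor(by, levels = seq_len(ny)))
  occ <- occ + as.numeric(tab) * dt
  dim(occ) <- c(nx, ny)
  if (all(occ == 0)) stop("zero occupancy everywhere")
  sx <- stats::approx(position$time_s, position$x_cm, xout = spike_times)$y
  sy <- stats::approx(position$time_s, position$y_cm, xout = spike_times)$y
  sbx <- pmin(floor(sx / bin_cm) + 1L, nx)
  sby <- pmin(floor(sy / bin_cm) + 1L, ny)
  cnt <- matrix(as.numeric(table(factor(sbx, levels = seq_len(nx)),
                                 factor(sby, levels = seq_len(ny)))), nx, ny)
  k <- gaussian_kernel_2d(filter_width_bins / 2.355)
  visited <- occ > 0
  if (smooth_first) {
    rate <- conv2_same(cnt, k) / pmax(conv2_same(occ, k), 1e-12)
  } else {
    raw <- cnt / pmax(occ, 1e-12)
    raw[!visited] <- 0
    rate <- conv2_same(raw, k)
  }
  rate[!visited] <- NA
  p <- occ / sum(occ)
  p[!visited] <- 0
  mean_rate <- sum(p[visited] * rate[visited])
  map <- structure(list(rate = rate, occupancy_prob = p,
                        mean_rate_hz = mean_rate,
                        peak_rate_hz = suppressWarnings(max(rate, na.rm = TRUE)),
                        bin_cm = bin_cm),
                   class = "rate_map")
  map$si_bits_per_spike <- spatial_information(map)
  map
}

#' Spatial information content (bits/spike)
#'
#' `SI = sum_i p_i (lambda_i / lambda) log2(lambda_i / lambda)` over
#' visited bins, with the convention `0 * log 0 = 0`; `lambda` is the
#' occupancy-weighted mean rate.  NA when the mean rate is zero.
#'
#' @param map a [build_rate_map()] result.
#' @return bits per spike (non-negative), or NA.
#' @export
spatial_information <- function(map) {
  stopifnot(inherits(map, "rate_map"))
  lam <- map$mean_rate_hz
  if (!is.finite(lam) || lam <= 0) return(NA_real_)
  p <- map$occupancy_prob
  r <- map$rate
  sel <- p > 0 & is.finite(r) & r > 0
  sum(p[sel] * (r[sel] / lam) * log2(r[sel] / lam))
}

#' Place-cell inclusion filter
#'
#' Keeps units whose peak smoothed rate in any spatial bin exceeds 0.4 Hz
#' (strict inequality).
#'
#' @param maps named list of `rate_map`s (or numeric vector of peak rates).
#' @param peak_hz threshold (default 0.4).
#' @return character (or integer) vector of included unit names/indices.
#' @export
place_cell_filter <- function(maps, peak_hz = 0.4) {
  peaks <- if (is.numeric(maps)) maps else
    vapply(maps, function(m) m$peak_rate_hz, numeric(1))
  idx <- which(peaks > peak_hz)
  if (!is.null(names(peaks))) names(peaks)[idx] else idx
}

#' Compare spatial information between two unit subgroups
#'
#' Two-sided Wilcoxon rank-sum test and group medians, e.g. for
#' higher- vs lower-weight dCA1 units from [weight_split_decoding()].
#'
#' @param si numeric spatial-information values (bits/spike).
#' @param groups factor/character of the same length with two levels.
#' @param min_n minimum units per group (default 5; otherwise p = NA).
#' @return list `p_value`, `medians`, `n`.
#' @export
compare_subgroups <- function(si, groups, min_n = 5) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2, length(si) == length(groups))
  sp <- split(si, groups)
  n <- vapply(sp, length, 1L)
  p <- if (all(n >= min_n)) {
    stats::wilcox.test(sp[[1]], sp[[2]], exact = FALSE)$p.value
  } else NA_real_
  list(p_value = p, medians = vapply(sp, stats::median, numeric(1)), n = n)
}
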