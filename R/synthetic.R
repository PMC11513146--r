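#' Configuration for a synthetic dCA1-BLA recording session
#'
#' Collects every parameter of the ground-truth generator.  The defaults
#' describe a desk-scale version of a typical dual-site fear-conditioning
#' session: pre-training sleep, training with foot shocks, post-training
#' sleep and a recall test, with ripples during the sleep epochs, planted
#' co-activating BLA assemblies, one assembly yoked to a fraction of
#' post-training ripples at a 35-ms dCA1-to-BLA lag, a many-to-one weighted
#' dCA1-to-BLA coupled target unit, and place-field-modulated dCA1 firing
#' on a random walk during training.
#'
#' @param epoch_durations named numeric vector of seconds per epoch, in order
#'   `pre_sleep`, `training`, `post_sleep`, `test`.
#' @param n_dca1,n_bla unit counts per region.
#' @param baseline_rate_dca1,baseline_rate_bla background Poisson rates (Hz).
#' @param n_assemblies number of planted (disjoint) BLA assemblies.
#' @param assembly_size members per assembly (2-6 is realistic).
#' @param assembly_event_rate background co-activation event rate per
#'   assembly (events/s), all epochs.
#' @param assembly_gain multiplicative rate gain of members inside a 25-ms
#'   event window; must be >= 1.
#' @param yoked_assembly index of the assembly yoked to post-training
#'   ripples (the planted "memory" assembly), or 0 for none.
#' @param yoked_fraction fraction of post-training-sleep ripples that recruit
#'   the yoked assembly (the paper-scale value is not published; free
#'   parameter, default 0.3).
#' @param shock_gain multiplicative increase of the yoked assembly's event
#'   rate after the first shock during training (makes it shock-activated).
#' @param ripple_rate ripple events/s during sleep epochs.
#' @param ripple_amp_sd,ripple_amp_jitter mean and s.d. of injected ripple
#'   peak amplitude, in units of s.d. of the baseline 100-250 Hz envelope.
#' @param ripple_dur_ms,ripple_dur_jitter_ms mean and s.d. of injected
#'   ripple duration (ms).
#' @param dca1_ripple_gain_mean mean multiplicative dCA1 rate gain within
#'   +/-50 ms of ripple peaks (log-normal across units).
#' @param coupling_weights dCA1-to-BLA-target weight vector (length
#'   `n_dca1`) for the coupled target unit; `NULL` for broad uniform
#'   weights, `NA` to skip the coupled unit.
#' @param lag_ms dCA1-to-BLA latency in ms (default 35).
#' @param lfp_fs LFP sampling rate in Hz (default 2000; must be >= 1000).
#' @param arena_cm square arena side (cm) for the training random walk.
#' @param place_sigma_cm place-field width (cm).
#' @param place_peak_hz place-field peak rate (Hz).
#' @param pos_fs position sampling rate (Hz).
#' @param shock_interval_min minutes between shocks; shocks start at 3 min
#'   after training onset (3, 6, 9, ... min), at most 10.
#' @param seed master seed; together with the config it fully determines
#'   every generated sample.
#' @return an object of class `session_config`.
#' @export
session_config <- function(epoch_durations = c(pre_sleep = 3600, training = 1800,
                                               post_sleep = 3600, test = 300),
                           n_dca1 = 55, n_bla = 58,
                           baseline_rate_dca1 = 2, baseline_rate_bla = 5,
                           n_assemblies = 6, assembly_size = 4,
                           assembly_event_rate = 0.2, assembly_gain = 8,
                           yoked_assembly = 1, yoked_fraction = 0.3,
                           shock_gain = 4,
                           ripple_rate = 0.5,
                           ripple_amp_sd = 10, ripple_amp_jitter = 2,
                           ripple_dur_ms = 60, ripple_dur_jitter_ms = 10,
                           dca1_ripple_gain_mean = 3,
                           coupling_weights = NULL,
                           lag_ms = 35, lfp_fs = 2000,
                           arena_cm = 25, place_sigma_cm = 5,
                           place_peak_hz = 8, pos_fs = 30,
                           shock_interval_min = 3,
                           seed = 1) {
  req <- c("pre_sleep", "training", "post_sleep", "test")
  if (!all(req %in% names(epoch_durations))) {
    stop("epoch_durations must name: ", paste(req, collapse = ", "))
  }
  epoch_durations <- epoch_durations[req]
  if (any(epoch_durations <= 0)) stop("epoch durations must be positive")
  rates <- c(baseline_rate_dca1, baseline_rate_bla, assembly_event_rate,
             ripple_rate, place_peak_hz)
  if (any(rates < 0)) stop("all rates must be >= 0")
  if (lag_ms < 0) stop("lag_ms must be >= 0")
  if (assembly_gain < 1) stop("assembly_gain < 1 would invert the planted structure")
  if (yoked_fraction < 0 || yoked_fraction > 1) stop("yoked_fraction must be in [0, 1]")
  starts <- cumsum(c(0, utils::head(epoch_durations, -1)))
  epochs <- data.frame(name = req,
                       start_s = unname(starts),
                       end_s = unname(starts + epoch_durations),
                       stringsAsFactors = FALSE)
  cfg <- list(epochs = epochs,
              n_dca1 = n_dca1, n_bla = n_bla,
              baseline_rate_dca1 = baseline_rate_dca1,
              baseline_rate_bla = baseline_rate_bla,
              n_assemblies = n_assemblies, assembly_size = assembly_size,
              assembly_event_rate = assembly_event_rate,
              assembly_gain = assembly_gain,
              yoked_assembly = yoked_assembly,
              yoked_fraction = yoked_fraction,
              shock_gain = shock_gain,
              ripple_rate = ripple_rate,
              ripple_amp_sd = ripple_amp_sd,
              ripple_amp_jitter = ripple_amp_jitter,
              ripple_dur_ms = ripple_dur_ms,
              ripple_dur_jitter_ms = ripple_dur_jitter_ms,
              dca1_ripple_gain_mean = dca1_ripple_gain_mean,
              coupling_weights = coupling_weights,
              lag_ms = lag_ms, lfp_fs = lfp_fs,
              arena_cm = arena_cm, place_sigma_cm = place_sigma_cm,
              place_peak_hz = place_peak_hz, pos_fs = pos_fs,
              shock_interval_min = shock_interval_min,
              seed = seed)
  class(cfg) <- "session_config"
  cfg
}

#' @export
print.session_config <- function(x, ...) {
  cat("<session_config>\n")
  cat("  epochs:", paste(sprintf("%s %g-%g s", x$epochs$name, x$epochs$start_s,
                                 x$epochs$end_s), collapse = "; "), "\n")
  cat(sprintf("  units: %d dCA1 + %d BLA; %d planted assemblies (size %d)\n",
              x$n_dca1, x$n_bla, x$n_assemblies, x$assembly_size))
  cat(sprintf("  ripple rate %.2g /s; yoked assembly %d (fraction %.2g, lag %g ms)\n",
              x$ripple_rate, x$yoked_assembly, x$yoked_fraction, x$lag_ms))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

epoch_window <- function(cfg, name) {
  e <- cfg$epochs[cfg$epochs$name == name, ]
  c(e$start_s, e$end_s)
}

shock_times <- function(cfg) {
  tr <- epoch_window(cfg, "training")
  t0 <- tr[1]
  s <- t0 + seq(cfg$shock_interval_min * 60, by = cfg$shock_interval_min * 60,
                length.out = 10)
  s[s < tr[2] - 30]   # keep shocks at least 30 s before training end
}

# Poisson event times on [t0, t1) with a hard minimum spacing (thinning).
poisson_times <- function(rate, t0, t1, min_gap = 0) {
  if (rate <= 0 || t1 <= t0) return(numeric(0))
  n <- stats::rpois(1, rate * (t1 - t0))
  t <- sort(stats::runif(n, t0, t1))
  if (min_gap > 0 && length(t) > 1) {
    keep <- c(TRUE, diff(t) >= min_gap)
    while (!all(keep)) {           # re-check spacing after each removal pass
      t <- t[keep]
      keep <- c(TRUE, diff(t) >= min_gap)
    }
  }
  t
}

#' Generate a synthetic LFP trace with injected ripples
#'
#' Background is 1/f ("pink") noise with a prominent 1-4 Hz delta component
#' during sleep epochs, mimicking slow-wave sleep.  Ripples are sinusoidal
#' bursts (frequency drawn uniformly from 100-250 Hz) under a Gaussian
#' amplitude envelope, injected during sleep epochs; their peak amplitude is
#' expressed in units of the s.d. of the baseline band-passed (100-250 Hz)
#' envelope, so detection thresholds are directly interpretable.
#'
#' @param cfg a [session_config()].
#' @param n_ripples optional exact number of ripples per sleep epoch
#'   (overrides `cfg$ripple_rate`).
#' @param delta_epochs epoch names receiving the delta component
#'   (default both sleep epochs).
#' @return a list with `lfp` (class `lfp_trace`: `samples`, `fs`) and
#'   `truth`, a data.frame of injected ripples (`onset_s`, `peak_s`,
#'   `offset_s`, `amp_sd`, `freq_hz`, `epoch`).
#' @export
generate_lfp <- function(cfg, n_ripples = NULL,
                         delta_epochs = c("pre_sleep", "post_sleep")) {
  stopifnot(inherits(cfg, "session_config"))
  fs <- cfg$lfp_fs
  if (fs < 1000) stop("lfp_fs < 1000 Hz cannot represent 250 Hz ripples cleanly")
  set.seed(derive_seeds(cfg$seed, 8)[1])
  total_s <- max(cfg$epochs$end_s)
  n <- round(total_s * fs)
  # pink background: shape white noise by 1/sqrt(f)
  nf <- stats::nextn(n, c(2L, 3L, 5L))
  wh <- stats::rnorm(nf)
  W <- stats::fft(wh)
  fr <- seq_len(nf) - 1L
  af <- pmax(pmin(fr, nf - fr) * fs / nf, 0.1)
  pink <- Re(stats::fft(W / sqrt(af), inverse = TRUE) / nf)[seq_len(n)]
  pink <- pink / stats::sd(pink) * 30    # 30 uV broadband background
  tt <- (seq_len(n) - 1) / fs
  x <- pink
  # delta during sleep: two slow sinusoids with random phase
  for (ep in delta_epochs) {
    w <- epoch_window(cfg, ep)
    idx <- which(tt >= w[1] & tt < w[2])
    f1 <- stats::runif(1, 1, 2.5); f2 <- stats::runif(1, 2.5, 4)
    ph <- stats::runif(2, 0, 2 * pi)
    x[idx] <- x[idx] + 60 * sin(2 * pi * f1 * tt[idx] + ph[1]) +
      40 * sin(2 * pi * f2 * tt[idx] + ph[2])
  }
  # baseline ripple-band envelope s.d. (before injection), estimated on a
  # 300-s sleep subsegment -- the background is stationary by construction
  sl <- epoch_window(cfg, "pre_sleep")
  cal <- seq(round(sl[1] * fs) + 1,
             round(min(sl[1] + 300, sl[2]) * fs))
  env0 <- Mod(fft_bandpass(x[cal], fs, 100, 250, analytic = TRUE))
  env_sd <- stats::sd(env0)
  truth <- list()
  for (ep in c("pre_sleep", "post_sleep")) {
    w <- epoch_window(cfg, ep)
    if (!is.null(n_ripples)) {
      peaks <- sort(stats::runif(n_ripples, w[1] + 1, w[2] - 1))
      gap <- 0.3
      while (length(peaks) > 1 && any(diff(peaks) < gap)) {
        bad <- which(diff(peaks) < gap)[1] + 1L
        peaks[bad] <- stats::runif(1, w[1] + 1, w[2] - 1)
        peaks <- sort(peaks)
      }
    } else {
      peaks <- poisson_times(cfg$ripple_rate, w[1] + 1, w[2] - 1, min_gap = 0.3)
    }
    if (!length(peaks)) next
    m <- length(peaks)
    amp <- pmax(stats::rnorm(m, cfg$ripple_amp_sd, cfg$ripple_amp_jitter), 4)
    dur <- pmax(stats::rnorm(m, cfg$ripple_dur_ms, cfg$ripple_dur_jitter_ms), 30) / 1000
    frq <- stats::runif(m, 100, 250)
    for (i in seq_len(m)) {
      sig <- dur[i] / 6                       # burst spans +/- 3 sigma
      span <- seq(max(1, round((peaks[i] - 3 * sig) * fs)),
                  min(n, round((peaks[i] + 3 * sig) * fs)))
      ts <- tt[span] - peaks[i]
      x[span] <- x[span] + amp[i] * env_sd *
        exp(-0.5 * (ts / sig)^2) * sin(2 * pi * frq[i] * ts)
    }
    truth[[ep]] <- data.frame(onset_s = peaks - dur / 2, peak_s = peaks,
                              offset_s = peaks + dur / 2, amp_sd = amp,
                              freq_hz = frq, epoch = ep,
                              stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(onset_s = numeric(0), peak_s = numeric(0), offset_s = numeric(0),
               amp_sd = numeric(0), freq_hz = numeric(0), epoch = character(0))
  rownames(truth) <- NULL
  lfp <- structure(list(samples = x, fs = fs, t0 = 0), class = "lfp_trace")
  list(lfp = lfp, truth = truth)
}

# Draw member sets: disjoint random subsets of 1..n_bla.
draw_assembly_members <- function(n_bla, n_assemblies, size) {
  if (n_assemblies * size > n_bla) stop("assemblies would exceed unit count")
  pool <- sample.int(n_bla, n_assemblies * size)
  split(pool, rep(seq_len(n_assemblies), each = size))
}

#' Generate BLA spikes with planted co-activating assemblies
#'
#' Every unit fires as a homogeneous Poisson process at its baseline rate.
#' On top, each planted assembly has event times (background Poisson in all
#' epochs; the yoked assembly additionally gets events 35 ms after a fraction
#' of post-training ripples, and its background event rate is multiplied by
#' `shock_gain` after the first shock during training).  Within a 25-ms
#' window at each event, member units fire at `assembly_gain` times their
#' baseline rate.  Event windows are aligned to the 25-ms analysis grid of
#' their epoch so the planted structure is maximally visible to the binned
#' ICA stage.
#'
#' @param cfg a [session_config()].
#' @param ripple_truth optional data.frame of true ripples (from
#'   [generate_lfp()]); needed when `cfg$yoked_assembly > 0`.
#' @param yoke_pre if `TRUE`, the yoked assembly also follows pre-training
#'   ripples (default `FALSE`: coupling emerges only after training).
#' @param recruit_prob optional per-ripple recruitment probability for the
#'   yoked assembly, aligned with the rows of `ripple_truth` that fall in
#'   the yoked epochs (e.g. proportional to dCA1 drive, giving the
#'   many-to-one weighted mapping); default: constant
#'   `cfg$yoked_fraction`.
#' @return list with `spikes` (data.frame `unit_id`, `region`, `time_s`),
#'   `members` (list of member index vectors), and `events` (list of event
#'   time vectors per assembly).
#' @export
generate_assembly_spikes <- function(cfg, ripple_truth = NULL, yoke_pre = FALSE,
                                     recruit_prob = NULL) {
  stopifnot(inherits(cfg, "session_config"))
  if (cfg$assembly_gain < 1) stop("assembly_gain < 1 would invert the planted structure")
  set.seed(derive_seeds(cfg$seed, 8)[2])
  total <- max(cfg$epochs$end_s)
  win <- 0.025
  members <- draw_assembly_members(cfg$n_bla, cfg$n_assemblies, cfg$assembly_size)
  snap_to_grid <- function(t) {
    # align each event to the start of its epoch's 25-ms bin grid
    ep <- findInterval(t, cfg$epochs$start_s)
    st <- cfg$epochs$start_s[ep]
    st + floor((t - st) / win) * win
  }
  sh <- shock_times(cfg)
  events <- vector("list", cfg$n_assemblies)
  for (a in seq_len(cfg$n_assemblies)) {
    ev <- numeric(0)
    for (i in seq_len(nrow(cfg$epochs))) {
      w <- c(cfg$epochs$start_s[i], cfg$epochs$end_s[i])
      rate <- cfg$assembly_event_rate
      if (cfg$epochs$name[i] == "training" && a == cfg$yoked_assembly &&
          length(sh) && cfg$shock_gain != 1) {
        ev <- c(ev, poisson_times(rate, w[1], sh[1]),
                poisson_times(rate * cfg$shock_gain, sh[1], w[2]))
      } else {
        ev <- c(ev, poisson_times(rate, w[1], w[2]))
      }
    }
    if (a == cfg$yoked_assembly && a > 0 && !is.null(ripple_truth) &&
        cfg$yoked_fraction > 0) {
      eps <- if (yoke_pre) c("pre_sleep", "post_sleep") else "post_sleep"
      rt <- ripple_truth[ripple_truth$epoch %in% eps, "onset_s"]
      if (length(rt)) {
        pr <- recruit_prob %||% rep(cfg$yoked_fraction, length(rt))
        stopifnot(length(pr) == length(rt))
        pick <- rt[stats::runif(length(rt)) < pr]
        ev <- c(ev, pick + cfg$lag_ms / 1000)
      }
    }
    events[[a]] <- sort(unique(snap_to_grid(ev[ev < total - win])))
  }
  # background spikes
  base <- cfg$baseline_rate_bla
  n_bg <- stats::rpois(cfg$n_bla, base * total)
  sp_unit <- lapply(n_bg, function(k) stats::runif(k, 0, total))
  # extra spikes inside event windows: rate base*(gain-1) for members
  extra_rate <- base * (cfg$assembly_gain - 1)
  for (a in seq_len(cfg$n_assemblies)) {
    ev <- events[[a]]
    if (!length(ev)) next
    for (u in members[[a]]) {
      k <- stats::rpois(length(ev), extra_rate * win)
      if (sum(k) == 0) next
      ts <- rep(ev, k) + stats::runif(sum(k), 0, win)
      sp_unit[[u]] <- c(sp_unit[[u]], ts)
    }
  }
  spikes <- data.frame(
    unit_id = rep(sprintf("bla_%02d", seq_len(cfg$n_bla)),
                  vapply(sp_unit, length, 1L)),
    region = "BLA",
    time_s = unlist(sp_unit),
    stringsAsFactors = FALSE)
  spikes <- spikes[order(spikes$unit_id, spikes$time_s), ]
  rownames(spikes) <- NULL
  list(spikes = spikes, members = members, events = events)
}

#' Generate dCA1 spikes with ripple-locked rate gains
#'
#' Units fire as Poisson processes at baseline, with a unit-specific
#' multiplicative gain (log-normal across units) within +/-50 ms of each
#' ripple peak, emulating ripple-participating CA1 cells.
#'
#' @param cfg a [session_config()].
#' @param ripple_truth true ripple table from [generate_lfp()].
#' @return list with `spikes` data.frame and `ripple_gains` per unit.
#' @export
generate_dca1_spikes <- function(cfg, ripple_truth = NULL) {
  stopifnot(inherits(cfg, "session_config"))
  set.seed(derive_seeds(cfg$seed, 8)[3])
  total <- max(cfg$epochs$end_s)
  base <- cfg$baseline_rate_dca1
  gains <- stats::rlnorm(cfg$n_dca1, log(cfg$dca1_ripple_gain_mean), 0.4)
  half <- 0.05
  peaks <- if (!is.null(ripple_truth)) sort(ripple_truth$peak_s) else numeric(0)
  sp_unit <- vector("list", cfg$n_dca1)
  for (u in seq_len(cfg$n_dca1)) {
    k <- stats::rpois(1, base * total)
    ts <- stats::runif(k, 0, total)
    if (length(peaks)) {
      extra <- stats::rpois(length(peaks), base * (gains[u] - 1) * 2 * half)
      if (sum(extra) > 0) {
        ts <- c(ts, rep(peaks, extra) + stats::runif(sum(extra), -half, half))
      }
    }
    sp_unit[[u]] <- sort(ts[ts >= 0 & ts < total])
  }
  spikes <- data.frame(
    unit_id = rep(sprintf("dca1_%02d", seq_len(cfg$n_dca1)),
                  vapply(sp_unit, length, 1L)),
    region = "dCA1",
    time_s = unlist(sp_unit),
    stringsAsFactors = FALSE)
  rownames(spikes) <- NULL
  list(spikes = spikes, ripple_gains = gains)
}

#' Generate a BLA target unit coupled to the dCA1 population
#'
#' The generative twin of the GLM decoder: for each ripple and each window
#' pair of the schedule, the target's spike count in the (lag-shifted) BLA
#' window is Poisson with log-rate `b0 + w . x`, where `x` holds the dCA1
#' population counts in the paired dCA1 window.  Outside ripple windows the
#' target fires at a low baseline.  During epochs not listed in
#' `active_epochs` (e.g. pre-training sleep) the weights are zero.
#'
#' @param cfg a [session_config()].
#' @param dca1_spikes dCA1 spike data.frame (`unit_id`, `time_s`).
#' @param ripple_truth true/detected ripple table with `onset_s` and `epoch`.
#' @param weights coupling weight vector, length `n_dca1`; default
#'   `cfg$coupling_weights` or broad uniform 0.15.
#' @param schedule a [window_schedule()]; default uses `cfg$lag_ms`.
#' @param active_epochs epochs in which the coupling is on.
#' @param target_mean desired mean target count per active window (sets the
#'   intercept).
#' @param baseline_hz target unit's background rate outside windows.
#' @return list with `spikes` (data.frame for unit `bla_target`),
#'   `weights`, `intercepts` per window pair.
#' @export
generate_coupled_population <- function(cfg, dca1_spikes, ripple_truth,
                                        weights = NULL, schedule = NULL,
                                        active_epochs = c("training", "post_sleep"),
                                        target_mean = 1.5, baseline_hz = 0.5) {
  stopifnot(inherits(cfg, "session_config"))
  set.seed(derive_seeds(cfg$seed, 8)[4])
  weights <- weights %||% cfg$coupling_weights %||% rep(0.15, cfg$n_dca1)
  if (length(weights) != cfg$n_dca1) stop("coupling_weights length must equal n_dca1")
  schedule <- schedule %||% window_schedule(cfg$lag_ms)
  total <- max(cfg$epochs$end_s)
  units <- sort(unique(dca1_spikes$unit_id))
  sp_by_unit <- split(dca1_spikes$time_s, dca1_spikes$unit_id)[units]
  sp_by_unit <- lapply(sp_by_unit, sort)
  onsets <- sort(ripple_truth$onset_s)
  ep_of <- cfg$epochs$name[findInterval(onsets, cfg$epochs$start_s)]
  target <- stats::runif(stats::rpois(1, baseline_hz * total), 0, total)
  intercepts <- numeric(nrow(schedule))
  for (p in seq_len(nrow(schedule))) {
    xlo <- onsets + schedule$dca1_lo[p] / 1000
    xhi <- onsets + schedule$dca1_hi[p] / 1000
    X <- vapply(sp_by_unit, function(ts) count_in_windows(ts, xlo, xhi),
                numeric(length(onsets)))
    eta <- drop(X %*% weights)
    active <- ep_of %in% active_epochs
    b0 <- log(target_mean) - mean(eta[if (any(active)) active else TRUE])
    intercepts[p] <- b0
    # inactive epochs (zero coupling) get no ripple-locked drive at all:
    # the target fires at its flat baseline there
    lam <- ifelse(active, exp(b0 + eta), 0)
    k <- stats::rpois(length(onsets), lam)
    if (sum(k) > 0) {
      blo <- onsets + schedule$bla_lo[p] / 1000
      width <- (schedule$bla_hi[p] - schedule$bla_lo[p]) / 1000
      target <- c(target, rep(blo, k) + stats::runif(sum(k), 0, width))
    }
  }
  target <- sort(target[target >= 0 & target < total])
  spikes <- data.frame(unit_id = "bla_target", region = "BLA",
                       time_s = target, stringsAsFactors = FALSE)
  list(spikes = spikes, weights = weights, intercepts = intercepts)
}

#' Generate a random-walk trajectory and place-cell spikes
#'
#' The trajectory is a smoothed (AR(1)-velocity) random walk reflected at
#' the walls of a square arena.  Place cells fire as inhomogeneous Poisson
#' processes with Gaussian spatial tuning; uniform cells fire
#' position-independently at the matched mean rate.
#'
#' @param cfg a [session_config()].
#' @param duration_s trajectory length in seconds (defaults to the training
#'   epoch duration); the trace starts at the training epoch start.
#' @param n_place,n_uniform numbers of place-tuned and untuned cells.
#' @param sigma_cm place-field widths, recycled over place cells.
#' @param unit_prefix prefix for generated unit ids.
#' @return list with `position` (data.frame `time_s`, `x_cm`, `y_cm`),
#'   `spikes` data.frame, `centers` (n_place x 2 matrix) and `sigma_cm`.
#' @export
generate_trajectory_and_place_cells <- function(cfg, duration_s = NULL,
                                                n_place = NULL, n_uniform = 0,
                                                sigma_cm = NULL,
                                                unit_prefix = "dca1") {
  stopifnot(inherits(cfg, "session_config"))
  if (cfg$arena_cm < 2) stop("arena smaller than 2x2 bins rejected")
  set.seed(derive_seeds(cfg$seed, 8)[5])
  tr <- epoch_window(cfg, "training")
  duration_s <- duration_s %||% (tr[2] - tr[1])
  n_place <- n_place %||% cfg$n_dca1
  sigma_cm <- rep(sigma_cm %||% cfg$place_sigma_cm, length.out = n_place)
  fs <- cfg$pos_fs
  n <- round(duration_s * fs)
  L <- cfg$arena_cm
  # AR(1) velocity random walk, reflecting walls; mean speed ~8 cm/s
  step_sd <- 8 / fs
  vx <- stats::filter(stats::rnorm(n, 0, step_sd), 0.9, method = "recursive")
  vy <- stats::filter(stats::rnorm(n, 0, step_sd), 0.9, method = "recursive")
  reflect <- function(p) {
    p <- p %% (2 * L)
    ifelse(p > L, 2 * L - p, p)
  }
  x <- reflect(L / 2 + cumsum(as.numeric(vx)))
  y <- reflect(L / 2 + cumsum(as.numeric(vy)))
  time_s <- tr[1] + (seq_len(n) - 1) / fs
  centers <- cbind(stats::runif(n_place, 0.1 * L, 0.9 * L),
                   stats::runif(n_place, 0.1 * L, 0.9 * L))
  dt <- 1 / fs
  spike_one <- function(rate_t) {
    k <- stats::rpois(n, rate_t * dt)
    if (sum(k) == 0) return(numeric(0))
    sort(rep(time_s, k) + stats::runif(sum(k), 0, dt))
  }
  sp <- vector("list", n_place + n_uniform)
  mean_rates <- numeric(n_place)
  for (u in seq_len(n_place)) {
    d2 <- (x - centers[u, 1])^2 + (y - centers[u, 2])^2
    rate_t <- cfg$place_peak_hz * exp(-d2 / (2 * sigma_cm[u]^2)) + 0.1
    mean_rates[u] <- mean(rate_t)
    sp[[u]] <- spike_one(rate_t)
  }
  for (u in seq_len(n_uniform)) {
    flat <- if (n_place) mean(mean_rates) else cfg$place_peak_hz / 4
    sp[[n_place + u]] <- spike_one(rep(flat, n))
  }
  ids <- c(sprintf("%s_%02d", unit_prefix, seq_len(n_place)),
           if (n_uniform) sprintf("%s_u%02d", unit_prefix, seq_len(n_uniform)))
  spikes <- data.frame(
    unit_id = rep(ids, vapply(sp, length, 1L)),
    region = "dCA1",
    time_s = unlist(sp),
    stringsAsFactors = FALSE)
  rownames(spikes) <- NULL
  list(position = data.frame(time_s = time_s, x_cm = x, y_cm = y),
       spikes = spikes, centers = centers, sigma_cm = sigma_cm)
}

#' Simulate a full synthetic session with ground truth
#'
#' Orchestrates [generate_lfp()], [generate_dca1_spikes()],
#' [generate_assembly_spikes()], [generate_coupled_population()] and
#' [generate_trajectory_and_place_cells()] into one session bundle with the
#' complete planted ground truth attached.
#'
#' @param cfg a [session_config()].
#' @param with_position include the training-epoch trajectory and
#'   place-modulated dCA1 cells (replacing sleep-epoch-only dCA1 units would
#'   complicate the ground truth, so place spikes are added for the same
#'   unit ids during training).
#' @param with_coupled_target append the GLM-coupled `bla_target` unit.
#' @return an object of class `session_bundle`.
#' @export
simulate_session <- function(cfg = session_config(), with_position = TRUE,
                             with_coupled_target = TRUE) {
  lfp <- generate_lfp(cfg)
  dca1 <- generate_dca1_spikes(cfg, lfp$truth)
  # recruitment of the yoked assembly scales with the dCA1 population count
  # preceding each post-training ripple (mean = yoked_fraction): the
  # many-to-one weighted mapping the session is meant to embody.  The window
  # [-200,-100) ms is the decoding-schedule partner of the +35 ms BLA
  # window the yoked events land in.
  post_on <- lfp$truth$onset_s[lfp$truth$epoch == "post_sleep"]
  recruit <- NULL
  if (length(post_on)) {
    ts <- sort(dca1$spikes$time_s)
    x <- count_in_windows(ts, post_on - 0.2, post_on - 0.1)
    recruit <- pmin(cfg$yoked_fraction * x / max(mean(x), 1e-9), 1)
  }
  bla <- generate_assembly_spikes(cfg, lfp$truth, recruit_prob = recruit)
  spikes <- rbind(dca1$spikes, bla$spikes)
  truth <- list(ripples = lfp$truth,
                assembly_members = bla$members,
                assembly_events = bla$events,
                yoked_assembly = cfg$yoked_assembly,
                yoked_fraction = cfg$yoked_fraction,
                dca1_ripple_gains = dca1$ripple_gains,
                shock_times = shock_times(cfg))
  position <- NULL
  if (with_position) {
    pc <- generate_trajectory_and_place_cells(cfg)
    # place spikes reuse the dCA1 unit ids; add them during training only
    spikes <- rbind(spikes, pc$spikes)
    position <- pc$position
    truth$place_field_centers <- pc$centers
  }
  if (with_coupled_target) {
    tgt <- generate_coupled_population(cfg, dca1$spikes, lfp$truth)
    spikes <- rbind(spikes, tgt$spikes)
    truth$coupling_weights <- tgt$weights
  }
  spikes <- spikes[order(spikes$unit_id, spikes$time_s), ]
  rownames(spikes) <- NULL
  structure(list(spikes = spikes, lfp = lfp$lfp, epochs = cfg$epochs,
                 shock_times = truth$shock_times, position = position,
                 truth = truth, config = cfg),
            class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  cat("<session_bundle>\n")
  cat(sprintf("  %d spikes from %d units; epochs: %s\n",
              nrow(x$spikes), length(unique(x$spikes$unit_id)),
              paste(x$epochs$name, collapse = ", ")))
  if (!is.null(x$lfp)) {
    cat(sprintf("  LFP: %d samples at %g Hz\n", length(x$lfp$samples), x$lfp$fs))
  }
  if (!is.null(x$truth)) cat("  ground truth attached\n")
  invisible(x)
}
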