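`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared synthetic-world builders.  Everything is seeded and small enough
# for the default test run; the acceptance suite re-uses these at the
# criterion sizes.

short_cfg <- function(seed = 1, ...) {
  session_config(
    epoch_durations = c(pre_sleep = 240, training = 240, post_sleep = 240,
                        test = 60),
    seed = seed, ...)
}

# dCA1 population + non-overlapping ripples + GLM-coupled target unit.
# Ripple onsets are spaced >= 0.8 s so the 100-ms window schedule of
# neighbouring ripples cannot overlap (the schedule spans -300..+335 ms).
glm_world <- function(seed, n_dca1 = 30, n_rip_per_epoch = 250,
                      weights = NULL, dca1_gain = 4) {
  set.seed(seed + 40000)
  weights <- weights %||% stats::runif(n_dca1, 0, 0.4)
  sleep_s <- max(700, ceiling(n_rip_per_epoch * 1.7) + 20)
  cfg <- session_config(
    epoch_durations = c(pre_sleep = sleep_s, training = 60,
                        post_sleep = sleep_s, test = 30),
    n_dca1 = n_dca1, baseline_rate_dca1 = 2,
    dca1_ripple_gain_mean = dca1_gain,
    coupling_weights = weights, seed = seed)
  spaced <- function(lo, hi, n) {
    on <- lo + cumsum(stats::runif(2 * n, 0.8, 2.2))
    utils::head(on[on < hi], n)
  }
  pre <- spaced(5, sleep_s - 5, n_rip_per_epoch)
  post <- spaced(sleep_s + 65, 2 * sleep_s + 55, n_rip_per_epoch)
  truth <- data.frame(
    onset_s = c(pre, post), peak_s = c(pre, post) + 0.03,
    offset_s = c(pre, post) + 0.06, amp_sd = 10, freq_hz = 180,
    epoch = rep(c("pre_sleep", "post_sleep"), c(length(pre), length(post))),
    stringsAsFactors = FALSE)
  d <- generate_dca1_spikes(cfg, truth)
  tg <- generate_coupled_population(cfg, d$spikes, truth)
  list(cfg = cfg, ripples = truth, dca1 = d$spikes, target = tg,
       pre_onsets = pre, post_onsets = post, weights = weights)
}

# BLA population with planted disjoint assemblies on one long sleep epoch.
assembly_world <- function(seed, n_bla = 58, n_assemblies = 2, size = 4,
                           event_rate = 0.5, gain = 8, sleep_s = 1200) {
  cfg <- session_config(
    epoch_durations = c(pre_sleep = 10, training = 10, post_sleep = sleep_s,
                        test = 10),
    n_bla = n_bla, n_assemblies = n_assemblies, assembly_size = size,
    assembly_event_rate = event_rate, assembly_gain = gain,
    yoked_assembly = 0, seed = seed)
  g <- generate_assembly_spikes(cfg)
  ep <- unlist(cfg$epochs[cfg$epochs$name == "post_sleep",
                          c("start_s", "end_s")])
  list(cfg = cfg, gen = g, epoch = ep)
}

# Labeled ripple table: memory ripples optionally enlarged/elongated.
labeled_ripples <- function(seed, n_mem = 200, n_non = 2000,
                            amp_shift = 0, dur_shift_ms = 0,
                            t_lo = 5, t_hi = 3600) {
  set.seed(seed)
  n <- n_mem + n_non
  onset <- sort(stats::runif(n, t_lo, t_hi))
  lab <- sample(rep(c("memory", "non_memory"), c(n_mem, n_non)))
  amp <- 5 + stats::rgamma(n, shape = 4, scale = 1) +
    ifelse(lab == "memory", amp_shift, 0)
  dur <- 40 + stats::rgamma(n, shape = 5, scale = 6) +
    ifelse(lab == "memory", dur_shift_ms, 0)
  data.frame(onset_s = onset, peak_s = onset + dur / 2000,
             offset_s = onset + dur / 1000, amplitude_sd = amp,
             duration_ms = dur, label = lab, stringsAsFactors = FALSE)
}

# Jaccard index between an integer member set and the planted set.
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Convert planted member unit numbers to row indices of a binned matrix.
member_rows <- function(members, mat) {
  match(sprintf("bla_%02d", members), mat$unit_ids)
}

expect_all_recovered <- function(gen, mat, patterns) {
  jac <- vapply(gen$members, function(m) {
    max(vapply(patterns, function(p) jaccard(p$members, member_rows(m, mat)),
               numeric(1)))
  }, numeric(1))
  expect_equal(unname(jac), rep(1, length(gen$members)))
}
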