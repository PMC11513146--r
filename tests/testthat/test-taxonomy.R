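# activation trace with planted supra-threshold bins at chosen times
stub_trace <- function(active_times, t0 = 0, t1 = 600, bin_s = 0.025,
                       seed = 1) {
  set.seed(seed)
  times <- seq(t0, t1 - bin_s, by = bin_s)
  strength <- stats::rnorm(length(times), 0, 0.5)
  idx <- unique(findInterval(active_times, times))
  strength[idx[idx >= 1]] <- 50
  structure(list(strength = strength, times = times, bin_s = bin_s,
                 mean = mean(strength), sd = stats::sd(strength),
                 threshold_sd = 5, event_bins = integer(0),
                 event_times = numeric(0), mode = "quadratic"),
            class = "activation_trace")
}

test_that("classify_ripples: definition, planted fraction, monotonicity", {
  set.seed(5)
  onsets <- sort(runif(400, 1, 598))
  rip <- data.frame(onset_s = onsets, peak_s = onsets + 0.03,
                    offset_s = onsets + 0.06, amplitude_sd = 8,
                    duration_ms = 60, label = "unlabeled",
                    stringsAsFactors = FALSE)
  # flat (constant) trace -> zero memory ripples
  flat <- stub_trace(numeric(0))
  flat$strength[] <- 1
  expect_true(all(classify_ripples(rip, flat)$label == "non_memory"))
  # no trace -> unlabeled with warning
  expect_warning(un <- classify_ripples(rip, NULL), "unlabeled")
  expect_true(all(un$label == "unlabeled"))
  # planted fraction f of ripples get an activation bin 35 ms after onset
  f <- 0.3
  yoked <- runif(400) < f
  tr <- stub_trace(onsets[yoked] + 0.035)
  lab <- classify_ripples(rip, tr)
  expect_true(all(lab$label[yoked] == "memory"))
  frac <- mean(lab$label == "memory")
  expect_lt(abs(frac - mean(yoked)), 0.05)
  # labels partition the input
  expect_true(all(lab$label %in% c("memory", "non_memory")))
  # raising the cut never adds memory labels
  lab4 <- classify_ripples(rip, tr, threshold_sd = 4)
  expect_true(all(which(lab4$label == "memory") %in%
                    which(lab$label == "memory")))
})

test_that("compare_ripple_properties: planted differences and contracts", {
  rip0 <- labeled_ripples(1, n_mem = 200, n_non = 2000)      # identical dists
  out0 <- compare_ripple_properties(rip0)
  expect_equal(out0$property, c("amplitude_sd", "duration_ms"))
  expect_true(all(out0$p_value > 0.001))
  rip1 <- labeled_ripples(2, amp_shift = 2, dur_shift_ms = 15)
  out1 <- compare_ripple_properties(rip1)
  expect_true(all(out1$p_value < 0.01))
  expect_gt(out1$median_memory[1], out1$median_non_memory[1])
  # tiny class -> p NA, summaries still present
  rip2 <- labeled_ripples(3, n_mem = 3, n_non = 50)
  out2 <- compare_ripple_properties(rip2)
  expect_true(all(is.na(out2$p_value)))
})

test_that("firing difference scores: bounds, algebra, exchangeability", {
  # algebraic cases via the internal helper, exercised through the API:
  # construct two units with known rates around labeled ripples
  set.seed(11)
  rip <- labeled_ripples(4, n_mem = 60, n_non = 600, t_hi = 1400)
  # space the onsets so +/-100 ms windows are disjoint (algebraic oracle)
  rip$onset_s <- seq(5, by = 2, length.out = nrow(rip))
  mem <- rip$onset_s[rip$label == "memory"]
  # unit 'mn1': fires once in every memory window, never at non-memory
  sp <- data.frame(unit_id = "mn1", region = "dCA1", time_s = mem + 0.01)
  sc <- firing_difference_scores(rbind(sp), rip, split_seed = 1)
  expect_equal(sc$m_n[sc$unit_id == "mn1"], 1)
  # label-blind Poisson units: scores in [0,1]; m_n comparable to m1_m2
  sp2 <- do.call(rbind, lapply(1:12, function(u) {
    data.frame(unit_id = sprintf("u%02d", u), region = "dCA1",
               time_s = sort(runif(3 * 1400, 0, 1400)))
  }))
  sc2 <- firing_difference_scores(sp2, rip, split_seed = 2)
  expect_true(all(sc2$m_n >= 0 & sc2$m_n <= 1))
  expect_true(all(sc2$m1_m2 >= 0 & sc2$m1_m2 <= 1, na.rm = TRUE))
  # one-sided: under exchangeable labels m_n must not EXCEED its
  # split-half noise floor (class-size asymmetry makes the two-sided
  # comparison reject for the uninteresting reason E[m_n] < E[m1_m2])
  p <- stats::wilcox.test(sc2$m_n, sc2$m1_m2, paired = TRUE,
                          alternative = "greater", exact = FALSE)$p.value
  expect_gt(p, 0.05)
  expect_error(firing_difference_scores(sp2, rip[rip$label != "memory", ]),
               "at least 2")
})

test_that("selectivity index: symmetry, saturation, enlargement ordering", {
  rip0 <- labeled_ripples(5)
  s0 <- selectivity_index(rip0, 6)
  expect_lt(abs(s0 - 0.5), 0.05)
  # all above-threshold ripples are memory-class -> S = 1
  rip1 <- labeled_ripples(6)
  rip1$amplitude_sd <- ifelse(rip1$label == "memory", 20, 5)
  expect_equal(unname(selectivity_index(rip1, 8)), 1)
  # planted enlargement: higher thresholds more selective
  rip2 <- labeled_ripples(7, amp_shift = 2)
  s <- selectivity_index(rip2, c(4, 6, 8))
  expect_true(s["sd8"] >= s["sd6"] && s["sd6"] >= s["sd4"])
  expect_error(selectivity_index(rip0[rip0$label == "memory", ]), "non-empty")
})

test_that("population profiles group units by class-difference response", {
  set.seed(21)
  rip <- labeled_ripples(8, n_mem = 250, n_non = 1200, t_hi = 3500)
  mem <- rip$onset_s[rip$label == "memory"]
  mk <- function(u, extra_at = NULL, frac = 1) {
    ts <- sort(c(runif(2 * 3500, 0, 3500),
                 if (!is.null(extra_at)) {
                   extra_at[runif(length(extra_at)) < frac] + 0.02
                 }))
    data.frame(unit_id = u, region = "dCA1", time_s = ts)
  }
  spikes <- rbind(mk("up1", mem), mk("up2", mem),
                  mk("none1"), mk("none2"), mk("none3"))
  prof <- population_peri_ripple_profiles(spikes, rip)
  expect_equal(sort(prof$summary$unit_id[prof$summary$group == "up"]),
               c("up1", "up2"))
  expect_true(all(prof$summary$group[prof$summary$unit_id %in%
                                       c("none1", "none2", "none3")] == "none"))
  # display order: up -> none -> down
  expect_false(is.unsorted(match(prof$summary$group,
                                 c("up", "none", "down"))))
  expect_equal(nrow(prof$z_memory), 5)
})
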