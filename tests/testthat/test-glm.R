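test_that("window_schedule invariants", {
  s <- window_schedule()
  expect_equal(s$dca1_lo, c(-300, -200, -100, 0))
  expect_equal(s$bla_lo, c(-65, 35, 135, 235))
  expect_true(all(s$dca1_hi - s$dca1_lo == 100))
  expect_true(all(s$bla_hi - s$bla_lo == 100))
  # constant dCA1 -> BLA offset within pairs; offset = lag modulo the width
  off <- unique(s$bla_lo - s$dca1_lo)
  expect_length(off, 1)
  expect_equal(off %% 100, 35)
  s50 <- window_schedule(lag_ms = 50)
  expect_equal(unique(s50$bla_lo - s50$dca1_lo) %% 100, 50)
})

test_that("extract_ripple_counts does exact boundary bookkeeping", {
  sched <- window_schedule()
  sp <- data.frame(unit_id = "u1", region = "dCA1", time_s = 9.95)
  cnt <- extract_ripple_counts(sp, onsets = 10, target_times = numeric(0),
                               sched)
  x <- vapply(cnt, function(cw) cw$X[1, 1], numeric(1))
  expect_equal(x, c(0, 0, 1, 0))           # -50 ms lands in [-100, 0) only
  # silent population -> all zeros
  cnt0 <- extract_ripple_counts(sp[0, ], onsets = c(10, 20),
                                target_times = numeric(0), sched,
                                units = "u1")
  expect_true(all(vapply(cnt0, function(cw) sum(cw$X) + sum(cw$y), 1) == 0))
  # counts match the generator's construction exactly
  w <- glm_world(31, n_dca1 = 12, n_rip_per_epoch = 60)
  cnt1 <- extract_ripple_counts(w$dca1, w$post_onsets, w$target$spikes$time_s,
                                sched)
  cw <- cnt1[[2]]     # pair 2: dCA1 [-200,-100), BLA [35,135)
  u <- sort(unique(w$dca1$unit_id))[3]
  ts <- sort(w$dca1$time_s[w$dca1$unit_id == u])
  manual_x <- vapply(w$post_onsets, function(o) {
    sum(ts >= o - 0.2 & ts < o - 0.1)
  }, numeric(1))
  expect_equal(unname(cw$X[, u]), unname(manual_x))
  tg <- sort(w$target$spikes$time_s)
  manual_y <- vapply(w$post_onsets, function(o) {
    sum(tg >= o + 0.035 & tg < o + 0.135)
  }, numeric(1))
  expect_equal(unname(cw$y), unname(manual_y))
})

test_that("fit_glm: degenerate target, recovery, duplicated predictor", {
  set.seed(41)
  X <- matrix(rpois(200 * 8, 1), 200)
  f0 <- fit_glm(X, rep(0, 200))
  expect_lt(max(predict(f0, X)), 1e-3)
  # parameter recovery on data from the model family
  beta <- runif(8, 0, 0.4)
  eta <- drop(X %*% beta)
  y <- rpois(200, exp(-1 + eta))
  f <- fit_glm(X, y)
  expect_equal(unname(coef(lm(f$coef ~ beta))[2]), 1, tolerance = 0.3)
  # duplicating a predictor leaves predictions essentially unchanged
  X2 <- cbind(X, X[, 1])
  f2 <- fit_glm(X2, y)
  expect_equal(predict(f2, X2), predict(f, X), tolerance = 0.05)
  expect_warning(fit_glm(matrix(rpois(12, 1), 2), c(1, 2)), "unstable")
})

test_that("decode_and_score dissociates coupled from uncoupled epochs", {
  w <- glm_world(42, n_dca1 = 25, n_rip_per_epoch = 200)
  post <- decode_and_score(w$dca1, w$post_onsets, w$target$spikes$time_s,
                           split_seed = 1, n_shuffles = 60)
  pre <- decode_and_score(w$dca1, w$pre_onsets, w$target$spikes$time_s,
                          split_seed = 1, n_shuffles = 60)
  expect_true(all(post$summary$r >= -1 & post$summary$r <= 1, na.rm = TRUE))
  sig_post <- post$summary$r > post$summary$null_q975
  expect_gte(sum(sig_post), 3)
  expect_true(sig_post[4])                 # strongest (ripple-window) pair
  expect_false(isTRUE(pre$summary$r[4] > pre$summary$null_q975[4]))
  # shuffle null centered at zero
  expect_lt(abs(stats::median(post$null_r[, 2])), 0.05)
  expect_error(decode_and_score(w$dca1, w$post_onsets[1:10],
                                w$target$spikes$time_s), "20 ripples")
})

test_that("r approaches 1 in the near-noiseless large-count limit", {
  set.seed(43)
  n <- 300
  X <- matrix(rpois(n * 5, 4), n)
  beta <- rep(0.25, 5)
  mu <- exp(1.2 + drop(X %*% beta) / 2)  # scaled to keep counts sane
  y <- rpois(n, 50 * mu / mean(mu))       # large counts: relative noise small
  tr <- 1:150
  f <- fit_glm(X[tr, ], y[tr])
  r <- stats::cor(predict(f, X[-tr, ]), y[-tr])
  expect_gte(r, 0.9)
})

test_that("weight_split separates sparse from broad coupling", {
  sparse <- c(rep(1, 10), rep(0, 20))
  w1 <- glm_world(44, n_dca1 = 30, n_rip_per_epoch = 400, weights = sparse)
  sp <- weight_split_decoding(w1$dca1, w1$post_onsets,
                              w1$target$spikes$time_s, split_seed = 1,
                              n_shuffles = 60)
  # the ranking puts most coupled units into the top half
  top15 <- sp$ranking$unit_id[1:15]
  expect_gte(sum(sprintf("dca1_%02d", 1:10) %in% top15), 7)
  expect_gt(sp$top$summary$r[4], sp$top$summary$null_q975[4])
  expect_false(isTRUE(sp$bottom$summary$r[4] > sp$bottom$summary$null_q975[4]))
  # broad coupling: both halves decode
  w2 <- glm_world(45, n_dca1 = 30, n_rip_per_epoch = 220,
                  weights = rep(0.15, 30))
  br <- weight_split_decoding(w2$dca1, w2$post_onsets,
                              w2$target$spikes$time_s, split_seed = 1,
                              n_shuffles = 60)
  expect_gt(br$top$summary$r[4], br$top$summary$null_q975[4])
  expect_gt(br$bottom$summary$r[4], br$bottom$summary$null_q975[4])
})
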