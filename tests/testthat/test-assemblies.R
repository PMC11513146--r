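test_that("bin_and_zscore: arithmetic, z-statistics, zero-variance drops", {
  set.seed(1)
  sp <- data.frame(unit_id = "u1", region = "BLA",
                   time_s = sort(runif(2500, 0, 250)))
  mat <- bin_and_zscore(sp, c(0, 10), bin_ms = 25)
  expect_equal(ncol(mat$values), 400)                 # 10 s / 25 ms
  expect_error(bin_and_zscore(sp, c(0, 2)), "100 bins")
  big <- bin_and_zscore(sp, c(0, 250), bin_ms = 25)   # 10^4 bins
  expect_lt(abs(mean(big$values)), 0.05)
  expect_true(stats::sd(big$values) > 0.95 && stats::sd(big$values) < 1.05)
  # silent unit dropped with warning
  sp2 <- rbind(sp, data.frame(unit_id = "silent", region = "BLA",
                              time_s = 999))
  expect_warning(m2 <- bin_and_zscore(sp2, c(0, 250)), "silent")
  expect_false("silent" %in% m2$unit_ids)
  expect_true("silent" %in% m2$dropped_units)
})

test_that("marchenko_pastur_bound closed form and guards", {
  expect_equal(marchenko_pastur_bound(100, 400), 2.25)
  expect_error(marchenko_pastur_bound(100, 100), "n_bins")
  expect_lt(marchenko_pastur_bound(10, 1e7), 1.01)    # q -> 0 limit
})

test_that("count_significant_components: null, planted, duplicated row", {
  # i.i.d. Poisson null: mostly zero components (edge fluctuation allows
  # occasional single exceedances; see the methods vignette)
  nulls <- vapply(1:15, function(s) {
    set.seed(s + 300)
    counts <- matrix(stats::rpois(40 * 6000, 0.2), 40)
    m <- structure(list(values = (counts - rowMeans(counts)) /
                          apply(counts, 1, stats::sd),
                        bin_s = 0.025), class = "binned_matrix")
    count_significant_components(m)
  }, numeric(1))
  expect_gte(mean(nulls == 0), 0.8)
  # planted: two assemblies -> exactly 2
  w <- assembly_world(41, n_bla = 40, sleep_s = 900)
  mat <- bin_and_zscore(w$gen$spikes, w$epoch)
  expect_equal(count_significant_components(mat), 2)
  # duplicating a unit's row adds at least one component
  m2 <- mat
  m2$values <- rbind(m2$values, m2$values[1, ])
  expect_gte(count_significant_components(m2),
             count_significant_components(mat) + 1)
})

test_that("extract_assembly_patterns recovers planted members exactly", {
  w <- assembly_world(7)
  mat <- bin_and_zscore(w$gen$spikes, w$epoch)
  k <- count_significant_components(mat)
  expect_equal(k, 2)
  pats <- extract_assembly_patterns(mat, k, seed = 1)
  expect_length(pats, 2)
  for (p in pats) {
    expect_equal(sum(p$weights^2), 1, tolerance = 1e-10)
    expect_gt(p$weights[which.max(abs(p$weights))], 0)  # sign convention
  }
  expect_all_recovered(w$gen, mat, pats)
  # determinism given seed
  pats2 <- extract_assembly_patterns(mat, k, seed = 1)
  expect_identical(lapply(pats, `[[`, "weights"),
                   lapply(pats2, `[[`, "weights"))
})

test_that("pattern extraction is equivariant to unit order", {
  w <- assembly_world(8, n_bla = 30, sleep_s = 600)
  mat <- bin_and_zscore(w$gen$spikes, w$epoch)
  perm <- sample(nrow(mat$values))
  matp <- mat
  matp$values <- mat$values[perm, ]
  matp$unit_ids <- mat$unit_ids[perm]
  a <- extract_assembly_patterns(mat, 2, seed = 3)
  b <- extract_assembly_patterns(matp, 2, seed = 3)
  # compare member id sets, which are order-free
  key <- function(ps) sort(vapply(ps, function(p) {
    paste(sort(p$member_ids), collapse = ",")
  }, character(1)))
  expect_equal(key(a), key(b))
})

test_that("activation_strength: definition edge cases and planted contrast", {
  w <- assembly_world(9, n_bla = 30, sleep_s = 600)
  mat <- bin_and_zscore(w$gen$spikes, w$epoch)
  pats <- extract_assembly_patterns(mat, 2, seed = 1)
  # zero population vector -> zero strength in both modes
  m0 <- mat
  m0$values[, 1] <- 0
  expect_equal(activation_strength(pats[[1]], m0)$strength[1], 0)
  expect_equal(activation_strength(pats[[1]], m0, mode = "linear")$strength[1], 0)
  # one-hot pattern in quadratic mode is identically zero
  onehot <- list(weights = c(1, rep(0, nrow(mat$values) - 1)))
  expect_equal(max(abs(activation_strength(onehot, mat)$strength)), 0)
  # dimension mismatch
  expect_error(activation_strength(list(weights = c(1, 0)), mat), "match")
  # planted event bins carry much higher strength
  tr <- activation_strength(pats[[1]], mat)
  best <- which.max(vapply(w$gen$members, function(m) {
    jaccard(pats[[1]]$members, member_rows(m, mat))
  }, numeric(1)))
  ev_bins <- findInterval(w$gen$events[[best]], mat$times)
  ev_bins <- ev_bins[ev_bins >= 1]
  expect_gt(mean(tr$strength[ev_bins]), 5 * mean(tr$strength[-ev_bins]))
  # events are exactly the announced rule
  expect_equal(tr$event_bins,
               which(tr$strength > tr$mean + tr$threshold_sd * tr$sd))
})

test_that("surrogate null separates planted structure from chance", {
  w <- assembly_world(10, n_bla = 30, sleep_s = 600)
  mat <- bin_and_zscore(w$gen$spikes, w$epoch)
  pats <- extract_assembly_patterns(mat, 2, seed = 1)
  tr <- activation_strength(pats[[1]], mat)
  real_rate <- length(tr$event_bins) / (ncol(mat$values) * mat$bin_s)
  null <- surrogate_activation_null(pats[[1]], mat, n_surrogates = 100,
                                    seed = 1)
  expect_length(null, 100)
  expect_gt(real_rate, stats::quantile(null, 0.975))
  expect_length(surrogate_activation_null(pats[[1]], mat, 1, seed = 2), 1)
})

test_that("match_assemblies pairs identical and sign-flipped patterns", {
  w <- assembly_world(11, n_bla = 30, sleep_s = 600)
  mat <- bin_and_zscore(w$gen$spikes, w$epoch)
  pats <- extract_assembly_patterns(mat, 2, seed = 1)
  m <- match_assemblies(pats, pats)
  expect_equal(m$pairs$a, m$pairs$b)
  expect_equal(m$pairs$similarity, c(1, 1), tolerance = 1e-12)
  flipped <- lapply(pats, function(p) {
    p$weights <- -p$weights
    p
  })
  m2 <- match_assemblies(pats, flipped)
  expect_equal(m2$pairs$similarity, c(1, 1), tolerance = 1e-12)
  expect_length(m2$unmatched_a, 0)
})

test_that("split-half pattern stability on one session", {
  w <- assembly_world(12, sleep_s = 1600)
  ep <- w$epoch
  half <- (ep[1] + ep[2]) / 2
  m1 <- bin_and_zscore(w$gen$spikes, c(ep[1], half))
  m2 <- bin_and_zscore(w$gen$spikes, c(half, ep[2]))
  p1 <- extract_assembly_patterns(m1, 2, seed = 1)
  p2 <- extract_assembly_patterns(m2, 2, seed = 1)
  mm <- match_assemblies(p1, p2)
  expect_gte(mean(mm$pairs$similarity), 0.8)
})
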