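#' Lag-shifted window schedule for ripple-locked decoding
#'
#' Four 100-ms predictor (dCA1) windows and four 100-ms target (BLA)
#' windows relative to ripple onset.  The protocol's windows are
#' dCA1 `[-300,-200), [-200,-100), [-100,0), [0,100)` ms and BLA
#' `[-65,35), [35,135), [135,235), [235,335)` ms: the BLA grid is the
#' 100-ms grid shifted by the 35-ms dCA1-to-BLA latency, so the constant
#' dCA1-to-BLA offset within a pair is `lag_ms` modulo the 100-ms window
#' width.
#'
#' @param lag_ms dCA1-to-BLA latency in ms (default 35).
#' @return data.frame of class `window_schedule` with columns `pair`,
#'   `dca1_lo`, `dca1_hi`, `bla_lo`, `bla_hi` (ms relative to onset).
#' @export
window_schedule <- function(lag_ms = 35) {
  dlo <- c(-300, -200, -100, 0)
  blo <- c(-100, 0, 100, 200) + lag_ms
  s <- data.frame(pair = seq_along(dlo),
                  dca1_lo = dlo, dca1_hi = dlo + 100,
                  bla_lo = blo, bla_hi = blo + 100)
  class(s) <- c("window_schedule", "data.frame")
  s
}

#' Extract ripple-locked count matrices
#'
#' For each window pair: `X` holds every dCA1 unit's spike count in the
#' dCA1 window of each ripple (ripples x units) and `y` the target's count
#' in the paired BLA window.  Overlapping ripple windows are kept (each
#' ripple is one sample).
#'
#' @param spikes dCA1 spike data.frame (`unit_id`, `time_s`).
#' @param onsets ripple onsets (s).
#' @param target_times target point process (BLA unit spikes or assembly
#'   activation events).
#' @param schedule a [window_schedule()].
#' @param units optional fixed unit order.
#' @return list of length `nrow(schedule)`; each element has `X`, `y`,
#'   `pair`.
#' @export
extract_ripple_counts <- function(spikes, onsets, target_times, schedule,
                                  units = NULL) {
  units <- units %||% sort(unique(spikes$unit_id))
  sp <- split(spikes$time_s, factor(spikes$unit_id, levels = units))
  sp <- lapply(sp, sort)
  target_times <- sort(target_times)
  onsets <- sort(onsets)
  lapply(seq_len(nrow(schedule)), function(p) {
    xlo <- onsets + schedule$dca1_lo[p] / 1000
    xhi <- onsets + schedule$dca1_hi[p] / 1000
    X <- vapply(sp, function(ts) count_in_windows(ts, xlo, xhi),
                numeric(length(onsets)))
    if (is.null(dim(X))) X <- matrix(X, nrow = length(onsets))
    colnames(X) <- units
    y <- count_in_windows(target_times,
                          onsets + schedule$bla_lo[p] / 1000,
                          onsets + schedule$bla_hi[p] / 1000)
    list(X = X, y = y, pair = schedule$pair[p])
  })
}

#' Ridge-penalized Poisson GLM (log link)
#'
#' Iteratively reweighted least squares with a small L2 penalty on the
#' slopes (not the intercept) for separability and collinearity
#' robustness.  On non-convergence the ridge is increased tenfold up to
#' three times before erroring.  Deterministic given the data.
#'
#' @param X predictor matrix (ripples x units), non-negative counts.
#' @param y target count vector.
#' @param ridge initial L2 penalty (default 1e-4).
#' @param max_iter IRLS iterations per attempt.
#' @param tol convergence tolerance on the coefficient change.
#' @return list of class `poisson_ridge`: `intercept`, `coef`,
#'   `ridge_used`, `converged`, `iterations`.
#' @export
fit_glm <- function(X, y, ridge = 1e-4, max_iter = 100, tol = 1e-8) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(y >= 0))
  if (nrow(X) < ncol(X) / 2) {
    warning("fewer than n_units/2 training ripples; fit may be unstable")
  }
  n <- nrow(X); d <- ncol(X)
  if (all(y == 0)) {
    # degenerate target: the MLE intercept is -Inf; return the capped fit
    return(structure(list(intercept = log(1e-8), coef = rep(0, d),
                          ridge_used = ridge, converged = TRUE,
                          iterations = 0L),
                     class = "poisson_ridge"))
  }
  Xi <- cbind(1, X)
  for (attempt in 0:3) {
    lam <- ridge * 10^attempt
    pen <- diag(c(0, rep(lam, d)), d + 1)
    beta <- c(log(mean(y) + 1e-8), rep(0, d))
    ok <- FALSE
    change <- Inf
    it <- 0L
    for (it in seq_len(max_iter)) {
      eta <- pmin(drop(Xi %*% beta), 30)     # cap to avoid overflow
      mu <- exp(eta)
      W <- mu
      z <- eta + (y - mu) / pmax(mu, 1e-10)
      XtW <- t(Xi * W)
      upd <- tryCatch(solve(XtW %*% Xi + n * pen, XtW %*% z),
                      error = function(e) NULL)
      if (is.null(upd) || any(!is.finite(upd))) break
      change <- max(abs(upd - beta))
      beta <- drop(upd)
      if (change < tol) { ok <- TRUE; break }
    }
    if (ok || (it == max_iter && all(is.finite(beta)) && change < 1e-4)) {
      return(structure(list(intercept = beta[1], coef = beta[-1],
                            ridge_used = lam, converged = ok,
                            iterations = it),
                       class = "poisson_ridge"))
    }
  }
  stop("Poisson ridge GLM failed to converge (ridge escalated to ",
       ridge * 1000, ")")
}

#' @export
predict.poisson_ridge <- function(object, newdata, ...) {
  exp(pmin(object$intercept + drop(as.matrix(newdata) %*% object$coef), 30))
}

#' Decode ripple-locked target counts from the dCA1 population
#'
#' Randomly partitions ripples into equal train/test halves, fits the
#' Poisson ridge GLM per window pair on the training half, and scores the
#' Pearson correlation between predicted and observed test counts.  The
#' shuffle control permutes the held-out target counts across ripples
#' (default 100 shuffles) and recomputes the correlation.
#'
#' @param spikes dCA1 spike data.frame.
#' @param onsets ripple onsets (s); at least 20.
#' @param target_times target point process.
#' @param schedule a [window_schedule()].
#' @param split_seed seed for the train/test split and the shuffles.
#' @param n_shuffles shuffle-control size (default 100).
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @param units optional fixed dCA1 unit order.
#' @return object of class `decoding_result`: `summary` data.frame
#'   (`pair`, `r`, `null_q975`, `null_median`, `p_value`, `n_train`,
#'   `n_test`), `coefficients` (units x pairs), `null_r` matrix
#'   (shuffles x pairs), `schedule`.
#' @export
decode_and_score <- function(spikes, onsets, target_times, schedule = window_schedule(),
                             split_seed = 1, n_shuffles = 100,
                             cor_method = "pearson", units = NULL) {
  if (length(onsets) < 20) stop("need at least 20 ripples to decode")
  counts <- extract_ripple_counts(spikes, onsets, target_times, schedule,
                                  units = units)
  n <- length(onsets)
  set.seed(split_seed)
  train <- sort(sample.int(n, floor(n / 2)))
  test <- setdiff(seq_len(n), train)
  perms <- replicate(n_shuffles, sample.int(length(test)))
  rows <- list(); coefs <- list(); nulls <- list()
  for (cw in counts) {
    fit <- fit_glm(cw$X[train, , drop = FALSE], cw$y[train])
    pred <- predict(fit, cw$X[test, , drop = FALSE])
    yte <- cw$y[test]
    r <- safe_cor(pred, yte, cor_method)
    null_r <- apply(perms, 2, function(p) safe_cor(pred, yte[p], cor_method))
    pval <- if (is.na(r)) NA_real_ else mean(null_r >= r, na.rm = TRUE)
    rows[[length(rows) + 1]] <- data.frame(
      pair = cw$pair, r = r,
      null_q975 = stats::quantile(null_r, 0.975, na.rm = TRUE, names = FALSE),
      null_median = stats::median(null_r, na.rm = TRUE),
      p_value = pval, n_train = length(train), n_test = length(test))
    coefs[[length(coefs) + 1]] <- fit$coef
    nulls[[length(nulls) + 1]] <- null_r
  }
  structure(list(summary = do.call(rbind, rows),
                 coefficients = do.call(cbind, coefs),
                 null_r = do.call(cbind, nulls),
                 schedule = schedule),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("<decoding_result>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Rank dCA1 units by peri-target cross-correlation peak
#'
#' Each unit's weight is the peak of its smoothed cross-correlogram
#' (z-scored against the baseline band) around the target's activation
#' events, within +/-`peak_window_ms`.
#'
#' @param spikes dCA1 spike data.frame.
#' @param target_times target activation/spike times.
#' @param peak_window_ms peak search half-window (default 350 ms, wide
#'   enough to cover every window pair of the decoding schedule).
#' @param ... passed to [peri_event_histogram()].
#' @return data.frame `unit_id`, `peak_z`, ordered decreasing.
#' @export
rank_units_by_crosscorr <- function(spikes, target_times, peak_window_ms = 350,
                                    ...) {
  units <- sort(unique(spikes$unit_id))
  pk <- vapply(units, function(u) {
    ts <- sort(spikes$time_s[spikes$unit_id == u])
    peh <- peri_event_histogram(ts, target_times, ...)
    sel <- abs(peh$lag_ms) <= peak_window_ms
    if (all(is.na(peh$z))) return(NA_real_)
    max(peh$z[sel])
  }, numeric(1))
  out <- data.frame(unit_id = units, peak_z = pk, stringsAsFactors = FALSE)
  out <- out[order(-out$peak_z), ]
  rownames(out) <- NULL
  out
}

#' Decode separately with the top and bottom halves of the dCA1 population
#'
#' Units are ranked by their peri-target cross-correlation peak; the top
#' 50% and bottom 50% (middle unit to the bottom half when odd, logged)
#' are decoded independently, each against its own shuffle null.
#'
#' @param spikes dCA1 spike data.frame.
#' @param onsets ripple onsets (s).
#' @param target_times target point process.
#' @param ranking_times times used for the ranking cross-correlogram
#'   (default `target_times`; the protocol ranks on training or post-sleep
#'   activity).
#' @param schedule a [window_schedule()].
#' @param split_seed seed for splits and shuffles.
#' @param n_shuffles shuffle-control size.
#' @return list with `top` and `bottom` [decode_and_score()] results and
#'   `ranking`.
#' @export
weight_split_decoding <- function(spikes, onsets, target_times,
                                  ranking_times = NULL,
                                  schedule = window_schedule(),
                                  split_seed = 1, n_shuffles = 100) {
  ranking <- rank_units_by_crosscorr(spikes, ranking_times %||% target_times)
  n <- nrow(ranking)
  n_top <- floor(n / 2)
  if (n %% 2 == 1) message("odd unit count: middle unit assigned to bottom half")
  top_units <- ranking$unit_id[seq_len(n_top)]
  bot_units <- ranking$unit_id[(n_top + 1):n]
  dec <- function(us) {
    decode_and_score(spikes[spikes$unit_id %in% us, ], onsets, target_times,
                     schedule, split_seed, n_shuffles, units = us)
  }
  list(top = dec(top_units), bottom = dec(bot_units), ranking = ranking)
}
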