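#' Bin spikes and z-score per unit
#'
#' Bins each unit's spike train on a grid anchored at the epoch start
#' (default 25-ms bins) and z-scores each row.  Units with zero count
#' variance (e.g. silent units) are excluded with a warning, since their
#' z-score is undefined.
#'
#' @param spikes data.frame with `unit_id` and `time_s` (optionally
#'   restricted to one region first).
#' @param epoch numeric `c(start_s, end_s)` or a data.frame of intervals
#'   (`start_s`, `end_s`) whose bins are concatenated (e.g. SWS intervals).
#' @param bin_ms bin width in ms (default 25).
#' @param units optional character vector fixing the unit order (silent
#'   units then still appear, and are dropped with a warning).
#' @return object of class `binned_matrix`: `values` (units x bins,
#'   z-scored), `counts` (raw counts), `bin_s`, `times` (bin start times),
#'   `unit_ids`, `dropped_units`.
#' @export
bin_and_zscore <- function(spikes, epoch, bin_ms = 25, units = NULL) {
  bin_s <- bin_ms / 1000
  if (is.data.frame(epoch) || is.matrix(epoch)) {
    iv <- as.data.frame(epoch)
  } else {
    iv <- data.frame(start_s = epoch[1], end_s = epoch[2])
  }
  edges_list <- lapply(seq_len(nrow(iv)), function(i) {
    nb <- floor((iv[i, 2] - iv[i, 1]) / bin_s)
    iv[i, 1] + seq_len(nb) * bin_s - bin_s   # bin start times
  })
  starts <- unlist(edges_list)
  if (length(starts) < 100) stop("epoch must contain at least 100 bins")
  units <- units %||% sort(unique(spikes$unit_id))
  sp <- split(spikes$time_s, factor(spikes$unit_id, levels = units))
  counts <- t(vapply(sp, function(ts) {
    ts <- sort(ts)
    count_in_windows(ts, starts, starts + bin_s)
  }, numeric(length(starts))))
  sds <- apply(counts, 1, stats::sd)
  drop <- sds == 0 | is.na(sds)
  if (any(drop)) {
    warning("dropping ", sum(drop), " zero-variance unit(s): ",
            paste(units[drop], collapse = ", "))
  }
  vals <- (counts[!drop, , drop = FALSE] -
             rowMeans(counts[!drop, , drop = FALSE])) / sds[!drop]
  structure(list(values = vals, counts = counts[!drop, , drop = FALSE],
                 bin_s = bin_s, times = starts,
                 unit_ids = units[!drop], dropped_units = units[drop]),
            class = "binned_matrix")
}

#' Marchenko-Pastur upper eigenvalue bound
#'
#' Largest eigenvalue of the correlation matrix expected for uncorrelated
#' data with `n_units` rows and `n_bins` columns:
#' `(1 + sqrt(n_units / n_bins))^2`.
#'
#' @param n_units,n_bins matrix dimensions; requires `n_bins > n_units`.
#' @return the bound (a scalar > 1).
#' @export
marchenko_pastur_bound <- function(n_units, n_bins) {
  if (n_bins <= n_units) stop("Marchenko-Pastur bound requires n_bins > n_units")
  (1 + sqrt(n_units / n_bins))^2
}

correlation_eigen <- function(mat) {
  Z <- mat$values
  C <- tcrossprod(Z) / (ncol(Z) - 1)
  eigen(C, symmetric = TRUE)
}

#' Count significant co-activation components
#'
#' Number of correlation-matrix eigenvalues strictly above the
#' Marchenko-Pastur bound.
#'
#' @param mat a [bin_and_zscore()] result.
#' @return non-negative integer.
#' @export
count_significant_components <- function(mat) {
  stopifnot(inherits(mat, "binned_matrix"))
  lam <- correlation_eigen(mat)$values
  bound <- marchenko_pastur_bound(nrow(mat$values), ncol(mat$values))
  sum(lam > bound)
}

sym_decorrelate <- function(W) {
  s <- eigen(W %*% t(W), symmetric = TRUE)
  s$vectors %*% diag(1 / sqrt(s$values), nrow(W)) %*% t(s$vectors) %*% W
}

# FastICA with symmetric decorrelation and tanh (logcosh) nonlinearity.
# X must be whitened (rows uncorrelated, unit variance).
fast_ica_core <- function(X, seed, max_iter = 500, tol = 1e-6) {
  d <- nrow(X)
  set.seed(seed)
  W <- sym_decorrelate(matrix(stats::rnorm(d * d), d))
  B <- ncol(X)
  for (it in seq_len(max_iter)) {
    WX <- W %*% X
    G <- tanh(WX)
    W1 <- G %*% t(X) / B - diag(rowMeans(1 - G^2), d) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) return(list(W = W, converged = TRUE, iterations = it))
  }
  list(W = W, converged = FALSE, iterations = max_iter)
}

#' Extract assembly patterns by PCA projection plus ICA rotation
#'
#' Projects the z-scored population matrix onto its `n_components` leading
#' principal components (the ones above the Marchenko-Pastur bound), runs
#' FastICA on the whitened projection, and maps the unmixing rows back to
#' unit space.  Each pattern is normalized to unit length with the sign
#' convention that its largest-magnitude entry is positive; members are the
#' units whose weight exceeds the pattern's mean weight + 2 s.d.  Patterns
#' are ordered by explained variance (descending).
#'
#' @param mat a [bin_and_zscore()] result.
#' @param n_components number of patterns (typically from
#'   [count_significant_components()]); must be >= 1.
#' @param seed FastICA seed (deterministic given seed).
#' @param member_sd member criterion in s.d. of the weights (default 2).
#' @param max_retries re-seeds tried on ICA non-convergence before erroring.
#' @return list of class `assembly_patterns`; each element has `weights`
#'   (named, unit length), `members` (indices into `mat$unit_ids`),
#'   `member_ids`, `id`, `explained_variance`.
#' @export
extract_assembly_patterns <- function(mat, n_components, seed = 1,
                                      member_sd = 2, max_retries = 3) {
  stopifnot(inherits(mat, "binned_matrix"))
  if (n_components < 1) stop("n_components must be >= 1")
  Z <- mat$values
  eg <- correlation_eigen(mat)
  P <- eg$vectors[, seq_len(n_components), drop = FALSE]
  lam <- eg$values[seq_len(n_components)]
  Y <- diag(1 / sqrt(lam), n_components) %*% t(P) %*% Z   # whitened scores
  res <- NULL
  for (try in 0:max_retries) {
    res <- fast_ica_core(Y, seed + try)
    if (res$converged) break
  }
  if (!res$converged) stop("FastICA failed to converge after ", max_retries + 1,
                           " seeds")
  V <- P %*% t(res$W)          # patterns in unit space (rotation of the PCs)
  C <- tcrossprod(Z) / (ncol(Z) - 1)
  pats <- lapply(seq_len(ncol(V)), function(k) {
    w <- V[, k]
    w <- w / sqrt(sum(w^2))
    if (w[which.max(abs(w))] < 0) w <- -w
    names(w) <- mat$unit_ids
    members <- which(w > mean(w) + member_sd * stats::sd(w))
    list(weights = w, members = members,
         member_ids = mat$unit_ids[members],
         explained_variance = drop(t(w) %*% C %*% w))
  })
  ord <- order(vapply(pats, `[[`, 1, "explained_variance"), decreasing = TRUE)
  pats <- pats[ord]
  for (k in seq_along(pats)) pats[[k]]$id <- k
  structure(pats, class = "assembly_patterns")
}

#' @export
print.assembly_patterns <- function(x, ...) {
  cat(sprintf("<assembly_patterns> %d pattern(s)\n", length(x)))
  for (p in x) {
    cat(sprintf("  #%d: %d members (%s); expl.var %.3f\n", p$id,
                length(p$members), paste(p$member_ids, collapse = ", "),
                p$explained_variance))
  }
  invisible(x)
}

#' Assembly activation strength and supra-threshold events
#'
#' Projects each z-scored population column onto an assembly pattern.  In
#' the default `quadratic` mode the strength is the quadratic form
#' `z' P z` with projector `P = w w'` and zeroed diagonal, which removes
#' single-unit contributions; `linear` mode is the plain projection `w . z`.
#' Activation events are the bins whose strength exceeds the mean by
#' `threshold_sd` s.d. (default 5).
#'
#' @param pattern one element of [extract_assembly_patterns()] (or any list
#'   with a `weights` vector matching `mat$unit_ids`).
#' @param mat a [bin_and_zscore()] result sharing the unit indexing.
#' @param mode `"quadratic"` (default) or `"linear"`.
#' @param threshold_sd event criterion (default 5).
#' @return object of class `activation_trace`: `strength`, `times` (bin
#'   starts), `bin_s`, `mean`, `sd`, `threshold_sd`, `event_bins`,
#'   `event_times` (bin centers), `mode`.
#' @export
activation_strength <- function(pattern, mat, mode = c("quadratic", "linear"),
                                threshold_sd = 5) {
  mode <- match.arg(mode)
  stopifnot(inherits(mat, "binned_matrix"))
  w <- pattern$weights
  if (length(w) != nrow(mat$values)) {
    stop("pattern length (", length(w), ") does not match matrix units (",
         nrow(mat$values), ")")
  }
  Z <- mat$values
  p <- drop(crossprod(Z, w))
  strength <- if (mode == "quadratic") p^2 - drop(crossprod(Z^2, w^2)) else p
  mu <- mean(strength)
  sdv <- stats::sd(strength)
  ev <- which(strength > mu + threshold_sd * sdv)
  structure(list(strength = strength, times = mat$times, bin_s = mat$bin_s,
                 mean = mu, sd = sdv, threshold_sd = threshold_sd,
                 event_bins = ev, event_times = mat$times[ev] + mat$bin_s / 2,
                 mode = mode),
            class = "activation_trace")
}

#' Surrogate-assembly null distribution of activation event rates
#'
#' Builds surrogate data by independently circularly shifting each unit's
#' bin series (preserves autocorrelation, destroys co-activation) -- or by
#' fully permuting each row -- recomputes the activation strength for the
#' same pattern, and returns each surrogate's event rate (events/s).
#' The event threshold (mean + 5 s.d. of the *real* activation trace) is
#' held fixed across surrogates: the surrogate distribution answers how
#' often data without co-activation would cross the assembly's own
#' threshold, which is the usual fixed-statistic permutation logic.
#'
#' @param pattern assembly pattern (see [activation_strength()]).
#' @param mat a [bin_and_zscore()] result.
#' @param n_surrogates number of surrogates (default 500).
#' @param seed RNG seed.
#' @param method `"circular"` (default) or `"permute"`.
#' @param mode,threshold_sd passed to [activation_strength()].
#' @return numeric vector of length `n_surrogates` (event rates, events/s).
#' @export
surrogate_activation_null <- function(pattern, mat, n_surrogates = 500,
                                      seed = 1, method = c("circular", "permute"),
                                      mode = "quadratic", threshold_sd = 5) {
  method <- match.arg(method)
  stopifnot(n_surrogates >= 1)
  set.seed(seed)
  Z <- mat$values
  n <- nrow(Z); B <- ncol(Z)
  total_s <- B * mat$bin_s
  real <- activation_strength(pattern, mat, mode = mode,
                              threshold_sd = threshold_sd)
  cut <- real$mean + threshold_sd * real$sd
  smat <- mat
  vapply(seq_len(n_surrogates), function(s) {
    if (method == "circular") {
      sh <- sample.int(B, n, replace = TRUE)
      idx <- (matrix(seq_len(B) - 1L, n, B, byrow = TRUE) + sh) %% B + 1L
      Zs <- Z[cbind(rep(seq_len(n), B), as.vector(idx))]
      dim(Zs) <- c(n, B)
    } else {
      Zs <- t(apply(Z, 1, sample))
    }
    smat$values <- Zs
    str <- activation_strength(pattern, smat, mode = mode,
                               threshold_sd = threshold_sd)$strength
    sum(str > cut) / total_s
  }, numeric(1))
}

#' Match two sets of assembly patterns
#'
#' Greedy one-to-one pairing maximizing absolute cosine similarity
#' (patterns are sign-ambiguous).  Patterns left without a partner are
#' flagged as unmatched.
#'
#' @param patterns_a,patterns_b `assembly_patterns` lists over the same
#'   unit universe.
#' @return list with `pairs` (data.frame `a`, `b`, `similarity`),
#'   `unmatched_a`, `unmatched_b`.
#' @export
match_assemblies <- function(patterns_a, patterns_b) {
  A <- vapply(patterns_a, function(p) p$weights, numeric(length(patterns_a[[1]]$weights)))
  B <- vapply(patterns_b, function(p) p$weights, numeric(length(patterns_b[[1]]$weights)))
  S <- abs(t(A) %*% B)
  pairs <- data.frame(a = integer(0), b = integer(0), similarity = numeric(0))
  Sw <- S
  while (nrow(Sw) * ncol(Sw) > 0 && any(is.finite(Sw))) {
    ij <- arrayInd(which.max(Sw), dim(Sw))
    a <- ij[1]; b <- ij[2]
    pairs <- rbind(pairs, data.frame(a = a, b = b, similarity = S[a, b]))
    Sw[a, ] <- -Inf
    Sw[, b] <- -Inf
    if (nrow(pairs) == min(dim(S))) break
  }
  pairs <- pairs[order(pairs$a), ]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       unmatched_a = setdiff(seq_len(nrow(S)), pairs$a),
       unmatched_b = setdiff(seq_len(ncol(S)), pairs$b))
}
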