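#' Analysis run configuration
#'
#' Aggregates every stage parameter with defaults equal to the protocol's
#' published constants: 25-ms assembly bins, 5/1 s.d. ripple peak/boundary
#' thresholds with a 20-ms minimum duration, the 3.3-z / 3-consecutive-bin
#' modulation rule, 2-s.d. pattern membership, 5-s.d. activation events,
#' 500 surrogates, 100 shuffles, the 35-ms lag window schedule, the 0.4-Hz
#' place-cell filter and the 8-s.d. closed-loop trigger.
#'
#' @param seed master seed; all stage seeds are derived from it.
#' @param bin_ms assembly bin width.
#' @param ripple_peak_sd,ripple_boundary_sd,ripple_min_ms ripple detector.
#' @param content_peak_sd lower ripple threshold used for content analyses.
#' @param activation_sd activation-event threshold.
#' @param member_sd pattern-membership threshold.
#' @param z_thresh,consec_bins modulation rule.
#' @param n_surrogates,n_shuffles surrogate/shuffle counts.
#' @param lag_ms GLM lag.
#' @param place_peak_hz place-cell filter.
#' @param trigger_sd closed-loop trigger threshold.
#' @param memory_ripple_sd activation criterion (s.d. above median) for
#'   memory-ripple labeling.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, bin_ms = 25, ripple_peak_sd = 5,
                       ripple_boundary_sd = 1, ripple_min_ms = 20,
                       content_peak_sd = 3, activation_sd = 5, member_sd = 2,
                       z_thresh = 3.3, consec_bins = 3, n_surrogates = 500,
                       n_shuffles = 100, lag_ms = 35, place_peak_hz = 0.4,
                       trigger_sd = 8, memory_ripple_sd = 2) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

write_csv_out <- function(df, dir, name) {
  data.table::fwrite(df, file.path(dir, name))
}

#' Run the full dCA1-BLA analysis pipeline
#'
#' Stage order: slow-wave-sleep detection, ripple detection per sleep
#' epoch, BLA assembly extraction from post-training SWS, memory
#' classification (peri-ripple modulation, RMI/MAI, permutation test),
#' ripple taxonomy (memory/non-memory labels, property comparison, content
#' scores, selectivity), GLM decoding of the memory assembly from the dCA1
#' population (pre vs post), and spatial information scoring (when a
#' position trace exists).  Stages whose inputs are absent are skipped
#' with a warning.  All results are written as CSV/JSON under `out_dir`
#' together with a deterministic run manifest.
#'
#' @param bundle a `session_bundle`.
#' @param cfg a [run_config()].
#' @param out_dir output directory.
#' @return invisible list of all stage results.
#' @export
run_pipeline <- function(bundle, cfg = run_config(), out_dir) {
  stopifnot(inherits(bundle, "session_bundle"))
  validate_epochs(bundle$epochs)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(cfg$seed, 6)
  res <- list()
  counts <- list()
  stage <- "init"
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (partial outputs preserved in ", out_dir, ")", call. = FALSE)
    })
  }
  epochs <- bundle$epochs
  sleep_eps <- intersect(c("pre_sleep", "post_sleep"), epochs$name)
  has_lfp <- !is.null(bundle$lfp)

  # --- SWS + ripples ---------------------------------------------------
  sws <- list(); ripples <- list()
  if (!has_lfp) {
    warning("no LFP in bundle: ripple stages skipped")
  } else {
    run_stage("ripples", {
      fs <- bundle$lfp$fs
      for (ep in sleep_eps) {
        w <- unlist(epochs[epochs$name == ep, c("start_s", "end_s")])
        idx <- seq(max(1, round(w[1] * fs) + 1), min(length(bundle$lfp$samples),
                                                     round(w[2] * fs)))
        seg <- bundle$lfp$samples[idx]
        env <- ripple_envelope(seg, fs)
        ev0 <- detect_ripples(env, fs, cfg$ripple_peak_sd,
                              cfg$ripple_boundary_sd, cfg$ripple_min_ms,
                              t0 = w[1])
        si <- detect_sws(seg, fs, ripples = ev0, t0 = w[1])
        ev <- detect_ripples(env, fs, cfg$ripple_peak_sd,
                             cfg$ripple_boundary_sd, cfg$ripple_min_ms,
                             stats_intervals = si, t0 = w[1])
        ev$epoch <- ep
        sws[[ep]] <- si
        ripples[[ep]] <- ev
      }
      all_sws <- do.call(rbind, lapply(names(sws), function(e) {
        cbind(sws[[e]], epoch = e)
      }))
      write_csv_out(all_sws, out_dir, "sws_intervals.csv")
      write_csv_out(do.call(rbind, ripples), out_dir, "ripples.csv")
      counts$ripples <- vapply(ripples, nrow, 1L)
    })
  }
  res$sws <- sws
  res$ripples <- ripples

  # --- assemblies ------------------------------------------------------
  bla <- bundle$spikes[bundle$spikes$region == "BLA", ]
  post_iv <- if (length(sws) && !is.null(sws$post_sleep) && nrow(sws$post_sleep)) {
    sws$post_sleep
  } else {
    epochs[epochs$name == "post_sleep", c("start_s", "end_s")]
  }
  run_stage("assemblies", {
    mat_post <- bin_and_zscore(bla, post_iv, cfg$bin_ms)
    n_sig <- count_significant_components(mat_post)
    counts$significant_components <- n_sig
    if (n_sig < 1) stop("no significant co-activation components")
    pats <- extract_assembly_patterns(mat_post, n_sig, seed = seeds[1],
                                      member_sd = cfg$member_sd)
    wtab <- data.frame(unit_id = mat_post$unit_ids,
                       vapply(pats, function(p) p$weights,
                              numeric(length(mat_post$unit_ids))))
    names(wtab)[-1] <- sprintf("assembly_%02d", seq_along(pats))
    write_csv_out(wtab, out_dir, "assembly_weights.csv")
    res$patterns <- pats
    res$mat_post <- mat_post
  })

  # --- activation traces + memory classification -----------------------
  pre_w <- unlist(epochs[epochs$name == "pre_sleep", c("start_s", "end_s")])
  train_w <- unlist(epochs[epochs$name == "training", c("start_s", "end_s")])
  if (!("post_sleep" %in% epochs$name)) {
    warning("no post-sleep epoch: memory classification skipped")
  } else if (length(ripples) < 2 || !nrow(ripples$pre_sleep %||% data.frame())) {
    warning("pre/post ripples unavailable: memory classification skipped")
  } else {
    run_stage("memory_classification", {
      # activation events per assembly, using post-SWS templates, on each
      # epoch's 25-ms grid (events = the assembly point process)
      whole <- rbind(data.frame(start_s = pre_w[1], end_s = pre_w[2]),
                     data.frame(start_s = train_w[1], end_s = train_w[2]),
                     epochs[epochs$name == "post_sleep", c("start_s", "end_s")])
      mat_all <- bin_and_zscore(bla, whole, cfg$bin_ms,
                                units = res$mat_post$unit_ids)
      traces <- lapply(res$patterns, activation_strength, mat = mat_all,
                       threshold_sd = cfg$activation_sd)
      activity <- lapply(traces, function(tr) tr$event_times)
      names(activity) <- sprintf("assembly_%02d", seq_along(activity))
      tab <- memory_index_table(activity,
                                pre_onsets = ripples$pre_sleep$onset_s,
                                post_onsets = ripples$post_sleep$onset_s,
                                baseline_intervals = post_iv,
                                training_epoch = train_w,
                                shocks = bundle$shock_times)
      write_csv_out(tab, out_dir, "memory_classification.csv")
      perm <- permutation_test_proportion(activity, ripples$post_sleep$onset_s,
                                          post_iv, n_shuffles = cfg$n_shuffles,
                                          seed = seeds[2])
      jsonlite::write_json(perm, file.path(out_dir, "permutation_test.json"),
                           auto_unbox = TRUE, digits = NA)
      counts$memory_assemblies <- sum(tab$label == "memory")
      res$memory_table <- tab
      res$traces <- traces
      res$permutation <- perm
    })
  }

  # --- ripple taxonomy -------------------------------------------------
  dca1 <- bundle$spikes[bundle$spikes$region == "dCA1", ]
  mem_idx <- if (!is.null(res$memory_table)) which(res$memory_table$label == "memory") else integer(0)
  if (length(mem_idx)) {
    run_stage("taxonomy", {
      tr <- res$traces[[mem_idx[1]]]
      labeled <- classify_ripples(ripples$post_sleep, tr,
                                  threshold_sd = cfg$memory_ripple_sd)
      write_csv_out(labeled, out_dir, "ripples_labeled.csv")
      props <- compare_ripple_properties(labeled)
      write_csv_out(props, out_dir, "ripple_properties.csv")
      if (sum(labeled$label == "memory") >= 2 &&
          sum(labeled$label == "non_memory") >= 2) {
        scores <- firing_difference_scores(dca1, labeled, split_seed = seeds[3])
        write_csv_out(scores, out_dir, "content_scores.csv")
        sel <- selectivity_index(labeled)
        jsonlite::write_json(as.list(sel), file.path(out_dir, "selectivity.json"),
                             auto_unbox = TRUE, digits = NA)
        res$content_scores <- scores
        res$selectivity <- sel
      }
      counts$memory_ripples <- sum(labeled$label == "memory")
      counts$non_memory_ripples <- sum(labeled$label == "non_memory")
      res$labeled_ripples <- labeled
    })
  } else if (!is.null(res$memory_table)) {
    warning("no memory assembly found: taxonomy skipped")
  }

  # --- GLM decoding ----------------------------------------------------
  if (length(mem_idx) && length(unique(dca1$unit_id)) > 20) {
    run_stage("glm_decoding", {
      target <- res$traces[[mem_idx[1]]]$event_times
      schedule <- window_schedule(cfg$lag_ms)
      dec <- list()
      for (ep in names(ripples)) {
        if (nrow(ripples[[ep]]) < 20) next
        dec[[ep]] <- decode_and_score(dca1, ripples[[ep]]$onset_s, target,
                                      schedule, split_seed = seeds[4],
                                      n_shuffles = cfg$n_shuffles)
      }
      dsum <- do.call(rbind, lapply(names(dec), function(e) {
        cbind(epoch = e, dec[[e]]$summary)
      }))
      write_csv_out(dsum, out_dir, "glm_decoding.csv")
      res$decoding <- dec
    })
  }

  # --- spatial ---------------------------------------------------------
  if (is.null(bundle$position)) {
    warning("no position trace: spatial stage skipped")
  } else {
    run_stage("spatial", {
      units <- sort(unique(dca1$unit_id))
      maps <- lapply(units, function(u) {
        ts <- dca1$time_s[dca1$unit_id == u]
        build_rate_map(ts, bundle$position)
      })
      names(maps) <- units
      si_tab <- data.frame(
        unit_id = units,
        peak_hz = vapply(maps, function(m) m$peak_rate_hz, 1),
        si_bits_per_spike = vapply(maps, function(m) m$si_bits_per_spike, 1))
      si_tab$included <- si_tab$unit_id %in% place_cell_filter(maps, cfg$place_peak_hz)
      write_csv_out(si_tab, out_dir, "spatial_information.csv")
      counts$place_cells <- sum(si_tab$included)
      res$spatial <- si_tab
    })
  }

  manifest <- list(package_version = as.character(utils::packageVersion("swrassembly")),
                   config = unclass(cfg), counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
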