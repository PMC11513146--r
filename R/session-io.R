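#' Write a session bundle to a directory
#'
#' Flat-file session format: `spikes.csv` (`unit_id`, `region`, `time_s`),
#' `lfp.csv` (one `sample_uv` column; sampling rate in `session.json`),
#' `session.json` (epochs, shock times, LFP metadata), optional
#' `position.csv` and `truth.json` (ground truth for synthetic sessions).
#'
#' @param bundle a `session_bundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(bundle, dir) {
  stopifnot(inherits(bundle, "session_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(bundle$spikes, file.path(dir, "spikes.csv"))
  meta <- list(epochs = bundle$epochs,
               shock_times = bundle$shock_times %||% numeric(0))
  if (!is.null(bundle$lfp)) {
    data.table::fwrite(data.table::data.table(sample_uv = bundle$lfp$samples),
                       file.path(dir, "lfp.csv"))
    meta$lfp <- list(fs = bundle$lfp$fs, t0 = bundle$lfp$t0 %||% 0,
                     units = "uV")
  }
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(bundle$position)) {
    data.table::fwrite(bundle$position, file.path(dir, "position.csv"))
  }
  if (!is.null(bundle$truth)) {
    jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         force = TRUE)
  }
  invisible(dir)
}

validate_epochs <- function(epochs) {
  stopifnot(all(c("name", "start_s", "end_s") %in% names(epochs)))
  if (any(epochs$end_s <= epochs$start_s)) stop("epoch with non-positive length")
  if (is.unsorted(epochs$start_s, strictly = TRUE)) {
    stop("epochs must be ordered by start time")
  }
  if (nrow(epochs) > 1 &&
      any(epochs$start_s[-1] < epochs$end_s[-nrow(epochs)])) {
    stop("epochs overlap")
  }
  epochs
}

#' Load a session bundle from a directory
#'
#' Reads and validates the flat-file format written by [write_session()]:
#' requires `spikes.csv` and `session.json`; `lfp.csv`, `position.csv`
#' and `truth.json` are optional.  Validation failures name the offending
#' file and value.
#'
#' @param dir session directory.
#' @return a `session_bundle`.
#' @export
load_session <- function(dir) {
  spikes_f <- file.path(dir, "spikes.csv")
  meta_f <- file.path(dir, "session.json")
  for (f in c(spikes_f, meta_f)) {
    if (!file.exists(f)) stop("missing required session file: ", f)
  }
  spikes <- as.data.frame(data.table::fread(spikes_f))
  bad <- setdiff(unique(spikes$region), c("dCA1", "BLA"))
  if (length(bad)) {
    stop("spikes.csv: unknown region label(s): ", paste(bad, collapse = ", "))
  }
  spikes <- spikes[order(spikes$unit_id, spikes$time_s), ]
  rownames(spikes) <- NULL
  meta <- jsonlite::read_json(meta_f, simplifyVector = TRUE)
  epochs <- validate_epochs(as.data.frame(meta$epochs))
  total <- max(epochs$end_s)
  if (any(spikes$time_s < 0 | spikes$time_s > total)) {
    stop("spikes.csv: spike times outside the session epochs")
  }
  lfp <- NULL
  lfp_f <- file.path(dir, "lfp.csv")
  if (file.exists(lfp_f)) {
    samples <- data.table::fread(lfp_f)[["sample_uv"]]
    lfp <- structure(list(samples = samples, fs = meta$lfp$fs,
                          t0 = meta$lfp$t0 %||% 0),
                     class = "lfp_trace")
  }
  position <- NULL
  pos_f <- file.path(dir, "position.csv")
  if (file.exists(pos_f)) position <- as.data.frame(data.table::fread(pos_f))
  truth <- NULL
  truth_f <- file.path(dir, "truth.json")
  if (file.exists(truth_f)) {
    truth <- jsonlite::read_json(truth_f, simplifyVector = TRUE)
  }
  structure(list(spikes = spikes, lfp = lfp, epochs = epochs,
                 shock_times = unlist(meta$shock_times) %||% numeric(0),
                 position = position, truth = truth, config = NULL),
            class = "session_bundle")
}
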