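#' Write a session bundle to disk
#'
#' A bundle is a directory of plain-text files: `trials.csv` (one row per
#' stimulus event), `counts.csv` (long-format neuron/event/bin spike
#' counts), `pupil.csv` (time, size), `meta.json` (array dimensions and
#' window metadata) and, for synthetic sessions, `truth.json` with the
#' generating parameters.
#'
#' @param session A `task_session`.
#' @param path Directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "task_session"))
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create bundle directory '%s'.", path))
  }
  readr::write_csv(session$events, file.path(path, "trials.csv"), progress = FALSE)
  d <- dim(session$counts)
  idx <- which(session$counts != 0L, arr.ind = TRUE)
  long <- data.table::data.table(
    neuron = idx[, 1], event = idx[, 2], bin = idx[, 3],
    count = session$counts[idx]
  )
  data.table::fwrite(long, file.path(path, "counts.csv"))
  if (!is.null(session$pupil)) {
    readr::write_csv(session$pupil, file.path(path, "pupil.csv"), progress = FALSE)
  }
  meta <- list(
    n_neurons = d[1], n_events = d[2], n_bins = d[3],
    bin_width_s = session$bins$bin_width,
    n_baseline = session$bins$n_baseline, n_evoked = session$bins$n_evoked
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE)
  if (!is.null(session$truth)) {
    tr <- session$truth
    tr_json <- lapply(tr, function(x) if (is.matrix(x)) unclass(x) else x)
    jsonlite::write_json(tr_json, file.path(path, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a session bundle from disk
#'
#' Inverse of [write_session()]; validates that the counts array, trial
#' table and metadata agree. A missing pupil file disables pupil features
#' with a warning; a missing truth sidecar simply yields `truth = NULL`.
#'
#' @param path Bundle directory.
#' @return A `task_session`.
#' @export
read_session <- function(path) {
  meta_f <- file.path(path, "meta.json")
  if (!file.exists(meta_f)) abort(sprintf("No meta.json in '%s': not a session bundle.", path))
  meta <- jsonlite::read_json(meta_f, simplifyVector = TRUE)
  events <- readr::read_csv(file.path(path, "trials.csv"),
                            show_col_types = FALSE, progress = FALSE)
  if (nrow(events) != meta$n_events) {
    abort(sprintf("Axis mismatch: trials.csv has %d events but meta.json declares %d.",
                  nrow(events), meta$n_events))
  }
  long <- data.table::fread(file.path(path, "counts.csv"))
  if (nrow(long) > 0 &&
      (max(long$neuron) > meta$n_neurons || max(long$event) > meta$n_events ||
       max(long$bin) > meta$n_bins)) {
    abort("Axis mismatch: counts.csv indices exceed the declared array dimensions.")
  }
  counts <- array(0L, dim = c(meta$n_neurons, meta$n_events, meta$n_bins))
  counts[cbind(long$neuron, long$event, long$bin)] <- long$count
  pupil_f <- file.path(path, "pupil.csv")
  pupil <- NULL
  if (file.exists(pupil_f)) {
    pupil <- readr::read_csv(pupil_f, show_col_types = FALSE, progress = FALSE)
  } else {
    warn("No pupil.csv in bundle; pupil-dependent analyses are disabled.")
  }
  truth <- NULL
  truth_f <- file.path(path, "truth.json")
  if (file.exists(truth_f)) {
    truth <- jsonlite::read_json(truth_f, simplifyVector = TRUE)
    for (nm in c("mu_active", "mu_passive", "loadings_active", "loadings_passive",
                 "gain")) {
      truth[[nm]] <- as.matrix(truth[[nm]])
      if (nm %in% c("mu_active", "mu_passive", "gain")) {
        colnames(truth[[nm]]) <- truth$stimuli
      }
    }
    class(truth) <- "ground_truth"
  }
  structure(
    list(
      events = events, counts = counts,
      bins = list(bin_width = meta$bin_width_s, n_baseline = meta$n_baseline,
                  n_evoked = meta$n_evoked),
      pupil = pupil, truth = truth, config = NULL
    ),
    class = "task_session"
  )
}

#' Write a ready-made synthetic fixture bundle
#'
#' @param path Directory for the bundle.
#' @param region_mode Passed to [ground_truth()].
#' @param seed Session seed.
#' @param ... Further arguments to [simulate_session()] / [ground_truth()].
#' @return The session object, invisibly.
#' @export
make_fixture <- function(path, region_mode = c("dPEG_like", "A1_like"),
                         seed = 1L, ...) {
  region_mode <- match.arg(region_mode)
  cfg <- session_config(seed = seed)
  s <- simulate_session(cfg, region_mode = region_mode, ...)
  write_session(s, path)
  invisible(s)
}
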