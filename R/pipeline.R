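# Convenience composition: simulated nights -> normalized records ->
# window tensors -> training/validation structures.

#' Convert a simulated PSG-like night into a normalized 10 Hz record
#'
#' Decimates the belts to `to_fs` when simulated at a higher rate, aligns
#' labels, applies robust per-channel normalization and attaches severity.
#'
#' @param night A night from [simulate_night()].
#' @param to_fs Target rate (10 Hz).
#' @return A [night_record()].
#' @export
psg_night_record <- function(night, to_fs = 10) {
  chest <- night$chest; abd <- night$abd; labels <- night$labels
  if (night$fs != to_fs) {
    chest <- decimate_signal(chest, night$fs, to_fs)
    abd <- decimate_signal(abd, night$fs, to_fs)
    ev10 <- events_to_samples(night$events, to_fs)
    labels <- rasterize_labels(ev10, length(chest))
  }
  al <- align_and_trim(chest, abd, labels)
  night_record(robust_normalize(al$chest), robust_normalize(al$abd),
               al$labels, fs = to_fs,
               night_id = night$night_id %||% NA_character_,
               severity = grade_severity(night$true_ahi %||% 0))
}

#' Convert a simulated radar night into a normalized 10 Hz record
#'
#' Runs the full radar chain ([extract_radar_respiration()]) on the night's
#' range-bin cube against its synchronized reference belts, rasterizes the
#' truth events at 10 Hz, normalizes, and assembles the record.
#'
#' @param night A night from [simulate_night()] with a `cube`.
#' @param cfg A [ridge_config()].
#' @param to_fs Target rate (10 Hz).
#' @return A [night_record()].
#' @export
radar_night_record <- function(night, cfg = ridge_config(), to_fs = 10) {
  stopifnot(!is.null(night$cube))
  L10 <- floor(length(night$chest) / (night$fs / to_fs))
  ev10 <- events_to_samples(night$events, to_fs)
  labels10 <- rasterize_labels(ev10, L10)
  ex <- extract_radar_respiration(
    night$cube, y_chest = night$chest, y_abd = night$abd,
    labels_10 = labels10, cfg = cfg,
    carrier_freq_hz = night$rparams$carrier_freq_hz, to_fs = to_fs)
  night_record(robust_normalize(ex$chest), robust_normalize(ex$abd),
               ex$labels, fs = to_fs,
               night_id = night$night_id %||% NA_character_,
               severity = grade_severity(night$true_ahi %||% 0))
}

#' Convert second-based events to sample-index intervals
#'
#' Seconds map to half-open 0-based sample intervals via
#' `[floor(start * fs), ceiling(end * fs))`.
#'
#' @param events Data.frame with `start_s`, `end_s`, `code`.
#' @param fs Sampling rate in Hz.
#' @return An `event_intervals` data.frame.
#' @export
events_to_samples <- function(events, fs) {
  out <- data.frame(start = sec_to_start(events$start_s, fs),
                    end = sec_to_end(events$end_s, fs),
                    code = as.integer(events$code))
  class(out) <- c("event_intervals", "data.frame")
  out
}

#' Stack a list of night records into training tensors + night structures
#'
#' Windows every night and concatenates the tensors; also returns, per
#' night, the structure used by the event-F1 validation callback (windows,
#' binary truth events). Each record is tail-trimmed to the span covered by
#' the constant-stride windows (`(N - 1) * S + T` samples) so that
#' full-night fusion has complete coverage; that trimmed span is the
#' analyzed record length used for AHI.
#'
#' @param records List of [night_record()] objects.
#' @param T,S Window length and stride in samples.
#' @return List with `X` (N x T x 2), `y` (N x T), and `nights` (per-night
#'   list of `windows` + `truth_events`).
#' @export
cohort_windows <- function(records, T = 2048L, S = 300L) {
  Xs <- list(); ys <- list(); nights <- list()
  for (rec in records) {
    L <- nrow(rec$signal)
    if (L < T) stop("night ", rec$night_id, " shorter than one window")
    Lc <- ((L - T) %/% S) * S + T
    if (Lc < L) {
      rec$signal <- rec$signal[seq_len(Lc), , drop = FALSE]
      rec$labels <- rec$labels[seq_len(Lc)]
      rec$binary_labels <- rec$binary_labels[seq_len(Lc)]
    }
    ws <- window_night(rec, T = T, S = S)
    Xs[[length(Xs) + 1L]] <- ws$X
    ys[[length(ys) + 1L]] <- ws$y
    nights[[length(nights) + 1L]] <- list(
      windows = ws,
      truth_events = labels_to_events(rec$binary_labels),
      night_id = rec$night_id, severity = rec$severity)
  }
  Ns <- vapply(Xs, function(a) dim(a)[1L], integer(1))
  X <- array(0, dim = c(sum(Ns), T, 2L))
  y <- matrix(0L, sum(Ns), T)
  at <- 0L
  for (i in seq_along(Xs)) {
    X[at + seq_len(Ns[i]), , ] <- Xs[[i]]
    y[at + seq_len(Ns[i]), ] <- ys[[i]]
    at <- at + Ns[i]
  }
  list(X = X, y = y, nights = nights)
}

#' Evaluate a trained model on a list of night structures
#'
#' @param model A `segnet`.
#' @param nights Night structures from [cohort_windows()].
#' @param postproc_cfg A [postproc_config()].
#' @param fs Sampling rate.
#' @return An `eval_report` from [evaluate_cohort()].
#' @export
evaluate_model_on_nights <- function(model, nights,
                                     postproc_cfg = postproc_config(),
                                     fs = 10) {
  evals <- lapply(nights, function(nt) {
    probs <- segnet_predict(model, nt$windows$X)
    evaluate_night(probs, nt$windows$starts, nt$windows$L,
                   nt$truth_events, postproc_cfg, fs)
  })
  evaluate_cohort(evals)
}

#' Read a YAML configuration file into the matching config objects
#'
#' Recognized top-level sections: `sim`, `radar_sim`, `ridge`, `model`,
#' `train`, `loss`, `postproc`; each section's entries are passed to the
#' corresponding constructor.
#'
#' @param path YAML file path.
#' @return Named list of config objects (only the sections present).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  builders <- list(sim = sim_params, radar_sim = radar_sim_params,
                   ridge = ridge_config, model = model_config,
                   train = train_config, loss = loss_config,
                   postproc = postproc_config)
  out <- list()
  for (nm in names(raw)) {
    if (!nm %in% names(builders)) {
      stop("unknown config section: ", nm)
    }
    out[[nm]] <- do.call(builders[[nm]], raw[[nm]])
  }
  out
}
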