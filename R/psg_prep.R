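# Annotation parsing, event cleaning, label rasterization, robust
# normalization and sliding-window tensor construction.

# event-string dictionary: normalized string -> integer code 0..5
.event_dict <- c(
  normal = 0L,
  obstructiveapnea = 1L,
  centralapnea = 2L,
  mixedapnea = 3L,
  hypopnea = 4L,
  otherrespevent = 5L
)

normalize_event_string <- function(s) {
  s <- tolower(gsub("[^A-Za-z]", "", s))
  # strip either dialect prefix ("respiratoryevent" before "respevent")
  s <- sub("^respiratoryevent", "", s)
  s <- sub("^respevent", "", s)
  s
}

#' Parse a hospital-dialect annotation table
#'
#' Reads rows of `(epoch, time, duration, event)` (seconds), coerces numeric
#' fields, drops invalid rows (missing time, non-positive duration unless it
#' is a midnight wrap, unknown event string) and maps event strings to
#' integer codes 0-5 via an explicit dictionary. Both the
#' `"Respiratory Event ..."` and `"RespEvent..."` prefixes are accepted.
#'
#' A row whose recorded end time precedes its start (negative duration) is
#' retained as a midnight-wrap candidate when adding 24 h yields a plausible
#' event (duration in (0, 2 h]); the wrap itself is corrected by
#' [resolve_events()].
#'
#' @param x A CSV path or a data.frame with columns `epoch`, `time`,
#'   `duration`, `event`.
#' @return A data.frame with columns `epoch`, `time_s`, `duration_s`,
#'   `code`; attribute `n_dropped` counts removed rows.
#' @export
parse_annotations <- function(x) {
  df <- if (is.character(x)) read.csv(x, stringsAsFactors = FALSE) else x
  required <- c("epoch", "time", "duration", "event")
  if (!all(required %in% names(df))) {
    stop("annotation table must have columns: ",
         paste(required, collapse = ", "))
  }
  out <- data.frame(epoch = integer(0), time_s = numeric(0),
                    duration_s = numeric(0), code = integer(0))
  if (nrow(df) == 0L) {
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  time_s <- suppressWarnings(as.numeric(df$time))
  dur_s <- suppressWarnings(as.numeric(df$duration))
  code <- .event_dict[normalize_event_string(as.character(df$event))]
  wrap <- !is.na(dur_s) & dur_s <= 0 & (dur_s + 86400) > 0 &
    (dur_s + 86400) <= 7200
  valid <- !is.na(time_s) & !is.na(dur_s) & !is.na(code) & time_s >= 0 &
    (dur_s > 0 | wrap)
  n_dropped <- sum(!valid)
  if (n_dropped > 0L) {
    log_msg("parse_annotations: dropped %d invalid row(s)", n_dropped)
  }
  out <- data.frame(
    epoch = suppressWarnings(as.integer(df$epoch[valid])),
    time_s = time_s[valid],
    duration_s = dur_s[valid],
    code = unname(code[valid])
  )
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Clean parsed annotations into disjoint sample-index event intervals
#'
#' Applies, in order: (i) midnight-wrap correction (recorded end before
#' start gains 24 h); (ii) overlap resolution by priority (apnea subtypes,
#' codes 1-3, dominate hypopnea, code 4; otherwise the longer event is
#' retained); (iii) merging of same-code neighbors separated by <= 3 s.
#' Normal/other rows (codes 0, 5) do not define intervals of their own for
#' the segmentation task and are dropped here; code 5 is bookkeeping only.
#'
#' Seconds map to half-open, 0-based sample intervals via
#' `[floor(start * fs), ceiling(end * fs))`.
#'
#' @param rows Parsed annotation rows from [parse_annotations()].
#' @param fs Sampling rate of the label timeline in Hz.
#' @param merge_gap_s Adjacency merge gap in seconds (3 s).
#' @return A data.frame of class `event_intervals` with columns `start`,
#'   `end` (samples, half-open) and `code`, sorted and pairwise disjoint.
#' @export
resolve_events <- function(rows, fs, merge_gap_s = 3) {
  if (nrow(rows) == 0L) return(empty_events())
  rows <- rows[rows$code %in% 1:4, , drop = FALSE]
  if (nrow(rows) == 0L) return(empty_events())
  start_s <- rows$time_s
  end_s <- rows$time_s + rows$duration_s
  wrap <- end_s < start_s
  end_s[wrap] <- end_s[wrap] + 86400
  ev <- data.frame(
    start = sec_to_start(start_s, fs),
    end = sec_to_end(end_s, fs),
    code = rows$code
  )
  ev <- ev[ev$end > ev$start, , drop = FALSE]
  if (nrow(ev) == 0L) return(empty_events())
  ev <- ev[order(ev$start, ev$end), , drop = FALSE]

  # (ii) overlap resolution: apnea (1-3) beats hypopnea (4); ties keep the
  # longer event. The losing event is cropped out of the overlap region; a
  # fully covered loser is dropped.
  priority <- function(code) ifelse(code %in% 1:3, 2L, 1L)
  resolved <- ev[1L, , drop = FALSE]
  for (i in seq_len(nrow(ev))[-1L]) {
    cur <- ev[i, ]
    last <- resolved[nrow(resolved), ]
    if (cur$start < last$end) {  # overlap
      p_last <- priority(last$code); p_cur <- priority(cur$code)
      len_last <- last$end - last$start; len_cur <- cur$end - cur$start
      keep_last <- (p_last > p_cur) ||
        (p_last == p_cur && len_last >= len_cur)
      if (keep_last) {
        if (cur$end > last$end) {           # crop current to the remainder
          cur$start <- last$end
          resolved <- rbind(resolved, cur)
        }                                   # else fully covered: drop
      } else {
        last$end <- cur$start               # crop previous up to the winner
        if (last$end > last$start) {
          resolved[nrow(resolved), ] <- last
          resolved <- rbind(resolved, cur)
        } else {
          resolved[nrow(resolved), ] <- cur
        }
      }
    } else {
      resolved <- rbind(resolved, cur)
    }
  }

  # (iii) merge same-code neighbors with gap <= merge_gap_s
  gap_max <- merge_gap_s * fs
  merged <- resolved[1L, , drop = FALSE]
  for (i in seq_len(nrow(resolved))[-1L]) {
    cur <- resolved[i, ]
    last <- merged[nrow(merged), ]
    if (cur$code == last$code && (cur$start - last$end) <= gap_max) {
      merged$end[nrow(merged)] <- cur$end
    } else {
      merged <- rbind(merged, cur)
    }
  }
  rownames(merged) <- NULL
  merged$start <- as.integer(merged$start)
  merged$end <- as.integer(merged$end)
  merged$code <- as.integer(merged$code)
  class(merged) <- c("event_intervals", "data.frame")
  merged
}

empty_events <- function() {
  out <- data.frame(start = integer(0), end = integer(0), code = integer(0))
  class(out) <- c("event_intervals", "data.frame")
  out
}

#' Rasterize event intervals into a per-sample label sequence
#'
#' Sample `i` (0-based) receives the code of the covering event, else 0.
#' Portions of events extending outside `[0, L)` are clipped.
#'
#' @param events `event_intervals` (sample-index, half-open).
#' @param L Night length in samples.
#' @param fs Unused placeholder kept for call-site symmetry (intervals are
#'   already in samples).
#' @return Integer vector of length `L`.
#' @export
rasterize_labels <- function(events, L, fs = NULL) {
  labels <- integer(L)
  for (i in seq_len(nrow(events))) {
    a <- max(events$start[i], 0L)
    b <- min(events$end[i], L)
    if (b > a) labels[(a + 1L):b] <- events$code[i]
    if (events$end[i] > L) log_msg("rasterize_labels: event truncated at L")
  }
  labels
}

#' Extract half-open event intervals back out of a label sequence
#'
#' Inverse of [rasterize_labels()]: maximal runs of a constant nonzero code
#' become intervals.
#'
#' @param labels Integer label vector.
#' @return An `event_intervals` data.frame.
#' @export
labels_to_events <- function(labels) {
  r <- rle(as.integer(labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0L
  out <- data.frame(start = as.integer(starts[keep]),
                    end = as.integer(ends[keep]),
                    code = as.integer(r$values[keep]))
  class(out) <- c("event_intervals", "data.frame")
  out
}

#' Binarize integer event labels
#'
#' Codes 1-4 (apnea subtypes and hypopnea) are the positive class; Normal
#' (0) and other respiratory annotations (5) are negative.
#'
#' @param labels Integer vector with values in 0-5.
#' @return Integer 0/1 vector of the same length.
#' @export
binarize_labels <- function(labels) {
  if (any(!labels %in% 0:5)) stop("label codes must lie in 0..5")
  as.integer(labels %in% 1:4)
}

#' Robust per-night, per-channel normalization
#'
#' NaN/Inf are replaced with zeros before statistics; the channel is centered
#' by its median, clipped to median +/- 4*IQR, and scaled by the IQR. When
#' the IQR is degenerate the standard deviation is used instead; when both
#' are degenerate the output is all zeros. The degeneracy threshold is
#' `1e-6` of the channel's mean absolute deviation from the median.
#'
#' @param x Numeric channel (one night).
#' @return Normalized channel, median 0 and `|x| <= 4` when non-degenerate.
#' @export
robust_normalize <- function(x) {
  x[!is.finite(x)] <- 0
  med <- median(x)
  dev <- x - med
  tol <- 1e-6 * mean(abs(dev))
  iqr <- diff(quantile(x, c(0.25, 0.75), names = FALSE))
  scale <- if (iqr > tol) iqr else sd(x)
  if (!is.finite(scale) || scale <= tol) {
    log_msg("robust_normalize: degenerate channel, emitting zeros")
    return(numeric(length(x)))
  }
  clip(dev, -4 * scale, 4 * scale) / scale
}

#' Assemble a full-night record
#'
#' @param chest,abd Normalized 10 Hz channels (equal length).
#' @param labels Integer per-sample labels (codes 0-5), same length.
#' @param fs Sampling rate in Hz.
#' @param night_id Identifier.
#' @param severity Optional severity class 0-3 (from the reference AHI).
#' @return An object of class `night_record` with `signal` (L x 2 matrix),
#'   `labels`, `binary_labels`, `fs`, `night_id`, `severity`.
#' @export
night_record <- function(chest, abd, labels, fs = 10, night_id = NA_character_,
                         severity = NA_integer_) {
  stopifnot(length(chest) == length(abd), length(chest) == length(labels))
  structure(list(
    signal = cbind(chest = chest, abd = abd),
    labels = as.integer(labels),
    binary_labels = binarize_labels(labels),
    fs = fs, night_id = night_id, severity = severity
  ), class = "night_record")
}

#' Prepare a simulated night into a normalized record
#'
#' Applies [robust_normalize()] per channel and attaches the severity grade
#' implied by the true AHI.
#'
#' @param night A night from [simulate_night()] (at 10 Hz).
#' @return A [night_record()].
#' @export
prepare_night <- function(night) {
  night_record(
    chest = robust_normalize(night$chest),
    abd = robust_normalize(night$abd),
    labels = night$labels,
    fs = night$fs,
    night_id = night$night_id %||% NA_character_,
    severity = grade_severity(night$true_ahi %||% 0)
  )
}

#' Slice a night into overlapping model windows
#'
#' Windows of `T` samples with stride `S`; window `k` (0-based) covers
#' samples `[k*S, k*S + T)`. The label slice of each window equals the
#' corresponding slice of the full-night binary labels.
#'
#' @param night A [night_record()].
#' @param T Window length in samples (default 2048, i.e. 204.8 s at 10 Hz).
#' @param S Stride in samples (default 300, i.e. 30 s at 10 Hz).
#' @return A list of class `window_set`: `X` (N x T x 2 array), `y`
#'   (N x T matrix of 0/1), `starts` (0-based start samples), `L`,
#'   `night_id`.
#' @export
window_night <- function(night, T = 2048L, S = 300L) {
  L <- nrow(night$signal)
  if (L < T) {
    stop("night shorter than one window (", L, " < ", T,
         "); pad or shorten the window")
  }
  N <- (L - T) %/% S + 1L
  starts <- (seq_len(N) - 1L) * S
  X <- array(0, dim = c(N, T, 2L))
  y <- matrix(0L, N, T)
  for (k in seq_len(N)) {
    idx <- (starts[k] + 1L):(starts[k] + T)
    X[k, , ] <- night$signal[idx, ]
    y[k, ] <- night$binary_labels[idx]
  }
  structure(list(X = X, y = y, starts = starts, L = L,
                 night_id = night$night_id),
            class = "window_set")
}
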