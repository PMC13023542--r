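# Full-night probability fusion, probability-to-event conversion, interval
# matching, and event-/recording-level metrics.

#' Post-processing configuration
#'
#' @param tau Probability threshold in (0, 1); default 0.5.
#' @param g_min_s Maximum inter-event gap merged into one event (6 s).
#' @param d_min_s Minimum event duration retained (10 s, AASM convention).
#' @param iou_theta Interval-IoU threshold for one-to-one event matching
#'   (0.1).
#' @return An object of class `postproc_config`.
#' @export
postproc_config <- function(tau = 0.5, g_min_s = 6, d_min_s = 10,
                            iou_theta = 0.1) {
  stopifnot(tau > 0, tau < 1, g_min_s > 0, d_min_s > 0,
            iou_theta >= 0, iou_theta < 1)
  structure(list(tau = tau, g_min_s = g_min_s, d_min_s = d_min_s,
                 iou_theta = iou_theta), class = "postproc_config")
}

#' Fuse overlapping window probabilities into a full-night sequence
#'
#' Per-sample unbiased average over all windows covering the sample:
#' `p[t] = sum_k p_k[t - s_k] / #covering windows`.
#'
#' @param window_probs N x T matrix of per-window probabilities.
#' @param starts 0-based window start samples (length N).
#' @param L Night length in samples.
#' @return List of class `fused_probability` with `p_hat` (length L),
#'   `coverage` counts, `fs` unset (attach downstream).
#' @export
fuse_windows <- function(window_probs, starts, L) {
  if (is.null(dim(window_probs))) {
    window_probs <- matrix(window_probs, nrow = 1L)
  }
  N <- nrow(window_probs); T <- ncol(window_probs)
  stopifnot(length(starts) == N)
  acc <- numeric(L); cov <- integer(L)
  for (k in seq_len(N)) {
    idx <- (starts[k] + 1L):(starts[k] + T)
    if (starts[k] < 0L || starts[k] + T > L) {
      stop("window ", k, " extends outside [0, L)")
    }
    acc[idx] <- acc[idx] + window_probs[k, ]
    cov[idx] <- cov[idx] + 1L
  }
  if (any(cov == 0L)) {
    gaps <- runs_true(cov == 0L)
    stop("uncovered samples: ",
         paste(sprintf("[%d,%d)", gaps[, 1L], gaps[, 2L]), collapse = " "))
  }
  structure(list(p_hat = acc / cov, coverage = cov),
            class = "fused_probability")
}

#' Convert a fused probability sequence to event intervals
#'
#' Thresholds at `tau` (>=), takes maximal runs of positives, merges
#' consecutive events whose gap is <= `g_min_s`, then removes events
#' shorter than `d_min_s`. Output events are sorted, disjoint, and each at
#' least `d_min_s` long.
#'
#' @param p A `fused_probability` or plain numeric vector in `[0, 1]`.
#' @param cfg A [postproc_config()].
#' @param fs Sampling rate in Hz (default 10).
#' @return An `event_intervals` data.frame (code 1 for all events; the
#'   binary task does not assign subtypes).
#' @export
probability_to_events <- function(p, cfg = postproc_config(), fs = 10) {
  if (inherits(p, "fused_probability")) p <- p$p_hat
  runs <- runs_true(p >= cfg$tau)
  if (nrow(runs) == 0L) return(empty_events())
  # merge gaps <= g_min_s
  merged <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      gap <- runs[i, "start"] - merged[nrow(merged), "end"]
      if (gap / fs <= cfg$g_min_s) {
        merged[nrow(merged), "end"] <- runs[i, "end"]
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
  }
  keep <- (merged[, "end"] - merged[, "start"]) / fs >= cfg$d_min_s
  merged <- merged[keep, , drop = FALSE]
  out <- data.frame(start = as.integer(merged[, "start"]),
                    end = as.integer(merged[, "end"]),
                    code = rep(1L, nrow(merged)))
  class(out) <- c("event_intervals", "data.frame")
  out
}

#' Intersection-over-union of two half-open intervals
#'
#' @param a,b Two-element vectors `c(start, end)` with `end > start`
#'   (half-open `[start, end)`).
#' @return IoU in `[0, 1]`; 0 for disjoint intervals.
#' @export
interval_iou <- function(a, b) {
  if (a[2L] <= a[1L] || b[2L] <= b[1L]) stop("empty interval")
  inter <- max(0, min(a[2L], b[2L]) - max(a[1L], b[1L]))
  uni <- max(a[2L], b[2L]) - min(a[1L], b[1L])
  # union of two possibly disjoint intervals: total covered length
  uni <- (a[2L] - a[1L]) + (b[2L] - b[1L]) - inter
  inter / uni
}

#' One-to-one event matching by interval IoU
#'
#' Builds the bipartite graph of (prediction, truth) pairs with
#' `IoU > iou_theta` and computes a maximum-cardinality one-to-one matching
#' (augmenting-path search seeded greedily by descending IoU, deterministic
#' tie-break by earlier start). Unmatched predictions are false positives;
#' unmatched truths are false negatives.
#'
#' @param pred,truth `event_intervals` (sorted, disjoint).
#' @param iou_theta IoU threshold.
#' @return List with `tp`, `fp`, `fn` counts and a `pairs` data.frame
#'   (`pred`, `truth`, `iou`).
#' @export
match_events <- function(pred, truth, iou_theta = 0.1) {
  np <- nrow(pred); nt <- nrow(truth)
  if (np == 0L || nt == 0L) {
    return(list(tp = 0L, fp = np, fn = nt,
                pairs = data.frame(pred = integer(0), truth = integer(0),
                                   iou = numeric(0))))
  }
  # candidate edges above threshold
  edges <- list()
  for (i in seq_len(np)) {
    a <- c(pred$start[i], pred$end[i])
    for (j in seq_len(nt)) {
      if (truth$start[j] >= a[2L]) break
      if (truth$end[j] <= a[1L]) next
      iou <- interval_iou(a, c(truth$start[j], truth$end[j]))
      if (iou > iou_theta) edges[[length(edges) + 1L]] <- c(i, j, iou)
    }
  }
  if (length(edges) == 0L) {
    return(list(tp = 0L, fp = np, fn = nt,
                pairs = data.frame(pred = integer(0), truth = integer(0),
                                   iou = numeric(0))))
  }
  E <- do.call(rbind, edges)
  # neighbor lists per prediction, sorted by descending IoU then start
  nb <- split(seq_len(nrow(E)), E[, 1L])
  for (k in names(nb)) {
    o <- order(-E[nb[[k]], 3L], truth$start[E[nb[[k]], 2L]])
    nb[[k]] <- nb[[k]][o]
  }
  match_t <- rep(0L, nt)  # truth j -> pred i
  match_p <- rep(0L, np)
  try_augment <- function(i, visited) {
    for (e in nb[[as.character(i)]]) {
      j <- E[e, 2L]
      if (visited[j]) next
      visited[j] <- TRUE
      if (match_t[j] == 0L) {
        match_t[j] <<- i; match_p[i] <<- j
        return(TRUE)
      }
      res <- try_augment(match_t[j], visited)
      if (res) {
        match_t[j] <<- i; match_p[i] <<- j
        return(TRUE)
      }
    }
    FALSE
  }
  # process predictions by descending best IoU for deterministic pairing
  best_iou <- vapply(seq_len(np), function(i) {
    k <- as.character(i)
    if (is.null(nb[[k]])) -1 else E[nb[[k]][1L], 3L]
  }, numeric(1))
  for (i in order(-best_iou, pred$start)) {
    if (best_iou[i] < 0) next
    try_augment(i, visited = logical(nt))
  }
  matched <- which(match_p != 0L)
  pairs <- data.frame(pred = matched, truth = match_p[matched])
  pairs$iou <- vapply(seq_len(nrow(pairs)), function(r) {
    interval_iou(c(pred$start[pairs$pred[r]], pred$end[pairs$pred[r]]),
                 c(truth$start[pairs$truth[r]], truth$end[pairs$truth[r]]))
  }, numeric(1))
  tp <- nrow(pairs)
  list(tp = tp, fp = np - tp, fn = nt - tp, pairs = pairs)
}

#' Event-level precision, recall and F1 from counts
#'
#' `0/0` cases return 0 by convention.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return List with `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1)
}

#' Apnea-hypopnea index from an event count
#'
#' `AHI = N / (L / (3600 * fs))` events per hour, where `L` is the analyzed
#' record length in samples.
#'
#' @param n_events Number of events.
#' @param L Record length in samples.
#' @param fs Sampling rate in Hz.
#' @return AHI in events/hour.
#' @export
estimate_ahi <- function(n_events, L, fs = 10) {
  if (L <= 0) stop("L must be > 0")
  n_events / (L / (3600 * fs))
}

#' AHI error and agreement statistics across recordings
#'
#' @param pred_ahis,true_ahis Equal-length numeric vectors.
#' @return List with `mae`, `rmse`, `pearson`, `spearman`.
#' @export
ahi_errors <- function(pred_ahis, true_ahis) {
  if (length(pred_ahis) != length(true_ahis)) stop("length mismatch")
  d <- pred_ahis - true_ahis
  list(
    mae = mean(abs(d)),
    rmse = sqrt(mean(d^2)),
    pearson = suppressWarnings(cor(pred_ahis, true_ahis)),
    spearman = suppressWarnings(cor(pred_ahis, true_ahis,
                                    method = "spearman"))
  )
}

#' Severity grade from AHI
#'
#' AASM cutoffs, left-closed: Normal `[0, 5)`, Mild `[5, 15)`, Moderate
#' `[15, 30)`, Severe `[30, Inf)`.
#'
#' @param ahi Non-negative AHI (vectorized).
#' @return Integer class 0-3.
#' @export
grade_severity <- function(ahi) {
  if (any(ahi < 0)) stop("AHI must be >= 0")
  as.integer(cut(ahi, breaks = c(-Inf, 5, 15, 30, Inf), right = FALSE)) - 1L
}

#' Cohen's kappa from a confusion matrix
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = trace / total` and chance agreement
#' `p_e = sum_i row_i * col_i / total^2`. A degenerate table with
#' `p_e = 1` returns 1 when agreement is perfect and errors otherwise.
#'
#' @param confusion Square matrix of non-negative counts (rows = truth,
#'   columns = prediction).
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(confusion) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion),
            all(confusion >= 0))
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix")
  po <- sum(diag(confusion)) / total
  pe <- sum(rowSums(confusion) * colSums(confusion)) / total^2
  if (abs(1 - pe) < 1e-12) {
    if (abs(po - 1) < 1e-12) return(1)
    stop("degenerate confusion matrix: chance agreement is 1")
  }
  (po - pe) / (1 - pe)
}

#' Evaluate one night end-to-end from window probabilities
#'
#' Fuses windows, converts to events, matches against the truth, and
#' estimates the night's AHI.
#'
#' @param window_probs N x T matrix of per-window probabilities.
#' @param starts 0-based window starts.
#' @param L Night length in samples.
#' @param truth_events `event_intervals` ground truth.
#' @param cfg A [postproc_config()].
#' @param fs Sampling rate (Hz).
#' @return List with `tp`, `fp`, `fn`, `pred_events`, `ahi_pred`,
#'   `ahi_true`, `fused`.
#' @export
evaluate_night <- function(window_probs, starts, L, truth_events,
                           cfg = postproc_config(), fs = 10) {
  fused <- fuse_windows(window_probs, starts, L)
  pred_events <- probability_to_events(fused, cfg, fs)
  m <- match_events(pred_events, truth_events, cfg$iou_theta)
  list(tp = m$tp, fp = m$fp, fn = m$fn, pred_events = pred_events,
       ahi_pred = estimate_ahi(nrow(pred_events), L, fs),
       ahi_true = estimate_ahi(nrow(truth_events), L, fs),
       fused = fused)
}

#' Aggregate per-night evaluations into a cohort report
#'
#' Pools TP/FP/FN over nights for event-level metrics and computes
#' recording-level AHI errors, the 4x4 severity confusion matrix (rows =
#' truth), severity accuracy and Cohen's kappa.
#'
#' @param night_evals List of per-night records from [evaluate_night()].
#' @return List of class `eval_report`.
#' @export
evaluate_cohort <- function(night_evals) {
  tp <- sum(vapply(night_evals, `[[`, numeric(1), "tp"))
  fp <- sum(vapply(night_evals, `[[`, numeric(1), "fp"))
  fn <- sum(vapply(night_evals, `[[`, numeric(1), "fn"))
  prf <- precision_recall_f1(tp, fp, fn)
  ahi_pred <- vapply(night_evals, `[[`, numeric(1), "ahi_pred")
  ahi_true <- vapply(night_evals, `[[`, numeric(1), "ahi_true")
  errs <- ahi_errors(ahi_pred, ahi_true)
  sev_pred <- grade_severity(ahi_pred)
  sev_true <- grade_severity(ahi_true)
  confusion <- matrix(0L, 4L, 4L,
                      dimnames = list(truth = 0:3, pred = 0:3))
  for (i in seq_along(sev_pred)) {
    confusion[sev_true[i] + 1L, sev_pred[i] + 1L] <-
      confusion[sev_true[i] + 1L, sev_pred[i] + 1L] + 1L
  }
  kappa <- tryCatch(cohens_kappa(confusion), error = function(e) NA_real_)
  structure(list(
    tp = tp, fp = fp, fn = fn,
    precision = prf$precision, recall = prf$recall, f1 = prf$f1,
    ahi_mae = errs$mae, ahi_rmse = errs$rmse,
    pearson = errs$pearson, spearman = errs$spearman,
    severity_confusion = confusion,
    severity_accuracy = mean(sev_pred == sev_true),
    kappa = kappa,
    ahi_pred = ahi_pred, ahi_true = ahi_true
  ), class = "eval_report")
}

#' Sample-level ROC AUC of fused probabilities against binary labels
#'
#' Rank-based (Mann-Whitney) AUC; ties share ranks.
#'
#' @param p Probabilities.
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`; `NA` when one class is absent.
#' @export
sample_roc_auc <- function(p, labels) {
  stopifnot(length(p) == length(labels))
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(p)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bland-Altman agreement numbers for AHI
#'
#' @param pred,true Equal-length numeric vectors.
#' @return List with `bias` (mean of true - pred) and `loa` (95% limits of
#'   agreement).
#' @export
bland_altman <- function(pred, true) {
  d <- true - pred
  list(bias = mean(d), loa = mean(d) + c(-1.96, 1.96) * sd(d))
}
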