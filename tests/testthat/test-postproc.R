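# Probability fusion, event conversion, matching, and clinical metrics.

test_that("window fusion is the unbiased coverage-count mean", {
  # two overlapping windows averaging 0.3 and 0.7 -> 0.5 in the overlap
  probs <- rbind(rep(0.3, 100), rep(0.7, 100))
  f <- fuse_windows(probs, starts = c(0L, 50L), L = 150L)
  expect_equal(f$p_hat[51:100], rep(0.5, 50))
  expect_equal(f$p_hat[1:50], rep(0.3, 50))
  expect_equal(f$coverage[51:100], rep(2L, 50))

  # single window passes through
  f1 <- fuse_windows(matrix(runif(80), 1), 0L, 80L)
  expect_equal(f1$p_hat, as.numeric(f1$p_hat))
  expect_true(all(f1$coverage == 1L))

  # random layout equals a brute-force per-sample oracle
  withr::with_seed(41, {
    T <- 64L; L <- 500L
    starts <- sort(sample(0:(L - T), 12))
    starts[1L] <- 0L; starts[12L] <- L - T
    probs <- matrix(runif(12 * T), 12, T)
  })
  if (max(diff(c(starts, L - T))) <= T) {
    f2 <- fuse_windows(probs, starts, L)
    acc <- numeric(L); cov <- numeric(L)
    for (k in 1:12) {
      idx <- (starts[k] + 1L):(starts[k] + T)
      acc[idx] <- acc[idx] + probs[k, ]; cov[idx] <- cov[idx] + 1
    }
    expect_lt(max(abs(f2$p_hat - acc / cov)), 1e-12)
  }

  expect_error(fuse_windows(matrix(0.5, 1, 10), 0L, 100L), "uncovered")
})

test_that("probability-to-event conversion merges small gaps and drops short events", {
  cfg <- postproc_config()
  # runs [0,500) and [530,1000) samples at 10 Hz: 3 s gap <= 6 s -> one event
  p <- numeric(1100)
  p[1:500] <- 1; p[531:1000] <- 1
  ev <- probability_to_events(p, cfg, fs = 10)
  expect_equal(nrow(ev), 1L)
  expect_equal(c(ev$start, ev$end), c(0L, 1000L))

  # a lone 9 s run (< 10 s minimum) is discarded
  p2 <- numeric(500); p2[101:190] <- 1
  expect_equal(nrow(probability_to_events(p2, cfg, fs = 10)), 0L)
  # a 10 s run survives
  p3 <- numeric(500); p3[101:200] <- 1
  expect_equal(nrow(probability_to_events(p3, cfg, fs = 10)), 1L)

  # constant 1 -> a single full-night event
  ev4 <- probability_to_events(rep(1, 3000), cfg, fs = 10)
  expect_equal(nrow(ev4), 1L)
  expect_equal(c(ev4$start, ev4$end), c(0L, 3000L))

  # threshold is inclusive (>= tau)
  expect_equal(nrow(probability_to_events(rep(0.5, 200), cfg, fs = 10)), 1L)
})

test_that("event conversion is idempotent and monotone in the threshold", {
  withr::with_seed(13, {
    for (rep in 1:20) {
      p <- stats::filter(runif(4000), rep(1 / 31, 31), circular = TRUE)
      p <- as.numeric((p - min(p)) / diff(range(p)))
      cfg <- postproc_config()
      ev <- probability_to_events(p, cfg, fs = 10)
      # rasterize the events back to a 0/1 signal and re-convert
      lab <- rasterize_labels(ev, length(p))
      ev2 <- probability_to_events(as.numeric(lab > 0), cfg, fs = 10)
      expect_equal(ev2$start, ev$start)
      expect_equal(ev2$end, ev$end)
      # raising tau never increases the total thresholded duration
      durs <- vapply(c(0.2, 0.4, 0.6, 0.8),
                     function(tau) sum(p >= tau), numeric(1))
      expect_true(all(diff(durs) <= 0))
    }
  })
})

test_that("interval IoU matches hand computations", {
  expect_equal(interval_iou(c(0, 100), c(50, 150)), 1 / 3)
  expect_equal(interval_iou(c(10, 20), c(10, 20)), 1)
  expect_equal(interval_iou(c(0, 10), c(20, 30)), 0)
  expect_error(interval_iou(c(5, 5), c(0, 10)), "empty")
})

test_that("event matching is one-to-one and equals the exhaustive oracle", {
  mk <- function(s, e) {
    out <- data.frame(start = as.integer(s), end = as.integer(e),
                      code = rep(1L, length(s)))
    class(out) <- c("event_intervals", "data.frame")
    out
  }
  # identical lists: all matched
  ev <- mk(c(0, 200, 400), c(100, 300, 500))
  m <- match_events(ev, ev, 0.1)
  expect_equal(c(m$tp, m$fp, m$fn), c(3L, 0L, 0L))

  # one prediction spanning two truths matches exactly one (no double count)
  pred <- mk(0, 300)
  truth <- mk(c(0, 200), c(150, 300))
  m2 <- match_events(pred, truth, 0.1)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(1L, 0L, 1L))

  # randomized equivalence with the brute-force optimal matcher
  withr::with_seed(59, {
    for (rep in 1:40) {
      pred <- random_disjoint_events(sample(0:8, 1), 3000)
      truth <- random_disjoint_events(sample(0:8, 1), 3000)
      got <- match_events(pred, truth, 0.1)$tp
      want <- brute_force_match(pred, truth, 0.1)
      expect_equal(got, want)
    }
  })
})

test_that("precision/recall/F1 and their conventions", {
  m <- precision_recall_f1(2, 1, 1)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)
  expect_equal(unlist(precision_recall_f1(5, 0, 0)),
               c(precision = 1, recall = 1, f1 = 1))
  expect_equal(unlist(precision_recall_f1(0, 0, 0)),
               c(precision = 0, recall = 0, f1 = 0))
})

test_that("AHI arithmetic and error statistics", {
  expect_equal(estimate_ahi(8, 288000, 10), 1.0)
  expect_equal(estimate_ahi(0, 1000, 10), 0)
  expect_equal(estimate_ahi(21, 3 * 3600 * 10, 10), 7.0)
  expect_error(estimate_ahi(3, 0, 10), "L must")

  a <- c(3, 7, 12, 30)
  expect_equal(ahi_errors(a, a)[c("mae", "rmse")], list(mae = 0, rmse = 0))
  expect_equal(ahi_errors(a, a)$pearson, 1)
  shifted <- ahi_errors(a + 2, a)
  expect_equal(shifted$mae, 2)
  expect_equal(shifted$rmse, 2)

  withr::with_seed(71, {
    p <- runif(10, 0, 40); t <- runif(10, 0, 40)
  })
  e <- ahi_errors(p, t)
  expect_lt(abs(e$mae - mean(abs(p - t))), 1e-10)
  expect_lt(abs(e$rmse - sqrt(mean((p - t)^2))), 1e-10)
  expect_lt(abs(e$spearman - cor(rank(p), rank(t))), 1e-10)
  expect_error(ahi_errors(1:3, 1:4), "length")
})

test_that("severity grading uses left-closed AASM cutoffs", {
  expect_equal(grade_severity(c(0, 4.9, 5, 14.9, 15, 29.9, 30, 80)),
               c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L))
  expect_error(grade_severity(-1), ">= 0")
})

test_that("Cohen's kappa matches hand evaluation and chance behavior", {
  expect_equal(cohens_kappa(diag(c(5, 3, 2, 1))), 1)
  tab <- matrix(c(25, 10, 5, 60), 2, 2)  # rows truth: [[25,5],[10,60]]
  expect_equal(cohens_kappa(tab), 0.29 / 0.44, tolerance = 1e-12)
  # independence: kappa concentrates near 0
  withr::with_seed(83, {
    ks <- replicate(200, {
      a <- sample(1:4, 400, replace = TRUE)
      b <- sample(1:4, 400, replace = TRUE)
      cohens_kappa(as.matrix(table(factor(a, 1:4), factor(b, 1:4))))
    })
  })
  expect_lt(abs(mean(ks)), 0.02)
  expect_error(cohens_kappa(matrix(0, 2, 2)), "empty")
  one_cell <- matrix(c(10, 0, 0, 0), 2, 2)
  expect_equal(cohens_kappa(one_cell), 1)
})

test_that("night evaluation composes fusion, conversion and matching", {
  withr::with_seed(97, {
    L <- 6000L; fs <- 10
    truth <- random_disjoint_events(5, 4000L, min_len = 120L,
                                    max_len = 300L)
  })
  # spread truths out to respect the post-processing gap
  truth$start <- truth$start + seq(0L, by = 150L,
                                   length.out = nrow(truth))
  truth$end <- truth$end + seq(0L, by = 150L, length.out = nrow(truth))
  lab <- rasterize_labels(truth, L)
  # windows that tile the night with overlap, probabilities = truth
  T <- 1000L; S <- 500L
  starts <- seq(0L, L - T, by = S)
  probs <- t(vapply(starts, function(s) as.numeric(lab[(s + 1):(s + T)] > 0),
                    numeric(T)))
  r <- evaluate_night(probs, starts, L, truth)
  expect_equal(r$tp, nrow(truth))
  expect_equal(r$fp, 0L)
  expect_equal(r$fn, 0L)
  expect_equal(r$ahi_pred, r$ahi_true)

  # all-zero probabilities: nothing predicted
  r0 <- evaluate_night(matrix(0, length(starts), T), starts, L, truth)
  expect_equal(r0$fp, 0L)
  expect_equal(r0$fn, nrow(truth))
  expect_equal(r0$ahi_pred, 0)

  # composition equals running the stages by hand
  fused <- fuse_windows(probs, starts, L)
  ev <- probability_to_events(fused, postproc_config(), 10)
  m <- match_events(ev, truth, 0.1)
  expect_equal(r$tp, m$tp)
  expect_equal(nrow(r$pred_events), nrow(ev))
})

test_that("sample ROC AUC and Bland-Altman numbers behave", {
  lab <- c(rep(0, 50), rep(1, 50))
  expect_equal(sample_roc_auc(c(runif(50, 0, 0.4), runif(50, 0.6, 1)), lab), 1)
  withr::with_seed(7, auc <- sample_roc_auc(runif(2000), rbinom(2000, 1, 0.3)))
  expect_lt(abs(auc - 0.5), 0.05)
  ba <- bland_altman(c(1, 2, 3), c(2, 3, 4))
  expect_equal(ba$bias, 1)
})
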