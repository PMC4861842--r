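# Accelerometer synthesis, windowed variance/band-power features, HMM
# decoding, event post-processing and evaluation.

test_that("signal synthesis honours the schedule contract", {
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      activity = character(0))
  sig <- synthesize_accel(empty, seed = 1, duration_s = 60)
  expect_equal(nrow(sig$samples), 60 * 12)
  expect_equal(ncol(sig$samples), 3)

  sig2 <- synthesize_accel(empty, seed = 1, duration_s = 60)
  expect_identical(sig$samples, sig2$samples)   # byte-identical under seed

  overlap <- data.frame(start_s = c(0, 50), end_s = c(60, 120),
                        activity = c("feeding", "rumination"))
  expect_error(synthesize_accel(overlap, seed = 1), "overlap")
  bad <- data.frame(start_s = 0, end_s = 60, activity = "sleeping")
  expect_error(synthesize_accel(bad, seed = 1), "activity")
})

test_that("pure rumination at high SNR puts the dominant DFT peak in the chew band", {
  cfg <- accel_config(snr = 3)
  sch <- data.frame(start_s = 0, end_s = 300, activity = "rumination")
  sig <- synthesize_accel(sch, cfg, seed = 2)
  res <- sqrt(rowSums(sig$samples^2))
  n <- length(res)
  p <- Mod(stats::fft(res - mean(res)))^2
  freqs <- (seq_len(n) - 1) * cfg$fs / n
  half <- 2:(floor(n / 2))
  peak <- freqs[half][which.max(p[half])]
  expect_gt(peak, 0.5)
  expect_lte(peak, 2)
  expect_equal(peak, cfg$chew_freq, tolerance = 0.05)
})

test_that("window features: constant signal gives zero variance and band power", {
  m <- matrix(1, nrow = 12 * 60, ncol = 3)
  fe <- window_features(signal_from_matrix(m), 30)
  expect_equal(fe$variance, rep(0, 2))
  expect_equal(fe$chew, rep(0, 2))
  expect_equal(fe$broad, rep(0, 2))
})

test_that("a unit 1 Hz sinusoid has variance ~0.5 concentrated in the chew band", {
  t <- (0:(12 * 30 - 1)) / 12
  m <- cbind(0, 0, 10 + sin(2 * pi * 1 * t))   # offset keeps resultant linear
  fe <- window_features(signal_from_matrix(m), 30)
  expect_equal(fe$variance, 0.5, tolerance = 0.01)
  total_nondc <- fe$chew + fe$broad +
    window_features(signal_from_matrix(m), 30,
                    bands = list(low = c(0, 0.5)))$low
  expect_gt(fe$chew / total_nondc, 0.999)
  expect_error(window_features(signal_from_matrix(m), 120), "longer")
})

test_that("Parseval: band powers over a full partition sum to the window variance", {
  withr::with_seed(5, m <- matrix(rnorm(12 * 300 * 3), ncol = 3))
  fe <- window_features(signal_from_matrix(m), 30,
                        bands = list(b1 = c(0, 2), b2 = c(2, 4),
                                     b3 = c(4, 6)))
  N <- 12 * 30
  pop_var <- fe$variance * (N - 1) / N
  expect_equal(fe$b1 + fe$b2 + fe$b3, pop_var, tolerance = 1e-10)
})

test_that("white-noise band powers are proportional to bandwidth", {
  withr::with_seed(6, m <- cbind(0, 0, 10 + rnorm(12 * 30 * 300)))
  fe <- window_features(signal_from_matrix(m), 30)
  # chew (0.5,2] holds 45 of the 180 non-DC bins, broad (2,6] holds 120
  ratio <- mean(fe$chew) / mean(fe$broad)
  expect_equal(ratio, 45 / 120, tolerance = 0.02)
})

test_that("two well-separated regimes are decoded with >= 99% accuracy", {
  withr::with_seed(9, {
    truth <- rep(rep(c(TRUE, FALSE), 10), times = rep(c(20, 25), 10))[1:400]
    fe <- data.frame(
      window_start = (seq_along(truth) - 1) * 30,
      variance = exp(rnorm(400, ifelse(truth, 0, -2), 0.3)),
      chew = exp(rnorm(400, ifelse(truth, 0, -4), 0.3)),
      broad = exp(rnorm(400, ifelse(truth, -3, -1.5), 0.3)))
  })
  attr(fe, "bands") <- list(chew = c(0.5, 2), broad = c(2, 6))
  hmm <- decode_states(fe, n_states = 2, seed = 10)
  expect_gte(mean(hmm$is_rumination == truth), 0.99)

  # label-permutation invariance across restarts: the chew/broad ratio rule
  # gives the same final labelling whatever the initialisation
  hmm2 <- decode_states(fe, n_states = 2, seed = 4711)
  expect_gte(mean(hmm$is_rumination == hmm2$is_rumination), 0.99)
})

test_that("degenerate single-state input collapses onto one state", {
  fe <- data.frame(window_start = (0:199) * 30, variance = 1,
                   chew = 0.5, broad = 0.5)
  attr(fe, "bands") <- list(chew = c(0.5, 2), broad = c(2, 6))
  hmm <- suppressWarnings(decode_states(fe, n_states = 2, seed = 12))
  expect_gte(max(table(hmm$states)) / 200, 0.99)
})

test_that("state paths become events per the run-length rules", {
  ev <- states_to_events(rep(TRUE, 40), window_s = 60)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_min, 40)
  expect_equal(ev$start_s, 0)
  expect_equal(ev$end_s, 2400)

  # two runs separated by one 30-s gap merge when merge_gap_s > 30
  path <- c(rep(TRUE, 10), FALSE, rep(TRUE, 10))
  merged <- states_to_events(path, 30, merge_gap_s = 60, min_event_s = 0)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$duration_min, 10.5)
  split <- states_to_events(path, 30, merge_gap_s = 15, min_event_s = 0)
  expect_equal(nrow(split), 2)

  # short events are dropped after merging
  short <- states_to_events(c(TRUE, rep(FALSE, 20)), 30, merge_gap_s = 0,
                            min_event_s = 120)
  expect_equal(nrow(short), 0)
})

test_that("events match a brute-force run-length oracle on random paths", {
  withr::with_seed(13, {
    for (rep_i in 1:5) {
      path <- runif(200) < 0.4
      ev <- states_to_events(path, 30, merge_gap_s = 0, min_event_s = 0)
      r <- rle(path)                       # independent encoder
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      oracle <- data.frame(start_s = (starts[r$values] - 1) * 30,
                           end_s = ends[r$values] * 30)
      expect_equal(ev$start_s, oracle$start_s)
      expect_equal(ev$end_s, oracle$end_s)
    }
  })
})

test_that("event evaluation counts windows the way the definitions say", {
  tru <- data.frame(start_s = c(0, 150), end_s = c(90, 180))
  expect_equal(evaluate_events(tru, tru, 30, span = c(0, 300))$sensitivity,
               100)
  expect_equal(evaluate_events(tru, tru, 30, span = c(0, 300))$ppv, 100)

  none <- data.frame(start_s = numeric(0), end_s = numeric(0))
  expect_equal(evaluate_events(none, tru, 30, span = c(0, 300))$sensitivity,
               0)
  expect_true(is.na(evaluate_events(tru, none, 30,
                                    span = c(0, 300))$sensitivity))

  # hand-built 10-window case: truth covers windows 1-3 and 6; prediction
  # covers windows 1-3 and 8 -> TP 3, FN 1, FP 1
  truth <- data.frame(start_s = c(0, 150), end_s = c(90, 180))
  pred <- data.frame(start_s = c(0, 210), end_s = c(90, 240))
  rep_ <- evaluate_events(pred, truth, 30, span = c(0, 300))
  expect_equal(rep_$tp, 3); expect_equal(rep_$fp, 1); expect_equal(rep_$fn, 1)
  expect_equal(rep_$sensitivity, 75)
  expect_equal(rep_$ppv, 75)
})

test_that("lower SNR never improves expected sensitivity (ladder, paired seeds)", {
  sens_at <- function(snr) {
    cfg <- accel_config(snr = snr)
    mean(vapply(1:3, function(s) {
      sch <- data.frame(
        start_s = c(0, 4000, 9000), end_s = c(3000, 6000, 12000),
        activity = c("rumination", "feeding", "rumination"))
      sig <- synthesize_accel(sch, cfg, seed = 100 + s, duration_s = 14400)
      fe <- window_features(sig, cfg$window_s, cfg$bands)
      hmm <- suppressWarnings(decode_states(fe, 3, seed = 200 + s))
      ev <- states_to_events(hmm, cfg$window_s)
      evaluate_events(ev, sch[sch$activity == "rumination",
                              c("start_s", "end_s")],
                      cfg$window_s, span = c(0, 14400))$sensitivity
    }, numeric(1)))
  }
  ladder <- vapply(c(1, 0.3, 0.08), sens_at, numeric(1))
  expect_gte(ladder[1], ladder[2] - 5)
  expect_gte(ladder[2], ladder[3] - 5)
  expect_gt(ladder[1], 95)
})

test_that("end-to-end daily rumination time is recovered within 5%", {
  cfg <- barn_config(seed = 31, n_nonlame = 1, n_lame = 1, n_days = 1)
  barn <- simulate_barn(cfg)
  cid <- barn$rumination$cow_id[1]
  tru <- barn$rumination[barn$rumination$cow_id == cid, ]
  vis <- barn$visits[barn$visits$cow_id == cid & barn$visits$duration_s > 0, ]
  sch <- rbind(data.frame(start_s = tru$start_s, end_s = tru$end_s,
                          activity = "rumination"),
               data.frame(start_s = vis$start_s,
                          end_s = vis$start_s + vis$duration_s,
                          activity = "feeding"))
  ac <- accel_config()
  sig <- synthesize_accel(sch, ac, seed = 32, duration_s = 86400)
  hmm <- decode_states(window_features(sig, ac$window_s, ac$bands), 3,
                       seed = 33)
  pred <- states_to_events(hmm, ac$window_s)
  expect_lt(abs(sum(pred$duration_min) - sum(tru$duration_min)) /
              sum(tru$duration_min), 0.05)
})

test_that("signals round-trip through the text + sidecar format", {
  sig <- synthesize_accel(data.frame(start_s = 0, end_s = 10,
                                     activity = "other"),
                          seed = 14, duration_s = 10, cow_id = 9)
  prefix <- file.path(withr::local_tempdir(), "sig")
  write_signal(sig, prefix)
  back <- read_signal(prefix)
  expect_equal(back$samples, sig$samples, tolerance = 1e-12)
  expect_equal(back$cow_id, 9)
  expect_equal(back$fs, 12)
})
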