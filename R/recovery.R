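# Seeded parameter-recovery suites: simulate a calibrated barn, run the
# estimation pipeline, return per-seed estimates. Used by the test suite
# and by scripts/acceptance.R, so both measure the same computation.

#' Visit-level slope-model recovery suite
#'
#' For each seed: generate a 16-cow x 22-day visit stream under the
#' locomotion-rate truth world ([m3_truth_config()]), fit the no-intercept
#' random-slope model of visit intake (g) on visit duration (min) with
#' duration-by-locomotion and duration-by-milk interactions by ML, and
#' return the three slope coefficients.
#'
#' @param seeds integer vector of generator seeds.
#' @param config a [m3_truth_config()] (per-seed seed is overridden).
#' @return data.frame `seed`, `a` (baseline g/min), `b` (g/min per
#'   locomotion unit), `c` (g/min per l milk).
#' @export
m3_recovery <- function(seeds, config = m3_truth_config()) {
  out <- lapply(seeds, function(s) {
    cfg <- config; cfg$seed <- as.integer(s)
    co <- make_cohort(cfg)
    v <- simulate_visits(co, cfg$n_days, cfg, place_starts = FALSE)
    v$dur_min <- v$duration_s / 60
    v$fmi_g <- 1000 * v$fmi_kg
    v$loco <- co$mean_locomotion[match(v$cow_id, co$cow_id)]
    v$milk <- co$milk_level[match(v$cow_id, co$cow_id)]
    f <- fit_lmm(fmi_g ~ 0 + dur_min + dur_min:loco + dur_min:milk, v,
                 group = "cow_id", random = ~ 0 + dur_min, method = "ML")
    data.frame(seed = s, a = unname(stats::coef(f)["dur_min"]),
               b = unname(stats::coef(f)["dur_min:loco"]),
               c = unname(stats::coef(f)["dur_min:milk"]))
  })
  do.call(rbind, out)
}

#' Daily-model recovery suite
#'
#' For each seed: simulate the group-mean barn ([barn_config()]), derive
#' daily characteristics, fit the daily lameness model (response ~ lame +
#' DIM + random cow intercept, REML) for feeding frequency, feeding rate
#' and rumination time and extract the lame-group least-square means; fit
#' the rumination-association model (rumination ~ milk + lameness +
#' feeding rate) and extract the feeding-rate coefficient; and test
#' lameness on rumination time by ML likelihood ratio against the
#' intercept + cow null.
#'
#' @param seeds integer vector of generator seeds.
#' @param config a [barn_config()] (per-seed seed is overridden).
#' @return data.frame `seed`, `lsm_ffreq`, `lsm_frate`, `lsm_rumtime`
#'   (lame-group LSMs), `m2_dfr` (min/day per g/min), `p_rum_lame` (LRT
#'   p-value for lameness on rumination time).
#' @export
m1_recovery <- function(seeds, config = barn_config()) {
  out <- lapply(seeds, function(s) {
    barn <- simulate_barn(config, seed = as.integer(s))
    d <- daily_summaries(barn$visits, barn$rumination, barn$milk,
                         barn$cohort)
    ls_of <- function(resp) {
      fit <- fit_lmm(stats::as.formula(paste(resp, "~ lame + dim")), d,
                     group = "cow_id")
      lsm(fit, "lame")$lsm[2]
    }
    m2 <- fit_lmm(dRUMtime ~ dMY + lame + dFR, d, group = "cow_id")
    p <- lrt(fit_lmm(dRUMtime ~ lame + dim, d, "cow_id", method = "ML"),
             fit_lmm(dRUMtime ~ 1, d, "cow_id", method = "ML"))$p_value
    data.frame(seed = s, lsm_ffreq = ls_of("dFfreq"),
               lsm_frate = ls_of("dFR"), lsm_rumtime = ls_of("dRUMtime"),
               m2_dfr = unname(stats::coef(m2)["dFR"]), p_rum_lame = p)
  })
  do.call(rbind, out)
}

#' Rumination-classifier recovery suite
#'
#' For each seed: simulate a small barn, synthesize `n_cow_days` full days
#' of 12 Hz accelerometer signal from the known activity schedule at the
#' configured SNR, classify rumination (windowed variance + band-power
#' features, Gaussian HMM, Viterbi, event post-processing) and score the
#' window-level sensitivity and positive predictive value against the
#' schedule.
#'
#' @param seeds integer vector of seeds.
#' @param n_cow_days cow-days of signal per seed.
#' @param accel an [accel_config()].
#' @return data.frame `seed`, `sensitivity`, `ppv` (percent).
#' @export
classifier_recovery <- function(seeds, n_cow_days = 4,
                                accel = accel_config()) {
  out <- lapply(seeds, function(s) {
    cfg <- barn_config(seed = as.integer(s), n_nonlame = 1, n_lame = 1,
                       n_days = max(1L, ceiling(n_cow_days / 2)))
    barn <- simulate_barn(cfg)
    rep_ <- classify_sample(barn, n_cow_days, accel, seed = as.integer(s))
    data.frame(seed = s, sensitivity = rep_$sensitivity, ppv = rep_$ppv)
  })
  do.call(rbind, out)
}

#' Type-I-error simulation for the lameness likelihood-ratio test
#'
#' Simulates daily records under the null (no lameness effect: cow random
#' intercept + day noise only), tests lameness by ML likelihood ratio, and
#' returns the per-replicate p-values. The rejection rate at alpha = 0.05
#' should sit within binomial noise of 0.05.
#'
#' @param n_reps number of replicates.
#' @param seed RNG seed.
#' @param n_nonlame,n_lame,n_days cohort layout per replicate.
#' @param sd_cow,sd_day variance components of the null world.
#' @return numeric vector of p-values, length `n_reps`.
#' @export
lrt_null_simulation <- function(n_reps = 500, seed = 1, n_nonlame = 7,
                                n_lame = 9, n_days = 22, sd_cow = 46,
                                sd_day = 25) {
  n_cows <- n_nonlame + n_lame
  with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      d <- expand.grid(day = seq_len(n_days), cow_id = seq_len(n_cows))
      d$lame <- d$cow_id > n_nonlame
      d$y <- 480 + stats::rnorm(n_cows, 0, sd_cow)[d$cow_id] +
        stats::rnorm(nrow(d), 0, sd_day)
      lrt(fit_lmm(y ~ lame, d, "cow_id", method = "ML"),
          fit_lmm(y ~ 1, d, "cow_id", method = "ML"))$p_value
    }, numeric(1))
  })
}
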