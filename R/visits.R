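#' Parlor concentrate allowance
#'
#' Cows receive 0.6 kg/day of concentrate in the milking parlor, plus an
#' extra 1 kg/day per 3 l of daily milk yield above 30 l/day.
#'
#' @param milk_yield daily milk yield, l/day (vectorized, non-negative).
#' @return concentrate allowance, kg/day.
#' @export
#' @examples
#' parlor_concentrate(36)  # 2.6
parlor_concentrate <- function(milk_yield) {
  if (any(!is.finite(milk_yield)) || any(milk_yield < 0))
    stop("milk_yield must be non-negative and finite")
  0.6 + pmax(0, (milk_yield - 30) / 3)
}

#' Simulate feed-station visits
#'
#' Generates the visit stream of a cohort over `n_days` study days. Each
#' cow-day has a feeding-time budget (its trait-level feeding time, a
#' days-in-milk trend of `dim_trend_ftime` min/day centred at the cohort
#' mean DIM, and multiplicative day noise); a Poisson number of visits
#' divides that budget into gamma-proportioned durations, and intake per
#' visit is duration x the cow's day-level feeding rate x multiplicative
#' visit noise. Intake is capped at `cap_kg` per visit by ending the visit
#' early (duration shrinks with the intake) unless the cow overrides the
#' door with probability `cap_override_p`. Visit start times avoid the
#' cow's three 40-min milking absences and the daily 30-min station reset
#' window; feed eaten during the reset window is accumulated per station as
#' unassigned mass (attribute `unassigned`), never booked to a cow.
#'
#' @param cohort a [make_cohort()] data.frame.
#' @param n_days number of study days (default from `config`).
#' @param config a [barn_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return data.frame with columns `cow_id`, `station_id`, `day`, `start_s`,
#'   `duration_s`, `fmi_kg`, `capped`, `override`; attributes `unassigned`
#'   (kg per station-day) and `total_disappearance_kg` (assigned +
#'   unassigned mass, for mass-balance checks).
#' @export
#' @param place_starts place visit start times on the day timeline (avoiding
#'   milking absences and the reset window)? Setting `FALSE` skips the
#'   placement (start times become `NA`) for analyses that only use
#'   durations and intakes; the duration/intake stream is unchanged except
#'   for the rare visit that placement would have truncated.
simulate_visits <- function(cohort, n_days = NULL, config = barn_config(),
                            seed = NULL, place_starts = TRUE) {
  stopifnot(inherits(config, "herd_config"))
  if (is.null(n_days)) n_days <- config$n_days
  if (n_days < 1) stop("n_days must be >= 1")
  if (is.null(seed)) seed <- config$seed
  day_s <- 86400
  with_seed(seed, {
    rows <- vector("list", nrow(cohort) * n_days)
    r <- 0L
    # trends are centred at the study-period grand-mean DIM so the
    # configured group means are the expected values at that grand mean
    # (which is what a least-square mean estimates)
    dim_centre <- config$dim_mean + (n_days - 1) / 2
    for (ci in seq_len(nrow(cohort))) {
      cow <- cohort[ci, ]
      for (day in seq_len(n_days)) {
        dimc <- cow$dim_start + day - 1 - dim_centre
        t_day <- cow$true_feeding_time * rnoise1(1, config$ftime_day_cv) +
          config$dim_trend_ftime * dimc
        t_day <- max(5, t_day)
        freq <- cow$true_visits_per_day +
          if (cow$lame) config$dim_trend_freq_lame * dimc else 0
        n <- max(1L, stats::rpois(1, max(2, freq)))
        rate_day <- cow$true_feeding_rate * rnoise1(1, config$rate_day_cv)
        w <- stats::rgamma(n, shape = config$visit_dur_shape)
        dur <- t_day * 60 * w / sum(w)                       # seconds
        fmi <- dur / 60 * rate_day * rnoise1(n, config$visit_noise_cv) / 1000
        over_cap <- fmi > config$cap_kg
        override <- over_cap & stats::runif(n) < config$cap_override_p
        cap_it <- over_cap & !override
        if (any(cap_it)) {
          scl <- config$cap_kg / fmi[cap_it]
          dur[cap_it] <- dur[cap_it] * scl
          fmi[cap_it] <- config$cap_kg
        }
        if (place_starts) {
          # absences: one 40-min block inside each milking window, plus reset
          mw <- config$milking_windows
          abs_start <- mw[, 1] + stats::runif(nrow(mw)) *
            (mw[, 2] - mw[, 1] - config$milking_absence_s)
          blocked <- rbind(cbind(abs_start, abs_start + config$milking_absence_s),
                           matrix(config$reset_window, ncol = 2))
          starts <- place_intervals(dur, free_intervals(blocked, day_s))
          dur2 <- attr(starts, "duration")
          shrunk <- which(dur2 < dur - 1e-9)
          if (length(shrunk))                                 # keep rate relation
            fmi[shrunk] <- fmi[shrunk] * dur2[shrunk] / pmax(dur[shrunk], 1e-9)
        } else {
          starts <- rep(NA_real_, n)
          dur2 <- dur
        }
        r <- r + 1L
        rows[[r]] <- data.frame(
          cow_id = cow$cow_id,
          station_id = sample.int(config$n_stations, n, replace = TRUE),
          day = day, start_s = as.numeric(starts), duration_s = dur2,
          fmi_kg = fmi, capped = cap_it, override = override
        )
      }
    }
    visits <- do.call(rbind, rows[seq_len(r)])
    visits <- visits[order(visits$cow_id, visits$day, visits$start_s), ]
    rownames(visits) <- NULL
    # unassigned mass eaten during the station reset window
    loss <- expand.grid(station_id = seq_len(config$n_stations),
                        day = seq_len(n_days))
    if (config$station_loss_mean > 0) {
      shp <- 2
      loss$kg <- pmin(config$station_loss_max,
                      stats::rgamma(nrow(loss), shape = shp,
                                    scale = config$station_loss_mean / shp))
    } else loss$kg <- 0
    attr(visits, "unassigned") <- loss
    attr(visits, "total_disappearance_kg") <- sum(visits$fmi_kg) + sum(loss$kg)
    visits
  })
}

#' Contaminate a visit stream with measurement artifacts
#'
#' Appends, at the configured per-visit rates, the three artifact families
#' that feed-station loggers produce: zero-duration visits, implausibly
#' short visits (duration < 4 s) with intake > 0.1 kg, and extreme-rate
#' outliers far off the cow's intake-vs-duration line (including negative
#' intakes). Ground-truth labels are kept in the `artifact` column so
#' cleaning can be scored against them.
#'
#' @param visits a [simulate_visits()] data.frame.
#' @param config a [barn_config()]; rates in `config$contamination`.
#' @param seed optional seed.
#' @return visits data.frame with appended contaminated rows and an
#'   `artifact` label column (`"none"` for original rows).
#' @export
inject_artifacts <- function(visits, config = barn_config(), seed = NULL) {
  rates <- config$contamination
  stopifnot(all(rates >= 0), all(rates <= 1))
  if (!"artifact" %in% names(visits)) visits$artifact <- "none"
  n <- nrow(visits)
  if (n == 0 || sum(rates) == 0) return(visits)
  with_seed(seed, {
    add <- lapply(names(rates), function(type) {
      k <- stats::rbinom(1, n, rates[[type]])
      if (k == 0) return(NULL)
      src <- visits[sample.int(n, k, replace = TRUE), , drop = FALSE]
      src$artifact <- type
      src$capped <- FALSE
      src$override <- FALSE
      if (type == "zero_duration") {
        src$duration_s <- 0
        src$fmi_kg <- 0
      } else if (type == "short_intake") {
        src$duration_s <- stats::runif(k, 0.5, 3.9)
        src$fmi_kg <- stats::runif(k, 0.15, 1.5)
      } else if (type == "rate_outlier") {
        neg <- stats::runif(k) < 0.5
        mins <- pmax(src$duration_s, 30) / 60
        src$fmi_kg <- ifelse(neg, -stats::runif(k, 0.1, 2),
                             pmin(mins * stats::runif(k, 900, 2500) / 1000 +
                                    stats::runif(k, 2, 6), 30))
      }
      src
    })
    out <- rbind(visits, do.call(rbind, add))
    out <- out[order(out$cow_id, out$day, out$start_s), ]
    rownames(out) <- NULL
    for (a in c("unassigned", "total_disappearance_kg"))
      attr(out, a) <- attr(visits, a)
    out
  })
}

#' Simulate daily milk yields
#'
#' Daily yield is the cow's milk level plus a days-in-milk trend
#' (`dim_trend_milk` l/day per DIM, centred at the cohort mean DIM) and
#' day-level noise, split over three milkings. A fraction
#' `milk_missing_rate` of cow-days has no recorded yield (`observed =
#' FALSE`); the latent value is kept so downstream generation can condition
#' on it.
#'
#' @inheritParams simulate_visits
#' @return data.frame `cow_id`, `day`, `m1`, `m2`, `m3`, `yield_l`,
#'   `observed`.
#' @export
simulate_milk <- function(cohort, n_days = NULL, config = barn_config(),
                          seed = NULL) {
  stopifnot(inherits(config, "herd_config"))
  if (is.null(n_days)) n_days <- config$n_days
  if (is.null(seed)) seed <- config$seed
  with_seed(seed, {
    grid <- expand.grid(day = seq_len(n_days), cow = seq_len(nrow(cohort)))
    g <- cohort$lame[grid$cow] + 1L
    dimc <- cohort$dim_start[grid$cow] + grid$day - 1 -
      (config$dim_mean + (n_days - 1) / 2)
    y <- cohort$milk_level[grid$cow] + config$dim_trend_milk * dimc +
      stats::rnorm(nrow(grid), 0, config$milk_day_sd[g])
    y <- pmax(0.5, y)
    fr <- matrix(stats::rnorm(nrow(grid) * 3, rep(config$milking_fracs,
                                                  each = nrow(grid)), 0.02),
                 ncol = 3)
    fr <- pmax(fr, 0.05)
    fr <- fr / rowSums(fr)
    out <- data.frame(cow_id = cohort$cow_id[grid$cow], day = grid$day,
                      m1 = y * fr[, 1], m2 = y * fr[, 2], m3 = y * fr[, 3])
    out$yield_l <- out$m1 + out$m2 + out$m3
    out$observed <- stats::runif(nrow(out)) >= config$milk_missing_rate
    out[order(out$cow_id, out$day), ]
  })
}
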