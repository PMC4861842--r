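#' Simulate a ground-truth rumination schedule
#'
#' Generates per-cow-day rumination bouts. The daily rumination-time target
#' follows the structural model on realized daily feeding rate, milk yield
#' and lameness (`rum_intercept + rum_per_rate * dFR + rum_per_milk * dMY +
#' rum_lame * lame + cow effect + day noise`); a Poisson number of events
#' (mean `rum_freq_mean`, ~20 min each) with gamma-proportioned durations is
#' normalised to that target and placed so that no event overlaps a milking
#' window or a feed-station visit of the same cow.
#'
#' @param cohort a [make_cohort()] data.frame.
#' @param n_days number of study days.
#' @param config a [barn_config()].
#' @param visits optional visit stream; when given, the day's realized
#'   feeding rate drives the rumination target and events avoid the visits.
#' @param milk optional [simulate_milk()] table supplying the day's (latent)
#'   milk yield; otherwise the cow's milk level is used.
#' @param seed optional seed overriding `config$seed`.
#' @return data.frame `cow_id`, `day`, `start_s`, `end_s`, `duration_min`.
#' @export
simulate_rumination_schedule <- function(cohort, n_days = NULL,
                                         config = barn_config(),
                                         visits = NULL, milk = NULL,
                                         seed = NULL) {
  stopifnot(inherits(config, "herd_config"))
  if (is.null(n_days)) n_days <- config$n_days
  if (n_days < 1) stop("n_days must be >= 1")
  if (is.null(seed)) seed <- config$seed
  day_s <- 86400
  mw <- config$milking_windows
  with_seed(seed, {
    rows <- vector("list", nrow(cohort) * n_days)
    r <- 0L
    for (ci in seq_len(nrow(cohort))) {
      cow <- cohort[ci, ]
      v_cow <- if (!is.null(visits))
        visits[visits$cow_id == cow$cow_id & visits$duration_s > 0, ] else NULL
      m_cow <- if (!is.null(milk)) milk[milk$cow_id == cow$cow_id, ] else NULL
      for (day in seq_len(n_days)) {
        v <- if (!is.null(v_cow)) v_cow[v_cow$day == day, ] else NULL
        dfr <- if (!is.null(v) && nrow(v) > 0 && sum(v$duration_s) > 0)
          1000 * sum(v$fmi_kg) / (sum(v$duration_s) / 60)
        else cow$true_feeding_rate
        dmy <- if (!is.null(m_cow) && any(m_cow$day == day))
          m_cow$yield_l[match(day, m_cow$day)] else cow$milk_level
        target <- config$rum_intercept + config$rum_per_rate * dfr +
          config$rum_per_milk * dmy + config$rum_lame * cow$lame +
          cow$rum_cow_effect + stats::rnorm(1, 0, config$rum_day_sd)
        target <- min(max(target, 60), 900)                    # min/day
        n_ev <- max(1L, stats::rpois(1, config$rum_freq_mean))
        w <- stats::rgamma(n_ev, shape = config$rum_event_shape)
        dur <- target * 60 * w / sum(w)                        # seconds
        blocked <- mw
        if (!is.null(v) && nrow(v) > 0)
          blocked <- rbind(blocked, cbind(v$start_s, v$start_s + v$duration_s))
        starts <- place_intervals(dur, free_intervals(blocked, day_s))
        dur2 <- attr(starts, "duration")
        keep <- is.finite(starts) & dur2 > 0
        r <- r + 1L
        rows[[r]] <- data.frame(
          cow_id = cow$cow_id, day = day,
          start_s = as.numeric(starts[keep]),
          end_s = as.numeric(starts[keep]) + dur2[keep],
          duration_min = dur2[keep] / 60
        )
      }
    }
    out <- do.call(rbind, rows[seq_len(r)])
    out <- out[order(out$cow_id, out$day, out$start_s), ]
    rownames(out) <- NULL
    out
  })
}

#' Simulate a complete synthetic barn
#'
#' Convenience wrapper running [make_cohort()], [simulate_visits()],
#' [simulate_milk()] and [simulate_rumination_schedule()] under one seed,
#' optionally contaminating the visit stream with [inject_artifacts()].
#'
#' @param config a [barn_config()].
#' @param seed optional seed overriding `config$seed`.
#' @param contaminate add labelled visit artifacts?
#' @return list of class `herd_barn`: `cohort`, `visits`, `milk`,
#'   `rumination`, `config`.
#' @export
simulate_barn <- function(config = barn_config(), seed = NULL,
                          contaminate = FALSE) {
  if (is.null(seed)) seed <- config$seed
  ss <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 5))
  cohort <- make_cohort(config, seed = ss[1])
  visits <- simulate_visits(cohort, config$n_days, config, seed = ss[2])
  milk <- simulate_milk(cohort, config$n_days, config, seed = ss[3])
  rumination <- simulate_rumination_schedule(cohort, config$n_days, config,
                                             visits = visits, milk = milk,
                                             seed = ss[4])
  if (contaminate) visits <- inject_artifacts(visits, config, seed = ss[5])
  structure(list(cohort = cohort, visits = visits, milk = milk,
                 rumination = rumination, config = config),
            class = "herd_barn")
}

#' @export
print.herd_barn <- function(x, ...) {
  cat("<herd_barn> ", nrow(x$cohort), " cows (",
      sum(!x$cohort$lame), " non-lame / ", sum(x$cohort$lame), " lame), ",
      nrow(x$visits), " visits, ", nrow(x$rumination),
      " rumination events, ", sum(x$milk$observed), " milk cow-days\n",
      sep = "")
  invisible(x)
}
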