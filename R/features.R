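#' Daily behavioural characteristics per cow-day
#'
#' Aggregates cleaned visits, rumination events and milk yields into one row
#' per cow-day: daily fresh-matter intake `dFMI` (kg), feeding time `dFtime`
#' (min), feeding frequency `dFfreq` (visits), mean intake and duration per
#' visit `mvFMI` / `mvFdur`, daily feeding rate `dFR = 1000 * dFMI / dFtime`
#' (g/min), rumination time/frequency/mean event duration `dRUMtime`,
#' `dRUMfreq`, `meRUMdur`, and milk yield `dMY` (l, `NA` when unrecorded).
#' Cow-days with no visits get zero feeding sums and missing per-visit
#' means.
#'
#' @param visits cleaned visit data.frame.
#' @param events rumination events (`cow_id`, `day`, `duration_min`) or NULL.
#' @param milk milk table (`cow_id`, `day`, `yield_l`, optional `observed`)
#'   or NULL.
#' @param cohort cohort data.frame supplying `dim_start`, `lame`,
#'   `mean_locomotion`.
#' @param days integer vector of study days to summarise (default: all days
#'   present in `visits`).
#' @param exclude_days days to mask out (e.g. incomplete boundary days).
#' @return data.frame of class `herd_daily`, one row per cow-day.
#' @export
daily_summaries <- function(visits, events = NULL, milk = NULL, cohort,
                            days = NULL, exclude_days = NULL) {
  if (is.null(days)) days <- sort(unique(visits$day))
  days <- setdiff(days, exclude_days)
  grid <- expand.grid(day = days, cow_id = cohort$cow_id)
  key <- function(cow, day) paste(cow, day, sep = "#")
  gk <- key(grid$cow_id, grid$day)

  agg <- function(df, val, fun) {
    if (is.null(df) || nrow(df) == 0) return(numeric(0))
    tapply(df[[val]], key(df$cow_id, df$day), fun)
  }
  v <- visits[visits$day %in% days, , drop = FALSE]
  s_fmi <- agg(v, "fmi_kg", sum)
  s_dur <- agg(v, "duration_s", sum)
  n_vis <- agg(v, "fmi_kg", length)
  m_dur <- agg(v, "duration_s", mean)

  out <- data.frame(cow_id = grid$cow_id, day = grid$day)
  ci <- match(out$cow_id, cohort$cow_id)
  out$dim <- cohort$dim_start[ci] + out$day - 1
  out$lame <- cohort$lame[ci]
  out$mean_locomotion <- cohort$mean_locomotion[ci]
  out$dFMI <- unname(ifelse(is.na(s_fmi[gk]), 0, s_fmi[gk]))
  out$dFtime <- unname(ifelse(is.na(s_dur[gk]), 0, s_dur[gk])) / 60
  out$dFfreq <- unname(ifelse(is.na(n_vis[gk]), 0, n_vis[gk]))
  out$mvFMI <- ifelse(out$dFfreq > 0, out$dFMI / out$dFfreq, NA_real_)
  out$mvFdur <- unname(m_dur[gk])
  out$dFR <- ifelse(out$dFtime > 0, 1000 * out$dFMI / out$dFtime, NA_real_)
  if (!is.null(events)) {
    e <- events[events$day %in% days, , drop = FALSE]
    rt <- agg(e, "duration_min", sum)
    rf <- agg(e, "duration_min", length)
    out$dRUMtime <- unname(ifelse(is.na(rt[gk]), 0, rt[gk]))
    out$dRUMfreq <- unname(ifelse(is.na(rf[gk]), 0, rf[gk]))
    out$meRUMdur <- ifelse(out$dRUMfreq > 0, out$dRUMtime / out$dRUMfreq,
                           NA_real_)
  } else out$dRUMtime <- out$dRUMfreq <- out$meRUMdur <- NA_real_
  if (!is.null(milk)) {
    m <- milk
    if ("observed" %in% names(m)) m <- m[m$observed, , drop = FALSE]
    my <- tapply(m$yield_l, key(m$cow_id, m$day), sum)
    out$dMY <- unname(my[gk])
  } else out$dMY <- NA_real_
  out <- out[order(out$cow_id, out$day), ]
  rownames(out) <- NULL
  class(out) <- c("herd_daily", "data.frame")
  out
}

#' Overall per-cow feeding rate
#'
#' Slope of the origin regression of visit intake on visit duration for one
#' cow, in g/min: `60000 * slope_kg_s`.
#'
#' @param visits one cow's cleaned visits.
#' @return feeding rate, g/min.
#' @export
cow_feeding_rate <- function(visits) {
  60000 * origin_slope(visits)$slope_kg_s
}

#' Inter- and intra-individual variation of daily characteristics
#'
#' For each characteristic and lameness group: the inter-individual mean,
#' SD and CV are taken across per-cow means (each cow weighted equally);
#' the intra-individual SD and CV are per-cow day-to-day SD and CV averaged
#' across cows, with the intra "mean" the cow-day-weighted pooled mean
#' (which differs from the inter mean when cows contribute unequal numbers
#' of days).
#'
#' @param daily a [daily_summaries()] data.frame.
#' @param vars characteristics to decompose (default: all Table-style
#'   columns present).
#' @return data.frame of class `herd_cv`: one row per characteristic x
#'   group, columns `inter_mean`, `inter_sd`, `inter_cv`, `intra_mean`,
#'   `intra_sd`, `intra_cv`, `n_cows`, `n_cow_days`.
#' @export
cv_decomposition <- function(daily, vars = NULL) {
  if (is.null(vars))
    vars <- intersect(c("dMY", "dFMI", "dFtime", "dFfreq", "mvFMI", "mvFdur",
                        "dFR", "dRUMtime", "dRUMfreq", "meRUMdur"),
                      names(daily))
  groups <- sort(unique(daily$lame))
  rows <- list()
  for (v in vars) for (g in groups) {
    d <- daily[daily$lame == g & !is.na(daily[[v]]), c("cow_id", v)]
    if (nrow(d) == 0) next
    cows <- unique(d$cow_id)
    if (length(cows) < 2)
      warning("group with a single cow: inter SD undefined for ", v)
    mu_k <- tapply(d[[v]], d$cow_id, mean)
    sd_k <- tapply(d[[v]], d$cow_id, stats::sd)
    n_k <- tapply(d[[v]], d$cow_id, length)
    ok <- n_k >= 2
    inter_mean <- mean(mu_k)
    inter_sd <- if (length(mu_k) >= 2) stats::sd(mu_k) else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      characteristic = v, lame = g,
      inter_mean = inter_mean, inter_sd = inter_sd,
      inter_cv = 100 * inter_sd / inter_mean,
      intra_mean = mean(d[[v]]),
      intra_sd = mean(sd_k[ok]),
      intra_cv = mean(100 * sd_k[ok] / mu_k[ok]),
      n_cows = length(cows), n_cow_days = nrow(d)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("herd_cv", "data.frame")
  out
}

#' Unaccounted feed per cow
#'
#' Feed disappearing during the daily station reset window, spread over the
#' herd: `mean_loss_per_station * n_stations / n_cows` kg/cow/day.
#'
#' @param mean_loss_per_station kg/station/day.
#' @param n_stations,n_cows positive counts.
#' @return kg/cow/day.
#' @export
#' @examples
#' unaccounted_feed(2.8, 12, 20)  # 1.68 -> ~1.7 kg/cow/day
unaccounted_feed <- function(mean_loss_per_station, n_stations, n_cows) {
  stopifnot(mean_loss_per_station >= 0, n_stations > 0, n_cows > 0)
  mean_loss_per_station * n_stations / n_cows
}

#' Time to eat a feed mass at a given rate
#'
#' @param mass_kg feed mass, kg.
#' @param rate_g_per_min feeding rate, g/min (> 0).
#' @return minutes.
#' @export
#' @examples
#' eating_time(1.7, 250)  # 6.8 min, i.e. under 7 minutes
eating_time <- function(mass_kg, rate_g_per_min) {
  if (any(rate_g_per_min <= 0)) stop("feeding rate must be positive")
  1000 * mass_kg / rate_g_per_min
}
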