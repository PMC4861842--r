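#' Synthetic-barn generator configuration
#'
#' Builds the configuration object consumed by [make_cohort()],
#' [simulate_visits()], [simulate_milk()], [simulate_rumination_schedule()]
#' and [simulate_barn()]. Defaults describe a 16-cow loose-housed herd
#' (7 non-lame, 9 lame) observed for 22 days at 12 automatic feed stations,
#' calibrated to published group-level lameness contrasts: per-group means
#' are the mixed-model least-square means (feeding frequency 60.3/33.9
#' visits/day, feeding rate 206/289 g/min, daily intake 39.4/33.8 kg,
#' milk 18.8/25.9 l/day, rumination 480/482 min/day for non-lame/lame),
#' between-cow SDs the inter-individual and day-level SDs the
#' intra-individual spreads of the same study.
#'
#' Daily rumination time is generated structurally from daily feeding rate
#' and milk yield (intercept 461 min/day, -0.24 min per g/min, +3.57 min
#' per l, -1.66 min for lame cows) plus a cow effect and day noise, so the
#' near-null lameness effect on rumination emerges rather than being set.
#'
#' @param seed integer or NULL; generator seed recorded in the config.
#' @param rate_model `"group"` draws each cow's true feeding rate from its
#'   lameness-group distribution; `"locomotion"` builds it linearly from the
#'   cow's mean locomotion score and milk level (visit-level truth
#'   `m3_base + m3_per_loco * loco + m3_per_milk * milk` g/min), the world
#'   used for visit-level slope recovery.
#' @param ... named overrides of any default field.
#' @return An object of class `herd_config` (a validated named list).
#' @seealso [m3_truth_config()], [simulate_barn()]
#' @export
#' @examples
#' cfg <- barn_config(seed = 1)
#' cfg$feed_rate_mean
barn_config <- function(seed = NULL, rate_model = c("group", "locomotion"), ...) {
  rate_model <- match.arg(rate_model)
  cfg <- list(
    seed = if (is.null(seed)) NULL else as.integer(seed),
    n_nonlame = 7L, n_lame = 9L, n_days = 22L, n_stations = 12L,
    # cohort-level covariates
    dim_mean = 238, dim_sd = 91.1, dim_range = c(54, 362),
    parity_probs = c(0.125, 0.375, 0.5),           # 1st / 2nd / 3rd+ lactation
    score_inconsistent_p = 0.1,                    # one of four scores off-group
    # per-group truths, order c(non-lame, lame)
    feed_freq_mean = c(60.3, 33.9), feed_freq_sd = c(10.1, 17.8),  # visits/day
    feed_rate_mean = c(206, 289),   feed_rate_sd  = c(48.1, 74.4), # g/min
    fmi_mean  = c(39.4, 33.8), fmi_sd  = c(6.48, 9.63),            # kg/day
    ftime_mean = c(197, 119),  ftime_sd = c(37.4, 44.2),           # min/day
    #   (used only by the locomotion-rate world, where feeding time is drawn
    #    independently of the rate and daily intake emerges as their product)
    milk_mean = c(18.8, 25.9), milk_sd = c(8.85, 5.96),            # l/day
    milk_day_sd = c(2.82, 1.35), milk_missing_rate = 0.08,
    milking_fracs = c(0.40, 0.33, 0.27),
    # rumination: structural model on daily feeding rate + milk + lameness
    rum_intercept = 461, rum_per_rate = -0.24, rum_per_milk = 3.57,
    rum_lame = -1.66, rum_cow_sd = 40, rum_day_sd = 24,
    rum_freq_mean = 24.75,                         # events/cow/day
    rum_event_shape = 4,                           # gamma shape of event length
    # within-cow dynamics
    ftime_day_cv = 0.09, rate_day_cv = 0.06, visit_noise_cv = 0.10,
    visit_dur_shape = 1.5,
    dim_trend_ftime = 0.32,                        # min/day per DIM (centred)
    dim_trend_milk = -0.05,                        # l/day per DIM (centred)
    dim_trend_freq_lame = 0.136,                   # visits/day per DIM, lame only
    # feed-station mechanics
    cap_kg = 5, cap_override_p = 0.05,
    reset_window = c(11 * 3600 + 45 * 60, 12 * 3600 + 15 * 60),
    station_loss_mean = 2.8, station_loss_max = 11.4,  # kg/station/day
    milking_windows = matrix(c(7.5, 10, 14.5, 16.5, 21.5, 23.5) * 3600,
                             ncol = 2, byrow = TRUE,
                             dimnames = list(NULL, c("start", "end"))),
    milking_absence_s = 40 * 60,                   # per cow per milking
    # contamination rates for inject_artifacts()
    contamination = c(zero_duration = 0.0103, short_intake = 0.012,
                      rate_outlier = 0.012),
    # visit-level truth used when rate_model == "locomotion"
    rate_model = rate_model,
    m3_base = 119, m3_per_loco = 36, m3_per_milk = 0.32,
    m3_cow_slope_sd = 25
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_config(structure(cfg, class = "herd_config"))
}

#' Visit-level truth configuration for feeding-rate slope recovery
#'
#' Same barn as [barn_config()] but each cow's true feeding rate is the
#' linear predictor on its mean locomotion score and milk level, so the
#' no-intercept random-slope visit model can recover the baseline slope
#' (119 g/min) and the locomotion increment (36 g/min per score unit).
#'
#' @inheritParams barn_config
#' @return A `herd_config`.
#' @export
m3_truth_config <- function(seed = NULL, ...) {
  barn_config(seed = seed, rate_model = "locomotion", ...)
}

validate_config <- function(cfg) {
  if (cfg$n_nonlame + cfg$n_lame < 2) stop("need at least 2 cows in total")
  stopifnot(
    cfg$n_nonlame >= 0, cfg$n_lame >= 0,
    cfg$n_days >= 1, cfg$n_stations >= 1,
    all(cfg$feed_freq_sd >= 0), all(cfg$feed_rate_sd >= 0),
    all(cfg$fmi_sd >= 0), all(cfg$milk_sd >= 0), all(cfg$milk_day_sd >= 0),
    cfg$rum_cow_sd >= 0, cfg$rum_day_sd >= 0, cfg$rum_freq_mean > 0,
    all(cfg$contamination >= 0), all(cfg$contamination <= 1),
    cfg$cap_override_p >= 0, cfg$cap_override_p <= 1,
    cfg$cap_kg > 0, cfg$station_loss_mean >= 0,
    cfg$milk_missing_rate >= 0, cfg$milk_missing_rate < 1
  )
  if (!cfg$rate_model %in% c("group", "locomotion"))
    stop("rate_model must be 'group' or 'locomotion'")
  cfg
}

#' @export
print.herd_config <- function(x, ...) {
  cat("<herd_config> ", x$n_nonlame, " non-lame + ", x$n_lame, " lame cows, ",
      x$n_days, " days, ", x$n_stations, " stations; rate_model=",
      x$rate_model, "; seed=", if (is.null(x$seed)) "NULL" else x$seed,
      "\n", sep = "")
  invisible(x)
}

#' Read / write a generator configuration as YAML
#'
#' @param cfg a `herd_config`.
#' @param path file path.
#' @return `read_config()` returns a `herd_config`; `write_config()` the path,
#'   invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "herd_config"))
  out <- unclass(cfg)
  out$contamination <- as.list(cfg$contamination)  # keep names in the YAML map
  out$milking_windows <- apply(cfg$milking_windows, 1, as.numeric, simplify = FALSE)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$milking_windows <- matrix(unlist(raw$milking_windows), ncol = 2,
                                byrow = TRUE,
                                dimnames = list(NULL, c("start", "end")))
  raw$contamination <- unlist(raw$contamination)
  base <- barn_config()
  cfg <- utils::modifyList(unclass(base), raw)
  cfg <- cfg[names(base)]
  validate_config(structure(cfg, class = "herd_config"))
}
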