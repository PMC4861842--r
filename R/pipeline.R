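#' Run the full synthetic-barn pipeline
#'
#' Executes generate -> synthesize/classify -> clean -> characterize ->
#' model as one reproducible run: simulates a contaminated barn, classifies
#' rumination from synthesized accelerometer traces on a subset of cow-days
#' (the full herd-period signal is deliberately not synthesized; the truth
#' schedule drives the daily characteristics, as a validated classifier
#' would), cleans the visit stream, derives daily characteristics and the
#' CV table, fits the daily lameness models, the visit-level slope model
#' and the rumination-association model family, and writes every artifact
#' plus a run manifest into `out_dir`.
#'
#' @param config a [barn_config()].
#' @param out_dir output directory (created if needed).
#' @param seed run seed (overrides `config$seed`).
#' @param classify_cow_days how many cow-days of accelerometer signal to
#'   synthesize and classify (0 skips the stage).
#' @param accel an [accel_config()] for the classification stage.
#' @param figures write diagnostic plots (PDF)?
#' @return the run manifest (list), invisibly. Identical `(config, seed)`
#'   reproduce identical table outputs byte for byte.
#' @export
run_pipeline <- function(config = barn_config(), out_dir, seed = NULL,
                         classify_cow_days = 2, accel = accel_config(),
                         figures = TRUE) {
  if (is.null(seed)) seed <- config$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  manifest <- list(seed = seed, config_checksum = fnv1a32(
    paste(deparse(unclass(config)), collapse = "")), stages = list())
  wcsv <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(x, p, row.names = FALSE)
    p
  }
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  barn <- run("simulate", simulate_barn(config, seed = seed,
                                        contaminate = TRUE))
  wcsv(barn$cohort, "cohort.csv")
  wcsv(cbind(barn$visits,
             start_iso = format(as.POSIXct((barn$visits$day - 1) * 86400 +
                                             barn$visits$start_s,
                                           origin = "2020-01-01",
                                           tz = "UTC"),
                                "%Y-%m-%dT%H:%M:%SZ")),
       "visits.csv")
  wcsv(barn$milk[barn$milk$observed, setdiff(names(barn$milk), "observed")],
       "milk.csv")
  wcsv(barn$rumination, "rumination_truth.csv")
  write_config(config, file.path(out_dir, "config.yaml"))
  manifest$stages$simulate <- list(n_cows = nrow(barn$cohort),
                                   n_visits = nrow(barn$visits),
                                   n_rumination = nrow(barn$rumination),
                                   n_milk_days = sum(barn$milk$observed))

  if (classify_cow_days > 0) {
    rep_ <- run("classify", classify_sample(barn, classify_cow_days, accel,
                                            seed = (seed %||% 0) + 101))
    jsonlite::write_json(rep_[c("sensitivity", "ppv", "tp", "fp", "fn",
                                "tn")],
                         file.path(out_dir, "classification_report.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages$classify <- list(cow_days = classify_cow_days,
                                     sensitivity = rep_$sensitivity,
                                     ppv = rep_$ppv)
  }

  cl <- run("clean", clean_visits(barn$visits, cap_kg = config$cap_kg))
  wcsv(cl$visits, "cleaned.csv")
  jsonlite::write_json(cl$report[c("n_input", "n_zero_duration_excluded",
                                   "n_outliers_pass1", "n_fmi_replaced",
                                   "n_duration_replaced", "frac_affected")],
                       file.path(out_dir, "cleaning_report.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$stages$clean <- list(n_in = cl$report$n_input,
                                n_out = nrow(cl$visits))

  daily <- run("characterize",
               daily_summaries(cl$visits, barn$rumination, barn$milk,
                               barn$cohort))
  wcsv(daily, "daily.csv")
  cvt <- cv_decomposition(daily)
  wcsv(cvt, "cvtable.csv")
  manifest$stages$characterize <- list(n_cow_days = nrow(daily))

  models <- run("model", fit_study_models(daily, cl$visits, barn$cohort))
  jsonlite::write_json(models, file.path(out_dir, "models.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest$stages$model <- list(n_m1 = length(models$m1),
                                m2_best = models$m2_table$name[
                                  which.max(models$m2_table$R2)])

  if (figures) run("figures", pipeline_figures(daily, cl$visits, out_dir))
  manifest$outputs <- list.files(out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

# Classify a few cow-days of synthesized signal against the truth schedule.
classify_sample <- function(barn, n_cow_days, accel, seed = NULL) {
  ev <- barn$rumination
  # contamination artifacts are logger glitches, not real occupancy: the
  # physical activity schedule is the clean visit stream
  if ("artifact" %in% names(barn$visits))
    barn$visits <- barn$visits[barn$visits$artifact == "none", , drop = FALSE]
  keys <- unique(ev[, c("cow_id", "day")])
  keys <- utils::head(keys, n_cow_days)
  preds <- list(); truths <- list()
  for (i in seq_len(nrow(keys))) {
    off <- (i - 1) * 86400
    cid <- keys$cow_id[i]; d <- keys$day[i]
    tru <- ev[ev$cow_id == cid & ev$day == d, , drop = FALSE]
    vis <- barn$visits[barn$visits$cow_id == cid & barn$visits$day == d &
                         barn$visits$duration_s > 0, , drop = FALSE]
    sched <- rbind(
      data.frame(start_s = tru$start_s, end_s = tru$end_s,
                 activity = "rumination"),
      data.frame(start_s = vis$start_s, end_s = vis$start_s + vis$duration_s,
                 activity = "feeding"))
    sig <- synthesize_accel(sched, accel, seed = (seed %||% 0) + i,
                            duration_s = 86400, cow_id = cid)
    fe <- window_features(sig, accel$window_s, accel$bands)
    hmm <- decode_states(fe, n_states = 3, seed = (seed %||% 0) + 1000 + i)
    pr <- states_to_events(hmm, accel$window_s)
    pr$start_s <- pr$start_s + off; pr$end_s <- pr$end_s + off
    preds[[i]] <- pr
    truths[[i]] <- data.frame(start_s = tru$start_s + off,
                              end_s = tru$end_s + off)
  }
  evaluate_events(do.call(rbind, preds), do.call(rbind, truths),
                  window_s = accel$window_s,
                  span = c(0, nrow(keys) * 86400))
}

# The three study model families on one barn realisation.
fit_study_models <- function(daily, cleaned_visits, cohort) {
  responses <- c("dMY", "dFMI", "dFtime", "dFfreq", "dRUMtime", "dRUMfreq",
                 "mvFdur", "dFR")
  m1 <- lapply(responses, function(resp) {
    f <- stats::as.formula(paste(resp, "~ lame * dim"))
    red <- reduce_interactions(f, daily, group = "cow_id")
    fit <- red$fit
    null_fit <- fit_lmm(stats::as.formula(paste(resp, "~ 1")), fit$data,
                        group = "cow_id")
    ls <- lsm(fit, "lame")
    list(response = resp, formula = deparse(red$fixed),
         lsm_nonlame = ls$lsm[1], se_nonlame = ls$se[1],
         lsm_lame = ls$lsm[2], se_lame = ls$se[2],
         p_value = lrt(fit, null_fit)$p_value,
         interaction_kept = any(grepl(":", attr(stats::terms(red$fixed),
                                                "term.labels"))))
  })
  names(m1) <- responses
  # visit-level slope model: intake (g) on duration (min), no intercept
  v <- cleaned_visits
  v$dur_min <- v$duration_s / 60
  v$fmi_g <- 1000 * v$fmi_kg
  v$loco <- cohort$mean_locomotion[match(v$cow_id, cohort$cow_id)]
  v$milk <- cohort$milk_level[match(v$cow_id, cohort$cow_id)]
  m3_fit <- fit_lmm(fmi_g ~ 0 + dur_min + dur_min:loco + dur_min:milk, v,
                    group = "cow_id", random = ~ 0 + dur_min)
  m3 <- list(coefficients = as.list(stats::coef(m3_fit)),
             se = as.list(m3_fit$se), sigma2_slope = m3_fit$sigma2_group)
  # rumination-association family on milk-complete cow-days
  specs <- list(
    "M2.1.1" = dRUMtime ~ lame, "M2.1.2" = dRUMtime ~ dFtime,
    "M2.1.3" = dRUMtime ~ dFMI, "M2.1.4" = dRUMtime ~ dFR,
    "M2.1.5" = dRUMtime ~ dMY, "M2.1.6" = dRUMtime ~ dFfreq,
    "M2.2.1" = dRUMtime ~ dMY + lame, "M2.2.2" = dRUMtime ~ dMY + dFR,
    "M2.3.1" = dRUMtime ~ dMY + lame + dFtime,
    "M2.3.2" = dRUMtime ~ dMY + lame + dFR,
    "M2.3.3" = dRUMtime ~ dMY + lame + dFfreq,
    "M2.4" = dRUMtime ~ dMY + lame + dFMI + lame:dFMI)
  m2_table <- compare_models(specs, daily, group = "cow_id")
  m232 <- fit_lmm(dRUMtime ~ dMY + lame + dFR,
                  daily[stats::complete.cases(daily[c("dRUMtime", "dMY",
                                                      "dFR")]), ],
                  group = "cow_id")
  list(m1 = m1, m3 = m3, m2_table = m2_table,
       m2_3_2 = list(coefficients = as.list(stats::coef(m232)),
                     se = as.list(m232$se)))
}

# Diagnostic plots mirroring the study's figure panels.
pipeline_figures <- function(daily, visits, out_dir) {
  grDevices::pdf(file.path(out_dir, "diagnostics.pdf"), width = 7,
                 height = 6)
  on.exit(grDevices::dev.off(), add = TRUE)
  col <- ifelse(daily$lame, "red", "black")
  plot(visits$duration_s / 60, visits$fmi_kg, pch = ".",
       xlab = "visit duration (min)", ylab = "intake (kg/visit)",
       main = "Intake vs visit duration")
  plot(daily$dFfreq, daily$mvFMI, col = col, pch = 16,
       xlab = "visits/day", ylab = "mean intake per visit (kg)",
       main = "Per-visit intake vs feeding frequency")
  fr <- seq(max(1, min(daily$dFfreq)), max(daily$dFfreq), length.out = 100)
  graphics::lines(fr, mean(daily$dFMI, na.rm = TRUE) / fr, lty = 2)
  plot(daily$dFfreq, daily$mvFdur, col = col, pch = 16,
       xlab = "visits/day", ylab = "mean visit duration (s)",
       main = "Visit duration vs feeding frequency")
  for (h in 1:4) graphics::lines(fr, h * 3600 / fr, lty = h)
  ok <- stats::complete.cases(daily[c("dMY", "dRUMtime")])
  plot(daily$dMY[ok], daily$dRUMtime[ok], col = col[ok], pch = 16,
       xlab = "milk yield (l/day)", ylab = "rumination (min/day)",
       main = "Rumination vs milk yield")
  invisible(NULL)
}
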