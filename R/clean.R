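# Two-pass regression cleaning of feed-station visits.
#
# Per cow, intake is regressed on visit duration through the origin; visits
# off that line by more than k residual SDs, or implausibly short with
# appreciable intake, are flagged, the line is refit without them, and the
# flagged (and newly deviating) visits are repaired from the second line:
# the intake is replaced for large/negative intakes, the duration for long
# visits with low intake and for sub-4-second visits.

#' Drop zero-duration visits
#'
#' @param visits data.frame with at least `duration_s`.
#' @return list `visits` (rows with `duration_s > 0`) and `n_dropped`.
#' @export
drop_zero_duration <- function(visits) {
  keep <- visits$duration_s > 0
  list(visits = visits[keep, , drop = FALSE], n_dropped = sum(!keep))
}

#' Origin regression of intake on visit duration
#'
#' Least-squares line through the origin for one cow's visits:
#' `slope = sum(duration * fmi) / sum(duration^2)` (kg/s), with the SD of
#' the residuals about that line.
#'
#' @param visits one cow's visits (`duration_s`, `fmi_kg`).
#' @return list `slope_kg_s`, `resid_sd`, `n`.
#' @export
origin_slope <- function(visits) {
  use <- visits$duration_s > 0
  d <- visits$duration_s[use]; f <- visits$fmi_kg[use]
  if (length(d) < 2) stop("need at least 2 positive-duration visits")
  slope <- sum(d * f) / sum(d * d)
  res <- f - slope * d
  list(slope_kg_s = slope, resid_sd = stats::sd(res), n = length(d))
}

#' First-pass outlier flags for one cow
#'
#' Flags the union of (1) visits deviating more than `k` residual SDs from
#' the first origin-regression line and (2) visits with duration < 4 s and
#' intake > 0.1 kg. With a zero residual SD, rule (1) flags every off-line
#' point.
#'
#' @param visits one cow's visits.
#' @param slope,resid_sd first-pass line from [origin_slope()].
#' @param k SD-unit threshold (default 5).
#' @return logical flag vector along `visits` rows.
#' @export
first_check <- function(visits, slope, resid_sd, k = 5) {
  res <- visits$fmi_kg - slope * visits$duration_s
  rule1 <- if (resid_sd > 0) abs(res) > k * resid_sd else abs(res) > 1e-12
  rule2 <- visits$duration_s < 4 & visits$fmi_kg > 0.1
  rule1 | rule2
}

#' Second-pass refit and case-based replacement for one cow
#'
#' Refits the origin line on unflagged visits, then repairs every pass-1
#' flagged visit and every visit newly deviating more than `k` residual SDs
#' from the second line. Replacement is case based: visits < 4 s with
#' intake > 0.1 kg get `duration := fmi / slope2`; large (`> cap_kg` or
#' above-line by > k SD) or non-positive intakes get `fmi := slope2 *
#' duration`; long visits with low intake (below-line) get `duration := fmi
#' / slope2`. The untouched field is preserved bitwise.
#'
#' @param visits one cow's visits.
#' @param flagged logical vector from [first_check()].
#' @param k SD-unit threshold.
#' @param cap_kg the per-visit intake cap used to call an intake "large".
#' @return list `visits` (with `replaced_field` column), `slope2`,
#'   `resid_sd2`, `n_fmi_replaced`, `n_duration_replaced`.
#' @export
second_check_and_replace <- function(visits, flagged, k = 5, cap_kg = 5) {
  if (!"replaced_field" %in% names(visits)) visits$replaced_field <- "none"
  ok <- !flagged & visits$duration_s > 0
  if (sum(ok) < 2) stop("fewer than 2 unflagged visits; cannot refit")
  fit2 <- origin_slope(visits[ok, , drop = FALSE])
  slope2 <- fit2$slope_kg_s; sd2 <- fit2$resid_sd
  if (!is.finite(slope2) || slope2 <= 0)
    stop("non-positive second-pass slope; pathological cow data")
  res2 <- visits$fmi_kg - slope2 * visits$duration_s
  newdev <- if (sd2 > 0) abs(res2) > k * sd2 else rep(FALSE, nrow(visits))
  # negative intake is physically impossible: always repaired, even when a
  # contamination-inflated residual SD hides it from the +/-5 SD rule
  newdev <- (newdev | visits$fmi_kg < 0) & !flagged
  fix <- which(flagged | newdev)
  for (i in fix) {
    d <- visits$duration_s[i]; f <- visits$fmi_kg[i]
    if (d < 4 && f > 0.1) {                       # short visit, real intake
      visits$duration_s[i] <- f / slope2
      visits$replaced_field[i] <- "duration"
    } else if (f <= 0 || f > cap_kg || res2[i] > 0) {  # large/negative intake
      visits$fmi_kg[i] <- slope2 * d
      visits$replaced_field[i] <- "fmi"
    } else {                                       # long visit, low intake
      visits$duration_s[i] <- f / slope2
      visits$replaced_field[i] <- "duration"
    }
  }
  list(visits = visits, slope2 = slope2, resid_sd2 = sd2,
       n_fmi_replaced = sum(visits$replaced_field[fix] == "fmi"),
       n_duration_replaced = sum(visits$replaced_field[fix] == "duration"))
}

#' Two-pass cleaning of a visit stream
#'
#' Composition of [drop_zero_duration()], per-cow [origin_slope()],
#' [first_check()] and [second_check_and_replace()]. Cows with fewer than
#' two usable visits, or with a pathological (non-positive) second-pass
#' slope, are passed through unchanged with a warning.
#'
#' @param visits visit data.frame (`cow_id`, `duration_s`, `fmi_kg`, ...).
#' @param k SD-unit threshold for both passes (default 5).
#' @param cap_kg per-visit intake cap (kg) used by the replacement rules.
#' @return list of class `herd_cleaning`: `visits` (cleaned, with
#'   `replaced_field`) and `report` (a `cleaning_report` list with counts
#'   and per-cow slopes/SDs for both passes).
#' @export
clean_visits <- function(visits, k = 5, cap_kg = 5) {
  n_input <- nrow(visits)
  dz <- drop_zero_duration(visits)
  v <- dz$visits
  v$replaced_field <- "none"
  percow <- list()
  out <- vector("list", 0)
  n_out1 <- 0L; n_fmi <- 0L; n_dur <- 0L
  for (id in unique(v$cow_id)) {
    vc <- v[v$cow_id == id, , drop = FALSE]
    res <- tryCatch({
      fit1 <- origin_slope(vc)
      fl <- first_check(vc, fit1$slope_kg_s, fit1$resid_sd, k = k)
      sec <- second_check_and_replace(vc, fl, k = k, cap_kg = cap_kg)
      percow[[as.character(id)]] <- list(
        cow_id = id, n = nrow(vc),
        slope1_g_s = 1000 * fit1$slope_kg_s, resid_sd1 = fit1$resid_sd,
        slope2_g_s = 1000 * sec$slope2, resid_sd2 = sec$resid_sd2,
        n_flagged_pass1 = sum(fl))
      n_out1 <- n_out1 + sum(fl)
      n_fmi <- n_fmi + sec$n_fmi_replaced
      n_dur <- n_dur + sec$n_duration_replaced
      sec$visits
    }, error = function(e) {
      warning("cow ", id, " skipped: ", conditionMessage(e), call. = FALSE)
      vc
    })
    out[[length(out) + 1]] <- res
  }
  cleaned <- do.call(rbind, out)
  nr <- nrow(cleaned)
  k2 <- if ("day" %in% names(cleaned)) cleaned$day else rep(0, nr)
  k3 <- if ("start_s" %in% names(cleaned)) cleaned$start_s else rep(0, nr)
  cleaned <- cleaned[order(cleaned$cow_id, k2, k3), , drop = FALSE]
  rownames(cleaned) <- NULL
  report <- structure(list(
    n_input = n_input,
    n_zero_duration_excluded = dz$n_dropped,
    n_outliers_pass1 = n_out1,
    n_fmi_replaced = n_fmi,
    n_duration_replaced = n_dur,
    frac_affected = (dz$n_dropped + n_fmi + n_dur) / max(n_input, 1),
    per_cow = percow, k = k, cap_kg = cap_kg
  ), class = "cleaning_report")
  structure(list(visits = cleaned, report = report), class = "herd_cleaning")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report> ", x$n_input, " visits: ",
      x$n_zero_duration_excluded, " zero-duration excluded, ",
      x$n_outliers_pass1, " pass-1 flags, ",
      x$n_fmi_replaced, " FMI and ", x$n_duration_replaced,
      " durations replaced (", sprintf("%.1f%%", 100 * x$frac_affected),
      " of visits affected)\n", sep = "")
  invisible(x)
}
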