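#' Categorize lameness from four locomotion scores
#'
#' A cow is classed as lame when at least three of its four locomotion
#' scores (1-5 visual gait scale) are 3 or higher; this majority rule keeps
#' a cow that improves after treatment late in the study in the lame group.
#'
#' @param scores integer vector of exactly four scores in 1..5.
#' @return list with `lame` (logical) and `mean_locomotion` (numeric).
#' @export
#' @examples
#' categorize_lameness(c(4, 4, 4, 2))  # lame, mean 3.5
categorize_lameness <- function(scores) {
  if (length(scores) != 4 || anyNA(scores))
    stop("exactly four non-missing locomotion scores are required")
  if (!all(scores %in% 1:5)) stop("locomotion scores must be integers in 1..5")
  list(lame = sum(scores >= 3) >= 3, mean_locomotion = mean(scores))
}

#' Generate a synthetic cow cohort
#'
#' Draws per-cow trait profiles from the configured lameness-group
#' distributions: feeding rate and visit frequency lognormal (positive,
#' right-skewed), daily intake and milk level truncated normal, locomotion
#' scores consistent with group membership by construction. When
#' `cfg$rate_model == "locomotion"` the true feeding rate is instead built
#' from the cow's mean locomotion score and milk level plus a cow-level
#' random slope.
#'
#' @param config a [barn_config()].
#' @param n_cows total herd size; must equal `n_nonlame + n_lame`.
#' @param seed optional seed overriding `config$seed`.
#' @return data.frame of class `herd_cohort`, one row per cow.
#' @export
make_cohort <- function(config = barn_config(), n_cows = NULL, seed = NULL) {
  stopifnot(inherits(config, "herd_config"))
  n_total <- config$n_nonlame + config$n_lame
  if (is.null(n_cows)) n_cows <- n_total
  if (n_cows < 2) stop("n_cows must be at least 2")
  if (n_cows != n_total)
    stop("config group sizes (", config$n_nonlame, " + ", config$n_lame,
         ") are inconsistent with n_cows = ", n_cows)
  if (is.null(seed)) seed <- config$seed
  with_seed(seed, {
    lame <- rep(c(FALSE, TRUE), c(config$n_nonlame, config$n_lame))
    g <- lame + 1L                                   # 1 non-lame, 2 lame
    scores <- t(vapply(lame, draw_scores, integer(4),
                       p_flip = config$score_inconsistent_p))
    mean_loco <- rowMeans(scores)
    dim_start <- round(rnorm_trunc(n_cows, config$dim_mean, config$dim_sd,
                                   lower = config$dim_range[1]))
    dim_start <- pmin(dim_start, config$dim_range[2])
    parity <- sample.int(3L, n_cows, replace = TRUE, prob = config$parity_probs)
    milk_level <- rnorm_trunc(n_cows, config$milk_mean[g], config$milk_sd[g],
                              lower = 2)
    freq <- numeric(n_cows)
    rate <- numeric(n_cows)
    for (k in 1:2) {
      idx <- which(g == k)
      if (!length(idx)) next
      freq[idx] <- pmax(2, rlnorm_mm(length(idx), config$feed_freq_mean[k],
                                     config$feed_freq_sd[k]))
      rate[idx] <- rlnorm_mm(length(idx), config$feed_rate_mean[k],
                             config$feed_rate_sd[k])
    }
    if (config$rate_model == "locomotion") {
      rate <- config$m3_base + config$m3_per_loco * mean_loco +
        config$m3_per_milk * milk_level +
        stats::rnorm(n_cows, 0, config$m3_cow_slope_sd)
      rate <- pmax(30, rate)
      # feeding time independent of the rate: keeps the cow random slope
      # exogenous to the visit-duration design, so the no-intercept slope
      # model is estimable without endogeneity bias; intake emerges
      ftime <- rlnorm_mm(n_cows, config$ftime_mean[g], config$ftime_sd[g])
      fmi <- rate * ftime / 1000
    } else {
      fmi <- rnorm_trunc(n_cows, config$fmi_mean[g], config$fmi_sd[g],
                         lower = 10)
      ftime <- 1000 * fmi / rate
    }
    rum_re <- stats::rnorm(n_cows, 0, config$rum_cow_sd)
    true_rum <- config$rum_intercept + config$rum_per_rate * rate +
      config$rum_per_milk * milk_level + config$rum_lame * lame + rum_re
    out <- data.frame(
      cow_id = seq_len(n_cows), parity = parity, dim_start = dim_start,
      lame = lame,
      loco1 = scores[, 1], loco2 = scores[, 2], loco3 = scores[, 3],
      loco4 = scores[, 4], mean_locomotion = mean_loco,
      true_feeding_rate = rate,            # g/min
      true_visits_per_day = freq,          # visits/day
      true_fmi = fmi,                      # kg/day
      true_feeding_time = ftime,           # min/day
      true_rumination_time = pmax(60, true_rum),  # min/day
      rum_cow_effect = rum_re,
      milk_level = milk_level              # l/day at mean DIM
    )
    class(out) <- c("herd_cohort", "data.frame")
    out
  })
}

# Four locomotion scores consistent with lameness status; with probability
# p_flip one of the four crosses the lame threshold the other way (majority
# rule still classifies the cow into its group).
draw_scores <- function(lame, p_flip = 0.1) {
  s <- if (lame) sample(3:5, 4, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  else sample(1:2, 4, replace = TRUE)
  if (stats::runif(1) < p_flip) {
    i <- sample.int(4, 1)
    s[i] <- if (lame) sample(1:2, 1) else 3L
  }
  as.integer(s)
}
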