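#' Segment feature windows with a Gaussian-emission hidden Markov model
#'
#' Fits an `n_states`-state HMM with diagonal Gaussian emissions to the
#' natural log of the windowed features (variance and band powers; a small
#' epsilon keeps zeros finite) by EM, keeping the best of several random
#' restarts, and returns the Viterbi state path. The state with the highest
#' mean chew-band-to-broadband log ratio is labelled rumination, which
#' makes the labelling invariant to state permutation across restarts.
#'
#' @param features an [window_features()] data.frame (>= 10 windows).
#' @param n_states 2 or 3 hidden states.
#' @param seed optional RNG seed.
#' @param n_restarts EM restarts (best log-likelihood kept).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   tolerance; non-convergence after all restarts yields a warning and the
#'   best fit so far.
#' @param eps additive offset before the log transform.
#' @return object of class `herd_hmm`: `states` (Viterbi path),
#'   `rumination_state`, `is_rumination`, `loglik`, `model` (init,
#'   transition, means, vars), `converged`.
#' @export
decode_states <- function(features, n_states = 3, seed = NULL,
                          n_restarts = 5, max_iter = 100, tol = 1e-6,
                          eps = 1e-12) {
  if (!n_states %in% 2:3) stop("n_states must be 2 or 3")
  fcols <- setdiff(names(features), "window_start")
  Y <- log(as.matrix(features[fcols]) + eps)
  T_ <- nrow(Y)
  if (T_ < 10) stop("need at least 10 windows")
  d <- ncol(Y)
  bands <- attr(features, "bands")
  chew_col <- if (!is.null(bands)) names(bands)[1] else "chew"
  broad_col <- if (!is.null(bands)) names(bands)[length(bands)] else "broad"

  log_dens <- function(mu, v) {
    ld <- matrix(0, T_, n_states)
    for (s in seq_len(n_states))
      ld[, s] <- -0.5 * colSums((t(Y) - mu[s, ])^2 / v[s, ] +
                                  log(2 * pi * v[s, ]))
    ld
  }

  run_em <- function() {
    km <- tryCatch(stats::kmeans(Y, centers = n_states, nstart = 2),
                   error = function(e) NULL)
    assign0 <- if (is.null(km)) sample.int(n_states, T_, replace = TRUE)
    else km$cluster
    mu <- t(vapply(seq_len(n_states), function(s)
      colMeans(Y[assign0 == s, , drop = FALSE]), numeric(d)))
    mu[!is.finite(mu)] <- 0
    v <- t(vapply(seq_len(n_states), function(s) {
      vs <- apply(Y[assign0 == s, , drop = FALSE], 2, stats::var)
      vs[!is.finite(vs) | vs < 1e-6] <- 1e-6
      vs
    }, numeric(d)))
    init <- rep(1 / n_states, n_states)
    trans <- matrix(0.1 / (n_states - 1), n_states, n_states)
    diag(trans) <- 0.9
    ll_old <- -Inf; converged <- FALSE
    for (it in seq_len(max_iter)) {
      fb <- hmm_forward_backward(log_dens(mu, v), init, trans)
      gam <- fb$gamma
      init <- pmax(gam[1, ], 1e-8); init <- init / sum(init)
      xi <- fb$xi + 1e-8
      trans <- xi / rowSums(xi)
      wsum <- colSums(gam)
      for (s in seq_len(n_states)) {
        mu[s, ] <- colSums(Y * gam[, s]) / wsum[s]
        v[s, ] <- pmax(colSums((t(t(Y) - mu[s, ]))^2 * gam[, s]) / wsum[s],
                       1e-6)
      }
      if (is.finite(ll_old) &&
          abs(fb$loglik - ll_old) < tol * (abs(ll_old) + 1)) {
        converged <- TRUE; ll_old <- fb$loglik; break
      }
      ll_old <- fb$loglik
    }
    list(loglik = ll_old, mu = mu, v = v, init = init, trans = trans,
         converged = converged)
  }

  with_seed(seed, {
    fits <- lapply(seq_len(n_restarts), function(i) run_em())
    best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
    if (!any(vapply(fits, `[[`, logical(1), "converged")))
      warning("EM did not converge in any restart; returning best fit so far")
    path <- hmm_viterbi(log_dens(best$mu, best$v), log(best$init),
                        log(best$trans))
    ratio <- best$mu[, match(chew_col, fcols)] -
      best$mu[, match(broad_col, fcols)]
    rum_state <- which.max(ratio)
    structure(list(states = as.integer(path), rumination_state = rum_state,
                   is_rumination = path == rum_state, loglik = best$loglik,
                   model = list(init = best$init, trans = best$trans,
                                means = best$mu, vars = best$v,
                                features = fcols),
                   converged = best$converged, n_states = n_states),
              class = "herd_hmm")
  })
}

#' @export
print.herd_hmm <- function(x, ...) {
  cat("<herd_hmm> ", x$n_states, " states, ", length(x$states),
      " windows, rumination state ", x$rumination_state, " (",
      sum(x$is_rumination), " windows), logLik ", sprintf("%.1f", x$loglik),
      if (!x$converged) " [not converged]", "\n", sep = "")
  invisible(x)
}

#' Turn a rumination state path into events
#'
#' Consecutive rumination windows become one event; events separated by a
#' gap shorter than `merge_gap_s` are merged; events shorter than
#' `min_event_s` are dropped (after merging).
#'
#' @param path a `herd_hmm` object or a logical per-window rumination
#'   indicator.
#' @param window_s window length, seconds.
#' @param merge_gap_s,min_event_s merge and minimum-length thresholds (s).
#' @param t0 timestamp of the first window.
#' @return data.frame `start_s`, `end_s`, `duration_min`.
#' @export
states_to_events <- function(path, window_s, merge_gap_s = 60,
                             min_event_s = 120, t0 = 0) {
  stopifnot(merge_gap_s >= 0, min_event_s >= 0)
  ind <- if (inherits(path, "herd_hmm")) path$is_rumination else as.logical(path)
  if (!length(ind) || !any(ind))
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_min = numeric(0)))
  r <- rle(ind)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ev <- data.frame(start_s = t0 + (starts[r$values] - 1) * window_s,
                   end_s = t0 + ends[r$values] * window_s)
  # merge events separated by short gaps
  if (nrow(ev) > 1) {
    keep_start <- ev$start_s[1]; out <- NULL
    cur_end <- ev$end_s[1]
    for (i in 2:nrow(ev)) {
      if (ev$start_s[i] - cur_end < merge_gap_s) cur_end <- ev$end_s[i]
      else { out <- rbind(out, c(keep_start, cur_end))
             keep_start <- ev$start_s[i]; cur_end <- ev$end_s[i] }
    }
    out <- rbind(out, c(keep_start, cur_end))
    ev <- data.frame(start_s = out[, 1], end_s = out[, 2])
  }
  ev <- ev[ev$end_s - ev$start_s >= min_event_s, , drop = FALSE]
  ev$duration_min <- (ev$end_s - ev$start_s) / 60
  rownames(ev) <- NULL
  ev
}

#' Score predicted rumination events against ground truth
#'
#' Rasterises both event lists onto a window grid over the common span; a
#' window counts as rumination when at least half of it is covered by an
#' event. Sensitivity is `100 * TP / (TP + FN)`, positive predictive value
#' `100 * TP / (TP + FP)`; an empty truth makes sensitivity undefined
#' (`NA`).
#'
#' @param predicted,truth data.frames with `start_s`, `end_s` over the same
#'   cow-time span.
#' @param window_s evaluation window, seconds (default 30).
#' @param span numeric `c(from, to)`; default covers both event lists.
#' @return list of class `classification_report`: `sensitivity`, `ppv`
#'   (percent), `tp`, `fp`, `fn`, `tn`, `n_windows`.
#' @export
evaluate_events <- function(predicted, truth, window_s = 30, span = NULL) {
  if (is.null(span)) {
    lo <- suppressWarnings(min(predicted$start_s, truth$start_s, 0))
    hi <- suppressWarnings(max(predicted$end_s, truth$end_s, 0))
    span <- c(lo, hi)
  }
  n_w <- max(1, ceiling((span[2] - span[1]) / window_s))
  rasterize <- function(ev) {
    cov <- numeric(n_w)
    for (i in seq_len(nrow(ev))) {
      w0 <- max(1, floor((ev$start_s[i] - span[1]) / window_s) + 1)
      w1 <- min(n_w, ceiling((ev$end_s[i] - span[1]) / window_s))
      if (w1 < w0) next
      for (w in w0:w1) {
        ws <- span[1] + (w - 1) * window_s
        cov[w] <- cov[w] +
          max(0, min(ev$end_s[i], ws + window_s) - max(ev$start_s[i], ws))
      }
    }
    cov / window_s >= 0.5
  }
  p <- rasterize(predicted); t_ <- rasterize(truth)
  tp <- sum(p & t_); fp <- sum(p & !t_); fn <- sum(!p & t_)
  tn <- sum(!p & !t_)
  structure(list(
    sensitivity = if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn),
    ppv = if (tp + fp == 0) NA_real_ else 100 * tp / (tp + fp),
    tp = tp, fp = fp, fn = fn, tn = tn, n_windows = n_w),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> sensitivity %.1f%%, PPV %.1f%% (TP %d, FP %d, FN %d, TN %d)\n",
              x$sensitivity, x$ppv, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}
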