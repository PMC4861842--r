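# Linear mixed models with a single (possibly non-intercept) random term
# per grouping level, fitted by profiling the deviance over the variance
# ratio lambda = var(group) / var(residual). Each group's covariance is
# sigma^2 (I + lambda z z'), a rank-1 update, so likelihood evaluation is
# O(n) via Woodbury/Sherman-Morrison group blocks.

#' Fit a linear mixed model with one random term
#'
#' Supports the random-intercept-per-cow models used for daily
#' characteristics and the no-intercept random-slope model used at visit
#' level. Variance components are estimated by numerically profiled ML or
#' REML over the variance ratio; fixed effects are generalized least
#' squares at the optimum; conditional residuals use the predicted (BLUP)
#' group effects.
#'
#' @param fixed two-sided model formula for the fixed effects (use `~ 0 +
#'   ...` for no-intercept models).
#' @param data data.frame; rows with missing values in any used variable
#'   are dropped.
#' @param group name of the grouping column (e.g. `"cow_id"`).
#' @param random one-sided formula for the single random term: `~1` for a
#'   random intercept, `~0 + x` for a random slope on `x`.
#' @param method `"REML"` (default) or `"ML"`.
#' @return object of class `herd_lmm`: coefficients, SEs, `vcov`,
#'   variance components (`sigma2`, `sigma2_group`, `lambda`), `logLik`,
#'   `deviance`, `AIC`, `BIC` (ML-based), conditional `RSS`, BLUPs, and the
#'   ingredients needed for refits and least-square means.
#' @export
fit_lmm <- function(fixed, data, group, random = ~1,
                    method = c("REML", "ML")) {
  method <- match.arg(method)
  vars <- unique(c(all.vars(fixed), group, all.vars(random)))
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars))
    stop("variables not in data: ", paste(missing_vars, collapse = ", "))
  dat <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  if (nrow(dat) < 3) stop("too few complete rows")
  mf <- stats::model.frame(fixed, dat)
  y <- as.numeric(stats::model.response(mf))
  X <- stats::model.matrix(fixed, dat)
  # drop aliased columns
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- qrX$pivot[(qrX$rank + 1):ncol(X)]
    warning("dropping aliased fixed-effect column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, -drop, drop = FALSE]
  }
  z <- if (length(all.vars(random)) == 0) rep(1, nrow(dat))
  else {
    Zm <- stats::model.matrix(random, dat)
    if (ncol(Zm) != 1)
      stop("random must describe exactly one column (use ~1 or ~0 + x)")
    as.numeric(Zm[, 1])
  }
  g <- factor(dat[[group]])
  if (nlevels(g) < 2) stop("need at least 2 groups")
  fit <- lmm_engine(y, X, z, g, method)
  structure(c(fit, list(fixed = fixed, random = random, group = group,
                        method = method, data = dat, y = y, X = X, z = z,
                        g = g)),
            class = "herd_lmm")
}

# Core profiled fit given the design. Returns estimates and criteria.
lmm_engine <- function(y, X, z, g, method) {
  n <- length(y); p <- ncol(X)
  S <- rowsum(z * z, g)[, 1]
  Zy <- rowsum(z * y, g)[, 1]
  ZX <- rowsum(X * z, g)
  XtX <- crossprod(X); Xty <- crossprod(X, y)[, 1]; yty <- sum(y * y)
  reml <- method == "REML"

  eval_lambda <- function(lambda) {
    cvec <- lambda / (1 + lambda * S)
    A <- XtX - crossprod(ZX * sqrt(cvec))
    u <- Xty - crossprod(ZX, cvec * Zy)[, 1]
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) return(list(dev = Inf))
    beta <- backsolve(ch, forwardsolve(t(ch), u))
    w <- yty - sum(cvec * Zy^2) - sum(beta * u)
    w <- max(w, 1e-300)
    ld <- sum(log1p(lambda * S))
    if (reml) {
      ldA <- 2 * sum(log(diag(ch)))
      dev <- (n - p) * (log(2 * pi * w / (n - p)) + 1) + ld + ldA
      s2 <- w / (n - p)
    } else {
      dev <- n * (log(2 * pi * w / n) + 1) + ld
      s2 <- w / n
    }
    list(dev = dev, beta = beta, sigma2 = s2, w = w, chol = ch, cvec = cvec)
  }

  # coarse grid on log(lambda), refined by optimize(), boundary checked
  grid <- c(-Inf, seq(-10, 10, length.out = 41))
  devs <- vapply(grid, function(t) eval_lambda(if (is.finite(t)) exp(t) else 0)$dev,
                 numeric(1))
  devs[is.nan(devs)] <- Inf
  i <- which.min(devs)
  if (!length(i) || !is.finite(devs[i]))
    stop("mixed-model fit failed to converge: no finite deviance ",
         "(design not estimable with n = ", n, ", p = ", p, "?)")
  if (is.finite(grid[i])) {
    lo <- grid[max(2, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(function(t) eval_lambda(exp(t))$dev, c(lo, hi),
                           tol = 1e-9)
    lambda <- exp(opt$minimum)
    if (eval_lambda(0)$dev <= opt$objective) lambda <- 0
  } else lambda <- 0
  est <- eval_lambda(lambda)
  beta <- est$beta
  names(beta) <- colnames(X)
  Ainv <- chol2inv(est$chol)
  vcov <- est$sigma2 * Ainv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov))
  # BLUPs and conditional residuals
  r <- y - X %*% beta
  Zr <- rowsum(z * r[, 1], g)[, 1]
  blup <- lambda * Zr / (1 + lambda * S)
  resid_cond <- r[, 1] - blup[g] * z
  RSS <- sum(resid_cond^2)
  k <- p + 2
  logLik <- -est$dev / 2
  list(coefficients = beta, se = se, vcov = vcov,
       sigma2 = est$sigma2, sigma2_group = lambda * est$sigma2,
       lambda = lambda, logLik = logLik, deviance = est$dev,
       AIC = est$dev + 2 * k, BIC = est$dev + k * log(length(y)),
       RSS = RSS, blups = blup, resid_cond = resid_cond,
       fitted = y - resid_cond, n = n, p = p, df_model = k)
}

#' @export
print.herd_lmm <- function(x, digits = 4, ...) {
  cat("Linear mixed model (", x$method, "), ", x$n, " rows, ",
      nlevels(x$g), " groups (", x$group, ")\n", sep = "")
  cat("  fixed: ", deparse(x$fixed), "\n  random: ", deparse(x$random),
      "\n", sep = "")
  tab <- data.frame(Estimate = x$coefficients, SE = x$se)
  print(round(tab, digits))
  cat(sprintf("  var(%s) = %.4g, var(residual) = %.4g\n", x$group,
              x$sigma2_group, x$sigma2))
  cat(sprintf("  logLik = %.2f, AIC = %.1f, BIC = %.1f, RSS = %.4g\n",
              x$logLik, x$AIC, x$BIC, x$RSS))
  invisible(x)
}

#' @export
logLik.herd_lmm <- function(object, ...) {
  structure(object$logLik, df = object$df_model, nobs = object$n,
            class = "logLik")
}

#' @export
coef.herd_lmm <- function(object, ...) object$coefficients

#' @export
vcov.herd_lmm <- function(object, ...) object$vcov

# Refit an existing model with a different estimation method on the same
# rows (used by lrt, which needs ML likelihoods).
refit_lmm <- function(fit, method) {
  if (fit$method == method) return(fit)
  new <- lmm_engine(fit$y, fit$X, fit$z, fit$g, method)
  structure(c(new, list(fixed = fit$fixed, random = fit$random,
                        group = fit$group, method = method, data = fit$data,
                        y = fit$y, X = fit$X, z = fit$z, g = fit$g)),
            class = "herd_lmm")
}

#' Likelihood-ratio test of nested mixed models
#'
#' Twice the ML log-likelihood difference against a chi-square with as many
#' degrees of freedom as the difference in fixed-effect count. REML fits
#' are automatically refitted with ML (REML likelihoods are not comparable
#' across fixed structures). Errors if the models are not nested or were
#' not fitted to identical rows.
#'
#' @param full,reduced `herd_lmm` fits; `reduced` nested in `full`.
#' @return list of class `herd_lrt`: `statistic`, `df`, `p_value`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "herd_lmm"), inherits(reduced, "herd_lmm"))
  if (full$n != reduced$n || !isTRUE(all.equal(full$y, reduced$y)))
    stop("models were not fitted to identical rows")
  df <- full$p - reduced$p
  if (df < 0) stop("'full' has fewer fixed effects than 'reduced'")
  # nesting: reduced columns must lie in the column space of the full X
  proj <- qr.resid(qr(full$X), reduced$X)
  if (max(abs(proj)) > 1e-6 * max(1, max(abs(reduced$X))))
    stop("models are not nested")
  fm <- refit_lmm(full, "ML"); rm_ <- refit_lmm(reduced, "ML")
  stat <- 2 * (fm$logLik - rm_$logLik)
  if (stat < -1e-6) warning("negative LRT statistic beyond tolerance; ",
                            "check convergence")
  stat <- max(stat, 0)
  structure(list(statistic = stat, df = df,
                 p_value = if (df == 0) 1 else
                   stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "herd_lrt")
}

#' @export
print.herd_lrt <- function(x, ...) {
  cat(sprintf("LRT: chisq = %.3f, df = %d, p = %.4g\n", x$statistic, x$df,
              x$p_value))
  invisible(x)
}

#' Residual-sum-of-squares R-squared
#'
#' `R^2 = (RSS_null - RSS_fit) / RSS_null`, with RSS the sum of squared
#' conditional residuals and the null model containing only the intercept
#' and the random group effect.
#'
#' @param fit,null_fit `herd_lmm` objects on the same rows and response.
#' @return numeric R-squared (NA when the null RSS is zero).
#' @export
rss_r2 <- function(fit, null_fit) {
  if (fit$n != null_fit$n || !isTRUE(all.equal(fit$y, null_fit$y)))
    stop("fits are not on the same rows/response")
  if (null_fit$RSS <= 0) return(NA_real_)
  (null_fit$RSS - fit$RSS) / null_fit$RSS
}

#' Least-square means for a factor
#'
#' Model predictions per factor level with all continuous covariates held
#' at their means over the fitted rows (interactions evaluated at level x
#' covariate mean), random effects at zero; standard errors from the
#' coefficient covariance.
#'
#' @param fit a `herd_lmm`.
#' @param factor name of a (logical or factor) fixed-effect variable.
#' @return data.frame `level`, `lsm`, `se`.
#' @export
lsm <- function(fit, factor = "lame") {
  if (!factor %in% names(fit$data))
    stop("'", factor, "' is not a model variable")
  x <- fit$data[[factor]]
  levels <- if (is.logical(x)) c(FALSE, TRUE) else
    if (is.factor(x)) levels(x) else sort(unique(x))
  out <- lapply(levels, function(lev) {
    nd <- fit$data
    nd[[factor]] <- if (is.factor(x)) base::factor(lev, levels = levels(x)) else lev
    Xn <- stats::model.matrix(fit$fixed, nd)
    Xn <- Xn[, colnames(fit$X), drop = FALSE]
    cvec <- colMeans(Xn)
    data.frame(level = lev,
               lsm = sum(cvec * fit$coefficients),
               se = sqrt(drop(t(cvec) %*% fit$vcov %*% cvec)))
  })
  do.call(rbind, out)
}

#' Stepwise elimination of non-significant interactions
#'
#' Starting from the highest order, iteratively removes the non-significant
#' interaction term with the largest likelihood-ratio p-value (respecting
#' marginality: a term contained in a retained higher-order term is never a
#' candidate) until every remaining interaction is significant or none
#' remain. Main effects are never dropped.
#'
#' @param fixed starting fixed-effect formula (with interactions).
#' @param data,group,random as in [fit_lmm()].
#' @param alpha significance threshold (default 0.05).
#' @return list: `fixed` (final formula), `fit` (final REML fit), `path`
#'   (data.frame logging every tested drop).
#' @export
reduce_interactions <- function(fixed, data, group, random = ~1,
                                alpha = 0.05) {
  response <- deparse(fixed[[2]])
  tt <- stats::terms(fixed)
  labels <- attr(tt, "term.labels")
  intercept <- attr(tt, "intercept") == 1
  path <- list()
  repeat {
    ords <- vapply(strsplit(labels, ":", fixed = TRUE), length, integer(1))
    inters <- labels[ords >= 2]
    if (!length(inters)) break
    contained <- function(a, b) all(strsplit(a, ":", fixed = TRUE)[[1]] %in%
                                      strsplit(b, ":", fixed = TRUE)[[1]])
    droppable <- inters[vapply(inters, function(a)
      !any(vapply(setdiff(labels, a), function(b)
        length(strsplit(b, ":", fixed = TRUE)[[1]]) >
          length(strsplit(a, ":", fixed = TRUE)[[1]]) && contained(a, b),
        logical(1))), logical(1))]
    if (!length(droppable)) break
    form_full <- stats::reformulate(labels, response, intercept = intercept)
    environment(form_full) <- environment(fixed)
    fit_full <- fit_lmm(form_full, data, group, random, method = "ML")
    ps <- vapply(droppable, function(tm) {
      form_red <- stats::reformulate(setdiff(labels, tm), response,
                                     intercept = intercept)
      environment(form_red) <- environment(fixed)
      lrt(fit_full, fit_lmm(form_red, data, group, random, method = "ML"))$p_value
    }, numeric(1))
    for (j in seq_along(droppable))
      path[[length(path) + 1]] <- data.frame(term = droppable[j],
                                             p_value = ps[j])
    nonsig <- which(ps > alpha)
    if (!length(nonsig)) break
    cand_ord <- vapply(strsplit(droppable[nonsig], ":", fixed = TRUE),
                       length, integer(1))
    pick <- nonsig[cand_ord == max(cand_ord)]
    pick <- pick[which.max(ps[pick])]
    path[[length(path)]]$dropped <- TRUE
    labels <- setdiff(labels, droppable[pick])
  }
  final <- stats::reformulate(labels, response, intercept = intercept)
  environment(final) <- environment(fixed)
  path_df <- if (length(path)) {
    pd <- do.call(rbind, lapply(path, function(d) {
      if (is.null(d$dropped)) d$dropped <- FALSE
      d
    }))
    rownames(pd) <- NULL; pd
  } else data.frame(term = character(0), p_value = numeric(0),
                    dropped = logical(0))
  list(fixed = final, fit = fit_lmm(final, data, group, random, "REML"),
       path = path_df)
}

#' Fit and rank a family of models on identical rows
#'
#' Fits each candidate fixed-effect structure by ML on the common
#' complete-case row set of all candidates, and reports RSS, R-squared
#' (against the intercept + random-group null), AIC and BIC, sorted by
#' decreasing RSS.
#'
#' @param specs named list of fixed-effect formulas.
#' @param data,group,random as in [fit_lmm()].
#' @return data.frame `name`, `RSS`, `R2`, `AIC`, `BIC` (class
#'   `herd_model_table`), sorted by decreasing RSS.
#' @export
compare_models <- function(specs, data, group, random = ~1) {
  stopifnot(is.list(specs), length(specs) >= 1)
  if (is.null(names(specs)) || any(names(specs) == ""))
    names(specs) <- paste0("M", seq_along(specs))
  vars <- unique(c(unlist(lapply(specs, all.vars)), group, all.vars(random)))
  cc <- data[stats::complete.cases(data[vars]), , drop = FALSE]
  response <- deparse(specs[[1]][[2]])
  null_form <- stats::as.formula(paste(response, "~ 1"))
  environment(null_form) <- environment(specs[[1]])
  null_fit <- fit_lmm(null_form, cc, group, random, method = "ML")
  rows <- lapply(names(specs), function(nm) {
    f <- fit_lmm(specs[[nm]], cc, group, random, method = "ML")
    if (f$n != null_fit$n) stop("row-set mismatch for model ", nm)
    data.frame(name = nm, RSS = f$RSS, R2 = rss_r2(f, null_fit),
               AIC = f$AIC, BIC = f$BIC, n = f$n)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$RSS), ]
  rownames(out) <- NULL
  class(out) <- c("herd_model_table", "data.frame")
  out
}
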