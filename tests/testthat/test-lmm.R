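# Mixed-model engine: oracle equivalence (lme4, direct multivariate-normal
# density, closed-form ANOVA), inference tools, LSM, stepwise reduction.

test_that("REML and ML fits match lme4 on random-intercept data", {
  skip_if_not_installed("lme4")
  d <- ri_data(12, 8, seed = 7)
  fit <- fit_lmm(y ~ x + f, d, group = "g", method = "REML")
  ref <- lme4::lmer(y ~ x + f + (1 | g), d, REML = TRUE)
  expect_equal(fit$logLik, as.numeric(stats::logLik(ref)), tolerance = 1e-8)
  expect_equal(unname(coef(fit)), unname(lme4::fixef(ref)),
               tolerance = 1e-7)
  expect_equal(unname(fit$se), unname(sqrt(diag(as.matrix(vcov(ref))))),
               tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(ref))$vcov
  expect_equal(c(fit$sigma2_group, fit$sigma2), vc, tolerance = 1e-6)

  fitm <- fit_lmm(y ~ x + f, d, group = "g", method = "ML")
  refm <- lme4::lmer(y ~ x + f + (1 | g), d, REML = FALSE)
  expect_equal(fitm$logLik, as.numeric(stats::logLik(refm)),
               tolerance = 1e-8)
  expect_equal(fitm$AIC, stats::AIC(refm), tolerance = 1e-6)
  expect_equal(fitm$BIC, stats::BIC(refm), tolerance = 1e-6)
})

test_that("no-intercept random-slope fits match lme4", {
  skip_if_not_installed("lme4")
  withr::with_seed(21, {
    d <- data.frame(g = rep(1:10, each = 12), x = runif(120, 0.5, 8))
    d$y <- (3 + rep(rnorm(10, 0, 0.8), each = 12)) * d$x +
      rnorm(120, 0, 0.5)
  })
  fit <- fit_lmm(y ~ 0 + x, d, group = "g", random = ~ 0 + x)
  ref <- lme4::lmer(y ~ 0 + x + (0 + x | g), d, REML = TRUE)
  expect_equal(unname(coef(fit)), unname(lme4::fixef(ref)),
               tolerance = 1e-6)
  expect_equal(fit$logLik, as.numeric(stats::logLik(ref)), tolerance = 1e-8)
  vc <- as.data.frame(lme4::VarCorr(ref))$vcov
  expect_equal(c(fit$sigma2_group, fit$sigma2), vc, tolerance = 1e-5)
})

test_that("likelihood agrees with a direct multivariate-normal evaluation", {
  d <- ri_data(5, 5, seed = 3)[1:24, ]
  for (method in c("ML", "REML")) {
    fit <- fit_lmm(y ~ x, d, group = "g", method = method)
    X <- cbind(1, d$x)
    V <- diag(nrow(d)) * fit$sigma2
    for (g in unique(d$g)) {
      i <- which(d$g == g)
      V[i, i] <- V[i, i] + fit$sigma2_group
    }
    r <- d$y - X %*% coef(fit)
    ll <- -0.5 * (nrow(d) * log(2 * pi) +
                    as.numeric(determinant(V)$modulus) +
                    drop(t(r) %*% solve(V, r)))
    if (method == "ML") {
      expect_equal(fit$logLik, ll, tolerance = 1e-7)
    } else {
      # REML adds the fixed-effect integration term
      llr <- ll - 0.5 * as.numeric(determinant(
        t(X) %*% solve(V, X))$modulus) + 0.5 * ncol(X) * log(2 * pi)
      expect_equal(fit$logLik, llr, tolerance = 1e-6)
    }
  }
})

test_that("balanced one-way data reproduces closed-form ANOVA estimators", {
  a <- 8; n <- 6
  withr::with_seed(31, {
    d <- data.frame(g = rep(1:a, each = n))
    d$y <- 10 + rep(rnorm(a, 0, 2), each = n) + rnorm(a * n, 0, 1)
  })
  fit <- fit_lmm(y ~ 1, d, group = "g", method = "REML")
  gm <- tapply(d$y, d$g, mean)
  msb <- n * stats::var(gm)
  msw <- sum((d$y - gm[d$g])^2) / (a * (n - 1))
  expect_equal(fit$sigma2, msw, tolerance = 1e-5)
  expect_equal(fit$sigma2_group, (msb - msw) / n, tolerance = 1e-5)
  expect_equal(unname(coef(fit)), mean(gm), tolerance = 1e-8)
})

test_that("zero between-group variance collapses to ordinary least squares", {
  withr::with_seed(41, {
    d <- data.frame(g = rep(1:10, each = 10), x = rnorm(100))
    d$y <- 1 + 2 * d$x + rnorm(100)      # no group effect at all
  })
  fit <- fit_lmm(y ~ x, d, group = "g", method = "REML")
  ols <- stats::lm(y ~ x, d)
  expect_lt(fit$sigma2_group / fit$sigma2, 0.05)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 0.02)
  if (fit$lambda == 0)
    expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-8)
})

test_that("REML and ML converge as the number of groups grows", {
  withr::with_seed(51, {
    d <- data.frame(g = rep(1:200, each = 5), x = rnorm(1000))
    d$y <- 2 + d$x + rep(rnorm(200, 0, 1), each = 5) + rnorm(1000, 0, 1)
  })
  fr <- fit_lmm(y ~ x, d, group = "g", method = "REML")
  fm <- fit_lmm(y ~ x, d, group = "g", method = "ML")
  expect_equal(fr$sigma2_group, fm$sigma2_group, tolerance = 0.02)
  expect_equal(fr$sigma2, fm$sigma2, tolerance = 0.02)
  expect_equal(coef(fr), coef(fm), tolerance = 0.02)
})

test_that("aliased fixed-effect columns are dropped with a warning", {
  d <- ri_data(6, 6, seed = 61)
  d$x2 <- d$x
  expect_warning(fit <- fit_lmm(y ~ x + x2, d, group = "g"), "aliased")
  expect_equal(length(coef(fit)), 2)
})

test_that("LRT: identical models give statistic 0 and p = 1; oracle statistic", {
  d <- ri_data(10, 6, seed = 71)
  f1 <- fit_lmm(y ~ x + f, d, group = "g", method = "ML")
  f0 <- fit_lmm(y ~ x, d, group = "g", method = "ML")
  same <- lrt(f1, fit_lmm(y ~ x + f, d, group = "g", method = "ML"))
  expect_equal(same$statistic, 0, tolerance = 1e-8)
  expect_equal(same$p_value, 1)

  out <- lrt(f1, f0)
  expect_equal(out$statistic, 2 * (f1$logLik - f0$logLik))
  expect_equal(out$df, 1)
  expect_equal(out$p_value,
               stats::pchisq(out$statistic, 1, lower.tail = FALSE))
  # REML fits are refitted with ML automatically and give the same test
  r1 <- fit_lmm(y ~ x + f, d, group = "g", method = "REML")
  r0 <- fit_lmm(y ~ x, d, group = "g", method = "REML")
  expect_equal(lrt(r1, r0)$statistic, out$statistic, tolerance = 1e-7)

  d$z <- rnorm(nrow(d))
  expect_error(lrt(f0, fit_lmm(y ~ z, d, group = "g", method = "ML")),
               "not nested")
  expect_error(lrt(f1, fit_lmm(y ~ x, d[1:50, ], group = "g",
                               method = "ML")), "identical rows")
})

test_that("RSS R-squared follows its definition and a residual oracle", {
  d <- ri_data(8, 8, seed = 81)
  fit <- fit_lmm(y ~ x + f, d, group = "g")
  null_fit <- fit_lmm(y ~ 1, d, group = "g")
  expect_equal(rss_r2(null_fit, null_fit), 0)
  r2 <- rss_r2(fit, null_fit)
  expect_equal(r2, (null_fit$RSS - fit$RSS) / null_fit$RSS)
  # conditional residual oracle: y - X beta - z * blup
  res <- d$y - fit$X %*% coef(fit) -
    fit$blups[as.character(fit$g)] * fit$z
  expect_equal(fit$RSS, sum(res^2), tolerance = 1e-8)
  # a perfect-fit model has R^2 ~ 1
  d$yy <- 1 + 2 * d$x
  perfect <- fit_lmm(yy ~ x, d, group = "g")
  null2 <- fit_lmm(yy ~ 1, d, group = "g")
  expect_gt(rss_r2(perfect, null2), 0.999999)
})

test_that("least-square means equal group means on balanced factor-only data", {
  withr::with_seed(91, {
    d <- data.frame(g = rep(1:10, each = 8),
                    lame = rep(c(FALSE, TRUE), each = 40))
    d$y <- 5 + 3 * d$lame + rep(rnorm(10, 0, 0.01), each = 8) +
      rnorm(80, 0, 0.01)
  })
  fit <- fit_lmm(y ~ lame, d, group = "g")
  ls <- lsm(fit, "lame")
  expect_equal(ls$lsm, as.numeric(tapply(d$y, d$lame, mean)),
               tolerance = 0.02)
  # adding a centred covariate leaves the LSM difference unchanged
  d$x <- rnorm(80); d$x <- d$x - mean(d$x)
  fit2 <- fit_lmm(y ~ lame + x, d, group = "g")
  ls2 <- lsm(fit2, "lame")
  expect_equal(diff(ls$lsm), diff(ls2$lsm), tolerance = 1e-3)
  expect_error(lsm(fit, "absent"), "not a model variable")
})

test_that("stepwise reduction drops null interactions and keeps real ones", {
  d0 <- ri_data(10, 10, seed = 101)          # y has no f:x interaction
  red <- reduce_interactions(y ~ x * f, d0, group = "g")
  expect_identical(attr(stats::terms(red$fixed), "term.labels"),
                   c("x", "f"))
  expect_true(any(red$path$dropped))

  plain <- reduce_interactions(y ~ x + f, d0, group = "g")
  expect_identical(attr(stats::terms(plain$fixed), "term.labels"),
                   c("x", "f"))
  expect_equal(nrow(plain$path), 0)

  # a real interaction survives
  d1 <- d0; d1$y <- d1$y + 3 * d1$x * d1$f
  kept <- reduce_interactions(y ~ x * f, d1, group = "g")
  expect_true("x:f" %in% attr(stats::terms(kept$fixed), "term.labels"))
})

test_that("the generator's lame-by-DIM effect on per-visit intake is retained", {
  # the lame group's visit frequency drifts with DIM, so mean intake per
  # visit carries a true lameness-by-DIM interaction the reducer must keep
  barn <- simulate_barn(barn_config(seed = 3))
  d <- daily_summaries(barn$visits, barn$rumination, barn$milk, barn$cohort)
  red <- reduce_interactions(mvFMI ~ lame * dim, d, group = "cow_id")
  expect_true("lame:dim" %in% attr(stats::terms(red$fixed), "term.labels"))
})

test_that("model comparison fits on identical rows and sorts by RSS", {
  barn <- simulate_barn(barn_config(seed = 1))
  d <- daily_summaries(barn$visits, barn$rumination, barn$milk, barn$cohort)
  specs <- list("null+" = dRUMtime ~ lame,
                "rate" = dRUMtime ~ dFR,
                "milk" = dRUMtime ~ dMY,
                "three" = dRUMtime ~ dMY + lame + dFR)
  tab <- compare_models(specs, d, group = "cow_id")
  expect_true(all(diff(tab$RSS) <= 0))
  expect_equal(length(unique(tab$n)), 1)     # identical row sets
  # nesting: the richer model never has larger RSS than its submodels
  expect_lte(tab$RSS[tab$name == "three"],
             min(tab$RSS[tab$name %in% c("null+", "rate", "milk")]))
  expect_gte(tab$R2[tab$name == "three"],
             max(tab$R2[tab$name %in% c("null+", "rate", "milk")]))
})
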