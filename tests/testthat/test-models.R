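test_that("a variance-free LMM reproduces ordinary least squares", {
  d <- sim_lmm_data(6, 24, beta = c(0.5, 0.3, -0.2, 0.1, 0, 0, 0, 0),
                    tau_p = 0, tau_i = 0, sigma = 1, seed = 2)
  fit <- suppressMessages(fit_lmm_dv(d, "dv"))
  ols <- stats::lm(dv ~ ssim * type2 * response, d)
  expect_true(is_singular_fit(fit))
  b <- fit$estimates$b
  names(b) <- fit$estimates$term
  expect_equal(b, stats::coef(ols), tolerance = 1e-6)
})

test_that("singularity fallback drops the item intercept once and records it", {
  d <- sim_lmm_data(10, 24, beta = c(0.2, 0.3, 0, 0, 0, 0, 0, 0),
                    tau_p = 0.6, tau_i = 0, sigma = 1, seed = 3)
  fit <- suppressMessages(fit_lmm_dv(d, "dv"))
  expect_true(is_singular_fit(fit))
  fb <- suppressMessages(fallback_on_singularity(fit, d))
  expect_identical(fb$provenance$random, "participant")
  expect_true(fb$provenance$fallback)
  # participant variance is essentially unchanged by dropping a zero
  # item component
  expect_equal(unname(fb$varcomp["participant"]),
               unname(fit$varcomp["participant"]), tolerance = 0.05)
  # at most one fallback: a second call is the identity
  expect_identical(fallback_on_singularity(fb, d), fb)
  # a healthy fit passes through untouched
  d2 <- sim_lmm_data(10, 24, tau_p = 0.6, tau_i = 0.5, sigma = 0.8,
                     seed = 4)
  fit2 <- fit_lmm_dv(d2, "dv")
  expect_false(is_singular_fit(fit2))
  expect_identical(fallback_on_singularity(fit2, d2), fit2)
})

test_that("model criticism removes planted gross outliers and only refits once", {
  d <- sim_lmm_data(8, 30, tau_p = 0.4, tau_i = 0.3, sigma = 1,
                    seed = 5)
  planted <- c(11, 101, 180)
  d$dv[planted] <- d$dv[planted] + 10  # ~10 residual SD
  fit <- fit_lmm_dv(d, "dv")
  cr <- model_criticism(fit, d)
  expect_true(all(planted %in% cr$removed))
  expect_identical(cr$fit$provenance$criticism_removed, cr$removed)
  expect_equal(stats::nobs(cr$fit$fit), nrow(d) - length(cr$removed))
  # clean, well-behaved data: nothing to remove, fit returned as-is
  d2 <- sim_lmm_data(4, 12, sigma = 1, seed = 6)
  d2$dv <- round(d2$dv / 10, 1)  # residuals well inside 2.5 SD
  fit2 <- suppressMessages(fit_lmm_dv(d2, "dv"))
  cr2 <- model_criticism(fit2, d2, threshold = 10)
  expect_length(cr2$removed, 0)
  expect_equal(cr2$fit$estimates$b, fit2$estimates$b)
})

test_that("simple slopes collapse to the marginal slope without interactions", {
  d <- sim_lmm_data(8, 24, beta = c(0, 0.4, 0, 0, 0, 0, 0, 0),
                    tau_p = 0.5, tau_i = 0.3, seed = 7)
  fit <- fit_lmm_dv(d, "dv", fixed = "ssim + type2 + response")
  sl <- simple_slopes(fit)
  expect_equal(nrow(sl), 4L)
  marg <- fit$estimates$b[fit$estimates$term == "ssim"]
  expect_equal(sl$b, rep(marg, 4), tolerance = 1e-12)
})

test_that("contrast-based slopes equal releveled refits and per-cell truth", {
  beta <- c(0, 0.5, 0.2, -0.1, -0.4, 0.3, 0.25, 0.6)
  d <- sim_lmm_data(12, 40, beta = beta, tau_p = 0.5, tau_i = 0.3,
                    sigma = 0.7, seed = 8)
  fit <- fit_lmm_dv(d, "dv")
  sl <- simple_slopes(fit)
  # releveled refit: make "old"/"old" the reference cell
  d2 <- d
  d2$type2 <- stats::relevel(d2$type2, "old")
  d2$response <- stats::relevel(d2$response, "old")
  fit2 <- fit_lmm_dv(d2, "dv")
  b_oo <- fit2$estimates$b[fit2$estimates$term == "ssim"]
  got <- sl$b[sl$type2 == "old" & sl$response == "old"]
  expect_equal(got, b_oo, tolerance = 1e-8)
  # the design-implied true slopes are recovered within 4 SE
  truth <- c(beta[2], beta[2] + beta[5], beta[2] + beta[6],
             beta[2] + beta[5] + beta[6] + beta[8])
  key <- paste(sl$type2, sl$response)
  ord <- match(c("old new", "new old", "old old"), key)
  expect_lt(abs(sl$b[key == "new new"] - truth[1]),
            4 * sl$se[key == "new new"])
  for (i in 1:3)
    expect_lt(abs(sl$b[ord[i]] - truth[i + 1]), 4 * sl$se[ord[i]])
})

test_that("the response GLMM estimates and flags behave on degenerate input", {
  # perfectly separable toy data: must flag, not crash
  d <- data.frame(
    participant = factor(rep(1:4, each = 12)),
    item = factor(rep(1:12, 4)),
    ssim = rep(seq(-1, 1, length.out = 12), 4),
    type2 = factor("new", levels = c("new", "old")))
  d$response_coded <- as.integer(d$ssim > 0)
  fit <- suppressMessages(suppressWarnings(
    fit_glmm_response(d, fixed = "ssim")))
  expect_s3_class(fit, "mixed_fit")
  expect_true(fit$singular || !fit$converged ||
                any(fit$estimates$se > 10))
})

test_that("pseudo-R2 is a variance ratio in [0, 1] with the logit residual", {
  d <- sim_lmm_data(10, 24, beta = c(0, 0.8, 0, 0, 0, 0, 0, 0),
                    tau_p = 0.6, tau_i = 0.4, sigma = 1, seed = 9)
  fit <- fit_lmm_dv(d, "dv")
  r2 <- pseudo_r2(fit)
  expect_gt(r2, 0); expect_lt(r2, 1)
  # hand recomputation from the fitted components
  vf <- stats::var(as.vector(lme4::getME(fit$fit, "X") %*%
                               lme4::fixef(fit$fit)))
  vr <- sum(as.data.frame(lme4::VarCorr(fit$fit))$vcov[1:2])
  expect_equal(r2, (vf + vr) / (vf + vr + stats::sigma(fit$fit)^2),
               tolerance = 1e-10)
  # binomial: residual variance is pi^2/3, so R2 < 1 even when saturated
  d$response_coded <- rbinom(nrow(d), 1, stats::plogis(d$ssim))
  fitb <- suppressMessages(suppressWarnings(fit_glmm_response(d)))
  expect_gt(fitb$pseudo_r2_total, 0)
  expect_lt(fitb$pseudo_r2_total, 1)
})

test_that("observed power counts rejections with a binomial interval", {
  # large planted effect: near-certain rejection even with few sims
  d <- sim_lmm_data(10, 32, beta = c(0, 0.2, 0, 0, 0, 0, 0, 1.2),
                    tau_p = 0.3, tau_i = 0.2, sigma = 0.6, seed = 10)
  fit <- fit_lmm_dv(d, "dv")
  pw <- observed_power(fit, d, n_sims = 25, seed = 42)
  expect_equal(pw$n_converged + pw$n_failed, 25)
  expect_gte(pw$power, 0.8)
  expect_true(pw$ci[1] <= pw$power && pw$power <= pw$ci[2])
})

test_that("descriptives and correlations match direct formulas", {
  set.seed(11)
  tb <- data.frame(initiation_rt = rexp(200, 1 / 300),
                   md = rnorm(200, 0.2, 0.1),
                   sample_entropy = rexp(200, 2),
                   md_time = runif(200, 400, 1400))
  dd <- dv_descriptives(tb)
  expect_equal(dd$df, 198L)
  expect_equal(dd$descriptives$mean[2], mean(tb$md))
  r_manual <- sum((tb$md - mean(tb$md)) *
                    (tb$sample_entropy - mean(tb$sample_entropy))) /
    sqrt(sum((tb$md - mean(tb$md))^2) *
           sum((tb$sample_entropy - mean(tb$sample_entropy))^2))
  expect_equal(dd$correlations["md", "sample_entropy"], r_manual,
               tolerance = 1e-12)
  # duplicated column correlates at exactly 1
  tb2 <- tb; tb2$md_time <- tb2$md
  expect_equal(dv_descriptives(tb2)$correlations["md", "md_time"], 1)
  # constant column flagged, correlations NA
  tb3 <- tb; tb3$sample_entropy <- 0.5
  dd3 <- dv_descriptives(tb3)
  expect_identical(dd3$constant, "sample_entropy")
  expect_true(all(is.na(dd3$correlations["sample_entropy",
                                         c("md", "md_time")])))
})
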