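#' Mixed-model fits with crossed random intercepts
#'
#' All confirmatory models in the pipeline share one structure: fixed
#' effects built from SSim, stimulus type (`type2`: new vs. old truth)
#' and the participant's response, with crossed random intercepts for
#' participant and item.  Explicit old/new judgements are fit with a
#' binomial-logit GLMM (Laplace approximation); the four
#' decision-dynamics DVs with Gaussian LMMs by REML, with
#' Satterthwaite-type denominator degrees of freedom for t and F tests.
#'
#' `fit_glmm_response()` fits
#' `response_coded ~ ssim * type2 + (1|participant) + (1|item)`;
#' `fit_lmm_dv()` fits
#' `dv ~ ssim * type2 * response + (1|participant) + (1|item)`
#' (or the random structure given in `random`).
#'
#' @param table a [build_model_table()] data frame.
#' @param fixed right-hand-side of the fixed part, as a string.
#' @param random character vector of random-intercept grouping factors,
#'   a nonempty subset of `c("participant", "item")`.
#' @param control an optional `glmerControl()`/`lmerControl()` object.
#' @return An object of class `mixed_fit`: list with the underlying
#'   `merMod` in `$fit`, the coefficient table in `$estimates`, variance
#'   components in `$varcomp`, flags `$singular` and `$converged`,
#'   `$pseudo_r2_total`, and a `$provenance` record (random structure,
#'   fallback and criticism events, estimator names).
#' @export
fit_glmm_response <- function(table, fixed = "ssim * type2",
                              random = c("participant", "item"),
                              control = NULL) {
  fit_mixed(model_spec(dv = "response_coded", fixed = fixed,
                       random = random, family = "binomial"),
            table, control = control)
}

#' @rdname fit_glmm_response
#' @param dv name of the dependent-variable column (`md`,
#'   `log_entropy`, `log_init_rt`, `log_mdtime`, ...).
#' @param df_method `"satterthwaite"` (the confirmatory default) or
#'   `"residual"` (a cheaper n - p fallback, recorded in provenance).
#' @export
fit_lmm_dv <- function(table, dv, fixed = "ssim * type2 * response",
                       random = c("participant", "item"),
                       control = NULL,
                       df_method = c("satterthwaite", "residual")) {
  fit_mixed(model_spec(dv = dv, fixed = fixed, random = random,
                       family = "gaussian"),
            table, control = control, df_method = df_method)
}

#' @rdname fit_glmm_response
#' @param family `"gaussian"` or `"binomial"` (logit link).
#' @export
model_spec <- function(dv, fixed, random = c("participant", "item"),
                       family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  if (length(random) == 0L)
    stop("at least one random-intercept factor is required", call. = FALSE)
  list(dv = dv, fixed = fixed, random = random, family = family)
}

spec_formula <- function(spec) {
  stats::as.formula(paste(
    spec$dv, "~", spec$fixed, "+",
    paste(sprintf("(1 | %s)", spec$random), collapse = " + ")),
    env = globalenv())
}

#' @rdname fit_glmm_response
#' @param spec a [model_spec()].
#' @param reml fit Gaussian models by REML (the confirmatory default);
#'   set `FALSE` for likelihood-ratio comparisons.
#' @param singular_tol relative variance-component tolerance below which
#'   a fit is flagged singular.
#' @export
fit_mixed <- function(spec, table, control = NULL, reml = TRUE,
                      singular_tol = 1e-6,
                      df_method = c("satterthwaite", "residual")) {
  df_method <- match.arg(df_method)
  form <- spec_formula(spec)
  msgs <- character(0)
  fit <- withCallingHandlers(
    if (spec$family == "binomial") {
      lme4::glmer(form, data = table, family = stats::binomial(),
                  control = control %||% lme4::glmerControl())
    } else if (df_method == "satterthwaite") {
      lmerTest::lmer(form, data = table, REML = reml,
                     control = control %||% lme4::lmerControl())
    } else {
      lme4::lmer(form, data = table, REML = reml,
                 control = control %||% lme4::lmerControl())
    },
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  as_mixed_fit(fit, spec, msgs, singular_tol = singular_tol,
               df_method = df_method)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fit_df_method <- function(fit) {
  if (fit$spec$family == "gaussian" &&
      identical(fit$provenance$df_method, "residual")) "residual"
  else "satterthwaite"
}

as_mixed_fit <- function(fit, spec, msgs = character(0),
                         singular_tol = 1e-6, provenance = list(),
                         df_method = "satterthwaite") {
  est <- as.data.frame(stats::coef(summary(fit)))
  if (spec$family == "binomial") {
    names(est) <- c("b", "se", "z", "p")[seq_len(ncol(est))]
  } else if (ncol(est) == 5L) {
    names(est) <- c("b", "se", "df", "t", "p")
  } else {
    # plain lme4 fit: residual-df fallback
    names(est) <- c("b", "se", "t")
    est$df <- stats::nobs(fit) - length(lme4::fixef(fit))
    est$p <- 2 * stats::pt(-abs(est$t), est$df)
    est <- est[c("b", "se", "df", "t", "p")]
  }
  est$term <- rownames(est); rownames(est) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  converged <- !any(grepl("failed to converge|convergence",
                          c(msgs, unlist(fit@optinfo$conv$lme4$messages)),
                          ignore.case = TRUE))
  structure(list(
    fit = fit, spec = spec, estimates = est,
    varcomp = stats::setNames(vc$vcov, ifelse(is.na(vc$grp), "residual",
                                              vc$grp)),
    singular = lme4::isSingular(fit, tol = singular_tol),
    converged = converged,
    pseudo_r2_total = pseudo_r2(fit),
    messages = msgs,
    provenance = utils::modifyList(list(
      random = spec$random, family = spec$family,
      df_method = if (spec$family == "gaussian") df_method else "wald_z",
      pseudo_r2_method = "nakagawa_conditional",
      fallback = FALSE, criticism_removed = integer(0)), provenance)),
    class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat("<mixed_fit> ", x$spec$dv, " ~ ", x$spec$fixed, " + ",
      paste(sprintf("(1|%s)", x$spec$random), collapse = " + "),
      "  [", x$spec$family, "]\n", sep = "")
  cat("  n = ", stats::nobs(x$fit),
      if (x$singular) "  (singular)" else "",
      if (!x$converged) "  (convergence warning)" else "", "\n", sep = "")
  print(x$estimates, digits = 3)
  cat("  pseudo-R2 (total) = ", round(x$pseudo_r2_total, 3), "\n", sep = "")
  invisible(x)
}

#' @rdname fit_glmm_response
#' @param x a `mixed_fit`.
#' @export
estimates <- function(x) x$estimates

#' @rdname fit_glmm_response
#' @export
is_singular_fit <- function(x) isTRUE(x$singular)

#' Total pseudo-R-squared of a mixed model
#'
#' The conditional coefficient of determination in the
#' Nakagawa-Schielzeth sense: variance explained by fixed plus random
#' effects over total variance, with the distribution-specific residual
#' variance (`pi^2/3` on the latent scale for the binomial-logit model).
#'
#' @param fit a `merMod` or `mixed_fit`.
#' @return Value in `[0, 1]`.
#' @export
pseudo_r2 <- function(fit) {
  if (inherits(fit, "mixed_fit")) fit <- fit$fit
  var_f <- stats::var(as.vector(
    lme4::getME(fit, "X") %*% lme4::fixef(fit)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_re <- sum(vc$vcov[!is.na(vc$grp) & vc$grp != "Residual"])
  var_res <- if (inherits(fit, "glmerMod")) pi^2 / 3
             else stats::sigma(fit)^2
  (var_f + var_re) / (var_f + var_re + var_res)
}

#' Refit with a simplified random structure after a singular fit
#'
#' When a variance component is estimated at the zero boundary
#' (singular fit), the random structure is simplified by removing the
#' item intercept and the model refitted; the event is recorded in the
#' fit's provenance.  Non-singular fits are returned unchanged.
#'
#' @param fit a `mixed_fit`.
#' @param table the modelling table the fit was estimated on.
#' @param control optional fitting control.
#' @return A `mixed_fit`; at most one fallback is ever applied.
#' @export
fallback_on_singularity <- function(fit, table, control = NULL) {
  if (!is_singular_fit(fit)) return(fit)
  if (isTRUE(fit$provenance$fallback)) return(fit)
  spec2 <- fit$spec
  spec2$random <- setdiff(spec2$random, "item")
  if (length(spec2$random) == 0L) spec2$random <- "participant"
  refit <- fit_mixed(spec2, table, control = control,
                     df_method = fit_df_method(fit))
  refit$provenance$fallback <- TRUE
  refit$provenance$fallback_from <- fit$spec$random
  if (refit$singular)
    warning("fallback fit is still singular; proceeding", call. = FALSE)
  refit
}

#' Model criticism: refit after removing large standardized residuals
#'
#' A single pass: fit, remove observations whose absolute standardized
#' conditional residual exceeds `threshold` SD, refit once.  The
#' removed row indices (relative to `table`) are recorded in the
#' refitted model's provenance.
#'
#' @param fit a `mixed_fit` estimated on `table`.
#' @param table the modelling table.
#' @param threshold residual SD cutoff (2.5 by convention).
#' @param control optional fitting control.
#' @return List with `fit` (the refitted `mixed_fit`) and `removed`
#'   (integer row indices of `table` that were dropped).
#' @export
model_criticism <- function(fit, table, threshold = 2.5,
                            control = NULL) {
  r <- stats::resid(fit$fit, type = "pearson", scaled = TRUE)
  removed <- which(abs(r) > threshold)
  if (length(removed) > 0.2 * nrow(table))
    warning("model criticism removed more than 20% of rows (",
            length(removed), " of ", nrow(table),
            "); the model is likely misspecified", call. = FALSE)
  if (length(removed) == 0L) {
    fit$provenance$criticism_removed <- integer(0)
    return(list(fit = fit, removed = integer(0)))
  }
  refit <- fit_mixed(fit$spec, table[-removed, , drop = FALSE],
                     control = control,
                     df_method = fit_df_method(fit))
  refit$provenance$fallback <- fit$provenance$fallback
  refit$provenance$criticism_removed <- as.integer(removed)
  list(fit = refit, removed = as.integer(removed))
}

#' Simple slopes of SSim within design cells
#'
#' The SSim slope inside each cell of the stimulus-type by response
#' design (or type alone for the response GLMM), computed by a linear
#' contrast on the fixed-effect vector -- never by subsetting the data.
#' For Gaussian models the test uses Satterthwaite degrees of freedom;
#' for the binomial GLMM a Wald z.
#'
#' @param fit a `mixed_fit` whose fixed part contains the continuous
#'   predictor `var`.
#' @param cells data frame of cells with optional columns `type2` and
#'   `response` (levels `"new"`/`"old"`).  Defaults to every cell the
#'   fixed part distinguishes.
#' @param var name of the continuous predictor (default `"ssim"`).
#' @return Data frame with one row per cell: the slope `b`, `se`, test
#'   statistic (`t` with `df`, or `z`), and `p`.
#' @export
simple_slopes <- function(fit, cells = NULL, var = "ssim") {
  beta <- lme4::fixef(fit$fit)
  terms <- names(beta)
  has_resp <- any(grepl("response", terms))
  if (is.null(cells)) {
    cells <- if (has_resp)
      expand.grid(type2 = c("new", "old"), response = c("new", "old"),
                  stringsAsFactors = FALSE)
    else data.frame(type2 = c("new", "old"), stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, , drop = FALSE]
    L <- slope_contrast(terms, cell, var = var)
    if (all(L == 0))
      stop("fixed part contains no '", var, "' term", call. = FALSE)
    if (fit$spec$family == "gaussian" &&
        inherits(fit$fit, "lmerModLmerTest")) {
      ct <- lmerTest::contest1D(fit$fit, L)
      out <- data.frame(b = ct$Estimate, se = ct$`Std. Error`,
                        statistic = ct$`t value`, df = ct$df,
                        p = ct$`Pr(>|t|)`)
    } else {
      b <- sum(L * beta)
      se <- sqrt(drop(t(L) %*% as.matrix(stats::vcov(fit$fit)) %*% L))
      out <- data.frame(b = b, se = se, statistic = b / se, df = NA_real_,
                        p = 2 * stats::pnorm(-abs(b / se)))
    }
    cbind(cell, out, row.names = NULL)
  })
  do.call(rbind, rows)
}

# Contrast vector picking out the SSim slope in one design cell under
# treatment coding with reference level "new" for both factors.
slope_contrast <- function(terms, cell, var = "ssim") {
  sat <- function(part) {
    if (part == var) return(TRUE)
    if (part == "type2old") return(identical(cell$type2, "old"))
    if (part == "responseold") return(identical(cell$response, "old"))
    FALSE
  }
  vapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (!var %in% parts) return(0)
    if (all(vapply(parts, sat, logical(1)))) 1 else 0
  }, numeric(1))
}

#' Likelihood-ratio test of one fixed-effect term
#'
#' Fits the model and its reduction without `drop_term`, both by
#' maximum likelihood, and compares them by likelihood ratio.  This is
#' the omnibus test the power stage simulates.
#'
#' @param table modelling table.
#' @param dv dependent-variable column.
#' @param fixed fixed-part right-hand side.
#' @param drop_term term absent from the reduced model.
#' @param random random-intercept factors.
#' @param family `"gaussian"` or `"binomial"`.
#' @return List with `chisq`, `df`, `p`.
#' @export
lrt_term <- function(table, dv, fixed = "ssim * type2 * response",
                     drop_term = "ssim:type2:response",
                     random = c("participant", "item"),
                     family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  form <- spec_formula(model_spec(dv, fixed, random, family))
  red <- stats::update(form, paste(". ~ . -", drop_term))
  fit1 <- if (family == "binomial")
    lme4::glmer(form, table, stats::binomial())
  else lme4::lmer(form, table, REML = FALSE)
  fit0 <- if (family == "binomial")
    lme4::glmer(red, table, stats::binomial())
  else lme4::lmer(red, table, REML = FALSE)
  a <- stats::anova(fit1, fit0)
  list(chisq = a$Chisq[2], df = a$Df[2], p = a$`Pr(>Chisq)`[2])
}

#' Observed power by parametric simulation
#'
#' Simulates the response from the fitted full model (new draws of the
#' random effects and residuals), refits the full model and a reduced
#' model without `drop_term`, and tests the term by likelihood ratio at
#' level `alpha`; observed power is the rejection proportion over the
#' converged simulations, with a Clopper-Pearson binomial CI.  Both
#' models are (re)fit by maximum likelihood for the comparison.
#'
#' @param fit a `mixed_fit` (typically the model refitted after model
#'   criticism), with its table in `table`.
#' @param table the modelling table the fit used.
#' @param drop_term fixed-effect term defining the reduced model
#'   (default: the SSim by type by response triple interaction).
#' @param n_sims number of simulations.
#' @param alpha test level.
#' @param seed RNG seed.
#' @return List of class `power_result`: `power`, `ci` (95% binomial),
#'   `n_rejections`, `n_converged`, `n_failed`, `n_sims`, `alpha`,
#'   `effect`.
#' @export
observed_power <- function(fit, table, drop_term = "ssim:type2:response",
                           n_sims = 1000, alpha = 0.05, seed = 1L) {
  spec <- fit$spec
  form_full <- spec_formula(spec)
  full_ml <- if (spec$family == "binomial") fit$fit else
    lme4::lmer(form_full, data = table, REML = FALSE)
  red_form <- stats::update(form_full,
                            paste(". ~ . -", drop_term))
  red_ml <- if (spec$family == "binomial")
    lme4::glmer(red_form, data = table, family = stats::binomial())
  else lme4::lmer(red_form, data = table, REML = FALSE)

  sims <- stats::simulate(full_ml, nsim = n_sims, seed = seed,
                          use.u = FALSE)
  n_fail <- 0L; n_rej <- 0L
  for (j in seq_len(n_sims)) {
    y <- sims[[j]]
    res <- tryCatch({
      f1 <- quiet_refit(full_ml, y)
      f0 <- quiet_refit(red_ml, y)
      a <- suppressMessages(stats::anova(f1, f0))
      a$`Pr(>Chisq)`[2]
    }, error = function(e) NA_real_)
    if (is.na(res)) n_fail <- n_fail + 1L
    else if (res < alpha) n_rej <- n_rej + 1L
  }
  n_conv <- n_sims - n_fail
  ci <- if (n_conv > 0)
    as.numeric(stats::binom.test(n_rej, n_conv)$conf.int)
  else c(NA_real_, NA_real_)
  structure(list(effect = drop_term, n_sims = n_sims, alpha = alpha,
                 power = if (n_conv > 0) n_rej / n_conv else NA_real_,
                 ci = ci, n_rejections = n_rej, n_converged = n_conv,
                 n_failed = n_fail),
            class = "power_result")
}

quiet_refit <- function(object, y) {
  msgs <- character(0)
  f <- withCallingHandlers(
    lme4::refit(object, newresp = y),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage"))
  if (any(grepl("failed to converge", msgs)))
    stop("refit did not converge", call. = FALSE)
  f
}

#' @export
print.power_result <- function(x, ...) {
  cat("<power_result> ", x$effect, ": power = ",
      round(100 * x$power, 1), "% (", x$n_rejections, "/",
      x$n_converged, " rejections at alpha = ", x$alpha,
      "; 95% CI ", round(100 * x$ci[1], 1), "-",
      round(100 * x$ci[2], 1), "%)\n", sep = "")
  invisible(x)
}

#' Descriptive statistics and correlations of the four DVs
#'
#' Mean, SD and range per dependent variable (temporal DVs in raw ms)
#' and the pairwise Pearson correlation matrix across trials, with the
#' degrees of freedom (`n - 2`) used for the correlation tests.
#' Constant columns are flagged and their correlations set to `NA`.
#'
#' @param table a trial table carrying `initiation_rt`, `md`,
#'   `sample_entropy`, `md_time`.
#' @return List with `descriptives` (data frame), `correlations`
#'   (matrix), `df`, and `constant` (names of zero-variance DVs).
#' @export
dv_descriptives <- function(table) {
  dvs <- c("initiation_rt", "md", "sample_entropy", "md_time")
  x <- as.matrix(table[dvs])
  x <- x[stats::complete.cases(x), , drop = FALSE]
  desc <- data.frame(
    dv = dvs,
    mean = colMeans(x),
    sd = apply(x, 2, stats::sd),
    min = apply(x, 2, min),
    max = apply(x, 2, max),
    row.names = NULL)
  const <- dvs[desc$sd == 0]
  cm <- suppressWarnings(stats::cor(x))
  if (length(const)) cm[const, ] <- cm[, const] <- NA_real_
  diag(cm) <- 1
  list(descriptives = desc, correlations = cm,
       df = nrow(x) - 2L, constant = const)
}
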