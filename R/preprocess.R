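#' Trial-exclusion filters
#'
#' The pipeline applies three exclusion rules, in a fixed order, each
#' marking rows with an `excluded` flag and a reason rather than
#' dropping them, so that full accounting
#' (`n_input = n_retained + sum of per-reason exclusions`) is preserved:
#'
#' 1. `filter_overall_rt()` — trials whose overall RT (movement
#'    initiation to option selection) is faster than `lower` or slower
#'    than `upper` ms (strict inequalities: boundary trials are kept);
#'    reason `"rt_bounds"`.
#' 2. `filter_aberrant()` — trials whose trajectory could not be
#'    processed; reason `"aberrant"`.  A trial failing both rules counts
#'    only under `"rt_bounds"`.
#' 3. `filter_participant_outliers()` — trials where MD or sample
#'    entropy lies more than `k` SD from that participant's own mean
#'    (computed on the surviving rows); reason `"dv_outlier"`.  This
#'    rule is single-pass: it is applied once, never iterated.
#'
#' @param trials data frame carrying the measure columns of
#'   [measure_trials()].
#' @param lower,upper overall-RT bounds in ms.
#' @return `trials` with logical `excluded` and character
#'   `excluded_reason` columns updated.
#' @export
filter_overall_rt <- function(trials, lower = 300, upper = 5000) {
  trials <- ensure_exclusion_cols(trials)
  bad <- !trials$excluded & !is.na(trials$total_rt) &
    (trials$total_rt < lower | trials$total_rt > upper)
  trials$excluded[bad] <- TRUE
  trials$excluded_reason[bad] <- "rt_bounds"
  trials
}

#' @rdname filter_overall_rt
#' @export
filter_aberrant <- function(trials) {
  trials <- ensure_exclusion_cols(trials)
  bad <- !trials$excluded & trials$aberrant
  trials$excluded[bad] <- TRUE
  trials$excluded_reason[bad] <- "aberrant"
  trials
}

#' @rdname filter_overall_rt
#' @param k SD multiple for the per-participant outlier rule.
#' @param pooled use the pooled (all-participant) mean and SD instead of
#'   each participant's own; provided for sensitivity analysis only.
#' @export
filter_participant_outliers <- function(trials, k = 3, pooled = FALSE) {
  trials <- ensure_exclusion_cols(trials)
  alive <- !trials$excluded
  if (!pooled) {
    n_g <- table(as.character(trials$participant)[alive])
    few <- names(n_g)[n_g < 2L]
    if (length(few))
      warning("participant(s) with < 2 surviving trials, no DV-outlier ",
              "filtering applied: ", paste(few, collapse = ", "),
              call. = FALSE)
  }
  for (dv in c("md", "sample_entropy")) {
    v <- trials[[dv]]
    if (pooled) {
      mu <- rep(mean(v[alive]), nrow(trials))
      sdv <- rep(stats::sd(v[alive]), nrow(trials))
    } else {
      grp <- as.character(trials$participant)
      mu_g <- tapply(v[alive], grp[alive], mean)
      sd_g <- tapply(v[alive], grp[alive], stats::sd)
      mu <- mu_g[grp]; sdv <- sd_g[grp]
    }
    bad <- alive & !is.na(sdv) & sdv > 0 & abs(v - mu) > k * sdv
    trials$excluded[bad] <- TRUE
    trials$excluded_reason[bad] <- "dv_outlier"
    alive <- !trials$excluded
  }
  trials
}

ensure_exclusion_cols <- function(trials) {
  if (is.null(trials$excluded)) trials$excluded <- FALSE
  if (is.null(trials$excluded_reason))
    trials$excluded_reason <- NA_character_
  trials
}

#' @rdname filter_overall_rt
#' @param ... passed on to the individual filters.
#' @export
apply_trial_filters <- function(trials, lower = 300, upper = 5000, k = 3,
                                ...) {
  trials <- filter_overall_rt(trials, lower, upper)
  trials <- filter_aberrant(trials)
  filter_participant_outliers(trials, k = k, ...)
}

#' Per-reason exclusion accounting
#'
#' @param trials filtered trial table.
#' @return List with `n_input`, `n_retained`, and per-reason counts and
#'   fractions (of `n_input`).
#' @export
exclusion_report <- function(trials) {
  trials <- ensure_exclusion_cols(trials)
  n <- nrow(trials)
  reasons <- c("rt_bounds", "aberrant", "dv_outlier")
  counts <- vapply(reasons, function(r)
    sum(trials$excluded & trials$excluded_reason == r, na.rm = TRUE), 0L)
  list(n_input = n, n_retained = sum(!trials$excluded),
       counts = as.list(counts),
       fractions = as.list(counts / n))
}

#' Build the modelling table
#'
#' Joins SSim scores onto the surviving trials and applies the standard
#' transforms: natural log for initiation RT, sample entropy and
#' MD-time; maximum deviation left untransformed.  Stimulus truth
#' (`type2`) is `old` for studied items and `new` otherwise; responses
#' are coded 0 (`new`) / 1 (`old`).
#'
#' @param trials filtered trial table (the `excluded` rows are dropped).
#' @param ssim_scores data frame from [score_items()].
#' @param log_base base of the log transforms (natural log by default;
#'   slope magnitudes are base-sensitive, so this is configurable).
#' @return Data frame of class `model_table` with columns
#'   `participant`, `item`, `list_id`, `item_type`, `type2`, `response`,
#'   `response_coded`, `ssim`, the raw measures, and `log_init_rt`,
#'   `log_entropy`, `log_mdtime`.
#' @export
build_model_table <- function(trials, ssim_scores, log_base = exp(1)) {
  trials <- ensure_exclusion_cols(trials)
  keep <- trials[!trials$excluded, , drop = FALSE]
  key_t <- paste(tolower(keep$item), keep$list_id)
  key_s <- paste(tolower(ssim_scores$word), ssim_scores$list_id)
  idx <- match(key_t, key_s)
  if (anyNA(idx))
    stop("no SSim score for item(s): ",
         paste(unique(keep$item[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  keep$ssim <- ssim_scores$ssim[idx]
  keep$type2 <- factor(ifelse(keep$item_type == "studied", "old", "new"),
                       levels = c("new", "old"))
  keep$response <- factor(keep$response, levels = c("new", "old"))
  keep$response_coded <- as.integer(keep$response == "old")
  keep$log_init_rt <- log(keep$initiation_rt, base = log_base)
  keep$log_entropy <- log(keep$sample_entropy, base = log_base)
  keep$log_mdtime <- log(keep$md_time, base = log_base)
  dv_cols <- c("ssim", "md", "log_init_rt", "log_entropy", "log_mdtime")
  nonfinite <- rowSums(!is.finite(as.matrix(keep[dv_cols]))) > 0
  if (any(nonfinite))
    stop("non-finite modelling values in ", sum(nonfinite),
         " retained row(s); run the aberrant filter first", call. = FALSE)
  keep$participant <- factor(keep$participant)
  keep$item <- factor(keep$item)
  class(keep) <- c("model_table", "data.frame")
  keep
}
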