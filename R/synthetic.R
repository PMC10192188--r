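#' Configuration of the synthetic DRM experiment
#'
#' All parameters of the synthetic-data generator, including the
#' ground-truth coefficients, in one list.  The defaults encode the
#' study design the package targets: 12 lists of 12 studied words, a
#' recognition set of 96 items per participant (48 studied -- list
#' positions 1, 4, 7 and 10 -- plus 12 critical lures, 24 weak lures
#' and 12 unrelated words), start button at (0, -0.35) and response
#' buttons at (+/-0.50, 0.25) in screen-height units.
#'
#' The embedding generator places one unit-sphere cluster centre per
#' list and draws members as `normalize(centre + sigma * g / sqrt(dim))`
#' with isotropic Gaussian `g`, so `sigma` is approximately the noise
#' norm relative to the unit centre: studied words use `sigma_studied`,
#' critical lures the tighter `sigma_critical`, weak lures the looser
#' `sigma_weak`, and unrelated words are isotropic.  This yields the
#' defining SSim gradient critical > weak > unrelated.
#'
#' Old/new responses follow a logistic model on z-scored SSim,
#' `logit p(old) = beta0 + beta_ssim z + beta_type [studied]
#' + beta_ssim_type z [studied] + u_participant + u_item`.
#' Trajectories follow a two-attractor motor model: after a log-normal
#' initiation delay the pointer moves with per-step displacement
#' `v * ((1 - w) u_chosen + w u_other)` plus Gaussian motor noise,
#' where the competitor weight `w(t) = clamp(alpha0 + alpha1 * conflict,
#' 0, 0.9) * exp(-t / tau_w)` decays over time.  By default the SSim
#' conflict term (`conflict = z(SSim)`) enters only for new items
#' correctly rejected (`conflict_mode = "pattern"`);
#' `conflict_mode = "crossed"` applies it in every cell, and
#' `conflict_mode = "none"` nowhere (for null calibration).
#'
#' @param seed integer RNG seed; every generator run is fully
#'   deterministic given it.
#' @param dim embedding dimensionality.
#' @param n_lists,words_per_list,n_weak,n_unrelated stimulus design.
#' @param n_participants number of simulated participants.
#' @param sigma_studied,sigma_critical,sigma_weak cluster noise scales.
#' @param zipf_exponent exponent of the Zipfian frequency law.
#' @param beta0,beta_ssim,beta_type,beta_ssim_type fixed effects of the
#'   response model (logit scale).
#' @param tau_participant,tau_item random-intercept SDs.
#' @param sample_rate_hz,sample_jitter_ms mouse sampling rate and
#'   per-sample timing jitter.
#' @param speed per-step displacement (screen units).
#' @param motor_noise_sd stationary SD of the per-coordinate motor
#'   noise (screen units).
#' @param motor_noise_ar lag-1 autocorrelation of the motor noise;
#'   physiological jitter is smooth, not white, and this controls how
#'   irregular the x-velocity profile (hence sample entropy) is.
#' @param noise_conflict reduction of the motor-noise lag-1
#'   autocorrelation at competitor weight 1: conflicted movements are
#'   not only more curved but also less smooth, which is what links
#'   sample entropy to indecision (noise amplitude alone cannot, since
#'   the entropy tolerance scales with the series SD).
#' @param alpha0,alpha1 baseline and SSim-scaled competitor attraction.
#' @param tau_w attraction decay time constant (ms).
#' @param tau_init participant SD on the initiation-delay meanlog.
#' @param tau_traj participant SD on the baseline attraction `alpha0`.
#' @param init_meanlog,init_sdlog log-normal initiation-delay
#'   parameters (ms scale).
#' @param conflict_mode `"pattern"`, `"crossed"` or `"none"`.
#' @param start,button_x,button_y,button_radius recognition-screen
#'   geometry (screen-height units).
#' @param max_steps hard cap on motion steps per trial.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, dim = 50L,
                         n_lists = 12L, words_per_list = 12L,
                         n_weak = 2L, n_unrelated = 12L,
                         n_participants = 40L,
                         sigma_studied = 0.6, sigma_critical = 0.3,
                         sigma_weak = 1.0, zipf_exponent = 1.0,
                         beta0 = -1.0, beta_ssim = 0.9,
                         beta_type = 2.2, beta_ssim_type = -0.8,
                         tau_participant = 0.8, tau_item = 0.4,
                         sample_rate_hz = 80, sample_jitter_ms = 1.0,
                         speed = 0.009, motor_noise_sd = 0.0012,
                         motor_noise_ar = 0.995, noise_conflict = 0.8,
                         alpha0 = 0.55, alpha1 = 0.35, tau_w = 1100,
                         tau_init = 0.25, tau_traj = 0.08,
                         init_meanlog = log(280), init_sdlog = 0.45,
                         conflict_mode = c("pattern", "crossed", "none"),
                         start = c(0, -0.35), button_x = 0.5,
                         button_y = 0.25, button_radius = 0.05,
                         max_steps = 400L) {
  conflict_mode <- match.arg(conflict_mode)
  stopifnot(sigma_studied > 0, sigma_critical > 0, sigma_weak > 0,
            tau_participant >= 0, tau_item >= 0, speed > 0,
            motor_noise_sd >= 0, tau_w > 0)
  cfg <- as.list(environment())
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config> seed ", x$seed, ": ", x$n_lists, " lists x ",
      x$words_per_list, " words, ", x$n_participants,
      " participants, conflict mode '", x$conflict_mode, "'\n", sep = "")
  invisible(x)
}

unit_rows <- function(m) m / sqrt(rowSums(m^2))

#' Generate the synthetic stimulus material
#'
#' Builds the cluster-structured embedding space, the study-list
#' definitions and Zipfian frequency norms described in
#' [synth_config()].  Studied-word positions within each list are
#' assigned by descending cosine to the critical lure, emulating the
#' forward-associative-strength ordering of normed DRM lists.
#'
#' @param cfg a [synth_config()].
#' @return List with `space` ([embedding_space()]), `lists`
#'   ([study_lists()]) and `freqs` ([freq_norms()]).
#' @export
gen_embedding_space <- function(cfg) {
  d <- cfg$dim
  words <- character(0); vecs <- list(); rows <- list()
  mem <- function(sigma, centre, n)
    unit_rows(centre[rep(1L, n), , drop = FALSE] +
                sigma * matrix(stats::rnorm(n * d), n, d) / sqrt(d))
  for (l in seq_len(cfg$n_lists)) {
    lid <- sprintf("l%02d", l)
    centre <- unit_rows(matrix(stats::rnorm(d), 1, d))
    sw <- mem(cfg$sigma_studied, centre, cfg$words_per_list)
    cl <- mem(cfg$sigma_critical, centre, 1L)
    wk <- mem(cfg$sigma_weak, centre, cfg$n_weak)
    sw_names <- sprintf("%s_w%02d", lid, seq_len(cfg$words_per_list))
    # FAS-descending proxy: order studied words by cosine to the lure
    ord <- order(as.vector(sw %*% t(cl)), decreasing = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      list_id = lid,
      role = c(rep("studied", cfg$words_per_list), "critical_lure",
               rep("weak_lure", cfg$n_weak)),
      position = c(seq_len(cfg$words_per_list), rep(NA_integer_,
                                                    1L + cfg$n_weak)),
      word = c(sw_names, sprintf("%s_critical", lid),
               sprintf("%s_weak%d", lid, seq_len(cfg$n_weak))))
    words <- c(words, sw_names, sprintf("%s_critical", lid),
               sprintf("%s_weak%d", lid, seq_len(cfg$n_weak)))
    vecs[[length(vecs) + 1L]] <- rbind(sw[ord, , drop = FALSE], cl, wk)
  }
  un <- unit_rows(matrix(stats::rnorm(cfg$n_unrelated * d),
                         cfg$n_unrelated, d))
  un_names <- sprintf("unrel%02d", seq_len(cfg$n_unrelated))
  assigned <- sprintf("l%02d", sample.int(cfg$n_lists, cfg$n_unrelated,
                                          replace = TRUE))
  rows[[length(rows) + 1L]] <- data.frame(
    list_id = assigned, role = "unrelated", position = NA_integer_,
    word = un_names)
  words <- c(words, un_names)
  vecs[[length(vecs) + 1L]] <- un

  m <- do.call(rbind, vecs)
  rownames(m) <- words
  # Zipfian counts over a random rank permutation of the lexicon
  ranks <- sample.int(length(words))
  counts <- stats::setNames(1e6 / ranks^cfg$zipf_exponent, words)
  list(space = embedding_space(m),
       lists = study_lists(do.call(rbind, rows),
                           words_per_list = cfg$words_per_list),
       freqs = freq_norms(counts))
}

#' The recognition item set implied by the study design
#'
#' 48 studied words (list positions 1, 4, 7, 10), 12 critical lures,
#' 24 weak lures and 12 unrelated words: 96 items.
#'
#' @param lists a [study_lists()] object.
#' @param studied_positions which studied positions enter recognition.
#' @return Data frame with `item`, `list_id`, `item_type`.
#' @export
recognition_items <- function(lists, studied_positions = c(1, 4, 7, 10)) {
  df <- as.data.frame(lists)
  keep <- df$role != "studied" |
    (!is.na(df$position) & df$position %in% studied_positions)
  out <- df[keep, c("word", "list_id", "role")]
  names(out) <- c("item", "list_id", "item_type")
  rownames(out) <- NULL
  out
}

#' Simulate old/new responses
#'
#' Bernoulli draws from the logistic ground-truth model of
#' [synth_config()] for every participant by recognition item.  SSim is
#' z-scored over the recognition item set inside the linear predictor,
#' so coefficient magnitudes are comparable across embedding draws.
#' The old/new button sides are counterbalanced across participants.
#'
#' @param cfg a [synth_config()].
#' @param items data frame from [recognition_items()].
#' @param scores SSim scores from [score_items()].
#' @return Trial table: `trial_id`, `participant`, `item`, `list_id`,
#'   `item_type`, `response` (`"new"`/`"old"`), `response_side`
#'   (`"left"`/`"right"`), `ssim_z`, `conflict`.
#' @export
gen_responses <- function(cfg, items, scores) {
  key <- paste(scores$word, scores$list_id)
  idx <- match(paste(items$item, items$list_id), key)
  if (anyNA(idx)) stop("unscored recognition item(s)", call. = FALSE)
  s <- scores$ssim[idx]
  z <- if (stats::sd(s) > 0) (s - mean(s)) / stats::sd(s) else s * 0
  np <- cfg$n_participants; ni <- nrow(items)
  u_p <- stats::rnorm(np, 0, cfg$tau_participant)
  u_i <- stats::rnorm(ni, 0, cfg$tau_item)
  studied <- as.numeric(items$item_type == "studied")
  d <- data.frame(
    participant = rep(sprintf("p%02d", seq_len(np)), each = ni),
    item = rep(items$item, np),
    list_id = rep(items$list_id, np),
    item_type = rep(items$item_type, np),
    ssim_z = rep(z, np))
  eta <- cfg$beta0 + cfg$beta_ssim * d$ssim_z +
    cfg$beta_type * rep(studied, np) +
    cfg$beta_ssim_type * d$ssim_z * rep(studied, np) +
    rep(u_p, each = ni) + rep(u_i, np)
  d$response <- ifelse(stats::runif(nrow(d)) < stats::plogis(eta),
                       "old", "new")
  # counterbalanced button mapping: odd participants have "old" on the right
  old_right <- rep(seq_len(np) %% 2L == 1L, each = ni)
  d$response_side <- ifelse((d$response == "old") == old_right,
                            "right", "left")
  d$conflict <- switch(cfg$conflict_mode,
    pattern = ifelse(d$item_type != "studied" & d$response == "new",
                     d$ssim_z, 0),
    crossed = d$ssim_z,
    none = 0)
  d$trial_id <- sprintf("t%06d", seq_len(nrow(d)))
  d[c("trial_id", "participant", "item", "list_id", "item_type",
      "response", "response_side", "ssim_z", "conflict")]
}

#' Simulate raw mouse trajectories
#'
#' Two-attractor motor model (see [synth_config()]), advanced for all
#' trials in lock-step for speed: each trial rests at the start button
#' through its log-normal initiation delay, then steps toward the
#' chosen button with a decaying pull toward the competitor, ending
#' when the pointer enters the chosen button's radius.
#'
#' @param cfg a [synth_config()].
#' @param trials output of [gen_responses()].
#' @return List with `trials` (the input plus `start_click_t`,
#'   `end_click_t`) and `samples` (long data frame `trial_id`, `t`,
#'   `x`, `y`).
#' @export
gen_trajectories <- function(cfg, trials) {
  n <- nrow(trials)
  dt <- 1000 / cfg$sample_rate_hz
  pid <- factor(trials$participant)
  u_init <- stats::rnorm(nlevels(pid), 0, cfg$tau_init)
  u_traj <- stats::rnorm(nlevels(pid), 0, cfg$tau_traj)
  delay <- stats::rlnorm(n, cfg$init_meanlog + u_init[as.integer(pid)],
                         cfg$init_sdlog)
  tgt_x <- ifelse(trials$response_side == "right", cfg$button_x,
                  -cfg$button_x)
  w0 <- pmin(pmax(cfg$alpha0 + u_traj[as.integer(pid)] +
                    cfg$alpha1 * trials$conflict, 0), 0.9)

  px <- rep(cfg$start[1], n); py <- rep(cfg$start[2], n)
  tt <- delay + stats::rnorm(n, 0, cfg$sample_jitter_ms)
  # pre-onset rest samples at the start position
  n_rest <- pmax(1L, floor(delay / dt))
  rest <- data.frame(
    trial_id = rep(trials$trial_id, n_rest + 1L),
    t = unlist(lapply(seq_len(n), function(i)
      seq(0, by = dt, length.out = n_rest[i] + 1L))),
    x = rep(cfg$start[1], sum(n_rest + 1L)),
    y = rep(cfg$start[2], sum(n_rest + 1L)))

  active <- rep(TRUE, n)
  out_id <- list(rest$trial_id); out_t <- list(rest$t)
  out_x <- list(rest$x); out_y <- list(rest$y)
  elapsed <- rep(0, n)
  # AR(1) motor noise; conflict makes the jitter both rougher (lower
  # autocorrelation) and larger, so that irregularity survives the
  # bigger systematic velocity of high-conflict trials
  phi <- pmin(pmax(cfg$motor_noise_ar - cfg$noise_conflict * w0, 0.5),
              0.9999)
  trial_sd <- cfg$motor_noise_sd * (1 + 2 * cfg$noise_conflict * w0)
  innov_sd <- trial_sd * sqrt(1 - phi^2)
  nx <- stats::rnorm(n, 0, trial_sd)
  ny <- stats::rnorm(n, 0, trial_sd)
  for (step in seq_len(cfg$max_steps)) {
    if (!any(active)) break
    i <- which(active)
    w <- w0[i] * exp(-elapsed[i] / cfg$tau_w)
    cx <- tgt_x[i] - px[i]; cy <- cfg$button_y - py[i]
    cl <- sqrt(cx^2 + cy^2); cl[cl == 0] <- 1
    ox <- -tgt_x[i] - px[i]; oy <- cfg$button_y - py[i]
    ol <- sqrt(ox^2 + oy^2); ol[ol == 0] <- 1
    mx <- (1 - w) * cx / cl + w * ox / ol
    my <- (1 - w) * cy / cl + w * oy / ol
    nx[i] <- phi[i] * nx[i] + stats::rnorm(length(i), 0, innov_sd[i])
    ny[i] <- phi[i] * ny[i] + stats::rnorm(length(i), 0, innov_sd[i])
    px[i] <- px[i] + cfg$speed * mx + nx[i]
    py[i] <- py[i] + cfg$speed * my + ny[i]
    step_dt <- dt + stats::rnorm(length(i), 0, cfg$sample_jitter_ms)
    step_dt[step_dt < 1] <- 1
    elapsed[i] <- elapsed[i] + step_dt
    tt[i] <- delay[i] + elapsed[i]
    out_id[[length(out_id) + 1L]] <- trials$trial_id[i]
    out_t[[length(out_t) + 1L]] <- tt[i]
    out_x[[length(out_x) + 1L]] <- px[i]
    out_y[[length(out_y) + 1L]] <- py[i]
    reached <- sqrt((px[i] - tgt_x[i])^2 + (py[i] - cfg$button_y)^2) <
      cfg$button_radius
    active[i[reached]] <- FALSE
  }
  samples <- data.frame(trial_id = unlist(out_id), t = unlist(out_t),
                        x = unlist(out_x), y = unlist(out_y))
  samples <- samples[order(match(samples$trial_id, trials$trial_id),
                           samples$t), ]
  rownames(samples) <- NULL
  end_t <- tapply(samples$t, samples$trial_id, max)
  trials$start_click_t <- 0
  trials$end_click_t <- as.numeric(end_t[trials$trial_id])
  list(trials = trials, samples = samples)
}

#' Generate and write a complete synthetic experiment
#'
#' Runs the full generator chain under `cfg$seed` and writes every
#' input file the analysis pipeline reads -- word vectors (word2vec
#' text), frequency norms (TSV), study lists (CSV), trial log and
#' mouse samples (CSV) -- plus `ground_truth.json` holding the exact
#' configuration used.  Output is byte-identical for a given seed.
#'
#' @param cfg a [synth_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the generated objects and the file
#'   paths.
#' @export
gen_experiment <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  mat <- gen_embedding_space(cfg)
  items <- recognition_items(mat$lists)
  scores <- score_items(mat$lists, mat$space, mat$freqs)
  trials <- gen_responses(cfg, items, scores)
  traj <- gen_trajectories(cfg, trials)

  paths <- list(
    vectors = file.path(out_dir, "vectors.txt"),
    freqs = file.path(out_dir, "frequencies.tsv"),
    lists = file.path(out_dir, "lists.csv"),
    trials = file.path(out_dir, "trials.csv"),
    samples = file.path(out_dir, "samples.csv"),
    ground_truth = file.path(out_dir, "ground_truth.json"))
  write_word_vectors(mat$space, paths$vectors)
  write_frequency_norms(mat$freqs, paths$freqs)
  write_study_lists(mat$lists, paths$lists)
  utils::write.csv(traj$trials, paths$trials, row.names = FALSE)
  utils::write.csv(traj$samples, paths$samples, row.names = FALSE)
  gt <- unclass(cfg)
  jsonlite::write_json(gt, paths$ground_truth, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(config = cfg, space = mat$space, lists = mat$lists,
                 freqs = mat$freqs, items = items, scores = scores,
                 trials = traj$trials, samples = traj$samples,
                 paths = paths))
}

#' @rdname gen_experiment
#' @param path a `ground_truth.json` written by `gen_experiment()`.
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  gt$conflict_mode <- as.character(gt$conflict_mode)
  gt
}
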