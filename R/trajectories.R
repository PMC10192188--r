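#' Raw mouse trajectories
#'
#' One recognition trial's mouse record: samples `(x, y, t)` in
#' screen-normalized coordinates (origin at screen centre, y increasing
#' upward, units of screen height; the PsychoPy "height" convention) with
#' `t` in ms since trial start, plus the start-button click time and the
#' response click time.
#'
#' @param t,x,y numeric vectors of equal length; `t` strictly increasing.
#' @param start_click_t ms of the click on the start button.
#' @param end_click_t ms of the response click.
#' @return An object of class `raw_trajectory`.
#' @export
raw_trajectory <- function(t, x, y, start_click_t = t[1],
                           end_click_t = t[length(t)]) {
  if (length(t) < 2L)
    stop("degenerate trajectory: fewer than 2 samples", call. = FALSE)
  if (length(x) != length(t) || length(y) != length(t))
    stop("x, y, t must have equal length", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("sample times must be strictly increasing", call. = FALSE)
  structure(list(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
                 start_click_t = as.numeric(start_click_t),
                 end_click_t = as.numeric(end_click_t)),
            class = "raw_trajectory")
}

#' @export
print.raw_trajectory <- function(x, ...) {
  cat("<raw_trajectory> ", length(x$t), " samples, ",
      round(x$t[length(x$t)] - x$t[1]), " ms\n", sep = "")
  invisible(x)
}

#' Initiation reaction time
#'
#' Time from the start-button click to movement onset, defined as the
#' first sample whose Euclidean displacement from the start position
#' exceeds `threshold` (screen units).
#'
#' @param raw a [raw_trajectory()].
#' @param threshold movement-onset displacement threshold.
#' @param origin reference position for the displacement; defaults to
#'   the first recorded sample (which sits on the start button).
#' @return Initiation RT in ms.
#' @export
initiation_rt <- function(raw, threshold = 0.01, origin = NULL) {
  i <- onset_index(raw, threshold, origin)
  raw$t[i] - raw$start_click_t
}

# Index of the movement-onset sample; error if the hand never moves.
onset_index <- function(raw, threshold = 0.01, origin = NULL) {
  if (is.null(origin)) origin <- c(raw$x[1], raw$y[1])
  d <- sqrt((raw$x - origin[1])^2 + (raw$y - origin[2])^2)
  i <- which(d > threshold)
  if (length(i) == 0L)
    stop("no movement: all samples within the onset threshold",
         call. = FALSE)
  i[1L]
}

#' Time-normalize a trajectory to a fixed number of steps
#'
#' Linearly interpolates x and y at `n_steps` time points equally spaced
#' over the trajectory's time span, so that trajectories differing in
#' duration and sampling can be compared step by step.  The first and
#' last raw samples are preserved exactly.
#'
#' @param raw a [raw_trajectory()] (trim it to the movement window
#'   first; see [measure_trial()]).
#' @param n_steps number of normalized steps (101 by convention).
#' @return An object of class `normalized_trajectory`: list with `x`,
#'   `y`, `step_times` (each length `n_steps`), `remapped` flag and
#'   `chosen_side` (`"left"`, `"right"`, or `NA` when the endpoint sits
#'   exactly on the start abscissa).
#' @export
time_normalize <- function(raw, n_steps = 101L) {
  if (length(raw$t) < 2L)
    stop("degenerate trajectory: fewer than 2 samples", call. = FALSE)
  tt <- seq(raw$t[1], raw$t[length(raw$t)], length.out = n_steps)
  xs <- stats::approx(raw$t, raw$x, xout = tt)$y
  ys <- stats::approx(raw$t, raw$y, xout = tt)$y
  # endpoints exactly, independent of interpolation round-off
  xs[c(1L, n_steps)] <- raw$x[c(1L, length(raw$x))]
  ys[c(1L, n_steps)] <- raw$y[c(1L, length(raw$y))]
  side <- if (xs[n_steps] < xs[1L]) "left"
          else if (xs[n_steps] > xs[1L]) "right" else NA_character_
  structure(list(x = xs, y = ys, step_times = tt,
                 remapped = FALSE, chosen_side = side),
            class = "normalized_trajectory")
}

#' Remap trajectories symmetrically onto one canonical side
#'
#' Trajectories that end on the right are mirrored about the vertical
#' axis through the start x, so every trajectory ends on the left and
#' trajectories from both response buttons are directly comparable.
#' Mirroring also flips the recorded chosen side, so the signed maximum
#' deviation (positive toward the non-chosen option) is preserved.
#'
#' @param traj a `normalized_trajectory`.
#' @param chosen_side `"left"` or `"right"`; required only when the
#'   endpoint lies exactly on the start abscissa, where geometry cannot
#'   decide the side and the recorded response button must.
#' @return The remapped `normalized_trajectory` (`remapped = TRUE`).
#' @export
remap_symmetric <- function(traj, chosen_side = NULL) {
  side <- traj$chosen_side
  if (is.na(side)) {
    if (is.null(chosen_side))
      stop("ambiguous side: endpoint on the start abscissa; ",
           "supply `chosen_side` from the recorded response button",
           call. = FALSE)
    side <- chosen_side
  }
  if (side == "right") {
    traj$x <- 2 * traj$x[1L] - traj$x
    traj$chosen_side <- "left"
  } else traj$chosen_side <- side
  traj$remapped <- TRUE
  traj
}

#' Maximum deviation from the direct path
#'
#' The furthest point of the trajectory from the idealized straight line
#' joining its first and last points, as a signed perpendicular
#' distance: positive values lie on the side of the non-chosen option
#' (attraction toward the competitor), so small negative values indicate
#' curvature away from it.  Ties in absolute distance resolve to the
#' earliest step.
#'
#' @param traj a `normalized_trajectory` with known `chosen_side`.
#' @return List with `md` (signed, screen units) and `md_step` (1-based
#'   index of the attaining step).
#' @export
max_deviation <- function(traj) {
  n <- length(traj$x)
  dx <- traj$x[n] - traj$x[1L]; dy <- traj$y[n] - traj$y[1L]
  len <- sqrt(dx^2 + dy^2)
  if (len == 0)
    stop("degenerate trajectory: start and end coincide", call. = FALSE)
  if (is.na(traj$chosen_side))
    stop("chosen side unknown; remap or supply it first", call. = FALSE)
  cross <- dx * (traj$y - traj$y[1L]) - dy * (traj$x - traj$x[1L])
  # cross > 0 is the left of the travel direction; the non-chosen
  # option sits right of travel for a left response and vice versa
  signed <- cross / len * if (traj$chosen_side == "left") -1 else 1
  # earliest step on ties, to a float tolerance
  m <- max(abs(signed))
  step <- which(abs(signed) >= m - 1e-12 * max(m, 1))[1L]
  list(md = signed[[step]], md_step = as.integer(step))
}

#' Time at which the maximum deviation is reached
#'
#' @param traj a `normalized_trajectory`.
#' @param md_step step index from [max_deviation()].
#' @return The interpolated clock time (ms) of that step.
#' @export
md_time <- function(traj, md_step) {
  if (md_step < 1L || md_step > length(traj$step_times))
    stop("md_step out of range", call. = FALSE)
  traj$step_times[[md_step]]
}

#' Sample entropy of a series
#'
#' Quantifies the irregularity and unpredictability of movement along
#' the x-axis: `-ln(A/B)`, where `B` counts ordered pairs of distinct
#' length-`m` templates within Chebyshev distance `r` of one another and
#' `A` counts the corresponding length-`m+1` pairs (self-matches
#' excluded; templates indexed `1..N-m` for both lengths, so a constant
#' series scores exactly 0).  By package convention the series is the
#' first difference of the 101 normalized x positions.
#'
#' @param series numeric vector, length greater than `m + 1`.
#' @param m template length (default 3).
#' @param r match tolerance; default `0.2 * sd(series)`.
#' @return Nonnegative entropy value.  When no `m+1` templates match
#'   (`A = 0`) the entropy is undefined and an error of class
#'   `drmtrack_entropy_undefined` is signalled; batch processing flags
#'   such trials aberrant instead of aborting.
#' @export
sample_entropy <- function(series, m = 3L, r = 0.2 * stats::sd(series)) {
  n <- length(series)
  if (n <= m + 1L)
    stop("series too short for sample entropy (need length > m + 1)",
         call. = FALSE)
  counts <- sampen_counts(as.numeric(series), as.integer(m),
                          as.numeric(r))
  a <- counts[[1L]]; b <- counts[[2L]]
  if (b == 0 || a == 0)
    stop(structure(class = c("drmtrack_entropy_undefined", "error",
                             "condition"),
                   list(message = "sample entropy undefined: no template matches",
                        call = NULL)))
  -log(a / b)
}

#' Compute all decision-dynamics measures for one trial
#'
#' Runs the full per-trial chain: movement onset by displacement
#' threshold, trimming to the movement window, 101-step time
#' normalization, symmetric remapping, then maximum deviation, sample
#' entropy (on the differenced x series), MD-time and the two reaction
#' times.  A failure at any stage marks the trial aberrant (with the
#' reason) rather than aborting a batch.
#'
#' @param raw a [raw_trajectory()].
#' @param params list of processing parameters; see
#'   [measure_params()] for defaults.
#' @param chosen_side optional recorded response side, used only to
#'   disambiguate endpoints on the start abscissa.
#' @return One-row data frame: `initiation_rt`, `md`, `sample_entropy`,
#'   `md_time`, `total_rt`, `aberrant`, `aberrant_reason`.
#' @export
measure_trial <- function(raw, params = measure_params(),
                          chosen_side = NULL) {
  v <- measure_core(raw, params, chosen_side)
  data.frame(initiation_rt = v$initiation_rt, md = v$md,
             sample_entropy = v$sample_entropy, md_time = v$md_time,
             total_rt = v$total_rt, aberrant = v$aberrant,
             aberrant_reason = v$aberrant_reason,
             stringsAsFactors = FALSE)
}

# the per-trial chain without data-frame overhead; failures become the
# aberrant flag
measure_core <- function(raw, params, chosen_side = NULL) {
  tryCatch({
    i0 <- onset_index(raw, params$init_threshold)
    init <- raw$t[i0] - raw$start_click_t
    if (i0 > length(raw$t) - 1L)
      stop("degenerate trajectory: no samples after movement onset",
           call. = FALSE)
    keep <- seq.int(i0, length(raw$t))
    win <- list(t = raw$t[keep], x = raw$x[keep], y = raw$y[keep])
    ntr <- time_normalize(win, params$n_steps)
    ntr <- remap_symmetric(ntr, chosen_side)
    mdv <- max_deviation(ntr)
    ser <- if (params$entropy_use_diff) diff(ntr$x) else ntr$x
    ent <- sample_entropy(ser, m = params$entropy_m,
                          r = params$entropy_r_factor * stats::sd(ser))
    list(initiation_rt = init, md = mdv$md, sample_entropy = ent,
         md_time = ntr$step_times[mdv$md_step] - win$t[1L],
         total_rt = raw$end_click_t - win$t[1L],
         aberrant = FALSE, aberrant_reason = NA_character_)
  }, error = function(e) {
    list(initiation_rt = NA_real_, md = NA_real_,
         sample_entropy = NA_real_, md_time = NA_real_,
         total_rt = NA_real_, aberrant = TRUE,
         aberrant_reason = conditionMessage(e))
  })
}

#' @rdname measure_trial
#' @param n_steps normalized step count.
#' @param init_threshold movement-onset displacement (screen units).
#' @param entropy_m,entropy_r_factor sample-entropy template length and
#'   tolerance factor (`r = factor * sd(series)`).
#' @param entropy_use_diff compute entropy on the differenced x series.
#' @export
measure_params <- function(n_steps = 101L, init_threshold = 0.01,
                           entropy_m = 3L, entropy_r_factor = 0.2,
                           entropy_use_diff = TRUE) {
  list(n_steps = as.integer(n_steps), init_threshold = init_threshold,
       entropy_m = as.integer(entropy_m),
       entropy_r_factor = entropy_r_factor,
       entropy_use_diff = entropy_use_diff)
}

#' Batch trajectory measurement
#'
#' Applies [measure_trial()] to every trial of a trial log, picking each
#' trial's samples out of a long-format sample table.
#'
#' @param trials data frame with one row per trial; must contain
#'   `trial_id`, `start_click_t`, `end_click_t` and `response`
#'   (`"left"`/`"right"` side is inferred from the recorded button via
#'   the `response_side` column when present).
#' @param samples long data frame with columns `trial_id`, `t`, `x`, `y`.
#' @param params a [measure_params()] list.
#' @return `trials` with the measure columns appended; trials with no or
#'   too few samples are flagged aberrant.
#' @export
measure_trials <- function(trials, samples, params = measure_params()) {
  stopifnot(all(c("trial_id", "start_click_t", "end_click_t")
                %in% names(trials)),
            all(c("trial_id", "t", "x", "y") %in% names(samples)))
  id <- as.character(trials$trial_id)
  f <- factor(as.character(samples$trial_id), levels = id)
  t_s <- split(samples$t, f)
  x_s <- split(samples$x, f)
  y_s <- split(samples$y, f)
  has_side <- "response_side" %in% names(trials)
  n <- nrow(trials)
  cols <- list(initiation_rt = numeric(n), md = numeric(n),
               sample_entropy = numeric(n), md_time = numeric(n),
               total_rt = numeric(n), aberrant = logical(n),
               aberrant_reason = character(n))
  for (i in seq_len(n)) {
    ti <- t_s[[i]]
    v <- if (length(ti) < 2L) {
      list(initiation_rt = NA_real_, md = NA_real_,
           sample_entropy = NA_real_, md_time = NA_real_,
           total_rt = NA_real_, aberrant = TRUE,
           aberrant_reason = "degenerate: fewer than 2 samples")
    } else {
      o <- order(ti)
      raw <- tryCatch(
        raw_trajectory(ti[o], x_s[[i]][o], y_s[[i]][o],
                       trials$start_click_t[i], trials$end_click_t[i]),
        error = function(e) NULL)
      if (is.null(raw)) {
        list(initiation_rt = NA_real_, md = NA_real_,
             sample_entropy = NA_real_, md_time = NA_real_,
             total_rt = NA_real_, aberrant = TRUE,
             aberrant_reason = "invalid sample record")
      } else {
        measure_core(raw, params,
                     if (has_side) trials$response_side[i] else NULL)
      }
    }
    for (nm in names(cols)) cols[[nm]][i] <- v[[nm]]
  }
  cbind(trials, as.data.frame(cols, stringsAsFactors = FALSE))
}
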