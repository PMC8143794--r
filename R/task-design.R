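# Task structure: a dual-stimulus random-dot decision task. Each trial shows an
# adaptation stimulus (AS) carrying one strong feature (70% coherence on colour
# or motion), then a test stimulus (TS) judged on an instructed context
# (colour or motion) at 12.8% or 25.6% coherence. Repeating a feature between
# AS and TS suppresses the neurons tuned to it, which is the experimental
# handle all downstream regressors code.

#' Regressor names of the repetition-suppression design
#' @export
rs_regressors <- function() {
  c("context", "switch", "rel_adapt", "irrel_adapt", "resp_adapt", "choice")
}

#' Regressor names of the encoding design
#' @export
encoding_regressors <- function() {
  c("context", "rel_strength", "irrel_strength", "choice")
}

as_types <- function() c("colour_green", "colour_red", "motion_left", "motion_right")

#' The full factorial condition grid
#'
#' The task crosses 4 adaptation-stimulus types with 2 test-stimulus contexts,
#' 2 motion directions, 2 colours and 2 coherence levels: 64 conditions.
#'
#' @return A tibble with one row per condition (64 rows) and columns
#'   `as_type`, `ts_context`, `ts_direction`, `ts_colour`, `ts_coherence_pct`.
#' @export
#' @examples
#' nrow(condition_grid())
condition_grid <- function() {
  tidyr::expand_grid(
    as_type = as_types(),
    ts_context = c("colour", "motion"),
    ts_direction = c("left", "right"),
    ts_colour = c("green", "red"),
    ts_coherence_pct = c(12.8, 25.6)
  )
}

#' Condition label string for a trial
#'
#' @param trials A trial tibble with the factorial columns of [condition_grid()].
#' @return Character vector of labels such as
#'   `"AS:colour_green|CTX:motion|DIR:left|COL:red|COH:12.8"`.
#' @export
condition_label <- function(trials) {
  paste0(
    "AS:", trials$as_type,
    "|CTX:", trials$ts_context,
    "|DIR:", trials$ts_direction,
    "|COL:", trials$ts_colour,
    "|COH:", format(trials$ts_coherence_pct, trim = TRUE)
  )
}

#' Correct response to a test stimulus
#'
#' The response mapping is fixed throughout the task: green colour and leftward
#' motion map to the index finger; red colour and rightward motion map to the
#' middle finger. Under a colour context the colour determines the correct
#' response; under a motion context the motion direction does.
#'
#' @param context `"colour"` or `"motion"` (vectorised).
#' @param ts_direction `"left"` or `"right"`.
#' @param ts_colour `"green"` or `"red"`.
#' @return Character vector, `"index"` or `"middle"`.
#' @export
#' @examples
#' required_response("colour", "left", "red") # "middle": red wins under colour
#' required_response("motion", "left", "red") # "index": direction wins
required_response <- function(context, ts_direction, ts_colour) {
  stopifnot(
    all(context %in% c("colour", "motion")),
    all(ts_direction %in% c("left", "right")),
    all(ts_colour %in% c("green", "red"))
  )
  ifelse(
    context == "colour",
    ifelse(ts_colour == "green", "index", "middle"),
    ifelse(ts_direction == "left", "index", "middle")
  )
}

# Correct response to the adaptation stimulus, which carries a single feature.
as_required_response <- function(as_type) {
  unname(c(
    colour_green = "index", colour_red = "middle",
    motion_left = "index", motion_right = "middle"
  )[as_type])
}

# Dimension and feature carried by the adaptation stimulus.
as_dimension <- function(as_type) sub("_.*$", "", as_type)
as_feature <- function(as_type) sub("^[a-z]+_", "", as_type)

#' Generate a balanced, randomised session schedule
#'
#' Builds a trial table in which every one of the 64 factorial conditions
#' appears equally often, then shuffles trial order with a seeded uniform
#' permutation. Blocks are filled sequentially from the shuffled order.
#'
#' @param n_blocks Number of blocks (a standard MEG session uses 8).
#' @param trials_per_block Trials per block (standard: 128).
#' @param seed Integer seed; identical seeds give identical schedules.
#' @param session_id Session identifier recorded on every trial.
#' @param phase Experimental phase label (default `"meg_pre"`).
#' @return A trial tibble with one row per trial: identifiers, the factorial
#'   condition columns, the correct AS response, and empty outcome columns
#'   (`ts_response`, `ts_correct`, `ts_rt_ms`) to be filled by a simulator or
#'   real data.
#' @export
#' @examples
#' sched <- generate_session_schedule(8, 128, seed = 1)
#' nrow(sched) # 1024
generate_session_schedule <- function(n_blocks, trials_per_block, seed,
                                      session_id = "S01", phase = "meg_pre") {
  stopifnot(n_blocks >= 1, trials_per_block >= 1)
  total <- n_blocks * trials_per_block
  if (total %% 64L != 0L) {
    stop(sprintf(
      "n_blocks * trials_per_block = %d is not divisible by 64 (remainder %d)",
      total, total %% 64L
    ), call. = FALSE)
  }
  reps <- total %/% 64L
  grid <- condition_grid()
  sched <- grid[rep(seq_len(nrow(grid)), each = reps), ]
  ord <- withr::with_seed(seed, sample.int(total))
  sched <- sched[ord, ]
  tibble::tibble(
    session_id = session_id,
    block = rep(seq_len(n_blocks), each = trials_per_block),
    trial_index = seq_len(total),
    phase = phase,
    as_type = sched$as_type,
    ts_context = sched$ts_context,
    ts_direction = sched$ts_direction,
    ts_colour = sched$ts_colour,
    ts_coherence_pct = sched$ts_coherence_pct,
    as_response = as_required_response(sched$as_type),
    ts_response = NA_character_,
    ts_correct = NA_integer_,
    ts_rt_ms = NA_real_
  )
}

#' Default multi-week training plan
#'
#' The study schedule: a screening session (768 trials), two pre-training MEG
#' sessions (1024 each), seven days of a one-dimensional training task
#' (1200/day), twelve days of the two-dimensional task (1200/day), and three
#' days of the full dual-stimulus task (1024/day).
#'
#' @return A tibble with columns `phase`, `n_sessions`, `trials_per_session`.
#' @export
default_training_plan <- function() {
  tibble::tibble(
    phase = c("screening", "meg_pre", "train_1d", "train_2d", "train_full"),
    n_sessions = c(1L, 2L, 7L, 12L, 3L),
    trials_per_session = c(768L, 1024L, 1200L, 1200L, 1024L)
  )
}

#' Trial counts of a training plan
#'
#' @param plan A tibble with columns `phase`, `n_sessions`,
#'   `trials_per_session`; defaults to [default_training_plan()].
#' @return A tibble with per-phase `trials` plus a class carrying the grand
#'   total, available via `glance()` or `attr(x, "total_trials")`.
#' @export
#' @examples
#' attr(generate_training_plan(), "total_trials") # 28688
generate_training_plan <- function(plan = default_training_plan()) {
  if (nrow(plan) > 0) {
    stopifnot(all(c("phase", "n_sessions", "trials_per_session") %in% names(plan)))
    if (any(plan$n_sessions < 0) || any(plan$trials_per_session < 0)) {
      stop("training plan counts must be non-negative", call. = FALSE)
    }
  }
  out <- dplyr::mutate(plan, trials = .data$n_sessions * .data$trials_per_session)
  attr(out, "total_trials") <- if (nrow(out)) sum(out$trials) else 0L
  class(out) <- c("training_plan", class(out))
  out
}

#' @export
glance.training_plan <- function(x, ...) {
  tibble::tibble(n_phases = nrow(x), total_trials = attr(x, "total_trials"))
}

check_trial_fields <- function(trials, fields) {
  missing_col <- setdiff(fields, names(trials))
  if (length(missing_col)) {
    stop("trial table is missing column(s): ", paste(missing_col, collapse = ", "),
      call. = FALSE
    )
  }
  for (f in fields) {
    bad <- which(is.na(trials[[f]]))
    if (length(bad)) {
      stop(sprintf("missing value in '%s' at trial index %d", f, bad[1]),
        call. = FALSE
      )
    }
  }
  invisible(trials)
}

# Resolve the choice actually made on the TS: the recorded response when
# present, otherwise the correct response (an idealised all-correct observer).
resolved_ts_response <- function(trials) {
  req <- required_response(trials$ts_context, trials$ts_direction, trials$ts_colour)
  resp <- trials$ts_response
  if (is.null(resp)) resp <- rep(NA_character_, nrow(trials))
  ifelse(is.na(resp), req, resp)
}

#' Code the six repetition-suppression regressors
#'
#' One row per trial with 0/1 columns:
#' \describe{
#'   \item{context}{motion context = 1, colour = 0.}
#'   \item{switch}{the AS stimulus dimension differs from the TS context.}
#'   \item{rel_adapt}{the AS feature equals the TS feature on the attended
#'     dimension (implies no switch).}
#'   \item{irrel_adapt}{the AS feature equals the TS feature on the unattended
#'     dimension (implies a switch).}
#'   \item{resp_adapt}{the finger required by the AS equals the correct TS
#'     response.}
#'   \item{choice}{rightward pole (middle finger) = 1; uses the recorded
#'     response when present, else the correct response.}
#' }
#'
#' @param trials A trial tibble as from [generate_session_schedule()].
#' @return A tibble with the six regressor columns, rows aligned to `trials`.
#' @export
code_rs_regressors <- function(trials) {
  check_trial_fields(trials, c(
    "as_type", "ts_context", "ts_direction", "ts_colour", "as_response"
  ))
  dim_as <- as_dimension(trials$as_type)
  feat_as <- as_feature(trials$as_type)
  ts_feat_on_as_dim <- ifelse(dim_as == "colour", trials$ts_colour, trials$ts_direction)
  same_dim <- dim_as == trials$ts_context
  feat_match <- feat_as == ts_feat_on_as_dim
  req <- required_response(trials$ts_context, trials$ts_direction, trials$ts_colour)
  tibble::tibble(
    context = as.integer(trials$ts_context == "motion"),
    switch = as.integer(!same_dim),
    rel_adapt = as.integer(same_dim & feat_match),
    irrel_adapt = as.integer(!same_dim & feat_match),
    resp_adapt = as.integer(trials$as_response == req),
    choice = as.integer(resolved_ts_response(trials) == "middle")
  )
}

# Signed, level-scaled evidence on each stimulus dimension. Rightward motion
# and red colour are the positive (middle-finger) pole; 12.8% -> magnitude 1,
# 25.6% -> magnitude 2.
signed_strengths <- function(trials) {
  mag <- ifelse(trials$ts_coherence_pct == 25.6, 2, 1)
  motion <- ifelse(trials$ts_direction == "right", 1, -1) * mag
  colour <- ifelse(trials$ts_colour == "red", 1, -1) * mag
  tibble::tibble(
    motion_strength = motion,
    colour_strength = colour,
    rel_strength = ifelse(trials$ts_context == "motion", motion, colour),
    irrel_strength = ifelse(trials$ts_context == "motion", colour, motion)
  )
}

#' Code the four encoding-model regressors
#'
#' Codes test-stimulus properties independently of the adaptation stimulus:
#' context (motion = 1), signed relevant and irrelevant input strength in
#' \{-2, -1, +1, +2\} (positive values are evidence for a right choice;
#' magnitude 2 is the high-coherence level), and choice direction (right = 1).
#'
#' @inheritParams code_rs_regressors
#' @return A tibble with columns `context`, `rel_strength`, `irrel_strength`,
#'   `choice`.
#' @export
code_encoding_regressors <- function(trials) {
  check_trial_fields(trials, c(
    "ts_context", "ts_direction", "ts_colour", "ts_coherence_pct"
  ))
  if (!all(trials$ts_coherence_pct %in% c(12.8, 25.6))) {
    bad <- which(!trials$ts_coherence_pct %in% c(12.8, 25.6))[1]
    stop(sprintf("invalid ts_coherence_pct at trial index %d", bad), call. = FALSE)
  }
  s <- signed_strengths(trials)
  tibble::tibble(
    context = as.integer(trials$ts_context == "motion"),
    rel_strength = s$rel_strength,
    irrel_strength = s$irrel_strength,
    choice = as.integer(resolved_ts_response(trials) == "middle")
  )
}

#' Pairwise design-matrix correlations
#'
#' Pearson correlations between all regressor pairs, reported both as `r` and
#' as signed shared variance `sign(r) * r^2` (the convention used to state
#' design dependencies).
#'
#' @param design A design tibble/data frame of numeric regressors.
#' @return A tibble with columns `var1`, `var2`, `r`, `signed_r2` covering all
#'   ordered pairs including the diagonal.
#' @export
design_correlations <- function(design) {
  X <- as.matrix(design)
  stopifnot(is.numeric(X), nrow(X) >= 2)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop(
      "constant column(s): ", paste(colnames(X)[sds == 0], collapse = ", "),
      " (correlation undefined)",
      call. = FALSE
    )
  }
  R <- stats::cor(X)
  tibble::tibble(
    var1 = rep(colnames(R), times = ncol(R)),
    var2 = rep(colnames(R), each = ncol(R)),
    r = as.vector(R),
    signed_r2 = as.vector(sign(R) * R^2)
  )
}
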