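#' Read and write pen trajectories
#'
#' Trajectories are tables with columns `t` (seconds, strictly increasing),
#' `x`, `y` (canvas units).  The CSV dialect has exactly the header `t,x,y`;
#' the JSON dialect is a list of records with the same fields.  Both
#' round-trip losslessly (numbers are written with full precision).
#'
#' @param path file path; format chosen by extension (`.csv` or `.json`).
#' @return `read_trajectory`: a data.frame with columns `t,x,y`.
#' @export
read_trajectory <- function(path) {
  ext <- tolower(tools::file_ext(path))
  traj <- switch(ext,
    csv  = utils::read.csv(path, colClasses = "numeric"),
    json = as.data.frame(jsonlite::fromJSON(path, simplifyVector = TRUE)),
    stop("unsupported trajectory format: ", ext)
  )
  validate_trajectory(traj)
  traj
}

#' @rdname read_trajectory
#' @param traj data.frame with columns `t,x,y`.
#' @export
write_trajectory <- function(traj, path) {
  validate_trajectory(traj)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines("t,x,y", con)
      writeLines(sprintf("%.17g,%.17g,%.17g", traj$t, traj$x, traj$y), con)
    },
    json = jsonlite::write_json(traj, path, dataframe = "rows",
                                digits = I(17)),
    stop("unsupported trajectory format: ", ext)
  )
  invisible(path)
}

validate_trajectory <- function(traj) {
  stopifnot(is.data.frame(traj), all(c("t", "x", "y") %in% names(traj)),
            all(is.finite(traj$t)), all(is.finite(traj$x)),
            all(is.finite(traj$y)))
  if (nrow(traj) > 1 && any(diff(traj$t) <= 0))
    stop("trajectory timestamps must be strictly increasing", call. = FALSE)
  invisible(traj)
}

#' Writing-angle bins
#'
#' Centres of `n` equally spaced circular bins on `[0, 2*pi)`; bin 0 is
#' centred on angle 0 and the binning wraps (bin 0 is adjacent to bin n-1).
#'
#' @param n number of bins.
#' @return numeric vector of bin centres (radians).
#' @export
angle_bins <- function(n = 16L) (seq_len(n) - 1) * 2 * pi / n

#' Belief over writing angles from recent pen samples
#'
#' The heading of the latest displacement is spread over the circular bins
#' with a von Mises kernel of concentration `kappa`; zero displacement yields
#' a uniform belief (signalling "no motion").
#'
#' @param window data.frame or matrix of recent pen samples (columns `x`,
#'   `y`), at least two rows; only the last two are used.
#' @param n_angle number of angle bins.
#' @param kappa von Mises concentration of the heading kernel.
#' @return an `hpbu_belief` over bins labelled `a0..a{n-1}`.
#' @export
angle_belief <- function(window, n_angle = 16L, kappa = 8) {
  w <- as.matrix(window[, c("x", "y"), drop = FALSE])
  stopifnot(nrow(w) >= 2)
  d <- w[nrow(w), ] - w[nrow(w) - 1, ]
  centers <- angle_bins(n_angle)
  labels <- paste0("a", seq_len(n_angle) - 1)
  if (sqrt(sum(d^2)) < 1e-12) return(uniform_belief(labels))
  theta <- atan2(d[2], d[1])
  belief(exp(kappa * cos(centers - theta)), labels)
}

#' Surprise of a new angle observation under a predictive belief
#'
#' The surprise is the negative log probability that the predictor assigns to
#' the mode bin of the current angle belief.  An event fires when the
#' surprise exceeds `threshold` (nats).
#'
#' @param pred predictive `hpbu_belief` over angle bins (e.g. the
#'   exponentially discounted mixture of past angle beliefs).
#' @param current current angle `hpbu_belief`.
#' @param threshold surprise threshold in nats.
#' @return list with elements `surprise` (nats) and `fired` (logical).
#' @export
detect_surprise <- function(pred, current, threshold = 2.5) {
  check_same_labels(pred, current)
  mode_bin <- which.max(as.numeric(current))
  s <- -log(max(as.numeric(pred)[mode_bin], 1e-300))
  list(surprise = s, fired = s > threshold)
}

#' Oculocentric transform
#'
#' Codes a planar point relative to the current gaze anchor as relative polar
#' coordinates: angle (`atan2`, radians; 0 by convention for zero
#' displacement), Euclidean length, and the elapsed time `dt`.
#'
#' @param origin,current planar points `c(x, y)`.
#' @param dt seconds since the previous event (`>= 0`).
#' @return list with `angle`, `length`, `dt`.
#' @export
to_oculocentric <- function(origin, current, dt) {
  stopifnot(dt >= 0)
  d <- as.numeric(current) - as.numeric(origin)
  len <- sqrt(sum(d^2))
  ang <- if (len < 1e-12) 0 else atan2(d[2], d[1])
  if (ang < 0) ang <- ang + 2 * pi
  list(angle = ang, length = len, dt = dt)
}

#' @rdname to_oculocentric
#' @param event list or one-row data.frame with `angle` and `length`.
#' @return `from_oculocentric`: the planar endpoint `c(x, y)`.
#' @export
from_oculocentric <- function(origin, event) {
  as.numeric(origin) +
    event$length * c(cos(event$angle), sin(event$angle))
}

empty_events <- function() {
  data.frame(angle = numeric(), length = numeric(), dt = numeric(),
             t = numeric(), x = numeric(), y = numeric())
}

#' Vision level state
#'
#' Creates the streaming state of the Vision level: the discounted angle
#' predictor, the oculocentric anchor, the per-level Kalman state, and the
#' accumulated surprise events.
#'
#' @param config an [hpbu_config()].
#' @return list of class `hpbu_vision`.
#' @export
vision_init <- function(config = hpbu_config()) {
  labels <- paste0("a", seq_len(config$n_angle) - 1)
  structure(list(
    config = config,
    pred = uniform_belief(labels),
    level = level_state(labels, config$precision$vision, "perception"),
    n_seen = 0L,
    refractory = 0L,
    prev = NULL,            # previous sample c(t, x, y)
    origin = NULL,          # oculocentric anchor
    start = NULL,
    last_event_t = NA_real_,
    events = empty_events(),
    last_surprise = NA_real_
  ), class = "hpbu_vision")
}

#' Advance the Vision level by one pen sample
#'
#' Computes the current angle belief, updates the vision-level Kalman state
#' (top-down signal: the discounted predictor; bottom-up: the new belief),
#' evaluates surprise, and — after burn-in and outside the post-event
#' refractory window — emits a surprise event anchored at the current pen
#' position, resetting the oculocentric origin there.
#'
#' @param state an `hpbu_vision`.
#' @param t time of the sample (seconds).
#' @param pos planar pen position `c(x, y)`.
#' @return the updated state; `state$new_event` is the event emitted this
#'   step (one-row data.frame) or `NULL`.
#' @export
vision_step <- function(state, t, pos) {
  cfg <- state$config
  state$new_event <- NULL
  pos <- as.numeric(pos)
  if (is.null(state$prev)) {
    state$prev <- c(t, pos)
    state$origin <- pos
    state$start <- pos
    return(state)
  }
  w <- rbind(state$prev[2:3], pos)
  colnames(w) <- c("x", "y")
  b <- angle_belief(w, cfg$n_angle, cfg$kappa_angle)
  state$level <- update_level(state$level, p_td = state$pred, p_bu = b)
  det <- detect_surprise(state$pred, b, cfg$surprise_threshold)
  state$last_surprise <- det$surprise
  moving <- max(as.numeric(b)) > 1.5 / cfg$n_angle   # non-uniform => motion
  if (det$fired && moving && state$n_seen >= cfg$n_burn &&
      state$refractory == 0L) {
    dt <- if (is.na(state$last_event_t)) 0 else t - state$last_event_t
    ev <- to_oculocentric(state$origin, pos, dt)
    state$new_event <- data.frame(angle = ev$angle, length = ev$length,
                                  dt = ev$dt, t = t, x = pos[1], y = pos[2])
    state$events <- rbind(state$events, state$new_event)
    state$origin <- pos
    state$last_event_t <- t
    state$refractory <- cfg$n_burn
  } else if (state$refractory > 0L) {
    state$refractory <- state$refractory - 1L
  }
  lam <- cfg$lambda_decay
  state$pred <- belief(lam * as.numeric(state$pred) + (1 - lam) * as.numeric(b),
                       names(state$pred))
  state$n_seen <- state$n_seen + 1L
  state$prev <- c(t, pos)
  state
}

#' Flush the terminal stroke event at trajectory end
#'
#' The pen lifting is treated as a maximally surprising boundary: the stroke
#' from the current oculocentric anchor to the final pen position is emitted
#' as a closing event (provided the pen has moved since the last event).
#'
#' @param state an `hpbu_vision` that has consumed a whole trajectory.
#' @return the updated state; `state$new_event` holds the flushed event or
#'   `NULL`.
#' @export
vision_finish <- function(state) {
  state$new_event <- NULL
  if (is.null(state$prev)) return(state)
  t <- state$prev[1]; pos <- state$prev[2:3]
  len <- sqrt(sum((pos - state$origin)^2))
  if (len < 1e-9) return(state)
  dt <- if (is.na(state$last_event_t)) 0 else t - state$last_event_t
  ev <- to_oculocentric(state$origin, pos, dt)
  state$new_event <- data.frame(angle = ev$angle, length = ev$length,
                                dt = ev$dt, t = t, x = pos[1], y = pos[2])
  state$events <- rbind(state$events, state$new_event)
  state$origin <- pos
  state$last_event_t <- t
  state
}

#' Segment a trajectory into surprise events
#'
#' Streams a full trajectory through the Vision level and returns the emitted
#' surprise events (including the terminal flush event), coded in the
#' oculocentric frame.
#'
#' @param traj data.frame with columns `t,x,y`.
#' @param config an [hpbu_config()].
#' @return data.frame with columns `angle,length,dt,t,x,y` (one row per
#'   event).
#' @export
segment_trajectory <- function(traj, config = hpbu_config()) {
  validate_trajectory(traj)
  st <- vision_init(config)
  for (i in seq_len(nrow(traj)))
    st <- vision_step(st, traj$t[i], c(traj$x[i], traj$y[i]))
  st <- vision_finish(st)
  st$events
}

#' Confirm a motor done signal against visual evidence
#'
#' Closes the long-range motor coordination loop: when Motor Control reports
#' arrival at a subgoal, the Vision level checks whether the visual stream
#' confirms the movement.  The confirmation anchor is the most recent visual
#' surprise event within `tau_confirm` seconds of the done signal if one
#' exists, otherwise the visual pen position at the done time.  The anchor
#' must lie within `r_confirm` (a fraction of the subgoal stroke length) of
#' the subgoal; otherwise nothing is forwarded and the mismatch propagates as
#' unexplained prediction error.
#'
#' @param done list with `subgoal` (planar point), `time` (s), and `length`
#'   (stroke length of the subgoal, canvas units).
#' @param vision an `hpbu_vision` that has consumed the visual stream up to
#'   the done time.
#' @param visual_sample most recent visual sample as `c(t, x, y)`, or `NULL`
#'   if the visual stream is exhausted.
#' @param origin current oculocentric anchor of the production event chain.
#' @param last_event_t time of the previously forwarded event (`NA` for the
#'   first).
#' @param config an [hpbu_config()].
#' @return a one-row event data.frame (`angle,length,dt,t,x,y`) to forward to
#'   the Sequence level, or `NULL` when confirmation fails.
#' @export
confirm_motor_done <- function(done, vision, visual_sample, origin,
                               last_event_t = NA_real_,
                               config = hpbu_config()) {
  tau <- config$tau_confirm_samples / config$sample_rate
  r <- config$r_confirm_frac * max(done$length, 1e-9)
  anchor <- NULL
  if (nrow(vision$events) > 0) {
    ev <- vision$events[nrow(vision$events), ]
    if (abs(ev$t - done$time) <= tau) anchor <- c(ev$t, ev$x, ev$y)
  }
  if (is.null(anchor) && !is.null(visual_sample) &&
      abs(visual_sample[1] - done$time) <= tau) {
    anchor <- visual_sample
  }
  if (is.null(anchor)) return(NULL)
  if (sqrt(sum((anchor[2:3] - as.numeric(done$subgoal))^2)) > r) return(NULL)
  dt <- if (is.na(last_event_t)) 0 else anchor[1] - last_event_t
  ev <- to_oculocentric(origin, anchor[2:3], max(dt, 0))
  data.frame(angle = ev$angle, length = ev$length, dt = ev$dt,
             t = anchor[1], x = anchor[2], y = anchor[3])
}
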