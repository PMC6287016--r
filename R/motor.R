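#' Motor plant parameters
#'
#' Constants of the single-joint equilibrium-point plant: a damped spring
#' toward the lookahead goal with a goal-forcing term that steers through
#' each subgoal in turn,
#' \deqn{\ddot y = \alpha(\beta(x_{i+3} - y) - \dot y) + g, \qquad
#'       g = (x_i - y)\,\dot\varphi, \qquad
#'       \dot\varphi = \gamma\,\varphi\,e^{-\mu|\varphi|},}
#' with \eqn{\varphi} the bearing to the current subgoal minus the heading
#' of the velocity, wrapped to \eqn{(-\pi, \pi]}.  At the defaults
#' (`beta = alpha/4`) the linear part is critically damped.
#'
#' @param alpha,beta,gamma,mu plant constants (defaults 25, 6.25, 10,
#'   `1/pi`).
#' @param dt_int integration step in seconds (semi-implicit Euler).
#' @param phi_mode `"heading"` computes \eqn{\varphi} relative to the
#'   velocity heading (zero-velocity convention: `g = 0`); `"bearing"` uses
#'   the absolute bearing to the subgoal.
#' @return list of class `hpbu_spring_params`.
#' @export
spring_params <- function(alpha = 25, beta = 6.25, gamma = 10, mu = 1 / pi,
                          dt_int = 1e-3, phi_mode = c("heading", "bearing")) {
  phi_mode <- match.arg(phi_mode)
  stopifnot(alpha > 0, beta > 0, gamma >= 0, mu > 0, dt_int > 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, mu = mu,
                 dt_int = dt_int, phi_mode = phi_mode),
            class = "hpbu_spring_params")
}

#' @rdname spring_params
#' @param config an [hpbu_config()]; convenience constructor from the
#'   `spring` block.
#' @export
spring_params_from_config <- function(config = hpbu_config()) {
  s <- config$spring
  spring_params(s$alpha, s$beta, s$gamma, s$mu, s$dt_int,
                if (identical(s$phi_mode, "position")) "heading" else s$phi_mode)
}

#' Motor plant state
#'
#' @param y planar pen position.
#' @param y_dot planar pen velocity.
#' @param goals matrix (or data.frame) of planar subgoals, one row each.
#' @param goal_index index of the active subgoal.
#' @param t current time (s).
#' @param deadlines optional per-goal schedule: the active goal also advances
#'   once its deadline (absolute time) has passed, which keeps the goal
#'   train moving at the pace of the sequence's timing goals.
#' @return list of class `hpbu_spring`.
#' @export
spring_state <- function(y, y_dot = c(0, 0), goals, goal_index = 1L, t = 0,
                         deadlines = NULL) {
  goals <- as.matrix(goals)
  stopifnot(ncol(goals) == 2, nrow(goals) >= 1)
  structure(list(y = as.numeric(y), y_dot = as.numeric(y_dot),
                 goals = goals, goal_index = as.integer(goal_index),
                 t = t, n_steps = 0L, deadlines = deadlines),
            class = "hpbu_spring")
}

#' Densify a stroke into a motor goal train
#'
#' The Sequence level emits one position/timing goal per stroke event; the
#' plant tracks a train of intermediate goals laid out along the straight
#' line to the event subgoal, spaced `spacing` apart, with the event timing
#' split evenly across them.  The 3-goal lookahead of the plant then stays
#' local to the stroke, and the lookahead is clamped at the event subgoal so
#' the pen plants the corner before the next stroke begins.
#'
#' @param from,to planar stroke endpoints.
#' @param dt timing goal of the stroke (seconds; `<= 0` means unscheduled).
#' @param t0 absolute start time of the stroke.
#' @param spacing goal spacing in canvas units.
#' @return list with `goals` (matrix, last row = `to`) and `deadlines`
#'   (absolute times, `Inf` when unscheduled).
#' @export
densify_stroke <- function(from, to, dt, t0, spacing = 0.05) {
  from <- as.numeric(from); to <- as.numeric(to)
  len <- sqrt(sum((to - from)^2))
  k <- max(1L, ceiling(len / spacing))
  frac <- seq_len(k) / k
  goals <- cbind(from[1] + frac * (to[1] - from[1]),
                 from[2] + frac * (to[2] - from[2]))
  deadlines <- if (is.finite(dt) && dt > 0) t0 + frac * dt
               else rep(Inf, k)
  list(goals = goals, deadlines = deadlines)
}

wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  ifelse(a == -pi, pi, a)
}

spring_accel <- function(y, y_dot, xi, xi3, p) {
  d_i <- xi - y
  speed <- sqrt(sum(y_dot^2))
  g <- c(0, 0)
  if (sqrt(sum(d_i^2)) > 1e-12 &&
      (p$phi_mode == "bearing" || speed > 1e-9)) {
    phi_goal <- atan2(d_i[2], d_i[1])
    phi <- if (p$phi_mode == "heading")
      wrap_angle(phi_goal - atan2(y_dot[2], y_dot[1]))
    else
      wrap_angle(phi_goal)
    phi_dot <- p$gamma * phi * exp(-p$mu * abs(phi))
    g <- d_i * phi_dot
  }
  p$alpha * (p$beta * (xi3 - y) - y_dot) + g
}

lookahead_goal <- function(state, ahead = 3L) {
  i <- min(state$goal_index + ahead, nrow(state$goals))
  state$goals[i, ]
}

#' One integration step of the motor plant
#'
#' Semi-implicit Euler update of the damped spring with goal forcing; the
#' lookahead target is the subgoal three positions ahead (clamped to the
#' final goal near sequence end).  With zero velocity the forcing term is
#' dropped for that step (the heading is undefined).
#'
#' @param state an `hpbu_spring` with a populated goal buffer.
#' @param params an `hpbu_spring_params`.
#' @return the updated state.
#' @export
spring_step <- function(state, params) {
  xi <- state$goals[state$goal_index, ]
  xi3 <- lookahead_goal(state)
  acc <- spring_accel(state$y, state$y_dot, xi, xi3, params)
  state$y_dot <- state$y_dot + acc * params$dt_int
  state$y <- state$y + state$y_dot * params$dt_int
  state$t <- state$t + params$dt_int
  state$n_steps <- state$n_steps + 1L
  state
}

#' Drive the pen to the final subgoal of its goal train
#'
#' Integrates the plant along the goal train in `state`: intermediate goals
#' advance when the pen comes within half the inter-goal spacing or when
#' their scheduled deadline passes (whichever is first), so the train moves
#' at the pace of the timing goals while arrivals keep spatial fidelity.
#' The final goal of the train — the event subgoal — must be reached within
#' `tolerance`; integration stops there or at `timeout` seconds, recording
#' pen samples at `sample_rate`.  The returned done signal is the long-range
#' notification to the Vision level: the subgoal, the arrival time, and
#' whether it was reached.
#'
#' @param state an `hpbu_spring` whose goal train ends at the event subgoal.
#' @param params an `hpbu_spring_params`.
#' @param tolerance arrival radius at the event subgoal (canvas units).
#' @param timeout maximum time for this subgoal (s).
#' @param sample_rate pen sampling rate (Hz).
#' @return list with `state`, `samples` (data.frame `t,x,y`), and `done`
#'   (list `subgoal`, `time`, `reached`, `length`).
#' @export
run_to_goal <- function(state, params, tolerance, timeout = 2,
                        sample_rate = 100) {
  n <- nrow(state$goals)
  target <- state$goals[n, ]
  stroke_len <- sqrt(sum((target - state$y)^2))
  spacing <- if (n >= 2)
    sqrt(sum((state$goals[2, ] - state$goals[1, ])^2)) else stroke_len
  every <- max(1L, round(1 / (sample_rate * params$dt_int)))
  t0 <- state$t
  hold_until <- if (!is.null(state$deadlines) &&
                    is.finite(state$deadlines[n])) state$deadlines[n] else -Inf
  ts <- xs <- ys <- numeric(0)
  reached <- sqrt(sum((target - state$y)^2)) < tolerance
  while ((!reached && state$t - t0 < timeout) ||
         (reached && state$t < hold_until)) {
    state <- spring_step(state, params)
    if (state$n_steps %% every == 0L) {
      ts <- c(ts, state$t); xs <- c(xs, state$y[1]); ys <- c(ys, state$y[2])
    }
    # advance intermediate goals by arrival or schedule
    while (state$goal_index < n) {
      xi <- state$goals[state$goal_index, ]
      hit <- sqrt(sum((xi - state$y)^2)) < spacing / 2
      due <- !is.null(state$deadlines) &&
        is.finite(state$deadlines[state$goal_index]) &&
        state$t >= state$deadlines[state$goal_index]
      if (hit || due) state$goal_index <- state$goal_index + 1L else break
    }
    reached <- reached || sqrt(sum((target - state$y)^2)) < tolerance
  }
  done <- list(subgoal = target, time = state$t, reached = reached,
               length = stroke_len)
  list(state = state,
       samples = data.frame(t = ts, x = xs, y = ys),
       done = done)
}

#' Play back a full goal sequence
#'
#' Convenience wrapper that visits every subgoal in order with
#' [run_to_goal()], concatenating the sampled trajectory and collecting the
#' done signals.
#'
#' @param start starting pen position.
#' @param goals matrix/data.frame of planar subgoals (one row each).
#' @param params an `hpbu_spring_params`.
#' @param config an [hpbu_config()] (tolerance fraction, timeout, sample
#'   rate).
#' @param lengths optional per-goal stroke lengths used for the relative
#'   tolerance; defaults to the distances between consecutive goals.
#' @return list with `trajectory` (data.frame `t,x,y`) and `dones` (list of
#'   done signals).
#' @export
run_goals <- function(start, goals, params = spring_params(),
                      config = hpbu_config(), lengths = NULL, dts = NULL) {
  goals <- as.matrix(goals)
  if (is.null(lengths)) {
    anchors <- rbind(as.numeric(start), goals)
    lengths <- sqrt(rowSums((goals - anchors[-nrow(anchors), , drop = FALSE])^2))
  }
  if (is.null(dts)) dts <- rep(NA_real_, nrow(goals))
  st <- NULL
  traj <- NULL
  dones <- vector("list", nrow(goals))
  for (i in seq_len(nrow(goals))) {
    from <- if (is.null(st)) as.numeric(start) else st$y
    t0 <- if (is.null(st)) 0 else st$t
    dense <- densify_stroke(from, goals[i, ],
                            if (is.na(dts[i])) 0 else dts[i], t0,
                            config$spring$goal_spacing)
    if (is.null(st)) {
      st <- spring_state(start, c(0, 0), dense$goals,
                         deadlines = dense$deadlines)
    } else {
      st$goals <- dense$goals
      st$goal_index <- 1L
      st$deadlines <- dense$deadlines
    }
    tol <- config$spring$tolerance_frac * max(lengths[i], 1e-6)
    res <- run_to_goal(st, params, tol, config$spring$timeout,
                       config$sample_rate)
    st <- res$state
    traj <- rbind(traj, res$samples)
    dones[[i]] <- res$done
  }
  list(trajectory = traj, dones = dones, state = st)
}
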