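#' Sequence hypotheses
#'
#' A sequence hypothesis is an ordered list of surprise events — relative
#' polar angle, stroke length, and inter-event delay `dt` — learned from one
#' demonstration trajectory.  The same event table built online during a
#' trial is the observed sequence it is scored against.
#'
#' @param id identifier (unique within a repertoire).
#' @param events data.frame with columns `angle` (radians), `length` (canvas
#'   units), `dt` (seconds); at least 2 rows, `dt[1] == 0`.
#' @param schema_id owning schema id (filled in by clustering).
#' @param source_digit generating digit label, kept for evaluation only.
#' @return list of class `hpbu_sequence`.
#' @export
sequence_hypothesis <- function(id, events, schema_id = NA_character_,
                                source_digit = NA_integer_) {
  events <- as.data.frame(events)[, c("angle", "length", "dt")]
  stopifnot(nrow(events) >= 2, all(events$length >= 0),
            abs(events$dt[1]) < 1e-12, all(events$dt[-1] > 0))
  structure(list(id = id, events = events, schema_id = schema_id,
                 source_digit = source_digit),
            class = "hpbu_sequence")
}

circ_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

as_events <- function(x) {
  if (inherits(x, "hpbu_sequence")) x$events else as.data.frame(x)
}

#' Spatial comparison of an observed event prefix against a hypothesis
#'
#' Aligns the observed events with the first `|observed|` events of the
#' hypothesis and scores each aligned pair with a Gaussian kernel on the
#' circular angle difference (s.d. `sigma_a`) and on the length difference
#' (s.d. `sigma_l_frac` of the stored event length).  The score \eqn{\iota}
#' is the geometric mean of the per-event kernels, hence in `[0, 1]` and
#' invariant to the prefix length; observations that overrun a shorter
#' hypothesis are penalised by `exp(-overrun_penalty)` per extra event.
#'
#' @param observed events observed so far (data.frame with
#'   `angle,length,dt`, at least one row, or an `hpbu_sequence`).
#' @param hypothesis an `hpbu_sequence` (or bare event table).
#' @param config an [hpbu_config()].
#' @return scalar \eqn{\iota \in [0, 1]}.
#' @export
compare_sequences <- function(observed, hypothesis, config = hpbu_config()) {
  obs <- as_events(observed)
  hyp <- as_events(hypothesis)
  if (nrow(obs) < 1) stop("observed sequence is empty", call. = FALSE)
  m <- nrow(obs); n <- nrow(hyp)
  k <- min(m, n)
  da <- circ_diff(obs$angle[seq_len(k)], hyp$angle[seq_len(k)])
  dl <- obs$length[seq_len(k)] - hyp$length[seq_len(k)]
  sl <- config$sigma_l_frac * pmax(hyp$length[seq_len(k)], 1e-6)
  kern <- exp(-da^2 / (2 * config$sigma_a^2)) * exp(-dl^2 / (2 * sl^2))
  iota <- exp(mean(log(pmax(kern, 1e-300))))
  if (m > n) iota <- iota * exp(-config$overrun_penalty * (m - n))
  min(max(iota, 0), 1)
}

#' Temporal-binding likelihood of an observed sequence
#'
#' Multiplies the spatial score \eqn{\iota} with a Gaussian factor on the
#' timing error of the latest event,
#' \deqn{P(s'|s_i) = \iota(s', s_i)\,
#'   e^{-(s'_{\Delta t} - s_{i,\Delta t})^2 / (2 \pi_S^2)},}
#' where \eqn{s'_{\Delta t}} is the observed delay of the newest event and
#' \eqn{s_{i,\Delta t}} the delay stored at the corresponding position of the
#' hypothesis.  The sequence-level temporal precision \eqn{\pi_S} (seconds)
#' stretches or sharpens the binding window.
#'
#' @inheritParams compare_sequences
#' @param pi_s temporal-binding precision in seconds (`> 0`); defaults to
#'   `config$pi_s_temporal`.
#' @return scalar likelihood in `[0, 1]`.
#' @export
sequence_likelihood <- function(observed, hypothesis, pi_s = NULL,
                                config = hpbu_config()) {
  if (is.null(pi_s)) pi_s <- config$pi_s_temporal
  if (!is.finite(pi_s) || pi_s <= 0)
    stop("temporal precision pi_s must be positive", call. = FALSE)
  obs <- as_events(observed)
  hyp <- as_events(hypothesis)
  iota <- compare_sequences(obs, hyp, config)
  j <- min(nrow(obs), nrow(hyp))
  ddt <- obs$dt[nrow(obs)] - hyp$dt[j]
  iota * exp(-ddt^2 / (2 * pi_s^2))
}

#' Sequence level state
#'
#' Holds the Kalman level state over all sequence hypotheses of a repertoire
#' plus the observed event sequence accumulated during the current trial.
#'
#' @param repertoire an `hpbu_repertoire` (see [train_repertoire()]).
#' @param config an [hpbu_config()].
#' @param mode `"perception"` or `"production"`.
#' @return list of class `hpbu_seqlevel`.
#' @export
sequence_level_init <- function(repertoire, config = hpbu_config(),
                                mode = "perception") {
  ids <- names(repertoire$sequences)
  structure(list(
    level = level_state(ids, config$precision$sequence, mode),
    observed = empty_events()[, c("angle", "length", "dt")],
    last_lik = stats::setNames(rep(NA_real_, length(ids)), ids),
    config = config
  ), class = "hpbu_seqlevel")
}

seq_membership <- function(repertoire) {
  vapply(repertoire$sequences, function(s) s$schema_id, character(1))
}

#' One update of the Sequence level
#'
#' Grows the observed sequence if a vision event arrived, scores all
#' hypotheses with the temporal-binding likelihood to form the bottom-up
#' posterior (prior times likelihood; without new evidence the prior carries
#' over unchanged), builds the top-down posterior by mixing the schema
#' posterior over each schema's member sequences (uniform within a schema),
#' performs the level Kalman update, and returns the upward message
#' \eqn{P_{bu}(C|S)} obtained by summing the sequence posterior within each
#' schema.
#'
#' @param state an `hpbu_seqlevel`.
#' @param schema_posterior `hpbu_belief` over schema ids.
#' @param event one-row event data.frame from the Vision level, or `NULL`.
#' @param repertoire the `hpbu_repertoire`.
#' @return list with `state` (updated) and `upward` (belief over schemas).
#' @export
update_sequence_level <- function(state, schema_posterior, event, repertoire) {
  cfg <- state$config
  membership <- seq_membership(repertoire)
  ids <- names(repertoire$sequences)
  prior <- state$level$posterior
  if (!is.null(event)) {
    state$observed <- rbind(state$observed,
                            as.data.frame(event)[, c("angle", "length", "dt")])
    lik <- vapply(repertoire$sequences, function(s)
      sequence_likelihood(state$observed, s, config = cfg), numeric(1))
    state$last_lik <- lik
    p_bu <- belief(as.numeric(prior) * pmax(lik, cfg$eps_floor), ids)
  } else {
    p_bu <- prior
  }
  sizes <- table(membership)
  w <- as.numeric(schema_posterior)[match(membership, names(schema_posterior))] /
    as.numeric(sizes[membership])
  p_td <- belief(w, ids)
  state$level <- update_level(state$level, p_td = p_td, p_bu = p_bu)
  up <- tapply(as.numeric(state$level$posterior), membership, sum)
  upward <- belief(as.numeric(up), names(up))
  list(state = state, upward = upward)
}

#' Next motor goal of an intended sequence
#'
#' Converts the `step_index`-th event of the intended sequence into a planar
#' subgoal relative to the given oculocentric anchor, together with its
#' stored timing.  Past the final event an end-of-sequence signal is
#' returned (production complete).
#'
#' @param sequence an `hpbu_sequence`.
#' @param step_index 1-based event index.
#' @param origin planar anchor point from which the event's polar
#'   coordinates are projected.
#' @return list with `end = TRUE` past the sequence end, otherwise
#'   `target` (planar point), `length`, `dt`, `angle` and `end = FALSE`.
#' @export
emit_motor_goal <- function(sequence, step_index, origin) {
  ev <- sequence$events
  if (step_index > nrow(ev)) return(list(end = TRUE))
  e <- ev[step_index, ]
  list(end = FALSE, target = from_oculocentric(origin, e),
       length = e$length, dt = e$dt, angle = e$angle)
}
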