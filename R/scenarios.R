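#' Train a repertoire from a demonstration corpus
#'
#' Each trajectory is segmented by the Vision level into a surprise-event
#' sequence and stored as a sequence hypothesis; schemas are then built by
#' single-linkage clustering on full-sequence similarity.  Trajectories
#' yielding fewer than two events are skipped with a warning.  Online
#' learning of new representations during inference is out of scope: the
#' repertoire is fixed after training.
#'
#' @param corpus an `hpbu_corpus` (see [generate_corpus()]), or a list with
#'   `trajectories` (named list of `t,x,y` data.frames) and `manifest`
#'   (data.frame with `id` and `digit`).
#' @param config an [hpbu_config()].
#' @return list of class `hpbu_repertoire` with `sequences`, `schemas`,
#'   `link_threshold`, `format`.
#' @export
train_repertoire <- function(corpus, config = hpbu_config()) {
  man <- corpus$manifest
  stopifnot(nrow(man) >= 1)
  seqs <- list()
  n <- 0L
  for (i in seq_len(nrow(man))) {
    ev <- segment_trajectory(corpus$trajectories[[man$id[i]]], config)
    if (nrow(ev) < 2) {
      warning("trajectory ", man$id[i], " yielded fewer than 2 events; skipped")
      next
    }
    n <- n + 1L
    seqs[[n]] <- sequence_hypothesis(sprintf("s%03d", n),
                                     ev[, c("angle", "length", "dt")],
                                     source_digit = man$digit[i])
  }
  if (n == 0L) stop("no trainable trajectories in corpus", call. = FALSE)
  built <- build_schemas(seqs, config$link_threshold, config)
  structure(list(sequences = built$sequences, schemas = built$schemas,
                 link_threshold = config$link_threshold,
                 format = "hpbu-repertoire-1"),
            class = "hpbu_repertoire")
}

#' Persist and restore a repertoire
#'
#' The repertoire (event sequences, schema memberships, and the clustering
#' threshold used at training time) is stored as versioned JSON.
#'
#' @param repertoire an `hpbu_repertoire`.
#' @param path JSON file path.
#' @export
save_repertoire <- function(repertoire, path) {
  payload <- list(
    format = repertoire$format,
    link_threshold = repertoire$link_threshold,
    sequences = lapply(unname(repertoire$sequences), function(s)
      list(id = s$id, schema_id = s$schema_id,
           source_digit = s$source_digit,
           angle = s$events$angle, length = s$events$length,
           dt = s$events$dt)),
    schemas = lapply(unname(repertoire$schemas), function(c)
      list(id = c$id, members = c$members))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_repertoire
#' @export
load_repertoire <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  seqs <- lapply(raw$sequences, function(s)
    sequence_hypothesis(s$id,
                        data.frame(angle = unlist(s$angle),
                                   length = unlist(s$length),
                                   dt = unlist(s$dt)),
                        schema_id = s$schema_id,
                        source_digit = s$source_digit))
  names(seqs) <- vapply(seqs, `[[`, character(1), "id")
  schemas <- lapply(raw$schemas, function(c)
    list(id = c$id, members = unlist(c$members)))
  names(schemas) <- vapply(schemas, `[[`, character(1), "id")
  structure(list(sequences = seqs, schemas = schemas,
                 link_threshold = raw$link_threshold, format = raw$format),
            class = "hpbu_repertoire")
}

#' Schema explaining a digit
#'
#' The schema holding the majority of the sequences learned from exemplars
#' of `digit` (`NA` if the digit is not represented).
#'
#' @param repertoire an `hpbu_repertoire`.
#' @param digit 0-9.
#' @return schema id or `NA`.
#' @export
digit_schema <- function(repertoire, digit) {
  src <- vapply(repertoire$sequences, function(s)
    as.integer(s$source_digit), integer(1))
  mem <- seq_membership(repertoire)
  hits <- mem[!is.na(src) & src == digit]
  if (length(hits) == 0) return(NA_character_)
  names(sort(table(hits), decreasing = TRUE))[1]
}

new_trial_log <- function(scenario, mode, digit, feedback_digit = NA) {
  structure(list(scenario = scenario, mode = mode, digit = digit,
                 feedback_digit = feedback_digit,
                 steps = NULL, seq_posterior = NULL, schema_posterior = NULL,
                 events = NULL, trajectory = NULL, soa = NULL,
                 n_goals = 0L, intended_sequence = NA_character_,
                 intended_schema = NA_character_),
            class = "hpbu_trial")
}

#' Run the perception loop on a trajectory
#'
#' Streams a trajectory through the hierarchy in perception mode: the
#' Schema level is updated first (with the previous step's upward message),
#' then the Sequence level (with the current schema posterior and the
#' previous step's vision event), then the Vision level consumes the new
#' pen sample.  The terminal stroke event is flushed and absorbed at the
#' end.  No motor goals are emitted in perception.
#'
#' @param traj trajectory data.frame `t,x,y`.
#' @param repertoire an `hpbu_repertoire`.
#' @param config an [hpbu_config()].
#' @param scenario label recorded in the log.
#' @param digit perceived digit label, for the log only.
#' @return an `hpbu_trial` log.
#' @export
run_perception <- function(traj, repertoire, config = hpbu_config(),
                           scenario = "a", digit = NA) {
  validate_trajectory(traj)
  vision <- vision_init(config)
  seq_state <- sequence_level_init(repertoire, config, "perception")
  schema_state <- schema_level_init(repertoire$schemas, config, "perception")
  upward <- NULL
  pending <- NULL
  n <- nrow(traj)
  rows <- vector("list", n + 1L)
  seq_post <- matrix(NA_real_, n + 1L, length(repertoire$sequences),
                     dimnames = list(NULL, names(repertoire$sequences)))
  sch_post <- matrix(NA_real_, n + 1L, length(repertoire$schemas),
                     dimnames = list(NULL, sort(names(repertoire$schemas))))
  step_of <- function(i, t) {
    data.frame(
      step = i, t = t,
      f_v = vision$level$free_energy,
      f_s = seq_state$level$free_energy,
      f_c = schema_state$level$free_energy,
      gain_s = seq_state$level$gain,
      seq_map = names(which.max(seq_state$level$posterior)),
      schema_map = names(which.max(schema_state$level$posterior)),
      seq_max_p = max(as.numeric(seq_state$level$posterior)),
      schema_max_p = max(as.numeric(schema_state$level$posterior)),
      event = !is.null(pending),
      surprise = vision$last_surprise
    )
  }
  for (i in seq_len(n)) {
    schema_state <- update_schema_level(schema_state, upward, NULL)
    res <- update_sequence_level(seq_state, schema_state$level$posterior,
                                 pending, repertoire)
    seq_state <- res$state
    upward <- res$upward
    vision <- vision_step(vision, traj$t[i], c(traj$x[i], traj$y[i]))
    pending <- vision$new_event
    rows[[i]] <- step_of(i, traj$t[i])
    seq_post[i, ] <- as.numeric(seq_state$level$posterior)
    sch_post[i, ] <- as.numeric(schema_state$level$posterior)
  }
  vision <- vision_finish(vision)
  pending <- vision$new_event
  schema_state <- update_schema_level(schema_state, upward, NULL)
  res <- update_sequence_level(seq_state, schema_state$level$posterior,
                               pending, repertoire)
  seq_state <- res$state
  rows[[n + 1L]] <- step_of(n + 1L, traj$t[n])
  seq_post[n + 1L, ] <- as.numeric(seq_state$level$posterior)
  sch_post[n + 1L, ] <- as.numeric(schema_state$level$posterior)

  log <- new_trial_log(scenario, "perception", digit)
  log$steps <- do.call(rbind, rows)
  log$seq_posterior <- seq_post
  log$schema_posterior <- sch_post
  log$events <- vision$events
  log$trajectory <- traj
  log
}

plan_goals <- function(events, anchor) {
  pos <- as.numeric(anchor)
  out <- matrix(NA_real_, nrow(events), 2)
  for (j in seq_len(nrow(events))) {
    pos <- from_oculocentric(pos, events[j, ])
    out[j, ] <- pos
  }
  out
}

#' Run the production loop for an intended digit
#'
#' Sets an intention on the digit's schema (gating production), selects the
#' intended sequence, and drives the motor plant through its subgoals.  The
#' Vision level consumes the visual stream — the plant's own output when
#' feedback is veridical, or a replayed trajectory of a different digit when
#' the visual feedback is substituted — and each motor done signal is
#' confirmed against that stream before an event is forwarded to the
#' Sequence level.  The sense-of-agency estimate is updated once per done
#' signal from the intended sequence's temporal-binding likelihood (zero
#' when confirmation failed) and the Sequence level's free energy.
#'
#' @param repertoire an `hpbu_repertoire`.
#' @param digit digit to produce (must be represented in the repertoire).
#' @param config an [hpbu_config()].
#' @param feedback_traj optional replayed trajectory (`t,x,y`, time-aligned
#'   to trial start) substituted for the plant's own output as visual input.
#' @param start pen start position on the canvas.
#' @param scenario label recorded in the log.
#' @param feedback_digit label of the replayed digit, for the log only.
#' @return an `hpbu_trial` log.
#' @export
run_production <- function(repertoire, digit, config = hpbu_config(),
                           feedback_traj = NULL, start = c(0.3, 0.5),
                           scenario = if (is.null(feedback_traj)) "c" else "d",
                           feedback_digit = NA) {
  schema_id <- digit_schema(repertoire, digit)
  if (is.na(schema_id))
    stop("digit ", digit, " is not represented in the repertoire",
         call. = FALSE)
  if (!is.null(feedback_traj)) {
    # replayed stream is time-aligned to trial start and anchored at the
    # production start position (both pens start at the same point)
    validate_trajectory(feedback_traj)
    feedback_traj$x <- feedback_traj$x - feedback_traj$x[1] + start[1]
    feedback_traj$y <- feedback_traj$y - feedback_traj$y[1] + start[2]
  }
  seq_state <- sequence_level_init(repertoire, config, "production")
  schema_state <- schema_level_init(repertoire$schemas, config, "production")
  intention <- set_intention(schema_id, repertoire,
                             seq_state$level$posterior, config$boost, config)
  vision <- vision_init(config)
  params <- spring_params_from_config(config)

  s_i <- repertoire$sequences[[intention$s_i]]
  n_ev <- nrow(s_i$events)
  chain_anchor <- as.numeric(start)
  st <- NULL
  upward <- NULL
  origin_prod <- as.numeric(start)
  last_t <- NA_real_
  soa <- config$soa_init
  fed <- 0L   # rows of the feedback stream already consumed
  traj <- NULL
  rows <- list()
  soa_rows <- list()
  fwd_events <- empty_events()
  seq_post <- NULL
  sch_post <- NULL
  j <- 1L
  step <- 0L
  while (j <= n_ev) {
    ev_j <- s_i$events[j, , drop = FALSE]
    target <- from_oculocentric(chain_anchor, ev_j)
    from <- if (is.null(st)) as.numeric(start) else st$y
    t0 <- if (is.null(st)) 0 else st$t
    dense <- densify_stroke(from, target, ev_j$dt, t0,
                            config$spring$goal_spacing)
    if (is.null(st)) {
      st <- spring_state(start, c(0, 0), dense$goals,
                         deadlines = dense$deadlines)
    } else {
      st$goals <- dense$goals
      st$goal_index <- 1L
      st$deadlines <- dense$deadlines
    }
    tol <- config$spring$tolerance_frac * max(ev_j$length, 1e-6)
    res <- run_to_goal(st, params, tol, config$spring$timeout,
                       config$sample_rate)
    st <- res$state
    traj <- rbind(traj, res$samples)
    done <- res$done

    # visual stream: own output (veridical) or the replayed trajectory
    if (is.null(feedback_traj)) {
      stream <- res$samples
    } else {
      sel <- which(feedback_traj$t <= done$time)
      sel <- sel[sel > fed]
      stream <- feedback_traj[sel, , drop = FALSE]
      fed <- fed + length(sel)
    }
    for (r in seq_len(nrow(stream)))
      vision <- vision_step(vision, stream$t[r],
                            c(stream$x[r], stream$y[r]))
    visual_sample <- if (is.null(feedback_traj)) {
      if (nrow(res$samples)) unlist(res$samples[nrow(res$samples), ]) else NULL
    } else if (fed > 0) {
      unlist(feedback_traj[fed, c("t", "x", "y")])
    } else NULL

    conf <- confirm_motor_done(done, vision, visual_sample, origin_prod,
                               last_t, config)
    schema_state <- update_schema_level(schema_state, upward, intention)
    res2 <- update_sequence_level(seq_state, schema_state$level$posterior,
                                  conf, repertoire)
    seq_state <- res2$state
    upward <- res2$upward
    if (!is.null(conf)) {
      fwd_events <- rbind(fwd_events, conf)
      origin_prod <- c(conf$x, conf$y)
      last_t <- conf$t
    }
    lik <- if (!is.null(conf) && nrow(seq_state$observed) > 0)
      sequence_likelihood(seq_state$observed, s_i, config = config)
    else 0
    f_s <- seq_state$level$free_energy
    gain <- kalman_gain(f_s, config$precision$sequence)
    soa <- update_soa(soa, lik, f_s, config$precision$sequence)
    step <- step + 1L
    soa_rows[[step]] <- data.frame(step = step, likelihood = lik, f_s = f_s,
                                   gain = gain, soa = soa)
    rows[[step]] <- data.frame(
      step = step, t = done$time,
      f_v = vision$level$free_energy, f_s = f_s,
      f_c = schema_state$level$free_energy,
      gain_s = seq_state$level$gain,
      seq_map = names(which.max(seq_state$level$posterior)),
      schema_map = names(which.max(schema_state$level$posterior)),
      seq_max_p = max(as.numeric(seq_state$level$posterior)),
      schema_max_p = max(as.numeric(schema_state$level$posterior)),
      event = !is.null(conf), reached = done$reached,
      intended = intention$s_i
    )
    seq_post <- rbind(seq_post, as.numeric(seq_state$level$posterior))
    sch_post <- rbind(sch_post, as.numeric(schema_state$level$posterior))
    # within-schema handover of the intended sequence
    before <- intention$s_i
    intention <- maybe_switch_intention(intention, seq_state$level$posterior,
                                        repertoire, config)
    if (intention$s_i != before) {
      s_i <- repertoire$sequences[[intention$s_i]]
      n_ev <- nrow(s_i$events)
    }
    chain_anchor <- as.numeric(done$subgoal)
    j <- j + 1L
  }
  intention$active <- FALSE

  log <- new_trial_log(scenario, "production", digit, feedback_digit)
  log$steps <- do.call(rbind, rows)
  log$soa <- do.call(rbind, soa_rows)
  log$seq_posterior <- seq_post
  log$schema_posterior <- sch_post
  log$events <- fwd_events
  log$trajectory <- traj
  log$n_goals <- step
  log$intended_sequence <- intention$s_i
  log$intended_schema <- intention$target_schema
  log$vision_events <- vision$events
  log
}

#' Run one of the four simulation scenarios
#'
#' * `a` — perceive a known digit (default 5).
#' * `b` — perceive a digit written in a way unknown to the repertoire
#'   (default 4, which the standard training corpus excludes).
#' * `c` — produce a digit with veridical visual feedback (default 9).
#' * `d` — produce one digit (default 1) while the Vision level receives the
#'   replayed trajectory of a different, known digit (default 3);
#'   proprioception (internal to the plant) remains correct.
#'
#' @param scenario `"a"`, `"b"`, `"c"` or `"d"`.
#' @param repertoire a trained `hpbu_repertoire`.
#' @param config an [hpbu_config()].
#' @param seed integer seed for the stimulus/feedback exemplar.
#' @param digit perceived (a, b) or produced (c, d) digit; defaults mirror
#'   the standard scenario set.
#' @param feedback_digit replayed digit for scenario d (default 3); must
#'   differ from `digit` and be known to the repertoire.
#' @param noise exemplar noise levels for generated stimuli.
#' @param out_dir optional directory to write the trial log to.
#' @return an `hpbu_trial` log.
#' @export
run_scenario <- function(scenario = c("a", "b", "c", "d"), repertoire,
                         config = hpbu_config(), seed = 1, digit = NULL,
                         feedback_digit = NULL,
                         noise = list(angle = 0.1, scale = 0.05,
                                      timing = 0.05),
                         out_dir = NULL) {
  scenario <- match.arg(scenario)
  tmpl <- digit_templates()
  if (is.null(digit))
    digit <- switch(scenario, a = 5, b = 4, c = 9, d = 1)
  log <- switch(scenario,
    a = ,
    b = {
      traj <- generate_digit(tmpl[[as.character(digit)]], seed = seed,
                             noise = noise)
      run_perception(traj, repertoire, config, scenario, digit)
    },
    c = run_production(repertoire, digit, config, scenario = "c"),
    d = {
      if (is.null(feedback_digit)) feedback_digit <- 3
      if (feedback_digit == digit)
        stop("scenario d requires a feedback digit different from the ",
             "produced digit", call. = FALSE)
      if (is.na(digit_schema(repertoire, feedback_digit)))
        stop("scenario d requires the feedback digit to be known to the ",
             "repertoire", call. = FALSE)
      fb <- generate_digit(tmpl[[as.character(feedback_digit)]], seed = seed,
                           noise = noise)
      run_production(repertoire, digit, config, feedback_traj = fb,
                     scenario = "d", feedback_digit = feedback_digit)
    })
  if (!is.null(out_dir)) write_trial_log(log, out_dir)
  log
}

#' Write a trial log to disk
#'
#' Per-step records, events, the trajectory, and (for production trials) the
#' agency trace are written as CSV; scenario metadata as JSON.  Output is
#' deterministic for identical trials.
#'
#' @param log an `hpbu_trial`.
#' @param dir output directory (created if needed).
#' @export
write_trial_log <- function(log, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(log$steps, file.path(dir, "steps.csv"), row.names = FALSE)
  utils::write.csv(log$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  write_trajectory(log$trajectory, file.path(dir, "trajectory.csv"))
  if (!is.null(log$soa))
    utils::write.csv(log$soa, file.path(dir, "soa.csv"), row.names = FALSE)
  meta <- list(scenario = log$scenario, mode = log$mode, digit = log$digit,
               feedback_digit = log$feedback_digit,
               n_goals = log$n_goals,
               intended_sequence = log$intended_sequence,
               intended_schema = log$intended_schema)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Summarize trial logs
#'
#' One row per trial: terminal free energy per level, the chosen schema,
#' event counts, and (for production trials) final and peak sense of agency.
#' Fields that do not apply (no agency trace in perception) are `NA`, not
#' zero.
#'
#' @param logs list of `hpbu_trial` objects.
#' @return data.frame, one row per log.
#' @export
summarize_trials <- function(logs) {
  stopifnot(length(logs) >= 1)
  do.call(rbind, lapply(logs, function(lg) {
    last <- lg$steps[nrow(lg$steps), ]
    data.frame(
      scenario = lg$scenario, mode = lg$mode, digit = lg$digit,
      feedback_digit = lg$feedback_digit,
      n_steps = nrow(lg$steps),
      n_events = nrow(lg$events),
      terminal_f_v = last$f_v, terminal_f_s = last$f_s,
      terminal_f_c = last$f_c,
      chosen_schema = last$schema_map,
      final_soa = if (is.null(lg$soa)) NA_real_
                  else lg$soa$soa[nrow(lg$soa)],
      peak_soa = if (is.null(lg$soa)) NA_real_ else max(lg$soa$soa)
    )
  }))
}
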