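#' Elastic full-sequence similarity
#'
#' Symmetric similarity between two complete event sequences used for
#' schema clustering: a global alignment over events with the same Gaussian
#' match kernel as [compare_sequences()] and a fixed per-event gap factor
#' `exp(-gap_penalty)`, normalised as a geometric mean over the longer
#' sequence.  Unlike the online prefix score, a single dropped or extra
#' event costs one gap rather than shifting every later comparison, which
#' keeps exemplars of the same digit together when segmentation wobbles by
#' one event.
#'
#' @param a,b `hpbu_sequence` objects or bare event tables.
#' @param config an [hpbu_config()].
#' @return scalar similarity in `[0, 1]`; 1 for identical sequences.
#' @export
elastic_iota <- function(a, b, config = hpbu_config()) {
  ea <- as_events(a); eb <- as_events(b)
  na <- nrow(ea); nb <- nrow(eb)
  gap <- -config$gap_penalty
  # log match kernel for every event pair
  da <- outer(ea$angle, eb$angle, circ_diff)
  dl <- outer(ea$length, eb$length, `-`)
  sl <- config$sigma_l_frac *
    pmax(matrix(eb$length, na, nb, byrow = TRUE), 1e-6)
  lk <- -da^2 / (2 * config$sigma_a^2) - dl^2 / (2 * sl^2)
  dp <- matrix(-Inf, na + 1L, nb + 1L)
  dp[1, ] <- gap * (0:nb)
  dp[, 1] <- gap * (0:na)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      dp[i + 1, j + 1] <- max(dp[i, j] + lk[i, j],
                              dp[i, j + 1] + gap,
                              dp[i + 1, j] + gap)
    }
  }
  min(exp(dp[na + 1, nb + 1] / max(na, nb)), 1)
}

#' Pairwise full-sequence similarity
#'
#' [elastic_iota()] between every pair of stored sequences.
#'
#' @param sequences list of `hpbu_sequence` objects.
#' @param config an [hpbu_config()].
#' @return symmetric numeric matrix with unit diagonal.
#' @export
pairwise_iota <- function(sequences, config = hpbu_config()) {
  n <- length(sequences)
  m <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        m[i, j] <- m[j, i] <- elastic_iota(sequences[[i]], sequences[[j]],
                                           config)
      }
    }
  }
  rownames(m) <- colnames(m) <- vapply(sequences, `[[`, character(1), "id")
  m
}

#' Cluster sequences into schemas
#'
#' Single-linkage agglomerative clustering on the distance `1 - iota`,
#' cutting all links with similarity below `link_threshold`.  The result is
#' a partition of the repertoire: each sequence belongs to exactly one
#' schema.  Schema ids are assigned in order of first member appearance, so
#' the clustering is deterministic for a given input order.
#'
#' @param sequences list of `hpbu_sequence` objects (at least one).
#' @param link_threshold similarity cut in `[0, 1]`; defaults to
#'   `config$link_threshold`.
#' @param config an [hpbu_config()].
#' @return list with `schemas` (named list of `id`, `members`) and
#'   `sequences` (the input with `schema_id` filled in).
#' @export
build_schemas <- function(sequences, link_threshold = NULL,
                          config = hpbu_config()) {
  stopifnot(length(sequences) >= 1)
  if (is.null(link_threshold)) link_threshold <- config$link_threshold
  ids <- vapply(sequences, `[[`, character(1), "id")
  if (length(sequences) == 1) {
    cl <- 1L
  } else {
    sim <- pairwise_iota(sequences, config)
    hc <- stats::hclust(stats::as.dist(1 - sim), method = "single")
    cl <- stats::cutree(hc, h = 1 - link_threshold)
  }
  # relabel clusters by order of first appearance
  cl <- as.integer(factor(cl, levels = unique(cl)))
  schema_ids <- sprintf("c%02d", cl)
  schemas <- lapply(sort(unique(schema_ids)), function(cid) {
    list(id = cid, members = ids[schema_ids == cid])
  })
  names(schemas) <- vapply(schemas, `[[`, character(1), "id")
  for (i in seq_along(sequences)) sequences[[i]]$schema_id <- schema_ids[i]
  names(sequences) <- ids
  list(schemas = schemas, sequences = sequences)
}

#' Schema level state
#'
#' @param schemas named list of schemas (`id`, `members`).
#' @param config an [hpbu_config()].
#' @param mode `"perception"` or `"production"`.
#' @return list of class `hpbu_schemalevel`.
#' @export
schema_level_init <- function(schemas, config = hpbu_config(),
                              mode = "perception") {
  ids <- sort(names(schemas))
  structure(list(
    level = level_state(ids, config$precision$schema, mode),
    config = config
  ), class = "hpbu_schemalevel")
}

#' One update of the Schema level
#'
#' The bottom-up posterior is the upward message from the Sequence level
#' (or, lacking one, the empirical prior); the top-down posterior is the
#' empirical prior itself — the Schema level is the top of the hierarchy.
#' After the Kalman update, an active intention multiplies the target
#' schema's posterior by its boost factor and renormalizes; the boost is
#' maintained every step while the intention is active.
#'
#' @param state an `hpbu_schemalevel`.
#' @param upward belief over schema ids from the Sequence level, or `NULL`.
#' @param intention an `hpbu_intention` or `NULL`.
#' @return the updated state.
#' @export
update_schema_level <- function(state, upward, intention = NULL) {
  prior <- state$level$posterior
  p_bu <- if (is.null(upward)) prior else {
    check_same_labels(upward, prior)
    upward
  }
  state$level <- update_level(state$level, p_td = prior, p_bu = p_bu)
  if (!is.null(intention) && isTRUE(intention$active)) {
    p <- as.numeric(state$level$posterior)
    names(p) <- names(state$level$posterior)
    p[intention$target_schema] <- p[intention$target_schema] * intention$boost
    state$level$posterior <- belief(p, names(p))
  }
  state
}

#' Set a motor intention
#'
#' The intention gating signal licenses production: it marks a target
#' schema, selects the member sequence with the highest current sequence
#' posterior (ties broken by lowest id) as the intended sequence, and — while
#' active — maintains a multiplicative probability boost of the target schema
#' at every Schema-level update.  Without an intention the hierarchy never
#' emits motor goals.
#'
#' @param schema_id id of an existing schema.
#' @param repertoire the `hpbu_repertoire`.
#' @param seq_posterior current belief over sequences (used for the intended-
#'   sequence pick); `NULL` means uniform, i.e. lowest member id.
#' @param boost multiplicative factor `>= 1`; defaults to `config$boost`.
#' @param config an [hpbu_config()].
#' @return list of class `hpbu_intention` with `target_schema`, `boost`,
#'   `active`, `s_i` (intended sequence id).
#' @export
set_intention <- function(schema_id, repertoire, seq_posterior = NULL,
                          boost = NULL, config = hpbu_config()) {
  if (is.null(boost)) boost <- config$boost
  if (!schema_id %in% names(repertoire$schemas))
    stop("unknown schema: ", schema_id, call. = FALSE)
  stopifnot(boost >= 1)
  members <- sort(repertoire$schemas[[schema_id]]$members)
  s_i <- if (is.null(seq_posterior)) members[1] else {
    p <- as.numeric(seq_posterior)[match(members, names(seq_posterior))]
    members[which.max(p)]   # which.max takes the first (lowest id) on ties
  }
  structure(list(target_schema = schema_id, boost = boost,
                 active = TRUE, s_i = s_i),
            class = "hpbu_intention")
}

#' Within-schema switch of the intended sequence
#'
#' During production the intended sequence may hand over to another member
#' of the same schema when that member's posterior exceeds the intended
#' one's by `config$switch_factor`.
#'
#' @param intention an active `hpbu_intention`.
#' @param seq_posterior current belief over sequences.
#' @param repertoire the `hpbu_repertoire`.
#' @param config an [hpbu_config()].
#' @return the (possibly updated) intention.
#' @export
maybe_switch_intention <- function(intention, seq_posterior, repertoire,
                                   config = hpbu_config()) {
  if (!isTRUE(intention$active)) return(intention)
  members <- sort(repertoire$schemas[[intention$target_schema]]$members)
  p <- as.numeric(seq_posterior)[match(members, names(seq_posterior))]
  best <- members[which.max(p)]
  if (best != intention$s_i &&
      max(p) > config$switch_factor * p[match(intention$s_i, members)]) {
    intention$s_i <- best
  }
  intention
}
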