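#' Discrete beliefs
#'
#' A belief is a normalized probability distribution over a finite, labelled
#' hypothesis set, represented as a named numeric vector of class
#' `hpbu_belief`.  Probabilities are floored at `eps` (so that no hypothesis
#' ever has exactly zero mass, which would make surprise infinite) and then
#' renormalized.
#'
#' @param probs non-negative numeric vector.
#' @param labels character vector of unique hypothesis labels; defaults to
#'   `names(probs)` or `h1..hn`.
#' @param eps probability floor, strictly positive.
#' @return named numeric vector of class `hpbu_belief`, summing to 1.
#' @export
#' @examples
#' belief(c(3, 1), c("a", "b"))
belief <- function(probs, labels = NULL, eps = 1e-10) {
  if (is.null(labels)) labels <- names(probs)
  if (is.null(labels)) labels <- paste0("h", seq_along(probs))
  stopifnot(length(labels) == length(probs), !anyDuplicated(labels),
            all(is.finite(probs)), all(probs >= 0), eps > 0)
  p <- pmax(as.numeric(probs), eps)
  p <- p / sum(p)
  names(p) <- labels
  class(p) <- "hpbu_belief"
  p
}

#' @rdname belief
#' @param x object to test.
#' @export
is_belief <- function(x) inherits(x, "hpbu_belief")

#' @rdname belief
#' @export
uniform_belief <- function(labels, eps = 1e-10) {
  belief(rep(1, length(labels)), labels, eps)
}

#' @rdname belief
#' @param on label receiving (almost) all mass.
#' @export
point_belief <- function(labels, on, eps = 1e-10) {
  stopifnot(on %in% labels)
  belief(as.numeric(labels == on), labels, eps)
}

#' @export
print.hpbu_belief <- function(x, ...) {
  cat("<belief over", length(x), "hypotheses>\n")
  print(round(unclass(x), 4), ...)
  invisible(x)
}

check_same_labels <- function(p, q) {
  if (length(p) != length(q) || !identical(names(p), names(q)))
    stop("beliefs are defined over different label sets", call. = FALSE)
}

#' Variational free energy of a belief pair
#'
#' Free energy is the sum of the surprise (entropy of the posterior) and the
#' KL divergence of the posterior from the prior,
#' \deqn{F = H(P) + D_{KL}(P \| Q) = -\sum_i P_i \ln Q_i,}
#' i.e. the cross entropy of `posterior` under `prior`, in nats.  It is zero
#' only for point-mass agreement and equals \eqn{H(P)} exactly when
#' \eqn{P = Q}.
#'
#' @param posterior,prior beliefs over the same label set.
#' @param eps probability floor applied before the logarithm.
#' @return non-negative scalar (nats).
#' @export
#' @examples
#' u <- uniform_belief(letters[1:4])
#' free_energy(u, u) # = log(4)
free_energy <- function(posterior, prior, eps = 1e-10) {
  check_same_labels(posterior, prior)
  p <- pmax(as.numeric(posterior), eps); p <- p / sum(p)
  q <- pmax(as.numeric(prior), eps);     q <- q / sum(q)
  f <- -sum(p * log(q))
  max(f, 0)
}

#' Free-energy weighted Kalman gain
#'
#' The gain \eqn{K = F/(F+\pi)} that weights the mixing of top-down and
#' bottom-up posteriors; it lies in `[0, 1)`, grows with free energy (more
#' unexplained prediction error shifts weight to the non-driving signal) and
#' shrinks with precision.
#'
#' @param f free energy, non-negative scalar.
#' @param precision level precision \eqn{\pi > 0}.
#' @return scalar gain in `[0, 1)`.
#' @export
kalman_gain <- function(f, precision) {
  if (!is.finite(precision) || precision <= 0)
    stop("precision must be a positive scalar", call. = FALSE)
  stopifnot(is.finite(f), f >= 0)
  f / (f + precision)
}

#' Mix two beliefs with a Kalman gain
#'
#' In perception the bottom-up signal drives and the top-down signal corrects:
#' \eqn{P_t = P_{bu} + K (P_{td} - P_{bu})}; in production the roles invert.
#' Since \eqn{K \in [0,1)} the result is a convex combination and hence a
#' normalized distribution.
#'
#' @param p_td,p_bu top-down and bottom-up beliefs over the same labels.
#' @param gain Kalman gain in `[0, 1)`.
#' @param mode `"perception"` or `"production"`.
#' @return an `hpbu_belief`.
#' @export
belief_mix <- function(p_td, p_bu, gain, mode = c("perception", "production")) {
  mode <- match.arg(mode)
  check_same_labels(p_td, p_bu)
  stopifnot(gain >= 0, gain < 1)
  p <- if (mode == "perception") {
    as.numeric(p_bu) + gain * (as.numeric(p_td) - as.numeric(p_bu))
  } else {
    as.numeric(p_td) + gain * (as.numeric(p_bu) - as.numeric(p_td))
  }
  belief(p, names(p_td))
}

#' Level state
#'
#' Bundles the per-level quantities of the hierarchy: the previous posterior
#' (used as empirical prior), the current posterior, free energy, precision,
#' gain, and the update mode.
#'
#' @param labels hypothesis labels of the level.
#' @param precision level precision \eqn{\pi > 0}.
#' @param mode `"perception"` or `"production"`.
#' @param prior optional initial belief (default uniform).
#' @return list of class `hpbu_level`.
#' @export
level_state <- function(labels, precision, mode = "perception", prior = NULL) {
  if (is.null(prior)) prior <- uniform_belief(labels)
  stopifnot(precision > 0)
  structure(list(
    prior = prior, posterior = prior,
    free_energy = 0, precision = precision,
    gain = 0, mode = mode
  ), class = "hpbu_level")
}

#' One belief-update step of a hierarchy level
#'
#' Computes the level free energy from the driving/correcting pair, derives
#' the Kalman gain from free energy and the level precision, and mixes the
#' two posteriors into the new level posterior.  In perception the free
#' energy is \eqn{H(P_{td}) + D_{KL}(P_{td}\|P_{bu})} and the bottom-up
#' signal drives the mix; in production the roles of the two signals are
#' swapped.  The new posterior is stored and serves as the empirical prior
#' of the next step.
#'
#' @param state an `hpbu_level`.
#' @param p_td,p_bu top-down and bottom-up beliefs over the level's labels.
#' @return the updated `hpbu_level`.
#' @export
update_level <- function(state, p_td, p_bu) {
  stopifnot(inherits(state, "hpbu_level"))
  check_same_labels(p_td, p_bu)
  f <- if (state$mode == "perception") free_energy(p_td, p_bu)
       else                            free_energy(p_bu, p_td)
  k <- kalman_gain(f, state$precision)
  post <- belief_mix(p_td, p_bu, k, state$mode)
  state$prior <- state$posterior
  state$posterior <- post
  state$free_energy <- f
  state$gain <- k
  state
}
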