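#' One Kalman update of the sense-of-agency estimate
#'
#' The agency estimate \eqn{\hat a_t} tracks the temporal-binding likelihood
#' of the intended sequence through a Kalman filter whose gain is governed by
#' the Sequence level's free energy and precision:
#' \deqn{K_t = \frac{F_S}{F_S + \pi_S}, \qquad
#'       \hat a_t = \hat a_{t-1} + K_t\,(P(s'|s_I) - \hat a_{t-1}).}
#' Because the update is convex, strong fluctuations are dampened: the
#' one-step change never exceeds \eqn{K_t}.
#'
#' @param prev previous estimate \eqn{\hat a_{t-1} \in [0, 1]}.
#' @param likelihood \eqn{P(s'|s_I) \in [0, 1]}, the likelihood of the
#'   observed sequence under the intended one.
#' @param f_s Sequence-level free energy (nats, `>= 0`).
#' @param pi_s Sequence-level precision (`> 0`).
#' @return updated estimate \eqn{\hat a_t \in [0, 1]}.
#' @export
update_soa <- function(prev, likelihood, f_s, pi_s) {
  if (!is.finite(prev) || prev < 0 || prev > 1)
    stop("previous agency estimate must lie in [0, 1]", call. = FALSE)
  if (!is.finite(likelihood) || likelihood < 0 || likelihood > 1)
    stop("likelihood must lie in [0, 1]", call. = FALSE)
  if (!is.finite(f_s) || f_s < 0)
    stop("free energy must be non-negative", call. = FALSE)
  k <- kalman_gain(f_s, pi_s)
  prev + k * (likelihood - prev)
}

#' Accumulate a sense-of-agency trace over a trial
#'
#' Folds [update_soa()] over per-step records of the intended-sequence
#' likelihood and the Sequence-level free energy.  The estimate is updated
#' once per Sequence-level update step (event-driven), not per pen sample.
#'
#' @param likelihoods numeric vector of per-step \eqn{P(s'|s_I)}.
#' @param free_energies numeric vector of per-step \eqn{F_S} (same length).
#' @param pi_s Sequence-level precision (`> 0`).
#' @param a0 initial estimate (default 0).
#' @return data.frame with columns `step`, `likelihood`, `f_s`, `gain`,
#'   `soa`; zero rows for an empty trial.
#' @export
run_agency <- function(likelihoods, free_energies, pi_s, a0 = 0) {
  stopifnot(length(likelihoods) == length(free_energies))
  n <- length(likelihoods)
  gains <- soa <- numeric(n)
  a <- a0
  for (i in seq_len(n)) {
    gains[i] <- kalman_gain(free_energies[i], pi_s)
    a <- update_soa(a, likelihoods[i], free_energies[i], pi_s)
    soa[i] <- a
  }
  data.frame(step = seq_len(n), likelihood = likelihoods,
             f_s = free_energies, gain = gains, soa = soa)
}
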