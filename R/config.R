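#' Model configuration
#'
#' Builds the full set of tunable constants used across the hierarchy.  Every
#' constant the model uses is surfaced here; nothing is hard-coded elsewhere.
#' Values can be overridden individually, or loaded from a YAML/JSON file with
#' [load_config()].
#'
#' @param ... named overrides for any top-level or nested entry, e.g.
#'   `precision = list(sequence = 2)` or `surprise_threshold = 3`.
#'
#' @details The main groups are:
#' * `precision`: per-level precision \eqn{\pi} entering the Kalman gain
#'   \eqn{K = F/(F+\pi)} (vision 1, sequence 1, schema 2).
#' * `eps_floor`: probability floor applied before any logarithm (1e-10).
#' * `n_angle`, `kappa_angle`: number of circular writing-angle bins and the
#'   von Mises concentration of the heading kernel (16 bins; kappa chosen so
#'   roughly 90% of kernel mass falls on the true bin and its two neighbours).
#' * `lambda_decay`, `surprise_threshold`, `n_burn`: event segmentation —
#'   exponential decay of the angle predictor, surprise threshold in nats,
#'   and the burn-in/refractory length in samples.
#' * `sigma_a`, `sigma_l_frac`, `overrun_penalty`: sequence comparison kernel
#'   widths (circular angle s.d.; length s.d. as a fraction of the stored
#'   event length) and the per-extra-event overrun penalty; `gap_penalty`
#'   is the per-gap cost of the elastic alignment used for clustering.
#' * `pi_s_temporal`: temporal-binding width \eqn{\pi_S} in seconds.
#' * `link_threshold`: schema clustering cut on full-sequence similarity.
#' * `boost`, `switch_factor`: intention gating boost (applied each step while
#'   active) and the posterior ratio at which the intended sequence may switch
#'   within its schema.
#' * `spring`: motor plant constants `alpha`, `beta`, `gamma`, `mu`, the
#'   integration step `dt_int`, `phi_mode` (`"position"` or `"velocity"`),
#'   goal `tolerance_frac` (fraction of stroke length), per-goal `timeout`
#'   in seconds and the pen `sample_rate` in Hz.
#' * `tau_confirm_samples`, `r_confirm_frac`: the vision-side confirmation
#'   window for the long-range motor done signal (in sampling periods, and as
#'   a fraction of the subgoal stroke length).
#' * `soa_init`: initial sense-of-agency estimate.
#'
#' @return a nested list of class `hpbu_config`.
#' @export
#' @examples
#' cfg <- hpbu_config(surprise_threshold = 3)
#' cfg$surprise_threshold
hpbu_config <- function(...) {
  cfg <- list(
    precision = list(vision = 1.0, sequence = 8.0, schema = 2.0),
    eps_floor = 1e-10,
    n_angle = 16L,
    kappa_angle = 8,
    lambda_decay = 0.8,
    surprise_threshold = 2.5,
    n_burn = 3L,
    sigma_a = 2 * pi / 16,
    sigma_l_frac = 0.25,
    overrun_penalty = 0.5,
    gap_penalty = 1.0,
    pi_s_temporal = 0.15,
    link_threshold = 0.6,
    boost = 3.0,
    switch_factor = 2.0,
    soa_init = 0,
    sample_rate = 100,
    tau_confirm_samples = 2,
    r_confirm_frac = 0.25,
    spring = list(
      alpha = 25, beta = 6.25, gamma = 10, mu = 1 / pi,
      dt_int = 1e-3, phi_mode = "position",
      tolerance_frac = 0.05, timeout = 2, goal_spacing = 0.05
    )
  )
  cfg <- modifyList(cfg, list(...))
  class(cfg) <- "hpbu_config"
  cfg
}

#' Load a configuration file
#'
#' Reads per-level precisions and all other model constants from a YAML or
#' JSON file and merges them over the defaults of [hpbu_config()].
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return an `hpbu_config` list.
#' @export
load_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml  = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config format: ", ext)
  )
  cfg <- modifyList(hpbu_config(), raw)
  class(cfg) <- "hpbu_config"
  cfg
}
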