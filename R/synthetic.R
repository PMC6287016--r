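#' Single-stroke digit templates
#'
#' Parametric templates for the digits 0-9, each a single pen-down stroke
#' through an ordered control polygon on a unit canvas with a nominal
#' duration.  Digits that are usually written with a pen lift (4, 5) use
#' cursive one-stroke forms, since the hierarchy has no pen-up concept.
#' Corners of the control polygon become the surprising stroke events the
#' Vision level segments.
#'
#' @return named list (`"0"`..`"9"`) of templates, each a list with
#'   `digit`, `points` (n x 2 matrix), `duration` (s).
#' @export
digit_templates <- function() {
  pts <- list(
    "0" = c(0.50, 0.90, 0.14, 0.48, 0.50, 0.06, 0.86, 0.48, 0.52, 0.88),
    "1" = c(0.32, 0.68, 0.55, 0.90, 0.55, 0.10),
    "2" = c(0.20, 0.60, 0.45, 0.90, 0.75, 0.70, 0.25, 0.10, 0.80, 0.10),
    "3" = c(0.20, 0.86, 0.68, 0.90, 0.74, 0.64, 0.48, 0.55, 0.76, 0.40,
            0.58, 0.08, 0.22, 0.22),
    "4" = c(0.62, 0.90, 0.20, 0.42, 0.80, 0.42, 0.66, 0.62, 0.66, 0.08),
    "5" = c(0.78, 0.90, 0.26, 0.90, 0.24, 0.58, 0.64, 0.64, 0.74, 0.28,
            0.40, 0.10, 0.20, 0.38),
    "6" = c(0.70, 0.90, 0.26, 0.12, 0.62, 0.10, 0.66, 0.42, 0.30, 0.36),
    "7" = c(0.20, 0.86, 0.80, 0.86, 0.38, 0.08),
    "8" = c(0.66, 0.86, 0.30, 0.86, 0.36, 0.54, 0.70, 0.54, 0.60, 0.08,
            0.28, 0.12, 0.66, 0.32, 0.50, 0.80),
    "9" = c(0.74, 0.78, 0.36, 0.88, 0.24, 0.56, 0.62, 0.50, 0.70, 0.80,
            0.60, 0.06)
  )
  durs <- c("0" = 3.6, "1" = 1.9, "2" = 3.4, "3" = 3.3, "4" = 3.4,
            "5" = 3.7, "6" = 3.2, "7" = 2.5, "8" = 4.5, "9" = 3.6)
  out <- lapply(names(pts), function(d) {
    m <- matrix(pts[[d]], ncol = 2, byrow = TRUE)
    colnames(m) <- c("x", "y")
    list(digit = as.integer(d), points = m, duration = unname(durs[d]))
  })
  names(out) <- names(pts)
  out
}

# light corner-preserving smoothing of a dense polyline
smooth_polyline <- function(m, passes = 2L) {
  n <- nrow(m)
  if (n < 3) return(m)
  for (p in seq_len(passes)) {
    interior <- 2:(n - 1)
    m[interior, ] <- (m[interior - 1, ] + 2 * m[interior, ] +
                        m[interior + 1, ]) / 4
  }
  m
}

# resample a control polygon into a dense arc-length parameterised polyline
densify <- function(points, n_fine = 800L) {
  seg <- diff(points)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  total <- cum[length(cum)]
  s <- seq(0, total, length.out = n_fine)
  x <- stats::approx(cum, points[, 1], xout = s)$y
  y <- stats::approx(cum, points[, 2], xout = s)$y
  cbind(x = x, y = y)
}

min_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

#' Generate one noisy digit exemplar
#'
#' Jitters the template's control polygon (each segment's direction rotated
#' by a zero-mean Gaussian angle, each segment length scaled by a zero-mean
#' Gaussian factor, the total duration scaled likewise), interpolates the
#' jittered polygon into a smooth-curvature path, and samples it at
#' `sampling_rate` with a bell-shaped (minimum-jerk) speed profile.
#' Deterministic for a given seed; with all noise levels zero the noiseless
#' template path is returned.
#'
#' @param template one element of [digit_templates()].
#' @param seed integer seed (`NULL` leaves the RNG state alone).
#' @param noise list with `angle` (rad), `scale` (fraction), `timing`
#'   (fraction) standard deviations.
#' @param sampling_rate pen sampling rate in Hz.
#' @return trajectory data.frame `t,x,y`.
#' @export
generate_digit <- function(template, seed = NULL,
                           noise = list(angle = 0.1, scale = 0.05,
                                        timing = 0.05),
                           sampling_rate = 100) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  pts <- template$points
  seg <- diff(pts)
  ang <- atan2(seg[, 2], seg[, 1])
  len <- sqrt(rowSums(seg^2))
  k <- length(ang)
  ang <- ang + stats::rnorm(k, 0, noise$angle)
  len <- len * pmax(1 + stats::rnorm(k, 0, noise$scale), 0.1)
  jit <- apply(rbind(pts[1, ],
                     cbind(len * cos(ang), len * sin(ang))), 2, cumsum)
  dur <- template$duration * max(1 + stats::rnorm(1, 0, noise$timing), 0.2)
  path <- smooth_polyline(densify(jit))
  seg2 <- diff(path)
  cum <- c(0, cumsum(sqrt(rowSums(seg2^2))))
  total <- cum[length(cum)]
  t <- seq(0, dur, by = 1 / sampling_rate)
  s <- min_jerk(t / dur) * total
  data.frame(t = t,
             x = stats::approx(cum, path[, 1], xout = s, ties = "ordered")$y,
             y = stats::approx(cum, path[, 2], xout = s, ties = "ordered")$y)
}

#' Corpus specification
#'
#' @param digits digits to include (subset of 0-9); exclusions are honoured
#'   by simply listing fewer digits.
#' @param n_per_digit exemplars per digit.
#' @param noise noise levels as in [generate_digit()].
#' @param master_seed master seed; per-exemplar child seeds are derived from
#'   it with a counter and recorded in the manifest.
#' @return list of class `hpbu_corpus_spec`.
#' @export
corpus_spec <- function(digits = 0:9, n_per_digit = 10,
                        noise = list(angle = 0.1, scale = 0.05,
                                     timing = 0.05),
                        master_seed = 0) {
  stopifnot(length(digits) >= 1, all(digits %in% 0:9), n_per_digit >= 1)
  structure(list(digits = sort(unique(as.integer(digits))),
                 n_per_digit = as.integer(n_per_digit),
                 noise = noise, master_seed = as.integer(master_seed)),
            class = "hpbu_corpus_spec")
}

child_seed <- function(master, digit, k) {
  (abs(master) %% 100000L) * 10007L + digit * 101L + k
}

#' Generate a digit corpus
#'
#' Produces `n_per_digit` noisy exemplars per included digit; child seeds
#' are derived from the master seed so the corpus is exactly reproducible.
#' Optionally writes one CSV per exemplar plus a `manifest.json`.
#'
#' @param spec an [corpus_spec()].
#' @param out_dir optional directory; created if needed.
#' @return list of class `hpbu_corpus` with `trajectories` (named list of
#'   data.frames), `manifest` (data.frame `id,digit,seed` plus noise
#'   levels), and `spec`.
#' @export
generate_corpus <- function(spec = corpus_spec(), out_dir = NULL) {
  stopifnot(inherits(spec, "hpbu_corpus_spec"))
  if (length(spec$digits) == 0) stop("empty digit set", call. = FALSE)
  tmpl <- digit_templates()
  trajs <- list()
  rows <- list()
  for (d in spec$digits) {
    for (k in seq_len(spec$n_per_digit)) {
      sd <- child_seed(spec$master_seed, d, k)
      id <- sprintf("d%d_e%02d", d, k)
      trajs[[id]] <- generate_digit(tmpl[[as.character(d)]], seed = sd,
                                    noise = spec$noise)
      rows[[id]] <- data.frame(id = id, digit = d, seed = sd,
                               angle_sd = spec$noise$angle,
                               scale_sd = spec$noise$scale,
                               timing_sd = spec$noise$timing)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  corpus <- structure(list(trajectories = trajs, manifest = manifest,
                           spec = spec, format = "hpbu-corpus-1"),
                      class = "hpbu_corpus")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(trajs))
      write_trajectory(trajs[[id]], file.path(out_dir, paste0(id, ".csv")))
    jsonlite::write_json(
      list(format = "hpbu-corpus-1", manifest = manifest),
      file.path(out_dir, "manifest.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  corpus
}

#' Read a corpus directory written by [generate_corpus()]
#'
#' @param dir directory containing `manifest.json` and one CSV per exemplar.
#' @return an `hpbu_corpus`.
#' @export
read_corpus <- function(dir) {
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  manifest <- as.data.frame(man$manifest)
  trajs <- lapply(manifest$id, function(id)
    read_trajectory(file.path(dir, paste0(id, ".csv"))))
  names(trajs) <- manifest$id
  structure(list(trajectories = trajs, manifest = manifest,
                 spec = NULL, format = man$format),
            class = "hpbu_corpus")
}
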