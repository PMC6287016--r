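#' Plot a trial log
#'
#' Renders the Sequence- and Schema-level posterior heatmaps over trial
#' steps, the free-energy traces of the three belief levels, and (for
#' production trials) the sense-of-agency trace.
#'
#' @param log an `hpbu_trial`.
#' @param file optional PNG path; when given the plot is written there,
#'   otherwise the current device is used.
#' @param width,height device size in pixels when writing a PNG.
#' @return the log, invisibly.
#' @export
plot_trial <- function(log, file = NULL, width = 900, height = 700) {
  if (!is.null(file)) {
    grDevices::png(file, width = width, height = height)
    on.exit(grDevices::dev.off())
  }
  has_soa <- !is.null(log$soa)
  graphics::par(mfrow = c(if (has_soa) 4 else 3, 1),
                mar = c(2.5, 4, 2, 1))
  pal <- grDevices::colorRampPalette(c("darkgreen", "white"))(64)
  if (!is.null(log$seq_posterior)) {
    graphics::image(seq_len(nrow(log$seq_posterior)),
                    seq_len(ncol(log$seq_posterior)),
                    pmin(log$seq_posterior, 0.6), col = pal,
                    xlab = "", ylab = "sequence",
                    main = paste0("scenario ", log$scenario,
                                  ": sequence posterior"))
  }
  if (!is.null(log$schema_posterior)) {
    graphics::image(seq_len(nrow(log$schema_posterior)),
                    seq_len(ncol(log$schema_posterior)),
                    pmin(log$schema_posterior, 0.6), col = pal,
                    xlab = "", ylab = "schema", main = "schema posterior")
  } else {
    graphics::plot.new()
  }
  graphics::matplot(log$steps$step,
                    cbind(log$steps$f_v, log$steps$f_s, log$steps$f_c),
                    type = "l", lty = 1, col = c("grey50", "red", "blue"),
                    xlab = "step", ylab = "free energy (nats)")
  graphics::legend("topright", c("vision", "sequence", "schema"),
                   col = c("grey50", "red", "blue"), lty = 1, bty = "n")
  if (has_soa) {
    graphics::plot(log$soa$step, log$soa$soa, type = "l", ylim = c(0, 1),
                   xlab = "step", ylab = "SoA estimate")
  }
  invisible(log)
}
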