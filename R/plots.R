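# Base-graphics figures; headless-safe when written to a PDF device.

#' Plot incremental net benefit and EVPI curves
#'
#' Two panels: the expected incremental net benefit over the no-model
#' baseline under current and perfect information (their gap is the EVPI),
#' and the EVPI itself, both against the risk threshold.
#'
#' @param result A [compute_voi()] result.
#' @param file Optional path; when given the plot is written to a PDF there
#'   (headless-safe), otherwise the current device is used.
#' @param max_threshold Right edge of the x axis. Default 0.5.
#' @return Invisibly, `result`.
#' @export
plot_voi <- function(result, file = NULL, max_threshold = 0.5) {
  stopifnot(inherits(result, "voi_result"))
  if (!is.null(file)) {
    grDevices::pdf(file, width = 9, height = 4.5)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  cv <- result$curves[result$curves$threshold <= max_threshold, ]
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(cv$threshold, cv$delta_perfect, type = "l", col = "red",
                 xlab = "Risk threshold", ylab = "Incremental net benefit",
                 main = "Current vs perfect information",
                 ylim = range(0, cv$delta_perfect))
  graphics::lines(cv$threshold, cv$delta_current, col = "black")
  graphics::legend("topright", c("perfect", "current"),
                   col = c("red", "black"), lty = 1, bty = "n")
  graphics::plot(cv$threshold, cv$evpi, type = "l", col = "blue",
                 xlab = "Risk threshold", ylab = "EVPI", main = "EVPI")
  graphics::abline(h = 0, col = "gray", lty = 2)
  invisible(result)
}

#' Plot the decision curve with optimism correction
#'
#' Net benefit of the proposed model (apparent and optimism-corrected)
#' against treating all and treating none.
#'
#' @param report An [harrell_correct()] report containing the `"nb"` metric.
#' @param y Observed outcomes (for the treat-all curve).
#' @param file Optional PDF path (headless-safe).
#' @param max_threshold Right edge of the x axis. Default 0.5.
#' @return Invisibly, `report`.
#' @export
plot_decision_curve <- function(report, y, file = NULL,
                                max_threshold = 0.5) {
  stopifnot(inherits(report, "optimism_report"), !is.null(report$nb))
  if (!is.null(file)) {
    grDevices::pdf(file, width = 6, height = 4.5)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  nb <- report$nb[report$nb$threshold <= max_threshold, ]
  all_nb <- nb_empirical_all(y, nb$threshold)
  ylim <- range(0, nb$apparent, nb$corrected, all_nb)
  graphics::plot(nb$threshold, nb$apparent, type = "l", col = "darkgray",
                 xlab = "Risk threshold", ylab = "Net benefit",
                 main = "Decision curve", ylim = ylim)
  graphics::lines(nb$threshold, nb$corrected, col = "red")
  graphics::lines(nb$threshold, all_nb, col = "black")
  graphics::abline(h = 0, col = "gray", lty = 2)
  graphics::legend("topright",
                   c("model (apparent)", "model (corrected)", "treat all",
                     "treat none"),
                   col = c("darkgray", "red", "black", "gray"),
                   lty = c(1, 1, 1, 2), bty = "n")
  invisible(report)
}
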