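# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#' @export
ggplot2::autoplot

#' Plot a tissue TAC set
#'
#' @param object A `tacset`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tacset <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"time_s",
                              names_to = "tissue", values_to = "activity")
  ggplot(long, aes(.data$time_s, .data$activity, colour = .data$tissue)) +
    geom_line() +
    labs(x = "time (s)", y = "activity concentration",
         title = paste0("Tissue time-activity curves (case ",
                        attr(object, "case"), ")"))
}

#' Plot a 1TCM fit
#'
#' Measured myocardial TAC, blood input and the fitted model curve.
#'
#' @param object A `fit_1tcm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fit_1tcm <- function(object, ...) {
  d <- object$data
  pred <- tissue_tac_1tcm(object$params, d$blood, d$time_s)
  long <- dplyr::bind_rows(
    tibble(time_s = d$time_s, activity = d$myocardium, curve = "myocardium"),
    tibble(time_s = d$time_s, activity = d$blood, curve = "blood input"),
    tibble(time_s = d$time_s, activity = pred, curve = "1TCM fit")
  )
  ggplot(long, aes(.data$time_s, .data$activity, colour = .data$curve)) +
    geom_line() +
    labs(x = "time (s)", y = "activity",
         title = sprintf("1TCM fit: K1 = %.3g ml/g/min, k2 = %.3g /min, VL = %.3g%%",
                         object$params$K1, object$params$k2,
                         100 * object$params$VL))
}

#' Plot a respiratory displacement trace
#'
#' @param object A `displacement_trace`.
#' @param truth Optional tibble (`resp_gate`, `displacement_mm`) with the
#'   phantom motion law for comparison.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.displacement_trace <- function(object, truth = NULL, ...) {
  p <- ggplot(object, aes(.data$resp_gate, .data$displacement_mm)) +
    geom_line() + geom_point() +
    labs(x = "respiratory gate", y = "LV displacement (mm)",
         title = "Respiratory displacement of the reconstructed LV")
  if (!is.null(truth)) {
    p <- p + geom_line(data = truth, linetype = "dashed", colour = "grey40")
  }
  p
}
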