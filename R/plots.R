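#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_tile geom_text labs theme_minimal scale_fill_gradient
#' @export
ggplot2::autoplot

#' Plot a ventricular volume curve
#'
#' Volume against cardiac phase with the selected ED and ES phases
#' marked.
#'
#' @param object a `volume_curve`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot volume_curve
#' @export
autoplot.volume_curve <- function(object, ...) {
  ph <- select_phases(object)
  extremes <- object[ph, ]
  extremes$label <- c("ED", "ES")
  ggplot(object, aes(x = .data$phase, y = .data$volume_ml)) +
    geom_line(color = "grey40") +
    geom_point(data = extremes, aes(color = .data$label), size = 3) +
    labs(
      x = "cardiac phase", y = "volume (ml)", color = NULL,
      title = paste0(attr(object, "structure") %||% "", " volume curve")
    ) +
    theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bland-Altman scatter plot
#'
#' Mean of the paired values against their difference, with the bias and
#' 1.96-SD limits of agreement.
#'
#' @param x,y paired numeric series (x typically the automatic
#'   measurement, y the manual one).
#' @param label axis label for the measurement.
#' @return a ggplot.
#' @export
plot_bland_altman <- function(x, y, label = "measurement") {
  ba <- bland_altman(x, y)
  df <- tibble(mean = (x + y) / 2, diff = x - y)
  ggplot(df, aes(x = .data$mean, y = .data$diff)) +
    geom_point(alpha = 0.6) +
    geom_hline(yintercept = ba$bias, color = "steelblue") +
    geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
               linetype = "dashed", color = "steelblue") +
    labs(
      x = paste("mean", label), y = paste("difference in", label),
      title = sprintf("bias %.2f [%.2f, %.2f]", ba$bias, ba$loa_low,
                      ba$loa_high)
    ) +
    theme_minimal()
}

#' Plot an experiment's classification transition matrix
#'
#' Tile plot of the none/minor/major CMR classification by the manual and
#' (corrected) automatic methods.
#'
#' @param object an `arvc_experiment`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot arvc_experiment
#' @export
autoplot.arvc_experiment <- function(object, ...) {
  tr <- object$agreement$transitions
  if (nrow(tr) == 0) abort("empty experiment: nothing to plot.")
  levs <- c("none", "minor", "major")
  tr$manual <- factor(tr$manual, levels = levs)
  tr$auto <- factor(tr$auto, levels = levs)
  ggplot(tr, aes(x = .data$auto, y = .data$manual, fill = .data$n)) +
    geom_tile(color = "white") +
    geom_text(aes(label = .data$n)) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(
      x = "automatic classification", y = "manual classification",
      fill = "subjects", title = "CMR TFC classification transitions"
    ) +
    theme_minimal()
}
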