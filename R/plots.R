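# ggplot2 views of the package's result objects.

#' Plot cross-validation ROC/PR curves with confidence ribbons
#'
#' @param object A `crescan_cv_curves` from [roc_pr_curves()].
#' @param ... Unused.
#' @return A ggplot: mean curve per panel with the pointwise t-based
#'   confidence ribbon.
#' @export
autoplot.crescan_cv_curves <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(curve = dplyr::recode(.data$curve,
                                        roc = "ROC (TPR vs FPR)",
                                        pr = "Precision/Recall"))
  ggplot(df, aes(x = .data$x, y = .data$mean)) +
    geom_ribbon(aes(ymin = .data$lo, ymax = .data$hi), alpha = 0.25) +
    geom_line() +
    facet_wrap(~curve) +
    labs(x = NULL, y = NULL,
         title = sprintf("Cross-validation over %d repeats (%.0f%% CI)",
                         object$repeats, 100 * object$level)) +
    theme_minimal()
}

#' Plot a genome-wide prediction
#'
#' Score track per chromosome with predicted regions overlaid; when the
#' prediction is cross-validated, region opacity encodes the fraction of
#' repeats supporting each locus.
#'
#' @param object A `crescan_prediction`.
#' @param ... Unused.
#' @return A ggplot faceted by seqname.
#' @export
autoplot.crescan_prediction <- function(object, ...) {
  curve <- object$curve
  regs <- object$regions
  if (!"support" %in% names(regs)) regs$support <- 1
  p <- ggplot(curve, aes(x = .data$start, y = .data$value)) +
    geom_step(linewidth = 0.3) +
    facet_wrap(~seqname, ncol = 1, scales = "free_x") +
    labs(x = "position (bp)", y = "window score") +
    theme_minimal()
  if (nrow(regs) > 0) {
    ymax <- max(curve$value)
    p <- p + geom_rect(
      data = regs,
      aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = ymax,
          alpha = .data$support),
      fill = "firebrick", inherit.aes = FALSE) +
      scale_alpha_identity()
  }
  p
}
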