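#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline geom_col
#'   labs scale_colour_manual coord_flip
#' @export
ggplot2::autoplot

call_colours <- c(up = "#c0392b", down = "#2980b9", ns = "#27ae60")

#' MA plot of a pairwise differential-expression result
#'
#' Mean log2 intensity (A) against the log2 ratio (M); genes called up or
#' down are highlighted, the dashed lines mark +/- the fold-change threshold.
#' Genes with a zero pooled count on one side have no A and are omitted from
#' the panel.
#'
#' @param de An `eld_de` tibble from [compare_groups()].
#' @return A ggplot object.
#' @export
plot_ma <- function(de) {
  stopifnot(inherits(de, "eld_de"))
  lfc <- attr(de, "lfc_min")
  d <- tidy(de)
  d <- d[is.finite(d$m) & is.finite(d$a), ]
  ggplot(d, aes(x = .data$a, y = .data$m, colour = .data$call)) +
    geom_point(size = 0.6, alpha = 0.6) +
    geom_hline(yintercept = c(-lfc, lfc), linetype = "dashed") +
    scale_colour_manual(values = call_colours) +
    labs(x = "A (mean log2 RPKM)", y = "M (log2 ratio)",
         title = paste(attr(de, "contrast"), collapse = " vs "),
         colour = "call")
}

#' @method autoplot eld_de
#' @export
autoplot.eld_de <- function(object, ...) plot_ma(object)

#' Bar chart of category assignments
#'
#' @param x An `eld_classification` (or assignment tibble).
#' @return A ggplot object.
#' @export
plot_categories <- function(x) {
  s <- category_summary(x)
  d <- s[!s$grouping & s$n > 0, ]
  d$label <- factor(d$label, levels = rev(ALL_CATEGORIES))
  ggplot(d, aes(x = .data$label, y = .data$n)) +
    geom_col(fill = "#34495e") +
    coord_flip() +
    labs(x = NULL, y = "genes", title = "Expression category assignments")
}

#' @method autoplot eld_classification
#' @export
autoplot.eld_classification <- function(object, ...) plot_categories(object)

#' Dosage-comparison plot
#'
#' Actual triploid level against the in-silico prediction on the log2 scale;
#' points off the dashed unit band are the up/down calls.
#'
#' @param x A `dosage_comparison` tibble.
#' @return A ggplot object.
#' @export
plot_dosage <- function(x) {
  stopifnot(inherits(x, "dosage_comparison"))
  lfc <- attr(x, "lfc_min")
  d <- tidy(x)
  d <- d[d$tested & d$predicted > 0 & d$at_elv > 0, ]
  ggplot(d, aes(x = log2(.data$predicted), y = .data$m,
                colour = .data$call)) +
    geom_point(size = 0.6, alpha = 0.6) +
    geom_hline(yintercept = c(-lfc, lfc), linetype = "dashed") +
    scale_colour_manual(values = call_colours) +
    labs(x = paste0("log2 ", attr(x, "prediction"), "-ELV"),
         y = "M = log2(AT-ELV / prediction)",
         title = paste0("Actual vs ", attr(x, "prediction"),
                        "-ELV triploid expression"))
}

#' @method autoplot dosage_comparison
#' @export
autoplot.dosage_comparison <- function(object, ...) plot_dosage(object)
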