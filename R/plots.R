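#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_point geom_ribbon
#'   geom_hline geom_tile geom_col labs scale_fill_manual theme_minimal
#'   theme element_text ylim
NULL

#' @export
ggplot2::autoplot

#' Plot a Kaplan-Meier curve
#'
#' @param object An `lp_km` fit from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot: survival step function with censoring marks.
#' @method autoplot lp_km
#' @export
autoplot.lp_km <- function(object, ...) {
  steps <- tidy(object)
  coords <- bind_rows(tibble(time = 0, surv = 1), steps)
  ggplot(coords, aes(x = .data$time, y = .data$surv)) +
    geom_step() +
    geom_point(data = filter(steps, .data$n_censor > 0), shape = 3) +
    ylim(0, 1) +
    labs(x = "Months from diagnosis", y = "Survival probability") +
    theme_minimal()
}

#' Plot normalized coverage of a copy-number call
#'
#' Per-amplicon normalized coverage of the sample against the
#' panel-of-normals interval; amplicons below the lower bound are
#' highlighted.
#'
#' @param object A `cnv_call` from [call_loss()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cnv_call
#' @export
autoplot.cnv_call <- function(object, ...) {
  d <- mutate(object$amplicons,
              amplicon = factor(.data$amplicon_id,
                                levels = .data$amplicon_id),
              idx = seq_len(n()))
  ggplot(d, aes(x = .data$idx, y = .data$normalized)) +
    geom_ribbon(aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
                fill = "grey85") +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    geom_point(aes(colour = .data$below_ci)) +
    geom_step() +
    ggplot2::scale_x_continuous(breaks = d$idx, labels = d$amplicon_id) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "black"),
      guide = "none") +
    labs(title = sprintf("%s %s: %s", object$sample_id, object$gene,
                         if (object$loss_called) "loss called" else
                           "no loss"),
         x = NULL, y = "Normalized coverage") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Plot an oncoprint
#'
#' Gene-by-patient tile plot of the categorical alteration matrix from
#' [oncoprint_matrix()].
#'
#' @param oncoprint An `oncoprint` tibble.
#' @return A ggplot.
#' @export
plot_oncoprint <- function(oncoprint) {
  pal <- c(hotspot_mutation = "#b2182b", other_mutation = "#ef8a62",
           loss = "#2166ac", rearrangement = "#762a83",
           multiple = "#1b7837", none = "grey92")
  ggplot(oncoprint,
         aes(x = .data$patient_id,
             y = factor(.data$gene, levels = rev(levels(.data$gene))),
             fill = .data$category)) +
    geom_tile(colour = "white", linewidth = 0.3) +
    scale_fill_manual(values = pal, drop = FALSE) +
    labs(x = NULL, y = NULL, fill = "Alteration") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, size = 6))
}
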