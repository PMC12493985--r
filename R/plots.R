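# ggplot2 displays for the main result types

#' @describeIn ncm_fit occurrence frequency vs log10 mean relative
#'   abundance with the fitted neutral prediction and Wilson envelope.
#' @param object an `ncm_fit`.
#' @export
autoplot.ncm_fit <- function(object, ...) {
  dat <- object$otus
  curve <- tibble(p = 10^seq(log10(min(dat$p)), log10(max(dat$p)),
                             length.out = 200))
  curve$predicted <- ncm_predict(curve$p, object$m, object$N)
  ci <- wilson_interval(curve$predicted, n = object$n_sites,
                        level = object$ci_level)
  curve$lower <- ci$lower
  curve$upper <- ci$upper
  ggplot2::ggplot(dat, ggplot2::aes(x = log10(.data$p))) +
    ggplot2::geom_point(ggplot2::aes(y = .data$freq, colour = .data$partition),
                        alpha = 0.6, size = 1) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$predicted),
                       colour = "blue") +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$lower),
                       colour = "blue", linetype = "dashed") +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$upper),
                       colour = "blue", linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(above = "#2c7fb8",
                                            within = "grey40",
                                            below = "#d95f02")) +
    ggplot2::labs(
      x = "log10(mean relative abundance)", y = "Occurrence frequency",
      colour = NULL,
      title = sprintf("Neutral model fit: Nm = %.0f, R2 = %.3f",
                      object$Nm, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot per-site trophic status
#'
#' Bar chart of TRIX by site coloured by class, with the 4/5 scale lines.
#'
#' @param trophic tibble from [trophic_status()].
#' @return a ggplot.
#' @export
plot_trophic_status <- function(trophic) {
  ggplot2::ggplot(trophic,
                  ggplot2::aes(x = stats::reorder(.data$site_id, .data$trix),
                               y = .data$trix, fill = .data$trix_class)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(4, 5), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(oligotrophic = "#74add1",
                                          mesotrophic = "#9970ab",
                                          eutrophic = "#f46d43"),
                               drop = FALSE) +
    ggplot2::labs(x = NULL, y = "TRIX", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot assembly-process fractions
#'
#' Stacked bar of the five-process partition; accepts one
#' [classify_processes()] tibble or a named list of them (one bar each).
#'
#' @param fractions tibble or named list of tibbles.
#' @return a ggplot.
#' @export
plot_process_fractions <- function(fractions) {
  if (is.data.frame(fractions)) fractions <- list(community = fractions)
  df <- purrr::imap_dfr(fractions, function(x, nm) {
    dplyr::mutate(as_tibble(x), group = nm)
  })
  df$process <- factor(df$process, levels = c(
    "variable_selection", "homogeneous_selection", "dispersal_limitation",
    "homogenizing_dispersal", "undominated"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$fraction,
                                   fill = .data$process)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = NULL, y = "Fraction of site pairs", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a distance-decay relationship
#'
#' Pairwise similarity vs distance with the OLS line.
#'
#' @param decay result of [distance_decay()] (carries its pairs as an
#'   attribute).
#' @return a ggplot.
#' @export
plot_distance_decay <- function(decay) {
  pairs <- attr(decay, "pairs")
  if (is.null(pairs)) abort("No pairwise data attached; pass a distance_decay() result.")
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$distance_km,
                                      y = .data$similarity)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = decay$slope, intercept = decay$intercept,
                         colour = "blue") +
    ggplot2::labs(x = "Distance (km)", y = "Bray-Curtis similarity",
                  title = sprintf("slope = %.2e per km, R2 = %.3f",
                                  decay$slope, decay$r_squared)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.trait_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, dplyr::where(is.numeric), "sample_id"),
    -dplyr::all_of("sample_id"), names_to = "trait", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trait, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::facet_wrap(~trait, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
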