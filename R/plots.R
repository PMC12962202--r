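#' Plot a fitted parameter map
#'
#' Raster view of one fitted map; the PDFF display is clipped to the
#' conventional \[-5, 105\]% window (raw values are untouched).
#'
#' @param object A `fam_fit`.
#' @param value Which map to show (`"pdff"`, `"r2star"`, `"psi"`, `"water"`,
#'   `"fat"`, `"residual"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fam_fit <- function(object, value = "pdff", ...) {
  df <- tidy(object, all_voxels = TRUE)
  col <- switch(value, r2star = "r2star_s", psi = "psi_hz", value)
  if (value == "pdff") df$pdff <- pmin(105, pmax(-5, df$pdff))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data[[col]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "black") +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = col, title = paste0(object$method, " fit: ", value)) +
    ggplot2::theme_minimal()
}

#' Plot a flip-angle schedule
#'
#' Flip angle per excitation, with the target/achieved signal profiles when
#' the schedule was solved from a target.
#'
#' @param object A [flip_schedule()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fam_schedule <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$excitation, .data$flip_deg)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "excitation", y = "flip angle (deg)") +
    ggplot2::theme_minimal()
}

#' Plot a k-space weighting profile
#'
#' @param weighting A [kspace_weighting()] result.
#' @return A ggplot of relative amplitude per PE line.
#' @export
plot_kweights <- function(weighting) {
  stopifnot(inherits(weighting, "fam_kweights"))
  df <- tibble::tibble(pe_line = seq_along(weighting$weights),
                       weight = weighting$weights)
  ggplot2::ggplot(df, ggplot2::aes(.data$pe_line, .data$weight)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "PE line", y = "relative amplitude",
                  title = paste0("k-space weighting (T1 = ", weighting$t1_ms, " ms)")) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' @param object A `fam_agreement`.
#' @param ... Unused.
#' @return A ggplot with the mean difference and the 1.96 SD limits.
#' @export
autoplot.fam_agreement <- function(object, ...) {
  df <- tidy(object)
  g <- glance(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$mean, .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = g$mean_diff, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(g$lower, g$upper), linetype = 2) +
    ggplot2::labs(x = "pair mean", y = "difference",
                  title = paste0(object$kind, " = ", signif(g$coefficient, 3))) +
    ggplot2::theme_minimal()
}
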