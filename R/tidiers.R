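#' Tidy a fitted map set into a long voxel table
#'
#' One row per valid voxel with coordinates and all fitted maps — the
#' tabular form for downstream dplyr/ggplot2 work.
#'
#' @param x A `fam_fit`.
#' @param all_voxels Include invalid voxels (as `NA` rows)? Default `FALSE`.
#' @param ... Unused.
#' @return A tibble with `x`, `y`, `pdff`, `r2star_s`, `psi_hz`, `water`,
#'   `fat`, `residual`.
#' @export
tidy.fam_fit <- function(x, all_voxels = FALSE, ...) {
  d <- dim(x$pdff)
  fit <- x
  out <- tibble::tibble(
    x = rep(seq_len(d[1]), d[2]),
    y = rep(seq_len(d[2]), each = d[1]),
    pdff = as.vector(fit$pdff),
    r2star_s = as.vector(fit$r2star_s),
    psi_hz = as.vector(fit$psi_hz),
    water = as.vector(fit$water),
    fat = as.vector(fit$fat),
    residual = as.vector(fit$residual),
    valid = as.vector(fit$valid)
  )
  if (!all_voxels) out <- dplyr::filter(out, .data$valid)
  dplyr::select(out, -"valid")
}

#' One-row summary of a fit
#'
#' @param x A `fam_fit`.
#' @param ... Unused.
#' @return A tibble with the method tag, voxel counts, and median PDFF/R2*
#'   and total residual over valid voxels.
#' @export
glance.fam_fit <- function(x, ...) {
  v <- x$valid
  tibble::tibble(
    method = x$method,
    n_voxels = length(v),
    n_valid = sum(v),
    median_pdff = stats::median(x$pdff[v]),
    median_r2star_s = stats::median(x$r2star_s[v]),
    total_residual = sum(x$residual[v])
  )
}

#' Tidy Bland-Altman pairs
#'
#' @param x A `fam_agreement` from [bland_altman()].
#' @param ... Unused.
#' @return Tibble of pair means and differences.
#' @export
tidy.fam_agreement <- function(x, ...) {
  tibble::tibble(mean = x$means, diff = x$diffs)
}

#' One-row Bland-Altman summary
#'
#' @inheritParams tidy.fam_agreement
#' @return Tibble with `kind`, `n`, `mean_diff`, `sd_diff`, `coefficient`
#'   and the limits of agreement.
#' @export
glance.fam_agreement <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, n = x$n, mean_diff = x$mean_diff, sd_diff = x$sd_diff,
    coefficient = x$coefficient,
    lower = x$mean_diff - x$coefficient,
    upper = x$mean_diff + x$coefficient
  )
}

#' Tidy a flip schedule
#'
#' @param x A [flip_schedule()].
#' @param ... Unused.
#' @return Tibble with `excitation`, `flip_deg`, `pe_line`, and (when the
#'   schedule was solved from a target) `target` and `achieved` signal.
#' @export
tidy.fam_schedule <- function(x, ...) {
  out <- tibble::tibble(
    excitation = seq_along(x$alphas_deg),
    flip_deg = x$alphas_deg,
    pe_line = x$pe_order
  )
  design <- attr(x, "design")
  if (!is.null(design)) {
    out$target <- design$target
    out$achieved <- design$achieved
    out$capped <- design$capped
  }
  out
}
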