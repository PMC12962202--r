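#' ROI summary table
#'
#' Averages map voxels within each ROI, returning per-ROI mean, SD (n-1
#' denominator) and voxel count. All non-`voxels` columns of the ROI tibble
#' (nominal labels etc.) are carried through.
#'
#' @param map A numeric matrix, or a `fam_fit` (then `value` selects which
#'   map to summarize).
#' @param rois ROI tibble with a `voxels` list-column of linear indices, as
#'   produced by [vial_rois()] or [label_rois()].
#' @param value Map name when `map` is a `fam_fit` (default `"pdff"`).
#' @param map_id Optional identifier recorded in the table.
#' @return A tibble with `mean`, `sd`, `n_vox` per ROI.
#' @export
roi_summary <- function(map, rois, value = "pdff", map_id = value) {
  if (inherits(map, "fam_fit")) {
    method <- map$method
    map <- map[[if (value == "r2star") "r2star_s" else value]]
  } else {
    method <- NA_character_
  }
  stopifnot(is.matrix(map) || is.array(map))
  nvox <- prod(dim(map))
  out <- dplyr::mutate(
    dplyr::select(rois, -dplyr::any_of(c("n_vox"))),
    mean = purrr::map_dbl(.data$voxels, function(idx) {
      if (length(idx) < 1L) stop("empty ROI", call. = FALSE)
      if (any(idx < 1L | idx > nvox)) stop("ROI indices outside map", call. = FALSE)
      mean(map[idx])
    }),
    sd = purrr::map_dbl(.data$voxels, function(idx) {
      if (length(idx) > 1L) stats::sd(map[idx]) else 0
    }),
    n_vox = lengths(.data$voxels),
    map_id = map_id,
    method = method
  )
  dplyr::select(out, -"voxels")
}

#' Per-ROI bias against a reference table
#'
#' Joins a measurement table to a reference table on matched ROI ids and
#' computes `bias = mean - reference mean` per ROI.
#'
#' @param table ROI summary tibble with columns `roi` and `mean`.
#' @param reference_table Reference tibble with columns `roi` and `mean`.
#' @param by Join column (default `"roi"`).
#' @return `table` with added `ref_mean` and `bias` columns.
#' @export
bias_vs_reference <- function(table, reference_table, by = "roi") {
  ref <- dplyr::select(reference_table, dplyr::all_of(by), ref_mean = "mean")
  if (!setequal(table[[by]], ref[[by]])) {
    stop("ROI ids do not match between table and reference", call. = FALSE)
  }
  out <- dplyr::left_join(table, ref, by = by)
  dplyr::mutate(out, bias = .data$mean - .data$ref_mean)
}

#' Reference table from the low-T1w vial convention
#'
#' Implements the reference convention for the PDFF x T1 vial phantom: for
#' each nominal-PDFF group, the vial whose water T1 is smallest (200 ms in
#' the standard phantom, closest to the ~300 ms fat T1) defines the group's
#' reference PDFF, measured from a separate low-flip-angle steady-state
#' acquisition. The returned table maps every ROI id to its group reference
#' mean and can be passed to [bias_vs_reference()].
#'
#' @param ref_table ROI summary of the reference acquisition, with columns
#'   `roi`, `pdff` (nominal fraction), `t1w_ms` and `mean`.
#' @return Tibble with columns `roi` and `mean` (the group reference mean).
#' @export
vial_reference_table <- function(ref_table) {
  groups <- dplyr::summarise(
    dplyr::group_by(ref_table, .data$pdff),
    mean = .data$mean[which.min(.data$t1w_ms)],
    .groups = "drop"
  )
  dplyr::select(
    dplyr::left_join(dplyr::select(ref_table, "roi", "pdff"), groups, by = "pdff"),
    "roi", "mean"
  )
}

#' Bland-Altman agreement statistics
#'
#' Differences `a - b` between paired measurements summarized as the mean
#' difference, the SD of differences (n-1 denominator) and the agreement
#' coefficient `1.96 * SD`. The `kind` tag names the study design the pairs
#' come from: limits of agreement between two methods (`"LoA"`), test-retest
#' repeatability coefficient (`"RC"`), or between-condition reproducibility
#' coefficient (`"RDC"`). Swapping `a` and `b` flips the sign of the mean
#' difference but leaves the coefficient unchanged.
#'
#' @param pairs_a,pairs_b Paired numeric vectors (at least 3 pairs).
#' @param kind One of `"LoA"`, `"RC"`, `"RDC"`.
#' @return An object of class `fam_agreement`; see [tidy.fam_agreement()].
#' @export
bland_altman <- function(pairs_a, pairs_b, kind = c("LoA", "RC", "RDC")) {
  kind <- match.arg(kind)
  if (length(pairs_a) != length(pairs_b)) stop("pairs must have equal length", call. = FALSE)
  ok <- stats::complete.cases(pairs_a, pairs_b)
  d <- pairs_a[ok] - pairs_b[ok]
  if (length(d) < 3L) stop("at least 3 complete pairs required", call. = FALSE)
  sdd <- stats::sd(d)
  structure(
    list(n = length(d), mean_diff = mean(d), sd_diff = sdd,
         coefficient = 1.96 * sdd, kind = kind,
         means = (pairs_a[ok] + pairs_b[ok]) / 2, diffs = d),
    class = "fam_agreement"
  )
}

#' @export
print.fam_agreement <- function(x, ...) {
  cat("<fam_agreement> ", x$kind, ": n = ", x$n,
      ", mean diff = ", signif(x$mean_diff, 4),
      ", 1.96 SD = ", signif(x$coefficient, 4), "\n", sep = "")
  invisible(x)
}

#' Voxel-wise SD across repeated maps
#'
#' Per-voxel standard deviation (n-1 denominator) over repeated acquisitions
#' of the same map — the standard surrogate for voxel noise.
#'
#' @param maps List of at least 2 numeric matrices of equal shape.
#' @return Matrix of per-voxel SDs.
#' @export
voxelwise_sd <- function(maps) {
  if (length(maps) < 2L) stop("at least 2 repetitions required", call. = FALSE)
  d <- dim(maps[[1]])
  if (!all(vapply(maps, function(m) identical(dim(m), d), logical(1)))) {
    stop("all maps must share the same shape", call. = FALSE)
  }
  x <- vapply(maps, as.vector, numeric(prod(d)))
  array(apply(x, 1, stats::sd), d)
}

#' Normalize ROI SD values by a reference method
#'
#' Divides each ROI summary value by the median ROI value of the reference
#' method on the same system, removing hardware-dependent scale so noise can
#' be compared across systems.
#'
#' @param table ROI summary tibble (typically of a voxel-wise SD map).
#' @param reference_table Same-system ROI summary of the reference method.
#' @param value_col Column to normalize (default `"mean"`).
#' @return `table` with an added `normalized` column.
#' @export
normalize_sd <- function(table, reference_table, value_col = "mean") {
  ref_med <- stats::median(reference_table[[value_col]])
  if (!is.finite(ref_med) || ref_med <= 0) {
    stop("reference median must be positive", call. = FALSE)
  }
  dplyr::mutate(table, normalized = .data[[value_col]] / ref_med)
}

#' Exclude ROIs with high R2*
#'
#' Removes rows whose summary R2* strictly exceeds the field-strength
#' threshold (276 1/s at 1.5T, 397 1/s at 3T by default), the rule used to
#' guard PDFF accuracy against heavy R2* decay at the protocol echo times.
#' Values exactly at the threshold are retained. The rule is idempotent.
#'
#' @param table Tibble with an `r2star` column of summary R2* values (1/s).
#' @param b0_t Field strength (T); must match a configured threshold.
#' @param thresholds Named vector of thresholds by field strength.
#' @return Filtered tibble.
#' @export
r2star_exclude <- function(table, b0_t,
                           thresholds = c("1.5" = 276, "3" = 397)) {
  key <- names(thresholds)[abs(as.numeric(names(thresholds)) - b0_t) < 0.11]
  if (length(key) != 1L) {
    stop("no configured R2* threshold for B0 = ", b0_t, " T", call. = FALSE)
  }
  dplyr::filter(table, .data$r2star <= thresholds[[key]])
}

#' Whole-liver PDFF from segment summaries
#'
#' Unweighted mean of the available segment summary means (1-9 segments
#' after any exclusion). Returns `NA` with a warning when no segments
#' survive.
#'
#' @param segment_table Tibble with one row per surviving segment and a
#'   `mean` column.
#' @return Scalar whole-liver PDFF (same units as `mean`).
#' @export
whole_liver_pdff <- function(segment_table) {
  n <- nrow(segment_table)
  if (n == 0L) {
    warning("no segments survive exclusion; whole-liver PDFF is missing")
    return(NA_real_)
  }
  if (n > 9L) stop("at most 9 segments expected", call. = FALSE)
  mean(segment_table$mean)
}
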