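#' Vessel morphometry by pixel accumulation
#'
#' Length is the number of skeleton (centerline) pixels, area the number of
#' mask pixels, and width the ratio area / length -- all raw pixel
#' accumulation, with no diagonal weighting by default. A diagonal-weighted
#' length (counting \eqn{\sqrt 2} per diagonal step along traced branches)
#' is available behind `diagonal_weighted = TRUE`.
#'
#' @param skeleton Logical matrix of surviving centerline pixels; must be a
#'   subset of `mask`.
#' @param mask Logical matrix of surviving vessel-area pixels.
#' @param diagonal_weighted Use arc length along branches instead of the raw
#'   pixel count for `length_px` (default `FALSE`).
#' @param mm_per_px Optional physical calibration; when supplied the output
#'   gains `length_mm`, `area_mm2` and `width_mm` columns.
#' @return One-row tibble: `length_px`, `area_px2`, `width_px`, `defined`
#'   (`FALSE`, with `width_px = NA`, when the skeleton is empty).
#' @export
measure_vessels <- function(skeleton, mask, diagonal_weighted = FALSE,
                            mm_per_px = NULL) {
  assert_mask(skeleton, arg = "skeleton")
  assert_mask(mask, dim(skeleton), arg = "mask")
  if (any(skeleton & !mask)) {
    vca_stop("inconsistent inputs: the skeleton must be a subset of the mask")
  }
  len <- if (diagonal_weighted) skeleton_arc_length(skeleton) else sum(skeleton)
  area <- sum(mask)
  defined <- len > 0
  out <- tibble::tibble(
    length_px = as.numeric(len),
    area_px2 = as.numeric(area),
    width_px = if (defined) area / len else NA_real_,
    defined = defined)
  if (!is.null(mm_per_px)) {
    out$length_mm <- out$length_px * mm_per_px
    out$area_mm2 <- out$area_px2 * mm_per_px^2
    out$width_mm <- out$width_px * mm_per_px
  }
  out
}

# Euclidean arc length along traced branches: 1 per axial step, sqrt(2) per
# diagonal step; isolated pixels contribute 1.
skeleton_arc_length <- function(skeleton) {
  g <- skeleton_graph(skeleton, warn_nonthin = FALSE)
  if (length(g$pixel_idx) == 0L) return(0)
  nr <- g$dim[1L]
  step_len <- function(px) {
    if (length(px) < 2L) return(1)
    r <- (px - 1L) %% nr + 1L
    c <- (px - 1L) %/% nr + 1L
    sum(sqrt(diff(r)^2 + diff(c)^2))
  }
  total <- sum(vapply(g$branches$pixels, step_len, numeric(1)))
  isolated <- sum(g$degree == 0L)
  total + isolated
}

#' Signed percent change relative to a reference
#'
#' `(current - reference) / reference * 100`; negative values are
#' reductions, so a length shortened to 63.2 from 100 reports -36.8.
#'
#' @param reference Reference (pre/earlier) value, `> 0`.
#' @param current Current (later) value.
#' @return Signed percent change.
#' @seealso [percent_of_reference()]
#' @export
percent_change <- function(reference, current) {
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    vca_stop("`reference` must be finite and > 0")
  }
  (current - reference) / reference * 100
}

#' Current value expressed as percent of a reference
#'
#' `current / reference * 100` (e.g. 117.7 means "increased to 117.7% of
#' the reference value").
#'
#' @inheritParams percent_change
#' @return Percent of reference.
#' @export
percent_of_reference <- function(reference, current) {
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    vca_stop("`reference` must be finite and > 0")
  }
  current / reference * 100
}
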