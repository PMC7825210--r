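#' Parameters for starting-point detection
#'
#' A pixel is *effective* when its intensity reaches `effective_intensity`
#' (default: the Otsu threshold of the region of interest). Centered probe
#' lines of `line_length` pixels are laid through each effective pixel in
#' `n_directions` directions; a line is *empty* when it contains no effective
#' pixel besides (possibly) the center. The pixel is a starting point of the
#' vascular network iff the fraction of empty lines is below
#' `empty_line_proportion_max`.
#'
#' @param line_length Odd probe-line length in pixels, `>= 3` (default 7).
#' @param n_directions 2 (axes), 4 (+ diagonals, default) or 8 (+ knight-step
#'   directions); each direction is a full line through the center, covering
#'   both rays.
#' @param effective_intensity Threshold in `[0, 1]`, or `NULL` to use the
#'   Otsu threshold of the image.
#' @param empty_line_proportion_max Proportion in `[0, 1]` (default 0.5).
#' @return A `start_point_params` list.
#' @export
start_point_params <- function(line_length = 7L, n_directions = 4L,
                               effective_intensity = NULL,
                               empty_line_proportion_max = 0.5) {
  if (line_length < 3L || line_length %% 2L == 0L) {
    vca_stop("`line_length` must be odd and >= 3")
  }
  if (!n_directions %in% c(2L, 4L, 8L)) {
    vca_stop("`n_directions` must be 2, 4 or 8")
  }
  if (!is.null(effective_intensity) &&
      (effective_intensity < 0 || effective_intensity > 1)) {
    vca_stop("`effective_intensity` must be in [0, 1]")
  }
  if (empty_line_proportion_max < 0 || empty_line_proportion_max > 1) {
    vca_stop("`empty_line_proportion_max` must be in [0, 1]")
  }
  structure(list(line_length = as.integer(line_length),
                 n_directions = as.integer(n_directions),
                 effective_intensity = effective_intensity,
                 empty_line_proportion_max = empty_line_proportion_max),
            class = "start_point_params")
}

#' Parameters for connectivity growth
#'
#' @param d_max Maximum Euclidean admission distance in pixels (default 2:
#'   a candidate joins the network when its minimum distance to the current
#'   network point set is within 2 pixels). For `d_max = 2` the admission
#'   neighborhood is the 5x5 window minus its four corners.
#' @param effective_intensity Threshold candidate pixels must reach, or
#'   `NULL` for the Otsu threshold of the image.
#' @return A `growth_params` list.
#' @export
growth_params <- function(d_max = 2, effective_intensity = NULL) {
  if (!is.numeric(d_max) || length(d_max) != 1L || d_max <= 0) {
    vca_stop("`d_max` must be > 0")
  }
  if (!is.null(effective_intensity) &&
      (effective_intensity < 0 || effective_intensity > 1)) {
    vca_stop("`effective_intensity` must be in [0, 1]")
  }
  structure(list(d_max = d_max, effective_intensity = effective_intensity),
            class = "growth_params")
}

probe_directions <- function(n_directions) {
  dirs <- list(c(0L, 1L), c(1L, 0L))
  if (n_directions >= 4L) dirs <- c(dirs, list(c(1L, 1L), c(1L, -1L)))
  if (n_directions == 8L) {
    dirs <- c(dirs, list(c(1L, 2L), c(2L, 1L), c(1L, -2L), c(2L, -1L)))
  }
  dirs
}

resolve_effective <- function(img, threshold) {
  threshold %||% otsu_threshold(img)
}

#' Detect starting points of the vascular network
#'
#' Every pixel is examined in a boustrophedon ("Z-shaped") raster scan; the
#' starting-point criterion is a pure per-pixel predicate, so the returned
#' set does not depend on the scan order and the scan is computed in
#' vectorized form. Probe lines are cropped at the image border (positions
#' falling outside the image contribute no effective pixels).
#'
#' @param img Grayscale matrix in `[0, 1]`.
#' @param params A [start_point_params()].
#' @return Logical matrix marking starting points, with the resolved
#'   effective-intensity threshold in `attr(, "threshold")`. An image with
#'   no effective pixels yields an empty (all-`FALSE`) set.
#' @export
detect_starting_points <- function(img, params = start_point_params()) {
  assert_gray(img)
  thr <- resolve_effective(img, params$effective_intensity)
  eff <- img >= thr
  half <- (params$line_length - 1L) %/% 2L
  dirs <- probe_directions(params$n_directions)
  n_empty <- matrix(0L, nrow(img), ncol(img))
  for (d in dirs) {
    has <- matrix(FALSE, nrow(img), ncol(img))
    for (m in c(-half:-1, 1:half)) {
      has <- has | shift_mat(eff, m * d[1L], m * d[2L])
    }
    n_empty <- n_empty + !has
  }
  starts <- eff & (n_empty / length(dirs) < params$empty_line_proportion_max)
  attr(starts, "threshold") <- thr
  starts
}

#' Grow the vascular network from starting points
#'
#' Returns the closure of `starts` under the relation "effective pixel whose
#' minimum Euclidean distance to a network member is `<= d_max`": starting
#' from the seed set, candidate pixels within the admission neighborhood of
#' any member that also pass the intensity test are admitted, and admission
#' repeats until a full pass adds no pixel (a fixed point). The fixed point
#' is computed by frontier expansion and equals breadth-first closure, so
#' the result is independent of any pixel visiting order; `starts` is always
#' a subset of the result.
#'
#' @param img Grayscale matrix in `[0, 1]`.
#' @param starts Logical matrix of seed pixels (see
#'   [detect_starting_points()]).
#' @param params A [growth_params()].
#' @return Logical matrix of network pixels; resolved threshold in
#'   `attr(, "threshold")`.
#' @export
grow_network <- function(img, starts, params = growth_params()) {
  assert_gray(img)
  assert_mask(starts, dim(img), arg = "starts")
  thr <- resolve_effective(img, params$effective_intensity)
  eff <- img >= thr
  offs <- neighborhood_offsets(params$d_max)
  net <- starts
  frontier <- starts
  sweeps <- 0L
  max_sweeps <- length(img) + 1L  # hard termination bound: each sweep adds >= 1 pixel
  while (any(frontier)) {
    sweeps <- sweeps + 1L
    if (sweeps > max_sweeps) {
      vca_stop("growth failed to reach a fixed point within the pixel-count bound",
               class = "octavca_internal_error")
    }
    cand <- dilate_by_offsets(frontier, offs) & eff & !net
    if (!any(cand)) break
    net <- net | cand
    frontier <- cand
  }
  attr(net, "threshold") <- thr
  net
}

#' Rotate an image by quarter turns
#'
#' Lossless 90-degree-multiple rotation (counter-clockwise per turn). Only
#' quarter turns are supported: arbitrary angles would require interpolation
#' and corrupt the exact set semantics of the pipeline.
#'
#' @param img Numeric or logical matrix.
#' @param quarter_turns Integer 0--3.
#' @return The rotated matrix.
#' @seealso [rotated_to_original()] for the coordinate bijection back to the
#'   unrotated frame.
#' @export
rotate_quarter <- function(img, quarter_turns) {
  if (!is_quarter_turn(quarter_turns)) {
    vca_stop("`quarter_turns` must be an integer in 0..3 (only quarter turns are lossless)")
  }
  k <- as.integer(quarter_turns)
  out <- img
  for (i in seq_len(k)) {
    out <- t(out)[rev(seq_len(ncol(out))), , drop = FALSE]
  }
  out
}

#' Map rotated-frame coordinates back to the original frame
#'
#' Inverse of the coordinate action of [rotate_quarter()]: for an original
#' image of size `R x C` rotated counter-clockwise by `quarter_turns`, each
#' rotated-frame pixel `(r', c')` (1-based) maps to a unique original-frame
#' pixel. The map is a bijection.
#'
#' @param coords Two-column matrix of (row, col) 1-based rotated-frame
#'   coordinates.
#' @param quarter_turns Integer 0--3 used for the rotation.
#' @param dim_original `c(rows, cols)` of the *unrotated* image.
#' @return Two-column matrix of original-frame coordinates.
#' @export
rotated_to_original <- function(coords, quarter_turns, dim_original) {
  if (!is_quarter_turn(quarter_turns)) {
    vca_stop("`quarter_turns` must be an integer in 0..3")
  }
  coords <- matrix(as.integer(coords), ncol = 2L)
  R <- dim_original[1L]
  C <- dim_original[2L]
  rp <- coords[, 1L]
  cp <- coords[, 2L]
  res <- switch(as.character(as.integer(quarter_turns)),
    "0" = cbind(rp, cp),
    "1" = cbind(cp, C - rp + 1L),
    "2" = cbind(R - rp + 1L, C - cp + 1L),
    "3" = cbind(R - cp + 1L, rp)
  )
  colnames(res) <- c("row", "col")
  res
}

#' Extract the complete vascular network with rotation merging
#'
#' Runs starting-point detection and connectivity growth on the image and on
#' its 90, 180 and 270-degree rotations, maps each grown set back to the
#' original frame, and returns the union. Growing from rotated frames
#' recovers network parts whose starting points are only detected under a
#' different orientation. The effective-intensity threshold is resolved once
#' on the unrotated image (the histogram is rotation-invariant) and shared
#' by all four runs.
#'
#' @param img Grayscale matrix in `[0, 1]`.
#' @param sp A [start_point_params()].
#' @param gp A [growth_params()].
#' @return Logical network matrix; threshold in `attr(, "threshold")`.
#' @export
extract_network <- function(img, sp = start_point_params(), gp = growth_params()) {
  assert_gray(img)
  thr <- sp$effective_intensity %||% gp$effective_intensity %||% otsu_threshold(img)
  sp$effective_intensity <- thr
  gp$effective_intensity <- thr
  net <- matrix(FALSE, nrow(img), ncol(img))
  for (k in 0:3) {
    rimg <- rotate_quarter(img, k)
    st <- detect_starting_points(rimg, sp)
    g <- grow_network(rimg, st, gp)
    net <- net | rotate_quarter(g, (4L - k) %% 4L)
  }
  attr(net, "threshold") <- thr
  net
}
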