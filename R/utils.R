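#' @importFrom rlang %||% abort
#' @importFrom stats rnorm runif sd pt
#' @importFrom utils write.csv read.csv
NULL

# Classed conditions so the CLI can map failures to exit codes:
#   octavca_validation_error -> 2, octavca_io_error -> 3, anything else -> 4.
vca_stop <- function(msg, class = "octavca_validation_error") {
  rlang::abort(msg, class = class)
}

vca_io_stop <- function(msg) vca_stop(msg, class = "octavca_io_error")

#' @keywords internal
assert_gray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    vca_stop(sprintf("`%s` must be a numeric matrix (grayscale image)", arg))
  }
  if (nrow(img) < 1L || ncol(img) < 1L) {
    vca_stop(sprintf("`%s` must have at least one row and one column", arg))
  }
  if (anyNA(img) || any(!is.finite(img))) {
    vca_stop(sprintf("`%s` contains non-finite intensities", arg))
  }
  if (min(img) < 0 || max(img) > 1) {
    vca_stop(sprintf("`%s` intensities must lie in [0, 1]; rescale on read", arg))
  }
  invisible(img)
}

assert_mask <- function(mask, dim_ref = NULL, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask)) {
    vca_stop(sprintf("`%s` must be a logical matrix", arg))
  }
  if (anyNA(mask)) vca_stop(sprintf("`%s` contains NA", arg))
  if (!is.null(dim_ref) && !identical(dim(mask), as.integer(dim_ref))) {
    vca_stop(sprintf("`%s` has shape %s but the host image is %s",
                     arg, paste(dim(mask), collapse = "x"),
                     paste(dim_ref, collapse = "x")))
  }
  invisible(mask)
}

# Translate matrix content by (dr, dc): out[r, c] = m[r - dr, c - dc],
# out-of-range positions filled with `fill`.
shift_mat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- seq_len(nr) - dr
  sc <- seq_len(nc) - dc
  rok <- sr >= 1L & sr <= nr
  cok <- sc >= 1L & sc <= nc
  if (any(rok) && any(cok)) {
    out[rok, cok] <- m[sr[rok], sc[cok]]
  }
  out
}

# All integer offsets (dr, dc) != (0, 0) with dr^2 + dc^2 <= d_max^2.
# For d_max = 2 this is the 5x5 window minus its four corners (20 offsets).
neighborhood_offsets <- function(d_max) {
  if (!is.numeric(d_max) || length(d_max) != 1L || d_max <= 0) {
    vca_stop("`d_max` must be a single positive number")
  }
  r <- floor(d_max)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= d_max^2 & !(g$dr == 0 & g$dc == 0), , drop = FALSE]
  as.matrix(g)
}

disk_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  as.matrix(g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE])
}

# Dilate a logical matrix by a set of offsets (rows of `offs`), OR-combined.
dilate_by_offsets <- function(mask, offs) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(offs))) {
    out <- out | shift_mat(mask, offs[i, 1L], offs[i, 2L])
  }
  out
}

mask_coords <- function(mask) {
  which(mask, arr.ind = TRUE)
}

coords_to_mask <- function(coords, dim) {
  m <- matrix(FALSE, dim[1L], dim[2L])
  if (NROW(coords) > 0L) m[cbind(coords[, 1L], coords[, 2L])] <- TRUE
  m
}

# 8-connectivity neighbor count of each TRUE pixel (value meaningless off-mask).
neighbor_count8 <- function(mask) {
  n <- matrix(0L, nrow(mask), ncol(mask))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    n <- n + shift_mat(mask, dr, dc)
  }
  n
}

# Label 8-connected components of a logical matrix. Returns an integer matrix,
# 0 off-mask, labels 1..k on-mask. igraph does the component search.
label_components8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  vid <- integer(length(mask))
  vid[idx] <- seq_along(idx)
  edges <- NULL
  # half the offsets suffice for an undirected adjacency
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    both <- mask & shift_mat(mask, off[1L], off[2L])
    j <- which(both)
    if (length(j)) {
      i <- j - off[1L] - off[2L] * nrow(mask)
      edges <- rbind(edges, cbind(vid[i], vid[j]))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  lab
}

is_quarter_turn <- function(k) {
  is.numeric(k) && length(k) == 1L && !is.na(k) && k == as.integer(k) && k >= 0 && k <= 3
}
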