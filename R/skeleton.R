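# Lookup table over the 8-bit ring code (bits: N, NE, E, SE, S, SW, W, NW):
# TRUE when the foreground ring cells form exactly one 8-connected component,
# i.e. the center pixel is "simple" and can be deleted without splitting the
# local topology.
ring_simple_lut <- local({
  pos <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  vapply(0:255, function(code) {
    on <- which(bitwAnd(code, bitwShiftL(1L, 0:7)) != 0L)
    if (length(on) == 0L) return(FALSE)
    # count components among ring cells (8-adjacency of their positions)
    comp <- seq_along(on)
    repeat {
      changed <- FALSE
      for (i in seq_along(on)) for (j in seq_along(on)) {
        if (comp[i] != comp[j] &&
            max(abs(pos[on[i], ] - pos[on[j], ])) <= 1L) {
          comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    length(unique(comp)) == 1L
  }, logical(1))
})

# Sequential removal of redundant staircase pixels left by Zhang-Suen
# thinning: a pixel with >= 2 neighbors whose foreground ring is a single
# 8-connected component can be deleted without changing connectivity.
# Raster-order sequential passes repeat until stable.
thin_cleanup <- function(img) {
  nr <- nrow(img)
  nc <- ncol(img)
  off <- c(-1L, -1L + nr, nr, 1L + nr, 1L, 1L - nr, -nr, -1L - nr)  # N..NW
  bit <- bitwShiftL(1L, 0:7)
  repeat {
    changed <- FALSE
    idx <- which(img)
    for (p in idx) {
      r <- (p - 1L) %% nr + 1L
      c <- (p - 1L) %/% nr + 1L
      if (r == 1L || r == nr || c == 1L || c == nc) {
        nb <- ring_code_border(img, r, c)
      } else {
        nb <- img[p + off]
      }
      deg <- sum(nb)
      if (deg >= 2L && ring_simple_lut[sum(bit[nb]) + 1L]) {
        img[p] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img
}

ring_code_border <- function(img, r, c) {
  nr <- nrow(img)
  nc <- ncol(img)
  pos <- rbind(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
               c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))
  rr <- r + pos[, 1L]
  cc <- c + pos[, 2L]
  ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
  nb <- logical(8L)
  nb[ok] <- img[cbind(rr[ok], cc[ok])]
  nb
}

#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' Morphological thinning to a unit-width centerline: parallel Zhang-Suen
#' subiterations to convergence, followed by a sequential cleanup that
#' deletes the redundant staircase pixels Zhang-Suen is known to leave on
#' diagonal runs (a pixel is deleted only when it has two or more neighbors
#' and its foreground ring is a single 8-connected component, so
#' connectivity and endpoints are preserved). The output is always a subset
#' of the input; an empty mask yields an empty skeleton.
#'
#' @param mask Logical matrix (binary vessel mask).
#' @return Logical matrix, the 1-px-wide skeleton.
#' @export
skeletonize <- function(mask) {
  assert_mask(mask)
  img <- mask
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p2 <- shift_mat(img, -1L,  0L)  # N
      p3 <- shift_mat(img, -1L,  1L)  # NE
      p4 <- shift_mat(img,  0L,  1L)  # E
      p5 <- shift_mat(img,  1L,  1L)  # SE
      p6 <- shift_mat(img,  1L,  0L)  # S
      p7 <- shift_mat(img,  1L, -1L)  # SW
      p8 <- shift_mat(img,  0L, -1L)  # W
      p9 <- shift_mat(img, -1L, -1L)  # NW
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      cond <- img & b >= 2L & b <= 6L & a == 1L
      if (phase == 1L) {
        cond <- cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        img[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  thin_cleanup(img)
}

#' Filter parameters for piece-by-piece skeleton analysis
#'
#' @param min_branch_length Terminal branches (endpoint-to-junction) shorter
#'   than this many pixels are pruned (default 5).
#' @param min_length_per_node_ratio Components whose total skeleton length
#'   divided by (number of bifurcation points + number of breakpoints) falls
#'   below this value are removed as noise or artifacts (default 3.0). The
#'   denominator is clamped to at least 1, so closed loops (which have no
#'   nodes) are retained whenever their circumference reaches the threshold,
#'   while isolated single pixels (ratio 1) are removed.
#' @return A `filter_params` list.
#' @export
filter_params <- function(min_branch_length = 5, min_length_per_node_ratio = 3) {
  if (min_branch_length <= 0 || min_length_per_node_ratio <= 0) {
    vca_stop("filter thresholds must be > 0")
  }
  structure(list(min_branch_length = min_branch_length,
                 min_length_per_node_ratio = min_length_per_node_ratio),
            class = "filter_params")
}

# Directed adjacency of skeleton pixels under 8-connectivity.
skeleton_adjacency <- function(skel) {
  nr <- nrow(skel)
  idx <- which(skel)
  vid <- integer(length(skel))
  vid[idx] <- seq_along(idx)
  from <- integer(0)
  to <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    both <- skel & shift_mat(skel, dr, dc)
    j <- which(both)
    if (length(j)) {
      i <- j - dr - dc * nr
      from <- c(from, vid[j])
      to <- c(to, vid[i])
    }
  }
  list(idx = idx, from = from, to = to,
       adj = split(seq_along(from), factor(from, levels = seq_along(idx))))
}

#' Build the skeleton branch graph
#'
#' Classifies every skeleton pixel by its 8-connectivity neighbor count
#' (breakpoint = exactly 1 neighbor, i.e. an endpoint; bifurcation point =
#' 3 or more neighbors), groups pixels into 8-connected components, and
#' traces the maximal branches running between node pixels (endpoints and
#' junctions). Branch length is the branch's pixel count including both of
#' its end pixels, so junction pixels are counted once in each incident
#' branch. Components that are pure cycles yield a single closed branch;
#' isolated single pixels form components of total length 1 with neither
#' breakpoints nor bifurcations.
#'
#' @param skeleton Logical matrix, normally the output of [skeletonize()].
#'   Input that is not unit-width (it contains a 2x2 block of pixels)
#'   triggers a warning, not an error; the graph is still built.
#' @param warn_nonthin Emit the non-thin warning (default `TRUE`).
#' @return A `skeleton_graph` object: list with `skeleton`, `components`
#'   (tibble: component, total_length, n_bifurcations, n_breakpoints,
#'   n_branches, ratio), `branches` (tibble with a list-column of pixel
#'   linear indices), and per-pixel internals.
#' @export
skeleton_graph <- function(skeleton, warn_nonthin = TRUE) {
  assert_mask(skeleton, arg = "skeleton")
  skel <- skeleton
  if (warn_nonthin) {
    block <- skel & shift_mat(skel, 1L, 0L) & shift_mat(skel, 0L, 1L) &
      shift_mat(skel, 1L, 1L)
    if (any(block)) {
      warning("skeleton is not unit-width (contains a 2x2 pixel block); ",
              "building the graph anyway", call. = FALSE)
    }
  }
  idx <- which(skel)
  n <- length(idx)
  empty_components <- tibble::tibble(
    component = integer(0), total_length = integer(0),
    n_bifurcations = integer(0), n_breakpoints = integer(0),
    n_branches = integer(0), ratio = numeric(0))
  empty_branches <- tibble::tibble(
    component = integer(0), branch = integer(0), length = integer(0),
    terminal = logical(0), closed = logical(0), pixels = list())
  if (n == 0L) {
    return(structure(list(skeleton = skel, dim = dim(skel),
                          components = empty_components,
                          branches = empty_branches,
                          pixel_idx = integer(0), degree = integer(0),
                          membership = integer(0)),
                     class = "skeleton_graph"))
  }
  adjd <- skeleton_adjacency(skel)
  deg <- lengths(adjd$adj)
  is_node <- deg == 1L | deg >= 3L
  lab <- label_components8(skel)
  memb <- lab[idx]

  m <- length(adjd$from)
  visited <- logical(m)
  # reverse directed edge id of edge e = (a -> b): the entry (b -> a)
  rev_of <- function(e) {
    cand <- adjd$adj[[adjd$to[e]]]
    cand[adjd$to[cand] == adjd$from[e]][1L]
  }
  branches <- list()
  trace_from <- function(v, e0) {
    path <- v
    e <- e0
    repeat {
      visited[e] <<- TRUE
      visited[rev_of(e)] <<- TRUE
      w <- adjd$to[e]
      path <- c(path, w)
      if (is_node[w] || w == v && length(path) > 2L) break
      nxt <- adjd$adj[[w]]
      nxt <- nxt[!visited[nxt] & adjd$to[nxt] != adjd$from[e]]
      if (length(nxt) == 0L) break  # closed back into the path
      e <- nxt[1L]
    }
    path
  }
  for (v in which(is_node)) {
    for (e in adjd$adj[[v]]) {
      if (!visited[e]) branches[[length(branches) + 1L]] <- trace_from(v, e)
    }
  }
  # pure cycles: components with no node pixels and untraced edges
  for (v in order(idx)) {
    es <- adjd$adj[[v]]
    if (length(es) && !is_node[v] && !any(visited[es])) {
      branches[[length(branches) + 1L]] <- trace_from(v, es[1L])
    }
  }
  if (length(branches)) {
    br_comp <- vapply(branches, function(p) memb[p[1L]], integer(1))
    br_len <- vapply(branches, function(p) length(unique(p)), integer(1))
    br_closed <- vapply(branches, function(p) {
      p[1L] == p[length(p)] && length(p) > 2L
    }, logical(1))
    br_terminal <- vapply(branches, function(p) {
      ends <- deg[c(p[1L], p[length(p)])]
      sum(ends == 1L) == 1L && sum(ends >= 3L) == 1L
    }, logical(1))
    br_pixels <- lapply(branches, function(p) idx[unique(p)])
    ord <- order(br_comp)
    branches_tb <- tibble::tibble(
      component = br_comp, branch = seq_along(branches), length = br_len,
      terminal = br_terminal, closed = br_closed, pixels = br_pixels)[ord, ]
    branches_tb$branch <- seq_len(nrow(branches_tb))
  } else {
    branches_tb <- empty_branches
  }

  comp_ids <- sort(unique(memb))
  comp_tb <- tibble::tibble(
    component = comp_ids,
    total_length = as.integer(tabulate(memb, max(memb))[comp_ids]),
    n_bifurcations = vapply(comp_ids, function(cid) {
      sum(deg[memb == cid] >= 3L)
    }, integer(1)),
    n_breakpoints = vapply(comp_ids, function(cid) {
      sum(deg[memb == cid] == 1L)
    }, integer(1)),
    n_branches = vapply(comp_ids, function(cid) {
      sum(branches_tb$component == cid)
    }, integer(1)))
  comp_tb$ratio <- comp_tb$total_length /
    pmax(comp_tb$n_bifurcations + comp_tb$n_breakpoints, 1L)

  structure(list(skeleton = skel, dim = dim(skel), components = comp_tb,
                 branches = branches_tb, pixel_idx = idx,
                 degree = as.integer(deg), membership = memb),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d px in %d component(s), %d branch(es)\n",
              length(x$pixel_idx), nrow(x$components), nrow(x$branches)))
  print(x$components, n = 10)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.skeleton_graph <- function(x, ...) {
  x$components
}

#' Piece-by-piece noise and artifact filtering
#'
#' Two-stage cleanup of the skeleton graph: (a) terminal branches (running
#' from an endpoint into a junction) shorter than `min_branch_length` are
#' pruned iteratively -- the graph is rebuilt after every pass -- until no
#' such branch remains; (b) each remaining component whose ratio of total
#' length to (bifurcation points + breakpoints) falls below
#' `min_length_per_node_ratio` is removed entirely, as is any component
#' whose total length is below `min_branch_length` (such a component -- an
#' isolated dot, a tiny loop punched out of a noise blob -- contains only
#' too-short branches). Closed loops meeting both length rules are kept.
#' The pruning in (a) keeps the junction pixel itself. Filtering is
#' idempotent and never increases the skeleton pixel count.
#'
#' @param graph A [skeleton_graph()].
#' @param params A [filter_params()].
#' @return The filtered `skeleton_graph`, rebuilt from surviving pixels.
#'   `attr(, "decisions")` holds the component table evaluated by stage (b)
#'   with a `kept` flag.
#' @export
filter_pieces <- function(graph, params = filter_params()) {
  stopifnot(inherits(graph, "skeleton_graph"))
  skel <- graph$skeleton
  repeat {
    g <- skeleton_graph(skel, warn_nonthin = FALSE)
    if (nrow(g$branches) == 0L) break
    short <- g$branches$terminal & g$branches$length < params$min_branch_length
    if (!any(short)) break
    for (i in which(short)) {
      px <- g$branches$pixels[[i]]
      keep_junction <- px[g$degree[match(px, g$pixel_idx)] >= 3L]
      skel[setdiff(px, keep_junction)] <- FALSE
    }
    # pruning can leave a redundant bump at the junction; re-minimize
    skel <- thin_cleanup(skel)
  }
  g <- skeleton_graph(skel, warn_nonthin = FALSE)
  decisions <- g$components
  decisions$kept <- decisions$ratio >= params$min_length_per_node_ratio &
    decisions$total_length >= params$min_branch_length
  drop_ids <- decisions$component[!decisions$kept]
  if (length(drop_ids)) {
    skel[g$pixel_idx[g$membership %in% drop_ids]] <- FALSE
  }
  out <- skeleton_graph(skel, warn_nonthin = FALSE)
  attr(out, "decisions") <- decisions
  out
}

#' Restrict a binary mask to components with surviving skeleton
#'
#' Keeps the 8-connected components of `mask` that contain at least one
#' pixel of the (filtered) skeleton, so that area quantification uses only
#' the vessels that survived piece-by-piece analysis.
#'
#' @param graph A (filtered) [skeleton_graph()].
#' @param mask Logical matrix, the pre-skeleton binary network; the skeleton
#'   must be a subset of it.
#' @return Logical matrix, the restricted mask.
#' @export
mask_from_graph <- function(graph, mask) {
  stopifnot(inherits(graph, "skeleton_graph"))
  assert_mask(mask, graph$dim)
  if (any(graph$skeleton & !mask)) {
    vca_stop("the skeleton is not a subset of `mask`")
  }
  if (length(graph$pixel_idx) == 0L) {
    return(matrix(FALSE, graph$dim[1L], graph$dim[2L]))
  }
  lab <- label_components8(mask)
  keep <- unique(lab[graph$pixel_idx])
  out <- mask & matrix(lab %in% keep, nrow(mask), ncol(mask))
  out
}
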