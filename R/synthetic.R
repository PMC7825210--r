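#' Parameters for the synthetic angiogram generator
#'
#' The generator emulates en-face OCTA angiograms: bright branching vessel
#' trees of varying caliber on a darker background, multiplicative speckle
#' noise, elongated "tail" artifacts smearing downward beneath vessels, and
#' isolated bright noise clusters placed well away from any vessel. Defaults
#' describe a moderately noisy 256 x 256 scan.
#'
#' @param image_size `c(rows, cols)` (default `c(256, 256)`).
#' @param n_trees Number of vessel trees (default 5).
#' @param branch_prob Per-growth-step probability of spawning a child branch
#'   (default 0.08).
#' @param width_range `c(min, max)` vessel caliber in pixels (default
#'   `c(3, 7)`); root calibers are drawn from this range and children taper
#'   toward the minimum.
#' @param step_len Pixels advanced per growth step (default 2).
#' @param tortuosity Standard deviation of the per-step heading change in
#'   radians (default 0.15).
#' @param speckle_sigma Scale of multiplicative Gaussian speckle,
#'   `pixel * (1 + speckle_sigma * N(0,1))` (default 0.15).
#' @param n_noise_clusters Isolated bright blobs to inject (default 6).
#' @param cluster_radius_px Maximum blob radius in pixels (default 3).
#' @param tail_artifact_strength Relative intensity in `[0, 1]` of the
#'   decaying downward smear under each vessel pixel (default 0.4).
#' @param background_level Background intensity in `[0, 1)` (default 0.08);
#'   must be below `vessel_intensity`.
#' @param vessel_intensity On-vessel intensity before noise (default 0.85).
#' @param target_length_px Optional centerline pixel budget: growth stops
#'   once the true centerline reaches this many pixels (trees keep being
#'   seeded until the budget is met). `NULL` (default) grows exactly
#'   `n_trees` trees.
#' @param seed Integer RNG seed; generation is fully deterministic given the
#'   seed (R's default Mersenne-Twister generator, applied locally without
#'   touching the caller's RNG state).
#' @return A `synth_params` list.
#' @export
synth_params <- function(image_size = c(256L, 256L), n_trees = 5L,
                         branch_prob = 0.08, width_range = c(3, 7),
                         step_len = 2, tortuosity = 0.15,
                         speckle_sigma = 0.15, n_noise_clusters = 6L,
                         cluster_radius_px = 3, tail_artifact_strength = 0.4,
                         background_level = 0.08, vessel_intensity = 0.85,
                         target_length_px = NULL, seed = 1L) {
  p <- list(image_size = as.integer(image_size), n_trees = as.integer(n_trees),
            branch_prob = branch_prob, width_range = width_range,
            step_len = step_len, tortuosity = tortuosity,
            speckle_sigma = speckle_sigma,
            n_noise_clusters = as.integer(n_noise_clusters),
            cluster_radius_px = cluster_radius_px,
            tail_artifact_strength = tail_artifact_strength,
            background_level = background_level,
            vessel_intensity = vessel_intensity,
            target_length_px = if (is.null(target_length_px)) NULL
                               else as.numeric(target_length_px),
            seed = as.integer(seed))
  validate_synth_params(p)
  structure(p, class = "synth_params")
}

validate_synth_params <- function(p) {
  fail <- function(field, why) {
    vca_stop(sprintf("invalid synth_params field `%s`: %s", field, why))
  }
  if (length(p$image_size) != 2L || any(p$image_size < 16L)) {
    fail("image_size", "must be c(rows, cols) with both >= 16")
  }
  if (p$n_trees < 0L) fail("n_trees", "must be >= 0")
  if (p$branch_prob < 0 || p$branch_prob > 1) fail("branch_prob", "must be in [0, 1]")
  if (length(p$width_range) != 2L || p$width_range[1L] < 1 ||
      p$width_range[2L] < p$width_range[1L]) {
    fail("width_range", "need 1 <= min <= max")
  }
  if (p$step_len <= 0) fail("step_len", "must be > 0")
  if (p$tortuosity < 0) fail("tortuosity", "must be >= 0")
  if (p$speckle_sigma < 0) fail("speckle_sigma", "must be >= 0")
  if (p$n_noise_clusters < 0L) fail("n_noise_clusters", "must be >= 0")
  if (p$cluster_radius_px < 1) fail("cluster_radius_px", "must be >= 1")
  if (p$tail_artifact_strength < 0 || p$tail_artifact_strength > 1) {
    fail("tail_artifact_strength", "must be in [0, 1]")
  }
  if (p$background_level < 0 || p$background_level >= p$vessel_intensity) {
    fail("background_level", "must be in [0, vessel_intensity)")
  }
  if (p$vessel_intensity > 1) fail("vessel_intensity", "must be <= 1")
  if (!is.null(p$target_length_px) && p$target_length_px < 1) {
    fail("target_length_px", "must be >= 1 when given")
  }
  invisible(p)
}

# 8-connected integer pixels along a segment (Bresenham-style interpolation).
raster_segment <- function(r0, c0, r1, c1) {
  n <- max(abs(round(r1) - round(r0)), abs(round(c1) - round(c0)), 1)
  cbind(round(seq(r0, r1, length.out = n + 1)),
        round(seq(c0, c1, length.out = n + 1)))
}

#' Generate a synthetic angiogram with exact ground truth
#'
#' Vessel trees are grown as random walks: each branch starts from a border
#' (or interior, for later trees) root heading inward, advances `step_len`
#' pixels per step with its heading perturbed by `tortuosity`, and spawns
#' child branches with probability `branch_prob` per step; root calibers are
#' drawn from `width_range` and children taper toward the minimum caliber.
#' The mask is the union of disks of the local radius centered on every
#' centerline pixel. The noise-free render is `background_level` off-mask
#' and `vessel_intensity` on-mask; tail artifacts then smear a decaying
#' intensity 3--10 px downward from each vessel pixel, isolated bright
#' clusters are placed at least 10 px (center to nearest mask pixel) from
#' any vessel, and finally each pixel is multiplied by
#' `(1 + speckle_sigma * N(0, 1))` and clipped to `[0, 1]`.
#'
#' @param params A [synth_params()].
#' @return A `synthetic_angiogram` object: `image` (numeric matrix),
#'   `mask` and `centerline` (logical matrices, `centerline` a subset of
#'   `mask`), `total_length_px`, `total_area_px`, `mean_width_px`,
#'   `noise_cluster_pixels` (two-column coordinate matrix) with parallel
#'   `noise_cluster_ids`, and `params`.
#' @examples
#' truth <- generate_angiogram(synth_params(image_size = c(64, 64), seed = 7))
#' truth$total_length_px
#' @export
generate_angiogram <- function(params = synth_params()) {
  validate_synth_params(params)
  withr::with_seed(params$seed, generate_angiogram_impl(params))
}

generate_angiogram_impl <- function(p) {
  nr <- p$image_size[1L]
  nc <- p$image_size[2L]
  centerline <- matrix(FALSE, nr, nc)
  radius_at <- list()  # per-branch: coords + radius, stamped later
  budget <- p$target_length_px %||% Inf
  count_cl <- function() sum(centerline)

  # Branches claim a corridor (tube dilated by 1 px) in `claimed` under their
  # own id; a branch terminates when it would enter another branch's corridor,
  # so tubes never overlap and the true centerline stays in one-to-one
  # correspondence with the rendered mask. A child branch gets a short grace
  # period while escaping its parent's tube, during which the mask is stamped
  # (keeping the junction connected) but no centerline pixels are recorded
  # (they would duplicate the parent's).
  claimed <- matrix(0L, nr, nc)
  next_branch_id <- 1L

  stamp_claim <- function(seg, radius, id) {
    offs <- disk_offsets(radius + 1)
    for (i in seq_len(nrow(offs))) {
      rr <- seg[, 1L] + offs[i, 1L]
      cc <- seg[, 2L] + offs[i, 2L]
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      lin <- cbind(rr[ok], cc[ok])
      free <- claimed[lin] == 0L
      claimed[lin[free, , drop = FALSE]] <<- id
    }
  }

  grow_tree <- function(root, heading, caliber) {
    # stack of branches; children are shorter and spawning stops at depth 4,
    # so the branching process is bounded regardless of branch_prob
    stack <- list(list(pos = root, heading = heading, caliber = caliber,
                       steps = sample(30:80, 1L), depth = 0L, grace = 0L,
                       parent = 0L))
    while (length(stack) > 0L && count_cl() < budget) {
      br <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      pos <- br$pos
      heading <- br$heading
      id <- next_branch_id
      next_branch_id <<- next_branch_id + 1L
      for (s in seq_len(br$steps)) {
        if (count_cl() >= budget) break
        heading <- heading + stats::rnorm(1L, 0, p$tortuosity)
        nxt <- pos + p$step_len * c(sin(heading), cos(heading))
        seg <- raster_segment(pos[1L], pos[2L], nxt[1L], nxt[2L])
        seg <- seg[seg[, 1L] >= 2L & seg[, 1L] <= nr - 1L &
                   seg[, 2L] >= 2L & seg[, 2L] <= nc - 1L, , drop = FALSE]
        if (nrow(seg) == 0L) break  # left the canvas
        in_grace <- s <= br$grace
        owner <- claimed[cbind(seg[, 1L], seg[, 2L])]
        hit <- if (in_grace) {
          rep(FALSE, nrow(seg))       # free passage out of the parent tube
        } else {
          owner != 0L & owner != id
        }
        if (any(hit)) {  # truncate at the first foreign corridor pixel
          seg <- seg[seq_len(which(hit)[1L] - 1L), , drop = FALSE]
          owner <- owner[seq_len(nrow(seg))]
        }
        if (nrow(seg)) {
          # while escaping the parent tube, record centerline only for pixels
          # already outside every existing corridor: inside, the parent tube
          # provides both mask area and centerline
          own <- owner == 0L | owner == id
          cl_px <- seg[own, , drop = FALSE]
          if (nrow(cl_px)) {
            centerline[cl_px] <<- TRUE
            stamp_claim(cl_px, br$caliber / 2, id)
          }
          radius_at[[length(radius_at) + 1L]] <<-
            list(coords = seg, radius = br$caliber / 2)
        }
        if (any(hit)) break
        pos <- nxt
        if (pos[1L] < 2 || pos[1L] > nr - 1 || pos[2L] < 2 || pos[2L] > nc - 1) break
        if (br$depth < 4L && !in_grace && stats::runif(1L) < p$branch_prob) {
          child_cal <- max(p$width_range[1L],
                           br$caliber * stats::runif(1L, 0.6, 0.85))
          turn <- sample(c(-1, 1), 1L) * stats::runif(1L, 0.35, 0.9)
          child_steps <- max(8L, as.integer(round(br$steps * stats::runif(1L, 0.4, 0.7))))
          child_grace <- ceiling((br$caliber / 2 + child_cal / 2 + 2) / p$step_len)
          stack[[length(stack) + 1L]] <-
            list(pos = pos, heading = heading + turn, caliber = child_cal,
                 steps = child_steps, depth = br$depth + 1L,
                 grace = as.integer(child_grace), parent = id)
        }
      }
    }
  }

  seed_tree <- function(first) {
    if (first) {
      side <- sample(1:4, 1L)
      t <- stats::runif(1L, 0.2, 0.8)
      root <- switch(side,
        c(2, t * nc), c(nr - 1, t * nc), c(t * nr, 2), c(t * nr, nc - 1))
      # headings: sin = row step, cos = col step; side 1 (top) grows down, etc.
      if (side == 1L) heading <- stats::runif(1L, 0.25 * pi, 0.75 * pi)
      if (side == 2L) heading <- stats::runif(1L, -0.75 * pi, -0.25 * pi)
      if (side == 3L) heading <- stats::runif(1L, -0.25 * pi, 0.25 * pi)
      if (side == 4L) heading <- stats::runif(1L, 0.75 * pi, 1.25 * pi)
    } else {
      root <- c(stats::runif(1L, 0.2 * nr, 0.8 * nr),
                stats::runif(1L, 0.2 * nc, 0.8 * nc))
      heading <- stats::runif(1L, 0, 2 * pi)
    }
    caliber <- stats::runif(1L, p$width_range[1L], p$width_range[2L])
    grow_tree(root, heading, caliber)
  }

  if (is.finite(budget)) {
    i <- 0L
    while (count_cl() < budget && i < 1000L) {
      i <- i + 1L
      seed_tree(i == 1L)
    }
  } else {
    for (i in seq_len(p$n_trees)) seed_tree(i == 1L)
  }

  # stamp disks: group centerline pixels by radius for vectorized stamping
  mask <- matrix(FALSE, nr, nc)
  if (length(radius_at)) {
    radii <- vapply(radius_at, `[[`, numeric(1), "radius")
    for (r in unique(radii)) {
      coords <- do.call(rbind, lapply(radius_at[radii == r], `[[`, "coords"))
      offs <- disk_offsets(r)
      for (i in seq_len(nrow(offs))) {
        rr <- coords[, 1L] + offs[i, 1L]
        cc <- coords[, 2L] + offs[i, 2L]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        mask[cbind(rr[ok], cc[ok])] <- TRUE
      }
    }
  }

  img <- matrix(p$background_level, nr, nc)
  img[mask] <- p$vessel_intensity

  # tail artifacts: each vessel pixel leaks decaying intensity downward for a
  # random 3-10 px (decay factor 0.75 per pixel)
  if (p$tail_artifact_strength > 0 && any(mask)) {
    tail_len <- matrix(0L, nr, nc)
    tail_len[mask] <- sample(3:10, sum(mask), replace = TRUE)
    tail_img <- matrix(0, nr, nc)
    for (d in 1:10) {
      src <- mask & (tail_len >= d)
      contrib <- shift_mat(src, d, 0L) *
        (p$tail_artifact_strength * p$vessel_intensity * 0.75^(d - 1))
      tail_img <- pmax(tail_img, contrib)
    }
    img <- pmax(img, tail_img)
  }

  # isolated bright noise clusters, >= 10 px (center to nearest mask pixel)
  cluster_pixels <- matrix(integer(0), 0L, 2L,
                           dimnames = list(NULL, c("row", "col")))
  cluster_ids <- integer(0)
  if (p$n_noise_clusters > 0L) {
    mc <- mask_coords(mask)
    margin <- ceiling(p$cluster_radius_px) + 1L
    for (k in seq_len(p$n_noise_clusters)) {
      placed <- FALSE
      for (attempt in seq_len(500L)) {
        ctr <- c(sample(margin:(nr - margin), 1L),
                 sample(margin:(nc - margin), 1L))
        # isolated means isolated: >= 10 px from vessels and from other
        # clusters, so clusters never merge into elongated vessel-like blobs
        obstacles <- rbind(mc, cluster_pixels)
        dmin <- if (nrow(obstacles)) {
          sqrt(min((obstacles[, 1L] - ctr[1L])^2 + (obstacles[, 2L] - ctr[2L])^2))
        } else Inf
        if (dmin >= 10) {
          rad <- stats::runif(1L, 1.2, p$cluster_radius_px)
          offs <- disk_offsets(rad)
          px <- cbind(ctr[1L] + offs[, 1L], ctr[2L] + offs[, 2L])
          img[px] <- pmin(1, p$vessel_intensity * stats::runif(1L, 0.9, 1.05))
          colnames(px) <- c("row", "col")
          cluster_pixels <- rbind(cluster_pixels, px)
          cluster_ids <- c(cluster_ids, rep(k, nrow(px)))
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        vca_stop("could not place an isolated noise cluster >= 10 px from vessels; the image is too crowded")
      }
    }
  }

  if (p$speckle_sigma > 0) {
    img <- img * (1 + p$speckle_sigma * stats::rnorm(length(img)))
  }
  img <- matrix(pmin(pmax(img, 0), 1), nr, nc)

  total_length <- sum(centerline)
  total_area <- sum(mask)
  structure(list(image = img, mask = mask, centerline = centerline,
                 total_length_px = total_length, total_area_px = total_area,
                 mean_width_px = if (total_length > 0) total_area / total_length
                                 else NA_real_,
                 noise_cluster_pixels = cluster_pixels,
                 noise_cluster_ids = cluster_ids, params = p),
            class = "synthetic_angiogram")
}

#' @export
print.synthetic_angiogram <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_angiogram> %dx%d, length %d px, area %d px^2, ",
                     "mean width %.2f px, %d noise-cluster px\n"),
              nrow(x$image), ncol(x$image), x$total_length_px, x$total_area_px,
              x$mean_width_px, nrow(x$noise_cluster_pixels)))
  invisible(x)
}

#' Write a synthetic angiogram and its ground truth to disk
#'
#' Writes `image.tif` (32-bit float TIFF: the noisy render, exact to single
#' precision), `mask.png` and `centerline.png` (0/255 PNG, exact),
#' `noise_clusters.csv`, and a plain-text `manifest.txt` of `key=value`
#' scalar truths (totals, mean width, seed, and all generator parameters).
#'
#' @param truth A [generate_angiogram()] result.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest file, invisibly.
#' @export
write_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "synthetic_angiogram"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) vca_io_stop(sprintf("cannot create output directory %s", dir))
  probe <- file.path(dir, ".octavca_write_test")
  if (!isTRUE(tryCatch({ file.create(probe, showWarnings = FALSE) },
                       error = function(e) FALSE))) {
    vca_io_stop(sprintf("directory %s is not writable", dir))
  }
  unlink(probe)
  tiff::writeTIFF(truth$image, file.path(dir, "image.tif"),
                  bits.per.sample = 32L)
  write_gray_png(truth$mask, file.path(dir, "mask.png"))
  write_gray_png(truth$centerline, file.path(dir, "centerline.png"))
  cl <- as.data.frame(truth$noise_cluster_pixels)
  cl$cluster <- truth$noise_cluster_ids
  utils::write.csv(cl, file.path(dir, "noise_clusters.csv"), row.names = FALSE)
  p <- truth$params
  kv <- c(
    total_length_px = truth$total_length_px,
    total_area_px = truth$total_area_px,
    mean_width_px = truth$mean_width_px,
    image_rows = nrow(truth$image), image_cols = ncol(truth$image),
    n_trees = p$n_trees, branch_prob = p$branch_prob,
    width_min = p$width_range[1L], width_max = p$width_range[2L],
    step_len = p$step_len, tortuosity = p$tortuosity,
    speckle_sigma = p$speckle_sigma, n_noise_clusters = p$n_noise_clusters,
    cluster_radius_px = p$cluster_radius_px,
    tail_artifact_strength = p$tail_artifact_strength,
    background_level = p$background_level,
    vessel_intensity = p$vessel_intensity,
    target_length_px = p$target_length_px %||% NA,
    seed = p$seed)
  manifest <- file.path(dir, "manifest.txt")
  writeLines(sprintf("%s=%s", names(kv),
                     vapply(kv, format, character(1), digits = 17)),
             manifest)
  invisible(manifest)
}

#' Read a synthetic angiogram truth directory back
#'
#' Inverse of [write_truth()].
#'
#' @param dir Directory written by [write_truth()].
#' @return A `synthetic_angiogram` object.
#' @export
read_truth <- function(dir) {
  manifest <- file.path(dir, "manifest.txt")
  if (!file.exists(manifest)) {
    vca_io_stop(sprintf("no manifest.txt in %s", dir))
  }
  lines <- readLines(manifest)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(
    vapply(kv, function(x) paste(x[-1L], collapse = "="), character(1)),
    vapply(kv, `[[`, character(1), 1L))
  num <- function(k) {
    v <- vals[[k]]
    if (identical(v, "NA")) NA_real_ else as.numeric(v)
  }
  img <- tiff::readTIFF(file.path(dir, "image.tif"))
  cl_df <- utils::read.csv(file.path(dir, "noise_clusters.csv"))
  clusters <- matrix(as.integer(c(cl_df$row, cl_df$col)), ncol = 2L,
                     dimnames = list(NULL, c("row", "col")))
  cluster_ids <- as.integer(cl_df$cluster)
  p <- synth_params(
    image_size = c(num("image_rows"), num("image_cols")),
    n_trees = num("n_trees"), branch_prob = num("branch_prob"),
    width_range = c(num("width_min"), num("width_max")),
    step_len = num("step_len"), tortuosity = num("tortuosity"),
    speckle_sigma = num("speckle_sigma"),
    n_noise_clusters = num("n_noise_clusters"),
    cluster_radius_px = num("cluster_radius_px"),
    tail_artifact_strength = num("tail_artifact_strength"),
    background_level = num("background_level"),
    vessel_intensity = num("vessel_intensity"),
    target_length_px = if (is.na(num("target_length_px"))) NULL
                       else num("target_length_px"),
    seed = num("seed"))
  structure(list(image = img,
                 mask = read_mask_png(file.path(dir, "mask.png")),
                 centerline = read_mask_png(file.path(dir, "centerline.png")),
                 total_length_px = num("total_length_px"),
                 total_area_px = num("total_area_px"),
                 mean_width_px = num("mean_width_px"),
                 noise_cluster_pixels = clusters,
                 noise_cluster_ids = cluster_ids, params = p),
            class = "synthetic_angiogram")
}
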