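# Independent brute-force oracles and small fixture builders. These must stay
# naive (per-pixel loops, queue BFS) so they check the vectorized
# implementations from a genuinely different route.

# Exhaustive Otsu: loop over every candidate bin edge, recompute class
# weights and means from scratch, maximize between-class variance.
bf_otsu <- function(img, n_bins = 256L) {
  v <- as.vector(img)
  bins <- pmin(floor(v * n_bins) + 1L, n_bins)
  h <- tabulate(bins, n_bins)
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  best_k <- NA_integer_
  best_s <- -Inf
  for (k in seq_len(n_bins - 1L)) {
    n0 <- sum(h[1:k])
    n1 <- sum(h) - n0
    if (n0 == 0L || n1 == 0L) next
    w0 <- n0 / sum(h)
    w1 <- n1 / sum(h)
    mu0 <- sum(h[1:k] * centers[1:k]) / n0
    mu1 <- sum(h[(k + 1L):n_bins] * centers[(k + 1L):n_bins]) / n1
    s <- w0 * w1 * (mu0 - mu1)^2
    if (s > best_s) {
      best_s <- s
      best_k <- k
    }
  }
  best_k / n_bins
}

# Queue-based BFS closure over effective pixels with Euclidean <= d_max
# adjacency, seeded from `starts`.
bf_bfs_closure <- function(eff, starts, d_max = 2) {
  nr <- nrow(eff)
  nc <- ncol(eff)
  r <- floor(d_max)
  net <- starts
  queue <- which(starts)
  while (length(queue)) {
    p <- queue[1L]
    queue <- queue[-1L]
    pr <- (p - 1L) %% nr + 1L
    pc <- (p - 1L) %/% nr + 1L
    for (dr in -r:r) for (dc in -r:r) {
      if (dr == 0L && dc == 0L) next
      if (dr^2 + dc^2 > d_max^2) next
      rr <- pr + dr
      cc <- pc + dc
      if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
      if (eff[rr, cc] && !net[rr, cc]) {
        net[rr, cc] <- TRUE
        queue <- c(queue, rr + (cc - 1L) * nr)
      }
    }
  }
  net
}

# Per-pixel 8-neighbor counting with explicit loops.
bf_neighbor_count <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    n <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      rr <- r + dr
      cc <- c + dc
      if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc && mask[rr, cc]) {
        n <- n + 1L
      }
    }
    out[r, c] <- n
  }
  out
}

# Per-pixel starting-point scan with explicit probe-line loops.
bf_start_points <- function(img, thr, line_length, dirs, p_max) {
  nr <- nrow(img)
  nc <- ncol(img)
  half <- (line_length - 1L) %/% 2L
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (img[r, c] < thr) next
    empty <- 0L
    for (d in dirs) {
      has <- FALSE
      for (m in c(-half:-1, 1:half)) {
        rr <- r + m * d[1L]
        cc <- c + m * d[2L]
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc && img[rr, cc] >= thr) {
          has <- TRUE
        }
      }
      if (!has) empty <- empty + 1L
    }
    out[r, c] <- (empty / length(dirs)) < p_max
  }
  out
}

# Flood-fill 8-connected labelling by queue (oracle for igraph-backed
# labelling and for mask_from_graph).
bf_label8 <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (p in which(mask)) {
    if (lab[p] != 0L) next
    nxt <- nxt + 1L
    queue <- p
    lab[p] <- nxt
    while (length(queue)) {
      q <- queue[1L]
      queue <- queue[-1L]
      qr <- (q - 1L) %% nr + 1L
      qc <- (q - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- qr + dr
        cc <- qc + dc
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        if (mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          queue <- c(queue, rr + (cc - 1L) * nr)
        }
      }
    }
  }
  lab
}

# Fixtures -------------------------------------------------------------------

# logical matrix with each pixel TRUE with probability p
random_map <- function(nr, nc, p, seed) {
  withr::with_seed(seed, matrix(stats::runif(nr * nc) < p, nr, nc))
}

# a "Y": one vertical arm and two diagonal arms of `arm` pixels each,
# meeting at a single junction pixel
y_skeleton <- function(arm = 10L) {
  n <- 2L * arm + 3L
  m <- matrix(FALSE, n, n)
  cj <- arm + 2L
  m[(cj - arm):(cj - 1L), cj] <- TRUE          # up
  m[cj, cj] <- TRUE                            # junction
  for (i in seq_len(arm)) {
    m[cj + i, cj - i] <- TRUE                  # down-left diagonal
    m[cj + i, cj + i] <- TRUE                  # down-right diagonal
  }
  m
}

hline_mask <- function(nr = 10L, nc = 30L, row = 5L, cols = 4:23) {
  m <- matrix(FALSE, nr, nc)
  m[row, cols] <- TRUE
  m
}

# quiet parameters: no noise of any kind
clean_params <- function(...) {
  synth_params(speckle_sigma = 0, n_noise_clusters = 0L,
               tail_artifact_strength = 0, ...)
}

# drop attributes (e.g. the recorded threshold) for raw raster comparisons
strip <- function(m) {
  structure(as.logical(m), dim = dim(m))
}
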