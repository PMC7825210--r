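test_that("starting-point detection matches the per-pixel probe-line oracle", {
  dirs4 <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  dirs2 <- dirs4[1:2]
  withr::with_seed(11, {
    for (i in 1:6) {
      img <- matrix(runif(32 * 32), 32, 32)
      got <- detect_starting_points(
        img, start_point_params(effective_intensity = 0.5))
      expect_identical(strip(got), strip(bf_start_points(img, 0.5, 7L, dirs4, 0.5)))
      got2 <- detect_starting_points(
        img, start_point_params(line_length = 5, n_directions = 2,
                                effective_intensity = 0.6,
                                empty_line_proportion_max = 0.75))
      expect_identical(strip(got2),
                       strip(bf_start_points(img, 0.6, 5L, dirs2, 0.75)))
    }
  })
})

test_that("a solid bright square yields interior starting points; a dark image none", {
  img <- matrix(0, 21, 21)
  img[1:21, 1:21] <- 1
  st <- detect_starting_points(img, start_point_params(effective_intensity = 0.5))
  expect_true(st[11, 11])  # all probe lines full at the center
  zero <- matrix(0, 16, 16)
  st0 <- detect_starting_points(zero, start_point_params(effective_intensity = 0.5))
  expect_identical(sum(st0), 0L)
})

test_that("network growth equals the BFS-closure oracle exactly", {
  withr::with_seed(17, {
    for (i in 1:15) {
      eff <- matrix(runif(32 * 32), 32, 32)
      img <- eff
      emap <- img >= 0.6
      starts <- matrix(FALSE, 32, 32)
      cand <- which(emap)
      if (length(cand) == 0) next
      starts[sample(cand, min(4, length(cand)))] <- TRUE
      got <- grow_network(img, starts, growth_params(effective_intensity = 0.6))
      want <- bf_bfs_closure(emap, starts, 2)
      expect_identical(strip(got), strip(want))
      expect_true(all(got[starts]))  # starts always in the closure
    }
  })
})

test_that("growth bridges gaps up to the 2-px admission distance and no further", {
  img <- matrix(0, 9, 40)
  img[5, 3:18] <- 1
  img[5, 20:38] <- 1   # one dark pixel: separation 2
  starts <- matrix(FALSE, 9, 40)
  starts[5, 3] <- TRUE
  net <- grow_network(img, starts, growth_params(effective_intensity = 0.5))
  expect_true(all(net[5, 20:38]))  # bridged
  img2 <- matrix(0, 9, 40)
  img2[5, 3:15] <- 1
  img2[5, 19:38] <- 1  # three dark pixels: separation 3 > d_max
  net2 <- grow_network(img2, starts, growth_params(effective_intensity = 0.5))
  expect_false(any(net2[5, 19:38]))
  expect_identical(sum(grow_network(img, matrix(FALSE, 9, 40),
                                    growth_params(effective_intensity = 0.5))),
                   0L)  # empty starts -> empty network
})

test_that("growth is monotone in the seed set and antitone in the threshold", {
  withr::with_seed(23, {
    img <- matrix(runif(40 * 40), 40, 40)
    emap <- which(img >= 0.55)
    s1 <- matrix(FALSE, 40, 40)
    s1[sample(emap, 3)] <- TRUE
    s2 <- s1
    s2[sample(emap, 5)] <- TRUE
    g1 <- grow_network(img, s1, growth_params(effective_intensity = 0.55))
    g2 <- grow_network(img, s2, growth_params(effective_intensity = 0.55))
    expect_true(all(g2[g1]))  # larger seed set grows a superset
    g_hi <- grow_network(img, s1, growth_params(effective_intensity = 0.7))
    expect_true(all(g1[g_hi]))  # raising the threshold never grows the set
  })
})

test_that("quarter-turn rotation is a lossless bijection tracked by impulses", {
  img <- matrix(0, 7, 9)
  img[2, 5] <- 1
  for (k in 0:3) {
    rot <- rotate_quarter(img, k)
    hit <- which(rot == 1, arr.ind = TRUE)
    back <- rotated_to_original(hit, k, dim(img))
    expect_identical(unname(back), cbind(2L, 5L))
  }
  r <- matrix(runif(12 * 5), 12, 5)
  expect_identical(rotate_quarter(rotate_quarter(r, 1), 3), r)
  expect_identical(
    rotate_quarter(rotate_quarter(rotate_quarter(rotate_quarter(r, 1), 1), 1), 1),
    r)
  expect_identical(rotate_quarter(r, 0), r)
  expect_error(rotate_quarter(r, 4), "quarter")
  expect_error(rotate_quarter(r, 1.5), "quarter")
})

test_that("rotation-merged extraction contains the unrotated run and is equivariant", {
  tr <- generate_angiogram(synth_params(image_size = c(96, 96), seed = 5))
  img <- tr$image
  thr <- otsu_threshold(img)
  sp <- start_point_params(effective_intensity = thr)
  gp <- growth_params(effective_intensity = thr)
  merged <- extract_network(img, sp, gp)
  single <- grow_network(img, detect_starting_points(img, sp), gp)
  expect_true(all(merged[single]))  # union property
  rot <- extract_network(rotate_quarter(img, 1), sp, gp)
  expect_identical(strip(rotate_quarter(rot, 3)), strip(merged))
})

test_that("noise-free extraction equals BFS closure of the merged starting points", {
  tr <- generate_angiogram(clean_params(image_size = c(96, 96), n_trees = 2,
                                        seed = 9))
  img <- tr$image
  thr <- otsu_threshold(img)
  sp <- start_point_params(effective_intensity = thr)
  starts_all <- matrix(FALSE, nrow(img), ncol(img))
  for (k in 0:3) {
    st <- detect_starting_points(rotate_quarter(img, k), sp)
    starts_all <- starts_all | rotate_quarter(st, (4 - k) %% 4)
  }
  want <- bf_bfs_closure(img >= thr, starts_all, 2)
  got <- extract_network(img, sp, growth_params(effective_intensity = thr))
  expect_identical(strip(got), strip(want))
})
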