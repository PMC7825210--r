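test_that("thinning leaves an already-thin line untouched and shrinks within input", {
  line <- hline_mask()
  expect_identical(skeletonize(line), line)
  expect_identical(sum(skeletonize(matrix(FALSE, 5, 5))), 0L)
  withr::with_seed(3, {
    for (i in 1:5) {
      blob <- random_map(24, 24, 0.55, seed = 100 + i)
      sk <- skeletonize(blob)
      expect_true(all(blob[sk]))  # skeleton within the mask
    }
  })
})

test_that("a filled rectangle thins to a single near-axial unit-width path", {
  rect <- matrix(FALSE, 20, 45)
  rect[8:12, 5:40] <- TRUE
  sk <- skeletonize(rect)
  lab <- bf_label8(sk)
  expect_identical(max(lab), 1L)  # component count preserved
  deg <- bf_neighbor_count(sk)
  expect_true(all(deg[sk] <= 2))  # a simple path: no junctions
  expect_identical(sum(deg[sk] == 1), 2L)  # exactly two ends
})

test_that("the branch graph classifies a line and a Y by forced counts", {
  g <- skeleton_graph(hline_mask())
  expect_identical(nrow(g$components), 1L)
  expect_identical(g$components$total_length, 20L)
  expect_identical(g$components$n_bifurcations, 0L)
  expect_identical(g$components$n_breakpoints, 2L)
  expect_identical(nrow(g$branches), 1L)
  expect_identical(g$branches$length, 20L)

  y <- skeleton_graph(y_skeleton(10))
  expect_identical(y$components$n_bifurcations, 1L)
  expect_identical(y$components$n_breakpoints, 3L)
  expect_identical(nrow(y$branches), 3L)
  expect_identical(y$components$total_length, 31L)
})

test_that("pixel classification agrees with brute-force 8-neighbor counting", {
  withr::with_seed(7, {
    for (i in 1:10) {
      sk <- skeletonize(random_map(20, 20, 0.4, seed = 200 + i))
      if (sum(sk) == 0) next
      g <- skeleton_graph(sk, warn_nonthin = FALSE)
      deg_bf <- bf_neighbor_count(sk)
      expect_identical(g$degree, deg_bf[g$pixel_idx])
      n_bif_bf <- sum(deg_bf[sk] >= 3)
      n_end_bf <- sum(deg_bf[sk] == 1)
      expect_identical(sum(g$components$n_bifurcations), n_bif_bf)
      expect_identical(sum(g$components$n_breakpoints), n_end_bf)
    }
  })
})

test_that("isolated pixels and branch totals keep consistent bookkeeping", {
  m <- matrix(FALSE, 9, 9)
  m[5, 5] <- TRUE
  g <- skeleton_graph(m)
  expect_identical(g$components$total_length, 1L)
  expect_identical(g$components$n_breakpoints, 0L)
  expect_identical(g$components$n_bifurcations, 0L)
  # branch pixel sets cover every non-isolated pixel; lengths over-count only
  # shared junction pixels
  y <- skeleton_graph(y_skeleton(6))
  covered <- sort(unique(unlist(y$branches$pixels)))
  expect_identical(covered, sort(y$pixel_idx))
  expect_gte(sum(y$branches$length),
             y$components$total_length - y$components$n_bifurcations)
})

test_that("a non-thin skeleton triggers a warning but still builds", {
  m <- matrix(FALSE, 6, 6)
  m[2:3, 2:3] <- TRUE
  expect_warning(g <- skeleton_graph(m), "unit-width")
  expect_identical(nrow(g$components), 1L)
})

test_that("the ratio rule removes short free segments and keeps long lines", {
  five <- matrix(FALSE, 9, 9)
  five[5, 3:7] <- TRUE  # ratio 5/2 = 2.5 < 3
  f <- filter_pieces(skeleton_graph(five))
  expect_identical(sum(f$skeleton), 0L)
  forty <- matrix(FALSE, 9, 50)
  forty[5, 6:45] <- TRUE  # ratio 40/2 = 20, branch length 40
  f2 <- filter_pieces(skeleton_graph(forty))
  expect_identical(f2$skeleton, forty)
})

test_that("short terminal branches are pruned, the junction pixel survives", {
  m <- matrix(FALSE, 15, 40)
  m[8, 4:35] <- TRUE   # long trunk
  m[5:7, 20] <- TRUE   # 3-px stub onto the trunk
  g <- filter_pieces(skeleton_graph(m))
  expect_true(all(g$skeleton[8, 4:35]))
  expect_false(any(g$skeleton[5:7, 20]))
})

test_that("iterated pruning removes stub chains that expose new short branches", {
  m <- matrix(FALSE, 15, 40)
  m[8, 4:35] <- TRUE   # trunk
  m[5:7, 20] <- TRUE   # stub onto the trunk
  m[6, 21:22] <- TRUE  # side twig off the stub: pruning it exposes the stub
  g <- filter_pieces(skeleton_graph(m))
  # the whole stub chain is gone; the trunk survives intact up to a possible
  # 1-px connectivity-preserving jog at the former junction
  expect_identical(sum(g$skeleton), 32L)
  expect_true(all(which(g$skeleton, arr.ind = TRUE)[, "row"] %in% 7:8))
  expect_identical(max(bf_label8(g$skeleton)), 1L)
  expect_identical(g$components$n_breakpoints, 2L)
  expect_identical(g$components$n_bifurcations, 0L)
})

test_that("filtering is idempotent and never grows the skeleton", {
  for (s in c(4, 9)) {
    tr <- generate_angiogram(synth_params(image_size = c(128, 128), seed = s))
    seg0 <- segment_angiogram(tr$image)
    g1 <- filter_pieces(skeleton_graph(seg0$skeleton_raw, warn_nonthin = FALSE))
    expect_lte(sum(g1$skeleton), sum(seg0$skeleton_raw))
    g2 <- filter_pieces(g1)
    expect_identical(g2$skeleton, g1$skeleton)
  }
})

test_that("filtering is the identity on a clean well-proportioned tree", {
  y <- y_skeleton(12)  # arms 12 >= 5; ratio 37/4 = 9.25 >= 3
  g <- filter_pieces(skeleton_graph(y))
  expect_identical(g$skeleton, y)
})

test_that("mask_from_graph keeps exactly the components with surviving skeleton", {
  mask <- matrix(FALSE, 20, 40)
  mask[8:10, 4:35] <- TRUE    # vessel-like bar
  mask[15:17, 10:12] <- TRUE  # small blob far from the bar
  sk <- skeletonize(mask)
  g <- filter_pieces(skeleton_graph(sk, warn_nonthin = FALSE))
  out <- mask_from_graph(g, mask)
  lab <- bf_label8(mask)
  keep <- unique(lab[g$pixel_idx])
  expect_identical(out, mask & matrix(lab %in% keep, 20, 40))
  expect_true(any(out[8:10, 4:35]))
  expect_false(any(out[15:17, 10:12]))  # blob component removed
  # boundary cases
  all_keep <- skeleton_graph(skeletonize(mask), warn_nonthin = FALSE)
  expect_identical(mask_from_graph(all_keep, mask), mask)
  none <- skeleton_graph(matrix(FALSE, 20, 40))
  expect_identical(sum(mask_from_graph(none, mask)), 0L)
})
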