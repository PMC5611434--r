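test_that("surface extraction matches face-neighbor counting", {
  single <- binary_mask(cbind(3L, 3L, 3L), c(5L, 5L, 5L))
  expect_equal(extract_surface_voxels(single), single$voxels)

  cube <- cuboid_mask(5, 5, 5)
  expect_equal(nrow(extract_surface_voxels(cube)), 125L - 27L)
})

test_that("surface voxels preserve the global farthest pair", {
  for (seed in c(1, 2, 3, 4, 5)) {
    blob <- random_blob(seed)
    surf <- extract_surface_voxels(blob)
    all_pts <- subaxis:::voxel_world_coords(blob$voxels, blob$affine)
    surf_pts <- subaxis:::voxel_world_coords(surf, blob$affine)
    expect_equal(max(stats::dist(surf_pts)), max(stats::dist(all_pts)),
                 tolerance = 1e-12)
  }
})

test_that("farthest pair matches the brute-force oracle on random points", {
  set.seed(31)
  pts <- matrix(runif(500 * 3, 0, 50), ncol = 3)
  fp <- farthest_pair(pts)
  expect_equal(fp$distance, brute_force_diameter(pts), tolerance = 1e-12)
  expect_equal(sqrt(sum((fp$p1 - fp$p2)^2)), fp$distance, tolerance = 1e-12)
})

test_that("farthest pair is deterministic under the tie rule", {
  # collinear centers at x = 0, 5, 9
  pts <- cbind(c(0, 5, 9), 0, 0)
  idx <- cbind(c(1L, 6L, 10L), 1L, 1L)
  fp <- farthest_pair(pts, idx)
  expect_equal(fp$distance, 9)
  expect_equal(unname(fp$p1[1]), 0)

  # unit-cube corners: all four main diagonals tie; the winning pair must
  # contain the lexicographically smallest corner (0,0,0) and its opposite
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  fp2 <- farthest_pair(corners, indices = corners)
  expect_equal(unname(fp2$p1), c(0, 0, 0))
  expect_equal(unname(fp2$p2), c(1, 1, 1))
  expect_error(farthest_pair(corners[1, , drop = FALSE]), "at least 2")
})

test_that("axis orientation is posterior-to-anterior and symmetric", {
  p1 <- c(0, -30, 5); p2 <- c(3, -6, 2)
  ax <- orient_posterior_anterior(p1, p2)
  expect_equal(ax$p_posterior, p1)
  ax_swapped <- orient_posterior_anterior(p2, p1)
  expect_equal(ax_swapped, ax)
  expect_error(orient_posterior_anterior(p1, p1), "zero-length")
  expect_warning(orient_posterior_anterior(c(0, 0, 0), c(1, 0, 0)), "tie")
})

test_that("collinear voxels bin exactly evenly and follow the conventions", {
  m <- collinear_mask(100)
  res <- parcellate_mask(m)
  expect_equal(res$n_voxels, rep(10L, 10))
  expect_equal(sum(res$volume_mm3), 100)

  lab <- attr(res, "labeling")
  ax <- attr(res, "axis")
  # endpoint voxels land in segments 1 and 10
  t_vals <- lab$t_raw
  expect_equal(lab$labels[which.min(t_vals)], 1L)
  expect_equal(lab$labels[which.max(t_vals)], 10L)
  expect_error(project_and_bin(m, ax, n_segments = 1), "at least 2")

  # 101 voxels put one exactly at t = 0.5: the boundary goes to segment 6
  m101 <- collinear_mask(101)
  lab101 <- attr(parcellate_mask(m101), "labeling")
  mid <- which(abs(lab101$t_raw - 0.5) < 1e-12)
  expect_length(mid, 1L)
  expect_equal(lab101$labels[mid], 6L)
})

test_that("segment volumes conserve total volume and keep empty segments", {
  for (seed in 1:5) {
    blob <- random_blob(seed + 100)
    res <- parcellate_mask(blob)
    expect_identical(sum(res$volume_mm3), mask_volume(blob))
    expect_equal(nrow(res), 10L)
  }
  # pathological: two distant clusters leave middle segments empty
  vox <- rbind(as.matrix(expand.grid(1:2, 1:2, 1:2)),
               as.matrix(expand.grid(1:2, 30:31, 1:2)))
  m <- binary_mask(vox, c(40L, 40L, 40L))
  res <- parcellate_mask(m)
  expect_true(any(res$volume_mm3 == 0))
  expect_equal(sum(res$volume_mm3), mask_volume(m))
})

test_that("anatomical region mapping follows the 47% head fraction", {
  expect_equal(map_segment_to_region(1:10),
               c(rep("body", 5), "transition", rep("head", 4)))
  expect_error(map_segment_to_region(3, head_fraction = 1.2), "head_fraction")
  expect_error(map_segment_to_region(11), "out of range")
})

test_that("a straight tube parcellates into near-equal segments", {
  m <- cuboid_mask(3, 100, 3)
  res <- parcellate_mask(m)
  expect_true(all(abs(res$volume_mm3 - sum(res$volume_mm3) / 10) <=
                    0.15 * sum(res$volume_mm3) / 10))
})

test_that("segment volumes are invariant under grid reorientation", {
  m <- random_phantom(21, length_range = c(25, 35))
  base <- parcellate_mask(m)$volume_mm3
  for (perm in list(c(2, 1, 3), c(3, 2, 1))) {
    for (flip in list(c(FALSE, TRUE, FALSE), c(TRUE, TRUE, TRUE))) {
      res <- parcellate_mask(reorient_mask(m, perm, flip))$volume_mm3
      expect_identical(res, base)
    }
  }
})

test_that("projection t stays within [0,1] when the axis is the diameter", {
  for (seed in 1:5) {
    blob <- random_blob(seed + 200)
    # blobs can tie on the anterior coordinate; the orientation fallback warns
    res <- suppressWarnings(parcellate_mask(blob))
    lab <- attr(res, "labeling")
    expect_lt(lab$max_clamp, 1e-9 * attr(res, "axis")$length_mm)
  }
})

test_that("phantom ground truth aligns with the parcellation", {
  # curved tube: segment labels increase with true arc fraction
  tt <- seq(0, 1, length.out = 9)
  cp <- cbind(8 * sin(pi * tt), 45 * tt, 0 * tt)
  m <- generate_phantom_mask(phantom_spec(cp, radius = 2))
  res <- parcellate_mask(m)
  lab <- attr(res, "labeling")
  f <- attr(m, "arc_fraction")
  expect_gte(cor(lab$labels, f, method = "spearman"), 0.9)
  mean_f <- tapply(f, lab$labels, mean)
  expect_gte(cor(as.numeric(names(mean_f)), mean_f, method = "spearman"), 0.9)
  # posterior endpoint lands near the posterior cap
  expect_lt(sqrt(sum((attr(res, "axis")$p_posterior - attr(m, "endpoint_posterior"))^2)),
            0.25 * 45)
})

test_that("posterior radius atrophy scales the half-volume ratio as radius^2", {
  # long tube so end caps are a small share of each half's volume; the
  # centerline is off-lattice so discrete disc counts track pi*r^2 instead
  # of resonating with integer shells
  cp <- cbind(0.3, seq(0, 140, length.out = 5), 0.4)
  shrink <- function(f) ifelse(f < 0.5, 0.8, 1)
  m0 <- generate_phantom_mask(phantom_spec(cp, radius = 3))
  m1 <- generate_phantom_mask(phantom_spec(cp, radius = 3, atrophy = shrink))
  ratio <- function(m) {
    res <- parcellate_mask(m)
    sum(res$volume_mm3[1:5]) / sum(res$volume_mm3[6:10])
  }
  expect_equal(ratio(m1) / ratio(m0), 0.64, tolerance = 0.1)
})
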