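# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk.

# Solid axis-aligned cuboid mask with unit voxels.
cuboid_mask <- function(nx, ny, nz, voxel_size = 1) {
  vox <- as.matrix(expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz)))
  binary_mask(vox, c(nx, ny, nz), affine = diag(c(rep(voxel_size, 3), 1)))
}

# Random connected blob: union of balls along a random walk. Capped at
# `max_voxels` voxels.
random_blob <- function(seed, n_steps = 8, max_voxels = 2000) {
  set.seed(seed)
  dim <- c(24L, 24L, 24L)
  centers <- matrix(12, 1, 3)
  for (s in seq_len(n_steps)) {
    centers <- rbind(centers, pmin(pmax(centers[s, ] + sample(-3:3, 3, TRUE), 4), 21))
  }
  radii <- runif(nrow(centers), 1.2, 2.8)
  grid <- as.matrix(expand.grid(i = 1:24, j = 1:24, k = 1:24))
  inside <- rep(FALSE, nrow(grid))
  for (s in seq_len(nrow(centers))) {
    d2 <- rowSums((grid - matrix(centers[s, ], nrow(grid), 3, TRUE))^2)
    inside <- inside | d2 <= radii[s]^2
  }
  vox <- grid[inside, , drop = FALSE]
  if (nrow(vox) > max_voxels) vox <- vox[seq_len(max_voxels), , drop = FALSE]
  binary_mask(vox, dim, affine = diag(4))
}

# A mask of collinear voxels along the anterior (y) axis.
collinear_mask <- function(n = 100) {
  vox <- cbind(i = rep(1L, n), j = seq_len(n), k = rep(1L, n))
  binary_mask(vox, c(1L, n, 1L), affine = diag(4))
}

# Maximum pairwise distance by an independent O(n^2) route (stats::dist).
brute_force_diameter <- function(points) {
  max(stats::dist(points))
}

# Small long-format cohort table built by hand.
toy_cohort <- function(n = 30, seed = 99, n_segments = 10) {
  set.seed(seed)
  demo <- tibble::tibble(
    participant_id = sprintf("S%03d", 1:n),
    group = factor(rep(c("CN", "SCD", "MCI"), length.out = n)),
    sex = factor(sample(c("F", "M"), n, TRUE)),
    age = rnorm(n, 72, 5),
    icv = rnorm(n, 1.45e6, 1e5),
    abeta42 = runif(n, 250, 1000),
    ptau = runif(n, 20, 120),
    memory_errors = sample(0:10, n, TRUE)
  )
  tidyr::expand_grid(demo,
                     hemisphere = c("left", "right"),
                     segment = seq_len(n_segments)) |>
    dplyr::mutate(volume_mm3 = rnorm(dplyr::n(), 50, 8))
}
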