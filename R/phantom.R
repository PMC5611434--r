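# Tube phantoms: synthetic stand-ins for subfield masks with known geometry.
#
# A phantom is a tube around a parametric centerline (piecewise-linear
# through control points, finely resampled). Every voxel whose center lies
# within the local radius of the centerline is in the mask. The generator
# stores ground truth - centerline endpoints and each mask voxel's arc
# fraction - so parcellation output can be checked against known geometry.

#' Specify a tube phantom
#'
#' @param control_points Numeric matrix (m x 3) of centerline control points
#'   in mm, ordered from the posterior to the anterior end (NIfTI world
#'   convention: axis 2 points anterior).
#' @param radius Tube radius in mm: a scalar or a function of arc fraction
#'   `f` in `[0, 1]`.
#' @param atrophy Multiplicative radius factor as a function of arc fraction
#'   (default none). Effective radius must stay >= 1 voxel.
#' @param voxel_size Isotropic voxel edge in mm (default 1).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(control_points, radius = 2,
                         atrophy = NULL, voxel_size = 1) {
  control_points <- as.matrix(control_points)
  stopifnot(ncol(control_points) == 3L, nrow(control_points) >= 2L)
  radius_fun <- if (is.function(radius)) radius else function(f) rep(radius, length(f))
  atrophy_fun <- atrophy %||% function(f) rep(1, length(f))
  structure(list(control_points = control_points, radius = radius_fun,
                 atrophy = atrophy_fun, voxel_size = voxel_size),
            class = "phantom_spec")
}

#' Voxelize a tube phantom into a binary mask
#'
#' @param spec A [phantom_spec()].
#' @param step Centerline resampling step in mm (default 0.25).
#' @return A [binary_mask()] with attributes `arc_fraction` (per mask
#'   voxel), `endpoint_posterior`, `endpoint_anterior` (world mm) and
#'   `centerline` (the resampled polyline).
#' @export
generate_phantom_mask <- function(spec, step = 0.25) {
  stopifnot(inherits(spec, "phantom_spec"))
  cp <- spec$control_points
  seg_len <- sqrt(rowSums((cp[-1, , drop = FALSE] - cp[-nrow(cp), , drop = FALSE])^2))
  total_len <- sum(seg_len)
  if (total_len < 20) abort("centerline arc length must be >= 20 mm.")
  # resample polyline at ~`step` mm
  cum <- c(0, cumsum(seg_len))
  s_out <- seq(0, total_len, by = step)
  if (s_out[length(s_out)] < total_len) s_out <- c(s_out, total_len)
  seg_idx <- pmin(findInterval(s_out, cum, rightmost.closed = TRUE), nrow(cp) - 1L)
  frac <- (s_out - cum[seg_idx]) / seg_len[seg_idx]
  cl <- cp[seg_idx, , drop = FALSE] +
    (cp[seg_idx + 1L, , drop = FALSE] - cp[seg_idx, , drop = FALSE]) * frac
  f_arc <- s_out / total_len
  r_eff <- spec$radius(f_arc) * spec$atrophy(f_arc)
  if (any(r_eff < spec$voxel_size)) {
    abort("effective radius fell below one voxel; increase radius or relax atrophy.")
  }
  vs <- spec$voxel_size
  rmax <- max(r_eff)
  lo <- floor((apply(cl, 2, min) - rmax - vs) / vs)
  hi <- ceiling((apply(cl, 2, max) + rmax + vs) / vs)
  dims <- as.integer(hi - lo + 1L)
  affine <- diag(c(vs, vs, vs, 1))
  affine[1:3, 4] <- lo * vs
  grid <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                                k = seq_len(dims[3])))
  xyz <- voxel_world_coords(grid, affine)
  # nearest centerline sample per voxel, in chunks to bound memory
  n_vox <- nrow(xyz)
  best_d2 <- rep(Inf, n_vox)
  best_i <- integer(n_vox)
  cl_sq <- rowSums(cl^2)
  chunk <- 20000L
  for (start in seq(1L, n_vox, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_vox)
    d2 <- outer(rowSums(xyz[idx, , drop = FALSE]^2), cl_sq, "+") -
      2 * tcrossprod(xyz[idx, , drop = FALSE], cl)
    wi <- max.col(-d2, ties.method = "first")
    best_d2[idx] <- d2[cbind(seq_along(idx), wi)]
    best_i[idx] <- wi
  }
  inside <- best_d2 <= r_eff[best_i]^2 + 1e-12
  if (!any(inside)) abort("phantom voxelization is empty.")
  mask <- binary_mask(grid[inside, , drop = FALSE], dims, affine = affine)
  attr(mask, "arc_fraction") <- f_arc[best_i[inside]]
  attr(mask, "endpoint_posterior") <- cl[1, ]
  attr(mask, "endpoint_anterior") <- cl[nrow(cl), ]
  attr(mask, "centerline") <- cl
  mask
}

#' Random tube phantom
#'
#' A mildly curved tube with randomized length, curvature, and radius - the
#' workhorse for property-based testing of the parcellation.
#'
#' @param seed Integer seed.
#' @param length_range Arc-length range in mm.
#' @param radius_range Radius range in mm.
#' @param curvature Maximum lateral bow as a fraction of length.
#' @param voxel_size Isotropic voxel edge in mm.
#' @return A [binary_mask()] with phantom ground-truth attributes.
#' @export
random_phantom <- function(seed, length_range = c(30, 60),
                           radius_range = c(1.5, 3), curvature = 0.15,
                           voxel_size = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  len <- runif(1, length_range[1], length_range[2])
  r <- runif(1, radius_range[1], radius_range[2])
  bow <- runif(2, -curvature, curvature) * len
  tt <- seq(0, 1, length.out = 9)
  cp <- cbind(bow[1] * sin(pi * tt), len * tt, bow[2] * sin(pi * tt))
  generate_phantom_mask(phantom_spec(cp, radius = r, voxel_size = voxel_size))
}
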