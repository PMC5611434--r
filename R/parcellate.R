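# Anterior-posterior axis parcellation.
#
# The long axis of the mask is the straight line between the two surface
# voxels with the greatest Euclidean distance between them, oriented from the
# most posterior to the most anterior endpoint. The line is divided into
# `n_segments` equal intervals; every voxel center is projected onto the line
# and assigned to the interval it lands in. Segment 1 is the most posterior.

#' Extract surface voxels of a binary mask
#'
#' A voxel is on the surface if at least one of its 6 face-neighbors is
#' outside the mask (out-of-grid counts as outside). Face connectivity is
#' sufficient for the farthest-pair search: a voxel with all 6 face-neighbors
#' present lies inside the octahedral hull of its neighbors and cannot attain
#' the maximum pairwise distance.
#'
#' @param mask A [binary_mask()].
#' @return Integer matrix (n x 3) of surface voxel indices (1-based).
#' @export
extract_surface_voxels <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- mask$dim
  arr <- array(FALSE, d)
  arr[mask$voxels] <- TRUE
  # pad with FALSE so out-of-grid neighbors read as absent
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  core <- function(di, dj, dk) {
    pad[(2:(d[1] + 1)) + di, (2:(d[2] + 1)) + dj, (2:(d[3] + 1)) + dk]
  }
  interior <- core(-1, 0, 0) & core(1, 0, 0) &
    core(0, -1, 0) & core(0, 1, 0) &
    core(0, 0, -1) & core(0, 0, 1)
  surf <- arr & !interior
  out <- which(surf, arr.ind = TRUE)
  colnames(out) <- c("i", "j", "k")
  out
}

#' Farthest pair of points
#'
#' Exhaustive O(n^2) search for a pair of points attaining the maximum
#' Euclidean distance. Ties are broken deterministically in world
#' coordinates: each candidate pair's endpoints are ordered internally by
#' coordinate-lexicographic comparison, and the pair whose ordered
#' (point, point) tuple is lexicographically smallest wins. World-space
#' tie-breaking keeps the result invariant under any permutation or flip of
#' the stored voxel grid (index-based rules are not).
#'
#' @param points Numeric matrix (n x 3) of world-mm coordinates.
#' @param indices Optional integer matrix (n x 3) of voxel index triples,
#'   carried through to the result for bookkeeping.
#' @return List with `i`, `j` (row numbers), `p1`, `p2` (coordinates, in the
#'   tie-rule's canonical order) and `distance`.
#' @export
farthest_pair <- function(points, indices = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) abort("need at least 2 points.")
  sq <- rowSums(points^2)
  # squared distances via Gram matrix; symmetric, diag 0
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(points)
  d2[d2 < 0] <- 0
  dmax <- max(d2)
  tol <- 1e-9 * max(dmax, 1)
  cand <- which(d2 >= dmax - tol, arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  # canonical key: endpoints sorted lexicographically, then compare pairs
  key <- apply(cand, 1L, function(ij) {
    a <- points[ij[1], ]; b <- points[ij[2], ]
    if (vec_less(b, a)) c(b, a) else c(a, b)
  })
  best <- 1L
  if (ncol(key) > 1L) {
    for (c2 in 2L:ncol(key)) if (vec_less(key[, c2], key[, best])) best <- c2
  }
  ij <- cand[best, ]
  if (vec_less(points[ij[2], ], points[ij[1], ])) ij <- rev(ij)
  list(i = ij[1], j = ij[2],
       p1 = points[ij[1], ], p2 = points[ij[2], ],
       distance = sqrt(d2[ij[1], ij[2]]))
}

vec_less <- function(a, b) {
  d <- a != b
  if (!any(d)) return(FALSE)
  k <- which(d)[1]
  a[k] < b[k]
}

#' Orient an axis from posterior to anterior
#'
#' @param p1,p2 Endpoint world-mm coordinates.
#' @param anterior_axis World axis pointing anterior (2 for RAS world space).
#' @return An `axis_line`: `p_posterior`, `p_anterior`, `length_mm`.
#' @export
orient_posterior_anterior <- function(p1, p2, anterior_axis = 2L) {
  L <- sqrt(sum((p2 - p1)^2))
  if (L <= 0) abort("zero-length axis.")
  a1 <- p1[anterior_axis]; a2 <- p2[anterior_axis]
  if (a1 < a2) {
    post <- p1; ant <- p2
  } else if (a2 < a1) {
    post <- p2; ant <- p1
  } else {
    warn("axis endpoints tie on the anterior axis; using lexicographic order (anatomically implausible input).")
    if (vec_less(p1, p2)) { post <- p1; ant <- p2 } else { post <- p2; ant <- p1 }
  }
  structure(list(p_posterior = post, p_anterior = ant, length_mm = L),
            class = "axis_line")
}

#' Project voxels onto the axis and bin into segments
#'
#' For voxel center x, `t = ((x - p_posterior) . u) / L` with u the unit axis
#' vector; t is clamped to `[0, 1]` and the label is
#' `min(floor(n * t) + 1, n)`, so bins are half-open `[(s-1)/n, s/n)` with
#' t = 1 assigned to segment n. When the axis is the mask's own farthest
#' pair, every unclamped t already lies in `[0, 1]` up to floating point.
#'
#' @param mask A [binary_mask()].
#' @param axis An `axis_line` from [orient_posterior_anterior()].
#' @param n_segments Number of equal-length segments (default 10).
#' @return A `segment_labeling`: integer `labels` per mask voxel, the axis,
#'   `n_segments`, and the largest clamp adjustment `max_clamp`.
#' @export
project_and_bin <- function(mask, axis, n_segments = 10L) {
  stopifnot(inherits(mask, "binary_mask"), inherits(axis, "axis_line"))
  if (n_segments < 2L) abort("`n_segments` must be at least 2.")
  xyz <- voxel_world_coords(mask$voxels, mask$affine)
  u <- (axis$p_anterior - axis$p_posterior) / axis$length_mm
  t_raw <- as.vector((xyz - matrix(axis$p_posterior, nrow(xyz), 3, byrow = TRUE)) %*% u) /
    axis$length_mm
  t_cl <- pmin(pmax(t_raw, 0), 1)
  labels <- pmin(floor(n_segments * t_cl) + 1L, n_segments)
  structure(
    list(labels = as.integer(labels), n_segments = as.integer(n_segments),
         axis = axis, t_raw = t_raw,
         max_clamp = max(abs(t_cl - t_raw))),
    class = "segment_labeling"
  )
}

#' Segment volumes from a labeling
#'
#' Volume of a segment is its voxel count times the voxel volume; empty
#' segments are kept with volume 0, so the volumes always sum exactly to the
#' total mask volume.
#'
#' @param labeling A `segment_labeling`.
#' @param voxel_volume Voxel volume in mm^3.
#' @return Tibble with columns `segment`, `n_voxels`, `volume_mm3`.
#' @export
segment_volumes <- function(labeling, voxel_volume) {
  stopifnot(inherits(labeling, "segment_labeling"))
  counts <- tabulate(labeling$labels, nbins = labeling$n_segments)
  tibble(segment = seq_len(labeling$n_segments),
         n_voxels = counts,
         volume_mm3 = counts * voxel_volume)
}

#' Map a segment index to a gross anatomical region
#'
#' The hippocampal head spans approximately the anterior 47% of the combined
#' head + body length, so with 10 segments from posterior, segments 1--5 lie
#' in the body, the body/head transition falls in segment 6, and segments
#' 7--10 lie in the head.
#'
#' @param segment Integer vector of segment indices in `1..n_segments`.
#' @param head_fraction Anterior fraction occupied by the head (default 0.47).
#' @param n_segments Total number of segments (default 10).
#' @return Character vector: `"body"`, `"transition"` or `"head"`.
#' @export
map_segment_to_region <- function(segment, head_fraction = 0.47, n_segments = 10L) {
  if (head_fraction <= 0 || head_fraction >= 1) {
    abort("`head_fraction` must be in (0, 1).")
  }
  if (any(segment < 1 | segment > n_segments)) abort("segment index out of range.")
  lo <- (segment - 1) / n_segments
  hi <- segment / n_segments
  boundary <- 1 - head_fraction
  dplyr::case_when(hi <= boundary ~ "body",
                   lo >= boundary ~ "head",
                   TRUE ~ "transition")
}

#' Parcellate a binary mask into anterior-posterior segments
#'
#' Runs the full pipeline: surface extraction, farthest-pair axis search,
#' posterior-to-anterior orientation, projection binning, and per-segment
#' volume computation.
#'
#' @param mask A [binary_mask()].
#' @param n_segments Number of segments (default 10).
#' @param participant_id,hemisphere Identifiers carried into the output.
#' @return Tibble with one row per segment: `participant_id`, `hemisphere`,
#'   `segment`, `n_voxels`, `volume_mm3`, `total_mm3`, `axis_length_mm`,
#'   `region`. The `axis_line` and `segment_labeling` are attached as
#'   attributes `"axis"` and `"labeling"`.
#' @export
parcellate_mask <- function(mask, n_segments = 10L,
                            participant_id = NA_character_,
                            hemisphere = NA_character_) {
  surf <- extract_surface_voxels(mask)
  if (nrow(surf) < 2L) abort("mask too small to define an axis.")
  pts <- voxel_world_coords(surf, mask$affine)
  fp <- farthest_pair(pts, indices = surf)
  axis <- orient_posterior_anterior(fp$p1, fp$p2, mask$anterior_axis)
  lab <- project_and_bin(mask, axis, n_segments)
  vols <- segment_volumes(lab, mask$voxel_volume)
  out <- tibble(
    participant_id = participant_id,
    hemisphere = hemisphere,
    segment = vols$segment,
    n_voxels = vols$n_voxels,
    volume_mm3 = vols$volume_mm3,
    total_mm3 = sum(vols$volume_mm3),
    axis_length_mm = axis$length_mm,
    region = map_segment_to_region(vols$segment, n_segments = n_segments)
  )
  attr(out, "axis") <- axis
  attr(out, "labeling") <- lab
  out
}
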