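# Subfield probability volumes and binary masks.
#
# A probability volume is the segmentation tool's per-voxel membership
# intensity (0-255, 127 ~ probability 0.5) on a regular grid with a NIfTI
# affine mapping 0-based voxel indices to world millimetres. NIfTI world
# space is RAS (+x right, +y anterior, +z superior), so the anterior axis in
# world coordinates is axis 2 regardless of how the grid is stored on disk.

#' Construct a subfield probability volume
#'
#' Wraps a 3-D array of membership intensities (integers in 0--255) together
#' with its voxel geometry. Values \{0, 1\} are interpreted as an
#' already-binarized mask and rescaled to \{0, 255\} with a warning.
#'
#' @param intensities 3-D numeric array with values in `[0, 255]`.
#' @param affine 4x4 matrix mapping 0-based voxel indices to world mm
#'   (NIfTI convention). Must be invertible.
#' @param anterior_axis World axis pointing anterior; 2 (the RAS "A" axis)
#'   for any NIfTI-conformant affine.
#' @return A `prob_volume` object.
#' @export
prob_volume <- function(intensities, affine = diag(4), anterior_axis = 2L) {
  if (length(dim(intensities)) != 3L) {
    abort("`intensities` must be a 3-D array.")
  }
  if (anyNA(intensities)) abort("`intensities` must not contain NA.")
  rng <- range(intensities)
  if (rng[1] < 0 || rng[2] > 255) {
    abort("intensities must lie in [0, 255].")
  }
  if (rng[2] <= 1 && any(intensities > 0)) {
    warn("input looks binary (values in {0, 1}); rescaling to {0, 255}.")
    intensities <- intensities * 255
  }
  affine <- check_affine(affine)
  vs <- affine_voxel_size(affine)
  structure(
    list(
      intensities = intensities,
      affine = affine,
      voxel_size = vs,
      anterior_axis = as.integer(anterior_axis)
    ),
    class = "prob_volume"
  )
}

check_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L))) abort("`affine` must be 4x4.")
  if (abs(det(affine[1:3, 1:3])) < 1e-12) {
    abort("`affine` is not invertible: degenerate voxel-to-world map.")
  }
  affine
}

affine_voxel_size <- function(affine) {
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vs <= 0)) abort("voxel sizes must be strictly positive.")
  vs
}

#' Read a subfield probability map from a NIfTI file
#'
#' Loads a single-frame 3-D NIfTI volume and returns a [prob_volume()] whose
#' affine is the image's stored voxel-to-world transform.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A `prob_volume`.
#' @export
read_mask_volume <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img_arr <- array(as.vector(img), d[1:3])
  } else if (length(d) == 3L) {
    img_arr <- array(as.vector(img), d)
  } else {
    abort("expected a 3-D single-frame NIfTI volume.")
  }
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  prob_volume(img_arr, affine = aff)
}

#' Write a probability volume or binary mask as NIfTI
#'
#' @param x A `prob_volume` or `binary_mask`.
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_mask_volume <- function(x, path) {
  arr <- if (inherits(x, "binary_mask")) {
    a <- array(0L, x$dim)
    a[x$voxels] <- 255L
    a
  } else {
    x$intensities
  }
  img <- RNifti::asNifti(arr)
  RNifti::sform(img) <- structure(x$affine, code = 2L)
  RNifti::qform(img) <- structure(x$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Binarize a probability volume
#'
#' A voxel belongs to the subfield if its intensity is at or above the
#' threshold. The default 127 corresponds to membership probability 0.5 or
#' higher; the comparison is inclusive because 127/255 is just below 0.5, so
#' a strict comparison would drop the boundary probability itself.
#'
#' @param vol A [prob_volume()].
#' @param threshold Integer intensity in `[1, 255]`; default 127.
#' @return A `binary_mask`: voxel index matrix (1-based), grid dimensions,
#'   affine, voxel size and voxel volume (mm^3).
#' @export
threshold_probability_map <- function(vol, threshold = 127L) {
  stopifnot(inherits(vol, "prob_volume"))
  if (threshold < 1 || threshold > 255) abort("`threshold` must be in [1, 255].")
  keep <- vol$intensities >= threshold
  if (!any(keep)) abort("no voxels at or above threshold.")
  binary_mask(which(keep, arr.ind = TRUE), dim(vol$intensities),
              affine = vol$affine, anterior_axis = vol$anterior_axis)
}

#' Construct a binary mask from voxel indices
#'
#' @param voxels Integer matrix (n x 3) of 1-based voxel indices.
#' @param dim Grid dimensions (length 3).
#' @param affine 4x4 voxel-to-world affine (0-based indices, mm).
#' @param anterior_axis World axis pointing anterior (2 for RAS).
#' @return A `binary_mask`.
#' @export
binary_mask <- function(voxels, dim, affine = diag(4), anterior_axis = 2L) {
  voxels <- matrix(as.integer(voxels), ncol = 3L,
                   dimnames = list(NULL, c("i", "j", "k")))
  if (nrow(voxels) == 0L) abort("mask is empty.")
  affine <- check_affine(affine)
  vs <- affine_voxel_size(affine)
  structure(
    list(
      voxels = voxels,
      dim = as.integer(dim),
      affine = affine,
      voxel_size = vs,
      voxel_volume = prod(vs),
      anterior_axis = as.integer(anterior_axis)
    ),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", nrow(x$voxels), " voxels on a ",
      paste(x$dim, collapse = "x"), " grid; voxel volume ",
      format(x$voxel_volume), " mm^3\n", sep = "")
  invisible(x)
}

#' @export
print.prob_volume <- function(x, ...) {
  cat("<prob_volume> ", paste(dim(x$intensities), collapse = "x"),
      " grid; voxel size ", paste(format(x$voxel_size), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Total volume of a binary mask in mm^3
#' @param mask A `binary_mask`.
#' @return Numeric scalar.
#' @export
mask_volume <- function(mask) nrow(mask$voxels) * mask$voxel_volume

# World-mm coordinates of voxel centers (rows of `voxels`, 1-based indices).
voxel_world_coords <- function(voxels, affine) {
  idx0 <- cbind(voxels[, 1] - 1, voxels[, 2] - 1, voxels[, 3] - 1)
  t(affine[1:3, 1:3] %*% t(idx0) + affine[1:3, 4])
}

#' Reorient the stored grid of a mask
#'
#' Applies one of the 48 axis permutation/flip symmetries to the voxel grid
#' and updates the affine so world-space geometry is unchanged. Useful for
#' checking that parcellation results do not depend on storage order.
#'
#' @param mask A `binary_mask`.
#' @param perm Permutation of `1:3`: new axis a holds old axis `perm[a]`.
#' @param flip Logical length 3: whether each *new* axis is reversed.
#' @return A `binary_mask` over the reordered grid.
#' @export
reorient_mask <- function(mask, perm = 1:3, flip = c(FALSE, FALSE, FALSE)) {
  stopifnot(sort(perm) == 1:3, length(flip) == 3L)
  old_dim <- mask$dim
  new_dim <- old_dim[perm]
  # new index n along new axis a corresponds to old index along old axis perm[a]
  vox_old <- mask$voxels
  vox_new <- vox_old[, perm, drop = FALSE]
  for (a in 1:3) {
    if (flip[a]) vox_new[, a] <- new_dim[a] + 1L - vox_new[, a]
  }
  # affine_new maps new 0-based indices to the same world point:
  # old0[perm[a]] = flip ? (new_dim[a]-1) - new0[a] : new0[a]
  P <- matrix(0, 4, 4); P[4, 4] <- 1
  for (a in 1:3) {
    if (flip[a]) {
      P[perm[a], a] <- -1
      P[perm[a], 4] <- new_dim[a] - 1
    } else {
      P[perm[a], a] <- 1
    }
  }
  binary_mask(vox_new, new_dim, affine = mask$affine %*% P,
              anterior_axis = mask$anterior_axis)
}
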