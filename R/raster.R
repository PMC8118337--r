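# Synthetic confocal acquisition: rasterize membrane meshes into anisotropic
# intensity stacks (the inverse of the preprocessing chain, used to test it).

#' 3D intensity stack with physical voxel size
#'
#' @param intensities 3D numeric array indexed \[x, y, z\] (x fastest).
#' @param voxel_size_nm length-3 positive vector of physical voxel size in
#'   nanometres.
#' @return object of class `voxel_stack`.
#' @export
voxel_stack <- function(intensities, voxel_size_nm = c(110, 110, 300)) {
  if (length(dim(intensities)) != 3L)
    .stop_erythro("intensities must be a 3D array", "invalid_argument")
  if (length(voxel_size_nm) != 3L || any(voxel_size_nm <= 0))
    .stop_erythro("voxel_size_nm must be 3 positive lengths",
                  "invalid_argument")
  if (any(!is.finite(intensities)))
    .stop_erythro("intensities must be finite", "invalid_argument")
  structure(list(intensities = intensities,
                 voxel_size_nm = as.numeric(voxel_size_nm)),
            class = "voxel_stack")
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<voxel_stack> %d x %d x %d voxels at %g x %g x %g nm, range [%.3g, %.3g]\n",
    d[1], d[2], d[3], x$voxel_size_nm[1], x$voxel_size_nm[2],
    x$voxel_size_nm[3], min(x$intensities), max(x$intensities)))
  invisible(x)
}

# mesh surface sample points (um) with area weights; spacing in um
.surface_samples <- function(mesh, spacing) {
  cpp_sample_triangles(mesh$vertices, mesh$faces, spacing)
}

#' Rasterize a mesh into a synthetic membrane-stain confocal stack
#'
#' Emulates a membrane-stained cell: the mesh surface is densely point
#' sampled, each sample is splatted as an anisotropic Gaussian (the optical
#' blur), intensities are normalized so the membrane shell peaks near 1,
#' and Gaussian read noise is added and clipped at zero. Deterministic for a
#' fixed `seed`.
#'
#' @param mesh an [rbc_mesh()] (micrometres, centered).
#' @param dims stack size in voxels, default `c(100, 100, 68)`.
#' @param voxel_size_nm physical voxel size, default `c(110, 110, 300)`.
#' @param blur_sigma_nm Gaussian blur sigma; a scalar (isotropic) or a
#'   length-3 vector. The default `c(80, 80, 160)` pairs a confocal-like
#'   lateral sigma with an axial sigma wide enough that flat membrane
#'   patches between z-planes stay above threshold.
#' @param noise_sd additive Gaussian noise sd relative to the shell peak.
#' @param seed integer seed for the noise.
#' @param center_offset_um place the cell center at this physical offset
#'   (um) from the stack center.
#' @return a [voxel_stack()].
#' @export
rasterize_to_stack <- function(mesh, dims = c(100L, 100L, 68L),
                               voxel_size_nm = c(110, 110, 300),
                               blur_sigma_nm = c(80, 80, 160),
                               noise_sd = 0.05, seed = 1L,
                               center_offset_um = c(0, 0, 0)) {
  stack <- .rasterize_scene(list(mesh), list(center_offset_um), dims,
                            voxel_size_nm, blur_sigma_nm)
  if (noise_sd > 0) {
    noise <- .with_seed(seed,
                        array(rnorm(prod(dims), sd = noise_sd), dim = dims))
    noisy <- stack$intensities + noise
    noisy[noisy < 0] <- 0  # clip at zero, preserving the array shape
    stack$intensities <- noisy
  }
  stack
}

#' Rasterize several cells into one field of view
#'
#' @param meshes list of [rbc_mesh()] objects.
#' @param centers_um list of physical offsets (um) from the stack center.
#' @inheritParams rasterize_to_stack
#' @return a [voxel_stack()].
#' @export
rasterize_scene <- function(meshes, centers_um, dims = c(300L, 300L, 68L),
                            voxel_size_nm = c(110, 110, 300),
                            blur_sigma_nm = c(80, 80, 160),
                            noise_sd = 0.05, seed = 1L) {
  stack <- .rasterize_scene(meshes, centers_um, dims, voxel_size_nm,
                            blur_sigma_nm)
  if (noise_sd > 0) {
    noise <- .with_seed(seed,
                        array(rnorm(prod(dims), sd = noise_sd), dim = dims))
    noisy <- stack$intensities + noise
    noisy[noisy < 0] <- 0  # clip at zero, preserving the array shape
    stack$intensities <- noisy
  }
  stack
}

.rasterize_scene <- function(meshes, centers_um, dims, voxel_size_nm,
                             blur_sigma_nm) {
  dims <- as.integer(dims)
  if (length(blur_sigma_nm) == 1L) blur_sigma_nm <- rep(blur_sigma_nm, 3L)
  pitch_um <- voxel_size_nm / 1000
  sigma_um <- blur_sigma_nm / 1000
  sigma_vox <- sigma_um / pitch_um
  fov_um <- dims * pitch_um
  vol <- numeric(prod(dims))
  for (i in seq_along(meshes)) {
    mesh <- meshes[[i]]
    off <- centers_um[[i]]
    ext_lo <- apply(mesh$vertices, 2, min) + off
    ext_hi <- apply(mesh$vertices, 2, max) + off
    margin <- 3 * sigma_um
    if (any(ext_lo - margin < -fov_um / 2) ||
        any(ext_hi + margin > fov_um / 2))
      .stop_erythro(sprintf("mesh '%s' exceeds the field of view",
                            mesh$provenance), "field_of_view_error")
    smp <- .surface_samples(mesh, spacing = min(sigma_um) / 2)
    pts <- sweep(smp$points, 2, off, "+")
    # physical position -> 0-based voxel-center coordinates
    pts_vox <- sweep(sweep(pts, 2, fov_um / 2, "+"), 2, pitch_um, "/") - 0.5
    vol <- vol + cpp_splat(pts_vox, smp$weights, dims, sigma_vox)
  }
  # normalize so a locally flat membrane patch peaks at ~1:
  # sum of area-weighted Gaussians over a plane integrates to 2*pi*sigma_t^2
  # in the two tangential directions (um^2 per unit weight)
  norm <- 2 * pi * prod(sort(sigma_um)[1:2])
  voxel_stack(array(vol / norm, dim = dims), voxel_size_nm)
}
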