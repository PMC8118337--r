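# The rotation- and translation-invariant shape descriptor: occupancy of
# the cell on a 64^3 grid, sampled on 32 concentric spheres, decomposed
# into 16 spherical-harmonics frequencies per sphere. Degrees 0 and 2 are
# expressed as the sorted eigenvalues of their joint quadratic form (3
# scalars); the remaining 14 degrees {1, 3, 4, ..., 15} contribute their
# band energies, giving 32 x (3 + 14) = 544 features.

#' Descriptor configuration
#'
#' @param grid_size cubic voxel grid edge (default 64).
#' @param n_radii concentric sampling spheres (default 32; at most
#'   `grid_size / 2`).
#' @param n_freq spherical-harmonics frequencies per sphere (default 16).
#' @param n_theta,n_phi angular quadrature resolution (defaults 24 x 48,
#'   exact for degree `n_freq - 1`).
#' @param occupancy_mode `"surface"` (default; antialiased membrane shell,
#'   matching isosurface-based cell capture) or `"solid"` (filled body).
#' @param scale_mode `"fixed_physical"` (default; one micrometre-per-voxel
#'   constant for the whole study, so absolute cell size stays
#'   discriminative) or `"fit_to_grid"` (bounding sphere scaled to 90% of
#'   the grid radius).
#' @param voxel_um physical voxel pitch for `fixed_physical` (default 0.2,
#'   i.e. a 12.8 um field).
#' @return a `descriptor_config` list.
#' @export
descriptor_config <- function(grid_size = 64L, n_radii = 32L, n_freq = 16L,
                              n_theta = 24L, n_phi = 48L,
                              occupancy_mode = c("surface", "solid"),
                              scale_mode = c("fixed_physical",
                                             "fit_to_grid"),
                              voxel_um = 0.2) {
  occupancy_mode <- match.arg(occupancy_mode)
  scale_mode <- match.arg(scale_mode)
  if (n_radii > grid_size / 2)
    .stop_erythro("n_radii must be at most grid_size / 2",
                  "invalid_argument")
  if (n_freq < 3L)
    .stop_erythro("n_freq must be at least 3", "invalid_argument")
  structure(list(grid_size = as.integer(grid_size),
                 n_radii = as.integer(n_radii),
                 n_freq = as.integer(n_freq),
                 n_theta = as.integer(n_theta), n_phi = as.integer(n_phi),
                 occupancy_mode = occupancy_mode, scale_mode = scale_mode,
                 voxel_um = voxel_um),
            class = "descriptor_config")
}

#' Descriptor feature length implied by a configuration
#' @param config a [descriptor_config()].
#' @return `n_radii * (3 + n_freq - 2)`; 544 at defaults.
#' @export
descriptor_length <- function(config = descriptor_config()) {
  config$n_radii * (3L + config$n_freq - 2L)
}

#' Voxelize a mesh onto the descriptor grid
#'
#' Surface mode splats an antialiased occupancy shell (Gaussian of the
#' distance to the surface, sigma 1.0 voxel) -- the membrane-as-isosurface
#' reading of cell capture, and much more rotation-stable than a binary
#' shell. Solid mode additionally floods the interior to a binary body.
#' The mesh (already bounding-box centered) is placed at the cube center.
#'
#' @param mesh an [rbc_mesh()].
#' @param config a [descriptor_config()].
#' @return a [voxel_stack()] of `grid_size^3` occupancies in \[0, 1\].
#' @export
voxelize_mesh <- function(mesh, config = descriptor_config()) {
  g <- config$grid_size
  if (nrow(mesh$vertices) < 4L)
    .stop_erythro("empty mesh", "scale_error")
  # re-center on the volume centroid: the bounding-box center is not
  # rotation covariant, so sampling spheres anchored there would break the
  # descriptor's rotation invariance for asymmetric cells
  mesh$vertices <- sweep(mesh$vertices, 2, mesh_centroid(mesh))
  if (config$scale_mode == "fixed_physical") {
    pitch <- config$voxel_um
    rmax <- max(sqrt(rowSums(mesh$vertices^2)))
    if (rmax / pitch > g / 2 - 1)
      .stop_erythro(sprintf(
        "mesh radius %.2f um exceeds the %.2f um descriptor field",
        rmax, pitch * (g / 2 - 1)), "scale_error")
  } else {
    rmax <- max(sqrt(rowSums(mesh$vertices^2)))
    pitch <- rmax / (0.9 * g / 2)
  }
  ctr <- (g - 1) / 2  # 0-based center of the cube
  if (config$occupancy_mode == "solid") {
    # exact interior occupancy by z-column parity against the mesh
    vol <- as.numeric(cpp_voxelize_solid_grid(mesh$vertices, mesh$faces,
                                              g, pitch, ctr))
  } else {
    sigma_vox <- 1.0
    smp <- .surface_samples(mesh, spacing = sigma_vox * pitch / 2)
    pts_vox <- smp$points / pitch + ctr
    vol <- cpp_splat(pts_vox, smp$weights, rep(g, 3L),
                     rep(sigma_vox, 3L))
    vol <- pmin(1, vol / (2 * pi * (sigma_vox * pitch)^2))
  }
  out <- voxel_stack(array(vol, dim = rep(g, 3L)),
                     rep(pitch * 1000, 3L))
  attr(out, "pitch_um") <- pitch
  out
}

#' Sample the occupancy on one concentric sphere
#'
#' Trilinear interpolation of the grid on the sphere of radius
#' `radius_index` voxels about the cube center, over the angular
#' quadrature grid.
#'
#' @param grid a `grid_size^3` [voxel_stack()] from [voxelize_mesh()].
#' @param radius_index integer in 1 .. n_radii.
#' @param config a [descriptor_config()].
#' @return numeric vector of samples matching `sh_basis(...)$dirs`.
#' @export
sample_spherical_function <- function(grid, radius_index,
                                      config = descriptor_config()) {
  g <- config$grid_size
  if (radius_index < 1L || radius_index > config$n_radii ||
      radius_index > g / 2)
    .stop_erythro("radius_index out of range", "index_error")
  basis <- sh_basis(config$n_freq, config$n_theta, config$n_phi)
  ctr <- (g - 1) / 2
  pts <- basis$dirs * radius_index + ctr
  cpp_trilinear(as.numeric(grid$intensities), dim(grid$intensities), pts)
}

#' Min-max normalization of a descriptor vector
#'
#' Affine map of the raw feature vector onto \[0, 1\]; a constant vector
#' maps to all zeros with a warning.
#'
#' @param vector numeric feature vector.
#' @return normalized vector.
#' @export
normalize_descriptor <- function(vector) {
  rng <- range(vector)
  if (diff(rng) <= 0) {
    warning("constant descriptor vector; returning all zeros")
    return(rep(0, length(vector)))
  }
  (vector - rng[1]) / diff(rng)
}

#' Build the 544-dimensional spherical-harmonics shape descriptor
#'
#' For each of the `n_radii` concentric spheres the occupancy is sampled
#' and decomposed into real spherical harmonics; degrees 0 and 2 become
#' the three sorted eigenvalues of their joint quadratic form
#' ([euclid_f0_f2()]), degrees {1, 3, 4, ..., n_freq - 1} contribute their
#' band energies. Features are laid out radius-major and min-max
#' normalized.
#'
#' @param mesh an [rbc_mesh()].
#' @param config a [descriptor_config()].
#' @return an `sh_spectrum`: list with `coefficients` (n_coef x n_radii),
#'   `euclid_scalars` (n_radii x 3), `band_energies` (n_radii x 14),
#'   `vector` (length 544 at defaults), `normalized_vector`, `config`.
#' @export
build_descriptor <- function(mesh, config = descriptor_config()) {
  grid <- voxelize_mesh(mesh, config)
  basis <- sh_basis(config$n_freq, config$n_theta, config$n_phi)
  ctr <- (config$grid_size - 1) / 2
  vol <- as.numeric(grid$intensities)
  d <- dim(grid$intensities)
  samples <- vapply(seq_len(config$n_radii), function(r)
    cpp_trilinear(vol, d, basis$dirs * r + ctr),
    numeric(nrow(basis$dirs)))
  coeff <- sh_decompose(samples, basis)  # n_coef x n_radii
  bands_all <- sh_band_energy(coeff, basis)  # n_freq x n_radii
  keep_l <- setdiff(0:(config$n_freq - 1L), c(0L, 2L))
  euclid <- t(vapply(seq_len(config$n_radii), function(r)
    euclid_f0_f2(coeff[, r], basis), numeric(3)))
  bands <- t(bands_all[keep_l + 1L, , drop = FALSE])
  vec <- as.numeric(t(cbind(euclid, bands)))  # radius-major
  structure(list(coefficients = coeff, euclid_scalars = euclid,
                 band_energies = bands, vector = vec,
                 normalized_vector = normalize_descriptor(vec),
                 config = config),
            class = "sh_spectrum")
}

#' @export
print.sh_spectrum <- function(x, ...) {
  cat(sprintf("<sh_spectrum> %d features (%d radii x (3 + %d bands))\n",
              length(x$vector), nrow(x$euclid_scalars),
              ncol(x$band_energies)))
  invisible(x)
}

#' Descriptor table for a list of meshes
#'
#' @param meshes list of [rbc_mesh()] objects.
#' @param config a [descriptor_config()].
#' @param ids optional character ids (default mesh provenance).
#' @return matrix of normalized descriptors, one row per mesh, with row
#'   names `ids`.
#' @export
describe_meshes <- function(meshes, config = descriptor_config(),
                            ids = NULL) {
  n <- length(meshes)
  out <- matrix(0, n, descriptor_length(config))
  for (i in seq_len(n))
    out[i, ] <- build_descriptor(meshes[[i]], config)$normalized_vector
  rownames(out) <- ids %||%
    vapply(meshes, function(m) m$provenance, character(1))
  out
}

#' Write / read a descriptor table as TSV
#'
#' One row per cell: `cell_id` then the feature columns `f001 ...`.
#' @param descriptors matrix from [describe_meshes()].
#' @param path TSV file.
#' @export
write_descriptors <- function(descriptors, path) {
  df <- data.frame(cell_id = rownames(descriptors) %||%
                     seq_len(nrow(descriptors)), descriptors,
                   check.names = FALSE)
  colnames(df) <- c("cell_id", sprintf("f%03d", seq_len(ncol(descriptors))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
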