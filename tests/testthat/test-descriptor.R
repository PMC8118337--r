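# The 544-dimensional descriptor: voxelization, spherical sampling,
# assembly, invariances.

test_that("descriptor length and layout match the configuration", {
  d <- build_descriptor(canonical_mesh("spherocyte"))
  expect_length(d$vector, 544L)
  expect_length(d$normalized_vector, 544L)
  expect_equal(dim(d$euclid_scalars), c(32L, 3L))
  expect_equal(dim(d$band_energies), c(32L, 14L))
  expect_equal(range(d$normalized_vector), c(0, 1))
  # non-default geometry scales accordingly
  cfg <- descriptor_config(grid_size = 32L, n_radii = 16L, n_freq = 8L)
  expect_equal(descriptor_length(cfg), 16L * (3L + 6L))
  expect_length(build_descriptor(canonical_mesh("spherocyte"),
                                 cfg)$vector, 144L)
  expect_error(descriptor_config(n_radii = 40L), class = "invalid_argument")
})

test_that("voxelization is centered, bounded and respects the scale", {
  m <- canonical_mesh("discocyte")
  g <- voxelize_mesh(m)
  expect_equal(dim(g$intensities), rep(64L, 3L))
  expect_true(all(g$intensities >= 0 & g$intensities <= 1))
  # translate: identical occupancy (centering precedes voxelization)
  mt <- m
  mt$vertices <- sweep(mt$vertices, 2, c(1.3, -0.4, 2))
  expect_equal(voxelize_mesh(mt)$intensities, g$intensities,
               tolerance = 1e-12)
  # an oversized mesh cannot fit the fixed physical field
  big <- m
  big$vertices <- big$vertices * 2
  expect_error(voxelize_mesh(big), class = "scale_error")
  # solid mode: occupied count of a ball within 5% of (4/3) pi r^3
  sph <- canonical_mesh("spherocyte")  # radius 2.8 um = 14 voxels
  solid <- voxelize_mesh(sph, descriptor_config(occupancy_mode = "solid"))
  expect_equal(sum(solid$intensities), 4 / 3 * pi * 14^3, tolerance = 0.05)
})

test_that("spherical sampling reads inside/on/outside the occupancy", {
  cfg <- descriptor_config(occupancy_mode = "solid")
  sph <- canonical_mesh("spherocyte")  # 14-voxel radius on the grid
  g <- voxelize_mesh(sph, cfg)
  # interior: constant 1 (up to trilinear floating-point dust)
  expect_true(all(sample_spherical_function(g, 8L, cfg) >= 1 - 1e-9))
  expect_true(all(sample_spherical_function(g, 30L, cfg) == 0))
  # membrane shell sampled at its own radius: occupied on >= 90% of the
  # quadrature points (direct membership oracle at half maximum)
  shell <- voxelize_mesh(sph, descriptor_config())
  near <- sample_spherical_function(shell, 14L, descriptor_config())
  expect_gt(mean(near >= 0.5), 0.9)
  expect_error(sample_spherical_function(g, 33L, cfg),
               class = "index_error")
})

test_that("a solid sphere has no higher-harmonic energy off the surface", {
  d <- build_descriptor(canonical_mesh("spherocyte"),
                        descriptor_config(occupancy_mode = "solid"))
  # radii well inside (constant 1) and well outside (constant 0) the
  # 14-voxel surface; the crossing radius itself aliases on the grid
  quiet <- c(1:12, 17:32)
  expect_lt(max(d$band_energies[quiet, ]), 1e-6)
  inner <- 1:11
  expect_lt(max(abs(d$euclid_scalars[inner, ] -
                      d$euclid_scalars[inner, 1])), 1e-6)
})

test_that("rotations leave the normalized descriptor nearly unchanged", {
  set.seed(17)
  for (cls in c("discocyte", "echinocyte_III", "cell_cluster")) {
    m <- canonical_mesh(cls)
    d0 <- build_descriptor(m)$normalized_vector
    for (i in 1:3) {
      dr <- build_descriptor(rotate_mesh(m,
                                         random_rotation_matrix()))
      rel <- sqrt(sum((dr$normalized_vector - d0)^2)) / sqrt(sum(d0^2))
      expect_lt(rel, 0.05)
    }
  }
})

test_that("descriptor distance grows monotonically along a morph", {
  disc <- canonical_mesh("discocyte")
  sph <- canonical_mesh("spherocyte")
  d0 <- build_descriptor(remesh_radial(disc))$normalized_vector
  dist_t <- vapply(seq(0.1, 1, by = 0.1), function(t) {
    dm <- build_descriptor(morph_meshes(disc, sph, t))$normalized_vector
    sqrt(sum((dm - d0)^2))
  }, numeric(1))
  expect_true(all(diff(dist_t) > 0))
})

test_that("descriptor tables round trip through TSV", {
  meshes <- list(canonical_mesh("discocyte"), canonical_mesh("spherocyte"))
  x <- describe_meshes(meshes, ids = c("a", "b"))
  path <- tempfile(fileext = ".tsv")
  write_descriptors(x, path)
  x2 <- read_descriptors(path)
  expect_equal(unname(x2), unname(x), tolerance = 1e-12)
  expect_equal(rownames(x2), c("a", "b"))
})
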