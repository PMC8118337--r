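# Stack preprocessing: TIFF I/O, cropping, interpolation, binarization,
# isosurface extraction and the full chain.

test_that("TIFF round trip preserves intensities and voxel metadata", {
  st <- voxel_stack(array(runif(20 * 16 * 5), dim = c(20, 16, 5)),
                    c(110, 110, 300))
  path <- tempfile(fileext = ".tif")
  write_tiff(st, path)
  rt <- read_tiff(path)
  expect_equal(dim(rt$intensities), c(20L, 16L, 5L))
  expect_equal(rt$voxel_size_nm, c(110, 110, 300))
  expect_lt(max(abs(rt$intensities - st$intensities)), 1e-6)  # float32
  # load_stack goes through the same reader
  ls_ <- load_stack(path)
  expect_equal(dim(ls_$intensities), dim(rt$intensities))
  expect_error(load_stack(tempfile()), class = "format_error")
  empty <- tempfile(fileext = ".tif")
  file.create(empty)
  expect_error(read_tiff(empty), class = "format_error")
})

test_that("isotropic interpolation follows the floor(n z/xy) rule", {
  st <- voxel_stack(array(runif(100 * 100 * 68), dim = c(100, 100, 68)),
                    c(110, 110, 300))
  iso <- interpolate_isotropic(st)
  expect_equal(dim(iso$intensities), c(100L, 100L, 185L))
  expect_equal(iso$voxel_size_nm, rep(110, 3))
  # already isotropic: unchanged
  same <- interpolate_isotropic(iso)
  expect_equal(dim(same$intensities)[3], 185L)
  expect_lt(max(abs(same$intensities - iso$intensities)), 1e-12)
  # arithmetic of the rule
  st2 <- voxel_stack(array(0, dim = c(12, 12, 10)), c(100, 100, 200))
  expect_equal(dim(interpolate_isotropic(st2)$intensities)[3], 20L)
  st3 <- voxel_stack(array(0, dim = c(8, 8, 1)), c(110, 110, 300))
  expect_error(interpolate_isotropic(st3), class = "invalid_input")
})

test_that("binarize thresholds, keeps the largest blob and fills holes", {
  cfg <- preprocess_config(threshold_fraction = 0.5)
  uni <- voxel_stack(array(3, dim = c(8, 8, 8)))
  expect_true(all(binarize(uni, cfg)$intensities == 1))
  expect_error(binarize(voxel_stack(array(0, dim = c(6, 6, 6))), cfg),
               class = "empty_cell")
  # two blobs: only the larger survives
  a <- array(0, dim = c(30, 30, 10))
  a[3:12, 3:12, 3:8] <- 1       # 600 voxels
  a[20:24, 20:24, 3:6] <- 1     # 100 voxels
  two <- binarize(voxel_stack(a), cfg)
  expect_equal(sum(two$intensities), 600)
  expect_equal(attr(two, "n_components"), 2L)
  # hollow shell becomes solid, volume near analytic (4/3) pi r^3
  shell <- ball_stack(20)$intensities - ball_stack(17)$intensities
  solid <- binarize(voxel_stack(array(shell, dim = dim(shell)),
                                rep(100, 3)), cfg)
  expect_equal(sum(solid$intensities), 4 / 3 * pi * 20^3,
               tolerance = 0.1)
})

test_that("threshold monotonicity: higher fraction, never more volume", {
  st <- rasterize_to_stack(canonical_mesh("discocyte"), seed = 2L)
  iso <- interpolate_isotropic(st)
  vols <- vapply(c(0.1, 0.2, 0.4, 0.6), function(f) {
    sum(binarize(iso, preprocess_config(threshold_fraction = f,
                                        min_cell_voxels = 1L))$intensities)
  }, numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("extract_isosurface recovers volume, centers, and is
           translation invariant", {
  bs <- ball_stack(20, pitch_nm = 100)  # radius 2 um
  mesh <- extract_isosurface(bs)
  expect_true(mesh_is_closed(mesh))
  expect_equal(mesh_volume(mesh), 4 / 3 * pi * 2^3, tolerance = 0.05)
  ctr <- (apply(mesh$vertices, 2, max) + apply(mesh$vertices, 2, min)) / 2
  expect_lt(max(abs(ctr)), 1e-9)
  # shifted ball: identical mesh after centering
  shifted <- extract_isosurface(ball_stack(20, pitch_nm = 100,
                                           center = c(5, -3, 2)))
  expect_equal(shifted$vertices, mesh$vertices, tolerance = 1e-6)
  expect_error(
    extract_isosurface(voxel_stack(array(0, dim = c(6, 6, 6)))),
    class = "empty_cell")
})

test_that("crop_cells finds separated cells and applies the filters", {
  meshes <- list(canonical_mesh("discocyte"), canonical_mesh("spherocyte"),
                 canonical_mesh("echinocyte_II"))
  centers <- list(c(-8, -8, 0), c(8, 6, 1), c(-2, 9, -1))
  sc <- rasterize_scene(meshes, centers, dims = c(300L, 300L, 68L),
                        seed = 21L)
  crops <- crop_cells(sc)
  expect_length(crops, 3L)
  # centroid oracle from the generator's scene geometry (px, 1-based)
  truth <- t(vapply(centers, function(o)
    (o[1:2] + 300 * 0.110 / 2) / 0.110, numeric(2)))
  for (cr in crops) {
    got <- c(cr$window$x0 + cr$window$width / 2,
             cr$window$y0 + cr$window$height / 2)
    expect_lt(min(sqrt(rowSums(sweep(truth, 2, got)^2))), 3)
    expect_equal(dim(cr$stack$intensities), c(100L, 100L, 68L))
  }
  # blank stack: no cells
  blank <- voxel_stack(array(0, dim = c(150, 150, 10)))
  expect_length(crop_cells(blank), 0L)
  # cell whose footprint reaches into the border margin is excluded
  edge <- rasterize_scene(list(meshes[[2]]), list(c(-10.2, 0, 0)),
                          dims = c(250L, 120L, 68L), seed = 22L)
  expect_length(crop_cells(edge,
                           preprocess_config(border_margin_px = 12L)), 0L)
})

test_that("full preprocessing round trip keeps the volume within 10%", {
  m <- canonical_mesh("discocyte")  # worst case: flat, thin
  rec <- preprocess_stack(rasterize_to_stack(m, seed = 31L))
  expect_true(mesh_is_closed(rec))
  expect_lt(abs(mesh_volume(rec) / mesh_volume(m) - 1), 0.10)
  # without ridge compensation the outward bias is visible but bounded
  rec_raw <- preprocess_stack(rasterize_to_stack(m, seed = 31L),
                              compensate = FALSE)
  expect_gt(mesh_volume(rec_raw), mesh_volume(rec))
})
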