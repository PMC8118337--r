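# The parametric shape generator: class definitions, morphs, datasets.

test_that("shape_spec enforces the SDE score and parameter contracts", {
  sp <- shape_spec("discocyte")
  expect_equal(sp$sde_score, 0)
  expect_null(shape_spec("knizocyte")$sde_score)
  expect_error(shape_spec("torocyte"), class = "invalid_spec")
  expect_error(shape_spec("discocyte", diameter_um = -2),
               class = "invalid_spec")
  expect_error(shape_spec("discocyte", diameter_um = 20),
               class = "invalid_spec")
  expect_error(shape_spec("echinocyte_III",
                          geometry_params = list(n_spikes = -1)),
               class = "invalid_spec")
})

test_that("canonical SDE scores are 7 equally spaced anchors on [-1, 1]", {
  s <- canonical_sde_score(sde_classes())
  expect_equal(s, seq(-1, 1, by = 1 / 3))
  expect_equal(diff(s), rep(1 / 3, 6))
  expect_error(canonical_sde_score("knizocyte"), class = "invalid_argument")
  expect_equal(sde_half_interval(), 0.17)
})

test_that("every canonical mesh is closed, centered and deterministic", {
  for (cls in all_shape_classes()) {
    m <- canonical_mesh(cls)
    expect_true(mesh_is_closed(m), label = paste(cls, "closed"))
    ctr <- (apply(m$vertices, 2, max) + apply(m$vertices, 2, min)) / 2
    expect_lt(max(abs(ctr)), 1e-9)
    expect_gt(mesh_volume(m), 0)
  }
  a <- make_canonical_mesh(shape_spec("acanthocyte", seed = 7L))
  b <- make_canonical_mesh(shape_spec("acanthocyte", seed = 7L))
  expect_identical(a$vertices, b$vertices)
})

test_that("class-defining geometry matches the morphological criteria", {
  # spherocyte: sphericity within 1% of 1
  expect_equal(mesh_sphericity(canonical_mesh("spherocyte")), 1,
               tolerance = 0.01)
  # echinocyte III: more than 25 spike protrusions
  expect_gt(count_spikes(canonical_mesh("echinocyte_III")), 25)
  # discocyte: center thinner than the rim, measured by a ray-casting
  # oracle along chords parallel to the symmetry axis
  disc <- canonical_mesh("discocyte")
  chord <- function(rho) {
    h <- erythroshape:::cpp_ray_hits(disc$vertices, disc$faces,
                                     c(rho, 0, -10), c(0, 0, 1))
    if (length(h) >= 2) diff(range(h)) else 0
  }
  center_thickness <- chord(0)
  rim_thickness <- max(vapply(seq(0.5, 3.8, by = 0.1), chord, numeric(1)))
  expect_lt(center_thickness / rim_thickness, 1)
  # stomatocytes: a single polar concavity (radial dip at the cup pole)
  for (cls in c("stomatocyte_I", "stomatocyte_II")) {
    rf <- radial_function(shape_spec(cls))
    r_pole <- rf(matrix(c(0, 0, 1), 1))
    r_off <- rf(matrix(c(sin(0.9), 0, cos(0.9)), 1))
    r_bottom <- rf(matrix(c(0, 0, -1), 1))
    expect_lt(r_pole, r_off)     # concave top
    expect_gt(r_bottom, r_pole)  # convex bottom
  }
  # knizocyte: 3-fold rotational symmetry of the radial field
  rfk <- radial_function(shape_spec("knizocyte"))
  dirs <- icosphere(2L)$vertices
  rot120 <- matrix(c(cos(2 * pi / 3), sin(2 * pi / 3), 0,
                     -sin(2 * pi / 3), cos(2 * pi / 3), 0,
                     0, 0, 1), 3, 3)
  expect_equal(rfk(dirs), rfk(dirs %*% rot120), tolerance = 1e-9)
})

test_that("spike counting is monotone in the spike-count parameter", {
  counts <- vapply(c(10L, 20L, 30L), function(n) {
    count_spikes(make_canonical_mesh(
      shape_spec("echinocyte_III", geometry_params = list(n_spikes = n))))
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
  expect_equal(counts[3], 30, tolerance = 2)
})

test_that("morphs interpolate the shared parameterization linearly", {
  disc <- canonical_mesh("discocyte")
  sph <- canonical_mesh("spherocyte")
  # identity morph
  m_id <- morph_meshes(disc, disc, 0.5)
  expect_equal(m_id$vertices, remesh_radial(disc)$vertices,
               tolerance = 1e-12)
  # endpoints
  m0 <- morph_meshes(disc, sph, 0)
  expect_lt(max(abs(m0$vertices - remesh_radial(disc)$vertices)), 1e-9)
  m1 <- morph_meshes(disc, sph, 1)
  expect_lt(max(abs(m1$vertices - remesh_radial(sph)$vertices)), 1e-9)
  # volume bounds along the morph (signed tetrahedron-sum oracle on the
  # endpoints): the radial (dual Minkowski) interpolation satisfies
  # V(t)^(1/3) <= (1-t) V(0)^(1/3) + t V(1)^(1/3); pointwise r >= r_end/2
  # at t = 0.5 gives the lower bound V/8. The midpoint volume can dip
  # below both endpoints (thin rims average away), so betweenness of the
  # endpoint volumes is NOT an invariant of this construction.
  vmid <- mesh_volume(morph_meshes(disc, sph, 0.5))
  v0 <- mesh_volume(m0); v1 <- mesh_volume(m1)
  expect_lt(vmid, ((v0^(1 / 3) + v1^(1 / 3)) / 2)^3 * 1.001)
  expect_gt(vmid, min(v0, v1) / 8)
  expect_error(morph_meshes(disc, sph, 1.5), class = "invalid_argument")
})

test_that("morph scores are linear in the morph weight", {
  expect_equal(morph_score("discocyte", "echinocyte_I", 0.5), 1 / 6)
  expect_equal(morph_score("spherocyte", "spherocyte", 0.3), -1)
  t <- seq(0, 1, by = 0.1)
  expect_equal(morph_score("stomatocyte_I", "discocyte", t),
               (1 - t) * (-1 / 3))
})

test_that("generate_dataset is labeled, jittered, rotated, deterministic", {
  cells <- generate_dataset(sde_classes(), 10L, seed = 3L)
  expect_length(cells, 70L)
  expect_equal(sum(vapply(cells, function(c)
    c$spec$shape_class == "discocyte", logical(1))), 10L)
  # determinism
  again <- generate_dataset(sde_classes(), 10L, seed = 3L)
  expect_identical(cells[[5]]$mesh$vertices, again[[5]]$mesh$vertices)
  # zero jitter: same class differs only by rotation (equal radial
  # multisets about the centroid)
  nj <- generate_dataset("discocyte", 2L,
                         jitter = list(diameter_sd = 0, param_sd = 0),
                         seed = 4L)
  r1 <- sort(sqrt(rowSums(sweep(nj[[1]]$mesh$vertices, 2,
                                mesh_centroid(nj[[1]]$mesh))^2)))
  r2 <- sort(sqrt(rowSums(sweep(nj[[2]]$mesh$vertices, 2,
                                mesh_centroid(nj[[2]]$mesh))^2)))
  expect_equal(r1, r2, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(nj[[1]]$mesh$vertices,
                                nj[[2]]$mesh$vertices)))
  expect_error(generate_dataset(character(0), 5L),
               class = "invalid_argument")
  expect_error(generate_dataset("discocyte", 0L),
               class = "invalid_argument")
})
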