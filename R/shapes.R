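# Parametric canonical RBC shape generator.
#
# Every canonical shape is modeled as a star-shaped radial function
# r(theta, phi) evaluated on a fixed icosphere grid, which makes remeshing
# and morphing (shared parameterization) exact by construction. Dimensions
# are micrometres; the biconcave disc uses the classic thickness polynomial
# of a disc of revolution with documented default coefficients.

#' The seven SDE classes in scale order
#'
#' Stomatocyte-discocyte-echinocyte (SDE) shapes ordered along the
#' continuous scale from -1 (spherocyte) to +1 (echinocyte III).
#' @return character vector of length 7.
#' @export
sde_classes <- function() {
  c("spherocyte", "stomatocyte_II", "stomatocyte_I", "discocyte",
    "echinocyte_I", "echinocyte_II", "echinocyte_III")
}

#' All supported shape classes
#' @return character vector: 7 SDE classes then 5 non-SDE classes.
#' @export
all_shape_classes <- function() {
  c(sde_classes(),
    "knizocyte", "keratocyte", "acanthocyte", "multilobate", "cell_cluster")
}

#' Canonical SDE score of a shape class
#'
#' Seven equally spaced anchors on \[-1, +1\]: spherocyte -1,
#' stomatocyte II -2/3, stomatocyte I -1/3, discocyte 0, echinocyte I +1/3,
#' echinocyte II +2/3, echinocyte III +1.
#'
#' @param shape_class character vector of SDE class names.
#' @return numeric scores.
#' @export
canonical_sde_score <- function(shape_class) {
  scores <- setNames(seq(-1, 1, length.out = 7L), sde_classes())
  bad <- !(shape_class %in% sde_classes())
  if (any(bad))
    .stop_erythro(paste("not an SDE class:",
                        paste(unique(shape_class[bad]), collapse = ", ")),
                  "invalid_argument")
  unname(scores[shape_class])
}

#' Matching half-interval between adjacent perfect SDE shapes
#'
#' Half the canonical score spacing, rounded to the two decimals used when
#' judging whether a predicted score matches a manually assigned class.
#' @return 0.17.
#' @export
sde_half_interval <- function() {
  spacing <- diff(canonical_sde_score(sde_classes()[1:2]))
  round(spacing / 2, 2)
}

# class-specific default geometry (um and dimensionless amplitudes)
.shape_defaults <- function(shape_class) {
  switch(shape_class,
    spherocyte     = list(diameter_um = 5.6),
    stomatocyte_I  = list(diameter_um = 7.0, polar_frac = 0.52,
                          cup_depth = 0.45, cup_width = 0.55),
    stomatocyte_II = list(diameter_um = 6.2, polar_frac = 0.72,
                          cup_depth = 0.65, cup_width = 0.60),
    discocyte      = list(diameter_um = 7.82, c0 = 0.81, c2 = 7.83,
                          c4 = -4.39, ref_diameter = 7.82),
    echinocyte_I   = list(diameter_um = 7.6, c0 = 1.30, c2 = 7.0,
                          c4 = -4.0, ref_diameter = 7.82,
                          n_spikes = 10, spike_amp = 0.18,
                          spike_width = 0.45),
    echinocyte_II  = list(diameter_um = 7.0, polar_frac = 0.64,
                          n_spikes = 18, spike_amp = 0.45,
                          spike_width = 0.30),
    echinocyte_III = list(diameter_um = 6.4, polar_frac = 0.84,
                          n_spikes = 30, spike_amp = 0.65,
                          spike_width = 0.24),
    knizocyte      = list(diameter_um = 7.6, polar_frac = 0.50,
                          lobe_count = 3, lobe_amp = 0.22),
    keratocyte     = list(diameter_um = 7.4, polar_frac = 0.55,
                          notch_depth = 0.50, notch_width = 0.45,
                          horn_amp = 0.50, horn_width = 0.30),
    multilobate    = list(diameter_um = 7.2, lobe_count = 4,
                          lobe_amp = 0.90, lobe_width = 0.55),
    acanthocyte    = list(diameter_um = 6.4, n_spikes = 7,
                          spike_amp = 0.55, spike_width = 0.28,
                          irregularity = 0.45),
    cell_cluster   = list(diameter_um = 9.5, radius_frac_b = 0.88,
                          offset_frac = 0.80),
    .stop_erythro(paste("unknown shape_class:", shape_class), "invalid_spec")
  )
}

#' Specification of one synthetic cell
#'
#' @param shape_class one of [all_shape_classes()].
#' @param diameter_um overall cell diameter in micrometres (4 to 12);
#'   `NULL` uses the class default.
#' @param geometry_params named list overriding class-default geometry
#'   (cup depth/width, spike count/amplitude/width, lobe count, ...).
#' @param seed integer seed for any stochastic geometry (e.g. acanthocyte
#'   spicule placement).
#' @return a `shape_spec` with fields `shape_class`, `sde_score` (present
#'   iff the class is on the SDE scale), `diameter_um`, `geometry_params`,
#'   `seed`.
#' @export
shape_spec <- function(shape_class, diameter_um = NULL,
                       geometry_params = list(), seed = 1L) {
  if (length(shape_class) != 1L || !(shape_class %in% all_shape_classes()))
    .stop_erythro(paste("unknown shape_class:", shape_class), "invalid_spec")
  defaults <- .shape_defaults(shape_class)
  gp <- modifyList(defaults, geometry_params)
  d <- diameter_um %||% gp$diameter_um
  if (!is.numeric(d) || d <= 0)
    .stop_erythro("diameter_um must be positive", "invalid_spec")
  if (d < 4 || d > 12)
    .stop_erythro("diameter_um outside the supported range [4, 12] um",
                  "invalid_spec")
  if (!is.null(gp$n_spikes) && gp$n_spikes < 0)
    .stop_erythro("spike count must be >= 0", "invalid_spec")
  gp$diameter_um <- d
  structure(list(
    shape_class = shape_class,
    sde_score = if (shape_class %in% sde_classes())
      canonical_sde_score(shape_class) else NULL,
    diameter_um = d,
    geometry_params = gp,
    seed = as.integer(seed)), class = "shape_spec")
}

#' @export
print.shape_spec <- function(x, ...) {
  cat(sprintf("<shape_spec> %s, diameter %.2f um%s, seed %d\n",
              x$shape_class, x$diameter_um,
              if (!is.null(x$sde_score))
                sprintf(", SDE score %+.2f", x$sde_score) else "",
              x$seed))
  invisible(x)
}

# run expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# quasi-uniform directions on the sphere (Fibonacci lattice)
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

# radial distance of an oblate spheroid with semi-axes (a, a, c)
.r_spheroid <- function(dirs, a, c_) {
  s2 <- dirs[, 1]^2 + dirs[, 2]^2
  1 / sqrt(s2 / a^2 + dirs[, 3]^2 / c_^2)
}

# Gaussian bumps around fixed directions; returns additive radial term
.r_bumps <- function(dirs, centers, amp, width) {
  ca <- dirs %*% t(centers)  # keep the matrix shape (pmin would drop it)
  ca[ca > 1] <- 1
  ca[ca < -1] <- -1
  ang <- acos(ca)
  if (length(amp) == 1L) amp <- rep(amp, ncol(ang))
  if (length(width) == 1L) width <- rep(width, ncol(ang))
  rowSums(exp(-sweep(ang^2, 2, 2 * width^2, "/")) %*% diag(amp, ncol(ang)))
}

# radial function of the biconcave disc of revolution with thickness
# profile T(rho) = sqrt(1-(2 rho/D)^2) (c0 + c2 (2 rho/D)^2 + c4 (2 rho/D)^4),
# coefficients scaled from the reference diameter; solved per direction by
# bisection of r |cos(theta)| = T(r sin(theta)) / 2.
.r_biconcave <- function(dirs, diameter, c0, c2, c4, ref_diameter) {
  scale <- diameter / ref_diameter
  c0 <- c0 * scale; c2 <- c2 * scale; c4 <- c4 * scale
  thickness <- function(rho) {
    x2 <- pmin(1, (2 * rho / diameter)^2)
    sqrt(1 - x2) * pmax(0, c0 + c2 * x2 + c4 * x2^2)
  }
  s <- sqrt(dirs[, 1]^2 + dirs[, 2]^2)
  cz <- abs(dirs[, 3])
  lo <- rep(0, nrow(dirs))
  hi <- rep(diameter, nrow(dirs))
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    g <- mid * cz - thickness(mid * s) / 2
    up <- g >= 0  # >= so equatorial rays (cz == 0) converge to the rim
    hi[up] <- mid[up]
    lo[!up] <- mid[!up]
  }
  (lo + hi) / 2
}

#' Radial function of a canonical shape
#'
#' @param spec a [shape_spec()].
#' @return a function mapping an n x 3 matrix of unit directions to radial
#'   distances in micrometres.
#' @export
radial_function <- function(spec) {
  gp <- spec$geometry_params
  d <- spec$diameter_um
  cls <- spec$shape_class
  a <- d / 2
  force(gp); force(d); force(cls); force(a)
  switch(cls,
    spherocyte = function(dirs) rep(a, nrow(dirs)),
    discocyte = function(dirs)
      .r_biconcave(dirs, d, gp$c0, gp$c2, gp$c4, gp$ref_diameter),
    stomatocyte_I = ,
    stomatocyte_II = function(dirs) {
      base <- .r_spheroid(dirs, a, a * gp$polar_frac)
      theta <- acos(pmin(1, pmax(-1, dirs[, 3])))
      base * (1 - gp$cup_depth * exp(-(theta / gp$cup_width)^2))
    },
    echinocyte_I = function(dirs) {
      base <- .r_biconcave(dirs, d, gp$c0, gp$c2, gp$c4, gp$ref_diameter)
      ctr <- .fibonacci_sphere(round(gp$n_spikes))
      base + .r_bumps(dirs, ctr, gp$spike_amp, gp$spike_width)
    },
    echinocyte_II = ,
    echinocyte_III = function(dirs) {
      base <- .r_spheroid(dirs, a, a * gp$polar_frac)
      ctr <- .fibonacci_sphere(round(gp$n_spikes))
      base + .r_bumps(dirs, ctr, gp$spike_amp, gp$spike_width)
    },
    knizocyte = function(dirs) {
      base <- .r_spheroid(dirs, a, a * gp$polar_frac)
      phi <- atan2(dirs[, 2], dirs[, 1])
      s2 <- dirs[, 1]^2 + dirs[, 2]^2
      base * (1 + gp$lobe_amp * s2 * cos(round(gp$lobe_count) * phi))
    },
    keratocyte = function(dirs) {
      base <- .r_spheroid(dirs, a, a * gp$polar_frac)
      notch <- matrix(c(1, 0, 0), 1, 3)
      horns <- rbind(c(cos(0.9), sin(0.9), 0), c(cos(0.9), -sin(0.9), 0))
      base * (1 - gp$notch_depth *
                exp(-(acos(pmin(1, dirs %*% t(notch)))^2) /
                      (2 * gp$notch_width^2))) +
        .r_bumps(dirs, horns, gp$horn_amp, gp$horn_width)
    },
    multilobate = function(dirs) {
      ctr <- .fibonacci_sphere(round(gp$lobe_count))
      base <- a - gp$lobe_amp / 2
      base + .r_bumps(dirs, ctr, gp$lobe_amp, gp$lobe_width)
    },
    acanthocyte = function(dirs) {
      par <- .with_seed(spec$seed, {
        n <- round(gp$n_spikes)
        list(ctr = {
          m <- matrix(rnorm(3 * n), n, 3)
          m / sqrt(rowSums(m^2))
        },
        amp = gp$spike_amp * (1 + gp$irregularity * runif(n, -1, 1)),
        width = gp$spike_width * (1 + gp$irregularity * runif(n, -1, 1)))
      })
      a * 0.82 + .r_bumps(dirs, par$ctr, par$amp, par$width)
    },
    cell_cluster = function(dirs) {
      r1 <- a * 0.58
      r2 <- r1 * gp$radius_frac_b
      off <- gp$offset_frac * r1 / 2
      exit_t <- function(cx, R) {
        dc <- dirs[, 1] * cx
        disc <- dc^2 - cx^2 + R^2
        ifelse(disc >= 0, dc + sqrt(pmax(0, disc)), 0)
      }
      pmax(exit_t(off, r1), exit_t(-off, r2))
    }
  )
}

#' Build the triangle mesh of a canonical shape
#'
#' Evaluates the shape's radial function on the fixed icosphere grid and
#' returns a closed, bounding-box-centered triangle mesh. Deterministic for
#' a fixed `spec$seed`.
#'
#' @param spec a [shape_spec()].
#' @param subdivisions icosphere subdivision level (default 4, 2562
#'   vertices).
#' @return an [rbc_mesh()].
#' @export
make_canonical_mesh <- function(spec, subdivisions = 4L) {
  if (!inherits(spec, "shape_spec"))
    .stop_erythro("spec must be a shape_spec", "invalid_spec")
  ico <- icosphere(subdivisions)
  r <- radial_function(spec)(ico$vertices)
  if (any(!is.finite(r)) || any(r <= 0))
    .stop_erythro("radial function produced non-positive radii",
                  "invalid_spec")
  rbc_mesh(ico$vertices * r, ico$faces,
           provenance = sprintf("%s(d=%.2f,seed=%d)", spec$shape_class,
                                spec$diameter_um, spec$seed))
}

#' Linear morph between two meshes on the shared spherical grid
#'
#' Both meshes are first remeshed onto the same icosphere parameterization
#' ([remesh_radial()]); the morph linearly interpolates corresponding grid
#' points, so `t = 0` reproduces the remeshed first mesh and `t = 1` the
#' remeshed second.
#'
#' @param mesh_a,mesh_b closed, star-shaped [rbc_mesh()] objects.
#' @param t interpolation weight in \[0, 1\].
#' @param subdivisions icosphere subdivision level.
#' @return the interpolated [rbc_mesh()].
#' @export
morph_meshes <- function(mesh_a, mesh_b, t, subdivisions = 4L) {
  if (t < 0 || t > 1)
    .stop_erythro("t must be in [0, 1]", "invalid_argument")
  ra <- remesh_radial(mesh_a, subdivisions)
  rb <- remesh_radial(mesh_b, subdivisions)
  rbc_mesh((1 - t) * ra$vertices + t * rb$vertices, ra$faces,
           provenance = sprintf("morph(t=%.3f)", t), center = FALSE)
}

#' Ground-truth SDE score of a morph between two canonical shapes
#'
#' Linear in the morph weight: (1 - t) score_a + t score_b.
#' @param class_a,class_b SDE class names.
#' @param t morph weight in \[0, 1\].
#' @export
morph_score <- function(class_a, class_b, t) {
  (1 - t) * canonical_sde_score(class_a) + t * canonical_sde_score(class_b)
}

#' Count spike-like protrusions of a mesh
#'
#' Remeshes the cell onto the icosphere grid and counts strict local maxima
#' of the radial field over the one-ring whose prominence over the local
#' 3-ring median exceeds `min_prominence` (um). Used to verify echinocyte
#' spike criteria.
#'
#' @param mesh an [rbc_mesh()].
#' @param min_prominence minimum radial prominence in um (default 0.04).
#' @param subdivisions icosphere subdivision level.
#' @return integer spike count.
#' @export
count_spikes <- function(mesh, min_prominence = 0.04, subdivisions = 4L) {
  rm_ <- remesh_radial(mesh, subdivisions)
  r <- sqrt(rowSums(rm_$vertices^2))
  key <- paste0("ring3_", subdivisions)
  hit <- .erythro_cache[[key]]
  if (is.null(hit)) {
    adj <- mesh_adjacency(icosphere(subdivisions))
    ring3 <- lapply(seq_along(adj), function(i) {
      cur <- unique(c(i, adj[[i]]))
      for (s in 1:2) cur <- unique(c(cur, unlist(adj[cur])))
      cur
    })
    hit <- list(adj = adj, ring3 = ring3)
    .erythro_cache[[key]] <- hit
  }
  adj <- hit$adj
  ring3 <- hit$ring3
  is_max <- vapply(seq_along(r), function(i) all(r[i] > r[adj[[i]]]),
                   logical(1))
  prom <- vapply(seq_along(r), function(i) r[i] - median(r[ring3[[i]]]),
                 numeric(1))
  sum(is_max & prom >= min_prominence)
}

#' Generate a labeled synthetic mesh dataset
#'
#' Draws `n_per_class` cells per class with jittered size and geometry and a
#' uniformly random 3D orientation; all randomness flows from `seed`.
#'
#' @param classes character vector of shape classes (default: all 12).
#' @param n_per_class cells per class (>= 1).
#' @param jitter named list: `diameter_sd` (fractional sd of the diameter,
#'   default 0.05) and `param_sd` (fractional sd of each numeric geometry
#'   parameter, default 0.08); set both to 0 for rotation-only variation.
#' @param seed integer seed.
#' @return list of entries, each `list(mesh, spec, rotation)`.
#' @export
generate_dataset <- function(classes = all_shape_classes(), n_per_class,
                             jitter = list(), seed = 1L) {
  if (length(classes) == 0L)
    .stop_erythro("empty class list", "invalid_argument")
  if (n_per_class < 1L)
    .stop_erythro("n_per_class must be >= 1", "invalid_argument")
  jit <- modifyList(list(diameter_sd = 0.05, param_sd = 0.08), jitter)
  out <- vector("list", length(classes) * n_per_class)
  idx <- 0L
  .with_seed(seed, {
    for (cls in classes) {
      defaults <- .shape_defaults(cls)
      for (i in seq_len(n_per_class)) {
        idx <- idx + 1L
        gp <- defaults
        for (nm in names(gp)) {
          if (nm %in% c("diameter_um", "ref_diameter", "n_spikes",
                        "lobe_count")) next
          gp[[nm]] <- gp[[nm]] * (1 + jit$param_sd * rnorm(1))
        }
        dia <- defaults$diameter_um * (1 + jit$diameter_sd * rnorm(1))
        dia <- min(12, max(4, dia))
        cell_seed <- sample.int(.Machine$integer.max, 1L)
        spec <- shape_spec(cls, diameter_um = dia, geometry_params = gp,
                           seed = cell_seed)
        rot <- random_rotation_matrix()
        mesh <- rotate_mesh(make_canonical_mesh(spec), rot)
        mesh$provenance <- sprintf("%s#%d(seed=%d)", cls, i, cell_seed)
        out[[idx]] <- list(mesh = mesh, spec = spec, rotation = rot)
      }
    }
  })
  out
}
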