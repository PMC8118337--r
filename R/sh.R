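# Real orthonormal spherical harmonics on a Gauss-Legendre x equispaced-phi
# quadrature grid. The grid is exact for band-limited functions up to
# degree n_freq - 1 (Gauss-Legendre in cos(theta) integrates the Legendre
# products exactly; the phi sum is exact once n_phi > 2 (n_freq - 1)).

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
# method (symmetric tridiagonal Jacobi matrix).
.gauss_legendre <- function(n) {
  if (n == 1L) return(list(x = 0, w = 2))
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = 2 * e$vectors[1, ord]^2)
}

# Fully normalized associated Legendre values P_bar_l^m(x) such that
# int_-1^1 P_bar_l^m P_bar_l'^m dx = delta_ll' * (2/(2l+1)) ... we fold the
# full spherical normalization in directly: rows are indexed by (l, m >= 0).
.legendre_norm <- function(lmax, x) {
  nx <- length(x)
  out <- vector("list", lmax + 1L)
  sx <- sqrt(pmax(0, 1 - x^2))
  for (l in 0:lmax) out[[l + 1L]] <- matrix(0, nx, l + 1L)
  # unnormalized P_l^m via the stable (l-m) upward recursion, then scaled
  # by N_l^m = sqrt((2l+1)/(4 pi) (l-m)!/(l+m)!); fine in double for l <= 15
  for (m in 0:lmax) {
    p_prev <- rep(0, nx)
    # P_m^m = (-1)^m (2m-1)!! (1-x^2)^(m/2)
    dfact <- if (m == 0) 1 else prod(seq(1, 2 * m - 1, by = 2))
    p_curr <- (-1)^m * dfact * sx^m
    for (l in m:lmax) {
      norm <- sqrt((2 * l + 1) / (4 * pi) *
                     exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      out[[l + 1L]][, m + 1L] <- norm * p_curr
      if (l < lmax) {
        p_next <- ((2 * l + 1) * x * p_curr - (l + m) * p_prev) /
          (l - m + 1)
        p_prev <- p_curr
        p_curr <- p_next
      }
    }
  }
  out
}

#' Spherical-harmonics quadrature basis
#'
#' Builds (and memoises) the real orthonormal spherical-harmonics basis
#' evaluated on a Gauss-Legendre (theta) x equispaced (phi) quadrature grid,
#' exact for analysis of band-limited functions up to degree `n_freq - 1`.
#'
#' @param n_freq number of frequencies (degrees 0 .. n_freq - 1),
#'   default 16.
#' @param n_theta Gauss-Legendre nodes in cos(theta) (default 24; must be
#'   >= n_freq).
#' @param n_phi equispaced azimuthal samples (default 48; must be
#'   > 2 (n_freq - 1)).
#' @return list with `dirs` (n_pts x 3 unit vectors), `weights`
#'   (quadrature weights summing to 4 pi), `Y` (n_freq^2 x n_pts real
#'   orthonormal harmonics), `l` and `m` (degree/order per row of `Y`).
#' @export
sh_basis <- function(n_freq = 16L, n_theta = 24L, n_phi = 48L) {
  if (n_theta < n_freq || n_phi <= 2L * (n_freq - 1L))
    .stop_erythro("quadrature grid too coarse for exact analysis",
                  "quadrature_error")
  key <- sprintf("sh_basis_%d_%d_%d", n_freq, n_theta, n_phi)
  hit <- .erythro_cache[[key]]
  if (!is.null(hit)) return(hit)
  gl <- .gauss_legendre(n_theta)
  phi <- 2 * pi * (seq_len(n_phi) - 0.5) / n_phi
  ct <- rep(gl$x, each = n_phi)
  st <- sqrt(pmax(0, 1 - ct^2))
  ph <- rep(phi, n_theta)
  dirs <- cbind(st * cos(ph), st * sin(ph), ct)
  w <- rep(gl$w, each = n_phi) * (2 * pi / n_phi)
  lmax <- n_freq - 1L
  leg <- .legendre_norm(lmax, gl$x)
  n_coef <- n_freq^2
  Y <- matrix(0, n_coef, nrow(dirs))
  lv <- integer(n_coef)
  mv <- integer(n_coef)
  row <- 0L
  for (l in 0:lmax) {
    plm <- leg[[l + 1L]]  # n_theta x (l+1), m = 0..l
    for (m in (-l):l) {
      row <- row + 1L
      lv[row] <- l
      mv[row] <- m
      am <- abs(m)
      base <- rep(plm[, am + 1L], each = n_phi)
      Y[row, ] <- if (m == 0) base
      else if (m > 0) sqrt(2) * base * cos(m * ph)
      else sqrt(2) * base * sin(am * ph)
    }
  }
  out <- list(dirs = dirs, weights = w, Y = Y, l = lv, m = mv,
              Yw = Y * rep(w, each = n_coef))
  .erythro_cache[[key]] <- out
  out
}

#' Spherical-harmonics analysis of sampled functions
#'
#' Projects one or more functions sampled on the basis quadrature grid onto
#' the real orthonormal harmonics: a_lm = sum_i w_i f(x_i) Y_lm(x_i). Exact
#' for inputs band-limited to degree `n_freq - 1`.
#'
#' @param samples numeric vector (one function) or matrix with one column
#'   per function, rows matching `basis$dirs`.
#' @param basis a [sh_basis()].
#' @return coefficient vector/matrix with `n_freq^2` rows ordered by
#'   (l, m = -l..l).
#' @export
sh_decompose <- function(samples, basis = sh_basis()) {
  samples <- as.matrix(samples)
  if (nrow(samples) != ncol(basis$Y))
    .stop_erythro("sample count does not match the quadrature grid",
                  "quadrature_error")
  coeff <- basis$Yw %*% samples
  if (ncol(coeff) == 1L) coeff <- coeff[, 1]
  coeff
}

#' Evaluate a spherical-harmonics expansion on the quadrature grid
#' @param coeff coefficient vector (length `n_freq^2`).
#' @param basis a [sh_basis()].
#' @return sampled values on `basis$dirs`.
#' @export
sh_synthesize <- function(coeff, basis = sh_basis()) {
  drop(crossprod(basis$Y, coeff))
}

#' Per-degree band energy
#'
#' L2 norm over orders m of the degree-l coefficients; rotation invariant
#' and Parseval-consistent (`sum_l band^2 = int |f|^2 dOmega` for
#' orthonormal harmonics).
#'
#' @param coeff coefficient vector or matrix from [sh_decompose()].
#' @param basis the [sh_basis()] used for the decomposition.
#' @return numeric vector (or matrix) of band energies for l = 0 ..
#'   n_freq - 1.
#' @export
sh_band_energy <- function(coeff, basis = sh_basis()) {
  coeff <- as.matrix(coeff)
  lmax <- max(basis$l)
  out <- matrix(0, lmax + 1L, ncol(coeff))
  for (l in 0:lmax)
    out[l + 1L, ] <- sqrt(colSums(coeff[basis$l == l, , drop = FALSE]^2))
  if (ncol(out) == 1L) out[, 1] else out
}

# 6x6 map from (a00, a2-2 .. a22) to the quadratic-form coefficients
# (xx, yy, zz, xy, xz, yz); computed numerically from the package's own
# basis so it is immune to sign-convention mistakes.
.quadform_map <- function(basis) {
  key <- "quadform_map"
  hit <- .erythro_cache[[key]]
  if (!is.null(hit)) return(hit)
  d <- basis$dirs
  monomials <- cbind(d[, 1]^2, d[, 2]^2, d[, 3]^2,
                     d[, 1] * d[, 2], d[, 1] * d[, 3], d[, 2] * d[, 3])
  sel <- basis$l %in% c(0L, 2L)
  # coefficients of each monomial in the (a00, a2m) subspace: 6 x 6
  M <- sh_decompose(monomials, basis)[sel, , drop = FALSE]
  inv <- solve(M)
  .erythro_cache[[key]] <- inv
  inv
}

#' Euclidean expression of the degree-0 plus degree-2 part
#'
#' The l = 0 and l = 2 components of a spherical function jointly define a
#' quadratic form a1 x^2 + a2 y^2 + a3 z^2 on the unit sphere (using
#' x^2 + y^2 + z^2 = 1). This returns the form's eigenvalues sorted
#' descending -- a rotation-invariant triple.
#'
#' @param coeff full coefficient vector from [sh_decompose()], or a
#'   length-6 vector `c(a00, a2m-2 .. a2m2)`.
#' @param basis the [sh_basis()] used.
#' @return numeric triple `a1 >= a2 >= a3`.
#' @export
euclid_f0_f2 <- function(coeff, basis = sh_basis()) {
  if (length(coeff) == 6L) a <- coeff
  else {
    sel <- basis$l %in% c(0L, 2L)
    a <- coeff[sel]
  }
  q <- drop(.quadform_map(basis) %*% a)
  Q <- matrix(c(q[1], q[4] / 2, q[5] / 2,
                q[4] / 2, q[2], q[6] / 2,
                q[5] / 2, q[6] / 2, q[3]), 3, 3)
  sort(eigen(Q, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}
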