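# Spherical-harmonics analysis: quadrature exactness, oracles, the
# Euclidean expression of the degree-0/2 part, and normalization.

test_that("the quadrature basis is orthonormal to machine precision", {
  b <- sh_basis()
  gram <- (b$Y * rep(b$weights, each = nrow(b$Y))) %*% t(b$Y)
  expect_lt(max(abs(gram - diag(nrow(gram)))), 1e-10)
  expect_equal(sum(b$weights), 4 * pi, tolerance = 1e-12)
  expect_error(sh_basis(16L, 8L, 48L), class = "quadrature_error")
})

test_that("decomposition reproduces known coefficients", {
  b <- sh_basis()
  # constant function: only a00 = sqrt(4 pi)
  a <- sh_decompose(rep(1, nrow(b$dirs)), b)
  expect_equal(a[1], sqrt(4 * pi), tolerance = 1e-10)
  expect_lt(max(abs(a[-1])), 1e-10)
  # a sampled basis function comes back as a delta (orthonormality)
  row_32 <- which(b$l == 3 & b$m == 2)
  a2 <- sh_decompose(b$Y[row_32, ], b)
  expect_equal(a2[row_32], 1, tolerance = 1e-10)
  expect_lt(max(abs(a2[-row_32])), 1e-10)
  # band-limited synthesis round trip
  set.seed(2)
  coeff <- rnorm(256)
  f <- sh_synthesize(coeff, b)
  expect_equal(sh_decompose(f, b), coeff, tolerance = 1e-10)
})

test_that("coefficients match closed forms and brute-force quadrature", {
  b <- sh_basis()
  x <- b$dirs[, 1]; y <- b$dirs[, 2]; z <- b$dirs[, 3]
  # closed-form band energies of Cartesian monomials (hand-derived):
  # f = x is pure degree 1 with int x^2 dOmega = 4 pi / 3
  expect_equal(sh_band_energy(sh_decompose(x, b), b)[2],
               sqrt(4 * pi / 3), tolerance = 1e-10)
  # f = xy is pure degree 2 with int (xy)^2 dOmega = 4 pi / 15
  e_xy <- sh_band_energy(sh_decompose(x * y, b), b)
  expect_equal(e_xy[3], sqrt(4 * pi / 15), tolerance = 1e-10)
  expect_lt(max(e_xy[-3]), 1e-10)
  # brute-force oracle: independent dense Simpson quadrature in cos(theta)
  # (4th order, so the degree-15 oscillations integrate below 1e-8) times
  # an equispaced phi sum, which is exact for the azimuthal orders involved
  f_fun <- function(d) 0.3 + d[, 1] * d[, 2] - 0.5 * d[, 3]^2 + d[, 1]
  n_ct <- 3000L; n_ph <- 64L
  ct <- seq(-1, 1, length.out = n_ct + 1L)
  h <- 2 / n_ct
  w_ct <- h / 3 * c(1, rep(c(4, 2), length.out = n_ct - 1L), 1)
  ph <- 2 * pi * (seq_len(n_ph) - 0.5) / n_ph
  st <- sqrt(pmax(0, 1 - ct^2))
  dirs_d <- cbind(rep(st, each = n_ph) * cos(ph),
                  rep(st, each = n_ph) * sin(ph), rep(ct, each = n_ph))
  w_d <- rep(w_ct, each = n_ph) * (2 * pi / n_ph)
  leg <- erythroshape:::.legendre_norm(15L, ct)
  fv <- f_fun(dirs_d)
  phv <- rep(ph, n_ct + 1L)
  a_oracle <- numeric(256)
  idx <- 0L
  for (l in 0:15) for (m in (-l):l) {
    idx <- idx + 1L
    base <- rep(leg[[l + 1L]][, abs(m) + 1L], each = n_ph)
    yv <- if (m == 0) base
    else if (m > 0) sqrt(2) * base * cos(m * phv)
    else sqrt(2) * base * sin(-m * phv)
    a_oracle[idx] <- sum(w_d * fv * yv)
  }
  a_fast <- sh_decompose(f_fun(b$dirs), b)
  expect_lt(max(abs(a_fast - a_oracle)), 1e-8)
})

test_that("Parseval holds per band for random band-limited functions", {
  b <- sh_basis()
  set.seed(9)
  for (rep_ in 1:5) {
    coeff <- rnorm(256)
    f <- sh_synthesize(coeff, b)
    bands <- sh_band_energy(sh_decompose(f, b), b)
    # sum over bands equals the quadrature of |f|^2
    expect_equal(sum(bands^2), sum(b$weights * f^2), tolerance = 1e-8)
    # per band: ||f_l||^2 = sum_m a_lm^2 of the generating coefficients
    for (l in 0:15)
      expect_equal(bands[l + 1]^2, sum(coeff[b$l == l]^2),
                   tolerance = 1e-8)
  }
})

test_that("euclid_f0_f2 returns the rotation-invariant eigenvalue triple", {
  b <- sh_basis()
  # isotropic: f == c gives (c, c, c) since x^2 + y^2 + z^2 = 1
  expect_equal(euclid_f0_f2(sh_decompose(rep(2.5, nrow(b$dirs)), b), b),
               rep(2.5, 3), tolerance = 1e-8)
  # f = z^2 decomposes into l = 0 and l = 2 parts with eigenvalues (1,0,0)
  expect_equal(euclid_f0_f2(sh_decompose(b$dirs[, 3]^2, b), b),
               c(1, 0, 0), tolerance = 1e-8)
  # rotated copies give the identical sorted triple
  set.seed(4)
  q <- matrix(rnorm(9), 3); q <- qr.Q(qr(q))
  f1 <- (b$dirs[, 1] + 0.5 * b$dirs[, 3])^2
  dr <- b$dirs %*% q
  f2 <- (dr[, 1] + 0.5 * dr[, 3])^2
  expect_equal(euclid_f0_f2(sh_decompose(f1, b), b),
               euclid_f0_f2(sh_decompose(f2, b), b), tolerance = 1e-8)
  # descending order is part of the contract
  tri <- euclid_f0_f2(sh_decompose(f1, b), b)
  expect_true(all(diff(tri) <= 0))
})

test_that("min-max normalization obeys its arithmetic contract", {
  expect_equal(normalize_descriptor(c(2, 4, 6)), c(0, 0.5, 1))
  v <- c(0, 0.25, 0.7, 1)
  expect_equal(normalize_descriptor(v), v)  # idempotent on [0,1] range
  expect_warning(z <- normalize_descriptor(c(5, 5, 5)))
  expect_equal(z, c(0, 0, 0))
})
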