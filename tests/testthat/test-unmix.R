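test_that("solve_nnls handles exact and degenerate cases", {
  R <- hcr10_reference_matrix()
  M <- nrow(R$R)

  # b = 0 -> x = 0, residual 0
  f0 <- solve_nnls(numeric(M), R)
  expect_equal(unname(f0$x), numeric(ncol(R$R)))
  expect_equal(f0$residual, 0)

  # b exactly representable as 3.7 * column j
  for (j in c(1L, 6L, 11L)) {
    f <- solve_nnls(3.7 * R$R[, j], R)
    expect_equal(unname(f$x[j]), 3.7, tolerance = 1e-9)
    expect_equal(unname(f$x[-j]), numeric(ncol(R$R) - 1), tolerance = 1e-9)
    expect_lt(f$residual, 1e-9)
  }

  expect_error(solve_nnls(c(1, NA, rep(0, M - 2)), R), "non-finite")
  expect_error(solve_nnls(numeric(M - 1), R), "length")
})

test_that("active-set solution matches the support-enumeration oracle", {
  worst <- 0
  for (seed in 1:60) {
    set.seed(seed)
    M <- sample(3:8, 1)
    C <- sample(2:min(4, M), 1)   # full column rank keeps x unique
    A <- matrix(runif(M * C), M, C)
    b <- if (seed %% 3 == 0) {
      # sometimes a representable b so the zero-residual branch is hit
      A %*% runif(C)
    } else {
      runif(M) - 0.2 * runif(M)
    }
    b <- pmax(as.numeric(b), 0)
    got <- solve_nnls(b, A)
    oracle <- nnls_oracle(A, b)
    worst <- max(worst, max(abs(got$x - oracle$x)),
                 abs(got$residual - oracle$residual))
  }
  expect_lt(worst, 1e-9)
})

test_that("NNLS never returns negative coefficients and bounds the residual", {
  R <- hcr10_reference_matrix()
  for (seed in 1:20) {
    set.seed(seed)
    b <- rexp(nrow(R$R))
    f <- solve_nnls(b, R)
    expect_true(all(f$x >= 0))
    expect_lte(f$residual, sqrt(sum(b^2)) + 1e-12)
  }
})

test_that("unmixing is positively scale-equivariant and permutation-equivariant", {
  R <- hcr10_reference_matrix()
  set.seed(3)
  b <- rexp(nrow(R$R))
  f1 <- solve_nnls(b, R)
  # powers of two scale exactly in floating point
  f2 <- solve_nnls(4 * b, R)
  expect_equal(unname(f2$x), unname(4 * f1$x), tolerance = 1e-13)
  expect_equal(f2$residual, 4 * f1$residual, tolerance = 1e-13)

  perm <- c(3, 1, 2, 5, 4, 11, 6, 10, 7, 9, 8)
  fp <- solve_nnls(b, R$R[, perm])
  expect_equal(unname(fp$x), unname(f1$x[perm]), tolerance = 1e-10)
})

test_that("spectral_image clamps negatives with a warning and checks shape", {
  sch <- tiny_scheme()
  dat <- array(1, c(1, 2, 2, 3))
  dat[1, 1, 1, 1] <- -0.5
  expect_warning(img <- spectral_image(dat, c(1, 1, 1), sch), "clamped")
  expect_equal(img$data[1, 1, 1, 1], 0)

  # (Y,X,M) promoted to Z = 1
  img2 <- spectral_image(array(1, c(4, 5, 3)), c(1, 1, 1), sch)
  expect_equal(dim(img2$data), c(1L, 4L, 5L, 3L))

  expect_error(spectral_image(array(1, c(1, 2, 2, 4)), c(1, 1, 1), sch),
               "scheme M")
  expect_error(spectral_image(array(1, c(1, 2, 2, 3)), c(0, 1, 1), sch),
               "pixel_size")
})

test_that("unmix_image equals the per-pixel loop for any chunk size", {
  scheme <- hcr10_scheme()
  Rm <- small_refmat()
  set.seed(10)
  dat <- array(rexp(16 * 16 * 2 * scheme$M), c(2L, 16L, 16L, scheme$M))
  img <- spectral_image(dat, c(1.2, 0.18, 0.18), scheme)
  um_chunked <- unmix_image(img, Rm, chunk_size = 7L)
  um_big <- unmix_image(img, Rm, chunk_size = 1e6L)
  expect_identical(um_chunked$coefficients, um_big$coefficients)
  expect_identical(um_chunked$residual, um_big$residual)
  # explicit per-pixel loop oracle
  for (i in sample(16, 4)) {
    for (j in sample(16, 4)) {
      f <- solve_nnls(dat[1, i, j, ], Rm)
      expect_equal(um_chunked$coefficients[1, i, j, ], unname(f$x),
                   tolerance = 1e-12)
      expect_equal(um_chunked$residual[1, i, j], f$residual,
                   tolerance = 1e-9)
    }
  }
})

test_that("unmixing a pure-column image recovers a uniform coefficient", {
  Rm <- small_refmat()
  scheme <- hcr10_scheme()
  M <- scheme$M
  dat <- aperm(array(2 * Rm$R[, 2] %o% rep(1, 36), c(M, 6, 6)), c(2, 3, 1))
  dat <- array(dat, c(1L, 6L, 6L, M))
  img <- spectral_image(dat, c(1, 1, 1), scheme)
  um <- unmix_image(img, Rm)
  expect_equal(as.vector(um$coefficients[, , , 2]), rep(2, 36),
               tolerance = 1e-9)
  expect_lt(max(abs(um$coefficients[, , , c(1, 3)])), 1e-9)
  expect_lt(max(um$residual), 1e-9)

  # all-zero image
  um0 <- unmix_image(spectral_image(array(0, c(1, 4, 4, M)),
                                    c(1, 1, 1), scheme), Rm)
  expect_true(all(um0$coefficients == 0))
  expect_true(all(um0$residual == 0))
  expect_true(all(um0$relative_residual == 0))
})

test_that("scheme mismatch between image and matrix is a descriptive error", {
  sch <- tiny_scheme()
  cols <- list(A = c(1, 0, 0), B = c(0, 1, 0), C = c(0, 0, 1))
  Rm <- ref_from_cols(cols, sch)
  other <- acquisition_scheme(c(488, 562),
                              list(rbind(c(500, 540), c(545, 585)),
                                   rbind(c(575, 630))))
  img <- spectral_image(array(1, c(1, 2, 2, 3)), c(1, 1, 1), other)
  expect_error(unmix_image(img, Rm), "excitations differ")
})

test_that("extra AF channels append, rename, and can reduce the residual", {
  Rm <- small_refmat()
  scheme <- hcr10_scheme()
  af2_model <- fluorophore_model("AFx", 460, 620, excitation_width = 70,
                                 emission_width = 60)
  af2 <- reference_spectrum("whatever",
                            predict_response(af2_model, scheme), scheme)
  R4 <- add_af_channels(Rm, list(af2))
  expect_equal(ncol(R4$R), 4L)
  expect_equal(R4$channel_names[4], "AF2")
  expect_equal(R4$n_af, 2L)

  # duplicating an existing column propagates the conditioning warning
  dup <- reference_spectrum("dup", Rm$R[, 3], scheme)
  expect_warning(add_af_channels(Rm, list(dup)), "collinear")

  # two-tissue sample: second AF source present in the image; unmixing
  # with both AF references fits strictly better on average
  set.seed(8)
  n <- 12L
  ab <- matrix(rexp(n * n * 2, rate = 2), ncol = 2)
  af1 <- as.numeric(rexp(n * n, rate = 4))
  af2f <- as.numeric(rexp(n * n, rate = 4))
  B <- cbind(ab, af1, af2f) %*% t(cbind(Rm$R, af2$intensities))
  img <- spectral_image(array(B, c(1L, n, n, scheme$M)), c(1, 1, 1), scheme)
  um1 <- unmix_image(img, Rm)
  um2 <- unmix_image(img, R4)
  expect_lt(mean(um2$residual), mean(um1$residual))
  expect_lt(max(um2$residual), 1e-6)   # 2-AF model is exact here
})
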