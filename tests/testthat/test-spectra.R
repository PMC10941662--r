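test_that("reference spectra are normalized, validated, non-degenerate", {
  sch <- tiny_scheme()
  s <- reference_spectrum("A", c(2, 4, 1), sch)
  expect_equal(max(s$intensities), 1)
  expect_equal(s$intensities, c(0.5, 1, 0.25))
  expect_error(reference_spectrum("A", c(0, 0, 0), sch), "degenerate")
  expect_error(reference_spectrum("A", c(1, -1, 0), sch), "negative")
  expect_error(reference_spectrum("A", c(1, 2), sch), "does not match")
})

test_that("extraction averages the brightest pixels and normalizes", {
  sch <- tiny_scheme()
  # homogeneous image: every pixel is s -> s / max(s), selection irrelevant
  s <- c(1, 5, 2)
  data <- array(rep(s, each = 200), c(1L, 10L, 20L, 3L))
  img <- spectral_image(data, c(1, 1, 1), sch)
  got <- extract_reference_spectrum(img, "S")
  expect_equal(got$intensities, s / max(s), tolerance = 1e-14)

  # two-region image: 1% of pixels are bright 10*b, the rest dim a;
  # oracle = brute-force pick of brightest pixels, then mean + normalize
  a <- c(4, 1, 0.5)
  b <- c(0.2, 1, 2)
  n <- 1000L
  mat <- matrix(rep(a, each = n), n, 3)
  bright <- 1:10
  mat[bright, ] <- matrix(rep(10 * b, each = 10), 10, 3)
  img2 <- spectral_image(array(mat, c(1L, 20L, 50L, 3L)), c(1, 1, 1), sch)
  got2 <- extract_reference_spectrum(img2, "B", top_fraction = 0.001)
  # oracle
  totals <- rowSums(mat)
  sel <- order(totals, decreasing = TRUE)[1:max(1, ceiling(0.001 * n))]
  oracle <- colMeans(mat[sel, , drop = FALSE])
  expect_equal(got2$intensities, oracle / max(oracle), tolerance = 1e-14)
  expect_equal(got2$intensities, b / max(b), tolerance = 1e-14)

  # explicit mask override
  msk <- array(FALSE, c(1L, 20L, 50L))
  msk[1, 1, 1] <- TRUE
  got3 <- extract_reference_spectrum(img2, "M", mask = msk)
  expect_equal(got3$intensities, 10 * b / max(10 * b), tolerance = 1e-14)
  expect_error(extract_reference_spectrum(img2, mask = integer(0)),
               "empty mask")
  zero <- spectral_image(array(0, c(1, 4, 4, 3)), c(1, 1, 1), sch)
  expect_error(extract_reference_spectrum(zero), "all zero")
})

test_that("extraction is invariant to positive rescaling of the image", {
  fx <- hcr10_fixture_inputs(seed = 2, dim = c(2L, 16L, 16L))
  img <- fx$oneplex[[5]]
  s1 <- extract_reference_spectrum(img, "Ch5")
  scaled <- spectral_image(img$data * 37.5, img$pixel_size, img$scheme)
  s2 <- extract_reference_spectrum(scaled, "Ch5")
  expect_equal(s1$intensities, s2$intensities, tolerance = 1e-12)
})

test_that("eleven 1-plex/AF images assemble into an 11-column matrix", {
  fx <- hcr10_fixture_inputs(seed = 1, dim = c(2L, 16L, 16L))
  R <- build_reference_matrix(fx$oneplex, fx$af_image)
  expect_equal(ncol(R$R), 11L)
  expect_equal(R$n_af, 1L)
  expect_equal(R$channel_names,
               c(paste0("Ch", 1:10), "AF"))
  expect_true(all(apply(R$R, 2, max) == 1))
})

test_that("condition_report matches an independent SVD and flags collinearity", {
  # orthonormal columns: condition 1, min angle 90, no warning
  I3 <- diag(3)
  sch <- tiny_scheme()
  rep1 <- condition_report(I3)
  expect_equal(rep1$condition_number, 1)
  expect_equal(rep1$min_angle_deg, 90)
  expect_false(rep1$warn)

  # duplicated column: cosine 1, angle 0, warning
  dup <- cbind(c(1, 2, 3), c(1, 2, 3), c(0, 1, 0))
  rep2 <- condition_report(dup)
  expect_equal(rep2$cosine_similarity[1, 2], 1, tolerance = 1e-12)
  expect_equal(rep2$min_angle_deg, 0, tolerance = 1e-5)
  expect_true(rep2$warn)

  # random seeded 26x11: condition equals independent computation
  set.seed(42)
  A <- matrix(runif(26 * 11), 26, 11)
  got <- condition_report(A)$condition_number
  if (requireNamespace("pracma", quietly = TRUE)) {
    expect_equal(got, pracma::cond(A), tolerance = 1e-10)
  }
  expect_equal(got, kappa(A, exact = TRUE), tolerance = 1e-10)
})

test_that("AF optimizer equals exhaustive argmax and partitions the red range", {
  # single nonzero entry at ex = 470
  ex <- seq(440, 500, by = 10)
  em <- seq(450, 700, by = 10)
  I <- matrix(0, length(ex), length(em))
  I[ex == 470, 10] <- 1
  got <- optimize_af_channel(eem_scan(ex, em, I))
  expect_equal(got$af_excitation, 470)

  # separable scan peaked at 488: argmax 488, 4 equal bands to range end
  ex2 <- c(450, 470, 488, 510, 530)
  em2 <- seq(460, 760, by = 5)
  f <- exp(-(ex2 - 488)^2 / 200)
  g <- exp(-(em2 - 600)^2 / 5000)
  got2 <- optimize_af_channel(eem_scan(ex2, em2, outer(f, g)))
  expect_equal(got2$af_excitation, 488)
  expect_equal(nrow(got2$bands), 4L)
  widths <- got2$bands[, "end"] - got2$bands[, "start"]
  expect_equal(max(widths) - min(widths), 0, tolerance = 1e-12)
  expect_equal(unname(got2$bands[1, "start"]), 488 + 10)
  expect_equal(unname(got2$bands[4, "end"]), max(em2))
  # contiguous
  expect_equal(unname(got2$bands[-1, "start"]),
               unname(got2$bands[-4, "end"]))

  # flat scan: tie broken toward the shortest wavelength
  flat <- optimize_af_channel(eem_scan(ex2, em2,
                                       matrix(1, length(ex2), length(em2))))
  expect_equal(flat$af_excitation, min(ex2))

  expect_error(
    optimize_af_channel(eem_scan(ex2, em2,
                                 matrix(0, length(ex2), length(em2)))),
    "no autofluorescence")
})

test_that("AF optimizer equals the exhaustive row-sum argmax on random scans", {
  guard <- 10
  for (seed in 1:25) {
    set.seed(seed)
    ex <- sort(sample(400:600, 8))
    em <- seq(420, 780, by = 15)
    I <- matrix(rexp(length(ex) * length(em)), length(ex))
    got <- optimize_af_channel(eem_scan(ex, em, I), guard = guard)
    scores <- sapply(seq_along(ex), function(i) {
      sum(I[i, em >= ex[i] + guard])
    })
    expect_equal(got$af_excitation, ex[which.max(scores)])
    expect_equal(got$scores, scores)
  }
})

test_that("reference CSV round-trips through write and read", {
  R <- hcr10_reference_matrix()
  path <- withr::local_tempfile(fileext = ".csv")
  write_reference_csv(R, path)
  back <- read_reference_csv(path, hcr10_scheme(), n_af = 1L)
  expect_equal(back$channel_names, R$channel_names)
  expect_equal(unname(back$R), unname(R$R), tolerance = 1e-12)
})
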