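test_that("predict_response follows the excitation-times-band-integral model", {
  sch <- acquisition_scheme(500, list(rbind(c(510, 510 + 6 * 15 * 2))))
  f <- fluorophore_model("F", excitation_peak = 500, emission_peak = 600,
                         emission_width = 15, brightness = 2.5)
  # band spanning +/- 6 sigma around the emission peak captures ~everything
  wide <- acquisition_scheme(500, list(rbind(c(600 - 6 * 15, 600 + 6 * 15))))
  expect_equal(predict_response(f, wide), 2.5, tolerance = 1e-8)

  # excitation 10 sigma off peak: essentially dark
  far <- fluorophore_model("F", excitation_peak = 500 - 10 * 18,
                           emission_peak = 600, excitation_width = 18,
                           emission_width = 15, brightness = 1)
  expect_lt(max(predict_response(far, wide)), 1e-20)

  # one-sigma band at peak excitation: the Gaussian CDF value
  one_sigma <- acquisition_scheme(500, list(rbind(c(600, 615))))
  expect_equal(predict_response(f, one_sigma),
               2.5 * (pnorm(1) - pnorm(0)), tolerance = 1e-12)
})

test_that("fluorophore model validates its parameters", {
  expect_error(fluorophore_model("F", 600, 550), "Stokes")
  expect_error(fluorophore_model("F", 500, 550, excitation_width = 0),
               "widths")
  expect_error(fluorophore_model("F", 500, 550, brightness = -1),
               "brightness")
})

test_that("noise-free rendering is the exact linear superposition", {
  scheme <- hcr10_scheme()
  fl <- hcr10_fluorophores()[1:3]
  afs <- hcr10_af_spectrum(scheme)
  sc <- hcr10_demo_scene(dim = c(2L, 16L, 16L), seed = 3)
  sc$channels <- sc$channels[1:3]
  r <- render_spectral_image(sc, fl, afs, scheme)
  # reconstruct the expectation by hand from truth and responses
  n <- prod(dim(r$truth)[1:3])
  A <- matrix(r$truth, nrow = n)
  expected <- A %*% t(r$responses) + as.vector(r$af_field) %o% afs
  expect_equal(as.vector(r$image$data), as.vector(expected),
               tolerance = 1e-14)

  # zero abundances and AF off -> all-zero image
  sc0 <- scene_spec(c(1L, 8L, 8L), c(1, 1, 1),
                    channels = list(list(domains = list())),
                    af = list(amplitude = 0))
  r0 <- render_spectral_image(sc0, fl[1], NULL, scheme)
  expect_true(all(r0$image$data == 0))
})

test_that("noise-free total intensity satisfies the conservation identity", {
  scheme <- hcr10_scheme()
  fl <- hcr10_fluorophores()[1:2]
  afs <- hcr10_af_spectrum(scheme)
  sc <- make_redundant_detection_scene(dim = c(2L, 20L, 20L), seed = 11)
  r <- render_spectral_image(sc, fl, afs, scheme)
  total <- sum(r$image$data)
  expected <- sum(vapply(1:2, function(c) {
    sum(r$truth[, , , c]) * sum(r$responses[, c])
  }, 0)) + sum(r$af_field) * sum(afs)
  expect_equal(total, expected, tolerance = 1e-10)
})

test_that("Poisson noise has the expected mean and variance scaling", {
  scheme <- acquisition_scheme(500, list(rbind(c(510, 560))))
  f <- fluorophore_model("F", 500, 530, emission_width = 15)
  budget <- 1e4
  draws <- 2000L
  vals <- vapply(seq_len(draws), function(i) {
    sc <- scene_spec(c(1L, 1L, 1L), c(1, 1, 1),
                     channels = list(list(domains = list(
                       list(type = "box", lo = c(0, 0, 0), hi = c(1, 1, 1),
                            amplitude = 2)))),
                     af = list(amplitude = 0),
                     noise = list(photon_budget = budget,
                                  read_noise_sd = 0),
                     seed = i)
    render_spectral_image(sc, list(f), NULL, scheme)$image$data[1, 1, 1, 1]
  }, 0)
  mu <- 2 * predict_response(f, scheme)
  se <- sqrt(mu / budget / draws)
  expect_lt(abs(mean(vals) - mu), 3 * se)
  # var(X/budget) = mu/budget
  expect_equal(var(vals) * budget, mu, tolerance = 0.15)
})

test_that("identical seeds reproduce identical noisy renders", {
  scheme <- hcr10_scheme()
  fl <- hcr10_fluorophores()[1:2]
  sc <- make_redundant_detection_scene(dim = c(1L, 12L, 12L),
                                       photon_budget = 100, seed = 5)
  r1 <- render_spectral_image(sc, fl, hcr10_af_spectrum(scheme), scheme)
  r2 <- render_spectral_image(sc, fl, hcr10_af_spectrum(scheme), scheme)
  expect_identical(r1$image$data, r2$image$data)
})

test_that("redundant-detection scenes share one field scaled by the gains", {
  sc <- make_redundant_detection_scene(gains = c(1, 1), seed = 2)
  gt <- build_abundance(sc)
  expect_identical(gt$abundance[, , , 1], gt$abundance[, , , 2])

  sc2 <- make_redundant_detection_scene(gains = c(1, 2), seed = 2)
  gt2 <- build_abundance(sc2)
  expect_equal(gt2$abundance[, , , 2], 2 * gt2$abundance[, , , 1],
               tolerance = 1e-14)
})

test_that("single-molecule scenes respect count, separation, determinism", {
  expect_equal(nrow(build_abundance(
    make_single_molecule_scene(0, seed = 1))$dots), 0L)

  sc <- make_single_molecule_scene(25, min_separation_um = 2, seed = 9)
  d <- build_abundance(sc)$dots
  d1 <- d[d$channel == 1, ]
  expect_equal(nrow(d1), 25L)
  pos <- as.matrix(d1[, c("z_um", "y_um", "x_um")])
  pd <- as.matrix(dist(pos))
  expect_gte(min(pd[upper.tri(pd)]), 2)

  sc2 <- make_single_molecule_scene(25, min_separation_um = 2, seed = 9)
  expect_identical(build_abundance(sc2)$dots, d)

  # infeasible packing errors out
  expect_error(
    make_single_molecule_scene(200, dim = c(1L, 10L, 10L),
                               pixel_size = c(1, 0.1, 0.1),
                               min_separation_um = 1, margin_um = 0.1,
                               seed = 1, max_tries = 50),
    "min separation")
})

test_that("fixture fluorophores span the intended emission range", {
  fl <- hcr10_fluorophores()
  peaks <- vapply(fl, function(f) f$emission_peak, 0)
  expect_length(peaks, 10L)
  expect_lt(min(peaks), 430)
  expect_gt(max(peaks), 790)
})
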