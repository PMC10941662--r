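#' Parametric fluorophore model
#'
#' Gaussian stand-in for a fluorophore's excitation and emission spectra.
#' Real dye spectra are asymmetric; the Gaussian form is used because its
#' band integrals are analytic (via the normal CDF) and its overlap between
#' neighbouring channels is directly controllable, which is what the
#' simulator needs to stress linear unmixing.
#'
#' @param name Channel label.
#' @param excitation_peak,emission_peak Peak wavelengths in nm
#'   (`emission_peak >= excitation_peak`, the Stokes shift is non-negative).
#' @param excitation_width,emission_width Gaussian sigma in nm, > 0.
#' @param brightness Photons per unit abundance at peak excitation with the
#'   full emission spectrum collected; >= 0.
#' @return Object of class `fluorophore_model`.
#' @export
fluorophore_model <- function(name, excitation_peak, emission_peak,
                              excitation_width = 18, emission_width = 20,
                              brightness = 1) {
  if (emission_peak < excitation_peak) {
    stop("emission_peak must be >= excitation_peak (non-negative Stokes shift)")
  }
  if (excitation_width <= 0 || emission_width <= 0) stop("widths must be > 0")
  if (brightness < 0) stop("brightness must be >= 0")
  structure(list(name = as.character(name),
                 excitation_peak = excitation_peak,
                 excitation_width = excitation_width,
                 emission_peak = emission_peak,
                 emission_width = emission_width,
                 brightness = brightness),
            class = "fluorophore_model")
}

#' Predicted detector response of a fluorophore under a scheme
#'
#' For each (excitation `e`, band `[a, b]`) measurement the response is
#' `brightness * exp(-(e - excitation_peak)^2 / (2 sigma_ex^2))` times the
#' integral over `[a, b]` of the unit-area Gaussian emission density.
#' This is the noise-free reference spectrum of the fluorophore on that
#' scheme, before normalization.
#'
#' @param f A [fluorophore_model()].
#' @param scheme An [acquisition_scheme()].
#' @return Numeric M-vector.
#' @export
predict_response <- function(f, scheme) {
  stopifnot(inherits(f, "fluorophore_model"),
            inherits(scheme, "acquisition_scheme"))
  mt <- measurement_table(scheme)
  ex_eff <- exp(-(mt$excitation_nm - f$excitation_peak)^2 /
                  (2 * f$excitation_width^2))
  em_frac <- stats::pnorm(mt$band_end_nm, f$emission_peak, f$emission_width) -
    stats::pnorm(mt$band_start_nm, f$emission_peak, f$emission_width)
  f$brightness * ex_eff * em_frac
}

#' The bundled 10-plex fluorophore set
#'
#' Ten Gaussian fluorophore models whose excitation peaks sit on the ten
#' non-AF lines of [hcr10_scheme()] and whose emission peaks span
#' 425-795 nm, deliberately overlapping between neighbours so that
#' separation genuinely requires unmixing.
#'
#' @return List of ten [fluorophore_model()] objects named Ch1..Ch10.
#' @export
hcr10_fluorophores <- function() {
  ex <- c(400, 441, 482, 523, 564, 605, 646, 687, 728, 770)
  bright <- c(1.0, 0.9, 1.1, 1.0, 0.95, 1.05, 1.0, 0.9, 1.1, 1.0)
  lapply(seq_along(ex), function(i) {
    fluorophore_model(paste0("Ch", i), ex[i], ex[i] + 25,
                      excitation_width = 18, emission_width = 20,
                      brightness = bright[i])
  })
}

#' Autofluorescence model and spectrum for the bundled fixture
#'
#' Tissue autofluorescence is modelled as one broad pseudo-fluorophore:
#' efficiently excited in the violet-blue, with a wide emission spread across
#' the visible range. `hcr10_af_spectrum` returns its (unnormalized)
#' predicted response on a scheme.
#'
#' @return `hcr10_af_model()`: a [fluorophore_model()];
#'   `hcr10_af_spectrum(scheme)`: numeric M-vector.
#' @export
hcr10_af_model <- function() {
  fluorophore_model("AF", excitation_peak = 405, emission_peak = 520,
                    excitation_width = 60, emission_width = 90,
                    brightness = 1)
}

#' @rdname hcr10_af_model
#' @param scheme An [acquisition_scheme()].
#' @export
hcr10_af_spectrum <- function(scheme) {
  predict_response(hcr10_af_model(), scheme)
}

# -- deterministic sub-seed derivation: one master seed, one stream per stage
derive_seed <- function(master, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(master) * 69069 + h * 7919 + 1) %% (2^31 - 1))
}

#' Scene specification for the spectral simulator
#'
#' A scene is a voxel grid plus, per fluorophore channel, an abundance field
#' defined as a union of geometric domains (boxes, ellipsoids, axis stripes)
#' and/or point sources (diffraction-limited dots rendered as Gaussians with
#' per-axis PSF sigma), an autofluorescence field, and a noise model.
#'
#' Channels may share an abundance field (`share`/`gain`), the simulator
#' analog of two-channel redundant detection of one target.
#'
#' @param dim Integer grid shape `c(Z, Y, X)`.
#' @param pixel_size Physical voxel size in µm, `c(z, y, x)`.
#' @param channels List of channel specs. Each is a list with optional
#'   elements `domains` (list of domain specs, see Details), `dots`
#'   (data.frame with `z_um`, `y_um`, `x_um`, `amplitude`), `psf_sigma_um`
#'   (length-3, required when `dots` present), or `share` (index of an
#'   earlier channel whose field is reused) with `gain`.
#' @param af List `list(amplitude = ...)`; the AF field is a smooth
#'   low-frequency map scaled by `amplitude` (0 disables AF).
#' @param noise List with `photon_budget` (photons per intensity unit for
#'   Poisson noise; `NULL` disables) and `read_noise_sd` (Gaussian sigma in
#'   intensity units).
#' @param seed Master seed; all randomness in rendering derives from it.
#'
#' @details Domain specs: `list(type = "box", lo =, hi =, amplitude =)`,
#'   `list(type = "ellipsoid", center =, radii =, amplitude =)`,
#'   `list(type = "stripe", axis = "z"|"y"|"x", lo =, hi =, amplitude =)`;
#'   all coordinates in µm, with the origin at the outer corner of voxel
#'   `[1,1,1]` and voxel centers at `(i - 0.5) * pixel_size`.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(dim, pixel_size, channels, af = list(amplitude = 0),
                       noise = list(photon_budget = NULL, read_noise_sd = 0),
                       seed = 1L) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L),
            length(pixel_size) == 3L, all(pixel_size > 0))
  for (ch in channels) {
    for (d in ch$domains) {
      if (!is.null(d$amplitude) && d$amplitude < 0) {
        stop("domain amplitudes must be >= 0")
      }
    }
    if (!is.null(ch$dots) && nrow(ch$dots) > 0) {
      if (is.null(ch$psf_sigma_um) || any(ch$psf_sigma_um <= 0)) {
        stop("channels with dots need psf_sigma_um > 0")
      }
      if (any(ch$dots$amplitude < 0)) stop("dot amplitudes must be >= 0")
    }
  }
  if (!is.null(af$amplitude) && af$amplitude < 0) {
    stop("AF amplitude must be >= 0")
  }
  structure(list(dim = dim, pixel_size = as.numeric(pixel_size),
                 channels = channels, af = af, noise = noise,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# voxel-center coordinate grids (µm), one vector per axis
axis_coords <- function(dim, pixel_size) {
  lapply(1:3, function(a) (seq_len(dim[a]) - 0.5) * pixel_size[a])
}

render_domain <- function(d, cz, cy, cx) {
  nz <- length(cz); ny <- length(cy); nx <- length(cx)
  amp <- if (is.null(d$amplitude)) 1 else d$amplitude
  field <- array(0, c(nz, ny, nx))
  if (d$type == "box") {
    iz <- cz >= d$lo[1] & cz <= d$hi[1]
    iy <- cy >= d$lo[2] & cy <= d$hi[2]
    ix <- cx >= d$lo[3] & cx <= d$hi[3]
    field[iz, iy, ix] <- amp
  } else if (d$type == "ellipsoid") {
    dz <- (cz - d$center[1]) / d$radii[1]
    dy <- (cy - d$center[2]) / d$radii[2]
    dx <- (cx - d$center[3]) / d$radii[3]
    r2 <- outer(outer(dz^2, dy^2, `+`), dx^2, `+`)
    field[r2 <= 1] <- amp
  } else if (d$type == "stripe") {
    co <- switch(d$axis, z = cz, y = cy, x = cx)
    sel <- co >= d$lo & co <= d$hi
    if (d$axis == "z") field[sel, , ] <- amp
    if (d$axis == "y") field[, sel, ] <- amp
    if (d$axis == "x") field[, , sel] <- amp
  } else {
    stop("unknown domain type: ", d$type)
  }
  field
}

render_dots <- function(dots, psf_sigma_um, cz, cy, cx) {
  field <- array(0, c(length(cz), length(cy), length(cx)))
  for (i in seq_len(nrow(dots))) {
    gz <- exp(-(cz - dots$z_um[i])^2 / (2 * psf_sigma_um[1]^2))
    gy <- exp(-(cy - dots$y_um[i])^2 / (2 * psf_sigma_um[2]^2))
    gx <- exp(-(cx - dots$x_um[i])^2 / (2 * psf_sigma_um[3]^2))
    field <- field + dots$amplitude[i] * outer(outer(gz, gy), gx)
  }
  field
}

#' Ground-truth abundance fields of a scene
#'
#' @param scene A [scene_spec()].
#' @return List with `abundance` (Z,Y,X,C array), `af_field` (Z,Y,X array,
#'   unscaled by spectrum), and `dots` (data.frame of ground-truth dot
#'   positions with a `channel` column; zero rows when the scene has none).
#' @export
build_abundance <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  co <- axis_coords(scene$dim, scene$pixel_size)
  C <- length(scene$channels)
  ab <- array(0, c(scene$dim, max(C, 1L)))
  fields <- vector("list", C)
  dot_rows <- list()
  for (c in seq_len(C)) {
    ch <- scene$channels[[c]]
    if (!is.null(ch$share)) {
      if (ch$share >= c) stop("share must reference an earlier channel")
      gain <- if (is.null(ch$gain)) 1 else ch$gain
      fields[[c]] <- fields[[ch$share]] * gain
    } else {
      f <- array(0, scene$dim)
      for (d in ch$domains) {
        f <- f + render_domain(d, co[[1]], co[[2]], co[[3]])
      }
      if (!is.null(ch$dots) && nrow(ch$dots) > 0) {
        f <- f + render_dots(ch$dots, ch$psf_sigma_um,
                             co[[1]], co[[2]], co[[3]])
      }
      fields[[c]] <- f
    }
    ab[, , , c] <- fields[[c]]
    src <- if (!is.null(ch$share)) scene$channels[[ch$share]]$dots else ch$dots
    if (!is.null(src) && nrow(src) > 0) {
      dot_rows[[length(dot_rows) + 1L]] <-
        cbind(src[c("z_um", "y_um", "x_um", "amplitude")], channel = c)
    }
  }
  # AF: smooth low-frequency raised-cosine map, strictly positive where on
  af_field <- array(0, scene$dim)
  if (!is.null(scene$af$amplitude) && scene$af$amplitude > 0) {
    wy <- 0.55 + 0.45 * cos(2 * pi * (co[[2]] - mean(co[[2]])) /
                              (scene$dim[2] * scene$pixel_size[2]))
    wx <- 0.55 + 0.45 * cos(2 * pi * (co[[3]] - mean(co[[3]])) /
                              (scene$dim[3] * scene$pixel_size[3]))
    plane <- outer(wy, wx)
    for (z in seq_len(scene$dim[1])) af_field[z, , ] <- plane
    af_field <- scene$af$amplitude * af_field
  }
  dots <- if (length(dot_rows)) do.call(rbind, dot_rows) else
    data.frame(z_um = numeric(0), y_um = numeric(0), x_um = numeric(0),
               amplitude = numeric(0), channel = integer(0))
  rownames(dots) <- NULL
  list(abundance = ab, af_field = af_field, dots = dots)
}

#' Render a spectral image from a scene
#'
#' Forward model of acquisition: the expected pixel spectrum is the linear
#' superposition `sum_c abundance_c * response_c + AF_field * af_spectrum`.
#' With a finite photon budget the observed value is
#' `Poisson(expected * budget) / budget` plus Gaussian read noise, clamped at
#' zero; with noise disabled the observation equals the expectation exactly.
#' Identical seeds give identical images.
#'
#' @param scene A [scene_spec()].
#' @param fluorophores List of [fluorophore_model()], one per scene channel.
#' @param af_spectrum Numeric M-vector (the AF response on `scheme`), or
#'   `NULL` when the scene has no AF.
#' @param scheme An [acquisition_scheme()].
#' @return List with `image` (a [spectral_image()]), `truth` (Z,Y,X,C
#'   abundance array), `af_field`, `dots` (ground-truth dot table), and
#'   `responses` (M x C matrix of noise-free fluorophore responses).
#' @export
render_spectral_image <- function(scene, fluorophores, af_spectrum, scheme) {
  stopifnot(inherits(scene, "scene_spec"),
            inherits(scheme, "acquisition_scheme"))
  if (length(fluorophores) != length(scene$channels)) {
    stop("scene has ", length(scene$channels), " channels but ",
         length(fluorophores), " fluorophore models were given")
  }
  gt <- build_abundance(scene)
  M <- scheme$M
  R <- vapply(fluorophores, predict_response, numeric(M), scheme = scheme)
  R <- matrix(R, nrow = M)
  n_pix <- prod(scene$dim)
  A <- matrix(gt$abundance, nrow = n_pix)        # n_pix x C
  expected <- A %*% t(R)                          # n_pix x M
  has_af <- !is.null(af_spectrum) && any(gt$af_field > 0)
  if (has_af) {
    stopifnot(length(af_spectrum) == M)
    expected <- expected + as.vector(gt$af_field) %o% as.numeric(af_spectrum)
  }
  observed <- expected
  budget <- scene$noise$photon_budget
  read_sd <- scene$noise$read_noise_sd
  if (!is.null(budget) || (!is.null(read_sd) && read_sd > 0)) {
    seed <- derive_seed(scene$seed, "render")
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    if (!is.null(budget)) {
      observed <- matrix(stats::rpois(length(expected), expected * budget),
                         nrow = n_pix) / budget
    }
    if (!is.null(read_sd) && read_sd > 0) {
      observed <- observed + stats::rnorm(length(observed), sd = read_sd)
    }
    observed <- pmax(observed, 0)
  }
  img <- spectral_image(array(observed, c(scene$dim, M)),
                        pixel_size = scene$pixel_size, scheme = scheme)
  list(image = img, truth = gt$abundance, af_field = gt$af_field,
       dots = gt$dots, responses = R)
}

#' Two-channel redundant-detection scene
#'
#' One target's abundance field observed through two fluorophore channels
#' whose signals differ only by per-channel gains -- the simulator analog of
#' detecting one mRNA with two probe sets driving two orthogonal HCR
#' amplifiers. The base field is a seeded set of random ellipsoidal
#' expression blobs.
#'
#' @param dim,pixel_size Grid shape and voxel size (µm).
#' @param gains Length-2 positive gains for the two channels.
#' @param n_blobs Number of random ellipsoidal expression domains.
#' @param amplitude Peak abundance scale of the blobs.
#' @param af_amplitude AF field amplitude.
#' @param photon_budget,read_noise_sd Noise model (see [scene_spec()]).
#' @param seed Master seed.
#' @return A [scene_spec()] with two channels, the second sharing the
#'   first's field scaled by `gains[2]/gains[1]`.
#' @export
make_redundant_detection_scene <- function(dim = c(4L, 48L, 48L),
                                           pixel_size = c(1.2, 0.18, 0.18),
                                           gains = c(1, 2),
                                           n_blobs = 8,
                                           amplitude = 1,
                                           af_amplitude = 0.1,
                                           photon_budget = NULL,
                                           read_noise_sd = 0,
                                           seed = 1L) {
  stopifnot(length(gains) == 2L, all(gains > 0))
  fov <- dim * pixel_size                # (z,y,x) extent µm
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(derive_seed(seed, "blobs"))
  domains <- lapply(seq_len(n_blobs), function(i) {
    center <- stats::runif(3, 0.15, 0.85) * fov
    radii <- c(stats::runif(1, 0.3, 0.8) * fov[1],
               stats::runif(2, 0.08, 0.25) * fov[2:3])
    list(type = "ellipsoid", center = center, radii = radii,
         amplitude = gains[1] * amplitude * stats::runif(1, 0.4, 1))
  })
  scene_spec(dim, pixel_size,
             channels = list(
               list(domains = domains),
               list(share = 1L, gain = gains[2] / gains[1])
             ),
             af = list(amplitude = af_amplitude),
             noise = list(photon_budget = photon_budget,
                          read_noise_sd = read_noise_sd),
             seed = seed)
}

#' Single-molecule (dHCR-like) scene with shared ground-truth dots
#'
#' Samples dot positions uniformly in the field of view with rejection to
#' enforce a minimum pairwise separation, and writes the same positions into
#' both channels of a redundant pair.
#'
#' @param n_dots Number of molecules (>= 0).
#' @param dim,pixel_size Grid shape and voxel size (µm).
#' @param psf_sigma_um Per-axis PSF sigma (z, y, x) in µm.
#' @param amplitude Peak intensity per dot.
#' @param min_separation_um Minimum pairwise distance between dots (µm).
#' @param margin_um Keep-out border so dots are not clipped by the FOV edge.
#' @param af_amplitude,photon_budget,read_noise_sd As in [scene_spec()].
#' @param seed Master seed.
#' @param max_tries Rejection-sampling retry bound per dot.
#' @return A [scene_spec()]; its ground-truth dots are available through
#'   [build_abundance()] / [render_spectral_image()].
#' @export
make_single_molecule_scene <- function(n_dots,
                                       dim = c(3L, 96L, 96L),
                                       pixel_size = c(1.2, 0.18, 0.18),
                                       psf_sigma_um = c(0.9, 0.25, 0.25),
                                       amplitude = 1,
                                       min_separation_um = 2,
                                       margin_um = 1,
                                       af_amplitude = 0.05,
                                       photon_budget = NULL,
                                       read_noise_sd = 0,
                                       seed = 1L,
                                       max_tries = 2000L) {
  stopifnot(n_dots >= 0, min_separation_um >= 0)
  fov <- dim * pixel_size
  # per-axis keep-out border, capped so thin axes (single z-slice) still work
  margin <- pmin(rep(margin_um, length.out = 3), 0.45 * fov)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(derive_seed(seed, "dots"))
  pos <- matrix(numeric(0), ncol = 3)
  tries <- 0L
  while (nrow(pos) < n_dots) {
    cand <- margin + stats::runif(3) * (fov - 2 * margin)
    ok <- nrow(pos) == 0L ||
      min(sqrt(colSums((t(pos) - cand)^2))) >= min_separation_um
    if (ok) {
      pos <- rbind(pos, cand)
    } else {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("could not place ", n_dots, " dots with min separation ",
             min_separation_um, " µm after ", max_tries, " retries")
      }
    }
  }
  dots <- data.frame(z_um = pos[, 1], y_um = pos[, 2], x_um = pos[, 3],
                     amplitude = rep(amplitude, nrow(pos)))
  scene_spec(dim, pixel_size,
             channels = list(
               list(dots = dots, psf_sigma_um = psf_sigma_um),
               list(share = 1L, gain = 1)
             ),
             af = list(amplitude = af_amplitude),
             noise = list(photon_budget = photon_budget,
                          read_noise_sd = read_noise_sd),
             seed = seed)
}

#' Bundled 10-plex embryo-like demo scene
#'
#' Ten fluorophore channels with seeded random ellipsoidal expression
#' domains plus an AF field, on the [hcr10_scheme()] geometry; used by the
#' end-to-end workflow fixture and tests.
#'
#' @param dim,pixel_size Grid shape and voxel size (µm).
#' @param photon_budget,read_noise_sd Noise model.
#' @param seed Master seed.
#' @return A [scene_spec()] with 10 channels.
#' @export
hcr10_demo_scene <- function(dim = c(3L, 64L, 64L),
                             pixel_size = c(1.2, 0.18, 0.18),
                             photon_budget = NULL,
                             read_noise_sd = 0,
                             seed = 1L) {
  fov <- dim * pixel_size
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(derive_seed(seed, "demo"))
  channels <- lapply(1:10, function(c) {
    domains <- lapply(1:3, function(i) {
      center <- stats::runif(3, 0.1, 0.9) * fov
      radii <- c(stats::runif(1, 0.4, 0.9) * fov[1],
                 stats::runif(2, 0.1, 0.3) * fov[2:3])
      list(type = "ellipsoid", center = center, radii = radii,
           amplitude = stats::runif(1, 0.5, 1.5))
    })
    list(domains = domains)
  })
  scene_spec(dim, pixel_size, channels = channels,
             af = list(amplitude = 0.1),
             noise = list(photon_budget = photon_budget,
                          read_noise_sd = read_noise_sd),
             seed = seed)
}

#' Simulate an excitation-emission matrix scan of an AF model
#'
#' @param model A [fluorophore_model()] describing autofluorescence.
#' @param excitations,emissions Scan axes (nm).
#' @return An [eem_scan()].
#' @export
simulate_af_eem <- function(model = hcr10_af_model(),
                            excitations = seq(380, 700, by = 10),
                            emissions = seq(400, 800, by = 5)) {
  ex_eff <- exp(-(excitations - model$excitation_peak)^2 /
                  (2 * model$excitation_width^2))
  em_den <- stats::dnorm(emissions, model$emission_peak, model$emission_width)
  eem_scan(excitations, emissions,
           model$brightness * outer(ex_eff, em_den))
}
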