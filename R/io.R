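#' Write / read spectral and unmixed stacks as multi-page float TIFF
#'
#' Stacks are stored as 32-bit multi-page TIFF (page order: slowest Z,
#' fastest measurement/channel) with a JSON sidecar (`<path>.json`) carrying
#' the axis layout, pixel sizes, acquisition scheme and channel names.
#' Samples are quantized to 32 bits relative to a power-of-two full scale
#' recorded in the sidecar (precision 2^-33 of full scale); writing a stack
#' that was itself read from disk is exactly lossless, so write/read cycles
#' are bit-stable.
#'
#' @param img A [spectral_image()].
#' @param path Output `.tif` path; the sidecar goes to `paste0(path,
#'   ".json")`.
#' @return `write_spectral_stack` returns `path` invisibly.
#' @export
write_spectral_stack <- function(img, path) {
  stopifnot(inherits(img, "spectral_image"))
  write_stack(img$data, path,
              meta = list(kind = "spectral",
                          pixel_size_um = img$pixel_size,
                          scheme = scheme_to_list(img$scheme)))
}

#' @rdname write_spectral_stack
#' @param scheme Expected [acquisition_scheme()]; the stack's channel count
#'   must equal its M.
#' @param pixel_size Override voxel size (z, y, x µm) when the sidecar is
#'   absent.
#' @export
read_spectral_stack <- function(path, scheme, pixel_size = NULL) {
  st <- read_stack(path)
  meta <- st$meta
  dat <- st$data
  if (dim(dat)[4] != scheme$M) {
    stop("stack has ", dim(dat)[4], " channels but scheme expects M = ",
         scheme$M, " measurements")
  }
  if (!is.null(meta$scheme)) {
    d <- scheme_diff(scheme, scheme_from_list(meta$scheme))
    if (!isTRUE(d)) stop("stack scheme differs: ", paste(d, collapse = "; "))
  }
  ps <- if (!is.null(pixel_size)) pixel_size else meta$pixel_size_um
  if (is.null(ps)) {
    stop("no pixel size in sidecar; pass pixel_size explicitly")
  }
  spectral_image(dat, ps, scheme)
}

#' Write an unmixed image (coefficients + residual maps)
#'
#' @param um An [unmixed_image()].
#' @param path Output `.tif` path for the coefficient stack; the residual
#'   map goes to `sub(".tif", "_residual.tif", path)`.
#' @return Invisibly, the coefficient-stack path.
#' @export
write_unmixed_stack <- function(um, path) {
  stopifnot(inherits(um, "unmixed_image"))
  write_stack(um$coefficients, path,
              meta = list(kind = "unmixed",
                          pixel_size_um = um$pixel_size,
                          channel_names = um$channel_names))
  rpath <- sub("\\.tif{1,2}$", "_residual.tif", path)
  write_stack(array(um$residual, c(dim(um$residual), 1L)), rpath,
              meta = list(kind = "residual",
                          pixel_size_um = um$pixel_size))
  invisible(path)
}

#' @rdname write_unmixed_stack
#' @export
read_unmixed_stack <- function(path) {
  st <- read_stack(path)
  rpath <- sub("\\.tif{1,2}$", "_residual.tif", path)
  resid <- if (file.exists(rpath)) {
    r <- read_stack(rpath)$data
    array(r, dim(r)[1:3])
  } else {
    array(0, dim(st$data)[1:3])
  }
  b_dims <- dim(st$data)[1:3]
  unmixed_image(st$data, resid,
                array(0, b_dims),   # relative residual is not persisted
                channel_names = unlist(st$meta$channel_names),
                pixel_size = unlist(st$meta$pixel_size_um))
}

scheme_to_list <- function(scheme) {
  list(excitations = scheme$excitations,
       bands = lapply(scheme$detector_bands, function(b) {
         lapply(seq_len(nrow(b)), function(i) as.numeric(b[i, ]))
       }))
}

scheme_from_list <- function(l) {
  bands <- lapply(l$bands, function(bb) {
    do.call(rbind, lapply(bb, function(b) as.numeric(unlist(b))))
  })
  acquisition_scheme(as.numeric(unlist(l$excitations)), bands)
}

# internal: (Z,Y,X,K) array <-> multi-page 32-bit TIFF + JSON sidecar.
# Samples are stored as 32-bit integers k = round(v / scale * 2^32) with a
# power-of-two scale recorded in the sidecar; the reader reconstructs
# k / 2^32 * scale. Quantization is 2^-33 of full scale, and re-writing a
# read stack is exactly idempotent. (The underlying TIFF writer truncates
# u * (2^32 - 1), so we hand it (k + 0.5) / (2^32 - 1), which truncates to
# exactly k.)
write_stack <- function(arr, path, meta = list()) {
  stopifnot(length(dim(arr)) == 4L)
  d <- dim(arr)
  mx <- max(arr, 0)
  scale <- if (mx <= 0) 1 else 2^ceiling(log2(mx) + 1e-12)
  pages <- vector("list", d[1] * d[4])
  p <- 1L
  for (z in seq_len(d[1])) {
    for (k in seq_len(d[4])) {
      u <- pmin(pmax(matrix(arr[z, , , k], d[2], d[3]) / scale, 0), 1)
      ki <- pmin(round(u * 2^32), 2^32 - 1)
      pages[[p]] <- pmin((ki + 0.5) / (2^32 - 1), 1)
      p <- p + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta$dim <- d
  meta$scale <- scale
  meta$page_order <- "z_slow_channel_fast"
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  n <- length(pages)
  if (!is.null(meta$dim)) {
    d <- as.integer(unlist(meta$dim))
    if (d[1] * d[4] != n) stop("sidecar page count mismatch for ", path)
  } else {
    d <- c(1L, dim(pages[[1]])[1], dim(pages[[1]])[2], n)
  }
  scale <- if (!is.null(meta$scale)) as.numeric(meta$scale) else 1
  arr <- array(0, d)
  p <- 1L
  for (z in seq_len(d[1])) {
    for (k in seq_len(d[4])) {
      arr[z, , , k] <- pages[[p]] * scale
      p <- p + 1L
    }
  }
  list(data = arr, meta = meta)
}

# ---- bundled synthetic fixture inputs ----------------------------------

#' Generate the bundled 10-plex synthetic input set
#'
#' Produces what a 10-plex experiment acquires: ten 1-plex reference images
#' (one fluorophore each, no AF so the extracted spectrum is pure), one
#' unlabeled AF image, and the 10-plex sample image (all channels plus AF),
#' all on [hcr10_scheme()].
#'
#' @param seed Master seed.
#' @param dim,pixel_size Grid geometry of all images.
#' @param photon_budget,read_noise_sd Noise model of the 10-plex image
#'   (references are rendered noise-free).
#' @return List with `oneplex` (named list of [spectral_image()]),
#'   `af_image`, `image` (the 10-plex [spectral_image()]), `truth`
#'   (abundance array of the 10-plex scene), `scheme`, `true_matrix`
#'   (the noise-free [hcr10_reference_matrix()]).
#' @export
hcr10_fixture_inputs <- function(seed = 1L,
                                 dim = c(3L, 48L, 48L),
                                 pixel_size = c(1.2, 0.18, 0.18),
                                 photon_budget = NULL,
                                 read_noise_sd = 0) {
  scheme <- hcr10_scheme()
  fl <- hcr10_fluorophores()
  afs <- hcr10_af_spectrum(scheme)
  fov <- dim * pixel_size
  oneplex <- lapply(seq_along(fl), function(c) {
    sc <- scene_spec(dim, pixel_size,
                     channels = list(list(domains = list(
                       list(type = "box", lo = 0.25 * fov, hi = 0.75 * fov,
                            amplitude = 1)))),
                     af = list(amplitude = 0),
                     seed = derive_seed(seed, paste0("oneplex", c)))
    render_spectral_image(sc, fl[c], NULL, scheme)$image
  })
  names(oneplex) <- vapply(fl, function(f) f$name, "")
  af_scene <- scene_spec(dim, pixel_size,
                         channels = list(list(domains = list())),
                         af = list(amplitude = 1),
                         seed = derive_seed(seed, "af"))
  af_image <- render_spectral_image(af_scene, fl[1], afs, scheme)$image
  mscene <- hcr10_demo_scene(dim = dim, pixel_size = pixel_size,
                             photon_budget = photon_budget,
                             read_noise_sd = read_noise_sd, seed = seed)
  rendered <- render_spectral_image(mscene, fl, afs, scheme)
  list(oneplex = oneplex, af_image = af_image, image = rendered$image,
       truth = rendered$truth, scheme = scheme,
       true_matrix = hcr10_reference_matrix(scheme))
}

# ---- end-to-end workflow ------------------------------------------------

#' Run the full spectral-imaging workflow
#'
#' Reference extraction (ten 1-plex images plus an unlabeled AF image) ->
#' reference-matrix build with conditioning diagnostics -> per-pixel linear
#' unmixing -> optional qHCR voxel statistics and dHCR dot detection /
#' colocalization, with all outputs written to an output directory:
#' `references.csv`, `condition_report.json`, `unmixed.tif` (+ sidecar and
#' residual map), optional `voxels.csv`, `scatter_stats.csv`, per-channel
#' dot CSVs and `colocalization.csv`, and a `run_report.json` recording
#' package version, seed, parameters and collected warnings. Rerunning with
#' the same config and inputs reproduces all outputs bit-exactly.
#'
#' @param config A named list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{output_dir}{Directory for outputs (created).}
#'     \item{seed}{Master seed (default 1).}
#'     \item{use_fixture}{If TRUE, inputs come from
#'       [hcr10_fixture_inputs()] (with optional `fixture` sub-list:
#'       `dim`, `photon_budget`, `read_noise_sd`).}
#'     \item{paths}{Otherwise: `oneplex` (character vector of ten stack
#'       paths), `af`, `image`; plus `scheme` (YAML path).}
#'     \item{top_fraction}{Reference-selection fraction (default 0.001).}
#'     \item{qhcr}{Optional: list(`channel_a`, `channel_b`,
#'       `voxel_size_um`, `quantile`).}
#'     \item{dots}{Optional: list(`channels`, `scales_um`, `threshold`,
#'       `radius_um`).}
#'   }
#'   Unknown top-level keys are an error.
#' @return Invisibly, a list with the in-memory results (`reference_matrix`,
#'   `condition`, `unmixed`, and stage outputs) plus `report`.
#' @export
run_workflow <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("output_dir", "seed", "use_fixture", "fixture", "paths",
             "top_fraction", "qhcr", "dots")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$output_dir)) stop("config needs output_dir")
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  top_fraction <- if (is.null(config$top_fraction)) 0.001 else
    config$top_fraction
  warnings_seen <- character(0)
  collect <- function(expr, stage) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop("stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen,
                            paste0(stage, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  # --- inputs
  inputs <- collect({
    if (isTRUE(config$use_fixture)) {
      fx <- config$fixture
      do.call(hcr10_fixture_inputs, c(list(seed = seed), fx))
    } else {
      p <- config$paths
      if (is.null(p$oneplex) || is.null(p$af) || is.null(p$image)) {
        stop("paths must provide oneplex, af and image")
      }
      scheme <- read_scheme_yaml(p$scheme)
      oneplex <- lapply(p$oneplex, read_spectral_stack, scheme = scheme)
      names(oneplex) <- if (!is.null(names(p$oneplex))) names(p$oneplex)
      else paste0("Ch", seq_along(oneplex))
      list(oneplex = oneplex,
           af_image = read_spectral_stack(p$af, scheme),
           image = read_spectral_stack(p$image, scheme),
           scheme = scheme)
    }
  }, "inputs")

  # --- reference spectra + conditioning
  refmat <- collect(
    build_reference_matrix(inputs$oneplex, inputs$af_image,
                           top_fraction = top_fraction),
    "refspec")
  cond <- collect(condition_report(refmat), "condition")
  write_reference_csv(refmat, file.path(out_dir, "references.csv"))
  jsonlite::write_json(
    list(condition_number = cond$condition_number,
         min_angle_deg = cond$min_angle_deg,
         worst_pair = cond$worst_pair, warn = cond$warn),
    file.path(out_dir, "condition_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (cond$warn) {
    warnings_seen <- c(warnings_seen, paste0(
      "condition: reference columns nearly collinear (min angle ",
      signif(cond$min_angle_deg, 3), " deg)"))
  }

  # --- unmix
  um <- collect(unmix_image(inputs$image, refmat), "unmix")
  write_unmixed_stack(um, file.path(out_dir, "unmixed.tif"))

  results <- list(reference_matrix = refmat, condition = cond, unmixed = um)

  # --- optional qHCR voxel statistics
  if (!is.null(config$qhcr)) {
    q <- config$qhcr
    results$voxels <- collect(
      bin_voxels(um, unlist(q$voxel_size_um)), "qhcr")
    write_voxel_csv(results$voxels, file.path(out_dir, "voxels.csv"))
    results$scatter <- collect(
      qhcr_scatter_stats(results$voxels, q$channel_a, q$channel_b,
                         quantile = if (is.null(q$quantile)) 0.999
                         else q$quantile),
      "qhcr")
    utils::write.csv(
      data.frame(channel_a = q$channel_a, channel_b = q$channel_b,
                 pearson_r = results$scatter$pearson_r,
                 slope_through_origin = results$scatter$slope_through_origin,
                 slope = results$scatter$slope,
                 intercept = results$scatter$intercept,
                 n_voxels = results$scatter$n_voxels),
      file.path(out_dir, "scatter_stats.csv"), row.names = FALSE)
  }

  # --- optional dHCR dot detection + colocalization
  if (!is.null(config$dots)) {
    dc <- config$dots
    chans <- unlist(dc$channels)
    dots <- collect(lapply(chans, function(ch) {
      j <- match(ch, um$channel_names)
      if (is.na(j)) stop("dot channel not in unmixed image: ", ch)
      detect_dots(array(um$coefficients[, , , j],
                        dim(um$coefficients)[1:3]),
                  um$pixel_size, unlist(dc$scales_um), dc$threshold,
                  channel = ch)
    }), "dots")
    names(dots) <- chans
    for (ch in chans) {
      write_dots_csv(dots[[ch]],
                     file.path(out_dir, paste0("dots_", ch, ".csv")))
    }
    results$dots <- dots
    if (length(chans) == 2L) {
      results$coloc <- collect(
        colocalize(dots[[1]], dots[[2]], radius_um = dc$radius_um), "coloc")
      utils::write.csv(
        data.frame(channel_a = chans[1], channel_b = chans[2],
                   fraction_a = results$coloc$fraction_a,
                   fraction_b = results$coloc$fraction_b,
                   n_pairs = nrow(results$coloc$pairs),
                   radius_um = results$coloc$radius_um),
        file.path(out_dir, "colocalization.csv"), row.names = FALSE)
    }
  }

  report <- list(
    package = "specmix",
    version = as.character(utils::packageVersion("specmix")),
    seed = seed,
    parameters = config[setdiff(names(config), "output_dir")],
    n_channels = length(refmat$channel_names),
    channel_names = refmat$channel_names,
    mean_relative_residual = mean(um$relative_residual),
    warnings = warnings_seen)
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$report <- report
  invisible(results)
}
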