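#' Reference spectrum of one unmixing channel
#'
#' The measurement vector of a single fluorophore (or of autofluorescence)
#' across all (excitation, detector) combinations of a scheme, normalized so
#' its maximum detector reading equals 1. With this convention the unmixed
#' coefficient of a channel is on the same intensity scale as the raw image.
#'
#' @param channel_name Channel label.
#' @param intensities Numeric M-vector, all finite and >= 0, not all zero.
#' @param scheme The [acquisition_scheme()] the vector is aligned to.
#' @return Object of class `reference_spectrum` with fields `channel_name`,
#'   `intensities` (max = 1) and `normalization = "max1"`.
#' @export
reference_spectrum <- function(channel_name, intensities, scheme) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  intensities <- as.numeric(intensities)
  if (length(intensities) != scheme$M) {
    stop("spectrum length ", length(intensities),
         " does not match scheme M = ", scheme$M)
  }
  if (any(!is.finite(intensities))) stop("spectrum has non-finite entries")
  if (any(intensities < 0)) stop("spectrum has negative entries")
  mx <- max(intensities)
  if (mx == 0) stop("degenerate reference: spectrum is all zero")
  structure(list(channel_name = as.character(channel_name),
                 intensities = intensities / mx,
                 normalization = "max1",
                 scheme = scheme),
            class = "reference_spectrum")
}

#' Reference matrix for linear unmixing
#'
#' Binds reference spectra into the M x C matrix `R` of the per-pixel model
#' `b ~ R x, x >= 0`. Fluorophore channels come first, followed by one or
#' more autofluorescence (AF) channels.
#'
#' @param spectra List of [reference_spectrum()] objects on one scheme, in
#'   channel order (fluorophores first, then AF).
#' @param n_af Number of trailing AF channels (>= 0).
#' @return Object of class `reference_matrix` with fields `R` (M x C matrix,
#'   columns named), `scheme`, `channel_names`, `n_af`.
#' @export
reference_matrix <- function(spectra, n_af = 1L) {
  if (length(spectra) < 1L) stop("need at least one reference spectrum")
  scheme <- spectra[[1]]$scheme
  for (s in spectra) {
    if (!inherits(s, "reference_spectrum")) {
      stop("all columns must be reference_spectrum objects")
    }
    d <- scheme_diff(scheme, s$scheme)
    if (!isTRUE(d)) stop("spectra are on different schemes: ", d[1])
  }
  names <- vapply(spectra, function(s) s$channel_name, "")
  if (anyDuplicated(names)) {
    stop("duplicate channel names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  if (n_af < 0L || n_af > length(spectra)) stop("invalid n_af")
  R <- vapply(spectra, function(s) s$intensities, numeric(scheme$M))
  R <- matrix(R, nrow = scheme$M, dimnames = list(NULL, names))
  structure(list(R = R, scheme = scheme, channel_names = names,
                 n_af = as.integer(n_af)),
            class = "reference_matrix")
}

#' @export
print.reference_matrix <- function(x, ...) {
  cat("Reference matrix:", nrow(x$R), "measurements x", ncol(x$R),
      "channels (", x$n_af, "AF )\n")
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Extract a reference spectrum from a 1-plex (or unlabeled) image
#'
#' Operationalizes "region of maximum expression": by default the pixels
#' whose summed-over-measurements intensity lies in the top 0.1% are
#' selected, their M-vectors averaged, and the mean normalized to max 1.
#' An explicit logical/integer mask over (Z,Y,X) overrides the quantile
#' selection (e.g. an anatomical region).
#'
#' The result is invariant to rescaling the input image by any positive
#' scalar, since the normalization cancels it.
#'
#' @param image A [spectral_image()].
#' @param channel_name Label for the resulting spectrum.
#' @param top_fraction Fraction of brightest pixels to average (in (0, 1)).
#' @param mask Optional logical array (Z,Y,X) or integer index vector into
#'   the flattened (Z,Y,X) grid; overrides `top_fraction`.
#' @return A [reference_spectrum()].
#' @export
extract_reference_spectrum <- function(image, channel_name = "Ch",
                                       top_fraction = 0.001, mask = NULL) {
  stopifnot(inherits(image, "spectral_image"))
  M <- image$scheme$M
  n_pix <- prod(dim(image$data)[1:3])
  B <- matrix(image$data, nrow = n_pix)     # pixels x M
  if (!is.null(mask)) {
    idx <- if (is.logical(mask)) which(as.vector(mask)) else as.integer(mask)
    if (length(idx) == 0L) stop("degenerate reference: empty mask")
  } else {
    if (top_fraction <= 0 || top_fraction >= 1) {
      stop("top_fraction must be in (0, 1)")
    }
    totals <- rowSums(B)
    k <- max(1L, ceiling(top_fraction * n_pix))
    idx <- order(totals, decreasing = TRUE)[seq_len(k)]
  }
  m <- colMeans(B[idx, , drop = FALSE])
  if (max(m) == 0) stop("degenerate reference: selected pixels are all zero")
  reference_spectrum(channel_name, m, image$scheme)
}

#' Build a reference matrix from 1-plex images plus an AF image
#'
#' Runs [extract_reference_spectrum()] on each 1-plex fluorophore image and
#' on the unlabeled AF image, and binds the results into a
#' [reference_matrix()] (fluorophores first, AF last).
#'
#' @param oneplex_images Named list of [spectral_image()], one per
#'   fluorophore channel.
#' @param af_image [spectral_image()] of an unlabeled sample, or `NULL` for
#'   a matrix without an AF channel.
#' @param top_fraction Passed to [extract_reference_spectrum()].
#' @param af_name Name for the AF channel.
#' @return A [reference_matrix()].
#' @export
build_reference_matrix <- function(oneplex_images, af_image = NULL,
                                   top_fraction = 0.001, af_name = "AF") {
  nm <- names(oneplex_images)
  if (is.null(nm)) nm <- paste0("Ch", seq_along(oneplex_images))
  spectra <- Map(function(img, name) {
    extract_reference_spectrum(img, name, top_fraction = top_fraction)
  }, oneplex_images, nm)
  n_af <- 0L
  if (!is.null(af_image)) {
    spectra <- c(spectra,
                 list(extract_reference_spectrum(af_image, af_name,
                                                 top_fraction = top_fraction)))
    n_af <- 1L
  }
  reference_matrix(unname(spectra), n_af = n_af)
}

#' Excitation-emission matrix scan
#'
#' Fluorescence intensity measured on a grid of excitation and emission
#' wavelengths; used to place the autofluorescence channel.
#'
#' @param excitations,emissions Axis wavelengths (nm).
#' @param intensity Matrix `length(excitations) x length(emissions)` of
#'   non-negative intensities.
#' @return Object of class `eem_scan`.
#' @export
eem_scan <- function(excitations, emissions, intensity) {
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != length(excitations) ||
      ncol(intensity) != length(emissions)) {
    stop("intensity matrix dims must match excitation x emission axes")
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("EEM intensities must be finite and >= 0")
  }
  structure(list(excitations = as.numeric(excitations),
                 emissions = as.numeric(emissions),
                 intensity = intensity),
            class = "eem_scan")
}

#' Choose the autofluorescence excitation and detector bands from an EEM scan
#'
#' Picks the excitation wavelength whose total emission (summed over
#' emissions red of the excitation plus a guard offset) is maximal, then
#' lays out `n_detectors` contiguous equal-width bands covering the red-of-
#' excitation emission range. Ties are broken toward the shortest
#' wavelength.
#'
#' @param scan An [eem_scan()].
#' @param n_detectors Number of AF detector bands (default 4).
#' @param guard Offset in nm between the excitation line and the first
#'   detector band (default 10).
#' @return List with `af_excitation` (nm), `bands` (n x 2 matrix), and
#'   `scores` (per-excitation total emission used for the argmax).
#' @export
optimize_af_channel <- function(scan, n_detectors = 4L, guard = 10) {
  stopifnot(inherits(scan, "eem_scan"), n_detectors >= 1L)
  if (all(scan$intensity == 0)) stop("no autofluorescence detected")
  scores <- vapply(seq_along(scan$excitations), function(i) {
    keep <- scan$emissions >= scan$excitations[i] + guard
    sum(scan$intensity[i, keep])
  }, 0)
  best <- which(scores == max(scores))[1]   # ties -> shortest wavelength
  ex <- scan$excitations[best]
  lo <- ex + guard
  hi <- max(scan$emissions)
  if (hi <= lo) stop("emission range does not extend red of the excitation")
  edges <- seq(lo, hi, length.out = n_detectors + 1)
  bands <- cbind(start = edges[-length(edges)], end = edges[-1])
  list(af_excitation = ex, bands = bands, scores = scores)
}

#' Conditioning diagnostics for a reference matrix
#'
#' Reports how ill-posed unmixing against `R` would be: the 2-norm condition
#' number, the pairwise cosine similarity of columns, and the minimum
#' pairwise angle. A warning flag is raised when any two columns are closer
#' than `min_angle_deg` apart (near-collinear references make coefficients
#' unstable). Purely diagnostic; never mutates the matrix.
#'
#' @param R A [reference_matrix()] or plain M x C matrix.
#' @param min_angle_deg Warning threshold on the minimum pairwise angle
#'   (degrees, default 5).
#' @return List with `condition_number`, `cosine_similarity` (C x C),
#'   `min_angle_deg`, `worst_pair` (character length 2), `warn` (logical).
#' @export
condition_report <- function(R, min_angle_deg = 5) {
  mat <- if (inherits(R, "reference_matrix")) R$R else as.matrix(R)
  sv <- svd(mat, nu = 0, nv = 0)$d
  cond <- if (min(sv) == 0) Inf else max(sv) / min(sv)
  norms <- sqrt(colSums(mat^2))
  if (any(norms == 0)) stop("reference matrix has an all-zero column")
  U <- sweep(mat, 2, norms, "/")
  cosine <- crossprod(U)
  cosine <- pmin(pmax(cosine, -1), 1)
  C <- ncol(mat)
  min_angle <- 90
  worst <- c(NA_character_, NA_character_)
  if (C >= 2) {
    ang <- acos(cosine) * 180 / pi
    diag(ang) <- NA
    min_angle <- min(ang, na.rm = TRUE)
    w <- which(ang == min_angle, arr.ind = TRUE)[1, ]
    nm <- colnames(mat)
    if (is.null(nm)) nm <- paste0("col", seq_len(C))
    worst <- nm[w]
  }
  list(condition_number = cond,
       cosine_similarity = cosine,
       min_angle_deg = min_angle,
       worst_pair = worst,
       warn = min_angle < min_angle_deg)
}

#' Read / write reference spectra as CSV
#'
#' Long format with one row per (channel, measurement): columns `channel`,
#' `excitation_nm`, `band_start_nm`, `band_end_nm`, `intensity`.
#'
#' @param R A [reference_matrix()].
#' @param path Output CSV path.
#' @return `write_reference_csv` returns `path` invisibly;
#'   `read_reference_csv` returns a [reference_matrix()].
#' @export
write_reference_csv <- function(R, path) {
  stopifnot(inherits(R, "reference_matrix"))
  mt <- measurement_table(R$scheme)
  rows <- do.call(rbind, lapply(seq_along(R$channel_names), function(j) {
    data.frame(channel = R$channel_names[j],
               excitation_nm = mt$excitation_nm,
               band_start_nm = mt$band_start_nm,
               band_end_nm = mt$band_end_nm,
               intensity = R$R[, j])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_csv
#' @param scheme The [acquisition_scheme()] the CSV is aligned to.
#' @param n_af Number of trailing AF channels in the file.
#' @export
read_reference_csv <- function(path, scheme, n_af = 1L) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel", "excitation_nm", "band_start_nm", "band_end_nm",
            "intensity")
  if (!all(need %in% names(d))) {
    stop("reference CSV must have columns: ", paste(need, collapse = ", "))
  }
  chans <- unique(d$channel)
  spectra <- lapply(chans, function(ch) {
    sub <- d[d$channel == ch, ]
    if (nrow(sub) != scheme$M) {
      stop("channel ", ch, " has ", nrow(sub), " rows, scheme M = ",
           scheme$M)
    }
    reference_spectrum(ch, sub$intensity, scheme)
  })
  reference_matrix(spectra, n_af = n_af)
}

#' Noise-free reference matrix of the bundled 10-plex fixture
#'
#' Predicted responses of the ten [hcr10_fluorophores()] plus the
#' [hcr10_af_spectrum()] on [hcr10_scheme()], each normalized to max 1.
#'
#' @param scheme Scheme to evaluate on (default [hcr10_scheme()]).
#' @return An 11-column [reference_matrix()].
#' @export
hcr10_reference_matrix <- function(scheme = hcr10_scheme()) {
  fl <- hcr10_fluorophores()
  spectra <- lapply(fl, function(f) {
    reference_spectrum(f$name, predict_response(f, scheme), scheme)
  })
  spectra <- c(spectra,
               list(reference_spectrum("AF", hcr10_af_spectrum(scheme),
                                       scheme)))
  reference_matrix(spectra, n_af = 1L)
}
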