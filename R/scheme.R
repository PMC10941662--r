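#' Acquisition scheme for multi-excitation spectral imaging
#'
#' An acquisition scheme describes the measurement axis of a spectral
#' (lambda-stack) experiment: an ordered set of excitation laser lines, each
#' paired with one or more detector emission bands. Every (excitation,
#' detector-band) pair contributes one measurement per pixel, so a scheme with
#' excitations \eqn{e_1 < \dots < e_K} and \eqn{n_k} detectors per excitation
#' yields an M-dimensional pixel spectrum with \eqn{M = \sum_k n_k}.
#'
#' @param excitations Numeric vector of excitation wavelengths in nm,
#'   strictly increasing.
#' @param detector_bands List of length `length(excitations)`; element k is a
#'   two-column matrix (or data.frame) of emission band `start`/`end`
#'   wavelengths in nm for excitation k. Each excitation must carry between
#'   1 and 4 bands, every band must satisfy `start < end`, and no band may
#'   start blue of its excitation line.
#'
#' @return An object of class `acquisition_scheme` with fields
#'   `excitations`, `detector_bands` and the measurement dimension `M`.
#' @examples
#' sch <- acquisition_scheme(
#'   c(488, 561),
#'   list(rbind(c(500, 540), c(545, 585)), rbind(c(575, 630)))
#' )
#' sch$M  # 3
#' @export
acquisition_scheme <- function(excitations, detector_bands) {
  excitations <- as.numeric(excitations)
  if (length(excitations) < 1L) {
    stop("acquisition scheme needs at least one excitation wavelength")
  }
  if (any(diff(excitations) <= 0)) {
    stop("excitation wavelengths must be strictly increasing")
  }
  if (!is.list(detector_bands) ||
      length(detector_bands) != length(excitations)) {
    stop("detector_bands must be a list with one element per excitation")
  }
  detector_bands <- lapply(detector_bands, function(b) {
    b <- as.matrix(b)
    storage.mode(b) <- "double"
    if (ncol(b) != 2L) stop("each detector band needs start and end columns")
    colnames(b) <- c("start", "end")
    b
  })
  counts <- vapply(detector_bands, nrow, integer(1))
  if (any(counts < 1L) || any(counts > 4L)) {
    stop("each excitation must have between 1 and 4 detector bands")
  }
  for (k in seq_along(excitations)) {
    b <- detector_bands[[k]]
    if (any(b[, "start"] >= b[, "end"])) {
      stop("detector band start must be < end (excitation ",
           excitations[k], " nm)")
    }
    if (any(b[, "start"] < excitations[k])) {
      stop("detector band must not start blue of its excitation line (",
           excitations[k], " nm)")
    }
  }
  structure(
    list(excitations = excitations,
         detector_bands = detector_bands,
         M = sum(counts)),
    class = "acquisition_scheme"
  )
}

#' Flat table of the measurement axis
#'
#' Expands an acquisition scheme into one row per (excitation, detector band)
#' measurement, in acquisition order.
#'
#' @param scheme An [acquisition_scheme()].
#' @return A data.frame with columns `index`, `excitation_nm`,
#'   `band_start_nm`, `band_end_nm`.
#' @export
measurement_table <- function(scheme) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  rows <- do.call(rbind, lapply(seq_along(scheme$excitations), function(k) {
    b <- scheme$detector_bands[[k]]
    data.frame(excitation_nm = scheme$excitations[k],
               band_start_nm = b[, "start"],
               band_end_nm = b[, "end"])
  }))
  rows <- cbind(index = seq_len(nrow(rows)), rows)
  rownames(rows) <- NULL
  rows
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat("Acquisition scheme:", length(x$excitations), "excitations,",
      x$M, "detector measurements\n")
  for (k in seq_along(x$excitations)) {
    b <- x$detector_bands[[k]]
    cat(sprintf("  %g nm: %s\n", x$excitations[k],
                paste(sprintf("[%g-%g]", b[, 1], b[, 2]), collapse = " ")))
  }
  invisible(x)
}

#' Compare two acquisition schemes
#'
#' @param a,b Acquisition schemes.
#' @return `TRUE` if the schemes have identical excitations and bands,
#'   otherwise a character vector describing the differences.
#' @export
scheme_diff <- function(a, b) {
  msgs <- character(0)
  if (!isTRUE(all.equal(a$excitations, b$excitations))) {
    msgs <- c(msgs, paste0("excitations differ: [",
                           paste(a$excitations, collapse = ","), "] vs [",
                           paste(b$excitations, collapse = ","), "]"))
  }
  if (length(a$excitations) == length(b$excitations)) {
    for (k in seq_along(a$excitations)) {
      if (!isTRUE(all.equal(a$detector_bands[[k]], b$detector_bands[[k]]))) {
        msgs <- c(msgs, paste0("detector bands differ at excitation ",
                               a$excitations[k], " nm"))
      }
    }
  }
  if (length(msgs) == 0L) TRUE else msgs
}

#' Contiguous equal-width detector bands
#'
#' Helper that lays out `n` contiguous equal-width emission bands starting a
#' guard offset red of the excitation line.
#'
#' @param excitation Excitation wavelength (nm).
#' @param n Number of bands.
#' @param width Width of each band (nm).
#' @param guard Offset between the excitation line and the first band (nm).
#' @return Two-column matrix of band starts and ends.
#' @export
contiguous_bands <- function(excitation, n, width = 35, guard = 10) {
  starts <- excitation + guard + width * (seq_len(n) - 1)
  cbind(start = starts, end = starts + width)
}

#' The bundled 11-excitation / 26-detector scheme
#'
#' The default acquisition geometry used by the simulator fixtures: 11
#' excitation lines between 400 and 770 nm, each followed by between one and
#' four contiguous detector bands, for a total of 26 (excitation, detector)
#' measurements spanning the visible to near-IR emission range.
#'
#' @return An [acquisition_scheme()] with `M = 26`.
#' @export
hcr10_scheme <- function() {
  excitations <- c(400, 405, 441, 482, 523, 564, 605, 646, 687, 728, 770)
  n_bands <- c(4L, 3L, 3L, 3L, 2L, 2L, 2L, 2L, 2L, 2L, 1L)
  bands <- Map(contiguous_bands, excitations, n_bands)
  acquisition_scheme(excitations, bands)
}

#' Read / write an acquisition scheme as YAML
#'
#' The YAML layout is a list of excitation entries, each with
#' `excitation_nm` and a `bands` list of `[start, end]` pairs.
#'
#' @param path File path.
#' @return `read_scheme_yaml` returns an [acquisition_scheme()];
#'   `write_scheme_yaml` returns `path` invisibly.
#' @export
read_scheme_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$excitations)) stop("scheme YAML lacks an 'excitations' list")
  ex <- vapply(y$excitations, function(e) as.numeric(e$excitation_nm), 0)
  bands <- lapply(y$excitations, function(e) {
    do.call(rbind, lapply(e$bands, function(b) as.numeric(unlist(b))))
  })
  acquisition_scheme(ex, bands)
}

#' @rdname read_scheme_yaml
#' @param scheme An [acquisition_scheme()].
#' @export
write_scheme_yaml <- function(scheme, path) {
  y <- list(excitations = lapply(seq_along(scheme$excitations), function(k) {
    b <- scheme$detector_bands[[k]]
    list(excitation_nm = scheme$excitations[k],
         bands = lapply(seq_len(nrow(b)), function(i) as.numeric(b[i, ])))
  }))
  yaml::write_yaml(y, path)
  invisible(path)
}
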