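#' Spectral image stack
#'
#' A (Z, Y, X, M) array of non-negative intensities with physical voxel
#' sizes and the acquisition scheme that defines its measurement axis M.
#' Negative raw intensities (detector offset artifacts) are clamped to zero
#' with a warning.
#'
#' @param data Numeric array, either (Z, Y, X, M) or (Y, X, M) which is
#'   promoted to Z = 1.
#' @param pixel_size Voxel size in µm, `c(z, y, x)`, all > 0.
#' @param scheme An [acquisition_scheme()]; `dim(data)[4]` must equal its M.
#' @return Object of class `spectral_image`.
#' @export
spectral_image <- function(data, pixel_size, scheme) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  if (length(dim(data)) == 3L) {
    data <- array(data, c(1L, dim(data)))
  }
  if (length(dim(data)) != 4L) {
    stop("spectral image data must be a (Z,Y,X,M) array")
  }
  if (dim(data)[4] != scheme$M) {
    stop("image has ", dim(data)[4], " measurement channels but scheme M = ",
         scheme$M)
  }
  if (length(pixel_size) != 3L || any(pixel_size <= 0)) {
    stop("pixel_size must be three positive values (z, y, x) in µm")
  }
  if (any(!is.finite(data))) stop("image contains non-finite intensities")
  n_neg <- sum(data < 0)
  if (n_neg > 0) {
    warning(n_neg, " negative intensities clamped to 0 (detector offset?)")
    data[data < 0] <- 0
  }
  structure(list(data = data, pixel_size = as.numeric(pixel_size),
                 scheme = scheme),
            class = "spectral_image")
}

#' @export
print.spectral_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Spectral image: Z=%d Y=%d X=%d, M=%d measurements, %s µm/px\n",
              d[1], d[2], d[3], d[4],
              paste(signif(x$pixel_size, 3), collapse = " x ")))
  invisible(x)
}

#' Non-negative least squares by Lawson-Hanson active set
#'
#' Solves `min ||R x - b||_2 subject to x >= 0` exactly (to numerical
#' precision) for the small systems of spectral unmixing (M up to ~26
#' measurements, C up to ~12 channels). Variables move between an active
#' (zero) set and a passive set; at each step the variable with the largest
#' positive gradient joins the passive set, an unconstrained least-squares
#' problem is solved on that set, and any variables driven negative are
#' stepped back to the boundary. Terminates at the KKT point, which for this
#' convex problem is the global minimum.
#'
#' @param b Numeric M-vector of measured intensities (finite).
#' @param R A [reference_matrix()] or plain M x C matrix.
#' @param tol Gradient tolerance for the KKT test; default scales with the
#'   problem magnitude.
#' @return List with `x` (C-vector, >= 0, named when R has column names)
#'   and `residual` (the Euclidean norm of `R x - b`).
#' @export
solve_nnls <- function(b, R, tol = NULL) {
  A <- if (inherits(R, "reference_matrix")) R$R else as.matrix(R)
  b <- as.numeric(b)
  if (length(b) != nrow(A)) {
    stop("b has length ", length(b), ", reference matrix has ", nrow(A),
         " rows")
  }
  if (any(!is.finite(b))) stop("b contains non-finite values")
  fit <- nnls_core(crossprod(A), crossprod(A, b), tol = tol)
  x <- fit$x
  names(x) <- colnames(A)
  r <- A %*% x - b
  list(x = x, residual = sqrt(sum(r * r)))
}

# Lawson-Hanson on the normal equations: minimize x'Gx/2 - x'h, x >= 0,
# with G = R'R (C x C) and h = R'b. Working on the Gram matrix makes the
# per-pixel cost independent of M after a one-off crossprod.
nnls_core <- function(G, h, tol = NULL) {
  C <- length(h)
  if (is.null(tol)) tol <- 1e-10 * max(abs(h), 1)
  x <- numeric(C)
  passive <- rep(FALSE, C)
  w <- h                                   # negative gradient at x = 0
  iter <- 0L
  max_iter <- 30L * max(C, 1L)
  while (iter < max_iter) {
    cand <- which(!passive & w > tol)
    if (length(cand) == 0L) break
    iter <- iter + 1L
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      P <- which(passive)
      z <- numeric(C)
      z[P] <- solve(G[P, P, drop = FALSE], h[P])
      if (all(z[P] > 0)) {
        x <- z
        break
      }
      # step from x toward z until the first passive variable hits zero
      neg <- P[z[P] <= 0]
      denom <- x[neg] - z[neg]
      ratios <- ifelse(denom > 0, x[neg] / denom, 0)
      alpha <- min(ratios)
      x <- x + alpha * (z - x)
      x[neg[ratios <= alpha]] <- 0
      passive[P[x[P] <= 0]] <- FALSE
      x[!passive] <- 0
    }
    w <- h - as.vector(G %*% x)
  }
  list(x = x, iterations = iter)
}

#' Unmixed multichannel image
#'
#' @param coefficients (Z, Y, X, C) array of non-negative unmixed channel
#'   coefficients.
#' @param residual (Z, Y, X) array of per-pixel Euclidean misfit norms.
#' @param relative_residual (Z, Y, X) array of residual / ||b|| (0 when
#'   b = 0); a unitless QC map.
#' @param channel_names Ordered labels, AF channel(s) last.
#' @param pixel_size Voxel size (z, y, x) in µm.
#' @return Object of class `unmixed_image`.
#' @export
unmixed_image <- function(coefficients, residual, relative_residual,
                          channel_names, pixel_size) {
  stopifnot(length(dim(coefficients)) == 4L,
            all(dim(coefficients)[1:3] == dim(residual)),
            dim(coefficients)[4] == length(channel_names))
  structure(list(coefficients = coefficients, residual = residual,
                 relative_residual = relative_residual,
                 channel_names = channel_names,
                 pixel_size = as.numeric(pixel_size)),
            class = "unmixed_image")
}

#' @export
print.unmixed_image <- function(x, ...) {
  d <- dim(x$coefficients)
  cat(sprintf("Unmixed image: Z=%d Y=%d X=%d, %d channels (%s)\n",
              d[1], d[2], d[3], d[4],
              paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  mean residual %.4g, mean relative residual %.4g\n",
              mean(x$residual), mean(x$relative_residual)))
  invisible(x)
}

#' Linearly unmix a spectral image
#'
#' Applies [solve_nnls()] to every pixel's M-vector against the reference
#' matrix, yielding one non-negative coefficient channel per reference
#' column plus a per-pixel residual norm. Pixels are processed in chunks
#' purely for memory locality; chunking is bit-identical to a per-pixel
#' loop because every pixel is solved independently.
#'
#' @param img A [spectral_image()].
#' @param R A [reference_matrix()] on the same scheme.
#' @param chunk_size Pixels per chunk (default 4096).
#' @return An [unmixed_image()] carrying the reference channel names and
#'   the input's pixel sizes.
#' @export
unmix_image <- function(img, R, chunk_size = 4096L) {
  stopifnot(inherits(img, "spectral_image"),
            inherits(R, "reference_matrix"))
  d <- scheme_diff(img$scheme, R$scheme)
  if (!isTRUE(d)) {
    stop("image and reference matrix schemes differ: ",
         paste(d, collapse = "; "))
  }
  A <- R$R
  C <- ncol(A)
  dims <- dim(img$data)
  n_pix <- prod(dims[1:3])
  B <- matrix(img$data, nrow = n_pix)             # pixels x M
  G <- crossprod(A)
  H <- B %*% A                                    # pixels x C, rows = R'b
  X <- matrix(0, n_pix, C)
  res2 <- numeric(n_pix)
  b2 <- rowSums(B * B)
  starts <- seq.int(1L, n_pix, by = max(1L, as.integer(chunk_size)))
  for (s in starts) {
    e <- min(s + chunk_size - 1L, n_pix)
    for (i in s:e) {
      x <- nnls_core(G, H[i, ])$x
      X[i, ] <- x
      # ||Ax-b||^2 = b'b - 2 x'A'b + x'A'Ax, clipped at 0 for roundoff
      res2[i] <- max(0, b2[i] - 2 * sum(x * H[i, ]) + sum(x * (G %*% x)))
    }
  }
  resid <- sqrt(res2)
  rel <- ifelse(sqrt(b2) > 0, resid / sqrt(b2), 0)
  unmixed_image(array(X, c(dims[1:3], C)),
                array(resid, dims[1:3]),
                array(rel, dims[1:3]),
                channel_names = R$channel_names,
                pixel_size = img$pixel_size)
}

#' Append auxiliary autofluorescence channels to a reference matrix
#'
#' Samples with several distinct autofluorescence sources (e.g. two tissue
#' types) can be unmixed with one AF reference spectrum per source; this
#' appends extra AF columns. Appended channels are renamed AF1, AF2, ...
#' continuing after the existing AF columns.
#'
#' @param R A [reference_matrix()].
#' @param extra_af List of [reference_spectrum()] on the same scheme.
#' @return A new [reference_matrix()]; a [condition_report()] warning is
#'   emitted if the appended columns make any pair near-collinear.
#' @export
add_af_channels <- function(R, extra_af) {
  stopifnot(inherits(R, "reference_matrix"))
  if (length(extra_af) == 0L) return(R)
  existing <- lapply(seq_along(R$channel_names), function(j) {
    reference_spectrum(R$channel_names[j], R$R[, j], R$scheme)
  })
  k <- R$n_af
  extra <- lapply(seq_along(extra_af), function(i) {
    s <- extra_af[[i]]
    stopifnot(inherits(s, "reference_spectrum"))
    reference_spectrum(paste0("AF", k + i), s$intensities, R$scheme)
  })
  out <- reference_matrix(c(existing, extra),
                          n_af = R$n_af + length(extra_af))
  rep_ <- condition_report(out)
  if (rep_$warn) {
    warning("near-collinear reference columns after adding AF channels: ",
            paste(rep_$worst_pair, collapse = " vs "),
            sprintf(" (min angle %.2f deg)", rep_$min_angle_deg))
  }
  out
}
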