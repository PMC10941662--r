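# --- separable image filtering on 3D arrays (replicate boundary) ---------

filter_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  n <- dim(a)[1]
  m <- prod(dim(a)[2:3])
  mat <- matrix(a, nrow = n)
  r <- (length(kernel) - 1L) %/% 2L
  idx <- c(rep(1L, r), seq_len(n), rep(n, r))   # replicate padding
  padded <- mat[idx, , drop = FALSE]
  out <- matrix(0, n, m)
  for (k in seq_along(kernel)) {
    out <- out + kernel[k] * padded[k:(k + n - 1L), , drop = FALSE]
  }
  res <- array(out, dim(a))
  aperm(res, order(perm))
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

gauss_blur3 <- function(arr, sigma_px) {
  for (a in 1:3) {
    if (dim(arr)[a] > 1L) {
      arr <- filter_axis(arr, gauss_kernel(sigma_px[a]), a)
    }
  }
  arr
}

# shift with -Inf fill, for neighborhood maxima
shift3 <- function(arr, dz, dy, dx) {
  d <- dim(arr)
  out <- array(-Inf, d)
  src <- function(n, s) {
    i <- seq_len(n) + s
    ok <- i >= 1L & i <= n
    list(dst = seq_len(n)[ok], src = i[ok])
  }
  z <- src(d[1], dz); y <- src(d[2], dy); x <- src(d[3], dx)
  out[z$dst, y$dst, x$dst] <- arr[z$src, y$src, x$src]
  out
}

neighborhood_max <- function(arr) {
  mx <- array(-Inf, dim(arr))
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    if (abs(dz) == 1 && dim(arr)[1] == 1L) next
    mx <- pmax(mx, shift3(arr, dz, dy, dx))
  }
  mx
}

#' Scale-normalized Laplacian-of-Gaussian response of a 3D channel
#'
#' Smooths the image with an anisotropic Gaussian (per-axis sigma in pixels
#' = `sigma_um / pixel_size[axis]`) and applies the scale-normalized
#' negative Laplacian `-sum_ax sigma_ax^2 d^2/d_ax^2`, so a Gaussian blob of
#' matching scale produces a positive peak at its center whose height is
#' comparable across scales.
#'
#' @param image 3D (Z,Y,X) numeric array.
#' @param pixel_size Voxel size (z, y, x) in µm.
#' @param sigma_um Detection scale in µm.
#' @return List with `response` (3D array) and `sigma_px` (the per-axis
#'   sigma actually used, after clamping to >= 1 pixel).
#' @export
log_response <- function(image, pixel_size, sigma_um) {
  sigma_px <- sigma_um / pixel_size
  if (any(sigma_px < 1)) {
    warning(sprintf(
      "scale %.3g µm is below one pixel on axis(es) %s; clamped to 1 px",
      sigma_um, paste(c("z", "y", "x")[sigma_px < 1], collapse = ",")))
    sigma_px <- pmax(sigma_px, 1)
  }
  sm <- gauss_blur3(image, sigma_px)
  lap <- array(0, dim(image))
  for (a in 1:3) {
    if (dim(image)[a] > 1L) {
      lap <- lap + sigma_px[a]^2 * filter_axis(sm, c(1, -2, 1), a)
    }
  }
  list(response = -lap, sigma_px = sigma_px)
}

#' Detect diffraction-limited dots by scale-space LoG maxima
#'
#' Computes the scale-normalized LoG response at each scale, finds local
#' maxima over space and adjacent scales above `threshold`, and resolves
#' maxima closer than `min_separation_um` by keeping the stronger response.
#' Deterministic for a given image.
#'
#' @param image 3D (Z,Y,X) numeric array (one unmixed channel).
#' @param pixel_size Voxel size (z, y, x) in µm.
#' @param scales_um Numeric vector of detection scales sigma in µm (>= 1).
#' @param threshold Minimum LoG response for a detection (> 0).
#' @param min_separation_um Minimum distance between kept dots (µm);
#'   default twice the mean scale.
#' @param channel Label stored in the output.
#' @return A data.frame of class `dot_list` with columns `z_um`, `y_um`,
#'   `x_um`, `sigma_um`, `intensity` (LoG response), `channel`, ordered by
#'   decreasing intensity.
#' @export
detect_dots <- function(image, pixel_size, scales_um, threshold,
                        min_separation_um = NULL, channel = "Ch") {
  stopifnot(length(dim(image)) == 3L, length(scales_um) >= 1L,
            threshold > 0)
  if (is.null(min_separation_um)) min_separation_um <- 2 * mean(scales_um)
  n_s <- length(scales_um)
  resp <- vector("list", n_s)
  for (s in seq_len(n_s)) {
    resp[[s]] <- log_response(image, pixel_size, scales_um[s])$response
  }
  cands <- list()
  for (s in seq_len(n_s)) {
    nb <- neighborhood_max(resp[[s]])
    if (s > 1L) nb <- pmax(nb, resp[[s - 1L]])
    if (s < n_s) nb <- pmax(nb, resp[[s + 1L]])
    hit <- which(resp[[s]] > threshold & resp[[s]] >= nb)
    if (length(hit)) {
      ind <- arrayInd(hit, dim(image))
      cands[[length(cands) + 1L]] <- data.frame(
        z_um = (ind[, 1] - 0.5) * pixel_size[1],
        y_um = (ind[, 2] - 0.5) * pixel_size[2],
        x_um = (ind[, 3] - 0.5) * pixel_size[3],
        sigma_um = scales_um[s],
        intensity = resp[[s]][hit])
    }
  }
  if (length(cands) == 0L) {
    out <- data.frame(z_um = numeric(0), y_um = numeric(0),
                      x_um = numeric(0), sigma_um = numeric(0),
                      intensity = numeric(0), channel = character(0))
    class(out) <- c("dot_list", "data.frame")
    return(out)
  }
  d <- do.call(rbind, cands)
  d <- d[order(-d$intensity, d$z_um, d$y_um, d$x_um), , drop = FALSE]
  # greedy separation pruning: strongest responses win
  keep <- logical(nrow(d))
  pos <- as.matrix(d[, c("z_um", "y_um", "x_um")])
  kept <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(nrow(d))) {
    if (nrow(kept) == 0L ||
        min(sqrt(colSums((t(kept) - pos[i, ])^2))) >= min_separation_um) {
      keep[i] <- TRUE
      kept <- rbind(kept, pos[i, ])
    }
  }
  d <- d[keep, , drop = FALSE]
  d$channel <- channel
  rownames(d) <- NULL
  class(d) <- c("dot_list", "data.frame")
  d
}

#' One-to-one cross-channel dot matching and colocalization fractions
#'
#' Matches dots of channel A to dots of channel B one-to-one by greedy
#' ascending-distance assignment among all pairs within `radius_um` (ties
#' broken by channel-A then channel-B index). The colocalization fraction
#' of a channel is the fraction of its dots that are matched; as false
#' positives and false negatives vanish, both fractions approach one from
#' below.
#'
#' @param dots_a,dots_b Dot tables ([detect_dots()] output or any
#'   data.frame with `z_um`, `y_um`, `x_um`); must be non-empty.
#' @param radius_um Match radius in µm (> 0); default twice the mean
#'   detection scale of the inputs when `sigma_um` columns are present.
#' @return List of class `coloc_result`: `fraction_a`, `fraction_b`,
#'   `pairs` (data.frame with `index_a`, `index_b`, `distance_um`),
#'   `radius_um`, `n_a`, `n_b`.
#' @export
colocalize <- function(dots_a, dots_b, radius_um = NULL) {
  if (nrow(dots_a) == 0L || nrow(dots_b) == 0L) {
    stop("colocalization undefined for empty channel")
  }
  if (is.null(radius_um)) {
    if (!("sigma_um" %in% names(dots_a))) {
      stop("radius_um required when dot tables carry no sigma_um")
    }
    radius_um <- 2 * mean(c(dots_a$sigma_um, dots_b$sigma_um))
  }
  stopifnot(radius_um > 0)
  pa <- as.matrix(dots_a[, c("z_um", "y_um", "x_um")])
  pb <- as.matrix(dots_b[, c("z_um", "y_um", "x_um")])
  dist2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * pa %*% t(pb)
  dist <- sqrt(pmax(dist2, 0))
  within <- which(dist <= radius_um, arr.ind = TRUE)
  pairs <- data.frame(index_a = integer(0), index_b = integer(0),
                      distance_um = numeric(0))
  if (nrow(within) > 0L) {
    cand <- data.frame(index_a = within[, 1], index_b = within[, 2],
                       distance_um = dist[within])
    cand <- cand[order(cand$distance_um, cand$index_a, cand$index_b), ]
    used_a <- logical(nrow(pa)); used_b <- logical(nrow(pb))
    for (i in seq_len(nrow(cand))) {
      a <- cand$index_a[i]; b <- cand$index_b[i]
      if (!used_a[a] && !used_b[b]) {
        used_a[a] <- TRUE; used_b[b] <- TRUE
        pairs <- rbind(pairs, cand[i, ])
      }
    }
    rownames(pairs) <- NULL
  }
  structure(list(fraction_a = nrow(pairs) / nrow(pa),
                 fraction_b = nrow(pairs) / nrow(pb),
                 pairs = pairs, radius_um = radius_um,
                 n_a = nrow(pa), n_b = nrow(pb)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "Colocalization: %d/%d (A: %.3f), %d/%d (B: %.3f), radius %.2f µm\n",
    nrow(x$pairs), x$n_a, x$fraction_a, nrow(x$pairs), x$n_b, x$fraction_b,
    x$radius_um))
  invisible(x)
}

#' Replicate summary of colocalization fractions
#'
#' @param results List of [colocalize()] results (one per replicate
#'   specimen), or a numeric vector of fractions for a single channel.
#' @return Data.frame with rows `fraction_a`/`fraction_b` (or `fraction`)
#'   and columns `mean`, `sem`, `n`. The s.e.m. is the sample standard
#'   deviation over sqrt(n); with a single replicate it is reported as 0
#'   with a warning.
#' @export
coloc_summary <- function(results) {
  summarize <- function(v) {
    n <- length(v)
    sem <- if (n > 1L) stats::sd(v) / sqrt(n) else {
      warning("single replicate: s.e.m. reported as 0")
      0
    }
    c(mean = mean(v), sem = sem, n = n)
  }
  if (is.numeric(results)) {
    out <- as.data.frame(t(summarize(results)))
    rownames(out) <- "fraction"
    return(out)
  }
  stopifnot(length(results) >= 1L)
  fa <- vapply(results, function(r) r$fraction_a, 0)
  fb <- vapply(results, function(r) r$fraction_b, 0)
  out <- as.data.frame(rbind(fraction_a = summarize(fa),
                             fraction_b = summarize(fb)))
  out
}

#' Read / write dot lists as CSV
#'
#' Columns: `z_um`, `y_um`, `x_um`, `sigma_um`, `intensity`, `channel`.
#'
#' @param dots A dot table.
#' @param path CSV path.
#' @return `write_dots_csv` returns `path` invisibly; `read_dots_csv`
#'   returns a `dot_list` data.frame.
#' @export
write_dots_csv <- function(dots, path) {
  utils::write.csv(as.data.frame(dots), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dots_csv
#' @export
read_dots_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(d) <- c("dot_list", "data.frame")
  d
}
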