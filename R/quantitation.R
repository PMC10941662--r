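#' Signal-to-background ratio from paired masks
#'
#' Estimates S/B as `(mean(high) - mean(low)) / mean(low)` where `high` is a
#' region of high expression (signal plus background) and `low` a region of
#' no or low expression (background only). Because any residual expression
#' in the low region inflates the background estimate, this is a
#' conservative lower bound on the true signal-to-background.
#'
#' @param channel Numeric array (any shape), one unmixed channel.
#' @param high_mask,low_mask Logical arrays matching `channel` (or index
#'   vectors); must be non-empty and disjoint.
#' @return The S/B ratio (scalar).
#' @export
signal_to_background <- function(channel, high_mask, low_mask) {
  hi <- if (is.logical(high_mask)) which(as.vector(high_mask)) else
    as.integer(high_mask)
  lo <- if (is.logical(low_mask)) which(as.vector(low_mask)) else
    as.integer(low_mask)
  if (length(hi) == 0L || length(lo) == 0L) {
    stop("signal and background masks must be non-empty")
  }
  if (length(intersect(hi, lo)) > 0L) {
    stop("signal and background masks must be disjoint")
  }
  v <- as.vector(channel)
  mean_lo <- mean(v[lo])
  if (mean_lo == 0) {
    stop("zero background estimate; add a read-noise floor or enlarge the ",
         "background region")
  }
  (mean(v[hi]) - mean_lo) / mean_lo
}

#' Aggregate an unmixed image into subcellular voxels
#'
#' Partitions the pixel grid into voxel blocks of physical size
#' `voxel_size` µm (pixels per voxel per axis = `round(voxel/pixel)`, at
#' least 1) and sums the raw unmixed intensities within each block.
#' Sum (not mean) aggregation is used because a voxel's amplified HCR
#' signal models the molecule count it contains; the sum scales linearly
#' with content. Trailing partial blocks are dropped, so the voxel count is
#' `prod(floor(extent / pixels_per_voxel))`.
#'
#' @param unmixed An [unmixed_image()], or a plain (Z,Y,X,C) array (then
#'   `pixel_size` and `channel_names` must be given).
#' @param voxel_size Target voxel size in µm, `c(z, y, x)`; each must be >=
#'   the corresponding pixel size.
#' @param pixel_size,channel_names Only for plain-array input.
#' @return A data.frame of class `voxel_table`: columns `vz`, `vy`, `vx`
#'   (1-based voxel indices) plus one summed-intensity column per channel.
#'   Attributes: `voxel_size_um` (achieved size), `pixels_per_voxel`,
#'   `channel_names`.
#' @export
bin_voxels <- function(unmixed, voxel_size, pixel_size = NULL,
                       channel_names = NULL) {
  if (inherits(unmixed, "unmixed_image")) {
    arr <- unmixed$coefficients
    pixel_size <- unmixed$pixel_size
    channel_names <- unmixed$channel_names
  } else {
    arr <- unmixed
    if (is.null(pixel_size)) stop("pixel_size required for array input")
    if (is.null(channel_names)) {
      channel_names <- paste0("Ch", seq_len(dim(arr)[4]))
    }
  }
  stopifnot(length(dim(arr)) == 4L, length(voxel_size) == 3L)
  if (any(voxel_size < pixel_size)) {
    stop("voxel size must be >= pixel size on every axis")
  }
  ppv <- pmax(1L, as.integer(round(voxel_size / pixel_size)))
  dims <- dim(arr)[1:3]
  nv <- dims %/% ppv
  if (any(nv < 1L)) stop("image too small for the requested voxel size")
  keep <- lapply(1:3, function(a) seq_len(nv[a] * ppv[a]))
  arr <- arr[keep[[1]], keep[[2]], keep[[3]], , drop = FALSE]
  C <- dim(arr)[4]
  # block-sum via aggregation over the voxel index of each pixel
  vz <- (seq_len(dim(arr)[1]) - 1L) %/% ppv[1]
  vy <- (seq_len(dim(arr)[2]) - 1L) %/% ppv[2]
  vx <- (seq_len(dim(arr)[3]) - 1L) %/% ppv[3]
  vox_id <- as.vector(
    outer(outer(vz, vy * nv[1], `+`), vx * nv[1] * nv[2], `+`)
  ) + 1L
  sums <- matrix(0, prod(nv), C)
  for (c in seq_len(C)) {
    sums[, c] <- as.vector(
      rowsum(as.vector(arr[, , , c]), vox_id, reorder = TRUE)
    )
  }
  colnames(sums) <- channel_names
  idx <- arrayInd(seq_len(prod(nv)), nv)
  out <- data.frame(vz = idx[, 1], vy = idx[, 2], vx = idx[, 3],
                    sums, check.names = FALSE)
  attr(out, "voxel_size_um") <- ppv * pixel_size
  attr(out, "pixels_per_voxel") <- ppv
  attr(out, "channel_names") <- channel_names
  class(out) <- c("voxel_table", "data.frame")
  out
}

#' Quantile-normalize a voxel-table channel
#'
#' Divides a channel's voxel intensities by its `quantile` value (default
#' the 99.9th percentile, more robust to single hot voxels than the max).
#' Values above the quantile exceed 1; nothing is clipped. The output is
#' invariant to rescaling the inputs.
#'
#' @param table A [bin_voxels()] voxel table.
#' @param channel Channel name (column) to normalize.
#' @param quantile Normalization quantile in (0, 1], default 0.999.
#' @return Numeric vector of normalized intensities with attribute
#'   `divisor`.
#' @export
normalize_voxels <- function(table, channel, quantile = 0.999) {
  if (!channel %in% names(table)) stop("channel not in table: ", channel)
  if (nrow(table) == 0L) stop("empty voxel table")
  v <- table[[channel]]
  q <- stats::quantile(v, quantile, names = FALSE, type = 7)
  if (q <= 0) stop("all-zero (or degenerate) channel: ", channel)
  out <- v / q
  attr(out, "divisor") <- q
  out
}

#' Two-channel scatter statistics for qHCR redundant detection
#'
#' If the amplified signal scales linearly with molecules per voxel, the
#' scatter of two redundant channels' normalized voxel intensities lies on
#' a line through the origin. This reports the Pearson correlation, the
#' least-squares slope through the origin (`sum(ab)/sum(a^2)`), and a
#' free-intercept ordinary least-squares fit so the zero-intercept claim is
#' itself checkable.
#'
#' @param table A voxel table from [bin_voxels()].
#' @param channel_a,channel_b Column names of the two channels.
#' @param normalize Normalize each channel by its [normalize_voxels()]
#'   quantile first (default TRUE).
#' @param quantile Normalization quantile.
#' @return List of class `scatter_stats`: `pearson_r`,
#'   `slope_through_origin`, `slope`, `intercept`, `n_voxels`.
#' @export
qhcr_scatter_stats <- function(table, channel_a, channel_b,
                               normalize = TRUE, quantile = 0.999) {
  if (nrow(table) < 2L) stop("need at least 2 voxels")
  a <- if (normalize) as.numeric(normalize_voxels(table, channel_a, quantile))
  else table[[channel_a]]
  b <- if (normalize) as.numeric(normalize_voxels(table, channel_b, quantile))
  else table[[channel_b]]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("degenerate scatter: zero variance in a channel")
  }
  r <- stats::cor(a, b)
  s0 <- sum(a * b) / sum(a * a)
  fit <- stats::lm.fit(cbind(1, a), b)
  structure(list(pearson_r = r,
                 slope_through_origin = s0,
                 slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 n_voxels = length(a)),
            class = "scatter_stats")
}

#' @export
print.scatter_stats <- function(x, ...) {
  cat(sprintf(paste0("qHCR scatter: r = %.4f, slope through origin = %.4f,",
                     " free fit %.4f x + %.4f (n = %d voxels)\n"),
              x$pearson_r, x$slope_through_origin, x$slope, x$intercept,
              x$n_voxels))
  invisible(x)
}

#' Scale images to 8-bit for display with a fixed saturated fraction
#'
#' Pools all pixels across the provided replicate images, takes the
#' `1 - saturation_fraction` quantile (inverse-ECDF order statistic) as the
#' clip value, and maps `[0, clip]` linearly to `[0, 255]`. With
#' `saturation_fraction = 0` the clip value is the pooled maximum, so no
#' pixel is saturated below the true maximum (the convention used for
#' single-molecule displays).
#'
#' @param images A numeric array or list of arrays (replicates pooled for
#'   the common clip value).
#' @param saturation_fraction Fraction of pooled pixels to saturate, in
#'   `[0, 1)`; default 0.001 (0.1%).
#' @return List of integer arrays in 0..255 (same shapes as input; a single
#'   array input returns a single array), with attribute `clip_value`.
#' @export
display_scale <- function(images, saturation_fraction = 0.001) {
  single <- !is.list(images)
  if (single) images <- list(images)
  if (saturation_fraction < 0 || saturation_fraction >= 1) {
    stop("saturation_fraction must be in [0, 1)")
  }
  pooled <- unlist(lapply(images, as.vector), use.names = FALSE)
  if (length(pooled) == 0L) stop("no pixels to scale")
  clip <- if (saturation_fraction == 0) max(pooled) else
    stats::quantile(pooled, 1 - saturation_fraction, names = FALSE, type = 1)
  if (clip <= 0) clip <- max(max(pooled), 1)  # constant-zero guard
  out <- lapply(images, function(im) {
    scaled <- pmin(im / clip, 1) * 255
    sc <- round(scaled)                       # round-half-even, base R
    array(as.integer(sc), dim = if (is.null(dim(im))) length(im) else dim(im))
  })
  attr(out, "clip_value") <- clip
  if (single) {
    o <- out[[1]]
    attr(o, "clip_value") <- clip
    return(o)
  }
  out
}

#' Write a voxel table to CSV (and read it back)
#'
#' @param table A voxel table.
#' @param path CSV path.
#' @return `write_voxel_csv` returns `path` invisibly; `read_voxel_csv`
#'   returns a data.frame.
#' @export
write_voxel_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_voxel_csv
#' @export
read_voxel_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
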