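# shared fixtures and independent oracles for the test suite

# tiny 2-excitation / 3-measurement scheme
tiny_scheme <- function() {
  acquisition_scheme(
    c(488, 561),
    list(rbind(c(500, 540), c(545, 585)), rbind(c(575, 630)))
  )
}

# reference matrix from explicit columns (each normalized by constructor)
ref_from_cols <- function(cols, scheme, n_af = 0L) {
  spectra <- lapply(seq_along(cols), function(j) {
    reference_spectrum(names(cols)[j] %||% paste0("C", j), cols[[j]], scheme)
  })
  reference_matrix(spectra, n_af = n_af)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent NNLS oracle: enumerate all supports, solve unconstrained
# least squares on each, keep feasible (non-negative) solutions, return the
# minimum-residual one. Exact for small C by exhaustion.
nnls_oracle <- function(A, b) {
  C <- ncol(A)
  best_x <- numeric(C)
  best_r <- sqrt(sum(b^2))
  for (mask in seq_len(2^C - 1)) {
    S <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(C) - 1L)) > 0L)
    As <- A[, S, drop = FALSE]
    xs <- tryCatch(qr.solve(As, b), error = function(e) NULL)
    if (is.null(xs) || any(xs < -1e-12)) next
    xs <- pmax(xs, 0)
    r <- sqrt(sum((As %*% xs - b)^2))
    if (r < best_r - 1e-13) {
      best_r <- r
      best_x <- numeric(C)
      best_x[S] <- xs
    }
  }
  list(x = best_x, residual = best_r)
}

# brute-force minimum-total-distance one-to-one assignment between two dot
# tables, over pairs within radius (exhaustive over permutations; tiny n)
coloc_oracle <- function(dots_a, dots_b, radius_um) {
  pa <- as.matrix(dots_a[, c("z_um", "y_um", "x_um")])
  pb <- as.matrix(dots_b[, c("z_um", "y_um", "x_um")])
  na <- nrow(pa); nb <- nrow(pb)
  dist <- sqrt(outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * pa %*% t(pb))
  best <- list(n = 0L, cost = Inf)
  assign_rec <- function(i, used_b, n, cost) {
    if (i > na) {
      if (n > best$n || (n == best$n && cost < best$cost)) {
        best <<- list(n = n, cost = cost)
      }
      return()
    }
    assign_rec(i + 1L, used_b, n, cost)     # leave dot i unmatched
    for (j in seq_len(nb)) {
      if (!used_b[j] && dist[i, j] <= radius_um) {
        used_b[j] <- TRUE
        assign_rec(i + 1L, used_b, n + 1L, cost + dist[i, j])
        used_b[j] <- FALSE
      }
    }
  }
  assign_rec(1L, logical(nb), 0L, 0)
  best
}

# a small 3-channel reference matrix (2 fluorophores + AF) on hcr10_scheme
small_refmat <- function(channels = c(4L, 7L)) {
  scheme <- hcr10_scheme()
  fl <- hcr10_fluorophores()
  spectra <- lapply(channels, function(c) {
    reference_spectrum(fl[[c]]$name, predict_response(fl[[c]], scheme),
                       scheme)
  })
  spectra <- c(spectra, list(reference_spectrum(
    "AF", hcr10_af_spectrum(scheme), scheme)))
  reference_matrix(spectra, n_af = 1L)
}

# unmix a rendered redundant/single-molecule scene against the true
# 2-fluor + AF matrix; returns list(um, rendered)
unmix_two_channel <- function(scene, channels = c(4L, 7L)) {
  scheme <- hcr10_scheme()
  fl <- hcr10_fluorophores()
  r <- render_spectral_image(scene, fl[channels],
                             hcr10_af_spectrum(scheme), scheme)
  list(um = unmix_image(r$image, small_refmat(channels)), rendered = r)
}
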