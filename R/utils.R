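# Internal helpers shared across modules.

#' Stop with a classed condition
#'
#' All user-facing validation errors in the package carry the class
#' `vg_invalid_parameter` (or a more specific class) so callers can
#' distinguish them from programming errors.
#' @noRd
vg_stop <- function(msg, class = "vg_invalid_parameter", call. = FALSE) {
  stop(structure(
    class = c(class, "vg_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

#' Check a scalar is a finite number
#' @noRd
assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    vg_stop(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    vg_stop(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x))
  }
  invisible(x)
}

#' Is the input a 2D image (matrix) or 3D volume (array)?
#' @noRd
img_ndim <- function(x) {
  if (is.matrix(x)) return(2L)
  if (is.array(x) && length(dim(x)) == 3L) return(3L)
  vg_stop("input must be a 2D matrix or a 3D array")
}

#' Reflect-pad indices
#'
#' Index vector 1..n extended by `pad` on both sides with mirror boundary
#' (abcd -> cb|abcd|cb), the convention used by every convolution here.
#' @noRd
reflect_index <- function(n, pad) {
  if (n == 1L) return(rep(1L, n + 2L * pad))
  # fold arbitrary out-of-range indices back into 1..n (mirror: cb|abcd|cb)
  i <- abs(seq.int(1L - pad, n + pad) - 1L) %% (2L * (n - 1L))
  as.integer(ifelse(i >= n, 2L * (n - 1L) - i, i) + 1L)
}

#' 1D convolution along one dimension of a 2D/3D array, reflect padding
#'
#' Kernel is applied as correlation with its (symmetric or antisymmetric)
#' taps centred on each voxel; accumulation is one shifted-slab add per
#' tap, which keeps everything vectorised.
#' @noRd
conv_along <- function(x, kernel, dim_index) {
  d <- dim(x)
  nd <- length(d)
  n <- d[dim_index]
  k <- length(kernel)
  pad <- (k - 1L) %/% 2L
  ridx <- reflect_index(n, pad)

  # build padded array by indexing along dim_index
  args <- rep(list(quote(expr = )), nd)
  args[[dim_index]] <- ridx
  xp <- do.call(`[`, c(list(x), args, list(drop = FALSE)))

  out <- array(0, dim = d)
  for (t in seq_len(k)) {
    if (kernel[t] == 0) next
    args[[dim_index]] <- seq.int(t, t + n - 1L)
    out <- out + kernel[t] * do.call(`[`, c(list(xp), args, list(drop = FALSE)))
  }
  out
}

#' Run code with a temporary RNG seed (restores global state)
#' @noRd
local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Clip to the 8-bit display range used throughout
#' @noRd
clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Linear index <-> coordinates for 2D/3D arrays
#' @noRd
coords_to_index <- function(coords, dims) {
  coords <- as.matrix(coords)
  if (length(dims) == 2L) {
    coords[, 1L] + (coords[, 2L] - 1L) * dims[1L]
  } else {
    coords[, 1L] + (coords[, 2L] - 1L) * dims[1L] +
      (coords[, 3L] - 1L) * dims[1L] * dims[2L]
  }
}

#' @noRd
index_to_coords <- function(idx, dims) {
  idx <- as.integer(idx) - 1L
  if (length(dims) == 2L) {
    cbind(row = idx %% dims[1L] + 1L, col = idx %/% dims[1L] + 1L)
  } else {
    plane <- dims[1L] * dims[2L]
    cbind(
      row = idx %% dims[1L] + 1L,
      col = (idx %% plane) %/% dims[1L] + 1L,
      slice = idx %/% plane + 1L
    )
  }
}

#' Otsu's threshold on a numeric vector
#'
#' Histogram-based (256 bins over the data range); returns the bin edge
#' maximising between-class variance. Used as the default cut on Sobel
#' gradient magnitudes.
#' @noRd
otsu_threshold <- function(x) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1L])
  nb <- 256L
  h <- tabulate(pmin(pmax(floor((x - rng[1L]) / diff(rng) * nb) + 1L, 1L), nb), nb)
  p <- h / sum(h)
  mids <- rng[1L] + (seq_len(nb) - 0.5) / nb * diff(rng)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[nb]
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}
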