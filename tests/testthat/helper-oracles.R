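# Independent oracles, deliberately brute-force: these re-derive expected
# values by enumeration or closed form and never share code with the
# implementation paths they check.

# Per-pixel distance to a set of segments; mask = any distance <= radius.
# Segments given as list(p0 = c(x, y), p1 = c(x, y), radius).
brute_mask_oracle <- function(size, segments) {
  mask <- matrix(FALSE, size, size)
  for (r in seq_len(size)) {
    for (cc in seq_len(size)) {
      p <- c(cc, r) # (x, y)
      for (s in segments) {
        v <- s$p1 - s$p0
        t <- sum((p - s$p0) * v) / sum(v * v)
        t <- min(max(t, 0), 1)
        d <- sqrt(sum((p - (s$p0 + t * v))^2))
        if (d <= s$radius) {
          mask[r, cc] <- TRUE
          break
        }
      }
    }
  }
  mask
}

# Brute-force Euclidean distance transform (distance to nearest
# background pixel, center to center).
brute_edt <- function(mask) {
  bg <- which(!mask, arr.ind = TRUE)
  out <- array(0, dim = dim(mask))
  fg <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(fg))) {
    d2 <- rowSums((bg - matrix(fg[i, ], nrow(bg), ncol(bg), byrow = TRUE))^2)
    out[matrix(fg[i, ], 1)] <- sqrt(min(d2))
  }
  out
}

# Closed-form eigenvalues (gamma = 2 normalized) of the Gaussian-smoothed
# Hessian at the center of a Gaussian structure of width w and amplitude
# `contrast`: a Gaussian of width w convolved with a Gaussian of width
# sigma is a Gaussian of width s = sqrt(w^2 + sigma^2), with amplitude
# damped by (w^2/s^2)^(n_thin/2) where n_thin counts the thin axes.
# Each thin axis contributes lambda = -sigma^2 * A / s^2; thick axes 0.
analytic_center_eigs <- function(kind, w, sigma, contrast, ndim = 3) {
  n_thin <- switch(kind, blob = ndim, sheet = 1, tube = ndim - 1)
  s2 <- w^2 + sigma^2
  amp <- contrast * (w^2 / s2)^(n_thin / 2)
  lam <- -sigma^2 * amp / s2
  c(rep(0, ndim - n_thin), rep(lam, n_thin))
}

# Direct double-sum DFT of a small matrix under the 1/(MN) scaling,
# centered like dft2() (DC at floor(M/2)+1, floor(N/2)+1).
brute_dft2 <- function(f) {
  M <- nrow(f); N <- ncol(f)
  Fm <- matrix(0 + 0i, M, N)
  for (u in 0:(M - 1)) {
    for (v in 0:(N - 1)) {
      acc <- 0 + 0i
      for (x in 0:(M - 1)) {
        for (y in 0:(N - 1)) {
          acc <- acc + f[x + 1, y + 1] *
            exp(-2i * pi * (u * x / M + v * y / N))
        }
      }
      Fm[u + 1, v + 1] <- acc / (M * N)
    }
  }
  # center: DC (u = 0, index 1) moves to floor(M/2) + 1
  sh <- function(n) c(seq.int(n %/% 2 + 1, n), seq_len(n %/% 2))
  Fm[sh(M), sh(N)]
}

# Nearest-neighbor rotation of a matrix about its center by `deg`
# degrees (same convention as the phantoms: x = col, y = row).
rotate_nn <- function(m, deg) {
  n <- nrow(m)
  c0 <- (n + 1) / 2
  a <- deg * pi / 180
  out <- matrix(NA, n, ncol(m))
  for (r in seq_len(n)) {
    for (cc in seq_len(ncol(m))) {
      x <- cc - c0; y <- r - c0
      xs <- round(cos(a) * x - sin(a) * y + c0)
      ys <- round(sin(a) * x + cos(a) * y + c0)
      if (xs >= 1 && xs <= ncol(m) && ys >= 1 && ys <= n) {
        out[r, cc] <- m[ys, xs]
      }
    }
  }
  out
}

# Smallest distance from each point (row, col) to a centerline point set.
dist_to_centerline <- function(pt, centerline_pts) {
  min(sqrt((centerline_pts[, "row"] - pt[1])^2 +
             (centerline_pts[, "col"] - pt[2])^2))
}

all_centerline_points <- function(phantom) {
  do.call(rbind, lapply(phantom$centerline, `[[`, "points"))
}

dice_of <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}
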