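# Gaussian-derivative Hessian fields for 2D images and 3D volumes.

# Sampled Gaussian derivative kernels at scale sigma, with moment
# corrections so that discrete responses match the continuous operators:
# order 0 sums to 1, order 1 satisfies sum(k * x) = 1 (after negation it
# differentiates), order 2 sums to 0 and satisfies sum(k * x^2) = 2.
gaussian_kernel <- function(sigma, order) {
  radius <- max(1L, ceiling(4 * sigma))
  x <- seq.int(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) {
    k <- -x / sigma^2 * g
    k <- k - mean(k)
    return(k / sum(k * -x))
  }
  if (order == 2L) {
    k <- (x^2 - sigma^2) / sigma^4 * g
    k <- k - mean(k)
    return(k * 2 / sum(k * x^2))
  }
  vg_stop("derivative order must be 0, 1 or 2")
}

# Sort three eigenvalue arrays by absolute value, elementwise, using a
# 3-element sorting network (vectorised over all voxels).
order_by_abs3 <- function(e1, e2, e3) {
  sw <- function(a, b) {
    s <- abs(a) > abs(b)
    list(ifelse(s, b, a), ifelse(s, a, b))
  }
  p <- sw(e1, e2); e1 <- p[[1]]; e2 <- p[[2]]
  p <- sw(e2, e3); e2 <- p[[1]]; e3 <- p[[2]]
  p <- sw(e1, e2); e1 <- p[[1]]; e2 <- p[[2]]
  list(e1, e2, e3)
}

# Closed-form eigenvalues of symmetric 3x3 matrices, vectorised
# (trigonometric method; exact up to rounding).
sym3_eigenvalues <- function(xx, yy, zz, xy, xz, yz) {
  q <- (xx + yy + zz) / 3
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * (xy^2 + xz^2 + yz^2)
  p <- sqrt(p2 / 6)
  safe_p <- ifelse(p > 0, p, 1)
  bxx <- (xx - q) / safe_p; byy <- (yy - q) / safe_p; bzz <- (zz - q) / safe_p
  bxy <- xy / safe_p; bxz <- xz / safe_p; byz <- yz / safe_p
  detb <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
    bxz * (bxy * byz - byy * bxz)
  r <- pmin(pmax(detb / 2, -1), 1)
  phi <- acos(r) / 3
  eA <- q + 2 * p * cos(phi)
  eC <- q + 2 * p * cos(phi + 2 * pi / 3)
  eB <- 3 * q - eA - eC
  iso <- p == 0
  if (any(iso)) {
    eA[iso] <- q[iso]; eB[iso] <- q[iso]; eC[iso] <- q[iso]
  }
  list(eA, eB, eC)
}

#' Multiscale Gaussian Hessian of an image or volume
#'
#' Computes the second-derivative (Hessian) matrix at every pixel/voxel by
#' separable convolution with sampled Gaussian derivative kernels at scale
#' `sigma`, with reflect boundary handling. Derivatives are multiplied by
#' `sigma^2` (gamma = 2 scale normalization) so responses are comparable
#' across scales. Eigenvalues are ordered by absolute value,
#' `|lambda1| <= |lambda2| (<= |lambda3|)`, and the structureness `S` is
#' the Frobenius norm of the Hessian at each location.
#'
#' @param image 2D matrix or 3D array of gray values.
#' @param sigma Gaussian scale in pixels, > 0.
#' @return A `hessian_field` object with components `sigma`, `ndim`, the
#'   Hessian entries (`xx`, `xy`, `yy`, and in 3D `zz`, `xz`, `yz`), the
#'   ordered eigenvalue arrays `lambda1`, `lambda2` (, `lambda3`), and the
#'   structureness array `S`.
#' @examples
#' p <- make_tube_2d(32, 0, 3, 100)
#' h <- gaussian_hessian(p$image, 2)
#' h$lambda2[16, 16] < 0  # dark in the second derivative across the tube
#' @export
gaussian_hessian <- function(image, sigma) {
  assert_number(sigma, "sigma")
  if (sigma <= 0) vg_stop("`sigma` must be positive")
  nd <- img_ndim(image)
  if (any(dim(image) < 2L)) vg_stop("image needs at least 2 pixels per axis")
  g0 <- gaussian_kernel(sigma, 0L)
  g1 <- gaussian_kernel(sigma, 1L)
  g2 <- gaussian_kernel(sigma, 2L)
  s2 <- sigma^2
  if (nd == 2L) {
    xx <- s2 * conv_along(conv_along(image, g2, 1L), g0, 2L)
    yy <- s2 * conv_along(conv_along(image, g0, 1L), g2, 2L)
    xy <- s2 * conv_along(conv_along(image, g1, 1L), g1, 2L)
    tr <- xx + yy
    disc <- sqrt(((xx - yy) / 2)^2 + xy^2)
    ea <- tr / 2 - disc
    eb <- tr / 2 + disc
    s <- abs(ea) > abs(eb)
    l1 <- ifelse(s, eb, ea)
    l2 <- ifelse(s, ea, eb)
    out <- list(
      sigma = sigma, ndim = 2L, xx = xx, xy = xy, yy = yy,
      lambda1 = l1, lambda2 = l2,
      S = sqrt(xx^2 + 2 * xy^2 + yy^2)
    )
  } else {
    xx <- s2 * conv_along(conv_along(conv_along(image, g2, 1L), g0, 2L), g0, 3L)
    yy <- s2 * conv_along(conv_along(conv_along(image, g0, 1L), g2, 2L), g0, 3L)
    zz <- s2 * conv_along(conv_along(conv_along(image, g0, 1L), g0, 2L), g2, 3L)
    xy <- s2 * conv_along(conv_along(conv_along(image, g1, 1L), g1, 2L), g0, 3L)
    xz <- s2 * conv_along(conv_along(conv_along(image, g1, 1L), g0, 2L), g1, 3L)
    yz <- s2 * conv_along(conv_along(conv_along(image, g0, 1L), g1, 2L), g1, 3L)
    ee <- sym3_eigenvalues(xx, yy, zz, xy, xz, yz)
    ee <- order_by_abs3(ee[[1]], ee[[2]], ee[[3]])
    out <- list(
      sigma = sigma, ndim = 3L, xx = xx, xy = xy, yy = yy, zz = zz,
      xz = xz, yz = yz,
      lambda1 = ee[[1]], lambda2 = ee[[2]], lambda3 = ee[[3]],
      S = sqrt(xx^2 + yy^2 + zz^2 + 2 * (xy^2 + xz^2 + yz^2))
    )
  }
  structure(out, class = "hessian_field")
}

#' @export
print.hessian_field <- function(x, ...) {
  cat(sprintf("<hessian_field> %dD, sigma = %g\n", x$ndim, x$sigma))
  invisible(x)
}
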