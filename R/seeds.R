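# Automatic seed-point selection inside detected vessels.
#
# Strategy: anchor at the strongest vesselness response in the region of
# interest, cut a 1D cross-section perpendicular to the detected tube
# direction, matched-filter it with a Gaussian template, and take the
# filter maximum as the seed — skipping candidates that land on Sobel
# edge pixels, since seeds must avoid region boundaries.

#' Sobel edge map
#'
#' Standard 3x3 Sobel gradient magnitude with reflect boundary handling,
#' thresholded into a binary edge map. With the default `threshold = NULL`
#' the cut is chosen by Otsu's method on the magnitude values.
#'
#' @param image 2D numeric matrix.
#' @param threshold gradient-magnitude cutoff, or `NULL` for Otsu.
#' @return Logical matrix of edge pixels with attributes `threshold` and
#'   `magnitude`.
#' @export
sobel_edges <- function(image, threshold = NULL) {
  if (img_ndim(image) != 2L) vg_stop("`image` must be 2D")
  # separable Sobel: smooth [1 2 1] x derivative [-1 0 1]
  gx <- conv_along(conv_along(image, c(-1, 0, 1), 2L), c(1, 2, 1), 1L)
  gy <- conv_along(conv_along(image, c(-1, 0, 1), 1L), c(1, 2, 1), 2L)
  mag <- sqrt(gx^2 + gy^2)
  if (is.null(threshold)) threshold <- otsu_threshold(mag)
  structure(mag > threshold, threshold = threshold, magnitude = mag)
}

bilinear_sample <- function(image, x, y) {
  # x = col, y = row (continuous, 1-based)
  x0 <- floor(x); y0 <- floor(y)
  x0 <- pmin(pmax(x0, 1L), ncol(image) - 1L)
  y0 <- pmin(pmax(y0, 1L), nrow(image) - 1L)
  dx <- x - x0; dy <- y - y0
  i00 <- image[cbind(y0, x0)]
  i01 <- image[cbind(y0, x0 + 1L)]
  i10 <- image[cbind(y0 + 1L, x0)]
  i11 <- image[cbind(y0 + 1L, x0 + 1L)]
  i00 * (1 - dx) * (1 - dy) + i01 * dx * (1 - dy) +
    i10 * (1 - dx) * dy + i11 * dx * dy
}

#' Gray-level cross-section perpendicular to a direction
#'
#' Samples the image by bilinear interpolation at unit spacing along the
#' line through `anchor` perpendicular to `direction` (the tube
#' direction), producing the vessel's cross-sectional gray profile.
#' Samples falling outside the image are dropped and the result is
#' flagged as truncated.
#'
#' @param image 2D numeric matrix.
#' @param anchor length-2 integer-ish `(row, col)` position.
#' @param direction unit tube-direction vector `(x, y)`.
#' @param half_length samples on each side of the anchor; the full
#'   profile has `2 * half_length + 1` samples when nothing is truncated.
#' @return Numeric vector of gray values with attributes `positions`
#'   (matrix of row/col sample positions), `offsets` (signed distances
#'   from the anchor) and `truncated`.
#' @export
cross_section <- function(image, anchor, direction, half_length) {
  if (img_ndim(image) != 2L) vg_stop("`image` must be 2D")
  if (length(direction) != 2L || sum(direction^2) == 0) {
    vg_stop("`direction` must be a non-zero length-2 vector")
  }
  d <- direction / sqrt(sum(direction^2))
  perp <- c(-d[2L], d[1L]) # (x, y) rotated 90 degrees
  t <- seq.int(-half_length, half_length)
  x <- anchor[2L] + t * perp[1L]
  y <- anchor[1L] + t * perp[2L]
  inside <- x >= 1 & x <= ncol(image) & y >= 1 & y <= nrow(image)
  truncated <- !all(inside)
  if (truncated) {
    warning("cross-section truncated at the image boundary", call. = FALSE)
  }
  vals <- bilinear_sample(image, x[inside], y[inside])
  structure(vals,
            positions = cbind(row = y[inside], col = x[inside]),
            offsets = t[inside], truncated = truncated)
}

#' Matched filter for a vessel cross-section
#'
#' Correlates a 1D profile with a zero-mean Gaussian template of width
#' `kernel_sigma` (reflect padding), suppressing noise and flat
#' background so the filter response peaks at the vessel center.
#'
#' @param profile numeric vector of gray values.
#' @param kernel_sigma template width in samples.
#' @return Filtered profile, same length, attributes preserved.
#' @export
matched_filter <- function(profile, kernel_sigma) {
  assert_number(kernel_sigma, "kernel_sigma")
  if (kernel_sigma <= 0) vg_stop("`kernel_sigma` must be positive")
  radius <- max(1L, ceiling(3 * kernel_sigma))
  if (length(profile) < 2L * radius + 1L) {
    vg_stop("profile shorter than the matched-filter support")
  }
  x <- seq.int(-radius, radius)
  k <- exp(-x^2 / (2 * kernel_sigma^2))
  k <- k - mean(k)
  out <- as.numeric(conv_along(matrix(as.numeric(profile), ncol = 1L), k, 1L))
  attributes(out) <- attributes(profile)
  out
}

#' Select a seed point inside a detected vessel
#'
#' Anchors at the maximum of the vesselness map (or, without enhancement,
#' the maximum gray value) inside the region of interest, cuts the
#' cross-section perpendicular to the primary detected direction, matched
#' filters it, and returns the strongest response that does not sit on an
#' edge pixel, walking down the response ranking otherwise.
#'
#' @param image 2D numeric matrix (full image).
#' @param roi integer vector `c(row_min, row_max, col_min, col_max)`.
#' @param detection a `vessel_detection` with `detected = TRUE`.
#' @param edges logical edge map from [sobel_edges()] (same shape as
#'   `image`).
#' @param vesselness optional enhancement map used to place the anchor;
#'   `NULL` falls back to raw gray values.
#' @param scale_map optional argmax-scale map from
#'   [multiscale_enhance()]; when present, the matched-filter sigma
#'   defaults to half the anchor's best scale.
#' @param direction optional row of `detection$directions` to use
#'   (default 1, the primary direction).
#' @return A `seed_candidate`: `coords` (row, col), `value`, `direction`,
#'   `profile`, `filtered`, `edge_distance`, `roi`.
#' @export
select_seed <- function(image, roi, detection, edges, vesselness = NULL,
                        scale_map = NULL, direction = 1L) {
  if (!inherits(detection, "vessel_detection")) {
    vg_stop("`detection` must come from detect_vessel()")
  }
  if (!detection$detected) {
    vg_stop("no vessel detected in this region of interest",
            class = "vg_no_vessel")
  }
  if (nrow(detection$directions) < direction) {
    vg_stop("requested direction not present in the detection")
  }
  roi <- as.integer(roi)
  # anchor inside a 2-pixel margin so the cross-section stays in-image
  m <- 2L
  rows <- max(roi[1L] + m, 1L):min(roi[2L] - m, nrow(image))
  cols <- max(roi[3L] + m, 1L):min(roi[4L] - m, ncol(image))
  score <- if (is.null(vesselness)) image else vesselness
  sub <- score[rows, cols, drop = FALSE]
  best <- which(sub == max(sub))[1L] # column-major = row-major in coords
  anchor <- c(rows[(best - 1L) %% length(rows) + 1L],
              cols[(best - 1L) %/% length(rows) + 1L])

  dirv <- c(detection$directions$vx[direction],
            detection$directions$vy[direction])
  half_len <- max(4L, min(length(rows), length(cols)) %/% 2L - 1L)
  prof <- suppressWarnings(cross_section(image, anchor, dirv, half_len))
  ks <- if (!is.null(scale_map)) max(scale_map[anchor[1L], anchor[2L]] / 2, 1)
        else 2
  filt <- matched_filter(prof, ks)
  pos <- attr(prof, "positions")

  ord <- order(filt, decreasing = TRUE)
  for (i in ord) {
    rc <- round(pos[i, ])
    # strictly inside the region of interest (and the image)
    if (rc[1L] <= max(roi[1L], 1L) || rc[1L] >= min(roi[2L], nrow(image)) ||
        rc[2L] <= max(roi[3L], 1L) || rc[2L] >= min(roi[4L], ncol(image))) next
    if (edges[rc[1L], rc[2L]]) next
    edge_idx <- which(edges[roi[1L]:roi[2L], roi[3L]:roi[4L]], arr.ind = TRUE)
    edist <- if (nrow(edge_idx)) {
      min(sqrt((edge_idx[, 1L] + roi[1L] - 1L - rc[1L])^2 +
               (edge_idx[, 2L] + roi[3L] - 1L - rc[2L])^2))
    } else Inf
    return(structure(
      list(coords = c(row = rc[[1L]], col = rc[[2L]]),
           value = image[rc[1L], rc[2L]],
           direction = dirv, anchor = anchor,
           profile = as.numeric(prof), filtered = as.numeric(filt),
           edge_distance = edist, roi = roi),
      class = "seed_candidate"
    ))
  }
  vg_stop("every candidate lies on an edge pixel", class = "vg_seed_not_found")
}

#' @export
print.seed_candidate <- function(x, ...) {
  cat(sprintf("<seed_candidate> (%d, %d), gray %.1f, edge distance %.1f\n",
              x$coords[1L], x$coords[2L], x$value, x$edge_distance))
  invisible(x)
}

#' One seed per detected direction
#'
#' Convenience wrapper running [select_seed()] once per row of
#' `detection$directions` (primary and sub-primary); seeds mapping to the
#' same pixel are deduplicated.
#'
#' @inheritParams select_seed
#' @return List of `seed_candidate` objects.
#' @export
select_seeds <- function(image, roi, detection, edges, vesselness = NULL,
                         scale_map = NULL) {
  out <- list()
  for (k in seq_len(nrow(detection$directions))) {
    s <- tryCatch(
      select_seed(image, roi, detection, edges, vesselness, scale_map,
                  direction = k),
      vg_seed_not_found = function(e) NULL
    )
    if (!is.null(s) &&
        !any(vapply(out, function(o) all(o$coords == s$coords), logical(1)))) {
      out[[length(out) + 1L]] <- s
    }
  }
  out
}
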