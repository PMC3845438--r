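# Synthetic vascular phantoms with exact ground truth.
#
# Every generator is a pure function of (parameters, seed): the gray image,
# the binary mask (pixels within `radius` of a centerline, before noise) and
# the per-branch centerlines are all reproducible bit-for-bit. Tubes have a
# Gaussian cross-section (peak = background + contrast, width parameter =
# radius) so closed-form Hessian oracles exist; masks are cut at the radius,
# i.e. at the exp(-1/2) relative-intensity level of the profile.

VG_BACKGROUND <- 60

# cospi/sinpi keep axis-aligned phantoms exactly axis-aligned (cos(90deg)
# is 0, not 6e-17), so symmetry invariants hold bitwise.
dirvec <- function(angle_deg) {
  c(cospi(angle_deg / 180), sinpi(angle_deg / 180))
}

#' Construct a phantom object
#' @noRd
new_phantom <- function(image, mask, centerline, meta) {
  structure(
    list(image = image, mask = mask, centerline = centerline, meta = meta),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf(
    "<phantom> %s, %d branch(es), %d mask pixel(s)\n",
    paste(d, collapse = "x"), length(x$centerline), sum(x$mask)
  ))
  invisible(x)
}

# Distance from every pixel (grid) to a segment p0->p1; coordinates are
# (x = col, y = row). Returns a matrix of distances.
dist_to_segment <- function(nrow_, ncol_, p0, p1) {
  x <- matrix(rep(seq_len(ncol_), each = nrow_), nrow_, ncol_)
  y <- matrix(rep(seq_len(nrow_), ncol_), nrow_, ncol_)
  vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
  len2 <- vx * vx + vy * vy
  if (len2 == 0) {
    return(sqrt((x - p0[1])^2 + (y - p0[2])^2))
  }
  t <- ((x - p0[1]) * vx + (y - p0[2]) * vy) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((x - (p0[1] + t * vx))^2 + (y - (p0[2] + t * vy))^2)
}

# Ordered centerline pixels along a segment (row/col, deduplicated).
segment_centerline <- function(p0, p1) {
  len <- sqrt(sum((p1 - p0)^2))
  t <- seq(0, 1, length.out = max(2L, ceiling(len * 2) + 1L))
  pts <- cbind(
    row = round(p0[2] + t * (p1[2] - p0[2])),
    col = round(p0[1] + t * (p1[1] - p0[1]))
  )
  pts[!duplicated(pts), , drop = FALSE]
}

# Shared assembly: segments is a list of lists(p0, p1, radius, id, parent).
assemble_phantom_2d <- function(size, segments, contrast, noise_sd, seed, meta) {
  profile <- matrix(0, size, size)
  mask <- matrix(FALSE, size, size)
  centerline <- vector("list", length(segments))
  for (i in seq_along(segments)) {
    s <- segments[[i]]
    d <- dist_to_segment(size, size, s$p0, s$p1)
    profile <- pmax(profile, contrast * exp(-d^2 / (2 * s$radius^2)))
    mask <- mask | (d <= s$radius)
    centerline[[i]] <- list(
      id = s$id, parent = s$parent, radius = s$radius,
      p0 = s$p0, p1 = s$p1,
      points = segment_centerline(s$p0, s$p1)
    )
  }
  image <- VG_BACKGROUND + profile
  if (noise_sd > 0) {
    image <- image + local_seed(seed, {
      matrix(stats::rnorm(size * size, sd = noise_sd), size, size)
    })
  }
  new_phantom(clip255(image), mask, centerline, meta)
}

#' Straight-tube phantom (2D)
#'
#' A bright bar of Gaussian cross-section through the image center at a
#' given orientation, on a darker uniform background (gray 60), with
#' optional additive Gaussian noise, clipped to the 8-bit range.
#'
#' Angles are measured in degrees from the +x (column) axis towards +y
#' (increasing row), so 0 degrees is a horizontal bar and 90 degrees a
#' vertical one. The ground-truth mask contains exactly the pixels within
#' `radius` of the centerline and is computed before noise is added.
#'
#' @param size image side length in pixels (square image).
#' @param angle_deg tube orientation in `[0, 180)` degrees.
#' @param radius Gaussian width parameter of the cross-section, in pixels;
#'   also the half-width at which the ground-truth mask is cut.
#' @param contrast peak gray level above the background (gray levels).
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed integer seed controlling the noise; the generator is a pure
#'   function of its arguments.
#' @return A `phantom` object: `image` (matrix in `[0, 255]`), `mask`
#'   (logical matrix), `centerline` (list of branches with ordered
#'   row/col points), `meta` (parameters).
#' @examples
#' p <- make_tube_2d(64, 30, 3, 100, 5, seed = 1)
#' sum(p$mask)
#' @export
make_tube_2d <- function(size, angle_deg, radius, contrast, noise_sd = 0,
                         seed = 0L) {
  assert_number(size, "size", lower = 8)
  assert_number(angle_deg, "angle_deg", lower = 0)
  if (angle_deg >= 180) vg_stop("`angle_deg` must lie in [0, 180)")
  assert_number(radius, "radius")
  assert_number(contrast, "contrast")
  if (radius < 1) vg_stop("`radius` must be >= 1")
  if (contrast <= 0) vg_stop("`contrast` must be positive")
  assert_number(noise_sd, "noise_sd", lower = 0)

  size <- as.integer(size)
  c0 <- (size + 1) / 2
  d <- dirvec(angle_deg)
  # long segment through the center spanning the whole image
  half <- size # generous: clipped implicitly by the grid
  p0 <- c(c0, c0) - half * d
  p1 <- c(c0, c0) + half * d
  seg <- list(list(p0 = p0, p1 = p1, radius = radius, id = 1L, parent = NA_integer_))
  ph <- assemble_phantom_2d(
    size, seg, contrast, noise_sd, seed,
    meta = list(
      kind = "tube", size = size, angle_deg = angle_deg, radius = radius,
      contrast = contrast, noise_sd = noise_sd, seed = as.integer(seed),
      background = VG_BACKGROUND
    )
  )
  keep <- ph$centerline[[1]]$points[, "row"] >= 1 &
    ph$centerline[[1]]$points[, "row"] <= size &
    ph$centerline[[1]]$points[, "col"] >= 1 &
    ph$centerline[[1]]$points[, "col"] <= size
  ph$centerline[[1]]$points <- ph$centerline[[1]]$points[keep, , drop = FALSE]
  ph
}

#' Y-branch phantom (2D)
#'
#' A trunk segment running into the image center at `trunk_angle`, splitting
#' there into two child segments at `trunk_angle +/- branch_angle`. The
#' ground truth records three centerline branches with parent links
#' (trunk = 1, children = 2, 3).
#'
#' @inheritParams make_tube_2d
#' @param trunk_angle direction of travel of the trunk, degrees.
#' @param branch_angle half-opening angle of the bifurcation, degrees;
#'   must be non-zero so the children are distinct.
#' @return A `phantom` object with a 3-branch centerline.
#' @export
make_branch_2d <- function(size, trunk_angle, branch_angle, radius, contrast,
                           noise_sd = 0, seed = 0L) {
  assert_number(size, "size", lower = 16)
  assert_number(trunk_angle, "trunk_angle")
  assert_number(branch_angle, "branch_angle")
  if (branch_angle %% 180 == 0) vg_stop("child angles must differ from the trunk")
  if (radius < 1) vg_stop("`radius` must be >= 1")
  if (contrast <= 0) vg_stop("`contrast` must be positive")

  size <- as.integer(size)
  c0 <- c((size + 1) / 2, (size + 1) / 2)
  len <- size / 3
  segs <- list(
    list(p0 = c0 - len * dirvec(trunk_angle), p1 = c0, radius = radius,
         id = 1L, parent = NA_integer_),
    list(p0 = c0, p1 = c0 + len * dirvec(trunk_angle + branch_angle),
         radius = radius, id = 2L, parent = 1L),
    list(p0 = c0, p1 = c0 + len * dirvec(trunk_angle - branch_angle),
         radius = radius, id = 3L, parent = 1L)
  )
  pad <- radius + 1
  for (s in segs) {
    if (any(c(s$p0, s$p1) < 1 + pad) || any(c(s$p0, s$p1) > size - pad)) {
      vg_stop("branch geometry extends outside the image")
    }
  }
  assemble_phantom_2d(
    size, segs, contrast, noise_sd, seed,
    meta = list(
      kind = "branch", size = size, trunk_angle = trunk_angle,
      branch_angle = branch_angle, radius = radius, contrast = contrast,
      noise_sd = noise_sd, seed = as.integer(seed), background = VG_BACKGROUND
    )
  )
}

#' Binary-tree phantom (2D)
#'
#' A recursive binary vascular tree: the root grows upward from near the
#' bottom edge; each branch splits into two children rotated by +/- the
#' opening half-angle, with segment length shrinking geometrically and
#' child radius `max(1, parent - 1)`. `depth` counts levels, so a tree of
#' depth `d` has `2^d - 1` branches.
#'
#' @inheritParams make_tube_2d
#' @param depth number of levels (>= 1); depth 1 is a single tube.
#' @param radius_root radius of the root branch in pixels.
#' @param branch_angle half-opening angle at each bifurcation, degrees.
#' @param length_frac root segment length as a fraction of `size`.
#' @param shrink per-level segment length multiplier.
#' @return A `phantom` object with `2^depth - 1` centerline branches.
#' @export
make_tree_2d <- function(size, depth, radius_root, contrast, noise_sd = 0,
                         seed = 0L, branch_angle = 30, length_frac = 0.3,
                         shrink = 0.68) {
  assert_number(size, "size", lower = 16)
  assert_number(depth, "depth", lower = 1)
  if (radius_root < 1) vg_stop("`radius_root` must be >= 1")
  if (contrast <= 0) vg_stop("`contrast` must be positive")
  depth <- as.integer(depth)
  size <- as.integer(size)
  if (size * length_frac * shrink^(depth - 1) < 2) {
    vg_stop("tree depth/length degenerate: leaf segments shorter than 2 px")
  }

  segs <- list()
  nid <- 0L
  recurse <- function(p0, angle, level, radius, len, parent) {
    p1 <- p0 + len * dirvec(angle)
    nid <<- nid + 1L
    id <- nid
    segs[[id]] <<- list(p0 = p0, p1 = p1, radius = radius, id = id,
                        parent = parent)
    if (level < depth) {
      r2 <- max(1, radius - 1)
      recurse(p1, angle + branch_angle, level + 1L, r2, len * shrink, id)
      recurse(p1, angle - branch_angle, level + 1L, r2, len * shrink, id)
    }
  }
  # root starts near the bottom edge and grows upward (-y)
  start <- c((size + 1) / 2, size - radius_root - 2)
  recurse(start, -90, 1L, radius_root, size * length_frac, NA_integer_)

  pad <- 2
  for (s in segs) {
    if (any(c(s$p0, s$p1) < 1 + pad) || any(c(s$p0, s$p1) > size - pad)) {
      vg_stop("tree depth/length degenerate: branches leave the image")
    }
  }
  assemble_phantom_2d(
    size, segs, contrast, noise_sd, seed,
    meta = list(
      kind = "tree", size = size, depth = depth, radius_root = radius_root,
      contrast = contrast, noise_sd = noise_sd, seed = as.integer(seed),
      branch_angle = branch_angle, length_frac = length_frac,
      shrink = shrink, background = VG_BACKGROUND
    )
  )
}

#' Blob, sheet, and tube volumes (3D)
#'
#' Centered anisotropic Gaussian structures used to probe the eigenvalue
#' geometry of the 3D Hessian: a `blob` is isotropic (three equal
#' eigenvalues at the center), a `sheet` is thin along z only (one large
#' eigenvalue), and a `tube` runs along z (two large, one zero). Intensity
#' is `background + contrast * exp(-q/2)` with `q` the appropriate
#' quadratic form at width `scale`.
#'
#' @param size volume side length in voxels (cube).
#' @param kind one of `"blob"`, `"sheet"`, `"tube"`.
#' @param scale Gaussian width parameter along the thin axes, voxels.
#' @param contrast peak gray above background.
#' @param seed noise seed (only used when `noise_sd > 0`).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @return A `phantom` object whose mask cuts the structure at `scale`
#'   (distance along the thin axes), with the tube's centerline recorded.
#' @export
make_blob_sheet_tube_3d <- function(size, kind, scale, contrast, seed = 0L,
                                    noise_sd = 0) {
  if (!is.character(kind) || length(kind) != 1L ||
      !kind %in% c("blob", "sheet", "tube")) {
    vg_stop("`kind` must be one of \"blob\", \"sheet\", \"tube\"")
  }
  assert_number(size, "size", lower = 8)
  assert_number(scale, "scale", lower = 1)
  if (contrast <= 0) vg_stop("`contrast` must be positive")
  size <- as.integer(size)
  c0 <- (size + 1) / 2
  ax <- seq_len(size) - c0
  X <- array(rep(ax, times = size * size), dim = c(size, size, size))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  # axis convention: dim1 = x(row), dim2 = y(col), dim3 = z(slice)
  q <- switch(kind,
    blob  = (X^2 + Y^2 + Z^2) / scale^2,
    sheet = Z^2 / scale^2,
    tube  = (X^2 + Y^2) / scale^2
  )
  image <- VG_BACKGROUND + contrast * exp(-q / 2)
  if (noise_sd > 0) {
    image <- image + local_seed(seed, {
      array(stats::rnorm(size^3, sd = noise_sd), dim = dim(image))
    })
  }
  mask <- q <= 1
  centerline <- if (kind == "tube") {
    list(list(id = 1L, parent = NA_integer_, radius = scale,
              points = cbind(row = round(c0), col = round(c0),
                             slice = seq_len(size))))
  } else {
    list()
  }
  new_phantom(
    clip255(image), mask, centerline,
    meta = list(kind = kind, size = size, scale = scale, contrast = contrast,
                noise_sd = noise_sd, seed = as.integer(seed),
                background = VG_BACKGROUND)
  )
}
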