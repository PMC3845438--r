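# Branch-based seeded region growing with LIFO branch deferral.
#
# Growth proceeds in cycles. Each cycle expands the active front by a
# Chebyshev (8/26-neighborhood) or Manhattan (4/6-neighborhood) shell of
# radius `step`; candidates are accepted by the dynamic gray-level test
# g >= mu - h * sigma together with the region-of-interest bounds
# [c_min, c_max]. When the newly accepted front splits into several
# connected components, a bifurcation is declared: every component founds
# a child branch, the largest continues growing and the rest are pushed
# onto a LIFO stack, to be resumed only after the active lineage stops.

#' Exact Euclidean distance transform of a binary mask
#'
#' Distance from every foreground pixel/voxel to the nearest background
#' one (center-to-center), computed with the separable lower-envelope
#' algorithm (exact, O(n) per scan line). Background pixels get 0.
#'
#' @param mask logical matrix or 3D array.
#' @return Numeric array of distances, same shape.
#' @export
distance_transform <- function(mask) {
  nd <- img_ndim(mask)
  BIG <- 1e12
  f <- array(ifelse(mask, BIG, 0), dim = dim(mask))
  for (d in seq_len(nd)) f <- dt_pass(f, d)
  sqrt(f)
}

# One pass of the squared 1D distance transform along dimension d.
dt_pass <- function(f, d) {
  dims <- dim(f)
  n <- dims[d]
  if (n == 1L) return(f)
  # move target dimension first, apply per column, move back
  perm <- c(d, setdiff(seq_along(dims), d))
  m <- matrix(aperm(f, perm), nrow = n)
  for (j in seq_len(ncol(m))) m[, j] <- dt1d(m[, j])
  aperm(array(m, dim = dims[perm]), order(perm))
}

dt1d <- function(f) {
  n <- length(f)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  for (q in seq.int(2L, n)) {
    repeat {
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
      if (k > 1L && s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  d <- numeric(n); k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Growth parameters
#'
#' @param neighborhood 4 or 8 (2D), 6 or 26 (3D); `NULL` picks 8/26 by
#'   image dimensionality. 4/6 use the Manhattan metric, 8/26 Chebyshev.
#' @param step cycles-per-expansion radius (1 or 2); 2 widens the
#'   candidate shell, merging near-fragments and cutting spurious
#'   branches.
#' @param h spread multiplier of the acceptance test `g >= mu - h*sigma`.
#' @param k exclusion rate: gray levels per pixel of branch thickness in
#'   the reference level `mu_i = c_min + k * d_i`; 0 disables the
#'   thickness dependence.
#' @param d_c thickness cap (pixels) of the linear gray/thickness law.
#' @param c_min,c_max gray bounds of the region of interest. `NULL`
#'   derives `c_min` from the seed: background (image median) plus
#'   `exp(-1/2)` of the seed-neighborhood peak above background — the
#'   relative level at which a Gaussian cross-section has fallen to its
#'   nominal radius. `c_max` defaults to 255.
#' @param sigma_mode `"sd"` (running standard deviation of the branch's
#'   recent pixels, floored at `sigma_min`) or `"constant"`.
#' @param sigma_min floor on the running spread, gray levels.
#' @param sigma_const spread used when `sigma_mode = "constant"`.
#' @param window number of most recent accepted pixels entering the
#'   running statistics; reset at branch creation.
#' @param max_cycles safety bound; `NULL` = image diagonal in pixels.
#' @param eq10_continuous use `c_min` instead of `c_max` in the capped
#'   branch of the reference-gray law, removing its discontinuity.
#' @return A `growth_params` object.
#' @export
growth_params <- function(neighborhood = NULL, step = 2, h = 2, k = 0,
                          d_c = 10, c_min = NULL, c_max = 255,
                          sigma_mode = c("sd", "constant"), sigma_min = 10,
                          sigma_const = 10, window = 200, max_cycles = NULL,
                          eq10_continuous = FALSE) {
  sigma_mode <- match.arg(sigma_mode)
  if (!step %in% c(1, 2)) vg_stop("`step` must be 1 or 2")
  if (!is.null(neighborhood) && !neighborhood %in% c(4, 8, 6, 26)) {
    vg_stop("`neighborhood` must be 4, 8, 6 or 26")
  }
  if (h < 0) vg_stop("`h` must be >= 0")
  if (k < 0) vg_stop("`k` must be >= 0")
  if (d_c <= 0) vg_stop("`d_c` must be positive")
  if (!is.null(c_min) && c_min > c_max) vg_stop("need c_min <= c_max")
  structure(
    list(neighborhood = neighborhood, step = step, h = h, k = k, d_c = d_c,
         c_min = c_min, c_max = c_max, sigma_mode = sigma_mode,
         sigma_min = sigma_min, sigma_const = sigma_const, window = window,
         max_cycles = max_cycles, eq10_continuous = eq10_continuous),
    class = "growth_params"
  )
}

#' Acceptance test for a candidate pixel
#'
#' `TRUE` iff `g >= mu - h * sigma` (vectorised over `g`).
#'
#' @param g candidate gray value(s).
#' @param mu branch reference gray level.
#' @param sigma branch gray spread, >= 0.
#' @param h spread multiplier.
#' @export
accept_pixel <- function(g, mu, sigma, h) {
  if (any(sigma < 0)) vg_stop("`sigma` must be >= 0")
  g >= mu - h * sigma
}

#' Reference gray level of a branch from its thickness
#'
#' Piecewise-linear law: `c_min + k * d_i` for thin branches
#' (`d_i < d_c`) and `c_max + k * d_c` at or beyond the cap (as printed;
#' `continuous = TRUE` substitutes `c_min`, removing the jump at `d_c`).
#'
#' @param d_i branch thickness in pixels, >= 0 (vectorised).
#' @param params a `growth_params` object with resolved `c_min`/`c_max`.
#' @param continuous override of `params$eq10_continuous`.
#' @export
branch_reference_gray <- function(d_i, params, continuous = NULL) {
  if (any(d_i < 0)) vg_stop("`d_i` must be >= 0")
  if (is.null(continuous)) continuous <- isTRUE(params$eq10_continuous)
  cap <- if (continuous) params$c_min else params$c_max
  ifelse(d_i < params$d_c, params$c_min + params$k * d_i,
         cap + params$k * params$d_c)
}

#' Average thickness of a branch
#'
#' Twice the mean boundary distance (Euclidean distance transform minus
#' the half-pixel center-to-boundary offset) over the branch's pixels
#' inside the current mask, so a 1-pixel-wide line reports ~1 and a
#' filled disk of radius r about 2r/3.
#'
#' @param pixels branch pixels as an n x 2 (or n x 3) coordinate matrix,
#'   or a vector of linear indices into `mask`.
#' @param mask logical mask of everything accepted so far.
#' @return Thickness `d_i` in pixels.
#' @export
estimate_thickness <- function(pixels, mask) {
  idx <- if (is.matrix(pixels)) coords_to_index(pixels, dim(mask)) else pixels
  if (!length(idx)) vg_stop("branch has no pixels")
  edt <- distance_transform(mask)
  2 * mean(edt[idx] - 0.5)
}

neighbor_offsets <- function(nd, neighborhood, radius) {
  r <- seq.int(-radius, radius)
  if (nd == 2L) {
    g <- expand.grid(dr = r, dc = r)
  } else {
    g <- expand.grid(dr = r, dc = r, ds = r)
  }
  g <- as.matrix(g)
  dist <- if (neighborhood %in% c(4, 6)) rowSums(abs(g)) else
    apply(abs(g), 1L, max)
  g[dist >= 1 & dist <= radius, , drop = FALSE]
}

#' Connected components of a same-cycle front
#'
#' Partitions a set of pixels (all sharing one growth-cycle index) into
#' connected components under the stated neighborhood (4/8 in 2D, 6/26 in
#' 3D). More than one component signals a bifurcation.
#'
#' @param pixels n x 2 (or n x 3) matrix of pixel coordinates.
#' @param neighborhood 4, 8, 6 or 26.
#' @param radius adjacency radius in the neighborhood's metric. The
#'   definition of connectivity itself uses 1; [grow()] passes its
#'   `step`, since candidates expand by `step` per cycle and two accepted
#'   pixels that close to each other are part of one advancing front.
#' @return List of integer vectors of row indices into `pixels`, largest
#'   component first (ties broken by smallest row-major coordinate).
#' @export
detect_branches <- function(pixels, neighborhood = 8, radius = 1) {
  pixels <- as.matrix(pixels)
  n <- nrow(pixels)
  if (n == 0L) return(list())
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  manhattan <- neighborhood %in% c(4, 6)
  for (i in seq_len(n - 1L)) {
    di <- abs(pixels[seq.int(i + 1L, n), , drop = FALSE] -
                matrix(pixels[i, ], n - i, ncol(pixels), byrow = TRUE))
    adj <- if (manhattan) rowSums(di) <= radius else
      apply(di, 1L, max) <= radius
    for (j in which(adj)) {
      ri <- find(i); rj <- find(i + j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(seq_len(n), roots)
  sizes <- lengths(comps)
  # row-major key of each component's smallest pixel, for deterministic ties
  dims <- apply(pixels, 2L, max)
  keys <- vapply(comps, function(ix) {
    min(coords_to_index(pixels[ix, , drop = FALSE], dims))
  }, numeric(1))
  unname(comps[order(-sizes, keys)])
}

#' Branch-based region growing
#'
#' Grows a vessel segmentation from a single seed. See the module header
#' for the cycle semantics; the result records, per pixel, the growth
#' cycle at which it was accepted (seed = 1) and the branch it belongs
#' to, plus a branch table with parent links reconstructing the
#' bifurcation tree.
#'
#' @param image 2D matrix or 3D array with gray values in `[0, 255]`.
#' @param seed seed position: `c(row, col)` or `c(row, col, slice)`.
#' @param params a `growth_params` object.
#' @return A `vessel_segmentation`: `mask` (logical), `cycle_map`
#'   (integer, 0 = never accepted), `branch_map` (integer branch id per
#'   pixel), `branches` (data frame: id, parent, founding_cycle,
#'   n_pixels, mu, d_i, stopped_cycle), `seed`, `params` (with resolved
#'   bounds), `truncated`.
#' @examples
#' p <- make_tube_2d(48, 0, 3, 100)
#' seg <- grow(p$image, c(24, 24), growth_params())
#' sum(seg$mask & p$mask) / sum(seg$mask | p$mask)
#' @export
grow <- function(image, seed, params = growth_params()) {
  nd <- img_ndim(image)
  dims <- dim(image)
  seed <- as.integer(seed)
  if (length(seed) != nd || any(seed < 1L) || any(seed > dims)) {
    vg_stop("`seed` must be a position inside the image")
  }
  if (!inherits(params, "growth_params")) {
    vg_stop("`params` must come from growth_params()")
  }
  neigh <- params$neighborhood
  if (is.null(neigh)) neigh <- if (nd == 2L) 8 else 26
  if ((nd == 2L && !neigh %in% c(4, 8)) || (nd == 3L && !neigh %in% c(6, 26))) {
    vg_stop("neighborhood does not match image dimensionality")
  }
  max_cycles <- params$max_cycles
  if (is.null(max_cycles)) max_cycles <- ceiling(sqrt(sum(dims^2)))

  seed_idx <- coords_to_index(matrix(seed, 1L), dims)
  g_seed <- image[seed_idx]

  # resolve region-of-interest gray bounds
  c_min <- params$c_min
  if (is.null(c_min)) {
    bg <- stats::median(image)
    lo <- pmax(seed - 2L, 1L); hi <- pmin(seed + 2L, dims)
    nb <- if (nd == 2L) image[lo[1L]:hi[1L], lo[2L]:hi[2L]]
          else image[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]]
    c_min <- bg + exp(-0.5) * max(max(nb) - bg, 0)
  }
  c_max <- params$c_max
  params$c_min <- c_min
  params$c_max <- c_max
  if (g_seed < c_min || g_seed > c_max) {
    vg_stop(sprintf(
      "seed gray %.1f fails its own acceptance window [%.1f, %.1f]",
      g_seed, c_min, c_max), class = "vg_invalid_seed")
  }

  offsets <- neighbor_offsets(nd, neigh, params$step)
  n_off <- nrow(offsets)

  cyc <- array(0L, dim = dims)
  branch_map <- array(0L, dim = dims)
  visited <- array(FALSE, dim = dims)
  cyc[seed_idx] <- 1L
  branch_map[seed_idx] <- 1L
  visited[seed_idx] <- TRUE

  branches <- list(list(
    id = 1L, parent = NA_integer_, founding_cycle = 1L,
    pixels = seed_idx, recent = g_seed, cycles_grown = 0L,
    stopped_cycle = NA_integer_, d_i = NA_real_
  ))
  active <- 1L
  front <- seed_idx
  stack <- integer(0) # branch ids, LIFO
  cycle <- 1L
  truncated <- FALSE

  branch_sigma <- function(b) {
    if (params$sigma_mode == "constant") return(params$sigma_const)
    if (length(b$recent) < 2L) return(params$sigma_min)
    max(stats::sd(b$recent), params$sigma_min)
  }
  branch_mu <- function(b) {
    # k = 0 makes the reference level thickness-free (= c_min), so it is
    # usable from the branch's first cycle; this avoids a transient where
    # an early strict running-mean threshold rejects rim pixels that are
    # accepted cycles later as detached stragglers (spurious branches).
    # With k > 0 the thickness only becomes measurable after a few
    # cycles, so the running mean bridges the gap.
    if (params$k == 0 || b$cycles_grown >= 3L) {
      d_i <- if (params$k > 0) estimate_thickness(b$pixels, visited) else 0
      branch_reference_gray(d_i, params)
    } else {
      mean(b$recent)
    }
  }

  repeat {
    if (length(front) == 0L) {
      branches[[active]]$stopped_cycle <- cycle
      if (!length(stack)) break
      active <- stack[length(stack)]
      stack <- stack[-length(stack)]
      front <- branches[[active]]$pixels
      next
    }
    if (cycle >= max_cycles) {
      truncated <- TRUE
      branches[[active]]$stopped_cycle <- cycle
      break
    }
    cycle <- cycle + 1L

    fc <- index_to_coords(front, dims)
    cand <- fc[rep(seq_len(nrow(fc)), each = n_off), , drop = FALSE] +
      offsets[rep(seq_len(n_off), nrow(fc)), , drop = FALSE]
    inside <- rowSums(cand >= 1L) == nd &
      rowSums(cand <= matrix(dims, nrow(cand), nd, byrow = TRUE)) == nd
    cand <- unique(coords_to_index(cand[inside, , drop = FALSE], dims))
    cand <- cand[!visited[cand]]
    if (!length(cand)) { front <- integer(0); next }

    b <- branches[[active]]
    mu <- branch_mu(b)
    sg <- branch_sigma(b)
    gv <- image[cand]
    acc <- cand[accept_pixel(gv, mu, sg, params$h) & gv >= c_min & gv <= c_max]
    if (!length(acc)) { front <- integer(0); next }
    acc <- sort(acc)

    comps <- detect_branches(index_to_coords(acc, dims), neigh,
                             radius = params$step)
    visited[acc] <- TRUE
    cyc[acc] <- cycle

    if (length(comps) == 1L) {
      branch_map[acc] <- active
      b$pixels <- c(b$pixels, acc)
      b$recent <- utils::tail(c(b$recent, image[acc]), params$window)
      b$cycles_grown <- b$cycles_grown + 1L
      branches[[active]] <- b
      front <- acc
    } else {
      # bifurcation: the active branch stops, each component founds a child
      branches[[active]]$stopped_cycle <- cycle
      child_ids <- length(branches) + seq_along(comps)
      for (ci in seq_along(comps)) {
        px <- acc[comps[[ci]]]
        branch_map[px] <- child_ids[ci]
        branches[[child_ids[ci]]] <- list(
          id = child_ids[ci], parent = active, founding_cycle = cycle,
          pixels = px, recent = image[px], cycles_grown = 1L,
          stopped_cycle = NA_integer_, d_i = NA_real_
        )
      }
      # largest component continues; the rest wait on the LIFO stack
      stack <- c(stack, rev(child_ids[-1L]))
      active <- child_ids[1L]
      front <- acc[comps[[1L]]]
    }
  }

  for (i in seq_along(branches)) {
    branches[[i]]$d_i <- estimate_thickness(branches[[i]]$pixels, visited)
  }
  tab <- data.frame(
    id = vapply(branches, `[[`, integer(1), "id"),
    parent = vapply(branches, `[[`, integer(1), "parent"),
    founding_cycle = vapply(branches, `[[`, integer(1), "founding_cycle"),
    n_pixels = vapply(branches, function(b) length(b$pixels), integer(1)),
    mu = vapply(branches, function(b) mean(b$recent), numeric(1)),
    d_i = vapply(branches, `[[`, numeric(1), "d_i"),
    stopped_cycle = vapply(branches, `[[`, integer(1), "stopped_cycle")
  )
  structure(
    list(mask = visited, cycle_map = cyc, branch_map = branch_map,
         branches = tab, seed = seed, params = params, truncated = truncated),
    class = "vessel_segmentation"
  )
}

#' @export
print.vessel_segmentation <- function(x, ...) {
  cat(sprintf(
    "<vessel_segmentation> %d pixel(s), %d branch(es), %d cycle(s)%s\n",
    sum(x$mask), nrow(x$branches), max(x$cycle_map),
    if (x$truncated) " [truncated]" else ""
  ))
  invisible(x)
}

#' Branch counts across growing configurations
#'
#' Reruns [grow()] on a phantom under several (step, neighborhood)
#' settings and tabulates the number of branches each produces. Widening
#' the neighborhood or the step merges front fragments and should never
#' increase the count on tree-like structures.
#'
#' @param phantom a `phantom` object (2D) with a centerline.
#' @param configs data frame with columns `step` and `neighborhood`.
#' @param params base `growth_params`; step/neighborhood are overridden
#'   per row.
#' @param seed_point optional `(row, col)`; defaults to the starting
#'   point of the phantom's first centerline branch (the tree root), so
#'   growth proceeds in one direction along the trunk.
#' @return `configs` with an added `branches` column.
#' @export
branch_count_experiment <- function(phantom, configs,
                                    params = growth_params(),
                                    seed_point = NULL) {
  if (!inherits(phantom, "phantom")) vg_stop("`phantom` required")
  if (is.null(seed_point)) {
    seed_point <- phantom$centerline[[1L]]$points[1L, ]
  }
  configs$branches <- NA_integer_
  for (i in seq_len(nrow(configs))) {
    p <- params
    p$step <- configs$step[i]
    p$neighborhood <- configs$neighborhood[i]
    seg <- grow(phantom$image, seed_point, p)
    configs$branches[i] <- nrow(seg$branches)
  }
  configs
}
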