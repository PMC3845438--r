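# End-to-end pipeline: enhance -> spectral detection per tile -> seed
# selection -> branch-based growing, plus evaluation metrics and a
# reproducible JSON run report.

#' Pipeline configuration
#'
#' Collects every stage's parameters into one validated object that
#' serializes losslessly to JSON (see [write_config()]), so a run is
#' fully reproducible from its report.
#'
#' @param input path to the input image (`.pgm`) or volume (`.json`),
#'   or `NULL` when the image is passed to [run_pipeline()] directly.
#' @param output_dir directory for all outputs; created if missing.
#' @param mode `"2d"` (native) or `"3d-slicewise"` (the 2D procedure per
#'   slice for detection/seeding, 3D growing).
#' @param skip_enhancement run detection and seeding on the raw image,
#'   skipping the Hessian stage.
#' @param enhancement list of [vesselness_params()] arguments.
#' @param spectrum list: `dtheta`, `omega`, `threshold`, `window`.
#' @param growth list of [growth_params()] arguments.
#' @param tile spectral region-of-interest side length, pixels.
#' @param overlap tile overlap fraction in `[0, 0.9]`.
#' @param rescale min-max rescale gray to `[0, 255]` when the input
#'   exceeds the 8-bit range.
#' @param seed RNG seed recorded in the report (the pipeline itself is
#'   deterministic; the seed feeds any randomized downstream use).
#' @param verbose print per-stage progress to stderr.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(input = NULL, output_dir = tempfile("vgrun"),
                            mode = c("2d", "3d-slicewise"),
                            skip_enhancement = FALSE,
                            enhancement = list(),
                            spectrum = list(dtheta = 1, omega = 5,
                                            threshold = vg_default_threshold(),
                                            window = TRUE),
                            growth = list(), tile = 64, overlap = 0.5,
                            rescale = TRUE, seed = 0L, verbose = FALSE) {
  mode <- match.arg(mode)
  if (!is.null(input) && !file.exists(input)) {
    vg_stop(sprintf("input path does not exist: %s", input))
  }
  assert_number(tile, "tile", lower = 16)
  assert_number(overlap, "overlap", lower = 0, upper = 0.9)
  sp <- utils::modifyList(
    list(dtheta = 1, omega = 5, threshold = vg_default_threshold(),
         window = TRUE),
    spectrum
  )
  # validate stage parameter lists eagerly
  do.call(vesselness_params, enhancement)
  do.call(growth_params, growth)
  structure(
    list(input = input, output_dir = output_dir, mode = mode,
         skip_enhancement = isTRUE(skip_enhancement),
         enhancement = enhancement, spectrum = sp, growth = growth,
         tile = as.integer(tile), overlap = overlap,
         rescale = isTRUE(rescale), seed = as.integer(seed),
         verbose = isTRUE(verbose)),
    class = "pipeline_config"
  )
}

#' Serialize / parse a pipeline configuration
#'
#' JSON round-trips are idempotent: `write_config(read_config(p))`
#' reproduces the file byte for byte.
#'
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$enhancement <- as.list(x$enhancement)
  x$growth <- as.list(x$growth)
  x$spectrum <- as.list(x$spectrum)
  do.call(pipeline_config, x)
}

#' Segmentation metrics against a reference mask
#'
#' @param mask logical (or 0/1) predicted mask.
#' @param reference logical reference mask of the same shape.
#' @return List: `accuracy` (fraction of pixels agreeing with the
#'   reference), `dice`, `sensitivity`, `specificity`, and the raw
#'   confusion counts.
#' @export
evaluate <- function(mask, reference) {
  if (!identical(dim(mask), dim(reference))) {
    vg_stop("mask and reference have different shapes")
  }
  m <- as.logical(mask); r <- as.logical(reference)
  tp <- sum(m & r); tn <- sum(!m & !r)
  fp <- sum(m & !r); fn <- sum(!m & r)
  list(
    accuracy = (tp + tn) / length(m),
    dice = if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn),
    sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
    tp = tp, tn = tn, fp = fp, fn = fn
  )
}

# 50%-overlap tiling of [1, n]; returns a matrix of (from, to).
tile_ranges <- function(n, tile, overlap) {
  tile <- min(tile, n)
  stride <- max(1L, floor(tile * (1 - overlap)))
  from <- unique(pmin(seq.int(1L, max(n - tile + 1L, 1L), by = stride),
                      n - tile + 1L))
  if (from[length(from)] + tile - 1L < n) from <- c(from, n - tile + 1L)
  cbind(from = from, to = from + tile - 1L)
}

#' Run the full vessel segmentation pipeline
#'
#' Stages: (1) multiscale Hessian enhancement (optional); (2) tiled
#' spectral analysis — each region of interest is Fourier transformed,
#' its angular energy profile computed, and the trough-peak-trough test
#' applied; (3) automatic seed selection in every detecting tile;
#' (4) branch-based region growing from the strongest seed. Outputs
#' (mask, cycle map, branch table, seeds, the seed tile's angular
#' profile, JSON report) are written under `config$output_dir`; stage
#' timings go to a separate `timings.json` so the report itself is
#' deterministic.
#'
#' @param config a `pipeline_config`.
#' @param image optional in-memory image overriding `config$input`.
#' @return A `pipeline_result` list: `status` (`"ok"` or `"no-vessel"`),
#'   `segmentation`, `seeds`, `detections`, `enhanced`, `report`, and
#'   `paths` of everything written.
#' @export
run_pipeline <- function(config, image = NULL) {
  if (!inherits(config, "pipeline_config")) {
    vg_stop("`config` must come from pipeline_config()")
  }
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(name) {
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    t0 <<- proc.time()[["elapsed"]]
    if (config$verbose) message(sprintf("[vesselgrow] %s done", name))
  }

  if (is.null(image)) {
    if (is.null(config$input)) vg_stop("no input image")
    image <- read_image(config$input)
  }
  if (config$rescale && (max(image) > 255 || min(image) < 0)) {
    rng <- range(image)
    image <- (image - rng[1L]) / diff(rng) * 255
  }
  nd <- img_ndim(image)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  tick("load")

  vparams <- do.call(vesselness_params, config$enhancement)
  enh <- NULL
  if (!config$skip_enhancement) {
    enh <- multiscale_enhance(image, vparams)
  }
  tick("enhance")

  # detection + seeding operate on 2D planes
  plane_ids <- if (nd == 2L) list(NULL) else as.list(seq_len(dim(image)[3L]))
  detections <- list()
  seeds <- list()
  sp <- config$spectrum
  for (pl in plane_ids) {
    img2 <- if (is.null(pl)) image else image[, , pl]
    enh2 <- if (is.null(enh)) NULL else if (is.null(pl)) enh$enhanced else
      enh$enhanced[, , pl]
    smap2 <- if (is.null(enh)) NULL else if (is.null(pl)) enh$scale_map else
      enh$scale_map[, , pl]
    edges <- sobel_edges(img2)
    rtiles <- tile_ranges(nrow(img2), config$tile, config$overlap)
    ctiles <- tile_ranges(ncol(img2), config$tile, config$overlap)
    for (ri in seq_len(nrow(rtiles))) {
      for (ci in seq_len(nrow(ctiles))) {
        roi <- c(rtiles[ri, ], ctiles[ci, ])
        sub <- img2[roi[1L]:roi[2L], roi[3L]:roi[4L]]
        spec_t <- dft2(sub, window = isTRUE(sp$window))
        # power profile gates the detection, magnitude carries orientation
        det <- detect_vessel(
          angular_energy_profile(spec_t, dtheta = sp$dtheta,
                                 omega = sp$omega, measure = "power"),
          threshold = sp$threshold
        )
        if (!det$detected) next
        prof <- angular_energy_profile(spec_t, dtheta = sp$dtheta,
                                       omega = sp$omega)
        det$directions <- find_feature_directions(prof,
                                                  formula = "continuous")
        if (!nrow(det$directions)) next
        rec <- list(roi = roi, plane = pl, detection = det, profile = prof)
        detections[[length(detections) + 1L]] <- rec
        ss <- select_seeds(img2, roi, det, edges, vesselness = enh2,
                           scale_map = smap2)
        for (s in ss) {
          s$plane <- pl
          seeds[[length(seeds) + 1L]] <- s
        }
      }
    }
  }
  tick("detect_and_seed")

  paths <- list(report = file.path(config$output_dir, "report.json"))
  report <- list(
    package = "vesselgrow",
    config = unclass(config),
    image_dims = dim(image),
    n_tiles_detected = length(detections),
    n_seeds = length(seeds)
  )

  if (!length(seeds)) {
    empty <- array(FALSE, dim = dim(image))
    paths$mask <- file.path(config$output_dir,
                            if (nd == 2L) "mask.pgm" else "mask.json")
    if (nd == 2L) write_pgm(empty * 255, paths$mask)
    else write_volume_json(empty * 255, paths$mask)
    report$status <- "no-vessel"
    jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    tick("grow")
    jsonlite::write_json(timings, file.path(config$output_dir, "timings.json"),
                         auto_unbox = TRUE)
    return(structure(
      list(status = "no-vessel", segmentation = NULL, seeds = seeds,
           detections = detections, enhanced = enh, report = report,
           paths = paths),
      class = "pipeline_result"
    ))
  }

  # grow from the strongest seed (highest enhancement response, falling
  # back to gray value); connected trees are reached from one seed
  score <- vapply(seeds, function(s) {
    if (!is.null(enh)) {
      e <- if (nd == 2L) enh$enhanced else enh$enhanced[, , s$plane]
      e[s$coords[1L], s$coords[2L]]
    } else s$value
  }, numeric(1))
  best <- seeds[[order(-score, vapply(seeds, function(s)
    sum(s$coords), numeric(1)))[1L]]]
  seed_pos <- if (nd == 2L) best$coords else c(best$coords, best$plane)
  gparams <- do.call(growth_params, config$growth)
  seg <- grow(image, seed_pos, gparams)
  tick("grow")

  # outputs
  if (nd == 2L) {
    paths$mask <- file.path(config$output_dir, "mask.pgm")
    paths$cycle_map <- file.path(config$output_dir, "cycle_map.pgm")
    write_pgm(seg$mask * 255, paths$mask)
    write_pgm(seg$cycle_map, paths$cycle_map, maxval = 65535)
  } else {
    paths$mask <- file.path(config$output_dir, "mask.json")
    paths$cycle_map <- file.path(config$output_dir, "cycle_map.json")
    write_volume_json(seg$mask * 255, paths$mask)
    write_volume_json(seg$cycle_map, paths$cycle_map)
  }
  paths$branches <- file.path(config$output_dir, "branches.json")
  jsonlite::write_json(seg$branches, paths$branches, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  paths$seeds <- file.path(config$output_dir, "seeds.csv")
  seed_df <- do.call(rbind, lapply(seeds, function(s) {
    data.frame(row = s$coords[1L] - 1L, col = s$coords[2L] - 1L,
               plane = if (is.null(s$plane)) NA_integer_ else s$plane - 1L,
               gray = s$value, vx = s$direction[1L], vy = s$direction[2L],
               edge_distance = s$edge_distance)
  }))
  utils::write.csv(seed_df, paths$seeds, row.names = FALSE)
  paths$profile <- file.path(config$output_dir, "profile.csv")
  prof0 <- detections[[1L]]$profile
  utils::write.csv(
    data.frame(theta = prof0$theta, energy = prof0$energy,
               normalized = prof0$normalized),
    paths$profile, row.names = FALSE
  )

  report$status <- "ok"
  report$seed_used <- unname(seed_pos - 1L) # 0-based in the report
  report$n_branches <- nrow(seg$branches)
  report$n_mask_pixels <- sum(seg$mask)
  report$truncated <- seg$truncated
  report$growth_resolved <- list(c_min = seg$params$c_min,
                                 c_max = seg$params$c_max)
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  jsonlite::write_json(timings, file.path(config$output_dir, "timings.json"),
                       auto_unbox = TRUE)

  structure(
    list(status = "ok", segmentation = seg, seeds = seeds,
         detections = detections, enhanced = enh, report = report,
         paths = paths),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s: %d tile(s) detected, %d seed(s)%s\n",
              x$status, length(x$detections), length(x$seeds),
              if (x$status == "ok")
                sprintf(", %d branch(es)", nrow(x$segmentation$branches))
              else ""))
  invisible(x)
}
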