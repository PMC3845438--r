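# Plain-text image and volume I/O.
#
# 2D images travel as ASCII PGM (P2), 3D volumes as a small JSON
# container {dims, values} — both text formats readable anywhere without
# binary-format dependencies.

#' Read an ASCII PGM (P2) image
#'
#' @param path file path.
#' @return Numeric matrix (rows = image rows, top to bottom).
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  tokens <- scan(text = paste(lines, collapse = " "), what = character(),
                 quiet = TRUE)
  if (tokens[1L] != "P2") vg_stop("only ASCII PGM (P2) is supported")
  nums <- as.numeric(tokens[-1L])
  w <- nums[1L]; h <- nums[2L]
  vals <- nums[-(1:3)] # drop width, height, maxval
  if (length(vals) != w * h) vg_stop("corrupt PGM: wrong pixel count")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write an ASCII PGM (P2) image
#'
#' Values are rounded and clipped to `[0, maxval]`.
#'
#' @param image numeric matrix.
#' @param path file path.
#' @param maxval maximum gray value declared in the header (255 for 8-bit
#'   masks/images, 65535 for cycle maps).
#' @export
write_pgm <- function(image, path, maxval = 255) {
  v <- pmin(pmax(round(image), 0), maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), as.character(maxval)),
             con)
  apply(v, 1L, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

#' Read/write a 3D volume as JSON
#'
#' @param volume 3D numeric array.
#' @param path file path.
#' @return `read_volume_json` returns the array; `write_volume_json` the
#'   path, invisibly.
#' @export
write_volume_json <- function(volume, path) {
  if (img_ndim(volume) != 3L) vg_stop("`volume` must be 3D")
  jsonlite::write_json(
    list(dims = dim(volume), values = as.numeric(volume)),
    path, auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

#' @rdname write_volume_json
#' @export
read_volume_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  array(x$values, dim = x$dims)
}

#' Load a 2D image or 3D volume by extension
#'
#' `.pgm` is read as ASCII PGM; `.json` as a volume container.
#' @param path file path.
#' @export
read_image <- function(path) {
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) return(read_pgm(path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    return(read_volume_json(path))
  }
  vg_stop("unsupported image format (use .pgm or .json)")
}

#' Save a phantom with its ground truth
#'
#' Writes `<stem>.pgm` (2D) or `<stem>.json` (3D) for the gray image,
#' `<stem>_mask.pgm`/`.json` for the 0/255 ground-truth mask, and a
#' sidecar `<stem>_truth.json` holding the generator parameters and the
#' per-branch centerlines (0-based row/col coordinates).
#'
#' @param phantom a `phantom` object.
#' @param stem output path without extension.
#' @return The sidecar path, invisibly.
#' @export
write_phantom <- function(phantom, stem) {
  if (!inherits(phantom, "phantom")) vg_stop("`phantom` required")
  is2d <- img_ndim(phantom$image) == 2L
  if (is2d) {
    write_pgm(phantom$image, paste0(stem, ".pgm"))
    write_pgm(phantom$mask * 255, paste0(stem, "_mask.pgm"))
  } else {
    write_volume_json(phantom$image, paste0(stem, ".json"))
    write_volume_json(phantom$mask * 255, paste0(stem, "_mask.json"))
  }
  truth <- list(
    meta = phantom$meta,
    centerline = lapply(phantom$centerline, function(b) {
      list(id = b$id, parent = b$parent, radius = b$radius,
           points = unname(b$points - 1L)) # 0-based on disk
    })
  )
  side <- paste0(stem, "_truth.json")
  jsonlite::write_json(truth, side, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(side)
}
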