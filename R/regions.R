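# Region extraction: lower-arm pixels from a body-part label map and
# nasal-bridge pixels from 68-point facial landmarks. The package consumes
# the detectors' output formats (label-map PNGs, landmark CSVs) and never
# runs the neural models itself.

ARM_PART_LABELS <- c(19L, 20L) # DensePose IUV parts: left / right lower arm
NASAL_BRIDGE_LANDMARKS <- 27:30 # 68-point convention, 0-based indices

new_region_sample <- function(region, pixels, provenance = list(), reason = NULL) {
  pixels <- if (is.null(pixels) || length(pixels) == 0L) {
    matrix(integer(0), ncol = 3, dimnames = list(NULL, c("r", "g", "b")))
  } else {
    as_rgb_matrix(pixels)
  }
  structure(
    list(
      region = region, pixels = pixels, pixel_count = nrow(pixels),
      provenance = provenance, reason = reason
    ),
    class = "region_sample"
  )
}

#' @export
print.region_sample <- function(x, ...) {
  cat(sprintf(
    "<region_sample> %s: %d pixels%s\n", x$region, x$pixel_count,
    if (!is.null(x$reason)) paste0(" (", x$reason, ")") else ""
  ))
  invisible(x)
}

#' Read an RGB image as an 8-bit array
#'
#' Reads a PNG into an height x width x 3 integer array with values in
#' \[0, 255\]. 16-bit PNGs are rescaled to the 8-bit range; an alpha channel
#' is dropped; grayscale images are replicated across channels.
#'
#' @param path Path to a PNG file.
#' @return An h x w x 3 integer array.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path) # values in [0, 1] regardless of bit depth
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  if (dim(img)[3L] == 1L) img <- img[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(img)[3L] == 4L) img <- img[, , 1:3, drop = FALSE]
  arr <- array(as.integer(round(img * 255)), dim(img))
  arr
}

#' Read a body-part label map
#'
#' A label map is a single-channel PNG whose gray levels are integer part IDs
#' in the DensePose IUV convention (0 = background, 19/20 = lower arms),
#' stored as value/255 in 8-bit gray. A matrix passes through unchanged.
#'
#' @param x Path to a PNG, or an integer matrix.
#' @return An integer matrix of part labels.
#' @export
read_part_labels <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "integer"
    return(x)
  }
  img <- png::readPNG(x)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  matrix(as.integer(round(img * 255)), nrow = nrow(img))
}

#' Read a facial landmark set
#'
#' Accepts either a long CSV with columns `index,x,y[,confidence]` (0-based
#' landmark indices, pixel coordinates with x right / y down) or the OpenFace
#' wide CSV dialect (one row per face with columns `x_0..x_67, y_0..y_67`,
#' possibly padded with spaces).
#'
#' @param path Path to the CSV file.
#' @return data.frame with columns `index`, `x`, `y` and, when present,
#'   `confidence`.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  names(df) <- trimws(names(df))
  if (all(c("index", "x", "y") %in% names(df))) {
    return(df[order(df$index), intersect(c("index", "x", "y", "confidence"), names(df)),
      drop = FALSE
    ])
  }
  xs <- grep("^x_[0-9]+$", names(df), value = TRUE)
  ys <- grep("^y_[0-9]+$", names(df), value = TRUE)
  if (length(xs) == 0L || length(xs) != length(ys)) {
    stop("unrecognised landmark CSV layout: need index,x,y columns or x_i/y_i pairs",
      call. = FALSE
    )
  }
  idx <- as.integer(sub("^x_", "", xs))
  data.frame(
    index = idx[order(idx)],
    x = as.numeric(df[1L, xs[order(idx)]]),
    y = as.numeric(df[1L, ys[order(idx)]])
  )
}

pixels_at <- function(image, rows, cols) {
  cbind(
    r = image[cbind(rows, cols, 1L)],
    g = image[cbind(rows, cols, 2L)],
    b = image[cbind(rows, cols, 3L)]
  )
}

#' Extract lower-arm pixels from a part label map
#'
#' Collects all and only the pixels whose part label marks the left or right
#' lower arm, in row-major order. Zero matching pixels yield an empty sample
#' (the pipeline, not this function, decides exclusion).
#'
#' @param image An h x w x 3 image array (see [read_image()]).
#' @param parts An integer label matrix of the same h x w (see
#'   [read_part_labels()]).
#' @param arm_labels Part IDs to collect; default 19 and 20.
#' @return A `region_sample` with region `"arm"`; provenance records the
#'   per-label pixel counts.
#' @export
extract_arm_pixels <- function(image, parts, arm_labels = ARM_PART_LABELS) {
  parts <- read_part_labels(parts)
  if (!identical(dim(parts), dim(image)[1:2])) {
    stop("label map dimensions do not match the image", call. = FALSE)
  }
  hit <- which(matrix(parts %in% arm_labels, nrow(parts)), arr.ind = TRUE)
  per_label <- vapply(arm_labels, function(l) sum(parts == l), integer(1))
  names(per_label) <- paste0("label_", arm_labels)
  if (nrow(hit) == 0L) {
    return(new_region_sample("arm", NULL,
      provenance = list(label_counts = per_label), reason = "no_region"
    ))
  }
  ord <- order(hit[, 1L], hit[, 2L]) # row-major
  hit <- hit[ord, , drop = FALSE]
  new_region_sample("arm", pixels_at(image, hit[, 1L], hit[, 2L]),
    provenance = list(label_counts = per_label)
  )
}

#' Extract nasal-bridge pixels from facial landmarks
#'
#' Samples the pixels at landmarks 27-30 of the 68-point convention -- the
#' nasal bridge, chosen because it is central, rarely occluded and uniformly
#' lit. With `radius = 0` (default) exactly the four landmark pixels are
#' taken; with radius r, the union of the (2r+1)^2 neighbourhoods, clipped to
#' the image and deduplicated. Landmark coordinates are 0-based (x right,
#' y down) and are rounded half-up to the nearest pixel.
#'
#' @param image An h x w x 3 image array.
#' @param landmarks data.frame with columns `index`, `x`, `y` (see
#'   [read_landmarks()]).
#' @param radius Non-negative integer neighbourhood half-width.
#' @return A `region_sample` with region `"face"`; if any of landmarks 27-30
#'   is missing or out of frame, an empty sample with the reason recorded.
#' @export
extract_face_pixels <- function(image, landmarks, radius = 0L) {
  stopifnot(radius >= 0L)
  h <- dim(image)[1L]; w <- dim(image)[2L]
  pts <- landmarks[match(NASAL_BRIDGE_LANDMARKS, landmarks$index), , drop = FALSE]
  if (anyNA(pts$index)) {
    return(new_region_sample("face", NULL, reason = "no_region"))
  }
  col <- floor(pts$x + 0.5) + 1L # 0-based image coords -> 1-based matrix
  row <- floor(pts$y + 0.5) + 1L
  if (any(row < 1L | row > h | col < 1L | col > w)) {
    return(new_region_sample("face", NULL,
      provenance = list(landmarks = NASAL_BRIDGE_LANDMARKS), reason = "no_region"
    ))
  }
  off <- seq(-radius, radius)
  grid <- expand.grid(dr = off, dc = off)
  coords <- unique(do.call(rbind, lapply(seq_along(row), function(i) {
    cbind(row = row[i] + grid$dr, col = col[i] + grid$dc)
  })))
  coords <- coords[coords[, 1L] >= 1L & coords[, 1L] <= h &
    coords[, 2L] >= 1L & coords[, 2L] <= w, , drop = FALSE]
  new_region_sample("face", pixels_at(image, coords[, 1L], coords[, 2L]),
    provenance = list(landmarks = NASAL_BRIDGE_LANDMARKS, radius = radius)
  )
}
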