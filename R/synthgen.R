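# Synthetic cohort generator: images with painted arm and face regions of
# known Lab ground truth, plus matching label maps, landmark sets and gold
# annotations. Emulates a standardized AI-generated photo cohort (uniform
# lighting, pose and quality) so the full pipeline is testable without any
# clinical data.

with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Render a noisy colour patch with known ground truth
#'
#' Draws every pixel as the given Lab colour plus independent Gaussian noise
#' per channel, then converts to 8-bit sRGB (clipping out-of-gamut values).
#' With `sigma = 0` all pixels are bit-identical and the patch ITA equals
#' `ita_from_lab(lab)` exactly (up to 8-bit quantisation of the colour).
#'
#' @param lab Length-3 Lab colour at the patch centre.
#' @param size `c(height, width)` in pixels.
#' @param sigma Noise standard deviation per Lab channel (0 = noiseless).
#' @param seed Mandatory RNG seed; the caller's RNG state is untouched.
#' @return List with `image` (h x w x 3 integer array), `mask` (logical
#'   matrix, all TRUE), and `clipped_fraction` of channels clipped at the
#'   gamut boundary; a warning is raised when clipping is substantial.
#' @export
make_patch <- function(lab, size = c(32L, 32L), sigma = 0, seed) {
  stopifnot(sigma >= 0, length(size) == 2L)
  n <- size[1L] * size[2L]
  rgbm <- with_seed(seed, {
    labm <- matrix(rep(as.numeric(lab), each = n), ncol = 3) +
      matrix(stats::rnorm(3 * n, sd = sigma), ncol = 3)
    lab_to_srgb(labm)
  })
  clipped <- attr(rgbm, "clipped_fraction")
  if (clipped > 0.01) {
    warning(sprintf("%.1f%% of channels clipped at the sRGB gamut boundary",
      100 * clipped), call. = FALSE)
  }
  img <- array(0L, c(size, 3L))
  for (ch in 1:3) img[, , ch] <- matrix(rgbm[, ch], size[1L], size[2L])
  list(image = img, mask = matrix(TRUE, size[1L], size[2L]),
    clipped_fraction = clipped)
}

#' Specification of a synthetic cohort
#'
#' @param n_images Number of images to generate.
#' @param weights Sampling weights over the Monk tones (length 10,
#'   nonnegative, at least one positive). Uniform by default.
#' @param sigma Lab channel noise standard deviation; default 2, a mild
#'   within-region texture comparable to smooth, evenly lit skin.
#' @param lighting_amplitude Amplitude of a multiplicative left-to-right L*
#'   ramp over skin regions (0 = perfectly even lighting; 0.2 means +/-10%
#'   L* across the image), emulating uneven illumination of clinical photos.
#' @param image_size `c(height, width)`; default 96 x 96.
#' @param armless_fraction Fraction of images whose label map contains no
#'   lower-arm pixels (clothing/posture), exercising the exclusion path.
#'   Exactly `round(fraction * n_images)` images are affected.
#' @param palette Reference palette supplying the class centroid colours;
#'   default [monk_palette()].
#' @param seed Mandatory RNG seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_images = 100L, weights = rep(1, 10), sigma = 2,
                           lighting_amplitude = 0, image_size = c(96L, 96L),
                           armless_fraction = 0, seed) {
  stopifnot(
    n_images >= 1L, all(weights >= 0), any(weights > 0), sigma >= 0,
    lighting_amplitude >= 0, armless_fraction >= 0, armless_fraction <= 1,
    length(image_size) == 2L, all(image_size >= 48L)
  )
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  structure(
    list(
      n_images = as.integer(n_images), weights = weights, sigma = sigma,
      lighting_amplitude = lighting_amplitude,
      image_size = as.integer(image_size),
      armless_fraction = armless_fraction,
      palette = monk_palette(), seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

# body layout, relative to an h x w canvas: two lower-arm rectangles at the
# lower left/right, one face square top-centre with the nasal bridge as a
# vertical run of landmarks 27-30 down its middle.
cohort_layout <- function(h, w) {
  arm_h <- max(10L, h %/% 5L); arm_w <- max(6L, w %/% 8L)
  face <- max(16L, h %/% 4L)
  list(
    arm_left = list(rows = (h - arm_h + 1L):h, cols = 2L:(1L + arm_w)),
    arm_right = list(rows = (h - arm_h + 1L):h, cols = (w - arm_w):(w - 1L)),
    face = list(rows = 3L:(2L + face), cols = (w - face) %/% 2L + 1L:face)
  )
}

paint_region <- function(image, rows, cols, lab, sigma, amp, w) {
  n <- length(rows) * length(cols)
  grid <- expand.grid(row = rows, col = cols)
  labm <- matrix(rep(as.numeric(lab), each = n), ncol = 3)
  if (sigma > 0) labm <- labm + matrix(stats::rnorm(3 * n, sd = sigma), ncol = 3)
  if (amp > 0) { # multiplicative lightness ramp across image columns
    ramp <- 1 + amp * ((grid$col - 1) / (w - 1) - 0.5)
    labm[, 1L] <- pmin(labm[, 1L] * ramp, 100)
  }
  rgbm <- lab_to_srgb(labm)
  for (ch in 1:3) image[cbind(grid$row, grid$col, ch)] <- rgbm[, ch]
  image
}

#' Generate a synthetic cohort with colorimetric ground truth
#'
#' For each image: a Monk tone is drawn from the spec's weights; both lower
#' arms (part labels 19/20) and a face patch with nasal-bridge landmarks
#' 27-30 are painted in that tone's reference colour plus Lab noise; the
#' gold mean Lab is the reference swatch itself, so the gold ITA and gold
#' class are exact by construction. A seeded subset of images gets a label
#' map without arm labels to exercise the exclusion path.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `records` -- one list per image with `image_id`,
#'   `image`, `parts`, `landmarks` (directly consumable by [run_batch()])
#'   plus `gold_class`, `gold_lab`, `gold_ita` -- and `gold`, a long
#'   data.frame (`image_id`, `region`, `scale`, `class`) holding gold
#'   classes on both the Monk and Fitzpatrick scales.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  h <- spec$image_size[1L]; w <- spec$image_size[2L]
  lay <- cohort_layout(h, w)
  fitz <- fitzpatrick_scale()
  pal_lab <- as.matrix(spec$palette[, c("L", "a", "b")])

  with_seed(spec$seed, {
    classes <- sample(nrow(spec$palette), spec$n_images,
      replace = TRUE, prob = spec$weights
    )
    n_armless <- round(spec$armless_fraction * spec$n_images)
    armless <- sample(spec$n_images, n_armless)

    records <- lapply(seq_len(spec$n_images), function(i) {
      k <- classes[i]
      lab_k <- pal_lab[k, ]
      image <- array(119L, c(h, w, 3L)) # neutral gray background
      parts <- matrix(0L, h, w)
      image <- paint_region(image, lay$face$rows, lay$face$cols, lab_k,
        spec$sigma, spec$lighting_amplitude, w)
      if (!(i %in% armless)) {
        image <- paint_region(image, lay$arm_left$rows, lay$arm_left$cols,
          lab_k, spec$sigma, spec$lighting_amplitude, w)
        image <- paint_region(image, lay$arm_right$rows, lay$arm_right$cols,
          lab_k, spec$sigma, spec$lighting_amplitude, w)
        parts[lay$arm_left$rows, lay$arm_left$cols] <- 19L
        parts[lay$arm_right$rows, lay$arm_right$cols] <- 20L
      }
      mid_col <- lay$face$cols[ceiling(length(lay$face$cols) / 2)]
      top_row <- lay$face$rows[3L]
      landmarks <- data.frame( # 0-based coords down the nasal bridge
        index = 27:30,
        x = rep(mid_col - 1L, 4L),
        y = (top_row - 1L) + 0:3 * 2L
      )
      list(
        image_id = sprintf("synth_%04d", i),
        image = image, parts = parts, landmarks = landmarks,
        gold_class = k, gold_lab = lab_k,
        gold_ita = unname(ita_from_lab(lab_k))
      )
    })

    gold <- do.call(rbind, lapply(records, function(r) {
      data.frame(
        image_id = r$image_id,
        region = rep(c("arm", "face"), each = 2L),
        scale = rep(c("monk", "fitzpatrick"), 2L),
        class = rep(c(r$gold_class, classify_ita(r$gold_ita, fitz)), 2L),
        gold_ita = r$gold_ita,
        stringsAsFactors = FALSE
      )
    }))
    list(records = records, gold = gold, spec = spec)
  })
}

#' Write a synthetic cohort to disk
#'
#' Materialises a cohort as PNG images, single-channel PNG label maps,
#' per-image landmark CSVs and a `gold.csv`, the same formats the pipeline
#' reads back for detector-produced data.
#'
#' @param cohort Result of [make_cohort()].
#' @param dir Output directory (created if needed).
#' @return A manifest data.frame with the file paths, invisibly; also
#'   written as `manifest.csv`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort$records, function(r) {
    ip <- file.path(dir, paste0(r$image_id, ".png"))
    pp <- file.path(dir, paste0(r$image_id, "_parts.png"))
    lp <- file.path(dir, paste0(r$image_id, "_landmarks.csv"))
    png::writePNG(r$image / 255, ip)
    png::writePNG(r$parts / 255, pp)
    utils::write.csv(r$landmarks, lp, row.names = FALSE)
    data.frame(image_id = r$image_id, image = ip, parts = pp, landmarks = lp,
      stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(cohort$gold, file.path(dir, "gold.csv"), row.names = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
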