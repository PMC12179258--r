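# -- internal helpers ---------------------------------------------------------

#' Coerce colour input to an n x 3 numeric matrix
#'
#' Accepts a length-3 vector, an n x 3 matrix/data.frame, or a character
#' vector of "#RRGGBB" hex strings.
#' @noRd
as_rgb_matrix <- function(x) {
  if (is.character(x)) {
    x <- t(grDevices::col2rgb(x))
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop("an RGB colour needs exactly 3 channels", call. = FALSE)
    x <- matrix(x, nrow = 1L)
  }
  if (ncol(x) != 3L) stop("RGB input must have 3 columns", call. = FALSE)
  storage.mode(x) <- "double"
  colnames(x) <- c("r", "g", "b")
  x
}

as_lab_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop("a Lab colour needs exactly 3 components", call. = FALSE)
    x <- matrix(x, nrow = 1L)
  }
  if (ncol(x) != 3L) stop("Lab input must have 3 columns", call. = FALSE)
  storage.mode(x) <- "double"
  colnames(x) <- c("L", "a", "b")
  x
}

# -- colour space conversion --------------------------------------------------

#' Convert 8-bit sRGB colours to CIELAB
#'
#' Uses the IEC 61966-2-1 sRGB transfer function with the D65 illuminant and
#' the 2 degree standard observer -- the universal conventions for consumer
#' digital images. These conventions matter: the Monk-scale calibration in
#' [derive_thresholds()] reproduces its published boundaries only under them.
#'
#' @param rgb A length-3 vector, an n x 3 matrix (columns r, g, b in
#'   \[0, 255\]), or a character vector of "#RRGGBB" hex strings.
#' @param white Reference white passed to the converter; "D65" (default).
#'   Exposed for completeness, but skin-tone calibration assumes D65.
#' @return An n x 3 matrix with columns `L`, `a`, `b`; `L` in \[0, 100\].
#' @examples
#' srgb_to_lab(c(255, 255, 255)) # L* = 100, neutral chroma
#' srgb_to_lab("#d7bd96")        # Monk tone 5 reference swatch
#' @export
srgb_to_lab <- function(rgb, white = "D65") {
  m <- as_rgb_matrix(rgb)
  if (anyNA(m) || any(m < 0 | m > 255)) {
    stop("RGB channels must be within [0, 255]", call. = FALSE)
  }
  lab <- farver::convert_colour(m, from = "rgb", to = "lab", white_to = white)
  colnames(lab) <- c("L", "a", "b")
  lab
}

#' Convert CIELAB colours to 8-bit sRGB
#'
#' Inverse of [srgb_to_lab()]. Out-of-gamut colours are clipped to \[0, 255\]
#' after conversion; the fraction of clipped channels is attached as the
#' `"clipped_fraction"` attribute so callers (notably the synthetic-image
#' generator) can record a gamut warning.
#'
#' @param lab A length-3 vector or n x 3 matrix (columns L, a, b).
#' @inheritParams srgb_to_lab
#' @return An n x 3 integer matrix with columns `r`, `g`, `b` in \[0, 255\].
#' @export
lab_to_srgb <- function(lab, white = "D65") {
  m <- as_lab_matrix(lab)
  rgb <- farver::convert_colour(m, from = "lab", to = "rgb", white_from = white)
  # the converter saturates at the gamut boundary; flag colours whose
  # round-trip Lab moved materially (i.e. that were actually clipped)
  back <- farver::convert_colour(rgb, from = "rgb", to = "lab", white_to = white)
  clipped <- mean(apply(abs(back - m), 1, max) > 1)
  rgb <- round(pmin(pmax(rgb, 0), 255))
  storage.mode(rgb) <- "integer"
  colnames(rgb) <- c("r", "g", "b")
  attr(rgb, "clipped_fraction") <- clipped
  rgb
}

# -- ITA ----------------------------------------------------------------------

#' Individual Typology Angle from CIELAB
#'
#' Computes ITA = arctan((L* - 50) / b*) * 180 / pi, the standard colorimetric
#' measure of constitutive skin pigmentation: higher angles are lighter skin.
#' The implementation uses the quadrant-aware two-argument arctangent of
#' (L* - 50, b*) and clamps the result to \[-90, 90\] degrees, so the function
#' is total: at b* = 0 it returns +90 for L* > 50 and -90 for L* < 50, and for
#' (non-physiological) b* < 0 it saturates at +/-90 by the sign of L* - 50.
#' L* = 50 gives 0 for every nonzero b*.
#'
#' @param lab A length-3 vector or n x 3 matrix of Lab colours.
#' @return Numeric vector of ITA values in degrees, in \[-90, 90\].
#' @examples
#' ita_from_lab(c(60, 0, 10)) # 45
#' ita_from_lab(c(40, 0, 10)) # -45
#' @export
ita_from_lab <- function(lab) {
  m <- as_lab_matrix(lab)
  ita(m[, 1L], m[, 3L])
}

#' ITA from lightness and blue-yellow chromaticity
#'
#' Vectorised core of [ita_from_lab()]; a* does not enter the formula.
#'
#' @param L Lightness L* values.
#' @param b Chromaticity b* values.
#' @return ITA in degrees, clamped to \[-90, 90\].
#' @export
ita <- function(L, b) {
  ang <- atan2(L - 50, b) * 180 / pi
  ang <- pmin(pmax(ang, -90), 90)
  # atan2(0, b < 0) is 180 degrees; the formula's ratio form gives 0 there
  ang[L == 50 & b != 0] <- 0
  unname(ang)
}

# -- regional aggregation -----------------------------------------------------

#' Mean ITA of a pixel region
#'
#' Aggregates a set of sRGB pixels into one ITA value. The default
#' (`"mean_of_itas"`) converts every pixel to Lab, computes per-pixel ITA and
#' averages the angles. The alternative (`"ita_of_mean_lab"`) averages the Lab
#' channels first and takes the ITA of the mean colour; the two differ on
#' heterogeneous regions because ITA is nonlinear in (L*, b*).
#'
#' @param pixels An n x 3 matrix of 8-bit sRGB pixels (or anything
#'   [srgb_to_lab()] accepts), or a `region_sample` from the regions module.
#' @param method Aggregation rule; see Details.
#' @return A single ITA value in degrees.
#' @export
region_ita <- function(pixels, method = c("mean_of_itas", "ita_of_mean_lab")) {
  method <- match.arg(method)
  if (inherits(pixels, "region_sample")) pixels <- pixels$pixels
  m <- as_rgb_matrix(pixels)
  if (nrow(m) == 0L) {
    stop(empty_region_error("cannot aggregate an empty pixel region"))
  }
  lab <- srgb_to_lab(m)
  switch(method,
    mean_of_itas    = mean(ita(lab[, 1L], lab[, 3L])),
    ita_of_mean_lab = ita_from_lab(colMeans(lab))
  )
}

empty_region_error <- function(msg) {
  structure(
    class = c("skintone_empty_region", "error", "condition"),
    list(message = msg, call = NULL)
  )
}
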