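# Skin tone scales: palette-driven calibration of ITA class boundaries and
# classification on the Monk (10-tone) and Fitzpatrick (6-type) scales.

#' The Monk Skin Tone Scale reference palette
#'
#' The ten sRGB reference swatches of the Monk Skin Tone Scale, tone 1
#' (lightest) to tone 10 (darkest), transcribed from the scale's public
#' definition at skintone.google and bundled as a versioned data file under
#' `inst/extdata/monk_palette.json`. Class boundaries are always recomputed
#' from this palette by [derive_thresholds()], never hard-coded.
#'
#' @return A `reference_palette`: data.frame with columns `label` and `hex`.
#' @export
monk_palette <- function() {
  read_palette(system.file("extdata", "monk_palette.json",
    package = "skintone", mustWork = TRUE
  ), name = "monk")
}

#' Read a reference palette from JSON
#'
#' A palette file is a JSON array of swatch objects, ordered lightest first,
#' each either `{"label": k, "hex": "#RRGGBB"}` or
#' `{"label": k, "lab": [L, a, b]}`.
#'
#' @param path Path to the JSON file.
#' @param name Palette name; defaults to the file stem.
#' @return A `reference_palette` data.frame with columns `label`, `hex`
#'   (NA for Lab-specified swatches) and `L`, `a`, `b`.
#' @export
read_palette <- function(path, name = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(raw) < 2L) stop("a palette needs at least 2 swatches", call. = FALSE)
  label <- vapply(raw, function(s) as.integer(s[["label"]]), integer(1))
  hex <- vapply(raw, function(s) {
    if (!is.null(s[["hex"]])) as.character(s[["hex"]]) else NA_character_
  }, character(1))
  lab <- t(vapply(raw, function(s) {
    # exact [[ indexing: $lab would partially match $label
    if (!is.null(s[["lab"]])) as.numeric(unlist(s[["lab"]])) else srgb_to_lab(s[["hex"]])[1L, ]
  }, numeric(3)))
  colnames(lab) <- c("L", "a", "b")
  pal <- data.frame(label = label, hex = hex, lab, stringsAsFactors = FALSE)
  attr(pal, "name") <- name %||% sub("\\.[^.]+$", "", basename(path))
  class(pal) <- c("reference_palette", "data.frame")
  pal
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' ITA of each palette swatch
#' @param palette A `reference_palette` (or data.frame with L, a, b columns).
#' @return Numeric vector of swatch ITA values, in palette order.
#' @export
palette_ita <- function(palette) {
  ita(palette$L, palette$b)
}

#' Calibrate a skin tone scale from a reference palette
#'
#' Computes the ITA of every reference swatch and places the boundary between
#' adjacent tones at the mean of their ITA values, giving K - 1 thresholds in
#' strictly descending order for a K-class scale. Every swatch classifies back
#' to its own class under [classify_ita()] by construction.
#'
#' @param palette A `reference_palette`, e.g. [monk_palette()].
#' @param name Scale name; defaults to the palette name.
#' @return A `skintone_scale` object: list with `name`, `K`, `labels`,
#'   `boundaries` (descending ITA thresholds) and `swatch_ita`.
#' @examples
#' monk <- derive_thresholds(monk_palette())
#' round(monk$boundaries, 2)
#' @export
derive_thresholds <- function(palette, name = NULL) {
  sw <- palette_ita(palette)
  bad <- which(diff(sw) >= 0)
  if (length(bad)) {
    stop(sprintf(
      "palette ITAs must be strictly decreasing; swatches %d (%.2f) and %d (%.2f) violate this",
      bad[1L], sw[bad[1L]], bad[1L] + 1L, sw[bad[1L] + 1L]
    ), call. = FALSE)
  }
  new_scale(
    name = name %||% attr(palette, "name") %||% "custom",
    boundaries = (sw[-length(sw)] + sw[-1L]) / 2,
    labels = as.character(palette$label),
    swatch_ita = sw
  )
}

new_scale <- function(name, boundaries, labels, swatch_ita = NULL) {
  stopifnot(length(labels) == length(boundaries) + 1L)
  if (any(diff(boundaries) >= 0)) {
    stop("scale boundaries must be strictly descending", call. = FALSE)
  }
  structure(
    list(
      name = name, K = length(labels), labels = labels,
      boundaries = as.numeric(boundaries), swatch_ita = swatch_ita
    ),
    class = "skintone_scale"
  )
}

#' @export
print.skintone_scale <- function(x, ...) {
  cat(sprintf(
    "<skintone_scale> %s: %d classes, boundaries %s\n",
    x$name, x$K, paste(sprintf("%.2f", x$boundaries), collapse = ", ")
  ))
  invisible(x)
}

#' The Monk scale with calibrated ITA boundaries
#'
#' Convenience wrapper: [derive_thresholds()] applied to [monk_palette()].
#' @return A 10-class `skintone_scale`.
#' @export
monk_scale <- function() {
  derive_thresholds(monk_palette(), name = "monk")
}

#' The Fitzpatrick scale with published ITA cut-offs
#'
#' The six Fitzpatrick phototypes (I lightest to VI darkest) with the widely
#' used ITA bands from the colorimetric literature: type I above 55, II
#' (41, 55\], III (28, 41\], IV (10, 28\], V (-30, 10\], VI at or below -30.
#' The cut-offs are overridable for sensitivity analyses; no palette backs
#' this scale, so `swatch_ita` is NULL.
#'
#' @param boundaries Descending ITA thresholds; default `c(55, 41, 28, 10, -30)`.
#' @return A 6-class `skintone_scale` with Roman-numeral labels.
#' @export
fitzpatrick_scale <- function(boundaries = c(55, 41, 28, 10, -30)) {
  new_scale("fitzpatrick", boundaries, c("I", "II", "III", "IV", "V", "VI"))
}

#' Classify ITA values on a skin tone scale
#'
#' Assigns class k when `boundaries[k] <= ita < boundaries[k - 1]` (with
#' virtual outer bounds at +/-Inf). An ITA exactly equal to a boundary thus
#' belongs to the lighter class whose interval lists it as lower bound: on the
#' Monk scale an ITA of 30.61 is tone 5, not 6. Exact boundary hits are
#' measure-zero in practice; the convention only fixes the tie.
#'
#' @param ita_values Numeric vector of ITA values in degrees.
#' @param scale A `skintone_scale`.
#' @param labels If TRUE return class labels instead of 1-based indices.
#' @return Integer class indices in \[1, K\] (or labels).
#' @examples
#' classify_ita(c(90, 0, -90), monk_scale()) # 1, 6, 10
#' @export
classify_ita <- function(ita_values, scale, labels = FALSE) {
  stopifnot(inherits(scale, "skintone_scale"))
  idx <- 1L + vapply(
    ita_values,
    function(x) if (is.na(x)) NA_integer_ else sum(scale$boundaries > x),
    integer(1)
  )
  if (labels) scale$labels[idx] else idx
}

#' Export a scale as a correlation table
#'
#' One row per class with its open upper and lower ITA bounds. The outer
#' bounds are printed as the conventional +/-100 sentinels (ITA itself cannot
#' leave \[-90, 90\]; the sentinels are cosmetic, for table fidelity).
#'
#' @param scale A `skintone_scale`.
#' @return data.frame with columns `class`, `label`, `upper_ita`, `lower_ita`.
#' @export
scale_table <- function(scale) {
  data.frame(
    class = seq_len(scale$K),
    label = scale$labels,
    upper_ita = c(100, scale$boundaries),
    lower_ita = c(scale$boundaries, -100)
  )
}

#' Write a scale's correlation table to CSV or JSON
#'
#' @param scale A `skintone_scale`.
#' @param path Output path; format chosen by extension (.csv or .json).
#' @return The path, invisibly.
#' @export
write_scale <- function(scale, path) {
  tab <- scale_table(scale)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(tab, path, digits = NA)
  } else {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}
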