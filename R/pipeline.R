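# Per-image orchestration and batch execution: region extraction -> regional
# mean ITA -> classification on every configured scale, with flag-and-continue
# handling of unusable images.

#' Pipeline run configuration
#'
#' @param aggregation How pixels aggregate to a regional ITA; see
#'   [region_ita()].
#' @param face_radius Neighbourhood half-width around each nasal-bridge
#'   landmark, in pixels; 0 samples exactly the four landmark pixels.
#' @param min_arm_pixels Arm regions with fewer pixels than this are flagged
#'   `below_min_pixels` and not classified. Images with too few detected arm
#'   pixels are excluded rather than classified from unreliable samples.
#' @param scales Named list of `skintone_scale` objects applied to every
#'   region. Defaults to the calibrated Monk scale and the Fitzpatrick scale.
#' @param exclude_ids Optional character vector of image ids excluded up
#'   front (e.g. a human-curated erythema/tattoo exclusion list; the
#'   automated pipeline cannot judge those).
#' @return A `run_config` list.
#' @export
run_config <- function(aggregation = c("mean_of_itas", "ita_of_mean_lab"),
                       face_radius = 0L,
                       min_arm_pixels = 50L,
                       scales = NULL,
                       exclude_ids = character(0)) {
  structure(
    list(
      aggregation = match.arg(aggregation),
      face_radius = as.integer(face_radius),
      min_arm_pixels = as.integer(min_arm_pixels),
      scales = scales %||% list(monk = monk_scale(), fitzpatrick = fitzpatrick_scale()),
      exclude_ids = exclude_ids
    ),
    class = "run_config"
  )
}

result_row <- function(image_id, region, pixel_count = 0L, mean_ita = NA_real_,
                       classes = NULL, config, exclusion_reason = "") {
  row <- data.frame(
    image_id = image_id, region = region,
    pixel_count = pixel_count, mean_ita = mean_ita,
    exclusion_reason = exclusion_reason, stringsAsFactors = FALSE
  )
  for (nm in names(config$scales)) {
    row[[nm]] <- if (is.null(classes)) NA_integer_ else classes[[nm]]
  }
  row[c("image_id", "region", "pixel_count", "mean_ita",
        names(config$scales), "exclusion_reason")]
}

#' Process one image
#'
#' For each region whose annotation is supplied, extracts the pixel sample,
#' computes the regional mean ITA and classifies it on every configured
#' scale. Regions that cannot be used (no detected pixels, or an arm sample
#' below the minimum pixel count) are flagged with an exclusion reason and
#' never silently dropped.
#'
#' @param image An h x w x 3 image array or a PNG path.
#' @param parts Optional part label map (matrix or PNG path) for the arm
#'   region.
#' @param landmarks Optional landmark set (data.frame or CSV path) for the
#'   face region.
#' @param config A [run_config()].
#' @param image_id Identifier used in the results table.
#' @return data.frame with one row per available region and columns
#'   `image_id`, `region`, `pixel_count`, `mean_ita`, one class column per
#'   scale, and `exclusion_reason`.
#' @export
process_image <- function(image, parts = NULL, landmarks = NULL,
                          config = run_config(), image_id = "image") {
  if (is.null(parts) && is.null(landmarks)) {
    stop("at least one of `parts` or `landmarks` is required", call. = FALSE)
  }
  if (is.character(image)) image <- read_image(image)
  if (is.character(landmarks)) landmarks <- read_landmarks(landmarks)

  samples <- list()
  if (!is.null(parts)) samples$arm <- extract_arm_pixels(image, parts)
  if (!is.null(landmarks)) {
    samples$face <- extract_face_pixels(image, landmarks, radius = config$face_radius)
  }

  rows <- lapply(names(samples), function(region) {
    s <- samples[[region]]
    reason <- s$reason %||% ""
    if (reason == "" && region == "arm" && s$pixel_count < config$min_arm_pixels) {
      reason <- "below_min_pixels"
    }
    if (reason != "" || s$pixel_count == 0L) {
      return(result_row(image_id, region, s$pixel_count,
        config = config,
        exclusion_reason = if (reason == "") "no_region" else reason
      ))
    }
    m_ita <- region_ita(s, method = config$aggregation)
    classes <- lapply(config$scales, function(sc) classify_ita(m_ita, sc))
    result_row(image_id, region, s$pixel_count, m_ita, classes, config)
  })
  do.call(rbind, rows)
}

#' Process a batch of images
#'
#' Runs [process_image()] over a manifest, in manifest order. Per-image
#' failures (unreadable files, malformed annotations) are recorded as rows
#' with an `error:` exclusion reason and the run continues. Images on the
#' config's exclusion list are flagged `excluded_by_list`.
#'
#' @param manifest Either a list of records -- each a list with `image_id`,
#'   `image`, and optional `parts` / `landmarks` entries (paths or in-memory
#'   objects) -- or a data.frame with columns of those names holding paths.
#' @param config A [run_config()].
#' @param out Optional CSV path for the results table.
#' @return The results data.frame (one block of region rows per image);
#'   attribute `"summary"` holds processed/excluded counts.
#' @export
run_batch <- function(manifest, config = run_config(), out = NULL) {
  if (is.data.frame(manifest)) {
    manifest <- lapply(seq_len(nrow(manifest)), function(i) as.list(manifest[i, ]))
  }
  if (length(manifest) == 0L) stop("empty manifest", call. = FALSE)

  rows <- lapply(manifest, function(rec) {
    id <- rec$image_id %||% "image"
    if (id %in% config$exclude_ids) {
      return(result_row(id, "all",
        config = config, exclusion_reason = "excluded_by_list"
      ))
    }
    tryCatch(
      process_image(rec$image, rec$parts, rec$landmarks, config, image_id = id),
      error = function(e) {
        result_row(id, "all",
          config = config,
          exclusion_reason = paste0("error:", conditionMessage(e))
        )
      }
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "summary") <- c(
    images = length(manifest),
    region_rows = nrow(res),
    excluded = sum(res$exclusion_reason != "")
  )
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
  res
}
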