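#' Read a whole-mount micrograph
#'
#' Reads an 8-bit grey-level TIFF or PNG micrograph into an integer matrix
#' (rows x columns, grey levels 0--255). Colour images are converted to grey
#' using the luminance weights 0.299/0.587/0.114.
#'
#' @param path path to a TIFF or PNG file.
#' @return An integer matrix of grey levels in [0, 255].
#' @export
read_micrograph <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported micrograph format: '", ext, "' (use TIFF or PNG)")
  )
  if (length(dim(arr)) == 3) {
    nc <- dim(arr)[3]
    w <- if (nc >= 3) c(0.299, 0.587, 0.114) else rep(1 / nc, nc)
    arr <- Reduce(`+`, lapply(seq_len(min(nc, 3)), function(i) arr[, , i] * w[i]))
  }
  m <- round(arr * 255)
  storage.mode(m) <- "integer"
  m
}

#' Write a micrograph matrix to file
#'
#' @param pixels integer matrix of grey levels in [0, 255].
#' @param path output path ending in .tif/.tiff or .png.
#' @return The path, invisibly.
#' @export
write_micrograph <- function(pixels, path) {
  ext <- tolower(tools::file_ext(path))
  img <- pixels / 255
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8),
    png = png::writePNG(img, path),
    stop("unsupported micrograph format: '", ext, "'")
  )
  invisible(path)
}

oocyte_record_cols <- c(
  "object_id", "diameter_um", "major_um", "minor_um", "area_um2",
  "roundness", "ellipticity", "mean_grey", "centroid_row", "centroid_col"
)

empty_oocyte_tbl <- function() {
  tbl <- stats::setNames(
    as.data.frame(matrix(numeric(0), 0, length(oocyte_record_cols))),
    oocyte_record_cols
  )
  tibble::as_tibble(tbl)
}

#' Detect candidate oocytes in a micrograph
#'
#' Segments dark objects (stained oocytes) from the light background by a
#' global grey-level threshold, fills holes, labels connected components and
#' measures one record per object. Objects touching the image border are
#' discarded because their size cannot be measured. No filtering by the
#' acceptance thresholds happens here; see \code{\link{filter_oocytes}}.
#'
#' Descriptors per object: fitted-ellipse axes from image moments (um),
#' equivalent diameter sqrt(major * minor) (um), area (um^2),
#' roundness 4A/(pi * major^2), ellipticity = area / ellipse area capped at 1,
#' mean 8-bit grey level, and the 0-based (row, col) centroid.
#'
#' @param pixels integer/numeric matrix of 8-bit grey levels, or a file path
#'   accepted by \code{\link{read_micrograph}}.
#' @param config a \code{\link{detection_config}}; supplies the segmentation
#'   grey threshold and the px/um resolution.
#' @param micrograph_id optional label attached to every record.
#' @return A tibble with one row per detected object (possibly zero rows):
#'   columns \code{object_id}, \code{diameter_um}, \code{major_um},
#'   \code{minor_um}, \code{area_um2}, \code{roundness}, \code{ellipticity},
#'   \code{mean_grey}, \code{centroid_row}, \code{centroid_col} and, if given,
#'   \code{micrograph_id}.
#' @export
detect_oocytes <- function(pixels, config = detection_config(),
                           micrograph_id = NULL) {
  stopifnot(inherits(config, "detection_config"))
  if (is.character(pixels)) pixels <- read_micrograph(pixels)
  if (!is.matrix(pixels) || length(dim(pixels)) != 2 || !is.numeric(pixels)) {
    stop("micrograph must be a 2-D numeric matrix of 8-bit grey levels")
  }
  if (length(pixels) == 0) stop("micrograph raster is empty")
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("grey levels must lie in [0, 255]")
  }

  res <- config$resolution_px_per_um
  mask <- pixels < config$max_grey
  out <- empty_oocyte_tbl()
  if (any(mask)) {
    storage.mode(mask) <- "integer"
    filled <- EBImage::fillHull(mask)
    lab <- EBImage::bwlabel(filled)
    n <- max(lab)
    if (n > 0) {
      labm <- lab
      border <- unique(c(labm[1, ], labm[nrow(labm), ], labm[, 1], labm[, ncol(labm)]))
      border <- border[border > 0]
      keep <- setdiff(seq_len(n), border)
      if (length(keep) > 0) {
        # moment-based ellipse fit per component: centroid and second
        # central moments via grouped sums; axes = 4 * sqrt(eigenvalues)
        # (full axis lengths), the standard moment-ellipse convention
        fg <- which(labm > 0)
        lv <- labm[fg]
        r <- (fg - 1) %% nrow(labm) + 1
        c_ <- (fg - 1) %/% nrow(labm) + 1
        sums <- rowsum(cbind(1, r, c_, r^2, c_^2, r * c_, pixels[fg]),
                       group = lv)
        ids <- as.integer(rownames(sums))
        area <- sums[, 1]
        mr <- sums[, 2] / area
        mc <- sums[, 3] / area
        vrr <- sums[, 4] / area - mr^2
        vcc <- sums[, 5] / area - mc^2
        vrc <- sums[, 6] / area - mr * mc
        mean_grey_all <- sums[, 7] / area
        tr <- (vrr + vcc) / 2
        det_half <- sqrt(pmax(0, ((vrr - vcc) / 2)^2 + vrc^2))
        l1 <- pmax(tr + det_half, 0)
        l2 <- pmax(tr - det_half, 0)
        sel <- match(keep, ids)
        major_px <- unname(4 * sqrt(l1[sel]))
        minor_px <- unname(4 * sqrt(l2[sel]))
        area_px <- unname(area[sel])
        ell_area_px <- pi / 4 * major_px * minor_px
        out <- tibble::tibble(
          object_id = seq_along(keep),
          diameter_um = sqrt(major_px * minor_px) / res,
          major_um = major_px / res,
          minor_um = minor_px / res,
          area_um2 = area_px / res^2,
          roundness = ifelse(major_px > 0, 4 * area_px / (pi * major_px^2), 1),
          ellipticity = ifelse(ell_area_px > 0, pmin(1, area_px / ell_area_px), 0),
          mean_grey = unname(mean_grey_all[sel]),
          centroid_row = unname(mr[sel] - 1),
          centroid_col = unname(mc[sel] - 1)
        )
      }
    }
  }
  if (!is.null(micrograph_id)) {
    out <- dplyr::mutate(out, micrograph_id = micrograph_id, .before = 1)
  }
  out
}

#' Apply the oocyte acceptance thresholds
#'
#' Flags each detected object as accepted or rejected against the size,
#' grey-tone, roundness and ellipticity thresholds. Rejected records are
#' retained with the first failing criterion recorded (checked in the order
#' size, grey, roundness, ellipticity), so totals are auditable. Row order is
#' preserved and filtering is idempotent.
#'
#' @param records tibble from \code{\link{detect_oocytes}} (extra columns are
#'   preserved).
#' @param config a \code{\link{detection_config}}.
#' @return The input tibble with logical \code{passed_filter} and character
#'   \code{rejection_reason} (\code{"none"}, \code{"size"}, \code{"grey"},
#'   \code{"roundness"} or \code{"ellipticity"}) columns replaced/added.
#' @export
filter_oocytes <- function(records, config = detection_config()) {
  stopifnot(is.data.frame(records), inherits(config, "detection_config"))
  records <- dplyr::as_tibble(records)
  if (nrow(records) == 0) {
    records$passed_filter <- logical(0)
    records$rejection_reason <- character(0)
    return(records)
  }
  size_ok <- records$diameter_um >= config$min_diameter_um &
    records$diameter_um <= config$max_diameter_um
  grey_ok <- records$mean_grey < config$max_grey
  round_ok <- records$roundness >= config$roundness_min &
    records$roundness <= config$roundness_max
  ell_ok <- records$ellipticity >= config$ellipticity_min
  reason <- rep("none", nrow(records))
  reason[!ell_ok] <- "ellipticity"
  reason[!round_ok] <- "roundness"
  reason[!grey_ok] <- "grey"
  reason[!size_ok] <- "size"
  records$passed_filter <- size_ok & grey_ok & round_ok & ell_ok
  records$rejection_reason <- reason
  records
}

#' Pool per-micrograph detections into per-fish diameters with QC flags
#'
#' Concatenates the accepted oocyte diameters across the micrographs of each
#' fish and raises quality-control flags: \code{low_count} when fewer than
#' \code{min_oocytes} accepted oocytes were photographed, and
#' \code{few_micrographs} when fewer than \code{min_micrographs} micrographs
#' contributed. The defaults encode the sampling protocol of three
#' micrographs totalling at least 200 oocytes per fish.
#'
#' @param records tibble of filtered records (needs \code{diameter_um},
#'   \code{passed_filter} and \code{micrograph_id}; a \code{fish_id} column
#'   groups multiple fish, otherwise a single fish is assumed).
#' @param min_oocytes,min_micrographs QC thresholds.
#' @return A tibble with one row per fish: \code{fish_id}, \code{n_micrographs},
#'   \code{n_oocytes}, \code{low_count}, \code{few_micrographs} and a
#'   \code{diameters} list-column of accepted diameters (um).
#' @export
merge_fish_detections <- function(records, min_oocytes = 200,
                                  min_micrographs = 3) {
  stopifnot(is.data.frame(records))
  if (!"micrograph_id" %in% names(records)) {
    stop("records need a micrograph_id column")
  }
  if (!"fish_id" %in% names(records)) records$fish_id <- "fish"
  if (!"passed_filter" %in% names(records)) records$passed_filter <- TRUE
  records |>
    dplyr::group_by(.data$fish_id) |>
    dplyr::summarise(
      n_micrographs = dplyr::n_distinct(.data$micrograph_id),
      n_oocytes = sum(.data$passed_filter),
      diameters = list(.data$diameter_um[.data$passed_filter]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      low_count = .data$n_oocytes < min_oocytes,
      few_micrographs = .data$n_micrographs < min_micrographs,
      .before = "diameters"
    )
}
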