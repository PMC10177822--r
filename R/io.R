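# Readers and writers: raster + JSON sidecar slices, CSV score/dose tables,
# JSON reports. The sidecar carries pixel spacing and the linear HU mapping
# (hu = stored * hu_slope + hu_intercept), mirroring how DICOM rescales
# stored pixel values.

#' Write a CT slice as raster plus JSON sidecar
#'
#' Two raster formats:
#' * `"raw"` (default): little-endian float64 dump, bit-exact for any HU
#'   values;
#' * `"png"`: 8-bit grayscale PNG of the rescaled values
#'   `(hu - hu_intercept) / hu_slope` rounded to 0..255 — viewable anywhere
#'   but quantized to one stored unit (`hu_slope` HU; lossless when the HU
#'   values are already multiples of `hu_slope` above `hu_intercept`).
#'
#' The sidecar `<prefix>.json` records the format, dimensions, pixel spacing,
#' HU mapping, id, and optionally a ground-truth record.
#'
#' @param image A [ct_slice()].
#' @param prefix Output path prefix (writes `<prefix>.raw` or `<prefix>.png`
#'   and `<prefix>.json`).
#' @param format `"raw"` or `"png"`.
#' @param hu_intercept,hu_slope Linear mapping between stored and HU values
#'   for the PNG format; the default covers -1024 to 1016 HU in 8 HU steps.
#' @param ground_truth Optional one-row data frame stored in the sidecar.
#' @return `prefix`, invisibly.
#' @export
write_slice <- function(image, prefix, format = c("raw", "png"),
                        hu_intercept = -1024, hu_slope = 8,
                        ground_truth = NULL) {
  format <- match.arg(format)
  if (!inherits(image, "ct_slice")) abort("`image` must be a ct_slice")
  sidecar <- list(
    format = format,
    width_px = ncol(image$pixels),
    height_px = nrow(image$pixels),
    pixel_spacing_mm = image$pixel_spacing_mm,
    hu_intercept = hu_intercept,
    hu_slope = hu_slope,
    id = image$id
  )
  if (!is.null(ground_truth)) sidecar$ground_truth <- as.list(ground_truth)
  if (format == "png") {
    stored <- round((image$pixels - hu_intercept) / hu_slope)
    if (any(stored < 0 | stored > 255)) {
      abort("HU values fall outside the representable 8-bit range for this hu_intercept/hu_slope")
    }
    png::writePNG(stored / 255, paste0(prefix, ".png"))
  } else {
    con <- file(paste0(prefix, ".raw"), "wb")
    on.exit(close(con))
    # column-major doubles, little-endian
    writeBin(as.vector(image$pixels), con, size = 8, endian = "little")
  }
  jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a CT slice written by [write_slice()]
#'
#' @param prefix Path prefix used at write time.
#' @return A [ct_slice()]; the ground truth, if present in the sidecar, is
#'   attached as attribute `"ground_truth"`.
#' @export
read_slice <- function(prefix) {
  sc_path <- paste0(prefix, ".json")
  if (!file.exists(sc_path)) abort(sprintf("sidecar not found: %s", sc_path))
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  need <- c("format", "width_px", "height_px", "pixel_spacing_mm",
            "hu_intercept", "hu_slope")
  missing_fields <- setdiff(need, names(sc))
  if (length(missing_fields)) {
    abort(sprintf("malformed sidecar: missing field(s) %s",
                  paste(missing_fields, collapse = ", ")),
          class = "ctiq_schema_error")
  }
  nr <- as.integer(sc$height_px)
  nc <- as.integer(sc$width_px)
  if (identical(sc$format, "png")) {
    stored <- png::readPNG(paste0(prefix, ".png")) * 255
    if (length(dim(stored)) == 3) stored <- stored[, , 1]
    pix <- round(stored) * sc$hu_slope + sc$hu_intercept
  } else if (identical(sc$format, "raw")) {
    con <- file(paste0(prefix, ".raw"), "rb")
    on.exit(close(con))
    pix <- matrix(readBin(con, "double", n = nr * nc, size = 8,
                          endian = "little"), nr, nc)
  } else {
    abort(sprintf("malformed sidecar: unknown format '%s'", sc$format),
          class = "ctiq_schema_error")
  }
  if (!identical(dim(pix), c(nr, nc))) {
    abort("raster dimensions disagree with the sidecar", class = "ctiq_schema_error")
  }
  out <- ct_slice(pix, sc$pixel_spacing_mm, id = sc$id %||% "slice")
  if (!is.null(sc$ground_truth)) {
    attr(out, "ground_truth") <- as_tibble(sc$ground_truth)
  }
  out
}

#' Read a rater-score CSV
#'
#' Expects a header `item, rater_1, ..., rater_k` (any k >= 2) plus an
#' optional `parameter` column; anything else is rejected with the expected
#' layout.
#'
#' @param path CSV file path.
#' @return Tibble in the [generate_rater_table()] layout.
#' @export
read_rater_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  rater_cols <- grep("^rater_\\d+$", names(df), value = TRUE)
  extra <- setdiff(names(df), c("item", "parameter", rater_cols))
  if (length(extra) || length(rater_cols) < 2 || !"item" %in% names(df)) {
    abort(sprintf(
      "unexpected rater-table header [%s]; expected: item[, parameter], rater_1, rater_2, ...",
      paste(names(df), collapse = ", ")), class = "ctiq_schema_error")
  }
  as_tibble(df)
}

#' Read a dose-record CSV
#'
#' Expects columns `exam_id, ctdivol, scan_length` with optional `dlp`
#' (validated against `ctdivol * scan_length` at 1%).
#'
#' @param path CSV file path.
#' @return Validated tibble of dose records.
#' @export
read_dose_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  extra <- setdiff(names(df), c("exam_id", "ctdivol", "scan_length", "dlp"))
  if (length(extra) || !all(c("ctdivol", "scan_length") %in% names(df))) {
    abort(sprintf(
      "unexpected dose-table header [%s]; expected: exam_id, ctdivol, scan_length[, dlp]",
      paste(names(df), collapse = ", ")), class = "ctiq_schema_error")
  }
  validate_dose_records(as_tibble(df))
}

#' Write a quality report (or any result tibble) as JSON
#'
#' Serializes the object together with its provenance and a hash of the
#' parameters so a report can be traced to the exact configuration that
#' produced it. Numeric metric fields are rounded half-up to one decimal at
#' serialization only.
#'
#' @param report A `ct_quality` object or a data frame.
#' @param path Output JSON path.
#' @param digits Decimals kept in serialized metrics (default 1).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, digits = 1) {
  if (inherits(report, "ct_quality")) {
    g <- glance(report)
    num <- vapply(g, is.numeric, logical(1))
    g[num] <- lapply(g[num], round_half_up, digits = digits)
    payload <- list(
      summary = g,
      profiles = tidy(report),
      noise_detail = report$noise_note,
      provenance = report$provenance,
      config_hash = rlang::hash(report$provenance$params)
    )
  } else {
    payload <- list(summary = as.data.frame(report),
                    config_hash = rlang::hash(report))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
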