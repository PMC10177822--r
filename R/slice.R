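#' CT slice in Hounsfield units
#'
#' Light container for a single 2D CT slice: a numeric matrix of Hounsfield
#' units plus its isotropic pixel spacing. Rows run top to bottom (y), columns
#' left to right (x); physical coordinates in mm are measured from the centre
#' of the top-left pixel, so pixel `(i, j)` sits at `x = (j-1) * spacing`,
#' `y = (i-1) * spacing`.
#'
#' @param pixels Numeric matrix of gray values (HU), all finite.
#' @param pixel_spacing_mm Isotropic pixel spacing in mm (> 0).
#' @param id Optional character label for provenance.
#' @return An object of class `ct_slice`.
#' @examples
#' sl <- ct_slice(matrix(0, 32, 32), pixel_spacing_mm = 0.5)
#' dim(sl$pixels)
#' @export
ct_slice <- function(pixels, pixel_spacing_mm, id = "slice") {
  if (!is.matrix(pixels) || !is.numeric(pixels) || any(dim(pixels) < 2)) {
    abort("`pixels` must be a numeric matrix with at least 2 rows and columns")
  }
  if (!all(is.finite(pixels))) abort("`pixels` must contain only finite HU values")
  stopifnot_scalar_num(pixel_spacing_mm, "pixel_spacing_mm", positive = TRUE)
  structure(
    list(pixels = pixels, pixel_spacing_mm = pixel_spacing_mm,
         id = as.character(id)[1]),
    class = "ct_slice"
  )
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf(
    "<ct_slice '%s'> %d x %d px @ %.4g mm (%.4g x %.4g mm), HU range [%.1f, %.1f]\n",
    x$id, nrow(x$pixels), ncol(x$pixels), x$pixel_spacing_mm,
    (ncol(x$pixels) - 1) * x$pixel_spacing_mm,
    (nrow(x$pixels) - 1) * x$pixel_spacing_mm,
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' @export
dim.ct_slice <- function(x) dim(x$pixels)

#' Tidy a CT slice into long pixel form
#'
#' @param x A [ct_slice()].
#' @param ... Unused.
#' @return A tibble with one row per pixel: `row`, `col`, `x_mm`, `y_mm`,
#'   `hu`.
#' @export
tidy.ct_slice <- function(x, ...) {
  nr <- nrow(x$pixels)
  nc <- ncol(x$pixels)
  tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    x_mm = (rep(seq_len(nc), each = nr) - 1) * x$pixel_spacing_mm,
    y_mm = (rep(seq_len(nr), times = nc) - 1) * x$pixel_spacing_mm,
    hu = as.vector(x$pixels)
  )
}

#' @rdname tidy.ct_slice
#' @export
autoplot.ct_slice <- function(x, ...) {
  df <- tidy(x)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm, fill = .data$hu)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", name = "HU") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [mm]", y = "y [mm]", title = x$id)
}
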