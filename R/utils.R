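# Shared numerical helpers. Nothing here is exported except round_half_up,
# which user code needs to reproduce printed tables from exact arithmetic.

#' Round half away from zero
#'
#' Reporting helper: rounds with ties going away from zero (so 28.5 -> 29,
#' 2.025 -> 2.03), the convention used for printed dose and metric tables.
#' Base [round()] rounds half to even, which prints 2.02 for 2.025.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(28.53)        # 29
#' round_half_up(2.02884, 2)   # 2.03
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  # tiny eps guards binary representations of exact .5 ties (e.g. 0.285 * 1000)
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

# Bilinear interpolation of a pixel-center raster at physical coordinates (mm).
# Pixel (i, j) (row, col, 1-based) sits at x = (j-1)*s, y = (i-1)*s.
# Errors if any point lies outside the raster hull by more than `tol` mm.
bilinear_sample <- function(pixels, spacing_mm, x_mm, y_mm, tol = 1e-9,
                            context = "sample point") {
  nr <- nrow(pixels)
  nc <- ncol(pixels)
  gx <- x_mm / spacing_mm
  gy <- y_mm / spacing_mm
  bad <- gx < -tol / spacing_mm | gx > (nc - 1) + tol / spacing_mm |
    gy < -tol / spacing_mm | gy > (nr - 1) + tol / spacing_mm
  if (any(bad)) {
    k <- which(bad)[1L]
    abort(sprintf(
      "%s %d at (%.3f, %.3f) mm falls outside the raster (%.3f x %.3f mm)",
      context, k, x_mm[k], y_mm[k],
      (nc - 1) * spacing_mm, (nr - 1) * spacing_mm
    ), class = "ctiq_out_of_bounds")
  }
  j0 <- pmin(pmax(floor(gx), 0), nc - 2)
  i0 <- pmin(pmax(floor(gy), 0), nr - 2)
  fx <- gx - j0
  fy <- gy - i0
  p11 <- pixels[cbind(i0 + 1, j0 + 1)]
  p12 <- pixels[cbind(i0 + 1, j0 + 2)]
  p21 <- pixels[cbind(i0 + 2, j0 + 1)]
  p22 <- pixels[cbind(i0 + 2, j0 + 2)]
  (1 - fy) * ((1 - fx) * p11 + fx * p12) + fy * ((1 - fx) * p21 + fx * p22)
}

# uniform-spacing check used by the three-point slope windows
is_uniform <- function(positions, rel_tol = 1e-6) {
  d <- diff(positions)
  if (length(d) == 0) return(TRUE)
  max(abs(d - d[1])) <= rel_tol * abs(d[1])
}

stopifnot_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0", name))
  if (nonneg && x < 0) abort(sprintf("`%s` must be >= 0", name))
  invisible(x)
}
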