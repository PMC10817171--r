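#' Construct a single-slice MR image
#'
#' Container for one 2D MR slice: a pixel matrix in arbitrary signal units
#' plus the acquisition parameters the pipeline needs (TR/TE/FA for SPGR,
#' TI for inversion recovery).
#'
#' @param pixels numeric matrix of pixel values (rows x cols), all finite.
#' @param modality one of `"IR"`, `"SPGR"`, `"other"`.
#' @param tr repetition time in ms (required and positive for SPGR).
#' @param te echo time in ms, or `NA`.
#' @param fa nominal flip angle in degrees, or `NA`.
#' @param ti inversion time in ms, or `NA` (required for IR).
#' @param pixel_spacing length-2 numeric, mm per pixel (row, col).
#' @return An object of class `image2d`.
#' @export
image2d <- function(pixels, modality = c("other", "IR", "SPGR"),
                    tr = NA_real_, te = NA_real_, fa = NA_real_,
                    ti = NA_real_, pixel_spacing = c(1, 1)) {
  modality <- match.arg(modality)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("'pixels' must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("'pixels' must have positive dimensions", call. = FALSE)
  }
  if (!all(is.finite(pixels))) {
    stop("'pixels' must be finite everywhere", call. = FALSE)
  }
  if (modality == "SPGR" && (!is.finite(tr) || tr <= 0)) {
    stop("SPGR images require tr > 0", call. = FALSE)
  }
  if (modality == "IR" && (!is.finite(ti) || ti <= 0)) {
    stop("IR images require ti > 0", call. = FALSE)
  }
  structure(
    list(pixels = pixels, modality = modality,
         tr = as.numeric(tr), te = as.numeric(te), fa = as.numeric(fa),
         ti = as.numeric(ti), pixel_spacing = as.numeric(pixel_spacing)),
    class = "image2d"
  )
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %s %dx%d  TR=%s TE=%s FA=%s TI=%s\n",
              x$modality, nrow(x$pixels), ncol(x$pixels),
              format(x$tr), format(x$te), format(x$fa), format(x$ti)))
  invisible(x)
}

#' @export
dim.image2d <- function(x) dim(x$pixels)

#' Construct an ROI polygon
#'
#' Vertices use the package-wide convention: 0-based coordinates with
#' `x` = column (increasing rightwards) and `y` = row (increasing
#' downwards). The polygon is implicitly closed.
#'
#' @param x,y numeric vertex coordinates (equal length, at least 3).
#' @return An object of class `roi_polygon`.
#' @export
roi_polygon <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("a polygon needs at least 3 vertices", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("polygon vertices must be finite", call. = FALSE)
  }
  structure(list(x = as.numeric(x), y = as.numeric(y)), class = "roi_polygon")
}

#' Polygon approximating an ellipse
#'
#' Convenience constructor used by the phantom and the replicate study to
#' turn analytic ellipse parameters into a traced contour.
#'
#' @param center length-2 `(x, y)` in 0-based pixel coordinates.
#' @param semi_axes length-2 `(a, b)` semi-axis lengths in pixels.
#' @param rotation rotation angle in radians (counter-clockwise in x/y).
#' @param n number of vertices.
#' @return An [roi_polygon()].
#' @export
ellipse_polygon <- function(center, semi_axes, rotation = 0, n = 32L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ex <- semi_axes[1] * cos(th)
  ey <- semi_axes[2] * sin(th)
  roi_polygon(
    x = center[1] + ex * cos(rotation) - ey * sin(rotation),
    y = center[2] + ex * sin(rotation) + ey * cos(rotation)
  )
}
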