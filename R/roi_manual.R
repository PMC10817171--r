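#' Rasterize a polygon to a pixel mask
#'
#' A pixel belongs to the mask iff its center lies inside the polygon under
#' the even-odd (crossing-number) rule. Pixel centers sit at integer
#' 0-based coordinates (x = column index, y = row index).
#'
#' @param poly an [roi_polygon()].
#' @param shape length-2 `(rows, cols)` of the target grid.
#' @return Logical matrix of dimension `shape`.
#' @export
rasterize_polygon <- function(poly, shape) {
  stopifnot(inherits(poly, "roi_polygon"))
  nr <- as.integer(shape[1])
  nc <- as.integer(shape[2])
  px <- poly$x
  py <- poly$y
  nv <- length(px)
  xs <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr) - 1, times = nc), nr, nc)
  inside <- matrix(FALSE, nr, nc)
  j <- nv
  for (i in seq_len(nv)) {
    xi <- px[i]; yi <- py[i]
    xj <- px[j]; yj <- py[j]
    if (yi != yj) {
      crosses <- (yi > ys) != (yj > ys)
      xcut <- (xj - xi) * (ys - yi) / (yj - yi) + xi
      flip <- crosses & (xs < xcut)
      inside[flip] <- !inside[flip]
    }
    j <- i
  }
  inside
}

#' Manual myometrial ROI: whole-uterus contour minus endometrial contour
#'
#' Implements the manual protocol: the myometrial mask is the rasterized
#' whole-uterus polygon with the rasterized endometrial polygon removed.
#' The junctional zone (inner myometrium) stays included by construction.
#'
#' @param whole polygon tracing the external myometrial contour.
#' @param endo polygon tracing the external endometrial contour.
#' @param shape length-2 `(rows, cols)`.
#' @return Logical mask.
#' @export
manual_myometrial_mask <- function(whole, endo, shape) {
  w <- rasterize_polygon(whole, shape)
  e <- rasterize_polygon(endo, shape)
  mask <- w & !e
  if (!any(mask)) {
    stop("myometrial mask is empty; whole-uterus and endometrial contours may be swapped",
         call. = FALSE)
  }
  mask
}

#' Mean quantitative T1 over an ROI
#'
#' Arithmetic mean of the valid (non-`NA`) T1-map pixels under the mask.
#' Invalid fits inside the ROI (e.g. flow voids in the myometrium) are
#' excluded, with the exclusion count attached and reported.
#'
#' @param mask logical ROI mask.
#' @param t1map a [compute_t1_map()] result (or bare numeric matrix in ms).
#' @return Mean qT1 in ms, with attributes `n_pixels` (valid pixels
#'   averaged) and `n_invalid` (masked pixels excluded as invalid).
#' @export
mean_qt1 <- function(mask, t1map) {
  t1 <- if (inherits(t1map, "t1_map")) t1map$t1 else t1map
  stopifnot(is.matrix(t1), is.logical(mask))
  if (!identical(dim(mask), dim(t1))) {
    stop("mask and T1 map shapes differ", call. = FALSE)
  }
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  vals <- t1[mask]
  bad <- is.na(vals)
  if (all(bad)) stop("all masked pixels have invalid T1", call. = FALSE)
  if (any(bad)) {
    message(sprintf("mean_qt1: excluded %d invalid pixel(s) of %d",
                    sum(bad), length(vals)))
  }
  structure(mean(vals[!bad]), n_pixels = sum(!bad), n_invalid = sum(bad))
}
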