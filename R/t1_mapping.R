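#' Two-point VFA T1 fit for a pixel
#'
#' Solves the linearised SPGR equation for two flip angles: with
#' `y_i = S_i / sin(a_i)` and `x_i = S_i / tan(a_i)` (effective angles
#' `a_i = b1 * fa_i`), the signal pairs lie on a line of slope
#' `m = E1 = exp(-TR/T1)`, so `T1 = -TR / log(m)`.
#'
#' Non-physical fits are discarded, not clipped: a slope outside (0, 1), a
#' degenerate denominator, or a T1 outside `(t1_min, t1_max]` yields `NA`.
#'
#' @param s1,s2 signal at the low / high flip angle (vectorised).
#' @param fa1,fa2 nominal flip angles in degrees, `fa1 != fa2`.
#' @param tr repetition time in ms, > 0.
#' @param b1 multiplicative flip-angle scale (vector or scalar), > 0.
#' @param t1_min,t1_max validity window in ms; fits outside are `NA`.
#' @return Numeric vector of T1 in ms, `NA` where invalid.
#' @export
fit_t1_pixel <- function(s1, s2, fa1 = 4, fa2 = 18, tr = 5, b1 = 1,
                         t1_min = 1, t1_max = 10000) {
  if (fa1 == fa2) stop("fa1 and fa2 must differ", call. = FALSE)
  if (tr <= 0) stop("tr must be > 0", call. = FALSE)
  if (any(b1 <= 0)) stop("b1 must be > 0", call. = FALSE)
  a1 <- b1 * fa1 * pi / 180
  a2 <- b1 * fa2 * pi / 180
  y1 <- s1 / sin(a1)
  y2 <- s2 / sin(a2)
  x1 <- s1 / tan(a1)
  x2 <- s2 / tan(a2)
  dx <- x2 - x1
  m <- (y2 - y1) / dx
  t1 <- -tr / log(m)
  bad <- !is.finite(m) | m <= 0 | m >= 1 | dx == 0 |
    !is.finite(t1) | t1 <= t1_min | t1 > t1_max
  t1[bad] <- NA_real_
  t1
}

#' Per-pixel T1 map from two SPGR flip-angle images
#'
#' Applies [fit_t1_pixel()] pixel by pixel to a low/high flip-angle SPGR
#' pair, with optional B1 correction. The two acquisitions must share the
#' image grid and agree on TR within 1%; the fit uses the mean TR.
#'
#' @param spgr_lo,spgr_hi [image2d()]s with modality `"SPGR"` and distinct
#'   flip angles (conventionally 4 and 18 degrees).
#' @param b1 optional B1 map: a positive matrix matching the image shape,
#'   or `NULL` for no correction (all ones).
#' @param t1_min,t1_max validity window passed to [fit_t1_pixel()].
#' @return An object of class `t1_map`: list with `t1` (matrix, ms, `NA`
#'   invalid) and provenance fields `fa1`, `fa2`, `tr`, `b1_applied`.
#' @export
compute_t1_map <- function(spgr_lo, spgr_hi, b1 = NULL,
                           t1_min = 1, t1_max = 10000) {
  stopifnot(inherits(spgr_lo, "image2d"), inherits(spgr_hi, "image2d"))
  if (spgr_lo$modality != "SPGR" || spgr_hi$modality != "SPGR") {
    stop("both inputs must have modality SPGR", call. = FALSE)
  }
  if (!identical(dim(spgr_lo$pixels), dim(spgr_hi$pixels))) {
    stop("SPGR images have different shapes", call. = FALSE)
  }
  if (abs(spgr_lo$tr - spgr_hi$tr) > 0.01 * spgr_lo$tr) {
    stop("SPGR TR values disagree by more than 1%", call. = FALSE)
  }
  if (!is.finite(spgr_lo$fa) || !is.finite(spgr_hi$fa) ||
      spgr_lo$fa == spgr_hi$fa) {
    stop("SPGR images must carry distinct flip angles", call. = FALSE)
  }
  shape <- dim(spgr_lo$pixels)
  if (is.null(b1)) {
    b1v <- 1
    b1_applied <- FALSE
  } else {
    if (!is.matrix(b1) || !identical(dim(b1), shape)) {
      stop("b1 map shape does not match the images", call. = FALSE)
    }
    if (any(b1 <= 0)) stop("b1 map must be strictly positive", call. = FALSE)
    b1v <- as.vector(b1)
    b1_applied <- TRUE
  }
  tr <- mean(c(spgr_lo$tr, spgr_hi$tr))
  t1 <- fit_t1_pixel(as.vector(spgr_lo$pixels), as.vector(spgr_hi$pixels),
                     spgr_lo$fa, spgr_hi$fa, tr, b1v, t1_min, t1_max)
  t1 <- matrix(t1, shape[1], shape[2])
  n_invalid <- sum(is.na(t1))
  if (n_invalid > 0) {
    message(sprintf("compute_t1_map: %d/%d pixels invalid (%.1f%%)",
                    n_invalid, length(t1), 100 * n_invalid / length(t1)))
  }
  structure(
    list(t1 = t1, fa1 = spgr_lo$fa, fa2 = spgr_hi$fa, tr = tr,
         b1_applied = b1_applied),
    class = "t1_map"
  )
}

#' @export
print.t1_map <- function(x, ...) {
  cat(sprintf(
    "<t1_map> %dx%d  FA %g/%g deg, TR %g ms, B1 %s; %d invalid px\n",
    nrow(x$t1), ncol(x$t1), x$fa1, x$fa2, x$tr,
    if (x$b1_applied) "corrected" else "uncorrected", sum(is.na(x$t1))))
  invisible(x)
}
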