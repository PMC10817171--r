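#' Rasterize a polygon boundary to a one-pixel contour mask
#'
#' Each polygon edge is sampled at unit steps along its major axis and
#' rounded to the nearest pixel, producing an 8-connected closed outline
#' of the traced external myometrial contour. Interior pixels are not set.
#'
#' @param poly an [roi_polygon()].
#' @param shape length-2 `(rows, cols)`.
#' @return Logical matrix marking boundary pixels.
#' @export
trace_contour_mask <- function(poly, shape) {
  stopifnot(inherits(poly, "roi_polygon"))
  nr <- as.integer(shape[1])
  nc <- as.integer(shape[2])
  px <- c(poly$x, poly$x[1])
  py <- c(poly$y, poly$y[1])
  mask <- matrix(FALSE, nr, nc)
  for (i in seq_len(length(px) - 1L)) {
    n <- max(abs(px[i + 1] - px[i]), abs(py[i + 1] - py[i]), 1)
    steps <- ceiling(n)
    t <- seq(0, 1, length.out = steps + 1L)
    xs <- round(px[i] + t * (px[i + 1] - px[i]))
    ys <- round(py[i] + t * (py[i + 1] - py[i]))
    ok <- xs >= 0 & xs < nc & ys >= 0 & ys < nr
    mask[cbind(ys[ok] + 1L, xs[ok] + 1L)] <- TRUE
  }
  if (!any(mask)) stop("contour lies entirely outside the image", call. = FALSE)
  mask
}

#' Region enclosed by a contour mask
#'
#' Pixels not reachable from the image border without crossing the contour
#' (4-connected background flood), excluding the contour itself.
#'
#' @param contour logical contour mask (8-connected closed loop).
#' @return Logical mask of strictly interior pixels.
#' @export
enclosed_region <- function(contour) {
  stopifnot(is.logical(contour), is.matrix(contour))
  outside <- flood_from_border(contour)
  !outside & !contour
}

#' Grow the endometrial ROI from a seed by adaptive intensity threshold
#'
#' Starting from the user-chosen endometrial center, the 8-connected
#' component of pixels within a relative intensity tolerance of the seed
#' intensity, `|I(p) - I(seed)| <= (t/100) * I(seed)`, is grown with the
#' tolerance stepped upward from `t = 3` in 1% increments. The largest
#' tolerance whose component still excludes every contour pixel wins,
#' maximizing the endometrial area while respecting the traced external
#' myometrial contour.
#'
#' @param ir IR [image2d()] (the high endometrium/myometrium contrast
#'   image on which the ROI is defined).
#' @param seed length-2 `(x, y)` pixel, 0-based, strictly inside the
#'   contour's enclosed region.
#' @param contour logical contour mask from [trace_contour_mask()].
#' @param t_start,t_max initial and maximal tolerance, percent.
#' @param seed_stat `"pixel"` uses the seed pixel intensity as reference;
#'   `"mean3x3"` uses the 3x3 neighbourhood mean.
#' @return List with `mask` (logical endometrial ROI) and `tolerance_pct`
#'   (the chosen tolerance `t`).
#' @export
grow_endometrial_roi <- function(ir, seed, contour, t_start = 3L,
                                 t_max = 100L,
                                 seed_stat = c("pixel", "mean3x3")) {
  stopifnot(inherits(ir, "image2d"))
  seed_stat <- match.arg(seed_stat)
  img <- ir$pixels
  nr <- nrow(img)
  nc <- ncol(img)
  if (!identical(dim(contour), dim(img))) {
    stop("contour and image shapes differ", call. = FALSE)
  }
  r <- as.integer(seed[2]) + 1L
  c <- as.integer(seed[1]) + 1L
  if (r < 1L || r > nr || c < 1L || c > nc) {
    stop("seed outside the image", call. = FALSE)
  }
  if (contour[r, c]) stop("seed lies on the contour", call. = FALSE)
  interior <- enclosed_region(contour)
  if (!interior[r, c]) {
    stop("seed is not inside the region enclosed by the contour",
         call. = FALSE)
  }
  iref <- if (seed_stat == "pixel") {
    img[r, c]
  } else {
    rr <- max(1L, r - 1L):min(nr, r + 1L)
    cc <- max(1L, c - 1L):min(nc, c + 1L)
    mean(img[rr, cc])
  }
  idx0 <- (c - 1L) * nr + r
  best <- NULL
  best_t <- NA_integer_
  for (t in seq.int(t_start, t_max)) {
    tol <- abs(img - iref) <= (t / 100) * abs(iref)
    tol[idx0] <- TRUE
    comp <- connected_component(tol, idx0)
    if (any(comp & contour)) {
      if (t == t_start) {
        stop(sprintf(
          "region already touches the contour at the initial %d%% tolerance; check seed and contour",
          t_start), call. = FALSE)
      }
      break
    }
    best <- comp
    best_t <- t
  }
  list(mask = best, tolerance_pct = best_t)
}

#' Sampling band between the endometrial ROI and the myometrial contour
#'
#' The pixels from which myometrial signal statistics are sampled: the
#' interior enclosed by the traced contour, minus the endometrial ROI and
#' the contour pixels themselves.
#'
#' @param endo logical endometrial ROI mask.
#' @param contour logical contour mask.
#' @return Logical band mask.
#' @export
band_mask <- function(endo, contour) {
  stopifnot(is.logical(endo), is.logical(contour),
            identical(dim(endo), dim(contour)))
  interior <- enclosed_region(contour)
  if (any(endo & !interior)) {
    stop("endometrial ROI extends outside the contour's enclosed region",
         call. = FALSE)
  }
  band <- interior & !endo & !contour
  if (!any(band)) stop("sampling band is empty", call. = FALSE)
  band
}

#' Retain band pixels within +/- z SD of the band mean
#'
#' Computes the band's sample mean and SD once (no iteration) and keeps the
#' pixels whose intensity deviates from the mean by at most `z` sample
#' standard deviations, boundary inclusive. With the default `z = 1.96`
#' and Gaussian band intensities this retains about 95% of the band and
#' drops flow voids and partial-volume outliers.
#'
#' @param ir IR [image2d()] supplying the intensities.
#' @param band logical band mask with at least 2 pixels.
#' @param z half-width of the retention window in SDs.
#' @return Logical myometrial mask (subset of `band`).
#' @export
filter_sd <- function(ir, band, z = 1.96) {
  stopifnot(inherits(ir, "image2d"), is.logical(band))
  if (!identical(dim(band), dim(ir$pixels))) {
    stop("band and image shapes differ", call. = FALSE)
  }
  n <- sum(band)
  if (n < 2L) {
    stop("band has fewer than 2 pixels; SD undefined", call. = FALSE)
  }
  vals <- ir$pixels[band]
  m <- mean(vals)
  s <- stats::sd(vals)
  band & (abs(ir$pixels - m) <= z * s)
}

#' Register an ROI to another sequence by exhaustive translation search
#'
#' Slides the myometrial mask over the target SPGR image across every
#' integer offset in `{-search..+search}^2` and evaluates the sum of
#' squared deviations (SSD) of the covered pixel values about the ROI
#' mean. The offset minimizing the SSD registers the IR-frame ROI onto the
#' SPGR frame: a well-placed myometrial ROI covers homogeneous muscle, so
#' within-ROI variance is smallest at the true alignment.
#'
#' @param myo logical myometrial mask (IR frame), non-empty.
#' @param spgr target SPGR [image2d()].
#' @param search half-width of the square search window in pixels.
#' @param mean_mode `"own"` measures deviations about each shifted ROI's
#'   own mean on the SPGR image; `"fixed"` uses the unshifted ROI's mean
#'   throughout.
#' @return List with `dx`, `dy` (optimal shift, x = column, y = row),
#'   and `ssd_surface` (a `(2*search+1)^2` matrix, rows = dy, cols = dx,
#'   `NA` where the shifted mask leaves the image). Ties are broken by the
#'   smallest shift magnitude, then row-major order (dy, then dx).
#' @export
optimize_shift <- function(myo, spgr, search = 10L,
                           mean_mode = c("own", "fixed")) {
  mean_mode <- match.arg(mean_mode)
  stopifnot(is.logical(myo), inherits(spgr, "image2d"))
  img <- spgr$pixels
  if (!identical(dim(myo), dim(img))) {
    stop("mask and image shapes differ", call. = FALSE)
  }
  if (!any(myo)) stop("myometrial mask is empty", call. = FALSE)
  nr <- nrow(img)
  nc <- ncol(img)
  idx <- which(myo)
  r0 <- (idx - 1L) %% nr + 1L
  c0 <- (idx - 1L) %/% nr + 1L
  offs <- seq.int(-search, search)
  surface <- matrix(NA_real_, length(offs), length(offs),
                    dimnames = list(dy = offs, dx = offs))
  mu_fixed <- mean(img[idx])
  for (iy in seq_along(offs)) {
    rr <- r0 + offs[iy]
    if (min(rr) < 1L || max(rr) > nr) next
    for (ix in seq_along(offs)) {
      cc <- c0 + offs[ix]
      if (min(cc) < 1L || max(cc) > nc) next
      vals <- img[(cc - 1L) * nr + rr]
      mu <- if (mean_mode == "own") mean(vals) else mu_fixed
      surface[iy, ix] <- sum((vals - mu)^2)
    }
  }
  if (all(is.na(surface))) {
    stop("every candidate shift places the ROI outside the image",
         call. = FALSE)
  }
  best <- which(surface <= min(surface, na.rm = TRUE), arr.ind = TRUE)
  if (nrow(best) > 1L) {
    dys <- offs[best[, 1]]
    dxs <- offs[best[, 2]]
    rad <- dxs^2 + dys^2
    ord <- order(rad, dys, dxs)
    best <- best[ord[1L], , drop = FALSE]
  }
  list(dx = offs[best[1, 2]], dy = offs[best[1, 1]], ssd_surface = surface)
}

#' Semiautomatic myometrial ROI placement and mean qT1
#'
#' End-to-end semiautomatic protocol. The user supplies only the
#' endometrial center click and a rough external myometrial contour; the
#' algorithm then (a) rasterizes the contour, (b) grows the endometrial
#' ROI by adaptive intensity tolerance, (c) samples the band between the
#' endometrial ROI and the contour, (d) keeps band pixels within +/-1.96
#' SD of the band mean as the myometrial ROI, (e) registers that ROI onto
#' the SPGR image by exhaustive translation SSD minimization, and (f)
#' averages the T1 map over the optimally placed ROI. Fully deterministic.
#'
#' @param ir IR [image2d()] (ROI-definition frame).
#' @param spgr SPGR [image2d()] used as the registration target
#'   (conventionally the high-flip-angle acquisition).
#' @param t1map [compute_t1_map()] result, in the SPGR frame.
#' @param seed length-2 `(x, y)` endometrial center, 0-based.
#' @param contour_poly [roi_polygon()] tracing the external myometrial
#'   contour on the IR image.
#' @param sd_z SD-filter half width (default 1.96).
#' @param search registration search half-width in pixels (default 10).
#' @param mean_mode SSD reference-mean mode, see [optimize_shift()].
#' @param seed_stat seed-intensity mode, see [grow_endometrial_roi()].
#' @return An object of class `semiauto_result` with fields `seed`,
#'   `contour` (input polygon), `tolerance_pct`, `endo_mask`, `band_mask`,
#'   `myo_mask` (IR frame), `optimal_shift` `(dx, dy)`, `ssd_surface`,
#'   `myo_mask_shifted` (SPGR frame) and `mean_qt1` (ms, with pixel-count
#'   attributes).
#' @export
semiauto_qt1 <- function(ir, spgr, t1map, seed, contour_poly,
                         sd_z = 1.96, search = 10L,
                         mean_mode = c("own", "fixed"),
                         seed_stat = c("pixel", "mean3x3")) {
  mean_mode <- match.arg(mean_mode)
  seed_stat <- match.arg(seed_stat)
  shape <- dim(ir$pixels)
  contour <- with_stage("trace_contour", trace_contour_mask(contour_poly, shape))
  grown <- with_stage("grow_endometrium",
                      grow_endometrial_roi(ir, seed, contour,
                                           seed_stat = seed_stat))
  band <- with_stage("band_sampling", band_mask(grown$mask, contour))
  myo <- with_stage("sd_filter", filter_sd(ir, band, z = sd_z))
  reg <- with_stage("shift_search",
                    optimize_shift(myo, spgr, search = search,
                                   mean_mode = mean_mode))
  myo_shifted <- shift_mask(myo, reg$dx, reg$dy)
  mqt1 <- with_stage("mean_qt1", mean_qt1(myo_shifted, t1map))
  structure(
    list(seed = seed, contour = contour_poly,
         tolerance_pct = grown$tolerance_pct,
         endo_mask = grown$mask, band_mask = band, myo_mask = myo,
         optimal_shift = c(dx = reg$dx, dy = reg$dy),
         ssd_surface = reg$ssd_surface,
         myo_mask_shifted = myo_shifted, mean_qt1 = mqt1),
    class = "semiauto_result"
  )
}

#' @export
print.semiauto_result <- function(x, ...) {
  cat(sprintf(
    paste0("<semiauto_result> tolerance %d%%, endo %d px, myo %d px, ",
           "shift (%d, %d), mean qT1 %.1f ms\n"),
    x$tolerance_pct, sum(x$endo_mask), sum(x$myo_mask),
    x$optimal_shift[["dx"]], x$optimal_shift[["dy"]], x$mean_qt1))
  invisible(x)
}
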