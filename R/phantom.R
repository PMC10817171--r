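#' Tissue specification for the digital phantom
#'
#' @param name tissue label (unique within a phantom).
#' @param t1 longitudinal relaxation time in ms, > 0.
#' @param m0 equilibrium signal in arbitrary units, > 0.
#' @return An object of class `tissue_spec`.
#' @export
tissue_spec <- function(name, t1, m0) {
  stopifnot_scalar_number(t1, "t1")
  stopifnot_scalar_number(m0, "m0")
  if (t1 <= 0 || m0 <= 0) stop("t1 and m0 must be > 0", call. = FALSE)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("'name' must be a non-empty string", call. = FALSE)
  }
  structure(list(name = name, t1 = t1, m0 = m0), class = "tissue_spec")
}

#' Digital uterus phantom specification
#'
#' Describes a single oblique pelvic slice: an elliptical myometrial ring
#' (outer minus inner ellipse) enclosing a brighter endometrial core, over a
#' uniform background, with optional extra-uterine confounders (bladder,
#' bowel, vessel). A smooth multiplicative B1 field and an integer
#' translation between the IR and SPGR acquisitions can be requested.
#'
#' Default tissue T1s sit inside the myometrial range observed in vivo at
#' 3 T (roughly 1200-2500 ms): myometrium 1500 ms, endometrium 2200 ms,
#' background 300 ms. Ellipse coordinates follow the package convention
#' (0-based, x = column, y = row, y increases downwards).
#'
#' @param shape length-2 integer `(rows, cols)`.
#' @param center ellipse center `(x, y)` shared by outer/inner ellipses.
#' @param outer_axes,inner_axes semi-axes `(a, b)` of the outer and inner
#'   myometrial ellipses in pixels; the region between them is myometrium.
#' @param rotation ellipse rotation in radians.
#' @param endo_axes semi-axes of the endometrial ellipse; defaults to
#'   `inner_axes` so the endometrium fills the cavity. Must fit strictly
#'   inside `inner_axes`.
#' @param myometrium,endometrium,background [tissue_spec()]s.
#' @param confounders list of extra shapes, each a list with fields
#'   `center`, `axes`, optional `rotation`, and `tissue` (a [tissue_spec()]).
#' @param noise_sd default acquisition noise SD in signal units (>= 0);
#'   individual simulators may override it.
#' @param b1_range length-2 bounds of the smooth multiplicative B1 field.
#' @param ir_to_spgr_shift integer `(dx, dy)` translation applied to the
#'   SPGR acquisitions relative to the IR frame; components within +/-10 so
#'   the registration search window can recover it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L),
                         center = c(63.5, 55),
                         outer_axes = c(30, 22),
                         inner_axes = c(16, 11),
                         rotation = 0.3,
                         endo_axes = inner_axes,
                         myometrium = tissue_spec("myometrium", 1500, 1000),
                         endometrium = tissue_spec("endometrium", 2200, 1000),
                         background = tissue_spec("background", 300, 800),
                         confounders = default_confounders(),
                         noise_sd = 0,
                         b1_range = c(1, 1),
                         ir_to_spgr_shift = c(0L, 0L)) {
  if (length(shape) != 2L || any(shape < 16)) {
    stop("'shape' must be two dimensions of at least 16", call. = FALSE)
  }
  if (any(inner_axes >= outer_axes)) {
    stop("inner ellipse must lie strictly inside the outer ellipse",
         call. = FALSE)
  }
  if (any(endo_axes > inner_axes)) {
    stop("endometrium must fit inside the myometrium inner ellipse",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (length(b1_range) != 2L || any(b1_range <= 0) ||
      b1_range[1] > b1_range[2]) {
    stop("'b1_range' must be positive increasing bounds", call. = FALSE)
  }
  shift <- ir_to_spgr_shift
  if (length(shift) != 2L || any(shift != round(shift))) {
    stop("'ir_to_spgr_shift' must be two integers", call. = FALSE)
  }
  if (any(abs(shift) > 10)) {
    stop("|shift components| must be <= 10 (registration search window)",
         call. = FALSE)
  }
  tissues <- c(list(myometrium, endometrium, background),
               lapply(confounders, `[[`, "tissue"))
  names <- vapply(tissues, `[[`, "", "name")
  if (anyDuplicated(names)) {
    stop("tissue names must be unique within a phantom", call. = FALSE)
  }
  structure(
    list(shape = as.integer(shape), center = center,
         outer_axes = outer_axes, inner_axes = inner_axes,
         rotation = rotation, endo_axes = endo_axes,
         myometrium = myometrium, endometrium = endometrium,
         background = background, confounders = confounders,
         noise_sd = noise_sd, b1_range = b1_range,
         ir_to_spgr_shift = as.integer(shift)),
    class = "phantom_spec"
  )
}

#' Default extra-uterine confounders
#'
#' A urine-filled bladder (long T1), a bowel loop (short T1) and a small
#' vessel (blood-like T1), all kept at least 11 px from the image border so
#' every shift in the +/-10 px registration window stays in bounds.
#'
#' @return List of confounder shapes for [phantom_spec()].
#' @export
default_confounders <- function() {
  list(
    list(center = c(63.5, 104), axes = c(14, 9), rotation = 0,
         tissue = tissue_spec("bladder", 4000, 1000)),
    list(center = c(22, 24), axes = c(8, 8), rotation = 0,
         tissue = tissue_spec("bowel", 600, 900)),
    list(center = c(104, 22), axes = c(3, 3), rotation = 0,
         tissue = tissue_spec("vessel", 1700, 1200))
  )
}

ellipse_mask <- function(shape, center, axes, rotation = 0) {
  nr <- shape[1]
  nc <- shape[2]
  xs <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr) - 1, times = nc), nr, nc)
  dx <- xs - center[1]
  dy <- ys - center[2]
  u <- (dx * cos(rotation) + dy * sin(rotation)) / axes[1]
  v <- (-dx * sin(rotation) + dy * cos(rotation)) / axes[2]
  u * u + v * v <= 1
}

#' Render a phantom to per-pixel ground truth
#'
#' Produces the per-pixel T1 / M0 / B1 maps, the tissue label map and the
#' per-tissue masks. Rendering is deterministic: the `seed` argument is
#' accepted for API symmetry with the simulators but all randomness lives
#' in the acquisition simulation, not the anatomy.
#'
#' @param spec a [phantom_spec()].
#' @param seed unused; kept so phantom construction and simulation share a
#'   call signature.
#' @return An object of class `phantom_truth` with fields `t1_map_true`,
#'   `m0_map`, `b1_map`, `labels` (integer matrix with a `levels`
#'   attribute), `masks` (named list of logical matrices) and `spec`.
#' @export
make_phantom <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  outer <- ellipse_mask(shape, spec$center, spec$outer_axes, spec$rotation)
  inner <- ellipse_mask(shape, spec$center, spec$inner_axes, spec$rotation)
  endo <- ellipse_mask(shape, spec$center, spec$endo_axes, spec$rotation)
  if (any(endo & !inner)) {
    stop("endometrium region extends outside the myometrium inner ellipse",
         call. = FALSE)
  }
  if (!any(outer & !inner)) {
    stop("myometrial ring is empty", call. = FALSE)
  }

  tissues <- list(spec$background, spec$myometrium, spec$endometrium)
  labels <- matrix(1L, shape[1], shape[2])
  for (cf in spec$confounders) {
    rot <- if (is.null(cf$rotation)) 0 else cf$rotation
    m <- ellipse_mask(shape, cf$center, cf$axes, rot)
    if (any(m & outer)) {
      stop(sprintf("confounder '%s' overlaps the uterus", cf$tissue$name),
           call. = FALSE)
    }
    tissues <- c(tissues, list(cf$tissue))
    labels[m] <- length(tissues)
  }
  labels[outer & !inner] <- 2L   # myometrial ring
  labels[inner] <- 1L            # cavity not claimed by endometrium
  labels[endo] <- 3L
  # any cavity gap between endometrium and ring keeps background tissue

  tnames <- vapply(tissues, `[[`, "", "name")
  t1s <- vapply(tissues, `[[`, 0, "t1")
  m0s <- vapply(tissues, `[[`, 0, "m0")
  t1_map <- matrix(t1s[labels], shape[1], shape[2])
  m0_map <- matrix(m0s[labels], shape[1], shape[2])
  masks <- lapply(seq_along(tissues), function(i) labels == i)
  names(masks) <- tnames
  attr(labels, "levels") <- tnames

  # Smooth radial B1 field: maximal at the uterus center, scaled into
  # b1_range at the largest center-to-corner distance.
  nr <- shape[1]; nc <- shape[2]
  xs <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr) - 1, times = nc), nr, nc)
  r2 <- (xs - spec$center[1])^2 + (ys - spec$center[2])^2
  b1 <- spec$b1_range[2] - (spec$b1_range[2] - spec$b1_range[1]) *
    r2 / max(r2, 1)

  structure(
    list(t1_map_true = t1_map, m0_map = m0_map, b1_map = b1,
         labels = labels, masks = masks, spec = spec),
    class = "phantom_truth"
  )
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %dx%d, tissues: %s\n",
              nrow(x$labels), ncol(x$labels),
              paste(attr(x$labels, "levels"), collapse = ", ")))
  invisible(x)
}

spgr_signal <- function(m0, t1, fa_deg, tr, b1 = 1) {
  a <- b1 * fa_deg * pi / 180
  e1 <- exp(-tr / t1)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

ir_signal <- function(m0, t1, ti) {
  m0 * abs(1 - 2 * exp(-ti / t1))
}

#' Simulate a spoiled gradient echo acquisition of a phantom
#'
#' Pixel values follow the standard SPGR steady-state signal
#' `S = M0 sin(a_eff) (1 - E1) / (1 - E1 cos(a_eff))` with
#' `E1 = exp(-TR/T1)` and `a_eff = B1 * a_nominal`. The phantom's
#' IR-to-SPGR translation is applied (the SPGR frame is shifted relative
#' to the IR frame), then i.i.d. Gaussian noise of SD `noise_sd` is added.
#'
#' @param truth a [make_phantom()] result.
#' @param fa_deg nominal flip angle in degrees, > 0.
#' @param tr repetition time in ms, > 0.
#' @param noise_sd Gaussian noise SD in signal units; defaults to the
#'   phantom spec's `noise_sd`.
#' @param seed RNG seed for the noise (ignored when `noise_sd` is 0).
#' @return An [image2d()] with modality `"SPGR"`.
#' @export
simulate_spgr <- function(truth, fa_deg, tr = 5, noise_sd = NULL,
                          seed = NULL) {
  stopifnot(inherits(truth, "phantom_truth"))
  stopifnot_scalar_number(fa_deg, "fa_deg")
  stopifnot_scalar_number(tr, "tr")
  if (fa_deg <= 0 || tr <= 0) stop("fa_deg and tr must be > 0", call. = FALSE)
  if (is.null(noise_sd)) noise_sd <- truth$spec$noise_sd

  s <- spgr_signal(truth$m0_map, truth$t1_map_true, fa_deg, tr, truth$b1_map)
  shift <- truth$spec$ir_to_spgr_shift
  if (any(shift != 0L)) {
    bg <- truth$spec$background
    fill <- spgr_signal(bg$m0, bg$t1, fa_deg, tr,
                        mean(range(truth$spec$b1_range)))
    s <- shift_matrix(s, shift[1], shift[2], fill)
  }
  if (noise_sd > 0) {
    s <- s + with_seed(seed, matrix(stats::rnorm(length(s), 0, noise_sd),
                                    nrow(s), ncol(s)))
  }
  image2d(s, "SPGR", tr = tr, te = 2.5, fa = fa_deg)
}

#' Simulate an inversion-recovery acquisition of a phantom
#'
#' Magnitude IR signal under the long-TR approximation,
#' `S = M0 |1 - 2 exp(-TI/T1)|`. The IR image defines the reference frame:
#' no inter-sequence shift is applied here.
#'
#' @param truth a [make_phantom()] result.
#' @param ti inversion time in ms, > 0 (default 200 ms, the high
#'   endometrium/myometrium contrast setting).
#' @param noise_sd Gaussian noise SD; defaults to the spec's `noise_sd`.
#' @param seed RNG seed for the noise.
#' @return An [image2d()] with modality `"IR"` carrying TI metadata.
#' @export
simulate_ir <- function(truth, ti = 200, noise_sd = NULL, seed = NULL) {
  stopifnot(inherits(truth, "phantom_truth"))
  stopifnot_scalar_number(ti, "ti")
  if (ti <= 0) stop("ti must be > 0", call. = FALSE)
  if (is.null(noise_sd)) noise_sd <- truth$spec$noise_sd
  s <- ir_signal(truth$m0_map, truth$t1_map_true, ti)
  if (noise_sd > 0) {
    s <- s + with_seed(seed, matrix(stats::rnorm(length(s), 0, noise_sd),
                                    nrow(s), ncol(s)))
  }
  image2d(s, "IR", tr = 7800, te = 10, ti = ti)
}

shift_matrix <- function(m, dx, dy, fill) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Translate an image by an integer pixel offset
#'
#' Content moves by `+dx` columns (rightwards) and `+dy` rows (downwards);
#' pixels shifted in from outside the grid take `fill`.
#'
#' @param image an [image2d()].
#' @param dx,dy integer shifts, each within +/-10.
#' @param fill value for pixels entering from outside (default 0).
#' @return A shifted [image2d()] with unchanged metadata.
#' @export
apply_shift <- function(image, dx, dy, fill = 0) {
  stopifnot(inherits(image, "image2d"))
  if (!is_count(dx) || !is_count(dy)) {
    stop("dx and dy must be integers", call. = FALSE)
  }
  if (abs(dx) > 10 || abs(dy) > 10) {
    stop("|dx| and |dy| must be <= 10", call. = FALSE)
  }
  out <- image
  out$pixels <- shift_matrix(image$pixels, as.integer(dx), as.integer(dy),
                             fill)
  out
}

#' Translate a logical mask by an integer pixel offset
#'
#' @param mask logical matrix.
#' @param dx,dy integer shifts.
#' @return Shifted logical matrix; pixels entering from outside are FALSE.
#' @export
shift_mask <- function(mask, dx, dy) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!is_count(dx) || !is_count(dy)) {
    stop("dx and dy must be integers", call. = FALSE)
  }
  shift_matrix(mask, as.integer(dx), as.integer(dy), FALSE)
}
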