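#' End-to-end phantom reproducibility study
#'
#' Simulates the full observer study on digital uterus phantoms: for each
#' synthetic subject one IR acquisition and one two-flip-angle SPGR pair
#' are simulated (with noise, a smooth B1 field and a random integer
#' IR-to-SPGR misregistration), and three ROI input sets are derived —
#' observer 1 session 1, observer 1 session 2, and observer 2 — by
#' jittering the traced contours (Gaussian SD `jitter_sd` per vertex) and
#' the endometrial seed click. Both the manual and semiautomatic pipelines
#' are run on every input set, giving interobserver (observer 1 vs 2) and
#' intraobserver (session 1 vs 2) measurement tables per method, which are
#' then compared with the full agreement battery.
#'
#' Subject anatomy varies around the defaults: myometrial T1 is drawn from
#' a truncated normal centred at 1500 ms within the physiological
#' 1200-2500 ms span, the endometrium sits 900 ms above it, and ellipse
#' geometry is mildly randomized. Acquisition noise defaults to 2% of the
#' myometrial low-flip-angle SPGR signal.
#'
#' @param n number of synthetic subjects (default 23).
#' @param seed integer seed controlling every random draw.
#' @param jitter_sd SD of the per-vertex contour jitter in pixels.
#' @param noise_frac acquisition noise as a fraction of the myometrial
#'   low-FA SPGR signal.
#' @param shift_max maximal |component| of the random IR-to-SPGR shift.
#' @return An object of class `replicate_report`: per-method interobserver
#'   and intraobserver [measurement_table()]s, the four
#'   [agreement_report()]s, and the [compare_methods()] results
#'   (`inter_comparison`, `intra_comparison`), plus the `seed` and
#'   configuration used.
#' @export
replicate_study <- function(n = 23L, seed = 7L, jitter_sd = 2,
                            noise_frac = 0.02, shift_max = 3L) {
  measurements <- with_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      out[[i]] <- simulate_subject(jitter_sd, noise_frac, shift_max)
    }
    out
  })
  get_tbl <- function(method, a, b) {
    measurement_table(
      vapply(measurements, function(m) m[[method]][[a]], 0),
      vapply(measurements, function(m) m[[method]][[b]], 0),
      labels = c(a, b)
    )
  }
  man_inter <- get_tbl("manual", "obs1_s1", "obs2")
  man_intra <- get_tbl("manual", "obs1_s1", "obs1_s2")
  semi_inter <- get_tbl("semiauto", "obs1_s1", "obs2")
  semi_intra <- get_tbl("semiauto", "obs1_s1", "obs1_s2")
  structure(
    list(
      n = n, seed = seed,
      config = list(jitter_sd = jitter_sd, noise_frac = noise_frac,
                    shift_max = shift_max),
      true_t1 = vapply(measurements, `[[`, 0, "true_t1"),
      manual_inter = man_inter, manual_intra = man_intra,
      semiauto_inter = semi_inter, semiauto_intra = semi_intra,
      reports = list(
        manual_inter = agreement_report(man_inter, "manual interobserver"),
        manual_intra = agreement_report(man_intra, "manual intraobserver"),
        semiauto_inter = agreement_report(semi_inter,
                                          "semiautomatic interobserver"),
        semiauto_intra = agreement_report(semi_intra,
                                          "semiautomatic intraobserver")
      ),
      inter_comparison = compare_methods(man_inter, semi_inter),
      intra_comparison = compare_methods(man_intra, semi_intra)
    ),
    class = "replicate_report"
  )
}

# One synthetic subject: anatomy, acquisitions and six measurements.
# Runs inside the caller's seeded RNG stream.
simulate_subject <- function(jitter_sd, noise_frac, shift_max) {
  myo_t1 <- min(max(stats::rnorm(1, 1500, 200), 1200), 2500)
  center <- c(63.5, 55) + stats::runif(2, -3, 3)
  outer_axes <- c(stats::runif(1, 26, 32), stats::runif(1, 19, 23))
  inner_axes <- outer_axes * stats::runif(1, 0.48, 0.55)
  rotation <- stats::runif(1, -0.4, 0.4)
  shift <- as.integer(round(stats::runif(2, -shift_max, shift_max)))
  myo <- tissue_spec("myometrium", myo_t1, 1000)
  noise_sd <- noise_frac * spgr_signal(myo$m0, myo$t1, 4, 5)
  spec <- phantom_spec(
    center = center, outer_axes = outer_axes, inner_axes = inner_axes,
    rotation = rotation,
    myometrium = myo,
    endometrium = tissue_spec("endometrium", myo_t1 + 900, 1000),
    noise_sd = noise_sd,
    b1_range = c(0.95, 1.02),
    ir_to_spgr_shift = shift
  )
  truth <- make_phantom(spec)
  seeds <- sample.int(2^31 - 1L, 3L)
  ir <- simulate_ir(truth, seed = seeds[1])
  spgr_lo <- simulate_spgr(truth, 4, 5, seed = seeds[2])
  spgr_hi <- simulate_spgr(truth, 18, 5, seed = seeds[3])
  # B1 correction uses the true field in the SPGR frame, as a measured
  # B1 map would be acquired alongside the SPGR images
  b1 <- shift_matrix(truth$b1_map, shift[1], shift[2],
                     mean(spec$b1_range))
  t1map <- suppressMessages(compute_t1_map(spgr_lo, spgr_hi, b1 = b1))

  outer_poly <- ellipse_polygon(center, outer_axes, rotation, n = 28L)
  endo_poly <- ellipse_polygon(center, spec$endo_axes, rotation, n = 20L)

  one_observer <- function() {
    jit <- function(p) {
      roi_polygon(p$x + stats::rnorm(length(p$x), 0, jitter_sd),
                  p$y + stats::rnorm(length(p$y), 0, jitter_sd))
    }
    whole_j <- jit(outer_poly)
    endo_j <- jit(endo_poly)
    seed_px <- round(center + stats::rnorm(2, 0, jitter_sd))
    manual <- suppressMessages(
      mean_qt1(manual_myometrial_mask(whole_j, endo_j, dim(ir$pixels)),
               t1map))
    semi <- suppressMessages(
      semiauto_qt1(ir, spgr_hi, t1map, seed_px, whole_j))
    list(manual = as.numeric(manual), semi = semi$mean_qt1)
  }
  o1a <- one_observer()
  o1b <- one_observer()
  o2 <- one_observer()
  list(
    true_t1 = myo_t1,
    manual = list(obs1_s1 = o1a$manual, obs1_s2 = o1b$manual,
                  obs2 = o2$manual),
    semiauto = list(obs1_s1 = as.numeric(o1a$semi),
                    obs1_s2 = as.numeric(o1b$semi),
                    obs2 = as.numeric(o2$semi))
  )
}

#' @export
print.replicate_report <- function(x, ...) {
  cat(sprintf("<replicate_report> n = %d phantom subjects, seed %d\n",
              x$n, x$seed))
  cat("interobserver:\n")
  print(x$inter_comparison)
  cat("intraobserver:\n")
  print(x$intra_comparison)
  invisible(x)
}
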