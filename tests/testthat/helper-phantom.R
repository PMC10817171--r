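# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk.

default_truth <- function(...) {
  make_phantom(phantom_spec(...))
}

outer_contour_poly <- function(spec, n = 28L) {
  ellipse_polygon(spec$center, spec$outer_axes, spec$rotation, n = n)
}

# Simulate a complete noiseless, registered acquisition set.
simulate_study <- function(spec = phantom_spec(), seed = 1L) {
  truth <- make_phantom(spec)
  list(
    spec = spec,
    truth = truth,
    ir = simulate_ir(truth, seed = seed),
    spgr_lo = simulate_spgr(truth, 4, 5, seed = seed + 1L),
    spgr_hi = simulate_spgr(truth, 18, 5, seed = seed + 2L)
  )
}
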