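# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive (per-point loops, aov(), dynamic programming) so they
# share no code path with the package implementation they check.

# Scalar even-odd point-in-polygon test (classic pnpoly).
oracle_point_in_polygon <- function(px, py, x, y) {
  n <- length(px)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((py[i] > y) != (py[j] > y) &&
        x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i]) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_rasterize <- function(poly, shape) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (r in seq_len(shape[1])) {
    for (c in seq_len(shape[2])) {
      m[r, c] <- oracle_point_in_polygon(poly$x, poly$y, c - 1, r - 1)
    }
  }
  m
}

# Exact two-sided signed-rank p-value from the full W distribution
# (generating-function enumeration over all 2^n sign assignments).
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  stopifnot(!anyDuplicated(abs(d)))
  w_obs <- sum(rk[d > 0])
  wmax <- n * (n + 1) / 2
  counts <- c(1, rep(0, wmax))  # counts[w + 1] = #assignments with W = w
  for (r in seq_len(n)) {
    shifted <- c(rep(0, r), counts)[seq_along(counts)]
    counts <- counts + shifted
  }
  probs <- counts / 2^n
  p_le <- sum(probs[seq_len(w_obs + 1)])
  p_ge <- sum(probs[(w_obs + 1):length(probs)])
  min(1, 2 * min(p_le, p_ge))
}

# ICC(2,k) from aov() mean squares (two-way ANOVA on long data).
oracle_icc2k_aov <- function(v1, v2) {
  n <- length(v1)
  long <- data.frame(
    y = c(v1, v2),
    subject = factor(rep(seq_len(n), 2)),
    rater = factor(rep(1:2, each = n))
  )
  tab <- summary(stats::aov(y ~ subject + rater, data = long))[[1]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (msc - mse) / n)
}

# Naive per-shift SSD surface (double loop, own-mean deviations).
oracle_ssd_surface <- function(myo, img, search = 10L) {
  nr <- nrow(img)
  nc <- ncol(img)
  idx <- which(myo, arr.ind = TRUE)
  offs <- seq.int(-search, search)
  surface <- matrix(NA_real_, length(offs), length(offs))
  for (iy in seq_along(offs)) {
    for (ix in seq_along(offs)) {
      rr <- idx[, 1] + offs[iy]
      cc <- idx[, 2] + offs[ix]
      if (any(rr < 1 | rr > nr | cc < 1 | cc > nc)) next
      vals <- numeric(nrow(idx))
      for (k in seq_len(nrow(idx))) vals[k] <- img[rr[k], cc[k]]
      surface[iy, ix] <- sum((vals - mean(vals))^2)
    }
  }
  surface
}

# Seeded flood fill at a fixed relative tolerance (recursive frontier,
# 8-connectivity) for checking the region grower.
oracle_flood <- function(img, seed_rc, iref, tol_frac) {
  nr <- nrow(img)
  nc <- ncol(img)
  ok <- abs(img - iref) <= tol_frac * abs(iref)
  ok[seed_rc[1], seed_rc[2]] <- TRUE
  comp <- matrix(FALSE, nr, nc)
  stack <- list(seed_rc)
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (comp[p[1], p[2]]) next
    comp[p[1], p[2]] <- TRUE
    for (dr in -1:1) {
      for (dc in -1:1) {
        r <- p[1] + dr
        c <- p[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            ok[r, c] && !comp[r, c]) {
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  comp
}
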