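# Internal helpers shared across modules.

# Evaluate `expr` with a temporary RNG state seeded from `seed`, restoring
# the caller's RNG afterwards so library code never perturbs user simulations.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Re-raise any error from `expr` with a pipeline stage label so composed
# pipelines report which step failed.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

# 8-connected component of `mask` containing linear index `start`.
# Vectorised frontier expansion on the linear index grid.
connected_component <- function(mask, start) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  stopifnot(mask[start])
  comp <- matrix(FALSE, nr, nc)
  comp[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    r <- (frontier - 1L) %% nr + 1L
    c <- (frontier - 1L) %/% nr + 1L
    rr <- c(r - 1L, r - 1L, r - 1L, r, r, r + 1L, r + 1L, r + 1L)
    cc <- c(c - 1L, c, c + 1L, c - 1L, c + 1L, c - 1L, c, c + 1L)
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    cand <- unique((cc[ok] - 1L) * nr + rr[ok])
    cand <- cand[mask[cand] & !comp[cand]]
    comp[cand] <- TRUE
    frontier <- cand
  }
  comp
}

# Region reachable from the image border through non-blocked pixels
# (4-connectivity, so it cannot slip diagonally through an 8-connected
# contour). Used to define the interior enclosed by a contour mask.
flood_from_border <- function(blocked) {
  nr <- nrow(blocked)
  nc <- ncol(blocked)
  visited <- matrix(FALSE, nr, nc)
  border <- c(
    seq_len(nr),                       # first column
    (nc - 1L) * nr + seq_len(nr),      # last column
    (seq_len(nc) - 1L) * nr + 1L,      # first row
    (seq_len(nc) - 1L) * nr + nr       # last row
  )
  frontier <- unique(border[!blocked[border]])
  visited[frontier] <- TRUE
  while (length(frontier)) {
    r <- (frontier - 1L) %% nr + 1L
    c <- (frontier - 1L) %/% nr + 1L
    rr <- c(r - 1L, r + 1L, r, r)
    cc <- c(c, c, c - 1L, c + 1L)
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    cand <- unique((cc[ok] - 1L) * nr + rr[ok])
    cand <- cand[!blocked[cand] & !visited[cand]]
    visited[cand] <- TRUE
    frontier <- cand
  }
  visited
}
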