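# Independent oracles and shared fixtures for the test suite.

# Dynamic-programming oracle for the minimum-cost column-monotone path
# through a probability map, including the auxiliary probability-1 entry and
# exit columns. Written independently of the package's Dijkstra solver:
# plain R, forward DP over columns. Returns the optimal rows (ties resolved
# to the lexicographically smallest row sequence via a cost-to-go table) and
# the total path cost.
dp_boundary_oracle <- function(P, wmin = 1e-5) {
  H <- nrow(P); W <- ncol(P)
  # cost-to-go from each real vertex (r, c) to the sink
  g <- matrix(0, H, W)
  # exit: edge (r, W) -> right aux row b (|b - r| <= 1), then descend to H
  for (r in 1:H) {
    bs <- max(1, r - 1):min(H, r + 1)
    g[r, W] <- min((1 - P[r, W] + wmin) + (H - bs) * wmin)
  }
  if (W > 1) {
    for (cc in (W - 1):1) {
      for (r in 1:H) {
        rs <- max(1, r - 1):min(H, r + 1)
        g[r, cc] <- min(2 - (P[r, cc] + P[rs, cc + 1]) + wmin + g[rs, cc + 1])
      }
    }
  }
  # entry: descend left aux to row a, edge a -> r (|r - a| <= 1)
  entry <- vapply(1:H, function(r) {
    as_ <- max(1, r - 1):min(H, r + 1)
    min((as_ - 1) * wmin + (1 - P[r, 1] + wmin))
  }, 0)
  total <- min(entry + g[, 1])
  tol <- 1e-9 * (1 + abs(total))
  rows <- integer(W)
  r <- which(abs(entry + g[, 1] - total) <= tol)[1]
  rows[1] <- r
  if (W > 1) {
    for (cc in 1:(W - 1)) {
      rs <- max(1, r - 1):min(H, r + 1)
      step <- 2 - (P[r, cc] + P[rs, cc + 1]) + wmin + g[rs, cc + 1]
      r <- rs[which(abs(step - g[r, cc]) <= tol)[1]]
      rows[cc + 1] <- r
    }
  }
  list(rows = rows - 1L, cost = total)   # rows 0-based like the solver
}

# total cost of a given 0-based row path under the package's graph model
path_cost <- function(P, rows, wmin = 1e-5) {
  H <- nrow(P); W <- ncol(P)
  r <- rows + 1L
  entry <- min(((max(1, r[1] - 1):min(H, r[1] + 1)) - 1) * wmin) +
    (1 - P[r[1], 1] + wmin)
  interior <- 0
  if (W > 1)
    for (cc in 1:(W - 1))
      interior <- interior + 2 - (P[r[cc], cc] + P[r[cc + 1], cc + 1]) + wmin
  exit <- (1 - P[r[W], W] + wmin) +
    min((H - (max(1, r[W] - 1):min(H, r[W] + 1))) * wmin)
  entry + interior + exit
}

# hand-rolled 3x3 vertical Sobel correlation with replicate padding, used as
# the oracle for the package's boundary-map conversion
sobel_oracle <- function(x) {
  h <- nrow(x); w <- ncol(x)
  pad <- x[c(1, 1:h, h), c(1, 1:w, w)]
  k <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)  # columns of the kernel
  out <- matrix(0, h, w)
  for (r in 1:h)
    for (cc in 1:w)
      out[r, cc] <- sum(k * pad[r:(r + 2), cc:(cc + 2)])
  out
}

# --------------------------------------------------------------------------
# fixtures

# flat noise-free phantom: exact recovery is attainable for both pipelines
flat_fixture <- function(seed = 3L, size = 64L) {
  pp <- phantom_params_scaled(size, size, speckle_level = 0,
                              shadow_count = 0L, missing_margin = 0L,
                              curvature_amplitude = 0,
                              mean_depths = c(15, 26, 38) * size / 64,
                              seed = seed)
  b <- generate_boundaries(pp)
  scan <- render_bscan(pp, b, identifier = "flat_fixture")
  list(params = pp, boundaries = b, scan = scan)
}

# gently curved noise-free phantom (long boundary step runs)
curved_fixture <- function(seed = 3L, size = 64L) {
  pp <- phantom_params_scaled(size, size, speckle_level = 0,
                              shadow_count = 0L, missing_margin = 0L,
                              curvature_amplitude = 2,
                              curvature_smoothness = 60, seed = seed)
  b <- generate_boundaries(pp)
  scan <- render_bscan(pp, b, identifier = "curved_fixture")
  list(params = pp, boundaries = b, scan = scan)
}

as_dataset <- function(entries_train, entries_val) {
  structure(list(train = entries_train, validation = entries_val),
            class = "oct_dataset")
}

fixture_entry <- function(fx, pid = 1, id = "fx") {
  list(scan = fx$scan, boundaries = fx$boundaries, participant = pid,
       id = id)
}

round_half_up <- octseg:::round_half_up
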