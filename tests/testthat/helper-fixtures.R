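# Shared fixtures: control-point constructors and an independent
# finite-difference curvature oracle.

# Control points whose base curvature (s = 0) is exactly `kappa`:
# P0 = B, P1 = B + (d,0,0), P2 = B + (2d, 2 d^2 kappa, 0).
make_cp <- function(kappa, base = c(0, 0, 0), d = 5) {
  list(
    p0 = base,
    p1 = base + c(d, 0, 0),
    p2 = base + c(2 * d, 2 * d^2 * kappa, 0)
  )
}

# One frame-table row for a whisker with given base curvature.
make_frame_row <- function(time_ms, trial_id, whisker_id, kappa, base_x = 0) {
  cp <- make_cp(kappa, base = c(base_x, 0, 0))
  tibble::tibble(
    time_ms = time_ms, trial_id = trial_id, whisker_id = whisker_id,
    p0x = cp$p0[1], p0y = cp$p0[2], p0z = cp$p0[3],
    p1x = cp$p1[1], p1y = cp$p1[2], p1z = cp$p1[3],
    p2x = cp$p2[1], p2y = cp$p2[2], p2z = cp$p2[3]
  )
}

# Finite-difference curvature on a dense (n-point) sampling of the Bezier
# curve; independent of the closed-form path (uses only bezier_point()).
# Snaps s to the nearest interior grid point and returns both that grid
# value and the curvature there.
fd_curvature <- function(p0, p1, p2, s, n = 1e4) {
  h <- 1 / (n - 1)
  i <- max(2, min(n - 1, round(s / h) + 1))
  s0 <- (i - 1) * h
  b <- bezier_point(p0, p1, p2, c(s0 - h, s0, s0 + h))
  d1 <- (b[3, ] - b[1, ]) / (2 * h)
  d2 <- (b[3, ] - 2 * b[2, ] + b[1, ]) / h^2
  cr <- c(
    d1[2] * d2[3] - d1[3] * d2[2],
    d1[3] * d2[1] - d1[1] * d2[3],
    d1[1] * d2[2] - d1[2] * d2[1]
  )
  list(s = s0, kappa = sqrt(sum(cr^2)) / sqrt(sum(d1^2))^3)
}

# Random proper rotation matrix.
random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Small deterministic two-whisker touch table.
demo_touches <- function() {
  tibble::tibble(
    trial_id = c(1, 1, 1, 2),
    whisker_id = c("C1", "C2", "C1", "C1"),
    onset_ms = c(100, 250, 400, 150),
    offset_ms = c(140, 300, 450, 200),
    strength = c(0.05, -0.02, 0.03, 0.04),
    abs_strength = c(0.05, 0.02, 0.03, 0.04)
  )
}
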