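#' Evaluate a quadratic Bezier curve
#'
#' A tracked whisker is represented as a quadratic 3D Bezier curve
#' \eqn{b(s) = (1-s)^2 P_0 + 2s(1-s) P_1 + s^2 P_2}, where \eqn{P_0} is the
#' control point closest to the whisker base and \eqn{0 \le s \le 1}
#' parameterises location along the curve.
#'
#' @param p0,p1,p2 Numeric length-3 vectors: the control points, in mm.
#'   `p0` is the point closest to the whisker base.
#' @param s Curve parameter(s) in \[0, 1\]. May be a vector.
#' @return A numeric matrix with one row per value of `s` and columns
#'   `x`, `y`, `z` (mm).
#' @examples
#' bezier_point(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0), s = c(0, 0.5, 1))
#' @export
bezier_point <- function(p0, p1, p2, s) {
  check_control_point(p0, "p0")
  check_control_point(p1, "p1")
  check_control_point(p2, "p2")
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1)) {
    stop("`s` must lie in [0, 1].", call. = FALSE)
  }
  b <- outer((1 - s)^2, p0) + outer(2 * s * (1 - s), p1) + outer(s^2, p2)
  colnames(b) <- c("x", "y", "z")
  b
}

#' Closed-form 3D curvature of a quadratic Bezier whisker
#'
#' Computes \eqn{\kappa_{3D}(s) = |b'(s) \times b''(s)| / |b'(s)|^3}, the
#' reciprocal of the radius of the osculating circle, in 1/mm. The intrinsic
#' shape of a quadratic curve is fully described by this curvature function,
#' which is the proxy used throughout for whisker bending (and hence, up to a
#' stiffness factor, for bending moment at the base).
#'
#' For a quadratic curve \eqn{b'(s) = 2[(1-s)(P_1-P_0) + s(P_2-P_1)]} and
#' \eqn{b''(s) = 2(P_0 - 2P_1 + P_2)} is constant, so the cross product has a
#' closed form. If the tangent vanishes at `s` (pathological tracking output:
#' all control points coincident or mirrored) curvature is reported as 0 with
#' a warning.
#'
#' @inheritParams bezier_point
#' @return Numeric vector of curvatures (1/mm), one per value of `s`.
#' @examples
#' # straight whisker: zero curvature everywhere
#' bezier_curvature(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), s = 0.3)
#' # bent whisker, curvature at the base
#' bezier_curvature(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0), s = 0)
#' @export
bezier_curvature <- function(p0, p1, p2, s) {
  check_control_point(p0, "p0")
  check_control_point(p1, "p1")
  check_control_point(p2, "p2")
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1)) {
    stop("`s` must lie in [0, 1].", call. = FALSE)
  }
  # b'(s) = 2[(1-s) d1 + s d2], b'' = 2 (d2 - d1)
  d1 <- p1 - p0
  d2 <- p2 - p1
  dd <- 2 * (d2 - d1)
  db <- 2 * (outer(1 - s, d1) + outer(s, d2))
  cr <- cbind(
    db[, 2] * dd[3] - db[, 3] * dd[2],
    db[, 3] * dd[1] - db[, 1] * dd[3],
    db[, 1] * dd[2] - db[, 2] * dd[1]
  )
  speed <- sqrt(rowSums(db^2))
  k <- numeric(length(s))
  degen <- speed == 0
  if (any(degen)) {
    warning("Degenerate tangent (|b'(s)| = 0); reporting curvature 0.",
      call. = FALSE
    )
  }
  ok <- !degen
  k[ok] <- sqrt(rowSums(cr[ok, , drop = FALSE]^2)) / speed[ok]^3
  k
}

check_control_point <- function(p, name) {
  if (!is.numeric(p) || length(p) != 3L || any(!is.finite(p))) {
    stop(sprintf("`%s` must be a finite numeric length-3 point.", name),
      call. = FALSE
    )
  }
  invisible(p)
}

frame_cols <- c(
  "p0x", "p0y", "p0z", "p1x", "p1y", "p1z", "p2x", "p2y", "p2z"
)

check_frames <- function(frames) {
  need <- c("time_ms", "trial_id", "whisker_id", frame_cols)
  missing <- setdiff(need, names(frames))
  if (length(missing) > 0) {
    stop(
      "`frames` is missing columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(frames)
}

#' Per-frame curvature at the whisker base
#'
#' Adds a `kappa` column (1/mm) to a frame table, evaluating the closed-form
#' Bezier curvature at parameter `s` (default the whisker base, `s = 0`,
#' where bending during pole contact is expressed).
#'
#' @param frames A data frame with one row per whisker per 1 kHz video frame:
#'   columns `time_ms`, `trial_id`, `whisker_id`, and control points
#'   `p0x,p0y,p0z,p1x,p1y,p1z,p2x,p2y,p2z` (mm).
#' @param s Curve parameter at which curvature is evaluated, default 0.
#' @return The input as a tibble with a `kappa` column appended.
#' @export
compute_curvature <- function(frames, s = 0) {
  check_frames(frames)
  p0 <- as.matrix(frames[, c("p0x", "p0y", "p0z")])
  p1 <- as.matrix(frames[, c("p1x", "p1y", "p1z")])
  p2 <- as.matrix(frames[, c("p2x", "p2y", "p2z")])
  d1 <- p1 - p0
  d2 <- p2 - p1
  db <- 2 * ((1 - s) * d1 + s * d2)
  dd <- 2 * (d2 - d1)
  cr <- cbind(
    db[, 2] * dd[, 3] - db[, 3] * dd[, 2],
    db[, 3] * dd[, 1] - db[, 1] * dd[, 3],
    db[, 1] * dd[, 2] - db[, 2] * dd[, 1]
  )
  speed <- sqrt(rowSums(db^2))
  kappa <- ifelse(speed == 0, 0, sqrt(rowSums(cr^2)) / speed^3)
  dplyr::mutate(tibble::as_tibble(frames), kappa = kappa)
}

#' Resting curvature per whisker per trial
#'
#' The contact-free reference curvature \eqn{\kappa_{3D,0}} against which
#' touch-induced bending is measured. For each whisker in each trial it is the
#' median of base curvature \eqn{\kappa_{3D}(0)} over all frames of that trial
#' during which the whisker is not in contact with the pole; the median is
#' robust to occasional tracking noise.
#'
#' @inheritParams compute_curvature
#' @param touches A data frame of touch events with columns `trial_id`,
#'   `whisker_id`, `onset_ms`, `offset_ms`. Frames of a whisker falling in any
#'   of its own closed contact intervals `[onset_ms, offset_ms]` are excluded.
#' @return A tibble with columns `trial_id`, `whisker_id`, `kappa_rest`
#'   (1/mm) and `n_free_frames`.
#' @export
rest_curvature <- function(frames, touches, s = 0) {
  fr <- compute_curvature(frames, s = s)
  tw <- dplyr::select(
    touches, "trial_id", "whisker_id", "onset_ms", "offset_ms"
  )
  fr <- dplyr::left_join(
    fr,
    dplyr::mutate(tw, .contact = TRUE),
    by = dplyr::join_by(
      "trial_id", "whisker_id",
      time_ms >= onset_ms, time_ms <= offset_ms
    )
  )
  free <- dplyr::filter(fr, is.na(.data$.contact))
  out <- dplyr::summarise(
    dplyr::group_by(free, .data$trial_id, .data$whisker_id),
    kappa_rest = stats::median(.data$kappa),
    n_free_frames = dplyr::n(),
    .groups = "drop"
  )
  out
}

#' Signed curvature change of a contact frame
#'
#' \eqn{\Delta\kappa_{3D}(s) = \kappa_{3D}(s) - \kappa_{3D,0}(s)}: curvature
#' during contact minus resting curvature. The curvature function itself is
#' unsigned; the difference is signed and can be negative when contact
#' straightens the whisker (direction of touch).
#'
#' @inheritParams bezier_point
#' @param kappa_rest Resting curvature \eqn{\kappa_{3D,0}} (1/mm) for the
#'   same whisker, estimated from contact-free frames.
#' @return Signed curvature change (1/mm).
#' @export
delta_kappa <- function(p0, p1, p2, kappa_rest, s = 0) {
  if (length(kappa_rest) != 1L || !is.finite(kappa_rest) || kappa_rest < 0) {
    stop("`kappa_rest` must be a single non-negative finite value.",
      call. = FALSE
    )
  }
  bezier_curvature(p0, p1, p2, s) - kappa_rest
}

#' Touch strength from tracked frames
#'
#' The strength of each touch is the mean of \eqn{\Delta\kappa_{3D}} at the
#' whisker base (`s = 0`) over the 5 ms interval following touch onset —
#' the half-open window `[onset, onset + 5)`, i.e. exactly 5 frames at the
#' 1 kHz frame rate.
#'
#' @inheritParams rest_curvature
#' @param rest Optional precomputed output of [rest_curvature()]; computed
#'   from `frames` and `touches` when `NULL`.
#' @param window_ms Length of the averaging window after onset, default 5.
#' @return `touches` as a tibble with `strength` (signed, 1/mm) and
#'   `abs_strength` columns appended.
#' @export
touch_strength <- function(frames, touches, rest = NULL, window_ms = 5) {
  if (is.null(rest)) rest <- rest_curvature(frames, touches)
  fr <- compute_curvature(frames, s = 0)
  tt <- tibble::as_tibble(touches)
  tt$.touch_row <- seq_len(nrow(tt))
  joined <- dplyr::inner_join(
    dplyr::select(
      tt, ".touch_row", "trial_id", "whisker_id", "onset_ms"
    ),
    dplyr::select(fr, "trial_id", "whisker_id", "time_ms", "kappa"),
    by = dplyr::join_by("trial_id", "whisker_id", onset_ms <= time_ms),
    relationship = "many-to-many"
  )
  joined <- dplyr::filter(joined, .data$time_ms < .data$onset_ms + window_ms)
  got <- dplyr::summarise(
    dplyr::group_by(joined, .data$.touch_row),
    n_frames = dplyr::n(),
    kappa_mean = mean(.data$kappa),
    .groups = "drop"
  )
  tt2 <- dplyr::left_join(tt, got, by = ".touch_row")
  bad <- is.na(tt2$n_frames) | tt2$n_frames < window_ms
  if (any(bad)) {
    stop(
      "Missing frames in the strength window for touches at onset(s) ",
      paste(utils::head(tt2$onset_ms[bad], 5), collapse = ", "),
      " ms (need every frame in [onset, onset+", window_ms, ")).",
      call. = FALSE
    )
  }
  tt2 <- dplyr::left_join(
    tt2, rest,
    by = c("trial_id", "whisker_id")
  )
  if (any(is.na(tt2$kappa_rest))) {
    miss <- unique(tt2$whisker_id[is.na(tt2$kappa_rest)])
    stop(
      "No resting-curvature estimate for whisker(s): ",
      paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  out <- dplyr::mutate(
    tt2,
    strength = .data$kappa_mean - .data$kappa_rest,
    abs_strength = abs(.data$strength)
  )
  dplyr::select(
    out, -".touch_row", -"n_frames", -"kappa_mean", -"kappa_rest",
    -dplyr::any_of("n_free_frames")
  )
}

#' Whisker-base displacement and speed over the touch-onset window
#'
#' Base displacement \eqn{D_b} is the Euclidean distance between the whisker
#' base (control point 0) at touch onset (`t = 0`) and 5 ms later (`t = 5`);
#' base speed is \eqn{D_b / \Delta t}, proportional to whisker speed at
#' contact.
#'
#' @inheritParams rest_curvature
#' @param dt_ms Interval between the two base samples, default 5 ms.
#' @return `touches` as a tibble with `base_displacement` (mm) and
#'   `base_speed` (mm/ms) columns appended.
#' @export
base_kinematics <- function(frames, touches, dt_ms = 5) {
  check_frames(frames)
  fr <- dplyr::select(
    tibble::as_tibble(frames),
    "trial_id", "whisker_id", "time_ms", "p0x", "p0y", "p0z"
  )
  tt <- tibble::as_tibble(touches)
  tt$.touch_row <- seq_len(nrow(tt))
  t0 <- dplyr::inner_join(
    dplyr::select(tt, ".touch_row", "trial_id", "whisker_id", "onset_ms"),
    fr,
    by = dplyr::join_by("trial_id", "whisker_id", onset_ms == time_ms)
  )
  t5 <- dplyr::inner_join(
    dplyr::mutate(
      dplyr::select(tt, ".touch_row", "trial_id", "whisker_id", "onset_ms"),
      t5 = .data$onset_ms + dt_ms
    ),
    fr,
    by = dplyr::join_by("trial_id", "whisker_id", t5 == time_ms)
  )
  both <- dplyr::inner_join(
    dplyr::select(t0, ".touch_row", x0 = "p0x", y0 = "p0y", z0 = "p0z"),
    dplyr::select(t5, ".touch_row", x5 = "p0x", y5 = "p0y", z5 = "p0z"),
    by = ".touch_row"
  )
  if (nrow(both) < nrow(tt)) {
    stop("Missing base frames at onset or onset+", dt_ms, " ms for ",
      nrow(tt) - nrow(both), " touch(es).",
      call. = FALSE
    )
  }
  both <- dplyr::mutate(
    both,
    base_displacement = sqrt((.data$x5 - .data$x0)^2 +
      (.data$y5 - .data$y0)^2 + (.data$z5 - .data$z0)^2),
    base_speed = .data$base_displacement / dt_ms
  )
  out <- dplyr::left_join(
    tt,
    dplyr::select(both, ".touch_row", "base_displacement", "base_speed"),
    by = ".touch_row"
  )
  dplyr::select(out, -".touch_row")
}
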