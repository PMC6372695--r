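#' Circular helix polyline
#'
#' Points on the helix `(r cos t, r sin t, c t)` at uniform arc-length
#' spacing. Its Frenet curvature is `r / (r^2 + c^2)` and torsion
#' `c / (r^2 + c^2)` (positive: right-handed for `c > 0`), which makes the
#' helix the analytic oracle for every discrete estimator and for end-to-end
#' tracing checks. `c = 0` degenerates to a circle (zero torsion).
#'
#' @param r Helix radius, micrometres (> 0).
#' @param c Pitch parameter, micrometres per radian (rise = `2 pi c` per
#'   turn); sign sets the handedness.
#' @param turns Number of full turns.
#' @param spacing Arc-length spacing of the returned points, micrometres.
#' @return Matrix of points (columns x, y, z).
#' @export
make_helix <- function(r, c = 0, turns = 2, spacing = 0.2) {
  stopifnot(r > 0, spacing > 0, turns > 0)
  speed <- sqrt(r^2 + c^2)
  tt <- seq(0, 2 * pi * turns, by = spacing / speed)
  cbind(x = r * cos(tt), y = r * sin(tt), z = c * tt)
}

#' Analytic curvature and torsion of a circular helix
#' @rdname make_helix
#' @export
helix_curvature <- function(r, c = 0) r / (r^2 + c^2)

#' @rdname make_helix
#' @export
helix_torsion <- function(r, c = 0) c / (r^2 + c^2)

#' Tortuosity parameters for the random neurite generator
#'
#' The generator is a correlated random walk: at each step of length
#' `step_length` the direction is rotated by a turning angle drawn as the
#' absolute value of a zero-mean normal, about an axis perpendicular to the
#' current direction. The discrete (Menger) curvature contributed by a
#' turning angle `theta` over steps of length `h` is exactly
#' `2 sin(theta / 2) / h`, so the turning-angle spread is calibrated by
#' solving `E[2 sin(theta / 2)] / h = target_mean_curvature` (numerical
#' expectation over the folded normal); the realised mean curvature is then
#' unbiased for the target. `turning_sd = 0` (or `target_mean_curvature = 0`)
#' gives a straight line.
#'
#' `chirality_bias = 0` draws the azimuth of the turning axis uniformly, so
#' left- and right-handed twists are equally likely and the expected signed
#' torsion is zero (achiral). A non-zero bias in `[-1, 1]` mixes in a
#' consistent per-step twist of the turning plane, biasing torsion toward
#' the corresponding handedness.
#'
#' @param step_length Step (inter-node spacing), micrometres.
#' @param target_mean_curvature Desired expected discrete curvature,
#'   micrometres^-1; calibrated to `turning_sd` when the latter is `NULL`.
#' @param turning_sd SD of the (pre-folding) turning angle, radians;
#'   overrides calibration when given.
#' @param chirality_bias Scalar in `[-1, 1]`; 0 is achiral.
#' @return A list of class `tortuosity_params`.
#' @export
tortuosity_params <- function(step_length = 0.5,
                              target_mean_curvature = 0.4,
                              turning_sd = NULL, chirality_bias = 0) {
  stopifnot(step_length > 0, abs(chirality_bias) <= 1)
  if (is.null(turning_sd)) {
    stopifnot(target_mean_curvature >= 0)
    turning_sd <- calibrate_turning_sd(target_mean_curvature, step_length)
  }
  structure(list(step_length = step_length,
                 target_mean_curvature = target_mean_curvature,
                 turning_sd = turning_sd, chirality_bias = chirality_bias),
            class = "tortuosity_params")
}

# solve E[2 |sin(theta/2)|] / h = kappa for the folded-normal scale sigma.
# |sin| because a rotation by theta > pi turns the direction by 2 pi - theta:
# the chord (Menger) curvature of a step pair is 2 |sin(theta/2)| / h for any
# rotation angle. The expectation approaches 4/pi as sigma grows, so targets
# with kappa * h beyond ~1.27 are unreachable at that step length.
calibrate_turning_sd <- function(kappa, h) {
  if (kappa <= 0) return(0)
  target <- kappa * h
  expected <- function(sigma) {
    if (sigma == 0) return(0)
    t <- seq(0, max(12 * sigma, pi), length.out = 20001)
    f <- 2 * abs(sin(t / 2)) * 2 * dnorm(t, sd = sigma)
    sum((f[-1] + f[-length(f)]) / 2) * (t[2] - t[1])
  }
  if (target >= expected(3) - 1e-3) {
    abort("target curvature unreachable at this step length")
  }
  # the map sigma -> E is smooth and strictly increasing on (0, 3]; invert
  # once on a dense grid and interpolate (cached per step length)
  key <- format(h, digits = 15)
  inv <- .calibration_cache[[key]]
  if (is.null(inv)) {
    sig <- seq(1e-6, 3, length.out = 600)
    ex <- vapply(sig, expected, numeric(1))
    inv <- stats::splinefun(ex, sig, method = "hyman")
    .calibration_cache[[key]] <- inv
  }
  inv(target)
}

.calibration_cache <- new.env(parent = emptyenv())

#' Generate a tortuous neurite polyline
#'
#' Correlated random walk with calibrated turning-angle spread (see
#' [tortuosity_params()]); reproducible for a fixed seed.
#'
#' @param params A [tortuosity_params()].
#' @param length Total arc length, micrometres (>= 2 steps).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param start Start position (length-3).
#' @param initial_direction Unit start direction; random when `NULL`.
#' @return Matrix of node positions (columns x, y, z), spaced
#'   `params$step_length` apart.
#' @export
make_tortuous_neurite <- function(params, length, seed = NULL,
                                  start = c(0, 0, 0),
                                  initial_direction = NULL) {
  stopifnot(inherits(params, "tortuosity_params"),
            length >= 2 * params$step_length)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, make_tortuous_neurite(
      params, length, seed = NULL, start = start,
      initial_direction = initial_direction)))
  }
  h <- params$step_length
  n_steps <- max(2L, as.integer(round(length / h)))
  if (is.null(initial_direction)) {
    v <- rnorm(3)
    d <- v / sqrt(sum(v^2))
  } else {
    d <- initial_direction / sqrt(sum(initial_direction^2))
  }
  # orthonormal frame transported along the walk
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  n1 <- ref - sum(ref * d) * d
  n1 <- n1 / sqrt(sum(n1^2))
  n2 <- cross3v(d, n1)
  pts <- matrix(0, n_steps + 1, 3)
  pts[1, ] <- start
  phi <- runif(1, -pi, pi)
  b <- params$chirality_bias
  for (i in seq_len(n_steps)) {
    theta <- if (params$turning_sd > 0) abs(rnorm(1, sd = params$turning_sd))
             else 0
    dphi <- (1 - abs(b)) * runif(1, -pi, pi) + b * pi / 3
    phi <- phi + dphi
    axis <- cos(phi) * n1 + sin(phi) * n2
    d_new <- rotate_about(d, axis, theta)
    pts[i + 1, ] <- pts[i, ] + h * d_new
    # parallel-transport the frame
    n1 <- n1 - sum(n1 * d_new) * d_new
    nrm <- sqrt(sum(n1^2))
    if (nrm < 1e-12) {
      ref <- if (abs(d_new[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      n1 <- ref - sum(ref * d_new) * d_new
      nrm <- sqrt(sum(n1^2))
    }
    n1 <- n1 / nrm
    n2 <- cross3v(d_new, n1)
    d <- d_new
  }
  colnames(pts) <- c("x", "y", "z")
  pts
}

cross3v <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Rodrigues rotation of vector v by angle about a unit axis
rotate_about <- function(v, axis, angle) {
  v * cos(angle) + cross3v(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}
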