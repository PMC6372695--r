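#' Tracing parameters
#'
#' All values the automatic tracer needs but that are not dictated by the
#' data: they are explicit and tunable, with defaults calibrated on tube
#' phantoms of known geometry. Lengths in micrometres unless noted.
#'
#' @param gvf_mu Gradient-vector-flow regularisation weight (must satisfy
#'   `mu <= 1/6` for the explicit 3D diffusion update to be stable).
#' @param gvf_iterations Diffusion iterations.
#' @param step March step of the tracer, micrometres; `NULL` means 2 voxels.
#' @param intensity_stop Stop tracing when the interpolated intensity falls
#'   below this; `NULL` estimates background + 2 x noise SD from the volume
#'   (median and MAD).
#' @param max_turn_per_step Largest allowed direction change per step,
#'   radians.
#' @param min_trace_length Chains shorter than this are discarded.
#' @param seed_spacing Minimum spacing between seed points.
#' @param seed_threshold Brightness a voxel must exceed to seed a trace;
#'   `NULL` estimates median + 6 x MAD, high enough that pure noise never
#'   seeds but any tube with usable contrast does.
#' @param recentre_radius Radius of the perpendicular-plane intensity
#'   centroid used to re-centre each step; `NULL` means 6 voxels.
#' @param max_radius Largest radius probed by the radius estimator.
#' @return A list of class `trace_params`.
#' @export
trace_params <- function(gvf_mu = 0.1, gvf_iterations = 80, step = NULL,
                         intensity_stop = NULL, max_turn_per_step = 0.6,
                         min_trace_length = 2, seed_spacing = 2,
                         seed_threshold = NULL,
                         recentre_radius = NULL, max_radius = 2) {
  stopifnot(gvf_mu > 0, gvf_mu <= 1 / 6, gvf_iterations >= 1)
  structure(list(gvf_mu = gvf_mu, gvf_iterations = gvf_iterations,
                 step = step, intensity_stop = intensity_stop,
                 max_turn_per_step = max_turn_per_step,
                 min_trace_length = min_trace_length,
                 seed_spacing = seed_spacing,
                 seed_threshold = seed_threshold,
                 recentre_radius = recentre_radius,
                 max_radius = max_radius),
            class = "trace_params")
}

shift3 <- function(a, axis, by) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  n <- d[axis]
  # replicate-boundary shift
  if (by == 1) idx[[axis]] <- c(1, seq_len(n - 1))
  else if (by == -1) idx[[axis]] <- c(seq_len(n - 1) + 1, n)
  else abort("by must be +/- 1")
  do.call(`[`, c(list(a), idx))
}

laplacian3 <- function(a) {
  shift3(a, 1, 1) + shift3(a, 1, -1) +
    shift3(a, 2, 1) + shift3(a, 2, -1) +
    shift3(a, 3, 1) + shift3(a, 3, -1) - 6 * a
}

grad3 <- function(a) {
  list(x = (shift3(a, 1, -1) - shift3(a, 1, 1)) / 2,
       y = (shift3(a, 2, -1) - shift3(a, 2, 1)) / 2,
       z = (shift3(a, 3, -1) - shift3(a, 3, 1)) / 2)
}

# 3D Sobel gradient: central difference along one axis, triangular
# smoothing (1 2 1) along the two others
sobel3d <- function(a) {
  sm <- function(v, axis) (shift3(v, axis, 1) + 2 * v +
                             shift3(v, axis, -1)) / 4
  df <- function(v, axis) (shift3(v, axis, -1) - shift3(v, axis, 1)) / 2
  list(x = df(sm(sm(a, 2), 3), 1),
       y = df(sm(sm(a, 1), 3), 2),
       z = df(sm(sm(a, 1), 2), 3))
}

#' Gradient vector flow of a volume
#'
#' Diffuses the intensity gradient field by the standard explicit iteration
#' minimising the gradient-vector-flow energy: far from edges the field is
#' smoothed (Laplacian term, weight `mu`), near edges it is anchored to the
#' raw gradient. On bright tubes the resulting vectors point toward the
#' centerline from both sides and vanish on it, which is the centerline
#' evidence the seed finder exploits.
#'
#' @param vol A `phantom_volume` or plain 3D array.
#' @param mu Regularisation weight.
#' @param iterations Number of diffusion steps.
#' @return A list of class `vector_field` with arrays `u`, `v`, `w` and the
#'   normalised source volume `f`.
#' @export
compute_gvf <- function(vol, mu = 0.1, iterations = 80) {
  a <- if (inherits(vol, "phantom_volume")) vol$data else vol
  if (length(dim(a)) != 3) abort("compute_gvf needs a 3D volume")
  if (any(!is.finite(a))) abort("non-finite intensities")
  rng <- range(a)
  f <- if (diff(rng) > 0) (a - rng[1]) / diff(rng) else a * 0
  g <- grad3(f)
  b <- g$x^2 + g$y^2 + g$z^2
  u <- g$x; v <- g$y; w <- g$z
  for (it in seq_len(iterations)) {
    u <- u + mu * laplacian3(u) - b * (u - g$x)
    v <- v + mu * laplacian3(v) - b * (v - g$y)
    w <- w + mu * laplacian3(w) - b * (w - g$z)
  }
  structure(list(u = u, v = v, w = w, f = f), class = "vector_field")
}

#' Seed points for tracing
#'
#' Candidate centerline voxels are bright voxels where the gradient-vector-
#' flow magnitude is a local minimum within the 26-neighbourhood (the field
#' vanishes on a tube's axis and points inward on its flanks). Candidates
#' are thinned greedily, brightest first, to at least `seed_spacing` apart,
#' and masked voxels are excluded.
#'
#' @param field A [compute_gvf()] result.
#' @param vol The source `phantom_volume` (or array plus `voxel_size`).
#' @param params A [trace_params()].
#' @param mask Optional logical array of voxels excluded from seeding.
#' @param voxel_size Required when `vol` is a bare array.
#' @return A tibble of seed points: voxel indices `i, j, k`, world
#'   coordinates `x, y, z`, intensity.
#' @export
find_seeds <- function(field, vol, params = trace_params(), mask = NULL,
                       voxel_size = NULL) {
  a <- if (inherits(vol, "phantom_volume")) vol$data else vol
  vs <- if (inherits(vol, "phantom_volume")) vol$voxel_size else voxel_size
  origin <- if (inherits(vol, "phantom_volume")) vol$origin else c(0, 0, 0)
  stopifnot(!is.null(vs))
  thr <- params$seed_threshold %||% (median(a) + 6 * stats::mad(a))
  M <- sqrt(field$u^2 + field$v^2 + field$w^2)
  bright <- a > thr
  if (!is.null(mask)) bright <- bright & !mask
  # local minimum of |field| within the 26-neighbourhood
  locmin <- array(TRUE, dim(a))
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- M
    if (dx != 0) nb <- shift3(nb, 1, dx)
    if (dy != 0) nb <- shift3(nb, 2, dy)
    if (dz != 0) nb <- shift3(nb, 3, dz)
    locmin <- locmin & (M <= nb)
  }
  cand <- which(bright & locmin, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(tibble(i = integer(), j = integer(), k = integer(),
                  x = double(), y = double(), z = double(),
                  intensity = double()))
  }
  inten <- a[cand]
  ord <- order(inten, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  inten <- inten[ord]
  keep <- integer(0)
  min_d2 <- (params$seed_spacing / vs)^2
  for (i in seq_len(nrow(cand))) {
    if (length(keep) > 0) {
      d2 <- rowSums((cand[keep, , drop = FALSE] -
                       matrix(cand[i, ], length(keep), 3, byrow = TRUE))^2)
      if (min(d2) < min_d2) next
    }
    keep <- c(keep, i)
  }
  cand <- cand[keep, , drop = FALSE]
  tibble(i = cand[, 1], j = cand[, 2], k = cand[, 3],
         x = (cand[, 1] - 0.5) * vs + origin[1],
         y = (cand[, 2] - 0.5) * vs + origin[2],
         z = (cand[, 3] - 0.5) * vs + origin[3],
         intensity = inten[keep])
}

# background + 2 x noise SD, robustly from median and MAD (most voxels are
# background in sparse Golgi-style volumes)
auto_threshold <- function(a) {
  med <- median(a)
  med + 2 * stats::mad(a)
}

#' Mask manually assigned structures
#'
#' Voxels inside the constituents of a manually built model (somata, thick
#' neurites, vessels), dilated by `dilation`, are marked so the automatic
#' tracer never enters them.
#'
#' @param vol A `phantom_volume`.
#' @param manual_model A [tissue_model()] (may be empty / `NULL`).
#' @param dilation Radial dilation added to every node radius, micrometres.
#' @return Logical array of the volume's shape.
#' @export
apply_mask <- function(vol, manual_model = NULL, dilation = 0.1) {
  stopifnot(inherits(vol, "phantom_volume"))
  dims <- dim(vol$data)
  if (is.null(manual_model) || nrow(manual_model$nodes) == 0) {
    return(array(FALSE, dims))
  }
  acc <- array(0, dims)
  nd <- manual_model$nodes
  for (cid in unique(nd$constituent_id)) {
    sub <- order_tree_rows(nd[nd$constituent_id == cid, ])
    pos <- setNames(seq_len(nrow(sub)), sub$node_id)
    if (nrow(sub) == 1) {
      acc <- paint_capsule(acc, vol$origin, vol$voxel_size,
                           p = c(sub$x[1], sub$y[1], sub$z[1]),
                           q = c(sub$x[1], sub$y[1], sub$z[1]),
                           rp = sub$r[1] + dilation, rq = sub$r[1] + dilation)
      next
    }
    for (i in seq_len(nrow(sub))) {
      if (is.na(sub$parent_id[i])) next
      j <- pos[[as.character(sub$parent_id[i])]]
      acc <- paint_capsule(acc, vol$origin, vol$voxel_size,
                           p = c(sub$x[j], sub$y[j], sub$z[j]),
                           q = c(sub$x[i], sub$y[i], sub$z[i]),
                           rp = sub$r[j] + dilation, rq = sub$r[i] + dilation)
    }
  }
  acc > 0
}
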