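# trilinear interpolation at world points (matrix, rows = points)
interp3 <- function(vol, pts) {
  a <- vol$data
  dims <- dim(a)
  g <- sweep(pts, 2, vol$origin) / vol$voxel_size + 0.5  # voxel coords
  g1 <- pmin(pmax(g, 1), matrix(dims, nrow(pts), 3, byrow = TRUE))
  i0 <- pmin(floor(g1), matrix(dims - 1L, nrow(pts), 3, byrow = TRUE))
  fr <- g1 - i0
  out <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
      (if (dy) fr[, 2] else 1 - fr[, 2]) *
      (if (dz) fr[, 3] else 1 - fr[, 3])
    idx <- cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)
    out <- out + w * a[idx]
  }
  out
}

in_bounds <- function(vol, p, pad = 1) {
  g <- (p - vol$origin) / vol$voxel_size + 0.5
  all(g >= 1 + pad) && all(g <= dim(vol$data) - pad)
}

is_masked <- function(vol, mask, p) {
  if (is.null(mask)) return(FALSE)
  g <- round((p - vol$origin) / vol$voxel_size + 0.5)
  g <- pmin(pmax(g, 1), dim(vol$data))
  mask[g[1], g[2], g[3]]
}

# tube direction at a world point from the structure tensor of the Sobel
# gradients in a Gaussian-weighted window: gradients are strong across a
# bright tube and weak along it, so the minor eigenvector is the local axis
local_direction <- function(grads, vol, p, window_vox = 4) {
  vs <- vol$voxel_size
  offs <- expand.grid(dx = -window_vox:window_vox,
                      dy = -window_vox:window_vox,
                      dz = -window_vox:window_vox)
  offs <- as.matrix(offs)
  wt <- exp(-rowSums(offs^2) / (2 * (window_vox / 1.5)^2))
  qpts <- sweep(offs * vs, 2, p, "+")
  gx <- interp3_arr(grads$x, vol, qpts)
  gy <- interp3_arr(grads$y, vol, qpts)
  gz <- interp3_arr(grads$z, vol, qpts)
  G <- cbind(gx, gy, gz) * sqrt(wt)
  Tm <- crossprod(G)
  ev <- eigen(Tm, symmetric = TRUE)
  ev$vectors[, 3]
}

interp3_arr <- function(arr, vol, pts) {
  interp3(list(data = arr, origin = vol$origin,
               voxel_size = vol$voxel_size), pts)
}

# intensity-weighted centroid in the plane perpendicular to dir
recentre_point <- function(vol, p, dir, radius, thr) {
  vs <- vol$voxel_size
  e1 <- if (abs(dir[1]) < 0.9) cross3v(dir, c(1, 0, 0)) else
    cross3v(dir, c(0, 1, 0))
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3v(dir, e1)
  u <- seq(-radius, radius, by = vs)
  gridd <- as.matrix(expand.grid(a = u, b = u))
  gridd <- gridd[rowSums(gridd^2) <= radius^2, , drop = FALSE]
  qpts <- sweep(outer(gridd[, 1], e1) + outer(gridd[, 2], e2), 2, p, "+")
  iv <- interp3(vol, qpts)
  w <- pmax(iv - thr, 0)
  if (sum(w) <= 0) return(p)
  shift_ab <- colSums(gridd * w) / sum(w)
  p + shift_ab[1] * e1 + shift_ab[2] * e2
}

#' Estimate the local tube radius at a point
#'
#' Half-maximum convention: the radius is the scale at which the mean
#' intensity on a spherical shell around the point falls to background plus
#' half of the centre's excess over background.
#'
#' @param vol A `phantom_volume`.
#' @param p World point (length 3).
#' @param background Background intensity; `NULL` for a robust estimate.
#' @param max_radius Largest probed radius, micrometres.
#' @return Radius in micrometres.
#' @export
estimate_radius <- function(vol, p, background = NULL, max_radius = 2) {
  bg <- background %||% median(vol$data)
  centre <- interp3(vol, matrix(p, 1))
  excess <- centre - bg
  if (excess <= 0) return(0)
  half <- bg + excess / 2
  dirs <- shell_dirs()
  radii <- seq(vol$voxel_size, max_radius, by = vol$voxel_size / 2)
  prev <- centre
  for (rr in radii) {
    qpts <- sweep(dirs * rr, 2, p, "+")
    m <- mean(interp3(vol, qpts))
    if (m <= half) {
      # linear interpolation between the last two shells
      r0 <- if (rr == radii[1]) 0 else rr - vol$voxel_size / 2
      frac <- (prev - half) / (prev - m)
      return(r0 + frac * (rr - r0))
    }
    prev <- m
  }
  max_radius
}

shell_dirs <- function() {
  # 26 lattice directions, normalised: cheap near-uniform shell sample
  d <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  d <- d[rowSums(abs(d)) > 0, ]
  d / sqrt(rowSums(d^2))
}

#' Trace a neurite centerline from a seed point
#'
#' Marches bidirectionally from the seed. Each step advances by
#' `params$step` along the local tube axis (minor eigenvector of the Sobel
#' structure tensor, sign-aligned with the march), then re-centres on the
#' intensity centroid of the perpendicular plane. The march stops when the
#' interpolated intensity falls below the stop threshold, the volume
#' boundary or a masked voxel is reached, the direction turns by more than
#' `max_turn_per_step`, or the chain approaches an existing trace
#' (`avoid` points) to within the de-duplication distance.
#'
#' @param vol A `phantom_volume`.
#' @param seed World coordinates (length 3) of the seed.
#' @param params A [trace_params()].
#' @param mask Optional logical array; seeds and steps inside it are
#'   rejected.
#' @param grads Precomputed [sobel3d()] gradients of the volume (computed on
#'   demand when `NULL`).
#' @param avoid Optional matrix of already-traced node positions.
#' @return A tibble of ordered nodes (`x`, `y`, `z`, `r`), possibly with
#'   zero rows when the seed is rejected.
#' @export
trace_from_seed <- function(vol, seed, params = trace_params(), mask = NULL,
                            grads = NULL, avoid = NULL) {
  stopifnot(inherits(vol, "phantom_volume"))
  if (is_masked(vol, mask, seed)) {
    inform("seed rejected: inside masked region")
    return(tibble(x = double(), y = double(), z = double(), r = double()))
  }
  if (is.null(grads)) grads <- sobel3d(vol$data)
  vs <- vol$voxel_size
  step <- params$step %||% (2 * vs)
  thr <- params$intensity_stop %||% auto_threshold(vol$data)
  bg <- median(vol$data)
  rc <- params$recentre_radius %||% (6 * vs)
  d0 <- local_direction(grads, vol, seed)
  p0 <- recentre_point(vol, seed, d0, rc, thr)
  d0 <- local_direction(grads, vol, p0)
  march <- function(dir) {
    p <- p0
    pts <- NULL
    for (s in seq_len(100000L)) {
      pn <- p + step * dir
      if (!in_bounds(vol, pn)) break
      if (is_masked(vol, mask, pn)) break
      dn <- local_direction(grads, vol, pn)
      if (sum(dn * dir) < 0) dn <- -dn
      ang <- acos(pmin(1, pmax(-1, sum(dn * dir))))
      if (ang > params$max_turn_per_step) break
      pn <- recentre_point(vol, pn, dn, rc, thr)
      if (interp3(vol, matrix(pn, 1)) < thr) break
      if (!is.null(avoid) && nrow(avoid) > 0) {
        d2 <- min(rowSums(sweep(avoid, 2, pn)^2))
        if (d2 < (2 * vs)^2) break
      }
      step_vec <- pn - p
      nrm <- sqrt(sum(step_vec^2))
      if (nrm < step / 4) break  # stalled
      dir <- step_vec / nrm
      pts <- rbind(pts, pn)
      p <- pn
    }
    pts
  }
  fwd <- march(d0)
  bwd <- march(-d0)
  chain <- rbind(if (!is.null(bwd)) bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
                 matrix(p0, 1), fwd)
  out <- tibble(x = chain[, 1], y = chain[, 2], z = chain[, 3], r = 0)
  out$r <- vapply(seq_len(nrow(out)), function(i) {
    estimate_radius(vol, c(out$x[i], out$y[i], out$z[i]), background = bg,
                    max_radius = params$max_radius)
  }, numeric(1))
  out
}

#' Trace all neurites in a volume
#'
#' Runs the full automatic model-generation stage: gradient vector flow,
#' seed detection, masking of manually assigned structures, bidirectional
#' Sobel-guided tracing from every surviving seed (brightest first, with
#' duplicate traces suppressed), and assembly into a [tissue_model()] of
#' `smooth_neurite` constituents. Chains shorter than
#' `params$min_trace_length` are dropped.
#'
#' @param vol A `phantom_volume`.
#' @param params A [trace_params()].
#' @param manual_model Optional manually assigned model to mask out.
#' @param mask_dilation Dilation applied to the manual mask, micrometres.
#' @param case_id,dataset_id Metadata for the returned model.
#' @return A [tissue_model()].
#' @export
trace_volume <- function(vol, params = trace_params(), manual_model = NULL,
                         mask_dilation = 0.1, case_id = "",
                         dataset_id = "") {
  stopifnot(inherits(vol, "phantom_volume"))
  mask <- if (!is.null(manual_model)) {
    apply_mask(vol, manual_model, mask_dilation)
  }
  field <- compute_gvf(vol, mu = params$gvf_mu,
                       iterations = params$gvf_iterations)
  seeds <- find_seeds(field, vol, params, mask = mask)
  grads <- sobel3d(vol$data)
  chains <- list()
  avoid <- matrix(numeric(0), 0, 3)
  for (i in seq_len(nrow(seeds))) {
    sp <- c(seeds$x[i], seeds$y[i], seeds$z[i])
    if (nrow(avoid) > 0) {
      d2 <- min(rowSums(sweep(avoid, 2, sp)^2))
      if (d2 < max(params$seed_spacing, 2 * vol$voxel_size)^2) next
    }
    ch <- trace_from_seed(vol, sp, params, mask = mask, grads = grads,
                          avoid = avoid)
    if (nrow(ch) < 2) next
    if (polyline_length(node_matrix(ch)) < params$min_trace_length) next
    chains[[length(chains) + 1]] <- ch
    avoid <- rbind(avoid, node_matrix(ch))
  }
  nodes <- imap(chains, function(ch, k) {
    tibble(constituent_id = as.integer(k), ctype = "smooth_neurite",
           node_id = seq_len(nrow(ch)),
           parent_id = c(NA_integer_, seq_len(nrow(ch) - 1L)),
           x = ch$x, y = ch$y, z = ch$z, r = ch$r)
  })
  nd <- if (length(nodes)) bind_rows(nodes) else
    tibble(constituent_id = integer(), ctype = character(),
           node_id = integer(), parent_id = integer(),
           x = double(), y = double(), z = double(), r = double())
  tissue_model(nd, voxel_size = vol$voxel_size,
               case_id = case_id, dataset_id = dataset_id)
}
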