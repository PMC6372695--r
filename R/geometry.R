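#' Resample a polyline at uniform arc-length spacing
#'
#' Linear interpolation along the cumulative arc length; both endpoints are
#' preserved. Discrete curvature and torsion estimators are only stable on
#' evenly spaced nodes, so every chain is resampled before estimation.
#'
#' @param pts Numeric matrix, one point per row, 3 columns (micrometres).
#' @param spacing Target spacing in micrometres.
#' @return Matrix of resampled points. If `spacing` is at least the total
#'   arc length, just the two endpoints.
#' @export
resample_polyline <- function(pts, spacing) {
  pts <- as.matrix(pts)
  stopifnot(nrow(pts) >= 2, spacing > 0)
  d <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                       pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(d))
  total <- s[length(s)]
  if (total <= 0) abort("polyline has zero length")
  if (spacing >= total) {
    return(pts[c(1, nrow(pts)), , drop = FALSE])
  }
  n_out <- round(total / spacing) + 1
  si <- seq(0, total, length.out = n_out)
  out <- vapply(1:3, function(k) approx(s, pts[, k], xout = si,
                                        ties = "ordered")$y,
                numeric(n_out))
  matrix(out, ncol = 3,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Per-node discrete curvature of a polyline
#'
#' At every interior node the curvature is the Menger curvature of the node
#' and its two neighbours: the reciprocal of the circumradius of the triangle
#' they span, `4 * area / (|ab| |bc| |ca|)`. For points sampled from a smooth
#' curve this converges to the Frenet curvature; a collinear triple gives 0.
#'
#' @param pts Numeric matrix, >= 3 rows, consecutive points distinct.
#' @return Numeric vector of length `nrow(pts) - 2`, micrometres^-1.
#' @export
curvature_profile <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  stopifnot(n >= 3)
  a <- pts[1:(n - 2), , drop = FALSE]
  b <- pts[2:(n - 1), , drop = FALSE]
  c_ <- pts[3:n, , drop = FALSE]
  ab <- b - a; bc <- c_ - b; ca <- a - c_
  lab <- sqrt(rowSums(ab^2)); lbc <- sqrt(rowSums(bc^2))
  lca <- sqrt(rowSums(ca^2))
  if (any(lab == 0) || any(lbc == 0)) {
    abort("duplicate consecutive points")
  }
  cr <- cross3(ab, bc)
  area2 <- sqrt(rowSums(cr^2))     # twice the triangle area
  2 * area2 / (lab * lbc * lca)
}

#' Per-window discrete signed torsion of a polyline
#'
#' Every run of four consecutive nodes spans a tetrahedron whose signed
#' volume vanishes exactly when the four points are coplanar. For a curve
#' sampled at arc spacing `h`, the determinant
#' `det(p2 - p1, p3 - p1, p4 - p1)` expands to `kappa^2 tau h^6` to leading
#' order, so torsion is recovered as `6 V / (kappa^2 h^6)` with `kappa` the
#' mean Menger curvature of the window and `h` its mean step. The sign is
#' the handedness of the window: a right-handed helix is positive. Windows
#' with near-zero curvature (locally straight, torsion undefined) return
#' `NA` and are excluded from summaries.
#'
#' @param pts Numeric matrix, >= 4 rows.
#' @param kappa_floor Curvature (micrometres^-1) below which a window is
#'   treated as degenerate.
#' @return Numeric vector of length `nrow(pts) - 3`, micrometres^-1, `NA`
#'   where undefined.
#' @export
torsion_profile <- function(pts, kappa_floor = 1e-6) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  stopifnot(n >= 4)
  p1 <- pts[1:(n - 3), , drop = FALSE]
  p2 <- pts[2:(n - 2), , drop = FALSE]
  p3 <- pts[3:(n - 1), , drop = FALSE]
  p4 <- pts[4:n, , drop = FALSE]
  a <- p2 - p1; b <- p3 - p1; c_ <- p4 - p1
  vol6 <- rowSums(cross3(a, b) * c_)   # 6 * signed volume
  kap <- curvature_profile(pts)
  k <- (kap[1:(n - 3)] + kap[2:(n - 2)]) / 2
  h <- (sqrt(rowSums((p2 - p1)^2)) + sqrt(rowSums((p3 - p2)^2)) +
          sqrt(rowSums((p4 - p3)^2))) / 3
  tau <- vol6 / (k^2 * h^6)
  tau[k < kappa_floor] <- NA_real_
  tau
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Geometry of neurite segments
#'
#' Resamples each segment chain at uniform arc-length spacing and computes
#' the unweighted mean of its curvature profile, the unweighted mean of its
#' signed torsion profile, the mean node radius (of the original nodes), and
#' the arc length. Segments too short for an estimator (fewer than 3
#' resampled nodes for curvature, 4 for torsion) report that statistic as
#' `NA`; torsion windows flagged degenerate are likewise dropped, so the
#' torsion n can be smaller than the curvature n.
#'
#' @param segments Tibble from [split_segments()] (any tibble with a `nodes`
#'   list-column works).
#' @param spacing Resampling spacing, micrometres.
#' @return The input tibble with columns `mean_curvature`, `mean_torsion`,
#'   `mean_radius`, `arc_length`, `n_curvature_nodes`, `n_torsion_nodes`
#'   added (the `nodes` list-column is retained).
#' @export
segment_geometry <- function(segments, spacing = 0.5) {
  stopifnot(is.data.frame(segments), "nodes" %in% names(segments))
  geo <- map(segments$nodes, chain_geometry, spacing = spacing)
  segments$mean_curvature <- map_dbl(geo, "mean_curvature")
  segments$mean_torsion <- map_dbl(geo, "mean_torsion")
  segments$mean_radius <- map_dbl(geo, "mean_radius")
  segments$arc_length <- map_dbl(geo, "arc_length")
  segments$n_curvature_nodes <- map_int(geo, "n_curvature_nodes")
  segments$n_torsion_nodes <- map_int(geo, "n_torsion_nodes")
  segments
}

chain_geometry <- function(nodes, spacing) {
  pts <- node_matrix(nodes)
  out <- list(mean_curvature = NA_real_, mean_torsion = NA_real_,
              mean_radius = mean(nodes$r), arc_length = polyline_length(pts),
              n_curvature_nodes = 0L, n_torsion_nodes = 0L)
  if (nrow(pts) < 2 || out$arc_length <= 0) return(out)
  rs <- resample_polyline(pts, spacing)
  if (nrow(rs) >= 3) {
    kap <- curvature_profile(rs)
    out$mean_curvature <- mean(kap)
    out$n_curvature_nodes <- length(kap)
  }
  if (nrow(rs) >= 4) {
    tau <- torsion_profile(rs)
    tau <- tau[!is.na(tau)]
    if (length(tau) > 0) {
      out$mean_torsion <- mean(tau)
      out$n_torsion_nodes <- length(tau)
    }
  }
  out
}
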