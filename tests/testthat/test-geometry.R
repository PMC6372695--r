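test_that("resampling straightens out uneven spacing and is idempotent", {
  line <- cbind(x = c(0, 0.3, 1.1, 2, 4, 7, 10), y = 0, z = 0)
  rs <- resample_polyline(line, 1)
  expect_equal(nrow(rs), 11)
  expect_equal(rs[, 1], seq(0, 10), tolerance = 1e-12)
  expect_true(all(rs[, 2] == 0) && all(rs[, 3] == 0))
  rs2 <- resample_polyline(rs, 1)
  expect_equal(rs2, rs, tolerance = 1e-9)
  # spacing beyond the total length returns the endpoints
  ends <- resample_polyline(line, 50)
  expect_equal(nrow(ends), 2)
  expect_equal(ends[2, ], line[7, ], ignore_attr = TRUE)
})

test_that("resampling a circle preserves three-point circumradius", {
  R <- 2
  th <- seq(0, 2 * pi, length.out = 200)
  circ <- cbind(R * cos(th), R * sin(th), 0)
  rs <- resample_polyline(circ, R / 5)
  kap <- curvature_profile(rs)
  expect_true(all(abs(kap - 1 / R) / (1 / R) < 0.01))
})

test_that("Menger curvature is exact on circles and zero on lines", {
  th <- seq(0, 2 * pi, length.out = 37)[-37]
  circ <- cbind(2 * cos(th), 2 * sin(th), 0)
  expect_equal(curvature_profile(circ), rep(0.5, 34), tolerance = 1e-9)
  expect_equal(curvature_profile(straight_chain(20)), rep(0, 18))
  expect_error(curvature_profile(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))),
               "duplicate")
})

test_that("helix estimators hit the closed-form curvature and torsion", {
  P <- make_helix(1, 1, turns = 4, spacing = 0.2)
  kap <- curvature_profile(P)
  tau <- torsion_profile(P)
  expect_equal(mean(kap), 0.5, tolerance = 0.01)
  expect_equal(mean(tau, na.rm = TRUE), 0.5, tolerance = 0.02)
  # mirroring flips torsion sign exactly, leaves curvature unchanged
  M <- P; M[, 3] <- -M[, 3]
  expect_equal(torsion_profile(M), -tau)
  expect_equal(curvature_profile(M), kap)
})

test_that("planar curves have zero torsion", {
  zig <- cbind(x = 0:9, y = rep(c(0, 1), 5), z = 0)
  expect_equal(torsion_profile(zig), rep(0, 7))
})

test_that("random smooth curves match an independent Frenet oracle", {
  curve <- function(t) {
    cbind(3 * cos(t) + 0.4 * cos(3 * t),
          3 * sin(t) - 0.3 * sin(2 * t),
          1.2 * t + 0.5 * sin(2 * t))
  }
  tt <- seq(0.5, 5.5, length.out = 6000)
  P <- curve(tt)
  rs <- resample_polyline(P, 0.03)
  kap <- curvature_profile(rs)
  tau <- torsion_profile(rs)
  # oracle profiles interpolated onto the resampled nodes by arc length
  o <- t(vapply(tt, function(t0) frenet_oracle(function(t) drop(curve(t)),
                                               t0),
                numeric(2)))
  s_all <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
  s_rs <- c(0, cumsum(sqrt(rowSums(diff(rs)^2))))
  n <- nrow(rs)
  kap_o <- approx(s_all, o[, 1], xout = s_rs[2:(n - 1)])$y
  tau_o <- approx(s_all, o[, 2], xout = s_rs[2:(n - 2)] +
                    diff(s_rs)[1] / 2)$y
  rel_k <- abs(kap - kap_o) / kap_o
  expect_lt(stats::quantile(rel_k, 0.95), 0.05)
  ok <- !is.na(tau)
  err_t <- abs(tau[ok] - tau_o[ok]) / pmax(abs(tau_o[ok]), 0.2)
  expect_lt(stats::quantile(err_t, 0.95), 0.05)
})

test_that("curvature and torsion transform correctly under scaling,
           rigid motion and reflection", {
  withr::with_seed(5, {
    P <- make_tortuous_neurite(tortuosity_params(0.5, 0.5), 25)
  })
  kap <- curvature_profile(P)
  tau <- torsion_profile(P)
  # rigid motion: both invariant
  Q <- rigid_transform(P)
  expect_equal(curvature_profile(Q), kap, tolerance = 1e-8)
  expect_equal(torsion_profile(Q), tau, tolerance = 1e-6)
  # uniform scaling by s: curvature and torsion scale by 1/s
  s <- 2.5
  expect_equal(curvature_profile(P * s), kap / s, tolerance = 1e-10)
  expect_equal(torsion_profile(P * s), tau / s, tolerance = 1e-10)
  expect_equal(polyline_length(P * s), s * polyline_length(P))
  # reflection: curvature even, torsion odd
  Rf <- P; Rf[, 1] <- -Rf[, 1]
  expect_equal(curvature_profile(Rf), kap)
  expect_equal(torsion_profile(Rf), -tau)
})

test_that("segment_geometry summarises chains and tracks estimator support", {
  m <- helix_model(r = 1, c = 1, turns = 4, spacing = 0.1, tube_r = 0.25)
  g <- segment_geometry(split_segments(m), spacing = 0.2)
  expect_equal(g$mean_curvature, 0.5, tolerance = 0.01)
  expect_equal(g$mean_torsion, 0.5, tolerance = 0.02)
  expect_equal(g$mean_radius, 0.25)
  expect_equal(g$arc_length, 4 * 2 * pi * sqrt(2), tolerance = 0.01)
  expect_true(g$n_torsion_nodes <= g$n_curvature_nodes)
  # a 3-node segment supports curvature but not torsion
  tri <- chain_model(rbind(c(0, 0, 0), c(1, 0.2, 0), c(2, 0, 0)))
  g3 <- segment_geometry(split_segments(tri), spacing = 1.1)
  expect_false(is.na(g3$mean_curvature))
  expect_true(is.na(g3$mean_torsion))
  expect_equal(g3$n_torsion_nodes, 0L)
})

test_that("spine metrics follow the fixtures", {
  base <- chain_nodes(straight_chain(5), cid = 1L)
  spine2 <- tibble::tibble(constituent_id = 2L, ctype = "spine",
                           node_id = 1:2, parent_id = c(NA, 1L),
                           x = 2, y = c(0, 1), z = 0, r = 0.2)
  mush <- tibble::tibble(constituent_id = 3L, ctype = "spine",
                         node_id = 1:3, parent_id = c(NA, 1L, 2L),
                         x = 3, y = c(0, 0.6, 1.2), z = 0,
                         r = c(0.1, 0.1, 0.3))
  att <- tibble::tibble(constituent_id = c(2L, 3L),
                        parent_constituent_id = 1L,
                        parent_node_id = c(3L, 4L))
  m <- annotate_constituents(tissue_model(dplyr::bind_rows(base, spine2, mush),
                                          attachments = att))
  sm <- spine_metrics(m)
  s2 <- sm[sm$constituent_id == 2L, ]
  expect_equal(s2$length, 1)
  expect_equal(s2$radius_ratio, 1)
  s3 <- sm[sm$constituent_id == 3L, ]
  expect_equal(s3$min_radius, 0.1)
  expect_equal(s3$max_radius, 0.3)
  expect_equal(s3$radius_ratio, 3)
  # zero minimum radius: ratio undefined and flagged
  zr <- mush; zr$constituent_id <- 4L; zr$r[1] <- 0
  m2 <- tissue_model(dplyr::bind_rows(base, zr),
                     attachments = tibble::tibble(
                       constituent_id = 4L, parent_constituent_id = 1L,
                       parent_node_id = 2L))
  sm2 <- spine_metrics(m2)
  expect_true(is.na(sm2$radius_ratio))
  expect_false(sm2$ratio_defined)
})

test_that("spine density is spines per spiny-dendrite length", {
  base <- chain_nodes(straight_chain(21), cid = 1L)  # 20 um
  spines <- purrr::map(1:10, function(k) {
    tibble::tibble(constituent_id = 1L + k, ctype = "spine", node_id = 1:2,
                   parent_id = c(NA, 1L), x = k, y = c(0, 0.5), z = 0,
                   r = 0.15)
  })
  att <- tibble::tibble(constituent_id = 1L + 1:10,
                        parent_constituent_id = 1L,
                        parent_node_id = 1:10)
  m <- annotate_constituents(
    tissue_model(dplyr::bind_rows(base, dplyr::bind_rows(spines)),
                 attachments = att))
  expect_equal(spine_density(m), 0.5)
  m0 <- chain_model(straight_chain(5))
  expect_warning(d0 <- spine_density(m0), "density reported as 0")
  expect_equal(d0, 0)
})

test_that("spine density estimates recover the Poisson generator rate", {
  d_true <- 0.4
  long <- chain_model(straight_chain(401, 0.5))  # 200 um
  m <- attach_spines(long, density = d_true, seed = 21)
  d_hat <- spine_density(m)
  se <- sqrt(d_true / 200)  # Poisson counting error over 200 um
  expect_lt(abs(d_hat - d_true), 3 * se)
})
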