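test_that("helix generator hits its closed forms and chirality", {
  expect_equal(helix_curvature(1, 1), 0.5)
  expect_equal(helix_torsion(1, 1), 0.5)
  expect_equal(helix_torsion(2, 0), 0)
  P <- make_helix(1, 1, turns = 3, spacing = 0.2)
  M <- P; M[, 3] <- -M[, 3]
  expect_equal(mean(torsion_profile(M), na.rm = TRUE),
               -mean(torsion_profile(P), na.rm = TRUE))
})

test_that("zero turning concentration gives a straight line", {
  p <- tortuosity_params(0.5, target_mean_curvature = 0)
  pts <- make_tortuous_neurite(p, 20, seed = 4)
  expect_equal(max(curvature_profile(pts)), 0, tolerance = 1e-10)
})

test_that("the tortuous generator is seed-reproducible and seed-sensitive", {
  p <- tortuosity_params(0.5, 0.4)
  a <- make_tortuous_neurite(p, 15, seed = 8)
  b <- make_tortuous_neurite(p, 15, seed = 8)
  c_ <- make_tortuous_neurite(p, 15, seed = 9)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a, c_)))
})

test_that("turning-angle calibration makes realised curvature unbiased", {
  p <- tortuosity_params(step_length = 0.5, target_mean_curvature = 0.45)
  kaps <- withr::with_seed(12, {
    purrr::map_dbl(1:1000, ~ mean(curvature_profile(
      make_tortuous_neurite(p, 15))))
  })
  expect_lt(abs(mean(kaps) - 0.45) / 0.45, 0.05)
})

test_that("achiral generation has torsion symmetric about zero", {
  p <- tortuosity_params(0.5, 0.5, chirality_bias = 0)
  taus <- withr::with_seed(13, {
    unlist(purrr::map(1:150, function(i) {
      tau <- torsion_profile(make_tortuous_neurite(p, 40))
      tau[!is.na(tau)]
    }))
  })
  expect_gte(length(taus), 1e4)
  expect_lt(abs(mean(taus)), 3 * sd(taus) / sqrt(length(taus)))
})

test_that("spine attachment follows density and the mixture is recoverable", {
  dend <- chain_model(straight_chain(41, 0.5))  # 20 um
  m0 <- attach_spines(dend, density = 0, seed = 1)
  expect_equal(sum(m0$nodes$ctype == "spine"), 0)
  expect_equal(unique(m0$nodes$ctype), "smooth_neurite")
  # Poisson expectation: density 0.5 on 20 um -> 10 spines on average
  counts <- withr::with_seed(14, {
    purrr::map_int(1:150, function(i) {
      nrow(attr(attach_spines(dend, density = 0.5), "spine_truth"))
    })
  })
  expect_lt(abs(mean(counts) - 10), 3 * sqrt(10 / 150))
  # stubby/mushroom mixture separates by 2-component clustering
  long <- chain_model(straight_chain(801, 0.5))  # 400 um
  m <- attach_spines(long, density = 0.5, stubby_frac = 0.5, seed = 15)
  truth <- attr(m, "spine_truth")
  sm <- spine_metrics(m)
  j <- dplyr::inner_join(sm, truth, by = "constituent_id")
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  X <- cbind(log(j$length.x), log(j$min_radius))
  mc <- withr::with_seed(16, Mclust(X, G = 2, verbose = FALSE))
  agree <- max(mean((mc$classification == 1) == (j$class == "stubby")),
               mean((mc$classification == 2) == (j$class == "stubby")))
  expect_gt(agree, 0.9)
})

test_that("cohorts are reproducible and degenerate specs collapse", {
  cases <- cohort_spec()$cases[c(1, 5), ]
  cases$n_segments <- 20L
  a <- make_cohort(cohort_spec(cases = cases, seed = 30))
  b <- make_cohort(cohort_spec(cases = cases, seed = 30))
  expect_identical(purrr::map(a$models, "nodes"),
                   purrr::map(b$models, "nodes"))
  expect_identical(a$truth, b$truth)
  d <- make_cohort(cohort_spec(cases = cases, seed = 31))
  expect_false(identical(a$truth, d$truth))
  # zero-variance curvature spec: every segment gets the case mean
  cases0 <- cases
  cases0$curvature_sd <- 1e-12
  z <- make_cohort(cohort_spec(cases = cases0, seed = 30))
  means <- tapply(z$truth$target_curvature, z$truth$case_id, mean)
  expect_equal(as.vector(means[c("S1", "N1")]), c(0.46, 0.33),
               tolerance = 1e-6)
  expect_equal(as.vector(tapply(z$truth$target_curvature, z$truth$case_id,
                                sd)),
               c(0, 0), tolerance = 1e-6)
})

test_that("rasterization produces calibrated tubes on noisy background", {
  # empty model: background plus noise only
  empty <- tissue_model(chain_nodes(straight_chain(2))[0, ])
  spec <- raster_spec(voxel_size = 0.1, background_level = 100,
                      foreground_level = 1000, noise_sd = 15)
  v0 <- rasterize(empty, spec, seed = 3)
  expect_equal(mean(v0$data), 100, tolerance = 0.02)
  expect_equal(sd(as.vector(v0$data)), 15, tolerance = 0.1)
  # straight tube: the brightest voxels hug the axis
  tube <- chain_model(straight_chain(11), r = 0.4)
  v <- rasterize(tube, raster_spec(voxel_size = 0.1, noise_sd = 0), seed = 1)
  idx <- which(v$data > max(v$data) * 0.999, arr.ind = TRUE)
  w <- sweep((idx - 0.5) * v$voxel_size, 2, -v$origin)
  d_axis <- sqrt(w[, 2]^2 + w[, 3]^2)  # axis along x at y = z = 0
  ok <- w[, 1] > 0 & w[, 1] < 10
  expect_true(all(d_axis[ok] <= v$voxel_size * 1.0001))
})

test_that("noiseless tube mass grows linearly with tube length", {
  spec <- raster_spec(voxel_size = 0.1, noise_sd = 0, psf_sigma = 0.12)
  mass <- purrr::map_dbl(c(5, 10, 15), function(L) {
    tube <- chain_model(straight_chain(L + 1), r = 0.4)
    v <- rasterize(tube, spec, seed = 1)
    sum(v$data - spec$background_level)
  })
  # end caps contribute a constant, so increments isolate the per-length mass
  inc <- diff(mass) / 5
  expect_equal(inc[1], inc[2], tolerance = 0.02)
  # per-micrometre excess mass matches the analytic cylinder cross-section
  # (up to voxelization of the 4-voxel-radius disc)
  analytic <- pi * 0.4^2 *
    (spec$foreground_level - spec$background_level) / spec$voxel_size^3
  expect_equal(inc[1], analytic, tolerance = 0.05)
})

test_that("an under-resolved model triggers a warning", {
  thin <- chain_model(straight_chain(3), r = 0.05)
  expect_warning(rasterize(thin, raster_spec(voxel_size = 0.2), seed = 1),
                 "under-resolved")
})

test_that("volumes round-trip through TIFF stacks", {
  skip_if_not_installed("tiff")
  tube <- chain_model(straight_chain(4), r = 0.4)
  v <- rasterize(tube, raster_spec(voxel_size = 0.15), seed = 2)
  f <- withr::local_tempfile(fileext = ".tif")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_equal(dim(v2$data), dim(v$data))
  expect_equal(v2$voxel_size, v$voxel_size)
  expect_equal(v2$origin, as.numeric(v$origin))
  # 16-bit quantisation: relative error bounded by the intensity range
  expect_lt(max(abs(v2$data - v$data)), diff(range(v$data)) / 65535 * 1.01)
})
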