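test_that("rigid alignment recovers identity and known transforms", {
  tpl <- small_template()
  tr0 <- rigid_align(tpl, tpl$mesh)
  expect_equal(tr0$rotation, diag(3), tolerance = 1e-6)
  expect_equal(tr0$translation, c(0, 0, 0), tolerance = 1e-4)

  R <- facefa:::rotation_about(c(0.2, 1, 0.3), 8)
  t_ <- c(5, -3, 2)
  scan <- surface_mesh(apply_transform(rigid_transform(R, t_),
                                       tpl$mesh$vertices), tpl$mesh$faces)
  tr <- rigid_align(tpl, scan)
  expect_lt(max(abs(tr$rotation - R)), 1e-3)
  expect_lt(max(abs(tr$translation - t_)), 1e-3)
  expect_equal(tr$scale, 1)
})

test_that("rigid alignment with scaling recovers a doubled scan", {
  tpl <- small_template()
  scan <- surface_mesh(2 * tpl$mesh$vertices, tpl$mesh$faces)
  tr <- rigid_align(tpl, scan, allow_scale = TRUE)
  expect_lt(abs(tr$scale - 2), 1e-3)
})

test_that("non-rigid mapping reproduces the template on itself and tracks rigid scans", {
  tpl <- small_template()
  mf <- nonrigid_map(tpl, tpl$mesh)
  expect_lt(max(abs(mf$positions - tpl$mesh$vertices)), 1e-3)

  R <- facefa:::rotation_about(c(0, 1, 0.5), 6)
  tr <- rigid_transform(R, c(3, 1, -2))
  scan <- surface_mesh(apply_transform(tr, tpl$mesh$vertices), tpl$mesh$faces)
  mf2 <- nonrigid_map(tpl, scan)
  expect_lt(max(abs(mf2$positions - scan$vertices)), 5e-3)
})

test_that("non-rigid mapping recovers a smooth normal-directed warp", {
  tpl <- make_symmetric_template(300)
  V <- tpl$mesh$vertices
  set.seed(42)
  nrm <- facefa:::vertex_normals(V, tpl$mesh$faces)
  # orthogonalize the height profile against all rigid motions along normals
  n <- nrow(V)
  Xc <- sweep(V, 2, colMeans(V))
  basis <- cbind(nrm,
                 rowSums(facefa:::cross3(matrix(rep(c(1, 0, 0), each = n), n), Xc) * nrm),
                 rowSums(facefa:::cross3(matrix(rep(c(0, 1, 0), each = n), n), Xc) * nrm),
                 rowSums(facefa:::cross3(matrix(rep(c(0, 0, 1), each = n), n), Xc) * nrm))
  qb <- qr.Q(qr(basis))
  h <- facefa:::smooth_field(tpl, 8, 40)[, 1]
  h <- h - as.vector(qb %*% crossprod(qb, h))
  warp <- h * nrm
  amp <- 2
  warp <- amp * warp / sqrt(mean(rowSums(warp^2)))
  warped <- V + warp
  scan <- surface_mesh(warped, tpl$mesh$faces)
  mf <- nonrigid_map(tpl, scan)
  rmse <- sqrt(mean(rowSums((mf$positions - warped)^2)))
  # tangential position on a smooth surface is only weakly identifiable by
  # geometric correspondence; the stated recovery threshold at this density
  # is 30% of the warp amplitude, while the surface geometry itself is
  # recovered much more closely
  expect_lt(rmse, 0.30 * amp)
  cp <- facefa:::closest_points(mf$positions, facefa:::mesh_accel(scan))
  expect_lt(mean(cp$dist), 0.25)
})

test_that("mapped vertices are attracted onto the scan surface", {
  p <- sim_params(n_individuals = 2, seed = 21)
  sim <- simulate_faces(p)
  for (m in sim$meshes) {
    mf <- nonrigid_map(sim$template, m)
    accel <- facefa:::mesh_accel(m)
    cp <- facefa:::closest_points(mf$positions, accel)
    expect_gte(mean(cp$dist <= mapping_params()$correspondence_distance_cap),
               0.99)
  }
})

test_that("mapping is rigid-equivariant and deterministic", {
  # noise-free scan: correspondence decisions are stable across poses
  p <- sim_params(n_individuals = 1, sensor_noise_sd = 0, seed = 22)
  sim <- simulate_faces(p)
  scan <- sim$meshes[[1]]
  mf1 <- nonrigid_map(sim$template, scan)
  mf1b <- nonrigid_map(sim$template, scan)
  expect_identical(mf1$positions, mf1b$positions)

  set.seed(1)
  tr <- random_rigid(8, 4)
  mf2 <- nonrigid_map(sim$template, apply_transform(tr, scan))
  expect_lt(max(abs(mf2$positions - apply_transform(tr, mf1$positions))), 5e-3)

  # sensor noise makes closest-point assignment pose-dependent at the scale
  # of the noise; equivariance then holds only to that scale
  noisy <- simulate_faces(sim_params(n_individuals = 1, seed = 23))$meshes[[1]]
  nf1 <- nonrigid_map(sim$template, noisy)
  nf2 <- nonrigid_map(sim$template, apply_transform(tr, noisy))
  dev <- sqrt(rowSums((nf2$positions -
                         apply_transform(tr, nf1$positions))^2))
  expect_lt(sqrt(mean(dev^2)), 0.2)
})

test_that("a non-overlapping scan raises a mapping failure", {
  tpl <- small_template()
  far <- surface_mesh(tpl$mesh$vertices + 500, tpl$mesh$faces)
  # centroid initialization absorbs pure translation, so shrink the scan to a
  # sliver of template scale as well
  tiny <- surface_mesh(tpl$mesh$vertices * 0.02 + 500, tpl$mesh$faces)
  expect_error(nonrigid_map(tpl, tiny), "mapping failure")
})

test_that("mapping parameter validation rejects bad schedules", {
  expect_error(mapping_params(stiffness_schedule = c(1, 2)), "diff")
  expect_error(mapping_params(stiffness_schedule = c(1, -1)))
  expect_error(mapping_params(convergence_tol = 0))
})
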