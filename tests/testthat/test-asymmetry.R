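test_that("mirror_relabel fixes symmetric faces, is an involution, and flips perturbations", {
  tpl <- small_template()
  V <- tpl$mesh$vertices
  expect_equal(mirror_relabel(V, tpl)$positions, V, tolerance = 0)

  set.seed(1)
  face <- V + matrix(rnorm(length(V), 0, 0.5), ncol = 3)
  expect_identical(mirror_relabel(mirror_relabel(face, tpl), tpl)$positions,
                   face)

  # a perturbation delta on one side reappears mirrored on the other side
  i <- setdiff(seq_along(tpl$pairing), tpl$midline)[1]
  j <- tpl$pairing[i]
  pert <- V
  pert[i, ] <- pert[i, ] + c(0.3, 0.2, -0.1)
  mir <- mirror_relabel(pert, tpl)$positions
  expect_equal(mir[j, ] - V[j, ], c(-0.3, 0.2, -0.1), tolerance = 1e-12,
               ignore_attr = TRUE)

  bad <- tpl
  bad$pairing[1] <- 2L
  expect_error(mirror_relabel(V, bad), "involution")
})

test_that("weighted Procrustes with uniform weights matches the closed-form oracle", {
  tpl <- small_template()
  set.seed(2)
  face <- tpl$mesh$vertices + matrix(rnorm(length(tpl$mesh$vertices), 0, 1),
                                     ncol = 3)
  for (i in 1:5) {
    tr <- random_rigid(25, 20)
    mirror <- apply_transform(tr, face + matrix(rnorm(length(face), 0, 0.3),
                                                ncol = 3))
    got <- weighted_procrustes(face, mirror)$transform
    want <- oracle_procrustes(mirror, face)
    expect_lt(max(abs(got$rotation - want$R)), 1e-9)
    expect_lt(max(abs(got$translation - want$t)), 1e-9)
  }
})

test_that("already-aligned mirrors give the identity transform", {
  tpl <- small_template()
  got <- weighted_procrustes(tpl$mesh$vertices,
                             mirror_relabel(tpl$mesh$vertices, tpl))
  expect_equal(got$transform$rotation, diag(3), tolerance = 1e-9)
  expect_equal(got$transform$translation, c(0, 0, 0), tolerance = 1e-9)
})

test_that("weights concentrated on a symmetric subregion align that subregion exactly", {
  tpl <- small_template()
  V <- tpl$mesh$vertices
  # displace a patch asymmetrically, keep the rest exactly symmetric
  patch <- order(-V[, 2])[1:20]                 # top of the face
  keep <- setdiff(seq_len(nrow(V)), unique(c(patch, tpl$pairing[patch])))
  face <- V
  face[patch, 3] <- face[patch, 3] + 3
  w <- rep(0, nrow(V)); w[keep] <- 1
  res <- weighted_procrustes(face, mirror_relabel(face, tpl), weights = w)
  resid <- sqrt(rowSums((face - res$aligned$positions)^2))
  expect_lt(max(resid[keep]), 1e-9)

  expect_error(weighted_procrustes(face, mirror_relabel(face, tpl),
                                   weights = rep(0, nrow(V))), "zero")
})

test_that("degenerate collinear configurations are rejected", {
  X <- cbind(seq_len(10), 0, 0)
  expect_error(facefa:::kabsch_weighted(X, X + 1), "collinear|degenerate")
})

test_that("total asymmetry recovers planted antisymmetric perturbations and is rigid-invariant", {
  tpl <- small_template()
  V <- tpl$mesh$vertices
  set.seed(3)
  nrm <- facefa:::vertex_normals(V, tpl$mesh$faces)
  qb <- facefa:::normal_rigid_basis(V, nrm, tpl$pairing)
  u <- facefa:::unit_asym_field(tpl, 10, 30, nrm, qb)

  # symmetric face: zero field
  z <- total_asymmetry(V, tpl)
  expect_lt(facefa:::field_rms(z$displacements), 1e-12)

  # planted half-field: recovered total equals the full antisymmetric field
  amp <- 0.8
  face <- V + (amp / 2) * u
  ta <- total_asymmetry(face, tpl)
  expect_lt(max(abs(ta$displacements - amp * u)), 1e-6)

  # invariance to rigid pre-transformation of the input face
  tr <- random_rigid(15, 10)
  ta2 <- total_asymmetry(apply_transform(tr, face), tpl)
  expect_lt(max(abs(ta2$displacements - ta$displacements)), 1e-6)
})

test_that("DA is the vertex-wise mean and FA the DA-corrected residual", {
  tpl <- small_template()
  n <- nrow(tpl$mesh$vertices)
  set.seed(4)
  v <- matrix(rnorm(3 * n), n, 3)
  f1 <- asymmetry_field(v, "total")
  f2 <- asymmetry_field(-v, "total")
  da <- directional_asymmetry(list(f1, f2))
  expect_equal(max(abs(da$displacements)), 0)

  da2 <- directional_asymmetry(list(f1, f1, f1))
  expect_equal(da2$displacements, v)

  # fa = total - da; sample mean of FA fields is identically zero
  fields <- lapply(1:5, function(i) asymmetry_field(matrix(rnorm(3 * n), n, 3),
                                                    "total"))
  da3 <- directional_asymmetry(fields)
  fas <- lapply(fields, fluctuating_asymmetry, da = da3)
  acc <- Reduce(`+`, lapply(fas, `[[`, "displacements"))
  expect_lt(max(abs(acc)), 1e-10)

  expect_equal(fluctuating_asymmetry(f1, da2)$displacements, matrix(0, n, 3))
  expect_error(directional_asymmetry(list(f1)), "two")
  expect_error(fluctuating_asymmetry(
    f1, asymmetry_field(matrix(0, 4, 3), "DA")), "differ")
})

test_that("DA of zero-mean antisymmetric samples vanishes within Monte-Carlo error", {
  tpl <- small_template(80)
  V <- tpl$mesh$vertices
  nrm <- facefa:::vertex_normals(V, tpl$mesh$faces)
  qb <- facefa:::normal_rigid_basis(V, nrm, tpl$pairing)
  set.seed(5)
  n_rep <- 200
  fields <- lapply(seq_len(n_rep), function(i) {
    asymmetry_field(0.5 * facefa:::unit_asym_field(tpl, 10, 30, nrm, qb),
                    "total")
  })
  da <- directional_asymmetry(fields)
  # per-vertex SE of the mean ~ field sd / sqrt(n)
  norms <- sqrt(rowSums(da$displacements^2))
  se <- 0.5 / sqrt(n_rep)
  expect_lt(mean(norms), 3 * se)
})

test_that("fa_score reduces fields as stated", {
  tpl <- small_template()
  n <- nrow(tpl$mesh$vertices)
  zero <- asymmetry_field(matrix(0, n, 3), "FA")
  expect_equal(fa_score(zero)$value, 0)

  one <- matrix(0, n, 3); one[7, ] <- c(3, 4, 0)   # norm 5
  f <- asymmetry_field(one, "FA")
  expect_equal(fa_score(f)$value, 5 / sqrt(n), tolerance = 1e-12)
  expect_equal(fa_score(f, "mean-norm")$value, 5 / n, tolerance = 1e-12)

  set.seed(6)
  g <- asymmetry_field(matrix(rnorm(3 * n), n, 3), "FA")
  expect_equal(fa_score(asymmetry_field(2.5 * g$displacements, "FA"))$value,
               2.5 * fa_score(g)$value, tolerance = 1e-12)

  expect_error(fa_score(asymmetry_field(one, "total")), "FA")
})

test_that("heat-map channel averages vertex norms and localizes planted patches", {
  tpl <- small_template()
  n <- nrow(tpl$mesh$vertices)
  zero <- asymmetry_field(matrix(0, n, 3), "total")
  expect_equal(heatmap_field(list(zero, zero)), rep(0, n))

  set.seed(7)
  v <- matrix(rnorm(3 * n), n, 3)
  one <- asymmetry_field(v, "total")
  expect_equal(heatmap_field(list(one)), sqrt(rowSums(v^2)))

  # planted high-asymmetry patch: channel maximum inside the patch
  V <- tpl$mesh$vertices
  ctr <- V[which.max(V[, 3]), ]
  d2 <- rowSums(sweep(V, 2, ctr)^2)
  patch <- which(d2 < 400)
  f <- matrix(rnorm(3 * n, 0, 0.05), n, 3)
  f[patch, 1] <- f[patch, 1] + 2
  ch <- heatmap_field(list(asymmetry_field(f, "total")))
  expect_true(which.max(ch) %in% patch)

  hm <- heatmap_field(list(one), template = tpl)
  expect_s3_class(hm, "surface_mesh")
  expect_equal(hm$scalar, sqrt(rowSums(v^2)))
})

test_that("measure_fa_sample ties the pieces together on faces in correspondence", {
  p <- sim_params(n_individuals = 8, sensor_noise_sd = 0, jitter_rot_deg = 0,
                  jitter_trans_mm = 0, template_vertices = 150, seed = 8)
  sim <- simulate_faces(p)
  direct <- purrr::imap(sim$meshes,
                        function(m, id) facefa:::mapped_face(m$vertices, id))
  fs <- measure_fa_sample(direct, sim$template)
  expect_s3_class(tidy(fs), "tbl_df")
  expect_equal(nrow(tidy(fs)), 8L)
  expect_true(all(tidy(fs)$fa_score >= 0))
  # sample mean of FA fields is zero by construction
  acc <- Reduce(`+`, lapply(fs$fa, `[[`, "displacements"))
  expect_lt(max(abs(acc)), 1e-9)
  expect_equal(glance(fs)$n, 8L)
})
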