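#' Parameters of the synthetic face-sample generator
#'
#' Each synthetic scan is built as: symmetric template + individual symmetric
#' deformation + a shared directional-asymmetry (DA) field with an individual
#' scale + an individual zero-mean fluctuating-asymmetry (FA) field + Gaussian
#' sensor noise, followed by random rigid pose jitter. Asymmetric fields are
#' planted as half-fields so that the measured asymmetry (face minus mirror)
#' has exactly the stated magnitude: a planted FA magnitude sigma yields a
#' total-asymmetry contribution of rms sigma mm.
#'
#' @param n_individuals Number of faces.
#' @param template_vertices,template_width Template density and face width
#'   (mm) passed to [make_symmetric_template()].
#' @param sigma_sym SD (rms mm) of the individual symmetric shape variation.
#' @param da_rms rms magnitude (mm) of the shared DA field as measured in the
#'   total-asymmetry decomposition.
#' @param da_scale_sd SD of the per-individual multiplicative DA scale
#'   (mean 1).
#' @param fa_sigma_mean,fa_sigma_sd Mean and SD (mm) of the per-individual FA
#'   magnitude, drawn from a normal truncated at zero.
#' @param sensor_noise_sd Per-coordinate Gaussian scanner noise SD (mm).
#' @param jitter_rot_deg,jitter_trans_mm Ranges of the uniform rigid pose
#'   jitter (max rotation angle about a random axis; max translation per
#'   axis).
#' @param field_smoothness Gaussian kernel width (mm) of the random smooth
#'   fields; `n_bumps` controls their spatial complexity.
#' @param n_bumps Number of Gaussian bumps per random field.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_individuals = 50,
                       template_vertices = 300,
                       template_width = 140,
                       sigma_sym = 2,
                       da_rms = 1,
                       da_scale_sd = 0.2,
                       fa_sigma_mean = 0.5,
                       fa_sigma_sd = 0.15,
                       sensor_noise_sd = 0.1,
                       jitter_rot_deg = 5,
                       jitter_trans_mm = 5,
                       field_smoothness = 30,
                       n_bumps = 12,
                       seed = 1L) {
  stopifnot(n_individuals >= 1, sigma_sym >= 0, da_rms >= 0, da_scale_sd >= 0,
            fa_sigma_mean >= 0, fa_sigma_sd >= 0, sensor_noise_sd >= 0,
            jitter_rot_deg >= 0, jitter_trans_mm >= 0)
  structure(as.list(environment()), class = "sim_params")
}

#' Build a face-like mirror-symmetric template mesh
#'
#' A regular grid over the face's frontal extent, displaced in depth by a
#' smooth dome with nose and brow ridges, mirrored exactly across the plane
#' x = 0. The grid uses an odd number of columns so a column of midline
#' vertices lies exactly on x = 0; the left-right pairing maps column i to
#' column nx+1-i. The construction is exactly symmetric in floating point, so
#' [validate_template()] passes at tolerance 0.
#'
#' @param n_vertices Approximate vertex count (honoured within meshing
#'   granularity; a published-scale density of several thousand vertices is a
#'   configuration, not a constant).
#' @param width,height,depth Face extents in mm.
#' @return A [template_mesh()].
#' @export
make_symmetric_template <- function(n_vertices = 150, width = 140,
                                    height = 180, depth = 45) {
  stopifnot(n_vertices >= 10)
  aspect <- height / width
  nx <- max(5L, round(sqrt(n_vertices / aspect)))
  if (nx %% 2L == 0L) nx <- nx + 1L
  ny <- max(4L, round(n_vertices / nx))
  half <- (nx - 1L) %/% 2L
  upos <- seq_len(half) / half
  u <- c(-rev(upos), 0, upos)        # exactly antisymmetric abscissae
  v <- seq(-1, 1, length.out = ny)
  uu <- rep(u, times = ny)
  vv <- rep(v, each = nx)
  # depth profile: dome + nose ridge + brow ridge, all even in u
  z <- depth * (
    0.8 * exp(-(uu^2 + 0.6 * vv^2)) +
      0.35 * exp(-(uu / 0.18)^2 - ((vv + 0.15) / 0.45)^2) +
      0.12 * exp(-((vv - 0.40) / 0.15)^2) * exp(-(uu / 0.7)^2))
  V <- cbind(uu * width / 2, vv * height / 2, z)
  # grid triangulation with mirror-symmetric quad diagonals: the left and
  # right halves use opposite diagonals so the face set (and therefore the
  # vertex normals) is exactly invariant under the left-right reflection
  idx <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  mid <- (nx + 1L) %/% 2L
  left <- i < mid
  F <- rbind(
    cbind(idx(i[left], j[left]), idx(i[left] + 1L, j[left]),
          idx(i[left] + 1L, j[left] + 1L)),
    cbind(idx(i[left], j[left]), idx(i[left] + 1L, j[left] + 1L),
          idx(i[left], j[left] + 1L)),
    cbind(idx(i[!left], j[!left]), idx(i[!left] + 1L, j[!left]),
          idx(i[!left], j[!left] + 1L)),
    cbind(idx(i[!left] + 1L, j[!left]), idx(i[!left] + 1L, j[!left] + 1L),
          idx(i[!left], j[!left] + 1L)))
  pairing <- idx(rep(nx:1, times = ny), rep(seq_len(ny), each = nx))
  template_mesh(surface_mesh(V, F), pairing)
}

# Random smooth 3D vector field over the template vertices: a sum of Gaussian
# bumps centred on randomly chosen vertices, independent per coordinate.
smooth_field <- function(template, n_bumps = 12, lambda = 30) {
  V <- template$mesh$vertices
  n <- nrow(V)
  ctr <- V[sample.int(n, n_bumps, replace = TRUE), , drop = FALSE]
  coefs <- matrix(stats::rnorm(n_bumps * 3L), n_bumps, 3L)
  D2 <- outer(rowSums(V^2), rowSums(ctr^2), "+") - 2 * V %*% t(ctr)
  K <- exp(-pmax(D2, 0) / (2 * lambda^2))
  K %*% coefs
}

symmetrize_field <- function(f, template) (f + mirror_field(f, template)) / 2

antisymmetrize_field <- function(f, template) (f - mirror_field(f, template)) / 2

# Basis of the template's rigid motions expressed along vertex normals and
# restricted to the antisymmetric scalar subspace, used to make planted
# asymmetric height fields orthogonal to what a Procrustes superimposition
# can absorb while keeping them exactly antisymmetric.
normal_rigid_basis <- function(V, nrm, pairing) {
  n <- nrow(V)
  Xc <- sweep(V, 2L, colMeans(V))
  b <- cbind(nrm[, 1], nrm[, 2], nrm[, 3],
             rowSums(cross3(matrix(rep(c(1, 0, 0), each = n), n), Xc) * nrm),
             rowSums(cross3(matrix(rep(c(0, 1, 0), each = n), n), Xc) * nrm),
             rowSums(cross3(matrix(rep(c(0, 0, 1), each = n), n), Xc) * nrm))
  b <- (b - b[pairing, , drop = FALSE]) / 2
  keep <- sqrt(colMeans(b^2)) > 1e-9
  qr.Q(qr(b[, keep, drop = FALSE]))
}

# Antisymmetric unit field whose *measured* asymmetry (f - mirror(f) applied
# to a face built as base + f/2) has rms 1. The field is directed along the
# template's vertex normals: a tangential displacement of a smooth surface is
# a re-parametrization, not a change of shape, so planted asymmetry must act
# normally to be geometrically real. The scalar height profile is
# antisymmetrized across the pairing and orthogonalized against the rigid
# motions (whose components a Procrustes superimposition would absorb).
unit_asym_field <- function(template, n_bumps, lambda, nrm, qb) {
  g <- smooth_field(template, n_bumps, lambda)[, 1]
  h <- (g - g[template$pairing]) / 2
  h <- h - as.vector(qb %*% crossprod(qb, h))
  f <- h * nrm
  r <- field_rms(f)
  if (r < 1e-12) stop("degenerate random asymmetric field", call. = FALSE)
  f / r
}

#' Simulate a sample of synthetic face scans with known asymmetry structure
#'
#' @param params A [sim_params()].
#' @param template Optional pre-built [template_mesh()] (must be symmetric);
#'   by default one is built from `params`.
#' @return Object of class `fa_face_sim`: list with `meshes` (named list of
#'   [surface_mesh()]), `truth` (tibble: `source_id`, `fa_mag_true`,
#'   `da_scale`), `template`, `da_field` (the planted measured-scale DA
#'   field), and `params`. Deterministic given `params$seed`.
#' @export
simulate_faces <- function(params = sim_params(), template = NULL) {
  stopifnot(inherits(params, "sim_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)
  if (is.null(template)) {
    template <- make_symmetric_template(params$template_vertices,
                                        params$template_width)
  }
  V <- template$mesh$vertices
  F <- template$mesh$faces
  n <- params$n_individuals
  nrm <- vertex_normals(V, F)
  qb <- normal_rigid_basis(V, nrm, template$pairing)
  da_unit <- if (params$da_rms > 0) {
    unit_asym_field(template, params$n_bumps, params$field_smoothness, nrm, qb)
  } else matrix(0, nrow(V), 3L)
  ids <- sprintf("id%03d", seq_len(n))
  da_scales <- 1 + stats::rnorm(n, 0, params$da_scale_sd)
  fa_mags <- abs(stats::rnorm(n, params$fa_sigma_mean, params$fa_sigma_sd))
  if (params$fa_sigma_mean == 0 && params$fa_sigma_sd == 0) fa_mags <- rep(0, n)
  meshes <- vector("list", n)
  fa_mag_true <- numeric(n)
  for (i in seq_len(n)) {
    pos <- V
    if (params$sigma_sym > 0) {
      s <- symmetrize_field(smooth_field(template, params$n_bumps,
                                         params$field_smoothness), template)
      r <- field_rms(s)
      if (r > 1e-12) pos <- pos + s * (params$sigma_sym / r)
    }
    if (params$da_rms > 0) {
      pos <- pos + (da_scales[i] * params$da_rms / 2) * da_unit
    }
    fa_unit <- if (fa_mags[i] > 0) {
      unit_asym_field(template, params$n_bumps,
                      params$field_smoothness, nrm, qb)
    } else matrix(0, nrow(V), 3L)
    pos <- pos + (fa_mags[i] / 2) * fa_unit
    # ground truth: rms of the planted deviation from the population-mean
    # asymmetry (idiosyncratic field plus the individual's DA-scale deviation,
    # which the DA correction cannot and should not remove)
    fa_mag_true[i] <- field_rms(fa_mags[i] * fa_unit +
                                  (da_scales[i] - 1) * params$da_rms * da_unit)
    meshes[[i]] <- pos
  }
  clean <- meshes
  meshes <- lapply(meshes, scan_once, params = params, faces = F)
  names(meshes) <- names(clean) <- ids
  structure(list(
    meshes = meshes,
    clean = clean,
    truth = tibble::tibble(source_id = ids, fa_mag_true = fa_mag_true,
                           fa_mag_idiosyncratic = fa_mags,
                           da_scale = da_scales),
    template = template,
    da_field = params$da_rms * da_unit,
    params = params),
    class = "fa_face_sim")
}

# One scanning event: sensor noise plus rigid pose jitter on clean geometry.
scan_once <- function(pos, params, faces) {
  if (params$sensor_noise_sd > 0) {
    pos <- pos + matrix(stats::rnorm(length(pos), 0, params$sensor_noise_sd),
                        nrow(pos), 3L)
  }
  if (params$jitter_rot_deg > 0 || params$jitter_trans_mm > 0) {
    axis <- stats::rnorm(3)
    ang <- stats::runif(1, -params$jitter_rot_deg, params$jitter_rot_deg)
    tr <- rigid_transform(rotation_about(axis, ang),
                          stats::runif(3, -params$jitter_trans_mm,
                                       params$jitter_trans_mm))
    pos <- apply_transform(tr, pos)
  }
  surface_mesh(pos, faces)
}

#' Re-scan the individuals of a simulated sample
#'
#' Produces a second, independent "scanning session" of the same synthetic
#' individuals: the clean per-individual geometry is kept and only the sensor
#' noise and rigid pose jitter are redrawn — the measurement model of a
#' retest-reliability study.
#'
#' @param sim An `fa_face_sim` from [simulate_faces()].
#' @param seed Seed for the new session's noise and jitter.
#' @return An `fa_face_sim` with new `meshes` and identical `truth`.
#' @export
rescan_faces <- function(sim, seed) {
  stopifnot(inherits(sim, "fa_face_sim"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sim$meshes <- lapply(sim$clean, scan_once, params = sim$params,
                       faces = sim$template$mesh$faces)
  sim$params$seed <- seed
  sim
}

#' @export
print.fa_face_sim <- function(x, ...) {
  cat(sprintf("<fa_face_sim> %d faces, template %d vertices, seed %d\n",
              length(x$meshes), nrow(x$template$mesh$vertices), x$params$seed))
  invisible(x)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Parameters of the synthetic rating generator
#'
#' Simulated raters score each target on each item. The target's latent
#' attractiveness is a linear blend of its standardized true FA magnitude and
#' independent noise chosen so that the latent correlation with true FA is
#' `target_r`; each rating adds independent rater noise, which sets the
#' expected interrater reliability ICC(3,k) = 1 / (1 + rater_noise_sd^2 / k).
#'
#' @param target_r Latent correlation between true FA magnitude and
#'   attractiveness (signed; negative plants the inverse association).
#' @param n_raters Named or unnamed length-2 vector: raters per sex.
#' @param rater_noise_sd Rater noise SD in latent (unit-variance) units.
#' @param scale Length-2 rating scale bounds.
#' @param items Item labels.
#' @param round_scores Round and clip scores to scale integers (realism);
#'   leave off for exact recovery studies.
#' @param familiar_prob Probability that a rater-target entry is flagged as
#'   highly familiar (familiarity code 3).
#' @param seed Integer seed.
#' @return An object of class `rating_sim_params`.
#' @export
rating_sim_params <- function(target_r = 0,
                              n_raters = c(male = 15, female = 15),
                              rater_noise_sd = 2,
                              scale = c(-3, 3),
                              items = c("short", "long"),
                              round_scores = FALSE,
                              familiar_prob = 0,
                              seed = 1L) {
  stopifnot(abs(target_r) <= 1, all(n_raters >= 1), rater_noise_sd >= 0,
            length(scale) == 2L, familiar_prob >= 0, familiar_prob <= 1)
  structure(as.list(environment()), class = "rating_sim_params")
}

#' Simulate an attractiveness-rating table for a set of targets
#'
#' @param truth Tibble with `source_id` and `fa_mag_true` (e.g. from
#'   [simulate_faces()]).
#' @param params A [rating_sim_params()].
#' @return Tidy ratings tibble (`target_id`, `rater_id`, `rater_sex`, `item`,
#'   `score`, `familiarity`) with attributes `scale` and `expected_icc`.
#' @export
simulate_ratings <- function(truth, params = rating_sim_params()) {
  stopifnot(inherits(params, "rating_sim_params"),
            all(c("source_id", "fa_mag_true") %in% names(truth)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)
  n <- nrow(truth)
  zfa <- if (stats::sd(truth$fa_mag_true) > 0) {
    as.numeric(scale(truth$fa_mag_true))
  } else rep(0, n)
  r <- params$target_r
  latent <- r * zfa + sqrt(1 - r^2) * stats::rnorm(n)
  sexes <- if (!is.null(names(params$n_raters))) names(params$n_raters)
           else c("male", "female")
  raters <- purrr::map2_dfr(sexes, params$n_raters, function(sx, k) {
    tibble::tibble(rater_id = paste0(sx, "_", seq_len(k)), rater_sex = sx)
  })
  grid <- tidyr::expand_grid(target_id = truth$source_id,
                             rater_id = raters$rater_id,
                             item = params$items)
  grid <- dplyr::left_join(grid, raters, by = "rater_id")
  grid$score <- latent[match(grid$target_id, truth$source_id)] +
    stats::rnorm(nrow(grid), 0, params$rater_noise_sd)
  if (params$round_scores) {
    grid$score <- pmin(pmax(round(grid$score), params$scale[1]), params$scale[2])
  }
  grid$familiarity <- ifelse(stats::runif(nrow(grid)) < params$familiar_prob, 3L, 1L)
  k_total <- sum(params$n_raters)
  attr(grid, "scale") <- params$scale
  attr(grid, "expected_icc") <- 1 / (1 + params$rater_noise_sd^2 / k_total)
  attr(grid, "seed") <- params$seed
  grid
}
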