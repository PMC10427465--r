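#' Parameters of the non-rigid template-to-scan mapping
#'
#' The non-rigid iterative-closest-points stage fits a per-vertex displacement
#' field regularized by a graph-Laplacian smoothness penalty whose weight
#' follows a decreasing (coarse-to-fine) stiffness schedule.
#'
#' @param max_iterations Total iteration budget across the whole schedule.
#' @param stiffness_schedule Strictly positive, non-increasing sequence of
#'   smoothness weights.
#' @param correspondence_distance_cap Correspondences farther than this (mm)
#'   are rejected and the vertex is extrapolated from its neighbours.
#' @param normal_compatibility_min Minimum cosine between the deformed
#'   template's vertex normal and the scan's surface normal at the
#'   correspondence for it to be accepted.
#' @param convergence_tol Stop a stiffness level once the mean per-vertex
#'   motion per iteration falls below this (mm).
#' @param displacement_prior Weight of a weak zero-deformation prior that
#'   anchors the tangential parametrization (tangential position on a smooth
#'   surface is otherwise determined only by the regularizer); expressed
#'   relative to the unit data-term weight.
#' @return An object of class `mapping_params`.
#' @export
mapping_params <- function(max_iterations = 100,
                           stiffness_schedule = c(50, 20, 8, 3, 1, 0.4,
                                                  0.15, 0.05),
                           correspondence_distance_cap = 10,
                           normal_compatibility_min = cos(60 * pi / 180),
                           convergence_tol = 1e-3,
                           displacement_prior = 0.1) {
  stopifnot(max_iterations >= 1,
            all(stiffness_schedule > 0),
            all(diff(stiffness_schedule) <= 0),
            correspondence_distance_cap > 0,
            convergence_tol > 0, displacement_prior >= 0)
  structure(list(max_iterations = as.integer(max_iterations),
                 stiffness_schedule = as.numeric(stiffness_schedule),
                 correspondence_distance_cap = correspondence_distance_cap,
                 normal_compatibility_min = normal_compatibility_min,
                 convergence_tol = convergence_tol,
                 displacement_prior = displacement_prior),
            class = "mapping_params")
}

#' Rigidly align a template onto a scan by iterative closest points
#'
#' Minimizes the sum of squared distances from the (transformed) template
#' vertices to their closest points on the scan surface, alternating
#' closest-point assignment with closed-form weighted superimposition.
#'
#' @param template A [template_mesh()] or [surface_mesh()].
#' @param scan A [surface_mesh()].
#' @param allow_scale Estimate a global scale factor (default: pure rigid).
#' @param max_iter,tol ICP iteration cap and convergence tolerance on the mean
#'   vertex motion (mm).
#' @return A [rigid_transform()] mapping template coordinates into scan
#'   coordinates. Warns if the iteration cap is reached before convergence.
#' @export
rigid_align <- function(template, scan, allow_scale = FALSE,
                        max_iter = 200, tol = 1e-6) {
  X <- template_vertices(template)
  stopifnot(inherits(scan, "surface_mesh"))
  accel <- mesh_accel(scan)
  # initialize with centroid alignment (and rms-radius scale if estimating it)
  s0 <- 1
  if (allow_scale) {
    rx <- sqrt(mean(rowSums(sweep(X, 2L, colMeans(X))^2)))
    ry <- sqrt(mean(rowSums(sweep(scan$vertices, 2L, colMeans(scan$vertices))^2)))
    s0 <- ry / rx
  }
  tr <- rigid_transform(diag(3), colMeans(scan$vertices) - s0 * colMeans(X), s0)
  Yprev <- apply_transform(tr, X)
  converged <- FALSE
  best <- list(res = Inf, tr = tr)
  min_motion <- Inf
  stagnant <- 0L
  for (it in seq_len(max_iter)) {
    cp <- closest_points(Yprev, accel)
    tr <- kabsch_weighted(X, cp$points, allow_scale = allow_scale)
    Y <- apply_transform(tr, X)
    res <- mean(rowSums((Y - cp$points)^2))
    if (res < best$res) best <- list(res = res, tr = tr)
    motion <- mean(sqrt(rowSums((Y - Yprev)^2)))
    Yprev <- Y
    # converged: per-iteration motion negligible. Stagnant: the motion has
    # stopped shrinking for a while, i.e. ICP oscillates in a small limit
    # cycle (typical on noisy surfaces); keep the best-residual pose seen.
    if (motion < 0.7 * min_motion) stagnant <- 0L else stagnant <- stagnant + 1L
    min_motion <- min(min_motion, motion)
    if (motion < tol || stagnant >= 12L) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("rigid_align reached max_iter before converging; returning best transform")
  }
  tr <- best$tr
  # polish with soft-assignment targets: the hard closest-point objective has
  # many local minima a few hundredths of a millimetre apart (facet
  # switching); blending candidate faces with a Gaussian kernel merges them,
  # so the refined pose no longer depends on the initial pose of the scan
  Y <- apply_transform(tr, X)
  for (it in seq_len(max_iter)) {
    cp <- soft_closest_points(Y, accel)
    tr <- kabsch_weighted(X, cp, allow_scale = allow_scale)
    Y2 <- apply_transform(tr, X)
    motion <- mean(sqrt(rowSums((Y2 - Y)^2)))
    Y <- Y2
    if (motion < 1e-9) break
  }
  tr
}

# Smoothly tapered acceptance weight for a correspondence: full weight well
# inside the distance cap and normal-compatibility threshold, ramping to zero
# at them.
gate_taper <- function(dist, compat, params) {
  cap <- params$correspondence_distance_cap
  wd <- pmin(1, pmax(0, (cap - dist) / (0.25 * cap)))
  wc <- pmin(1, pmax(0, (compat - params$normal_compatibility_min) / 0.15))
  wd * wc
}

template_vertices <- function(template) {
  if (inherits(template, "template_mesh")) template$mesh$vertices
  else if (inherits(template, "surface_mesh")) template$vertices
  else stop("template must be a template_mesh or surface_mesh", call. = FALSE)
}

template_faces <- function(template) {
  if (inherits(template, "template_mesh")) template$mesh$faces
  else template$faces
}

#' Map the template onto a scan with non-rigid iterative closest points
#'
#' After rigid initialization, fits a smooth per-vertex displacement field by
#' alternating (i) closest-point correspondence from the deformed template to
#' the scan surface, with rejection by distance cap and normal compatibility,
#' and (ii) a sparse linear solve of the data term plus graph-Laplacian
#' smoothness penalty. Rejected vertices carry no data term and are
#' extrapolated by the regularizer. The result is one position per template
#' vertex in dense correspondence with the scan.
#'
#' @inheritParams rigid_align
#' @param params A [mapping_params()].
#' @param source_id Identifier stored with the result.
#' @return A `mapped_face`: list with `positions` (n x 3 mm, template order)
#'   and `source_id`.
#' @export
nonrigid_map <- function(template, scan, params = mapping_params(),
                         allow_scale = FALSE, source_id = NULL) {
  stopifnot(inherits(params, "mapping_params"), inherits(scan, "surface_mesh"))
  Xt <- template_vertices(template)
  Ft <- template_faces(template)
  tr <- rigid_align(template, scan, allow_scale = allow_scale)
  X <- apply_transform(tr, Xt)
  accel <- mesh_accel(scan)
  cp0 <- closest_points(X, accel)
  if (stats::median(cp0$dist) > params$correspondence_distance_cap) {
    stop("mapping failure: scan does not overlap the rigidly aligned template",
         call. = FALSE)
  }
  n <- nrow(X)
  L <- graph_laplacian(Ft, n)
  D <- matrix(0, n, 3L)
  inner_cap <- max(2L, ceiling(params$max_iterations / length(params$stiffness_schedule)))
  total <- 0L
  tpl_accel <- mesh_accel(surface_mesh(X, Ft))
  S <- scan$vertices
  Sn <- vertex_normals(S, scan$faces)
  for (alpha in params$stiffness_schedule) {
    for (inner in seq_len(inner_cap)) {
      Y <- X + D
      nrm <- vertex_normals(Y, Ft)
      # forward: deformed template vertices -> scan surface; the distance and
      # normal gates taper smoothly to zero so acceptance is continuous in
      # the pose (binary gates make the fit jump when a borderline
      # correspondence flips)
      cp <- closest_points(Y, accel)
      compat <- rowSums(nrm * cp$normals)
      w <- gate_taper(cp$dist, compat, params)
      # reverse: scan vertices -> deformed template surface, expressed in
      # barycentric coordinates; anchors the tangential parametrization
      tpl_accel <- accel_update(tpl_accel, Y)
      rp <- closest_points(S, tpl_accel)
      rcompat <- rowSums(Sn * rp$normals)
      rw <- gate_taper(rp$dist, rcompat, params) *
        border_taper(rp$points, tpl_accel)
      rok <- which(rw > 0)
      A <- Matrix::Diagonal(n, x = w + params$displacement_prior + 1e-9) +
        alpha * L
      rhs <- w * (cp$points - X)
      if (length(rok) > 0L) {
        fb <- tpl_accel$F[rp$face[rok], , drop = FALSE]
        B <- Matrix::sparseMatrix(
          i = rep(seq_along(rok), 3L),
          j = as.vector(fb),
          x = as.vector(rp$bary[rok, , drop = FALSE]),
          dims = c(length(rok), n))
        Wr <- Matrix::Diagonal(length(rok), x = rw[rok])
        A <- A + Matrix::crossprod(B, Wr %*% B)
        rhs <- rhs + as.matrix(Matrix::crossprod(B, rw[rok] *
                                                      (S[rok, , drop = FALSE] -
                                                         as.matrix(B %*% X))))
      }
      Dnew <- as.matrix(Matrix::solve(A, rhs))
      motion <- mean(sqrt(rowSums((Dnew - D)^2)))
      D <- Dnew
      total <- total + 1L
      if (motion < params$convergence_tol) break
    }
  }
  structure(list(positions = X + D, source_id = source_id),
            class = "mapped_face")
}

#' @export
print.mapped_face <- function(x, ...) {
  cat(sprintf("<mapped_face> %d vertices%s\n", nrow(x$positions),
              if (is.null(x$source_id)) "" else paste0(" [", x$source_id, "]")))
  invisible(x)
}

mapped_face <- function(positions, source_id = NULL) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3L, all(is.finite(positions)))
  structure(list(positions = positions, source_id = source_id),
            class = "mapped_face")
}
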