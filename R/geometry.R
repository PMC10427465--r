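# Low-level mesh geometry used by the registration and asymmetry code.
# All coordinates are in millimetres.

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

face_normals <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  cross3(b - a, c_ - a)  # area-weighted (unnormalized)
}

vertex_normals <- function(vertices, faces) {
  fn <- face_normals(vertices, faces)
  n <- matrix(0, nrow(vertices), 3L)
  for (j in 1:3) {
    idx <- faces[, j]
    for (k in 1:3) {
      n[, k] <- n[, k] + tapply_sum(fn[, k], idx, nrow(vertices))
    }
  }
  normalize_rows(n)
}

tapply_sum <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# Precomputed acceleration structure for repeated closest-point queries.
mesh_accel <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  vf <- vector("list", nrow(V))
  sp <- split(rep(seq_len(nrow(F)), 3L), as.vector(F))
  vf[as.integer(names(sp))] <- sp
  fn <- normalize_rows(face_normals(V, F))
  # faces touching a border edge (an edge used by only one face): matches on
  # them are unreliable and are rejected by the non-rigid fit
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  border_edge <- names(which(table(key) == 1L))
  fidx <- rep(seq_len(nrow(F)), 3L)
  border_face <- sort(unique(fidx[key %in% border_edge]))
  is_border <- logical(nrow(F))
  is_border[border_face] <- TRUE
  border_vertices <- sort(unique(as.vector(F[border_face, ])))
  mean_edge <- {
    e2 <- mesh_edges(F)
    mean(sqrt(rowSums((V[e2[, 1], , drop = FALSE] -
                         V[e2[, 2], , drop = FALSE])^2)))
  }
  list(V = V, F = F, vert_faces = vf, face_normals = fn,
       border_face = is_border, border_vertices = border_vertices,
       mean_edge = mean_edge)
}

# Smooth weight that fades matches near an open-mesh border: 0 at the border
# vertices, 1 beyond about 1.5 edge lengths. Continuous in the query point,
# unlike a binary border-face rejection.
border_taper <- function(points, accel) {
  bv <- accel$border_vertices
  if (length(bv) == 0L) return(rep(1, nrow(points)))
  B <- accel$V[bv, , drop = FALSE]
  d2 <- outer(rowSums(points^2), rowSums(B^2), "+") - 2 * points %*% t(B)
  dmin <- sqrt(pmax(apply(d2, 1L, min), 0))
  pmin(1, dmin / (0.6 * accel$mean_edge))
}

nearest_vertex <- function(P, V, chunk = 2048L) {
  nP <- nrow(P)
  out <- integer(nP)
  v2 <- rowSums(V^2)
  i <- 1L
  while (i <= nP) {
    j <- min(i + chunk - 1L, nP)
    Pc <- P[i:j, , drop = FALSE]
    D <- outer(rowSums(Pc^2), v2, "+") - 2 * Pc %*% t(V)
    out[i:j] <- max.col(-D, ties.method = "first")
    i <- j + 1L
  }
  out
}

# Closest point on each triangle (A, B, C) for the paired query points Pp,
# fully vectorized over rows. Returns the closest points and their squared
# distances.
tri_closest <- function(Pp, A, B, C) {
  E0 <- B - A; E1 <- C - A; D0 <- Pp - A
  a <- rowSums(E0 * E0); b <- rowSums(E0 * E1); c_ <- rowSums(E1 * E1)
  d <- rowSums(E0 * D0); e <- rowSums(E1 * D0)
  det <- a * c_ - b * b
  ok <- det > 1e-300
  u <- ifelse(ok, (c_ * d - b * e) / det, -1)
  v <- ifelse(ok, (a * e - b * d) / det, -1)
  inside <- ok & u >= 0 & v >= 0 & (u + v) <= 1
  # interior candidate
  Pint <- A + u * E0 + v * E1
  d_int <- ifelse(inside, rowSums((Pp - Pint)^2), Inf)
  # edge candidates
  t1 <- pmin(pmax(ifelse(a > 0, d / a, 0), 0), 1); P1 <- A + t1 * E0
  t2 <- pmin(pmax(ifelse(c_ > 0, e / c_, 0), 0), 1); P2 <- A + t2 * E1
  E2 <- C - B; D1 <- Pp - B
  c2 <- rowSums(E2 * E2)
  t3 <- pmin(pmax(ifelse(c2 > 0, rowSums(E2 * D1) / c2, 0), 0), 1); P3 <- B + t3 * E2
  d1 <- rowSums((Pp - P1)^2); d2 <- rowSums((Pp - P2)^2); d3 <- rowSums((Pp - P3)^2)
  dmat <- cbind(d_int, d1, d2, d3)
  which_c <- max.col(-dmat, ties.method = "first")
  best <- Pint
  sel <- which_c == 2L; best[sel, ] <- P1[sel, , drop = FALSE]
  sel <- which_c == 3L; best[sel, ] <- P2[sel, , drop = FALSE]
  sel <- which_c == 4L; best[sel, ] <- P3[sel, , drop = FALSE]
  list(points = best, d2 = dmat[cbind(seq_along(which_c), which_c)])
}

# Closest point on the surface of `accel` for every row of P.
# Returns list(points, normals, dist, face).
closest_points <- function(P, accel) {
  V <- accel$V
  F <- accel$F
  nn <- nearest_vertex(P, V)
  fs <- accel$vert_faces[nn]
  lens <- lengths(fs)
  pi_ <- rep.int(seq_len(nrow(P)), lens)
  fi <- unlist(fs, use.names = FALSE)
  A <- V[F[fi, 1], , drop = FALSE]
  B <- V[F[fi, 2], , drop = FALSE]
  C <- V[F[fi, 3], , drop = FALSE]
  Pp <- P[pi_, , drop = FALSE]
  tc <- tri_closest(Pp, A, B, C)
  best <- tc$points
  dbest <- tc$d2
  # reduce over candidate faces per query point
  o <- order(pi_, dbest)
  keep <- o[!duplicated(pi_[o])]
  idx <- pi_[keep]
  pts <- matrix(NA_real_, nrow(P), 3L)
  pts[idx, ] <- best[keep, , drop = FALSE]
  nrm <- matrix(NA_real_, nrow(P), 3L)
  nrm[idx, ] <- accel$face_normals[fi[keep], , drop = FALSE]
  dist <- rep(NA_real_, nrow(P))
  dist[idx] <- sqrt(dbest[keep])
  # barycentric coordinates of the chosen point on its face
  kA <- A[keep, , drop = FALSE]
  kE0 <- B[keep, , drop = FALSE] - kA
  kE1 <- C[keep, , drop = FALSE] - kA
  dp <- best[keep, , drop = FALSE] - kA
  ka <- rowSums(kE0 * kE0); kb <- rowSums(kE0 * kE1); kc <- rowSums(kE1 * kE1)
  kdet <- pmax(ka * kc - kb * kb, 1e-300)
  kd <- rowSums(kE0 * dp); ke <- rowSums(kE1 * dp)
  bu <- pmin(pmax((kc * kd - kb * ke) / kdet, 0), 1)
  bv <- pmin(pmax((ka * ke - kb * kd) / kdet, 0), 1)
  bary <- matrix(NA_real_, nrow(P), 3L)
  bary[idx, ] <- cbind(1 - bu - bv, bu, bv)
  list(points = pts, normals = nrm, dist = dist, bary = bary, face = {
    f <- integer(nrow(P)); f[idx] <- fi[keep]; f
  })
}

# Refresh an acceleration structure after moving vertices (fixed topology).
accel_update <- function(accel, V) {
  accel$V <- V
  accel$face_normals <- normalize_rows(face_normals(V, accel$F))
  accel
}

# Weighted rigid (optionally scaled) superimposition of X onto Y:
# finds s, R, t minimizing sum w_i || s R x_i + t - y_i ||^2.
kabsch_weighted <- function(X, Y, w = NULL, allow_scale = FALSE) {
  n <- nrow(X)
  if (is.null(w)) w <- rep(1, n)
  if (all(w == 0)) stop("weights must not be all zero", call. = FALSE)
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  sw <- sum(w)
  mx <- colSums(w * X) / sw
  my <- colSums(w * Y) / sw
  Xc <- sweep(X, 2L, mx)
  Yc <- sweep(Y, 2L, my)
  H <- t(Xc) %*% (w * Yc)
  sv <- svd(H)
  dsign <- sign(det(sv$v %*% t(sv$u)))
  if (dsign == 0) stop("degenerate configuration in superimposition", call. = FALSE)
  Dm <- diag(c(1, 1, dsign))
  R <- sv$v %*% Dm %*% t(sv$u)
  varx <- sum(w * Xc^2)
  if (varx <= 0) stop("degenerate configuration in superimposition", call. = FALSE)
  if (svd(Xc * sqrt(w))$d[2] < 1e-12 * sqrt(varx)) {
    stop("degenerate (collinear) configuration in superimposition", call. = FALSE)
  }
  s <- if (allow_scale) sum(sv$d * diag(Dm)) / varx else 1
  t_ <- my - s * as.vector(R %*% mx)
  rigid_transform(R, t_, s)
}

#' Rigid (similarity) transform
#'
#' Maps a point x to `scale * rotation %*% x + translation`.
#'
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation Length-3 vector (mm).
#' @param scale Positive scalar; 1 for a pure rigid motion.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0), scale = 1) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L, scale > 0)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 || det(rotation) < 0) {
    stop("rotation must be proper orthonormal", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 scale = as.numeric(scale)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points or a mesh
#'
#' @param transform A [rigid_transform()].
#' @param x An n x 3 coordinate matrix or a [surface_mesh()].
#' @return Transformed object of the same kind as `x`.
#' @export
apply_transform <- function(transform, x) {
  if (inherits(x, "surface_mesh")) {
    x$vertices <- apply_transform(transform, x$vertices)
    return(x)
  }
  sweep(transform$scale * x %*% t(transform$rotation), 2L,
        transform$translation, "+")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(pmax((sum(diag(x$rotation)) - 1) / 2, -1), 1)) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm, scale %.6f\n",
              ang, x$translation[1], x$translation[2], x$translation[3], x$scale))
  invisible(x)
}

rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

graph_laplacian <- function(faces, n) {
  e <- mesh_edges(faces)
  i <- c(e[, 1], e[, 2], e[, 1], e[, 2])
  j <- c(e[, 2], e[, 1], e[, 1], e[, 2])
  x <- c(rep(-1, 2L * nrow(e)), rep(1, 2L * nrow(e)))
  A <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  # duplicated (i,i) entries are summed by sparseMatrix, giving degree on the
  # diagonal and -1 off-diagonal
  A
}

# Project a per-vertex displacement field onto the orthogonal complement of
# the infinitesimal rigid motions of configuration X (translations and
# linearized rotations about the centroid). Used to construct perturbations
# that a Procrustes superimposition cannot absorb.
project_rigid_complement <- function(field, X) {
  n <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X))
  basis <- cbind(
    c(rep(1, n), rep(0, 2 * n)),
    c(rep(0, n), rep(1, n), rep(0, n)),
    c(rep(0, 2 * n), rep(1, n)),
    as.vector(cross3(matrix(rep(c(1, 0, 0), each = n), n), Xc)),
    as.vector(cross3(matrix(rep(c(0, 1, 0), each = n), n), Xc)),
    as.vector(cross3(matrix(rep(c(0, 0, 1), each = n), n), Xc)))
  qb <- qr.Q(qr(basis))
  f <- as.vector(field)
  matrix(f - qb %*% crossprod(qb, f), n, 3L)
}

# Soft closest point: Gaussian-weighted blend of per-face closest points over
# the faces incident to the k nearest vertices. Smooths the sub-facet
# ruggedness of the hard closest-point objective so ICP has a single, pose-
# independent optimum within a basin.
soft_closest_points <- function(P, accel, sigma = 1, k = 3L) {
  V <- accel$V
  F <- accel$F
  nP <- nrow(P)
  d2v <- outer(rowSums(P^2), rowSums(V^2), "+") - 2 * P %*% t(V)
  nnk <- matrix(0L, nP, k)
  for (j in seq_len(k)) {
    nnk[, j] <- max.col(-d2v, ties.method = "first")
    d2v[cbind(seq_len(nP), nnk[, j])] <- Inf
  }
  # candidate (point, face) pairs, deduplicated per point
  fs <- accel$vert_faces[as.vector(t(nnk))]        # row-major: k per point
  lens <- lengths(fs)
  pi_ <- rep.int(rep(seq_len(nP), each = k), lens)
  fi <- unlist(fs, use.names = FALSE)
  dup <- duplicated(cbind(pi_, fi))
  pi_ <- pi_[!dup]; fi <- fi[!dup]
  tc <- tri_closest(P[pi_, , drop = FALSE],
                    V[F[fi, 1], , drop = FALSE],
                    V[F[fi, 2], , drop = FALSE],
                    V[F[fi, 3], , drop = FALSE])
  # group minimum of d2 per point
  dmin <- rep(Inf, nP)
  o <- order(pi_, tc$d2)
  first <- !duplicated(pi_[o])
  dmin[pi_[o][first]] <- tc$d2[o][first]
  w <- exp(-(tc$d2 - dmin[pi_]) / (2 * sigma^2))
  num <- rowsum(w * tc$points, pi_)
  den <- rowsum(w, pi_)
  out <- matrix(NA_real_, nP, 3L)
  out[as.integer(rownames(num)), ] <- num / as.vector(den)
  out
}
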