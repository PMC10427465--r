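#' Per-vertex asymmetry field
#'
#' A displacement field (mm) over the template vertices. The `role` records
#' what the field represents: `"total"` (face minus its aligned mirror),
#' `"DA"` (directional asymmetry, the sample-mean total field), or `"FA"`
#' (fluctuating asymmetry, total minus DA).
#'
#' @param displacements n x 3 numeric matrix (mm).
#' @param role One of `"total"`, `"DA"`, `"FA"`.
#' @param source_id Identifier of the originating face (not used for DA).
#' @return An object of class `asymmetry_field`.
#' @export
asymmetry_field <- function(displacements, role = c("total", "DA", "FA"),
                            source_id = NULL) {
  role <- match.arg(role)
  displacements <- as.matrix(displacements)
  if (ncol(displacements) != 3L) stop("displacements must be n x 3", call. = FALSE)
  if (any(!is.finite(displacements))) stop("displacements must be finite", call. = FALSE)
  structure(list(displacements = displacements, role = role, source_id = source_id),
            class = "asymmetry_field")
}

#' @export
print.asymmetry_field <- function(x, ...) {
  cat(sprintf("<asymmetry_field:%s> %d vertices, rms %.4g mm%s\n", x$role,
              nrow(x$displacements), field_rms(x$displacements),
              if (is.null(x$source_id)) "" else paste0(" [", x$source_id, "]")))
  invisible(x)
}

field_rms <- function(displacements) {
  sqrt(mean(rowSums(displacements^2)))
}

#' Mirror a mapped face and relabel paired vertices
#'
#' Reflects the face across the sagittal plane x = 0 by reversing the sign of
#' the x coordinates, then relabels each vertex with its paired counterpart so
#' the mirror is again in template correspondence: output position i is the
#' input position at `pairing[i]` with x negated. The operation is an
#' involution.
#'
#' @param face A `mapped_face` (or n x 3 matrix) in template correspondence.
#' @param template The [template_mesh()] providing the left-right pairing.
#' @return A `mapped_face` of the mirrored, relabelled coordinates.
#' @export
mirror_relabel <- function(face, template) {
  stopifnot(inherits(template, "template_mesh"))
  pos <- if (inherits(face, "mapped_face")) face$positions else as.matrix(face)
  p <- template$pairing
  if (nrow(pos) != length(p)) {
    stop("face has ", nrow(pos), " vertices but template has ", length(p), call. = FALSE)
  }
  if (any(p[p] != seq_along(p))) {
    stop("template pairing is not an involution", call. = FALSE)
  }
  out <- pos[p, , drop = FALSE]
  out[, 1] <- -out[, 1]
  mapped_face(out, source_id = if (inherits(face, "mapped_face")) face$source_id)
}

# Same reflection+relabel applied to a displacement field (a vector field
# transforms like coordinates under the reflection).
mirror_field <- function(displacements, template) {
  p <- template$pairing
  out <- displacements[p, , drop = FALSE]
  out[, 1] <- -out[, 1]
  out
}

#' Weighted Procrustes superimposition of a mirror onto its face
#'
#' Rigidly (optionally with scale) superimposes `mirror` onto `face`,
#' minimizing the weighted sum of squared distances between corresponding
#' vertices. With uniform weights this is ordinary least-squares Procrustes
#' superimposition; non-uniform weights emphasize (e.g. symmetric) regions.
#'
#' @param face,mirror `mapped_face` objects (or n x 3 matrices) with equal
#'   vertex counts.
#' @param weights Per-vertex non-negative weights; `NULL` for uniform.
#' @param allow_scale Also estimate a scale factor (default off: asymmetry is
#'   reported in absolute mm).
#' @return A list with `aligned` (the transformed mirror, `mapped_face`) and
#'   `transform` (a [rigid_transform()]).
#' @export
weighted_procrustes <- function(face, mirror, weights = NULL, allow_scale = FALSE) {
  Y <- if (inherits(face, "mapped_face")) face$positions else as.matrix(face)
  X <- if (inherits(mirror, "mapped_face")) mirror$positions else as.matrix(mirror)
  if (nrow(X) != nrow(Y)) stop("face and mirror must have equal vertex counts", call. = FALSE)
  tr <- kabsch_weighted(X, Y, w = weights, allow_scale = allow_scale)
  list(aligned = mapped_face(apply_transform(tr, X)), transform = tr)
}

# Iteratively reweighted Procrustes: down-weights strongly asymmetric vertices
# with Gaussian weights on the residuals, sigma = rms residual, 3 iterations.
irw_procrustes_weights <- function(face, mirror, iterations = 3L) {
  Y <- if (inherits(face, "mapped_face")) face$positions else as.matrix(face)
  X <- if (inherits(mirror, "mapped_face")) mirror$positions else as.matrix(mirror)
  w <- rep(1, nrow(Y))
  for (i in seq_len(iterations)) {
    tr <- kabsch_weighted(X, Y, w = w)
    res <- sqrt(rowSums((Y - apply_transform(tr, X))^2))
    sigma <- max(sqrt(mean(res^2)), 1e-12)
    w <- exp(-(res / sigma)^2)
  }
  w
}

#' Total asymmetry of a mapped face
#'
#' Canonicalizes pose by ordinary Procrustes alignment of the face onto the
#' template (making the field invariant to rigid motion of the input), mirrors
#' and relabels it, superimposes the mirror onto the face by weighted
#' Procrustes, and subtracts the aligned mirror from the original:
#' `displacement[i] = face[i] - aligned_mirror[i]`.
#'
#' @inheritParams mirror_relabel
#' @param weights Per-vertex Procrustes weights (`NULL` = uniform) or the
#'   string `"irw"` for the iteratively reweighted scheme.
#' @param allow_scale Estimate scale in the mirror superimposition.
#' @return An [asymmetry_field()] with role `"total"`.
#' @export
total_asymmetry <- function(face, template, weights = NULL, allow_scale = FALSE) {
  pos <- if (inherits(face, "mapped_face")) face$positions else as.matrix(face)
  # pose canonicalization: rigid-align the face onto the template
  tr <- kabsch_weighted(pos, template$mesh$vertices)
  pos <- apply_transform(tr, pos)
  mir <- mirror_relabel(pos, template)
  if (identical(weights, "irw")) {
    weights <- irw_procrustes_weights(pos, mir)
  }
  wp <- weighted_procrustes(pos, mir, weights = weights, allow_scale = allow_scale)
  asymmetry_field(pos - wp$aligned$positions, role = "total",
                  source_id = if (inherits(face, "mapped_face")) face$source_id)
}

#' Directional asymmetry: the sample-mean total-asymmetry field
#'
#' @param fields List of [asymmetry_field()] objects with role `"total"`, all
#'   on the same template.
#' @return An [asymmetry_field()] with role `"DA"`.
#' @export
directional_asymmetry <- function(fields) {
  if (length(fields) < 2L) stop("need at least two fields to estimate DA", call. = FALSE)
  ns <- vapply(fields, function(f) nrow(f$displacements), 1L)
  if (length(unique(ns)) != 1L) stop("fields come from different templates", call. = FALSE)
  acc <- Reduce(`+`, lapply(fields, `[[`, "displacements"))
  asymmetry_field(acc / length(fields), role = "DA")
}

#' Fluctuating asymmetry: total asymmetry corrected for DA
#'
#' @param field An [asymmetry_field()] with role `"total"`.
#' @param da The sample [directional_asymmetry()] field.
#' @return An [asymmetry_field()] with role `"FA"`.
#' @export
fluctuating_asymmetry <- function(field, da) {
  if (!identical(dim(field$displacements), dim(da$displacements))) {
    stop("field and DA shapes differ", call. = FALSE)
  }
  asymmetry_field(field$displacements - da$displacements, role = "FA",
                  source_id = field$source_id)
}

#' Reduce an FA field to a scalar score
#'
#' Default aggregation is the root-mean-square over vertices of the
#' displacement-vector norms (`"rms"`, mm); `"mean-norm"` takes the plain mean
#' of the norms instead. The aggregation label is carried in the result so
#' alternative reductions remain comparable.
#'
#' @param field An [asymmetry_field()] with role `"FA"`.
#' @param aggregation `"rms"` (default) or `"mean-norm"`.
#' @return An object of class `fa_score` with fields `value` (mm) and
#'   `aggregation`.
#' @export
fa_score <- function(field, aggregation = c("rms", "mean-norm")) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(field, "asymmetry_field"))
  if (field$role != "FA") stop("fa_score expects a field with role 'FA'", call. = FALSE)
  if (nrow(field$displacements) == 0L) stop("empty field", call. = FALSE)
  norms <- sqrt(rowSums(field$displacements^2))
  value <- switch(aggregation, rms = sqrt(mean(norms^2)), `mean-norm` = mean(norms))
  structure(list(value = value, aggregation = aggregation,
                 source_id = field$source_id),
            class = "fa_score")
}

#' @export
print.fa_score <- function(x, ...) {
  cat(sprintf("<fa_score> %.6g mm (%s)\n", x$value, x$aggregation))
  invisible(x)
}

#' Heat-map channel: mean per-vertex asymmetry magnitude
#'
#' Averages the displacement-vector norms of a sample of asymmetry fields at
#' each template vertex, the quantity rendered as an asymmetry heat map.
#'
#' @param fields List of [asymmetry_field()] objects (length >= 1).
#' @param template Optional [template_mesh()]; if given, the channel is
#'   attached to a copy of the template surface as its scalar channel.
#' @return A numeric vector (mm) or, with `template`, a [surface_mesh()] with
#'   the channel attached.
#' @export
heatmap_field <- function(fields, template = NULL) {
  if (length(fields) < 1L) stop("need at least one field", call. = FALSE)
  ns <- vapply(fields, function(f) nrow(f$displacements), 1L)
  if (length(unique(ns)) != 1L) stop("fields come from different templates", call. = FALSE)
  norms <- vapply(fields, function(f) sqrt(rowSums(f$displacements^2)),
                  numeric(ns[1]))
  channel <- rowMeans(as.matrix(norms))
  if (is.null(template)) return(channel)
  m <- template$mesh
  m$scalar <- channel
  m
}

#' Measure dense FA for a sample of scans
#'
#' Runs the full dense pipeline on a set of scans sharing one template: maps
#' the template onto every scan ([nonrigid_map()]), computes per-face total
#' asymmetry, estimates directional asymmetry as the sample mean, corrects
#' each face for DA, and reduces the FA fields to scalar scores.
#'
#' @param meshes Named list of [surface_mesh()] scans, or of `mapped_face`
#'   objects already in correspondence (mapping is then skipped).
#' @param template A [template_mesh()].
#' @param params A [mapping_params()].
#' @param weights,allow_scale Passed to [total_asymmetry()].
#' @param aggregation Passed to [fa_score()].
#' @return An object of class `fa_sample`: list with `scores` (tibble:
#'   `source_id`, `fa_score`, `aggregation`), `total`, `da`, `fa` fields, the
#'   `template` and `mapped` faces. `tidy()` returns the score tibble.
#' @export
measure_fa_sample <- function(meshes, template, params = mapping_params(),
                              weights = NULL, allow_scale = FALSE,
                              aggregation = "rms") {
  stopifnot(length(meshes) >= 2L)
  ids <- names(meshes) %||% as.character(seq_along(meshes))
  mapped <- purrr::imap(meshes, function(m, id) {
    if (inherits(m, "mapped_face")) m
    else nonrigid_map(template, m, params = params, source_id = id)
  })
  total <- purrr::map(mapped, total_asymmetry, template = template,
                      weights = weights, allow_scale = allow_scale)
  da <- directional_asymmetry(unname(total))
  fa <- purrr::map(total, fluctuating_asymmetry, da = da)
  scores <- purrr::map(fa, fa_score, aggregation = aggregation)
  structure(list(
    scores = tibble::tibble(
      source_id = ids,
      fa_score = vapply(scores, `[[`, 0, "value"),
      aggregation = aggregation),
    total = total, da = da, fa = fa,
    template = template, mapped = mapped),
    class = "fa_sample")
}

#' @export
print.fa_sample <- function(x, ...) {
  cat(sprintf("<fa_sample> %d faces; mean FA %.4g mm (%s); DA rms %.4g mm\n",
              nrow(x$scores), mean(x$scores$fa_score), x$scores$aggregation[1],
              field_rms(x$da$displacements)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.fa_sample <- function(x, ...) x$scores

#' @export
glance.fa_sample <- function(x, ...) {
  tibble::tibble(n = nrow(x$scores),
                 mean_fa = mean(x$scores$fa_score),
                 sd_fa = stats::sd(x$scores$fa_score),
                 da_rms = field_rms(x$da$displacements),
                 aggregation = x$scores$aggregation[1])
}

#' Export FA scores as CSV
#'
#' @param sample An `fa_sample`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fa_scores <- function(sample, path) {
  utils::write.csv(sample$scores, path, row.names = FALSE)
  invisible(path)
}
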