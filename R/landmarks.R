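#' Landmark configuration for manual FA indices
#'
#' Holds named 2D or 3D landmark coordinates together with the bilateral
#' pairing scheme and the ordered midline landmark names used to fit the
#' facial midline.
#'
#' @param points A data frame or tibble with columns `name`, `x`, `y` and
#'   optionally `z` (mm, or pixels for 2D photographs).
#' @param bilateral_pairs Two-column data frame (or list of length-2 character
#'   vectors) of `(left, right)` landmark names.
#' @param midline Character vector (length >= 2) of midline landmark names.
#' @return An object of class `landmark_config`.
#' @export
landmark_config <- function(points, bilateral_pairs, midline) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("name", "x", "y") %in% names(points)))
  dim3 <- "z" %in% names(points)
  if (is.list(bilateral_pairs) && !is.data.frame(bilateral_pairs)) {
    bilateral_pairs <- do.call(rbind, lapply(bilateral_pairs, function(p) {
      data.frame(left = p[1], right = p[2])
    }))
  }
  bilateral_pairs <- tibble::as_tibble(bilateral_pairs)
  names(bilateral_pairs) <- c("left", "right")
  missing <- setdiff(c(bilateral_pairs$left, bilateral_pairs$right, midline),
                     points$name)
  if (length(missing) > 0L) {
    stop("landmarks missing from points: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(midline) < 2L) stop("need at least two midline landmarks", call. = FALSE)
  structure(list(points = points, pairs = bilateral_pairs,
                 midline = midline, dim = if (dim3) 3L else 2L),
            class = "landmark_config")
}

lm_coords <- function(config, names) {
  i <- match(names, config$points$name)
  m <- unname(as.matrix(config$points[i, c("x", "y", if (config$dim == 3L) "z")]))
  rownames(m) <- names
  m
}

#' Fit the facial midline from a landmark configuration
#'
#' In 2D, the midline is the least-squares line through the midline
#' landmarks (their first principal axis). In 3D, the sagittal plane normal is
#' the first principal direction of the left-minus-right vectors over the
#' bilateral pairs, the plane passes through the midline-landmark centroid,
#' and the returned axis is the midline landmarks' principal direction
#' projected into that plane. The `direction` (vertical axis, unit) and
#' `normal` (left-right axis, unit) together define horizontal and vertical
#' components.
#'
#' @param config A [landmark_config()].
#' @return List with `point`, `direction`, `normal`, `dim`.
#' @export
fit_midline <- function(config) {
  stopifnot(inherits(config, "landmark_config"))
  M <- lm_coords(config, config$midline)
  if (nrow(M) < 2L) stop("need at least two midline landmarks", call. = FALSE)
  ctr <- colMeans(M)
  Mc <- sweep(M, 2L, ctr)
  if (config$dim == 2L) {
    sv <- svd(Mc)
    dir <- sv$v[, 1]
    nrm <- c(-dir[2], dir[1])
  } else {
    L <- lm_coords(config, config$pairs$left)
    R <- lm_coords(config, config$pairs$right)
    Dlr <- L - R
    nrm <- svd(Dlr)$v[, 1]
    # keep sign stable: orient along the mean left-right vector
    if (sum(nrm * colMeans(Dlr)) < 0) nrm <- -nrm
    nrm <- nrm / sqrt(sum(nrm^2))
    sv <- svd(Mc)
    dir <- sv$v[, 1]
    dir <- dir - sum(dir * nrm) * nrm  # project into the sagittal plane
    if (sqrt(sum(dir^2)) < 1e-12) stop("midline landmarks degenerate", call. = FALSE)
    dir <- dir / sqrt(sum(dir^2))
  }
  list(point = ctr, direction = dir / sqrt(sum(dir^2)), normal = nrm,
       dim = config$dim)
}

signed_horizontal <- function(P, axis) {
  as.vector(sweep(P, 2L, axis$point) %*% axis$normal)
}

#' Horizontal facial FA (HFA)
#'
#' Aggregate over bilateral landmark pairs of the absolute difference between
#' the left and right landmark's perpendicular (horizontal) distances from
#' the fitted vertical midline.
#'
#' @param config A [landmark_config()].
#' @return Non-negative scalar (units of the landmarks).
#' @export
horizontal_fa <- function(config) {
  axis <- fit_midline(config)
  L <- lm_coords(config, config$pairs$left)
  R <- lm_coords(config, config$pairs$right)
  sum(abs(abs(signed_horizontal(L, axis)) - abs(signed_horizontal(R, axis))))
}

#' Vertical facial FA (VFA)
#'
#' Sum over bilateral landmark pairs of the absolute vertical offset (the
#' component of left minus right along the midline axis).
#'
#' @param config A [landmark_config()].
#' @return Non-negative scalar.
#' @export
vertical_fa <- function(config) {
  axis <- fit_midline(config)
  L <- lm_coords(config, config$pairs$left)
  R <- lm_coords(config, config$pairs$right)
  sum(abs(as.vector((L - R) %*% axis$direction)))
}

#' Comprehensive landmark FA
#'
#' Sum over bilateral pairs of the full Euclidean distance between the left
#' landmark and the right landmark reflected across the fitted midline (line
#' in 2D, sagittal plane in 3D). Optionally normalized by a reference
#' distance (e.g. interpupillary distance for 2D photographs).
#'
#' @param config A [landmark_config()].
#' @param normalize_by Optional positive reference distance to divide by.
#' @return Non-negative scalar.
#' @export
comprehensive_fa <- function(config, normalize_by = NULL) {
  axis <- fit_midline(config)
  L <- lm_coords(config, config$pairs$left)
  R <- lm_coords(config, config$pairs$right)
  h <- signed_horizontal(R, axis)
  Rrefl <- R - 2 * h %*% t(axis$normal)
  val <- sum(sqrt(rowSums((L - Rrefl)^2)))
  if (!is.null(normalize_by)) {
    stopifnot(normalize_by > 0)
    val <- val / normalize_by
  }
  val
}

#' All three landmark FA indices as a tibble
#'
#' @inheritParams comprehensive_fa
#' @return A tibble with columns `hfa`, `vfa`, `comprehensive`,
#'   `normalization`.
#' @export
landmark_fa_indices <- function(config, normalize_by = NULL) {
  tibble::tibble(
    hfa = horizontal_fa(config),
    vfa = vertical_fa(config),
    comprehensive = comprehensive_fa(config, normalize_by = normalize_by),
    normalization = if (is.null(normalize_by)) "none"
                    else paste0("ref=", format(normalize_by)))
}

#' Default 17-landmark scheme (7 bilateral pairs + 3 midline)
#'
#' A named pairing scheme for conventional facial landmarks: exocanthion,
#' endocanthion, pupil, alare, cheilion, zygion and gonion pairs plus nasion,
#' pronasale and pogonion on the midline.
#'
#' @return List with elements `pairs` (tibble `left`, `right`) and `midline`.
#' @export
default_landmark_scheme <- function() {
  base <- c("exocanthion", "endocanthion", "pupil", "alare", "cheilion",
            "zygion", "gonion")
  list(pairs = tibble::tibble(left = paste0(base, "_l"),
                              right = paste0(base, "_r")),
       midline = c("nasion", "pronasale", "pogonion"))
}

#' Read landmarks from CSV
#'
#' Expects columns `name`, `x`, `y` and optionally `z`.
#'
#' @param path CSV path.
#' @param scheme Pairing scheme as returned by [default_landmark_scheme()].
#' @return A [landmark_config()].
#' @export
read_landmarks <- function(path, scheme = default_landmark_scheme()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  landmark_config(df, scheme$pairs, scheme$midline)
}
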