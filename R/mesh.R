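#' Construct a triangulated surface mesh
#'
#' A `surface_mesh` stores vertex coordinates in millimetres, triangle
#' connectivity, and optionally one per-vertex scalar channel (used for
#' asymmetry heat maps).
#'
#' @param vertices Numeric matrix, one row per vertex, three columns (x, y, z
#'   in mm).
#' @param faces Integer matrix, one row per triangle, three columns of 1-based
#'   vertex indices.
#' @param scalar Optional numeric vector, one value per vertex.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, scalar = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must have three columns", call. = FALSE)
  if (nrow(vertices) < 3L) stop("a mesh needs at least three vertices", call. = FALSE)
  if (ncol(faces) != 3L) stop("faces must have three columns", call. = FALSE)
  if (nrow(faces) < 1L) stop("a mesh needs at least one face", call. = FALSE)
  if (any(!is.finite(vertices))) stop("vertex coordinates must be finite (no NaN/Inf)", call. = FALSE)
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  if (!is.null(scalar)) {
    scalar <- as.numeric(scalar)
    if (length(scalar) != nrow(vertices)) {
      stop("scalar channel must have one value per vertex", call. = FALSE)
    }
  }
  structure(list(vertices = vertices, faces = faces, scalar = scalar),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$scalar)) "" else ", scalar channel"))
  invisible(x)
}

#' Construct a symmetric template mesh with left-right vertex pairing
#'
#' The template is the reference surface for dense correspondence. Its
#' `pairing` is an involution over vertex indices mapping every left vertex to
#' its right counterpart; vertices with `pairing[i] == i` form the midline and
#' must lie on the sagittal plane x = 0.
#'
#' @param mesh A [surface_mesh()].
#' @param pairing Integer vector of length `nrow(mesh$vertices)`; 1-based.
#' @return An object of class `template_mesh` with elements `mesh`, `pairing`
#'   and `midline` (indices of self-paired vertices).
#' @seealso [validate_template()]
#' @export
template_mesh <- function(mesh, pairing) {
  stopifnot(inherits(mesh, "surface_mesh"))
  pairing <- as.integer(pairing)
  n <- nrow(mesh$vertices)
  if (length(pairing) != n) stop("pairing must have one entry per vertex", call. = FALSE)
  if (any(pairing < 1L) || any(pairing > n)) stop("pairing indices out of range", call. = FALSE)
  structure(list(mesh = mesh, pairing = pairing,
                 midline = which(pairing == seq_len(n))),
            class = "template_mesh")
}

#' @export
print.template_mesh <- function(x, ...) {
  cat(sprintf("<template_mesh> %d vertices (%d midline), %d faces\n",
              nrow(x$mesh$vertices), length(x$midline), nrow(x$mesh$faces)))
  invisible(x)
}

#' Validate the symmetry and pairing of a template mesh
#'
#' Checks that the pairing is an involution and that the template geometry is
#' mirror-symmetric about the plane x = 0: the position of `pairing[i]` must
#' equal the position of `i` with the sign of x reversed, within `tol`.
#'
#' @param template A [template_mesh()].
#' @param tol Symmetry tolerance in mm.
#' @return A tibble-backed report of class `template_validation` with fields
#'   `pass`, `max_residual`, `involution_violations` (indices), and
#'   `symmetry_residuals` (per-vertex mm).
#' @export
validate_template <- function(template, tol = 1e-9) {
  stopifnot(inherits(template, "template_mesh"))
  p <- template$pairing
  v <- template$mesh$vertices
  invol_bad <- which(p[p] != seq_along(p))
  mirrored <- v[p, , drop = FALSE]
  mirrored[, 1] <- -mirrored[, 1]
  resid <- sqrt(rowSums((v - mirrored)^2))
  out <- list(
    pass = length(invol_bad) == 0L && all(resid <= tol),
    tol = tol,
    max_residual = max(resid),
    involution_violations = invol_bad,
    symmetry_residuals = resid,
    flagged = which(resid > tol)
  )
  class(out) <- "template_validation"
  out
}

#' @export
print.template_validation <- function(x, ...) {
  cat(sprintf("<template_validation> %s (tol %g mm)\n",
              if (x$pass) "PASS" else "FAIL", x$tol))
  cat(sprintf("  max symmetry residual: %g mm; %d vertices flagged; %d involution violations\n",
              x$max_residual, length(x$flagged), length(x$involution_violations)))
  invisible(x)
}

#' Read a triangle mesh from PLY or OBJ
#'
#' PLY is supported in ascii and binary little-endian form; an extra per-vertex
#' float/double property named `quality` (or the first extra scalar property)
#' is read into the mesh's scalar channel. OBJ reading handles `v` and `f`
#' records (with or without `/`-separated attribute indices); materials and
#' normals are ignored. Coordinates are taken as millimetres.
#'
#' @param path File path.
#' @param format `"ply"`, `"obj"`, or `NULL` to infer from the extension.
#' @return A [surface_mesh()].
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- format %||% tolower(tools::file_ext(path))
  switch(format,
         ply = read_ply(path),
         obj = read_obj(path),
         stop("unsupported mesh format: ", format, call. = FALSE))
}

#' Write a triangle mesh to PLY or OBJ
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path.
#' @param format `"ply"`, `"obj"`, or `NULL` to infer from the extension.
#' @param binary For PLY, write binary little-endian instead of ascii.
#' @return Invisibly, `path`.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = FALSE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  format <- format %||% tolower(tools::file_ext(path))
  switch(format,
         ply = write_ply(mesh, path, binary = binary),
         obj = write_obj(mesh, path),
         stop("unsupported mesh format: ", format, call. = FALSE))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || identical(a, "")) b else a

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path, call. = FALSE)
  fmt <- NULL
  elements <- list()  # each: list(name, count, props = list(list(name, type, is_list, count_type)))
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of PLY header", call. = FALSE)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], type = tok[4], is_list = TRUE, count_type = tok[3])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], type = tok[2], is_list = FALSE)
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (is.null(elements$vertex) || is.null(elements$face)) {
    stop("PLY file lacks vertex or face element", call. = FALSE)
  }
  if (identical(fmt, "ascii")) {
    dat <- read_ply_ascii(con, elements)
  } else if (identical(fmt, "binary_little_endian")) {
    dat <- read_ply_binary(con, elements)
  } else {
    stop("unsupported PLY format: ", fmt, call. = FALSE)
  }
  vprops <- vapply(elements$vertex$props, `[[`, "", "name")
  need <- c("x", "y", "z")
  if (!all(need %in% vprops)) stop("PLY vertex element lacks x/y/z", call. = FALSE)
  V <- cbind(dat$vertex[["x"]], dat$vertex[["y"]], dat$vertex[["z"]])
  extra <- setdiff(vprops, need)
  scalar <- NULL
  if ("quality" %in% extra) scalar <- dat$vertex[["quality"]]
  else if (length(extra) > 0L) scalar <- dat$vertex[[extra[1]]]
  F <- dat$face
  surface_mesh(V, F + 1L, scalar = scalar)
}

read_ply_ascii <- function(con, elements) {
  lines <- readLines(con)
  lines <- lines[nzchar(trimws(lines))]
  pos <- 1L
  out <- list()
  for (el in elements) {
    if (el$name == "vertex") {
      block <- lines[pos:(pos + el$count - 1L)]
      pos <- pos + el$count
      m <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"), as.numeric))
      if (any(is.na(m))) stop("non-numeric or NaN vertex data in PLY", call. = FALSE)
      cols <- stats::setNames(lapply(seq_along(el$props), function(j) m[, j]),
                              vapply(el$props, `[[`, "", "name"))
      out$vertex <- cols
    } else if (el$name == "face") {
      block <- lines[pos:(pos + el$count - 1L)]
      pos <- pos + el$count
      rows <- lapply(strsplit(trimws(block), "\\s+"), as.integer)
      F <- do.call(rbind, lapply(rows, function(r) {
        if (r[1] != 3L) stop("only triangle faces are supported", call. = FALSE)
        r[2:4]
      }))
      out$face <- F
    } else {
      pos <- pos + el$count
    }
  }
  out
}

ply_type_info <- function(type) {
  switch(type,
         char = , int8 = list(what = "integer", size = 1L, signed = TRUE),
         uchar = , uint8 = list(what = "integer", size = 1L, signed = FALSE),
         short = , int16 = list(what = "integer", size = 2L, signed = TRUE),
         ushort = , uint16 = list(what = "integer", size = 2L, signed = FALSE),
         int = , int32 = list(what = "integer", size = 4L, signed = TRUE),
         uint = , uint32 = list(what = "integer", size = 4L, signed = FALSE),
         float = , float32 = list(what = "numeric", size = 4L, signed = TRUE),
         double = , float64 = list(what = "numeric", size = 8L, signed = TRUE),
         stop("unknown PLY type: ", type, call. = FALSE))
}

read_ply_binary <- function(con, elements) {
  out <- list()
  for (el in elements) {
    if (el$name == "vertex") {
      types <- lapply(el$props, function(p) ply_type_info(p$type))
      nprop <- length(types)
      cols <- replicate(nprop, numeric(el$count), simplify = FALSE)
      # fixed record: read all at once if homogeneous, else per row
      for (i in seq_len(el$count)) {
        for (j in seq_len(nprop)) {
          ti <- types[[j]]
          cols[[j]][i] <- readBin(con, ti$what, n = 1L, size = ti$size,
                                  signed = ti$signed, endian = "little")
        }
      }
      names(cols) <- vapply(el$props, `[[`, "", "name")
      out$vertex <- cols
    } else if (el$name == "face") {
      p <- el$props[[1]]
      ci <- ply_type_info(p$count_type)
      ii <- ply_type_info(p$type)
      F <- matrix(0L, el$count, 3L)
      for (i in seq_len(el$count)) {
        k <- readBin(con, ci$what, n = 1L, size = ci$size, signed = ci$signed,
                     endian = "little")
        if (k != 3L) stop("only triangle faces are supported", call. = FALSE)
        F[i, ] <- readBin(con, ii$what, n = 3L, size = ii$size, signed = ii$signed,
                          endian = "little")
      }
      out$face <- F
    }
  }
  out
}

write_ply <- function(mesh, path, binary = FALSE) {
  V <- mesh$vertices
  F <- mesh$faces - 1L
  has_scalar <- !is.null(mesh$scalar)
  hdr <- c("ply",
           sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", nrow(V)),
           "property double x", "property double y", "property double z",
           if (has_scalar) "property double quality",
           sprintf("element face %d", nrow(F)),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    rec <- if (has_scalar) cbind(V, mesh$scalar) else V
    writeBin(as.vector(t(rec)), con, size = 8L, endian = "little")
    for (i in seq_len(nrow(F))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(F[i, ]), con, size = 4L, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    rec <- if (has_scalar) cbind(V, mesh$scalar) else V
    writeLines(apply(rec, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
    writeLines(paste(3L, F[, 1], F[, 2], F[, 3]), con)
  }
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0L || length(flines) == 0L) {
    stop("OBJ file has no vertices or no faces", call. = FALSE)
  }
  V <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vlines)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  if (any(is.na(V))) stop("non-numeric or NaN vertex data in OBJ", call. = FALSE)
  F <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", flines)), "\\s+"), function(x) {
    idx <- as.integer(vapply(strsplit(x, "/"), `[[`, "", 1L))
    if (length(idx) != 3L) stop("only triangle faces are supported", call. = FALSE)
    idx
  }))
  surface_mesh(V, F)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  V <- mesh$vertices
  writeLines(apply(V, 1L, function(r) paste("v", paste(sprintf("%.17g", r), collapse = " "))), con)
  F <- mesh$faces
  writeLines(paste("f", F[, 1], F[, 2], F[, 3]), con)
  invisible(path)
}

#' Read or write a left-right pairing map as CSV
#'
#' The pairing is stored as a two-column CSV (`index`, `paired_index`),
#' 1-based, alongside the template geometry.
#'
#' @param path CSV path.
#' @return `read_pairing()` returns an integer vector; `write_pairing()`
#'   returns `path` invisibly.
#' @export
read_pairing <- function(path) {
  df <- utils::read.csv(path)
  p <- integer(nrow(df))
  p[df$index] <- df$paired_index
  p
}

#' @rdname read_pairing
#' @param pairing Integer pairing vector (an involution).
#' @export
write_pairing <- function(pairing, path) {
  utils::write.csv(
    data.frame(index = seq_along(pairing), paired_index = as.integer(pairing)),
    path, row.names = FALSE)
  invisible(path)
}
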