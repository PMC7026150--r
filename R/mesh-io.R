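#' Triangulated face mesh
#'
#' Container for a triangulated surface in millimetres: an `n x 3` vertex
#' matrix and an `m x 3` matrix of 1-based vertex indices. All geometry in
#' this package (geodesics, landmark snapping) runs over objects of this
#' class. Units are taken as mm throughout; no unit autodetection is
#' attempted.
#'
#' @param vertices numeric matrix, `n x 3`, columns x/y/z in mm.
#' @param faces integer matrix, `m x 3`, 1-based vertex indices; every face
#'   must be a triangle.
#' @param subject_id character scalar identifying the scan.
#' @param validate check invariants (index range, degenerate faces)?
#' @return an object of class `face_mesh`.
#' @export
face_mesh <- function(vertices, faces, subject_id = "unknown", validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must be triangles (3 columns)")
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  mesh <- structure(
    list(vertices = vertices, faces = faces,
         subject_id = as.character(subject_id)),
    class = "face_mesh"
  )
  if (validate) validate_mesh(mesh)
  mesh
}

#' Validate face-mesh invariants
#'
#' Checks that all face indices are in range and that no face used for
#' geodesics is degenerate (zero area). Connectivity over the landmark
#' region is enforced later, when a geodesic is actually requested (an
#' unreachable landmark raises a connectivity error there).
#'
#' @param mesh a [face_mesh()].
#' @param tol relative area threshold under which a face counts as degenerate.
#' @return `mesh`, invisibly; errors on violation.
#' @export
validate_mesh <- function(mesh, tol = 1e-12) {
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(v) < 3L || nrow(f) < 1L) stop("mesh needs >= 3 vertices and >= 1 face")
  if (min(f) < 1L || max(f) > nrow(v)) stop("face index out of vertex range")
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    stop("degenerate face: repeated vertex index")
  a <- triangle_areas(v, f)
  scale2 <- max(rowSums((v[f[, 1], , drop = FALSE] - v[f[, 2], , drop = FALSE])^2))
  if (any(a <= tol * scale2)) stop("degenerate face: zero area")
  invisible(mesh)
}

# areas of all triangles, vectorized (0.5 * |e1 x e2|)
triangle_areas <- function(v, f) {
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @export
print.face_mesh <- function(x, ...) {
  cat(sprintf("<face_mesh> subject '%s': %d vertices, %d faces (mm)\n",
              x$subject_id, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Read a triangle mesh from PLY or OBJ
#'
#' PLY support covers the `ascii` and `binary_little_endian` variants with
#' float or double vertex properties (extra per-vertex properties such as
#' normals are read and discarded) and triangular faces. OBJ support covers
#' `v` and `f` records only; `f` entries of the form `i`, `i/j`, `i//k`, or
#' `i/j/k` are accepted.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"ply"`, or `"obj"`.
#' @param subject_id subject identifier; defaults to the file stem.
#' @return a [face_mesh()].
#' @export
load_mesh <- function(path, format = c("auto", "ply", "obj"),
                      subject_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("mesh file not found: ", path)
  if (is.null(subject_id))
    subject_id <- tools::file_path_sans_ext(basename(path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("ply", "obj"))
      stop("cannot infer mesh format from extension '", ext, "'")
    format <- ext
  }
  if (format == "ply") read_ply(path, subject_id) else read_obj(path, subject_id)
}

#' Write a mesh to PLY (ascii) or OBJ
#'
#' @param mesh a [face_mesh()].
#' @param path output path.
#' @param format `"auto"`, `"ply"`, or `"obj"`.
#' @return `path`, invisibly.
#' @export
save_mesh <- function(mesh, path, format = c("auto", "ply", "obj")) {
  format <- match.arg(format)
  if (format == "auto") format <- tolower(tools::file_ext(path))
  v <- mesh$vertices; f <- mesh$faces
  if (format == "ply") {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(v)),
             "property double x", "property double y", "property double z",
             sprintf("element face %d", nrow(f)),
             "property list uchar int vertex_indices", "end_header")
    writeLines(hdr, con)
    writeLines(apply(format(v, digits = 17, trim = TRUE, scientific = FALSE),
                     1, paste, collapse = " "), con)
    writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else if (format == "obj") {
    lines <- c(paste("v", v[, 1], v[, 2], v[, 3]),
               paste("f", f[, 1], f[, 2], f[, 3]))
    writeLines(lines, path)
  } else stop("unsupported mesh format: ", format)
  invisible(path)
}

read_obj <- function(path, subject_id) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (!length(vl) || !length(fl)) stop("OBJ parse error: no v/f records in ", path)
  v <- matrix(scan(text = sub("^v ", "", vl), quiet = TRUE), ncol = 3, byrow = TRUE)
  ftok <- strsplit(trimws(sub("^f ", "", fl)), "[[:space:]]+")
  if (any(lengths(ftok) != 3L)) stop("OBJ parse error: non-triangular face")
  idx <- vapply(ftok, function(tk) as.integer(sub("/.*$", "", tk)), integer(3))
  f <- t(idx)
  if (anyNA(f)) stop("OBJ parse error: bad face index")
  face_mesh(v, f, subject_id)
}

read_ply <- function(path, subject_id) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is always ascii, terminated by end_header
  hdr <- character()
  repeat {
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (!length(ln)) stop("PLY parse error: truncated header in ", path)
    hdr <- c(hdr, ln)
    if (identical(trimws(ln), "end_header")) break
    if (length(hdr) > 500L) stop("PLY parse error: header too long")
  }
  if (!identical(trimws(hdr[1]), "ply")) stop("PLY parse error: missing magic in ", path)
  fmt_ln <- grep("^format ", hdr, value = TRUE)
  if (!length(fmt_ln)) stop("PLY parse error: missing format line")
  fmt <- strsplit(trimws(fmt_ln[1]), "[[:space:]]+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)

  # parse element/property declarations in order
  elements <- list(); cur <- NULL
  for (ln in hdr) {
    tk <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (tk[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tk[2], count = as.integer(tk[3]), props = list())
    } else if (tk[1] == "property" && !is.null(cur)) {
      if (tk[2] == "list") {
        cur$props[[tk[5]]] <- list(list = TRUE, count_type = tk[3], type = tk[4])
      } else {
        cur$props[[tk[3]]] <- list(list = FALSE, type = tk[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  ve <- elements[["vertex"]]; fe <- elements[["face"]]
  if (is.null(ve) || is.null(fe)) stop("PLY parse error: need vertex and face elements")
  pn <- names(ve$props)
  if (!all(c("x", "y", "z") %in% pn)) stop("PLY parse error: vertex needs x,y,z")

  if (fmt == "ascii") {
    vlines <- readLines(con, n = ve$count, warn = FALSE)
    vdat <- matrix(scan(text = vlines, quiet = TRUE), nrow = ve$count, byrow = TRUE)
    if (ncol(vdat) < length(pn)) stop("PLY parse error: short vertex record")
    v <- vdat[, match(c("x", "y", "z"), pn), drop = FALSE]
    flines <- readLines(con, n = fe$count, warn = FALSE)
    ftok <- strsplit(trimws(flines), "[[:space:]]+")
    cnt <- vapply(ftok, function(tk) as.integer(tk[1]), integer(1))
    if (any(cnt != 3L)) stop("PLY parse error: non-triangular face")
    f <- t(vapply(ftok, function(tk) as.integer(tk[2:4]), integer(3))) + 1L
  } else {
    sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
               short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
               int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
               float = 4L, float32 = 4L, double = 8L, float64 = 8L)
    ptypes <- vapply(ve$props, function(p) p$type, character(1))
    if (any(vapply(ve$props, function(p) p$list, logical(1))))
      stop("unsupported PLY: list property on vertices")
    if (!all(ptypes %in% c("float", "float32", "double", "float64")))
      stop("unsupported PLY: non-float vertex property in binary file")
    psz <- sizes[ptypes]
    if (length(unique(psz)) == 1L) {
      raw <- readBin(con, "double", n = ve$count * length(pn),
                     size = psz[1], endian = "little")
      vdat <- matrix(raw, nrow = ve$count, byrow = TRUE)
    } else {
      vdat <- matrix(0, ve$count, length(pn))
      for (i in seq_len(ve$count))
        for (j in seq_along(pn))
          vdat[i, j] <- readBin(con, "double", n = 1L, size = psz[j],
                                endian = "little")
    }
    v <- vdat[, match(c("x", "y", "z"), pn), drop = FALSE]
    lp <- fe$props[[1]]
    if (!lp$list) stop("PLY parse error: face element must be a list property")
    csz <- sizes[lp$count_type]; isz <- sizes[lp$type]
    f <- matrix(0L, fe$count, 3L)
    for (i in seq_len(fe$count)) {
      k <- readBin(con, "integer", n = 1L, size = csz, signed = csz > 1,
                   endian = "little")
      if (k != 3L) stop("PLY parse error: non-triangular face")
      f[i, ] <- readBin(con, "integer", n = 3L, size = isz, endian = "little")
    }
    f <- f + 1L
  }
  face_mesh(v, f, subject_id)
}
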