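# Triangle surface meshes and STL input/output.

#' Construct a triangle mesh
#'
#' Minimal container for one bone (or ground) surface: a vertex matrix in mm,
#' integer face indices, and a label from the controlled bone vocabulary.
#'
#' @param vertices Numeric matrix, n x 3, coordinates in mm.
#' @param faces Integer matrix, m x 3, 1-based vertex indices.
#' @param label Bone label; one of [BONE_LABELS] or `NA`.
#' @return Object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, label = NA_character_) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(vertices) == 0L) stop("empty mesh: no vertices")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face index out of range")
  if (!is.na(label) && !label %in% BONE_LABELS)
    stop("unknown bone label: ", label)
  structure(list(vertices = vertices, faces = faces, label = label),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh %s: %d vertices, %d faces>\n",
              ifelse(is.na(x$label), "?", x$label),
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# collapse exactly-coincident vertices and remap faces
dedup_vertices <- function(vertices, faces) {
  key <- paste(vertices[, 1], vertices[, 2], vertices[, 3], sep = "|")
  keep <- !duplicated(key)
  idx <- match(key, key[keep])
  # remap to positions within the kept set
  pos <- cumsum(keep)
  list(vertices = vertices[keep, , drop = FALSE],
       faces = matrix(pos[idx][as.vector(faces)], ncol = 3L))
}

# a bone mesh must span 3D space: >= 4 vertices not all coplanar
assert_non_degenerate <- function(mesh) {
  v <- mesh$vertices
  if (nrow(v) < 4L) stop("bone mesh needs at least 4 vertices")
  c0 <- colMeans(v)
  sv <- svd(sweep(v, 2, c0), nu = 0, nv = 0)$d
  if (sv[3] < 1e-9 * max(sv[1], 1))
    stop("bone mesh is degenerate (coplanar vertices)")
  invisible(mesh)
}

#' Read an STL surface mesh
#'
#' Reads binary or ASCII STL (auto-detected). Coincident vertices are merged
#' by exact coordinate match; the bone label is taken from the file stem
#' (case-insensitive) unless supplied.
#'
#' @param path Path to an `.stl` file.
#' @param label Optional label overriding the file-stem lookup.
#' @return A [triangle_mesh()].
#' @export
read_stl <- function(path, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(label)) {
    stem <- toupper(tools::file_path_sans_ext(basename(path)))
    if (!stem %in% BONE_LABELS)
      stop("file stem '", stem, "' is not a known bone label; pass `label`")
    label <- stem
  }
  sz <- file.info(path)$size
  if (sz < 15) stop("malformed STL: file too short")
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = min(sz, 84L))
  is_ascii <- identical(rawToChar(head[1:5]), "solid")
  if (is_ascii && sz >= 84) {
    # binary files may also start with "solid": trust the facet-count field
    nf <- readBin(head[81:84], "integer", size = 4L, endian = "little")
    if (!is.na(nf) && nf >= 0 && sz == 84 + 50 * as.double(nf)) is_ascii <- FALSE
  }
  vf <- if (is_ascii) parse_stl_ascii(path) else parse_stl_binary(con, head, sz)
  if (nrow(vf$vertices) == 0L) stop("empty mesh: STL contains no facets")
  dd <- dedup_vertices(vf$vertices, vf$faces)
  triangle_mesh(dd$vertices, dd$faces, label)
}

parse_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("malformed STL: ASCII vertex lines not in triples")
  nums <- suppressWarnings(
    vapply(strsplit(trimws(vl), "\\s+"),
           function(tok) as.numeric(tok[2:4]), numeric(3)))
  if (anyNA(nums)) stop("malformed STL: non-numeric vertex coordinates")
  v <- t(nums)
  list(vertices = v,
       faces = matrix(seq_len(nrow(v)), ncol = 3L, byrow = TRUE))
}

parse_stl_binary <- function(con, head, sz) {
  nf <- readBin(head[81:84], "integer", size = 4L, endian = "little")
  if (is.na(nf) || nf < 0 || sz != 84 + 50 * as.double(nf))
    stop("malformed STL: binary size does not match facet count")
  if (nf == 0L) return(list(vertices = matrix(0, 0, 3), faces = matrix(0L, 0, 3)))
  body <- readBin(con, "raw", n = 50L * nf)
  m <- matrix(body, nrow = 50L)
  vbytes <- as.vector(m[13:48, , drop = FALSE])       # 9 floats after the normal
  vals <- readBin(vbytes, "numeric", size = 4L, n = 9L * nf, endian = "little")
  v <- matrix(vals, ncol = 3L, byrow = TRUE)
  list(vertices = v,
       faces = matrix(seq_len(nrow(v)), ncol = 3L, byrow = TRUE))
}

#' Write a mesh to STL
#'
#' @param mesh A [triangle_mesh()].
#' @param path Output path.
#' @param ascii Write ASCII STL instead of binary.
#' @export
write_stl <- function(mesh, path, ascii = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0L) stop("cannot write STL without faces")
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- cc - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / ifelse(len > 0, len, 1)
  name <- ifelse(is.na(mesh$label), "mesh", mesh$label)
  if (ascii) {
    out <- file(path, "wt")
    on.exit(close(out))
    writeLines(paste("solid", name), out)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g", a[i, 1], a[i, 2], a[i, 3]),
        sprintf("      vertex %.9g %.9g %.9g", b[i, 1], b[i, 2], b[i, 3]),
        sprintf("      vertex %.9g %.9g %.9g", cc[i, 1], cc[i, 2], cc[i, 3]),
        "    endloop",
        "  endfacet"), out)
    }
    writeLines(paste("endsolid", name), out)
  } else {
    out <- file(path, "wb")
    on.exit(close(out))
    header <- charToRaw(sprintf("%-80s", paste("footload", name)))[1:80]
    writeBin(header, out)
    writeBin(as.integer(nrow(f)), out, size = 4L, endian = "little")
    tri <- cbind(nrm, a, b, cc)                       # 12 floats per facet
    for (i in seq_len(nrow(f))) {
      writeBin(tri[i, ], out, size = 4L, endian = "little")
      writeBin(as.raw(c(0, 0)), out)
    }
  }
  invisible(path)
}
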