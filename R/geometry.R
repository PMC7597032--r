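# Ground plane fitting, the foot anatomical reference frame, rigid
# realignment, and PCA bone-embedded frames.

unitize <- function(v, what = "vector") {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate ", what, " (near-zero length)")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

# elementary rotation matrices, angle in degrees
rot_x <- function(a) { a <- rad(a); matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3) }
rot_y <- function(a) { a <- rad(a); matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3) }
rot_z <- function(a) { a <- rad(a); matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3) }

#' Fit the ground plane to the segmented ground mesh
#'
#' Total least-squares plane through the ground vertices (SVD of the centred
#' vertex cloud). The plane is `normal . x = offset`; the normal is oriented
#' so the bones lie on its non-negative side.
#'
#' @param ground A [triangle_mesh()] of the segmented ground.
#' @param toward Optional 3-vector (or vertex matrix) on the bone side, used
#'   to orient the normal. When `NULL` the normal keeps a positive z.
#' @return Object of class `ground_plane`: `normal` (unit), `offset` (mm).
#' @export
fit_ground_plane <- function(ground, toward = NULL) {
  v <- if (inherits(ground, "triangle_mesh")) ground$vertices else as.matrix(ground)
  v <- unique(v)
  if (nrow(v) < 3L) stop("ground plane fit needs at least 3 vertices")
  c0 <- colMeans(v)
  sv <- svd(sweep(v, 2, c0))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("ground vertices are collinear; cannot fit a plane")
  normal <- sv$v[, 3]
  offset <- sum(normal * c0)
  flip <- if (!is.null(toward)) {
    tc <- if (is.matrix(toward)) colMeans(toward) else toward
    sum(normal * tc) - offset < 0
  } else normal[3] < 0
  if (flip) {
    normal <- -normal
    offset <- -offset
  }
  structure(list(normal = normal, offset = offset), class = "ground_plane")
}

# signed distance of points (n x 3 or length-3) above the plane
plane_distance <- function(points, plane) {
  if (is.null(dim(points))) points <- matrix(points, 1)
  as.vector(points %*% plane$normal) - plane$offset
}

# orthogonal projection of points onto the plane
plane_project <- function(points, plane) {
  if (is.null(dim(points))) points <- matrix(points, 1)
  d <- plane_distance(points, plane)
  points - outer(d, plane$normal)
}

# index of the vertex closest to the ground (most plantar)
most_plantar_index <- function(mesh, plane) {
  which.min(plane_distance(mesh$vertices, plane))
}

#' Construct the foot anatomical reference frame
#'
#' The vertical axis is the ground normal; the antero/posterior axis is the
#' ground-plane projection of the segment joining the most plantar points of
#' the calcaneus and of the second metatarsal head; the medio-lateral axis is
#' their cross product (`vert x ap`), completing a right-handed triad. The
#' origin is the ground projection of the calcaneal plantar point.
#'
#' The most plantar M2 point is searched in the distal portion of the bone
#' (fraction `distal_frac` of the longitudinal extent, from a provisional
#' frame built on the globally most plantar point), so that a proximally
#' drooping shaft cannot capture the axis; the frame is then rebuilt once.
#'
#' @param calcaneus,m2 [triangle_mesh()] objects in the scanner frame.
#' @param ground A [fit_ground_plane()] result in the same frame.
#' @param distal_frac Distal fraction of M2 searched for its plantar point.
#' @return Object of class `foot_frame`: `origin`, orthonormal `ap_axis`,
#'   `ml_axis`, `vert_axis`, and `foot_length` (mm, calcaneus-to-M2 plantar
#'   distance in the ground plane).
#' @export
compute_foot_frame <- function(calcaneus, m2, ground, distal_frac = 0.3) {
  p_cal <- calcaneus$vertices[most_plantar_index(calcaneus, ground), ]
  dists <- plane_distance(m2$vertices, ground)
  p_m2 <- m2$vertices[which.min(dists), ]
  frame <- build_foot_frame(p_cal, p_m2, ground)
  # refine: restrict the M2 search to the distal end along its own PCA axis
  vc <- sweep(unique(m2$vertices), 2, colMeans(unique(m2$vertices)))
  e1 <- eigen(crossprod(vc) / nrow(vc), symmetric = TRUE)$vectors[, 1]
  if (sum(e1 * frame$ap_axis) < 0) e1 <- -e1
  s <- as.vector(unique(m2$vertices) %*% e1)
  cut <- max(s) - distal_frac * (max(s) - min(s))
  sub <- unique(m2$vertices)[s >= cut, , drop = FALSE]
  p_m2 <- sub[which.min(plane_distance(sub, ground)), ]
  build_foot_frame(p_cal, p_m2, ground)
}

build_foot_frame <- function(p_cal, p_m2, ground) {
  q_cal <- drop(plane_project(p_cal, ground))
  q_m2 <- drop(plane_project(p_m2, ground))
  seg <- q_m2 - q_cal
  if (sqrt(sum(seg^2)) < 1e-9)
    stop("calcaneus and M2 plantar points coincide in the ground plane")
  ap <- seg / sqrt(sum(seg^2))
  vert <- ground$normal
  ml <- cross3(vert, ap)
  structure(list(origin = q_cal, ap_axis = ap, ml_axis = ml,
                 vert_axis = vert, foot_length = sqrt(sum(seg^2))),
            class = "foot_frame")
}

#' @export
print.foot_frame <- function(x, ...) {
  cat(sprintf("<foot_frame: origin (%.2f, %.2f, %.2f), foot length %.1f mm>\n",
              x$origin[1], x$origin[2], x$origin[3], x$foot_length))
  invisible(x)
}

#' Realign meshes into the foot anatomical frame
#'
#' Rigidly maps the frame axes onto world x (antero/posterior), y
#' (medio-lateral), z (vertical) and the frame origin onto (0,0,0); after
#' realignment the ground is the plane z = 0. Pairwise distances are
#' preserved exactly (pure rotation + translation).
#'
#' @param meshes A [triangle_mesh()] or a (possibly named) list of them.
#' @param frame A [compute_foot_frame()] result.
#' @return Realigned mesh(es), same shape as the input.
#' @export
realign <- function(meshes, frame) {
  R <- rbind(frame$ap_axis, frame$ml_axis, frame$vert_axis)
  one <- function(m) {
    v <- sweep(m$vertices, 2, frame$origin) %*% t(R)
    dimnames(v) <- NULL
    triangle_mesh(v, m$faces, m$label)
  }
  if (inherits(meshes, "triangle_mesh")) one(meshes) else lapply(meshes, one)
}

#' PCA bone-embedded anatomical frame
#'
#' Eigen-decomposition of the covariance of the unique bone-surface vertices
#' about their centroid. The three orthogonal axes of highest variance are,
#' for foot bones, the longitudinal (near antero/posterior), medio-lateral
#' and dorsi-plantar anatomical directions. Signs are resolved against the
#' foot frame: the longitudinal axis has non-negative dot product with the
#' antero/posterior axis; of the remaining two eigenvectors, the one more
#' parallel to the vertical becomes the dorsi-plantar axis (positive dorsal)
#' and the medio-lateral axis completes a right-handed triad.
#'
#' @param bone A realigned [triangle_mesh()].
#' @param foot Optional [compute_foot_frame()]; `NULL` means the identity
#'   frame (mesh already realigned), i.e. ap = x, ml = y, vertical = z.
#' @param tie_ratio Eigenvalue ratio below which the first two axes are
#'   considered tied: a degeneracy warning is raised, axes still returned.
#' @param area_weighted Weight each vertex by one third of the total area of
#'   its incident faces instead of uniformly.
#' @return Object of class `bone_frame`: `centroid`, `longitudinal_axis`,
#'   `ml_axis`, `dp_axis`, `variances` (descending eigenvalues, mm^2),
#'   `degenerate` flag and the bone `label`.
#' @export
pca_bone_frame <- function(bone, foot = NULL, tie_ratio = 1.05,
                           area_weighted = FALSE) {
  dd <- dedup_vertices(bone$vertices, bone$faces)
  v <- dd$vertices
  assert_non_degenerate(triangle_mesh(v, dd$faces, bone$label))
  w <- if (area_weighted) vertex_area_weights(v, dd$faces) else
    rep(1 / nrow(v), nrow(v))
  centroid <- colSums(v * w)
  vc <- sweep(v, 2, centroid)
  S <- crossprod(vc * w, vc)
  ed <- eigen(S, symmetric = TRUE)
  vals <- ed$values
  if (vals[3] <= 0) stop("degenerate bone covariance")
  vecs <- ed$vectors
  # deterministic sign fix before anatomical flips
  for (k in 1:3) {
    j <- which.max(abs(vecs[, k]))
    if (vecs[j, k] < 0) vecs[, k] <- -vecs[, k]
  }
  degenerate <- vals[1] / vals[2] < tie_ratio
  if (degenerate)
    warning("no dominant longitudinal axis (eigenvalue ratio ",
            sprintf("%.3f", vals[1] / vals[2]), " < ", tie_ratio,
            ") for bone ", ifelse(is.na(bone$label), "?", bone$label))
  ap <- if (is.null(foot)) c(1, 0, 0) else foot$ap_axis
  vert <- if (is.null(foot)) c(0, 0, 1) else foot$vert_axis
  long <- vecs[, 1]
  if (sum(long * ap) < 0) long <- -long
  rest <- vecs[, 2:3]
  dpi <- which.max(abs(crossprod(rest, vert)))
  dp <- rest[, dpi]
  if (sum(dp * vert) < 0) dp <- -dp
  ml <- cross3(dp, long)     # right-handed: long x ml = dp
  structure(list(centroid = centroid, longitudinal_axis = long,
                 ml_axis = ml, dp_axis = dp, variances = vals,
                 degenerate = degenerate, label = bone$label),
            class = "bone_frame")
}

# per-vertex weights: one third of incident-face area, normalised
vertex_area_weights <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  fa <- sqrt(rowSums(cr^2)) / 2
  w <- numeric(nrow(v))
  for (k in 1:3) {
    tw <- tapply(fa, f[, k], sum)
    w[as.integer(names(tw))] <- w[as.integer(names(tw))] + tw / 3
  }
  if (sum(w) <= 0) rep(1 / nrow(v), nrow(v)) else w / sum(w)
}

#' Export a frame as a plain data frame
#'
#' One row per element (origin/centroid and the three axes), suitable for
#' CSV/JSON serialisation.
#'
#' @param frame A `foot_frame` or `bone_frame`.
#' @return data.frame with columns `element`, `x`, `y`, `z`.
#' @export
frame_as_table <- function(frame) {
  if (inherits(frame, "foot_frame")) {
    m <- rbind(frame$origin, frame$ap_axis, frame$ml_axis, frame$vert_axis)
    el <- c("origin", "ap_axis", "ml_axis", "vert_axis")
  } else {
    m <- rbind(frame$centroid, frame$longitudinal_axis, frame$ml_axis,
               frame$dp_axis)
    el <- c("centroid", "longitudinal_axis", "ml_axis", "dp_axis")
  }
  data.frame(element = el, x = m[, 1], y = m[, 2], z = m[, 3],
             row.names = NULL)
}
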