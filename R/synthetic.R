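# Synthetic inputs with planted ground truth: ellipsoid bone meshes posed
# over a ground plane, rasterised plantar-pressure trials, and cohorts with
# planted linear angle-load relationships of controlled strength.

#' Generate an ellipsoid bone mesh with known pose
#'
#' Samples a scalene ellipsoid surface on a latitude/longitude grid that is
#' closed under reflection through the three principal planes, so the
#' vertex covariance is exactly diagonal in the body frame and PCA recovers
#' the planted axes exactly (up to sign). The analytic lowest point of the
#' posed ellipsoid (and its reflections) is inserted into the triangulation
#' so minimum heights and plantar landmarks are exact as well.
#'
#' @param semi_axes Strictly descending semi-axes (mm).
#' @param rotation Rotation angles `c(rx, ry, rz)` in degrees, applied as
#'   `Rz %*% Ry %*% Rx` to the body axes (body x = longitudinal).
#' @param translation Centroid position (mm).
#' @param n_vertices Approximate vertex budget for the grid.
#' @param label Bone label.
#' @return A [triangle_mesh()]; attribute `truth` holds `semi_axes`,
#'   the rotation matrix `R` (columns = body axes in world coordinates),
#'   `centroid`, the planted longitudinal axis and the analytic `min_z`.
#' @export
make_bone_mesh <- function(semi_axes, rotation = c(0, 0, 0),
                           translation = c(0, 0, 0), n_vertices = 800,
                           label = NA_character_) {
  if (length(semi_axes) != 3L || any(diff(semi_axes) >= 0))
    stop("semi-axes must be strictly descending (degenerate ellipsoid)")
  R <- rot_z(rotation[3]) %*% rot_y(rotation[2]) %*% rot_x(rotation[1])
  grid <- ellipsoid_grid(n_vertices)
  u <- grid$u
  faces <- grid$faces
  cell <- grid$cell
  # insert the analytic plantar tangent direction and its reflections,
  # keeping the sample set closed under the three principal reflections
  w <- semi_axes * as.vector(t(R) %*% c(0, 0, 1))
  if (sqrt(sum(w^2)) > 0) {
    ustar <- -w / sqrt(sum(w^2))
    signs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
    cand <- unique(sweep(signs, 2, ustar, "*"))
    for (i in seq_len(nrow(cand))) {
      ins <- insert_sphere_point(u, faces, cell, grid, cand[i, ])
      u <- ins$u; faces <- ins$faces; cell <- ins$cell
    }
  }
  v <- sweep(u, 2, semi_axes, "*") %*% t(R)
  v <- sweep(v, 2, translation, "+")
  # drop sliver faces created when an inserted point falls on a cell edge
  keep <- face_areas(v, faces) > 1e-9
  mesh <- triangle_mesh(v, faces[keep, , drop = FALSE], label)
  attr(mesh, "truth") <- list(
    semi_axes = semi_axes, R = R, centroid = translation,
    long_axis = R[, 1],
    min_z = translation[3] - sqrt(sum(w^2)),
    plantar_point = if (sqrt(sum(w^2)) > 0)
      as.vector(R %*% (semi_axes * ustar)) + translation else translation)
  mesh
}

.grid_cache <- new.env(parent = emptyenv())

# latitude/longitude unit-sphere grid, reflection-symmetric, with faces and
# a per-face cell id used when inserting extra points; cached per budget
ellipsoid_grid <- function(n_vertices) {
  key <- as.character(n_vertices)
  if (!is.null(.grid_cache[[key]])) return(.grid_cache[[key]])
  .grid_cache[[key]] <- build_ellipsoid_grid(n_vertices)
  .grid_cache[[key]]
}

build_ellipsoid_grid <- function(n_vertices) {
  nphi <- max(8L, 2L * round(sqrt(n_vertices / 2)))
  m <- max(3L, round(n_vertices / nphi) - 1L)
  thetas <- pi * seq_len(m) / (m + 1)
  phis <- 2 * pi * (seq_len(nphi) - 1) / nphi
  ring <- function(j) cbind(sin(thetas[j]) * cos(phis),
                            sin(thetas[j]) * sin(phis),
                            cos(thetas[j]))
  u <- rbind(c(0, 0, 1), do.call(rbind, lapply(seq_len(m), ring)), c(0, 0, -1))
  rid <- function(j, k) 1L + (j - 1L) * nphi + ((k - 1L) %% nphi) + 1L
  south <- nrow(u)
  faces <- list(); cell <- character()
  for (k in seq_len(nphi)) {
    faces[[length(faces) + 1L]] <- c(1L, rid(1, k), rid(1, k + 1))
    cell <- c(cell, paste0("T", k))
  }
  for (j in seq_len(m - 1L)) for (k in seq_len(nphi)) {
    faces[[length(faces) + 1L]] <- c(rid(j, k), rid(j + 1, k), rid(j + 1, k + 1))
    faces[[length(faces) + 1L]] <- c(rid(j, k), rid(j + 1, k + 1), rid(j, k + 1))
    cell <- c(cell, paste0("Q", j, "_", k), paste0("Q", j, "_", k))
  }
  for (k in seq_len(nphi)) {
    faces[[length(faces) + 1L]] <- c(south, rid(m, k + 1), rid(m, k))
    cell <- c(cell, paste0("B", k))
  }
  list(u = u, faces = do.call(rbind, faces), cell = cell,
       thetas = thetas, nphi = nphi, m = m)
}

# insert one unit-sphere point into its grid cell, re-fanning the cell's
# triangles around it; no-op if it coincides with an existing sample
insert_sphere_point <- function(u, faces, cell, grid, p) {
  p <- p / sqrt(sum(p^2))
  if (max(u %*% p) > 1 - 1e-12)
    return(list(u = u, faces = faces, cell = cell))
  theta <- acos(max(-1, min(1, p[3])))
  phi <- atan2(p[2], p[1]) %% (2 * pi)
  k <- min(grid$nphi, floor(phi / (2 * pi / grid$nphi)) + 1L)
  j <- findInterval(theta, grid$thetas)
  id <- if (j == 0L) paste0("T", k) else
    if (j >= grid$m) paste0("B", k) else paste0("Q", j, "_", k)
  hit <- which(cell == id)
  if (!length(hit)) return(list(u = u, faces = faces, cell = cell))
  u <- rbind(u, p)
  pnew <- nrow(u)
  # fan the boundary edges of the removed triangles around the new point
  tri <- faces[hit, , drop = FALSE]
  edges <- do.call(rbind, lapply(seq_len(nrow(tri)), function(i)
    rbind(tri[i, c(1, 2)], tri[i, c(2, 3)], tri[i, c(3, 1)])))
  ek <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  boundary <- edges[ek %in% names(which(table(ek) == 1L)), , drop = FALSE]
  newf <- cbind(boundary, pnew)
  faces <- rbind(faces[-hit, , drop = FALSE], newf)
  cell <- c(cell[-hit], rep(id, nrow(newf)))
  list(u = u, faces = faces, cell = cell)
}

face_areas <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sqrt(rowSums(cr^2)) / 2
}

# support point of a posed ellipsoid in direction -z (analytic lowest point)
ellipsoid_min_z <- function(semi_axes, R, centre) {
  centre[3] - sqrt(sum((semi_axes * as.vector(t(R) %*% c(0, 0, 1)))^2))
}

#' Default synthetic foot specification
#'
#' Thirteen scalene-ellipsoid bones (CAL, CUB, NAV, M1-M5, P1-P5) posed
#' over the ground with anatomically plausible sizes, declination angles
#' and heights (metatarsals pitched head-down by 8-18 degrees, hallux
#' phalanx plantarflexed, lesser phalanges slightly dorsiflexed, navicular
#' raised to arch height). Pose jitter (per-bone rotation and position
#' noise) makes each seeded foot an individual while keeping closed-form
#' ground truth.
#'
#' @param n_vertices Vertex budget per bone.
#' @param angle_jitter_sd,centre_jitter_sd Pose noise SDs (degrees, mm).
#' @param scene_pose Apply a random rigid scanner pose to the whole scene.
#' @return Specification list consumed by [make_foot()].
#' @export
default_foot_spec <- function(n_vertices = 800, angle_jitter_sd = 2.5,
                              centre_jitter_sd = 1.5, scene_pose = TRUE) {
  bone <- function(ax, rot, ctr_xy, plantar_z)
    list(semi_axes = ax, rotation = rot, centre_xy = ctr_xy,
         plantar_z = plantar_z)
  bones <- list(
    CAL = bone(c(40, 23, 19), c(0, -20, 0), c(45, 2), 1.0),
    CUB = bone(c(24, 14, 11), c(0, 0, -8), c(95, -18), 6),
    NAV = bone(c(23, 15, 10), c(10, 0, 5), c(95, 14), 22),
    M1 = bone(c(30, 11, 9), c(0, 18, 3), c(135, 25), 4),
    M2 = bone(c(33, 9, 7), c(0, 18, 0), c(140, 2), 4),
    M3 = bone(c(31, 8.5, 7), c(0, 14, -2), c(138, -12), 4.5),
    M4 = bone(c(29, 8, 6.5), c(0, 12, -5), c(133, -24), 5),
    M5 = bone(c(27, 9, 6), c(0, 10, -8), c(128, -35), 5.5),
    P1 = bone(c(17, 10, 7), c(0, 11, 0), c(175, 26), 3),
    P2 = bone(c(15, 6, 4.5), c(0, -6, 0), c(182, 8), 4),
    P3 = bone(c(14, 5.5, 4), c(0, -5, -3), c(178, -7), 4),
    P4 = bone(c(13, 5, 3.8), c(0, -5, -6), c(172, -20), 4),
    P5 = bone(c(12, 4.8, 3.5), c(0, -7, -10), c(165, -32), 4)
  )
  list(bones = bones, n_vertices = n_vertices,
       angle_jitter_sd = angle_jitter_sd,
       centre_jitter_sd = centre_jitter_sd,
       scene_pose = scene_pose, min_clearance = 0.5)
}

#' Generate a synthetic foot with analytic ground truth
#'
#' Builds the bone meshes and a ground mesh, applies a random rigid scanner
#' pose to the whole scene (so the pipeline must recover the anatomical
#' frame), and computes the ground-truth 84-variable vector analytically
#' from the planted poses: the foot frame from the analytic plantar tangent
#' points of calcaneus and M2, inclinations from the planted longitudinal
#' axes, heights from the ellipsoid support function. The truth never
#' passes through the measurement pipeline.
#'
#' @param spec A [default_foot_spec()] (possibly modified).
#' @param seed Integer seed driving pose jitter and the scanner pose.
#' @return List: `meshes` (named list incl. GROUND, in the posed scanner
#'   frame), `truth` (84-vector plus `foot_length`), `markers` (footprint
#'   xy of plantar landmarks, canonical frame), `bone_truth` (per-bone
#'   planted pose).
#' @export
make_foot <- function(spec = default_foot_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  meshes <- list()
  bt <- list()
  for (b in names(spec$bones)) {
    bs <- spec$bones[[b]]
    rot <- bs$rotation + stats::rnorm(3, 0, spec$angle_jitter_sd)
    ctr_xy <- bs$centre_xy + stats::rnorm(2, 0, spec$centre_jitter_sd)
    pz <- max(spec$min_clearance,
              bs$plantar_z + stats::rnorm(1, 0, spec$centre_jitter_sd / 2))
    R <- rot_z(rot[3]) %*% rot_y(rot[2]) %*% rot_x(rot[1])
    drop_z <- sqrt(sum((bs$semi_axes * as.vector(t(R) %*% c(0, 0, 1)))^2))
    ctr <- c(ctr_xy, pz + drop_z)
    if (ellipsoid_min_z(bs$semi_axes, R, ctr) < 0)
      stop("bone ", b, " placed below the ground")
    meshes[[b]] <- make_bone_mesh(bs$semi_axes, rot, ctr,
                                  spec$n_vertices, b)
    bt[[b]] <- attr(meshes[[b]], "truth")
  }
  meshes$GROUND <- ground_mesh()
  truth <- analytic_3d_variables(bt)
  markers <- rbind(CAL = bt$CAL$plantar_point[1:2],
                   M1 = bt$M1$plantar_point[1:2],
                   M2 = bt$M2$plantar_point[1:2],
                   M5 = bt$M5$plantar_point[1:2],
                   HLX = bt$P1$plantar_point[1:2])
  colnames(markers) <- c("x", "y")
  if (isTRUE(spec$scene_pose)) {
    ax <- stats::rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    ang <- stats::runif(1, 0, 180)
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3)
    Rs <- diag(3) + sin(rad(ang)) * K + (1 - cos(rad(ang))) * K %*% K
    ts <- stats::runif(3, -50, 50)
    meshes <- lapply(meshes, function(m)
      triangle_mesh(sweep(m$vertices %*% t(Rs), 2, ts, "+"), m$faces, m$label))
  }
  list(meshes = meshes, truth = truth, markers = markers, bone_truth = bt)
}

# flat rectangular ground mesh at z = 0
ground_mesh <- function(xlim = c(-60, 260), ylim = c(-80, 80), n = 5L) {
  xs <- seq(xlim[1], xlim[2], length.out = n)
  ys <- seq(ylim[1], ylim[2], length.out = n - 1L)
  v <- cbind(rep(xs, each = length(ys)), rep(ys, times = length(xs)), 0)
  idx <- function(i, j) (i - 1L) * length(ys) + j
  f <- list()
  for (i in seq_len(length(xs) - 1L)) for (j in seq_len(length(ys) - 1L)) {
    f[[length(f) + 1L]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
    f[[length(f) + 1L]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
  }
  triangle_mesh(v, do.call(rbind, f), "GROUND")
}

# ground-truth 84-vector from planted poses, using the same definitional
# trigonometry as the measurement formulas but fed with exact inputs
analytic_3d_variables <- function(bt) {
  p_cal <- bt$CAL$plantar_point
  p_m2 <- bt$M2$plantar_point
  seg <- c(p_m2[1:2] - p_cal[1:2], 0)
  fl <- sqrt(sum(seg^2))
  ap <- seg / fl
  vert <- c(0, 0, 1)
  ml <- cross3(vert, ap)
  M <- rbind(ap, ml, vert)
  fix <- function(u) {
    uf <- as.vector(M %*% u)
    if (uf[1] < 0) -uf else uf
  }
  angles <- list()
  axes <- list()
  for (b in forefoot_bones()) {
    axes[[b]] <- fix(bt[[b]]$long_axis)
    angles[[b]] <- axis_planar_angles(axes[[b]])
  }
  for (i in 1:5) {
    up <- axes[[paste0("M", i)]]
    ud <- axes[[paste0("P", i)]]
    ap_ <- axis_planar_angles(up)
    ad_ <- axis_planar_angles(ud)
    angles[[mtp_pairs()[i]]] <-
      c(R3 = deg(acos(max(-1, min(1, sum(up * ud))))),
        RL = wrap180(ad_[["IL"]] - ap_[["IL"]]),
        RF = wrap180(ad_[["IF"]] - ap_[["IF"]]),
        RT = wrap180(ad_[["IT"]] - ap_[["IT"]]))
  }
  heights <- list()
  for (b in c(forefoot_bones(), midfoot_bones())) {
    h <- max(0, bt[[b]]$min_z)
    heights[[b]] <- c(abs = h, rel = h / fl)
  }
  out <- assemble_3d_variables(angles, heights)
  attr(out, "foot_length") <- fl
  out
}

#' Default synthetic gait (pressure trial) specification
#'
#' A rasterised footprint on a 5 mm grid at 100 Hz: rounded heel, narrow
#' midfoot, broad metatarsal band, hallux and lesser-toe pads. Each region
#' carries a spatial pressure bump (floored Gaussian anchored at a sensor
#' centre) and a half-sine temporal profile; windows overlap so the foot is
#' in contact at every one of the 68 stance frames (contact time 680 ms).
#' Default peak amplitudes (kPa) are typical adult diabetic-gait values.
#' Region labels, the fan geometry and all loading metrics have closed
#' forms, returned as ground truth.
#'
#' @param stance_ms Stance duration (ms); frames run from 0 in 10 ms steps.
#' @param amplitudes Named peak pressures (kPa) per region.
#' @param trans_sd,rot_sd,amp_cv Trial-to-trial jitter: translation SD (mm),
#'   rotation SD (degrees), amplitude coefficient of variation.
#' @param n_trials Number of trials (recorded steps).
#' @return Specification list consumed by [make_pressure_trials()].
#' @export
default_gait_spec <- function(stance_ms = 680,
                              amplitudes = c(HINDFOOT = 300, MIDFOOT = 120,
                                             MET1 = 279, MET24 = 418,
                                             MET5 = 220, HLX = 363,
                                             TOES = 80),
                              trans_sd = 2, rot_sd = 1.5, amp_cv = 0.05,
                              n_trials = 5) {
  list(
    ny = 20L, nx = 56L, pitch = 5, dt = 10, y_centre = 50,
    stance_ms = stance_ms, amplitudes = amplitudes,
    windows = list(HINDFOOT = c(-10, 420), MIDFOOT = c(150, 300),
                   MET1 = c(260, 400), MET24 = c(260, 420),
                   MET5 = c(260, 380), HLX = c(300, 380),
                   TOES = c(300, 360)),
    anchors = list(HINDFOOT = c(37.5, 2.5), MIDFOOT = c(102.5, -2.5),
                   MET1 = c(187.5, 27.5), MET24 = c(187.5, 2.5),
                   MET5 = c(182.5, -27.5), HLX = c(237.5, 32.5),
                   TOES = c(242.5, -7.5)),
    sigmas = c(HINDFOOT = 15, MIDFOOT = 20, MET1 = 12, MET24 = 18,
               MET5 = 10, HLX = 8, TOES = 10),
    floor = 0.15,
    heel = list(centre = c(35, 0), r = 28),
    midfoot_rect = c(55, 150, -15, 12),     # x1 x2 y1 y2
    met_rect = c(150, 225, -30, 35),
    hallux = list(centre = c(240, 30), r = 10),
    toe_rect = c(230, 252, -18, 6),
    markers = rbind(CAL = c(15, 0), M1 = c(150, 22), M2 = c(150, 2),
                    M5 = c(150, -24), HLX = c(240, 30)),
    toe_offset = 15, fractions = c(0.30, 0.51, 0.19),
    trans_sd = trans_sd, rot_sd = rot_sd, amp_cv = amp_cv,
    n_trials = n_trials
  )
}

# design-frame region membership and ground-truth label of continuous points
gait_design_labels <- function(pts, spec) {
  in_disc <- function(p, d) (p[, 1] - d$centre[1])^2 +
    (p[, 2] - d$centre[2])^2 <= d$r^2
  in_rect <- function(p, r) p[, 1] >= r[1] & p[, 1] <= r[2] &
    p[, 2] >= r[3] & p[, 2] <= r[4]
  heel <- in_disc(pts, spec$heel)
  mid <- in_rect(pts, spec$midfoot_rect)
  met <- in_rect(pts, spec$met_rect)
  hlx <- in_disc(pts, spec$hallux)
  toe <- in_rect(pts, spec$toe_rect)
  contact <- heel | mid | met | hlx | toe
  apex <- c(spec$heel$centre[1] - spec$heel$r, spec$heel$centre[2])
  a_med <- atan2(spec$met_rect[4] - apex[2], spec$met_rect[1] - apex[1])
  a_lat <- atan2(spec$met_rect[3] - apex[2], spec$met_rect[1] - apex[1])
  gamma <- a_med - a_lat
  b1 <- a_med - spec$fractions[1] * gamma
  b2 <- a_med - (spec$fractions[1] + spec$fractions[2]) * gamma
  s_toe <- spec$markers["HLX", 1] - spec$toe_offset
  alpha <- atan2(pts[, 2] - apex[2], pts[, 1] - apex[1])
  third <- (s_toe - apex[1]) / 3
  lab <- rep("NONE", nrow(pts))
  toes_zone <- contact & pts[, 1] > s_toe
  lab[toes_zone & alpha > b1] <- "HLX"
  band <- contact & pts[, 1] > spec$met_rect[1] & pts[, 1] <= s_toe
  lab[band] <- ifelse(alpha[band] > b1, "MET1",
                      ifelse(alpha[band] > b2, "MET24", "MET5"))
  rear <- contact & pts[, 1] <= spec$met_rect[1]
  lab[rear & pts[, 1] <= apex[1] + third] <- "HINDFOOT"
  lab[rear & pts[, 1] > apex[1] + third &
        pts[, 1] <= apex[1] + 2 * third] <- "MIDFOOT"
  list(label = lab, contact = contact, gamma = deg(gamma),
       apex = apex, s_toe = s_toe)
}

# which pressure source feeds each point (sources tile the contact area)
gait_source_region <- function(pts, spec) {
  des <- gait_design_labels(pts, spec)
  src <- des$label
  # toes outside the hallux sector still carry (unreported) toe pressure
  toe_pts <- des$contact & pts[, 1] > des$s_toe & src == "NONE"
  src[toe_pts] <- "TOES"
  # rear contact beyond the middle third (none in the default design)
  src[des$contact & src == "NONE" & pts[, 1] <= des$s_toe] <- "MIDFOOT"
  src
}

#' Generate synthetic plantar-pressure trials with ground truth
#'
#' Rasterises the gait design into `n_trials` pressure-frame sequences.
#' Each trial applies a rigid in-plane jitter (to grid sampling and
#' markers) and per-region amplitude scaling. Ground truth contains the
#' analytic loading metrics of the unjittered design: `PP = A` per region,
#' `PTI = 2 A T / pi` for the half-sine windows, `PTIN = PTI / CT`,
#' `CT = stance_ms`, the planted region label grid and the planted arch
#' index (midfoot share of the toe-free contact pixels).
#'
#' @param spec A [default_gait_spec()] (possibly modified).
#' @param seed Integer seed for the trial jitter.
#' @return List `trials` (list of [pressure_sequence()]), `truth`.
#' @export
make_pressure_trials <- function(spec = default_gait_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, spec$stance_ms - spec$dt, by = spec$dt)
  nt <- length(times)
  pts0 <- grid_coords(spec$ny, spec$nx, spec$pitch)
  pts0[, 2] <- pts0[, 2] - spec$y_centre
  centre <- c(130, 0)
  trials <- vector("list", spec$n_trials)
  jitters <- vector("list", spec$n_trials)
  for (tr in seq_len(spec$n_trials)) {
    dxy <- stats::rnorm(2, 0, spec$trans_sd)
    dth <- rad(stats::rnorm(1, 0, spec$rot_sd))
    jitters[[tr]] <- c(dx = dxy[1], dy = dxy[2], dtheta = deg(dth))
    amp <- spec$amplitudes *
      pmax(0.2, stats::rnorm(length(spec$amplitudes), 1, spec$amp_cv))
    names(amp) <- names(spec$amplitudes)
    # map grid points back into the design frame (inverse rigid jitter)
    rel <- sweep(pts0, 2, centre + dxy)
    dpts <- cbind(cos(dth) * rel[, 1] + sin(dth) * rel[, 2],
                  -sin(dth) * rel[, 1] + cos(dth) * rel[, 2])
    dpts <- sweep(dpts, 2, centre, "+")
    src <- gait_source_region(dpts, spec)
    spatial <- numeric(nrow(dpts))
    for (rg in names(spec$amplitudes)) {
      sel <- src == rg
      if (!any(sel)) next
      d2 <- (dpts[sel, 1] - spec$anchors[[rg]][1])^2 +
        (dpts[sel, 2] - spec$anchors[[rg]][2])^2
      spatial[sel] <- amp[[rg]] *
        (spec$floor + (1 - spec$floor) * exp(-d2 / (2 * spec$sigmas[[rg]]^2)))
    }
    frames <- array(0, c(spec$ny, spec$nx, nt))
    for (ti in seq_len(nt)) {
      w <- numeric(nrow(dpts))
      for (rg in names(spec$amplitudes)) {
        win <- spec$windows[[rg]]
        ph <- (times[ti] - win[1]) / win[2]
        if (ph > 0 && ph < 1) w[src == rg] <- sin(pi * ph)
      }
      frames[, , ti] <- matrix(pmin(1270, spatial * w), spec$ny, spec$nx)
    }
    mk <- spec$markers
    relm <- sweep(mk, 2, centre)
    mk <- sweep(cbind(cos(dth) * relm[, 1] - sin(dth) * relm[, 2],
                      sin(dth) * relm[, 1] + cos(dth) * relm[, 2]),
                2, centre + dxy, "+")
    rownames(mk) <- rownames(spec$markers)
    mk[, 2] <- mk[, 2] + spec$y_centre
    trials[[tr]] <- pressure_sequence(frames, spec$pitch, spec$dt, mk)
  }
  # ground truth of the unjittered design
  des <- gait_design_labels(pts0, spec)
  labels <- matrix(des$label, spec$ny, spec$nx)
  pp <- spec$amplitudes[load_regions_map()]
  pti <- vapply(load_regions_map(), function(rg)
    2 * spec$amplitudes[[rg]] * (spec$windows[[rg]][2] / 1000) / pi, 0)
  names(pp) <- names(pti) <- load_regions()
  tf <- des$contact & pts0[, 1] <= des$s_toe
  apexx <- min(pts0[des$contact, 1]) - spec$pitch / 2
  third <- (des$s_toe - apexx) / 3
  sx <- pts0[, 1]
  ai <- sum(tf & sx > apexx + third & sx <= apexx + 2 * third) / sum(tf)
  list(trials = trials,
       truth = list(PP = pp, PTI = pti,
                    PTIN = pti / (spec$stance_ms / 1000),
                    CT = spec$stance_ms, AI = ai,
                    labels = labels, gamma = des$gamma,
                    jitter = jitters))
}

# LOAD region names in the generator's region vocabulary
load_regions_map <- function() c(HLX = "HLX", MET1 = "MET1",
                                 MET24 = "MET24", MET5 = "MET5")

#' Default synthetic cohort specification
#'
#' Group sizes mirror a small single-centre diabetic cohort (7 neuropathic,
#' 8 diabetes-only, 1 LADA). One linear angle-load link is planted by
#' default: second-phalanx 3D dorsiflexion driving the central-metatarsal
#' pressure-time integral with population R-squared 0.77. Unlinked
#' variables are independent draws around typical published cohort values;
#' only the clinical scores differ between groups.
#'
#' @param n Named group sizes `c(N = , D = , LADA = )`.
#' @param links List of planted links: each
#'   `list(var3d, load, slope, r2, group = NULL)` (`group = NULL` plants
#'   the link across all patients).
#' @return Specification list for [make_cohort()].
#' @export
default_cohort_spec <- function(n = c(N = 7, D = 8, LADA = 1),
                                links = list(list(var3d = "I3_P2",
                                                  load = "PTI_MET24",
                                                  slope = 2, r2 = 0.77,
                                                  group = NULL))) {
  list(n = n, links = links)
}

# means and SDs used for unlinked cohort variables (typical adult diabetic
# cohort values; heights in mm, angles degrees, pressures kPa)
cohort_variable_params <- function() {
  fb <- forefoot_bones()
  p <- list()
  set_ <- function(name, mean, sd) p[[name]] <<- c(mean = mean, sd = sd)
  i3m <- c(-18, -15, -12, -10, -8)
  i3p <- c(-10.8, 5.7, 4.6, 5.3, 7.5)
  sdp <- c(3.9, 8.9, 7.9, 8.4, 8.1)
  for (i in 1:5) {
    set_(paste0("I3_M", i), i3m[i], 4)
    set_(paste0("IL_M", i), i3m[i], 4)
    set_(paste0("IT_M", i), 0, 5)
    set_(paste0("IF_M", i), 0, 20)
    set_(paste0("I3_P", i), i3p[i], sdp[i])
    set_(paste0("IL_P", i), i3p[i], sdp[i])
    set_(paste0("IT_P", i), 0, 6)
    set_(paste0("IF_P", i), 0, 25)
  }
  rl <- c(12.2, 32.1, 26.8, 20.4, 16.1)
  rlsd <- c(5.1, 9.0, 8.6, 8.7, 9.1)
  for (i in 1:5) {
    pr <- paste0("M", i, "P", i)
    set_(paste0("R3_", pr), rl[i] + 3, rlsd[i])
    set_(paste0("RL_", pr), rl[i], rlsd[i])
    set_(paste0("RT_", pr), 4, 8)
    set_(paste0("RF_", pr), 8, 20)
  }
  for (b in fb[1:5]) set_(paste0("Hg_", b), 8, 3)
  for (b in fb[6:10]) set_(paste0("Hg_", b), 5, 2)
  set_("Hg_CUB", 8, 3); set_("Hg_NAV", 22, 5)
  for (b in c(fb, "CUB", "NAV"))
    p[[paste0("HgR_", b)]] <- p[[paste0("Hg_", b)]] / 180
  load_means <- c(PP_HLX = 363, PTI_HLX = 74, PTIN_HLX = 82,
                  PP_MET1 = 279, PTI_MET1 = 71, PTIN_MET1 = 77,
                  PP_MET24 = 418, PTI_MET24 = 106, PTIN_MET24 = 118,
                  PP_MET5 = 220, PTI_MET5 = 70, PTIN_MET5 = 76)
  load_sds <- c(133, 35, 39, 120, 38, 35, 178, 43, 52, 160, 53, 54)
  for (i in seq_along(load_means))
    set_(names(load_means)[i], load_means[[i]], load_sds[i])
  set_("CT", 680, 86); set_("AI", 0.22, 0.05)
  set_("AGE", 51.8, 16.5); set_("BMI", 24.0, 2.6)
  set_("YOD", 31.3, 14.4); set_("NSVPT", 1.70, 0.86)
  p
}

# group-conditional clinical score distributions (mean, sd)
clinical_group_params <- function(group) {
  if (group == "N")
    list(mnsi_history = c(7, 2), mnsi_physical = c(4, 1), mdns = c(10, 2),
         vpt_hallux = c(30, 4), vpt_malleolus = c(28, 4))
  else
    list(mnsi_history = c(3, 1.5), mnsi_physical = c(1, 0.6), mdns = c(4, 1.5),
         vpt_hallux = c(12, 4), vpt_malleolus = c(10, 4))
}

# draw one clinical record whose scores reproduce the intended group under
# the two-of-three rule (rejection sampling, deterministic under the seed)
draw_clinical_record <- function(group, age, bmi, yod) {
  pars <- clinical_group_params(if (group == "LADA") "D" else group)
  want <- if (group == "LADA") NULL else group
  for (i in 1:200) {
    d <- lapply(pars, function(ms) stats::rnorm(1, ms[1], ms[2]))
    rec <- try(clinical_record(
      mnsi_history = min(15, max(0, d$mnsi_history)),
      mnsi_physical = min(10, max(0, d$mnsi_physical)),
      mdns = min(46, max(0, d$mdns)),
      vpt_hallux = min(40, max(0, d$vpt_hallux)),
      vpt_malleolus = min(40, max(0, d$vpt_malleolus)),
      age = age, bmi = bmi, yod = yod,
      diagnosis = if (group == "LADA") "LADA" else "type1"), silent = TRUE)
    if (inherits(rec, "try-error")) next
    if (is.null(want) || classify_group(rec) == want) return(rec)
  }
  stop("could not draw a clinical record consistent with group ", group)
}

#' Generate a synthetic cohort variable table with planted correlations
#'
#' Draws the 102 analysis variables for every patient. Unlinked variables
#' are independent normal draws (heights clipped at zero, arch index at
#' `[0, 1]`). For each planted link the load variable is built as
#' `slope * angle + noise`, with the noise variance chosen from
#' `R2 = slope^2 var(angle) / (slope^2 var(angle) + var(noise))` so the
#' population R-squared equals the target; the intercept preserves the load
#' variable's nominal mean. Clinical scores are drawn per group so the
#' two-of-three rule reproduces the intended labels, and AGE/BMI/YOD/NS-VPT
#' come from those records.
#'
#' @param spec A [default_cohort_spec()].
#' @param seed Integer seed.
#' @return List `table` (data.frame: patient, group + 102 variables),
#'   `records` (clinical records), `truth` (per-link slope, intercept,
#'   noise SD, target R-squared).
#' @export
make_cohort <- function(spec = default_cohort_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- rep(names(spec$n), spec$n)
  npat <- length(groups)
  if (npat < 1L) stop("empty cohort")
  pars <- cohort_variable_params()
  tab <- data.frame(patient = sprintf("pt%02d", seq_len(npat)),
                    group = groups, stringsAsFactors = FALSE)
  for (v in unlist(variable_registry()))
    tab[[v]] <- stats::rnorm(npat, pars[[v]]["mean"], pars[[v]]["sd"])
  for (b in c(forefoot_bones(), "CUB", "NAV")) {
    tab[[paste0("Hg_", b)]] <- pmax(0, tab[[paste0("Hg_", b)]])
    tab[[paste0("HgR_", b)]] <- pmax(0, tab[[paste0("HgR_", b)]])
  }
  tab$AI <- pmin(1, pmax(0, tab$AI))
  truth <- list()
  for (lk in spec$links) {
    if (is.null(lk$r2) || lk$r2 <= 0 || lk$r2 > 1)
      stop("infeasible target R-squared (must lie in (0, 1])")
    if (is.null(tab[[lk$var3d]]) || is.null(tab[[lk$load]]))
      stop("unknown variable in link: ", lk$var3d, " -> ", lk$load)
    rows <- if (is.null(lk$group)) rep(TRUE, npat) else groups == lk$group
    if (sum(rows) < 3L) stop("linked group needs at least 3 patients")
    ang_sd <- pars[[lk$var3d]]["sd"]
    noise_sd <- abs(lk$slope) * ang_sd * sqrt((1 - lk$r2) / lk$r2)
    icpt <- pars[[lk$load]]["mean"] - lk$slope * pars[[lk$var3d]]["mean"]
    tab[[lk$load]][rows] <- icpt + lk$slope * tab[[lk$var3d]][rows] +
      stats::rnorm(sum(rows), 0, noise_sd)
    truth[[length(truth) + 1L]] <-
      list(var3d = lk$var3d, load = lk$load, slope = lk$slope,
           intercept = unname(icpt), noise_sd = unname(noise_sd),
           r2 = lk$r2, group = lk$group)
  }
  records <- list()
  for (i in seq_len(npat)) {
    records[[i]] <- draw_clinical_record(groups[i], age = tab$AGE[i],
                                         bmi = tab$BMI[i], yod = tab$YOD[i])
    tab$NSVPT[i] <- ns_vpt(records[[i]])
  }
  names(records) <- tab$patient
  list(table = tab, records = records, truth = truth)
}
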