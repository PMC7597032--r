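# The 84 skeletal "3D variables": absolute inclination and relative
# orientation angles (3D + three planar projections) and minimum bone
# heights, computed in the foot anatomical reference frame.

# wrap an angle in degrees to (-180, 180]
wrap180 <- function(a) {
  r <- ((a + 180) %% 360) - 180
  r[!is.na(r) & r == -180] <- 180
  r
}

# express a direction in foot-frame coordinates (identity when foot is NULL)
axis_in_foot <- function(u, foot = NULL) {
  if (is.null(foot)) return(u)
  c(sum(u * foot$ap_axis), sum(u * foot$ml_axis), sum(u * foot$vert_axis))
}

# planar decomposition of a unit axis in foot coordinates:
#   I3 elevation above the ground plane (dorsal positive),
#   IL lateral-plane angle from the ap axis (dorsal positive),
#   IT transverse-plane angle from the ap axis (positive toward ml),
#   IF frontal-plane angle from the ml axis (dorsal positive).
# A projection shorter than `tol` leaves that planar angle undefined (NA).
axis_planar_angles <- function(u, tol = 1e-9) {
  u <- u / sqrt(sum(u^2))
  c(I3 = deg(asin(max(-1, min(1, u[3])))),
    IL = if (sqrt(u[1]^2 + u[3]^2) < tol) NA_real_ else deg(atan2(u[3], u[1])),
    IF = if (sqrt(u[2]^2 + u[3]^2) < tol) NA_real_ else deg(atan2(u[3], u[2])),
    IT = if (sqrt(u[1]^2 + u[2]^2) < tol) NA_real_ else deg(atan2(u[2], u[1])))
}

#' Absolute inclination angles of one bone
#'
#' Angles of the bone's longitudinal axis relative to the foot frame: `I3`
#' is the signed 3D elevation above the transverse (ground) plane, positive
#' dorsal; `IL`, `IT`, `IF` are the signed angles of the axis projected into
#' the lateral, transverse and frontal anatomical planes. An axis orthogonal
#' to a projection plane yields `NA` for that plane.
#'
#' @param bone A [pca_bone_frame()] result.
#' @param foot Optional [compute_foot_frame()]; `NULL` for realigned data.
#' @return Named numeric vector `c(I3, IL, IF, IT)`, degrees.
#' @export
absolute_inclination <- function(bone, foot = NULL) {
  axis_planar_angles(axis_in_foot(bone$longitudinal_axis, foot))
}

#' Relative orientation angles between two adjacent bones
#'
#' `R3` is the unsigned 3D angle between the longitudinal axes of the
#' proximal and distal bone. The planar angles `RL`, `RF`, `RT` are signed
#' differences of the projected absolute inclinations (distal minus
#' proximal), so that a dorsiflexed distal segment is positive and
#' plantarflexion is negative, and `RL_MxPx = IL_Px - IL_Mx` holds
#' identically.
#'
#' @param proximal,distal [pca_bone_frame()] results (e.g. M1 and P1).
#' @param foot Optional [compute_foot_frame()].
#' @return Named numeric vector `c(R3, RL, RF, RT)`, degrees.
#' @export
relative_orientation <- function(proximal, distal, foot = NULL) {
  up <- axis_in_foot(proximal$longitudinal_axis, foot)
  ud <- axis_in_foot(distal$longitudinal_axis, foot)
  ap <- axis_planar_angles(up)
  ad <- axis_planar_angles(ud)
  c(R3 = deg(acos(max(-1, min(1, sum(up * ud))))),
    RL = wrap180(ad[["IL"]] - ap[["IL"]]),
    RF = wrap180(ad[["IF"]] - ap[["IF"]]),
    RT = wrap180(ad[["IT"]] - ap[["IT"]]))
}

#' Minimum height of a bone above the ground
#'
#' Minimum distance of the bone surface from the ground plane, clipped at
#' zero (a bone touching the ground has height 0).
#'
#' @param bone A [triangle_mesh()].
#' @param ground Optional [fit_ground_plane()]; `NULL` means the mesh is
#'   realigned and the ground is z = 0.
#' @return Height in mm.
#' @export
min_height <- function(bone, ground = NULL) {
  d <- if (is.null(ground)) bone$vertices[, 3] else
    plane_distance(bone$vertices, ground)
  max(0, min(d))
}

#' Foot-length-normalised bone height
#'
#' Minimum bone height divided by the foot length (the calcaneus-to-M2
#' plantar-point distance from the foot frame), giving a dimensionless,
#' scale-free height comparable across feet.
#'
#' @param bone_height Height in mm.
#' @param foot_length Foot length in mm; must be positive.
#' @return Dimensionless relative height.
#' @export
relative_height <- function(bone_height, foot_length) {
  if (!is.finite(foot_length) || foot_length <= 0)
    stop("foot length must be positive")
  bone_height / foot_length
}

#' Assemble the 84 named skeletal variables of one foot
#'
#' @param angles Named list: for each of M1-M5, P1-P5 a vector
#'   `c(I3, IL, IF, IT)` and for each pair M1P1-M5P5 a vector
#'   `c(R3, RL, RF, RT)` (as from [absolute_inclination()] and
#'   [relative_orientation()]).
#' @param heights Named list: for each of M1-M5, P1-P5, CUB, NAV a vector
#'   `c(abs = , rel = )`.
#' @return Named numeric vector of exactly 84 entries in the canonical order
#'   of [variable_names_3d()]; undefined angles are carried as `NA`.
#' @export
assemble_3d_variables <- function(angles, heights) {
  out <- stats::setNames(rep(NA_real_, 84L), variable_names_3d())
  for (b in forefoot_bones()) {
    if (is.null(angles[[b]])) stop(b, " required")
    for (m in c("I3", "IL", "IF", "IT"))
      out[paste0(m, "_", b)] <- angles[[b]][[m]]
  }
  for (p in mtp_pairs()) {
    if (is.null(angles[[p]])) stop(p, " required")
    for (m in c("R3", "RL", "RF", "RT"))
      out[paste0(m, "_", p)] <- angles[[p]][[m]]
  }
  for (b in c(forefoot_bones(), midfoot_bones())) {
    if (is.null(heights[[b]])) stop(b, " required")
    out[paste0("Hg_", b)] <- heights[[b]][["abs"]]
    out[paste0("HgR_", b)] <- heights[[b]][["rel"]]
  }
  out
}

#' Full skeletal stage for one foot
#'
#' Runs the geometric pipeline on a set of labelled bone meshes plus ground:
#' fits the ground plane, builds the foot anatomical frame, realigns all
#' meshes, derives PCA bone frames for the ten forefoot bones, and assembles
#' the 84 skeletal variables.
#'
#' @param meshes Named list of [triangle_mesh()] objects containing at least
#'   CAL, M1-M5, P1-P5, CUB, NAV and GROUND, all in one common frame.
#' @param area_weighted Passed to [pca_bone_frame()].
#' @return Named numeric vector of 84 variables, with attributes
#'   `foot_length` (mm), `frame` (the foot frame) and `degenerate` (labels
#'   of bones whose PCA had no dominant axis).
#' @export
foot_3d_variables <- function(meshes, area_weighted = FALSE) {
  need <- c("CAL", forefoot_bones(), midfoot_bones(), "GROUND")
  miss <- setdiff(need, names(meshes))
  if (length(miss)) stop(miss[1], " required")
  bone_v <- do.call(rbind, lapply(meshes[setdiff(need, "GROUND")],
                                  function(m) m$vertices))
  ground <- fit_ground_plane(meshes$GROUND, toward = bone_v)
  frame <- compute_foot_frame(meshes$CAL, meshes$M2, ground)
  aligned <- realign(meshes[setdiff(need, "GROUND")], frame)
  angles <- list()
  frames <- list()
  degen <- character()
  for (b in forefoot_bones()) {
    bf <- withCallingHandlers(
      pca_bone_frame(aligned[[b]], area_weighted = area_weighted),
      warning = function(w) {
        degen <<- c(degen, b)
        invokeRestart("muffleWarning")
      })
    frames[[b]] <- bf
    angles[[b]] <- absolute_inclination(bf)
  }
  for (i in 1:5)
    angles[[mtp_pairs()[i]]] <-
      relative_orientation(frames[[paste0("M", i)]], frames[[paste0("P", i)]])
  heights <- list()
  for (b in c(forefoot_bones(), midfoot_bones())) {
    h <- min_height(aligned[[b]])
    heights[[b]] <- c(abs = h, rel = relative_height(h, frame$foot_length))
  }
  out <- assemble_3d_variables(angles, heights)
  attr(out, "foot_length") <- frame$foot_length
  attr(out, "frame") <- frame
  attr(out, "degenerate") <- degen
  out
}
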