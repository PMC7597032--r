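# Dynamic plantar-pressure processing: footprints, marker-based anatomical
# masking with the 30/51/19% plantar-angle forefoot subdivision, regional
# loading metrics (PP, PTI, PTI_N), contact time and arch index.

#' Construct a pressure frame sequence
#'
#' One barefoot-walking trial: a time-ordered stack of 2D pressure grids
#' plus the footprint-plane positions of the anatomical skin markers.
#' Grid coordinates are in mm with `x = (col - 0.5) * pitch`,
#' `y = (row - 0.5) * pitch`.
#'
#' @param frames Numeric array `nrow x ncol x nframes`, pressures in kPa
#'   within the platform range 0-1270.
#' @param pitch Sensor pitch in mm (default 5, i.e. 4 sensors per cm^2).
#' @param dt Frame interval in ms (default 10, i.e. 100 Hz).
#' @param markers Numeric matrix with rows named CAL, M1, M2, M5, HLX and
#'   columns x, y (mm): calcaneus, metatarsal heads I/II/V, hallux.
#' @return Object of class `pressure_sequence`.
#' @export
pressure_sequence <- function(frames, pitch = 5, dt = 10, markers = NULL) {
  frames <- as.array(frames)
  if (length(dim(frames)) == 2L) dim(frames) <- c(dim(frames), 1L)
  if (length(dim(frames)) != 3L) stop("frames must be a rows x cols x time array")
  if (dim(frames)[3] < 1L) stop("at least one frame required")
  if (min(frames) < 0 || max(frames) > 1270)
    stop("pressures must lie in the platform range [0, 1270] kPa")
  if (!is.null(markers)) {
    markers <- as.matrix(markers)
    need <- c("CAL", "M1", "M2", "M5", "HLX")
    if (!all(need %in% rownames(markers)))
      stop("markers must include rows ", paste(need, collapse = ", "))
    markers <- markers[need, 1:2, drop = FALSE]
    colnames(markers) <- c("x", "y")
  }
  structure(list(frames = frames, pitch = pitch, dt = dt, markers = markers),
            class = "pressure_sequence")
}

# mm coordinates of every grid cell centre (column-major order)
grid_coords <- function(nr, nc, pitch) {
  cbind(x = rep((seq_len(nc) - 0.5) * pitch, each = nr),
        y = rep((seq_len(nr) - 0.5) * pitch, times = nc))
}

#' Peak-pressure image (footprint) of a trial
#'
#' Per-sensor maximum pressure over time, with the contact mask at the given
#' threshold.
#'
#' @param seq A [pressure_sequence()].
#' @param threshold Contact threshold, kPa.
#' @return Object of class `footprint`: `peak_image`, logical
#'   `contact_mask`, `pitch`, `markers`, `threshold`.
#' @export
peak_pressure_image <- function(seq, threshold = 10) {
  peak <- apply(seq$frames, c(1, 2), max)
  if (!any(peak > threshold))
    stop("empty footprint: no sensor exceeds the contact threshold")
  structure(list(peak_image = peak, contact_mask = peak > threshold,
                 pitch = seq$pitch, markers = seq$markers,
                 threshold = threshold),
            class = "footprint")
}

#' Contact time of a trial
#'
#' Number of frames with at least one sensor above the contact threshold,
#' times the frame interval.
#'
#' @param seq A [pressure_sequence()].
#' @param threshold Contact threshold, kPa.
#' @return Contact time in ms.
#' @export
contact_time <- function(seq, threshold = 10) {
  nt <- dim(seq$frames)[3]
  m <- matrix(seq$frames, ncol = nt)
  sum(apply(m, 2, max) > threshold) * seq$dt
}

# principal-axis pose (centroid + orientation angle) of a contact mask
mask_pose <- function(mask, pitch) {
  pts <- grid_coords(nrow(mask), ncol(mask), pitch)[as.vector(mask), , drop = FALSE]
  ctr <- colMeans(pts)
  S <- stats::cov(pts)
  v1 <- eigen(S, symmetric = TRUE)$vectors[, 1]
  list(centroid = ctr, angle = atan2(v1[2], v1[1]), points = pts)
}

#' Register footprints to the first and average them
#'
#' Rigid 2D registration by aligning each footprint's contact-mask centroid
#' and principal axis to the first footprint (rotation resolved to the
#' smaller of the two axis-flip alternatives), followed by bilinear
#' resampling and a pixelwise mean of the aligned peak images.
#'
#' @param footprints List of >= 2 [peak_pressure_image()] results on equal
#'   grids.
#' @param residual_bound Warn if the aligned contact masks overlap (Jaccard
#'   index) less than this bound.
#' @return Averaged `footprint`; attribute `transforms` holds per-trial
#'   `(dx, dy, dtheta)` (theta in degrees, mapping trial onto reference) and
#'   attribute `residual_flag` marks poor registrations.
#' @export
register_and_average <- function(footprints, residual_bound = 0.5) {
  if (length(footprints) < 2L) stop("need at least 2 footprints")
  ref <- footprints[[1]]
  pose_r <- mask_pose(ref$contact_mask, ref$pitch)
  nr <- nrow(ref$peak_image); nc <- ncol(ref$peak_image)
  tgt <- grid_coords(nr, nc, ref$pitch)
  acc <- ref$peak_image
  transforms <- list(c(dx = 0, dy = 0, dtheta = 0))
  flags <- FALSE
  for (i in seq_along(footprints)[-1]) {
    fp <- footprints[[i]]
    pose_i <- mask_pose(fp$contact_mask, fp$pitch)
    dth <- pose_r$angle - pose_i$angle
    dth <- atan2(sin(dth), cos(dth))
    if (dth > pi / 2) dth <- dth - pi
    if (dth <= -pi / 2) dth <- dth + pi
    # source coords of each target pixel (inverse transform)
    rel <- sweep(tgt, 2, pose_r$centroid)
    src <- cbind(cos(dth) * rel[, 1] + sin(dth) * rel[, 2],
                 -sin(dth) * rel[, 1] + cos(dth) * rel[, 2])
    src <- sweep(src, 2, pose_i$centroid, "+")
    acc <- acc + bilinear_sample(fp$peak_image, src, fp$pitch)
    aligned_mask <- bilinear_sample(fp$peak_image, src, fp$pitch) > fp$threshold
    dim(aligned_mask) <- dim(ref$contact_mask)
    jac <- sum(aligned_mask & ref$contact_mask) /
      max(1, sum(aligned_mask | ref$contact_mask))
    if (jac < residual_bound) {
      warning("footprint ", i, " registered poorly (overlap ",
              sprintf("%.2f", jac), ")")
      flags <- TRUE
    }
    transforms[[i]] <- c(dx = unname(pose_r$centroid[1] - pose_i$centroid[1]),
                         dy = unname(pose_r$centroid[2] - pose_i$centroid[2]),
                         dtheta = deg(dth))
  }
  avg <- acc / length(footprints)
  out <- structure(list(peak_image = avg, contact_mask = avg > ref$threshold,
                        pitch = ref$pitch, markers = ref$markers,
                        threshold = ref$threshold),
                   class = "footprint")
  attr(out, "transforms") <- transforms
  attr(out, "residual_flag") <- flags
  out
}

# bilinear interpolation of image at mm coords (0 outside)
bilinear_sample <- function(img, xy, pitch) {
  nr <- nrow(img); nc <- ncol(img)
  cx <- xy[, 1] / pitch + 0.5   # fractional column index
  ry <- xy[, 2] / pitch + 0.5   # fractional row index
  c0 <- floor(cx); r0 <- floor(ry)
  fx <- cx - c0; fy <- ry - r0
  val <- function(r, cc) {
    ok <- r >= 1 & r <= nr & cc >= 1 & cc <= nc
    v <- numeric(length(r))
    v[ok] <- img[cbind(r[ok], cc[ok])]
    v
  }
  out <- val(r0, c0) * (1 - fx) * (1 - fy) +
    val(r0, c0 + 1) * fx * (1 - fy) +
    val(r0 + 1, c0) * (1 - fx) * fy +
    val(r0 + 1, c0 + 1) * fx * fy
  matrix(out, nr, nc)
}

#' Marker-based anatomical region mask with plantar-angle subdivision
#'
#' Reconstructs the anatomical footprint masking: the whole-foot plantar
#' angle gamma is measured from the most posterior contact point (the apex)
#' between the medial and lateral tangents of the anterior part of the
#' footprint, and split by two interior rays into sectors of 30% (medial,
#' MET1), 51% (central, MET24) and 19% (lateral, MET5) of gamma. The
#' forefoot band lies between the metatarsal-head marker line and the toe
#' line (through the hallux marker, perpendicular to the foot axis, shifted
#' posteriorly by `toe_offset`); the hallux region is the contact anterior
#' to the toe line and medial of the MET1/MET24 boundary ray. The remaining
#' contact is labelled MIDFOOT/HINDFOOT by thirds of the toe-free extent.
#'
#' Apex and tangents are taken over contact *pixel corners* so that the
#' measured fan matches the underlying continuous footprint outline to
#' sub-pixel accuracy.
#'
#' @param fp A [peak_pressure_image()] result.
#' @param markers Marker matrix (defaults to the one carried by `fp`).
#' @param fractions Sector fractions medial-to-lateral, summing to 1.
#' @param toe_offset Posterior offset of the toe line from the hallux
#'   marker, mm.
#' @param anterior_frac Fraction of the axial extent ahead of which contact
#'   points are candidates for the tangent rays.
#' @return Object of class `region_mask`: character `labels` matrix (HLX,
#'   MET1, MET24, MET5, MIDFOOT, HINDFOOT, NONE), `gamma` (degrees), the
#'   fan angles, foot `axis`, apex, and the toe/metatarsal line parameters.
#' @export
plantar_angle_masks <- function(fp, markers = fp$markers,
                                fractions = c(0.30, 0.51, 0.19),
                                toe_offset = 15, anterior_frac = 0.5) {
  if (is.null(markers)) stop("markers required for anatomical masking")
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-9)
    stop("sector fractions must be positive and sum to 1")
  mask <- fp$contact_mask
  if (!any(mask)) stop("empty contact mask")
  pitch <- fp$pitch
  pts <- grid_coords(nrow(mask), ncol(mask), pitch)[as.vector(mask), , drop = FALSE]
  # foot axis from markers: heel toward metatarsal heads
  met_ctr <- colMeans(markers[c("M1", "M2", "M5"), ])
  a <- unitize(met_ctr - markers["CAL", ], "foot axis")
  perp <- c(-a[2], a[1])
  s <- pts %*% a
  t <- pts %*% perp
  # pixel corners of the contact set for apex/tangent estimation
  corners <- do.call(rbind, lapply(list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)),
                                   function(d) sweep(pts, 2, d * pitch / 2, "+")))
  cs <- corners %*% a
  ct <- corners %*% perp
  ord <- order(cs, abs(ct))
  apex <- corners[ord[1], ]
  s_apex <- cs[ord[1]]; t_apex <- ct[ord[1]]
  # tangent rays over the anterior part of the footprint
  cut <- min(cs) + anterior_frac * (max(cs) - min(cs))
  ant <- which(cs >= cut)
  if (length(ant) < 3L) stop("degenerate footprint: no anterior contact")
  hull <- ant[grDevices::chull(corners[ant, , drop = FALSE])]
  alpha <- atan2(ct[hull] - t_apex, cs[hull] - s_apex)
  med_sign <- sign(sum((markers["M1", ] - markers["M5", ]) * perp))
  if (med_sign == 0) med_sign <- 1
  a_med <- med_sign * max(med_sign * alpha)
  a_lat <- med_sign * min(med_sign * alpha)
  gamma <- abs(a_med - a_lat)
  if (gamma <= 0) stop("degenerate footprint: zero plantar angle")
  b1 <- a_med - med_sign * fractions[1] * gamma
  b2 <- a_med - med_sign * (fractions[1] + fractions[2]) * gamma
  # toe line and metatarsal-head marker line
  s_toe <- sum(markers["HLX", ] * a) - toe_offset
  mm <- markers[c("M1", "M2", "M5"), ]
  m0 <- colMeans(mm)
  mv <- eigen(stats::cov(mm), symmetric = TRUE)$vectors[, 1]
  nm <- c(-mv[2], mv[1])
  if (sum((markers["HLX", ] - m0) * nm) < 0) nm <- -nm
  ahead_met <- as.vector((pts %*% nm) - sum(m0 * nm)) > 0
  # per-pixel fan angle and sector
  alpha_p <- atan2(t - t_apex, s - s_apex)
  sector <- ifelse(med_sign * (alpha_p - b1) > 0, "MET1",
                   ifelse(med_sign * (alpha_p - b2) > 0, "MET24", "MET5"))
  lab <- rep("NONE", nrow(pts))
  toes <- s > s_toe
  lab[toes & med_sign * (alpha_p - b1) > 0] <- "HLX"
  band <- !toes & ahead_met
  lab[band] <- sector[band]
  third <- (s_toe - s_apex) / 3
  rear <- !toes & !ahead_met
  lab[rear & s <= s_apex + third] <- "HINDFOOT"
  lab[rear & s > s_apex + third & s <= s_apex + 2 * third] <- "MIDFOOT"
  labels <- matrix("NONE", nrow(mask), ncol(mask))
  labels[mask] <- lab
  structure(list(labels = labels, gamma = deg(gamma),
                 alpha_med = deg(a_med), alpha_lat = deg(a_lat),
                 boundary1 = deg(b1), boundary2 = deg(b2),
                 axis = a, apex = apex, s_apex = s_apex, s_toe = s_toe,
                 med_sign = med_sign, pitch = pitch),
            class = "region_mask")
}

#' Regional loading metrics of one trial
#'
#' Peak pressure (max over frames and sensors in the region), pressure-time
#' integral (integral of the regional peak-pressure curve, i.e. the max over
#' the region's sensors at each frame) and PTI normalised to contact time.
#' An alternative per-sensor convention (PTI = the largest single-sensor
#' time integral in the region) is available via `per_sensor_pti`.
#'
#' @param seq A [pressure_sequence()].
#' @param mask A [plantar_angle_masks()] result on the same grid.
#' @param region One of HLX, MET1, MET24, MET5 (or MIDFOOT/HINDFOOT).
#' @param threshold Contact threshold, kPa.
#' @param per_sensor_pti Use the per-sensor PTI convention.
#' @return List `PP` (kPa), `PTI` (kPa s), `PTIN` (kPa), `CT` (ms), and
#'   `empty` flag (TRUE when the region never makes contact; metrics 0).
#' @export
regional_metrics <- function(seq, mask, region, threshold = 10,
                             per_sensor_pti = FALSE) {
  if (!region %in% mask$labels) stop("region ", region, " not present in mask")
  idx <- which(as.vector(mask$labels == region))
  nt <- dim(seq$frames)[3]
  m <- matrix(seq$frames, ncol = nt)[idx, , drop = FALSE]
  ct <- contact_time(seq, threshold)
  if (max(m) <= threshold)
    return(list(PP = 0, PTI = 0, PTIN = 0, CT = ct, empty = TRUE))
  curve <- apply(m, 2, max)
  pp <- max(curve)
  pti <- if (per_sensor_pti) max(rowSums(m)) * seq$dt / 1000 else
    sum(curve) * seq$dt / 1000
  list(PP = pp, PTI = pti, PTIN = pti / (ct / 1000), CT = ct, empty = FALSE)
}

#' Arch index of a footprint
#'
#' The toe-free footprint (contact posterior to the toe line) is divided
#' into three equal-length bands along its own principal axis; the arch
#' index is the middle-band (midfoot) contact area over the total toe-free
#' contact area. Flat feet give high values, high arches low values.
#'
#' @param fp A [peak_pressure_image()] (or averaged) footprint.
#' @param mask A [plantar_angle_masks()] result (supplies the toe line).
#' @return Arch index in `[0, 1]`.
#' @export
arch_index <- function(fp, mask) {
  pts <- grid_coords(nrow(fp$contact_mask), ncol(fp$contact_mask), fp$pitch)
  pts <- pts[as.vector(fp$contact_mask), , drop = FALSE]
  keep <- as.vector(pts %*% mask$axis) <= mask$s_toe
  if (!any(keep)) stop("empty toe-free footprint")
  pts <- pts[keep, , drop = FALSE]
  v1 <- eigen(stats::cov(pts), symmetric = TRUE)$vectors[, 1]
  s <- as.vector(pts %*% v1)
  lo <- min(s) - fp$pitch / 2
  hi <- max(s) + fp$pitch / 2
  b <- lo + (hi - lo) * c(1, 2) / 3
  sum(s >= b[1] & s < b[2]) / length(s)
}

#' Loading and functional variables for one foot (five trials)
#'
#' Per-trial regional metrics averaged over the trials (the 12 LOAD
#' variables), contact time averaged over trials, and the arch index
#' computed on the registered-and-averaged footprint.
#'
#' @param trials List of [pressure_sequence()] objects (the five recorded
#'   steps of one foot).
#' @param threshold Contact threshold, kPa.
#' @param fractions,toe_offset,anterior_frac Passed to
#'   [plantar_angle_masks()].
#' @param per_sensor_pti Passed to [regional_metrics()].
#' @return List with `load` (named vector of the 12 LOAD variables), `func`
#'   (`CT` ms, `AI`), `footprint` (the averaged footprint), `mask` (mask of
#'   the averaged footprint) and `empty_regions` (region labels that never
#'   made contact in at least one trial).
#' @export
analyze_pressure_trials <- function(trials, threshold = 10,
                                    fractions = c(0.30, 0.51, 0.19),
                                    toe_offset = 15, anterior_frac = 0.5,
                                    per_sensor_pti = FALSE) {
  if (!length(trials)) stop("no trials supplied")
  per <- lapply(trials, function(tr) {
    fp <- peak_pressure_image(tr, threshold)
    msk <- plantar_angle_masks(fp, fractions = fractions,
                               toe_offset = toe_offset,
                               anterior_frac = anterior_frac)
    vals <- lapply(load_regions(), function(rg)
      regional_metrics(tr, msk, rg, threshold, per_sensor_pti))
    names(vals) <- load_regions()
    list(fp = fp, vals = vals, ct = contact_time(tr, threshold))
  })
  load <- stats::setNames(numeric(12), variable_names_load())
  empty <- character()
  for (rg in load_regions()) {
    pp <- mean(vapply(per, function(p) p$vals[[rg]]$PP, 0))
    pti <- mean(vapply(per, function(p) p$vals[[rg]]$PTI, 0))
    ptin <- mean(vapply(per, function(p) p$vals[[rg]]$PTIN, 0))
    load[paste0(c("PP_", "PTI_", "PTIN_"), rg)] <- c(pp, pti, ptin)
    if (any(vapply(per, function(p) p$vals[[rg]]$empty, TRUE)))
      empty <- c(empty, rg)
  }
  avg_fp <- if (length(trials) >= 2)
    register_and_average(lapply(per, `[[`, "fp")) else per[[1]]$fp
  avg_mask <- plantar_angle_masks(avg_fp, fractions = fractions,
                                  toe_offset = toe_offset,
                                  anterior_frac = anterior_frac)
  list(load = load,
       func = c(CT = mean(vapply(per, `[[`, 0, "ct")),
                AI = arch_index(avg_fp, avg_mask)),
       footprint = avg_fp, mask = avg_mask, empty_regions = empty)
}
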