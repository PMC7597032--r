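# Small in-code fixtures shared across the suite.

# unit tetrahedron: 4 vertices, 4 faces
tetrahedron_mesh <- function(label = NA_character_) {
  triangle_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)),
    label)
}

# 12-facet unit cube with every corner repeated per facet (36 raw vertices)
cube_facets <- function() {
  cs <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  quads <- list(c(1, 2, 4, 3), c(5, 7, 8, 6), c(1, 5, 6, 2),
                c(3, 4, 8, 7), c(1, 3, 7, 5), c(2, 6, 8, 4))
  v <- NULL
  for (q in quads) {
    v <- rbind(v, cs[q[1], ], cs[q[2], ], cs[q[3], ],
               cs[q[1], ], cs[q[3], ], cs[q[4], ])
  }
  triangle_mesh(v, matrix(seq_len(36), ncol = 3, byrow = TRUE), "CUB")
}

# slab-like stand-ins for calcaneus / M2 with known plantar points; the M2
# slab's lowest vertex sits at its distal end
slab_cal_mesh <- function(plantar = c(0, 0, 1)) {
  base <- rbind(c(-10, -8, 5), c(10, -8, 6), c(10, 8, 5), c(-10, 8, 6),
                c(0, 0, 25), c(5, 3, 18))
  triangle_mesh(rbind(plantar, base),
                rbind(c(1, 2, 3), c(1, 3, 4), c(5, 6, 7), c(2, 4, 6)), "CAL")
}

slab_m2_mesh <- function(plantar = c(120, 0, 2)) {
  xs <- seq(80, 118, length.out = 8)
  shaft <- cbind(rep(xs, 2), rep(c(-3, 3), each = 8), rep(c(6, 7), 8))
  triangle_mesh(rbind(plantar, shaft),
                rbind(c(1, 2, 10), c(2, 3, 11), c(4, 12, 5), c(6, 14, 7),
                      c(8, 16, 9), c(1, 9, 17)), "M2")
}

# a rigid transform applied to every mesh in a list
pose_meshes <- function(meshes, R, t) {
  lapply(meshes, function(m)
    triangle_mesh(sweep(m$vertices %*% t(R), 2, t, "+"), m$faces, m$label))
}

rotation_about <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
}

# constant-pressure sequence over a rectangular patch
rect_sequence <- function(value = 100, nframes = 50, nr = 12, nc = 30,
                          rows = 2:11, cols = 2:29, dt = 10, pitch = 5) {
  fr <- matrix(0, nr, nc)
  fr[rows, cols] <- value
  pressure_sequence(array(rep(fr, nframes), c(nr, nc, nframes)),
                    pitch = pitch, dt = dt)
}

# hand-built region mask covering given cells of a grid
manual_mask <- function(nr, nc, region_cells, region = "MET24", pitch = 5,
                        s_toe = 1e6) {
  labels <- matrix("NONE", nr, nc)
  labels[region_cells] <- region
  structure(list(labels = labels, gamma = 25, axis = c(1, 0),
                 s_apex = 0, s_toe = s_toe, med_sign = 1, pitch = pitch),
            class = "region_mask")
}

# brute-force Pearson r / p from the definitional sums
brute_pearson <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  sx <- x - sum(x) / n
  sy <- y - sum(y) / n
  r <- sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2), n = n)
}

# brute-force pooled-variance two-sample t
brute_ttest <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tt, p = 2 * stats::pt(-abs(tt), nx + ny - 2), df = nx + ny - 2)
}
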