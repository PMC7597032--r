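to_rad <- function(d) d * pi / 180
angles_of <- function(u) footload:::axis_planar_angles(u)

test_that("absolute inclinations follow the planar decomposition", {
  # axis along the antero/posterior axis: in-plane angles zero; the frontal
  # projection of a pure antero/posterior axis is undefined
  ap <- angles_of(c(1, 0, 0))
  expect_equal(unname(ap[c("I3", "IL", "IT")]), c(0, 0, 0))
  expect_true(is.na(ap[["IF"]]))
  # in-plane 45 degree elevation
  a45 <- angles_of(c(cos(to_rad(45)), 0, sin(to_rad(45))))
  expect_equal(a45[["I3"]], 45)
  expect_equal(a45[["IL"]], 45)
  expect_equal(a45[["IT"]], 0)
  # mixed elevation/bearing, trigonometric oracle evaluated independently
  u <- c(cos(to_rad(20)) * cos(to_rad(10)),
         cos(to_rad(20)) * sin(to_rad(10)), sin(to_rad(20)))
  am <- angles_of(u)
  expect_equal(am[["I3"]], 20, tolerance = 1e-12)
  expect_equal(am[["IT"]], 10, tolerance = 1e-12)
  expect_equal(am[["IL"]],
               atan2(sin(to_rad(20)), cos(to_rad(20)) * cos(to_rad(10))) * 180 / pi,
               tolerance = 1e-12)
  expect_equal(am[["IL"]], 20.29, tolerance = 1e-2)
})

test_that("an axis orthogonal to a projection plane is flagged undefined", {
  a <- angles_of(c(0, 1, 0))   # pure medio-lateral axis
  expect_true(is.na(a[["IL"]]))
  expect_equal(a[["I3"]], 0)
  expect_equal(a[["IT"]], 90)
})

test_that("planar consistency: in-plane axes collapse I3 onto IL", {
  for (elev in c(-60, -15, 10, 35, 80)) {
    a <- angles_of(c(cos(to_rad(elev)), 0, sin(to_rad(elev))))
    expect_equal(a[["I3"]], a[["IL"]], tolerance = 1e-12)
    expect_equal(a[["I3"]], elev, tolerance = 1e-12)
  }
  # axis in the ground plane: I3 = 0 and IT carries the bearing
  for (bear in c(-40, 5, 25)) {
    a <- angles_of(c(cos(to_rad(bear)), sin(to_rad(bear)), 0))
    expect_equal(a[["I3"]], 0, tolerance = 1e-12)
    expect_equal(a[["IT"]], bear, tolerance = 1e-12)
  }
})

test_that("dorsal rotation about the ml axis monotonically raises I3 and IL", {
  elevs <- seq(-80, 85, by = 5)
  i3 <- sapply(elevs, function(e)
    angles_of(c(cos(to_rad(e)), 0.12, sin(to_rad(e))) /
                sqrt(1 + 0.12^2))[["I3"]])
  il <- sapply(elevs, function(e)
    angles_of(c(cos(to_rad(e)), 0.12, sin(to_rad(e))) /
                sqrt(1 + 0.12^2))[["IL"]])
  expect_true(all(diff(i3) > 0))
  expect_true(all(diff(il) > 0))
})

fake_frame <- function(u) {
  u <- u / sqrt(sum(u^2))
  structure(list(longitudinal_axis = u, centroid = c(0, 0, 0)),
            class = "bone_frame")
}

test_that("relative orientation composes as differences of inclinations", {
  same <- relative_orientation(fake_frame(c(1, 0, 0.2)),
                               fake_frame(c(1, 0, 0.2)))
  # R3 = acos(dot) picks up sqrt-of-eps noise at exactly parallel axes
  expect_equal(unname(same), c(0, 0, 0, 0), tolerance = 1e-5)
  # metatarsal at -20 deg, phalanx at +12 deg in the lateral plane
  met <- fake_frame(c(cos(to_rad(-20)), 0, sin(to_rad(-20))))
  pha <- fake_frame(c(cos(to_rad(12)), 0, sin(to_rad(12))))
  r <- relative_orientation(met, pha)
  expect_equal(r[["RL"]], 32, tolerance = 1e-12)
  expect_equal(r[["R3"]], 32, tolerance = 1e-12)
  orth <- relative_orientation(fake_frame(c(1, 0, 0)),
                               fake_frame(c(0, 0.6, 0.8)))
  expect_equal(orth[["R3"]], 90, tolerance = 1e-12)
})

test_that("planar relative angles negate on argument swap, R3 does not", {
  set.seed(21)
  for (i in 1:20) {
    a <- fake_frame(c(abs(rnorm(1, 1, 0.2)), rnorm(2, 0, 0.3)))
    b <- fake_frame(c(abs(rnorm(1, 1, 0.2)), rnorm(2, 0, 0.3)))
    ab <- relative_orientation(a, b)
    ba <- relative_orientation(b, a)
    expect_equal(ab[["R3"]], ba[["R3"]], tolerance = 1e-12)
    for (m in c("RL", "RF", "RT"))
      expect_equal(ab[[m]], -ba[[m]], tolerance = 1e-12)
  }
})

test_that("minimum heights clip at the ground and normalise by foot length", {
  m <- triangle_mesh(rbind(c(0, 0, 12.3), c(5, 0, 20), c(0, 5, 30), c(2, 2, 40)),
                     rbind(c(1, 2, 3)), "NAV")
  expect_equal(min_height(m), 12.3)
  sunk <- triangle_mesh(rbind(c(0, 0, -2), c(5, 0, 20), c(0, 5, 30)),
                        rbind(c(1, 2, 3)), "NAV")
  expect_equal(min_height(sunk), 0)
  # analytic ellipsoid tangent: centre z = 20, vertical semi-axis 5
  b <- make_bone_mesh(c(12, 8, 5), c(0, 0, 0), c(0, 0, 20), 500, "CUB")
  expect_equal(min_height(b), 15, tolerance = 1e-9)
  expect_equal(relative_height(15, 200), 0.075)
  expect_equal(relative_height(0, 200), 0)
  expect_error(relative_height(10, 0), "positive")
})

test_that("the assembled vector has exactly 84 entries in canonical order", {
  foot <- make_foot(default_foot_spec(n_vertices = 300), seed = 2)
  v <- foot_3d_variables(foot$meshes)
  expect_length(v, 84L)
  expect_identical(names(v), variable_names_3d())
  measures <- sub("_.*", "", names(v))
  expect_equal(sum(measures %in% c("I3", "IL", "IF", "IT", "R3", "RL", "RF", "RT")),
               60L)
  expect_equal(sum(measures %in% c("Hg", "HgR")), 24L)
  fb_heights <- grepl("^Hg[R]?_(M|P)[1-5]$", names(v))
  expect_equal(sum(fb_heights), 20L)
  # bit-identical on re-run from the same meshes
  expect_identical(as.numeric(v), as.numeric(foot_3d_variables(foot$meshes)))
})

test_that("a missing required bone is reported by name", {
  foot <- make_foot(default_foot_spec(n_vertices = 300), seed = 2)
  broken <- foot$meshes[setdiff(names(foot$meshes), "P4")]
  expect_error(foot_3d_variables(broken), "P4 required")
  angles <- list(); heights <- list()
  expect_error(assemble_3d_variables(angles, heights), "M1 required")
})
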