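test_that("bone generator refuses degenerate ellipsoids and plants exact poses", {
  expect_error(make_bone_mesh(c(10, 10, 10)), "descending")
  expect_error(make_bone_mesh(c(10, 12, 5)), "descending")
  b <- make_bone_mesh(c(30, 10, 5), c(0, 0, 0), c(5, -3, 40), 600, "M1")
  tr <- attr(b, "truth")
  # analytic lowest point is an actual mesh vertex
  expect_equal(min(b$vertices[, 3]), tr$min_z, tolerance = 1e-12)
  expect_equal(tr$min_z, 35)
  f <- pca_bone_frame(b)
  expect_lt(max(abs(f$longitudinal_axis - c(1, 0, 0))), 1e-9)
  # planted 30 degree lateral-plane rotation recovered to < 0.1 deg
  b30 <- make_bone_mesh(c(30, 10, 5), c(0, -30, 0), c(0, 0, 40), 600, "M1")
  f30 <- pca_bone_frame(b30)
  il <- atan2(f30$longitudinal_axis[3], f30$longitudinal_axis[1]) * 180 / pi
  expect_lt(abs(il - 30), 0.1)
  # every face references valid vertices after tangent-point insertion
  expect_true(all(b$faces >= 1 & b$faces <= nrow(b$vertices)))
})

test_that("foot generator is seed-deterministic and errors below ground", {
  f1 <- make_foot(default_foot_spec(n_vertices = 300), seed = 12)
  f2 <- make_foot(default_foot_spec(n_vertices = 300), seed = 12)
  expect_identical(f1$meshes$M3$vertices, f2$meshes$M3$vertices)
  expect_identical(f1$truth, f2$truth)
  f3 <- make_foot(default_foot_spec(n_vertices = 300), seed = 13)
  expect_false(identical(f1$meshes$M3$vertices, f3$meshes$M3$vertices))
  expect_length(f1$truth, 84L)
  expect_identical(rownames(f1$markers), c("CAL", "M1", "M2", "M5", "HLX"))
  spec <- default_foot_spec(n_vertices = 300, angle_jitter_sd = 0,
                            centre_jitter_sd = 0)
  spec$min_clearance <- -50
  spec$bones$NAV$plantar_z <- -30
  expect_error(make_foot(spec, seed = 1), "below the ground")
})

test_that("a planted P2 inclination is recovered by the pipeline", {
  spec <- default_foot_spec(n_vertices = 500, angle_jitter_sd = 0,
                            centre_jitter_sd = 0)
  spec$bones$P2$rotation <- c(0, -15, 0)   # I3 = +15 degrees
  foot <- make_foot(spec, seed = 1)
  v <- foot_3d_variables(foot$meshes)
  expect_equal(unname(v["I3_P2"]), 15, tolerance = 0.1)
  expect_equal(unname(foot$truth["I3_P2"]), 15, tolerance = 1e-9)
})

test_that("pressure generator plants exact PP and CT and half-sine PTI", {
  spec <- default_gait_spec(trans_sd = 0, rot_sd = 0, amp_cv = 0)
  g <- make_pressure_trials(spec, seed = 1)
  tr1 <- g$trials[[1]]
  fp <- peak_pressure_image(tr1)
  msk <- plantar_angle_masks(fp)
  for (rg in c("HLX", "MET1", "MET24", "MET5")) {
    m <- regional_metrics(tr1, msk, rg)
    expect_equal(m$PP, unname(g$truth$PP[rg]))     # planted amplitude, exact
    expect_lt(abs(m$PTI - g$truth$PTI[[rg]]) / g$truth$PTI[[rg]], 0.1)
  }
  # the central-metatarsal half-sine integral matches 2AT/pi within 2%
  m24 <- regional_metrics(tr1, msk, "MET24")
  expect_lt(abs(m24$PTI - g$truth$PTI[["MET24"]]) / g$truth$PTI[["MET24"]],
            0.02)
  expect_equal(contact_time(tr1), g$truth$CT)      # 680 ms, exact
  # determinism and jitter structure
  g2 <- make_pressure_trials(spec, seed = 1)
  expect_identical(g$trials[[3]]$frames, g2$trials[[3]]$frames)
  gj <- make_pressure_trials(default_gait_spec(), seed = 9)
  expect_length(gj$trials, 5L)
  expect_false(identical(gj$trials[[1]]$frames, gj$trials[[2]]$frames))
})

test_that("cohort generator plants exact and calibrated correlations", {
  # zero-noise link: estimated r2 is exactly 1
  spec1 <- default_cohort_spec(links = list(list(var3d = "I3_P2",
                                                 load = "PTI_MET24",
                                                 slope = 2, r2 = 1)))
  co1 <- make_cohort(spec1, seed = 8)
  est <- pearson_r2(co1$table$I3_P2, co1$table$PTI_MET24)
  expect_equal(est$r2, 1, tolerance = 1e-9)
  # infeasible targets are refused
  bad <- default_cohort_spec(links = list(list(var3d = "I3_P2",
                                               load = "PTI_MET24",
                                               slope = 2, r2 = 1.2)))
  expect_error(make_cohort(bad, seed = 1), "infeasible")
  # group labels are consistent with the two-of-three rule
  co <- make_cohort(seed = 9)
  regroup <- vapply(co$records, classify_group, "")
  expect_identical(unname(regroup), co$table$group)
  expect_equal(as.integer(table(co$table$group)[c("N", "D", "LADA")]),
               c(7L, 8L, 1L))
  # determinism
  co2 <- make_cohort(seed = 9)
  expect_identical(co$table, co2$table)
})

test_that("planted population R2 is recovered on average across replicates", {
  spec <- default_cohort_spec(n = c(N = 200),
                              links = list(list(var3d = "I3_P2",
                                                load = "PTI_MET24",
                                                slope = 2, r2 = 0.77)))
  est <- vapply(1:40, function(s)
    pearson_r2(make_cohort(spec, seed = s)$table$I3_P2,
               make_cohort(spec, seed = s)$table$PTI_MET24)$r2, 0)
  expect_lt(abs(mean(est) - 0.77), 0.02)
  expect_gte(mean(abs(est - 0.77) <= 0.05), 0.85)
})
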