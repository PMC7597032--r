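test_that("peak image is the per-sensor maximum over frames", {
  fr <- array(0, c(4, 5, 2))
  fr[2, 2, ] <- c(50, 80)
  fr[3, 4, ] <- c(100, 100)
  fp <- peak_pressure_image(pressure_sequence(fr))
  expect_equal(fp$peak_image[2, 2], 80)
  expect_equal(fp$peak_image[3, 4], 100)
  expect_equal(sum(fp$contact_mask), 2L)
  expect_error(peak_pressure_image(pressure_sequence(array(0, c(3, 3, 2)))),
               "empty footprint")
  expect_error(pressure_sequence(array(2000, c(2, 2, 1))), "range")
})

test_that("contact time counts frames above threshold", {
  seq68 <- rect_sequence(100, nframes = 68)
  expect_equal(contact_time(seq68), 680)
  expect_equal(contact_time(pressure_sequence(array(1, c(3, 3, 10)))), 0)
  # ramp: 50 of 80 frames above threshold, counted brute force
  amp <- seq_len(80)
  fr <- array(0, c(2, 2, 80))
  fr[1, 1, ] <- amp
  expect_equal(contact_time(pressure_sequence(fr), threshold = 30),
               sum(amp > 30) * 10)
  expect_equal(contact_time(pressure_sequence(fr), threshold = 30), 500)
})

test_that("regional metrics have their closed forms", {
  cells <- cbind(rep(3:6, each = 4), rep(3:6, 4))
  msk <- manual_mask(12, 30, cells)
  # constant 100 kPa for 0.5 s: PP 100, PTI 50, PTI_N 100
  m <- regional_metrics(rect_sequence(100, nframes = 50, rows = 3:6, cols = 3:6),
                        msk, "MET24")
  expect_equal(m$PP, 100)
  expect_equal(m$PTI, 50)
  expect_equal(m$PTIN, 100)
  expect_false(m$empty)
  # a single 10 ms frame at 200 kPa
  one <- regional_metrics(rect_sequence(200, nframes = 1, rows = 3:6, cols = 3:6),
                          msk, "MET24")
  expect_equal(one$PP, 200)
  expect_equal(one$PTI, 2)
  # region with no contact: zeros and a flag
  far <- manual_mask(12, 30, cbind(1, 30), region = "MET5")
  e <- regional_metrics(rect_sequence(100, rows = 3:6, cols = 3:6), far, "MET5")
  expect_true(e$empty)
  expect_equal(c(e$PP, e$PTI, e$PTIN), c(0, 0, 0))
  expect_error(regional_metrics(rect_sequence(100), msk, "HLX"), "not present")
})

test_that("PTI is bounded by PP times contact time", {
  set.seed(31)
  cells <- cbind(rep(2:9, each = 6), rep(4:9, 8))
  msk <- manual_mask(12, 30, cells)
  for (i in 1:10) {
    fr <- array(runif(12 * 30 * 40, 0, 400), c(12, 30, 40))
    sq <- pressure_sequence(fr)
    m <- regional_metrics(sq, msk, "MET24")
    expect_gte(m$PTI, 0)
    expect_lte(m$PTI, m$PP * contact_time(sq) / 1000 + 1e-9)
    expect_lte(m$PTIN, m$PP + 1e-9)
  }
})

test_that("the plantar-angle fan splits gamma 30/51/19 and tiles the forefoot", {
  g <- make_pressure_trials(default_gait_spec(trans_sd = 0, rot_sd = 0,
                                              amp_cv = 0), seed = 1)
  fp <- peak_pressure_image(g$trials[[1]])
  msk <- plantar_angle_masks(fp)
  span1 <- abs(msk$alpha_med - msk$boundary1)
  span2 <- abs(msk$boundary1 - msk$boundary2)
  span3 <- abs(msk$boundary2 - msk$alpha_lat)
  expect_equal(span1 + span2 + span3, msk$gamma, tolerance = 1e-9)
  expect_equal(c(span1, span2, span3) / msk$gamma, c(0.30, 0.51, 0.19),
               tolerance = 1e-9)
  expect_gt(msk$gamma, 0)
  # metatarsal sectors are disjoint by construction and non-trivial
  tabs <- table(msk$labels)
  expect_true(all(c("MET1", "MET24", "MET5", "HLX", "MIDFOOT", "HINDFOOT")
                  %in% names(tabs)))
  # custom fractions are honoured
  msk2 <- plantar_angle_masks(fp, fractions = c(0.25, 0.50, 0.25))
  expect_equal(abs(msk2$alpha_med - msk2$boundary1) / msk2$gamma, 0.25,
               tolerance = 1e-9)
  expect_error(plantar_angle_masks(fp, fractions = c(0.5, 0.6, -0.1)),
               "fractions")
})

test_that("pipeline region labels agree with the generator's ground truth", {
  g <- make_pressure_trials(default_gait_spec(trans_sd = 0, rot_sd = 0,
                                              amp_cv = 0), seed = 1)
  fp <- peak_pressure_image(g$trials[[1]])
  msk <- plantar_angle_masks(fp)
  expect_gte(mean(msk$labels == g$truth$labels), 0.95)
  expect_equal(msk$gamma, g$truth$gamma, tolerance = 1)
})

test_that("registration recovers planted translations and rotations", {
  # five identical trials: the average equals any single footprint
  g0 <- make_pressure_trials(default_gait_spec(trans_sd = 0, rot_sd = 0,
                                               amp_cv = 0), seed = 4)
  fps <- lapply(g0$trials, peak_pressure_image)
  avg <- register_and_average(fps)
  expect_equal(avg$peak_image, fps[[1]]$peak_image, tolerance = 1e-9)
  # planted rigid jitter is recovered within a sensor pitch / 2 degrees
  gj <- make_pressure_trials(default_gait_spec(trans_sd = 4, rot_sd = 5,
                                               amp_cv = 0), seed = 8)
  fpj <- lapply(gj$trials, peak_pressure_image)
  avj <- register_and_average(fpj)
  tf <- attr(avj, "transforms")
  jt <- gj$truth$jitter
  for (i in 2:5) {
    # transform maps trial i onto trial 1: difference of planted jitters
    expect_lt(abs(tf[[i]]["dtheta"] - (jt[[1]]["dtheta"] - jt[[i]]["dtheta"])),
              2)
    planted_shift <- jt[[1]][c("dx", "dy")] - jt[[i]][c("dx", "dy")]
    expect_lt(max(abs(tf[[i]][c("dx", "dy")] - planted_shift)), 5 + 2)
  }
})

test_that("arch index is exact on constructed footprints", {
  # solid rectangle, length divisible by three: equal thirds
  sq <- rect_sequence(100, nframes = 5, nr = 12, nc = 32, rows = 3:10,
                      cols = 2:31)
  fp <- peak_pressure_image(sq)
  msk <- manual_mask(12, 32, cbind(1, 1))
  expect_equal(arch_index(fp, msk), 1 / 3)
  # middle third fully lifted: no midfoot contact
  fr <- array(0, c(12, 32, 5))
  fr[3:10, 2:11, ] <- 100
  fr[3:10, 22:31, ] <- 100
  fp0 <- peak_pressure_image(pressure_sequence(fr))
  expect_equal(arch_index(fp0, msk), 0)
  # toe line excludes anterior contact from the computation
  msk_toe <- manual_mask(12, 32, cbind(1, 1), s_toe = 107.5)
  expect_error(arch_index(fp0, manual_mask(12, 32, cbind(1, 1), s_toe = -1)),
               "empty toe-free")
  expect_gte(arch_index(fp, msk_toe), 0)
})

test_that("five identical trials average to the single-trial LOAD values", {
  g <- make_pressure_trials(default_gait_spec(trans_sd = 0, rot_sd = 0,
                                              amp_cv = 0), seed = 2)
  res <- analyze_pressure_trials(g$trials)
  one <- analyze_pressure_trials(g$trials[1])
  expect_equal(res$load, one$load, tolerance = 1e-12)
  expect_length(res$load, 12L)
  expect_identical(names(res$load), variable_names_load())
  expect_equal(unname(res$func["CT"]), 680)
})

test_that("pressure trials survive the CSV + JSON round trip", {
  g <- make_pressure_trials(default_gait_spec(n_trials = 1), seed = 6)
  prefix <- file.path(tempdir(), "trial1")
  write_pressure_trial(g$trials[[1]], prefix)
  back <- read_pressure_trial(prefix)
  expect_equal(back$frames, g$trials[[1]]$frames)
  expect_equal(back$markers, g$trials[[1]]$markers)
  expect_equal(back$dt, g$trials[[1]]$dt)
})
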