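test_that("zero-phase Butterworth has unit DC gain and the analytic cutoff gain", {
  x <- rep(3.7, 400)
  expect_lt(max(abs(butterworth_lowpass(x, 6, rate = 100) - 3.7)), 1e-9)

  tt <- (0:1999) / 100
  core <- 301:1700   # discard edges
  s6 <- sin(2 * pi * 6 * tt)
  y6 <- butterworth_lowpass(s6, 6, rate = 100)
  gain6 <- max(abs(y6[core])) / 1
  expect_lt(abs(gain6 - 0.5), 0.025)   # two-pass |H|^2 = 1/2 at cutoff

  s05 <- sin(2 * pi * 0.5 * tt)
  y05 <- butterworth_lowpass(s05, 6, rate = 100)
  expect_lt(abs(max(abs(y05[core])) - 1), 0.01)

  expect_error(butterworth_lowpass(rnorm(5), 6, rate = 100), "short")
  expect_error(butterworth_lowpass(rnorm(100), 60, rate = 100), "cutoff")
})

test_that("linear resampling is exact on lines and bounded on smooth signals", {
  t48 <- (0:95) / 48
  ramp <- 2 + 3 * t48
  r <- resample_linear(ramp, t48, target_hz = 100)
  expect_equal(r$values, 2 + 3 * r$time, tolerance = 1e-12)

  cst <- resample_linear(rep(5, 50), 48, target_hz = 100)
  expect_true(all(cst$values == 5))

  s <- sin(2 * pi * 1 * t48)
  rs <- resample_linear(s, t48, target_hz = 100)
  bound <- (2 * pi)^2 * (1 / 48)^2 / 8   # f''max dt^2 / 8
  expect_lt(max(abs(rs$values - sin(2 * pi * rs$time))), bound + 1e-12)

  expect_error(resample_linear(numeric(0), 48), "2 samples")
})

test_that("pulse synchronization recovers injected stream offsets", {
  ## constructed streams with offsets across +/- 2 s; the underlying signal
  ## is a known function of global time, so the post-sync residual is
  ## measured through signal alignment
  for (off in c(-2, -0.73, 0, 0.31, 1.9)) {
    tm <- (0:799) / 100
    sig <- function(gt) sin(2 * pi * 0.8 * gt)
    edge_m <- 2.5                      # physical pulse instant (marker clock)
    markers <- list(time = tm, rate = 100, pulse = as.numeric(tm >= edge_m),
                    data = list())
    ## the force device's clock starts `off` later/earlier; the pulse falls
    ## on its sample k_e
    k_e <- max(1L, round((edge_m - off) * 48))
    ts_f <- edge_m - k_e / 48          # realized clock offset
    tf <- (0:499) / 48
    force <- list(time = tf, pulse = as.numeric(seq_along(tf) - 1 >= k_e),
                  lateral = sig(ts_f + tf))
    out <- synchronize(markers, force)
    expect_equal(out$offset, ts_f, tolerance = 1e-9)
    core <- tm > max(0.2, ts_f + 0.2) & tm < min(7.8, ts_f + 499 / 48 - 0.2)
    resid <- out$force$lateral[core] - sig(tm[core])
    ## residual misalignment under 1 marker frame (10 ms): bound by the
    ## signal's maximum slope x 10 ms
    expect_lt(max(abs(resid)), 2 * pi * 0.8 * 0.010 + 1e-6)
  }
})

test_that("synchronization errors on absent or multiple pulses", {
  tm <- (0:99) / 100
  m <- list(time = tm, pulse = rep(0, 100), data = list())
  f <- list(time = (0:47) / 48, pulse = c(rep(0, 10), rep(1, 38)),
            lateral = rnorm(48))
  expect_error(synchronize(m, f), "no rising pulse edge in marker")
  m$pulse <- c(rep(0, 10), rep(1, 20), rep(0, 20), rep(1, 50))
  expect_error(synchronize(m, f), "multiple rising pulse edges")
})

test_that("rigid-body gap fill reproduces noise-free rigid motion", {
  tr <- simulate_trial(fx_subject(),
                       technique_grid()[technique_grid()$id == "g1.5_a70_neutral", ],
                       n_reps = 1, noise = list(marker_sd = 0), seed = 5)
  g <- inject_marker_gaps(tr, list(list(marker = "ACL2", start = 200,
                                        length = 8)))
  truth <- tr$markers$data$ACL2[200:207, ]
  out <- fill_gaps_spline(g$markers, max_gap_frames = 10)
  expect_false(out$excluded)
  expect_equal(out$audit$method, "rigid")
  expect_lt(max(abs(out$markers$data$ACL2[200:207, ] - truth)), 1e-6)

  ## no gaps: identity
  out2 <- fill_gaps_spline(tr$markers, max_gap_frames = 10)
  expect_identical(out2$markers$data, tr$markers$data)

  ## isolated marker, gap beyond the limit: exclusion flag
  g3 <- inject_marker_gaps(tr, list(list(marker = "RLWR", start = 150,
                                         length = 11)))
  out3 <- fill_gaps_spline(g3$markers, max_gap_frames = 10)
  expect_true(out3$excluded)
  expect_match(out3$reason, "RLWR")

  ## spline fill of a short gap on an isolated marker is close on smooth motion
  g4 <- inject_marker_gaps(tr, list(list(marker = "RLWR", start = 150,
                                         length = 5)))
  out4 <- fill_gaps_spline(g4$markers, max_gap_frames = 10)
  expect_false(out4$excluded)
  expect_lt(max(abs(out4$markers$data$RLWR[150:154, ] -
                      tr$markers$data$RLWR[150:154, ])), 1e-3)
})

test_that("scapula reconstruction is exact on linear calibration data", {
  calib <- list(height_fraction = c(1, 0.5, 0),
                offsets = list(AA = rbind(c(0.11, 0.02, 0.03),
                                          c(0.10, 0.025, 0.02),
                                          c(0.09, 0.03, 0.01))))
  pose <- list(list(origin = c(0, 0, 0), R = diag(3)),
               list(origin = c(1, 2, 3), R = rot_z_test(0.4)))
  out <- reconstruct_scapula(calib, pose, c(0.25, 0.25))
  line_at <- c(0.09, 0.03, 0.01) + 0.25 * (c(0.11, 0.02, 0.03) - c(0.09, 0.03, 0.01))
  expect_equal(out$AA[1, ], line_at, tolerance = 1e-12)
  expect_equal(out$AA[2, ], c(1, 2, 3) + as.vector(rot_z_test(0.4) %*% line_at),
               tolerance = 1e-12)

  ## zero slope: constant offset at any height
  calib$offsets$AA <- rbind(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  out2 <- reconstruct_scapula(calib, pose[1], 0.77)
  expect_equal(out2$AA[1, ], c(0.1, 0.2, 0.3), tolerance = 1e-12)

  calib$height_fraction <- c(1, 0.5)
  expect_error(reconstruct_scapula(calib, pose, 0.5), "height levels")
})

test_that("noisy calibration slopes are recovered within Monte-Carlo error", {
  slope <- c(0.02, -0.01, 0.015)
  errs <- replicate(20, {
    cal <- generate_scapula_calibration(fx_subject(), seed = sample.int(1e6, 1),
                                        noise_sd = 0.002, slope = slope)
    O <- cal$neutral$offsets$AA
    fit <- coef(lm(O ~ c(1, 0.5, 0)))[2, ]
    fit - slope
  })
  ## regression SE with 3 points at h = {0,.5,1} and sd = 2 mm
  se <- 0.002 / sqrt(0.5)
  expect_lt(max(abs(rowMeans(errs))), 3 * se / sqrt(20))
})

test_that("hand-force assembly uses the barbell gravity share per hand", {
  hf <- assemble_hand_force(rep(0, 10), barbell_mass = 16)
  expect_equal(hf$vertical, 78.48)
  expect_true(all(hf$force_on_hand[, 1] == 0))
  expect_true(all(hf$force_on_hand[, 2] == -78.48))
  expect_true(all(hf$force_on_hand[, 3] == 0))

  hf45 <- assemble_hand_force(rep(78.48, 4), barbell_mass = 16)
  ang <- atan2(abs(hf45$force_on_hand[1, 1]), abs(hf45$force_on_hand[1, 2]))
  expect_equal(unname(ang), pi / 4, tolerance = 1e-12)

  bend <- data.frame(grip_width = c(0.3, 0.5, 0.8), offset_n = c(1, 2, 4))
  hfb <- assemble_hand_force(rep(10, 3), 16, grip_width = 0.5,
                             bending_calibration = bend)
  expect_equal(unique(hfb$exerted_lateral), 8)
  expect_warning(assemble_hand_force(rep(10, 3), 16, grip_width = 1.2,
                                     bending_calibration = bend),
                 "nearest")
  expect_error(assemble_hand_force(rep(0, 3), barbell_mass = -1), "barbell_mass")
})

test_that("cycle segmentation puts the lowest point at exactly 50%", {
  ## symmetric triangle
  h <- c(seq(1, 0, length.out = 51), seq(0, 1, length.out = 51)[-1])
  p <- segment_cycles(h, prominence = 0.5)
  expect_equal(nrow(p$reps), 1)
  expect_equal(p$phase[p$reps$bottom], 50)
  expect_equal(p$phase[p$reps$start], 0)
  expect_equal(p$phase[p$reps$end], 100)
  expect_true(all(diff(p$phase[p$reps$start:p$reps$end]) > 0))

  ## asymmetric tempo: descent 1 s, ascent 3 s; bottom still at 50%
  h2 <- c(seq(1, 0, length.out = 101), seq(0, 1, length.out = 301)[-1])
  p2 <- segment_cycles(h2, prominence = 0.5)
  expect_equal(p2$phase[p2$reps$bottom], 50)
  expect_equal(sum(p2$phase <= 50, na.rm = TRUE), 101)

  ## three repetitions
  one <- c(seq(1, 0, length.out = 51), seq(0, 1, length.out = 51)[-1])
  h3 <- c(one, one[-1], one[-1])
  p3 <- segment_cycles(h3, prominence = 0.5)
  expect_equal(nrow(p3$reps), 3)

  expect_error(segment_cycles(rep(1, 100) + 0.001 * sin(1:100),
                              prominence = 0.05), "prominence")
})

test_that("joint centers are marker midpoints with a scapula-frame GH offset", {
  n <- 3
  mk <- list(time = (0:2) / 100, data = list(
    RLEL = matrix(rep(c(0, 0, 0), each = n), n),
    RMEL = matrix(rep(c(0, 0.06, 0), each = n), n),
    RLWR = matrix(rep(c(1, 1, 1), each = n), n),
    RMWR = matrix(rep(c(1, 1, 2), each = n), n)))
  jc <- compute_joint_centers(mk)
  expect_equal(jc$elbow[1, ], c(0, 0.03, 0))
  expect_equal(jc$wrist[1, ], c(1, 1, 1.5))

  ## GH center from reconstructed landmarks matches forward kinematics
  model <- fx_model()
  q <- posture_vector(model, model$reference_posture)
  fr <- forward_kinematics(model, q)
  mk2 <- fx_clean_trial()$markers
  jc2 <- compute_joint_centers(mk2, model = model)
  i <- 400
  qtrue <- fx_raw_trial()$ground_truth$q[i, ]
  fr_i <- forward_kinematics(model, qtrue)
  gh_true <- fk_point(fr_i, "scapula", model$segments$scapula$points$gh_center)
  expect_lt(vnorm(jc2$gh[i, ] - gh_true), 1e-9)

  expect_error(compute_joint_centers(list(data = list())), "missing markers")
})

test_that("preprocessing emits a synchronized, gap-free clean trial", {
  ct <- fx_clean_trial()
  expect_false(ct$excluded)
  expect_s3_class(ct, "clean_trial")
  expect_equal(nrow(ct$partition$reps), 2)
  expect_equal(ct$sync_offset, fx_raw_trial()$ground_truth$stream_offset,
               tolerance = 1e-9)
  expect_true(all(c("AA", "TS", "AI") %in% names(ct$markers$data)))
})
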