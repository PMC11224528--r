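test_that("the activation QP matches closed-form solutions", {
  ## single muscle, single DOF: a = M / (r Fmax)
  A <- matrix(10, 1, 1)   # r * Fmax
  s <- solve_activation_qp(A, 6, lb = 0, ub = 1)
  expect_true(s$feasible)
  expect_equal(s$a, 0.6, tolerance = 1e-8)

  ## zero moments, no passive: all activations zero
  A2 <- matrix(c(10, 12, -4, 3), 2, 2)
  s0 <- solve_activation_qp(A2, c(0, 0), lb = rep(0, 2), ub = rep(1, 2))
  expect_equal(max(abs(s0$a)), 0, tolerance = 1e-10)

  ## two muscles, one DOF, interior optimum: least-norm a_i = M r_i F_i / sum (r_j F_j)^2
  A3 <- matrix(c(10, 12), 1, 2)
  s3 <- solve_activation_qp(A3, 6, lb = rep(0, 2), ub = rep(1, 2))
  expect_equal(s3$a, 6 * c(10, 12) / (10^2 + 12^2), tolerance = 1e-8)

  ## infeasible demand: flagged, minimum-violation fallback returned
  s4 <- solve_activation_qp(matrix(c(1, 1), 1, 2), 5, lb = rep(0, 2),
                            ub = rep(1, 2))
  expect_false(s4$feasible)
  expect_true(s4$fallback)
  expect_equal(s4$a, c(1, 1), tolerance = 1e-6)
})

test_that("solver optimum matches exhaustive grid search on 3-muscle toys", {
  ## 2 DOF x 3 muscles, no cone: 1-D feasible manifold enumerated at 1e-3
  A <- matrix(c(8, 1,
                2, 6,
                5, 4), 2, 3)
  b <- c(4, 3)
  s <- solve_activation_qp(A, b, lb = rep(0, 3), ub = rep(1, 3))
  o <- grid_search_oracle(A, b, step = 1e-3)
  expect_true(s$feasible)
  expect_lt(max(abs(s$a - o$a)), 1e-3)
  expect_lt(abs(s$objective - o$objective), 1e-4)

  ## with an active stability cone: muscles 1-2 carry the moments, muscle 3
  ## is a pure stabilizer (zero moment arms, pure compression); the effort
  ## optimum violates the cone so the stabilizer must be recruited until
  ## the reaction sits exactly on the cone boundary
  cone <- list(G = matrix(c(1, 0.5, 8,
                            -2, -3, 0,
                            0.5, 1, 0), 3, 3, byrow = TRUE),
               r0 = c(0.5, -1, 0.2), tan_ap = 0.5, tan_si = 0.6,
               n_facets = 720)
  A5 <- matrix(c(6, 0.5,
                 1, 5,
                 0, 0), 2, 3)
  b5 <- c(3, 2)
  free <- solve_activation_qp(A5, b5, lb = rep(0, 3), ub = rep(1, 3))
  rfree <- cone$r0 + as.vector(cone$G %*% free$a)
  lhs <- sqrt((rfree[2] / cone$tan_ap)^2 + (rfree[3] / cone$tan_si)^2)
  expect_gt(lhs, rfree[1])   # unconstrained optimum outside the cone

  s5 <- solve_activation_qp(A5, b5, lb = rep(0, 3), ub = rep(1, 3),
                            cone = cone)
  o5 <- grid_search_oracle(A5, b5, cone = cone, step = 1e-3)
  expect_true(s5$feasible)
  expect_lt(max(abs(s5$a - o5$a)), 2e-3)
  expect_lt(abs(s5$objective - o5$objective), 1e-4)
  expect_gt(s5$objective, free$objective)

  ## the cone is active at the optimum: theta = theta_max (elliptical
  ## membership holds with equality)
  r <- cone$r0 + as.vector(cone$G %*% s5$a)
  expect_equal(sqrt((r[2] / cone$tan_ap)^2 + (r[3] / cone$tan_si)^2) / r[1],
               1, tolerance = 1e-3)

  ## relaxation monotonicity: removing the cone never increases the optimum
  expect_lte(free$objective, s5$objective + 1e-9)
})

test_that("frame solutions satisfy bounds, balance and the cone", {
  model <- fx_model()
  pos <- fx_posture(stride = 10)
  hf <- fx_clean_trial()$force
  Fh <- hf$force_on_hand[pos$sample_index, ]
  M <- inverse_dynamics(model, pos, hf)
  for (i in c(15, 44, 70)) {
    fs <- solve_frame(model, pos$q[i, ], M[i, ], Fh[i, ])
    expect_true(all(fs$a >= -1e-9 & fs$a <= 1 + 1e-9))
    if (fs$feasible) {
      expect_lt(fs$residual, 1e-6 * (1 + max(abs(M[i, ]))) + 1e-9)
      ## facet approximation of the elliptical cone: admissible overshoot
      ## is O((pi / n_facets)^2)
      expect_lte(fs$theta, fs$theta_max_dir + 1e-3)
    }
  }
})

test_that("a held posture yields constant activations over time", {
  model <- fx_model()
  q <- posture_vector(model, model$reference_posture)
  Q <- matrix(rep(q, 20), 20, byrow = TRUE, dimnames = list(NULL, names(q)))
  pos <- make_posture_series(Q, (0:19) / 10)
  Fh <- matrix(rep(c(-23.5, -78.48, 0), each = 20), 20)
  sol <- rmr_solve(model, pos, Fh)
  expect_true(all(sol$feasible))
  spread <- apply(sol$activations, 2, function(a) diff(range(a)))
  expect_lt(max(spread), 1e-6)
})

test_that("tight rate bounds cap the frame-to-frame activation step", {
  model <- fx_model()
  pos <- fx_posture(stride = 10)
  hf <- fx_clean_trial()$force
  slow <- rmr_solve(model, pos, hf,
                    options = list(max_infeasible = 1))
  dt <- diff(pos$time)[1]
  tau <- model$activation_dynamics
  ## defaults: rise limited by dt/tau_act, fall by dt/tau_deact
  steps <- diff(slow$activations)
  expect_lte(max(steps), dt / tau$tau_act + 1e-9)
  expect_gte(min(steps), -dt / tau$tau_deact - 1e-9)

  ## make the deactivation bound 50x tighter and check it binds exactly
  m2 <- model
  m2$activation_dynamics$tau_act <- tau$tau_act * 50
  m2$activation_dynamics$tau_deact <- tau$tau_deact * 50
  tight <- rmr_solve(m2, pos, hf, options = list(max_infeasible = 1))
  st <- diff(tight$activations)
  expect_lte(max(st), dt / (tau$tau_act * 50) + 1e-9)
  expect_gte(min(st), -dt / (tau$tau_deact * 50) - 1e-9)
  expect_gt(max(abs(st)), 0.5 * dt / (tau$tau_deact * 50)) # bound active
})

test_that("joint reactions equal an independent free-body summation", {
  model <- fx_model()
  set.seed(7)
  q0 <- posture_vector(model, model$reference_posture)
  for (r in 1:5) {
    q <- pmin(pmax(q0 + rnorm(model$nq, 0, 0.2), model$dof_table$lo),
              model$dof_table$hi)
    a <- runif(length(model$muscles))
    names(a) <- names(model$muscles)
    Fh <- rnorm(3, 0, 50)
    jr <- joint_reaction(model, q, a, Fh)

    ## independent free-body oracle written from scratch on path points
    fr <- forward_kinematics(model, q)
    geo <- muscle_geometry(model, q)
    for (jn in c("gh", "ac")) {
      fb <- if (jn == "gh") c("humerus", "forearm") else
        c("scapula", "humerus", "forearm")
      tot <- Fh
      for (sn in fb)

        tot <- tot + c(0, -model$segments[[sn]]$mass * 9.81, 0)
      for (mi in seq_along(model$muscles)) {
        mu <- model$muscles[[mi]]
        tension <- a[mi] * mu$fmax +
          passive_force(mu, geo$lnorm[mi], model$passive$k1, model$passive$k2)
        P <- t(vapply(mu$path, function(pp)
          fk_point(fr, pp$segment, pp$point), numeric(3)))
        segs <- vapply(mu$path, `[[`, character(1), "segment")
        for (k in seq_len(nrow(P))) {
          if (!(segs[k] %in% fb)) next
          if (k > 1 && !(segs[k - 1] %in% fb)) {
            tot <- tot + tension * (P[k - 1, ] - P[k, ]) / vnorm(P[k - 1, ] - P[k, ])
          }
          if (k < nrow(P) && !(segs[k + 1] %in% fb)) {
            tot <- tot + tension * (P[k + 1, ] - P[k, ]) / vnorm(P[k + 1, ] - P[k, ])
          }
        }
      }
      expect_lt(vnorm(jr[[jn]]$force - tot) / (1 + vnorm(tot)), 1e-9)
      expect_equal(jr[[jn]]$total, vnorm(tot), tolerance = 1e-9)
    }
  }
})

test_that("the reaction decomposition is an isometry with the stated signs", {
  B <- diag(3)
  d <- decompose_jrf(c(5, 0, 0), B)
  expect_equal(d$compression, 5)
  expect_equal(d$shear_ap, 0)
  expect_equal(d$shear_si, 0)

  d2 <- decompose_jrf(c(0, 3, -4), B)
  expect_equal(d2$compression, 0)
  expect_equal(d2$total, 5)

  set.seed(3)
  for (r in 1:50) {
    v <- rnorm(3, 0, 100)
    a <- rnorm(3); a <- a / vnorm(a)
    b <- rnorm(3); b <- b - sum(a * b) * a; b <- b / vnorm(b)
    cc <- cross3(a, b)
    d3 <- decompose_jrf(v, cbind(a, b, cc))
    expect_equal(d3$compression^2 + d3$shear_ap^2 + d3$shear_si^2,
                 d3$total^2, tolerance = 1e-12)
  }
  expect_error(decompose_jrf(c(1, 1, 1), matrix(1, 3, 3)), "orthonormal")
})

test_that("supraspinatus activity peaks around the lowest barbell point", {
  ## wide grip, 45 deg abduction: the stability demand is largest where the
  ## external moment peaks, at the bottom of the cycle
  grid <- technique_grid()
  cond <- grid[grid$id == "g2_a45_neutral", ]
  tr <- simulate_trial(fx_subject(), cond, n_reps = 2,
                       noise = list(marker_sd = 0, force_noise_sd = 0,
                                    lateral_frac = 0.3), seed = 7)
  calib <- generate_scapula_calibration(fx_subject())
  ct <- preprocess_trial(tr, calib)
  pos <- inverse_kinematics(fx_model(), ct$markers, stride = 10)
  sol <- rmr_solve(fx_model(), pos, ct$force)
  ph <- ct$partition$phase[pos$sample_index]
  a <- sol$activations[, "supraspinatus_ant"]
  peak_phase <- ph[which.max(a)]
  expect_gt(max(a), 0.05)
  expect_true(abs(peak_phase - 50) <= 10)
})

test_that("the mediolateral sweep reduces to the plain solution at fraction 0", {
  model <- fx_model()
  pos <- fx_posture(stride = 10)
  short <- make_posture_series(pos$q[20:40, ], pos$time[20:40])
  sw <- force_direction_sweep(model, short, fractions = c(0, 1),
                              vertical_force = 78.48)
  plain <- rmr_solve(model, short, matrix(rep(c(0, -78.48, 0), each = 21), 21))
  m_gh <- colMeans(plain$jrf$gh[, c("compression", "shear_ap", "shear_si")])
  row0 <- sw[sw$fraction == 0 & sw$joint == "gh", ]
  expect_equal(row0$compression, m_gh[1], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(row0$total, sqrt(sum(m_gh^2)), tolerance = 1e-8)
  expect_equal(nrow(sw), 4)
  expect_warning(force_direction_sweep(model, short, fractions = 3),
                 "fractions")
})
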