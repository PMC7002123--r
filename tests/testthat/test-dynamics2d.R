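test_that("visual_accel matches closed-form hand evaluations", {
  p <- vf_params(alpha0 = 1, alpha1 = 0.08, gamma = 1, v0 = 1)
  f <- list(x = 0, y = 0, v = 1, psi = 0)

  # empty field at preferred speed: exact fixed point
  expect_equal(visual_accel(f, arcset(), p), 0)

  # neighbor ahead at contact distance: repulsion dominates
  fld <- visual_field(f, data.frame(x = 1, y = 0), p$BL)
  expect_equal(visual_accel(f, fld, p),
               -2 * sin(pi / 6) + 0.08 * 2 * cos(pi / 6),
               tolerance = 1e-12)

  # at the balance distance the visual term vanishes exactly
  dstar <- equilibrium_distance_oracle(p$alpha1)
  fld_eq <- visual_field(f, data.frame(x = dstar, y = 0), p$BL)
  expect_equal(visual_accel(f, fld_eq, p), 0, tolerance = 1e-10)
  # and only relaxation remains off preferred speed
  f_slow <- list(x = 0, y = 0, v = 0.4, psi = 0)
  expect_equal(visual_accel(f_slow, fld_eq, p), p$gamma * (1 - 0.4),
               tolerance = 1e-10)
})

test_that("visual_turn: odd in the bearing, attractive at long range", {
  p <- vf_params(beta0 = 1, beta1 = 0.08)
  f <- list(x = 0, y = 0, v = 1, psi = 0)

  # symmetric arc straight ahead: no turn
  fld <- visual_field(f, data.frame(x = 2, y = 0), p$BL)
  expect_equal(visual_turn(f, fld, p), 0, tolerance = 1e-14)

  # distant neighbor at +pi/2: turn toward it (edge attraction wins)
  fld_l <- visual_field(f, data.frame(x = 0, y = 25), p$BL)
  delta <- asin(1 / 50)
  expect_equal(visual_turn(f, fld_l, p),
               -2 * sin(delta) + 0.08 * 2 * cos(delta) * sin(pi / 2),
               tolerance = 1e-12)
  expect_gt(visual_turn(f, fld_l, p), 0)

  # mirror-reflected configuration: negated output
  fld_r <- visual_field(f, data.frame(x = 0, y = -25), p$BL)
  expect_equal(visual_turn(f, fld_r, p), -visual_turn(f, fld_l, p),
               tolerance = 1e-12)
})

test_that("step_swarm: free motion, speed relaxation, mirror symmetry", {
  p <- vf_params(dt = 0.05, gamma = 1, v0 = 1)

  sw <- swarm2d(data.frame(x = 1, y = 2, v = 1, psi = pi / 3), p)
  s1 <- step_swarm(sw)
  expect_equal(s1$state$x, 1 + 0.05 * cos(pi / 3))
  expect_equal(s1$state$y, 2 + 0.05 * sin(pi / 3))
  expect_equal(s1$time, 0.05)

  # isolated agent off preferred speed relaxes by (1 - gamma dt) per step
  sw2 <- swarm2d(data.frame(x = 0, y = 0, v = 0.5, psi = 0), p)
  s2 <- step_swarm(sw2)
  expect_equal(s2$state$v, 1 - (1 - 0.5) * (1 - p$gamma * p$dt))

  # head-on mirror-symmetric pair stays mirror-symmetric
  p3 <- vf_params(alpha0 = 0.5, beta0 = 0.5, dt = 0.02)
  st <- data.frame(x = c(-2, 2), y = c(0.4, -0.4),
                   v = c(1, 1), psi = c(-0.1, wrap_angle(pi - 0.1)))
  sw3 <- swarm2d(st, p3)
  for (k in 1:25) sw3 <- step_swarm(sw3)
  a <- sw3$state[1, ]
  b <- sw3$state[2, ]
  expect_equal(a$x, -b$x, tolerance = 1e-10)
  expect_equal(a$y, -b$y, tolerance = 1e-10)
  expect_equal(a$v, b$v, tolerance = 1e-10)
  expect_equal(wrap_angle(a$psi - b$psi - pi) , 0, tolerance = 1e-10)
})

test_that("initialization is deterministic and respects the box", {
  p <- vf_params()
  a <- init_swarm(20, p, seed = 99)
  b <- init_swarm(20, p, seed = 99)
  expect_identical(a$state, b$state)
  expect_false(isTRUE(all.equal(a$state, init_swarm(20, p, seed = 100)$state)))

  big <- init_swarm(100, p, seed = 1, box_side = 30)
  expect_true(all(big$state$x >= 0 & big$state$x <= 30))
  expect_true(all(big$state$y >= 0 & big$state$y <= 30))
  expect_equal(big$state$v, rep(p$v0, 100))

  one <- init_swarm(1, p, seed = 5)
  expect_equal(nrow(one$state), 1L)
  expect_error(init_swarm(0, p), "positive")
})

test_that("run_swarm records the requested snapshots and is Markov", {
  p <- vf_params(alpha0 = 0.5, beta0 = 0.5, dt = 0.05)
  sw <- init_swarm(5, p, seed = 3, box_side = 8)

  tr <- run_swarm(sw, 10, 5)
  expect_equal(length(tr$times), 3L)
  expect_equal(tr$times, c(0, 0.25, 0.5))

  # single agent: exact straight line over any horizon
  iso <- swarm2d(data.frame(x = 0, y = 0, v = 1, psi = 0.7), p)
  tri <- run_swarm(iso, 40, 10)
  expect_equal(tri$states[-1, 1, "y"] / tri$states[-1, 1, "x"],
               rep(tan(0.7), 4), tolerance = 1e-12)

  # restarting from a recorded snapshot reproduces the suffix
  tr2 <- run_swarm(sw, 20, 5)
  mid <- swarm_at(tr2, 3)
  suf <- run_swarm(mid, 10, 5)
  expect_equal(suf$states[2, , ], tr2$states[4, , ], tolerance = 1e-12)
  expect_equal(suf$states[3, , ], tr2$states[5, , ], tolerance = 1e-12)
})

test_that("compiled integrator agrees with the R reference step", {
  p <- vf_params(alpha0 = 0.7, beta0 = 1.3, alpha1 = 0.08, beta1 = 0.05,
                 dt = 0.04)
  sw <- init_swarm(8, p, seed = 17, box_side = 6)
  s_r <- sw
  for (k in 1:5) s_r <- step_swarm(s_r)
  tr <- run_swarm(sw, 5, 5)
  expect_equal(as.matrix(s_r$state),
               matrix(tr$states[2, , ], ncol = 4,
                      dimnames = list(NULL, c("x", "y", "v", "psi"))),
               tolerance = 1e-10)
})

test_that("whole-swarm update is equivariant under rotation, translation
           and relabeling", {
  p <- vf_params(alpha0 = 0.5, beta0 = 0.8, dt = 0.05)
  sw <- init_swarm(6, p, seed = 21, box_side = 7)
  base <- step_swarm(sw)

  th <- 0.9
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  st <- sw$state
  rot_xy <- as.matrix(st[, c("x", "y")]) %*% t(R)
  sw_rot <- swarm2d(data.frame(x = rot_xy[, 1] + 3, y = rot_xy[, 2] - 2,
                               v = st$v, psi = wrap_angle(st$psi + th)), p)
  got <- step_swarm(sw_rot)
  exp_xy <- as.matrix(base$state[, c("x", "y")]) %*% t(R)
  expect_equal(got$state$x, exp_xy[, 1] + 3, tolerance = 1e-9)
  expect_equal(got$state$y, exp_xy[, 2] - 2, tolerance = 1e-9)
  expect_equal(got$state$v, base$state$v, tolerance = 1e-9)
  expect_equal(wrap_angle(got$state$psi - base$state$psi - th),
               rep(0, 6), tolerance = 1e-9)

  # permutation equivariance through the compiled path
  perm <- c(4, 1, 6, 2, 5, 3)
  sw_p <- swarm2d(sw$state[perm, ], p)
  tr <- run_swarm(sw, 20, 20)
  tr_p <- run_swarm(sw_p, 20, 20)
  expect_equal(tr_p$states[2, , ], tr$states[2, perm, ], tolerance = 1e-10)
})

test_that("halving dt shrinks the discretization error (explicit Euler)", {
  err_at <- function(dt) {
    p <- vf_params(alpha0 = 1, beta0 = 1, dt = dt)
    st <- data.frame(x = c(0, 2.3), y = c(0, 0.7), v = c(1, 1),
                     psi = c(0.2, -0.4))
    sw <- swarm2d(st, p)
    n <- round(2 / dt)
    tr <- run_swarm(sw, n, n)
    tr$states[2, , ]
  }
  ref <- err_at(0.0025)
  e1 <- max(abs(err_at(0.02) - ref))
  e2 <- max(abs(err_at(0.01) - ref))
  expect_lt(e2, 0.75 * e1)  # ~ halves for a first-order scheme
})

test_that("a front-back pair settles at the repulsion-attraction balance", {
  alpha1 <- 0.04
  dstar <- equilibrium_distance_oracle(alpha1)
  # oracle root is within 0.1% of the far-field formula BL/(2 alpha1)
  expect_equal(dstar, 1 / (2 * alpha1), tolerance = 1e-3)

  p <- vf_params(alpha0 = 0.5, beta0 = 0.5, alpha1 = alpha1,
                 beta1 = alpha1, dt = 0.05)
  sw <- make_fixture("pair_front_back", d = 5, params = p)
  tr <- run_swarm(sw, 20000, 2000)
  fin <- snapshot(tr, length(tr$times))
  sep <- sqrt(diff(fin$x)^2 + diff(fin$y)^2)
  expect_equal(sep, dstar, tolerance = 0.01)
})

test_that("integration failures name the offending agent", {
  p <- vf_params(alpha0 = 1e300, dt = 1e10)
  sw <- make_fixture("pair_front_back", d = 2, params = p)
  expect_error(run_swarm(sw, 50, 10), "agent")
})
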