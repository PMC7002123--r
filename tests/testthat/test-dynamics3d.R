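p3 <- function(...) {
  args <- list(alpha0 = 5, beta0 = 2, alpha1 = 0.1, beta1 = 0.1,
               lambda0 = 10, lambda1 = 0.1, dt = 0.01,
               retina_n_phi = 64, retina_n_theta = 32)
  args[names(list(...))] <- list(...)
  do.call(vf_params, args)
}

test_that("spherical retina renders caps with the right solid angle", {
  p <- vf_params(retina_n_phi = 256, retina_n_theta = 128)
  f <- list(x = 0, y = 0, z = 0, psi = 0)
  fld <- render_spherical_field(f, data.frame(x = 1, y = 0, z = 0), p)
  # occupied solid-angle fraction of a cap of angular radius pi/6
  frac <- sum(fld * rep(cos(attr(fld, "theta")), each = nrow(fld))) *
    attr(fld, "dphi") * attr(fld, "dtheta") / (4 * pi)
  expect_equal(frac, (1 - cos(pi / 6)) / 2, tolerance = 5e-3)

  # no neighbors: all-zero field
  empty <- render_spherical_field(f, data.frame(x = numeric(),
                                                y = numeric(),
                                                z = numeric()), p)
  expect_equal(sum(empty), 0)

  # binary union: a sphere fully hidden behind a nearer coaxial one
  near <- render_spherical_field(f, data.frame(x = 2, y = 0, z = 0), p)
  both <- render_spherical_field(f, data.frame(x = c(2, 40),
                                               y = 0, z = 0), p)
  expect_equal(unclass(both), unclass(near), ignore_attr = TRUE)

  expect_error(render_spherical_field(f, data.frame(x = 0, y = 0, z = 0), p),
               "degenerate")
})

test_that("spherical functionals vanish on the right symmetries", {
  p <- p3()
  f <- list(x = 0, y = 0, z = 0, psi = 0)
  expect_equal(unname(spherical_functionals(
    render_spherical_field(f, data.frame(x = numeric(), y = numeric(),
                                         z = numeric()), p))),
    rep(0, 6))

  # in-plane neighbors: field symmetric in theta => vertical terms zero
  fld <- render_spherical_field(f, data.frame(x = c(2, -1.5), y = c(1, 2),
                                              z = c(0, 0)), p)
  fn <- spherical_functionals(fld)
  expect_equal(fn[["A_vert"]], 0, tolerance = 1e-13)
  expect_equal(fn[["E_vert"]], 0, tolerance = 1e-13)

  # neighbor dead ahead: phi-symmetric => planar odd kernels zero
  fld2 <- render_spherical_field(f, data.frame(x = 3, y = 0, z = 0), p)
  fn2 <- spherical_functionals(fld2)
  expect_equal(fn2[["A_sin"]], 0, tolerance = 1e-13)
  expect_equal(fn2[["E_sin"]], 0, tolerance = 1e-13)
})

test_that("derivatives_3d wires the functionals into the three equations", {
  p <- p3()
  f <- list(x = 0, y = 0, z = 0, v_psi = p$v0, psi = 0, v_z = 0)

  # isolated agent at preferred speed: all derivatives zero
  fld0 <- render_spherical_field(f, data.frame(x = numeric(), y = numeric(),
                                               z = numeric()), p)
  expect_equal(unname(derivatives_3d(f, spherical_functionals(fld0), p)),
               c(0, 0, 0))

  # in-plane neighbors: no vertical motion can be chosen
  fld <- render_spherical_field(f, data.frame(x = c(2, -3), y = c(0.5, 1),
                                              z = c(0, 0)), p)
  der <- derivatives_3d(f, spherical_functionals(fld), p)
  expect_equal(der[["dv_z"]], 0, tolerance = 1e-12)

  # grid refinement: area functionals converge tightly; edge functionals
  # carry row-aliasing noise and settle more slowly
  fns <- vapply(c(128, 256, 512), function(ng) {
    pg <- p3(retina_n_phi = ng, retina_n_theta = ng / 2)
    fldg <- render_spherical_field(f, data.frame(x = 2, y = 0, z = 0), pg)
    spherical_functionals(fldg)[c("A_cos", "E_cos")]
  }, numeric(2))
  expect_lt(abs(fns["A_cos", 3] - fns["A_cos", 2]) / abs(fns["A_cos", 3]),
            0.02)
  expect_lt(abs(fns["E_cos", 3] - fns["E_cos", 2]) / abs(fns["E_cos", 3]),
            0.10)
})

test_that("3D stepping: straight flight, determinism, invariant plane", {
  p <- p3()
  iso <- swarm3d(data.frame(x = 0, y = 0, z = 1, v_psi = 1, psi = 0.3,
                            v_z = 0), p)
  tr <- run_swarm(iso, 50, 10)
  expect_equal(tr$states[, 1, "z"], rep(1, length(tr$times)))
  expect_equal(tr$states[-1, 1, "y"] / tr$states[-1, 1, "x"],
               rep(tan(0.3), length(tr$times) - 1), tolerance = 1e-12)

  # same seed, same trajectory
  a <- run_swarm(init_swarm_3d(5, p, seed = 8, box_side = 6), 30, 30)
  b <- run_swarm(init_swarm_3d(5, p, seed = 8, box_side = 6), 30, 30)
  expect_identical(a$states, b$states)

  # a swarm born exactly in z = 0 never leaves the plane
  ring <- make_fixture("ring", N = 6, radius = 4, params = p, dimension = 3)
  trr <- run_swarm(ring, 200, 50)
  expect_lt(max(abs(trr$states[, , "z"])), 1e-9)
  expect_lt(max(abs(trr$states[, , "v_z"])), 1e-9)
})

test_that("compiled 3D integrator agrees with the R reference step", {
  p <- p3()
  sw <- init_swarm_3d(5, p, seed = 33, box_side = 6)
  s_r <- step_swarm(step_swarm(sw))
  tr <- run_swarm(sw, 2, 2)
  expect_equal(as.matrix(s_r$state),
               matrix(tr$states[2, , ], ncol = 6,
                      dimnames = list(NULL, c("x", "y", "z", "v_psi",
                                              "psi", "v_z"))),
               tolerance = 1e-10)
})

test_that("3D update is equivariant under z-rotation and mirrors in z", {
  p <- p3()
  sw <- init_swarm_3d(5, p, seed = 12, box_side = 6)
  base <- step_swarm(sw)

  th <- 1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  st <- sw$state
  xy <- as.matrix(st[, c("x", "y")]) %*% t(R)
  sw_rot <- swarm3d(data.frame(x = xy[, 1] + 1, y = xy[, 2] - 4,
                               z = st$z + 2, v_psi = st$v_psi,
                               psi = wrap_angle(st$psi + th),
                               v_z = st$v_z), p)
  got <- step_swarm(sw_rot)
  exy <- as.matrix(base$state[, c("x", "y")]) %*% t(R)
  expect_equal(got$state$x, exy[, 1] + 1, tolerance = 1e-9)
  expect_equal(got$state$y, exy[, 2] - 4, tolerance = 1e-9)
  expect_equal(got$state$z, base$state$z + 2, tolerance = 1e-9)
  expect_equal(got$state$v_psi, base$state$v_psi, tolerance = 1e-9)

  # reflect z: dv_z flips, planar dynamics untouched
  sw_m <- swarm3d(data.frame(x = st$x, y = st$y, z = -st$z,
                             v_psi = st$v_psi, psi = st$psi,
                             v_z = -st$v_z), p)
  got_m <- step_swarm(sw_m)
  expect_equal(got_m$state$z, -base$state$z, tolerance = 1e-11)
  expect_equal(got_m$state$v_z, -base$state$v_z, tolerance = 1e-11)
  expect_equal(got_m$state$x, base$state$x, tolerance = 1e-11)
  expect_equal(got_m$state$psi, base$state$psi, tolerance = 1e-11)
})
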