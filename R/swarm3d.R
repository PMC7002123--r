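#' Construct a 3D swarm (cylindrical kinematics)
#'
#' In the 3D variant each sphere moves with a planar velocity `v_psi`
#' along its planar heading `psi` plus an independent vertical velocity
#' `v_z`; agents never pitch or roll, so the spherical retina stays
#' anchored to the world vertical and is rotated only by `psi`.
#'
#' @param state Data frame with numeric columns `x`, `y`, `z`, `v_psi`,
#'   `psi`, `v_z`.
#' @param params A [vf_params()] object (uses `lambda0`, `lambda1` and the
#'   retina grid resolution in addition to the 2D coefficients).
#' @param time Current simulation time.
#' @return Object of class `c("swarm3d", "vf_swarm")`.
#' @export
swarm3d <- function(state, params = vf_params(), time = 0) {
  state <- as.data.frame(state)
  need <- c("x", "y", "z", "v_psi", "psi", "v_z")
  missing <- setdiff(need, names(state))
  if (length(missing)) {
    stop("state is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!nrow(state)) stop("a swarm needs at least one agent")
  state <- state[, need]
  if (!all(vapply(state, function(col) all(is.finite(col)), logical(1)))) {
    stop("all agent state fields must be finite")
  }
  state$psi <- wrap_angle(state$psi)
  rownames(state) <- NULL
  structure(list(state = state, params = params, time = as.numeric(time)),
            class = c("swarm3d", "vf_swarm"))
}

#' Random initial 3D swarm
#'
#' Planar positions uniform in a square of side `box_side`, vertical
#' positions uniform in `[-box_side/4, box_side/4]` plus a small Gaussian
#' jitter (sd `1e-3 * BL`).  The jitter breaks the exact horizontal-plane
#' symmetry: a swarm starting exactly in one plane can never leave it, so
#' purely planar starts would mask the vertical dynamics entirely.
#' Headings uniform, planar speeds at `v0`, vertical speeds zero.
#'
#' @inheritParams init_swarm
#' @return A [swarm3d()] with a `seed` attribute.
#' @export
init_swarm_3d <- function(N, params = vf_params(), seed = 1L,
                          box_side = NULL) {
  if (!is.numeric(N) || length(N) != 1 || !is.finite(N) || N < 1) {
    stop("N must be a positive integer")
  }
  N <- as.integer(N)
  box_side <- box_side %||% default_box_side(N, params)
  if (box_side <= 0) stop("box_side must be positive")
  set.seed(seed)
  st <- data.frame(x = runif(N, 0, box_side),
                   y = runif(N, 0, box_side),
                   z = runif(N, -box_side / 4, box_side / 4) +
                     rnorm(N, 0, 1e-3 * params$BL),
                   v_psi = rep(params$v0, N),
                   psi = runif(N, -pi, pi),
                   v_z = rep(0, N))
  sw <- swarm3d(st, params, time = 0)
  attr(sw, "seed") <- as.integer(seed)
  sw
}

# Retina cell centers, symmetric about 0 by construction so that the
# horizontal-plane symmetry of the dynamics is exact on the grid.
retina_grid <- function(params) {
  np <- params$retina_n_phi
  nt <- params$retina_n_theta
  dphi <- 2 * pi / np
  dtheta <- pi / nt
  list(phi = (seq_len(np) - (np + 1) / 2) * dphi,
       theta = (seq_len(nt) - (nt + 1) / 2) * dtheta,
       dphi = dphi, dtheta = dtheta)
}

#' Render the binary spherical retina of a 3D agent
#'
#' Discretizes the sphere into an azimuth-elevation grid of cell centers
#' \eqn{\varphi_k \in (-\pi, \pi]}, \eqn{\theta_l \in (-\pi/2, \pi/2)} and
#' marks a cell occupied when some neighbor's spherical cap (angular
#' radius `asin(min(1, BL / (2 d)))` about the neighbor direction) covers
#' the cell center.  The retina is rotated only by the planar heading:
#' azimuth is measured from the heading, elevation from the world
#' horizontal.  Occlusion is the binary union over neighbors.
#'
#' @param focal Focal agent state with fields `x`, `y`, `z`, `psi`.
#' @param others Data frame of the other agents (columns `x`, `y`, `z`).
#' @param params A [vf_params()]; `retina_n_phi` x `retina_n_theta` sets
#'   the grid.
#' @return A 0/1 matrix of class `spherical_field` (rows = azimuth cells,
#'   columns = elevation cells) with attributes `phi`, `theta`, `dphi`,
#'   `dtheta`.
#' @export
render_spherical_field <- function(focal, others, params = vf_params()) {
  g <- retina_grid(params)
  f <- as_agent(focal, c("x", "y", "z", "psi"))
  cp <- cos(g$phi); sp <- sin(g$phi)
  ct <- cos(g$theta); st <- sin(g$theta)
  X <- outer(cp, ct)
  Y <- outer(sp, ct)
  Z <- matrix(st, length(g$phi), length(g$theta), byrow = TRUE)
  occ <- matrix(FALSE, length(g$phi), length(g$theta))
  others <- as.data.frame(others)
  if (nrow(others)) {
    cpsi <- cos(f$psi); spsi <- sin(f$psi)
    for (j in seq_len(nrow(others))) {
      dx <- others$x[j] - f$x
      dy <- others$y[j] - f$y
      dz <- others$z[j] - f$z
      d <- sqrt(dx^2 + dy^2 + dz^2)
      if (d == 0) {
        stop("degenerate geometry: a neighbor coincides with the focal agent")
      }
      xp <- cpsi * dx + spsi * dy
      yp <- -spsi * dx + cpsi * dy
      n1 <- xp / d; n2 <- yp / d; n3 <- dz / d
      crho <- cos(asin(min(1, params$BL / (2 * d))))
      occ <- occ | (X * n1 + Y * n2 + Z * n3 >= crho)
    }
  }
  structure(occ * 1, class = "spherical_field",
            phi = g$phi, theta = g$theta, dphi = g$dphi, dtheta = g$dtheta)
}

#' @export
print.spherical_field <- function(x, ...) {
  frac <- sum(x * rep(cos(attr(x, "theta")), each = nrow(x))) *
    attr(x, "dphi") * attr(x, "dtheta") / (4 * pi)
  cat(sprintf("<spherical retina %d x %d, occupied solid-angle fraction %.4f>\n",
              nrow(x), ncol(x), frac))
  invisible(x)
}

#' Area and edge functionals of a spherical retina
#'
#' Midpoint-rule quadrature of the binary field against the kernels
#' `cos(theta)cos(phi)`, `cos(theta)sin(phi)` and `sin(theta)` (area
#' terms), plus the row-wise edge sums: within each elevation row, 0/1
#' transitions along azimuth (periodic) are located at the midpoint
#' between adjacent cell centers and each contributes the azimuthal kernel
#' once, the row then being weighted by `cos(theta) * dtheta` for the
#' planar terms and `sin(theta) * dtheta` for the vertical one.  Up-down
#' (elevation-direction) edges are deliberately ignored, mirroring the 2D
#' unit-weight Dirac-comb rule row by row.
#'
#' @param field A `spherical_field` from [render_spherical_field()].
#' @return Named numeric vector `A_cos, A_sin, A_vert, E_cos, E_sin,
#'   E_vert`.
#' @export
spherical_functionals <- function(field) {
  if (!inherits(field, "spherical_field")) {
    stop("field must be a spherical_field")
  }
  phi <- attr(field, "phi"); theta <- attr(field, "theta")
  dphi <- attr(field, "dphi"); dtheta <- attr(field, "dtheta")
  np <- length(phi); nt <- length(theta)
  cp <- cos(phi); sp <- sin(phi)
  ct <- cos(theta); st <- sin(theta)
  w_area <- dphi * dtheta
  A_cos <- w_area * sum(field * outer(cp, ct))
  A_sin <- w_area * sum(field * outer(sp, ct))
  A_vert <- w_area * sum(field * matrix(st, np, nt, byrow = TRUE))
  E_cos <- E_sin <- E_vert <- 0
  for (l in seq_len(nt)) {
    v <- field[, l]
    trans <- which(v != c(v[np], v[-np]))
    if (length(trans)) {
      e_ang <- phi[trans] - dphi / 2
      E_cos <- E_cos + ct[l] * dtheta * sum(cos(e_ang))
      E_sin <- E_sin + ct[l] * dtheta * sum(sin(e_ang))
      E_vert <- E_vert + st[l] * dtheta * length(trans)
    }
  }
  c(A_cos = A_cos, A_sin = A_sin, A_vert = A_vert,
    E_cos = E_cos, E_sin = E_sin, E_vert = E_vert)
}

#' Velocity derivatives of a 3D agent
#'
#' The three coupled equations of the cylindrical model:
#' `dv_psi = alpha0 * (-A_cos + alpha1 * E_cos) + gamma * (v0 - v_psi)`,
#' `dpsi = beta0 * (-A_sin + beta1 * E_sin)`, and
#' `dv_z = lambda0 * (-A_vert + lambda1 * E_vert)`.
#' Relaxation toward the preferred speed applies to the planar speed only;
#' the vertical velocity equation has no relaxation term.  With all
#' agents exactly in the focal plane and the elevation grid symmetric
#' about the horizon, `dv_z` vanishes: no vertical direction can be chosen
#' unless a bias is introduced.
#'
#' @param focal Focal agent state (field `v_psi`).
#' @param functionals Output of [spherical_functionals()].
#' @param params A [vf_params()] object.
#' @return Named numeric vector `dv_psi, dpsi, dv_z`.
#' @export
derivatives_3d <- function(focal, functionals, params) {
  f <- as_agent(focal, "v_psi")
  fn <- functionals
  c(dv_psi = params$alpha0 * (-fn[["A_cos"]] +
                                params$alpha1 * fn[["E_cos"]]) +
      params$gamma * (params$v0 - f$v_psi),
    dpsi = params$beta0 * (-fn[["A_sin"]] + params$beta1 * fn[["E_sin"]]),
    dv_z = params$lambda0 * (-fn[["A_vert"]] +
                               params$lambda1 * fn[["E_vert"]]))
}

#' @export
step_swarm.swarm3d <- function(swarm) {
  st <- swarm$state
  p <- swarm$params
  N <- nrow(st)
  dv <- dpsi <- dvz <- numeric(N)
  for (i in seq_len(N)) {
    field <- render_spherical_field(st[i, ], st[-i, , drop = FALSE], p)
    der <- derivatives_3d(st[i, ], spherical_functionals(field), p)
    if (any(!is.finite(der))) {
      stop("integration failure: non-finite derivative (",
           paste(names(der)[!is.finite(der)], collapse = ", "),
           ") for agent ", i)
    }
    dv[i] <- der[["dv_psi"]]
    dpsi[i] <- der[["dpsi"]]
    dvz[i] <- der[["dv_z"]]
  }
  st$v_psi <- st$v_psi + p$dt * dv
  st$psi <- wrap_angle(st$psi + p$dt * dpsi)
  st$v_z <- st$v_z + p$dt * dvz
  st$x <- st$x + p$dt * st$v_psi * cos(st$psi)
  st$y <- st$y + p$dt * st$v_psi * sin(st$psi)
  st$z <- st$z + p$dt * st$v_z
  bad <- which(!is.finite(st$x) | !is.finite(st$y) | !is.finite(st$z))
  if (length(bad)) {
    stop("integration failure: non-finite state for agent ", bad[1])
  }
  out <- swarm
  out$state <- st
  out$time <- swarm$time + p$dt
  out
}

#' @export
run_swarm.swarm3d <- function(swarm, n_steps, record_every = 1L) {
  rec <- record_steps(n_steps, record_every)
  n_steps <- as.integer(n_steps)
  p <- swarm$params
  res <- sim3d_cpp(as.matrix(swarm$state), p$gamma, p$v0,
                   p$alpha0, p$alpha1, p$beta0, p$beta1,
                   p$lambda0, p$lambda1, p$BL, p$dt,
                   p$retina_n_phi, p$retina_n_theta, n_steps, rec)
  states <- res$states
  dimnames(states) <- list(NULL, NULL,
                           c("x", "y", "z", "v_psi", "psi", "v_z"))
  vf_trajectory(
    times = swarm$time + p$dt * rec,
    states = states,
    metadata = list(
      dimension = 3L,
      params = p,
      seed = attr(swarm, "seed") %||% NA_integer_,
      record_steps = rec,
      step_min_dist = list(times = swarm$time + p$dt * (0:n_steps),
                           min_dist = res$min_dist)
    )
  )
}
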