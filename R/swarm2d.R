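#' Construct a 2D swarm
#'
#' A swarm bundles the per-agent states (positions in BL, signed speed
#' along the heading in BL/time, heading angle in \eqn{(-\pi, \pi]}), the
#' model parameters, and the current time.  Speed is signed and never
#' clamped: the speed equation can drive an agent backwards (it then
#' oscillates forth and back without flipping its heading).
#'
#' @param state Data frame with numeric columns `x`, `y`, `v`, `psi`, one
#'   row per agent (at least one).
#' @param params A [vf_params()] object.
#' @param time Current simulation time.
#' @return Object of class `c("swarm2d", "vf_swarm")` with elements
#'   `state`, `params`, `time`.
#' @export
swarm2d <- function(state, params = vf_params(), time = 0) {
  state <- as.data.frame(state)
  need <- c("x", "y", "v", "psi")
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
            class = c("swarm2d", "vf_swarm"))
}

#' @export
print.vf_swarm <- function(x, ...) {
  dim <- if (inherits(x, "swarm3d")) 3L else 2L
  cat(sprintf("<%dD vision-based swarm: %d agents at t = %g>\n",
              dim, nrow(x$state), x$time))
  print(utils::head(x$state, 5))
  if (nrow(x$state) > 5) cat(sprintf("  ... %d more agents\n",
                                     nrow(x$state) - 5))
  invisible(x)
}

default_box_side <- function(N, params) {
  ceiling(sqrt(N)) * leq_from_coef(params$alpha1, params$BL)
}

#' Random initial swarm in a square box
#'
#' Positions are uniform in a square of side `box_side`, headings uniform
#' in \eqn{(-\pi, \pi]}, and all speeds start at the preferred speed `v0`.
#' The default box side, `ceiling(sqrt(N))` times the equilibrium length
#' `BL / (2 * alpha1)`, starts the group near its expected steady-state
#' density.  The same `(N, params, seed, box_side)` always yields the
#' identical swarm.
#'
#' @param N Number of agents (>= 1).
#' @param params A [vf_params()] object.
#' @param seed Integer seed for the initial condition.
#' @param box_side Side of the initialization square in BL; `NULL` for the
#'   density-matched default.
#' @return A [swarm2d()] with a `seed` attribute.
#' @export
init_swarm <- function(N, params = vf_params(), seed = 1L, box_side = NULL) {
  if (!is.numeric(N) || length(N) != 1 || !is.finite(N) || N < 1) {
    stop("N must be a positive integer")
  }
  N <- as.integer(N)
  box_side <- box_side %||% default_box_side(N, params)
  if (box_side <= 0) stop("box_side must be positive")
  set.seed(seed)
  st <- data.frame(x = runif(N, 0, box_side),
                   y = runif(N, 0, box_side),
                   v = rep(params$v0, N),
                   psi = runif(N, -pi, pi))
  sw <- swarm2d(st, params, time = 0)
  attr(sw, "seed") <- as.integer(seed)
  sw
}

#' Speed response to the visual field
#'
#' Time derivative of the signed speed of the focal agent: linear
#' relaxation toward the preferred speed plus the cosine-weighted visual
#' response, `gamma * (v0 - v) + alpha0 * (-A_cos + alpha1 * E_cos)`,
#' where `A_cos` is the cosine-weighted occupied area of the retina
#' (repulsive: things ahead brake, things behind accelerate) and `E_cos`
#' the cosine-weighted edge sum (attractive).
#'
#' @param focal Focal agent state with fields `v` (and anything else).
#' @param field The focal agent's visual field, an [arcset()].
#' @param params A [vf_params()] object.
#' @return Scalar acceleration dv/dt.
#' @export
visual_accel <- function(focal, field, params) {
  f <- as_agent(focal, "v")
  params$gamma * (params$v0 - f$v) +
    params$alpha0 * (-weighted_area_integral(field, "cos") +
                       params$alpha1 *
                         weighted_edge_sum(field_edges(field), "cos"))
}

#' Turning response to the visual field
#'
#' Time derivative of the heading: `beta0 * (-A_sin + beta1 * E_sin)` with
#' the sine-weighted area and edge functionals.  Positive output is a left
#' turn; the sine kernel makes the area term turn the agent away from
#' occupied retina and the edge term turn it toward edges, so a single
#' distant neighbor attracts while a close one repels.
#'
#' @inheritParams visual_accel
#' @return Scalar angular velocity dpsi/dt.
#' @export
visual_turn <- function(focal, field, params) {
  params$beta0 * (-weighted_area_integral(field, "sin") +
                    params$beta1 *
                      weighted_edge_sum(field_edges(field), "sin"))
}

#' Advance a swarm by one time step
#'
#' Synchronous explicit Euler: every agent's visual field is computed from
#' the pre-step states of all others, then speed and heading are updated
#' and the position advances along the updated velocity.  Produces an
#' error naming the agent and term if a non-finite value appears.
#'
#' @param swarm A [swarm2d()] or [swarm3d()].
#' @return The swarm advanced by `params$dt`.
#' @export
step_swarm <- function(swarm) UseMethod("step_swarm")

#' @export
step_swarm.swarm2d <- function(swarm) {
  st <- swarm$state
  p <- swarm$params
  N <- nrow(st)
  dv <- numeric(N)
  dpsi <- numeric(N)
  for (i in seq_len(N)) {
    field <- if (N > 1) {
      visual_field(st[i, ], st[-i, , drop = FALSE], p$BL)
    } else {
      new_arcset(numeric(), numeric())
    }
    dv[i] <- visual_accel(st[i, ], field, p)
    dpsi[i] <- visual_turn(st[i, ], field, p)
    if (!is.finite(dv[i])) {
      stop("integration failure: non-finite visual_accel for agent ", i)
    }
    if (!is.finite(dpsi[i])) {
      stop("integration failure: non-finite visual_turn for agent ", i)
    }
  }
  st$v <- st$v + p$dt * dv
  st$psi <- wrap_angle(st$psi + p$dt * dpsi)
  st$x <- st$x + p$dt * st$v * cos(st$psi)
  st$y <- st$y + p$dt * st$v * sin(st$psi)
  bad <- which(!is.finite(st$x) | !is.finite(st$y) | !is.finite(st$v))
  if (length(bad)) {
    stop("integration failure: non-finite state for agent ", bad[1])
  }
  out <- swarm
  out$state <- st
  out$time <- swarm$time + p$dt
  out
}

#' Run a swarm forward and record a trajectory
#'
#' Applies [step_swarm()] dynamics `n_steps` times through a compiled
#' integrator, recording every `record_every` steps (always including the
#' initial and final states).  The run is deterministic given the initial
#' swarm.  The trajectory also carries the minimum pairwise distance at
#' every integration step (not just recorded snapshots), so collision
#' detection does not depend on the recording stride.
#'
#' @param swarm A [swarm2d()] or [swarm3d()].
#' @param n_steps Number of Euler steps (>= 1).
#' @param record_every Recording stride in steps.
#' @return A [vf_trajectory()].
#' @export
run_swarm <- function(swarm, n_steps, record_every = 1L) {
  UseMethod("run_swarm")
}

record_steps <- function(n_steps, record_every) {
  if (!is.numeric(n_steps) || length(n_steps) != 1 || n_steps < 1) {
    stop("n_steps must be a positive integer")
  }
  if (!is.numeric(record_every) || length(record_every) != 1 ||
      record_every < 1) {
    stop("record_every must be a positive integer")
  }
  n_steps <- as.integer(n_steps)
  record_every <- as.integer(record_every)
  unique(c(seq(0L, n_steps, by = record_every), n_steps))
}

#' @export
run_swarm.swarm2d <- function(swarm, n_steps, record_every = 1L) {
  rec <- record_steps(n_steps, record_every)
  n_steps <- as.integer(n_steps)
  p <- swarm$params
  res <- sim2d_cpp(as.matrix(swarm$state), p$gamma, p$v0,
                   p$alpha0, p$alpha1, p$beta0, p$beta1,
                   p$BL, p$dt, n_steps, rec)
  states <- res$states
  dimnames(states) <- list(NULL, NULL, c("x", "y", "v", "psi"))
  vf_trajectory(
    times = swarm$time + p$dt * rec,
    states = states,
    metadata = list(
      dimension = 2L,
      params = p,
      seed = attr(swarm, "seed") %||% NA_integer_,
      record_steps = rec,
      step_min_dist = list(times = swarm$time + p$dt * (0:n_steps),
                           min_dist = res$min_dist)
    )
  )
}
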