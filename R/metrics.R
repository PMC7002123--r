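as_state <- function(x) {
  if (inherits(x, "vf_swarm")) return(x$state)
  if (inherits(x, "vf_trajectory")) {
    stop("pass a snapshot (see snapshot()) or use the *_series helpers")
  }
  as.data.frame(x)
}

is_state_3d <- function(st) all(c("z", "v_psi", "v_z") %in% names(st))

#' Polarization order parameter
#'
#' Magnitude of the mean unit velocity vector, `|sum(u_i)| / N`: 1 for a
#' perfectly aligned group, near `1/sqrt(N)` for random headings.  In 2D
#' the unit velocity is the heading vector `(cos psi, sin psi)`; in 3D it
#' is the normalized full velocity `v_psi e_psi + v_z e_z`, so vertical
#' motion degrades planar order.  Agents with exactly zero 3D speed
#' contribute a zero vector (an all-stopped group has polarization 0 by
#' convention).
#'
#' @param x A snapshot data frame or a swarm.
#' @return Scalar in `[0, 1]`.
#' @export
polarization <- function(x) {
  st <- as_state(x)
  n <- nrow(st)
  if (n < 1) stop("polarization needs at least one agent")
  if (is_state_3d(st)) {
    vx <- st$v_psi * cos(st$psi)
    vy <- st$v_psi * sin(st$psi)
    vz <- st$v_z
    sp <- sqrt(vx^2 + vy^2 + vz^2)
    ok <- sp > 0
    ux <- uy <- uz <- numeric(n)
    ux[ok] <- vx[ok] / sp[ok]
    uy[ok] <- vy[ok] / sp[ok]
    uz[ok] <- vz[ok] / sp[ok]
    sqrt(sum(ux)^2 + sum(uy)^2 + sum(uz)^2) / n
  } else {
    sqrt(sum(cos(st$psi))^2 + sum(sin(st$psi))^2) / n
  }
}

#' Polarization time series of a trajectory
#'
#' @param traj A [vf_trajectory()].
#' @return Data frame with columns `time`, `polarization`.
#' @export
polarization_series <- function(traj) {
  if (!inherits(traj, "vf_trajectory")) stop("traj must be a vf_trajectory")
  data.frame(
    time = traj$times,
    polarization = vapply(seq_along(traj$times),
                          function(i) polarization(snapshot(traj, i)),
                          numeric(1))
  )
}

position_cols <- function(st) {
  if (is_state_3d(st)) c("x", "y", "z") else c("x", "y")
}

#' Nearest-neighbor and minimum pairwise distances
#'
#' @param x A snapshot data frame or a swarm with at least two agents.
#' @return List with `mean_nnd` (mean over agents of the distance to the
#'   closest other agent) and `min_pairwise_distance` (global minimum), in
#'   BL.
#' @export
nearest_neighbor_stats <- function(x) {
  st <- as_state(x)
  if (nrow(st) < 2) {
    stop("nearest-neighbor statistics are undefined for fewer than 2 agents")
  }
  D <- as.matrix(dist(st[, position_cols(st)]))
  diag(D) <- Inf
  nnd <- apply(D, 1, min)
  list(mean_nnd = mean(nnd), min_pairwise_distance = min(D))
}

extents_snapshot <- function(st) {
  if (nrow(st) < 2) stop("extents are undefined for fewer than 2 agents")
  exy <- max(dist(st[, c("x", "y")]))
  ez <- if (is_state_3d(st)) max(st$z) - min(st$z) else 0
  c(extent_xy = exy, extent_z = ez)
}

#' Spatial extents of the swarm
#'
#' `extent_xy` is the maximum pairwise distance in the horizontal (x, y)
#' projection; `extent_z` the vertical spread `max(z) - min(z)` (zero for
#' 2D states).  Applied to a trajectory, returns the time average of the
#' instantaneous extents over the window (default: second half of the
#' run).
#'
#' @param x A snapshot data frame, a swarm, or a [vf_trajectory()].
#' @param window For a trajectory, `c(t_start, t_end)`; `NULL` for the
#'   second half.
#' @return Named numeric vector `extent_xy`, `extent_z` in BL.
#' @export
extents <- function(x, window = NULL) {
  if (inherits(x, "vf_trajectory")) {
    idx <- window_indices(x, window)
    vals <- vapply(idx, function(i) extents_snapshot(snapshot(x, i)),
                   numeric(2))
    return(c(extent_xy = mean(vals[1, ]), extent_z = mean(vals[2, ])))
  }
  extents_snapshot(as_state(x))
}

#' Minimum pairwise distance over a trajectory window
#'
#' Uses the per-step minimum-distance series recorded by [run_swarm()]
#' when present (so approaches between recorded snapshots are not
#' missed), otherwise falls back to the recorded snapshots.
#'
#' @param traj A [vf_trajectory()].
#' @param window `c(t_start, t_end)`; `NULL` for the second half of the
#'   per-step series.
#' @return Minimum center-to-center distance in BL.
#' @export
min_distance_in_window <- function(traj, window = NULL) {
  smd <- traj$metadata$step_min_dist
  if (!is.null(smd)) {
    tt <- smd$times
    if (is.null(window)) {
      window <- c(tt[1] + (tt[length(tt)] - tt[1]) / 2, tt[length(tt)])
    }
    sel <- tt >= window[1] - 1e-9 & tt <= window[2] + 1e-9
    if (!any(sel)) stop("window contains no integration steps")
    return(min(smd$min_dist[sel]))
  }
  idx <- window_indices(traj, window)
  min(vapply(idx, function(i) {
    nearest_neighbor_stats(snapshot(traj, i))$min_pairwise_distance
  }, numeric(1)))
}

#' Collision detection over a trajectory window
#'
#' Two agents collide when their center-to-center distance drops below one
#' body length.  Uses the per-step minimum-distance series recorded by
#' [run_swarm()] (every integration step, not just snapshots) when
#' available.
#'
#' @param traj A [vf_trajectory()].
#' @param window `c(t_start, t_end)`; `NULL` for the whole run.
#' @param BL Body length; defaults to the trajectory's parameters.
#' @return `TRUE` iff the minimum pairwise distance falls below `BL`
#'   anywhere in the window; `FALSE` for a single agent.
#' @export
collision_flag <- function(traj, window = NULL, BL = NULL) {
  if (!inherits(traj, "vf_trajectory")) stop("traj must be a vf_trajectory")
  if (n_agents(traj) < 2) return(FALSE)
  BL <- BL %||% traj$metadata$params$BL
  if (is.null(window)) {
    window <- c(traj$times[1], traj$times[length(traj$times)])
  }
  min_distance_in_window(traj, window) < BL
}

#' Nearest-neighbor identity turnover
#'
#' Distinguishes fluid swarms (agents permanently change position inside
#' the group) from crystal-like states (agents jiggle around locked
#' relative positions): across consecutive recorded snapshots in the
#' window, the fraction of agents whose nearest neighbor changed identity,
#' averaged over snapshot pairs.
#'
#' @param traj A [vf_trajectory()] with at least 2 agents.
#' @param window `c(t_start, t_end)`; `NULL` for the second half.
#' @return Scalar in `[0, 1]`; 0 means fully locked neighborhoods.
#' @export
neighbor_exchange_rate <- function(traj, window = NULL) {
  if (n_agents(traj) < 2) stop("neighbor exchange needs at least 2 agents")
  idx <- window_indices(traj, window)
  if (length(idx) < 2) stop("window must contain at least two snapshots")
  nn_of <- function(i) {
    st <- snapshot(traj, i)
    D <- as.matrix(dist(st[, position_cols(st)]))
    diag(D) <- Inf
    apply(D, 1, which.min)
  }
  ids <- vapply(idx, nn_of, integer(n_agents(traj)))
  mean(ids[, -1, drop = FALSE] != ids[, -ncol(ids), drop = FALSE])
}

#' Persistence of the internal swarm structure
#'
#' Correlation between the vectors of pairwise distances at snapshots
#' separated by a time lag, averaged over available snapshot pairs in the
#' window.  A crystal-like state, where agents oscillate around locked
#' relative positions, keeps its distance structure and scores near 1; a
#' fluid swarm whose members continually rearrange decorrelates toward 0.
#' Unlike raw nearest-neighbor identity turnover, this is insensitive to
#' fast small-amplitude jiggling around lattice sites and to rigid motion
#' of the whole group.
#'
#' @param traj A [vf_trajectory()] with at least 3 agents.
#' @param lag Time lag (same units as `traj$times`); default a quarter of
#'   the window.
#' @param window `c(t_start, t_end)`; `NULL` for the second half.
#' @return Mean Pearson correlation in `[-1, 1]`.
#' @export
structure_persistence <- function(traj, lag = NULL, window = NULL) {
  if (n_agents(traj) < 3) {
    stop("structure persistence needs at least 3 agents")
  }
  idx <- window_indices(traj, window)
  tt <- traj$times[idx]
  if (is.null(lag)) lag <- (tt[length(tt)] - tt[1]) / 4
  dt_snap <- if (length(tt) > 1) min(diff(tt)) else stop("window too short")
  k <- max(1L, round(lag / dt_snap))
  if (k >= length(idx)) stop("lag exceeds the window")
  dvec <- function(i) {
    st <- snapshot(traj, i)
    as.vector(dist(st[, position_cols(st)]))
  }
  pairs <- seq_len(length(idx) - k)
  mean(vapply(pairs, function(j) {
    stats::cor(dvec(idx[j]), dvec(idx[j + k]))
  }, numeric(1)))
}

#' Pairwise response map of the visual interaction
#'
#' Instantaneous speed and turning response of a focal agent at the origin
#' (heading +x, moving at the preferred speed so the relaxation term
#' vanishes) to a single neighbor placed at front-back distance `d_fb` and
#' left-right distance `d_lr`.  The subtended-angle term produces a
#' short-range repulsion and the edge term a long-range attraction, so the
#' `dv` zero-crossing along the front-back axis is the two-agent
#' equilibrium distance.  Placements coinciding with the focal agent give
#' `NA`.
#'
#' @param params A [vf_params()] object.
#' @param d_fb,d_lr Numeric vectors of front-back and left-right distances
#'   (BL); the map is evaluated on their grid.
#' @return Data frame with columns `d_fb`, `d_lr`, `dv`, `dpsi`.
#' @export
pair_response_map <- function(params, d_fb, d_lr = 0) {
  grid <- expand.grid(d_fb = as.numeric(d_fb), d_lr = as.numeric(d_lr))
  focal <- list(x = 0, y = 0, v = params$v0, psi = 0)
  out <- t(vapply(seq_len(nrow(grid)), function(k) {
    if (grid$d_fb[k] == 0 && grid$d_lr[k] == 0) return(c(NA_real_, NA_real_))
    field <- visual_field(focal,
                          data.frame(x = grid$d_fb[k], y = grid$d_lr[k]),
                          params$BL)
    c(visual_accel(focal, field, params),
      visual_turn(focal, field, params))
  }, numeric(2)))
  data.frame(d_fb = grid$d_fb, d_lr = grid$d_lr,
             dv = out[, 1], dpsi = out[, 2])
}

#' Summarize a run as one table row
#'
#' Steady-state diagnostics over a post-transient window (default: the
#' second half of the run): time-averaged polarization, mean
#' nearest-neighbor distance and extents, and the minimum pairwise
#' distance over every integration step in the window.  The fixed column
#' layout (parameters first, then metrics) is what the sweep drivers
#' concatenate into their CSV summaries.
#'
#' @param traj A [vf_trajectory()].
#' @param window `c(t_start, t_end)`; `NULL` for the second half.
#' @return One-row data frame with columns `N, alpha0, beta0, alpha1,
#'   beta1, lambda0, lambda1, seed, polarization, mean_nnd, min_dist,
#'   extent_xy, extent_z`.
#' @export
summarize_run <- function(traj, window = NULL) {
  if (!inherits(traj, "vf_trajectory")) stop("traj must be a vf_trajectory")
  p <- traj$metadata$params
  idx <- window_indices(traj, window)
  tt <- traj$times
  win <- if (is.null(window)) {
    c(tt[1] + (tt[length(tt)] - tt[1]) / 2, tt[length(tt)])
  } else {
    window
  }
  pol <- mean(vapply(idx, function(i) polarization(snapshot(traj, i)),
                     numeric(1)))
  nnd <- mean(vapply(idx, function(i) {
    nearest_neighbor_stats(snapshot(traj, i))$mean_nnd
  }, numeric(1)))
  ext <- extents(traj, win)
  data.frame(N = n_agents(traj),
             alpha0 = p$alpha0, beta0 = p$beta0,
             alpha1 = p$alpha1, beta1 = p$beta1,
             lambda0 = p$lambda0, lambda1 = p$lambda1,
             seed = traj$metadata$seed %||% NA_integer_,
             polarization = pol,
             mean_nnd = nnd,
             min_dist = min_distance_in_window(traj, win),
             extent_xy = ext[["extent_xy"]],
             extent_z = ext[["extent_z"]])
}
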