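#' Trajectory of a simulated swarm
#'
#' Time-indexed record of all agent states plus run metadata (parameters,
#' seed, model dimension, recording stride and the per-step minimum
#' pairwise distance series when produced by [run_swarm()]).
#'
#' @param times Strictly increasing numeric vector of snapshot times.
#' @param states Numeric array `[snapshot, agent, field]`; the third
#'   dimension is named (`x,y,v,psi` in 2D; `x,y,z,v_psi,psi,v_z` in 3D).
#' @param metadata Named list; must contain `dimension` and `params`.
#' @return Object of class `vf_trajectory`.
#' @export
vf_trajectory <- function(times, states, metadata) {
  times <- as.numeric(times)
  if (length(times) < 1) stop("a trajectory needs at least one snapshot")
  if (any(diff(times) <= 0)) stop("snapshot times must be strictly increasing")
  if (length(dim(states)) != 3 || dim(states)[1] != length(times)) {
    stop("states must be an array [snapshot, agent, field] matching times")
  }
  if (is.null(metadata$dimension)) stop("metadata must record the dimension")
  structure(list(times = times, states = states, metadata = metadata),
            class = "vf_trajectory")
}

#' @export
print.vf_trajectory <- function(x, ...) {
  d <- dim(x$states)
  cat(sprintf("<%dD trajectory: %d agents, %d snapshots, t in [%g, %g]>\n",
              x$metadata$dimension, d[2], d[1],
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Number of agents in a trajectory
#' @param traj A [vf_trajectory()].
#' @return Integer agent count.
#' @export
n_agents <- function(traj) dim(traj$states)[2]

#' Extract one snapshot of a trajectory
#'
#' @param traj A [vf_trajectory()].
#' @param i Snapshot index (1-based); alternatively give `time`.
#' @param time If supplied, the snapshot closest to this time is returned.
#' @return Data frame of agent states at that snapshot.
#' @export
snapshot <- function(traj, i = NULL, time = NULL) {
  if (!inherits(traj, "vf_trajectory")) stop("traj must be a vf_trajectory")
  if (is.null(i)) {
    if (is.null(time)) stop("supply a snapshot index i or a time")
    i <- which.min(abs(traj$times - time))
  }
  if (i < 1 || i > dim(traj$states)[1]) stop("snapshot index out of range")
  st <- traj$states[i, , , drop = FALSE]
  out <- as.data.frame(matrix(st, nrow = dim(traj$states)[2],
                              dimnames = list(NULL, dimnames(traj$states)[[3]])))
  out
}

# Reconstruct a swarm object from snapshot i (used for restart tests and
# the Markov property of the integrator).
#' Rebuild a swarm from a recorded snapshot
#' @inheritParams snapshot
#' @return A [swarm2d()] or [swarm3d()] positioned at that snapshot's time.
#' @export
swarm_at <- function(traj, i) {
  st <- snapshot(traj, i)
  if (traj$metadata$dimension == 2L) {
    swarm2d(st, traj$metadata$params, time = traj$times[i])
  } else {
    swarm3d(st, traj$metadata$params, time = traj$times[i])
  }
}

#' @export
as.data.frame.vf_trajectory <- function(x, ...) {
  d <- dim(x$states)
  fields <- dimnames(x$states)[[3]]
  out <- data.frame(
    time = rep(x$times, times = d[2]),
    agent_id = rep(seq_len(d[2]), each = d[1])
  )
  for (f in seq_along(fields)) {
    out[[fields[f]]] <- as.vector(x$states[, , f])
  }
  out <- out[order(out$time, out$agent_id), ]
  rownames(out) <- NULL
  out
}

# Snapshot indices whose times fall inside a window; default window is the
# second half of the run (the post-transient convention used throughout).
window_indices <- function(traj, window = NULL) {
  tt <- traj$times
  if (is.null(window)) {
    window <- c(tt[1] + (tt[length(tt)] - tt[1]) / 2, tt[length(tt)])
  }
  if (length(window) != 2 || window[2] < window[1]) {
    stop("window must be c(t_start, t_end) with t_start <= t_end")
  }
  idx <- which(tt >= window[1] - 1e-9 & tt <= window[2] + 1e-9)
  if (!length(idx)) stop("window contains no recorded snapshots")
  idx
}
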