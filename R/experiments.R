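config_defaults <- function() {
  list(dimension = 2L, N = NULL, n_steps = 20000L, record_every = 40L,
       seeds = 1L, box_side = NULL, params = list(), sweep = list(),
       output = NULL)
}

#' Load and validate an experiment configuration
#'
#' Reads a structured-text configuration (YAML or JSON, by file
#' extension), fills defaults, and validates every key.  Unknown keys are
#' rejected by name; parameter values are validated through [vf_params()]
#' (so e.g. a negative `dt` is a schema error); sweep axes must name model
#' parameters and have at least one value; `seeds` must be non-empty.
#'
#' Recognized top-level keys: `dimension` (2 or 3), `N` (required),
#' `n_steps`, `record_every`, `seeds`, `box_side`, `params` (sub-map of
#' [vf_params()] arguments), `sweep` (named map parameter -> value list),
#' `output` (CSV path for sweep summaries).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated list of class `vf_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    y <- yaml::read_yaml(path)
    # YAML 1.1 parses a bare `N` key as boolean FALSE; map it back
    names(y)[names(y) == "FALSE"] <- "N"
    y
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop_config("unsupported config format '.", ext, "' (use YAML or JSON)")
  }
  if (!is.list(raw)) stop_config("config must be a key-value mapping")
  defaults <- config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    stop_config("unknown configuration key: ", unknown[1])
  }
  cfg <- modifyList(defaults, raw, keep.null = TRUE)
  if (is.null(cfg$N)) stop_config("configuration key 'N' is required")
  if (!is.numeric(cfg$N) || cfg$N < 1) stop_config("'N' must be >= 1")
  cfg$N <- as.integer(cfg$N)
  if (!cfg$dimension %in% c(2, 3)) {
    stop_config("'dimension' must be 2 or 3")
  }
  cfg$dimension <- as.integer(cfg$dimension)
  if (!is.numeric(cfg$n_steps) || cfg$n_steps < 1) {
    stop_config("'n_steps' must be >= 1")
  }
  cfg$n_steps <- as.integer(cfg$n_steps)
  if (!is.numeric(cfg$record_every) || cfg$record_every < 1) {
    stop_config("'record_every' must be >= 1")
  }
  cfg$record_every <- as.integer(cfg$record_every)
  if (!length(cfg$seeds) || !is.numeric(unlist(cfg$seeds))) {
    stop_config("'seeds' must be a non-empty list of integers")
  }
  cfg$seeds <- as.integer(unlist(cfg$seeds))
  if (!is.null(cfg$box_side) &&
      (!is.numeric(cfg$box_side) || cfg$box_side <= 0)) {
    stop_config("'box_side' must be positive")
  }
  if (!is.list(cfg$params)) stop_config("'params' must be a mapping")
  bad <- setdiff(names(cfg$params), names(formals(vf_params)))
  if (length(bad)) stop_config("unknown parameter key: ", bad[1])
  cfg$params <- tryCatch(do.call(vf_params, cfg$params),
                         error = function(e) {
                           stop_config("invalid parameter: ",
                                       conditionMessage(e))
                         })
  if (!is.list(cfg$sweep)) stop_config("'sweep' must be a mapping")
  if (length(cfg$sweep)) {
    bad <- setdiff(names(cfg$sweep), names(formals(vf_params)))
    if (length(bad)) {
      stop_config("sweep axis is not a model parameter: ", bad[1])
    }
    for (ax in names(cfg$sweep)) {
      vals <- unlist(cfg$sweep[[ax]])
      if (!length(vals) || !is.numeric(vals)) {
        stop_config("sweep axis '", ax,
                    "' must list at least one numeric value")
      }
      cfg$sweep[[ax]] <- as.numeric(vals)
    }
  }
  structure(cfg, class = "vf_config")
}

set_param <- function(params, name, value) {
  p <- unclass(params)
  p[[name]] <- value
  do.call(vf_params, p)
}

failed_row <- function(N, params, seed, msg) {
  data.frame(N = N, alpha0 = params$alpha0, beta0 = params$beta0,
             alpha1 = params$alpha1, beta1 = params$beta1,
             lambda0 = params$lambda0, lambda1 = params$lambda1,
             seed = seed, polarization = NA_real_, mean_nnd = NA_real_,
             min_dist = NA_real_, extent_xy = NA_real_,
             extent_z = NA_real_, error = msg)
}

sweep_cell <- function(cfg, params, seed, dimension) {
  tryCatch({
    sw <- if (dimension == 2L) {
      init_swarm(cfg$N, params, seed, cfg$box_side)
    } else {
      init_swarm_3d(cfg$N, params, seed, cfg$box_side)
    }
    tr <- run_swarm(sw, cfg$n_steps, cfg$record_every)
    cbind(summarize_run(tr), error = NA_character_)
  }, error = function(e) {
    failed_row(cfg$N, params, seed, conditionMessage(e))
  })
}

#' Sweep the (alpha0, beta0) plane of the 2D model
#'
#' Runs one seeded simulation per `(alpha0, beta0, seed)` combination of
#' the config's sweep axes and collects one [summarize_run()] row each.
#' Failed cells are recorded (metrics `NA`, message in the `error`
#' column) and the sweep continues.  Rows are independent: re-running a
#' single cell standalone reproduces its row.
#'
#' @param config A `vf_config` from [load_config()] with `dimension: 2`
#'   and sweep axes `alpha0` and `beta0`.
#' @return Data frame of summary rows; also written as CSV to
#'   `config$output` when set.
#' @export
phase_sweep_2d <- function(config) {
  if (!inherits(config, "vf_config")) stop("config must come from load_config")
  if (config$dimension != 2L) {
    stop_config("phase_sweep_2d requires dimension 2")
  }
  if (is.null(config$sweep$alpha0) || is.null(config$sweep$beta0)) {
    stop_config("phase_sweep_2d requires sweep axes 'alpha0' and 'beta0'")
  }
  rows <- list()
  for (a0 in config$sweep$alpha0) {
    for (b0 in config$sweep$beta0) {
      p <- set_param(set_param(config$params, "alpha0", a0), "beta0", b0)
      for (seed in config$seeds) {
        rows[[length(rows) + 1L]] <- sweep_cell(config, p, seed, 2L)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(config$output)) {
    utils::write.csv(out, config$output, row.names = FALSE)
  }
  out
}

#' Sweep the vertical edge coefficient of the 3D model
#'
#' One seeded 3D run per `(lambda1, seed)`; the summary rows include the
#' vertical extent, the quantity whose sharp change with `lambda1`
#' signals the flattening transition.
#'
#' @param config A `vf_config` with `dimension: 3` and sweep axis
#'   `lambda1`.
#' @return Data frame of summary rows (CSV written to `config$output`
#'   when set).
#' @export
lambda_sweep_3d <- function(config) {
  if (!inherits(config, "vf_config")) stop("config must come from load_config")
  if (config$dimension != 3L) {
    stop_config("lambda_sweep_3d requires dimension 3")
  }
  if (is.null(config$sweep$lambda1) || !length(config$sweep$lambda1)) {
    stop_config("lambda_sweep_3d requires a non-empty sweep axis 'lambda1'")
  }
  rows <- list()
  for (l1 in config$sweep$lambda1) {
    p <- set_param(config$params, "lambda1", l1)
    for (seed in config$seeds) {
      rows[[length(rows) + 1L]] <- sweep_cell(config, p, seed, 3L)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(config$output)) {
    utils::write.csv(out, config$output, row.names = FALSE)
  }
  out
}

#' Write a trajectory to plain text
#'
#' Long-format CSV (`time, agent_id, state fields...`) with full `%.17g`
#' precision plus a JSON metadata sidecar at `<path>.json` (parameters,
#' seed, dimension, recording stride, per-step minimum-distance series).
#' [read_trajectory()] reproduces the trajectory exactly.
#'
#' @param traj A [vf_trajectory()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  if (!inherits(traj, "vf_trajectory")) stop("traj must be a vf_trajectory")
  df <- as.data.frame(traj)
  fmt <- df
  for (nm in names(fmt)) {
    if (is.double(fmt[[nm]])) fmt[[nm]] <- sprintf("%.17g", fmt[[nm]])
  }
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  meta <- traj$metadata
  smd <- meta$step_min_dist
  if (!is.null(smd)) {
    smd$min_dist[!is.finite(smd$min_dist)] <- NA_real_
  }
  jsonlite::write_json(
    list(dimension = meta$dimension,
         params = unclass(meta$params),
         seed = meta$seed,
         record_steps = meta$record_steps,
         times = traj$times,
         step_min_dist = smd),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, na = "null", null = "null")
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV path (the `<path>.json` sidecar must sit next to it).
#' @param dimension Optional expected model dimension (2 or 3); a mismatch
#'   with the stored metadata is an error.
#' @return A [vf_trajectory()].
#' @export
read_trajectory <- function(path, dimension = NULL) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) {
    stop("metadata sidecar not found: ", meta_path)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!is.null(dimension) && as.integer(dimension) != meta$dimension) {
    stop("dimension mismatch: file holds a ", meta$dimension,
         "D trajectory, expected ", dimension, "D")
  }
  df <- utils::read.csv(path)
  if (!nrow(df)) stop("empty trajectory file: ", path)
  fields <- setdiff(names(df), c("time", "agent_id"))
  times <- sort(unique(df$time))
  agents <- sort(unique(df$agent_id))
  df <- df[order(df$time, df$agent_id), ]
  states <- array(NA_real_,
                  dim = c(length(times), length(agents), length(fields)),
                  dimnames = list(NULL, NULL, fields))
  for (f in seq_along(fields)) {
    states[, , f] <- matrix(df[[fields[f]]], nrow = length(times),
                            byrow = TRUE)
  }
  params <- do.call(vf_params,
                    meta$params[intersect(names(meta$params),
                                          names(formals(vf_params)))])
  smd <- meta$step_min_dist
  if (!is.null(smd)) {
    smd <- list(times = as.numeric(smd$times),
                min_dist = as.numeric(smd$min_dist))
    smd$min_dist[is.na(smd$min_dist)] <- Inf
  }
  vf_trajectory(times, states,
                metadata = list(dimension = as.integer(meta$dimension),
                                params = params,
                                seed = meta$seed %||% NA_integer_,
                                record_steps = meta$record_steps,
                                step_min_dist = smd))
}

#' Canonical deterministic test configurations
#'
#' Named agent arrangements used throughout the test suite and useful for
#' exploring the model interactively:
#' \describe{
#'   \item{`pair_front_back(d)`}{two agents with a common heading, `d` BL
#'     apart along the heading axis;}
#'   \item{`pair_side(d)`}{two agents side by side, `d` BL apart
#'     perpendicular to the common heading;}
#'   \item{`line(N, spacing)`}{`N` agents along a line perpendicular to
#'     their common heading;}
#'   \item{`ring(N, radius)`}{`N` agents on a circle with tangential
#'     headings;}
#'   \item{`random_box(N, seed, box_side)`}{the seeded random
#'     initialization of [init_swarm()] / [init_swarm_3d()].}
#' }
#' All speeds start at `v0`.  With `dimension = 3` the configurations are
#' embedded at exactly `z = 0` with `v_z = 0` (no jitter), which is the
#' invariant plane of the 3D dynamics.
#'
#' @param name One of `"pair_front_back"`, `"pair_side"`, `"line"`,
#'   `"ring"`, `"random_box"`.
#' @param ... Arguments of the chosen fixture (see above).
#' @param params A [vf_params()] object.
#' @param dimension 2 or 3.
#' @return A [swarm2d()] or [swarm3d()].
#' @export
make_fixture <- function(name, ..., params = vf_params(), dimension = 2) {
  args <- list(...)
  v0 <- params$v0
  st <- switch(
    name,
    pair_front_back = {
      d <- args$d %||% args[[1]]
      data.frame(x = c(0, d), y = c(0, 0), v = v0, psi = 0)
    },
    pair_side = {
      d <- args$d %||% args[[1]]
      data.frame(x = c(0, 0), y = c(0, d), v = v0, psi = 0)
    },
    line = {
      N <- args$N %||% args[[1]]
      spacing <- args$spacing %||% args[[2]]
      data.frame(x = 0, y = (seq_len(N) - 1) * spacing, v = v0, psi = 0)
    },
    ring = {
      N <- args$N %||% args[[1]]
      radius <- args$radius %||% args[[2]]
      ang <- 2 * pi * (seq_len(N) - 1) / N
      data.frame(x = radius * cos(ang), y = radius * sin(ang),
                 v = v0, psi = wrap_angle(ang + pi / 2))
    },
    random_box = {
      N <- args$N %||% args[[1]]
      seed <- args$seed %||% 1L
      box <- args$box_side %||% NULL
      return(if (dimension == 2) {
        init_swarm(N, params, seed, box)
      } else {
        init_swarm_3d(N, params, seed, box)
      })
    },
    stop("unknown fixture name: ", name)
  )
  if (dimension == 2) {
    swarm2d(st, params)
  } else {
    swarm3d(data.frame(x = st$x, y = st$y, z = 0,
                       v_psi = st$v, psi = st$psi, v_z = 0),
            params)
  }
}
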