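#' Wrap angles to the retina convention
#'
#' Maps arbitrary angles to the half-open interval \eqn{(-\pi, \pi]} used
#' throughout the package for headings, bearings and retina coordinates
#' (positive angles are to the left of, i.e. counter-clockwise from, the
#' focal heading).
#'
#' @param x Numeric vector of angles in radians.
#' @return Numeric vector of the same length with values in \eqn{(-\pi, \pi]}.
#' @examples
#' wrap_angle(c(0, 3 * pi, -pi))
#' @export
wrap_angle <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce an agent argument (named list, one-row data frame, or swarm row)
# into a plain list; errors mention the missing field.
as_agent <- function(a, fields) {
  if (inherits(a, "vf_swarm")) {
    stop("pass a single agent state (one row of swarm$state), not a swarm")
  }
  a <- as.list(a)
  missing <- setdiff(fields, names(a))
  if (length(missing)) {
    stop("agent state is missing field(s): ", paste(missing, collapse = ", "))
  }
  lapply(a[fields], as.numeric)
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("vf_config_error", "error")))
}
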