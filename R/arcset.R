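#' Arc sets: the binary visual projection field in 2D
#'
#' An `arcset` represents the occupied part of the 1D retina of a disk
#' agent: a union of disjoint angular intervals in the retina coordinate
#' \eqn{\varphi \in (-\pi, \pi]}, measured from the focal agent's heading
#' with positive angles to the left.  Arcs that cross the \eqn{\pm\pi} cut
#' are stored split into two entries; the split points at exactly
#' \eqn{\pm\pi} are bookkeeping artifacts and are not reported as edges.
#'
#' @param lo,hi Numeric vectors of arc endpoints in \eqn{[-\pi, \pi]} with
#'   `lo < hi` elementwise, pairwise disjoint.
#' @return An object of class `arcset` with fields `lo` and `hi` (sorted by
#'   `lo`).
#' @seealso [occlusion_union()], [field_edges()], [weighted_area_integral()]
#' @examples
#' a <- arcset(lo = c(-pi / 6), hi = c(pi / 6))
#' arc_measure(a)
#' @export
arcset <- function(lo = numeric(), hi = numeric()) {
  lo <- as.numeric(lo)
  hi <- as.numeric(hi)
  if (length(lo) != length(hi)) stop("lo and hi must have equal length")
  if (length(lo)) {
    if (any(!is.finite(lo)) || any(!is.finite(hi))) {
      stop("arc endpoints must be finite")
    }
    if (any(lo < -pi - 1e-12) || any(hi > pi + 1e-12)) {
      stop("arc endpoints must lie in [-pi, pi]")
    }
    if (any(hi <= lo)) stop("each arc must have positive measure (lo < hi)")
    o <- order(lo)
    lo <- lo[o]
    hi <- hi[o]
    n <- length(lo)
    if (n > 1 && any(lo[-1] < hi[-n] - 1e-12)) {
      stop("arcs must be pairwise disjoint")
    }
    if (sum(hi - lo) > 2 * pi + 1e-9) {
      stop("total arc measure cannot exceed 2*pi")
    }
  }
  structure(list(lo = lo, hi = hi), class = "arcset")
}

new_arcset <- function(lo, hi) structure(list(lo = lo, hi = hi),
                                         class = "arcset")

#' @export
print.arcset <- function(x, ...) {
  n <- length(x$lo)
  cat(sprintf("<arcset: %d arc%s, measure %.4f rad>\n",
              n, if (n == 1) "" else "s", arc_measure(x)))
  if (n) {
    for (k in seq_len(n)) {
      cat(sprintf("  [%+.4f, %+.4f]\n", x$lo[k], x$hi[k]))
    }
  }
  invisible(x)
}

#' Total angular measure of an arc set
#'
#' @param field An [arcset()].
#' @return Total measure in radians, between 0 and \eqn{2\pi}.
#' @export
arc_measure <- function(field) {
  if (!inherits(field, "arcset")) stop("field must be an arcset")
  sum(field$hi - field$lo)
}

#' Angular projection of one disk neighbor
#'
#' Computes the retinal image of a single neighbor: the eye sits at the
#' center of the focal disk with a fully circular point of view (no blind
#' angles), so a neighbor of diameter `BL` at center-to-center distance `d`
#' subtends a half-width `asin(min(1, BL / (2 d)))` about its bearing.
#' Overlapping bodies (`d < BL`) clamp the half-width at \eqn{\pi/2}: the
#' model has no hard-core exclusion and a disk at contact fills the visual
#' half-plane.
#'
#' @param focal Focal agent state: anything with fields `x`, `y`, `psi`
#'   (a named list or one-row data frame).
#' @param neighbor Neighbor state with fields `x`, `y`.
#' @param BL Body length (disk diameter).
#' @return List with `center` (bearing relative to the focal heading, in
#'   \eqn{(-\pi, \pi]}) and `half_width` (in \eqn{(0, \pi/2]}).
#' @examples
#' subtended_arc(list(x = 0, y = 0, psi = 0), list(x = 1, y = 0), BL = 1)
#' @export
subtended_arc <- function(focal, neighbor, BL = 1) {
  f <- as_agent(focal, c("x", "y", "psi"))
  nb <- as_agent(neighbor, c("x", "y"))
  dx <- nb$x - f$x
  dy <- nb$y - f$y
  d <- sqrt(dx^2 + dy^2)
  if (d == 0) {
    stop("degenerate geometry: focal and neighbor positions coincide")
  }
  list(center = wrap_angle(atan2(dy, dx) - f$psi),
       half_width = asin(min(1, BL / (2 * d))))
}

#' Occlusion-resolved union of retinal arcs
#'
#' The binary visual field retains no depth: a nearer body hiding a farther
#' one is simply the set union of their projections.  Input arcs are given
#' as (center, half-width) pairs; the result is a normalized [arcset()]
#' (disjoint, sorted, wrapping arcs split at \eqn{\pm\pi}).
#'
#' @param centers Either a numeric vector of arc centers, or a list of
#'   `(center, half_width)` pairs as returned by [subtended_arc()] (in which
#'   case `half_widths` is omitted).
#' @param half_widths Numeric vector of half-widths in \eqn{(0, \pi/2]}.
#' @return An [arcset()]; empty input gives an empty arc set.
#' @examples
#' occlusion_union(c(0, 1.1), c(0.1, 0.1))
#' @export
occlusion_union <- function(centers, half_widths = NULL) {
  if (is.null(half_widths)) {
    if (!length(centers)) return(new_arcset(numeric(), numeric()))
    half_widths <- vapply(centers, function(a) a$half_width, numeric(1))
    centers <- vapply(centers, function(a) a$center, numeric(1))
  }
  centers <- as.numeric(centers)
  half_widths <- as.numeric(half_widths)
  if (length(centers) != length(half_widths)) {
    stop("centers and half_widths must have equal length")
  }
  if (!length(centers)) return(new_arcset(numeric(), numeric()))
  if (any(!is.finite(centers)) || any(!is.finite(half_widths))) {
    stop("arc centers and half-widths must be finite")
  }
  if (any(half_widths <= 0) || any(half_widths > pi / 2 + 1e-12)) {
    stop("half-widths must lie in (0, pi/2]")
  }
  lo <- wrap_angle(centers) - half_widths
  hi <- lo + 2 * half_widths
  shift <- lo < -pi
  lo[shift] <- lo[shift] + 2 * pi
  hi[shift] <- hi[shift] + 2 * pi
  w <- hi > pi
  lo2 <- c(lo[!w], lo[w], rep(-pi, sum(w)))
  hi2 <- c(hi[!w], rep(pi, sum(w)), hi[w] - 2 * pi)
  keep <- hi2 > lo2
  lo2 <- lo2[keep]
  hi2 <- hi2[keep]
  o <- order(lo2)
  lo2 <- lo2[o]
  hi2 <- hi2[o]
  mlo <- mhi <- numeric(0)
  cl <- lo2[1]
  ch <- hi2[1]
  for (k in seq_along(lo2)[-1]) {
    if (lo2[k] <= ch + 1e-12) {
      ch <- max(ch, hi2[k])
    } else {
      mlo <- c(mlo, cl)
      mhi <- c(mhi, ch)
      cl <- lo2[k]
      ch <- hi2[k]
    }
  }
  new_arcset(c(mlo, cl), c(mhi, ch))
}

#' Visual projection field of a focal agent
#'
#' Convenience wrapper: projects every other agent onto the focal retina
#' and resolves occlusion.  Positions in the same plane, lengths in BL.
#'
#' @param focal Focal agent state with fields `x`, `y`, `psi`.
#' @param others Data frame (or list coercible to one) of the remaining
#'   agents with columns `x`, `y`; zero rows give an empty field.
#' @param BL Body length.
#' @return An [arcset()].
#' @export
visual_field <- function(focal, others, BL = 1) {
  others <- as.data.frame(others)
  if (!nrow(others)) return(new_arcset(numeric(), numeric()))
  f <- as_agent(focal, c("x", "y", "psi"))
  dx <- others$x - f$x
  dy <- others$y - f$y
  d <- sqrt(dx^2 + dy^2)
  if (any(d == 0)) {
    stop("degenerate geometry: a neighbor coincides with the focal agent")
  }
  occlusion_union(wrap_angle(atan2(dy, dx) - f$psi),
                  asin(pmin(1, BL / (2 * d))))
}

#' Edges of the visual field
#'
#' Returns the angular positions of the boundaries of the occupied retina
#' (two per maximal arc).  Boundaries at exactly \eqn{\pm\pi} are dropped
#' when the field is continuous across the cut, since they are artifacts of
#' storing wrapping arcs split; a fully saturated retina therefore has no
#' edges and an empty field likewise.
#'
#' @param field An [arcset()].
#' @return Sorted numeric vector of edge angles (possibly empty).
#' @export
field_edges <- function(field) {
  if (!inherits(field, "arcset")) stop("field must be an arcset")
  lo <- field$lo
  hi <- field$hi
  n <- length(lo)
  if (!n) return(numeric())
  tol <- 1e-9
  wrap_cont <- lo[1] <= -pi + tol && hi[n] >= pi - tol
  if (wrap_cont) {
    e <- c(lo[-1], hi[-n])
  } else {
    e <- c(lo, hi)
  }
  sort(e)
}

#' Trigonometric area functional of the visual field
#'
#' Exact integral \eqn{\int \mathrm{kernel}(\varphi)\, V(\varphi)\,
#' d\varphi} of the binary field against a cosine or sine kernel.  The
#' cosine-weighted area drives the speed response (front-back), the
#' sine-weighted area the turning response (left-right); both are repulsive
#' in the equations of motion, entering with a minus sign.
#'
#' @param field An [arcset()].
#' @param kernel `"cos"` or `"sin"`.
#' @return The exact integral (closed form over each arc).
#' @examples
#' weighted_area_integral(arcset(-pi / 6, pi / 6), "cos")  # 2*sin(pi/6) = 1
#' @export
weighted_area_integral <- function(field, kernel = c("cos", "sin")) {
  if (!inherits(field, "arcset")) stop("field must be an arcset")
  kernel <- match.arg(kernel)
  if (!length(field$lo)) return(0)
  if (kernel == "cos") {
    sum(sin(field$hi) - sin(field$lo))
  } else {
    sum(cos(field$lo) - cos(field$hi))
  }
}

#' Trigonometric edge functional of the visual field
#'
#' The edge response of a binary field concentrates on the arc boundaries.
#' The squared retinal derivative of an indicator function is interpreted
#' as a unit-weight Dirac comb: each edge contributes `kernel(angle)`
#' exactly once, independent of any retina discretization.  This keeps the
#' edge coefficients `alpha1`, `beta1` dimensionless and reproduces the
#' far-field front-back equilibrium distance `BL / (2 * alpha1)`.
#'
#' @param edges Numeric vector of edge angles, as from [field_edges()].
#' @param kernel `"cos"` or `"sin"`.
#' @return Sum of the kernel over the edges (0 for no edges).
#' @examples
#' weighted_edge_sum(c(-pi / 6, pi / 6), "cos")  # sqrt(3)
#' @export
weighted_edge_sum <- function(edges, kernel = c("cos", "sin")) {
  kernel <- match.arg(kernel)
  if (!length(edges)) return(0)
  if (kernel == "cos") sum(cos(edges)) else sum(sin(edges))
}
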