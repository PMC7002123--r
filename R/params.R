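#' Model parameters
#'
#' Bundles every coefficient of the vision-based interaction model together
#' with the integration settings.  All lengths are measured in body lengths
#' (BL, the agent diameter) and time in units of BL divided by the preferred
#' speed, so the defaults `BL = 1`, `v0 = 1`, `gamma = 1` fix the natural
#' units of the model; all three remain configurable.
#'
#' The interaction terms act on the binary visual projection field of the
#' focal agent: the subtended-angle (area) terms with overall strengths
#' `alpha0` (speed response) and `beta0` (turning response) are repulsive,
#' while the edge terms, weighted by the dimensionless coefficients
#' `alpha1` and `beta1`, are attractive.  Their balance sets the front-back
#' equilibrium distance `BL / (2 * alpha1)` (far field) and the left-right
#' analogue `BL / (2 * beta1)`.  `lambda0` and `lambda1` are the vertical
#' counterparts used only by the 3D cylindrical model.  `alpha2` and `beta2`
#' are hooks for temporal-derivative (optical-flow) responses; they are
#' stored but the implemented dynamics are purely instantaneous, so both
#' default to zero and are ignored by the integrators.
#'
#' @param gamma Speed relaxation rate (1/time), non-negative.
#' @param v0 Preferred speed (BL/time), non-negative.
#' @param alpha0,beta0 Overall strength of the speed and turning responses.
#' @param alpha1,beta1 Dimensionless edge-attraction coefficients
#'   (non-negative).  A printed equilibrium length `L` corresponds to
#'   `alpha1 = BL / (2 * L)` in the far field.
#' @param alpha2,beta2 Temporal-derivative hooks, default 0 (unused).
#' @param lambda0,lambda1 Vertical response strength and edge coefficient
#'   (3D model only).
#' @param BL Body length: agent diameter and the length unit, positive.
#' @param dt Explicit-Euler time step, positive.  The default 0.05 (in units
#'   of BL/v0) is adequate for moderate response strengths; stiff settings
#'   (large `beta0` or `lambda0`) warrant a smaller step.
#' @param retina_n_phi,retina_n_theta Spherical retina resolution for the 3D
#'   model (azimuth x elevation cells, each at least 8; `retina_n_theta`
#'   should be even so the grid is symmetric about the horizon).
#' @return An object of class `vf_params` (a validated named list).
#' @examples
#' p <- vf_params(alpha0 = 0.2, beta0 = 0.01, alpha1 = 0.08, beta1 = 0.08)
#' p$alpha1
#' @export
vf_params <- function(gamma = 1, v0 = 1,
                      alpha0 = 1, alpha1 = 0.08, alpha2 = 0,
                      beta0 = 1, beta1 = 0.08, beta2 = 0,
                      lambda0 = 0, lambda1 = 0.08,
                      BL = 1, dt = 0.05,
                      retina_n_phi = 128L, retina_n_theta = 64L) {
  p <- list(gamma = as.numeric(gamma), v0 = as.numeric(v0),
            alpha0 = as.numeric(alpha0), alpha1 = as.numeric(alpha1),
            alpha2 = as.numeric(alpha2),
            beta0 = as.numeric(beta0), beta1 = as.numeric(beta1),
            beta2 = as.numeric(beta2),
            lambda0 = as.numeric(lambda0), lambda1 = as.numeric(lambda1),
            BL = as.numeric(BL), dt = as.numeric(dt),
            retina_n_phi = as.integer(retina_n_phi),
            retina_n_theta = as.integer(retina_n_theta))
  validate_vf_params(structure(p, class = "vf_params"))
}

validate_vf_params <- function(p) {
  scalar <- function(nm) {
    if (length(p[[nm]]) != 1 || !is.finite(p[[nm]])) {
      stop("parameter '", nm, "' must be a single finite number")
    }
  }
  for (nm in names(p)) scalar(nm)
  if (p$gamma < 0) stop("gamma must be >= 0")
  if (p$v0 < 0) stop("v0 must be >= 0")
  if (p$BL <= 0) stop("BL must be > 0")
  if (p$dt <= 0) stop("dt must be > 0")
  if (p$alpha1 < 0) stop("alpha1 must be >= 0")
  if (p$beta1 < 0) stop("beta1 must be >= 0")
  if (p$lambda1 < 0) stop("lambda1 must be >= 0")
  if (p$retina_n_phi < 8L) stop("retina_n_phi must be >= 8")
  if (p$retina_n_theta < 8L) stop("retina_n_theta must be >= 8")
  p
}

#' @export
print.vf_params <- function(x, ...) {
  cat("Vision-based flocking model parameters\n")
  cat(sprintf("  self-propulsion: gamma = %g, v0 = %g (BL = %g, dt = %g)\n",
              x$gamma, x$v0, x$BL, x$dt))
  cat(sprintf("  speed response:  alpha0 = %g, alpha1 = %g\n",
              x$alpha0, x$alpha1))
  cat(sprintf("  turn response:   beta0 = %g, beta1 = %g\n",
              x$beta0, x$beta1))
  cat(sprintf("  vertical (3D):   lambda0 = %g, lambda1 = %g, retina %d x %d\n",
              x$lambda0, x$lambda1, x$retina_n_phi, x$retina_n_theta))
  if (x$alpha2 != 0 || x$beta2 != 0) {
    cat("  note: alpha2/beta2 are stored but ignored by the dynamics\n")
  }
  invisible(x)
}

# Equilibrium length implied by an edge coefficient; used for default box
# sizes.  alpha1 = 0 means no attraction, fall back to 5 BL spacing.
leq_from_coef <- function(coef, BL) {
  if (coef > 0) BL / (2 * coef) else 5 * BL
}
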