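#' Active smooth-muscle-cell material parameters
#'
#' Parameters of the asymmetric triaxial SMC contraction law. Along the cell
#' axis the active stress is a skewed parabola peaking at `sigma_max` when
#' the cell stretch equals `lam_max`; the transverse (in-plane perpendicular)
#' stress is the same law scaled by `tau`; the radial response is linear with
#' stiffness `k_smc_radial`. `activation` gates the whole law (0 = passive,
#' 1 = maximal potassium-induced contraction). Defaults are the refined-fit
#' averages for porcine coronary arteries.
#'
#' @param rho1 Curvature parameter (MPa).
#' @param rho2 Skewness parameter (dimensionless); 0 gives a symmetric curve,
#'   positive values a gentler rise below `lam_max` than the fall above it.
#' @param lam_max Optimal cell stretch (dimensionless).
#' @param sigma_max Peak active stress at `lam_max` (MPa).
#' @param tau Transverse-to-longitudinal active stress ratio (dimensionless).
#' @param k_smc_radial Radial active stiffness (MPa).
#' @param activation Activation level in `[0, 1]`.
#' @param clamp If `TRUE` (default) negative values of the longitudinal /
#'   transverse law far from `lam_max` are clamped to zero (a contracting
#'   cell is not assigned active compression).
#' @return An object of class `smc_active_params`.
#' @export
smc_active_params <- function(rho1 = 0.31, rho2 = 1.43, lam_max = 1.34,
                              sigma_max = 0.09, tau = 0.23,
                              k_smc_radial = 0.01, activation = 1,
                              clamp = TRUE) {
  if (rho1 < 0 || sigma_max < 0 || k_smc_radial < 0 || tau < 0) {
    abort("`rho1`, `sigma_max`, `tau` and `k_smc_radial` must be >= 0.")
  }
  if (lam_max <= 0) abort("`lam_max` must be positive.")
  if (activation < 0 || activation > 1) abort("`activation` must lie in [0, 1].")
  structure(
    list(
      rho1 = rho1, rho2 = rho2, lam_max = lam_max, sigma_max = sigma_max,
      tau = tau, k_smc_radial = k_smc_radial, activation = activation,
      clamp = isTRUE(clamp)
    ),
    class = "smc_active_params"
  )
}

#' Active SMC stress laws
#'
#' `smc_longitudinal_stress()` evaluates the cell-axis law
#' `A * (rho1/2 * (lam_max^rho2 - lam^rho2 - 2) * (lam - lam_max)^2 + sigma_max)`;
#' `smc_transverse_stress()` is the same law scaled by `tau` at the
#' transverse stretch; `smc_radial_stress()` is the linear radial law
#' `A * k_smc_radial * lam_r`. Longitudinal and transverse values are clamped
#' at zero when `p$clamp` is set.
#'
#' @param lam,lam_t,lam_r Stretch(es) along the cell axis, transverse axis,
#'   and radial axis (dimensionless, > 0).
#' @param p An [smc_active_params()].
#' @return Active stress(es) in MPa.
#' @export
#' @examples
#' p <- smc_active_params()
#' smc_longitudinal_stress(p$lam_max, p) # equals sigma_max at the optimum
smc_longitudinal_stress <- function(lam, p) {
  stopifnot(inherits(p, "smc_active_params"))
  raw <- p$activation * (
    0.5 * p$rho1 * (p$lam_max^p$rho2 - lam^p$rho2 - 2) * (lam - p$lam_max)^2 +
      p$sigma_max
  )
  if (p$clamp) pmax(raw, 0) else raw
}

#' @rdname smc_longitudinal_stress
#' @export
smc_transverse_stress <- function(lam_t, p) {
  p$tau * smc_longitudinal_stress(lam_t, p)
}

#' @rdname smc_longitudinal_stress
#' @export
smc_radial_stress <- function(lam_r, p) {
  stopifnot(inherits(p, "smc_active_params"))
  p$activation * p$k_smc_radial * lam_r
}

# Vectorised active SMC 2nd PK stress over strain-state vectors, given the
# SMC orientation nodes of a layer plan. Chain rule: for
# lam = sqrt(n . (I + 2E) . n), d(lam)/dE = (n (x) n) / lam; the cells lie in
# the theta-z plane so n = (cos th, 0, sin th), n' = (-sin th, 0, cos th),
# and the radial stretch of the cell equals the wall radial stretch.
smc_stress_nodes <- function(Ett, Err, Ezz, smc_plan, p) {
  n <- length(Ett)
  if (p$activation == 0) {
    return(list(S_tt = numeric(n), S_rr = numeric(n), S_zz = numeric(n)))
  }
  Ctt <- 1 + 2 * Ett
  Crr <- 1 + 2 * Err
  Czz <- 1 + 2 * Ezz
  if (any(Ctt <= 0) || any(Crr <= 0) || any(Czz <= 0)) {
    abort("Invalid strain state: right Cauchy-Green tensor not positive.")
  }
  c2 <- cos(smc_plan$theta)^2
  s2 <- sin(smc_plan$theta)^2
  lam2 <- tcrossprod(Ctt, c2) + tcrossprod(Czz, s2) # cell-axis stretch^2, n x theta
  lamt2 <- tcrossprod(Ctt, s2) + tcrossprod(Czz, c2) # transverse stretch^2
  lam <- sqrt(lam2)
  lamt <- sqrt(lamt2)
  sig_l <- smc_longitudinal_stress(lam, p)
  sig_t <- smc_transverse_stress(lamt, p)
  wl <- sig_l / lam
  wt_ <- sig_t / lamt
  S_tt <- drop(wl %*% (smc_plan$wt * c2)) + drop(wt_ %*% (smc_plan$wt * s2))
  S_zz <- drop(wl %*% (smc_plan$wt * s2)) + drop(wt_ %*% (smc_plan$wt * c2))
  lam_r <- sqrt(Crr)
  S_rr <- smc_radial_stress(lam_r, p) / lam_r # orientation-independent
  list(S_tt = S_tt, S_rr = rep(S_rr, length.out = n), S_zz = S_zz)
}

#' Active second Piola-Kirchhoff stress of the SMC family
#'
#' Orientation average, over the mirrored medial SMC family, of the triaxial
#' chain-rule terms `sigma_l d(lam)/dE + sigma_t d(lam')/dE + sigma_r d(lam'')/dE`
#' with `d(lam)/dE = (n (x) n) / lam`. The cells lie in the
#' circumferential-axial plane; the radial cell stretch is the wall radial
#' stretch.
#'
#' @param E 3x3 Green-Lagrange strain matrix, (theta, r, z) basis.
#' @param micro A [microstructure_config()] (supplies the SMC orientation
#'   family).
#' @param p An [smc_active_params()].
#' @param quadrature A [quadrature_spec()].
#' @return A 3x3 diagonal stress matrix (MPa). Zero when `p$activation = 0`.
#' @export
smc_second_pk <- function(E, micro, p, quadrature = quadrature_spec()) {
  stopifnot(inherits(micro, "microstructure_config"))
  plan <- orientation_nodes(micro$media_smc, quadrature$n_angle)
  d <- diag_strain(E)
  S <- smc_stress_nodes(d$tt, d$rr, d$zz, plan, p)
  as_stress_tensor(S$S_tt, S$S_rr, S$S_zz)
}
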