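#' Zero-stress-state reference geometry of an artery segment
#'
#' The stress-free reference configuration of an artery is the radially
#' cut-open sector obtained after releasing residual stresses: an annular
#' sector with outer radius `R_outer`, inner radius `R_inner`, opening angle
#' `opening_angle` and axial length `length_ref`.
#'
#' @param R_outer,R_inner Outer and inner radii of the stress-free sector (mm).
#' @param opening_angle Opening angle of the cut-open sector (radians),
#'   in `[0, pi)`. Zero recovers a closed, residual-stress-free tube.
#' @param length_ref Axial length of the reference segment (mm).
#' @return An object of class `reference_geometry`.
#' @export
#' @examples
#' reference_geometry(R_outer = 2.5, R_inner = 1.75, opening_angle = 1.4)
reference_geometry <- function(R_outer, R_inner, opening_angle, length_ref = 10) {
  stopifnot(is.numeric(R_outer), is.numeric(R_inner), is.numeric(opening_angle))
  if (!(R_outer > R_inner && R_inner > 0)) {
    abort("`R_outer` must exceed `R_inner` and both must be positive.")
  }
  if (opening_angle < 0 || opening_angle >= pi) {
    abort("`opening_angle` must lie in [0, pi).")
  }
  if (length_ref <= 0) abort("`length_ref` must be positive.")
  structure(
    list(
      R_outer = as.numeric(R_outer), R_inner = as.numeric(R_inner),
      opening_angle = as.numeric(opening_angle),
      length_ref = as.numeric(length_ref)
    ),
    class = "reference_geometry"
  )
}

#' @export
print.reference_geometry <- function(x, ...) {
  cat(sprintf(
    "<reference_geometry> R_o = %.4g mm, R_i = %.4g mm, Theta = %.4g rad, L = %.4g mm\n",
    x$R_outer, x$R_inner, x$opening_angle, x$length_ref
  ))
  invisible(x)
}

# Sector factor (pi - Theta) / (lambda_z * pi) entering the incompressible map.
sector_factor <- function(geom, lam_z) (pi - geom$opening_angle) / (lam_z * pi)

#' Incompressible map from reference to loaded radius
#'
#' Maps a material point at radius `R_ref` in the zero-stress sector to its
#' radius in the loaded (pressurised, axially stretched) tube, under
#' incompressibility and axisymmetry:
#' `r(R) = sqrt(r_outer^2 - (R_outer^2 - R^2) * (pi - Theta) / (lambda_z * pi))`.
#'
#' @param R_ref Reference radius (mm), in `[R_inner, R_outer]`. Vectorised.
#' @param geom A [reference_geometry()].
#' @param lam_z Axial stretch of the loaded tube relative to the reference
#'   length (dimensionless, > 0).
#' @param r_outer Loaded outer radius (mm).
#' @return Loaded radius (mm), same length as `R_ref`.
#' @export
#' @examples
#' g <- reference_geometry(4, 3, 1.571)
#' loaded_radius(3.5, g, lam_z = 1.3, r_outer = 3.5)
loaded_radius <- function(R_ref, geom, lam_z, r_outer) {
  stopifnot(inherits(geom, "reference_geometry"), lam_z > 0, r_outer > 0)
  if (any(R_ref < geom$R_inner - 1e-12 | R_ref > geom$R_outer + 1e-12)) {
    abort("`R_ref` must lie within [R_inner, R_outer].")
  }
  k <- sector_factor(geom, lam_z)
  arg <- r_outer^2 - (geom$R_outer^2 - R_ref^2) * k
  if (any(arg < 0)) {
    abort(paste0(
      "Invalid loaded configuration: the incompressible radius map has a ",
      "negative square-root argument (r_outer too small for this axial stretch)."
    ))
  }
  sqrt(arg)
}

#' Loaded inner radius implied by incompressibility
#'
#' @inheritParams loaded_radius
#' @return Loaded inner radius (mm).
#' @export
inner_radius <- function(geom, lam_z, r_outer) {
  loaded_radius(geom$R_inner, geom, lam_z, r_outer)
}

#' Principal stretches through the wall
#'
#' Circumferential, radial and axial stretches of the distended-extended tube
#' at reference radius `R_ref`. The circumferential stretch carries the
#' residual-stress sector factor, `lambda_theta = (pi / (pi - Theta)) * r / R`;
#' the radial stretch is the analytic derivative of the radius map; their
#' product with `lambda_z` is 1 (incompressibility).
#'
#' @inheritParams loaded_radius
#' @return A tibble with columns `R_ref`, `r`, `lambda_theta`, `lambda_r`,
#'   `lambda_z`, one row per element of `R_ref`.
#' @export
stretches_at <- function(R_ref, geom, lam_z, r_outer) {
  if (any(R_ref <= 0)) abort("`R_ref` must be positive.")
  r <- loaded_radius(R_ref, geom, lam_z, r_outer)
  if (any(r <= 0)) abort("Loaded radius is zero: configuration degenerate at the axis.")
  k <- sector_factor(geom, lam_z)
  lam_t <- (pi / (pi - geom$opening_angle)) * r / R_ref
  lam_r <- R_ref * k / r  # d r / d R from the map, in closed form
  tibble(
    R_ref = R_ref, r = r,
    lambda_theta = lam_t, lambda_r = lam_r, lambda_z = lam_z
  )
}

# Physical basis used for all tensors: (theta, r, z).
basis_names <- c("theta", "r", "z")

#' Deformation gradient and Green-Lagrange strain from principal stretches
#'
#' Under axisymmetric distension-extension the deformation gradient is
#' diagonal in the cylindrical basis (theta, r, z) and the Green-Lagrange
#' strain is `E = (F^T F - I) / 2`, i.e. diagonal with entries
#' `(lambda^2 - 1) / 2`.
#'
#' @param stretches Numeric length-3 vector `(lambda_theta, lambda_r, lambda_z)`.
#' @return A 3x3 matrix with dimnames `c("theta", "r", "z")`.
#' @export
#' @examples
#' green_lagrange(c(1.6, 1/1.6/1.3, 1.3))
green_lagrange <- function(stretches) {
  stretches <- as.numeric(stretches)
  stopifnot(length(stretches) == 3, all(stretches > 0))
  E <- diag((stretches^2 - 1) / 2)
  dimnames(E) <- list(basis_names, basis_names)
  E
}

#' @rdname green_lagrange
#' @export
deformation_gradient <- function(stretches) {
  stretches <- as.numeric(stretches)
  stopifnot(length(stretches) == 3, all(stretches > 0))
  F_ <- diag(stretches)
  dimnames(F_) <- list(basis_names, basis_names)
  F_
}

#' Uniaxial fiber strain along a reference direction
#'
#' Affine fiber strain `e = E : (N otimes N)` for a unit fiber direction `N`
#' at angle `angle` from the circumferential axis, lying either in the
#' circumferential-axial plane (elastin, collagen, smooth muscle cells) or in
#' the circumferential-radial plane (inter-lamellar elastin). Shear strain
#' components vanish under distension-extension, so only the diagonal of `E`
#' enters.
#'
#' @param E 3x3 Green-Lagrange strain matrix in the (theta, r, z) basis.
#' @param angle Fiber angle(s) from the circumferential direction (radians).
#' @param plane `"circ-axial"` or `"circ-radial"`.
#' @return Fiber strain(s), dimensionless; same length as `angle`.
#' @export
fiber_strain <- function(E, angle, plane = c("circ-axial", "circ-radial")) {
  plane <- match.arg(plane)
  stopifnot(is.matrix(E), all(dim(E) == c(3, 3)))
  c2 <- cos(angle)^2
  s2 <- sin(angle)^2
  if (plane == "circ-axial") {
    E[1, 1] * c2 + E[3, 3] * s2
  } else {
    E[1, 1] * c2 + E[2, 2] * s2
  }
}
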