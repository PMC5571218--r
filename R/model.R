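#' Wall composition: layer split and constituent volume fractions
#'
#' The media occupies the inner fraction `media_fraction` of the wall
#' thickness (in the reference configuration); each layer carries volume
#' fractions of inter-lamellar elastin (`IL`), planar elastin (`E`), collagen
#' (`C`) and smooth muscle (`SMC`). The defaults describe an SMC-dominant
#' media and a collagen-dominant, SMC-free adventitia; they are working
#' assumptions, not measurements, and should be overridden when layer
#' composition is known.
#'
#' @param media_fraction Fraction of reference wall thickness occupied by the
#'   media, in (0, 1).
#' @param media,adventitia Named numeric vectors with entries `IL`, `E`, `C`,
#'   `SMC`, each in `[0, 1]`, summing to at most 1. The adventitia must have
#'   `SMC = 0`.
#' @return An object of class `wall_composition`.
#' @export
wall_composition <- function(media_fraction = 2 / 3,
                             media = c(IL = 0.15, E = 0.25, C = 0.20, SMC = 0.40),
                             adventitia = c(IL = 0, E = 0.30, C = 0.70, SMC = 0)) {
  if (media_fraction <= 0 || media_fraction >= 1) {
    abort("`media_fraction` must lie in (0, 1).")
  }
  check_frac <- function(f, nm) {
    if (!all(c("IL", "E", "C", "SMC") %in% names(f))) {
      abort(sprintf("`%s` needs named entries IL, E, C, SMC.", nm))
    }
    f <- f[c("IL", "E", "C", "SMC")]
    if (any(f < 0) || any(f > 1) || sum(f) > 1 + 1e-9) {
      abort(sprintf("`%s` fractions must be in [0, 1] and sum to <= 1.", nm))
    }
    f
  }
  media <- check_frac(media, "media")
  adventitia <- check_frac(adventitia, "adventitia")
  if (adventitia[["SMC"]] != 0) abort("The adventitia carries no SMC (`SMC` must be 0).")
  structure(
    list(
      media_fraction = media_fraction,
      media = media, adventitia = adventitia
    ),
    class = "wall_composition"
  )
}

#' Quadrature resolution for orientation, recruitment and radial integrals
#'
#' Node counts for the Gauss-Legendre rules: `n_angle` per orientation
#' family (on its effective support), `n_recruit` per recruitment
#' distribution, and `n_radial` per wall layer for transmural equilibrium
#' integrals. The defaults are conservative; fitting uses a coarser rule
#' (see [fit_config()]).
#'
#' @param n_angle,n_recruit,n_radial Positive integers.
#' @return An object of class `quadrature_spec`.
#' @export
quadrature_spec <- function(n_angle = 64, n_recruit = 32, n_radial = 64) {
  stopifnot(n_angle >= 1, n_recruit >= 1, n_radial >= 2)
  structure(
    list(
      n_angle = as.integer(n_angle), n_recruit = as.integer(n_recruit),
      n_radial = as.integer(n_radial)
    ),
    class = "quadrature_spec"
  )
}

#' Assemble a full artery model
#'
#' Bundles geometry, layer composition, microstructure, passive fiber and
#' active SMC parameters with a quadrature resolution, and precomputes the
#' per-layer orientation/recruitment quadrature plans used by the wall
#' mechanics.
#'
#' @param geometry A [reference_geometry()].
#' @param composition A [wall_composition()].
#' @param microstructure A [microstructure_config()].
#' @param passive A [passive_fiber_params()].
#' @param active An [smc_active_params()].
#' @param quadrature A [quadrature_spec()].
#' @return An object of class `artery_model`.
#' @export
#' @examples
#' m <- artery_model(reference_geometry(2.5, 1.75, 1.4))
#' luminal_pressure(m, lam_z = 1.3, r_outer = 2.2)
artery_model <- function(geometry,
                         composition = wall_composition(),
                         microstructure = statistical_default_config(),
                         passive = passive_fiber_params(),
                         active = smc_active_params(),
                         quadrature = quadrature_spec()) {
  stopifnot(
    inherits(geometry, "reference_geometry"),
    inherits(composition, "wall_composition"),
    inherits(microstructure, "microstructure_config"),
    inherits(passive, "passive_fiber_params"),
    inherits(active, "smc_active_params"),
    inherits(quadrature, "quadrature_spec")
  )
  m <- structure(
    list(
      geometry = geometry, composition = composition,
      microstructure = microstructure, passive = passive, active = active,
      quadrature = quadrature, plan = NULL
    ),
    class = "artery_model"
  )
  rebuild_plans(m)
}

rebuild_plans <- function(model) {
  model$plan <- list(
    media = build_layer_plan(
      "media", model$microstructure, model$quadrature, model$passive
    ),
    adventitia = build_layer_plan(
      "adventitia", model$microstructure, model$quadrature, model$passive
    )
  )
  model
}

#' @export
print.artery_model <- function(x, ...) {
  g <- x$geometry
  cat(sprintf(
    "<artery_model> mode = %s\n  geometry: R_o = %.3g, R_i = %.3g mm, Theta = %.3g rad\n",
    x$microstructure$mode, g$R_outer, g$R_inner, g$opening_angle
  ))
  cat(sprintf(
    "  passive: k_IL = %.3g, k_E = %.3g, k_C = %.3g MPa, M_C = %.3g\n",
    x$passive$k_IL, x$passive$k_E, x$passive$k_C, x$passive$M_C
  ))
  cat(sprintf(
    "  active: rho1 = %.3g, rho2 = %.3g, lam_max = %.3g, sigma_max = %.3g MPa, tau = %.3g, k_SMC = %.3g\n",
    x$active$rho1, x$active$rho2, x$active$lam_max, x$active$sigma_max,
    x$active$tau, x$active$k_smc_radial
  ))
  invisible(x)
}

# Reference radius of the media/adventitia interface.
interface_radius <- function(model) {
  g <- model$geometry
  g$R_inner + model$composition$media_fraction * (g$R_outer - g$R_inner)
}

# Map activation state labels to activation levels.
state_activation <- function(state) {
  if (is.numeric(state)) {
    return(state)
  }
  unname(c(passive = 0, full = 1)[state])
}
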