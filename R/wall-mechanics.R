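#' Total second Piola-Kirchhoff stress at a wall point
#'
#' Volume-weighted sum of the passive constituent stresses plus, in the
#' media, the active SMC contribution:
#' `S = f_IL S_IL + f_E S_E + f_C S_C + f_SMC S_SMC`. The layer is selected
#' by the reference radius (media inside the interface radius).
#'
#' @param E 3x3 Green-Lagrange strain matrix, (theta, r, z) basis.
#' @param R_ref Reference radius of the point (mm); selects the layer.
#' @param model An [artery_model()].
#' @param activation Activation level in `[0, 1]` (0 = passive state).
#' @return A 3x3 diagonal stress matrix (MPa); the constitutive "extra"
#'   stress, before the hydrostatic Lagrange multiplier.
#' @export
total_second_pk <- function(E, R_ref, model, activation = 0) {
  g <- model$geometry
  if (R_ref < g$R_inner - 1e-12 || R_ref > g$R_outer + 1e-12) {
    abort("`R_ref` lies outside the wall.")
  }
  layer <- if (R_ref <= interface_radius(model)) "media" else "adventitia"
  d <- diag_strain(E)
  S <- layer_stress_nodes(d$tt, d$rr, d$zz, layer, model, activation)
  as_stress_tensor(S$S_tt, S$S_rr, S$S_zz)
}

# Combined passive + active layer stress at strain-state vectors.
layer_stress_nodes <- function(Ett, Err, Ezz, layer, model, activation) {
  plan <- model$plan[[layer]]
  S <- layer_passive_stress_nodes(
    Ett, Err, Ezz, plan, model$composition[[layer]], model$passive
  )
  f_smc <- model$composition[[layer]][["SMC"]]
  if (layer == "media" && f_smc > 0 && activation > 0) {
    p <- model$active
    p$activation <- activation
    A <- smc_stress_nodes(Ett, Err, Ezz, plan$smc, p)
    S$S_tt <- S$S_tt + f_smc * A$S_tt
    S$S_rr <- S$S_rr + f_smc * A$S_rr
    S$S_zz <- S$S_zz + f_smc * A$S_zz
  }
  S
}

# Extra Cauchy stress state (hydrostatic part excluded) at per-layer
# Gauss-Legendre nodes of the reference wall. Returns a list with node-wise
# radii, stretches, reference-domain weights and extra Cauchy components.
wall_state <- function(model, lam_z, r_outer, activation = 0,
                       n_radial = model$quadrature$n_radial) {
  g <- model$geometry
  R_m <- interface_radius(model)
  seg <- list(
    media = c(g$R_inner, R_m),
    adventitia = c(R_m, g$R_outer)
  )
  k <- sector_factor(g, lam_z)
  sector <- pi / (pi - g$opening_angle)
  out <- lapply(names(seg), function(layer) {
    ab <- seg[[layer]]
    gl <- gl_nodes(n_radial, ab[1], ab[2])
    R <- gl$x
    arg <- r_outer^2 - (g$R_outer^2 - R^2) * k
    if (any(arg <= 0)) {
      abort("Invalid loaded configuration: negative square-root argument in the radius map.")
    }
    r <- sqrt(arg)
    lam_t <- sector * r / R
    lam_r <- R * k / r
    n <- length(R)
    Ett <- (lam_t^2 - 1) / 2
    Err <- (lam_r^2 - 1) / 2
    Ezz <- rep((lam_z^2 - 1) / 2, n)
    S <- layer_stress_nodes(Ett, Err, Ezz, layer, model, activation)
    # push forward: sigma_hat_kk = lambda_k^2 S_kk (diagonal F)
    list(
      R = R, wR = gl$w, r = r,
      lam_t = lam_t, lam_r = lam_r,
      sig_tt = lam_t^2 * S$S_tt,
      sig_rr = lam_r^2 * S$S_rr,
      sig_zz = lam_z^2 * S$S_zz
    )
  })
  lapply(setNames(names(out[[1]]), names(out[[1]])), function(f) {
    c(out[[1]][[f]], out[[2]][[f]])
  })
}

#' Luminal pressure carried by a loaded configuration
#'
#' Integrates radial equilibrium across the wall:
#' `p_i = int_{r_i}^{r_o} (sigma_tt - sigma_rr) / r dr`. The integrand uses
#' the constitutive extra stresses only -- the hydrostatic multiplier cancels
#' in the difference -- and the integral is evaluated in the reference domain
#' with per-layer Gauss-Legendre rules (the composition jump at the layer
#' interface is a quadrature breakpoint).
#'
#' @param model An [artery_model()].
#' @param lam_z Axial stretch.
#' @param r_outer Loaded outer radius (mm).
#' @param activation Activation level in `[0, 1]`, or `"passive"` / `"full"`.
#' @param n_radial Radial nodes per layer.
#' @return Luminal pressure in mmHg.
#' @export
luminal_pressure <- function(model, lam_z, r_outer, activation = 0,
                             n_radial = model$quadrature$n_radial) {
  activation <- state_activation(activation)
  ws <- wall_state(model, lam_z, r_outer, activation, n_radial)
  p_MPa <- sum(ws$wR * ws$lam_r * (ws$sig_tt - ws$sig_rr) / ws$r)
  MPa_to_mmHg(p_MPa)
}

#' Axial force and tension of the closed pressurised tube
#'
#' The reduced axial force is
#' `F = pi int (2 sigma_zz - sigma_tt - sigma_rr) r dr` (independent of the
#' hydrostatic multiplier); the axial tension adds the pressure acting on the
#' closed ends, `N = F + p_i pi r_i^2`.
#'
#' @inheritParams luminal_pressure
#' @return A one-row tibble with `axial_force_mN` and `axial_tension_mN`.
#' @export
axial_force <- function(model, lam_z, r_outer, activation = 0,
                        n_radial = model$quadrature$n_radial) {
  fp <- forward_point(model, lam_z, r_outer, activation, n_radial)
  tibble(
    axial_force_mN = fp[["axial_force_mN"]],
    axial_tension_mN = fp[["axial_tension_mN"]]
  )
}

# Fast path: pressure, force and tension from one wall-state evaluation.
forward_point <- function(model, lam_z, r_outer, activation = 0,
                          n_radial = model$quadrature$n_radial) {
  activation <- state_activation(activation)
  ws <- wall_state(model, lam_z, r_outer, activation, n_radial)
  F_N <- pi * sum(ws$wR * ws$lam_r * (2 * ws$sig_zz - ws$sig_tt - ws$sig_rr) * ws$r)
  p_MPa <- sum(ws$wR * ws$lam_r * (ws$sig_tt - ws$sig_rr) / ws$r)
  r_i <- inner_radius(model$geometry, lam_z, r_outer)
  c(
    pressure_mmHg = MPa_to_mmHg(p_MPa),
    axial_force_mN = 1e3 * F_N,
    axial_tension_mN = 1e3 * (F_N + p_MPa * pi * r_i^2),
    r_inner_mm = r_i
  )
}

#' Transmural Cauchy stress profile
#'
#' Integrates the radial equilibrium equation inward from the traction-free
#' outer surface, `sigma_rr(r) = -int_r^{r_o} (sigma_tt - sigma_rr)/r' dr'`,
#' then recovers the circumferential and axial components pointwise from the
#' extra stresses (the hydrostatic multiplier is eliminated by the
#' boundary condition `sigma_rr(r_o) = 0`).
#'
#' @inheritParams luminal_pressure
#' @param n_points Number of evenly spaced loaded radii reported.
#' @return A tibble with columns `r_mm`, `R_ref_mm`, `sigma_rr_MPa`,
#'   `sigma_tt_MPa`, `sigma_zz_MPa`, classed `artery_profile`.
#' @export
transmural_profile <- function(model, lam_z, r_outer, activation = 0,
                               n_points = 50,
                               n_radial = model$quadrature$n_radial) {
  activation <- state_activation(activation)
  g <- model$geometry
  r_i <- inner_radius(g, lam_z, r_outer)
  r_pts <- seq(r_i, r_outer, length.out = n_points)
  k <- sector_factor(g, lam_z)
  # invert the radius map: R(r) = sqrt(R_o^2 - (r_o^2 - r^2)/k)
  R_pts <- sqrt(g$R_outer^2 - (r_outer^2 - r_pts^2) / k)
  R_m <- interface_radius(model)

  # integrand of the equilibrium integral, in the reference domain
  integrand <- function(R) {
    st <- stretches_at(R, g, lam_z, r_outer)
    Ett <- (st$lambda_theta^2 - 1) / 2
    Err <- (st$lambda_r^2 - 1) / 2
    Ezz <- rep((lam_z^2 - 1) / 2, length(R))
    hat <- function(layer, idx) {
      S <- layer_stress_nodes(Ett[idx], Err[idx], Ezz[idx], layer, model, activation)
      (st$lambda_theta[idx]^2 * S$S_tt - st$lambda_r[idx]^2 * S$S_rr)
    }
    idx_m <- which(R <= R_m)
    idx_a <- which(R > R_m)
    val <- numeric(length(R))
    if (length(idx_m)) val[idx_m] <- hat("media", idx_m)
    if (length(idx_a)) val[idx_a] <- hat("adventitia", idx_a)
    val * st$lambda_r / st$r
  }
  seg_int <- function(a, b, n = 24) {
    if (b - a < 1e-14) {
      return(0)
    }
    gl <- gl_nodes(n, a, b)
    sum(gl$w * integrand(gl$x))
  }
  # integral from R_pts[j] to R_outer, split at the interface
  int_out <- vapply(R_pts, function(Rj) {
    if (Rj < R_m) seg_int(Rj, R_m) + seg_int(R_m, g$R_outer) else seg_int(Rj, g$R_outer)
  }, numeric(1))
  sig_rr_eq <- -int_out

  st <- stretches_at(R_pts, g, lam_z, r_outer)
  Ett <- (st$lambda_theta^2 - 1) / 2
  Err <- (st$lambda_r^2 - 1) / 2
  Ezz <- rep((lam_z^2 - 1) / 2, n_points)
  hat <- matrix(0, n_points, 3)
  for (layer in c("media", "adventitia")) {
    idx <- if (layer == "media") which(R_pts <= R_m) else which(R_pts > R_m)
    if (!length(idx)) next
    S <- layer_stress_nodes(Ett[idx], Err[idx], Ezz[idx], layer, model, activation)
    hat[idx, 1] <- st$lambda_theta[idx]^2 * S$S_tt
    hat[idx, 2] <- st$lambda_r[idx]^2 * S$S_rr
    hat[idx, 3] <- lam_z^2 * S$S_zz
  }
  out <- tibble(
    r_mm = r_pts, R_ref_mm = R_pts,
    sigma_rr_MPa = sig_rr_eq,
    sigma_tt_MPa = sig_rr_eq + (hat[, 1] - hat[, 2]),
    sigma_zz_MPa = sig_rr_eq + (hat[, 3] - hat[, 2])
  )
  class(out) <- c("artery_profile", class(out))
  out
}

# Smallest admissible loaded outer radius (inner radius pinched to zero).
floor_outer_radius <- function(model, lam_z) {
  g <- model$geometry
  sqrt((g$R_outer^2 - g$R_inner^2) * sector_factor(g, lam_z))
}

#' Solve the loaded outer radius at a target pressure
#'
#' Inverts the pressure-radius relation by safeguarded root bracketing:
#' finds `r_outer` such that [luminal_pressure()] matches `pressure_mmHg`.
#'
#' @inheritParams luminal_pressure
#' @param pressure_mmHg Target luminal pressure (mmHg).
#' @param guess Optional starting radius (mm); a converged neighbouring
#'   solution greatly speeds up pressure sweeps.
#' @param tol Convergence tolerance on the radius (mm).
#' @return The loaded outer radius (mm).
#' @export
solve_outer_radius <- function(model, lam_z, pressure_mmHg, activation = 0,
                               guess = NULL, tol = 1e-10,
                               n_radial = model$quadrature$n_radial) {
  activation <- state_activation(activation)
  g <- model$geometry
  f <- function(r) {
    luminal_pressure(model, lam_z, r, activation, n_radial) - pressure_mmHg
  }
  r_floor <- floor_outer_radius(model, lam_z) * (1 + 1e-9)
  r_scale <- sqrt(g$R_outer^2 * sector_factor(g, lam_z)) # lambda_theta ~ 1 radius
  lo <- max(r_floor, if (is.null(guess)) 0.8 * r_scale else 0.985 * guess)
  hi <- if (is.null(guess)) 1.3 * r_scale else 1.015 * guess
  flo <- f(lo)
  fhi <- f(hi)
  # expand the bracket geometrically until the target is straddled
  step <- 0.05 * r_scale
  iter <- 0
  while (flo > 0 && lo > r_floor * (1 + 1e-9) && iter < 60) {
    hi <- lo
    fhi <- flo
    lo <- max(r_floor, lo - step)
    flo <- f(lo)
    step <- step * 1.6
    iter <- iter + 1
  }
  step <- 0.05 * r_scale
  while (fhi < 0 && iter < 120) {
    lo <- hi
    flo <- fhi
    hi <- hi + step
    fhi <- f(hi)
    step <- step * 1.6
    iter <- iter + 1
  }
  if (flo > 0 || fhi < 0) {
    abort(sprintf(
      "No outer radius bracket found for %.3g mmHg (lam_z = %.3g, activation = %.2g).",
      pressure_mmHg, lam_z, activation
    ))
  }
  uniroot(f, lower = lo, upper = hi, f.lower = flo, f.upper = fhi, tol = tol)$root
}

#' Simulate a distension-extension protocol
#'
#' Forward-solves the model over a factorial loading schedule (one record per
#' pressure x axial stretch x activation state), returning the measured
#' channels of a biaxial test: outer radius, reduced axial force and axial
#' tension. The default schedule is a pressure ramp 0-160 mmHg in 20 mmHg
#' steps at axial stretches 1.3 and 1.5, in the passive and fully activated
#' states.
#'
#' @param model An [artery_model()].
#' @param pressures Pressures (mmHg).
#' @param stretches Axial stretch ratios.
#' @param states Character vector from `"passive"`, `"full"`.
#' @param n_radial Radial quadrature nodes per layer.
#' @return A tibble with columns `pressure_mmHg`, `lambda_z`, `state`,
#'   `r_outer_mm`, `r_inner_mm`, `axial_force_mN`, `axial_tension_mN`,
#'   classed `artery_predictions`.
#' @export
#' @examples
#' m <- artery_model(reference_geometry(2.5, 1.75, 1.4),
#'   quadrature = quadrature_spec(16, 8, 8)
#' )
#' simulate_protocol(m, pressures = c(60, 100), stretches = 1.3, states = "passive")
simulate_protocol <- function(model,
                              pressures = seq(0, 160, by = 20),
                              stretches = c(1.3, 1.5),
                              states = c("passive", "full"),
                              n_radial = model$quadrature$n_radial) {
  states <- match.arg(states, c("passive", "full"), several.ok = TRUE)
  grid <- tidyr::expand_grid(
    lambda_z = stretches, state = states, pressure_mmHg = sort(pressures)
  )
  n <- nrow(grid)
  r_o_v <- r_i_v <- f_v <- t_v <- numeric(n)
  guess <- NULL
  last_key <- NULL
  for (i in seq_len(n)) {
    key <- paste(grid$lambda_z[i], grid$state[i])
    if (!identical(key, last_key)) guess <- NULL # new sweep: cold start
    last_key <- key
    act <- state_activation(grid$state[i])
    r_o <- tryCatch(
      solve_outer_radius(model, grid$lambda_z[i], grid$pressure_mmHg[i],
        act,
        guess = guess, n_radial = n_radial
      ),
      error = function(e) {
        abort(sprintf(
          "Forward solve failed at %g mmHg, lambda_z = %g, state = %s: %s",
          grid$pressure_mmHg[i], grid$lambda_z[i], grid$state[i],
          conditionMessage(e)
        ))
      }
    )
    guess <- r_o
    fp <- forward_point(model, grid$lambda_z[i], r_o, act, n_radial)
    r_o_v[i] <- r_o
    r_i_v[i] <- fp[["r_inner_mm"]]
    f_v[i] <- fp[["axial_force_mN"]]
    t_v[i] <- fp[["axial_tension_mN"]]
  }
  out <- tibble(
    pressure_mmHg = grid$pressure_mmHg,
    lambda_z = grid$lambda_z,
    state = grid$state,
    r_outer_mm = r_o_v,
    r_inner_mm = r_i_v,
    axial_force_mN = f_v,
    axial_tension_mN = t_v
  )
  out <- dplyr::arrange(out, .data$lambda_z, .data$state, .data$pressure_mmHg)
  class(out) <- c("artery_predictions", class(out))
  out
}
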