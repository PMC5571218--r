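#' Draw a plausible zero-stress-state geometry
#'
#' Samples a synthetic porcine LAD-scale reference geometry: outer radius
#' 2-3 mm, wall-to-outer-radius ratio 0.2-0.35, opening angle 0.5-2.5 rad.
#' Deterministic for a given seed.
#'
#' @param seed Integer seed.
#' @return A [reference_geometry()].
#' @export
generate_reference_geometry <- function(seed = 1) {
  set.seed(seed)
  R_o <- runif(1, 2, 3)
  wall <- runif(1, 0.2, 0.35) * R_o
  theta <- runif(1, 0.5, 2.5)
  reference_geometry(
    R_outer = R_o, R_inner = R_o - wall,
    opening_angle = theta, length_ref = 10
  )
}

# Additive Gaussian measurement noise on the radius and force channels; the
# tension is recomputed to stay consistent with the noisy force and radius.
add_measurement_noise <- function(pred, noise, seed = NULL, geometry = NULL) {
  stopifnot(inherits(noise, "noise_scales"))
  if (!is.null(seed)) set.seed(seed)
  sd_r <- ifelse(pred$state == "passive", noise$r_outer_passive, noise$r_outer_full)
  sd_f <- ifelse(pred$state == "passive", noise$force_passive, noise$force_full)
  out <- pred
  out$r_outer_mm <- pred$r_outer_mm + rnorm(nrow(pred), 0, sd_r)
  out$axial_force_mN <- pred$axial_force_mN + rnorm(nrow(pred), 0, sd_f)
  if (!is.null(geometry)) {
    out$r_inner_mm <- purrr::map2_dbl(
      out$r_outer_mm, out$lambda_z,
      function(ro, lz) inner_radius(geometry, lz, ro)
    )
    out$axial_tension_mN <- out$axial_force_mN +
      1e3 * mmHg_to_MPa(out$pressure_mmHg) * pi * out$r_inner_mm^2
  }
  out
}

#' Generate a synthetic biaxial distension-extension dataset
#'
#' Forward-solves the supplied "truth" model over the standard protocol
#' (pressure 0-160 mmHg in 20 mmHg steps; axial stretches 1.3 and 1.5;
#' passive and potassium-activated states) and adds independent zero-mean
#' Gaussian measurement noise to the radius and force channels. With the
#' default `noise = NULL`, each channel's SD is `noise_frac` of that
#' channel's per-state range (set `noise_frac = 0` for noiseless data).
#'
#' @param model The ground-truth [artery_model()].
#' @param noise A [noise_scales()], or `NULL` to derive scales from
#'   `noise_frac`.
#' @param seed Integer seed for the noise draws.
#' @param pressures,stretches,states Loading schedule.
#' @param replicates Number of noisy replicates of the schedule.
#' @param noise_frac Fraction of each channel's range used as its SD when
#'   `noise` is `NULL`.
#' @return A tibble of experiment records classed `artery_dataset`, with
#'   attributes `geometry`, `noise`, `truth` (the generating parameter set)
#'   and `seed`.
#' @export
generate_experiment <- function(model, noise = NULL, seed = 1,
                                pressures = seq(0, 160, by = 20),
                                stretches = c(1.3, 1.5),
                                states = c("passive", "full"),
                                replicates = 1, noise_frac = 0.02) {
  stopifnot(inherits(model, "artery_model"))
  clean <- simulate_protocol(model,
    pressures = pressures,
    stretches = stretches, states = states
  )
  noiseless <- FALSE
  if (is.null(noise)) {
    noiseless <- noise_frac == 0
    # the stored scales also studentise the fitting objective, so they are
    # floored at 2% of each channel's range even for noiseless data
    scale_frac <- max(noise_frac, 0.02)
    rng <- function(x) max(diff(range(x)), 1e-6)
    by_state <- split(clean, clean$state)
    sc <- function(st, col) {
      if (!st %in% names(by_state)) {
        return(1e-6)
      }
      max(scale_frac * rng(by_state[[st]][[col]]), 1e-9)
    }
    noise <- noise_scales(
      r_outer_passive = sc("passive", "r_outer_mm"),
      force_passive = sc("passive", "axial_force_mN"),
      r_outer_full = sc("full", "r_outer_mm"),
      force_full = sc("full", "axial_force_mN")
    )
  }
  set.seed(seed)
  reps <- lapply(seq_len(replicates), function(k) {
    noisy <- if (noiseless) clean else {
      add_measurement_noise(clean, noise, seed = NULL, geometry = model$geometry)
    }
    noisy$replicate <- k
    noisy
  })
  out <- dplyr::bind_rows(reps)
  truth <- c(
    setNames(
      unlist(model$passive[c("k_IL", "k_E", "k_C", "M_C")]),
      c("k_IL", "k_E", "k_C", "M_C")
    ),
    setNames(
      unlist(model$active[c(
        "rho1", "rho2", "lam_max", "sigma_max", "tau",
        "k_smc_radial"
      )]),
      c("rho1", "rho2", "lam_max", "sigma_max", "tau", "k_smc")
    )
  )
  structure(
    out,
    geometry = model$geometry, noise = noise, truth = truth, seed = seed,
    class = c("artery_dataset", class(out))
  )
}
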