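#' Passive fiber material parameters
#'
#' Stiffnesses of the three passive fiber networks and the collagen
#' nonlinearity exponent. Fiber properties are taken constant through the
#' wall (both layers share one parameter set). Defaults are the refined-fit
#' averages for porcine left anterior descending coronary arteries.
#'
#' @param k_IL Inter-lamellar elastin stiffness (MPa).
#' @param k_E Planar elastin fiber stiffness (MPa).
#' @param k_C Collagen stiffness coefficient (MPa).
#' @param M_C Collagen power-law exponent (dimensionless, > 0).
#' @return An object of class `passive_fiber_params`.
#' @export
passive_fiber_params <- function(k_IL = 0.18, k_E = 0.27, k_C = 29.5, M_C = 5.23) {
  if (any(c(k_IL, k_E, k_C) < 0)) abort("Fiber stiffnesses must be >= 0.")
  if (M_C <= 0) abort("`M_C` must be positive.")
  structure(list(k_IL = k_IL, k_E = k_E, k_C = k_C, M_C = M_C),
    class = "passive_fiber_params"
  )
}

#' Linear tension-only elastin fiber law
#'
#' A single elastin fiber stores energy `w = k e^2 / 2` and carries stress
#' `k e` in tension; compressed fibers (`e <= 0`) carry nothing (negligible
#' bending/compressive rigidity).
#'
#' @param e Fiber strain(s) (dimensionless).
#' @param k Fiber stiffness (MPa).
#' @return A tibble with columns `energy` (MPa) and `stress` (MPa).
#' @export
#' @examples
#' elastin_energy_stress(c(-0.1, 0, 0.2), k = 0.27)
elastin_energy_stress <- function(e, k) {
  if (k < 0) abort("`k` must be >= 0.")
  ep <- pmax(e, 0)
  tibble(energy = 0.5 * k * ep^2, stress = k * ep)
}

#' Power-law collagen fiber law with straightening strain
#'
#' A wavy collagen fiber is recruited once its strain exceeds its
#' straightening strain `e0`; beyond recruitment
#' `w = k_C (e - e0)^(1 + M_C) / (1 + M_C)` and the fiber stress is
#' `k_C (e - e0)^M_C`, which tends to 0 continuously as `e -> e0+`.
#'
#' @param e Fiber strain(s).
#' @param params A [passive_fiber_params()].
#' @param e0 Straightening strain(s) (>= 0), recycled against `e`.
#' @return A tibble with columns `energy` (MPa) and `stress` (MPa).
#' @export
collagen_energy_stress <- function(e, params, e0) {
  stopifnot(inherits(params, "passive_fiber_params"))
  if (any(e0 < 0)) abort("`e0` must be >= 0.")
  ex <- pmax(e - e0, 0)
  tibble(
    energy = params$k_C * ex^(1 + params$M_C) / (1 + params$M_C),
    stress = params$k_C * ex^params$M_C
  )
}

# ---- layer quadrature plans ------------------------------------------------
# Each passive constituent is reduced to angle nodes (theta, wt), a plane
# ("tz" = circumferential-axial, "tr" = circumferential-radial), a stiffness
# field name, and (collagen) recruitment nodes. Medial mirrored families are
# collapsed to their [0, pi/2] half: the integrands of this loading (diagonal
# strain, n (x) n diagonal terms) are even in theta, so the mirrored half
# contributes identically.

build_layer_plan <- function(layer = c("media", "adventitia"), micro, quad,
                             params = passive_fiber_params()) {
  layer <- match.arg(layer)
  if (layer == "adventitia") {
    list(
      elastin = c(mixture_nodes(micro$adv_elastin, quad$n_angle),
        list(plane = "tz", type = "elastin", k_field = "k_E")
      ),
      collagen = c(mixture_nodes(micro$adv_collagen, quad$n_angle),
        list(plane = "tz", type = "collagen"),
        recruitment_funs(micro$adv_recruitment, params$M_C, quad$n_recruit)
      )
    )
  } else {
    fam <- orientation_nodes(micro$media_fiber, quad$n_angle)
    list(
      il = list(type = "il", plane = "tr"),
      elastin = c(fam, list(plane = "tz", type = "elastin", k_field = "k_E")),
      collagen = c(
        fam, list(plane = "tz", type = "collagen"),
        recruitment_funs(micro$media_recruitment, params$M_C, quad$n_recruit)
      ),
      smc = c(orientation_nodes(micro$media_smc, quad$n_angle), list(plane = "tz"))
    )
  }
}

# Recruitment-averaged single-fiber response (per unit k_C):
# stress(e) = E_e0[(e - e0)_+^M], energy(e) = E_e0[(e - e0)_+^(M+1)]/(M+1).
# These are smooth functions of the fiber strain even though the pointwise
# integrand has a kink at e0 = e, so they are evaluated in closed form
# (point, uniform) or tabulated on a spline from kink-split Gauss-Legendre
# quadrature (beta); naive fixed-node quadrature across the kink would lose
# accuracy.
recruitment_funs <- function(dist, M, n) {
  if (dist$kind == "point") {
    e0 <- dist$point_value
    return(list(
      rec_stress = function(e) ramp(e - e0)^M,
      rec_energy = function(e) ramp(e - e0)^(1 + M) / (1 + M)
    ))
  }
  if (dist$kind == "uniform") {
    a <- dist$lower
    b <- dist$upper
    w <- b - a
    return(list(
      rec_stress = function(e) {
        (ramp(e - a)^(M + 1) - ramp(e - b)^(M + 1)) / (w * (M + 1))
      },
      rec_energy = function(e) {
        (ramp(e - a)^(M + 2) - ramp(e - b)^(M + 2)) / (w * (M + 1) * (M + 2))
      }
    ))
  }
  a <- dist$lower
  b <- dist$upper
  # the master rule and strain grid depend on the distribution only, not on
  # M, so they are cached: during fitting the beta shapes are often fixed
  # while the collagen exponent moves
  key <- paste("beta", dist$shape1, dist$shape2, a, b, n, sep = "|")
  cached <- .rec_cache[[key]]
  if (is.null(cached)) {
    mean_b <- recruitment_mean(dist)
    sd_b <- (b - a) * sqrt(
      dist$shape1 * dist$shape2 /
        ((dist$shape1 + dist$shape2)^2 * (dist$shape1 + dist$shape2 + 1))
    )
    # tabulate on the density's effective window so narrow distributions are
    # resolved; outside it the response is 0 (below) or fully recruited and
    # smooth (above)
    a_eff <- max(a, mean_b - 12 * sd_b)
    b_eff <- min(b, mean_b + 12 * sd_b)
    eg <- seq(a_eff, b_eff, length.out = max(96, 2 * n))
    # one fine master rule for the density; the partial integrals truncate
    # it at x < e, which is benign because (e - x)^M has high-order contact
    master <- recruitment_nodes(dist, max(256, 2 * n))
    cached <- list(
      a_eff = a_eff, b_eff = b_eff, eg = eg, master = master,
      diffs = ramp(outer(eg, master$e0, "-"))
    )
    if (length(ls(.rec_cache)) > 200) rm(list = ls(.rec_cache), envir = .rec_cache)
    .rec_cache[[key]] <- cached
  }
  a_eff <- cached$a_eff
  b_eff <- cached$b_eff
  eg <- cached$eg
  master <- cached$master
  diffs <- cached$diffs
  tab <- function(pow, scale) {
    splinefun(eg, drop(diffs^pow %*% master$wt) / scale, method = "fmm")
  }
  sf <- tab(M, 1)
  wf <- tab(M + 1, M + 1)
  beyond <- function(e, pow, scale) {
    acc <- 0
    for (m in seq_along(master$e0)) {
      acc <- acc + master$wt[m] * (e - master$e0[m])^pow
    }
    acc / scale
  }
  eval_fun <- function(f, pow, scale) {
    function(e) {
      out <- e * 0
      mid <- e > a_eff & e < b_eff
      hi <- e >= b_eff
      if (any(mid)) out[mid] <- f(e[mid])
      if (any(hi)) out[hi] <- beyond(e[hi], pow, scale)
      out
    }
  }
  list(
    rec_stress = eval_fun(sf, M, 1),
    rec_energy = eval_fun(wf, M + 1, M + 1)
  )
}

# Branchless tension-only switch; faster than pmax on large matrices.
ramp <- function(x) (x > 0) * x

.rec_cache <- new.env(parent = emptyenv())

# ---- inter-lamellar elastin: closed-form plane integrals -------------------
# The IL network is isotropic in the circumferential-radial plane with
# angular density 1/pi on [-pi/2, pi/2]; its fiber strain
# e(th) = Ett cos^2 th + Err sin^2 th changes sign inside the interval
# whenever Ett and Err have opposite signs, so the tension-only integrals
# are evaluated in closed form over the tensile sub-interval instead of by
# quadrature (a kinked integrand defeats Gauss-Legendre accuracy).
# Building blocks: integrals of cos^4, sin^4, sin^2 cos^2 over [0, a].
il_plane_terms <- function(Ett, Err) {
  c4 <- function(a) 3 * a / 8 + sin(2 * a) / 4 + sin(4 * a) / 32
  s4 <- function(a) 3 * a / 8 - sin(2 * a) / 4 + sin(4 * a) / 32
  c2s2 <- function(a) a / 8 - sin(4 * a) / 32
  half <- pi / 2
  n <- length(Ett)
  C4 <- S4 <- C2S2 <- numeric(n)
  full <- Ett >= 0 & Err >= 0
  C4[full] <- c4(half)
  S4[full] <- s4(half)
  C2S2[full] <- c2s2(half)
  tin <- Ett > 0 & Err < 0 # tension only near the circumferential axis
  if (any(tin)) {
    a <- atan(sqrt(Ett[tin] / -Err[tin]))
    C4[tin] <- c4(a)
    S4[tin] <- s4(a)
    C2S2[tin] <- c2s2(a)
  }
  tout <- Ett < 0 & Err > 0 # tension only near the radial axis
  if (any(tout)) {
    a <- atan(sqrt(-Ett[tout] / Err[tout]))
    C4[tout] <- c4(half) - c4(a)
    S4[tout] <- s4(half) - s4(a)
    C2S2[tout] <- c2s2(half) - c2s2(a)
  }
  list(C4 = C4, S4 = S4, C2S2 = C2S2)
}

il_stress <- function(Ett, Err, k) {
  tm <- il_plane_terms(Ett, Err)
  list(
    S_tt = (2 * k / pi) * (Ett * tm$C4 + Err * tm$C2S2),
    S_rr = (2 * k / pi) * (Ett * tm$C2S2 + Err * tm$S4)
  )
}

il_energy <- function(Ett, Err, k) {
  tm <- il_plane_terms(Ett, Err)
  (k / pi) * (Ett^2 * tm$C4 + 2 * Ett * Err * tm$C2S2 + Err^2 * tm$S4)
}

# Fiber strain matrix for a constituent: rows = strain states, cols = angles.
constituent_strain <- function(Ett, Err, Ezz, con) {
  c2 <- cos(con$theta)^2
  s2 <- sin(con$theta)^2
  if (con$plane == "tz") {
    tcrossprod(Ett, c2) + tcrossprod(Ezz, s2)
  } else {
    tcrossprod(Ett, c2) + tcrossprod(Err, s2)
  }
}

# Fiber stress dW/de for a constituent at strain matrix `e` (tension-only
# switch applied per fiber, inside the integrand).
constituent_fiber_stress <- function(e, con, params) {
  if (con$type == "elastin") {
    params[[con$k_field]] * ramp(e)
  } else {
    params$k_C * con$rec_stress(e)
  }
}

constituent_fiber_energy <- function(e, con, params) {
  if (con$type == "elastin") {
    0.5 * params[[con$k_field]] * ramp(e)^2
  } else {
    params$k_C * con$rec_energy(e)
  }
}

# Vectorised passive layer stress over strain-state vectors. Returns a list
# of S_tt, S_rr, S_zz vectors (2nd Piola-Kirchhoff, MPa), volume-weighted.
layer_passive_stress_nodes <- function(Ett, Err, Ezz, plan, fractions, params) {
  n <- length(Ett)
  S_tt <- S_rr <- S_zz <- numeric(n)
  for (nm in names(plan)) {
    if (nm == "smc") next
    f <- switch(nm, il = fractions[["IL"]], elastin = fractions[["E"]],
      collagen = fractions[["C"]]
    )
    if (f == 0) next
    con <- plan[[nm]]
    if (con$type == "il") {
      il <- il_stress(Ett, Err, params$k_IL)
      S_tt <- S_tt + f * il$S_tt
      S_rr <- S_rr + f * il$S_rr
      next
    }
    e <- constituent_strain(Ett, Err, Ezz, con)
    sig <- constituent_fiber_stress(e, con, params)
    c2 <- cos(con$theta)^2
    s2 <- sin(con$theta)^2
    S_tt <- S_tt + f * drop(sig %*% (con$wt * c2))
    if (con$plane == "tz") {
      S_zz <- S_zz + f * drop(sig %*% (con$wt * s2))
    } else {
      S_rr <- S_rr + f * drop(sig %*% (con$wt * s2))
    }
  }
  list(S_tt = S_tt, S_rr = S_rr, S_zz = S_zz)
}

layer_passive_energy_nodes <- function(Ett, Err, Ezz, plan, fractions, params) {
  W <- numeric(length(Ett))
  for (nm in names(plan)) {
    if (nm == "smc") next
    f <- switch(nm, il = fractions[["IL"]], elastin = fractions[["E"]],
      collagen = fractions[["C"]]
    )
    if (f == 0) next
    con <- plan[[nm]]
    if (con$type == "il") {
      W <- W + f * il_energy(Ett, Err, params$k_IL)
      next
    }
    e <- constituent_strain(Ett, Err, Ezz, con)
    W <- W + f * drop(constituent_fiber_energy(e, con, params) %*% con$wt)
  }
  W
}

diag_strain <- function(E) {
  stopifnot(is.matrix(E), all(dim(E) == c(3, 3)))
  list(tt = E[1, 1], rr = E[2, 2], zz = E[3, 3])
}

as_stress_tensor <- function(S_tt, S_rr, S_zz) {
  S <- diag(c(S_tt, S_rr, S_zz))
  dimnames(S) <- list(basis_names, basis_names)
  S
}

#' Passive second Piola-Kirchhoff stress of one wall layer
#'
#' Volume-fraction-weighted orientation (and, for collagen, recruitment)
#' integral of the single-fiber stresses:
#' `S = sum_i f_i int R_i(theta) (dw_i/de) N (x) N dtheta`. The adventitia
#' carries the two bimodal fiber mixtures; the media carries the mirrored
#' planar family plus the isotropic inter-lamellar elastin term.
#'
#' @param E 3x3 Green-Lagrange strain matrix, (theta, r, z) basis.
#' @param layer `"media"` or `"adventitia"`.
#' @param micro A [microstructure_config()].
#' @param comp A [wall_composition()].
#' @param params A [passive_fiber_params()].
#' @param quadrature A [quadrature_spec()].
#' @return A 3x3 diagonal stress matrix (MPa).
#' @export
layer_passive_second_pk <- function(E, layer = c("media", "adventitia"),
                                    micro, comp, params,
                                    quadrature = quadrature_spec()) {
  layer <- match.arg(layer)
  plan <- build_layer_plan(layer, micro, quadrature, params)
  d <- diag_strain(E)
  S <- layer_passive_stress_nodes(
    d$tt, d$rr, d$zz, plan, comp[[layer]], params
  )
  as_stress_tensor(S$S_tt, S$S_rr, S$S_zz)
}

#' @rdname layer_passive_second_pk
#' @return `layer_passive_energy()`: the scalar layer strain-energy density
#'   (MPa), the potential whose strain gradient is the stress above.
#' @export
layer_passive_energy <- function(E, layer = c("media", "adventitia"),
                                 micro, comp, params,
                                 quadrature = quadrature_spec()) {
  layer <- match.arg(layer)
  plan <- build_layer_plan(layer, micro, quadrature, params)
  d <- diag_strain(E)
  layer_passive_energy_nodes(d$tt, d$rr, d$zz, plan, comp[[layer]], params)
}
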