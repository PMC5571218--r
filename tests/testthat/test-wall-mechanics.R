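test_that("total stress is the volume-weighted sum of constituent tensors", {
  m <- test_model()
  E <- green_lagrange(c(1.4, 1 / (1.4 * 1.3), 1.3))
  R_med <- with(m$geometry, R_inner + 0.2 * (R_outer - R_inner))
  R_adv <- with(m$geometry, R_inner + 0.9 * (R_outer - R_inner))

  S_tot <- total_second_pk(E, R_med, m, activation = 1)
  S_pass <- layer_passive_second_pk(
    E, "media", m$microstructure, m$composition, m$passive, m$quadrature
  )
  S_act <- m$composition$media[["SMC"]] *
    smc_second_pk(E, m$microstructure, m$active, m$quadrature)
  expect_equal(S_tot, S_pass + S_act, tolerance = 1e-12)

  # adventitial points carry no SMC term: activation is irrelevant there
  expect_equal(
    total_second_pk(E, R_adv, m, activation = 0),
    total_second_pk(E, R_adv, m, activation = 1)
  )

  # zero strain, passive: zero stress
  expect_equal(total_second_pk(green_lagrange(c(1, 1, 1)), R_med, m, 0),
    diag(0, 3),
    ignore_attr = TRUE
  )
  expect_error(total_second_pk(E, 5, m), "outside")
})

test_that("unloaded closed tube carries zero pressure and force", {
  g0 <- reference_geometry(2.5, 1.75, 0)
  m0 <- artery_model(g0, quadrature = quick_quad())
  expect_equal(luminal_pressure(m0, 1, 2.5, 0), 0)
  fa <- axial_force(m0, 1, 2.5, 0)
  expect_equal(fa$axial_force_mN, 0)
  expect_equal(fa$axial_tension_mN, 0)
})

test_that("transmural radial stress meets both boundary conditions", {
  m <- test_model()
  lam_z <- 1.3
  r_o <- solve_outer_radius(m, lam_z, 100, activation = 0)
  prof <- transmural_profile(m, lam_z, r_o, 0, n_points = 21)

  # traction-free outer surface
  expect_equal(prof$sigma_rr_MPa[21], 0, tolerance = 1e-14)
  # equilibrium integration reproduces the luminal pressure at the inner wall
  expect_equal(prof$sigma_rr_MPa[1], -mmHg_to_MPa(100), tolerance = 1e-8)
  # the wall is radially compressed throughout under inflation
  expect_true(all(prof$sigma_rr_MPa <= 1e-12))
  # hoop stress is tensile under 100 mmHg
  expect_true(all(prof$sigma_tt_MPa > 0))
})

test_that("thin-walled limit reproduces the Laplace law", {
  g <- reference_geometry(5.005, 4.995, 0)
  m <- artery_model(g,
    composition = wall_composition(media_fraction = 0.5),
    quadrature = quick_quad()
  )
  lam_z <- 1.2
  r_o <- 5.6
  p <- luminal_pressure(m, lam_z, r_o, 0)
  prof <- transmural_profile(m, lam_z, r_o, 0, n_points = 11)
  h <- r_o - inner_radius(g, lam_z, r_o)
  laplace <- prof$sigma_tt_MPa[6] * h / prof$r_mm[6]
  expect_equal(mmHg_to_MPa(p), laplace, tolerance = 5e-3)
})

test_that("equilibrium integrals are quadrature-converged", {
  m64 <- test_model(quadrature = quadrature_spec(32, 16, 64))
  m128 <- test_model(quadrature = quadrature_spec(32, 16, 128))
  p64 <- luminal_pressure(m64, 1.3, 2.0, 1)
  p128 <- luminal_pressure(m128, 1.3, 2.0, 1)
  expect_lt(abs(p128 - p64) / abs(p64), 1e-6)
  f64 <- axial_force(m64, 1.3, 2.0, 1)$axial_force_mN
  f128 <- axial_force(m128, 1.3, 2.0, 1)$axial_force_mN
  expect_lt(abs(f128 - f64) / abs(f64), 1e-6)
})

test_that("axial tension equals force plus the closed-end pressure term", {
  m <- test_model()
  for (act in c(0, 1)) {
    r_o <- solve_outer_radius(m, 1.3, 80, act)
    fa <- axial_force(m, 1.3, r_o, act)
    r_i <- inner_radius(m$geometry, 1.3, r_o)
    expect_equal(
      fa$axial_tension_mN - fa$axial_force_mN,
      1e3 * mmHg_to_MPa(80) * pi * r_i^2,
      tolerance = 1e-10 * abs(fa$axial_tension_mN)
    )
  }
})

test_that("two independent routes to the axial force agree", {
  # route 1: reference-domain reduced integrand (implementation)
  m <- test_model(quadrature = quadrature_spec(32, 16, 40))
  lam_z <- 1.3
  r_o <- solve_outer_radius(m, lam_z, 100, 0)
  F1 <- axial_force(m, lam_z, r_o, 0)$axial_force_mN

  # route 2: loaded-domain integral of the full axial Cauchy stress,
  # 2 pi int sigma_zz r dr - p_i pi r_i^2, with sigma_zz reconstructed from
  # the equilibrium-integrated radial stress at Gauss-Legendre radii
  g <- m$geometry
  r_i <- inner_radius(g, lam_z, r_o)
  k <- coromicro:::sector_factor(g, lam_z)
  R_m <- coromicro:::interface_radius(m)
  r_m <- loaded_radius(R_m, g, lam_z, r_o)

  hat_at <- function(r) {
    # extra Cauchy components at loaded radius r
    R <- sqrt(g$R_outer^2 - (r_o^2 - r^2) / k)
    t(vapply(seq_along(r), function(j) {
      st <- stretches_at(R[j], g, lam_z, r_o)
      E <- green_lagrange(c(st$lambda_theta, st$lambda_r, lam_z))
      S <- total_second_pk(E, R[j], m, 0)
      c(
        tt = st$lambda_theta^2 * S[1, 1], rr = st$lambda_r^2 * S[2, 2],
        zz = lam_z^2 * S[3, 3]
      )
    }, numeric(3)))
  }
  eq_integrand <- function(r) {
    h <- hat_at(r)
    (h[, "tt"] - h[, "rr"]) / r
  }
  # cumulative sigma_rr at per-layer GL radii, marching outward from -p_i
  nodes <- c(
    coromicro:::gl_nodes(20, r_i, r_m)$x,
    coromicro:::gl_nodes(20, r_m, r_o)$x
  )
  wts <- c(
    coromicro:::gl_nodes(20, r_i, r_m)$w,
    coromicro:::gl_nodes(20, r_m, r_o)$w
  )
  sig_rr <- numeric(length(nodes))
  acc <- -mmHg_to_MPa(100)
  prev <- r_i
  for (j in seq_along(nodes)) {
    acc <- acc + integrate(eq_integrand, prev, nodes[j], rel.tol = 1e-12)$value
    sig_rr[j] <- acc
    prev <- nodes[j]
  }
  h <- hat_at(nodes)
  sig_zz <- sig_rr + (h[, "zz"] - h[, "rr"])
  F2 <- 1e3 * (2 * pi * sum(wts * sig_zz * nodes) -
    mmHg_to_MPa(100) * pi * r_i^2)
  expect_equal(F1, F2, tolerance = 1e-8)
})

test_that("pressure-radius inversion round-trips and orders by activation", {
  m <- test_model()
  # passive pressure is strictly increasing in the outer radius
  rs <- seq(1.5, 2.2, length.out = 12)
  ps <- vapply(rs, function(r) luminal_pressure(m, 1.3, r, 0), numeric(1))
  expect_true(all(diff(ps) > 0))

  r_star <- 1.95
  p_star <- luminal_pressure(m, 1.3, r_star, 0)
  expect_equal(solve_outer_radius(m, 1.3, p_star, 0), r_star, tolerance = 1e-8)

  # zero-pressure passive radius sits below the lambda_z-stretched unloaded
  # radius, with a tiny residual
  r0 <- solve_outer_radius(m, 1.3, 0, 0)
  expect_lt(r0, m$geometry$R_outer * sqrt(coromicro:::sector_factor(m$geometry, 1.3)))
  expect_lt(abs(luminal_pressure(m, 1.3, r0, 0)), 1e-6)

  # SMC activation contracts the vessel at equal pressure
  expect_lt(
    solve_outer_radius(m, 1.3, 60, 1),
    solve_outer_radius(m, 1.3, 60, 0)
  )
})

test_that("protocol simulation reproduces the full factorial schedule and orderings", {
  m <- test_model()
  sim <- simulate_protocol(m)
  expect_equal(nrow(sim), 36)
  expect_equal(
    nrow(dplyr::distinct(sim, pressure_mmHg, lambda_z, state)), 36
  )

  wide_lz <- dplyr::inner_join(
    dplyr::filter(sim, lambda_z == 1.3),
    dplyr::filter(sim, lambda_z == 1.5),
    by = c("pressure_mmHg", "state"), suffix = c("_13", "_15")
  )
  expect_true(all(wide_lz$axial_force_mN_15 > wide_lz$axial_force_mN_13))
  expect_true(all(wide_lz$r_outer_mm_15 < wide_lz$r_outer_mm_13))

  wide_st <- dplyr::inner_join(
    dplyr::filter(sim, state == "passive"),
    dplyr::filter(sim, state == "full"),
    by = c("pressure_mmHg", "lambda_z"), suffix = c("_p", "_f")
  )
  expect_true(all(wide_st$axial_force_mN_f >= wide_st$axial_force_mN_p))
  expect_true(all(wide_st$r_outer_mm_f < wide_st$r_outer_mm_p))
})

test_that("vanishing dispersion reproduces the mean-value model", {
  shrink <- function(cfg, s) {
    shapes <- moment_match_beta(
      recruitment_mean <- coromicro:::recruitment_mean(cfg$adv_recruitment),
      s / 10, 0, 1
    )
    microstructure_config(
      adv_elastin = orientation_mixture(
        lapply(
          cfg$adv_elastin$components,
          function(d) orientation_dist(d$mean_angle, s, d$support)
        ),
        cfg$adv_elastin$weights
      ),
      adv_collagen = orientation_mixture(
        lapply(
          cfg$adv_collagen$components,
          function(d) orientation_dist(d$mean_angle, s, d$support)
        ),
        cfg$adv_collagen$weights
      ),
      adv_recruitment = recruitment_dist("beta",
        shape1 = shapes[["shape1"]],
        shape2 = shapes[["shape2"]], lower = 0, upper = 1
      ),
      media_fiber = orientation_dist(cfg$media_fiber$mean_angle, s, cfg$media_fiber$support),
      media_smc = orientation_dist(cfg$media_smc$mean_angle, s, cfg$media_smc$support),
      media_recruitment = recruitment_dist("uniform",
        lower = coromicro:::recruitment_mean(cfg$media_recruitment) - s / 10,
        upper = coromicro:::recruitment_mean(cfg$media_recruitment) + s / 10
      )
    )
  }
  base <- statistical_default_config()
  m_narrow <- artery_model(test_geom(),
    microstructure = shrink(base, 1e-4),
    quadrature = quick_quad()
  )
  m_mean <- artery_model(test_geom(),
    microstructure = collapse_to_mean(base),
    quadrature = quick_quad()
  )
  for (act in c(0, 1)) {
    for (r_o in c(1.9, 2.05)) {
      p_n <- luminal_pressure(m_narrow, 1.3, r_o, act)
      p_m <- luminal_pressure(m_mean, 1.3, r_o, act)
      expect_lt(abs(p_n - p_m) / abs(p_m), 1e-3)
      f_n <- axial_force(m_narrow, 1.3, r_o, act)$axial_force_mN
      f_m <- axial_force(m_mean, 1.3, r_o, act)$axial_force_mN
      expect_lt(abs(f_n - f_m) / abs(f_m), 1e-3)
    }
  }
})
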