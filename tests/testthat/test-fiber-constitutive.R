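test_that("elastin law is linear, tension-only, and matches its closed form", {
  expect_equal(
    elastin_energy_stress(c(0, -0.1), 0.27),
    tibble::tibble(energy = c(0, 0), stress = c(0, 0))
  )
  es <- elastin_energy_stress(0.2, 0.27)
  expect_equal(es$energy, 0.0054)
  expect_equal(es$stress, 0.054)
  expect_error(elastin_energy_stress(0.1, -1), ">= 0")
})

test_that("collagen law switches on at the straightening strain", {
  p <- passive_fiber_params(k_C = 2, M_C = 1)
  expect_equal(
    collagen_energy_stress(c(0.1, 0.05), p, 0.1),
    tibble::tibble(energy = c(0, 0), stress = c(0, 0))
  )
  cs <- collagen_energy_stress(0.2, p, 0.1)
  expect_equal(cs$energy, 0.01)
  expect_equal(cs$stress, 0.2)

  # fiber stress is the strain derivative of the fiber energy
  set.seed(5)
  for (i in 1:20) {
    pp <- passive_fiber_params(k_C = runif(1, 1, 50), M_C = runif(1, 1.5, 8))
    e0 <- runif(1, 0, 0.3)
    e <- e0 + runif(1, 0.05, 0.5)
    h <- 1e-6
    fd <- (collagen_energy_stress(e + h, pp, e0)$energy -
      collagen_energy_stress(e - h, pp, e0)$energy) / (2 * h)
    expect_equal(collagen_energy_stress(e, pp, e0)$stress, fd, tolerance = 1e-6)
  }
  # stress vanishes continuously at recruitment
  expect_lt(collagen_energy_stress(0.1 + 1e-8, passive_fiber_params(), 0.1)$stress, 1e-10)
  expect_error(collagen_energy_stress(0.2, passive_fiber_params(), -0.1), "e0")
})

test_that("layer stress vanishes at zero strain and energy is nonnegative", {
  micro <- statistical_default_config()
  comp <- wall_composition()
  prm <- passive_fiber_params()
  E0 <- green_lagrange(c(1, 1, 1))
  for (layer in c("media", "adventitia")) {
    expect_equal(layer_passive_second_pk(E0, layer, micro, comp, prm),
      diag(0, 3),
      ignore_attr = TRUE
    )
    expect_equal(layer_passive_energy(E0, layer, micro, comp, prm), 0)
  }
  set.seed(8)
  for (i in 1:10) {
    E <- random_strain()
    for (layer in c("media", "adventitia")) {
      expect_gte(layer_passive_energy(E, layer, micro, comp, prm), 0)
    }
  }
})

test_that("point-mass microstructure reproduces the closed-form discrete-angle sum", {
  micro <- collapse_to_mean(statistical_default_config())
  comp <- wall_composition()
  prm <- passive_fiber_params()
  E <- green_lagrange(c(1.5, 1 / (1.5 * 1.3), 1.3))
  Ett <- E[1, 1]
  Err <- E[2, 2]
  Ezz <- E[3, 3]

  # adventitia: two elastin + two collagen point angles, point recruitment
  hand_adv <- local({
    f <- comp$adventitia
    S <- matrix(0, 3, 3)
    for (j in 1:2) {
      mu <- micro$adv_elastin$components[[j]]$mean_angle
      e <- Ett * cos(mu)^2 + Ezz * sin(mu)^2
      sig <- prm$k_E * max(e, 0)
      S <- S + f[["E"]] * 0.5 * sig * diag(c(cos(mu)^2, 0, sin(mu)^2))
      muC <- micro$adv_collagen$components[[j]]$mean_angle
      eC <- Ett * cos(muC)^2 + Ezz * sin(muC)^2
      e0 <- micro$adv_recruitment$point_value
      sigC <- prm$k_C * max(eC - e0, 0)^prm$M_C
      S <- S + f[["C"]] * 0.5 * sigC * diag(c(cos(muC)^2, 0, sin(muC)^2))
    }
    S
  })
  got_adv <- layer_passive_second_pk(E, "adventitia", micro, comp, prm)
  expect_equal(got_adv, hand_adv, ignore_attr = TRUE, tolerance = 1e-12)

  # media: single mirrored family angle + isotropic IL integral
  hand_med <- local({
    f <- comp$media
    mu <- micro$media_fiber$mean_angle
    e <- Ett * cos(mu)^2 + Ezz * sin(mu)^2
    S <- f[["E"]] * prm$k_E * max(e, 0) * diag(c(cos(mu)^2, 0, sin(mu)^2))
    e0 <- micro$media_recruitment$point_value
    S <- S + f[["C"]] * prm$k_C * max(e - e0, 0)^prm$M_C *
      diag(c(cos(mu)^2, 0, sin(mu)^2))
    # IL elastin: (1/pi) int_{-pi/2}^{pi/2} k_IL max(e,0) (N x N) dtheta
    stt <- integrate(function(th) {
      eIL <- Ett * cos(th)^2 + Err * sin(th)^2
      prm$k_IL * pmax(eIL, 0) * cos(th)^2 / pi
    }, -pi / 2, pi / 2, rel.tol = 1e-12)$value
    srr <- integrate(function(th) {
      eIL <- Ett * cos(th)^2 + Err * sin(th)^2
      prm$k_IL * pmax(eIL, 0) * sin(th)^2 / pi
    }, -pi / 2, pi / 2, rel.tol = 1e-12)$value
    S + f[["IL"]] * diag(c(stt, srr, 0))
  })
  got_med <- layer_passive_second_pk(E, "media", micro, comp, prm)
  expect_equal(got_med, hand_med, ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("layer second PK stress is the strain gradient of the layer energy", {
  micro <- statistical_default_config()
  comp <- wall_composition()
  prm <- passive_fiber_params()
  quad <- quadrature_spec(32, 16, 8)
  set.seed(12)
  for (i in 1:10) {
    E <- random_strain()
    for (layer in c("media", "adventitia")) {
      S <- layer_passive_second_pk(E, layer, micro, comp, prm, quad)
      h <- 1e-5
      for (kk in 1:3) {
        Ep <- E
        Em <- E
        Ep[kk, kk] <- E[kk, kk] + h
        Em[kk, kk] <- E[kk, kk] - h
        fd <- (layer_passive_energy(Ep, layer, micro, comp, prm, quad) -
          layer_passive_energy(Em, layer, micro, comp, prm, quad)) / (2 * h)
        denom <- max(abs(S)) + 1e-8
        expect_lt(abs(S[kk, kk] - fd) / denom, 1e-5)
      }
    }
  }
})

test_that("point recruitment equals direct evaluation; beta matches Monte Carlo", {
  comp <- wall_composition()
  prm <- passive_fiber_params()
  E <- green_lagrange(c(1.55, 1 / (1.55 * 1.3), 1.3))

  base <- statistical_default_config()
  pt <- microstructure_config(
    adv_elastin = base$adv_elastin, adv_collagen = base$adv_collagen,
    adv_recruitment = recruitment_dist("point", point_value = 0.2),
    media_fiber = base$media_fiber, media_smc = base$media_smc,
    media_recruitment = base$media_recruitment
  )
  got <- layer_passive_second_pk(E, "adventitia", pt, comp, prm)
  # same layer with the collagen term rebuilt from single-e0 fiber stresses
  plan <- coromicro:::build_layer_plan("adventitia", pt, quadrature_spec())
  con <- plan$collagen
  e <- coromicro:::constituent_strain(E[1, 1], E[2, 2], E[3, 3], con)
  sig <- prm$k_C * pmax(e - 0.2, 0)^prm$M_C
  S_tt_C <- drop(sig %*% (con$wt * cos(con$theta)^2))
  ela <- plan$elastin
  eE <- coromicro:::constituent_strain(E[1, 1], E[2, 2], E[3, 3], ela)
  S_tt_E <- drop((prm$k_E * pmax(eE, 0)) %*% (ela$wt * cos(ela$theta)^2))
  expect_equal(
    got[1, 1],
    comp$adventitia[["C"]] * S_tt_C + comp$adventitia[["E"]] * S_tt_E,
    tolerance = 1e-12
  )

  # beta recruitment: quadrature expectation vs Monte-Carlo over e0 draws
  b <- base$adv_recruitment
  set.seed(21)
  e0s <- rbeta(1e5, b$shape1, b$shape2)
  efix <- 0.5
  mc <- prm$k_C * pmax(efix - e0s, 0)^prm$M_C
  rn <- coromicro:::recruitment_nodes(b, 32)
  quad_val <- sum(rn$wt * prm$k_C * pmax(efix - rn$e0, 0)^prm$M_C)
  expect_lt(abs(quad_val - mean(mc)), 3 * sd(mc) / sqrt(length(mc)))
})

test_that("layer quadrature is converged and collagen response is monotone", {
  micro <- statistical_default_config()
  comp <- wall_composition()
  prm <- passive_fiber_params()
  E <- green_lagrange(c(1.5, 1 / (1.5 * 1.3), 1.3))
  for (layer in c("media", "adventitia")) {
    S64 <- layer_passive_second_pk(E, layer, micro, comp, prm, quadrature_spec(64, 32, 8))
    S128 <- layer_passive_second_pk(E, layer, micro, comp, prm, quadrature_spec(128, 64, 8))
    expect_lt(max(abs(S128 - S64)) / max(abs(S64)), 1e-6)
  }
  # circumferential stress nondecreasing in E_tt at fixed other components
  Etts <- seq(0, 0.8, length.out = 15)
  vals <- vapply(Etts, function(Ett) {
    E2 <- diag(c(Ett, -0.2, 0.345))
    layer_passive_second_pk(E2, "adventitia", micro, comp, prm)[1, 1]
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
})
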