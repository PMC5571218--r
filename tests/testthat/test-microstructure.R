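test_that("truncated normal density is normalised, symmetric, and matches quadrature", {
  d <- orientation_dist(0.32, 0.26, c(0, pi))
  I <- integrate(function(x) truncated_normal_density(x, d), 0, pi,
    rel.tol = 1e-10
  )$value
  expect_equal(I, 1, tolerance = 1e-6)

  # symmetric about the mean when the mean sits at the support midpoint
  ds <- orientation_dist(pi / 2, 0.4, c(0, pi))
  off <- seq(0.05, 1.2, by = 0.2)
  expect_equal(
    truncated_normal_density(pi / 2 + off, ds),
    truncated_normal_density(pi / 2 - off, ds)
  )

  # normalising weight equals the integral of the untruncated normal
  K_oracle <- integrate(function(x) dnorm(x, 0.32, 0.26), 0, pi,
    rel.tol = 1e-12
  )$value
  expect_equal(d$norm_weight, K_oracle, tolerance = 1e-8)

  expect_equal(truncated_normal_density(c(-0.1, pi + 0.1), d), c(0, 0))
  expect_error(orientation_dist(0.3, -0.1), "sd_angle")
  expect_error(truncated_normal_density(0.3, orientation_dist(0.3, 0)), "point-mass")
})

test_that("orientation mixtures reduce, normalise and are bimodal where measured", {
  c1 <- orientation_dist(0.20, 0.30, c(0, pi))
  c2 <- orientation_dist(2.09, 0.22, c(0, pi))
  mix <- orientation_mixture(list(c1, c2), c(1, 0))
  th <- seq(0.01, pi - 0.01, length.out = 30)
  expect_equal(mixture_density(th, mix), truncated_normal_density(th, c1))

  mix2 <- orientation_mixture(list(c1, c2))
  I <- integrate(function(x) mixture_density(x, mix2), 0, pi, rel.tol = 1e-10)$value
  expect_equal(I, 1, tolerance = 1e-6)

  # adventitial collagen (sample 1 refined estimates) is bimodal with local
  # maxima near the two family means
  dens <- mixture_density(th, mix2)
  peaks <- th[which(diff(sign(diff(dens))) == -2) + 1]
  expect_length(peaks, 2)
  expect_lt(abs(peaks[1] - 0.20), 0.1)
  expect_lt(abs(peaks[2] - 2.09), 0.1)

  expect_error(orientation_mixture(list(c1, c2), c(0.7, 0.6)), "sum to 1")
})

test_that("recruitment densities follow their closed forms", {
  u <- recruitment_dist("uniform", lower = 0, upper = 0.35)
  expect_equal(recruitment_density(c(0.1, 0.3), u), rep(1 / 0.35, 2))
  expect_equal(recruitment_density(0.4, u), 0)

  b <- recruitment_dist("beta", shape1 = 6, shape2 = 60, lower = 0, upper = 1)
  I <- integrate(function(x) recruitment_density(x, b), 0, 1, rel.tol = 1e-10)$value
  expect_equal(I, 1, tolerance = 1e-6)

  p <- recruitment_dist("point", point_value = 0.3)
  expect_equal(recruitment_density(c(0.3, 0.2), p), c(Inf, 0))
})

test_that("beta moment matching is exact and detects infeasible moments", {
  sh <- moment_match_beta(0.35, 0.051, 0, 1)
  m <- sh[["shape1"]] / (sh[["shape1"]] + sh[["shape2"]])
  v <- sh[["shape1"]] * sh[["shape2"]] /
    ((sh[["shape1"]] + sh[["shape2"]])^2 * (sh[["shape1"]] + sh[["shape2"]] + 1))
  expect_equal(m, 0.35, tolerance = 1e-10)
  expect_equal(sqrt(v), 0.051, tolerance = 1e-10)

  # symmetric shapes when the target mean is the support midpoint
  sh2 <- moment_match_beta(0.5, 0.1, 0, 1)
  expect_equal(sh2[["shape1"]], sh2[["shape2"]], tolerance = 1e-12)

  # general bounds round trip
  sh3 <- moment_match_beta(0.2, 0.03, 0.05, 0.6)
  m3 <- 0.05 + 0.55 * sh3[["shape1"]] / (sh3[["shape1"]] + sh3[["shape2"]])
  expect_equal(m3, 0.2, tolerance = 1e-10)

  expect_error(moment_match_beta(0.5, 0.6, 0, 1), "Infeasible")
  expect_error(moment_match_beta(1.2, 0.1, 0, 1), "inside")

  # calibrated distribution reproduces the target mean in Monte Carlo
  set.seed(1)
  draws <- rbeta(1e6, sh[["shape1"]], sh[["shape2"]])
  expect_lt(abs(mean(draws) - 0.35), 3 * 0.051 / sqrt(1e6))
})

test_that("packaged statistical defaults are valid and carry the measured values", {
  cfg <- statistical_default_config()
  expect_equal(cfg$media_smc$mean_angle, 0.24)
  expect_equal(cfg$media_fiber$mean_angle, 0.23)
  expect_equal(cfg$media_recruitment$upper, 0.35)
  expect_equal(
    cfg$adv_recruitment$shape1 /
      (cfg$adv_recruitment$shape1 + cfg$adv_recruitment$shape2),
    0.35,
    tolerance = 1e-10
  )
  # every continuous distribution integrates to 1
  for (mx in list(cfg$adv_elastin, cfg$adv_collagen)) {
    I <- integrate(function(x) mixture_density(x, mx), 0, pi, rel.tol = 1e-9)$value
    expect_equal(I, 1, tolerance = 1e-6)
  }
  for (d in list(cfg$media_fiber, cfg$media_smc)) {
    I <- integrate(function(x) truncated_normal_density(x, d),
      d$support[1], d$support[2],
      rel.tol = 1e-9
    )$value
    expect_equal(I, 1, tolerance = 1e-6)
  }
  I <- integrate(function(x) recruitment_density(x, cfg$adv_recruitment), 0, 1,
    rel.tol = 1e-9
  )$value
  expect_equal(I, 1, tolerance = 1e-6)
})

test_that("quantile-domain quadrature reproduces density expectations and point masses", {
  d <- orientation_dist(0.6, 0.25, c(0, pi / 2))
  g <- function(th) cos(th)^2 * exp(th / 2)
  oracle <- integrate(function(x) truncated_normal_density(x, d) * g(x),
    0, pi / 2,
    rel.tol = 1e-12
  )$value
  nodes64 <- coromicro:::orientation_nodes(d, 64)
  expect_equal(sum(nodes64$wt * g(nodes64$theta)), oracle, tolerance = 1e-8)

  # doubling nodes moves the expectation by < 1e-8 relative
  nodes128 <- coromicro:::orientation_nodes(d, 128)
  e64 <- sum(nodes64$wt * g(nodes64$theta))
  e128 <- sum(nodes128$wt * g(nodes128$theta))
  expect_lt(abs(e128 - e64) / abs(e64), 1e-8)

  # point-mass limit: expectation is the integrand at the mean, exactly
  d0 <- orientation_dist(0.6, 0, c(0, pi / 2))
  n0 <- coromicro:::orientation_nodes(d0, 64)
  expect_identical(sum(n0$wt * g(n0$theta)), g(0.6))

  # recruitment expectations under beta vs dense quadrature oracle
  b <- recruitment_dist("beta", shape1 = 6.07, shape2 = 60, lower = 0, upper = 1)
  h <- function(e0) pmax(0.4 - e0, 0)^2
  rn <- coromicro:::recruitment_nodes(b, 64)
  oracle_b <- integrate(function(x) recruitment_density(x, b) * h(x), 0, 1,
    rel.tol = 1e-12
  )$value
  expect_equal(sum(rn$wt * h(rn$e0)), oracle_b, tolerance = 1e-6)
})
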