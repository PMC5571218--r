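#' Truncated-normal fiber orientation distribution
#'
#' Orientation densities of elastin, collagen and smooth muscle cells are
#' modelled as normal distributions truncated to an angular support, with the
#' normalising weight `K = Phi((hi - mu)/sigma) - Phi((lo - mu)/sigma)`.
#' A zero standard deviation is the degenerate point-mass limit used by the
#' mean-value model.
#'
#' @param mean_angle Mean orientation (radians, from the circumferential axis).
#' @param sd_angle Standard deviation (radians, >= 0; 0 gives a point mass).
#' @param support Length-2 numeric, angular support `(lo, hi)` in radians.
#' @return An object of class `orientation_dist`.
#' @export
#' @examples
#' orientation_dist(0.32, 0.26, support = c(0, pi))
orientation_dist <- function(mean_angle, sd_angle, support = c(0, pi)) {
  stopifnot(length(support) == 2, support[2] > support[1])
  if (sd_angle < 0) abort("`sd_angle` must be >= 0.")
  if (sd_angle == 0 && (mean_angle < support[1] || mean_angle > support[2])) {
    abort("Point-mass `mean_angle` must lie inside the support.")
  }
  K <- if (sd_angle == 0) 1 else {
    pnorm((support[2] - mean_angle) / sd_angle) -
      pnorm((support[1] - mean_angle) / sd_angle)
  }
  if (K <= 0) abort("Truncated-normal weight K is not positive; check the support.")
  structure(
    list(
      mean_angle = mean_angle, sd_angle = sd_angle,
      support = as.numeric(support), norm_weight = K
    ),
    class = "orientation_dist"
  )
}

#' Truncated-normal orientation density
#'
#' @param angle Angle(s) in radians; values outside the support return 0.
#' @param dist An [orientation_dist()].
#' @return Density values (1/rad).
#' @export
truncated_normal_density <- function(angle, dist) {
  stopifnot(inherits(dist, "orientation_dist"))
  if (dist$sd_angle <= 0) abort("Density undefined for a point-mass distribution (sd = 0).")
  inside <- angle >= dist$support[1] & angle <= dist$support[2]
  d <- numeric(length(angle))
  d[inside] <- dnorm(angle[inside], dist$mean_angle, dist$sd_angle) / dist$norm_weight
  d
}

#' Two-component orientation mixture
#'
#' Adventitial elastin and collagen orientations follow mixtures of two
#' truncated normal distributions (a near-circumferential and a
#' near-longitudinal family); the mixture weights must sum to 1.
#'
#' @param components List of [orientation_dist()] objects.
#' @param weights Numeric mixture weights, summing to 1.
#' @return An object of class `orientation_mixture`.
#' @export
orientation_mixture <- function(components, weights = rep(1 / length(components), length(components))) {
  stopifnot(length(components) == length(weights))
  if (!all(vapply(components, inherits, logical(1), "orientation_dist"))) {
    abort("All `components` must be orientation_dist objects.")
  }
  if (abs(sum(weights) - 1) > 1e-8) abort("Mixture `weights` must sum to 1.")
  if (any(weights < 0)) abort("Mixture `weights` must be nonnegative.")
  structure(list(components = components, weights = as.numeric(weights)),
    class = "orientation_mixture"
  )
}

#' Orientation mixture density
#'
#' @param angle Angle(s) in radians.
#' @param mix An [orientation_mixture()].
#' @return Density values (1/rad).
#' @export
mixture_density <- function(angle, mix) {
  stopifnot(inherits(mix, "orientation_mixture"))
  Reduce(`+`, Map(
    function(comp, w) w * truncated_normal_density(angle, comp),
    mix$components, mix$weights
  ))
}

#' Collagen straightening-strain (recruitment) distribution
#'
#' Wavy collagen fibers only bear load beyond their straightening strain
#' `e0`. In the adventitia `e0` follows a beta distribution on `[a, b]`; in
#' the media a uniform distribution is assumed; the mean-value model uses a
#' degenerate point distribution.
#'
#' @param kind `"beta"`, `"uniform"` or `"point"`.
#' @param shape1,shape2 Beta shape parameters (`kind = "beta"`).
#' @param lower,upper Support bounds (strain).
#' @param point_value All-mass location for `kind = "point"`.
#' @return An object of class `recruitment_dist`.
#' @export
#' @examples
#' recruitment_dist("uniform", lower = 0, upper = 0.35)
recruitment_dist <- function(kind = c("beta", "uniform", "point"),
                             shape1 = NULL, shape2 = NULL,
                             lower = 0, upper = 1, point_value = NULL) {
  kind <- match.arg(kind)
  if (kind == "beta") {
    if (is.null(shape1) || is.null(shape2) || shape1 <= 0 || shape2 <= 0) {
      abort("Beta recruitment needs positive `shape1` and `shape2`.")
    }
    if (!(upper > lower && lower >= 0)) abort("Need `upper > lower >= 0`.")
  } else if (kind == "uniform") {
    if (!(upper > lower)) abort("Need `upper > lower`.")
  } else {
    if (is.null(point_value) || point_value < 0) {
      abort("Point recruitment needs a nonnegative `point_value`.")
    }
  }
  structure(
    list(
      kind = kind, shape1 = shape1, shape2 = shape2,
      lower = lower, upper = upper, point_value = point_value
    ),
    class = "recruitment_dist"
  )
}

#' Recruitment-strain density
#'
#' @param e0 Straightening strain(s).
#' @param dist A [recruitment_dist()]. For a point distribution the density
#'   is a Dirac mass: `Inf` at the point, 0 elsewhere (expectations are
#'   evaluated by direct substitution, not through this density).
#' @return Density values (1/strain).
#' @export
recruitment_density <- function(e0, dist) {
  stopifnot(inherits(dist, "recruitment_dist"))
  switch(dist$kind,
    beta = {
      inside <- e0 >= dist$lower & e0 <= dist$upper
      d <- numeric(length(e0))
      w <- dist$upper - dist$lower
      d[inside] <- dbeta((e0[inside] - dist$lower) / w, dist$shape1, dist$shape2) / w
      d
    },
    uniform = ifelse(e0 >= dist$lower & e0 <= dist$upper,
      1 / (dist$upper - dist$lower), 0
    ),
    point = ifelse(e0 == dist$point_value, Inf, 0)
  )
}

# Mean of a recruitment distribution (closed form).
recruitment_mean <- function(dist) {
  switch(dist$kind,
    beta = dist$lower + (dist$upper - dist$lower) *
      dist$shape1 / (dist$shape1 + dist$shape2),
    uniform = (dist$lower + dist$upper) / 2,
    point = dist$point_value
  )
}

#' Calibrate beta shapes to a target mean and standard deviation
#'
#' Standard beta moment matching on `[a, b]`: with `m = (mean - a)/(b - a)`
#' and `s = sd/(b - a)`, the shapes are `alpha1 = m * nu`,
#' `alpha2 = (1 - m) * nu` where `nu = m (1 - m) / s^2 - 1`.
#'
#' @param target_mean,target_sd Desired mean and standard deviation (strain).
#' @param a,b Support bounds.
#' @return Named numeric vector `c(shape1, shape2)`.
#' @export
#' @examples
#' moment_match_beta(0.35, 0.051)
moment_match_beta <- function(target_mean, target_sd, a = 0, b = 1) {
  if (!(a < target_mean && target_mean < b)) {
    abort("`target_mean` must lie strictly inside (a, b).")
  }
  if (target_sd^2 >= (target_mean - a) * (b - target_mean)) {
    abort("Infeasible moments: variance exceeds the beta bound on this support.")
  }
  m <- (target_mean - a) / (b - a)
  s2 <- (target_sd / (b - a))^2
  nu <- m * (1 - m) / s2 - 1
  c(shape1 = m * nu, shape2 = (1 - m) * nu)
}

#' Full microstructural configuration of the wall
#'
#' Collects the orientation mixtures, symmetric medial families and
#' recruitment distributions of every constituent. Media elastin and collagen
#' share two mirrored truncated-normal families about the circumferential
#' direction; smooth muscle cells have their own mirrored family;
#' inter-lamellar elastin is isotropic in the circumferential-radial plane.
#'
#' @param adv_elastin,adv_collagen [orientation_mixture()] objects on `[0, pi]`.
#' @param adv_recruitment Adventitial collagen [recruitment_dist()] (beta, or
#'   point in the mean-value model).
#' @param media_fiber [orientation_dist()] of the medial elastin/collagen
#'   family on `[0, pi/2]` (mirrored internally).
#' @param media_smc [orientation_dist()] of the SMC family on `[0, pi/2]`.
#' @param media_recruitment Medial collagen [recruitment_dist()] (uniform on
#'   `[0, e_02]`, or point).
#' @param mode `"full"` (continuous distributions) or `"mean_value"`
#'   (all point masses).
#' @return An object of class `microstructure_config`.
#' @seealso [statistical_default_config()], [collapse_to_mean()]
#' @export
microstructure_config <- function(adv_elastin, adv_collagen, adv_recruitment,
                                  media_fiber, media_smc, media_recruitment,
                                  mode = c("full", "mean_value")) {
  mode <- match.arg(mode)
  stopifnot(
    inherits(adv_elastin, "orientation_mixture"),
    inherits(adv_collagen, "orientation_mixture"),
    inherits(adv_recruitment, "recruitment_dist"),
    inherits(media_fiber, "orientation_dist"),
    inherits(media_smc, "orientation_dist"),
    inherits(media_recruitment, "recruitment_dist")
  )
  if (mode == "mean_value") {
    sds <- c(
      vapply(adv_elastin$components, `[[`, numeric(1), "sd_angle"),
      vapply(adv_collagen$components, `[[`, numeric(1), "sd_angle"),
      media_fiber$sd_angle, media_smc$sd_angle
    )
    if (any(sds != 0) || adv_recruitment$kind != "point" ||
      media_recruitment$kind != "point") {
      abort("mean_value mode requires point-mass distributions throughout.")
    }
  }
  structure(
    list(
      adv_elastin = adv_elastin, adv_collagen = adv_collagen,
      adv_recruitment = adv_recruitment,
      media_fiber = media_fiber, media_smc = media_smc,
      media_recruitment = media_recruitment, mode = mode
    ),
    class = "microstructure_config"
  )
}

#' Packaged statistical microstructure defaults
#'
#' The default configuration packages the statistically measured orientation
#' and waviness distributions of porcine coronary arteries: bimodal
#' adventitial elastin and collagen mixtures (equal weights), mirrored medial
#' fiber and SMC families, a beta-distributed adventitial straightening
#' strain calibrated by moment matching to mean 0.35 and SD 0.051 on
#' `[0, 1]`, and a uniform medial straightening strain on `[0, 0.35]`.
#'
#' @return A `microstructure_config`.
#' @export
#' @examples
#' cfg <- statistical_default_config()
#' cfg$media_smc$mean_angle
statistical_default_config <- function() {
  shapes <- moment_match_beta(0.35, 0.051, a = 0, b = 1)
  microstructure_config(
    adv_elastin = orientation_mixture(list(
      orientation_dist(0.25, 0.17, c(0, pi)),
      orientation_dist(1.84, 0.38, c(0, pi))
    )),
    adv_collagen = orientation_mixture(list(
      orientation_dist(0.32, 0.23, c(0, pi)),
      orientation_dist(1.81, 0.33, c(0, pi))
    )),
    adv_recruitment = recruitment_dist("beta",
      shape1 = shapes[["shape1"]], shape2 = shapes[["shape2"]],
      lower = 0, upper = 1
    ),
    media_fiber = orientation_dist(0.23, 0.19, c(0, pi / 2)),
    media_smc = orientation_dist(0.24, 0.21, c(0, pi / 2)),
    media_recruitment = recruitment_dist("uniform", lower = 0, upper = 0.35)
  )
}

#' Collapse a microstructure configuration to its mean-value model
#'
#' Replaces every orientation distribution by a point mass at its mean and
#' every recruitment distribution by a point mass at its mean, giving the
#' degenerate single-angle ("mean-value") model.
#'
#' @param config A [microstructure_config()].
#' @return A `microstructure_config` with `mode = "mean_value"`.
#' @export
collapse_to_mean <- function(config) {
  stopifnot(inherits(config, "microstructure_config"))
  point_mix <- function(mix) {
    orientation_mixture(
      lapply(mix$components, function(d) {
        orientation_dist(d$mean_angle, 0, d$support)
      }),
      mix$weights
    )
  }
  microstructure_config(
    adv_elastin = point_mix(config$adv_elastin),
    adv_collagen = point_mix(config$adv_collagen),
    adv_recruitment = recruitment_dist("point",
      point_value = recruitment_mean(config$adv_recruitment)
    ),
    media_fiber = orientation_dist(
      config$media_fiber$mean_angle, 0, config$media_fiber$support
    ),
    media_smc = orientation_dist(
      config$media_smc$mean_angle, 0, config$media_smc$support
    ),
    media_recruitment = recruitment_dist("point",
      point_value = recruitment_mean(config$media_recruitment)
    ),
    mode = "mean_value"
  )
}

# ---- effective-support panel quadrature -----------------------------------
# Expectations over orientation and recruitment distributions are computed by
# density-weighted, mass-allocated composite Gauss-Legendre rules on the
# distribution's *effective* support (mean +/- 10 SD, clipped to the nominal
# support; the excluded tail mass is below 1e-20). The window is split into
# panels at mean +/- {1, 2, 4} SD and each panel receives nodes in proportion
# to its probability mass, so a fixed node budget resolves both wide and
# arbitrarily narrow distributions; the rule collapses exactly to the
# point-mass (mean-value) limit as sd -> 0.

.gl_cache <- new.env(parent = emptyenv())

gl_unit_nodes <- function(n) {
  key <- as.character(n)
  got <- .gl_cache[[key]]
  if (!is.null(got)) {
    return(got)
  }
  if (n == 1) {
    out <- list(x = 0.5, w = 1)
    .gl_cache[[key]] <- out
    return(out)
  }
  gl <- pracma::gaussLegendre(n, 0, 1)
  out <- list(x = gl$x, w = gl$w)
  .gl_cache[[key]] <- out
  out
}

# Cached Gauss-Legendre rule on an arbitrary interval.
gl_nodes <- function(n, a, b) {
  u <- gl_unit_nodes(n)
  list(x = a + (b - a) * u$x, w = (b - a) * u$w)
}

# Composite rule: breaks at mu + sd * c, nodes per panel proportional to the
# panel's probability mass (cdf need not be normalised).
panel_gl_nodes <- function(n, mu, sd, lo, hi, cdf, pdf, norm = 1) {
  cuts <- mu + sd * c(-10, -4, -2, -1, 0, 1, 2, 4, 10)
  cuts <- sort(unique(pmin(pmax(cuts, lo), hi)))
  if (length(cuts) < 2) cuts <- c(lo, hi)
  mass <- pmax(diff(cdf(cuts)), 0)
  keep <- which(mass > 1e-14 | diff(cuts) > 1e-13 * max(abs(cuts), 1))
  if (!length(keep)) keep <- seq_along(mass)
  n_i <- pmax(ceiling(n / 8), round(n * mass[keep] / sum(mass[keep])))
  xs <- ws <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    gl <- gl_nodes(n_i[j], cuts[i], cuts[i + 1])
    xs[[j]] <- gl$x
    ws[[j]] <- gl$w * pdf(gl$x)
  }
  w <- unlist(ws, use.names = FALSE)
  # renormalise to the exact probability mass of the window, so narrow
  # distributions carry full weight at any node budget
  target <- (cdf(cuts[length(cuts)]) - cdf(cuts[1])) / norm
  s <- sum(w)
  if (s > 0 && target > 0) w <- w * (target / s)
  list(x = unlist(xs, use.names = FALSE), w = w)
}

# Quadrature nodes/weights for one orientation_dist; weights sum to `weight`
# (up to negligible tail mass).
orientation_nodes <- function(dist, n, weight = 1) {
  if (dist$sd_angle == 0) {
    return(list(theta = dist$mean_angle, wt = weight))
  }
  gl <- panel_gl_nodes(
    n, dist$mean_angle, dist$sd_angle,
    dist$support[1], dist$support[2],
    cdf = function(x) pnorm((x - dist$mean_angle) / dist$sd_angle),
    pdf = function(x) truncated_normal_density(x, dist),
    norm = dist$norm_weight
  )
  list(theta = gl$x, wt = weight * gl$w)
}

mixture_nodes <- function(mix, n) {
  parts <- Map(
    function(comp, w) orientation_nodes(comp, n, w),
    mix$components, mix$weights
  )
  list(
    theta = unlist(lapply(parts, `[[`, "theta"), use.names = FALSE),
    wt = unlist(lapply(parts, `[[`, "wt"), use.names = FALSE)
  )
}

recruitment_nodes <- function(dist, n) {
  if (dist$kind == "point") {
    return(list(e0 = dist$point_value, wt = 1))
  }
  if (dist$kind == "uniform") {
    gl <- gl_nodes(n, dist$lower, dist$upper)
    return(list(e0 = gl$x, wt = gl$w / (dist$upper - dist$lower)))
  }
  m <- recruitment_mean(dist)
  s <- (dist$upper - dist$lower) * sqrt(
    dist$shape1 * dist$shape2 /
      ((dist$shape1 + dist$shape2)^2 * (dist$shape1 + dist$shape2 + 1))
  )
  gl <- panel_gl_nodes(
    n, m, s, dist$lower, dist$upper,
    cdf = function(x) {
      pbeta((x - dist$lower) / (dist$upper - dist$lower), dist$shape1, dist$shape2)
    },
    pdf = function(x) recruitment_density(x, dist)
  )
  list(e0 = gl$x, wt = gl$w)
}
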