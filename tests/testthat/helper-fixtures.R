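# Shared fixtures: a mid-size porcine-scale geometry and a model with a
# reduced (but converged-to-test-tolerance) quadrature so the suite stays fast.

quick_quad <- function() quadrature_spec(n_angle = 16, n_recruit = 8, n_radial = 6)

test_geom <- function() reference_geometry(R_outer = 2.5, R_inner = 1.75, opening_angle = 1.4)

test_model <- function(..., quadrature = quick_quad()) {
  artery_model(test_geom(), quadrature = quadrature, ...)
}

# Random diagonal Green-Lagrange strain in a physiological-ish range.
random_strain <- function() {
  lam <- c(runif(1, 0.9, 1.6), runif(1, 0.5, 1.1), runif(1, 1.0, 1.6))
  green_lagrange(lam)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
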