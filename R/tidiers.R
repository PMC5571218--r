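#' Tidy and glance methods for fitted artery models
#'
#' `tidy()` returns one row per estimated parameter with its search bounds;
#' `glance()` returns a one-row model summary with the objective value and
#' the per-channel goodness of fit (columns
#' `r2_<channel>_<state>`).
#'
#' @param x An `artery_fit` from [fit_parameters()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.artery_fit <- function(x, ...) {
  tibble(
    term = x$spec$name,
    estimate = unname(x$par[x$spec$name]),
    lower = x$spec$lower,
    upper = x$spec$upper
  )
}

#' @rdname tidy.artery_fit
#' @export
glance.artery_fit <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    tidyr::pivot_longer(x$r2, -"state", names_to = "metric"),
    names_from = c("metric", "state"), values_from = "value"
  )
  dplyr::bind_cols(
    tibble(
      sse = x$sse,
      nobs = nrow(x$data),
      n_par = length(x$par),
      mode = x$config$mode,
      generations = x$config$generations,
      converged = x$convergence
    ),
    wide
  )
}
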