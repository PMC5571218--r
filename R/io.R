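experiment_columns <- c(
  "pressure_mmHg", "lambda_z", "state", "r_outer_mm", "axial_force_mN"
)

#' Write / read biaxial experiment tables
#'
#' Datasets are stored as plain comma-separated CSV with a required header
#' (`pressure_mmHg`, `lambda_z`, `state`, `r_outer_mm`, `axial_force_mN`,
#' plus any extra columns such as `axial_tension_mN` and `replicate`). A JSON
#' sidecar (`<path>.json`) carries the reproducibility metadata: package
#' version, configuration hash, seed, geometry, noise scales and, for
#' synthetic data, the generating truth parameters.
#'
#' @param data An `artery_dataset` (or compatible tibble).
#' @param path CSV file path.
#' @return `write_experiment_table()` returns `path` invisibly;
#'   `load_experiment_table()` returns a validated `artery_dataset` tibble
#'   (with sidecar attributes restored when present).
#' @export
write_experiment_table <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE)
  meta <- list(
    tool = "coromicro",
    version = as.character(packageVersion("coromicro")),
    seed = attr(data, "seed"),
    config_hash = rlang::hash(list(
      attr(data, "geometry"), attr(data, "noise"), attr(data, "truth")
    )),
    geometry = unclass(attr(data, "geometry")),
    noise = unclass(attr(data, "noise")),
    truth = as.list(attr(data, "truth"))
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_experiment_table
#' @export
load_experiment_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(experiment_columns, names(df))
  if (length(missing)) {
    abort(sprintf(
      "Experiment table %s is missing column(s): %s",
      path, paste(missing, collapse = ", ")
    ))
  }
  for (col in setdiff(experiment_columns, "state")) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      abort(sprintf("Non-numeric value in column '%s' (row %d).", col, bad))
    }
  }
  bad_state <- which(!df$state %in% c("passive", "full"))
  if (length(bad_state)) {
    abort(sprintf(
      "Invalid state '%s' in column 'state' (row %d); expected 'passive' or 'full'.",
      df$state[bad_state[1]], bad_state[1]
    ))
  }
  bad_p <- which(df$pressure_mmHg < 0 | df$pressure_mmHg > 160)
  if (length(bad_p)) {
    abort(sprintf(
      "Pressure out of range [0, 160] mmHg in column 'pressure_mmHg' (row %d).",
      bad_p[1]
    ))
  }
  out <- as_tibble(df)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$geometry)) {
      attr(out, "geometry") <- do.call(reference_geometry, meta$geometry)
    }
    if (!is.null(meta$noise)) attr(out, "noise") <- do.call(noise_scales, meta$noise)
    if (!is.null(meta$truth)) attr(out, "truth") <- unlist(meta$truth)
    attr(out, "seed") <- meta$seed
  }
  class(out) <- c("artery_dataset", class(out))
  out
}

# ---- run configuration (YAML / JSON) --------------------------------------

check_keys <- function(x, allowed, block) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    abort(sprintf(
      "Unknown key(s) in %s block: %s", block, paste(unknown, collapse = ", ")
    ))
  }
}

dist_to_list <- function(d) {
  list(
    mean_angle = d$mean_angle, sd_angle = d$sd_angle,
    support = as.numeric(d$support)
  )
}
dist_from_list <- function(x, block) {
  check_keys(x, c("mean_angle", "sd_angle", "support"), block)
  orientation_dist(x$mean_angle, x$sd_angle, as.numeric(x$support))
}
mix_to_list <- function(m) {
  list(
    components = lapply(m$components, dist_to_list),
    weights = as.numeric(m$weights)
  )
}
mix_from_list <- function(x, block) {
  check_keys(x, c("components", "weights"), block)
  orientation_mixture(
    lapply(x$components, dist_from_list, block = block),
    as.numeric(x$weights)
  )
}
rec_to_list <- function(r) {
  list(
    kind = r$kind, shape1 = r$shape1, shape2 = r$shape2,
    lower = r$lower, upper = r$upper, point_value = r$point_value
  )
}
rec_from_list <- function(x, block) {
  check_keys(x, c("kind", "shape1", "shape2", "lower", "upper", "point_value"), block)
  recruitment_dist(
    kind = x$kind, shape1 = x$shape1, shape2 = x$shape2,
    lower = x$lower %||% 0, upper = x$upper %||% 1,
    point_value = x$point_value
  )
}

#' Serialise / parse a full run configuration
#'
#' A run configuration bundles the model blocks (geometry, composition,
#' microstructure, passive, active, quadrature) with a loading protocol and
#' a seed, as YAML (JSON is valid YAML and is also accepted). Unknown keys
#' are rejected.
#'
#' @param model An [artery_model()].
#' @param path File path (`.yaml`/`.yml`/`.json`).
#' @param protocol List with `pressures`, `stretches`, `states`.
#' @param seed Integer seed recorded in the config.
#' @return `write_run_config()` returns `path` invisibly; `read_run_config()`
#'   returns a list with elements `model` (an `artery_model`), `protocol`
#'   and `seed`.
#' @export
write_run_config <- function(model, path,
                             protocol = list(
                               pressures = seq(0, 160, 20),
                               stretches = c(1.3, 1.5),
                               states = c("passive", "full")
                             ),
                             seed = 1) {
  stopifnot(inherits(model, "artery_model"))
  micro <- model$microstructure
  cfg <- list(
    geometry = unclass(model$geometry),
    composition = list(
      media_fraction = model$composition$media_fraction,
      media = as.list(model$composition$media),
      adventitia = as.list(model$composition$adventitia)
    ),
    microstructure = list(
      mode = micro$mode,
      adv_elastin = mix_to_list(micro$adv_elastin),
      adv_collagen = mix_to_list(micro$adv_collagen),
      adv_recruitment = rec_to_list(micro$adv_recruitment),
      media_fiber = dist_to_list(micro$media_fiber),
      media_smc = dist_to_list(micro$media_smc),
      media_recruitment = rec_to_list(micro$media_recruitment)
    ),
    passive = unclass(model$passive),
    active = unclass(model$active),
    quadrature = unclass(model$quadrature),
    protocol = protocol,
    seed = seed
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, c(
    "geometry", "composition", "microstructure", "passive", "active",
    "quadrature", "protocol", "fit", "seed", "output"
  ), "top-level")
  check_keys(cfg$geometry, c("R_outer", "R_inner", "opening_angle", "length_ref"), "geometry")
  geom <- do.call(reference_geometry, cfg$geometry)

  comp <- wall_composition()
  if (!is.null(cfg$composition)) {
    check_keys(cfg$composition, c("media_fraction", "media", "adventitia"), "composition")
    comp <- wall_composition(
      media_fraction = cfg$composition$media_fraction %||% (2 / 3),
      media = unlist(cfg$composition$media %||% as.list(wall_composition()$media)),
      adventitia = unlist(cfg$composition$adventitia %||% as.list(wall_composition()$adventitia))
    )
  }
  micro <- statistical_default_config()
  if (!is.null(cfg$microstructure)) {
    mc <- cfg$microstructure
    check_keys(mc, c(
      "mode", "adv_elastin", "adv_collagen", "adv_recruitment",
      "media_fiber", "media_smc", "media_recruitment"
    ), "microstructure")
    micro <- microstructure_config(
      adv_elastin = mix_from_list(mc$adv_elastin, "adv_elastin"),
      adv_collagen = mix_from_list(mc$adv_collagen, "adv_collagen"),
      adv_recruitment = rec_from_list(mc$adv_recruitment, "adv_recruitment"),
      media_fiber = dist_from_list(mc$media_fiber, "media_fiber"),
      media_smc = dist_from_list(mc$media_smc, "media_smc"),
      media_recruitment = rec_from_list(mc$media_recruitment, "media_recruitment"),
      mode = mc$mode %||% "full"
    )
  }
  passive <- do.call(passive_fiber_params, cfg$passive %||% list())
  active <- do.call(smc_active_params, cfg$active %||% list())
  quad <- do.call(quadrature_spec, cfg$quadrature %||% list())
  model <- artery_model(geom,
    composition = comp, microstructure = micro,
    passive = passive, active = active, quadrature = quad
  )
  protocol <- cfg$protocol %||% list(
    pressures = seq(0, 160, 20), stretches = c(1.3, 1.5),
    states = c("passive", "full")
  )
  check_keys(protocol, c("pressures", "stretches", "states"), "protocol")
  protocol$pressures <- as.numeric(unlist(protocol$pressures))
  protocol$stretches <- as.numeric(unlist(protocol$stretches))
  protocol$states <- as.character(unlist(protocol$states))
  list(model = model, protocol = protocol, seed = cfg$seed %||% 1, fit = cfg$fit)
}

#' Packaged per-sample parameter estimate tables
#'
#' Parameter estimates for five porcine left anterior descending coronary
#' artery samples, from three fitting strategies: `"statistical"` (material
#' parameters with the statistically measured microstructure held fixed),
#' `"refined"` (material plus constrained geometric parameters), and
#' `"mean_value"` (the degenerate single-angle model). Shipped as plain CSV
#' under `inst/extdata/`.
#'
#' @param which One of `"statistical"`, `"refined"`, `"mean_value"`.
#' @return A tibble with columns `parameter`, `sample`, `value`.
#' @export
#' @examples
#' dplyr::filter(sample_estimates("refined"), parameter == "k_E")
sample_estimates <- function(which = c("refined", "statistical", "mean_value")) {
  which <- match.arg(which)
  path <- system.file("extdata",
    paste0("sample_estimates_", which, ".csv"),
    package = "coromicro"
  )
  out <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  out$sample <- as.integer(out$sample)
  out
}
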