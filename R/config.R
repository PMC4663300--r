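#' Default run configuration
#'
#' A flat key/value record of every tunable parameter with its standard
#' default, suitable for editing as a YAML file and passing to the
#' command-line interface.
#'
#' @return A named list.
#' @export
default_run_config <- function() {
  list(
    algorithm = "hafsa",
    clusters = 3L,
    m = 2,
    tol = 1e-5,
    max_iter = 200L,
    alpha = 0.5,
    pop_size = 20L,
    maxgen = 50L,
    visual = 25.6,
    step = 12.8,
    try_number = 3L,
    delta = 0.75,
    T0 = 1e4,
    T_end = 1e2,
    boltzmann_k = 1,
    k_min = 1L,
    seed = 1L
  )
}

#' Read / write a run configuration
#'
#' Configurations round-trip losslessly through YAML; unknown keys are
#' rejected so typos fail loudly.
#'
#' @param path File path.
#' @return `read_run_config()`: the configuration list with defaults filled
#'   in for missing keys.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- default_run_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, cfg)
}

#' @rdname read_run_config
#' @param config A configuration list (see [default_run_config()]).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Build the parameter objects a config describes.
config_to_params <- function(cfg) {
  list(
    afsa = afsa_params(pop_size = cfg$pop_size, maxgen = cfg$maxgen,
                       visual = cfg$visual, step = cfg$step,
                       try_number = cfg$try_number, delta = cfg$delta),
    anneal = anneal_schedule(T0 = cfg$T0, T_end = cfg$T_end,
                             maxgen = cfg$maxgen,
                             boltzmann_k = cfg$boltzmann_k)
  )
}

#' Segment an image according to a configuration
#'
#' Dispatches to [run_hafsa()] or [run_baseline()] based on
#' `config$algorithm`; the entry point behind the `segment` CLI subcommand.
#'
#' @param image Numeric matrix of gray values.
#' @param config A configuration list (see [default_run_config()]).
#' @return A `segmentation_result`.
#' @export
segment_image <- function(image, config = default_run_config()) {
  cfg <- utils::modifyList(default_run_config(), config)
  if (cfg$algorithm == "hafsa") {
    pp <- config_to_params(cfg)
    run_hafsa(image, c = cfg$clusters, params = pp$afsa, anneal = pp$anneal,
              k_min = cfg$k_min, m = cfg$m, seed = cfg$seed)
  } else if (cfg$algorithm %in% c("fcm", "sfcm")) {
    run_baseline(image, c = cfg$clusters, algorithm = cfg$algorithm,
                 m = cfg$m, alpha = cfg$alpha, tol = cfg$tol,
                 max_iter = cfg$max_iter, seed = cfg$seed)
  } else stop("unknown algorithm: ", cfg$algorithm)
}
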