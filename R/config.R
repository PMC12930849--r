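RUN_CONFIG_KEYS <- c(
  "engine", "buried", "topology", "trajectory", "stride", "workers",
  "mutations", "ph", "width", "window_ps", "timestep_ps", "method",
  "grid", "pca_variance", "seed", "out"
)

RUN_CONFIG_DEFAULTS <- list(
  engine = "propka", buried = TRUE, stride = 1L, workers = 1L,
  mutations = NULL, ph = 7.4, width = 1.0, window_ps = 5000,
  timestep_ps = 1, method = "kmedoids", grid = NULL, pca_variance = NULL,
  seed = 1L, out = "."
)

#' Parse and validate a run configuration
#'
#' Merges, in order of increasing precedence: package defaults, a
#' plain-text YAML configuration file, and explicit flag values. Unknown
#' keys raise an error listing the accepted keys; requesting buried ratios
#' with an engine that cannot produce them (anything but the empirical or
#' mock engine) is a validation error; referenced input paths must exist.
#' The resolved configuration (including the seed, which is recorded in
#' all output headers) is returned and can reproduce a run exactly.
#'
#' @param config_file Optional YAML file of key-value settings.
#' @param flags Named list of overrides (highest precedence).
#' @return A validated `run_config` list.
#' @export
parse_run_config <- function(config_file = NULL, flags = list()) {
  cfg <- RUN_CONFIG_DEFAULTS
  from_file <- if (!is.null(config_file)) {
    if (!file.exists(config_file)) {
      rlang::abort(paste0("Config file not found: ", config_file),
                   class = "trajpka_input_error")
    }
    yaml::read_yaml(config_file)
  } else {
    list()
  }
  for (layer in list(from_file, flags)) {
    if (length(layer) == 0) next
    unknown <- setdiff(names(layer), RUN_CONFIG_KEYS)
    if (length(unknown) > 0) {
      rlang::abort(
        paste0("Unknown configuration key(s): ",
               paste(unknown, collapse = ", "),
               "\nAccepted keys: ", paste(RUN_CONFIG_KEYS, collapse = ", ")),
        class = "trajpka_config_error"
      )
    }
    cfg[names(layer)] <- layer
  }
  if (!cfg$engine %in% c("mock", "propka", "pkai")) {
    rlang::abort(paste0("Unknown engine: ", cfg$engine),
                 class = "trajpka_config_error")
  }
  if (isTRUE(cfg$buried) && cfg$engine == "pkai") {
    rlang::abort(
      "Buried ratios are only available with the empirical engine (propka) or the mock engine",
      class = "trajpka_config_error"
    )
  }
  for (key in c("topology", "trajectory")) {
    for (p in cfg[[key]]) {
      if (!is.null(p) && !file.exists(p)) {
        rlang::abort(paste0("Configured path does not exist: ", p),
                     class = "trajpka_config_error"
        )
      }
    }
  }
  if (cfg$stride < 1 || cfg$workers < 1) {
    rlang::abort("stride and workers must be >= 1",
                 class = "trajpka_config_error")
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    if (is.null(v)) next
    cat(sprintf("  %s: %s\n", k, paste(format(v), collapse = ", ")))
  }
  invisible(x)
}
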