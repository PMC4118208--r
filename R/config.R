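# Flat key-value configuration files for the command-line interface.
# Format: `[section]` headers (`model`, `grid`, `simulation`), `key = value`
# lines, `#` comments. Values are parsed as numbers where possible.

#' Read a flat key-value configuration file
#'
#' @param path Path to the config file.
#' @return A named list of sections, each a named list of values.
#' @examples
#' tf <- tempfile(fileext = ".cfg")
#' writeLines(c("[model]", "alpha = 29", "[grid]", "n_points = 128"), tf)
#' read_config(tf)
#' @export
read_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  section <- "model"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      abort(sprintf("Cannot parse config line: '%s'", ln),
            class = "icgpv_bad_config")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[section]][[key]] <- if (is.na(num)) val else num
  }
  out
}

#' Build model parameters from a configuration list
#'
#' Applies every key of the `[model]` section onto `base`; unspecified
#' keys keep their defaults. Unknown keys are an error so that typos do not
#' silently fall back to defaults.
#'
#' @param config A list from [read_config()] (or a bare named list treated
#'   as the model section).
#' @param base Parameters to start from.
#' @return An [icg_params()] object.
#' @export
params_from_config <- function(config, base = icg_params()) {
  model <- config$model %||% config
  known <- names(base)
  for (key in names(model)) {
    if (!key %in% known)
      abort(sprintf("Unknown model parameter '%s' in config.", key),
            class = "icgpv_bad_config")
    base[[key]] <- model[[key]]
  }
  validate_icg_params(base)
}

#' Build a spatial grid from a configuration list
#'
#' @inheritParams params_from_config
#' @return An [icg_grid()].
#' @export
grid_from_config <- function(config) {
  icg_grid(config$grid$n_points %||% 256)
}
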