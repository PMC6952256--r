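#' Pipeline configuration
#'
#' Nested configuration of every stage, fully serialisable to YAML or JSON.
#' The defaults reproduce the method's stated constants: BT.601 luma
#' coefficients, weight intervals 16-128 (heavy) and 128-235 (thin),
#' stretch bounds P = 15 and Q = 236, and hybrid coefficient gamma = 0.6.
#'
#' @param enhance list: `beta`, `recenter`.
#' @param veil list: `window`, `p_factor`, `white_balance_A`.
#' @param bilateral list: `sigma_s`, `sigma_c`, `radius`.
#' @param illum list: `sigma_spatial`, `sigma_range`, `iterations`.
#' @param blend list: `smoke_level`, `transition_width`, `P`, `Q`,
#'   `majority_vote` (use one smoke level for a whole sequence to avoid
#'   flicker).
#' @param metrics list: `gamma`.
#' @param seed integer seed forwarded to simulation helpers.
#' @return nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(enhance = list(), veil = list(),
                            bilateral = list(), illum = list(),
                            blend = list(), metrics = list(), seed = 1L) {
  defaults <- list(
    enhance   = list(beta = 2, recenter = TRUE),
    veil      = list(window = 7L, p_factor = 0.95, white_balance_A = TRUE),
    bilateral = list(sigma_s = 3, sigma_c = 0.1, radius = 9L),
    illum     = list(sigma_spatial = 30, sigma_range = 0.2, iterations = 3L),
    blend     = list(smoke_level = "auto", transition_width = 16,
                     P = 15, Q = 236, majority_vote = TRUE),
    metrics   = list(gamma = 0.6),
    seed      = seed
  )
  cfg <- defaults
  for (section in c("enhance", "veil", "bilateral", "illum", "blend",
                    "metrics")) {
    user <- get(section)
    unknown <- setdiff(names(user), names(defaults[[section]]))
    if (length(unknown))
      stop("unknown ", section, " option(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    cfg[[section]][names(user)] <- user
  }
  structure(cfg, class = "pipeline_config")
}

#' Read or write a pipeline configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON, chosen by extension. Unspecified keys
#' keep their defaults.
#'
#' @param path configuration file path.
#' @return `read_config()` returns a `pipeline_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yml  = ,
    yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext, call. = FALSE)
  )
  do.call(pipeline_config, raw[intersect(names(raw),
    c("enhance", "veil", "bilateral", "illum", "blend", "metrics", "seed"))])
}

#' @rdname read_config
#' @param cfg a [pipeline_config()] object.
#' @export
write_config <- function(cfg, path) {
  ext <- tolower(tools::file_ext(path))
  x <- unclass(cfg)
  switch(ext,
    yml  = ,
    yaml = yaml::write_yaml(x, path),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    stop("unsupported config format: .", ext, call. = FALSE)
  )
  invisible(path)
}
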