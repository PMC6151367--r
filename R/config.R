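## Study configuration ----------------------------------------------------

#' Study configuration
#'
#' Validated configuration for an end-to-end study run. Unknown fields
#' are rejected; the object round-trips losslessly through YAML.
#'
#' @param seed master seed; every stage derives its own child seeds from
#'   it.
#' @param n_lesions cohort size (prefix of the 38-lesion template).
#' @param resolution ground-truth rasterization step, mm.
#' @param grid `"full"` (the five-family reconstruction grid) or
#'   `"minimal"` (matrix-size family only).
#' @param methods segmentation methods to run.
#' @param icc_form `"ICC11"` or `"ICC31"`.
#' @param cor_method `"spearman"` or `"pearson"`.
#' @param noise_scale base noise level for the acquisition emulator.
#' @return object of class `study_config`.
#' @export
study_config <- function(seed = 1L, n_lesions = 38L, resolution = 1.5,
                         grid = c("full", "minimal"),
                         methods = c("fixed60", "adaptive"),
                         icc_form = c("ICC11", "ICC31"),
                         cor_method = c("spearman", "pearson"),
                         noise_scale = 0.25) {
  grid <- match.arg(grid)
  icc_form <- match.arg(icc_form)
  cor_method <- match.arg(cor_method)
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(n_lesions >= 1, n_lesions <= 38, resolution > 0, noise_scale >= 0)
  structure(list(seed = as.integer(seed), n_lesions = as.integer(n_lesions),
                 resolution = resolution, grid = grid, methods = methods,
                 icc_form = icc_form, cor_method = cor_method,
                 noise_scale = noise_scale),
            class = "study_config")
}

#' Read / write a study configuration as YAML
#'
#' `read_study_config` rejects unknown keys so stale or misspelled
#' configuration files fail loudly.
#'
#' @param path YAML file path.
#' @return `read_study_config` returns a `study_config`;
#'   `write_study_config` returns `path` invisibly.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(study_config, raw)
}

#' @param config a `study_config`.
#' @rdname read_study_config
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
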