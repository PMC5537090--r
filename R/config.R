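#' Read a training run configuration from YAML
#'
#' The YAML file may set any [train_config()] field plus an optional
#' `augmentation:` section with grid overrides (`rotation_degrees`,
#' `width_scales`, `height_scales`, `shear_x_degrees`, `shear_y_degrees`,
#' `alphas`, `betas`), per-transform `enabled:` switches and
#' `switch_prob`.
#'
#' @param path YAML file path.
#' @return a [train_config()] object.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    baa_stop("baa_config_error", "the 'yaml' package is required for YAML configs")
  y <- yaml::read_yaml(path)
  aug <- NULL
  if (!is.null(y$augmentation)) {
    a <- y$augmentation
    args <- a[intersect(names(a),
                        c("rotation_degrees", "width_scales", "height_scales",
                          "shear_x_degrees", "shear_y_degrees", "alphas",
                          "betas", "switch_prob"))]
    if (!is.null(a$enabled)) args$enabled <- unlist(a$enabled)
    aug <- do.call(default_augmentation_config, args)
    y$augmentation <- NULL
  }
  known <- intersect(names(y),
                     names(formals(train_config)))
  do.call(train_config, c(y[known], list(augmentation = aug)))
}
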