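# Declarative pipeline configuration (YAML file + programmatic overrides).

.config_defaults <- function() list(
  transform = "dtcwt", scale = NULL, n_components = 20L, use_lda = TRUE,
  C1 = 1, C2 = 1, epsilon = 1e-6, k = 5L, runs = 10L, seed = 1L,
  image_size = 256L, n_slices = 32L, effect_size = 1, noise_sd = 0.05,
  texture_scale = 8, n_patients = 86L, n_controls = 86L)

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline in one validated list: the feature
#' transform and scale, PCA/LDA settings, twin SVM penalties, the
#' cross-validation layout, and the phantom generator parameters.  All
#' randomness in a run flows from the single `seed`.
#'
#' @param ... Named overrides of the defaults (see Details).
#' @details Fields and defaults: `transform` (`"dtcwt"`), `scale` (`NULL` =
#'   the 16x16-subband level), `n_components` (20), `use_lda` (`TRUE`),
#'   `C1`, `C2` (1), `epsilon` (1e-6), `k` (5), `runs` (10), `seed` (1),
#'   `image_size` (256), `n_slices` (32), `effect_size` (1), `noise_sd`
#'   (0.05), `texture_scale` (8), `n_patients`, `n_controls` (86).
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  cfg <- .config_defaults()
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  stopifnot(cfg$transform %in% c("dtcwt", "dwt"),
            is.null(cfg$scale) || cfg$scale >= 1,
            cfg$n_components >= 1, is.logical(cfg$use_lda),
            cfg$C1 > 0, cfg$C2 > 0, cfg$epsilon > 0,
            cfg$k >= 2, cfg$runs >= 1,
            cfg$image_size >= 32, cfg$n_slices >= 1,
            cfg$effect_size >= 0, cfg$noise_sd >= 0)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration file
#'
#' Configurations round-trip losslessly through YAML.
#'
#' @param path File path.
#' @param config A [pipeline_config()].
#' @return `read_pipeline_config` returns a `"pipeline_config"`;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  for (nm in names(x))
    cat(sprintf("  %-13s %s\n", nm,
                if (is.null(x[[nm]])) "(auto)" else format(x[[nm]])))
  invisible(x)
}
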