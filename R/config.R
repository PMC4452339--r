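#' Pipeline configuration
#'
#' All tunables of the detection pipeline with their defaults:
#'
#' | field | default | meaning |
#' |---|---|---|
#' | `threshold` | 130 | soft-tissue gray threshold (8-bit scale) |
#' | `presmooth_sigma` | 1 | pre-smoothing Gaussian sigma, px |
#' | `r0_mm`, `r1_mm` | 1.5, 15 | nodule radius range, mm (diameters 3-30 mm) |
#' | `n_scales` | 5 | number of dot-filter scales |
#' | `scale_normalize` | TRUE | multiply response by sigma_px^2 |
#' | `suspect_rel_threshold` | 0.1 | response binarization, fraction of max |
#' | `min_area_px` | 4 | minimum suspect area |
#' | `prune_iterations` | 8 | spur-pruning passes |
#' | `max_gap_px` | NULL | gap-fill reach (NULL = 2 x region diameter) |
#' | `d_threshold_mm` | 1.5 | d1/d2 decision threshold |
#' | `fit_window` | 15 | skeleton pixels in the local line fit |
#' | `spacing_mm` | 0.6 | pixel size when the image carries none |
#' | `seed` | 0 | RNG seed for phantom noise |
#'
#' @param ... overrides of the defaults by name; unknown names are an
#'   error.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(threshold = 130, presmooth_sigma = 1, r0_mm = 1.5, r1_mm = 15,
              n_scales = 5L, scale_normalize = TRUE,
              suspect_rel_threshold = 0.1, min_area_px = 4L,
              prune_iterations = 8L, max_gap_px = NULL, d_threshold_mm = 1.5,
              fit_window = 15L, spacing_mm = 0.6, seed = 0L)
  ov <- list(...)
  if (length(ov) > 0L) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad) > 0L || is.null(names(ov)) || any(names(ov) == "")) {
      stop("pipeline_config: unknown or unnamed option(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    cfg[names(ov)] <- ov
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

pipeline_config_validate <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) {
    cfg <- do.call(pipeline_config, as.list(cfg))
  }
  stopifnot(cfg$d_threshold_mm > 0, cfg$spacing_mm > 0,
            cfg$r0_mm > 0, cfg$r0_mm <= cfg$r1_mm, cfg$n_scales >= 1)
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML file holds exactly the [pipeline_config()] fields; unknown
#' keys are rejected with an error naming the key, and a config
#' round-trips losslessly through the file.
#'
#' @param path file path.
#' @param cfg a `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  cfg <- pipeline_config_validate(cfg)
  x <- unclass(cfg)
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("read_config: no such file: ", path, call. = FALSE)
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}
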