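# YAML serialization of model configurations.
#
# Schema (decoder filters are always derived by reversing the encoder's):
#   input_height: 512        input_width: 512
#   input_channels: 3        num_classes: 2
#   conv_kernel: 3           conv_stride: 1
#   leaky_slope: 0.1         dropout_rate: 0.1
#   norm_epsilon: 1.0e-5     seed: 42
#   pathways:
#   - pool_window: 4
#     encoder_filters: [40, 240]
#     bottleneck_filters: 240
#   - pool_window: 2
#     encoder_filters: [40, 80, 160, 220]
#     bottleneck_filters: 220

#' Write a model configuration to YAML
#'
#' @param config an [mpunet_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mpunet_config <- function(config, path) {
  stopifnot(inherits(config, "mpunet_config"))
  x <- list(
    input_height = config$input_height, input_width = config$input_width,
    input_channels = config$input_channels, num_classes = config$num_classes,
    conv_kernel = config$conv_kernel, conv_stride = config$conv_stride,
    leaky_slope = config$leaky_slope, dropout_rate = config$dropout_rate,
    norm_epsilon = config$norm_epsilon, seed = config$seed,
    pathways = lapply(config$pathways, function(p)
      list(pool_window = p$pool_window,
           encoder_filters = p$encoder_filters,
           bottleneck_filters = p$bottleneck_filters)))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a model configuration from YAML
#'
#' @param path YAML file following the schema in [write_mpunet_config()].
#' @return an [mpunet_config()].
#' @export
read_mpunet_config <- function(path) {
  x <- yaml::read_yaml(path)
  pathways <- lapply(x$pathways, function(p)
    pathway_spec(p$pool_window, unlist(p$encoder_filters),
                 p$bottleneck_filters))
  mpunet_config(
    pathways = pathways,
    input_size = c(x$input_height, x$input_width),
    input_channels = x$input_channels %||% 3L,
    num_classes = x$num_classes %||% 2L,
    conv_kernel = x$conv_kernel %||% 3L,
    conv_stride = x$conv_stride %||% 1L,
    leaky_slope = x$leaky_slope %||% 0.1,
    dropout_rate = x$dropout_rate %||% 0.1,
    norm_epsilon = x$norm_epsilon %||% 1e-5,
    seed = x$seed %||% 42L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save model weights
#'
#' Writes the configuration and every weight array to a plain-text JSON file
#' (framework-neutral and diff-able; fine for the model sizes this package
#' trains).
#'
#' @param model a `multipath_unet`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
save_mpunet <- function(model, path) {
  stopifnot(inherits(model, "multipath_unet"))
  cfg <- model$config
  out <- list(
    config = list(
      input_height = cfg$input_height, input_width = cfg$input_width,
      input_channels = cfg$input_channels, num_classes = cfg$num_classes,
      conv_kernel = cfg$conv_kernel, conv_stride = cfg$conv_stride,
      leaky_slope = cfg$leaky_slope, dropout_rate = cfg$dropout_rate,
      norm_epsilon = cfg$norm_epsilon, seed = cfg$seed,
      pathways = lapply(cfg$pathways, function(p)
        list(pool_window = p$pool_window,
             encoder_filters = p$encoder_filters,
             bottleneck_filters = p$bottleneck_filters))),
    params = lapply(model$params, function(layer)
      lapply(layer, function(a)
        list(dim = if (is.null(dim(a))) length(a) else dim(a),
             data = as.numeric(a)))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load model weights saved by [save_mpunet()]
#'
#' @param path `.json` path.
#' @return a `multipath_unet`.
#' @export
load_mpunet <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfgl <- x$config
  pw <- cfgl$pathways
  pathways <- if (is.data.frame(pw)) {
    lapply(seq_len(nrow(pw)), function(i)
      pathway_spec(pw$pool_window[i], unlist(pw$encoder_filters[i]),
                   pw$bottleneck_filters[i]))
  } else {
    lapply(pw, function(p) pathway_spec(p$pool_window,
                                        unlist(p$encoder_filters),
                                        p$bottleneck_filters))
  }
  config <- mpunet_config(
    pathways, c(cfgl$input_height, cfgl$input_width), cfgl$input_channels,
    cfgl$num_classes, cfgl$conv_kernel, cfgl$conv_stride, cfgl$leaky_slope,
    cfgl$dropout_rate, cfgl$norm_epsilon, cfgl$seed)
  model <- build_multipath_unet(config)
  for (nm in names(model$params))
    for (pn in names(model$params[[nm]])) {
      entry <- x$params[[nm]][[pn]]
      model$params[[nm]][[pn]] <- array(entry$data, entry$dim)
    }
  model
}
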