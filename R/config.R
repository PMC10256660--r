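#' Default run configuration
#'
#' Nested configuration mirroring the architecture, loss, training,
#' crop, prior and inference settings. Defaults are the study's stated
#' values: `alpha = 1`, `beta = 0.1`, `gamma = 0.2`, learning rate
#' `1e-4`, dropout keep-probability `0.8`, window depth 32 with step 1,
#' and a 5x5x5 structuring element.
#'
#' @return A `run_config` (nested named list).
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    segmenter = list(input_shape = c(192L, 192L, 32L), levels = 3L,
                     base_width = 40L, convs_per_block = 2L,
                     dropout_keep = 0.8),
    regressor = list(widths = c(24L, 48L, 96L, 192L)),
    loss = list(alpha = 1, beta = 0.1, gamma = 0.2),
    training = list(stage_epochs = c(10L, 5L, 10L), lr = 1e-4,
                    batch_size = 1L),
    augment = list(enabled = TRUE, rotation_max_deg = 15, p_rotate = 0.5,
                   p_mirror = 0.5, p_brightness = 0.5, p_gamma = 0.5,
                   p_noise = 0.5, brightness_frac = 0.1,
                   gamma_range = c(0.7, 1.43), noise_frac = 0.02),
    crop = list(row_offset = 0L, col_offset = 0L, height = 192L,
                width = 192L),
    prior = list(element = "cube5"),
    inference = list(depth = 32L, step = 1L, fusion = "mean")
  ), class = "run_config")
}

#' Load and validate a YAML run configuration
#'
#' Reads the file, overlays it on [default_config()], rejects unknown
#' keys, and validates value constraints. An empty file yields all
#' defaults. Loading the dump of a loaded config is the identity
#' (resolution is idempotent).
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(unclass(default_config()), user, "")
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

merge_config <- function(def, user, prefix) {
  if (!is.list(user))
    stop("config section '", sub("^\\.", "", prefix),
         "' must be a mapping")
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    stop("unknown config key: ",
         sub("^\\.", "", paste0(prefix, ".", unknown[1])))
  for (nm in names(user)) {
    if (is.list(def[[nm]]) && !is.null(names(def[[nm]]))) {
      def[[nm]] <- merge_config(def[[nm]], user[[nm]],
                                paste0(prefix, ".", nm))
    } else {
      val <- user[[nm]]
      if (is.list(val)) val <- unlist(val)
      if (is.numeric(def[[nm]]) && !is.numeric(val))
        stop("config key '", sub("^\\.", "", paste0(prefix, ".", nm)),
             "' must be numeric")
      if (is.integer(def[[nm]])) val <- as.integer(val)
      def[[nm]] <- val
    }
  }
  def
}

validate_config <- function(cfg) {
  with(cfg, {
    if (loss$alpha < 0 || loss$beta < 0 || loss$gamma < 0)
      stop("config error: loss weights must be nonnegative")
    if (training$lr <= 0) stop("config error: training.lr must be > 0")
    if (segmenter$dropout_keep <= 0 || segmenter$dropout_keep > 1)
      stop("config error: segmenter.dropout_keep must be in (0, 1]")
    if (length(regressor$widths) != 4)
      stop("config error: regressor.widths must have length 4")
    if (!prior$element %in% c("cube5", "diag5"))
      stop("config error: prior.element must be cube5 or diag5")
    if (!inference$fusion %in% c("mean", "max"))
      stop("config error: inference.fusion must be mean or max")
    if (inference$depth < 1 || inference$step < 1)
      stop("config error: inference depth/step must be >= 1")
    if (length(training$stage_epochs) != 3 ||
        any(training$stage_epochs < 1))
      stop("config error: training.stage_epochs needs three values >= 1")
  })
  invisible(cfg)
}

#' Write a resolved configuration to YAML
#'
#' @param cfg a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

## constructors from a resolved config
cfg_segmenter_spec <- function(cfg) {
  s <- cfg$segmenter
  segmenter_spec(s$input_shape, s$levels, s$base_width, s$convs_per_block,
                 s$dropout_keep)
}

cfg_regressor_spec <- function(cfg) regressor_spec(cfg$regressor$widths)

cfg_training_config <- function(cfg) {
  a <- cfg$augment
  ac <- if (isTRUE(a$enabled))
    augment_config(a$rotation_max_deg, a$p_rotate, a$p_mirror,
                   a$p_brightness, a$p_gamma, a$p_noise, a$brightness_frac,
                   a$gamma_range, a$noise_frac)
  else NULL
  training_config(cfg$training$stage_epochs, cfg$training$lr,
                  cfg$training$batch_size, cfg$seed,
                  loss_weights(cfg$loss$alpha, cfg$loss$beta,
                               cfg$loss$gamma),
                  ac, cfg$prior$element)
}
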