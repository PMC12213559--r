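## Run configuration: a nested key-value tree covering every stage, with a
## strict schema (unknown keys rejected, types checked) and lossless YAML
## round-trips.

#' Default run configuration
#'
#' The full nested configuration tree with every default materialized:
#' synthetic-data spec, preprocessing stages, model architecture, training
#' hyperparameters, split protocol, output paths and the global seed.
#'
#' @return a named nested list.
#' @seealso [loadConfig()], [saveConfig()], [validateConfig()]
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    synthetic = list(
      n_subjects_per_class = 20L, segments_per_subject = 50L,
      n_channels = 8L, sampling_rate = 128, segment_length = 256L,
      target_band = c(8, 12), power_ratio = 2, noise_floor = 1,
      line_noise_amplitude = 0, drift_amplitude = 0, seed = 1L),
    preprocess = list(
      notch = 50, band = c(0.5, 64), resample_to = 128,
      ref_channels = character(0), drop_refs = TRUE,
      segment_length = 256L, stride = 256L,
      stats_dialect = "per_segment"),
    model = list(
      in_channels = 8L, embed_width = 16L, stage2_width = 32L,
      n_levels = 2L, dafm_pool = 2L, cot_kernel = 3L, cot_groups = 4L,
      rounds = 2L, maxpool_size = 2L, classifier_hidden = 64L,
      n_classes = 2L, activation = "gelu", use_embedding = TRUE,
      conv_type = "dsc", use_dafm = TRUE, use_cot = TRUE),
    train = list(
      epochs = 30L, batch_size = 32L, learning_rate = 1e-3,
      lr_schedule = "cosine", weight_decay = 0.01, optimizer = "adam",
      loss = "cross_entropy", seed = 1L,
      early_stop_patience = NA_integer_),
    split = list(mode = "subject_wise", train_fraction = 0.8, seed = 1L),
    output = list(dir = "dscnet-out", log_level = "info")
  )
}

## recursive schema check against the default tree: unknown keys and type
## mismatches are rejected with the offending field path
checkAgainst <- function(cfg, ref, path = "") {
  if (!is.list(ref)) {
    ok <- switch(class(ref)[1],
      integer = is.numeric(cfg),
      numeric = is.numeric(cfg),
      character = is.character(cfg),
      logical = is.logical(cfg),
      is.null(cfg) || identical(class(cfg), class(ref)))
    if (!ok && !(is.logical(cfg) && all(is.na(cfg)))) {
      stop(sprintf("config field '%s': expected %s, got %s", path,
                   class(ref)[1], class(cfg)[1]), call. = FALSE)
    }
    return(invisible(TRUE))
  }
  if (!is.list(cfg)) {
    stop(sprintf("config field '%s': expected a section", path),
         call. = FALSE)
  }
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown)) {
    stop(sprintf("unknown config key '%s%s'",
                 if (nzchar(path)) paste0(path, ".") else "", unknown[1]),
         call. = FALSE)
  }
  for (nm in names(cfg)) {
    checkAgainst(cfg[[nm]], ref[[nm]],
                 if (nzchar(path)) paste(path, nm, sep = ".") else nm)
  }
  invisible(TRUE)
}

#' Validate a run configuration
#'
#' Checks the nested tree against the schema implied by
#' [defaultRunConfig()]: unknown keys and type mismatches are rejected
#' with the offending field path.
#'
#' @param cfg nested configuration list.
#' @return invisibly TRUE; errors otherwise.
#' @export
validateConfig <- function(cfg) {
  checkAgainst(cfg, defaultRunConfig())
}

#' Load / save a run configuration
#'
#' Configurations live in human-readable YAML.  Loading merges the file
#' over [defaultRunConfig()] (so every default is materialized), then
#' validates; saving writes the fully materialized tree, so
#' `loadConfig(saveConfig(cfg, p))` is structurally lossless.
#'
#' @param path YAML file path.
#' @return `loadConfig` returns the validated nested list; `saveConfig`
#'   returns `path` invisibly.
#' @export
loadConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  raw <- coerceLikeSchema(raw, defaultRunConfig())
  validateConfig(raw)
  cfg <- mergeConfig(defaultRunConfig(), raw)
  validateConfig(cfg)
  cfg
}

## YAML renders empty atomic vectors as empty sequences; restore the
## schema's type on load (unknown keys are left for the validator to name)
coerceLikeSchema <- function(cfg, ref) {
  for (nm in intersect(names(cfg), names(ref))) {
    if (is.list(ref[[nm]])) {
      if (is.list(cfg[[nm]])) {
        cfg[[nm]] <- coerceLikeSchema(cfg[[nm]], ref[[nm]])
      }
    } else if (is.list(cfg[[nm]]) && length(cfg[[nm]]) == 0L) {
      cfg[[nm]] <- ref[[nm]][0]
    } else if (is.list(cfg[[nm]]) &&
               all(vapply(cfg[[nm]], is.atomic, logical(1)))) {
      cfg[[nm]] <- unlist(cfg[[nm]])
    }
  }
  cfg
}

#' @rdname loadConfig
#' @param cfg nested configuration list.
#' @export
saveConfig <- function(cfg, path) {
  validateConfig(cfg)
  full <- mergeConfig(defaultRunConfig(), cfg)
  yaml::write_yaml(full, path)
  invisible(path)
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Build typed objects from a run configuration
#'
#' @param cfg validated nested list (see [loadConfig()]).
#' @return `configToSyntheticSpec` a [SyntheticSpec-class];
#'   `configToModelConfig` a [ModelConfig-class]; `configToTrainConfig` a
#'   [TrainConfig-class].
#' @name config-builders
NULL

#' @rdname config-builders
#' @export
configToSyntheticSpec <- function(cfg) {
  s <- cfg$synthetic
  syntheticSpec(s$n_subjects_per_class, s$segments_per_subject,
                s$n_channels, s$sampling_rate, s$segment_length,
                s$target_band, s$power_ratio, s$noise_floor,
                s$line_noise_amplitude, s$drift_amplitude, s$seed)
}

#' @rdname config-builders
#' @export
configToModelConfig <- function(cfg) {
  m <- cfg$model
  dscnetConfig(m$in_channels, m$embed_width, m$stage2_width, m$n_levels,
               m$dafm_pool, m$cot_kernel, m$cot_groups, m$rounds,
               m$maxpool_size, m$classifier_hidden, m$n_classes,
               m$activation, m$use_embedding, m$conv_type, m$use_dafm,
               m$use_cot)
}

#' @rdname config-builders
#' @export
configToTrainConfig <- function(cfg) {
  t <- cfg$train
  trainConfig(t$epochs, t$batch_size, t$learning_rate, t$lr_schedule,
              t$weight_decay, t$optimizer, t$loss, t$seed,
              if (is.null(t$early_stop_patience) ||
                  is.na(t$early_stop_patience)) NA_integer_
              else t$early_stop_patience)
}
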