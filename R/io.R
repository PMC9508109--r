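#' Write a synthetic trial to a dataset directory
#'
#' Emits the generator's artifacts as headered CSV files plus a JSON
#' sidecar (skeleton, template, seed) and a manifest listing every file.
#'
#' @param trial a `quail_trial` from [simulate_trial()].
#' @param dir output directory (created if needed).
#' @param obs optional named list of observation tables to write
#'   (`lateral`, `ventrodorsal`).
#' @param features optional [synthesize_features()] result.
#' @param rig optional two-view rig to serialize.
#' @return invisibly, the manifest data frame (file, rows).
#' @export
write_trial <- function(trial, dir, obs = NULL, features = NULL, rig = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  put <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files[[name]] <<- nrow(df)
  }
  put(trial$landmarks, "landmarks_3d.csv")
  put(trial$truth, "ground_truth.csv")
  put(trial$events, "events.csv")
  if (!is.null(obs)) {
    for (nm in names(obs)) put(obs[[nm]], paste0("observations_", nm, ".csv"))
  }
  if (!is.null(features)) {
    fm <- as.data.frame(features$features)
    names(fm) <- paste0("f", seq_len(ncol(fm)))
    put(cbind(frame = features$frames, fm), "features.csv")
  }
  if (!is.null(rig)) {
    write_rig_json(rig, file.path(dir, "rig.json"))
    files[["rig.json"]] <- NA_integer_
  }
  sidecar <- list(
    condition = trial$template$condition,
    fps = trial$fps, n_frames = trial$n_frames,
    n_strides = trial$n_strides, seed = trial$seed,
    skeleton = trial$skeleton$lengths,
    template = trial$template[c("condition", "speed", "contact_time",
                                "swing_time", "step_height", "hip_height",
                                "pelvis", "aperture_td")]
  )
  jsonlite::write_json(sidecar, file.path(dir, "trial.json"),
                       digits = NA, auto_unbox = TRUE)
  files[["trial.json"]] <- NA_integer_
  manifest <- data.frame(file = names(files),
                         rows = unlist(files, use.names = FALSE))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read pipeline CSV artifacts
#'
#' Thin readers for the dataset layout written by [write_trial()] and the
#' pipeline stages.
#'
#' @param path file path.
#' @return the data frame.
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Load, validate and resolve a pipeline configuration
#'
#' The YAML configuration has one section per stage plus shared fields.
#' Unknown top-level fields are rejected; missing fields fall back to the
#' defaults of [default_config()]. The resolved configuration should be
#' written beside the outputs of every run.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @param overrides named list merged over the file values (CLI-style).
#' @return named list, the resolved configuration.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad)) {
      stop("load_config: unknown field(s): ", paste(bad, collapse = ", "))
    }
    cfg <- modify_template(cfg, user)
  }
  cfg <- modify_template(cfg, overrides)
  stopifnot(cfg$fps > 0, cfg$simulate$n_strides >= 1,
            cfg$track$M >= 1, cfg$track$C > 0, cfg$track$epsilon >= 0,
            cfg$features$D >= 1, cfg$features$noise_sd >= 0,
            cfg$simulate$pixel_noise_sd >= 0)
  cfg
}

#' @rdname load_config
#' @export
default_config <- function() {
  list(
    condition = "level",
    seed = 1L,
    fps = 500,
    out_dir = "quailkin_run",
    simulate = list(n_strides = 1, pixel_noise_sd = 0.5),
    features = list(D = 192, noise_sd = 0.01, n_distractors = 8),
    track = list(M = 10, C = 1, epsilon = 0.1),
    reconstruct = list(cube_n = 3, cube_spacing = 0.05),
    analyze = list(velocity_cutoff_hz = 25),
    stats = list(alpha = 0.05)
  )
}

#' Write the resolved configuration next to a run's outputs
#' @param cfg configuration list.
#' @param dir output directory.
#' @return the file path, invisibly.
#' @export
write_config <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "config_resolved.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}
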