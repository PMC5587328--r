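# Run-record and configuration serialization. A saved run is a columnar CSV
# (epoch, one E/Q/R state column and one threshold column per node, the
# agent pose and motor columns) plus a JSON sidecar holding the full
# configuration and role assignment, so saved records can be re-analyzed
# without re-running the simulation.

#' Write a run record to disk
#'
#' Writes `<stem>.csv` (the epoch-indexed record) and `<stem>.json` (config,
#' roles, arena sidecar).
#'
#' @param run A `gh_run`.
#' @param stem Output path stem (without extension).
#' @return The CSV path, invisibly.
#' @export
write_run_record <- function(run, stem) {
  stopifnot(inherits(run, "gh_run"))
  n <- ncol(run$states)
  labels <- run$connectome_labels
  if (is.null(labels) || length(labels) != n) labels <- default_node_labels(n)
  st <- as.data.frame(matrix(states_to_letter(run$states),
                             nrow(run$states), n))
  names(st) <- paste0("state_", labels)
  th <- as.data.frame(run$thresholds)
  names(th) <- paste0("threshold_", labels)
  fe <- as.data.frame(run$forced_E)
  names(fe) <- paste0("forcedE_", labels)
  df <- cbind(run$trajectory["epoch"], st, th, fe,
              run$trajectory[setdiff(names(run$trajectory), "epoch")])
  csv <- paste0(stem, ".csv")
  utils::write.csv(df, csv, row.names = FALSE)
  cfg_out <- unclass(run$config)
  # NULL (resolve forced nodes at run time) is encoded by omitting the key;
  # an explicit vector (possibly empty) is kept as an array
  if (is.null(cfg_out$homeostasis_exclude)) {
    cfg_out <- cfg_out[setdiff(names(cfg_out), "homeostasis_exclude")]
  }
  sidecar <- list(config = cfg_out,
                  roles = unclass(run$roles),
                  arena = unclass(run$arena),
                  labels = labels)
  jsonlite::write_json(sidecar, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(csv)
}

#' Read a run record written by [write_run_record()]
#'
#' @param stem Path stem used when writing.
#' @return A `gh_run` object.
#' @export
read_run_record <- function(stem) {
  csv <- paste0(stem, ".csv")
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(csv, stringsAsFactors = FALSE)
  st_cols <- grep("^state_", names(df))
  th_cols <- grep("^threshold_", names(df))
  fe_cols <- grep("^forcedE_", names(df))
  S <- matrix(states_to_int(as.matrix(df[st_cols])),
              nrow(df), length(st_cols))
  cfg <- side$config
  # absent key = NULL (resolve forced nodes at run time); an explicit
  # integer vector (possibly empty) is an array
  he <- if (!"homeostasis_exclude" %in% names(cfg)) NULL
        else as.integer(unlist(cfg$homeostasis_exclude))
  config <- model_config(coupling = cfg$coupling,
                         initial_threshold = cfg$initial_threshold,
                         p_spont = cfg$p_spont, alpha = cfg$alpha,
                         rho = cfg$rho, variant = cfg$variant,
                         epochs = cfg$epochs, seed = cfg$seed,
                         bin_dt = cfg$bin_dt,
                         smooth_turn = isTRUE(cfg$smooth_turn),
                         homeostasis_exclude = he)
  rl <- side$roles
  roles <- node_roles(rl$rotate_left, rl$rotate_right, rl$forward_left,
                      rl$forward_right, rl$near_visual, rl$far_visual,
                      rl$somatosensory, rl$task_negative, rl$n_nodes)
  traj_cols <- c("epoch", "x", "y", "heading", "v", "h", "wall_distance",
                 "ray_left", "ray_right", "collided_left", "collided_right",
                 "n_tp_forced", "n_tn_forced_E")
  structure(list(states = S,
                 thresholds = as.matrix(df[th_cols]),
                 forced_E = as.matrix(df[fe_cols]) == TRUE,
                 trajectory = df[traj_cols],
                 config = config, roles = roles,
                 arena = arena(side$arena$width, side$arena$height),
                 connectome_labels = side$labels),
            class = "gh_run")
}

#' Read a model configuration (plus optional arena and roles) from JSON/YAML
#'
#' Keys mirror the [model_config()] arguments; optional top-level `arena`
#' (width/height) and `roles` blocks are returned alongside.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return List with `config`, and `arena`/`roles` when present (else NULL).
#' @export
read_model_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(model_config))
  cfg_args <- raw[intersect(names(raw), known)]
  config <- do.call(model_config, cfg_args)
  ar <- if (!is.null(raw$arena)) arena(raw$arena$width, raw$arena$height)
  roles <- if (!is.null(raw$roles)) {
    rl <- raw$roles
    node_roles(rl$rotate_left, rl$rotate_right, rl$forward_left,
               rl$forward_right, unlist(rl$near_visual),
               unlist(rl$far_visual), unlist(rl$somatosensory),
               unlist(rl$task_negative), rl$n_nodes)
  }
  list(config = config, arena = ar, roles = roles)
}

#' Export the agent trajectory as CSV
#'
#' Columns: epoch, x, y, heading, v, h, wall_distance, collided_left,
#' collided_right.
#'
#' @param run A `gh_run`.
#' @param path Output CSV path.
#' @export
write_trajectory <- function(run, path) {
  stopifnot(inherits(run, "gh_run"))
  cols <- c("epoch", "x", "y", "heading", "v", "h", "wall_distance",
            "collided_left", "collided_right")
  utils::write.csv(run$trajectory[cols], path, row.names = FALSE)
  invisible(path)
}
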