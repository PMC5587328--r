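# Config-driven experiment runners: the coupling x threshold phase sweep,
# the learning-rate x target-rate homeostasis sweep, and the multi-variant
# behavioral comparison, plus deterministic per-cell seed derivation.

#' Derive a per-cell/per-repeat seed from a master seed
#'
#' Deterministic integer hash so that sweep cells and repeats are
#' independent of evaluation order. Always in `[1, 2^31 - 2]`.
#'
#' @param master_seed Integer master seed.
#' @param cell Cell index (>= 1).
#' @param repeat_i Repeat index (>= 1).
#' @return An integer seed.
#' @export
derive_seed <- function(master_seed, cell = 1L, repeat_i = 1L) {
  m <- 2147483647   # 2^31 - 1, Mersenne prime modulus
  h <- (as.numeric(master_seed) %% m + 1) * 48271 %% m
  h <- (h * 31 + as.numeric(cell) * 2654435761) %% m
  h <- (h * 31 + as.numeric(repeat_i) * 40503) %% m
  as.integer(h %% (m - 1) + 1)
}

#' Specify a two-parameter sweep
#'
#' @param axis1_name,axis2_name Names of `model_config` fields to vary
#'   (e.g. `"coupling"`/`"initial_threshold"` or `"alpha"`/`"rho"`).
#' @param axis1_values,axis2_values Non-empty numeric grids.
#' @param epochs_per_cell Epochs per run (>= 1).
#' @param repeats_per_cell Seeded repeats per cell (default 1).
#' @param base_config A [model_config()] providing the fixed parameters.
#' @param seed Master seed.
#' @return A `sweep_spec` object.
#' @export
sweep_spec <- function(axis1_name, axis1_values, axis2_name, axis2_values,
                       epochs_per_cell = 2000L, repeats_per_cell = 1L,
                       base_config = model_config(), seed = 1L) {
  if (!length(axis1_values) || !length(axis2_values)) {
    stop("sweep grids must be non-empty", call. = FALSE)
  }
  if (epochs_per_cell < 1) stop("epochs_per_cell must be >= 1",
                                call. = FALSE)
  ok <- c("coupling", "initial_threshold", "p_spont", "alpha", "rho")
  if (!axis1_name %in% ok || !axis2_name %in% ok) {
    stop("sweep axes must be numeric model_config fields (",
         paste(ok, collapse = ", "), ")", call. = FALSE)
  }
  structure(list(axis1_name = axis1_name, axis1_values = axis1_values,
                 axis2_name = axis2_name, axis2_values = axis2_values,
                 epochs_per_cell = as.integer(epochs_per_cell),
                 repeats_per_cell = as.integer(repeats_per_cell),
                 base_config = base_config, seed = as.integer(seed)),
            class = "sweep_spec")
}

# one sweep run: config with cell values and derived seed patched in
sweep_cell_config <- function(spec, i, j, rep_i) {
  cfg <- spec$base_config
  cfg[[spec$axis1_name]] <- spec$axis1_values[i]
  cfg[[spec$axis2_name]] <- spec$axis2_values[j]
  cfg$epochs <- spec$epochs_per_cell
  cell <- (i - 1L) * length(spec$axis2_values) + j
  cfg$seed <- derive_seed(spec$seed, cell, rep_i)
  cfg
}

#' Coupling x threshold phase sweep of the static model
#'
#' Runs the embodied simulation in every grid cell with `variant = "static"`
#' and summarizes the mean activity and avalanche statistics, mapping the
#' phase transition between the near-silent and saturated regimes.
#'
#' @param spec A [sweep_spec()] whose axes are `coupling` and
#'   `initial_threshold`.
#' @param c A [connectome()].
#' @param roles A [node_roles()].
#' @param arena An [arena()].
#' @param verbose Log per-cell progress to stderr.
#' @return Long-format data frame: one row per cell x repeat with the axis
#'   values, seed, `mean_activity`, `n_cascades`, `exponent`, `ls_error`,
#'   `nll`, `kappa`.
#' @export
phase_sweep <- function(spec, c, roles = default_node_roles(c),
                        arena = default_arena(), verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  if (!setequal(c(spec$axis1_name, spec$axis2_name),
                c("coupling", "initial_threshold"))) {
    stop("phase_sweep axes must be coupling and initial_threshold",
         call. = FALSE)
  }
  spec$base_config$variant <- "static"
  sweep_engine(spec, c, roles, arena, verbose, function(run) {
    rep_ <- avalanche_report(run)
    data.frame(mean_activity = mean_activity(activity_raster(run)),
               n_cascades = rep_$n_cascades, exponent = rep_$exponent,
               ls_error = rep_$ls_error, nll = rep_$nll, kappa = rep_$kappa)
  })
}

#' Learning-rate x target-rate homeostasis sweep
#'
#' Runs the local-plasticity variant in every grid cell and reports the
#' attained activity rate (time-mean over the final half of the run,
#' discounting the adaptation transient), the mean off-diagonal node
#' correlation, avalanche statistics, and a divergence flag (monotone
#' threshold growth over the final half, the signature of an unattainable
#' target rate).
#'
#' @param spec A [sweep_spec()] whose axes are `alpha` and `rho`.
#' @inheritParams phase_sweep
#' @return Long-format data frame with `attained_rate`,
#'   `mean_offdiag_correlation`, `threshold_drift`, `diverged`, and the
#'   avalanche fit columns.
#' @export
homeostasis_sweep <- function(spec, c, roles = default_node_roles(c),
                              arena = default_arena(), verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  if (!setequal(c(spec$axis1_name, spec$axis2_name), c("alpha", "rho"))) {
    stop("homeostasis_sweep axes must be alpha and rho", call. = FALSE)
  }
  spec$base_config$variant <- "local"
  sweep_engine(spec, c, roles, arena, verbose, function(run) {
    half <- seq(floor(nrow(run$states) / 2) + 1, nrow(run$states))
    thr <- rowMeans(run$thresholds)[half]
    drift <- unname(stats::coef(stats::lm(thr ~ seq_along(thr)))[2])
    rep_ <- avalanche_report(run)
    data.frame(
      attained_rate = mean(run$states[half, ] == 1L),
      mean_offdiag_correlation =
        node_correlation_matrix(run$states[half, ])$mean_offdiag,
      threshold_drift = drift,
      # converged runs have mean per-epoch drift ~ alpha*(attained - rho) ~ 0;
      # sustained drift above 1% of alpha marks an unattainable target
      diverged = abs(drift) > run$config$alpha * 0.01,
      n_cascades = rep_$n_cascades, exponent = rep_$exponent,
      ls_error = rep_$ls_error, nll = rep_$nll, kappa = rep_$kappa)
  })
}

sweep_engine <- function(spec, c, roles, arena, verbose, summarize) {
  rows <- list()
  for (i in seq_along(spec$axis1_values)) {
    for (j in seq_along(spec$axis2_values)) {
      for (r in seq_len(spec$repeats_per_cell)) {
        cfg <- sweep_cell_config(spec, i, j, r)
        run <- run_simulation(c, roles, cfg, arena)
        row <- summarize(run)
        row[[spec$axis1_name]] <- spec$axis1_values[i]
        row[[spec$axis2_name]] <- spec$axis2_values[j]
        row$repeat_i <- r
        row$seed <- cfg$seed
        rows[[length(rows) + 1]] <- row
        if (verbose) {
          message(sprintf("[sweep] %s=%g %s=%g rep=%d done",
                          spec$axis1_name, spec$axis1_values[i],
                          spec$axis2_name, spec$axis2_values[j], r))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Specify a multi-variant behavioral study
#'
#' @param variants Subset of `c("static", "local", "macro", "combined")`
#'   (at least 2 for group comparisons).
#' @param n_repeats Seeded repeats per variant (default 30).
#' @param epochs Epochs per run (default 2000).
#' @param base_config A [model_config()] for the shared parameters.
#' @param seed Master seed.
#' @return A `variant_study_spec` object.
#' @export
variant_study_spec <- function(variants = c("static", "local", "macro",
                                            "combined"),
                               n_repeats = 30L, epochs = 2000L,
                               base_config = model_config(), seed = 1L) {
  variants <- match.arg(variants, several.ok = TRUE)
  if (n_repeats < 2) stop("n_repeats must be >= 2 for group statistics",
                          call. = FALSE)
  structure(list(variants = variants, n_repeats = as.integer(n_repeats),
                 epochs = as.integer(epochs), base_config = base_config,
                 seed = as.integer(seed)),
            class = "variant_study_spec")
}

#' Run the multi-variant behavioral comparison
#'
#' Runs `n_repeats` seeded simulations per variant, computes the
#' [run_metrics()] of each run, and performs every pairwise pooled-variance
#' t-test per metric.
#'
#' @param spec A [variant_study_spec()].
#' @inheritParams phase_sweep
#' @param out_dir Optional directory: writes `metrics.csv`,
#'   `comparisons.json`, and one trajectory plot PNG per variant.
#' @return List: `metrics` (one row per run) and `comparisons` (one row per
#'   variant pair x metric with t, df, p).
#' @export
variant_study <- function(spec, c, roles = default_node_roles(c),
                          arena = default_arena(), out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "variant_study_spec"))
  if (length(spec$variants) < 2) {
    stop("need at least 2 variants to compare", call. = FALSE)
  }
  metrics <- list()
  example_runs <- list()
  for (vi in seq_along(spec$variants)) {
    v <- spec$variants[vi]
    for (r in seq_len(spec$n_repeats)) {
      cfg <- spec$base_config
      cfg$variant <- v
      cfg$epochs <- spec$epochs
      cfg$seed <- derive_seed(spec$seed, vi, r)
      run <- run_simulation(c, roles, cfg, arena)
      m <- run_metrics(run)
      m$variant <- v
      m$repeat_i <- r
      m$seed <- cfg$seed
      metrics[[length(metrics) + 1]] <- m
      if (r == 1) example_runs[[v]] <- run
      if (verbose) message(sprintf("[variants] %s rep %d/%d done",
                                   v, r, spec$n_repeats))
    }
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL

  metric_cols <- setdiff(names(metrics), c("variant", "repeat_i", "seed"))
  pairs <- utils::combn(spec$variants, 2, simplify = FALSE)
  comp <- do.call(rbind, lapply(pairs, function(p) {
    do.call(rbind, lapply(metric_cols, function(mc) {
      a <- metrics[[mc]][metrics$variant == p[1]]
      b <- metrics[[mc]][metrics$variant == p[2]]
      tt <- compare_groups(a, b)
      data.frame(variant_a = p[1], variant_b = p[2], metric = mc,
                 mean_a = mean(a), mean_b = mean(b),
                 t = tt$t_statistic, df = tt$degrees_of_freedom,
                 p = tt$p_value)
    }))
  }))
  rownames(comp) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(comp, file.path(out_dir, "comparisons.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    for (v in names(example_runs)) {
      grDevices::png(file.path(out_dir, paste0("trajectory_", v, ".png")),
                     width = 600, height = 600)
      plot_trajectory(example_runs[[v]],
                      main = paste("trajectory:", v))
      grDevices::dev.off()
    }
  }
  list(metrics = metrics, comparisons = comp)
}

#' Plot an agent trajectory
#'
#' @param run A `gh_run`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_trajectory <- function(run, ...) {
  stopifnot(inherits(run, "gh_run"))
  tr <- run$trajectory
  graphics::plot(NA, xlim = c(0, run$arena$width),
                 ylim = c(0, run$arena$height), asp = 1,
                 xlab = "x (world units)", ylab = "y (world units)", ...)
  graphics::rect(0, 0, run$arena$width, run$arena$height, border = "grey40")
  graphics::lines(tr$x, tr$y, col = grDevices::adjustcolor("steelblue", 0.7))
  coll <- tr$collided_left | tr$collided_right
  if (any(coll)) graphics::points(tr$x[coll], tr$y[coll], pch = 4,
                                  col = "firebrick", cex = 0.6)
  invisible(run)
}
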