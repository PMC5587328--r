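# Behavioral and brain-environment coupling metrics: movement entropy,
# box-counting fractal dimension of the trajectory, wall-distance
# correlations, variability summaries, and the group-comparison tests.

#' Shannon entropy of the motor command stream
#'
#' Joint entropy (base 2) of the (v, h) pairs discretized into an
#' `n_bins` x `n_bins` equal-width grid over each series' observed range.
#' A constant axis collapses to a single bin, so a fully constant command
#' stream has zero entropy.
#'
#' @param v_series,h_series Equal-length numeric series (move and turn
#'   commands per epoch).
#' @param n_bins Bins per axis (default 16).
#' @param joint Use the joint (v, h) histogram (default); otherwise the sum
#'   of the two marginal entropies.
#' @return Entropy in bits, in `[0, 2 * log2(n_bins)]`.
#' @export
movement_entropy <- function(v_series, h_series, n_bins = 16L,
                             joint = TRUE) {
  if (!length(v_series) || length(v_series) != length(h_series)) {
    stop("v_series and h_series must be non-empty and of equal length",
         call. = FALSE)
  }
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  bin_axis <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) return(rep(1L, length(x)))
    pmin(floor((x - r[1]) / (r[2] - r[1]) * n_bins) + 1L, n_bins)
  }
  ent <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log2(p))
  }
  bv <- bin_axis(v_series); bh <- bin_axis(h_series)
  if (joint) {
    ent(table(bv, bh))
  } else {
    ent(table(bv)) + ent(table(bh))
  }
}

# Rasterize a polyline onto a `resolution` x `resolution` grid covering the
# arena; returns the distinct occupied cells as an integer matrix of
# (col, row) pixel coordinates in 1..resolution. Segments are drawn by
# stepping max(|dx|,|dy|)+1 evenly spaced samples per segment, which marks
# every 8-connected cell the ideal line passes through (Bresenham-style).
rasterize_trajectory <- function(trajectory, arena, resolution = 1024L) {
  x <- trajectory[[1]]; y <- trajectory[[2]]
  px <- pmin(pmax(floor(x / arena$width * resolution) + 1L, 1L), resolution)
  py <- pmin(pmax(floor(y / arena$height * resolution) + 1L, 1L), resolution)
  n <- length(px)
  if (n == 1) return(cbind(px, py))
  cells <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    steps <- max(abs(px[i + 1] - px[i]), abs(py[i + 1] - py[i])) + 1L
    cells[[i]] <- cbind(round(seq(px[i], px[i + 1], length.out = steps)),
                        round(seq(py[i], py[i + 1], length.out = steps)))
  }
  m <- unique(do.call(rbind, cells))
  colnames(m) <- NULL
  m
}

box_count <- function(cells, resolution, box_size) {
  bx <- (cells[, 1] - 1L) %/% box_size
  by <- (cells[, 2] - 1L) %/% box_size
  length(unique(bx * (resolution %/% box_size + 1L) + by))
}

#' Box-counting fractal dimension of a trajectory
#'
#' The trajectory polyline is rasterized onto a square binary grid covering
#' the arena, and the dimension is the negative least-squares slope of
#' `log2 N(s)` against `log2 s` over box sizes `s = resolution / 2^k`,
#' `k = 1 .. log2(resolution) - 2` (the largest boxes, which saturate for
#' any non-trivial trajectory, are excluded; the smallest retained box is 4
#' pixels). A line scores ~1, a space-filling trajectory ~2.
#'
#' @param trajectory Two-column matrix/data frame of (x, y) points, or a
#'   `gh_run`.
#' @param arena An [arena()] (taken from the run when a `gh_run` is given).
#' @param resolution Grid resolution, a power of 2 (default 1024).
#' @return List: `dimension`, `degenerate` (TRUE when all points fall in one
#'   cell, in which case the dimension is 0), and the `log2_sizes` /
#'   `log2_counts` table behind the fit.
#' @export
fractal_dimension <- function(trajectory, arena = NULL, resolution = 1024L) {
  if (inherits(trajectory, "gh_run")) {
    arena <- trajectory$arena
    trajectory <- trajectory$trajectory[, c("x", "y")]
  }
  if (is.null(arena)) stop("an arena is required", call. = FALSE)
  if (log2(resolution) %% 1 != 0) {
    stop("resolution must be a power of 2", call. = FALSE)
  }
  trajectory <- as.matrix(trajectory)
  if (nrow(trajectory) < 2) stop("need at least 2 trajectory points",
                                 call. = FALSE)
  cells <- rasterize_trajectory(as.data.frame(trajectory), arena, resolution)
  if (nrow(cells) == 1) {
    return(list(dimension = 0, degenerate = TRUE,
                log2_sizes = numeric(0), log2_counts = numeric(0)))
  }
  ks <- 1:(as.integer(log2(resolution)) - 2L)
  sizes <- resolution / 2^ks
  counts <- vapply(sizes, function(s) box_count(cells, resolution, s),
                   numeric(1))
  fit <- stats::lm(log2(counts) ~ log2(sizes))
  list(dimension = -unname(stats::coef(fit)[2]), degenerate = FALSE,
       log2_sizes = log2(sizes), log2_counts = log2(counts))
}

#' Distance to the nearest wall along a trajectory
#'
#' @param trajectory Two-column matrix/data frame of (x, y) points inside
#'   the arena.
#' @param arena An [arena()].
#' @return Numeric series of minimum Euclidean distances to the four
#'   bounding walls.
#' @export
wall_distance_series <- function(trajectory, arena) {
  trajectory <- as.matrix(trajectory)
  x <- trajectory[, 1]; y <- trajectory[, 2]
  if (any(x < 0 | x > arena$width | y < 0 | y > arena$height)) {
    stop("trajectory point outside the arena", call. = FALSE)
  }
  pmin(x, arena$width - x, y, arena$height - y)
}

# Pearson correlation; constant series give 0 with a flag instead of NA
safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(r = 0, degenerate = TRUE))
  }
  list(r = stats::cor(a, b), degenerate = FALSE)
}

#' Brain-environment coupling correlations of a run
#'
#' Pearson correlations over epochs between (a) wall distance and
#' network-mean activity, (b) wall distance and network-mean threshold, and
#' (c) network-mean threshold and network-mean activity. Raw epoch series
#' are used (no detrending or smoothing); a constant series yields r = 0
#' with a degenerate flag.
#'
#' @param run A `gh_run` with at least 3 epochs.
#' @return List: `r_wall_activity`, `r_wall_threshold`,
#'   `r_threshold_activity`, `degenerate` (named logical vector).
#' @export
coupling_correlations <- function(run) {
  stopifnot(inherits(run, "gh_run"))
  if (nrow(run$states) < 3) stop("need >= 3 epochs", call. = FALSE)
  act <- rowMeans(run$states == 1L)
  thr <- rowMeans(run$thresholds)
  wd <- run$trajectory$wall_distance
  a <- safe_cor(wd, act); b <- safe_cor(wd, thr); d <- safe_cor(thr, act)
  list(r_wall_activity = a$r, r_wall_threshold = b$r,
       r_threshold_activity = d$r,
       degenerate = c(wall_activity = a$degenerate,
                      wall_threshold = b$degenerate,
                      threshold_activity = d$degenerate))
}

#' Per-run summary metrics
#'
#' Computes the full metric set used by the variant comparisons:
#' grand-mean activity, mean across-node SD of activity per epoch (and the
#' alternative reading, the SD over time of the network-mean activity),
#' movement entropy, trajectory fractal dimension, the three coupling
#' correlations, and the SD and coefficient of variation over time of the
#' epoch-mean threshold.
#'
#' @param run A `gh_run`.
#' @param n_bins Entropy bins per axis (default 16).
#' @param resolution Fractal-dimension grid resolution (default 1024).
#' @return One-row data frame of metrics.
#' @export
run_metrics <- function(run, n_bins = 16L, resolution = 1024L) {
  stopifnot(inherits(run, "gh_run"))
  b <- run$states == 1L
  act_node_sd <- mean(apply(b, 1, stats::sd))
  act_time_sd <- stats::sd(rowMeans(b))
  thr_mean <- rowMeans(run$thresholds)
  cc <- coupling_correlations(run)
  fd <- fractal_dimension(run, resolution = resolution)
  data.frame(
    mean_activity = mean(b),
    activity_node_sd = act_node_sd,
    activity_time_sd = act_time_sd,
    movement_entropy = movement_entropy(run$trajectory$v, run$trajectory$h,
                                        n_bins = n_bins),
    fractal_dimension = fd$dimension,
    r_wall_activity = cc$r_wall_activity,
    r_wall_threshold = cc$r_wall_threshold,
    r_threshold_activity = cc$r_threshold_activity,
    threshold_sd = stats::sd(thr_mean),
    threshold_cv = stats::sd(thr_mean) / abs(mean(thr_mean))
  )
}

#' Pooled-variance two-sample t-test
#'
#' Classical equal-variance two-sample t-test with
#' `df = n_a + n_b - 2` (so 30-vs-30 groups give df = 58) and a two-sided
#' p-value. Zero pooled variance with unequal means returns t = +/-Inf with
#' a degenerate flag; with equal means, t = 0 and p = 1.
#'
#' @param metric_a,metric_b Numeric vectors of per-run metric values
#'   (length >= 2 each).
#' @return List: `t_statistic`, `degrees_of_freedom`, `p_value`,
#'   `degenerate`.
#' @export
compare_groups <- function(metric_a, metric_b) {
  na <- length(metric_a); nb <- length(metric_b)
  if (na < 2 || nb < 2) stop("each group needs >= 2 values", call. = FALSE)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(metric_a) + (nb - 1) * stats::var(metric_b)) /
    df
  if (sp2 == 0) {
    delta <- mean(metric_a) - mean(metric_b)
    t <- if (delta == 0) 0 else sign(delta) * Inf
    return(list(t_statistic = t, degrees_of_freedom = df,
                p_value = if (delta == 0) 1 else 0, degenerate = TRUE))
  }
  tt <- stats::t.test(metric_a, metric_b, var.equal = TRUE)
  list(t_statistic = unname(tt$statistic),
       degrees_of_freedom = unname(tt$parameter),
       p_value = tt$p.value, degenerate = FALSE)
}

#' One-sample test of per-run correlation coefficients
#'
#' Fisher z-transforms the per-run correlations and t-tests the transformed
#' values against zero with `df = n - 1`.
#'
#' @param r_values Per-run correlation coefficients (length >= 3, all
#'   strictly inside (-1, 1)).
#' @return List: `t_statistic`, `degrees_of_freedom`, `p_value`,
#'   `degenerate` (TRUE when the transformed values have zero variance).
#' @export
one_sample_correlation_test <- function(r_values) {
  if (length(r_values) < 3) stop("need >= 3 correlations", call. = FALSE)
  if (any(abs(r_values) >= 1)) {
    stop("|r| = 1 overflows the Fisher z-transform", call. = FALSE)
  }
  z <- atanh(r_values)
  df <- length(z) - 1
  if (stats::sd(z) == 0) {
    t <- if (mean(z) == 0) 0 else sign(mean(z)) * Inf
    return(list(t_statistic = t, degrees_of_freedom = df,
                p_value = if (mean(z) == 0) 1 else 0, degenerate = TRUE))
  }
  tt <- stats::t.test(z, mu = 0)
  list(t_statistic = unname(tt$statistic),
       degrees_of_freedom = unname(tt$parameter),
       p_value = tt$p.value, degenerate = FALSE)
}
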