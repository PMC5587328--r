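# Neuronal-avalanche detection and criticality statistics: cascade
# size/duration catalogs, least-squares power-law fits, negative
# log-likelihood against a reference law, and the kappa deviation statistic.

#' Detect avalanches in a binarized activity raster
#'
#' Epochs are grouped into consecutive bins of `bin_dt` (a trailing partial
#' bin is dropped) and the excitation events in each bin are summed over
#' nodes. A cascade is a maximal run of bins with at least one event,
#' bounded by silent bins; its size K is the total event count and its
#' duration the run length in bins. Cascades touching the record boundaries
#' are kept unless `censor_boundaries` is set.
#'
#' @param activity Epoch-by-node 0/1 matrix (e.g. [activity_raster()]).
#' @param bin_dt Positive integer bin width in epochs (default 1).
#' @param censor_boundaries Drop cascades that touch the first or last bin.
#' @return An `avalanche_catalog`: `sizes`, `durations`, `bin_dt`.
#' @export
detect_avalanches <- function(activity, bin_dt = 1L,
                              censor_boundaries = FALSE) {
  if (bin_dt < 1) stop("bin_dt must be >= 1", call. = FALSE)
  activity <- as.matrix(activity)
  if (length(activity) == 0) stop("empty activity raster", call. = FALSE)
  per_epoch <- rowSums(activity == 1L)
  n_bins <- length(per_epoch) %/% bin_dt
  if (n_bins == 0) {
    return(structure(list(sizes = integer(0), durations = integer(0),
                          bin_dt = as.integer(bin_dt)),
                     class = "avalanche_catalog"))
  }
  counts <- colSums(matrix(per_epoch[seq_len(n_bins * bin_dt)],
                           nrow = bin_dt))
  r <- rle(counts > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (censor_boundaries) {
    keep <- keep & starts > 1L & ends < n_bins
  }
  sizes <- vapply(which(keep), function(i) {
    sum(counts[starts[i]:ends[i]])
  }, numeric(1))
  structure(list(sizes = as.integer(sizes),
                 durations = as.integer(r$lengths[keep]),
                 bin_dt = as.integer(bin_dt)),
            class = "avalanche_catalog")
}

#' @export
print.avalanche_catalog <- function(x, ...) {
  cat("avalanche_catalog:", length(x$sizes), "cascades (bin_dt =",
      x$bin_dt, "epochs)\n")
  if (length(x$sizes)) {
    cat(sprintf("  size range [%d, %d], duration range [%d, %d] bins\n",
                min(x$sizes), max(x$sizes),
                min(x$durations), max(x$durations)))
  }
  invisible(x)
}

#' Empirical cascade-size distribution
#'
#' @param catalog An `avalanche_catalog` with at least one cascade.
#' @param field `"sizes"` (default) or `"durations"`.
#' @return Data frame with columns `size` and `prob` (summing to 1).
#' @export
size_distribution <- function(catalog, field = c("sizes", "durations")) {
  field <- match.arg(field)
  x <- catalog[[field]]
  if (!length(x)) stop("empty avalanche catalog", call. = FALSE)
  tab <- table(x)
  data.frame(size = as.integer(names(tab)),
             prob = as.numeric(tab) / length(x))
}

#' Least-squares power-law fit of a size distribution
#'
#' Ordinary least squares of `log10 P(K)` on `log10 K` over the observed
#' sizes (no logarithmic binning by default). The slope is the fitted
#' exponent; `ls_error` is the residual sum of squares.
#'
#' @param dist Data frame `size`/`prob` from [size_distribution()].
#' @param log_binned Pool probabilities into logarithmically spaced size
#'   bins (multiplicative factor 2) before fitting, a robustness variant.
#' @return List with `exponent` and `ls_error`.
#' @export
fit_powerlaw_ls <- function(dist, log_binned = FALSE) {
  dist <- dist[dist$prob > 0, , drop = FALSE]
  if (log_binned) {
    edges <- 2^(0:ceiling(log2(max(dist$size)) + 1))
    bin <- findInterval(dist$size, edges)
    # probability-weighted mean size per bin; bin mass converted to density
    size <- as.numeric(tapply(dist$size * dist$prob, bin, sum) /
                         tapply(dist$prob, bin, sum))
    prob <- as.numeric(tapply(dist$prob, bin, sum)) /
      diff(edges)[sort(unique(bin))]
  } else {
    size <- dist$size
    prob <- dist$prob
  }
  if (length(size) < 3) stop("need >= 3 distinct sizes to fit",
                             call. = FALSE)
  fit <- stats::lm(log10(prob) ~ log10(size))
  list(exponent = unname(stats::coef(fit)[2]),
       ls_error = sum(stats::residuals(fit)^2))
}

# pmf of the discrete power law k^exponent normalized on support min_k..max_k
reference_pmf <- function(min_k, max_k, exponent) {
  k <- min_k:max_k
  p <- k^exponent
  p / sum(p)
}

#' Negative log-likelihood under a reference power law
#'
#' Mean negative log-likelihood per cascade of the discrete power law
#' `P(K) proportional to K^exponent` normalized over the observed size range
#' `[min K, max K]`.
#'
#' @param catalog An `avalanche_catalog`.
#' @param reference_exponent Exponent of the reference law (default -1.5).
#' @return The mean NLL (nats).
#' @export
nll_reference <- function(catalog, reference_exponent = -1.5) {
  x <- catalog$sizes
  if (!length(x)) stop("empty avalanche catalog", call. = FALSE)
  lo <- min(x); hi <- max(x)
  if (lo == hi) stop("degenerate support: all cascade sizes identical",
                     call. = FALSE)
  pmf <- reference_pmf(lo, hi, reference_exponent)
  -mean(log(pmf[x - lo + 1]))
}

#' Kappa deviation statistic against a reference power law
#'
#' `kappa = 1 + (1/m) * sum_k [F_ref(beta_k) - F_emp(beta_k)]` over `m`
#' logarithmically spaced size points `beta_k` between the minimum and
#' maximum observed size, where `F_emp` is the empirical size CDF and
#' `F_ref` the CDF of the discrete reference power law on the same support.
#' Kappa = 1 indicates agreement; kappa < 1 a subcritical-like (too steep)
#' distribution, kappa > 1 a supercritical-like excess of large cascades.
#'
#' @param catalog An `avalanche_catalog` with at least 2 distinct sizes.
#' @param reference_exponent Reference exponent (default -1.5).
#' @param m Number of comparison points (default 10).
#' @return The scalar kappa.
#' @export
kappa_statistic <- function(catalog, reference_exponent = -1.5, m = 10L) {
  x <- catalog$sizes
  if (!length(x)) stop("empty avalanche catalog", call. = FALSE)
  lo <- min(x); hi <- max(x)
  if (lo == hi) stop("degenerate support: all cascade sizes identical",
                     call. = FALSE)
  if (m < 2) stop("m must be >= 2", call. = FALSE)
  beta <- exp(seq(log(lo), log(hi), length.out = m))
  pmf <- reference_pmf(lo, hi, reference_exponent)
  cdf_ref <- cumsum(pmf)
  idx <- floor(beta + 1e-9) - lo + 1          # guard exp/log round-off
  F_ref <- cdf_ref[pmax(pmin(idx, hi - lo + 1), 1)]
  F_emp <- stats::ecdf(x)(beta)
  1 + mean(F_ref - F_emp)
}

#' Full avalanche criticality report for a run or raster
#'
#' Convenience wrapper: detects cascades, fits the least-squares power law
#' to the size distribution, and computes the NLL and kappa against the
#' reference exponent.
#'
#' @param activity Epoch-by-node 0/1 raster, a `gh_run`, or a `gh_rest_run`.
#' @param bin_dt Bin width in epochs (defaults to the run's `bin_dt` when a
#'   `gh_run` is given, else 1).
#' @param reference_exponent Reference exponent (default -1.5).
#' @return List: `catalog`, `n_cascades`, `exponent`, `ls_error`, `nll`,
#'   `kappa` (fit fields are `NA` when the catalog is too small).
#' @export
avalanche_report <- function(activity, bin_dt = NULL,
                             reference_exponent = -1.5) {
  if (inherits(activity, c("gh_run", "gh_rest_run"))) {
    if (is.null(bin_dt)) bin_dt <- activity$config$bin_dt
    activity <- activity_raster(activity)
  }
  if (is.null(bin_dt)) bin_dt <- 1L
  cat_ <- detect_avalanches(activity, bin_dt)
  out <- list(catalog = cat_, n_cascades = length(cat_$sizes),
              exponent = NA_real_, ls_error = NA_real_, nll = NA_real_,
              kappa = NA_real_)
  if (length(unique(cat_$sizes)) >= 3) {
    f <- fit_powerlaw_ls(size_distribution(cat_))
    out$exponent <- f$exponent
    out$ls_error <- f$ls_error
  }
  if (length(unique(cat_$sizes)) >= 2) {
    out$nll <- nll_reference(cat_, reference_exponent)
    out$kappa <- kappa_statistic(cat_, reference_exponent)
  }
  out
}
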