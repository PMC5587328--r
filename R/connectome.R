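#' Construct a connectome object
#'
#' A connectome is a weighted, non-negative, zero-diagonal square matrix of
#' structural connection strengths (streamline-count-like, arbitrary units),
#' with one label and one hemisphere tag per node.
#'
#' @param weights Square numeric matrix, non-negative, zero diagonal.
#' @param labels Character vector of node identifiers (defaults to
#'   `L01..Lk, R01..Rk` for an even number of nodes, `n01..` otherwise).
#' @param hemisphere Character vector of `"left"`/`"right"` tags; defaults to
#'   first half left, second half right when the node count is even.
#' @return An object of class `connectome` with fields `weights`, `labels`,
#'   `hemisphere` and `n_nodes`.
#' @export
connectome <- function(weights, labels = NULL, hemisphere = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    stop("connectome matrix must be square, got ", nrow(weights), "x",
         ncol(weights), call. = FALSE)
  }
  if (!is.numeric(weights) || anyNA(weights)) {
    stop("connectome weights must be numeric and non-missing", call. = FALSE)
  }
  if (any(weights < 0)) {
    stop("connectome weights must be non-negative", call. = FALSE)
  }
  n <- nrow(weights)
  if (any(diag(weights) != 0)) {
    warning("nonzero diagonal entries set to 0 (no self-coupling)")
    diag(weights) <- 0
  }
  if (is.null(labels)) labels <- default_node_labels(n)
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop("need one label per node (", n, "), got ", length(labels),
         call. = FALSE)
  }
  if (is.null(hemisphere)) {
    hemisphere <- if (n %% 2 == 0) {
      rep(c("left", "right"), each = n / 2)
    } else {
      rep(NA_character_, n)
    }
  }
  if (length(hemisphere) != n) {
    stop("need one hemisphere tag per node", call. = FALSE)
  }
  dimnames(weights) <- list(labels, labels)
  structure(
    list(weights = weights, labels = labels, hemisphere = hemisphere,
         n_nodes = n),
    class = "connectome"
  )
}

default_node_labels <- function(n) {
  if (n %% 2 == 0) {
    h <- n / 2
    c(sprintf("L%02d", seq_len(h)), sprintf("R%02d", seq_len(h)))
  } else {
    sprintf("n%02d", seq_len(n))
  }
}

#' @export
print.connectome <- function(x, ...) {
  nz <- sum(x$weights > 0)
  cat("connectome:", x$n_nodes, "nodes,", nz, "non-zero directed entries",
      sprintf("(density %.3f)\n", nz / (x$n_nodes * (x$n_nodes - 1))))
  if (!anyNA(x$hemisphere)) {
    cat("  hemispheres:", sum(x$hemisphere == "left"), "left /",
        sum(x$hemisphere == "right"), "right\n")
  }
  cat(sprintf("  weight range: [%g, %g]\n", min(x$weights), max(x$weights)))
  invisible(x)
}

#' Load a connectome from a delimited text matrix
#'
#' Reads a plain numeric CSV/TSV matrix, optionally with a header row and a
#' first column of node labels, and validates it as a [connectome()].
#'
#' @param path Path to the file.
#' @param delimiter Field separator (default `","`).
#' @return A `connectome` object.
#' @export
load_connectome <- function(path, delimiter = ",") {
  if (!file.exists(path)) stop("cannot read connectome file: ", path,
                               call. = FALSE)
  raw <- utils::read.table(path, sep = delimiter, header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "")
  labels <- NULL
  hemisphere <- NULL
  is_num <- function(x) !anyNA(suppressWarnings(as.numeric(x)))
  # header row present when the first row is not fully numeric
  if (!is_num(unlist(raw[1, ], use.names = FALSE))) {
    raw <- raw[-1, , drop = FALSE]
  }
  if (!is_num(raw[[1]])) {   # first column holds labels
    labels <- as.character(raw[[1]])
    raw <- raw[, -1, drop = FALSE]
  }
  m <- matrix(suppressWarnings(as.numeric(as.matrix(raw))),
              nrow = nrow(raw), ncol = ncol(raw))
  if (anyNA(m)) stop("non-numeric entries in connectome matrix", call. = FALSE)
  if (nrow(m) != ncol(m)) {
    stop("connectome matrix must be square, got ", nrow(m), "x", ncol(m),
         call. = FALSE)
  }
  if (!is.null(labels)) {
    hemisphere <- hemisphere_from_labels(labels)
  }
  connectome(m, labels = labels, hemisphere = hemisphere)
}

hemisphere_from_labels <- function(labels) {
  tag <- ifelse(grepl("^L", labels), "left",
                ifelse(grepl("^R", labels), "right", NA_character_))
  if (anyNA(tag)) NULL else tag
}

#' Write a connectome to CSV
#'
#' Writes the weight matrix with a label header row and label first column,
#' at full double precision so that [load_connectome()] round-trips exactly.
#'
#' @param c A `connectome`.
#' @param path Output file path.
#' @export
write_connectome <- function(c, path) {
  stopifnot(inherits(c, "connectome"))
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e)
    stop("cannot write connectome to ", path, ": ", conditionMessage(e),
         call. = FALSE))
  on.exit(close(con))
  writeLines(paste(c("node", c$labels), collapse = ","), con)
  rows <- vapply(seq_len(c$n_nodes), function(i) {
    paste(c(c$labels[i],
            format(c$weights[i, ], digits = 17, scientific = TRUE,
                   trim = TRUE)),
          collapse = ",")
  }, character(1))
  writeLines(rows, con)
  invisible(NULL)
}

#' Generate a synthetic bilaterally organized connectome
#'
#' Produces a symmetric, non-negative, zero-diagonal weighted matrix that
#' emulates the gross statistics of streamline-count connectomes: two
#' hemispheres of equal size, modular block structure (denser connections
#' inside modules), mirrored left/right homologue pairs that are always
#' connected, and heavy-tailed (log-normal) positive weights. It makes no
#' claim of anatomical fidelity; it is a synthetic stand-in used to
#' constrain the network dynamics.
#'
#' @param n_nodes Even positive integer (default 66).
#' @param n_modules Modules per hemisphere (default 4).
#' @param intra_density Connection probability within a module (default 0.3).
#' @param inter_density Connection probability between modules, including
#'   across hemispheres (default 0.05); must not exceed `intra_density`.
#' @param weight_scale Multiplicative scale of the log-normal weights
#'   (default 1).
#' @param seed Integer seed; identical seeds give bitwise-identical matrices.
#' @return A `connectome` with `n_nodes` nodes tagged half left, half right.
#' @export
generate_synthetic_connectome <- function(n_nodes = 66, n_modules = 4,
                                          intra_density = 0.3,
                                          inter_density = 0.05,
                                          weight_scale = 1,
                                          seed = 1L) {
  if (n_nodes <= 0 || n_nodes %% 2 != 0) {
    stop("n_nodes must be an even positive integer", call. = FALSE)
  }
  if (intra_density <= 0 || intra_density > 1 ||
      inter_density <= 0 || inter_density > 1) {
    stop("densities must lie in (0, 1]", call. = FALSE)
  }
  if (inter_density > intra_density) {
    stop("inter_density must not exceed intra_density", call. = FALSE)
  }
  if (weight_scale <= 0) stop("weight_scale must be positive", call. = FALSE)
  half <- n_nodes / 2
  # mirrored module assignment: node i and its homologue i + half share one
  module <- rep(rep(seq_len(n_modules), length.out = half), 2)
  hemi <- rep(c("left", "right"), each = half)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  w <- matrix(0, n_nodes, n_nodes)
  for (i in seq_len(n_nodes - 1)) {
    for (j in (i + 1):n_nodes) {
      dens <- if (module[i] == module[j] && hemi[i] == hemi[j])
        intra_density else inter_density
      if (stats::runif(1) < dens) {
        w[i, j] <- w[j, i] <- stats::rlnorm(1, meanlog = 0, sdlog = 1) *
          weight_scale
      }
    }
  }
  # homologous mirror pairs always connected
  for (i in seq_len(half)) {
    j <- i + half
    if (w[i, j] == 0) {
      w[i, j] <- w[j, i] <- stats::rlnorm(1, meanlog = 0, sdlog = 1) *
        weight_scale
    }
  }
  connectome(w,
             labels = c(sprintf("L%02d", seq_len(half)),
                        sprintf("R%02d", seq_len(half))),
             hemisphere = hemi)
}
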