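# Node states are stored internally as integers: 0 = Q (quiescent),
# 1 = E (excited), 2 = R (refractory). Letters are used at the interfaces.

STATE_LEVELS <- c("Q", "E", "R")

states_to_int <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  out <- match(toupper(as.character(x)), STATE_LEVELS) - 1L
  if (anyNA(out)) stop("states must be in {E, Q, R}", call. = FALSE)
  out
}

states_to_letter <- function(x) STATE_LEVELS[as.integer(x) + 1L]

#' Construct a GH network state
#'
#' @param states Length-N vector over `{"E","Q","R"}` (or the internal
#'   integer coding 0=Q, 1=E, 2=R).
#' @param thresholds Length-N numeric vector of activation thresholds.
#' @param epoch Non-negative integer epoch index.
#' @return A `gh_state` object.
#' @export
gh_state <- function(states, thresholds, epoch = 0L) {
  s <- states_to_int(states)
  thresholds <- as.numeric(thresholds)
  if (length(s) != length(thresholds)) {
    stop("states and thresholds must have equal length", call. = FALSE)
  }
  structure(list(states = s, thresholds = thresholds,
                 epoch = as.integer(epoch)),
            class = "gh_state")
}

#' @export
print.gh_state <- function(x, ...) {
  tab <- table(factor(states_to_letter(x$states), levels = STATE_LEVELS))
  cat("gh_state: epoch", x$epoch, "|",
      paste(names(tab), tab, sep = "=", collapse = " "),
      sprintf("| thresholds [%.3g, %.3g]\n",
              min(x$thresholds), max(x$thresholds)))
  invisible(x)
}

#' Model configuration
#'
#' Collects every run parameter of the embodied GH model.
#'
#' @param coupling Global scaling factor g applied to the max-normalized
#'   connectivity matrix. The default 1.8 sits at the phase transition of
#'   the default 66-node synthetic connectome (see the package vignette).
#' @param initial_threshold Activation threshold at epoch 0, uniform over
#'   nodes (default 0.35).
#' @param p_spont Spontaneous Q to E firing probability per epoch
#'   (default 0.1).
#' @param alpha Homeostatic learning rate (non-negative; default 0.1).
#' @param rho Target activation rate in `[0, 1]` (default 0.1).
#' @param variant One of `"static"`, `"local"`, `"macro"`, `"combined"`:
#'   no plasticity, local threshold plasticity, macroscopic task-negative
#'   balancing, or both.
#' @param epochs Number of synchronous update steps (default 2000).
#' @param seed Integer master seed.
#' @param bin_dt Avalanche re-binning width in epochs (default 1).
#' @param smooth_turn Smooth the turn command like the move command
#'   (default FALSE; only the move command is smoothed).
#' @param homeostasis_exclude Node indices excluded from the threshold
#'   update. The default `NULL` means "the exogenously forced nodes", i.e.
#'   the task-positive and task-negative sets are resolved at run time
#'   (their state is clamped by the environment or the balancer, so
#'   updating their thresholds only accumulates unbounded drift). Pass
#'   `integer(0)` to apply the rule to every node.
#' @return A `model_config` object.
#' @export
model_config <- function(coupling = 1.8, initial_threshold = 0.35,
                         p_spont = 0.1, alpha = 0.1, rho = 0.1,
                         variant = c("static", "local", "macro", "combined"),
                         epochs = 2000L, seed = 1L, bin_dt = 1L,
                         smooth_turn = FALSE,
                         homeostasis_exclude = NULL) {
  variant <- match.arg(variant)
  if (p_spont < 0 || p_spont > 1) stop("p_spont must be in [0, 1]",
                                       call. = FALSE)
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]", call. = FALSE)
  if (alpha < 0) stop("alpha must be non-negative", call. = FALSE)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (coupling <= 0) stop("coupling must be positive", call. = FALSE)
  if (bin_dt < 1) stop("bin_dt must be >= 1", call. = FALSE)
  structure(list(coupling = coupling, initial_threshold = initial_threshold,
                 p_spont = p_spont, alpha = alpha, rho = rho,
                 variant = variant, epochs = as.integer(epochs),
                 seed = as.integer(seed), bin_dt = as.integer(bin_dt),
                 smooth_turn = isTRUE(smooth_turn),
                 homeostasis_exclude = if (!is.null(homeostasis_exclude))
                   as.integer(homeostasis_exclude)),
            class = "model_config")
}

#' Sensor, motor and task-negative node role assignment
#'
#' Roles are bilateral: each sensor/motor function is assigned to one node
#' per hemisphere. The six task-positive nodes (near visual, far visual,
#' somatosensory; left and right) are forced to the excited state by sensory
#' events; the four task-negative nodes are forced in complement to them
#' under macroscopic balancing; the four motor nodes (rotate and forward,
#' left and right) drive the agent.
#'
#' @param rotate_left,rotate_right,forward_left,forward_right Motor node
#'   indices.
#' @param near_visual,far_visual,somatosensory Length-2 integer vectors
#'   `c(left, right)`.
#' @param task_negative Length-4 integer vector: two bilateral pairs in
#'   priority order, alternating left/right (L1, R1, L2, R2).
#' @param n_nodes Network size, used for bounds checking.
#' @return A `node_roles` object.
#' @export
node_roles <- function(rotate_left, rotate_right, forward_left, forward_right,
                       near_visual, far_visual, somatosensory,
                       task_negative, n_nodes) {
  stopifnot(length(near_visual) == 2, length(far_visual) == 2,
            length(somatosensory) == 2, length(task_negative) == 4)
  all_idx <- c(rotate_left, rotate_right, forward_left, forward_right,
               near_visual, far_visual, somatosensory, task_negative)
  all_idx <- as.integer(all_idx)
  if (any(all_idx < 1) || any(all_idx > n_nodes)) {
    stop("role indices must lie in [1, n_nodes]", call. = FALSE)
  }
  if (anyDuplicated(all_idx)) {
    stop("role indices must be distinct", call. = FALSE)
  }
  roles <- list(rotate_left = as.integer(rotate_left),
                rotate_right = as.integer(rotate_right),
                forward_left = as.integer(forward_left),
                forward_right = as.integer(forward_right),
                near_visual = as.integer(near_visual),
                far_visual = as.integer(far_visual),
                somatosensory = as.integer(somatosensory),
                task_negative = as.integer(task_negative),
                n_nodes = as.integer(n_nodes))
  roles$task_positive <- c(roles$near_visual, roles$far_visual,
                           roles$somatosensory)
  structure(roles, class = "node_roles")
}

#' Default role assignment for a bilaterally labeled connectome
#'
#' Picks mirrored left/right node pairs for each role. The choice of which
#' regions carry sensor, motor and task-negative roles is intentionally
#' arbitrary (no anatomical claim is made); what matters is bilaterality and
#' disjointness.
#'
#' @param c A `connectome` with an even node count.
#' @return A `node_roles` object.
#' @export
default_node_roles <- function(c) {
  stopifnot(inherits(c, "connectome"))
  n <- c$n_nodes
  if (n %% 2 != 0 || n < 20) {
    stop("default roles need an even node count of at least 20",
         call. = FALSE)
  }
  half <- n / 2
  p <- function(i) c(i, i + half)  # mirrored pair
  node_roles(rotate_left = 1L, rotate_right = 1L + half,
             forward_left = 3L, forward_right = 3L + half,
             near_visual = p(5L), far_visual = p(6L), somatosensory = p(7L),
             task_negative = c(p(9L)[1], p(9L)[2], p(10L)[1], p(10L)[2]),
             n_nodes = n)
}

# coupling-scaled, max-normalized weight matrix used by the update rule
normalized_weights <- function(c, coupling) {
  w <- c$weights
  mx <- max(w)
  if (mx > 0) w <- w / mx
  coupling * w
}

# Core synchronous update. `states` integer vector, `w` the
# coupling-scaled normalized matrix. Consumes length(states) uniform draws
# from the R global RNG each call, regardless of how many nodes are
# quiescent, so the stream position is state-independent.
gh_step_core <- function(states, thresholds, w, p_spont,
                         forced_E = integer(0), forced_Q = integer(0)) {
  b <- as.numeric(states == 1L)
  input <- drop(w %*% b)
  u <- stats::runif(length(states))
  new <- integer(length(states))
  new[states == 1L] <- 2L                      # E -> R deterministically
  new[states == 2L] <- 0L                      # R -> Q deterministically
  q <- states == 0L
  fire <- q & (u < p_spont | input > thresholds)
  new[fire] <- 1L
  if (length(forced_E)) new[forced_E] <- 1L    # forcing overrides
  if (length(forced_Q)) new[forced_Q] <- 0L
  new
}

#' One synchronous GH update step
#'
#' Every excited node becomes refractory, every refractory node quiescent,
#' and a quiescent node i fires (Q to E) spontaneously with probability
#' `p_spont` or deterministically when its summed weighted input exceeds its
#' threshold: `g * sum_j (C_ij / max(C)) * b_j(t) > T_i`, with `b_j` the
#' binarized activity (1 iff excited). Nodes in `forced_E` / `forced_Q` are
#' then overwritten for this epoch only; a node forced E on consecutive
#' epochs stays E (its E-to-R rule is suppressed while forced). Thresholds
#' are unchanged. Uses the R global RNG; seed it for reproducibility.
#'
#' @param state A [gh_state()].
#' @param c A [connectome()].
#' @param config A [model_config()].
#' @param forced_E,forced_Q Disjoint integer index sets.
#' @return The updated `gh_state` with `epoch` incremented.
#' @export
step_states <- function(state, c, config, forced_E = integer(0),
                        forced_Q = integer(0)) {
  stopifnot(inherits(state, "gh_state"), inherits(c, "connectome"))
  n <- c$n_nodes
  if (length(state$states) != n) {
    stop("state dimension does not match connectome", call. = FALSE)
  }
  forced_E <- as.integer(forced_E); forced_Q <- as.integer(forced_Q)
  if (length(intersect(forced_E, forced_Q))) {
    stop("forced_E and forced_Q must be disjoint", call. = FALSE)
  }
  if (any(c(forced_E, forced_Q) < 1) || any(c(forced_E, forced_Q) > n)) {
    stop("forced indices out of range", call. = FALSE)
  }
  w <- normalized_weights(c, config$coupling)
  new <- gh_step_core(state$states, state$thresholds, w, config$p_spont,
                      forced_E, forced_Q)
  gh_state(new, state$thresholds, epoch = state$epoch + 1L)
}

#' Local homeostatic threshold update
#'
#' Applies the inhibitory plasticity rule `T_i <- T_i + alpha * (b_i - rho)`
#' to every node (optionally excluding `config$homeostasis_exclude`), where
#' `b_i` is the binarized activity. A no-op unless `config$variant` is
#' `"local"` or `"combined"`. Thresholds are not clamped: they may go
#' negative under prolonged silence, which makes any positive input
#' supra-threshold, as the un-clamped rule implies.
#'
#' @param state A [gh_state()].
#' @param config A [model_config()].
#' @return The `gh_state` with updated thresholds (states unchanged).
#' @export
update_thresholds <- function(state, config) {
  if (!config$variant %in% c("local", "combined")) return(state)
  b <- as.numeric(state$states == 1L)
  delta <- config$alpha * (b - config$rho)
  excl <- config$homeostasis_exclude   # NULL = no roles context: all nodes
  if (length(excl)) delta[excl] <- 0
  state$thresholds <- state$thresholds + delta
  state
}

#' Macroscopic task-negative balancing
#'
#' Keeps the number of exogenously activated nodes constant: with B = 4
#' task-negative (TN) nodes and k = min(|forced task-positive|, B), the
#' first B - k TN nodes in the fixed priority order (alternating left/right
#' across the two bilateral pairs) are forced excited and the remaining k
#' forced quiescent, so that |forced sensory (capped at B)| + |TN forced E|
#' = B at every epoch.
#'
#' @param tp_forced Indices of task-positive nodes being forced this epoch
#'   (must be a subset of the task-positive set).
#' @param roles A [node_roles()].
#' @return List with integer vectors `forced_E_tn` and `forced_Q_tn`.
#' @export
macro_balance <- function(tp_forced, roles) {
  tp_forced <- as.integer(tp_forced)
  if (length(setdiff(tp_forced, roles$task_positive))) {
    stop("tp_forced must be a subset of the task-positive node set",
         call. = FALSE)
  }
  tn <- roles$task_negative
  B <- length(tn)
  k <- min(length(tp_forced), B)
  list(forced_E_tn = tn[seq_len(B - k)],
       forced_Q_tn = if (k > 0) tn[(B - k + 1):B] else integer(0))
}

#' Grand mean activity of a binarized run record
#'
#' @param record Epoch-by-node matrix of binarized activity (0/1, or the
#'   internal state coding, in which case excited = 1 is used).
#' @return Mean of `b_i(t)` over all nodes and epochs, in `[0, 1]`.
#' @export
mean_activity <- function(record) {
  record <- as.matrix(record)
  if (length(record) == 0) stop("empty activity record", call. = FALSE)
  mean(record == 1L)
}

#' Pairwise node activity correlations
#'
#' Pearson correlation between the binarized activity time-courses of every
#' node pair. Pairs involving a constant series have undefined correlation
#' and are reported as 0; `flagged` marks the constant nodes.
#'
#' @param record Epoch-by-node binarized activity matrix with at least two
#'   epochs.
#' @return List with the `matrix`, the scalar `mean_offdiag`, and `flagged`.
#' @export
node_correlation_matrix <- function(record) {
  record <- as.matrix(record)
  if (nrow(record) < 2) stop("need >= 2 epochs", call. = FALSE)
  b <- matrix(as.numeric(record == 1L), nrow(record), ncol(record))
  sds <- apply(b, 2, stats::sd)
  flagged <- which(sds == 0)
  m <- suppressWarnings(stats::cor(b))
  m[is.na(m)] <- 0
  diag(m) <- 1
  off <- m[upper.tri(m)]
  list(matrix = m, mean_offdiag = mean(off), flagged = flagged)
}
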