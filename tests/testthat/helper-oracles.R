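# Independent reference implementations used as oracles. These are written
# deliberately as plain per-node/per-cell loops, sharing no code with the
# package's vectorized implementations.

# Exhaustive per-node GH update with p_spont = 0 (deterministic).
# states: character vector in {"E","Q","R"}; C: raw weight matrix;
# returns the next character state vector.
oracle_step <- function(states, C, g, thresholds, forced_E = integer(0),
                        forced_Q = integer(0)) {
  n <- length(states)
  Chat <- C / max(C)
  nxt <- character(n)
  for (i in seq_len(n)) {
    if (states[i] == "E") {
      nxt[i] <- "R"
    } else if (states[i] == "R") {
      nxt[i] <- "Q"
    } else {
      input <- 0
      for (j in seq_len(n)) {
        if (states[j] == "E") input <- input + g * Chat[i, j]
      }
      nxt[i] <- if (input > thresholds[i]) "E" else "Q"
    }
  }
  for (i in forced_E) nxt[i] <- "E"
  for (i in forced_Q) nxt[i] <- "Q"
  nxt
}

# all length-n state vectors over {E,Q,R}
all_state_vectors <- function(n) {
  grid <- do.call(expand.grid,
                  rep(list(c("E", "Q", "R")), n))
  apply(as.matrix(grid), 1, as.character, simplify = FALSE)
}

# Second, independent box-counting implementation: builds the full logical
# grid and counts occupied boxes by explicit block scanning.
oracle_box_count <- function(cells, resolution, box_size) {
  grid <- matrix(FALSE, resolution, resolution)
  grid[cells] <- TRUE
  nb <- resolution / box_size
  count <- 0
  for (bi in seq_len(nb)) {
    for (bj in seq_len(nb)) {
      rows <- ((bi - 1) * box_size + 1):(bi * box_size)
      cols <- ((bj - 1) * box_size + 1):(bj * box_size)
      if (any(grid[rows, cols])) count <- count + 1
    }
  }
  count
}

# Inverse-CDF sampler from the discrete power law k^expo on lo..hi
rpowerlaw <- function(n, lo, hi, expo) {
  k <- lo:hi
  p <- k^expo
  p <- p / sum(p)
  sample(k, n, replace = TRUE, prob = p)
}

# tiny chain connectome used across dynamics tests
chain3_connectome <- function() {
  connectome(matrix(c(0, 1, 0,
                      1, 0, 1,
                      0, 1, 0), 3, 3, byrow = TRUE),
             labels = c("a", "b", "c"),
             hemisphere = c("left", "left", "right"))
}

# roles on the default 66-node synthetic connectome
test_connectome <- function(seed = 1) generate_synthetic_connectome(seed = seed)
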