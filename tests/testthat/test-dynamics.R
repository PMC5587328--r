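test_that("single-step transitions follow the three-state rules", {
  con <- chain3_connectome()
  cfg <- model_config(coupling = 1, p_spont = 0, variant = "static")

  # excited nodes become refractory with probability 1
  s <- gh_state(c("E", "Q", "Q"), thresholds = c(0.5, 1.5, 0.5))
  set.seed(1)
  nxt <- step_states(s, con, cfg)
  expect_identical(embodiedGH:::states_to_letter(nxt$states),
                   c("R", "Q", "Q"))   # input to node 2 is 1, not > 1.5
  expect_equal(nxt$epoch, 1L)
  expect_equal(nxt$thresholds, s$thresholds)

  # lowering node 2's threshold lets the excitation propagate
  s2 <- gh_state(c("E", "Q", "Q"), thresholds = c(0.5, 0.5, 0.5))
  nxt2 <- step_states(s2, con, cfg)
  expect_identical(embodiedGH:::states_to_letter(nxt2$states),
                   c("R", "E", "Q"))

  # refractory resolves to quiescent; silence is absorbing at p_spont = 0
  s3 <- gh_state(c("R", "Q", "Q"), thresholds = rep(1, 3))
  expect_identical(embodiedGH:::states_to_letter(step_states(s3, con, cfg)$states),
                   c("Q", "Q", "Q"))
  s4 <- gh_state(c("Q", "Q", "Q"), thresholds = rep(1, 3))
  for (i in 1:5) s4 <- step_states(s4, con, cfg)
  expect_identical(embodiedGH:::states_to_letter(s4$states), c("Q", "Q", "Q"))
})

test_that("forcing overrides the computed state and validates its arguments", {
  con <- chain3_connectome()
  cfg <- model_config(coupling = 1, p_spont = 0, variant = "static")
  s <- gh_state(c("E", "Q", "Q"), thresholds = rep(9, 3))
  nxt <- step_states(s, con, cfg, forced_E = c(1L, 3L))
  # node 1 stays E while forced (its E->R rule is suppressed)
  expect_identical(embodiedGH:::states_to_letter(nxt$states), c("E", "Q", "E"))
  nxt2 <- step_states(nxt, con, cfg, forced_Q = 1L)
  expect_identical(embodiedGH:::states_to_letter(nxt2$states)[1], "Q")

  expect_error(step_states(s, con, cfg, forced_E = 1L, forced_Q = 1L),
               "disjoint")
  expect_error(step_states(s, con, cfg, forced_E = 9L), "range")
})

test_that("synchronous update agrees with an exhaustive per-node oracle", {
  set.seed(42)
  for (n in 2:4) {
    C <- matrix(stats::runif(n * n), n, n)
    C <- C + t(C); diag(C) <- 0
    con <- connectome(C, labels = sprintf("n%d", 1:n),
                      hemisphere = rep(NA_character_, n))
    g <- 1.3
    thr <- stats::runif(n, 0, 1.5)
    cfg <- model_config(coupling = g, p_spont = 0, variant = "static")
    for (sv in all_state_vectors(n)) {
      expected <- oracle_step(sv, C, g, thr)
      got <- step_states(gh_state(sv, thr), con, cfg)
      expect_identical(embodiedGH:::states_to_letter(got$states), expected)
    }
  }
})

test_that("every state partition stays exhaustive across a stochastic run", {
  con <- test_connectome()
  cfg <- model_config(epochs = 200, seed = 8, variant = "combined")
  run <- run_simulation(con, config = cfg)
  counts <- t(apply(run$states, 1, function(r) {
    c(sum(r == 0L), sum(r == 1L), sum(r == 2L))
  }))
  expect_true(all(rowSums(counts) == con$n_nodes))
})

test_that("threshold plasticity moves thresholds by alpha*(b - rho) and is gated by variant", {
  s <- gh_state(c("E", "Q", "R"), thresholds = c(1, 1, 1))
  cfg <- model_config(alpha = 0.1, rho = 0.1, variant = "local",
                      homeostasis_exclude = integer(0))
  out <- update_thresholds(s, cfg)
  expect_equal(out$thresholds, c(1.09, 0.99, 0.99))
  expect_identical(out$states, s$states)

  cfg0 <- model_config(alpha = 0, rho = 0.1, variant = "local",
                       homeostasis_exclude = integer(0))
  expect_equal(update_thresholds(s, cfg0)$thresholds, s$thresholds)

  cfg_static <- model_config(alpha = 0.1, rho = 0.1, variant = "static")
  expect_equal(update_thresholds(s, cfg_static)$thresholds, s$thresholds)

  cfg_ex <- model_config(alpha = 0.1, rho = 0.1, variant = "local",
                         homeostasis_exclude = 1L)
  expect_equal(update_thresholds(s, cfg_ex)$thresholds, c(1, 0.99, 0.99))
})

test_that("thresholds are not clamped and drift negative under silence", {
  s <- gh_state(c("Q", "Q"), thresholds = c(0.01, 0.01))
  cfg <- model_config(alpha = 0.1, rho = 0.5, variant = "local",
                      homeostasis_exclude = integer(0))
  for (i in 1:5) s <- update_thresholds(s, cfg)
  expect_true(all(s$thresholds < 0))
})

test_that("macro balancing keeps the exogenous activation budget at four", {
  con <- test_connectome()
  roles <- default_node_roles(con)
  tn <- roles$task_negative

  b0 <- macro_balance(integer(0), roles)
  expect_identical(b0$forced_E_tn, tn)
  expect_length(b0$forced_Q_tn, 0)

  b2 <- macro_balance(roles$near_visual, roles)
  expect_identical(b2$forced_E_tn, tn[1:2])
  expect_identical(b2$forced_Q_tn, tn[3:4])

  b6 <- macro_balance(roles$task_positive, roles)
  expect_length(b6$forced_E_tn, 0)
  expect_identical(b6$forced_Q_tn, tn)

  for (k in 0:6) {
    b <- macro_balance(roles$task_positive[seq_len(k)], roles)
    expect_equal(length(b$forced_E_tn) + min(k, 4), 4)
  }

  expect_error(macro_balance(roles$rotate_left, roles), "task-positive")
})

test_that("mean activity averages binarized firing over nodes and epochs", {
  expect_equal(mean_activity(matrix(0L, 5, 3)), 0)
  alt <- rbind(matrix(1L, 1, 2), matrix(0L, 1, 2),
               matrix(1L, 1, 2), matrix(0L, 1, 2))
  expect_equal(mean_activity(alt), 0.5)
  rec <- matrix(c(1, 0, 0, 1,
                  0, 0, 1, 0), 4, 2)   # 3 excited entries out of 8
  expect_equal(mean_activity(rec), 0.375)
  expect_error(mean_activity(matrix(numeric(0), 0, 0)), "empty")
})

test_that("node correlations handle perfect, inverse, independent and constant series", {
  a <- rep(c(1L, 0L), 50)
  m <- node_correlation_matrix(cbind(a, a))
  expect_equal(m$matrix[1, 2], 1)
  m2 <- node_correlation_matrix(cbind(a, 1L - a))
  expect_equal(m2$matrix[1, 2], -1)

  set.seed(7)
  flips <- cbind(stats::rbinom(1e4, 1, 0.5), stats::rbinom(1e4, 1, 0.5))
  m3 <- node_correlation_matrix(flips)
  expect_lt(abs(m3$matrix[1, 2]), 0.05)

  m4 <- node_correlation_matrix(cbind(a, rep(0L, 100)))
  expect_equal(m4$matrix[1, 2], 0)
  expect_equal(m4$flagged, 2)
  expect_error(node_correlation_matrix(matrix(0L, 1, 2)), "epochs")
})

test_that("an excited node is refractory then quiescent when left unforced", {
  con <- test_connectome()
  cfg <- model_config(epochs = 300, seed = 5, variant = "static")
  run <- run_simulation(con, config = cfg)
  S <- run$states
  FE <- run$forced_E
  for (t in seq_len(nrow(S) - 2)) {
    e_now <- which(S[t, ] == 1L & !FE[t + 1, ] & !FE[t + 2, ])
    if (length(e_now)) {
      expect_true(all(S[t + 1, e_now] == 2L))
      expect_true(all(S[t + 2, e_now] == 0L))
    }
  }
})
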