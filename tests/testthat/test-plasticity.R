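test_that("the complementary update moves the selected weight toward 1 and preserves the pair sum", {
  expect_equal(update_weight(0.5, 0.5, 0.1),
               list(w_selected = 0.55, w_deselected = 0.45))
  # fixed point at the bounds
  expect_equal(update_weight(1, 0, 0.3), list(w_selected = 1, w_deselected = 0))
  expect_error(update_weight(0.5, 0.5, 1.5), "alpha")
  expect_error(update_weight(1.4, -0.4, 0.1), "weights")
})

test_that("complementarity and bounds survive random update sequences", {
  set.seed(5)
  for (rep in 1:50) {
    w_sel <- runif(1)
    w_desel <- 1 - w_sel
    alpha <- runif(1, 0.001, 0.5)
    for (i in 1:40) {
      upd <- update_weight(w_sel, w_desel, alpha)
      w_sel <- upd$w_selected; w_desel <- upd$w_deselected
      expect_true(w_sel >= 0 && w_sel <= 1 && w_desel >= 0 && w_desel <= 1)
      expect_equal(w_sel + w_desel, 1, tolerance = 1e-12)
    }
  }
})

test_that("a persistently selected path is monotonically reinforced toward 1", {
  w <- 0.5; v <- 0.5
  traj <- numeric(1000)
  for (i in 1:1000) {
    upd <- update_weight(w, v, 0.01)
    w <- upd$w_selected; v <- upd$w_deselected
    traj[i] <- w
  }
  expect_true(all(diff(c(0.5, traj)) > 0))
  expect_gt(traj[1000], 1 - 1e-4)
})

test_that("annealing decrements to the floor in the closed-form number of spikes", {
  expect_equal(anneal_temperature(1.0, 0.005, 0.05), 0.995)
  expect_equal(anneal_temperature(0.051, 0.005, 0.05), 0.05)   # floor clamp
  T_cur <- 1.0
  n_steps <- 0L
  while (T_cur > 0.05) {
    T_cur <- anneal_temperature(T_cur, 0.005, 0.05)
    n_steps <- n_steps + 1L
  }
  expect_equal(n_steps, ceiling((1.0 - 0.05) / 0.005))
})

test_that("a zero learning rate leaves weights untouched and is reported unconverged at the cap", {
  cfg <- network_config(alpha = 0, seed = 3)
  res <- train(build_network(2, 2, cfg), two_electrode_set(),
               max_presentations = 300)
  expect_false(res$converged)
  expect_equal(res$presentations_used, 300L)
  expect_true(all(res$network$w_direct[, 2] == 0.5))
})

test_that("training an already-binarized net returns immediately", {
  res <- train(minimal_circuit_net(), two_electrode_set())
  expect_true(res$converged)
  expect_equal(res$presentations_used, 0L)
})

test_that("training is bitwise deterministic under a fixed seed", {
  pats <- two_electrode_set()
  cfg <- network_config(seed = 13)
  a <- train(build_network(2, 2, cfg), pats)
  b <- train(build_network(2, 2, cfg), pats)
  expect_identical(a$network$w_direct, b$network$w_direct)
  expect_identical(a$temperature_history, b$temperature_history)
  expect_identical(a$spike_history, b$spike_history)
  expect_equal(a$presentations_used, b$presentations_used)
})

test_that("layer temperatures are non-increasing and floored during training", {
  res <- train(build_network(2, 2, network_config(seed = 21)),
               two_electrode_set())
  th <- res$temperature_history
  for (l in unique(th$layer)) {
    temps <- th$temperature[th$layer == l]
    expect_true(all(diff(temps) <= 0))
    expect_true(all(temps >= 0.05 - 1e-12))
  }
})

test_that("converged minimal-circuit runs land in the oracle feasible set and pass the truth table", {
  pats <- two_electrode_set()
  feasible <- brute_force_configs(pats)
  expect_gt(length(feasible$configs), 0L)
  for (s in 1:5) {
    res <- train(build_network(2, 2, network_config(seed = s)), pats)
    expect_true(res$converged)
    expect_true(in_feasible_set(feasible, binary_config(res$network)))
    expect_true(all(truth_table(res$network)$correct))
  }
})

test_that("dimension mismatches between net and patterns are rejected", {
  expect_error(train(build_network(3, 3), two_electrode_set()), "width")
  expect_error(train(build_network(2, 3), two_electrode_set()), "classes")
})
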