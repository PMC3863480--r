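test_that("the Boltzmann path probability has its symmetric, annealed and hand-computed values", {
  for (T_b in c(0.05, 0.5, 1, 10)) {
    expect_identical(p_direct(0.5, 0.5, T_b), 0.5)   # symmetric weights
  }
  # hand evaluation: exp(1.6) / (exp(1.6) + exp(0.4))
  expect_equal(p_direct(0.8, 0.2, 0.5), 0.7685248, tolerance = 1e-6)
  # annealed limit: saturated weights at the temperature floor
  expect_gte(p_direct(1, 0, 0.05), 1 - 1e-6)
  expect_error(p_direct(0.5, 0.5, 0), "T_boltz")
  expect_error(p_direct(1.2, -0.2, 1), "weights")
})

test_that("direct and delay probabilities are complementary and monotone in w_direct", {
  set.seed(42)
  w <- runif(200)
  T_b <- runif(200, 0.01, 5)
  expect_equal(p_direct(w, 1 - w, T_b) + p_direct(1 - w, w, T_b),
               rep(1, 200), tolerance = 1e-12)
  # strictly increasing in w_direct at fixed T
  grid <- seq(0, 1, by = 0.05)
  for (T_b in c(0.05, 1)) {
    expect_true(all(diff(p_direct(grid, 1 - grid, T_b)) > 0))
  }
  # T -> 0 approaches the indicator of the larger weight
  expect_equal(p_direct(0.9, 0.1, 1e-4), 1, tolerance = 1e-9)
  expect_equal(p_direct(0.1, 0.9, 1e-4), 0, tolerance = 1e-9)
})

test_that("gating samples follow the Boltzmann probabilities and the input-layer clamp", {
  # fresh net at T_max: empirical direct fraction ~ 0.5 within 3 sigma
  net <- build_network(3, 3)
  set.seed(1)
  draws <- replicate(2000, sample_gating(net)[, -1])
  frac <- mean(draws)
  n_draws <- length(draws)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_draws))
  # input layer always direct
  set.seed(2)
  expect_true(all(replicate(50, sample_gating(net)[, 1]) == 1L))
  # binarized net at the temperature floor reproduces its configuration
  netb <- minimal_circuit_net()
  netb$temperatures <- rep(0.05, 2)
  set.seed(3)
  samples <- replicate(1000, sample_gating(netb), simplify = FALSE)
  match_frac <- mean(vapply(samples, function(g) all(g == minimal_circuit_bits()),
                            logical(1)))
  expect_gte(match_frac, 1 - 1e-3)
  # same seed, identical samples
  set.seed(99); a <- sample_gating(net)
  set.seed(99); b <- sample_gating(net)
  expect_identical(a, b)
})

test_that("the minimal circuit reproduces its truth table under propagation", {
  net <- minimal_circuit_net()
  pats <- two_electrode_set()
  v <- propagate(net, pattern = pats$patterns[[1]])
  expect_equal(v$spikes$output, 0L)      # simultaneous input -> output 0 only
  d <- propagate(net, pattern = pats$patterns[[2]])
  expect_equal(d$spikes$output, 1L)      # staggered input -> output 1 only
})

test_that("direct transit takes one clock step and the delay neuron adds exactly one more", {
  cfg <- network_config()
  one_col <- stim_pattern(data.frame(input = 0, step = 0), width = 1, duration = 1)
  direct <- set_binary_config(build_network(1, 2, cfg), matrix(1, 1, 2))
  delayed <- set_binary_config(build_network(1, 2, cfg), matrix(c(1, 0), 1, 2))
  t_direct <- propagate(direct, pattern = one_col)$spikes
  t_delay <- propagate(delayed, pattern = one_col)$spikes
  # layer-1 junction reached one step later on the delay path
  expect_equal(t_delay$step[t_delay$output == 1] -
                 t_direct$step[t_direct$output == 1], 1L)
  # direct path: one step per segment
  expect_equal(t_direct$step, c(1L, 2L))
})

test_that("propagation is deterministic, bounded and empty-safe", {
  net <- build_network(9, 9)
  pat <- make_bar_pattern(9, 9, 5)
  set.seed(4)
  g <- sample_gating(net)
  a <- propagate(net, g, pat)
  b <- propagate(net, g, pat)
  expect_identical(a, b)
  # signals in flight never exceed m
  per_step <- table(a$occupancy$step)
  expect_true(all(per_step <= 9L))
  # signals advance one layer per 1 or 2 clock steps
  dwell <- dplyr::count(a$occupancy, column, layer)
  expect_true(all(dwell$n %in% 1:2))

  empty <- stim_pattern(data.frame(input = integer(), step = integer()),
                        width = 9, duration = 9)
  tr <- propagate(net, g, empty)
  expect_equal(nrow(tr$spikes), 0L)
  expect_equal(nrow(tr$occupancy), 0L)

  expect_error(propagate(net, g, make_bar_pattern(5, 5, 1)), "width")
})

test_that("the wave front dissolves off the target layer of the analytic net", {
  net <- analytic_nine_net()
  bars <- nine_bar_set()
  for (k in 1:9) {
    tr <- propagate(net, pattern = bars$patterns[[k]])
    expect_equal(tr$spikes$output, k - 1L)   # exactly one spike, at layer k-1
  }
})

test_that("decoding reads the time-and-place code and flags silent or ambiguous traces", {
  trace <- structure(list(
    occupancy = tibble::tibble(step = 2L, column = 0L, layer = 0L),
    spikes = tibble::tibble(output = 3L, step = 7L),
    first_input_step = 2L, m = 4, n = 4), class = "propagation_trace")
  d <- decode(trace)
  expect_equal(d$feature, 3L)
  expect_equal(d$rel_time, 5L)
  expect_equal(d$status, "ok")

  trace$spikes <- trace$spikes[0, ]
  expect_equal(decode(trace)$status, "none")

  trace$spikes <- tibble::tibble(output = c(0L, 2L), step = c(3L, 5L))
  amb <- decode(trace)
  expect_equal(amb$status, "ambiguous")
  expect_equal(amb$n_outputs_fired, 2L)
})

test_that("the converged analytic net decodes every bar class to its own feature neuron", {
  net <- analytic_nine_net()
  bars <- nine_bar_set()
  decoded <- vapply(1:9, function(k) {
    decode(propagate(net, pattern = bars$patterns[[k]]))$feature
  }, integer(1))
  expect_equal(decoded, 0:8)
})

test_that("traces export to a flat CSV event log", {
  net <- minimal_circuit_net()
  tr <- propagate(net, pattern = two_electrode_set()$patterns[[2]])
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  log <- utils::read.csv(path)
  expect_equal(names(log), c("entity", "column", "layer", "step"))
  expect_equal(sum(log$entity == "spike"), 1L)
})
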