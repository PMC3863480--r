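test_that("construction gives the column architecture its structural constants", {
  net <- build_network(2, 2)
  expect_equal(net$m * net$n, 4L)                 # four delay neurons
  expect_equal(net$n, 2L)                         # two outputs
  expect_equal(net$thresholds, c(1L, 1L))         # signal paths minus one

  net9 <- build_network(9, 9)
  expect_equal(dim(net9$w_direct), c(9L, 9L))
  expect_true(all(net9$w_direct[, -1] == 0.5))    # trainable weights start 0.5
  expect_true(all(net9$w_direct[, 1] == 1))       # input layer clamped direct
  expect_equal(net9$temperatures, rep(1.0, 9))
  expect_equal(net9$thresholds, rep(8L, 9))

  tiny <- build_network(1, 1)
  expect_equal(tiny$thresholds, 0L)
  expect_true(is_converged(tiny))                 # nothing trainable
})

test_that("antagonistic weights are complementary after every operation", {
  net <- build_network(4, 4)
  expect_equal(net$w_direct + w_delay(net), matrix(1, 4, 4))
  net <- set_binary_config(net, matrix(c(rep(1, 4), rep(c(1, 0), 6)), nrow = 4))
  expect_equal(net$w_direct + w_delay(net), matrix(1, 4, 4))
  path <- withr::local_tempfile(fileext = ".json")
  save_network(net, path)
  back <- load_network(path)
  expect_equal(back$w_direct + w_delay(back), matrix(1, 4, 4))
})

test_that("binary configurations are imposed, read back, and guarded", {
  net <- build_network(3, 3)
  bits <- matrix(c(1, 1, 1, 0, 1, 0, 1, 0, 1), nrow = 3)
  net <- set_binary_config(net, bits)
  expect_equal(binary_config(net), matrix(as.integer(bits), nrow = 3))
  expect_true(is_converged(net))

  expect_error(set_binary_config(net, bits[, 1:2]), "3 x 3")
  bad <- bits; bad[2, 1] <- 0
  expect_error(set_binary_config(net, bad), "clamped")
  expect_error(set_binary_config(net, bits * 0.5), "binary")
})

test_that("convergence detection distinguishes fresh, binary and single-violator nets", {
  expect_false(is_converged(build_network(3, 3)))
  expect_true(is_converged(minimal_circuit_net()))
  net <- minimal_circuit_net()
  net$w_direct[1, 2] <- 0.5
  expect_false(is_converged(net))
})

test_that("networks round trip through JSON field by field", {
  net <- build_network(3, 4, network_config(seed = 11))
  net$w_direct[2, 3] <- 1 / 3   # non-representable decimal must survive
  net$temperatures[2] <- 0.123456789012345
  path <- withr::local_tempfile(fileext = ".json")
  save_network(net, path)
  back <- load_network(path)
  expect_identical(back$w_direct, net$w_direct)
  expect_identical(back$temperatures, net$temperatures)
  expect_identical(back$thresholds, net$thresholds)
  expect_equal(unclass(back$config), unclass(net$config))
})

test_that("truncated or foreign documents are rejected with a parse error", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"format": "columnhough-network", "version": 1,', path)
  expect_error(load_network(path), "parse")
  writeLines('{"something": "else"}', path)
  expect_error(load_network(path), "not a columnhough network")
})

test_that("a run resumed from a saved mid-training network matches the uninterrupted trajectory", {
  pats <- two_electrode_set()
  cfg <- network_config(seed = 7)
  full <- train(build_network(2, 2, cfg), pats)
  half <- train(build_network(2, 2, cfg), pats, max_presentations = 500)
  expect_false(half$converged)
  path <- withr::local_tempfile(fileext = ".json")
  save_network(half$network, path)
  resumed <- train(load_network(path), pats)
  expect_identical(resumed$network$w_direct, full$network$w_direct)
  expect_identical(resumed$network$temperatures, full$network$temperatures)
  expect_equal(resumed$presentations_used, full$presentations_used)
})

test_that("tidy and glance expose segments and summary in broom form", {
  net <- minimal_circuit_net()
  td <- tidy(net)
  expect_equal(nrow(td), 4L)
  expect_true(all(td$clamped[td$layer == 0]))
  expect_equal(td$w_direct + td$w_delay, rep(1, 4))
  gl <- glance(net)
  expect_equal(gl$n_delay_neurons, 4L)
  expect_true(gl$converged)
})
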