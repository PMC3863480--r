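# shared fixtures, built in code

# the unique feasible 2x2 configuration: delay at (column 1, layer 1)
minimal_circuit_bits <- function() matrix(c(1, 1, 1, 0), nrow = 2)

minimal_circuit_net <- function(config = network_config()) {
  set_binary_config(build_network(2, 2, config), minimal_circuit_bits())
}

analytic_nine_net <- function(config = network_config()) {
  set_binary_config(build_network(9, 9, config),
                    analytic_config(nine_bar_set(), config))
}

all_direct_bits <- function(m, n) matrix(1L, nrow = m, ncol = n)
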