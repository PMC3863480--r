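# columnhough

Cycle-accurate simulation of a self-structuring cortical-column delay-line
network: a feedforward spiking circuit that learns, from repetitively
presented spatiotemporal bar (or sinusoid) stimuli, to fire one
orientation-selective feature neuron per pattern class — a neural
realisation of a Hough transform from pixel space-time to an ordered
feature axis. It is written for computational neuroscientists studying
timing-based microcircuit plasticity and for experimenters designing
microelectrode-array (MEA) stimulation protocols that probe whether
cultured networks can assemble such circuits.

## The model in brief

`m` input neurons feed `m` parallel columns, each a chain of `n` block
segments. In every segment the path bifurcates into a direct branch
(1 clock step) and a delay branch (2 clock steps), controlled by
antagonistic weights `w_direct + w_delay = 1`. Output neuron `k` listens
behind segment layer `k` with threshold `m − 1`: it spikes only on a
planar wave front, the simultaneous arrival of all `m` column signals.
During training, path choice is stochastic with Boltzmann probability

    P_direct = e^(w_direct/T) / (e^(w_direct/T) + e^(w_delay/T)),

and any output spike reinforces, on its own layer, the paths actually
taken:

    w_sel ← w_sel + (1 − w_sel)·α,   w_desel ← w_desel − w_desel·α,

while annealing that layer's temperature `T` by `δT` down to `T_min`.
Weights binarize into gating switches; the converged configuration equals
the analytically derivable one in which each column's cumulative delay
count compensates the stimulus onset skew (`analytic_config()`), and — for
small networks — can be checked against exhaustive enumeration
(`brute_force_configs()`).

## Worked example

Train the minimal microcircuit — two input neurons, four delay neurons,
two output neurons — on the two-electrode stimulus pair (`V`: both
channels at t0; `D`: channel 2 at t0, channel 1 at t1):

```r
library(columnhough)
pats <- two_electrode_set()
res <- train(build_network(2, 2, network_config(seed = 42)), pats)
glance(res)
#> # A tibble: 1 × 6
#>   converged presentations_used n_spikes temp_min temp_max alpha
#>   <lgl>                  <int>    <int>    <dbl>    <dbl> <dbl>
#> 1 TRUE                    1572     1405     0.05     0.05  0.01

truth_table(res$network)[, c("stimulus", "target_fired", "off_target_fired", "correct")]
#> # A tibble: 2 × 4
#>   stimulus target_fired off_target_fired correct
#>   <chr>    <lgl>        <lgl>            <lgl>
#> 1 V        TRUE         FALSE            TRUE
#> 2 D        TRUE         FALSE            TRUE

binary_config(res$network)   # delay at column 1, layer 1 — the unique solution
#>      [,1] [,2]
#> [1,]    1    1
#> [2,]    1    0
```

The run converged after 1,572 presentations and reproduces the target
truth table: simultaneous input fires output 0, staggered input fires
output 1, with no off-target spikes. The learned configuration routes the
leading channel through its delay neuron so both signals coincide one
layer deeper.

The full-size analytic network classifies all nine bar slopes perfectly:

```r
bars <- nine_bar_set()
net9 <- set_binary_config(build_network(9, 9), analytic_config(bars))
glance(discriminate(net9, bars))
#> # A tibble: 1 × 4
#>   accuracy n_presentations n_none n_ambiguous
#>      <dbl>           <int>  <int>       <int>
#> 1        1               9      0           0
```

Export the stimulation timeline for an MEA session (channel, absolute
time in ms, pattern, repetition):

```r
write_mea_protocol(mea_protocol(pats, inter_pattern_gap = 10,
                                repetitions = 100, clock_ms = 1),
                   "protocol")
```

A thin command-line wrapper over these functions ships in
`inst/cli/columnhough.R` (`generate`, `train`, `oracle`, `verify`,
`discriminate`, `truth-table`, `export-protocol`).

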