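#' Boltzmann path-selection probability
#'
#' Probability that a signal takes the direct path at a bifurcation with
#' antagonistic weights `(w_direct, w_delay)` at Boltzmann temperature `T`:
#' `exp(w_direct / T) / (exp(w_direct / T) + exp(w_delay / T))`. High `T`
#' makes the choice near-random; as `T -> 0` the choice becomes the
#' indicator of the larger weight. Vectorized over all arguments.
#'
#' @param w_direct,w_delay Antagonistic weights in `[0, 1]`.
#' @param T_boltz Boltzmann temperature, > 0.
#' @return `P_direct` in `(0, 1)`; `P_delay = 1 - P_direct`.
#' @export
#' @examples
#' p_direct(0.5, 0.5, 1)    # 0.5 at symmetric weights, any T
#' p_direct(0.8, 0.2, 0.5)  # ~0.7685
p_direct <- function(w_direct, w_delay, T_boltz) {
  if (any(T_boltz <= 0)) abort_bad_arg("`T_boltz` must be > 0.")
  if (any(w_direct < 0 | w_direct > 1 | w_delay < 0 | w_delay > 1)) {
    abort_bad_arg("weights must lie in [0, 1].")
  }
  # logistic form of the two-state Boltzmann ratio; stable for small T
  stats::plogis((w_direct - w_delay) / T_boltz)
}

#' Sample a binary gating configuration for one presentation
#'
#' Draws one uniform random number per signal bifurcation and compares it
#' with the direct-path probability at the segment's layer temperature: the
#' delay path is taken iff the random number is greater than or equal to
#' `P_direct`. Input-layer segments are clamped direct.
#'
#' @param net A `delay_network`.
#' @return A `gating_sample`: an `m x n` binary matrix (1 = direct,
#'   0 = delay) with attribute `class`.
#' @export
sample_gating <- function(net) {
  stopifnot(inherits(net, "delay_network"))
  p <- p_direct(net$w_direct, 1 - net$w_direct,
                matrix(net$temperatures, nrow = net$m, ncol = net$n, byrow = TRUE))
  u <- matrix(stats::runif(net$m * net$n), nrow = net$m)
  g <- matrix(as.integer(u < p), nrow = net$m)   # u >= P_direct -> delay
  g[, 1L] <- 1L                                  # input layer clamp
  structure(g, class = c("gating_sample", class(g)))
}

# Junction arrival times for each event at each layer.
# gating: m x n binary (1 = direct); events: list(input0, step0) 0-based ints.
# Returns E x n matrix: arrival clock step of event e at the layer-(l-1)
# junction, i.e. step + l + (number of delay choices among layers 0..l-1).
.arrivals <- function(gating, input0, step0) {
  n <- ncol(gating)
  cum_delay <- t(apply(1L - gating, 1L, cumsum))   # m x n
  if (n == 1L) cum_delay <- matrix(cum_delay, ncol = 1L)
  outer(step0, seq_len(n), `+`) + cum_delay[input0 + 1L, , drop = FALSE]
}

# Earliest coincidence per layer: first clock step at which more than
# `thresholds[l]` distinct columns hold a signal at layer l. NA if never.
.spike_times <- function(arrivals, input0, thresholds) {
  n <- ncol(arrivals)
  out <- rep(NA_integer_, n)
  for (l in seq_len(n)) {
    times <- arrivals[, l]
    for (s in sort(unique(times))) {
      if (length(unique(input0[times == s])) > thresholds[l]) {
        out[l] <- s
        break
      }
    }
  }
  out
}

#' Propagate a stimulus pattern under a fixed gating sample
#'
#' Integer-clock wave-front propagation: each stimulus event injects a
#' signal into its column at its event time; the signal transits each block
#' segment in 1 clock step on the direct path or 2 on the delay path
#' (the delay neuron adds exactly one clock step). Output neuron `k`
#' observes the junction behind segment layer `k` and spikes at the first
#' clock step at which more than `thresholds[k]` distinct columns hold a
#' signal there (at the default threshold `m - 1`: a full planar wave
#' front). At most one spike per output per presentation; signals in
#' ablated columns are never injected.
#'
#' @param net A `delay_network`.
#' @param gating A [sample_gating()] matrix, or `NULL` to use the network's
#'   rounded binary configuration (requires a binarized network).
#' @param pattern A [stim_pattern()] with `width == net$m`.
#' @return A `propagation_trace`: list with `occupancy` (tibble `step`,
#'   `column`, `layer` — the segment each signal occupies at each clock
#'   step), `spikes` (tibble `output`, `step`), `first_input_step`, and the
#'   dimensions.
#' @export
propagate <- function(net, gating = NULL, pattern) {
  stopifnot(inherits(net, "delay_network"), inherits(pattern, "stim_pattern"))
  if (pattern$width != net$m) {
    abort_bad_arg(sprintf("pattern width %d does not match network m = %d.",
                          pattern$width, net$m))
  }
  if (is.null(gating)) {
    if (!is_converged(net, tol = 0.5 - 1e-9)) {
      abort_bad_arg("no gating sample given and network weights are not binarized.")
    }
    gating <- binary_config(net)
    gating[, 1L] <- 1L
  }
  if (!all(dim(gating) == c(net$m, net$n))) {
    abort_bad_arg("gating dimensions do not match the network.")
  }

  ev <- pattern$events
  if (length(net$ablated)) ev <- ev[!(ev$input %in% net$ablated), , drop = FALSE]
  empty <- nrow(ev) == 0L
  if (empty) {
    return(structure(list(
      occupancy = tibble::tibble(step = integer(), column = integer(), layer = integer()),
      spikes = tibble::tibble(output = integer(), step = integer()),
      first_input_step = NA_integer_, m = net$m, n = net$n
    ), class = "propagation_trace"))
  }

  arr <- .arrivals(gating, ev$input, ev$step)
  st <- .spike_times(arr, ev$input, net$thresholds)

  # occupancy: signal from event e sits in segment layer l-1 from its entry
  # (arrival at the previous junction; the event time for layer 0) until the
  # step before its arrival at junction l-1
  entries <- cbind(ev$step, arr[, -ncol(arr), drop = FALSE])
  occ <- purrr::map_dfr(seq_len(nrow(ev)), function(e) {
    purrr::map_dfr(seq_len(net$n), function(l) {
      tibble::tibble(step = seq.int(entries[e, l], arr[e, l] - 1L),
                     column = ev$input[e], layer = l - 1L)
    })
  })

  spikes <- tibble::tibble(output = which(!is.na(st)) - 1L,
                           step = as.integer(st[!is.na(st)]))
  structure(list(
    occupancy = dplyr::arrange(occ, .data$step, .data$layer, .data$column),
    spikes = spikes,
    first_input_step = min(ev$step), m = net$m, n = net$n
  ), class = "propagation_trace")
}

#' @export
print.propagation_trace <- function(x, ...) {
  cat(sprintf("<propagation_trace> %d x %d net, %d signal-steps, %d output spike(s)\n",
              x$m, x$n, nrow(x$occupancy), nrow(x$spikes)))
  if (nrow(x$spikes)) print(x$spikes)
  invisible(x)
}

#' Decode the time-and-place code of a trace
#'
#' The identity (place) of the firing feature neuron and its spike time
#' relative to the first input event jointly signal the detected feature.
#' Multiple distinct firing outputs are reported as ambiguous, never
#' silently resolved; a silent trace decodes to none.
#'
#' @param trace A [propagate()] result.
#' @return A one-row tibble: `feature` (output index or `NA`), `rel_time`
#'   (spike step minus first input step, or `NA`), `status` (`"ok"`,
#'   `"none"` or `"ambiguous"`), `n_outputs_fired`.
#' @export
decode <- function(trace) {
  stopifnot(inherits(trace, "propagation_trace"))
  k <- nrow(trace$spikes)
  if (k == 0L) {
    return(tibble::tibble(feature = NA_integer_, rel_time = NA_integer_,
                          status = "none", n_outputs_fired = 0L))
  }
  if (k > 1L) {
    return(tibble::tibble(feature = NA_integer_, rel_time = NA_integer_,
                          status = "ambiguous", n_outputs_fired = k))
  }
  tibble::tibble(feature = trace$spikes$output[1L],
                 rel_time = trace$spikes$step[1L] - trace$first_input_step,
                 status = "ok", n_outputs_fired = 1L)
}

#' Export a trace as a flat CSV event log
#'
#' @param trace A [propagate()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "propagation_trace"))
  log <- dplyr::bind_rows(
    dplyr::mutate(trace$occupancy, entity = "signal", .before = 1L),
    tibble::tibble(entity = "spike", step = trace$spikes$step,
                   column = NA_integer_, layer = trace$spikes$output)
  )
  utils::write.csv(log[, c("entity", "column", "layer", "step")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot a propagation trace
#'
#' Space-time diagram of signal occupancy per column, with output spikes
#' overlaid at their layer.
#'
#' @param object A `propagation_trace`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.propagation_trace <- function(object, ...) {
  p <- ggplot2::ggplot(object$occupancy,
                       ggplot2::aes(x = .data$step, y = .data$layer)) +
    ggplot2::geom_tile(ggplot2::aes(fill = factor(.data$column)),
                       width = 0.9, height = 0.9, alpha = 0.7) +
    ggplot2::labs(x = "clock step", y = "segment layer", fill = "column") +
    ggplot2::theme_minimal()
  if (nrow(object$spikes)) {
    p <- p + ggplot2::geom_point(data = object$spikes,
                                 ggplot2::aes(x = .data$step, y = .data$output),
                                 shape = 8, size = 3, colour = "red")
  }
  p
}
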