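#' Training configuration
#'
#' Parameters of the Boltzmann-annealed stochastic learning process. Every
#' layer carries its own temperature, starting at `T_max` and lowered by
#' `delta_T` on each learning-triggering output spike down to the floor
#' `T_min`; `alpha` is the learning slope parameter of the complementary
#' weight update.
#'
#' @param T_max Starting Boltzmann temperature (> `T_min`).
#' @param T_min Temperature floor (> 0). At the floor, path selection is
#'   effectively deterministic once weights are near 0/1.
#' @param delta_T Temperature decrement per spike (> 0).
#' @param alpha Learning slope parameter in (0, 1): fraction of the distance
#'   to the bound moved per update. `alpha = 0` is accepted and disables
#'   learning (useful as a control).
#' @param seed RNG seed for path sampling and presentation shuffling.
#' @param max_presentations Presentation cap for training.
#' @param convergence_tol Weight distance from {0, 1} below which a weight
#'   counts as binarized; in (0, 0.5).
#'
#' @return A `network_config` list.
#' @export
network_config <- function(T_max = 1.0, T_min = 0.05, delta_T = 0.005,
                           alpha = 0.01, seed = 1L,
                           max_presentations = 100000L,
                           convergence_tol = 1e-3) {
  check_scalar_number(T_max, "T_max"); check_scalar_number(T_min, "T_min")
  check_scalar_number(delta_T, "delta_T"); check_scalar_number(alpha, "alpha")
  if (!(T_max > T_min && T_min > 0)) abort_bad_arg("need T_max > T_min > 0.")
  if (delta_T <= 0) abort_bad_arg("`delta_T` must be > 0.")
  if (alpha < 0 || alpha >= 1) abort_bad_arg("`alpha` must lie in [0, 1).")
  if (convergence_tol <= 0 || convergence_tol >= 0.5) {
    abort_bad_arg("`convergence_tol` must lie in (0, 0.5).")
  }
  structure(
    list(T_max = T_max, T_min = T_min, delta_T = delta_T, alpha = alpha,
         seed = as.integer(seed),
         max_presentations = check_count(max_presentations, "max_presentations", 1L),
         convergence_tol = convergence_tol),
    class = "network_config"
  )
}

#' Construct a cortical-column delay-line network
#'
#' The network has `m` input neurons feeding `m` parallel cortical columns,
#' each a chain of `n` block segments (one delay neuron per segment, hence
#' `m * n` delay neurons), and `n` output (feature classifier) neurons, one
#' per segment layer. In every segment the signal path bifurcates into a
#' direct path (1 clock step) and a delay path (2 clock steps), governed by
#' the antagonistic weight pair `(w_direct, w_delay)` with
#' `w_direct + w_delay = 1`.
#'
#' Trainable weights start at 0.5. The input layer (layer 0) is clamped
#' direct (`w_direct = 1`), wiring it straight to the first output neuron.
#' Synapses onto the output neurons are hardwired at weight 1. Output
#' thresholds default to the number of signal paths minus 1 (`m - 1`), so an
#' output spikes only on a full planar wave front; `threshold_offset` lowers
#' them uniformly for the noise-robust variant.
#'
#' @param m Number of input neurons / columns (>= 1).
#' @param n Number of segment layers / output neurons (>= 1).
#' @param config A [network_config()].
#' @param threshold_offset Non-positive integer added to the default
#'   thresholds.
#'
#' @return A `delay_network` object with fields `m`, `n`, `w_direct`
#'   (`m x n` matrix, columns = layers 0..n-1), `thresholds`, `temperatures`
#'   (per layer), `hardwired_output_weight` (fixed 1), `ablated` (columns
#'   silenced by [ablate_columns()]), and `config`.
#' @export
#' @examples
#' net <- build_network(2, 2)
#' net$thresholds   # both 1: number of signal paths minus one
build_network <- function(m, n, config = network_config(), threshold_offset = 0L) {
  m <- check_count(m, "m", min = 1L)
  n <- check_count(n, "n", min = 1L)
  stopifnot(inherits(config, "network_config"))
  threshold_offset <- check_count(-threshold_offset, "-threshold_offset", min = 0L) * -1L
  w <- matrix(0.5, nrow = m, ncol = n)
  w[, 1L] <- 1.0   # input layer clamp: direct to the first output neuron
  structure(
    list(m = m, n = n,
         w_direct = w,
         thresholds = rep.int(m - 1L + threshold_offset, n),
         temperatures = rep(config$T_max, n),
         hardwired_output_weight = 1,
         ablated = integer(0),
         config = config,
         rng_state = NULL),
    class = "delay_network"
  )
}

#' Antagonistic delay-path weights
#'
#' The delay weight is always the complement of the direct weight.
#'
#' @param net A `delay_network`.
#' @return `m x n` matrix `1 - w_direct`.
#' @export
w_delay <- function(net) {
  stopifnot(inherits(net, "delay_network"))
  1 - net$w_direct
}

#' @export
print.delay_network <- function(x, ...) {
  trainable <- x$w_direct[, -1L, drop = FALSE]
  cat(sprintf("<delay_network> %d columns x %d layers (%d delay neurons), %d outputs\n",
              x$m, x$n, x$m * x$n, x$n))
  cat(sprintf("  thresholds: %s; temperatures in [%.3g, %.3g]\n",
              paste(x$thresholds, collapse = ", "),
              min(x$temperatures), max(x$temperatures)))
  if (length(trainable)) {
    cat(sprintf("  trainable w_direct: mean %.3f, %d/%d binarized (tol %.1e)\n",
                mean(trainable),
                sum(pmin(trainable, 1 - trainable) <= x$config$convergence_tol),
                length(trainable), x$config$convergence_tol))
  }
  if (length(x$ablated)) cat("  ablated columns:", paste(x$ablated, collapse = ", "), "\n")
  invisible(x)
}

#' Impose a binary direct/delay configuration
#'
#' Converged weights act as gating switches: 1 opens the direct path, 0
#' routes through the delay neuron. This sets every segment to a hard
#' binary choice, making propagation deterministic.
#'
#' @param net A `delay_network`.
#' @param bits `m x n` binary matrix (1 = direct, 0 = delay). The input
#'   layer (first column) must be all 1.
#' @return The modified network.
#' @export
set_binary_config <- function(net, bits) {
  stopifnot(inherits(net, "delay_network"))
  bits <- as.matrix(bits)
  if (!all(dim(bits) == c(net$m, net$n))) {
    abort_bad_arg(sprintf("`bits` must be a %d x %d matrix.", net$m, net$n))
  }
  if (!all(bits %in% c(0, 1))) abort_bad_arg("`bits` must be binary.")
  if (any(bits[, 1L] != 1)) {
    abort_bad_arg("input-layer segments (first column of `bits`) are clamped direct and cannot be set to delay.")
  }
  net$w_direct <- matrix(as.numeric(bits), nrow = net$m)
  net
}

#' Read the rounded binary configuration of a network
#'
#' @param net A `delay_network`.
#' @return `m x n` integer matrix: 1 where `w_direct > 0.5`.
#' @export
binary_config <- function(net) {
  stopifnot(inherits(net, "delay_network"))
  matrix(as.integer(net$w_direct > 0.5), nrow = net$m)
}

#' Is every trainable weight binarized?
#'
#' @param net A `delay_network`.
#' @param tol Distance from {0, 1} tolerated; defaults to the network
#'   config's `convergence_tol`.
#' @return Logical flag.
#' @export
is_converged <- function(net, tol = net$config$convergence_tol) {
  stopifnot(inherits(net, "delay_network"))
  w <- net$w_direct[, -1L, drop = FALSE]   # input layer is clamped, not trainable
  if (length(w) == 0) return(TRUE)
  all(pmin(w, 1 - w) <= tol)
}

#' Save / load a network as a versioned JSON document
#'
#' Round trips all weights, temperatures, thresholds, ablations, the
#' training configuration and the RNG state, so that a training run resumed
#' from a saved mid-training network reproduces the uninterrupted
#' trajectory bit for bit.
#'
#' @param net A `delay_network`.
#' @param path File path.
#' @return `save_network()` returns `path` invisibly; `load_network()`
#'   returns the restored `delay_network`.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "delay_network"))
  doc <- list(
    format = "columnhough-network", version = 1L,
    m = net$m, n = net$n,
    w_direct = net$w_direct,
    thresholds = net$thresholds,
    temperatures = net$temperatures,
    ablated = net$ablated,
    presentations_done = net$presentations_done,
    config = unclass(net$config),
    rng_state = net$rng_state
  )
  # I(17) significant digits: bit-exact double round trip
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) abort_bad_arg(
                    sprintf("cannot parse network document '%s': %s", path, conditionMessage(e))))
  if (is.null(doc$format) || doc$format != "columnhough-network") {
    abort_bad_arg("not a columnhough network document.")
  }
  if (is.null(doc$version) || doc$version != 1L) {
    abort_bad_arg(sprintf("unsupported network document version: %s", format(doc$version)))
  }
  cfg <- do.call(network_config, as.list(doc$config))
  net <- build_network(doc$m, doc$n, cfg)
  net$w_direct <- matrix(doc$w_direct, nrow = doc$m, ncol = doc$n)
  net$thresholds <- as.integer(doc$thresholds)
  net$temperatures <- as.numeric(doc$temperatures)
  net$ablated <- as.integer(doc$ablated)
  if (!is.null(doc$presentations_done)) {
    net$presentations_done <- as.integer(doc$presentations_done)
  }
  if (!is.null(doc$rng_state) && length(doc$rng_state)) {
    net$rng_state <- as.integer(doc$rng_state)
  }
  net
}

#' Tidy the segment weights of a network
#'
#' One row per block segment, broom style.
#'
#' @param x A `delay_network`.
#' @param ... Ignored.
#' @return A tibble with columns `column`, `layer` (both 0-based),
#'   `w_direct`, `w_delay`, `clamped`, `binarized`.
#' @export
tidy.delay_network <- function(x, ...) {
  tibble::tibble(
    column = rep(seq_len(x$m) - 1L, times = x$n),
    layer = rep(seq_len(x$n) - 1L, each = x$m),
    w_direct = as.vector(x$w_direct),
    w_delay = as.vector(1 - x$w_direct)
  ) |>
    dplyr::mutate(
      clamped = .data$layer == 0L,
      binarized = pmin(.data$w_direct, .data$w_delay) <= x$config$convergence_tol
    )
}

#' One-row network summary
#'
#' @param x A `delay_network`.
#' @param ... Ignored.
#' @return A one-row tibble: dimensions, delay-neuron count, fraction of
#'   trainable weights binarized, temperature range, convergence flag.
#' @export
glance.delay_network <- function(x, ...) {
  w <- x$w_direct[, -1L, drop = FALSE]
  tibble::tibble(
    m = x$m, n = x$n, n_delay_neurons = x$m * x$n, n_outputs = x$n,
    frac_binarized = if (length(w)) mean(pmin(w, 1 - w) <= x$config$convergence_tol) else 1,
    temp_min = min(x$temperatures), temp_max = max(x$temperatures),
    converged = is_converged(x)
  )
}

#' Heatmap of direct-path weights
#'
#' @param object A `delay_network`.
#' @param ... Ignored.
#' @return A ggplot object; columns on x, layers on y, fill = `w_direct`.
#' @export
autoplot.delay_network <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$column, y = .data$layer,
                               fill = .data$w_direct)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "grey85",
                                  high = "#2166ac", midpoint = 0.5,
                                  limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "segment layer", fill = "w_direct") +
    ggplot2::theme_minimal()
}
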