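#' Perturb a stimulus pattern with timing jitter and event dropout
#'
#' Noise model for robustness studies: each event's time step is shifted by
#' an independent uniform integer in `[-jitter_steps, +jitter_steps]`
#' (clipped to the pattern duration) and then deleted with probability
#' `dropout_prob`. Deterministic under a fixed RNG state (set `seed`, or
#' seed the session RNG).
#'
#' @param pattern A [stim_pattern()].
#' @param jitter_steps Maximum absolute timing shift, >= 0 (default 0).
#' @param dropout_prob Per-event deletion probability in `[0, 1]`.
#' @param seed Optional integer seed applied before drawing.
#' @return A perturbed [stim_pattern()] with the same width and duration.
#' @export
perturb_pattern <- function(pattern, jitter_steps = 0L, dropout_prob = 0,
                            seed = NULL) {
  stopifnot(inherits(pattern, "stim_pattern"))
  jitter_steps <- check_count(jitter_steps, "jitter_steps", min = 0L)
  check_scalar_number(dropout_prob, "dropout_prob")
  if (dropout_prob < 0 || dropout_prob > 1) {
    abort_bad_arg("`dropout_prob` must lie in [0, 1].")
  }
  if (!is.null(seed)) set.seed(seed)

  ev <- pattern$events
  n_ev <- nrow(ev)
  if (n_ev > 0 && jitter_steps > 0) {
    shift <- sample.int(2L * jitter_steps + 1L, n_ev, replace = TRUE) -
      jitter_steps - 1L
    ev$step <- pmin(pmax(ev$step + shift, 0L), pattern$duration - 1L)
  }
  if (n_ev > 0 && dropout_prob > 0) {
    ev <- ev[stats::runif(n_ev) >= dropout_prob, , drop = FALSE]
  }
  stim_pattern(ev, width = pattern$width, duration = pattern$duration,
               label = pattern$label, kind = pattern$kind)
}

#' Ablate delay-line columns
#'
#' Models the complete loss of whole delay lines: signals are never injected
#' into ablated columns. Stored weights are untouched — only signal
#' injection (and, optionally, output thresholds) change. Lowered thresholds
#' let the remaining columns still reach coincidence.
#'
#' @param net A `delay_network`.
#' @param columns 0-based column indices to silence; must leave at least one
#'   intact column.
#' @param threshold_offset Non-positive integer added to all output
#'   thresholds (e.g. `-1` tolerates one missing signal path).
#' @return The modified network.
#' @export
ablate_columns <- function(net, columns, threshold_offset = 0L) {
  stopifnot(inherits(net, "delay_network"))
  columns <- unique(as.integer(columns))
  if (length(columns) && (min(columns) < 0L || max(columns) >= net$m)) {
    abort_bad_arg(sprintf("`columns` must lie in [0, %d].", net$m - 1L))
  }
  if (length(union(net$ablated, columns)) >= net$m) {
    abort_bad_arg("cannot ablate every column of the network.")
  }
  if (threshold_offset > 0L) abort_bad_arg("`threshold_offset` must be <= 0.")
  net$ablated <- sort(union(net$ablated, columns))
  net$thresholds <- as.integer(net$thresholds + threshold_offset)
  net
}
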