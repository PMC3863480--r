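#' Analytic delay configuration for a bar pattern set
#'
#' Derives the binary direct/delay configuration under which every training
#' pattern produces a planar wave front exactly at its own output layer —
#' the deterministic end state the learning process discovers. The
#' alignment condition: for pattern `k`, the cumulative delay count of
#' column `i` over layers `1..k` must equal the onset skew of the pattern at
#' column `i` (`max onset - onset_i`), so all `m` signals coincide at layer
#' `k`. The per-layer delay bit is the increment of that cumulative
#' requirement between consecutive classes; an increment outside {0, 1}
#' means the skew cannot be compensated within one layer and is reported as
#' infeasible. Off the target layer the differing per-column velocities make
#' the front dissolve, which is verified by propagation before returning.
#'
#' This places each column's delays in the earliest layers consistent with
#' the class sequence (the canonical member of the feasible set).
#'
#' @param patterns A [pattern_set()] with exactly one event per column per
#'   pattern (bar-like patterns) and one class per layer.
#' @param config A [network_config()] for the returned network's metadata.
#' @return An `m x n` binary matrix (1 = direct, 0 = delay), input-layer
#'   column all 1, suitable for [set_binary_config()].
#' @export
#' @examples
#' analytic_config(two_electrode_set())
analytic_config <- function(patterns, config = network_config()) {
  stopifnot(inherits(patterns, "pattern_set"))
  m <- patterns$width
  n <- length(patterns$patterns)

  onsets <- matrix(NA_integer_, nrow = m, ncol = n)  # onset of column i in pattern k
  for (k in seq_len(n)) {
    ev <- patterns$patterns[[k]]$events
    if (nrow(ev) != m || anyDuplicated(ev$input)) {
      abort_bad_arg(sprintf(
        "pattern %d must activate every column exactly once for the analytic construction.",
        k - 1L))
    }
    onsets[ev$input + 1L, k] <- ev$step
  }

  # required cumulative delays D[i, k]: all signals of pattern k coincide at
  # layer k iff onset_i + D_i is constant; normalise to the latest onset
  D <- matrix(rep(apply(onsets, 2L, max), each = m) - onsets, nrow = m)
  if (any(D[, 1L] != 0L)) {
    bad <- which(D[, 1L] != 0L)[1L]
    abort_bad_arg(sprintf(
      "pattern 0 has onset skew at column %d but the input layer is clamped direct.",
      bad - 1L))
  }
  bits <- matrix(1L, nrow = m, ncol = n)
  if (n > 1L) {
    inc <- D[, -1L, drop = FALSE] - D[, -n, drop = FALSE]
    if (any(inc < 0L | inc > 1L)) {
      idx <- which(inc < 0L | inc > 1L, arr.ind = TRUE)[1L, ]
      abort_bad_arg(sprintf(
        "infeasible skew: column %d needs a delay increment of %d at layer %d.",
        idx[1L] - 1L, inc[idx[1L], idx[2L]], idx[2L]))
    }
    bits[, -1L] <- 1L - inc
  }

  # verify by propagation: every class must decode to its own output
  rep_ok <- verify_config(bits, patterns, config = config)
  if (!attr(rep_ok, "pass")) {
    abort_bad_arg("analytic construction failed propagation verification.")
  }
  bits
}

#' Enumerate all feasible binary configurations by brute force
#'
#' Exhaustively enumerates every admissible binary direct/delay
#' configuration of an `m x n` network (input layer clamped direct, so
#' `2^(m*(n-1))` candidates), propagates every training pattern under each,
#' and keeps the configurations under which each pattern `k` fires exactly
#' its own output `k` and nothing else. This is the independent reference
#' for both the analytic construction and learned configurations.
#'
#' @param patterns A [pattern_set()]; `m * (n - 1)` must not exceed
#'   `max_bits`.
#' @param config A [network_config()].
#' @param max_bits Enumeration bound (default 12, i.e. 4096 candidates).
#' @return A `feasible_set`: list with `configs` (list of `m x n` binary
#'   matrices), `m`, `n`, `n_candidates`.
#' @export
brute_force_configs <- function(patterns, config = network_config(),
                                max_bits = 12L) {
  stopifnot(inherits(patterns, "pattern_set"))
  m <- patterns$width
  n <- length(patterns$patterns)
  n_free <- m * (n - 1L)
  if (n_free > max_bits) {
    abort_bad_arg(sprintf(
      "enumeration bound exceeded: %d free segments > %d.", n_free, max_bits))
  }
  thresholds <- rep.int(m - 1L, n)
  ev_in <- lapply(patterns$patterns, function(p) p$events$input)
  ev_st <- lapply(patterns$patterns, function(p) p$events$step)
  keep <- list()
  for (code in seq_len(2^n_free) - 1L) {
    bits <- matrix(1L, nrow = m, ncol = n)
    if (n_free > 0L) {
      bits[, -1L] <- as.integer(bitwAnd(code %/% 2^(seq_len(n_free) - 1L), 1L))
    }
    ok <- TRUE
    for (k in seq_len(n)) {
      arr <- .arrivals(bits, ev_in[[k]], ev_st[[k]])
      st <- .spike_times(arr, ev_in[[k]], thresholds)
      if (!(sum(!is.na(st)) == 1L && !is.na(st[k]))) {
        ok <- FALSE
        break
      }
    }
    if (ok) keep[[length(keep) + 1L]] <- bits
  }
  structure(list(configs = keep, m = m, n = n, n_candidates = 2^n_free),
            class = "feasible_set")
}

#' @export
print.feasible_set <- function(x, ...) {
  cat(sprintf("<feasible_set> %d of %d candidate %d x %d configurations feasible\n",
              length(x$configs), x$n_candidates, x$m, x$n))
  invisible(x)
}

#' Is a configuration a member of a feasible set?
#'
#' @param set A [brute_force_configs()] result.
#' @param bits An `m x n` binary matrix.
#' @return Logical flag.
#' @export
in_feasible_set <- function(set, bits) {
  stopifnot(inherits(set, "feasible_set"))
  any(vapply(set$configs, function(b) all(b == bits), logical(1)))
}

#' Verify a binary configuration against a pattern set
#'
#' Propagates every pattern under the deterministic configuration and
#' decodes the result; the configuration passes iff pattern `k` decodes to
#' output `k` with exactly one spike, for every class.
#'
#' @param bits An `m x n` binary matrix, or a binarized `delay_network`.
#' @param patterns A [pattern_set()].
#' @param config A [network_config()] (ignored when `bits` is a network).
#' @return A tibble with one row per class: `class`, `label`, `decoded`,
#'   `rel_time`, `status`, `correct`; attribute `"pass"` is `TRUE` iff all
#'   classes are correct.
#' @export
verify_config <- function(bits, patterns, config = network_config()) {
  stopifnot(inherits(patterns, "pattern_set"))
  if (inherits(bits, "delay_network")) {
    net <- bits
    gating <- binary_config(net)
    gating[, 1L] <- 1L
  } else {
    gating <- as.matrix(bits)
    net <- set_binary_config(
      build_network(nrow(gating), ncol(gating), config), gating)
  }
  rows <- purrr::map_dfr(seq_along(patterns$patterns), function(k) {
    d <- decode(propagate(net, gating = gating,
                          pattern = patterns$patterns[[k]]))
    tibble::tibble(class = k - 1L, label = patterns$patterns[[k]]$label,
                   decoded = d$feature, rel_time = d$rel_time,
                   status = d$status)
  })
  rows$correct <- !is.na(rows$decoded) & rows$decoded == rows$class &
    rows$status == "ok"
  attr(rows, "pass") <- all(rows$correct)
  rows
}
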