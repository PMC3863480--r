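#' Discrimination test of a network on a pattern set
#'
#' Presents each pattern `repetitions` times, decodes the time-and-place
#' code, and tallies a confusion table. A fully binarized network propagates
#' deterministically; otherwise each presentation samples a fresh gating
#' configuration at the current layer temperatures. No-spike and ambiguous
#' outcomes are first-class categories, never coerced to a class.
#'
#' @param net A `delay_network`.
#' @param patterns A [pattern_set()] with `width == net$m`.
#' @param repetitions Presentations per pattern (default 1).
#' @param shuffle Present patterns in seeded random order (the "random test
#'   set" protocol); order does not affect per-pattern outcomes, only the
#'   log.
#' @return A `discrimination_report`: list with `confusion` (tibble: `class`,
#'   `decoded` — output index, `"none"` or `"ambiguous"` —, `n`), `accuracy`
#'   (fraction of presentations decoded to their own class), `outcomes`
#'   (tibble of every presentation: `class`, `rep`, `feature`, `rel_time`,
#'   `status`, `correct`).
#' @export
discriminate <- function(net, patterns, repetitions = 1L, shuffle = FALSE) {
  stopifnot(inherits(net, "delay_network"), inherits(patterns, "pattern_set"))
  repetitions <- check_count(repetitions, "repetitions", min = 1L)
  deterministic <- is_converged(net, tol = net$config$convergence_tol)

  jobs <- tidyr::expand_grid(class = seq_along(patterns$patterns) - 1L,
                             rep = seq_len(repetitions) - 1L)
  if (shuffle) jobs <- jobs[sample.int(nrow(jobs)), ]

  outcomes <- purrr::map_dfr(seq_len(nrow(jobs)), function(r) {
    k <- jobs$class[r]
    gating <- if (deterministic) NULL else sample_gating(net)
    d <- decode(propagate(net, gating = gating,
                          pattern = patterns$patterns[[k + 1L]]))
    dplyr::mutate(d, class = k, rep = jobs$rep[r], .before = 1L)
  })
  outcomes$correct <- outcomes$status == "ok" &
    !is.na(outcomes$feature) & outcomes$feature == outcomes$class

  confusion <- outcomes |>
    dplyr::mutate(decoded = dplyr::case_when(
      .data$status == "none" ~ "none",
      .data$status == "ambiguous" ~ "ambiguous",
      TRUE ~ as.character(.data$feature)
    )) |>
    dplyr::count(.data$class, .data$decoded, name = "n")

  structure(list(confusion = confusion,
                 accuracy = mean(outcomes$correct),
                 outcomes = outcomes,
                 repetitions = repetitions),
            class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat(sprintf("<discrimination_report> accuracy %.3f over %d presentations\n",
              x$accuracy, nrow(x$outcomes)))
  print(x$confusion)
  invisible(x)
}

#' @export
tidy.discrimination_report <- function(x, ...) x$confusion

#' @export
glance.discrimination_report <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy,
    n_presentations = nrow(x$outcomes),
    n_none = sum(x$outcomes$status == "none"),
    n_ambiguous = sum(x$outcomes$status == "ambiguous")
  )
}

#' Confusion heatmap of a discrimination report
#'
#' @param object A `discrimination_report`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.discrimination_report <- function(object, ...) {
  ggplot2::ggplot(object$confusion,
                  ggplot2::aes(x = .data$decoded, y = factor(.data$class),
                               fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::labs(x = "decoded", y = "true class", fill = "count") +
    ggplot2::theme_minimal()
}

#' Truth table of the minimal two-column microcircuit
#'
#' Evaluates the 2 x 2 network (two input neurons, four delay neurons, two
#' output neurons) on the two-electrode stimulus pair: the circuit realises
#' the mapping "both channels at t0 fires output 0; channel 2 at t0 then
#' channel 1 at t1 fires output 1". Off-target firing is reported, never
#' raised.
#'
#' @param net A binarized `delay_network` with `m = n = 2`.
#' @return A tibble with one row per stimulus: `stimulus` (`"V"`, `"D"`),
#'   `expected_output`, `fired_outputs` (list column), `target_fired`,
#'   `off_target_fired`, `correct`.
#' @export
truth_table <- function(net) {
  stopifnot(inherits(net, "delay_network"))
  if (net$m != 2L || net$n != 2L) {
    abort_bad_arg("truth_table() requires the minimal 2 x 2 microcircuit.")
  }
  pats <- two_electrode_set()
  purrr::map_dfr(1:2, function(k) {
    tr <- propagate(net, pattern = pats$patterns[[k]])
    fired <- tr$spikes$output
    tibble::tibble(
      stimulus = c("V", "D")[k],
      expected_output = k - 1L,
      fired_outputs = list(fired),
      target_fired = (k - 1L) %in% fired,
      off_target_fired = any(fired != k - 1L),
      correct = identical(fired, k - 1L)
    )
  })
}

#' Convergence diagnostics of a training run
#'
#' Summarises when each layer settled, the final temperatures, and — when
#' the weight trajectory was recorded for a 2 x 2 network — the presentation
#' index at which the rounded configuration's truth table first became
#' stable (first presentation from which the rounded binary configuration
#' classifies both minimal-circuit stimuli correctly and never changes
#' again).
#'
#' @param result A [train()] result.
#' @return A list with `per_layer` (tibble: layer, convergence iteration,
#'   spike count, final temperature), `presentations_used`, `converged`,
#'   and `truth_table_stable_at` (presentation index, or `NA` when not
#'   applicable).
#' @export
convergence_report <- function(result) {
  stopifnot(inherits(result, "training_result"))
  net <- result$network
  stable_at <- NA_integer_

  if (!is.null(result$weight_history) && net$m == 2L && net$n == 2L &&
      result$converged) {
    wh <- result$weight_history            # columns c0_l1, c1_l1
    final_bits <- as.integer(net$w_direct[, 2L] > 0.5)
    bits_hist <- (wh > 0.5) * 1L
    same <- bits_hist[, 1L] == final_bits[1L] & bits_hist[, 2L] == final_bits[2L]
    # last presentation at which the rounded config still differed
    last_diff <- if (all(same)) 0L else max(which(!same))
    offset <- result$presentations_used - nrow(wh)
    stable_at <- as.integer(offset + last_diff + 1L)
  }

  list(per_layer = tidy(result),
       presentations_used = result$presentations_used,
       converged = result$converged,
       truth_table_stable_at = stable_at)
}
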