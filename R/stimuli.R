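#' Spatiotemporal stimulus patterns
#'
#' A stimulus pattern is a binary image of `width` input channels by
#' `duration` clock steps, presented row-serially: at each integer clock step
#' the active pixels of one image row are applied in parallel to the input
#' layer. Internally it is stored as an event list, one `(input, step)` pair
#' per active cell (0-based indices), sorted by `(step, input)`.
#'
#' @param events A data frame with integer columns `input` and `step`.
#' @param width Number of input channels (m).
#' @param duration Number of clock steps spanned by the pattern.
#' @param label Pattern class label (slope in degrees for bars,
#'   cycles-per-grid for sinusoids).
#' @param kind Pattern kind, e.g. `"bar"` or `"sinusoid"`.
#'
#' @return A `stim_pattern` object: a list with fields `width`, `duration`,
#'   `events` (tibble), `label` and `kind`.
#' @export
stim_pattern <- function(events, width, duration, label = NA_real_, kind = "custom") {
  width <- check_count(width, "width", min = 1L)
  duration <- check_count(duration, "duration", min = 1L)
  events <- tibble::as_tibble(events)
  if (!all(c("input", "step") %in% names(events))) {
    abort_bad_arg("`events` must have columns `input` and `step`.")
  }
  events$input <- as.integer(events$input)
  events$step <- as.integer(events$step)
  if (nrow(events) > 0) {
    if (any(events$input < 0L) || any(events$input >= width)) {
      abort_bad_arg(sprintf("event `input` indices must lie in [0, %d].", width - 1L))
    }
    if (any(events$step < 0L) || any(events$step >= duration)) {
      abort_bad_arg(sprintf("event `step` values must lie in [0, %d].", duration - 1L))
    }
  }
  # duplicate activations of one (input, step) cell are idempotent
  events <- dplyr::distinct(events, .data$input, .data$step)
  events <- dplyr::arrange(events, .data$step, .data$input)
  structure(
    list(width = width, duration = duration,
         events = events[, c("input", "step")],
         label = as.numeric(label), kind = kind),
    class = "stim_pattern"
  )
}

#' @export
print.stim_pattern <- function(x, ...) {
  cat(sprintf("<stim_pattern> %s, %d channels x %d steps, %d events, label %s\n",
              x$kind, x$width, x$duration, nrow(x$events), format(x$label)))
  invisible(x)
}

#' Binary raster image of a pattern
#'
#' @param pattern A [stim_pattern()].
#' @return An integer matrix with `duration` rows (clock steps) and `width`
#'   columns (input channels); 1 marks an active cell.
#' @export
pattern_image <- function(pattern) {
  stopifnot(inherits(pattern, "stim_pattern"))
  img <- matrix(0L, nrow = pattern$duration, ncol = pattern$width)
  if (nrow(pattern$events) > 0) {
    img[cbind(pattern$events$step + 1L, pattern$events$input + 1L)] <- 1L
  }
  img
}

#' Build a pattern from a binary raster image
#'
#' Inverse of [pattern_image()]: rows are clock steps, columns input channels.
#'
#' @param image Binary matrix (steps x channels).
#' @inheritParams stim_pattern
#' @return A [stim_pattern()].
#' @export
image_to_pattern <- function(image, label = NA_real_, kind = "custom") {
  idx <- which(image != 0, arr.ind = TRUE)
  stim_pattern(
    tibble::tibble(input = idx[, 2L] - 1L, step = idx[, 1L] - 1L),
    width = ncol(image), duration = nrow(image), label = label, kind = kind
  )
}

#' Bar pattern of a given slope class
#'
#' Generates the spatiotemporal trace of a straight bar swept over an
#' `m`-channel input line: input `i` is activated at clock step
#' `round(i * k / (m - 1))` (half-up rounding), so class `k = 0` is a
#' horizontal bar (all inputs simultaneously) and class `k = n - 1` with
#' `m = n` is the 45-degree diagonal (one input per step). The label is the
#' bar slope in degrees, `atan(k / (m - 1))`.
#'
#' @param m Number of input channels; at least 2.
#' @param n Number of slope classes (and clock steps spanned).
#' @param k Class index, `0 <= k < n`.
#' @return A [stim_pattern()] with one event per input channel.
#' @export
#' @examples
#' make_bar_pattern(9, 9, 8) # diagonal bar, label 45
make_bar_pattern <- function(m, n, k) {
  m <- check_count(m, "m", min = 2L)
  n <- check_count(n, "n", min = 1L)
  k <- check_count(k, "k", min = 0L)
  if (k >= n) abort_bad_arg(sprintf("`k` must satisfy 0 <= k < n = %d, got %d.", n, k))
  i <- seq_len(m) - 1L
  steps <- as.integer(round_half_up(i * k / (m - 1)))
  stim_pattern(
    tibble::tibble(input = i, step = steps),
    width = m, duration = max(n, max(steps) + 1L),
    label = 180 / pi * atan(k / (m - 1)), kind = "bar"
  )
}

#' Discretized sinusoid pattern
#'
#' One input channel is active per clock step, following a rounded, clipped
#' sine trace across the channel line:
#' `i(t) = clip(round(c + A * sin(2 * pi * f * t / n + phase)), 0, m - 1)`
#' with centre `c = (m - 1) / 2` and default amplitude `A = (m - 1) / 2`.
#'
#' @inheritParams make_bar_pattern
#' @param frequency Cycles per grid (over the `n` clock steps); must be > 0.
#' @param phase Phase offset in radians.
#' @param amplitude Sine amplitude in channel units; traces exceeding the
#'   channel range are clipped to `[0, m - 1]`.
#' @return A [stim_pattern()] with label `frequency`.
#' @export
make_sinusoid_pattern <- function(m, n, frequency, phase = 0,
                                  amplitude = (m - 1) / 2) {
  m <- check_count(m, "m", min = 2L)
  n <- check_count(n, "n", min = 1L)
  check_scalar_number(frequency, "frequency")
  if (frequency <= 0) abort_bad_arg("`frequency` must be > 0.")
  check_scalar_number(phase, "phase")
  t <- seq_len(n) - 1L
  centre <- (m - 1) / 2
  i <- round_half_up(centre + amplitude * sin(2 * pi * frequency * t / n + phase))
  i <- pmin(pmax(i, 0), m - 1)
  stim_pattern(
    tibble::tibble(input = as.integer(i), step = t),
    width = m, duration = n, label = frequency, kind = "sinusoid"
  )
}

#' Pattern sets
#'
#' An ordered collection of stimulus patterns, one per feature class
#' `k = 0 .. n - 1`, all sharing `width` and `duration`, with strictly
#' increasing class labels.
#'
#' @param patterns List of [stim_pattern()] objects.
#' @param kind `"bars"`, `"sinusoids"` or another descriptive string.
#' @return A `pattern_set` object.
#' @export
pattern_set <- function(patterns, kind = "bars") {
  if (length(patterns) == 0) abort_bad_arg("`patterns` must be non-empty.")
  ok <- vapply(patterns, inherits, logical(1), what = "stim_pattern")
  if (!all(ok)) abort_bad_arg("all elements of `patterns` must be stim_pattern objects.")
  widths <- vapply(patterns, function(p) p$width, integer(1))
  durs <- vapply(patterns, function(p) p$duration, integer(1))
  if (length(unique(widths)) != 1L || length(unique(durs)) != 1L) {
    abort_bad_arg("all patterns in a set must share width and duration.")
  }
  labels <- vapply(patterns, function(p) p$label, numeric(1))
  if (any(diff(labels) <= 0)) {
    abort_bad_arg("pattern labels must be strictly increasing with class index.")
  }
  structure(
    list(patterns = patterns, kind = kind,
         width = widths[1L], duration = durs[1L], labels = labels),
    class = "pattern_set"
  )
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set> %s: %d classes, %d channels x %d steps\n",
              x$kind, length(x$patterns), x$width, x$duration))
  invisible(x)
}

#' @export
length.pattern_set <- function(x) length(x$patterns)

#' Full bar training set
#'
#' One bar pattern per slope class `k = 0 .. n - 1`, ordered by ascending
#' slope, matching the bottom-to-top arrangement of the feature classifier
#' column.
#'
#' @inheritParams make_bar_pattern
#' @return A [pattern_set()] of `n` bars.
#' @export
bar_pattern_set <- function(m, n) {
  pattern_set(lapply(seq_len(n) - 1L, function(k) make_bar_pattern(m, n, k)),
              kind = "bars")
}

#' Sinusoid training set
#'
#' @inheritParams make_sinusoid_pattern
#' @param frequencies Strictly increasing vector of cycles-per-grid values.
#' @return A [pattern_set()].
#' @export
sinusoid_pattern_set <- function(m, n, frequencies, phase = 0) {
  pattern_set(lapply(frequencies,
                     function(f) make_sinusoid_pattern(m, n, f, phase = phase)),
              kind = "sinusoids")
}

#' The nine-bar 9 x 9 training set
#'
#' Nine bars of ascending slope on a 9-channel, 9-step grid: the canonical
#' training set for the square network whose feature neurons span slopes
#' 0 to 45 degrees.
#'
#' @return A [pattern_set()] of 9 bar patterns.
#' @export
nine_bar_set <- function() bar_pattern_set(9L, 9L)

#' The two-electrode minimal stimulus pair
#'
#' The two spatiotemporal sequences of the minimal two-channel microcircuit
#' experiment, played like a piano on two adjacent electrodes:
#' * `V` (vertical bar, class 0): electrode 1 and electrode 2 activated in
#'   parallel at step 0;
#' * `D` (diagonal bar, class 1): electrode 2 (channel index 1) at step 0,
#'   then electrode 1 (channel index 0) at the consecutive step 1.
#'
#' @return A [pattern_set()] of the two patterns, labelled 0 and 45 degrees.
#' @export
two_electrode_set <- function() {
  v <- stim_pattern(tibble::tibble(input = c(0L, 1L), step = c(0L, 0L)),
                    width = 2L, duration = 2L, label = 0, kind = "bar")
  d <- stim_pattern(tibble::tibble(input = c(1L, 0L), step = c(0L, 1L)),
                    width = 2L, duration = 2L, label = 45, kind = "bar")
  pattern_set(list(v, d), kind = "bars")
}

#' Serialize / read a pattern set as JSON
#'
#' @param set A [pattern_set()].
#' @param path File path.
#' @return `write_pattern_set()` returns `path` invisibly;
#'   `read_pattern_set()` returns a [pattern_set()].
#' @export
write_pattern_set <- function(set, path) {
  stopifnot(inherits(set, "pattern_set"))
  doc <- list(
    format = "columnhough-pattern-set", version = 1L,
    kind = set$kind, width = set$width, duration = set$duration,
    patterns = lapply(set$patterns, function(p) {
      list(label = p$label, kind = p$kind,
           events = lapply(seq_len(nrow(p$events)),
                           function(r) c(p$events$input[r], p$events$step[r])))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pattern_set
#' @export
read_pattern_set <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$format) || doc$format != "columnhough-pattern-set") {
    abort_bad_arg("not a columnhough pattern-set document.")
  }
  pats <- lapply(doc$patterns, function(p) {
    ev <- do.call(rbind, lapply(p$events, unlist))
    if (is.null(ev)) ev <- matrix(integer(0), ncol = 2)
    stim_pattern(tibble::tibble(input = ev[, 1], step = ev[, 2]),
                 width = doc$width, duration = doc$duration,
                 label = p$label, kind = p$kind)
  })
  pattern_set(pats, kind = doc$kind)
}

#' Plot a stimulus pattern as a space-time raster
#'
#' @param object A [stim_pattern()].
#' @param ... Ignored.
#' @return A ggplot object: channels on x, clock steps on y (time downwards).
#' @export
autoplot.stim_pattern <- function(object, ...) {
  ev <- object$events
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$input, y = .data$step)) +
    ggplot2::geom_tile(fill = "grey20", width = 0.9, height = 0.9) +
    ggplot2::scale_y_reverse(breaks = seq(0, object$duration - 1)) +
    ggplot2::scale_x_continuous(breaks = seq(0, object$width - 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "input channel", y = "clock step",
                  title = sprintf("%s pattern, label %.3g", object$kind, object$label)) +
    ggplot2::theme_minimal()
}

#' Plot every pattern of a set, facetted by class
#'
#' @param object A [pattern_set()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.pattern_set <- function(object, ...) {
  ev <- purrr::map_dfr(seq_along(object$patterns), function(j) {
    p <- object$patterns[[j]]
    dplyr::mutate(p$events, class = j - 1L, label = p$label)
  })
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$input, y = .data$step)) +
    ggplot2::geom_tile(fill = "grey20", width = 0.9, height = 0.9) +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~class, labeller = ggplot2::label_both) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "input channel", y = "clock step") +
    ggplot2::theme_minimal()
}
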