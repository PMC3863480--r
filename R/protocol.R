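#' Build an MEA stimulation protocol from a pattern set
#'
#' Flattens a pattern set into a chronological electrode-stimulation timeline
#' for a microelectrode array: each repetition plays every pattern in order,
#' patterns separated by `inter_pattern_gap` clock steps, with one table row
#' per stimulation event. One clock step lasts `clock_ms` milliseconds (the
#' delay-neuron surcharge of the model equals one clock step, 1 ms at the
#' default).
#'
#' @param set A [pattern_set()].
#' @param inter_pattern_gap Silent clock steps inserted between consecutive
#'   patterns (and between repetitions); must be >= 0.
#' @param repetitions How many times the whole set is played; must be >= 1.
#' @param clock_ms Milliseconds per clock step; must be > 0.
#'
#' @return A tibble with columns `channel` (0-based electrode index),
#'   `time_ms` (absolute stimulation time), `pattern_id` (0-based class
#'   index) and `repetition` (0-based), sorted chronologically. The total
#'   row count is `repetitions` times the summed event count of the set.
#' @export
#' @examples
#' mea_protocol(two_electrode_set(), inter_pattern_gap = 10, repetitions = 1)
mea_protocol <- function(set, inter_pattern_gap = 10L, repetitions = 1L,
                         clock_ms = 1) {
  stopifnot(inherits(set, "pattern_set"))
  gap <- check_count(inter_pattern_gap, "inter_pattern_gap", min = 0L)
  repetitions <- check_count(repetitions, "repetitions", min = 1L)
  check_scalar_number(clock_ms, "clock_ms")
  if (clock_ms <= 0) abort_bad_arg("`clock_ms` must be > 0.")
  if (length(set$patterns) == 0) abort_bad_arg("pattern set is empty.")

  slot <- set$duration + gap           # clock steps reserved per pattern
  per_rep <- slot * length(set$patterns)
  rows <- purrr::map_dfr(seq_len(repetitions) - 1L, function(rep) {
    purrr::map_dfr(seq_along(set$patterns) - 1L, function(pid) {
      ev <- set$patterns[[pid + 1L]]$events
      tibble::tibble(
        channel = ev$input,
        time_ms = (rep * per_rep + pid * slot + ev$step) * clock_ms,
        pattern_id = pid,
        repetition = rep
      )
    })
  })
  dplyr::arrange(rows, .data$time_ms, .data$channel)
}

#' Write an MEA protocol to CSV and JSON
#'
#' @param protocol A tibble from [mea_protocol()].
#' @param path Output path; `.csv` and `.json` siblings are written when
#'   `path` has no extension, otherwise the named format only.
#' @return Invisibly, the character vector of files written.
#' @export
write_mea_protocol <- function(protocol, path) {
  stopifnot(is.data.frame(protocol))
  ext <- tolower(sub("^.*\\.([[:alnum:]]+)$", "\\1", basename(path)))
  written <- character(0)
  if (ext == "csv") {
    utils::write.csv(protocol, path, row.names = FALSE, quote = FALSE)
    written <- path
  } else if (ext == "json") {
    jsonlite::write_json(protocol, path, dataframe = "rows", digits = NA)
    written <- path
  } else {
    written <- c(paste0(path, ".csv"), paste0(path, ".json"))
    utils::write.csv(protocol, written[1], row.names = FALSE, quote = FALSE)
    jsonlite::write_json(protocol, written[2], dataframe = "rows", digits = NA)
  }
  invisible(written)
}
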