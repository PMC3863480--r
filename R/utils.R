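# internal helpers shared across modules

# Half-up rounding. base::round() rounds half to even, which would break the
# staircase rasterization of intermediate bar slopes (0.5 must map to 1).
round_half_up <- function(x) floor(x + 0.5)

abort_bad_arg <- function(msg) rlang::abort(msg, class = "columnhough_error")

check_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_bad_arg(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  check_scalar_number(x, name)
  if (x != as.integer(x) || x < min) {
    abort_bad_arg(sprintf("`%s` must be an integer >= %d, got %s.", name, min, format(x)))
  }
  as.integer(x)
}
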