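#' Complementary Hebbian weight update
#'
#' On a learning-triggering output spike, the weight of the path each signal
#' actually took is reinforced and its antagonistic partner depressed:
#' `w_sel <- w_sel + (1 - w_sel) * alpha`, `w_desel <- w_desel * (1 - alpha)`.
#' The increments cancel (their sum is `(1 - w_sel - w_desel) * alpha = 0`
#' for a complementary pair), so `w_direct + w_delay = 1` is preserved, both
#' weights stay in `[0, 1]`, and `(1, 0)` is a fixed point: the maximum of
#' the pair converges to 1 and the minimum to 0.
#'
#' @param w_selected,w_deselected Current weights of the taken and untaken
#'   path; complementary, each in `[0, 1]`.
#' @param alpha Learning slope parameter in `[0, 1)`.
#' @return Named list with `w_selected` and `w_deselected` after the update.
#' @export
#' @examples
#' update_weight(0.5, 0.5, 0.1) # (0.55, 0.45)
update_weight <- function(w_selected, w_deselected, alpha) {
  check_scalar_number(alpha, "alpha")
  if (alpha < 0 || alpha >= 1) abort_bad_arg("`alpha` must lie in [0, 1).")
  if (any(w_selected < 0 | w_selected > 1 | w_deselected < 0 | w_deselected > 1)) {
    abort_bad_arg("weights must lie in [0, 1].")
  }
  list(
    w_selected = pmin(1, pmax(0, w_selected + (1 - w_selected) * alpha)),
    w_deselected = pmin(1, pmax(0, w_deselected - w_deselected * alpha))
  )
}

#' Lower a layer temperature by one annealing step
#'
#' The Boltzmann temperature of a layer is lowered by `delta_T` each time
#' its output neuron spikes (learning-triggering spikes), never below
#' `T_min`.
#'
#' @param T_current Current temperature, `>= T_min`.
#' @param delta_T Decrement per spike.
#' @param T_min Temperature floor.
#' @return The annealed temperature.
#' @export
anneal_temperature <- function(T_current, delta_T, T_min) {
  pmax(T_current - delta_T, T_min)
}

#' Train a network on a pattern set
#'
#' The presentation loop of the self-structuring learning process. Each
#' presentation picks the next training pattern (cyclic round-robin by
#' default), samples one binary gating configuration per bifurcation from
#' the Boltzmann probabilities at the current layer temperatures, and
#' propagates the pattern. If at least one output neuron spikes, the
#' lowest-index spiking output `k` triggers learning: every layer-`k`
#' segment reinforces the path its column's signal took ([update_weight()]),
#' and layer `k`'s temperature is annealed one step. Input-layer weights are
#' clamped and never updated. Training stops when every trainable weight is
#' within `convergence_tol` of 0 or 1, or at `max_presentations`
#' (non-convergence is a reported outcome, not an error).
#'
#' Layers settle sequentially: the first trainable layer conditions the
#' arrival times seen by deeper layers, so its weights binarize first and
#' deeper layers follow.
#'
#' A network returned by a previous [train()] call carries its RNG state
#' and presentation counter, so training can be saved ([save_network()]),
#' reloaded and resumed with a trajectory identical to an uninterrupted run.
#'
#' @param net A `delay_network` (fresh or mid-training).
#' @param patterns A [pattern_set()] with `width == net$m` and one class per
#'   output (`length == net$n`).
#' @param config A [network_config()]; defaults to the network's own.
#' @param max_presentations Total presentation cap (including presentations
#'   already performed on a resumed network); defaults to the config value.
#' @param order `"roundrobin"` (cyclic, default) or `"shuffle"` (seeded
#'   random order within each epoch).
#' @param record_weights Record the trainable-weight trajectory per
#'   presentation (needed for stability scans); defaults to on for small
#'   nets (`m * (n - 1) <= 8`).
#'
#' @return A `training_result`: list with `network` (updated, with RNG
#'   state), `converged`, `presentations_used`, `layer_convergence` (tibble:
#'   `layer`, `iteration` — presentation index at which the layer's weights
#'   binarized and stayed binarized; 0 for the clamped input layer; `NA` if
#'   not converged), `temperature_history` (tibble: `presentation`, `layer`,
#'   `temperature` — one row per annealing event), `weight_history` (matrix
#'   of trainable `w_direct` per presentation, or `NULL`), `spike_history`
#'   (tibble: `presentation`, `pattern_id`, `output`).
#' @export
train <- function(net, patterns, config = net$config,
                  max_presentations = config$max_presentations,
                  order = c("roundrobin", "shuffle"),
                  record_weights = NULL) {
  stopifnot(inherits(net, "delay_network"), inherits(patterns, "pattern_set"))
  order <- match.arg(order)
  if (patterns$width != net$m) {
    abort_bad_arg(sprintf("pattern width %d does not match network m = %d.",
                          patterns$width, net$m))
  }
  if (length(patterns$patterns) != net$n) {
    abort_bad_arg(sprintf("pattern set has %d classes but network has n = %d outputs.",
                          length(patterns$patterns), net$n))
  }
  net$config <- config
  max_presentations <- check_count(max_presentations, "max_presentations", 1L)

  m <- net$m; n <- net$n
  tol <- config$convergence_tol
  alpha <- config$alpha
  dT <- config$delta_T; Tmin <- config$T_min
  if (is.null(record_weights)) record_weights <- m * (n - 1L) <= 8L

  done0 <- if (is.null(net$presentations_done)) 0L else net$presentations_done

  # restore or seed the shared RNG
  if (!is.null(net$rng_state)) {
    old_seed <- net$rng_state
    assign(".Random.seed", old_seed, envir = globalenv())
  } else {
    set.seed(config$seed)
  }

  W <- net$w_direct
  temps <- net$temperatures
  thr <- net$thresholds

  # precompute per-pattern event vectors and base arrival offsets
  n_pat <- length(patterns$patterns)
  ev_in <- lapply(patterns$patterns, function(p) p$events$input)
  ev_st <- lapply(patterns$patterns, function(p) p$events$step)
  if (length(net$ablated)) {
    for (j in seq_len(n_pat)) {
      keep <- !(ev_in[[j]] %in% net$ablated)
      ev_in[[j]] <- ev_in[[j]][keep]; ev_st[[j]] <- ev_st[[j]][keep]
    }
  }
  base_arr <- lapply(ev_st, function(s) outer(s, seq_len(n), `+`))

  trainable <- if (n > 1L) 2L:n else integer(0)
  layer_converged_now <- function(W) {
    vapply(trainable, function(l) all(pmin(W[, l], 1 - W[, l]) <= tol), logical(1))
  }
  marks <- rep(NA_real_, length(trainable))
  init_conv <- layer_converged_now(W)
  marks[init_conv] <- done0

  all_converged <- function(W) length(trainable) == 0L ||
    all(pmin(W[, trainable], 1 - W[, trainable]) <= tol)

  if (all_converged(W)) {
    net$w_direct <- W
    net$rng_state <- get(".Random.seed", envir = globalenv())
    net$presentations_done <- done0
    return(.training_result(net, TRUE, done0, marks, trainable,
                            integer(0), integer(0), numeric(0), integer(0),
                            NULL, config, record_weights))
  }

  budget <- max_presentations - done0
  if (budget < 1L) abort_bad_arg("`max_presentations` already reached on this network.")

  # preallocated logs
  log_pres <- integer(budget); log_layer <- integer(budget)
  log_temp <- numeric(budget); log_pat <- integer(budget)
  n_log <- 0L
  Whist <- if (record_weights) matrix(NA_real_, nrow = budget,
                                      ncol = m * length(trainable)) else NULL

  shuffle_order <- NULL
  temps_col <- rep(temps, each = m)   # vectorized per-segment temperatures
  converged <- FALSE
  p_abs <- done0

  for (step in seq_len(budget)) {
    p_abs <- p_abs + 1L
    # pattern choice
    if (order == "roundrobin") {
      j <- ((p_abs - 1L) %% n_pat) + 1L
    } else {
      pos <- ((p_abs - 1L) %% n_pat) + 1L
      if (pos == 1L) shuffle_order <- sample.int(n_pat)
      j <- shuffle_order[pos]
    }

    # gating sample: delay iff u >= P_direct
    pdir <- stats::plogis((2 * W - 1) / temps_col)
    g <- matrix(stats::runif(m * n) < pdir, nrow = m)
    g[, 1L] <- TRUE

    inp <- ev_in[[j]]
    if (length(inp)) {
      # cumulative delay count per column/layer
      cd <- 1 - g
      if (n > 1L) for (l in 2L:n) cd[, l] <- cd[, l - 1L] + cd[, l]
      arr <- base_arr[[j]] + cd[inp + 1L, , drop = FALSE]

      # lowest-index spiking output
      spike_l <- 0L
      for (l in seq_len(n)) {
        tl <- arr[, l]
        for (s in unique(tl)) {
          if (length(unique(inp[tl == s])) > thr[l]) { spike_l <- l; break }
        }
        if (spike_l) break
      }

      if (spike_l) {
        if (spike_l >= 2L) {     # trainable layer: reinforce sampled paths
          w <- W[, spike_l]
          sel_direct <- g[, spike_l]
          W[, spike_l] <- ifelse(sel_direct, w + (1 - w) * alpha, w * (1 - alpha))
        }
        temps[spike_l] <- max(temps[spike_l] - dT, Tmin)
        temps_col[(spike_l - 1L) * m + seq_len(m)] <- temps[spike_l]
        n_log <- n_log + 1L
        log_pres[n_log] <- p_abs; log_layer[n_log] <- spike_l - 1L
        log_temp[n_log] <- temps[spike_l]; log_pat[n_log] <- j - 1L
      }
    }

    if (record_weights) Whist[step, ] <- W[, trainable]

    # layer convergence bookkeeping
    conv_now <- layer_converged_now(W)
    newly <- conv_now & is.na(marks)
    marks[newly] <- p_abs
    marks[!conv_now] <- NA_real_

    if (all(conv_now)) { converged <- TRUE; break }
  }

  if (record_weights && !converged) {
    # keep full budget rows
  } else if (record_weights) {
    Whist <- Whist[seq_len(p_abs - done0), , drop = FALSE]
  }

  net$w_direct <- W
  net$temperatures <- temps
  net$rng_state <- get(".Random.seed", envir = globalenv())
  net$presentations_done <- p_abs
  .training_result(net, converged, p_abs, marks, trainable,
                   log_pres[seq_len(n_log)], log_layer[seq_len(n_log)],
                   log_temp[seq_len(n_log)], log_pat[seq_len(n_log)],
                   Whist, config, record_weights)
}

.training_result <- function(net, converged, used, marks, trainable,
                             log_pres, log_layer, log_temp, log_pat,
                             Whist, config, record_weights) {
  layer_conv <- tibble::tibble(
    layer = c(0L, trainable - 1L),
    iteration = c(0, as.numeric(marks))
  )
  if (!is.null(Whist)) {
    colnames(Whist) <- paste0("c", rep(seq_len(net$m) - 1L, times = length(trainable)),
                              "_l", rep(trainable - 1L, each = net$m))
  }
  structure(list(
    network = net,
    converged = converged,
    presentations_used = used,
    layer_convergence = layer_conv,
    temperature_history = tibble::tibble(presentation = log_pres,
                                         layer = log_layer,
                                         temperature = log_temp),
    spike_history = tibble::tibble(presentation = log_pres,
                                   pattern_id = log_pat,
                                   output = log_layer),
    weight_history = Whist,
    config = config
  ), class = "training_result")
}

#' @export
print.training_result <- function(x, ...) {
  cat(sprintf("<training_result> %s after %d presentations\n",
              if (x$converged) "converged" else "NOT converged",
              x$presentations_used))
  print(x$layer_convergence)
  invisible(x)
}

#' Tidy per-layer training summary
#'
#' @param x A `training_result`.
#' @param ... Ignored.
#' @return Tibble with one row per layer: convergence iteration, spike
#'   count, final temperature.
#' @export
tidy.training_result <- function(x, ...) {
  spikes <- dplyr::count(x$spike_history, layer = .data$output, name = "n_spikes")
  dplyr::left_join(x$layer_convergence, spikes, by = "layer") |>
    dplyr::mutate(
      n_spikes = dplyr::coalesce(.data$n_spikes, 0L),
      final_temperature = x$network$temperatures[.data$layer + 1L]
    )
}

#' One-row training summary
#'
#' @param x A `training_result`.
#' @param ... Ignored.
#' @return One-row tibble: convergence flag, presentations used, total
#'   spikes, final temperature range.
#' @export
glance.training_result <- function(x, ...) {
  tibble::tibble(
    converged = x$converged,
    presentations_used = x$presentations_used,
    n_spikes = nrow(x$spike_history),
    temp_min = min(x$network$temperatures),
    temp_max = max(x$network$temperatures),
    alpha = x$config$alpha
  )
}

#' Plot annealing and weight trajectories of a training run
#'
#' @param object A `training_result`.
#' @param ... Ignored.
#' @return A ggplot object: per-layer temperature versus presentation, and,
#'   when the weight trajectory was recorded, per-segment `w_direct` traces.
#' @export
autoplot.training_result <- function(object, ...) {
  th <- dplyr::mutate(object$temperature_history, layer = factor(.data$layer))
  p <- ggplot2::ggplot(th, ggplot2::aes(x = .data$presentation,
                                        y = .data$temperature,
                                        colour = .data$layer)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "presentation", y = "Boltzmann temperature") +
    ggplot2::theme_minimal()
  if (!is.null(object$weight_history)) {
    wh <- tibble::as_tibble(object$weight_history) |>
      dplyr::mutate(presentation = dplyr::row_number()) |>
      tidyr::pivot_longer(-"presentation", names_to = "segment",
                          values_to = "w_direct")
    p <- ggplot2::ggplot(wh, ggplot2::aes(x = .data$presentation,
                                          y = .data$w_direct,
                                          colour = .data$segment)) +
      ggplot2::geom_line() +
      ggplot2::geom_step(data = th,
                         mapping = ggplot2::aes(y = .data$temperature,
                                                group = .data$layer),
                         colour = "grey40", linetype = 2) +
      ggplot2::labs(x = "presentation", y = "w_direct (lines), T (dashed)") +
      ggplot2::theme_minimal()
  }
  p
}
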