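#' Initialize the network state
#'
#' Rates start at zero; both plastic weight matrices start at a small
#' positive uniform baseline plus Gaussian jitter of scale `w_init_scale`,
#' after which every postsynaptic unit's incoming weight row is normalized
#' to Euclidean norm `w_norm`. The global step counter `t` starts at 0 and
#' is never reset between trials.
#'
#' The same `(params, seed)` pair always yields a bit-identical state.
#' Note that this function seeds R's random generator; all subsequent
#' stochastic simulation on the same state draws from that stream.
#'
#' @param params A [wm_params()] object.
#' @param seed Non-negative integer seed.
#' @return A `wm_state` object: rates `f` and `c`, weight matrices `W_fc`
#'   (conjunctive x features), `W_cf` (features x conjunctive), `W_ff`
#'   (feature recurrence, used only by the `no_conjunctive_layer` variant),
#'   facilitation variables `u_f`, `u_c`, and step counter `t`.
#' @examples
#' s <- init_network(wm_params(), seed = 1)
#' sqrt(rowSums(s$W_fc^2))  # every row norm equals w_norm
#' @export
init_network <- function(params, seed = 0L) {
  validate_params(params)
  if (length(seed) != 1 || is.na(seed) || seed < 0) {
    stop("seed must be a single non-negative integer", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n_f <- n_features(params)
  n_c <- params$n_conj

  jittered <- function(nr, nc) {
    w <- matrix(1 + stats::rnorm(nr * nc, sd = params$w_init_scale), nr, nc)
    w <- pmax(w, 1e-6)
    w * (params$w_norm / sqrt(rowSums(w^2)))
  }

  state <- list(
    f = numeric(n_f),
    c = numeric(n_c),
    W_fc = jittered(n_c, n_f),
    W_cf = jittered(n_f, n_c),
    W_ff = {
      w <- jittered(n_f, n_f)
      diag(w) <- 0
      w * (params$w_norm / sqrt(rowSums(w^2)))
    },
    u_f = numeric(n_f),
    u_c = numeric(n_c),
    t = 0L
  )
  class(state) <- "wm_state"
  state
}

#' @export
print.wm_state <- function(x, ...) {
  cat(sprintf("<wm_state> t=%d, %d feature units, %d conjunctive units\n",
              x$t, length(x$f), length(x$c)))
  cat("  active features:", paste(which(x$f > 0.5), collapse = " "), "\n")
  cat("  active conjunctions:", paste(which(x$c > 0.5), collapse = " "), "\n")
  invisible(x)
}

#' One Euler step of the rate dynamics
#'
#' Feature drive is recurrent input `W_cf %*% c` plus external input, minus
#' within-dimension lateral inhibition `beta_f`, plus Gaussian noise;
#' conjunctive drive is `W_fc %*% f` minus lateral inhibition `beta_c` from
#' the other conjunctive units, plus noise. Each rate relaxes toward the
#' rate nonlinearity of its drive with time constant `tau` and is clipped
#' to \[0, 1\]. Under the `no_conjunctive_layer` variant the conjunctive
#' units are absent and features recur through the plastic `W_ff` matrix.
#'
#' `step_network()` performs the activation update only; continuous
#' plasticity is applied by [plasticity_update()], and [run_epoch()] fuses
#' the two over many steps.
#'
#' @param state A `wm_state`.
#' @param i_ext External input vector over the feature units.
#' @param params A [wm_params()] object.
#' @return The updated `wm_state` (step counter incremented).
#' @export
step_network <- function(state, i_ext, params) {
  res <- run_epoch_cpp(state, as.numeric(i_ext), 1L, params,
                       plastic = FALSE, record = FALSE)
  res$state
}

#' Continuous Hebbian plasticity with row normalization
#'
#' Applies the outer-product Hebbian increment `eta * c %o% f` to `W_fc`
#' (and its transpose-shaped counterpart `eta * f %o% c` to `W_cf`), then
#' renormalizes every postsynaptic unit's incoming weight row to norm
#' `w_norm`. There is no explicit decay term: because active synapses grow
#' and rows keep a fixed norm, the synapses of currently-inactive patterns
#' mechanically shrink — the erosion that makes unattended memories decay.
#'
#' Variant behavior: `no_c_to_f_plasticity` freezes `W_cf`;
#' `facilitation_only` applies no Hebbian term and instead increments
#' per-presynaptic-unit facilitation variables (shared across all
#' postsynaptic targets); `no_conjunctive_layer` updates the feature
#' recurrence `W_ff` (diagonal held at zero).
#'
#' @inheritParams step_network
#' @return The updated `wm_state`.
#' @export
plasticity_update <- function(state, params) {
  if (params$eta < 0) stop("eta must be >= 0", call. = FALSE)
  v <- params$variant
  if (v %in% c("full", "no_c_to_f_plasticity") && params$eta > 0) {
    state$W_fc <- normalize_rows_r(
      state$W_fc + params$eta * state$c %o% state$f, params$w_norm)
    if (v == "full") {
      state$W_cf <- normalize_rows_r(
        state$W_cf + params$eta * state$f %o% state$c, params$w_norm)
    }
  } else if (v == "no_conjunctive_layer" && params$eta > 0) {
    w <- state$W_ff + params$eta * state$f %o% state$f
    diag(w) <- 0
    state$W_ff <- normalize_rows_r(w, params$w_norm)
  } else if (v == "facilitation_only") {
    state$u_f <- state$u_f +
      params$facil_U * (1 - state$u_f) * state$f - state$u_f / params$facil_tau
    state$u_c <- state$u_c +
      params$facil_U * (1 - state$u_c) * state$c - state$u_c / params$facil_tau
  }
  state
}

normalize_rows_r <- function(w, w_norm) {
  nrm <- sqrt(rowSums(w^2))
  nrm[nrm == 0] <- 1
  w * (w_norm / nrm)
}

#' Run an epoch of constant input
#'
#' Applies [step_network()] followed by [plasticity_update()] `n_steps`
#' times with a constant external input (the whole loop runs in compiled
#' code), returning the updated state and the visited rates.
#'
#' @inheritParams step_network
#' @param n_steps Number of steps (>= 1).
#' @param record If `FALSE`, skip trace recording (faster; identical
#'   dynamics).
#' @return A list with elements `state` (updated `wm_state`) and `trace`
#'   (a `wm_trace`: step x unit matrix with feature columns `f1...` and
#'   conjunctive columns `c1...`, or `NULL` when `record = FALSE`).
#' @export
run_epoch <- function(state, i_ext, n_steps, params, record = TRUE) {
  stopifnot(n_steps >= 1)
  t0 <- state$t
  res <- run_epoch_cpp(state, as.numeric(i_ext), as.integer(n_steps), params,
                       plastic = TRUE, record = record)
  trace <- NULL
  if (record) {
    trace <- cbind(res$trace_f, res$trace_c)
    colnames(trace) <- unit_labels(params)
    attr(trace, "t0") <- t0
    attr(trace, "n_features") <- n_features(params)
    class(trace) <- c("wm_trace", class(trace))
  }
  list(state = res$state, trace = trace)
}

unit_labels <- function(params) {
  c(paste0("f", seq_len(n_features(params))),
    paste0("c", seq_len(params$n_conj)))
}

#' Tidy an activity trace
#'
#' Converts a `wm_trace` (step x unit matrix) into the long format used for
#' CSV export: one row per step per unit.
#'
#' @param trace A `wm_trace` from [run_epoch()] or [run_trial()].
#' @return A tibble with columns `step` (global step index), `unit_type`
#'   (`"feature"` or `"conjunctive"`), `unit_index`, `rate`.
#' @export
tidy_trace <- function(trace) {
  stopifnot(inherits(trace, "wm_trace"))
  n_f <- attr(trace, "n_features")
  t0 <- attr(trace, "t0") %||% 0L
  m <- unclass(trace)
  attr(m, "t0") <- NULL
  attr(m, "n_features") <- NULL
  tibble::as_tibble(m) |>
    dplyr::mutate(step = t0 + dplyr::row_number()) |>
    tidyr::pivot_longer(-"step", names_to = "unit", values_to = "rate") |>
    dplyr::mutate(
      unit_type = ifelse(startsWith(.data$unit, "f"), "feature",
                         "conjunctive"),
      unit_index = as.integer(sub("^[fc]", "", .data$unit))
    ) |>
    dplyr::select("step", "unit_type", "unit_index", "rate")
}

#' Heatmap of an activity trace
#'
#' Feature-unit rates as a heatmap with conjunctive-unit rates as line
#' traces below, the standard way single trials of this network are
#' visualized.
#'
#' @param trace A `wm_trace`.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace) {
  td <- tidy_trace(trace)
  td$panel <- ifelse(td$unit_type == "feature", "feature units",
                     "conjunctive units")
  ggplot2::ggplot(td) +
    ggplot2::facet_grid(panel ~ ., scales = "free_y", space = "free_y") +
    ggplot2::geom_raster(
      data = ~ dplyr::filter(.x, .data$unit_type == "feature"),
      ggplot2::aes(x = .data$step, y = .data$unit_index, fill = .data$rate)) +
    ggplot2::geom_line(
      data = ~ dplyr::filter(.x, .data$unit_type == "conjunctive"),
      ggplot2::aes(x = .data$step, y = .data$rate,
                   color = factor(.data$unit_index))) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "simulation step", y = NULL, color = "conj unit",
                  fill = "rate") +
    ggplot2::theme_minimal()
}
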