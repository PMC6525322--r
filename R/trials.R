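#' Build a timed trial script
#'
#' A standard working-memory trial is: a brief global inhibitory reset
#' (which quenches activity from the previous trial without touching the
#' weights), the items presented strictly sequentially (stimulus + blank
#' gap each), a memory delay, an optional incidental retro-cue and/or
#' excitatory pulse inside the delay, a probe driving a single feature of
#' the target item, a readout window, and an inter-trial blank.
#'
#' @param items Tibble of items from [make_items()].
#' @param params A [wm_params()] object; epoch durations come from
#'   `params$timing` unless overridden here.
#' @param probe_item Index (into `items`) of the probed target item.
#' @param probe_dim Dimension probed (default `params$probe_dim`, color).
#' @param report_dim Dimension scored (default `params$report_dim`,
#'   orientation).
#' @param delay_steps,stim_steps Optional overrides of the delay/stimulus
#'   durations.
#' @param retrocue `NULL` or `list(item =, dim =, at =)`: during the delay,
#'   present the cued item's feature on `dim` for `timing$cue` steps,
#'   starting `at` steps into the delay (default: mid-delay).
#' @param pulse `NULL` or `list(strength =, duration =, at =)`: a uniform
#'   excitatory input of `strength` to all feature units inside the delay
#'   (default duration `timing$pulse`, default onset mid-delay).
#' @param probe_interference `NULL`, or a feature index on the report
#'   dimension that is driven together with the probe (the
#'   probe-interference protocol).
#' @return A `wm_trial` script: an epoch table (`kind`, `duration`,
#'   list-column `input`) plus probe/target metadata.
#' @export
build_trial <- function(items, params, probe_item = nrow(items),
                        probe_dim = params$probe_dim,
                        report_dim = params$report_dim,
                        delay_steps = NULL, stim_steps = NULL,
                        retrocue = NULL, pulse = NULL,
                        probe_interference = NULL) {
  tm <- params$timing
  delay_steps <- as.integer(delay_steps %||% tm$delay)
  stim_steps <- as.integer(stim_steps %||% tm$stim)
  n_f <- n_features(params)
  dims <- dimension_names(params)

  epochs <- list(epoch_row("reset", tm$reset, rep(-1, n_f)))
  for (i in seq_len(nrow(items))) {
    if (stim_steps > 0) {
      epochs <- c(epochs, list(
        epoch_row("stimulus", stim_steps, encode_input(items[i, ], params))))
    }
    epochs <- c(epochs, list(epoch_row("blank", tm$gap, numeric(n_f))))
  }

  # delay, possibly split around cue / pulse events
  events <- list()
  if (!is.null(retrocue)) {
    at <- as.integer(retrocue$at %||% (delay_steps %/% 2))
    cue_dim <- retrocue$dim %||% params$probe_dim
    feat <- items[[dims[cue_dim]]][retrocue$item]
    events <- c(events, list(list(
      at = at, kind = "cue", duration = as.integer(tm$cue),
      input = single_feature_input(cue_dim, feat, params))))
  }
  if (!is.null(pulse)) {
    at <- as.integer(pulse$at %||% (delay_steps %/% 2))
    events <- c(events, list(list(
      at = at, kind = "pulse",
      duration = as.integer(pulse$duration %||% tm$pulse),
      input = rep(as.numeric(pulse$strength), n_f))))
  }
  if (length(events) > 0) {
    events <- events[order(vapply(events, `[[`, 0L, "at"))]
    pos <- 0L
    for (ev in events) {
      if (ev$at < pos || ev$at + ev$duration > delay_steps) {
        stop("cue/pulse scheduled outside the delay period", call. = FALSE)
      }
      if (ev$at > pos) {
        epochs <- c(epochs, list(epoch_row("delay", ev$at - pos,
                                           numeric(n_f))))
      }
      epochs <- c(epochs, list(epoch_row(ev$kind, ev$duration, ev$input)))
      pos <- ev$at + ev$duration
    }
    if (pos < delay_steps) {
      epochs <- c(epochs, list(epoch_row("delay", delay_steps - pos,
                                         numeric(n_f))))
    }
  } else if (delay_steps > 0) {
    epochs <- c(epochs, list(epoch_row("delay", delay_steps, numeric(n_f))))
  }

  probe_feature <- items[[dims[probe_dim]]][probe_item]
  probe_input <- single_feature_input(probe_dim, probe_feature, params)
  if (!is.null(probe_interference)) {
    probe_input <- probe_input +
      single_feature_input(report_dim, probe_interference, params)
  }
  epochs <- c(epochs, list(
    epoch_row("probe", tm$probe, probe_input),
    epoch_row("readout", tm$readout, numeric(n_f)),
    epoch_row("blank", tm$blank, numeric(n_f))
  ))

  new_trial_script(epochs,
                   items = items, probe_dim = probe_dim,
                   probe_feature = probe_feature, target_item = probe_item,
                   report_dim = report_dim)
}

epoch_row <- function(kind, duration, input) {
  list(kind = kind, duration = as.integer(duration), input = input)
}

new_trial_script <- function(epochs, ...) {
  epochs <- epochs[vapply(epochs, `[[`, 0L, "duration") > 0]
  tab <- tibble::tibble(
    kind = vapply(epochs, `[[`, "", "kind"),
    duration = vapply(epochs, `[[`, 0L, "duration"),
    input = lapply(epochs, `[[`, "input")
  )
  tab$end <- cumsum(tab$duration)
  tab$start <- tab$end - tab$duration + 1L
  script <- c(list(epochs = tab), list(...))
  class(script) <- "wm_trial"
  script
}

#' @export
print.wm_trial <- function(x, ...) {
  cat("<wm_trial>", sum(x$epochs$duration), "steps:",
      paste(sprintf("%s(%d)", x$epochs$kind, x$epochs$duration),
            collapse = " "), "\n")
  invisible(x)
}

#' Total scripted duration in steps
#' @param script A `wm_trial`.
#' @return Integer step count.
#' @export
script_duration <- function(script) sum(script$epochs$duration)

#' Build a stimulus-response rule trial
#'
#' Task rules are encoded exactly like memory items: each rule co-activates
#' one color feature and one response feature (a feature dimension reused
#' as motor plans), attended together so that a conjunctive unit binds
#' them. A test trial then drives the test color alone; pattern completion
#' re-activates the associated motor plan, which is read out as the
#' response.
#'
#' @param rules Tibble with columns `color` and `response` (feature
#'   indices).
#' @param test_color Color feature shown on the test trial. A color absent
#'   from `rules` is allowed (a generalization probe) and flagged in the
#'   returned script (`$generalization`).
#' @param params A [wm_params()] object.
#' @param encode_rules If `FALSE`, omit the rule-encoding epochs (used for
#'   test trials after the rules are already in memory).
#' @param motor_dim Dimension holding the motor plans (default: last
#'   dimension).
#' @return A `wm_trial` whose report dimension is the motor dimension.
#' @export
build_rule_trial <- function(rules, test_color, params, encode_rules = TRUE,
                             motor_dim = params$n_dims) {
  n_f <- n_features(params)
  tm <- params$timing
  epochs <- list(epoch_row("reset", tm$reset, rep(-1, n_f)))
  if (encode_rules) {
    for (r in seq_len(nrow(rules))) {
      input <- single_feature_input(1L, rules$color[r], params) +
        single_feature_input(motor_dim, rules$response[r], params)
      epochs <- c(epochs, list(epoch_row("stimulus", tm$stim, input),
                               epoch_row("blank", tm$gap, numeric(n_f))))
    }
  }
  epochs <- c(epochs, list(
    epoch_row("probe", tm$probe, single_feature_input(1L, test_color, params)),
    epoch_row("readout", tm$readout, numeric(n_f)),
    epoch_row("blank", tm$blank, numeric(n_f))
  ))
  idx <- match(test_color, rules$color)
  script <- new_trial_script(
    epochs,
    items = rules, probe_dim = 1L, probe_feature = test_color,
    target_item = idx, report_dim = motor_dim,
    target_response = if (!is.na(idx)) rules$response[idx] else NA_integer_,
    generalization = is.na(idx))
  script
}

#' Run one trial
#'
#' Executes the script's epochs with [run_epoch()] (plasticity operates
#' continuously, in every epoch), then reads out behavior: during the probe
#' and readout epochs, the report is the argmax over report-dimension
#' feature units at the first step on which any of them crosses
#' `readout_threshold`; if none crosses, no feature is reported (scored
#' incorrect). Weights carry over — there is no reset of plasticity between
#' trials.
#'
#' @param state A `wm_state`.
#' @param script A `wm_trial` from [build_trial()] or [build_rule_trial()].
#' @param params A [wm_params()] object.
#' @param record Record the full activity trace (needed for neural
#'   analyses; the readout and summary windows are always computed).
#' @param shuffle_before_probe If `TRUE`, apply [shuffle_weights()] to the
#'   state immediately before the probe epoch and quench all rates — the
#'   control in which the weights carry no information, so that any
#'   report arises from pattern completion through structureless weights
#'   and is correct at the guessing level (1 / `n_feat_per_dim` among
#'   trials that produce a report).
#' @return A list with `state` (updated) and `result`, a `wm_trial_result`:
#'   `reported` (feature index or `NA`), `correct`, `rt_steps`,
#'   `winner_conj` (per encoded item), `delay_f`/`delay_c` (mean rates over
#'   the final delay window), `trace`, and the epoch table with global step
#'   times.
#' @export
run_trial <- function(state, script, params, record = TRUE,
                      shuffle_before_probe = FALSE) {
  ep <- script$epochs
  t_start <- state$t
  first_probe <- which(ep$kind == "probe")[1]
  traces <- vector("list", nrow(ep))
  for (k in seq_len(nrow(ep))) {
    if (shuffle_before_probe && !is.na(first_probe) && k == first_probe) {
      state <- shuffle_weights(state, params)
      state$f[] <- 0
      state$c[] <- 0
    }
    res <- run_epoch(state, ep$input[[k]], ep$duration[k], params,
                     record = TRUE)
    state <- res$state
    traces[[k]] <- res$trace
  }
  trace <- do.call(rbind, lapply(traces, unclass))
  n_f <- n_features(params)

  # behavioral readout over probe + readout epochs
  probe_rows <- which(ep$kind == "probe")
  report <- list(reported = NA_integer_, rt = NA_integer_)
  if (length(probe_rows) > 0) {
    p0 <- ep$start[probe_rows[1]]
    ro <- probe_rows[1] + 1L
    p1 <- if (ro <= nrow(ep) && ep$kind[ro] == "readout") ep$end[ro]
          else ep$end[probe_rows[1]]
    units <- feature_unit(script$report_dim,
                          seq_len(params$n_feat_per_dim), params)
    win <- trace[p0:p1, units, drop = FALSE]
    crossed <- which(rowSums(win >= params$readout_threshold) > 0)
    if (length(crossed) > 0) {
      report$rt <- crossed[1]
      report$reported <- unname(which.max(win[crossed[1], ]))
    }
  }

  target_feat <- script_target_feature(script, params)
  correct <- !is.na(report$reported) && !is.na(target_feat) &&
    report$reported == target_feat

  # winner conjunction per stimulus epoch (mean rate, second half)
  stim_rows <- which(ep$kind == "stimulus")
  c_cols <- n_f + seq_len(params$n_conj)
  winner_conj <- vapply(stim_rows, function(k) {
    half <- ep$start[k] + ep$duration[k] %/% 2
    m <- colMeans(trace[half:ep$end[k], c_cols, drop = FALSE])
    which.max(m)
  }, 0L)

  # delay-window means (final window before the first post-delay event)
  delay_rows <- which(ep$kind == "delay")
  delay_f <- delay_c <- NULL
  if (length(delay_rows) > 0) {
    dend <- ep$end[delay_rows[length(delay_rows)]]
    w0 <- max(ep$start[delay_rows[length(delay_rows)]], dend - 49L)
    delay_f <- colMeans(trace[w0:dend, seq_len(n_f), drop = FALSE])
    delay_c <- colMeans(trace[w0:dend, c_cols, drop = FALSE])
  }

  colnames(trace) <- unit_labels(params)
  attr(trace, "t0") <- t_start
  attr(trace, "n_features") <- n_f
  class(trace) <- c("wm_trace", class(trace))

  result <- list(
    reported = report$reported, correct = correct, rt_steps = report$rt,
    winner_conj = winner_conj, delay_f = delay_f, delay_c = delay_c,
    epochs = ep[, c("kind", "duration", "start", "end")],
    t_start = t_start,
    trace = if (record) trace else NULL,
    script = script
  )
  class(result) <- "wm_trial_result"
  list(state = state, result = result)
}

script_target_feature <- function(script, params) {
  if (!is.null(script$target_response)) {
    return(script$target_response)
  }
  if (is.null(script$target_item) || is.na(script$target_item)) {
    return(NA_integer_)
  }
  dims <- dimension_names(params)
  script$items[[dims[script$report_dim]]][script$target_item]
}

#' @export
print.wm_trial_result <- function(x, ...) {
  cat(sprintf("<wm_trial_result> reported=%s correct=%s rt=%s\n",
              x$reported, x$correct, x$rt_steps))
  invisible(x)
}

#' Run a block of trials with continuous plasticity
#'
#' Weights persist across trials within a block (the model's source of
#' trial-history effects); blocks are independent replicates.
#'
#' @param state A `wm_state`.
#' @param scripts List of `wm_trial` scripts.
#' @param params A [wm_params()] object.
#' @param record Keep full traces in the per-trial results.
#' @return A list with `state`, `results` (list of `wm_trial_result`), and
#'   `table`: a tibble with one row per trial (`trial`, `reported`,
#'   `correct`, `rt_steps`).
#' @export
run_block <- function(state, scripts, params, record = FALSE) {
  results <- vector("list", length(scripts))
  for (i in seq_along(scripts)) {
    out <- run_trial(state, scripts[[i]], params, record = record)
    state <- out$state
    results[[i]] <- out$result
  }
  tab <- tibble::tibble(
    trial = seq_along(results),
    reported = vapply(results, function(r) r$reported %||% NA_integer_,
                      NA_integer_),
    correct = vapply(results, `[[`, TRUE, "correct"),
    rt_steps = vapply(results, function(r) r$rt_steps %||% NA_integer_,
                      NA_integer_)
  )
  list(state = state, results = results, table = tab)
}

#' Shuffle the plastic weights
#'
#' Randomly permutes every entry of each plastic weight matrix and
#' renormalizes the rows, destroying all stored associations while
#' preserving the weight statistics. Used as the chance-level control.
#' Draws from R's current random stream.
#'
#' @param state A `wm_state`.
#' @param params A [wm_params()] object.
#' @return The state with shuffled weights.
#' @export
shuffle_weights <- function(state, params) {
  perm <- function(w) {
    out <- matrix(sample(as.numeric(w)), nrow(w), ncol(w))
    normalize_rows_r(out, params$w_norm)
  }
  state$W_fc <- perm(state$W_fc)
  state$W_cf <- perm(state$W_cf)
  w <- perm(state$W_ff)
  diag(w) <- 0
  state$W_ff <- normalize_rows_r(w, params$w_norm)
  state
}

#' Serialize a trial script to JSON (and back) for replay
#'
#' @param script A `wm_trial`.
#' @param path File path.
#' @return `write_script_json()` returns `path` invisibly;
#'   `read_script_json()` returns a `wm_trial`.
#' @export
write_script_json <- function(script, path) {
  x <- unclass(script)
  x$epochs <- list(kind = x$epochs$kind, duration = x$epochs$duration,
                   input = x$epochs$input)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_script_json
#' @export
read_script_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  inputs <- x$epochs$input
  if (is.matrix(inputs)) {  # equal-length inputs simplify to a matrix
    inputs <- lapply(seq_len(nrow(inputs)), function(r) inputs[r, ])
  }
  epochs <- lapply(seq_along(x$epochs$kind), function(k) {
    epoch_row(x$epochs$kind[k], x$epochs$duration[k],
              as.numeric(inputs[[k]]))
  })
  extra <- x[setdiff(names(x), "epochs")]
  if (!is.null(extra$items)) extra$items <- tibble::as_tibble(extra$items)
  do.call(new_trial_script, c(list(epochs), extra))
}
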