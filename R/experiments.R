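## Simulated behavioral experiments. Each experiment is a parameterized,
## seeded protocol emitting a long-format tibble (one row per trial per
## measurement) stamped with the seed and config hash. Weights persist
## across trials within a block; blocks are independent replicates.

child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 44488 * 48271 + i * 16807) %% 2147483647)
}

new_experiment_table <- function(rows, experiment, params, seed) {
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, experiment = experiment, .before = 1)
  attr(out, "config_hash") <- config_hash(params)
  attr(out, "seed") <- seed
  attr(out, "experiment") <- experiment
  class(out) <- c("wm_experiment", class(out))
  out
}

#' @export
print.wm_experiment <- function(x, ...) {
  cat(sprintf("<wm_experiment> '%s', %d rows, seed %s, config %s\n",
              attr(x, "experiment"), nrow(x), attr(x, "seed"),
              attr(x, "config_hash")))
  NextMethod()
}

behavior_rows <- function(results, conds, block, block_seed) {
  tabs <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    tibble::tibble(
      block = block, trial = i, seed = block_seed,
      measurement = c("correct", "rt_steps", "reported"),
      value = c(as.numeric(r$correct),
                as.numeric(r$rt_steps %||% NA_real_),
                as.numeric(r$reported %||% NA_real_))
    )
  })
  dplyr::bind_cols(conds[rep(seq_len(nrow(conds)),
                             each = 3L), , drop = FALSE],
                   dplyr::bind_rows(tabs))
}

#' Summarize an experiment table
#'
#' Derived view: condition-wise means with percentile-bootstrap confidence
#' intervals. Raw rows are never replaced by this aggregation.
#'
#' @param tab A `wm_experiment` tibble.
#' @param measure Which measurement to aggregate (default `"correct"`).
#' @param by Condition columns to group by (default: all non-bookkeeping
#'   columns).
#' @param level Confidence level for the bootstrap interval.
#' @return A tibble with `mean`, `ci_lo`, `ci_hi`, `n` per condition.
#' @export
summarize_experiment <- function(tab, measure = "correct", by = NULL,
                                 level = 0.95) {
  keep <- by %||% setdiff(names(tab), c("experiment", "block", "trial",
                                        "seed", "measurement", "value"))
  tab |>
    dplyr::filter(.data$measurement == measure, !is.na(.data$value)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keep))) |>
    dplyr::summarise(
      mean = mean(.data$value),
      ci_lo = boot_ci(.data$value, level = level)[1],
      ci_hi = boot_ci(.data$value, level = level)[2],
      n = dplyr::n(), .groups = "drop")
}

#' @export
autoplot.wm_experiment <- function(object, measure = "correct",
                                   x = NULL, ...) {
  sm <- summarize_experiment(object, measure = measure)
  conds <- setdiff(names(sm), c("mean", "ci_lo", "ci_hi", "n"))
  x <- x %||% conds[1]
  color <- if (length(conds) > 1) conds[2] else NULL
  mapping <- ggplot2::aes(x = .data[[x]], y = .data$mean)
  if (!is.null(color)) {
    mapping <- utils::modifyList(
      mapping, ggplot2::aes(color = factor(.data[[color]]),
                            group = factor(.data[[color]])))
  }
  ggplot2::ggplot(sm, mapping) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi)) +
    ggplot2::labs(y = measure, color = color,
                  title = attr(object, "experiment")) +
    ggplot2::theme_minimal()
}

run_behavior_blocks <- function(params, n_trials, block_size, seed,
                                make_script, conds_of = NULL,
                                shuffle_before_probe = FALSE,
                                record = FALSE, keep_results = FALSE) {
  n_blocks <- ceiling(n_trials / block_size)
  rows <- list()
  all_results <- list()
  for (b in seq_len(n_blocks)) {
    bs <- child_seed(seed, b)
    state <- init_network(params, bs)
    n_in_block <- min(block_size, n_trials - (b - 1L) * block_size)
    results <- vector("list", n_in_block)
    conds <- vector("list", n_in_block)
    for (i in seq_len(n_in_block)) {
      sc <- make_script(params, b, i)
      out <- run_trial(state, sc$script, params, record = record,
                       shuffle_before_probe = shuffle_before_probe)
      state <- out$state
      results[[i]] <- out$result
      conds[[i]] <- sc$cond
    }
    rows[[b]] <- behavior_rows(results, dplyr::bind_rows(conds), b, bs)
    if (keep_results) all_results[[b]] <- results
  }
  list(rows = rows, results = all_results)
}

#' Set-size experiment: working-memory capacity
#'
#' For each set size, items are presented sequentially and one random item
#' is probed after the delay. Each additional item competes for
#' conjunctive units and can overwrite earlier synaptic traces, so mean
#' recall accuracy falls with set size.
#'
#' @param params A [wm_params()] object.
#' @param n_trials Trials per set size.
#' @param set_sizes Integer vector of set sizes (each `<=
#'   n_feat_per_dim`).
#' @param seed Integer run seed.
#' @param block_size Trials per block (weights are continuous within a
#'   block).
#' @param shuffled_weights If `TRUE`, the plastic weights are shuffled just
#'   before every probe — the chance-level control.
#' @return A `wm_experiment` tibble with condition columns `set_size` and
#'   `position` (probed serial position).
#' @export
exp_set_size <- function(params, n_trials = 200L, set_sizes = 1:4,
                         seed = 1L, block_size = 10L,
                         shuffled_weights = FALSE) {
  stopifnot(all(set_sizes <= params$n_feat_per_dim))
  rows <- list()
  for (k in set_sizes) {
    res <- run_behavior_blocks(
      params, n_trials, block_size, child_seed(seed, 1000L + k),
      make_script = function(p, b, i) {
        items <- make_items(k, p)
        pos <- sample.int(k, 1)
        list(script = build_trial(items, p, probe_item = pos),
             cond = tibble::tibble(set_size = k, position = pos))
      },
      shuffle_before_probe = shuffled_weights)
    rows <- c(rows, res$rows)
  }
  new_experiment_table(rows, "set_size", params, seed)
}

#' Serial-position experiment: primacy and recency
#'
#' Probes each serial position equally often at a fixed set size. Emits
#' per-trial correctness plus, for errors, which serial position the
#' reported feature belonged to (the transposition measure: confusions of
#' neighboring items).
#'
#' @inheritParams exp_set_size
#' @param set_size Number of items per trial.
#' @param shared_feature Use the shared-feature stimulus mode (two items
#'   share one feature), the stress condition that disrupts serial-position
#'   structure.
#' @param whole_report_trials Additional trials in which every item is
#'   probed successively in presentation order (the whole-sequence recall
#'   protocol used for the transposition analysis); their rows carry
#'   measurements `wr_correct` and `wr_reported_position`.
#' @return A `wm_experiment` tibble; measurement `reported_position` is the
#'   serial position of the reported feature (`NA` if the report matched no
#'   item).
#' @export
exp_serial_position <- function(params, n_trials = 200L, set_size = 4L,
                                seed = 1L, block_size = 10L,
                                shared_feature = FALSE,
                                whole_report_trials = n_trials %/% 2L) {
  dims <- dimension_names(params)
  items_env <- new.env()
  res <- run_behavior_blocks(
    params, n_trials, block_size, child_seed(seed, 2000L),
    make_script = function(p, b, i) {
      items <- make_items(set_size, p, shared_feature = shared_feature)
      pos <- (i - 1L) %% set_size + 1L
      assign(paste0("it", b, "_", i), items, envir = items_env)
      list(script = build_trial(items, p, probe_item = pos),
           cond = tibble::tibble(set_size = set_size, position = pos,
                                 block_trial = i))
    },
    keep_results = TRUE)
  rows <- res$rows
  # reported-position rows (transposition analysis)
  extra <- list()
  for (b in seq_along(res$results)) {
    for (i in seq_along(res$results[[b]])) {
      r <- res$results[[b]][[i]]
      items <- get(paste0("it", b, "_", i), envir = items_env)
      rep_pos <- if (!is.na(r$reported)) {
        m <- which(items[[dims[params$report_dim]]] == r$reported)
        if (length(m) == 1) m else NA_integer_
      } else NA_integer_
      pos <- (i - 1L) %% set_size + 1L
      extra[[length(extra) + 1L]] <- tibble::tibble(
        set_size = set_size, position = pos, block_trial = i,
        block = b, trial = i, seed = child_seed(seed, 2000L),
        measurement = "reported_position", value = as.numeric(rep_pos))
    }
  }
  # whole-sequence recall: successive single-item probes in order
  if (whole_report_trials > 0) {
    wr_seed <- child_seed(seed, 2500L)
    n_blocks <- ceiling(whole_report_trials / block_size)
    done <- 0L
    for (b in seq_len(n_blocks)) {
      state <- init_network(params, child_seed(wr_seed, b))
      for (i in seq_len(min(block_size, whole_report_trials - done))) {
        items <- make_items(set_size, params,
                            shared_feature = shared_feature)
        wr <- run_whole_report(state, items, params)
        state <- wr$state
        extra[[length(extra) + 1L]] <- tibble::tibble(
          set_size = set_size, position = seq_len(set_size),
          block_trial = i, block = b, trial = i,
          seed = child_seed(wr_seed, b),
          measurement = "wr_correct", value = as.numeric(wr$correct))
        extra[[length(extra) + 1L]] <- tibble::tibble(
          set_size = set_size, position = seq_len(set_size),
          block_trial = i, block = b, trial = i,
          seed = child_seed(wr_seed, b),
          measurement = "wr_reported_position",
          value = as.numeric(wr$reported_position))
      }
      done <- done + min(block_size, whole_report_trials - done)
    }
  }
  new_experiment_table(c(rows, extra), "serial_position", params, seed)
}

# run one whole-report trial: encode all items, delay, then probe each item
# in presentation order, reading out after each probe
run_whole_report <- function(state, items, params) {
  tm <- params$timing
  n_f <- n_features(params)
  dims <- dimension_names(params)
  state <- run_epoch(state, rep(-1, n_f), tm$reset, params,
                     record = FALSE)$state
  for (it in seq_len(nrow(items))) {
    state <- run_epoch(state, encode_input(items[it, ], params), tm$stim,
                       params, record = FALSE)$state
    state <- run_epoch(state, numeric(n_f), tm$gap, params,
                       record = FALSE)$state
  }
  state <- run_epoch(state, numeric(n_f), tm$delay, params,
                     record = FALSE)$state
  units <- feature_unit(params$report_dim, seq_len(params$n_feat_per_dim),
                        params)
  reported <- integer(nrow(items))
  for (it in seq_len(nrow(items))) {
    probe <- single_feature_input(params$probe_dim,
                                  items[[dims[params$probe_dim]]][it],
                                  params)
    pr <- run_epoch(state, probe, tm$probe, params)
    ro <- run_epoch(pr$state, numeric(n_f), tm$readout, params)
    state <- ro$state
    win <- rbind(unclass(pr$trace), unclass(ro$trace))[, units,
                                                       drop = FALSE]
    crossed <- which(rowSums(win >= params$readout_threshold) > 0)
    reported[it] <- if (length(crossed) > 0) {
      unname(which.max(win[crossed[1], ]))
    } else NA_integer_
  }
  state <- run_epoch(state, numeric(n_f), tm$blank, params,
                     record = FALSE)$state
  target <- items[[dims[params$report_dim]]]
  rep_pos <- vapply(reported, function(r) {
    if (is.na(r)) return(NA_integer_)
    m <- which(target == r)
    if (length(m) == 1) m else NA_integer_
  }, 0L)
  list(state = state, correct = !is.na(reported) & reported == target,
       reported_position = rep_pos)
}

#' Encoding-duration experiment
#'
#' Accuracy as a function of stimulus presentation time, per set size:
#' exponential-saturation shape with a set-size-dependent asymptote.
#'
#' @inheritParams exp_set_size
#' @param stim_grid Stimulus durations (steps); 0 means nothing is encoded.
#' @export
exp_encoding_duration <- function(params, stim_grid = c(0L, 5L, 10L, 20L,
                                                        35L, 50L),
                                  set_sizes = c(1L, 4L), n_trials = 100L,
                                  seed = 1L, block_size = 10L) {
  rows <- list()
  for (k in set_sizes) {
    for (st in stim_grid) {
      res <- run_behavior_blocks(
        params, n_trials, block_size,
        child_seed(seed, 3000L + 61L * k + st),
        make_script = function(p, b, i) {
          items <- make_items(k, p)
          pos <- sample.int(k, 1)
          list(script = build_trial(items, p, probe_item = pos,
                                    stim_steps = st),
               cond = tibble::tibble(set_size = k, stim_steps = st,
                                     position = pos))
        })
      rows <- c(rows, res$rows)
    }
  }
  new_experiment_table(rows, "encoding_duration", params, seed)
}

#' Delay-decay experiment: forgetting over time by memory load
#'
#' Accuracy as a function of delay length and set size. Unattended items
#' decay because continuous plasticity erodes their synaptic traces; the
#' attended (last) item is more robust.
#'
#' @inheritParams exp_set_size
#' @param delay_grid Delay durations in steps.
#' @export
exp_delay_decay <- function(params, delay_grid = c(10L, 100L, 300L, 600L),
                            set_sizes = c(1L, 3L), n_trials = 100L,
                            seed = 1L, block_size = 10L) {
  rows <- list()
  for (k in set_sizes) {
    for (d in delay_grid) {
      res <- run_behavior_blocks(
        params, n_trials, block_size,
        child_seed(seed, 4000L + 101L * k + d),
        make_script = function(p, b, i) {
          items <- make_items(k, p)
          pos <- sample.int(k, 1)
          list(script = build_trial(items, p, probe_item = pos,
                                    delay_steps = d),
               cond = tibble::tibble(set_size = k, delay = d,
                                     position = pos))
        })
      rows <- c(rows, res$rows)
    }
  }
  new_experiment_table(rows, "delay_decay", params, seed)
}

#' Retro-cue experiment: shifting the focus of attention
#'
#' Two items; mid-delay an incidental cue (one feature of one item) brings
#' that item back into the focus of attention. The final probe is
#' congruent (same item as the cue) or incongruent. Also emits the
#' delay-activity shift: mean rate of the cued vs uncued item's features
#' in the post-cue delay window, and a no-cue control arm.
#'
#' @inheritParams exp_set_size
#' @param cue_dim Dimension used for the incidental cue (default:
#'   location). Cueing on the probed dimension instead would let the cue
#'   bind the later probe feature to the currently active conjunction,
#'   confounding the congruency contrast.
#' @export
exp_retrocue <- function(params, n_trials = 200L, seed = 1L,
                         block_size = 10L, cue_dim = params$n_dims) {
  rows <- list()
  conds <- expand.grid(cue = c("cue", "none"), congruent = c(TRUE, FALSE))
  for (ci in seq_len(nrow(conds))) {
    cue <- as.character(conds$cue[ci])
    congruent <- conds$congruent[ci]
    res <- run_behavior_blocks(
      params, n_trials %/% 2L, block_size,
      child_seed(seed, 5000L + ci),
      make_script = function(p, b, i) {
        items <- make_items(2L, p)
        cued <- sample.int(2L, 1)
        probed <- if (congruent) cued else 3L - cued
        rc <- if (cue == "cue") list(item = cued, dim = cue_dim) else NULL
        list(script = build_trial(items, p, probe_item = probed,
                                  retrocue = rc),
             cond = tibble::tibble(cue = cue, congruent = congruent,
                                   cued_item = cued, probed_item = probed))
      },
      keep_results = TRUE)
    block_rows <- res$rows
    rows <- c(rows, block_rows)
    # post-cue delay activity of cued vs uncued item's features
    if (cue == "cue") {
      for (b in seq_along(res$results)) {
        for (i in seq_along(res$results[[b]])) {
          r <- res$results[[b]][[i]]
          cond_row <- block_rows[[b]]
          cued <- cond_row$cued_item[(i - 1L) * 3L + 1L]
          sc <- r$script
          rate_of <- function(it) {
            u <- vapply(seq_len(params$n_dims), function(d)
              feature_unit(d, sc$items[[dimension_names(params)[d]]][it],
                           params), 0L)
            mean(r$delay_f[u])
          }
          rows[[length(rows) + 1L]] <- tibble::tibble(
            cue = cue, congruent = congruent, cued_item = cued,
            probed_item = cond_row$probed_item[(i - 1L) * 3L + 1L],
            block = b, trial = i, seed = child_seed(seed, 5000L + ci),
            measurement = c("postcue_rate_cued", "postcue_rate_uncued"),
            value = c(rate_of(cued), rate_of(3L - cued)))
        }
      }
    }
  }
  new_experiment_table(rows, "retrocue", params, seed)
}

#' Excitatory-pulse experiment
#'
#' Two items; mid-delay all feature units receive a uniform excitatory
#' pulse. A weak pulse transiently re-activates the silent (unattended)
#' item, restoring its decodability; a strong pulse disrupts the attended
#' attractor and re-instates competition, hurting the attended item's
#' recall while improving the unattended item's.
#'
#' @inheritParams exp_set_size
#' @param strengths Named vector of pulse strengths; a strength of 0 is
#'   run as the no-pulse control.
#' @param durations Pulse durations in steps, matched to `strengths`: the
#'   weak pulse is long enough for re-activated traces to express; the
#'   strong pulse is kept brief so it disrupts the active attractor
#'   without letting continuous plasticity homogenize the stored weights.
#' @param decode_trials Extra trials (per pulse condition) recorded for
#'   the decoding time course of item 1.
#' @return A `wm_experiment` tibble. Behavioral rows carry conditions
#'   `pulse` and `position`; decoder rows (measurement
#'   `decoder_accuracy`, plus `chance`) carry `pulse` and `window`
#'   (`pre_pulse` / `post_pulse`).
#' @export
exp_pulse <- function(params, strengths = c(none = 0, weak = 1, strong = 3),
                      durations = c(none = 0L, weak = 30L, strong = 10L),
                      n_trials = 100L, seed = 1L, block_size = 10L,
                      decode_trials = 120L) {
  rows <- list()
  delay <- params$timing$delay
  for (si in seq_along(strengths)) {
    pname <- names(strengths)[si]
    strength <- strengths[[si]]
    for (pos in 1:2) {
      res <- run_behavior_blocks(
        params, n_trials %/% 2L, block_size,
        child_seed(seed, 6000L + 10L * si + pos),
        make_script = function(p, b, i) {
          items <- make_items(2L, p)
          pl <- if (strength > 0) {
            list(strength = strength, duration = durations[[pname]])
          } else NULL
          list(script = build_trial(items, p, probe_item = pos, pulse = pl),
               cond = tibble::tibble(pulse = pname, strength = strength,
                                     position = pos))
        })
      rows <- c(rows, res$rows)
    }
  }

  # decoding of item 1 (unattended) before vs after the pulse
  dims <- dimension_names(params)
  for (si in seq_along(strengths)) {
    pname <- names(strengths)[si]
    strength <- strengths[[si]]
    if (pname == "strong") next  # decoding contrast uses none/weak
    traces <- list(); labels <- integer(decode_trials)
    sds <- child_seed(seed, 6500L + si)
    state <- NULL
    for (i in seq_len(decode_trials)) {
      if ((i - 1L) %% 10L == 0L) {
        state <- init_network(params, child_seed(sds, i))
      }
      items <- make_items(2L, params)
      pl <- if (strength > 0) {
        list(strength = strength, duration = durations[[pname]])
      } else NULL
      sc <- build_trial(items, params, probe_item = 1L, pulse = pl)
      out <- run_trial(state, sc, params, record = TRUE)
      state <- out$state
      traces[[i]] <- out$result$trace
      labels[i] <- items[[dims[params$report_dim]]][1L]
    }
    ep <- build_trial(make_items(2L, params), params, probe_item = 1L,
                      pulse = list(strength = strength,
                                   duration = max(durations[[pname]],
                                                  1L)))$epochs
    pulse_row <- which(ep$kind == "pulse")[1]
    win_len <- ep$duration[pulse_row] + 10L
    pre <- c(ep$start[pulse_row] - win_len, ep$start[pulse_row] - 1L)
    # the pulse-evoked window: stimulation period plus the immediate
    # aftermath, where re-activated silent traces express
    post <- c(ep$start[pulse_row], ep$end[pulse_row] + 10L)
    rep_tc <- decode_timecourse(traces, labels,
                                windows = list(pre_pulse = pre,
                                               post_pulse = post),
                                units = "feature", params = params,
                                seed = child_seed(seed, 6600L + si))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      pulse = pname, strength = strength, position = 1L,
      window = rep_tc$window, block = NA_integer_, trial = NA_integer_,
      seed = sds,
      measurement = "decoder_accuracy", value = rep_tc$accuracy)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      pulse = pname, strength = strength, position = 1L,
      window = rep_tc$window, block = NA_integer_, trial = NA_integer_,
      seed = sds, measurement = "decoder_ci_lo", value = rep_tc$ci_lo)
  }
  new_experiment_table(rows, "pulse", params, seed)
}

#' Task-set experiment: Hick's law and response repetition
#'
#' Rules (color to motor-plan pairings) are encoded once per block; test
#' trials then present a single color and record the motor response and
#' its latency. Emits reaction-time rows (conditions `n_rules`,
#' `repetition`) and a rule-decodability row per block (decoding the
#' active rule from conjunctive-unit activity across trials).
#'
#' @inheritParams exp_set_size
#' @param n_rules_grid Numbers of rules to test.
#' @param tests_per_block Test trials following each rule-encoding pass.
#' @export
exp_task_set <- function(params, n_rules_grid = 2:4, n_trials = 120L,
                         seed = 1L, tests_per_block = 12L) {
  rows <- list()
  motor_dim <- params$n_dims
  for (nr in n_rules_grid) {
    n_blocks <- ceiling(n_trials / tests_per_block)
    for (b in seq_len(n_blocks)) {
      bs <- child_seed(seed, 7000L + 31L * nr + b)
      state <- init_network(params, bs)
      rules <- tibble::tibble(color = sample.int(params$n_feat_per_dim, nr),
                              response = sample.int(params$n_feat_per_dim,
                                                    nr))
      # encode the rules once (no test probe scored on this pass)
      enc <- build_rule_trial(rules, rules$color[1], params,
                              encode_rules = TRUE)
      # drop the probe/readout of the encoding pass: keep reset+stimuli
      enc_epochs <- enc$epochs[enc$epochs$kind %in% c("reset", "stimulus",
                                                      "blank"), ]
      for (k in seq_len(nrow(enc_epochs))) {
        state <- run_epoch(state, enc_epochs$input[[k]],
                           enc_epochs$duration[k], params,
                           record = FALSE)$state
      }
      prev_resp <- NA_integer_
      results <- vector("list", tests_per_block)
      conds <- vector("list", tests_per_block)
      conj_pats <- matrix(NA_real_, tests_per_block, params$n_conj)
      for (i in seq_len(tests_per_block)) {
        test_color <- rules$color[sample.int(nr, 1)]
        sc <- build_rule_trial(rules, test_color, params,
                               encode_rules = FALSE)
        out <- run_trial(state, sc, params, record = TRUE)
        state <- out$state
        r <- out$result
        # conjunctive pattern during the test (probe epoch mean)
        ep <- r$epochs
        pr <- which(ep$kind == "probe")[1]
        conj_pats[i, ] <- colMeans(
          unclass(r$trace)[ep$start[pr]:ep$end[pr],
                           n_features(params) + seq_len(params$n_conj),
                           drop = FALSE])
        target <- rules$response[match(test_color, rules$color)]
        results[[i]] <- r
        conds[[i]] <- tibble::tibble(
          n_rules = nr, test_color = test_color, target_response = target,
          repetition = isTRUE(target == prev_resp))
        prev_resp <- r$reported %||% NA_integer_
      }
      rows[[length(rows) + 1L]] <-
        behavior_rows(results, dplyr::bind_rows(conds), b, bs)
      # rule decodability from conjunctive units across trials
      labs <- vapply(conds, function(cc) cc$test_color, 0L)
      if (length(unique(labs)) >= 2 && min(table(labs)) >= 2) {
        dec <- train_linear_decoder(
          decode_dataset(conj_pats, labs, window = "test",
                         units = "conjunctive"),
          seed = bs, k = min(4L, min(table(labs))))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          n_rules = nr, block = b, trial = NA_integer_, seed = bs,
          measurement = c("rule_decoding", "rule_decoding_chance"),
          value = c(dec$cv_accuracy, dec$chance))
      }
    }
  }
  new_experiment_table(rows, "task_set", params, seed)
}

#' Trial-history experiment: flexible conjunctive coding
#'
#' A long series of one-item trials with continuous plasticity. For each
#' trial pair at lag k, the Pearson similarity of delay-period conjunctive
#' activity patterns is computed, split by whether the two trials showed
#' the same or different stimuli, and by how many intervening trials
#' contained a conjunction violation (an item sharing one feature with the
#' reference trial's item while mismatching on the other dimension).
#'
#' Uses a two-dimensional stimulus space (the canonical analysis varies
#' two feature dimensions) unless `params` already has `n_dims != 3`.
#'
#' @param params A [wm_params()] object; reduced to two dimensions for
#'   this protocol.
#' @param n_trial_series Number of sequential trials.
#' @param seed Integer seed.
#' @param max_lag Largest trial lag analyzed.
#' @return A `wm_experiment` tibble of pair rows: conditions `lag`,
#'   `pair_type` (`same` / `different` / `partial`), `n_violations`;
#'   measurement `similarity`.
#' @export
exp_trial_history <- function(params, n_trial_series = 2000L, seed = 1L,
                              max_lag = 10L) {
  if (params$n_dims == 3L) {
    params <- wm_params_override(params, n_dims = 2L, report_dim = 2L,
                                 probe_dim = 1L)
  }
  dims <- dimension_names(params)
  state <- init_network(params, child_seed(seed, 8000L))
  nfpd <- params$n_feat_per_dim
  stim <- matrix(0L, n_trial_series, params$n_dims)
  pats <- matrix(NA_real_, n_trial_series, params$n_conj)
  correct <- logical(n_trial_series)
  for (i in seq_len(n_trial_series)) {
    feats <- vapply(seq_len(params$n_dims),
                    function(d) sample.int(nfpd, 1), 0L)
    stim[i, ] <- feats
    item <- tibble::as_tibble(as.list(stats::setNames(feats, dims)))
    item$item <- 1L
    sc <- build_trial(item, params, probe_item = 1L)
    out <- run_trial(state, sc, params, record = TRUE)
    state <- out$state
    # conjunctive pattern over the whole delay period (the encoded item is
    # active at delay onset on every trial, so this window always carries
    # a real pattern even when the attractor later collapses)
    ep <- out$result$epochs
    dl <- which(ep$kind == "delay")
    pats[i, ] <- colMeans(
      unclass(out$result$trace)[ep$start[dl[1]]:ep$end[dl[length(dl)]],
                                n_features(params) + seq_len(params$n_conj),
                                drop = FALSE])
    correct[i] <- out$result$correct
  }
  rows <- list()
  for (k in seq_len(max_lag)) {
    idx <- (k + 1L):n_trial_series
    shares <- stim[idx, 1] == stim[idx - k, 1]
    shares2 <- stim[idx, 2] == stim[idx - k, 2]
    pair_type <- ifelse(shares & shares2, "same",
                        ifelse(!shares & !shares2, "different", "partial"))
    n_viol <- vapply(idx, function(n) {
      if (k == 1L) return(0L)
      mid <- (n - k + 1L):(n - 1L)
      sum((stim[mid, 1] == stim[n, 1]) != (stim[mid, 2] == stim[n, 2]))
    }, 0L)
    sim <- vapply(idx, function(n) pattern_similarity(pats[n, ],
                                                      pats[n - k, ]), 0)
    rows[[k]] <- tibble::tibble(
      lag = k, pair_type = pair_type, n_violations = n_viol,
      block = 1L, trial = idx, seed = child_seed(seed, 8000L),
      measurement = "similarity", value = sim)
  }
  rows[[length(rows) + 1L]] <- tibble::tibble(
    lag = NA_integer_, pair_type = NA_character_, n_violations = NA_integer_,
    block = 1L, trial = seq_len(n_trial_series),
    seed = child_seed(seed, 8000L),
    measurement = "correct", value = as.numeric(correct))
  new_experiment_table(rows, "trial_history", params, seed)
}

#' Lag at which same-vs-different pattern similarity becomes undetectable
#'
#' For each lag, the bootstrap confidence interval of the mean similarity
#' gap (same-stimulus minus different-stimulus pairs) is computed; the
#' reported value is the smallest lag whose interval includes zero — the
#' point at which conjunctive selectivity from a given trial has been
#' fully overwritten.
#'
#' @param tab Output of [exp_trial_history()].
#' @param level Confidence level.
#' @param n_boot Bootstrap resamples per lag.
#' @return A list: `lag_undetectable` (smallest such lag, `Inf` if none
#'   within range) and `by_lag` (tibble of gaps and intervals).
#' @export
history_gap_lag <- function(tab, level = 0.95, n_boot = 2000L) {
  sim <- dplyr::filter(tab, .data$measurement == "similarity",
                       !is.na(.data$value))
  lags <- sort(unique(sim$lag))
  by_lag <- lapply(lags, function(k) {
    s <- sim$value[sim$lag == k & sim$pair_type == "same"]
    d <- sim$value[sim$lag == k & sim$pair_type == "different"]
    ci <- boot_diff_ci(s, d, n_boot = n_boot, level = level)
    tibble::tibble(lag = k, gap = mean(s) - mean(d),
                   ci_lo = ci[1], ci_hi = ci[2],
                   detectable = ci[1] > 0)
  })
  by_lag <- dplyr::bind_rows(by_lag)
  und <- by_lag$lag[!by_lag$detectable]
  list(lag_undetectable = if (length(und) > 0) min(und) else Inf,
       by_lag = by_lag)
}

#' Previous-trial benefit experiment
#'
#' Series of one-item trials in which the item occasionally repeats the
#' previous trial's feature combination. Because the same conjunctive
#' unit is re-used, repeated combinations are recalled better. A
#' shuffled-weights arm removes the benefit.
#'
#' @inheritParams exp_set_size
#' @param p_repeat Probability that a trial repeats the previous item.
#' @export
exp_previous_trial_benefit <- function(params, n_trials = 300L, seed = 1L,
                                       block_size = 25L, p_repeat = 0.5,
                                       shuffled_weights = FALSE) {
  prev_env <- new.env()
  res <- run_behavior_blocks(
    params, n_trials, block_size, child_seed(seed, 9000L),
    make_script = function(p, b, i) {
      prev <- if (i > 1L) get("prev", envir = prev_env) else NULL
      repeated <- !is.null(prev) && stats::runif(1) < p_repeat
      items <- if (repeated) prev else make_items(1L, p)
      if (!repeated && !is.null(prev)) {
        # force a genuinely novel combination
        while (all(vapply(dimension_names(p), function(d)
          items[[d]][1] == prev[[d]][1], TRUE))) {
          items <- make_items(1L, p)
        }
      }
      assign("prev", items, envir = prev_env)
      list(script = build_trial(items, p, probe_item = 1L),
           cond = tibble::tibble(repetition = repeated,
                                 first_of_block = i == 1L))
    },
    shuffle_before_probe = shuffled_weights)
  new_experiment_table(res$rows, "previous_trial_benefit", params, seed)
}

#' Ablation experiment: the three simpler model variants
#'
#' Runs the capability probes — noiseless attractor persistence,
#' single-item recall, retro-cue shifting, and delay-dependent
#' interference with a second item — for the full model and each ablation
#' variant, emitting the capability matrix.
#'
#' @inheritParams exp_set_size
#' @param variants Character vector of variants to test.
#' @export
exp_ablations <- function(params, n_trials = 60L, seed = 1L,
                          variants = c("full", "facilitation_only",
                                       "no_c_to_f_plasticity",
                                       "no_conjunctive_layer")) {
  rows <- list()
  for (v in variants) {
    pv <- wm_params_override(params, variant = v)
    # persistence (noiseless)
    p0 <- wm_params_override(pv, noise_sigma = 0)
    s <- init_network(p0, child_seed(seed, 1L))
    item <- make_items(1L, p0)
    enc <- run_epoch(s, encode_input(item, p0), p0$timing$stim, p0)
    del <- run_epoch(enc$state, numeric(n_features(p0)), 500L, p0)
    fmean <- colMeans(del$trace[, seq_len(n_features(p0)), drop = FALSE])
    eu <- which(encode_input(item, p0) > 0)
    persist <- all(fmean[eu] > 0.5) && all(fmean[-eu] < 0.2)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      variant = v, block = NA_integer_, trial = NA_integer_,
      seed = child_seed(seed, 1L),
      measurement = c("persistence", "persistence_rate"),
      value = c(as.numeric(persist), mean(fmean[eu])))

    # single-item recall
    res <- run_behavior_blocks(
      pv, n_trials, 10L, child_seed(seed, 20L),
      make_script = function(p, b, i) {
        items <- make_items(1L, p)
        list(script = build_trial(items, p, probe_item = 1L),
             cond = tibble::tibble(variant = v, probe = "single"))
      })
    rows <- c(rows, res$rows)

    # retro-cue shifting: post-cue activity of cued item 1 vs item 2
    shift <- run_behavior_blocks(
      pv, n_trials %/% 2L, 10L, child_seed(seed, 30L),
      make_script = function(p, b, i) {
        items <- make_items(2L, p)
        list(script = build_trial(items, p, probe_item = 1L,
                                  retrocue = list(item = 1L,
                                                  dim = p$n_dims)),
             cond = tibble::tibble(variant = v, probe = "retrocue"))
      },
      keep_results = TRUE)
    sv <- unlist(lapply(shift$results, function(blk) {
      vapply(blk, function(r) {
        sc <- r$script
        rate_of <- function(it) {
          u <- vapply(seq_len(pv$n_dims), function(d)
            feature_unit(d, sc$items[[dimension_names(pv)[d]]][it], pv), 0L)
          mean(r$delay_f[u])
        }
        rate_of(1L) - rate_of(2L)
      }, 0)
    }))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      variant = v, block = NA_integer_, trial = NA_integer_,
      seed = child_seed(seed, 30L), measurement = "cue_shift",
      value = mean(sv))

    # delay interference: unattended accuracy, short vs long delay
    for (d in c(50L, 600L)) {
      res <- run_behavior_blocks(
        pv, n_trials, 10L, child_seed(seed, 40L + d),
        make_script = function(p, b, i) {
          items <- make_items(2L, p)
          list(script = build_trial(items, p, probe_item = 1L,
                                    delay_steps = d),
               cond = tibble::tibble(variant = v,
                                     probe = paste0("unattended_delay_", d)))
        })
      rows <- c(rows, res$rows)
    }
  }
  new_experiment_table(rows, "ablations", params, seed)
}

#' Generic parameter sweep
#'
#' Re-runs a named experiment over the cross-product of any model
#' parameter grid.
#'
#' @param params Base [wm_params()].
#' @param grid Named list of parameter values to cross (empty list: a
#'   single canonical run).
#' @param experiment Experiment name (one of
#'   `names(experiment_registry())`).
#' @param seed Integer seed.
#' @param ... Passed to the experiment function (e.g. `n_trials`).
#' @return A `wm_experiment` tibble with the swept parameters as columns.
#' @export
parameter_sweep <- function(params, grid = list(), experiment = "set_size",
                            seed = 1L, ...) {
  fn <- experiment_registry()[[experiment]]
  if (is.null(fn)) {
    stop("unknown experiment: ", experiment, call. = FALSE)
  }
  cells <- if (length(grid) == 0) {
    tibble::tibble(.cell = 1L)
  } else {
    tibble::as_tibble(expand.grid(grid, stringsAsFactors = FALSE))
  }
  out <- lapply(seq_len(nrow(cells)), function(ci) {
    over <- as.list(cells[ci, setdiff(names(cells), ".cell"), drop = FALSE])
    p <- do.call(wm_params_override, c(list(params), over))
    tab <- fn(p, seed = child_seed(seed, ci), ...)
    for (nm in names(over)) tab[[paste0("sweep_", nm)]] <- over[[nm]]
    tab$sweep_cell <- ci
    tab
  })
  res <- dplyr::bind_rows(out)
  attr(res, "config_hash") <- config_hash(list(params, grid))
  attr(res, "seed") <- seed
  attr(res, "experiment") <- paste0("sweep_", experiment)
  class(res) <- c("wm_experiment", class(res))
  res
}

#' Registry of named experiments
#'
#' @return Named list mapping experiment names to their functions.
#' @export
experiment_registry <- function() {
  list(set_size = exp_set_size,
       serial_position = exp_serial_position,
       encoding_duration = exp_encoding_duration,
       delay_decay = exp_delay_decay,
       retrocue = exp_retrocue,
       pulse = exp_pulse,
       task_set = exp_task_set,
       trial_history = exp_trial_history,
       previous_trial_benefit = exp_previous_trial_benefit,
       ablations = exp_ablations)
}

#' Modify selected fields of a parameter object
#'
#' Rebuilds (and revalidates) a [wm_params()] with the given fields
#' replaced.
#'
#' @param params A `wm_params`.
#' @param ... Fields to override.
#' @return A new `wm_params`.
#' @export
wm_params_override <- function(params, ...) {
  over <- list(...)
  x <- unclass(params)
  x$variant_code <- NULL
  x[names(over)] <- over
  do.call(wm_params, x)
}
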