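## Qualitative direction checks. Every simulated experiment has a set of
## directional predictions; each is tested with a two-sample percentile
## bootstrap at the 95% level (direction, not magnitude, is the contract).

check_row <- function(check, x, y, level = 0.95, margin = 0) {
  ci <- boot_diff_ci(x, y, level = level)
  tibble::tibble(check = check,
                 estimate = mean(as.numeric(x), na.rm = TRUE) -
                   mean(as.numeric(y), na.rm = TRUE),
                 ci_lo = ci[1], ci_hi = ci[2],
                 pass = isTRUE(ci[1] > margin))
}

meas <- function(tab, m, ...) {
  out <- dplyr::filter(tab, .data$measurement == m, !is.na(.data$value), ...)
  out$value
}

#' Direction checks for an experiment table
#'
#' Recomputes the qualitative predictions associated with an experiment
#' (e.g. accuracy strictly decreasing over set sizes, recency and primacy,
#' congruent > incongruent) from its raw rows, each as a bootstrap
#' direction test at the given level.
#'
#' @param tab A `wm_experiment` tibble.
#' @param level Confidence level for the bootstrap direction tests.
#' @return A tibble with columns `check`, `estimate`, `ci_lo`, `ci_hi`,
#'   `pass`.
#' @export
experiment_checks <- function(tab, level = 0.95) {
  exp_name <- attr(tab, "experiment") %||% tab$experiment[1]
  fn <- switch(exp_name,
               set_size = checks_set_size,
               serial_position = checks_serial_position,
               encoding_duration = checks_encoding_duration,
               delay_decay = checks_delay_decay,
               retrocue = checks_retrocue,
               pulse = checks_pulse,
               task_set = checks_task_set,
               trial_history = checks_trial_history,
               previous_trial_benefit = checks_previous_trial,
               ablations = checks_ablations,
               NULL)
  if (is.null(fn)) {
    stop("no checks registered for experiment '", exp_name, "'",
         call. = FALSE)
  }
  fn(tab, level)
}

checks_set_size <- function(tab, level) {
  ks <- sort(unique(tab$set_size))
  out <- lapply(seq_len(length(ks) - 1L), function(i) {
    check_row(sprintf("accuracy(set %d) > accuracy(set %d)",
                      ks[i], ks[i + 1L]),
              meas(tab, "correct", .data$set_size == ks[i]),
              meas(tab, "correct", .data$set_size == ks[i + 1L]), level)
  })
  # joint decreasing-trend check: observed means strictly decreasing and
  # the accuracy-vs-set-size slope negative at the bootstrap level
  vals <- lapply(ks, function(k) meas(tab, "correct", .data$set_size == k))
  means <- vapply(vals, mean, 0)
  n_boot <- 2000L
  slope_of <- function(m) stats::coef(stats::lm(m ~ ks))[[2]]
  slopes <- vapply(seq_len(n_boot), function(b) {
    slope_of(vapply(vals, function(v) mean(sample(v, replace = TRUE)), 0))
  }, 0)
  a <- (1 - level) / 2
  trend <- tibble::tibble(
    check = "accuracy strictly decreasing over set sizes (trend)",
    estimate = slope_of(means),
    ci_lo = unname(quantile(slopes, a)),
    ci_hi = unname(quantile(slopes, 1 - a)),
    pass = all(diff(means) < 0) && unname(quantile(slopes, 1 - a)) < 0)
  dplyr::bind_rows(c(out, list(trend)))
}

checks_serial_position <- function(tab, level) {
  acc <- function(p) meas(tab, "correct", .data$position == p)
  out <- dplyr::bind_rows(
    check_row("recency: position 4 > position 2", acc(4), acc(2), level),
    check_row("recency: position 4 > position 3", acc(4), acc(3), level),
    check_row("primacy: position 1 > position 2", acc(1), acc(2), level)
  )
  # transposition: per-available-position error rate, neighbors vs distant,
  # from the whole-report (successive probes in order) trials
  cor_tab <- dplyr::filter(tab, .data$measurement == "wr_correct")
  rep_tab <- dplyr::filter(tab, .data$measurement == "wr_reported_position")
  key <- c("block", "trial", "position")
  joined <- dplyr::inner_join(
    dplyr::select(cor_tab, dplyr::all_of(key), correct = "value"),
    dplyr::select(rep_tab, dplyr::all_of(key), rep_pos = "value"),
    by = key)
  err <- dplyr::filter(joined, .data$correct == 0, !is.na(.data$rep_pos))
  if (nrow(err) > 10) {
    set_size <- max(tab$position)
    per_trial <- function(r, type) {
      others <- setdiff(seq_len(set_size), r["position"])
      d <- abs(others - r["position"])
      sel <- if (type == "near") others[d == 1] else others[d >= 2]
      if (length(sel) == 0) return(NA_real_)
      as.numeric(r["rep_pos"] %in% sel) / length(sel)
    }
    m <- as.matrix(err[, c("position", "rep_pos")])
    near <- apply(m, 1, per_trial, type = "near")
    far <- apply(m, 1, per_trial, type = "far")
    out <- dplyr::bind_rows(out,
      check_row("transpositions: neighbor errors > distant errors",
                near[!is.na(near)], far[!is.na(far)], level))
  }
  out
}

checks_encoding_duration <- function(tab, level) {
  durs <- sort(unique(tab$stim_steps))
  lo <- durs[durs <= durs[ceiling(length(durs) / 2)]]
  hi <- setdiff(durs, lo)
  asym <- max(durs)
  dplyr::bind_rows(
    check_row("accuracy increases with encoding duration",
              meas(tab, "correct", .data$stim_steps %in% hi),
              meas(tab, "correct", .data$stim_steps %in% lo), level),
    check_row("asymptote higher at set size 1 than 4",
              meas(tab, "correct", .data$stim_steps == asym,
                   .data$set_size == min(tab$set_size)),
              meas(tab, "correct", .data$stim_steps == asym,
                   .data$set_size == max(tab$set_size)), level)
  )
}

delay_slopes <- function(tab, filter_expr = TRUE) {
  df <- dplyr::filter(tab, .data$measurement == "correct",
                      {{ filter_expr }})
  stats::coef(stats::lm(value ~ delay, data = df))[["delay"]]
}

checks_delay_decay <- function(tab, level) {
  k_lo <- min(tab$set_size); k_hi <- max(tab$set_size)
  ds <- sort(unique(tab$delay))
  short <- ds[ds <= stats::median(ds)]
  long <- setdiff(ds, short)
  # drop-with-delay contrast, bootstrap over trials
  drop_of <- function(sel) {
    x <- meas(tab, "correct", sel, .data$delay %in% short)
    y <- meas(tab, "correct", sel, .data$delay %in% long)
    list(short = x, long = y)
  }
  hi <- drop_of(tab$set_size == k_hi)
  lo <- drop_of(tab$set_size == k_lo)
  n_boot <- 2000L
  boot_drop <- function(d) {
    vapply(seq_len(n_boot), function(i) {
      mean(sample(d$short, replace = TRUE)) -
        mean(sample(d$long, replace = TRUE))
    }, 0)
  }
  dd <- boot_drop(hi) - boot_drop(lo)
  a <- (1 - level) / 2
  r1 <- tibble::tibble(
    check = sprintf("delay cost larger at set size %d than %d", k_hi, k_lo),
    estimate = (mean(hi$short) - mean(hi$long)) -
      (mean(lo$short) - mean(lo$long)),
    ci_lo = unname(quantile(dd, a)), ci_hi = unname(quantile(dd, 1 - a)),
    pass = unname(quantile(dd, a)) > 0)
  # attended (last) position decays slower than earlier positions
  att <- drop_of(tab$set_size == k_hi & tab$position == k_hi)
  una <- drop_of(tab$set_size == k_hi & tab$position < k_hi)
  du <- boot_drop(una) - boot_drop(att)
  r2 <- tibble::tibble(
    check = "attended (last) item decays slower than earlier items",
    estimate = (mean(una$short) - mean(una$long)) -
      (mean(att$short) - mean(att$long)),
    ci_lo = unname(quantile(du, a)), ci_hi = unname(quantile(du, 1 - a)),
    pass = unname(quantile(du, a)) > 0)
  r3 <- check_row(
    "attended item near ceiling at shortest delay",
    meas(tab, "correct", .data$set_size == k_hi,
         .data$position == k_hi, .data$delay == min(ds)),
    0.75, level)
  dplyr::bind_rows(r1, r2, r3)
}

checks_retrocue <- function(tab, level) {
  dplyr::bind_rows(
    check_row("congruent > incongruent accuracy (cued trials)",
              meas(tab, "correct", .data$cue == "cue", .data$congruent),
              meas(tab, "correct", .data$cue == "cue", !.data$congruent),
              level),
    check_row("delay activity shifts to the cued item",
              meas(tab, "postcue_rate_cued"),
              meas(tab, "postcue_rate_uncued"), level),
    check_row("no-cue control: recency (item 2 > item 1)",
              meas(tab, "correct", .data$cue == "none",
                   .data$probed_item == 2),
              meas(tab, "correct", .data$cue == "none",
                   .data$probed_item == 1), level)
  )
}

checks_pulse <- function(tab, level) {
  dec <- dplyr::filter(tab, .data$measurement == "decoder_accuracy",
                       .data$pulse == "weak")
  dlo <- dplyr::filter(tab, .data$measurement == "decoder_ci_lo",
                       .data$pulse == "weak")
  post <- dec$value[dec$window == "post_pulse"]
  pre <- dec$value[dec$window == "pre_pulse"]
  post_lo <- dlo$value[dlo$window == "post_pulse"]
  chance <- 1 / 4
  r1 <- tibble::tibble(
    check = "weak pulse: unattended decodability rises above chance",
    estimate = post - pre,
    ci_lo = post_lo - chance,
    ci_hi = NA_real_,
    pass = isTRUE(post > pre && post_lo > chance))
  dplyr::bind_rows(
    r1,
    check_row("strong pulse: attended accuracy falls",
              meas(tab, "correct", .data$pulse == "none",
                   .data$position == 2),
              meas(tab, "correct", .data$pulse == "strong",
                   .data$position == 2), level),
    check_row("strong pulse: unattended accuracy rises",
              meas(tab, "correct", .data$pulse == "strong",
                   .data$position == 1),
              meas(tab, "correct", .data$pulse == "none",
                   .data$position == 1), level)
  )
}

checks_task_set <- function(tab, level) {
  rts <- dplyr::filter(tab, .data$measurement == "rt_steps",
                       !is.na(.data$value))
  ks <- sort(unique(rts$n_rules))
  r1 <- check_row(
    sprintf("Hick's law: RT(%d rules) > RT(%d rules)", max(ks), min(ks)),
    rts$value[rts$n_rules == max(ks)],
    rts$value[rts$n_rules == min(ks)], level)
  r2 <- check_row("repeated response faster than switched",
                  rts$value[!rts$repetition],
                  rts$value[rts$repetition], level)
  dec <- meas(tab, "rule_decoding")
  ch <- meas(tab, "rule_decoding_chance")
  r3 <- check_row("active rule decodable from conjunctive units",
                  dec, mean(ch), level)
  dplyr::bind_rows(r1, r2, r3)
}

checks_trial_history <- function(tab, level) {
  sim <- dplyr::filter(tab, .data$measurement == "similarity",
                       !is.na(.data$value))
  gap_samples <- function(k, viol = NULL) {
    sel <- sim$lag == k
    if (!is.null(viol)) sel <- sel & (sim$n_violations > 0) == viol
    list(s = sim$value[sel & sim$pair_type == "same"],
         d = sim$value[sel & sim$pair_type == "different"])
  }
  g1 <- gap_samples(1L)
  r1 <- check_row("lag 1: same-stimulus similarity > different",
                  g1$s, g1$d, level)
  # gap shrinks with lag: two-sample-of-differences bootstrap
  k_far <- max(sim$lag[sim$lag <= 6L])
  gf <- gap_samples(k_far)
  n_boot <- 2000L
  bgap <- function(g) vapply(seq_len(n_boot), function(i) {
    mean(sample(g$s, replace = TRUE)) - mean(sample(g$d, replace = TRUE))
  }, 0)
  dd <- bgap(g1) - bgap(gf)
  a <- (1 - level) / 2
  r2 <- tibble::tibble(
    check = sprintf("same-vs-different gap shrinks from lag 1 to lag %d",
                    k_far),
    estimate = (mean(g1$s) - mean(g1$d)) - (mean(gf$s) - mean(gf$d)),
    ci_lo = unname(quantile(dd, a)), ci_hi = unname(quantile(dd, 1 - a)),
    pass = unname(quantile(dd, a)) > 0)
  gv <- gap_samples(2L, viol = TRUE)
  gn <- gap_samples(2L, viol = FALSE)
  dv <- bgap(gn) - bgap(gv)
  r3 <- tibble::tibble(
    check = "lag 2: intervening conjunction violation shrinks the gap",
    estimate = (mean(gn$s) - mean(gn$d)) - (mean(gv$s) - mean(gv$d)),
    ci_lo = unname(quantile(dv, a)), ci_hi = unname(quantile(dv, 1 - a)),
    pass = unname(quantile(dv, a)) > 0)
  dplyr::bind_rows(r1, r2, r3)
}

checks_previous_trial <- function(tab, level) {
  keep <- dplyr::filter(tab, !.data$first_of_block)
  check_row("repeated feature combination recalled better",
            meas(keep, "correct", .data$repetition),
            meas(keep, "correct", !.data$repetition), level, margin = -0.02)
}

checks_ablations <- function(tab, level) {
  persists <- function(v) {
    meas(tab, "persistence", .data$variant == v)[1] == 1
  }
  recall <- function(v) mean(meas(tab, "correct", .data$variant == v,
                                  .data$probe == "single"))
  shift <- function(v) meas(tab, "cue_shift", .data$variant == v)[1]
  interference <- function(v) {
    x <- meas(tab, "correct", .data$variant == v,
              .data$probe == "unattended_delay_50")
    y <- meas(tab, "correct", .data$variant == v,
              .data$probe == "unattended_delay_600")
    list(est = mean(x) - mean(y), ci = boot_diff_ci(x, y, level = level))
  }
  mk <- function(check, pass, estimate) {
    tibble::tibble(check = check, estimate = estimate,
                   ci_lo = NA_real_, ci_hi = NA_real_, pass = pass)
  }
  i_full <- interference("full")
  i_nc <- interference("no_conjunctive_layer")
  dplyr::bind_rows(
    mk("full: persistence", persists("full"), NA_real_),
    mk("full: recall well above chance", recall("full") > 0.5,
       recall("full")),
    mk("full: delay interference present", i_full$ci[1] > 0, i_full$est),
    mk("facilitation_only: loses persistence",
       !persists("facilitation_only"), NA_real_),
    mk("no_c_to_f_plasticity: keeps persistence",
       persists("no_c_to_f_plasticity"), NA_real_),
    mk("no_c_to_f_plasticity: loses recall",
       recall("no_c_to_f_plasticity") < 0.4,
       recall("no_c_to_f_plasticity")),
    mk("no_conjunctive_layer: keeps persistence",
       persists("no_conjunctive_layer"), NA_real_),
    mk("no_conjunctive_layer: keeps retro-cue shifting",
       shift("no_conjunctive_layer") > 0, shift("no_conjunctive_layer")),
    # "no loss": the accuracy drop from short to long delay is not
    # detectably positive for this variant
    mk("no_conjunctive_layer: loses delay interference",
       i_nc$ci[1] <= 0, i_nc$est)
  )
}
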