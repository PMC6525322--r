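#' Model parameters for the plastic-attractor network
#'
#' Constructs and validates the full set of network constants: population
#' sizes, the rate nonlinearity, lateral inhibition strengths, the Hebbian
#' learning rate, weight normalization, noise, input drive, readout, and the
#' epoch timing used by trial builders. All times are in dimensionless
#' simulation steps.
#'
#' The canonical configuration (the package default, shipped as
#' `inst/extdata/canonical.yaml`) was fixed by [calibrate()]: it is the
#' configuration under which the whole qualitative battery — attractor
#' persistence, winner uniqueness, capacity, serial position, retro-cueing,
#' pulse effects — expresses.
#'
#' @param n_dims Number of feature dimensions (canonically 3: color,
#'   orientation, location).
#' @param n_feat_per_dim Feature units per dimension (canonically 4).
#' @param n_conj Number of freely-conjunctive units (canonically 4).
#' @param tau Rate relaxation time constant, in steps.
#' @param beta_f Within-dimension lateral inhibition among feature units.
#' @param beta_c Lateral inhibition among conjunctive units.
#' @param eta Hebbian learning rate per step.
#' @param w_init_scale Standard deviation of the initial weight jitter.
#' @param w_norm Target Euclidean norm of each unit's incoming plastic
#'   weight row.
#' @param noise_sigma Standard deviation of the per-unit per-step Gaussian
#'   drive noise.
#' @param gain,threshold Gain and threshold of the rate nonlinearity
#'   (baseline-rectified logistic; see the methods vignette).
#' @param stim_drive External input magnitude during stimulus epochs.
#' @param readout_threshold Rate a report-dimension unit must cross to count
#'   as a behavioral report.
#' @param variant One of `"full"`, `"facilitation_only"`,
#'   `"no_c_to_f_plasticity"`, `"no_conjunctive_layer"`. Only the ablation
#'   experiment uses anything but `"full"`.
#' @param facil_U,facil_tau Increment fraction and decay time constant of the
#'   presynaptic facilitation variable (used only by the
#'   `facilitation_only` variant).
#' @param report_dim Dimension read out behaviorally (canonically 2,
#'   orientation).
#' @param probe_dim Dimension used to probe memory (canonically 1, color).
#' @param timing Named list of epoch durations in steps: `reset`, `stim`,
#'   `gap`, `delay`, `cue`, `pulse`, `probe`, `readout`, `blank`. Partial
#'   lists override the defaults.
#'
#' @return A `wm_params` object (named list).
#' @seealso [canonical_params()], [init_network()], [calibrate()]
#' @examples
#' p <- wm_params(noise_sigma = 0)
#' p$n_dims * p$n_feat_per_dim  # number of feature units
#' @export
wm_params <- function(n_dims = 3L,
                      n_feat_per_dim = 4L,
                      n_conj = 4L,
                      tau = 5,
                      beta_f = 1.4,
                      beta_c = 1.0,
                      eta = 0.02,
                      w_init_scale = 0.02,
                      w_norm = 1,
                      noise_sigma = 0.22,
                      gain = 6,
                      threshold = 0.6,
                      stim_drive = 1,
                      readout_threshold = 0.5,
                      variant = c("full", "facilitation_only",
                                  "no_c_to_f_plasticity",
                                  "no_conjunctive_layer"),
                      facil_U = 0.2,
                      facil_tau = 150,
                      report_dim = 2L,
                      probe_dim = 1L,
                      timing = list()) {
  variant <- match.arg(variant)
  default_timing <- list(reset = 10L, stim = 50L, gap = 10L, delay = 200L,
                         cue = 30L, pulse = 10L, probe = 100L, readout = 50L,
                         blank = 50L)
  bad <- setdiff(names(timing), names(default_timing))
  if (length(bad) > 0) {
    stop("unknown timing keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  default_timing[names(timing)] <- timing
  timing <- lapply(default_timing, function(x) as.integer(x))

  p <- list(
    n_dims = as.integer(n_dims),
    n_feat_per_dim = as.integer(n_feat_per_dim),
    n_conj = as.integer(n_conj),
    tau = as.numeric(tau), beta_f = as.numeric(beta_f),
    beta_c = as.numeric(beta_c), eta = as.numeric(eta),
    w_init_scale = as.numeric(w_init_scale), w_norm = as.numeric(w_norm),
    noise_sigma = as.numeric(noise_sigma), gain = as.numeric(gain),
    threshold = as.numeric(threshold), stim_drive = as.numeric(stim_drive),
    readout_threshold = as.numeric(readout_threshold),
    variant = variant, variant_code = variant_code(variant),
    facil_U = as.numeric(facil_U), facil_tau = as.numeric(facil_tau),
    report_dim = as.integer(report_dim), probe_dim = as.integer(probe_dim),
    timing = timing
  )
  class(p) <- "wm_params"
  validate_params(p)
  p
}

variant_code <- function(variant) {
  match(variant, c("full", "facilitation_only", "no_c_to_f_plasticity",
                   "no_conjunctive_layer")) - 1L
}

validate_params <- function(p) {
  stopifnot(inherits(p, "wm_params"))
  counts <- c(p$n_dims, p$n_feat_per_dim, p$n_conj)
  if (any(counts < 1L)) {
    stop("all population counts must be >= 1", call. = FALSE)
  }
  if (p$tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (p$eta < 0) stop("eta must be >= 0", call. = FALSE)
  if (p$noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (p$w_norm <= 0) stop("w_norm must be > 0", call. = FALSE)
  if (p$w_init_scale < 0) stop("w_init_scale must be >= 0", call. = FALSE)
  if (p$report_dim > p$n_dims || p$probe_dim > p$n_dims) {
    stop("report_dim and probe_dim must index an existing dimension",
         call. = FALSE)
  }
  invisible(p)
}

#' Number of feature units implied by a parameter set
#' @param params A `wm_params` object.
#' @return Integer, `n_dims * n_feat_per_dim`.
#' @export
n_features <- function(params) params$n_dims * params$n_feat_per_dim

#' Canonical calibrated parameters
#'
#' Reads the calibrated canonical configuration shipped with the package
#' (`inst/extdata/canonical.yaml`) and returns it as a [wm_params()] object.
#' Any argument accepted by [wm_params()] can be overridden.
#'
#' @param ... Overrides passed on to [wm_params()].
#' @return A `wm_params` object.
#' @export
canonical_params <- function(...) {
  path <- system.file("extdata", "canonical.yaml", package = "plastwm")
  cfg <- yaml::read_yaml(path)
  over <- list(...)
  cfg[names(over)] <- over
  do.call(wm_params, cfg)
}

#' @export
print.wm_params <- function(x, ...) {
  cat("<wm_params> variant:", x$variant, "\n")
  cat(sprintf("  units: %d dims x %d features + %d conjunctive\n",
              x$n_dims, x$n_feat_per_dim, x$n_conj))
  cat(sprintf("  tau=%g beta_f=%g beta_c=%g eta=%g w_norm=%g\n",
              x$tau, x$beta_f, x$beta_c, x$eta, x$w_norm))
  cat(sprintf("  gain=%g threshold=%g noise_sigma=%g stim_drive=%g\n",
              x$gain, x$threshold, x$noise_sigma, x$stim_drive))
  cat("  timing:", paste(sprintf("%s=%d", names(x$timing),
                                 unlist(x$timing)), collapse = " "), "\n")
  invisible(x)
}

#' Serialize parameters to and from YAML configuration files
#'
#' @param params A `wm_params` object.
#' @param path File path to write to / read from.
#' @return `write_params()` returns `path` invisibly; `read_params()`
#'   returns a `wm_params` object.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  x <- unclass(params)
  x$variant_code <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  cfg$variant_code <- NULL
  do.call(wm_params, cfg)
}

#' Stable hash of a configuration
#'
#' Used to stamp every output artifact so each row of an experiment table is
#' traceable to the exact configuration that produced it.
#'
#' @param x Any R object (typically a `wm_params` or run configuration).
#' @return A short hash string.
#' @export
config_hash <- function(x) {
  if (inherits(x, "wm_params")) x <- unclass(x)
  rlang::hash(x)
}
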