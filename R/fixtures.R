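#' Generate golden regression fixtures
#'
#' Produces small reference traces for regression testing: a one-item
#' encode/delay/probe trial for each model variant, plus a two-item
#' retro-cue trial and a two-item pulse trial for the full model. Each
#' fixture is a tidy trace CSV (downsampled in time) plus the final
#' plastic weight matrices; a manifest records the seed and config hash
#' of every scenario. Regenerating with the same seed reproduces every
#' file bit for bit.
#'
#' @param seed Integer seed.
#' @param dir Output directory.
#' @param every Keep every `every`-th step of each trace.
#' @return The manifest as a tibble, invisibly; files are written to
#'   `dir`.
#' @export
generate_fixtures <- function(seed = 2024L, dir, every = 20L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- canonical_params()
  scen <- list(
    full_one_item = list(variant = "full", kind = "one_item"),
    facilitation_only = list(variant = "facilitation_only",
                             kind = "one_item"),
    no_c_to_f_plasticity = list(variant = "no_c_to_f_plasticity",
                                kind = "one_item"),
    no_conjunctive_layer = list(variant = "no_conjunctive_layer",
                                kind = "one_item"),
    full_retrocue = list(variant = "full", kind = "retrocue"),
    full_pulse = list(variant = "full", kind = "pulse")
  )
  manifest <- list()
  for (nm in names(scen)) {
    sc <- scen[[nm]]
    p <- wm_params_override(base, variant = sc$variant)
    st <- init_network(p, child_seed(seed, match(nm, names(scen))))
    script <- switch(sc$kind,
      one_item = build_trial(make_items(1L, p), p, probe_item = 1L),
      retrocue = build_trial(make_items(2L, p), p, probe_item = 1L,
                             retrocue = list(item = 1L, dim = p$n_dims)),
      pulse = build_trial(make_items(2L, p), p, probe_item = 1L,
                          pulse = list(strength = 1)))
    out <- run_trial(st, script, p, record = TRUE)
    write_trace_csv(out$result$trace, file.path(dir,
                                                paste0(nm, "_trace.csv")),
                    run_id = nm, every = every)
    write_weights_csv(out$state$W_fc,
                      file.path(dir, paste0(nm, "_W_fc.csv")),
                      row_prefix = "c", col_prefix = "f")
    write_weights_csv(out$state$W_cf,
                      file.path(dir, paste0(nm, "_W_cf.csv")),
                      row_prefix = "f", col_prefix = "c")
    manifest[[nm]] <- tibble::tibble(
      scenario = nm, variant = sc$variant, kind = sc$kind,
      steps = script_duration(script), config_hash = config_hash(p))
  }
  manifest <- dplyr::bind_rows(manifest)
  manifest$seed <- seed
  manifest$every <- every
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(manifest)
}
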