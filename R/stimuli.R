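#' Names of the feature dimensions
#'
#' @param params A [wm_params()] object.
#' @return Character vector of dimension names: `color`, `orientation`,
#'   `location` for the canonical three dimensions, `dim1, dim2, ...`
#'   otherwise.
#' @export
dimension_names <- function(params) {
  if (params$n_dims == 3L) c("color", "orientation", "location")
  else paste0("dim", seq_len(params$n_dims))
}

#' Generate stimulus items
#'
#' An item is one feature index per dimension (e.g. a red vertical bar at
#' the top left). By default items within a trial are unique on every
#' dimension, so any single feature identifies its item. The shared-feature
#' mode instead forces two items to share a feature on exactly one
#' dimension, the stress condition under which serial-position structure
#' degrades.
#'
#' Draws from R's current random stream; seed upstream for reproducibility.
#'
#' @param n_items Number of items.
#' @param params A [wm_params()] object.
#' @param unique_per_dim Require all items to differ on every dimension.
#' @param shared_feature If `TRUE` (requires `n_items >= 2`), items 1 and 2
#'   share their feature on one randomly chosen dimension and differ
#'   elsewhere.
#' @return A tibble with one row per item and one column per dimension
#'   (feature indices in `1:n_feat_per_dim`), plus an `item` column.
#' @export
make_items <- function(n_items, params, unique_per_dim = TRUE,
                       shared_feature = FALSE) {
  nf <- params$n_feat_per_dim
  if (unique_per_dim && n_items > nf) {
    stop(sprintf(
      "cannot draw %d items unique per dimension with %d features/dimension",
      n_items, nf), call. = FALSE)
  }
  if (shared_feature && n_items < 2) {
    stop("shared_feature mode needs at least 2 items", call. = FALSE)
  }
  draw <- function() {
    if (unique_per_dim) sample.int(nf, n_items)
    else sample.int(nf, n_items, replace = TRUE)
  }
  m <- vapply(seq_len(params$n_dims), function(d) draw(), integer(n_items))
  m <- matrix(m, nrow = n_items)
  if (shared_feature) {
    d_shared <- sample.int(params$n_dims, 1)
    m[2, d_shared] <- m[1, d_shared]
    for (d in setdiff(seq_len(params$n_dims), d_shared)) {
      if (m[2, d] == m[1, d]) {
        m[2, d] <- sample(setdiff(seq_len(nf), m[1, d]), 1)
      }
    }
  }
  colnames(m) <- dimension_names(params)
  out <- tibble::as_tibble(m)
  out$item <- seq_len(n_items)
  dplyr::relocate(out, "item")
}

#' Feature-unit index of (dimension, feature)
#'
#' Dimension-major layout: unit `(d - 1) * n_feat_per_dim + k` codes
#' feature `k` of dimension `d`.
#'
#' @param dim Dimension index (1-based).
#' @param feat Feature index within the dimension (1-based).
#' @param params A [wm_params()] object.
#' @return Integer unit index into the feature vector.
#' @export
feature_unit <- function(dim, feat, params) {
  stopifnot(all(dim >= 1 & dim <= params$n_dims),
            all(feat >= 1 & feat <= params$n_feat_per_dim))
  as.integer((dim - 1L) * params$n_feat_per_dim + feat)
}

#' External input vector encoding a stimulus item
#'
#' Sensory input activates the item's feature units: `stim_drive` at
#' exactly one unit per dimension, zero elsewhere.
#'
#' @param item A single-row tibble from [make_items()] (or a named list
#'   with one feature index per dimension).
#' @param params A [wm_params()] object.
#' @return Numeric input vector of length `n_features(params)`.
#' @export
encode_input <- function(item, params) {
  dims <- dimension_names(params)
  x <- numeric(n_features(params))
  for (d in seq_along(dims)) {
    x[feature_unit(d, item[[dims[d]]][[1]], params)] <- params$stim_drive
  }
  x
}

#' Input vector driving a single feature
#'
#' Used for probes and incidental retro-cues: `drive` at one feature unit,
#' zero elsewhere.
#'
#' @param dim,feat Dimension and feature index (1-based).
#' @param params A [wm_params()] object.
#' @param drive Input magnitude (default `stim_drive`).
#' @return Numeric input vector.
#' @export
single_feature_input <- function(dim, feat, params, drive = NULL) {
  x <- numeric(n_features(params))
  x[feature_unit(dim, feat, params)] <- drive %||% params$stim_drive
  x
}
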