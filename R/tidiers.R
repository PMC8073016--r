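#' Tidy an attenuation fit
#'
#' @param x An `attenuation_fit`.
#' @param ... Unused.
#' @return The alpha grid with the mean matched-cell correlation at each
#'   candidate value.
#' @export
tidy.attenuation_fit <- function(x, ...) x$grid

#' @rdname tidy.attenuation_fit
#' @export
glance.attenuation_fit <- function(x, ...) {
  tibble(alpha = x$alpha, mean_r = max(x$grid$mean_r),
         n_pairs = nrow(x$pairs),
         intensity_floor = x$intensity_floor)
}

#' Tidy an activity landscape into long format
#'
#' @param x An `activity_landscape`.
#' @param ... Unused.
#' @return Long tibble with `cell`, `site_id`, `activity`, `expressed`,
#'   `variable`.
#' @export
tidy.activity_landscape <- function(x, ...) {
  tibble(
    cell = rep(rownames(x$activity), ncol(x$activity)),
    site_id = rep(colnames(x$activity), each = nrow(x$activity)),
    activity = as.vector(x$activity),
    expressed = as.vector(x$binary),
    variable = as.vector(x$variable)
  )
}

#' @rdname tidy.activity_landscape
#' @export
glance.activity_landscape <- function(x, ...) {
  tibble(
    n_cells = nrow(x$activity),
    n_sites = ncol(x$activity),
    prop_expressed = mean(x$binary, na.rm = TRUE),
    prop_variable = mean(x$variable, na.rm = TRUE),
    prop_missing = mean(is.na(x$activity))
  )
}

#' Tidy a divergence matrix into a pair table
#'
#' @param x A `divergence_matrix`.
#' @param ... Unused.
#' @return Tibble with one row per unordered cell pair: `cell_a`,
#'   `cell_b`, `divergence`, `lineage_distance`, `normalized`.
#' @export
tidy.divergence_matrix <- function(x, ...) .pair_table(x)

#' @rdname tidy.divergence_matrix
#' @export
glance.divergence_matrix <- function(x, ...) {
  ut <- upper.tri(x$D)
  tibble(n_cells = length(x$cells), n_pairs = sum(ut),
         mean_divergence = mean(x$D[ut]),
         normalized = !is.null(x$normalized))
}

#' Tidy transition calls
#'
#' @param x A `transition_calls` object.
#' @param ... Unused.
#' @return The underlying tibble of per-mother statistics.
#' @export
tidy.transition_calls <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "transition_calls")
  attr(out, "skipped") <- NULL
  attr(out, "alpha") <- NULL
  out
}

#' @rdname tidy.transition_calls
#' @export
glance.transition_calls <- function(x, ...) {
  tibble(n_tested = nrow(x), n_transitions = sum(x$is_transition),
         n_skipped = nrow(attr(x, "skipped") %||% tibble()),
         alpha = attr(x, "alpha"))
}

#' Tidy a left-right analysis
#'
#' @param x An `lr_analysis`.
#' @param ... Unused.
#' @return The per-pair tibble.
#' @export
tidy.lr_analysis <- function(x, ...) x$pairs

#' @rdname tidy.lr_analysis
#' @export
glance.lr_analysis <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, fraction_below = x$fraction_below,
         p_value = x$p_value, n_excluded = nrow(x$excluded))
}

#' Tidy co-dynamic clusters
#'
#' @param x A `codynamic_clusters` object.
#' @param ... Unused.
#' @return The site membership tibble.
#' @export
tidy.codynamic_clusters <- function(x, ...) x$sites

#' @rdname tidy.codynamic_clusters
#' @export
glance.codynamic_clusters <- function(x, ...) {
  multi <- x$sites$cluster_size >= 2
  tibble(n_sites = nrow(x$sites),
         n_clusters = length(unique(x$sites$cluster[multi])),
         n_pairs = nrow(x$pairs),
         threshold = x$threshold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
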