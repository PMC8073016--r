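#' Integrate replicate expression values for one cell at one position
#'
#' Expression is accepted only when strictly more than `threshold` (60%) of
#' the observed replicates have a positive value; the untransformed values
#' of all observed replicates (zeros included) are then averaged and
#' `log2(x + 1)` transformed. Otherwise the consensus activity is 0. A
#' cell/position is flagged replicate-variable when the expressed fraction
#' is strictly between 0 and 1. `NA` replicates (cell untraced in that
#' embryo) are excluded from the denominator.
#'
#' @param values Numeric vector of per-replicate instantaneous expression
#'   (untransformed units); `NA` = missing.
#' @param threshold Expressed-fraction threshold (strict >).
#' @return One-row tibble: `activity` (log2), `expressed`, `variable`,
#'   `n_replicates`, `frac_expressed`.
#' @export
integrate_replicates <- function(values, threshold = 0.60) {
  obs <- values[!is.na(values)]
  if (length(obs) == 0) {
    return(tibble(activity = NA_real_, expressed = NA, variable = NA,
                  n_replicates = 0L, frac_expressed = NA_real_))
  }
  frac <- mean(obs > 0)
  expressed <- frac > threshold
  tibble(
    activity = if (expressed) log2(mean(obs) + 1) else 0,
    expressed = expressed,
    variable = frac > 0 && frac < 1,
    n_replicates = length(obs),
    frac_expressed = frac
  )
}

#' Build a cells-by-positions chromatin activity landscape
#'
#' Applies the replicate-integration rule of [integrate_replicates()] to
#' every cell x integration-site combination and assembles the consensus
#' activities into a matrix with cells in lineal order and positions in
#' genome order.
#'
#' @param replicates Long tibble with columns `site_id`, `embryo_id`,
#'   `cell`, `value` (untransformed instantaneous expression; `NA` =
#'   untraced).
#' @param sites Optional site table (`site_id`, `chrom`, `start`, `end`)
#'   used to order positions by genome coordinate.
#' @param cells Optional character vector restricting/ordering the analysis
#'   cells (defaults to all cells present).
#' @param threshold Expressed-fraction threshold.
#' @return An `activity_landscape`: list with matrices `activity`, `binary`,
#'   `variable`, `n_reps`, `frac_expressed`, plus `cells` and `sites`.
#' @export
build_landscape <- function(replicates, sites = NULL, cells = NULL,
                            threshold = 0.60) {
  replicates <- as_tibble(replicates)
  need <- c("site_id", "embryo_id", "cell", "value")
  if (!all(need %in% names(replicates))) {
    abort(sprintf("replicates must have columns %s",
                  paste(need, collapse = ", ")))
  }
  if (!is.null(sites)) {
    sites <- as_tibble(sites)
    if (anyDuplicated(sites$site_id)) {
      abort(sprintf("duplicate site id: %s",
                    sites$site_id[duplicated(sites$site_id)][1]))
    }
    sites <- mutate(sites, mid = (.data$start + .data$end) / 2)
    sites <- sites[order(.chrom_rank(sites$chrom), sites$mid), ]
    site_levels <- sites$site_id
  } else {
    site_levels <- unique(replicates$site_id)
  }
  if (is.null(cells)) {
    cells <- unique(replicates$cell)
    cells <- cells[lineal_order(cells)]
  }
  cons <- replicates %>%
    filter(.data$cell %in% cells, .data$site_id %in% site_levels) %>%
    group_by(.data$site_id, .data$cell) %>%
    summarise(
      n_reps = sum(!is.na(value)),
      frac = ifelse(n_reps > 0, mean(value[!is.na(value)] > 0), NA_real_),
      activity = ifelse(
        !is.na(frac) & frac > threshold,
        log2(mean(value[!is.na(value)]) + 1), 0
      ),
      .groups = "drop"
    ) %>%
    mutate(activity = ifelse(.data$n_reps == 0, NA_real_, .data$activity))
  to_mat <- function(col, default = NA) {
    m <- matrix(default, length(cells), length(site_levels),
                dimnames = list(cells, site_levels))
    m[cbind(match(cons$cell, cells), match(cons$site_id, site_levels))] <-
      cons[[col]]
    m
  }
  activity <- to_mat("activity")
  frac <- to_mat("frac")
  structure(list(
    activity = activity,
    binary = activity > 0,
    variable = frac > 0 & frac < 1,
    n_reps = to_mat("n_reps", 0L),
    frac_expressed = frac,
    cells = cells,
    sites = sites
  ), class = "activity_landscape")
}

.chrom_rank <- function(chrom) {
  canon <- c("I", "II", "III", "IV", "V", "X", "MtDNA")
  r <- match(chrom, canon)
  ifelse(is.na(r), length(canon) + as.integer(factor(chrom)), r)
}

#' @export
print.activity_landscape <- function(x, ...) {
  cat(sprintf(
    "Chromatin activity landscape: %d cells x %d positions (%.0f%% on, %d NA)\n",
    nrow(x$activity), ncol(x$activity),
    100 * mean(x$binary, na.rm = TRUE), sum(is.na(x$activity))
  ))
  invisible(x)
}

#' @export
dim.activity_landscape <- function(x) dim(x$activity)

#' Are two cells' landscapes distinct?
#'
#' Counts the assayed positions at which two cells show a different on/off
#' state, skipping positions flagged replicate-variable (or unmeasured) in
#' either cell, and calls the landscapes distinct when the count reaches
#' `k` (default 5).
#'
#' @param landscape An [build_landscape()] result.
#' @param cell_a,cell_b Cell names (vectors of equal length are compared
#'   pairwise).
#' @param k Minimum number of differing positions.
#' @return Tibble with `cell_a`, `cell_b`, `n_differ`, `n_compared`,
#'   `distinct`.
#' @export
distinct_landscape_test <- function(landscape, cell_a, cell_b, k = 5L) {
  n <- max(length(cell_a), length(cell_b))
  cell_a <- rep_len(cell_a, n)
  cell_b <- rep_len(cell_b, n)
  missing <- setdiff(c(cell_a, cell_b), landscape$cells)
  if (length(missing) > 0) {
    abort(sprintf("cell %s not in landscape", missing[1]))
  }
  out <- purrr::map2(cell_a, cell_b, function(a, b) {
    ba <- landscape$binary[a, ]
    bb <- landscape$binary[b, ]
    va <- landscape$variable[a, ]
    vb <- landscape$variable[b, ]
    use <- !is.na(ba) & !is.na(bb) & !(va %in% TRUE) & !(vb %in% TRUE)
    tibble(n_differ = sum(ba[use] != bb[use]), n_compared = sum(use))
  })
  bind_rows(out) %>%
    mutate(cell_a = cell_a, cell_b = cell_b,
           distinct = .data$n_differ >= k) %>%
    select("cell_a", "cell_b", "n_differ", "n_compared", "distinct")
}

#' Replicate concordance per integration site
#'
#' For every pair of replicate embryos of a site, the Pearson correlation of
#' matched-cell expression and the fraction of matched cells with the same
#' on/off state, averaged over pairs.
#'
#' @param replicates Long tibble as in [build_landscape()].
#' @return Tibble with `site_id`, `n_replicates`, `n_pairs`, `mean_r`,
#'   `mean_consistency`.
#' @export
replicate_concordance <- function(replicates) {
  replicates <- as_tibble(replicates)
  out <- replicates %>%
    group_by(.data$site_id) %>%
    dplyr::group_map(function(sub, key) {
      embs <- unique(sub$embryo_id)
      if (length(embs) < 2) {
        return(tibble(site_id = key$site_id, n_replicates = length(embs),
                      n_pairs = 0L, mean_r = NA_real_,
                      mean_consistency = NA_real_))
      }
      prs <- combn(embs, 2, simplify = FALSE)
      stats <- purrr::map(prs, function(p) {
        a <- filter(sub, .data$embryo_id == p[1])
        b <- filter(sub, .data$embryo_id == p[2])
        m <- inner_join(select(a, "cell", x = "value"),
                        select(b, "cell", y = "value"), by = "cell") %>%
          filter(!is.na(.data$x), !is.na(.data$y))
        tibble(
          r = if (nrow(m) >= 3) suppressWarnings(cor(m$x, m$y)) else NA_real_,
          consistency = if (nrow(m) > 0) mean((m$x > 0) == (m$y > 0)) else NA_real_
        )
      }) %>% bind_rows()
      tibble(site_id = key$site_id, n_replicates = length(embs),
             n_pairs = length(prs),
             mean_r = mean(stats$r, na.rm = TRUE),
             mean_consistency = mean(stats$consistency, na.rm = TRUE))
    }) %>% bind_rows()
  out
}

#' Expression breadth of a landscape
#'
#' @param landscape An [build_landscape()] result.
#' @return List of two tibbles: `sites` (`site_id`,
#'   `prop_cells_expressing`) and `cells` (`cell`, `prop_sites_expressed`).
#' @export
expression_breadth <- function(landscape) {
  b <- landscape$binary
  list(
    sites = tibble(site_id = colnames(b),
                   prop_cells_expressing = unname(colMeans(b, na.rm = TRUE))),
    cells = tibble(cell = rownames(b),
                   prop_sites_expressed = unname(rowMeans(b, na.rm = TRUE)))
  )
}
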