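# fate lookup helper: accepts a named vector, a tibble(cell, fate), or a
# lineage_tree (leaf fates)
.fate_map <- function(fates) {
  if (inherits(fates, "lineage_tree")) {
    lv <- tree_leaves(fates)
    return(setNames(fates$fate[match(lv, fates$cell)], lv))
  }
  if (is.data.frame(fates)) {
    fcol <- intersect(c("fate", "tissue"), names(fates))[1]
    return(setNames(fates[[fcol]], fates$cell))
  }
  fates
}

#' Intra- versus inter-tissue chromatin activity divergence
#'
#' For each tissue, compares divergences between cell pairs of that tissue
#' (intra) with divergences between one cell of the tissue and one of
#' another analysis tissue (inter), by a one-sided Mann-Whitney U test
#' (intra < inter). Because intra-tissue pairs tend to be lineally closer,
#' a lineage-distance-matched control is also computed: `n_draws` seeded
#' resamples of the inter-tissue pairs, each matching the intra-tissue
#' lineage-distance distribution one pair at a time; the reported matched
#' p-value is the median MWU p across draws.
#'
#' @param dm A [divergence_matrix()].
#' @param fates Leaf fates: a [lineage_tree()], a tibble (`cell`, `fate`),
#'   or a named character vector.
#' @param tissues Analysis tissues.
#' @param n_draws Matched-control resamples.
#' @param seed Seed for the resampling.
#' @return Tibble with one row per tissue: set sizes, mean divergences,
#'   `p_inter`, `mean_inter_matched`, `p_matched`.
#' @export
tissue_divergence_analysis <- function(dm, fates,
                                       tissues = tissue_classes(analysis = TRUE),
                                       n_draws = 1000L, seed = 1L) {
  fm <- .fate_map(fates)
  cells <- intersect(dm$cells, names(fm)[fm %in% tissues])
  if (length(cells) < 3) abort("need at least 3 cells with analysis fates")
  pairs <- .pair_table(dm) %>%
    filter(.data$cell_a %in% cells, .data$cell_b %in% cells) %>%
    mutate(fate_a = unname(fm[.data$cell_a]),
           fate_b = unname(fm[.data$cell_b]))
  out <- list()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (t in tissues) {
    intra <- filter(pairs, .data$fate_a == t, .data$fate_b == t)
    inter <- filter(pairs, xor(.data$fate_a == t, .data$fate_b == t))
    if (length(unique(c(intra$cell_a, intra$cell_b))) < 2 ||
        nrow(intra) == 0 || nrow(inter) == 0) {
      next
    }
    p_inter <- suppressWarnings(
      wilcox.test(intra$divergence, inter$divergence,
                  alternative = "less")$p.value)
    pool <- split(inter$divergence, inter$lineage_distance)
    avail <- as.character(intra$lineage_distance) %in% names(pool)
    matched_means <- rep(NA_real_, n_draws)
    matched_p <- rep(NA_real_, n_draws)
    if (any(avail)) {
      keys <- as.character(intra$lineage_distance[avail])
      intra_d <- intra$divergence[avail]
      pool_mat <- matrix(NA_real_, n_draws, length(keys))
      for (k in unique(keys)) {
        cols <- which(keys == k)
        v <- pool[[k]]
        pool_mat[, cols] <- v[sample.int(length(v),
                                         n_draws * length(cols),
                                         replace = TRUE)]
      }
      matched_means <- rowMeans(pool_mat)
      for (b in seq_len(n_draws)) {
        matched_p[b] <- .mwu_less_p(intra_d, pool_mat[b, ])
      }
    }
    out[[length(out) + 1]] <- tibble(
      tissue = t,
      n_cells = sum(fm[cells] == t),
      n_intra = nrow(intra), n_inter = nrow(inter),
      mean_intra = mean(intra$divergence),
      mean_inter = mean(inter$divergence),
      p_inter = p_inter,
      mean_inter_matched = mean(matched_means, na.rm = TRUE),
      p_matched = median(matched_p, na.rm = TRUE),
      n_matched = sum(avail)
    )
  }
  bind_rows(out)
}

# one-sided Mann-Whitney U (x stochastically smaller than y), normal
# approximation with tie correction and continuity correction; used where
# the test is applied once per resampling draw
.mwu_less_p <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  tab <- tabulate(as.integer(2 * r))
  ties <- tab[tab > 1]
  sigma <- sqrt(nx * ny / 12 *
                  ((nx + ny + 1) - sum(ties^3 - ties) /
                     ((nx + ny) * (nx + ny - 1))))
  if (sigma == 0) return(1)
  stats::pnorm((U - mu + 0.5) / sigma)
}

# save/restore global RNG state so seeded analyses do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Left-right symmetric pair divergence versus matched controls
#'
#' For each bilaterally symmetric cell pair, compares its chromatin
#' activity divergence to the mean divergence of other same-tissue pairs at
#' the same lineage distance (the L-R pairs themselves are excluded from
#' the control pool). The per-pair control is the median of the pool, so
#' that under exchangeability a pair falls below its control half the
#' time. Reports the fraction of pairs falling below their control and a
#' one-sided Wilcoxon signed-rank test (pair < control).
#'
#' @param dm A [divergence_matrix()].
#' @param pairs Expanded L-R pairs (tibble `left`, `right`), e.g. from
#'   [expand_symmetric_pairs()]; unpaired rows are ignored.
#' @param fates Leaf fates (see [tissue_divergence_analysis()]).
#' @param tissues Analysis tissues.
#' @return An `lr_analysis` list: `pairs` tibble (with `divergence`,
#'   `control`, `below`), `fraction_below`, `p_value`, `n_pairs`, and
#'   `excluded` (pairs without usable controls or tissue agreement).
#' @export
lr_divergence_analysis <- function(dm, pairs, fates,
                                   tissues = tissue_classes(analysis = TRUE)) {
  fm <- .fate_map(fates)
  pairs <- as_tibble(pairs)
  if ("status" %in% names(pairs)) {
    pairs <- filter(pairs, .data$status == "paired")
  }
  pairs <- filter(pairs, .data$left %in% dm$cells, .data$right %in% dm$cells)
  pt <- .pair_table(dm) %>%
    mutate(fate_a = unname(fm[.data$cell_a]),
           fate_b = unname(fm[.data$cell_b]))
  lr_key <- c(paste(pairs$left, pairs$right), paste(pairs$right, pairs$left))
  pt$is_lr <- paste(pt$cell_a, pt$cell_b) %in% lr_key
  rows <- list()
  excluded <- list()
  for (i in seq_len(nrow(pairs))) {
    l <- pairs$left[i]
    r <- pairs$right[i]
    tl <- unname(fm[l])
    tr <- unname(fm[r])
    if (is.na(tl) || is.na(tr) || tl != tr || !tl %in% tissues) {
      excluded[[length(excluded) + 1]] <-
        tibble(left = l, right = r, reason = "tissue mismatch or non-analysis fate")
      next
    }
    d_lr <- dm$D[l, r]
    ld <- dm$L[l, r]
    ctl <- filter(pt, !.data$is_lr,
                  .data$fate_a == tl, .data$fate_b == tl,
                  .data$lineage_distance == ld,
                  !(.data$cell_a %in% c(l, r)) | !(.data$cell_b %in% c(l, r)))
    if (nrow(ctl) == 0) {
      excluded[[length(excluded) + 1]] <-
        tibble(left = l, right = r, reason = "no matched same-tissue control pairs")
      next
    }
    rows[[length(rows) + 1]] <- tibble(
      left = l, right = r, tissue = tl, lineage_distance = ld,
      divergence = d_lr, control = median(ctl$divergence),
      n_control = nrow(ctl), below = d_lr < median(ctl$divergence)
    )
  }
  if (length(rows) == 0) abort("no L-R pair with usable matched controls")
  res <- bind_rows(rows)
  p <- suppressWarnings(
    wilcox.test(res$divergence, res$control, paired = TRUE,
                alternative = "less")$p.value)
  structure(list(
    pairs = res,
    fraction_below = mean(res$below),
    p_value = p,
    n_pairs = nrow(res),
    excluded = bind_rows(excluded)
  ), class = "lr_analysis")
}

#' @export
print.lr_analysis <- function(x, ...) {
  cat(sprintf(
    "L-R analysis: %d pairs, %.0f%% below matched controls (signed-rank p = %.3g)\n",
    x$n_pairs, 100 * x$fraction_below, x$p_value
  ))
  invisible(x)
}
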