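#' Chromatin activity divergence between two cells
#'
#' Euclidean distance between two activity vectors across all integration
#' sites. Positions unmeasured (`NA`) in either cell are dropped from the
#' sum and the squared distance rescaled by `P / P_used` so divergences stay
#' comparable across coverage.
#'
#' @param x,y Numeric activity vectors of equal length (positions aligned).
#' @return Non-negative divergence, or `NA` if no shared positions.
#' @examples
#' chromatin_divergence(c(3, 0), c(0, 4)) # 5
#' @export
chromatin_divergence <- function(x, y) {
  if (length(x) != length(y)) abort("activity vectors differ in length")
  use <- !is.na(x) & !is.na(y)
  if (!any(use)) return(NA_real_)
  sqrt(sum((x[use] - y[use])^2) * length(x) / sum(use))
}

# pairwise divergence matrix between rows of a matrix, honouring the
# missing-position rescaling; fast path via dist() when complete
.pairwise_divergence <- function(mat) {
  if (!anyNA(mat)) return(as.matrix(dist(mat)))
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    xi <- mat[i, ]
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- chromatin_divergence(xi, mat[j, ])
    }
  }
  D
}

# lineage-distance matrix from cell names via shared root-path prefixes:
# the common-prefix length of two root paths is the depth of the LCA, and
# prefixes equal at level l are equal at every shallower level, so summing
# per-level prefix-id equality gives the LCA depth directly
.lineage_distance_matrix <- function(cells) {
  paths <- cell_root_path(cells)
  depth <- nchar(paths)
  n <- length(cells)
  cpl <- matrix(0L, n, n)
  for (l in seq_len(max(depth))) {
    pid <- ifelse(depth >= l, substr(paths, 1L, l), NA_character_)
    pid_i <- match(pid, unique(pid[!is.na(pid)]))
    eq <- outer(pid_i, pid_i, function(a, b) !is.na(a) & !is.na(b) & a == b)
    cpl <- cpl + eq
  }
  L <- outer(depth, depth, "+") - 2L * cpl
  diag(L) <- 0L
  dimnames(L) <- list(cells, cells)
  L
}

#' Pairwise divergence matrix with lineage-distance annotation
#'
#' @param landscape An [build_landscape()] result, or a numeric matrix of
#'   activities with cell names as row names.
#' @return A `divergence_matrix`: list with `D` (divergences), `L`
#'   (lineage distances), `cells`, and `normalized` (`NULL` until
#'   [normalize_by_lineage_distance()] is applied).
#' @export
divergence_matrix <- function(landscape) {
  mat <- if (inherits(landscape, "activity_landscape")) landscape$activity
         else as.matrix(landscape)
  if (is.null(rownames(mat))) abort("activity matrix needs cell row names")
  structure(list(
    D = .pairwise_divergence(mat),
    L = .lineage_distance_matrix(rownames(mat)),
    cells = rownames(mat),
    normalized = NULL,
    stratum_means = NULL
  ), class = "divergence_matrix")
}

#' @export
print.divergence_matrix <- function(x, ...) {
  cat(sprintf("Divergence matrix over %d cells (lineage distances %d..%d)%s\n",
              length(x$cells), min(x$L[upper.tri(x$L)]),
              max(x$L), if (is.null(x$normalized)) "" else ", normalized"))
  invisible(x)
}

# upper-triangle pair table of a divergence matrix
.pair_table <- function(dm) {
  idx <- which(upper.tri(dm$D), arr.ind = TRUE)
  tibble(
    cell_a = dm$cells[idx[, 1]],
    cell_b = dm$cells[idx[, 2]],
    divergence = dm$D[idx],
    lineage_distance = dm$L[idx],
    normalized = if (is.null(dm$normalized)) NA_real_ else dm$normalized[idx]
  )
}

#' Summarise divergence by lineage distance
#'
#' Cell pairs at an odd lineage distance involve cells of different
#' generations, so by default only even distances are summarised.
#'
#' @param dm A [divergence_matrix()].
#' @param even_only Keep only even lineage distances (default `TRUE`).
#' @return Tibble with `lineage_distance`, `mean`, `sd`, `n` (`sd` is `NA`
#'   for single-pair strata).
#' @export
divergence_by_lineage_distance <- function(dm, even_only = TRUE) {
  pairs <- .pair_table(dm)
  if (even_only) pairs <- filter(pairs, .data$lineage_distance %% 2 == 0)
  pairs %>%
    group_by(.data$lineage_distance) %>%
    summarise(mean = mean(.data$divergence),
              sd = sd(.data$divergence),
              n = dplyr::n(), .groups = "drop") %>%
    arrange(.data$lineage_distance)
}

#' Normalize divergences by lineage distance
#'
#' Divides each pair's divergence by the mean divergence of all pairs at
#' the same lineage distance, removing the systematic growth of divergence
#' with lineage distance before clustering. Strata with zero mean give
#' undefined (`NA`) normalized values and raise a warning.
#'
#' @param dm A [divergence_matrix()].
#' @return The same object with `normalized` and `stratum_means` filled in.
#' @export
normalize_by_lineage_distance <- function(dm) {
  ut <- upper.tri(dm$D)
  strata <- split(dm$D[ut], dm$L[ut])
  means <- vapply(strata, mean, numeric(1))
  if (any(means == 0)) {
    warn("zero mean divergence in some lineage-distance strata; normalized values undefined there")
  }
  denom <- matrix(means[as.character(dm$L)], nrow(dm$D), ncol(dm$D))
  norm <- dm$D / denom
  norm[denom == 0] <- NA_real_
  diag(norm) <- 0
  dimnames(norm) <- dimnames(dm$D)
  dm$normalized <- norm
  dm$stratum_means <- tibble(lineage_distance = as.integer(names(means)),
                             mean_divergence = unname(means))
  dm
}

# single clustering core shared by cell and position clustering: average-
# linkage agglomeration on the Euclidean distances between rows of `mat`,
# cut at `threshold`; cluster ids are renumbered by first appearance so the
# labelling is deterministic in the input order
.cluster_rows <- function(mat, threshold, linkage = "average") {
  if (nrow(mat) < 2) {
    return(tibble(item = rownames(mat), cluster = seq_len(nrow(mat))))
  }
  hc <- hclust(dist(mat), method = linkage)
  cl <- cutree(hc, h = threshold)
  relabel <- match(cl, unique(cl))
  tibble(item = rownames(mat), cluster = relabel)
}

#' Cluster cells by normalized chromatin activity divergence
#'
#' Hierarchical agglomerative clustering (Euclidean metric between rows of
#' the lineage-distance-normalized divergence matrix, average linkage), cut
#' at a fixed distance threshold (default 4.5).
#'
#' @param dm A [divergence_matrix()]; normalized on the fly if needed.
#' @param threshold Tree cut height.
#' @param linkage Linkage method for [stats::hclust()].
#' @return Tibble with `cell`, `cluster` (ids ordered by first appearance).
#' @export
cluster_cells <- function(dm, threshold = 4.5, linkage = "average") {
  if (is.null(dm$normalized)) dm <- normalize_by_lineage_distance(dm)
  if (anyNA(dm$normalized)) {
    abort("normalized divergence matrix has undefined entries")
  }
  .cluster_rows(dm$normalized, threshold, linkage) %>%
    rename(cell = "item")
}

#' Detect transition points of the chromatin activity landscape
#'
#' A cell division is a transition point when the divergences between cells
#' of the two daughter lineages (inter) are significantly larger than the
#' divergences within each daughter lineage (intra): one-sided
#' Mann-Whitney U tests (inter > intra), one per daughter, with
#' Benjamini-Hochberg adjustment across all tests of the run; both adjusted
#' p-values must fall below `alpha` and the mean inter-divergence must
#' exceed each mean intra-divergence. The transition score is the mean over
#' daughters of mean(inter) / mean(intra).
#'
#' @param tree A [lineage_tree()].
#' @param landscape An [build_landscape()] result, an activity matrix, or a
#'   precomputed [divergence_matrix()].
#' @param mothers Candidate mother cells; default all internal cells whose
#'   two daughters each subtend at least `min_leaves` analysis cells.
#' @param min_leaves Minimum analysis cells per daughter lineage.
#' @param alpha Adjusted significance level.
#' @return A `transition_calls` tibble: one row per tested mother with
#'   daughter ids, set sizes, mean divergences, raw and adjusted p-values,
#'   `transition_score` and `is_transition`; skipped mothers are recorded
#'   in `attr(, "skipped")`.
#' @export
detect_transition_points <- function(tree, landscape, mothers = NULL,
                                     min_leaves = 2L, alpha = 0.05) {
  dm <- if (inherits(landscape, "divergence_matrix")) landscape
        else divergence_matrix(landscape)
  analysis_cells <- intersect(tree_leaves(tree), dm$cells)
  kids <- split(tree$cell[!is.na(tree$parent)],
                tree$parent[!is.na(tree$parent)])
  internal <- names(kids)
  if (is.null(mothers)) mothers <- internal
  rows <- list()
  skipped <- list()
  for (m in mothers) {
    if (!m %in% internal) {
      skipped[[length(skipped) + 1]] <- tibble(mother = m, reason = "not an internal cell")
      next
    }
    d12 <- kids[[m]]
    cells1 <- intersect(leaves_under(tree, d12[1]), analysis_cells)
    cells2 <- intersect(leaves_under(tree, d12[2]), analysis_cells)
    if (length(cells1) < min_leaves || length(cells2) < min_leaves) {
      skipped[[length(skipped) + 1]] <- tibble(
        mother = m, reason = sprintf("daughter with < %d analysis cells", min_leaves))
      next
    }
    D1 <- dm$D[cells1, cells1, drop = FALSE]
    D2 <- dm$D[cells2, cells2, drop = FALSE]
    intra1 <- D1[upper.tri(D1)]
    intra2 <- D2[upper.tri(D2)]
    inter <- as.vector(dm$D[cells1, cells2, drop = FALSE])
    p1 <- suppressWarnings(
      wilcox.test(inter, intra1, alternative = "greater")$p.value)
    p2 <- suppressWarnings(
      wilcox.test(inter, intra2, alternative = "greater")$p.value)
    rows[[length(rows) + 1]] <- tibble(
      mother = m, daughter1 = d12[1], daughter2 = d12[2],
      n1 = length(cells1), n2 = length(cells2),
      mean_intra1 = mean(intra1), mean_intra2 = mean(intra2),
      mean_inter = mean(inter),
      p1 = p1, p2 = p2,
      transition_score = mean(mean(inter) / c(mean(intra1), mean(intra2)))
    )
  }
  if (length(rows) == 0) {
    abort("no candidate mother passed the min_leaves requirement")
  }
  calls <- bind_rows(rows)
  adj <- p.adjust(c(calls$p1, calls$p2), method = "BH")
  n <- nrow(calls)
  calls$q1 <- adj[seq_len(n)]
  calls$q2 <- adj[n + seq_len(n)]
  calls$is_transition <- calls$q1 < alpha & calls$q2 < alpha &
    calls$mean_inter > calls$mean_intra1 &
    calls$mean_inter > calls$mean_intra2
  attr(calls, "skipped") <- bind_rows(skipped)
  attr(calls, "alpha") <- alpha
  class(calls) <- c("transition_calls", class(calls))
  calls
}
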