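#' Construct a lineage tree
#'
#' A lineage tree is a tibble with one row per cell: `cell`, `parent`,
#' optional `birth_frame`/`death_frame`, and `fate` (one of Neu, Pha, Ski,
#' Mus, Int, Ger, Dea, Other for terminal cells; `NA` for internal cells).
#' Names are validated against Sulston nomenclature, each non-root cell must
#' have its canonical mother as parent, and every internal cell must have
#' exactly two daughters.
#'
#' @param nodes A data frame with at least `cell` and `parent` columns.
#' @return A `lineage_tree` (a tibble subclass), rows in lineal order.
#' @export
lineage_tree <- function(nodes) {
  nodes <- as_tibble(nodes)
  if (!all(c("cell", "parent") %in% names(nodes))) {
    abort("a lineage tree needs `cell` and `parent` columns")
  }
  if (anyDuplicated(nodes$cell)) {
    abort(sprintf("duplicated cell name: %s",
                  nodes$cell[duplicated(nodes$cell)][1]))
  }
  if (!"fate" %in% names(nodes)) nodes$fate <- NA_character_
  if (!"birth_frame" %in% names(nodes)) nodes$birth_frame <- NA_integer_
  if (!"death_frame" %in% names(nodes)) nodes$death_frame <- NA_integer_
  parse_cell_name(nodes$cell) # validates
  canonical <- cell_parent(nodes$cell)
  root <- is.na(nodes$parent) | !nzchar(nodes$parent)
  bad <- which(!root & nodes$parent != canonical)
  if (length(bad) > 0) {
    abort(sprintf(
      "cell %s lists parent %s but its Sulston mother is %s",
      nodes$cell[bad[1]], nodes$parent[bad[1]], canonical[bad[1]]
    ))
  }
  orphan <- which(!root & !nodes$parent %in% nodes$cell)
  if (length(orphan) > 0) {
    abort(sprintf("parent %s of cell %s is not in the tree",
                  nodes$parent[orphan[1]], nodes$cell[orphan[1]]))
  }
  n_children <- table(nodes$parent[!root])
  wrong <- names(n_children)[n_children != 2L]
  if (length(wrong) > 0) {
    abort(sprintf("internal cell %s has %d daughters (must be 2)",
                  wrong[1], as.integer(n_children[wrong[1]])))
  }
  fates_ok <- is.na(nodes$fate) | nodes$fate %in% tissue_classes()
  if (!all(fates_ok)) {
    abort(sprintf("unknown tissue fate '%s' for cell %s",
                  nodes$fate[!fates_ok][1], nodes$cell[!fates_ok][1]))
  }
  nodes <- nodes[lineal_order(nodes$cell), ]
  nodes <- nodes[, unique(c("cell", "parent", "birth_frame", "death_frame",
                            "fate", names(nodes)))]
  class(nodes) <- c("lineage_tree", class(tibble()))
  nodes
}

#' Tissue classes used throughout the package
#'
#' Terminal cells are classified into neuronal system (Neu), pharynx (Pha),
#' skin (Ski), body wall muscle (Mus), intestine (Int), germline (Ger),
#' programmed cell death (Dea), or Other. Fate and tissue analyses use only
#' the first six; Dea/Other cells are excluded.
#'
#' @param analysis If `TRUE`, return only the six analysis tissues.
#' @return Character vector of class labels.
#' @export
tissue_classes <- function(analysis = FALSE) {
  if (analysis) c("Neu", "Pha", "Ski", "Mus", "Int", "Ger")
  else c("Neu", "Pha", "Ski", "Mus", "Int", "Ger", "Dea", "Other")
}

#' Terminal cells of a lineage tree
#' @param tree A [lineage_tree()].
#' @return Character vector of leaf cell names, in lineal order.
#' @export
tree_leaves <- function(tree) {
  tree$cell[!tree$cell %in% tree$parent]
}

#' Descendants of a cell within a tree
#'
#' @param tree A [lineage_tree()].
#' @param cell A single cell name present in the tree.
#' @param include_self Include `cell` itself?
#' @return Character vector of descendant names in lineal order.
#' @export
tree_descendants <- function(tree, cell, include_self = TRUE) {
  if (!cell %in% tree$cell) abort(sprintf("cell %s not in tree", cell))
  kids <- split(tree$cell[!is.na(tree$parent)], tree$parent[!is.na(tree$parent)])
  out <- character(0)
  stack <- cell
  while (length(stack) > 0) {
    x <- stack[[1]]
    stack <- stack[-1]
    out <- c(out, x)
    stack <- c(kids[[x]], stack)
  }
  if (!include_self) out <- setdiff(out, cell)
  out
}

#' Terminal descendants of a cell
#' @inheritParams tree_descendants
#' @return Character vector of leaf names under `cell` (including `cell`
#'   itself if it is a leaf), lineal order.
#' @export
leaves_under <- function(tree, cell) {
  d <- tree_descendants(tree, cell, include_self = TRUE)
  intersect(d, tree_leaves(tree))
}

#' Developmental fate profile of a progenitor
#'
#' The fate of a progenitor is represented retrospectively as the pattern of
#' tissue types of its terminal descendants in lineal order. Each leaf is
#' keyed by its division path relative to the progenitor, encoded as a 0/1
#' string (0 = anterior/left/dorsal daughter).
#'
#' @param tree A [lineage_tree()].
#' @param cell Progenitor cell name.
#' @return A tibble with columns `leaf`, `path`, `fate`, in lineal order.
#' @export
fate_profile <- function(tree, cell) {
  lv <- leaves_under(tree, cell)
  if (length(lv) == 0) abort(sprintf("cell %s not in tree", cell))
  root_path <- cell_root_path(cell)
  paths <- substring(cell_root_path(lv), nchar(root_path) + 1L)
  fate <- tree$fate[match(lv, tree$cell)]
  tibble(leaf = lv, path = paths, fate = fate)[order(paths, method = "radix"), ]
}

# recursive aligned comparison of two fate patterns keyed by relative 0/1
# paths; returns c(score_sum, n_comparisons)
.align_fates <- function(x, y) {
  if (nrow(x) == 0 || nrow(y) == 0) return(c(0, 0)) # branch empty on one side
  x_leaf <- nrow(x) == 1 && !nzchar(x$path[1])
  y_leaf <- nrow(y) == 1 && !nzchar(y$path[1])
  if (x_leaf && y_leaf) {
    return(c(as.numeric(x$fate[1] == y$fate[1]), 1))
  }
  if (x_leaf) {
    # replicate the shallower side's fate across all opposing leaves
    return(c(sum(y$fate == x$fate[1]), nrow(y)))
  }
  if (y_leaf) {
    return(c(sum(x$fate == y$fate[1]), nrow(x)))
  }
  acc <- c(0, 0)
  for (b in c("0", "1")) {
    xb <- x[startsWith(x$path, b), ]
    yb <- y[startsWith(y$path, b), ]
    xb$path <- substring(xb$path, 2L)
    yb$path <- substring(yb$path, 2L)
    acc <- acc + .align_fates(xb, yb)
  }
  acc
}

#' Fate divergence between two progenitors
#'
#' Aligns the two fate profiles branch by branch (replicating the shallower
#' side's leaf fate across the opposing subtree where the trees differ in
#' depth), scores each aligned leaf pair 1 if the tissues match and 0
#' otherwise, and returns 1 minus the mean score. Dea/Other leaves are
#' removed from both profiles first; a branch present on only one side after
#' removal contributes no comparisons.
#'
#' @param x,y Fate profiles from [fate_profile()].
#' @param exclude Fates dropped before alignment.
#' @return A value in \[0, 1\], or `NA` (with a warning) if no comparable
#'   leaves remain.
#' @export
fate_divergence <- function(x, y, exclude = c("Dea", "Other")) {
  x <- x[!x$fate %in% exclude, ]
  y <- y[!y$fate %in% exclude, ]
  res <- .align_fates(x, y)
  if (res[2] == 0) {
    warn("no comparable leaves after exclusions; fate divergence undefined")
    return(NA_real_)
  }
  1 - res[1] / res[2]
}

#' Identify clonal tissue lineages
#'
#' For each tissue, the probability that a progenitor differentiates into
#' that tissue is computed bottom-up: a terminal cell scores 1 for its own
#' tissue (0 for every tissue if it is Dea/Other), and each progenitor's
#' probability is the unweighted mean of its two daughters' probabilities.
#' The most-rootward progenitors with probability > `min_prob` producing at
#' least `min_leaves` terminal cells of the tissue are reported; descendants
#' of a reported clone are not reported again for the same tissue.
#'
#' @param tree A [lineage_tree()].
#' @param tissues Tissues to scan (default the five major somatic tissues).
#' @param min_prob Probability threshold (strictly greater than).
#' @param min_leaves Minimum number of terminal cells of the tissue.
#' @return Tibble with `progenitor`, `tissue`, `probability`,
#'   `n_leaves_tissue`, `n_leaves`.
#' @export
identify_clonal_tissue_lineages <- function(tree,
                                            tissues = c("Neu", "Pha", "Ski",
                                                        "Mus", "Int"),
                                            min_prob = 0.85,
                                            min_leaves = 3L) {
  cells <- tree$cell
  leaves <- tree_leaves(tree)
  is_leaf <- cells %in% leaves
  depth <- cell_depth(cells)
  kids <- split(tree$cell[!is.na(tree$parent)], tree$parent[!is.na(tree$parent)])
  prob <- matrix(0, nrow = length(cells), ncol = length(tissues),
                 dimnames = list(cells, tissues))
  cnt <- matrix(0L, nrow = length(cells), ncol = length(tissues),
                dimnames = list(cells, tissues))
  fate <- tree$fate[match(cells, tree$cell)]
  for (i in which(is_leaf)) {
    if (!is.na(fate[i]) && fate[i] %in% tissues) {
      prob[i, fate[i]] <- 1
      cnt[i, fate[i]] <- 1L
    }
  }
  for (i in order(depth, decreasing = TRUE)) {
    if (is_leaf[i]) next
    ch <- kids[[cells[i]]]
    prob[i, ] <- colMeans(prob[ch, , drop = FALSE])
    cnt[i, ] <- colSums(cnt[ch, , drop = FALSE])
  }
  out <- list()
  roots <- cells[is.na(tree$parent) | !nzchar(tree$parent)]
  for (t in tissues) {
    stack <- roots
    while (length(stack) > 0) {
      x <- stack[[1]]
      stack <- stack[-1]
      if (prob[x, t] > min_prob && cnt[x, t] >= min_leaves) {
        out[[length(out) + 1]] <- tibble(
          progenitor = x, tissue = t, probability = prob[x, t],
          n_leaves_tissue = as.integer(cnt[x, t]),
          n_leaves = length(leaves_under(tree, x))
        )
      } else {
        stack <- c(kids[[x]], stack)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(progenitor = character(), tissue = character(),
                  probability = double(), n_leaves_tissue = integer(),
                  n_leaves = integer()))
  }
  bind_rows(out) %>% arrange(.data$tissue, .data$progenitor)
}

#' Expand a registry of left-right symmetric lineage pairs
#'
#' Each registry row names the roots of two bilaterally symmetric lineages.
#' Every descendant of the left root is paired with the right-root cell
#' reached by the mirrored division path (l and r swapped), at all depths
#' including the roots themselves. Cells without a mirrored partner in the
#' tree are reported with status `unpaired_left`/`unpaired_right`.
#'
#' @param registry Tibble with columns `left`, `right` (lineage-root pairs).
#' @param tree A [lineage_tree()].
#' @return Tibble with `left`, `right`, `depth` (divisions below the root
#'   pair), `status`.
#' @export
expand_symmetric_pairs <- function(registry, tree) {
  registry <- as_tibble(registry)
  out <- list()
  for (i in seq_len(nrow(registry))) {
    l0 <- registry$left[i]
    r0 <- registry$right[i]
    if (!l0 %in% tree$cell || !r0 %in% tree$cell) {
      abort(sprintf("registry pair (%s, %s) not in tree", l0, r0))
    }
    dl <- tree_descendants(tree, l0, include_self = TRUE)
    dr <- tree_descendants(tree, r0, include_self = TRUE)
    rel <- substring(dl, nchar(l0) + 1L)
    mirrored <- paste0(r0, chartr("lr", "rl", rel))
    paired <- mirrored %in% dr
    out[[length(out) + 1]] <- tibble(
      left = dl,
      right = ifelse(paired, mirrored, NA_character_),
      depth = nchar(rel),
      status = ifelse(paired, "paired", "unpaired_left")
    )
    rel_r <- substring(dr, nchar(r0) + 1L)
    back <- paste0(l0, chartr("lr", "rl", rel_r))
    miss_r <- !back %in% dl
    if (any(miss_r)) {
      out[[length(out) + 1]] <- tibble(
        left = NA_character_, right = dr[miss_r],
        depth = nchar(rel_r[miss_r]), status = "unpaired_right"
      )
    }
  }
  res <- bind_rows(out)
  if (any(res$status != "paired")) {
    warn(sprintf("%d cells without a mirrored partner",
                 sum(res$status != "paired")))
  }
  res
}

#' Classify a genomic position as chromosome arm or center
#'
#' Positions within 20% of a chromosome at each end are arms; the middle 60%
#' is the center. The 20% boundary itself is assigned to the center (the arm
#' condition is a strict inequality).
#'
#' @param position Numeric vector of coordinates (bp).
#' @param chrom_length Chromosome length(s) in bp (recycled).
#' @return Character vector, `"arm"` or `"center"`.
#' @export
classify_chromosome_region <- function(position, chrom_length) {
  n <- max(length(position), length(chrom_length))
  position <- rep_len(position, n)
  chrom_length <- rep_len(chrom_length, n)
  if (any(position < 0 | position > chrom_length)) {
    abort("position outside [0, chrom_length]")
  }
  ifelse(position < 0.2 * chrom_length | position > 0.8 * chrom_length,
         "arm", "center")
}
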