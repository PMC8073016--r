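#' Chromatin activity co-dynamic position clusters
#'
#' Computes pairwise Euclidean divergences between integration-site columns
#' of the landscape (across cells) and clusters the resulting
#' position-by-position divergence matrix with the same agglomerative core
#' used for cell clustering (Euclidean row metric, average linkage), cut at
#' a fixed threshold (default 65). Clusters with at least two members
#' define co-dynamic site pairs.
#'
#' @param landscape An [build_landscape()] result or an activity matrix
#'   (cells x positions).
#' @param threshold Tree cut height.
#' @param linkage Linkage method.
#' @return A `codynamic_clusters` list: `sites` (tibble `site_id`,
#'   `cluster`, `cluster_size`), `pairs` (tibble `site_a`, `site_b`,
#'   `cluster`), `threshold`.
#' @export
position_codynamic_clusters <- function(landscape, threshold = 65,
                                        linkage = "average") {
  mat <- if (inherits(landscape, "activity_landscape")) landscape$activity
         else as.matrix(landscape)
  if (ncol(mat) < 2) abort("need at least 2 positions")
  D <- .pairwise_divergence(t(mat))
  memb <- .cluster_rows(D, threshold, linkage) %>% rename(site_id = "item")
  memb <- memb %>%
    group_by(.data$cluster) %>%
    mutate(cluster_size = dplyr::n()) %>%
    ungroup()
  multi <- filter(memb, .data$cluster_size >= 2)
  prs <- if (nrow(multi) == 0) {
    tibble(site_a = character(), site_b = character(),
           cluster = integer())
  } else {
    multi %>%
      group_by(.data$cluster) %>%
      dplyr::group_map(function(g, key) {
        cmb <- combn(g$site_id, 2)
        tibble(site_a = cmb[1, ], site_b = cmb[2, ], cluster = key$cluster)
      }) %>% bind_rows()
  }
  structure(list(sites = memb, pairs = prs, threshold = threshold),
            class = "codynamic_clusters")
}

#' @export
print.codynamic_clusters <- function(x, ...) {
  multi <- unique(x$sites$cluster[x$sites$cluster_size >= 2])
  cat(sprintf(
    "Co-dynamic clustering: %d sites, %d multi-site clusters, %d co-dynamic pairs\n",
    nrow(x$sites), length(multi), nrow(x$pairs)
  ))
  invisible(x)
}

#' Chromosomal geometry of co-dynamic site pairs
#'
#' Classifies each pair of sites as linked (< 1 Mb apart on the same
#' chromosome, strict), same chromosome at >= 1 Mb, or on different
#' chromosomes, using interval midpoints.
#'
#' @param pairs Tibble with `site_a`, `site_b` (e.g. from
#'   [position_codynamic_clusters()]).
#' @param sites Site table (`site_id`, `chrom`, `start`, `end`).
#' @param linked_max Linkage distance bound in bp (strict <).
#' @param per_pair Return the per-pair classification instead of the
#'   summary?
#' @return Summary tibble (`category`, `n`, `fraction`) or, with
#'   `per_pair = TRUE`, the pair tibble with a `category` column.
#' @export
codynamic_pair_geometry <- function(pairs, sites, linked_max = 1e6,
                                    per_pair = FALSE) {
  sites <- as_tibble(sites) %>%
    mutate(mid = (.data$start + .data$end) / 2)
  miss <- setdiff(unique(c(pairs$site_a, pairs$site_b)), sites$site_id)
  if (length(miss) > 0) abort(sprintf("unknown site id: %s", miss[1]))
  pa <- match(pairs$site_a, sites$site_id)
  pb <- match(pairs$site_b, sites$site_id)
  cat3 <- case_when(
    sites$chrom[pa] != sites$chrom[pb] ~ "different_chrom",
    abs(sites$mid[pa] - sites$mid[pb]) < linked_max ~ "linked_lt_1Mb",
    TRUE ~ "same_chrom_ge_1Mb"
  )
  out <- as_tibble(pairs) %>% mutate(category = cat3)
  if (per_pair) return(out)
  lv <- c("linked_lt_1Mb", "same_chrom_ge_1Mb", "different_chrom")
  tibble(category = lv,
         n = vapply(lv, function(l) sum(cat3 == l), integer(1),
                    USE.NAMES = FALSE)) %>%
    mutate(fraction = if (nrow(out) > 0) .data$n / nrow(out) else NA_real_)
}

#' Genes within a window centred on each integration site
#'
#' Genes whose transcription start site lies within `window` bp centred on
#' the site midpoint (closed interval on both ends).
#'
#' @param sites Site table (`site_id`, `chrom`, `start`, `end`).
#' @param genes Gene table (`gene`, `chrom`, `tss`).
#' @param window Window width in bp (default 100 kb).
#' @return Tibble with `site_id`, `gene`.
#' @export
genes_in_window <- function(sites, genes, window = 1e5) {
  sites <- as_tibble(sites) %>%
    mutate(mid = (.data$start + .data$end) / 2)
  genes <- as_tibble(genes)
  inner_join(select(sites, "site_id", "chrom", "mid"),
             select(genes, "gene", "chrom", "tss"),
             by = "chrom", relationship = "many-to-many") %>%
    filter(.data$tss >= .data$mid - window / 2,
           .data$tss <= .data$mid + window / 2) %>%
    select("site_id", "gene")
}

#' Hypergeometric observed/expected enrichment
#'
#' The building block of all enrichment tests here: given a universe of
#' items of which `related` carry a label, and a draw of `drawn` items of
#' which `observed` carry it, computes the O/E ratio (observed over the
#' uniform-draw expectation `drawn * related / universe`) and the upper-tail
#' hypergeometric probability of at least `observed` labelled items.
#'
#' @param observed,drawn,related,universe Non-negative integer counts.
#' @return One-row tibble: `observed`, `expected`, `oe`, `p`.
#' @examples
#' hypergeom_enrichment(4, 5, 4, 10) # O/E 2, p = 6/252
#' @export
hypergeom_enrichment <- function(observed, drawn, related, universe) {
  if (drawn == 0 || universe == 0) abort("empty draw or universe")
  expected <- drawn * related / universe
  tibble(
    observed = observed,
    expected = expected,
    oe = if (expected > 0) observed / expected else NA_real_,
    p = phyper(observed - 1, related, universe - related, drawn,
               lower.tail = FALSE)
  )
}

# unordered gene-pair keys for the cross product of two gene sets
.gene_pair_keys <- function(g1, g2) {
  if (length(g1) == 0 || length(g2) == 0) return(character(0))
  grid <- expand.grid(a = g1, b = g2, stringsAsFactors = FALSE)
  grid <- grid[grid$a != grid$b, , drop = FALSE]
  unique(paste(pmin(grid$a, grid$b), pmax(grid$a, grid$b)))
}

#' Enrichment of functionally related genes among co-dynamic site pairs
#'
#' Genes are drawn from windows centred on each site; every co-dynamic site
#' pair contributes the unordered cross pairs of its two gene sets, and the
#' union over all (co-dynamic plus non-co-dynamic) site pairs forms the
#' universe. The fraction of related gene pairs among the co-dynamic-derived
#' set is compared to the universe rate (O/E) with a hypergeometric test.
#'
#' @param codyn_pairs Tibble of co-dynamic site pairs (`site_a`, `site_b`).
#' @param sites Site table; all sites define the non-co-dynamic pairs.
#' @param genes Gene table (`gene`, `chrom`, `tss`).
#' @param relations Tibble of related gene pairs (`gene_a`, `gene_b`;
#'   symmetric).
#' @param window Window width in bp.
#' @param universe `"site_pairs"` (default): gene pairs arising from any
#'   site pair; `"gene_pairs"`: all pairs of window genes.
#' @return One-row tibble with counts, `oe` and `p`.
#' @export
pairwise_functional_enrichment <- function(codyn_pairs, sites, genes,
                                           relations, window = 1e5,
                                           universe = c("site_pairs",
                                                        "gene_pairs")) {
  universe <- match.arg(universe)
  gw <- genes_in_window(sites, genes, window)
  site_genes <- split(gw$gene, gw$site_id)
  pair_keys <- function(prs) {
    if (nrow(prs) == 0) return(character(0))
    unique(unlist(purrr::map2(prs$site_a, prs$site_b, function(a, b) {
      .gene_pair_keys(site_genes[[a]], site_genes[[b]])
    })))
  }
  codyn_keys <- pair_keys(as_tibble(codyn_pairs))
  all_sites <- as_tibble(sites)$site_id
  cmb <- combn(all_sites, 2)
  univ_keys <- if (universe == "site_pairs") {
    pair_keys(tibble(site_a = cmb[1, ], site_b = cmb[2, ]))
  } else {
    .gene_pair_keys(unique(gw$gene), unique(gw$gene))
  }
  univ_keys <- union(univ_keys, codyn_keys)
  rel_keys <- unique(paste(pmin(relations$gene_a, relations$gene_b),
                           pmax(relations$gene_a, relations$gene_b)))
  if (length(codyn_keys) == 0) abort("no eligible gene pairs for co-dynamic sites")
  res <- hypergeom_enrichment(
    observed = sum(codyn_keys %in% rel_keys),
    drawn = length(codyn_keys),
    related = sum(univ_keys %in% rel_keys),
    universe = length(univ_keys)
  )
  mutate(res, n_codyn_gene_pairs = length(codyn_keys),
         n_universe_gene_pairs = length(univ_keys))
}

#' Co-dynamic cluster enrichment in clonal tissue lineages
#'
#' For every analysis cell of each clonal tissue lineage, the sites with
#' active (on) and silenced (off) chromatin are tested for overlap with each
#' multi-site co-dynamic cluster (hypergeometric O/E against a uniform draw
#' from the cell's assayed sites; BH adjustment within the cell across all
#' cluster x state tests). A cluster/state is called enriched in the lineage
#' when it is enriched (O/E > `oe_min`, Q < `q_max`) in at least
#' `min_cell_frac` of the lineage's cells.
#'
#' @param landscape An [build_landscape()] result.
#' @param clonal Clonal lineages (tibble `progenitor`, `tissue`), e.g. from
#'   [identify_clonal_tissue_lineages()].
#' @param clusters Site cluster memberships (tibble `site_id`, `cluster`),
#'   e.g. `position_codynamic_clusters()$sites`; singleton clusters are
#'   ignored.
#' @param tree A [lineage_tree()] for resolving lineage membership.
#' @param oe_min,q_max Enrichment thresholds.
#' @param min_cell_frac Fraction of lineage cells required.
#' @return Tibble with one row per lineage x cluster x state:
#'   `n_cells`, `frac_cells_enriched`, `called`.
#' @export
clonal_lineage_activity_enrichment <- function(landscape, clonal, clusters,
                                               tree, oe_min = 1.5,
                                               q_max = 0.05,
                                               min_cell_frac = 0.5) {
  clusters <- as_tibble(clusters)
  if ("cluster_size" %in% names(clusters)) {
    clusters <- filter(clusters, .data$cluster_size >= 2)
  } else {
    clusters <- clusters %>%
      group_by(.data$cluster) %>%
      filter(dplyr::n() >= 2) %>%
      ungroup()
  }
  cl_sets <- split(clusters$site_id, clusters$cluster)
  out <- list()
  for (i in seq_len(nrow(clonal))) {
    prog <- clonal$progenitor[i]
    cells <- intersect(leaves_under(tree, prog), landscape$cells)
    if (length(cells) == 0) {
      abort(sprintf("clonal lineage %s has no analysis cells", prog))
    }
    per_cell <- list()
    for (cc in cells) {
      b <- landscape$binary[cc, ]
      assayed <- names(b)[!is.na(b)]
      sets <- list(active = names(b)[b %in% TRUE],
                   silent = names(b)[b %in% FALSE])
      tests <- list()
      for (state in names(sets)) {
        s <- sets[[state]]
        if (length(s) == 0) next
        for (cl in names(cl_sets)) {
          cl_in <- intersect(cl_sets[[cl]], assayed)
          if (length(cl_in) == 0) next
          h <- hypergeom_enrichment(
            observed = length(intersect(s, cl_in)),
            drawn = length(s),
            related = length(cl_in),
            universe = length(assayed)
          )
          tests[[length(tests) + 1]] <- mutate(
            h, cell = cc, state = state, cluster = cl)
        }
      }
      if (length(tests) == 0) next
      tt <- bind_rows(tests)
      tt$q <- p.adjust(tt$p, method = "BH")
      tt$enriched <- tt$oe > oe_min & tt$q < q_max
      per_cell[[length(per_cell) + 1]] <- tt
    }
    cell_tab <- bind_rows(per_cell)
    summary <- cell_tab %>%
      group_by(.data$cluster, .data$state) %>%
      summarise(frac_cells_enriched = sum(enriched) / length(cells),
                .groups = "drop") %>%
      mutate(progenitor = prog, tissue = clonal$tissue[i],
             n_cells = length(cells),
             called = .data$frac_cells_enriched >= min_cell_frac)
    out[[length(out) + 1]] <- summary
  }
  bind_rows(out) %>%
    select("progenitor", "tissue", "cluster", "state", "n_cells",
           "frac_cells_enriched", "called")
}

#' Tissue-specific gene enrichment near active versus silenced sites
#'
#' For each clonal tissue lineage, sites active in at least half of the
#' lineage's cells are contrasted with sites silenced in at least half:
#' the density of the lineage's tissue-specific genes among window genes of
#' the active sites is divided by the density near the silenced sites.
#' A one-sided Wilcoxon signed-rank test across lineages asks whether
#' active-site density exceeds silenced-site density.
#'
#' @param landscape An [build_landscape()] result.
#' @param clonal Clonal lineages (tibble `progenitor`, `tissue`).
#' @param tissue_genes Tibble `tissue`, `gene`.
#' @param genes Gene table (`gene`, `chrom`, `tss`).
#' @param tree A [lineage_tree()].
#' @param window Window width in bp.
#' @param min_cell_frac Majority fraction defining lineage-level on/off.
#' @return List with `lineages` (per-lineage densities and ratio; `NA`
#'   ratio flags lineages without silenced sites or window genes) and
#'   `p_value`.
#' @export
tissue_gene_activity_enrichment <- function(landscape, clonal, tissue_genes,
                                            genes, tree, window = 1e5,
                                            min_cell_frac = 0.5) {
  gw <- genes_in_window(landscape$sites, genes, window)
  site_genes <- split(gw$gene, gw$site_id)
  rows <- list()
  for (i in seq_len(nrow(clonal))) {
    prog <- clonal$progenitor[i]
    tis <- clonal$tissue[i]
    cells <- intersect(leaves_under(tree, prog), landscape$cells)
    if (length(cells) == 0) next
    b <- landscape$binary[cells, , drop = FALSE]
    on_frac <- colMeans(b, na.rm = TRUE)
    active <- colnames(b)[!is.na(on_frac) & on_frac >= min_cell_frac]
    silent <- colnames(b)[!is.na(on_frac) & (1 - on_frac) >= min_cell_frac]
    tg <- tissue_genes$gene[tissue_genes$tissue == tis]
    density <- function(ss) {
      g <- unique(unlist(site_genes[intersect(ss, names(site_genes))]))
      if (length(g) == 0) return(NA_real_)
      mean(g %in% tg)
    }
    da <- density(active)
    ds <- density(silent)
    rows[[length(rows) + 1]] <- tibble(
      progenitor = prog, tissue = tis, n_cells = length(cells),
      n_active_sites = length(active), n_silent_sites = length(silent),
      density_active = da, density_silent = ds,
      ratio = if (length(silent) == 0 || is.na(da) || is.na(ds) || ds == 0)
        NA_real_ else da / ds
    )
  }
  lt <- bind_rows(rows)
  ok <- !is.na(lt$density_active) & !is.na(lt$density_silent) &
    lt$n_silent_sites > 0
  p <- if (sum(ok) >= 2) {
    suppressWarnings(wilcox.test(lt$density_active[ok], lt$density_silent[ok],
                                 paired = TRUE,
                                 alternative = "greater")$p.value)
  } else NA_real_
  list(lineages = lt, p_value = p)
}
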