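# adjusted Rand index from the pair-counting contingency table; used to
# compare recovered clusterings with the generator's planted partitions
ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) sum(choose(x, 2))
  si <- ch2(rowSums(tab))
  sj <- ch2(colSums(tab))
  sij <- ch2(as.vector(tab))
  expected <- si * sj / choose(sum(tab), 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# a small tree/config for fast unit tests (~42 terminal cells)
small_config <- function(seed = 1L, ...) {
  sim_config(
    seed = seed,
    founder_depths = c(AB = 4L, MS = 3L, E = 2L, C = 3L, D = 2L),
    clonal_lineages = tibble::tibble(progenitor = c("E", "D"),
                                     tissue = c("Int", "Mus")),
    ...
  )
}

# explicit igraph of a lineage tree, for brute-force oracles independent of
# the name algebra
tree_graph <- function(tree) {
  edges <- tree[!is.na(tree$parent), c("parent", "cell")]
  igraph::graph_from_data_frame(edges, directed = TRUE,
                                vertices = tree$cell)
}

# a tiny hand-built tree: progenitor X with leaves Xaa, Xap, Xp is not a
# valid Sulston founder, so fixtures use real names under AB
toy_tree <- function(fates) {
  cells <- names(fates)
  internal <- unique(unlist(lapply(cells, function(x) {
    sapply(seq_len(nchar(x) - 2), function(k) substr(x, 1, k + 1))
  })))
  internal <- internal[startsWith(internal, "AB")]
  nodes <- union(c("P0", "P1", "AB", internal), cells)
  tb <- tibble::tibble(
    cell = nodes,
    parent = cell_parent(nodes),
    fate = ifelse(nodes %in% cells, fates[nodes], NA_character_)
  )
  tb$parent[tb$cell == "P0"] <- NA
  # keep only nodes whose ancestors are present; P1 needed so P0 has 2 kids
  lineage_tree(tb)
}
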