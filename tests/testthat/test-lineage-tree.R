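test_that("lineage trees validate structure and parenthood", {
  good <- toy_tree(c(ABaa = "Neu", ABap = "Ski", ABp = "Mus"))
  expect_s3_class(good, "lineage_tree")
  expect_setequal(tree_leaves(good), c("ABaa", "ABap", "ABp", "P1"))
  # wrong parent
  bad <- tibble::tibble(cell = c("P0", "AB", "P1", "ABa", "ABp"),
                        parent = c(NA, "P0", "P0", "AB", "AB"))
  bad$parent[4] <- "P1"
  expect_error(lineage_tree(bad), "Sulston mother")
  # an internal cell with one daughter
  bad2 <- tibble::tibble(cell = c("P0", "AB", "P1", "ABa"),
                         parent = c(NA, "P0", "P0", "AB"))
  expect_error(lineage_tree(bad2), "must be 2")
})

test_that("fate profiles read leaves in lineal order", {
  tree <- toy_tree(c(ABaa = "Neu", ABap = "Ski", ABp = "Mus"))
  fp <- fate_profile(tree, "AB")
  expect_equal(fp$leaf, c("ABaa", "ABap", "ABp"))
  expect_equal(fp$fate, c("Neu", "Ski", "Mus"))
  expect_equal(fp$path, c("00", "01", "1"))
  leaf_fp <- fate_profile(tree, "ABaa")
  expect_equal(nrow(leaf_fp), 1)
  expect_equal(leaf_fp$fate, "Neu")
  expect_error(fate_profile(tree, "ABpp"), "not in tree")
})

test_that("fate divergence aligns unequal-depth branches by replication", {
  tx <- toy_tree(c(ABaa = "Neu", ABap = "Ski", ABp = "Mus"))
  ty <- toy_tree(c(ABa = "Neu", ABp = "Mus"))
  x <- fate_profile(tx, "AB")
  y <- fate_profile(ty, "AB")
  # y's anterior leaf is replicated over x's two anterior leaves: matches
  # 2 of 3 aligned leaves
  expect_equal(fate_divergence(x, y), 1 / 3)
  expect_equal(fate_divergence(y, x), 1 / 3)
  expect_equal(fate_divergence(x, x), 0)
  z <- x
  z$fate <- c("Mus", "Int", "Pha")
  expect_equal(fate_divergence(x, z), 1)
})

test_that("fate divergence is invariant under tissue relabeling", {
  tree <- generate_lineage(small_config(seed = 2))$tree
  x <- fate_profile(tree, "ABa")
  y <- fate_profile(tree, "ABp")
  d0 <- fate_divergence(x, y)
  # permute the analysis tissues among themselves (Dea/Other untouched so
  # the exclusion set is unchanged)
  rel2 <- setNames(c("Pha", "Ski", "Mus", "Int", "Ger", "Neu", "Dea",
                     "Other"), tissue_classes())
  x3 <- dplyr::mutate(x, fate = rel2[fate])
  y3 <- dplyr::mutate(y, fate = rel2[fate])
  expect_equal(fate_divergence(x3, y3), d0)
  expect_true(d0 >= 0 && d0 <= 1)
})

test_that("dying cells are excluded and may empty the comparison", {
  tx <- toy_tree(c(ABaa = "Dea", ABap = "Dea", ABp = "Mus"))
  ty <- toy_tree(c(ABa = "Neu", ABp = "Mus"))
  x <- fate_profile(tx, "AB")
  y <- fate_profile(ty, "AB")
  # x's anterior branch vanishes, so y's anterior leaf has no partner:
  # only the posterior Mus/Mus comparison remains
  expect_equal(fate_divergence(x, y), 0)
  all_dead <- dplyr::mutate(x, fate = "Dea")
  expect_warning(d <- fate_divergence(all_dead, y), "undefined")
  expect_true(is.na(d))
})

test_that("clonal probability is the unweighted daughter mean, not the leaf fraction", {
  # one daughter is a single Ski leaf's sibling lineage (1 Neu leaf), the
  # other a balanced 4-leaf Ski subtree: root Ski probability is
  # mean(0, 1) = 0.5, not 4/5
  fates <- c(ABa = "Neu",
             ABpaa = "Ski", ABpap = "Ski", ABppa = "Ski", ABppp = "Ski")
  tree <- toy_tree(fates)
  res <- identify_clonal_tissue_lineages(tree, min_prob = 0.45,
                                         min_leaves = 3)
  ab <- res[res$progenitor == "AB" & res$tissue == "Ski", ]
  expect_equal(ab$probability, 0.5)
  expect_equal(ab$n_leaves_tissue, 4L)
  # at the published threshold the root no longer qualifies; the pure
  # subtree is reported instead
  res2 <- identify_clonal_tissue_lineages(tree)
  expect_true("ABp" %in% res2$progenitor[res2$tissue == "Ski"])
  expect_false("AB" %in% res2$progenitor[res2$tissue == "Ski"])
  expect_equal(res2$probability[res2$progenitor == "ABp"], 1)
})

test_that("clonal lineages are non-nested and recover planted clones", {
  cfg <- small_config(seed = 4)
  lin <- generate_lineage(cfg)
  res <- identify_clonal_tissue_lineages(lin$tree)
  # planted clones are recovered at their planted roots
  expect_true(all(paste(cfg$clonal_lineages$progenitor,
                        cfg$clonal_lineages$tissue) %in%
                    paste(res$progenitor, res$tissue)))
  # non-nested within tissue
  for (t in unique(res$tissue)) {
    progs <- res$progenitor[res$tissue == t]
    for (p in progs) {
      desc <- tree_descendants(lin$tree, p, include_self = FALSE)
      expect_false(any(progs %in% desc))
    }
  }
  expect_true(all(res$probability > 0.85 & res$n_leaves_tissue >= 3))
})

test_that("symmetric pairs expand by path mirroring at all depths", {
  tree <- generate_lineage(sim_config(
    seed = 1, founder_depths = c(AB = 6L, MS = 2L, E = 2L, C = 2L, D = 2L),
    clonal_lineages = tibble::tibble(progenitor = "E", tissue = "Int"),
    transitions = tibble::tibble(mother = "ABa", delta = 5,
                                 frac_positions = 0.3)))$tree
  ex <- expand_symmetric_pairs(tibble::tibble(left = "ABal", right = "ABar"),
                               tree)
  expect_true(all(ex$status == "paired"))
  expect_equal(ex$right[ex$left == "ABalpp"], "ABarpp")
  expect_equal(sort(unique(ex$depth)), 0:4)
  # every left descendant paired exactly once
  expect_equal(anyDuplicated(ex$left), 0L)
})

test_that("the published symmetric pair maps to its depth-3 descendants", {
  # the ASEL/R progenitors arise from the registry pair by appending the
  # mirrored path ppp -> ppp
  rel <- "ppp"
  expect_equal(paste0("ABalppp", rel), "ABalpppppp")
  expect_equal(paste0("ABpraaa", chartr("lr", "rl", rel)), "ABpraaappp")
  expect_identical(lineage_distance("ABalpppppp", "ABpraaappp"), 16L)
})

test_that("asymmetric subtrees are reported as unpaired", {
  nodes <- tibble::tibble(
    cell = c("P0", "AB", "P1", "ABa", "ABp", "ABal", "ABar",
             "ABala", "ABalp"),
    parent = c(NA, "P0", "P0", "AB", "AB", "ABa", "ABa", "ABal", "ABal")
  )
  tree <- lineage_tree(nodes)
  expect_warning(
    ex <- expand_symmetric_pairs(
      tibble::tibble(left = "ABal", right = "ABar"), tree),
    "without a mirrored partner")
  expect_true(all(c("ABala", "ABalp") %in%
                    ex$left[ex$status == "unpaired_left"]))
  expect_equal(ex$status[ex$left == "ABal" & !is.na(ex$left)][1], "paired")
})

test_that("same-depth symmetric pairs sit at even lineage distances", {
  tree <- generate_lineage(small_config(seed = 9))$tree
  ex <- expand_symmetric_pairs(tibble::tibble(left = "ABpl", right = "ABpr"),
                               tree)
  paired <- ex[ex$status == "paired", ]
  expect_true(all(lineage_distance(paired$left, paired$right) %% 2 == 0))
})

test_that("chromosome arms are the outer 20%, boundary assigned to center", {
  expect_equal(classify_chromosome_region(10, 100), "arm")
  expect_equal(classify_chromosome_region(50, 100), "center")
  expect_equal(classify_chromosome_region(20, 100), "center")
  expect_equal(classify_chromosome_region(80, 100), "center")
  expect_equal(classify_chromosome_region(80.5, 100), "arm")
  expect_error(classify_chromosome_region(101, 100), "outside")
})
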