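test_that("chromatin divergence is the Euclidean distance", {
  expect_equal(chromatin_divergence(c(3, 0), c(0, 4)), 5)
  expect_equal(chromatin_divergence(1:5, 1:5), 0)
  perm <- c(3, 1, 4, 2, 5)
  x <- c(1, 0, 2, 5, 3)
  y <- c(0, 2, 2, 1, 4)
  expect_equal(chromatin_divergence(x[perm], y[perm]),
               chromatin_divergence(x, y))
  expect_error(chromatin_divergence(1:3, 1:4), "length")
})

test_that("missing positions are dropped with coverage rescaling", {
  x <- c(3, NA, 1, 2)
  y <- c(0, 5, 1, NA)
  # shared positions 1 and 3; squared sum 9 rescaled by 4/2
  expect_equal(chromatin_divergence(x, y), sqrt(9 * 2))
  expect_true(is.na(chromatin_divergence(c(NA, 1), c(2, NA))))
})

test_that("the divergence matrix matches a naive double loop", {
  set.seed(13)
  cells <- tree_leaves(generate_lineage(small_config())$tree)[1:20]
  mat <- matrix(runif(20 * 8, 0, 5), 20, 8, dimnames = list(cells, NULL))
  mat[sample(length(mat), 15)] <- NA
  dm <- divergence_matrix(mat)
  for (i in 1:19) for (j in (i + 1):20) {
    expect_equal(dm$D[i, j], chromatin_divergence(mat[i, ], mat[j, ]))
  }
  expect_equal(dm$D, t(dm$D))
  expect_true(all(diag(dm$D) == 0))
  # lineage distances agree with the name algebra
  expect_equal(dm$L[2, 5], lineage_distance(cells[2], cells[5]))
})

test_that("divergence grows with lineage distance under pure drift", {
  cfg <- sim_config(
    seed = 5, founder_depths = c(AB = 6L, MS = 4L, E = 3L, C = 4L, D = 3L),
    tissue_convergence = 0, predetermined = FALSE,
    clonal_lineages = tibble::tibble(progenitor = "E", tissue = "Int"),
    transitions = tibble::tibble(mother = character(), delta = numeric(),
                                 frac_positions = numeric()))
  land <- suppressWarnings(
    generate_landscape(generate_lineage(cfg)$tree, cfg))
  dm <- divergence_matrix(land$truth_activity)
  bd <- divergence_by_lineage_distance(dm)
  expect_true(all(bd$lineage_distance %% 2 == 0))
  # non-decreasing up to a small sampling slack at the deepest strata
  expect_true(all(diff(bd$mean) >= -0.03 * head(bd$mean, -1)))
  expect_gt(bd$mean[nrow(bd)], bd$mean[1])
})

test_that("single-pair strata flag an undefined spread", {
  act <- rbind(ABal = c(1, 0), ABar = c(0, 2), ABp = c(3, 3))
  dm <- divergence_matrix(act)
  bd <- divergence_by_lineage_distance(dm, even_only = FALSE)
  expect_true(all(is.na(bd$sd[bd$n == 1])))
})

test_that("lineage-distance normalization has unit stratum means", {
  cfg <- small_config(seed = 12)
  land <- suppressWarnings(
    generate_landscape(generate_lineage(cfg)$tree, cfg))
  dm <- normalize_by_lineage_distance(divergence_matrix(land$truth_activity))
  ut <- upper.tri(dm$normalized)
  strata <- split(dm$normalized[ut], dm$L[ut])
  expect_equal(unname(vapply(strata, mean, numeric(1))),
               rep(1, length(strata)))
  # scaling every activity leaves the normalized matrix unchanged
  dm2 <- normalize_by_lineage_distance(
    divergence_matrix(land$truth_activity * 3))
  expect_equal(dm2$normalized, dm$normalized)
  # all-equal landscapes give zero-mean strata and undefined values
  flat <- matrix(1, 4, 3,
                 dimnames = list(c("ABa", "ABp", "MSa", "MSp"), NULL))
  expect_warning(dmf <- normalize_by_lineage_distance(divergence_matrix(flat)),
                 "zero mean")
  expect_true(all(is.na(dmf$normalized[upper.tri(dmf$normalized)])))
})

test_that("cell clustering respects the threshold limits and input order", {
  cfg <- small_config(seed = 2)
  land <- suppressWarnings(
    generate_landscape(generate_lineage(cfg)$tree, cfg))
  L <- build_landscape(land$replicates, sites = land$sites)
  dm <- normalize_by_lineage_distance(divergence_matrix(L))
  one <- cluster_cells(dm, threshold = 1e9)
  expect_equal(max(one$cluster), 1L)
  singletons <- cluster_cells(dm, threshold = 1e-9)
  expect_equal(max(singletons$cluster), nrow(singletons))
  # permuting the cell order only relabels clusters
  cl <- cluster_cells(dm, threshold = 4.5)
  set.seed(8)
  perm <- sample(length(dm$cells))
  dmp <- normalize_by_lineage_distance(
    divergence_matrix(L$activity[perm, ]))
  clp <- cluster_cells(dmp, threshold = 4.5)
  m <- dplyr::inner_join(cl, clp, by = "cell")
  if (max(m$cluster.x) > 1) {
    expect_equal(ari(m$cluster.x, m$cluster.y), 1)
  } else {
    expect_equal(max(m$cluster.y), 1L)
  }
})

test_that("transition detection flags a planted switch and skips thin mothers", {
  cfg <- sim_config(seed = 1,
                    founder_depths = c(AB = 6L, MS = 4L, E = 3L,
                                       C = 4L, D = 3L))
  tree <- generate_lineage(cfg)$tree
  leaves <- tree_leaves(tree)
  set.seed(42)
  M <- pmax(matrix(rnorm(length(leaves) * 40, 2), length(leaves), 40,
                   dimnames = list(leaves, sprintf("s%02d", 1:40))), 0)
  aff <- sample(40, 12)
  shifted <- intersect(leaves_under(tree, "ABalp"), leaves)
  M[shifted, aff] <- M[shifted, aff] + 2
  calls <- detect_transition_points(tree, M)
  expect_true(calls$is_transition[calls$mother == "ABal"])
  expect_gt(calls$transition_score[calls$mother == "ABal"], 1)
  # a mother whose daughter is a single analysis cell is skipped
  calls2 <- detect_transition_points(tree, M,
                                     mothers = c("ABal", "Eaa"),
                                     min_leaves = 2)
  skipped <- attr(calls2, "skipped")
  expect_true("Eaa" %in% skipped$mother)
  # flagged calls always have inter above both intra means
  flagged <- calls[calls$is_transition, ]
  expect_true(all(flagged$mean_inter > flagged$mean_intra1 &
                    flagged$mean_inter > flagged$mean_intra2))
})

test_that("transition score pins the mean-of-ratios definition", {
  act <- rbind(
    ABaa = c(0, 0), ABap = c(0.5, 0), ABpa = c(4, 3), ABpp = c(4.5, 3),
    MSaa = c(1, 1), MSap = c(1, 1), MSpa = c(1, 1), MSpp = c(1, 1)
  )
  tree <- lineage_tree(tibble::tibble(
    cell = c("P0", "P1", "AB", "EMS", "P2", "MS", "E", "C", "P3",
             "ABa", "ABp", rownames(act)[1:4], "MSa", "MSp",
             rownames(act)[5:8]),
    parent = cell_parent(c("P0", "P1", "AB", "EMS", "P2", "MS", "E", "C",
                           "P3", "ABa", "ABp", rownames(act)[1:4], "MSa",
                           "MSp", rownames(act)[5:8]))
  ))
  calls <- detect_transition_points(tree, act, mothers = "AB")
  i1 <- chromatin_divergence(act["ABaa", ], act["ABap", ])
  i2 <- chromatin_divergence(act["ABpa", ], act["ABpp", ])
  inter <- mean(c(
    chromatin_divergence(act["ABaa", ], act["ABpa", ]),
    chromatin_divergence(act["ABaa", ], act["ABpp", ]),
    chromatin_divergence(act["ABap", ], act["ABpa", ]),
    chromatin_divergence(act["ABap", ], act["ABpp", ])))
  expect_equal(calls$transition_score,
               mean(c(inter / i1, inter / i2)))
})
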