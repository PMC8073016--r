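test_that("identical position columns always share a cluster", {
  act <- cbind(s1 = c(1, 2, 3, 4), s2 = c(1, 2, 3, 4),
               s3 = c(9, 0, 9, 0))
  rownames(act) <- c("ABaa", "ABap", "ABpa", "ABpp")
  cl <- position_codynamic_clusters(act, threshold = 5)
  memb <- setNames(cl$sites$cluster, cl$sites$site_id)
  expect_equal(memb[["s1"]], memb[["s2"]])
  expect_false(memb[["s1"]] == memb[["s3"]])
  expect_equal(nrow(cl$pairs), 1L)
  # a vanishing threshold leaves only singletons (no exactly-identical
  # columns present), hence no pairs
  act2 <- act
  act2[1, 2] <- 1.5
  cl0 <- position_codynamic_clusters(act2, threshold = 1e-12)
  expect_equal(nrow(cl0$pairs), 0L)
})

test_that("cell and position clustering share one agglomerative core", {
  set.seed(7)
  toy <- matrix(runif(36), 6, 6)
  toy <- toy + t(toy)
  diag(toy) <- 0
  rownames(toy) <- colnames(toy) <- paste0("it", 1:6)
  a <- chromoscape:::.cluster_rows(toy, threshold = 1.2)
  b <- chromoscape:::.cluster_rows(toy, threshold = 1.2)
  expect_identical(a, b)
  # the same matrix fed through either public route clusters identically
  hc <- stats::cutree(stats::hclust(stats::dist(toy), "average"), h = 1.2)
  expect_equal(ari(a$cluster, hc), 1)
})

test_that("pair geometry classifies linkage with a strict 1 Mb bound", {
  sites <- tibble::tibble(site_id = c("a", "b", "c", "d"),
                          chrom = c("I", "I", "I", "II"),
                          start = c(0, 5e5, 10e5, 0),
                          end = c(2, 5e5 + 2, 10e5 + 2, 2))
  prs <- tibble::tibble(site_a = c("a", "a", "a"),
                        site_b = c("b", "c", "d"))
  per <- codynamic_pair_geometry(prs, sites, per_pair = TRUE)
  expect_equal(per$category,
               c("linked_lt_1Mb", "same_chrom_ge_1Mb", "different_chrom"))
  summ <- codynamic_pair_geometry(prs, sites)
  expect_equal(sum(summ$fraction), 1)
  expect_equal(summ$n, c(1L, 1L, 1L))
  expect_error(codynamic_pair_geometry(
    tibble::tibble(site_a = "zz", site_b = "a"), sites), "unknown site")
})

test_that("gene windows are closed 100-kb intervals around site midpoints", {
  sites <- tibble::tibble(site_id = "s1", chrom = "I",
                          start = 1e6, end = 1e6)
  genes <- tibble::tibble(
    gene = c("g_in", "g_edge_lo", "g_edge_hi", "g_out", "g_other"),
    chrom = c("I", "I", "I", "I", "II"),
    tss = c(1e6, 1e6 - 5e4, 1e6 + 5e4, 1e6 + 5e4 + 1, 1e6)
  )
  gw <- genes_in_window(sites, genes)
  expect_setequal(gw$gene, c("g_in", "g_edge_lo", "g_edge_hi"))
  expect_equal(nrow(genes_in_window(sites, genes[0, ])), 0L)
})

test_that("hypergeometric enrichment reproduces the closed-form example", {
  h <- hypergeom_enrichment(4, 5, 4, 10)
  expect_equal(h$oe, 2)
  expect_equal(h$p, 6 / 252)
  # drawing everything related gives O/E 1 when all pairs are related
  h1 <- hypergeom_enrichment(5, 5, 10, 10)
  expect_equal(h1$oe, 1)
  expect_equal(h1$p, 1)
})

test_that("hypergeometric p matches brute-force enumeration on small universes", {
  brute <- function(obs, drawn, related, universe) {
    draws <- combn(universe, drawn)
    hits <- colSums(draws <= related) # items 1..related carry the label
    mean(hits >= obs)
  }
  set.seed(31)
  for (i in 1:25) {
    universe <- sample(4:12, 1)
    related <- sample(1:universe, 1)
    drawn <- sample(1:universe, 1)
    obs <- sample(0:min(drawn, related), 1)
    expect_equal(hypergeom_enrichment(obs, drawn, related, universe)$p,
                 brute(obs, drawn, related, universe),
                 tolerance = 1e-12)
  }
})

test_that("planted co-expression relations enrich in co-dynamic pairs", {
  cfg <- sim_config(seed = 2)
  study <- suppressWarnings(simulate_embryo_study(cfg, imaging = FALSE))
  L <- build_landscape(study$replicates, sites = study$sites)
  codyn <- position_codynamic_clusters(L)
  enr <- pairwise_functional_enrichment(
    codyn$pairs, study$sites, study$annotations$genes,
    study$annotations$coexpressed)
  expect_gt(enr$oe, 1.5)
  expect_lt(enr$p, 0.05)
})

test_that("a cell active exactly at one cluster's sites maximises its O/E", {
  sites <- sprintf("s%02d", 1:12)
  act <- matrix(0, 4, 12, dimnames = list(c("ABaa", "ABap", "ABpa", "ABpp"),
                                          sites))
  act[, 1:5] <- 3 # active sites: cluster 1 plus one singleton
  clusters <- tibble::tibble(site_id = sites,
                             cluster = rep(c(1L, 3L, 2L), c(4L, 1L, 7L)))
  tree <- toy_tree(c(ABaa = "Int", ABap = "Int", ABpa = "Int",
                     ABpp = "Int"))
  L <- structure(list(activity = act, binary = act > 0,
                      variable = act > 9, cells = rownames(act),
                      sites = NULL), class = "activity_landscape")
  res <- clonal_lineage_activity_enrichment(
    L, tibble::tibble(progenitor = "AB", tissue = "Int"), clusters, tree)
  on_c1 <- res[res$cluster == "1" & res$state == "active", ]
  expect_equal(on_c1$frac_cells_enriched, 1)
  expect_true(on_c1$called)
  off_c2 <- res[res$cluster == "2" & res$state == "silent", ]
  expect_true(off_c2$called)
})

test_that("uniform random activity yields no lineage enrichment calls", {
  set.seed(17)
  calls <- vapply(1:20, function(s) {
    sites <- sprintf("s%02d", 1:20)
    cells <- paste0("ABa", c("aaa", "aap", "apa", "app",
                             "paa", "pap", "ppa", "ppp"))
    act <- matrix(rbinom(8 * 20, 1, 0.5) * 3, 8, 20,
                  dimnames = list(cells, sites))
    clusters <- tibble::tibble(site_id = sites,
                               cluster = rep(1:4, each = 5))
    fates <- setNames(c(rep("Neu", 8), "Other"), c(cells, "ABp"))
    tree <- toy_tree(fates)
    L <- structure(list(activity = act, binary = act > 0,
                        variable = act > 9, cells = cells, sites = NULL),
                   class = "activity_landscape")
    res <- clonal_lineage_activity_enrichment(
      L, tibble::tibble(progenitor = "ABa", tissue = "Neu"),
      clusters, tree)
    sum(res$called)
  }, numeric(1))
  expect_lte(mean(calls > 0), 0.1)
})

test_that("tissue genes near active sites raise the density ratio", {
  cfg <- sim_config(seed = 3)
  study <- suppressWarnings(simulate_embryo_study(cfg, imaging = FALSE))
  L <- build_landscape(study$replicates, sites = study$sites)
  clonal <- study$truth$clonal_lineages
  res <- tissue_gene_activity_enrichment(
    L, clonal, study$annotations$tissue_genes, study$annotations$genes,
    study$tree)
  ok <- !is.na(res$lineages$ratio)
  expect_true(any(ok))
  expect_true(all(res$lineages$ratio[ok] > 1))
})
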