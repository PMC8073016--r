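#' Configuration for the synthetic embryo study generator
#'
#' Bundles every parameter of the ground-truth generator. The defaults are
#' the study conditions used throughout the package's tests and examples:
#' five founder lineages (AB, MS, E, C, D) at depths giving ~112 terminal
#' cells, 40 integration sites across the six chromosomes, four replicate
#' embryos per site, drift/noise/dropout levels typical of lineage-resolved
#' reporter imaging, and the published imaging constants (attenuation
#' 0.054/plane, 30 planes, centre plane 15). The reporter gain places
#' expressed cells well above the detection cutoff, as observed for the
#' real reporter.
#'
#' @param seed Integer seed; fully determines all generator output.
#' @param founder_depths Named integer vector of division rounds below each
#'   suffixing founder.
#' @param tissues Tissue pool for the stochastic fate process (the planted
#'   clones add Int/Mus/Neu clones on top).
#' @param fate_switch Probability a daughter resamples its tissue at a
#'   division (lineage fate mixing outside planted clones).
#' @param dea_rate Probability a terminal cell undergoes programmed death.
#' @param clonal_lineages Planted clonal tissue lineages (tibble
#'   `progenitor`, `tissue`): all their terminal cells get that tissue.
#' @param lr_pairs Left-right symmetric lineage-root registry (tibble
#'   `left`, `right`); fates are mirrored across each pair.
#' @param predetermined If `TRUE`, mirrored leaf pairs share identical true
#'   activity (L-R predetermination).
#' @param transitions Planted transition mothers (tibble `mother`, `delta`,
#'   `frac_positions`): the second daughter's subtree is shifted by
#'   `delta` log2 units at a `frac_positions` fraction of activity
#'   profiles (a heritable activation event).
#' @param n_sites Number of reporter integration sites.
#' @param codyn_sizes Sizes of the planted co-dynamic site clusters; member
#'   sites of a cluster share one cellular activity profile (chromatin
#'   co-regulation) up to per-site jitter.
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param site_on_prob Probability that a profile is active in a given
#'   tissue (chromatin activity is bimodal: most sites are expressed in a
#'   tissue-specific subset of cells).
#' @param region_flip Probability that a switch region flips a profile's
#'   tissue-level on/off state (chromatin identity resolved by lineage
#'   origin as well as tissue).
#' @param on_level,off_level Mean centroid activity (log2) of a profile in
#'   tissues where it is on / off (the off level is negative and clips to
#'   zero, i.e. silent).
#' @param level_sd SD of the on/off centroid levels.
#' @param baseline_sd SD of the per-profile overall brightness offset.
#' @param drift_sd Per-division SD of the heritable activity random walk.
#' @param codyn_jitter_sd Per-cell SD of the site-specific deviation of a
#'   co-dynamic member site from its shared cluster profile.
#' @param codyn_separation Guaranteed minimum Euclidean separation between
#'   distinct activity profiles, per cell (profiles closer than this by
#'   chance are redrawn so planted singleton sites stay distinguishable).
#' @param tissue_convergence Shrinkage of terminal cells toward their
#'   tissue centroid (0 = none, 1 = full convergence).
#' @param noise_cv Multiplicative replicate noise (lognormal sdlog).
#' @param dropout_rate Probability an expressed cell reads as off in one
#'   replicate.
#' @param miss_rate Probability a cell is untraced in one replicate embryo.
#' @param n_replicates Replicate embryos per integration site.
#' @param alpha_true Per-plane attenuation factor used when rendering
#'   imaging intensities.
#' @param center_plane,n_planes Imaging stack geometry.
#' @param background Additive background intensity (units).
#' @param frames_per_cell Imaged frames per cell cycle.
#' @param gain Intensity units per unit of linear reporter activity.
#' @param imaging_noise_cv Multiplicative per-frame imaging noise.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       founder_depths = c(AB = 8L, MS = 5L, E = 4L,
                                          C = 5L, D = 4L),
                       tissues = c("Neu", "Pha", "Ski", "Mus"),
                       fate_switch = 0.5,
                       dea_rate = 0.03,
                       clonal_lineages = tibble(
                         progenitor = c("E", "D", "ABala"),
                         tissue = c("Int", "Mus", "Neu")),
                       lr_pairs = tibble(left = "ABpl", right = "ABpr"),
                       predetermined = TRUE,
                       transitions = tibble(
                         mother = c("ABa", "MS", "C"),
                         delta = 6, frac_positions = 0.4),
                       n_sites = 40L,
                       codyn_sizes = c(6L, 5L, 5L),
                       chrom_lengths = c(I = 15e6, II = 15e6, III = 14e6,
                                         IV = 17e6, V = 21e6, X = 18e6),
                       site_on_prob = 0.6,
                       region_flip = 0.3,
                       on_level = 7, off_level = -2, level_sd = 1,
                       baseline_sd = 1,
                       drift_sd = 0.8,
                       codyn_jitter_sd = 0.3,
                       codyn_separation = 2.8,
                       tissue_convergence = 0.8,
                       noise_cv = 0.1,
                       dropout_rate = 0.03,
                       miss_rate = 0.05,
                       n_replicates = 4L,
                       alpha_true = 0.054,
                       center_plane = 15L, n_planes = 30L,
                       background = 10,
                       frames_per_cell = 7L,
                       gain = 300,
                       imaging_noise_cv = 0.1) {
  cfg <- as.list(environment())
  rates <- c(cfg$fate_switch, cfg$dea_rate, cfg$tissue_convergence,
             cfg$dropout_rate, cfg$miss_rate)
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  if (any(cfg$founder_depths < 2)) abort("founder depths must be >= 2")
  if (any(cfg$transitions$delta < 0)) abort("transition delta must be >= 0")
  if (sum(cfg$codyn_sizes) > cfg$n_sites) {
    abort("co-dynamic cluster sizes exceed the number of sites")
  }
  if (cfg$seed >= 2^31 - 1e6) abort("seed too large")
  class(cfg) <- "sim_config"
  cfg
}

# division letters at a given depth below a founder: first division a/p,
# second l/r, deeper a/p (a synthetic convention that guarantees l/r-named
# lineages for symmetric-pair plumbing)
.axis_at_depth <- function(d) if (d == 2) c("l", "r") else c("a", "p")

#' Generate a synthetic Sulston-named lineage tree
#'
#' Builds the founder scaffold (P0 through Z2/Z3) with complete binary
#' subtrees below AB, MS, E, C and D, assigns tissue fates by an inherit-
#' or-switch process, plants clonal tissue lineages, applies programmed
#' deaths, and mirrors fates across the configured L-R pairs (Z2/Z3 are
#' germline).
#'
#' @param config A [sim_config()].
#' @return List with `tree` (a [lineage_tree()]), `registry` (the L-R pair
#'   roots) and `planted_clonal` (the planted clone table).
#' @export
generate_lineage <- function(config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  F <- config$frames_per_cell
  scaffold <- tibble(
    cell = c("P0", "AB", "P1", "EMS", "P2", "MS", "E", "C", "P3",
             "D", "P4", "Z2", "Z3"),
    parent = c(NA, "P0", "P0", "P1", "P1", "EMS", "EMS", "P2", "P2",
               "P3", "P3", "P4", "P4")
  )
  rows <- list(scaffold)
  for (f in names(config$founder_depths)) {
    depth <- config$founder_depths[[f]]
    level <- f
    for (d in seq_len(depth)) {
      ax <- .axis_at_depth(d)
      child <- as.vector(rbind(paste0(level, ax[1]), paste0(level, ax[2])))
      rows[[length(rows) + 1]] <- tibble(
        cell = child, parent = rep(level, each = 2)
      )
      level <- child
    }
  }
  nodes <- bind_rows(rows)
  depth <- cell_depth(nodes$cell)
  nodes$birth_frame <- depth * F + 1L
  nodes$death_frame <- (depth + 1L) * F
  # fates: inherit-or-switch down the tree
  fate <- setNames(rep(NA_character_, nrow(nodes)), nodes$cell)
  ord <- order(depth)
  for (i in ord) {
    cell <- nodes$cell[i]
    par <- nodes$parent[i]
    if (is.na(par)) {
      fate[cell] <- sample(config$tissues, 1)
    } else if (is.na(fate[par]) || runif(1) < config$fate_switch) {
      fate[cell] <- sample(config$tissues, 1)
    } else {
      fate[cell] <- fate[par]
    }
  }
  leaves <- nodes$cell[!nodes$cell %in% nodes$parent]
  leaf_fate <- fate[leaves]
  dead <- runif(length(leaves)) < config$dea_rate
  leaf_fate[dead] <- "Dea"
  leaf_fate[leaves %in% c("Z2", "Z3")] <- "Ger"
  tree0 <- lineage_tree(mutate(
    nodes, fate = ifelse(nodes$cell %in% leaves,
                         leaf_fate[nodes$cell], NA_character_)))
  # plant clonal lineages
  for (i in seq_len(nrow(config$clonal_lineages))) {
    prog <- config$clonal_lineages$progenitor[i]
    lv <- leaves_under(tree0, prog)
    tree0$fate[match(lv, tree0$cell)] <- config$clonal_lineages$tissue[i]
  }
  # mirror fates across L-R pairs
  exp_pairs <- expand_symmetric_pairs(config$lr_pairs, tree0)
  prs <- filter(exp_pairs, .data$status == "paired")
  lv_idx <- prs$left %in% tree_leaves(tree0)
  tree0$fate[match(prs$right[lv_idx], tree0$cell)] <-
    tree0$fate[match(prs$left[lv_idx], tree0$cell)]
  list(tree = tree0, registry = config$lr_pairs,
       planted_clonal = config$clonal_lineages)
}

#' Generate a ground-truth activity landscape and replicate measurements
#'
#' Activity is generated per *profile*: each singleton site has its own
#' profile and each co-dynamic cluster shares one (member sites deviate
#' from it only by per-cell jitter, emulating chromatin co-regulation).
#' A profile's true per-cell activity (log2 scale) is a baseline plus a
#' heritable Gaussian random walk along tree edges, a planted switch at
#' each transition mother (second daughter's subtree, a fixed fraction of
#' profiles), and shrinkage of terminal cells toward their tissue
#' centroid; predetermined L-R pairs are copied exactly and values are
#' clipped at 0. Replicates are the untransformed linear activities with
#' multiplicative lognormal noise, Bernoulli on/off dropout and occasional
#' untraced cells.
#'
#' @param tree A [lineage_tree()] from [generate_lineage()].
#' @param config A [sim_config()].
#' @return List with `sites`, `truth_activity` (leaves x sites, log2),
#'   `truth_activity_all` (all nodes), `replicates` (long tibble
#'   `site_id`, `embryo_id`, `cell`, `value`), `codyn_truth`,
#'   `transition_truth`, and `cell_blocks` (the planted cell partition:
#'   tissue crossed with planted-switch history).
#' @export
generate_landscape <- function(tree, config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 1L)
  P <- config$n_sites
  chroms <- names(config$chrom_lengths)
  site_chrom <- rep(chroms, length.out = P)
  pos <- vapply(site_chrom, function(ch)
    round(runif(1, 5e5, config$chrom_lengths[[ch]] - 5e5)), numeric(1),
    USE.NAMES = FALSE)
  sites <- tibble(
    site_id = sprintf("site_%02d", seq_len(P)),
    chrom = site_chrom, start = pos, end = pos + 1
  )
  sites <- sites[order(.chrom_rank(sites$chrom), sites$start), ]
  sites$site_id <- sprintf("site_%02d", seq_len(P)) # ids follow genome order
  # co-dynamic cluster membership
  cl <- rep(0L, P)
  picked <- sample.int(P, sum(config$codyn_sizes))
  cl[picked] <- rep(seq_along(config$codyn_sizes), config$codyn_sizes)
  codyn <- tibble(site_id = sites$site_id, cluster = cl)
  cells <- tree$cell
  depth <- cell_depth(cells)
  kids <- split(tree$cell[!is.na(tree$parent)],
                tree$parent[!is.na(tree$parent)])
  # profiles: one per co-dynamic cluster plus one per singleton site
  nK <- length(config$codyn_sizes)
  profile_of_site <- ifelse(codyn$cluster > 0, codyn$cluster,
                            nK + cumsum(codyn$cluster == 0))
  nProf <- nK + sum(codyn$cluster == 0)
  # heritable random walk along tree edges, one track per profile
  walk <- matrix(0, length(cells), nProf, dimnames = list(cells, NULL))
  for (i in order(depth)) {
    par <- tree$parent[match(cells[i], tree$cell)]
    if (!is.na(par)) {
      walk[cells[i], ] <- walk[par, ] + rnorm(nProf, 0, config$drift_sd)
    }
  }
  base <- rnorm(nProf, 0, config$baseline_sd)
  leaves <- tree_leaves(tree)
  leaf_fate <- tree$fate[match(leaves, tree$cell)]
  leaf_founder <- parse_cell_name(leaves)$founder
  conv_tissues <- unique(stats::na.omit(leaf_fate))
  founders <- unique(leaf_founder)
  # chromatin state is specified jointly by tissue and lineage origin: each
  # profile carries a tissue-level on/off pattern, and each founder lineage
  # flips a fraction of those states (with matching on/off levels shared
  # across strata so unflipped lineages converge to the same centroid)
  nT <- length(conv_tissues)
  leaf_tissue_idx <- match(leaf_fate, conv_tissues)
  # nearly no site is constitutively on or off across all cells, so each
  # profile is active in an intermediate number of tissues
  draw_pattern <- function() {
    s <- runif(nT) < config$site_on_prob
    for (i in 1:50) {
      if (sum(s) >= 2 && sum(s) <= nT - 1) break
      s <- runif(nT) < config$site_on_prob
    }
    s
  }
  s_on <- vapply(seq_len(nProf), function(j) draw_pattern(), logical(nT))
  s_on <- matrix(s_on, nT, nProf)
  l_on <- matrix(rnorm(nT * nProf, config$on_level, config$level_sd),
                 nT, nProf)
  l_off <- matrix(rnorm(nT * nProf, config$off_level, config$level_sd),
                  nT, nProf)
  lam <- config$tissue_convergence
  # planted switches act on a fraction of profiles, at full strength,
  # across the second daughter's whole subtree
  trans <- as_tibble(config$transitions)
  trans_prof <- lapply(seq_len(nrow(trans)), function(i) {
    sample.int(nProf, max(1, round(trans$frac_positions[i] * nProf)))
  })
  flagged_daughter <- if (nrow(trans) > 0) {
    vapply(trans$mother, function(m) kids[[m]][2], character(1))
  } else character(0)
  # a planted switch shifts the activity of its affected profiles by delta
  # across the second daughter's whole subtree: a heritable activation
  # event at those genomic positions
  switch_shift <- matrix(0, length(cells), nProf,
                         dimnames = list(cells, NULL))
  for (h in seq_along(flagged_daughter)) {
    sub <- tree_descendants(tree, flagged_daughter[h], include_self = TRUE)
    switch_shift[sub, trans_prof[[h]]] <-
      switch_shift[sub, trans_prof[[h]]] + trans$delta[h]
  }
  # switch regions partition the terminal cells; beyond the tissue-level
  # pattern, each region re-specifies (flips) a fraction of the states, so
  # chromatin identity is resolved by lineage origin as well as tissue
  leaf_region_idx <- rep(1L, length(leaves))
  for (h in seq_along(flagged_daughter)) {
    under <- leaves %in% leaves_under(tree, flagged_daughter[h])
    leaf_region_idx[under] <- h + 1L
  }
  nR <- length(flagged_daughter) + 1L
  flips <- array(FALSE, dim = c(nT, nR, nProf))
  draw_flips <- function() {
    f <- array(runif(nT * nR) < config$region_flip, dim = c(nT, nR))
    f[, 1] <- FALSE # reference region keeps the tissue pattern
    f
  }
  for (p in seq_len(nProf)) flips[, , p] <- draw_flips()
  leaf_profile <- function(p) {
    state <- xor(s_on[cbind(leaf_tissue_idx, rep(p, length(leaves)))],
                 flips[cbind(leaf_tissue_idx, leaf_region_idx,
                             rep(p, length(leaves)))])
    cent <- ifelse(state, l_on[leaf_tissue_idx, p], l_off[leaf_tissue_idx, p])
    (1 - lam) * (base[p] + walk[leaves, p]) + lam * cent +
      switch_shift[leaves, p]
  }
  W <- vapply(seq_len(nProf), leaf_profile, numeric(length(leaves)))
  rownames(W) <- leaves
  # distinct profiles are guaranteed to be mutually separated after the
  # clip at 0 (the scale on which landscapes are observed): profiles whose
  # cellular patterns are too close by chance get their baseline, centroids
  # and heritable walk redrawn (repulsion), so planted singletons stay
  # singletons
  margin <- config$codyn_separation * sqrt(length(leaves))
  ord_depth <- order(depth)
  redraw_walk <- function(q) {
    for (i in ord_depth) {
      par <- tree$parent[match(cells[i], tree$cell)]
      walk[cells[i], q] <<- if (is.na(par)) 0 else
        walk[par, q] + rnorm(1, 0, config$drift_sd)
    }
  }
  for (iter in seq_len(200L)) {
    Dp <- as.matrix(dist(t(pmax(W, 0))))
    diag(Dp) <- Inf
    close <- which(Dp < margin, arr.ind = TRUE)
    if (nrow(close) == 0) break
    q <- max(close)
    base[q] <- rnorm(1, 0, config$baseline_sd)
    s_on[, q] <- draw_pattern()
    l_on[, q] <- rnorm(nT, config$on_level, config$level_sd)
    l_off[, q] <- rnorm(nT, config$off_level, config$level_sd)
    flips[, , q] <- draw_flips()
    redraw_walk(q)
    W[, q] <- leaf_profile(q)
    if (iter == 200L) warn("profile separation not reached after 200 redraws")
  }
  # all-node activity (unshrunk walk for internal cells, converged leaves)
  Wall <- matrix(rep(base, each = length(cells)), length(cells), nProf) +
    walk + switch_shift
  rownames(Wall) <- cells
  Wall[leaves, ] <- W
  # expand profiles to sites; member sites of a cluster deviate by jitter
  V <- Wall[, profile_of_site, drop = FALSE]
  dimnames(V) <- list(cells, sites$site_id)
  member <- which(codyn$cluster > 0)
  if (length(member) > 0 && config$codyn_jitter_sd > 0) {
    V[, member] <- V[, member] +
      matrix(rnorm(length(cells) * length(member), 0,
                   config$codyn_jitter_sd),
             length(cells), length(member))
  }
  # L-R predetermination: copy left onto right
  if (isTRUE(config$predetermined)) {
    prs <- expand_symmetric_pairs(config$lr_pairs, tree) %>%
      filter(.data$status == "paired", .data$left %in% leaves)
    V[prs$right, ] <- V[prs$left, , drop = FALSE]
  }
  V <- pmax(V, 0)
  truth <- V[leaves, , drop = FALSE]
  # planted cell partition: tissue crossed with switch region (the strata
  # that define a cell's centroid and toggles)
  block <- setNames(rep("", length(leaves)), leaves)
  for (h in seq_along(flagged_daughter)) {
    under <- intersect(leaves_under(tree, flagged_daughter[h]), leaves)
    block[under] <- paste0(block[under], "+", flagged_daughter[h])
  }
  cell_blocks <- tibble(cell = leaves, tissue = leaf_fate,
                        founder = leaf_founder,
                        block = paste0(leaf_fate, block))
  # replicate measurements (one embryo per site x replicate)
  R <- config$n_replicates
  reps <- list()
  A_lin <- 2^truth - 1
  for (r in seq_len(R)) {
    noise <- matrix(exp(rnorm(length(A_lin), 0, config$noise_cv)),
                    nrow(A_lin), ncol(A_lin))
    drop <- matrix(runif(length(A_lin)) < config$dropout_rate,
                   nrow(A_lin), ncol(A_lin))
    val <- A_lin * noise
    val[drop] <- 0
    miss <- matrix(runif(length(A_lin)) < config$miss_rate,
                   nrow(A_lin), ncol(A_lin))
    val[miss] <- NA_real_
    reps[[r]] <- tibble(
      site_id = rep(colnames(truth), each = nrow(truth)),
      embryo_id = paste0(rep(colnames(truth), each = nrow(truth)), "_rep", r),
      cell = rep(rownames(truth), ncol(truth)),
      value = as.vector(val)
    )
  }
  list(
    sites = sites,
    truth_activity = truth,
    truth_activity_all = V,
    replicates = bind_rows(reps),
    codyn_truth = codyn,
    cell_blocks = cell_blocks,
    transition_truth = mutate(trans,
                              daughter = flagged_daughter,
                              profiles = trans_prof)
  )
}

#' Render synthetic nuclei intensity tables for replicate embryos
#'
#' The inverse of the quantification pipeline: cellular reporter content is
#' the mother's final content (the protein is stable over embryogenesis)
#' plus linear accumulation at a rate proportional to the cell's true
#' activity; measured intensities are attenuated by `1/(1+alpha)^(z-c)`
#' with `z` the depth from the objective, on top of a constant background
#' and multiplicative per-frame noise. Each cell keeps one anatomical depth;
#' ventral-near-objective (VNO) and dorsal-near-objective (DNO) embryos
#' place it at mirrored planes.
#'
#' @param tree A [lineage_tree()].
#' @param activity_all True log2 activity for every tree node (matrix from
#'   [generate_landscape()], element `truth_activity_all`), or a single
#'   named numeric vector of per-cell activities for a one-integrant run.
#' @param config A [sim_config()].
#' @param integrants Site ids (columns of `activity_all`) to image;
#'   default all columns.
#' @param embryos_per_orientation Replicate embryos per orientation per
#'   integrant.
#' @return List with `nuclei` and `meta` tibbles (see [read_nuclei()]).
#' @export
generate_imaging <- function(tree, activity_all, config,
                             integrants = NULL,
                             embryos_per_orientation = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 2L)
  if (is.null(dim(activity_all))) {
    activity_all <- matrix(activity_all, ncol = 1,
                           dimnames = list(names(activity_all), "site_01"))
  }
  if (is.null(integrants)) integrants <- colnames(activity_all)
  cells <- tree$cell
  depth_div <- cell_depth(cells)
  F <- config$frames_per_cell
  nP <- config$n_planes
  cc <- config$center_plane
  # anatomical depth of each cell, shared across embryos
  anat <- setNames(sample.int(nP, length(cells), replace = TRUE), cells)
  kids_parent <- setNames(tree$parent, tree$cell)
  meta <- list()
  nuclei <- list()
  for (ig in integrants) {
    A <- config$gain * (2^activity_all[cells, ig] - 1)
    # cumulative content at end of each cell's cycle: inherited + own
    content_end <- setNames(numeric(length(cells)), cells)
    for (i in order(depth_div)) {
      par <- kids_parent[[cells[i]]]
      inherited <- if (is.na(par)) 0 else content_end[[par]]
      content_end[[cells[i]]] <- inherited + A[[cells[i]]]
    }
    inherited_of <- setNames(
      vapply(cells, function(x) {
        par <- kids_parent[[x]]
        if (is.na(par)) 0 else content_end[[par]]
      }, numeric(1)), cells)
    for (orient in c("VNO", "DNO")) {
      for (r in seq_len(embryos_per_orientation)) {
        eid <- sprintf("%s_%s_%d", ig, orient, r)
        z <- if (orient == "VNO") anat else nP + 1L - anat
        t_idx <- rep(seq_len(F), times = length(cells))
        cell_rep <- rep(cells, each = F)
        content <- inherited_of[cell_rep] + A[cell_rep] * t_idx / F
        atten <- (1 + config$alpha_true)^(z[cell_rep] - cc)
        signal <- content / atten *
          exp(rnorm(length(content), 0, config$imaging_noise_cv))
        nuclei[[length(nuclei) + 1]] <- tibble(
          embryo_id = eid,
          frame = rep(depth_div, each = F) * F + t_idx,
          cell = cell_rep,
          x = 50, y = 50,
          z_plane = unname(z[cell_rep]),
          radius_px = 5,
          raw_intensity = config$background + signal,
          background = config$background
        )
        meta[[length(meta) + 1]] <- tibble(
          embryo_id = eid, integrant_id = ig, orientation = orient,
          center_plane = cc, n_planes = nP
        )
      }
    }
  }
  list(nuclei = bind_rows(nuclei), meta = bind_rows(meta))
}

#' Generate synthetic annotation tables
#'
#' Genes are placed uniformly along the chromosomes; co-expression
#' relations are planted preferentially between genes near sites of the
#' same co-dynamic cluster; tissue-specific gene sets are planted near
#' sites active in each planted clonal lineage.
#'
#' @param sites Site table from [generate_landscape()].
#' @param codyn Co-dynamic truth (tibble `site_id`, `cluster`).
#' @param truth_activity Leaves x sites truth matrix.
#' @param tree A [lineage_tree()].
#' @param clonal Planted clonal lineages.
#' @param config A [sim_config()].
#' @param n_genes,rel_in_prob,n_bg_relations,tissue_gene_prob Generator
#'   knobs.
#' @return List with `genes`, `coexpressed`, `categories`, `tissue_genes`.
#' @export
generate_annotations <- function(sites, codyn, truth_activity, tree, clonal,
                                 config, n_genes = 3000L, rel_in_prob = 0.6,
                                 n_bg_relations = 400L,
                                 tissue_gene_prob = 0.6) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 3L)
  chroms <- names(config$chrom_lengths)
  w <- config$chrom_lengths / sum(config$chrom_lengths)
  gchrom <- sample(chroms, n_genes, replace = TRUE, prob = w)
  genes <- tibble(
    gene = sprintf("gene_%03d", seq_len(n_genes)),
    chrom = gchrom,
    tss = vapply(gchrom, function(ch)
      round(runif(1, 1, config$chrom_lengths[[ch]])), numeric(1))
  )
  gw <- genes_in_window(sites, genes, 1e5)
  site_genes <- split(gw$gene, gw$site_id)
  rel <- list()
  for (k in unique(codyn$cluster[codyn$cluster > 0])) {
    ss <- codyn$site_id[codyn$cluster == k]
    if (length(ss) < 2) next
    cmb <- combn(ss, 2)
    for (j in seq_len(ncol(cmb))) {
      g1 <- site_genes[[cmb[1, j]]]
      g2 <- site_genes[[cmb[2, j]]]
      if (is.null(g1) || is.null(g2)) next
      grid <- expand.grid(gene_a = g1, gene_b = g2,
                          stringsAsFactors = FALSE)
      grid <- grid[grid$gene_a != grid$gene_b, , drop = FALSE]
      keep <- runif(nrow(grid)) < rel_in_prob
      rel[[length(rel) + 1]] <- as_tibble(grid[keep, , drop = FALSE])
    }
  }
  bg <- tibble(
    gene_a = sample(genes$gene, n_bg_relations, replace = TRUE),
    gene_b = sample(genes$gene, n_bg_relations, replace = TRUE)
  ) %>% filter(.data$gene_a != .data$gene_b)
  coexpressed <- distinct(bind_rows(rel, bg))
  categories <- tibble(gene = genes$gene,
                       category = sample(sprintf("cat_%02d", 1:20),
                                         n_genes, replace = TRUE))
  tg <- list()
  for (i in seq_len(nrow(clonal))) {
    cells <- intersect(leaves_under(tree, clonal$progenitor[i]),
                       rownames(truth_activity))
    if (length(cells) == 0) next
    on_frac <- colMeans(truth_activity[cells, , drop = FALSE] > 0)
    active <- names(on_frac)[on_frac >= 0.5]
    g <- unique(unlist(site_genes[intersect(active, names(site_genes))]))
    keep <- g[runif(length(g)) < tissue_gene_prob]
    extra <- sample(setdiff(genes$gene, keep), 10)
    tg[[length(tg) + 1]] <- tibble(tissue = clonal$tissue[i],
                                   gene = c(keep, extra))
  }
  list(genes = genes, coexpressed = coexpressed, categories = categories,
       tissue_genes = distinct(bind_rows(tg)))
}

#' Run the full synthetic embryo study generator
#'
#' Chains [generate_lineage()], [generate_landscape()],
#' [generate_imaging()] and [generate_annotations()] and assembles a
#' machine-readable truth sidecar. With `dir` set, writes
#' `lineage.tsv`, `pairs.tsv`, `sites.bed`, `nuclei.tsv`, `meta.tsv`,
#' `replicates.tsv`, annotation TSVs and `truth.json`.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory.
#' @param imaging Render nuclei tables? (The imaging stage dominates run
#'   time; replicate expression tables are always generated.)
#' @param integrants Integrants to image; default the first
#'   `n_imaging_integrants` sites.
#' @param n_imaging_integrants Number of sites imaged when `integrants`
#'   is not given.
#' @param embryos_per_orientation Imaging replicates per orientation.
#' @return List with `tree`, `registry`, `sites`, `replicates`, `nuclei`,
#'   `meta`, `annotations`, `truth`.
#' @export
simulate_embryo_study <- function(config = sim_config(), dir = NULL,
                                  imaging = TRUE, integrants = NULL,
                                  n_imaging_integrants = 2L,
                                  embryos_per_orientation = 1L) {
  lin <- generate_lineage(config)
  land <- generate_landscape(lin$tree, config)
  if (is.null(integrants)) {
    integrants <- head(land$sites$site_id, n_imaging_integrants)
  }
  img <- if (imaging) {
    generate_imaging(lin$tree, land$truth_activity_all, config,
                     integrants = integrants,
                     embryos_per_orientation = embryos_per_orientation)
  } else list(nuclei = NULL, meta = NULL)
  ann <- generate_annotations(land$sites, land$codyn_truth,
                              land$truth_activity, lin$tree,
                              lin$planted_clonal, config)
  truth <- list(
    seed = config$seed,
    alpha_true = config$alpha_true,
    planted_transitions = select(land$transition_truth, "mother",
                                 "daughter", "delta", "frac_positions"),
    codyn_clusters = land$codyn_truth,
    cell_blocks = land$cell_blocks,
    clonal_lineages = lin$planted_clonal,
    predetermined = config$predetermined,
    lr_registry = lin$registry,
    true_activity = land$truth_activity
  )
  out <- list(tree = lin$tree, registry = lin$registry, sites = land$sites,
              replicates = land$replicates, nuclei = img$nuclei,
              meta = img$meta, annotations = ann, truth = truth,
              codyn_truth = land$codyn_truth,
              cell_blocks = land$cell_blocks,
              transition_truth = land$transition_truth)
  if (!is.null(dir)) {
    write_study(out, dir)
  }
  invisible(out)
}
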