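test_that("annular background recovers a uniform background exactly", {
  plane <- matrix(50, 61, 61)
  # bright nucleus disc of radius 5 at the centre
  for (i in 1:61) for (j in 1:61) {
    if (sqrt((i - 31)^2 + (j - 31)^2) <= 5) plane[i, j] <- 400
  }
  expect_equal(annular_background(plane, c(31, 31), 5), 50)
  # a fully disjoint neighbour changes nothing
  nb_far <- data.frame(x = 5, y = 5, radius = 2)
  expect_equal(annular_background(plane, c(31, 31), 5, nb_far), 50)
  # a neighbour covering the whole annulus leaves nothing to measure
  nb_cover <- data.frame(x = 31, y = 31, radius = 20)
  expect_warning(
    bg <- annular_background(plane, c(31, 31), 5, nb_cover), "empty")
  expect_true(is.na(bg))
})

test_that("annular background excludes neighbour nuclei pixels", {
  plane <- matrix(10, 61, 61)
  # a bright neighbour partially overlapping the annulus
  for (i in 1:61) for (j in 1:61) {
    if (sqrt((i - 31)^2 + (j - 40)^2) <= 4) plane[i, j] <- 1000
  }
  with_nb <- annular_background(plane, c(31, 31), 5,
                                data.frame(x = 31, y = 40, radius = 4))
  expect_equal(with_nb, 10)
  without_nb <- annular_background(plane, c(31, 31), 5)
  expect_gt(without_nb, 10)
})

test_that("background subtraction floors at zero", {
  expect_equal(raw_expression(10, 4), 6)
  expect_equal(raw_expression(4, 4), 0)
  expect_equal(raw_expression(3, 5), 0)
  expect_error(raw_expression(3, NA), "background")
})

test_that("attenuation correction boosts deep planes and is invertible", {
  expect_equal(correct_attenuation(10, 15, 0.054), 10)
  expect_equal(correct_attenuation(10, 16, 0.054), 10.54)
  # one plane above and below the centre compose to the identity
  up <- correct_attenuation(1, 16, 0.054)
  down <- correct_attenuation(1, 14, 0.054)
  expect_equal(up * down, 1)
  expect_error(correct_attenuation(1, 31, 0.054), "stack")
})

test_that("division-adjacent frames are dropped from the cell mean", {
  expect_equal(cell_mean_intensity(c(2, 4, 6, 8, 10), k = 1), 6)
  expect_equal(cell_mean_intensity(c(5, 7, 5), k = 1), 7)
  expect_error(cell_mean_intensity(c(5, 7), k = 1), "excluded")
})

test_that("mother subtraction isolates expression in the daughter cycle", {
  expect_equal(instantaneous_expression(20, 5), 15)
  expect_equal(instantaneous_expression(8, 0), 8)
  expect_equal(instantaneous_expression(3, 5), 0)
  expect_equal(instantaneous_expression(3, NA), 3)
})

test_that("the expression cutoff falls back to the published default", {
  expect_equal(estimate_expression_cutoff(NULL), 6.36)
  expect_warning(cut <- estimate_expression_cutoff(rep(0, 10)), "default")
  expect_equal(cut, 6.36)
  expect_equal(estimate_expression_cutoff(rep(0, 200)), 0)
})

test_that("the estimated cutoff matches the analytic null quantile", {
  set.seed(21)
  controls <- abs(rnorm(20000, 0, 2))
  est <- estimate_expression_cutoff(controls, q = 0.01)
  analytic <- qnorm(1 - 0.01 / 2, 0, 2) # |N(0,4)| quantile
  expect_lt(abs(est - analytic) / analytic, 0.05)
})

test_that("cutoff-and-log zeroes sub-threshold values and shifts the rest", {
  expect_equal(apply_cutoff_and_log(6.36, 6.36), 0)
  expect_equal(apply_cutoff_and_log(10, 6.36), 2.2141248, tolerance = 1e-6)
  expect_equal(apply_cutoff_and_log(0, 6.36), 0)
  expect_equal(apply_cutoff_and_log(c(1, 20), 6.36),
               c(0, log2(20 - 6.36 + 1)))
  expect_error(apply_cutoff_and_log(1, -1), ">= 0")
})

test_that("attenuation fitting recovers the generative factor exactly without noise", {
  cfg0 <- small_config(seed = 6, imaging_noise_cv = 0, alpha_true = 0)
  lin <- generate_lineage(cfg0)
  land <- suppressWarnings(generate_landscape(lin$tree, cfg0))
  img <- generate_imaging(lin$tree, land$truth_activity_all, cfg0,
                          integrants = "site_01")
  cells <- summarise_nuclei_cells(img$nuclei)
  fit0 <- fit_attenuation(cells, img$meta, grid = seq(0, 0.06, 0.002))
  expect_equal(fit0$alpha, 0)

  cfg3 <- small_config(seed = 6, imaging_noise_cv = 0, alpha_true = 0.03)
  img3 <- generate_imaging(lin$tree, land$truth_activity_all, cfg3,
                           integrants = "site_01")
  fit3 <- fit_attenuation(summarise_nuclei_cells(img3$nuclei), img3$meta,
                          grid = seq(0, 0.06, 0.002))
  expect_equal(fit3$alpha, 0.03)
})

test_that("the fitted correction never lowers the matched-cell correlation", {
  cfg <- small_config(seed = 8)
  lin <- generate_lineage(cfg)
  land <- suppressWarnings(generate_landscape(lin$tree, cfg))
  img <- generate_imaging(lin$tree, land$truth_activity_all, cfg,
                          integrants = "site_01",
                          embryos_per_orientation = 2)
  fit <- fit_attenuation(summarise_nuclei_cells(img$nuclei), img$meta)
  r_at <- function(a) fit$grid$mean_r[which.min(abs(fit$grid$alpha - a))]
  expect_gte(r_at(fit$alpha), r_at(0))
  expect_equal(fit$alpha, cfg$alpha_true, tolerance = 0.004)
})

test_that("quantify_cells runs the pipeline stages in the fixed order", {
  # two frames cells with a hand-checkable path: background subtraction,
  # then depth correction, then the trimmed mean, then mother subtraction
  nuclei <- tibble::tibble(
    embryo_id = "e1",
    frame = c(1:3, 4:6),
    cell = rep(c("AB", "ABa"), each = 3),
    z_plane = c(15, 15, 15, 16, 16, 16),
    raw_intensity = c(24, 30, 40, 60, 70, 80),
    background = 10
  )
  meta <- tibble::tibble(embryo_id = "e1", integrant_id = "s1",
                         orientation = "other", center_plane = 15,
                         n_planes = 30)
  q <- quantify_cells(nuclei, meta, alpha = 0.054, cutoff = 6.36)
  # AB: net 14,20,30 -> mean of middle frame = 20; last frame net 30
  expect_equal(q$mean_intensity[q$cell == "AB"], 20)
  # ABa: net 50,60,70 at z=16 -> corrected by 1.054; mean = 60 * 1.054
  expect_equal(q$mean_intensity[q$cell == "ABa"], 60 * 1.054)
  # mother's last frame corrected value is subtracted
  expect_equal(q$mother_last[q$cell == "ABa"], 30)
  expect_equal(q$instantaneous[q$cell == "ABa"], 60 * 1.054 - 30)
  expect_equal(q$activity[q$cell == "ABa"],
               log2(60 * 1.054 - 30 - 6.36 + 1))
  # the root cell has no mother contribution
  expect_equal(q$mother_last[q$cell == "AB"], 0)
})

test_that("activity is invariant to a constant added to nucleus and background", {
  nuclei <- tibble::tibble(
    embryo_id = "e1", frame = 1:5, cell = "AB", z_plane = 18,
    raw_intensity = c(30, 35, 40, 45, 50), background = 12
  )
  meta <- tibble::tibble(embryo_id = "e1", integrant_id = "s1",
                         orientation = "VNO", center_plane = 15,
                         n_planes = 30)
  q1 <- quantify_cells(nuclei, meta, alpha = 0.054)
  shifted <- dplyr::mutate(nuclei,
                           raw_intensity = raw_intensity + 100,
                           background = background + 100)
  q2 <- quantify_cells(shifted, meta, alpha = 0.054)
  expect_equal(q1$activity, q2$activity)
})

test_that("attenuation recovery is within one grid step at 10% noise", {
  alphas <- vapply(1:20, function(s) {
    cfg <- small_config(seed = 100 + s)
    lin <- generate_lineage(cfg)
    land <- suppressWarnings(generate_landscape(lin$tree, cfg))
    img <- generate_imaging(lin$tree, land$truth_activity_all, cfg,
                            integrants = "site_01")
    fit <- fit_attenuation(summarise_nuclei_cells(img$nuclei), img$meta)
    fit$alpha
  }, numeric(1))
  expect_lte(median(abs(alphas - 0.054)), 0.002)
})
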