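#' Annular local background around a nucleus
#'
#' Mean pixel value in the annulus between 1.2 and 2 nuclear radii from the
#' nucleus centroid, measured in the centroid's Z plane. Pixels falling
#' within 1.2 times the radius of any neighbouring nucleus are excluded.
#'
#' @param volume A 2D matrix (one plane) or 3D array `[x, y, z]` of pixel
#'   values.
#' @param centroid Numeric `c(x, y)` or `c(x, y, z)` nucleus centroid.
#' @param radius Nucleus radius in pixels.
#' @param neighbors Optional data frame of neighbouring nuclei with columns
#'   `x`, `y`, `radius` (and optionally `z`; neighbours in other planes are
#'   ignored).
#' @param inner,outer Annulus bounds as multiples of `radius`.
#' @return Mean background value, or `NA` (with a warning) if no annulus
#'   pixel survives the exclusions.
#' @export
annular_background <- function(volume, centroid, radius, neighbors = NULL,
                               inner = 1.2, outer = 2) {
  if (length(dim(volume)) == 3) {
    z <- as.integer(round(centroid[3]))
    if (is.na(z) || z < 1 || z > dim(volume)[3]) {
      abort("centroid z outside the stack")
    }
    plane <- volume[, , z]
  } else {
    plane <- volume
    z <- if (length(centroid) >= 3) centroid[3] else NA_real_
  }
  nx <- nrow(plane)
  ny <- ncol(plane)
  dx <- matrix(seq_len(nx) - centroid[1], nx, ny)
  dy <- matrix(seq_len(ny) - centroid[2], nx, ny, byrow = TRUE)
  d <- sqrt(dx^2 + dy^2)
  keep <- d >= inner * radius & d <= outer * radius
  if (!is.null(neighbors) && nrow(neighbors) > 0) {
    nb <- as_tibble(neighbors)
    if ("z" %in% names(nb) && !is.na(z)) {
      nb <- nb[is.na(nb$z) | round(nb$z) == round(z), ]
    }
    for (i in seq_len(nrow(nb))) {
      dn <- sqrt((matrix(seq_len(nx), nx, ny) - nb$x[i])^2 +
                 (matrix(seq_len(ny), nx, ny, byrow = TRUE) - nb$y[i])^2)
      keep <- keep & dn > inner * nb$radius[i]
    }
  }
  if (!any(keep)) {
    warn("annulus empty after neighbour exclusions")
    return(NA_real_)
  }
  mean(plane[keep])
}

#' Background-subtracted raw expression
#'
#' @param raw_intensity,background Numeric vectors (same units); negative
#'   differences are floored at 0.
#' @return Numeric vector of net intensities.
#' @export
raw_expression <- function(raw_intensity, background) {
  if (any(is.na(background))) abort("missing background value")
  pmax(raw_intensity - background, 0)
}

#' Correct an intensity for depth-dependent attenuation
#'
#' Fluorescence is dimmed multiplicatively with imaging depth. With
#' `z_plane` counted as depth from the objective, the measured intensity at
#' plane i is restored to the centre plane c by multiplying by
#' `(1 + alpha)^(i - c)`: cells deeper than the centre are boosted, cells
#' shallower are dimmed, and the correction is the identity at the centre.
#'
#' @param intensity Numeric vector of measured intensities.
#' @param z_plane Integer vector of planes (1..n_planes, increasing away
#'   from the objective).
#' @param alpha Per-plane attenuation factor (>= 0).
#' @param center Centre plane (default 15).
#' @param n_planes Stack size used for range checking (default 30).
#' @return Corrected intensities.
#' @export
correct_attenuation <- function(intensity, z_plane, alpha, center = 15,
                                n_planes = 30) {
  if (any(z_plane < 1 | z_plane > n_planes)) {
    abort("z_plane outside the stack")
  }
  intensity * (1 + alpha)^(z_plane - center)
}

#' Mean cell intensity with division-adjacent frames excluded
#'
#' Reporter signal immediately before and after a cell division is
#' unreliable (chromatin condensation, nuclear envelope breakdown), so `k`
#' frames at each end of a cell's series are dropped before averaging.
#'
#' @param values Numeric vector of per-frame (corrected) intensities in
#'   temporal order.
#' @param k Frames dropped at each end (default 1).
#' @return Mean of the retained frames.
#' @export
cell_mean_intensity <- function(values, k = 1L) {
  n <- length(values)
  if (n <= 2 * k) abort("all frames excluded as division-adjacent")
  mean(values[(k + 1):(n - k)])
}

#' Instantaneous expression by mother subtraction
#'
#' The stable reporter is inherited across divisions, so the mother's last
#' pre-division intensity is subtracted from the daughter's mean to isolate
#' expression during the daughter's own cell cycle (no expression is assumed
#' during division). Lineage entry points have no mother contribution (0).
#' Negative differences are floored at 0.
#'
#' @param cell_mean Daughter mean intensity.
#' @param mother_last Mother's last pre-division intensity (0 if none).
#' @return Instantaneous expression, same units.
#' @export
instantaneous_expression <- function(cell_mean, mother_last = 0) {
  mother_last[is.na(mother_last)] <- 0
  pmax(cell_mean - mother_last, 0)
}

#' Expression cutoff from reporter-free control embryos
#'
#' The empirical `1 - q` quantile of cellular intensities measured in
#' control embryos carrying only the lineaging marker. With no (or too few)
#' controls the published default 6.36 is used.
#'
#' @param control_intensities Numeric vector from control embryos, or
#'   `NULL`.
#' @param q Tail probability (default 0.01).
#' @param default Fallback cutoff.
#' @param min_n Minimum number of control values required.
#' @return Cutoff in intensity units.
#' @export
estimate_expression_cutoff <- function(control_intensities = NULL, q = 0.01,
                                       default = 6.36, min_n = 100L) {
  if (is.null(control_intensities)) return(default)
  if (length(control_intensities) < min_n) {
    warn(sprintf("only %d control values (< %d); using default cutoff %.2f",
                 length(control_intensities), min_n, default))
    return(default)
  }
  unname(quantile(control_intensities, probs = 1 - q, names = FALSE))
}

#' Apply the expression cutoff and log transform
#'
#' Values below the cutoff are set to 0; otherwise the cutoff is subtracted
#' and the result `log2(x + 1)` transformed, giving chromatin activity in
#' log2 units.
#'
#' @param x Instantaneous expression values.
#' @param cutoff Non-negative cutoff.
#' @return Activity values (log2 units, >= 0).
#' @export
apply_cutoff_and_log <- function(x, cutoff) {
  if (cutoff < 0) abort("cutoff must be >= 0")
  ifelse(x < cutoff, 0, log2(pmax(x - cutoff, 0) + 1))
}

# per embryo x cell summary used both for fitting and quantification:
# uncorrected net mean over retained frames, mean z, last-frame net and z
.summarise_nuclei <- function(nuclei, k = 1L) {
  nuclei %>%
    mutate(net = raw_expression(.data$raw_intensity, .data$background)) %>%
    arrange(.data$embryo_id, .data$cell, .data$frame) %>%
    group_by(.data$embryo_id, .data$cell) %>%
    summarise(
      n_frames_total = dplyr::n(),
      usable = n_frames_total > 2 * k,
      mean_net = if (usable) mean(net[(k + 1):(n_frames_total - k)]) else NA_real_,
      mean_z = if (usable) mean(z_plane[(k + 1):(n_frames_total - k)]) else mean(z_plane),
      last_net = net[n_frames_total],
      last_z = z_plane[n_frames_total],
      .groups = "drop"
    )
}

#' Fit the per-plane attenuation factor from opposite-orientation replicates
#'
#' Embryos lie with either the ventral (VNO) or dorsal (DNO) side near the
#' objective, so the same cell is imaged at mirrored depths in the two
#' orientations. For each candidate alpha on a grid, cellular intensities
#' are depth-corrected and the Pearson correlation of matched cells between
#' every VNO/DNO replicate pair of the same integrant is computed; the alpha
#' maximising the mean correlation is returned (ties resolved toward the
#' smallest alpha). Only cells whose uncorrected mean intensity exceeds
#' `intensity_floor` in both pair members enter the objective, but the
#' fitted correction is meant to be applied to all cells.
#'
#' @param cells Tibble with `embryo_id`, `cell`, `intensity` (uncorrected
#'   net mean) and `z` (mean plane), e.g. from [quantify_cells()]
#'   intermediates or [summarise_nuclei_cells()].
#' @param meta Embryo metadata: `embryo_id`, `integrant_id`, `orientation`
#'   (VNO/DNO/other), `center_plane`, `n_planes`.
#' @param grid Candidate alphas (default 0 to 0.10 by 0.002).
#' @param intensity_floor Eligibility floor (default 7).
#' @param min_cells Minimum matched cells per pair (default 3).
#' @return An `attenuation_fit` with elements `alpha`, `center`, `grid`
#'   (tibble of alpha vs mean correlation) and `pairs`.
#' @export
fit_attenuation <- function(cells, meta, grid = seq(0, 0.10, by = 0.002),
                            intensity_floor = 7, min_cells = 3L) {
  meta <- as_tibble(meta)
  cells <- as_tibble(cells) %>%
    inner_join(select(meta, "embryo_id", "integrant_id", "orientation",
                      "center_plane"),
               by = "embryo_id")
  pairs <- list()
  for (ig in unique(cells$integrant_id)) {
    sub <- filter(cells, .data$integrant_id == ig)
    vno <- unique(sub$embryo_id[sub$orientation == "VNO"])
    dno <- unique(sub$embryo_id[sub$orientation == "DNO"])
    for (ev in vno) for (ed in dno) {
      a <- filter(sub, .data$embryo_id == ev)
      b <- filter(sub, .data$embryo_id == ed)
      m <- inner_join(
        select(a, "cell", i1 = "intensity", z1 = "z", c1 = "center_plane"),
        select(b, "cell", i2 = "intensity", z2 = "z", c2 = "center_plane"),
        by = "cell"
      ) %>%
        filter(.data$i1 > intensity_floor, .data$i2 > intensity_floor)
      if (nrow(m) >= min_cells) {
        pairs[[length(pairs) + 1]] <-
          mutate(m, integrant_id = ig, vno = ev, dno = ed)
      }
    }
  }
  if (length(pairs) == 0) {
    abort("no opposite-orientation replicate pairs with enough matched cells")
  }
  mean_r <- vapply(grid, function(a) {
    rs <- vapply(pairs, function(m) {
      x <- m$i1 * (1 + a)^(m$z1 - m$c1)
      y <- m$i2 * (1 + a)^(m$z2 - m$c2)
      suppressWarnings(cor(x, y))
    }, numeric(1))
    mean(rs, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(round(mean_r, 12)) # ascending grid: ties -> smallest alpha
  fit <- list(
    alpha = grid[best],
    center = unique(meta$center_plane)[1],
    intensity_floor = intensity_floor,
    grid = tibble(alpha = grid, mean_r = mean_r),
    pairs = bind_rows(lapply(pairs, function(m) {
      tibble(integrant_id = m$integrant_id[1], vno = m$vno[1],
             dno = m$dno[1], n_cells = nrow(m))
    }))
  )
  class(fit) <- "attenuation_fit"
  fit
}

#' @export
print.attenuation_fit <- function(x, ...) {
  cat(sprintf(
    "Attenuation fit: alpha = %.3f (mean pair correlation %.3f over %d pairs)\n",
    x$alpha, max(x$grid$mean_r), nrow(x$pairs)
  ))
  invisible(x)
}

#' Per-cell summaries of a nuclei table
#'
#' Convenience wrapper exposing the per embryo x cell intermediates used by
#' [fit_attenuation()]: uncorrected net mean intensity over retained frames
#' and mean Z plane.
#'
#' @param nuclei Nuclei table (see [read_nuclei()]).
#' @param k Division-adjacent frames dropped at each series end.
#' @return Tibble with `embryo_id`, `cell`, `intensity`, `z`, `n_frames`.
#' @export
summarise_nuclei_cells <- function(nuclei, k = 1L) {
  .summarise_nuclei(nuclei, k = k) %>%
    filter(.data$usable) %>%
    select("embryo_id", "cell", intensity = "mean_net", z = "mean_z",
           n_frames = "n_frames_total")
}

#' Quantify instantaneous reporter expression per cell
#'
#' Runs the full per-cell quantification pipeline in fixed order: background
#' subtraction (per frame), depth attenuation correction, per-cell mean with
#' division-adjacent frames dropped, mother subtraction, cutoff, and
#' `log2(x + 1)` transform.
#'
#' @param nuclei Nuclei table: `embryo_id`, `frame`, `cell`, `z_plane`,
#'   `raw_intensity`, `background` (see [read_nuclei()]).
#' @param meta Embryo metadata (see [fit_attenuation()]).
#' @param alpha Attenuation factor, or `"auto"` to fit it from the data via
#'   [fit_attenuation()].
#' @param cutoff Expression cutoff, `"auto"` to estimate from `controls`,
#'   or a number (default 6.36).
#' @param controls Optional control intensities for `cutoff = "auto"`.
#' @param k Division-adjacent frames dropped at each series end.
#' @param ... Passed on to [fit_attenuation()] when `alpha = "auto"`.
#' @return Tibble with one row per embryo x cell: `embryo_id`, `cell`,
#'   `n_frames`, `mean_z`, `mean_intensity` (corrected), `mother_last`,
#'   `instantaneous`, `activity`, plus the `alpha` and `cutoff` used as
#'   attributes.
#' @export
quantify_cells <- function(nuclei, meta, alpha = "auto", cutoff = 6.36,
                           controls = NULL, k = 1L, ...) {
  nuclei <- as_tibble(nuclei)
  meta <- as_tibble(meta)
  summ <- .summarise_nuclei(nuclei, k = k)
  dropped <- filter(summ, !.data$usable)
  if (nrow(dropped) > 0) {
    warn(sprintf("%d cells dropped: all frames division-adjacent",
                 nrow(dropped)))
  }
  if (identical(alpha, "auto")) {
    fit <- fit_attenuation(
      summ %>% filter(.data$usable) %>%
        select("embryo_id", "cell", intensity = "mean_net", z = "mean_z"),
      meta, ...
    )
    alpha <- fit$alpha
  }
  if (identical(cutoff, "auto")) {
    cutoff <- estimate_expression_cutoff(controls)
  }
  res <- summ %>%
    filter(.data$usable) %>%
    left_join(select(meta, "embryo_id", "center_plane"), by = "embryo_id") %>%
    mutate(
      mean_intensity = .data$mean_net * (1 + alpha)^(.data$mean_z - .data$center_plane),
      last_corrected = .data$last_net * (1 + alpha)^(.data$last_z - .data$center_plane),
      mother = cell_parent(.data$cell)
    )
  mother_tbl <- select(res, "embryo_id", mother = "cell",
                       mother_last = "last_corrected")
  res <- res %>%
    left_join(mother_tbl, by = c("embryo_id", "mother")) %>%
    mutate(
      mother_last = ifelse(is.na(.data$mother_last), 0, .data$mother_last),
      instantaneous = instantaneous_expression(.data$mean_intensity,
                                               .data$mother_last),
      activity = apply_cutoff_and_log(.data$instantaneous, cutoff)
    ) %>%
    select("embryo_id", "cell", n_frames = "n_frames_total",
           mean_z = "mean_z", "mean_intensity", "mother_last",
           "instantaneous", "activity")
  attr(res, "alpha") <- alpha
  attr(res, "cutoff") <- cutoff
  res
}
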