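# All genomic coordinates in files follow the BED convention: 0-based,
# half-open. Tables are UTF-8 TSV with a header line.

.check_columns <- function(tbl, need, what) {
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    abort(sprintf("%s: missing column(s) %s", what,
                  paste(miss, collapse = ", ")))
  }
}

.validate_names_with_lines <- function(cells, what) {
  for (i in seq_along(cells)) {
    tryCatch(parse_cell_name(cells[i]), error = function(e) {
      abort(sprintf("%s, line %d: %s", what, i + 1L, conditionMessage(e)))
    })
  }
}

#' Read a nuclei intensity table
#'
#' TSV with columns `embryo_id`, `frame`, `cell`, `x`, `y`, `z_plane`,
#' `radius_px`, `raw_intensity`, `background` (one row per embryo x cell x
#' time point, in the dialect of StarryNite/AceTree exports).
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_nuclei <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  .check_columns(tbl, c("embryo_id", "frame", "cell", "z_plane",
                        "raw_intensity", "background"), "nuclei table")
  .validate_names_with_lines(unique(tbl$cell), basename(path))
  tbl
}

#' Read an embryo metadata table
#'
#' TSV with columns `embryo_id`, `integrant_id`, `orientation`
#' (VNO/DNO/other), `center_plane`, `n_planes`.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_embryo_meta <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  .check_columns(tbl, c("embryo_id", "integrant_id", "orientation",
                        "center_plane", "n_planes"), "embryo metadata")
  bad <- !tbl$orientation %in% c("VNO", "DNO", "other")
  if (any(bad)) {
    abort(sprintf("embryo metadata: unknown orientation '%s' (line %d)",
                  tbl$orientation[bad][1], which(bad)[1] + 1L))
  }
  tbl
}

#' Read a lineage file
#'
#' TSV with header `cell  parent  birth_frame  death_frame  fate`; `fate`
#' is one of Neu, Pha, Ski, Mus, Int, Ger, Dea, Other for terminal cells
#' and `NA` for internal cells.
#'
#' @param path File path.
#' @return A [lineage_tree()].
#' @export
read_lineage <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         na = "NA")
  .check_columns(tbl, c("cell", "parent", "fate"), "lineage file")
  .validate_names_with_lines(tbl$cell, basename(path))
  lineage_tree(tbl)
}

#' Write a lineage tree
#' @param tree A [lineage_tree()].
#' @param path Output path.
#' @export
write_lineage <- function(tree, path) {
  readr::write_tsv(as_tibble(tree)[, c("cell", "parent", "birth_frame",
                                       "death_frame", "fate")], path)
}

#' Read an integration-site position file
#'
#' BED3+1: `chrom  start  end  site_id`, 0-based half-open, no header.
#'
#' @param path File path.
#' @return Tibble with `site_id`, `chrom`, `start`, `end`.
#' @export
read_sites <- function(path) {
  tbl <- readr::read_tsv(path,
                         col_names = c("chrom", "start", "end", "site_id"),
                         show_col_types = FALSE, progress = FALSE)
  bad <- tbl$start >= tbl$end | tbl$start < 0
  if (any(bad)) {
    abort(sprintf("site file: start >= end or negative start at line %d",
                  which(bad)[1]))
  }
  if (anyDuplicated(tbl$site_id)) {
    abort(sprintf("site file: duplicate site id %s",
                  tbl$site_id[duplicated(tbl$site_id)][1]))
  }
  select(tbl, "site_id", "chrom", "start", "end")
}

#' Write an integration-site position file (BED3+1)
#' @param sites Tibble with `site_id`, `chrom`, `start`, `end`.
#' @param path Output path.
#' @export
write_sites <- function(sites, path) {
  readr::write_tsv(select(as_tibble(sites), "chrom", "start", "end",
                          "site_id"),
                   path, col_names = FALSE)
}

#' Read a symmetric-pair registry (two-column TSV `left  right`)
#' @param path File path.
#' @return Tibble.
#' @export
read_symmetric_pairs <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  .check_columns(tbl, c("left", "right"), "symmetric-pair registry")
  tbl
}

#' Read a chromatin activity landscape from CSV
#'
#' The activity matrix CSV has a first column `cell` and one column per
#' site id; companion binary and variable-flag CSVs are optional (binary is
#' recomputed as `activity > 0` when absent).
#'
#' @param activity_path CSV of consensus activities.
#' @param variable_path Optional CSV of replicate-variability flags.
#' @param sites Optional site table for genome ordering.
#' @return An `activity_landscape`.
#' @export
read_landscape <- function(activity_path, variable_path = NULL,
                           sites = NULL) {
  act <- readr::read_csv(activity_path, show_col_types = FALSE,
                         progress = FALSE)
  .check_columns(act, "cell", "landscape CSV")
  .validate_names_with_lines(act$cell, basename(activity_path))
  m <- as.matrix(act[, -1])
  rownames(m) <- act$cell
  variable <- if (!is.null(variable_path)) {
    v <- readr::read_csv(variable_path, show_col_types = FALSE,
                         progress = FALSE)
    vm <- as.matrix(v[, -1]) > 0
    rownames(vm) <- v$cell
    vm[rownames(m), colnames(m), drop = FALSE]
  } else {
    matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
  }
  structure(list(
    activity = m, binary = m > 0, variable = variable,
    n_reps = matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m)),
    frac_expressed = matrix(NA_real_, nrow(m), ncol(m),
                            dimnames = dimnames(m)),
    cells = rownames(m), sites = sites
  ), class = "activity_landscape")
}

#' Write a landscape to CSV files
#'
#' Writes `<prefix>_activity.csv`, `<prefix>_binary.csv`,
#' `<prefix>_variable.csv`.
#'
#' @param landscape An `activity_landscape`.
#' @param prefix Path prefix.
#' @return Invisibly, the paths written.
#' @export
write_landscape <- function(landscape, prefix) {
  w <- function(m, suffix) {
    p <- paste0(prefix, "_", suffix, ".csv")
    df <- as_tibble(as.data.frame(m * 1))
    readr::write_csv(dplyr::bind_cols(tibble(cell = rownames(m)), df), p)
    p
  }
  invisible(c(w(landscape$activity, "activity"),
              w(landscape$binary, "binary"),
              w(landscape$variable, "variable")))
}

#' Write all outputs of a synthetic embryo study
#'
#' @param study Result of [simulate_embryo_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_lineage(study$tree, file.path(dir, "lineage.tsv"))
  readr::write_tsv(study$registry, file.path(dir, "pairs.tsv"))
  write_sites(study$sites, file.path(dir, "sites.bed"))
  readr::write_tsv(study$replicates, file.path(dir, "replicates.tsv"))
  if (!is.null(study$nuclei)) {
    readr::write_tsv(study$nuclei, file.path(dir, "nuclei.tsv"))
    readr::write_tsv(study$meta, file.path(dir, "meta.tsv"))
  }
  ann <- study$annotations
  readr::write_tsv(ann$genes, file.path(dir, "genes.tsv"))
  readr::write_tsv(ann$coexpressed, file.path(dir, "coexpressed.tsv"))
  readr::write_tsv(ann$categories, file.path(dir, "categories.tsv"))
  readr::write_tsv(ann$tissue_genes, file.path(dir, "tissue_genes.tsv"))
  truth <- study$truth
  truth$true_activity <- list(
    cells = rownames(truth$true_activity),
    sites = colnames(truth$true_activity),
    activity = unname(apply(truth$true_activity, 1, as.numeric,
                            simplify = FALSE))
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
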