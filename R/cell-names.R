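# Sulston nomenclature: every embryonic cell carries a unique name formed from
# a founder prefix plus a string of division letters (a/p, l/r, d/v), the
# mother's full name being propagated to both daughters.  The founder
# generation itself follows a fixed genealogy from the zygote P0.

.founder_parent <- c(
  AB = "P0", P1 = "P0",
  EMS = "P1", P2 = "P1",
  MS = "EMS", E = "EMS",
  C = "P2", P3 = "P2",
  D = "P3", P4 = "P3",
  Z2 = "P4", Z3 = "P4"
)

.founder_depth <- c(
  P0 = 0L, AB = 1L, P1 = 1L, EMS = 2L, P2 = 2L,
  MS = 3L, E = 3L, C = 3L, P3 = 3L, D = 4L, P4 = 4L,
  Z2 = 5L, Z3 = 5L
)

# founders that divide by appending axis letters; the remaining founders
# (P0..P4, EMS, Z2, Z3) divide into named founders or do not divide in the
# embryo, so a letter suffix on them is a malformed name
.suffixing_founders <- c("AB", "MS", "E", "C", "D")

.axis_letters <- c("a", "p", "l", "r", "d", "v")

# lineal (visual tree) child order: a before p, l before r, d before v.
# Encoding each division as one bit gives every cell a root path whose
# lexicographic order is the depth-first tree order and whose common prefixes
# are common ancestors.
.letter_bit <- c(a = "0", l = "0", d = "0", p = "1", r = "1", v = "1")

.founder_path <- c(
  P0 = "", AB = "0", P1 = "1", EMS = "10", P2 = "11",
  MS = "100", E = "101", C = "110", P3 = "111",
  D = "1110", P4 = "1111", Z2 = "11110", Z3 = "11111"
)

.founders_by_length <- local({
  f <- names(.founder_parent)
  f <- c(f, "P0")
  f[order(nchar(f), decreasing = TRUE)]
})

#' Parse Sulston cell names
#'
#' Splits each name into its founder prefix and division-letter suffix and
#' validates both. The founder prefix must belong to the fixed founder
#' genealogy (P0 -> AB, P1; P1 -> EMS, P2; EMS -> MS, E; P2 -> C, P3;
#' P3 -> D, P4; P4 -> Z2, Z3) and the suffix may use only the six axis
#' letters a/p, l/r, d/v. Only AB, MS, E, C and D divide by appending
#' letters, so a suffix on any other founder is rejected.
#'
#' @param name Character vector of cell names.
#' @return A tibble with one row per name: `name`, `founder`, `suffix`,
#'   `depth` (divisions from P0).
#' @examples
#' parse_cell_name(c("ABalpppppp", "MSa", "EMS"))
#' @export
parse_cell_name <- function(name) {
  if (length(name) == 0 || any(is.na(name)) || any(!nzchar(name))) {
    abort("cell names must be non-empty strings")
  }
  founder <- character(length(name))
  suffix <- character(length(name))
  for (i in seq_along(name)) {
    nm <- name[[i]]
    hit <- .founders_by_length[startsWith(nm, .founders_by_length)]
    if (length(hit) == 0) {
      abort(sprintf("'%s': unknown founder prefix", nm))
    }
    f <- hit[[1]]
    s <- substring(nm, nchar(f) + 1L)
    if (nzchar(s)) {
      letters_s <- strsplit(s, "", fixed = TRUE)[[1]]
      bad <- which(!letters_s %in% .axis_letters)
      if (length(bad) > 0) {
        abort(sprintf(
          "'%s': illegal suffix letter '%s' at position %d",
          nm, letters_s[bad[1]], nchar(f) + bad[1]
        ))
      }
      if (!f %in% .suffixing_founders) {
        abort(sprintf(
          "'%s': founder %s does not divide by appending letters (position %d)",
          nm, f, nchar(f) + 1L
        ))
      }
    }
    founder[[i]] <- f
    suffix[[i]] <- s
  }
  tibble(
    name = name, founder = founder, suffix = suffix,
    depth = unname(.founder_depth[founder]) + nchar(suffix)
  )
}

#' Number of divisions separating a cell from the zygote
#'
#' @param name Character vector of cell names.
#' @return Integer vector of depths (P0 has depth 0).
#' @export
cell_depth <- function(name) {
  p <- parse_cell_name(name)
  as.integer(p$depth)
}

#' Mother of each cell
#'
#' For suffixed names the mother is the name with its last letter removed;
#' founders follow the founder genealogy. P0 has no mother (`NA`).
#'
#' @param name Character vector of cell names.
#' @return Character vector of mother names.
#' @export
cell_parent <- function(name) {
  p <- parse_cell_name(name)
  out <- ifelse(
    nzchar(p$suffix),
    paste0(p$founder, substr(p$suffix, 1L, nchar(p$suffix) - 1L)),
    unname(.founder_parent[p$founder])
  )
  out[p$name == "P0"] <- NA_character_
  out
}

# root path of each cell as a 0/1 string; lexicographic sort of these paths is
# the lineal (depth-first, a-before-p) order and shared prefixes identify
# common ancestors
cell_root_path <- function(name) {
  p <- parse_cell_name(name)
  bits <- vapply(strsplit(p$suffix, "", fixed = TRUE), function(s) {
    paste(.letter_bit[s], collapse = "")
  }, character(1))
  paste0(unname(.founder_path[p$founder]), bits)
}

#' Order cells lineally
#'
#' Returns the permutation that sorts cells in depth-first tree order with
#' daughter order a < p, l < r, d < v, matching standard lineage-tree
#' visualisations.
#'
#' @param name Character vector of cell names.
#' @return Integer permutation (as from [order()]).
#' @export
lineal_order <- function(name) {
  order(cell_root_path(name), method = "radix")
}

.common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- strsplit(substr(a, 1, n), "", fixed = TRUE)[[1]]
  bv <- strsplit(substr(b, 1, n), "", fixed = TRUE)[[1]]
  neq <- which(av != bv)
  if (length(neq) == 0) n else neq[1] - 1L
}

#' Lowest common ancestor of two cells
#'
#' Within one founder lineage the LCA is the founder plus the longest common
#' suffix prefix; across founders it is found by walking the founder
#' genealogy (P0 is the universal root).
#'
#' @param a,b Character vectors of cell names (recycled to common length).
#' @return Character vector of LCA names.
#' @examples
#' lowest_common_ancestor("ABalpppppp", "ABpraaappp") # "AB"
#' lowest_common_ancestor("MSa", "Ep") # "EMS"
#' @export
lowest_common_ancestor <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  pa <- parse_cell_name(a)
  pb <- parse_cell_name(b)
  out <- character(n)
  for (i in seq_len(n)) {
    if (pa$founder[i] == pb$founder[i]) {
      k <- .common_prefix_len(pa$suffix[i], pb$suffix[i])
      out[i] <- paste0(pa$founder[i], substr(pa$suffix[i], 1, k))
    } else {
      chain <- function(f) {
        acc <- f
        while (f != "P0") {
          f <- .founder_parent[[f]]
          acc <- c(acc, f)
        }
        acc
      }
      ca <- chain(pa$founder[i])
      cb <- chain(pb$founder[i])
      out[i] <- ca[ca %in% cb][1]
    }
  }
  out
}

#' Lineage distance between two cells
#'
#' The number of cell divisions separating two cells via their lowest common
#' ancestor: `depth(a) + depth(b) - 2 * depth(LCA)`. A metric on the lineage
#' tree; 0 iff the two names are identical.
#'
#' @param a,b Character vectors of cell names (recycled to common length).
#' @return Integer vector of division counts.
#' @examples
#' lineage_distance("ABalpppppp", "ABpraaappp") # 16
#' @export
lineage_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  lca <- lowest_common_ancestor(a, b)
  as.integer(cell_depth(a) + cell_depth(b) - 2L * cell_depth(lca))
}

#' Mirror a cell name across the left-right axis
#'
#' Swaps l and r in the division suffix (a/p and d/v are unchanged), the
#' path transformation relating bilaterally symmetric lineages.
#'
#' @param name Character vector of cell names.
#' @return Character vector of mirrored names.
#' @export
mirror_cell_name <- function(name) {
  p <- parse_cell_name(name)
  paste0(p$founder, chartr("lr", "rl", p$suffix))
}
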