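# Distance-based phylogeny: pairwise p-distances under partial deletion,
# neighbor-joining tree construction, and bootstrap supports from resampled
# alignment columns.

alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) {
    return(alignment)
  }
  alignment <- as_tibble(alignment)
  if (anyDuplicated(alignment$id)) {
    sod_error("duplicate taxon labels in alignment", "sod_input_error")
  }
  lens <- nchar(alignment$sequence)
  if (length(unique(lens)) != 1L) {
    sod_error("aligned sequences must have equal lengths", "sod_input_error")
  }
  m <- do.call(rbind, strsplit(toupper(alignment$sequence), "", fixed = TRUE))
  rownames(m) <- alignment$id
  m
}

#' Pairwise p-distances under partial deletion
#'
#' Alignment columns whose non-gap fraction falls below the site-coverage
#' threshold are removed globally; the distance between two rows is then the
#' proportion of mismatches over the columns where both are non-gap.
#'
#' @param alignment Tibble with `id`, `sequence` (equal-length aligned
#'   strings; `-` or `.` as gaps) or a character matrix.
#' @param threshold Site-coverage threshold in (0, 1]; default 0.70.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
pdistance_partial_deletion <- function(alignment, threshold = 0.7) {
  if (threshold <= 0 || threshold > 1) {
    sod_error("site-coverage threshold must be in (0, 1]", "sod_config_error")
  }
  m <- alignment_matrix(alignment)
  if (nrow(m) < 2L) {
    sod_error("at least two sequences are required", "sod_input_error")
  }
  gap <- m == "-" | m == "."
  keep <- colMeans(!gap) >= threshold
  m <- m[, keep, drop = FALSE]
  gap <- gap[, keep, drop = FALSE]
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- !gap[i, ] & !gap[j, ]
      if (!any(both)) {
        sod_error(
          paste0("no comparable sites between '", rownames(m)[i], "' and '",
                 rownames(m)[j], "'"),
          "sod_distance_error"
        )
      }
      d[i, j] <- d[j, i] <- sum(m[i, both] != m[j, both]) / sum(both)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining; exact on additive matrices. Negative branch
#' lengths are clamped to zero (recorded in the `"clamped"` attribute).
#'
#' @param dm Symmetric distance matrix with zero diagonal, >= 3 taxa.
#' @return An `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) {
    sod_error("neighbor joining requires at least 3 taxa", "sod_input_error")
  }
  if (any(abs(dm - t(dm)) > 1e-12) || any(diag(dm) != 0)) {
    sod_error("distance matrix must be symmetric with zero diagonal",
              "sod_input_error")
  }
  tree <- ape::nj(dm)
  clamped <- tree$edge.length < 0
  if (any(clamped)) {
    warn("negative neighbor-joining branch lengths clamped to 0")
    tree$edge.length[clamped] <- 0
  }
  attr(tree, "clamped") <- any(clamped)
  tree
}

#' Bootstrap supports for the neighbor-joining tree
#'
#' Alignment columns (after partial deletion) are resampled with replacement
#' per replicate; the support of each internal branch of the base tree is
#' the percentage of replicate trees containing the same bipartition.
#' Supports are attached as integer internal-node labels.
#'
#' @param alignment Tibble with `id`, `sequence` or a character matrix.
#' @param threshold Site-coverage threshold for partial deletion.
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return The base `ape::phylo` tree with `node.label` holding supports in
#'   0-100; the replicate count is attached as the `"replicates"` attribute.
#' @export
bootstrap_support <- function(alignment, threshold = 0.7, replicates = 1000L,
                              seed = 1L) {
  if (replicates < 1L) {
    sod_error("at least one bootstrap replicate is required",
              "sod_config_error")
  }
  m <- alignment_matrix(alignment)
  gap <- m == "-" | m == "."
  m <- m[, colMeans(!gap) >= threshold, drop = FALSE]
  base <- nj_tree(suppressWarnings(pdistance_partial_deletion(m, threshold = 1e-9)))
  ncol_m <- ncol(m)
  trees <- with_seed(seed, {
    out <- vector("list", replicates)
    for (b in seq_len(replicates)) {
      cols <- sample.int(ncol_m, ncol_m, replace = TRUE)
      rb <- tryCatch(
        suppressWarnings(nj_tree(
          pdistance_partial_deletion(m[, cols, drop = FALSE],
                                     threshold = 1e-9)
        )),
        sodsplice_error = function(e) NULL
      )
      out[[b]] <- rb
    }
    out
  })
  trees <- trees[!vapply(trees, is.null, logical(1))]
  counts <- ape::prop.clades(base, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- as.integer(round(100 * counts / length(trees)))
  base$node.label <- as.character(support)
  attr(base, "replicates") <- length(trees)
  base
}
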