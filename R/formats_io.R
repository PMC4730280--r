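# Readers/writers for the standard formats the pipeline touches: FASTA,
# FASTQ (Phred+33 only), a strict GFF3 dialect with explicit intron features,
# Newick trees and Ct CSV tables. Internal coordinates are 0-based half-open;
# everything on disk is 1-based inclusive.

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Tibble with columns `id`, `description`, `residues` (uppercased),
#'   in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    sod_error(paste0("no such file: ", path), "sod_format_error")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) sod_error(paste0("malformed FASTA: ", conditionMessage(e)),
                                  "sod_format_error")
  )
  if (length(set) == 0L) {
    sod_error("empty FASTA file", "sod_format_error")
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    sod_error(paste0("duplicate FASTA id '", ids[duplicated(ids)][1], "'"),
              "sod_format_error")
  }
  residues <- toupper(as.character(set))
  if (any(nchar(residues) == 0L)) {
    sod_error(paste0("empty sequence for id '", ids[nchar(residues) == 0L][1], "'"),
              "sod_format_error")
  }
  tibble(id = ids, description = unname(desc), residues = unname(residues))
}

#' Write sequences to FASTA
#'
#' @param records Tibble with `id` and `residues` columns (optionally
#'   `description`).
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  records <- as_tibble(records)
  lines <- unlist(lapply(seq_len(nrow(records)), function(i) {
    header <- paste0(">", records$id[i])
    if (!is.null(records$description) && nzchar(records$description[i])) {
      header <- paste(header, records$description[i])
    }
    s <- records$residues[i]
    starts <- seq(1L, nchar(s), by = width)
    c(header, substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }))
  writeLines(lines, path)
  invisible(path)
}

# FASTQ ----------------------------------------------------------------------

#' Read a FASTQ file (Phred+33)
#'
#' Strict 4-line records; qualities are decoded as Phred+33 and any other
#' dialect is rejected.
#'
#' @param path Path to a FASTQ file.
#' @return Tibble with `id`, `sequence`, `quality` columns.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) {
    sod_error(paste0("no such file: ", path), "sod_format_error")
  }
  lines <- readLines(path)
  while (length(lines) > 0L && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0L || length(lines) %% 4L != 0L) {
    sod_error("FASTQ file is not made of 4-line records", "sod_format_error")
  }
  idx <- seq(1L, length(lines), by = 4L)
  headers <- lines[idx]
  seqs <- toupper(lines[idx + 1L])
  seps <- lines[idx + 2L]
  quals <- lines[idx + 3L]
  if (any(!startsWith(headers, "@")) || any(!startsWith(seps, "+"))) {
    sod_error("FASTQ record missing '@' header or '+' separator",
              "sod_format_error")
  }
  ids <- sub("\\s.*$", "", substring(headers, 2L))
  bad <- nchar(seqs) != nchar(quals)
  if (any(bad)) {
    sod_error(
      paste0("sequence/quality length mismatch in record '", ids[bad][1], "'"),
      "sod_format_error"
    )
  }
  validate_residues(seqs, "dna", ids)
  invisible(lapply(quals, phred33_scores)) # rejects non Phred+33 dialects
  tibble(id = ids, sequence = seqs, quality = quals)
}

#' Read paired FASTQ files as read pairs
#'
#' @param path1,path2 Mate-1 and mate-2 FASTQ files. If `path2` is `NULL`,
#'   `path1` is taken as interleaved (mate 1 then mate 2, alternating).
#' @return Tibble with `pair_id`, `read1`, `qual1`, `read2`, `qual2`.
#' @export
read_fastq_pairs <- function(path1, path2 = NULL) {
  strip_mate <- function(x) sub("/[12]$", "", x)
  if (is.null(path2)) {
    all <- read_fastq(path1)
    if (nrow(all) %% 2L != 0L) {
      sod_error("interleaved FASTQ has an odd number of records",
                "sod_format_error")
    }
    m1 <- all[seq(1L, nrow(all), by = 2L), ]
    m2 <- all[seq(2L, nrow(all), by = 2L), ]
  } else {
    m1 <- read_fastq(path1)
    m2 <- read_fastq(path2)
    if (nrow(m1) != nrow(m2)) {
      sod_error("mate files contain different record counts",
                "sod_format_error")
    }
  }
  ids1 <- strip_mate(m1$id)
  ids2 <- strip_mate(m2$id)
  if (!all(ids1 == ids2)) {
    sod_error("mate records are not in matching order", "sod_format_error")
  }
  tibble(
    pair_id = ids1,
    read1 = m1$sequence, qual1 = m1$quality,
    read2 = m2$sequence, qual2 = m2$quality
  )
}

#' Write read pairs to FASTQ
#'
#' @param pairs Tibble as returned by [read_fastq_pairs()] or
#'   [simulate_read_pairs()].
#' @param path1 Mate-1 output path (or interleaved output if `path2` is
#'   `NULL`).
#' @param path2 Optional mate-2 output path.
#' @return `path1`, invisibly.
#' @export
write_fastq_pairs <- function(pairs, path1, path2 = NULL) {
  rec <- function(id, seq, qual) c(paste0("@", id), seq, "+", qual)
  l1 <- unlist(lapply(seq_len(nrow(pairs)), function(i) {
    rec(paste0(pairs$pair_id[i], "/1"), pairs$read1[i], pairs$qual1[i])
  }))
  l2 <- unlist(lapply(seq_len(nrow(pairs)), function(i) {
    rec(paste0(pairs$pair_id[i], "/2"), pairs$read2[i], pairs$qual2[i])
  }))
  if (is.null(path2)) {
    inter <- as.vector(rbind(
      matrix(l1, nrow = 4L), matrix(l2, nrow = 4L)
    ))
    writeLines(inter, path1)
  } else {
    writeLines(l1, path1)
    writeLines(l2, path2)
  }
  invisible(path1)
}

# GFF3 -----------------------------------------------------------------------

#' Serialise a gene model to GFF3 text
#'
#' Emits gene, mRNA, exon and explicit intron features. Internal 0-based
#' half-open coordinates are converted to 1-based inclusive. For minus-strand
#' models (stored on the coding strand) coordinates are flipped back to the
#' forward genomic strand so features remain ascending by start.
#'
#' @param model A `gene_model`.
#' @param path Optional output path; if `NULL` the lines are returned.
#' @return Character vector of GFF3 lines (invisibly if `path` given).
#' @export
write_gff3 <- function(model, path = NULL) {
  validate_gene_model(model)
  n <- nchar(model$seq)
  flip <- function(start, end) {
    if (model$strand == "+") cbind(start, end) else cbind(n - end, n - start)
  }
  line <- function(kind, start0, end0, id, parent = NULL) {
    g <- flip(start0, end0)
    attrs <- paste0("ID=", id)
    if (!is.null(parent)) attrs <- paste0(attrs, ";Parent=", parent)
    paste(model$gene_id, "sodsplice", kind, g[1] + 1L, g[2], ".",
          model$strand, ".", attrs, sep = "\t")
  }
  gid <- model$gene_id
  mid <- paste0(gid, ".t1")
  exons <- model_exons(model)
  lines <- c(
    "##gff-version 3",
    paste("##sequence-region", gid, 1L, n),
    line("gene", model$tss, model$tes, gid),
    line("mRNA", model$tss, model$tes, mid, gid)
  )
  feat <- list()
  for (i in seq_len(nrow(exons))) {
    feat[[length(feat) + 1L]] <- list(
      kind = "exon", start = exons$start[i], end = exons$end[i],
      id = paste0(mid, ".exon", i), parent = mid
    )
  }
  for (i in seq_len(nrow(model$introns))) {
    feat[[length(feat) + 1L]] <- list(
      kind = "intron", start = model$introns$start[i],
      end = model$introns$end[i],
      id = paste0(mid, ".", model$introns$intron[i]), parent = mid
    )
  }
  gstart <- vapply(feat, function(f) flip(f$start, f$end)[1], numeric(1))
  feat <- feat[order(gstart)]
  lines <- c(lines, vapply(
    feat, function(f) line(f$kind, f$start, f$end, f$id, f$parent), character(1)
  ))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read a gene model from GFF3 text
#'
#' Inverse of [write_gff3()]: expects the dialect that writer emits (a single
#' gene with explicit intron features). The region sequence is supplied
#' separately since GFF3 carries only coordinates; minus-strand features are
#' converted back onto the coding strand, so `seq` must already be the coding
#' strand sequence (as produced at load time).
#'
#' @param x Path to a GFF3 file or a character vector of GFF3 lines.
#' @param seq Region sequence on the coding strand.
#' @return A `gene_model`.
#' @export
read_gff3 <- function(x, seq) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  if (length(lines) == 0L || !grepl("^##gff-version 3", lines[1])) {
    sod_error("missing GFF3 version pragma", "sod_format_error")
  }
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(fields) != 9L)) {
    sod_error("GFF3 line does not have 9 columns", "sod_format_error")
  }
  df <- as_tibble(do.call(rbind, fields), .name_repair = "minimal")
  names(df) <- c("seqid", "source", "kind", "start", "end", "score",
                 "strand", "phase", "attributes")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$start > df$end)) {
    sod_error("GFF3 feature with start > end", "sod_format_error")
  }
  allowed <- c("gene", "mRNA", "exon", "intron", "CDS",
               "five_prime_UTR", "three_prime_UTR")
  if (!all(df$kind %in% allowed)) {
    sod_error(paste0("unknown feature kind '",
                     setdiff(df$kind, allowed)[1], "'"), "sod_format_error")
  }
  gene <- df[df$kind == "gene", ]
  if (nrow(gene) != 1L) {
    sod_error("expected exactly one gene feature", "sod_format_error")
  }
  strand <- gene$strand[1]
  n <- nchar(seq)
  to0 <- function(start1, end1) {
    if (strand == "+") cbind(start1 - 1L, end1) else cbind(n - end1, n - start1 + 1L)
  }
  g <- to0(gene$start[1], gene$end[1])
  introns <- df[df$kind == "intron", ]
  itab <- NULL
  if (nrow(introns) > 0L) {
    iv <- to0(introns$start, introns$end)
    ids <- sub("^.*ID=[^;]*\\.(I[0-9]+).*$", "\\1", introns$attributes)
    itab <- tibble(intron = ids, start = iv[, 1], end = iv[, 2])
    itab <- itab[order(itab$start), ]
  }
  gene_model(
    gene_id = gene$seqid[1], seq = seq, introns = itab,
    tss = g[1], tes = g[2], strand = strand
  )
}

# Newick ---------------------------------------------------------------------

#' Write a phylogenetic tree to Newick text
#'
#' Bootstrap supports, when present as integer node labels, are written as
#' internal-node labels.
#'
#' @param tree An `ape::phylo` object.
#' @param path Optional output path.
#' @return The Newick string (invisibly if `path` given).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  text <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

#' Read a Newick tree
#'
#' @param x Path to a Newick file or a Newick string.
#' @return An `ape::phylo` object.
#' @export
read_newick <- function(x) {
  tree <- if (length(x) == 1L && file.exists(x)) {
    ape::read.tree(x)
  } else {
    ape::read.tree(text = x)
  }
  if (is.null(tree)) {
    sod_error("unparseable Newick input", "sod_format_error")
  }
  tree
}

# Ct CSV ---------------------------------------------------------------------

#' Read a replicate Ct table from CSV
#'
#' Expects columns `condition`, `gene`, `replicate`, `ct` (comma-separated,
#' header row, UTF-8).
#'
#' @param path CSV path.
#' @return Tibble with the four columns, `ct` numeric.
#' @export
read_ct_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("condition", "gene", "replicate", "ct")
  if (!all(need %in% names(df))) {
    sod_error(paste0("Ct CSV must have columns: ", paste(need, collapse = ", ")),
              "sod_format_error")
  }
  if (any(!is.finite(df$ct))) {
    sod_error("non-finite Ct value", "sod_format_error")
  }
  as_tibble(df[, need])
}

#' Write a Ct table to CSV
#'
#' @param ct_table Tibble with `condition`, `gene`, `replicate`, `ct`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_csv <- function(ct_table, path) {
  readr::write_csv(ct_table, path)
  invisible(path)
}
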