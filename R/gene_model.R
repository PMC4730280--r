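# The gene_model S3 class: a genomic gene region on the coding strand with an
# ordered exon/intron structure and transcription bounds. Internal coordinates
# are 0-based half-open; GFF3 output converts to 1-based inclusive.

#' Construct a gene model
#'
#' A gene model describes a transcribed region: its sequence (always stored on
#' the coding strand), transcription start/termination sites, and the ordered
#' introns whose complement within `[tss, tes)` forms the exons. Every intron
#' must obey the GT-AG rule on the coding strand.
#'
#' @param gene_id Gene identifier.
#' @param seq Genomic region sequence (coding strand, uppercase A/C/G/T/N).
#' @param introns Tibble with 0-based half-open `start`, `end` columns
#'   (optionally an `intron` id column; defaults to I1, I2, ...).
#' @param tss,tes Transcription start/termination sites, 0-based half-open
#'   bounds within the region. Default to the whole region.
#' @param strand `"+"` or `"-"`. Minus-strand genes are expected to have been
#'   reverse-complemented at load time; the flag is retained for output.
#' @param states Optional per-intron splicing states: a named list (one entry
#'   per intron id) of state label vectors, e.g. `c("canonical", "retained")`.
#'   Labels are `"canonical"`, `"retained"`, `"alt5(+k)"`, `"alt3(-k)"`.
#' @param meta Optional list of free-form metadata.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, seq, introns = NULL, tss = 0L,
                       tes = nchar(seq), strand = "+", states = NULL,
                       meta = list()) {
  seq <- toupper(seq)
  validate_residues(seq, "dna", gene_id)
  if (is.null(introns) || nrow(introns) == 0L) {
    introns <- tibble(
      intron = character(), start = integer(), end = integer(),
      donor = character(), acceptor = character()
    )
  } else {
    introns <- as_tibble(introns)
    introns <- introns[order(introns$start), ]
    if (!"intron" %in% names(introns)) {
      introns$intron <- paste0("I", seq_len(nrow(introns)))
    }
    introns$donor <- substr0(seq, introns$start, introns$start + 2L)
    introns$acceptor <- substr0(seq, introns$end - 2L, introns$end)
    introns <- introns[, c("intron", "start", "end", "donor", "acceptor")]
  }
  model <- structure(
    list(
      gene_id = gene_id, seq = seq, strand = strand,
      tss = as.integer(tss), tes = as.integer(tes),
      introns = introns, states = states, meta = meta
    ),
    class = "gene_model"
  )
  validate_gene_model(model)
  model
}

#' Validate a gene model's invariants
#'
#' Checks that exons and introns alternate and tile `[tss, tes)` and that
#' every intron starts with GT and ends with AG on the coding strand.
#'
#' @param model A `gene_model`.
#' @return The model, invisibly; errors on violation.
#' @export
validate_gene_model <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  n <- nchar(model$seq)
  if (model$tss < 0L || model$tes > n || model$tss >= model$tes) {
    sod_error("transcription bounds outside the gene region", "sod_model_error")
  }
  ints <- model$introns
  if (nrow(ints) > 0L) {
    if (any(ints$start < model$tss) || any(ints$end > model$tes)) {
      sod_error("intron outside transcription bounds", "sod_model_error")
    }
    if (any(ints$end - ints$start < 4L)) {
      sod_error("intron shorter than 4 bp cannot carry GT..AG", "sod_model_error")
    }
    if (nrow(ints) > 1L && any(ints$start[-1L] < ints$end[-nrow(ints)])) {
      sod_error("introns overlap or touch out of order", "sod_model_error")
    }
    if (any(ints$start == model$tss) || any(ints$end == model$tes)) {
      sod_error("intron abuts a transcription bound; no flanking exon",
                "sod_model_error")
    }
    bad <- ints$donor != "GT" | ints$acceptor != "AG"
    if (any(bad)) {
      sod_error(
        paste0("intron ", ints$intron[bad][1], " violates the GT-AG rule"),
        "sod_model_error"
      )
    }
  }
  invisible(model)
}

#' Exons of a gene model
#'
#' The exons are the complement of the introns within `[tss, tes)`.
#'
#' @param model A `gene_model`.
#' @return Tibble with 0-based half-open `start`, `end` columns.
#' @export
model_exons <- function(model) {
  ints <- model$introns
  starts <- c(model$tss, ints$end)
  ends <- c(ints$start, model$tes)
  tibble(start = as.integer(starts), end = as.integer(ends))
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$gene_id, " (", x$strand, ") region ",
      nchar(x$seq), " bp, transcribed [", x$tss, ", ", x$tes, "), ",
      nrow(x$introns), " intron(s)\n", sep = "")
  if (nrow(x$introns) > 0L) {
    lens <- x$introns$end - x$introns$start
    cat("  intron lengths:", paste(lens, collapse = ", "), "bp\n")
  }
  if (!is.null(x$states)) {
    labs <- vapply(
      names(x$states),
      function(i) paste0(i, ":{", paste(x$states[[i]], collapse = ","), "}"),
      character(1)
    )
    cat("  splice states:", paste(labs, collapse = " "), "\n")
  }
  invisible(x)
}

# Splice-state labels --------------------------------------------------------

state_label <- function(type, offset = 0L) {
  switch(type,
    canonical = "canonical",
    retained = "retained",
    alt5 = sprintf("alt5(%+d)", offset),
    alt3 = sprintf("alt3(%+d)", offset),
    sod_error(paste0("unknown splice state type '", type, "'"),
              "sod_input_error")
  )
}

parse_state <- function(label) {
  if (label %in% c("canonical", "retained")) {
    return(list(type = label, offset = 0L))
  }
  m <- regmatches(label, regexec("^(alt5|alt3)\\(([+-][0-9]+)\\)$", label))[[1]]
  if (length(m) != 3L) {
    sod_error(paste0("unparseable splice state label '", label, "'"),
              "sod_input_error")
  }
  list(type = m[2], offset = as.integer(m[3]))
}

# Interval of the gene region spliced out under a given per-intron state.
spliced_interval <- function(intron_start, intron_end, label) {
  st <- parse_state(label)
  switch(st$type,
    canonical = c(intron_start, intron_end),
    retained = NULL,
    alt5 = c(intron_start + st$offset, intron_end),
    alt3 = c(intron_start, intron_end + st$offset)
  )
}

#' Assemble a transcript from per-intron splice states
#'
#' Applies one splicing choice per intron, left to right, and returns the
#' mature transcript sequence together with the genomic blocks it retains.
#'
#' @param model A `gene_model`.
#' @param states Character vector of state labels, one per intron, in intron
#'   order (`"canonical"`, `"retained"`, `"alt5(+k)"`, `"alt3(-k)"`).
#' @return List with `seq` (transcript sequence), `blocks` (tibble of retained
#'   genomic 0-based half-open intervals) and `states`.
#' @export
build_transcript <- function(model, states) {
  ints <- model$introns
  if (length(states) != nrow(ints)) {
    sod_error("one splice state required per intron", "sod_input_error")
  }
  removed <- list()
  for (i in seq_len(nrow(ints))) {
    iv <- spliced_interval(ints$start[i], ints$end[i], states[i])
    if (!is.null(iv)) {
      if (iv[2] - iv[1] < 4L) {
        sod_error("spliced interval shorter than 4 bp", "sod_input_error")
      }
      removed[[length(removed) + 1L]] <- iv
    }
  }
  cuts <- c(model$tss, unlist(removed), model$tes)
  starts <- cuts[seq(1L, length(cuts) - 1L, by = 2L)]
  ends <- cuts[seq(2L, length(cuts), by = 2L)]
  if (any(ends < starts) || is.unsorted(cuts)) {
    sod_error("splice states produce overlapping removals", "sod_input_error")
  }
  keep <- ends > starts
  blocks <- tibble(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
  seq <- paste(
    vapply(seq_len(nrow(blocks)),
           function(i) substr0(model$seq, blocks$start[i], blocks$end[i]),
           character(1)),
    collapse = ""
  )
  list(seq = seq, blocks = blocks, states = states)
}
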