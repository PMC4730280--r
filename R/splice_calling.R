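# GT-AG intron calling from junction-aware alignments and per-intron
# classification of alternative-splicing modes: intron retention and
# alternative 5'/3' splice sites, reported as signed offsets relative to the
# canonical intron.

#' Call GT-AG junctions from alignments
#'
#' One evidence entry per distinct (donor, acceptor) reference skip that
#' passes the GT-AG check and reaches the support threshold.
#'
#' @param alignments Alignment tibble from [map_reads()] (transcriptome
#'   mode).
#' @param reference Reference sequence string.
#' @param min_support Minimum number of distinct junction reads.
#' @return Tibble with `donor`, `acceptor` (0-based half-open intron
#'   bounds), `length`, `support`, sorted by donor.
#' @export
call_introns <- function(alignments, reference, min_support = 2L) {
  spliced <- alignments[!is.na(alignments$start2), ]
  if (nrow(spliced) == 0L) {
    return(tibble(donor = integer(), acceptor = integer(),
                  length = integer(), support = integer()))
  }
  jx <- dplyr::count(spliced, donor = .data$end1, acceptor = .data$start2,
                     name = "support")
  jx$length <- jx$acceptor - jx$donor
  gt <- substring(reference, jx$donor + 1L, jx$donor + 2L) == "GT"
  ag <- substring(reference, jx$acceptor - 1L, jx$acceptor) == "AG"
  jx <- jx[gt & ag & jx$support >= min_support & jx$length >= 4L, ]
  jx <- jx[order(jx$donor, jx$acceptor), ]
  as_tibble(jx[, c("donor", "acceptor", "length", "support")])
}

# Reads whose alignment contiguously crosses a boundary by >= `anchor`
# bases on each side (either aligned block of a mate qualifies; a reference
# skip never does).
boundary_support <- function(alignments, pos, anchor) {
  b1 <- alignments$start1 <= pos - anchor & alignments$end1 >= pos + anchor
  b2 <- !is.na(alignments$start2) &
    alignments$start2 <= pos - anchor & alignments$end2 >= pos + anchor
  sum(b1 | b2)
}

#' Classify per-intron splicing modes
#'
#' For each canonical intron of the model: a junction sharing its acceptor
#' but shifting the donor is an alternative 5' site; one sharing the donor
#' but shifting the acceptor is an alternative 3' site; the intron is
#' retained when enough single-block reads contiguously cross both
#' exon-intron boundaries. States accumulate (an intron can be both retained
#' and alternatively spliced). Junctions sharing neither end with any
#' canonical intron are reported as novel, not classified.
#'
#' @param junctions Junction tibble from [call_introns()].
#' @param alignments Alignment tibble (retention evidence).
#' @param model Canonical `gene_model` (from a fixture, a GFF3 annotation or
#'   [infer_canonical_model()]).
#' @param min_support Support threshold for non-canonical states (retention:
#'   per boundary).
#' @param anchor Minimum contiguous overhang on each side of a boundary for
#'   a read to count as retention evidence.
#' @return A splice catalog: tibble with `intron`, `start`, `end` (canonical
#'   bounds), `type`, `offset`, `support`; novel junctions are attached as
#'   the `"novel"` attribute.
#' @export
classify_events <- function(junctions, alignments, model,
                            min_support = 2L, anchor = 8L) {
  ints <- model$introns
  rows <- list()
  for (i in seq_len(nrow(ints))) {
    s <- ints$start[i]
    e <- ints$end[i]
    canon <- junctions[junctions$donor == s & junctions$acceptor == e, ]
    rows[[length(rows) + 1L]] <- tibble(
      intron = ints$intron[i], start = s, end = e,
      type = "canonical", offset = 0L,
      support = if (nrow(canon) > 0L) canon$support[1] else 0L
    )
    alt5 <- junctions[junctions$acceptor == e & junctions$donor != s, ]
    if (nrow(alt5) > 0L) {
      rows[[length(rows) + 1L]] <- tibble(
        intron = ints$intron[i], start = s, end = e,
        type = "alt5", offset = as.integer(alt5$donor - s),
        support = alt5$support
      )
    }
    alt3 <- junctions[junctions$donor == s & junctions$acceptor != e, ]
    if (nrow(alt3) > 0L) {
      rows[[length(rows) + 1L]] <- tibble(
        intron = ints$intron[i], start = s, end = e,
        type = "alt3", offset = as.integer(alt3$acceptor - e),
        support = alt3$support
      )
    }
    left_n <- boundary_support(alignments, s, anchor)
    right_n <- boundary_support(alignments, e, anchor)
    if (min(left_n, right_n) >= min_support) {
      rows[[length(rows) + 1L]] <- tibble(
        intron = ints$intron[i], start = s, end = e,
        type = "retained", offset = 0L,
        support = as.integer(min(left_n, right_n))
      )
    }
  }
  catalog <- dplyr::bind_rows(rows)
  matched <- junctions$donor %in% ints$start | junctions$acceptor %in% ints$end
  attr(catalog, "novel") <- junctions[!matched, ]
  catalog
}

#' Infer the canonical gene model from junction evidence
#'
#' Canonical introns are chosen greedily by support (ties: smaller length,
#' then smaller donor) among called junctions, rejecting any junction that
#' overlaps an already-accepted canonical intron.
#'
#' @param junctions Junction tibble from [call_introns()].
#' @param bounds List with `tss`, `tes` from [determine_bounds()].
#' @param reference Reference sequence string.
#' @param gene_id Gene identifier for the model.
#' @return A `gene_model` with canonical introns only.
#' @export
infer_canonical_model <- function(junctions, bounds, reference,
                                  gene_id = "gene") {
  jx <- junctions[order(-junctions$support, junctions$length,
                        junctions$donor), ]
  picked <- list()
  for (i in seq_len(nrow(jx))) {
    ok <- TRUE
    for (p in picked) {
      if (jx$donor[i] < p[2] && jx$acceptor[i] > p[1]) {
        ok <- FALSE
        break
      }
    }
    if (ok) picked[[length(picked) + 1L]] <- c(jx$donor[i], jx$acceptor[i])
  }
  itab <- NULL
  if (length(picked) > 0L) {
    m <- do.call(rbind, picked)
    m <- m[order(m[, 1]), , drop = FALSE]
    itab <- tibble(start = m[, 1], end = m[, 2])
  }
  gene_model(gene_id = gene_id, seq = reference, introns = itab,
             tss = bounds$tss, tes = bounds$tes)
}

#' Annotate a gene model from a splice catalog
#'
#' Builds the model whose exons are the complement of the catalog's
#' canonical introns within the transcription bounds, carrying the catalog's
#' per-intron state sets.
#'
#' @param catalog Splice catalog from [classify_events()].
#' @param bounds List with `tss`, `tes`.
#' @param reference Reference sequence string.
#' @param gene_id Gene identifier.
#' @return A `gene_model` with `states` filled in.
#' @export
annotate_model <- function(catalog, bounds, reference, gene_id = "gene") {
  ints <- dplyr::distinct(catalog[, c("intron", "start", "end")])
  ints <- ints[order(ints$start), ]
  attr(ints, "novel") <- NULL
  if (nrow(ints) > 1L) {
    overlap <- ints$start[-1L] < ints$end[-nrow(ints)]
    if (any(overlap)) {
      k <- which(overlap)[1]
      sod_error(
        paste0("overlapping canonical introns: ", ints$intron[k], " [",
               ints$start[k], ",", ints$end[k], ") and ", ints$intron[k + 1L],
               " [", ints$start[k + 1L], ",", ints$end[k + 1L], ")"),
        "sod_ambiguity_error"
      )
    }
  }
  states <- lapply(ints$intron, function(id) {
    sub <- catalog[catalog$intron == id, ]
    vapply(seq_len(nrow(sub)), function(r) {
      state_label(sub$type[r], sub$offset[r])
    }, character(1))
  })
  names(states) <- ints$intron
  gene_model(gene_id = gene_id, seq = reference,
             introns = ints, tss = bounds$tss, tes = bounds$tes,
             states = states)
}
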