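# Combinatorial transcript enumeration over per-intron splicing states, ORF
# and UTR annotation, translation, domain screening and distinct-protein
# counting -- including genes whose functional initiation codon sits inside a
# retainable intron.

#' Enumerate transcripts from per-intron state sets
#'
#' Produces exactly the Cartesian product of the per-intron state sets, each
#' transcript assembled by applying its states left to right, in
#' deterministic lexicographic order of state vectors.
#'
#' @param model A `gene_model`.
#' @param catalog Optional splice catalog from [classify_events()]; when
#'   `NULL` the model's own `states` are used. Introns absent from either
#'   are treated as canonical-only.
#' @param cap Error if the product of state-set sizes exceeds this.
#' @return Tibble with `transcript_id`, `state_label` (comma-collapsed),
#'   `states` (list-column), `seq`, `length`.
#' @export
enumerate_transcripts <- function(model, catalog = NULL, cap = 1e6) {
  ids <- model$introns$intron
  sets <- lapply(ids, function(id) {
    st <- if (!is.null(catalog)) {
      sub <- catalog[catalog$intron == id, ]
      if (nrow(sub) == 0L) {
        "canonical"
      } else {
        vapply(seq_len(nrow(sub)),
               function(r) state_label(sub$type[r], sub$offset[r]),
               character(1))
      }
    } else if (!is.null(model$states)) {
      model$states[[id]]
    } else {
      "canonical"
    }
    sort(unique(st))
  })
  n_tx <- prod(lengths(sets))
  if (n_tx > cap) {
    sod_error(paste0("state-set product ", n_tx, " exceeds the cap ", cap),
              "sod_size_error")
  }
  grid <- if (length(sets) == 0L) {
    data.frame(row.names = 1)
  } else {
    g <- expand.grid(rev(sets), stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
    g[, rev(seq_along(g)), drop = FALSE]
  }
  states <- lapply(seq_len(nrow(grid)), function(i) {
    as.character(unlist(grid[i, , drop = FALSE], use.names = FALSE))
  })
  seqs <- vapply(states, function(st) build_transcript(model, st)$seq,
                 character(1))
  tibble(
    transcript_id = sprintf("%s_iso%04d", model$gene_id, seq_along(states)),
    state_label = vapply(states, paste, character(1), collapse = ","),
    states = states,
    seq = seqs,
    length = nchar(seqs)
  )
}

#' Find the open reading frame of a transcript
#'
#' The longest ATG-initiated ORF terminating at an in-frame stop codon; ties
#' are broken in favour of the 5'-most start. Transcripts with no ORF of at
#' least `min_codons` codons (start and coding codons, excluding the stop)
#' yield `NULL`.
#'
#' @param transcript Nucleotide sequence.
#' @param min_codons Minimum ORF length in codons (default 50).
#' @return `NULL`, or a list with 0-based half-open `start`/`end` of the ORF
#'   (stop codon included), `utr5`, `utr3`, `protein`.
#' @export
find_orf <- function(transcript, min_codons = 50L) {
  n <- nchar(transcript)
  atg <- gregexpr("ATG", transcript, fixed = TRUE)[[1]]
  if (atg[1] == -1L) {
    return(NULL)
  }
  stops <- sort(unique(unlist(lapply(c("TAA", "TAG", "TGA"), function(cod) {
    p <- gregexpr(cod, transcript, fixed = TRUE)[[1]]
    if (p[1] == -1L) integer() else as.integer(p)
  }))))
  best_len <- -1L
  best_a <- NA_integer_
  best_s <- NA_integer_
  for (a in as.integer(atg)) {
    frame_stops <- stops[stops >= a + 3L & (stops - a) %% 3L == 0L]
    if (length(frame_stops) == 0L) next
    s <- frame_stops[1]
    len <- s + 3L - a
    if (len > best_len) {
      best_len <- len
      best_a <- a
      best_s <- s
    }
  }
  if (is.na(best_a) || (best_len / 3L - 1L) < min_codons) {
    return(NULL)
  }
  protein <- translate_cds(substr(transcript, best_a, best_s - 1L))
  list(
    start = best_a - 1L, end = best_s + 2L,
    utr5 = substr(transcript, 1L, best_a - 1L),
    utr3 = if (best_s + 3L <= n) substr(transcript, best_s + 3L, n) else "",
    protein = protein
  )
}

#' Screen enumerated isoforms for a domain profile
#'
#' Each transcript is ORF-annotated and translated; translations are checked
#' against the family profile and grouped by identical protein string.
#' Transcripts whose ORF is disrupted before the domain are kept with
#' verdict `"absent"`.
#'
#' @param transcripts Tibble from [enumerate_transcripts()].
#' @param profile A [domain_profile()].
#' @param config A [screen_config()].
#' @param min_codons ORF floor passed to [find_orf()].
#' @return Isoform report tibble: `transcript_id`, `state_label`, `states`,
#'   `has_orf`, `orf_start`, `orf_end`, `protein`, `verdict`, `n_matched`,
#'   `group` (distinct-protein group id; `NA` without an ORF).
#' @export
screen_isoforms <- function(transcripts, profile, config = screen_config(),
                            min_codons = 50L) {
  n <- nrow(transcripts)
  protein <- rep(NA_character_, n)
  orf_start <- rep(NA_integer_, n)
  orf_end <- rep(NA_integer_, n)
  verdict <- rep(NA_character_, n)
  n_matched <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    orf <- find_orf(transcripts$seq[i], min_codons)
    if (is.null(orf)) next
    protein[i] <- orf$protein
    orf_start[i] <- orf$start
    orf_end[i] <- orf$end
    chk <- domain_check(orf$protein, profile, config = config)
    verdict[i] <- chk$verdict
    n_matched[i] <- sum(chk$report$matched)
  }
  group <- rep(NA_integer_, n)
  has <- !is.na(protein)
  group[has] <- match(protein[has], unique(protein[has]))
  tibble(
    transcript_id = transcripts$transcript_id,
    state_label = transcripts$state_label,
    states = transcripts$states,
    has_orf = has, orf_start = orf_start, orf_end = orf_end,
    protein = protein, verdict = verdict, n_matched = n_matched,
    group = group
  )
}

#' Count distinct proteins among isoform reports
#'
#' @param reports Tibble from [screen_isoforms()].
#' @param filter Which reports to count: every ORF-bearing transcript, only
#'   domain-complete ones, or any with at least partial domain evidence.
#' @return List with `count` and `representatives` (one row per distinct
#'   protein: the transcript with the lexicographically smallest state
#'   vector).
#' @export
count_distinct_proteins <- function(reports,
                                    filter = c("all-with-ORF",
                                               "domain-complete",
                                               "domain-any")) {
  filter <- match.arg(filter)
  keep <- switch(filter,
    "all-with-ORF" = reports$has_orf,
    "domain-complete" = reports$has_orf & reports$verdict == "complete",
    "domain-any" = reports$has_orf & reports$verdict %in% c("complete",
                                                            "partial")
  )
  sub <- reports[keep, ]
  if (nrow(sub) == 0L) {
    return(list(count = 0L,
                representatives = sub[, c("transcript_id", "state_label",
                                          "protein", "verdict")]))
  }
  sub <- sub[order(sub$state_label), ]
  reps <- sub[!duplicated(sub$protein), ]
  list(
    count = length(unique(sub$protein)),
    representatives = reps[, c("transcript_id", "state_label", "protein",
                               "verdict")]
  )
}
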