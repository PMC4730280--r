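# Junction-aware mapping of paired-end reads to a gene region, paired-end
# determination of transcription bounds, and per-base coverage verification.
# Mates are anchored by exact seed words from both ends and extended; a mate
# may split once across a GT..AG reference skip. Mapping is deterministic and
# order-independent; equal-score alternative placements are dropped
# (conservative junction evidence).

#' Mapper configuration
#'
#' @param mode `"transcriptome"` (spliced, up to `max_mismatches`
#'   substitutions per mate) or `"genome"` (contiguous, exact).
#' @param max_mismatches Maximum substitutions per mate; defaults to 2 for
#'   transcriptome mode and 0 for genome mode.
#' @param seed_length Exact seed-word length used for anchoring.
#' @param span_min,span_max Allowed mate-pair span on the reference, in bp.
#' @param min_intron,max_intron Accepted reference-skip lengths.
#' @param min_block Minimum aligned block length flanking a skip.
#' @return A `mapper_config` list.
#' @export
mapper_config <- function(mode = c("transcriptome", "genome"),
                          max_mismatches = NULL, seed_length = 16L,
                          span_min = 1L, span_max = 2000L,
                          min_intron = 4L, max_intron = 2000L,
                          min_block = 8L) {
  mode <- match.arg(mode)
  if (is.null(max_mismatches)) {
    max_mismatches <- if (mode == "transcriptome") 2L else 0L
  }
  if (span_min < 1L || max_mismatches < 0L) {
    sod_error("invalid mapper configuration", "sod_config_error")
  }
  structure(
    list(mode = mode, max_mismatches = as.integer(max_mismatches),
         seed_length = as.integer(seed_length),
         span_min = as.integer(span_min), span_max = as.integer(span_max),
         min_intron = as.integer(min_intron),
         max_intron = as.integer(max_intron),
         min_block = as.integer(min_block)),
    class = "mapper_config"
  )
}

# Prepared reference: raw bytes plus an exact k-mer position index.
prepare_reference <- function(reference, config) {
  k <- config$seed_length
  n <- nchar(reference)
  if (n < k) {
    sod_error("reference shorter than the seed length", "sod_input_error")
  }
  kmers <- substring(reference, 1:(n - k + 1L), k:n)
  index <- new.env(parent = emptyenv(), size = length(kmers))
  for (i in seq_along(kmers)) {
    key <- kmers[i]
    index[[key]] <- c(index[[key]], i)
  }
  list(seq = reference, raw = charToRaw(reference), n = n, k = k,
       index = index)
}

# Map one mate sequence; returns NULL (unmapped/ambiguous) or a list with
# blocks (matrix: ref_start, ref_end, read_start; 0-based half-open),
# mismatches and strand.
map_mate <- function(seq, ref, config) {
  L <- nchar(seq)
  k <- ref$k
  if (L < 2L * k) {
    return(NULL)
  }
  best <- NULL
  best_mm <- config$max_mismatches + 1L
  ambiguous <- FALSE
  consider <- function(mm, blocks, strand) {
    if (mm < best_mm) {
      best <<- list(mismatches = mm, blocks = blocks, strand = strand)
      best_mm <<- mm
      ambiguous <<- FALSE
    } else if (mm == best_mm && !is.null(best) &&
                 !identical(blocks, best$blocks)) {
      ambiguous <<- TRUE
    }
  }
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    sraw <- charToRaw(s)
    # seed words tiled across the mate; each hit implies a candidate origin
    # for the block the seed sits in
    offs <- unique(c(seq(0L, L - k, by = 4L), L - k))
    origins <- integer()
    for (off in offs) {
      hits <- ref$index[[substr(s, off + 1L, off + k)]]
      if (!is.null(hits)) origins <- c(origins, hits - 1L - off)
    }
    origins <- unique(origins)
    # contiguous candidates
    for (p in origins) {
      if (p < 0L || p + L > ref$n) next
      mm <- sum(ref$raw[(p + 1L):(p + L)] != sraw)
      if (mm <= config$max_mismatches) {
        consider(mm, cbind(p, p + L, 0L), strand)
      }
    }
    if (config$mode == "genome") next
    # one-junction candidates: a pair of origins (p, p + skip) brackets a
    # candidate reference skip
    for (p in origins) {
      for (q in origins) {
        skip <- q - p
        if (skip < config$min_intron || skip > config$max_intron) next
        if (p < 0L || p + L + skip > ref$n) next
        d1 <- ref$raw[(p + 1L):(p + L)] != sraw
        d2 <- ref$raw[(p + skip + 1L):(p + skip + L)] != sraw
        lcum <- cumsum(d1)
        rsuf <- rev(cumsum(rev(d2)))
        bs <- config$min_block:(L - config$min_block)
        tot <- lcum[bs] + c(rsuf, 0)[bs + 1L]
        donor_ok <- ref$raw[p + bs + 1L] == charToRaw("G") &
          ref$raw[p + bs + 2L] == charToRaw("T")
        acc_ok <- ref$raw[p + bs + skip - 1L] == charToRaw("A") &
          ref$raw[p + bs + skip] == charToRaw("G")
        ok <- donor_ok & acc_ok & tot <= config$max_mismatches
        if (!any(ok)) next
        cand <- bs[ok][which.min(tot[ok])] # ties: leftmost donor
        mm <- min(tot[ok])
        consider(
          mm,
          rbind(
            cbind(p, p + cand, 0L),
            cbind(p + cand + skip, p + L + skip, cand)
          ),
          strand
        )
      }
    }
  }
  if (is.null(best) || ambiguous) {
    return(NULL)
  }
  best
}

#' Map a read pair to a reference
#'
#' Both mates are mapped (each orientation tried); the pair is retained only
#' if both mates map and their reference span falls within the configured
#' window. Unmapped is a value, not an error.
#'
#' @param read1,read2 Mate sequences.
#' @param ref A prepared reference from `prepare_reference()` or a reference
#'   sequence string.
#' @param config A [mapper_config()].
#' @return List with per-mate alignments (`mate1`, `mate2`) or `NULL`.
#' @export
map_read_pair <- function(read1, read2, ref, config = mapper_config()) {
  if (is.character(ref)) {
    ref <- prepare_reference(ref, config)
  }
  a1 <- map_mate(read1, ref, config)
  a2 <- map_mate(read2, ref, config)
  if (is.null(a1) || is.null(a2)) {
    return(NULL)
  }
  span <- max(a1$blocks[, 2], a2$blocks[, 2]) -
    min(a1$blocks[, 1], a2$blocks[, 1])
  if (span < config$span_min || span > config$span_max) {
    return(NULL)
  }
  list(mate1 = a1, mate2 = a2)
}

#' Map a table of read pairs
#'
#' @param pairs Tibble with `pair_id`, `read1`, `read2` (as produced by
#'   [simulate_read_pairs()] or [read_fastq_pairs()]).
#' @param reference Reference sequence string.
#' @param config A [mapper_config()].
#' @return Alignment tibble, one row per mapped mate: `read_id`, `mate`,
#'   `strand`, `mismatches`, `n_blocks`, and 0-based half-open block columns
#'   `start1`, `end1`, `rstart1`, `start2`, `end2`, `rstart2` (`NA` for
#'   single-block alignments).
#' @export
map_reads <- function(pairs, reference, config = mapper_config()) {
  ref <- prepare_reference(reference, config)
  rows <- vector("list", 2L * nrow(pairs))
  ids <- character(2L * nrow(pairs))
  strands <- character(2L * nrow(pairs))
  cnt <- 0L
  for (i in seq_len(nrow(pairs))) {
    hit <- map_read_pair(pairs$read1[i], pairs$read2[i], ref, config)
    if (is.null(hit)) next
    for (m in 1:2) {
      a <- hit[[m]]
      b <- a$blocks
      cnt <- cnt + 1L
      ids[cnt] <- pairs$pair_id[i]
      strands[cnt] <- a$strand
      rows[[cnt]] <- c(
        m, a$mismatches, nrow(b),
        b[1, 1], b[1, 2], b[1, 3],
        if (nrow(b) > 1L) c(b[2, 1], b[2, 2], b[2, 3]) else rep(NA_integer_, 3)
      )
    }
  }
  if (cnt == 0L) {
    return(tibble(
      read_id = character(), mate = integer(), strand = character(),
      mismatches = integer(), n_blocks = integer(),
      start1 = integer(), end1 = integer(), rstart1 = integer(),
      start2 = integer(), end2 = integer(), rstart2 = integer()
    ))
  }
  m <- do.call(rbind, rows[seq_len(cnt)])
  tibble(
    read_id = ids[seq_len(cnt)], mate = as.integer(m[, 1]),
    strand = strands[seq_len(cnt)], mismatches = as.integer(m[, 2]),
    n_blocks = as.integer(m[, 3]),
    start1 = as.integer(m[, 4]), end1 = as.integer(m[, 5]),
    rstart1 = as.integer(m[, 6]),
    start2 = as.integer(m[, 7]), end2 = as.integer(m[, 8]),
    rstart2 = as.integer(m[, 9])
  )
}

#' Determine transcription bounds from mapped pairs
#'
#' The paired-end rule: the transcription start site is the smallest
#' reference coordinate covered by any mapped mate, the termination site one
#' past the largest.
#'
#' @param alignments Alignment tibble from [map_reads()].
#' @return List with `tss`, `tes` (0-based half-open).
#' @export
determine_bounds <- function(alignments) {
  if (nrow(alignments) == 0L) {
    sod_error("no mapped pairs: cannot determine transcription bounds",
              "sod_evidence_error")
  }
  tss <- min(alignments$start1)
  tes <- max(c(alignments$end1, alignments$end2), na.rm = TRUE)
  list(tss = as.integer(tss), tes = as.integer(tes))
}

#' Per-base coverage and verification verdict
#'
#' Depth counts aligned blocks only (reference skips contribute nothing).
#' The region is `verified` when every base is covered by at least one read;
#' the minimum depth is reported so stronger support thresholds can be
#' checked.
#'
#' @param alignments Alignment tibble from [map_reads()].
#' @param region 0-based half-open `c(start, end)` interval to profile.
#' @return List with `depth` (tibble `pos`, `depth`), `min_depth`,
#'   `verified`, and `gaps` (uncovered intervals).
#' @export
coverage_profile <- function(alignments, region) {
  r0 <- region[1]
  r1 <- region[2]
  width <- r1 - r0
  if (width <= 0L) {
    sod_error("empty coverage region", "sod_input_error")
  }
  delta <- numeric(width + 1L)
  add <- function(s, e) {
    s <- pmax(s, r0)
    e <- pmin(e, r1)
    keep <- !is.na(s) & !is.na(e) & s < e
    s <- s[keep] - r0
    e <- e[keep] - r0
    for (i in seq_along(s)) {
      delta[s[i] + 1L] <<- delta[s[i] + 1L] + 1
      delta[e[i] + 1L] <<- delta[e[i] + 1L] - 1
    }
  }
  add(alignments$start1, alignments$end1)
  add(alignments$start2, alignments$end2)
  depth <- cumsum(delta[seq_len(width)])
  uncovered <- depth == 0
  gaps <- tibble(start = integer(), end = integer())
  if (any(uncovered)) {
    r <- rle(uncovered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gaps <- tibble(
      start = as.integer(starts[r$values] - 1L + r0),
      end = as.integer(ends[r$values] + r0)
    )
  }
  list(
    depth = tibble(pos = seq(r0, r1 - 1L), depth = as.integer(depth)),
    min_depth = as.integer(min(depth)),
    verified = !any(uncovered),
    gaps = gaps
  )
}
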