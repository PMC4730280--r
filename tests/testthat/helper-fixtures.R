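# Shared fixtures (built once per test run) and independent oracles.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.cache[[key]])) {
    .cache[[key]] <- builder()
  }
  .cache[[key]]
}

fx_cuzn <- function() cached("cuzn", cuzn_sod1_fixture)
fx_mn1 <- function() cached("mn1", mnsod1_fixture)
fx_mn2 <- function() cached("mn2", mnsod2_fixture)
fx_fixtures <- function() list(fx_cuzn(), fx_mn1(), fx_mn2())

fx_cuzn_reports <- function() {
  cached("cuzn_reports", function() {
    g <- fx_cuzn()
    screen_isoforms(enumerate_transcripts(g), g$meta$profile)
  })
}

# Independent brute-force Smith-Waterman oracle: textbook three-matrix affine
# DP filled with scalar loops (gap of length L costs open + ext * L).
bf_sw <- function(q, r, mat, open = 11, ext = 1) {
  qa <- strsplit(q, "", fixed = TRUE)[[1]]
  ra <- strsplit(r, "", fixed = TRUE)[[1]]
  m <- length(qa)
  n <- length(ra)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + mat[qa[i - 1], ra[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

blosum62 <- function() {
  cached("blosum62", function() {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
}

random_protein <- function(n) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# Bootstrap support of the bipartition separating `tips` from the rest.
split_support <- function(tree, tips) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  want <- sort(match(tips, labs))
  rest <- sort(setdiff(seq_along(labs), want))
  for (i in seq_along(pp)) {
    ds <- sort(pp[[i]])
    if (identical(ds, want) || identical(ds, rest)) {
      return(as.integer(tree$node.label[i]))
    }
  }
  NA_integer_
}

# All events (intron id, state label) a fixture's mixture realises.
truth_events <- function(model) {
  ev <- list()
  for (i in seq_len(nrow(model$introns))) {
    for (st in setdiff(model$states[[i]], "canonical")) {
      ev[[length(ev) + 1L]] <- c(model$introns$intron[i], st)
    }
  }
  ev
}
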