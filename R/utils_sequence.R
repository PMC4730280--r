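# Low-level sequence helpers shared across modules. All coordinates handled
# here are 0-based half-open unless a function name says otherwise.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*"
)

sod_error <- function(message, class, ...) {
  abort(message, class = c(class, "sodsplice_error"), ...)
}

#' Reverse-complement a nucleotide string
#'
#' @param x Character vector of nucleotide sequences (A, C, G, T, N).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(x) {
  vapply(x, function(s) {
    chars <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")[chars]
    if (anyNA(comp)) {
      sod_error("non-ACGTN letter in nucleotide sequence", "sod_input_error")
    }
    paste(comp, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Translate a coding sequence
#'
#' Translates an in-frame nucleotide string with the standard genetic code.
#' Stop codons translate to `*`.
#'
#' @param cds Coding sequence; length must be a multiple of 3.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) %% 3L != 0L) {
    sod_error("coding sequence length is not a multiple of 3", "sod_input_error")
  }
  if (nchar(cds) == 0L) {
    return("")
  }
  aa <- Biostrings::translate(
    Biostrings::DNAString(cds),
    if.fuzzy.codon = "solve", no.init.codon = TRUE
  )
  as.character(aa)
}

# Validate residue alphabet; `type` is "dna" or "protein".
validate_residues <- function(residues, type, ids = NULL) {
  pattern <- if (type == "dna") "^[ACGTN]+$" else "^[ARNDCQEGHILKMFPSTWYVX*]+$"
  bad <- !grepl(pattern, residues)
  if (any(bad)) {
    offender <- if (is.null(ids)) which(bad)[1] else ids[bad][1]
    sod_error(
      paste0("invalid ", type, " residues in record '", offender, "'"),
      "sod_format_error"
    )
  }
  invisible(TRUE)
}

# Phred+33 helpers -----------------------------------------------------------

#' Decode a Phred+33 quality string to integer scores
#'
#' @param quality Quality string (one character per base, offset 33).
#' @return Integer vector of Phred scores.
#' @export
#' @examples
#' phred33_scores("IIII")
phred33_scores <- function(quality) {
  scores <- as.integer(charToRaw(quality)) - 33L
  if (any(scores < 0L | scores > 60L)) {
    sod_error("quality string is not Phred+33", "sod_format_error")
  }
  scores
}

phred33_string <- function(scores) {
  rawToChar(as.raw(scores + 33L))
}

# Seeded RNG scoping: evaluates `expr` under a local seed without disturbing
# the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Random nucleotide string with no "ATG" substring (used for UTRs and intron
# interiors where a stray start codon would confound ORF logic).
random_dna_no_atg <- function(n, bases = c("A", "C", "G", "T")) {
  if (n <= 0) return("")
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      b <- sample(bases, 1L)
      if (i >= 3L && out[i - 2L] == "A" && out[i - 1L] == "T" && b == "G") next
      out[i] <- b
      break
    }
  }
  paste(out, collapse = "")
}

# substring of a 0-based half-open interval (vectorised over start/end)
substr0 <- function(x, start, end) {
  substring(x, start + 1L, end)
}
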