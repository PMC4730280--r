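# Generators for every input the pipeline needs: fixture genes with
# configurable GT-AG intron layouts (defaults follow the three studied sod
# genes), isoform mixtures, paired-end reads, qPCR Ct tables and decoy
# proteomes. All generators are pure functions of (config, seed).

#' Describe one intron of a fixture gene
#'
#' @param length Intron length in bp (>= 4, room for GT..AG).
#' @param retention Can the intron be retained in mature transcripts?
#' @param alt5 Optional alternative 5' donor offset, measured into the intron
#'   (0 < offset < length): the variant intron starts `alt5` bases downstream
#'   of the canonical donor.
#' @param alt3 Optional alternative 3' acceptor offset, measured into the
#'   intron: the variant intron ends `alt3` bases upstream of the canonical
#'   acceptor.
#' @param contains_start Does the functional ORF's initiation codon lie
#'   inside this (retainable) intron?
#' @return A one-row tibble.
#' @export
intron_spec <- function(length, retention = FALSE, alt5 = NA_integer_,
                        alt3 = NA_integer_, contains_start = FALSE) {
  length <- as.integer(length)
  if (length < 4L) {
    sod_error("intron length must be >= 4 (room for GT..AG)",
              "sod_config_error")
  }
  for (off in c(alt5, alt3)) {
    if (!is.na(off) && (off <= 0L || off >= length)) {
      sod_error("alternative-site offsets must lie inside the intron",
                "sod_config_error")
    }
  }
  if (contains_start && !retention) {
    sod_error("an initiation-codon intron must be retention-capable",
              "sod_config_error")
  }
  tibble(length = length, retention = retention,
         alt5 = as.integer(alt5), alt3 = as.integer(alt3),
         contains_start = contains_start)
}

#' Intron layouts of the three fixture genes
#'
#' The default layouts reproduce the studied gene structures: the Cu-Zn SOD
#' gene carries eight introns of 52, 76, 80, 125, 57, 58, 54 and 55 bp with
#' retention on I1/I3/I4/I7/I8, an alternative 3' site on I2 and on I3, and
#' the functional initiation codon inside I4; the first Mn SOD gene carries
#' introns of 154, 57 and 56 bp (I1 retained or alternatively donated, I2
#' retained); the second carries 47, 72, 126, 119, 88, 61 and 87 bp with
#' retention on I1/I3/I4/I5/I7.
#'
#' @return Tibble of intron specs (one row per intron).
#' @export
cuzn_sod1_introns <- function() {
  dplyr::bind_rows(
    intron_spec(52, retention = TRUE),
    intron_spec(76, alt3 = 6),
    intron_spec(80, retention = TRUE, alt3 = 9),
    intron_spec(125, retention = TRUE, contains_start = TRUE),
    intron_spec(57),
    intron_spec(58),
    intron_spec(54, retention = TRUE),
    intron_spec(55, retention = TRUE)
  )
}

#' @rdname cuzn_sod1_introns
#' @export
mnsod1_introns <- function() {
  dplyr::bind_rows(
    intron_spec(154, retention = TRUE, alt5 = 9),
    intron_spec(57, retention = TRUE),
    intron_spec(56)
  )
}

#' @rdname cuzn_sod1_introns
#' @export
mnsod2_introns <- function() {
  dplyr::bind_rows(
    intron_spec(47, retention = TRUE),
    intron_spec(72),
    intron_spec(126, retention = TRUE),
    intron_spec(119, retention = TRUE),
    intron_spec(88, retention = TRUE),
    intron_spec(61),
    intron_spec(87, retention = TRUE)
  )
}

#' Exon design for a fixture gene
#'
#' @param profile A [domain_profile()] whose residues the encoded protein
#'   carries.
#' @param protein_length Length of the encoded protein; defaults to the
#'   profile reference length.
#' @param utr5_length,utr3_length UTR lengths in bp; the 5' UTR is generated
#'   free of ATG trinucleotides.
#' @param insert_at Functional-mRNA positions (0-based) at which the inserted
#'   introns sit, one per intron spec; `NA` for the intron carrying the
#'   initiation codon, which is carved out of the mRNA instead.
#' @param start_pad How many 5' UTR bases the initiation-codon intron retains
#'   upstream of the ATG.
#' @return A `gene_design` list.
#' @export
gene_design <- function(profile, protein_length = nchar(profile$reference),
                        utr5_length = 60L, utr3_length = 80L,
                        insert_at = NULL, start_pad = 10L) {
  structure(
    list(profile = profile, protein_length = as.integer(protein_length),
         utr5_length = as.integer(utr5_length),
         utr3_length = as.integer(utr3_length),
         insert_at = insert_at, start_pad = as.integer(start_pad)),
    class = "gene_design"
  )
}

# Uniform random synonymous codon table (standard code, stops excluded).
codons_for <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- split(names(gc), unname(gc))
      tab[["*"]] <<- NULL
    }
    tab
  }
})

reverse_translate <- function(protein) {
  tab <- codons_for()
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  paste(vapply(aa, function(a) {
    ch <- tab[[a]]
    if (is.null(ch)) {
      sod_error(paste0("cannot reverse-translate residue '", a, "'"),
                "sod_config_error")
    }
    ch[sample.int(length(ch), 1L)]
  }, character(1)), collapse = "")
}

# Replace stray GT (near donors) / AG (near acceptors) dinucleotides inside
# an intron so junction calls are unambiguous; designed alternative sites are
# preserved.
intron_sequence <- function(length, alt5 = NA, alt3 = NA) {
  body <- strsplit(random_dna_no_atg(length - 4L), "", fixed = TRUE)[[1]]
  chars <- c("G", "T", body, "A", "G")
  if (!is.na(alt5)) {
    chars[alt5 + 1L] <- "G"
    chars[alt5 + 2L] <- "T"
  }
  if (!is.na(alt3)) {
    chars[length - alt3 - 1L] <- "A"
    chars[length - alt3] <- "G"
  }
  head_keep <- c(0L, if (!is.na(alt5)) alt5)
  for (j in setdiff(1:min(12L, length - 3L), head_keep)) {
    if (chars[j + 1L] == "G" && chars[j + 2L] == "T") chars[j + 1L] <- "C"
  }
  tail_keep <- c(length - 2L, if (!is.na(alt3)) length - alt3 - 2L)
  for (j in setdiff(max(0L, length - 12L):(length - 3L), tail_keep)) {
    if (chars[j + 1L] == "A" && chars[j + 2L] == "G") chars[j + 1L] <- "C"
  }
  # Scrub any ATG the designed-site edits may have produced: an intronic
  # start codon upstream of the functional ORF would confound ORF scans in
  # retained variants. Designed dinucleotides are never touched; the middle
  # T of an ATG overlapping a designed G is always a free position.
  designed <- c(1L, 2L, length - 1L, length,
                if (!is.na(alt5)) c(alt5 + 1L, alt5 + 2L),
                if (!is.na(alt3)) c(length - alt3 - 1L, length - alt3))
  repeat {
    hit <- regexpr("ATG", paste(chars, collapse = ""), fixed = TRUE)
    if (hit == -1L) break
    target <- c(hit + 1L, hit, hit + 2L)
    target <- target[!(target %in% designed)][1]
    chars[target] <- "C"
  }
  paste(chars, collapse = "")
}

state_set_from_spec <- function(spec) {
  states <- "canonical"
  if (spec$retention) states <- c(states, "retained")
  if (!is.na(spec$alt5)) states <- c(states, state_label("alt5", spec$alt5))
  if (!is.na(spec$alt3)) states <- c(states, state_label("alt3", -spec$alt3))
  states
}

#' Build a fixture gene from intron specs and an exon design
#'
#' Constructs the functional mRNA (ATG-free 5' UTR, a CDS encoding the
#' profile residues, 3' UTR), then threads the introns through it: ordinary
#' introns are inserted as GT..AG sequences, while an intron flagged
#' `contains_start` is carved out of the mRNA so that the functional ORF's
#' initiation codon lies inside it -- the canonical (all-spliced) transcript
#' then has no start codon for the domain-complete frame, and only
#' transcripts retaining that intron can encode the full protein.
#'
#' @param specs Tibble of [intron_spec()] rows.
#' @param design A [gene_design()].
#' @param seed Integer seed.
#' @param gene_id Gene identifier.
#' @return A `gene_model` whose `states` hold the per-intron splicing modes
#'   and whose `meta` records the encoded protein, family profile and the
#'   functional state vector.
#' @export
build_gene_fixture <- function(specs, design, seed = 1L, gene_id = "gene1") {
  with_seed(seed, {
    n <- nrow(specs)
    prof <- design$profile
    if (design$protein_length < max(prof$residues$position)) {
      sod_error("exon design shorter than the required domain positions",
                "sod_config_error")
    }
    protein <- profile_member(prof, seed + 13L)
    cds <- paste0(reverse_translate(protein), "TAA")
    utr5 <- random_dna_no_atg(design$utr5_length)
    utr3 <- random_dna_no_atg(design$utr3_length)
    mrna <- paste0(utr5, cds, utr3)
    u5 <- design$utr5_length

    carved <- which(specs$contains_start)
    if (length(carved) > 1L) {
      sod_error("at most one intron may carry the initiation codon",
                "sod_config_error")
    }
    insert_at <- design$insert_at
    if (is.null(insert_at)) {
      insert_at <- as.integer(round(seq(40L, nchar(mrna) - 40L,
                                        length.out = n)))
      if (length(carved) == 1L) insert_at[carved] <- NA_integer_
    }
    if (length(insert_at) != n) {
      sod_error("insert_at must give one position per intron",
                "sod_config_error")
    }

    carve_start <- NA_integer_
    if (length(carved) == 1L) {
      len_k <- specs$length[carved]
      pad <- design$start_pad
      if (len_k <= pad + 4L || pad < 2L) {
        sod_error("initiation-codon intron too short for the UTR pad",
                  "sod_config_error")
      }
      carve_start <- u5 - pad
      chars <- strsplit(mrna, "", fixed = TRUE)[[1]]
      chars[carve_start + 1L] <- "G"
      chars[carve_start + 2L] <- "T"
      # the new donor G must not complete an ATG with the UTR bases before it
      if (carve_start >= 2L && chars[carve_start - 1L] == "A" &&
            chars[carve_start] == "T") {
        chars[carve_start] <- "C"
      }
      # The carved intron must end in AG; its acceptor falls inside the CDS,
      # so rewrite the touched codon(s) with fixed safe choices and rederive
      # the protein from the CDS afterwards.
      t0 <- carve_start + len_k - 2L # 0-based mRNA position of the 'A'
      c0 <- t0 - u5
      if (c0 < 3L) {
        sod_error("initiation-codon intron acceptor falls before the CDS",
                  "sod_config_error")
      }
      phase <- c0 %% 3L
      codon_i <- c0 %/% 3L # 0-based codon index
      touched <- unique(c(codon_i, (c0 + 1L) %/% 3L)) + 1L
      if (any(touched %in% prof$residues$position) || any(touched == 1L)) {
        sod_error("carved-intron acceptor collides with a required residue",
                  "sod_config_error")
      }
      base <- u5 + codon_i * 3L
      if (phase == 0L) {
        chars[base + 1:3] <- c("A", "G", "A")
      } else if (phase == 1L) {
        chars[base + 1:3] <- c("A", "A", "G")
      } else {
        chars[base + 1:3] <- c("G", "C", "A")
        chars[base + 4:6] <- c("G", "G", "C")
      }
      mrna <- paste(chars, collapse = "")
      cds <- substr0(mrna, u5, u5 + nchar(cds))
      protein <- sub("\\*$", "", translate_cds(cds))
    }

    ins_seq <- rep(NA_character_, n)
    mchars <- strsplit(mrna, "", fixed = TRUE)[[1]]
    cds_end <- u5 + nchar(cds)
    for (i in seq_len(n)) {
      if (length(carved) == 1L && i == carved) next
      p <- insert_at[i]
      if (is.na(p) || p < 20L || p > nchar(mrna) - 20L) {
        sod_error("intron insertion points must lie 20 bp inside the mRNA",
                  "sod_config_error")
      }
      if (!is.na(carve_start) && p > carve_start &&
            p < carve_start + specs$length[carved]) {
        sod_error("intron insertion point falls inside the carved intron",
                  "sod_config_error")
      }
      # an inserted donor G after UTR bases "AT" would create a start codon
      in_utr <- (p - 1L) < u5 || (p - 1L) >= cds_end
      if (in_utr && p >= 2L && mchars[p - 1L] == "A" && mchars[p] == "T") {
        mchars[p] <- "C"
      }
      ins_seq[i] <- intron_sequence(specs$length[i], specs$alt5[i],
                                    specs$alt3[i])
    }
    mrna <- paste(mchars, collapse = "")

    # Assemble the genomic sequence and intron coordinates in mRNA order.
    anchor <- ifelse(is.na(insert_at), carve_start, insert_at)
    ord <- order(anchor)
    shift <- 0L
    gseq <- mrna
    istart <- integer(n)
    for (i in ord) {
      if (length(carved) == 1L && i == carved) {
        istart[i] <- carve_start + shift
      } else {
        p <- insert_at[i] + shift
        gseq <- paste0(substr0(gseq, 0L, p), ins_seq[i],
                       substr0(gseq, p, nchar(gseq)))
        istart[i] <- p
        shift <- shift + specs$length[i]
      }
    }
    if (is.unsorted(istart, strictly = TRUE)) {
      sod_error("intron anchors must be in ascending mRNA order",
                "sod_config_error")
    }
    introns <- tibble(
      intron = sprintf("I%d", seq_len(n)),
      start = istart,
      end = istart + specs$length
    )
    states <- lapply(seq_len(n), function(i) state_set_from_spec(specs[i, ]))
    names(states) <- sprintf("I%d", seq_len(n))

    functional <- rep("canonical", n)
    if (length(carved) == 1L) functional[carved] <- "retained"

    model <- gene_model(
      gene_id = gene_id, seq = gseq, introns = introns,
      states = states,
      meta = list(
        protein = protein, profile = prof, family = prof$family,
        functional_states = functional, mrna_functional = mrna,
        cds_mrna_start = u5, seed = seed
      )
    )
    check_fixture(model)
    model
  })
}

# Generator contract checks: the functional transcript must encode the
# designed protein as its best ORF, and (when the start codon is intronic)
# the canonical transcript must not encode a domain-complete protein.
check_fixture <- function(model) {
  fun <- build_transcript(model, model$meta$functional_states)
  orf <- find_orf(fun$seq)
  if (is.null(orf) || orf$protein != model$meta$protein) {
    sod_error("fixture functional transcript does not encode its protein",
              "sod_config_error")
  }
  if (any(model$meta$functional_states == "retained")) {
    canon <- build_transcript(model, rep("canonical", nrow(model$introns)))
    corf <- find_orf(canon$seq)
    if (!is.null(corf)) {
      v <- domain_check(corf$protein, model$meta$profile)$verdict
      if (v == "complete") {
        sod_error("canonical transcript unexpectedly encodes the full domain",
                  "sod_config_error")
      }
    }
  }
  invisible(model)
}

#' Ready-made fixture genes
#'
#' Convenience constructors pairing the printed intron layouts with a
#' matching exon design.
#'
#' @param seed Integer seed.
#' @return A `gene_model`.
#' @export
cuzn_sod1_fixture <- function(seed = 101L) {
  design <- gene_design(
    cuzn_profile(), utr5_length = 190L, utr3_length = 80L,
    insert_at = c(50L, 95L, 140L, NA, 400L, 500L, 600L, 720L),
    start_pad = 10L
  )
  build_gene_fixture(cuzn_sod1_introns(), design, seed = seed,
                     gene_id = "CuZnsod1")
}

#' @rdname cuzn_sod1_fixture
#' @export
mnsod1_fixture <- function(seed = 102L) {
  design <- gene_design(
    mn_profile(), utr5_length = 60L, utr3_length = 60L,
    insert_at = c(100L, 300L, 500L)
  )
  build_gene_fixture(mnsod1_introns(), design, seed = seed,
                     gene_id = "Mnsod1")
}

#' @rdname cuzn_sod1_fixture
#' @export
mnsod2_fixture <- function(seed = 103L) {
  design <- gene_design(
    mn_profile(), utr5_length = 60L, utr3_length = 80L,
    insert_at = c(80L, 180L, 280L, 380L, 480L, 580L, 680L)
  )
  build_gene_fixture(mnsod2_introns(), design, seed = seed,
                     gene_id = "Mnsod2")
}

# Isoform mixtures -----------------------------------------------------------

#' Default isoform mixture of a fixture gene
#'
#' The canonical transcript takes `canonical_prop` of the mixture; the
#' remainder is split equally over single-event variants (one per
#' non-canonical state of each intron).
#'
#' @param model A `gene_model` with `states`.
#' @param canonical_prop Proportion of the canonical transcript.
#' @return Tibble with `isoform`, `prop` and a `states` list-column.
#' @export
default_mixture <- function(model, canonical_prop = 0.7) {
  n <- nrow(model$introns)
  canon <- rep("canonical", n)
  variants <- list()
  labels <- character()
  for (i in seq_len(n)) {
    for (st in setdiff(model$states[[i]], "canonical")) {
      v <- canon
      v[i] <- st
      variants[[length(variants) + 1L]] <- v
      labels <- c(labels, paste0(model$introns$intron[i], ".",
                                 gsub("[()+]", "", st)))
    }
  }
  if (length(variants) == 0L) {
    return(tibble(isoform = "canonical", prop = 1,
                  states = list(canon)))
  }
  tibble(
    isoform = c("canonical", labels),
    prop = c(canonical_prop,
             rep((1 - canonical_prop) / length(variants), length(variants))),
    states = c(list(canon), variants)
  )
}

#' Read-simulation configuration
#'
#' Fragment sizes follow a Normal(`fragment_mean`, `fragment_sd`) truncated
#' to `[2 * read_length, fragment_max]`; sequencing errors are substitutions
#' only.
#'
#' @param read_length Mate length in bp.
#' @param fragment_mean,fragment_sd,fragment_max Fragment-size model.
#' @param coverage Total depth over the mixture.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed (recorded in the output).
#' @return A `sim_config` list.
#' @export
sim_config <- function(read_length = 75L, fragment_mean = 300,
                       fragment_sd = 50, fragment_max = 1000,
                       coverage = 30, error_rate = 0.005, seed = 1L) {
  structure(
    list(read_length = as.integer(read_length), fragment_mean = fragment_mean,
         fragment_sd = fragment_sd, fragment_min = 2L * as.integer(read_length),
         fragment_max = fragment_max, coverage = coverage,
         error_rate = error_rate, seed = as.integer(seed)),
    class = "sim_config"
  )
}

inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (length(hit) == 0L) return(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    for (p in hit) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
    }
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate paired-end reads from an isoform mixture
#'
#' Fragments are sampled from each isoform in proportion to
#' `coverage * prop * length`; mate 1 is the fragment 5' end, mate 2 the
#' reverse complement of its 3' end. Provenance (source isoform and fragment
#' start in transcript coordinates) is recorded. The same seed yields
#' byte-identical output.
#'
#' @param model A `gene_model`.
#' @param mixture Tibble as from [default_mixture()]; proportions must sum
#'   to 1.
#' @param config A [sim_config()].
#' @return Tibble with `pair_id`, `isoform`, `frag_start`, `frag_len`,
#'   `read1`, `qual1`, `read2`, `qual2`; the config is attached as an
#'   attribute.
#' @export
simulate_read_pairs <- function(model, mixture = default_mixture(model),
                                config = sim_config()) {
  if (abs(sum(mixture$prop) - 1) > 1e-9) {
    sod_error("mixture proportions must sum to 1", "sod_config_error")
  }
  R <- config$read_length
  qual <- strrep("I", R)
  with_seed(config$seed, {
    out <- lapply(seq_len(nrow(mixture)), function(i) {
      tx <- build_transcript(model, mixture$states[[i]])
      L <- nchar(tx$seq)
      n_frag <- as.integer(round(config$coverage * mixture$prop[i] * L /
                                   (2L * R)))
      if (n_frag == 0L) return(NULL)
      fmax <- min(config$fragment_max, L)
      if (fmax < config$fragment_min) {
        sod_error("isoform shorter than the minimum fragment size",
                  "sod_config_error")
      }
      flen <- integer(n_frag)
      for (f in seq_len(n_frag)) {
        ok <- FALSE
        for (attempt in seq_len(1000L)) {
          x <- round(rnorm(1L, config$fragment_mean, config$fragment_sd))
          if (x >= config$fragment_min && x <= fmax) {
            flen[f] <- as.integer(x)
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          sod_error("could not sample a fragment fitting the isoform",
                    "sod_config_error")
        }
      }
      fstart <- vapply(flen, function(fl) sample.int(L - fl + 1L, 1L) - 1L,
                       integer(1))
      r1 <- substr0(tx$seq, fstart, fstart + R)
      r2 <- revcomp(substr0(tx$seq, fstart + flen - R, fstart + flen))
      tibble(
        pair_id = sprintf("%s_%s_f%05d", model$gene_id, mixture$isoform[i],
                          seq_len(n_frag)),
        isoform = mixture$isoform[i],
        frag_start = fstart, frag_len = flen,
        read1 = inject_errors(r1, config$error_rate), qual1 = qual,
        read2 = inject_errors(r2, config$error_rate), qual2 = qual
      )
    })
    res <- dplyr::bind_rows(out)
    attr(res, "sim_config") <- config
    res
  })
}

# qPCR Ct tables --------------------------------------------------------------

#' Design of a synthetic qPCR experiment
#'
#' @param genes Target gene names.
#' @param conditions Condition/tissue names; the first is the calibrator
#'   unless `calibrator` says otherwise.
#' @param folds Tibble with `gene`, `condition`, `fold`: true expression of
#'   each gene in each condition relative to the calibrator (all > 0).
#' @param replicates Biological replicates per condition (>= 3).
#' @param baseline_ct Target-gene Ct in the calibrator condition.
#' @param reference_ct Reference-gene Ct (constant across conditions).
#' @param sd Gaussian Ct noise standard deviation, in cycles.
#' @param reference_sd Noise standard deviation for the reference gene;
#'   defaults to `sd`. Use 0 for a constant reference gene.
#' @param reference_gene Reference gene name.
#' @param calibrator Calibrator condition.
#' @param seed Integer seed.
#' @return A `ct_design` list.
#' @export
ct_design <- function(genes, conditions, folds, replicates = 4L,
                      baseline_ct = 24, reference_ct = 18, sd = 0.05,
                      reference_sd = sd, reference_gene = "gapdh",
                      calibrator = conditions[1], seed = 1L) {
  if (replicates < 3L) {
    sod_error("at least 3 replicates are required", "sod_config_error")
  }
  folds <- as_tibble(folds)
  if (any(folds$fold <= 0)) {
    sod_error("true fold changes must be positive", "sod_config_error")
  }
  structure(
    list(genes = genes, conditions = conditions, folds = folds,
         replicates = as.integer(replicates), baseline_ct = baseline_ct,
         reference_ct = reference_ct, sd = sd, reference_sd = reference_sd,
         reference_gene = reference_gene, calibrator = calibrator,
         seed = as.integer(seed)),
    class = "ct_design"
  )
}

#' Generate a replicate Ct table with known fold-change effects
#'
#' The generative model is the inverse of the 2^-ddCt statistic: a gene with
#' true fold F in a condition gets Ct = baseline - log2(F) + N(0, sd), while
#' the reference gene sits at its own constant baseline + N(0, sd).
#'
#' @param design A [ct_design()].
#' @return Tibble with `condition`, `gene`, `replicate`, `ct`.
#' @export
generate_ct_table <- function(design) {
  with_seed(design$seed, {
    grid <- tidyr::expand_grid(
      condition = design$conditions,
      gene = c(design$genes, design$reference_gene),
      replicate = seq_len(design$replicates)
    )
    fold <- rep(1, nrow(grid))
    key <- paste(grid$gene, grid$condition)
    fk <- paste(design$folds$gene, design$folds$condition)
    hit <- match(key, fk)
    fold[!is.na(hit)] <- design$folds$fold[hit[!is.na(hit)]]
    base <- ifelse(grid$gene == design$reference_gene,
                   design$reference_ct, design$baseline_ct)
    is_ref <- grid$gene == design$reference_gene
    noise_sd <- ifelse(is_ref, design$reference_sd, design$sd)
    ct <- base - ifelse(is_ref, 0, log2(fold)) +
      rnorm(nrow(grid), 0, noise_sd)
    out <- dplyr::mutate(grid, ct = ct)
    attr(out, "ct_design") <- design
    out
  })
}

# Decoy proteomes -------------------------------------------------------------

#' Generate a synthetic proteome with embedded SOD profiles
#'
#' Decoys are uniform random amino-acid sequences, rejection-sampled so that
#' none reaches a `partial` or `complete` verdict against any supplied
#' profile; embedded sequences carry a full residue profile at
#' alignment-consistent positions.
#'
#' @param n_decoys Number of decoy sequences (>= 0).
#' @param embedded_profiles List of [domain_profile()] objects to embed, one
#'   synthetic family member each.
#' @param seed Integer seed.
#' @param length_range Decoy length range.
#' @param config [screen_config()] used for the rejection check.
#' @return Tibble with `id`, `residues`.
#' @export
generate_proteome <- function(n_decoys, embedded_profiles = list(), seed = 1L,
                              length_range = c(120L, 250L),
                              config = screen_config()) {
  profiles <- default_domain_profiles()
  with_seed(seed, {
    emb <- lapply(seq_along(embedded_profiles), function(i) {
      p <- embedded_profiles[[i]]
      tibble(
        id = paste0("sod_", p$family, "_", i),
        residues = profile_member(p, sample.int(1e6, 1L))
      )
    })
    dec <- lapply(seq_len(n_decoys), function(i) {
      repeat {
        len <- sample(length_range[1]:length_range[2], 1L)
        s <- paste(sample(AA_ALPHABET[1:20], len, replace = TRUE),
                   collapse = "")
        verdicts <- vapply(profiles, function(p) {
          domain_check(s, p, config = config)$verdict
        }, character(1))
        if (all(verdicts == "absent")) {
          return(tibble(id = sprintf("decoy%04d", i), residues = s))
        }
      }
    })
    dplyr::bind_rows(c(emb, dec))
  })
}

# Two-family protein alignments ----------------------------------------------

#' Generate a two-family protein alignment for phylogeny exercises
#'
#' Two diverged family ancestors are drawn, members of each family are
#' mutated copies of their ancestor, and a few low-coverage (gappy) columns
#' are appended so that partial deletion has something to remove.
#'
#' @param n_per_family Members per family.
#' @param n_columns Ungapped alignment columns.
#' @param within Per-site mutation probability within a family.
#' @param gap_columns Number of appended columns gapped in most rows.
#' @param seed Integer seed.
#' @return Tibble with `id`, `sequence` (aligned, equal lengths).
#' @export
generate_family_alignment <- function(n_per_family = 4L, n_columns = 120L,
                                      within = 0.05, gap_columns = 6L,
                                      seed = 1L) {
  with_seed(seed, {
    aa <- AA_ALPHABET[1:20]
    anc_a <- sample(aa, n_columns, replace = TRUE)
    anc_b <- anc_a
    flip <- runif(n_columns) < 0.5
    anc_b[flip] <- vapply(anc_b[flip],
                          function(x) sample(setdiff(aa, x), 1L), character(1))
    member <- function(anc) {
      m <- anc
      hit <- runif(n_columns) < within
      m[hit] <- vapply(m[hit], function(x) sample(setdiff(aa, x), 1L),
                       character(1))
      m
    }
    rows <- c(
      lapply(seq_len(n_per_family), function(i) c("A", i, member(anc_a))),
      lapply(seq_len(n_per_family), function(i) c("B", i, member(anc_b)))
    )
    n_rows <- length(rows)
    gappy <- replicate(gap_columns, {
      col <- rep("-", n_rows)
      keep <- sample.int(n_rows, 2L)
      col[keep] <- sample(aa, 2L, replace = TRUE)
      col
    })
    tibble(
      id = vapply(rows, function(r) paste0(r[1], "_", r[2]), character(1)),
      sequence = vapply(seq_len(n_rows), function(i) {
        paste(c(rows[[i]][-(1:2)], gappy[i, ]), collapse = "")
      }, character(1))
    )
  })
}
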