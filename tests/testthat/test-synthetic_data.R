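test_that("fixture genes carry the studied intron layouts", {
  lens <- function(m) m$introns$end - m$introns$start
  expect_equal(lens(fx_cuzn()), c(52L, 76L, 80L, 125L, 57L, 58L, 54L, 55L))
  expect_equal(lens(fx_mn1()), c(154L, 57L, 56L))
  expect_equal(lens(fx_mn2()), c(47L, 72L, 126L, 119L, 88L, 61L, 87L))
  for (m in fx_fixtures()) {
    expect_true(all(m$introns$donor == "GT"))
    expect_true(all(m$introns$acceptor == "AG"))
  }
})

test_that("a zero-intron gene is the concatenation of its exons", {
  design <- gene_design(mn_profile(), utr5_length = 40L, utr3_length = 40L)
  g <- build_gene_fixture(mnsod1_introns()[0, ], design, seed = 9,
                          gene_id = "flat")
  expect_equal(nrow(g$introns), 0L)
  expect_equal(g$seq, g$meta$mrna_functional)
  expect_equal(model_exons(g), tibble::tibble(start = 0L, end = nchar(g$seq)))
})

test_that("the initiation codon sits inside the retainable intron", {
  g <- fx_cuzn()
  fun <- build_transcript(g, g$meta$functional_states)
  orf <- find_orf(fun$seq)
  # the functional ORF's ATG is the first ATG of the retained-I4 transcript
  expect_equal(as.integer(regexpr("ATG", fun$seq, fixed = TRUE)) - 1L,
               orf$start)
  expect_equal(orf$protein, g$meta$protein)
  # the canonical transcript has no start codon for the domain-complete frame
  canon <- build_transcript(g, rep("canonical", 8))
  corf <- find_orf(canon$seq)
  if (!is.null(corf)) {
    expect_false(domain_check(corf$protein, g$meta$profile)$verdict ==
                   "complete")
  }
  expect_true(nchar(canon$seq) < nchar(fun$seq))
})

test_that("simulated mate counts follow the coverage formula", {
  g <- fx_mn1()
  mix <- tibble::tibble(isoform = "canonical", prop = 1,
                        states = list(rep("canonical", 3)))
  L <- nchar(build_transcript(g, mix$states[[1]])$seq)
  cfg <- sim_config(coverage = 30, error_rate = 0, seed = 3)
  reads <- simulate_read_pairs(g, mix, cfg)
  expect_lt(abs(2 * nrow(reads) - 30 * L / 75), 0.1 * 30 * L / 75)
})

test_that("error-free mates are exact isoform substrings; seeds reproduce", {
  g <- fx_mn1()
  cfg <- sim_config(coverage = 10, error_rate = 0, seed = 5)
  reads <- simulate_read_pairs(g, config = cfg)
  mix <- default_mixture(g)
  txs <- setNames(
    lapply(mix$states, function(s) build_transcript(g, s)$seq),
    mix$isoform
  )
  for (i in seq_len(min(nrow(reads), 25L))) {
    tx <- txs[[reads$isoform[i]]]
    expect_true(grepl(reads$read1[i], tx, fixed = TRUE))
    expect_true(grepl(revcomp(reads$read2[i]), tx, fixed = TRUE))
  }
  again <- simulate_read_pairs(g, config = cfg)
  expect_identical(as.data.frame(reads), as.data.frame(again))
  p1 <- withr::local_tempfile()
  p2 <- withr::local_tempfile()
  write_fastq_pairs(reads, p1)
  write_fastq_pairs(again, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("Ct tables invert the 2^-ddCt statistic exactly at zero noise", {
  des <- ct_design(
    genes = "g", conditions = c("control", "treated"),
    folds = tibble::tibble(gene = "g", condition = "treated", fold = 1),
    replicates = 3, sd = 0, seed = 1
  )
  ct <- generate_ct_table(des)
  dct <- ct$ct[ct$gene == "g"] - ct$ct[ct$gene == "gapdh"]
  expect_true(all(dct == dct[1]))

  des4 <- ct_design(
    genes = "g", conditions = c("control", "treated"),
    folds = tibble::tibble(gene = "g", condition = "treated", fold = 4),
    replicates = 3, sd = 0, seed = 1
  )
  ct4 <- generate_ct_table(des4)
  treated <- ct4$ct[ct4$gene == "g" & ct4$condition == "treated"]
  control <- ct4$ct[ct4$gene == "g" & ct4$condition == "control"]
  expect_equal(unique(control - treated), 2)
})

test_that("proteome generation embeds profiles and is seed-deterministic", {
  prof <- cuzn_profile()
  p0 <- generate_proteome(0, list(prof), seed = 11)
  expect_equal(nrow(p0), 1L)
  refs <- tibble::tibble(id = "ref", family = "CuZn",
                         residues = prof$reference)
  hits <- screen_proteome(p0, refs)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$verdict, "complete")

  a <- generate_proteome(5, list(prof), seed = 12)
  b <- generate_proteome(5, list(prof), seed = 12)
  expect_identical(a, b)
})

test_that("family alignments are rectangular with unique labels", {
  al <- generate_family_alignment(seed = 2)
  expect_equal(length(unique(nchar(al$sequence))), 1L)
  expect_false(anyDuplicated(al$id) > 0)
  expect_equal(sum(startsWith(al$id, "A_")), 4L)
})
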