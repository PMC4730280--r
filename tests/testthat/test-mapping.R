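test_that("error-free exonic mates align as single exact blocks", {
  g <- fx_cuzn()
  # both mates inside the long internal exon [513, 608) + downstream region
  r1 <- substring(g$seq, 514, 588) # genomic [513, 588)
  r2 <- revcomp(substring(g$seq, 531, 605))
  aln <- map_reads(
    tibble::tibble(pair_id = "p1", read1 = r1, read2 = r2), g$seq
  )
  expect_equal(nrow(aln), 2L)
  expect_true(all(aln$n_blocks == 1L))
  expect_true(all(aln$mismatches == 0L))
  expect_equal(aln$start1[aln$mate == 1], 513L)
  expect_equal(aln$end1[aln$mate == 1], 588L)
  # emitted blocks are exact reference substrings
  expect_equal(substring(g$seq, aln$start1[1] + 1, aln$end1[1]), r1)
})

test_that("a mate straddling a spliced-out 80 bp intron splits at GT/AG", {
  g <- fx_cuzn()
  i3 <- g$introns[g$introns$intron == "I3", ]
  # 40 bases of the upstream exon, then 35 bases after the intron
  read <- paste0(substring(g$seq, i3$start - 39, i3$start),
                 substring(g$seq, i3$end + 1, i3$end + 35))
  mate2 <- revcomp(substring(g$seq, i3$end + 1, i3$end + 75))
  aln <- map_reads(tibble::tibble(pair_id = "p", read1 = read, read2 = mate2),
                   g$seq)
  spliced <- aln[aln$mate == 1, ]
  expect_equal(spliced$n_blocks, 2L)
  expect_equal(c(spliced$start1, spliced$end1), c(i3$start - 40L, i3$start))
  expect_equal(c(spliced$start2, spliced$end2), c(i3$end, i3$end + 35L))
  expect_equal(spliced$end2 - spliced$start1 - 75L, 80L) # the skip
  expect_equal(substring(g$seq, spliced$end1 + 1, spliced$end1 + 2), "GT")
  expect_equal(substring(g$seq, spliced$start2 - 1, spliced$start2), "AG")
})

test_that("pairs spanning more than the allowed distance are rejected", {
  set.seed(77)
  ref <- paste(sample(c("A", "C", "G", "T"), 3500, replace = TRUE),
               collapse = "")
  pair <- tibble::tibble(
    pair_id = "far",
    read1 = substring(ref, 101, 175),
    read2 = revcomp(substring(ref, 3101, 3175))
  )
  expect_equal(nrow(map_reads(pair, ref)), 0L)
  wide <- map_reads(pair, ref, mapper_config(span_max = 5000L))
  expect_equal(nrow(wide), 2L)
})

test_that("genome mode is contiguous and exact", {
  g <- fx_mn1()
  i1 <- g$introns[1, ]
  junction_read <- paste0(substring(g$seq, i1$start - 39, i1$start),
                          substring(g$seq, i1$end + 1, i1$end + 35))
  contiguous <- substring(g$seq, i1$start - 39, i1$start + 35)
  aln <- map_reads(
    tibble::tibble(pair_id = c("jx", "contig"),
                   read1 = c(junction_read, contiguous),
                   read2 = revcomp(c(junction_read, contiguous))),
    g$seq, mapper_config(mode = "genome")
  )
  expect_equal(unique(aln$read_id), "contig")
  expect_true(all(aln$n_blocks == 1L))
})

test_that("transcription bounds follow covered coordinates monotonically", {
  one <- tibble::tibble(
    read_id = "r", mate = 1L, strand = "+", mismatches = 0L, n_blocks = 1L,
    start1 = 10L, end1 = 85L, rstart1 = 0L,
    start2 = NA_integer_, end2 = NA_integer_, rstart2 = NA_integer_
  )
  expect_equal(determine_bounds(one), list(tss = 10L, tes = 85L))
  more <- dplyr::bind_rows(one, dplyr::mutate(one, start1 = 5L, end1 = 60L))
  b <- determine_bounds(more)
  expect_lte(b$tss, 10L)
  expect_gte(b$tes, 85L)
  expect_error(determine_bounds(one[0, ]), class = "sod_evidence_error")
})

test_that("coverage verification reports minimum depth and gaps", {
  full <- tibble::tibble(
    read_id = "r", mate = 1L, strand = "+", mismatches = 0L, n_blocks = 1L,
    start1 = 0L, end1 = 100L, rstart1 = 0L,
    start2 = NA_integer_, end2 = NA_integer_, rstart2 = NA_integer_
  )
  prof <- coverage_profile(full, c(0L, 100L))
  expect_true(prof$verified)
  expect_equal(prof$min_depth, 1L)

  split <- dplyr::bind_rows(
    dplyr::mutate(full, end1 = 40L),
    dplyr::mutate(full, start1 = 60L)
  )
  prof2 <- coverage_profile(split, c(0L, 100L))
  expect_false(prof2$verified)
  expect_equal(prof2$gaps, tibble::tibble(start = 40L, end = 60L))
})

test_that("mapping is order-independent", {
  g <- fx_mn1()
  reads <- simulate_read_pairs(
    g, config = sim_config(coverage = 10, error_rate = 0.005, seed = 8)
  )
  a <- map_reads(reads, g$seq)
  b <- map_reads(reads[sample(nrow(reads)), ], g$seq)
  expect_equal(dplyr::arrange(a, read_id, mate),
               dplyr::arrange(b, read_id, mate))
})
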