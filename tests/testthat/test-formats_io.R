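test_that("FASTA reading folds case, concatenates lines and keeps order", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "acgt"), p)
  rec <- read_fasta(p)
  expect_equal(rec$id, "a")
  expect_equal(rec$residues, "ACGT")

  writeLines(c(">a", "AC", "GT", ">b", "TT"), p)
  rec <- read_fasta(p)
  expect_equal(rec$residues, c("ACGT", "TT"))
  expect_equal(rec$id, c("a", "b"))
})

test_that("FASTA errors name duplicate ids and reject empty files", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "TT"), p)
  expect_error(read_fasta(p), "'a'", class = "sod_format_error")
  writeLines(character(), p)
  expect_error(read_fasta(p), class = "sod_format_error")
})

test_that("FASTA round-trips through write_fasta", {
  p <- withr::local_tempfile(fileext = ".fasta")
  recs <- tibble::tibble(
    id = c("s1", "s2"),
    description = c("first record", ""),
    residues = c(strrep("ACGT", 40), "TTGGA")
  )
  write_fasta(recs, p)
  back <- read_fasta(p)
  expect_equal(back, recs)
})

test_that("FASTQ is decoded as Phred+33 with strict record structure", {
  p <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r/1", "ACGT", "+", "IIII"), p)
  rec <- read_fastq(p)
  expect_equal(phred33_scores(rec$quality), rep(40L, 4))

  writeLines(c("@r", "ACGT", "+", "II"), p)
  expect_error(read_fastq(p), "'r'", class = "sod_format_error")
})

test_that("paired FASTQ modes detect pairing problems", {
  p1 <- withr::local_tempfile(fileext = ".fastq")
  p2 <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1/1", "ACGT", "+", "IIII", "@r2/1", "ACGT", "+", "IIII"), p1)
  writeLines(c("@r1/2", "TTTT", "+", "IIII"), p2)
  expect_error(read_fastq_pairs(p1, p2), class = "sod_format_error")

  writeLines(c("@r1/2", "TTTT", "+", "IIII", "@r2/2", "AAAA", "+", "IIII"), p2)
  pairs <- read_fastq_pairs(p1, p2)
  expect_equal(pairs$pair_id, c("r1", "r2"))

  write_fastq_pairs(pairs, p1) # interleaved round trip
  expect_equal(read_fastq_pairs(p1), pairs)
})

test_that("GFF3 output is 1-based inclusive and round-trips the model", {
  m <- gene_model("g1", "ACGTAC", tss = 0L, tes = 6L)
  lines <- write_gff3(m)
  expect_equal(lines[1], "##gff-version 3")
  exon <- strsplit(grep("\texon\t", lines, value = TRUE), "\t")[[1]]
  expect_equal(as.integer(exon[4:5]), c(1L, 6L))

  g <- fx_cuzn()
  back <- read_gff3(write_gff3(g), g$seq)
  expect_equal(back$introns, g$introns)
  expect_equal(c(back$tss, back$tes), c(g$tss, g$tes))
  expect_equal(back$strand, g$strand)
})

test_that("minus-strand genes are written on the forward strand, ascending", {
  seq <- paste0(strrep("A", 10), "GTAG", strrep("C", 16))
  m <- gene_model("gm", seq, introns = tibble::tibble(start = 10L, end = 14L),
                  tss = 2L, tes = 27L, strand = "-")
  lines <- write_gff3(m)
  body <- lines[!startsWith(lines, "#")]
  fields <- do.call(rbind, strsplit(body, "\t"))
  starts <- as.integer(fields[, 4])
  expect_true(all(fields[, 7] == "-"))
  # hand-converted: region length 30, gene [2,27) -> 4..28, intron [10,14) -> 17..20
  expect_equal(as.integer(fields[fields[, 3] == "gene", 4:5]), c(4L, 28L))
  expect_equal(as.integer(fields[fields[, 3] == "intron", 4:5]), c(17L, 20L))
  expect_true(all(diff(starts[fields[, 3] %in% c("exon", "intron")]) >= 0))
  back <- read_gff3(lines, seq)
  expect_equal(back$introns, m$introns)
  expect_equal(c(back$tss, back$tes, back$strand), c(m$tss, m$tes, m$strand))
})

test_that("Newick writing matches the standard format and round-trips", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.2);")
  expect_equal(write_newick(tr), "(A:0.1,B:0.2);")
  set.seed(42)
  big <- ape::rtree(8)
  back <- read_newick(write_newick(big))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(back), ape::unroot(big))), 0)
  expect_equal(sort(back$edge.length), sort(big$edge.length), tolerance = 1e-8)
})

test_that("Ct CSV round-trips and validates its schema", {
  p <- withr::local_tempfile(fileext = ".csv")
  ct <- generate_ct_table(ct_design(
    genes = "g", conditions = c("a", "b"),
    folds = tibble::tibble(gene = "g", condition = "b", fold = 2),
    replicates = 3, seed = 4
  ))
  write_ct_csv(ct, p)
  attr(ct, "ct_design") <- NULL
  expect_equal(as.data.frame(read_ct_csv(p)), as.data.frame(ct),
               tolerance = 1e-12)
  writeLines("x,y\n1,2", p)
  expect_error(read_ct_csv(p), class = "sod_format_error")
})
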